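# Periodic table: symbols indexed by atomic number.
ELEMENT_SYMBOLS <- c(
  "H", "He", "Li", "Be", "B", "C", "N", "O", "F", "Ne",
  "Na", "Mg", "Al", "Si", "P", "S", "Cl", "Ar", "K", "Ca",
  "Sc", "Ti", "V", "Cr", "Mn", "Fe", "Co", "Ni", "Cu", "Zn",
  "Ga", "Ge", "As", "Se", "Br", "Kr", "Rb", "Sr", "Y", "Zr",
  "Nb", "Mo", "Tc", "Ru", "Rh", "Pd", "Ag", "Cd", "In", "Sn",
  "Sb", "Te", "I", "Xe", "Cs", "Ba", "La", "Ce", "Pr", "Nd",
  "Pm", "Sm", "Eu", "Gd", "Tb", "Dy", "Ho", "Er", "Tm", "Yb",
  "Lu", "Hf", "Ta", "W", "Re", "Os", "Ir", "Pt", "Au", "Hg",
  "Tl", "Pb", "Bi", "Po", "At", "Rn", "Fr", "Ra", "Ac", "Th",
  "Pa", "U", "Np", "Pu", "Am", "Cm", "Bk", "Cf", "Es", "Fm",
  "Md", "No", "Lr", "Rf", "Db", "Sg", "Bh", "Hs", "Mt", "Ds",
  "Rg", "Cn", "Nh", "Fl", "Mc", "Lv", "Ts", "Og"
)

# Organic-subset symbols that may be written without brackets, and the
# default valences used to infer implicit hydrogen counts.
ORGANIC_SUBSET <- c("B", "C", "N", "O", "P", "S", "F", "Cl", "Br", "I")
AROMATIC_ORGANIC <- c("b", "c", "n", "o", "p", "s")
AROMATIC_BRACKET <- c("b", "c", "n", "o", "p", "s", "se", "as")

DEFAULT_VALENCES <- list(
  B = 3L, C = 4L, N = 3L, O = 2L, P = c(3L, 5L), S = c(2L, 4L, 6L),
  F = 1L, Cl = 1L, Br = 1L, I = 1L
)

symbol_to_z <- function(sym) {
  z <- match(sym, ELEMENT_SYMBOLS)
  z
}

#' First n prime numbers
#'
#' Simple sieve-backed prime lookup used for the corresponding-prime encoding
#' of ranks and ring sizes (`prime(1) = 2`, `prime(3) = 5`, `prime(6) = 13`).
#'
#' @param n How many leading primes to return.
#' @return Integer vector of the first `n` primes.
#' @examples
#' nth_primes(6) # 2 3 5 7 11 13
#' @export
nth_primes <- function(n) {
  stopifnot(n >= 1)
  limit <- max(15L, ceiling(n * (log(n + 1) + log(log(n + 3)) + 1)))
  repeat {
    is_p <- rep(TRUE, limit)
    is_p[1L] <- FALSE
    p <- 2L
    while (p * p <= limit) {
      if (is_p[p]) is_p[seq.int(p * p, limit, by = p)] <- FALSE
      p <- p + 1L
    }
    primes <- which(is_p)
    if (length(primes) >= n) return(primes[seq_len(n)])
    limit <- limit * 2L
  }
}
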