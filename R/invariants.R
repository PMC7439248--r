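# Atomic invariants: the 12-character local vector (+ 1 chirality digit),
# per-bond smallest-ring sizes, the prime-product ring invariant, and the
# weighted distance-shell invariant. Together they seed the initial ranks
# for extended-connectivity refinement.

#' Local invariant vector of an atom
#'
#' Twelve digits concatenated in fixed order: degree (1), atomic number (3),
#' attached hydrogens (1), charge sign (1; '1' only for negative), absolute
#' charge (1), connectivity (degree + H, 1), valence (bond-order sum + H, 1),
#' atomic mass (3, '000' when unspecified). The degree leads so that terminal
#' atoms sort first and are preferred as traversal starting points.
#'
#' @param mol A normalized `molecule`.
#' @param chirality_digits Optional integer vector of per-atom chirality
#'   invariants (0/1/2) appended as the 13th character; default all zero.
#' @return Character vector of 13-digit strings, one per atom.
#' @examples
#' local_vectors(parse_smiles("C")) # "0006400044000"
#' @export
local_vectors <- function(mol, chirality_digits = NULL) {
  n <- n_atoms(mol)
  if (is.null(chirality_digits)) chirality_digits <- integer(n)
  deg <- mol_degree(mol)
  bsum <- numeric(n)
  if (nrow(mol$bonds)) {
    for (k in seq_len(nrow(mol$bonds))) {
      o <- mol$bonds$kek_order[k]
      bsum[mol$bonds$a[k]] <- bsum[mol$bonds$a[k]] + o
      bsum[mol$bonds$b[k]] <- bsum[mol$bonds$b[k]] + o
    }
  }
  h <- mol$atoms$h_count
  q <- mol$atoms$charge
  conn <- deg + h
  val <- bsum + h
  if (any(deg > 9L)) stop("unsupported structure: atom degree > 9")
  if (any(abs(q) > 9L)) stop("unsupported structure: |charge| > 9")
  if (any(conn > 9L) || any(val > 9L)) stop("unsupported structure: connectivity or valence > 9")
  if (any(mol$atoms$z > 999L)) stop("unsupported structure: atomic number > 999")
  if (any(mol$atoms$isotope > 999L)) stop("unsupported structure: isotope mass > 999")
  sprintf("%d%03d%d%d%d%d%d%03d%d",
          deg, mol$atoms$z, h,
          as.integer(q < 0L), abs(q), conn, as.integer(val),
          mol$atoms$isotope, as.integer(chirality_digits))
}

#' Smallest ring size through each bond
#'
#' For every bond, a breadth-first search from one endpoint to the other in
#' the graph with that bond removed gives the shortest alternative path; the
#' smallest ring containing the bond has one more edge than that path. Bonds
#' on no ring get 0.
#'
#' @param mol A `molecule`.
#' @return The molecule with `bonds$ring_size` filled.
#' @examples
#' m <- bond_ring_sizes(parse_smiles("C1CC1"))
#' m$bonds$ring_size # 3 3 3
#' @export
bond_ring_sizes <- function(mol) {
  nb <- nrow(mol$bonds)
  if (!nb) return(mol)
  sizes <- integer(nb)
  for (k in seq_len(nb)) {
    path <- shortest_path_excluding(mol, mol$bonds$a[k], mol$bonds$b[k], k)
    sizes[k] <- if (is.null(path)) 0L else length(path)
  }
  mol$bonds$ring_size <- sizes
  mol
}

# TRUE for atoms that lie on at least one ring bond (ring sizes must be filled)
ring_atom_flags <- function(mol) {
  flags <- rep(FALSE, n_atoms(mol))
  on <- mol$bonds$ring_size > 0L
  flags[mol$bonds$a[on]] <- TRUE
  flags[mol$bonds$b[on]] <- TRUE
  flags
}

#' Prime-product ring invariant of each atom
#'
#' The product, over the atom's bonds, of the s-th prime where s is the
#' bond's smallest ring size (factor 1 for acyclic bonds): e.g. an atom with
#' three bonds all in 3-membered rings gets 5·5·5 = 125, and one with two
#' 3-ring bonds and one 6-ring bond gets 5·5·13 = 325. Unique factorization
#' makes the product unambiguous: factoring it back recovers the multiset of
#' incident smallest-ring sizes.
#'
#' @param mol A `molecule` with `bonds$ring_size` filled (see
#'   [bond_ring_sizes()]; computed here if missing).
#' @return List with `value` (numeric; exact while below 2^53), `big` (limb
#'   representation) and `key` (fixed-width hex, ordered like the value).
#' @export
ring_invariants <- function(mol) {
  if (nrow(mol$bonds) && anyNA(mol$bonds$ring_size)) mol <- bond_ring_sizes(mol)
  n <- n_atoms(mol)
  max_s <- if (nrow(mol$bonds)) max(mol$bonds$ring_size, 1L) else 1L
  primes <- nth_primes(max_s)
  bigs <- replicate(n, big_from_num(1), simplify = FALSE)
  if (nrow(mol$bonds)) {
    for (k in seq_len(nrow(mol$bonds))) {
      s <- mol$bonds$ring_size[k]
      if (s == 0L) next
      p <- primes[s]
      a <- mol$bonds$a[k]; b <- mol$bonds$b[k]
      bigs[[a]] <- big_mul_small(bigs[[a]], p)
      bigs[[b]] <- big_mul_small(bigs[[b]], p)
    }
  }
  width <- max(vapply(bigs, length, integer(1)))
  list(
    value = vapply(bigs, big_to_num, numeric(1)),
    big = bigs,
    key = vapply(bigs, big_hex, character(1), width = width)
  )
}

#' Distance-shell invariant and NOON of each atom
#'
#' BFS from each atom counts how many atoms sit at every topological
#' distance d; the invariant is the weighted sum count(d) * base^(d-1), so
#' with base 10 the decimal digits (read right to left) are the shell
#' counts. NOON, the number of the outermost occupied neighbour sphere, is
#' the atom's eccentricity. Shell counts >= base simply carry over; the
#' comparison key stays exact.
#'
#' @param mol A `molecule`.
#' @param base Positional weight base (default 10, reproducing decimal shell
#'   digits; set to `n_atoms(mol)` for carry-free behaviour).
#' @return List with `value` (numeric, exact below 2^53), `noon`, `big`,
#'   `key`.
#' @export
distance_invariants <- function(mol, base = 10L) {
  n <- n_atoms(mol)
  adj <- mol_adjacency(mol)
  bigs <- vector("list", n)
  noon <- integer(n)
  for (s in seq_len(n)) {
    dist <- rep(-1L, n)
    dist[s] <- 0L
    queue <- s
    while (length(queue)) {
      v <- queue[1L]; queue <- queue[-1L]
      for (w in adj[[v]]$nbr) if (dist[w] < 0L) { dist[w] <- dist[v] + 1L; queue <- c(queue, w) }
    }
    ecc <- max(dist)
    noon[s] <- max(ecc, 0L)
    counts <- if (ecc >= 1L) tabulate(dist[dist > 0L], nbins = ecc) else integer(0)
    v <- big_from_num(0)
    for (d in rev(seq_along(counts))) {   # Horner: value = sum counts[d]*base^(d-1)
      v <- big_mul_small(v, base)
      v <- big_add_small(v, counts[d])
    }
    bigs[[s]] <- v
  }
  width <- max(vapply(bigs, length, integer(1)))
  list(
    value = vapply(bigs, big_to_num, numeric(1)),
    noon = noon,
    big = bigs,
    key = vapply(bigs, big_hex, character(1), width = width)
  )
}

#' Chirality invariant digits
#'
#' Translates `@`/`@@` parity into a label-independent digit using the
#' symmetry classes of the neighbours computed *without* chirality: 0 for no
#' parity or when two neighbours share a class; otherwise the count of `@`
#' in the symbol when the written neighbour classes are an even permutation
#' of ascending order, else 3 minus that count. The implicit-H placeholder
#' ranks below every atom class.
#'
#' @param mol A normalized `molecule`.
#' @param achiral_classes Integer vector: per-atom symmetry class from the
#'   rank pipeline run with all chirality digits forced to 0.
#' @param strict Error instead of warn when parity sits on an atom without 4
#'   neighbour positions.
#' @return Integer vector of digits 0/1/2 per atom.
#' @export
chirality_invariants <- function(mol, achiral_classes, strict = FALSE) {
  n <- n_atoms(mol)
  out <- integer(n)
  for (i in which(mol$atoms$chiral > 0L)) {
    nbrs <- mol$nbr_order[[i]]
    if (length(nbrs) != 4L) {
      msg <- sprintf("atom %d: parity with %d neighbour positions", i, length(nbrs))
      if (strict) stop(msg) else warning(msg, "; invariant set to 0")
      next
    }
    cls <- integer(4L)
    cls[nbrs != -1L] <- achiral_classes[nbrs[nbrs != -1L]]
    if (anyDuplicated(cls)) next
    even <- permutation_is_even(rank(cls))
    out[i] <- if (even) mol$atoms$chiral[i] else 3L - mol$atoms$chiral[i]
  }
  out
}

# Parity of the permutation given as a rank vector (TRUE = even).
permutation_is_even <- function(perm) {
  inv <- 0L
  n <- length(perm)
  for (i in seq_len(n - 1L)) inv <- inv + sum(perm[(i + 1L):n] < perm[i])
  inv %% 2L == 0L
}

#' Initial atom ranks from the combined invariants
#'
#' Sorts atoms ascending by the key (13-digit invariant vector, ring
#' invariant, distance invariant); equal keys share a rank and ranks are
#' consecutive integers starting at 1.
#'
#' @inheritParams local_vectors
#' @param base Base for the distance invariant.
#' @return List with `ranks` (integer per atom) and the component invariants
#'   (`vector13`, `ring`, `distance`) for diagnostics.
#' @examples
#' initial_ranks(bond_ring_sizes(parse_smiles("CC1CO1")))$ranks # 1 4 2 3
#' @export
initial_ranks <- function(mol, chirality_digits = NULL, base = 10L) {
  if (nrow(mol$bonds) && anyNA(mol$bonds$ring_size)) mol <- bond_ring_sizes(mol)
  vec <- local_vectors(mol, chirality_digits)
  ring <- ring_invariants(mol)
  dist <- distance_invariants(mol, base = base)
  key <- paste0(vec, ring$key, dist$key)
  ranks <- match(key, sort(unique(key)))
  list(ranks = as.integer(ranks), vector13 = vec, ring = ring, distance = dist)
}
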