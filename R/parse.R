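# SMILES reader for the supported dialect: organic-subset and bracket atoms,
# charges, isotopes, explicit H counts, single/double/triple/aromatic bonds,
# branches, ring closures (digits and %nn), tetrahedral @/@@ chirality.
# Directional bonds (/ \), wildcard atoms and reaction arrows are rejected.

parse_error <- function(msg, offset) {
  stop(structure(
    class = c("smiles_parse_error", "error", "condition"),
    list(message = sprintf("SMILES parse error at position %d: %s", offset, msg),
         call = NULL, offset = offset)
  ))
}

#' Parse a SMILES string into a molecular graph
#'
#' Builds the molecule atom by atom, preserving the written neighbour order
#' (previous atom, then the implicit-H placeholder of a chiral bracket atom,
#' then ring closures at their digit position, then branches), which is what
#' gives the `@`/`@@` parity symbols their meaning. Implicit hydrogen counts
#' of organic-subset atoms are filled from the default-valence model after
#' kekulization of any aromatic system.
#'
#' @param text A single SMILES string.
#' @param perceive_aromaticity Detect aromatic rings written in Kekulé form
#'   (simple planar rings satisfying the 4n+2 electron count) and mark them
#'   aromatic. Lowercase input is trusted either way.
#' @return A `molecule` object.
#' @examples
#' mol <- parse_smiles("CC1CO1")
#' n_atoms(mol)
#' @export
parse_smiles <- function(text, perceive_aromaticity = TRUE) {
  stopifnot(is.character(text), length(text) == 1L, nzchar(text))
  chars <- strsplit(text, "", fixed = TRUE)[[1L]]
  n_ch <- length(chars)

  atoms <- list()   # each: list(z, aromatic, charge, isotope, h, h_explicit, chiral)
  bonds <- list()   # each: list(a, b, sym) sym in "", "-", "=", "#", ":"
  nbr <- list()     # written neighbour order; NA entries are unresolved ring digits
  last_atom <- 0L   # 0 = none (start or after '.')
  stack <- integer(0)
  pending <- NULL   # pending bond symbol with its offset
  rings <- list()   # open ring closures: key = digit label

  add_atom <- function(a) {
    atoms[[length(atoms) + 1L]] <<- a
    nbr[[length(atoms)]] <<- integer(0)
    length(atoms)
  }
  bond_exists <- function(a, b) {
    any(vapply(bonds, function(bd) (bd$a == a && bd$b == b) || (bd$a == b && bd$b == a), logical(1)))
  }
  add_bond <- function(a, b, sym, offset) {
    if (a == b) parse_error("ring closure bonds an atom to itself", offset)
    if (bond_exists(a, b)) parse_error("duplicate bond between the same atoms", offset)
    bonds[[length(bonds) + 1L]] <<- list(a = a, b = b, sym = sym)
  }

  finish_atom <- function(idx, offset) {
    # bond to previous atom, consuming any pending bond symbol
    if (last_atom > 0L) {
      sym <- if (is.null(pending)) "" else pending$sym
      add_bond(last_atom, idx, sym, offset)
      nbr[[last_atom]] <<- c(nbr[[last_atom]], idx)
      nbr[[idx]] <<- c(nbr[[idx]], last_atom)
    } else if (!is.null(pending)) {
      parse_error("bond symbol with no preceding atom", pending$offset)
    }
    pending <<- NULL
    last_atom <<- idx
  }

  i <- 1L
  while (i <= n_ch) {
    ch <- chars[i]
    if (ch == "(") {
      if (last_atom == 0L) parse_error("branch with no preceding atom", i)
      if (!is.null(pending)) parse_error("bond symbol before '('", i)
      stack <- c(stack, last_atom)
      i <- i + 1L
    } else if (ch == ")") {
      if (!length(stack)) parse_error("unbalanced ')'", i)
      if (!is.null(pending)) parse_error("dangling bond symbol before ')'", i)
      last_atom <- stack[length(stack)]
      stack <- stack[-length(stack)]
      i <- i + 1L
    } else if (ch == ".") {
      if (length(stack)) parse_error("'.' inside a branch", i)
      if (!is.null(pending)) parse_error("bond symbol before '.'", i)
      last_atom <- 0L
      i <- i + 1L
    } else if (ch %in% c("-", "=", "#", ":")) {
      if (!is.null(pending)) parse_error("two consecutive bond symbols", i)
      pending <- list(sym = ch, offset = i)
      i <- i + 1L
    } else if (ch %in% c("/", "\\")) {
      parse_error("directional bonds are not supported", i)
    } else if (ch == "*") {
      parse_error("wildcard atoms are not supported", i)
    } else if (grepl("[0-9%]", ch)) {
      # ring closure label
      if (last_atom == 0L) parse_error("ring closure digit with no preceding atom", i)
      if (ch == "%") {
        if (i + 2L > n_ch || !grepl("^[0-9][0-9]$", paste0(chars[i + 1L], chars[i + 2L])))
          parse_error("'%' must be followed by two digits", i)
        label <- paste0(chars[i + 1L], chars[i + 2L])
        i <- i + 3L
      } else {
        label <- ch
        i <- i + 1L
      }
      key <- as.character(as.integer(label))
      sym <- if (is.null(pending)) "" else pending$sym
      sym_off <- if (is.null(pending)) i - 1L else pending$offset
      pending <- NULL
      if (is.null(rings[[key]])) {
        nbr[[last_atom]] <- c(nbr[[last_atom]], NA_integer_)
        rings[[key]] <- list(atom = last_atom, pos = length(nbr[[last_atom]]),
                             sym = sym, offset = sym_off)
      } else {
        open <- rings[[key]]
        rings[[key]] <- NULL
        if (nzchar(open$sym) && nzchar(sym) && open$sym != sym)
          parse_error(sprintf("conflicting bond symbols on ring closure %s", key), sym_off)
        use_sym <- if (nzchar(open$sym)) open$sym else sym
        add_bond(open$atom, last_atom, use_sym, i - 1L)
        nbr[[open$atom]][open$pos] <- last_atom
        nbr[[last_atom]] <- c(nbr[[last_atom]], open$atom)
      }
    } else if (ch == "[") {
      res <- parse_bracket_atom(chars, i)
      idx <- add_atom(res$atom)
      finish_atom(idx, i)
      if (res$atom$h >= 1L) nbr[[idx]] <- c(nbr[[idx]], -1L)
      i <- res$next_i
    } else {
      # organic-subset atom (aliphatic or aromatic shorthand)
      two <- if (i < n_ch) paste0(ch, chars[i + 1L]) else ""
      if (two %in% c("Cl", "Br")) {
        sym <- two; i <- i + 2L
      } else if (ch %in% c("B", "C", "N", "O", "P", "S", "F", "I")) {
        sym <- ch; i <- i + 1L
      } else if (ch %in% AROMATIC_ORGANIC) {
        sym <- ch; i <- i + 1L
      } else {
        parse_error(sprintf("unexpected character '%s'", ch), i)
      }
      arom <- sym %in% AROMATIC_ORGANIC
      z <- symbol_to_z(if (arom) paste0(toupper(substr(sym, 1, 1)), substr(sym, 2, 10)) else sym)
      idx <- add_atom(list(z = z, aromatic = arom, charge = 0L, isotope = 0L,
                           h = NA_integer_, h_explicit = FALSE, chiral = 0L))
      finish_atom(idx, i - 1L)
    }
  }

  if (length(stack)) parse_error("unbalanced '(': branch never closed", n_ch)
  if (!is.null(pending)) parse_error("dangling bond symbol at end of input", pending$offset)
  if (length(rings)) {
    open <- rings[[1L]]
    parse_error(sprintf("unclosed ring closure digit %s", names(rings)[1L]), open$offset)
  }
  if (!length(atoms)) parse_error("no atoms in input", 1L)

  mol <- assemble_molecule(atoms, bonds, nbr)
  mol <- kekulize(mol)
  mol <- infer_implicit_h(mol)
  if (perceive_aromaticity) mol <- perceive_aromatic_rings(mol)
  mol
}

# Bracket atom grammar: [isotope? symbol chiral? Hcount? charge?]
parse_bracket_atom <- function(chars, i0) {
  i <- i0 + 1L
  n_ch <- length(chars)
  take_digits <- function() {
    s <- ""
    while (i <= n_ch && grepl("[0-9]", chars[i])) { s <- paste0(s, chars[i]); i <<- i + 1L }
    s
  }
  iso_s <- take_digits()
  isotope <- if (nzchar(iso_s)) as.integer(iso_s) else 0L

  if (i > n_ch) parse_error("unterminated bracket atom", i0)
  # element symbol: try two-character forms first
  two <- if (i < n_ch) paste0(chars[i], chars[i + 1L]) else ""
  one <- chars[i]
  arom <- FALSE
  if (two %in% AROMATIC_BRACKET) {
    sym <- two; arom <- TRUE; i <- i + 2L
  } else if (grepl("^[A-Z][a-z]$", two) && !is.na(symbol_to_z(two))) {
    sym <- two; i <- i + 2L
  } else if (one %in% AROMATIC_BRACKET) {
    sym <- one; arom <- TRUE; i <- i + 1L
  } else if (grepl("^[A-Z]$", one) && !is.na(symbol_to_z(one))) {
    sym <- one; i <- i + 1L
  } else {
    parse_error(sprintf("unknown element symbol '%s'", one), i)
  }
  z <- symbol_to_z(if (arom) paste0(toupper(substr(sym, 1, 1)), substr(sym, 2, 10)) else sym)

  chiral <- 0L
  if (i <= n_ch && chars[i] == "@") {
    chiral <- 1L; i <- i + 1L
    if (i <= n_ch && chars[i] == "@") { chiral <- 2L; i <- i + 1L }
  }

  h <- 0L
  if (i <= n_ch && chars[i] == "H") {
    i <- i + 1L
    hs <- take_digits()
    h <- if (nzchar(hs)) as.integer(hs) else 1L
  }

  charge <- 0L
  if (i <= n_ch && chars[i] %in% c("+", "-")) {
    sign <- if (chars[i] == "+") 1L else -1L
    first <- chars[i]
    i <- i + 1L
    reps <- 1L
    while (i <= n_ch && chars[i] == first) { reps <- reps + 1L; i <- i + 1L }
    if (reps == 1L) {
      cs <- take_digits()
      charge <- sign * (if (nzchar(cs)) as.integer(cs) else 1L)
    } else {
      charge <- sign * reps
    }
  }

  if (i > n_ch || chars[i] != "]")
    parse_error("expected ']' to close bracket atom", min(i, n_ch))
  list(atom = list(z = z, aromatic = arom, charge = charge, isotope = isotope,
                   h = h, h_explicit = TRUE, chiral = chiral),
       next_i = i + 1L)
}

assemble_molecule <- function(atoms, bonds, nbr) {
  adf <- data.frame(
    z = vapply(atoms, function(a) a$z, integer(1)),
    aromatic = vapply(atoms, function(a) a$aromatic, logical(1)),
    charge = vapply(atoms, function(a) a$charge, integer(1)),
    isotope = vapply(atoms, function(a) a$isotope, integer(1)),
    h_count = vapply(atoms, function(a) a$h, integer(1)),
    chiral = vapply(atoms, function(a) a$chiral, integer(1)),
    h_explicit = vapply(atoms, function(a) a$h_explicit, logical(1))
  )
  nb <- length(bonds)
  a_idx <- vapply(bonds, function(b) b$a, integer(1))
  b_idx <- vapply(bonds, function(b) b$b, integer(1))
  syms <- vapply(bonds, function(b) b$sym, character(1))
  arom_bond <- syms == ":" |
    (syms == "" & adf$aromatic[a_idx] & adf$aromatic[b_idx])
  order <- ifelse(syms == "=", 2L, ifelse(syms == "#", 3L, 1L))
  bdf <- data.frame(
    a = a_idx, b = b_idx,
    order = as.integer(order),
    aromatic = as.logical(arom_bond),
    kek_order = as.integer(order),
    ring_size = rep(NA_integer_, nb)
  )
  new_molecule(adf, bdf, nbr)
}

#' Read a SMILES line file
#'
#' One molecule per line, `SMILES[\t id]`; lines starting with `#` and blank
#' lines are skipped.
#'
#' @param path File path or connection.
#' @return data.frame with columns `smiles`, `id`, `line`.
#' @export
read_smiles_lines <- function(path) {
  lines <- readLines(path, warn = FALSE)
  keep <- which(nzchar(trimws(lines)) & !startsWith(trimws(lines), "#"))
  parts <- strsplit(lines[keep], "\t", fixed = TRUE)
  data.frame(
    smiles = vapply(parts, `[`, character(1), 1L),
    id = vapply(parts, function(p) if (length(p) > 1L) p[2L] else NA_character_, character(1)),
    line = keep
  )
}
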