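# SMILES generation: depth-first traversal guided by canonical ranks.
#
# Pass 1 walks the graph from the lowest-ranked atom (neighbours in
# ascending rank) and classifies each bond as tree or chord (ring closure).
# Pass 2 fixes the emission order, ring-closure digits and each atom's
# output neighbour order. Pass 3 compares the output neighbour order of
# every chiral atom with its written input order and keeps or inverts the
# parity symbol accordingly. The string is then assembled.

#' Generate a SMILES string for a given rank assignment
#'
#' @param mol A normalized, connected `molecule`.
#' @param ranks Integer per-atom ranks; the traversal starts at the
#'   lowest-ranked atom and branches toward lower ranks first. Ranks must be
#'   unique on ring atoms for a canonical traversal; remaining ties are
#'   broken by atom index (symmetric acyclic subtrees emit identical
#'   substrings).
#' @return List with `smiles`, `atom_output_order` and `ring_closure_bonds`
#'   (bond indices emitted as digit pairs).
#' @export
generate_smiles <- function(mol, ranks) {
  n <- n_atoms(mol)
  stopifnot(length(ranks) == n)
  adj <- mol_adjacency(mol)
  key <- order(ranks, seq_len(n))
  root <- key[1L]

  # pass 1: spanning tree + chords, neighbours in ascending (rank, index)
  parent <- integer(n)            # 0 = root/unvisited
  parent_bond <- integer(n)
  children <- vector("list", n)
  bond_state <- integer(max(1L, nrow(mol$bonds)))  # 0 unseen, 1 tree, 2 chord
  visited <- rep(FALSE, n)
  visited[root] <- TRUE
  dfs1 <- function(v) {
    ord <- order(ranks[adj[[v]]$nbr], adj[[v]]$nbr)
    for (j in ord) {
      w <- adj[[v]]$nbr[j]; bk <- adj[[v]]$bond[j]
      if (bond_state[bk] != 0L) next
      if (!visited[w]) {
        bond_state[bk] <<- 1L
        visited[w] <<- TRUE
        parent[w] <<- v; parent_bond[w] <<- bk
        children[[v]] <<- c(children[[v]], w)
        dfs1(w)
      } else {
        bond_state[bk] <<- 2L
      }
    }
  }
  dfs1(root)
  if (!all(visited)) stop("molecule is not connected; canonicalize components separately")
  chords <- which(bond_state == 2L)

  # pass 2: emission order, digit assignment, output neighbour orders
  emit_pos <- integer(n)
  out_nbr <- vector("list", n)
  chord_events <- vector("list", n)  # per atom: list of (digit, open, bond)
  digit_of_chord <- integer(length(bond_state))
  free_digits <- rep(TRUE, 99L)
  pos <- 0L
  walk <- function(v) {
    pos <<- pos + 1L
    emit_pos[v] <<- pos
    ord_n <- integer(0)
    if (parent[v] > 0L) ord_n <- parent[v]
    if (mol$atoms$h_count[v] >= 1L && mol$atoms$chiral[v] > 0L) ord_n <- c(ord_n, -1L)
    # chords at v in ascending (partner rank, partner index)
    inc <- adj[[v]]$bond
    ch <- inc[inc %in% chords]
    if (length(ch)) {
      partner <- ifelse(mol$bonds$a[ch] == v, mol$bonds$b[ch], mol$bonds$a[ch])
      for (t in order(ranks[partner], partner)) {
        bk <- ch[t]; w <- partner[t]
        if (digit_of_chord[bk] == 0L) {
          d <- which(free_digits)[1L]
          if (is.na(d)) stop("more than 99 simultaneous open ring closures")
          free_digits[d] <<- FALSE
          digit_of_chord[bk] <<- d
          chord_events[[v]] <<- c(chord_events[[v]], list(list(digit = d, open = TRUE, bond = bk)))
        } else {
          d <- digit_of_chord[bk]
          free_digits[d] <<- TRUE
          chord_events[[v]] <<- c(chord_events[[v]], list(list(digit = d, open = FALSE, bond = bk)))
        }
        ord_n <- c(ord_n, w)
      }
    }
    for (w in children[[v]]) {
      ord_n <- c(ord_n, w)
      walk(w)
    }
    out_nbr[[v]] <<- ord_n
  }
  walk(root)

  # pass 3: parity symbols relative to the written neighbour order
  parity <- integer(n)  # 0 none, 1 @, 2 @@
  for (i in which(mol$atoms$chiral > 0L)) {
    inp <- mol$nbr_order[[i]]
    outp <- out_nbr[[i]]
    if (length(inp) != 4L || length(outp) != 4L || !setequal(inp, outp)) {
      warning(sprintf("atom %d: cannot map chiral neighbour order; parity dropped", i))
      next
    }
    even <- permutation_is_even(match(outp, inp))
    parity[i] <- if (even) mol$atoms$chiral[i] else 3L - mol$atoms$chiral[i]
  }

  # string assembly
  build <- function(v) {
    s <- atom_token(mol, v, parity[v])
    for (ev in chord_events[[v]]) {
      if (ev$open) s <- paste0(s, bond_token(mol, ev$bond))
      s <- paste0(s, if (ev$digit <= 9L) ev$digit else sprintf("%%%02d", ev$digit))
    }
    kids <- children[[v]]
    if (length(kids)) {
      for (t in seq_along(kids)) {
        w <- kids[t]
        seg <- paste0(bond_token(mol, parent_bond[w]), build(w))
        s <- paste0(s, if (t < length(kids)) paste0("(", seg, ")") else seg)
      }
    }
    s
  }
  smiles <- build(root)
  list(smiles = smiles, atom_output_order = order(emit_pos),
       ring_closure_bonds = chords)
}

bond_token <- function(mol, k) {
  if (mol$bonds$aromatic[k]) return("")
  o <- mol$bonds$order[k]
  if (o == 2L) return("=")
  if (o == 3L) return("#")
  # explicit single between two aromatic atoms (e.g. biphenyl)
  if (mol$atoms$aromatic[mol$bonds$a[k]] && mol$atoms$aromatic[mol$bonds$b[k]]) return("-")
  ""
}

# H count the reader would infer for this atom written bare; NA if the
# element is outside the organic subset. For aromatic atoms this simulates
# the reader's kekulization of the *bare* spelling (a bare aromatic n is
# pyridine-like and takes a double bond; [nH] does not), so e.g. pyrrole
# nitrogen correctly falls back to a bracket atom.
inferred_h_for_write <- function(mol, v) {
  sym <- ELEMENT_SYMBOLS[mol$atoms$z[v]]
  vals <- DEFAULT_VALENCES[[sym]]
  if (is.null(vals)) return(NA_integer_)
  inc <- which(mol$bonds$a == v | mol$bonds$b == v)
  if (!mol$atoms$aromatic[v]) {
    bsum <- sum(mol$bonds$kek_order[inc])
  } else {
    sigma <- sum(ifelse(mol$bonds$aromatic[inc], 1L, mol$bonds$order[inc]))
    has_multi <- any(!mol$bonds$aromatic[inc] & mol$bonds$order[inc] > 1L)
    z <- mol$atoms$z[v]
    needy_bare <- !has_multi &&
      (z == 6L || (z %in% c(7L, 15L) && length(inc) == 2L))
    bsum <- sigma + as.integer(needy_bare)
  }
  fit <- vals[vals >= bsum]
  if (length(fit)) as.integer(fit[1L] - bsum) else 0L
}

atom_token <- function(mol, v, parity = 0L) {
  sym <- ELEMENT_SYMBOLS[mol$atoms$z[v]]
  arom <- mol$atoms$aromatic[v]
  wsym <- if (arom) tolower(sym) else sym
  bare_ok <- mol$atoms$charge[v] == 0L && mol$atoms$isotope[v] == 0L &&
    parity == 0L &&
    ((arom && wsym %in% AROMATIC_ORGANIC) || (!arom && sym %in% ORGANIC_SUBSET)) &&
    identical(mol$atoms$h_count[v], inferred_h_for_write(mol, v))
  if (bare_ok) return(wsym)
  h <- mol$atoms$h_count[v]
  q <- mol$atoms$charge[v]
  paste0(
    "[",
    if (mol$atoms$isotope[v] > 0L) mol$atoms$isotope[v] else "",
    wsym,
    c("", "@", "@@")[parity + 1L],
    if (h == 1L) "H" else if (h > 1L) paste0("H", h) else "",
    if (q > 0L) paste0("+", if (q > 1L) q else "") else "",
    if (q < 0L) paste0("-", if (q < -1L) -q else "") else "",
    "]"
  )
}
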