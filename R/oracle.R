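# Brute-force oracles, independent of the invariant/refinement pipeline:
# exact automorphism orbits and graph isomorphism by backtracking over
# label- and adjacency-preserving vertex maps. Used only for validation.

atom_labels_oracle <- function(mol) {
  paste(mol$atoms$z, mol$atoms$charge, mol$atoms$isotope,
        mol$atoms$h_count, mol$atoms$aromatic, sep = "/")
}

bond_label_matrix <- function(mol) {
  n <- n_atoms(mol)
  m <- matrix(0L, n, n)
  if (nrow(mol$bonds)) {
    lab <- ifelse(mol$bonds$aromatic, 9L, mol$bonds$order)
    m[cbind(mol$bonds$a, mol$bonds$b)] <- lab
    m[cbind(mol$bonds$b, mol$bonds$a)] <- lab
  }
  m
}

# Backtracking search for structure-preserving maps molA -> molB.
# callback(perm) is invoked per complete map; return FALSE from it to stop.
search_maps <- function(molA, molB, callback) {
  nA <- n_atoms(molA); nB <- n_atoms(molB)
  if (nA != nB) return(invisible(NULL))
  labA <- atom_labels_oracle(molA); labB <- atom_labels_oracle(molB)
  if (!identical(sort(labA), sort(labB))) return(invisible(NULL))
  bmA <- bond_label_matrix(molA); bmB <- bond_label_matrix(molB)
  degA <- mol_degree(molA); degB <- mol_degree(molB)
  adjA <- mol_adjacency(molA)

  # vertex order: BFS so each new vertex has a mapped neighbour (max pruning)
  ord <- integer(0); seen <- rep(FALSE, nA)
  for (s in seq_len(nA)) {
    if (seen[s]) next
    queue <- s; seen[s] <- TRUE
    while (length(queue)) {
      v <- queue[1L]; queue <- queue[-1L]
      ord <- c(ord, v)
      for (w in adjA[[v]]$nbr) if (!seen[w]) { seen[w] <- TRUE; queue <- c(queue, w) }
    }
  }

  perm <- integer(nA)      # image in B, 0 = unmapped
  used <- rep(FALSE, nB)
  go_on <- TRUE
  bt <- function(k) {
    if (!go_on) return(invisible(NULL))
    if (k > nA) {
      if (isFALSE(callback(perm))) go_on <<- FALSE
      return(invisible(NULL))
    }
    v <- ord[k]
    mapped_nbrs <- adjA[[v]]$nbr[perm[adjA[[v]]$nbr] != 0L]
    for (w in seq_len(nB)) {
      if (used[w] || labA[v] != labB[w] || degA[v] != degB[w]) next
      ok <- TRUE
      for (u in mapped_nbrs) {
        if (bmA[v, u] != bmB[w, perm[u]]) { ok <- FALSE; break }
      }
      if (ok) {
        # also: w must not be adjacent to images of non-neighbours of v
        img <- perm[perm != 0L]
        if (length(img)) {
          vb <- bmB[w, img]
          va <- bmA[v, which(perm != 0L)]
          if (!identical(va, vb)) ok <- FALSE
        }
      }
      if (!ok) next
      perm[v] <<- w; used[w] <<- TRUE
      bt(k + 1L)
      perm[v] <<- 0L; used[w] <<- FALSE
      if (!go_on) return(invisible(NULL))
    }
  }
  bt(1L)
  invisible(NULL)
}

#' Exact automorphism orbits by exhaustive search
#'
#' Enumerates every adjacency-, element- and bond-label-preserving
#' permutation of the molecular graph and partitions atoms into the orbits
#' of the automorphism group. Exponential in the worst case; intended for
#' validation graphs (roughly up to 24 atoms with the built-in pruning).
#'
#' @param mol A `molecule`.
#' @return List with `orbit` (integer orbit id per atom), `n_orbits` and
#'   `group_order` (|Aut|).
#' @examples
#' orbit_oracle(parse_smiles("CCC"))$n_orbits # 2 (ends vs middle)
#' @export
orbit_oracle <- function(mol) {
  n <- n_atoms(mol)
  parent <- seq_len(n)
  find <- function(x) { while (parent[x] != x) { parent[x] <<- parent[parent[x]]; x <- parent[x] }; x }
  unite <- function(a, b) { ra <- find(a); rb <- find(b); if (ra != rb) parent[ra] <<- rb }
  count <- 0L
  search_maps(mol, mol, function(perm) {
    count <<- count + 1L
    for (i in seq_len(n)) unite(i, perm[i])
    TRUE
  })
  roots <- vapply(seq_len(n), find, integer(1))
  list(orbit = match(roots, unique(roots)), n_orbits = length(unique(roots)),
       group_order = count)
}

#' Graph isomorphism test (brute force)
#'
#' @param molA,molB Two `molecule` objects.
#' @return TRUE if a structure-preserving bijection exists.
#' @export
is_isomorphic <- function(molA, molB) {
  found <- FALSE
  search_maps(molA, molB, function(perm) { found <<- TRUE; FALSE })
  found
}
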