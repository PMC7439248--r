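# Valence model and kekulization.
#
# Implicit hydrogen counts follow the standard default valences (B 3, C 4,
# N 3, O 2, P 3/5, S 2/4/6, halogens 1). Aromatic systems are assigned a
# Kekulé structure first so that bond-order sums (and hence H counts and the
# valence digit of the atomic invariant vector) are well defined.

# Which aromatic atoms must carry exactly one double bond in a Kekulé
# structure. Minimal documented ruleset for the supported dialect.
kekule_needs_double <- function(mol) {
  n <- n_atoms(mol)
  needs <- rep(FALSE, n)
  if (!any(mol$atoms$aromatic)) return(needs)
  deg <- mol_degree(mol)
  # atoms with an explicit double/triple bond are saturated already
  has_multi <- rep(FALSE, n)
  multi <- mol$bonds$order > 1L & !mol$bonds$aromatic
  has_multi[mol$bonds$a[multi]] <- TRUE
  has_multi[mol$bonds$b[multi]] <- TRUE
  for (i in seq_len(n)) {
    if (!mol$atoms$aromatic[i] || has_multi[i]) next
    z <- mol$atoms$z[i]; q <- mol$atoms$charge[i]
    h <- if (mol$atoms$h_explicit[i]) mol$atoms$h_count[i] else 0L
    if (z == 6L) {
      needs[i] <- q == 0L
    } else if (z %in% c(7L, 15L)) {
      needs[i] <- (q == 0L && h == 0L && deg[i] == 2L) ||
                  (q == 1L && h == 0L && deg[i] == 3L)
    } else if (z %in% c(8L, 16L, 34L)) {
      needs[i] <- q == 1L && deg[i] == 2L
    }
  }
  needs
}

# Assign a Kekulé structure: perfect matching over aromatic bonds restricted
# to the atoms that need a double bond. Backtracking search; molecules in the
# supported dialect are small enough that this is instant.
kekulize <- function(mol) {
  if (!any(mol$bonds$aromatic)) return(mol)
  needs <- kekule_needs_double(mol)
  if (!any(needs)) return(mol)
  adj <- mol_adjacency(mol)
  matched <- integer(n_atoms(mol))   # partner atom, 0 = unmatched
  bond_of <- integer(n_atoms(mol))
  order <- which(needs)

  try_match <- function(k) {
    if (k > length(order)) return(TRUE)
    v <- order[k]
    if (matched[v] != 0L) return(try_match(k + 1L))
    for (j in seq_along(adj[[v]]$nbr)) {
      w <- adj[[v]]$nbr[j]; bk <- adj[[v]]$bond[j]
      if (!mol$bonds$aromatic[bk] || !needs[w] || matched[w] != 0L) next
      matched[v] <<- w; matched[w] <<- v
      bond_of[v] <<- bk; bond_of[w] <<- bk
      if (try_match(k + 1L)) return(TRUE)
      matched[v] <<- 0L; matched[w] <<- 0L
    }
    FALSE
  }
  if (!try_match(1L)) stop("cannot kekulize aromatic system")
  dbl <- unique(bond_of[bond_of > 0L])
  mol$bonds$kek_order[dbl] <- 2L
  mol
}

# Fill implicit H counts for organic-subset atoms (bracket atoms keep their
# written count).
infer_implicit_h <- function(mol) {
  need <- !mol$atoms$h_explicit
  if (!any(need)) { mol$atoms$h_count[is.na(mol$atoms$h_count)] <- 0L; return(mol) }
  bsum <- numeric(n_atoms(mol))
  if (nrow(mol$bonds)) {
    for (k in seq_len(nrow(mol$bonds))) {
      o <- mol$bonds$kek_order[k]
      bsum[mol$bonds$a[k]] <- bsum[mol$bonds$a[k]] + o
      bsum[mol$bonds$b[k]] <- bsum[mol$bonds$b[k]] + o
    }
  }
  for (i in which(need)) {
    sym <- ELEMENT_SYMBOLS[mol$atoms$z[i]]
    vals <- DEFAULT_VALENCES[[sym]]
    if (is.null(vals)) { mol$atoms$h_count[i] <- 0L; next }
    fit <- vals[vals >= bsum[i]]
    mol$atoms$h_count[i] <- if (length(fit)) as.integer(fit[1L] - bsum[i]) else 0L
  }
  mol
}

# Minimal aromaticity perception for rings written in Kekulé form: a simple
# ring (size 5-7) all of whose atoms are sp2-capable and whose pi-electron
# count satisfies Hückel's 4n+2 is marked aromatic. Fused-system perception
# beyond shared single rings is out of scope and documented as such.
perceive_aromatic_rings <- function(mol) {
  if (!nrow(mol$bonds)) return(mol)
  if (!any(mol$bonds$order == 2L)) return(mol)    # needs at least one double bond
  rings <- smallest_rings(mol)
  if (!length(rings)) return(mol)
  adj <- mol_adjacency(mol)
  bond_lookup <- function(a, b) {
    j <- which((mol$bonds$a == a & mol$bonds$b == b) | (mol$bonds$a == b & mol$bonds$b == a))
    j[1L]
  }
  for (ring in rings) {
    m <- length(ring)
    if (m < 5L || m > 7L) next
    ring_bonds <- vapply(seq_len(m), function(t) {
      bond_lookup(ring[t], ring[if (t == m) 1L else t + 1L])
    }, integer(1))
    pi_e <- 0L; ok <- TRUE
    for (v in ring) {
      z <- mol$atoms$z[v]; q <- mol$atoms$charge[v]
      inc <- adj[[v]]$bond
      dbl_in <- any(mol$bonds$order[intersect(inc, ring_bonds)] == 2L)
      dbl_out <- any(mol$bonds$order[setdiff(inc, ring_bonds)] > 1L)
      if (dbl_out || any(mol$bonds$order[inc] == 3L)) { ok <- FALSE; break }
      if (z == 6L && q == 0L) {
        if (!dbl_in) { ok <- FALSE; break }
        pi_e <- pi_e + 1L
      } else if (z %in% c(7L, 15L)) {
        pi_e <- pi_e + if (dbl_in) 1L else 2L
      } else if (z %in% c(8L, 16L, 34L) && !dbl_in) {
        pi_e <- pi_e + 2L
      } else { ok <- FALSE; break }
    }
    if (!ok || pi_e < 2L || (pi_e - 2L) %% 4L != 0L) next
    mol$atoms$aromatic[ring] <- TRUE
    mol$bonds$aromatic[ring_bonds] <- TRUE
    mol$bonds$kek_order[ring_bonds] <- mol$bonds$order[ring_bonds]
    mol$bonds$order[ring_bonds] <- 1L
  }
  mol
}

# Unique smallest rings, one per bond that lies on a ring (as vertex cycles).
smallest_rings <- function(mol) {
  res <- list()
  seen <- character(0)
  for (k in seq_len(nrow(mol$bonds))) {
    path <- shortest_path_excluding(mol, mol$bonds$a[k], mol$bonds$b[k], k)
    if (is.null(path)) next
    ring <- path   # a ... b, closing bond k completes the cycle
    key <- paste(sort(ring), collapse = ",")
    if (key %in% seen) next
    seen <- c(seen, key)
    res[[length(res) + 1L]] <- ring
  }
  res
}

# BFS shortest path from a to b avoiding bond `skip`; NULL if none.
shortest_path_excluding <- function(mol, a, b, skip) {
  n <- n_atoms(mol)
  adj <- mol_adjacency(mol)
  prev <- integer(n)
  seen <- rep(FALSE, n)
  seen[a] <- TRUE
  queue <- a
  while (length(queue)) {
    v <- queue[1L]; queue <- queue[-1L]
    for (j in seq_along(adj[[v]]$nbr)) {
      if (adj[[v]]$bond[j] == skip) next
      w <- adj[[v]]$nbr[j]
      if (seen[w]) next
      seen[w] <- TRUE; prev[w] <- v
      if (w == b) {
        path <- b
        while (path[1L] != a) path <- c(prev[path[1L]], path)
        return(path)
      }
      queue <- c(queue, w)
    }
  }
  NULL
}
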