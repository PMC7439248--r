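# The molecular-graph container shared by every module.
#
# A `molecule` is a list with:
#   atoms     data.frame: z, aromatic, charge, isotope, h_count, chiral
#             (0 = none, 1 = @, 2 = @@), h_explicit (TRUE when the H count
#             came from a bracket atom rather than the valence model)
#   bonds     data.frame: a, b (1-based atom indices, a < b not enforced),
#             order (1/2/3; 1 for aromatic bonds), aromatic, kek_order
#             (order after kekulization; equals order for non-aromatic),
#             ring_size (smallest ring through the bond, 0 = acyclic,
#             NA until computed)
#   nbr_order list per atom: neighbour atom indices in written SMILES order,
#             with -1 marking the implicit-H placeholder of a bracket atom
#             (needed to interpret @/@@)

new_molecule <- function(atoms, bonds, nbr_order) {
  structure(list(atoms = atoms, bonds = bonds, nbr_order = nbr_order),
            class = "molecule")
}

#' @export
print.molecule <- function(x, ...) {
  cat(sprintf("<molecule: %d atoms, %d bonds>\n", n_atoms(x), nrow(x$bonds)))
  invisible(x)
}

#' Number of (heavy) atoms in a molecule
#' @param mol A `molecule`.
#' @return Integer count.
#' @export
n_atoms <- function(mol) nrow(mol$atoms)

# Adjacency as a list of data.frames (nbr, bond) per atom.
mol_adjacency <- function(mol) {
  n <- n_atoms(mol)
  adj <- vector("list", n)
  for (i in seq_len(n)) adj[[i]] <- list(nbr = integer(0), bond = integer(0))
  if (nrow(mol$bonds)) {
    for (k in seq_len(nrow(mol$bonds))) {
      a <- mol$bonds$a[k]; b <- mol$bonds$b[k]
      adj[[a]]$nbr <- c(adj[[a]]$nbr, b); adj[[a]]$bond <- c(adj[[a]]$bond, k)
      adj[[b]]$nbr <- c(adj[[b]]$nbr, a); adj[[b]]$bond <- c(adj[[b]]$bond, k)
    }
  }
  adj
}

mol_degree <- function(mol) {
  deg <- integer(n_atoms(mol))
  if (nrow(mol$bonds)) {
    t <- tabulate(c(mol$bonds$a, mol$bonds$b), nbins = n_atoms(mol))
    deg <- as.integer(t)
  }
  deg
}

# Connected components; returns integer component id per atom.
mol_components <- function(mol) {
  n <- n_atoms(mol)
  comp <- integer(n)
  adj <- mol_adjacency(mol)
  cid <- 0L
  for (s in seq_len(n)) {
    if (comp[s] != 0L) next
    cid <- cid + 1L
    queue <- s; comp[s] <- cid
    while (length(queue)) {
      v <- queue[1L]; queue <- queue[-1L]
      for (w in adj[[v]]$nbr) if (comp[w] == 0L) { comp[w] <- cid; queue <- c(queue, w) }
    }
  }
  comp
}

# Extract one component as a molecule (atom order preserved).
mol_subset <- function(mol, keep) {
  keep <- sort(keep)
  map <- integer(n_atoms(mol)); map[keep] <- seq_along(keep)
  atoms <- mol$atoms[keep, , drop = FALSE]
  rownames(atoms) <- NULL
  bsel <- mol$bonds$a %in% keep & mol$bonds$b %in% keep
  bonds <- mol$bonds[bsel, , drop = FALSE]
  bonds$a <- map[bonds$a]; bonds$b <- map[bonds$b]
  rownames(bonds) <- NULL
  nbr <- lapply(mol$nbr_order[keep], function(v) {
    w <- v
    w[v != -1L] <- map[v[v != -1L]]
    w
  })
  new_molecule(atoms, bonds, nbr)
}

# Build an all-carbon skeleton molecule from an edge list (used by the
# graph-family generators; valence 4 suffices for degree <= 4, atoms with
# higher degree simply get no implicit hydrogens).
molecule_from_graph <- function(n, edges) {
  atoms <- data.frame(
    z = rep(6L, n), aromatic = FALSE, charge = 0L, isotope = 0L,
    h_count = 0L, chiral = 0L, h_explicit = FALSE
  )
  if (length(edges) && !is.matrix(edges)) edges <- matrix(edges, ncol = 2, byrow = TRUE)
  nb <- if (length(edges)) nrow(edges) else 0L
  bonds <- data.frame(
    a = if (nb) as.integer(edges[, 1]) else integer(0),
    b = if (nb) as.integer(edges[, 2]) else integer(0),
    order = rep(1L, nb), aromatic = rep(FALSE, nb),
    kek_order = rep(1L, nb), ring_size = rep(NA_integer_, nb)
  )
  if (nb && any(bonds$a == bonds$b)) stop("self-loop in edge list")
  nbr <- vector("list", n)
  for (i in seq_len(n)) nbr[[i]] <- integer(0)
  for (k in seq_len(nb)) {
    nbr[[bonds$a[k]]] <- c(nbr[[bonds$a[k]]], bonds$b[k])
    nbr[[bonds$b[k]]] <- c(nbr[[bonds$b[k]]], bonds$a[k])
  }
  mol <- new_molecule(atoms, bonds, nbr)
  deg <- mol_degree(mol)
  mol$atoms$h_count <- pmax(0L, 4L - deg)
  mol
}
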