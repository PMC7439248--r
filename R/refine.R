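# Extended-connectivity refinement with powered primes ("Modified CANON").
#
# Each iteration rescores every atom as
#   prime(rank)^power * prod over neighbours prime(neighbour rank)^e(bond)
# and re-ranks the exact scores ascending to consecutive integers. The
# powered leading prime keeps previously distinct ranks from leveling or
# swapping; the bond exponent e() feeds bond orders into the refinement so
# that e.g. non-aromatic annulenes split correctly.

# Exponent applied to a neighbour's prime: single 1, aromatic 2, double 3,
# triple 4. Only the relative order matters; integers keep the arithmetic
# exact. Configurable for experimentation.
DEFAULT_BOND_EXPONENTS <- c(single = 1L, aromatic = 2L, double = 3L, triple = 4L)

bond_exponent <- function(mol, exponents = DEFAULT_BOND_EXPONENTS) {
  ifelse(mol$bonds$aromatic, exponents[["aromatic"]],
         c(exponents[["single"]], exponents[["double"]], exponents[["triple"]])[mol$bonds$order])
}

refine_adjacency <- function(mol, exponents = DEFAULT_BOND_EXPONENTS) {
  n <- n_atoms(mol)
  expo <- bond_exponent(mol, exponents)
  nbrs <- vector("list", n)
  exps <- vector("list", n)
  for (i in seq_len(n)) { nbrs[[i]] <- integer(0); exps[[i]] <- integer(0) }
  if (nrow(mol$bonds)) {
    for (k in seq_len(nrow(mol$bonds))) {
      a <- mol$bonds$a[k]; b <- mol$bonds$b[k]; e <- expo[k]
      nbrs[[a]] <- c(nbrs[[a]], b); exps[[a]] <- c(exps[[a]], e)
      nbrs[[b]] <- c(nbrs[[b]], a); exps[[b]] <- c(exps[[b]], e)
    }
  }
  list(nbr = nbrs, exp = exps)
}

#' Refine an atom partition to stability
#'
#' Iterates the powered-prime scoring until the number of classes stops
#' growing or every atom has a unique rank. The returned ranks are
#' consecutive integers from 1; the partition at each step strictly refines
#' the previous one (an internal check errors if two distinct ranks ever
#' merge).
#'
#' @param mol A normalized `molecule`.
#' @param ranks Integer starting ranks (need not be consecutive).
#' @param power Exponent on the atom's own prime; 8 guarantees stability for
#'   chemical degrees (it is also cheap: three squarings). The worked
#'   3-membered-ring example uses 2.
#' @param exponents Named bond-order exponent map, see
#'   `DEFAULT_BOND_EXPONENTS`.
#' @return Integer vector of refined consecutive ranks.
#' @export
refine_partition <- function(mol, ranks, power = 8L, exponents = DEFAULT_BOND_EXPONENTS) {
  stopifnot(length(ranks) == n_atoms(mol), all(ranks >= 1L), power >= 1L)
  adj <- refine_adjacency(mol, exponents)
  cpp_refine(adj$nbr, adj$exp, as.integer(ranks), as.integer(power))
}

#' One scoring pass, exact scores as decimal strings
#'
#' Exposes a single iteration of the refinement scoring (no re-ranking) for
#' inspection: score = prime(rank)^power times the product of each
#' neighbour's prime(rank)^exponent.
#'
#' @inheritParams refine_partition
#' @return Character vector of exact decimal scores per atom.
#' @examples
#' m <- parse_smiles("CC1CO1")
#' refine_scores(m, initial_ranks(m)$ranks, power = 2) # "28" "1470" "315" "525"
#' @export
refine_scores <- function(mol, ranks, power = 8L, exponents = DEFAULT_BOND_EXPONENTS) {
  stopifnot(length(ranks) == n_atoms(mol), all(ranks >= 1L))
  adj <- refine_adjacency(mol, exponents)
  cpp_score_pass(adj$nbr, adj$exp, as.integer(ranks), as.integer(power))
}

#' Symmetry classes of a molecule's atoms
#'
#' Full perception pipeline: local/ring/distance invariants seed initial
#' ranks, refinement with power 8 yields achiral classes, chirality
#' invariants are assigned from those classes, and (for chiral molecules)
#' the ranking plus refinement is re-run once with the 13th digit in place.
#' The returned ranks group atoms into candidate symmetry classes; atoms in
#' different classes are never automorphic, while rare highly regular graphs
#' may leave non-automorphic atoms in one class (the tiebreaking generator
#' compensates during canonicalization).
#'
#' @param mol A normalized `molecule`.
#' @param power Refinement power (default 8).
#' @param base Distance-invariant base (default 10).
#' @param strict Passed to [chirality_invariants()].
#' @return List with `classes` (integer per atom), `n_classes`, and
#'   `chirality` (the per-atom chirality digits).
#' @examples
#' sc <- symmetry_classes(parse_smiles("C1CC2CCC1CCC3CCC(CC3)CC2"))
#' sc$n_classes # 3
#' @export
symmetry_classes <- function(mol, power = 8L, base = 10L, strict = FALSE) {
  if (nrow(mol$bonds) && anyNA(mol$bonds$ring_size)) mol <- bond_ring_sizes(mol)
  init <- initial_ranks(mol, base = base)
  achiral <- refine_partition(mol, init$ranks, power = power)
  chir <- chirality_invariants(mol, achiral, strict = strict)
  if (any(chir > 0L)) {
    init2 <- initial_ranks(mol, chirality_digits = chir, base = base)
    classes <- refine_partition(mol, init2$ranks, power = power)
  } else {
    classes <- achiral
  }
  list(classes = classes, n_classes = max(classes), chirality = chir)
}
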