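# Tiebreaking on ring atoms and selection of the lexicographically minimal
# SMILES over all complete partitions (the canonical-code-by-automorphism-
# permutation step that makes the output provably label-independent).

#' Break ties on ring atoms
#'
#' While any class of the partition contains two or more ring atoms, the
#' tied ring-atom class with the maximal rank is selected and, for *each*
#' member atom in turn, all ranks are doubled, that atom's rank is reduced
#' by one, and the result is refined and recursed into. The leaves — one per
#' branch path — are partitions whose ring atoms all hold unique ranks.
#'
#' @param mol A normalized `molecule` with ring sizes computed.
#' @param part Integer refined symmetry-class ranks.
#' @param power,exponents Passed to [refine_partition()].
#' @return List of integer rank vectors (complete partitions), one per leaf,
#'   in branch order and with multiplicity.
#' @export
break_ties <- function(mol, part, power = 8L, exponents = DEFAULT_BOND_EXPONENTS) {
  if (nrow(mol$bonds) && anyNA(mol$bonds$ring_size)) mol <- bond_ring_sizes(mol)
  ring <- ring_atom_flags(mol)
  leaves <- list()
  recurse <- function(ranks) {
    tallies <- table(ranks[ring])
    tied <- as.integer(names(tallies)[tallies >= 2L])
    if (!length(tied)) {
      leaves[[length(leaves) + 1L]] <<- ranks
      return(invisible(NULL))
    }
    r_star <- max(tied)
    for (a in which(ranks == r_star & ring)) {
      nxt <- 2L * ranks
      nxt[a] <- nxt[a] - 1L
      recurse(refine_partition(mol, nxt, power = power, exponents = exponents))
    }
  }
  recurse(part)
  leaves
}

#' Canonical SMILES of a molecule
#'
#' Runs the complete pipeline: parsing/normalization (when given a string),
#' symmetry-class perception, chirality processing, exhaustive ring-atom
#' tiebreaking, one depth-first SMILES per complete partition, and selection
#' of the bytewise-lexicographically minimal string. Disconnected inputs are
#' canonicalized per component and joined with `.` in sorted order.
#'
#' @param x A SMILES string or a normalized `molecule`.
#' @param power Refinement power (default 8).
#' @param base Distance-invariant base (default 10).
#' @param strict Escalate normalization/chirality warnings to errors.
#' @return List with `smiles` (the canonical string), `traversal_count`
#'   (number of complete leaf partitions traversed, summed over components)
#'   and `n_classes` (symmetry classes, summed over components).
#' @examples
#' canonical_smiles("OCC")$smiles # "CCO"
#' canonical_smiles("C[C@H]1CC[C@H](N)CC1")$smiles # "C[C@@H]1CC[C@@H](N)CC1"
#' @export
canonical_smiles <- function(x, power = 8L, base = 10L, strict = FALSE) {
  mol <- if (is.character(x)) {
    normalize_molecule(parse_smiles(x), strict = strict)
  } else {
    stopifnot(inherits(x, "molecule"))
    normalize_molecule(x, strict = strict)
  }
  comp <- mol_components(mol)
  strings <- character(0)
  total_traversals <- 0L
  total_classes <- 0L
  for (cid in unique(comp)) {
    sub <- if (max(comp) > 1L) mol_subset(mol, which(comp == cid)) else mol
    sub <- bond_ring_sizes(sub)
    sc <- symmetry_classes(sub, power = power, base = base, strict = strict)
    leaves <- break_ties(sub, sc$classes, power = power)
    total_traversals <- total_traversals + length(leaves)
    total_classes <- total_classes + sc$n_classes
    # identical partitions reached along different branch paths yield the
    # same string; deduplicate before traversal (counts keep multiplicity)
    uniq <- unique(lapply(leaves, paste, collapse = ","))
    best <- NULL
    for (u in uniq) {
      ranks <- as.integer(strsplit(u, ",", fixed = TRUE)[[1L]])
      s <- generate_smiles(sub, ranks)$smiles
      if (is.null(best) || smiles_lt(s, best)) best <- s
    }
    strings <- c(strings, best)
  }
  list(smiles = paste(sort_c(strings), collapse = "."),
       traversal_count = total_traversals,
       n_classes = total_classes)
}

# bytewise ASCII comparison, independent of locale collation
smiles_lt <- function(a, b) {
  cmp <- utf8ToInt(a)
  cmpb <- utf8ToInt(b)
  l <- min(length(cmp), length(cmpb))
  for (i in seq_len(l)) {
    if (cmp[i] != cmpb[i]) return(cmp[i] < cmpb[i])
  }
  length(cmp) < length(cmpb)
}

sort_c <- function(x) {
  if (length(x) <= 1L) return(x)
  x[order(vapply(x, function(s) paste(sprintf("%03d", utf8ToInt(s)), collapse = ""), character(1)))]
}
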