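#' Normalize a parsed molecule
#'
#' Folds hydrogens written as explicit atoms into their heavy neighbour's
#' implicit-H count (preserving the written neighbour position as the
#' implicit-H placeholder so tetrahedral parity survives) and validates
#' chirality annotations. Idempotent. Hydrogens carrying an isotope label or
#' a charge, and hydrogens bonded only to hydrogens, are kept as atoms.
#'
#' @param mol A `molecule` from [parse_smiles()].
#' @param strict Error (instead of warn and clear) on a parity symbol whose
#'   atom does not have exactly four distinct neighbour positions.
#' @return The normalized `molecule`.
#' @examples
#' m <- normalize_molecule(parse_smiles("C([H])([H])([H])[H]"))
#' m$atoms$h_count # 4
#' @export
normalize_molecule <- function(mol, strict = FALSE) {
  deg <- mol_degree(mol)
  foldable <- which(
    mol$atoms$z == 1L & mol$atoms$isotope == 0L & mol$atoms$charge == 0L &
      mol$atoms$chiral == 0L & mol$atoms$h_count == 0L & deg == 1L
  )
  # keep H atoms whose only neighbour is itself a foldable H ([H][H])
  if (length(foldable) && nrow(mol$bonds)) {
    partner <- vapply(foldable, function(i) {
      k <- which(mol$bonds$a == i | mol$bonds$b == i)[1L]
      if (mol$bonds$a[k] == i) mol$bonds$b[k] else mol$bonds$a[k]
    }, integer(1))
    drop <- mol$atoms$z[partner] == 1L
    heavy <- partner[!drop]
    foldable <- foldable[!drop]
    if (length(foldable)) {
      for (t in seq_along(foldable)) {
        h <- foldable[t]; hv <- heavy[t]
        mol$atoms$h_count[hv] <- mol$atoms$h_count[hv] + 1L
        mol$nbr_order[[hv]][mol$nbr_order[[hv]] == h] <- -1L
      }
      keep <- setdiff(seq_len(n_atoms(mol)), foldable)
      mol <- mol_subset(mol, keep)
    }
  }
  # chirality validation: exactly 4 distinct neighbour positions, at most one
  # of which is the implicit hydrogen
  deg <- mol_degree(mol)
  for (i in which(mol$atoms$chiral > 0L)) {
    pos <- deg[i] + min(mol$atoms$h_count[i], 1L)
    ok <- pos == 4L && mol$atoms$h_count[i] <= 1L
    if (!ok) {
      msg <- sprintf("atom %d: parity symbol requires 4 distinct neighbour positions", i)
      if (strict) stop(msg)
      warning(msg, "; parity ignored")
      mol$atoms$chiral[i] <- 0L
    }
  }
  mol
}
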