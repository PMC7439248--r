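# Ring-atom tiebreaking, DFS generation and canonical selection.

test_that("acyclic molecules need no tiebreaking", {
  m <- bond_ring_sizes(parse_norm("CCO"))
  part <- symmetry_classes(m)$classes
  leaves <- break_ties(m, part)
  expect_length(leaves, 1L)
  expect_identical(leaves[[1L]], part)
})

test_that("leaf partition counts match the known traversal counts", {
  counts <- c(16L, 16L, 24L, 48L, 28L)
  smiles <- c(FIG1, FIG2, ADAMANTANE, CUBANE, PETERSEN72)
  for (i in seq_along(smiles)) {
    m <- bond_ring_sizes(parse_norm(smiles[i]))
    leaves <- break_ties(m, symmetry_classes(m)$classes)
    expect_length(leaves, counts[i])
    # leaves are complete: ring atoms hold unique ranks
    ring <- canonsmi:::ring_atom_flags(m)
    for (lf in leaves) expect_false(anyDuplicated(lf[ring]) > 0L)
  }
})

test_that("chain emission starts from the lowest-ranked terminal atom", {
  m <- parse_norm("CCO")
  expect_identical(generate_smiles(m, c(1L, 2L, 3L))$smiles, "CCO")
  expect_identical(canonical_smiles("OCC")$smiles, "CCO")
  expect_identical(canonical_smiles("CCO")$smiles, "CCO")
})

test_that("the two stereo traversals of the relative-chirality ring differ and the minimum wins", {
  m <- bond_ring_sizes(parse_norm(FIG7))
  leaves <- break_ties(m, symmetry_classes(m)$classes)
  expect_length(leaves, 2L)
  strs <- vapply(leaves, function(lf) generate_smiles(m, lf)$smiles, character(1))
  expect_setequal(strs, c("C[C@H]1CC[C@H](N)CC1", "C[C@@H]1CC[C@@H](N)CC1"))
  expect_identical(canonical_smiles(FIG7)$smiles, "C[C@@H]1CC[C@@H](N)CC1")
  expect_identical(canonical_smiles("C[C@@H]1CC[C@@H](N)CC1")$smiles,
                   "C[C@@H]1CC[C@@H](N)CC1")
})

test_that("generated strings re-parse to isomorphic graphs", {
  set.seed(17)
  for (s in c(OXIRANE, FIG2, ADAMANTANE, "c1cc[nH]c1", "CC(=O)[O-]", FIG7)) {
    m <- bond_ring_sizes(parse_norm(s))
    leaves <- break_ties(m, symmetry_classes(m)$classes)
    for (lf in leaves[seq_len(min(4L, length(leaves)))]) {
      out <- generate_smiles(m, lf)
      expect_true(is_isomorphic(m, parse_norm(out$smiles)), label = out$smiles)
      expect_setequal(out$atom_output_order, seq_len(n_atoms(m)))
    }
  }
})

test_that("canonicalization is idempotent and label-invariant", {
  set.seed(41)
  for (s in c(FIG1, CUBANE, FIG7, "Cc1ccccc1", "CC(C)(C)C")) {
    ref <- canonical_smiles(s)$smiles
    expect_identical(canonical_smiles(ref)$smiles, ref)
    mol <- parse_norm(s)
    for (s2 in relabelings(mol, 15)) {
      expect_identical(canonical_smiles(s2)$smiles, ref, label = s2)
    }
  }
})

test_that("stereocentres keep their configuration through canonicalization", {
  set.seed(43)
  for (s in c("N[C@@H](C)C(=O)O", "N[C@H](C)C(=O)O", FIG7)) {
    ref <- canonical_smiles(s)$smiles
    mol <- parse_norm(s)
    # the canonical string of every relabeling (which rewrites parity
    # symbols relative to its own output order) must agree bit for bit
    for (s2 in relabelings(mol, 10)) {
      expect_identical(canonical_smiles(s2)$smiles, ref, label = s2)
    }
  }
  # the two epimers stay distinct
  expect_false(identical(canonical_smiles("N[C@@H](C)C(=O)O")$smiles,
                         canonical_smiles("N[C@H](C)C(=O)O")$smiles))
})

test_that("disconnected inputs canonicalize per component, sorted", {
  r <- canonical_smiles("OCC.C1CC1")
  expect_identical(r$smiles, "C1CC1.CCO")
  expect_identical(canonical_smiles("C1CC1.CCO")$smiles, "C1CC1.CCO")
})

test_that("traversal counts follow the 2^N law for N para-linked rings", {
  for (N in 1:4) {
    r <- canonical_smiles(gen_bilateral_rings(N))
    expect_equal(r$traversal_count, 2L^N)
  }
  # cross-check against the automorphism group for the small cases
  for (N in 1:2) {
    mol <- parse_norm(gen_bilateral_rings(N))
    expect_equal(orbit_oracle(mol)$group_order, 2L^N)
  }
})

test_that("traversal count is at least the automorphism group order", {
  for (s in c(ADAMANTANE, CUBANE, FIG2, PETERSEN72)) {
    mol <- parse_norm(s)
    aut <- orbit_oracle(mol)$group_order
    trav <- canonical_smiles(s)$traversal_count
    expect_gte(trav, aut)
  }
  # equality on the exactly-perceived fixtures
  expect_equal(canonical_smiles(ADAMANTANE)$traversal_count,
               orbit_oracle(parse_norm(ADAMANTANE))$group_order)
  expect_equal(canonical_smiles(CUBANE)$traversal_count,
               orbit_oracle(parse_norm(CUBANE))$group_order)
})
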