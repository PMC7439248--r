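# Local vectors, per-bond ring sizes, prime-product ring invariants,
# distance invariants, chirality invariants and initial ranks.

test_that("local vector fields appear in the stated order", {
  # methane: degree 0, Z 006, H4, sign 0, |q| 0, conn 4, valence 4, mass 000, chir 0
  expect_identical(local_vectors(parse_smiles("C")), "0006400440000")
  # ethane CH3: degree 1, conn 4, valence 4
  expect_identical(local_vectors(parse_smiles("CC"))[1], "1006300440000")
  # alkoxide oxygen: negative charge -> sign digit 1, |q| 1
  # degree 1, Z 008, H 0, sign 1, |q| 1, conn 1, valence 1
  v <- local_vectors(parse_norm("[O-]C"))[1]
  expect_identical(substr(v, 1, 9), "100801111")
  # isotope occupies the mass field
  expect_identical(substr(local_vectors(parse_smiles("[13CH4]")), 10, 12), "013")
})

test_that("bond ring sizes come from BFS with the bond removed", {
  m <- bond_ring_sizes(parse_smiles("C1CCCCC1"))
  expect_true(all(m$bonds$ring_size == 6L))
  m <- bond_ring_sizes(parse_smiles("CC"))
  expect_identical(m$bonds$ring_size, 0L)
  # all-3-ring polycycle: every atom's minimal incident ring size is 3,
  # four atoms have maximal 3 and four have maximal 6
  m <- bond_ring_sizes(parse_smiles(FIG2))
  adj <- canonsmi:::mol_adjacency(m)
  mins <- vapply(adj, function(a) min(m$bonds$ring_size[a$bond]), integer(1))
  maxs <- vapply(adj, function(a) max(m$bonds$ring_size[a$bond]), integer(1))
  expect_true(all(mins == 3L))
  expect_identical(sort(maxs), c(rep(3L, 4), rep(6L, 4)))
})

test_that("ring invariants are products of ring-size-indexed primes", {
  ri <- ring_invariants(bond_ring_sizes(parse_smiles(FIG2)))
  expect_identical(sort(ri$value), c(rep(125, 4), rep(325, 4)))  # 5*5*5, 5*5*13
  expect_identical(ring_invariants(bond_ring_sizes(parse_smiles("CCO")))$value, rep(1, 3))
})

test_that("ring invariant factorization recovers the incident ring-size multiset", {
  for (s in c(FIG2, FIG1, ADAMANTANE, "C1CC1C1CCCCC1")) {
    m <- bond_ring_sizes(parse_smiles(s))
    ri <- ring_invariants(m)
    adj <- canonsmi:::mol_adjacency(m)
    for (i in seq_len(n_atoms(m))) {
      sizes <- m$bonds$ring_size[adj[[i]]$bond]
      sizes <- sizes[sizes > 0L]
      expo <- canonsmi:::big_factor_small_primes(ri$big[[i]], max(c(1L, sizes)))
      got <- rep(seq_along(expo), expo)
      expect_identical(sort(got), sort(sizes))
    }
  }
})

test_that("distance invariants reproduce the 24-fullerene shell sums", {
  di <- distance_invariants(parse_smiles(FULLERENE24))
  expect_identical(sort(unique(di$value)), c(25763, 35663))
  expect_identical(as.vector(table(di$value)), c(12L, 12L))
  expect_true(all(di$noon == 5L))

  expect_identical(distance_invariants(parse_smiles("C"))$value, 0)
  expect_identical(distance_invariants(parse_smiles("C"))$noon, 0L)
  expect_identical(distance_invariants(parse_smiles("CC"))$value, c(1, 1))
  expect_identical(distance_invariants(parse_smiles("CC"))$noon, c(1L, 1L))
})

test_that("distance invariant digit sums count the other atoms", {
  for (s in c(FIG1, FULLERENE24, ADAMANTANE)) {
    m <- parse_smiles(s)
    di <- distance_invariants(m, base = n_atoms(m))  # carry-free base
    for (i in seq_len(n_atoms(m))) {
      # digit sum in base n via repeated division
      n <- n_atoms(m); total <- 0; vv <- di$value[i]
      while (vv > 0) { total <- total + vv %% n; vv <- vv %/% n }
      expect_equal(total, n - 1)
    }
  }
})

test_that("chirality invariants follow neighbour-class parity", {
  # @ with ascending written classes: zero swaps, even -> 1
  m <- parse_norm("N[C@H](O)C")   # neighbours N, H, O, C all distinct classes
  achiral <- refine_partition(m, initial_ranks(bond_ring_sizes(m))$ranks)
  chir <- chirality_invariants(m, achiral)
  expect_true(chir[2] %in% 1:2)
  # inverting the symbol inverts the invariant
  m2 <- parse_norm("N[C@@H](O)C")
  chir2 <- chirality_invariants(m2, achiral)
  expect_identical(sort(unique(c(chir[2], chir2[2]))), c(1L, 2L))
  # no parity -> 0 by definition
  expect_identical(chirality_invariants(parse_norm("CCO"), c(1L, 2L, 3L)), c(0L, 0L, 0L))
  # two ring neighbours in one class -> 0 (relative-only stereochemistry)
  m7 <- bond_ring_sizes(parse_norm(FIG7))
  achiral7 <- refine_partition(m7, initial_ranks(m7)$ranks)
  expect_identical(chirality_invariants(m7, achiral7), rep(0L, 8))
})

test_that("initial ranks sort by (vector, ring, distance) ascending", {
  m <- bond_ring_sizes(parse_smiles(OXIRANE))
  expect_identical(initial_ranks(m)$ranks, c(1L, 4L, 2L, 3L))  # CH3, CH, CH2, O
  # ring invariants alone already give three classes in the bicyclic cage
  expect_equal(max(initial_ranks(bond_ring_sizes(parse_smiles(FIG1)))$ranks), 3L)
  # benzene: fully symmetric
  expect_equal(max(initial_ranks(bond_ring_sizes(parse_smiles("c1ccccc1")))$ranks), 1L)
})

test_that("invariants are label-invariant under random relabeling", {
  set.seed(23)
  for (s in c(FIG2, OXIRANE, FULLERENE24)) {
    mol <- parse_norm(s)
    mol <- bond_ring_sizes(mol)
    ring_ref <- sort(ring_invariants(mol)$value)
    dist_ref <- sort(distance_invariants(mol)$value)
    vec_ref <- sort(local_vectors(mol))
    for (s2 in relabelings(mol, 25)) {
      m2 <- bond_ring_sizes(parse_norm(s2))
      expect_identical(sort(ring_invariants(m2)$value), ring_ref)
      expect_identical(sort(distance_invariants(m2)$value), dist_ref)
      expect_identical(sort(local_vectors(m2)), vec_ref)
    }
  }
})
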