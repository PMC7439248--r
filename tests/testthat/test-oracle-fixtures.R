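# Brute-force oracles, generators and the CLI.

test_that("orbit oracle gives exact orbits on elementary graphs", {
  expect_equal(orbit_oracle(parse_smiles("CCC"))$n_orbits, 2L)  # ends vs middle
  o <- orbit_oracle(parse_norm(CUBANE))
  expect_equal(o$n_orbits, 1L)
  expect_equal(o$group_order, 48L)
  expect_equal(orbit_oracle(gen_cycle(6))$n_orbits, 1L)
  expect_equal(orbit_oracle(parse_smiles(FULLERENE24))$n_orbits, 2L)
  # labels matter: orbits respect elements and bond orders
  expect_equal(orbit_oracle(parse_norm("CCO"))$n_orbits, 3L)
  expect_equal(orbit_oracle(parse_norm("C1=CCC=CC1"))$n_orbits, 2L)
})

test_that("oracle group orders agree with igraph on plain skeletons", {
  for (g in list(parse_norm(CUBANE), gen_petersen(5, 2), gen_prism(5), gen_cycle(7))) {
    ig <- igraph::graph_from_edgelist(as.matrix(g$bonds[, c("a", "b")]), directed = FALSE)
    expect_equal(orbit_oracle(g)$group_order,
                 as.numeric(igraph::count_automorphisms(ig)$group_size))
  }
})

test_that("isomorphism oracle distinguishes non-isomorphic graphs", {
  expect_true(is_isomorphic(gen_cycle(6), parse_smiles("C1CCCCC1")))
  expect_false(is_isomorphic(gen_cycle(6), gen_theta(c(1L, 2L, 1L))))
  expect_false(is_isomorphic(parse_norm("CCO"), parse_norm("COC")))
})

test_that("refinement class count equals orbit count outside the counterexamples", {
  graphs <- c(
    lapply(3:10, gen_cycle),
    list(gen_theta(c(1L, 2L, 3L)), gen_theta(c(2L, 2L, 2L)), gen_theta(c(1L, 1L, 3L))),
    lapply(3:5, gen_prism)   # prism(4) is the cube
  )
  for (g in graphs) {
    g <- bond_ring_sizes(g)
    expect_equal(symmetry_classes(g)$n_classes, orbit_oracle(g)$n_orbits,
                 label = paste("graph n =", n_atoms(g)))
  }
  # documented counterexample: Petersen G(7,2) merges to one class
  p <- bond_ring_sizes(gen_petersen(7, 2))
  expect_lte(symmetry_classes(p)$n_classes, orbit_oracle(p)$n_orbits)
})

test_that("generated Petersen G(7,2) matches the printed SMILES", {
  expect_true(is_isomorphic(gen_petersen(7, 2), parse_norm(PETERSEN72)))
  # the classic G(5,2) Petersen graph is vertex-transitive
  expect_equal(orbit_oracle(gen_petersen(5, 2))$n_orbits, 1L)
})

test_that("k-regular generator yields connected simple k-regular graphs", {
  for (par in list(c(8L, 3L), c(10L, 3L), c(10L, 4L), c(14L, 3L))) {
    g <- gen_k_regular(par[1], par[2], seed = 99L)
    expect_equal(n_atoms(g), par[1])
    expect_true(all(canonsmi:::mol_degree(g) == par[2]))
    expect_equal(max(canonsmi:::mol_components(g)), 1L)
    # deterministic for a fixed seed
    g2 <- gen_k_regular(par[1], par[2], seed = 99L)
    expect_identical(g$bonds, g2$bonds)
  }
})

test_that("refinement classes never exceed true orbit counts on random regular graphs", {
  for (seed in 1:5) {
    g <- bond_ring_sizes(gen_k_regular(10L, 3L, seed = seed))
    expect_lte(symmetry_classes(g)$n_classes, orbit_oracle(g)$n_orbits)
  }
})

test_that("cli canonicalizes line files with ids, classes and traversals", {
  inp <- withr::local_tempfile(lines = c("# demo", "OCC\tethanol", FIG1))
  out <- withr::local_tempfile()
  code <- run_cli(c(inp, "-o", out, "--classes", "--traversals"))
  expect_equal(code, 0L)
  lines <- readLines(out)
  expect_length(lines, 2L)
  p1 <- strsplit(lines[1], "\t")[[1]]
  expect_identical(p1[1:2], c("CCO", "ethanol"))
  p2 <- strsplit(lines[2], "\t")[[1]]
  classes <- as.integer(strsplit(p2[2], " ")[[1]])
  expect_length(unique(classes), 3L)
  expect_identical(p2[3], "16")
})

test_that("cli handles empty input, malformed lines and strict mode", {
  empty <- withr::local_tempfile(lines = character(0))
  out <- withr::local_tempfile()
  expect_equal(run_cli(c(empty, "-o", out)), 0L)
  expect_length(readLines(out), 0L)

  bad <- withr::local_tempfile(lines = c("C1CC", "CCO"))
  expect_equal(suppressMessages(run_cli(c(bad, "-o", out))), 0L)
  expect_identical(readLines(out), "CCO")          # malformed line skipped
  expect_equal(suppressMessages(run_cli(c(bad, "-o", out, "--strict"))), 1L)

  expect_equal(suppressMessages(run_cli(c("/nonexistent/file.smi"))), 2L)
})

test_that("cli explain dump lists one invariant row per atom", {
  inp <- withr::local_tempfile(lines = "CC1CO1")
  out <- withr::local_tempfile()
  run_cli(c(inp, "-o", out, "--explain"))
  lines <- readLines(out)
  expect_length(grep("^#", lines), 5L)  # header + 4 atoms
  expect_identical(lines[length(lines)], canonical_smiles("CC1CO1")$smiles)
})

test_that("cli output is byte-deterministic", {
  set.seed(3)
  mols <- relabelings(parse_norm(ADAMANTANE), 5)
  inp <- withr::local_tempfile(lines = mols)
  o1 <- withr::local_tempfile(); o2 <- withr::local_tempfile()
  run_cli(c(inp, "-o", o1))
  run_cli(c(inp, "-o", o2))
  expect_identical(readLines(o1), readLines(o2))
  expect_length(unique(readLines(o1)), 1L)
})
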