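test_that("generate_molecules is deterministic and respects bounds", {
  expect_equal(generate_molecules(0, seed = 1), character(0))
  a <- generate_molecules(100, max_carbons = 12, seed = 7)
  b <- generate_molecules(100, max_carbons = 12, seed = 7)
  expect_identical(a, b)
  expect_equal(length(unique(canonicalize_smiles(a))), 100L)

  basics <- molecule_basics(a)
  expect_true(all(basics$n_carbon >= 1 & basics$n_carbon <= 12))
})

test_that("generated molecules all parse and re-canonicalize", {
  sm <- generate_molecules(50, max_carbons = 8, seed = 3)
  canon <- canonicalize_smiles(sm)
  expect_false(anyNA(canon))
  expect_identical(canonicalize_smiles(canon), canon)
})

test_that("planted_model validates noise and is reproducible", {
  expect_error(planted_model(noise_sd = -1), "noise_sd")
  m <- planted_model(seed = 4)
  sm <- generate_molecules(30, seed = 9)
  r1 <- assign_logS(sm, m)
  r2 <- assign_logS(sm, m)
  expect_identical(r1$logS, r2$logS)
})

test_that("assign_logS follows the planted relationship plus noise", {
  m <- planted_model(noise_sd = 0, seed = 2)
  sm <- c("CCO", "CCCC", "Oc1ccccc1")
  rec <- assign_logS(sm, m)
  counts <- attr(rec, "group_counts")
  manual <- m$intercept + as.vector(counts %*% m$coefficients[colnames(counts)])
  expect_equal(rec$logS, manual)
})

test_that("inject_duplicates plants recoverable exact/conflicting rows", {
  m <- planted_model(seed = 1)
  sm <- generate_molecules(40, seed = 21)
  rec <- assign_logS(sm, m)
  out <- inject_duplicates(rec, n_exact = 5, n_conflict = 3, seed = 8)
  expect_equal(nrow(out), nrow(rec) + 8L)
  cur <- curate(out, conflict_tolerance = 0.01)
  expect_equal(cur$provenance$collapsed, 5L)
  expect_equal(cur$provenance$conflict_molecules, 3L)
  expect_equal(cur$provenance$kept, nrow(rec) - 3L)
})

test_that("simulate_solubility_table is byte-reproducible under its seed", {
  s1 <- simulate_solubility_table(60, max_carbons = 10, n_exact = 4,
                                  n_conflict = 2, seed = 13)
  s2 <- simulate_solubility_table(60, max_carbons = 10, n_exact = 4,
                                  n_conflict = 2, seed = 13)
  expect_identical(s1$table, s2$table)
  p1 <- file.path(withr::local_tempdir(), "sim1.csv")
  p2 <- file.path(withr::local_tempdir(), "sim2.csv")
  write_simulation(s1, p1)
  write_simulation(s2, p2)
  expect_identical(readLines(p1), readLines(p2))
})
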