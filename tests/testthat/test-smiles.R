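test_that("parse_molecules builds heavy-atom graphs with implicit H", {
  ms <- parse_molecules(c("CCO", "c1ccccc1", "C"))
  expect_true(all(ms$ok))
  g <- ms$graph[[1]]
  expect_equal(g$n, 3L)
  expect_setequal(g$elem, c("C", "O"))
  expect_equal(sum(g$nH), 6L)  # C2H6O
  benz <- ms$graph[[2]]
  expect_true(all(benz$aromatic))
  expect_equal(benz$n_aromatic_rings, 1L)
  # single atoms are representable
  methane <- ms$graph[[3]]
  expect_equal(methane$n, 1L)
  expect_equal(methane$nH, 4L)
})

test_that("strict parsing errors while lenient parsing flags", {
  expect_error(parse_molecules(c("CCO", "%%bad%%")), "%%bad%%")
  ms <- parse_molecules(c("CCO", "%%bad%%"), strict = FALSE)
  expect_equal(ms$ok, c(TRUE, FALSE))
})

test_that("count_smarts counts substructure matches", {
  ms <- parse_molecules(c("CCO", "OCCO", "c1ccccc1"))
  oh <- count_smarts(ms, "[OX2H]")
  expect_equal(oh, c(1L, 2L, 0L))
  arom <- count_smarts(ms, "c")
  expect_equal(arom, c(0L, 0L, 6L))
})

test_that("count_functional_groups matches hand counts", {
  counts <- count_functional_groups(c("OCC(O)CO",       # glycerol
                                      "CC(=O)O",        # acetic acid
                                      "Nc1ccccc1",      # aniline
                                      "ClCCBr"))
  expect_equal(unname(counts[1, "n_oh"]), 3L)
  expect_equal(unname(counts[2, "n_cooh"]), 1L)
  # the carboxyl OH must not double count as hydroxyl
  expect_equal(unname(counts[2, "n_oh"]), 0L)
  expect_equal(unname(counts[3, "n_nh2"]), 1L)
  expect_equal(unname(counts[3, "n_aromatic_ring"]), 1L)
  expect_equal(unname(counts[4, "n_halogen"]), 2L)
  expect_equal(unname(counts[, "n_carbon"]), c(3L, 2L, 6L, 2L))
})

test_that("molecule_basics computes MW including implicit hydrogens", {
  b <- molecule_basics(c("C", "O", "c1ccccc1"))
  expect_equal(b$mw, c(16.043, 18.015, 78.114), tolerance = 1e-3)
  expect_equal(b$n_carbon, c(1L, 0L, 6L))
})
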