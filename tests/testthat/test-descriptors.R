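test_that("descriptor engine reproduces hand-computed topological values", {
  dm <- compute_descriptors(c("c1ccccc1", "CCO", "C"))
  v <- dm$values
  # benzene: Wiener index of C6 cycle = 27; 6 aromatic atoms; 1 ring
  expect_equal(v$Wiener[1], 27)
  expect_equal(v$nAromAtom[1], 6)
  expect_equal(v$nRing[1], 1)
  # ethanol: 2 carbons, 1 OH, MW of C2H6O
  expect_equal(v$nC[2], 2)
  expect_equal(v$MW[2], 46.069, tolerance = 1e-3)
  # methane: no bonds, Wiener 0
  expect_equal(v$Wiener[3], 0)
})

test_that("drop_non_numeric removes boolean screens and NA columns", {
  dm <- compute_descriptors(c("CCO", "CCC", "CCN"))
  expect_true("RuleOf5" %in% colnames(dm$values))
  num <- drop_non_numeric(dm)
  expect_false("RuleOf5" %in% colnames(num$values))
  expect_true(all(vapply(num$values, function(c) all(is.finite(c)), TRUE)))
  log <- num$stage_log
  expect_equal(log$stage[nrow(log)], "drop_non_numeric")
})

test_that("low_variance_filter thresholds on raw variance and validates", {
  x <- data.frame(a = c(1, 1, 1, 1), b = c(0, 10, 0, 10), c = rnorm(4))
  dm <- aquasol:::.new_descriptor_matrix(x)
  out <- low_variance_filter(dm, threshold = 0.1)
  expect_false("a" %in% colnames(out$values))
  expect_true("b" %in% colnames(out$values))
  expect_error(low_variance_filter(dm, threshold = -1), ">= 0")
})

test_that("pairwise_correlation_prune keeps the earlier of each pair", {
  set.seed(2)
  a <- rnorm(50)
  x <- data.frame(a = a, b = a + rnorm(50, sd = 1e-6), c = rnorm(50))
  dm <- aquasol:::.new_descriptor_matrix(x)
  out <- pairwise_correlation_prune(dm, cutoff = 0.95)
  expect_equal(colnames(out$values), c("a", "c"))
  expect_error(pairwise_correlation_prune(dm, cutoff = 0), "\\(0, 1\\]")
  expect_error(pairwise_correlation_prune(dm, cutoff = 1.5), "\\(0, 1\\]")
})

test_that("exclude_named drops leakage columns and notes absences", {
  dm <- compute_descriptors(c("CCO", "CCC"))
  out <- exclude_named(dm, "ESOL_logS")
  expect_false("ESOL_logS" %in% colnames(out$values))
  expect_message(exclude_named(out, "ESOL_logS"), "not present")
})

test_that("descriptor cascade logs monotone non-increasing column counts", {
  sm <- generate_molecules(60, max_carbons = 10, seed = 17)
  dm <- descriptor_cascade(compute_descriptors(sm))
  log <- dm$stage_log
  expect_true(all(diff(log$after) <= 0))
  expect_true(all(log$after <= log$before))
  expect_false("ESOL_logS" %in% colnames(dm$values))
  # survivors contain no offending correlated pair
  cm <- abs(stats::cor(as.matrix(dm$values)))
  diag(cm) <- 0
  expect_true(all(cm <= 0.95 + 1e-12))
})

test_that("write_descriptor_matrix emits values and stage log", {
  dm <- descriptor_cascade(compute_descriptors(c("CCO", "CCC", "CCN",
                                                 "CCCC", "CC(C)O")))
  path <- file.path(withr::local_tempdir(), "desc.csv")
  write_descriptor_matrix(dm, path)
  back <- utils::read.csv(path, check.names = FALSE)
  expect_equal(dim(back), dim(dm$values))
  expect_true(file.exists(paste0(path, ".stages.json")))
})
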