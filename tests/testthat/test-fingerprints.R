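test_that("fingerprints are invariant to SMILES spelling", {
  fp <- morgan_fingerprints(c("CCO", "OCC", "c1ccccc1", "C1=CC=CC=C1"))
  expect_identical(fp$bits[1, ], fp$bits[2, ])
  expect_identical(fp$bits[3, ], fp$bits[4, ])
  expect_false(identical(fp$bits[1, ], fp$bits[3, ]))
})

test_that("fingerprint matrix has the documented shape and bounds", {
  sm <- fixture_smiles()
  fp <- morgan_fingerprints(sm, radius = 2, n_bits = 2048)
  expect_equal(dim(fp$bits), c(length(sm), 2048L))
  expect_true(all(fp$bits %in% c(0L, 1L)))
  expect_equal(colnames(fp$bits)[1], "bit0")
  # at most n_atoms * (radius + 1) distinct environments per molecule
  basics <- molecule_basics(sm)
  ms <- parse_molecules(sm)
  heavy <- vapply(ms$graph, function(g) g$n, 1L)
  expect_true(all(rowSums(fp$bits) <= heavy * 3L))
})

test_that("bit_to_substructure round-trips for every set bit", {
  for (sm in c("CCO", "Oc1ccccc1", "CC(=O)O")) {
    fp <- morgan_fingerprints(sm)
    set_bits <- which(fp$bits[1, ] == 1L) - 1L
    for (b in set_bits) {
      envs <- bit_to_substructure(sm, b)
      expect_gt(nrow(envs), 0)
      # each reported environment re-hashes to the bit it came from
      g <- parse_molecules(sm)$graph[[1]]
      all_env <- aquasol:::.morgan_environments(g, 2L)
      for (k in seq_len(nrow(envs))) {
        id <- all_env$id[all_env$atom == envs$center_atom[k] &
                         all_env$radius == envs$radius[k]]
        expect_equal(id %% 2048, b)
      }
      expect_false(anyNA(envs$fragment))
    }
  }
  expect_error(bit_to_substructure("CCO", setdiff(0:2047,
    which(morgan_fingerprints("CCO")$bits[1, ] == 1L) - 1L)[1]),
    "not set")
})

test_that("fingerprints are invariant to atom renumbering", {
  set.seed(33)
  g <- parse_molecules("CC(=O)Nc1ccccc1O")$graph[[1]]
  ref <- aquasol:::.bits_from_env(aquasol:::.morgan_environments(g, 2L),
                                  2048L)
  for (i in 1:20) {
    p <- sample(g$n)
    pg <- permute_graph(g, p)
    bits <- aquasol:::.bits_from_env(
      aquasol:::.morgan_environments(pg, 2L), 2048L)
    expect_identical(bits, ref)
  }
})

test_that("bit_atlas collects distinct example fragments per bit", {
  sm <- c("CCO", "CCCO", "c1ccccc1")
  atlas <- bit_atlas(sm, max_examples = 3)
  expect_true(length(atlas) > 0)
  for (entry in atlas) {
    expect_true(all(c("molecule", "center_atom", "radius", "fragment")
                    %in% names(entry)))
    expect_equal(anyDuplicated(entry$fragment), 0L)
    expect_lte(nrow(entry), 3L)
  }
})

test_that("lasso_select finds sparse signal and validates input", {
  set.seed(9)
  n <- 120
  x <- matrix(rbinom(n * 40, 1, 0.3), n, 40,
              dimnames = list(NULL, paste0("bit", 0:39)))
  y <- 2 * x[, 3] - 1.5 * x[, 10] + rnorm(n, sd = 0.1)
  sel <- lasso_select(x, y, chosen_alpha = 0.01)
  expect_true(all(c(2L, 9L) %in% sel$selected_bit_ids))
  # heavier penalties select no more bits
  expect_true(all(diff(sel$n_selected) >= 0))  # grid stored descending
  expect_error(lasso_select(x, rep(1, n)), "constant")
})

test_that("bit frequencies and rare-feature ratios behave as documented", {
  x <- rbind(c(1, 1, 0, 1),
             c(1, 0, 0, 0),
             c(0, 0, 0, 0))
  colnames(x) <- paste0("bit", 0:3)
  counts <- bit_frequency_counts(x)
  expect_equal(unname(counts), c(2, 1, 0, 1))
  expect_equal(sum(counts), sum(x))
  expect_equal(rare_feature_ratio(x[1, ], counts, rare_threshold = 2), 2 / 3)
  expect_equal(rare_feature_ratio(x[1, ], counts, rare_threshold = 3), 1)
  expect_warning(r0 <- rare_feature_ratio(x[3, ], counts), "empty")
  expect_equal(r0, 0)
})
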