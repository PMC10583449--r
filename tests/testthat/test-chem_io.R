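test_that("read_molecule_table reads mapped columns and reports bad rows", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("structure,sol,origin",
               "CCO,-0.1,a",
               "CO,,b",
               "c1ccccc1,-1.64,a"), path)
  tab <- read_molecule_table(path, column_map = c(smiles = "structure",
                                                  logS = "sol",
                                                  source = "origin"))
  expect_equal(nrow(tab), 2L)
  expect_equal(tab$smiles, c("CCO", "c1ccccc1"))
  bad <- attr(tab, "bad_rows")
  expect_equal(nrow(bad), 1L)
  expect_equal(bad$smiles, "CO")
})

test_that("read_molecule_table validates file, columns and emptiness", {
  expect_error(read_molecule_table(file.path(tempdir(), "nope.csv")),
               "not found")
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("a,b", "CCO,-1"), path)
  expect_error(read_molecule_table(path), "not present")
  writeLines("smiles,logS", path)
  expect_error(read_molecule_table(path), "empty")
})

test_that("canonicalize_smiles maps spellings to one fixed point", {
  expect_identical(canonicalize_smiles("OCC"), canonicalize_smiles("CCO"))
  expect_identical(canonicalize_smiles("c1ccccc1"),
                   canonicalize_smiles("C1=CC=CC=C1"))
  once <- canonicalize_smiles(c("OCC", "C1=CC=CC=C1", "CC(N)C(=O)O"))
  expect_identical(canonicalize_smiles(once), once)
  expect_error(canonicalize_smiles("XYZ"), "XYZ")
  expect_true(is.na(canonicalize_smiles("XYZ", strict = FALSE)))
})

test_that("curate reproduces the worked duplicate/conflict example", {
  x <- data.frame(smiles = c("CCO", "CCO", "CO", "CCC", "CCC"),
                  logS = c(-1, -1, -2, -1, -3))
  cur <- curate(x, conflict_tolerance = 0.01)
  expect_setequal(cur$records$smiles, canonicalize_smiles(c("CCO", "CO")))
  expect_equal(sort(cur$records$logS), c(-2, -1))
  p <- cur$provenance
  expect_equal(p$kept, 2L)
  expect_equal(p$collapsed, 1L)
  expect_equal(p$conflict_molecules, 1L)
  expect_equal(p$conflict_rows, 2L)
})

test_that("curate handles empty input, mixtures and parse failures", {
  empty <- curate(data.frame(smiles = character(0), logS = numeric(0)))
  expect_equal(nrow(empty$records), 0L)
  expect_true(all(unlist(empty$provenance) == 0))

  x <- data.frame(smiles = c("CCO", "[Na+].[Cl-]", "not_a_molecule"),
                  logS = c(-1, 0, 0))
  cur <- curate(x)
  expect_equal(cur$provenance$mixtures, 1L)
  expect_equal(cur$provenance$parse_failures, 1L)
  expect_equal(cur$records$smiles, canonicalize_smiles("CCO"))
})

test_that("curate is idempotent and order-insensitive", {
  set.seed(5)
  x <- data.frame(
    smiles = c("CCO", "OCC", "CO", "CCC", "CCC", "c1ccccc1", "CC(C)O"),
    logS = c(-1, -1, -2, -1, -3, -1.6, -0.5))
  cur1 <- curate(x)
  cur2 <- curate(cur1$records[, c("smiles", "logS")])
  expect_equal(cur1$records$smiles, cur2$records$smiles)
  expect_equal(cur1$records$logS, cur2$records$logS)
  for (i in 1:5) {
    perm <- x[sample(nrow(x)), ]
    curp <- curate(perm)
    expect_equal(curp$records$smiles, cur1$records$smiles)
    expect_equal(curp$records$logS, cur1$records$logS)
  }
})

test_that("provenance conservation identity holds on random fixtures", {
  set.seed(11)
  pool <- c("C", "CC", "CCO", "CO", "CCC", "c1ccccc1", "CC(=O)O",
            "[Na+].[Cl-]", "bad_smiles")
  for (trial in 1:50) {
    n <- sample(0:25, 1)
    x <- data.frame(smiles = sample(pool, n, replace = TRUE),
                    logS = round(stats::rnorm(n), 1))
    p <- curate(x)$provenance
    grouped <- p$kept + p$collapsed + p$conflict_rows
    expect_equal(p$inputs,
                 grouped + p$parse_failures + p$mixtures)
  }
})

test_that("profile_dataset counts species and carbon range", {
  cur <- curate(data.frame(smiles = "CCO", logS = -0.1))
  pr <- profile_dataset(cur)
  expect_equal(unname(pr$species_counts["hydroxyl"]), 1L)
  expect_equal(unname(pr$species_counts["aromatic"]), 0L)
  expect_equal(pr$carbon_range, c(2L, 2L))

  cur2 <- curate(data.frame(smiles = c("c1ccccc1", "Clc1ccccc1"),
                            logS = c(-1.6, -2.4)))
  pr2 <- profile_dataset(cur2)
  expect_equal(unname(pr2$species_counts["aromatic"]), 2L)
  expect_equal(unname(pr2$species_counts["halogen"]), 1L)
  expect_error(profile_dataset(data.frame(smiles = character(0))), "empty")
})

test_that("write_curated_dataset emits CSV plus provenance JSON", {
  cur <- curate(data.frame(smiles = c("CCO", "CO"), logS = c(-0.1, 0.5)))
  path <- file.path(withr::local_tempdir(), "curated.csv")
  write_curated_dataset(cur, path)
  back <- utils::read.csv(path)
  expect_equal(back$smiles, cur$records$smiles)
  prov <- jsonlite::read_json(sub("\\.csv$", ".provenance.json", path))
  expect_equal(prov$kept, 2L)
})
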