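test_that("gibbs_energy reproduces the fixed-point arithmetic", {
  expect_equal(gibbs_energy(0, 0, 0), -0.5)
  expect_equal(gibbs_energy(10, 1, 1), -13.33)
  expect_equal(gibbs_energy(1, 0, 1), -4.84)
  expect_error(gibbs_energy(-1, 0, 0), "non-negative")
  b <- gibbs_coefficients()
  expect_equal(as.vector(b), c(-0.5, -1.37, 3.84, -2.97))
  expect_named(attr(b, "se"), names(b))
})

test_that("gibbs_energy is monotone with the documented signs", {
  alphas <- seq(0, 20, by = 2.5)
  cas <- 0:4
  cds <- 0:4
  for (ca in cas) for (cd in cds) {
    g <- gibbs_energy(alphas, ca, cd)
    expect_true(all(diff(g) < 0))  # strictly decreasing in alpha
  }
  for (a in alphas) for (cd in cds) {
    g <- gibbs_energy(a, cas, cd)
    expect_true(all(diff(g) > 0))  # strictly increasing in ca
  }
  for (a in alphas) for (ca in cas) {
    g <- gibbs_energy(a, ca, cds)
    expect_true(all(diff(g) < 0))  # strictly decreasing in cd
  }
})

test_that("polarizability_from_formula sums the element table", {
  # CH4: alpha(C) + 4 alpha(H)
  expect_equal(polarizability_from_formula("CH4"), 1.76 + 4 * 0.667)
  expect_equal(polarizability_from_formula("OH2"), 0.802 + 2 * 0.667)
  expect_true(is.na(polarizability_from_formula("Xx2")))
})

test_that("fragment_properties caps fragments and counts donors/acceptors", {
  props <- fragment_properties(c("CO", "CC(=O)O", "CC", "N"))
  # hydroxyl fragment: at least one donor
  expect_gte(props$cd[1], 1)
  # carboxyl fragment: both donor and acceptor
  expect_gte(props$ca[2], 1)
  expect_gte(props$cd[2], 1)
  # ethane: neither
  expect_equal(props$ca[3], 0)
  expect_equal(props$cd[3], 0)
  # hydrogen-capped formulas
  expect_equal(props$formula[3], "C2H6")
  expect_equal(props$gibbs,
               gibbs_energy(props$alpha, props$ca, props$cd))
})

test_that("fragment_thermo_table ranks by Gibbs energy with NAs last", {
  tab <- fragment_thermo_table(c(b1 = "O", b2 = "c1ccccc1", b3 = "[Xx"))
  expect_equal(tab$label[3], "b3")
  expect_true(is.na(tab$gibbs[3]))
  expect_true(all(diff(tab$gibbs[1:2]) >= 0))
})
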