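test_that("simulate_counts is deterministic and respects degenerate probabilities", {
  p <- reference_probabilities("control", quiet = TRUE)
  t1 <- simulate_counts(p, n_donors = 5, seed = 123)
  t2 <- simulate_counts(p, n_donors = 5, seed = 123)
  expect_identical(t1, t2)
  t3 <- simulate_counts(p, n_donors = 5, seed = 124)
  expect_false(identical(t1, t3))

  only_d <- c(discocyte = 1)
  td <- simulate_counts(only_d, n_donors = 4, cells_per_donor = 200, seed = 1)
  expect_true(all(td$count[td$shape_class == "discocyte"] == 200))
  expect_true(all(td$count[td$shape_class != "discocyte"] == 0))

  expect_error(simulate_counts(p, cells_per_donor = 0), "positive")
  expect_error(simulate_counts(c(discocyte = 0.5, echinocyte = 0.6)), "sum to 1")
  expect_error(simulate_counts(unname(p)), "named")
})

test_that("large multinomial samples recover the reference control percentages", {
  p <- reference_probabilities("control", quiet = TRUE)
  tab <- simulate_counts(p, n_donors = 1, cells_per_donor = 1e6,
                         overdispersion = NULL, seed = 77)
  frac <- tab$count / 1e6
  # within 3 binomial standard deviations, class by class
  sd3 <- 3 * sqrt(p * (1 - p) / 1e6)
  expect_true(all(abs(frac - p) <= pmax(sd3, 1e-9)))
  # and the percentage profile is within 0.1 of the reference column
  expect_true(all(abs(100 * frac - 100 * p) < 0.1))
})

test_that("Dirichlet overdispersion widens the between-donor spread", {
  p <- reference_probabilities("control", quiet = TRUE)
  pure <- simulate_counts(p, n_donors = 30, overdispersion = NULL, seed = 5)
  od <- simulate_counts(p, n_donors = 30, overdispersion = 100, seed = 5)
  disc_sd <- function(tab) sd(tab$count[tab$shape_class == "discocyte"]) / 10
  expect_gt(disc_sd(od), disc_sd(pure))
  # classes absent from the reference stay absent under Dirichlet draws
  expect_true(all(od$count[od$shape_class %in% c("spherocyte", "stomatocyte")] == 0))
})

test_that("zero-noise simulated spectra are exactly anchor-consistent", {
  m <- hb_deconvolution_model()
  E_oracle <- 1e4 * cramer_inverse_3x3(m$C)
  set.seed(31)
  for (i in 1:5) {
    conc <- runif(3, 1e-6, 1e-4)
    s <- simulate_spectrum(conc, model = m, noise_sd = 0)
    a <- anchors_from_spectrum(s, m)
    expect_equal(unname(a), drop(E_oracle %*% conc), tolerance = 1e-6)
    rec <- speciate(a, m)$concentrations
    expect_equal(unname(rec), conc, tolerance = 1e-6)
  }
})

test_that("the zero speciation gives a spectrum with zero anchors", {
  s <- simulate_spectrum(c(0, 0, 0), noise_sd = 0)
  expect_equal(unname(anchors_from_spectrum(s)), c(0, 0, 0), tolerance = 1e-10)
})

test_that("simulated spectra are deterministic in the seed and reject bad grids", {
  conc <- c(5e-5, 3e-5, 1e-5)
  s1 <- simulate_spectrum(conc, seed = 9)
  s2 <- simulate_spectrum(conc, seed = 9)
  expect_identical(s1$absorbance, s2$absorbance)
  expect_error(simulate_spectrum(conc, wavelength = seq(600, 700, 0.5)),
               "anchor")
})

test_that("Monte Carlo concentration noise matches closed-form propagation", {
  conc <- c(5e-5, 3e-5, 1e-5)
  grid <- seq(450, 650, by = 0.1)  # covers all anchors; keeps replicates cheap
  n_rep <- 400
  rec <- matrix(NA_real_, n_rep, 3)
  for (r in seq_len(n_rep)) {
    s <- simulate_spectrum(conc, wavelength = grid, noise_sd = 0.001,
                           seed = 20000 + r)
    rec[r, ] <- speciate(anchors_from_spectrum(s))$concentrations
  }
  expected_sd <- propagated_concentration_sd(0.001)
  for (j in 1:3)
    expect_equal(sd(rec[, j]), unname(expected_sd[j]), tolerance = 0.15)
  expect_equal(colMeans(rec), conc, tolerance = 0.05)
})

test_that("molar mass reproduces reference formula weights", {
  expect_equal(round(molar_mass("C23H27N3O7", adduct = "HCl"), 2), 493.94)
  expect_equal(round(molar_mass("H2O"), 2), 18.02)
  expect_equal(round(molar_mass("HCl"), 2), 36.46)
  expect_error(molar_mass("C2Xx5"), "parse|atomic weight")
  expect_error(molar_mass("UUO2"), "atomic weight")
})

test_that("dose-to-molarity arithmetic", {
  expect_equal(molarity_from_dose(0.1, 1, 493.94), 2.0245e-4, tolerance = 1e-4)
  expect_equal(molarity_from_dose(493.94, 1, 493.94), 1.0)
  # 200 mg over 5 L reproduces the working concentration 8.1e-5 mol/L
  expect_equal(signif(molarity_from_dose(0.2, 5, 493.94), 2), 8.1e-5)
  expect_error(molarity_from_dose(0, 1, 1), "positive")
  expect_error(molarity_from_dose(1, -1, 1), "positive")
})
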