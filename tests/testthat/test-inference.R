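test_that("background_subtract nets out the untreated control", {
  t45 <- release_observation("WT", "treated", 45, 0.05, 0.01)
  ctrl <- release_observation("WT", "untreated", 0, 0.02, 0.005)
  net <- background_subtract(t45, ctrl)
  expect_equal(as.numeric(net), 0.03)
  expect_equal(attr(net, "sem"), sqrt(0.01^2 + 0.005^2))
  # equal fractions -> 0; negative differences floored at 0
  same <- background_subtract(release_observation("WT", "treated", 45, 0.02),
                              release_observation("WT", "untreated", 0, 0.02))
  expect_equal(as.numeric(same), 0)
  floor0 <- background_subtract(
    release_observation("hns", "treated", 45, 0.01),
    release_observation("hns", "untreated", 0, 0.02))
  expect_equal(as.numeric(floor0), 0)
  # a hyper-breaking repair mutant: 0.30 - 0.02
  xn <- background_subtract(
    release_observation("xthA_nfo", "treated", 45, 0.30, 0.02),
    release_observation("xthA_nfo", "untreated", 0, 0.02, 0.005))
  expect_equal(as.numeric(xn), 0.28)
  expect_error(background_subtract(t45,
    release_observation("fis", "untreated", 0, 0.02)), "same strain")
})

test_that("invert_attachment_count solves the closed form and round-trips", {
  est <- invert_attachment_count(0.03, 100)
  expect_equal(est$a_hat, 475)
  # round trips over the grid (inverse-consistency property)
  for (a in c(50, 100, 400, 800)) for (b in c(100, 1000)) {
    f <- expected_release_closed_form(a, b)
    expect_identical(invert_attachment_count(f, b)$a_hat, a)
  }
  # the 50-loop prediction inverts back to ~50
  expect_equal(invert_attachment_count(0.443, 100)$a_hat, 50)
  # domain errors
  expect_error(invert_attachment_count(0, 100), "positive")
  expect_error(invert_attachment_count(1, 100), "maximum attainable")
  expect_error(invert_attachment_count(0.05, 1), "b >= 2")
})

test_that("bootstrap CI brackets the estimate and is seeded", {
  e1 <- invert_attachment_count(0.03, 100, sem = 0.01, rng_seed = 5)
  e2 <- invert_attachment_count(0.03, 100, sem = 0.01, rng_seed = 5)
  expect_identical(e1, e2)
  expect_lte(e1$ci_low, e1$a_hat)
  expect_gte(e1$ci_high, e1$a_hat)
  expect_gt(e1$ci_high - e1$ci_low, 0)
  # wider sem -> wider interval
  e3 <- invert_attachment_count(0.03, 100, sem = 0.02, rng_seed = 5)
  expect_gt(e3$ci_high - e3$ci_low, e1$ci_high - e1$ci_low)
})

test_that("scenario_discriminate ranks by z-score", {
  obs <- release_observation("WT", "treated", 45, 0.03, 0.01)
  preds <- list(envelope = list(mean = 0, se = 0),
                scaffold = list(mean = 0.9, se = 0.01),
                random_a400 = list(mean = 0.04, se = 0.002))
  r <- scenario_discriminate(obs, preds)
  expect_equal(r$scenario[1], "random_a400")
  expect_equal(r$z[1], abs(0.03 - 0.04) / sqrt(0.01^2 + 0.002^2))
  # exact match -> z = 0; zero observation ranks envelope first
  r2 <- scenario_discriminate(release_observation("WT", "t", 45, 0.9, 0.01),
                              preds)
  expect_equal(r2$scenario[1], "scaffold")
  expect_equal(r2$z[1], 0)
  r3 <- scenario_discriminate(release_observation("WT", "t", 45, 0, 0.01),
                              preds)
  expect_equal(r3$scenario[1], "envelope")
})

test_that("kinetic fit recovers noiseless parameters to 4 significant figures", {
  # the half-at-15-min shape: (1 - e^{-15k}) / (1 - e^{-60k}) = 1/2, i.e.
  # x^3 + x^2 + x - 1 = 0 with x = e^{-15k}; solve independently by uniroot
  x <- uniroot(function(x) x^3 + x^2 + x - 1, c(0.4, 0.7), tol = 1e-12)$root
  k_true <- -log(x) / 15
  expect_equal(k_true, 0.0406, tolerance = 1e-3)
  fit <- fit_release_kinetics(kinetic_series(0.05, 0.09, k_true))
  expect_true(fit$converged && fit$identifiable)
  expect_equal(fit$f0, 0.05, tolerance = 1e-4)
  expect_equal(fit$A, 0.09, tolerance = 1e-4)
  expect_equal(fit$k, k_true, tolerance = 1e-4)
})

test_that("kinetic fit flags flat series and rejects short ones", {
  flat <- data.frame(time_min = c(0, 15, 60), released_fraction = 0.05)
  fit <- fit_release_kinetics(flat)
  expect_false(fit$identifiable)
  expect_equal(fit$A, 0)
  expect_true(is.na(fit$k))
  expect_error(fit_release_kinetics(
    data.frame(time_min = c(0, 15), released_fraction = c(0.05, 0.1))),
    "at least 3")
  expect_error(fit_release_kinetics(
    data.frame(time_min = c(5, 15, 30), released_fraction = c(0.05, 0.1, 0.12))),
    "t = 0")
})

test_that("kinetic fit recovers A within 10% (median over noisy seeds)", {
  k_true <- 0.040625
  A_hats <- vapply(1:100, function(s) {
    set.seed(s)
    ser <- kinetic_series(0.05, 0.09, k_true, times = c(0, 10, 15, 30, 60))
    ser$released_fraction <- ser$released_fraction + rnorm(5, 0, 0.005)
    fit_release_kinetics(ser)$A
  }, numeric(1))
  expect_lt(abs(median(A_hats) - 0.09) / 0.09, 0.10)
})

test_that("transcription_share arithmetic and scale invariance", {
  expect_equal(transcription_share(0.09, 0.03), 2 / 3)
  expect_equal(transcription_share(0.05, 0), 1)
  expect_equal(transcription_share(0.05, 0.05), 0)
  expect_error(transcription_share(0, 0), "positive")
  expect_error(transcription_share(0.05, 0.06), "delta_rif")
  for (c in c(0.1, 1, 7.3))
    expect_equal(transcription_share(c * 0.09, c * 0.03),
                 transcription_share(0.09, 0.03))
})
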