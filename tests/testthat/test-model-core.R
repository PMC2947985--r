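test_that("burst-coordinate transforms are exact inverses", {
  bc <- to_burst_coordinates(rate_constants(1, 10, 100))
  expect_equal(bc$b, 10)
  expect_equal(bc$tau, 0.1)
  expect_equal(bc$kappa_a, 1)
  bc2 <- to_burst_coordinates(rate_constants(3.7, 1, 1))
  expect_equal(bc2$b, 1)
  expect_equal(bc2$tau, 1)
  expect_equal(bc2$kappa_a, 3.7)

  set.seed(7)
  for (i in 1:100) {
    r <- rate_constants(kappa_a = 10^runif(1, -2, 1),
                        kappa_r = 10^runif(1, -2, 2),
                        kappa_t_plus = 10^runif(1, 0, 3))
    bc <- to_burst_coordinates(r)
    r2 <- from_burst_coordinates(bc$b, bc$kappa_a, bc$tau,
                                 r$kappa_p_plus, r$kappa_p_minus)
    expect_equal(unclass(r2), unclass(r), tolerance = 1e-12)
  }
  expect_error(rate_constants(-1, 1, 1), "positive")
  expect_error(rate_constants(1, 1, 1, kappa_p_minus = 1.5), "kappa_p_minus")
})

test_that("active fraction formula matches its limits and the CME oracle", {
  expect_equal(active_fraction(5, 0), 0)
  expect_equal(active_fraction(10, 0.1), 0.5)
  expect_equal(active_fraction(3, 0.05), 0.15 / 1.15)
  expect_error(active_fraction(-1, 1))
  # exact identity with the oracle's gene-state marginal
  g <- marginal(fix_oracle_small(), "gene_state")
  r <- fix_rates_small()
  expect_lt(abs(g[["active"]] - active_fraction(r$kappa_a, 1 / r$kappa_r)),
            1e-10)
})

test_that("regime classification follows the switching-rate thresholds", {
  expect_identical(classify_regime(rate_constants(0.5, 20, 200)), "Bursting")
  expect_identical(classify_regime(rate_constants(50, 50, 5)), "Fast")
  expect_identical(classify_regime(rate_constants(0.01, 0.01, 5)), "Slow")
  expect_identical(classify_regime(rate_constants(1, 1, 5)), "Intermediate")
  # thresholds configurable (small burst size so bursting cannot pre-empt)
  expect_identical(classify_regime(rate_constants(1, 1, 0.5), fast = 0.5),
                   "Fast")
})

test_that("analytic moments match limits, symmetry, and the exact oracle", {
  # constitutive limit: Poisson transcripts
  m <- analytic_moments(rate_constants(5, 1e-9, 7, 1, 0.25))
  expect_equal(m$transcript_fano, 1, tolerance = 1e-6)
  expect_equal(m$transcript_mean, 7, tolerance = 1e-6)
  # symmetric switching halves the transcription rate
  m2 <- analytic_moments(rate_constants(2, 2, 40, 1, 0.25))
  expect_equal(m2$transcript_mean, 20)
  # exact agreement with the fully enumerated steady state
  ma <- analytic_moments(fix_rates_small())
  expect_equal(ma$transcript_mean, 100 * 0.5 / 10.5, tolerance = 1e-12)
  jm <- joint_moments(fix_oracle_small())
  expect_equal(jm$transcript_mean, ma$transcript_mean, tolerance = 5e-3)
  expect_equal(jm$transcript_var, ma$transcript_var, tolerance = 5e-3)
  expect_equal(jm$protein_mean, ma$protein_mean, tolerance = 5e-3)
  expect_equal(jm$protein_var, ma$protein_var, tolerance = 5e-3)
})

test_that("bursting approximation scales correctly and is accurate deep in regime", {
  calib <- calibration()
  a1 <- bursting_approximation(10, 0.5, calib)
  a2 <- bursting_approximation(10, 1.0, calib)
  expect_equal(a2$protein_mean / a1$protein_mean, 2)
  expect_equal(a2$protein_var / a1$protein_var, 2)
  b1 <- bursting_approximation(10, 0.5, calib)
  b2 <- bursting_approximation(20, 0.5, calib)
  expect_equal(b2$protein_mean / b1$protein_mean, 2)
  expect_equal(b2$protein_var / b1$protein_var, 4)
  # mean within 15% of the exact moments at kappa_r = 50; the leading-order
  # variance overestimates by the protein-lifetime filter (1 + kappa_p_minus)
  ap <- bursting_approximation(20, 1, calib, kappa_r = 50)
  ex <- analytic_moments(from_burst_coordinates(20, 1, 1 / 50))
  expect_equal(ap$protein_mean, ex$protein_mean, tolerance = 0.15)
  expect_equal(ap$protein_var / (1 + calib$kappa_p_minus), ex$protein_var,
               tolerance = 0.1)
  expect_warning(bursting_approximation(10, 1, calib, kappa_r = 2), "regime")
})

test_that("bursting approximation error in the mean vanishes as kappa_r grows", {
  calib <- calibration()
  errs <- vapply(c(10, 100, 1000), function(kr) {
    ap <- bursting_approximation(10, 0.5, calib, kappa_r = Inf)
    ex <- analytic_moments(from_burst_coordinates(10, 0.5, 1 / kr))
    abs(ap$protein_mean / ex$protein_mean - 1)
  }, numeric(1))
  expect_true(all(diff(errs) < 0))
})

test_that("moment matching inverts the bursting relations", {
  calib <- calibration()   # gamma 2.5, kappa_p_minus 0.25
  mm <- moment_match(100, 4000, calib)
  expect_equal(mm$kappa_a, 0.625)
  expect_equal(mm$b, 64)
  # doubling the mean at fixed CV doubles b, leaves kappa_a unchanged
  mm2 <- moment_match(200, 16000, calib)
  expect_equal(mm2$kappa_a, mm$kappa_a)
  expect_equal(mm2$b, 2 * mm$b)
  # round trip through the forward approximation, to machine precision
  fwd <- bursting_approximation(17, 0.4, calib)
  nu <- calib$nu
  rec <- moment_match(nu * fwd$protein_mean, nu^2 * fwd$protein_var, calib)
  expect_equal(rec$b, 17, tolerance = 1e-12)
  expect_equal(rec$kappa_a, 0.4, tolerance = 1e-12)
  expect_error(moment_match(10, -5), "insufficient signal")
  expect_error(moment_match(-1, 5), "insufficient signal")
})

test_that("moment matching recovers a solved bursting clone within 20%", {
  r <- from_burst_coordinates(15, 0.8, 0.02)
  m <- analytic_moments(r)
  calib <- calibration()
  mm <- moment_match(calib$nu * m$protein_mean,
                     calib$nu^2 * m$protein_var, calib)
  expect_equal(mm$b, 15, tolerance = 0.2)
  expect_equal(mm$kappa_a, 0.8, tolerance = 0.2)
})

test_that("rates serialize to flat configs, with per-hour normalization", {
  r <- rate_constants(0.4, 25, 600)
  p1 <- file.path(tempdir(), "rates.yaml")
  write_rates(r, p1)
  rt <- read_rates(p1)
  expect_equal(unclass(rt$rates), unclass(r), tolerance = 1e-12)
  # per-hour input is normalized by the transcript degradation rate
  p2 <- file.path(tempdir(), "rates_h.json")
  jsonlite::write_json(list(kappa_a = 0.08, kappa_r = 5, kappa_t_plus = 120,
                            kappa_p_plus = 2, kappa_p_minus = 0.05,
                            kappa_t_minus_per_hour = 0.2),
                       p2, auto_unbox = TRUE)
  rh <- read_rates(p2)
  expect_equal(rh$rates$kappa_a, 0.4)
  expect_equal(rh$rates$kappa_r, 25)
  expect_equal(rh$rates$kappa_t_plus, 600)
  expect_equal(rh$rates$kappa_p_minus, 0.25)
})
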