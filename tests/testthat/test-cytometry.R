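test_that("event tables validate and round-trip through CSV", {
  df <- data.frame(gfp = c(5, 10), fsc = c(500, 510), ssc = c(480, 505))
  ev <- event_table(df, clone_id = "c1")
  expect_s3_class(ev, "event_table")
  expect_error(event_table(df[, 1:2]), "columns")
  expect_error(event_table(transform(df, gfp = c(-1, 5))), "positive")
  p <- file.path(tempdir(), "ev.csv")
  write_events(ev, p)
  ev2 <- read_events(p)
  expect_equal(ev2$gfp, ev$gfp)
})

test_that("scatter gating keeps the central quantile box", {
  set.seed(4)
  n <- 20000
  ev <- event_table(data.frame(gfp = rep(10, n),
                               fsc = runif(n, 1, 1024),
                               ssc = runif(n, 1, 1024)))
  expect_equal(nrow(gate_events(ev, 1)), n)
  frac <- nrow(gate_events(ev, 0.6)) / n
  expect_equal(frac, 0.36, tolerance = 0.03)   # independent uniform axes
  expect_identical(gate_events(ev, 0.6)$fsc, gate_events(ev, 0.6)$fsc)
  small <- event_table(data.frame(gfp = rep(10, 300),
                                  fsc = runif(300, 1, 1024),
                                  ssc = runif(300, 1, 1024)))
  expect_error(gate_events(small, 0.1), "200")
})

test_that("log-binned histograms conserve mass and report clipping", {
  h <- rfu_histogram(rep(50, 1000))
  expect_equal(sum(h$mass), 1)
  expect_equal(sum(h$mass > 0), 1L)          # delta lands in one bin
  set.seed(5)
  x <- rlnorm(20000, log(30), 0.4)
  h2 <- rfu_histogram(x)
  ratio <- h2$edges[2] / h2$edges[1]
  expect_lt(abs(log(hist_mean(h2)) - log(mean(x))), log(ratio) / 2)
  h3 <- rfu_histogram(c(0.01, 50, 5000))
  expect_equal(unname(h3$clipped), c(1L, 1L))
  expect_error(rfu_histogram(numeric(0)))
})

test_that("Fourier smoothing denoises without distorting the signal", {
  bins <- default_bins()
  truth <- diff(plnorm(bins, log(50), 0.45)); truth <- truth / sum(truth)
  set.seed(6)
  counts <- rmultinom(1, 4000, truth)[, 1]
  noisy <- burstfit:::new_rfu_histogram(counts / sum(counts), bins,
                                        n_events = 4000L)
  sm <- smooth_histogram(noisy, cutoff = 16)
  expect_equal(sum(sm$mass), 1, tolerance = 1e-9)
  expect_lt(sum((sm$mass - truth)^2), sum((noisy$mass - truth)^2))
  expect_warning(ident <- smooth_histogram(noisy, cutoff = 200), "Nyquist")
  expect_equal(ident$mass, noisy$mass)
  auto <- smooth_histogram(noisy, cutoff = "auto", n_boot = 25, seed = 2)
  expect_true(auto$smoothing$cutoff %in% c(8, 12, 16, 24, 32, 48))
  auto2 <- smooth_histogram(noisy, cutoff = "auto", n_boot = 25, seed = 2)
  expect_identical(auto$mass, auto2$mass)    # seeded determinism
})

test_that("gate optimization resolves size-coupled fluorescence", {
  rates <- from_burst_coordinates(15, 0.8, 0.02)
  calib <- calibration()
  indep <- simulate_clone(rates, calib, n_events = 10000,
                          size_coupling = 0, seed = 31)
  g0 <- optimize_gate(indep$events, n_boot = 60, seed = 1)
  expect_equal(as.numeric(g0), 1)            # nothing to remove
  coupled <- simulate_clone(rates, calib, n_events = 10000,
                            size_coupling = 1.5, s_cv = 0.4, seed = 32)
  g1 <- optimize_gate(coupled$events, n_boot = 60, seed = 1)
  expect_lt(as.numeric(g1), 1)
  devs <- attr(g1, "deviations")
  # gating reduces the deviation-to-target objective vs no gating
  expect_lt(devs[[as.character(as.numeric(g1))]], devs[["1"]])
  expect_error(optimize_gate(indep$events, candidate_fractions = 0.6),
               "candidate")
})

test_that("autofluorescence convolution adds means and variances", {
  af <- fix_af()
  bins <- default_bins()
  sig_mass <- diff(plnorm(bins, log(60), 0.5))
  sig <- burstfit:::new_rfu_histogram(sig_mass / sum(sig_mass), bins)
  conv <- convolve_autofluorescence(sig, af)
  expect_equal(hist_mean(conv), hist_mean(sig) + af$mean, tolerance = 0.01)
  expect_equal(hist_var(conv), hist_var(sig) + af$var, tolerance = 0.05)
  # a zero-fluorescence model reproduces the background profile
  delta <- burstfit:::new_rfu_histogram(c(1, rep(0, 255)), bins)
  back <- convolve_autofluorescence(delta, af)
  expect_lt(sum(abs(back$mass - af$hist$mass)), 0.05)
})

test_that("Wiener deconvolution inverts the background convolution", {
  af <- fix_af()
  bins <- default_bins()
  sig_mass <- diff(plnorm(bins, log(60), 0.5))
  sig <- burstfit:::new_rfu_histogram(sig_mass / sum(sig_mass), bins)
  conv <- convolve_autofluorescence(sig, af)
  dec <- deconvolve_autofluorescence(conv, af)
  expect_lt(sum(abs(dec$mass - sig$mass)), 0.02)
  # bursting-model histogram: mean recovered within 2%
  calib <- calibration()
  msig <- model_to_rfu(fix_pmf_mid(), calib, autofluor = NULL)
  mdec <- deconvolve_autofluorescence(convolve_autofluorescence(msig, af), af)
  expect_equal(hist_mean(mdec), hist_mean(msig), tolerance = 0.02)
  # deconvolving the background by itself concentrates mass near zero
  self <- deconvolve_autofluorescence(af$hist, af)
  expect_lt(hist_mean(self), 1)
  # deconvolution sharpens; heavy regularization suppresses amplification
  expect_lte(hist_var(mdec), hist_var(convolve_autofluorescence(msig, af)))
  big <- deconvolve_autofluorescence(conv, af, noise_level = 1e6)
  expect_lte(hist_var(big), hist_var(conv) + 2 * af$var)
  dim_hist <- burstfit:::new_rfu_histogram(
    diff(plnorm(bins, log(1), 0.3)) / sum(diff(plnorm(bins, log(1), 0.3))),
    bins)
  expect_error(deconvolve_autofluorescence(dim_hist, af),
               "insufficient signal")
})

test_that("the forward calibration map is linear and translation-invariant", {
  af <- fix_af()
  calib <- calibration()
  h <- model_to_rfu(fix_pmf_mid(), calib, af)
  m <- analytic_moments(from_burst_coordinates(15, 0.8, 0.02))
  expect_equal(hist_mean(h), calib$nu * m$protein_mean + af$mean,
               tolerance = 0.02)
  # changing kappa_p_plus with nu co-derived leaves the prediction invariant
  calib2 <- calibration(kappa_p_plus = 20)
  pmf2 <- marginal(steady_state(from_burst_coordinates(15, 0.8, 0.02,
                                                       kappa_p_plus = 20),
                                options = list(method = "direct")),
                   "protein", interpolate = TRUE)
  h2 <- model_to_rfu(pmf2, calib2, af)
  expect_lt(sum(abs(h$mass - h2$mass)), 0.01)
})

test_that("clones below twice the background mean are excluded", {
  af <- fix_af()
  bins <- default_bins()
  mk <- function(mu) {
    m <- diff(plnorm(bins, log(mu), 0.4))
    burstfit:::new_rfu_histogram(m / sum(m), bins)
  }
  # signal mean below the background mean fails the doubled-total rule
  hists <- list(dim = mk(af$mean * 1.5), bright = mk(af$mean * 6))
  keep <- include_clones(hists, af)
  expect_false(keep[["dim"]])
  expect_true(keep[["bright"]])
  expect_equal(attr(keep, "report")$threshold[1], 2 * af$mean)
})
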