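test_that("scenario specifications derive coupled parameter ranges", {
  sp <- scenario_spec("combined")
  # coupling aligns geometric centers: b spans exactly b_range
  expect_equal(sp$coupling * sp$kappa_a_range^2, sp$b_range, tolerance = 1e-10)
  tr <- draw_ensemble_parameters(sp)
  expect_true(all(tr$b >= sp$b_range[1] & tr$b <= sp$b_range[2]))
  expect_equal(tr$b, sp$coupling * tr$kappa_a^2)
  tr2 <- draw_ensemble_parameters(sp)
  expect_identical(tr, tr2)                      # pure function of (spec, seed)
  f <- draw_ensemble_parameters(scenario_spec("frequency_only", n_clones = 10))
  expect_true(all(f$b == 15))
  expect_true(all(f$kappa_a >= 0.1 & f$kappa_a <= 3))
  s <- draw_ensemble_parameters(scenario_spec("size_only", n_clones = 10))
  expect_true(all(s$kappa_a == 0.3))
  expect_true(all(s$b >= 2 & s$b <= 50))
})

test_that("clone simulation is seeded and reproduces the analytic mean", {
  rates <- from_burst_coordinates(15, 0.8, 0.02)
  calib <- calibration()
  cl1 <- simulate_clone(rates, calib, n_events = 4000, size_coupling = 0,
                        seed = 51)
  cl2 <- simulate_clone(rates, calib, n_events = 4000, size_coupling = 0,
                        seed = 51)
  expect_identical(cl1$events$gfp, cl2$events$gfp)
  cl3 <- simulate_clone(rates, calib, n_events = 4000, size_coupling = 0,
                        seed = 52)
  expect_false(identical(cl1$events$gfp, cl3$events$gfp))
  expect_equal(nrow(cl1$events), 4000L)
  # with no size coupling, mean GFP = nu * protein mean + background mean
  m <- analytic_moments(rates)
  expected <- calib$nu * m$protein_mean + 5
  se <- sd(cl1$events$gfp) / sqrt(4000)
  expect_lt(abs(mean(cl1$events$gfp) - expected), 3 * se + 0.05 * expected)
})

test_that("size coupling tilts fluorescence against forward scatter", {
  rates <- from_burst_coordinates(15, 0.8, 0.02)
  cl <- simulate_clone(rates, calibration(), n_events = 10000,
                       size_coupling = 0.5, seed = 53)
  ct <- cor.test(log(cl$events$gfp), log(cl$events$fsc))
  expect_gt(ct$estimate, 0.05)
  expect_lt(ct$p.value, 0.01)
  cl0 <- simulate_clone(rates, calibration(), n_events = 10000,
                        size_coupling = 0, seed = 53)
  expect_lt(abs(cor(log(cl0$events$gfp), log(cl0$events$fsc))), 0.05)
})

test_that("background generator hits its configured moments", {
  af <- generate_autofluorescence(mean_rfu = 5, cv = 0.5, n_events = 20000,
                                  seed = 13)
  expect_equal(mean(af$gfp), 5, tolerance = 0.03)
  expect_equal(sd(af$gfp) / mean(af$gfp), 0.5, tolerance = 0.05)
  expect_true(all(af$fsc >= 1 & af$fsc <= 1024))
})

test_that("exact stochastic simulation agrees with the enumerated oracle", {
  r <- fix_rates_small()
  sam <- simulate_clone_ssa(r, duration = 40, n_cells = 20000, seed = 2)
  # constitutive-limit transcript marginal is Poisson
  rc <- rate_constants(1, 1e-9, 5, 1, 0.25)
  sc <- simulate_clone_ssa(rc, duration = 40, n_cells = 5000, seed = 3)
  expect_equal(mean(sc[, "transcript"]), 5, tolerance = 0.05)
  expect_equal(var(sc[, "transcript"]) / mean(sc[, "transcript"]), 1,
               tolerance = 0.1)
  # pooled chi-square against the exact protein marginal
  pm <- marginal(fix_oracle_small(), "protein", interpolate = TRUE)
  brk <- c(-0.5, seq(4.5, 80.5, by = 4), Inf)
  obs <- as.integer(table(cut(sam[, "protein"], brk)))
  cdf <- cumsum(pm)
  up <- pmin(floor(brk[-1]) + 1, length(pm))
  ex <- diff(c(0, cdf[up[-length(up)]], 1))
  expect_gt(suppressWarnings(chisq.test(obs, p = ex)$p.value), 0.01)
  # doubling the duration leaves the distribution unchanged (stationarity)
  sam2 <- simulate_clone_ssa(r, duration = 80, n_cells = 5000, seed = 4)
  ks <- suppressWarnings(ks.test(sam[, "protein"], sam2[, "protein"]))
  expect_gt(ks$p.value, 0.01)
})

test_that("sampling and simulating paths give indistinguishable event tables", {
  rates <- fix_rates_small()
  calib <- calibration(kappa_p_plus = 1)
  c_cme <- simulate_clone(rates, calib, n_events = 10000, seed = 61,
                          method = "cme")
  c_ssa <- simulate_clone(rates, calib, n_events = 10000, seed = 61,
                          method = "ssa")
  ks <- suppressWarnings(ks.test(c_cme$protein, c_ssa$protein))
  expect_gt(ks$p.value, 0.01)
})

test_that("ensembles carry their ground truth and serialize to plain text", {
  sp <- scenario_spec("size_only", n_clones = 3, n_events = 1500, seed = 9,
                      b_range = c(8, 20))
  ens <- generate_ensemble(sp)
  expect_length(ens$clones, 3)
  expect_equal(nrow(ens$truth), 3)
  expect_equal(ens$clones[[2]]$burst$b, ens$truth$b[2])
  d <- file.path(tempdir(), "ens")
  write_ensemble(ens, d)
  expect_true(file.exists(file.path(d, "clone_02.csv")))
  expect_true(file.exists(file.path(d, "autofluorescence.csv")))
  man <- jsonlite::read_json(file.path(d, "manifest.json"),
                             simplifyVector = TRUE)
  expect_equal(man$truth$b, ens$truth$b, tolerance = 1e-9)
  ev <- read_events(file.path(d, "clone_02.csv"))
  expect_equal(nrow(ev), 1500)
})
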