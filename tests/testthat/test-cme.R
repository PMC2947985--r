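test_that("axis grids follow the graded construction rules", {
  g <- build_axis_grid(10, fine_limit = 10, growth = 1.5)
  expect_equal(g$n_bins, 11L)
  expect_true(all(g$width == 1L))

  g2 <- build_axis_grid(1000, fine_limit = 32, growth = 1.2)
  expect_true(all(g2$width[1:33] == 1L))
  expect_true(all(diff(g2$width) >= 0))
  expect_gte(max(g2$hi), 1000)
  expect_equal(g2$lo[-1], g2$hi[-g2$n_bins] + 1L)   # exact partition

  # doubling growth never increases the bin count
  for (mx in c(200, 1000, 5000)) {
    n1 <- build_axis_grid(mx, 32, 1.1)$n_bins
    n2 <- build_axis_grid(mx, 32, 1.2)$n_bins
    expect_lte(n2, n1)
  }
  # width cap respected
  g3 <- build_axis_grid(5000, 16, 1.5, max_width = 20)
  expect_lte(max(g3$width), 20L)
  # fine_limit above max collapses to fully fine
  expect_equal(build_axis_grid(5, fine_limit = 50)$n_bins, 6L)
})

test_that("the enumerated oracle reproduces exact closed forms", {
  # near-constitutive gene: Poisson transcript distribution, pointwise
  r <- rate_constants(1, 1e-12, 5, 1, 0.25)
  o <- brute_force_oracle(r, max_transcripts = 30, max_proteins = 120)
  mt <- marginal(o, "transcript")
  expect_lt(max(abs(mt$mass - dpois(0:30, 5))), 1e-10)
  # two-state balance for the gene marginal
  g <- marginal(fix_oracle_small(), "gene_state")
  expect_lt(abs(g[["active"]] - 0.5 / 10.5), 1e-10)
  expect_equal(sum(marginal(fix_oracle_small(), "protein")$mass), 1,
               tolerance = 1e-9)
})

test_that("steady state reaches the constitutive limit", {
  r <- rate_constants(50, 1e-6, 5, 1, 0.25)
  s <- steady_state(r, options = list(method = "direct"))
  jm <- joint_moments(s)
  expect_equal(jm$protein_mean, 5 * 1 / 0.25, tolerance = 0.02)
  pm <- marginal(s, "transcript", interpolate = TRUE)
  expect_lt(tv_unit(pm, dpois(0:(length(pm) - 1), 5)), 5e-3)
})

test_that("the alternating-Euler march and the direct solve share a fixed point", {
  r <- fix_rates_small()
  opts <- list(fine_limit = 32, growth = 1.2, width_cap = 1)
  s1 <- steady_state(r, options = c(opts, method = "march"))
  s2 <- steady_state(r, options = c(opts, method = "direct"))
  expect_lt(0.5 * sum(abs(s1$p - s2$p)), 1e-6)
  expect_lt(s1$residual, 1e-9)
  expect_equal(sum(s1$p), 1, tolerance = 1e-9)
})

test_that("the split-operator step conserves probability mass exactly", {
  r <- fix_rates_small()
  grid <- default_grid(r, fine_limit = 24, growth = 1.3)
  gen <- burstfit:::build_generator(r, grid)
  ns <- nrow(gen$A_T)
  p <- numeric(ns); p[1] <- 1
  I <- Matrix::Diagonal(ns)
  dt <- 0.01
  fT <- Matrix::lu(I - dt * gen$A_T)
  fP <- Matrix::lu(I - dt * gen$A_P)
  for (k in 1:40) {
    p <- if (k %% 2) as.numeric(Matrix::solve(fT, p + dt * (gen$A_P %*% p)))
         else as.numeric(Matrix::solve(fP, p + dt * (gen$A_T %*% p)))
    expect_lt(abs(sum(p) - 1), 1e-12)
  }
})

test_that("coarse-grained solutions agree with the oracle at desk scale", {
  set.seed(12)
  for (i in 1:3) {
    b <- exp(runif(1, log(4), log(20)))
    ka <- exp(runif(1, log(0.3), log(1.2)))
    r <- from_burst_coordinates(b, ka, 0.03, kappa_p_plus = 1)
    m <- analytic_moments(r)
    mt <- ceiling(m$transcript_mean + 14 * sqrt(m$transcript_var))
    mp <- ceiling(stats::qgamma(1 - 1e-11,
                                shape = m$protein_mean^2 / m$protein_var,
                                scale = m$protein_var / m$protein_mean))
    o <- brute_force_oracle(r, mt, mp)
    caps <- c(max(1, 0.25 * m$transcript_var / m$transcript_mean),
              max(1, 0.25 * m$protein_var / m$protein_mean))
    g <- build_grid(mt, mp, fine_limit = 96, growth = 1.08, max_width = caps)
    s <- steady_state(r, g, options = list(method = "direct",
                                           boundary_tol = 1))
    expect_lt(tv_unit(marginal(s, "protein", interpolate = TRUE),
                      marginal(o, "protein", interpolate = TRUE)), 1e-3)
  }
})

test_that("refining the grid monotonically approaches the oracle", {
  r <- fix_rates_small()
  pm_o <- marginal(fix_oracle_small(), "protein", interpolate = TRUE)
  tvs <- vapply(list(c(16, 1.4, 2), c(32, 1.2, 1), c(64, 1.1, 0.5)),
                function(cfg) {
    s <- steady_state(r, options = list(method = "direct",
                                        fine_limit = cfg[1],
                                        growth = cfg[2], width_cap = cfg[3]))
    tv_unit(marginal(s, "protein", interpolate = TRUE), pm_o)
  }, numeric(1))
  expect_true(all(diff(tvs) < 0))
  expect_lt(tvs[3] / tvs[1], 0.5)
})

test_that("marginals conserve mass and reproduce joint summaries", {
  s <- steady_state(fix_rates_small(), options = list(method = "direct"))
  for (ax in c("protein", "transcript")) {
    m <- marginal(s, ax)
    expect_equal(sum(m$mass), 1, tolerance = 1e-9)
    pmf <- marginal(s, ax, interpolate = TRUE)
    expect_equal(sum(pmf), 1, tolerance = 1e-9)
    # interpolation redistributes within bins but preserves each bin's mass
    for (k in which(m$width > 1)[1:3]) {
      expect_equal(sum(pmf[(m$lo[k]:m$hi[k]) + 1]), m$mass[k],
                   tolerance = 1e-9)
    }
  }
  g <- marginal(s, "gene_state")
  r <- fix_rates_small()
  expect_equal(unname(g[["active"]]),
               active_fraction(r$kappa_a, 1 / r$kappa_r), tolerance = 1e-6)
  expect_error(marginal(s, "nonsense"))
})

test_that("a user-supplied grid that is too small is a hard error", {
  r <- fix_rates_small()
  g <- build_grid(10, 20, fine_limit = 10)
  expect_error(steady_state(r, g, options = list(method = "direct")),
               "boundary")
})

test_that("joint distributions serialize to columnar text plus metadata", {
  s <- steady_state(fix_rates_small(),
                    options = list(method = "direct", fine_limit = 16,
                                   growth = 1.4, width_cap = 2))
  stem <- file.path(tempdir(), "joint")
  write_joint_distribution(s, stem)
  df <- read.csv(paste0(stem, ".csv"))
  expect_equal(sum(df$mass), 1, tolerance = 1e-8)
  meta <- jsonlite::read_json(paste0(stem, ".json"), simplifyVector = TRUE)
  expect_equal(meta$rates$kappa_r, 10)
})
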