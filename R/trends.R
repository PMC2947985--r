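# Cross-clone analyses: variance-mean power law, typical-shape construction,
# burst-parameter regressions, burst-size/frequency correlation, and
# active-fraction predictions under the two modes of burst-size control.

#' Per-clone summary table
#'
#' Collects histogram moments and (optionally) fitted burst parameters into
#' the data.frame consumed by the trend analyses. Only clones passing the
#' twice-autofluorescence inclusion rule should be included.
#'
#' @param hists Named list of processed `rfu_histogram`s.
#' @param fits Optional list of `fit_result`s in the same order.
#' @return A data.frame with columns `clone`, `mu`, `sigma2`, and when fits
#'   are given `b`, `kappa_a`, `tau_max`, `f_max`.
#' @export
clone_summaries <- function(hists, fits = NULL) {
  out <- data.frame(
    clone = if (is.null(names(hists))) as.character(seq_along(hists))
            else names(hists),
    mu = vapply(hists, hist_mean, numeric(1)),
    sigma2 = vapply(hists, hist_var, numeric(1)))
  if (!is.null(fits)) {
    out$b <- vapply(fits, `[[`, numeric(1), "b_opt")
    out$kappa_a <- vapply(fits, `[[`, numeric(1), "kappa_a_opt")
    out$tau_max <- vapply(fits, `[[`, numeric(1), "tau_max")
    out$f_max <- vapply(fits, `[[`, numeric(1), "f_max")
  }
  out
}

# log10-log10 ordinary least squares with standard-theory 95% CIs
powerlaw_ols <- function(x, y, min_points = 5L) {
  ok <- is.finite(x) & is.finite(y) & x > 0 & y > 0
  if (sum(ok) < min_points)
    stop("need at least ", min_points, " positive points for the regression")
  fit <- stats::lm(log10(y[ok]) ~ log10(x[ok]))
  ci <- stats::confint(fit, level = 0.95)
  s <- summary(fit)
  list(alpha = unname(stats::coef(fit)[2]),
       beta = unname(stats::coef(fit)[1]),
       r_squared = s$r.squared,
       alpha_ci = unname(ci[2, ]), beta_ci = unname(ci[1, ]),
       n = sum(ok), fit = fit)
}

#' Variance-mean power law across clones
#'
#' Ordinary least squares of `log10 sigma^2` on `log10 mu` over the clone
#' set: the power-law exponent `alpha` discriminates Poisson-like shape
#' variation (`alpha = 1`, burst-frequency modulation) from pure
#' distribution scaling (`alpha = 2`, burst-size modulation).
#'
#' @param summaries A [clone_summaries()] data.frame (>= 5 clones).
#' @return A `trend_fit` list: `alpha`, `beta`, `r_squared`, 95% CIs, `n`.
#' @export
variance_mean_regression <- function(summaries) {
  out <- powerlaw_ols(summaries$mu, summaries$sigma2)
  structure(c(out, list(which = "sigma2_vs_mu")), class = "trend_fit")
}

#' Power-law trend of a fitted burst parameter with distribution mean
#'
#' Same estimator as [variance_mean_regression()], applied to the fitted
#' burst size or burst frequency against the processed-histogram mean.
#'
#' @param summaries A [clone_summaries()] data.frame with fit columns.
#' @param which `"b"` or `"kappa_a"`.
#' @return A `trend_fit`.
#' @export
parameter_trend <- function(summaries, which = c("b", "kappa_a")) {
  which <- match.arg(which)
  out <- powerlaw_ols(summaries$mu, summaries[[which]])
  structure(c(out, list(which = paste0(which, "_vs_mu"))),
            class = "trend_fit")
}

#' @export
print.trend_fit <- function(x, ...) {
  cat(sprintf(
    "%s: alpha = %.3f [%.3f, %.3f], beta = %.3f, R^2 = %.3f (n = %d)\n",
    x$which, x$alpha, x$alpha_ci[1], x$alpha_ci[2], x$beta, x$r_squared,
    x$n))
  invisible(x)
}

#' Scatter statistics and correlation of the fitted burst parameters
#'
#' Pearson correlation and log-log regression slope (with 95% CI) of burst
#' size against burst frequency, plus the sigma/mu scatter statistic of each
#' log10 parameter. Under independent integration-site control of the two
#' parameters the correlation is near zero; under coupled control
#' (`b` proportional to `kappa_a^2`) it approaches one.
#'
#' @param summaries A [clone_summaries()] data.frame with fit columns.
#' @return List: `pearson_r`, `slope`, `slope_ci`, `r_squared`,
#'   `scatter_log10_b`, `scatter_log10_kappa_a`, `n`.
#' @export
burst_correlation <- function(summaries) {
  if (nrow(summaries) < 5L) stop("need at least 5 clones")
  lb <- log10(summaries$b); la <- log10(summaries$kappa_a)
  reg <- powerlaw_ols(summaries$kappa_a, summaries$b)
  scatter <- function(v) stats::sd(v) / abs(mean(v))
  list(pearson_r = stats::cor(la, lb),
       slope = reg$alpha, slope_ci = reg$alpha_ci,
       r_squared = reg$r_squared,
       scatter_log10_b = scatter(lb),
       scatter_log10_kappa_a = scatter(la),
       n = nrow(summaries))
}

#' Typical distribution shape across clones
#'
#' Translates each clone's (deconvolved) histogram to a common mean and
#' rescales fluorescence about that mean according to the variance-mean
#' power law: `x -> mu_0 + (x - mu) * (mu_0 / mu)^(alpha / 2)`, then
#' averages the transformed distributions with equal weight. With a
#' well-fitting power law every transformed clone has mean `mu_0` and
#' variance `10^beta * mu_0^alpha`, so the average exposes the shared
#' distribution shape.
#'
#' @param hists List of `rfu_histogram`s (identical bins).
#' @param alpha Power-law exponent from [variance_mean_regression()].
#' @param target_mean `mu_0`; default the median of the clone means.
#' @return An `rfu_histogram` with attributes `cv` (coefficient of
#'   variation) and `target_mean`.
#' @export
typical_shape <- function(hists, alpha, target_mean = NULL) {
  mus <- vapply(hists, hist_mean, numeric(1))
  if (any(mus <= 0)) stop("all clone means must be positive")
  mu0 <- if (is.null(target_mean)) stats::median(mus) else target_mean
  bins <- hists[[1]]$edges
  acc <- numeric(length(bins) - 1L)
  for (k in seq_along(hists)) {
    h <- hists[[k]]
    if (!isTRUE(all.equal(h$edges, bins))) stop("histogram binning mismatch")
    s <- (mu0 / mus[k])^(alpha / 2)
    new_edges <- mu0 + (bins - mus[k]) * s      # monotone in x
    cm <- c(0, cumsum(h$mass))
    cum_at <- stats::approxfun(new_edges, cm, rule = 2)
    m <- diff(cum_at(bins))
    m[m < 0] <- 0
    m[1] <- m[1] + cum_at(bins[1])              # mass shifted below range
    acc <- acc + m / sum(c(m[1], m[-1]))
  }
  out <- new_rfu_histogram(acc / sum(acc), bins)
  attr(out, "cv") <- sqrt(hist_var(out)) / hist_mean(out)
  attr(out, "target_mean") <- mu0
  out
}

#' Predicted active fractions under the two modes of burst-size control
#'
#' Burst size `b = kappa_t_plus * tau` can be modulated by the stability of
#' the active state (Mode 1: `tau` varies, transcription rate fixed) or by
#' the active-state transcription rate (Mode 2: `kappa_t_plus` varies, `tau`
#' fixed). The two modes predict distinct active-fraction patterns across
#' clones: under Mode 1 `f` tracks the clone mean (small-f limit:
#' `f ~ kappa_a * b / kappa_t_plus`), under Mode 2 `f` mirrors the
#' burst-frequency scatter. Predictions are clipped at each clone's `f_max`
#' bound when available.
#'
#' @param summaries A [clone_summaries()] data.frame with fit columns.
#' @param mode 1 (fixed transcription rate) or 2 (fixed active duration).
#' @param fixed_value `kappa_t_plus` for Mode 1, `tau` for Mode 2 (> 0).
#' @return Data.frame: `clone`, `f`, `f_unclipped`, `clipped`.
#' @export
mode_prediction <- function(summaries, mode = c(1, 2), fixed_value) {
  mode <- match.arg(as.character(mode[1]), c("1", "2"))
  if (fixed_value <= 0) stop("fixed_value must be positive")
  f_raw <- if (mode == "1") {
    tau_i <- summaries$b / fixed_value
    active_fraction(summaries$kappa_a, tau_i)
  } else {
    active_fraction(summaries$kappa_a, fixed_value)
  }
  f <- f_raw
  clipped <- rep(FALSE, length(f))
  if (!is.null(summaries$f_max)) {
    clipped <- f_raw > summaries$f_max
    f <- pmin(f_raw, summaries$f_max)
  }
  data.frame(clone = summaries$clone, f = f, f_unclipped = f_raw,
             clipped = clipped)
}

#' Full cross-clone trend report
#'
#' Bundles the variance-mean regression, both parameter trends, and the
#' burst correlation into one list (serializable with
#' [jsonlite::write_json()]).
#'
#' @param summaries A [clone_summaries()] data.frame with fit columns.
#' @return A `trend_report` list.
#' @export
trend_report <- function(summaries) {
  structure(list(
    variance_mean = variance_mean_regression(summaries),
    b_trend = parameter_trend(summaries, "b"),
    kappa_a_trend = parameter_trend(summaries, "kappa_a"),
    correlation = burst_correlation(summaries),
    n_clones = nrow(summaries)), class = "trend_report")
}

#' @export
print.trend_report <- function(x, ...) {
  print(x$variance_mean); print(x$b_trend); print(x$kappa_a_trend)
  cat(sprintf("log b vs log kappa_a: pearson r = %.2f, slope = %.2f [%.2f, %.2f]\n",
              x$correlation$pearson_r, x$correlation$slope,
              x$correlation$slope_ci[1], x$correlation$slope_ci[2]))
  invisible(x)
}
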