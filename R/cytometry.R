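# Transforms between model space and cytometer space: event gating,
# log-binned fluorescence histograms, Fourier smoothing, autofluorescence
# convolution / Wiener deconvolution, and protein -> RFU calibration.

#' Cytometry event table
#'
#' Validates a per-cell event table with columns `gfp` (fluorescence, RFU),
#' `fsc` and `ssc` (forward/side scatter on the instrument's 1-1024 linear
#' scale).
#'
#' @param df A data.frame with numeric columns `gfp`, `fsc`, `ssc`.
#' @param clone_id Optional clone identifier stored as an attribute.
#' @return The data.frame, classed `event_table`.
#' @export
event_table <- function(df, clone_id = NA_character_) {
  need <- c("gfp", "fsc", "ssc")
  if (!all(need %in% names(df)))
    stop("event table needs columns gfp, fsc, ssc")
  if (anyNA(df[need])) stop("event table contains missing values")
  if (any(df$gfp <= 0)) stop("gfp values must be positive RFU")
  df <- as.data.frame(df)
  attr(df, "clone_id") <- clone_id
  class(df) <- c("event_table", "data.frame")
  df
}

#' Read / write cytometry event tables
#'
#' Plain-text readers and writers for per-cell event tables with columns
#' `gfp`, `fsc`, `ssc` (CSV, or TSV for `.tsv`/`.txt` paths).
#'
#' @param path File path.
#' @return `read_events` returns an `event_table`.
#' @export
read_events <- function(path) {
  sep <- if (grepl("\\.(tsv|txt)$", path)) "\t" else ","
  event_table(utils::read.table(path, header = TRUE, sep = sep),
              clone_id = sub("\\.[^.]*$", "", basename(path)))
}

#' @rdname read_events
#' @param events An `event_table`.
#' @export
write_events <- function(events, path) {
  sep <- if (grepl("\\.(tsv|txt)$", path)) "\t" else ","
  utils::write.table(events, path, sep = sep, row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Default log-spaced fluorescence bins
#'
#' 256 log-spaced bins covering the instrument's four decades
#' (0.1 to 1000 RFU by default).
#'
#' @param n_bins Number of bins.
#' @param rfu_min,rfu_max Range covered.
#' @return Numeric vector of `n_bins + 1` strictly increasing edges with a
#'   constant ratio.
#' @export
default_bins <- function(n_bins = 256, rfu_min = 0.1, rfu_max = 1000) {
  10^seq(log10(rfu_min), log10(rfu_max), length.out = n_bins + 1)
}

new_rfu_histogram <- function(mass, edges, n_events = NA_integer_,
                              clipped = c(low = 0L, high = 0L),
                              smoothing = NULL) {
  structure(list(mass = mass, edges = edges,
                 centers = sqrt(edges[-1] * edges[-length(edges)]),
                 n_events = n_events, clipped = clipped,
                 smoothing = smoothing),
            class = "rfu_histogram")
}

#' @export
print.rfu_histogram <- function(x, ...) {
  cat(sprintf(
    "RFU histogram: %d log bins [%.3g, %.3g], mean %.3g RFU, CV %.2f%s\n",
    length(x$mass), x$edges[1], x$edges[length(x$edges)],
    hist_mean(x), sqrt(hist_var(x)) / hist_mean(x),
    if (is.null(x$smoothing)) "" else
      sprintf(", smoothed (cutoff %d)", x$smoothing$cutoff)))
  invisible(x)
}

#' Histogram moments
#'
#' Mean and variance of a binned fluorescence distribution, evaluated at the
#' geometric bin centers.
#'
#' @param hist An `rfu_histogram`.
#' @return A single number (RFU, or RFU squared for the variance).
#' @export
hist_mean <- function(hist) sum(hist$mass * hist$centers)

#' @rdname hist_mean
#' @export
hist_var <- function(hist) {
  mu <- hist_mean(hist)
  sum(hist$mass * (hist$centers - mu)^2)
}

#' Scatter-gate a cytometry event table
#'
#' Retains events inside the central `gate_fraction` quantile box of
#' (FSC, SSC), optionally after an elliptical live-cell gate at 2.5 median
#' absolute deviations, the standard first-pass debris filter.
#'
#' @param events An `event_table`.
#' @param gate_fraction Central fraction of each scatter axis to keep
#'   (0 < fraction <= 1; the conventional default is 0.6, the mid 60%).
#' @param live_gate Apply the elliptical pre-gate first.
#' @param min_events Minimum surviving events (default 200).
#' @return The gated `event_table`.
#' @export
gate_events <- function(events, gate_fraction = 0.6, live_gate = FALSE,
                        min_events = 200L) {
  stopifnot(inherits(events, "event_table"))
  if (gate_fraction <= 0 || gate_fraction > 1)
    stop("gate_fraction must be in (0, 1]")
  keep <- rep(TRUE, nrow(events))
  if (live_gate) {
    z <- function(v) (v - stats::median(v)) / (stats::mad(v) + 1e-12)
    keep <- (z(events$fsc)^2 + z(events$ssc)^2) <= 2.5^2
  }
  if (gate_fraction < 1) {
    lo <- (1 - gate_fraction) / 2; hi <- 1 - lo
    for (ax in c("fsc", "ssc")) {
      q <- stats::quantile(events[[ax]][keep], c(lo, hi), names = FALSE)
      keep <- keep & events[[ax]] >= q[1] & events[[ax]] <= q[2]
    }
  }
  out <- events[keep, , drop = FALSE]
  if (nrow(out) < min_events)
    stop("fewer than ", min_events, " events survive the gate")
  attr(out, "clone_id") <- attr(events, "clone_id")
  class(out) <- c("event_table", "data.frame")
  out
}

#' Log-binned fluorescence histogram of gated events
#'
#' Normalized probability mass over log-spaced RFU bins; values outside the
#' binned range are clipped into the end bins and the clipping is reported.
#'
#' @param events An `event_table` (or numeric vector of RFU values).
#' @param bins Bin edges, as from [default_bins()].
#' @return An `rfu_histogram`.
#' @export
rfu_histogram <- function(events, bins = default_bins()) {
  gfp <- if (is.data.frame(events)) events$gfp else events
  if (length(gfp) == 0L) stop("no events to histogram")
  clipped <- c(low = sum(gfp < bins[1]), high = sum(gfp > bins[length(bins)]))
  gfp <- pmin(pmax(gfp, bins[1]), bins[length(bins)])
  idx <- findInterval(gfp, bins, rightmost.closed = TRUE)
  idx <- pmin(pmax(idx, 1L), length(bins) - 1L)
  mass <- tabulate(idx, nbins = length(bins) - 1L)
  new_rfu_histogram(mass / sum(mass), bins, n_events = length(gfp),
                    clipped = clipped)
}

#' Low-pass Fourier smoothing of a histogram
#'
#' Smooths the binned distribution by discarding discrete-Fourier harmonics
#' (over the log-bin index) above `cutoff`, then clipping negative ripples to
#' zero and renormalizing. `cutoff = "auto"` selects the cutoff by a
#' bootstrap: multinomial resamples of the histogram are smoothed at each
#' candidate and the cutoff minimizing the mean squared deviation from the
#' full-sample histogram (a cross-validation-style bias-plus-variance proxy)
#' is chosen.
#'
#' @param hist An `rfu_histogram`.
#' @param cutoff Highest retained harmonic index, or `"auto"`.
#' @param candidates Candidate cutoffs for `"auto"`.
#' @param n_boot Bootstrap resamples for `"auto"` (default 50).
#' @param seed RNG seed for the bootstrap.
#' @return The smoothed `rfu_histogram` (with `smoothing` metadata).
#' @export
smooth_histogram <- function(hist, cutoff = "auto",
                             candidates = c(8, 12, 16, 24, 32, 48),
                             n_boot = 50, seed = 1L) {
  stopifnot(inherits(hist, "rfu_histogram"))
  n <- length(hist$mass)
  if (identical(cutoff, "auto")) {
    ne <- if (is.na(hist$n_events)) 10000L else hist$n_events
    withr_seed <- .with_seed(seed, {
      devs <- vapply(candidates, function(co) {
        mean(vapply(seq_len(n_boot), function(i) {
          counts <- stats::rmultinom(1L, ne, hist$mass)[, 1L]
          sm <- .fourier_lowpass(counts / ne, co)
          sum((sm - hist$mass)^2)
        }, numeric(1)))
      }, numeric(1))
    })
    cutoff <- candidates[which.min(devs)]
  }
  cutoff <- as.integer(cutoff)
  if (cutoff >= n %/% 2) {
    warning("cutoff at or above Nyquist; returning histogram unchanged")
    hist$smoothing <- list(cutoff = cutoff, identity = TRUE)
    return(hist)
  }
  out <- hist
  out$mass <- .fourier_lowpass(hist$mass, cutoff)
  out$smoothing <- list(cutoff = cutoff, identity = FALSE)
  out
}

# Low-pass with a cosine-tapered transfer function: unity up to cutoff/2,
# cosine rolloff to zero at cutoff. A brick-wall response would ring
# (circular sinc lobes leak mass across the whole axis, which clipping then
# turns into spurious far-tail mass); the taper keeps the response compact.
.fourier_lowpass <- function(mass, cutoff) {
  n <- length(mass)
  if (cutoff >= n %/% 2) return(mass)
  k <- c(0:(n %/% 2), -((n - n %/% 2 - 1):1))   # signed harmonic index
  ak <- abs(k)
  c1 <- cutoff / 2
  resp <- ifelse(ak <= c1, 1,
          ifelse(ak >= cutoff, 0,
                 0.5 * (1 + cos(pi * (ak - c1) / (cutoff - c1)))))
  sm <- Re(stats::fft(stats::fft(mass) * resp, inverse = TRUE)) / n
  sm[sm < 0] <- 0
  sm / sum(sm)
}

# evaluate an expression with a local, restored RNG state
.with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv())
          else suppressWarnings(rm(".Random.seed", envir = globalenv())))
  set.seed(seed)
  expr
}

#' Bootstrap-optimized scatter gate
#'
#' Chooses the scatter-gate width that best resolves the fluorescence profile
#' at the mean scattering measure. The target is the smoothed GFP histogram
#' of events in a thin FSC slice centred on the mean FSC; for each candidate
#' gate fraction, bootstrap resamples of the full event table are gated,
#' histogrammed and smoothed, and their mean squared deviation from the
#' target is recorded. The candidate with the smallest mean deviation wins
#' (ties go to the larger fraction, which retains more events).
#'
#' @param events An `event_table`.
#' @param candidate_fractions At least two candidate gate fractions.
#' @param n_boot Bootstrap resamples per candidate (default 100).
#' @param seed RNG seed.
#' @param slice_fraction Fraction of events, nearest the mean FSC, defining
#'   the target slice (default 0.1).
#' @param bins,cutoff Histogram bins and smoothing cutoff used throughout.
#' @return The selected gate fraction, with attribute `deviations` (mean
#'   bootstrap deviation per candidate).
#' @export
optimize_gate <- function(events, candidate_fractions = c(0.2, 0.4, 0.6, 0.8, 1),
                          n_boot = 100, seed = 1L, slice_fraction = 0.1,
                          bins = default_bins(), cutoff = 16) {
  stopifnot(inherits(events, "event_table"))
  if (length(candidate_fractions) < 2L) stop("need >= 2 candidate fractions")
  cf <- sort(candidate_fractions)
  d <- abs(events$fsc - mean(events$fsc))
  slice <- events[d <= stats::quantile(d, slice_fraction), , drop = FALSE]
  class(slice) <- class(events)
  target <- smooth_histogram(rfu_histogram(slice, bins), cutoff)$mass
  devs <- .with_seed(seed, {
    vapply(cf, function(fr) {
      ok <- 0L; tot <- 0
      for (i in seq_len(n_boot)) {
        res <- events[sample.int(nrow(events), replace = TRUE), , drop = FALSE]
        class(res) <- class(events)
        h <- tryCatch({
          g <- gate_events(res, fr)
          smooth_histogram(rfu_histogram(g, bins), cutoff)$mass
        }, error = function(e) NULL)
        if (is.null(h)) next
        ok <- ok + 1L
        tot <- tot + sum((h - target)^2)
      }
      if (ok == 0L) return(NA_real_)
      tot / ok
    }, numeric(1))
  })
  if (all(is.na(devs))) stop("all candidate gates failed the event threshold")
  best <- max(cf[devs <= min(devs, na.rm = TRUE) + 1e-15 & !is.na(devs)])
  structure(best, deviations = stats::setNames(devs, cf))
}

#' Autofluorescence profile
#'
#' Summarizes a separately measured event table of uninfected (reporter-free)
#' cells as the background-fluorescence distribution that clone measurements
#' are convolved with.
#'
#' @param events An `event_table` of background events (or an
#'   `rfu_histogram`).
#' @param bins Bin edges; must match the clone histograms.
#' @param cutoff Smoothing cutoff applied to the measured profile.
#' @return An object of class `autofluorescence_profile` with fields `hist`,
#'   `mean`, `var`.
#' @export
autofluorescence_profile <- function(events, bins = default_bins(),
                                     cutoff = 16) {
  h <- if (inherits(events, "rfu_histogram")) events
       else smooth_histogram(rfu_histogram(events, bins), cutoff)
  structure(list(hist = h, mean = hist_mean(h), var = hist_var(h)),
            class = "autofluorescence_profile")
}

# ---- linear-RFU lattice machinery -----------------------------------------
# Sums of independent fluorescence contributions convolve on the linear RFU
# scale, not the log-binned scale, so histograms are resampled onto a uniform
# linear lattice for convolution and deconvolution, then re-binned.

make_lattice <- function(rfu_max, n = 4096L) {
  step <- rfu_max / n
  list(step = step, n = as.integer(n),
       edges = seq(0, rfu_max, length.out = n + 1L))
}

# piecewise-uniform-density resampling of log-binned mass onto the lattice
hist_to_lattice <- function(hist, lattice) {
  cum_at <- function(x) {
    cm <- c(0, cumsum(hist$mass))
    stats::approx(hist$edges, cm, xout = pmin(pmax(x, hist$edges[1]),
                                              hist$edges[length(hist$edges)]),
                  rule = 2)$y
  }
  diff(cum_at(lattice$edges))
}

lattice_to_hist <- function(mass, lattice, bins, n_events = NA_integer_,
                            smoothing = NULL) {
  cm <- c(0, cumsum(mass))
  cum_at <- function(x) stats::approx(lattice$edges, cm,
                                      xout = pmin(pmax(x, 0), lattice$edges[lattice$n + 1L]),
                                      rule = 2)$y
  m <- diff(cum_at(bins))
  m[m < 0] <- 0
  # mass below the first or above the last edge is clipped into the end bins
  m[1] <- m[1] + cum_at(bins[1])
  m[length(m)] <- m[length(m)] + (sum(mass) - cum_at(bins[length(bins)]))
  new_rfu_histogram(m / sum(m), bins, n_events = n_events,
                    smoothing = smoothing)
}

fft_convolve <- function(a, b) {
  n <- length(a) + length(b) - 1L
  nfft <- stats::nextn(n, 2)
  out <- Re(stats::fft(stats::fft(c(a, numeric(nfft - length(a)))) *
                       stats::fft(c(b, numeric(nfft - length(b)))),
                       inverse = TRUE)) / nfft
  out <- out[seq_len(n)]
  out[out < 0] <- 0
  out
}

#' Convolve a model histogram with the autofluorescence background
#'
#' Computes the distribution of the sum (reporter signal +
#' autofluorescence), resampling both distributions to a common linear-RFU
#' lattice, convolving there, and re-binning to the log bins. Means (and, for
#' independent contributions, variances) add up to binning error.
#'
#' @param model_hist An `rfu_histogram` of the signal.
#' @param autofluor An `autofluorescence_profile`.
#' @param n_lattice Lattice resolution (default 4096).
#' @return An `rfu_histogram` on the same bins as `model_hist`.
#' @export
convolve_autofluorescence <- function(model_hist, autofluor,
                                      n_lattice = 4096L) {
  stopifnot(inherits(autofluor, "autofluorescence_profile"))
  bins <- model_hist$edges
  if (!isTRUE(all.equal(bins, autofluor$hist$edges)))
    stop("model and autofluorescence histograms must share binning")
  lat <- make_lattice(bins[length(bins)], n_lattice)
  s <- fft_convolve(hist_to_lattice(model_hist, lat),
                    hist_to_lattice(autofluor$hist, lat))
  lat2 <- list(step = lat$step, n = length(s),
               edges = seq(0, by = lat$step, length.out = length(s) + 1L))
  lattice_to_hist(s, lat2, bins, n_events = model_hist$n_events)
}

#' Wiener deconvolution of the autofluorescence background
#'
#' Removes the additive autofluorescence contribution from a measured
#' distribution by regularized Fourier-domain division on the linear-RFU
#' lattice. The regularization constant (`noise_level`, a fraction of the
#' peak spectral power of the background kernel) suppresses noise
#' amplification; output is clipped to non-negative densities and
#' renormalized.
#'
#' @param data_hist Measured `rfu_histogram`.
#' @param autofluor An `autofluorescence_profile`.
#' @param noise_level Regularization, relative to peak kernel power
#'   (default 1e-3).
#' @param n_lattice Lattice resolution.
#' @return The deconvolved signal `rfu_histogram`.
#' @export
deconvolve_autofluorescence <- function(data_hist, autofluor,
                                        noise_level = 1e-3,
                                        n_lattice = 4096L) {
  stopifnot(inherits(autofluor, "autofluorescence_profile"))
  if (hist_mean(data_hist) < autofluor$mean)
    stop("insufficient signal: data mean below autofluorescence mean")
  bins <- data_hist$edges
  lat <- make_lattice(bins[length(bins)], n_lattice)
  # zero-pad to twice the lattice so circular wrap-around lands in the pad;
  # padded cells hold negative lags, physically zero fluorescence
  n2 <- 2L * lat$n
  g <- stats::fft(c(hist_to_lattice(data_hist, lat), numeric(lat$n)))
  h <- stats::fft(c(hist_to_lattice(autofluor$hist, lat), numeric(lat$n)))
  p2 <- Mod(h)^2
  s <- Re(stats::fft(g * Conj(h) / (p2 + noise_level * max(p2)),
                     inverse = TRUE)) / n2
  s[s < 0] <- 0
  # remove broadband Gibbs ripples left by the regularized inverse: clipped
  # low-amplitude lobes far from the signal would otherwise carry spurious
  # mass to high fluorescence after renormalization
  s[s < 1e-4 * max(s)] <- 0
  out <- s[seq_len(lat$n)]
  out[1] <- out[1] + sum(s[(lat$n + 1L):n2])   # negative lags clip to zero
  lattice_to_hist(out, lat, bins, n_events = data_hist$n_events)
}

#' Forward map: protein distribution to predicted cytometer histogram
#'
#' Converts a steady-state protein count PMF to the predicted measured
#' fluorescence distribution: counts are scaled by the per-protein
#' fluorescence `nu = gamma * kappa_p_minus / kappa_p_plus`, convolved with
#' the autofluorescence profile on the linear lattice, and binned to the log
#' bins. This is the complete forward map used by the fitting module.
#'
#' @param protein_pmf Numeric PMF over protein counts `0, 1, 2, ...` (as from
#'   `marginal(joint, "protein", interpolate = TRUE)`).
#' @param calib A [calibration()] object.
#' @param autofluor An `autofluorescence_profile`, or `NULL` for no
#'   background.
#' @param bins Output bin edges.
#' @param n_lattice Lattice resolution.
#' @return An `rfu_histogram`.
#' @export
model_to_rfu <- function(protein_pmf, calib, autofluor = NULL,
                         bins = default_bins(), n_lattice = 4096L) {
  nu <- calib$nu
  rfu_max_model <- nu * (length(protein_pmf) - 1L)
  lat_max <- max(bins[length(bins)], rfu_max_model * 1.05)
  lat <- make_lattice(lat_max, n_lattice)
  # deposit each count's mass into its lattice cell
  cell <- pmin(floor(nu * (seq_along(protein_pmf) - 1L) / lat$step), lat$n - 1L) + 1L
  sig <- numeric(lat$n)
  agg <- rowsum(protein_pmf, cell)
  sig[as.integer(rownames(agg))] <- agg[, 1L]
  if (!is.null(autofluor)) {
    if (!isTRUE(all.equal(bins, autofluor$hist$edges)))
      stop("bins must match the autofluorescence profile")
    sig <- fft_convolve(sig, hist_to_lattice(autofluor$hist, lat))
  }
  lat2 <- list(step = lat$step, n = length(sig),
               edges = seq(0, by = lat$step, length.out = length(sig) + 1L))
  lattice_to_hist(sig, lat2, bins)
}

#' Clone inclusion rule
#'
#' Clones whose mean fluorescence is below twice the autofluorescence mean
#' are too close to background for model fitting and are excluded.
#'
#' @param hists A list of `rfu_histogram`s (one per clone).
#' @param autofluor An `autofluorescence_profile`.
#' @return Logical inclusion vector with attribute `report` (a data.frame of
#'   clone means and the threshold).
#' @export
include_clones <- function(hists, autofluor) {
  mu <- vapply(hists, hist_mean, numeric(1))
  keep <- mu >= 2 * autofluor$mean
  structure(keep, report = data.frame(
    clone = if (is.null(names(hists))) seq_along(hists) else names(hists),
    mean_rfu = mu, threshold = 2 * autofluor$mean, included = keep))
}

#' Write a histogram as CSV with JSON metadata
#'
#' @param hist An `rfu_histogram`.
#' @param path Output stem; `<path>.csv` and `<path>.json` are written.
#' @export
write_histogram <- function(hist, path) {
  utils::write.csv(data.frame(bin_left = hist$edges[-length(hist$edges)],
                              bin_right = hist$edges[-1],
                              mass = hist$mass),
                   paste0(path, ".csv"), row.names = FALSE)
  jsonlite::write_json(list(n_events = hist$n_events,
                            clipped = as.list(hist$clipped),
                            smoothing = hist$smoothing),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_histogram
#' @export
read_histogram <- function(path) {
  df <- utils::read.csv(paste0(path, ".csv"))
  meta <- tryCatch(jsonlite::read_json(paste0(path, ".json"),
                                       simplifyVector = TRUE),
                   error = function(e) list())
  new_rfu_histogram(df$mass / sum(df$mass),
                    c(df$bin_left, df$bin_right[nrow(df)]),
                    n_events = if (is.null(meta$n_events)) NA_integer_
                               else meta$n_events,
                    smoothing = meta$smoothing)
}
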