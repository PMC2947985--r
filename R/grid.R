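#' Graded coarse-grained state grid for one count axis
#'
#' Builds the bin layout used by the coarse-grained master-equation solver on
#' a single molecular-count axis: unit-width bins (one bin per count) up to
#' `fine_limit`, after which bin widths grow geometrically by `growth`
#' (rounded to whole counts, never decreasing) until the final edge reaches
#' at least `max_count`. At low counts the scheme therefore reproduces the
#' master equation exactly; at high counts, where the distribution admits a
#' continuum description, states are lumped.
#'
#' @param max_count Largest count that must be covered (>= 0).
#' @param fine_limit Largest count resolved at unit width (default 32).
#' @param growth Geometric width growth factor for coarse bins (default 1.2).
#' @param max_width Cap on coarse-bin width (counts). Distribution tails in
#'   the bursting regime decay exponentially with a scale of order
#'   variance/mean, and any interface flux approximation needs bins no wider
#'   than a fraction of that scale wherever appreciable mass lives; the
#'   parameter-aware grids built by [default_grid()] set it accordingly.
#' @return An object of class `count_grid`: integer vectors `lo`, `hi`
#'   (inclusive count ranges per bin), `width`, representative values `x`
#'   (bin midpoints), and `n_bins`.
#' @examples
#' g <- build_axis_grid(1000, fine_limit = 32, growth = 1.2)
#' g$n_bins
#' @export
build_axis_grid <- function(max_count, fine_limit = 32, growth = 1.2,
                            max_width = Inf) {
  max_count <- as.integer(ceiling(max_count))
  if (fine_limit > max_count) fine_limit <- max_count
  if (growth <= 1) stop("growth must be > 1")
  lo <- 0:fine_limit
  hi <- 0:fine_limit
  if (max_count > fine_limit) {
    w_real <- 1
    nxt <- fine_limit + 1L
    last_w <- 1L
    cap <- if (is.finite(max_width)) max(1L, as.integer(floor(max_width)))
           else .Machine$integer.max
    while (nxt <= max_count) {
      w_real <- min(w_real * growth, cap)
      w <- max(last_w, as.integer(round(w_real)))  # widths non-decreasing
      w <- min(w, cap)
      lo <- c(lo, nxt)
      hi <- c(hi, min(nxt + w - 1L, .Machine$integer.max))
      nxt <- nxt + w
      last_w <- w
    }
  }
  structure(list(lo = as.integer(lo), hi = as.integer(hi),
                 width = as.integer(hi - lo + 1L),
                 x = (lo + hi) / 2,
                 n_bins = length(lo),
                 fine_limit = as.integer(fine_limit),
                 growth = growth, max_width = max_width,
                 max_count = max(hi)),
            class = "count_grid")
}

#' Joint state grid over gene state, transcript and protein counts
#'
#' Combines two [build_axis_grid()] layouts (transcripts, proteins) with the
#' two-valued gene-state axis. Default truncations are parameter-aware: mean
#' plus `n_sd` standard deviations per axis from [analytic_moments()],
#' auto-expanded by the solver if truncation-boundary mass is excessive.
#'
#' @param max_transcripts,max_proteins Axis truncations (counts).
#' @param fine_limit Unit-width region per axis; either one value or a
#'   length-2 vector (transcripts, proteins).
#' @param growth Coarse-bin growth factor (scalar or length-2).
#' @return An object of class `state_grid` with components `transcript` and
#'   `protein` (each a `count_grid`) and `n_states`.
#' @export
build_grid <- function(max_transcripts, max_proteins,
                       fine_limit = 32, growth = 1.2, max_width = Inf) {
  fine_limit <- rep_len(fine_limit, 2L)
  growth <- rep_len(growth, 2L)
  max_width <- rep_len(max_width, 2L)
  tg <- build_axis_grid(max_transcripts, fine_limit[1], growth[1], max_width[1])
  pg <- build_axis_grid(max_proteins, fine_limit[2], growth[2], max_width[2])
  structure(list(transcript = tg, protein = pg,
                 n_states = 2L * tg$n_bins * pg$n_bins),
            class = "state_grid")
}

#' @export
print.state_grid <- function(x, ...) {
  cat(sprintf(
    "state grid: 2 gene states x %d transcript bins (max %d) x %d protein bins (max %d) = %d states\n",
    x$transcript$n_bins, x$transcript$max_count,
    x$protein$n_bins, x$protein$max_count, x$n_states))
  invisible(x)
}

#' Default parameter-aware grid for a rate set
#'
#' Truncates each axis at the larger of mean + `n_sd` standard deviations
#' and the `1 - tail_prob` quantile of a moment-matched Gamma distribution
#' (bursting-regime marginals are Gamma-like with exponential tails, for
#' which standard-deviation-based truncation is far too generous), and caps
#' coarse-bin widths at `width_cap` times each axis's tail decay scale
#' (variance/mean, the Fano factor) -- the resolution the centered flux
#' scheme needs to stay oscillation-free.
#'
#' @param rates A `rate_constants` object.
#' @param n_sd Number of standard deviations beyond the mean (default 8).
#' @param tail_prob Truncated tail probability bound (default 1e-10).
#' @param fine_limit,growth Passed to [build_grid()].
#' @param width_cap Coarse-bin width cap as a fraction of each axis's Fano
#'   factor (default 0.5). Larger values give smaller, faster, less accurate
#'   grids; beyond ~0.5 the stationary solve develops visible ripples.
#' @param min_count Lower bound on each truncation (default 16).
#' @return A `state_grid`.
#' @export
default_grid <- function(rates, n_sd = 8, tail_prob = 1e-10,
                         fine_limit = 32, growth = 1.2,
                         width_cap = 0.5, min_count = 16) {
  m <- analytic_moments(rates)
  qb <- function(mean, var) {
    k <- mean^2 / var
    max(mean + n_sd * sqrt(var),
        stats::qgamma(1 - tail_prob, shape = k, scale = var / mean))
  }
  mt <- ceiling(qb(m$transcript_mean, m$transcript_var))
  mp <- ceiling(qb(m$protein_mean, m$protein_var))
  caps <- c(max(1, width_cap * m$transcript_var / m$transcript_mean),
            max(1, width_cap * m$protein_var / m$protein_mean))
  build_grid(max(min_count, mt), max(min_count, mp),
             fine_limit = fine_limit, growth = growth, max_width = caps)
}
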