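# Synthetic clonal cytometry data with known ground truth: protein counts
# drawn from the model's exact steady state (or by exact stochastic
# simulation), passed through an emulated cytometer with cell-size coupling
# and autofluorescence background.

#' Scenario specification for a synthetic clone ensemble
#'
#' Defines how burst parameters vary across an ensemble of integration
#' clones. `"frequency_only"` varies the burst frequency `kappa_a`
#' (log-uniform) at fixed burst size; `"size_only"` varies the burst size
#' (log-uniform, via the active-state transcription rate) at fixed frequency;
#' `"combined"` couples them as `b = c * kappa_a^2`, the modulation pattern
#' in which a more productive integration increases activation, active-state
#' stability and transcription rate proportionately. For `"combined"` the
#' `kappa_a` range is derived from `b_range` and `coupling` so the burst
#' sizes span exactly `b_range`.
#'
#' @param scenario One of `"frequency_only"`, `"size_only"`, `"combined"`.
#' @param n_clones Number of clones (default 31).
#' @param kappa_a_range Log-uniform activation-rate range (default
#'   `c(0.1, 3)`).
#' @param b_range Burst-size range or fixed-scenario bounds (default
#'   `c(2, 50)`).
#' @param b_fixed,kappa_a_fixed Fixed values for the single-parameter
#'   scenarios (defaults 15 and 0.3).
#' @param coupling Coefficient `c` in `b = c * kappa_a^2`; default aligns
#'   the geometric centers of `b_range` and `kappa_a_range`.
#' @param tau Active duration, fixed across clones (default 0.02).
#' @param calib A [calibration()] object.
#' @param n_events Cytometry events per clone (default 10000).
#' @param autofluor_mean,autofluor_cv Background fluorescence parameters
#'   (defaults 5 RFU, 0.5).
#' @param size_coupling Exponent of the latent cell-size factor in the
#'   fluorescence signal (default 0.5).
#' @param s_cv Log-sd of the latent size factor (default 0.25).
#' @param seed Integer seed; every generator below is a pure function of
#'   (spec, seed).
#' @return A `scenario_spec` list.
#' @export
scenario_spec <- function(scenario = c("combined", "frequency_only", "size_only"),
                          n_clones = 31L, kappa_a_range = c(0.1, 3),
                          b_range = c(2, 50), b_fixed = 15,
                          kappa_a_fixed = 0.3, coupling = NULL,
                          tau = 0.02, calib = calibration(),
                          n_events = 10000L, autofluor_mean = 5,
                          autofluor_cv = 0.5, size_coupling = 0.5,
                          s_cv = 0.25, seed = 1L) {
  scenario <- match.arg(scenario)
  stopifnot(all(kappa_a_range > 0), all(b_range > 0), tau > 0, n_clones >= 1)
  if (is.null(coupling)) {
    gm <- function(r) sqrt(r[1] * r[2])
    coupling <- gm(b_range) / gm(kappa_a_range)^2
  }
  if (scenario == "combined") {
    kappa_a_range <- sqrt(b_range / coupling)
    if (any(!is.finite(kappa_a_range)))
      stop("infeasible coupling for requested b_range")
  }
  structure(list(scenario = scenario, n_clones = as.integer(n_clones),
                 kappa_a_range = kappa_a_range, b_range = b_range,
                 b_fixed = b_fixed, kappa_a_fixed = kappa_a_fixed,
                 coupling = coupling, tau = tau, calib = calib,
                 n_events = as.integer(n_events),
                 autofluor_mean = autofluor_mean,
                 autofluor_cv = autofluor_cv,
                 size_coupling = size_coupling, s_cv = s_cv,
                 seed = as.integer(seed)),
            class = "scenario_spec")
}

#' Ground-truth burst parameters for a scenario
#'
#' Draws the per-clone burst coordinates (without simulating events), the
#' deterministic first stage of [generate_ensemble()].
#'
#' @param spec A [scenario_spec()].
#' @return A data.frame with columns `clone`, `kappa_a`, `b`, `tau`.
#' @export
draw_ensemble_parameters <- function(spec) {
  stopifnot(inherits(spec, "scenario_spec"))
  .with_seed(spec$seed, {
    lu <- function(r, n) exp(stats::runif(n, log(r[1]), log(r[2])))
    ka <- switch(spec$scenario,
                 frequency_only = lu(spec$kappa_a_range, spec$n_clones),
                 size_only = rep(spec$kappa_a_fixed, spec$n_clones),
                 combined = lu(spec$kappa_a_range, spec$n_clones))
    b <- switch(spec$scenario,
                frequency_only = rep(spec$b_fixed, spec$n_clones),
                size_only = lu(spec$b_range, spec$n_clones),
                combined = spec$coupling * ka^2)
    data.frame(clone = seq_len(spec$n_clones), kappa_a = ka, b = b,
               tau = spec$tau)
  })
}

#' Simulate one clonal cytometry measurement
#'
#' Draws per-cell protein counts from the model's steady state (by
#' inverse-CDF sampling of the solved protein marginal, or by exact
#' stochastic simulation) and emulates the cytometer: each cell carries a
#' latent size factor `s ~ lognormal(0, s_cv)`; measured fluorescence is
#' `nu * protein * s^eta` plus an autofluorescence draw, clipped to the
#' instrument's four-decade range, and forward/side scatter are
#' `512 * s * (1 + noise)` clipped to the 1-1024 channel range.
#'
#' @param rates A [rate_constants()] object (ground truth).
#' @param calib A [calibration()] object.
#' @param n_events Number of cells (>= 1000).
#' @param autofluor_mean,autofluor_cv Background lognormal parameters.
#' @param size_coupling Exponent `eta` coupling fluorescence to cell size.
#' @param s_cv Log-sd of the size factor.
#' @param seed Integer seed (same seed, bit-identical table).
#' @param method `"cme"` (sample the solved steady-state marginal) or
#'   `"ssa"` (exact stochastic simulation); the two agree statistically.
#' @param solver_options Options for [steady_state()] when `method = "cme"`.
#' @param ssa_duration Simulated time for `"ssa"` (default 40 transcript
#'   lifetimes, i.e. 10 protein lifetimes at the default rates).
#' @return A `synthetic_clone`: list with `events` (an [event_table()]),
#'   `rates`, `burst` (ground-truth coordinates), `protein`, `scenario`,
#'   `seed`.
#' @export
simulate_clone <- function(rates, calib = calibration(), n_events = 10000L,
                           autofluor_mean = 5, autofluor_cv = 0.5,
                           size_coupling = 0.5, s_cv = 0.25, seed = 1L,
                           method = c("cme", "ssa"),
                           solver_options = list(method = "direct"),
                           ssa_duration = 40) {
  stopifnot(inherits(rates, "rate_constants"), n_events >= 1000)
  method <- match.arg(method)
  protein <- .with_seed(seed, {
    if (method == "cme") {
      pmf <- marginal(steady_state(rates, options = solver_options),
                      "protein", interpolate = TRUE)
      sample.int(length(pmf), n_events, replace = TRUE, prob = pmf) - 1L
    } else {
      simulate_clone_ssa(rates, duration = ssa_duration,
                         n_cells = n_events, seed = seed + 1L)[, "protein"]
    }
  })
  events <- .with_seed(seed + 104729L, {
    s <- stats::rlnorm(n_events, 0, s_cv)
    af <- .rlnorm_meancv(n_events, autofluor_mean, autofluor_cv)
    gfp <- calib$nu * protein * s^size_coupling + af
    fsc <- 512 * s * (1 + stats::rnorm(n_events, 0, 0.05))
    ssc <- 512 * s * (1 + stats::rnorm(n_events, 0, 0.1))
    event_table(data.frame(gfp = pmin(pmax(gfp, 0.1), 1000),
                           fsc = pmin(pmax(fsc, 1), 1024),
                           ssc = pmin(pmax(ssc, 1), 1024)))
  })
  structure(list(events = events, rates = rates,
                 burst = to_burst_coordinates(rates), protein = protein,
                 scenario = NA_character_, seed = as.integer(seed)),
            class = "synthetic_clone")
}

# lognormal draws parameterized by arithmetic mean and CV
.rlnorm_meancv <- function(n, mean, cv) {
  sdlog <- sqrt(log(1 + cv^2))
  stats::rlnorm(n, log(mean) - sdlog^2 / 2, sdlog)
}

#' Exact stochastic simulation of the two-state model
#'
#' Gillespie simulation of the full reaction scheme (promoter switching,
#' transcription, transcript decay, translation, protein decay), sampled at
#' the end time. Used as an independent cross-check of the master-equation
#' solvers.
#'
#' @param rates A [rate_constants()] object.
#' @param duration Simulated time in transcript lifetimes (default 40; at
#'   least 10 protein lifetimes recommended for stationarity).
#' @param n_cells Number of independent cells.
#' @param seed Integer seed.
#' @return Integer matrix with columns `transcript`, `protein`.
#' @export
simulate_clone_ssa <- function(rates, duration = 40, n_cells = 1000L,
                               seed = 1L) {
  stopifnot(inherits(rates, "rate_constants"))
  out <- .with_seed(seed, {
    ssa_telegraph_cpp(as.integer(n_cells), duration, rates$kappa_a,
                      rates$kappa_r, rates$kappa_t_plus,
                      rates$kappa_p_plus, rates$kappa_p_minus)
  })
  colnames(out) <- c("transcript", "protein")
  out
}

#' Generate an autofluorescence event table
#'
#' Background (reporter-free) cells: lognormal fluorescence with configurable
#' mean and CV, scatter generated exactly as in [simulate_clone()] with zero
#' signal.
#'
#' @param mean_rfu Mean background fluorescence (default 5 RFU).
#' @param cv Coefficient of variation (default 0.5).
#' @param n_events Number of cells.
#' @param s_cv Size-factor log-sd.
#' @param seed Integer seed.
#' @return An [event_table()].
#' @export
generate_autofluorescence <- function(mean_rfu = 5, cv = 0.5,
                                      n_events = 10000L, s_cv = 0.25,
                                      seed = 1L) {
  .with_seed(seed, {
    s <- stats::rlnorm(n_events, 0, s_cv)
    event_table(data.frame(
      gfp = pmin(pmax(.rlnorm_meancv(n_events, mean_rfu, cv), 0.1), 1000),
      fsc = pmin(pmax(512 * s * (1 + stats::rnorm(n_events, 0, 0.05)), 1), 1024),
      ssc = pmin(pmax(512 * s * (1 + stats::rnorm(n_events, 0, 0.1)), 1), 1024)))
  })
}

#' Generate a clonal ensemble with known ground truth
#'
#' Draws per-clone burst parameters according to the scenario, simulates
#' each clone's cytometry events, and returns the clones together with the
#' ground-truth manifest and a matched autofluorescence table.
#'
#' @param spec A [scenario_spec()].
#' @param method Passed to [simulate_clone()].
#' @param solver_options Passed to [simulate_clone()].
#' @return A list with `clones` (list of `synthetic_clone`), `truth` (the
#'   parameter data.frame), `autofluor_events` (an [event_table()]), and
#'   `spec`.
#' @export
generate_ensemble <- function(spec, method = "cme",
                              solver_options = list(method = "direct")) {
  stopifnot(inherits(spec, "scenario_spec"))
  truth <- draw_ensemble_parameters(spec)
  clones <- lapply(seq_len(spec$n_clones), function(i) {
    rates <- from_burst_coordinates(truth$b[i], truth$kappa_a[i], spec$tau,
                                    kappa_p_plus = spec$calib$kappa_p_plus,
                                    kappa_p_minus = spec$calib$kappa_p_minus)
    cl <- simulate_clone(rates, spec$calib, spec$n_events,
                         autofluor_mean = spec$autofluor_mean,
                         autofluor_cv = spec$autofluor_cv,
                         size_coupling = spec$size_coupling,
                         s_cv = spec$s_cv,
                         seed = spec$seed + 7919L * i,
                         method = method, solver_options = solver_options)
    cl$scenario <- spec$scenario
    attr(cl$events, "clone_id") <- sprintf("clone_%02d", i)
    cl
  })
  af <- generate_autofluorescence(spec$autofluor_mean, spec$autofluor_cv,
                                  spec$n_events, spec$s_cv,
                                  seed = spec$seed + 104729L)
  list(clones = clones, truth = truth, autofluor_events = af, spec = spec)
}

#' Write an ensemble to disk
#'
#' Per-clone event CSVs plus a JSON ground-truth manifest, the plain-text
#' serialization of a synthetic study.
#'
#' @param ensemble As returned by [generate_ensemble()].
#' @param dir Output directory (created if needed).
#' @export
write_ensemble <- function(ensemble, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (cl in ensemble$clones) {
    write_events(cl$events,
                 file.path(dir, paste0(attr(cl$events, "clone_id"), ".csv")))
  }
  write_events(ensemble$autofluor_events, file.path(dir, "autofluorescence.csv"))
  jsonlite::write_json(
    list(truth = ensemble$truth,
         spec = ensemble$spec[setdiff(names(ensemble$spec), "calib")],
         calib = unclass(ensemble$spec$calib)),
    file.path(dir, "manifest.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
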