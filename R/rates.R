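#' Kinetic rate constants of the two-state promoter model
#'
#' Constructs the five kinetic rates of the two-state (telegraph) gene model,
#' all expressed in units of the transcript degradation rate, which is fixed
#' at 1 by convention. The promoter switches from the repressed to the active
#' configuration at rate `kappa_a` and back at rate `kappa_r`; the active
#' state transcribes at rate `kappa_t_plus`; each transcript is translated at
#' rate `kappa_p_plus` and protein is lost (degradation plus dilution by cell
#' division) at rate `kappa_p_minus`.
#'
#' @param kappa_a Gene activation rate (> 0).
#' @param kappa_r Gene inactivation rate (> 0).
#' @param kappa_t_plus Active-state transcription rate (> 0).
#' @param kappa_p_plus Translation rate per transcript (> 0).
#' @param kappa_p_minus Effective protein degradation/dilution rate
#'   (0 < value < 1: protein decays more slowly than transcript here).
#' @return An object of class `rate_constants`.
#' @examples
#' rate_constants(kappa_a = 0.3, kappa_r = 50, kappa_t_plus = 750)
#' @export
rate_constants <- function(kappa_a, kappa_r, kappa_t_plus,
                           kappa_p_plus = 10, kappa_p_minus = 0.25) {
  r <- list(kappa_a = kappa_a, kappa_r = kappa_r,
            kappa_t_plus = kappa_t_plus,
            kappa_p_plus = kappa_p_plus, kappa_p_minus = kappa_p_minus)
  for (nm in names(r)) {
    v <- r[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0)
      stop("rate '", nm, "' must be a single finite positive number")
  }
  if (kappa_p_minus >= 1)
    stop("kappa_p_minus must be < 1 (protein decays slower than transcript)")
  structure(r, class = "rate_constants")
}

#' @export
print.rate_constants <- function(x, ...) {
  cat("Two-state model rates (units of transcript degradation rate):\n")
  cat(sprintf("  kappa_a = %g, kappa_r = %g, kappa_t_plus = %g\n",
              x$kappa_a, x$kappa_r, x$kappa_t_plus))
  cat(sprintf("  kappa_p_plus = %g, kappa_p_minus = %g\n",
              x$kappa_p_plus, x$kappa_p_minus))
  bc <- to_burst_coordinates(x)
  cat(sprintf("  burst size b = %g, active duration tau = %g, regime: %s\n",
              bc$b, bc$tau, classify_regime(x)))
  invisible(x)
}

#' Calibration constants linking protein counts to cytometer fluorescence
#'
#' `gamma` is the fluorescence (RFU) per mean transcript, estimated from the
#' measured ratio of cytometry and transcript-count means; the per-protein
#' fluorescence is derived as `nu = gamma * kappa_p_minus / kappa_p_plus`, so
#' that the predicted mean fluorescence gamma * (mean transcripts) is
#' independent of the translation rate. `kappa_p_plus` only needs to be large
#' enough that protein shot noise is negligible; changing it with `nu`
#' co-updated leaves predicted fluorescence histograms invariant up to
#' protein-shot-noise corrections.
#'
#' @param gamma RFU per mean transcript (default 2.5).
#' @param kappa_p_minus Protein degradation/dilution rate in transcript
#'   degradation units (default 0.25, from 0.05 per hour over 0.2 per hour).
#' @param kappa_p_plus Translation rate per transcript (default 10).
#' @return An object of class `calibration`, with derived field `nu`
#'   (RFU per protein).
#' @export
calibration <- function(gamma = 2.5, kappa_p_minus = 0.25, kappa_p_plus = 10) {
  if (gamma <= 0 || kappa_p_minus <= 0 || kappa_p_plus <= 0)
    stop("calibration constants must be positive")
  structure(list(gamma = gamma,
                 kappa_p_minus = kappa_p_minus,
                 kappa_p_plus = kappa_p_plus,
                 nu = gamma * kappa_p_minus / kappa_p_plus),
            class = "calibration")
}

#' Burst coordinates of a parameter set
#'
#' Re-expresses the integration-site-dependent rates as transcriptional burst
#' coordinates: burst size `b = kappa_t_plus / kappa_r` (mean transcripts per
#' activation event), burst frequency `kappa_a`, and active duration
#' `tau = 1 / kappa_r` (mean active-state lifetime in transcript-lifetime
#' units).
#'
#' @param rates A `rate_constants` object.
#' @return An object of class `burst_coordinates` with fields `b`, `kappa_a`,
#'   `tau` (and the protein rates carried along for round-tripping).
#' @seealso [from_burst_coordinates()]
#' @export
to_burst_coordinates <- function(rates) {
  stopifnot(inherits(rates, "rate_constants"))
  structure(list(b = rates$kappa_t_plus / rates$kappa_r,
                 kappa_a = rates$kappa_a,
                 tau = 1 / rates$kappa_r,
                 kappa_p_plus = rates$kappa_p_plus,
                 kappa_p_minus = rates$kappa_p_minus),
            class = "burst_coordinates")
}

#' Rates from burst coordinates
#'
#' Inverse of [to_burst_coordinates()]: `kappa_r = 1/tau`,
#' `kappa_t_plus = b/tau`.
#'
#' @param b Burst size (> 0).
#' @param kappa_a Burst frequency (> 0).
#' @param tau Active duration (> 0).
#' @param kappa_p_plus,kappa_p_minus Protein rates, as in [rate_constants()].
#' @return A `rate_constants` object.
#' @export
from_burst_coordinates <- function(b, kappa_a, tau,
                                   kappa_p_plus = 10, kappa_p_minus = 0.25) {
  if (b <= 0 || tau <= 0) stop("b and tau must be positive")
  rate_constants(kappa_a = kappa_a, kappa_r = 1 / tau,
                 kappa_t_plus = b / tau,
                 kappa_p_plus = kappa_p_plus, kappa_p_minus = kappa_p_minus)
}

#' Steady-state active fraction
#'
#' Probability of finding the promoter in the active configuration at steady
#' state, `f = kappa_a * tau / (1 + kappa_a * tau)`. Equals
#' `kappa_a / (kappa_a + kappa_r)` since `tau = 1 / kappa_r`.
#'
#' @param kappa_a Activation rate (> 0).
#' @param tau Active duration (>= 0).
#' @return Active fraction in `[0, 1)`.
#' @export
active_fraction <- function(kappa_a, tau) {
  if (any(kappa_a <= 0) || any(tau < 0))
    stop("require kappa_a > 0 and tau >= 0")
  kappa_a * tau / (1 + kappa_a * tau)
}

#' Classify the dynamic regime of a parameter set
#'
#' The qualitative expression regimes of the two-state model depend on the
#' gene-state switching rates relative to transcript degradation: "Fast"
#' switching approximates constitutive expression, "Slow" switching gives
#' pulsatile (eventually bimodal) expression, "Bursting" combines fast
#' inactivation with a transcription rate large enough that multiple
#' transcripts are made per short activation, and everything else is
#' "Intermediate". Thresholds are order-of-magnitude separations and are
#' configurable.
#'
#' @param rates A `rate_constants` object.
#' @param fast Threshold for "fast" switching (default 10).
#' @param slow Threshold for "slow" switching (default 0.1).
#' @param min_burst Minimum burst size for the bursting regime (default 2).
#' @return One of `"Bursting"`, `"Fast"`, `"Slow"`, `"Intermediate"`.
#' @export
classify_regime <- function(rates, fast = 10, slow = 0.1, min_burst = 2) {
  stopifnot(inherits(rates, "rate_constants"))
  b <- rates$kappa_t_plus / rates$kappa_r
  if (rates$kappa_r >= fast && b >= min_burst) return("Bursting")
  if (min(rates$kappa_a, rates$kappa_r) >= fast) return("Fast")
  if (max(rates$kappa_a, rates$kappa_r) <= slow) return("Slow")
  "Intermediate"
}

#' Exact steady-state moments of the two-state model
#'
#' Solves the (closed, linear) moment equations of the two-state gene model
#' exactly at steady state. Writing `g` for the active-state indicator, `T`
#' for transcript and `P` for protein count, the first and second moments obey
#' linear balance equations that can be solved sequentially; no
#' approximation is involved, so these values serve to certify the numerical
#' CME solutions.
#'
#' @param rates A `rate_constants` object.
#' @return A list with `f` (active fraction), `transcript_mean`,
#'   `transcript_var`, `transcript_fano`, `protein_mean`, `protein_var`,
#'   `tp_cov` (transcript-protein covariance).
#' @export
analytic_moments <- function(rates) {
  stopifnot(inherits(rates, "rate_constants"))
  ka <- rates$kappa_a; kr <- rates$kappa_r; kt <- rates$kappa_t_plus
  kp <- rates$kappa_p_plus; kd <- rates$kappa_p_minus
  f <- ka / (ka + kr)
  mT <- f * kt                       # transcript mean (kappa_t_minus = 1)
  mP <- kp * mT / kd                 # protein mean
  # second moments, solved in dependency order
  gT <- (ka * mT + kt * f) / (1 + ka + kr)        # <g T>
  T2 <- (2 * kt * gT + kt * f + mT) / 2           # <T^2>
  gP <- (ka * mP + kp * gT) / (ka + kr + kd)      # <g P>
  TP <- (kt * gP + kp * T2) / (1 + kd)            # <T P>
  P2 <- (2 * kp * TP + kp * mT + kd * mP) / (2 * kd)  # <P^2>
  vT <- T2 - mT^2
  vP <- P2 - mP^2
  out <- list(f = f,
              transcript_mean = mT, transcript_var = vT,
              transcript_fano = vT / mT,
              protein_mean = mP, protein_var = vP,
              tp_cov = TP - mT * mP)
  if (!all(vapply(out, is.finite, logical(1))))
    stop("analytic moments overflowed; rates too extreme")
  out
}

#' Bursting-regime approximation to protein moments
#'
#' In the bursting regime (fast inactivation, `kappa_r >> 1`) each activation
#' produces on average `b` transcripts essentially instantaneously, each of
#' which yields a protein burst of scale `beta = b * kappa_p_plus` fluorescent
#' proteins per transcript lifetime. To leading order the protein mean is
#' `kappa_a * b * kappa_p_plus / kappa_p_minus` and the variance is
#' `mean * b * kappa_p_plus`. The approximation is good for `b >> 1` and
#' `kappa_p_minus << 1`; outside the bursting regime a warning is issued.
#'
#' @param b Burst size.
#' @param kappa_a Burst frequency.
#' @param calib A [calibration()] object (supplies the protein rates).
#' @param kappa_r Optional inactivation rate used only for the regime check
#'   (default `Inf`, i.e. assume deep bursting).
#' @return List with `protein_mean` and `protein_var`.
#' @export
bursting_approximation <- function(b, kappa_a, calib = calibration(),
                                   kappa_r = Inf) {
  if (b <= 0 || kappa_a <= 0) stop("b and kappa_a must be positive")
  if (is.finite(kappa_r) && kappa_r < 10)
    warning("kappa_r < 10: bursting approximation used outside its regime")
  mP <- kappa_a * b * calib$kappa_p_plus / calib$kappa_p_minus
  list(protein_mean = mP, protein_var = mP * b * calib$kappa_p_plus)
}

#' Burst parameters from distribution moments
#'
#' Analytically inverts the bursting-regime moment relations to obtain the
#' unique burst size and frequency reproducing a measured
#' (autofluorescence-corrected) fluorescence mean and variance. In RFU units
#' the bursting relations read `mean = gamma * kappa_a * b` and
#' `variance = gamma * kappa_p_minus * b * mean`, giving
#' `kappa_a = kappa_p_minus * mean^2 / variance` and
#' `b = variance / (gamma * kappa_p_minus * mean)`.
#'
#' @param mean_rfu Corrected distribution mean (RFU, > 0).
#' @param variance_rfu Corrected distribution variance (RFU^2, > 0).
#' @param calib A [calibration()] object.
#' @return A `burst_coordinates` object (with `tau = NA`, not resolved by
#'   moments alone).
#' @export
moment_match <- function(mean_rfu, variance_rfu, calib = calibration()) {
  if (!is.finite(mean_rfu) || mean_rfu <= 0)
    stop("insufficient signal: corrected mean must be positive")
  if (!is.finite(variance_rfu) || variance_rfu <= 0)
    stop("insufficient signal: corrected variance must be positive")
  kappa_a <- calib$kappa_p_minus * mean_rfu^2 / variance_rfu
  b <- variance_rfu / (calib$gamma * calib$kappa_p_minus * mean_rfu)
  structure(list(b = b, kappa_a = kappa_a, tau = NA_real_,
                 kappa_p_plus = calib$kappa_p_plus,
                 kappa_p_minus = calib$kappa_p_minus),
            class = "burst_coordinates")
}

#' Read or write rates as a flat key-value config
#'
#' Rates serialize to a flat YAML/JSON mapping with keys `kappa_a`, `kappa_r`,
#' `kappa_t_plus`, `kappa_p_plus`, `kappa_p_minus`, `gamma`. Rates may
#' alternatively be given in per-hour units together with
#' `kappa_t_minus_per_hour` (default 0.2), in which case they are normalized
#' on read.
#'
#' @param path File path (`.yaml`/`.yml` or `.json`).
#' @return For `read_rates`, a list with elements `rates` (`rate_constants`)
#'   and `calib` (`calibration`).
#' @export
read_rates <- function(path) {
  x <- if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path)
       else jsonlite::read_json(path, simplifyVector = TRUE)
  unit <- 1
  if (!is.null(x$kappa_t_minus_per_hour)) unit <- x$kappa_t_minus_per_hour
  gamma <- if (is.null(x$gamma)) 2.5 else x$gamma
  kp <- if (is.null(x$kappa_p_plus)) 10 * unit else x$kappa_p_plus
  kd <- if (is.null(x$kappa_p_minus)) 0.25 * unit else x$kappa_p_minus
  rates <- rate_constants(kappa_a = x$kappa_a / unit,
                          kappa_r = x$kappa_r / unit,
                          kappa_t_plus = x$kappa_t_plus / unit,
                          kappa_p_plus = kp / unit,
                          kappa_p_minus = kd / unit)
  list(rates = rates,
       calib = calibration(gamma = gamma,
                           kappa_p_minus = rates$kappa_p_minus,
                           kappa_p_plus = rates$kappa_p_plus))
}

#' @rdname read_rates
#' @param rates A `rate_constants` object.
#' @param gamma RFU per mean transcript to record alongside the rates.
#' @export
write_rates <- function(rates, path, gamma = 2.5) {
  stopifnot(inherits(rates, "rate_constants"))
  x <- c(unclass(rates), list(gamma = gamma))
  if (grepl("\\.ya?ml$", path)) yaml::write_yaml(x, path)
  else jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
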