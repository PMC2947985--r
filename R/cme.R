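# Steady-state solution of the two-state gene-expression master equation on a
# graded coarse-grained grid, plus an exactly enumerated oracle for validation.

# Transition coefficients between adjacent bins of one count axis for a
# birth-death process with constant birth rate `lambda` and linear death rate
# `death * n`. Fine-fine interfaces (both widths 1) carry the exact
# master-equation rates. Coarse interfaces carry a flux-form discretization
# of the corresponding Fokker-Planck equation, `J = v u - D du/dx` with
# `v = lambda - death*x`, `D = (lambda + death*x)/2` evaluated at the
# interface:
#   * "central": linear interpolation of the density at the interface --
#     second-order accurate and free of numerical diffusion (the target
#     discretization at large counts), but dispersive where advection
#     dominates, which makes under-resolved far tails oscillate. Its
#     off-diagonal coefficients may be negative (it is a flux scheme, not a
#     jump process); mass conservation is exact by construction.
#   * "sg": Scharfetter-Gummel exponential fitting -- a positivity-preserving
#     proper generator, at the cost of first-order numerical diffusion where
#     advection dominates.
#   * "hybrid" (default): central up to `central_upto`, chosen where the
#     true tail mass falls below ~1e-8, SG beyond it -- second-order accuracy
#     wherever mass lives, monotone decay into the truncation boundary.
axis_transition_rates <- function(ax, lambda, death,
                                  scheme = c("hybrid", "central", "sg"),
                                  central_upto = Inf) {
  scheme <- match.arg(scheme)
  n <- ax$n_bins
  if (n < 2L) return(list(up = numeric(0), down = numeric(0)))
  k <- seq_len(n - 1L)
  w_l <- ax$width[k]; w_r <- ax$width[k + 1L]
  fine <- (w_l == 1L) & (w_r == 1L)
  up <- numeric(n - 1L); down <- numeric(n - 1L)
  # exact master-equation rates in the unit-width region
  up[fine] <- lambda
  down[fine] <- death * ax$lo[k + 1L][fine]
  if (any(!fine)) {
    j <- which(!fine)
    e <- ax$lo[k + 1L][j] - 0.5          # interface count value
    v <- lambda - death * e              # drift at interface
    D <- (lambda + death * e) / 2        # diffusion at interface
    h <- ax$x[k + 1L][j] - ax$x[k][j]
    # centered flux where requested, equilibrium-fitted elsewhere
    use_central <- switch(scheme,
                          central = rep(TRUE, length(j)),
                          sg = rep(FALSE, length(j)),
                          hybrid = e <= central_upto)
    wl <- (ax$x[k + 1L][j] - e) / h      # interpolation weight on u_k
    A_c <- v * wl + D / h
    C_c <- -v * (1 - wl) + D / h
    # fitted flux (Scharfetter-Gummel exponential fitting):
    # A = (D/h) zeta(z), C = (D/h) zeta(-z), zeta(z) = z/(1-e^-z), z = v h/D
    zeta <- function(z) ifelse(abs(z) < 1e-8, 1 + z / 2, z / (1 - exp(-z)))
    z_f <- pmax(pmin(v * h / D, 40), -40)
    A_f <- (D / h) * zeta(z_f)
    C_f <- (D / h) * zeta(-z_f)
    up[j] <- ifelse(use_central, A_c, A_f) / w_l[j]
    down[j] <- ifelse(use_central, C_c, C_f) / w_r[j]
  }
  list(up = up, down = down)
}

# 1-based linear index for (gene g in 1:2, transcript bin t, protein bin p),
# protein fastest. Used consistently by the generator and all marginals.
.state_index <- function(g, t, p, nt, np) ((g - 1L) * nt + (t - 1L)) * np + p

# Build the two halves of the coarse-grained generator as sparse matrices:
# `A_T` (transcript birth/death plus gene switching) and `A_P` (protein
# birth/death). Columns of each half sum to zero, so every split scheme
# built from them conserves probability mass exactly.
build_generator <- function(rates, grid, scheme = "hybrid") {
  tg <- grid$transcript; pg <- grid$protein
  mom <- analytic_moments(rates)
  # centered fluxes wherever the true distribution carries appreciable mass
  # (tails decay exponentially with scale ~ variance/mean; 18.4 scales is
  # mass ~ 1e-8), monotone exponential-fitted fluxes beyond, so dispersive
  # ripples cannot reach the truncation boundary
  t_bulk <- mom$transcript_mean +
    18.4 * max(1, mom$transcript_var / mom$transcript_mean)
  p_bulk <- mom$protein_mean +
    18.4 * max(1, mom$protein_var / mom$protein_mean)
  nt <- tg$n_bins; np <- pg$n_bins
  ns <- 2L * nt * np
  p_all <- seq_len(np)

  from <- list(); to <- list(); val <- list(); nblk <- 0L
  add <- function(f, t, r) {
    nblk <<- nblk + 1L
    from[[nblk]] <<- f; to[[nblk]] <<- t; val[[nblk]] <<- r
  }
  flush <- function() {
    jj <- unlist(from); ii <- unlist(to); xx <- unlist(val)
    keep <- xx != 0
    A <- Matrix::sparseMatrix(i = ii[keep], j = jj[keep], x = xx[keep],
                              dims = c(ns, ns))
    Matrix::diag(A) <- Matrix::diag(A) - Matrix::colSums(A)
    from <<- list(); to <<- list(); val <<- list(); nblk <<- 0L
    A
  }

  # --- transcript transitions (death everywhere; birth only when active) ---
  if (nt > 1L) {
    tr_act <- axis_transition_rates(tg, rates$kappa_t_plus, 1, scheme, t_bulk)
    tr_rep <- axis_transition_rates(tg, 0, 1, scheme, t_bulk)
    kseq <- seq_len(nt - 1L)
    for (g in 1:2) {
      tr <- if (g == 2L) tr_act else tr_rep
      lo <- rep(.state_index(g, kseq, 1L, nt, np), each = np) +
        rep(p_all - 1L, times = nt - 1L)
      hi <- lo + np
      add(lo, hi, rep(tr$up, each = np))
      add(hi, lo, rep(tr$down, each = np))
    }
  }
  # --- gene switching (diagonal in transcript and protein) ---
  s_rep <- seq_len(nt * np)
  s_act <- s_rep + nt * np
  add(s_rep, s_act, rep(rates$kappa_a, nt * np))
  add(s_act, s_rep, rep(rates$kappa_r, nt * np))
  A_T <- flush()

  # --- protein transitions (birth rate depends on the transcript bin) ---
  if (np > 1L) {
    kseq <- seq_len(np - 1L)
    for (t in seq_len(nt)) {
      pr <- axis_transition_rates(pg, rates$kappa_p_plus * tg$x[t],
                                  rates$kappa_p_minus, scheme, p_bulk)
      for (g in 1:2) {
        from_lo <- .state_index(g, t, kseq, nt, np)
        add(from_lo, from_lo + 1L, pr$up)
        add(from_lo + 1L, from_lo, pr$down)
      }
    }
  }
  A_P <- flush()

  list(A_T = A_T, A_P = A_P)
}

new_joint_distribution <- function(p, grid, rates, residual, iterations,
                                   boundary_mass, method) {
  structure(list(p = p, grid = grid, rates = rates,
                 residual = residual, iterations = iterations,
                 boundary_mass = boundary_mass, method = method),
            class = "joint_distribution")
}

#' @export
print.joint_distribution <- function(x, ...) {
  cat(sprintf(
    "joint steady-state distribution (%s): %d states, residual %.2e, boundary mass %.2e\n",
    x$method, length(x$p), x$residual, x$boundary_mass))
  invisible(x)
}

.boundary_mass <- function(p, grid) {
  nt <- grid$transcript$n_bins; np <- grid$protein$n_bins
  arr <- array(p, dim = c(np, nt, 2L))   # protein fastest
  sum(arr[np, , ]) + sum(arr[, nt, ]) - sum(arr[np, nt, ])
}

#' Steady-state joint distribution of the two-state model
#'
#' Solves the chemical master equation of the two-state gene model for its
#' stationary distribution over (gene state, transcript count, protein count)
#' on a graded coarse-grained grid. The default method integrates the
#' coarse-grained system in time with a forward/backward Euler scheme that
#' alternates treating transcript-side and protein-side transitions
#' implicitly or explicitly (stable for stiff systems; both half-operators
#' are flux-form generators, so probability mass is conserved exactly at
#' every step and the scheme's fixed point is exactly stationary for any step
#' size). Method `"direct"` instead computes the stationary vector of the
#' identical coarse generator by a sparse LU solve; the two agree to solver
#' tolerance and `"direct"` is markedly faster, so it is the workhorse during
#' model fitting.
#'
#' @param rates A [rate_constants()] object.
#' @param grid A [build_grid()] `state_grid`, or `NULL` to size one
#'   automatically from the analytic moments (mean + 8 sd per axis, expanded
#'   if truncation-boundary mass is excessive).
#' @param options List of solver options: `method` ("march" or "direct"),
#'   `residual_tol` (L1 stationarity residual, default 1e-9), `boundary_tol`
#'   (default 1e-8), `max_steps` (march, default 50000), `dt0` (initial step,
#'   default 0.1 / max total outflow rate), `check_every` (march residual
#'   checks, default 25), `fine_limit`, `growth`, `n_sd` (auto-grid).
#' @return A `joint_distribution`: probability vector `p` (protein index
#'   fastest, then transcript, then gene state), the grid, convergence
#'   metadata (`residual`, `iterations`, `boundary_mass`).
#' @export
steady_state <- function(rates, grid = NULL, options = list()) {
  stopifnot(inherits(rates, "rate_constants"))
  o <- utils::modifyList(list(method = "march", residual_tol = 1e-9,
                              boundary_tol = 1e-8, max_steps = 50000L,
                              dt0 = NULL, check_every = 25L,
                              fine_limit = 48, growth = 1.15, n_sd = 8,
                              tail_prob = 1e-10, width_cap = 0.5,
                              scheme = "hybrid"),
                         options)
  auto <- is.null(grid)
  n_sd <- o$n_sd
  tail_prob <- o$tail_prob
  width_cap <- o$width_cap
  tries <- 0L
  repeat {
    if (auto) grid <- default_grid(rates, n_sd = n_sd,
                                   tail_prob = tail_prob,
                                   fine_limit = o$fine_limit,
                                   growth = o$growth,
                                   width_cap = width_cap)
    sol <- if (auto && tries < 4L) {
      # a rippling (negative-mass) solve means the width cap was too loose
      # for these rates: tighten and rebuild
      tryCatch(.steady_state_on_grid(rates, grid, o),
               error = function(e) {
                 if (grepl("negative mass", conditionMessage(e))) NULL
                 else stop(e)
               })
    } else .steady_state_on_grid(rates, grid, o)
    if (is.null(sol)) {
      width_cap <- width_cap / 2
      tries <- tries + 1L
      next
    }
    bm <- .boundary_mass(sol$p, grid)
    if (bm <= o$boundary_tol) {
      return(new_joint_distribution(sol$p, grid, rates, sol$residual,
                                    sol$iterations, bm, o$method))
    }
    if (!auto || tries >= 4L)
      stop(sprintf("truncation-boundary mass %.2e exceeds tolerance %.2e; use a larger grid",
                   bm, o$boundary_tol))
    # bursting-regime tails are exponential, not Gaussian: expand the
    # quantile-based truncation multiplicatively (coarse bins keep large
    # truncations cheap)
    tail_prob <- tail_prob * 1e-3
    n_sd <- n_sd * 1.5
    tries <- tries + 1L
  }
}

.steady_state_on_grid <- function(rates, grid, o) {
  gen <- build_generator(rates, grid, o$scheme)
  A_T <- gen$A_T; A_P <- gen$A_P
  ns <- nrow(A_T)
  if (identical(o$method, "direct")) {
    # fix p[1] = 1 and solve the remaining equations, then normalize; avoids
    # the fill-in of a dense normalization row
    A <- A_T + A_P
    x <- as.numeric(Matrix::solve(A[-1L, -1L], -A[-1L, 1L, drop = FALSE],
                                  sparse = TRUE))
    p <- c(1, x)
    p <- p / sum(p)
    neg <- -sum(pmin(p, 0))
    if (neg > 1e-3)
      stop(sprintf("stationary solution has negative mass %.1e: grid too coarse for these rates (reduce width_cap / growth)",
                   neg))
    p[p < 0] <- 0
    p <- p / sum(p)
    res <- sum(abs(A %*% p))
    return(list(p = p, residual = res, iterations = 1L))
  }
  # alternating implicit/explicit Euler march
  A <- A_T + A_P
  kmax <- max(-Matrix::diag(A))
  dt <- if (is.null(o$dt0)) 0.1 / kmax else o$dt0
  I <- Matrix::Diagonal(ns)
  fac_T <- Matrix::lu(I - dt * A_T)
  fac_P <- Matrix::lu(I - dt * A_P)
  p <- numeric(ns); p[1L] <- 1       # repressed, zero transcripts/proteins
  prev_res <- Inf
  step <- 0L
  trace <- numeric(0)
  while (step < o$max_steps) {
    for (k in seq_len(o$check_every)) {
      step <- step + 1L
      if (step %% 2L == 1L) {
        p <- as.numeric(Matrix::solve(fac_T, p + dt * (A_P %*% p)))
      } else {
        p <- as.numeric(Matrix::solve(fac_P, p + dt * (A_T %*% p)))
      }
    }
    res <- sum(abs(A %*% p))
    trace <- c(trace, res)
    if (!is.finite(res) || res > 2 * prev_res) {
      # too aggressive a step: halve and refactor
      dt <- dt / 2
      fac_T <- Matrix::lu(I - dt * A_T)
      fac_P <- Matrix::lu(I - dt * A_P)
      prev_res <- Inf
      if (!is.finite(res)) { p <- numeric(ns); p[1L] <- 1 }
      next
    }
    if (res < o$residual_tol) break
    if (res > 0.2 * prev_res || res < prev_res) {
      # smooth decay: double the step toward stationarity
      if (res > 0.2 * prev_res) {
        dt <- dt * 2
        fac_T <- Matrix::lu(I - dt * A_T)
        fac_P <- Matrix::lu(I - dt * A_P)
      }
    }
    prev_res <- res
  }
  res <- sum(abs(A %*% p))
  if (res >= o$residual_tol)
    stop(sprintf("steady_state march did not converge in %d steps; residual trace: %s",
                 step, paste(sprintf("%.2e", utils::tail(trace, 8)), collapse = " ")))
  p[p < 0] <- 0
  p <- p / sum(p)
  list(p = p, residual = res, iterations = step)
}

#' Exact stationary solution of the fully enumerated master equation
#'
#' Enumerates every state of the truncated two-state model (no
#' coarse-graining) and computes the exact stationary probability vector of
#' the truncated generator by block-tridiagonal elimination in the protein
#' index (each block couples the 2 x (max_transcripts + 1) gene/transcript
#' states). This is the validation oracle for [steady_state()]: exact linear
#' algebra on the same reaction scheme, sharing no code with the
#' coarse-grained path.
#'
#' @param rates A [rate_constants()] object.
#' @param max_transcripts,max_proteins Truncation bounds (counts); defaults
#'   are mean + 8 sd from [analytic_moments()]. Total state count is capped
#'   at about 5e5.
#' @return A `joint_distribution` on a fully fine (unit-width) grid.
#' @export
brute_force_oracle <- function(rates, max_transcripts = NULL,
                               max_proteins = NULL) {
  stopifnot(inherits(rates, "rate_constants"))
  m <- analytic_moments(rates)
  if (is.null(max_transcripts))
    max_transcripts <- ceiling(m$transcript_mean + 8 * sqrt(m$transcript_var))
  if (is.null(max_proteins))
    max_proteins <- ceiling(m$protein_mean + 8 * sqrt(m$protein_var))
  mt <- as.integer(max_transcripts); mp <- as.integer(max_proteins)
  nb <- 2L * (mt + 1L)                    # block size over (gene, transcript)
  ns <- nb * (mp + 1L)
  if (ns > 6e5) stop("oracle state space too large (", ns, " states)")

  kt <- rates$kappa_t_plus; ka <- rates$kappa_a; kr <- rates$kappa_r
  kp <- rates$kappa_p_plus; kd <- rates$kappa_p_minus
  tcount <- 0:mt
  # gene/transcript sub-generator G (dense nb x nb), state order:
  # (g = repressed, T = 0..mt) then (g = active, T = 0..mt)
  G <- matrix(0, nb, nb)
  ir <- 1:(mt + 1L); ia <- (mt + 2L):nb
  for (t in 0:mt) {
    # transcript death (both gene states)
    if (t > 0) { G[ir[t], ir[t + 1L]] <- t; G[ia[t], ia[t + 1L]] <- t }
    # transcript birth (active only, reflecting at mt)
    if (t < mt) G[ia[t + 2L], ia[t + 1L]] <- kt
  }
  G[cbind(ia, ir)] <- ka                  # activation
  G[cbind(ir, ia)] <- kr                  # inactivation
  diag(G) <- diag(G) - colSums(G)
  birth <- kp * c(tcount, tcount)         # protein birth rate per block state

  # backward recursion pi_p = S_p pi_{p-1}
  S <- vector("list", mp + 1L)
  Snext <- NULL
  for (p in mp:1) {
    M <- G
    diag(M) <- diag(M) - kd * p - (if (p < mp) birth else 0)
    if (p < mp) M <- M + kd * (p + 1) * Snext
    Snext <- solve(M, diag(-birth, nb))
    S[[p + 1L]] <- Snext
  }
  M0 <- G
  diag(M0) <- diag(M0) - birth
  M0 <- M0 + kd * S[[2L]]
  M0[1L, ] <- 1
  rhs <- numeric(nb); rhs[1L] <- 1
  pi0 <- solve(M0, rhs)
  # forward propagation
  P <- matrix(0, nb, mp + 1L)
  P[, 1L] <- pi0
  for (p in 1:mp) P[, p + 1L] <- S[[p + 1L]] %*% P[, p]
  P[P < 0] <- 0
  leak <- (sum(P[, mp + 1L]) + sum(P[c(mt + 1L, nb), ])) / sum(P)
  P <- P / sum(P)

  grid <- build_grid(mt, mp, fine_limit = max(mt, mp), growth = 2)
  # reorder into the standard state layout (protein fastest, then transcript,
  # then gene state)
  arr <- array(0, dim = c(mp + 1L, mt + 1L, 2L))
  arr[, , 1L] <- t(P[ir, , drop = FALSE])
  arr[, , 2L] <- t(P[ia, , drop = FALSE])
  res <- sum(abs(.oracle_residual(rates, arr, mt, mp)))
  new_joint_distribution(as.numeric(arr), grid, rates, res, 1L, leak,
                         "oracle")
}

# generator action for the fully enumerated system, used only to report the
# oracle's own residual
.oracle_residual <- function(rates, arr, mt, mp) {
  kt <- rates$kappa_t_plus; ka <- rates$kappa_a; kr <- rates$kappa_r
  kp <- rates$kappa_p_plus; kd <- rates$kappa_p_minus
  d <- array(0, dim = dim(arr))
  tc <- 0:mt; pc <- 0:mp
  out_rate <- outer(pc * kd, tc, `+`) * 0  # placeholder dims (np, nt)
  for (g in 1:2) {
    lamT <- if (g == 2L) kt else 0
    sw_in <- if (g == 2L) ka * arr[, , 1L] else kr * arr[, , 2L]
    sw_out <- if (g == 2L) kr else ka
    birthT <- matrix(rep(ifelse(tc < mt, lamT, 0), each = mp + 1L), mp + 1L)
    deathT <- matrix(rep(tc, each = mp + 1L), mp + 1L)
    birthP <- outer(rep(1, mp + 1L), kp * tc)
    birthP[mp + 1L, ] <- 0
    deathP <- matrix(rep(pc * kd, mt + 1L), mp + 1L)
    a <- arr[, , g]
    flux_out <- (birthT + deathT + birthP + deathP + sw_out) * a
    flux_in <- sw_in
    flux_in[, 2:(mt + 1L)] <- flux_in[, 2:(mt + 1L)] +
      (if (g == 2L) kt else 0) * a[, 1:mt]
    flux_in[, 1:mt] <- flux_in[, 1:mt] +
      sweep(a[, 2:(mt + 1L), drop = FALSE], 2, tc[2:(mt + 1L)], `*`)
    flux_in[2:(mp + 1L), ] <- flux_in[2:(mp + 1L), ] +
      sweep(a[1:mp, , drop = FALSE], 2, kp * tc, `*`)
    flux_in[1:mp, ] <- flux_in[1:mp, ] + kd * pc[2:(mp + 1L)] * a[2:(mp + 1L), ]
    d[, , g] <- flux_in - flux_out
  }
  d
}

#' Marginal distribution of a joint steady state
#'
#' Sums the joint distribution over the other axes. For count axes the
#' marginal is returned per bin; with `interpolate = TRUE` coarse-bin masses
#' are additionally spread over their integer counts using a monotone
#' interpolation of the probability density (bin mass / bin width), giving a
#' per-count PMF for downstream convolution; fine-region masses are passed
#' through unchanged and each coarse bin's total mass is preserved exactly.
#'
#' @param joint A `joint_distribution`.
#' @param axis One of `"protein"`, `"transcript"`, `"gene_state"`.
#' @param interpolate Return a per-count PMF (count axes only).
#' @return For count axes: a data.frame (`lo`, `hi`, `x`, `width`, `mass`),
#'   or, if `interpolate = TRUE`, a numeric PMF vector over counts `0..max`.
#'   For `"gene_state"`: named vector `c(repressed, active)`.
#' @export
marginal <- function(joint, axis = c("protein", "transcript", "gene_state"),
                     interpolate = FALSE) {
  stopifnot(inherits(joint, "joint_distribution"))
  axis <- match.arg(axis)
  tg <- joint$grid$transcript; pg <- joint$grid$protein
  arr <- array(joint$p, dim = c(pg$n_bins, tg$n_bins, 2L))
  if (axis == "gene_state") {
    g <- c(repressed = sum(arr[, , 1L]), active = sum(arr[, , 2L]))
    return(g / sum(g))
  }
  ax <- if (axis == "protein") pg else tg
  mass <- if (axis == "protein") rowSums(arr, dims = 1L) else
    apply(arr, 2L, sum)
  mass <- as.numeric(mass)
  if (!interpolate) {
    return(data.frame(lo = ax$lo, hi = ax$hi, x = ax$x, width = ax$width,
                      mass = mass))
  }
  pmf_from_binned(ax, mass)
}

# Spread binned masses over integer counts: exact in the unit-width region,
# density-interpolated (mass-preserving per bin) in the coarse region.
pmf_from_binned <- function(ax, mass) {
  n_counts <- ax$max_count + 1L
  out <- numeric(n_counts)
  fine <- ax$width == 1L
  out[ax$lo[fine] + 1L] <- mass[fine]
  if (any(!fine)) {
    dens <- mass / ax$width
    sf <- stats::splinefun(ax$x, dens, method = "monoH.FC")
    for (k in which(!fine)) {
      counts <- ax$lo[k]:ax$hi[k]
      w <- pmax(sf(counts), 0)
      if (sum(w) <= 0) w <- rep(1, length(counts))
      out[counts + 1L] <- mass[k] * w / sum(w)
    }
  }
  out / sum(out)
}

#' Moments of a joint distribution
#'
#' Means and variances of the transcript and protein marginals, with the
#' standard uniform within-bin correction `(w^2 - 1) / 12` applied to second
#' moments of coarse bins, plus the active-state probability.
#'
#' @param joint A `joint_distribution`.
#' @return List with `transcript_mean`, `transcript_var`, `protein_mean`,
#'   `protein_var`, `f`.
#' @export
joint_moments <- function(joint) {
  mom <- function(axis) {
    m <- marginal(joint, axis)
    mu <- sum(m$mass * m$x)
    ex2 <- sum(m$mass * (m$x^2 + (m$width^2 - 1) / 12))
    c(mean = mu, var = ex2 - mu^2)
  }
  tm <- mom("transcript"); pm <- mom("protein")
  g <- marginal(joint, "gene_state")
  list(transcript_mean = tm[["mean"]], transcript_var = tm[["var"]],
       protein_mean = pm[["mean"]], protein_var = pm[["var"]],
       f = g[["active"]])
}

#' Serialize a joint distribution
#'
#' Writes bin edges and masses as a plain-text columnar table together with a
#' JSON metadata header (rates, residual, grid specification).
#'
#' @param joint A `joint_distribution`.
#' @param path Output path; `<path>.csv` and `<path>.json` are written.
#' @return `path`, invisibly.
#' @export
write_joint_distribution <- function(joint, path) {
  tg <- joint$grid$transcript; pg <- joint$grid$protein
  arr <- array(joint$p, dim = c(pg$n_bins, tg$n_bins, 2L))
  df <- expand.grid(protein_bin = seq_len(pg$n_bins),
                    transcript_bin = seq_len(tg$n_bins),
                    gene_state = c("repressed", "active"))
  df$mass <- as.numeric(arr)
  keep <- df$mass > 0
  utils::write.csv(df[keep, ], paste0(path, ".csv"), row.names = FALSE)
  meta <- list(rates = unclass(joint$rates), residual = joint$residual,
               boundary_mass = joint$boundary_mass, method = joint$method,
               transcript_grid = list(lo = tg$lo, hi = tg$hi),
               protein_grid = list(lo = pg$lo, hi = pg$hi))
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}
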