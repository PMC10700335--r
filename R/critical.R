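new_power_law_fit <- function(exponent, amplitude, stderr, window, n, r2,
                              kind) {
  structure(list(exponent = exponent, amplitude = amplitude,
                 stderr = stderr, window = window, n_points = n,
                 r_squared = r2, kind = kind),
            class = "power_law_fit")
}

#' @export
print.power_law_fit <- function(x, ...) {
  cat(sprintf("Power-law fit (%s): exponent = %.4f +/- %.4f\n",
              x$kind, x$exponent, x$stderr))
  cat(sprintf("  amplitude = %.4g, %d points, R^2 = %.5f, window %s\n",
              x$amplitude, x$n_points, x$r_squared, x$window))
  invisible(x)
}

loglog_fit <- function(x, y, kind, window_desc) {
  if (length(x) < 4L)
    stop("power-law fit needs at least 4 usable points, got ", length(x),
         call. = FALSE)
  fit <- lm(log(y) ~ log(x))
  sm <- suppressWarnings(summary(fit))  # noiseless inputs fit exactly
  new_power_law_fit(exponent = unname(coef(fit)[2]),
                    amplitude = exp(unname(coef(fit)[1])),
                    stderr = sm$coefficients[2, 2],
                    window = window_desc, n = length(x),
                    r2 = sm$r.squared, kind = kind)
}

#' Order-parameter exponent beta above the lower threshold
#'
#' Least-squares slope of `log(rho_s)` versus `log(lam - lam_c1)` over a
#' distance window above the critical point: `rho_s ~ (lam - lam_c1)^beta`.
#' For a continuous transition in the directed-percolation class in 1+1
#' dimensions the expected exponent is `beta ~= 0.276`.
#'
#' @param scan data frame with columns `lam` and `rho_s` (e.g. from
#'   [steady_state_scan()]).
#' @param lam_c1 lower critical point; all used points must lie above it.
#' @param window distance window `c(lo, hi)` on `lam - lam_c1`; points
#'   outside it are dropped.  Default upper edge 0.05.
#' @return A `power_law_fit` with the exponent (beta), amplitude, standard
#'   error, window and fit quality.
#' @export
fit_beta <- function(scan, lam_c1, window = c(0, 0.05)) {
  stopifnot(is.data.frame(scan), all(c("lam", "rho_s") %in% names(scan)))
  d <- scan$lam - lam_c1
  keep <- d > window[1] & d <= window[2] & d > 0 &
    is.finite(scan$rho_s) & scan$rho_s > 0
  loglog_fit(d[keep], scan$rho_s[keep], kind = "beta",
             window_desc = sprintf("lam - lam_c1 in (%g, %g]",
                                   max(window[1], 0), window[2]))
}

#' Decay exponent delta at the lower threshold
#'
#' Least-squares slope of `log(rho)` versus `log(t)` for the critical decay
#' from a fully occupied lattice, `rho(t) ~ t^-delta`; returns the negated
#' slope.  The directed-percolation value in 1+1 dimensions is
#' `delta ~= 0.1595`.
#'
#' @param rho_t data frame with columns `t` (time steps, >= 1) and `rho`.
#' @param window time window `c(lo, hi)` used for the fit; the default skips
#'   the initial transient.
#' @return A `power_law_fit` with the exponent (delta).
#' @export
fit_delta <- function(rho_t, window = c(100, 10000)) {
  stopifnot(is.data.frame(rho_t), all(c("t", "rho") %in% names(rho_t)))
  keep <- rho_t$t >= window[1] & rho_t$t <= window[2] & rho_t$t >= 1 &
    is.finite(rho_t$rho) & rho_t$rho > 0
  f <- loglog_fit(rho_t$t[keep], rho_t$rho[keep], kind = "delta",
                  window_desc = sprintf("t in [%g, %g]",
                                        window[1], window[2]))
  f$exponent <- -f$exponent
  f
}

#' Quasistationary cell-occupancy histogram
#'
#' Samples the number of active particles `n` inside a fixed window of
#' `window_size` sites at the centre of the lattice, over the post-discard
#' steps of surviving realizations, and tabulates the occurrence of each
#' occupancy `0..window_size`.  Near a continuous transition the histogram
#' has a single peak; bimodality in the neighbourhood of the upper threshold
#' signals a discontinuous transition.
#'
#' @param params a [sirs_params()] object (its `lam` is the probed value).
#' @param window_size number of sites in the central observation cell.
#' @param reps realizations.
#' @param discard transient steps excluded from sampling.
#' @param rho0 initial infected density.
#' @param master_seed integer master seed.
#' @param max_steps cap per realization; a run must stay active throughout to
#'   count as surviving.
#' @param thin sampling interval in steps.
#' @return An object of class `cell_histogram`: integer `counts` named by
#'   occupancy `0..window_size`, `n_samples`, `surviving`, `lam`,
#'   `window_size`.
#' @export
cell_histogram <- function(params, window_size = 100L, reps = 50L,
                           discard = 500L, rho0 = 0.1, master_seed = 1L,
                           max_steps = params$max_steps, thin = 1L) {
  stopifnot(window_size >= 1L, window_size <= params$N)
  lo <- (params$N - window_size) %/% 2L + 1L
  win <- c(lo, lo + window_size - 1L)
  L <- as.integer(max_steps) + 1L
  if (discard >= L) stop("discard must be smaller than the run length")
  samp_idx <- seq.int(discard + 1L, L, by = thin)
  seeds <- spawn_seeds(master_seed, reps)
  counts <- integer(window_size + 1L)
  n_surv <- 0L
  for (i in seq_len(reps)) {
    set.seed(seeds[i])
    st <- make_init_state(params, "random", rho0)
    tr <- run_until_absorbed(st, params, max_steps = max_steps, window = win)
    if (!tr$survived) next
    n_surv <- n_surv + 1L
    tb <- tabulate(tr$window_counts[samp_idx] + 1L, nbins = window_size + 1L)
    counts <- counts + tb
  }
  if (n_surv == 0L)
    stop("all realizations were absorbed before the sampling window; ",
         "no quasistationary samples available")
  structure(list(counts = setNames(counts, 0:window_size),
                 n_samples = sum(counts), surviving = n_surv,
                 lam = params$lam, window_size = as.integer(window_size),
                 discard = as.integer(discard), thin = as.integer(thin)),
            class = "cell_histogram")
}

#' @export
print.cell_histogram <- function(x, ...) {
  cat(sprintf(paste0("Cell-occupancy histogram: lambda = %g, window %d ",
                     "sites, %d samples from %d surviving run(s)\n"),
              x$lam, x$window_size, x$n_samples, x$surviving))
  nz <- which(x$counts > 0) - 1L
  if (length(nz))
    cat(sprintf("  occupied range n = %d..%d, modes (half-width 2): %d\n",
                min(nz), max(nz), count_modes(x, smoothing = 2L)))
  invisible(x)
}

#' Count modes of a smoothed occupancy histogram
#'
#' Applies a moving average of half-width `smoothing` bins (truncated at the
#' edges) and counts the local maxima of the smoothed curve; a flat plateau
#' counts once.  Raw counts are too noise-sensitive for mode counting, hence
#' the default smoothing.
#'
#' @param hist a `cell_histogram`, or a bare numeric vector of counts.
#' @param smoothing moving-average half-width in bins.
#' @param min_frac minimum height of a countable maximum, as a fraction of
#'   the largest smoothed bin.  Isolated stray counts in an otherwise empty
#'   tail survive any moving average as a tiny plateau; the prominence floor
#'   discards them so the count reflects genuine modes.
#' @return Integer number of local maxima.
#' @export
count_modes <- function(hist, smoothing = 2L, min_frac = 0.05) {
  counts <- if (inherits(hist, "cell_histogram")) as.numeric(hist$counts)
            else as.numeric(hist)
  n <- length(counts)
  if (n == 0L || sum(counts) == 0) stop("empty histogram")
  h <- as.integer(smoothing)
  padded <- c(numeric(h), counts, numeric(h))  # bins outside the range are empty
  sm <- vapply(seq_len(n), function(i) {
    mean(padded[i:(i + 2L * h)])
  }, numeric(1))
  # collapse runs of equal smoothed values, then count interior peaks;
  # boundaries behave as if flanked by -Inf so edge plateaus count too
  r <- rle(sm)
  v <- c(-Inf, r$values, -Inf)
  j <- seq_along(r$values)
  is_max <- v[j + 1L] > v[j] & v[j + 1L] > v[j + 2L]
  sum(is_max & r$values >= min_frac * max(sm))
}

#' Order-parameter variance
#'
#' `chi = N * (E[rho^2] - E[rho]^2)` over per-step density samples (taken
#' from surviving configurations).  `chi` peaks at the size-dependent
#' pseudo-transition point.
#'
#' @param rho_samples numeric vector of density samples (>= 2).
#' @param N lattice size.
#' @return Non-negative scalar.
#' @export
variance_chi <- function(rho_samples, N) {
  stopifnot(length(rho_samples) >= 2L)
  N * (mean(rho_samples^2) - mean(rho_samples)^2)
}

#' Locate the pseudo-transition point from a variance curve
#'
#' Takes the grid maximum of `chi(lam)` and refines it with the parabola
#' through the maximum and its two neighbours.  A maximum on the grid
#' boundary cannot be refined: the boundary value is returned with a
#' warning.
#'
#' @param chi_curve data frame with columns `lam` and `chi` (>= 5 points).
#' @return The abscissa of the peak.
#' @export
locate_pseudo_critical <- function(chi_curve) {
  stopifnot(is.data.frame(chi_curve),
            all(c("lam", "chi") %in% names(chi_curve)))
  ok <- is.finite(chi_curve$chi)
  lam <- chi_curve$lam[ok]; chi <- chi_curve$chi[ok]
  if (length(lam) < 5L)
    stop("need at least 5 finite grid points spanning the peak")
  i <- which.max(chi)
  if (i == 1L || i == length(lam)) {
    warning("variance maximum at the grid boundary; returning the ",
            "boundary value unrefined")
    return(lam[i])
  }
  x1 <- lam[i - 1L]; x2 <- lam[i]; x3 <- lam[i + 1L]
  y1 <- chi[i - 1L]; y2 <- chi[i]; y3 <- chi[i + 1L]
  den <- (x2 - x1) * (y2 - y3) - (x2 - x3) * (y2 - y1)
  if (den == 0) return(x2)  # flat top: keep the grid maximum
  x2 - 0.5 * ((x2 - x1)^2 * (y2 - y3) - (x2 - x3)^2 * (y2 - y1)) / den
}

#' Finite-size extrapolation of the upper critical point
#'
#' Ordinary least squares of the pseudo-transition points on the inverse
#' system size, `lam_N = lam_c2 + a / N`; the intercept estimates the upper
#' critical point in the infinite-size limit.
#'
#' @param points data frame with columns `N` and `lambda_N` (>= 3 distinct
#'   sizes).
#' @return An object of class `fss_result` with `points`, `lambda_c2`
#'   (intercept) and `slope_a`.
#' @export
extrapolate_lambda_c2 <- function(points) {
  stopifnot(is.data.frame(points),
            all(c("N", "lambda_N") %in% names(points)))
  if (length(unique(points$N)) < 3L)
    stop("finite-size extrapolation needs at least 3 distinct sizes")
  fit <- lm(lambda_N ~ I(1 / N), data = points)
  structure(list(points = points,
                 lambda_c2 = unname(coef(fit)[1]),
                 slope_a = unname(coef(fit)[2]),
                 fit = fit),
            class = "fss_result")
}

#' @export
print.fss_result <- function(x, ...) {
  cat("Finite-size extrapolation lam_N = lambda_c2 + a/N\n")
  cat(sprintf("  lambda_c2 = %.5f, a = %.4g (%d sizes: %s)\n",
              x$lambda_c2, x$slope_a, nrow(x$points),
              paste(sort(unique(x$points$N)), collapse = ", ")))
  invisible(x)
}

#' Variance curve over an infectivity grid for one system size
#'
#' Convenience wrapper around [steady_state_scan()] restricted to surviving
#' configurations, returning the `chi(lam)` curve used to locate the
#' pseudo-transition point.
#'
#' @inheritParams steady_state_scan
#' @return Data frame with columns `lam`, `chi`, `n_samples`, `surviving`.
#' @export
chi_curve <- function(params, lam_grid, rho0 = 0.1, reps = 100L,
                      discard = 1000L, master_seed = 1L,
                      max_steps = params$max_steps, thin = 5L) {
  sc <- steady_state_scan(params, lam_grid, rho0 = rho0, reps = reps,
                          discard = discard, master_seed = master_seed,
                          average_over = "surviving", max_steps = max_steps,
                          thin = thin)
  sc[, c("lam", "chi", "n_samples", "surviving")]
}

#' Full finite-size pipeline for the upper critical point
#'
#' For each lattice size, computes the surviving-run variance curve, locates
#' its peak by parabolic interpolation, and extrapolates the pseudo-critical
#' points against `1/N`.
#'
#' @param params base [sirs_params()] (its `N` and `lam` are overridden).
#' @param N_grid lattice sizes (>= 3 distinct values).
#' @param lam_grid infectivity grid spanning the variance peaks.
#' @param rho0,reps,discard,max_steps,thin forwarded to [chi_curve()].
#' @param master_seed integer master seed (one sub-seed per size).
#' @return An `fss_result`; the per-size variance curves are attached as
#'   attribute `"curves"`.
#' @export
fss_lambda_c2 <- function(params, N_grid, lam_grid, rho0 = 0.1, reps = 100L,
                          discard = 1000L, master_seed = 1L,
                          max_steps = 2000L, thin = 5L) {
  stopifnot(length(N_grid) >= 3L)
  seeds <- spawn_seeds(master_seed, length(N_grid))
  curves <- list()
  lam_N <- numeric(length(N_grid))
  for (j in seq_along(N_grid)) {
    cc <- chi_curve(set_size(params, N_grid[j]), lam_grid, rho0 = rho0,
                    reps = reps, discard = discard, master_seed = seeds[j],
                    max_steps = max_steps, thin = thin)
    curves[[j]] <- cc
    lam_N[j] <- locate_pseudo_critical(cc)
  }
  res <- extrapolate_lambda_c2(data.frame(N = N_grid, lambda_N = lam_N))
  attr(res, "curves") <- setNames(curves, N_grid)
  res
}

#' Estimate the lower critical point from a steady-state scan
#'
#' `method = "bracket"` (default): the midpoint between the largest `lam`
#' whose steady density is statistically zero and the smallest whose density
#' is significantly positive; the resolution is that of the scan grid, so
#' bisection-style refinement is achieved by re-scanning a finer grid inside
#' the bracket (see [refine_lambda_c1()]).  `method = "powerlaw"`: the
#' candidate critical point inside the bracket that maximizes the log-log
#' linearity (R^2) of the order-parameter power law, reflecting a
#' best-estimate fit-quality criterion.
#'
#' A density is called statistically zero when it does not exceed
#' `se_mult` standard errors plus the absolute floor `zero_floor`.
#'
#' @param scan data frame with columns `lam`, `rho_s` and optionally
#'   `rho_s_se`.
#' @param method `"bracket"` or `"powerlaw"`.
#' @param se_mult multiple of the standard error for the zero test.
#' @param zero_floor absolute density floor below which `rho_s` is treated
#'   as zero (e.g. a few sites' worth, `10/N`, for finite-size scans).
#' @param n_candidates candidate grid size for `method = "powerlaw"`.
#' @return List with `lambda_c1`, `bracket` (the two bracketing `lam`
#'   values) and `method`.
#' @export
estimate_lambda_c1 <- function(scan, method = c("bracket", "powerlaw"),
                               se_mult = 3, zero_floor = 0,
                               n_candidates = 25L) {
  method <- match.arg(method)
  stopifnot(is.data.frame(scan), all(c("lam", "rho_s") %in% names(scan)))
  se <- if ("rho_s_se" %in% names(scan)) scan$rho_s_se else 0
  positive <- scan$rho_s > pmax(se_mult * se, zero_floor)
  if (!any(positive) || all(positive))
    stop("scan does not bracket the onset: need both statistically-zero ",
         "and significantly-positive points")
  lam_zero <- max(scan$lam[!positive])
  lam_pos <- min(scan$lam[positive])
  if (lam_pos < lam_zero)
    warning("noisy scan: smallest positive lam lies below largest zero lam")
  bracket <- sort(c(lam_zero, lam_pos))
  est <- mean(bracket)
  if (method == "powerlaw") {
    cand <- seq(bracket[1], bracket[2], length.out = n_candidates)
    # profile the critical point over a FIXED set of clearly supercritical
    # points; letting the point set shrink with the candidate rewards
    # candidates that chase the first grid point
    keep <- scan$lam > bracket[2] & scan$rho_s > 0
    if (sum(keep) < 4L)
      stop("too few positive points above the bracket for the power-law ",
           "criterion")
    r2 <- vapply(cand, function(lc) {
      suppressWarnings(
        summary(lm(log(scan$rho_s[keep]) ~
                     log(scan$lam[keep] - lc))))$r.squared
    }, numeric(1))
    est <- cand[which.max(r2)]
  }
  list(lambda_c1 = est, bracket = bracket, method = method)
}

#' Decay-linearity refinement of the lower critical point
#'
#' At the critical point the order parameter decays as a pure power law from
#' a maximal-activity start, so among nearby candidates the critical one has
#' the straightest log-log decay: subcritical candidates bend downward,
#' supercritical ones flatten.  For each candidate infectivity this runs an
#' ensemble decay from the phase-randomized fully occupied start
#' ([init_occupied_random()]) and scores the shape of the ensemble-mean
#' density over the fit window.  This time-dependent criterion discriminates
#' candidates a steady-state scan cannot: slightly subcritical infectivities
#' keep a slowly decaying density residue for thousands of steps and
#' masquerade as active in finite-time scans, which biases scan-based
#' brackets low.
#'
#' Two scoring rules are available.  `"curvature"` (default) fits a
#' quadratic in log-log to each candidate's decay and locates the sign
#' change of the quadratic coefficient by regressing it on the candidate
#' infectivity: subcritical decays curve downward (negative coefficient),
#' supercritical ones flatten upward, and the root of the fitted trend
#' estimates the critical point, interpolating between grid candidates.
#' `"straightness"` picks the candidate maximizing the log-log R^2; it is
#' simpler but fragile at small ensembles, where a smoothly *curved*
#' subcritical decay can outscore a straight but noisy critical one.
#'
#' @param params base [sirs_params()] (its `lam` is overridden).
#' @param candidates candidate infectivities, normally spanning a bracket
#'   from [refine_lambda_c1()] or [estimate_lambda_c1()].
#' @param reps realizations per candidate.
#' @param steps decay length in time steps.
#' @param window log-log fit window on `t`, as in [fit_delta()].
#' @param master_seed integer master seed (one sub-seed per candidate).
#' @param criterion `"curvature"` or `"straightness"` (see Details).
#' @return List with `lambda_c1` (the estimate; under `"curvature"` it may
#'   lie between grid candidates), `candidates`, `curvature` (quadratic
#'   coefficients), `r2` scores, per-candidate `fits` (from [fit_delta()])
#'   and `curves` (data frames of `t`, `rho`), and `best` (index of the
#'   candidate nearest the estimate).
#' @export
estimate_lambda_c1_decay <- function(params, candidates, reps = 10L,
                                     steps = 8000L,
                                     window = c(100, steps),
                                     master_seed = 1L,
                                     criterion = c("curvature",
                                                   "straightness")) {
  criterion <- match.arg(criterion)
  stopifnot(length(candidates) >= 2L, reps >= 1L)
  seeds <- spawn_seeds(master_seed, length(candidates))
  fits <- vector("list", length(candidates))
  curves <- vector("list", length(candidates))
  curv <- numeric(length(candidates))
  for (j in seq_along(candidates)) {
    es <- run_ensemble(set_lambda(params, candidates[j]), init = "occupied",
                       reps = reps, discard = 0L, master_seed = seeds[j],
                       max_steps = steps)
    curves[[j]] <- data.frame(t = seq_along(es$rho_mean_t) - 1,
                              rho = es$rho_mean_t)
    fits[[j]] <- fit_delta(curves[[j]], window = window)
    keep <- curves[[j]]$t >= window[1] & curves[[j]]$t <= window[2] &
      curves[[j]]$rho > 0
    lt <- log(curves[[j]]$t[keep])
    curv[j] <- unname(coef(lm(log(curves[[j]]$rho[keep]) ~ lt +
                                I(lt^2)))[3])
  }
  r2 <- vapply(fits, function(f) f$r_squared, numeric(1))
  if (criterion == "curvature") {
    # local interpolation at the first downward-to-flat sign change; the
    # subcritical side's curvature grows fast and nonlinearly, so a global
    # trend fit would be tilted by the most subcritical candidates
    n <- length(curv)
    cross <- which(curv[-n] < 0 & curv[-1] >= 0)
    if (length(cross)) {
      i <- cross[1]
      # local trend over the crossing neighbourhood (up to 4 candidates):
      # more data than the bare pair, but none of the tilt a global fit
      # picks up from the fast-growing far-subcritical curvature
      idx <- max(1L, i - 1L):min(n, i + 2L)
      est <- NA_real_
      if (length(idx) >= 3L) {
        tr <- coef(lm(curv[idx] ~ candidates[idx]))
        if (is.finite(tr[2]) && tr[2] > 0) {
          est <- unname(-tr[1] / tr[2])
          est <- min(max(est, candidates[idx[1]]),
                     candidates[idx[length(idx)]])
        }
      }
      if (!is.finite(est))
        est <- candidates[i] - curv[i] *
          (candidates[i + 1] - candidates[i]) / (curv[i + 1] - curv[i])
    } else if (all(curv < 0)) {
      est <- max(candidates)  # onset above the window: signal an edge
    } else if (all(curv >= 0)) {
      est <- min(candidates)
    } else {
      est <- candidates[which.min(abs(curv))]
    }
  } else {
    est <- candidates[which.max(r2)]
  }
  best <- which.min(abs(candidates - est))
  list(lambda_c1 = est, candidates = candidates, curvature = curv, r2 = r2,
       fits = fits, curves = curves, best = best)
}

#' Iterated decay-linearity refinement inside a bracket
#'
#' Drives [estimate_lambda_c1_decay()] to a stable estimate: round one spans
#' the bracket (extended one grid step above it, since finite-time scan
#' brackets err low), later rounds zoom in on the winner with a third of the
#' spacing.  A winner on a window edge shifts the window and retries (up to
#' `max_shifts` times per round), so the argmax is always interior.
#'
#' @param params base [sirs_params()].
#' @param bracket two infectivities bounding the onset, e.g. from
#'   [refine_lambda_c1()].
#' @param rounds zoom rounds.
#' @param n_cand candidates in the first round (later rounds use 5).
#' @param reps,master_seed forwarded to [estimate_lambda_c1_decay()].
#' @param steps decay length per round (recycled); later rounds benefit
#'   from longer decays, since a candidate misplaced by the finer spacing
#'   only reveals its bend at later times.
#' @param max_shifts edge-shift retries per round.
#' @return List with `lambda_c1` and the per-round refinement results.
#' @export
refine_lambda_c1_decay <- function(params, bracket, rounds = 2L, n_cand = 7L,
                                   reps = 8L, steps = 5000L,
                                   master_seed = 1L, max_shifts = 2L) {
  stopifnot(length(bracket) == 2L, bracket[1] < bracket[2], rounds >= 1L)
  steps <- rep_len(as.integer(steps), rounds)
  lo <- bracket[1]
  hi <- bracket[2] + diff(bracket)
  nc <- as.integer(n_cand)
  seeds <- spawn_seeds(master_seed, rounds * (max_shifts + 1L))
  used <- 0L
  history <- list()
  est <- NA_real_
  for (r in seq_len(rounds)) {
    shifts <- 0L
    repeat {
      cand <- seq(lo, hi, length.out = nc)
      used <- used + 1L
      res <- estimate_lambda_c1_decay(params, cand, reps = reps,
                                      steps = steps[r],
                                      master_seed = seeds[used])
      history[[length(history) + 1L]] <- res
      est <- res$lambda_c1
      s <- diff(cand[1:2])
      at_edge <- res$best == 1L || res$best == nc
      if (!at_edge || shifts >= max_shifts) break
      shift <- (nc %/% 2L) * s * (if (res$best == nc) 1 else -1)
      lo <- max(lo + shift, 0); hi <- min(hi + shift, 1)
      shifts <- shifts + 1L
    }
    spacing <- diff(seq(lo, hi, length.out = nc)[1:2]) / 3
    lo <- max(est - 2 * spacing, 0)
    hi <- min(est + 2 * spacing, 1)
    nc <- 5L
  }
  list(lambda_c1 = est, rounds = history)
}

#' Bracket-and-refine estimation of the lower critical point
#'
#' Runs [steady_state_scan()] on successively finer grids: each level
#' brackets the onset with [estimate_lambda_c1()] and the next level scans
#' inside the bracket (expanded by one grid step), mirroring bisection down
#' to the final grid resolution.
#'
#' @param params base [sirs_params()].
#' @param lam_range initial search interval `c(lo, hi)`.
#' @param levels number of refinement levels.
#' @param grid_pts grid points per level.
#' @param rho0,reps,discard,max_steps forwarded to [steady_state_scan()].
#' @param zero_floor absolute zero floor; default `10 / N` (activity below
#'   ten sites on average is indistinguishable from extinction en route).
#' @param master_seed integer master seed.
#' @return List with `lambda_c1`, `bracket`, and the per-level `scans`.
#' @export
refine_lambda_c1 <- function(params, lam_range = c(0.07, 0.12), levels = 2L,
                             grid_pts = 7L, rho0 = 0.1, reps = 20L,
                             discard = 4000L, max_steps = 6000L,
                             zero_floor = 10 / params$N, master_seed = 1L) {
  stopifnot(levels >= 1L, grid_pts >= 4L)
  seeds <- spawn_seeds(master_seed, levels)
  scans <- vector("list", levels)
  est <- NULL
  for (lev in seq_len(levels)) {
    grid <- seq(lam_range[1], lam_range[2], length.out = grid_pts)
    sc <- steady_state_scan(params, grid, rho0 = rho0, reps = reps,
                            discard = discard, master_seed = seeds[lev],
                            max_steps = max_steps)
    scans[[lev]] <- sc
    est <- estimate_lambda_c1(sc, method = "bracket",
                              zero_floor = zero_floor)
    step <- diff(grid[1:2])
    lam_range <- c(max(est$bracket[1] - step / 2, 0),
                   min(est$bracket[2] + step / 2, 1))
  }
  list(lambda_c1 = est$lambda_c1, bracket = est$bracket, scans = scans)
}
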