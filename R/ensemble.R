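#' Duration of one full infection cycle (trapped-configuration cutoff)
#'
#' The number of time steps from the step at which a particle becomes
#' infected through the step at which it first returns to S, inclusive:
#' `tau_I + tau_R + 1`.  A realization whose activity dies out within this
#' window never completes a second infection generation and is classified as
#' a trapped configuration.  For the study parameters `tau_I = 7`,
#' `tau_R = 9` the cutoff is 17 time steps.
#'
#' @param params a [sirs_params()] object.
#' @return Integer number of time steps.
#' @export
trapped_cutoff <- function(params) {
  params$tau_I + params$tau_R + 1L
}

#' Classify a realization as a trapped configuration
#'
#' A trajectory is trapped when its activity goes extinct at a time step not
#' later than the cutoff (inclusive).  Surviving runs are never trapped.
#'
#' @param traj a `sirs_trajectory`.
#' @param cutoff time-step cutoff, normally [trapped_cutoff()].
#' @return `TRUE` or `FALSE`.
#' @export
classify_trapped <- function(traj, cutoff) {
  !isTRUE(traj$survived) && !is.na(traj$extinct_step) &&
    traj$extinct_step <= cutoff
}

make_init_state <- function(params, init, rho0) {
  switch(init,
         random = {
           if (is.null(rho0))
             stop("init = 'random' requires rho0", call. = FALSE)
           init_uniform_random(params, rho0)
         },
         single = init_single_seed(params),
         full = init_full(params),
         occupied = init_occupied_random(params),
         stop("unknown init spec: ", init, call. = FALSE))
}

#' Run an ensemble of independent realizations
#'
#' Runs `reps` realizations with per-realization sub-seeds derived from the
#' master seed (see [spawn_seeds()]), averages the order parameter per step,
#' and summarises trapped/surviving statistics.  With
#' `average_over = "all"`, absorbed runs contribute zero density after
#' absorption; with `"surviving"` only runs still active at `max_steps`
#' enter the averages (the convention for the quasistationary analysis).
#'
#' The steady-state density `rho_s_mean` is the time average of the ensemble
#' mean over the post-discard window.  `chi` is the order-parameter variance
#' `N * (E[rho^2] - E[rho]^2)` over the pooled per-step densities of
#' surviving runs in the same window (thinned by `thin` to reduce
#' autocorrelation).
#'
#' @param params a [sirs_params()] object.
#' @param init one of `"random"`, `"single"`, `"full"`, `"occupied"` (the
#'   phase-randomized fully occupied start, see [init_occupied_random()]).
#' @param rho0 initial infected density, required for `init = "random"`.
#' @param reps number of realizations (>= 1).
#' @param discard transient time steps excluded from steady-state averages.
#' @param average_over averaging set: all runs or surviving runs only.
#' @param master_seed integer master seed.
#' @param max_steps cap on updates per realization.
#' @param thin sampling interval (steps) for the pooled density samples.
#'
#' @return An object of class `sirs_ensemble`: per-step ensemble mean
#'   `rho_mean_t`, `rho_s_mean`, per-rep steady densities `rho_s_rep`,
#'   `dtco` (fraction of trapped configurations), `surviving` count, `chi`,
#'   `var_rho`, `n_samples`, the cutoff used, and the call parameters.
#' @export
run_ensemble <- function(params, init = c("random", "single", "full",
                                          "occupied"),
                         rho0 = NULL, reps, discard = 0L,
                         average_over = c("all", "surviving"),
                         master_seed = 1L, max_steps = params$max_steps,
                         thin = 1L) {
  init <- match.arg(init)
  average_over <- match.arg(average_over)
  stopifnot(reps >= 1L, discard >= 0L, thin >= 1L)
  max_steps <- as.integer(max_steps)
  L <- max_steps + 1L
  if (discard >= L)
    stop("discard must be smaller than the number of recorded steps")
  cutoff <- trapped_cutoff(params)
  seeds <- spawn_seeds(master_seed, reps)

  sum_all <- numeric(L)
  sum_surv <- numeric(L)
  rho_s_rep <- numeric(reps)
  n_surv <- 0L
  n_trap <- 0L
  samp_idx <- seq.int(discard + 1L, L, by = thin)
  s1 <- 0; s2 <- 0; ns <- 0L  # pooled surviving-run density moments

  for (i in seq_len(reps)) {
    set.seed(seeds[i])
    st <- make_init_state(params, init, rho0)
    tr <- run_until_absorbed(st, params, max_steps = max_steps)
    rho <- tr$rho
    if (length(rho) < L) rho <- c(rho, numeric(L - length(rho)))
    sum_all <- sum_all + rho
    rho_s_rep[i] <- mean(rho[(discard + 1L):L])
    if (tr$survived) {
      n_surv <- n_surv + 1L
      sum_surv <- sum_surv + rho
      x <- rho[samp_idx]
      s1 <- s1 + sum(x); s2 <- s2 + sum(x^2); ns <- ns + length(x)
    }
    if (classify_trapped(tr, cutoff)) n_trap <- n_trap + 1L
  }

  empty <- average_over == "surviving" && n_surv == 0L
  if (empty)
    warning("average_over = 'surviving' but no realization survived; ",
            "returning an empty (NA) summary")
  rho_mean_t <- if (average_over == "all") sum_all / reps
                else if (empty) rep(NA_real_, L) else sum_surv / n_surv
  var_rho <- if (ns > 0L) max(s2 / ns - (s1 / ns)^2, 0) else NA_real_

  structure(
    list(lam = params$lam, rho0 = rho0, N = params$N, reps = as.integer(reps),
         init = init, average_over = average_over,
         rho_mean_t = rho_mean_t,
         rho_s_mean = if (empty) NA_real_
                      else mean(rho_mean_t[(discard + 1L):L]),
         rho_s_rep = rho_s_rep,
         dtco = n_trap / reps, surviving = n_surv, trapped = n_trap,
         cutoff = cutoff, chi = if (is.na(var_rho)) NA_real_
                                else params$N * var_rho,
         var_rho = var_rho, n_samples = ns,
         discard = as.integer(discard), thin = as.integer(thin),
         max_steps = max_steps, master_seed = as.integer(master_seed),
         empty = empty),
    class = "sirs_ensemble")
}

#' @export
print.sirs_ensemble <- function(x, ...) {
  cat(sprintf("SIRS ensemble: lambda = %g, N = %d, %d reps (init = %s%s)\n",
              x$lam, x$N, x$reps, x$init,
              if (!is.null(x$rho0)) sprintf(", rho0 = %g", x$rho0) else ""))
  cat(sprintf("  rho_s = %.5f (average over %s, discard %d)\n",
              x$rho_s_mean, x$average_over, x$discard))
  cat(sprintf("  surviving %d / %d, trapped %d (DTCO = %.3f, cutoff %d)\n",
              x$surviving, x$reps, x$trapped, x$dtco, x$cutoff))
  if (!is.na(x$chi))
    cat(sprintf("  chi = %.4f from %d surviving-run samples\n",
                x$chi, x$n_samples))
  invisible(x)
}

#' Density of trapped configurations along an initial-density grid
#'
#' For each initial density `rho0` the fraction of realizations whose
#' activity dies within one infection cycle (the DTCO).  Trapped runs
#' resolve within the cutoff, so realizations are capped shortly after it.
#'
#' @param params a [sirs_params()] object.
#' @param rho0_grid initial densities to probe.
#' @param reps realizations per grid point.
#' @param master_seed integer master seed.
#' @param max_steps cap per realization; the default, one step past the
#'   trapped cutoff, is sufficient to classify every run.
#' @return A data frame with columns `rho0`, `dtco`, `trapped`, `reps`.
#' @export
dtco_curve <- function(params, rho0_grid, reps, master_seed = 1L,
                       max_steps = trapped_cutoff(params) + 1L) {
  stopifnot(length(rho0_grid) >= 1L)
  seeds <- spawn_seeds(master_seed, length(rho0_grid))
  cutoff <- trapped_cutoff(params)
  rows <- lapply(seq_along(rho0_grid), function(j) {
    sub <- spawn_seeds(seeds[j], reps)
    trapped <- 0L
    for (i in seq_len(reps)) {
      set.seed(sub[i])
      st <- init_uniform_random(params, rho0_grid[j])
      tr <- run_until_absorbed(st, params, max_steps = max_steps)
      if (classify_trapped(tr, cutoff)) trapped <- trapped + 1L
    }
    data.frame(rho0 = rho0_grid[j], dtco = trapped / reps,
               trapped = trapped, reps = as.integer(reps))
  })
  out <- do.call(rbind, rows)
  attr(out, "lam") <- params$lam
  attr(out, "cutoff") <- cutoff
  out
}

#' Steady-state scan of the order parameter over an infectivity grid
#'
#' Runs one ensemble per `lam` value and tabulates the steady-state density,
#' its between-realization standard error, the surviving-run order-parameter
#' variance `chi`, and survivor/trapped counts.  Reproduces the
#' two-threshold phase diagram: `rho_s` is zero below the lower threshold,
#' positive between the thresholds, and collapses again above the upper one.
#'
#' @param params base [sirs_params()] (its `lam` is overridden).
#' @param lam_grid ascending infection probabilities.
#' @param rho0 initial infected density for every ensemble.
#' @param reps realizations per grid point.
#' @param discard transient steps excluded from averages.
#' @param master_seed integer master seed (one sub-seed per grid point).
#' @param average_over averaging set, as in [run_ensemble()].
#' @param max_steps cap per realization.
#' @param thin sampling interval for the variance samples.
#' @return A data frame with one row per `lam`: `lam`, `rho_s`, `rho_s_se`,
#'   `chi`, `var_rho`, `n_samples`, `surviving`, `dtco`.
#' @export
steady_state_scan <- function(params, lam_grid, rho0 = 0.1, reps = 100L,
                              discard = 0L, master_seed = 1L,
                              average_over = "all",
                              max_steps = params$max_steps, thin = 1L) {
  stopifnot(length(lam_grid) >= 1L, !is.unsorted(lam_grid))
  seeds <- spawn_seeds(master_seed, length(lam_grid))
  rows <- lapply(seq_along(lam_grid), function(j) {
    es <- run_ensemble(set_lambda(params, lam_grid[j]), init = "random",
                       rho0 = rho0, reps = reps, discard = discard,
                       average_over = average_over, master_seed = seeds[j],
                       max_steps = max_steps, thin = thin)
    data.frame(lam = lam_grid[j], rho_s = es$rho_s_mean,
               rho_s_se = stats::sd(es$rho_s_rep) / sqrt(es$reps),
               chi = es$chi, var_rho = es$var_rho, n_samples = es$n_samples,
               surviving = es$surviving, dtco = es$dtco)
  })
  out <- do.call(rbind, rows)
  attr(out, "params") <- params
  attr(out, "rho0") <- rho0
  attr(out, "reps") <- as.integer(reps)
  attr(out, "discard") <- as.integer(discard)
  out
}
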