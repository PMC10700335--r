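#' One synchronous update of the lattice
#'
#' Applies the SIRS rules to every site simultaneously, computed entirely
#' from the state at the current step: an S site with `m >= 1` infected
#' neighbours (among its `k` neighbours on each side, periodic boundaries)
#' becomes I with probability `1 - (1 - lam)^m`; an I site moves to R after
#' `tau_I` full steps; an R site returns to S after `tau_R` full steps.
#' Transitions never chain within a step, so a site cannot be infected and
#' recover in the same update.
#'
#' Randomness comes from R's RNG stream (`set.seed()` makes runs
#' reproducible).  Both steppers consume exactly one uniform draw per S site
#' with at least one infected neighbour, visiting sites in ascending order,
#' so `sync_step()` (compiled) and `sync_step_reference()` (plain per-site R
#' loop, kept as an independent oracle) produce identical states from
#' identical RNG states.
#'
#' @param state a `sirs_state` satisfying its invariants.
#' @param params a [sirs_params()] object with `N` matching the state.
#' @return The updated `sirs_state` one step later.
#' @seealso [run_until_absorbed()] for full trajectories.
#' @export
sync_step <- function(state, params) {
  assert_state(state, params)
  res <- cpp_sirs_step(state$compartments, state$clock, params$k, params$lam,
                       params$tau_I, params$tau_R)
  new_state(res$comp, res$clock, state$time + 1L, params)
}

#' @rdname sync_step
#' @export
sync_step_reference <- function(state, params) {
  assert_state(state, params)
  N <- params$N; k <- params$k
  comp <- state$compartments
  clk <- state$clock
  ninf <- integer(N)
  for (j in seq_len(N)) {
    if (comp[j] != SIRS_CODES[["I"]]) next
    for (d in seq_len(k)) {
      r <- j + d; if (r > N) r <- r - N
      l <- j - d; if (l < 1L) l <- l + N
      ninf[r] <- ninf[r] + 1L
      if (l != r) ninf[l] <- ninf[l] + 1L
    }
  }
  ncomp <- comp; nclk <- clk
  for (i in seq_len(N)) {
    c0 <- comp[i]
    if (c0 == SIRS_CODES[["S"]]) {
      m <- ninf[i]
      nclk[i] <- 0L
      if (m > 0L && runif(1) < 1 - (1 - params$lam)^m) {
        ncomp[i] <- SIRS_CODES[["I"]]
      }
    } else if (c0 == SIRS_CODES[["I"]]) {
      if (clk[i] == params$tau_I - 1L) {
        ncomp[i] <- SIRS_CODES[["R"]]; nclk[i] <- 0L
      } else nclk[i] <- clk[i] + 1L
    } else {
      if (clk[i] == params$tau_R - 1L) {
        ncomp[i] <- SIRS_CODES[["S"]]; nclk[i] <- 0L
      } else nclk[i] <- clk[i] + 1L
    }
  }
  new_state(ncomp, nclk, state$time + 1L, params)
}

#' Run a realization until absorption or a step cap
#'
#' Iterates the synchronous update until the lattice reaches the absorbing
#' all-S configuration or `max_steps` updates have been performed.  Time
#' steps are counted 1-based with the initial configuration as step 1, the
#' convention used for all reported absorption times; e.g. a ring of 11
#' sites with `k = 1`, `lam = 1`, `tau_I = 2`, `tau_R = 3` seeded at the
#' centre reaches all-S at step 11.
#'
#' Two absorption marks are recorded: `extinct_step`, the first step with no
#' infected site (after which the dynamics drain deterministically), and
#' `absorbed_step`, the first all-S step.  `survived` is `TRUE` when
#' infected sites are present at every recorded step.
#'
#' @param state initial `sirs_state`.
#' @param params a [sirs_params()] object.
#' @param record_spacetime record the full step-by-site compartment grid.
#' @param max_steps cap on synchronous updates (defaults to
#'   `params$max_steps`).
#' @param stop_when_absorbed stop at the first all-S step (default); when
#'   `FALSE` the run always performs `max_steps` updates, which keeps the
#'   recorded grid rectangular for space-time diagrams.
#' @param window optional 1-based `c(lo, hi)` site range; the count of
#'   infected sites inside it is recorded at every step (used for the
#'   quasistationary cell-occupancy histograms).
#'
#' @return A `sirs_trajectory`: `rho` (density at each recorded step,
#'   `rho[1]` is the initial density), `steps` (updates performed),
#'   `extinct_step`, `absorbed_step`, `survived`, `final_state`, and
#'   optionally `spacetime` and `window_counts`.
#' @examples
#' p <- sirs_params(N = 11, lam = 1, k = 1, tau_I = 2, tau_R = 3,
#'                  max_steps = 100)
#' run_until_absorbed(init_single_seed(p), p)$absorbed_step  # 11
#' @export
run_until_absorbed <- function(state, params, record_spacetime = FALSE,
                               max_steps = params$max_steps,
                               stop_when_absorbed = TRUE, window = NULL) {
  assert_state(state, params)
  max_steps <- as.integer(max_steps)
  if (max_steps == 0L && active_density(state) > 0)
    warning("degenerate run: max_steps = 0 with an active initial state")
  win <- c(-1L, -1L)
  if (!is.null(window)) {
    stopifnot(length(window) == 2L, window[1] >= 1, window[2] <= params$N,
              window[1] <= window[2])
    win <- as.integer(window)
  }
  res <- cpp_sirs_run(state$compartments, state$clock, params$k, params$lam,
                      params$tau_I, params$tau_R, max_steps,
                      record_spacetime, stop_when_absorbed, win[1], win[2])
  structure(
    list(rho = res$rho, steps = res$steps,
         extinct_step = res$extinct_step,
         absorbed_step = res$absorbed_step,
         survived = res$survived,
         final_state = new_state(res$comp, res$clock,
                                 state$time + res$steps, params),
         spacetime = res$spacetime, window_counts = res$window_counts,
         params = params),
    class = "sirs_trajectory")
}

#' @export
print.sirs_trajectory <- function(x, ...) {
  cat(sprintf("SIRS trajectory: %d update(s), %d recorded step(s)\n",
              x$steps, length(x$rho)))
  if (x$survived) {
    cat(sprintf("  surviving (rho at last step = %.4f)\n",
                x$rho[length(x$rho)]))
  } else {
    cat(sprintf("  activity extinct at step %d; all-S %s\n", x$extinct_step,
                if (is.na(x$absorbed_step)) "not reached within the cap"
                else sprintf("reached at step %d", x$absorbed_step)))
  }
  invisible(x)
}
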