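new_state <- function(comp, clock, time, params) {
  structure(list(compartments = as.integer(comp), clock = as.integer(clock),
                 time = as.integer(time), N = params$N),
            class = "sirs_state")
}

#' Initial lattice configurations
#'
#' Three initial conditions used throughout the study: a single infected seed
#' at the centre of the ring, a uniformly random configuration with a given
#' initial density of infected sites, and a fully infected lattice.  All
#' non-infected sites start susceptible with their phase clocks at zero, and
#' the state is labelled time step 1 (the convention throughout the package:
#' the initial configuration is the first time step, each synchronous update
#' adds one).
#'
#' @param params a [sirs_params()] object.
#' @param rho0 initial density of infected sites in `[0, 1]`; exactly
#'   `round(rho0 * N)` sites are infected, chosen uniformly without
#'   replacement from R's RNG stream.
#'
#' @return A `sirs_state`: integer compartment codes (0 = S, 1 = I, 2 = R),
#'   per-site clocks, and the internal 0-based update counter `time`.
#' @examples
#' p <- sirs_params(N = 11, lam = 1, k = 1, tau_I = 2, tau_R = 3)
#' s <- init_single_seed(p)
#' active_density(s)  # 1/11
#' @export
init_single_seed <- function(params) {
  N <- params$N
  comp <- rep.int(SIRS_CODES[["S"]], N)
  centre <- N %/% 2L + 1L  # 1-based index of the central site
  comp[centre] <- SIRS_CODES[["I"]]
  new_state(comp, integer(N), 0L, params)
}

#' @rdname init_single_seed
#' @export
init_uniform_random <- function(params, rho0) {
  stopifnot(is.numeric(rho0), length(rho0) == 1L, rho0 >= 0, rho0 <= 1)
  N <- params$N
  n_inf <- as.integer(round(rho0 * N))
  comp <- rep.int(SIRS_CODES[["S"]], N)
  if (n_inf > 0L) comp[sample.int(N, n_inf)] <- SIRS_CODES[["I"]]
  new_state(comp, integer(N), 0L, params)
}

#' @rdname init_single_seed
#' @export
init_full <- function(params) {
  N <- params$N
  new_state(rep.int(SIRS_CODES[["I"]], N), integer(N), 0L, params)
}

#' @rdname init_single_seed
#' @details
#' `init_full()` puts every site in I with clock 0.  Note that with
#' synchronized clocks this configuration is itself (transiently) absorbing:
#' there are no susceptible sites, so the whole lattice moves to R in
#' lock-step and drains to all-S within `tau_I + tau_R` updates — this is the
#' high-infectivity absorption mechanism.  For time-dependent studies that
#' need a surviving maximal-activity start (e.g. the critical decay of the
#' order parameter), use `init_occupied_random()`: every site is occupied by
#' the infection cycle with a uniformly random phase, i.e. infected with
#' probability `tau_I / (tau_I + tau_R)` and refractory otherwise, clocks
#' uniform over the respective compartment.  No site starts susceptible, but
#' the phases are desynchronized so activity persists.
#' @export
init_occupied_random <- function(params) {
  N <- params$N
  cycle <- params$tau_I + params$tau_R
  phase <- sample.int(cycle, N, replace = TRUE) - 1L
  inf <- phase < params$tau_I
  comp <- ifelse(inf, SIRS_CODES[["I"]], SIRS_CODES[["R"]])
  clock <- ifelse(inf, phase, phase - params$tau_I)
  new_state(comp, clock, 0L, params)
}

#' Density of active (infected) sites
#'
#' The order parameter of the automaton at a single time step: the fraction
#' of sites in compartment I.
#'
#' @param state a `sirs_state`.
#' @return A density in `[0, 1]`.
#' @export
active_density <- function(state) {
  sum(state$compartments == SIRS_CODES[["I"]]) / state$N
}

#' Compartment counts of a lattice state
#'
#' @param state a `sirs_state`.
#' @return Named integer vector with the S, I and R counts (summing to `N`).
#' @export
compartment_counts <- function(state) {
  counts <- tabulate(state$compartments + 1L, nbins = 3L)
  setNames(counts, SIRS_LABELS)
}

#' @export
print.sirs_state <- function(x, ...) {
  counts <- compartment_counts(x)
  cat(sprintf("SIRS lattice state: N = %d, time step %d\n", x$N, x$time + 1L))
  cat(sprintf("  S = %d, I = %d, R = %d (rho = %.4f)\n",
              counts[["S"]], counts[["I"]], counts[["R"]],
              counts[["I"]] / x$N))
  if (x$N <= 80L)
    cat("  ", paste(SIRS_LABELS[x$compartments + 1L], collapse = ""), "\n",
        sep = "")
  invisible(x)
}

# Internal: checks state invariants; used by the steppers' contracts.
assert_state <- function(state, params) {
  stopifnot(length(state$compartments) == params$N,
            length(state$clock) == params$N,
            all(state$compartments %in% SIRS_CODES),
            all(state$clock >= 0L))
  i <- state$compartments == SIRS_CODES[["I"]]
  r <- state$compartments == SIRS_CODES[["R"]]
  if (any(state$clock[i] >= params$tau_I))
    stop("state invariant violated: I clock must stay below tau_I")
  if (any(state$clock[r] >= params$tau_R))
    stop("state invariant violated: R clock must stay below tau_R")
  invisible(state)
}
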