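#' Model parameters for the SIRS ring automaton
#'
#' Bundles the lattice size, neighbourhood range, infection probability and
#' the two phase clocks, together with run controls.  Defaults follow the
#' study conditions of the two-threshold regime: `k = 3` neighbours on each
#' side (degree `2k`), infectious period `tau_I = 7` steps and refractory
#' period `tau_R = 9` steps, so that `tau_R > tau_I`.
#'
#' @param N lattice size (number of sites on the periodic ring).
#' @param lam infection probability per infected neighbour and step, in
#'   `[0, 1]`.  An S site with `m` infected neighbours becomes infected with
#'   probability `1 - (1 - lam)^m`.
#' @param k neighbours per side; every site is coupled to its `k` nearest
#'   neighbours on each side (total degree `2k`, which must be `< N`).
#' @param tau_I infectious period: full time steps a site spends in I.
#' @param tau_R refractory period: full time steps a site spends in R.
#' @param max_steps default cap on synchronous updates per realization.
#' @param seed optional integer seed stored with the parameters; functions
#'   that consume randomness take explicit seeds, this field is a convenience
#'   default.
#'
#' @return An object of class `sirs_params` (a validated list).
#' @examples
#' p <- sirs_params(N = 100, lam = 0.12)
#' p
#' @export
sirs_params <- function(N, lam, k = 3L, tau_I = 7L, tau_R = 9L,
                        max_steps = 10000L, seed = NULL) {
  p <- structure(
    list(N = as.integer(N), lam = as.numeric(lam), k = as.integer(k),
         tau_I = as.integer(tau_I), tau_R = as.integer(tau_R),
         max_steps = as.integer(max_steps),
         seed = if (is.null(seed)) NULL else as.integer(seed)),
    class = "sirs_params")
  validate_sirs_params(p)
}

#' @rdname sirs_params
#' @param p a `sirs_params` object (or plain list with the same fields).
#' @export
validate_sirs_params <- function(p) {
  bad <- character(0)
  chk <- function(ok, msg) if (!isTRUE(ok)) bad <<- c(bad, msg)
  chk(is.numeric(p$N) && length(p$N) == 1L && p$N >= 1, "N must be a positive integer")
  chk(is.numeric(p$k) && length(p$k) == 1L && p$k >= 1, "k must be a positive integer")
  chk(is.numeric(p$lam) && length(p$lam) == 1L && p$lam >= 0 && p$lam <= 1,
      "lam must lie in [0, 1]")
  chk(is.numeric(p$tau_I) && p$tau_I >= 1, "tau_I must be >= 1")
  chk(is.numeric(p$tau_R) && p$tau_R >= 1, "tau_R must be >= 1")
  chk(is.numeric(p$max_steps) && p$max_steps >= 0, "max_steps must be >= 0")
  if (length(bad) == 0L && p$N > 1L)
    chk(2L * p$k < p$N, "2*k must be smaller than N (degree-2k ring)")
  if (length(bad))
    stop("invalid sirs_params: ", paste(bad, collapse = "; "), call. = FALSE)
  p
}

#' @export
print.sirs_params <- function(x, ...) {
  cat("SIRS ring parameters\n")
  cat(sprintf("  N = %d sites, k = %d neighbours per side (degree %d)\n",
              x$N, x$k, 2L * x$k))
  cat(sprintf("  lambda = %g, tau_I = %d, tau_R = %d (%s)\n",
              x$lam, x$tau_I, x$tau_R,
              if (x$tau_R > x$tau_I) "two-threshold regime tau_R > tau_I"
              else "single-threshold regime tau_I >= tau_R"))
  cat(sprintf("  max_steps = %d\n", x$max_steps))
  invisible(x)
}

# Replace the infection probability (used by scans over lambda).
set_lambda <- function(params, lam) {
  params$lam <- as.numeric(lam)
  validate_sirs_params(params)
}

# Replace the lattice size (used by finite-size scans).
set_size <- function(params, N) {
  params$N <- as.integer(N)
  validate_sirs_params(params)
}

#' Deterministic sub-seed derivation
#'
#' Derives `n` per-realization seeds from a master seed with a counter-based
#' affine hash, so ensembles are reproducible and independent of evaluation
#' order.  All seeds stay below 2^31.
#'
#' @param master integer master seed.
#' @param n number of sub-seeds.
#' @return integer vector of length `n`.
#' @export
spawn_seeds <- function(master, n) {
  i <- as.numeric(seq_len(n))
  as.integer((as.numeric(master) %% 2147483647 * 48271 + i * 1664525 + 12345) %%
               2147483647)
}
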