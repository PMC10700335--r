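#' Record a space-time diagram
#'
#' Runs the automaton for a fixed number of updates and keeps the full
#' step-by-site compartment grid.  Row 1 is the initial configuration and
#' time increases downward.  Given the same RNG seed the dynamics are
#' identical to [run_until_absorbed()]; the run is not cut short at
#' absorption, so post-absorption rows show the lattice draining to all-S.
#'
#' @param params a [sirs_params()] object.
#' @param init one of `"single"`, `"random"`, `"full"`.
#' @param steps number of synchronous updates to record (grid has
#'   `steps + 1` rows).
#' @param rho0 initial density for `init = "random"`.
#' @return An object of class `spacetime_record`: integer `grid`
#'   (steps+1 x N, codes 0 = S, 1 = I, 2 = R), `params`, `init`.
#' @export
record_spacetime <- function(params, init = c("single", "random", "full",
                                              "occupied"),
                             steps, rho0 = NULL) {
  init <- match.arg(init)
  stopifnot(steps >= 1L)
  st <- make_init_state(params, init, rho0)
  tr <- run_until_absorbed(st, params, record_spacetime = TRUE,
                           max_steps = steps, stop_when_absorbed = FALSE)
  structure(list(grid = tr$spacetime, params = params, init = init,
                 rho0 = rho0),
            class = "spacetime_record")
}

#' @export
print.spacetime_record <- function(x, ...) {
  cat(sprintf("Space-time record: %d steps x %d sites (init = %s)\n",
              nrow(x$grid), ncol(x$grid), x$init))
  invisible(x)
}

#' Export a space-time diagram to a plain-text file
#'
#' Two dependency-free formats: `"text"` writes one row per time step with
#' space-separated `S`/`I`/`R` symbols (plus a header comment that lets
#' [read_grid()] reconstruct the record); `"pgm"` writes a plain (P2)
#' portable graymap with one pixel per site and step on a 0-2 gray scale,
#' mapping I to 0 (black), R to 1 and S to 2 (lightest), time increasing
#' downward.
#'
#' @param rec a `spacetime_record`.
#' @param path output file path.
#' @param format `"text"` or `"pgm"`.
#' @return `path`, invisibly.
#' @export
export_grid <- function(rec, path, format = c("text", "pgm")) {
  format <- match.arg(format)
  stopifnot(inherits(rec, "spacetime_record"))
  g <- rec$grid
  p <- rec$params
  con <- file(path, open = "wt")
  on.exit(close(con))
  if (format == "text") {
    writeLines(sprintf(
      "# sirsring spacetime N=%d k=%d lam=%.17g tau_I=%d tau_R=%d init=%s",
      p$N, p$k, p$lam, p$tau_I, p$tau_R, rec$init), con)
    sym <- SIRS_LABELS[g + 1L]
    dim(sym) <- dim(g)
    writeLines(apply(sym, 1L, paste, collapse = " "), con)
  } else {
    gray <- c(2L, 0L, 1L)[g + 1L]  # S -> 2, I -> 0, R -> 1
    dim(gray) <- dim(g)
    writeLines(c("P2", sprintf("%d %d", ncol(g), nrow(g)), "2"), con)
    writeLines(apply(gray, 1L, paste, collapse = " "), con)
  }
  invisible(path)
}

#' Re-read a text-matrix space-time diagram
#'
#' Parses a file written by [export_grid()] with `format = "text"` and
#' reconstructs the `spacetime_record` (round-trip fidelity).
#'
#' @param path file written by [export_grid()].
#' @return A `spacetime_record`.
#' @export
read_grid <- function(path) {
  lines <- readLines(path)
  hdr <- lines[1]
  if (!grepl("^# sirsring spacetime ", hdr))
    stop("not a sirsring text-matrix file: ", path)
  kv <- strsplit(sub("^# sirsring spacetime ", "", hdr), " ")[[1]]
  f <- function(key) sub(paste0("^", key, "="), "",
                         kv[startsWith(kv, paste0(key, "="))])
  params <- sirs_params(N = as.integer(f("N")), lam = as.numeric(f("lam")),
                        k = as.integer(f("k")), tau_I = as.integer(f("tau_I")),
                        tau_R = as.integer(f("tau_R")))
  body <- lines[-1]
  body <- body[nzchar(body)]
  rows <- strsplit(body, " ", fixed = TRUE)
  code <- setNames(SIRS_CODES, SIRS_LABELS)
  g <- do.call(rbind, lapply(rows, function(r) unname(code[r])))
  storage.mode(g) <- "integer"
  structure(list(grid = g, params = params, init = f("init"), rho0 = NULL),
            class = "spacetime_record")
}
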