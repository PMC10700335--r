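CONFIG_DEFAULTS <- list(
  experiment = NULL,  # required
  N = 1000L, k = 3L, lam = 0.1, tau_I = 7L, tau_R = 9L,
  init = "random", rho0 = 0.1, reps = 100L, discard = 0L,
  max_steps = 10000L, thin = 1L, steps = 500L, window_size = 100L,
  lam_grid = NULL, rho0_grid = NULL, N_grid = NULL,
  lam_c1 = NULL, seed = 1L, out = ".", format = "text")

EXPERIMENTS <- c("simulate", "scan", "exponents", "dtco", "qsd", "fss",
                 "spacetime")

#' Read a flat key-value run configuration
#'
#' One `key = value` pair per line; `#` starts a comment; grids are
#' comma-separated lists (e.g. `lam_grid = 0.095, 0.1, 0.105`).  Values that
#' parse as numbers become numeric, everything else stays character.
#'
#' @param path configuration file.
#' @return A named list (unvalidated; see [validate_config()]).
#' @export
read_run_config <- function(path) {
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  cfg <- list()
  for (ln in lines) {
    if (!grepl("=", ln, fixed = TRUE))
      stop("malformed config line (expected key = value): ", ln)
    key <- trimws(sub("=.*$", "", ln))
    val <- trimws(sub("^[^=]*=", "", ln))
    parts <- trimws(strsplit(val, ",", fixed = TRUE)[[1]])
    num <- suppressWarnings(as.numeric(parts))
    cfg[[key]] <- if (!anyNA(num)) num else parts
  }
  cfg
}

#' Validate a run configuration and inject defaults
#'
#' Checks every model-parameter invariant (reporting each violated bound
#' with its field name) and fills unset fields with the package defaults
#' (`k = 3`, `tau_I = 7`, `tau_R = 9`, ...).  A configuration with
#' `tau_R <= tau_I` is accepted — the simulator supports the
#' single-threshold regime — with a note that the two-threshold analysis
#' assumes `tau_R > tau_I`.
#'
#' @param cfg named list, e.g. from [read_run_config()].
#' @return The completed configuration (class `sirs_config`).
#' @export
validate_config <- function(cfg = list()) {
  unknown <- setdiff(names(cfg), names(CONFIG_DEFAULTS))
  if (length(unknown))
    stop("unknown config field(s): ", paste(unknown, collapse = ", "))
  cfg <- modifyList(CONFIG_DEFAULTS, cfg, keep.null = TRUE)
  bad <- character(0)
  chk <- function(ok, msg) if (!isTRUE(ok)) bad <<- c(bad, msg)
  if (!is.null(cfg$experiment))
    chk(cfg$experiment %in% EXPERIMENTS,
        sprintf("experiment: must be one of %s",
                paste(EXPERIMENTS, collapse = ", ")))
  chk(cfg$N >= 1, "N: must be >= 1")
  chk(cfg$k >= 1, "k: must be >= 1")
  chk(cfg$N == 1 || 2 * cfg$k < cfg$N, "k: 2*k must be smaller than N")
  chk(cfg$lam >= 0 && cfg$lam <= 1, "lam: must lie in [0, 1]")
  chk(cfg$tau_I >= 1, "tau_I: must be >= 1")
  chk(cfg$tau_R >= 1, "tau_R: must be >= 1")
  chk(cfg$rho0 >= 0 && cfg$rho0 <= 1, "rho0: must lie in [0, 1]")
  chk(cfg$reps >= 1, "reps: must be >= 1")
  chk(cfg$discard >= 0, "discard: must be >= 0")
  chk(cfg$max_steps >= 0, "max_steps: must be >= 0")
  chk(cfg$init %in% c("random", "single", "full"),
      "init: must be random, single or full")
  for (g in c("lam_grid", "rho0_grid", "N_grid"))
    if (!is.null(cfg[[g]]))
      chk(is.numeric(cfg[[g]]) && length(cfg[[g]]) >= 1,
          sprintf("%s: must be a numeric list", g))
  if (!is.null(cfg$lam_grid))
    chk(all(cfg$lam_grid >= 0 & cfg$lam_grid <= 1),
        "lam_grid: values must lie in [0, 1]")
  if (length(bad))
    stop("invalid config: ", paste(bad, collapse = "; "), call. = FALSE)
  if (cfg$tau_R <= cfg$tau_I)
    message("note: tau_R <= tau_I gives the single-threshold regime; ",
            "the two-threshold analysis assumes tau_R > tau_I")
  structure(cfg, class = "sirs_config")
}

config_params <- function(cfg, N = cfg$N, lam = cfg$lam) {
  sirs_params(N = N, lam = lam, k = cfg$k, tau_I = cfg$tau_I,
              tau_R = cfg$tau_R, max_steps = cfg$max_steps)
}

write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

write_manifest <- function(cfg, out_dir, files) {
  vals <- vapply(names(CONFIG_DEFAULTS), function(k) {
    v <- cfg[[k]]
    if (is.null(v)) "" else paste(format(v, digits = 17), collapse = ",")
  }, character(1))
  lines <- c(sprintf("package_version: %s",
                     as.character(packageVersion("sirsring"))),
             sprintf("%s: %s", names(vals), vals),
             sprintf("output: %s", files))
  writeLines(lines, file.path(out_dir, "manifest.txt"))
}

#' Run a configured experiment stage
#'
#' Executes the stage selected by `cfg$experiment` and writes delimited
#' result tables plus a manifest recording every parameter and seed, so the
#' manifest and seed suffice to regenerate any table byte-identically.
#' Stages: `simulate` (one trajectory), `scan` (steady-state scan over
#' `lam_grid`), `exponents` (beta from a scan above `lam_c1` and delta from
#' the critical decay), `dtco` (trapped fraction over `rho0_grid`), `qsd`
#' (cell-occupancy histogram), `fss` (variance-peak extrapolation over
#' `N_grid`), `spacetime` (diagram export).
#'
#' @param cfg configuration list or `sirs_config`.
#' @param out_dir output directory (default `cfg$out`), created if missing.
#' @return Named list of result objects, invisibly; files are written as a
#'   side effect and logged per stage with survivor counts where relevant.
#' @export
run_experiment <- function(cfg, out_dir = NULL) {
  if (!inherits(cfg, "sirs_config")) cfg <- validate_config(cfg)
  if (is.null(cfg$experiment))
    stop("config must set an experiment selector (one of ",
         paste(EXPERIMENTS, collapse = ", "), ")")
  out_dir <- out_dir %||% cfg$out
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  seed <- as.integer(cfg$seed)
  t0 <- proc.time()[["elapsed"]]
  res <- switch(
    cfg$experiment,
    simulate = {
      p <- config_params(cfg)
      set.seed(seed)
      st <- make_init_state(p, cfg$init, cfg$rho0)
      tr <- run_until_absorbed(st, p)
      f <- write_tsv(data.frame(step = seq_along(tr$rho), rho = tr$rho),
                     file.path(out_dir, "trajectory.tsv"))
      message(sprintf("simulate: %d step(s); %s", length(tr$rho),
                      if (tr$survived) "surviving at the cap"
                      else sprintf("extinct at step %d, all-S at step %s",
                                   tr$extinct_step,
                                   format(tr$absorbed_step))))
      list(trajectory = tr, files = f)
    },
    scan = {
      if (is.null(cfg$lam_grid)) stop("scan requires lam_grid")
      sc <- steady_state_scan(config_params(cfg), sort(cfg$lam_grid),
                              rho0 = cfg$rho0, reps = cfg$reps,
                              discard = cfg$discard, master_seed = seed,
                              max_steps = cfg$max_steps, thin = cfg$thin)
      message(sprintf("scan: %d lambda value(s); survivors per point: %s",
                      nrow(sc), paste(sc$surviving, collapse = " ")))
      list(scan = sc, files = write_tsv(sc, file.path(out_dir, "scan.tsv")))
    },
    exponents = {
      if (is.null(cfg$lam_grid) || is.null(cfg$lam_c1))
        stop("exponents requires lam_grid and lam_c1")
      p <- config_params(cfg)
      sc <- steady_state_scan(p, sort(cfg$lam_grid), rho0 = cfg$rho0,
                              reps = cfg$reps, discard = cfg$discard,
                              master_seed = seed, max_steps = cfg$max_steps)
      fb <- fit_beta(sc, cfg$lam_c1)
      dec <- run_ensemble(config_params(cfg, lam = cfg$lam_c1),
                          init = "full", reps = cfg$reps,
                          discard = cfg$discard,
                          master_seed = spawn_seeds(seed, 2L)[2],
                          max_steps = cfg$max_steps)
      fd <- fit_delta(data.frame(t = seq_along(dec$rho_mean_t) - 1,
                                 rho = dec$rho_mean_t),
                      window = c(100, cfg$max_steps))
      tab <- data.frame(exponent = c("beta", "delta"),
                        value = c(fb$exponent, fd$exponent),
                        stderr = c(fb$stderr, fd$stderr),
                        r_squared = c(fb$r_squared, fd$r_squared))
      message(sprintf("exponents: beta = %.4f, delta = %.4f",
                      fb$exponent, fd$exponent))
      list(beta = fb, delta = fd, scan = sc,
           files = write_tsv(tab, file.path(out_dir, "exponents.tsv")))
    },
    dtco = {
      if (is.null(cfg$rho0_grid)) stop("dtco requires rho0_grid")
      dc <- dtco_curve(config_params(cfg), cfg$rho0_grid, reps = cfg$reps,
                       master_seed = seed)
      message(sprintf("dtco: trapped fractions %s",
                      paste(format(dc$dtco, digits = 3), collapse = " ")))
      list(dtco = dc, files = write_tsv(dc, file.path(out_dir, "dtco.tsv")))
    },
    qsd = {
      h <- cell_histogram(config_params(cfg), window_size = cfg$window_size,
                          reps = cfg$reps, discard = cfg$discard,
                          rho0 = cfg$rho0, master_seed = seed,
                          max_steps = cfg$max_steps, thin = cfg$thin)
      message(sprintf("qsd: %d samples from %d surviving run(s); modes: %d",
                      h$n_samples, h$surviving, count_modes(h)))
      tab <- data.frame(n = as.integer(names(h$counts)),
                        count = as.integer(h$counts))
      list(histogram = h,
           files = write_tsv(tab, file.path(out_dir, "histogram.tsv")))
    },
    fss = {
      if (is.null(cfg$N_grid) || is.null(cfg$lam_grid))
        stop("fss requires N_grid and lam_grid")
      fs <- fss_lambda_c2(config_params(cfg), cfg$N_grid,
                          sort(cfg$lam_grid), rho0 = cfg$rho0,
                          reps = cfg$reps, discard = cfg$discard,
                          master_seed = seed, max_steps = cfg$max_steps,
                          thin = cfg$thin)
      tab <- rbind(fs$points,
                   data.frame(N = Inf, lambda_N = fs$lambda_c2))
      message(sprintf("fss: lambda_c2 = %.4f (slope a = %.3g)",
                      fs$lambda_c2, fs$slope_a))
      list(fss = fs,
           files = write_tsv(tab, file.path(out_dir, "fss.tsv")))
    },
    spacetime = {
      p <- config_params(cfg)
      set.seed(seed)
      rec <- record_spacetime(p, init = cfg$init, steps = cfg$steps,
                              rho0 = cfg$rho0)
      ext <- if (cfg$format == "pgm") "pgm" else "txt"
      f <- file.path(out_dir, paste0("spacetime.", ext))
      export_grid(rec, f, format = if (ext == "pgm") "pgm" else "text")
      message(sprintf("spacetime: %d x %d grid -> %s",
                      nrow(rec$grid), ncol(rec$grid), f))
      list(record = rec, files = f)
    })
  write_manifest(cfg, out_dir, basename(res$files))
  message(sprintf("stage '%s' finished in %.1f s", cfg$experiment,
                  proc.time()[["elapsed"]] - t0))
  invisible(res)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
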