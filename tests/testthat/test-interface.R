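test_that("config validation reports violated bounds by field name", {
  expect_error(validate_config(list(lam = 1.2)), "lam")
  expect_error(validate_config(list(N = 100, k = 60)), "k")
  expect_error(validate_config(list(reps = 0)), "reps")
  expect_error(validate_config(list(experiment = "frobnicate")), "experiment")
  expect_error(validate_config(list(nonsense = 1)), "unknown config field")

  # an empty config yields the full documented defaults
  cfg <- validate_config(list())
  expect_identical(cfg$k, 3L)
  expect_identical(cfg$tau_I, 7L)
  expect_identical(cfg$tau_R, 9L)

  # the single-threshold regime is accepted with a note
  expect_message(validate_config(list(tau_I = 9, tau_R = 7)),
                 "single-threshold")
})

test_that("flat key-value config files parse into typed fields", {
  path <- withr::local_tempfile(fileext = ".cfg")
  writeLines(c("experiment = scan   # stage",
               "N = 500", "lam_grid = 0.10, 0.12, 0.14",
               "init = random", "rho0 = 0.1"), path)
  cfg <- read_run_config(path)
  expect_identical(cfg$experiment, "scan")
  expect_equal(cfg$N, 500)
  expect_equal(cfg$lam_grid, c(0.10, 0.12, 0.14))
  expect_identical(cfg$init, "random")
  expect_error(read_run_config({
    p2 <- withr::local_tempfile(); writeLines("just words", p2); p2
  }), "malformed")
})

test_that("the simulate stage reproduces the worked example and is byte-stable", {
  dir_a <- withr::local_tempdir()
  dir_b <- withr::local_tempdir()
  cfg <- list(experiment = "simulate", N = 11, k = 1, lam = 1, tau_I = 2,
              tau_R = 3, init = "single", max_steps = 100, seed = 4)
  suppressMessages(res <- run_experiment(cfg, out_dir = dir_a))
  expect_identical(res$trajectory$absorbed_step, 11L)
  traj <- read.table(file.path(dir_a, "trajectory.tsv"), header = TRUE)
  expect_identical(nrow(traj), 11L)
  expect_equal(traj$rho[11], 0)

  suppressMessages(run_experiment(cfg, out_dir = dir_b))
  expect_identical(readLines(file.path(dir_a, "trajectory.tsv")),
                   readLines(file.path(dir_b, "trajectory.tsv")))
  expect_identical(readLines(file.path(dir_a, "manifest.txt")),
                   readLines(file.path(dir_b, "manifest.txt")))
  expect_true(any(grepl("seed: 4", readLines(file.path(dir_a,
                                                       "manifest.txt")))))
})

test_that("scan and dtco stages write tables consistent with their modules", {
  out <- withr::local_tempdir()
  cfg <- list(experiment = "scan", N = 150, lam_grid = c(0.0, 0.3),
              rho0 = 0.2, reps = 5, discard = 50, max_steps = 100, seed = 2)
  suppressMessages(res <- run_experiment(cfg, out_dir = out))
  tab <- read.table(file.path(out, "scan.tsv"), header = TRUE)
  expect_equal(tab$rho_s[1], 0)  # no transmission at lambda = 0
  expect_identical(nrow(tab), 2L)

  cfg2 <- list(experiment = "dtco", N = 150, lam = 0, rho0_grid = c(0.2, 0.8),
               reps = 6, seed = 3)
  suppressMessages(run_experiment(cfg2, out_dir = out))
  dtab <- read.table(file.path(out, "dtco.tsv"), header = TRUE)
  expect_equal(dtab$dtco, c(1, 1))
})

test_that("the spacetime stage exports a parseable grid", {
  out <- withr::local_tempdir()
  cfg <- list(experiment = "spacetime", N = 11, k = 1, lam = 1, tau_I = 2,
              tau_R = 3, init = "single", steps = 12, seed = 1)
  suppressMessages(run_experiment(cfg, out_dir = out))
  rec <- read_grid(file.path(out, "spacetime.txt"))
  expect_identical(dim(rec$grid), c(13L, 11L))
  expect_true(all(rec$grid[12:13, ] == 0L))
})
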