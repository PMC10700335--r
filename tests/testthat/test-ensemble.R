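test_that("trapped cutoff equals one inclusive infection cycle", {
  expect_identical(trapped_cutoff(sirs_params(N = 100, lam = 0.1)), 17L)

  # oracle: a single isolated particle's cycle, simulated step by step
  cycle_length <- function(tau_I, tau_R) {
    p <- sirs_params(N = 9, lam = 0, k = 1, tau_I = tau_I, tau_R = tau_R,
                     max_steps = 100)
    s <- init_single_seed(p)
    step <- 1L  # the seed is infected at step 1
    repeat {
      s <- sync_step(s, p)
      step <- step + 1L
      if (count_of(s, "S") == 9L) return(step)  # first step back in S
    }
  }
  for (taus in list(c(2L, 3L), c(1L, 1L), c(7L, 9L))) {
    p <- sirs_params(N = 100, lam = 0.1, tau_I = taus[1], tau_R = taus[2])
    expect_identical(trapped_cutoff(p), cycle_length(taus[1], taus[2]))
  }
})

test_that("trapped classification is inclusive at the cutoff", {
  fake <- function(extinct, survived = FALSE)
    structure(list(extinct_step = extinct, survived = survived),
              class = "sirs_trajectory")
  expect_true(classify_trapped(fake(5L), 17L))
  expect_true(classify_trapped(fake(17L), 17L))   # "not longer than"
  expect_false(classify_trapped(fake(18L), 17L))
  expect_false(classify_trapped(fake(NA_integer_, survived = TRUE), 17L))
})

test_that("ensembles with zero infectivity have zero steady state and full trapping", {
  p <- sirs_params(N = 200, lam = 0, max_steps = 60)
  es <- run_ensemble(p, init = "random", rho0 = 0.3, reps = 20,
                     discard = 30, master_seed = 5)
  expect_equal(es$rho_s_mean, 0)
  expect_identical(es$surviving, 0L)
  expect_equal(es$dtco, 1)  # all die within one cycle
  # with averaging over all runs, the mean density never increases
  expect_true(all(diff(es$rho_mean_t) <= 1e-12))

  dc <- dtco_curve(p, c(0.1, 0.5, 0.9), reps = 10, master_seed = 6)
  expect_equal(dc$dtco, c(1, 1, 1))
})

test_that("ensemble results are bit-reproducible given the master seed", {
  p <- sirs_params(N = 300, lam = 0.12, max_steps = 300)
  a <- run_ensemble(p, init = "random", rho0 = 0.1, reps = 10,
                    discard = 100, master_seed = 77)
  b <- run_ensemble(p, init = "random", rho0 = 0.1, reps = 10,
                    discard = 100, master_seed = 77)
  expect_identical(a, b)
  c <- run_ensemble(p, init = "random", rho0 = 0.1, reps = 10,
                    discard = 100, master_seed = 78)
  expect_false(identical(a$rho_mean_t, c$rho_mean_t))
})

test_that("an all-absorbed ensemble under surviving-average is flagged, not zeroed", {
  p <- sirs_params(N = 100, lam = 0, max_steps = 50)
  expect_warning(
    es <- run_ensemble(p, init = "random", rho0 = 0.2, reps = 5,
                       discard = 10, average_over = "surviving",
                       master_seed = 1),
    "no realization survived")
  expect_true(es$empty)
  expect_true(is.na(es$rho_s_mean))
})

test_that("a single-point scan equals the corresponding ensemble", {
  p <- sirs_params(N = 200, lam = 0.5, max_steps = 200)
  sc <- steady_state_scan(p, 0.12, rho0 = 0.1, reps = 8, discard = 100,
                          master_seed = 9, max_steps = 200)
  es <- run_ensemble(sirs_params(N = 200, lam = 0.12, max_steps = 200),
                     init = "random", rho0 = 0.1, reps = 8, discard = 100,
                     master_seed = spawn_seeds(9, 1)[1], max_steps = 200)
  expect_identical(nrow(sc), 1L)
  expect_equal(sc$rho_s, es$rho_s_mean)
  expect_equal(sc$surviving, es$surviving)
})
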