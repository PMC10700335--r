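test_that("zero infectivity only advances clocks and drains the lattice", {
  p <- sirs_params(N = 60, lam = 0, tau_I = 7, tau_R = 9, max_steps = 100)
  set.seed(11)
  s <- random_state(p)
  s1 <- sync_step(s, p)
  # no S site changes compartment
  expect_true(all(s1$compartments[s$compartments == 0L] == 0L))
  # I and R clocks advance (or roll over into the next compartment)
  i_stay <- s$compartments == 1L & s$clock < p$tau_I - 1L
  expect_true(all(s1$clock[i_stay] == s$clock[i_stay] + 1L))
  expect_true(all(s1$compartments[s$compartments == 1L & !i_stay] == 2L))

  # every configuration reaches all-S within tau_I + tau_R updates
  for (rep in 1:5) {
    set.seed(rep)
    s0 <- random_state(p)
    tr <- run_until_absorbed(s0, p)
    expect_false(tr$survived)
    expect_lte(tr$absorbed_step, p$tau_I + p$tau_R + 1L)  # 1-based steps
  }
})

test_that("the all-S state is an absorbing fixed point", {
  p <- sirs_params(N = 30, lam = 0.9, max_steps = 10)
  s <- init_uniform_random(p, 0)
  s1 <- sync_step(s, p)
  expect_identical(s1$compartments, s$compartments)
  expect_identical(s1$clock, s$clock)
})

test_that("deterministic front advances one site per step until wrap-around", {
  p <- sirs_params(N = 101, lam = 1, k = 1, tau_I = 2, tau_R = 3,
                   max_steps = 200)
  s <- init_single_seed(p)
  centre <- 101 %/% 2 + 1
  for (t in 1:40) {
    s <- sync_step(s, p)
    inf <- which(s$compartments == 1L)
    expect_true(all(c(centre - t, centre + t) %in% inf))
    expect_equal(range(inf), c(centre - t, centre + t))
  }
})

test_that("Fig.-1 worked example: 11-site ring absorbs at the 11th time step", {
  p <- sirs_params(N = 11, lam = 1, k = 1, tau_I = 2, tau_R = 3,
                   max_steps = 100)
  tr <- run_until_absorbed(init_single_seed(p), p)
  expect_identical(tr$absorbed_step, 11L)
  expect_identical(tr$extinct_step, 8L)
  expect_equal(tr$rho[1], 1 / 11)
  # absorbed means absorbed: density is zero from extinction onwards
  expect_true(all(tr$rho[tr$extinct_step:length(tr$rho)] == 0))
})

test_that("compiled and reference steppers are in lockstep on random states", {
  for (rep in 1:100) {
    set.seed(1000 + rep)
    N <- sample(10:60, 1)
    k <- sample(1:min(3, (N - 1) %/% 2), 1)
    p <- sirs_params(N = N, lam = runif(1), k = k,
                     tau_I = sample(1:7, 1), tau_R = sample(1:9, 1))
    s0 <- random_state(p)
    seed <- sample.int(1e6, 1)
    set.seed(seed); a <- sync_step(s0, p)
    set.seed(seed); b <- sync_step_reference(s0, p)
    expect_identical(a, b)
  }
})

test_that("compiled run matches repeated reference stepping over a whole run", {
  p <- sirs_params(N = 31, lam = 0.35, k = 2, tau_I = 3, tau_R = 4,
                   max_steps = 60)
  set.seed(99)
  s0 <- random_state(p)
  set.seed(1234)
  tr <- run_until_absorbed(s0, p, stop_when_absorbed = FALSE)
  set.seed(1234)
  s <- s0
  rho_ref <- active_density(s)
  for (t in 1:60) {
    s <- sync_step_reference(s, p)
    rho_ref <- c(rho_ref, active_density(s))
  }
  expect_equal(tr$rho, rho_ref)
  expect_identical(tr$final_state$compartments, s$compartments)
  expect_identical(tr$final_state$clock, s$clock)
})

test_that("deterministic absorption step agrees with the reference stepper", {
  p <- sirs_params(N = 31, lam = 1, k = 1, tau_I = 2, tau_R = 3,
                   max_steps = 200)
  tr <- run_until_absorbed(init_single_seed(p), p)
  # independent per-site reference loop, run once
  s <- init_single_seed(p)
  step <- 1L
  while (count_of(s, "S") < 31L) {
    s <- sync_step_reference(s, p)
    step <- step + 1L
  }
  expect_identical(tr$absorbed_step, step)
})

test_that("conservation and the absorbing property hold along trajectories", {
  p <- sirs_params(N = 80, lam = 0.4, max_steps = 150)
  set.seed(8)
  s <- init_uniform_random(p, 0.2)
  for (t in 1:60) {
    s <- sync_step(s, p)
    expect_identical(sum(compartment_counts(s)), 80L)
  }
  # once extinct, the infected count stays zero for 100 further steps
  pl <- sirs_params(N = 40, lam = 0, max_steps = 200)
  set.seed(9)
  tr <- run_until_absorbed(random_state(pl), pl, stop_when_absorbed = FALSE)
  expect_false(tr$survived)
  expect_true(all(tr$rho[tr$extinct_step:length(tr$rho)] == 0))
  expect_gte(length(tr$rho) - tr$extinct_step, 100)
})

test_that("a zero-step cap on an active state is flagged as degenerate", {
  p <- sirs_params(N = 20, lam = 0.5, k = 1, max_steps = 0)
  expect_warning(tr <- run_until_absorbed(init_single_seed(p), p),
                 "degenerate")
  expect_true(tr$survived)
  expect_identical(tr$steps, 0L)
})
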