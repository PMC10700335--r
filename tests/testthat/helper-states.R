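# Build a random valid lattice state (compartments and clocks within their
# allowed ranges) for property-style tests.
random_state <- function(params, p_compartment = c(0.4, 0.3, 0.3)) {
  N <- params$N
  comp <- sample(0:2, N, replace = TRUE, prob = p_compartment)
  clock <- integer(N)
  i <- comp == 1L
  r <- comp == 2L
  clock[i] <- sample.int(params$tau_I, sum(i), replace = TRUE) - 1L
  clock[r] <- sample.int(params$tau_R, sum(r), replace = TRUE) - 1L
  structure(list(compartments = comp, clock = clock, time = 0L, N = N),
            class = "sirs_state")
}

count_of <- function(state, label) {
  code <- c(S = 0L, I = 1L, R = 2L)[[label]]
  sum(state$compartments == code)
}
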