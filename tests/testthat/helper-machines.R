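# Reference machines and small pipeline helpers shared across tests.

# Golden-mean process: after a 1 emit 0; after a 0 emit 0 or 1 equiprobably.
golden_mean_machine <- function(p = 0.5) {
  epsilon_machine(data.frame(from = c(0, 0, 1), symbol = c(0, 1, 0),
                             to = c(0, 1, 0), prob = c(1 - p, p, 1)))
}

# Two states exchanging with probabilities a (from 0) and b (from 1); the
# emitted symbol names the target state.
switching_machine <- function(a, b) {
  epsilon_machine(data.frame(from = c(0, 0, 1, 1), symbol = c(0, 1, 1, 0),
                             to = c(0, 1, 1, 0), prob = c(1 - a, a, 1 - b, b)))
}

# Deterministic period-2 alternator.
alternator_machine <- function() {
  epsilon_machine(data.frame(from = c(0, 1), symbol = c(1, 0),
                             to = c(1, 0), prob = c(1, 1)))
}

# Stationary probability that the machine emits symbol 1.
p1_of <- function(m) {
  pi <- if (is.null(m$pi)) stationary_distribution(m) else m$pi
  ids <- vapply(m$states, `[[`, integer(1), "id")
  sum(vapply(seq_along(ids), function(i) {
    tr <- m$trans[m$trans$from == ids[i] & m$trans$symbol == 1, ]
    pi[i] * sum(tr$prob)
  }, numeric(1)))
}

# Most frequent value (ties broken toward the smaller value).
modal <- function(x) {
  tab <- sort(table(x), decreasing = TRUE)
  as.numeric(names(tab)[1])
}

# Full pipeline at one preset/rate/seed; returns state count, stationary
# symbol-1 probability and the machine.
run_rate <- function(preset, rate, seed, n_pulses = 32768L) {
  sp <- run_experiment(experiment_config(preset, rates_hz = rate,
                                         n_pulses = n_pulses, seed = seed))
  m <- attr(sp, "machines")[[1]]
  list(n_states = sp$n_states[1], p1 = p1_of(m), machine = m,
       theta = sp$theta[1])
}
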