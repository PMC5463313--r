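# shared fixtures, built in code

# a sampler already past burn-in, fed a fixed batch of treatment values
fed_sampler <- function(values = c(0.55, 0.71, 0.64, 0.48, 0.80), ...) {
  update(sham_sampler(...), values)
}

# a small, fast synthetic trial
tiny_trial <- function(seed = 11, n = 8L, visits = 3L, ...) {
  run_trial(trial_config(n_participants = n, n_visits = visits,
                         seed = seed, ...))
}

alloc_of <- function(trial) {
  stats::setNames(trial$participants$arm, trial$participants$pid)
}

# independent inverse-CDF truncated-normal sampler (oracle route)
rtnorm_icdf <- function(n, mean, sd, lower, upper) {
  u <- runif(n, pnorm(lower, mean, sd), pnorm(upper, mean, sd))
  qnorm(u, mean, sd)
}

# closed-form truncated-normal moments
tnorm_moments <- function(mean, sd, lower, upper) {
  a <- (lower - mean) / sd
  b <- (upper - mean) / sd
  z <- pnorm(b) - pnorm(a)
  m <- mean + sd * (dnorm(a) - dnorm(b)) / z
  v <- sd^2 * (1 + (a * dnorm(a) - b * dnorm(b)) / z -
                 ((dnorm(a) - dnorm(b)) / z)^2)
  list(mean = m, sd = sqrt(v), accept = z)
}
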