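test_that("running estimates are the sample mean and n-1 SD", {
  s <- update(sham_sampler(n_min = 2), c(0.5, 0.7))
  expect_equal(s$mean_hat, 0.6)
  # hand computation: sqrt(((0.5-0.6)^2 + (0.7-0.6)^2) / (2 - 1))
  expect_equal(s$sd_hat, sqrt(0.02))
  s <- update(s, 0.9)
  expect_equal(s$mean_hat, mean(c(0.5, 0.7, 0.9)))
  expect_equal(s$sd_hat, sd(c(0.5, 0.7, 0.9)))
})

test_that("prior is used until the burn-in count is reached", {
  s <- sham_sampler(prior_mean = 0.7, prior_sd = 0.2, n_min = 3)
  expect_equal(coef(s), c(mean = 0.7, sd = 0.2))
  s <- update(s, c(0.4, 0.5))
  expect_equal(coef(s), c(mean = 0.7, sd = 0.2))
  s <- update(s, 0.6)
  expect_equal(unname(coef(s)), c(0.5, 0.1))
})

test_that("negative concentrations are rejected", {
  expect_error(update(sham_sampler(), c(0.5, -0.1)), "non-negative")
})

test_that("below-LOD treatment values are excluded or substituted at LOD/2", {
  s_ex <- update(sham_sampler(n_min = 1, lod = 0.1), c(0.5, 0.7, NA),
                 below_lod = c(FALSE, FALSE, TRUE))
  expect_equal(s_ex$values, c(0.5, 0.7))
  s_sub <- update(sham_sampler(n_min = 1, lod = 0.1,
                               lod_action = "substitute"),
                  c(0.5, 0.7, NA), below_lod = c(FALSE, FALSE, TRUE))
  expect_equal(s_sub$values, c(0.5, 0.7, 0.05))
})

test_that("shifting all observations by c shifts the mean and not the SD", {
  set.seed(42)
  for (shift in c(-0.2, 0.1, 0.5)) {
    x <- runif(20, 0.3, 0.9)
    s0 <- update(sham_sampler(), x)
    s1 <- update(sham_sampler(), x + shift)
    expect_equal(s1$mean_hat, s0$mean_hat + shift)
    expect_equal(s1$sd_hat, s0$sd_hat)
  }
})

test_that("every sham draw lies inside the current window", {
  set.seed(7)
  for (i in 1:25) {
    lo <- runif(1, 0.1, 0.6)
    hi <- lo + runif(1, 0.1, 0.6)
    s <- sham_sampler(lower = lo, upper = hi,
                      prior_mean = runif(1, 0, 1.2),
                      prior_sd = runif(1, 0.05, 0.5))
    d <- draw_sham(s, n = 200)
    expect_true(all(d$values >= lo & d$values <= hi))
  }
})

test_that("a degenerate fit returns the mean inside the window and errors outside", {
  s <- update(sham_sampler(n_min = 1), c(0.8, 0.8, 0.8))
  expect_equal(s$sd_hat, 0)
  expect_equal(draw_sham(s, n = 5)$values, rep(0.8, 5))
  out <- update(sham_sampler(n_min = 1, lower = 0.6, upper = 1.0),
                c(0.2, 0.2))
  expect_error(draw_sham(out), "degenerate")
})

test_that("rejection draws match the closed-form truncated-normal mean", {
  s <- sham_sampler(lower = 0.3, upper = 1.0,
                    prior_mean = 0.5, prior_sd = 0.25)
  d <- draw_sham(s, n = 1e5, seed = 31)
  mom <- tnorm_moments(0.5, 0.25, 0.3, 1.0)
  mc_se <- mom$sd / sqrt(1e5)
  expect_lt(abs(mean(d$values) - mom$mean), 3 * mc_se)
})

test_that("rejection and inverse-CDF samplers agree in distribution", {
  s <- sham_sampler(lower = 0.3, upper = 1.0,
                    prior_mean = 0.5, prior_sd = 0.25)
  rej <- draw_sham(s, n = 1e4, seed = 5)$values
  set.seed(6)
  icdf <- round(rtnorm_icdf(1e4, 0.5, 0.25, 0.3, 1.0), 2)
  d <- ecdf_distance(rej, icdf)
  # two-sample KS 1% critical value: 1.628 * sqrt(2 / n)
  expect_lt(d, 1.628 * sqrt(2 / 1e4))
})

test_that("draws are reproducible from a seed and from saved RNG state", {
  s <- fed_sampler()
  expect_identical(draw_sham(s, n = 20, seed = 99)$values,
                   draw_sham(s, n = 20, seed = 99)$values)
  d1 <- draw_sham(s, n = 10, seed = 123)
  path <- withr::local_tempfile(fileext = ".json")
  write_sampler(d1$sampler, path)
  restored <- read_sampler(path)
  expect_identical(draw_sham(d1$sampler, n = 10)$values,
                   draw_sham(restored, n = 10)$values)
})

test_that("sampler state round-trips through JSON", {
  s <- apply_threshold_policy(fed_sampler(c(0.2, 0.3, 0.25, 0.4)),
                              threshold_policy(manual_override = TRUE))
  path <- withr::local_tempfile(fileext = ".json")
  write_sampler(s, path)
  r <- read_sampler(path)
  for (f in c("values", "mean_hat", "sd_hat", "lower", "upper",
              "initial_lower", "lowered", "n_min", "lod_action"))
    expect_equal(r[[f]], s[[f]], info = f)
})

test_that("threshold policy lowers the bound on override or data trigger, one-way", {
  pol <- threshold_policy(trigger_fraction = 0.5, trigger_window = 10)
  # manual override mirrors the oversight-board decision
  s <- apply_threshold_policy(fed_sampler(), threshold_policy(
    manual_override = TRUE))
  expect_equal(s$lower, 0.3)
  expect_true(s$lowered)
  # all recent values in range: no switch
  s2 <- apply_threshold_policy(fed_sampler(runif(12, 0.6, 1.0)), pol)
  expect_equal(s2$lower, 0.6)
  # boundary: exactly 5 of the last 10 below 0.6 fires the trigger
  vals <- c(rep(0.65, 5), rep(0.55, 5))
  s3 <- apply_threshold_policy(fed_sampler(vals), pol)
  expect_equal(s3$lower, 0.3)
  # insufficient data, no override: unchanged
  s4 <- apply_threshold_policy(fed_sampler(c(0.2, 0.2)), pol)
  expect_equal(s4$lower, 0.6)
  # one-way: later in-range data never re-raises the bound
  s5 <- apply_threshold_policy(update(s3, rep(0.8, 20)), pol)
  expect_equal(s5$lower, 0.3)
})

test_that("constructor rejects invalid windows and priors", {
  expect_error(sham_sampler(lower = 1.0, upper = 0.6), "less than")
  expect_error(sham_sampler(prior_sd = 0), "positive")
  expect_error(threshold_policy(adjusted_lower = 0.7), "below")
})
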