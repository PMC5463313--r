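#' Sequential sham-concentration sampler
#'
#' Constructs the sampler used to issue sham plasma drug concentrations for
#' placebo participants during a double-blind trial with therapeutic drug
#' monitoring. The sampler keeps a running Gaussian fit (sample mean and
#' standard deviation) of the concentrations observed so far in the treatment
#' arm, and draws sham values by rejection sampling from that Gaussian
#' truncated to the current reporting window -- initially the drug's
#' therapeutic range.
#'
#' Before `n_min` treatment-arm values have accrued the sampler falls back to
#' a prior mean and SD, so sham values can be issued from the first laboratory
#' batch onward. Treatment-arm values reported below the assay limit of
#' detection are excluded from estimation by default (`lod_action =
#' "exclude"`), or substituted at half the limit (`lod_action =
#' "substitute"`).
#'
#' @param lower,upper Reporting window bounds in mmol/L. Defaults are the
#'   lithium therapeutic range, 0.6--1.0 mmol/L.
#' @param prior_mean,prior_sd Gaussian parameters used until `n_min`
#'   treatment-arm values are available. Default prior is centred in the
#'   therapeutic window.
#' @param n_min Burn-in count: minimum number of accumulated values before
#'   the running estimates replace the prior.
#' @param lod Assay limit of detection in mmol/L.
#' @param lod_action How below-LOD treatment values enter estimation:
#'   `"exclude"` drops them, `"substitute"` imputes `lod / 2`.
#' @param max_iter Maximum rejection-sampling rounds per batch of draws
#'   before switching to inverse-CDF truncated-normal sampling.
#' @param digits Decimal places for reported sham values (half-even
#'   rounding, matching laboratory report precision).
#' @return An object of class `sham_sampler`.
#' @seealso [update.sham_sampler()], [draw_sham()],
#'   [apply_threshold_policy()], [write_sampler()]
#' @examples
#' s <- sham_sampler()
#' s <- update(s, c(0.55, 0.71, 0.64, 0.48))
#' coef(s)
#' draw_sham(s, n = 3, seed = 1)$values
#' @export
sham_sampler <- function(lower = 0.6, upper = 1.0,
                         prior_mean = 0.7, prior_sd = 0.2, n_min = 3L,
                         lod = 0.1, lod_action = c("exclude", "substitute"),
                         max_iter = 10000L, digits = 2L) {
  lod_action <- match.arg(lod_action)
  stopifnot(is.numeric(lower), is.numeric(upper), length(lower) == 1L,
            length(upper) == 1L)
  if (!(lower < upper))
    stop("'lower' must be strictly less than 'upper'")
  if (prior_sd <= 0) stop("'prior_sd' must be positive")
  if (n_min < 1L) stop("'n_min' must be a positive integer")
  if (max_iter < 1L) stop("'max_iter' must be a positive integer")
  if (lod <= 0) stop("'lod' must be positive")
  obj <- list(
    values = numeric(0),
    lower = lower, upper = upper,
    initial_lower = lower,
    prior_mean = prior_mean, prior_sd = prior_sd, n_min = as.integer(n_min),
    mean_hat = prior_mean, sd_hat = prior_sd,
    lod = lod, lod_action = lod_action,
    max_iter = as.integer(max_iter), digits = as.integer(digits),
    lowered = FALSE,
    n_fallback = 0L,
    rng_state = NULL
  )
  class(obj) <- "sham_sampler"
  obj
}

#' Update the running treatment-arm estimates
#'
#' Feeds a new batch of treatment-arm concentrations into the sampler and
#' recomputes the running mean and sample standard deviation (n - 1
#' denominator) over all accumulated values. While fewer than `n_min` values
#' have accrued, the prior mean and SD are used instead; the sample SD
#' additionally requires at least two values.
#'
#' @param object A [sham_sampler()] object.
#' @param values Numeric vector of treatment-arm concentrations (mmol/L,
#'   non-negative). Must come from the treatment arm only; feeding placebo
#'   rows would corrupt the estimates.
#' @param below_lod Optional logical vector flagging values reported below
#'   the assay limit of detection. Flagged entries are excluded or
#'   substituted at `lod / 2` according to the sampler's `lod_action`; the
#'   numeric entry at a flagged position is ignored.
#' @param ... Unused.
#' @return The updated `sham_sampler`.
#' @export
update.sham_sampler <- function(object, values, below_lod = NULL, ...) {
  values <- as.numeric(values)
  if (is.null(below_lod)) below_lod <- rep(FALSE, length(values))
  if (length(below_lod) != length(values))
    stop("'below_lod' must match 'values' in length")
  if (any(!below_lod & (is.na(values) | values < 0)))
    stop("treatment-arm concentrations must be non-negative and non-missing")
  if (any(below_lod)) {
    if (object$lod_action == "substitute") {
      values[below_lod] <- object$lod / 2
    } else {
      values <- values[!below_lod]
    }
  }
  object$values <- c(object$values, values)
  n <- length(object$values)
  object$mean_hat <- if (n >= object$n_min) mean(object$values) else
    object$prior_mean
  object$sd_hat <- if (n >= max(object$n_min, 2L)) stats::sd(object$values)
    else object$prior_sd
  object
}

#' Draw sham concentrations from the current truncated Gaussian
#'
#' Draws `n` sham values by rejection sampling: proposals from
#' Normal(`mean_hat`, `sd_hat`) are kept only if they fall inside the current
#' window `[lower, upper]`. If after `max_iter` rounds some draws are still
#' unresolved (the acceptance probability is pathologically small), those
#' draws fall back to exact inverse-CDF truncated-normal sampling and the
#' event is counted in `n_fallback` and messaged. Results are rounded
#' half-even to `digits` decimals; a rounded value that would leave the
#' window is clamped to the nearest bound.
#'
#' A degenerate fit (`sd_hat = 0`) returns `mean_hat` when it lies inside
#' the window and is an error otherwise (no valid draw exists).
#'
#' @param sampler A [sham_sampler()] object.
#' @param n Number of sham values to draw.
#' @param seed Optional integer; when given, `set.seed(seed)` is called
#'   first. Otherwise the sampler's saved RNG state is used if present, else
#'   the global RNG stream.
#' @return A list with `values` (numeric vector of length `n`) and
#'   `sampler`, the sampler with its RNG bookkeeping advanced.
#' @export
draw_sham <- function(sampler, n = 1L, seed = NULL) {
  stopifnot(inherits(sampler, "sham_sampler"), n >= 1L)
  mu <- sampler$mean_hat
  sdv <- sampler$sd_hat
  lo <- sampler$lower
  hi <- sampler$upper
  if (sdv < 0) stop("'sd_hat' must be non-negative")
  if (sdv == 0) {
    if (mu < lo || mu > hi)
      stop("degenerate fit: sd_hat = 0 with mean_hat outside the window; ",
           "acceptance probability is zero")
    return(list(values = rep(round(mu, sampler$digits), n),
                sampler = sampler))
  }
  if (!is.null(seed)) {
    set.seed(seed)
  } else if (!is.null(sampler$rng_state)) {
    assign(".Random.seed", sampler$rng_state, envir = globalenv())
  } else if (!exists(".Random.seed", envir = globalenv())) {
    stats::runif(1) # initialise the RNG stream
  }

  out <- rep(NA_real_, n)
  pending <- seq_len(n)
  iter <- 0L
  while (length(pending) && iter < sampler$max_iter) {
    prop <- stats::rnorm(length(pending), mu, sdv)
    ok <- prop >= lo & prop <= hi
    out[pending[ok]] <- prop[ok]
    pending <- pending[!ok]
    iter <- iter + 1L
  }
  if (length(pending)) {
    # acceptance probability too small for rejection sampling; draw the
    # remainder exactly via the inverse CDF of the truncated normal
    plo <- stats::pnorm(lo, mu, sdv)
    phi <- stats::pnorm(hi, mu, sdv)
    u <- stats::runif(length(pending), plo, phi)
    out[pending] <- stats::qnorm(u, mu, sdv)
    sampler$n_fallback <- sampler$n_fallback + length(pending)
    message("draw_sham: inverse-CDF fallback used for ", length(pending),
            " draw(s)")
  }
  out <- round(out, sampler$digits)
  out <- pmin(pmax(out, lo), hi)
  if (!is.null(sampler$rng_state) || !is.null(seed))
    sampler$rng_state <- get(".Random.seed", envir = globalenv())
  list(values = out, sampler = sampler)
}

#' Simulate sham concentrations
#'
#' [stats::simulate()] method: a convenience wrapper around [draw_sham()]
#' that returns just the simulated values.
#'
#' @param object A [sham_sampler()] object.
#' @param nsim Number of sham values to draw.
#' @param seed Optional integer seed, as in [draw_sham()].
#' @param ... Unused.
#' @return Numeric vector of length `nsim`, with the advanced sampler
#'   attached as attribute `"sampler"`.
#' @export
simulate.sham_sampler <- function(object, nsim = 1L, seed = NULL, ...) {
  res <- draw_sham(object, n = nsim, seed = seed)
  structure(res$values, sampler = res$sampler)
}

#' Threshold-adjustment policy for the sham window
#'
#' During the trial, poor adherence in the treatment arm produced
#' concentrations well below the therapeutic range; keeping sham values
#' inside the original window would then have unblinded the dose-adjusting
#' investigator. The remedy is a one-way lowering of the sham window's lower
#' bound (in the motivating trial, from 0.6 to 0.3 mmol/L, sanctioned by the
#' Data Safety and Monitoring Board). That decision was a human judgement;
#' this policy object reproduces it either by `manual_override`, or by a
#' data-driven trigger: the bound is lowered once at least `trigger_fraction`
#' of the last `trigger_window` treatment-arm values fall below
#' `initial_lower`.
#'
#' @param initial_lower Protocol lower bound of the window (mmol/L).
#' @param adjusted_lower Lowered bound applied once triggered (mmol/L);
#'   must be below `initial_lower`.
#' @param trigger_fraction Fraction of recent values below `initial_lower`
#'   at or above which the switch fires, in (0, 1].
#' @param trigger_window Number of most recent treatment values inspected.
#' @param manual_override Logical; force the switch regardless of data,
#'   mirroring an oversight-board decision.
#' @return An object of class `threshold_policy`.
#' @export
threshold_policy <- function(initial_lower = 0.6, adjusted_lower = 0.3,
                             trigger_fraction = 0.5, trigger_window = 10L,
                             manual_override = FALSE) {
  if (!(adjusted_lower < initial_lower))
    stop("'adjusted_lower' must be below 'initial_lower'")
  if (trigger_fraction <= 0 || trigger_fraction > 1)
    stop("'trigger_fraction' must be in (0, 1]")
  if (trigger_window < 1L) stop("'trigger_window' must be positive")
  structure(list(initial_lower = initial_lower,
                 adjusted_lower = adjusted_lower,
                 trigger_fraction = trigger_fraction,
                 trigger_window = as.integer(trigger_window),
                 manual_override = isTRUE(manual_override)),
            class = "threshold_policy")
}

#' Apply the threshold policy to a sampler
#'
#' Lowers the sampler's window lower bound to `policy$adjusted_lower` when
#' the manual override is set, or when the fraction of the last
#' `trigger_window` accumulated treatment values below `policy$initial_lower`
#' reaches `trigger_fraction`. The switch is one-way: once lowered the bound
#' is never raised again. With fewer than `trigger_window` values and no
#' override, the sampler is returned unchanged.
#'
#' @param sampler A [sham_sampler()] object.
#' @param policy A [threshold_policy()] object.
#' @return The (possibly adjusted) `sham_sampler`.
#' @export
apply_threshold_policy <- function(sampler, policy) {
  stopifnot(inherits(sampler, "sham_sampler"),
            inherits(policy, "threshold_policy"))
  if (sampler$lowered) return(sampler)
  fire <- policy$manual_override
  if (!fire && length(sampler$values) >= policy$trigger_window) {
    recent <- utils::tail(sampler$values, policy$trigger_window)
    fire <- mean(recent < policy$initial_lower) >= policy$trigger_fraction
  }
  if (fire) {
    sampler$lower <- policy$adjusted_lower
    sampler$lowered <- TRUE
  }
  sampler
}

#' @export
print.sham_sampler <- function(x, ...) {
  cat("Sham concentration sampler\n")
  cat(sprintf("  window: [%.2f, %.2f] mmol/L%s\n", x$lower, x$upper,
              if (x$lowered) "  (lower bound adjusted)" else ""))
  n <- length(x$values)
  src <- if (n >= x$n_min) sprintf("from %d treatment-arm values", n) else
    sprintf("prior (burn-in, %d/%d values)", n, x$n_min)
  cat(sprintf("  Gaussian fit: mean %.3f, sd %.3f  [%s]\n",
              x$mean_hat, x$sd_hat, src))
  if (x$n_fallback > 0L)
    cat(sprintf("  inverse-CDF fallback used for %d draw(s)\n", x$n_fallback))
  invisible(x)
}

#' @export
coef.sham_sampler <- function(object, ...) {
  c(mean = object$mean_hat, sd = object$sd_hat)
}

#' @export
summary.sham_sampler <- function(object, ...) {
  mu <- object$mean_hat; sdv <- object$sd_hat
  a <- (object$lower - mu) / sdv
  b <- (object$upper - mu) / sdv
  z <- stats::pnorm(b) - stats::pnorm(a)
  tmean <- if (sdv > 0 && z > 0)
    mu + sdv * (stats::dnorm(a) - stats::dnorm(b)) / z else mu
  out <- list(n = length(object$values), mean_hat = mu, sd_hat = sdv,
              lower = object$lower, upper = object$upper,
              lowered = object$lowered,
              acceptance_prob = if (sdv > 0) z else
                as.numeric(mu >= object$lower && mu <= object$upper),
              truncated_mean = tmean)
  class(out) <- "summary.sham_sampler"
  out
}

#' @export
print.summary.sham_sampler <- function(x, ...) {
  cat("Sham sampler summary\n")
  cat(sprintf("  treatment-arm values accrued: %d\n", x$n))
  cat(sprintf("  fit: Normal(%.3f, %.3f), window [%.2f, %.2f]%s\n",
              x$mean_hat, x$sd_hat, x$lower, x$upper,
              if (x$lowered) " (adjusted)" else ""))
  cat(sprintf("  rejection acceptance probability: %.3f\n",
              x$acceptance_prob))
  cat(sprintf("  expected sham value (truncated mean): %.3f mmol/L\n",
              x$truncated_mean))
  invisible(x)
}

#' Save / restore sampler state as JSON
#'
#' The sampler is serialised to JSON so the unblinded statistician can
#' restart between laboratory-report batches with the estimates, window,
#' and RNG state intact. If the sampler has no saved RNG state at write
#' time, the current global RNG state is captured so that a re-run from the
#' saved file reproduces the next batch's draws exactly.
#'
#' @param sampler A [sham_sampler()] object.
#' @param path File path for the JSON state.
#' @return `write_sampler()` returns `path` invisibly; `read_sampler()`
#'   returns the restored `sham_sampler`.
#' @export
write_sampler <- function(sampler, path) {
  stopifnot(inherits(sampler, "sham_sampler"))
  if (is.null(sampler$rng_state) &&
      exists(".Random.seed", envir = globalenv()))
    sampler$rng_state <- get(".Random.seed", envir = globalenv())
  jsonlite::write_json(unclass(sampler), path, auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_sampler
#' @export
read_sampler <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  obj <- sham_sampler(lower = raw$lower, upper = raw$upper,
                      prior_mean = raw$prior_mean, prior_sd = raw$prior_sd,
                      n_min = raw$n_min, lod = raw$lod,
                      lod_action = raw$lod_action,
                      max_iter = raw$max_iter, digits = raw$digits)
  obj$values <- as.numeric(raw$values)
  obj$initial_lower <- raw$initial_lower
  obj$mean_hat <- raw$mean_hat
  obj$sd_hat <- raw$sd_hat
  obj$lowered <- isTRUE(raw$lowered)
  obj$n_fallback <- as.integer(raw$n_fallback)
  if (!is.null(raw$rng_state)) obj$rng_state <- as.integer(raw$rng_state)
  obj
}
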