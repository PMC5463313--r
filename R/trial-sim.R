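#' Synthetic trial configuration
#'
#' Parameters for generating a synthetic two-arm placebo-controlled trial
#' with therapeutic drug monitoring, so the sham-sampling, dosing, and
#' re-blinding workflow can be exercised end to end without trial data.
#' Defaults emulate a lithium trial of roughly 66 participants followed over
#' 8 scheduled visits (about 250 measurements per arm), with linear
#' dose--concentration response, between-participant clearance variability,
#' imperfect adherence, and non-trough sampling-time noise.
#'
#' @param n_participants Number of participants across both arms.
#' @param n_visits Number of scheduled TDM visits per participant.
#' @param block_size Randomisation block size (positive even integer).
#' @param pk_constant Steady-state concentration per unit weight-normalised
#'   dose, mmol/L per (mg/kg/day), at median clearance and full adherence.
#'   Default 0.0375 so the protocol initiation rate of 20 mg/kg/day lands at
#'   0.75 mmol/L, mid-window.
#' @param clearance_cv Coefficient of variation of between-participant
#'   clearance (lognormal, median 1).
#' @param adherence_mean Population mean adherence propensity in \[0, 1\].
#'   Default 0.75 reflects the substantial non-adherence such trials see.
#' @param adherence_kappa Beta concentration parameter for per-participant
#'   propensities and per-visit adherence draws; larger is less variable.
#' @param sampling_time_sd SD of the deviation (hours) of actual sampling
#'   time from the scheduled trough; positive deviations are late arrivals.
#' @param decay_lambda First-order elimination rate (per hour) applied to
#'   the sampling-time deviation. Default 0.023/h keeps a 6-h deviation
#'   under a 15\% concentration change, of the order of lithium's
#'   elimination rate.
#' @param assay_lod Assay limit of detection (mmol/L).
#' @param assay_cv Coefficient of variation of multiplicative lognormal
#'   assay noise (mean 1).
#' @param weight_mean,weight_sd Body-weight distribution (kg), truncated
#'   below at 40 kg.
#' @param ae_prob Per-visit probability of a drug-related-judged adverse
#'   event, identical in both arms (sham AEs are never generated; in a
#'   placebo-controlled trial AE judgements occur in both arms).
#' @param baseline_date Date of the first visit.
#' @param visit_interval_days Days between scheduled visits.
#' @param seed Integer seed; the whole trial is reproducible from it.
#' @return An object of class `trial_config`.
#' @export
trial_config <- function(n_participants = 66L, n_visits = 8L,
                         block_size = 4L, pk_constant = 0.0375,
                         clearance_cv = 0.25, adherence_mean = 0.75,
                         adherence_kappa = 10, sampling_time_sd = 2,
                         decay_lambda = 0.023, assay_lod = 0.1,
                         assay_cv = 0.05, weight_mean = 70, weight_sd = 12,
                         ae_prob = 0.08,
                         baseline_date = as.Date("2014-01-06"),
                         visit_interval_days = 21L, seed = 1L) {
  if (n_participants < 1L || n_visits < 1L)
    stop("'n_participants' and 'n_visits' must be positive")
  if (block_size < 2L || block_size %% 2L != 0L)
    stop("'block_size' must be a positive even integer")
  if (clearance_cv < 0 || assay_cv < 0 || sampling_time_sd < 0)
    stop("coefficients of variation and noise SDs must be non-negative")
  if (adherence_mean < 0 || adherence_mean > 1)
    stop("'adherence_mean' must be in [0, 1]")
  if (pk_constant <= 0) stop("'pk_constant' must be positive")
  if (assay_lod <= 0) stop("'assay_lod' must be positive")
  if (ae_prob < 0 || ae_prob > 1) stop("'ae_prob' must be in [0, 1]")
  structure(list(n_participants = as.integer(n_participants),
                 n_visits = as.integer(n_visits),
                 block_size = as.integer(block_size),
                 pk_constant = pk_constant, clearance_cv = clearance_cv,
                 adherence_mean = adherence_mean,
                 adherence_kappa = adherence_kappa,
                 sampling_time_sd = sampling_time_sd,
                 decay_lambda = decay_lambda, assay_lod = assay_lod,
                 assay_cv = assay_cv, weight_mean = weight_mean,
                 weight_sd = weight_sd, ae_prob = ae_prob,
                 baseline_date = as.Date(baseline_date),
                 visit_interval_days = as.integer(visit_interval_days),
                 seed = as.integer(seed)),
            class = "trial_config")
}

#' Block randomisation
#'
#' Allocates participants to treatment or placebo in permuted blocks: each
#' complete block contains exactly `block_size / 2` of each arm in random
#' order. A final incomplete block takes the leading assignments of one
#' further permuted block, so the arm imbalance never exceeds
#' `block_size / 2`. Deterministic given `seed`; the caller's RNG stream is
#' left untouched.
#'
#' @param pids Character vector of participant identifiers, in enrolment
#'   order.
#' @param block_size Positive even block size.
#' @param seed Integer seed.
#' @return Named character vector mapping pid to `"treatment"` or
#'   `"placebo"`.
#' @export
block_randomise <- function(pids, block_size = 4L, seed = 1L) {
  if (block_size < 2L || block_size %% 2L != 0L)
    stop("'block_size' must be a positive even integer: blocks must split ",
         "evenly between the two arms")
  if (anyDuplicated(pids)) stop("'pids' must be unique")
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old))
    assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  n <- length(pids)
  n_blocks <- ceiling(n / block_size)
  arms <- unlist(lapply(seq_len(n_blocks), function(b)
    sample(rep(c("treatment", "placebo"), block_size / 2L))))
  stats::setNames(arms[seq_len(n)], pids)
}

# Beta draws parameterised by mean and concentration; degenerate means pass
# through exactly so noise-free configurations stay noise-free
rbeta_mean <- function(n, mean, kappa) {
  if (mean <= 0) return(rep(0, n))
  if (mean >= 1) return(rep(1, n))
  stats::rbeta(n, mean * kappa, (1 - mean) * kappa)
}

#' Steady-state concentration under the linear PK model
#'
#' The generator's pharmacokinetic model: steady-state trough concentration
#' proportional to the adherence-weighted daily dose, divided by individual
#' clearance (a lognormal multiple of population clearance, which scales
#' linearly with body weight), decayed for sampling-time deviation from the
#' scheduled trough, and multiplied by optional assay noise:
#' \deqn{C = k \cdot \frac{D \cdot a}{CL_i \cdot W}
#'       \cdot e^{-\lambda t} \cdot \epsilon}
#' where \eqn{k} is `pk_constant` (mmol/L per mg/kg/day), \eqn{D} the daily
#' dose (mg), \eqn{a} the adherence draw, \eqn{CL_i} the dimensionless
#' clearance factor, \eqn{W} the weight (kg), \eqn{t} the sampling offset
#' (h), and \eqn{\epsilon} a multiplicative noise term (pass 1 to disable).
#' With all noise terms fixed, concentration is exactly proportional to
#' dose -- the linearity the dose engine relies on.
#'
#' @param profile List or one-row data frame with `weight_kg` and
#'   `clearance_factor`.
#' @param daily_dose_mg Daily dose in mg (non-negative).
#' @param adherence_draw Fraction of prescribed drug taken, in \[0, 1\].
#' @param sampling_offset_h Deviation of sampling time from the scheduled
#'   trough, hours (positive = late).
#' @param config A [trial_config()] supplying `pk_constant` and
#'   `decay_lambda`.
#' @param noise_mult Multiplicative assay-noise factor (default 1).
#' @return Concentration in mmol/L.
#' @export
simulate_true_concentration <- function(profile, daily_dose_mg,
                                        adherence_draw = 1,
                                        sampling_offset_h = 0,
                                        config = trial_config(),
                                        noise_mult = 1) {
  if (any(daily_dose_mg < 0)) stop("'daily_dose_mg' must be non-negative")
  if (any(adherence_draw < 0 | adherence_draw > 1))
    stop("'adherence_draw' must be in [0, 1]")
  config$pk_constant * daily_dose_mg * adherence_draw /
    (profile$clearance_factor * profile$weight_kg) *
    exp(-config$decay_lambda * sampling_offset_h) * noise_mult
}

# participant generation: weights, clearance factors, adherence
# propensities, block-randomised arms
make_participants <- function(config) {
  n <- config$n_participants
  pid <- sprintf("P%03d", seq_len(n))
  weight <- pmax(40, stats::rnorm(n, config$weight_mean, config$weight_sd))
  sdlog <- sqrt(log(1 + config$clearance_cv^2))
  clearance <- if (sdlog > 0) stats::rlnorm(n, 0, sdlog) else rep(1, n)
  propensity <- rbeta_mean(n, config$adherence_mean, config$adherence_kappa)
  arm <- block_randomise(pid, config$block_size, seed = config$seed)
  data.frame(pid = pid, weight_kg = weight, clearance_factor = clearance,
             adherence_propensity = propensity,
             arm = unname(arm[pid]), stringsAsFactors = FALSE)
}

#' Run a synthetic trial end to end
#'
#' Simulates the full closed loop the method operates in: at each visit the
#' laboratory measures treatment-arm concentrations (placebo reported below
#' the limit of detection), the unblinded statistician re-blinds the batch
#' -- updating the sham sampler with the batch's treatment values and
#' drawing sham values for placebo rows -- and the dose-adjusting
#' investigator issues rule-based recommendations from the re-blinded file,
#' which set each participant's dose at the next visit. Placebo doses are
#' therefore titrated on sham values, exactly as in a blinded trial.
#'
#' @param config A [trial_config()].
#' @param policy A [dose_policy()].
#' @param sampler A [sham_sampler()]; defaults to one whose window is the
#'   dose policy's target range.
#' @param threshold A [threshold_policy()] consulted at every batch (set
#'   `trigger_fraction = 1` and a huge window to disable).
#' @return An object of class `tdm_trial`: a list with `participants`,
#'   `visits` (the unblinded truth table: doses, adherence draws, true and
#'   reported concentrations, re-blinded concentrations), `recommendations`,
#'   `audit` (one row per sham substitution), the final `sampler`, and the
#'   configurations.
#' @export
run_trial <- function(config = trial_config(), policy = dose_policy(),
                      sampler = NULL, threshold = threshold_policy()) {
  stopifnot(inherits(config, "trial_config"), inherits(policy, "dose_policy"))
  set.seed(config$seed)
  participants <- make_participants(config)
  n <- nrow(participants)
  alloc <- stats::setNames(participants$arm, participants$pid)
  if (is.null(sampler))
    sampler <- sham_sampler(lower = policy$target_lower,
                            upper = policy$target_upper,
                            lod = config$assay_lod)
  sdlog_assay <- sqrt(log(1 + config$assay_cv^2))
  current_dose <- stats::setNames(initial_dose(participants$weight_kg, policy),
                                  participants$pid)
  visits <- vector("list", config$n_visits)
  recs <- vector("list", config$n_visits)
  audit <- vector("list", config$n_visits)
  for (v in seq_len(config$n_visits)) {
    date <- config$baseline_date + (v - 1L) * config$visit_interval_days
    adh <- vapply(participants$adherence_propensity, function(p)
      rbeta_mean(1L, p, config$adherence_kappa), 0)
    offset <- stats::rnorm(n, 0, config$sampling_time_sd)
    amult <- if (sdlog_assay > 0)
      stats::rlnorm(n, -sdlog_assay^2 / 2, sdlog_assay) else rep(1, n)
    dose <- unname(current_dose[participants$pid])
    true_conc <- ifelse(
      participants$arm == "treatment",
      simulate_true_concentration(participants, dose, adh, offset,
                                  config, amult),
      0)
    below <- true_conc < config$assay_lod
    reported <- ifelse(participants$arm == "placebo" | below, "<LOD",
                       sprintf("%.2f", round(true_conc, 2)))
    ae <- stats::runif(n) < config$ae_prob
    lab <- data.frame(pid = participants$pid, date = as.character(date),
                      value = suppressWarnings(as.numeric(reported)),
                      below_lod = reported == "<LOD",
                      raw = reported, stringsAsFactors = FALSE)
    rb <- reblind(lab, alloc, sampler, threshold)
    sampler <- rb$sampler
    out <- rb$reblinded
    conc_num <- suppressWarnings(as.numeric(out$concentration))
    ctx <- data.frame(pid = out$pid, date = out$date,
                      current_dose_mg = unname(current_dose[out$pid]),
                      concentration = conc_num,
                      below_lod = out$concentration == "<LOD",
                      ae_related = unname(stats::setNames(
                        ae, participants$pid)[out$pid]),
                      stringsAsFactors = FALSE)
    rv <- recommend_doses(ctx, policy)
    current_dose[rv$pid] <- rv$new_daily_dose_mg
    visits[[v]] <- data.frame(
      pid = participants$pid, visit = v, date = as.character(date),
      daily_dose_mg = dose, adherence_draw = adh,
      sampling_offset_h = offset,
      true_concentration = true_conc, reported = reported,
      below_lod = below, ae_related = ae,
      reblinded_concentration = unname(stats::setNames(
        out$concentration, out$pid)[participants$pid]),
      stringsAsFactors = FALSE)
    rv$visit <- v
    recs[[v]] <- rv
    audit[[v]] <- rb$audit
  }
  structure(list(participants = participants,
                 visits = do.call(rbind, visits),
                 recommendations = do.call(rbind, recs),
                 audit = do.call(rbind, audit),
                 sampler = sampler,
                 config = config, dose_policy = policy),
            class = "tdm_trial")
}

#' @export
print.tdm_trial <- function(x, ...) {
  tab <- table(x$participants$arm)
  cat(sprintf("Synthetic TDM trial: %d participants (%s), %d visits\n",
              nrow(x$participants),
              paste(sprintf("%d %s", tab, names(tab)), collapse = ", "),
              x$config$n_visits))
  cat(sprintf("  %d visit rows; %d sham substitutions; %d recommendations\n",
              nrow(x$visits), nrow(x$audit), nrow(x$recommendations)))
  cat(sprintf("  sham window now [%.2f, %.2f] mmol/L\n",
              x$sampler$lower, x$sampler$upper))
  invisible(x)
}

#' Write trial files
#'
#' Writes the synthetic trial as the file set the workflow consumes: the
#' blinded laboratory report (`lab_report.csv`: pid, date, value with the
#' literal token `<LOD`), the dose / adverse-event context
#' (`dose_context.csv`), and -- for the unblinded role only -- the
#' allocation list (`allocation.csv`) and the full truth table
#' (`truth.csv`).
#'
#' @param trial A `tdm_trial` from [run_trial()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the named vector of file paths written.
#' @export
write_trial <- function(trial, dir) {
  stopifnot(inherits(trial, "tdm_trial"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(lab = file.path(dir, "lab_report.csv"),
             context = file.path(dir, "dose_context.csv"),
             allocation = file.path(dir, "allocation.csv"),
             truth = file.path(dir, "truth.csv"))
  lab <- data.frame(pid = trial$visits$pid, date = trial$visits$date,
                    value = trial$visits$reported)
  utils::write.csv(lab, paths["lab"], row.names = FALSE, quote = FALSE)
  ctx <- data.frame(pid = trial$visits$pid, date = trial$visits$date,
                    current_dose_mg = trial$visits$daily_dose_mg,
                    ae_related = trial$visits$ae_related,
                    adherent = trial$visits$adherence_draw >= 0.8)
  utils::write.csv(ctx, paths["context"], row.names = FALSE, quote = FALSE)
  utils::write.csv(data.frame(pid = trial$participants$pid,
                              arm = trial$participants$arm),
                   paths["allocation"], row.names = FALSE, quote = FALSE)
  truth <- merge(trial$visits,
                 trial$participants[, c("pid", "arm", "weight_kg")],
                 by = "pid", sort = FALSE)
  truth <- truth[order(truth$pid, truth$visit), ]
  utils::write.csv(truth, paths["truth"], row.names = FALSE, quote = FALSE)
  invisible(paths)
}
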