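#' Protocol dose-policy constants
#'
#' Holds the protocol constants for rule-based dose individualisation:
#' the therapeutic target window, the point target used for linear-PK
#' scaling, the weight-based initiation rate, the usual daily-dose range
#' qualifying upward adjustment, the tablet increment, and the assay limit
#' of detection. Defaults are the lithium protocol values: target 0.6--1.0
#' mmol/L, initiation at 20 mg/kg/day, usual doses 500--1500 mg/day.
#'
#' @param target_lower,target_upper Therapeutic window bounds (mmol/L).
#' @param target_mid Point concentration targeted when scaling doses
#'   (mmol/L); default is the window midpoint, 0.8.
#' @param init_rate_mg_per_kg Initiation rate in mg/kg/day.
#' @param usual_min_mg,usual_max_mg Usual daily-dose range (mg). Upward
#'   adjustment never exceeds `usual_max_mg`; decreases for safety may go
#'   below `usual_min_mg`.
#' @param tablet_increment_mg Smallest dose step (mg); every emitted dose is
#'   a multiple of it. Default 250 mg, a common lithium carbonate strength.
#' @param lod_mmol_per_l Assay limit of detection (mmol/L).
#' @return An object of class `dose_policy`.
#' @export
dose_policy <- function(target_lower = 0.6, target_upper = 1.0,
                        target_mid = 0.8, init_rate_mg_per_kg = 20,
                        usual_min_mg = 500, usual_max_mg = 1500,
                        tablet_increment_mg = 250, lod_mmol_per_l = 0.1) {
  if (!(target_lower < target_mid && target_mid < target_upper))
    stop("need target_lower < target_mid < target_upper")
  if (!(usual_min_mg < usual_max_mg))
    stop("need usual_min_mg < usual_max_mg")
  if (tablet_increment_mg <= 0) stop("'tablet_increment_mg' must be positive")
  if (lod_mmol_per_l <= 0) stop("'lod_mmol_per_l' must be positive")
  if (init_rate_mg_per_kg <= 0) stop("'init_rate_mg_per_kg' must be positive")
  structure(list(target_lower = target_lower, target_upper = target_upper,
                 target_mid = target_mid,
                 init_rate_mg_per_kg = init_rate_mg_per_kg,
                 usual_min_mg = usual_min_mg, usual_max_mg = usual_max_mg,
                 tablet_increment_mg = tablet_increment_mg,
                 lod_mmol_per_l = lod_mmol_per_l),
            class = "dose_policy")
}

# round to a tablet multiple; "nearest" breaks ties toward the lower dose
round_increment <- function(x, inc, mode = c("nearest", "down")) {
  mode <- match.arg(mode)
  q <- x / inc
  k <- switch(mode,
              down = floor(q),
              nearest = {
                f <- floor(q)
                ifelse(q - f > 0.5, f + 1, f)
              })
  k * inc
}

#' Weight-based initiation dose
#'
#' The starting daily dose is the initiation rate times body weight, rounded
#' to the nearest tablet increment (ties toward the lower dose), then
#' clamped to the usual daily-dose range.
#'
#' @param weight_kg Body weight in kg (positive); vectorised.
#' @param policy A [dose_policy()] object.
#' @return Daily dose(s) in mg.
#' @examples
#' initial_dose(50)  # 20 mg/kg/day -> 1000 mg
#' initial_dose(90)  # 1800 mg clamped to the 1500 mg ceiling
#' @export
initial_dose <- function(weight_kg, policy = dose_policy()) {
  stopifnot(inherits(policy, "dose_policy"))
  if (any(is.na(weight_kg)) || any(weight_kg <= 0))
    stop("'weight_kg' must be positive")
  raw <- policy$init_rate_mg_per_kg * weight_kg
  dose <- round_increment(raw, policy$tablet_increment_mg, "nearest")
  pmin(pmax(dose, policy$usual_min_mg), policy$usual_max_mg)
}

#' Rule-based dose recommendation from one concentration report
#'
#' Encodes the protocol's dose-individualisation rules, applied to the
#' re-blinded concentration so the same rules act on true and sham values
#' alike:
#' \itemize{
#'   \item concentration inside the target window: hold the current dose;
#'   \item above the window: decrease, scaling the dose by
#'     `target_mid / concentration` under linear pharmacokinetics and
#'     rounding down to a tablet multiple (decreases may pass below the
#'     usual minimum dose);
#'   \item below the window with a drug-related adverse event: hold -- doses
#'     are never adjusted upward under a related AE;
#'   \item below the window otherwise: scale up by
#'     `target_mid / concentration`; if the scaled dose would exceed the
#'     usual maximum, upward adjustment is considered unsafe and an
#'     adherence-confirmation note is issued instead, dose unchanged;
#'     otherwise increase to the scaled dose rounded to the nearest tablet
#'     multiple (ties toward the lower dose), capped at the usual maximum;
#'   \item below the limit of detection: adherence note, dose unchanged
#'     (linear scaling from a near-zero concentration is meaningless).
#' }
#'
#' @param current_dose_mg Current daily dose in mg (non-negative).
#' @param concentration Reported plasma concentration (mmol/L), or `NA`
#'   when `below_lod` is set.
#' @param below_lod Logical: concentration reported below the assay limit
#'   of detection.
#' @param ae_related Logical: a significant adverse event judged related to
#'   the study drug is active.
#' @param policy A [dose_policy()] object.
#' @return An object of class `dose_recommendation`: a list with `action`
#'   (one of `"increase"`, `"decrease"`, `"hold"`, `"adherence_note"`),
#'   `new_daily_dose_mg`, and a `rationale` code (`in_range`, `above_range`,
#'   `below_range_scaled`, `ae_hold`, `ceiling_note`, `below_lod_note`).
#' @examples
#' recommend_dose(1000, 0.8)                     # in range: hold
#' recommend_dose(800, 0.5)                      # scale up toward 0.8
#' recommend_dose(800, 0.5, ae_related = TRUE)   # AE: no upward adjustment
#' recommend_dose(800, 0.4)                      # scaled dose > 1500: note
#' @export
recommend_dose <- function(current_dose_mg, concentration,
                           below_lod = FALSE, ae_related = FALSE,
                           policy = dose_policy()) {
  stopifnot(inherits(policy, "dose_policy"))
  if (is.na(current_dose_mg) || current_dose_mg < 0)
    stop("'current_dose_mg' must be non-negative")
  rec <- function(action, dose, rationale)
    structure(list(action = action, new_daily_dose_mg = dose,
                   rationale = rationale),
              class = "dose_recommendation")
  if (isTRUE(below_lod))
    return(rec("adherence_note", current_dose_mg, "below_lod_note"))
  if (is.na(concentration) || concentration <= 0)
    stop("'concentration' must be positive unless flagged below the LOD")
  inc <- policy$tablet_increment_mg
  if (concentration >= policy$target_lower &&
      concentration <= policy$target_upper)
    return(rec("hold", current_dose_mg, "in_range"))
  if (concentration > policy$target_upper) {
    new <- round_increment(current_dose_mg * policy$target_mid /
                             concentration, inc, "down")
    return(rec("decrease", new, "above_range"))
  }
  # concentration below the target window
  if (isTRUE(ae_related))
    return(rec("hold", current_dose_mg, "ae_hold"))
  raw <- current_dose_mg * policy$target_mid / concentration
  if (raw > policy$usual_max_mg)
    return(rec("adherence_note", current_dose_mg, "ceiling_note"))
  new <- round_increment(raw, inc, "nearest")
  new <- min(new, round_increment(policy$usual_max_mg, inc, "down"))
  if (new > current_dose_mg)
    rec("increase", new, "below_range_scaled")
  else
    rec("hold", current_dose_mg, "below_range_scaled")
}

#' @export
print.dose_recommendation <- function(x, ...) {
  cat(sprintf("Dose recommendation: %s -> %g mg/day  [%s]\n",
              x$action, x$new_daily_dose_mg, x$rationale))
  invisible(x)
}

#' Batch dose recommendations over a re-blinded report
#'
#' Applies [recommend_dose()] row-wise to a re-blinded concentration report
#' joined with its dose / adverse-event context, producing the
#' recommendations table the dose-adjusting investigator would send out.
#'
#' @param data A data frame with columns `pid`, `date`,
#'   `current_dose_mg`, `concentration` (numeric; `NA` allowed where
#'   `below_lod` is `TRUE`), `below_lod` (logical), and `ae_related`
#'   (logical).
#' @param policy A [dose_policy()] object.
#' @return A data frame `pid, date, action, new_daily_dose_mg, rationale`.
#' @export
recommend_doses <- function(data, policy = dose_policy()) {
  need <- c("pid", "date", "current_dose_mg", "concentration",
            "below_lod", "ae_related")
  miss <- setdiff(need, names(data))
  if (length(miss))
    stop("missing columns in dose context: ", paste(miss, collapse = ", "))
  recs <- lapply(seq_len(nrow(data)), function(i)
    recommend_dose(data$current_dose_mg[i], data$concentration[i],
                   below_lod = isTRUE(data$below_lod[i]),
                   ae_related = isTRUE(data$ae_related[i]),
                   policy = policy))
  data.frame(pid = data$pid, date = data$date,
             action = vapply(recs, `[[`, "", "action"),
             new_daily_dose_mg = vapply(recs, `[[`, 0, "new_daily_dose_mg"),
             rationale = vapply(recs, `[[`, "", "rationale"),
             stringsAsFactors = FALSE)
}
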