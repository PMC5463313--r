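#' Arm-wise concentration summaries
#'
#' Median and interquartile range per arm, the descriptive summary used to
#' judge whether sham and true concentrations are distributionally similar.
#' Quartiles use linear interpolation between order statistics
#' ([stats::quantile()] type 7); results are rounded to two decimals,
#' matching laboratory report precision.
#'
#' @param values A named list of numeric concentration vectors (one per
#'   arm), or a data frame with columns `arm` and `concentration`.
#' @return A data frame with columns `arm`, `n`, `median`, `iqr_low`,
#'   `iqr_high`.
#' @export
summarise_by_arm <- function(values) {
  if (is.data.frame(values)) {
    if (!all(c("arm", "concentration") %in% names(values)))
      stop("data frame input needs columns 'arm' and 'concentration'")
    values <- split(values$concentration, values$arm)
  }
  if (!length(values) || any(!vapply(values, length, 0L)))
    stop("every arm must contribute at least one value")
  rows <- lapply(names(values), function(a) {
    x <- values[[a]]
    if (any(is.na(x))) stop("missing concentrations in arm '", a, "'")
    q <- stats::quantile(x, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
    data.frame(arm = a, n = length(x), median = round(q[2], 2),
               iqr_low = round(q[1], 2), iqr_high = round(q[3], 2),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Two-sample empirical-CDF sup distance
#'
#' The Kolmogorov--Smirnov statistic \eqn{D = \sup_t |\hat F_x(t) -
#' \hat F_y(t)|}, computed exactly over the pooled sample points. Used
#' descriptively to quantify how far the sham distribution sits from the
#' true treatment-arm distribution (a perfectly calibrated sham stream
#' differs only by truncation to the reporting window).
#'
#' @param x,y Non-empty numeric vectors.
#' @return D in \[0, 1\].
#' @export
ecdf_distance <- function(x, y) {
  if (!length(x) || !length(y)) stop("both samples must be non-empty")
  if (any(is.na(x)) || any(is.na(y))) stop("samples must not contain NA")
  pts <- sort(unique(c(x, y)))
  fx <- stats::ecdf(x)
  fy <- stats::ecdf(y)
  max(abs(fx(pts) - fy(pts)))
}

#' Dose-action contingency table
#'
#' Cross-tabulates dose recommendations by (unblinded) arm and action, with
#' marginal totals and row percentages -- the table used to check that dose
#' adjustments occur at similar rates in both arms, the trial's working
#' evidence that blinding held.
#'
#' @param recommendations Data frame with columns `pid` and `action` (from
#'   [recommend_doses()] or [run_trial()]).
#' @param allocations Named character vector pid -> arm.
#' @return An object of class `dose_action_table`: a list with `counts`
#'   (arm-by-action matrix with `Total` margins) and `row_pct` (percentage
#'   of each action taken in each arm).
#' @export
dose_action_table <- function(recommendations, allocations) {
  unknown <- setdiff(unique(recommendations$pid), names(allocations))
  if (length(unknown))
    stop("recommendation pid(s) missing from allocations: ",
         paste(unknown, collapse = ", "))
  actions <- c("increase", "decrease", "hold", "adherence_note")
  arm <- factor(unname(allocations[recommendations$pid]),
                levels = c("treatment", "placebo"))
  act <- factor(recommendations$action, levels = actions)
  counts <- table(arm = arm, action = act)
  counts <- stats::addmargins(counts, FUN = list(Total = sum), quiet = TRUE)
  col_tot <- counts["Total", ]
  row_pct <- sweep(counts, 2, ifelse(col_tot > 0, col_tot, 1), "/") * 100
  structure(list(counts = unclass(counts), row_pct = unclass(row_pct)),
            class = "dose_action_table")
}

#' @export
print.dose_action_table <- function(x, digits = 1, ...) {
  cat("Dose actions by arm (counts):\n")
  print(x$counts)
  cat("\nShare of each action by arm (%):\n")
  print(round(x$row_pct[setdiff(rownames(x$row_pct), "Total"), , drop = FALSE],
              digits))
  invisible(x)
}

#' Blinding diagnostics for a trial
#'
#' Assembles the diagnostics the unblinded role uses to assess whether the
#' sham stream preserved blinding: arm-wise median/IQR of sham (placebo) vs
#' true (treatment) concentrations, the empirical-CDF sup distance between
#' the two, the range of each, and the dose-action table. Below-LOD
#' treatment rows carry no numeric value and are excluded from the
#' distributional comparison.
#'
#' @param reblinded Re-blinded data frame (`pid`, `date`, `concentration`
#'   as character) from [reblind()] or read back from its CSV.
#' @param allocations Named character vector pid -> arm.
#' @param recommendations Optional recommendations data frame; when given,
#'   the dose-action table is included.
#' @return An object of class `blinding_assessment`: list with
#'   `arm_summary`, `ecdf_distance`, `range_sham`, `range_true`, `n_sham`,
#'   `n_true`, `n_below_lod_treatment`, and optionally `dose_actions`.
#' @export
assess_blinding <- function(reblinded, allocations, recommendations = NULL) {
  unknown <- setdiff(unique(reblinded$pid), names(allocations))
  if (length(unknown))
    stop("re-blinded pid(s) missing from allocations: ",
         paste(unknown, collapse = ", "))
  arm <- unname(allocations[reblinded$pid])
  num <- suppressWarnings(as.numeric(reblinded$concentration))
  below <- reblinded$concentration == "<LOD"
  sham <- num[arm == "placebo" & !below]
  true <- num[arm == "treatment" & !below]
  if (!length(sham) || !length(true))
    stop("need at least one numeric value in each arm")
  out <- list(
    arm_summary = summarise_by_arm(list(treatment = true, placebo = sham)),
    ecdf_distance = ecdf_distance(sham, true),
    range_sham = range(sham),
    range_true = range(true),
    n_sham = length(sham), n_true = length(true),
    n_below_lod_treatment = sum(below & arm == "treatment"))
  if (!is.null(recommendations))
    out$dose_actions <- dose_action_table(recommendations, allocations)
  class(out) <- "blinding_assessment"
  out
}

#' @export
print.blinding_assessment <- function(x, ...) {
  writeLines(format_blinding_report(x))
  invisible(x)
}

#' Format a blinding assessment as a plain-text report
#'
#' @param x A `blinding_assessment` from [assess_blinding()].
#' @return Character vector of report lines.
#' @export
format_blinding_report <- function(x) {
  s <- x$arm_summary
  line <- function(a) {
    r <- s[s$arm == a, ]
    sprintf("  %-9s n = %3d, median (IQR) %.2f (%.2f, %.2f) mmol/L",
            a, r$n, r$median, r$iqr_low, r$iqr_high)
  }
  out <- c("Blinding assessment",
           sprintf("%d sham concentrations issued against %d observed %s",
                   x$n_sham, x$n_true, "treatment-arm measurements"),
           line("placebo"), line("treatment"),
           sprintf("  sham range  [%.2f, %.2f]; true range  [%.2f, %.2f]",
                   x$range_sham[1], x$range_sham[2],
                   x$range_true[1], x$range_true[2]),
           sprintf("  treatment values below LOD: %d",
                   x$n_below_lod_treatment),
           sprintf("  ECDF sup distance (sham vs true): %.3f",
                   x$ecdf_distance))
  if (!is.null(x$dose_actions)) {
    cts <- x$dose_actions$counts
    changes <- cts[, c("increase", "decrease"), drop = FALSE]
    out <- c(out,
      sprintf("  dose-change recommendations: %d total (%d treatment, %d placebo)",
              sum(changes["Total", ]), sum(changes["treatment", ]),
              sum(changes["placebo", ])),
      sprintf("    increases %d (%d vs %d), decreases %d (%d vs %d)",
              cts["Total", "increase"], cts["treatment", "increase"],
              cts["placebo", "increase"],
              cts["Total", "decrease"], cts["treatment", "decrease"],
              cts["placebo", "decrease"]))
  }
  out
}

#' JSON summary of a blinding assessment
#'
#' @param x A `blinding_assessment`.
#' @param path Output JSON path.
#' @return The path, invisibly.
#' @export
write_assessment_json <- function(x, path) {
  stopifnot(inherits(x, "blinding_assessment"))
  obj <- list(arm_summary = x$arm_summary,
              ecdf_distance = x$ecdf_distance,
              range_sham = x$range_sham, range_true = x$range_true,
              n_sham = x$n_sham, n_true = x$n_true,
              n_below_lod_treatment = x$n_below_lod_treatment)
  if (!is.null(x$dose_actions)) {
    m <- x$dose_actions$counts
    obj$dose_actions <- lapply(rownames(m), function(r)
      as.list(stats::setNames(as.numeric(m[r, ]), colnames(m))))
    names(obj$dose_actions) <- rownames(m)
  }
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(path)
}
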