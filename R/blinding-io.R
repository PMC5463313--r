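#' Read a laboratory concentration report
#'
#' Parses the CSV the laboratory sends to the unblinded statistician:
#' columns `pid`, `date`, `value`, where `value` is a concentration in
#' mmol/L or the literal token `<LOD` for results below the assay limit of
#' detection. Malformed rows (non-numeric, negative) are collected into an
#' error report attached as attribute `"errors"` rather than silently
#' dropped; missing columns are a hard error.
#'
#' @param path Path to the lab-report CSV.
#' @return A data frame with columns `pid`, `date`, `value` (numeric, `NA`
#'   for below-LOD rows), `below_lod` (logical), and `raw` (the value field
#'   exactly as received, preserved so treatment rows can be passed through
#'   byte-identically). Attribute `"errors"` is a data frame
#'   (`line`, `pid`, `raw`, `reason`) of rejected rows.
#' @export
read_lab_report <- function(path) {
  df <- utils::read.csv(path, colClasses = "character",
                        strip.white = TRUE)
  need <- c("pid", "date", "value")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("lab report is missing required column(s): ",
         paste(miss, collapse = ", "))
  raw <- df$value
  below <- raw == "<LOD"
  num <- suppressWarnings(as.numeric(raw))
  bad <- !below & (is.na(num) | num < 0)
  errors <- data.frame(line = which(bad) + 1L, # +1 for the header line
                       pid = df$pid[bad], raw = raw[bad],
                       reason = ifelse(is.na(num[bad]),
                                       "unparseable value",
                                       "negative concentration"),
                       stringsAsFactors = FALSE)
  out <- data.frame(pid = df$pid, date = df$date, value = num,
                    below_lod = below, raw = raw,
                    stringsAsFactors = FALSE)[!bad, ]
  rownames(out) <- NULL
  structure(out, errors = errors)
}

#' Re-blind a laboratory batch
#'
#' The core unblinded-statistician step. Treatment-arm rows pass through
#' exactly as received (below-LOD rows included); each placebo row's value
#' is replaced by a sham draw. Before drawing, the sampler's running
#' estimates are refreshed with this batch's treatment-arm values and the
#' threshold policy is consulted, so sham values always reflect the
#' treatment-arm distribution up to and including the current batch. The
#' output carries no treatment-arm information and is sorted by
#' (pid, date); sham values are formatted at the laboratory's two-decimal
#' precision so true and sham values are typographically indistinguishable.
#'
#' @param rows Parsed lab rows as returned by [read_lab_report()] (columns
#'   `pid`, `date`, `value`, `below_lod`; an optional `raw` column preserves
#'   the as-received value text).
#' @param allocations Named character vector mapping pid to `"treatment"` or
#'   `"placebo"` -- the unblinded allocation list. Every pid in `rows` must
#'   be present; an unknown pid is a hard error, since guessing an arm could
#'   mis-blind.
#' @param sampler A [sham_sampler()].
#' @param policy Optional [threshold_policy()] applied after the estimate
#'   update.
#' @return A list with `reblinded` (data frame `pid`, `date`,
#'   `concentration` as character -- a number or `<LOD` -- with no arm
#'   column), `sampler` (updated), and `audit` (one row per sham
#'   substitution: timestamp, pid, date, estimates, window, drawn value).
#' @export
reblind <- function(rows, allocations, sampler, policy = NULL) {
  stopifnot(inherits(sampler, "sham_sampler"))
  unknown <- setdiff(unique(rows$pid), names(allocations))
  if (length(unknown))
    stop("pid(s) missing from the allocation list: ",
         paste(unknown, collapse = ", "),
         " -- refusing to re-blind without a known arm")
  arm <- unname(allocations[rows$pid])
  if (!all(arm %in% c("treatment", "placebo")))
    stop("allocations must be 'treatment' or 'placebo'")
  if (!"raw" %in% names(rows))
    rows$raw <- ifelse(rows$below_lod, "<LOD", sprintf("%.2f", rows$value))
  trt <- arm == "treatment"
  sampler <- update(sampler, rows$value[trt],
                    below_lod = rows$below_lod[trt])
  if (!is.null(policy)) sampler <- apply_threshold_policy(sampler, policy)
  concentration <- rows$raw
  n_pla <- sum(!trt)
  audit <- NULL
  if (n_pla > 0) {
    drawn <- draw_sham(sampler, n = n_pla)
    sampler <- drawn$sampler
    concentration[!trt] <- sprintf("%.*f", sampler$digits, drawn$values)
    audit <- data.frame(
      timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
      pid = rows$pid[!trt], date = rows$date[!trt],
      mean_hat = sampler$mean_hat, sd_hat = sampler$sd_hat,
      lower = sampler$lower, upper = sampler$upper,
      n_obs = length(sampler$values),
      value = drawn$values, stringsAsFactors = FALSE)
  }
  out <- data.frame(pid = rows$pid, date = rows$date,
                    concentration = concentration,
                    stringsAsFactors = FALSE)
  ord <- order(out$pid, out$date)
  out <- out[ord, ]
  rownames(out) <- NULL
  list(reblinded = out, sampler = sampler, audit = audit)
}

#' Write the re-blinded report and audit log
#'
#' `write_reblinded()` writes the single arm-free file passed to the
#' dose-adjusting investigator (columns exactly `pid`, `date`,
#' `concentration`). `append_audit()` appends sham-substitution audit rows
#' to a CSV, creating it with a header on first use.
#'
#' @param reblinded Re-blinded data frame from [reblind()].
#' @param audit Audit data frame from [reblind()] (may be `NULL`).
#' @param path Output CSV path.
#' @return The path, invisibly.
#' @export
write_reblinded <- function(reblinded, path) {
  stopifnot(identical(names(reblinded), c("pid", "date", "concentration")))
  utils::write.csv(reblinded, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_reblinded
#' @export
append_audit <- function(audit, path) {
  if (is.null(audit) || nrow(audit) == 0L) return(invisible(path))
  first <- !file.exists(path)
  utils::write.table(audit, path, sep = ",", row.names = FALSE,
                     col.names = first, append = !first, quote = FALSE)
  invisible(path)
}

#' Read an allocation list
#'
#' Reads the unblinded allocation CSV (`pid`, `arm`) into the named vector
#' [reblind()] expects.
#'
#' @param path Path to the allocation CSV.
#' @return Named character vector pid -> arm.
#' @export
read_allocations <- function(path) {
  df <- utils::read.csv(path, colClasses = "character", strip.white = TRUE)
  if (!all(c("pid", "arm") %in% names(df)))
    stop("allocation file must have columns 'pid' and 'arm'")
  if (anyDuplicated(df$pid)) stop("duplicate pid in allocation list")
  stats::setNames(df$arm, df$pid)
}
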