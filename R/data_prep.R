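#' Exclude observations near elevated CRP
#'
#' Removes ANC observations recorded from `window` days before until
#' `window` days after any CRP value above `threshold` (endpoints
#' inclusive), the rule used to discard measurements taken during likely
#' infections.  CRP evidence comes from the record's own observations and,
#' when present, a standalone `crp_events` data.frame (columns `time`,
#' `crp`).  Observations with unknown (NA) CRP are never treated as
#' elevated and are retained unless they fall in the window of another
#' elevated value.
#'
#' @param record a [patient_record()].
#' @param threshold CRP threshold (mg/L), default 5.
#' @param window half-width of the exclusion interval (days), default 14.
#' @return List with `record` (filtered copy) and `report` (per-patient
#'   counts: `n_total`, `n_excluded`, `n_remaining`, `n_crp_missing`).
#' @export
crp_exclusion_filter <- function(record, threshold = 5, window = 14) {
  obs <- record$observations
  crp_t <- numeric(0)
  if (!is.null(obs$crp)) {
    known <- !is.na(obs$crp)
    crp_t <- obs$time[known & obs$crp > threshold]
  }
  if (!is.null(record$crp_events)) {
    ce <- record$crp_events
    crp_t <- c(crp_t, ce$time[!is.na(ce$crp) & ce$crp > threshold])
  }
  excl <- rep(FALSE, nrow(obs))
  for (s in crp_t)
    excl <- excl | abs(obs$time - s) <= window
  out <- record
  out$observations <- obs[!excl, , drop = FALSE]
  rownames(out$observations) <- NULL
  report <- list(
    n_total = nrow(obs), n_excluded = sum(excl),
    n_remaining = nrow(obs) - sum(excl),
    n_crp_missing = if (is.null(obs$crp)) nrow(obs) else sum(is.na(obs$crp))
  )
  list(record = out, report = report)
}

#' Apply the CRP exclusion filter to a whole cohort
#'
#' @param records list of [patient_record()]s (e.g. an `anc_cohort`).
#' @inheritParams crp_exclusion_filter
#' @return List with `records` (filtered; patients left with zero
#'   observations are retained but flagged in the report) and `report`, a
#'   `filter_report` containing aggregate and per-patient counts.
#' @export
filter_cohort <- function(records, threshold = 5, window = 14) {
  res <- lapply(records, crp_exclusion_filter, threshold = threshold,
                window = window)
  per <- do.call(rbind, lapply(res, function(r)
    data.frame(id = r$record$id, n_total = r$report$n_total,
               n_excluded = r$report$n_excluded,
               n_remaining = r$report$n_remaining,
               n_crp_missing = r$report$n_crp_missing)))
  out <- lapply(res, `[[`, "record")
  attributes(out) <- attributes(records)
  report <- structure(list(
    n_total = sum(per$n_total), n_excluded = sum(per$n_excluded),
    n_remaining = sum(per$n_remaining), per_patient = per
  ), class = "filter_report")
  list(records = out, report = report)
}

#' @export
print.filter_report <- function(x, ...) {
  cat(sprintf("CRP exclusion filter: %d of %d observations excluded, %d remaining\n",
              x$n_excluded, x$n_total, x$n_remaining))
  invisible(x)
}

#' Threshold fractions of remaining ANC observations
#'
#' Fractions of observations below 0.5 G/L, below 2 G/L, and inside the
#' target range \[0.5, 2\] G/L (both ends inclusive; the categories
#' overlap, so the fractions need not sum to one).
#'
#' @param records list of [patient_record()]s (typically CRP-filtered).
#' @param low,high target-range bounds (G/L).
#' @return List with `n`, `frac_below_low`, `frac_below_high`,
#'   `frac_in_range`.
#' @export
threshold_summary <- function(records, low = 0.5, high = 2) {
  anc <- unlist(lapply(records, function(r) r$observations$anc))
  if (length(anc) == 0) stop("no observations to summarize")
  list(n = length(anc),
       frac_below_low = mean(anc < low),
       frac_below_high = mean(anc < high),
       frac_in_range = mean(anc >= low & anc <= high))
}

#' Chronological train/test split of one record
#'
#' The first `floor(train_fraction * n)` observations (at least one) form
#' the training set, the remainder the held-out set.  Dose events are never
#' split: both returned records carry the full schedule, so held-out
#' predictions can be forward-simulated.
#'
#' @param record a [patient_record()].
#' @param train_fraction fraction of observations used for estimation
#'   (default 0.7).
#' @return List with `train` and `test` (both `patient_record`s; `test`
#'   may have zero observations) and `n_train`.
#' @export
split_in_out <- function(record, train_fraction = 0.7) {
  n <- nrow(record$observations)
  if (n < 1) stop("record has no observations")
  n_train <- max(1L, floor(train_fraction * n))
  tr <- record; te <- record
  tr$observations <- record$observations[seq_len(n_train), , drop = FALSE]
  te$observations <- record$observations[setdiff(seq_len(n), seq_len(n_train)),
                                         , drop = FALSE]
  rownames(te$observations) <- NULL
  list(train = tr, test = te, n_train = n_train)
}

#' Chronological split of a whole cohort
#'
#' @param records list of [patient_record()]s.
#' @inheritParams split_in_out
#' @return List with `train` and `test` cohorts (parallel lists).
#' @export
split_cohort <- function(records, train_fraction = 0.7) {
  sp <- lapply(records, split_in_out, train_fraction = train_fraction)
  tr <- lapply(sp, `[[`, "train")
  te <- lapply(sp, `[[`, "test")
  attributes(tr) <- attributes(records)
  attributes(te) <- attributes(records)
  list(train = tr, test = te)
}
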