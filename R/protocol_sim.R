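#' Dosing protocol definition
#'
#' Either a constant daily dose per body surface area or the patient's own
#' recorded schedule (`"recorded"`).
#'
#' @param name protocol label.
#' @param dose_per_bsa constant daily dose (mg/m^2), or `NULL` for the
#'   recorded-schedule protocol.
#' @return Object of class `protocol`.
#' @export
protocol <- function(name, dose_per_bsa = NULL) {
  if (!is.null(dose_per_bsa) && dose_per_bsa < 0)
    stop("dose_per_bsa must be >= 0")
  structure(list(name = name, dose_per_bsa = dose_per_bsa),
            class = "protocol")
}

#' The comparison protocols of the dosing study
#'
#' The recorded-schedule arm plus constant daily 6MP at 25, 50, 75 and
#' 100 mg/m^2 (half, one, one-and-a-half and twice the 50 mg/m^2 reference
#' dose used by AIEOP-type regimens).
#'
#' @return Named list of [protocol()]s.
#' @export
default_protocols <- function() {
  list(FittedModels = protocol("FittedModels"),
       `25 mg/m2` = protocol("25 mg/m2", 25),
       `50 mg/m2` = protocol("50 mg/m2", 50),
       `75 mg/m2` = protocol("75 mg/m2", 75),
       `100 mg/m2` = protocol("100 mg/m2", 100))
}

#' Build the dose schedule a protocol implies for one patient
#'
#' Constant protocols dose `dose_per_bsa * bsa` mg daily over the patient's
#' recorded treatment window (first to last recorded dose day).  No tablet
#' rounding is applied by default so that dose proportionality is exact;
#' set `round_to` to emulate tablet steps.  The recorded-schedule protocol
#' returns the patient's own schedule unchanged.
#'
#' @param protocol a [protocol()].
#' @param record a [patient_record()].
#' @param round_to optional tablet rounding step (mg).
#' @return A [dose_schedule()].
#' @export
build_protocol_schedule <- function(protocol, record, round_to = NULL) {
  if (is.null(protocol$dose_per_bsa)) return(record$doses)
  if (nrow(record$doses) > 0) {
    t0 <- min(record$doses$time); t1 <- max(record$doses$time)
  } else {
    t0 <- 0; t1 <- max(record$observations$time)
  }
  days <- seq(floor(t0), floor(t1))
  amt <- rep(protocol$dose_per_bsa * record$bsa, length(days))
  if (!is.null(round_to)) amt <- round(amt / round_to) * round_to
  dose_schedule(days, amt)
}

#' Simulate a cohort under alternative dosing protocols
#'
#' For each patient and protocol, simulates from the drug-free steady state
#' under the protocol's schedule and records the ANC at the patient's own
#' observation time points, summarized as min / median / max.  Parameters
#' are either the simulation truth stored in the records or the fitted
#' empirical Bayes estimates.
#'
#' @param records list of [patient_record()]s.
#' @param params_source `"true"` (use `true_params`) or `"fitted"`
#'   (use `fit`).
#' @param protocols list of [protocol()]s, default [default_protocols()].
#' @param fit an `mtanc_fit`, required when `params_source = "fitted"`.
#' @param consts a [pk_constants()].
#' @param engine simulation engine passed to [simulate_anc()].
#' @param round_to optional tablet rounding for the constant arms.
#' @return Object of class `protocol_summary`: data.frame with `id`,
#'   `protocol`, `min`, `median`, `max` (failed patient-protocol cells are
#'   dropped and listed in attribute `failed`).
#' @export
simulate_protocols <- function(records, params_source = c("true", "fitted"),
                               protocols = default_protocols(), fit = NULL,
                               consts = pk_constants(), engine = "hybrid",
                               round_to = NULL) {
  params_source <- match.arg(params_source)
  if (params_source == "fitted" && is.null(fit))
    stop("params_source = \"fitted\" requires a fit")
  rows <- list(); failed <- list()
  for (i in seq_along(records)) {
    rec <- records[[i]]
    par_i <- if (params_source == "true") {
      if (is.null(rec$true_params)) stop("record has no true_params")
      rec$true_params
    } else {
      v <- fit$theta * exp(fit$eta[i, ])
      individual_params(v[["Base"]], v[["k_tr"]], v[["gamma"]],
                        v[["slope"]])
    }
    tt <- rec$observations$time
    times <- sort(unique(c(0, tt)))
    for (pn in names(protocols)) {
      sched <- build_protocol_schedule(protocols[[pn]], rec, round_to)
      anc <- tryCatch({
        tr <- simulate_anc(par_i, rec$bsa, sched, times, consts = consts,
                           engine = engine)
        tr[match(tt, tr[, "time"]), "x_ma"]
      }, error = function(e) NULL)
      if (is.null(anc)) {
        failed[[length(failed) + 1]] <- list(id = rec$id, protocol = pn)
        next
      }
      rows[[length(rows) + 1]] <- data.frame(
        id = rec$id, protocol = pn, min = min(anc),
        median = median(anc), max = max(anc))
    }
  }
  out <- do.call(rbind, rows)
  out$protocol <- factor(out$protocol, levels = names(protocols))
  structure(out, class = c("protocol_summary", "data.frame"),
            failed = failed,
            doses = vapply(protocols, function(p)
              p$dose_per_bsa %||% NA_real_, numeric(1)))
}

#' Boxplot-ready summary and dose-effect trend of a protocol study
#'
#' Quartiles with 1.5 IQR whiskers per protocol for each of the three
#' per-patient statistics, plus a linear regression of the cohort median of
#' patient-median ANC on the constant protocol dose.
#'
#' @param summary a `protocol_summary`.
#' @return List with `boxstats` (protocol, statistic, lower whisker, q1,
#'   median, q3, upper whisker, n_outliers), `trend` (data.frame of dose
#'   vs cohort-median ANC for the constant arms) and `trend_fit` (slope,
#'   intercept, r_squared of the linear dose-effect relation).
#' @export
protocol_report <- function(summary) {
  stats_nm <- c("min", "median", "max")
  rows <- list()
  for (pn in levels(summary$protocol)) {
    sub <- summary[summary$protocol == pn, ]
    if (nrow(sub) == 0) next
    for (st in stats_nm) {
      v <- sub[[st]]
      q <- quantile(v, c(0.25, 0.5, 0.75), names = FALSE)
      iqr <- q[3] - q[1]
      wl <- min(v[v >= q[1] - 1.5 * iqr]); wh <- max(v[v <= q[3] + 1.5 * iqr])
      rows[[length(rows) + 1]] <- data.frame(
        protocol = pn, statistic = st, whisker_lo = wl, q1 = q[1],
        median = q[2], q3 = q[3], whisker_hi = wh,
        n_outliers = sum(v < wl | v > wh))
    }
  }
  boxstats <- do.call(rbind, rows)
  doses <- attr(summary, "doses")
  const <- names(doses)[!is.na(doses)]
  trend <- data.frame(
    dose = doses[const],
    median_anc = vapply(const, function(pn)
      median(summary$median[summary$protocol == pn]), numeric(1)))
  trend_fit <- NULL
  if (nrow(trend) >= 3) {
    m <- lm(median_anc ~ dose, data = trend)
    sse <- sum(m$residuals^2)
    sst <- sum((trend$median_anc - mean(trend$median_anc))^2)
    trend_fit <- list(slope = unname(coef(m)[2]),
                      intercept = unname(coef(m)[1]),
                      r_squared = 1 - sse / sst)
  }
  list(boxstats = boxstats, trend = trend, trend_fit = trend_fit)
}

#' Boxplots of the protocol study
#'
#' @param x a `protocol_summary`.
#' @param statistic which per-patient statistic to plot.
#' @param ... passed to [boxplot()].
#' @export
plot.protocol_summary <- function(x, statistic = c("median", "min", "max"),
                                  ...) {
  statistic <- match.arg(statistic)
  boxplot(x[[statistic]] ~ x$protocol, xlab = "protocol",
          ylab = sprintf("per-patient %s ANC (G/L)", statistic), ...)
  invisible(x)
}
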