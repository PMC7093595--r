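#' Individual predictions for a set of records
#'
#' Model ANC at each record's observation times under the fitted fixed
#' effects and that patient's empirical Bayes random effects.  Records are
#' matched to the fit by position; ids are checked when available.
#'
#' @param fit an `mtanc_fit`.
#' @param records list of [patient_record()]s, parallel to the records the
#'   fit was estimated on (they may carry more observations, e.g. the full
#'   series after a fit on the training split).
#' @param model prediction model.
#' @return List of numeric prediction vectors, one per record.
#' @export
individual_predictions <- function(fit, records, model = nlme_ode_model()) {
  lapply(seq_along(records), function(i) {
    .model_predictor(model, records[[i]])(fit$theta, fit$eta[i, ])
  })
}

#' Per-patient accuracy metrics
#'
#' Mean absolute error and root mean squared error of the individual
#' (empirical Bayes) predictions per patient, summarized across the cohort
#' by median and standard deviation.  `MAE <= RMSE` always.
#'
#' @param records list of [patient_record()]s (full series).
#' @param fit an `mtanc_fit` on these patients (possibly on their training
#'   split only).
#' @param scope which observations to score: `"all"`, `"in-sample"` (first
#'   `train_fraction` of each series) or `"out-of-sample"` (the rest).
#' @param train_fraction split fraction defining the scopes.
#' @param model prediction model.
#' @return Object of class `accuracy_report`: data.frame `per_patient`
#'   (id, n, mae, rmse), plus `mae_median`, `mae_sd`, `rmse_median`,
#'   `rmse_sd`, `scope` and the ids of patients skipped for having no
#'   scored observations.
#' @export
accuracy_metrics <- function(records, fit,
                             scope = c("all", "in-sample", "out-of-sample"),
                             train_fraction = 0.7,
                             model = nlme_ode_model()) {
  scope <- match.arg(scope)
  preds <- individual_predictions(fit, records, model)
  rows <- list(); skipped <- character(0)
  for (i in seq_along(records)) {
    rec <- records[[i]]
    n <- nrow(rec$observations)
    idx <- switch(scope,
      "all" = seq_len(n),
      "in-sample" = seq_len(max(1L, floor(train_fraction * n))),
      "out-of-sample" = setdiff(seq_len(n),
                                seq_len(max(1L, floor(train_fraction * n)))))
    if (length(idx) == 0) { skipped <- c(skipped, as.character(rec$id)); next }
    r <- rec$observations$anc[idx] - preds[[i]][idx]
    rows[[length(rows) + 1]] <- data.frame(
      id = rec$id, n = length(idx),
      mae = mean(abs(r)), rmse = sqrt(mean(r^2)))
  }
  if (length(rows) == 0) stop("no observations in the requested scope")
  per <- do.call(rbind, rows)
  structure(list(per_patient = per,
                 mae_median = median(per$mae), mae_sd = sd(per$mae),
                 rmse_median = median(per$rmse), rmse_sd = sd(per$rmse),
                 scope = scope, skipped = skipped),
            class = "accuracy_report")
}

#' @export
print.accuracy_report <- function(x, ...) {
  cat(sprintf("Accuracy (%s, %d patients): median MAE %.3f (SD %.3f), median RMSE %.3f (SD %.3f) G/L\n",
              x$scope, nrow(x$per_patient), x$mae_median, x$mae_sd,
              x$rmse_median, x$rmse_sd))
  invisible(x)
}

#' Held-out predictions after a fit on the training split
#'
#' Forward-simulates each patient over the full horizon with the random
#' effects conditioned on the training observations only, and returns the
#' predictions for the held-out (final) part of each series.  No held-out
#' information enters the predictions.
#'
#' @param records full-series [patient_record()]s.
#' @param fit_on_train `mtanc_fit` estimated on the training split of
#'   these records.
#' @param train_fraction the split fraction used for that fit.
#' @param model prediction model.
#' @return data.frame with `id`, `time`, `observed`, `predicted`.
#' @export
predict_held_out <- function(records, fit_on_train, train_fraction = 0.7,
                             model = nlme_ode_model()) {
  preds <- individual_predictions(fit_on_train, records, model)
  out <- lapply(seq_along(records), function(i) {
    rec <- records[[i]]
    n <- nrow(rec$observations)
    idx <- setdiff(seq_len(n), seq_len(max(1L, floor(train_fraction * n))))
    if (length(idx) == 0) return(NULL)
    data.frame(id = rec$id, time = rec$observations$time[idx],
               observed = rec$observations$anc[idx],
               predicted = preds[[i]][idx])
  })
  do.call(rbind, out)
}

#' Visual predictive check
#'
#' Simulates `n_sim` replicate cohorts from the fitted population model on
#' every patient's own design (doses, observation times, BSA), then
#' compares observed percentiles per time bin with the distribution of the
#' same percentiles across simulated replicates.
#'
#' Bins are observation-time quantile bins; the bin count defaults to
#' `max(8, round(sqrt(number of distinct observation times)))`.
#'
#' @param records list of [patient_record()]s.
#' @param fit an `mtanc_fit` (or any list with `theta`, `omega2`,
#'   `sigma2`).
#' @param n_sim number of replicate cohorts (default 1000; below 100 a
#'   warning is issued because the band confidence intervals become
#'   unreliable).
#' @param percentiles percentiles tracked per bin.
#' @param n_bins number of time bins (NULL for the default rule).
#' @param seed optional seed for the replicate simulations.
#' @param model prediction model.
#' @param error residual error model.
#' @return Object of class `vpc_result`: `bins` (data.frame with bin
#'   mid/lo/hi, n, observed percentiles, simulated band median and 95 pct
#'   CI for each percentile), `coverage` (fraction of observations inside
#'   the outer simulated percentile band), `n_sim`.
#' @export
vpc <- function(records, fit, n_sim = 1000,
                percentiles = c(2.5, 50, 97.5), n_bins = NULL,
                seed = NULL, model = nlme_ode_model(),
                error = c("proportional", "additive")) {
  error <- match.arg(error)
  if (n_sim < 100)
    warning("n_sim < 100: confidence intervals of the bands are unreliable")
  if (!is.null(seed)) set.seed(seed)
  theta <- fit$theta; omega2 <- fit$omega2; sigma2 <- fit$sigma2

  obs_t <- unlist(lapply(records, function(r) r$observations$time))
  obs_y <- unlist(lapply(records, function(r) r$observations$anc))
  if (is.null(n_bins))
    n_bins <- max(8, round(sqrt(length(unique(obs_t)))))
  edges <- unique(quantile(obs_t, probs = seq(0, 1, length.out = n_bins + 1),
                           names = FALSE))
  bin <- findInterval(obs_t, edges, rightmost.closed = TRUE,
                      all.inside = TRUE)
  n_bins <- length(edges) - 1

  pr <- percentiles / 100
  obs_pct <- t(vapply(seq_len(n_bins), function(b)
    quantile(obs_y[bin == b], probs = pr, names = FALSE),
    numeric(length(pr))))

  predictors <- lapply(records, function(r) .model_predictor(model, r))
  n_per <- vapply(records, function(r) nrow(r$observations), integer(1))
  sim_pct <- array(NA_real_, c(n_sim, n_bins, length(pr)))
  p <- length(theta)
  for (s in seq_len(n_sim)) {
    ysim <- vector("list", length(records))
    for (i in seq_along(records)) {
      eta <- rnorm(p, 0, sqrt(omega2))
      f <- predictors[[i]](theta, eta)
      if (is.null(f)) f <- rep(NA_real_, n_per[i])
      eps <- rnorm(n_per[i], 0, sqrt(sigma2))
      y <- if (error == "proportional") f * (1 + eps) else f + eps
      ysim[[i]] <- pmax(y, 0)
    }
    ys <- unlist(ysim)
    for (b in seq_len(n_bins))
      sim_pct[s, b, ] <- quantile(ys[bin == b], probs = pr, names = FALSE,
                                  na.rm = TRUE)
  }
  band <- lapply(seq_along(pr), function(k) {
    t(vapply(seq_len(n_bins), function(b)
      quantile(sim_pct[, b, k], probs = c(0.025, 0.5, 0.975),
               names = FALSE), numeric(3)))
  })
  bins <- data.frame(
    bin = seq_len(n_bins),
    t_lo = edges[-length(edges)], t_hi = edges[-1],
    t_mid = (edges[-1] + edges[-length(edges)]) / 2,
    n = as.integer(tabulate(bin, n_bins)))
  for (k in seq_along(pr)) {
    nm <- sprintf("p%g", percentiles[k])
    bins[[paste0("obs_", nm)]] <- obs_pct[, k]
    bins[[paste0("sim_", nm)]] <- band[[k]][, 2]
    bins[[paste0("sim_", nm, "_lo")]] <- band[[k]][, 1]
    bins[[paste0("sim_", nm, "_hi")]] <- band[[k]][, 3]
  }
  lo_nm <- sprintf("sim_p%g", min(percentiles))
  hi_nm <- sprintf("sim_p%g", max(percentiles))
  inside <- obs_y >= bins[[lo_nm]][bin] & obs_y <= bins[[hi_nm]][bin]
  structure(list(bins = bins, coverage = mean(inside),
                 percentiles = percentiles, n_sim = n_sim),
            class = "vpc_result")
}

#' @export
print.vpc_result <- function(x, ...) {
  cat(sprintf("VPC: %d simulations, %d bins; %.1f%% of observations inside the %g-%g percentile band\n",
              x$n_sim, nrow(x$bins), 100 * x$coverage,
              min(x$percentiles), max(x$percentiles)))
  invisible(x)
}

#' Plot a visual predictive check
#'
#' Observed percentiles (lines with points) against the simulated
#' percentile bands (shaded).
#'
#' @param x a `vpc_result`.
#' @param ... passed to [plot()].
#' @export
plot.vpc_result <- function(x, ...) {
  b <- x$bins
  pcts <- x$percentiles
  ylim <- range(0, unlist(b[grep("^(obs|sim)_", names(b))]), na.rm = TRUE)
  plot(NA, xlim = range(b$t_lo, b$t_hi), ylim = ylim,
       xlab = "time (days)", ylab = "ANC (G/L)", ...)
  for (p in pcts) {
    nm <- sprintf("p%g", p)
    polygon(c(b$t_mid, rev(b$t_mid)),
            c(b[[paste0("sim_", nm, "_lo")]],
              rev(b[[paste0("sim_", nm, "_hi")]])),
            col = grDevices::adjustcolor("steelblue", 0.3), border = NA)
    lines(b$t_mid, b[[paste0("sim_", nm)]], col = "steelblue")
    lines(b$t_mid, b[[paste0("obs_", nm)]], col = "black", lty = 2)
    points(b$t_mid, b[[paste0("obs_", nm)]], pch = 16, cex = 0.6)
  }
  invisible(x)
}
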