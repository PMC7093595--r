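#' Log-normal IIV variance expressed as a coefficient of variation
#'
#' `CV% = 100 * sqrt(exp(omega2) - 1)` for a log-normally distributed
#' parameter with log-scale variance `omega2`.
#'
#' @param omega2 variance(s) on the log scale, >= 0.
#' @return CV in percent, vectorized.
#' @examples
#' iiv_as_cv(log(2))   # 100
#' @export
iiv_as_cv <- function(omega2) {
  if (any(omega2 < 0)) stop("omega2 must be non-negative")
  100 * sqrt(exp(omega2) - 1)
}

#' ODE-based prediction model for the mixed-effects machinery
#'
#' Wraps the PK/PD simulator as a prediction model: individual parameters
#' are `theta * exp(eta)` and the prediction is the model ANC at the
#' record's observation times (fast hybrid engine).
#'
#' @param consts a [pk_constants()].
#' @param h_rk4 maximum integrator step (days) of the fixed-step PD solver.
#' @return A model object (list with `predict` and `make_predictor`) usable
#'   by [foce_objective()] and [fit_population()].
#' @export
nlme_ode_model <- function(consts = pk_constants(), h_rk4 = 0.1) {
  make_predictor <- function(record) {
    base <- .make_anc_predictor(record$observations$time,
                                record$doses$time, record$doses$amount,
                                record$bsa, consts, h_rk4)
    sens <- attr(base, "sens")
    out <- function(theta, eta) base(theta * exp(eta))
    # analytic eta-Jacobian via forward sensitivities and the chain rule
    # d f / d eta_k = (d f / d p_k) * p_k  for  p = theta * exp(eta)
    attr(out, "jac") <- function(theta, eta) {
      p <- theta * exp(eta)
      r <- sens(p)
      if (is.null(r)) return(NULL)
      list(f = r$f, J = sweep(r$J, 2, p, "*"))
    }
    out
  }
  list(name = "anc_ode", param_names = c("Base", "k_tr", "gamma", "slope"),
       make_predictor = make_predictor,
       predict = function(record, theta, eta) make_predictor(record)(theta, eta))
}

.model_predictor <- function(model, record) {
  if (!is.null(model$make_predictor)) model$make_predictor(record)
  else function(theta, eta) model$predict(record, theta, eta)
}

# -2 log joint density terms for one patient given predictions f
# (residual part only; caller adds the eta prior)
.resid_neg2ll <- function(y, f, sigma2, error) {
  if (is.null(f) || any(!is.finite(f))) return(Inf)
  if (error == "proportional") {
    if (any(f <= 1e-10)) return(Inf)
    g <- sigma2 * f^2
  } else g <- rep(sigma2, length(f))
  sum((y - f)^2 / g + log(g))
}

#' Inner (MAP) objective for one patient
#'
#' The conditional -2 log joint density of the data and the random effects,
#' up to an additive constant: residual terms
#' `sum((y - f)^2 / g + log g)` with `g = sigma2 * f^2` (proportional
#' error) or `g = sigma2` (additive), plus the prior terms
#' `eta' Omega^-1 eta + log det Omega`.  Its minimizer over `eta` is the
#' empirical Bayes estimate.
#'
#' @param record a [patient_record()].
#' @param theta fixed-effect vector.
#' @param omega2 diagonal IIV variances (entries equal to 0 fix the
#'   corresponding random effect at zero and drop its prior term).
#' @param sigma2 residual variance.
#' @param eta random-effect vector (same length as `theta`).
#' @param model prediction model, default [nlme_ode_model()].
#' @param error `"proportional"` or `"additive"` residual model.
#' @return Scalar objective value (`Inf` if the trajectory fails).
#' @export
individual_map_objective <- function(record, theta, omega2, sigma2, eta,
                                     model = nlme_ode_model(),
                                     error = c("proportional", "additive")) {
  error <- match.arg(error)
  free <- which(omega2 > 0)
  if (any(eta[setdiff(seq_along(eta), free)] != 0))
    stop("eta must be 0 where omega2 is 0")
  f <- .model_predictor(model, record)(theta, eta)
  .resid_neg2ll(record$observations$anc, f, sigma2, error) +
    (if (length(free) > 0)
       sum(eta[free]^2 / omega2[free]) + sum(log(omega2[free])) else 0)
}

# Damped Gauss-Newton solver for the inner MAP problem.
# pfun(eta_full) -> f; returns eta (full length), f, J (n x k over free
# dims), obj, converged.  Gradient and curvature use the analytic
# derivative of the objective in f with a forward-difference Jacobian.
.inner_solve <- function(pfun, y, omega2, sigma2, eta0, error,
                         free = which(omega2 > 0),
                         gtol = 1e-6, maxit = 40, h = 1e-4, jfun = NULL) {
  p <- length(omega2)
  k <- length(free)
  eta <- eta0
  obj_of <- function(e) {
    f <- pfun(e)
    list(f = f, obj = .resid_neg2ll(y, f, sigma2, error) +
           (if (k > 0) sum(e[free]^2 / omega2[free]) else 0))
  }
  cur <- obj_of(eta)
  if (any(eta != 0)) {                  # dual start: warm vs prior mode
    cur0 <- obj_of(numeric(p))
    if (!is.finite(cur$obj) ||
        (is.finite(cur0$obj) && cur0$obj < cur$obj)) {
      eta <- numeric(p)
      cur <- cur0
    }
  }
  if (!is.finite(cur$obj))
    return(list(eta = eta, f = cur$f, J = NULL, obj = Inf,
                converged = FALSE))
  if (k == 0)
    return(list(eta = eta, f = cur$f, J = matrix(0, length(y), 0),
                obj = cur$obj + 0, converged = TRUE))

  Oinv <- 1 / omega2[free]
  lambda <- 1e-4
  converged <- FALSE
  J <- matrix(0, length(y), k)
  jac_eta <- NULL                       # eta at which J was computed
  get_jac <- function(e, f) {
    if (!is.null(jfun)) {
      r <- jfun(e)
      if (!is.null(r)) return(r$J[, free, drop = FALSE])
    }
    Jm <- matrix(0, length(y), k)       # forward-difference fallback
    for (j in seq_len(k)) {
      ej <- e; ej[free[j]] <- ej[free[j]] + h
      fj <- pfun(ej)
      if (is.null(fj)) fj <- f          # one-sided failure: zero column
      Jm[, j] <- (fj - f) / h
    }
    Jm
  }
  for (it in seq_len(maxit)) {
    f <- cur$f
    J <- get_jac(eta, f)
    jac_eta <- eta
    if (error == "proportional") {
      g <- sigma2 * f^2
      w <- -2 * (y - f) / g - 2 * (y - f)^2 / (sigma2 * f^3) + 2 / f
    } else {
      g <- rep(sigma2, length(f))
      w <- -2 * (y - f) / g
    }
    grad <- drop(crossprod(J, w)) + 2 * Oinv * eta[free]
    if (any(!is.finite(grad))) break    # keep the best iterate
    if (max(abs(grad)) < gtol) { converged <- TRUE; break }
    H <- 2 * crossprod(J, J / g) + diag(2 * Oinv, k)
    # Newton step already negligible: declare convergence without a
    # line-search evaluation
    full <- tryCatch(solve(H, -grad), error = function(e) NULL)
    if (!is.null(full) && all(is.finite(full)) &&
        max(abs(full)) < 1e-6) { converged <- TRUE; break }
    accepted <- FALSE
    for (ls in 1:12) {
      step <- tryCatch(solve(H + diag(lambda * max(diag(H)), k), -grad),
                       error = function(e) NULL)
      if (!is.null(step)) {
        cand <- eta
        cand[free] <- cand[free] + step
        new <- obj_of(cand)
        if (is.finite(new$obj) && new$obj < cur$obj) {
          improvement <- cur$obj - new$obj
          eta <- cand; cur <- new
          lambda <- max(lambda / 3, 1e-8)
          accepted <- TRUE
          # stop when further refinement cannot matter: either the
          # objective is flat, or a slow large-residual crawl has set in
          if (improvement < 1e-6 * (1 + abs(new$obj)) ||
              (it >= 8 && improvement < 1e-4)) converged <- TRUE
          break
        }
      }
      lambda <- lambda * 10
    }
    if (!accepted || converged) break   # stalled or objective flat
  }
  # refresh the Jacobian at the final eta unless already current
  f <- cur$f
  if (is.null(jac_eta) || any(jac_eta != eta)) J <- get_jac(eta, f)
  list(eta = eta, f = f, J = J, obj = cur$obj, converged = converged)
}

# FOCE-I marginal contribution of one patient, linearized about eta*:
#   r = y - f(eta*) + J eta*,   V = J Omega J' + diag(g(eta*))
#   -2 ll_i = n log(2 pi) + log det V + r' V^-1 r
# The eta-epsilon interaction enters through g evaluated at eta* rather
# than at zero.
.foce_contrib <- function(y, f, J, eta_free, omega2_free, sigma2, error) {
  n <- length(y)
  g <- if (error == "proportional") sigma2 * f^2 else rep(sigma2, n)
  r <- y - f
  if (length(eta_free) > 0) {
    r <- r + drop(J %*% eta_free)
    V <- J %*% (omega2_free * t(J))
    diag(V) <- diag(V) + g
  } else V <- diag(g, n)
  ch <- tryCatch(chol(V), error = function(e) NULL)
  if (is.null(ch)) return(Inf)
  z <- backsolve(ch, r, transpose = TRUE)
  n * log(2 * pi) + 2 * sum(log(diag(ch))) + sum(z^2)
}

#' FOCE objective with eta-epsilon interaction
#'
#' The approximate marginal -2 log-likelihood summed over patients: for
#' each patient the inner MAP problem is solved for the empirical Bayes
#' `eta*`, the model is linearized about `eta*`, and the Gaussian marginal
#' of the linearized model — with the residual variance evaluated at
#' `eta*` (the interaction) — is evaluated exactly.  On models that are
#' linear in `eta` with additive error this equals the exact marginal
#' -2 log-likelihood.
#'
#' @inheritParams individual_map_objective
#' @param records list of [patient_record()]s.
#' @param eta_start optional warm-start matrix (patients x parameters).
#' @param inner_control list with `gtol`, `maxit` for the inner solver.
#' @return Scalar objective; attributes `etas` (empirical Bayes estimates),
#'   `preds` (per-patient individual predictions at `eta*`) and
#'   `converged` (per-patient inner convergence flags).
#' @export
foce_objective <- function(records, theta, omega2, sigma2,
                           model = nlme_ode_model(),
                           error = c("proportional", "additive"),
                           eta_start = NULL,
                           inner_control = list()) {
  error <- match.arg(error)
  gtol <- inner_control$gtol %||% 1e-6
  maxit <- inner_control$maxit %||% 40
  p <- length(theta)
  free <- which(omega2 > 0)
  n_rec <- length(records)
  etas <- matrix(0, n_rec, p)
  preds <- vector("list", n_rec)
  conv <- logical(n_rec)
  total <- 0
  # Without a warm start the inner problems can have several local modes
  # (strong drug effects make trajectories nearly bimodal), so cold solves
  # are seeded from the best of a fixed one-at-a-time design around zero.
  cold_start <- function(pfun, y, i) {
    cand <- matrix(0, 1 + 2 * length(free), p)
    a <- 0.75 * sqrt(omega2[free])
    for (j in seq_along(free)) {
      cand[2 * j, free[j]] <- a[j]
      cand[2 * j + 1, free[j]] <- -a[j]
    }
    vals <- apply(cand, 1, function(e)
      .resid_neg2ll(y, pfun(e), sigma2, error) +
        (if (length(free) > 0) sum(e[free]^2 / omega2[free]) else 0))
    cand[which.min(vals), ]
  }
  for (i in seq_len(n_rec)) {
    rec <- records[[i]]
    pf0 <- .model_predictor(model, rec)
    pfun <- function(e) pf0(theta, e)
    jac <- attr(pf0, "jac")
    jfun <- if (is.null(jac)) NULL else function(e) jac(theta, e)
    e0 <- if (!is.null(eta_start)) eta_start[i, ]
          else cold_start(pfun, rec$observations$anc, i)
    sol <- .inner_solve(pfun, rec$observations$anc, omega2, sigma2,
                        eta0 = e0, error = error, free = free,
                        gtol = gtol, maxit = maxit, jfun = jfun)
    if (!is.finite(sol$obj)) {
      total <- Inf
      conv[i] <- FALSE
      next
    }
    etas[i, ] <- sol$eta
    preds[[i]] <- sol$f
    conv[i] <- sol$converged
    total <- total + .foce_contrib(rec$observations$anc, sol$f, sol$J,
                                   sol$eta[free], omega2[free], sigma2,
                                   error)
  }
  structure(total, etas = etas, preds = preds, converged = conv)
}

#' Fit the population model by FOCE-I
#'
#' Minimizes [foce_objective()] over log-transformed fixed effects, IIV
#' variances and residual variance with a quasi-Newton outer optimizer and
#' warm-started inner problems.  Deterministic given data, initial values
#' and options.
#'
#' @param records list of [patient_record()]s (>= 2, each >= 1 observation).
#' @param init a [population_model()] holding initial values.
#' @param model prediction model, default [nlme_ode_model()].
#' @param error residual error model.
#' @param fix named list of parameters to hold fixed: optional elements
#'   `theta` (named vector), `omega2` (named vector; a 0 entry removes that
#'   random effect), `sigma2` (scalar).
#' @param control list: `outer_maxit` (default 100) iterations of the
#'   forward-difference quasi-Newton phase, `polish_maxit` (20) extra
#'   iterations with central differences to remove the O(h) gradient bias,
#'   `reltol` (1e-8), `ndeps` (finite-difference step on the log scale,
#'   1e-3), `inner_gtol` (1e-6), `inner_maxit` (40), `trace` (FALSE).
#' @return Object of class `mtanc_fit`: estimates (`theta`, `omega2`,
#'   `sigma2`), empirical Bayes `eta` matrix, per-patient `predictions`,
#'   final `objective`, accepted-objective `trace`, convergence info.
#' @export
fit_population <- function(records, init = population_model(),
                           model = nlme_ode_model(),
                           error = c("proportional", "additive"),
                           fix = list(), control = list()) {
  error <- match.arg(error)
  if (length(records) < 2) stop("need at least 2 patients")
  ctl <- list(outer_maxit = 100, polish_maxit = 20, reltol = 1e-8,
              ndeps = 1e-3, inner_gtol = 1e-6, inner_maxit = 40,
              trace = FALSE)
  ctl[names(control)] <- control

  pn <- names(init$theta)
  theta0 <- init$theta; omega20 <- init$omega2; sigma20 <- init$sigma2
  if (!is.null(fix$theta)) theta0[names(fix$theta)] <- fix$theta
  if (!is.null(fix$omega2)) omega20[names(fix$omega2)] <- fix$omega2
  if (!is.null(fix$sigma2)) sigma20 <- fix$sigma2

  free_th <- setdiff(pn, names(fix$theta))
  free_om <- setdiff(pn[omega20 > 0], names(fix$omega2))
  free_sg <- is.null(fix$sigma2)
  par0 <- c(log(theta0[free_th]),
            setNames(log(omega20[free_om]), paste0("om_", free_om, recycle0 = TRUE)),
            if (free_sg) c(sg = log(sigma20)))
  if (length(par0) == 0) stop("no free parameters")

  env <- new.env()
  env$etas <- NULL
  env$trace <- numeric(0)
  env$best <- Inf
  env$neval <- 0L

  unpack <- function(par) {
    th <- theta0; om <- omega20; sg <- sigma20
    th[free_th] <- exp(par[seq_along(free_th)])
    if (length(free_om) > 0)
      om[free_om] <- exp(par[length(free_th) + seq_along(free_om)])
    if (free_sg) sg <- exp(par[length(par)])
    list(theta = th, omega2 = om, sigma2 = sg)
  }
  fn <- function(par, update_cache = TRUE) {
    if (any(!is.finite(par)) || any(abs(par) > 50)) return(Inf)
    pp <- unpack(par)
    val <- foce_objective(records, pp$theta, pp$omega2, pp$sigma2,
                          model = model, error = error,
                          eta_start = env$etas,
                          inner_control = list(gtol = ctl$inner_gtol,
                                               maxit = ctl$inner_maxit))
    env$neval <- env$neval + 1L
    # warm-start cache: keep the empirical Bayes etas only from near-best
    # evaluations, so wild line-search probes cannot poison later solves
    if (update_cache && is.finite(val) &&
        val < env$best + max(10, 0.01 * abs(env$best)))
      env$etas <- attr(val, "etas")
    if (is.finite(val) && val < env$best) {
      env$best <- val
      env$trace <- c(env$trace, as.numeric(val))
      if (ctl$trace)
        message(sprintf("eval %d  obj %.4f", env$neval, val))
    }
    env$last_par <- par
    env$last_val <- as.numeric(val)
    as.numeric(val)
  }
  # finite-difference gradients; the warm-start cache is frozen across the
  # perturbed evaluations so all components share one expansion state.
  # Forward differences drive the main descent; a central-difference
  # polishing phase removes the O(h) bias that otherwise limits terminal
  # precision along strongly correlated parameter directions.
  gr_fwd <- function(par) {
    f0 <- if (!is.null(env$last_par) && isTRUE(all.equal(par, env$last_par)))
      env$last_val else fn(par)
    g <- numeric(length(par))
    for (k in seq_along(par)) {
      pk <- par; pk[k] <- pk[k] + ctl$ndeps
      fk <- fn(pk, update_cache = FALSE)
      g[k] <- if (is.finite(fk) && is.finite(f0)) (fk - f0) / ctl$ndeps
              else 0
    }
    env$last_par <- par
    env$last_val <- f0
    g
  }
  gr_ctr <- function(par) {
    g <- numeric(length(par))
    for (k in seq_along(par)) {
      pk1 <- par; pk1[k] <- pk1[k] + ctl$ndeps
      pk2 <- par; pk2[k] <- pk2[k] - ctl$ndeps
      f1 <- fn(pk1, update_cache = FALSE)
      f2 <- fn(pk2, update_cache = FALSE)
      g[k] <- if (is.finite(f1) && is.finite(f2))
        (f1 - f2) / (2 * ctl$ndeps) else 0
    }
    g
  }

  opt <- optim(par0, fn, gr_fwd, method = "BFGS",
               control = list(maxit = ctl$outer_maxit,
                              reltol = ctl$reltol))
  if (ctl$polish_maxit > 0)
    opt <- optim(opt$par, fn, gr_ctr, method = "BFGS",
                 control = list(maxit = ctl$polish_maxit,
                                reltol = ctl$reltol))
  pp <- unpack(opt$par)
  final <- foce_objective(records, pp$theta, pp$omega2, pp$sigma2,
                          model = model, error = error,
                          eta_start = env$etas,
                          inner_control = list(gtol = ctl$inner_gtol,
                                               maxit = ctl$inner_maxit))
  etas <- attr(final, "etas")
  colnames(etas) <- pn
  structure(list(
    theta = pp$theta, omega2 = pp$omega2, sigma2 = pp$sigma2,
    eta = etas, predictions = attr(final, "preds"),
    objective = as.numeric(final), trace = env$trace,
    convergence = opt$convergence, message = opt$message,
    n_eval = env$neval, counts = opt$counts,
    inner_converged = attr(final, "converged"),
    par = opt$par, free = list(theta = free_th, omega2 = free_om,
                               sigma2 = free_sg),
    init = init, fix = fix, error = error, control = ctl,
    ids = vapply(records, function(r) as.character(r$id), character(1))
  ), class = "mtanc_fit")
}

#' @export
print.mtanc_fit <- function(x, ...) {
  cat("FOCE-I population fit\n")
  cat(sprintf("  objective: %.3f  (outer convergence code %d, %d evaluations)\n",
              x$objective, x$convergence, x$n_eval))
  est <- rbind(`fixed effect` = x$theta,
               `IIV CV%` = iiv_as_cv(x$omega2))
  print(round(est, 4))
  cat(sprintf("  residual variance sigma2 = %.4f%s\n", x$sigma2,
              if (!x$free$sigma2) " (fixed)" else ""))
  invisible(x)
}

#' Relative standard errors of a converged fit
#'
#' Central finite-difference Hessian of the FOCE objective at the optimum
#' on the (log) estimation scale; covariance `2 * H^-1`; delta-method
#' back-transform.  For a log-transformed parameter the relative standard
#' error of the natural-scale estimate equals the standard error of its
#' logarithm.
#'
#' @param fit an `mtanc_fit`.
#' @param records the records the fit was estimated on.
#' @param model,error as used for the fit.
#' @param h finite-difference step on the log scale.
#' @return data.frame with `parameter`, `estimate`, `rse_pct`; if the
#'   Hessian is not positive definite, `rse_pct` is NA and the eigenvalues
#'   are attached as attribute `eigenvalues`.
#' @export
standard_errors <- function(fit, records, model = nlme_ode_model(),
                            error = fit$error, h = 1e-3) {
  par <- fit$par
  p <- length(par)
  env_etas <- fit$eta
  fn <- function(pr) {
    th <- fit$theta; om <- fit$omega2; sg <- fit$sigma2
    th[fit$free$theta] <- exp(pr[seq_along(fit$free$theta)])
    if (length(fit$free$omega2) > 0)
      om[fit$free$omega2] <-
        exp(pr[length(fit$free$theta) + seq_along(fit$free$omega2)])
    if (fit$free$sigma2) sg <- exp(pr[p])
    as.numeric(foce_objective(records, th, om, sg, model = model,
                              error = error, eta_start = env_etas))
  }
  H <- matrix(NA_real_, p, p)
  f0 <- fn(par)
  for (i in seq_len(p)) {
    for (j in i:p) {
      if (i == j) {
        ei <- rep(0, p); ei[i] <- h
        H[i, i] <- (fn(par + ei) - 2 * f0 + fn(par - ei)) / h^2
      } else {
        ei <- rep(0, p); ei[i] <- h
        ej <- rep(0, p); ej[j] <- h
        H[i, j] <- H[j, i] <-
          (fn(par + ei + ej) - fn(par + ei - ej) -
           fn(par - ei + ej) + fn(par - ei - ej)) / (4 * h^2)
      }
    }
  }
  ev <- eigen(H, symmetric = TRUE, only.values = TRUE)$values
  est <- c(fit$theta[fit$free$theta],
           setNames(fit$omega2[fit$free$omega2],
                    paste0("omega2_", fit$free$omega2, recycle0 = TRUE)),
           if (fit$free$sigma2) c(sigma2 = fit$sigma2))
  out <- data.frame(parameter = names(par), estimate = unname(est),
                    rse_pct = NA_real_)
  if (all(ev > 0)) {
    covm <- 2 * solve(H)
    out$rse_pct <- 100 * sqrt(diag(covm))
  } else attr(out, "eigenvalues") <- ev
  out
}
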