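# Fast simulation path: closed-form linear PK + compiled 5-state PD ODE.
# The PK cascade is linear in the dose history, so gut, central and 6-TGN
# levels are exact sums of exponentials; only the nonlinear maturation chain
# is integrated numerically (single lsoda call, no dose events).

# Evaluate the three PK states analytically at sorted times `t`.
# `tb`, `b`: gut bolus times/amounts (already scaled by F);
# `g0`, `c0`, `tgn0`: gut/central/6-TGN levels at `t0`.
# At an output time equal to a dose time the pre-dose state is reported,
# matching the event handling of the ODE engines.
.analytic_pk <- function(t, tb, b, g0, c0, tgn0, t0, consts, cl) {
  ka <- consts$k_a; k20 <- consts$k_20; a3 <- consts$FM3 * consts$k_me
  d0 <- t - t0
  gut <- g0 * exp(-ka * d0)
  cen <- c0 * exp(-k20 * d0) +
    g0 * ka * (exp(-ka * d0) - exp(-k20 * d0)) / (k20 - ka)
  tgn <- tgn0 * exp(-cl * d0) +
    (if (c0 != 0) c0 * a3 * (exp(-k20 * d0) - exp(-cl * d0)) / (cl - k20)
     else 0) +
    g0 * a3 * ka * (exp(-ka * d0) / ((k20 - ka) * (cl - ka)) +
                    exp(-k20 * d0) / ((ka - k20) * (cl - k20)) +
                    exp(-cl * d0) / ((ka - cl) * (k20 - cl)))
  if (length(tb) > 0) {
    dmat <- outer(t, tb, "-")           # n_t x n_d lags
    on <- dmat > 0
    dmat[!on] <- 0
    eka  <- exp(-ka  * dmat) * on
    ek20 <- exp(-k20 * dmat) * on
    ecl  <- exp(-cl  * dmat) * on
    gut <- gut + drop(eka %*% b)
    cen <- cen + drop((eka - ek20) %*% b) * ka / (k20 - ka)
    tgn <- tgn + a3 * ka * drop(
      (eka / ((k20 - ka) * (cl - ka)) +
       ek20 / ((ka - k20) * (cl - k20)) +
       ecl / ((ka - cl) * (k20 - cl))) %*% b)
  }
  cbind(x_6mpgut = gut, x_6mp = cen, x_6tgn = pmax(tgn, 0))
}

# Hybrid engine body used by simulate_anc(); same contract as the compiled
# full-system path.  Requires distinct rates k_a, k_20, CL (true for the
# published constants over any plausible BSA).
.simulate_hybrid <- function(params, bsa, doses, times, consts, x0,
                             rtol, atol, h_rk4 = 0.1) {
  cl <- clearance_6tgn(bsa, consts)
  stopifnot(abs(consts$k_a - consts$k_20) > 1e-8,
            abs(consts$k_a - cl) > 1e-8, abs(consts$k_20 - cl) > 1e-8)
  t0 <- times[1]; tf <- times[length(times)]
  tb <- numeric(0); b <- numeric(0)
  if (!is.null(doses) && nrow(doses) > 0) {
    d <- doses[doses$amount > 0 & doses$time <= tf, , drop = FALSE]
    if (nrow(d) > 0 && any(d$time < t0))
      stop("dose events before the first output time are not representable")
    if (nrow(d) > 0) {
      amt <- tapply(d$amount, d$time, sum)
      tb <- as.numeric(names(amt))
      b <- consts$F * unname(amt)
      # a dose at the start time is folded into the initial state, as in
      # the event-based engines
      if (tb[1] == t0) {
        x0[1] <- x0[1] + b[1]
        tb <- tb[-1]; b <- b[-1]
      }
    }
  }
  # initial gut mass behaves as a bolus at t0 for the 6-TGN forcing
  # (6-TGN is continuous across gut boluses, so the convention at the
  # instant itself is immaterial there)
  tbc <- tb; bc <- b
  if (x0[1] > 0) {
    tbc <- c(t0, tb); bc <- c(x0[1], b)
    o <- order(tbc); tbc <- tbc[o]; bc <- bc[o]
  }
  .C("mtanc_set_doses", as.integer(length(tbc)), as.double(tbc),
     as.double(bc),
     as.double(c(consts$k_a, consts$k_20, cl, consts$FM3 * consts$k_me)),
     as.double(c(x0[2], x0[3], t0)), PACKAGE = "mtanc")
  .pred_state$token <- -1L       # invalidate any cached predictor state

  pparms <- c(params$k_tr, params$gamma, params$slope, params$Base,
              consts$k_ma)
  # fixed-step RK4 on a grid whose breakpoints include every dose and
  # output time (the forcing is smooth within each step); falls back to
  # lsoda if the state leaves the admissible region mid-step
  brk <- sort(unique(c(times, tb[tb > t0 & tb < tf])))
  pos <- match(times, brk)
  res <- .C("mtanc_pd_rk4", as.double(pparms), as.integer(length(brk)),
            as.double(brk), as.double(h_rk4), as.integer(length(times)),
            as.integer(pos), as.double(unname(x0[4:8])),
            yout = double(5 * length(times)), status = integer(1),
            PACKAGE = "mtanc")
  if (res$status == 0) {
    pdmat <- matrix(res$yout, ncol = 5, byrow = TRUE)
  } else {
    pd <- deSolve::lsoda(y = unname(x0[4:8]), times = times,
                         func = "mtanc_pd_derivs", parms = pparms,
                         dllname = "mtanc", initfunc = "mtanc_pd_initparms",
                         rtol = rtol, atol = atol, maxsteps = 50000)
    istate <- attr(pd, "istate")
    if (!is.null(istate) && istate[1] < 0)
      stop(sprintf("ODE integration failed (istate = %d) near t = %.3f",
                   istate[1], pd[nrow(pd), 1]))
    if (nrow(pd) < length(times))
      stop(sprintf("ODE integration stopped early at t = %.3f",
                   pd[nrow(pd), 1]))
    pdmat <- pd[, -1, drop = FALSE]
  }
  pk <- .analytic_pk(times, tb, b, g0 = x0[1], c0 = x0[2], tgn0 = x0[3],
                     t0 = t0, consts = consts, cl = cl)
  out <- cbind(time = times, pk, pdmat)
  colnames(out) <- c("time", .state_names)
  class(out) <- "matrix"
  out
}

# Registry so a predictor only re-installs its dose arrays in the C state
# when the previously used predictor was a different one.
.pred_state <- new.env(parent = emptyenv())
.pred_state$token <- 0L
.pred_state$counter <- 0L
.predictor_counter <- function() {
  .pred_state$counter <- .pred_state$counter + 1L
  .pred_state$counter
}

# Lean ANC predictor factory for the estimation loop: precomputes the dose
# bolus arrays and RK4 breakpoint grid for one patient design, returning a
# closure that maps an individual parameter vector (Base, k_tr, gamma,
# slope) to model ANC at the observation times.  Returns NULL from the
# closure when the trajectory leaves the admissible region (caller treats
# this as an infinite objective).
.make_anc_predictor <- function(obs_times, dose_times, dose_amounts, bsa,
                                consts = pk_constants(), h_rk4 = 0.1) {
  keep <- dose_amounts > 0
  dt <- dose_times[keep]; da <- dose_amounts[keep]
  t0 <- min(0, obs_times, dt)
  tf <- max(obs_times)
  keep <- dt <= tf
  dt <- dt[keep]; da <- da[keep]
  if (anyDuplicated(dt)) {
    s <- rowsum(da, dt)
    dt <- as.numeric(rownames(s)); da <- as.numeric(s)
  }
  o <- order(dt); dt <- dt[o]; da <- consts$F * da[o]
  cl <- clearance_6tgn(bsa, consts)
  rates <- c(consts$k_a, consts$k_20, cl, consts$FM3 * consts$k_me)
  brk <- sort(unique(c(t0, obs_times, dt)))
  pos <- match(obs_times, brk)
  nd <- length(dt); nb <- length(brk); no <- length(obs_times)
  k_ma <- consts$k_ma
  init <- c(0, 0, t0)

  token <- .predictor_counter()
  install_doses <- function() {
    if (!identical(.pred_state$token, token)) {
      .C("mtanc_set_doses", as.integer(nd), dt, da, rates, init,
         PACKAGE = "mtanc")
      .pred_state$token <- token
    }
  }
  bad <- function(p) any(!is.finite(p)) || any(p <= 1e-8) || any(p > 1e6)

  pred <- function(p) {
    # p = c(Base, k_tr, gamma, slope), all > 0
    if (bad(p)) return(NULL)
    amp <- p[1] * k_ma / p[2]
    if (!is.finite(amp)) return(NULL)
    install_doses()
    res <- .C("mtanc_pd_rk4",
              as.double(c(p[2], p[3], p[4], p[1], k_ma)),
              as.integer(nb), brk, as.double(h_rk4), as.integer(no),
              as.integer(pos), as.double(c(amp, amp, amp, amp, p[1])),
              yout = double(5 * no), status = integer(1),
              PACKAGE = "mtanc")
    if (res$status != 0) return(NULL)
    res$yout[seq(5, 5 * no, by = 5)]
  }
  # analytic forward sensitivities: f and the n x 4 Jacobian d f / d p
  attr(pred, "sens") <- function(p) {
    if (bad(p)) return(NULL)
    install_doses()
    res <- .C("mtanc_pd_rk4_sens",
              as.double(c(p[2], p[3], p[4], p[1], k_ma)),
              as.integer(nb), brk, as.double(h_rk4), as.integer(no),
              as.integer(pos), yout = double(5 * no), status = integer(1),
              PACKAGE = "mtanc")
    if (res$status != 0) return(NULL)
    m <- matrix(res$yout, ncol = 5, byrow = TRUE)
    list(f = m[, 1], J = m[, 2:5, drop = FALSE])
  }
  pred
}
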