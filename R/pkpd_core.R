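#' @useDynLib mtanc
#' @importFrom stats median quantile rnorm runif sd setNames optim lm coef rpois
#' @importFrom graphics plot lines points polygon boxplot
#' @importFrom utils read.csv write.csv
NULL

.state_names <- c("x_6mpgut", "x_6mp", "x_6tgn",
                  "x_pr", "x_tr1", "x_tr2", "x_tr3", "x_ma")

#' Published PK/PD model constants
#'
#' Fixed constants of the oral 6MP absorption/metabolism model and the
#' neutrophil death rate.  Defaults are the published per-day values; time
#' unit is days throughout the package.
#'
#' @param F bioavailability fraction of oral 6MP (dimensionless, <= 1).
#' @param k_a first-order absorption rate from the GI tract (1/day).
#' @param k_20 first-order elimination rate of central 6MP (1/day); this
#'   elimination comprises metabolic transformation.
#' @param FM3 fraction of the metabolic transformation that yields 6-TGN
#'   (dimensionless, <= 1).
#' @param k_me metabolic transformation rate of 6MP (1/day).
#' @param cl_coef coefficient of the BSA-dependent 6-TGN clearance
#'   (per-day scale).
#' @param cl_exp BSA exponent of the 6-TGN clearance (dimensionless).
#' @param k_ma death rate of mature circulating neutrophils (1/day).
#' @return An object of class `pk_constants` (named list).
#' @examples
#' pk_constants()
#' @export
pk_constants <- function(F = 0.22, k_a = 31.2, k_20 = 12.72, FM3 = 0.019,
                         k_me = 9.9216, cl_coef = 0.219, cl_exp = 1.16,
                         k_ma = 2.3765) {
  x <- list(F = F, k_a = k_a, k_20 = k_20, FM3 = FM3, k_me = k_me,
            cl_coef = cl_coef, cl_exp = cl_exp, k_ma = k_ma)
  vals <- unlist(x)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("all PK constants must be finite and strictly positive")
  if (F > 1) stop("bioavailability F must be <= 1")
  if (FM3 > 1) stop("fractional transformation FM3 must be <= 1")
  structure(x, class = "pk_constants")
}

#' Per-patient pharmacodynamic parameters
#'
#' One realization of the four individual parameters: neutrophil baseline,
#' transit rate, feedback exponent and linear drug-effect slope.
#'
#' @param Base neutrophil baseline (G/L).
#' @param k_tr transition rate between maturation compartments (1/day).
#' @param gamma exponent of the feedback term `(Base/x_ma)^gamma`.
#' @param slope linear PD coefficient multiplying the 6-TGN level.
#' @return An object of class `individual_params`.
#' @export
individual_params <- function(Base, k_tr, gamma, slope) {
  x <- c(Base = Base, k_tr = k_tr, gamma = gamma, slope = slope)
  if (any(!is.finite(x)) || any(x <= 0))
    stop("individual parameters must be finite and strictly positive")
  structure(as.list(x), class = "individual_params")
}

#' BSA-dependent clearance of 6-TGN
#'
#' `CL(BSA) = cl_coef * BSA^cl_exp` on the per-day scale.
#'
#' @param bsa body surface area in m^2 (>= 0).
#' @param consts a [pk_constants()] object.
#' @return Clearance (per day), vectorized over `bsa`.
#' @examples
#' clearance_6tgn(1.0)   # 0.219
#' @export
clearance_6tgn <- function(bsa, consts = pk_constants()) {
  if (any(!is.finite(bsa)) || any(bsa < 0))
    stop("bsa must be finite and non-negative")
  consts$cl_coef * bsa^consts$cl_exp
}

#' Linear drug effect
#'
#' `E_drug = slope * x_6tgn`.  Values >= 1 are allowed and mean the
#' proliferation term becomes non-positive (net cell kill); callers must not
#' clip.
#'
#' @param slope linear PD coefficient (>= 0).
#' @param x_6tgn 6-TGN level (>= 0).
#' @return The dimensionless effect, vectorized.
#' @export
drug_effect <- function(slope, x_6tgn) {
  if (any(slope < 0) || any(x_6tgn < 0))
    stop("slope and x_6tgn must be non-negative")
  slope * x_6tgn
}

#' Mean neutrophil maturation time
#'
#' `MMT = n_tr / k_tr` for a maturation chain with `n_tr` transit
#' compartments sharing rate `k_tr`.
#'
#' @param k_tr transition rate (1/day).
#' @param n_tr number of transit compartments (default 3).
#' @return MMT in days.
#' @examples
#' mean_maturation_time(0.148)          # ~20.3 days
#' mean_maturation_time(0.148) * 24     # ~487 hours
#' @export
mean_maturation_time <- function(k_tr, n_tr = 3) {
  if (any(k_tr <= 0)) stop("k_tr must be positive")
  n_tr / k_tr
}

#' Drug-free steady state of the model
#'
#' Returns the equilibrium state with no drug on board: drug compartments at
#' zero, all proliferating/transit compartments at `Base * k_ma / k_tr`, and
#' circulating neutrophils at `Base`.  This is an exact fixed point of the
#' continuous dynamics with zero dosing.
#'
#' @param params an [individual_params()] object.
#' @param consts a [pk_constants()] object.
#' @return Named state vector of length 8.
#' @export
steady_state_init <- function(params, consts = pk_constants()) {
  amp <- params$Base * consts$k_ma / params$k_tr
  setNames(c(0, 0, 0, amp, amp, amp, amp, params$Base), .state_names)
}

#' Continuous right-hand side of the model
#'
#' Reference R implementation of the eight coupled ODEs.  Oral doses are
#' impulses handled outside this function (see [simulate_anc()]); the
#' continuous RHS therefore contains no input term.
#'
#' @param t time (day); the system is autonomous, `t` is ignored.
#' @param state named state vector (see [steady_state_init()] for the order).
#' @param params an [individual_params()] object.
#' @param consts a [pk_constants()] object.
#' @param bsa body surface area (m^2), sets the 6-TGN clearance.
#' @param clamp_6tgn optional value at which to hold `x_6tgn` fixed
#'   (its derivative is then 0); used for equilibrium analyses.
#' @return Named vector of derivatives.
#' @export
anc_rhs <- function(t, state, params, consts = pk_constants(), bsa,
                    clamp_6tgn = NULL) {
  s <- unname(state)
  tgn <- if (!is.null(clamp_6tgn)) clamp_6tgn else s[3]
  x_ma <- s[8]
  if (!is.finite(x_ma) || x_ma <= 0)
    stop("x_ma must be strictly positive (feedback term undefined)")
  cl <- clearance_6tgn(bsa, consts)
  e <- drug_effect(params$slope, tgn)
  fb <- (params$Base / x_ma)^params$gamma
  d <- c(
    -consts$k_a * s[1],
    consts$k_a * s[1] - consts$k_20 * s[2],
    if (!is.null(clamp_6tgn)) 0 else consts$FM3 * consts$k_me * s[2] - cl * tgn,
    params$k_tr * s[4] * ((1 - e) * fb - 1),
    params$k_tr * (s[4] - s[5]),
    params$k_tr * (s[5] - s[6]),
    params$k_tr * (s[6] - s[7]),
    params$k_tr * s[7] - consts$k_ma * x_ma
  )
  setNames(d, .state_names)
}

#' Oral dose schedule
#'
#' @param time dose times (days), non-decreasing.
#' @param amount oral 6MP amounts (mg), >= 0.  The bioavailable fraction
#'   `F * amount` enters the gut compartment as an instantaneous bolus.
#' @return A `dose_schedule` data frame with columns `time` and `amount`.
#' @export
dose_schedule <- function(time = numeric(), amount = numeric()) {
  if (length(time) != length(amount))
    stop("time and amount must have equal length")
  if (is.unsorted(time)) stop("dose times must be non-decreasing")
  if (any(amount < 0)) stop("dose amounts must be non-negative")
  structure(data.frame(time = as.numeric(time), amount = as.numeric(amount)),
            class = c("dose_schedule", "data.frame"))
}

#' Simulate the model under impulse oral dosing
#'
#' Integrates the eight-state system with a stiff multistep solver (lsoda,
#' compiled RHS).  Each dose adds `F * amount` to the gut compartment as a
#' bolus event; the solver restarts at every event.  The ANC prediction is
#' the `x_ma` column.
#'
#' @param params an [individual_params()] object.
#' @param bsa body surface area (m^2).
#' @param doses a [dose_schedule()] (or `NULL` for no dosing).
#' @param times sorted output times (days); integration starts at `times[1]`.
#' @param consts a [pk_constants()] object.
#' @param x0 initial state, or `NULL` for [steady_state_init()].
#' @param clamp_6tgn optional fixed 6-TGN level (see [anc_rhs()]).
#' @param rtol,atol solver relative/absolute tolerances.
#' @param engine `"compiled"` (default, full 8-state C RHS with bolus
#'   events), `"hybrid"` (closed-form linear PK + compiled 5-state PD ODE;
#'   much faster for long daily-dosing histories, used internally for
#'   estimation and predictive simulation), or `"R"` (reference R RHS, used
#'   for cross-checks).
#' @return Matrix with a `time` column and one column per state.
#' @examples
#' p <- individual_params(Base = 2.34, k_tr = 0.148, gamma = 0.769,
#'                        slope = 0.242)
#' d <- dose_schedule(time = 0:27, amount = rep(40, 28))
#' tr <- simulate_anc(p, bsa = 0.82, doses = d, times = 0:28)
#' tr[29, "x_ma"]
#' @export
simulate_anc <- function(params, bsa, doses = NULL, times,
                         consts = pk_constants(), x0 = NULL,
                         clamp_6tgn = NULL, rtol = 1e-8, atol = 1e-10,
                         engine = c("compiled", "hybrid", "R")) {
  engine <- match.arg(engine)
  if (length(times) < 2) stop("need at least two output times")
  if (is.unsorted(times, strictly = TRUE))
    stop("output times must be strictly increasing")
  if (is.null(x0)) x0 <- steady_state_init(params, consts)
  x0 <- setNames(as.numeric(x0), .state_names)
  if (any(x0 < 0)) stop("initial state must be non-negative")
  if (engine == "hybrid") {
    if (!is.null(clamp_6tgn))
      stop("clamp_6tgn requires the \"compiled\" or \"R\" engine")
    return(.simulate_hybrid(params, bsa, doses, times, consts, x0,
                            rtol, atol))
  }

  t0 <- times[1]; tf <- times[length(times)]
  ev <- NULL
  if (!is.null(doses) && nrow(doses) > 0) {
    d <- doses[doses$amount > 0, , drop = FALSE]
    d <- d[d$time <= tf, , drop = FALSE]
    if (any(d$time < t0))
      stop("dose events before the first output time are not representable")
    if (nrow(d) > 0) {
      # bolus of the bioavailable fraction into the gut compartment
      amt <- tapply(d$amount, d$time, sum)
      tev <- as.numeric(names(amt))
      at_start <- tev == t0
      if (any(at_start))
        x0[1] <- x0[1] + consts$F * sum(amt[at_start])
      if (any(!at_start))
        ev <- data.frame(var = 1, time = tev[!at_start],
                         value = consts$F * unname(amt[!at_start]),
                         method = "add")
    }
  }

  pvec <- c(consts$k_a, consts$k_20, consts$FM3, consts$k_me,
            clearance_6tgn(bsa, consts), params$k_tr, params$gamma,
            params$slope, params$Base,
            consts$k_ma, if (is.null(clamp_6tgn)) -1 else clamp_6tgn)

  # run the solver over output times merged with event times (all event
  # times must be solver stops anyway; requested rows are extracted below)
  tsolve <- if (is.null(ev)) times else sort(unique(c(times, ev$time)))
  if (engine == "compiled") {
    out <- deSolve::lsoda(y = x0, times = tsolve, func = "mtanc_derivs",
                          parms = pvec, dllname = "mtanc",
                          initfunc = "mtanc_initparms",
                          rtol = rtol, atol = atol, maxsteps = 50000,
                          events = if (is.null(ev)) NULL else list(data = ev))
  } else {
    rhs <- function(t, y, p) {
      list(unname(anc_rhs(t, y, params, consts, bsa, clamp_6tgn)))
    }
    out <- deSolve::lsoda(y = x0, times = tsolve, func = rhs, parms = NULL,
                          rtol = rtol, atol = atol, maxsteps = 50000,
                          events = if (is.null(ev)) NULL else list(data = ev))
  }
  istate <- attr(out, "istate")
  if (!is.null(istate) && istate[1] < 0)
    stop(sprintf("ODE integration failed (istate = %d) near t = %.3f",
                 istate[1], out[nrow(out), 1]))
  if (nrow(out) < length(tsolve))
    stop(sprintf("ODE integration stopped early at t = %.3f",
                 out[nrow(out), 1]))
  out <- out[match(times, out[, 1]), , drop = FALSE]
  colnames(out) <- c("time", .state_names)
  class(out) <- "matrix"
  out
}

#' Export a trajectory in tidy long format
#'
#' @param traj matrix from [simulate_anc()].
#' @param patient_id identifier stored in the first column.
#' @return data.frame with columns `patient_id`, `time`, `state`, `value`.
#' @export
trajectory_long <- function(traj, patient_id = 1L) {
  st <- setdiff(colnames(traj), "time")
  data.frame(
    patient_id = patient_id,
    time = rep(traj[, "time"], times = length(st)),
    state = rep(st, each = nrow(traj)),
    value = as.vector(traj[, st])
  )
}
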