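#' Population parameter model
#'
#' Fixed effects, diagonal log-normal inter-individual variances and the
#' proportional residual variance that define the population distribution
#' of individual PD parameters.
#'
#' Defaults are the in-sample population estimates this model family was
#' built around: fixed effects (Base 2.34 G/L, k_tr 0.148/day, gamma 0.769,
#' slope 0.242), IIV coefficients of variation 23.1/16.5/10.7/44.9 percent
#' for Base/k_tr/gamma/slope, and proportional residual variance 0.226.
#'
#' @param theta named numeric of fixed effects `Base`, `k_tr`, `gamma`,
#'   `slope` (all > 0).
#' @param omega2 named numeric of IIV variances (log scale) for the same
#'   four parameters, >= 0.  The default converts the CV percentages above
#'   via `omega2 = log(1 + (cv/100)^2)`.
#' @param sigma2 proportional residual error magnitude (>= 0).
#' @param sigma_as whether `sigma2` is a variance (default) or a standard
#'   deviation (then squared internally).  The magnitude 0.226 read as a
#'   variance implies roughly 48 percent residual CV; both readings are
#'   supported.
#' @return Object of class `population_model`.
#' @export
population_model <- function(theta = c(Base = 2.34, k_tr = 0.148,
                                       gamma = 0.769, slope = 0.242),
                             omega2 = log(1 + (c(Base = 23.1, k_tr = 16.5,
                                                 gamma = 10.7,
                                                 slope = 44.9) / 100)^2),
                             sigma2 = 0.226,
                             sigma_as = c("variance", "sd")) {
  sigma_as <- match.arg(sigma_as)
  nm <- c("Base", "k_tr", "gamma", "slope")
  theta <- theta[nm]; omega2 <- omega2[nm]
  if (any(is.na(theta)) || any(theta <= 0))
    stop("theta must contain positive Base, k_tr, gamma, slope")
  if (any(is.na(omega2)) || any(omega2 < 0))
    stop("omega2 must contain non-negative variances for all four parameters")
  if (length(sigma2) != 1 || sigma2 < 0) stop("sigma2 must be >= 0")
  if (sigma_as == "sd") sigma2 <- sigma2^2
  structure(list(theta = theta, omega2 = omega2, sigma2 = sigma2),
            class = "population_model")
}

#' @export
print.population_model <- function(x, ...) {
  cat("Population model\n  fixed effects:",
      paste(sprintf("%s=%.4g", names(x$theta), x$theta), collapse = ", "),
      "\n  IIV CV%:     ",
      paste(sprintf("%s=%.3g", names(x$omega2), iiv_as_cv(x$omega2)),
            collapse = ", "),
      "\n  sigma2:", format(x$sigma2), "\n")
  invisible(x)
}

#' Virtual cohort configuration
#'
#' Settings of the synthetic-cohort generator.  Defaults emulate the study
#' population: 116 patients, BSA between 0.47 and 1.98 m^2, follow-up of
#' 200 to 581 days, daily oral 6MP titrated around 50 mg/m^2 rounded to
#' 2.5 mg tablets, roughly weekly ANC visits, and sporadic CRP-elevating
#' infection episodes during which dosing is withheld.
#'
#' @param n_patients number of virtual patients.
#' @param bsa_range BSA range (m^2).
#' @param bsa_dist `"loguniform"` over the range (default), or
#'   `"triangular"` with mode `bsa_mode` to pull the median toward 0.82.
#' @param bsa_mode mode of the triangular BSA option (m^2).
#' @param follow_up_range follow-up duration range (days).
#' @param target_dose nominal daily 6MP dose (mg/m^2).
#' @param dose_round tablet rounding step (mg).
#' @param obs_interval nominal visit spacing (days).
#' @param obs_jitter maximum whole-day jitter applied to each visit.
#' @param infection_rate infection episode rate (1/day; default 2/year).
#' @param infection_duration episode duration (days).
#' @param crp_infection CRP plateau during an episode (mg/L).
#' @param crp_baseline_max upper bound of the healthy CRP draw (mg/L).
#' @param anc_hold ANC threshold (G/L) below which the dose is halved.
#' @param anc_restore ANC threshold (G/L) above which the dose is stepped
#'   back up by 25 percent of the nominal dose (capped at nominal).
#' @param titration enable the closed-loop titration emulator.
#' @return Object of class `cohort_config`.
#' @export
cohort_config <- function(n_patients = 116, bsa_range = c(0.47, 1.98),
                          bsa_dist = c("loguniform", "triangular"),
                          bsa_mode = 0.82,
                          follow_up_range = c(200, 581), target_dose = 50,
                          dose_round = 2.5, obs_interval = 7,
                          obs_jitter = 1, infection_rate = 2 / 365,
                          infection_duration = 7, crp_infection = 20,
                          crp_baseline_max = 4.9,
                          anc_hold = 0.5, anc_restore = 2,
                          titration = TRUE) {
  bsa_dist <- match.arg(bsa_dist)
  stopifnot(n_patients >= 1, length(bsa_range) == 2,
            bsa_range[1] > 0, diff(bsa_range) >= 0,
            length(follow_up_range) == 2, follow_up_range[1] > 0,
            diff(follow_up_range) >= 0, target_dose >= 0,
            obs_interval >= 1, obs_jitter >= 0, infection_rate >= 0,
            infection_duration > 0, anc_hold >= 0, anc_restore >= anc_hold)
  structure(as.list(environment()), class = "cohort_config")
}

#' Draw individual parameters from the population model
#'
#' Each parameter is the fixed effect times `exp(eta)` with
#' `eta ~ N(0, diag(omega2))`.
#'
#' @param pop a [population_model()].
#' @param seed optional integer seed.
#' @return An [individual_params()] object with the `eta` draw attached as
#'   an attribute.
#' @export
sample_individual_params <- function(pop, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  eta <- rnorm(4, 0, sqrt(pop$omega2))
  names(eta) <- names(pop$theta)
  v <- pop$theta * exp(eta)
  out <- individual_params(v[["Base"]], v[["k_tr"]], v[["gamma"]],
                           v[["slope"]])
  attr(out, "eta") <- eta
  out
}

# Shared generator body: closed-loop titrated treatment of one patient
# using the current RNG stream.  Weekly visits; the decision uses the most
# recent observed (noisy) ANC; doses are withheld during infection
# episodes.  Returns doses, observations and bookkeeping.
.simulate_titrated <- function(bsa, params, config, consts,
                               engine = "hybrid") {
  fu <- round(runif(1, config$follow_up_range[1], config$follow_up_range[2]))
  rnd <- function(x) round(x / config$dose_round) * config$dose_round
  nominal <- rnd(config$target_dose * bsa)

  # visit days: roughly weekly with whole-day jitter, always starting at 0
  k <- seq(0, floor(fu / config$obs_interval))
  visits <- k * config$obs_interval +
    if (config$obs_jitter > 0)
      sample(seq(-config$obs_jitter, config$obs_jitter),
             length(k), replace = TRUE) else 0
  visits[1] <- 0
  visits <- sort(unique(pmin(pmax(visits, 0), fu)))

  # infection episodes: Poisson process with fixed duration
  n_ep <- rpois(1, config$infection_rate * fu)
  ep_start <- sort(runif(n_ep, 0, fu))
  in_episode <- function(t) {
    n_ep > 0 && any(t >= ep_start & t <= ep_start + config$infection_duration)
  }

  state <- steady_state_init(params, consts)
  current <- nominal
  sigma <- sqrt(config$pop_sigma2)
  obs_t <- obs_y <- obs_crp <- numeric(length(visits))
  dose_t <- dose_a <- numeric(0)
  n_trunc <- 0L

  observe <- function(x_ma) {
    y <- x_ma * (1 + rnorm(1, 0, sigma))
    if (y < 0) y <- x_ma * (1 + rnorm(1, 0, sigma))   # resample once
    if (y < 0) { y <- 0; n_trunc <<- n_trunc + 1L }
    y
  }
  crp_at <- function(t) {
    if (in_episode(t)) config$crp_infection
    else runif(1, 0, config$crp_baseline_max)
  }

  obs_t[1] <- 0
  obs_y[1] <- observe(state[["x_ma"]])
  obs_crp[1] <- crp_at(0)

  for (i in seq_len(length(visits) - 1)) {
    t0 <- visits[i]; t1 <- visits[i + 1]
    days <- seq(ceiling(t0), ceiling(t1) - 1)
    amt <- vapply(days, function(d) {
      if (current <= 0 || in_episode(d)) 0 else current
    }, numeric(1))
    seg_doses <- if (any(amt > 0))
      dose_schedule(days[amt > 0], amt[amt > 0]) else NULL
    tr <- simulate_anc(params, bsa, seg_doses, c(t0, t1), consts = consts,
                       x0 = state, engine = engine)
    state <- tr[2, -1]
    dose_t <- c(dose_t, days[amt > 0]); dose_a <- c(dose_a, amt[amt > 0])
    obs_t[i + 1] <- t1
    obs_y[i + 1] <- observe(state[["x_ma"]])
    obs_crp[i + 1] <- crp_at(t1)

    if (config$titration) {
      y <- obs_y[i + 1]
      if (y < config$anc_hold) {
        current <- max(0, floor((current / 2) / config$dose_round) *
                            config$dose_round)
      } else if (y > config$anc_restore && current < nominal) {
        current <- min(nominal, rnd(current + 0.25 * nominal))
      }
    }
  }
  list(doses = dose_schedule(dose_t, dose_a),
       observations = data.frame(time = obs_t, anc = obs_y, crp = obs_crp),
       follow_up = fu, nominal_dose = nominal, n_truncated = n_trunc,
       infection_starts = ep_start)
}

#' Build a titrated dosing schedule for one virtual patient
#'
#' Emulates the clinical dose-adjustment loop: daily dosing at the nominal
#' `target_dose * bsa` (rounded to `dose_round`), halved whenever the most
#' recent observed ANC drops below `anc_hold`, stepped back up by 25 percent
#' of nominal (capped at nominal) when ANC exceeds `anc_restore`, and
#' withheld during infection episodes.
#'
#' @param bsa body surface area (m^2).
#' @param config a [cohort_config()].
#' @param params the patient's [individual_params()] (the feedback loop
#'   requires simulating the patient).
#' @param consts a [pk_constants()].
#' @param seed optional integer seed.
#' @return A [dose_schedule()].
#' @export
make_dosing_schedule <- function(bsa, config, params,
                                 consts = pk_constants(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  cfg <- config
  cfg$pop_sigma2 <- config$pop_sigma2 %||% 0
  .simulate_titrated(bsa, params, cfg, consts)$doses
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Generate one virtual patient record
#'
#' Draws individual parameters, runs the titrated treatment, and returns
#' dose events plus noisy ANC observations with concurrent CRP values.
#' Observed ANC is `x_ma * (1 + eps)`, `eps ~ N(0, sigma2)`, resampled once
#' and then clamped at zero if negative.
#'
#' @param pop a [population_model()].
#' @param config a [cohort_config()].
#' @param consts a [pk_constants()].
#' @param id patient identifier.
#' @param seed optional integer seed.
#' @return Object of class `patient_record`: fields `id`, `bsa`, `doses`,
#'   `observations` (time, anc, crp), `true_params`, `eta`, `follow_up`,
#'   `n_truncated`.
#' @export
generate_patient <- function(pop, config = cohort_config(),
                             consts = pk_constants(), id = 1L,
                             seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  bsa <- .draw_bsa(config)
  params <- sample_individual_params(pop)
  cfg <- config
  cfg$pop_sigma2 <- pop$sigma2
  sim <- .simulate_titrated(bsa, params, cfg, consts)
  patient_record(id = id, bsa = bsa, doses = sim$doses,
                 observations = sim$observations,
                 true_params = params, eta = attr(params, "eta"),
                 follow_up = sim$follow_up, n_truncated = sim$n_truncated)
}

.draw_bsa <- function(config) {
  r <- config$bsa_range
  if (config$bsa_dist == "loguniform") {
    exp(runif(1, log(r[1]), log(r[2])))
  } else {
    # triangular via inverse CDF
    m <- config$bsa_mode; u <- runif(1)
    fc <- (m - r[1]) / (r[2] - r[1])
    if (u < fc) r[1] + sqrt(u * (r[2] - r[1]) * (m - r[1]))
    else r[2] - sqrt((1 - u) * (r[2] - r[1]) * (r[2] - m))
  }
}

#' Patient record constructor
#'
#' @param id identifier.
#' @param bsa body surface area (m^2).
#' @param doses a [dose_schedule()].
#' @param observations data.frame with columns `time` (strictly
#'   increasing), `anc` (>= 0) and optionally `crp` (>= 0, NA = unknown).
#' @param true_params,eta simulation truth (absent for real data).
#' @param ... further fields stored as-is.
#' @return Object of class `patient_record`.
#' @export
patient_record <- function(id, bsa, doses, observations,
                           true_params = NULL, eta = NULL, ...) {
  stopifnot(is.data.frame(observations),
            all(c("time", "anc") %in% names(observations)))
  if (is.unsorted(observations$time, strictly = TRUE))
    stop("observation times must be strictly increasing")
  if (any(observations$anc < 0)) stop("anc must be non-negative")
  if (!is.null(observations$crp) &&
      any(observations$crp < 0, na.rm = TRUE))
    stop("crp must be non-negative")
  if (!is.finite(bsa) || bsa <= 0) stop("bsa must be positive")
  structure(list(id = id, bsa = bsa, doses = doses,
                 observations = observations, true_params = true_params,
                 eta = eta, ...),
            class = "patient_record")
}

#' @export
print.patient_record <- function(x, ...) {
  cat(sprintf("Patient %s: BSA %.2f m^2, %d dose events, %d observations\n",
              x$id, x$bsa, nrow(x$doses), nrow(x$observations)))
  invisible(x)
}

#' Generate a virtual cohort
#'
#' Independent patient records under a shared population model and
#' configuration.  A master seed drives per-patient substreams, so cohorts
#' are reproducible and individual patients can be regenerated.
#'
#' @param pop a [population_model()].
#' @param config a [cohort_config()].
#' @param consts a [pk_constants()].
#' @param seed master integer seed.
#' @return Object of class `anc_cohort` (list of `patient_record`s) with a
#'   `manifest` attribute recording the seed and configuration.
#' @export
generate_cohort <- function(pop, config = cohort_config(),
                            consts = pk_constants(), seed = 1L) {
  set.seed(seed)
  subseeds <- sample.int(.Machine$integer.max, config$n_patients)
  records <- lapply(seq_len(config$n_patients), function(i) {
    generate_patient(pop, config, consts, id = i, seed = subseeds[i])
  })
  structure(records, class = "anc_cohort",
            manifest = list(seed = seed, n_patients = config$n_patients,
                            config = unclass(config)))
}

#' @export
print.anc_cohort <- function(x, ...) {
  nobs <- vapply(x, function(r) nrow(r$observations), integer(1))
  cat(sprintf("Virtual cohort: %d patients, %d ANC observations (%d-%d per patient)\n",
              length(x), sum(nobs), min(nobs), max(nobs)))
  invisible(x)
}
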