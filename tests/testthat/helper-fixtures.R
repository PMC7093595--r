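# Programmatic fixtures shared across test files.

default_params <- function() {
  individual_params(Base = 2.34, k_tr = 0.148, gamma = 0.769, slope = 0.242)
}

# Small, fast cohort for functional tests (not the study-scale defaults).
tiny_cohort <- function(n = 6, seed = 101, follow_up = c(150, 200), ...) {
  generate_cohort(population_model(),
                  cohort_config(n_patients = n,
                                follow_up_range = follow_up, ...),
                  seed = seed)
}

# Cohort with exactly 5897 ANC observations of which exactly 1150 fall
# inside CRP exclusion windows (CRP > 5 at two visit days per patient for
# 115 patients; each window of +/- 14 days covers 5 weekly visits).
crp_filter_fixture <- function() {
  mk <- function(id, n_obs, spike_days) {
    tt <- 7 * (seq_len(n_obs) - 1)
    crp <- rep(1, n_obs)
    crp[tt %in% spike_days] <- 20
    patient_record(id = id, bsa = 1, doses = dose_schedule(),
                   observations = data.frame(time = tt, anc = 1.8,
                                             crp = crp))
  }
  c(lapply(1:115, mk, n_obs = 51, spike_days = c(70, 210)),
    list(mk(116, 32, numeric(0))))
}

# Deterministic toy records for the mixed-effects tests: f = a + B eta
# (linear in eta), additive error.
linear_toy <- function(n_pat = 4, n_obs = 6, p = 2, seed = 7,
                       omega = 0.5, sigma = 0.3) {
  set.seed(seed)
  recs <- lapply(seq_len(n_pat), function(i) {
    B <- matrix(rnorm(n_obs * p), n_obs, p)
    a <- rnorm(n_obs, 5)
    y <- a + drop(B %*% rnorm(p, 0, omega)) + rnorm(n_obs, 0, sigma)
    list(id = i, a = a, B = B,
         observations = data.frame(time = seq_len(n_obs), anc = y))
  })
  model <- list(predict = function(record, theta, eta)
    record$a + drop(record$B %*% eta[seq_len(ncol(record$B))]))
  list(records = recs, model = model, p = p)
}

# Nonlinear toy: one-compartment-like curve, 2 random effects
#   f_j = theta1 * exp(eta1) * exp(-theta2 * exp(eta2) * t_j)
nonlinear_toy <- function(n_pat = 3, seed = 13, omega2 = c(0.2, 0.1),
                          sigma2 = 0.04, theta = c(10, 0.3),
                          error = "proportional") {
  set.seed(seed)
  tt <- c(0.5, 1, 2, 3, 5, 8)
  model <- list(predict = function(record, theta, eta)
    theta[1] * exp(eta[1]) * exp(-theta[2] * exp(eta[2]) * record$observations$time))
  recs <- lapply(seq_len(n_pat), function(i) {
    eta <- rnorm(2, 0, sqrt(omega2))
    f <- theta[1] * exp(eta[1]) * exp(-theta[2] * exp(eta[2]) * tt)
    y <- if (error == "proportional") f * (1 + rnorm(length(tt), 0, sqrt(sigma2)))
         else f + rnorm(length(tt), 0, sqrt(sigma2))
    list(id = i, observations = data.frame(time = tt, anc = pmax(y, 0.01)))
  })
  list(records = recs, model = model, theta = theta, omega2 = omega2,
       sigma2 = sigma2)
}
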