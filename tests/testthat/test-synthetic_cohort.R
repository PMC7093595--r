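test_that("population model defaults encode the reported scales", {
  pop <- population_model()
  expect_equal(unname(pop$theta), c(2.34, 0.148, 0.769, 0.242))
  expect_equal(unname(iiv_as_cv(pop$omega2)), c(23.1, 16.5, 10.7, 44.9),
               tolerance = 1e-10)
  expect_equal(pop$sigma2, 0.226)
  expect_equal(population_model(sigma2 = 0.3, sigma_as = "sd")$sigma2, 0.09)
  expect_error(population_model(theta = c(Base = -1, k_tr = 1, gamma = 1,
                                          slope = 1)), "positive")
})

test_that("individual parameters follow theta * exp(eta)", {
  pop <- population_model()
  # degenerate: zero variances reproduce the fixed effects exactly
  pop0 <- pop; pop0$omega2[] <- 0
  pr <- sample_individual_params(pop0, seed = 1)
  expect_equal(unlist(pr[c("Base", "k_tr", "gamma", "slope")]),
               pop$theta, tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(unname(attr(pr, "eta")), rep(0, 4))
  # a forced eta doubles the parameter
  expect_equal(pop$theta[["Base"]] * exp(log(2)), 2 * pop$theta[["Base"]])
})

test_that("sampled parameter CVs match the log-normal model", {
  pop <- population_model()
  set.seed(42)
  draws <- replicate(2e4, {
    eta <- rnorm(1, 0, sqrt(pop$omega2[["Base"]]))
    pop$theta[["Base"]] * exp(eta)
  })
  cv <- 100 * sd(draws) / mean(draws)
  expect_equal(cv, 23.1, tolerance = 0.02 * 23.1)
  # via the package sampler
  set.seed(43)
  b <- replicate(2e4, sample_individual_params(pop)$Base)
  expect_equal(100 * sd(b) / mean(b), 23.1, tolerance = 0.02 * 23.1)
})

test_that("nominal dose is target * BSA rounded to 2.5 mg tablets", {
  pop <- population_model()
  cfg <- cohort_config(titration = FALSE, infection_rate = 0,
                       follow_up_range = c(100, 100), obs_jitter = 0)
  set.seed(7)
  params <- sample_individual_params(pop)
  sch <- make_dosing_schedule(0.82, cfg, params, seed = 5)
  expect_true(all(sch$amount == 40))    # 50 * 0.82 = 41 -> 40
  expect_equal(nrow(sch), 98)           # daily, decisions at weekly visits
})

test_that("titration halves the dose after an observed ANC below 0.5", {
  pop <- population_model()
  # strong drug effect forces ANC low, so titration must engage
  pop_low <- pop
  pop_low$theta[["slope"]] <- 2.5
  pop_low$omega2[] <- 0; pop_low$sigma2 <- 0
  cfg <- cohort_config(infection_rate = 0, obs_jitter = 0,
                       follow_up_range = c(250, 250))
  rec <- generate_patient(pop_low, cfg, id = 1, seed = 2)
  obs <- rec$observations
  expect_lt(min(obs$anc), 0.5)
  amt_by_day <- setNames(rec$doses$amount, rec$doses$time)
  first_low <- obs$time[min(which(obs$anc < 0.5))]
  before <- amt_by_day[as.character(first_low - 1)]
  after <- amt_by_day[as.character(first_low + 1)]
  expect_equal(unname(after),
               unname(floor((before / 2) / 2.5) * 2.5))
  # and the dose is restored toward nominal after recovery above 2
  expect_true(any(rec$doses$amount > after))
})

test_that("zero residual variance reproduces the model trajectory", {
  pop <- population_model(sigma2 = 0)
  cfg <- cohort_config(infection_rate = 0, obs_jitter = 0,
                       follow_up_range = c(120, 120), titration = FALSE)
  rec <- generate_patient(pop, cfg, id = 1, seed = 9)
  tr <- simulate_anc(rec$true_params, rec$bsa, rec$doses,
                     sort(unique(c(0, rec$observations$time))),
                     engine = "hybrid")
  pred <- tr[match(rec$observations$time, tr[, "time"]), "x_ma"]
  expect_equal(rec$observations$anc, unname(pred), tolerance = 1e-6)
})

test_that("no infections means CRP stays below the filter threshold", {
  cfg <- cohort_config(infection_rate = 0, follow_up_range = c(150, 200))
  coh <- generate_cohort(population_model(),
                         cohort_config(n_patients = 4, infection_rate = 0,
                                       follow_up_range = c(150, 200)),
                         seed = 3)
  crp <- unlist(lapply(coh, function(r) r$observations$crp))
  expect_true(all(crp <= 5))
  expect_equal(filter_cohort(coh)$report$n_excluded, 0)
})

test_that("residual error magnitude matches sigma2 in repeated sampling", {
  pop <- population_model()      # sigma2 = 0.226
  set.seed(31)
  x_ma <- 1.7
  y <- x_ma * (1 + rnorm(2e4, 0, sqrt(pop$sigma2)))
  v <- var(y / x_ma - 1)
  expect_equal(v, 0.226, tolerance = 0.03 * 0.226)
})

test_that("cohorts are reproducible and patient-level independent", {
  cfg <- cohort_config(n_patients = 4, follow_up_range = c(120, 160))
  a <- generate_cohort(population_model(), cfg, seed = 77)
  b <- generate_cohort(population_model(), cfg, seed = 77)
  expect_identical(a[[3]]$observations, b[[3]]$observations)
  expect_identical(a[[3]]$doses, b[[3]]$doses)
  d <- generate_cohort(population_model(), cfg, seed = 78)
  expect_false(identical(a[[1]]$observations$anc,
                         d[[1]]$observations$anc))
})

test_that("default-configuration cohorts look like the study data", {
  coh <- generate_cohort(population_model(),
                         cohort_config(n_patients = 30), seed = 123)
  nobs <- vapply(coh, function(r) nrow(r$observations), integer(1))
  expect_true(all(nobs >= 28))          # 200 days of weekly visits
  anc <- unlist(lapply(coh, function(r) r$observations$anc))
  expect_true(all(anc >= 0))
  trunc_frac <- sum(vapply(coh, function(r) r$n_truncated, integer(1))) /
    length(anc)
  expect_lt(trunc_frac, 0.01)           # truncation is rare
  frac2 <- mean(anc < 2)
  expect_gt(frac2, 0.56 - 0.15)         # generator calibration band
  expect_lt(frac2, 0.56 + 0.15)
  bsa <- vapply(coh, function(r) r$bsa, numeric(1))
  expect_true(all(bsa >= 0.47 & bsa <= 1.98))
})
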