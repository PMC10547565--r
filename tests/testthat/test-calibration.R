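sim_cohort <- function(bank, n, seed, ...) {
  generate_cohort(bank, cohort_config(n_persons = n, timepoints = 1,
                                      occasion_mean = 0, occasion_sd = 1,
                                      within_person_icc = 0, missingness = 0,
                                      seed = seed, ...))
}

quiet_fit <- function(...) suppressWarnings(grm_calibrate(...))

test_that("a bank with no free items is returned unchanged with its loglik", {
  bank <- oks_bank()                      # all rows anchored
  cohort <- sim_cohort(bank, 150, 21)
  fit <- grm_calibrate(cohort$responses, bank)
  expect_true(fit$converged)
  for (col in c("a", kneemetric:::THRESHOLD_COLS))
    expect_identical(fit$bank[[col]], bank[[col]])
  expect_true(is.finite(fit$loglik))
  # the reported loglik matches a direct evaluation
  grid <- fit$grid
  codes <- kneemetric:::response_codes(cohort$responses, bank)
  ll <- kneemetric:::loglik_matrix(codes, bank, grid$nodes)
  direct <- sum(log(colSums(grid$weights * exp(ll))))
  expect_equal(fit$loglik, direct, tolerance = 1e-8)
})

test_that("anchors stay bitwise invariant and the EM trace is monotone", {
  bank <- oks_haas_bank()
  cohort <- sim_cohort(bank, 400, 33)
  fit <- quiet_fit(cohort$responses, bank)
  anchors <- which(bank$fixed)
  for (col in c("a", kneemetric:::THRESHOLD_COLS))
    expect_identical(fit$bank[[col]][anchors], bank[[col]][anchors])
  expect_true(all(diff(fit$trace) >= -1e-8))
  expect_true(all(fit$bank$n_categories[anchors] == 5L))
})

test_that("free HAAS parameters are recovered from simulated data", {
  bank <- oks_haas_bank()
  cohort <- sim_cohort(bank, 2000, 77)
  fit <- quiet_fit(cohort$responses, bank)
  expect_true(fit$converged)
  free <- which(!bank$fixed)
  err_a <- fit$bank$a[free] - bank$a[free]
  expect_lt(sqrt(mean(err_a^2)), 0.10)
  errs_b <- unlist(lapply(free, function(i) {
    id <- bank$item_id[i]
    truth <- kneemetric:::item_thresholds(bank, i)[fit$collapse[[id]]$boundary_map]
    est <- kneemetric:::item_thresholds(fit$bank, i)
    (est - truth)[abs(truth) <= 4]
  }))
  expect_lt(sqrt(mean(errs_b^2)), 0.30)
})

test_that("unobserved top categories are merged (or rejected on request)", {
  bank <- oks_haas_bank()
  cohort <- sim_cohort(bank, 500, 55)
  w <- testthat::capture_warnings(grm_calibrate(cohort$responses, bank))
  expect_true(any(grepl("merged", w)))
  expect_error(
    suppressWarnings(grm_calibrate(cohort$responses, bank,
                                   calibration_config(unobserved = "error"))),
    "unobserved")
})

test_that("calibration without anchor responses is rejected", {
  bank <- oks_haas_bank()
  cohort <- sim_cohort(bank, 60, 12)
  df <- as.data.frame(cohort$responses)
  df[, bank$item_id[bank$fixed]] <- NA_integer_
  expect_error(grm_calibrate(response_matrix(df, bank), bank),
               "not identified")
})

test_that("the latent density is estimable when anchors fix the metric", {
  bank <- oks_haas_bank()
  # null case: data generated under N(0, 1)
  cohort <- sim_cohort(bank, 4000, 91)
  fit0 <- quiet_fit(cohort$responses, bank,
                    calibration_config(estimate_density = TRUE,
                                       range = c(-8, 8)))
  expect_lt(abs(fit0$density["mean"]), 0.1)
  expect_lt(abs(fit0$density["sd"] - 1), 0.1)
  # shifted and widened truth: theta ~ N(1.0, 1.5^2)
  shifted <- generate_cohort(bank, cohort_config(
    n_persons = 4000, timepoints = 1, occasion_mean = 1.0, occasion_sd = 1.5,
    within_person_icc = 0, missingness = 0, seed = 92))
  fit1 <- quiet_fit(shifted$responses, bank,
                    calibration_config(estimate_density = TRUE,
                                       range = c(-8, 8)))
  expect_lt(abs(fit1$density["mean"] - 1.0), 0.1)
  expect_lt(abs(fit1$density["sd"] - 1.5), 0.1)
  # disabled: exactly the prior
  fit2 <- quiet_fit(cohort$responses, bank)
  expect_identical(unname(fit2$density), c(0, 1))
})

test_that("standard errors are positive, anchored items get none, and n scales them", {
  bank <- oks_haas_bank()
  fit1 <- quiet_fit(sim_cohort(bank, 1000, 61)$responses, bank)
  fit4 <- quiet_fit(sim_cohort(bank, 4000, 62)$responses, bank)
  se1 <- parameter_standard_errors(fit1)
  se4 <- parameter_standard_errors(fit4)
  expect_false(any(se1$item_id %in% bank$item_id[bank$fixed]))
  expect_true(all(se1$se[!se1$singular] > 0))
  shared <- intersect(paste(se1$item_id, se1$parameter),
                      paste(se4$item_id, se4$parameter))
  r <- se1$se[match(shared, paste(se1$item_id, se1$parameter))] /
    se4$se[match(shared, paste(se4$item_id, se4$parameter))]
  r <- r[is.finite(r)]
  # quadrupling n should halve SEs, roughly
  expect_equal(stats::median(r), 2, tolerance = 0.25)
})

test_that("a single free binary item's SE(a) approaches the Fisher bound", {
  oks <- oks_bank()
  extra <- graded_item("free_bin", "NEW", a = 1.2, b = 0.3)
  bank <- item_bank(rbind(as.data.frame(oks), as.data.frame(extra)))
  cohort <- sim_cohort(bank, 5000, 13)
  fit <- quiet_fit(cohort$responses, bank)
  se <- parameter_standard_errors(fit)
  se_a <- se$se[se$item_id == "free_bin" & se$parameter == "a"]
  # analytic single-item Fisher information for a at known theta ~ N(0,1):
  # I_aa = n * E[(theta - b)^2 P(1-P)], by fine quadrature at the estimates
  a_hat <- fit$bank$a[fit$bank$item_id == "free_bin"]
  b_hat <- kneemetric:::item_thresholds(fit$bank, 13L)
  th <- seq(-8, 8, length.out = 2001)
  w <- stats::dnorm(th); w <- w / sum(w)
  p <- stats::plogis(a_hat * (th - b_hat))
  bound <- 1 / sqrt(5000 * sum(w * (th - b_hat)^2 * p * (1 - p)))
  expect_equal(se_a, bound, tolerance = 0.20)
})

test_that("simulate -> calibrate -> table closes the loop within 0.1 logits", {
  bank <- oks_haas_bank()
  cohort <- sim_cohort(bank, 4000, 101)
  fit <- quiet_fit(cohort$responses, bank)
  grid <- quadrature_grid(121, c(-8, 13))
  # categories never observed in the sample were merged during the fit;
  # the truth table is built in the same layout with the true parameters
  truth_tab <- summed_score_eap_table(
    bank_subset(collapse_truth_bank(bank, fit), "HAAS"), grid)
  est_tab <- summed_score_eap_table(bank_subset(fit$bank, "HAAS"), grid)
  expect_identical(nrow(est_tab), nrow(truth_tab))
  expect_lt(max(abs(est_tab$eap - truth_tab$eap)), 0.1)
})

test_that("fit methods expose coefficients, likelihood, scores and reports", {
  bank <- oks_haas_bank()
  cohort <- sim_cohort(bank, 400, 19)
  fit <- quiet_fit(cohort$responses, bank)
  cf <- coef(fit)
  expect_true(all(grepl("^haas_", names(cf))))
  ll <- logLik(fit)
  expect_s3_class(ll, "logLik")
  expect_equal(as.numeric(ll), fit$loglik)
  sc <- predict(fit)
  expect_identical(nrow(sc), 400L)
  expect_true(all(is.finite(sc$theta_hat)))
  f <- tempfile(fileext = ".json")
  write_calibration_report(fit, f)
  rep <- jsonlite::read_json(f)
  expect_true(rep$converged)
  expect_length(rep$loglik_trace, length(fit$trace))
  sim <- simulate(fit, nsim = 1, seed = 3, n_persons = 50)
  expect_identical(nrow(sim[[1]]$responses), 50L)
})
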