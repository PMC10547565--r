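test_that("Cronbach's alpha matches hand arithmetic and its limits", {
  x <- cbind(a = c(0, 1, 2), b = c(0, 1, 2))
  expect_equal(cronbach_alpha(x), 1)
  # k = 2: alpha = 2 * (1 - (1 + 1) / 3) = 2/3
  y <- cbind(a = c(0, 1, 2), b = c(0, 2, 1))
  expect_equal(cronbach_alpha(y), 2 / 3)
  set.seed(5)
  z <- matrix(stats::rnorm(5000 * 6), 5000, 6)
  expect_lt(abs(cronbach_alpha(z)), 0.05)
  expect_warning(out <- cronbach_alpha(matrix(1, 5, 3)), "undefined")
  expect_true(is.na(out))
})

test_that("disattenuation divides by the root product of reliabilities", {
  # construct totals with an exact Pearson correlation of 0.60
  x <- c(-2, -1, 0, 1, 2) / sqrt(2.5)
  e <- c(1, -1, 0, -1, 1); e <- e / sqrt(sum(e^2) / 4)
  y <- 0.6 * x + sqrt(1 - 0.36) * (e - mean(e))
  expect_equal(stats::cor(x, y), 0.6, tolerance = 1e-12)
  expect_equal(as.numeric(disattenuated_correlation(x, y, 0.8, 0.9)),
               0.6 / sqrt(0.72), tolerance = 1e-12)
  expect_equal(as.numeric(disattenuated_correlation(x, y, 1, 1)), 0.6,
               tolerance = 1e-12)
  flagged <- disattenuated_correlation(x, 2 * x + 1, 0.9, 0.9)
  expect_gt(as.numeric(flagged), 1)
  expect_true(attr(flagged, "flagged"))
  expect_error(disattenuated_correlation(x, y, 0, 0.9), "\\(0, 1\\]")
})

test_that("Loevinger's H is 1 for perfect Guttman data and matches the 2x2 case", {
  # deterministic double-monotone pattern
  g <- cbind(easy = rep(c(0, 1, 1, 1), 25), mid = rep(c(0, 0, 1, 1), 25),
             hard = rep(c(0, 0, 0, 1), 25))
  h <- loevinger_h(g)
  expect_equal(unname(h$h_item), rep(1, 3))
  expect_equal(h$h_scale, 1)
  # P(easy fail, hard pass) = 0.05 with marginals 0.6 / 0.4:
  # H = 1 - 0.05 / 0.16 = 0.6875
  tab <- rbind(matrix(c(1, 1), 35, 2, byrow = TRUE),
               matrix(c(1, 0), 25, 2, byrow = TRUE),
               matrix(c(0, 1), 5, 2, byrow = TRUE),
               matrix(c(0, 0), 35, 2, byrow = TRUE))
  colnames(tab) <- c("easy", "hard")
  expect_equal(loevinger_h(tab)$h_scale, 0.6875, tolerance = 1e-12)
  set.seed(9)
  ind <- matrix(sample(0:3, 5000 * 4, replace = TRUE), 5000, 4)
  expect_lt(max(abs(loevinger_h(ind)$h_item)), 0.05)
})

test_that("Q3 is symmetric with the small negative null bias", {
  bank <- oks_haas_bank()
  cohort <- generate_cohort(bank, cohort_config(
    n_persons = 3000, timepoints = 1, occasion_mean = 0,
    within_person_icc = 0, missingness = 0, seed = 301))
  q3 <- yen_q3(cohort$responses, bank)
  expect_true(all(is.na(diag(q3))))
  expect_identical(q3, t(q3))
  off <- q3[upper.tri(q3)]
  expect_lt(abs(mean(off) - (-1 / (nrow(bank) - 1))), 0.02)
  expect_true(all(off < 0.2))
})

test_that("a cloned item pair is the only one crossing the Q3 threshold", {
  bank <- oks_haas_bank()
  cohort <- generate_cohort(bank, cohort_config(
    n_persons = 1500, timepoints = 1, occasion_mean = 0,
    within_person_icc = 0, missingness = 0,
    local_dependence = list(items = c("oks_pain", "oks_nightpain"),
                            copy_prob = 0.9),
    seed = 302))
  q3 <- yen_q3(cohort$responses, bank)
  expect_gt(q3["oks_pain", "oks_nightpain"], 0.2)
  rest <- q3
  rest["oks_pain", "oks_nightpain"] <- NA
  rest["oks_nightpain", "oks_pain"] <- NA
  expect_true(all(rest[upper.tri(rest)] < 0.2, na.rm = TRUE))
})

test_that("DIF gains vanish when the groups carry identical data", {
  bank <- oks_haas_bank()
  cohort <- generate_cohort(bank, cohort_config(
    n_persons = 300, timepoints = 1, occasion_mean = 0,
    within_person_icc = 0, missingness = 0, seed = 303))
  df <- as.data.frame(cohort$responses)
  df2 <- rbind(df, df)
  df2$sex <- rep(c("A", "B"), each = nrow(df))
  df2$person_id <- seq_len(nrow(df2))
  dup <- response_matrix(df2, bank)
  res <- dif_scan(dup, bank, "oks_work", "sex")
  expect_lt(abs(res$delta_r2_uniform), 1e-9)
  expect_lt(abs(res$delta_r2_total), 1e-9)
  expect_false(res$flag)
})

test_that("DIF scans flag injected uniform DIF but not permuted labels", {
  bank <- oks_haas_bank()
  flags_null <- flags_dif <- logical(5)
  for (s in 1:5) {
    null_c <- generate_cohort(bank, cohort_config(
      n_persons = 2000, timepoints = 1, occasion_mean = 0,
      within_person_icc = 0, missingness = 0, seed = 400 + s))
    flags_null[s] <- dif_scan(null_c$responses, bank, "oks_work", "sex")$flag
    dif_c <- generate_cohort(bank, cohort_config(
      n_persons = 2000, timepoints = 1, occasion_mean = 0,
      within_person_icc = 0, missingness = 0,
      dif = list(item_id = "oks_work", shift = 0.5,
                 group = "sex", focal = "F"),
      seed = 500 + s))
    flags_dif[s] <- dif_scan(dif_c$responses, bank, "oks_work", "sex")$flag
  }
  expect_false(any(flags_null))
  expect_true(all(flags_dif))
})

test_that("DIF preconditions are enforced", {
  bank <- oks_haas_bank()
  cohort <- generate_cohort(bank, cohort_config(
    n_persons = 60, timepoints = 1, occasion_mean = 0,
    within_person_icc = 0, missingness = 0, seed = 71))
  expect_error(dif_scan(cohort$responses, bank, "oks_work", "sex"),
               ">= 50")
  expect_error(dif_scan(cohort$responses, bank, "nope", "sex"), "unknown")
})

test_that("Bland-Altman reports mean, SD and 1.96 limits", {
  expect_equal(bland_altman(c(1, 2, 3), c(1, 2, 3)),
               list(mean_diff = 0, sd_diff = 0, loa_low = 0, loa_high = 0,
                    n = 3L))
  ba <- bland_altman(c(0, 1, 2), c(1, 1, 1))   # differences -1, 0, 1
  expect_equal(ba$mean_diff, 0)
  expect_equal(ba$sd_diff, 1)
  expect_equal(ba$loa_low, -1.96)
  expect_equal(ba$loa_high, 1.96)
  shifted <- bland_altman(c(0, 1, 2) + 0.7, c(1, 1, 1))
  expect_equal(shifted$mean_diff, 0.7)
  expect_equal(shifted$loa_low, -1.96 + 0.7)
  expect_equal(shifted$loa_high, 1.96 + 0.7)
  expect_error(bland_altman(1, 1), ">= 2")
})

test_that("the assembled report is deterministic and serializes to JSON", {
  bank <- oks_haas_bank()
  cohort <- generate_cohort(bank, cohort_config(
    n_persons = 264, timepoints = 2, seed = 99))
  r1 <- grm_diagnostics(cohort$responses, bank, dif_groups = "sex")
  r2 <- grm_diagnostics(cohort$responses, bank, dif_groups = "sex")
  expect_identical(r1$alpha, r2$alpha)
  expect_identical(r1$q3, r2$q3)
  expect_identical(r1$flags, r2$flags)
  expect_s3_class(r1, "diagnostics_report")
  expect_true(all(unlist(r1$alpha) > 0.5))
  f <- tempfile(fileext = ".json")
  write_diagnostics_json(r1, f)
  parsed <- jsonlite::read_json(f)
  expect_named(parsed$flags, c("h_item_below_0.3", "q3_above_0.2",
                               "dif_flagged"), ignore.order = TRUE)
})
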