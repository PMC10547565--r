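#' Cronbach's alpha
#'
#' Internal consistency `k/(k-1) * (1 - sum(item variances) / variance
#' of the total score)` on listwise-complete cases, with `n - 1`
#' variance denominators.
#'
#' @param items Data frame or matrix of item scores (one instrument).
#' @return Alpha, or `NA` with a warning when the total-score variance
#'   is zero.
#' @export
cronbach_alpha <- function(items) {
  x <- as.matrix(items)
  x <- x[stats::complete.cases(x), , drop = FALSE]
  if (ncol(x) < 2L || nrow(x) < 2L)
    stop("alpha needs >= 2 items and >= 2 complete cases")
  k <- ncol(x)
  vt <- stats::var(rowSums(x))
  if (vt == 0) {
    warning("zero total-score variance; alpha undefined")
    return(NA_real_)
  }
  k / (k - 1) * (1 - sum(apply(x, 2L, stats::var)) / vt)
}

#' Disattenuated correlation of two sum scores
#'
#' The raw Pearson correlation divided by the square root of the
#' product of the two scales' reliabilities, mitigating attenuation by
#' measurement error. Values above 1 can arise from sampling error and
#' are returned as-is with a flag attribute.
#'
#' @param sum_a,sum_b Paired totals (pairs with missings dropped).
#' @param alpha_a,alpha_b Reliabilities in `(0, 1]`.
#' @return Correlation with attribute `flagged` (`TRUE` when > 1).
#' @export
disattenuated_correlation <- function(sum_a, sum_b, alpha_a, alpha_b) {
  if (alpha_a <= 0 || alpha_b <= 0)
    stop("reliabilities must be in (0, 1]")
  ok <- stats::complete.cases(sum_a, sum_b)
  r <- stats::cor(sum_a[ok], sum_b[ok]) / sqrt(alpha_a * alpha_b)
  structure(r, flagged = r > 1)
}

#' Loevinger's H scalability coefficients
#'
#' Mokken scalability in the covariance formulation: for an item pair,
#' `H_ij = cov(X_i, X_j) / cov_max`, where `cov_max` is the covariance
#' of the comonotone arrangement of the two observed marginals (the
#' maximum attainable given the marginals, i.e. zero Guttman error).
#' Item and scale coefficients aggregate numerators and denominators.
#'
#' @param items Data frame or matrix of ordinal item scores; listwise
#'   complete cases are used.
#' @return List: `h_item` (named per item), `h_pair` (matrix), `h_scale`.
#' @export
loevinger_h <- function(items) {
  x <- as.matrix(items)
  x <- x[stats::complete.cases(x), , drop = FALSE]
  k <- ncol(x)
  if (k < 2L) stop("H needs >= 2 items")
  num <- den <- matrix(NA_real_, k, k,
                       dimnames = list(colnames(x), colnames(x)))
  for (i in seq_len(k - 1L)) for (j in (i + 1L):k) {
    cv <- stats::cov(x[, i], x[, j])
    cvmax <- stats::cov(sort(x[, i]), sort(x[, j]))
    if (cvmax <= 0) {
      warning("pair (", colnames(x)[i], ", ", colnames(x)[j],
              ") has zero maximal covariance; excluded")
      next
    }
    num[i, j] <- num[j, i] <- cv
    den[i, j] <- den[j, i] <- cvmax
  }
  h_pair <- num / den
  h_item <- rowSums(num, na.rm = TRUE) / rowSums(den, na.rm = TRUE)
  h_scale <- sum(num[upper.tri(num)], na.rm = TRUE) /
    sum(den[upper.tri(den)], na.rm = TRUE)
  list(h_item = h_item, h_pair = h_pair, h_scale = h_scale)
}

#' Yen's Q3 residual correlations
#'
#' Screens local independence: each person's latent trait is estimated
#' by pattern EAP under the bank, residuals `x_pi - E[X_i | theta_p]`
#' are formed per item, and `Q3[i, j]` is the Pearson correlation of
#' the residuals of items i and j over the persons observing both.
#' Values above 0.2 conventionally suggest local dependence; under
#' local independence Q3 centres near `-1/(k-1)`.
#'
#' @param responses A [response_matrix()].
#' @param bank The [item_bank()].
#' @param grid A [quadrature_grid()] (default covers the bank).
#' @param min_pairs Minimum joint observations per cell (default 3).
#' @return Symmetric matrix with `NA` diagonal.
#' @export
yen_q3 <- function(responses, bank, grid = NULL, min_pairs = 3L) {
  if (is.null(grid)) grid <- default_grid_for_bank(bank)
  codes <- response_codes(responses, bank)
  keep <- rowSums(!is.na(codes)) >= 2L
  codes <- codes[keep, , drop = FALSE]
  scores <- score_cohort(responses[keep, , drop = FALSE], bank, grid,
                         "pattern_eap")
  theta <- scores$theta_hat
  k <- nrow(bank)
  resid <- matrix(NA_real_, nrow(codes), k,
                  dimnames = list(NULL, bank$item_id))
  for (i in seq_len(k)) {
    P <- category_probabilities(theta, bank[i, , drop = FALSE])
    expected <- as.vector(P %*% (seq_len(ncol(P)) - 1L))
    resid[, i] <- codes[, i] - expected
  }
  q3 <- matrix(NA_real_, k, k, dimnames = list(bank$item_id, bank$item_id))
  for (i in seq_len(k - 1L)) for (j in (i + 1L):k) {
    ok <- !is.na(resid[, i]) & !is.na(resid[, j])
    if (sum(ok) < min_pairs) next
    q3[i, j] <- q3[j, i] <- stats::cor(resid[ok, i], resid[ok, j])
  }
  q3
}

nagelkerke_r2 <- function(ll_model, ll_null, n) {
  (1 - exp(2 * (ll_null - ll_model) / n)) / (1 - exp(2 * ll_null / n))
}

#' Differential item functioning scan by ordinal logistic regression
#'
#' Fits proportional-odds models `response ~ matching score` (M0),
#' `+ group` (M1) and `+ group x score` (M2) and reports the Nagelkerke
#' pseudo-R-squared gains: `uniform = R2(M1) - R2(M0)` and
#' `total = R2(M2) - R2(M0)`. A total gain above `threshold` (default
#' 2%) flags the item. The matching variable is the total score over
#' all items on complete cases (`matching = "rest"` excludes the
#' studied item).
#'
#' @param responses A [response_matrix()].
#' @param bank The [item_bank()].
#' @param item_id Item under study.
#' @param group Binary grouping: the name of a metadata column
#'   (`"sex"`, `"age_group"`) or a vector of labels, two levels.
#' @param matching `"total"` (default) or `"rest"`.
#' @param threshold Flagging threshold on the total pseudo-R2 gain.
#' @param min_group Minimum persons per group (default 50).
#' @return List: `delta_r2_uniform`, `delta_r2_total`, `flag`,
#'   `converged`, `n`, plus a `message` when the fit failed.
#' @export
dif_scan <- function(responses, bank, item_id, group,
                     matching = c("total", "rest"), threshold = 0.02,
                     min_group = 50L) {
  matching <- match.arg(matching)
  i <- match(item_id, bank$item_id)
  if (is.na(i)) stop("unknown item_id '", item_id, "'")
  codes <- response_codes(responses, bank)
  g <- if (is.character(group) && length(group) == 1L)
    responses[[group]] else group
  ok <- stats::complete.cases(codes) & !is.na(g)
  codes <- codes[ok, , drop = FALSE]
  g <- factor(g[ok])
  if (nlevels(g) != 2L) stop("group must have exactly 2 levels")
  if (any(table(g) < min_group))
    stop("each group needs >= ", min_group, " persons (have ",
         paste(table(g), collapse = ", "), ")")
  score <- rowSums(codes)
  if (matching == "rest") score <- score - codes[, i]
  y <- factor(codes[, i], levels = sort(unique(codes[, i])), ordered = TRUE)
  n <- length(y)
  if (nlevels(y) < 2L)
    return(list(delta_r2_uniform = NA_real_, delta_r2_total = NA_real_,
                flag = FALSE, converged = FALSE, n = n,
                message = "item has a single observed category"))
  d <- data.frame(y = y, score = score, g = g)
  fit_ll <- function(formula) {
    m <- MASS::polr(formula, data = d, method = "logistic", Hess = FALSE)
    as.numeric(stats::logLik(m))
  }
  res <- tryCatch({
    ll_null <- fit_ll(y ~ 1)
    ll0 <- fit_ll(y ~ score)
    ll1 <- fit_ll(y ~ score + g)
    ll2 <- fit_ll(y ~ score * g)
    r2 <- vapply(c(ll0, ll1, ll2), nagelkerke_r2, numeric(1),
                 ll_null = ll_null, n = n)
    list(delta_r2_uniform = r2[2] - r2[1],
         delta_r2_total = r2[3] - r2[1],
         flag = (r2[3] - r2[1]) > threshold,
         converged = TRUE, n = n, message = NULL)
  }, error = function(e)
    list(delta_r2_uniform = NA_real_, delta_r2_total = NA_real_,
         flag = FALSE, converged = FALSE, n = n,
         message = conditionMessage(e)))
  res
}

#' Bland-Altman agreement of paired scores
#'
#' Differences are `scores_a - scores_b`; reports their mean, SD
#' (`n - 1` denominator), and the 95% limits of agreement
#' `mean +/- 1.96 SD`.
#'
#' @param scores_a,scores_b Paired measurements on a common scale.
#' @return List: `mean_diff`, `sd_diff`, `loa_low`, `loa_high`, `n`.
#' @export
bland_altman <- function(scores_a, scores_b) {
  ok <- stats::complete.cases(scores_a, scores_b)
  d <- scores_a[ok] - scores_b[ok]
  if (length(d) < 2L) stop("Bland-Altman needs >= 2 complete pairs")
  m <- mean(d)
  s <- stats::sd(d)
  list(mean_diff = m, sd_diff = s,
       loa_low = m - 1.96 * s, loa_high = m + 1.96 * s, n = length(d))
}

#' Run the full assumption-testing and agreement battery
#'
#' Convenience wrapper assembling, for a paired two-instrument response
#' matrix: per-instrument Cronbach's alpha, the disattenuated
#' sum-score correlation, Loevinger's H over all items, Yen's Q3, DIF
#' scans of every item by the requested grouping variables, and
#' Bland-Altman agreement of the two instruments' common-scale scores
#' (each instrument scored by its own summed-score EAP table). A flat
#' `flags` element mirrors the conventional thresholds (H_i > 0.3
#' required, Q3 > 0.2 and pseudo-R2 gain > 2% flagged).
#'
#' @param responses A [response_matrix()] covering both instruments.
#' @param bank The combined [item_bank()].
#' @param grid A [quadrature_grid()] (default covers the bank).
#' @param dif_groups Metadata columns to scan for DIF (default
#'   `c("sex", "age_group")`); set `NULL` to skip.
#' @param dif_min_group Group-size floor passed to [dif_scan()].
#' @return List of class `diagnostics_report`.
#' @export
grm_diagnostics <- function(responses, bank, grid = NULL,
                            dif_groups = c("sex", "age_group"),
                            dif_min_group = 50L) {
  if (is.null(grid)) grid <- default_grid_for_bank(bank)
  insts <- unique(bank$instrument)
  codes <- response_codes(responses, bank)
  alpha <- list()
  sums <- list()
  for (ins in insts) {
    cols <- bank$item_id[bank$instrument == ins]
    alpha[[ins]] <- cronbach_alpha(codes[, cols, drop = FALSE])
    cc <- codes[, cols, drop = FALSE]
    s <- rowSums(cc)
    sums[[ins]] <- s                       # NA unless instrument complete
  }
  dis <- if (length(insts) == 2L)
    disattenuated_correlation(sums[[1]], sums[[2]],
                              alpha[[1]], alpha[[2]]) else NULL
  h <- loevinger_h(codes)
  q3 <- yen_q3(responses, bank, grid)
  dif <- list()
  for (grp in dif_groups) for (id in bank$item_id) {
    res <- tryCatch(dif_scan(responses, bank, id, grp,
                             min_group = dif_min_group),
                    error = function(e)
                      list(delta_r2_uniform = NA_real_,
                           delta_r2_total = NA_real_, flag = FALSE,
                           converged = FALSE, n = 0L,
                           message = conditionMessage(e)))
    dif[[paste(id, grp, sep = ".")]] <- res
  }
  ba <- NULL
  if (length(insts) == 2L) {
    sc <- lapply(insts, function(ins) {
      sub <- bank_subset(bank, ins)
      score_cohort(responses, sub, method = "summed_eap")$theta_hat
    })
    ba <- tryCatch(bland_altman(sc[[1]], sc[[2]]), error = function(e) NULL)
  }
  off <- q3[upper.tri(q3)]
  flags <- list(
    h_item_below_0.3 = names(h$h_item)[!is.na(h$h_item) & h$h_item <= 0.3],
    q3_above_0.2 = sum(off > 0.2, na.rm = TRUE),
    dif_flagged = names(Filter(function(z) isTRUE(z$flag), dif)))
  structure(list(alpha = alpha, disattenuated_r = dis,
                 loevinger = h, q3 = q3, dif = dif, bland_altman = ba,
                 flags = flags),
            class = "diagnostics_report")
}

#' @export
print.diagnostics_report <- function(x, ...) {
  cat("IRT assumption-testing battery\n")
  for (ins in names(x$alpha))
    cat(sprintf("  alpha[%s] = %.3f\n", ins, x$alpha[[ins]]))
  if (!is.null(x$disattenuated_r))
    cat(sprintf("  disattenuated r = %.3f%s\n", x$disattenuated_r,
                if (isTRUE(attr(x$disattenuated_r, "flagged")))
                  " (FLAG: > 1)" else ""))
  cat(sprintf("  scale H = %.3f; %d item(s) with H_i <= 0.3\n",
              x$loevinger$h_scale, length(x$flags$h_item_below_0.3)))
  cat(sprintf("  Q3 pairs > 0.2: %d (max %.3f)\n", x$flags$q3_above_0.2,
              max(x$q3, na.rm = TRUE)))
  cat(sprintf("  DIF flags: %s\n",
              if (length(x$flags$dif_flagged))
                paste(x$flags$dif_flagged, collapse = ", ") else "none"))
  if (!is.null(x$bland_altman))
    cat(sprintf("  Bland-Altman: mean %.3f, LoA [%.3f, %.3f]\n",
                x$bland_altman$mean_diff, x$bland_altman$loa_low,
                x$bland_altman$loa_high))
  invisible(x)
}

#' Serialize a diagnostics report as JSON
#' @param report A [grm_diagnostics()] result.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_diagnostics_json <- function(report, path) {
  out <- list(
    package_version = as.character(utils::packageVersion("kneemetric")),
    alpha = report$alpha,
    disattenuated_r = as.numeric(report$disattenuated_r),
    disattenuated_flag = isTRUE(attr(report$disattenuated_r, "flagged")),
    h_item = as.list(report$loevinger$h_item),
    h_scale = report$loevinger$h_scale,
    q3 = report$q3,
    dif = report$dif,
    bland_altman = report$bland_altman,
    flags = report$flags)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  invisible(path)
}
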