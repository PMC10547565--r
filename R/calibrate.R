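#' Calibration configuration
#'
#' Settings for [grm_calibrate()]: quadrature, EM stopping rules, the
#' policy for unobserved categories on free items, and whether the
#' latent density of the calibration sample is estimated alongside the
#' free items (identified because the anchors fix the metric).
#'
#' @param n_nodes,range,prior_mean,prior_sd Quadrature grid spec; see
#'   [quadrature_grid()].
#' @param max_cycles Maximum EM cycles (default 500).
#' @param tol_loglik Convergence tolerance on the marginal log-likelihood
#'   change (default 1e-6).
#' @param tol_param Convergence tolerance on the largest parameter change
#'   (default 1e-4).
#' @param estimate_density If `TRUE`, profile-update a normal latent
#'   density (mean, SD) each cycle; if `FALSE` the density stays at the
#'   prior.
#' @param unobserved `"merge"` collapses unobserved categories of free
#'   items into their lower neighbour (with a warning); `"error"` stops.
#' @param seed Optional integer recorded with the fit.
#' @return List of class `calibration_config`.
#' @export
calibration_config <- function(n_nodes = 61L, range = c(-6, 6),
                               prior_mean = 0, prior_sd = 1,
                               max_cycles = 500L,
                               tol_loglik = 1e-6, tol_param = 1e-4,
                               estimate_density = FALSE,
                               unobserved = c("merge", "error"),
                               seed = NULL) {
  stopifnot(tol_loglik > 0, tol_param > 0, max_cycles >= 1L)
  structure(list(n_nodes = n_nodes, range = range,
                 prior_mean = prior_mean, prior_sd = prior_sd,
                 max_cycles = as.integer(max_cycles),
                 tol_loglik = tol_loglik, tol_param = tol_param,
                 estimate_density = isTRUE(estimate_density),
                 unobserved = match.arg(unobserved), seed = seed),
            class = "calibration_config")
}

# collapse unobserved categories of one item's codes; returns the recoded
# vector, new K, and for each new threshold the index of the original one
collapse_categories <- function(x, K) {
  obs <- sort(unique(x[!is.na(x)]))
  if (length(obs) == length(seq_len(K) - 1L) && all(obs == seq_len(K) - 1L))
    return(list(x = x, K = K, boundary_map = seq_len(K - 1L),
                collapsed = FALSE))
  recode <- vapply(0:(K - 1L), function(cat) {
    below <- obs[obs <= cat]
    if (!length(below)) 0L else match(below[length(below)], obs) - 1L
  }, integer(1))
  list(x = ifelse(is.na(x), NA_integer_, recode[x + 1L]),
       K = length(obs),
       boundary_map = obs[-1L],  # new boundary j <=> original boundary obs[j+1]
       collapsed = TRUE)
}

# natural <-> working parameterization (log a, b1, log increments)
pars_to_working <- function(a, b) {
  if (length(b) == 1L) c(log(a), b) else c(log(a), b[1], log(diff(b)))
}
working_to_pars <- function(w) {
  a <- exp(w[1])
  b <- if (length(w) == 2L) w[2] else cumsum(c(w[2], exp(w[-(1:2)])))
  list(a = a, b = b)
}

# expected complete-data negative log-likelihood of one free item
item_mstep_obj <- function(w, N, nodes) {
  p <- working_to_pars(w)
  P <- category_probabilities(nodes, list(a = p$a, b = p$b))
  -sum(N * log(pmax(P, PROB_FLOOR)))
}

start_values <- function(x, K) {
  # thresholds at normal quantiles of observed cumulative proportions
  x <- x[!is.na(x)]
  p_lt <- vapply(seq_len(K - 1L), function(k) mean(x < k), numeric(1))
  b <- stats::qnorm(pmin(pmax(p_lt, 0.01), 0.99))
  for (k in seq_along(b)[-1])          # enforce strict increase
    if (b[k] <= b[k - 1]) b[k] <- b[k - 1] + 0.1
  list(a = 1, b = b)
}

#' Fixed-parameter (anchored) graded response model calibration
#'
#' Estimates the free items of a bank by marginal maximum likelihood
#' with an EM algorithm while anchor items (`fixed = TRUE`) keep their
#' published parameters untouched, placing the free items on the
#' anchors' established latent metric. The E-step computes each
#' person-occasion's posterior over the quadrature grid under the
#' current parameters; the M-step maximizes each free item's expected
#' complete-data log-likelihood with thresholds kept strictly ordered by
#' a log-increment reparameterization. The marginal log-likelihood is
#' non-decreasing across cycles. Repeated measures are treated as
#' independent rows.
#'
#' @param responses A [response_matrix()] covering the bank's items.
#' @param bank An [item_bank()] whose `fixed` column marks the anchors;
#'   free items' parameters serve only as layout (their `a`/`b` values
#'   are replaced by starting values).
#' @param config A [calibration_config()].
#' @return Object of class `grm_calibration`: the estimated `bank`
#'   (anchors bitwise unchanged), `loglik`, the per-cycle `trace`,
#'   `cycles`, `converged`, the fitted latent `density`, any category
#'   `collapse` records, and the inputs needed by the methods.
#' @seealso [parameter_standard_errors()], [summed_score_eap_table()]
#' @examples
#' bank <- oks_haas_bank()
#' cohort <- generate_cohort(bank, cohort_config(n_persons = 150,
#'                                               timepoints = 1, seed = 1))
#' fit <- grm_calibrate(cohort$responses, bank,
#'                      calibration_config(max_cycles = 30))
#' coef(fit)
#' @export
grm_calibrate <- function(responses, bank, config = calibration_config()) {
  stopifnot(inherits(config, "calibration_config"))
  codes <- response_codes(responses, bank)
  free <- which(!bank$fixed)
  anchors <- which(bank$fixed)
  if (length(anchors) && !any(!is.na(codes[, anchors])))
    stop("no responses observed on any anchor item; the metric is not identified")
  grid <- quadrature_grid(config$n_nodes, config$range,
                          config$prior_mean, config$prior_sd)
  nq <- length(grid$nodes)
  n <- nrow(codes)

  # category collapse on free items
  collapse <- list()
  K_free <- integer(0)
  for (i in free) {
    cc <- collapse_categories(codes[, i], bank$n_categories[i])
    if (cc$collapsed) {
      if (config$unobserved == "error")
        stop("item '", bank$item_id[i],
             "' has unobserved categories; collapse or merge them first")
      warning("item '", bank$item_id[i], "': ",
              bank$n_categories[i] - cc$K,
              " unobserved categor", if (bank$n_categories[i] - cc$K > 1L)
                "ies" else "y", " merged into lower neighbour")
      codes[, i] <- cc$x
    }
    collapse[[bank$item_id[i]]] <- cc[c("K", "boundary_map", "collapsed")]
  }
  for (i in free)
    if (length(unique(codes[!is.na(codes[, i]), i])) < 2L)
      stop("item '", bank$item_id[i], "' has fewer than 2 observed categories")

  # anchor contribution to the log-likelihood matrix is constant
  ll_anchor <- if (length(anchors))
    loglik_matrix(codes[, anchors, drop = FALSE],
                  bank[anchors, , drop = FALSE], grid$nodes)
  else matrix(0, nq, n)

  # starting values
  est <- list()
  for (i in free)
    est[[bank$item_id[i]]] <- start_values(codes[, i],
                                           collapse[[bank$item_id[i]]]$K)

  free_ll <- function() {
    ll <- ll_anchor
    for (i in free) {
      e <- est[[bank$item_id[i]]]
      logP <- log(pmax(category_probabilities(grid$nodes, e), PROB_FLOOR))
      x <- codes[, i]; obs <- which(!is.na(x))
      ll[, obs] <- ll[, obs] + logP[, x[obs] + 1L, drop = FALSE]
    }
    ll
  }

  w <- grid$weights
  density <- c(mean = config$prior_mean, sd = config$prior_sd)
  trace <- numeric(0)
  converged <- FALSE
  cycle <- 0L
  marginal <- function(ll) {
    mx <- apply(ll, 2L, max)
    sum(log(colSums(w * exp(sweep(ll, 2L, mx)))) + mx)
  }
  ll <- free_ll()
  trace <- marginal(ll)

  while (cycle < config$max_cycles) {
    cycle <- cycle + 1L
    # E-step: normalized posterior over nodes, per person
    lw <- sweep(ll, 2L, apply(ll, 2L, max))
    post <- w * exp(lw)
    post <- sweep(post, 2L, colSums(post), "/")
    max_delta <- 0
    # M-step: each free item separately
    for (i in free) {
      id <- bank$item_id[i]
      x <- codes[, i]; obs <- which(!is.na(x))
      K <- collapse[[id]]$K
      N <- vapply(seq_len(K) - 1L, function(k) {
        sel <- obs[x[obs] == k]
        if (length(sel)) rowSums(post[, sel, drop = FALSE]) else numeric(nq)
      }, numeric(nq))
      w0 <- pars_to_working(est[[id]]$a, est[[id]]$b)
      opt <- stats::optim(w0, item_mstep_obj, N = N, nodes = grid$nodes,
                          method = "BFGS",
                          control = list(maxit = 50, reltol = 1e-10))
      new <- working_to_pars(opt$par)
      max_delta <- max(max_delta, abs(new$a - est[[id]]$a),
                       abs(new$b - est[[id]]$b))
      est[[id]] <- new
    }
    # optional profile update of the latent normal density
    if (config$estimate_density) {
      mass <- rowSums(post) / n
      mu <- sum(mass * grid$nodes)
      sigma <- sqrt(max(sum(mass * grid$nodes^2) - mu^2, 1e-6))
      max_delta <- max(max_delta, abs(mu - density["mean"]),
                       abs(sigma - density["sd"]))
      density <- c(mean = mu, sd = sigma)
      w <- stats::dnorm(grid$nodes, mu, sigma)
      w <- w / sum(w)
    }
    ll <- free_ll()
    trace <- c(trace, marginal(ll))
    nt <- length(trace)
    if (trace[nt] < trace[nt - 1L] - 1e-8)
      warning("marginal log-likelihood decreased at cycle ", cycle)
    if (abs(trace[nt] - trace[nt - 1L]) < config$tol_loglik &&
        max_delta < config$tol_param) {
      converged <- TRUE
      break
    }
  }
  if (!converged)
    warning("EM did not converge in ", config$max_cycles, " cycles")

  # assemble the estimated bank; anchor rows are copied untouched
  out_bank <- as.data.frame(bank)
  for (i in free) {
    id <- bank$item_id[i]
    out_bank$a[i] <- est[[id]]$a
    out_bank$n_categories[i] <- collapse[[id]]$K
    bvals <- rep(NA_real_, MAX_THRESHOLDS)
    bvals[seq_along(est[[id]]$b)] <- est[[id]]$b
    out_bank[i, THRESHOLD_COLS] <- as.list(bvals)
  }
  out_bank <- item_bank(out_bank, metadata = "fixed-parameter calibration fit")

  structure(list(bank = out_bank, input_bank = bank, codes = codes,
                 grid = structure(list(nodes = grid$nodes, weights = w,
                                       prior_mean = unname(density["mean"]),
                                       prior_sd = unname(density["sd"])),
                                  class = "quadrature_grid"),
                 loglik = trace[length(trace)], trace = trace,
                 cycles = cycle, converged = converged,
                 density = density, collapse = collapse,
                 se = NULL, config = config, call = match.call()),
            class = "grm_calibration")
}

#' @export
print.grm_calibration <- function(x, ...) {
  free <- !x$bank$fixed
  cat("Fixed-parameter graded response model calibration\n")
  cat(sprintf("  %d anchor + %d free items, %d person-occasions\n",
              sum(!free), sum(free), nrow(x$codes)))
  cat(sprintf("  marginal log-likelihood %.4f after %d EM cycles (%s)\n",
              x$loglik, x$cycles,
              if (x$converged) "converged" else "NOT converged"))
  if (x$config$estimate_density)
    cat(sprintf("  latent density: N(%.3f, %.3f^2)\n",
                x$density["mean"], x$density["sd"]))
  invisible(x)
}

#' @export
coef.grm_calibration <- function(object, free_only = TRUE, ...) {
  bank <- object$bank
  rows <- if (free_only) which(!bank$fixed) else seq_len(nrow(bank))
  out <- list()
  for (i in rows) {
    b <- item_thresholds(bank, i)
    v <- c(bank$a[i], b)
    names(v) <- paste(bank$item_id[i], c("a", paste0("b", seq_along(b))),
                      sep = ".")
    out[[length(out) + 1L]] <- v
  }
  unlist(out)
}

#' @export
logLik.grm_calibration <- function(object, ...) {
  free <- which(!object$bank$fixed)
  df <- sum(object$bank$n_categories[free]) # a + (K-1) thresholds per item
  if (object$config$estimate_density) df <- df + 2L
  structure(object$loglik, df = df, nobs = nrow(object$codes),
            class = "logLik")
}

#' @export
summary.grm_calibration <- function(object, ...) {
  if (is.null(object$se)) object$se <- parameter_standard_errors(object)
  structure(list(fit = object, se = object$se),
            class = "summary.grm_calibration")
}

#' @export
print.summary.grm_calibration <- function(x, ...) {
  print(x$fit)
  cat("\nFree item estimates (block-diagonal observed-information SEs):\n")
  print(x$se, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Observed-information standard errors for free item parameters
#'
#' Numerically differentiates the marginal log-likelihood with respect
#' to each free item's parameters at the estimates, one item block at a
#' time (cross-item blocks ignored). A singular block yields `NA` SEs
#' with a flag rather than a fabricated value. Anchored items have no
#' sampling variability and receive no rows.
#'
#' @param fit A [grm_calibrate()] result.
#' @return Data frame: `item_id`, `parameter`, `estimate`, `se`,
#'   `singular`.
#' @export
parameter_standard_errors <- function(fit) {
  bank <- fit$bank
  codes <- fit$codes
  grid <- fit$grid
  free <- which(!bank$fixed)
  others_ll <- function(i) {
    keep <- setdiff(seq_len(nrow(bank)), i)
    loglik_matrix(codes[, keep, drop = FALSE], bank[keep, , drop = FALSE],
                  grid$nodes)
  }
  out <- NULL
  for (i in free) {
    base_ll <- others_ll(i)
    x <- codes[, i]; obs <- which(!is.na(x))
    K <- bank$n_categories[i]
    mar <- function(par) {
      a <- par[1]; b <- par[-1]
      if (a <= 0 || any(diff(b) <= 0)) return(-1e10)
      logP <- log(pmax(category_probabilities(grid$nodes,
                                              list(a = a, b = b)),
                       PROB_FLOOR))
      ll <- base_ll
      ll[, obs] <- ll[, obs] + logP[, x[obs] + 1L, drop = FALSE]
      mx <- apply(ll, 2L, max)
      sum(log(colSums(grid$weights * exp(sweep(ll, 2L, mx)))) + mx)
    }
    par <- c(bank$a[i], item_thresholds(bank, i))
    H <- -pracma::hessian(mar, par)
    se <- rep(NA_real_, length(par))
    singular <- TRUE
    cov <- tryCatch(solve(H), error = function(e) NULL)
    if (!is.null(cov) && all(diag(cov) > 0)) {
      se <- sqrt(diag(cov))
      singular <- FALSE
    }
    out <- rbind(out, data.frame(
      item_id = bank$item_id[i],
      parameter = c("a", paste0("b", seq_len(K - 1L))),
      estimate = par, se = se, singular = singular))
  }
  rownames(out) <- NULL
  out
}

#' @export
predict.grm_calibration <- function(object, newdata = NULL,
                                    method = c("pattern_eap", "summed_eap"),
                                    ...) {
  method <- match.arg(method)
  if (is.null(newdata)) {
    newdata <- as.data.frame(object$codes)
    newdata$person_id <- seq_len(nrow(newdata))
    newdata$timepoint <- 1L
    newdata <- response_matrix(newdata, object$bank)
  }
  score_cohort(newdata, object$bank, object$grid, method)
}

#' @export
simulate.grm_calibration <- function(object, nsim = 1, seed = NULL,
                                     n_persons = nrow(object$codes), ...) {
  if (is.null(seed)) seed <- 1L
  lapply(seq_len(nsim), function(s) {
    generate_cohort(object$bank,
                    cohort_config(n_persons = n_persons, timepoints = 1,
                                  occasion_mean = object$density["mean"],
                                  occasion_sd = object$density["sd"],
                                  missingness = 0, seed = seed + s - 1L))
  })
}

#' @export
plot.grm_calibration <- function(x, theta = seq(-6, 6, length.out = 121),
                                 ...) {
  insts <- unique(x$bank$instrument)
  total <- test_information(theta, x$bank)
  graphics::plot(theta, total, type = "l", lwd = 2, col = "red",
                 xlab = "knee health (logits)", ylab = "test information",
                 main = "Test information", ...)
  cols <- c("blue", "orange", "darkgreen", "purple")
  for (j in seq_along(insts))
    graphics::lines(theta,
                    test_information(theta, bank_subset(x$bank, insts[j])),
                    col = cols[(j - 1L) %% length(cols) + 1L])
  graphics::legend("topright", legend = c("combined", insts), lwd = c(2, rep(1, length(insts))),
                   col = c("red", cols[seq_along(insts)]), bty = "n")
  invisible(x)
}

#' Write a calibration report as JSON
#'
#' Serializes estimates, standard errors, the log-likelihood trace, the
#' configuration echo and seed to structured text; the estimated bank
#' itself goes through [write_item_bank()].
#'
#' @param fit A [grm_calibrate()] result.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_calibration_report <- function(fit, path) {
  if (is.null(fit$se)) fit$se <- parameter_standard_errors(fit)
  report <- list(
    package_version = as.character(utils::packageVersion("kneemetric")),
    config = unclass(fit$config),
    seed = fit$config$seed,
    converged = fit$converged,
    cycles = fit$cycles,
    marginal_loglik = fit$loglik,
    loglik_trace = fit$trace,
    latent_density = as.list(fit$density),
    estimates = fit$se,
    collapsed_items = names(Filter(function(z) z$collapsed, fit$collapse)))
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  invisible(path)
}
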