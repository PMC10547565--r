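#' Quadrature grid over the latent trait
#'
#' Equally spaced nodes with weights proportional to a normal prior
#' density, renormalized to sum to one. The latent trait ("knee health")
#' lives on the logit scale fixed by the anchor calibration, so a
#' standard normal prior corresponds to the anchor population.
#'
#' @param n_nodes Number of nodes (default 61).
#' @param range Length-2 numeric, node range in logits (default `c(-6, 6)`).
#' @param prior_mean,prior_sd Normal prior parameters (default 0, 1).
#' @return Object of class `quadrature_grid` with elements `nodes`,
#'   `weights`, `prior_mean`, `prior_sd`.
#' @export
quadrature_grid <- function(n_nodes = 61L, range = c(-6, 6),
                            prior_mean = 0, prior_sd = 1) {
  stopifnot(n_nodes >= 2L, length(range) == 2L, range[1] < range[2],
            prior_sd > 0)
  nodes <- seq(range[1], range[2], length.out = n_nodes)
  w <- stats::dnorm(nodes, prior_mean, prior_sd)
  structure(list(nodes = nodes, weights = w / sum(w),
                 prior_mean = prior_mean, prior_sd = prior_sd),
            class = "quadrature_grid")
}

#' @export
print.quadrature_grid <- function(x, ...) {
  cat(sprintf("Quadrature grid: %d nodes on [%.3g, %.3g], N(%.3g, %.3g) prior\n",
              length(x$nodes), min(x$nodes), max(x$nodes),
              x$prior_mean, x$prior_sd))
  invisible(x)
}

# Grid for a bank whose thresholds may exceed the default range: extend to
# [min(b) - 4, max(b) + 2] so posteriors for extreme sum scores are covered.
default_grid_for_bank <- function(bank, n_nodes = 61L,
                                  prior_mean = 0, prior_sd = 1) {
  b <- unlist(lapply(seq_len(nrow(bank)), function(i) item_thresholds(bank, i)))
  lo <- min(-6, min(b) - 4)
  hi <- max(6, max(b) + 2)
  quadrature_grid(n_nodes, c(lo, hi), prior_mean, prior_sd)
}

# internal parameter view of a one-row bank (or a list with a/b)
as_grm_pars <- function(item) {
  if (inherits(item, "item_bank") || is.data.frame(item)) {
    stopifnot(nrow(item) == 1L)
    list(a = item$a[1], b = item_thresholds(item, 1L),
         K = item$n_categories[1])
  } else {
    list(a = item$a, b = item$b, K = length(item$b) + 1L)
  }
}

PROB_FLOOR <- 1e-300

# cumulative boundary curves P(X >= k | theta) for k = 1..K-1,
# returned as length(theta) x (K-1); vectorized over theta
grm_pstar <- function(theta, a, b) {
  out <- matrix(0, length(theta), length(b))
  for (k in seq_along(b)) out[, k] <- stats::plogis(a * (theta - b[k]))
  out
}

#' Cumulative category probability of a graded item
#'
#' The graded response model boundary curve
#' \eqn{P(X \ge k \mid \theta) = \mathrm{logistic}(a(\theta - b_k))}
#' on the logit metric (no 1.7 scaling constant).
#'
#' @param theta Latent trait value(s), logits.
#' @param item A one-row [item_bank()] (or `list(a=, b=)`).
#' @param k Boundary index, `1 <= k <= K - 1`.
#' @return Probabilities in (0, 1), one per `theta`.
#' @export
cumulative_probability <- function(theta, item, k) {
  p <- as_grm_pars(item)
  if (length(k) != 1L || k < 1L || k > p$K - 1L)
    stop("boundary index k must lie in 1..", p$K - 1L)
  stats::plogis(p$a * (theta - p$b[k]))
}

#' Category probabilities of a graded item
#'
#' Adjacent differences of the cumulative boundary curves:
#' \eqn{P_k = P^*_k - P^*_{k+1}} with \eqn{P^*_0 = 1}, \eqn{P^*_K = 0}.
#' Categories are coded 0-based, so column `k + 1` holds the probability
#' of response code `k`.
#'
#' @inheritParams cumulative_probability
#' @return `length(theta) x K` matrix; rows sum to 1.
#' @export
category_probabilities <- function(theta, item) {
  p <- as_grm_pars(item)
  ps <- cbind(1, grm_pstar(theta, p$a, p$b), 0)
  out <- ps[, seq_len(p$K), drop = FALSE] -
    ps[, seq_len(p$K) + 1L, drop = FALSE]
  dimnames(out) <- list(NULL, paste0("cat", seq_len(p$K) - 1L))
  out
}

# per-item list of node x K category probability matrices
bank_category_probs <- function(bank, theta) {
  lapply(seq_len(nrow(bank)), function(i)
    category_probabilities(theta, bank[i, , drop = FALSE]))
}

#' Log-likelihood of one response vector at a latent trait value
#'
#' Sums log category probabilities over the non-missing responses of one
#' person; missing responses (NA) contribute nothing (ignorable
#' missingness). Probabilities are floored at 1e-300 before taking logs.
#'
#' @param responses Integer codes, `0..K_i - 1` or `NA`, in bank item order.
#' @param bank An [item_bank()].
#' @param theta Latent trait value(s), logits.
#' @return Log-likelihood, one value per `theta`; 0 if all responses missing.
#' @export
response_loglikelihood <- function(responses, bank, theta) {
  check_codes(responses, bank)
  ll <- numeric(length(theta))
  for (i in seq_len(nrow(bank))) {
    x <- responses[i]
    if (is.na(x)) next
    P <- category_probabilities(theta, bank[i, , drop = FALSE])
    ll <- ll + log(pmax(P[, x + 1L], PROB_FLOOR))
  }
  ll
}

check_codes <- function(responses, bank) {
  if (length(responses) != nrow(bank))
    stop("expected ", nrow(bank), " responses, got ", length(responses))
  bad <- which(!is.na(responses) &
                 (responses < 0L | responses > bank$n_categories - 1L |
                    responses != floor(responses)))
  if (length(bad))
    stop("invalid response code ", responses[bad[1]], " for item '",
         bank$item_id[bad[1]], "' (categories 0..",
         bank$n_categories[bad[1]] - 1L, ")")
  invisible(TRUE)
}

#' Fisher information of a graded item
#'
#' \eqn{I(\theta) = \sum_k (P_k')^2 / P_k} with
#' \eqn{P_k' = a [P^*_k (1 - P^*_k) - P^*_{k+1}(1 - P^*_{k+1})]};
#' equals the negative expected second derivative of the log-likelihood.
#'
#' @inheritParams cumulative_probability
#' @return Nonnegative information, one value per `theta`.
#' @export
item_information <- function(theta, item) {
  p <- as_grm_pars(item)
  ps <- cbind(1, grm_pstar(theta, p$a, p$b), 0)
  dps <- p$a * ps * (1 - ps)                 # derivative of each boundary
  P <- ps[, seq_len(p$K), drop = FALSE] - ps[, seq_len(p$K) + 1L, drop = FALSE]
  dP <- dps[, seq_len(p$K), drop = FALSE] - dps[, seq_len(p$K) + 1L, drop = FALSE]
  rowSums(dP^2 / pmax(P, PROB_FLOOR))
}

#' Test information of an item bank
#'
#' Item informations are additive under local independence, so test
#' information is their sum; an empty bank carries zero information.
#'
#' @param theta Latent trait value(s), logits.
#' @param bank An [item_bank()] (possibly instrument-restricted).
#' @return Nonnegative information, one value per `theta`.
#' @export
test_information <- function(theta, bank) {
  info <- numeric(length(theta))
  for (i in seq_len(nrow(bank)))
    info <- info + item_information(theta, bank[i, , drop = FALSE])
  info
}

#' Marginal reliability implied by an information level
#'
#' The approximation `reliability = 1 - 1/information`, under which an
#' information level of 5.0 corresponds to a marginal reliability of
#' 0.80 (the conventional floor for group-level measurement) and 9.8 to
#' roughly 0.90 (individual-level precision).
#'
#' @param info Positive information level(s).
#' @return Reliability in `(-Inf, 1)`.
#' @export
reliability_from_information <- function(info) {
  if (any(!is.finite(info) | info <= 0))
    stop("information must be strictly positive")
  1 - 1 / info
}
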