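# shared fixtures and independent oracles, built in code

toy_bank_234 <- function() {
  item_bank(rbind(
    as.data.frame(graded_item("t2", "TOY", a = 1.2, b = 0.3)),
    as.data.frame(graded_item("t3", "TOY", a = 0.8, b = c(-1.0, 0.8))),
    as.data.frame(graded_item("t4", "TOY", a = 1.5, b = c(-1.5, 0.2, 1.7)))))
}

random_bank <- function(n_items, max_cat = 5L, instrument = "RND") {
  rows <- lapply(seq_len(n_items), function(i) {
    K <- sample(2:max_cat, 1L)
    as.data.frame(graded_item(paste0("r", i), instrument,
                              a = stats::runif(1, 0.5, 2.5),
                              b = sort(stats::rnorm(K - 1L, 0, 1.5))))
  })
  item_bank(do.call(rbind, rows))
}

# brute-force sum-score likelihoods by enumerating every response pattern
enumerate_sum_scores <- function(bank, grid) {
  cats <- lapply(bank$n_categories, function(K) 0:(K - 1L))
  patterns <- as.matrix(expand.grid(cats))
  n_scores <- sum(bank$n_categories - 1L) + 1L
  out <- matrix(0, n_scores, length(grid$nodes))
  probs <- lapply(seq_len(nrow(bank)), function(i)
    category_probabilities(grid$nodes, bank[i, , drop = FALSE]))
  for (r in seq_len(nrow(patterns))) {
    p <- rep(1, length(grid$nodes))
    for (i in seq_len(ncol(patterns)))
      p <- p * probs[[i]][, patterns[r, i] + 1L]
    s <- sum(patterns[r, ])
    out[s + 1L, ] <- out[s + 1L, ] + p
  }
  out
}

# finite-difference Fisher information: -E[d^2/dtheta^2 log P_X(theta)]
fd_item_information <- function(theta, item, h = 1e-3) {
  P0 <- category_probabilities(theta, item)
  Pp <- category_probabilities(theta + h, item)
  Pm <- category_probabilities(theta - h, item)
  d2 <- (log(Pp) - 2 * log(P0) + log(Pm)) / h^2
  -rowSums(P0 * d2)
}

# complete-case response matrix from a raw code matrix
codes_to_responses <- function(codes, bank) {
  df <- data.frame(person_id = seq_len(nrow(codes)), timepoint = 1L)
  df <- cbind(df, as.data.frame(codes))
  names(df)[-(1:2)] <- bank$item_id
  response_matrix(df, bank)
}

oks_bank <- function() bank_subset(oks_haas_bank(), "OKS")
haas_bank <- function() bank_subset(oks_haas_bank(), "HAAS")

# truth bank re-expressed in the category layout a fit collapsed to,
# keeping the true parameter values of the retained boundaries
collapse_truth_bank <- function(bank, fit) {
  df <- as.data.frame(bank)
  for (id in names(fit$collapse)) {
    cc <- fit$collapse[[id]]
    i <- match(id, df$item_id)
    b <- kneemetric:::item_thresholds(bank, i)[cc$boundary_map]
    df$n_categories[i] <- cc$K
    vals <- rep(NA_real_, 6L)
    vals[seq_along(b)] <- b
    df[i, kneemetric:::THRESHOLD_COLS] <- as.list(vals)
  }
  item_bank(df)
}
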