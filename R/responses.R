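RESPONSE_META_COLS <- c("person_id", "timepoint", "age_group", "sex")

#' Construct a response matrix bound to an item bank
#'
#' One row per person-occasion; metadata columns `person_id`,
#' `timepoint`, `age_group`, `sex` followed by one integer column per
#' bank item (0-based category codes, `NA` = missing), in bank order.
#'
#' @param data Data frame with the metadata and item columns.
#' @param bank The [item_bank()] whose items the columns encode.
#' @return Object of class `response_matrix`.
#' @export
response_matrix <- function(data, bank) {
  data <- as.data.frame(data, stringsAsFactors = FALSE)
  missing_meta <- setdiff(c("person_id", "timepoint"), names(data))
  if (length(missing_meta))
    stop("response matrix needs metadata columns: ",
         paste(missing_meta, collapse = ", "))
  for (col in setdiff(RESPONSE_META_COLS, names(data))) data[[col]] <- NA
  missing_items <- setdiff(bank$item_id, names(data))
  if (length(missing_items))
    stop("response matrix is missing item columns: ",
         paste(missing_items, collapse = ", "))
  key <- paste(data$person_id, data$timepoint, sep = "\r")
  if (anyDuplicated(key))
    stop("duplicate (person_id, timepoint) rows")
  for (i in seq_len(nrow(bank))) {
    id <- bank$item_id[i]
    x <- data[[id]]
    bad <- which(!is.na(x) & (x < 0 | x > bank$n_categories[i] - 1L |
                                x != floor(x)))
    if (length(bad))
      stop("row ", bad[1], ", item '", id, "': code ", x[bad[1]],
           " outside 0..", bank$n_categories[i] - 1L)
    data[[id]] <- as.integer(x)
  }
  data <- data[, c(RESPONSE_META_COLS, bank$item_id)]
  rownames(data) <- NULL
  structure(data, item_ids = bank$item_id,
            class = c("response_matrix", "data.frame"))
}

#' @export
print.response_matrix <- function(x, ...) {
  ids <- attr(x, "item_ids")
  cat("Response matrix: ", nrow(x), " person-occasions x ", length(ids),
      " items; ", sum(is.na(as.matrix(x[, ids]))), " missing cells\n", sep = "")
  print(utils::head(as.data.frame(x), 6))
  if (nrow(x) > 6) cat("... (", nrow(x) - 6, " more rows)\n", sep = "")
  invisible(x)
}

# integer matrix of codes, persons x items, in bank order
response_codes <- function(responses, bank) {
  as.matrix(as.data.frame(responses)[, bank$item_id, drop = FALSE])
}

#' Read a response matrix from delimited text
#' @param path CSV path (empty cells = missing).
#' @param bank The [item_bank()] defining the item columns.
#' @return A [response_matrix()].
#' @export
read_responses <- function(path, bank) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  response_matrix(raw, bank)
}

#' Write a response matrix as delimited text
#' @param responses A [response_matrix()].
#' @param path Output CSV path; missing cells are written empty.
#' @return `path`, invisibly.
#' @export
write_responses <- function(responses, path) {
  utils::write.csv(as.data.frame(responses), path, row.names = FALSE, na = "")
  invisible(path)
}

# node x person matrix of response log-likelihoods (missing ignored)
loglik_matrix <- function(codes, bank, nodes) {
  ll <- matrix(0, length(nodes), nrow(codes))
  probs <- bank_category_probs(bank, nodes)
  for (i in seq_len(ncol(codes))) {
    x <- codes[, i]
    obs <- which(!is.na(x))
    if (!length(obs)) next
    logP <- log(pmax(probs[[i]], PROB_FLOOR))
    ll[, obs] <- ll[, obs] + logP[, x[obs] + 1L, drop = FALSE]
  }
  ll
}
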