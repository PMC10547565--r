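#' @keywords internal
"_PACKAGE"

MAX_THRESHOLDS <- 6L
THRESHOLD_COLS <- paste0("b", seq_len(6L))
BANK_COLS <- c("item_id", "instrument", "n_categories", "a",
               THRESHOLD_COLS, "fixed")

#' Construct a graded response model item
#'
#' A graded item is defined by a positive discrimination `a` and `K - 1`
#' strictly increasing difficulty thresholds (logits), where `K` is the
#' number of ordered response categories. The `fixed` flag marks anchor
#' items whose parameters are frozen during calibration.
#'
#' @param item_id Unique item label.
#' @param instrument Instrument label, e.g. `"OKS"` or `"HAAS"`.
#' @param a Discrimination (logit slope), strictly positive.
#' @param b Numeric vector of `K - 1` strictly increasing thresholds.
#' @param fixed Logical; `TRUE` for anchor items.
#' @return A one-row [item_bank()].
#' @examples
#' graded_item("oks_walking", "OKS", a = 1.330,
#'             b = c(-1.920, -1.103, 0.675, 2.323), fixed = TRUE)
#' @export
graded_item <- function(item_id, instrument, a, b, fixed = FALSE) {
  b <- as.numeric(b)
  if (length(b) < 1L || length(b) > MAX_THRESHOLDS)
    stop("item '", item_id, "': between 1 and ", MAX_THRESHOLDS,
         " thresholds are supported")
  row <- data.frame(item_id = as.character(item_id),
                    instrument = as.character(instrument),
                    n_categories = length(b) + 1L,
                    a = as.numeric(a),
                    stringsAsFactors = FALSE)
  for (j in seq_len(MAX_THRESHOLDS))
    row[[THRESHOLD_COLS[j]]] <- if (j <= length(b)) b[j] else NA_real_
  row$fixed <- isTRUE(fixed)
  item_bank(row)
}

#' Construct and validate an item bank
#'
#' An item bank is a data frame with one row per graded item and columns
#' `item_id`, `instrument`, `n_categories`, `a`, `b1`..`b6` (unused
#' threshold cells `NA`) and `fixed`. Row order is the canonical column
#' order for response matrices scored against the bank.
#'
#' @param items Data frame in the bank layout (extra columns are dropped).
#' @param metadata Optional free-text provenance string.
#' @return Object of class `item_bank`.
#' @export
item_bank <- function(items, metadata = NULL) {
  items <- as.data.frame(items, stringsAsFactors = FALSE)
  missing_cols <- setdiff(BANK_COLS, names(items))
  if (length(missing_cols))
    stop("item bank is missing columns: ", paste(missing_cols, collapse = ", "))
  items <- items[, BANK_COLS]
  items$item_id <- as.character(items$item_id)
  items$instrument <- as.character(items$instrument)
  items$n_categories <- as.integer(items$n_categories)
  items$fixed <- as.logical(items$fixed)
  if (anyDuplicated(items$item_id))
    stop("duplicate item_id: ",
         paste(unique(items$item_id[duplicated(items$item_id)]), collapse = ", "))
  for (i in seq_len(nrow(items))) {
    id <- items$item_id[i]
    K <- items$n_categories[i]
    if (is.na(K) || K < 2L)
      stop("item '", id, "': n_categories must be an integer >= 2")
    if (!is.finite(items$a[i]) || items$a[i] <= 0)
      stop("item '", id, "': discrimination must be > 0")
    b <- as.numeric(items[i, THRESHOLD_COLS])
    if (sum(!is.na(b)) != K - 1L)
      stop("item '", id, "': expected ", K - 1L,
           " thresholds but found ", sum(!is.na(b)))
    b <- b[!is.na(b)]
    if (any(!is.finite(b)))
      stop("item '", id, "': thresholds must be finite")
    if (K > 2L && any(diff(b) <= 0))
      stop("item '", id, "': thresholds must be strictly increasing")
  }
  rownames(items) <- NULL
  structure(items, metadata = metadata,
            class = c("item_bank", "data.frame"))
}

#' @export
print.item_bank <- function(x, ...) {
  cat("Item bank: ", nrow(x), " items (",
      paste(sprintf("%s: %d", names(table(x$instrument)),
                    as.integer(table(x$instrument))), collapse = ", "),
      "), ", sum(x$fixed), " anchored\n", sep = "")
  meta <- attr(x, "metadata")
  if (!is.null(meta)) cat("  ", meta, "\n", sep = "")
  print.data.frame(x, digits = 4)
  invisible(x)
}

item_thresholds <- function(bank, i) {
  b <- as.numeric(bank[i, THRESHOLD_COLS])
  b[!is.na(b)]
}

bank_item <- function(bank, item) {
  if (is.character(item)) {
    i <- match(item, bank$item_id)
    if (is.na(i)) stop("unknown item_id '", item, "'")
    item <- i
  }
  item_bank(bank[item, , drop = FALSE], metadata = attr(bank, "metadata"))
}

#' Restrict a bank to one instrument
#' @param bank An [item_bank()].
#' @param instrument Instrument label present in the bank.
#' @return The sub-bank, in the original item order.
#' @export
bank_subset <- function(bank, instrument) {
  keep <- bank$instrument == instrument
  if (!any(keep)) stop("no items for instrument '", instrument, "'")
  item_bank(bank[keep, , drop = FALSE], metadata = attr(bank, "metadata"))
}

#' Read an item bank from delimited text
#'
#' Expects CSV with header `item_id, instrument, n_categories, a, b1..b6,
#' fixed`; empty cells mark unused thresholds. Validation failures name
#' the offending item.
#'
#' @param path CSV file path.
#' @return An [item_bank()].
#' @export
read_item_bank <- function(path) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  for (col in THRESHOLD_COLS)
    if (!col %in% names(raw)) raw[[col]] <- NA_real_
  item_bank(raw, metadata = paste0("read from ", basename(path)))
}

#' Write an item bank as delimited text
#' @param bank An [item_bank()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_item_bank <- function(bank, path) {
  out <- as.data.frame(bank)
  utils::write.csv(out, path, row.names = FALSE, na = "")
  invisible(path)
}

#' The published OKS-HAAS anchor bank
#'
#' Loads the packaged point estimates of the published graded response
#' model calibration of the 12 OKS items (anchored, from the NHS PROMs
#' registry) and the 4 HAAS items (estimated against that anchor). The
#' OKS items carry 5 response categories each; the HAAS items carry 7
#' (activity level), 5 (running), 6 (walking) and 4 (stair climbing).
#'
#' @return An [item_bank()] with 16 items; OKS rows have `fixed = TRUE`.
#' @examples
#' bank <- oks_haas_bank()
#' nrow(bank)                     # 16
#' sum(bank$n_categories - 1)     # 66 boundary curves
#' @export
oks_haas_bank <- function() {
  path <- system.file("extdata", "oks_haas_bank.csv", package = "kneemetric",
                      mustWork = TRUE)
  bank <- read_item_bank(path)
  attr(bank, "metadata") <- "published OKS anchor + HAAS calibration, point estimates"
  bank
}
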