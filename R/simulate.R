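#' Cohort simulation configuration
#'
#' Describes a paired-instrument arthroplasty-like cohort: persons
#' observed at several occasions, with a latent "knee health" shift
#' between the baseline and post-operative occasions, within-person
#' dependence through a shared person effect, item-level missingness,
#' and optional injected differential item functioning (DIF) or local
#' dependence (LD).
#'
#' Defaults emulate the registry-and-trial setting the package targets:
#' 528 persons, 7 occasions, baseline latent distribution N(-1, 1) and
#' post-operative occasions N(+1, 1), HAAS item missingness 4-6% and
#' OKS item missingness 2%, and an intraclass correlation of 0.5
#' between occasions of the same person.
#'
#' @param n_persons Number of persons (>= 1).
#' @param timepoints Number of occasions per person.
#' @param occasion_mean Latent mean per occasion; default -1 at the
#'   first occasion and +1 afterwards. Recycled to `timepoints`.
#' @param occasion_sd Latent SD per occasion (recycled).
#' @param within_person_icc Share of occasion variance carried by the
#'   person effect, in `[0, 1]`; 0 makes occasions independent.
#' @param missingness `NULL` for the per-item defaults, a single rate,
#'   or a named vector by `item_id`.
#' @param dif Optional `list(item_id=, shift=, group=, focal=)`: the
#'   focal group's copy of that item has all thresholds shifted by
#'   `shift` logits (`group` is `"sex"` or `"age_group"`).
#' @param local_dependence Optional `list(items = c(id1, id2),
#'   copy_prob=)`, applied by [inject_local_dependence()].
#' @param seed Mandatory integer seed.
#' @return List of class `cohort_config`.
#' @export
cohort_config <- function(n_persons = 528L, timepoints = 7L,
                          occasion_mean = NULL, occasion_sd = 1,
                          within_person_icc = 0.5,
                          missingness = NULL, dif = NULL,
                          local_dependence = NULL, seed) {
  if (missing(seed) || is.null(seed)) stop("a seed is mandatory")
  stopifnot(n_persons >= 1L, timepoints >= 1L,
            within_person_icc >= 0, within_person_icc <= 1)
  if (is.null(occasion_mean))
    occasion_mean <- if (timepoints == 1L) 0 else c(-1, rep(1, timepoints - 1L))
  occasion_mean <- rep_len(occasion_mean, timepoints)
  occasion_sd <- rep_len(occasion_sd, timepoints)
  stopifnot(all(occasion_sd > 0))
  if (!is.null(missingness) && is.null(names(missingness)))
    stopifnot(length(missingness) == 1L, missingness >= 0, missingness <= 1)
  structure(list(n_persons = as.integer(n_persons),
                 timepoints = as.integer(timepoints),
                 occasion_mean = occasion_mean, occasion_sd = occasion_sd,
                 within_person_icc = within_person_icc,
                 missingness = missingness, dif = dif,
                 local_dependence = local_dependence,
                 seed = as.integer(seed)),
            class = "cohort_config")
}

# per-item missing rates mirroring typical paired OKS/HAAS completeness
default_missingness <- function(bank) {
  rate <- ifelse(bank$instrument == "HAAS", 0.05, 0.02)
  special <- c(haas_activity = 0.06, haas_running = 0.05,
               haas_walking = 0.04, haas_stairs = 0.04)
  hit <- bank$item_id %in% names(special)
  rate[hit] <- special[bank$item_id[hit]]
  stats::setNames(rate, bank$item_id)
}

resolve_missingness <- function(bank, missingness) {
  if (is.null(missingness)) return(default_missingness(bank))
  if (is.null(names(missingness)))
    return(stats::setNames(rep(missingness, nrow(bank)), bank$item_id))
  out <- default_missingness(bank)
  out[names(missingness)] <- missingness
  out
}

draw_categories <- function(theta, item) {
  P <- category_probabilities(theta, item)
  cum <- t(apply(P, 1L, cumsum))
  u <- stats::runif(length(theta))
  as.integer(rowSums(cum < u))
}

#' Generate a synthetic paired-instrument cohort with known truth
#'
#' Draws each person-occasion's latent trait from the configured
#' occasion distribution (sharing a person effect across occasions),
#' draws item responses from the graded response model, and applies
#' completely-at-random missingness per item. Fully reproducible from
#' the config seed.
#'
#' @param bank An [item_bank()].
#' @param config A [cohort_config()].
#' @return List: `responses` (a [response_matrix()]), `thetas` (data
#'   frame `person_id`, `timepoint`, `theta`), and the echoed `config`.
#' @export
generate_cohort <- function(bank, config) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(config$seed)
  n <- config$n_persons
  tp <- config$timepoints
  rate <- resolve_missingness(bank, config$missingness)

  person_id <- sprintf("P%04d", seq_len(n))
  age_group <- sample(c("<60", ">=60"), n, replace = TRUE,
                      prob = c(0.28, 0.72))
  sex <- sample(c("M", "F"), n, replace = TRUE, prob = c(0.58, 0.42))
  z <- stats::rnorm(n)                         # shared person effect

  icc <- config$within_person_icc
  rows <- expand.grid(t = seq_len(tp), p = seq_len(n))[, c("p", "t")]
  e <- stats::rnorm(nrow(rows))
  theta <- config$occasion_mean[rows$t] +
    config$occasion_sd[rows$t] * (sqrt(icc) * z[rows$p] + sqrt(1 - icc) * e)

  banks <- list(ref = bank)
  focal_rows <- rep(FALSE, nrow(rows))
  if (!is.null(config$dif)) {
    d <- config$dif
    pair <- inject_dif(bank, d$item_id, d$shift)
    banks$focal <- pair$focal
    grp <- if (identical(d$group, "age_group")) age_group else sex
    focal_rows <- grp[rows$p] == d$focal
  }

  codes <- matrix(NA_integer_, nrow(rows), nrow(bank),
                  dimnames = list(NULL, bank$item_id))
  for (i in seq_len(nrow(bank))) {
    x <- integer(nrow(rows))
    ref <- !focal_rows
    if (any(ref))
      x[ref] <- draw_categories(theta[ref], banks$ref[i, , drop = FALSE])
    if (any(focal_rows))
      x[focal_rows] <- draw_categories(theta[focal_rows],
                                       banks$focal[i, , drop = FALSE])
    x[stats::runif(nrow(rows)) < rate[bank$item_id[i]]] <- NA_integer_
    codes[, i] <- x
  }

  df <- data.frame(person_id = person_id[rows$p], timepoint = rows$t,
                   age_group = age_group[rows$p], sex = sex[rows$p],
                   stringsAsFactors = FALSE)
  df <- cbind(df, as.data.frame(codes))
  responses <- response_matrix(df, bank)
  if (!is.null(config$local_dependence)) {
    ld <- config$local_dependence
    responses <- inject_local_dependence(responses, ld$items, ld$copy_prob,
                                         bank = bank)
  }
  list(responses = responses,
       thetas = data.frame(person_id = person_id[rows$p],
                           timepoint = rows$t, theta = theta,
                           stringsAsFactors = FALSE),
       config = config)
}

#' Inject uniform DIF into an item bank
#'
#' Returns a reference/focal bank pair in which the focal group's copy
#' of one item has every threshold shifted by `group_shift` logits
#' (positive shift = the item is uniformly harder for the focal group
#' at any given trait level).
#'
#' @param bank An [item_bank()].
#' @param item_id Item to shift.
#' @param group_shift Shift in logits; 0 returns identical banks.
#' @return List with elements `reference` and `focal`.
#' @export
inject_dif <- function(bank, item_id, group_shift) {
  i <- match(item_id, bank$item_id)
  if (is.na(i)) stop("unknown item_id '", item_id, "'")
  focal <- as.data.frame(bank)
  used <- !is.na(as.numeric(focal[i, THRESHOLD_COLS]))
  focal[i, THRESHOLD_COLS[used]] <-
    as.numeric(focal[i, THRESHOLD_COLS[used]]) + group_shift
  list(reference = bank,
       focal = item_bank(focal, metadata = attr(bank, "metadata")))
}

#' Inject local dependence by response copying
#'
#' With probability `copy_prob` per person-occasion, the second item's
#' response is replaced by the first item's (both items must share the
#' same number of categories), creating residual dependence beyond the
#' latent trait.
#'
#' @param responses A [response_matrix()].
#' @param item_pair Character vector of two item ids.
#' @param copy_prob Copy probability in `[0, 1]`.
#' @param bank Optional [item_bank()]; when given, the two items'
#'   category counts are checked for equality.
#' @return The modified [response_matrix()].
#' @export
inject_local_dependence <- function(responses, item_pair, copy_prob,
                                    bank = NULL) {
  stopifnot(length(item_pair) == 2L, copy_prob >= 0, copy_prob <= 1)
  ids <- attr(responses, "item_ids")
  if (!all(item_pair %in% ids))
    stop("unknown item(s): ",
         paste(setdiff(item_pair, ids), collapse = ", "))
  if (!is.null(bank)) {
    K <- bank$n_categories[match(item_pair, bank$item_id)]
    if (K[1] != K[2])
      stop("items '", item_pair[1], "' and '", item_pair[2],
           "' have different category counts (", K[1], " vs ", K[2], ")")
  }
  x1 <- responses[[item_pair[1]]]
  x2 <- responses[[item_pair[2]]]
  if (copy_prob == 0) return(responses)
  copy <- stats::runif(nrow(responses)) < copy_prob & !is.na(x1)
  x2[copy] <- x1[copy]
  responses[[item_pair[2]]] <- x2
  responses
}
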