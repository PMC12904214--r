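# Training-cohort fixture: 89 prospectively studied adults with ptosis and/or
# diplopia suspicious of OMG (39 with a final OMG diagnosis).  Counts are
# stored per OMG stratum (per OMG x age stratum for the AChR antibody test,
# whose sensitivity is strongly age-dependent).  The AChR split by age is not
# published as a joint table; the values below are the unique integer split
# consistent with the published margins (33/39 positive among OMG-positive,
# 2/50 among OMG-negative, age margins 10/13/16 and 15/17/18) and the
# reported 27/29 sensitivity in the over-50s, and are flagged "derived".

.training_strata <- function() {
  list(
    age = list(parents = "omg",
               states = c("18-50", "50-70", "70+"),
               counts = rbind(negative = c(15, 17, 18),
                              positive = c(10, 13, 16)),
               missing = c(negative = 0, positive = 0),
               provenance = "printed"),
    sex = list(parents = "omg",
               states = c("male", "female"),
               counts = rbind(negative = c(18, 32),
                              positive = c(23, 16)),
               missing = c(negative = 0, positive = 0),
               provenance = "printed"),
    diplopia = list(parents = "omg",
                    states = c("negative", "positive"),
                    counts = rbind(negative = c(14, 36),
                                   positive = c(15, 24)),
                    missing = c(negative = 0, positive = 0),
                    provenance = "printed"),
    ptosis = list(parents = "omg",
                  states = c("negative", "positive"),
                  counts = rbind(negative = c(19, 31),
                                 positive = c(10, 29)),
                  missing = c(negative = 0, positive = 0),
                  provenance = "printed"),
    achr = list(parents = c("omg", "age"),
                states = c("negative", "positive"),
                counts = rbind("negative.18-50" = c(15, 0),
                               "negative.50-70" = c(17, 0),
                               "negative.70+"   = c(16, 2),
                               "positive.18-50" = c(4, 6),
                               "positive.50-70" = c(1, 12),
                               "positive.70+"   = c(1, 15)),
                missing = c(negative = 0, positive = 0),
                provenance = "derived"),
    upgaze = list(parents = "omg",
                  states = c("negative", "positive"),
                  counts = rbind(negative = c(32, 14),
                                 positive = c(13, 25)),
                  missing = c(negative = 4, positive = 1),
                  provenance = "printed"),
    ice = list(parents = "omg",
               states = c("negative", "positive"),
               counts = rbind(negative = c(21, 9),
                              positive = c(8, 13)),
               missing = c(negative = 20, positive = 18),
               provenance = "printed"),
    besinger = list(parents = "omg",
                    states = c("-1to1", "1to4", "4to8", "8to24"),
                    counts = rbind(negative = c(5, 25, 18, 2),
                                   positive = c(5, 14, 16, 4)),
                    missing = c(negative = 0, positive = 0),
                    provenance = "printed"),
    edrophonium = list(parents = "omg",
                       states = c("negative", "positive"),
                       counts = rbind(negative = c(36, 4),
                                      positive = c(2, 29)),
                       missing = c(negative = 10, positive = 8),
                       provenance = "printed"),
    rns = list(parents = "omg",
               states = c("negative", "positive"),
               counts = rbind(negative = c(42, 8),
                              positive = c(14, 23)),
               missing = c(negative = 0, positive = 2),
               provenance = "printed"),
    sfemg = list(parents = "omg",
                 states = c("negative", "positive"),
                 counts = rbind(negative = c(28, 22),
                                positive = c(9, 27)),
                 missing = c(negative = 0, positive = 3),
                 provenance = "printed")
  )
}

.training_outcome <- c(negative = 50, positive = 39)

#' The packaged training-cohort fixture
#'
#' Per-variable counts of the 89-patient training cohort (50 OMG-negative,
#' 39 OMG-positive), stratified by OMG status (by OMG and age bin for the
#' AChR antibody test) and including the number of missing examinations per
#' stratum.  Each variable carries a provenance flag: `"printed"` for counts
#' taken directly from the published table, `"derived"` for the AChR-by-age
#' split reconstructed from published margins.
#'
#' @return An object of class `omg_fixture`.
#' @seealso [omg_training_counts()], [expand_fixture()]
#' @export
omg_training_fixture <- function() {
  structure(list(outcome_counts = .training_outcome,
                 strata = .training_strata()),
            class = "omg_fixture")
}

#' @export
print.omg_fixture <- function(x, ...) {
  cat("Training fixture:", sum(x$outcome_counts), "records (",
      x$outcome_counts[["negative"]], "OMG-negative,",
      x$outcome_counts[["positive"]], "OMG-positive )\n")
  prov <- vapply(x$strata, `[[`, character(1), "provenance")
  cat("Variables:", paste(names(x$strata), collapse = ", "), "\n")
  cat("Derived rows:", paste(names(prov)[prov == "derived"], collapse = ", "),
      "\n")
  invisible(x)
}

#' Training-cohort sufficient statistics
#'
#' The fixture's counts rearranged into the per-CPT `omg_counts` layout of
#' [count_records()] for a given network (default network by default): the
#' ground truth that [expand_fixture()] record sets reproduce.
#'
#' @param fixture Fixture from [omg_training_fixture()].
#' @param network Target network structure.
#' @return An `omg_counts` object.
#' @export
omg_training_counts <- function(fixture = omg_training_fixture(),
                                network = omg_default_network()) {
  stopifnot(inherits(fixture, "omg_fixture"), inherits(network, "omg_network"))
  outcome <- network$outcome
  oc_states <- network$variables[[outcome]]$states
  res <- lapply(network$variables, function(spec) {
    v <- spec$name
    st <- fixture$strata[[v]]
    if (v == outcome) {
      # outcome CPT row counts come from the stratified table of its parent
      stopifnot(length(spec$parents) == 1L)
      pa <- fixture$strata[[spec$parents]]
      arr <- array(0L, dim = c(length(oc_states), length(pa$states)),
                   dimnames = stats::setNames(list(oc_states, pa$states),
                                              c(v, spec$parents)))
      for (s in oc_states) arr[s, ] <- as.integer(pa$counts[s, ])
    } else if (length(spec$parents) == 0L) {
      tot <- colSums(st$counts)
      arr <- array(as.integer(tot), dim = length(st$states),
                   dimnames = stats::setNames(list(st$states), v))
    } else if (identical(st$parents, "omg") &&
               identical(spec$parents, outcome)) {
      arr <- array(0L, dim = c(length(st$states), length(oc_states)),
                   dimnames = stats::setNames(list(st$states, oc_states),
                                              c(v, outcome)))
      for (s in oc_states) arr[, s] <- as.integer(st$counts[s, ])
    } else {
      # stratified by two parents (achr: omg x age)
      stopifnot(setequal(st$parents, spec$parents))
      dims <- stats::setNames(
        c(list(st$states),
          lapply(st$parents, function(p) network$variables[[p]]$states)),
        c(v, st$parents))
      arr <- array(0L, dim = unname(lengths(dims)), dimnames = dims)
      for (rn in rownames(st$counts)) {
        parts <- strsplit(rn, ".", fixed = TRUE)[[1L]]
        arr[, parts[1L], parts[2L]] <- as.integer(st$counts[rn, ])
      }
      if (!identical(st$parents, spec$parents))
        arr <- aperm(arr, c(v, spec$parents))
    }
    structure(list(variable = v, counts = arr, n_used = sum(arr)),
              class = "omg_count_table")
  })
  structure(res, class = "omg_counts")
}

#' Expand the training fixture into one admissible record set
#'
#' Emits a record set whose per-CPT complete-case counts equal the fixture's
#' counts exactly.  Because only margins within OMG strata (and OMG-by-age
#' strata for AChR) are published, the joint distribution across tests is not
#' identified: the expansion fixes each variable's values within its stratum
#' and is one admissible reconstruction, not the true patient records.
#' Multi-test summaries computed from it are therefore illustrative only.
#'
#' @param fixture Fixture from [omg_training_fixture()].
#' @param seed Optional integer; when given, value-to-record assignment is
#'   shuffled within each stratum (margins are unchanged).  `NULL` gives a
#'   canonical deterministic block assignment.
#' @param network Network supplying the column order and state spaces.
#' @return A record data.frame with `sum(outcome counts)` rows.
#' @examples
#' recs <- expand_fixture()
#' nrow(recs)                     # 89
#' sum(recs$omg == "positive")    # 39
#' @export
expand_fixture <- function(fixture = omg_training_fixture(), seed = NULL,
                           network = omg_default_network()) {
  stopifnot(inherits(fixture, "omg_fixture"))
  if (!is.null(seed)) {
    old <- get_rng_state()
    on.exit(restore_rng_state(old))
    set.seed(seed)
  }
  oc <- fixture$outcome_counts
  omg <- rep(names(oc), oc)
  n <- length(omg)
  df <- data.frame(omg = omg, stringsAsFactors = FALSE)

  stratum_values <- function(st, row) {
    vals <- c(rep(st$states, st$counts[row, ]),
              rep(NA_character_, if (row %in% names(st$missing)) st$missing[[row]] else 0L))
    if (!is.null(seed)) vals <- sample(vals) else vals
  }

  for (v in names(fixture$strata)) {
    st <- fixture$strata[[v]]
    col <- rep(NA_character_, n)
    if (identical(st$parents, "omg")) {
      for (s in names(oc)) {
        idx <- which(omg == s)
        vals <- stratum_values(st, s)
        if (length(vals) != length(idx))
          stop("fixture counts for '", v, "', stratum '", s,
               "' are inconsistent with the cohort size", call. = FALSE)
        col[idx] <- vals
      }
    } else {
      # stratified by omg and a previously assigned variable (achr: omg x age)
      other <- setdiff(st$parents, "omg")
      stopifnot(length(other) == 1L, other %in% names(df))
      for (rn in rownames(st$counts)) {
        parts <- strsplit(rn, ".", fixed = TRUE)[[1L]]
        idx <- which(omg == parts[1L] & df[[other]] == parts[2L])
        vals <- rep(st$states, st$counts[rn, ])
        if (!is.null(seed)) vals <- sample(vals)
        if (length(vals) != length(idx))
          stop("fixture counts for '", v, "', stratum '", rn,
               "' are inconsistent with the stratum size", call. = FALSE)
        col[idx] <- vals
      }
    }
    df[[v]] <- col
  }
  validate_records(df, network)
}

#' Training-cohort records (one admissible expansion)
#'
#' Convenience wrapper: `expand_fixture(omg_training_fixture(), seed)`.
#'
#' @inheritParams expand_fixture
#' @return A record data.frame with 89 rows.
#' @export
omg_training_records <- function(seed = NULL) {
  expand_fixture(omg_training_fixture(), seed = seed)
}

#' Per-variable missingness of the training cohort
#'
#' Fraction of the 89 training records in which each examination is missing;
#' usable as `missing_rates` for [generate_cohort()] to emulate the training
#' data's missing-value pattern.
#'
#' @param fixture Fixture from [omg_training_fixture()].
#' @return Named numeric vector of missing fractions in `[0, 1]`.
#' @export
omg_training_missing_rates <- function(fixture = omg_training_fixture()) {
  n <- sum(fixture$outcome_counts)
  rates <- vapply(fixture$strata, function(st) sum(st$missing) / n, numeric(1))
  c(rates, omg = 0)
}
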