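# Rank-based AUC (Mann-Whitney with mid-ranks, i.e. ties count one half).
auc_midrank <- function(scores, is_positive) {
  np <- sum(is_positive)
  nn <- sum(!is_positive)
  if (np == 0L || nn == 0L) return(NA_real_)
  r <- rank(scores)
  (sum(r[is_positive]) - np * (np + 1) / 2) / (np * nn)
}

#' Evaluate a fitted model on records for one predictor set
#'
#' Restricts to records complete with respect to the predictor set and the
#' outcome, scores each record by the median posterior probability of the
#' positive outcome given only the predictor-set evidence, classifies at the
#' strict 50% threshold, and reports the misclassification rate and the
#' rank-based AUC (ties counted one half).
#'
#' @param fit An `omg_fit`.
#' @param records Record data.frame.
#' @param predictors Non-empty character vector of predictor variables
#'   (must exclude the outcome).
#' @param n_samples Posterior draws per distinct evidence pattern.
#' @param seed Integer seed (default 20160101); `NULL` consumes the current
#'   RNG stream.
#' @return An `omg_validation` report: `predictor_set`, `n_cases`,
#'   `error_rate`, `auc`, plus per-record `scores`.
#' @examples
#' fit <- fit_network(omg_training_counts())
#' evaluate_predictors(fit, omg_training_records(), "achr")
#' @export
evaluate_predictors <- function(fit, records, predictors,
                                n_samples = 10000, seed = 20160101) {
  stopifnot(inherits(fit, "omg_fit"))
  net <- fit$network
  records <- validate_records(records, net)
  predictors <- unique(as.character(predictors))
  if (length(predictors) == 0L)
    stop("predictor set must be non-empty", call. = FALSE)
  unknown <- setdiff(predictors, variable_names(net))
  if (length(unknown))
    stop("unknown predictor(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  if (net$outcome %in% predictors)
    stop("the outcome cannot be a predictor", call. = FALSE)
  need <- c(predictors, net$outcome)
  complete <- !Reduce(`|`, lapply(records[need], is.na))
  sub <- records[complete, , drop = FALSE]
  if (nrow(sub) == 0L)
    stop("no records are complete for predictor set {",
         paste(predictors, collapse = ", "), "}", call. = FALSE)
  keys <- apply(sub[predictors], 1L, paste, collapse = "\r")
  uniq <- sort(unique(keys))
  medians <- with_seed(seed, {
    vapply(uniq, function(k) {
      i <- match(k, keys)
      ev <- stats::setNames(unlist(sub[i, predictors, drop = FALSE]),
                            predictors)
      p <- posterior_query_draws(fit, ev, net$outcome,
                                 n_samples)[, net$positive_state]
      stats::median(p)
    }, numeric(1))
  })
  score <- medians[match(keys, uniq)]
  actual <- sub[[net$outcome]] == net$positive_state
  predicted <- score > 0.5
  structure(list(predictor_set = predictors,
                 n_cases = nrow(sub),
                 error_rate = mean(predicted != actual),
                 auc = auc_midrank(score, actual),
                 per_fold = NULL,
                 scores = data.frame(score = unname(score),
                                     actual = sub[[net$outcome]],
                                     classified = ifelse(predicted,
                                                         net$positive_state,
                                                         "negative"),
                                     stringsAsFactors = FALSE)),
            class = "omg_validation")
}

#' k-fold cross-validation of a predictor set
#'
#' Restricts to records complete for the predictor set and the outcome,
#' partitions them into `k` near-equal folds by a seeded random permutation
#' (unstratified), refits the network on the remaining folds and evaluates
#' the held-out fold.  Folds containing a single outcome class contribute to
#' the mean error but are skipped in the mean AUC.
#'
#' @param records Record data.frame.
#' @param predictors Predictor variable names.
#' @param network Network structure to refit per fold.
#' @param k Number of folds (default 10).
#' @param prior_strength Prior concentration per state for the per-fold fits.
#' @param n_samples Posterior draws per evidence pattern.
#' @param seed Integer seed controlling folds and scoring draws.
#' @return An `omg_validation` report with fold-averaged `error_rate` and
#'   `auc` plus a `per_fold` data.frame.
#' @export
cross_validate <- function(records, predictors,
                           network = omg_default_network(), k = 10,
                           prior_strength = 1, n_samples = 10000,
                           seed = 20160101) {
  stopifnot(inherits(network, "omg_network"), k >= 2)
  records <- validate_records(records, network)
  predictors <- unique(as.character(predictors))
  need <- c(predictors, network$outcome)
  complete <- !Reduce(`|`, lapply(records[need], is.na))
  sub <- records[complete, , drop = FALSE]
  n <- nrow(sub)
  if (n < k)
    stop("fewer complete records (", n, ") than folds (", k, ")",
         call. = FALSE)
  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(seed)
  fold <- sample(rep_len(seq_len(k), n))
  per_fold <- data.frame(fold = seq_len(k), n = NA_integer_,
                         error_rate = NA_real_, auc = NA_real_)
  for (f in seq_len(k)) {
    train <- sub[fold != f, , drop = FALSE]
    test <- sub[fold == f, , drop = FALSE]
    fit_f <- fit_network(count_records(train, network), network,
                         prior_strength = prior_strength)
    rep_f <- evaluate_predictors(fit_f, test, predictors,
                                 n_samples = n_samples, seed = NULL)
    per_fold$n[f] <- rep_f$n_cases
    per_fold$error_rate[f] <- rep_f$error_rate
    per_fold$auc[f] <- rep_f$auc
  }
  structure(list(predictor_set = predictors,
                 n_cases = n,
                 error_rate = mean(per_fold$error_rate),
                 auc = if (all(is.na(per_fold$auc))) NA_real_
                       else mean(per_fold$auc, na.rm = TRUE),
                 auc_folds_skipped = sum(is.na(per_fold$auc)),
                 per_fold = per_fold,
                 scores = NULL),
            class = "omg_validation")
}

#' @export
print.omg_validation <- function(x, ...) {
  cat("Predictor set: {", paste(x$predictor_set, collapse = ", "), "}\n")
  cat(sprintf("  cases: %d   error rate: %.2f%%   AUC: %s\n",
              x$n_cases, 100 * x$error_rate,
              if (is.na(x$auc)) "undefined" else sprintf("%.3f", x$auc)))
  if (!is.null(x$per_fold)) {
    cat("  per fold:\n")
    print(x$per_fold, row.names = FALSE)
    if (isTRUE(x$auc_folds_skipped > 0))
      cat("  (", x$auc_folds_skipped,
          "single-class fold(s) skipped for AUC )\n")
  }
  invisible(x)
}

#' @export
as.data.frame.omg_validation <- function(x, ...) {
  data.frame(predictor_set = paste(x$predictor_set, collapse = "+"),
             n_cases = x$n_cases, error_rate = x$error_rate, auc = x$auc,
             stringsAsFactors = FALSE)
}

#' Sensitivity and specificity of one diagnostic test
#'
#' Computed from the records in which both the test and the outcome are
#' observed: sensitivity is the fraction of outcome-positive cases with a
#' positive test, specificity the fraction of outcome-negative cases with a
#' negative test.  Empty strata yield `NA` with the raw counts reported.
#'
#' @param records Record data.frame.
#' @param test_variable A binary test variable with states
#'   `negative`/`positive`.
#' @param network Network supplying the schema and the outcome.
#' @return An `omg_sens_spec`: `sensitivity`, `specificity` and a 2x2
#'   `counts` matrix (outcome in rows, test in columns).
#' @examples
#' sens_spec(omg_training_records(), "edrophonium")
#' @export
sens_spec <- function(records, test_variable,
                      network = omg_default_network()) {
  stopifnot(inherits(network, "omg_network"))
  records <- validate_records(records, network)
  if (!test_variable %in% variable_names(network))
    stop("unknown test variable '", test_variable, "'", call. = FALSE)
  if (!setequal(network$variables[[test_variable]]$states,
                c("negative", "positive")))
    stop("'", test_variable, "' is not a binary negative/positive test",
         call. = FALSE)
  outcome <- network$outcome
  ok <- !is.na(records[[test_variable]]) & !is.na(records[[outcome]])
  sub <- records[ok, , drop = FALSE]
  counts <- table(
    factor(sub[[outcome]], levels = network$variables[[outcome]]$states),
    factor(sub[[test_variable]], levels = c("negative", "positive")))
  counts <- matrix(as.integer(counts), nrow = nrow(counts),
                   dimnames = stats::setNames(dimnames(counts),
                                              c(outcome, test_variable)))
  pos_row <- counts[network$positive_state, ]
  neg_row <- counts["negative", ]
  structure(list(
    test = test_variable,
    sensitivity = if (sum(pos_row) == 0L) NA_real_
                  else pos_row[["positive"]] / sum(pos_row),
    specificity = if (sum(neg_row) == 0L) NA_real_
                  else neg_row[["negative"]] / sum(neg_row),
    counts = counts), class = "omg_sens_spec")
}

#' @export
print.omg_sens_spec <- function(x, ...) {
  fmt <- function(v) if (is.na(v)) "undefined (empty stratum)"
                     else sprintf("%.1f%%", 100 * v)
  cat("Test:", x$test, "\n")
  cat("  sensitivity:", fmt(x$sensitivity),
      sprintf("(%d/%d)\n", x$counts[2L, "positive"], sum(x$counts[2L, ])))
  cat("  specificity:", fmt(x$specificity),
      sprintf("(%d/%d)\n", x$counts[1L, "negative"], sum(x$counts[1L, ])))
  invisible(x)
}
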