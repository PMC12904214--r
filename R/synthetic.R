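#' Generate a synthetic suspected-OMG cohort
#'
#' Ancestral sampling from the network in topological order, followed by
#' independent per-variable masking (missing completely at random) at the
#' requested rates.  The outcome is never masked: generated cohorts are
#' intended as training/validation sets with known diagnosis.  The defaults
#' emulate the training cohort: plug-in posterior-mean parameters of the
#' fixture fit and no missingness; pass
#' [omg_training_missing_rates()] to reproduce the training data's
#' missing-examination pattern.
#'
#' @param n Number of records.
#' @param model An `omg_fit` (plug-in posterior means are used) or a
#'   parameter list as returned by [plugin_parameters()] /
#'   [sample_parameters()] (then `network` must be given).
#' @param missing_rates Named numeric vector of per-variable missing
#'   probabilities in `[0, 1]`; variables not named are never missing.
#' @param seed Integer seed; `NULL` consumes the current RNG stream.
#' @param network Network structure (taken from `model` when it is a fit).
#' @return A record data.frame with an attribute `seed`.
#' @examples
#' fit <- fit_network(omg_training_counts())
#' cohort <- generate_cohort(200, fit, seed = 1)
#' table(cohort$omg)
#' @export
generate_cohort <- function(n, model = fit_network(omg_training_counts()),
                            missing_rates = NULL, seed = NULL,
                            network = NULL) {
  stopifnot(is.numeric(n), length(n) == 1L, n >= 1)
  n <- as.integer(n)
  if (inherits(model, "omg_fit")) {
    network <- model$network
    params <- posterior_mean(model)
  } else {
    if (is.null(network))
      stop("when 'model' is a parameter list, 'network' must be supplied",
           call. = FALSE)
    params <- model
  }
  stopifnot(inherits(network, "omg_network"))
  for (v in variable_names(network)) {
    arr <- params[[v]]
    if (is.null(arr))
      stop("no parameters for variable '", v, "'", call. = FALSE)
    m <- matrix(arr, nrow = dim(arr)[1L])
    if (any(m < 0) || any(abs(colSums(m) - 1) > 1e-8))
      stop("parameters for '", v, "' are not probability vectors",
           call. = FALSE)
  }
  if (!is.null(missing_rates)) {
    if (is.null(names(missing_rates)) ||
        !all(names(missing_rates) %in% variable_names(network)))
      stop("missing_rates must be named by declared variables", call. = FALSE)
    if (any(missing_rates < 0 | missing_rates > 1))
      stop("missing_rates must lie in [0, 1]", call. = FALSE)
    if (isTRUE(missing_rates[[network$outcome]] > 0))
      stop("the outcome ('", network$outcome,
           "') cannot be masked in a generated cohort", call. = FALSE)
  }
  with_seed(seed, {
    df <- as.data.frame(stats::setNames(
      rep(list(rep(NA_character_, n)), length(network$variables)),
      variable_names(network)), stringsAsFactors = FALSE)
    for (v in topo_sort(network)) {
      spec <- network$variables[[v]]
      if (length(spec$parents) == 0L) {
        df[[v]] <- sample(spec$states, n, replace = TRUE,
                          prob = as.numeric(params[[v]]))
      } else {
        key <- do.call(paste, c(df[spec$parents], sep = "\r"))
        for (u in unique(key)) {
          idx <- which(key == u)
          cfg <- stats::setNames(
            unlist(df[idx[1L], spec$parents, drop = FALSE]), spec$parents)
          p <- do.call(`[`, c(list(params[[v]]), list(TRUE),
                              as.list(cfg[spec$parents])))
          df[[v]][idx] <- sample(spec$states, length(idx), replace = TRUE,
                                 prob = as.numeric(p))
        }
      }
    }
    for (v in names(missing_rates)) {
      r <- missing_rates[[v]]
      if (r > 0) df[[v]][stats::runif(n) < r] <- NA_character_
    }
    df <- df[variable_names(network)]
    attr(df, "seed") <- seed
    df
  })
}
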