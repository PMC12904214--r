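# Evidence: a named character vector of observed states for a subset of
# variables.  Accepts named list / named vector / single-row record
# data.frame (NA = unobserved).
as_evidence <- function(x, network, forbid = character()) {
  if (is.data.frame(x)) {
    stopifnot(nrow(x) <= 1L)
    x <- if (nrow(x)) unlist(x[1L, , drop = TRUE]) else character()
    x <- x[!is.na(x)]
  }
  x <- unlist(x)
  if (length(x) == 0L) return(stats::setNames(character(), character()))
  if (is.null(names(x)) || any(!nzchar(names(x))))
    stop("evidence must be named (variable = state)", call. = FALSE)
  x <- vapply(x, as.character, character(1))
  unknown <- setdiff(names(x), variable_names(network))
  if (length(unknown))
    stop("unknown evidence variable(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  if (anyDuplicated(names(x)))
    stop("duplicated evidence variable(s)", call. = FALSE)
  bad <- intersect(names(x), forbid)
  if (length(bad))
    stop("variable(s) cannot be used as evidence here: ",
         paste(bad, collapse = ", "), call. = FALSE)
  for (v in names(x))
    if (!x[[v]] %in% network$variables[[v]]$states)
      stop("'", x[[v]], "' is not a state of '", v, "'", call. = FALSE)
  x
}

# Variables that must be kept for an exact query: evidence, query, and their
# ancestors; unobserved barren descendants integrate to one and are dropped.
relevant_variables <- function(network, evidence_vars, query) {
  kept <- variable_names(network)
  fixed <- union(evidence_vars, query)
  repeat {
    barren <- kept[!kept %in% fixed &
                     !vapply(kept, function(v)
                       any(children_of(network, v) %in% kept), logical(1))]
    if (!length(barren)) break
    kept <- setdiff(kept, barren)
  }
  kept
}

# CPT entry lookup: probability of `assignment[[var]]` given the assigned
# parent states, from a parameter array list.
cpt_entry <- function(params, network, var, assignment) {
  spec <- network$variables[[var]]
  arr <- params[[var]]
  idx <- c(list(assignment[[var]]), as.list(assignment[spec$parents]))
  do.call(`[`, c(list(arr), idx))
}

#' Joint probability of a full assignment
#'
#' The defining factorization of the network: the product over all variables
#' of the CPT entry for the assigned state given the assigned parent states.
#'
#' @param network An `omg_network`.
#' @param params Parameter list (probability arrays), e.g. from
#'   [plugin_parameters()] or [sample_parameters()].
#' @param assignment Named character vector assigning a state to every
#'   variable.
#' @return A probability.
#' @export
joint_probability <- function(network, params, assignment) {
  stopifnot(inherits(network, "omg_network"))
  assignment <- as_evidence(assignment, network)
  missing_vars <- setdiff(variable_names(network), names(assignment))
  if (length(missing_vars))
    stop("assignment must cover every variable; missing: ",
         paste(missing_vars, collapse = ", "), call. = FALSE)
  prod(vapply(variable_names(network),
              function(v) cpt_entry(params, network, v, assignment),
              numeric(1)))
}

#' Conditional distribution of one variable given partial evidence
#'
#' Exact inference by enumeration: unobserved variables outside the
#' ancestral set of query-plus-evidence integrate to one and are pruned; the
#' joint is then summed over the remaining unobserved variables and
#' renormalised.  With the small diagnostic network this grid never exceeds
#' a few dozen cells, keeping the computation fully transparent.
#'
#' @param network An `omg_network`.
#' @param params Parameter list (probability arrays).
#' @param evidence Named states for any subset of variables excluding the
#'   query (named vector/list, or a single-row record with `NA` for
#'   unobserved).
#' @param query Variable whose conditional distribution is returned.
#' @return Named probability vector over the query's states (sums to 1).
#' @examples
#' fit <- fit_network(omg_training_counts())
#' conditional_query(fit$network, plugin_parameters(fit),
#'                   c(edrophonium = "positive"), "omg")
#' @export
conditional_query <- function(network, params, evidence, query) {
  stopifnot(inherits(network, "omg_network"))
  if (!query %in% variable_names(network))
    stop("unknown query variable '", query, "'", call. = FALSE)
  evidence <- as_evidence(evidence, network, forbid = query)
  kept <- relevant_variables(network, names(evidence), query)
  free <- setdiff(kept, names(evidence))   # includes the query
  grid <- expand.grid(lapply(free, function(v) network$variables[[v]]$states),
                      stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE)
  names(grid) <- free
  qstates <- network$variables[[query]]$states
  acc <- stats::setNames(numeric(length(qstates)), qstates)
  for (i in seq_len(nrow(grid))) {
    assignment <- c(evidence, stats::setNames(unlist(grid[i, , drop = FALSE]),
                                              free))
    p <- prod(vapply(kept, function(v)
      cpt_entry(params, network, v, assignment), numeric(1)))
    acc[[assignment[[query]]]] <- acc[[assignment[[query]]]] + p
  }
  total <- sum(acc)
  if (total <= 0)
    stop("evidence has probability zero under the supplied parameters",
         call. = FALSE)
  acc / total
}

# Column index of (state, parent configuration) in a CPT flattened
# column-major with the child dimension first.
flat_index <- function(network, var, state, assignment) {
  spec <- network$variables[[var]]
  k <- length(spec$states)
  cfg <- 0L
  stride <- 1L
  for (p in spec$parents) {
    pos <- match(assignment[[p]], network$variables[[p]]$states)
    cfg <- cfg + (pos - 1L) * stride
    stride <- stride * length(network$variables[[p]]$states)
  }
  cfg * k + match(state, spec$states)
}

# Monte-Carlo posterior draws of P(query | evidence): returns an
# n_samples x n_query_states matrix of conditional probabilities, one row
# per posterior parameter draw.  Consumes the current RNG stream.
posterior_query_draws <- function(fit, evidence, query, n_samples) {
  net <- fit$network
  kept <- relevant_variables(net, names(evidence), query)
  kept <- topo_sort(net)[topo_sort(net) %in% kept]
  # one Dirichlet draw per CPT row per sample, flattened child-fastest
  draws <- lapply(stats::setNames(kept, kept), function(v) {
    alpha <- as.numeric(fit$alpha[[v]])
    k <- length(net$variables[[v]]$states)
    g <- matrix(stats::rgamma(n_samples * length(alpha),
                              shape = rep(alpha, each = n_samples)),
                nrow = n_samples)
    for (j in seq_len(length(alpha) / k)) {
      cols <- ((j - 1L) * k + 1L):(j * k)
      g[, cols] <- g[, cols, drop = FALSE] /
        rowSums(g[, cols, drop = FALSE])
    }
    g
  })
  free <- setdiff(kept, names(evidence))
  grid <- expand.grid(lapply(free, function(v) net$variables[[v]]$states),
                      stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE)
  names(grid) <- free
  qstates <- net$variables[[query]]$states
  acc <- matrix(0, nrow = n_samples, ncol = length(qstates),
                dimnames = list(NULL, qstates))
  for (i in seq_len(nrow(grid))) {
    assignment <- c(evidence, stats::setNames(unlist(grid[i, , drop = FALSE]),
                                              free))
    p <- rep(1, n_samples)
    for (v in kept)
      p <- p * draws[[v]][, flat_index(net, v, assignment[[v]], assignment)]
    acc[, assignment[[query]]] <- acc[, assignment[[query]]] + p
  }
  acc / rowSums(acc)
}

#' Predict the outcome probability under partial evidence
#'
#' Draws `n_samples` parameter sets from the fitted Dirichlet posteriors,
#' computes the exact conditional probability of the positive outcome under
#' each draw, and summarises the resulting posterior predictive distribution
#' by its median and equal-tailed 95% credible interval.  A case is
#' classified positive when the median probability strictly exceeds 50%.
#'
#' @param object An `omg_fit`.
#' @param evidence Observed states for any subset of non-outcome variables
#'   (named vector/list, or single-row record with `NA` for unobserved).
#' @param n_samples Number of posterior parameter draws (default 10000).
#' @param seed Integer seed for the draws (default 20160101); `NULL`
#'   consumes the current RNG stream.
#' @param ... Unused.
#' @return An `omg_prediction`: median, `q025`, `q975`, `n_samples`, `seed`,
#'   `classification`, and the evidence used.
#' @examples
#' fit <- fit_network(omg_training_counts())
#' predict(fit, c(sex = "male"))
#' predict(fit, c(edrophonium = "negative", achr = "negative"))
#' @export
predict.omg_fit <- function(object, evidence = character(),
                            n_samples = 10000, seed = 20160101, ...) {
  stopifnot(n_samples >= 1)
  net <- object$network
  evidence <- as_evidence(evidence, net, forbid = net$outcome)
  p <- with_seed(seed,
                 posterior_query_draws(object, evidence, net$outcome,
                                       n_samples))[, net$positive_state]
  q <- unname(stats::quantile(p, c(0.025, 0.5, 0.975)))
  structure(list(evidence = evidence,
                 median = q[2L], q025 = q[1L], q975 = q[3L],
                 n_samples = as.integer(n_samples), seed = seed,
                 classification = if (q[2L] > 0.5) "positive" else "negative"),
            class = "omg_prediction")
}

#' @export
print.omg_prediction <- function(x, ...) {
  ev <- if (length(x$evidence))
    paste(names(x$evidence), x$evidence, sep = "=", collapse = ", ")
  else "(none)"
  cat("OMG probability given evidence:", ev, "\n")
  cat(sprintf("  median %.1f%%  (95%% CI %.1f%% - %.1f%%)\n",
              100 * x$median, 100 * x$q025, 100 * x$q975))
  cat("  classification:", x$classification,
      sprintf("(%d posterior draws, seed %s)\n", x$n_samples,
              if (is.null(x$seed)) "stream" else x$seed))
  invisible(x)
}
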