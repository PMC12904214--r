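#' Fit Dirichlet posteriors to counted records
#'
#' Conjugate update: every conditional probability table row receives an
#' independent Dirichlet posterior whose concentration parameters are the
#' observed counts plus a symmetric prior (`prior_strength` per state,
#' default 1, i.e. a uniform prior on every CPT row).
#'
#' @param counts An `omg_counts` object from [count_records()] or
#'   [omg_training_counts()].
#' @param network The network the counts were taken under.
#' @param prior_strength Positive prior concentration added to every count.
#' @return An object of class `omg_fit` holding one concentration array per
#'   variable (same shape as the count arrays).
#' @examples
#' fit <- fit_network(omg_training_counts())
#' cpd_summary(fit, "edrophonium", "positive", c(omg = "positive"))
#' @export
fit_network <- function(counts, network = omg_default_network(),
                        prior_strength = 1) {
  stopifnot(inherits(counts, "omg_counts"), inherits(network, "omg_network"))
  if (!is.numeric(prior_strength) || length(prior_strength) != 1L ||
      !is.finite(prior_strength) || prior_strength <= 0)
    stop("prior_strength must be a single positive number", call. = FALSE)
  missing_tables <- setdiff(variable_names(network), names(counts))
  if (length(missing_tables))
    stop("no count table for variable(s): ",
         paste(missing_tables, collapse = ", "), call. = FALSE)
  alpha <- lapply(network$variables, function(spec) {
    ct <- counts[[spec$name]]
    expected_dim <- c(length(spec$states),
                      vapply(spec$parents,
                             function(p) n_states(network, p), integer(1)))
    if (!identical(as.integer(dim(ct$counts)), as.integer(expected_dim)))
      stop("count table for '", spec$name,
           "' does not match the network structure", call. = FALSE)
    ct$counts + prior_strength
  })
  n_used <- vapply(counts[variable_names(network)], `[[`, numeric(1), "n_used")
  structure(list(network = network, alpha = alpha,
                 prior_strength = prior_strength, n_used = n_used),
            class = "omg_fit")
}

#' @export
print.omg_fit <- function(x, ...) {
  cat("Fitted discrete Bayesian network (Dirichlet posteriors)\n")
  cat("  prior strength:", x$prior_strength, "per state\n")
  cat("  records used per table:\n")
  for (v in names(x$n_used))
    cat(sprintf("    %-12s %d\n", v, as.integer(x$n_used[[v]])))
  invisible(x)
}

# Extract one CPT row's concentration vector for a parent configuration
# given as a named character vector/list (names = parent variables).
row_alpha <- function(fit, variable, parents = NULL) {
  spec <- fit$network$variables[[variable]]
  if (is.null(spec))
    stop("unknown variable '", variable, "'", call. = FALSE)
  arr <- fit$alpha[[variable]]
  if (length(spec$parents) == 0L) {
    out <- as.vector(arr)
    names(out) <- spec$states
    return(out)
  }
  parents <- unlist(parents)
  bad <- setdiff(spec$parents, names(parents))
  if (length(bad))
    stop("missing parent state(s) for '", variable, "': ",
         paste(bad, collapse = ", "), call. = FALSE)
  for (p in spec$parents)
    if (!parents[[p]] %in% fit$network$variables[[p]]$states)
      stop("'", parents[[p]], "' is not a state of parent '", p, "'",
           call. = FALSE)
  out <- do.call(`[`, c(list(arr), list(TRUE), as.list(parents[spec$parents])))
  names(out) <- spec$states
  out
}

#' Exact credible summary of one CPT entry
#'
#' The marginal posterior of a single entry of a Dirichlet-distributed
#' probability vector with concentrations `a` is Beta(`a[state]`,
#' `sum(a) - a[state]`); the equal-tailed 95% interval and median are exact
#' Beta quantiles (no sampling).
#'
#' @param fit An `omg_fit`.
#' @param variable Variable name.
#' @param state Child state whose probability is summarised.
#' @param parents Named character vector of parent states (omit for roots).
#' @return Named numeric vector `c(q025, median, q975)` of probabilities.
#' @examples
#' fit <- fit_network(omg_training_counts())
#' cpd_summary(fit, "omg", "positive", c(sex = "male"))
#' @export
cpd_summary <- function(fit, variable, state, parents = NULL) {
  stopifnot(inherits(fit, "omg_fit"))
  a <- row_alpha(fit, variable, parents)
  if (!state %in% names(a))
    stop("'", state, "' is not a state of '", variable, "'", call. = FALSE)
  shape1 <- a[[state]]
  shape2 <- sum(a) - shape1
  q <- stats::qbeta(c(0.025, 0.5, 0.975), shape1, shape2)
  c(q025 = q[1L], median = q[2L], q975 = q[3L])
}

#' Tabulate credible summaries for all CPT entries
#'
#' One row per (variable, parent configuration, state) with the exact
#' equal-tailed 95% credible interval around the posterior median; the layout
#' of a published CPD table.
#'
#' @param fit An `omg_fit`.
#' @param variables Variables to include (default: all).
#' @param percent Report percentages instead of probabilities.
#' @return A data.frame with columns `variable`, `parents`, `state`, `q025`,
#'   `median`, `q975`.
#' @export
cpd_table <- function(fit, variables = NULL, percent = FALSE) {
  stopifnot(inherits(fit, "omg_fit"))
  net <- fit$network
  if (is.null(variables)) variables <- variable_names(net)
  rows <- list()
  for (v in variables) {
    spec <- net$variables[[v]]
    cfgs <- if (length(spec$parents)) {
      grid <- expand.grid(lapply(spec$parents,
                                 function(p) net$variables[[p]]$states),
                          stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE)
      names(grid) <- spec$parents
      grid
    } else data.frame(row.names = 1L)
    for (i in seq_len(max(1L, nrow(cfgs)))) {
      cfg <- if (ncol(cfgs)) unlist(cfgs[i, , drop = FALSE]) else NULL
      for (s in spec$states) {
        q <- cpd_summary(fit, v, s, cfg)
        rows[[length(rows) + 1L]] <- data.frame(
          variable = v,
          parents = if (is.null(cfg)) "" else
            paste(names(cfg), cfg, sep = "=", collapse = ", "),
          state = s, q025 = q[["q025"]], median = q[["median"]],
          q975 = q[["q975"]], stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  if (percent) out[c("q025", "median", "q975")] <-
      100 * out[c("q025", "median", "q975")]
  rownames(out) <- NULL
  out
}

# Posterior-mean plug-in parameters: list of probability arrays.
posterior_mean <- function(fit) {
  stopifnot(inherits(fit, "omg_fit"))
  lapply(fit$alpha, function(arr) {
    k <- dim(arr)[1L]
    m <- matrix(arr, nrow = k)
    m <- sweep(m, 2L, colSums(m), `/`)
    array(m, dim = dim(arr), dimnames = dimnames(arr))
  })
}

#' Plug-in parameters of a fitted network
#'
#' Posterior-mean probability vectors for every CPT row; usable as the
#' `params` argument of [conditional_query()], [joint_probability()] and
#' [generate_cohort()].
#'
#' @param fit An `omg_fit`.
#' @return Named list of probability arrays, one per variable.
#' @export
plugin_parameters <- function(fit) posterior_mean(fit)

#' Draw one parameter set from the posterior
#'
#' Every CPT row is drawn independently from its Dirichlet posterior (via
#' normalised Gamma variates).  The same seed yields the identical draw.
#'
#' @param fit An `omg_fit`.
#' @param seed Integer seed, or `NULL` to consume the current RNG stream.
#' @return Named list of probability arrays, one per variable.
#' @export
sample_parameters <- function(fit, seed = NULL) {
  stopifnot(inherits(fit, "omg_fit"))
  with_seed(seed, {
    lapply(fit$alpha[topo_sort(fit$network)], function(arr) {
      g <- array(stats::rgamma(length(arr), shape = arr), dim = dim(arr),
                 dimnames = dimnames(arr))
      k <- dim(arr)[1L]
      m <- matrix(g, nrow = k)
      m <- sweep(m, 2L, colSums(m), `/`)
      array(m, dim = dim(arr), dimnames = dimnames(arr))
    })[variable_names(fit$network)]
  })
}

#' Serialize a fitted model to a plain-text file
#'
#' Writes the network structure, prior strength and every concentration
#' parameter as human-auditable YAML.
#'
#' @param fit An `omg_fit`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @seealso [read_model()]
#' @export
write_model <- function(fit, path) {
  stopifnot(inherits(fit, "omg_fit"))
  net <- fit$network
  doc <- list(
    outcome = net$outcome,
    positive_state = net$positive_state,
    prior_strength = fit$prior_strength,
    variables = lapply(unname(net$variables), function(v) list(
      name = v$name, states = as.list(v$states), parents = as.list(v$parents),
      n_used = as.integer(fit$n_used[[v$name]]),
      alpha = as.list(as.numeric(fit$alpha[[v$name]])))))
  yaml::write_yaml(doc, path)
  invisible(path)
}

#' Read a serialized model
#'
#' @param path Path written by [write_model()].
#' @return An `omg_fit`.
#' @export
read_model <- function(path) {
  doc <- yaml::read_yaml(path)
  vars <- lapply(doc$variables, function(v)
    variable_spec(v$name, unlist(v$states),
                  if (is.null(v$parents)) character() else unlist(v$parents)))
  net <- omg_network(vars, outcome = doc$outcome,
                     positive_state = doc$positive_state)
  alpha <- lapply(doc$variables, function(v) {
    spec <- net$variables[[v$name]]
    dims <- stats::setNames(
      c(list(spec$states),
        lapply(spec$parents, function(p) net$variables[[p]]$states)),
      c(v$name, spec$parents))
    array(as.numeric(unlist(v$alpha)), dim = unname(lengths(dims)), dimnames = dims)
  })
  names(alpha) <- vapply(doc$variables, `[[`, character(1), "name")
  n_used <- vapply(doc$variables, function(v) as.numeric(v$n_used), numeric(1))
  names(n_used) <- names(alpha)
  structure(list(network = net, alpha = alpha[variable_names(net)],
                 prior_strength = doc$prior_strength,
                 n_used = n_used[variable_names(net)]),
            class = "omg_fit")
}
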