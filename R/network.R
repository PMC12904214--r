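#' Declare a categorical network variable
#'
#' A variable is a named categorical quantity with an ordered set of states
#' and an ordered list of parent variables in the directed acyclic graph.
#'
#' @param name Variable name (single non-empty string).
#' @param states Character vector of at least two distinct state labels.
#'   Order is preserved and determines the order of probability vectors.
#' @param parents Character vector of parent variable names (possibly empty).
#' @return An object of class `omg_variable`.
#' @examples
#' variable_spec("ice", c("negative", "positive"), parents = "omg")
#' @export
variable_spec <- function(name, states, parents = character()) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  states <- as.character(states)
  if (length(states) < 2L || anyDuplicated(states))
    stop("variable '", name, "': states must be >= 2 distinct labels", call. = FALSE)
  parents <- as.character(parents)
  if (anyDuplicated(parents))
    stop("variable '", name, "': duplicated parent names", call. = FALSE)
  if (name %in% parents)
    stop("variable '", name, "' cannot be its own parent", call. = FALSE)
  structure(list(name = name, states = states, parents = parents),
            class = "omg_variable")
}

#' Assemble a Bayesian network structure
#'
#' Collects variable declarations into a directed acyclic graph. Validation
#' checks that every parent refers to a declared variable and that the parent
#' relation admits a topological order.
#'
#' @param variables List of [variable_spec()] objects.
#' @param outcome Name of the outcome variable (queried by default in
#'   prediction; never accepted as evidence there).
#' @param positive_state State label of `outcome` that counts as a positive
#'   diagnosis.
#' @return An object of class `omg_network`.
#' @seealso [omg_default_network()], [read_network()]
#' @export
omg_network <- function(variables, outcome, positive_state = "positive") {
  stopifnot(is.list(variables), length(variables) > 0L)
  for (v in variables)
    if (!inherits(v, "omg_variable"))
      stop("all variables must be created with variable_spec()", call. = FALSE)
  nms <- vapply(variables, `[[`, character(1), "name")
  if (anyDuplicated(nms))
    stop("duplicated variable names: ",
         paste(unique(nms[duplicated(nms)]), collapse = ", "), call. = FALSE)
  names(variables) <- nms
  for (v in variables) {
    bad <- setdiff(v$parents, nms)
    if (length(bad))
      stop("variable '", v$name, "': undeclared parent(s) ",
           paste(bad, collapse = ", "), call. = FALSE)
  }
  if (!outcome %in% nms)
    stop("outcome '", outcome, "' is not a declared variable", call. = FALSE)
  if (!positive_state %in% variables[[outcome]]$states)
    stop("positive_state '", positive_state, "' is not a state of '",
         outcome, "'", call. = FALSE)
  net <- structure(list(variables = variables, outcome = outcome,
                        positive_state = positive_state),
                   class = "omg_network")
  topo_sort(net)  # errors on cycles
  net
}

#' Topological order of the network variables
#'
#' @param network An `omg_network`.
#' @return Character vector of variable names, parents always before children.
#' @export
topo_sort <- function(network) {
  stopifnot(inherits(network, "omg_network"))
  pending <- network$variables
  ordered <- character()
  while (length(pending)) {
    ready <- vapply(pending, function(v) all(v$parents %in% ordered), logical(1))
    if (!any(ready))
      stop("network graph contains a cycle involving: ",
           paste(names(pending), collapse = ", "), call. = FALSE)
    ordered <- c(ordered, names(pending)[ready])
    pending <- pending[!ready]
  }
  ordered
}

variable_names <- function(network) names(network$variables)

n_states <- function(network, var) length(network$variables[[var]]$states)

children_of <- function(network, var) {
  nms <- variable_names(network)
  nms[vapply(network$variables, function(v) var %in% v$parents, logical(1))]
}

#' @export
print.omg_network <- function(x, ...) {
  cat("Discrete Bayesian network:", length(x$variables), "variables\n")
  cat("  outcome:", x$outcome, "(positive state:", paste0(x$positive_state, ")\n"))
  for (v in x$variables) {
    pa <- if (length(v$parents)) paste(v$parents, collapse = ", ") else "-"
    cat(sprintf("  %-12s states: %-28s parents: %s\n",
                v$name, paste(v$states, collapse = "/"), pa))
  }
  invisible(x)
}

#' Read a network structure from a YAML file
#'
#' The file lists `outcome`, `positive_state` and one entry per variable with
#' `name`, `states` and `parents`.  The packaged default network is shipped
#' in this format (see [omg_default_network()]).
#'
#' @param path Path to a YAML network description.
#' @return An `omg_network`.
#' @export
read_network <- function(path) {
  doc <- yaml::read_yaml(path)
  if (is.null(doc$variables))
    stop("network file has no 'variables' section: ", path, call. = FALSE)
  vars <- lapply(doc$variables, function(v)
    variable_spec(v$name, unlist(v$states),
                  if (is.null(v$parents)) character() else unlist(v$parents)))
  omg_network(vars, outcome = doc$outcome,
              positive_state = if (is.null(doc$positive_state)) "positive"
                               else doc$positive_state)
}

#' Write a network structure to a YAML file
#'
#' @param network An `omg_network`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_network <- function(network, path) {
  stopifnot(inherits(network, "omg_network"))
  doc <- list(
    outcome = network$outcome,
    positive_state = network$positive_state,
    variables = lapply(unname(network$variables), function(v)
      list(name = v$name, states = as.list(v$states),
           parents = as.list(v$parents))))
  yaml::write_yaml(doc, path)
  invisible(path)
}

#' The default suspected-OMG network
#'
#' Twelve categorical variables: age (three bins) and sex as roots, the OMG
#' diagnosis depending on sex, the AChR antibody result depending on OMG and
#' age, and each remaining sign or test (diplopia, ptosis, sustained upgaze,
#' ice pack test, Besinger/QMG score bin, edrophonium, RNS, sfEMG) depending
#' on OMG alone.
#'
#' @return An `omg_network`.
#' @examples
#' net <- omg_default_network()
#' topo_sort(net)
#' @export
omg_default_network <- function() {
  read_network(system.file("extdata", "omg_network.yaml", package = "omgnet",
                           mustWork = TRUE))
}
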