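#' Count sufficient statistics from patient records
#'
#' For each network variable X, tabulates the observed states of X for every
#' configuration of its parents.  Complete cases are taken per conditional
#' probability table: a record contributes to X's table iff X and all parents
#' of X are observed in that record, so a missing ice test does not discard
#' the record's information about, say, the edrophonium table.
#'
#' @param records Record data.frame (character states, `NA` missing).
#' @param network An `omg_network`.
#' @return An `omg_counts` object: one `omg_count_table` per variable, each
#'   holding an integer array `counts` (first dimension child states, then
#'   one dimension per parent) and `n_used`, the number of contributing
#'   records.
#' @examples
#' recs <- omg_training_records()
#' count_records(recs, omg_default_network())[["edrophonium"]]
#' @export
count_records <- function(records, network) {
  stopifnot(inherits(network, "omg_network"))
  records <- validate_records(records, network)
  res <- lapply(network$variables, function(v) {
    vars <- c(v$name, v$parents)
    complete <- if (nrow(records) == 0L) logical(0) else
      !Reduce(`|`, lapply(records[vars], is.na))
    sub <- records[complete, vars, drop = FALSE]
    fac <- lapply(vars, function(w)
      factor(sub[[w]], levels = network$variables[[w]]$states))
    names(fac) <- vars
    tab <- table(fac)
    counts <- array(as.integer(tab), dim = dim(tab), dimnames = dimnames(tab))
    structure(list(variable = v$name, counts = counts,
                   n_used = sum(counts)),
              class = "omg_count_table")
  })
  structure(res, class = "omg_counts")
}

#' @export
print.omg_count_table <- function(x, ...) {
  cat("Counts for '", x$variable, "' (n_used = ", x$n_used, ")\n", sep = "")
  print(x$counts)
  invisible(x)
}

#' @export
print.omg_counts <- function(x, ...) {
  for (ct in x) print(ct)
  invisible(x)
}
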