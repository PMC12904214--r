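# Shared fixtures and independent oracles for the test suite.

default_net <- omg_default_network()
default_fit <- fit_network(omg_training_counts())

# A three-variable chain a -> b -> c with a ternary sink, small enough for
# exhaustive checks.
tiny_network <- function() {
  omg_network(list(
    variable_spec("a", c("negative", "positive")),
    variable_spec("b", c("negative", "positive"), parents = "a"),
    variable_spec("c", c("low", "mid", "high"), parents = "b")
  ), outcome = "b")
}

# Random parameter arrays for any network (Dirichlet(1) draws per row).
random_params <- function(network) {
  lapply(network$variables, function(spec) {
    k <- length(spec$states)
    ncfg <- prod(vapply(spec$parents,
                        function(p) length(network$variables[[p]]$states),
                        integer(1)))
    m <- matrix(rgamma(k * ncfg, 1), nrow = k)
    m <- sweep(m, 2L, colSums(m), `/`)
    dims <- c(list(spec$states),
              lapply(spec$parents, function(p) network$variables[[p]]$states))
    names(dims) <- c(spec$name, spec$parents)
    array(m, dim = unname(lengths(dims)), dimnames = dims)
  })
}

# Brute-force conditional distribution: tabulate the full joint over every
# assignment (product computed inline, independently of the inference code)
# and sum the rows compatible with the evidence.
oracle_query <- function(network, params, evidence, query) {
  vars <- names(network$variables)
  grid <- expand.grid(lapply(vars, function(v) network$variables[[v]]$states),
                      stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE)
  names(grid) <- vars
  p <- rep(1, nrow(grid))
  for (v in vars) {
    spec <- network$variables[[v]]
    arr <- params[[v]]
    ci <- match(grid[[v]], spec$states)
    idx <- ci
    stride <- length(spec$states)
    for (pa in spec$parents) {
      idx <- idx + (match(grid[[pa]], network$variables[[pa]]$states) - 1L) *
        stride
      stride <- stride * length(network$variables[[pa]]$states)
    }
    p <- p * as.numeric(arr)[idx]
  }
  keep <- rep(TRUE, nrow(grid))
  for (v in names(evidence)) keep <- keep & grid[[v]] == evidence[[v]]
  num <- tapply(p[keep], factor(grid[[query]][keep],
                                levels = network$variables[[query]]$states),
                sum, default = 0)
  out <- as.numeric(num) / sum(p[keep])
  names(out) <- network$variables[[query]]$states
  out
}

# Explicit pairwise Mann-Whitney AUC (ties count one half).
oracle_auc <- function(scores, is_positive) {
  pos <- scores[is_positive]
  neg <- scores[!is_positive]
  tot <- 0
  for (sp in pos) for (sn in neg)
    tot <- tot + if (sp > sn) 1 else if (sp == sn) 0.5 else 0
  tot / (length(pos) * length(neg))
}
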