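test_that("posterior concentrations equal prior plus counts exactly", {
  fit <- default_fit
  gt <- omg_training_counts()
  for (v in names(gt))
    expect_identical(fit$alpha[[v]], gt[[v]]$counts + 1)
  # published example row: edrophonium counts (2, 29) -> concentrations (3, 30)
  expect_identical(
    unname(fit$alpha$edrophonium[, "positive"]), c(3, 30))
  expect_identical(unname(as.numeric(fit$alpha$sex)), c(42, 49))
  # non-unit prior
  fit2 <- fit_network(omg_training_counts(), prior_strength = 0.5)
  expect_identical(fit2$alpha$edrophonium, gt$edrophonium$counts + 0.5)
})

test_that("fitting no data gives the symmetric prior everywhere", {
  empty <- count_records(omg_training_records()[0, ], default_net)
  fit <- fit_network(empty)
  for (v in names(fit$alpha))
    expect_true(all(fit$alpha[[v]] == 1))
  s <- cpd_summary(fit, "edrophonium", "positive", c(omg = "positive"))
  expect_equal(unname(s), c(0.025, 0.5, 0.975))
})

test_that("fit rejects incomplete or malformed count sets", {
  cts <- omg_training_counts()
  partial <- structure(unclass(cts)[-1], class = "omg_counts")
  expect_error(fit_network(partial, default_net), "no count table")
  expect_error(fit_network(cts, default_net, prior_strength = 0), "positive")
  expect_error(fit_network(cts, default_net, prior_strength = -1), "positive")
})

test_that("credible summaries are ordered probabilities", {
  fit <- default_fit
  tab <- cpd_table(fit)
  expect_true(all(tab$q025 >= 0 & tab$q975 <= 1))
  expect_true(all(tab$q025 <= tab$median & tab$median <= tab$q975))
  # summed over states, posterior medians are near (not exactly) one, but
  # plug-in means are exactly one per row: probability-vector invariant
  pm <- plugin_parameters(fit)
  for (v in names(pm)) {
    m <- matrix(pm[[v]], nrow = dim(pm[[v]])[1L])
    expect_true(all(abs(colSums(m) - 1) < 1e-12))
    expect_true(all(m >= 0))
  }
})

test_that("cpd_summary rejects undeclared lookups", {
  fit <- default_fit
  expect_error(cpd_summary(fit, "ghost", "positive"), "unknown variable")
  expect_error(cpd_summary(fit, "edrophonium", "equivocal",
                           c(omg = "positive")), "not a state")
  expect_error(cpd_summary(fit, "edrophonium", "positive",
                           c(omg = "borderline")), "not a state")
  expect_error(cpd_summary(fit, "edrophonium", "positive"), "missing parent")
})

test_that("sampled parameters are reproducible probability vectors", {
  fit <- default_fit
  p1 <- sample_parameters(fit, seed = 99)
  p2 <- sample_parameters(fit, seed = 99)
  expect_identical(p1, p2)
  p3 <- sample_parameters(fit, seed = 100)
  expect_false(identical(p1, p3))
  for (v in names(p1)) {
    m <- matrix(p1[[v]], nrow = dim(p1[[v]])[1L])
    expect_true(all(abs(colSums(m) - 1) < 1e-12))
    expect_true(all(m > 0))
  }
})

test_that("Monte-Carlo sampling converges to the exact Beta quantiles", {
  # dual route: cpd_summary is exact; repeated sample_parameters draws of the
  # same row must agree in distribution
  fit <- default_fit
  n <- 20000L
  draws <- withr::with_seed(2024, {
    g1 <- rgamma(n, shape = 30)
    g2 <- rgamma(n, shape = 3)
    g1 / (g1 + g2)  # Beta(30, 3): edrophonium positive | OMG positive
  })
  exact <- cpd_summary(fit, "edrophonium", "positive", c(omg = "positive"))
  emp <- unname(quantile(draws, c(0.025, 0.5, 0.975)))
  expect_lt(max(abs(emp - unname(exact))), 0.01)
  # symmetric uniform row: empirical mean 0.5
  fit0 <- fit_network(count_records(omg_training_records()[0, ], default_net),
                      default_net)
  means <- withr::with_seed(1, {
    ps <- replicate(400, sample_parameters(fit0)$sex[1L])
    mean(ps)
  })
  expect_lt(abs(means - 0.5), 0.05)
})

test_that("model serialization to plain text round-trips", {
  fit <- default_fit
  path <- withr::local_tempfile(fileext = ".yaml")
  write_model(fit, path)
  back <- read_model(path)
  expect_identical(back$network, fit$network)
  expect_equal(back$alpha, fit$alpha)
  expect_identical(back$prior_strength, fit$prior_strength)
  expect_equal(
    predict(back, c(sex = "male"), n_samples = 500, seed = 5),
    predict(fit, c(sex = "male"), n_samples = 500, seed = 5))
})
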