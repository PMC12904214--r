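test_that("the joint factorization is a proper distribution", {
  tiny <- tiny_network()
  # uniform CPTs: every full assignment has probability 1 / prod(k)
  uni <- lapply(random_params(tiny), function(arr) {
    arr[] <- 1 / dim(arr)[1L]
    arr
  })
  expect_equal(joint_probability(tiny, uni,
                                 c(a = "negative", b = "positive", c = "mid")),
               1 / (2 * 2 * 3))
  # random parameters: the joint sums to one over all assignments
  withr::with_seed(31, {
    params <- random_params(tiny)
    grid <- expand.grid(a = tiny$variables$a$states,
                        b = tiny$variables$b$states,
                        c = tiny$variables$c$states,
                        stringsAsFactors = FALSE)
    tot <- sum(vapply(seq_len(nrow(grid)), function(i)
      joint_probability(tiny, params, unlist(grid[i, ])), numeric(1)))
    expect_equal(tot, 1, tolerance = 1e-12)
  })
  expect_error(joint_probability(tiny, uni, c(a = "negative")), "missing")
})

test_that("enumeration inference matches the brute-force joint oracle", {
  tiny <- tiny_network()
  withr::with_seed(17, {
    for (rep in 1:25) {
      params <- random_params(tiny)
      vars <- names(tiny$variables)
      query <- sample(vars, 1)
      ev_vars <- setdiff(vars, query)
      ev_vars <- ev_vars[runif(length(ev_vars)) < 0.5]
      evidence <- vapply(ev_vars, function(v)
        sample(tiny$variables[[v]]$states, 1), character(1))
      got <- conditional_query(tiny, params, evidence, query)
      want <- oracle_query(tiny, params, evidence, query)
      expect_equal(got, want, tolerance = 1e-12)
      expect_equal(sum(got), 1, tolerance = 1e-12)
    }
  })
})

test_that("parent-only evidence reduces to a CPT lookup", {
  pm <- plugin_parameters(default_fit)
  got <- conditional_query(default_net, pm, c(sex = "male"), "omg")
  expect_equal(unname(got), unname(pm$omg[, "male"]), tolerance = 1e-12)
  # empty evidence: law of total probability over sex
  marg <- conditional_query(default_net, pm, character(), "omg")
  by_hand <- pm$omg[, "male"] * pm$sex[["male"]] +
    pm$omg[, "female"] * pm$sex[["female"]]
  expect_equal(unname(marg), unname(by_hand), tolerance = 1e-12)
})

test_that("impossible evidence is reported, not silently normalised", {
  tiny <- tiny_network()
  params <- random_params(tiny)
  params$b[, "negative"] <- c(1, 0)  # b=positive impossible when a=negative
  params$a[] <- c(1, 0)              # a always negative
  expect_error(conditional_query(tiny, params, c(b = "positive"), "c"),
               "probability zero")
})

test_that("evidence contracts are enforced", {
  expect_error(predict(default_fit, c(omg = "positive"), n_samples = 10),
               "cannot be used as evidence")
  expect_error(predict(default_fit, c(ghost = "positive"), n_samples = 10),
               "unknown evidence")
  expect_error(predict(default_fit, c(sex = "trilateral"), n_samples = 10),
               "not a state")
  expect_error(conditional_query(default_net, plugin_parameters(default_fit),
                                 c(omg = "positive"), "omg"),
               "cannot be used as evidence")
})

test_that("a confirmatory test result never lowers the plug-in OMG probability", {
  pm <- plugin_parameters(default_fit)
  base <- conditional_query(default_net, pm, character(), "omg")[["positive"]]
  for (v in c("diplopia", "ptosis", "upgaze", "ice", "edrophonium",
              "rns", "sfemg")) {
    cpt <- pm[[v]]
    best <- rownames(cpt)[which.max(cpt[, "positive"])]
    lr <- cpt[best, "positive"] / cpt[best, "negative"]
    if (lr <= 1) next
    with_ev <- conditional_query(default_net, pm,
                                 stats::setNames(best, v), "omg")[["positive"]]
    expect_gte(with_ev, base)
  }
})

test_that("prediction is reproducible and summarises the posterior draws", {
  p1 <- predict(default_fit, c(sex = "male"), n_samples = 2000, seed = 8)
  p2 <- predict(default_fit, c(sex = "male"), n_samples = 2000, seed = 8)
  expect_identical(p1, p2)
  expect_true(p1$q025 <= p1$median && p1$median <= p1$q975)
  expect_identical(p1$classification, "positive")
  # negative edrophonium pushes the probability well below the threshold
  pneg <- predict(default_fit, c(edrophonium = "negative"),
                  n_samples = 2000, seed = 8)
  expect_lt(pneg$median, 0.5)
  expect_identical(pneg$classification, "negative")
})

test_that("prediction medians approach the exact CPT posterior under parent-only evidence", {
  exact <- cpd_summary(default_fit, "omg", "positive", c(sex = "male"))
  pred <- predict(default_fit, c(sex = "male"), n_samples = 20000, seed = 3)
  expect_lt(abs(pred$median - exact[["median"]]), 0.01)
  expect_lt(abs(pred$q025 - exact[["q025"]]), 0.015)
  expect_lt(abs(pred$q975 - exact[["q975"]]), 0.015)
})
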