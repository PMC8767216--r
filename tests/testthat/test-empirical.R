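test_that("filtering removes constants first, then single-input rules", {
  f <- filter_automata(list(or_rule(2), constant_rule(2, 1), copy_rule()))
  expect_equal(f$n_retained, 1L)
  expect_equal(f$n_constant, 1L)
  expect_equal(f$n_single_input, 1L)
  expect_identical(f$retained[[1]]$outputs, or_rule(2)$outputs)

  expect_warning(f0 <- filter_automata(list(constant_rule(1, 0),
                                            constant_rule(3, 1))),
                 "no automata")
  expect_equal(f0$n_retained, 0L)

  # idempotence
  mixed <- c(list(constant_rule(2, 0), copy_rule(), copy_rule(negate = TRUE)),
             all_rules(2)[c(2, 7, 10)])
  once <- filter_automata(mixed)
  twice <- filter_automata(once$retained)
  expect_equal(twice$n_retained, once$n_retained)
  expect_equal(twice$n_constant, 0L)
  expect_equal(twice$n_single_input, 0L)
})

test_that("filter counts match a hand tally on a 20-rule fixture", {
  rules <- c(rep(list(constant_rule(2, 1)), 3),   # 3 constants
             rep(list(constant_rule(1, 0)), 2),   # 2 more constants (k=1)
             rep(list(copy_rule()), 4),           # 4 single-input
             rep(list(or_rule(2)), 5),
             rep(list(xor_rule(3)), 4),
             rep(list(and_rule(4)), 2))
  f <- filter_automata(rules)
  expect_equal(f$n_total, 20L)
  expect_equal(f$n_constant, 5L)
  expect_equal(f$n_single_input, 4L)
  expect_equal(f$n_retained, 11L)
})

test_that("summary statistics match closed-form moments of a 5-rule set", {
  # k values: 2, 2, 3, 4, 8 ; hand-computed moments
  rules <- list(or_rule(2), xor_rule(2), and_rule(3), xor_rule(4), or_rule(8))
  s <- summarize_set(rules)
  k <- c(2, 2, 3, 4, 8)
  m2 <- mean((k - mean(k))^2); m3 <- mean((k - mean(k))^3)
  m4 <- mean((k - mean(k))^4)
  expect_equal(s$n, 5L)
  expect_equal(s$k$mean, mean(k))
  expect_equal(s$k$median, 3)
  expect_equal(s$k$q1, 2)      # median of lower half {2, 2}
  expect_equal(s$k$q3, 6)      # median of upper half {4, 8}
  expect_equal(s$k$skewness, m3 / m2^1.5)
  expect_equal(s$k$ex_kurtosis, m4 / m2^2 - 3)
  # ke of the set: 1.25, 2, 1.25, 4, OR8
  expect_equal(s$ke$mean,
               mean(c(1.25, 2, 1.25, 4, effective_connectivity(or_rule(8)))))
  expect_error(summarize_set(list(or_rule(2))), "at least 2")
})

test_that("identical rules give zero dispersion and zero skewness", {
  s <- summarize_set(rep(list(or_rule(2)), 6))
  expect_equal(s$k$mean, 2)
  expect_equal(s$ke$mean, 1.25)
  expect_equal(s$ke$q3 - s$ke$q1, 0)
  expect_equal(s$k$skewness, 0)
  # symmetric set
  sym <- summarize_set(c(rep(list(or_rule(2)), 2), rep(list(or_rule(4)), 2)))
  expect_equal(sym$k$skewness, 0)
})

test_that("mean k_e never exceeds mean k across random networks", {
  set.seed(90)
  cat4 <- build_catalogue(4, 0.25)
  for (i in 1:5) {
    net <- generate_rbn(15, cat4, sample(c(1.5, 2, 2.5), 1))
    expect_lte(network_mean_ke(net), mean(network_in_degrees(net)))
  }
})

test_that("collection analysis labels opposite regimes and refits boundaries", {
  set.seed(91)
  cat22 <- build_catalogue(2, 0.5)
  chaotic_nets <- lapply(1:6, function(i) generate_rbn(30, cat22, 2.0))
  cat_low <- build_catalogue(3, 0.125)   # near-constant rules, stable
  stable_nets <- lapply(1:6, function(i) generate_rbn(30, cat_low, 1.5))
  res <- analyze_model_collection(c(chaotic_nets, stable_nets),
                                  pairs = 150, seed = 5)
  expect_equal(res$table$regime,
               c(rep("chaotic", 6), rep("stable", 6)))
  expect_s3_class(res$ct_fit, "criticality_fit")
  expect_s3_class(res$st_fit, "criticality_fit")
  expect_null(res$notice)

  # single-label collection: refit skipped with notice
  res1 <- analyze_model_collection(chaotic_nets, pairs = 100, seed = 6)
  expect_null(res1$ct_fit)
  expect_match(res1$notice, "single regime")
})
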