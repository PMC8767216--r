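test_that("worked examples of schema redescription are reproduced", {
  s <- prime_schemata(or_rule(2))
  expect_setequal(s$on, c("1#", "#1"))
  expect_identical(s$off, "00")

  s1 <- prime_schemata(constant_rule(2, 1))
  expect_identical(s1$on, "##")
  expect_length(s1$off, 0)

  s3 <- prime_schemata(and_rule(3))
  expect_identical(s3$on, "111")
  expect_setequal(s3$off, c("0##", "#0#", "##0"))
})

test_that("schemata cover their class and are maximal (prime)", {
  covers <- function(pattern, tuple) {
    p <- strsplit(pattern, "")[[1]]
    all(p == "#" | p == as.character(tuple))
  }
  set.seed(11)
  for (rep in 1:20) {
    k <- sample(2:4, 1)
    r <- random_rule(k, runif(1))
    s <- prime_schemata(r)
    tup <- input_tuples(k)
    for (a in seq_len(nrow(tup))) {
      pats <- if (r$outputs[a] == 1L) s$on else s$off
      expect_true(any(vapply(pats, covers, logical(1), tuple = tup[a, ])))
    }
    # every schema is consistent, and widening any literal breaks it
    for (cls in c("on", "off")) {
      want <- if (cls == "on") 1L else 0L
      for (pat in s[[cls]]) {
        rows <- which(vapply(seq_len(nrow(tup)), function(a)
          covers(pat, tup[a, ]), logical(1)))
        expect_true(all(r$outputs[rows] == want))
        lits <- which(strsplit(pat, "")[[1]] != "#")
        for (j in lits) {
          wider <- pat
          substr(wider, j, j) <- "#"
          rows2 <- which(vapply(seq_len(nrow(tup)), function(a)
            covers(wider, tup[a, ]), logical(1)))
          expect_false(all(r$outputs[rows2] == want))
        }
      }
    }
  }
})

test_that("effective connectivity reproduces the canonical values", {
  expect_equal(effective_connectivity(or_rule(2)), 1.25)
  expect_equal(effective_connectivity(and_rule(2)), 1.25)
  expect_equal(effective_connectivity(xor_rule(2)), 2)
  expect_equal(effective_connectivity(xor_rule(4)), 4)
  expect_equal(effective_connectivity(and_rule(3)), 1.25)  # (7*1 + 1*3)/8
  expect_equal(effective_connectivity(copy_rule()), 1)
  expect_equal(effective_connectivity(constant_rule(3, 0)), 0)
  expect_equal(effective_connectivity(constant_rule(2, 1)), 0)
})

test_that("schema-based k_e equals the minimal-subset oracle exhaustively", {
  # all 2^(2^2) = 16 rules of k = 2 and all 256 rules of k = 3
  for (k in 1:3) {
    for (r in all_rules(k)) {
      expect_equal(effective_connectivity(r), oracle_ke(r))
    }
  }
})

test_that("k_e equals the oracle on random k = 4 rules, exactly", {
  set.seed(404)
  for (i in 1:150) {
    r <- random_rule(4, runif(1))
    expect_identical(effective_connectivity(r), oracle_ke(r))
  }
})

test_that("compiled kernel and prime-implicant route agree", {
  set.seed(77)
  for (i in 1:30) {
    k <- sample(2:6, 1)
    r <- random_rule(k, runif(1))
    expect_equal(effective_connectivity(r), canalcrit:::schema_ke(r))
  }
})

test_that("k_e is invariant under output/input symmetries", {
  set.seed(21)
  for (i in 1:20) {
    k <- sample(2:4, 1)
    r <- random_rule(k, runif(1))
    ke <- effective_connectivity(r)
    # output complementation
    expect_equal(effective_connectivity(boolean_rule(k, 1L - r$outputs)), ke)
    # input permutation
    perm <- sample(k)
    tup <- input_tuples(k)
    idx <- apply(tup[, perm, drop = FALSE], 1, function(x) sum(x * 2^((k - 1):0))) + 1
    expect_equal(effective_connectivity(boolean_rule(k, r$outputs[idx])), ke)
    # negation of one input
    j <- sample(k, 1)
    idx2 <- bitwXor(0:(2^k - 1), 2^(k - j)) + 1
    expect_equal(effective_connectivity(boolean_rule(k, r$outputs[idx2])), ke)
    # bounded by arity; equality only for parity at k >= 2
    expect_lte(ke, k)
  }
  # parity saturates the bound; every other non-constant k=3 rule is below it
  for (r in all_rules(3)) {
    ke <- effective_connectivity(r)
    parity <- identical(r$outputs, xor_rule(3)$outputs) ||
      identical(r$outputs, 1L - xor_rule(3)$outputs)
    if (parity) expect_equal(ke, 3) else expect_lt(ke, 3)
  }
})

test_that("average sensitivity matches closed-form values", {
  expect_equal(average_sensitivity(and_rule(2)), 1)
  expect_equal(average_sensitivity(or_rule(2)), 1)
  expect_equal(average_sensitivity(copy_rule()), 1)
  expect_equal(average_sensitivity(copy_rule(negate = TRUE)), 1)
  expect_equal(average_sensitivity(xor_rule(2)), 2)
  expect_equal(average_sensitivity(xor_rule(5)), 5)
  expect_equal(average_sensitivity(constant_rule(3, 1)), 0)
})

test_that("mean sensitivity of random rules approaches 2 k p (1 - p)", {
  # the generator places an exact ON count, so entry pairs are sampled
  # without replacement: the iid-entry value 2kp(1-p) carries the
  # finite-population factor S/(S-1)
  set.seed(314)
  for (case in list(c(k = 3, p = 0.25), c(k = 4, p = 0.5))) {
    k <- case[["k"]]; p <- case[["p"]]
    S <- 2^k
    s <- replicate(400, average_sensitivity(random_rule(k, p)))
    expected <- 2 * k * p * (1 - p) * S / (S - 1)
    expect_lt(abs(mean(s) - expected), 3 * sd(s) / sqrt(length(s)))
  }
})

test_that("network mean k_e averages per-node values", {
  net_or <- boolean_network(rep(list(or_rule(2)), 4),
                            rep(list(c(1L, 2L)), 4))
  expect_equal(network_mean_ke(net_or), 1.25)
  net_mix <- boolean_network(list(or_rule(2), or_rule(2), xor_rule(2), xor_rule(2)),
                             rep(list(c(1L, 2L)), 4))
  expect_equal(network_mean_ke(net_mix), 1.625)
  net <- fixture_network()
  expect_equal(network_mean_ke(net),
               mean(vapply(network_rules(net), oracle_ke, numeric(1))))
})
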