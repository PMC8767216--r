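# Independent brute-force oracles, kept free of the package's schema and
# simulation code paths so they can vouch for them.

# Minimal-sufficient-subset effective connectivity: for each LUT entry,
# the enput count is the smallest number of inputs whose fixation to the
# entry's states forces the rule's output, found by exhaustive subset
# enumeration. k_e is the mean over entries.
oracle_ke <- function(rule) {
  k <- rule$k
  if (k == 0L) return(0)
  out <- rule$outputs
  tup <- input_tuples(k)
  S <- 2L^k
  subsets <- lapply(0:(S - 1L), function(m) which(bitwAnd(m, 2L^(0:(k - 1L))) > 0L))
  subsets <- subsets[order(lengths(subsets))]
  total <- 0
  for (a in seq_len(S)) {
    for (sub in subsets) {
      match_rows <- if (length(sub) == 0L) seq_len(S) else {
        which(colSums(t(tup[, sub, drop = FALSE]) == tup[a, sub]) == length(sub))
      }
      if (all(out[match_rows] == out[a])) {
        total <- total + length(sub)
        break
      }
    }
  }
  total / S
}

# All 2^(2^k) rules of arity k (k small), as a list of boolean_rule
all_rules <- function(k) {
  S <- 2L^k
  lapply(0:(2L^S - 1L), function(code) {
    boolean_rule(k, as.integer(bitwAnd(code, 2L^(0:(S - 1L))) > 0L))
  })
}

# Exact expected Derrida divergence for tiny networks: average Hamming
# distance after t steps over ALL configurations and ALL m-subsets.
oracle_derrida_exact <- function(net, m, t = 1L) {
  n <- network_size(net)
  stopifnot(n <= 12L)
  configs <- as.matrix(expand.grid(rep(list(0:1), n)))
  subsets <- utils::combn(n, m)
  advance <- function(x) {
    for (s in seq_len(t)) x <- step_network(net, x)
    x
  }
  tot <- 0
  cnt <- 0
  for (ci in seq_len(nrow(configs))) {
    x <- as.integer(configs[ci, ])
    fx <- advance(x)
    for (si in seq_len(ncol(subsets))) {
      y <- x
      y[subsets[, si]] <- 1L - y[subsets[, si]]
      tot <- tot + hamming(fx, advance(y))
      cnt <- cnt + 1
    }
  }
  tot / cnt
}

# A small heterogeneous fixture network with hand-picked rules
fixture_network <- function() {
  boolean_network(
    rules = list(or_rule(2), and_rule(2), xor_rule(2), copy_rule(),
                 boolean_rule(3, c(0L, 1L, 1L, 0L, 1L, 0L, 0L, 1L)),
                 constant_rule(1, 1), copy_rule(negate = TRUE),
                 boolean_rule(2, c(1L, 0L, 0L, 0L))),
    inputs = list(c(2L, 3L), c(1L, 4L), c(5L, 6L), 7L,
                  c(1L, 2L, 8L), 6L, 3L, c(4L, 5L))
  )
}
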