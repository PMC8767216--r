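#' Effective connectivity of a Boolean rule
#'
#' Effective connectivity `k_e` measures how many inputs an automaton
#' *really* needs, once canalization (dynamical redundancy) is accounted
#' for. Every LUT entry is matched against the rule's wildcard schemata;
#' the entry's *enput* count is `k` minus the wildcard count of the most
#' compressed schema covering it (equivalently, the size of the smallest
#' input subset whose fixation forces the output). `k_e` is the mean enput
#' count over all `2^k` entries, so `0 <= k_e <= k`, with `k_e = 0` only
#' for constant rules and `k_e = k` only for parity rules (or non-constant
#' rules with `k <= 1`).
#'
#' For `k <= 12` the computation runs in compiled code via a subcube
#' dynamic programme; larger arities fall back to prime-implicant
#' enumeration, which is efficient for the canalized rules found in
#' biological models.
#'
#' @param rule a [boolean_rule()].
#' @return `k_e`, a real number in `[0, k]`.
#' @examples
#' effective_connectivity(or_rule(2))   # 1.25
#' effective_connectivity(xor_rule(2))  # 2: parity has no redundancy
#' @export
effective_connectivity <- function(rule) {
  stopifnot(is_boolean_rule(rule))
  if (rule$k <= 12L) .ke_lut(rule$outputs) else schema_ke(rule)
}

#' Effective connectivity for a batch of equal-arity LUTs
#'
#' @param outputs integer 0/1 matrix, one `2^k`-long LUT per row.
#' @return Numeric vector of `k_e` values, one per row.
#' @export
effective_connectivity_batch <- function(outputs) {
  outputs <- as.matrix(outputs)
  storage.mode(outputs) <- "integer"
  .ke_lut_batch(outputs)
}

#' Average sensitivity of a Boolean rule
#'
#' The activity of input `j` is the probability, over uniformly random
#' input tuples, that flipping input `j` flips the output; sensitivity is
#' the sum of activities over all inputs. It aggregates each input's
#' influence independently and therefore, unlike effective connectivity,
#' ignores collective canalization: e.g. `s(AND2) = s(COPY) = 1` although
#' their `k_e` differ.
#'
#' @param rule a [boolean_rule()].
#' @return Sensitivity `s >= 0`.
#' @export
average_sensitivity <- function(rule) {
  stopifnot(is_boolean_rule(rule))
  k <- rule$k
  if (k == 0L) return(0)
  out <- rule$outputs
  alpha <- 0:(2L^k - 1L)
  s <- 0
  for (j in seq_len(k)) {
    partner <- bitwXor(alpha, 2L^(k - j))
    s <- s + mean(out != out[partner + 1L])
  }
  s
}

#' Mean effective connectivity of a network
#'
#' Arithmetic mean of per-node `k_e` over all nodes.
#'
#' @param net a [boolean_network()].
#' @return Mean `k_e`.
#' @export
network_mean_ke <- function(net) {
  stopifnot(is_boolean_network(net))
  mean(vapply(net$rules, effective_connectivity, numeric(1L)))
}

#' Canalization summary of a rule
#'
#' @param rule a [boolean_rule()].
#' @return List with `k`, `k_e` and `sensitivity`.
#' @export
canalization_summary <- function(rule) {
  stopifnot(is_boolean_rule(rule))
  list(k = rule$k,
       k_e = effective_connectivity(rule),
       sensitivity = average_sensitivity(rule))
}
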