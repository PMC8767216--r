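#' Boolean automaton as a look-up table
#'
#' A Boolean automaton with `k` inputs is fully described by its look-up
#' table (LUT): one output state for each of the `2^k` input combinations.
#' Rows are ordered lexicographically over the input tuple
#' `(i1, ..., ik)` with the *first* input most significant, so row 1 is
#' `(0, ..., 0)` and row `2^k` is `(1, ..., 1)`.
#'
#' @param k number of inputs (non-negative integer).
#' @param outputs integer vector of 0/1 output states, length `2^k`,
#'   in lexicographic row order.
#' @param name optional rule label.
#' @return An object of class `boolean_rule`: a list with elements `k`,
#'   `outputs` and `name`.
#' @examples
#' r <- boolean_rule(2, c(0, 1, 1, 1))  # OR of two inputs
#' evaluate_rule(r, c(0, 0))
#' rule_bias(r)
#' @export
boolean_rule <- function(k, outputs, name = NULL) {
  k <- as.integer(k)
  if (length(k) != 1L || is.na(k) || k < 0L) {
    stop("'k' must be a single non-negative integer", call. = FALSE)
  }
  outputs <- as.integer(outputs)
  if (length(outputs) != 2L^k) {
    stop(sprintf("'outputs' must have length 2^k = %d, got %d",
                 2L^k, length(outputs)), call. = FALSE)
  }
  if (anyNA(outputs) || !all(outputs %in% c(0L, 1L))) {
    stop("'outputs' must contain only 0 and 1", call. = FALSE)
  }
  structure(list(k = k, outputs = outputs, name = name),
            class = "boolean_rule")
}

#' @export
print.boolean_rule <- function(x, ...) {
  nm <- if (is.null(x$name)) "" else paste0(" '", x$name, "'")
  cat(sprintf("Boolean rule%s: k = %d, bias = %.4g, k_e = %.4g\n",
              nm, x$k, rule_bias(x), effective_connectivity(x)))
  if (x$k <= 4L) {
    tup <- input_tuples(x$k)
    cat(paste0("  ", apply(tup, 1L, paste0, collapse = ""), " -> ",
               x$outputs, collapse = "\n"), "\n")
  } else {
    cat("  outputs:", paste0(x$outputs, collapse = ""), "\n")
  }
  invisible(x)
}

is_boolean_rule <- function(x) inherits(x, "boolean_rule")

#' All input tuples of a k-input rule, in LUT row order
#'
#' @param k number of inputs.
#' @return A `2^k` by `k` 0/1 matrix; row `a` is the input tuple of LUT
#'   row `a` (first input most significant).
#' @export
input_tuples <- function(k) {
  k <- as.integer(k)
  if (k == 0L) return(matrix(integer(0), nrow = 1L, ncol = 0L))
  vapply(seq_len(k),
         function(j) rep(rep(c(0L, 1L), each = 2L^(k - j)), times = 2L^(j - 1L)),
         integer(2L^k))
}

# 1-based LUT row index of an input tuple (first input most significant)
lut_index <- function(inputs) {
  k <- length(inputs)
  if (k == 0L) return(1L)
  sum(as.integer(inputs) * 2L^((k - 1L):0L)) + 1L
}

#' Evaluate a Boolean rule on one input tuple
#'
#' @param rule a [boolean_rule()].
#' @param input_states 0/1 vector of length `rule$k`.
#' @return The output state (0 or 1).
#' @export
evaluate_rule <- function(rule, input_states) {
  stopifnot(is_boolean_rule(rule))
  input_states <- as.integer(input_states)
  if (length(input_states) != rule$k) {
    stop(sprintf("arity mismatch: rule has k = %d inputs, got %d states",
                 rule$k, length(input_states)), call. = FALSE)
  }
  if (anyNA(input_states) || !all(input_states %in% c(0L, 1L))) {
    stop("input states must be 0 or 1", call. = FALSE)
  }
  rule$outputs[lut_index(input_states)]
}

#' Output bias of a rule
#'
#' The bias `p` is the fraction of LUT entries whose output is 1, i.e.
#' the probability that the automaton transitions ON under uniformly
#' random inputs.
#'
#' @param rule a [boolean_rule()].
#' @return Bias in `[0, 1]`.
#' @export
rule_bias <- function(rule) {
  stopifnot(is_boolean_rule(rule))
  mean(rule$outputs)
}

#' Random Boolean rule with fixed arity and bias
#'
#' Draws a rule with exactly `round(p * 2^k)` ON entries placed uniformly
#' at random in the LUT, mirroring how rules are built when sweeping a
#' bias grid: the bias is realized as an integer ON count, so requested
#' biases that are not multiples of `1/2^k` are rounded to the nearest
#' attainable value. Uses the current R RNG stream; seed with
#' [set.seed()] for reproducibility.
#'
#' @param k number of inputs.
#' @param p requested bias.
#' @return A [boolean_rule()] whose realized bias is `round(p * 2^k) / 2^k`.
#' @export
random_rule <- function(k, p) {
  k <- as.integer(k)
  if (length(k) != 1L || is.na(k) || k < 0L) {
    stop("'k' must be a single non-negative integer", call. = FALSE)
  }
  if (p < 0 || p > 1) stop("'p' must lie in [0, 1]", call. = FALSE)
  size <- 2L^k
  ones <- as.integer(round(p * size))
  outputs <- integer(size)
  if (ones > 0L) outputs[sample.int(size, ones)] <- 1L
  boolean_rule(k, outputs)
}

# ---- named rule constructors (convenience, used widely in tests) --------

#' Common named rules
#'
#' Constructors for frequently used automata: `or_rule(k)` and
#' `and_rule(k)` are the k-input disjunction/conjunction, `xor_rule(k)`
#' the k-input parity, `constant_rule(k, value)` the tautology or
#' contradiction, and `copy_rule(negate)` the 1-input identity (or NOT).
#'
#' @param k number of inputs.
#' @param value constant output (0 or 1).
#' @param negate if `TRUE`, `copy_rule` returns negation.
#' @name named_rules
NULL

#' @rdname named_rules
#' @export
or_rule <- function(k = 2L) {
  tup <- input_tuples(k)
  boolean_rule(k, as.integer(rowSums(tup) > 0L), name = paste0("OR", k))
}

#' @rdname named_rules
#' @export
and_rule <- function(k = 2L) {
  tup <- input_tuples(k)
  boolean_rule(k, as.integer(rowSums(tup) == k), name = paste0("AND", k))
}

#' @rdname named_rules
#' @export
xor_rule <- function(k = 2L) {
  tup <- input_tuples(k)
  boolean_rule(k, as.integer(rowSums(tup) %% 2L), name = paste0("XOR", k))
}

#' @rdname named_rules
#' @export
constant_rule <- function(k, value) {
  value <- as.integer(value)
  stopifnot(value %in% c(0L, 1L))
  boolean_rule(k, rep(value, 2L^k), name = paste0("CONST", value))
}

#' @rdname named_rules
#' @export
copy_rule <- function(negate = FALSE) {
  boolean_rule(1L, if (negate) c(1L, 0L) else c(0L, 1L),
               name = if (negate) "NOT" else "COPY")
}

# Is the rule constant (tautology or contradiction)?
is_constant_rule <- function(rule) {
  stopifnot(is_boolean_rule(rule))
  all(rule$outputs == rule$outputs[1L])
}
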