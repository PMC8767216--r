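#' Boolean network of automata
#'
#' A Boolean network is a directed graph whose nodes are Boolean automata:
#' node `i` carries an ordered list of input nodes and a [boolean_rule()]
#' whose arity equals the number of inputs. All nodes update synchronously.
#'
#' @param rules list of [boolean_rule()] objects, one per node.
#' @param inputs list of integer vectors; `inputs[[i]]` are the (ordered)
#'   node indices feeding node `i`. Self-inputs are allowed; external
#'   "input nodes" are conventionally modelled as 1-input self-loop copy
#'   rules.
#' @param names optional character vector of node names.
#' @return An object of class `boolean_network`.
#' @examples
#' # two nodes copying each other
#' net <- boolean_network(list(copy_rule(), copy_rule()), list(2L, 1L))
#' step_network(net, c(1L, 0L))
#' @export
boolean_network <- function(rules, inputs, names = NULL) {
  n <- length(rules)
  if (n == 0L) stop("a network needs at least one node", call. = FALSE)
  if (length(inputs) != n) {
    stop("'rules' and 'inputs' must have the same length", call. = FALSE)
  }
  if (!all(vapply(rules, is_boolean_rule, logical(1L)))) {
    stop("all elements of 'rules' must be boolean_rule objects", call. = FALSE)
  }
  inputs <- lapply(inputs, as.integer)
  for (i in seq_len(n)) {
    ins <- inputs[[i]]
    if (anyNA(ins) || any(ins < 1L) || any(ins > n)) {
      stop(sprintf("node %d has an input reference outside 1..%d", i, n),
           call. = FALSE)
    }
    if (length(ins) != rules[[i]]$k) {
      stop(sprintf("node %d: rule arity %d but %d inputs listed",
                   i, rules[[i]]$k, length(ins)), call. = FALSE)
    }
    if (rules[[i]]$k < 1L) {
      stop(sprintf("node %d: rules in networks need at least one input", i),
           call. = FALSE)
    }
  }
  if (is.null(names)) names <- paste0("x", seq_len(n))
  if (length(names) != n || anyDuplicated(names)) {
    stop("'names' must be unique and one per node", call. = FALSE)
  }
  structure(list(rules = rules, inputs = inputs, names = names),
            class = "boolean_network")
}

is_boolean_network <- function(x) inherits(x, "boolean_network")

#' @export
print.boolean_network <- function(x, ...) {
  ks <- network_in_degrees(x)
  cat(sprintf("Boolean network: %d nodes, in-degree %s\n",
              network_size(x),
              if (length(unique(ks)) == 1L) sprintf("k = %d", ks[1L])
              else sprintf("in [%d, %d], mean %.2f", min(ks), max(ks), mean(ks))))
  invisible(x)
}

#' Network accessors
#'
#' `network_size` returns the number of nodes, `network_in_degrees` the
#' per-node in-degree vector, `network_rules` the list of rules, and
#' `network_biases` the per-node rule biases.
#'
#' @param net a [boolean_network()].
#' @name network_accessors
NULL

#' @rdname network_accessors
#' @export
network_size <- function(net) {
  stopifnot(is_boolean_network(net))
  length(net$rules)
}

#' @rdname network_accessors
#' @export
network_in_degrees <- function(net) {
  stopifnot(is_boolean_network(net))
  vapply(net$rules, function(r) r$k, integer(1L))
}

#' @rdname network_accessors
#' @export
network_rules <- function(net) {
  stopifnot(is_boolean_network(net))
  net$rules
}

#' @rdname network_accessors
#' @export
network_biases <- function(net) {
  stopifnot(is_boolean_network(net))
  vapply(net$rules, rule_bias, numeric(1L))
}

#' Synchronous update of one configuration
#'
#' Every node simultaneously evaluates its rule on the states its inputs
#' held at the current time step.
#'
#' @param net a [boolean_network()].
#' @param config 0/1 state vector of length `network_size(net)`. A `time`
#'   attribute, if present, is incremented on the result.
#' @return The successor configuration.
#' @export
step_network <- function(net, config) {
  stopifnot(is_boolean_network(net))
  n <- network_size(net)
  states <- as.integer(config)
  if (length(states) != n) {
    stop(sprintf("configuration length %d does not match network size %d",
                 length(states), n), call. = FALSE)
  }
  if (anyNA(states) || !all(states %in% c(0L, 1L))) {
    stop("configuration states must be 0 or 1", call. = FALSE)
  }
  nxt <- step_configs(net, matrix(states, ncol = 1L))[, 1L]
  t0 <- attr(config, "time")
  if (!is.null(t0)) attr(nxt, "time") <- t0 + 1L
  nxt
}

# Synchronous update of many configurations at once.
# S: n x C integer matrix, one configuration per column. Returns same shape.
step_configs <- function(net, S) {
  n <- network_size(net)
  out <- matrix(0L, nrow = n, ncol = ncol(S))
  for (i in seq_len(n)) {
    ins <- net$inputs[[i]]
    k <- length(ins)
    block <- S[ins, , drop = FALSE]
    idx <- as.integer(2L^((k - 1L):0L) %*% block)
    out[i, ] <- net$rules[[i]]$outputs[idx + 1L]
  }
  out
}

#' Hamming distance between configurations
#'
#' @param a,b 0/1 vectors of equal length.
#' @return Number of differing positions.
#' @export
hamming <- function(a, b) {
  if (length(a) != length(b)) {
    stop("configurations must have equal length", call. = FALSE)
  }
  sum(as.integer(a) != as.integer(b))
}

#' Random homogeneous input wiring
#'
#' Draws, for each of `n` nodes, `k` distinct input nodes uniformly at
#' random (self-inputs permitted).
#'
#' @param n number of nodes.
#' @param k in-degree.
#' @return List of length-`k` integer vectors.
#' @keywords internal
random_inputs <- function(n, k) {
  if (k > n) stop("cannot draw more distinct inputs than nodes", call. = FALSE)
  lapply(seq_len(n), function(i) sample.int(n, k))
}
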