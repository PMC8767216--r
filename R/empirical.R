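#' Filter an automata set for canalization analysis
#'
#' Removes constant rules (tautologies and contradictions, for which
#' `k_e = 0` by definition) and then single-input rules (for which
#' `k_e = k = 1` carries no canalization information), returning the
#' retained set together with removal counts. Idempotent.
#'
#' @param rules list of [boolean_rule()] objects.
#' @return List with `retained` (list of rules), `n_total`,
#'   `n_constant`, `n_single_input`, `n_retained`.
#' @export
filter_automata <- function(rules) {
  stopifnot(all(vapply(rules, is_boolean_rule, logical(1L))))
  n_total <- length(rules)
  const <- vapply(rules, is_constant_rule, logical(1L))
  rules2 <- rules[!const]
  single <- vapply(rules2, function(r) r$k == 1L, logical(1L))
  retained <- rules2[!single]
  if (length(retained) == 0L) {
    warning("no automata retained after filtering")
  }
  list(retained = retained, n_total = n_total,
       n_constant = sum(const), n_single_input = sum(single),
       n_retained = length(retained))
}

# quartiles by the median-of-halves rule: split the sorted data at the
# median (excluding it when n is odd), take the median of each half
quartiles_mh <- function(x) {
  x <- sort(x)
  n <- length(x)
  half <- n %/% 2L
  c(q1 = stats::median(x[seq_len(half)]),
    q3 = stats::median(x[(n - half + 1L):n]))
}

# Pearson's moment coefficient of skewness (population moments)
moment_skewness <- function(x) {
  m <- mean(x)
  m2 <- mean((x - m)^2)
  if (m2 == 0) return(0)
  mean((x - m)^3) / m2^1.5
}

# excess kurtosis (normal = 0)
excess_kurtosis <- function(x) {
  m <- mean(x)
  m2 <- mean((x - m)^2)
  if (m2 == 0) return(0)
  mean((x - m)^4) / m2^2 - 3
}

distribution_stats <- function(x) {
  q <- quartiles_mh(x)
  list(mean = mean(x), median = stats::median(x),
       q1 = unname(q["q1"]), q3 = unname(q["q3"]),
       skewness = moment_skewness(x),
       ex_kurtosis = excess_kurtosis(x))
}

#' Summary statistics of a filtered automata set
#'
#' Distributional statistics of in-degree `k` and effective connectivity
#' `k_e` over a set of automata: mean, median, interquartile range
#' (reported as the `(q3, q1)` endpoint pair, median-of-halves
#' quartiles), Pearson's moment coefficient of skewness and excess
#' kurtosis (normal = 0).
#'
#' @param rules list of at least two [boolean_rule()] objects (typically
#'   the `retained` set from [filter_automata()]).
#' @return Object of class `automata_set_summary`: `n`, and stat lists
#'   `k` and `ke`.
#' @export
summarize_set <- function(rules) {
  stopifnot(all(vapply(rules, is_boolean_rule, logical(1L))))
  if (length(rules) < 2L) stop("need at least 2 automata", call. = FALSE)
  k <- vapply(rules, function(r) as.numeric(r$k), numeric(1L))
  ke <- vapply(rules, effective_connectivity, numeric(1L))
  structure(list(n = length(rules),
                 k = distribution_stats(k),
                 ke = distribution_stats(ke)),
            class = "automata_set_summary")
}

#' @export
print.automata_set_summary <- function(x, ...) {
  fmt <- function(s) {
    sprintf("mean %.3g, median %.3g, IQR %.3g-%.3g, skew %.3g, ex.kurt %.3g",
            s$mean, s$median, s$q3, s$q1, s$skewness, s$ex_kurtosis)
  }
  cat(sprintf("Automata set (n = %d)\n  k  : %s\n  k_e: %s\n",
              x$n, fmt(x$k), fmt(x$ke)))
  invisible(x)
}

#' Canalization and regime analysis of a network collection
#'
#' For each user-supplied (possibly heterogeneous) Boolean network:
#' per-node means of `k`, `p` and `k_e`, the Derrida parameter, and the
#' regime label. When both labels occur, class-2 criticality boundaries
#' are re-fitted on the per-network table in both the structural
#' `(mean k, mean p)` and canalization `(mean k_e, mean p)` spaces.
#'
#' @param networks list of [boolean_network()] objects.
#' @param pairs,t,m_max Derrida settings (see [derrida_curve()]).
#' @param seed RNG seed for the Derrida simulations.
#' @return List with `table` (one row per network: `mean_k`, `mean_p`,
#'   `mean_ke`, `zeta`, `regime`), `st_fit` and `ct_fit` (class-2
#'   `criticality_fit`s, or `NULL` with a `notice` when refitting is not
#'   possible).
#' @export
analyze_model_collection <- function(networks, pairs = 250L, t = 1L,
                                     m_max = NULL, seed = 1L) {
  stopifnot(length(networks) >= 1L,
            all(vapply(networks, is_boolean_network, logical(1L))))
  set.seed(seed)
  rows <- lapply(seq_along(networks), function(i) {
    net <- networks[[i]]
    zeta <- derrida_zeta(net, pairs = pairs, t = t, m_max = m_max)
    data.frame(network = i,
               n = network_size(net),
               mean_k = mean(network_in_degrees(net)),
               mean_p = mean(network_biases(net)),
               mean_ke = network_mean_ke(net),
               zeta = zeta,
               regime = classify_regime(zeta),
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  st_fit <- ct_fit <- NULL
  notice <- NULL
  labels <- as.integer(tab$zeta > 1)
  if (length(unique(labels)) == 2L) {
    rec <- data.frame(k = tab$mean_k, p = tab$mean_p, ke = tab$mean_ke,
                      zeta = tab$zeta, chaotic = labels)
    st_fit <- fit_model(rec, 2L, kappa = "k")
    ct_fit <- fit_model(rec, 2L, kappa = "ke")
  } else {
    notice <- "single regime label in collection; boundary refit skipped"
  }
  list(table = tab, st_fit = st_fit, ct_fit = ct_fit, notice = notice)
}
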