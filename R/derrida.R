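#' Derrida divergence curve of a Boolean network
#'
#' Perturbation-spreading experiment: for each of `pairs` trials, draw a
#' random configuration and a copy with `m` distinct node states flipped
#' (`m` uniform on `1..m_max` by default), advance both `t` synchronous
#' steps, and record the Hamming distance between the results. The curve
#' reports the mean distance per perturbation size `m`.
#'
#' @param net a [boolean_network()].
#' @param pairs number of configuration pairs (`I`).
#' @param t number of synchronous steps.
#' @param m_max largest perturbation size; default `floor(n/10)` (at
#'   least 1).
#' @param stratified if `TRUE`, spread pairs evenly over `m = 1..m_max`
#'   instead of drawing `m` at random (variance control; off by default).
#' @return A data frame of class `derrida_curve` with columns `m`,
#'   `mean_h`, `n_pairs`, `sd_h`, and attributes `pairs`, `t`, `m_max`.
#' @export
derrida_curve <- function(net, pairs = 250L, t = 1L, m_max = NULL,
                          stratified = FALSE) {
  stopifnot(is_boolean_network(net), pairs >= 1L, t >= 1L)
  n <- network_size(net)
  if (is.null(m_max)) m_max <- max(1L, n %/% 10L)
  m_max <- as.integer(m_max)
  if (m_max < 1L || m_max > n) stop("'m_max' must lie in 1..n", call. = FALSE)
  ms <- if (stratified) rep_len(seq_len(m_max), pairs)
        else sample.int(m_max, pairs, replace = TRUE)
  S0 <- matrix(sample(c(0L, 1L), n * pairs, replace = TRUE), nrow = n)
  S1 <- S0
  for (j in seq_len(pairs)) {
    flip <- sample.int(n, ms[j])
    S1[flip, j] <- 1L - S1[flip, j]
  }
  for (s in seq_len(t)) {
    S0 <- step_configs(net, S0)
    S1 <- step_configs(net, S1)
  }
  h <- colSums(S0 != S1)
  mu <- tapply(h, ms, mean)
  nn <- tapply(h, ms, length)
  sdv <- tapply(h, ms, stats::sd)
  curve <- data.frame(m = as.integer(names(mu)),
                      mean_h = as.numeric(mu),
                      n_pairs = as.integer(nn),
                      sd_h = as.numeric(sdv))
  curve <- curve[order(curve$m), ]
  rownames(curve) <- NULL
  attr(curve, "pairs") <- pairs
  attr(curve, "t") <- t
  attr(curve, "m_max") <- m_max
  class(curve) <- c("derrida_curve", "data.frame")
  curve
}

#' Derrida parameter: slope of the divergence curve at the origin
#'
#' Ordinary least-squares slope of mean Hamming divergence against
#' perturbation size, constrained through the origin, over all observed
#' `m` values. At `t = 1` the Derrida map is near-linear in `m`, making
#' this the natural discrete estimate of the slope at the origin.
#'
#' @param curve a [derrida_curve()], or any data frame with columns `m`
#'   and `mean_h`, or a numeric vector of mean divergences named by `m`.
#' @return The slope `zeta >= 0`.
#' @export
derrida_coefficient <- function(curve) {
  if (is.numeric(curve) && !is.null(names(curve))) {
    curve <- data.frame(m = as.numeric(names(curve)), mean_h = as.numeric(curve))
  }
  if (!is.data.frame(curve) || !all(c("m", "mean_h") %in% names(curve)) ||
      nrow(curve) == 0L) {
    stop("'curve' must be a non-empty table with columns m and mean_h",
         call. = FALSE)
  }
  w <- sum(curve$m^2)
  if (w <= 0) stop("divergence table has zero total weight", call. = FALSE)
  sum(curve$m * curve$mean_h) / w
}

#' Classify the dynamical regime from the Derrida parameter
#'
#' A network is labelled chaotic iff `zeta > 1` strictly; the boundary
#' value `zeta = 1` (criticality) is grouped with the stable side.
#'
#' @param zeta Derrida parameter(s), non-negative.
#' @return Character vector, `"chaotic"` or `"stable"`. The binary
#'   regime indicator used in regression is `as.integer(zeta > 1)`.
#' @export
classify_regime <- function(zeta) {
  if (any(zeta < 0)) stop("'zeta' must be non-negative", call. = FALSE)
  ifelse(zeta > 1, "chaotic", "stable")
}

#' One-call Derrida parameter of a network
#'
#' @inheritParams derrida_curve
#' @return `zeta` from [derrida_coefficient()] of the simulated curve.
#' @export
derrida_zeta <- function(net, pairs = 250L, t = 1L, m_max = NULL,
                         stratified = FALSE) {
  derrida_coefficient(derrida_curve(net, pairs = pairs, t = t,
                                    m_max = m_max, stratified = stratified))
}
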