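#' Regime records from an ensemble manifest
#'
#' Flattens a swept manifest into the regression table: one row per
#' network with its tuning parameters, Derrida parameter and binary
#' regime label (1 = chaotic, i.e. `zeta > 1`).
#'
#' @param manifest data frame with columns `k`, `p`, `mean_ke`, `zeta`.
#' @return Data frame with columns `k`, `p`, `ke`, `zeta`, `chaotic`.
#' @export
regime_records <- function(manifest) {
  stopifnot(all(c("k", "p", "mean_ke", "zeta") %in% names(manifest)))
  data.frame(k = manifest$k, p = manifest$p, ke = manifest$mean_ke,
             zeta = manifest$zeta,
             chaotic = as.integer(manifest$zeta > 1))
}

# design matrix for one model class; kappa is "k" or "ke"
# classes (increasing complexity):
#   1: c1*kappa
#   2: c1*kappa*p(1-p)
#   3: c1*kappa + c2*p(1-p)
#   4: c1*kappa + c2*kappa*p(1-p)
#   5: c1*kappa*p(1-p) + c2*p(1-p)
#   6: c1*kappa + c2*kappa*p(1-p) + c3*p(1-p)
class_terms <- function(class_id) {
  switch(class_id,
         `1` = "kappa",
         `2` = "kappa_pq",
         `3` = c("kappa", "pq"),
         `4` = c("kappa", "kappa_pq"),
         `5` = c("kappa_pq", "pq"),
         `6` = c("kappa", "kappa_pq", "pq"),
         stop("class_id must be 1..6", call. = FALSE))
}

design_frame <- function(records, terms, kappa) {
  kap <- records[[kappa]]
  pq <- records$p * (1 - records$p)
  cols <- list(kappa = kap, pq = pq, kappa_pq = kap * pq)
  as.data.frame(cols[terms])
}

fit_logistic <- function(X, y) {
  dat <- cbind(X, .y = y)
  warn <- character(0)
  fit <- withCallingHandlers(
    stats::glm(.y ~ ., family = stats::binomial(), data = dat,
               control = stats::glm.control(maxit = 100L)),
    warning = function(w) {
      warn <<- c(warn, conditionMessage(w))
      invokeRestart("muffleWarning")
    })
  list(fit = fit, warnings = warn)
}

#' Fit a criticality model class by logistic regression
#'
#' Fits `P(chaotic) = logistic(b0 + sum bi * term_i)` by maximum
#' likelihood for one of the six model classes, with `kappa` either the
#' structural in-degree `k` or the mean effective connectivity `ke`. The
#' fitted 0.5-probability locus is rearranged into boundary form
#' `sum c_i * term_i = 1` with `c_i = -b_i / b0` (the algebra:
#' `b0 + sum bi ti = 0  <=>  sum (-bi/b0) ti = 1`). No regularization is
#' applied — the coefficients are read as theory constants; (quasi-)
#' separation is handled by the iteration cap and surfaced in
#' `diagnostics`.
#'
#' @param records regime table from [regime_records()] (columns `k`,
#'   `p`, `ke`, `chaotic`).
#' @param class_id model class 1..6.
#' @param kappa `"ke"` (canalization) or `"k"` (structural).
#' @return Object of class `criticality_fit`: raw logistic coefficients,
#'   boundary coefficients, threshold `tau = 0.5`, convergence
#'   diagnostics and the underlying `glm` fit.
#' @export
fit_model <- function(records, class_id, kappa = c("ke", "k")) {
  kappa <- match.arg(kappa)
  y <- records$chaotic
  if (length(unique(y)) < 2L) {
    stop("records must contain both regime labels", call. = FALSE)
  }
  terms <- class_terms(as.character(class_id))
  X <- design_frame(records, terms, kappa)
  res <- fit_logistic(X, y)
  new_criticality_fit(res, terms, kappa, class_id)
}

new_criticality_fit <- function(res, terms, kappa, class_id) {
  beta <- stats::coef(res$fit)
  b0 <- beta[["(Intercept)"]]
  bt <- beta[names(beta) != "(Intercept)"]
  boundary <- if (abs(b0) > 0) -bt / b0 else rep(NA_real_, length(bt))
  names(boundary) <- terms
  structure(list(class_id = class_id,
                 kappa = kappa,
                 terms = terms,
                 coefficients = beta,
                 boundary = boundary,
                 tau = 0.5,
                 diagnostics = list(converged = res$fit$converged,
                                    warnings = res$warnings),
                 glm = res$fit),
            class = "criticality_fit")
}

#' @export
print.criticality_fit <- function(x, ...) {
  pretty <- c(kappa = x$kappa,
              pq = "p(1-p)",
              kappa_pq = paste0(x$kappa, "*p(1-p)"),
              k = "k", ke = "<ke>", k_ke = paste0("k*<ke>"))
  lhs <- paste(sprintf("%.3g*%s", x$boundary, pretty[x$terms]),
               collapse = " + ")
  cat(sprintf("Criticality model (class %s, kappa = %s)\n",
              as.character(x$class_id), x$kappa))
  cat("  boundary:", lhs, "= 1\n")
  if (!x$diagnostics$converged || length(x$diagnostics$warnings)) {
    cat("  note: fit flagged (separation or non-convergence)\n")
  }
  invisible(x)
}

#' Predict regime probabilities and labels from a fitted boundary
#'
#' @param object a `criticality_fit`.
#' @param records regime table (same columns as for [fit_model()]).
#' @param ... unused.
#' @return List with `prob` (fitted chaotic probability) and `pred`
#'   (binary label; ties at the 0.5 threshold predict chaotic).
#' @export
predict.criticality_fit <- function(object, records, ...) {
  X <- if (identical(object$terms, c("k", "ke", "k_ke"))) {
    interaction_frame(records)
  } else {
    design_frame(records, object$terms, object$kappa)
  }
  eta <- object$coefficients[["(Intercept)"]] +
    as.matrix(X) %*% object$coefficients[colnames(X)]
  prob <- as.numeric(stats::plogis(eta))
  list(prob = prob, pred = as.integer(prob >= object$tau))
}

interaction_frame <- function(records) {
  data.frame(k = records$k, ke = records$ke, k_ke = records$k * records$ke)
}

#' Logistic fit with a k x <ke> interaction
#'
#' Fits `P(chaotic) = logistic(b0 + b1 k + b2 <ke> + b3 k<ke>)` and
#' rearranges the 0.5 locus into `c1 k + c2 <ke> + c3 k<ke> = 1`; used to
#' test whether structural in-degree adds information beyond effective
#' connectivity.
#'
#' @inheritParams fit_model
#' @return A `criticality_fit` with terms `k`, `ke`, `k_ke`.
#' @export
fit_interaction_model <- function(records) {
  y <- records$chaotic
  if (length(unique(y)) < 2L) {
    stop("records must contain both regime labels", call. = FALSE)
  }
  X <- interaction_frame(records)
  res <- fit_logistic(X, y)
  new_criticality_fit(res, c("k", "ke", "k_ke"), "ke", "interaction")
}

#' Structural-theory classification
#'
#' The classical critical boundary `2 k p (1 - p) = 1`: a network is
#' predicted chaotic iff `2 k p (1 - p) > 1` (the boundary itself is
#' grouped with the stable side, matching the strict `zeta > 1` labeling
#' on the other axis).
#'
#' @param k in-degree(s).
#' @param p bias(es).
#' @return Integer vector, 1 = chaotic.
#' @export
st_theoretical_classify <- function(k, p) {
  as.integer(2 * k * p * (1 - p) > 1)
}

#' Classification metrics: MCC, AUC, McFadden R-squared
#'
#' MCC is computed from the confusion counts as
#' `(TP*TN - FP*FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN))`, defined as 0
#' when any factor of the denominator is 0. AUC is the normalized
#' Mann-Whitney rank statistic of `scores` for the positive class.
#' McFadden's R-squared is `1 - LL(model)/LL(null)` where the null
#' log-likelihood uses `null_prob` (by default the label base rate; in
#' cross-validation pass the training-split base rate).
#'
#' @param predicted binary predictions (1 = chaotic).
#' @param labels binary ground-truth labels.
#' @param scores optional numeric ranking scores / probabilities; needed
#'   for AUC, and interpreted as probabilities for the likelihood.
#' @param null_prob intercept-only model probability for McFadden's R2.
#' @return Object of class `metric_report`: list with `tp`, `fp`, `tn`,
#'   `fn`, `mcc`, `auc`, `r2`.
#' @export
score_classifier <- function(predicted, labels, scores = NULL,
                             null_prob = NULL) {
  if (length(predicted) == 0L) stop("empty input", call. = FALSE)
  if (length(predicted) != length(labels)) {
    stop("'predicted' and 'labels' must have equal length", call. = FALSE)
  }
  predicted <- as.integer(predicted)
  labels <- as.integer(labels)
  stopifnot(all(predicted %in% 0:1), all(labels %in% 0:1))
  tp <- sum(predicted == 1L & labels == 1L)
  fp <- sum(predicted == 1L & labels == 0L)
  tn <- sum(predicted == 0L & labels == 0L)
  fn <- sum(predicted == 0L & labels == 1L)
  mcc <- mcc_from_counts(tp, fp, tn, fn)
  auc <- r2 <- NA_real_
  if (!is.null(scores)) {
    stopifnot(length(scores) == length(labels))
    n1 <- sum(labels == 1L)
    n0 <- sum(labels == 0L)
    if (n1 > 0L && n0 > 0L) {
      r <- rank(scores)
      auc <- (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
    }
    eps <- 1e-12
    pr <- pmin(pmax(scores, eps), 1 - eps)
    ll <- sum(labels * log(pr) + (1 - labels) * log(1 - pr))
    p0 <- if (is.null(null_prob)) mean(labels) else null_prob
    p0 <- pmin(pmax(p0, eps), 1 - eps)
    ll0 <- sum(labels * log(p0) + (1 - labels) * log(1 - p0))
    r2 <- if (ll0 == 0) NA_real_ else 1 - ll / ll0
  }
  structure(list(tp = tp, fp = fp, tn = tn, fn = fn,
                 mcc = mcc, auc = auc, r2 = r2),
            class = "metric_report")
}

#' @export
print.metric_report <- function(x, ...) {
  cat(sprintf("MCC %.4f | AUC %s | McFadden R2 %s | TP %d FP %d TN %d FN %d\n",
              x$mcc,
              ifelse(is.na(x$auc), "NA", sprintf("%.4f", x$auc)),
              ifelse(is.na(x$r2), "NA", sprintf("%.4f", x$r2)),
              x$tp, x$fp, x$tn, x$fn))
  invisible(x)
}

mcc_from_counts <- function(tp, fp, tn, fn) {
  f <- as.double(c(tp + fp, tp + fn, tn + fp, tn + fn))
  if (any(f == 0)) return(0)
  (as.double(tp) * tn - as.double(fp) * fn) / sqrt(prod(f))
}

#' Nested fourfold cross-validation of a criticality model
#'
#' The data are split into 4 outer folds; each outer training split
#' (75% of the data) is itself split into 4 inner folds, and the model is
#' fitted on three inner folds and scored on the held-out one — 16
#' train/test pairs in total, every test split disjoint from its
#' training data. The null model for McFadden's R-squared is the
#' intercept-only probability of each training split. Fold assignment
#' depends only on `seed` and the number of rows, so different models
#' evaluated with the same seed share folds (enabling paired tests).
#'
#' @inheritParams fit_model
#' @param class_id model class 1..6, or `"interaction"`.
#' @param seed fold-assignment seed.
#' @return Data frame of class `cv_result` with one row per fold
#'   (`outer`, `inner`, `mcc`, `auc`, `r2`).
#' @export
nested_cv <- function(records, class_id, kappa = c("ke", "k"), seed = 1L) {
  kappa <- match.arg(kappa)
  y <- records$chaotic
  if (min(table(factor(y, levels = 0:1))) < 16L) {
    stop("need at least 16 records of each regime label", call. = FALSE)
  }
  n <- nrow(records)
  set.seed(seed)
  outer <- sample(rep_len(1:4, n))
  rows <- list()
  for (o in 1:4) {
    tr_o <- which(outer != o)
    inner <- sample(rep_len(1:4, length(tr_o)))
    for (i in 1:4) {
      test_idx <- tr_o[inner == i]
      train_idx <- tr_o[inner != i]
      train <- records[train_idx, ]
      test <- records[test_idx, ]
      fit <- if (identical(class_id, "interaction")) {
        fit_interaction_model(train)
      } else {
        fit_model(train, class_id, kappa)
      }
      pr <- predict(fit, test)
      rep_ <- score_classifier(pr$pred, test$chaotic, scores = pr$prob,
                               null_prob = mean(train$chaotic))
      rows[[length(rows) + 1L]] <- data.frame(
        outer = o, inner = i, mcc = rep_$mcc, auc = rep_$auc, r2 = rep_$r2)
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("cv_result", "data.frame")
  out
}

#' Average metrics over cross-validation folds
#'
#' @param cv a `cv_result` from [nested_cv()].
#' @return Named numeric vector with mean `mcc`, `auc`, `r2`.
#' @export
cv_summary <- function(cv) {
  c(mcc = mean(cv$mcc), auc = mean(cv$auc), r2 = mean(cv$r2))
}

#' One-sided paired t-test for fold scores
#'
#' Classical paired t statistic on the per-fold score differences, with
#' the alternative that the first model's mean score is greater. Defined
#' behaviour on degenerate input (zero variance of the differences):
#' identical score vectors give p = 0.5; a constant positive (negative)
#' shift gives p = 0 (p = 1), flagged as degenerate.
#'
#' @param scores_a,scores_b equal-length score vectors (e.g. per-fold
#'   MCCs of two models on shared folds); the alternative is
#'   `mean(scores_a) > mean(scores_b)`.
#' @return List with `statistic`, `df`, `p_value`, `mean_diff`,
#'   `degenerate`.
#' @export
paired_t_onesided <- function(scores_a, scores_b) {
  if (length(scores_a) != length(scores_b) || length(scores_a) < 2L) {
    stop("need two equal-length score vectors of length >= 2", call. = FALSE)
  }
  d <- scores_a - scores_b
  n <- length(d)
  s <- stats::sd(d)
  if (s == 0) {
    p <- if (mean(d) == 0) 0.5 else if (mean(d) > 0) 0 else 1
    return(list(statistic = NA_real_, df = n - 1L, p_value = p,
                mean_diff = mean(d), degenerate = TRUE))
  }
  tstat <- mean(d) / (s / sqrt(n))
  list(statistic = tstat, df = n - 1L,
       p_value = stats::pt(tstat, df = n - 1L, lower.tail = FALSE),
       mean_diff = mean(d), degenerate = FALSE)
}

#' Pareto selection of the optimal model class
#'
#' Given per-class mean metrics in the fixed complexity order (class 1
#' to 6), returns the lowest-complexity class whose metric is within
#' `delta` of the best over all classes — the "substantial rise followed
#' by marginal gain" reading of the complexity/performance front.
#'
#' @param metrics numeric vector of per-class metrics, complexity order.
#' @param delta tolerance below the maximum (default 0.01).
#' @return The selected class index.
#' @export
pareto_select <- function(metrics, delta = 0.01) {
  stopifnot(length(metrics) >= 1L)
  unname(which(metrics >= max(metrics) - delta)[1L])
}

#' Synthetic regime records from a known class-2 boundary
#'
#' Generates records whose labels follow a known law
#' `c * ke * p(1-p) = 1` with logistic noise:
#' `P(chaotic) = logistic(steepness * (c * ke * p(1-p) - 1))`. Used for
#' parameter-recovery checks of the fitting machinery.
#'
#' @param n number of records.
#' @param c_true boundary coefficient.
#' @param steepness logistic noise scale (larger = crisper labels).
#' @param ke_range,p_range uniform sampling ranges.
#' @return A regime record table (`k`, `p`, `ke`, `zeta`, `chaotic`);
#'   `zeta` is `NA` (labels come from the law, not from dynamics).
#' @export
simulate_boundary_records <- function(n, c_true = 3.94, steepness = 10,
                                      ke_range = c(0.5, 8),
                                      p_range = c(0.01, 0.5)) {
  ke <- stats::runif(n, ke_range[1L], ke_range[2L])
  p <- stats::runif(n, p_range[1L], p_range[2L])
  pq <- p * (1 - p)
  prob <- stats::plogis(steepness * (c_true * ke * pq - 1))
  data.frame(k = sample(c(2, 3, 4, 6, 8), n, replace = TRUE),
             p = p, ke = ke, zeta = NA_real_,
             chaotic = stats::rbinom(n, 1L, prob))
}
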