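#' Pipeline configuration
#'
#' Bundles every stage's settings: the ensemble grid, the Derrida
#' estimation parameters, and the model-fitting options. All randomness
#' downstream derives from the spec's master seed.
#'
#' @param spec an [ensemble_spec()].
#' @param pairs,t,m_max,stratified Derrida settings ([derrida_curve()]);
#'   `m_max = NULL` means `floor(N/10)`.
#' @param classes model classes to fit (subset of 1..6).
#' @param delta Pareto tolerance ([pareto_select()]).
#' @param ga_params catalogue GA overrides ([ga_fill_bins()]).
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(spec = ensemble_spec(), pairs = 250L, t = 1L,
                            m_max = NULL, stratified = FALSE,
                            classes = 1:6, delta = 0.01, ga_params = list()) {
  stopifnot(inherits(spec, "ensemble_spec"), pairs >= 1L, t >= 1L,
            all(classes %in% 1:6), delta >= 0)
  if (!is.null(m_max)) stopifnot(m_max >= 1L, m_max <= spec$N)
  structure(list(spec = spec,
                 derrida = list(pairs = as.integer(pairs), t = as.integer(t),
                                m_max = m_max, stratified = stratified),
                 classes = as.integer(classes), delta = delta,
                 ga_params = ga_params),
            class = "pipeline_config")
}

#' Run the full criticality-analysis pipeline
#'
#' Catalogue construction, ensemble sweep, Derrida labeling, boundary
#' fits for every requested model class in both the structural (`k`) and
#' canalization (`<k_e>`) instances, the `k x <k_e>` interaction fit,
#' nested fourfold cross-validation of every model on shared folds,
#' Pareto selection of the optimal class, and the one-sided paired
#' t-test of the canalization class-2 model against the empirical
#' structural one. Deterministic given the spec's master seed.
#'
#' @param config a [pipeline_config()].
#' @param progress emit stage messages.
#' @return Object of class `pipeline_result`; see Details. Key elements:
#'   `manifest`, `records`, `fits` (list indexed `c<class>_<kappa>`),
#'   `interaction_fit`, `cv` (per-fold metrics per model), `cv_means`,
#'   `pareto`, `chaotic_fraction`, `ct_vs_st_test`, `skipped`.
#' @export
run_pipeline <- function(config, progress = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  spec <- config$spec
  if (progress) message("stage 1/4: rule catalogues")
  cats <- build_catalogues(spec, ga_params = config$ga_params,
                           progress = progress)
  if (progress) message("stage 2/4: ensemble sweep + Derrida labeling")
  dset <- config$derrida
  network_fn <- function(net, row) {
    list(zeta = derrida_zeta(net, pairs = dset$pairs, t = dset$t,
                             m_max = dset$m_max,
                             stratified = dset$stratified))
  }
  ens <- generate_ensemble(spec, cats, network_fn = network_fn,
                           progress = progress)
  manifest <- ens$manifest
  manifest$regime <- classify_regime(manifest$zeta)
  records <- regime_records(manifest)
  if (progress) message("stage 3/4: boundary fits")
  if (progress) message("stage 4/4: cross-validation")
  analysis <- analyze_records(records, classes = config$classes,
                              delta = config$delta,
                              cv_seed = derive_seed(spec$seed, 1L, stream = 3L))
  structure(c(list(manifest = manifest, skipped = ens$skipped,
                   catalogue_sizes = vapply(cats, catalogue_size, integer(1L)),
                   config = config),
              analysis),
            class = "pipeline_result")
}

#' Model fitting and evaluation on a regime table
#'
#' The analysis half of [run_pipeline()], callable on its own — e.g. to
#' resume from a saved records table; rerunning it on reloaded records
#' reproduces the downstream results exactly.
#'
#' @param records regime table ([regime_records()]).
#' @param classes model classes to fit.
#' @param delta Pareto tolerance.
#' @param cv_seed fold-assignment seed shared by all models.
#' @return List with `records`, `fits`, `interaction_fit`, `cv`,
#'   `cv_means`, `pareto`, `chaotic_fraction`, `ct_vs_st_test`.
#' @export
analyze_records <- function(records, classes = 1:6, delta = 0.01,
                            cv_seed = 1L) {
  fits <- list()
  cv <- list()
  for (cls in classes) {
    for (kap in c("k", "ke")) {
      key <- sprintf("c%d_%s", cls, kap)
      fits[[key]] <- fit_model(records, cls, kappa = kap)
      cv[[key]] <- nested_cv(records, cls, kappa = kap, seed = cv_seed)
    }
  }
  interaction_fit <- fit_interaction_model(records)
  cv_means <- do.call(rbind, lapply(names(cv), function(key) {
    s <- cv_summary(cv[[key]])
    data.frame(model = key, mcc = s[["mcc"]], auc = s[["auc"]], r2 = s[["r2"]])
  }))
  pareto <- list()
  for (kap in c("k", "ke")) {
    keys <- sprintf("c%d_%s", classes, kap)
    keys <- keys[keys %in% cv_means$model]
    mccs <- cv_means$mcc[match(keys, cv_means$model)]
    pareto[[kap]] <- classes[pareto_select(mccs, delta = delta)]
  }
  ct_vs_st <- if (all(c("c2_ke", "c2_k") %in% names(cv))) {
    paired_t_onesided(cv[["c2_ke"]]$mcc, cv[["c2_k"]]$mcc)
  } else NULL
  list(records = records, fits = fits, interaction_fit = interaction_fit,
       cv = cv, cv_means = cv_means, pareto = pareto,
       chaotic_fraction = mean(records$chaotic),
       ct_vs_st_test = ct_vs_st)
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat(sprintf("Criticality pipeline result: %d networks (%.1f%% chaotic), %d skipped cells\n",
              nrow(x$records), 100 * x$chaotic_fraction, nrow(x$skipped)))
  if (!is.null(x$fits$c2_ke)) {
    cat(sprintf("  canalization boundary:  %.3f * <ke> * p(1-p) = 1\n",
                x$fits$c2_ke$boundary[["kappa_pq"]]))
  }
  if (!is.null(x$fits$c2_k)) {
    cat(sprintf("  structural boundary:    %.3f * k * p(1-p) = 1\n",
                x$fits$c2_k$boundary[["kappa_pq"]]))
  }
  if (!is.null(x$cv_means)) {
    ct <- x$cv_means[x$cv_means$model == "c2_ke", ]
    if (nrow(ct)) {
      cat(sprintf("  class-2 <ke> CV: MCC %.3f, AUC %.3f, R2 %.3f\n",
                  ct$mcc, ct$auc, ct$r2))
    }
  }
  invisible(x)
}

# tiny FNV-style hash for provenance lines
config_hash <- function(config) {
  s <- paste(deparse(config[setdiff(names(config), "spec")]),
             deparse(unclass(config$spec)[setdiff(names(config$spec), "ke_bins")]),
             collapse = "")
  h <- 2166136261
  for (ch in utf8ToInt(s)) h <- ((h * 16777619) + ch) %% 2^32
  sprintf("%08x", as.integer(h %% 2^31))
}

#' Write pipeline outputs as tab-separated text
#'
#' Emits `manifest.tsv`, `records.tsv`, `boundaries.tsv`, `cv.tsv` and
#' `cv_means.tsv` under `dir`, each with a provenance comment block
#' (package version, master seed, configuration hash).
#'
#' @param result a `pipeline_result`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_pipeline_results <- function(result, dir) {
  stopifnot(inherits(result, "pipeline_result"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  prov <- c(sprintf("# canalcrit %s",
                    as.character(utils::packageVersion("canalcrit"))),
            sprintf("# seed %d", result$config$spec$seed),
            sprintf("# config %s", config_hash(result$config)))
  emit <- function(df, file) {
    path <- file.path(dir, file)
    writeLines(prov, path)
    suppressWarnings(utils::write.table(df, path, sep = "\t", append = TRUE,
                                        row.names = FALSE, quote = FALSE))
  }
  emit(result$manifest, "manifest.tsv")
  emit(result$records, "records.tsv")
  bounds <- do.call(rbind, lapply(names(result$fits), function(key) {
    f <- result$fits[[key]]
    data.frame(model = key, term = f$terms,
               coefficient = unname(f$coefficients[-1L]),
               boundary = unname(f$boundary),
               intercept = unname(f$coefficients[1L]))
  }))
  emit(bounds, "boundaries.tsv")
  emit(do.call(rbind, lapply(names(result$cv), function(key) {
    cbind(model = key, result$cv[[key]])
  })), "cv.tsv")
  emit(result$cv_means, "cv_means.tsv")
  invisible(dir)
}
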