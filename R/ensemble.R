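#' Specification of a random Boolean network ensemble sweep
#'
#' Describes a grid of ensemble cells `(k, p, <k_e> bin)`. Within a cell
#' every generated network has `N` nodes, homogeneous in-degree `k`,
#' homogeneous rule bias `p`, and all node rules drawn from the
#' catalogue bin centred on the requested `<k_e>`. Attainable biases are
#' multiples of `1/2^k`; the grid is the multiples of `p_step` clipped to
#' `[p_min, p_max]` (the lower edge is a clipping bound, since very small
#' biases are unattainable at small `k`).
#'
#' @param N nodes per network.
#' @param k vector of in-degrees.
#' @param p_step bias grid step per `k` (single value or one per `k`);
#'   default `1/2^k`. Must be a multiple of `1/2^k`.
#' @param p_min,p_max bias grid clipping bounds.
#' @param ke_bins function of `k` returning bin centres, or `NULL` for
#'   the default `seq(1, k, by = 0.5)`.
#' @param replicates networks per viable cell.
#' @param cap catalogue sampling cap (see [build_catalogue()]).
#' @param seed master seed; all cell, network and catalogue seeds derive
#'   from it.
#' @return An object of class `ensemble_spec`.
#' @export
ensemble_spec <- function(N = 100L, k = c(2L, 3L, 4L, 6L, 8L), p_step = NULL,
                          p_min = 0.01, p_max = 0.5, ke_bins = NULL,
                          replicates = 10L, cap = 10000L, seed = 1L) {
  k <- as.integer(k)
  stopifnot(N >= 1L, all(k >= 1L), replicates >= 1L)
  if (is.null(p_step)) p_step <- 1 / 2^k
  p_step <- rep_len(p_step, length(k))
  for (i in seq_along(k)) {
    m <- p_step[i] * 2^k[i]
    if (abs(m - round(m)) > 1e-9) {
      stop(sprintf("p_step %g is not a multiple of 1/2^%d", p_step[i], k[i]),
           call. = FALSE)
    }
  }
  if (is.null(ke_bins)) ke_bins <- function(k) seq(1, k, by = 0.5)
  structure(list(N = as.integer(N), k = k, p_step = p_step,
                 p_min = p_min, p_max = p_max, ke_bins = ke_bins,
                 replicates = as.integer(replicates), cap = as.integer(cap),
                 seed = as.integer(seed)),
            class = "ensemble_spec")
}

#' @export
print.ensemble_spec <- function(x, ...) {
  cells <- sum(vapply(seq_along(x$k), function(i) {
    length(p_grid(x, i)) * length(x$ke_bins(x$k[i]))
  }, numeric(1L)))
  cat(sprintf(
    "Ensemble spec: N = %d, k in {%s}, %d grid cells (max), %d replicates/cell, seed %d\n",
    x$N, paste(x$k, collapse = ", "), cells, x$replicates, x$seed))
  invisible(x)
}

# bias grid for the i-th k value of a spec
p_grid <- function(spec, i) {
  step <- spec$p_step[i]
  m <- seq_len(floor(spec$p_max / step + 1e-9))
  ps <- m * step
  ps[ps >= spec$p_min - 1e-12 & ps <= spec$p_max + 1e-12]
}

# deterministic sub-seed derivation (kept below 2^31 - 1)
derive_seed <- function(master, index, stream = 0L) {
  as.integer((as.double(master %% 1048576L) * 2039 +
                as.double(index) * 7919 + as.double(stream) * 502133) %%
               2147483647)
}

#' Build all catalogues an ensemble spec needs
#'
#' One catalogue per `(k, p)` grid point, each GA-extended towards the
#' requested bins (see [full_catalogue()]). Catalogue RNG is seeded from
#' the spec's master seed, independently per grid point.
#'
#' @param spec an [ensemble_spec()].
#' @param ga_params passed to [ga_fill_bins()].
#' @param progress emit per-catalogue messages.
#' @return Named list of `rule_catalogue` objects, keys `"k=<k>,p=<p>"`.
#' @export
build_catalogues <- function(spec, ga_params = list(), progress = FALSE) {
  cats <- list()
  idx <- 0L
  for (i in seq_along(spec$k)) {
    kk <- spec$k[i]
    for (p in p_grid(spec, i)) {
      idx <- idx + 1L
      set.seed(derive_seed(spec$seed, idx, stream = 1L))
      key <- catalogue_key(kk, p)
      if (progress) message("catalogue ", key)
      cats[[key]] <- full_catalogue(kk, p, bins = spec$ke_bins(kk),
                                    cap = spec$cap, ga_params = ga_params)
    }
  }
  cats
}

catalogue_key <- function(k, p) sprintf("k=%d,p=%.10g", k, p)

#' Generate one random Boolean network from a catalogue bin
#'
#' Each node receives `k` distinct random inputs (self-inputs allowed)
#' and a rule drawn uniformly (with replacement) from the catalogue
#' entries in the requested `k_e` bin. Uses the current RNG stream.
#'
#' @param N number of nodes.
#' @param catalogue a `rule_catalogue` at the desired `(k, p)`.
#' @param bin_centre `k_e` bin centre.
#' @return A [boolean_network()] with attribute `mean_ke`, the realized
#'   mean effective connectivity (exact, from catalogue annotations).
#' @export
generate_rbn <- function(N, catalogue, bin_centre) {
  stopifnot(inherits(catalogue, "rule_catalogue"))
  rows <- which(catalogue$bin == bin_centre)
  if (length(rows) == 0L) {
    stop(structure(class = c("canalcrit_empty_bin", "error", "condition"),
                   list(message = sprintf(
                     "catalogue (k = %d, p = %.4g) has no rules in bin %.2f",
                     catalogue$k, catalogue$p, bin_centre),
                     call = sys.call())))
  }
  k <- catalogue$k
  pick <- rows[sample.int(length(rows), N, replace = TRUE)]
  rules <- lapply(pick, function(r) boolean_rule(k, catalogue$outputs[r, ]))
  net <- boolean_network(rules, random_inputs(N, k))
  attr(net, "mean_ke") <- mean(catalogue$ke[pick])
  net
}

#' Sweep an ensemble grid
#'
#' Iterates over all viable `(k, p, bin)` cells of the spec, generating
#' `replicates` networks per cell under hierarchically derived seeds (a
#' cell can be regenerated independently of the rest of the sweep).
#' Non-viable cells (no catalogue rule in the bin) are recorded as
#' skipped, not fabricated.
#'
#' @param spec an [ensemble_spec()].
#' @param catalogues from [build_catalogues()]; built on the fly if
#'   `NULL`.
#' @param network_fn optional function `(net, row)` returning a named
#'   list of extra per-network columns (e.g. Derrida statistics). When
#'   supplied, networks are discarded after the call, keeping memory flat.
#' @param progress emit per-k messages.
#' @return List with `manifest` (one row per network: cell parameters,
#'   seed, realized `mean_ke`, plus any `network_fn` columns),
#'   `networks` (list, `NULL` when `network_fn` is used) and `skipped`
#'   (data frame of non-viable cells).
#' @export
generate_ensemble <- function(spec, catalogues = NULL, network_fn = NULL,
                              progress = FALSE) {
  stopifnot(inherits(spec, "ensemble_spec"))
  if (is.null(catalogues)) catalogues <- build_catalogues(spec, progress = progress)
  keep <- is.null(network_fn)
  rows <- list()
  nets <- if (keep) list() else NULL
  skipped <- list()
  cell <- 0L
  for (i in seq_along(spec$k)) {
    kk <- spec$k[i]
    if (progress) message("ensemble cells for k = ", kk)
    for (p in p_grid(spec, i)) {
      cat_kp <- catalogues[[catalogue_key(kk, p)]]
      if (is.null(cat_kp)) stop("missing catalogue for ", catalogue_key(kk, p))
      for (bin in spec$ke_bins(kk)) {
        cell <- cell + 1L
        if (!any(cat_kp$bin == bin)) {
          skipped[[length(skipped) + 1L]] <-
            data.frame(k = kk, p = p, bin = bin)
          next
        }
        cell_seed <- derive_seed(spec$seed, cell, stream = 2L)
        set.seed(cell_seed)
        for (r in seq_len(spec$replicates)) {
          net <- generate_rbn(spec$N, cat_kp, bin)
          row <- data.frame(k = kk, p = p, bin = bin, replicate = r,
                            cell_seed = cell_seed,
                            mean_ke = attr(net, "mean_ke"))
          if (!is.null(network_fn)) {
            extra <- network_fn(net, row)
            row <- cbind(row, as.data.frame(extra))
          } else {
            nets[[length(nets) + 1L]] <- net
          }
          rows[[length(rows) + 1L]] <- row
        }
      }
    }
  }
  manifest <- if (length(rows)) do.call(rbind, rows) else
    data.frame(k = numeric(0), p = numeric(0), bin = numeric(0))
  skipped <- if (length(skipped)) do.call(rbind, skipped) else
    data.frame(k = numeric(0), p = numeric(0), bin = numeric(0))
  list(manifest = manifest, networks = nets, skipped = skipped)
}
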