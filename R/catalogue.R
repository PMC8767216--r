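#' Bin centre for an effective-connectivity value
#'
#' Catalogue and ensemble construction bin `k_e` into half-open intervals
#' `[c - 0.25, c + 0.25)` centred on multiples of 0.5 (bin width 0.5,
#' half-width `epsilon = 0.25`). A boundary value such as `k_e = 1.25`
#' belongs to the upper bin (1.5).
#'
#' @param ke numeric vector of effective connectivities.
#' @return Numeric vector of bin centres.
#' @export
ke_bin <- function(ke) {
  floor((ke + 0.25) * 2) / 2
}

new_catalogue <- function(k, ones, outputs, ke, source) {
  structure(list(k = as.integer(k),
                 p = ones / 2^k,
                 ones = as.integer(ones),
                 outputs = outputs,
                 ke = ke,
                 bin = ke_bin(ke),
                 source = source),
            class = "rule_catalogue")
}

#' @export
print.rule_catalogue <- function(x, ...) {
  cat(sprintf("Rule catalogue: k = %d, p = %.4g, %d rules (%s)\n",
              x$k, x$p, nrow(x$outputs),
              paste(unique(x$source), collapse = "+")))
  if (nrow(x$outputs) > 0L) {
    tab <- table(x$bin)
    cat("  k_e bins:", paste(sprintf("%s:%d", names(tab), tab), collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
as.data.frame.rule_catalogue <- function(x, ...) {
  data.frame(k = rep(x$k, length(x$ke)), p = rep(x$p, length(x$ke)),
             ke = x$ke, bin = x$bin, source = x$source,
             outputs = apply(x$outputs, 1L, paste0, collapse = ""),
             stringsAsFactors = FALSE)
}

catalogue_size <- function(cat) nrow(cat$outputs)

#' Build a catalogue of Boolean rules at fixed (k, p)
#'
#' Enumerates or samples distinct `k`-input rules with exactly
#' `round(p * 2^k)` ON entries, computes each rule's effective
#' connectivity, and assigns it to a `k_e` bin (see [ke_bin()]).
#' Enumeration is exhaustive whenever `k <= 4` or the number of rules
#' `choose(2^k, ones)` does not exceed `cap`; otherwise `cap` distinct
#' rules are drawn uniformly (duplicates rejected). Uses the current RNG
#' stream when sampling.
#'
#' @param k number of inputs (>= 1).
#' @param p requested bias; realized as `round(p * 2^k)` ON entries.
#' @param cap sampling cap for non-exhaustive catalogues.
#' @return A `rule_catalogue` object.
#' @export
build_catalogue <- function(k, p, cap = 10000L) {
  k <- as.integer(k)
  if (k < 1L) stop("'k' must be >= 1", call. = FALSE)
  S <- 2L^k
  ones <- as.integer(round(p * S))
  if (ones < 0L || ones > S) {
    stop(structure(class = c("canalcrit_empty_catalogue", "error", "condition"),
                   list(message = sprintf("no rule of k = %d attains bias %g", k, p),
                        call = sys.call())))
  }
  total <- choose(S, ones)
  if (k <= 4L || total <= cap) {
    outputs <- enumerate_outputs(S, ones)
    source <- "exhaustive"
  } else {
    outputs <- sample_outputs(S, ones, cap)
    source <- "sampled"
  }
  ke <- effective_connectivity_batch(outputs)
  new_catalogue(k, ones, outputs, ke, rep(source, nrow(outputs)))
}

# all C(S, ones) output vectors, one per row
enumerate_outputs <- function(S, ones) {
  if (ones == 0L || ones == S) {
    return(matrix(rep(as.integer(ones == S), S), nrow = 1L))
  }
  pos <- utils::combn(S, ones)
  n <- ncol(pos)
  outputs <- matrix(0L, nrow = n, ncol = S)
  outputs[cbind(rep(seq_len(n), each = ones), as.vector(pos))] <- 1L
  outputs
}

# cap distinct random output vectors with a fixed ON count
sample_outputs <- function(S, ones, cap) {
  seen <- new.env(hash = TRUE, parent = emptyenv())
  outputs <- matrix(0L, nrow = cap, ncol = S)
  got <- 0L
  attempts <- 0L
  while (got < cap) {
    attempts <- attempts + 1L
    if (attempts > 100L * cap) {
      outputs <- outputs[seq_len(got), , drop = FALSE]
      warning("sampling stalled before reaching the catalogue cap")
      break
    }
    idx <- sort.int(sample.int(S, ones))
    key <- paste(idx, collapse = ",")
    if (!is.null(seen[[key]])) next
    seen[[key]] <- TRUE
    got <- got + 1L
    outputs[got, idx] <- 1L
  }
  outputs
}

#' Fill hard-to-reach effective-connectivity bins with a genetic algorithm
#'
#' Random generation at fixed `(k, p)` concentrates `k_e` in a narrow
#' range; bins far from that range (very canalized rules, or parity-like
#' rules) are found by a bias-preserving genetic algorithm: individuals
#' are output vectors with a fixed ON count, fitness is
#' `-|k_e - target|`, selection is tournament (size 3) with elitism, and
#' mutation swaps one ON with one OFF entry (so the bias is exact by
#' construction; there is no crossover, which would break the ON count).
#' The initial population mixes uniformly random rules with canalization
#' templates — subcube-confined rules and input-subset parities — whose
#' `k_e` spans the whole `[1, k]` range, so the search only refines
#' locally instead of traversing the rugged `k_e` landscape from scratch.
#' A bin search stops as soon as enough in-bin rules are collected, and a
#' bin is reported unreachable when fitness stagnates with no hit.
#'
#' @param k,p arity and bias (as in [build_catalogue()]).
#' @param target_bins bin centres to populate (multiples of 0.5 within
#'   `[0.75, k + 0.25]`).
#' @param ga_params optional list overriding `pop_size` (100),
#'   `max_generations` (500), `tournament` (3), `stagnation` (100),
#'   `collect` (25, rules kept per bin).
#' @return A `rule_catalogue` of the rules found (source `"ga"`), with an
#'   `unreachable` attribute: a data frame of bins that could not be
#'   populated and the closest `k_e` achieved.
#' @export
ga_fill_bins <- function(k, p, target_bins, ga_params = list()) {
  k <- as.integer(k)
  S <- 2L^k
  ones <- as.integer(round(p * S))
  if (ones < 0L || ones > S) stop("bias not attainable at this k", call. = FALSE)
  par <- utils::modifyList(
    list(pop_size = 100L, max_generations = 500L, tournament = 3L,
         stagnation = 100L, collect = 25L),
    ga_params)
  eps <- 0.25
  bad <- target_bins[target_bins < 1 - eps | target_bins > k + eps]
  if (length(bad)) {
    stop(sprintf("target bins outside [%.2f, %.2f]: %s",
                 1 - eps, k + eps, paste(bad, collapse = ", ")), call. = FALSE)
  }
  out_list <- list()
  ke_list <- list()
  unreachable <- data.frame(bin = numeric(0), best_ke = numeric(0))
  for (centre in target_bins) {
    res <- ga_search_bin(S, ones, centre, par)
    if (nrow(res$outputs) > 0L) {
      out_list[[length(out_list) + 1L]] <- res$outputs
      ke_list[[length(ke_list) + 1L]] <- res$ke
    } else {
      unreachable <- rbind(unreachable,
                           data.frame(bin = centre, best_ke = res$best_ke))
    }
  }
  outputs <- if (length(out_list)) do.call(rbind, out_list)
             else matrix(integer(0), ncol = S)
  ke <- if (length(ke_list)) unlist(ke_list) else numeric(0)
  cat <- new_catalogue(k, ones, outputs, ke, rep("ga", length(ke)))
  attr(cat, "unreachable") <- unreachable
  cat
}

# Initial GA population: a mixture of uniformly random rules and
# canalization templates that land in otherwise hard-to-reach k_e ranges,
# which the swap-mutation search then refines into the requested bin:
#  * cube rules — all ON entries confined to a d-dimensional subcube
#    (k - d inputs fixed), giving low k_e for small d;
#  * parity rules over a random subset of j inputs (only when
#    ones = S/2), giving k_e = j exactly;
#  * parity over all k inputs with a few ON/OFF swaps, covering the
#    near-parity range k_e ~ k.
ga_seed_population <- function(S, ones, centre, np) {
  k <- as.integer(round(log2(S)))
  tup <- input_tuples(k)
  pop <- matrix(0L, nrow = np, ncol = S)
  kinds <- sample(c("random", "cube", if (2L * ones == S) c("xor", "parity")),
                  np, replace = TRUE)
  kinds[1L] <- "random"
  dmin <- max(1L, ceiling(log2(max(ones, 1L))))
  for (i in seq_len(np)) {
    v <- integer(S)
    if (kinds[i] == "random" || (kinds[i] == "cube" && dmin > k)) {
      v[sample.int(S, ones)] <- 1L
    } else if (kinds[i] == "cube") {
      d <- if (dmin == k) k else sample(seq.int(dmin, k), 1L)
      inside <- seq_len(S)
      if (d < k) {
        fixed <- sample.int(k, k - d)
        vals <- sample(c(0L, 1L), k - d, replace = TRUE)
        inside <- which(colSums(t(tup[, fixed, drop = FALSE]) == vals) == k - d)
      }
      v[sample(inside, ones)] <- 1L
    } else if (kinds[i] == "xor") {
      j <- sample.int(k, 1L)
      v <- as.integer(rowSums(tup[, sample.int(k, j), drop = FALSE]) %% 2L)
    } else {
      v <- as.integer(rowSums(tup) %% 2L)
      for (s in seq_len(sample.int(6L, 1L) - 1L)) {
        on <- which(v == 1L); off <- which(v == 0L)
        v[on[sample.int(length(on), 1L)]] <- 0L
        v[off[sample.int(length(off), 1L)]] <- 1L
      }
    }
    pop[i, ] <- v
  }
  pop
}

ga_search_bin <- function(S, ones, centre, par) {
  # degenerate biases give k_e = 0 for every rule
  empty <- list(outputs = matrix(integer(0), ncol = S), ke = numeric(0))
  if (ones == 0L || ones == S) {
    empty$best_ke <- 0
    return(empty)
  }
  np <- par$pop_size
  pop <- ga_seed_population(S, ones, centre, np)
  hits <- new.env(hash = TRUE, parent = emptyenv())
  hit_out <- list()
  hit_ke <- numeric(0)
  best_fit <- -Inf
  best_ke <- NA_real_
  stagnant <- 0L
  first_hit_gen <- NA_integer_
  for (gen in seq_len(par$max_generations)) {
    ke <- effective_connectivity_batch(pop)
    fit <- -abs(ke - centre)
    in_bin <- ke_bin(ke) == centre
    if (any(in_bin)) {
      if (is.na(first_hit_gen)) first_hit_gen <- gen
      for (i in which(in_bin)) {
        key <- paste0(pop[i, ], collapse = "")
        if (is.null(hits[[key]])) {
          hits[[key]] <- TRUE
          hit_out[[length(hit_out) + 1L]] <- pop[i, ]
          hit_ke <- c(hit_ke, ke[i])
        }
      }
    }
    if (length(hit_ke) >= par$collect) break
    if (!is.na(first_hit_gen) && gen - first_hit_gen >= 25L) break
    gen_best <- max(fit)
    if (gen_best > best_fit + 1e-12) {
      best_fit <- gen_best
      best_ke <- ke[which.max(fit)]
      stagnant <- 0L
    } else {
      stagnant <- stagnant + 1L
    }
    if (is.na(first_hit_gen) && stagnant >= par$stagnation) break
    # next generation: elitism + tournament selection + swap mutation
    elite <- pop[which.max(fit), ]
    new_pop <- matrix(0L, nrow = np, ncol = S)
    new_pop[1L, ] <- elite
    cand <- matrix(sample.int(np, (np - 1L) * par$tournament, replace = TRUE),
                   nrow = np - 1L)
    winners <- cand[cbind(seq_len(np - 1L),
                          max.col(matrix(fit[cand], nrow = np - 1L)))]
    for (r in seq_len(np - 1L)) {
      child <- pop[winners[r], ]
      on <- which(child == 1L)
      off <- which(child == 0L)
      child[on[sample.int(length(on), 1L)]] <- 0L
      child[off[sample.int(length(off), 1L)]] <- 1L
      new_pop[r + 1L, ] <- child
    }
    pop <- new_pop
  }
  if (length(hit_ke) == 0L) {
    empty$best_ke <- best_ke
    return(empty)
  }
  list(outputs = do.call(rbind, hit_out), ke = hit_ke)
}

#' Catalogue with GA-filled bins
#'
#' Convenience wrapper: builds the random/exhaustive catalogue at
#' `(k, p)` and then runs [ga_fill_bins()] for any requested bin the
#' random stage left empty. Exhaustive catalogues are never GA-extended
#' (their empty bins are genuinely unreachable).
#'
#' @inheritParams build_catalogue
#' @param bins bin centres the ensemble design needs.
#' @param ga_params passed to [ga_fill_bins()].
#' @return A `rule_catalogue` (with an `unreachable` attribute when bins
#'   could not be populated).
#' @export
full_catalogue <- function(k, p, bins = seq(1, k, by = 0.5), cap = 10000L,
                           ga_params = list()) {
  cat <- build_catalogue(k, p, cap = cap)
  missing_bins <- setdiff(bins, unique(cat$bin))
  missing_bins <- missing_bins[missing_bins >= 0.75 & missing_bins <= k + 0.25]
  if (cat$source[1L] == "exhaustive" || length(missing_bins) == 0L) {
    attr(cat, "unreachable") <- data.frame(
      bin = setdiff(bins, unique(cat$bin)), best_ke = NA_real_)
    return(cat)
  }
  ga <- ga_fill_bins(k, p, missing_bins, ga_params = ga_params)
  merged <- combine_catalogues(cat, ga)
  attr(merged, "unreachable") <- attr(ga, "unreachable")
  merged
}

combine_catalogues <- function(a, b) {
  stopifnot(a$k == b$k, a$ones == b$ones)
  outputs <- rbind(a$outputs, b$outputs)
  key <- apply(outputs, 1L, paste0, collapse = "")
  keep <- !duplicated(key)
  new_catalogue(a$k, a$ones, outputs[keep, , drop = FALSE],
                c(a$ke, b$ke)[keep], c(a$source, b$source)[keep])
}

#' Write / read a rule catalogue as tab-separated text
#'
#' Columns: `k`, `p`, `bin`, `ke`, `source`, `outputs` (the LUT as a bit
#' string in lexicographic row order). Reloading does not recompute
#' `k_e`.
#'
#' @param cat a `rule_catalogue`.
#' @param path file path.
#' @name catalogue_io
#' @export
write_catalogue <- function(cat, path) {
  stopifnot(inherits(cat, "rule_catalogue"))
  utils::write.table(as.data.frame(cat), path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname catalogue_io
#' @export
read_catalogue <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          colClasses = c(outputs = "character"),
                          stringsAsFactors = FALSE)
  if (nrow(df) == 0L) stop("empty catalogue file", call. = FALSE)
  k <- df$k[1L]
  outputs <- do.call(rbind, lapply(strsplit(df$outputs, ""),
                                   function(x) as.integer(x)))
  new_catalogue(k, round(df$p[1L] * 2^k), outputs, df$ke, df$source)
}
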