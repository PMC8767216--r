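#' Wildcard-schema redescription of a Boolean rule
#'
#' A rule's LUT can be compressed into *wildcard schemata*: patterns over
#' `{0, 1, #}` where `#` marks an input whose state is irrelevant to the
#' transition. Maximal schemata (no `#` can be added without breaking the
#' guarantee) are the prime implicants of the rule's ON-set and OFF-set.
#' They are computed here by Quine-McCluskey-style merging, separately for
#' transitions to 1 and to 0.
#'
#' @param rule a [boolean_rule()].
#' @return An object of class `schema_set`: a list with `k` and two
#'   character vectors `on` and `off` of patterns such as `"1#"`. A
#'   constant rule yields a single all-`#` schema on its output side and
#'   none on the other.
#' @examples
#' prime_schemata(or_rule(2))  # ON: 1#, #1; OFF: 00
#' @export
prime_schemata <- function(rule) {
  stopifnot(is_boolean_rule(rule))
  k <- rule$k
  on_idx <- which(rule$outputs == 1L) - 1L
  off_idx <- which(rule$outputs == 0L) - 1L
  on <- prime_implicants(on_idx, k)
  off <- prime_implicants(off_idx, k)
  structure(list(k = k,
                 on = implicant_patterns(on, k),
                 off = implicant_patterns(off, k)),
            class = "schema_set")
}

#' @export
print.schema_set <- function(x, ...) {
  cat(sprintf("Wildcard schemata (k = %d)\n", x$k))
  cat("  ON :", if (length(x$on)) paste(x$on, collapse = ", ") else "(none)", "\n")
  cat("  OFF:", if (length(x$off)) paste(x$off, collapse = ", ") else "(none)", "\n")
  invisible(x)
}

#' Serialize / read schema sets as text
#'
#' One line per schema: the pattern over `{0,1,#}`, whitespace, and the
#' output class it guarantees (0 or 1).
#'
#' @param schemata a `schema_set` from [prime_schemata()].
#' @param path file path.
#' @name schema_io
#' @export
write_schemata <- function(schemata, path) {
  stopifnot(inherits(schemata, "schema_set"))
  lines <- c(paste(schemata$on, 1L), paste(schemata$off, 0L))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname schema_io
#' @export
read_schemata <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  parts <- strsplit(trimws(lines), "\\s+")
  pat <- vapply(parts, `[`, character(1L), 1L)
  out <- as.integer(vapply(parts, `[`, character(1L), 2L))
  if (anyNA(out) || !all(out %in% c(0L, 1L)) ||
      !all(grepl("^[01#]+$", pat)) || length(unique(nchar(pat))) > 1L) {
    stop("malformed schema file", call. = FALSE)
  }
  structure(list(k = nchar(pat[1L]), on = pat[out == 1L], off = pat[out == 0L]),
            class = "schema_set")
}

# ---- internal: Quine-McCluskey on a set of minterms ---------------------

# Implicants are pairs (value, mask): 'mask' is the wildcard bitmask,
# 'value' the entry index with masked bits cleared. Bit weight of input
# position j (1-based, first input most significant) is 2^(k-j).
# Returns a 2-column matrix (value, mask) of all prime implicants.
prime_implicants <- function(minterms, k) {
  if (length(minterms) == 0L) {
    return(matrix(integer(0), ncol = 2L,
                  dimnames = list(NULL, c("value", "mask"))))
  }
  if (k == 0L) {
    return(matrix(c(0L, 0L), ncol = 2L,
                  dimnames = list(NULL, c("value", "mask"))))
  }
  cur_v <- as.integer(minterms)
  cur_m <- rep(0L, length(cur_v))
  primes_v <- integer(0)
  primes_m <- integer(0)
  bits <- 2L^(0:(k - 1L))
  repeat {
    combined <- rep(FALSE, length(cur_v))
    new_v <- integer(0)
    new_m <- integer(0)
    for (mask in unique(cur_m)) {
      grp <- which(cur_m == mask)
      vs <- cur_v[grp]
      free_bits <- bits[bitwAnd(mask, bits) == 0L]
      for (b in free_bits) {
        lo <- which(bitwAnd(vs, b) == 0L)
        if (length(lo) == 0L) next
        hit <- lo[(vs[lo] + b) %in% vs]
        if (length(hit) == 0L) next
        hi <- match(vs[hit] + b, vs)
        combined[grp[hit]] <- TRUE
        combined[grp[hi]] <- TRUE
        new_v <- c(new_v, vs[hit])
        new_m <- c(new_m, rep(bitwOr(mask, b), length(hit)))
      }
    }
    primes_v <- c(primes_v, cur_v[!combined])
    primes_m <- c(primes_m, cur_m[!combined])
    if (length(new_v) == 0L) break
    key <- paste(new_v, new_m)
    keep <- !duplicated(key)
    cur_v <- new_v[keep]
    cur_m <- new_m[keep]
  }
  key <- paste(primes_v, primes_m)
  keep <- !duplicated(key)
  cbind(value = primes_v[keep], mask = primes_m[keep])
}

# character patterns like "1#0" from an implicant matrix
implicant_patterns <- function(imp, k) {
  if (nrow(imp) == 0L) return(character(0))
  vapply(seq_len(nrow(imp)), function(i) {
    chars <- character(k)
    for (j in seq_len(k)) {
      b <- 2L^(k - j)
      chars[j] <- if (bitwAnd(imp[i, "mask"], b) != 0L) "#"
                  else as.character(as.integer(bitwAnd(imp[i, "value"], b) != 0L))
    }
    paste0(chars, collapse = "")
  }, character(1L))
}

# does implicant (value, mask) cover 0-based entry alpha?
implicant_covers <- function(value, mask, alpha, k) {
  bitwAnd(alpha, bitwNot(mask) %% 2L^k) == value
}

# k_e computed through the schema route (used for k > 12 and as a
# cross-check of the compiled kernel): per LUT entry take the covering
# prime implicant with the most wildcards.
schema_ke <- function(rule) {
  k <- rule$k
  if (k == 0L) return(0)
  imps <- list(`0` = prime_implicants(which(rule$outputs == 0L) - 1L, k),
               `1` = prime_implicants(which(rule$outputs == 1L) - 1L, k))
  wc <- lapply(imps, function(m) {
    if (nrow(m) == 0L) integer(0)
    else vapply(m[, "mask"], function(x) sum(bitwAnd(x, 2L^(0:(k - 1L))) != 0L),
                numeric(1L))
  })
  total <- 0
  for (alpha in 0:(2L^k - 1L)) {
    cls <- as.character(rule$outputs[alpha + 1L])
    m <- imps[[cls]]
    cover <- bitwAnd(alpha, bitwNot(m[, "mask"]) %% 2L^k) == m[, "value"]
    total <- total + (k - max(wc[[cls]][cover]))
  }
  total / 2L^k
}
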