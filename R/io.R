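#' Read a Boolean network from a text file
#'
#' Two formats are supported:
#'
#' * `"bnet"` — logical-expression lines `target, expression` using the
#'   operators `&`, `|`, `!` and parentheses (the common .bnet dialect; a
#'   `targets, factors` header and `#` comments are ignored). A node's
#'   ordered input list is the order of first occurrence of identifiers
#'   in its expression. Nodes that are referenced but have no line of
#'   their own are treated as external input nodes: they get a 1-input
#'   self-loop copy rule. Constant expressions `0` / `1` become
#'   constant rules with a self-loop (networks require arity >= 1).
#' * `"table"` — tab-separated truth-table records with header
#'   `node  inputs  outputs`: node id, comma-separated ordered input ids,
#'   and the `2^k` output bits as a string in lexicographic row order
#'   (first input most significant).
#'
#' @param path file path.
#' @param format `"bnet"` or `"table"`.
#' @return A [boolean_network()] with node names from the file.
#' @examples
#' toy <- system.file("extdata", "toy_circuit.bnet", package = "canalcrit")
#' net <- read_network(toy)
#' network_mean_ke(net)
#' @export
read_network <- function(path, format = c("bnet", "table")) {
  format <- match.arg(format)
  lines <- readLines(path)
  if (format == "bnet") parse_bnet(lines) else parse_truth_table(lines)
}

#' Write a Boolean network to a text file
#'
#' `"table"` writes the truth-table format of [read_network()] and
#' round-trips LUTs bit-exactly. `"bnet"` writes each rule as its full
#' canonical disjunctive normal form (one conjunction per ON entry, every
#' input named in order), which also round-trips exactly at the cost of
#' verbosity; constant rules are written as a contradiction/tautology
#' over their inputs.
#'
#' @param net a [boolean_network()].
#' @param path file path.
#' @param format `"bnet"` or `"table"`.
#' @export
write_network <- function(net, path, format = c("bnet", "table")) {
  format <- match.arg(format)
  stopifnot(is_boolean_network(net))
  lines <- if (format == "bnet") deparse_bnet(net) else deparse_truth_table(net)
  writeLines(lines, path)
  invisible(path)
}

parse_bnet <- function(lines) {
  raw <- lines
  keep <- !grepl("^\\s*(#|$)", raw)
  keep[grepl("^\\s*targets\\s*,\\s*factors\\s*$", raw, ignore.case = TRUE)] <- FALSE
  idx <- which(keep)
  targets <- character(0)
  exprs <- character(0)
  for (ln in idx) {
    line <- raw[ln]
    cm <- regexpr(",", line, fixed = TRUE)
    if (cm < 0L) stop(sprintf("line %d: expected 'target, expression'", ln),
                      call. = FALSE)
    targets <- c(targets, trimws(substr(line, 1L, cm - 1L)))
    exprs <- c(exprs, trimws(substr(line, cm + 1L, nchar(line))))
  }
  if (anyDuplicated(targets)) stop("duplicate target node", call. = FALSE)
  inputs_of <- vector("list", length(targets))
  for (j in seq_along(exprs)) {
    ln <- idx[j]
    e <- exprs[j]
    leftover <- gsub("[A-Za-z_.][A-Za-z0-9_.]*|[01()!&| \t]", "", e)
    if (nchar(leftover) > 0L || !nzchar(e)) {
      stop(sprintf("line %d: unsupported token(s) '%s' in expression", ln,
                   leftover), call. = FALSE)
    }
    m <- gregexpr("[A-Za-z_.][A-Za-z0-9_.]*", e)[[1L]]
    ids <- if (m[1L] > 0L) unique(regmatches(e, list(m))[[1L]]) else character(0)
    inputs_of[[j]] <- ids
  }
  referenced <- unique(unlist(inputs_of))
  externals <- setdiff(referenced, targets)
  nodes <- c(targets, externals)
  rules <- vector("list", length(nodes))
  inlist <- vector("list", length(nodes))
  for (j in seq_along(targets)) {
    ids <- inputs_of[[j]]
    if (length(ids) == 0L) {
      # constant expression: self-loop constant rule
      val <- eval(str2lang(exprs[j]), envir = baseenv())
      rules[[j]] <- constant_rule(1L, as.integer(as.logical(val)))
      inlist[[j]] <- j
      next
    }
    k <- length(ids)
    tup <- input_tuples(k)
    env <- new.env(parent = baseenv())
    for (q in seq_len(k)) assign(ids[q], tup[, q] == 1L, envir = env)
    val <- eval(str2lang(exprs[j]), envir = env)
    val <- as.integer(as.logical(val))
    if (length(val) == 1L) val <- rep(val, 2L^k)
    if (length(val) != 2L^k || anyNA(val)) {
      stop(sprintf("line %d: expression did not evaluate to a Boolean rule",
                   idx[j]), call. = FALSE)
    }
    rules[[j]] <- boolean_rule(k, val)
    inlist[[j]] <- match(ids, nodes)
  }
  for (j in seq_along(externals)) {
    at <- length(targets) + j
    rules[[at]] <- copy_rule()
    inlist[[at]] <- at
  }
  boolean_network(rules, inlist, names = nodes)
}

deparse_bnet <- function(net) {
  n <- network_size(net)
  lines <- character(n)
  for (i in seq_len(n)) {
    rule <- net$rules[[i]]
    ids <- net$names[net$inputs[[i]]]
    k <- rule$k
    tup <- input_tuples(k)
    on <- which(rule$outputs == 1L)
    terms <- if (length(on) == 0L) {
      # contradiction over all inputs, preserving the input list
      paste(c(ids[1L], paste0("!", ids[1L]), ids[-1L]), collapse = " & ")
    } else {
      vapply(on, function(a) {
        lits <- ifelse(tup[a, ] == 1L, ids, paste0("!", ids))
        paste0("(", paste(lits, collapse = " & "), ")")
      }, character(1L))
    }
    lines[i] <- paste0(net$names[i], ", ", paste(terms, collapse = " | "))
  }
  c("targets, factors", lines)
}

parse_truth_table <- function(lines) {
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  if (length(parts) == 0L) stop("empty network file", call. = FALSE)
  if (identical(tolower(trimws(parts[[1L]][1L])), "node")) parts <- parts[-1L]
  nodes <- vapply(parts, function(x) trimws(x[1L]), character(1L))
  if (anyDuplicated(nodes)) stop("duplicate node record", call. = FALSE)
  ins <- lapply(parts, function(x) trimws(strsplit(x[2L], ",", fixed = TRUE)[[1L]]))
  bits <- vapply(parts, function(x) trimws(x[3L]), character(1L))
  referenced <- unique(unlist(ins))
  externals <- setdiff(referenced, nodes)
  all_nodes <- c(nodes, externals)
  rules <- vector("list", length(all_nodes))
  inlist <- vector("list", length(all_nodes))
  for (j in seq_along(nodes)) {
    k <- length(ins[[j]])
    if (!grepl("^[01]+$", bits[j]) || nchar(bits[j]) != 2L^k) {
      stop(sprintf("record %d ('%s'): output string must be %d bits of 0/1",
                   j, nodes[j], 2L^k), call. = FALSE)
    }
    rules[[j]] <- boolean_rule(k, as.integer(strsplit(bits[j], "")[[1L]]))
    inlist[[j]] <- match(ins[[j]], all_nodes)
  }
  for (j in seq_along(externals)) {
    at <- length(nodes) + j
    rules[[at]] <- copy_rule()
    inlist[[at]] <- at
  }
  boolean_network(rules, inlist, names = all_nodes)
}

deparse_truth_table <- function(net) {
  n <- network_size(net)
  body <- vapply(seq_len(n), function(i) {
    paste(net$names[i],
          paste(net$names[net$inputs[[i]]], collapse = ","),
          paste0(net$rules[[i]]$outputs, collapse = ""),
          sep = "\t")
  }, character(1L))
  c("node\tinputs\toutputs", body)
}
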