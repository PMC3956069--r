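#' Read a tab-separated expression matrix
#'
#' Expects a TSV file whose first row holds sample ids, first column holds
#' gene ids, and whose body is strictly numeric. Missing values are
#' rejected, not imputed.
#'
#' @param path path to the TSV file.
#' @return an [expression_matrix()].
#' @export
read_expression_matrix <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) < 2L)
    stop("expression file needs a header and at least one gene row", call. = FALSE)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  header <- fields[[1L]]
  # header may or may not carry a leading cell for the gene-id column
  body <- fields[-1L]
  ncells <- lengths(body)
  sample_ids <- if (length(header) == ncells[1L]) header[-1L] else header
  n <- length(sample_ids)
  bad <- which(ncells != n + 1L)
  if (length(bad))
    stop(sprintf("ragged row at line %d: expected %d fields, found %d",
                 bad[1L] + 1L, n + 1L, ncells[bad[1L]]), call. = FALSE)
  gene_ids <- vapply(body, `[[`, character(1L), 1L)
  vals <- suppressWarnings(
    vapply(body, function(f) as.numeric(f[-1L]), numeric(n)))
  vals <- if (n == 1L) matrix(vals, nrow = 1L) else vals
  vals <- t(vals)
  if (anyNA(vals)) {
    bad <- which(is.na(vals), arr.ind = TRUE)[1L, ]
    stop(sprintf("non-numeric cell at gene '%s', sample '%s'",
                 gene_ids[bad[1L]], sample_ids[bad[2L]]), call. = FALSE)
  }
  expression_matrix(vals, gene_ids = gene_ids, sample_ids = sample_ids)
}

#' Write an expression matrix to TSV
#'
#' Inverse of [read_expression_matrix()]: header row of sample ids
#' (with a leading `gene` cell), one row per gene.
#'
#' @param X an [expression_matrix()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_expression_matrix <- function(X, path) {
  X <- validate_expression_matrix(X)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(c("gene", colnames(X)), collapse = "\t"), con)
  body <- apply(X, 1L, function(v)
    paste(format(v, digits = 17, scientific = FALSE, trim = TRUE),
          collapse = "\t"))
  writeLines(paste(rownames(X), body, sep = "\t"), con)
  invisible(path)
}

#' Read a signed directed edge list
#'
#' Accepts DREAM-style 2- or 3-column TSV files of `regulator TAB target
#' [TAB sign]` triples. Recognised sign tokens: `1`, `+1`, `+` (activating)
#' and `-1`, `−1`, `-` (inhibiting). A missing third column defaults
#' to activating. Gene ids are collected in first-appearance order.
#'
#' @param path path to the edge-list file.
#' @return a [signed_network()].
#' @export
read_signed_edge_list <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  fields <- strsplit(lines, "[\t ]+")
  ncols <- lengths(fields)
  if (length(fields) && !all(ncols %in% c(2L, 3L)))
    stop("edge list rows must have 2 or 3 columns", call. = FALSE)
  reg <- vapply(fields, `[[`, character(1L), 1L)
  tgt <- vapply(fields, `[[`, character(1L), 2L)
  tok <- vapply(fields, function(f) if (length(f) >= 3L) f[[3L]] else "1",
                character(1L))
  sign <- map_sign_token(tok)
  key <- paste(reg, tgt, sep = "\r")
  if (anyDuplicated(key)) {
    d <- which(duplicated(key))[1L]
    stop(sprintf("duplicate edge: %s -> %s", reg[d], tgt[d]), call. = FALSE)
  }
  gene_ids <- unique(c(rbind(reg, tgt)))  # first-appearance order
  signed_network(gene_ids,
                 data.frame(regulator = reg, target = tgt, sign = sign,
                            stringsAsFactors = FALSE))
}

map_sign_token <- function(tok) {
  out <- integer(length(tok))
  out[tok %in% c("1", "+1", "+")] <- 1L
  out[tok %in% c("-1", "−1", "-")] <- -1L
  bad <- which(out == 0L)
  if (length(bad))
    stop("unknown sign token: '", tok[bad[1L]], "'", call. = FALSE)
  out
}

#' Write a signed edge list to TSV
#'
#' @param net a [signed_network()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_signed_edge_list <- function(net, path) {
  stopifnot(is_signed_network(net))
  con <- file(path, "w")
  on.exit(close(con))
  if (nrow(net$edges))
    writeLines(paste(net$edges$regulator, net$edges$target, net$edges$sign,
                     sep = "\t"), con)
  invisible(path)
}

#' Collapse a directed signed network to an undirected gold standard
#'
#' Direction and self-interactions are disregarded: each directed edge
#' contributes its unordered pair, self-edges are dropped, reciprocal
#' edges collapse to one pair.
#'
#' @param net a [signed_network()].
#' @return an [undirected_truth()] over the same gene set.
#' @export
to_undirected_truth <- function(net) {
  stopifnot(is_signed_network(net))
  e <- net$edges
  keep <- e$regulator != e$target
  undirected_truth(net$gene_ids, cbind(e$regulator[keep], e$target[keep]))
}

#' Write a ranked prediction list
#'
#' Emits one line `gene_i TAB gene_j TAB weight` per unordered gene pair
#' (every pair is covered, since AUC is computed over the complete ranked
#' list), sorted by weight descending with ties broken by lexicographic
#' pair id; within a line the lexicographically smaller gene comes first.
#'
#' @param w a [weight_matrix()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_ranked_edges <- function(w, path) {
  stopifnot(is_weight_matrix(w))
  ids <- rownames(w)
  p <- upper_pairs(nrow(w))
  a <- pmin(ids[p[, 1L]], ids[p[, 2L]])
  b <- pmax(ids[p[, 1L]], ids[p[, 2L]])
  wt <- unclass_matrix(w)[p]
  o <- order(-wt, a, b)
  writeLines(paste(a[o], b[o],
                   format(wt[o], digits = 17, scientific = FALSE, trim = TRUE),
                   sep = "\t"), path)
  invisible(path)
}

#' Read a gold-standard pair list
#'
#' DREAM-style gold standards list `gene_i TAB gene_j [TAB flag]`, where a
#' third column of 1/0 marks true/absent interactions; only flag-1 rows
#' (or all rows, if no flag) become truth pairs.
#'
#' @param path path to the pair list.
#' @param gene_ids optional full gene universe; defaults to the genes seen
#'   in the file.
#' @return an [undirected_truth()].
#' @export
read_gold_standard <- function(path, gene_ids = NULL) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  fields <- strsplit(lines, "[\t ]+")
  a <- vapply(fields, `[[`, character(1L), 1L)
  b <- vapply(fields, `[[`, character(1L), 2L)
  flag <- vapply(fields, function(f) if (length(f) >= 3L) f[[3L]] else "1",
                 character(1L))
  keep <- flag != "0"
  if (is.null(gene_ids)) gene_ids <- unique(c(rbind(a, b)))
  undirected_truth(gene_ids, cbind(a[keep], b[keep]))
}
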