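#' Construct an expression matrix
#'
#' The central data container: a genes x samples matrix of real-valued
#' steady-state expression levels. Rows are genes, columns are samples
#' (experiments). All downstream matrices (mutual information, predicted
#' weights) follow the row order of this matrix.
#'
#' @param values numeric matrix, genes in rows, samples in columns.
#' @param gene_ids character vector of unique gene identifiers
#'   (default: rownames of `values`).
#' @param sample_ids character vector of unique sample identifiers
#'   (default: colnames of `values`).
#' @return a numeric matrix of class `expression_matrix` with gene ids as
#'   rownames and sample ids as colnames.
#' @examples
#' X <- expression_matrix(matrix(rnorm(6), 3, 2),
#'                        gene_ids = c("A", "B", "C"),
#'                        sample_ids = c("s1", "s2"))
#' @export
expression_matrix <- function(values, gene_ids = rownames(values),
                              sample_ids = colnames(values)) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(gene_ids)) gene_ids <- paste0("G", seq_len(nrow(values)))
  if (is.null(sample_ids)) sample_ids <- paste0("S", seq_len(ncol(values)))
  rownames(values) <- as.character(gene_ids)
  colnames(values) <- as.character(sample_ids)
  class(values) <- c("expression_matrix", class(values))
  validate_expression_matrix(values)
}

#' @rdname expression_matrix
#' @param x object to validate / test.
#' @export
validate_expression_matrix <- function(x) {
  stopifnot(is.matrix(x), is.numeric(x))
  if (nrow(x) < 2L || ncol(x) < 2L)
    stop("expression matrix needs at least 2 genes and 2 samples", call. = FALSE)
  if (anyNA(x) || any(!is.finite(x))) {
    bad <- which(!is.finite(x), arr.ind = TRUE)[1L, ]
    stop(sprintf("non-finite expression value at gene '%s', sample '%s'",
                 rownames(x)[bad[1L]], colnames(x)[bad[2L]]), call. = FALSE)
  }
  dup <- rownames(x)[duplicated(rownames(x))]
  if (length(dup))
    stop("duplicate gene id: ", dup[1L], call. = FALSE)
  dup <- colnames(x)[duplicated(colnames(x))]
  if (length(dup))
    stop("duplicate sample id: ", dup[1L], call. = FALSE)
  x
}

#' @rdname expression_matrix
#' @export
is_expression_matrix <- function(x) inherits(x, "expression_matrix")

#' Construct a signed directed network
#'
#' Ground-truth container for simulation: a directed graph of
#' regulator -> target interactions, each signed +1 (activating) or
#' -1 (inhibiting).
#'
#' @param gene_ids character vector of unique gene ids (node set).
#' @param edges data.frame with columns `regulator`, `target`, `sign`;
#'   `sign` must be +1 or -1. Duplicate (regulator, target) rows are an
#'   error. Self-edges are permitted but flagged with a warning.
#' @return object of class `signed_network`: a list with `gene_ids` and
#'   `edges`.
#' @export
signed_network <- function(gene_ids, edges) {
  gene_ids <- as.character(gene_ids)
  if (anyDuplicated(gene_ids))
    stop("duplicate gene id: ", gene_ids[duplicated(gene_ids)][1L], call. = FALSE)
  edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  if (nrow(edges) == 0L) {
    edges <- data.frame(regulator = character(), target = character(),
                        sign = integer(), stringsAsFactors = FALSE)
  } else {
    stopifnot(all(c("regulator", "target", "sign") %in% names(edges)))
    edges$regulator <- as.character(edges$regulator)
    edges$target <- as.character(edges$target)
    edges$sign <- as.integer(edges$sign)
    if (!all(edges$sign %in% c(-1L, 1L)))
      stop("edge sign must be +1 or -1", call. = FALSE)
    unknown <- setdiff(c(edges$regulator, edges$target), gene_ids)
    if (length(unknown))
      stop("edge endpoint not in gene_ids: ", unknown[1L], call. = FALSE)
    key <- paste(edges$regulator, edges$target, sep = "\r")
    if (anyDuplicated(key)) {
      d <- edges[duplicated(key), , drop = FALSE][1L, ]
      stop(sprintf("duplicate edge: %s -> %s", d$regulator, d$target),
           call. = FALSE)
    }
    if (any(edges$regulator == edges$target))
      warning("network contains self-edges", call. = FALSE)
  }
  structure(list(gene_ids = gene_ids, edges = edges),
            class = "signed_network")
}

#' @rdname signed_network
#' @param x object to test.
#' @export
is_signed_network <- function(x) inherits(x, "signed_network")

#' @export
print.signed_network <- function(x, ...) {
  cat(sprintf("signed_network: %d genes, %d edges (%d activating, %d inhibiting)\n",
              length(x$gene_ids), nrow(x$edges),
              sum(x$edges$sign == 1L), sum(x$edges$sign == -1L)))
  invisible(x)
}

#' Construct an undirected gold standard
#'
#' Evaluation gold standard: the set of unordered gene pairs that
#' interact, with direction and self-interactions disregarded.
#'
#' @param gene_ids character vector of unique gene ids.
#' @param pairs two-column character matrix or data.frame of gene pairs;
#'   order within a pair is irrelevant, self-pairs are an error.
#' @return object of class `undirected_truth`: list with `gene_ids` and a
#'   canonical two-column `pairs` matrix (each row sorted, rows unique).
#' @export
undirected_truth <- function(gene_ids, pairs) {
  gene_ids <- as.character(gene_ids)
  if (anyDuplicated(gene_ids))
    stop("duplicate gene id", call. = FALSE)
  pairs <- as.matrix(pairs)
  if (length(pairs) == 0L) {
    pairs <- matrix(character(), 0L, 2L)
  } else {
    stopifnot(ncol(pairs) == 2L)
    mode(pairs) <- "character"
    if (any(pairs[, 1L] == pairs[, 2L]))
      stop("self-pair in undirected truth", call. = FALSE)
    unknown <- setdiff(as.vector(pairs), gene_ids)
    if (length(unknown))
      stop("pair endpoint not in gene_ids: ", unknown[1L], call. = FALSE)
    pairs <- t(apply(pairs, 1L, sort))
    pairs <- unique(pairs)
  }
  colnames(pairs) <- c("a", "b")
  structure(list(gene_ids = gene_ids, pairs = pairs),
            class = "undirected_truth")
}

#' @export
print.undirected_truth <- function(x, ...) {
  cat(sprintf("undirected_truth: %d genes, %d interacting pairs\n",
              length(x$gene_ids), nrow(x$pairs)))
  invisible(x)
}

#' Construct a predicted weight matrix
#'
#' Symmetric genes x genes matrix of predicted interaction weights with
#' the orientation contract "larger weight = more confident edge". The
#' diagonal is defined but ignored by evaluation.
#'
#' @param weights symmetric numeric matrix with gene ids as dimnames.
#' @param gene_ids optional gene ids (default: rownames).
#' @return numeric matrix of class `weight_matrix`.
#' @export
weight_matrix <- function(weights, gene_ids = rownames(weights)) {
  weights <- as.matrix(weights)
  storage.mode(weights) <- "double"
  if (is.null(gene_ids)) gene_ids <- paste0("G", seq_len(nrow(weights)))
  dimnames(weights) <- list(gene_ids, gene_ids)
  if (nrow(weights) != ncol(weights))
    stop("weight matrix must be square", call. = FALSE)
  if (any(!is.finite(weights)))
    stop("weight matrix must be finite", call. = FALSE)
  if (max(abs(weights - t(weights))) > 1e-8 * max(1, max(abs(weights))))
    stop("weight matrix must be symmetric", call. = FALSE)
  weights <- (weights + t(weights)) / 2  # exact symmetry
  class(weights) <- c("weight_matrix", class(weights))
  weights
}

#' @rdname weight_matrix
#' @param x object to test.
#' @export
is_weight_matrix <- function(x) inherits(x, "weight_matrix")

# strip s3 class so base matrix ops behave predictably
unclass_matrix <- function(x) {
  class(x) <- "matrix"
  x
}

# all unordered pairs (i < j) of n items, as a 2-column integer matrix;
# row order is the column-major upper triangle, matching upper.tri()
upper_pairs <- function(n) {
  idx <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  idx[, c("row", "col"), drop = FALSE]
}

# canonical "a|b" key for unordered string pairs
pair_key <- function(a, b) {
  paste(pmin(a, b), pmax(a, b), sep = "\r")
}
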