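#' Correlation-based interaction weights
#'
#' Scores every gene pair by the absolute value of a correlation
#' coefficient between their expression profiles: Pearson's r, Spearman's
#' rho (Pearson on within-gene ranks) or Kendall's tau-a
#' \eqn{(n_c - n_d) / (n(n-1)/2)} counted over all sample pairs (ties
#' contribute zero to the numerator).
#'
#' Pairs involving a constant-variance profile score 0 (undefined
#' correlation carries no evidence); this never raises an error
#' mid-benchmark.
#'
#' @param X an [expression_matrix()] with n >= 3 samples.
#' @param flavor `"pearson"`, `"spearman"` or `"kendall"`.
#' @return a [weight_matrix()] with entries in `[0, 1]`, zero diagonal.
#' @export
correlation_weights <- function(X, flavor = c("pearson", "spearman", "kendall")) {
  flavor <- match.arg(flavor)
  X <- validate_expression_matrix(X)
  if (ncol(X) < 3L) stop("need at least 3 samples", call. = FALSE)
  w <- abs(signed_correlation(X, flavor))
  diag(w) <- 0
  weight_matrix(w, gene_ids = rownames(X))
}

# signed correlation matrix with constant-profile pairs mapped to 0
signed_correlation <- function(X, flavor) {
  M <- unclass_matrix(X)
  if (flavor == "kendall") return(kendall_tau_matrix(M))
  if (flavor == "spearman")
    M <- t(apply(M, 1L, rank))
  r <- suppressWarnings(stats::cor(t(M)))
  r[!is.finite(r)] <- 0
  r
}

# Kendall tau-a for all gene pairs at once: per gene, the vector of
# sign(X_ik - X_il) over sample pairs k < l; the dot product of two such
# sign vectors is n_c - n_d (ties contribute 0).
kendall_tau_matrix <- function(M) {
  n <- ncol(M)
  ut <- upper.tri(matrix(0, n, n))
  S <- t(apply(M, 1L, function(x) sign(outer(x, x, "-"))[ut]))
  tau <- tcrossprod(S) / (n * (n - 1) / 2)
  tau[!is.finite(tau)] <- 0
  tau
}

#' Hub-favouring corrected Spearman weights
#'
#' Corrects Spearman's coefficient for a pair by the mean correlation of
#' each endpoint with all other genes, favouring hub genes:
#' directionally, \eqn{w_{i \to j} = | \rho_{ij} \cdot
#' \mathrm{mean}_{k \ne i} \rho_{ik} |}; the reported weight is the
#' maximum over the two orientations. The mean excludes the
#' self-correlation term.
#'
#' @inheritParams correlation_weights
#' @return a [weight_matrix()], zero diagonal.
#' @export
spearman_c <- function(X) {
  X <- validate_expression_matrix(X)
  if (ncol(X) < 3L) stop("need at least 3 samples", call. = FALSE)
  rho <- signed_correlation(X, "spearman")
  N <- nrow(rho)
  row_mean <- (rowSums(rho) - diag(rho)) / (N - 1)
  w_dir <- abs(rho * row_mean)  # row i scaled by gene i's mean correlation
  w <- pmax(w_dir, t(w_dir))
  diag(w) <- 0
  weight_matrix(w, gene_ids = rownames(X))
}

#' Soft-power transform of a weight matrix
#'
#' Raises each weight in `[0, 1]` to the power `beta` ("softpower"),
#' amplifying strong correlations. The transform is strictly monotone, so
#' ranking-based accuracy (AUC) against any gold standard is unchanged;
#' it only reshapes the weight distribution.
#'
#' @param w a [weight_matrix()] with entries in `[0, 1]`.
#' @param beta positive exponent.
#' @return a [weight_matrix()].
#' @export
softpower <- function(w, beta) {
  stopifnot(is_weight_matrix(w))
  if (!is.numeric(beta) || length(beta) != 1L || beta <= 0)
    stop("beta must be a positive number", call. = FALSE)
  if (min(w) < 0 || max(w) > 1)
    stop("softpower expects weights in [0, 1]", call. = FALSE)
  weight_matrix(unclass_matrix(w)^beta, gene_ids = rownames(w))
}

#' Mutual-rank weights
#'
#' For each gene i, ranks |Pearson r| with every other gene (rank 1 =
#' strongest, ties receive average ranks); the mutual rank of a pair is
#' the geometric mean \eqn{MR_{ij} = \sqrt{rank_{ij} \cdot rank_{ji}}}.
#' Reported weight is `1 / MR` so that larger means stronger.
#'
#' @inheritParams correlation_weights
#' @return a [weight_matrix()], zero diagonal.
#' @export
mutual_rank <- function(X) {
  X <- validate_expression_matrix(X)
  if (nrow(X) < 3L) stop("need at least 3 genes", call. = FALSE)
  a <- abs(signed_correlation(X, "pearson"))
  N <- nrow(a)
  rk <- matrix(0, N, N)
  for (i in seq_len(N)) {
    others <- setdiff(seq_len(N), i)
    rk[i, others] <- rank(-a[i, others])  # rank 1 = strongest
  }
  mr <- sqrt(rk * t(rk))
  w <- 1 / mr
  w[!is.finite(w)] <- 0
  diag(w) <- 0
  weight_matrix(w, gene_ids = rownames(X))
}

#' Euclidean-distance weights on median-normalized profiles
#'
#' Profiles are normalized to their absolute deviation from the per-gene
#' median, \eqn{\hat X_{ik} = |X_{ik} - \mathrm{median}(X_i)|}; pairs are
#' scored by the negated Euclidean distance between normalized profiles
#' (larger = stronger).
#'
#' @param X an [expression_matrix()].
#' @return a [weight_matrix()] of non-positive values, zero diagonal.
#' @export
euclid <- function(X) {
  X <- validate_expression_matrix(X)
  Xh <- euclid_normalize(X)
  d <- as.matrix(stats::dist(Xh))
  w <- -d
  diag(w) <- 0
  weight_matrix(w, gene_ids = rownames(X))
}

euclid_normalize <- function(X) {
  M <- unclass_matrix(X)
  abs(M - apply(M, 1L, stats::median))
}

#' Generalized knockout z-score weights
#'
#' Assumes the sample in which a gene attains its minimum expression is
#' the experiment in which it was knocked out (exactly true for knockout
#' designs, a heuristic otherwise). The effect of gene i on gene j is the
#' normalized deviation of j's expression in that sample from j's mean:
#' \eqn{z_{ij} = |X_{j,k^*(i)} - \bar X_j| / \mathrm{sd}(X_j)} with
#' \eqn{k^*(i) = \mathrm{argmin}_k X_{ik}} (first index on ties). The
#' reported weight is \eqn{\max(z_{ij}, z_{ji})}; zero-variance profiles
#' contribute 0.
#'
#' @param X an [expression_matrix()] with n >= 3 samples.
#' @return a [weight_matrix()], zero diagonal.
#' @export
zscore_generalized <- function(X) {
  X <- validate_expression_matrix(X)
  if (ncol(X) < 3L) stop("need at least 3 samples", call. = FALSE)
  M <- unclass_matrix(X)
  kstar <- apply(M, 1L, which.min)           # first index on ties
  mu <- rowMeans(M)
  sdv <- apply(M, 1L, stats::sd)
  # z[i, j]: deviation of gene j at gene i's minimum sample
  z <- abs(t(M[, kstar, drop = FALSE]) - rep(mu, each = nrow(M))) /
    rep(pmax(sdv, .Machine$double.eps), each = nrow(M))
  z[, sdv == 0] <- 0
  w <- pmax(z, t(z))
  diag(w) <- 0
  weight_matrix(w, gene_ids = rownames(X))
}

#' Mass-distance weights
#'
#' For a pair of profiles, the per-sample mass \eqn{M_k(i,j)} is the
#' empirical fraction of all genes whose expression in sample k lies in
#' the closed interval bounded by \eqn{X_{ik}} and \eqn{X_{jk}}; the mass
#' distance is the product over samples, \eqn{md_{ij} = \prod_k M_k}.
#' Small volume = similar profiles, so the ranking weight is the negated
#' log mass, \eqn{w_{ij} = -\sum_k \log M_k} (a strictly monotone
#' transform of \eqn{-md}, immune to the underflow of the raw product
#' for large n).
#'
#' @param X an [expression_matrix()].
#' @return a [weight_matrix()] of nonnegative values, diagonal ignored.
#' @seealso [mass_distance_values()] for the raw product.
#' @export
mass_distance <- function(X) {
  X <- validate_expression_matrix(X)
  w <- -mass_distance_log(X)
  diag(w) <- 0
  weight_matrix(w, gene_ids = rownames(X))
}

#' @rdname mass_distance
#' @return `mass_distance_values` returns the raw product matrix
#'   \eqn{md_{ij} \in (0, 1]}.
#' @export
mass_distance_values <- function(X) {
  md <- exp(mass_distance_log(validate_expression_matrix(X)))
  dimnames(md) <- list(rownames(X), rownames(X))
  md
}

# sum over samples of log M_k; frequencies estimated from all genes'
# values at that sample (coordinate-wise empirical distribution)
mass_distance_log <- function(X) {
  M <- unclass_matrix(X)
  N <- nrow(M)
  out <- matrix(0, N, N)
  for (k in seq_len(ncol(M))) {
    v <- M[, k]
    sv <- sort(v)
    lo <- outer(v, v, pmin)
    hi <- outer(v, v, pmax)
    n_le <- matrix(findInterval(hi, sv), N, N)
    n_lt <- matrix(findInterval(lo, sv, left.open = TRUE), N, N)
    out <- out + log((n_le - n_lt) / N)
  }
  out
}
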