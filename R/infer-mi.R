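#' Equal-width discretization of expression profiles
#'
#' Per gene, the range `[min, max]` is split into `bins` equal-width
#' intervals; values map to bin indices `0 .. bins-1`, the maximum falls
#' into the top bin, and a constant profile maps entirely to bin 0.
#'
#' @param X an [expression_matrix()] (or plain numeric matrix).
#' @param bins number of bins (>= 2). The package default elsewhere is
#'   `ceiling(sqrt(n))` for n samples.
#' @return integer matrix of the same shape as `X`.
#' @export
discretize_equal_width <- function(X, bins) {
  bins <- as.integer(bins)
  stopifnot(bins >= 2L)
  M <- if (is_expression_matrix(X)) unclass_matrix(X) else as.matrix(X)
  lo <- apply(M, 1L, min)
  width <- (apply(M, 1L, max) - lo) / bins
  D <- floor((M - lo) / pmax(width, .Machine$double.xmin))
  D[D >= bins] <- bins - 1L         # top boundary closes the last bin
  D[width == 0, ] <- 0L             # constant gene
  storage.mode(D) <- "integer"
  dimnames(D) <- dimnames(M)
  D
}

#' Pairwise mutual information of discretized profiles
#'
#' Empirical (maximum-likelihood) mutual information, in nats, between
#' every pair of rows of a discretized matrix:
#' \eqn{I(X_i;X_j) = \sum_{x,y} p(x,y) \log \frac{p(x,y)}{p(x)p(y)}}.
#' The diagonal holds the per-gene entropy \eqn{H(X_i) = I(X_i;X_i)}.
#'
#' @param D integer matrix of bin indices (genes x samples), e.g. from
#'   [discretize_equal_width()].
#' @return symmetric numeric matrix of MI values (nats), nonnegative up
#'   to floating tolerance.
#' @export
mutual_info_matrix <- function(D) {
  D <- as.matrix(D)
  storage.mode(D) <- "integer"
  N <- nrow(D)
  n <- ncol(D)
  B <- max(D) + 1L
  # per-gene marginal entropies
  H <- apply(D, 1L, function(d) {
    p <- tabulate(d + 1L, B) / n
    -sum(p[p > 0] * log(p[p > 0]))
  })
  mi <- diag(H, N)
  for (i in seq_len(N - 1L)) {
    di <- D[i, ]
    for (j in (i + 1L):N) {
      joint <- tabulate(di * B + D[j, ] + 1L, B * B) / n
      pos <- joint > 0
      hj <- -sum(joint[pos] * log(joint[pos]))
      mi[i, j] <- mi[j, i] <- H[i] + H[j] - hj
    }
  }
  dimnames(mi) <- list(rownames(D), rownames(D))
  mi
}

default_bins <- function(X) max(2L, ceiling(sqrt(ncol(X))))

#' Relevance-network weights
#'
#' Scores each gene pair by the mutual information between their
#' discretized expression profiles (equal-width bins, empirical entropy
#' estimator).
#'
#' @param X an [expression_matrix()].
#' @param bins number of equal-width bins; default `ceiling(sqrt(n))`.
#' @return a [weight_matrix()] of MI values in nats, zero diagonal.
#' @export
relevance_network <- function(X, bins = default_bins(X)) {
  X <- validate_expression_matrix(X)
  mi <- mutual_info_matrix(discretize_equal_width(X, bins))
  mi[mi < 0] <- 0  # clip floating noise
  diag(mi) <- 0
  weight_matrix(mi, gene_ids = rownames(X))
}

#' Context-likelihood-of-relatedness weights
#'
#' Background-corrects the mutual-information matrix: for each gene i the
#' MI values to all other genes form a background distribution with mean
#' \eqn{\mu_i} and standard deviation \eqn{\sigma_i} (diagonal excluded);
#' the directional score is \eqn{z_i(j) = \max(0, (I_{ij} - \mu_i) /
#' \sigma_i)} and the pair weight combines both directions by the
#' Euclidean norm \eqn{w_{ij} = \sqrt{z_i(j)^2 + z_j(i)^2}}. A gene with
#' zero background spread contributes z = 0.
#'
#' @inheritParams relevance_network
#' @return a [weight_matrix()], zero diagonal.
#' @export
clr <- function(X, bins = default_bins(X)) {
  X <- validate_expression_matrix(X)
  if (nrow(X) < 3L) stop("need at least 3 genes", call. = FALSE)
  mi <- mutual_info_matrix(discretize_equal_width(X, bins))
  weight_matrix(clr_from_mi(mi), gene_ids = rownames(X))
}

# background z-scoring of an MI matrix (rows = background, diagonal out)
clr_from_mi <- function(mi) {
  off <- mi; diag(off) <- NA
  mu <- rowMeans(off, na.rm = TRUE)
  sdv <- apply(off, 1L, stats::sd, na.rm = TRUE)
  z <- (mi - mu) / ifelse(sdv > 0, sdv, Inf)  # sigma = 0 -> z = 0
  z[z < 0] <- 0
  w <- sqrt(z^2 + t(z)^2)
  diag(w) <- 0
  w
}

#' ARACNE weights (data-processing-inequality pruning)
#'
#' Starts from the mutual-information matrix and, for every unordered
#' gene triple, marks the strictly smallest of the three MI values for
#' removal when it undercuts the smaller of the other two by more than
#' the tolerance `eps` (an indirect interaction under the data processing
#' inequality). Surviving entries keep their MI value; pruned entries
#' are set to 0.
#'
#' @inheritParams relevance_network
#' @param eps DPI tolerance (>= 0); default 0.1.
#' @return a [weight_matrix()], zero diagonal.
#' @export
aracne <- function(X, bins = default_bins(X), eps = 0.1) {
  X <- validate_expression_matrix(X)
  stopifnot(eps >= 0)
  mi <- mutual_info_matrix(discretize_equal_width(X, bins))
  mi[mi < 0] <- 0
  weight_matrix(aracne_from_mi(mi, eps), gene_ids = rownames(X))
}

# DPI pruning: in every triangle the strictly smallest MI is zeroed when
# it undercuts the smaller of the other two by more than eps
aracne_from_mi <- function(mi, eps) {
  diag(mi) <- 0
  N <- nrow(mi)
  w <- mi
  if (N >= 3L) {
    for (i in seq_len(N - 1L)) {
      for (j in (i + 1L):N) {
        k <- setdiff(seq_len(N), c(i, j))
        if (any(mi[i, j] < pmin(mi[i, k], mi[j, k]) - eps)) w[i, j] <- w[j, i] <- 0
      }
    }
  }
  w
}

#' PCIT weights (partial-correlation DPI pruning)
#'
#' Correlation analogue of ARACNE: for every gene triple (i, j, k) the
#' first-order partial correlations
#' \eqn{r_{ij \cdot k} = (r_{ij} - r_{ik} r_{jk}) /
#' \sqrt{(1 - r_{ik}^2)(1 - r_{jk}^2)}} are computed and the trio's local
#' tolerance \eqn{\epsilon_k} is the average absolute ratio of partial to
#' direct correlation over its three pairs. The data-processing
#' inequality is then applied to the partials: edge (i, j) is pruned
#' when, for some k, both \eqn{|r_{ij \cdot k}| \le \epsilon_k
#' |r_{ik \cdot j}|} and \eqn{|r_{ij \cdot k}| \le \epsilon_k
#' |r_{jk \cdot i}|} hold — its conditional dependence collapses while
#' the two links through k persist, the signature of an indirect chain.
#' Kept edges are weighted \eqn{|r_{ij}|}, pruned edges 0. Pairs with
#' \eqn{|r| = 1} somewhere in the trio make the partials degenerate;
#' such pairs are kept.
#'
#' @param X an [expression_matrix()] with N >= 3 genes and n >= 4 samples.
#' @return a [weight_matrix()], zero diagonal.
#' @export
pcit <- function(X) {
  X <- validate_expression_matrix(X)
  if (nrow(X) < 3L) stop("need at least 3 genes", call. = FALSE)
  if (ncol(X) < 4L) stop("need at least 4 samples", call. = FALSE)
  r <- signed_correlation(X, "pearson")
  N <- nrow(r)
  keep <- matrix(TRUE, N, N)
  for (i in seq_len(N - 1L)) {
    for (j in (i + 1L):N) {
      ks <- setdiff(seq_len(N), c(i, j))
      tp <- trio_partials(r[i, j], r[i, ks], r[j, ks])
      tolr <- (abs(tp$p_ij / r[i, j]) + abs(tp$p_ik / r[i, ks]) +
                 abs(tp$p_jk / r[j, ks])) / 3
      tolr[!is.finite(tolr)] <- 1   # zero direct correlation: neutral trio
      prune <- !tp$degenerate &
        abs(tp$p_ij) <= tolr * abs(tp$p_ik) &
        abs(tp$p_ij) <= tolr * abs(tp$p_jk)
      if (any(prune)) keep[i, j] <- keep[j, i] <- FALSE
    }
  }
  w <- abs(r) * keep
  diag(w) <- 0
  weight_matrix(w, gene_ids = rownames(X))
}

# first-order partial correlations of a trio; vectorized over k.
# degenerate (|r| = 1) trios are flagged and excluded from pruning
trio_partials <- function(rij, rik, rjk) {
  den_ij <- (1 - rik^2) * (1 - rjk^2)
  den_ik <- (1 - rij^2) * (1 - rjk^2)
  den_jk <- (1 - rij^2) * (1 - rik^2)
  list(
    p_ij = (rij - rik * rjk) / sqrt(pmax(den_ij, .Machine$double.eps)),
    p_ik = (rik - rij * rjk) / sqrt(pmax(den_ik, .Machine$double.eps)),
    p_jk = (rjk - rij * rik) / sqrt(pmax(den_jk, .Machine$double.eps)),
    degenerate = den_ij <= 0 | den_ik <= 0 | den_jk <= 0)
}

#' Greedy minimum-redundancy maximum-relevance selection
#'
#' Orders candidate regulators of a target gene by greedy forward
#' selection: each step picks the unselected gene maximizing
#' \eqn{s_i = I(X_i; X_t) - \frac{1}{|S|} \sum_{k \in S} I(X_i; X_k)}
#' (pure relevance for the first pick) and records that step score.
#'
#' @param target gene id of the target.
#' @param X an [expression_matrix()].
#' @param bins number of equal-width MI bins.
#' @param max_regulators maximum number of genes to select (default all).
#' @param mi optional precomputed MI matrix over `rownames(X)`.
#' @return data.frame with columns `gene`, `score` (step score at
#'   selection) and `step`, in selection order.
#' @export
mrmr_select <- function(target, X, bins = default_bins(X),
                        max_regulators = nrow(X) - 1L, mi = NULL) {
  X <- validate_expression_matrix(X)
  if (!target %in% rownames(X)) stop("unknown target gene: ", target, call. = FALSE)
  if (is.null(mi)) mi <- mutual_info_matrix(discretize_equal_width(X, bins))
  t_idx <- match(target, rownames(X))
  cand <- setdiff(seq_len(nrow(X)), t_idx)
  m <- min(max_regulators, length(cand))
  rel <- mi[cand, t_idx]
  red_sum <- numeric(length(cand))
  picked <- integer(0)
  sel_gene <- character(m); sel_score <- numeric(m)
  avail <- rep(TRUE, length(cand))
  for (s in seq_len(m)) {
    score <- rel - if (length(picked)) red_sum / length(picked) else 0
    score[!avail] <- -Inf
    best <- which.max(score)
    sel_gene[s] <- rownames(X)[cand[best]]
    sel_score[s] <- score[best]
    avail[best] <- FALSE
    picked <- c(picked, best)
    red_sum <- red_sum + mi[cand, cand[best]]
  }
  data.frame(gene = sel_gene, score = sel_score, step = seq_len(m),
             stringsAsFactors = FALSE)
}

#' MRNET weights (forward MRMR selection)
#'
#' Places each gene in turn in the role of target with all other genes as
#' candidate regulators, runs greedy MRMR forward selection and takes the
#' step score of gene i for target j as the directional weight; the pair
#' weight is the maximum over both directions, with negative scores
#' clipped to 0 for ranking.
#'
#' @inheritParams relevance_network
#' @return a [weight_matrix()], zero diagonal.
#' @export
mrnet <- function(X, bins = default_bins(X)) {
  X <- validate_expression_matrix(X)
  mi <- mutual_info_matrix(discretize_equal_width(X, bins))
  N <- nrow(X)
  s <- matrix(0, N, N)  # s[i, j] = step score of regulator i for target j
  for (j in seq_len(N)) {
    sel <- mrmr_select(rownames(X)[j], X, mi = mi)
    s[match(sel$gene, rownames(X)), j] <- sel$score
  }
  w <- pmax(s, t(s))
  w[w < 0] <- 0
  diag(w) <- 0
  weight_matrix(w, gene_ids = rownames(X))
}

# set score used by the backward/replacement variant: total relevance of
# the subset minus the mean pairwise redundancy within it
mrnet_b_set_score <- function(sel, rel, mi_cc) {
  if (!length(sel)) return(0)
  red <- if (length(sel) >= 2L)
    mean(mi_cc[sel, sel][upper.tri(mi_cc[sel, sel])]) else 0
  sum(rel[sel]) - red
}

#' MRNET-B weights (backward selection with replacement)
#'
#' Variant of [mrnet()] that, per target, starts from the full candidate
#' set and repeatedly drops the gene whose removal most improves the set
#' score (total relevance minus mean pairwise redundancy), then attempts
#' single in/out swaps until no improvement. Genes in the final subset
#' are weighted by their MRMR-style score within it,
#' \eqn{s_i = I_{it} - \mathrm{mean}_{k \in S \setminus i} I_{ik}};
#' directions combine by maximum, negatives clip to 0.
#'
#' @inheritParams relevance_network
#' @return a [weight_matrix()], zero diagonal.
#' @export
mrnet_b <- function(X, bins = default_bins(X)) {
  X <- validate_expression_matrix(X)
  mi <- mutual_info_matrix(discretize_equal_width(X, bins))
  N <- nrow(X)
  s <- matrix(0, N, N)
  for (j in seq_len(N)) {
    cand <- setdiff(seq_len(N), j)
    rel <- stats::setNames(mi[cand, j], NULL)
    mi_cc <- mi[cand, cand, drop = FALSE]
    sel <- mrnet_b_select(rel, mi_cc)
    if (length(sel)) {
      sub <- cand[sel]
      sc <- vapply(seq_along(sel), function(q) {
        others <- sel[-q]
        rel[sel[q]] - if (length(others)) mean(mi_cc[sel[q], others]) else 0
      }, numeric(1L))
      s[sub, j] <- sc
    }
  }
  w <- pmax(s, t(s))
  w[w < 0] <- 0
  diag(w) <- 0
  weight_matrix(w, gene_ids = rownames(X))
}

# backward elimination then sequential single-swap replacement on
# candidate indices 1..length(rel); returns selected index vector
mrnet_b_select <- function(rel, mi_cc) {
  sel <- seq_along(rel)
  score <- mrnet_b_set_score(sel, rel, mi_cc)
  # backward phase
  while (length(sel) > 1L) {
    drops <- vapply(seq_along(sel), function(q)
      mrnet_b_set_score(sel[-q], rel, mi_cc), numeric(1L))
    best <- which.max(drops)
    if (drops[best] <= score) break
    sel <- sel[-best]
    score <- drops[best]
  }
  # replacement phase: single swaps while they improve
  repeat {
    out <- setdiff(seq_along(rel), sel)
    if (!length(out) || !length(sel)) break
    improved <- FALSE
    for (q in seq_along(sel)) {
      for (o in out) {
        trial <- c(sel[-q], o)
        sc <- mrnet_b_set_score(trial, rel, mi_cc)
        if (sc > score + 1e-12) {
          sel <- trial; score <- sc; improved <- TRUE
          break
        }
      }
      if (improved) break
    }
    if (!improved) break
  }
  sort(sel)
}
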