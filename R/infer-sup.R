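#' Outer-product features for a gene pair
#'
#' The feature vector of an unordered pair is the symmetrized outer
#' product of the two expression profiles,
#' \eqn{(X_i \otimes X_j + X_j \otimes X_i)/2}, flattened to length
#' \eqn{n^2}. The raw outer product is order-dependent; averaging the
#' two orientations makes the features bit-exactly invariant under
#' swapping the pair, so predicted interactions are symmetric and
#' undirected.
#'
#' @param X an [expression_matrix()].
#' @param pair length-2 character vector of gene ids.
#' @return numeric vector of length `ncol(X)^2`.
#' @export
outer_product_features <- function(X, pair) {
  X <- validate_expression_matrix(X)
  stopifnot(length(pair) == 2L, all(pair %in% rownames(X)))
  xi <- unclass_matrix(X)[pair[1L], ]
  xj <- unclass_matrix(X)[pair[2L], ]
  as.vector((outer(xi, xj) + outer(xj, xi)) / 2)
}

#' Build a labeled gene-pair dataset
#'
#' Every unordered gene pair becomes one sample with outer-product
#' features, labeled +1 when the pair interacts in the gold standard and
#' -1 otherwise.
#'
#' @param X an [expression_matrix()].
#' @param truth an [undirected_truth()] over the same genes.
#' @return list of class `pair_dataset` with elements `pairs` (2-column
#'   id matrix), `features` (pairs x n^2 matrix), `labels` (+1/-1),
#'   `gene_ids` and `n_samples_expr`.
#' @export
build_pair_dataset <- function(X, truth) {
  X <- validate_expression_matrix(X)
  stopifnot(inherits(truth, "undirected_truth"))
  if (!setequal(rownames(X), truth$gene_ids))
    stop("expression matrix and truth cover different gene sets", call. = FALSE)
  ids <- rownames(X)
  p <- upper_pairs(nrow(X))
  pairs <- cbind(ids[p[, 1L]], ids[p[, 2L]])
  feats <- t(apply(pairs, 1L, function(pr) outer_product_features(X, pr)))
  labels <- ifelse(pair_key(pairs[, 1L], pairs[, 2L]) %in%
                     pair_key(truth$pairs[, 1L], truth$pairs[, 2L]), 1L, -1L)
  structure(list(pairs = pairs, features = feats, labels = labels,
                 gene_ids = ids, n_samples_expr = ncol(X)),
            class = "pair_dataset")
}

#' Training configuration for the pair classifier
#'
#' @param C_grid positive complexity values for grid search.
#' @param folds number of cross-validation folds (>= 2).
#' @param label_fraction fraction of true labels retained in the
#'   semi-supervised schemes, in (0, 1].
#' @param label_mode `"full"` (all labels kept), `"pos_neg"` (a seeded
#'   `label_fraction` of positives and of negatives keep their labels,
#'   everything unlabeled is relabeled negative) or `"pos_only"` (only a
#'   fraction of positives keep +1, everything else is relabeled
#'   negative).
#' @param standardize standardize feature columns (fitted on training
#'   pairs only) before training.
#' @param seed integer seed for fold assignment and label sampling.
#' @return list of class `train_config`.
#' @export
train_config <- function(C_grid = c(0.01, 0.1, 1, 10, 100), folds = 5L,
                         label_fraction = 1, label_mode = c("full", "pos_neg",
                                                            "pos_only"),
                         standardize = TRUE, seed = 1L) {
  label_mode <- match.arg(label_mode)
  stopifnot(length(C_grid) > 0L, all(C_grid > 0), folds >= 2L)
  if (label_fraction <= 0 || label_fraction > 1)
    stop("label_fraction must be in (0, 1]", call. = FALSE)
  structure(list(C_grid = C_grid, folds = as.integer(folds),
                 label_fraction = label_fraction, label_mode = label_mode,
                 standardize = isTRUE(standardize), seed = as.integer(seed)),
            class = "train_config")
}

#' Apply a semi-supervised labeling scheme
#'
#' Emulates partial knowledge of the network: a seeded random
#' `label_fraction` of the positives (and, in `pos_neg` mode, of the
#' negatives) keep their true labels; every remaining sample is relabeled
#' negative, which is what a relabel-as-negative semi-supervised
#' classifier trains on. `full` mode returns the dataset unchanged.
#' Retained counts use `ceiling(fraction * n)`.
#'
#' @param ds a fully labeled [build_pair_dataset()] result.
#' @param cfg a [train_config()].
#' @return the dataset with updated `labels`.
#' @export
apply_label_scheme <- function(ds, cfg) {
  stopifnot(inherits(ds, "pair_dataset"), inherits(cfg, "train_config"))
  if (cfg$label_mode == "full" || cfg$label_fraction == 1) return(ds)
  withr::with_seed(cfg$seed + 90001L, {
    pos <- which(ds$labels == 1L)
    keep_pos <- if (length(pos))
      sample(pos, min(length(pos), ceiling(cfg$label_fraction * length(pos))))
    else integer(0)
    if (cfg$label_mode == "pos_neg") {
      neg <- which(ds$labels == -1L)
      # negatives keep their labels too, but unlabeled samples are
      # relabeled negative, so only the positive retention is visible
      sample(neg, min(length(neg), ceiling(cfg$label_fraction * length(neg))))
    }
    labels <- rep(-1L, length(ds$labels))
    labels[keep_pos] <- 1L
    ds$labels <- labels
    ds
  })
}

#' Train a linear maximum-margin pair classifier
#'
#' Linear soft-margin classifier with complexity parameter `C`, solved in
#' the primal with L2-regularized squared-hinge loss
#' \deqn{\min_{w,b}\ \tfrac{1}{2}\|w\|^2 + C \sum_i \max(0,\,
#'   1 - y_i(w^\top x_i + b))^2}
#' via L-BFGS with analytic gradients (an equivalent of the dual
#' quadratic program for linear kernels). Samples are weighted equally.
#'
#' The complexity parameter follows the dimensionless convention of
#' common SVM front ends: feature columns are standardized and the
#' matrix scaled by \eqn{1/\sqrt{d}} so a sample has roughly unit norm,
#' and `C` multiplies the *mean* loss. The default grid
#' `{0.01, ..., 100}` then brackets the under-/over-fitting transition
#' regardless of the feature dimension \eqn{d = n^2}.
#'
#' @param ds a [build_pair_dataset()] result (possibly relabeled).
#' @param C positive complexity parameter.
#' @param standardize standardize feature columns before fitting (the
#'   centering/scaling is stored in the model and applied at prediction).
#' @return list of class `margin_classifier` with `w`, `b`, `center`,
#'   `scale`, `C`.
#' @export
train_margin_classifier <- function(ds, C = 1, standardize = TRUE) {
  stopifnot(inherits(ds, "pair_dataset"), C > 0)
  y <- as.numeric(ds$labels)
  if (length(unique(y)) < 2L)
    stop("training data must contain both classes", call. = FALSE)
  Xf <- ds$features
  d <- ncol(Xf)
  if (standardize) {
    center <- colMeans(Xf)
    scale <- apply(Xf, 2L, stats::sd)
    scale[scale == 0] <- 1
  } else {
    center <- rep(0, d); scale <- rep(1, d)
  }
  scale <- scale * sqrt(d)  # unit-norm-ish samples
  Xf <- sweep(sweep(Xf, 2L, center), 2L, scale, "/")
  n <- nrow(Xf)
  obj <- function(th) {
    w <- th[seq_len(d)]; b <- th[d + 1L]
    m <- 1 - y * (drop(Xf %*% w) + b)
    0.5 * sum(w^2) + C / n * sum(pmax(m, 0)^2)
  }
  grd <- function(th) {
    w <- th[seq_len(d)]; b <- th[d + 1L]
    m <- 1 - y * (drop(Xf %*% w) + b)
    act <- pmax(m, 0)
    gy <- -2 * C / n * act * y
    c(w + drop(crossprod(Xf, gy)), sum(gy))
  }
  fit <- stats::optim(numeric(d + 1L), obj, grd, method = "L-BFGS-B",
                      control = list(maxit = 500L, factr = 1e4))
  structure(list(w = fit$par[seq_len(d)], b = fit$par[d + 1L],
                 center = center, scale = scale, C = C),
            class = "margin_classifier")
}

# signed decision values for a feature matrix
decision_values <- function(model, feats) {
  Xs <- sweep(sweep(feats, 2L, model$center), 2L, model$scale, "/")
  drop(Xs %*% model$w) + model$b
}

#' Decision-value weight matrix
#'
#' Scores gene pairs by the signed distance to the decision boundary,
#' interpreted as an interaction confidence; symmetry follows from the
#' order-invariant pair features.
#'
#' @param model a trained [train_margin_classifier()] model.
#' @param X an [expression_matrix()].
#' @param pairs optional 2-column id matrix of pairs to score (default:
#'   all unordered pairs). Unscored pairs get `-Inf`-free minimal filler
#'   (the minimum scored value) so the matrix stays finite.
#' @return a [weight_matrix()].
#' @export
decision_weights <- function(model, X, pairs = NULL) {
  X <- validate_expression_matrix(X)
  ids <- rownames(X)
  if (is.null(pairs)) {
    p <- upper_pairs(nrow(X))
    pairs <- cbind(ids[p[, 1L]], ids[p[, 2L]])
  }
  feats <- t(apply(pairs, 1L, function(pr) outer_product_features(X, pr)))
  f <- decision_values(model, feats)
  w <- matrix(min(f), nrow(X), nrow(X), dimnames = list(ids, ids))
  w[cbind(pairs[, 1L], pairs[, 2L])] <- f
  w[cbind(pairs[, 2L], pairs[, 1L])] <- f
  diag(w) <- min(f)
  weight_matrix(w, gene_ids = ids)
}

#' Cross-validated whole-network pair classification
#'
#' Partitions all unordered pairs into seeded folds; per fold, the
#' training portion receives the semi-supervised labeling scheme, the
#' complexity parameter is grid-searched on a stratified 80/20 split of
#' training pairs only (scored by AUC against the training-visible
#' labels), the model is retrained on the full training portion and the
#' held-out fold's pairs are scored. Test labels never touch training.
#' If a fold leaves the training data single-class, the folds are
#' redrawn once (seeded) before erroring.
#'
#' @param X an [expression_matrix()].
#' @param truth an [undirected_truth()].
#' @param cfg a [train_config()].
#' @return list with `weights` (out-of-fold decision-value
#'   [weight_matrix()]), `mean_auc`, `sd_auc` and `fold_auc` (per-fold
#'   AUCs against the true labels of the held-out pairs).
#' @export
crossval_score <- function(X, truth, cfg = train_config()) {
  X <- validate_expression_matrix(X)
  stopifnot(inherits(cfg, "train_config"))
  ds <- build_pair_dataset(X, truth)
  n_pairs <- nrow(ds$pairs)
  folds_ok <- function(fold) {
    all(vapply(seq_len(cfg$folds), function(f) {
      tr <- apply_label_scheme(subset_pairs(ds, fold != f), cfg)
      length(unique(tr$labels)) == 2L
    }, logical(1L)))
  }
  fold <- draw_folds(n_pairs, cfg$folds, cfg$seed)
  if (!folds_ok(fold)) {
    fold <- draw_folds(n_pairs, cfg$folds, cfg$seed + 1L)
    if (!folds_ok(fold))
      stop("could not draw folds with both classes in every training set",
           call. = FALSE)
  }
  scores <- rep(NA_real_, n_pairs)
  fold_auc <- numeric(cfg$folds)
  for (f in seq_len(cfg$folds)) {
    tr <- apply_label_scheme(subset_pairs(ds, fold != f), cfg)
    C_best <- select_C(tr, cfg)
    model <- train_margin_classifier(tr, C_best, cfg$standardize)
    te_idx <- which(fold == f)
    fte <- decision_values(model, ds$features[te_idx, , drop = FALSE])
    # decision scales differ between fold models; store within-fold
    # fractional ranks (monotone per fold) so the assembled matrix has a
    # single comparable scale
    scores[te_idx] <- rank(fte) / length(fte)
    fold_auc[f] <- tryCatch(
      auc_from_scores(fte, ds$labels[te_idx] == 1L),
      error = function(e) NA_real_)  # fold without positives
  }
  w <- matrix(0, nrow(X), nrow(X), dimnames = list(rownames(X), rownames(X)))
  w[cbind(ds$pairs[, 1L], ds$pairs[, 2L])] <- scores
  w[cbind(ds$pairs[, 2L], ds$pairs[, 1L])] <- scores
  diag(w) <- min(scores)
  list(weights = weight_matrix(w, gene_ids = rownames(X)),
       mean_auc = mean(fold_auc, na.rm = TRUE),
       sd_auc = stats::sd(fold_auc[!is.na(fold_auc)]),
       fold_auc = fold_auc)
}

draw_folds <- function(n, k, seed) {
  withr::with_seed(seed + 50021L,
    sample(rep_len(seq_len(k), n)))
}

subset_pairs <- function(ds, keep) {
  structure(list(pairs = ds$pairs[keep, , drop = FALSE],
                 features = ds$features[keep, , drop = FALSE],
                 labels = ds$labels[keep],
                 gene_ids = ds$gene_ids,
                 n_samples_expr = ds$n_samples_expr),
            class = "pair_dataset")
}

# grid-search C on a single stratified 80/20 split of the training pairs,
# scored by AUC against the labels the training stage is allowed to see
select_C <- function(tr, cfg) {
  if (length(cfg$C_grid) == 1L) return(cfg$C_grid)
  idx_pos <- which(tr$labels == 1L)
  idx_neg <- which(tr$labels == -1L)
  withr::with_seed(cfg$seed + 61003L, {
    hold <- c(sample(idx_pos, max(1L, floor(0.2 * length(idx_pos)))),
              sample(idx_neg, max(1L, floor(0.2 * length(idx_neg)))))
  })
  inner_tr <- subset_pairs(tr, setdiff(seq_along(tr$labels), hold))
  if (length(unique(inner_tr$labels)) < 2L) return(1)
  best_C <- cfg$C_grid[1L]; best_auc <- -Inf
  for (C in cfg$C_grid) {
    m <- train_margin_classifier(inner_tr, C, cfg$standardize)
    a <- tryCatch(
      auc_from_scores(decision_values(m, tr$features[hold, , drop = FALSE]),
                      tr$labels[hold] == 1L),
      error = function(e) NA_real_)
    if (!is.na(a) && a > best_auc) { best_auc <- a; best_C <- C }
  }
  best_C
}
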