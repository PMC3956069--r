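#' Tree-ensemble importance weights
#'
#' Each gene in turn becomes the target of an Extra-Trees regression on
#' all other genes' profiles; a regulator's importance for the target is
#' its share of the total variance reduction over all split nodes,
#' normalized to sum to one per target (zero for a constant target).
#' The pair weight combines directions by the maximum. Deterministic
#' given `seed`.
#'
#' @param X an [expression_matrix()] with n >= 5 samples.
#' @param n_trees number of trees per target (default 100).
#' @param k_features candidate predictors per split; default
#'   `ceiling(sqrt(N - 1))`.
#' @param min_leaf minimum samples per leaf.
#' @param seed integer seed.
#' @return a [weight_matrix()], zero diagonal.
#' @export
genie <- function(X, n_trees = 100L, k_features = NULL, min_leaf = 2L,
                  seed = 1L) {
  X <- validate_expression_matrix(X)
  if (ncol(X) < 5L) stop("need at least 5 samples", call. = FALSE)
  M <- unclass_matrix(X)
  N <- nrow(M)
  if (is.null(k_features)) k_features <- ceiling(sqrt(N - 1L))
  imp <- matrix(0, N, N)  # imp[i, j] = importance of regulator i for target j
  for (j in seq_len(N)) {
    Xp <- t(M[-j, , drop = FALSE])   # samples x predictors
    y <- M[j, ]
    v <- .extratrees_importance(Xp, y, as.integer(n_trees),
                                as.integer(k_features), as.integer(min_leaf),
                                as.integer(seed) + j)
    imp[-j, j] <- v
  }
  w <- pmax(imp, t(imp))
  diag(w) <- 0
  weight_matrix(w, gene_ids = rownames(X))
}

sigmoid_fn <- function(u) 1 / (1 + exp(-u))

#' Sigmoid-regression weights
#'
#' Models each gene's (min-max scaled) profile as a soft-thresholded
#' linear combination of all other genes,
#' \eqn{\hat X_{ik} = \mathrm{sig}(\sum_{j \ne i} w_{ij} X_{jk})}, and
#' minimizes the squared residual by gradient descent with backtracking
#' step halving from a zero initialization (tolerance 1e-6 relative
#' objective change, at most `max_iter` iterations). Undirected weights
#' average the two orientations' magnitudes,
#' \eqn{\bar w_{ij} = (|w_{ij}| + |w_{ji}|)/2}.
#'
#' @param X an [expression_matrix()].
#' @param max_iter maximum gradient-descent iterations per gene.
#' @param tol relative objective-change tolerance.
#' @return a [weight_matrix()] with attribute `converged` (logical per
#'   gene); non-convergence returns the best iterate with a warning.
#' @export
sigmoid_fit <- function(X, max_iter = 5000L, tol = 1e-6) {
  X <- validate_expression_matrix(X)
  M <- unclass_matrix(X)
  rng <- apply(M, 1L, function(v) diff(range(v)))
  Ms <- (M - apply(M, 1L, min)) / ifelse(rng > 0, rng, 1)
  N <- nrow(Ms)
  W <- matrix(0, N, N)
  converged <- logical(N)
  for (i in seq_len(N)) {
    P <- Ms[-i, , drop = FALSE]      # predictors x samples
    y <- Ms[i, ]
    w <- numeric(N - 1L)
    u <- drop(crossprod(P, w))
    pred <- sigmoid_fn(u)
    obj <- sum((pred - y)^2)
    step <- 1
    for (it in seq_len(max_iter)) {
      grad <- drop(P %*% (2 * (pred - y) * pred * (1 - pred)))
      repeat {
        w_new <- w - step * grad
        u_new <- drop(crossprod(P, w_new))
        pred_new <- sigmoid_fn(u_new)
        obj_new <- sum((pred_new - y)^2)
        if (obj_new <= obj || step < 1e-12) break
        step <- step / 2
      }
      done <- abs(obj - obj_new) <= tol * max(obj, 1e-12)
      w <- w_new; pred <- pred_new; obj <- obj_new
      step <- step * 1.2
      if (done) { converged[i] <- TRUE; break }
    }
    W[i, -i] <- w
  }
  if (!all(converged))
    warning(sum(!converged), " gene fit(s) hit max_iter; best iterate kept",
            call. = FALSE)
  wbar <- (abs(W) + t(abs(W))) / 2
  diag(wbar) <- 0
  out <- weight_matrix(wbar, gene_ids = rownames(X))
  attr(out, "converged") <- converged
  out
}
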