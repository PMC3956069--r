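#' Area under the ROC curve of a predicted topology
#'
#' Scores a predicted weight matrix against an undirected gold standard
#' over the complete ranked list of unordered gene pairs (self-pairs and
#' edge direction excluded by construction). Computed via the
#' Mann-Whitney rank-sum equivalence with midranks, which equals the
#' trapezoidal area over the ranked list and is robust to tied weights.
#'
#' @param w a [weight_matrix()] (larger = more confident edge).
#' @param truth an [undirected_truth()] over the same genes.
#' @return AUC in `[0, 1]`; 0.5 is random, 1.0 perfect.
#' @export
auc <- function(w, truth) {
  stopifnot(is_weight_matrix(w), inherits(truth, "undirected_truth"))
  ids <- rownames(w)
  if (!setequal(ids, truth$gene_ids))
    stop("weight matrix and truth cover different gene sets", call. = FALSE)
  p <- upper_pairs(nrow(w))
  scores <- unclass_matrix(w)[p]
  labels <- pair_key(ids[p[, 1L]], ids[p[, 2L]]) %in%
    pair_key(truth$pairs[, 1L], truth$pairs[, 2L])
  auc_from_scores(scores, labels)
}

# midrank Mann-Whitney AUC from scores and logical labels
auc_from_scores <- function(scores, labels) {
  P <- sum(labels)
  M <- length(labels)
  if (P == 0L || P == M)
    stop("truth must contain both interacting and non-interacting pairs",
         call. = FALSE)
  r <- rank(scores)  # midranks
  (sum(r[labels]) - P * (P + 1) / 2) / (P * (M - P))
}

#' F1 score and Matthews correlation at a threshold
#'
#' Thresholds the predicted weights (predicted positive when weight >=
#' threshold), forms the confusion matrix over unordered pairs, and
#' returns the standard F1 and Matthews correlation coefficient; any
#' zero denominator yields 0 by convention.
#'
#' @inheritParams auc
#' @param threshold finite decision threshold on the weights.
#' @return named numeric vector `c(f1 = ..., mcc = ...)`.
#' @export
f1_mcc <- function(w, truth, threshold) {
  stopifnot(is_weight_matrix(w), inherits(truth, "undirected_truth"),
            is.finite(threshold))
  ids <- rownames(w)
  p <- upper_pairs(nrow(w))
  pred <- unclass_matrix(w)[p] >= threshold
  pos <- pair_key(ids[p[, 1L]], ids[p[, 2L]]) %in%
    pair_key(truth$pairs[, 1L], truth$pairs[, 2L])
  tp <- sum(pred & pos); fp <- sum(pred & !pos)
  fn <- sum(!pred & pos); tn <- sum(!pred & !pos)
  f1 <- if (2 * tp + fp + fn > 0) 2 * tp / (2 * tp + fp + fn) else 0
  den <- sqrt(tp + fp) * sqrt(tp + fn) * sqrt(tn + fp) * sqrt(tn + fn)
  mcc <- if (den > 0) (tp * tn - fp * fn) / den else 0
  c(f1 = f1, mcc = mcc)
}

# best F1 over the distinct observed weights, used when no threshold is
# supplied by the caller
best_f1_threshold <- function(w, truth) {
  thr <- sort(unique(unclass_matrix(w)[upper_pairs(nrow(w))]))
  f1s <- vapply(thr, function(t) f1_mcc(w, truth, t)[["f1"]], numeric(1L))
  thr[which.max(f1s)]
}

#' Benchmark configuration
#'
#' @param methods list of [method_spec()]s (or bare names) and/or
#'   [train_config()]s for supervised entries.
#' @param designs character vector of experiment kinds.
#' @param node_sizes,sample_sizes integer vectors of the sweep grid. For
#'   knockout/knockdown designs the sample number is coupled to the node
#'   number (one sample per gene) and `sample_sizes` is ignored.
#' @param repeats number of seeded repeats per cell.
#' @param simulator a [simulator_params()].
#' @param source_network optional [signed_network()] to extract
#'   subnetworks from; default: a 300-gene builtin generated from the
#'   configuration seed.
#' @param seed master seed; every cell's seed is derived from it.
#' @return list of class `benchmark_config`.
#' @export
benchmark_config <- function(methods, designs = "multifactorial",
                             node_sizes = 30L, sample_sizes = 30L,
                             repeats = 10L, simulator = simulator_params(),
                             source_network = NULL, seed = 1L) {
  methods <- lapply(methods, function(m)
    if (is.character(m)) method_spec(m) else m)
  ok <- vapply(methods, function(m)
    inherits(m, "method_spec") || inherits(m, "train_config"), logical(1L))
  stopifnot(all(ok), length(methods) > 0L, repeats >= 1L,
            length(designs) > 0L, length(node_sizes) > 0L,
            all(designs %in% c("knockout", "knockdown", "multifactorial")))
  structure(list(methods = methods, designs = designs,
                 node_sizes = as.integer(node_sizes),
                 sample_sizes = as.integer(sample_sizes),
                 repeats = as.integer(repeats), simulator = simulator,
                 source_network = source_network, seed = as.integer(seed)),
            class = "benchmark_config")
}

# deterministic 31-bit seed from the master seed and a cell label
cell_seed <- function(seed, ...) {
  label <- paste(c(seed, ...), collapse = "|")
  h <- 0
  for (v in utf8ToInt(label)) h <- (h * 131 + v) %% 2147483647
  as.integer(h)
}

method_label <- function(m) {
  if (inherits(m, "method_spec")) return(m$name)
  sprintf("svm_%s_%d", m$label_mode, round(100 * m$label_fraction))
}

#' Run a benchmark sweep
#'
#' For every (method, design, node size, sample size, repeat) cell:
#' extract a seeded subnetwork from the source network, simulate the
#' design, run the method and score AUC (plus F1/MCC at the maximum-F1
#' threshold) against the subnetwork's undirected truth. Per-cell seeds
#' derive deterministically from the configuration seed, so any cell can
#' be reproduced in isolation. A method failure on a cell is recorded
#' with its message and the sweep continues.
#'
#' @param cfg a [benchmark_config()].
#' @return data.frame of class `benchmark_result` with one row per cell
#'   and repeat: method, design, n_nodes, n_samples, repeat, auc, f1,
#'   mcc, error.
#' @export
run_benchmark <- function(cfg) {
  stopifnot(inherits(cfg, "benchmark_config"))
  source <- cfg$source_network
  if (is.null(source))
    source <- generate_source_network(300L, mean_degree = 3,
                                      seed = cell_seed(cfg$seed, "source"))
  rows <- list()
  for (design in cfg$designs) {
    for (nn in cfg$node_sizes) {
      samp_sizes <- if (design == "multifactorial") cfg$sample_sizes else nn
      for (ns in samp_sizes) {
        for (rep_i in seq_len(cfg$repeats)) {
          sseed <- cell_seed(cfg$seed, design, nn, ns, rep_i)
          sub <- sample_subnetwork(source, nn, seed = sseed)
          params <- cfg$simulator
          params$seed <- sseed
          sim <- simulate_experiments(sub, experiment_design(design, ns), params)
          truth <- to_undirected_truth(sub)
          for (m in cfg$methods) {
            lbl <- method_label(m)
            res <- tryCatch({
              if (inherits(m, "method_spec")) {
                mm <- m
                if (mm$name == "genie" && is.null(mm$params$seed))
                  mm$params$seed <- cell_seed(sseed, "genie")
                w <- infer(mm, sim$expr)
              } else {
                mm <- m
                mm$seed <- cell_seed(sseed, "cv")
                cv <- crossval_score(sim$expr, truth, mm)
              }
              if (inherits(m, "method_spec")) {
                a <- auc(w, truth)
              } else {
                # the cross-validation protocol: accuracy is the mean of
                # the per-fold test AUCs
                a <- cv$mean_auc
                w <- cv$weights
              }
              fm <- f1_mcc(w, truth, best_f1_threshold(w, truth))
              list(auc = a, f1 = fm[["f1"]], mcc = fm[["mcc"]],
                   error = NA_character_)
            }, error = function(e)
              list(auc = NA_real_, f1 = NA_real_, mcc = NA_real_,
                   error = conditionMessage(e)))
            rows[[length(rows) + 1L]] <- data.frame(
              method = lbl, design = design, n_nodes = nn, n_samples = ns,
              rep = rep_i, auc = res$auc, f1 = res$f1, mcc = res$mcc,
              error = res$error, stringsAsFactors = FALSE)
          }
        }
      }
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("benchmark_result", class(out))
  out
}

#' Summarize and rank methods in a benchmark result
#'
#' Mean and sd of AUC per method within each group, plus the rank by
#' mean AUC (1 = best; ties broken by method name for stability).
#'
#' @param res a [run_benchmark()] result.
#' @param group_by character vector of grouping columns (default
#'   `"design"`).
#' @return data.frame with group columns, method, mean_auc, sd_auc, n,
#'   rank.
#' @export
rank_methods <- function(res, group_by = "design") {
  stopifnot(nrow(res) > 0L, all(group_by %in% names(res)))
  res <- res[!is.na(res$auc), , drop = FALSE]
  key <- interaction(res[group_by], drop = TRUE)
  out <- do.call(rbind, lapply(split(res, key), function(g) {
    agg <- do.call(rbind, lapply(split(g, g$method), function(m)
      data.frame(m[1L, group_by, drop = FALSE], method = m$method[1L],
                 mean_auc = mean(m$auc), sd_auc = stats::sd(m$auc),
                 n = nrow(m), stringsAsFactors = FALSE)))
    agg <- agg[order(-agg$mean_auc, agg$method), , drop = FALSE]
    agg$rank <- seq_len(nrow(agg))
    agg
  }))
  rownames(out) <- NULL
  out
}
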