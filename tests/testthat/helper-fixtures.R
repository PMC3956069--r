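# small deterministic fixtures shared across test files

expr3x2 <- function() {
  expression_matrix(matrix(c(1, 2, 3, 4, 5, 6), 3, 2, byrow = TRUE),
                    gene_ids = c("A", "B", "C"),
                    sample_ids = c("s1", "s2"))
}

seeded_expr <- function(n_genes, n_samples, seed = 1) {
  withr::with_seed(seed, {
    expression_matrix(matrix(stats::runif(n_genes * n_samples),
                             n_genes, n_samples))
  })
}

# straight-line and hub-and-spokes activating networks on n genes
chain_network <- function(n = 10) {
  ids <- sprintf("g%02d", seq_len(n))
  signed_network(ids, data.frame(regulator = ids[seq_len(n - 1)],
                                 target = ids[2:n], sign = 1L))
}

star_network <- function(n = 10) {
  ids <- sprintf("g%02d", seq_len(n))
  signed_network(ids, data.frame(regulator = ids[1], target = ids[2:n],
                                 sign = 1L))
}

# weak connectivity of a signed network, by undirected flood fill
is_weakly_connected <- function(net) {
  n <- length(net$gene_ids)
  if (n == 1L) return(TRUE)
  idx <- stats::setNames(seq_len(n), net$gene_ids)
  reg <- idx[net$edges$regulator]
  tgt <- idx[net$edges$target]
  seen <- logical(n)
  frontier <- 1L
  seen[1L] <- TRUE
  while (length(frontier)) {
    nb <- unique(c(tgt[reg %in% frontier], reg[tgt %in% frontier]))
    frontier <- nb[!seen[nb]]
    seen[frontier] <- TRUE
  }
  all(seen)
}

# brute-force AUC: concordant positive/negative score pairs (+0.5 ties)
auc_bruteforce <- function(scores, labels) {
  pos <- scores[labels]
  neg <- scores[!labels]
  tot <- 0
  for (p in pos) for (q in neg)
    tot <- tot + (p > q) + 0.5 * (p == q)
  tot / (length(pos) * length(neg))
}

label_pairs <- function(w, truth) {
  ids <- rownames(w)
  p <- grnbench:::upper_pairs(nrow(w))
  list(scores = grnbench:::unclass_matrix(w)[p],
       labels = grnbench:::pair_key(ids[p[, 1]], ids[p[, 2]]) %in%
         grnbench:::pair_key(truth$pairs[, 1], truth$pairs[, 2]))
}
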