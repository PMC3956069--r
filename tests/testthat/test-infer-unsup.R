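test_that("correlation weights match hand-evaluated coefficients", {
  X <- expression_matrix(rbind(A = c(1, 2, 3), B = c(1, 3, 2)))
  expect_equal(correlation_weights(X, "pearson")["A", "B"], 0.5)
  expect_equal(correlation_weights(X, "kendall")["A", "B"], 1 / 3)

  # copies and sign flips both give weight 1 under every flavour
  Y <- expression_matrix(rbind(A = c(0.3, 1.4, 2.2, 0.9),
                               B = c(0.3, 1.4, 2.2, 0.9),
                               C = -c(0.3, 1.4, 2.2, 0.9)))
  for (fl in c("pearson", "spearman", "kendall")) {
    w <- correlation_weights(Y, fl)
    expect_equal(w["A", "B"], 1)
    expect_equal(w["A", "C"], 1)
  }
  expect_error(correlation_weights(expr3x2(), "pearson"), "3 samples")
})

test_that("constant profiles score zero instead of erroring", {
  X <- expression_matrix(rbind(A = c(1, 2, 3, 4), B = c(2, 2, 2, 2),
                               C = c(4, 3, 2, 1)))
  for (fl in c("pearson", "spearman", "kendall"))
    expect_identical(correlation_weights(X, fl)["A", "B"], 0)
  expect_identical(spearman_c(X)["A", "B"], 0)
})

test_that("spearman is exactly pearson on within-gene ranks", {
  X <- seeded_expr(6, 9, seed = 31)  # continuous draws: tie-free
  ranks <- t(apply(unclass(X), 1, rank))
  expect_identical(
    unclass(correlation_weights(X, "spearman")),
    unclass(correlation_weights(
      expression_matrix(ranks, rownames(X), colnames(X)), "pearson")))
})

test_that("kendall agrees with O(n^2) concordance counting, ties included", {
  tau_oracle <- function(x, y) {
    n <- length(x); s <- 0
    for (k in seq_len(n - 1)) for (l in (k + 1):n)
      s <- s + sign(x[k] - x[l]) * sign(y[k] - y[l])
    unname(s / (n * (n - 1) / 2))
  }
  for (seed in 1:6) {
    n <- sample(4:12, 1)
    X <- withr::with_seed(seed, expression_matrix(
      matrix(sample(0:4, 3 * n, replace = TRUE), 3, n)))  # heavy ties
    w <- correlation_weights(X, "kendall")
    M <- unclass(X)
    for (i in 1:2) for (j in (i + 1):3)
      expect_equal(w[i, j], abs(tau_oracle(M[i, ], M[j, ])), tolerance = 1e-12)
  }
})

test_that("spearman_c matches a two-loop oracle and the 2-gene closed form", {
  X <- seeded_expr(5, 8, seed = 7)
  w <- spearman_c(X)
  rho <- stats::cor(apply(unclass(X), 1, rank))
  N <- nrow(rho)
  for (i in 1:(N - 1)) for (j in (i + 1):N) {
    mi <- mean(rho[i, setdiff(1:N, i)])
    mj <- mean(rho[j, setdiff(1:N, j)])
    expect_equal(w[i, j], max(abs(rho[i, j] * mi), abs(rho[i, j] * mj)),
                 tolerance = 1e-12)
  }

  X2 <- seeded_expr(2, 7, seed = 8)
  rho12 <- stats::cor(rank(unclass(X2)[1, ]), rank(unclass(X2)[2, ]))
  expect_equal(spearman_c(X2)[1, 2], rho12^2, tolerance = 1e-12)
})

test_that("softpower is the stated elementwise transform and AUC-invariant", {
  w <- weight_matrix(matrix(c(0, .5, .5, 0), 2, 2))
  expect_equal(softpower(w, 1), w)
  expect_equal(softpower(w, 2)[1, 2], 0.25)
  expect_error(softpower(w, 0), "positive")
  expect_error(softpower(w, -2), "positive")

  for (seed in 1:5) {
    wr <- withr::with_seed(seed, {
      m <- matrix(stats::runif(100), 10, 10)
      weight_matrix((m + t(m)) / 2)
    })
    truth <- withr::with_seed(seed + 100, {
      p <- grnbench:::upper_pairs(10)
      pick <- sample(nrow(p), 12)
      undirected_truth(rownames(wr), cbind(rownames(wr)[p[pick, 1]],
                                           rownames(wr)[p[pick, 2]]))
    })
    base <- auc(wr, truth)
    for (beta in c(0.5, 2, 6))
      expect_identical(auc(softpower(wr, beta), truth), base)
  }
})

test_that("equal-width binning follows the interval rules", {
  X <- expression_matrix(rbind(A = c(0, 0.5, 1), B = c(3, 3, 3)))
  D <- discretize_equal_width(X, 2)
  expect_identical(unname(D[1, ]), c(0L, 1L, 1L))  # boundary goes up
  expect_identical(unname(D[2, ]), c(0L, 0L, 0L))  # constant gene

  # evenly spaced distinct values with bins = n: identity up to labels
  X2 <- expression_matrix(rbind(A = c(10, 20, 30, 40, 50), B = 1:5))
  D2 <- discretize_equal_width(X2, 5)
  expect_identical(unname(D2[1, ]), 0:4)
  expect_identical(unname(D2[2, ]), 0:4)
})

test_that("mutual information matches closed forms", {
  D <- rbind(A = c(0L, 0L, 1L, 1L), B = c(1L, 1L, 0L, 0L),
             C = c(0L, 1L, 0L, 1L))
  mi <- mutual_info_matrix(D)
  expect_equal(mi["A", "B"], log(2), tolerance = 1e-12)  # exact relabeling
  expect_equal(mi["A", "C"], 0, tolerance = 1e-12)       # independent
  expect_equal(mi["A", "A"], log(2), tolerance = 1e-12)  # I(X;X) = H(X)
  expect_true(isSymmetric(mi))
})

test_that("mutual information is symmetric, nonnegative, diag = entropy", {
  for (seed in 1:5) {
    D <- withr::with_seed(seed,
      matrix(sample(0:3, 6 * 20, replace = TRUE), 6, 20))
    mi <- mutual_info_matrix(D)
    expect_true(isSymmetric(mi))
    expect_true(all(mi >= -1e-12))
    H <- apply(D, 1, function(d) {
      p <- table(d) / length(d)
      -sum(p * log(p))
    })
    expect_equal(unname(diag(mi)), unname(H), tolerance = 1e-12)
  }
})

test_that("relevance network reads weights off the MI matrix", {
  X <- expression_matrix(rbind(A = c(1, 1, 5, 5), B = c(5, 5, 1, 1),
                               C = c(1, 5, 1, 5)))
  w <- relevance_network(X, bins = 2)
  expect_equal(w["A", "B"], log(2), tolerance = 1e-12)
  expect_equal(w["A", "C"], 0, tolerance = 1e-12)
  expect_identical(unname(diag(unclass(w))), rep(0, 3))
})

test_that("clr background-corrects the MI matrix as specified", {
  expect_true(all(grnbench:::clr_from_mi(matrix(0.4, 4, 4)) == 0))

  mi <- rbind(c(NA, 0.9, 0.1), c(0.9, NA, 0.1), c(0.1, 0.1, NA))
  diag(mi) <- 1
  w <- grnbench:::clr_from_mi(mi)
  # hand arithmetic: z_1(2) = (0.9 - 0.5)/sd(c(0.9, 0.1)) = 1/sqrt(2)
  expect_equal(w[1, 2], 1, tolerance = 1e-12)
  expect_identical(w[1, 3], 0)  # negative z clipped; row-3 sd is zero
  expect_true(isSymmetric(w))
  expect_equal(max(w), w[1, 2])  # unique maximum

  X <- seeded_expr(6, 12, seed = 5)
  expect_true(isSymmetric(unclass(clr(X))))
})

test_that("aracne prunes exactly the DPI-violating triangle minima", {
  # N = 2: no triples, identical to the relevance network
  X2 <- seeded_expr(2, 8, seed = 2)
  expect_equal(unclass(aracne(X2, bins = 3)),
               unclass(relevance_network(X2, bins = 3)))

  mi <- rbind(c(0, 0.9, 0.8), c(0.9, 0, 0.1), c(0.8, 0.1, 0))
  w <- grnbench:::aracne_from_mi(mi, eps = 0)
  expect_identical(w[2, 3], 0)           # strict minimum pruned
  expect_identical(w[1, 2], 0.9)
  expect_identical(w[1, 3], 0.8)

  # eps above the largest MI: nothing pruned
  expect_equal(grnbench:::aracne_from_mi(mi, eps = 1), mi)
})

test_that("aracne agrees with brute-force triple enumeration", {
  for (seed in 1:4) {
    X <- seeded_expr(8, 15, seed = seed)
    eps <- 0.05
    w <- aracne(X, bins = 4, eps = eps)
    mi <- mutual_info_matrix(discretize_equal_width(X, 4))
    mi[mi < 0] <- 0
    diag(mi) <- 0
    pruned <- matrix(FALSE, 8, 8)
    for (i in 1:6) for (j in (i + 1):7) for (k in (j + 1):8) {
      v <- c(mi[i, j], mi[i, k], mi[j, k])
      lo <- which.min(v)
      if (v[lo] < min(v[-lo]) - eps) {
        pr <- rbind(c(i, j), c(i, k), c(j, k))[lo, , drop = FALSE]
        pruned[pr] <- TRUE
        pruned[pr[, 2:1, drop = FALSE]] <- TRUE
      }
    }
    expect_equal(unname(unclass(w)), unname(mi * !pruned))
    # support is a subset of the relevance network's support
    rn_w <- relevance_network(X, bins = 4)
    expect_true(all(unclass(w)[unclass(rn_w) == 0] == 0))
  }
})

test_that("pcit partial correlations and pruning behave as specified", {
  tp <- grnbench:::trio_partials(0.5, 0.5, 0.5)
  expect_equal(tp$p_ij, 1 / 3, tolerance = 1e-12)

  # pairwise-uncorrelated third gene: partial equals the raw correlation
  tp2 <- grnbench:::trio_partials(0.42, 0, 0)
  expect_equal(tp2$p_ij, 0.42, tolerance = 1e-12)

  # chain g1 -> g2 -> g3: r13 ~ r12 * r23 so the 1-3 partial collapses
  # and the 1-3 edge is pruned while the direct links survive
  for (seed in 11:15) {
    X <- withr::with_seed(seed, {
      x1 <- stats::rnorm(40)
      x2 <- x1 + stats::rnorm(40, 0, 0.7)
      x3 <- x2 + stats::rnorm(40, 0, 0.7)
      expression_matrix(rbind(g1 = x1, g2 = x2, g3 = x3))
    })
    w <- pcit(X)
    expect_identical(w["g1", "g3"], 0)
    expect_gt(w["g1", "g2"], 0)
    expect_gt(w["g2", "g3"], 0)
  }
})

test_that("mrmr forward selection follows relevance minus mean redundancy", {
  X <- seeded_expr(5, 16, seed = 13)
  mi <- mutual_info_matrix(discretize_equal_width(X, 4))
  sel <- mrmr_select(rownames(X)[1], X, bins = 4)
  # independent two-loop oracle over the same MI matrix
  cand <- 2:5
  chosen <- integer(0)
  for (s in seq_len(nrow(sel))) {
    best <- -Inf; who <- NA
    for (i in setdiff(cand, chosen)) {
      red <- if (length(chosen)) mean(mi[i, chosen]) else 0
      sc <- mi[i, 1] - red
      if (sc > best) { best <- sc; who <- i }
    }
    expect_identical(sel$gene[s], rownames(X)[who])
    expect_equal(sel$score[s], best, tolerance = 1e-12)
    chosen <- c(chosen, who)
  }

  # first pick is pure relevance
  expect_identical(sel$gene[1], rownames(X)[1 + which.max(mi[2:5, 1])])
})

test_that("a duplicated candidate is redundant and selected last", {
  X <- withr::with_seed(17, {
    t_ <- stats::runif(12)
    a <- t_ + stats::rnorm(12, 0, 0.1)
    expression_matrix(rbind(T = t_, A = a, A2 = a))
  })
  sel <- mrmr_select("T", X, bins = 3)
  # the copy is picked after the original, scored relevance minus its
  # own entropy, which can never be positive
  expect_identical(sel$gene[2], "A2")
  expect_lte(sel$score[2], 0)
  mi <- mutual_info_matrix(discretize_equal_width(X, 3))
  expect_equal(sel$score[2], mi["A2", "T"] - mi["A2", "A2"],
               tolerance = 1e-12)
})

test_that("mrnet combines directional scores symmetrically", {
  X2 <- seeded_expr(2, 10, seed = 19)
  mi <- mutual_info_matrix(discretize_equal_width(X2, 4))
  expect_equal(mrnet(X2, bins = 4)[1, 2], mi[1, 2], tolerance = 1e-12)

  X <- withr::with_seed(23, {
    hub <- stats::runif(20)
    expression_matrix(rbind(H = hub,
                            L1 = hub + stats::rnorm(20, 0, 0.15),
                            L2 = hub + stats::rnorm(20, 0, 0.15),
                            L3 = hub + stats::rnorm(20, 0, 0.15)))
  })
  w <- mrnet(X)
  expect_true(isSymmetric(unclass(w)))
  hub_leaf <- c(w["H", "L1"], w["H", "L2"], w["H", "L3"])
  leaf_leaf <- c(w["L1", "L2"], w["L1", "L3"], w["L2", "L3"])
  expect_gt(min(hub_leaf), max(leaf_leaf))
})

test_that("mrnet_b backward/replacement selection is near-optimal", {
  X2 <- seeded_expr(2, 10, seed = 19)
  expect_equal(unclass(mrnet_b(X2, bins = 4)), unclass(mrnet(X2, bins = 4)))

  top2 <- 0
  beats_forward <- 0
  for (s in 1:50) {
    X <- withr::with_seed(s, {
      M <- matrix(stats::rnorm(6 * 12), 6, 12)
      M[2, ] <- M[1, ] * 0.8 + stats::rnorm(12, 0, 0.4)
      M[3, ] <- M[1, ] * 0.5 + stats::rnorm(12, 0, 0.6)
      expression_matrix(M)
    })
    mi <- mutual_info_matrix(discretize_equal_width(X, 4))
    rel <- mi[2:6, 1]
    mi_cc <- mi[2:6, 2:6]
    sel <- grnbench:::mrnet_b_select(rel, mi_cc)
    sc <- grnbench:::mrnet_b_set_score(sel, rel, mi_cc)
    all_sc <- unlist(lapply(1:5, function(m) {
      apply(utils::combn(5, m), 2, grnbench:::mrnet_b_set_score, rel, mi_cc)
    }))
    all_sc <- sort(unique(round(all_sc, 10)), decreasing = TRUE)
    if (round(sc, 10) >= all_sc[min(2, length(all_sc))]) top2 <- top2 + 1
    fwd <- mrmr_select(rownames(X)[1], X, mi = mi)
    fwd_set <- match(fwd$gene[fwd$score > 0], rownames(X)) - 1
    if (sc >= grnbench:::mrnet_b_set_score(fwd_set, rel, mi_cc) - 1e-12)
      beats_forward <- beats_forward + 1
  }
  expect_gte(top2, 45)           # within top-2 subsets on >= 90% of draws
  expect_gte(beats_forward, 45)  # replacement at least matches forward
})

test_that("tree-ensemble importance recovers a planted regulator", {
  X <- withr::with_seed(29, {
    M <- matrix(stats::runif(10 * 30), 10, 30)
    M[1, ] <- M[2, ]  # gene 1 is an exact copy of gene 2
    expression_matrix(M)
  })
  w <- genie(X, n_trees = 100, seed = 4)
  expect_identical(names(which.max(w["G1", -1])), "G2")
  expect_true(isSymmetric(unclass(w)))
  expect_identical(unclass(w), unclass(genie(X, n_trees = 100, seed = 4)))

  # per-target normalized importances sum to at most one
  imp <- grnbench:::.extratrees_importance(
    t(unclass(X)[-1, ]), unclass(X)[1, ], 50L, 3L, 2L, 9L)
  expect_lte(sum(imp), 1 + 1e-12)
  # constant target: all-zero importances
  imp0 <- grnbench:::.extratrees_importance(
    t(unclass(X)[-1, ]), rep(1, 30), 50L, 3L, 2L, 9L)
  expect_identical(imp0, rep(0, 9))
})

test_that("sigmoid regression finds a planted soft-threshold regulator", {
  X <- withr::with_seed(5, {
    x2 <- c(0, 1, stats::runif(14))
    noise <- matrix(stats::runif(4 * 16), 4)
    expression_matrix(rbind(G1 = 1 / (1 + exp(-2 * x2)), G2 = x2,
                            N1 = noise[1, ], N2 = noise[2, ],
                            N3 = noise[3, ], N4 = noise[4, ]))
  })
  w <- suppressWarnings(sigmoid_fit(X))
  expect_identical(names(which.max(w["G1", -1])), "G2")
  expect_true(isSymmetric(unclass(w)))
  expect_true(all(unclass(w) >= 0))
})

test_that("mass distance counts bounded probability mass", {
  # 3 genes x 2 samples, each column a permutation of {1, 2, 3}
  X <- expression_matrix(rbind(A = c(1, 2), B = c(2, 3), C = c(3, 1)))
  md <- mass_distance_values(X)
  # exhaustive counting oracle over the columns
  M <- unclass(X)
  for (i in 1:2) for (j in (i + 1):3) {
    ref <- 1
    for (k in 1:2) {
      lo <- min(M[i, k], M[j, k]); hi <- max(M[i, k], M[j, k])
      ref <- ref * mean(M[, k] >= lo & M[, k] <= hi)
    }
    expect_equal(md[i, j], ref, tolerance = 1e-12)
  }
  # identical profiles: product of the shared values' frequencies
  # (column 1 holds {1, 1, 3} so freq(1) = 2/3; column 2 {2, 2, 1})
  X2 <- expression_matrix(rbind(A = c(1, 2), B = c(1, 2), C = c(3, 1)))
  expect_equal(mass_distance_values(X2)["A", "B"], (2 / 3) * (2 / 3),
               tolerance = 1e-12)
  # widening the interval never decreases the mass: the A-C interval
  # contains the A-B interval in every coordinate
  X3 <- expression_matrix(rbind(A = c(2, 2), B = c(3, 3), C = c(4, 4)))
  md3 <- mass_distance_values(X3)
  expect_gte(md3["A", "C"], md3["A", "B"])
  w <- mass_distance(X)
  expect_true(isSymmetric(unclass(w)))
})

test_that("mutual rank is the geometric mean of directional ranks", {
  X <- seeded_expr(6, 10, seed = 37)
  w <- mutual_rank(X)
  a <- abs(stats::cor(t(unclass(X))))
  rk <- matrix(0, 6, 6)
  for (i in 1:6) rk[i, -i] <- rank(-a[i, -i])
  for (i in 1:5) for (j in (i + 1):6)
    expect_equal(w[i, j], 1 / sqrt(rk[i, j] * rk[j, i]), tolerance = 1e-12)

  # mutual top correlates: MR = 1, maximal weight
  top <- which(a - diag(6) == max(a - diag(6)), arr.ind = TRUE)[1, ]
  if (rk[top[1], top[2]] == 1 && rk[top[2], top[1]] == 1)
    expect_equal(w[top[1], top[2]], 1)
  expect_equal(sqrt(2 * 8), 4)  # the rank pair (2, 8) maps to MR 4
})

test_that("euclid normalizes to median deviation and negates distance", {
  expect_identical(unname(grnbench:::euclid_normalize(
    expression_matrix(rbind(A = c(1, 2, 9), B = c(0, 0, 1))))[1, ]),
    c(1, 0, 7))

  X <- expression_matrix(rbind(A = c(1, 2, 9), B = c(1, 2, 9),
                               C = c(5, 2, 4)))
  w <- euclid(X)
  expect_identical(w["A", "B"], 0)             # copies: top weight
  expect_true(all(w["A", "C"] < 0))
  # median reflection with equal medians: normalized profiles coincide
  a <- c(1, 2, 3, 4, 7)
  refl <- 2 * stats::median(a) - a
  X2 <- expression_matrix(rbind(A = a, B = refl, C = c(0, 1, 0, 1, 0)))
  expect_equal(euclid(X2)["A", "B"], 0, tolerance = 1e-12)
})

test_that("generalized z-score matches direct arithmetic on a 3x3 matrix", {
  X <- expression_matrix(rbind(g1 = c(0, 5, 5), g2 = c(9, 1, 8),
                               g3 = c(4, 4, 0)))
  w <- zscore_generalized(X)
  M <- unclass(X)
  kstar <- c(1, 2, 3)  # argmin of each row
  z <- matrix(0, 3, 3)
  for (i in 1:3) for (j in 1:3)
    z[i, j] <- abs(M[j, kstar[i]] - mean(M[j, ])) / stats::sd(M[j, ])
  ref <- pmax(z, t(z)); diag(ref) <- 0
  expect_equal(unname(unclass(w)), ref, tolerance = 1e-12)
  expect_equal(w["g1", "g2"], abs(9 - 6) / stats::sd(c(9, 1, 8)),
               tolerance = 1e-12)

  # a zero-variance profile contributes z = 0 as the deviating gene;
  # the pair weight falls back to the other orientation
  X2 <- expression_matrix(rbind(g1 = c(0, 5, 5), g2 = c(2, 2, 2),
                               g3 = c(4, 4, 0)))
  w2 <- zscore_generalized(X2)
  M2 <- unclass(X2)
  z2 <- matrix(0, 3, 3)
  for (i in 1:3) for (j in 1:3) {
    s <- stats::sd(M2[j, ])
    z2[i, j] <- if (s > 0)
      abs(M2[j, which.min(M2[i, ])] - mean(M2[j, ])) / s else 0
  }
  ref2 <- pmax(z2, t(z2)); diag(ref2) <- 0
  expect_equal(unname(unclass(w2)), ref2, tolerance = 1e-12)
})

test_that("the dispatcher routes, injects defaults and rejects unknowns", {
  X <- seeded_expr(6, 10, seed = 41)
  expect_identical(unclass(infer("pearson", X)),
                   unclass(correlation_weights(X, "pearson")))
  expect_identical(unclass(infer(method_spec("aracne"), X)),
                   unclass(aracne(X, eps = 0.1)))
  expect_error(method_spec("bayes_net"), "roster")
  expect_error(infer("mic", X), "roster")
})

test_that("every roster method returns a valid weight matrix on 10x10 data", {
  X <- seeded_expr(10, 10, seed = 43)
  for (m in method_roster()) {
    w <- infer(m, X)
    expect_s3_class(w, "weight_matrix")
    expect_true(all(is.finite(w)), info = m)
    expect_true(isSymmetric(unclass(w)), info = m)
    expect_identical(rownames(w), rownames(X))
  }
})

test_that("similarity-only methods prefer the profile mimic over true regulators", {
  ex <- mixed_regulation_example()
  similarity_roster <- c("pearson", "spearman", "kendall", "spearman_c",
                         "rn", "clr", "aracne", "pcit", "mrnet", "mrnet_b",
                         "md", "mr", "euclid")
  for (m in similarity_roster) {
    w <- infer(m, ex$expr)
    expect_gt(w["C", "D"], w["A", "D"], label = paste0(m, " w[C,D]"))
    expect_gt(w["C", "D"], w["B", "D"], label = paste0(m, " w[C,D]"))
  }
})
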