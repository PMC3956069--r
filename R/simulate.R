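#' Simulator parameters
#'
#' Controls for the steady-state expression simulator. The kinetic model
#' is a saturating-response fixed point
#' \deqn{x_i = s_i \cdot g(b_i + \sum_j k_{ji}\,\mathrm{sign}_{ji}\,x_j)}
#' where `g(u) = u_max * u / (K + u)` for `u > 0` and a small leak
#' otherwise, `b_i` the basal input, `k_{ji}` sampled interaction
#' strengths and `s_i` a clamp multiplier (1 unless perturbed).
#'
#' @param basal basal transcription input (> 0); default 0.1 puts
#'   unregulated genes at the low end of the dynamic range.
#' @param strength_range interval of positive reals from which
#'   interaction-strength magnitudes are drawn uniformly.
#' @param steepness multiplier on the regulation input (slope of the
#'   response); > 0.
#' @param u_max saturation ceiling of the response function.
#' @param K half-saturation constant.
#' @param noise_sd sd (log scale) of multiplicative lognormal measurement
#'   noise; >= 0.
#' @param perturb_fraction fraction of genes perturbed per multifactorial
#'   sample, in (0, 1].
#' @param perturb_sd sd of the normal basal-input perturbation.
#' @param max_iter,tol fixed-point solver controls.
#' @param seed integer seed; all simulator randomness flows from it.
#' @return list of class `simulator_params`.
#' @export
simulator_params <- function(basal = 0.1, strength_range = c(0.5, 2),
                             steepness = 1, u_max = 1, K = 1,
                             noise_sd = 0.05, perturb_fraction = 0.2,
                             perturb_sd = 0.3, max_iter = 20000L,
                             tol = 1e-9, seed = 1L) {
  stopifnot(basal > 0, length(strength_range) == 2L,
            all(strength_range > 0), strength_range[1L] <= strength_range[2L],
            steepness > 0, u_max > 0, K > 0, noise_sd >= 0,
            perturb_fraction > 0, perturb_fraction <= 1,
            perturb_sd >= 0, max_iter >= 1L, tol > 0)
  structure(list(basal = basal, strength_range = strength_range,
                 steepness = steepness, u_max = u_max, K = K,
                 noise_sd = noise_sd, perturb_fraction = perturb_fraction,
                 perturb_sd = perturb_sd, max_iter = as.integer(max_iter),
                 tol = tol, seed = as.integer(seed)),
            class = "simulator_params")
}

#' Experiment design
#'
#' @param kind one of `"knockout"` (each gene in turn clamped to zero),
#'   `"knockdown"` (each gene in turn clamped to half its unperturbed
#'   steady level) or `"multifactorial"` (a small random subset of basal
#'   inputs perturbed per sample).
#' @param n_samples number of samples (columns). For knockout/knockdown
#'   designs it must not exceed the gene count: genes are perturbed in
#'   row order, one per sample.
#' @return list of class `experiment_design`.
#' @export
experiment_design <- function(kind = c("knockout", "knockdown", "multifactorial"),
                              n_samples) {
  kind <- match.arg(kind)
  n_samples <- as.integer(n_samples)
  stopifnot(n_samples >= 1L)
  structure(list(kind = kind, n_samples = n_samples),
            class = "experiment_design")
}

#' Mixed-regulation counterexample for similarity-based inference
#'
#' Constructs the classic failure mode of similarity-only network
#' scores: gene A inhibits gene D, gene B activates gene D with equal
#' strength, so D's profile is the balanced mix `D = (B - A)/2 + const`;
#' gene C does not regulate D but happens to match the mix exactly.
#' Every method that scores pairs by profile similarity alone then ranks
#' the non-edge pair C-D above the true regulatory pairs A-D and B-D.
#'
#' @param n number of samples (default 12).
#' @return list with `expr` (4-gene [expression_matrix()], genes A, B,
#'   C, D) and `truth` (the true pairs A-D and B-D as an
#'   [undirected_truth()]).
#' @export
mixed_regulation_example <- function(n = 12L) {
  stopifnot(n >= 6L)
  a <- withr::with_seed(4242L, stats::runif(n, 0, 1))
  b <- withr::with_seed(2424L, stats::runif(n, 0, 1))
  d <- (b - a) / 2 + 0.5
  vals <- rbind(A = a, B = b, C = d, D = d)
  list(expr = expression_matrix(vals, gene_ids = c("A", "B", "C", "D"),
                                sample_ids = sprintf("s%02d", seq_len(n))),
       truth = undirected_truth(c("A", "B", "C", "D"),
                                rbind(c("A", "D"), c("B", "D"))))
}

# saturating response with a small continuous leak: negative inputs
# clip to zero and a shift epsilon keeps g(u <= 0) at a positive floor
# (inhibited genes stay nonzero so multiplicative log-noise is defined);
# continuity matters — a jump at u = 0 can leave the kinetic map without
# a fixed point under feedback
sat_leak <- 1e-3
sat_response <- function(u, params) {
  eps <- sat_leak * params$K / max(params$u_max - sat_leak, sat_leak)
  v <- pmax(u, 0) + eps
  params$u_max * v / (params$K + v)
}
sat_response_deriv <- function(u, params) {
  eps <- sat_leak * params$K / max(params$u_max - sat_leak, sat_leak)
  v <- pmax(u, 0) + eps
  ifelse(u > 0, params$u_max * params$K / (params$K + v)^2, 0)
}

#' Generate a scale-free-leaning source network
#'
#' Stand-in for a curated source network: preferential-attachment growth
#' (each new node sends a regulatory edge to targets chosen with
#' probability proportional to degree + 1, plus occasional extra edges to
#' reach the requested mean degree), giving a weakly connected directed
#' graph with a heavier-tailed degree distribution than an
#' Erdos-Renyi graph of equal density. Signs are drawn i.i.d. with
#' probability `activating_fraction` of being activating.
#'
#' @param n_genes number of genes (>= 2).
#' @param mean_degree target mean total degree (edges ~ n_genes *
#'   mean_degree / 2); must be < n_genes.
#' @param activating_fraction probability that an edge is activating.
#' @param seed integer seed; the result is deterministic given it.
#' @return a [signed_network()].
#' @export
generate_source_network <- function(n_genes, mean_degree = 3,
                                    activating_fraction = 0.7, seed = 1L) {
  n_genes <- as.integer(n_genes)
  stopifnot(n_genes >= 2L, activating_fraction >= 0, activating_fraction <= 1)
  if (mean_degree >= n_genes)
    stop("mean_degree must be smaller than n_genes", call. = FALSE)
  withr::with_seed(as.integer(seed), {
    n_edges <- max(n_genes - 1L, round(n_genes * mean_degree / 2))
    ids <- sprintf("G%03d", seq_len(n_genes))
    reg <- integer(n_edges)
    tgt <- integer(n_edges)
    deg <- rep(0L, n_genes)
    # growth phase: node i attaches to an earlier node by degree
    for (i in 2L:n_genes) {
      j <- sample.int(i - 1L, 1L, prob = deg[seq_len(i - 1L)] + 1)
      reg[i - 1L] <- i; tgt[i - 1L] <- j
      deg[i] <- deg[i] + 1L; deg[j] <- deg[j] + 1L
    }
    # densification phase: extra edges, endpoints degree-biased
    k <- n_genes  # next free slot is n_genes (n_genes - 1 edges used)
    seen <- new.env(hash = TRUE, parent = emptyenv())
    for (e in seq_len(n_edges - (n_genes - 1L))) {
      repeat {
        a <- sample.int(n_genes, 1L, prob = deg + 1)
        b <- sample.int(n_genes, 1L, prob = deg + 1)
        key <- paste0(a, ".", b)
        dup <- a == b ||
          (a > 1L && b == tgt[a - 1L] && a == reg[a - 1L]) ||
          !is.null(seen[[key]])
        # also avoid duplicating a growth-phase edge exactly
        if (!dup && !any(reg == a & tgt == b)) break
      }
      seen[[key]] <- TRUE
      reg[k] <- a; tgt[k] <- b
      deg[a] <- deg[a] + 1L; deg[b] <- deg[b] + 1L
      k <- k + 1L
    }
    sign <- ifelse(stats::runif(n_edges) < activating_fraction, 1L, -1L)
    signed_network(ids, data.frame(regulator = ids[reg], target = ids[tgt],
                                   sign = sign, stringsAsFactors = FALSE))
  })
}

#' Extract a connected subnetwork
#'
#' Greedy neighbourhood expansion: starting from a seeded random node,
#' repeatedly add the outside node with the most links to the current
#' node set (ties broken by a seeded draw) until `n_nodes` are collected;
#' the induced signed subgraph is returned.
#'
#' @param source a [signed_network()].
#' @param n_nodes number of nodes to extract (2 <= n_nodes <= |source|).
#' @param seed integer seed.
#' @return a [signed_network()] over the extracted node set.
#' @export
sample_subnetwork <- function(source, n_nodes, seed = 1L) {
  stopifnot(is_signed_network(source))
  n_nodes <- as.integer(n_nodes)
  N <- length(source$gene_ids)
  stopifnot(n_nodes >= 2L, n_nodes <= N)
  if (n_nodes == N) return(source)
  idx <- stats::setNames(seq_len(N), source$gene_ids)
  reg <- idx[source$edges$regulator]
  tgt <- idx[source$edges$target]
  # undirected adjacency counts for the expansion
  withr::with_seed(as.integer(seed), {
    current <- logical(N)
    links <- integer(N)  # links from each outside node into `current`
    start <- sample.int(N, 1L)
    add_node <- function(v) {
      current[v] <<- TRUE
      nb <- c(tgt[reg == v], reg[tgt == v])
      for (u in nb) links[u] <<- links[u] + 1L
      links[v] <<- 0L
    }
    add_node(start)
    for (i in seq_len(n_nodes - 1L)) {
      cand <- which(!current & links > 0L)
      if (!length(cand))
        stop("source network has no connected component large enough; ",
             "use a larger component", call. = FALSE)
      best <- cand[links[cand] == max(links[cand])]
      pick <- if (length(best) == 1L) best else best[sample.int(length(best), 1L)]
      add_node(pick)
    }
    keep_genes <- source$gene_ids[current]
    e <- source$edges
    keep <- e$regulator %in% keep_genes & e$target %in% keep_genes
    signed_network(keep_genes, e[keep, , drop = FALSE])
  })
}

#' Solve the steady state of a signed network
#'
#' Damped fixed-point iteration of the saturating kinetic model
#' (see [simulator_params()]), starting from `x = basal`. Clamped genes
#' are held at their clamp level exactly throughout; basal offsets shift
#' individual genes' basal input (multifactorial perturbation).
#'
#' @param net a [signed_network()].
#' @param params a [simulator_params()].
#' @param clamp optional named numeric vector, gene id -> level held fixed.
#' @param basal_offsets optional named numeric vector, gene id -> additive
#'   basal-input offset.
#' @return named numeric vector of N steady expression levels, all in
#'   `[0, u_max]`.
#' @export
steady_state <- function(net, params, clamp = NULL, basal_offsets = NULL) {
  stopifnot(is_signed_network(net), inherits(params, "simulator_params"))
  N <- length(net$gene_ids)
  if (N == 0L) stop("empty network", call. = FALSE)
  W <- interaction_strengths(net, params)
  basal <- rep(params$basal, N)
  names(basal) <- net$gene_ids
  if (!is.null(basal_offsets)) {
    stopifnot(all(names(basal_offsets) %in% net$gene_ids))
    basal[names(basal_offsets)] <- basal[names(basal_offsets)] + basal_offsets
  }
  clamped <- logical(N)
  clamp_level <- numeric(N)
  if (!is.null(clamp) && length(clamp)) {
    stopifnot(all(names(clamp) %in% net$gene_ids))
    clamped[match(names(clamp), net$gene_ids)] <- TRUE
    clamp_level[match(names(clamp), net$gene_ids)] <- clamp
  }
  x <- pmin(basal, params$u_max)
  x[x < 0] <- 0
  x[clamped] <- clamp_level[clamped]
  # F(x): one synchronous update of the kinetic map
  Fmap <- function(x) {
    u <- params$steepness * (basal + drop(crossprod(W, x)))
    xn <- sat_response(u, params)
    xn[clamped] <- clamp_level[clamped]
    xn
  }
  # Newton iteration on G(x) = x - F(x) from a given start; returns the
  # solution or NULL. Used near the fixed point (quadratic) and as a
  # rescue from the orbit average when the fixed point is unstable and
  # damped iteration circles a limit cycle around it.
  newton_from <- function(x0) {
    x <- x0
    for (k in seq_len(100L)) {
      Fx <- Fmap(x)
      res <- max(abs(Fx - x))
      if (!is.finite(res) || res > 1e3) return(NULL)
      if (res < params$tol) return(Fx)
      u <- params$steepness * (basal + drop(crossprod(W, x)))
      gp <- sat_response_deriv(u, params) * params$steepness
      gp[clamped] <- 0
      J <- diag(N) - gp * t(W)   # J[i, j] = dG_i / dx_j
      step <- tryCatch(solve(J, Fx - x), error = function(e) NULL)
      if (is.null(step)) return(NULL)
      x <- x + step
      x[clamped] <- clamp_level[clamped]
    }
    NULL
  }
  # damped iteration with stall-adaptive damping; inhibitory feedback
  # loops can orbit the fixed point, in which case Newton started from
  # the running orbit average finds it
  Fx <- Fmap(x)
  res <- max(abs(Fx - x))
  damp <- 0.5
  best <- Inf
  stall <- 0L
  xavg <- x
  for (it in seq_len(params$max_iter)) {
    if (res < params$tol) {
      x <- Fx  # clamps exact, consistent with the map
      names(x) <- net$gene_ids
      return(x)
    }
    if (res < 1e-4) {  # local quadratic finish
      sol <- newton_from(x)
      if (!is.null(sol)) {
        names(sol) <- net$gene_ids
        return(sol)
      }
    }
    x <- (1 - damp) * x + damp * Fx
    x[clamped] <- clamp_level[clamped]
    xavg <- 0.98 * xavg + 0.02 * x
    Fx <- Fmap(x)
    res <- max(abs(Fx - x))
    if (res < best * (1 - 1e-4)) {
      best <- res
      stall <- 0L
    } else if ((stall <- stall + 1L) >= 200L) {
      sol <- newton_from(xavg)
      if (!is.null(sol)) {
        names(sol) <- net$gene_ids
        return(sol)
      }
      damp <- max(damp / 2, 0.02)
      best <- res
      stall <- 0L
    }
  }
  stop(sprintf("steady state did not converge in %d iterations (residual %.3g)",
               params$max_iter, res), call. = FALSE)
}

# signed strength matrix W[j, i] = effect of regulator j on target i;
# magnitudes drawn uniformly from strength_range, deterministic in seed
interaction_strengths <- function(net, params) {
  N <- length(net$gene_ids)
  W <- matrix(0, N, N, dimnames = list(net$gene_ids, net$gene_ids))
  e <- net$edges
  if (nrow(e)) {
    mag <- withr::with_seed(params$seed + 77003L,
      stats::runif(nrow(e), params$strength_range[1L], params$strength_range[2L]))
    W[cbind(e$regulator, e$target)] <- mag * e$sign
  }
  W
}

#' Simulate a designed expression experiment
#'
#' Produces one steady-state expression column per sample, following the
#' design: knockout clamps gene k to zero in sample k; knockdown clamps
#' gene k to half its unperturbed steady level (downstream effects
#' propagate by re-solving the fixed point); multifactorial perturbs the
#' basal input of a random `perturb_fraction` subset of genes by
#' `Normal(0, perturb_sd)` draws in every sample. Multiplicative
#' lognormal measurement noise (sd `noise_sd` on the log scale) is then
#' applied to every entry. No metadata about which gene was perturbed is
#' attached to the output.
#'
#' @param net a [signed_network()].
#' @param design an [experiment_design()].
#' @param params a [simulator_params()]; `params$seed` drives all
#'   randomness.
#' @return list with `expr` (an [expression_matrix()], genes x samples)
#'   and `network` (the input net, the simulation ground truth).
#' @export
simulate_experiments <- function(net, design, params = simulator_params()) {
  stopifnot(is_signed_network(net), inherits(design, "experiment_design"))
  N <- length(net$gene_ids)
  if (design$kind %in% c("knockout", "knockdown") && design$n_samples > N)
    stop("knockout/knockdown designs allow at most one sample per gene",
         call. = FALSE)
  base_level <- steady_state(net, params)
  cols <- withr::with_seed(params$seed, {
    lapply(seq_len(design$n_samples), function(k) {
      x <- switch(design$kind,
        knockout = steady_state(net, params,
          clamp = stats::setNames(0, net$gene_ids[k])),
        knockdown = steady_state(net, params,
          clamp = stats::setNames(base_level[k] / 2, net$gene_ids[k])),
        multifactorial = {
          m <- max(1L, round(params$perturb_fraction * N))
          who <- sample.int(N, m)
          off <- stats::setNames(stats::rnorm(m, 0, params$perturb_sd),
                                 net$gene_ids[who])
          steady_state(net, params, basal_offsets = off)
        })
      noise <- if (params$noise_sd > 0)
        exp(stats::rnorm(N, 0, params$noise_sd)) else rep(1, N)
      list(clean = x, noisy = x * noise)
    })
  })
  vals <- vapply(cols, `[[`, numeric(N), "noisy")
  X <- expression_matrix(vals, gene_ids = net$gene_ids,
                         sample_ids = sprintf("%s_%03d",
                                              substr(design$kind, 1L, 2L),
                                              seq_len(design$n_samples)))
  attr(X, "clean") <- vapply(cols, `[[`, numeric(N), "clean")
  list(expr = X, network = net)
}
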