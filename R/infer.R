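#' @useDynLib grnbench, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

#' The unsupervised method roster
#'
#' @return character vector of the sixteen recognized method names.
#' @export
method_roster <- function() {
  c("pearson", "spearman", "kendall", "spearman_c", "rn", "clr", "aracne",
    "pcit", "mrnet", "mrnet_b", "genie", "sigmoid", "md", "mr", "euclid",
    "zscore")
}

#' Specify an unsupervised inference method
#'
#' @param name a method name from [method_roster()].
#' @param ... method parameters (e.g. `bins`, `eps` for aracne, `beta`
#'   for a soft-power post-transform, `n_trees`/`seed` for genie).
#' @return list of class `method_spec`.
#' @export
method_spec <- function(name, ...) {
  if (!name %in% method_roster())
    stop("unknown method '", name, "'; roster: ",
         paste(method_roster(), collapse = ", "), call. = FALSE)
  structure(list(name = name, params = list(...)), class = "method_spec")
}

#' Run an unsupervised inference method by name
#'
#' Dispatcher over the full method roster. Every returned matrix obeys
#' the weight-matrix contract: symmetric, finite, larger = stronger
#' predicted interaction. A `beta` parameter applies a soft-power
#' post-transform to methods whose weights live in `[0, 1]`.
#'
#' @param method a [method_spec()] or a bare method name.
#' @param X an [expression_matrix()].
#' @return a [weight_matrix()].
#' @export
infer <- function(method, X) {
  if (is.character(method)) method <- method_spec(method)
  stopifnot(inherits(method, "method_spec"))
  p <- method$params
  beta <- p$beta
  arg <- function(name, default) if (!is.null(p[[name]])) p[[name]] else default
  w <- switch(method$name,
    pearson   = correlation_weights(X, "pearson"),
    spearman  = correlation_weights(X, "spearman"),
    kendall   = correlation_weights(X, "kendall"),
    spearman_c = spearman_c(X),
    rn        = relevance_network(X, bins = arg("bins", default_bins(X))),
    clr       = clr(X, bins = arg("bins", default_bins(X))),
    aracne    = aracne(X, bins = arg("bins", default_bins(X)),
                       eps = arg("eps", 0.1)),
    pcit      = pcit(X),
    mrnet     = mrnet(X, bins = arg("bins", default_bins(X))),
    mrnet_b   = mrnet_b(X, bins = arg("bins", default_bins(X))),
    genie     = genie(X, n_trees = arg("n_trees", 100L),
                      seed = arg("seed", 1L)),
    sigmoid   = suppressWarnings(
                  sigmoid_fit(X, max_iter = arg("max_iter", 5000L))),
    md        = mass_distance(X),
    mr        = mutual_rank(X),
    euclid    = euclid(X),
    zscore    = zscore_generalized(X))
  if (!is.null(beta)) w <- softpower(w, beta)
  w
}
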