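#' Per-patient fold-change prior scores
#'
#' The initial gene importance for a patient is the absolute log2 ratio of
#' the patient's expression to the mean control profile, with a pseudocount
#' guarding zeros: \eqn{f_j = |\log_2((x_j + pc) / (c_j + pc))|}. A linear
#' ratio variant (`method = "ratio"`, \eqn{f_j = (x_j + pc)/(c_j + pc)}) is
#' available.
#'
#' @param expr Tumour expression tibble.
#' @param control Control profile tibble from [control_profile()].
#' @param sample Sample id (a column of `expr`) to score.
#' @param pseudocount Positive pseudocount (default 1).
#' @param method `"log2"` (default) or `"ratio"`.
#' @return A tibble with columns `gene` and `f` over the genes shared by
#'   `expr` and `control`.
#' @export
fold_change_scores <- function(expr, control, sample, pseudocount = 1,
                               method = c("log2", "ratio")) {
  method <- match.arg(method)
  stopifnot(pseudocount > 0)
  expr <- validate_expression(expr)
  if (!sample %in% names(expr)[-1]) abort(sprintf("sample '%s' not in expression table", sample))
  shared <- intersect(expr$gene, control$gene)
  if (length(shared) == 0) abort("no genes shared between expression and control")
  x <- expr[[sample]][match(shared, expr$gene)]
  cc <- control$mean_value[match(shared, control$gene)]
  if (any(x < 0) || any(cc < 0)) abort("negative expression value")
  f <- switch(method,
    log2 = abs(log2((x + pseudocount) / (cc + pseudocount))),
    ratio = (x + pseudocount) / (cc + pseudocount)
  )
  tibble::tibble(gene = shared, f = f)
}

#' Directed GeneRank gene prioritization
#'
#' Iterates the damped propagation
#' \deqn{r_j^{(n)} = (1 - d)\, f_j + d \sum_i w_{ij}\, r_i^{(n-1)} / \deg_i}{}
#' from \eqn{r^{(0)} = f} until the one-norm of successive iterates falls
#' below `eps`. Here \eqn{w_{ij} = 1} iff the network holds an edge i -> j
#' ("i depends on j") and \eqn{\deg_i = \sum_j w_{ij}} is the number of genes
#' i depends on, so each gene passes its current score, split equally, to the
#' genes it depends on. Genes with \eqn{\deg_i = 0} propagate nothing (no
#' teleportation), and isolated genes settle at \eqn{(1-d) f_j}. For
#' \eqn{d < 1} the operator is a one-norm contraction, so convergence is
#' guaranteed.
#'
#' @param network An `np_depnet`.
#' @param scores A tibble with columns `gene` and `f` (nonnegative finite
#'   prior scores) covering every network gene, or NULL for the
#'   uniform prior f = 1 (topology-only ranking).
#' @param d Damping weight on the network, in \[0, 1). 0.85 for the
#'   breast-cancer preset; 0.30 for the ovarian/glioblastoma presets.
#' @param eps One-norm convergence tolerance (default 1e-5).
#' @param max_iter Iteration cap (default 1000); non-convergence is flagged,
#'   not fatal.
#' @param degree_mode `"out"` (default; deg_i counts the genes i depends on,
#'   making the propagation operator substochastic) or `"in"` (the opposite
#'   reading of the degree, exposed for sensitivity analysis).
#' @param normalize_f If TRUE, divide f by its maximum before iterating
#'   (the original undirected formulation normalizes; off by default).
#' @param init `"scores"` (r0 = f, default) or `"uniform"` (r0 = 1).
#' @return An object of class `np_generank`: a tibble (`gene`, `score`,
#'   `rank`) with attributes `iterations`, `converged`, `residual`, `d`.
#'   Ranks are dense 1..N, descending score, ties broken by gene id.
#' @export
generank <- function(network, scores = NULL, d = 0.85, eps = 1e-5,
                     max_iter = 1000, degree_mode = c("out", "in"),
                     normalize_f = FALSE, init = c("scores", "uniform")) {
  degree_mode <- match.arg(degree_mode)
  init <- match.arg(init)
  stopifnot(inherits(network, "np_depnet"), d >= 0, d < 1, eps > 0, max_iter >= 1)
  genes <- network$genes
  N <- length(genes)
  if (N == 0) abort("empty network")
  if (is.null(scores)) {
    f <- rep(1, N)
  } else {
    if (!all(genes %in% scores$gene)) abort("every network gene needs a prior score")
    f <- scores$f[match(genes, scores$gene)]
  }
  if (any(!is.finite(f)) || any(f < 0)) abort("prior scores must be finite and >= 0")
  if (normalize_f && max(f) > 0) f <- f / max(f)

  src <- match(network$edges$source, genes)
  tgt <- match(network$edges$target, genes)
  if (degree_mode == "in") { tmp <- src; src <- tgt; tgt <- tmp }
  deg <- tabulate(src, nbins = N) # genes each source depends on
  w <- 1 / deg[src]               # per-edge share passed source -> target

  r <- if (init == "scores") f else rep(1, N)
  converged <- FALSE
  iter <- 0
  resid <- NA_real_
  repeat {
    iter <- iter + 1
    prop <- numeric(N)
    if (length(src) > 0) {
      contrib <- r[src] * w
      prop <- as.vector(tapply_sum(contrib, tgt, N))
    }
    r_new <- (1 - d) * f + d * prop
    resid <- sum(abs(r_new - r))
    r <- r_new
    if (resid < eps) { converged <- TRUE; break }
    if (iter >= max_iter) break
  }
  out <- rank_genes(tibble::tibble(gene = genes, score = r))
  structure(out, class = c("np_generank", class(out)),
            iterations = iter, converged = converged, residual = resid,
            d = d, eps = eps)
}

# sum values by integer group into a length-n vector
tapply_sum <- function(values, group, n) {
  out <- numeric(n)
  agg <- rowsum(values, group)
  out[as.integer(rownames(agg))] <- agg[, 1]
  out
}

#' Rank genes by score
#'
#' Descending score order; ties broken lexicographically by gene id so the
#' ranking is deterministic.
#'
#' @param scores A tibble with columns `gene` and `score` (finite).
#' @return The tibble sorted by rank with an integer `rank` column
#'   (1 = most important).
#' @export
rank_genes <- function(scores) {
  stopifnot(all(c("gene", "score") %in% names(scores)))
  if (any(!is.finite(scores$score))) abort("scores must be finite")
  out <- dplyr::arrange(tibble::as_tibble(scores),
                        dplyr::desc(.data$score), .data$gene)
  out$rank <- seq_len(nrow(out))
  out
}

#' Top-ranked gene set
#'
#' The first `ceiling(q * N)` genes by rank; q = 0.05 reproduces the "top 5%"
#' selection used to nominate important genes.
#'
#' @param ranked A ranked tibble (e.g. from [generank()]).
#' @param q Fraction in (0, 1].
#' @return Character vector of gene ids.
#' @export
top_fraction <- function(ranked, q = 0.05) {
  stopifnot(q > 0, q <= 1)
  n <- ceiling(q * nrow(ranked))
  ranked$gene[order(ranked$rank)][seq_len(n)]
}

#' Topology-only ranking with a uniform prior
#'
#' Runs [generank()] with every initial score set to 1, ranking genes purely
#' by their position in the dependency network.
#'
#' @inheritParams generank
#' @param ... Passed to [generank()].
#' @return An `np_generank`.
#' @export
uniform_prior_ranking <- function(network, d = 0.85, ...) {
  generank(network, scores = NULL, d = d, ...)
}

#' @describeIn generank Ranked scores as a plain tibble.
#' @param x An `np_generank`.
#' @param ... Unused.
#' @export
tidy.np_generank <- function(x, ...) {
  tibble::as_tibble(unclass(x)[c("gene", "score", "rank")])
}

#' @describeIn generank One-row convergence summary.
#' @export
glance.np_generank <- function(x, ...) {
  tibble::tibble(
    n_genes = nrow(x),
    d = attr(x, "d"),
    iterations = attr(x, "iterations"),
    converged = attr(x, "converged"),
    residual = attr(x, "residual")
  )
}

#' Plot the top of a ranked gene list
#'
#' @param object An `np_generank`.
#' @param n_top Number of leading genes to show.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.np_generank <- function(object, n_top = 20, ...) {
  df <- head(dplyr::arrange(tidy(object), .data$rank), n_top)
  ggplot2::ggplot(df, ggplot2::aes(
    x = stats::reorder(.data$gene, -.data$rank), y = .data$score
  )) +
    ggplot2::geom_col() +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "GeneRank score",
                  title = sprintf("Top %d ranked genes", nrow(df)))
}
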