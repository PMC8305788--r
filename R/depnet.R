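#' Conditional mutual information of binary vectors (bits)
#'
#' Plug-in estimate of CMI(A; P | B) for binary vectors, in bits:
#' \deqn{\sum_{a,p,b} \frac{n(a,p,b)}{N}
#'       \log_2 \frac{N(a,p,b)\, n(b)}{n(a,b)\, n(p,b)}}{}
#' with zero-count cells contributing nothing. The estimate is clamped at 0
#' against floating-point rounding. CMI(A; P | B) measures how informative
#' gene A's state is about the prognostic label P once gene B's state is
#' known; it is symmetric in its first two arguments.
#'
#' @param a,p,b Equal-length vectors with entries in \{0, 1\}.
#' @return A nonnegative scalar in bits (at most 1 for binary variables).
#' @export
cmi <- function(a, p, b) {
  if (length(a) != length(p) || length(a) != length(b)) {
    abort("a, p, b must have equal lengths")
  }
  if (length(a) < 1) abort("vectors must be non-empty")
  if (!all(c(a, p, b) %in% c(0, 1))) abort("entries must be 0 or 1")
  N <- length(a)
  tot <- 0
  for (bb in c(0, 1)) {
    idx <- b == bb
    nb <- sum(idx)
    if (nb == 0) next
    as <- a[idx]; ps <- p[idx]
    n1a <- sum(as); n1p <- sum(ps)
    n11 <- sum(as & ps)
    cnt <- c(n11, n1a - n11, n1p - n11, nb - n1a - n1p + n11)
    na_ <- c(n1a, n1a, nb - n1a, nb - n1a)
    np_ <- c(n1p, nb - n1p, n1p, nb - n1p)
    nz <- cnt > 0
    tot <- tot + sum(cnt[nz] * log2(cnt[nz] * nb / (na_[nz] * np_[nz])))
  }
  max(tot / N, 0)
}

# Vectorized CMI of every gene (rows of X) against p, conditioned on gene j.
# X: 0/1 genes x samples matrix; p: 0/1 vector. Returns a vector over rows.
cmi_vs_target <- function(X, p, j) {
  N <- ncol(X)
  out <- numeric(nrow(X))
  for (s in c(0, 1)) {
    idx <- which(X[j, ] == s)
    ns <- length(idx)
    if (ns == 0) next
    Xs <- X[, idx, drop = FALSE]
    ps <- p[idx]
    n11 <- as.vector(Xs %*% ps)
    n1a <- rowSums(Xs)
    n1p <- sum(ps)
    term <- function(n, na_, np_) {
      v <- numeric(length(n))
      nz <- n > 0
      v[nz] <- n[nz] * log2(n[nz] * ns / (na_[nz] * np_[nz]))
      v
    }
    out <- out +
      term(n11, n1a, rep(n1p, length(n1a))) +
      term(n1a - n11, n1a, rep(ns - n1p, length(n1a))) +
      term(n1p - n11, ns - n1a, rep(n1p, length(n1a))) +
      term(ns - n1a - n1p + n11, ns - n1a, rep(ns - n1p, length(n1a)))
  }
  pmax(out / N, 0)
}

#' Empirical CMI null distribution from random gene pairs
#'
#' Samples ordered gene pairs uniformly at random with replacement (both
#' orientations eligible) and records the CMI of each pair with the risk
#' label until `n_values` values are collected; their mean and standard
#' deviation form the null model for the edge z-test. Optionally the risk
#' vector is permuted independently for every draw, which removes genuine
#' signal from the null sample.
#'
#' @param cohort An `np_cohort` from [binarize_cohort()].
#' @param n_values Number of null CMI values to draw (default 10000; the
#'   full-scale analysis described in the methods used 1e6).
#' @param seed Integer seed making the draw reproducible.
#' @param permute_risk If TRUE, permute the risk label between draws.
#' @return An object of class `np_null`: list with `mean`, `sd`, `n`, `seed`,
#'   `permuted`.
#' @export
cmi_null <- function(cohort, n_values = 10000, seed = 1, permute_risk = FALSE) {
  stopifnot(inherits(cohort, "np_cohort"), n_values >= 2)
  G <- nrow(cohort$X)
  if (G < 2) abort("need >= 2 genes")
  r <- as.numeric(cohort$risk)
  if (length(unique(r)) < 2) abort("degenerate null (sd = 0): risk labels are constant")
  vals <- withr::with_seed(seed, {
    src <- sample.int(G, n_values, replace = TRUE)
    tgt <- sample.int(G, n_values, replace = TRUE)
    same <- src == tgt
    while (any(same)) {
      tgt[same] <- sample.int(G, sum(same), replace = TRUE)
      same <- src == tgt
    }
    if (permute_risk) {
      vapply(seq_len(n_values), function(k) {
        cmi_vs_target(cohort$X[src[k], , drop = FALSE], sample(r), tgt[k])[1]
      }, numeric(1))
    } else {
      out <- numeric(n_values)
      for (j in unique(tgt)) {
        take <- which(tgt == j)
        col <- cmi_vs_target(cohort$X, r, j)
        out[take] <- col[src[take]]
      }
      out
    }
  })
  s <- sd(vals)
  if (s <= 0) abort("degenerate null (sd = 0)")
  structure(
    list(mean = mean(vals), sd = s, n = n_values, seed = seed,
         permuted = permute_risk),
    class = "np_null"
  )
}

#' @export
print.np_null <- function(x, ...) {
  cat(sprintf("<np_null> mean %.6g, sd %.6g (n = %d, seed = %d)\n",
              x$mean, x$sd, x$n, x$seed))
  invisible(x)
}

#' z-test significance of a CMI value against the empirical null
#'
#' @param cmi_value CMI value(s) in bits.
#' @param null An `np_null` model.
#' @return A tibble with columns `z` and `p` (one-sided upper tail).
#' @export
edge_significance <- function(cmi_value, null) {
  stopifnot(inherits(null, "np_null"))
  if (null$sd <= 0) abort("null sd must be > 0")
  z <- (cmi_value - null$mean) / null$sd
  tibble::tibble(z = z, p = pnorm(z, lower.tail = FALSE))
}

#' Build the prognosis-conditioned gene dependency network
#'
#' Evaluates CMI(A, P | B) for every ordered gene pair (A, B), A != B, and
#' retains the directed edge A -> B (read: "A's prognostic information
#' depends on B") when its one-sided z-test p-value against the empirical
#' null falls below `p_threshold`. All scanned genes are kept as network
#' nodes, including genes incident to no significant edge, so downstream
#' ranking operates over the full gene universe.
#'
#' @param cohort An `np_cohort`.
#' @param null An `np_null` from [cmi_null()], or NULL to build one with
#'   default settings.
#' @param p_threshold Retention threshold on the edge p-value (default 1e-5).
#' @param method `"ztest"` (normal tail on the empirical null, the default)
#'   or `"permutation"` (empirical tail proportion of the null sample,
#'   available as a calibration-robust alternative).
#' @param null_values When `method = "permutation"`, the raw null draws are
#'   required; pass the result of `cmi_null(..., keep = TRUE)` style draws
#'   via this argument (a numeric vector).
#' @return An object of class `np_depnet`: list with `genes`, `edges` (a
#'   tibble `source`, `target`, `cmi_bits`, `z`, `p` sorted by p), `null`,
#'   and `p_threshold`.
#' @export
build_network <- function(cohort, null = NULL, p_threshold = 1e-5,
                          method = c("ztest", "permutation"),
                          null_values = NULL) {
  method <- match.arg(method)
  stopifnot(inherits(cohort, "np_cohort"), p_threshold > 0, p_threshold < 1)
  if (is.null(null)) null <- cmi_null(cohort)
  X <- cohort$X
  r <- as.numeric(cohort$risk)
  G <- nrow(X)
  src <- integer(0); tgt <- integer(0); val <- numeric(0)
  for (j in seq_len(G)) {
    col <- cmi_vs_target(X, r, j)
    col[j] <- NA_real_
    sig <- edge_significance(col, null)
    keep <- which(!is.na(col) & sig$p < p_threshold)
    if (method == "permutation") {
      if (is.null(null_values)) abort("permutation method needs null_values")
      pperm <- vapply(col, function(v) mean(null_values >= v), numeric(1))
      keep <- which(!is.na(col) & pperm < p_threshold)
    }
    if (length(keep) > 0) {
      src <- c(src, keep); tgt <- c(tgt, rep(j, length(keep)))
      val <- c(val, col[keep])
    }
  }
  sig <- edge_significance(val, null)
  edges <- tibble::tibble(
    source = cohort$genes[src],
    target = cohort$genes[tgt],
    cmi_bits = val,
    z = sig$z,
    p = sig$p
  )
  edges <- dplyr::arrange(edges, .data$p, .data$source, .data$target)
  if (nrow(edges) == 0) warn("no significant gene pairs: returning an empty network")
  structure(
    list(genes = cohort$genes, edges = edges, null = null,
         p_threshold = p_threshold),
    class = "np_depnet"
  )
}

#' Construct a dependency network from an explicit edge list
#'
#' Convenience constructor used for worked examples and tests; the edge
#' direction convention is the same as [build_network()]: `source` depends on
#' `target`.
#'
#' @param edges A data frame with `source` and `target` columns (optionally
#'   `cmi_bits`, `z`, `p`).
#' @param genes Node universe; defaults to the genes present in `edges`.
#' @return An `np_depnet`.
#' @export
depnet <- function(edges, genes = NULL) {
  edges <- tibble::as_tibble(edges)
  stopifnot(all(c("source", "target") %in% names(edges)))
  if (any(edges$source == edges$target)) abort("self-loops are not allowed")
  if (anyDuplicated(edges[, c("source", "target")])) abort("duplicate edges")
  if (is.null(genes)) genes <- sort(unique(c(edges$source, edges$target)))
  if (!all(c(edges$source, edges$target) %in% genes)) {
    abort("edge endpoints must be in the gene universe")
  }
  for (cn in c("cmi_bits", "z", "p")) if (!cn %in% names(edges)) edges[[cn]] <- NA_real_
  structure(
    list(genes = genes, edges = edges, null = NULL, p_threshold = NA_real_),
    class = "np_depnet"
  )
}

#' @export
print.np_depnet <- function(x, ...) {
  cat(sprintf("<np_depnet> %d genes, %d directed edges (source depends on target)\n",
              length(x$genes), nrow(x$edges)))
  invisible(x)
}

#' @describeIn depnet Edge list of a dependency network as a tibble.
#' @param x An `np_depnet`.
#' @param ... Unused.
#' @export
tidy.np_depnet <- function(x, ...) x$edges

#' @describeIn depnet One-row network summary.
#' @export
glance.np_depnet <- function(x, ...) {
  tibble::tibble(
    n_genes = length(x$genes),
    n_edges = nrow(x$edges),
    p_threshold = x$p_threshold,
    null_mean = x$null$mean %||% NA_real_,
    null_sd = x$null$sd %||% NA_real_
  )
}

#' Write a network edge list to TSV
#'
#' The file carries a header comment recording the direction convention.
#'
#' @param network An `np_depnet`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_network <- function(network, path) {
  stopifnot(inherits(network, "np_depnet"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# direction: source depends on target", con)
  writeLines(sprintf("# genes: %s", paste(network$genes, collapse = ",")), con)
  writeLines(paste(c("source", "target", "cmi_bits", "z", "p"), collapse = "\t"), con)
  if (nrow(network$edges) > 0) {
    writeLines(sprintf("%s\t%s\t%.17g\t%.17g\t%.17g",
                       network$edges$source, network$edges$target,
                       network$edges$cmi_bits, network$edges$z,
                       network$edges$p), con)
  }
  invisible(path)
}

#' Read a network edge list written by [write_network()]
#' @param path Path to the edge-list TSV.
#' @return An `np_depnet`.
#' @export
read_network <- function(path) {
  lines <- readLines(path)
  gl <- grep("^# genes:", lines, value = TRUE)
  genes <- if (length(gl) == 1) strsplit(sub("^# genes: ", "", gl), ",", fixed = TRUE)[[1]] else NULL
  body <- lines[!startsWith(lines, "#")]
  df <- readr::read_tsv(I(paste(body, collapse = "\n")),
                        col_types = "ccddd", progress = FALSE)
  depnet(df, genes = genes)
}
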