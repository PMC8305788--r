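# Independent oracles kept deliberately naive: they re-derive the same
# quantities by brute force and never share code with the implementation.

# triple-loop plug-in CMI over the 8-cell joint count table, in bits
oracle_cmi <- function(a, p, b) {
  N <- length(a)
  tot <- 0
  for (aa in 0:1) for (pp in 0:1) for (bb in 0:1) {
    napb <- sum(a == aa & p == pp & b == bb)
    if (napb == 0) next
    nb <- sum(b == bb)
    nab <- sum(a == aa & b == bb)
    npb <- sum(p == pp & b == bb)
    tot <- tot + napb / N * log2(napb * nb / (nab * npb))
  }
  max(tot, 0)
}

# direct linear solve of the GeneRank fixed point r = (1-d) f + d M r,
# M[j, i] = w_ij / deg_i with w_ij = 1 iff edge i -> j ("i depends on j")
oracle_generank_solve <- function(edges, genes, f, d) {
  N <- length(genes)
  W <- matrix(0, N, N, dimnames = list(genes, genes))
  for (k in seq_len(nrow(edges))) W[edges$source[k], edges$target[k]] <- 1
  deg <- rowSums(W)
  M <- matrix(0, N, N)
  for (i in seq_len(N)) if (deg[i] > 0) M[, i] <- W[i, ] / deg[i]
  solve(diag(N) - d * M, (1 - d) * f)
}

# brute-force one-sided two-sample KS statistic: scan every rank position
oracle_ks_dplus <- function(x, y) {
  best <- 0
  for (g in sort(c(x, y))) {
    gap <- mean(x <= g) - mean(y <= g)
    if (gap > best) best <- gap
  }
  best
}

# random directed network on n nodes with edge probability prob
random_network <- function(n, prob = 0.15) {
  genes <- sprintf("n%02d", seq_len(n))
  pairs <- expand.grid(source = genes, target = genes,
                       stringsAsFactors = FALSE)
  pairs <- pairs[pairs$source != pairs$target, ]
  keep <- runif(nrow(pairs)) < prob
  depnet(tibble::tibble(source = pairs$source[keep],
                        target = pairs$target[keep]),
         genes = genes)
}

# small deterministic expression tibble
toy_expression <- function(values, genes = NULL, samples = NULL) {
  m <- as.matrix(values)
  if (is.null(genes)) genes <- sprintf("g%d", seq_len(nrow(m)))
  if (is.null(samples)) samples <- sprintf("s%d", seq_len(ncol(m)))
  out <- tibble::as_tibble(as.data.frame(m))
  names(out) <- samples
  dplyr::bind_cols(tibble::tibble(gene = genes), out)
}
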