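# Independent brute-force oracles, deliberately written as plain scalar
# loops so they share no code path with the implementation.

# Pearson correlation of two vectors from the definition.
oracle_cor <- function(x, y) {
  mx <- sum(x) / length(x)
  my <- sum(y) / length(y)
  sum((x - mx) * (y - my)) /
    sqrt(sum((x - mx)^2) * sum((y - my)^2))
}

# Topological overlap from the definition, element by element.
oracle_tom <- function(A) {
  n <- nrow(A)
  out <- diag(n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      l <- 0
      for (u in seq_len(n)) {
        if (u != i && u != j) l <- l + A[i, u] * A[u, j]
      }
      ki <- sum(A[i, -i])
      kj <- sum(A[j, -j])
      out[i, j] <- (l + A[i, j]) / (min(ki, kj) + 1 - A[i, j])
    }
  }
  out
}

# Signed connectivity by per-edge accumulation.
oracle_kwithin <- function(gene, edges, weights, labels) {
  pos <- 0
  neg <- 0
  for (i in seq_len(nrow(edges))) {
    if (!edges$significant[i]) next
    a <- edges$gene_a[i]
    b <- edges$gene_b[i]
    if (a != gene && b != gene) next
    if (labels[[a]] != labels[[b]] || labels[[a]] == 0) next
    w <- weights[i]
    if (w > 0) pos <- pos + w else neg <- neg + abs(w)
  }
  pos - neg
}

# Minimal hand-built differential edge table with the class and attributes
# build_edge_table() would attach.
make_edges <- function(gene_a, gene_b, delta, significant = NULL,
                       genes = NULL) {
  if (is.null(significant)) significant <- rep(TRUE, length(delta))
  df <- data.frame(gene_a = gene_a, gene_b = gene_b,
                   r_R = tanh(delta), r_S = 0,
                   z_R = delta, z_S = 0, delta = delta,
                   p_value = 2 * pnorm(-abs(delta)), lfdr = 0,
                   significant = significant, sign = sign(delta),
                   stringsAsFactors = FALSE)
  if (is.null(genes)) genes <- sort(unique(c(gene_a, gene_b)))
  structure(df, class = c("diffcorr_edges", "data.frame"), genes = genes,
            n_R = 6L, n_S = 6L)
}

# Correlation sets for a pair of small matrices.
corr_pair <- function(expr_R, expr_S) {
  list(R = correlation_matrix(expr_R, "R"),
       S = correlation_matrix(expr_S, "S"))
}

# The standard planted three-module design used by the recovery tests.
planted_spec <- function(seed, n_samples = 50L) {
  synthetic_spec(120, module_sizes = c(40L, 40L, 40L),
                 rho_R = c(0.8, 0.8, 0.8), rho_S = c(0, 0, 0),
                 n_samples_R = n_samples, n_samples_S = n_samples,
                 seed = seed)
}
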