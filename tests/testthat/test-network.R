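# Scaled adjacency, TOM, module detection, signed connectivity, hubs.

test_that("scale_delta_matrix divides by the maximum magnitude", {
  m <- matrix(0, 3, 3)
  expect_equal(scale_delta_matrix(m), m)

  d <- matrix(c(0, -4, 1, -4, 0, 2, 1, 2, 0), 3, 3)
  a <- scale_delta_matrix(d)
  expect_equal(max(a), 1)
  expect_equal(a[1, 2], 1)
  expect_equal(a[1, 3], 0.25)
  expect_equal(unname(diag(a)), rep(0, 3))

  withr::with_seed(1, {
    r <- matrix(rnorm(36), 6, 6); r <- r + t(r); diag(r) <- 0
    a <- scale_delta_matrix(r)
    expect_equal(a, abs(r) / max(abs(r)) * (1 - diag(6)) , tolerance = 1e-12)
  })
  expect_error(scale_delta_matrix(matrix(1:9, 3, 3)), "symmetric")
})

test_that("TOM closed forms: triangle, path, empty graph", {
  tri <- matrix(1, 3, 3) - diag(3)
  expect_equal(topological_overlap(tri), matrix(1, 3, 3))  # (1+1)/(2+1-1)

  path <- matrix(0, 3, 3)
  path[1, 2] <- path[2, 1] <- 1
  path[2, 3] <- path[3, 2] <- 1
  tom <- topological_overlap(path)
  expect_equal(tom[1, 3], 0.5)  # (1*1 + 0)/(min(1,1) + 1 - 0)

  empty <- matrix(0, 4, 4)
  tome <- topological_overlap(empty)
  expect_equal(tome[upper.tri(tome)], rep(0, 6))
  expect_equal(unname(diag(tome)), rep(1, 4))
})

test_that("TOM is symmetric, in [0,1], and matches the brute-force oracle", {
  vals <- c(0, 0.5, 1)
  # exhaustive over all 3-node and 4-node weighted graphs
  for (n in 3:4) {
    np <- choose(n, 2)
    grids <- as.matrix(expand.grid(rep(list(vals), np)))
    for (g in seq_len(nrow(grids))) {
      A <- matrix(0, n, n)
      A[upper.tri(A)] <- grids[g, ]
      A <- A + t(A)
      tom <- topological_overlap(A)
      expect_true(all(tom >= -1e-12 & tom <= 1 + 1e-12))
      expect_equal(tom, oracle_tom(A), tolerance = 1e-10)
    }
  }
  expect_error(topological_overlap(matrix(2, 2, 2) - 2 * diag(2)), "\\[0, 1\\]")
})

test_that("two disconnected cliques are recovered as two modules", {
  A <- matrix(0, 20, 20)
  A[1:10, 1:10] <- 1
  A[11:20, 11:20] <- 1
  diag(A) <- 0
  rownames(A) <- colnames(A) <- sprintf("g%02d", 1:20)
  asg <- detect_modules(topological_overlap(A), min_module_size = 5)
  expect_equal(length(unique(asg$module)), 2)
  expect_equal(length(unique(asg$module[1:10])), 1)
  expect_equal(length(unique(asg$module[11:20])), 1)
  expect_true(all(asg$module > 0))
})

test_that("an overlap-free TOM leaves every gene unassigned", {
  tom <- diag(6)
  rownames(tom) <- colnames(tom) <- letters[1:6]
  asg <- suppressWarnings(detect_modules(tom, min_module_size = 2))
  expect_equal(asg$module, rep(0L, 6))
})

test_that("fixed-k cutting and deterministic relabelling work", {
  A <- matrix(0, 15, 15)
  A[1:8, 1:8] <- 0.9
  A[9:15, 9:15] <- 0.9
  diag(A) <- 0
  rownames(A) <- colnames(A) <- sprintf("g%02d", 1:15)
  asg <- detect_modules(topological_overlap(A), min_module_size = 3,
                        method = "fixed_k", k = 2)
  # module 1 is the larger block by the size-rank convention
  expect_equal(unique(asg$module[1:8]), 1L)
  expect_equal(unique(asg$module[9:15]), 2L)
})

test_that("signed connectivity does the Eq-style arithmetic", {
  # node 'a': intramodular weights +0.5, +0.3, -0.2 -> kWithin 0.6.
  # an extra (insignificant) edge fixes max|delta| = 1 so scaled weights
  # equal the raw deltas.
  e <- make_edges(gene_a = c("a", "a", "a", "x"),
                  gene_b = c("b", "c", "d", "y"),
                  delta = c(0.5, 0.3, -0.2, 1),
                  significant = c(TRUE, TRUE, TRUE, FALSE))
  asg <- data.frame(gene = c("a", "b", "c", "d", "x", "y"),
                    module = c(1L, 1L, 1L, 1L, 0L, 0L))
  out <- signed_connectivity(e, asg)
  expect_equal(out$kWithin[out$gene == "a"], 0.6)
  expect_equal(out$conn_pos[out$gene == "a"], 0.8)
  expect_equal(out$conn_neg[out$gene == "a"], 0.2)
  expect_equal(out$n_intramodular_edges[out$gene == "a"], 3L)
  # a node with no intramodular edges scores zero
  expect_equal(out$kWithin[out$gene == "x"], 0)
})

test_that("splitting an edge into parallel contributions preserves kWithin", {
  e1 <- make_edges(c("a", "a"), c("b", "c"), delta = c(0.8, -1))
  e2 <- make_edges(c("a", "a", "a"), c("b", "b", "c"),
                   delta = c(0.5, 0.3, -1))
  asg <- data.frame(gene = c("a", "b", "c"), module = 1L)
  expect_equal(signed_connectivity(e1, asg)$kWithin,
               signed_connectivity(e2, asg)$kWithin)
})

test_that("signed connectivity matches brute-force accumulation", {
  withr::with_seed(21, {
    genes <- sprintf("n%02d", 1:15)
    pairs <- t(combn(genes, 2))
    keep <- sample(nrow(pairs), 40)
    e <- make_edges(pairs[keep, 1], pairs[keep, 2],
                    delta = runif(40, -2, 2),
                    significant = sample(c(TRUE, FALSE), 40, TRUE, c(.7, .3)),
                    genes = genes)
    asg <- data.frame(gene = genes,
                      module = sample(c(0L, 1L, 2L), 15, TRUE))
    out <- signed_connectivity(e, asg)
    w <- e$delta / max(abs(e$delta))
    labels <- setNames(asg$module, asg$gene)
    for (g in genes) {
      expect_equal(out$kWithin[out$gene == g],
                   oracle_kwithin(g, e, w, labels), tolerance = 1e-12)
    }
  })
})

test_that("unlabeled endpoints are an error", {
  e <- make_edges("a", "b", delta = 1)
  expect_error(signed_connectivity(e, data.frame(gene = "a", module = 1L)),
               "missing from the module assignment")
})

test_that("largest_component picks the biggest piece with tie-breaking", {
  # module 1: one clique of 4 -> the whole module
  e <- make_edges(c("a", "a", "a", "b", "b", "c"),
                  c("b", "c", "d", "c", "d", "d"),
                  delta = rep(1, 6))
  net <- differential_network(e)
  asg <- data.frame(gene = c("a", "b", "c", "d"), module = 1L)
  expect_equal(largest_component(net, asg, 1), c("a", "b", "c", "d"))

  # components of size 5 and 3 -> the 5-node set
  e2 <- make_edges(c("p1", "p2", "p3", "p4", "q1", "q2"),
                   c("p2", "p3", "p4", "p5", "q2", "q3"),
                   delta = rep(1, 6))
  net2 <- differential_network(e2)
  asg2 <- data.frame(gene = c(paste0("p", 1:5), paste0("q", 1:3)),
                     module = 1L)
  expect_equal(largest_component(net2, asg2, 1), paste0("p", 1:5))

  # removing one clique's edges post hoc leaves the other clique
  e3 <- e2[!grepl("^q", e2$gene_a), , drop = FALSE]
  attr(e3, "genes") <- attr(e2, "genes")
  net3 <- differential_network(e3)
  expect_equal(largest_component(net3, asg2, 1), paste0("p", 1:5))

  expect_error(largest_component(net2, asg2, 9), "does not exist")
  asg_iso <- data.frame(gene = "z", module = 2L)
  net_iso <- differential_network(
    make_edges("a", "b", delta = 1, genes = c("a", "b", "z")))
  expect_warning(out <- largest_component(net_iso,
                                          rbind(asg_iso,
                                                data.frame(gene = c("a", "b"),
                                                           module = 1L)), 2),
                 "no significant edges")
  expect_length(out, 0)
})

test_that("hub ranking is by kWithin then name", {
  expect_equal(hub_nodes(c(a = 0.6, b = 0.2), 1), "a")
  expect_equal(hub_nodes(c(b = 0.5, a = 0.5, c = 0.5), 3), c("a", "b", "c"))
  withr::with_seed(5, {
    kw <- setNames(runif(30), sprintf("g%02d", 1:30))
    full <- names(sort(kw, decreasing = TRUE))
    expect_equal(hub_nodes(kw, 10), full[1:10])
  })
})

test_that("network exports carry the documented columns and attributes", {
  sim <- generate_expression_pair(
    synthetic_spec(20, module_sizes = 10, rho_R = 0.9, rho_S = 0, seed = 31))
  cp <- corr_pair(sim$expr_R, sim$expr_S)
  e <- suppressWarnings(build_edge_table(cp$R, cp$S))
  net <- differential_network(e)
  asg <- detect_modules(topological_overlap(net$adjacency),
                        min_module_size = 5)
  asg <- signed_connectivity(e, asg)
  tsv <- withr::local_tempfile(fileext = ".tsv")
  gml <- withr::local_tempfile(fileext = ".graphml")
  export_network(net, asg, tsv_path = tsv, graphml_path = gml)
  tab <- read.delim(tsv)
  expect_identical(names(tab), c("source", "target", "weight", "sign", "lfdr"))
  expect_equal(nrow(tab), nrow(net$edges))
  g <- igraph::read_graph(gml, format = "graphml")
  expect_equal(igraph::gorder(g), length(net$nodes))
  expect_equal(igraph::gsize(g), nrow(net$edges))
  expect_true("module" %in% igraph::vertex_attr_names(g))
})
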