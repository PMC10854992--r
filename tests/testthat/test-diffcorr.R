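# Correlation sets, Fisher z, the difference statistic and the edge table.

test_that("correlation_matrix matches the definitional formula", {
  sim <- generate_expression_pair(synthetic_spec(5, seed = 1))
  cs <- correlation_matrix(sim$expr_R, "R")
  expect_true(isSymmetric(cs$r))
  expect_equal(unname(diag(cs$r)), rep(1, 5))
  for (i in 1:4) {
    for (j in (i + 1):5) {
      expect_equal(cs$r[i, j],
                   oracle_cor(sim$expr_R[i, ], sim$expr_R[j, ]),
                   tolerance = 1e-12)
    }
  }
  expect_equal(cs$n, 6L)
})

test_that("duplicated and negated genes give r = 1 and r = -1", {
  sim <- generate_expression_pair(synthetic_spec(3, seed = 2))
  x <- rbind(sim$expr_R, dup = sim$expr_R[1, ], neg = -sim$expr_R[1, ])
  # perfect correlations are clipped before the Fisher transform
  expect_warning(cs <- correlation_matrix(x, "R"), "clipped")
  expect_equal(cs$r["G0001", "dup"], 1)
  expect_equal(cs$r["G0001", "neg"], -1)
})

test_that("correlation_matrix names zero-variance offenders", {
  sim <- generate_expression_pair(synthetic_spec(3, seed = 3))
  sim$expr_R["G0002", ] <- 5
  expect_error(correlation_matrix(sim$expr_R), "G0002")
})

test_that("fisher_z has its closed form, odd symmetry, and clipping", {
  expect_equal(fisher_z(0), 0)
  expect_equal(fisher_z(0.9), 0.5 * log(19), tolerance = 1e-12)
  expect_equal(fisher_z(0.9), 1.47222, tolerance = 1e-5)
  expect_equal(fisher_z(-0.9), -fisher_z(0.9))
  r <- seq(-0.95, 0.95, by = 0.05)
  expect_equal(fisher_z(r), 0.5 * log((1 + r) / (1 - r)), tolerance = 1e-12)
  expect_warning(z1 <- fisher_z(1), "clipped")
  expect_true(is.finite(z1))
  expect_error(fisher_z(NA_real_), "finite")
})

test_that("delta_statistic matches the two-sample Fisher-z closed form", {
  # at n_R = n_S = 6 the denominator is sqrt(2/3)
  expect_equal(delta_statistic(sqrt(2 / 3), 0, 6, 6), 1, tolerance = 1e-10)
  expect_equal(delta_statistic(0.816497, 0, 6, 6), 1, tolerance = 1e-5)
  expect_equal(delta_statistic(2, 0, 6, 6), 2.44949, tolerance = 1e-5)
  expect_equal(delta_statistic(1.2, 1.2, 6, 9), 0)
  # antisymmetric under condition swap
  expect_equal(delta_statistic(1.4, 0.3, 6, 8),
               -delta_statistic(0.3, 1.4, 8, 6))
  expect_error(delta_statistic(1, 0, 3, 6), "> 3")
})

test_that("edge_pvalue is the two-sided normal tail", {
  expect_equal(edge_pvalue(0), 1)
  expect_equal(edge_pvalue(1.959964), 0.05, tolerance = 1e-5)
  expect_equal(edge_pvalue(-1.959964), edge_pvalue(1.959964))
  expect_error(edge_pvalue(Inf), "finite")
})

test_that("edge table enumerates each unordered pair exactly once", {
  sim <- generate_expression_pair(synthetic_spec(6, seed = 5))
  cp <- corr_pair(sim$expr_R, sim$expr_S)
  e <- suppressWarnings(build_edge_table(cp$R, cp$S))
  expect_equal(nrow(e), choose(6, 2))
  expect_true(all(e$gene_a < e$gene_b))
  expect_false(any(duplicated(e[, c("gene_a", "gene_b")])))
  expect_identical(colnames(e),
                   c("gene_a", "gene_b", "r_R", "r_S", "z_R", "z_S",
                     "delta", "p_value", "lfdr", "significant", "sign"))
})

test_that("edge statistics match a from-scratch scalar recomputation", {
  sim <- generate_expression_pair(
    synthetic_spec(8, module_sizes = 4, rho_R = 0.7, rho_S = 0.1, seed = 6))
  cp <- corr_pair(sim$expr_R, sim$expr_S)
  e <- suppressWarnings(build_edge_table(cp$R, cp$S))
  for (i in seq_len(nrow(e))) {
    ra <- oracle_cor(sim$expr_R[e$gene_a[i], ], sim$expr_R[e$gene_b[i], ])
    rs <- oracle_cor(sim$expr_S[e$gene_a[i], ], sim$expr_S[e$gene_b[i], ])
    za <- 0.5 * log((1 + ra) / (1 - ra))
    zs <- 0.5 * log((1 + rs) / (1 - rs))
    dd <- (za - zs) / sqrt(1 / 3 + 1 / 3)
    expect_equal(e$delta[i], dd, tolerance = 1e-10)
    expect_equal(e$p_value[i], 2 * (1 - pnorm(abs(dd))), tolerance = 1e-10)
  }
})

test_that("condition swap negates delta and sign, preserves p and lfdr", {
  sim <- generate_expression_pair(
    synthetic_spec(20, module_sizes = 10, rho_R = 0.8, rho_S = 0, seed = 7))
  cp <- corr_pair(sim$expr_R, sim$expr_S)
  fwd <- suppressWarnings(build_edge_table(cp$R, cp$S))
  # swapped run: S plays R and vice versa
  swp <- suppressWarnings(build_edge_table(
    correlation_matrix(sim$expr_S, "R"), correlation_matrix(sim$expr_R, "S")))
  expect_equal(swp$delta, -fwd$delta)
  expect_equal(swp$sign, -fwd$sign)
  expect_equal(swp$p_value, fwd$p_value)
  expect_equal(swp$lfdr, fwd$lfdr, tolerance = 1e-12)
})

test_that("gene permutation leaves the edge set unchanged", {
  sim <- generate_expression_pair(synthetic_spec(7, seed = 8))
  cp <- corr_pair(sim$expr_R, sim$expr_S)
  e1 <- suppressWarnings(build_edge_table(cp$R, cp$S))
  perm <- c(4, 1, 7, 3, 6, 2, 5)
  cp2 <- corr_pair(sim$expr_R[perm, ], sim$expr_S[perm, ])
  e2 <- suppressWarnings(build_edge_table(cp2$R, cp2$S))
  expect_equal(e1, e2, ignore_attr = TRUE)
})

test_that("identical inputs give all-zero delta and no significant edge", {
  sim <- generate_expression_pair(synthetic_spec(6, seed = 9))
  e <- build_edge_table(correlation_matrix(sim$expr_R, "R"),
                        correlation_matrix(sim$expr_R, "S"))
  expect_true(all(e$delta == 0))
  expect_true(all(e$lfdr == 1))
  expect_false(any(e$significant))
})

test_that("gene-set mismatch is reported with the symmetric difference", {
  sim <- generate_expression_pair(synthetic_spec(5, seed = 10))
  expect_error(
    build_edge_table(correlation_matrix(sim$expr_R, "R"),
                     correlation_matrix(sim$expr_S[1:4, ], "S")),
    "G0005")
})

test_that("edge table export is stable and round-trips", {
  sim <- generate_expression_pair(synthetic_spec(6, seed = 11))
  cp <- corr_pair(sim$expr_R, sim$expr_S)
  e <- suppressWarnings(build_edge_table(cp$R, cp$S))
  p1 <- withr::local_tempfile(fileext = ".tsv")
  p2 <- withr::local_tempfile(fileext = ".tsv")
  write_edge_table(e, p1)
  write_edge_table(e, p2)
  expect_identical(readLines(p1), readLines(p2))
  back <- read.delim(p1)
  expect_identical(names(back), names(e))
  expect_true(all(back$significant %in% c("true", "false")))
})
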