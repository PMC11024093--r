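test_that("per-gene z-scoring standardises and drops unscorable genes", {
  m <- cbind(g1 = c(1, 2, 3), g2 = c(5, 5, 5), g3 = c(0, 10, 20))
  expect_warning(z <- zscore_genes(m), "zero-variance")
  expect_equal(colnames(z), c("g1", "g3"))
  # hand computation with the n-1 denominator: sd(1,2,3) = 1
  expect_equal(unname(z[, "g1"]), c(-1, 0, 1))
  expect_equal(unname(colMeans(z)), c(0, 0))
  expect_equal(unname(apply(z, 2, sd)), c(1, 1))

  m_na <- cbind(g1 = c(1, NA, 3), g2 = c(1, 2, 4))
  expect_warning(z2 <- zscore_genes(m_na), "missing")
  expect_equal(colnames(z2), "g2")
})

test_that("signature refinement keeps co-expressed genes only", {
  set.seed(61)
  latent <- rnorm(50)
  co <- sapply(1:5, function(i) latent)          # perfectly co-expressed
  anti <- -latent                                # perfectly anti-correlated
  m <- cbind(co, anti) + 0
  colnames(m) <- c(paste0("co", 1:5), "anti")
  m <- m + matrix(rnorm(length(m), sd = 1e-6), nrow = 50)
  z <- zscore_genes(m)
  expect_setequal(refine_signature(z, colnames(m)), paste0("co", 1:5))

  # brute-force per-gene correlation on a structured synthetic matrix
  sim <- simulate_expression(expression_sim_spec(n_tumors = 120,
                                                 noise_sd = 1.5, seed = 62))
  z <- zscore_genes(sim$expr)
  gl <- epimes_gene_lists()
  for (genes in list(gl$epithelial, gl$mesenchymal)) {
    avg <- rowMeans(z[, genes])
    keep_bf <- genes[vapply(genes, function(g) cor(z[, g], avg) > 0.5,
                            logical(1))]
    expect_setequal(refine_signature(z, genes), keep_bf)
  }
  expect_error(refine_signature(z, c(gl$epithelial, "NOT_A_GENE")),
               "absent")
})

test_that("stratification is balanced, ordered and affine-invariant", {
  z <- cbind(E = seq(-2, 2.5, by = 0.5), M = rev(seq(-2, 2.5, by = 0.5)))
  rownames(z) <- sprintf("T%02d", 1:10)
  res <- score_and_stratify(z, "E", "M")
  expect_equal(as.integer(table(res$quintile)), rep(2, 5))
  expect_equal(as.character(res$quintile),
               rep(c("H-MES", "L-MES", "Ambig", "L-EPI", "H-EPI"),
                   each = 2))
  # monotone label order in score
  agg <- tapply(res$score, res$quintile, range)
  for (i in 1:4) expect_lte(max(agg[[i]]), min(agg[[i + 1]]))

  # unbalanced n: sizes within one of each other
  set.seed(63)
  sim <- simulate_expression(expression_sim_spec(n_tumors = 23, seed = 3))
  zz <- zscore_genes(sim$expr)
  gl <- epimes_gene_lists()
  r23 <- score_and_stratify(zz, gl$epithelial, gl$mesenchymal)
  expect_lte(diff(range(table(r23$quintile))), 1)

  # per-gene affine rescaling of raw expression leaves scores unchanged
  sim2 <- sim$expr
  sim2 <- sweep(sweep(sim2, 2, runif(ncol(sim2), 0.5, 3), "*"),
                2, runif(ncol(sim2), -5, 5), "+")
  r_affine <- score_and_stratify(zscore_genes(sim2), gl$epithelial,
                                 gl$mesenchymal)
  expect_equal(r_affine$score, r23$score)
  expect_error(score_and_stratify(zz[1:4, ], gl$epithelial,
                                  gl$mesenchymal), "five tumors")
})

test_that("score tracks the latent axis and extremes are concordant", {
  sim <- simulate_expression(expression_sim_spec(n_tumors = 300,
                                                 noise_sd = 0.5, seed = 64))
  z <- zscore_genes(sim$expr)
  gl <- epimes_gene_lists()
  epi <- refine_signature(z, gl$epithelial)
  mes <- refine_signature(z, gl$mesenchymal)
  res <- score_and_stratify(z, epi, mes)
  expect_gt(cor(res$score, sim$latent, method = "spearman"), 0.9)

  # low-noise extremes land in the extreme quintiles almost always
  lo <- simulate_expression(expression_sim_spec(n_tumors = 300,
                                                noise_sd = 0.1, seed = 65))
  zlo <- zscore_genes(lo$expr)
  rlo <- score_and_stratify(zlo, refine_signature(zlo, gl$epithelial),
                            refine_signature(zlo, gl$mesenchymal))
  top <- order(lo$latent, decreasing = TRUE)[1:30]
  bottom <- order(lo$latent)[1:30]
  conc <- mean(c(rlo$quintile[top] == "H-EPI",
                 rlo$quintile[bottom] == "H-MES"))
  expect_gt(conc, 0.95)
})

test_that("per-stratum marker correlations behave as expected", {
  sim <- simulate_expression(expression_sim_spec(n_tumors = 200, seed = 66))
  strata <- rep(c("A", "B"), each = 100)
  self <- marker_correlations(sim$expr, "VIM", "VIM", strata)
  expect_equal(self$r, c(1, 1))
  expect_true(all(self$p < 1e-10))

  tiny <- marker_correlations(sim$expr[1:5, ], "VIM", "CDH1",
                              c("A", "A", "A", "B", "B"))
  expect_true(is.na(tiny$r[tiny$stratum == "B"]))
  expect_false(is.na(tiny$r[tiny$stratum == "A"]))

  # correlation decays as independent noise is added to a copy
  set.seed(67)
  target <- rnorm(150)
  rs <- sapply(c(0.1, 1, 4), function(s) {
    m <- cbind(T1 = target, M1 = target + rnorm(150, sd = s))
    marker_correlations(m, "T1", "M1", rep("all", 150))$r
  })
  expect_true(all(diff(rs) < 0))
  expect_error(marker_correlations(sim$expr, "NOPE", "VIM", strata),
               "target")
})

test_that("correlation-matrix clustering recovers block structure", {
  set.seed(68)
  lat1 <- rnorm(80); lat2 <- rnorm(80)
  m <- cbind(sapply(1:4, function(i) lat1 + rnorm(80, sd = 0.1)),
             sapply(1:4, function(i) lat2 + rnorm(80, sd = 0.1)))
  colnames(m) <- paste0("g", 1:8)
  cm <- cor(m)
  cl <- cluster_correlation_matrix(cm, k = 2)
  expect_true(partitions_equal(cl$groups, rep(1:2, each = 4)))

  singletons <- cluster_correlation_matrix(cm, k = 8)
  expect_equal(length(unique(singletons$groups)), 8)
  expect_error(cluster_correlation_matrix(cm, k = 9), "exceed")
  expect_error(cluster_correlation_matrix(cm[, 1:3], 2), "square")
})

test_that("clustering matches a naive agglomerative implementation", {
  set.seed(69)
  m <- matrix(rnorm(80 * 20), 80, 20)
  colnames(m) <- sprintf("G%02d", 1:20)
  cm <- cor(m)
  for (k in c(2, 4, 7)) {
    cl <- cluster_correlation_matrix(cm, k)
    expect_true(partitions_equal(cl$groups, bf_average_linkage(cm, k)))
  }
})

test_that("comparative-Ct quantitation follows the exponential rule", {
  q <- ddct_quantitation(c(0, 1, -2))
  expect_equal(q$fold_change, c(1, 0.5, 4))
  expect_equal(q$percent_remaining, c(100, 50, 400))
  expect_equal(q$relative_mrna, c(0, -1, 2))
  expect_error(ddct_quantitation(Inf), "finite")
})
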