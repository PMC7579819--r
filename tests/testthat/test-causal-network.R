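test_that("Hamming distance counts directed-status disagreements", {
  genes <- c("A", "B", "C", "D")
  g1 <- graph_from_edges(genes, c("A", "B"), c("B", "C"))
  expect_equal(hamming_distance(g1, g1), 0)
  empty <- graph_from_edges(genes, character(0), character(0))
  expect_equal(hamming_distance(empty, g1), 2)
  # (A->B, B->C) vs (B->A, B->C, C->D): reversal 2 + extra edge 1
  g2 <- graph_from_edges(genes, c("B", "B", "C"), c("A", "C", "D"))
  expect_equal(hamming_distance(g1, g2), 3)
  g3 <- graph_from_edges(c("A", "B"), "A", "B")
  expect_error(hamming_distance(g1, g3), "gene sets")
})

test_that("learned networks are deterministic and respect IV directionality", {
  st <- synthetic_study(n_cases = 0, n_controls = 300, seed = 13)
  ivs <- build_instruments(st$genotypes, st$genes, st$panel, st$hic,
                           st$expr)
  g1 <- learn_network(st$expr, ivs, alpha = 0.001)
  g2 <- learn_network(st$expr, ivs, alpha = 0.001)
  expect_identical(g1$edges, g2$edges)
  # no edge ever enters an IV node
  iv_ids <- g1$edges$from[g1$edges$type == "iv"]
  expect_false(any(g1$edges$to %in% iv_ids))
  # gene subgraph acyclic
  expect_true(igraph::is_dag(as_igraph(g1)))
})

test_that("skeletons are nested across significance levels", {
  st <- synthetic_study(n_cases = 0, n_controls = 250, seed = 17)
  alphas <- c(0.0005, 0.001, 0.005, 0.01)
  skels <- lapply(alphas, function(a)
    und_pairs(learn_network(st$expr, NULL, alpha = a)$skeleton$from,
              learn_network(st$expr, NULL, alpha = a)$skeleton$to))
  for (i in seq_len(length(alphas) - 1))
    expect_true(all(skels[[i]] %in% skels[[i + 1]]))
})

test_that("a chain with IVs on odd genes is recovered and oriented", {
  iv_genes <- sprintf("c%02d", seq(1, 9, 2))
  base <- chain_system(10, beta = 0.8)
  panel <- snp_panel(paste0("v", 1:5), "chr2", 1:5 * 100000L, 0.3)
  sys <- true_system(base$lambda, base$genes,
                     genetic_effects = data.frame(snp_id = panel$snp_id,
                                                  gene_id = iv_genes,
                                                  effect = 0.7))
  res <- sapply(1:10, function(s) {
    n <- 500
    geno <- simulate_genotypes(panel, n, seed = 400 + s)
    e2 <- simulate_cohorts(sys, geno, 0, n, seed = 900 + s)
    Z <- scale(geno)
    colnames(Z) <- paste0(iv_genes, ".iv1")
    ivs <- instrument_matrix(Z, data.frame(iv_id = colnames(Z),
                                           gene_id = iv_genes))
    g <- learn_network(e2, ivs, alpha = 0.001)
    te <- true_edges(sys); eg <- gene_edges(g)
    truth_dir <- paste(te$from, te$to)
    ivo <- eg[eg$oriented_by == "iv", ]
    c(recall = mean(und_pairs(te$from, te$to) %in%
                      und_pairs(eg$from, eg$to)),
      orient = if (nrow(ivo))
        mean(paste(ivo$from, ivo$to) %in% truth_dir) else NA)
  })
  expect_gte(mean(res["recall", ]), 0.9)
  expect_gte(mean(res["orient", ], na.rm = TRUE), 0.9)
})

test_that("pure-noise data yields almost no edges at small alpha", {
  counts <- vapply(1:10, function(s) {
    set.seed(600 + s)
    e <- expression_matrix(matrix(rnorm(200 * 20), 200,
                                  dimnames = list(NULL, sprintf("n%02d",
                                                                1:20))))
    nrow(gene_edges(learn_network(e, NULL, alpha = 0.001)))
  }, numeric(1))
  n_tests <- 10 * 2 * choose(20, 2)
  bound <- 0.001 * n_tests + 3 * sqrt(n_tests * 0.001 * 0.999)
  expect_lte(sum(counts), bound)
})

test_that("tuning uses the standard grid and is reproducible", {
  sys <- chain_system(6, beta = 0.8)
  e <- sim_expr(sys, 400, seed = 31)
  tr <- tune_by_hamming(e, NULL, n_subsamples = 4, subsample_frac = 0.5,
                        seed = 2)
  expect_equal(tr$report$alpha, c(0.01, 0.005, 0.001, 0.0005))
  # strong signal: every subsample recovers the same chain
  expect_true(any(tr$report$mean_distance == 0))
  expect_equal(tr$report$mean_distance[tr$report$alpha == tr$selected], 0)
  tr2 <- tune_by_hamming(e, NULL, n_subsamples = 4, subsample_frac = 0.5,
                         seed = 2)
  expect_identical(tr$report, tr2$report)
  expect_error(tune_by_hamming(e, NULL, n_subsamples = 2,
                               subsample_frac = 0.01),
               "subsample_frac")
})

test_that("ties in tuning break toward the sparser value", {
  sys <- chain_system(5, beta = 0.8)
  e <- sim_expr(sys, 500, seed = 37)
  tr <- tune_by_hamming(e, NULL, n_subsamples = 3, subsample_frac = 0.6,
                        seed = 5)
  tied <- tr$report$alpha[tr$report$mean_distance ==
                            min(tr$report$mean_distance)]
  expect_equal(tr$selected, min(tied))
})

test_that("permuting isolated genes leaves the network untouched", {
  st <- synthetic_study(n_cases = 0, n_controls = 300, seed = 41)
  g <- learn_network(st$expr, NULL, alpha = 0.001)
  roles <- degrees_and_roles(g)
  expect_true(any(roles$role == "isolated"))
  sr <- permutation_stability(st$expr, NULL, g, role = "isolated",
                              degree = 0, n_perm = 3, seed = 9)
  expect_equal(sr$mean_stability, 1.0, tolerance = 1e-3)
  expect_error(permutation_stability(st$expr, NULL, g,
                                     role = "broadcaster", degree = 5,
                                     n_perm = 2, seed = 1),
               "no eligible")
})

test_that("permutation stability is high on a strong-signal network", {
  sys <- chain_system(8, beta = 0.8)
  # attach two extra receptors to make degree-2 broadcasters: c01 -> x1
  lam <- rbind(cbind(sys$lambda, matrix(0, 8, 1)), matrix(0, 1, 9))
  ids <- c(rownames(sys$lambda), "x01")
  dimnames(lam) <- list(ids, ids)
  lam["x01", "c01"] <- 0.8
  genes <- gene_annotation(ids, "chr1", seq_along(ids) * 1e6,
                           seq_along(ids) * 1e6 + 100)
  sys2 <- true_system(lam, genes)
  e <- sim_expr(sys2, 500, seed = 43)
  g <- learn_network(e, NULL, alpha = 0.001)
  roles <- degrees_and_roles(g)
  expect_true("c01" %in% roles$gene_id[roles$role == "broadcaster" &
                                         roles$out_degree == 2])
  sr <- permutation_stability(e, NULL, g, role = "broadcaster", degree = 2,
                              n_perm = 5, seed = 11)
  expect_gte(sr$mean_stability, 0.9)
  expect_identical(
    sr$per_perm,
    permutation_stability(e, NULL, g, role = "broadcaster", degree = 2,
                          n_perm = 5, seed = 11)$per_perm)
})
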