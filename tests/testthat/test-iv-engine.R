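test_that("cis window selection uses inclusive 40 kb boundaries", {
  gene <- gene_annotation("g", "chr1", 100000L, 120000L)
  panel <- snp_panel(c("s1", "s2", "s3"), "chr1",
                     c(59999L, 60000L, 160000L), 0.3)
  rs <- select_region_snps(gene, panel, hic = NULL, window = 40000)
  expect_setequal(rs$snp_id, c("s2", "s3")) # 59999 excluded, 60000 in
  expect_true(all(rs$provenance == "cis"))

  far <- snp_panel("s9", "chr2", 1000L, 0.3)
  expect_equal(nrow(select_region_snps(gene, far, NULL)), 0)
})

test_that("Hi-C-linked SNPs join the region without duplicates", {
  gene <- gene_annotation("g", "chr1", 1000000L, 1020000L)
  panel <- snp_panel(paste0("s", 1:6), "chr1",
                     c(1000500L, 1010000L, 5000100L, 5000200L, 5000300L,
                       7000000L), 0.3)
  hic <- data.frame(chrom_a = "chr1", start_a = 999999L, end_a = 1001000L,
                    chrom_b = "chr1", start_b = 5000000L, end_b = 5001000L)
  rs <- select_region_snps(gene, panel, hic)
  expect_equal(sum(rs$provenance == "cis"), 2)
  expect_equal(sum(rs$provenance == "hic"), 3)
  expect_false(anyDuplicated(rs$snp_id) > 0)
  # symmetric: anchor order swapped gives the same set
  hic_sw <- hic[, c(4:6, 1:3)]
  names(hic_sw) <- names(hic)
  expect_setequal(select_region_snps(gene, panel, hic_sw)$snp_id, rs$snp_id)
})

test_that("region selection is order-independent across panel layouts", {
  gene <- gene_annotation("g", "chr1", 1000000L, 1020000L)
  p1 <- snp_panel(c("a", "b", "x"), c("chr1", "chr1", "chr2"),
                  c(990000L, 1010000L, 5L), 0.3)
  p2 <- snp_panel(c("x", "a", "b"), c("chr2", "chr1", "chr1"),
                  c(5L, 990000L, 1010000L), 0.3)
  expect_setequal(select_region_snps(gene, p1, NULL)$snp_id,
                  select_region_snps(gene, p2, NULL)$snp_id)
})

test_that("MCA reproduces an independent dense eigendecomposition", {
  set.seed(31)
  geno <- matrix(rbinom(20 * 6, 2, 0.3), 20, 6,
                 dimnames = list(NULL, paste0("s", 1:6)))
  dec <- mca_factor_scores(geno)
  orc <- ca_oracle(geno)
  k <- dec$n_components
  expect_lt(max(abs(dec$lambda[1:k] - orc$values[1:k])), 1e-8)
  # factor scores centered in the row-mass metric
  expect_lt(max(abs(colSums(dec$scores * dec$r))), 1e-10)
  # eigenvalue conservation: sum equals total inertia of the table
  expect_lt(abs(sum(dec$lambda) - sum(orc$S^2)), 1e-8)
})

test_that("MCA reconstruction recovers the correspondence matrix", {
  set.seed(32)
  geno <- matrix(rbinom(15 * 3, 2, 0.4), 15, 3)
  dec <- mca_factor_scores(geno)
  recon <- diag(sqrt(dec$r)) %*% dec$F %*%
    diag(sqrt(dec$lambda), length(dec$lambda)) %*% t(dec$T) %*%
    diag(sqrt(dec$c)) + outer(dec$r, dec$c)
  expect_lt(max(abs(recon - dec$Y)), 1e-8)
})

test_that("monomorphic blocks give zero components with a diagnostic", {
  geno <- matrix(2L, 10, 2)
  dec <- mca_factor_scores(geno)
  expect_equal(dec$n_components, 0)
  expect_equal(ncol(dec$scores), 0)
  expect_false(is.na(dec$diagnostic))
  expect_error(mca_factor_scores(matrix(0:1, 1, 2)), "2 samples")
})

test_that("instrument scores within a region are mass-orthogonal", {
  st <- synthetic_study(n_cases = 0, n_controls = 300, seed = 21)
  ivs <- build_instruments(st$genotypes, st$genes, st$panel, st$hic,
                           st$expr)
  expect_gt(n_instruments(ivs), 0)
  n <- nrow(ivs$scores)
  for (g in unique(ivs$meta$gene_id)) {
    cols <- which(ivs$meta$gene_id == g)
    if (length(cols) < 2) next
    gram <- crossprod(ivs$scores[, cols, drop = FALSE] * sqrt(1 / n))
    expect_lt(max(abs(gram[upper.tri(gram)])), 1e-8)
  }
  # scores invariant to sample reordering (up to the same reordering)
  ord <- rev(seq_len(nrow(st$expr)))
  geno2 <- st$genotypes[ord, ]
  attr(geno2, "panel") <- st$panel
  expr2 <- expression_matrix(unclass(st$expr)[ord, ],
                             expr_cohort(st$expr)[ord])
  ivs2 <- build_instruments(geno2, st$genes, st$panel, st$hic, expr2)
  expect_equal(ivs2$scores[rownames(ivs$scores), ], ivs$scores,
               tolerance = 1e-10)
})

test_that("a cis effect of 0.5 at n = 300 yields a strong IV almost always", {
  genes <- gene_annotation("g1", "chr1", 1000000L, 1020000L)
  panel <- snp_panel("s1", "chr1", 1005000L, 0.3)
  lam <- matrix(0, 1, 1)
  sys <- true_system(lam, genes,
                     genetic_effects = data.frame(snp_id = "s1",
                                                  gene_id = "g1",
                                                  effect = 0.5))
  hits <- vapply(1:200, function(r) {
    geno <- simulate_genotypes(panel, 300, seed = 1000 + r)
    expr <- simulate_cohorts(sys, geno, 0, 300, seed = 2000 + r)
    ivs <- build_instruments(geno, genes, panel, NULL, expr)
    n_instruments(ivs) >= 1 && any(ivs$meta$F > 10)
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("nothing passing the strength screen gives an empty matrix", {
  st <- synthetic_study(n_cases = 0, n_controls = 100, seed = 8)
  noise <- expression_matrix(
    matrix(rnorm(100 * 30), 100,
           dimnames = list(rownames(st$expr), colnames(st$expr))))
  ivs <- build_instruments(st$genotypes, st$genes, st$panel, st$hic, noise,
                           f_threshold = 1e6)
  expect_equal(n_instruments(ivs), 0)
})

test_that("validity screen retains valid IVs at close to the nominal rate", {
  kept <- vapply(1:200, function(r) {
    set.seed(100 + r)
    n <- 300
    z <- rnorm(n)                     # valid IV: touches y only through x
    x <- 0.6 * z + rnorm(n)
    y <- 0.7 * x + rnorm(n)
    w <- rnorm(n)
    expr <- expression_matrix(cbind(x = x, y = y, w = w))
    rownames(expr) <- sprintf("S%03d", 1:n)
    ivs <- instrument_matrix(matrix(z, dimnames = list(rownames(expr),
                                                       "x.iv1")),
                             data.frame(iv_id = "x.iv1", gene_id = "x"))
    n_instruments(validate_instruments(ivs, expr, 0.05)) == 1
  }, logical(1))
  expect_gte(mean(kept), (1 - 0.05) - 0.03)
})

test_that("pleiotropic IVs are removed by the validity screen", {
  removed <- vapply(1:200, function(r) {
    set.seed(300 + r)
    n <- 500
    z <- rnorm(n)
    x <- 0.6 * z + rnorm(n)
    y <- 0.5 * x + 0.4 * z + rnorm(n)  # direct path z -> y: violation
    expr <- expression_matrix(cbind(x = x, y = y))
    rownames(expr) <- sprintf("S%03d", 1:n)
    ivs <- instrument_matrix(matrix(z, dimnames = list(rownames(expr),
                                                       "x.iv1")),
                             data.frame(iv_id = "x.iv1", gene_id = "x"))
    n_instruments(validate_instruments(ivs, expr, 0.05)) == 0
  }, logical(1))
  expect_gte(mean(removed), 0.8)
})
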