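#' Default synthetic gene annotation (30 genes)
#'
#' Thirty genes on one chromosome, spaced 1 Mb apart with 20 kb bodies, so
#' that +/-40 kb cis windows never overlap between neighbours.
#'
#' @return a [gene_annotation()].
#' @export
default_gene_annotation <- function() {
  i <- 1:30
  gene_annotation(gene_id = sprintf("g%02d", i), chrom = "chr1",
                  tss = i * 1000000L, tes = i * 1000000L + 20000L)
}

# deterministic cycling helpers for effect sizes and MAFs
.cycle <- function(vals, n) rep_len(vals, n)

#' Default ground-truth causal system (30 genes, chain + hub topology)
#'
#' Two 8-gene chains, two 5-gene hub stars (out-degree 4), one mediator with
#' two upstream effectors and one downstream gene, and two isolated genes.
#' Effect magnitudes cycle through \[0.5, 0.8\] with occasional repression
#' (negative sign). Half of the genes (the odd-numbered ones) carry genetic
#' effects: one cis SNP (effect 0.7/allele) and one SNP inside their first
#' Hi-C distal anchor (effect 0.5/allele). The case cohort loses the
#' mediator edge g27 -> g28.
#'
#' @param hic the [simulate_hic_map()] used to place distal causal SNPs
#'   (needed so the panel and the genetic effects agree); pass the map built
#'   by [synthetic_study()].
#' @param panel the matching [snp_panel()] from [default_snp_panel()].
#' @return a [true_system()].
#' @export
default_true_system <- function(hic, panel) {
  genes <- default_gene_annotation()
  p <- nrow(genes)
  edges <- rbind(
    data.frame(from = sprintf("g%02d", 1:7), to = sprintf("g%02d", 2:8)),
    data.frame(from = sprintf("g%02d", 9:15), to = sprintf("g%02d", 10:16)),
    data.frame(from = "g17", to = sprintf("g%02d", 18:21)),
    data.frame(from = "g22", to = sprintf("g%02d", 23:26)),
    data.frame(from = c("g08", "g16", "g27"), to = c("g27", "g27", "g28")))
  betas <- .cycle(c(0.8, 0.65, -0.5, 0.7, 0.55, -0.6, 0.75), nrow(edges))
  lam <- matrix(0, p, p, dimnames = list(genes$gene_id, genes$gene_id))
  for (k in seq_len(nrow(edges))) lam[edges$to[k], edges$from[k]] <- betas[k]
  iv_genes <- sprintf("g%02d", seq(1, 29, by = 2))
  ge <- do.call(rbind, lapply(iv_genes, function(g) {
    cis <- paste0(g, "_cis2")
    dist <- paste0(g, "_hic1")
    data.frame(snp_id = c(cis, if (dist %in% panel$snp_id) dist),
               gene_id = g,
               effect = c(0.7, if (dist %in% panel$snp_id) 0.5),
               stringsAsFactors = FALSE)
  }))
  loadings <- matrix(0, p, 4,
                     dimnames = list(genes$gene_id,
                                     c("cov1", "cov2", "cov3", "batch")))
  loadings[, "cov1"] <- 0.3
  loadings[1:10, "batch"] <- 0.4
  true_system(lambda = lam, genes = genes, genetic_effects = ge,
              sigma2 = 1,
              deleted_edges_cases = data.frame(from = "g27", to = "g28",
                                               stringsAsFactors = FALSE),
              covariate_loadings = loadings)
}

#' Default synthetic SNP panel (150 SNPs)
#'
#' Four cis SNPs per gene (inside the gene body) plus one SNP at the
#' midpoint of each gene's first Hi-C distal anchor. MAFs cycle through
#' \{0.15, 0.25, 0.35, 0.45, 0.3, 0.2, 0.4\}.
#'
#' @param hic a [simulate_hic_map()] over [default_gene_annotation()].
#' @return a [snp_panel()].
#' @export
default_snp_panel <- function(hic) {
  genes <- default_gene_annotation()
  offs <- c(2000L, 6000L, 11000L, 16000L)
  cis <- do.call(rbind, lapply(seq_len(nrow(genes)), function(i) {
    data.frame(snp_id = paste0(genes$gene_id[i], "_cis", 1:4),
               chrom = genes$chrom[i], pos = genes$start[i] + offs,
               stringsAsFactors = FALSE)
  }))
  dist <- do.call(rbind, lapply(genes$gene_id, function(g) {
    h <- hic[hic$gene_id == g, , drop = FALSE]
    if (!nrow(h)) return(NULL)
    mid <- as.integer((h$start_b[1] + h$end_b[1]) %/% 2) + 1L
    data.frame(snp_id = paste0(g, "_hic1"), chrom = h$chrom_b[1],
               pos = mid, stringsAsFactors = FALSE)
  }))
  tab <- rbind(cis, dist)
  tab <- tab[order(tab$chrom, tab$pos), , drop = FALSE]
  # nudge any coincident positions apart (strictly increasing required)
  while (any(dup <- duplicated(tab[c("chrom", "pos")]))) {
    tab$pos[dup] <- tab$pos[dup] + 1L
    tab <- tab[order(tab$chrom, tab$pos), , drop = FALSE]
  }
  snp_panel(tab$snp_id, tab$chrom, tab$pos,
            maf = .cycle(c(0.15, 0.25, 0.35, 0.45, 0.3, 0.2, 0.4), nrow(tab)))
}

#' Simulate the full default study
#'
#' One call that builds the default annotation, Hi-C map, SNP panel,
#' genotypes, covariates and two-cohort expression (controls with the full
#' effect matrix, cases with the mediator edge g27 -> g28 deleted), and
#' residualizes expression on the covariates. All stage seeds are derived
#' deterministically from `seed`.
#'
#' @param n_cases,n_controls cohort sizes (default 300 each).
#' @param seed integer master seed.
#' @param residualize residualize expression on the covariates (default TRUE).
#' @return list of class `synthetic_study` with elements `genes`, `hic`,
#'   `panel`, `system`, `genotypes`, `covariates`, `expr_raw`, `expr`.
#' @export
synthetic_study <- function(n_cases = 300L, n_controls = 300L, seed = 1L,
                            residualize = TRUE) {
  seed <- as.integer(seed)
  genes <- default_gene_annotation()
  hic <- simulate_hic_map(genes, n_distal_per_gene = 2L,
                          anchor_width = 10000L, min_gap = 300000L,
                          seed = seed + 1L)
  panel <- default_snp_panel(hic)
  system <- default_true_system(hic, panel)
  n <- n_cases + n_controls
  genotypes <- simulate_genotypes(panel, n, seed = seed + 2L)
  covariates <- simulate_covariates(n, seed = seed + 3L)
  expr_raw <- simulate_cohorts(system, genotypes, n_cases = n_cases,
                               n_controls = n_controls,
                               covariates = covariates, seed = seed + 4L)
  expr <- if (residualize) residualize_expression(expr_raw, covariates)
          else expr_raw
  structure(list(genes = genes, hic = hic, panel = panel, system = system,
                 genotypes = genotypes, covariates = covariates,
                 expr_raw = expr_raw, expr = expr, seed = seed),
            class = "synthetic_study")
}

#' @export
print.synthetic_study <- function(x, ...) {
  cat("synthetic_study:", nrow(x$expr), "samples x", ncol(x$expr), "genes;",
      nrow(x$panel), "SNPs;", sum(expr_cohort(x$expr) == "case"), "cases /",
      sum(expr_cohort(x$expr) == "control"), "controls; seed", x$seed, "\n")
  invisible(x)
}

#' Ground-truth system for the permutation-stability harness
#'
#' A large star-motif system designed so that the network holds at least ten
#' broadcasters of each out-degree 1..5 and ten receptors of each in-degree
#' 1..5: for each degree d, ten "hub" stars (one broadcaster feeding d
#' leaves) and, for d >= 2, ten "sink" stars (d dedicated feeder genes into
#' one receptor). All effects are 0.8, residual variances 1; no genetic or
#' covariate terms. 380 genes, 290 edges.
#'
#' @return a [true_system()].
#' @export
stability_true_system <- function() {
  ids <- character(0)
  edges <- list()
  for (d in 1:5) for (i in 1:10) {
    hub <- sprintf("h%d_%02d", d, i)
    leaves <- sprintf("l%d_%02d_%d", d, i, seq_len(d))
    ids <- c(ids, hub, leaves)
    edges[[length(edges) + 1L]] <- data.frame(from = hub, to = leaves,
                                              stringsAsFactors = FALSE)
  }
  for (d in 2:5) for (i in 1:10) {
    feeders <- sprintf("f%d_%02d_%d", d, i, seq_len(d))
    sink <- sprintf("s%d_%02d", d, i)
    ids <- c(ids, feeders, sink)
    edges[[length(edges) + 1L]] <- data.frame(from = feeders, to = sink,
                                              stringsAsFactors = FALSE)
  }
  ed <- do.call(rbind, edges)
  p <- length(ids)
  genes <- gene_annotation(gene_id = ids, chrom = "chr1",
                           tss = seq_len(p) * 1000000L,
                           tes = seq_len(p) * 1000000L + 20000L)
  lam <- matrix(0, p, p, dimnames = list(ids, ids))
  for (k in seq_len(nrow(ed))) lam[ed$to[k], ed$from[k]] <- 0.8
  true_system(lambda = lam, genes = genes, sigma2 = 1)
}

#' Simulate expression for the stability harness
#'
#' @param n number of samples (must exceed the 380 genes; default 800).
#' @param seed integer seed.
#' @return list with elements `system` and `expr`.
#' @export
stability_study <- function(n = 800L, seed = 1L) {
  system <- stability_true_system()
  p <- nrow(system$lambda)
  if (n <= p) stop("n must exceed the number of genes (", p, ")")
  panel <- snp_panel("dummy", "chr1", 1L, 0.5)
  geno <- simulate_genotypes(panel, n, seed = seed + 1L)
  expr <- simulate_cohorts(system, geno, n_cases = 0L, n_controls = n,
                           seed = seed + 2L)
  list(system = system, expr = expr)
}
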