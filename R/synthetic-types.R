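#' SNP panel
#'
#' A table of biallelic SNPs with genomic coordinates and minor-allele
#' frequencies, the sampling frame for [simulate_genotypes()] and the
#' coordinate source for [select_region_snps()].
#'
#' @param snp_id character vector of unique SNP identifiers.
#' @param chrom chromosome name per SNP.
#' @param pos 1-based basepair position per SNP (VCF convention); positions
#'   must be strictly increasing within each chromosome.
#' @param maf minor-allele frequency per SNP, in (0, 0.5].
#'
#' @return A `data.frame` of class `snp_panel` with one row per SNP.
#' @export
snp_panel <- function(snp_id, chrom, pos, maf) {
  stopifnot(length(snp_id) == length(pos))
  chrom <- rep_len(chrom, length(snp_id))
  maf <- rep_len(maf, length(snp_id))
  if (anyDuplicated(snp_id)) stop("duplicate snp_id in panel")
  if (any(maf <= 0 | maf > 0.5)) stop("maf must be in (0, 0.5]")
  pos <- as.integer(pos)
  for (ch in unique(chrom)) {
    p <- pos[chrom == ch]
    if (is.unsorted(p, strictly = TRUE))
      stop("positions must be strictly increasing within chromosome ", ch)
  }
  out <- data.frame(snp_id = as.character(snp_id), chrom = as.character(chrom),
                    pos = pos, maf = as.numeric(maf),
                    stringsAsFactors = FALSE)
  class(out) <- c("snp_panel", "data.frame")
  out
}

#' Gene annotation table
#'
#' BED-like gene coordinates. `tss`/`tes` are given in transcription order
#' and normalized internally so that start <= end in genomic coordinates.
#'
#' @param gene_id unique gene identifiers.
#' @param chrom chromosome per gene.
#' @param tss,tes transcription start / end site (1-based basepairs).
#' @param strand `"+"` or `"-"` per gene.
#' @return A `data.frame` of class `gene_annotation` with columns `gene_id`,
#'   `chrom`, `start`, `end` (genomic order), `strand`.
#' @export
gene_annotation <- function(gene_id, chrom, tss, tes, strand = "+") {
  chrom <- rep_len(chrom, length(gene_id))
  if (anyDuplicated(gene_id)) stop("duplicate gene_id")
  strand <- rep_len(strand, length(gene_id))
  if (!all(strand %in% c("+", "-"))) stop("strand must be '+' or '-'")
  start <- pmin(as.integer(tss), as.integer(tes))
  end <- pmax(as.integer(tss), as.integer(tes))
  out <- data.frame(gene_id = as.character(gene_id),
                    chrom = as.character(chrom),
                    start = start, end = end, strand = strand,
                    stringsAsFactors = FALSE)
  class(out) <- c("gene_annotation", "data.frame")
  out
}

#' Ground-truth causal system for the synthetic generator
#'
#' Bundles everything [simulate_cohorts()] needs: the gene-gene effect matrix
#' (strictly lower-triangular in the generating topological order, hence
#' acyclic), per-SNP genetic effects, residual variances, the mediator edges
#' deleted in the case cohort, and nuisance-covariate loadings.
#'
#' @param lambda numeric genes x genes matrix; `lambda[i, j]` is the direct
#'   effect of gene `j` on gene `i`. Must be strictly lower-triangular.
#' @param genes a [gene_annotation()] whose `gene_id` order matches `lambda`.
#' @param genetic_effects data.frame with columns `snp_id`, `gene_id`,
#'   `effect` (per-allele additive effect on expression), or `NULL`.
#' @param sigma2 per-gene residual variances (> 0); recycled if length 1.
#' @param deleted_edges_cases data.frame with columns `from` (mediator) and
#'   `to` (downstream); each pair must be a nonzero entry of `lambda`. These
#'   edges are zeroed when generating the case cohort.
#' @param covariate_loadings genes x covariates numeric matrix or `NULL`.
#' @return An object of class `true_system`.
#' @export
true_system <- function(lambda, genes, genetic_effects = NULL, sigma2 = 1,
                        deleted_edges_cases = NULL,
                        covariate_loadings = NULL) {
  stopifnot(is.matrix(lambda), nrow(lambda) == ncol(lambda))
  p <- nrow(lambda)
  stopifnot(inherits(genes, "gene_annotation"), nrow(genes) == p)
  if (any(lambda[upper.tri(lambda, diag = TRUE)] != 0))
    stop("lambda must be strictly lower-triangular (acyclic generating order)")
  dimnames(lambda) <- list(genes$gene_id, genes$gene_id)
  sigma2 <- rep_len(as.numeric(sigma2), p)
  if (any(sigma2 <= 0)) stop("sigma2 must be positive")
  names(sigma2) <- genes$gene_id
  if (!is.null(genetic_effects)) {
    stopifnot(all(c("snp_id", "gene_id", "effect") %in% names(genetic_effects)))
    if (!all(genetic_effects$gene_id %in% genes$gene_id))
      stop("genetic_effects reference unknown genes")
  }
  if (!is.null(deleted_edges_cases) && nrow(deleted_edges_cases)) {
    stopifnot(all(c("from", "to") %in% names(deleted_edges_cases)))
    ok <- mapply(function(f, t) lambda[t, f] != 0,
                 deleted_edges_cases$from, deleted_edges_cases$to)
    if (!all(ok))
      stop("deleted_edges_cases must be nonzero entries of lambda")
  }
  if (!is.null(covariate_loadings)) {
    stopifnot(is.matrix(covariate_loadings), nrow(covariate_loadings) == p)
    rownames(covariate_loadings) <- genes$gene_id
  }
  structure(list(lambda = lambda, genes = genes,
                 genetic_effects = genetic_effects, sigma2 = sigma2,
                 deleted_edges_cases = deleted_edges_cases,
                 covariate_loadings = covariate_loadings),
            class = "true_system")
}

#' @export
print.true_system <- function(x, ...) {
  cat("true_system:", nrow(x$lambda), "genes,",
      sum(x$lambda != 0), "causal edges,",
      if (is.null(x$genetic_effects)) 0L else nrow(x$genetic_effects),
      "genetic effects,",
      if (is.null(x$deleted_edges_cases)) 0L else nrow(x$deleted_edges_cases),
      "edges deleted in cases\n")
  invisible(x)
}

#' True gene-gene edges of a synthetic system
#'
#' @param system a [true_system()].
#' @return data.frame with columns `from`, `to`, `effect` (one row per
#'   nonzero entry of the effect matrix).
#' @export
true_edges <- function(system) {
  stopifnot(inherits(system, "true_system"))
  idx <- which(system$lambda != 0, arr.ind = TRUE)
  out <- data.frame(from = colnames(system$lambda)[idx[, 2]],
                    to = rownames(system$lambda)[idx[, 1]],
                    effect = system$lambda[idx],
                    stringsAsFactors = FALSE)
  out[order(out$from, out$to), , drop = FALSE]
}
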