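#' Select SNPs in a gene's cis window and Hi-C-linked regions
#'
#' The cis window is `[start - window, end + window]`, inclusive on both
#' ends (SNP positions are 1-based, VCF convention). A SNP is Hi-C-linked
#' when it falls inside an anchor whose paired anchor overlaps the cis
#' window (anchors are 0-based half-open, BEDPE convention). Strand is
#' ignored: the window is symmetric around the gene span.
#'
#' @param gene single row of a [gene_annotation()].
#' @param panel a [snp_panel()].
#' @param hic a [simulate_hic_map()]-style data.frame or `NULL`.
#' @param window cis half-width in basepairs (default 40000).
#' @return data.frame of class `region_snp_set` with columns `gene_id`,
#'   `snp_id`, `provenance` (`"cis"` or `"hic"`), ordered by genomic
#'   position; zero rows when nothing qualifies.
#' @export
select_region_snps <- function(gene, panel, hic = NULL, window = 40000L) {
  stopifnot(nrow(gene) == 1, inherits(panel, "snp_panel"))
  snp_gr <- GenomicRanges::GRanges(panel$chrom,
                                   IRanges::IRanges(panel$pos, panel$pos))
  win_gr <- GenomicRanges::GRanges(
    gene$chrom, IRanges::IRanges(max(1L, gene$start - window),
                                 gene$end + window))
  cis_idx <- S4Vectors::queryHits(
    suppressWarnings(GenomicRanges::findOverlaps(snp_gr, win_gr)))
  hic_idx <- integer(0)
  if (!is.null(hic) && nrow(hic)) {
    a_gr <- GenomicRanges::GRanges(hic$chrom_a,
                                   IRanges::IRanges(hic$start_a + 1L,
                                                    pmax(hic$end_a,
                                                         hic$start_a + 1L)))
    b_gr <- GenomicRanges::GRanges(hic$chrom_b,
                                   IRanges::IRanges(hic$start_b + 1L,
                                                    pmax(hic$end_b,
                                                         hic$start_b + 1L)))
    a_hit <- S4Vectors::queryHits(
      suppressWarnings(GenomicRanges::findOverlaps(a_gr, win_gr)))
    b_hit <- S4Vectors::queryHits(
      suppressWarnings(GenomicRanges::findOverlaps(b_gr, win_gr)))
    paired <- c(b_gr[a_hit], a_gr[b_hit])
    if (length(paired))
      hic_idx <- S4Vectors::queryHits(
        suppressWarnings(GenomicRanges::findOverlaps(snp_gr, paired)))
  }
  idx <- sort(unique(c(cis_idx, hic_idx)))
  prov <- ifelse(idx %in% cis_idx, "cis", "hic")
  out <- data.frame(gene_id = rep(gene$gene_id, length(idx)),
                    snp_id = panel$snp_id[idx], provenance = prov,
                    stringsAsFactors = FALSE)
  ord <- order(panel$chrom[idx], panel$pos[idx])
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("region_snp_set", "data.frame")
  out
}

#' Multiple correspondence analysis of a genotype block
#'
#' Builds the 0/1 indicator matrix over the observed categories of each SNP
#' (categories {0, 1, 2}; zero-count categories dropped), scales it by its
#' grand total into the correspondence matrix `Y`, and computes the singular
#' value decomposition of the doubly standardized residual
#' `R^{-1/2} (Y - r c^T) C^{-1/2} = F Lambda^{1/2} T^t`, where `r` and `c`
#' are row and column masses. Row factor scores are
#' `R^{-1/2} F Lambda^{1/2}`.
#'
#' @param geno_sub samples x SNPs matrix with entries in {0, 1, 2}
#'   (>= 2 samples, >= 1 SNP).
#' @param tol singular values with `d^2 <= tol` count as non-informative.
#' @return list of class `ca_decomposition` with elements `Y`, `r`, `c`,
#'   `F`, `T`, `lambda` (eigenvalues, descending), `scores` (samples x
#'   informative components), `n_components`, `categories` (data.frame
#'   mapping indicator columns to SNP and genotype category), `diagnostic`.
#'   A block with no genetic variation yields `n_components = 0` and a
#'   diagnostic message, never an error.
#' @export
mca_factor_scores <- function(geno_sub, tol = 1e-12) {
  geno_sub <- as.matrix(geno_sub)
  n <- nrow(geno_sub); m <- ncol(geno_sub)
  if (n < 2) stop("need at least 2 samples")
  if (m < 1) stop("need at least 1 SNP")
  if (!all(geno_sub %in% c(0, 1, 2))) stop("genotypes must be in {0,1,2}")
  snp_ids <- colnames(geno_sub)
  if (is.null(snp_ids)) snp_ids <- paste0("snp", seq_len(m))
  cols <- list(); cat_tab <- list()
  for (j in seq_len(m)) {
    lev <- sort(unique(geno_sub[, j]))
    for (l in lev) {
      cols[[length(cols) + 1L]] <- as.numeric(geno_sub[, j] == l)
      cat_tab[[length(cat_tab) + 1L]] <-
        data.frame(snp_id = snp_ids[j], category = l,
                   stringsAsFactors = FALSE)
    }
  }
  ind <- do.call(cbind, cols)
  categories <- do.call(rbind, cat_tab)
  colnames(ind) <- paste(categories$snp_id, categories$category, sep = ".")
  Y <- ind / sum(ind)
  r <- rowSums(Y); c <- colSums(Y)
  S <- (Y - outer(r, c)) / outer(sqrt(r), sqrt(c))
  sv <- svd(S)
  # deterministic sign convention: the largest-|.| entry of each right
  # singular vector is positive (ties to the earliest category column)
  for (j in seq_along(sv$d)) {
    idx <- which.max(abs(sv$v[, j]))
    if (sv$v[idx, j] < 0) {
      sv$v[, j] <- -sv$v[, j]
      sv$u[, j] <- -sv$u[, j]
    }
  }
  lambda <- sv$d^2
  informative <- which(lambda > tol)
  scores <- if (length(informative)) {
    sc <- (sv$u[, informative, drop = FALSE] *
             rep(sv$d[informative], each = n)) / sqrt(r)
    colnames(sc) <- paste0("dim", seq_along(informative))
    rownames(sc) <- rownames(geno_sub)
    sc
  } else matrix(0, n, 0, dimnames = list(rownames(geno_sub), NULL))
  diagnostic <- if (!length(informative))
    "no genetic variation in block: 0 informative components" else NA_character_
  structure(list(Y = Y, r = r, c = c, F = sv$u, T = sv$v, lambda = lambda,
                 scores = scores, n_components = length(informative),
                 categories = categories, diagnostic = diagnostic),
            class = "ca_decomposition")
}

#' Construct an instrument matrix
#'
#' Container for genotype-derived instrumental variables: a samples x IVs
#' score matrix plus per-IV metadata.
#'
#' @param scores numeric samples x IVs matrix (colnames are IV ids).
#' @param meta data.frame with at least columns `iv_id` and `gene_id`
#'   (the instrumented/exposure gene), one row per score column.
#' @return object of class `instrument_matrix`.
#' @export
instrument_matrix <- function(scores, meta) {
  stopifnot(is.matrix(scores), nrow(meta) == ncol(scores),
            all(c("iv_id", "gene_id") %in% names(meta)))
  colnames(scores) <- meta$iv_id
  structure(list(scores = scores, meta = meta), class = "instrument_matrix")
}

#' @export
print.instrument_matrix <- function(x, ...) {
  cat("instrument_matrix:", ncol(x$scores), "IVs for",
      length(unique(x$meta$gene_id)), "genes over", nrow(x$scores),
      "samples\n")
  invisible(x)
}

#' Number of IVs in an instrument matrix
#' @param ivs an [instrument_matrix()].
#' @return integer count.
#' @export
n_instruments <- function(ivs) if (is.null(ivs)) 0L else ncol(ivs$scores)

#' Build instrumental variables for every gene
#'
#' Per gene: select the region SNPs (cis window plus Hi-C-linked), run
#' multiple correspondence analysis on the genotype block, and retain the
#' components most strongly associated with the gene's own transcript:
#' components are ranked by their regression F-statistic against the
#' transcript, kept only while F reaches `f_threshold` (the weak-instrument
#' screen), and capped at `max_components` per region. Genotype MCA spectra
#' are typically flat, so strength against the transcript -- not eigenvalue
#' -- decides which components carry cis-regulatory signal.
#'
#' @param genotypes a [simulate_genotypes()]-style matrix.
#' @param genes a [gene_annotation()].
#' @param panel the matching [snp_panel()].
#' @param hic Hi-C contact map or `NULL`.
#' @param expr an [expression_matrix()] with the same samples, same order,
#'   as `genotypes`.
#' @param window cis half-width (bp).
#' @param f_threshold minimum strength F-statistic (default 10).
#' @param max_components retention cap per gene region (default 5).
#' @return an [instrument_matrix()]; zero columns when no component passes
#'   (network learning then proceeds without IV anchors).
#' @export
build_instruments <- function(genotypes, genes, panel, hic, expr,
                              window = 40000L, f_threshold = 10,
                              max_components = 5L) {
  if (!identical(rownames(genotypes), rownames(expr)))
    stop("genotype and expression samples must be identical and aligned")
  n <- nrow(expr)
  score_cols <- list(); meta <- list()
  for (i in seq_len(nrow(genes))) {
    gid <- genes$gene_id[i]
    if (!gid %in% colnames(expr)) {
      warning("gene ", gid, " absent from expression matrix; skipped")
      next
    }
    region <- select_region_snps(genes[i, ], panel, hic, window)
    if (!nrow(region)) next
    dec <- mca_factor_scores(genotypes[, region$snp_id, drop = FALSE])
    if (dec$n_components == 0) next
    lam <- dec$lambda[seq_len(dec$n_components)]
    y <- expr[, gid]
    r2 <- suppressWarnings(as.vector(cor(dec$scores, y))^2)
    r2[!is.finite(r2)] <- 0
    Fst <- (n - 2) * r2 / pmax(1 - r2, 1e-300)
    # strength-ranked retention: strongest components first, up to the cap
    keep <- order(-Fst, seq_along(Fst))
    keep <- keep[Fst[keep] >= f_threshold]
    keep <- keep[seq_len(min(length(keep), max_components))]
    for (k in keep) {
      iv_id <- paste0(gid, ".iv", k)
      score_cols[[iv_id]] <- dec$scores[, k]
      meta[[iv_id]] <- data.frame(
        iv_id = iv_id, gene_id = gid, component = k,
        eigenvalue = lam[k], F = Fst[k], n_snps = nrow(region),
        stringsAsFactors = FALSE)
    }
  }
  if (!length(score_cols))
    return(instrument_matrix(
      matrix(0, n, 0, dimnames = list(rownames(expr), NULL)),
      data.frame(iv_id = character(), gene_id = character(),
                 component = integer(), eigenvalue = numeric(),
                 F = numeric(), n_snps = integer(),
                 stringsAsFactors = FALSE)))
  sc <- do.call(cbind, score_cols)
  rownames(sc) <- rownames(expr)
  instrument_matrix(sc, do.call(rbind, c(meta, list(make.row.names = FALSE))))
}

#' Screen instruments against the exclusion restriction
#'
#' For each IV of exposure gene `e` and every candidate outcome gene
#' `o != e`, tests the association of the IV with `o` conditional on `e`
#' (partial-regression t-test). P-values are Benjamini-Hochberg adjusted
#' across all IV x outcome tests; an IV with any adjusted p below
#' `alpha_validity` shows evidence of a path to an outcome not through its
#' exposure (e.g. pleiotropy) and is dropped.
#'
#' @param ivs an [instrument_matrix()] (nonempty).
#' @param expr an [expression_matrix()] aligned to the IV samples.
#' @param alpha_validity significance level after FDR (default 0.05).
#' @return the filtered [instrument_matrix()]; metadata gains
#'   `validity_min_q` and `validity` (`"pass"`/`"fail"` kept in the
#'   attribute table), and the full per-outcome test table is attached as
#'   element `validity`.
#' @export
validate_instruments <- function(ivs, expr, alpha_validity = 0.05) {
  stopifnot(inherits(ivs, "instrument_matrix"))
  if (n_instruments(ivs) == 0) stop("ivs is empty")
  n <- nrow(expr)
  genes <- colnames(expr)
  tests <- list()
  for (e in unique(ivs$meta$gene_id)) {
    iv_idx <- which(ivs$meta$gene_id == e)
    xe <- cbind(1, expr[, e])
    qe <- qr(xe)
    Rz <- qr.resid(qe, ivs$scores[, iv_idx, drop = FALSE])
    out_genes <- setdiff(genes, e)
    Ro <- qr.resid(qe, unclass_expr(expr)[, out_genes, drop = FALSE])
    pc <- suppressWarnings(cor(Rz, Ro))
    pc[!is.finite(pc)] <- 0
    df <- n - 3
    tstat <- pc * sqrt(df / pmax(1 - pc^2, 1e-300))
    pv <- 2 * pt(-abs(tstat), df)
    tests[[e]] <- data.frame(
      iv_id = rep(ivs$meta$iv_id[iv_idx], times = length(out_genes)),
      exposure = e,
      outcome = rep(out_genes, each = length(iv_idx)),
      p = as.vector(pv), stringsAsFactors = FALSE)
  }
  tab <- do.call(rbind, c(tests, list(make.row.names = FALSE)))
  tab$q <- bh_adjust(tab$p)
  min_q <- tapply(tab$q, tab$iv_id, min)
  meta <- ivs$meta
  meta$validity_min_q <- as.numeric(min_q[meta$iv_id])
  meta$validity <- ifelse(meta$validity_min_q < alpha_validity,
                          "fail", "pass")
  keep <- which(meta$validity == "pass")
  out <- instrument_matrix(ivs$scores[, keep, drop = FALSE],
                           meta[keep, , drop = FALSE])
  out$validity <- tab
  out$validity_alpha <- alpha_validity
  out$dropped <- meta$iv_id[meta$validity == "fail"]
  out
}
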