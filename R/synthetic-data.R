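#' Simulate genotypes under Hardy-Weinberg equilibrium
#'
#' Each sample's genotype at each SNP is an independent Binomial(2, maf)
#' draw, i.e. additive coding {0, 1, 2} of the minor-allele count.
#'
#' @param panel a [snp_panel()].
#' @param n_samples number of samples (>= 1).
#' @param seed integer seed; the draw is fully reproducible.
#' @return Integer matrix (samples x SNPs) of class `genotype_matrix` with
#'   sample ids as rownames, SNP ids as colnames, and the panel attached as
#'   attribute `"panel"`.
#' @export
simulate_genotypes <- function(panel, n_samples, seed = 1L) {
  stopifnot(inherits(panel, "snp_panel"), n_samples >= 1)
  withr_seed(seed, {
    g <- vapply(panel$maf, function(m) rbinom(n_samples, 2L, m),
                integer(n_samples))
  })
  g <- matrix(as.integer(g), nrow = n_samples,
              dimnames = list(sprintf("S%04d", seq_len(n_samples)),
                              panel$snp_id))
  attr(g, "panel") <- panel
  class(g) <- c("genotype_matrix", class(g))
  g
}

# evaluate expr under a local RNG state (restores the caller's state)
withr_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

#' Simulate a Hi-C contact map linking genes to distal anchors
#'
#' For each gene one anchor covers the gene body and `n_distal_per_gene`
#' distal anchors are placed on the same chromosome at least `min_gap`
#' basepairs away from the extended cis window `[start - cis_window,
#' end + cis_window]`, so distal anchors never overlap the cis window.
#' Anchors use the 0-based half-open BEDPE convention.
#'
#' @param genes a [gene_annotation()].
#' @param n_distal_per_gene distal anchors per gene (0 allowed).
#' @param anchor_width anchor width in basepairs.
#' @param min_gap minimum distance (bp) between a distal anchor and the
#'   gene's cis window; must exceed the cis window width.
#' @param chrom_len named vector of chromosome lengths; defaults to the
#'   furthest annotated coordinate plus 2 Mb per chromosome.
#' @param cis_window cis window half-width used for the gap guarantee.
#' @param seed integer seed.
#' @return data.frame of class `hic_map` with columns `chrom_a`, `start_a`,
#'   `end_a`, `chrom_b`, `start_b`, `end_b`, `gene_id` (anchor A covers the
#'   gene, anchor B is distal).
#' @export
simulate_hic_map <- function(genes, n_distal_per_gene = 2L,
                             anchor_width = 10000L, min_gap = 300000L,
                             chrom_len = NULL, cis_window = 40000L,
                             seed = 1L) {
  stopifnot(inherits(genes, "gene_annotation"), n_distal_per_gene >= 0)
  win_width <- max(genes$end - genes$start) + 2L * cis_window
  if (n_distal_per_gene > 0 && min_gap <= win_width)
    stop("min_gap must exceed the cis window width (", win_width, " bp)")
  if (is.null(chrom_len)) {
    chrom_len <- tapply(genes$end, genes$chrom, max) + 2e6
  }
  rec <- vector("list", nrow(genes))
  withr_seed(seed, {
    for (i in seq_len(nrow(genes))) {
      g <- genes[i, ]
      len <- chrom_len[[g$chrom]]
      # candidate distal starts, excluding the forbidden interval around the
      # cis window (0-based half-open anchors)
      lo_max <- g$start - cis_window - min_gap - anchor_width
      hi_min <- g$end + cis_window + min_gap
      hi_max <- len - anchor_width
      sides <- list()
      if (lo_max >= 1) sides$left <- c(0, lo_max)
      if (hi_min <= hi_max) sides$right <- c(hi_min, hi_max)
      if (n_distal_per_gene > 0 && !length(sides)) {
        warning("no valid distal placement for gene ", g$gene_id,
                "; skipped")
        next
      }
      starts <- integer(0)
      if (n_distal_per_gene > 0) {
        tot <- sum(vapply(sides, function(s) s[2] - s[1] + 1, 0))
        u <- floor(runif(n_distal_per_gene) * tot)
        starts <- vapply(u, function(x) {
          for (s in sides) {
            w <- s[2] - s[1] + 1
            if (x < w) return(as.integer(s[1] + x))
            x <- x - w
          }
          as.integer(sides[[length(sides)]][2])
        }, integer(1))
      }
      if (!length(starts)) next
      body_start <- max(0L, g$start - 1L)
      rec[[i]] <- data.frame(
        chrom_a = g$chrom, start_a = body_start,
        end_a = body_start + max(anchor_width, g$end - g$start + 1L),
        chrom_b = g$chrom, start_b = starts,
        end_b = starts + anchor_width, gene_id = g$gene_id,
        stringsAsFactors = FALSE)
    }
  })
  out <- do.call(rbind, rec)
  if (is.null(out))
    out <- data.frame(chrom_a = character(), start_a = integer(),
                      end_a = integer(), chrom_b = character(),
                      start_b = integer(), end_b = integer(),
                      gene_id = character(), stringsAsFactors = FALSE)
  # deduplicate as unordered anchor pairs
  key <- apply(out[, 1:6], 1, function(r) {
    a <- paste(r[1:3], collapse = ":"); b <- paste(r[4:6], collapse = ":")
    paste(sort(c(a, b)), collapse = "|")
  })
  out <- out[!duplicated(key), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("hic_map", "data.frame")
  out
}

#' Construct an expression matrix with cohort labels
#'
#' @param values numeric samples x genes matrix with dimnames.
#' @param cohort `"case"`/`"control"` label per sample (recycled if length 1).
#' @return The matrix with class `expression_matrix` and attribute `cohort`.
#' @export
expression_matrix <- function(values, cohort = "control") {
  stopifnot(is.matrix(values), !anyNA(values))
  cohort <- rep_len(as.character(cohort), nrow(values))
  stopifnot(all(cohort %in% c("case", "control")))
  attr(values, "cohort") <- cohort
  class(values) <- c("expression_matrix", class(values))
  values
}

#' Cohort labels of an expression matrix
#' @param expr an [expression_matrix()].
#' @return character vector of per-sample labels.
#' @export
expr_cohort <- function(expr) {
  co <- attr(expr, "cohort")
  if (is.null(co)) rep("control", nrow(expr)) else co
}

#' Subset an expression matrix to one cohort
#' @param expr an [expression_matrix()].
#' @param cohort `"case"` or `"control"`.
#' @return an [expression_matrix()] restricted to the cohort.
#' @export
cohort_subset <- function(expr, cohort) {
  keep <- expr_cohort(expr) == cohort
  expression_matrix(unclass_expr(expr)[keep, , drop = FALSE], cohort)
}

unclass_expr <- function(expr) {
  attr(expr, "cohort") <- NULL
  class(expr) <- "matrix"
  matrix(as.numeric(expr), nrow = nrow(expr), dimnames = dimnames(expr))
}

#' Simulate nuisance covariates
#'
#' Three standard-normal continuous covariates plus one balanced binary
#' covariate, mimicking RIN/batch/sex-style nuisance structure.
#'
#' @param n_samples number of samples.
#' @param seed integer seed.
#' @return numeric matrix (samples x 4) with columns `cov1..cov3`, `batch`.
#' @export
simulate_covariates <- function(n_samples, seed = 1L) {
  withr_seed(seed, {
    m <- cbind(cov1 = rnorm(n_samples), cov2 = rnorm(n_samples),
               cov3 = rnorm(n_samples),
               batch = rbinom(n_samples, 1L, 0.5))
  })
  rownames(m) <- sprintf("S%04d", seq_len(n_samples))
  m
}

#' Simulate case and control expression from a ground-truth system
#'
#' Generation follows the recursive linear structural-equation model: for
#' each gene in the generating topological order,
#' `Z_i = sum_j lambda[i, j] Z_j + genetic terms + covariate terms + U_i`
#' with `U_i ~ N(0, sigma2_i)`. Controls use the full effect matrix; cases
#' use the matrix with `deleted_edges_cases` zeroed (loss of mediators).
#' Both cohorts share the genotype-generating process.
#'
#' @param system a [true_system()].
#' @param genotypes a [simulate_genotypes()] matrix with at least
#'   `n_cases + n_controls` rows; the first `n_controls` rows are assigned to
#'   controls, the following `n_cases` to cases.
#' @param n_cases,n_controls cohort sizes.
#' @param covariates optional samples x covariates matrix aligned to
#'   `genotypes` rows; required when the system has covariate loadings.
#' @param seed integer seed.
#' @return An [expression_matrix()] (samples x genes) with cohort labels.
#' @export
simulate_cohorts <- function(system, genotypes, n_cases, n_controls,
                             covariates = NULL, seed = 1L) {
  stopifnot(inherits(system, "true_system"))
  n <- n_cases + n_controls
  if (nrow(genotypes) < n) stop("not enough genotyped samples")
  lam <- system$lambda
  p <- nrow(lam)
  if (any(lam[upper.tri(lam, diag = TRUE)] != 0))
    stop("cyclic or non-triangular effect matrix")
  lam_case <- lam
  del <- system$deleted_edges_cases
  if (!is.null(del) && nrow(del))
    for (k in seq_len(nrow(del))) lam_case[del$to[k], del$from[k]] <- 0
  geno <- genotypes[seq_len(n), , drop = FALSE]
  cohort <- rep(c("control", "case"), c(n_controls, n_cases))
  # per-gene genetic term, shared by both cohorts
  gterm <- matrix(0, n, p, dimnames = list(rownames(geno), rownames(lam)))
  ge <- system$genetic_effects
  if (!is.null(ge) && nrow(ge)) {
    for (k in seq_len(nrow(ge))) {
      if (!ge$snp_id[k] %in% colnames(geno))
        stop("genetic effect references SNP absent from genotypes: ",
             ge$snp_id[k])
      gterm[, ge$gene_id[k]] <- gterm[, ge$gene_id[k]] +
        ge$effect[k] * geno[, ge$snp_id[k]]
    }
  }
  cl <- system$covariate_loadings
  if (!is.null(cl)) {
    if (is.null(covariates))
      stop("system has covariate loadings; supply covariates")
    cv <- covariates[seq_len(n), , drop = FALSE]
    gterm <- gterm + cv %*% t(cl)
  }
  withr_seed(seed, {
    U <- matrix(rnorm(n * p), n, p) %*% diag(sqrt(system$sigma2), p)
  })
  Z <- matrix(0, n, p, dimnames = list(rownames(geno), rownames(lam)))
  is_case <- cohort == "case"
  for (i in seq_len(p)) {
    par_ctl <- which(lam[i, ] != 0)
    par_cas <- which(lam_case[i, ] != 0)
    zi <- gterm[, i] + U[, i]
    if (length(par_ctl))
      zi[!is_case] <- zi[!is_case] +
        Z[!is_case, par_ctl, drop = FALSE] %*% lam[i, par_ctl]
    if (length(par_cas))
      zi[is_case] <- zi[is_case] +
        Z[is_case, par_cas, drop = FALSE] %*% lam_case[i, par_cas]
    Z[, i] <- zi
  }
  expression_matrix(Z, cohort)
}

#' Residualize expression on covariates
#'
#' Per gene, returns the residuals of the least-squares fit on the covariate
#' columns plus an intercept. Rank-deficient covariate matrices are rejected
#' with the offending columns named.
#'
#' @param expr an [expression_matrix()] or plain samples x genes matrix.
#' @param covariates samples x covariates numeric matrix aligned to `expr`.
#' @return expression matrix of residuals, cohort labels preserved.
#' @export
residualize_expression <- function(expr, covariates) {
  X <- cbind(`(Intercept)` = 1, covariates)
  if (nrow(X) != nrow(expr)) stop("covariates do not cover all samples")
  if (anyNA(X)) stop("covariates contain missing values")
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    bad <- colnames(X)[qx$pivot[(qx$rank + 1):ncol(X)]]
    stop("covariate matrix is rank-deficient; collinear column(s): ",
         paste(bad, collapse = ", "))
  }
  res <- qr.resid(qx, unclass_expr(expr))
  dimnames(res) <- dimnames(expr)
  expression_matrix(res, expr_cohort(expr))
}
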