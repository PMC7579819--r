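# Independent oracles and small fixture builders used across the suite.
# Each oracle deliberately takes a different computational route than the
# package implementation it checks.

# correspondence-analysis oracle: dense eigendecomposition of the
# standardized residual cross-product (indicator built via model.matrix)
ca_oracle <- function(geno) {
  m <- ncol(geno)
  ind <- do.call(cbind, lapply(seq_len(m), function(j) {
    f <- factor(geno[, j])
    stats::model.matrix(~ f - 1)
  }))
  P <- ind / sum(ind)
  r <- rowSums(P); cc <- colSums(P)
  S <- diag(1 / sqrt(r)) %*% (P - r %o% cc) %*% diag(1 / sqrt(cc))
  ev <- eigen(S %*% t(S), symmetric = TRUE)
  list(values = ev$values, S = S, r = r)
}

# exact upper-tail hypergeometric by exhaustive enumeration of all draws
hyper_enum <- function(k, N, M, n) {
  if (n == 0) return(as.numeric(k <= 0))
  draws <- utils::combn(N, n)
  mean(colSums(draws <= M) >= k)
}

# Benjamini-Hochberg step-up by the direct definition
# adj_i = min_{j: p_j >= p_i} p_j * m / rank(p_j), clipped at 1
bh_hand <- function(p) {
  m <- length(p)
  vapply(seq_len(m), function(i) {
    cand <- vapply(seq_len(m), function(j) {
      if (p[j] >= p[i]) p[j] * m / sum(p <= p[j]) else Inf
    }, numeric(1))
    min(1, min(cand))
  }, numeric(1))
}

# hand-built causal_graph over gene-gene edges only
graph_from_edges <- function(genes, from, to, effect = NA_real_) {
  edges <- if (length(from))
    data.frame(from = from, to = to, type = "gene",
               effect = rep_len(effect, length(from)), p = NA_real_,
               oriented_by = "bic", stringsAsFactors = FALSE)
  else data.frame(from = character(), to = character(), type = character(),
                  effect = numeric(), p = numeric(),
                  oriented_by = character(), stringsAsFactors = FALSE)
  structure(list(genes = genes, edges = edges, skeleton = NULL,
                 n_cycle_edges_removed = 0L, alpha = 0.001,
                 alpha_orient = 0.01),
            class = "causal_graph")
}

make_module <- function(core, members, boundary = character(0)) {
  structure(list(core = core, members = members, boundary = boundary,
                 max_path_length = NA_real_), class = "module")
}

# linear-chain ground-truth system g1 -> g2 -> ... -> gp
chain_system <- function(p, beta = 0.8, sigma2 = 1, delete = NULL) {
  genes <- gene_annotation(sprintf("c%02d", seq_len(p)), "chr1",
                           seq_len(p) * 1000000L,
                           seq_len(p) * 1000000L + 20000L)
  lam <- matrix(0, p, p, dimnames = list(genes$gene_id, genes$gene_id))
  beta <- rep_len(beta, p - 1)
  for (i in seq_len(p - 1)) lam[i + 1, i] <- beta[i]
  true_system(lam, genes, sigma2 = sigma2, deleted_edges_cases = delete)
}

# mediator motif p1, p2 -> m -> d; the m -> d edge optionally deleted in
# cases
mediator_system <- function(beta_md = 0.5, beta_up = 0.6, delete = TRUE) {
  ids <- c("p1", "p2", "m", "d")
  genes <- gene_annotation(ids, "chr1", 1:4 * 1000000L,
                           1:4 * 1000000L + 20000L)
  lam <- matrix(0, 4, 4, dimnames = list(ids, ids))
  lam["m", "p1"] <- beta_up; lam["m", "p2"] <- beta_up
  lam["d", "m"] <- beta_md
  true_system(lam, genes, sigma2 = 1,
              deleted_edges_cases = if (delete)
                data.frame(from = "m", to = "d", stringsAsFactors = FALSE))
}

# expression draw from a system without genetics/covariates
sim_expr <- function(system, n, seed, n_cases = 0L) {
  panel <- snp_panel("s1", "chr1", 1L, 0.5)
  geno <- simulate_genotypes(panel, n, seed = seed)
  simulate_cohorts(system, geno, n_cases = n_cases,
                   n_controls = n - n_cases, seed = seed + 5000L)
}

# undirected pair keys ("a|b" with a < b) for skeleton comparisons
und_pairs <- function(from, to) {
  if (!length(from)) return(character(0))
  unique(vapply(seq_along(from), function(i)
    paste(sort(c(from[i], to[i])), collapse = "|"), character(1)))
}
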