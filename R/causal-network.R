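#' Learn an IV-anchored causal gene network
#'
#' Three deterministic stages:
#' \enumerate{
#'   \item \strong{Skeleton} by neighborhood selection: the significance of
#'     gene `j` in the regression of gene `i` on all other genes equals the
#'     full-order partial-correlation test, computed here in one pass from
#'     the inverse covariance matrix. A pair is kept when both its
#'     partial-correlation test and its marginal-correlation test pass
#'     `alpha` after Bonferroni correction within the neighborhood (the
#'     marginal screen removes moral-graph spouse links, which are
#'     conditionally dependent but marginally independent).
#'   \item \strong{IV orientation}: for a skeleton pair \{A, B\} where A is
#'     instrumented, an IV of A associating with B (marginal test,
#'     Bonferroni over A's IVs, level `alpha_orient`) implies the flow
#'     A -> B; genetic variation is upstream of expression, so IV -> gene
#'     edges are fixed and nothing ever points into an IV node. Conflicts
#'     are resolved toward the smaller p; cycles by dropping the
#'     weakest-p edge.
#'   \item \strong{BIC completion}: remaining undirected pairs are oriented
#'     by greedy BIC descent over repeated deterministic sweeps, subject to
#'     acyclicity; exact ties orient from the lexicographically smaller
#'     gene.
#' }
#' Edge effects are then refit by least squares of each gene on its final
#' parent set.
#'
#' @param expr an [expression_matrix()] (samples x genes, n > genes + 1).
#' @param ivs an [instrument_matrix()] aligned to `expr`, or `NULL`.
#' @param alpha skeleton edge significance level in (0, 1).
#' @param alpha_orient significance level for the IV orientation test.
#' @return object of class `causal_graph`: list with `genes`, `edges`
#'   (data.frame `from`, `to`, `type` = `"gene"`/`"iv"`, `effect`, `p`),
#'   `skeleton` (pre-orientation pairs with screening p-values),
#'   `n_cycle_edges_removed`, `alpha`, `alpha_orient`.
#' @export
learn_network <- function(expr, ivs = NULL, alpha = 0.001,
                          alpha_orient = 0.01) {
  stopifnot(alpha > 0, alpha < 1)
  X <- unclass_expr(expr)
  genes <- colnames(X)
  p <- length(genes); n <- nrow(X)
  if (is.null(genes)) stop("expression matrix must have gene colnames")
  if (n <= p + 1)
    stop("need more samples than genes (+1) for neighborhood selection")
  sk <- .skeleton(X, alpha)
  und <- sk$pairs
  # --- IV orientation -------------------------------------------------
  iv_cols <- if (!is.null(ivs) && n_instruments(ivs) > 0)
    split(seq_len(ncol(ivs$scores)), ivs$meta$gene_id) else list()
  directed <- data.frame(from = character(), to = character(),
                         p = numeric(), stringsAsFactors = FALSE)
  bic_pairs <- list()
  if (nrow(und)) for (k in seq_len(nrow(und))) {
    A <- und$from[k]; B <- und$to[k]
    pA <- .iv_assoc_p(ivs, iv_cols[[A]], X[, B], n)
    pB <- .iv_assoc_p(ivs, iv_cols[[B]], X[, A], n)
    sigA <- pA < alpha_orient; sigB <- pB < alpha_orient
    if (sigA && (!sigB || pA < pB || (pA == pB && A < B))) {
      directed <- rbind(directed,
                        data.frame(from = A, to = B, p = und$p[k]))
    } else if (sigB) {
      directed <- rbind(directed,
                        data.frame(from = B, to = A, p = und$p[k]))
    } else {
      bic_pairs[[length(bic_pairs) + 1L]] <- c(A, B, und$p[k])
    }
  }
  iv_oriented <- paste(directed$from, directed$to, sep = "\r")
  cyc <- .break_cycles(directed, genes)
  directed <- cyc$edges
  # --- BIC completion -------------------------------------------------
  adj <- matrix(FALSE, p, p, dimnames = list(genes, genes))
  if (nrow(directed)) adj[cbind(directed$from, directed$to)] <- TRUE
  orient <- .bic_orient(X, adj, bic_pairs)
  adj <- orient$adj
  edge_p <- c(setNames(directed$p,
                       paste(directed$from, directed$to, sep = "\r")),
              orient$p)
  # --- refit effects on final parent sets ------------------------------
  rows <- list()
  for (g in genes) {
    pa <- genes[adj[, g]]
    if (!length(pa)) next
    fit <- .ols(X[, pa, drop = FALSE], X[, g])
    for (j in seq_along(pa)) {
      key <- paste(pa[j], g, sep = "\r")
      rows[[key]] <- data.frame(
        from = pa[j], to = g, type = "gene", effect = fit$beta[j],
        p = unname(edge_p[key]),
        oriented_by = if (key %in% iv_oriented) "iv" else "bic",
        stringsAsFactors = FALSE)
    }
  }
  if (length(iv_cols)) for (g in names(iv_cols)) {
    if (!g %in% genes) next
    Z <- ivs$scores[, iv_cols[[g]], drop = FALSE]
    fit <- .ols(Z, X[, g])
    for (j in seq_len(ncol(Z)))
      rows[[paste0("iv\r", colnames(Z)[j])]] <- data.frame(
        from = colnames(Z)[j], to = g, type = "iv", effect = fit$beta[j],
        p = fit$pval[j], oriented_by = "fixed", stringsAsFactors = FALSE)
  }
  edges <- if (length(rows))
    do.call(rbind, c(rows, list(make.row.names = FALSE)))
  else data.frame(from = character(), to = character(), type = character(),
                  effect = numeric(), p = numeric(),
                  oriented_by = character(), stringsAsFactors = FALSE)
  edges <- edges[order(edges$type, edges$from, edges$to), , drop = FALSE]
  rownames(edges) <- NULL
  structure(list(genes = genes, edges = edges, skeleton = und,
                 n_cycle_edges_removed = cyc$n_removed, alpha = alpha,
                 alpha_orient = alpha_orient),
            class = "causal_graph")
}

# skeleton by partial + marginal correlation screens, Bonferroni within
# neighborhood; returns pairs (from < to lexicographically) with p = max of
# the two Bonferroni-adjusted screen p-values
.skeleton <- function(X, alpha) {
  n <- nrow(X); p <- ncol(X); genes <- colnames(X)
  S <- cov(X)
  sds <- sqrt(diag(S))
  if (any(sds < 1e-12)) stop("constant gene expression column(s): ",
                             paste(genes[sds < 1e-12], collapse = ", "))
  Rm <- cov2cor(S)
  Om <- chol2inv(chol(S))
  dd <- 1 / sqrt(diag(Om))
  Pc <- -Om * outer(dd, dd); diag(Pc) <- 1
  bonf <- p - 1
  p_part <- .cor_p(Pc, n - p) * bonf
  p_marg <- .cor_p(Rm, n - 2) * bonf
  keep <- p_part < alpha & p_marg < alpha
  idx <- which(keep & upper.tri(keep), arr.ind = TRUE)
  pairs <- data.frame(from = genes[idx[, 1]], to = genes[idx[, 2]],
                      p = pmin(pmax(p_part[idx], p_marg[idx]), 1),
                      stringsAsFactors = FALSE)
  pairs <- pairs[order(pairs$from, pairs$to), , drop = FALSE]
  rownames(pairs) <- NULL
  list(pairs = pairs, p_part = p_part, p_marg = p_marg)
}

.cor_p <- function(R, df) {
  tval <- R * sqrt(df / pmax(1 - R^2, 1e-300))
  2 * pt(-abs(tval), df)
}

# min Bonferroni-adjusted marginal-association p of a gene's IVs with y
.iv_assoc_p <- function(ivs, cols, y, n) {
  if (is.null(cols) || !length(cols)) return(1)
  r <- as.vector(suppressWarnings(cor(ivs$scores[, cols, drop = FALSE], y)))
  r[!is.finite(r)] <- 0
  pv <- .cor_p(matrix(r), n - 2)
  min(pmin(pv * length(cols), 1))
}

# remove weakest-p edges until the directed edge set is acyclic
.break_cycles <- function(directed, genes) {
  n_removed <- 0L
  repeat {
    if (!nrow(directed)) break
    g <- igraph::graph_from_data_frame(directed[, c("from", "to")],
                                       vertices = genes)
    if (igraph::is_dag(g)) break
    comp <- igraph::components(g, mode = "strong")
    bad_nodes <- names(comp$membership)[comp$membership %in%
                                          which(comp$csize > 1)]
    in_cycle <- directed$from %in% bad_nodes & directed$to %in% bad_nodes
    cand <- which(in_cycle)
    cand <- cand[order(-directed$p[cand], directed$from[cand],
                       directed$to[cand])]
    directed <- directed[-cand[1], , drop = FALSE]
    n_removed <- n_removed + 1L
  }
  list(edges = directed, n_removed = n_removed)
}

.ols <- function(X, y) {
  X1 <- cbind(`(Intercept)` = 1, X)
  qx <- qr(X1)
  beta <- qr.coef(qx, y)
  res <- qr.resid(qx, y)
  df <- length(y) - qx$rank
  rss <- sum(res^2)
  s2 <- rss / max(df, 1)
  XtXinv <- chol2inv(qr.R(qx))
  se <- sqrt(pmax(diag(XtXinv), 0) * s2)
  tval <- beta / se
  pval <- 2 * pt(-abs(tval), df)
  list(beta = beta[-1], se = se[-1], tval = tval[-1], pval = pval[-1],
       df = df, rss = rss, sigma2 = s2)
}

.bic_node <- function(X, node, parents) {
  n <- nrow(X)
  X1 <- cbind(1, X[, parents, drop = FALSE])
  rss <- sum(qr.resid(qr(X1), X[, node])^2)
  n * log(rss / n) + ncol(X1) * log(n)
}

# orient undirected pairs by greedy BIC sweeps subject to acyclicity
.bic_orient <- function(X, adj, bic_pairs) {
  genes <- colnames(adj)
  p_out <- c()
  if (!length(bic_pairs)) return(list(adj = adj, p = p_out))
  tab <- do.call(rbind, bic_pairs)
  pairs <- data.frame(a = tab[, 1], b = tab[, 2],
                      p = as.numeric(tab[, 3]), stringsAsFactors = FALSE)
  pairs <- pairs[order(pairs$a, pairs$b), , drop = FALSE]
  state <- rep(NA_character_, nrow(pairs)) # "ab" or "ba"
  for (pass in 1:10) {
    changed <- FALSE
    for (k in seq_len(nrow(pairs))) {
      A <- pairs$a[k]; B <- pairs$b[k]
      # detach this pair's current edge before scoring
      adj[A, B] <- FALSE; adj[B, A] <- FALSE
      paA <- genes[adj[, A]]; paB <- genes[adj[, B]]
      bic_ab <- .bic_node(X, B, c(paB, A)) + .bic_node(X, A, paA)
      bic_ba <- .bic_node(X, A, c(paA, B)) + .bic_node(X, B, paB)
      pick <- if (abs(bic_ab - bic_ba) < 1e-9) "ab"
              else if (bic_ab < bic_ba) "ab" else "ba"
      if (pick == "ab" && .reachable(adj, B, A)) pick <- "ba"
      if (pick == "ba" && .reachable(adj, A, B)) pick <- "ab"
      if (pick == "ab") adj[A, B] <- TRUE else adj[B, A] <- TRUE
      if (!identical(state[k], pick)) { state[k] <- pick; changed <- TRUE }
    }
    if (!changed) break
  }
  key <- ifelse(state == "ab", paste(pairs$a, pairs$b, sep = "\r"),
                paste(pairs$b, pairs$a, sep = "\r"))
  list(adj = adj, p = setNames(pairs$p, key))
}

# is `to` reachable from `from` along directed edges?
.reachable <- function(adj, from, to) {
  if (from == to) return(TRUE)
  seen <- structure(logical(ncol(adj)), names = colnames(adj))
  stack <- from
  while (length(stack)) {
    v <- stack[[1]]; stack <- stack[-1]
    if (seen[v]) next
    seen[v] <- TRUE
    nb <- colnames(adj)[adj[v, ]]
    if (to %in% nb) return(TRUE)
    stack <- c(stack, nb[!seen[nb]])
  }
  FALSE
}

#' @export
print.causal_graph <- function(x, ...) {
  eg <- x$edges[x$edges$type == "gene", ]
  ei <- x$edges[x$edges$type == "iv", ]
  cat("causal_graph:", length(x$genes), "genes,", nrow(eg),
      "gene-gene edges,", nrow(ei), "IV->gene edges (alpha =", x$alpha,
      ")\n")
  invisible(x)
}

#' Gene-gene edges of a causal graph
#' @param graph a [learn_network()] result.
#' @return data.frame of directed gene-gene edges.
#' @export
gene_edges <- function(graph) {
  stopifnot(inherits(graph, "causal_graph"))
  graph$edges[graph$edges$type == "gene", , drop = FALSE]
}

# directed gene-gene adjacency matrix
.gene_adjacency <- function(graph) {
  adj <- matrix(FALSE, length(graph$genes), length(graph$genes),
                dimnames = list(graph$genes, graph$genes))
  eg <- gene_edges(graph)
  if (nrow(eg)) adj[cbind(eg$from, eg$to)] <- TRUE
  adj
}

#' Gene-gene subgraph as an igraph object
#' @param graph a [learn_network()] result.
#' @return a directed [igraph::graph].
#' @export
as_igraph <- function(graph) {
  igraph::graph_from_data_frame(gene_edges(graph)[, c("from", "to")],
                                vertices = graph$genes)
}

#' Hamming distance between two causal graphs
#'
#' Number of ordered gene pairs whose directed-edge status differs: a
#' present/absent mismatch counts 1, a reversed edge counts 2. Only
#' gene-gene edges are compared; both graphs must be over the same genes.
#'
#' @param g1,g2 [learn_network()] results on identical gene sets.
#' @return integer distance.
#' @export
hamming_distance <- function(g1, g2) {
  if (!setequal(g1$genes, g2$genes))
    stop("graphs have different gene sets")
  a1 <- .gene_adjacency(g1)
  a2 <- .gene_adjacency(g2)[g1$genes, g1$genes]
  sum(a1 != a2)
}

#' Tune the skeleton significance level by Hamming-distance stability
#'
#' For each candidate value, networks are learned on `n_subsamples` random
#' subsamples (drawn once, without replacement, and reused across the grid)
#' and the mean pairwise Hamming distance, normalized by the number of
#' ordered gene pairs, is computed. The value minimizing the mean distance
#' is selected; ties break toward the sparser (smaller) value.
#'
#' @param expr an [expression_matrix()].
#' @param ivs optional [instrument_matrix()].
#' @param grid candidate significance levels (default the tuning set
#'   0.01, 0.005, 0.001, 0.0005).
#' @param n_subsamples number of subsamples (>= 2, default 10).
#' @param subsample_frac fraction of samples per subsample.
#' @param seed integer seed for the subsample draw.
#' @param alpha_orient orientation level passed through.
#' @return object of class `tuning_report`: data.frame `report` (`alpha`,
#'   `mean_distance`), `selected`.
#' @export
tune_by_hamming <- function(expr, ivs = NULL,
                            grid = c(0.01, 0.005, 0.001, 0.0005),
                            n_subsamples = 10L, subsample_frac = 0.5,
                            seed = 1L, alpha_orient = 0.01) {
  stopifnot(n_subsamples >= 2)
  n <- nrow(expr); p <- ncol(expr)
  n_sub <- floor(subsample_frac * n)
  if (n_sub < p / 2 || n_sub <= p + 1)
    stop("subsample too small for neighborhood regression (", n_sub,
         " samples for ", p, " genes); increase subsample_frac")
  withr_seed(seed, {
    subs <- lapply(seq_len(n_subsamples), function(i) sort(sample(n, n_sub)))
  })
  mean_dist <- vapply(grid, function(a) {
    nets <- lapply(subs, function(idx) {
      e <- expression_matrix(unclass_expr(expr)[idx, , drop = FALSE],
                             expr_cohort(expr)[idx])
      iv_sub <- if (!is.null(ivs) && n_instruments(ivs) > 0)
        instrument_matrix(ivs$scores[idx, , drop = FALSE], ivs$meta)
      else NULL
      learn_network(e, iv_sub, alpha = a, alpha_orient = alpha_orient)
    })
    ij <- combn(length(nets), 2)
    mean(vapply(seq_len(ncol(ij)), function(k)
      hamming_distance(nets[[ij[1, k]]], nets[[ij[2, k]]]),
      numeric(1))) / (p * (p - 1))
  }, numeric(1))
  ord <- order(mean_dist, grid) # ties -> smaller (sparser) value
  structure(list(report = data.frame(alpha = grid,
                                     mean_distance = mean_dist),
                 selected = grid[ord[1]]),
            class = "tuning_report")
}

#' @export
print.tuning_report <- function(x, ...) {
  print(x$report)
  cat("selected alpha:", x$selected, "\n")
  invisible(x)
}

#' Permutation stability of a learned network
#'
#' Following the stability design: sample `n_genes` genes of one role
#' (broadcaster or receptor) sharing the same out-/in-degree, independently
#' permute each selected gene's expression vector across samples, relearn
#' the network at the same significance level, and report
#' `stability = 1 - changed / total` directed-edge statuses, where by
#' default `total` is the number of ordered gene pairs (so `1 - stability`
#' is the normalized Hamming distance to the unpermuted network);
#' `denominator = "edges"` divides by the original edge count instead.
#'
#' @param expr an [expression_matrix()].
#' @param ivs optional [instrument_matrix()] used for relearning.
#' @param graph the unpermuted [learn_network()] result on `expr`.
#' @param role `"broadcaster"`, `"receptor"` or `"isolated"` (degree 0,
#'   useful for testing).
#' @param degree out-degree (broadcasters) or in-degree (receptors) of the
#'   genes to permute, typically 1..5.
#' @param n_genes genes permuted per permutation (default 10); if fewer are
#'   eligible all are used and recorded.
#' @param n_perm number of permutations.
#' @param seed integer seed.
#' @param denominator `"pairs"` (default) or `"edges"`.
#' @return object of class `stability_result`: data.frame `per_perm`
#'   (`perm`, `n_changed`, `stability`), `mean_stability`,
#'   `mean_changed`, `role`, `degree`, `n_genes_used`.
#' @export
permutation_stability <- function(expr, ivs = NULL, graph, role, degree,
                                  n_genes = 10L, n_perm = 20L, seed = 1L,
                                  denominator = c("pairs", "edges")) {
  denominator <- match.arg(denominator)
  role <- match.arg(role, c("broadcaster", "receptor", "isolated"))
  roles <- degrees_and_roles(graph)
  eligible <- switch(role,
    broadcaster = roles$gene_id[roles$role == "broadcaster" &
                                  roles$out_degree == degree],
    receptor = roles$gene_id[roles$role == "receptor" &
                               roles$in_degree == degree],
    isolated = roles$gene_id[roles$role == "isolated"])
  if (!length(eligible))
    stop("no eligible genes with role '", role, "' and degree ", degree)
  n_use <- min(n_genes, length(eligible))
  X <- unclass_expr(expr)
  n <- nrow(X)
  p <- length(graph$genes)
  orig_adj <- .gene_adjacency(graph)
  denom <- if (denominator == "pairs") p * (p - 1) else max(sum(orig_adj), 1)
  res <- withr_seed(seed, {
    lapply(seq_len(n_perm), function(b) {
      sel <- if (n_use < length(eligible))
        sample(eligible, n_use) else eligible
      Xp <- X
      for (g in sel) Xp[, g] <- Xp[sample(n), g]
      net <- learn_network(expression_matrix(Xp, expr_cohort(expr)), ivs,
                           alpha = graph$alpha,
                           alpha_orient = graph$alpha_orient)
      sum(orig_adj != .gene_adjacency(net)[graph$genes, graph$genes])
    })
  })
  changed <- unlist(res)
  per_perm <- data.frame(perm = seq_len(n_perm), n_changed = changed,
                         stability = pmax(1 - changed / denom, 0))
  structure(list(per_perm = per_perm,
                 mean_stability = mean(per_perm$stability),
                 mean_changed = mean(changed), role = role, degree = degree,
                 n_genes_used = n_use, denominator = denominator),
            class = "stability_result")
}

#' @export
print.stability_result <- function(x, ...) {
  cat("permutation stability (", x$role, ", degree ", x$degree, "): mean ",
      round(x$mean_stability, 4), " over ", nrow(x$per_perm),
      " permutations (", x$n_genes_used, " genes each)\n", sep = "")
  invisible(x)
}
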