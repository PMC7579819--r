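#' Fit the recursive structural-equation model on a fixed network
#'
#' The network fixes the zero pattern of the gene-gene effect matrix: under
#' the recursive Gaussian SEM `Z = (I - Lambda) U` with diagonal residual
#' covariance, node-wise ordinary least squares of each gene on its graph
#' parents is the maximum-likelihood estimator, so each row of `Lambda` is
#' estimated by one regression. Parent sets beyond the condition-number cap
#' are refit with a small ridge and flagged.
#'
#' @param expr_cohort an [expression_matrix()] for one cohort.
#' @param graph a [learn_network()] result (acyclic gene subgraph).
#' @param conf_level confidence level for per-edge intervals (default 0.95).
#' @param kappa_max condition-number cap for parent design matrices.
#' @return object of class `sem_fit`: `lambda_hat` (genes x genes,
#'   `[child, parent]`), `delta_hat` (residual variances), `edges`
#'   (data.frame `from`, `to`, `est`, `se`, `lo`, `hi`, `significant`,
#'   `ridged`), `cohort`.
#' @export
fit_sem <- function(expr_cohort, graph, conf_level = 0.95,
                    kappa_max = 1e8) {
  stopifnot(inherits(graph, "causal_graph"))
  X <- unclass_expr(expr_cohort)
  genes <- graph$genes
  stopifnot(all(genes %in% colnames(X)))
  if (!igraph::is_dag(as_igraph(graph))) stop("gene subgraph is not acyclic")
  n <- nrow(X)
  adj <- .gene_adjacency(graph)
  max_pa <- max(c(0, colSums(adj)))
  if (n < max_pa + 10)
    stop("cohort too small for the largest parent set (need >= ",
         max_pa + 10, " samples)")
  p <- length(genes)
  lam <- matrix(0, p, p, dimnames = list(genes, genes))
  delta <- setNames(numeric(p), genes)
  rows <- list()
  z <- qt(1 - (1 - conf_level) / 2, df = Inf) # placeholder, refined per fit
  for (g in genes) {
    pa <- genes[adj[, g]]
    if (!length(pa)) {
      delta[g] <- var(X[, g])
      next
    }
    Xp <- X[, pa, drop = FALSE]
    ridged <- FALSE
    sv <- svd(scale(Xp, scale = FALSE), nu = 0, nv = 0)$d
    if (length(sv) > 1 && sv[1] / max(sv[length(sv)], 1e-300) > kappa_max) {
      ridged <- TRUE
      ctr <- scale(Xp, scale = FALSE)
      yc <- X[, g] - mean(X[, g])
      beta <- solve(crossprod(ctr) + 1e-6 * diag(ncol(ctr)),
                    crossprod(ctr, yc))
      res <- yc - ctr %*% beta
      df <- n - length(pa) - 1
      s2 <- sum(res^2) / df
      se <- sqrt(diag(solve(crossprod(ctr) + 1e-6 * diag(ncol(ctr)))) * s2)
      fit <- list(beta = as.vector(beta), se = se, df = df, sigma2 = s2)
    } else {
      o <- .ols(Xp, X[, g])
      fit <- list(beta = o$beta, se = o$se, df = o$df, sigma2 = o$sigma2)
    }
    tq <- qt(1 - (1 - conf_level) / 2, fit$df)
    lam[g, pa] <- fit$beta
    delta[g] <- fit$sigma2
    rows[[g]] <- data.frame(
      from = pa, to = g, est = fit$beta, se = fit$se,
      lo = fit$beta - tq * fit$se, hi = fit$beta + tq * fit$se,
      ridged = ridged, stringsAsFactors = FALSE)
  }
  edges <- if (length(rows))
    do.call(rbind, c(rows, list(make.row.names = FALSE)))
  else data.frame(from = character(), to = character(), est = numeric(),
                  se = numeric(), lo = numeric(), hi = numeric(),
                  ridged = logical(), stringsAsFactors = FALSE)
  edges$significant <- edges$lo > 0 | edges$hi < 0
  co <- unique(expr_cohort_label(expr_cohort))
  structure(list(lambda_hat = lam, delta_hat = delta, edges = edges,
                 cohort = co, conf_level = conf_level, n = n),
            class = "sem_fit")
}

expr_cohort_label <- function(expr) {
  co <- unique(expr_cohort(expr))
  if (length(co) == 1) co else "mixed"
}

#' @export
print.sem_fit <- function(x, ...) {
  cat("sem_fit (", x$cohort, "): ", nrow(x$edges), " edges, n = ", x$n,
      "\n", sep = "")
  invisible(x)
}

#' Exclusive effect of a mediator on a downstream gene
#'
#' The effect of the mediator on its downstream gene after adjusting for
#' the mediator's upstream genes: the mediator's coefficient in the
#' regression of the downstream gene on the mediator plus the mediator's
#' graph parents. Significance is judged by the t-based confidence
#' interval excluding zero.
#'
#' @param expr_cohort an [expression_matrix()] for one cohort.
#' @param mediator,downstream gene ids; `(mediator -> downstream)` must be
#'   a graph edge and the mediator must have at least one parent.
#' @param graph a [learn_network()] result.
#' @param conf_level confidence level (default 0.95).
#' @return one-row data.frame of class `exclusive_effect` with columns
#'   `mediator`, `downstream`, `cohort`, `est`, `se`, `lo`, `hi`,
#'   `significant`.
#' @export
exclusive_effect <- function(expr_cohort, mediator, downstream, graph,
                             conf_level = 0.95) {
  adj <- .gene_adjacency(graph)
  if (!adj[mediator, downstream])
    stop("(", mediator, " -> ", downstream, ") is not a graph edge")
  parents <- graph$genes[adj[, mediator]]
  if (!length(parents))
    stop("mediator ", mediator, " has no upstream genes")
  X <- unclass_expr(expr_cohort)
  preds <- c(mediator, parents)
  if (any(apply(X[, preds, drop = FALSE], 2, sd) < 1e-12))
    stop("zero-variance regressor among ", paste(preds, collapse = ", "))
  fit <- .ols(X[, preds, drop = FALSE], X[, downstream])
  tq <- qt(1 - (1 - conf_level) / 2, fit$df)
  out <- data.frame(mediator = mediator, downstream = downstream,
                    cohort = expr_cohort_label(expr_cohort),
                    est = fit$beta[1], se = fit$se[1],
                    lo = fit$beta[1] - tq * fit$se[1],
                    hi = fit$beta[1] + tq * fit$se[1],
                    stringsAsFactors = FALSE)
  out$significant <- out$lo > 0 | out$hi < 0
  class(out) <- c("exclusive_effect", "data.frame")
  out
}

#' Detect mediators lost in the case cohort
#'
#' Candidate mediators are genes with more than one upstream effector
#' (in-degree >= 2) and at least one downstream gene. For every candidate
#' mediator-downstream pair the exclusive effect is computed in both
#' cohorts; a pair is \emph{lost} when it is significant (CI excludes 0)
#' in controls and non-significant in cases.
#'
#' @param expr_cases,expr_controls [expression_matrix()] objects aligned to
#'   the same graph.
#' @param graph a [learn_network()] result.
#' @param conf_level confidence level (default 0.95).
#' @return list of class `lost_mediators`: `effects` (both cohorts' rows,
#'   forest-plot-ready), `lost` (data.frame of lost pairs), `candidates`.
#' @export
detect_lost_mediators <- function(expr_cases, expr_controls, graph,
                                  conf_level = 0.95) {
  roles <- degrees_and_roles(graph)
  cand <- roles$gene_id[roles$in_degree >= 2 & roles$out_degree >= 1]
  adj <- .gene_adjacency(graph)
  eff <- list()
  lost <- list()
  for (m in cand) {
    for (d in graph$genes[adj[m, ]]) {
      ec <- exclusive_effect(expr_controls, m, d, graph, conf_level)
      ea <- exclusive_effect(expr_cases, m, d, graph, conf_level)
      ec$cohort <- "control"; ea$cohort <- "case"
      eff[[paste(m, d)]] <- rbind(ec, ea)
      if (ec$significant && !ea$significant)
        lost[[paste(m, d)]] <- data.frame(
          mediator = m, downstream = d, est_control = ec$est,
          est_case = ea$est, stringsAsFactors = FALSE)
    }
  }
  effects <- if (length(eff))
    do.call(rbind, c(eff, list(make.row.names = FALSE)))
  else NULL
  lost_df <- if (length(lost))
    do.call(rbind, c(lost, list(make.row.names = FALSE)))
  else data.frame(mediator = character(), downstream = character(),
                  est_control = numeric(), est_case = numeric(),
                  stringsAsFactors = FALSE)
  structure(list(effects = effects, lost = lost_df, candidates = cand),
            class = "lost_mediators")
}

#' @export
print.lost_mediators <- function(x, ...) {
  cat("lost_mediators:", length(x$candidates), "candidate mediators,",
      nrow(x$lost), "lost pairs\n")
  if (nrow(x$lost)) print(x$lost)
  invisible(x)
}

# closed-form ridge for the loss 1/2 ||y - X b||^2 + nu ||b||^2
.ridge_beta <- function(X, y, nu) {
  solve(crossprod(X) + 2 * nu * diag(ncol(X)), crossprod(X, y))
}

# inner k-fold CV choosing nu by MSPE (ties -> smaller nu)
.choose_nu <- function(X, y, nu_grid, folds) {
  mspe <- vapply(nu_grid, function(nu) {
    errs <- vapply(unique(folds), function(f) {
      tr <- folds != f
      mx <- colMeans(X[tr, , drop = FALSE]); my <- mean(y[tr])
      b <- .ridge_beta(sweep(X[tr, , drop = FALSE], 2, mx), y[tr] - my, nu)
      pred <- sweep(X[!tr, , drop = FALSE], 2, mx) %*% b + my
      mean((pred - y[!tr])^2)
    }, numeric(1))
    mean(errs)
  }, numeric(1))
  nu_grid[order(mspe, nu_grid)[1]]
}

#' Core-based prediction of module member transcription
#'
#' For each member gene of a module, predictors are its direct graph
#' parents within the module, always including the core when the core is an
#' ancestor. All transcriptions are scaled to unit standard deviation;
#' prediction uses ridge regression (squared-L2 penalty,
#' `1/2 ||g - S beta||^2 + nu ||beta||^2`) with `nu` selected by inner
#' 5-fold cross-validation on the training folds. The whole 5-fold
#' cross-validation is repeated `repeats` times and the mean correlation
#' between predicted and observed values and the mean squared prediction
#' error (MSPE) over repeats are reported; a member is a good predictor
#' target when mean correlation > 0.6 and MSPE < 0.3.
#'
#' @param expr_cohort an [expression_matrix()] for one cohort.
#' @param module a `module` from [find_modules()].
#' @param graph the [learn_network()] result the module came from.
#' @param nu_grid ridge penalty grid (default `10^seq(-3, 2, length 6)`).
#' @param k outer folds (default 5); the cohort must have >= 5k samples.
#' @param repeats repetitions of the full k-fold procedure (default 200).
#' @param seed integer seed; fold assignments are derived from it, so
#'   reruns are bit-identical.
#' @param corr_threshold,mspe_threshold good-predictor rule (0.6 / 0.3).
#' @return data.frame of class `prediction_result` with columns `core`,
#'   `target`, `predictors`, `mean_corr`, `mean_mspe`, `good_predictor`,
#'   `n_folds_skipped`.
#' @export
core_prediction_cv <- function(expr_cohort, module, graph,
                               nu_grid = 10^seq(-3, 2, length.out = 6),
                               k = 5L, repeats = 200L, seed = 1L,
                               corr_threshold = 0.6, mspe_threshold = 0.3) {
  stopifnot(inherits(module, "module"), length(module$members) >= 1)
  X <- unclass_expr(expr_cohort)
  n <- nrow(X)
  if (n < 5 * k) stop("cohort must have at least 5k samples")
  adj <- .gene_adjacency(graph)
  Xs <- scale(X, center = TRUE, scale = TRUE) # unit-SD transcriptions
  res <- lapply(module$members, function(g) {
    preds <- intersect(graph$genes[adj[, g]], c(module$core, module$members))
    if (!module$core %in% preds) preds <- c(module$core, preds)
    preds <- setdiff(preds, g)
    S <- Xs[, preds, drop = FALSE]
    y <- Xs[, g]
    corrs <- numeric(repeats); mspes <- numeric(repeats)
    skipped <- 0L
    withr_seed(seed, {
      for (rep_i in seq_len(repeats)) {
        fold <- sample(rep_len(seq_len(k), n))
        pred <- rep(NA_real_, n)
        for (f in seq_len(k)) {
          tr <- fold != f
          if (sd(y[tr]) < 1e-12) { skipped <- skipped + 1L; next }
          inner <- rep_len(seq_len(5L), sum(tr))
          nu <- .choose_nu(S[tr, , drop = FALSE], y[tr], nu_grid, inner)
          mx <- colMeans(S[tr, , drop = FALSE]); my <- mean(y[tr])
          b <- .ridge_beta(sweep(S[tr, , drop = FALSE], 2, mx),
                           y[tr] - my, nu)
          pred[!tr] <- sweep(S[!tr, , drop = FALSE], 2, mx) %*% b + my
        }
        ok <- !is.na(pred)
        corrs[rep_i] <- cor(pred[ok], y[ok])
        mspes[rep_i] <- mean((pred[ok] - y[ok])^2)
      }
    })
    data.frame(core = module$core, target = g,
               predictors = paste(preds, collapse = ","),
               mean_corr = mean(corrs), mean_mspe = mean(mspes),
               good_predictor = mean(corrs) > corr_threshold &
                 mean(mspes) < mspe_threshold,
               n_folds_skipped = skipped, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, c(res, list(make.row.names = FALSE)))
  class(out) <- c("prediction_result", "data.frame")
  out
}

#' Call novel candidate genes by conditional analysis
#'
#' A module member outside the known disease-gene list is a candidate when
#' its association with the core remains significant after conditioning on
#' the known genes present in the module (t-test on the core coefficient,
#' Benjamini-Hochberg across members) in \emph{both} cohorts.
#'
#' @param expr_cases,expr_controls cohort [expression_matrix()] objects.
#' @param module a `module` from [find_modules()].
#' @param graph the corresponding [learn_network()] result.
#' @param known_genes character vector of established disease genes.
#' @param q_threshold FDR level (default 0.05).
#' @return list of class `novel_candidates`: `candidates` (gene ids),
#'   `table` (per member and cohort: core coefficient p and q),
#'   `conditioned_on` (known genes used; empty means plain association,
#'   flagged in `conditional`).
#' @export
conditional_novel_genes <- function(expr_cases, expr_controls, module,
                                    graph, known_genes,
                                    q_threshold = 0.05) {
  members <- setdiff(module$members, c(known_genes, module$core))
  knowns <- intersect(known_genes, c(module$members, module$core))
  knowns <- setdiff(knowns, module$core)
  if (!length(members))
    return(structure(list(candidates = character(0), table = NULL,
                          conditioned_on = knowns,
                          conditional = length(knowns) > 0),
                     class = "novel_candidates"))
  one_cohort <- function(expr, label) {
    X <- unclass_expr(expr)
    pv <- vapply(members, function(g) {
      preds <- c(module$core, knowns)
      fit <- .ols(X[, preds, drop = FALSE], X[, g])
      fit$pval[1]
    }, numeric(1))
    data.frame(gene_id = members, cohort = label, p = pv,
               q = bh_adjust(pv), stringsAsFactors = FALSE)
  }
  tab <- rbind(one_cohort(expr_controls, "control"),
               one_cohort(expr_cases, "case"))
  sig_ctl <- tab$gene_id[tab$cohort == "control" & tab$q < q_threshold]
  sig_cas <- tab$gene_id[tab$cohort == "case" & tab$q < q_threshold]
  structure(list(candidates = sort(intersect(sig_ctl, sig_cas)), table = tab,
                 conditioned_on = knowns, conditional = length(knowns) > 0),
            class = "novel_candidates")
}

#' @export
print.novel_candidates <- function(x, ...) {
  cat("novel candidates (conditioned on ",
      if (length(x$conditioned_on)) paste(x$conditioned_on, collapse = ", ")
      else "nothing: plain association", "): ",
      if (length(x$candidates)) paste(x$candidates, collapse = ", ")
      else "none", "\n", sep = "")
  invisible(x)
}

#' Replicate network edges in an independent expression set
#'
#' Per gene-gene edge, a simple linear regression of the target on the
#' source gene in the replication data gives a two-sided p-value; p-values
#' are Benjamini-Hochberg adjusted across tested edges and an edge
#' replicates when q < `q_threshold`. Small replication sets are allowed.
#'
#' @param graph a [learn_network()] result.
#' @param replication_expr samples x genes matrix covering at least one
#'   edge's gene pair (missing genes are excluded and counted).
#' @param q_threshold FDR level (default 0.05).
#' @return list of class `replication_result`: `edges` (data.frame `from`,
#'   `to`, `est`, `p`, `q`, `replicated`), `fraction_replicated`,
#'   `n_excluded`.
#' @export
replicate_edges <- function(graph, replication_expr, q_threshold = 0.05) {
  eg <- gene_edges(graph)
  X <- as.matrix(replication_expr)
  have <- eg$from %in% colnames(X) & eg$to %in% colnames(X)
  n_excluded <- sum(!have)
  eg <- eg[have, , drop = FALSE]
  if (!nrow(eg)) stop("replication matrix covers no graph edge")
  res <- lapply(seq_len(nrow(eg)), function(k) {
    fit <- .ols(X[, eg$from[k], drop = FALSE], X[, eg$to[k]])
    data.frame(from = eg$from[k], to = eg$to[k], est = fit$beta[1],
               p = fit$pval[1], stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, c(res, list(make.row.names = FALSE)))
  tab$q <- bh_adjust(tab$p)
  tab$replicated <- tab$q < q_threshold
  structure(list(edges = tab,
                 fraction_replicated = mean(tab$replicated),
                 n_excluded = n_excluded, q_threshold = q_threshold),
            class = "replication_result")
}

#' @export
print.replication_result <- function(x, ...) {
  cat("replicate_edges:", sum(x$edges$replicated), "/", nrow(x$edges),
      "edges replicated (fraction", round(x$fraction_replicated, 3),
      ");", x$n_excluded, "excluded\n")
  invisible(x)
}
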