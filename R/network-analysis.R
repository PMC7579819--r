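#' Degrees and regulatory roles of every gene
#'
#' Counts gene-gene edges only. Roles: \emph{broadcaster} (out > 0, in = 0),
#' \emph{receptor} (in > 0, out = 0), \emph{mediator} (both > 0),
#' \emph{isolated} (neither). IV -> gene edges never contribute to degrees;
#' they set the `has_iv` flag.
#'
#' @param graph a [learn_network()] result.
#' @return data.frame of class `gene_role_table` with columns `gene_id`,
#'   `in_degree`, `out_degree`, `degree`, `role`, `has_iv`.
#' @export
degrees_and_roles <- function(graph) {
  stopifnot(inherits(graph, "causal_graph"))
  eg <- gene_edges(graph)
  ei <- graph$edges[graph$edges$type == "iv", , drop = FALSE]
  out_d <- table(factor(eg$from, levels = graph$genes))
  in_d <- table(factor(eg$to, levels = graph$genes))
  out_d <- as.integer(out_d); in_d <- as.integer(in_d)
  role <- ifelse(out_d > 0 & in_d == 0, "broadcaster",
          ifelse(in_d > 0 & out_d == 0, "receptor",
          ifelse(in_d > 0 & out_d > 0, "mediator", "isolated")))
  out <- data.frame(gene_id = graph$genes, in_degree = in_d,
                    out_degree = out_d, degree = in_d + out_d, role = role,
                    has_iv = graph$genes %in% ei$to,
                    stringsAsFactors = FALSE)
  class(out) <- c("gene_role_table", "data.frame")
  out
}

#' All downstream pathways of a gene
#'
#' Enumerates every simple directed path from `gene` that ends at a
#' receptor: a gene's effect propagates downstream until it reaches a
#' receptor, and each such maximal route is one pathway.
#'
#' @param graph a [learn_network()] result.
#' @param gene gene id present in the graph.
#' @param max_paths cap guarding against path explosion; when hit, the
#'   returned list carries attribute `overflow = TRUE`.
#' @return list of character vectors (each a path, first element `gene`);
#'   empty for receptors and isolated genes. Attribute `overflow` flags a
#'   truncated enumeration.
#' @export
downstream_pathways <- function(graph, gene, max_paths = 10000L) {
  stopifnot(inherits(graph, "causal_graph"))
  if (!gene %in% graph$genes) stop("gene not in graph: ", gene)
  adj <- .gene_adjacency(graph)
  receptors <- colnames(adj)[colSums(adj) > 0 & rowSums(adj) == 0]
  paths <- list(); overflow <- FALSE
  walk <- function(path) {
    if (overflow) return()
    v <- path[length(path)]
    kids <- colnames(adj)[adj[v, ]]
    if (!length(kids)) {
      if (length(path) > 1 && v %in% receptors) {
        if (length(paths) >= max_paths) { overflow <<- TRUE; return() }
        paths[[length(paths) + 1L]] <<- path
      }
      return()
    }
    for (k in kids) if (!k %in% path) walk(c(path, k))
  }
  walk(gene)
  attr(paths, "overflow") <- overflow
  paths
}

#' Find cores and their modules
#'
#' A \emph{core} is a gene with high out-degree (default >= 4); its
#' \emph{module} is the core plus its descendant closure, whose boundary is
#' made of receptor genes (receptors have no out-edges, so the closure is
#' naturally truncated there). Modules may overlap; each is identified by
#' its core gene.
#'
#' @param graph a [learn_network()] result.
#' @param core_min_outdegree out-degree threshold for core status.
#' @return list of `module` objects, each a list with `core`, `members`
#'   (core excluded), `boundary` (member receptors), `max_path_length`
#'   (longest directed path from the core within the module).
#' @export
find_modules <- function(graph, core_min_outdegree = 4L) {
  roles <- degrees_and_roles(graph)
  cores <- roles$gene_id[roles$out_degree >= core_min_outdegree]
  adj <- .gene_adjacency(graph)
  lapply(cores, function(core) {
    # BFS descendant closure with path lengths (DAG: longest path via
    # repeated relaxation over members)
    members <- character(0)
    frontier <- colnames(adj)[adj[core, ]]
    while (length(frontier)) {
      members <- union(members, frontier)
      frontier <- setdiff(
        unique(unlist(lapply(frontier, function(v) colnames(adj)[adj[v, ]]))),
        members)
    }
    sub <- c(core, members)
    sub_adj <- adj[sub, sub, drop = FALSE]
    dist <- setNames(rep(-Inf, length(sub)), sub); dist[core] <- 0
    g <- igraph::graph_from_adjacency_matrix(sub_adj, mode = "directed")
    ord <- names(igraph::topo_sort(g))
    for (v in ord) {
      if (!is.finite(dist[v])) next
      for (w in sub[sub_adj[v, ]])
        dist[w] <- max(dist[w], dist[v] + 1)
    }
    boundary <- members[colSums(sub_adj)[members] > 0 &
                          rowSums(sub_adj)[members] == 0]
    structure(list(core = core, members = members, boundary = boundary,
                   max_path_length = max(c(0, dist[is.finite(dist)]))),
              class = "module")
  })
}

#' @export
print.module <- function(x, ...) {
  cat("module[core ", x$core, "]: ", length(x$members), " members, ",
      length(x$boundary), " boundary receptors, max pathway length ",
      x$max_path_length, "\n", sep = "")
  invisible(x)
}

#' Odds ratio between high connectivity and a gene annotation
#'
#' Cross-tabulates high-degree status (degree >= `degree_threshold`, total
#' or out-degree) against a boolean per-gene annotation. OR = ad/bc with
#' Haldane-Anscombe +0.5 correction when any cell is zero; 95\% CI by
#' Woolf's log-OR normal approximation.
#'
#' @param roles a [degrees_and_roles()] table.
#' @param flag named logical vector covering every gene in `roles`.
#' @param degree_threshold high-connectivity cutoff (default 3).
#' @param degree_kind `"total"` or `"out"`.
#' @return list of class `or_result`: `counts` (a, b, c, d), `or`, `ci`
#'   (length 2), `corrected`, or a diagnostic when a margin is empty.
#' @export
annotation_degree_odds_ratio <- function(roles, flag, degree_threshold = 3L,
                                         degree_kind = c("total", "out")) {
  degree_kind <- match.arg(degree_kind)
  if (!all(roles$gene_id %in% names(flag)))
    stop("flag must be defined for all genes")
  fl <- flag[roles$gene_id]
  deg <- if (degree_kind == "total") roles$degree else roles$out_degree
  high <- deg >= degree_threshold
  a <- sum(high & fl); b <- sum(high & !fl)
  cc <- sum(!high & fl); d <- sum(!high & !fl)
  if ((a + b == 0) || (cc + d == 0) || (a + cc == 0) || (b + d == 0))
    return(structure(list(counts = c(a = a, b = b, c = cc, d = d),
                          or = NA_real_, ci = c(NA_real_, NA_real_),
                          corrected = FALSE,
                          diagnostic = "a margin is empty; OR undefined"),
                     class = "or_result"))
  corrected <- any(c(a, b, cc, d) == 0)
  if (corrected) { a <- a + 0.5; b <- b + 0.5; cc <- cc + 0.5; d <- d + 0.5 }
  or <- (a * d) / (b * cc)
  se <- sqrt(1 / a + 1 / b + 1 / cc + 1 / d)
  ci <- exp(log(or) + c(-1, 1) * 1.959963984540054 * se)
  structure(list(counts = c(a = a, b = b, c = cc, d = d), or = or, ci = ci,
                 corrected = corrected, diagnostic = NA_character_),
            class = "or_result")
}

#' @export
print.or_result <- function(x, ...) {
  if (is.na(x$or)) cat("OR undefined:", x$diagnostic, "\n")
  else cat("OR =", signif(x$or, 4), " 95% CI [",
           signif(x$ci[1], 4), ",", signif(x$ci[2], 4), "]",
           if (x$corrected) " (continuity-corrected)", "\n")
  invisible(x)
}

#' Proportion of high-degree genes per annotation class
#'
#' @param roles a [degrees_and_roles()] table.
#' @param flag named logical vector covering every gene.
#' @param degree_threshold high-connectivity cutoff (default 4).
#' @param degree_kind `"total"` or `"out"`.
#' @return list with `prop_flagged`, `prop_unflagged` (exact fractions;
#'   `NA` with a note when a class is empty) and the underlying counts.
#' @export
annotation_degree_proportions <- function(roles, flag, degree_threshold = 4L,
                                          degree_kind = c("total", "out")) {
  degree_kind <- match.arg(degree_kind)
  if (!all(roles$gene_id %in% names(flag)))
    stop("flag must be defined for all genes")
  fl <- flag[roles$gene_id]
  deg <- if (degree_kind == "total") roles$degree else roles$out_degree
  high <- deg >= degree_threshold
  pf <- if (sum(fl) == 0) NA_real_ else sum(high & fl) / sum(fl)
  pu <- if (sum(!fl) == 0) NA_real_ else sum(high & !fl) / sum(!fl)
  list(prop_flagged = pf, prop_unflagged = pu,
       n_flagged = sum(fl), n_unflagged = sum(!fl),
       n_high_flagged = sum(high & fl), n_high_unflagged = sum(high & !fl),
       note = if (anyNA(c(pf, pu))) "empty annotation class" else NA_character_)
}
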