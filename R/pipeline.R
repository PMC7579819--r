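#' Read a pipeline run configuration
#'
#' YAML with any of the fields understood by [run_pipeline()]; omitted
#' fields take the documented defaults. Referenced input paths are checked
#' at validation time.
#'
#' @param path YAML file.
#' @return a validated config list of class `run_config`.
#' @export
read_run_config <- function(path) {
  validate_run_config(yaml::read_yaml(path))
}

#' Default pipeline configuration (synthetic mode)
#' @return a config list of class `run_config`.
#' @export
default_run_config <- function() {
  validate_run_config(list())
}

#' @rdname read_run_config
#' @param config a partially specified config list.
#' @export
validate_run_config <- function(config = list()) {
  def <- list(
    mode = "synthetic", out_dir = tempfile("transnet_run_"), seed = 1L,
    n_cases = 300L, n_controls = 300L, window = 40000L,
    grid = c(0.01, 0.005, 0.001, 0.0005), n_subsamples = 6L,
    subsample_frac = 0.5, alpha_orient = 0.01, f_threshold = 10,
    alpha_validity = 0.05, core_min_outdegree = 4L,
    stability_role = "broadcaster", stability_degree = 1L,
    stability_n_perm = 5L, predict_repeats = 20L, q_threshold = 0.05,
    replication_n = 25L, known_genes = character(0),
    structure_cohort = "pooled",
    expr_path = NULL, genotype_path = NULL, gene_path = NULL,
    hic_path = NULL, covariate_path = NULL, term_set_path = NULL)
  cfg <- utils::modifyList(def, config)
  stopifnot(cfg$mode %in% c("synthetic", "files"),
            cfg$structure_cohort %in% c("pooled", "control", "case"),
            all(cfg$grid > 0 & cfg$grid < 1),
            cfg$q_threshold > 0 && cfg$q_threshold < 1)
  for (f in c("expr_path", "genotype_path", "gene_path", "hic_path",
              "covariate_path", "term_set_path"))
    if (!is.null(cfg[[f]]) && !file.exists(cfg[[f]]))
      stop("configured path does not exist: ", f, " = ", cfg[[f]])
  if (cfg$mode == "files" && is.null(cfg$expr_path))
    stop("mode 'files' requires expr_path")
  class(cfg) <- c("run_config", "list")
  cfg
}

.hash_config <- function(cfg) {
  s <- paste(deparse(cfg[order(names(cfg))]), collapse = "")
  sprintf("cfg%08x", sum(utf8ToInt(s) * (seq_along(utf8ToInt(s)) %% 97 + 1))
          %% .Machine$integer.max)
}

.stage <- function(name, manifest, expr) {
  message("[transnet] stage ", name, " ...")
  val <- tryCatch(expr, error = function(e)
    stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
  val
}

#' Run the full analysis pipeline
#'
#' Executes, in order: simulate (or load) -> residualize -> build-iv ->
#' tune -> learn -> stability -> properties -> compare -> predict ->
#' enrich -> replicate. Every stage logs its input/output sizes, all stage
#' seeds are derived from the single configured seed, and a JSON manifest
#' carrying the config hash, the seed and every written file is saved to
#' the output directory.
#'
#' @param config a config list (see [validate_run_config()] for fields and
#'   defaults) or a YAML path.
#' @return list of class `run_manifest` with one element per stage plus
#'   `files`, `config_hash` and `seed` (also written to
#'   `out_dir/manifest.json`).
#' @export
run_pipeline <- function(config = list()) {
  cfg <- if (is.character(config)) read_run_config(config)
         else validate_run_config(config)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- as.integer(cfg$seed)
  files <- character(0)
  keep <- function(name, path) { files[[name]] <<- path; path }
  stages <- list()

  # --- 1: simulate or load -------------------------------------------
  stages$simulate <- .stage("simulate", stages, {
    if (cfg$mode == "synthetic") {
      st <- synthetic_study(n_cases = cfg$n_cases,
                            n_controls = cfg$n_controls, seed = seed,
                            residualize = FALSE)
      write_genotypes_tsv(st$genotypes,
                          keep("genotypes", file.path(cfg$out_dir,
                                                      "genotypes.tsv")))
      write_expression_tsv(st$expr_raw,
                           keep("expression",
                                file.path(cfg$out_dir, "expression.tsv")))
      write_bedpe(st$hic, keep("hic", file.path(cfg$out_dir, "hic.bedpe")))
      write_gene_annotation(st$genes,
                            keep("genes", file.path(cfg$out_dir,
                                                    "genes.bed")))
      write_truth(st$system,
                  keep("truth", file.path(cfg$out_dir, "truth_edges.tsv")),
                  keep("truth_manifest",
                       file.path(cfg$out_dir, "truth_manifest.json")),
                  params = list(seed = seed, n_cases = cfg$n_cases,
                                n_controls = cfg$n_controls))
      st
    } else {
      expr <- read_expression_tsv(cfg$expr_path)
      list(expr_raw = expr,
           genotypes = if (!is.null(cfg$genotype_path))
             read_genotypes(cfg$genotype_path),
           genes = if (!is.null(cfg$gene_path))
             read_gene_annotation(cfg$gene_path),
           hic = if (!is.null(cfg$hic_path))
             read_hic_bedpe(cfg$hic_path),
           panel = NULL,
           covariates = if (!is.null(cfg$covariate_path)) {
             cv <- read.table(cfg$covariate_path, header = TRUE,
                              sep = "\t", row.names = 1)
             as.matrix(cv)
           })
    }
  })
  st <- stages$simulate

  # --- 2: residualize -------------------------------------------------
  expr <- .stage("residualize", stages, {
    if (!is.null(st$covariates))
      residualize_expression(st$expr_raw, st$covariates)
    else st$expr_raw
  })
  stages$residualize <- list(n_samples = nrow(expr), n_genes = ncol(expr))

  # --- 3: build instruments ------------------------------------------
  ivs <- .stage("build_iv", stages, {
    if (is.null(st$genotypes) || is.null(st$genes)) NULL
    else {
      panel <- if (!is.null(st$panel)) st$panel else attr(st$genotypes,
                                                          "panel")
      iv0 <- build_instruments(st$genotypes, st$genes, panel, st$hic, expr,
                               window = cfg$window,
                               f_threshold = cfg$f_threshold)
      if (n_instruments(iv0) > 0)
        iv0 <- validate_instruments(iv0, expr,
                                    alpha_validity = cfg$alpha_validity)
      utils::write.table(iv0$meta,
                         keep("iv_meta", file.path(cfg$out_dir,
                                                   "iv_metadata.tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      iv0
    }
  })
  stages$build_iv <- list(n_ivs = n_instruments(ivs))

  expr_struct <- switch(cfg$structure_cohort,
                        pooled = expr,
                        control = cohort_subset(expr, "control"),
                        case = cohort_subset(expr, "case"))
  iv_struct <- if (!is.null(ivs) && n_instruments(ivs) > 0 &&
                   cfg$structure_cohort != "pooled") {
    idx <- which(expr_cohort(expr) == cfg$structure_cohort)
    instrument_matrix(ivs$scores[idx, , drop = FALSE], ivs$meta)
  } else ivs

  # --- 4: tune --------------------------------------------------------
  tuning <- .stage("tune", stages, {
    tr <- tune_by_hamming(expr_struct, iv_struct, grid = cfg$grid,
                          n_subsamples = cfg$n_subsamples,
                          subsample_frac = cfg$subsample_frac,
                          seed = seed + 11L,
                          alpha_orient = cfg$alpha_orient)
    utils::write.table(tr$report,
                       keep("tuning", file.path(cfg$out_dir, "tuning.tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    tr
  })
  stages$tune <- list(selected_alpha = tuning$selected)

  # --- 5: learn -------------------------------------------------------
  graph <- .stage("learn", stages, {
    g <- learn_network(expr_struct, iv_struct, alpha = tuning$selected,
                       alpha_orient = cfg$alpha_orient)
    write_edge_list(g, keep("edges", file.path(cfg$out_dir, "edges.tsv")))
    g
  })
  stages$learn <- list(n_gene_edges = nrow(gene_edges(graph)),
                       alpha = graph$alpha)

  # --- 6: stability ---------------------------------------------------
  stages$stability <- .stage("stability", stages, {
    roles <- degrees_and_roles(graph)
    avail <- switch(cfg$stability_role,
                    broadcaster = roles$out_degree[roles$role ==
                                                     "broadcaster"],
                    receptor = roles$in_degree[roles$role == "receptor"])
    if (!length(avail)) {
      list(skipped = "no eligible genes for stability role")
    } else {
      deg <- if (cfg$stability_degree %in% avail) cfg$stability_degree
             else as.integer(names(sort(table(avail),
                                        decreasing = TRUE))[1])
      sr <- permutation_stability(expr_struct, iv_struct, graph,
                                  role = cfg$stability_role, degree = deg,
                                  n_perm = cfg$stability_n_perm,
                                  seed = seed + 13L)
      utils::write.table(sr$per_perm,
                         keep("stability",
                              file.path(cfg$out_dir, "stability.tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      list(mean_stability = sr$mean_stability, degree = deg)
    }
  })

  # --- 7: properties --------------------------------------------------
  props <- .stage("properties", stages, {
    roles <- degrees_and_roles(graph)
    utils::write.table(roles,
                       keep("roles", file.path(cfg$out_dir, "roles.tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    modules <- find_modules(graph,
                            core_min_outdegree = cfg$core_min_outdegree)
    if (length(modules)) {
      mod_tab <- do.call(rbind, lapply(modules, function(m)
        data.frame(core = m$core, n_members = length(m$members),
                   members = paste(m$members, collapse = ","),
                   max_path_length = m$max_path_length)))
      utils::write.table(mod_tab,
                         keep("modules",
                              file.path(cfg$out_dir, "modules.tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
    flag <- setNames(roles$has_iv, roles$gene_id)
    or_res <- annotation_degree_odds_ratio(roles, flag,
                                           degree_threshold = 3L)
    list(roles = roles, modules = modules, iv_degree_or = or_res)
  })
  stages$properties <- list(n_modules = length(props$modules),
                            iv_degree_or = props$iv_degree_or$or)

  # --- 8: compare -----------------------------------------------------
  expr_cases <- cohort_subset(expr, "case")
  expr_controls <- cohort_subset(expr, "control")
  two_cohorts <- nrow(expr_cases) > 0 && nrow(expr_controls) > 0
  cmp <- .stage("compare", stages, {
    if (!two_cohorts) list(skipped = "single-cohort data") else {
      sem_ctl <- fit_sem(expr_controls, graph)
      sem_cas <- fit_sem(expr_cases, graph)
      lm_res <- detect_lost_mediators(expr_cases, expr_controls, graph)
      if (!is.null(lm_res$effects))
        utils::write.table(lm_res$effects,
                           keep("exclusive_effects",
                                file.path(cfg$out_dir,
                                          "exclusive_effects.tsv")),
                           sep = "\t", quote = FALSE, row.names = FALSE)
      utils::write.table(lm_res$lost,
                         keep("lost_mediators",
                              file.path(cfg$out_dir,
                                        "lost_mediators.tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      list(sem_control = sem_ctl, sem_case = sem_cas, lost = lm_res)
    }
  })
  stages$compare <- if (two_cohorts)
    list(n_lost = nrow(cmp$lost$lost),
         n_candidate_mediators = length(cmp$lost$candidates))
  else cmp

  # --- 9: predict -----------------------------------------------------
  preds <- .stage("predict", stages, {
    if (!length(props$modules)) list(skipped = "no modules") else {
      res <- lapply(props$modules, function(m) {
        pc <- core_prediction_cv(expr_controls, m, graph,
                                 repeats = cfg$predict_repeats,
                                 seed = seed + 17L)
        if (two_cohorts && nrow(expr_cases) >= 25) {
          pa <- core_prediction_cv(expr_cases, m, graph,
                                   repeats = cfg$predict_repeats,
                                   seed = seed + 17L)
          pc$good_predictor <- pc$good_predictor & pa$good_predictor
          pc$mean_corr_cases <- pa$mean_corr
          pc$mean_mspe_cases <- pa$mean_mspe
        }
        pc
      })
      tab <- do.call(rbind, c(res, list(make.row.names = FALSE)))
      utils::write.table(tab,
                         keep("predictions",
                              file.path(cfg$out_dir, "predictions.tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      tab
    }
  })
  stages$predict <- if (is.data.frame(preds))
    list(n_targets = nrow(preds), n_good = sum(preds$good_predictor))
  else preds

  # --- candidates (part of predict stage outputs) ---------------------
  if (is.data.frame(preds) && two_cohorts && length(props$modules)) {
    cands <- lapply(props$modules, function(m) {
      good <- preds$good_predictor[preds$core == m$core]
      if (!any(good)) return(character(0))
      conditional_novel_genes(expr_cases, expr_controls, m, graph,
                              known_genes = cfg$known_genes,
                              q_threshold = cfg$q_threshold)$candidates
    })
    stages$predict$candidates <- sort(unique(unlist(cands)))
  }

  # --- 10: enrich -----------------------------------------------------
  stages$enrich <- .stage("enrich", stages, {
    term_sets <- if (!is.null(cfg$term_set_path))
      read_term_sets(cfg$term_set_path)
    else {
      roles <- props$roles
      ts <- split(roles$gene_id, roles$role)
      for (m in props$modules)
        ts[[paste0("module_", m$core)]] <- c(m$core, m$members)
      ts
    }
    roles <- props$roles
    query <- roles$gene_id[roles$degree >= 3]
    if (!length(query)) list(skipped = "empty query") else {
      enr <- hypergeom_enrichment(query, term_sets, roles$gene_id)
      utils::write.table(enr,
                         keep("enrichment",
                              file.path(cfg$out_dir, "enrichment.tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      list(n_terms = nrow(enr), n_significant = sum(enr$q < cfg$q_threshold))
    }
  })

  # --- 11: replicate --------------------------------------------------
  stages$replicate <- .stage("replicate", stages, {
    if (cfg$mode != "synthetic" || nrow(gene_edges(graph)) == 0) {
      list(skipped = "no replication data")
    } else {
      rep_geno <- simulate_genotypes(st$panel, cfg$replication_n,
                                     seed = seed + 19L)
      rep_expr <- simulate_cohorts(st$system, rep_geno,
                                   n_cases = 0L,
                                   n_controls = cfg$replication_n,
                                   covariates = simulate_covariates(
                                     cfg$replication_n, seed = seed + 20L),
                                   seed = seed + 21L)
      rr <- replicate_edges(graph, rep_expr,
                            q_threshold = cfg$q_threshold)
      utils::write.table(rr$edges,
                         keep("replication",
                              file.path(cfg$out_dir, "replication.tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      list(fraction_replicated = rr$fraction_replicated,
           n_edges = nrow(rr$edges))
    }
  })

  manifest <- list(config_hash = .hash_config(cfg), seed = seed,
                   stages = names(stages), files = as.list(files),
                   summary = stages[setdiff(names(stages), "simulate")])
  jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  out <- c(stages["simulate"], list(graph = graph, tuning = tuning,
                                    ivs = ivs, expr = expr),
           manifest)
  class(out) <- c("run_manifest", "list")
  out
}

#' @export
print.run_manifest <- function(x, ...) {
  cat("transnet run:", length(x$stages), "stages, config", x$config_hash,
      ", seed", x$seed, "\n")
  cat("outputs:", length(x$files), "files\n")
  invisible(x)
}
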