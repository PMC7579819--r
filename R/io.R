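#' Write genotypes as TSV
#'
#' Samples in rows (first column `sample_id`), SNP ids as remaining column
#' headers, additive {0,1,2} calls.
#'
#' @param genotypes a genotype matrix (samples x SNPs).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_genotypes_tsv <- function(genotypes, path) {
  df <- data.frame(sample_id = rownames(genotypes),
                   as.data.frame(unclass(genotypes)), check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write genotypes as a minimal VCF (GT field only)
#'
#' @param genotypes a genotype matrix with a [snp_panel()] attached (as
#'   produced by [simulate_genotypes()]), or supply `panel`.
#' @param path output `.vcf` file.
#' @param panel optional [snp_panel()] overriding the attached one.
#' @return `path`, invisibly.
#' @export
write_genotypes_vcf <- function(genotypes, path, panel = NULL) {
  if (is.null(panel)) panel <- attr(genotypes, "panel")
  if (is.null(panel)) stop("no SNP panel available for coordinates")
  stopifnot(identical(panel$snp_id, colnames(genotypes)))
  gt_code <- c(`0` = "0/0", `1` = "0/1", `2` = "1/1")
  header <- c("##fileformat=VCFv4.2",
              "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
              paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                      "INFO", "FORMAT", rownames(genotypes)),
                    collapse = "\t"))
  body <- vapply(seq_len(nrow(panel)), function(j) {
    paste(c(panel$chrom[j], panel$pos[j], panel$snp_id[j], "A", "G", ".",
            "PASS", ".", "GT", gt_code[as.character(genotypes[, j])]),
          collapse = "\t")
  }, character(1))
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read genotypes from TSV or VCF
#'
#' TSV as written by [write_genotypes_tsv()]; VCF (GT field) via the vcfR
#' package when the file ends in `.vcf`.
#'
#' @param path input file.
#' @return integer matrix (samples x SNPs).
#' @export
read_genotypes <- function(path) {
  if (grepl("\\.vcf$", path, ignore.case = TRUE)) {
    if (!requireNamespace("vcfR", quietly = TRUE))
      stop("reading VCF requires the vcfR package")
    v <- vcfR::read.vcfR(path, verbose = FALSE)
    gt <- vcfR::extract.gt(v, element = "GT")
    counts <- matrix(vapply(strsplit(gt, "[/|]"),
                            function(a) sum(a != "0"), integer(1)),
                     nrow = nrow(gt), dimnames = dimnames(gt))
    return(t(counts))
  }
  df <- read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                   stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  storage.mode(m) <- "integer"
  m
}

#' Write an expression matrix as TSV
#'
#' Samples in rows with `sample_id` and `cohort` columns, gene ids as the
#' remaining headers.
#'
#' @param expr an [expression_matrix()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_expression_tsv <- function(expr, path) {
  df <- data.frame(sample_id = rownames(expr), cohort = expr_cohort(expr),
                   as.data.frame(unclass_expr(expr)), check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an expression matrix written by [write_expression_tsv()]
#' @param path input file.
#' @return an [expression_matrix()].
#' @export
read_expression_tsv <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                   stringsAsFactors = FALSE)
  m <- as.matrix(df[, setdiff(names(df), c("sample_id", "cohort")),
                    drop = FALSE])
  rownames(m) <- df$sample_id
  expression_matrix(m, df$cohort)
}

#' Write a Hi-C contact map as 6-column BEDPE
#' @param hic a [simulate_hic_map()]-style data.frame.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_bedpe <- function(hic, path) {
  write.table(hic[, c("chrom_a", "start_a", "end_a",
                      "chrom_b", "start_b", "end_b")],
              path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Read a BEDPE contact map
#' @param path input file (at least 6 columns, 0-based half-open anchors).
#' @return data.frame of class `hic_map`.
#' @export
read_hic_bedpe <- function(path) {
  df <- read.table(path, header = FALSE, sep = "\t",
                   stringsAsFactors = FALSE)
  out <- df[, 1:6]
  names(out) <- c("chrom_a", "start_a", "end_a",
                  "chrom_b", "start_b", "end_b")
  class(out) <- c("hic_map", "data.frame")
  out
}

#' Read a BED-like gene annotation
#'
#' Five tab-separated columns: chrom, tss, tes, strand, gene id (no
#' header).
#'
#' @param path input file.
#' @return a [gene_annotation()].
#' @export
read_gene_annotation <- function(path) {
  df <- read.table(path, header = FALSE, sep = "\t",
                   stringsAsFactors = FALSE)
  gene_annotation(gene_id = df[[5]], chrom = df[[1]], tss = df[[2]],
                  tes = df[[3]], strand = df[[4]])
}

#' Write a gene annotation as BED-like TSV
#' @param genes a [gene_annotation()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_gene_annotation <- function(genes, path) {
  write.table(genes[, c("chrom", "start", "end", "strand", "gene_id")],
              path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Read gene-set annotations from a two-column TSV (term, gene)
#' @param path input file (no header).
#' @return named list: term -> character vector of genes.
#' @export
read_term_sets <- function(path) {
  df <- read.table(path, header = FALSE, sep = "\t",
                   stringsAsFactors = FALSE)
  split(df[[2]], df[[1]])
}

#' Write a causal graph as an edge-list TSV
#' @param graph a [learn_network()] result.
#' @param path output file (columns source, target, edge_type, effect, p).
#' @return `path`, invisibly.
#' @export
write_edge_list <- function(graph, path) {
  ed <- graph$edges
  names(ed)[1:3] <- c("source", "target", "edge_type")
  write.table(ed, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write the ground-truth edges and a JSON parameter manifest
#' @param system a [true_system()].
#' @param edge_path TSV path for the truth edge list (source, target,
#'   effect).
#' @param manifest_path JSON path for seeds/parameters (optional).
#' @param params list written to the manifest.
#' @return `edge_path`, invisibly.
#' @export
write_truth <- function(system, edge_path, manifest_path = NULL,
                        params = list()) {
  ed <- true_edges(system)
  names(ed) <- c("source", "target", "effect")
  write.table(ed, edge_path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(manifest_path))
    jsonlite::write_json(params, manifest_path, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
  invisible(edge_path)
}
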