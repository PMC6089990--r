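#' Load and validate a pipeline configuration
#'
#' Configuration is a YAML file (or an equivalent named list) with the
#' sections:
#' \describe{
#'   \item{paths}{`fasta`, `gff`, `mutant`, `parent` (VCF `.vcf` or
#'     delimited tables), optional `gene_set`, `expression`, `probe_map`.}
#'   \item{thresholds}{`blosum_threshold` (default 0), `alpha` (default
#'     0.01), `ratio` (default 2.0).}
#'   \item{inactivating_policy}{`"default"` or `"include-inframe"`.}
#'   \item{table_format}{column mapping for delimited variant tables
#'     (`chrom`, `pos`, `ref`, `alt`).}
#'   \item{output_dir}{run directory for artifacts.}
#'   \item{seed}{seed recorded in the manifest.}
#' }
#'
#' @param config Path to a YAML file or a named list.
#' @return Validated config list with defaults filled in.
#' @export
pipeline_config <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config))
  defaults <- list(
    thresholds = list(blosum_threshold = 0L, alpha = 0.01, ratio = 2.0),
    inactivating_policy = "default",
    table_format = list(chrom = "chrom", pos = "pos", ref = "ref",
                        alt = "alt"),
    output_dir = "conseqr_run",
    seed = 1L
  )
  for (k in names(defaults)) {
    if (is.null(config[[k]])) {
      config[[k]] <- defaults[[k]]
    } else if (is.list(defaults[[k]])) {
      for (kk in names(defaults[[k]])) {
        if (is.null(config[[k]][[kk]])) config[[k]][[kk]] <- defaults[[k]][[kk]]
      }
    }
  }
  th <- config$thresholds
  if (th$alpha <= 0 || th$alpha > 1) stop("alpha must be in (0, 1]")
  if (th$ratio < 1) stop("ratio threshold must be >= 1")
  for (key in c("fasta", "gff", "mutant", "parent")) {
    p <- config$paths[[key]]
    if (is.null(p)) stop("config paths$", key, " is required")
    if (!file.exists(p)) stop("missing input file for paths$", key, ": ", p)
  }
  config
}

read_strain_input <- function(path, genome, config, strain) {
  if (grepl("\\.vcf(\\.gz)?$", path)) {
    read_vcf(path, genome, strain = strain)
  } else {
    read_variant_table(path, genome, strain = strain,
                       columns = config$table_format)
  }
}

#' Run the annotation pipeline end-to-end
#'
#' Reads the reference and annotation, both strain variant sets, computes
#' the mutant-private differential variants, classifies their consequences,
#' and writes a run directory containing the full consequence table, the
#' per-gene variation report, the summary JSON, a normalized differential
#' VCF, and a manifest recording inputs (with checksums), thresholds and
#' package version. Progress is logged with `message()`.
#'
#' @param config See [pipeline_config()].
#' @return The `ConsequenceSummary`, invisibly; artifact paths in
#'   `attr(, "artifacts")`.
#' @export
run_annotate <- function(config) {
  config <- pipeline_config(config)
  t0 <- Sys.time()
  message("reading reference: ", config$paths$fasta)
  genome <- read_fasta(config$paths$fasta)
  message("reading gene models: ", config$paths$gff)
  genes <- read_gff3(config$paths$gff, genome)
  message("reading variant sets")
  mutant <- read_strain_input(config$paths$mutant, genome, config, "mutant")
  parent <- read_strain_input(config$paths$parent, genome, config, "parent")
  diff <- differential_variants(mutant, parent)
  message(nrow(diff$variants), " differential variant(s) (",
          nrow(mutant$variants), " mutant, ", nrow(parent$variants),
          " parent)")
  matrix <- substitution_matrix(threshold = config$thresholds$blosum_threshold)
  ann <- annotate_variants(diff, genome, genes, matrix = matrix,
                           policy = config$inactivating_policy)
  summary <- summarize_consequences(ann)

  out <- config$output_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  ann_path <- file.path(out, "consequences.tsv")
  utils::write.table(ann, ann_path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  report_path <- file.path(out, "gene_report.tsv")
  utils::write.table(format_gene_report(ann, genes, genome), report_path,
                     sep = "\t", row.names = FALSE, quote = FALSE)
  vcf_path <- file.path(out, "differential.vcf")
  write_vcf(diff, genome, vcf_path)
  summary_path <- file.path(out, "summary.json")
  jsonlite::write_json(unclass(summary), summary_path, auto_unbox = TRUE,
                       pretty = TRUE)
  manifest <- list(
    package = "conseqr",
    version = as.character(utils::packageVersion("conseqr")),
    started = format(t0, "%Y-%m-%d %H:%M:%S"),
    seed = config$seed,
    thresholds = config$thresholds,
    inactivating_policy = config$inactivating_policy,
    inputs = lapply(config$paths, function(p)
      list(path = p, md5 = unname(tools::md5sum(p)))),
    artifacts = list(consequences = ann_path, gene_report = report_path,
                     differential_vcf = vcf_path, summary = summary_path)
  )
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  message("run complete: ", out)
  attr(summary, "artifacts") <- manifest$artifacts
  invisible(summary)
}

#' Render a human-readable report from a summary JSON
#'
#' Deterministic plain-text rendering of a pipeline summary: the tally
#' sentence plus, when a gene report is available alongside, the per-gene
#' variation table. Validates the summary schema before rendering.
#'
#' @param summary A `ConsequenceSummary`, or the path to a `summary.json`
#'   written by [run_annotate()].
#' @param gene_report Optional data frame (or TSV path) from
#'   [format_gene_report()].
#' @return Character vector of report lines.
#' @export
run_report <- function(summary, gene_report = NULL) {
  if (is.character(summary)) {
    summary <- jsonlite::read_json(summary, simplifyVector = TRUE)
  }
  need <- c("counts", "n_variants", "n_genes_affected", "n_inactivating",
            "schema_version")
  missing_f <- setdiff(need, names(summary))
  if (length(missing_f) > 0L) {
    stop("summary schema mismatch; missing fields: ",
         paste(missing_f, collapse = ", "))
  }
  if (!identical(as.character(summary$schema_version), "1.0")) {
    stop("unsupported summary schema version: ", summary$schema_version)
  }
  cts <- summary$counts
  miss <- cts$missense_conservative + cts$missense_nonconservative
  lines <- c(
    sprintf("Differential CDS consequences: %d variant-gene pair(s) affecting %d coding sequence(s).",
            summary$n_variants, summary$n_genes_affected),
    sprintf("  %d missense (%d conservative, %d non-conservative), %d nonsense, %d sense (stop-loss), %d frameshift, %d in-frame indel, %d synonymous, %d start-loss, %d complex.",
            miss, cts$missense_conservative, cts$missense_nonconservative,
            cts$nonsense, cts$sense, cts$frameshift, cts$inframe_indel,
            cts$synonymous, cts$start_loss, cts$complex),
    sprintf("  CDS-inactivating: %d.", summary$n_inactivating)
  )
  if (!is.null(gene_report)) {
    if (is.character(gene_report)) {
      gene_report <- utils::read.delim(gene_report, stringsAsFactors = FALSE)
    }
    lines <- c(lines, "",
               paste("chromosome", "gene_id", "symbol", "cds_length",
                     "variation", sep = "\t"))
    if (nrow(gene_report) > 0L) {
      lines <- c(lines, sprintf("%s\t%s\t%s\t%d\t%s",
                                gene_report$chromosome, gene_report$gene_id,
                                gene_report$symbol, gene_report$cds_length,
                                gene_report$variation))
    }
  }
  lines
}
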