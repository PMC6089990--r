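#' Differential-expression threshold filter
#'
#' Per-probe two-sided t-tests (Welch by default) between treated and
#' control replicates, combined with a linear-scale fold-change threshold on
#' the ratio of replicate means. A probe is retained iff `p < alpha` AND
#' the ratio is `> ratio` (up) or `< 1/ratio` (down) — both inequalities
#' strict, so a probe sitting exactly on a threshold is excluded.
#'
#' @param intensities Numeric matrix of positive intensities, probes in rows
#'   (rownames are probe ids), samples in columns.
#' @param condition Character/factor vector, one of `"treated"`/`"control"`
#'   per column; at least 2 replicates of each.
#' @param alpha P-value threshold (strict).
#' @param ratio Fold-change threshold (strict, linear scale).
#' @param log_scale Run the t-test on log2 intensities (default) or on the
#'   linear scale.
#' @param var_equal Pooled-variance t-test instead of Welch.
#' @return Data frame with `probe`, `ratio` (treated/control), `p_value`,
#'   `direction` (`"up"`/`"down"`), `retained`.
#' @export
de_filter <- function(intensities, condition, alpha = 0.01, ratio = 2.0,
                      log_scale = TRUE, var_equal = FALSE) {
  m <- as.matrix(intensities)
  if (is.null(rownames(m))) stop("intensity matrix needs probe rownames")
  if (anyNA(m) || any(m <= 0)) stop("intensities must be positive and complete")
  condition <- as.character(condition)
  if (length(condition) != ncol(m)) {
    stop("condition labels must match the number of columns")
  }
  bad <- setdiff(unique(condition), c("treated", "control"))
  if (length(bad) > 0L) stop("unknown condition label(s): ",
                             paste(bad, collapse = ", "))
  trt <- condition == "treated"
  if (sum(trt) < 2L || sum(!trt) < 2L) {
    stop("need >= 2 replicates per condition")
  }
  tm <- if (log_scale) log2(m) else m
  pv <- vapply(seq_len(nrow(m)), function(i) {
    stats::t.test(tm[i, trt], tm[i, !trt], var.equal = var_equal)$p.value
  }, numeric(1L))
  fc <- rowMeans(m[, trt, drop = FALSE]) / rowMeans(m[, !trt, drop = FALSE])
  data.frame(
    probe = rownames(m),
    ratio = unname(fc),
    p_value = pv,
    direction = ifelse(fc > 1, "up", "down"),
    retained = pv < alpha & (fc > ratio | fc < 1 / ratio),
    row.names = NULL
  )
}

#' Overlap of retained DE probes with a gene set
#'
#' Counts retained up- and down-regulated probes whose gene belongs to a
#' gene set (for example a curated mitochondrial-proteome list). Probe ids
#' are harmonized to gene ids via `probe_map`; probes without a mapping are
#' excluded with a message.
#'
#' @param results Output of [de_filter()].
#' @param gene_set Character vector of gene ids (or a list with `members`).
#' @param probe_map Optional data frame with columns `probe`, `gene`; when
#'   `NULL`, probe ids are used as gene ids directly.
#' @return Named integer vector `c(n_up = ..., n_down = ...)`.
#' @export
set_overlap <- function(results, gene_set, probe_map = NULL) {
  members <- if (is.list(gene_set) && !is.null(gene_set$members))
    gene_set$members else gene_set
  members <- unique(as.character(members))
  kept <- results[results$retained, , drop = FALSE]
  if (is.null(probe_map)) {
    kept$gene <- kept$probe
  } else {
    idx <- match(kept$probe, probe_map$probe)
    if (anyNA(idx)) {
      message(sum(is.na(idx)), " retained probe(s) without a gene mapping; excluded")
    }
    kept$gene <- probe_map$gene[idx]
    kept <- kept[!is.na(kept$gene), , drop = FALSE]
  }
  inset <- kept$gene %in% members
  c(n_up = sum(inset & kept$direction == "up"),
    n_down = sum(inset & kept$direction == "down"))
}

#' Fraction of the transcriptome called differentially expressed
#'
#' `100 * n_de / n_probesets`, rounded half-up to two decimals (so 6.3688
#' reports as 6.37).
#'
#' @param n_de Number of differentially expressed loci.
#' @param n_probesets Total number of probe sets on the array.
#' @return Percentage, two decimals.
#' @export
transcriptome_fraction <- function(n_de, n_probesets) {
  stopifnot(n_probesets > 0)
  floor(100 * n_de / n_probesets * 100 + 0.5) / 100
}

#' Read an expression matrix from a delimited file
#'
#' Expects probes in rows (first column = probe id) and a header row of
#' sample names; condition labels are supplied separately or parsed from
#' column names of the form `treated_1`, `control_2`, ...
#'
#' @param path Path to a TSV file.
#' @param condition Optional condition labels; parsed from column-name
#'   prefixes when omitted.
#' @return List with `intensities` (matrix) and `condition`.
#' @export
read_expression_matrix <- function(path, condition = NULL) {
  tab <- utils::read.delim(path, check.names = FALSE)
  m <- as.matrix(tab[, -1L, drop = FALSE])
  rownames(m) <- as.character(tab[[1L]])
  if (anyDuplicated(rownames(m))) stop("duplicate probe ids in ", path)
  if (is.null(condition)) {
    condition <- sub("_.*$", "", colnames(m))
  }
  list(intensities = m, condition = condition)
}

#' Read a gene set (one id per line)
#'
#' @param path Path to a plain-text file, one gene id per line; blank lines
#'   and lines starting with `#` are ignored.
#' @param name Set name (defaults to the file name).
#' @return List with `name` and unique `members`.
#' @export
read_gene_set <- function(path, name = NULL) {
  if (is.null(name)) name <- sub("\\.[^.]*$", "", basename(path))
  ids <- readLines(path)
  ids <- trimws(ids)
  ids <- ids[nzchar(ids) & !startsWith(ids, "#")]
  list(name = name, members = unique(ids))
}

#' Read a probe-to-gene map (two-column TSV)
#'
#' @param path Path to a TSV with columns `probe` and `gene` (header
#'   required).
#' @return Data frame with `probe`, `gene`.
#' @export
read_probe_map <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("probe", "gene") %in% names(tab))) {
    stop("probe map needs 'probe' and 'gene' columns")
  }
  tab[, c("probe", "gene")]
}
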