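#' Construct a gene model
#'
#' A `GeneModel` is a stranded set of CDS segments on one chromosome, the
#' coordinate frame for all consequence calls. Coordinates are 1-based
#' inclusive (GFF3/VCF convention) throughout.
#'
#' @param gene_id Stable gene identifier.
#' @param chromosome Chromosome id (must exist in the genome when models are
#'   read via [read_gff3()]).
#' @param strand `"+"` or `"-"`.
#' @param segments Data frame with `start` and `end` columns, 1-based
#'   inclusive, non-overlapping. Stored sorted in genomic order.
#' @param symbol Gene symbol; defaults to `gene_id`.
#' @param description Free-text description.
#' @return A `GeneModel` object. `coding_ok` is `FALSE` when the total CDS
#'   length is not divisible by 3; such genes are kept for locating variants
#'   but excluded from codon-level classification.
#' @export
GeneModel <- function(gene_id, chromosome, strand, segments,
                      symbol = gene_id, description = "") {
  stopifnot(is.character(gene_id), length(gene_id) == 1L)
  if (!strand %in% c("+", "-")) stop("strand must be '+' or '-'")
  segments <- as.data.frame(segments)[, c("start", "end")]
  segments$start <- as.integer(segments$start)
  segments$end <- as.integer(segments$end)
  segments <- segments[order(segments$start), , drop = FALSE]
  rownames(segments) <- NULL
  if (any(segments$end < segments$start)) {
    stop("gene ", gene_id, ": segment end < start")
  }
  if (nrow(segments) > 1L &&
      any(segments$start[-1L] <= segments$end[-nrow(segments)])) {
    stop("gene ", gene_id, ": overlapping CDS segments")
  }
  len <- sum(segments$end - segments$start + 1L)
  structure(list(
    gene_id = gene_id,
    symbol = symbol,
    chromosome = chromosome,
    strand = strand,
    segments = segments,
    description = description,
    cds_length = len,
    length_codons = if (len %% 3L == 0L) len %/% 3L else NA_integer_,
    coding_ok = len %% 3L == 0L
  ), class = "GeneModel")
}

#' @export
print.GeneModel <- function(x, ...) {
  cat(sprintf("GeneModel %s (%s) %s:%s strand %s, %d segment(s), %d nt%s\n",
              x$gene_id, x$symbol, x$chromosome,
              paste0(min(x$segments$start), "-", max(x$segments$end)),
              x$strand, nrow(x$segments), x$cds_length,
              if (x$coding_ok) sprintf(" (%d codons)", x$length_codons)
              else " [not a multiple of 3; excluded from classification]"))
  invisible(x)
}

#' Read gene models from GFF3
#'
#' Builds one [GeneModel()] per gene by grouping CDS features through their
#' `Parent` attributes (CDS -> mRNA -> gene, or CDS -> gene directly).
#' CDS-only files (no gene/mRNA features) are accepted: each distinct CDS
#' `Parent` (or `ID`) becomes a gene. Genes whose total CDS length is not
#' divisible by 3 are flagged (`coding_ok = FALSE`) with a warning and are
#' excluded from codon-level consequence calling downstream. CDS features
#' without any parent linkage are skipped with a warning.
#'
#' @param path Path to a GFF3 file.
#' @param genome A `Genome`; CDS segments outside chromosome bounds raise an
#'   error.
#' @param feature_types Feature types treated as CDS segments.
#' @return Named list of `GeneModel` objects, keyed by gene id.
#' @export
read_gff3 <- function(path, genome, feature_types = "CDS") {
  if (!file.exists(path)) stop("GFF3 file not found: ", path)
  gr <- rtracklayer::import(path, format = "gff3")
  mc <- S4Vectors::mcols(gr)
  type <- as.character(mc$type)
  ids <- if ("ID" %in% names(mc)) as.character(mc$ID) else rep(NA_character_, length(gr))
  parents <- if ("Parent" %in% names(mc)) {
    vapply(as.list(mc$Parent), function(p) {
      if (length(p) == 0L) NA_character_ else p[[1L]]
    }, character(1L))
  } else rep(NA_character_, length(gr))

  # map transcript id -> gene id
  tx2gene <- list()
  is_tx <- type %in% c("mRNA", "transcript")
  for (i in which(is_tx)) {
    if (!is.na(ids[i])) {
      tx2gene[[ids[i]]] <- if (!is.na(parents[i])) parents[i] else ids[i]
    }
  }
  gene_meta <- list()
  for (i in which(type == "gene")) {
    if (is.na(ids[i])) next
    nm <- if ("Name" %in% names(mc) && !is.na(mc$Name[i])) as.character(mc$Name[i]) else ids[i]
    desc <- if ("description" %in% names(mc) && !is.na(mc$description[i]))
      as.character(mc$description[i]) else ""
    gene_meta[[ids[i]]] <- list(symbol = nm, description = desc)
  }

  cds_idx <- which(type %in% feature_types)
  if (length(cds_idx) == 0L) stop("no CDS features in ", path)

  groups <- list()
  for (i in cds_idx) {
    key <- parents[i]
    if (is.na(key)) key <- ids[i]
    if (is.na(key)) {
      warning("CDS feature at ", as.character(GenomicRanges::seqnames(gr))[i],
              ":", GenomicRanges::start(gr)[i],
              " has no Parent/ID; skipped")
      next
    }
    gene_id <- if (!is.null(tx2gene[[key]])) tx2gene[[key]] else key
    groups[[gene_id]] <- c(groups[[gene_id]], i)
  }

  models <- list()
  for (gene_id in names(groups)) {
    idx <- groups[[gene_id]]
    chrom <- unique(as.character(GenomicRanges::seqnames(gr))[idx])
    strand <- unique(as.character(GenomicRanges::strand(gr))[idx])
    if (length(chrom) != 1L || length(strand) != 1L) {
      warning("gene ", gene_id, ": inconsistent chromosome/strand; skipped")
      next
    }
    if (!strand %in% c("+", "-")) {
      warning("gene ", gene_id, ": unstranded CDS; skipped")
      next
    }
    if (!chrom %in% names(genome)) {
      stop("gene ", gene_id, ": chromosome '", chrom, "' not in genome")
    }
    seg <- data.frame(start = GenomicRanges::start(gr)[idx],
                      end = GenomicRanges::end(gr)[idx])
    n <- chrom_length(genome, chrom)
    if (any(seg$start < 1L) || any(seg$end > n)) {
      stop("gene ", gene_id, ": CDS outside chromosome bounds")
    }
    meta <- gene_meta[[gene_id]]
    gm <- GeneModel(gene_id, chrom, strand, seg,
                    symbol = if (!is.null(meta)) meta$symbol else gene_id,
                    description = if (!is.null(meta)) meta$description else "")
    if (!gm$coding_ok) {
      warning("gene ", gene_id, ": CDS length ", gm$cds_length,
              " not divisible by 3; excluded from consequence calling")
    }
    models[[gene_id]] <- gm
  }
  models
}

#' Write gene models to GFF3
#'
#' Emits gene, mRNA and CDS features with ID/Parent linkage so the file
#' round-trips through [read_gff3()].
#'
#' @param genes Named list of `GeneModel` objects.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(genes, path) {
  chroms <- character(0); starts <- integer(0); ends <- integer(0)
  strands <- character(0); types <- character(0); phases <- integer(0)
  ids <- character(0); parents <- list(); names_ <- character(0)
  for (g in genes) {
    gs <- min(g$segments$start); ge <- max(g$segments$end)
    mrna_id <- paste0(g$gene_id, "_mRNA")
    n_seg <- nrow(g$segments)
    # GFF3 phase: bases to trim from the segment start (in transcript
    # order) to reach the next codon boundary
    seg_len <- g$segments$end - g$segments$start + 1L
    tx_order <- if (g$strand == "+") seq_len(n_seg) else rev(seq_len(n_seg))
    prev <- c(0L, cumsum(seg_len[tx_order]))[seq_len(n_seg)]
    phase_tx <- (3L - prev %% 3L) %% 3L
    phase <- integer(n_seg)
    phase[tx_order] <- phase_tx
    chroms <- c(chroms, g$chromosome, g$chromosome, rep(g$chromosome, n_seg))
    starts <- c(starts, gs, gs, g$segments$start)
    ends <- c(ends, ge, ge, g$segments$end)
    strands <- c(strands, rep(g$strand, 2L + n_seg))
    types <- c(types, "gene", "mRNA", rep("CDS", n_seg))
    phases <- c(phases, NA_integer_, NA_integer_, phase)
    ids <- c(ids, g$gene_id, mrna_id, rep(NA_character_, n_seg))
    parents <- c(parents, list(character(0)), list(g$gene_id),
                 rep(list(mrna_id), n_seg))
    names_ <- c(names_, g$symbol, rep(NA_character_, 1L + n_seg))
  }
  gr <- GenomicRanges::GRanges(chroms, IRanges::IRanges(starts, ends),
                               strand = strands)
  gr$type <- types
  gr$phase <- phases
  gr$ID <- ids
  gr$Name <- names_
  gr$Parent <- IRanges::CharacterList(parents)
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Extract the spliced, strand-corrected coding sequence of a gene
#'
#' Segments are concatenated in genomic order; for minus-strand genes the
#' concatenation is reverse-complemented so the result reads 5'->3' in
#' transcript orientation. Warns (does not fail) when the CDS does not start
#' with ATG, does not end with a stop codon, or contains `N`.
#'
#' @param gene A `GeneModel`.
#' @param genome A `Genome`.
#' @return A `CodingSequence` object: list with `gene_id`, `nucleotides` and
#'   `length_codons` (codon count including the stop codon).
#' @export
extract_cds <- function(gene, genome) {
  parts <- mapply(function(s, e) genome_slice(genome, gene$chromosome, s, e),
                  gene$segments$start, gene$segments$end)
  nt <- paste(parts, collapse = "")
  if (gene$strand == "-") nt <- revcomp(nt)
  n <- nchar(nt)
  if (grepl("N", nt, fixed = TRUE)) {
    warning("gene ", gene$gene_id, ": CDS contains N")
  }
  if (n %% 3L == 0L) {
    if (substr(nt, 1L, 3L) != "ATG") {
      warning("gene ", gene$gene_id, ": CDS does not start with ATG")
    }
    if (!substr(nt, n - 2L, n) %in% STOP_CODONS) {
      warning("gene ", gene$gene_id, ": CDS does not end with a stop codon")
    }
  }
  structure(list(
    gene_id = gene$gene_id,
    nucleotides = nt,
    length_codons = if (n %% 3L == 0L) n %/% 3L else NA_integer_
  ), class = "CodingSequence")
}

# 1-based CDS offset (transcript orientation) of a genomic position, or NA
# when the position does not fall inside any CDS segment of the gene.
cds_offset_of <- function(gene, pos) {
  seg <- gene$segments
  cum <- 0L
  plus_off <- NA_integer_
  for (i in seq_len(nrow(seg))) {
    if (pos >= seg$start[i] && pos <= seg$end[i]) {
      plus_off <- cum + (pos - seg$start[i] + 1L)
      break
    }
    cum <- cum + (seg$end[i] - seg$start[i] + 1L)
  }
  if (is.na(plus_off)) return(NA_integer_)
  if (gene$strand == "+") plus_off else gene$cds_length - plus_off + 1L
}

# inverse of cds_offset_of
genomic_pos_of <- function(gene, offset) {
  stopifnot(offset >= 1L, offset <= gene$cds_length)
  plus_off <- if (gene$strand == "+") offset else gene$cds_length - offset + 1L
  seg <- gene$segments
  cum <- 0L
  for (i in seq_len(nrow(seg))) {
    w <- seg$end[i] - seg$start[i] + 1L
    if (plus_off <= cum + w) {
      return(seg$start[i] + (plus_off - cum - 1L))
    }
    cum <- cum + w
  }
  stop("offset out of range") # unreachable
}

gene_span <- function(gene) {
  c(min(gene$segments$start), max(gene$segments$end))
}
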