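#' Construct a per-strain variant set
#'
#' The atomic variant record is the normalized 4-tuple
#' (chromosome, pos, ref, alt), 1-based, with anchored (non-empty) alleles.
#' Genotype and zygosity are deliberately ignored: strains are treated as
#' haploid call sets. Duplicate records are dropped with a warning.
#'
#' @param strain Strain name.
#' @param variants Data frame with columns `chrom`, `pos`, `ref`, `alt`.
#' @param genome_id Optional identifier of the reference the calls were made
#'   against; [differential_variants()] refuses to compare sets with
#'   different ids.
#' @return A `StrainVariantSet`.
#' @export
variant_set <- function(strain, variants, genome_id = NULL) {
  variants <- as.data.frame(variants)
  need <- c("chrom", "pos", "ref", "alt")
  if (!all(need %in% names(variants))) {
    stop("variant table must have columns: ", paste(need, collapse = ", "))
  }
  variants <- variants[, need]
  variants$chrom <- as.character(variants$chrom)
  variants$pos <- as.integer(variants$pos)
  variants$ref <- toupper(as.character(variants$ref))
  variants$alt <- toupper(as.character(variants$alt))
  if (nrow(variants) > 0L) {
    if (any(is.na(variants$pos)) || any(variants$pos < 1L)) {
      stop("positions must be 1-based integers >= 1")
    }
    if (any(!nzchar(variants$ref)) || any(!nzchar(variants$alt))) {
      stop("alleles must be non-empty (anchored representation)")
    }
    if (any(variants$ref == variants$alt)) {
      stop("ref == alt for ",
           sum(variants$ref == variants$alt), " record(s)")
    }
    key <- variant_key(variants)
    if (anyDuplicated(key)) {
      warning("dropping ", sum(duplicated(key)), " duplicate variant record(s)")
      variants <- variants[!duplicated(key), , drop = FALSE]
    }
    variants <- variants[order(variants$chrom, variants$pos,
                               variants$ref, variants$alt), , drop = FALSE]
    rownames(variants) <- NULL
  }
  structure(list(strain = strain, variants = variants, genome_id = genome_id),
            class = "StrainVariantSet")
}

#' @export
print.StrainVariantSet <- function(x, ...) {
  cat(sprintf("StrainVariantSet '%s': %d variant(s)\n",
              x$strain, nrow(x$variants)))
  if (nrow(x$variants) > 0L) print(utils::head(x$variants, 6L))
  invisible(x)
}

variant_key <- function(df) {
  paste(df$chrom, df$pos, df$ref, df$alt, sep = ":")
}

check_ref_matches <- function(df, genome, context = "variant") {
  if (nrow(df) == 0L) return(invisible(TRUE))
  obs <- vapply(seq_len(nrow(df)), function(i) {
    n <- chrom_length(genome, df$chrom[i])
    end <- df$pos[i] + nchar(df$ref[i]) - 1L
    if (end > n) return(NA_character_)
    genome_slice(genome, df$chrom[i], df$pos[i], end)
  }, character(1L))
  bad <- is.na(obs) | obs != df$ref
  if (any(bad)) {
    off <- df[bad, , drop = FALSE]
    stop("REF allele disagrees with the reference genome for ",
         sum(bad), " ", context, " record(s): ",
         paste(utils::head(variant_key(off), 5L), collapse = "; "))
  }
  invisible(TRUE)
}

#' Normalize a variant (trim + left-align)
#'
#' Canonical representation: shared suffix then prefix trimmed, and indels
#' shifted to their leftmost equivalent placement against the reference
#' (VCF community convention), keeping alleles anchored (non-empty).
#' Idempotent; the identity on already-normal variants.
#'
#' @param chrom,pos,ref,alt Variant fields (1-based, uppercase alleles).
#' @param genome A `Genome`; the ref allele must match it at `pos`.
#' @return List with normalized `chrom`, `pos`, `ref`, `alt`.
#' @export
normalize_variant <- function(chrom, pos, ref, alt, genome) {
  pos <- as.integer(pos)
  ref <- toupper(ref); alt <- toupper(alt)
  if (ref == alt) stop("ref == alt at ", chrom, ":", pos)
  repeat {
    changed <- FALSE
    nr <- nchar(ref); na <- nchar(alt)
    if (nr > 0L && na > 0L &&
        substr(ref, nr, nr) == substr(alt, na, na) &&
        (nr > 1L || na > 1L)) {
      ref <- substr(ref, 1L, nr - 1L)
      alt <- substr(alt, 1L, na - 1L)
      changed <- TRUE
    }
    if (nchar(ref) == 0L || nchar(alt) == 0L) {
      if (pos <= 1L) {
        stop("cannot left-align variant at start of ", chrom)
      }
      pos <- pos - 1L
      b <- genome_slice(genome, chrom, pos, pos)
      ref <- paste0(b, ref)
      alt <- paste0(b, alt)
      changed <- TRUE
    }
    if (!changed) break
  }
  while (nchar(ref) >= 2L && nchar(alt) >= 2L &&
         substr(ref, 1L, 1L) == substr(alt, 1L, 1L)) {
    ref <- substr(ref, 2L, nchar(ref))
    alt <- substr(alt, 2L, nchar(alt))
    pos <- pos + 1L
  }
  list(chrom = chrom, pos = pos, ref = ref, alt = alt)
}

normalize_variant_table <- function(df, genome) {
  if (nrow(df) == 0L) return(df)
  check_ref_matches(df, genome)
  out <- df
  for (i in seq_len(nrow(df))) {
    v <- normalize_variant(df$chrom[i], df$pos[i], df$ref[i], df$alt[i], genome)
    out$pos[i] <- v$pos; out$ref[i] <- v$ref; out$alt[i] <- v$alt
  }
  out
}

#' Read a strain variant set from VCF
#'
#' Multi-allelic records are split into one variant per alternate allele;
#' records failing filters (FILTER not PASS/missing) are excluded by default.
#' Symbolic alleles (e.g. `<DEL>`, breakends, `*`) are skipped with a
#' warning. All variants are checked against the reference genome and
#' normalized (see [normalize_variant()]).
#'
#' @param path Path to a VCF 4.x file (sites-only or single-sample).
#' @param genome A `Genome`.
#' @param strain Strain name; defaults to the file name.
#' @param keep_filtered Keep non-PASS records too.
#' @param genome_id Optional reference identifier stored on the set.
#' @return A `StrainVariantSet`.
#' @export
read_vcf <- function(path, genome, strain = NULL, keep_filtered = FALSE,
                     genome_id = NULL) {
  if (!file.exists(path)) stop("VCF file not found: ", path)
  if (is.null(strain)) strain <- sub("\\.vcf(\\.gz)?$", "", basename(path))
  vcf <- VariantAnnotation::readVcf(path, genome = "genome")
  vcf <- VariantAnnotation::expand(vcf)
  if (length(vcf) == 0L) {
    return(variant_set(strain, data.frame(chrom = character(0), pos = integer(0),
                                          ref = character(0), alt = character(0)),
                       genome_id = genome_id))
  }
  rr <- SummarizedExperiment::rowRanges(vcf)
  df <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(rr)),
    pos = GenomicRanges::start(rr),
    ref = as.character(VariantAnnotation::ref(vcf)),
    alt = as.character(VariantAnnotation::alt(vcf)),
    filter = VariantAnnotation::filt(vcf),
    stringsAsFactors = FALSE
  )
  sym <- grepl("[<>\\[\\]]", df$alt) | df$alt == "*" | !nzchar(df$alt)
  if (any(sym)) {
    warning("skipping ", sum(sym), " symbolic/structural allele record(s)")
    df <- df[!sym, , drop = FALSE]
  }
  if (!keep_filtered) {
    keep <- df$filter %in% c("PASS", ".") | is.na(df$filter)
    df <- df[keep, , drop = FALSE]
  }
  df$filter <- NULL
  df <- normalize_variant_table(df, genome)
  variant_set(strain, df, genome_id = genome_id)
}

#' Read a strain variant set from a delimited table
#'
#' Reader for flat supplementary-style variant lists. The column layout is
#' config-driven because such tables have no fixed dialect.
#'
#' @param path Path to a delimited text file with a header row.
#' @param genome A `Genome`.
#' @param strain Strain name; defaults to the file name.
#' @param columns Named list mapping the required fields `chrom`, `pos`,
#'   `ref`, `alt` to column names in the file.
#' @param sep Field separator.
#' @param genome_id Optional reference identifier stored on the set.
#' @return A `StrainVariantSet` (same contract as [read_vcf()]).
#' @export
read_variant_table <- function(path, genome, strain = NULL,
                               columns = list(chrom = "chrom", pos = "pos",
                                              ref = "ref", alt = "alt"),
                               sep = "\t", genome_id = NULL) {
  if (!file.exists(path)) stop("variant table not found: ", path)
  if (is.null(strain)) strain <- sub("\\.[^.]*$", "", basename(path))
  # colClasses: allele columns like "T" must not auto-convert to logical
  tab <- utils::read.delim(path, sep = sep, stringsAsFactors = FALSE,
                           check.names = FALSE, colClasses = "character")
  need <- c("chrom", "pos", "ref", "alt")
  missing_map <- setdiff(need, names(columns))
  if (length(missing_map) > 0L) {
    stop("column mapping incomplete; missing: ",
         paste(missing_map, collapse = ", "))
  }
  absent <- setdiff(unlist(columns[need]), names(tab))
  if (length(absent) > 0L) {
    stop("columns not found in ", basename(path), ": ",
         paste(absent, collapse = ", "))
  }
  df <- data.frame(chrom = as.character(tab[[columns$chrom]]),
                   pos = as.integer(tab[[columns$pos]]),
                   ref = toupper(as.character(tab[[columns$ref]])),
                   alt = toupper(as.character(tab[[columns$alt]])),
                   stringsAsFactors = FALSE)
  if (nrow(df) > 0L && any(df$pos < 1L, na.rm = TRUE)) {
    stop("positions must be 1-based (found pos < 1)")
  }
  df <- normalize_variant_table(df, genome)
  variant_set(strain, df, genome_id = genome_id)
}

#' Variants private to the mutant strain
#'
#' Exact set difference mutant \\ parent on normalized
#' (chrom, pos, ref, alt) keys: the variants that distinguish the mutant
#' from its parent. Both sets must derive from the same reference.
#'
#' @param mutant,parent `StrainVariantSet` objects, normalized against the
#'   same genome.
#' @return A `StrainVariantSet` of mutant-private variants.
#' @export
differential_variants <- function(mutant, parent) {
  stopifnot(inherits(mutant, "StrainVariantSet"),
            inherits(parent, "StrainVariantSet"))
  if (!is.null(mutant$genome_id) && !is.null(parent$genome_id) &&
      !identical(mutant$genome_id, parent$genome_id)) {
    stop("variant sets were called against different references: '",
         mutant$genome_id, "' vs '", parent$genome_id, "'")
  }
  keep <- !(variant_key(mutant$variants) %in% variant_key(parent$variants))
  variant_set(mutant$strain, mutant$variants[keep, , drop = FALSE],
              genome_id = mutant$genome_id)
}

#' Write a variant set as a sites-only VCF
#'
#' @param vset A `StrainVariantSet`.
#' @param genome The `Genome` the set is normalized against (for contig
#'   headers).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(vset, genome, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    sprintf("##source=conseqr %s", as.character(utils::packageVersion("conseqr"))),
    sprintf("##contig=<ID=%s,length=%d>", names(genome),
            nchar(unclass(genome))),
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO"
  ), con)
  df <- vset$variants
  if (nrow(df) > 0L) {
    writeLines(sprintf("%s\t%d\t.\t%s\t%s\t.\tPASS\t.",
                       df$chrom, df$pos, df$ref, df$alt), con)
  }
  invisible(path)
}
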