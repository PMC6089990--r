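# Independent brute-force oracle for consequence calls: rebuilds the whole
# transcript as a base vector, applies the variant to it, re-translates both
# proteins and derives category + notation from the diff. Deliberately
# shares no code with the package's incremental classifier.

helper_revcomp <- function(s) {
  paste(rev(strsplit(chartr("ACGTN", "TGCAN", s), "")[[1L]]), collapse = "")
}

.oracle_blosum <- local({
  e <- new.env()
  suppressWarnings(utils::data("BLOSUM62", package = "Biostrings", envir = e))
  get("BLOSUM62", envir = e)
})

# transcript as (genomic position, transcript base) vectors
oracle_transcript <- function(genome, gene) {
  gpos <- unlist(lapply(seq_len(nrow(gene$segments)), function(i) {
    seq(gene$segments$start[i], gene$segments$end[i])
  }))
  chromseq <- unclass(genome)[[gene$chromosome]]
  bases <- substring(chromseq, gpos, gpos)
  if (gene$strand == "-") {
    gpos <- rev(gpos)
    bases <- rev(chartr("ACGTN", "TGCAN", bases))
  }
  list(gpos = gpos, bases = bases)
}

oracle_translate <- function(bases) {
  codons <- apply(matrix(bases, nrow = 3L), 2L, paste, collapse = "")
  aa <- unname(Biostrings::GENETIC_CODE[codons])
  aa[is.na(aa)] <- "X"
  aa
}

# returns list(category, notation) for the consequence of (pos, ref, alt)
# in `gene`, or NULL when the variant does not touch the gene's CDS
oracle_classify <- function(genome, gene, pos, ref, alt, thr = 0L) {
  tr <- oracle_transcript(genome, gene)
  nr <- nchar(ref); na <- nchar(alt)
  if (nr == 1L && na == 1L) {
    idx <- which(tr$gpos == pos)
    if (length(idx) == 0L) return(NULL)
    mut <- tr$bases
    mut[idx] <- if (gene$strand == "-") chartr("ACGT", "TGCA", alt) else alt
    ref_aa_all <- oracle_translate(tr$bases)
    alt_aa_all <- oracle_translate(mut)
    ci <- (idx - 1L) %/% 3L + 1L
    ra <- ref_aa_all[ci]; aa <- alt_aa_all[ci]
    category <- if (ra == aa) {
      "synonymous"
    } else if (ci == 1L && paste(tr$bases[1:3], collapse = "") == "ATG") {
      "start_loss"
    } else if (ra == "*") {
      "sense"
    } else if (aa == "*") {
      "nonsense"
    } else if (.oracle_blosum[ra, aa] >= thr) {
      "missense_conservative"
    } else {
      "missense_nonconservative"
    }
    return(list(category = category, notation = paste0(ra, ci, aa)))
  }
  if (nr == 1L && na > 1L && substr(alt, 1L, 1L) == ref) {
    # insertion between pos and pos+1
    i1 <- which(tr$gpos == pos); i2 <- which(tr$gpos == pos + 1L)
    if (length(i1) == 0L && length(i2) == 0L) return(NULL)
    if (length(i1) == 0L || length(i2) == 0L) {
      return(list(category = "complex", notation = NA_character_))
    }
    s_gen <- substr(alt, 2L, na)
    s_t <- if (gene$strand == "-") helper_revcomp(s_gen) else s_gen
    mut_len <- length(tr$bases) + nchar(s_t)
    category <- if (mut_len %% 3L == length(tr$bases) %% 3L)
      "inframe_indel" else "frameshift"
    p <- min(i1, i2)
    return(list(category = category,
                notation = sprintf("+%s %d/%d", s_t, p, p + 1L)))
  }
  if (na == 1L && nr > 1L && substr(ref, 1L, 1L) == alt) {
    drange <- (pos + 1L):(pos + nr - 1L)
    idx <- which(tr$gpos %in% drange)
    if (length(idx) == 0L) return(NULL)
    if (length(idx) < length(drange)) {
      return(list(category = "complex", notation = NA_character_))
    }
    mut_len <- length(tr$bases) - length(idx)
    category <- if (mut_len %% 3L == length(tr$bases) %% 3L)
      "inframe_indel" else "frameshift"
    p <- min(idx)
    s_t <- paste(tr$bases[sort(idx)], collapse = "")
    return(list(category = category, notation = sprintf("-%s %d", s_t, p)))
  }
  list(category = "complex", notation = NA_character_)
}

# compare every CDS-classified row of annotate_variants() output against
# the oracle; returns number of disagreements (0 expected)
oracle_disagreements <- function(ann, genome, genes, thr = 0L) {
  cl <- ann[ann$region == "CDS" & !is.na(ann$category), , drop = FALSE]
  bad <- 0L
  for (i in seq_len(nrow(cl))) {
    o <- oracle_classify(genome, genes[[cl$gene_id[i]]],
                         cl$pos[i], cl$ref[i], cl$alt[i], thr)
    if (is.null(o) || o$category != cl$category[i] ||
        (!is.na(o$notation) && o$notation != cl$notation[i])) {
      bad <- bad + 1L
    }
  }
  bad
}

# single-gene toy fixture: genome with one gene built from a given CDS
make_gene_fixture <- function(cds, strand = "+", chrom = "chrI",
                              left = 20L, right = 20L) {
  pad_l <- strrep("TG", ceiling(left / 2))
  pad_r <- strrep("CA", ceiling(right / 2))
  gseq <- if (strand == "-") helper_revcomp(cds) else cds
  genome <- Genome(stats::setNames(paste0(pad_l, gseq, pad_r), chrom))
  gene <- GeneModel("g1", chrom, strand,
                    data.frame(start = nchar(pad_l) + 1L,
                               end = nchar(pad_l) + nchar(gseq)))
  list(genome = genome, gene = gene, genes = list(g1 = gene),
       offset0 = nchar(pad_l))
}
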