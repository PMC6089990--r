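# Deterministic worked example: a parent/mutant strain pair whose private
# variants reproduce the full range of CDS-inactivating lesion notations on
# yeast-style gene models.

.demo_gene_specs <- function() {
  # one entry per gene: chromosome, codon count (stop included), strand,
  # codons to pin, and the lesions to plant (in CDS coordinates)
  list(
    list(symbol = "CYC8", chrom = "chrII", codons = 967, strand = "+",
         pin = list(`404` = "CAA"),
         lesions = list(list(type = "ins", p = 1211, seq = "TTG"))),
    list(symbol = "TBS1", chrom = "chrII", codons = 1095, strand = "-",
         pin = list(`1078` = "AGT"),
         lesions = list(list(type = "del", p = 3233, len = 1))),
    list(symbol = "HTA1", chrom = "chrIV", codons = 133, strand = "+",
         pin = list(`39` = "CAT"),
         lesions = list(list(type = "ins", p = 117, seq = "G"))),
    list(symbol = "SEM1", chrom = "chrIV", codons = 90, strand = "-",
         pin = list(`21` = "TGT"),
         lesions = list(list(type = "ins", p = 61, seq = "A"))),
    list(symbol = "CDC40", chrom = "chrIV", codons = 456, strand = "+",
         pin = list(`94` = "GAA"),
         lesions = list(list(type = "sub", ci = 94, within = 1, alt = "T"))),
    list(symbol = "YHR214C-B", chrom = "chrVIII", codons = 1794, strand = "+",
         pin = list(`1782` = "GAA"),
         lesions = list(list(type = "sub", ci = 1782, within = 1, alt = "T"))),
    list(symbol = "FRE8", chrom = "chrXII", codons = 687, strand = "-",
         pin = list(`15` = "TGC"),
         lesions = list(list(type = "sub", ci = 15, within = 3, alt = "A"))),
    list(symbol = "SIR3", chrom = "chrXII", codons = 979, strand = "+",
         pin = list(`673` = "GGA", `674` = "CAT"),
         lesions = list(list(type = "del", p = 2020, len = 1))),
    list(symbol = "PGM2", chrom = "chrXIII", codons = 570, strand = "+",
         pin = list(`405` = "TGG"),
         lesions = list(list(type = "sub", ci = 405, within = 3, alt = "A"))),
    list(symbol = "INP1", chrom = "chrXIII", codons = 421, strand = "+",
         pin = list(`362` = "GAC"),
         lesions = list(list(type = "ins", p = 1085, seq = "T"))),
    list(symbol = "MRPL44", chrom = "chrXIII", codons = 148, strand = "-",
         pin = list(`5` = "CAA"),
         lesions = list(list(type = "sub", ci = 5, within = 1, alt = "T"))),
    list(symbol = "NAM9", chrom = "chrXIV", codons = 487, strand = "+",
         pin = list(`396` = "TGG"),
         lesions = list(list(type = "sub", ci = 396, within = 3, alt = "A"))),
    list(symbol = "INP53", chrom = "chrXV", codons = 1108, strand = "+",
         pin = list(`356` = "AAA"),
         lesions = list(list(type = "sub", ci = 356, within = 1, alt = "T"))),
    list(symbol = "GEP3", chrom = "chrXV", codons = 557, strand = "-",
         pin = list(`373` = "GTT", `376` = "AAA"),
         lesions = list(list(type = "sub", ci = 373, within = 2, alt = "G"),
                        list(type = "sub", ci = 376, within = 1, alt = "T"))),
    list(symbol = "RPL33A", chrom = "chrXVI", codons = 283, strand = "+",
         pin = list(`25` = "TGG"),
         lesions = list(list(type = "sub", ci = 25, within = 3, alt = "A")))
  )
}

#' Deterministic demonstration strain pair
#'
#' Builds a toy multi-chromosome genome carrying 15 yeast-style genes (both
#' strands, realistic CDS lengths in codons including the stop codon), a
#' parent strain with a few background variants, and a mutant strain that
#' additionally carries one CDS-inactivating-scale lesion per gene: nine
#' stop-gains (e.g. `Q5*` in MRPL44-like, `E94*` in CDC40-like genes), five
#' single-base indels (frameshifts such as `-G 3233`), one in-frame 3-nt
#' insertion (`+TTG 1211/1212`), and one additional missense (`V373G`) in
#' the gene that also carries `K376*`. Everything is constructed
#' deterministically; the same objects are returned on every call.
#'
#' @return List with `genome`, `genes`, `parent`, `mutant`
#'   (`StrainVariantSet`s) and `truth` (the planted lesions with their
#'   expected notations).
#' @export
demo_strain_pair <- function() {
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                   envir = globalenv())
  })
  set.seed(20180813L %% 100000L)
  specs <- .demo_gene_specs()
  chroms <- unique(vapply(specs, `[[`, character(1L), "chrom"))
  seqs <- stats::setNames(rep("", length(chroms)), chroms)
  genes <- list()
  cds_store <- list()
  for (sp in specs) {
    cds <- random_cds(sp$codons)
    for (ci_chr in names(sp$pin)) {
      ci <- as.integer(ci_chr)
      substr(cds, 3L * ci - 2L, 3L * ci) <- sp$pin[[ci_chr]]
    }
    gseq <- if (sp$strand == "-") revcomp(cds) else cds
    gap <- random_dna(sample(100:200, 1L))
    start <- nchar(seqs[[sp$chrom]]) + nchar(gap) + 1L
    seqs[[sp$chrom]] <- paste0(seqs[[sp$chrom]], gap, gseq)
    gid <- sp$symbol
    genes[[gid]] <- GeneModel(gid, sp$chrom, sp$strand,
                              data.frame(start = start,
                                         end = start + nchar(gseq) - 1L),
                              symbol = sp$symbol,
                              description = paste0(sp$symbol, "-like gene"))
    cds_store[[gid]] <- cds
  }
  for (ch in chroms) {
    seqs[[ch]] <- paste0(seqs[[ch]], random_dna(sample(100:200, 1L)))
  }
  genome <- Genome(seqs)

  truth <- list()
  for (sp in specs) {
    g <- genes[[sp$symbol]]
    cds <- cds_store[[sp$symbol]]
    for (le in sp$lesions) {
      if (le$type == "sub") {
        offset <- 3L * (le$ci - 1L) + le$within
        pos <- genomic_pos_of(g, offset)
        rb <- substr(cds, offset, offset)
        ref <- if (g$strand == "-") comp_base(rb) else rb
        alt <- if (g$strand == "-") comp_base(le$alt) else le$alt
        ref_codon <- substr(cds, 3L * le$ci - 2L, 3L * le$ci)
        alt_codon <- ref_codon
        substr(alt_codon, le$within, le$within) <- le$alt
        notation <- paste0(translate_codon(ref_codon), le$ci,
                           translate_codon(alt_codon))
      } else if (le$type == "ins") {
        p <- le$p
        if (g$strand == "+") {
          pos <- genomic_pos_of(g, p)
          ins <- le$seq
        } else {
          pos <- genomic_pos_of(g, p) - 1L
          ins <- revcomp(le$seq)
        }
        ref <- genome_slice(genome, g$chromosome, pos, pos)
        alt <- paste0(ref, ins)
        notation <- sprintf("+%s %d/%d", le$seq, p, p + 1L)
      } else {
        p <- le$p
        dseq <- substr(cds, p, p + le$len - 1L)
        if (g$strand == "+") {
          gs <- genomic_pos_of(g, p)
          ge <- genomic_pos_of(g, p + le$len - 1L)
        } else {
          gs <- genomic_pos_of(g, p + le$len - 1L)
          ge <- genomic_pos_of(g, p)
        }
        pos <- gs - 1L
        b <- genome_slice(genome, g$chromosome, pos, pos)
        ref <- paste0(b, genome_slice(genome, g$chromosome, gs, ge))
        alt <- b
        notation <- sprintf("-%s %d", dseq, p)
      }
      v <- normalize_variant(g$chromosome, pos, ref, alt, genome)
      if (v$pos != pos || v$ref != ref || v$alt != alt) {
        stop("demo lesion in ", sp$symbol, " is not left-normal as planted")
      }
      truth[[length(truth) + 1L]] <- data.frame(
        chrom = g$chromosome, pos = pos, ref = ref, alt = alt,
        gene_id = sp$symbol, notation = notation)
    }
  }
  truth <- do.call(rbind, truth)

  # shared background: a handful of intergenic SNVs present in both strains
  env <- .block_env()
  for (i in seq_len(nrow(truth))) {
    .block(env, truth$chrom[i],
           truth$pos[i]:(truth$pos[i] + nchar(truth$ref[i]) - 1L))
  }
  spectrum <- mutation_spectrum()
  bg <- list()
  for (i in seq_len(8L)) {
    row <- .plant_intergenic(genome, genes, spectrum, env)
    if (!is.null(row)) bg[[length(bg) + 1L]] <-
        row[, c("chrom", "pos", "ref", "alt")]
  }
  bg <- do.call(rbind, bg)

  parent <- variant_set("parent", bg, genome_id = "demo")
  mutant <- variant_set("mutant",
                        rbind(bg, truth[, c("chrom", "pos", "ref", "alt")]),
                        genome_id = "demo")
  list(genome = genome, genes = genes, parent = parent, mutant = mutant,
       truth = truth)
}
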