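SENSE_CODONS <- setdiff(names(Biostrings::GENETIC_CODE), c("TAA", "TAG", "TGA"))

#' NTG-like mutation spectrum
#'
#' Substitution probabilities per reference base plus indel parameters.
#' The default puts 0.8 of the substitution mass of G and C on the
#' G:C -> A:T transition, the classic alkylation signature of
#' nitrosoguanidine mutagenesis; A:T sites get a milder generic transition
#' bias.
#'
#' @param gc_to_at Probability mass on G->A and C->T at G/C sites.
#' @param transition Probability mass on the transition at A/T sites.
#' @param indel_rate Fraction of events that are indels rather than
#'   substitutions.
#' @param indel_length_probs Probabilities of indel lengths 1, 2, 3, ...
#' @return A `MutationSpectrum` object; `substitution` rows sum to 1 over
#'   the three non-reference bases.
#' @export
mutation_spectrum <- function(gc_to_at = 0.8, transition = 0.5,
                              indel_rate = 0.1,
                              indel_length_probs = c(0.6, 0.2, 0.2)) {
  stopifnot(gc_to_at >= 0, gc_to_at <= 1, transition >= 0, transition <= 1,
            indel_rate >= 0, indel_rate <= 1, all(indel_length_probs >= 0))
  bases <- c("A", "C", "G", "T")
  m <- matrix(0, 4, 4, dimnames = list(bases, bases))
  fill <- function(ref, ts_alt, mass) {
    others <- setdiff(bases, c(ref, ts_alt))
    m[ref, ts_alt] <<- mass
    m[ref, others] <<- (1 - mass) / 2
  }
  fill("G", "A", gc_to_at)
  fill("C", "T", gc_to_at)
  fill("A", "G", transition)
  fill("T", "C", transition)
  structure(list(substitution = m, indel_rate = indel_rate,
                 indel_length_probs = indel_length_probs / sum(indel_length_probs),
                 gc_to_at = gc_to_at, transition = transition),
            class = "MutationSpectrum")
}

#' Simulation configuration for toy genomes
#'
#' @param n_chromosomes Number of chromosomes.
#' @param n_genes Total genes, distributed round-robin over chromosomes.
#' @param gene_length_codons Range (min, max) of gene lengths in codons,
#'   stop codon included.
#' @param strand_prob Probability that a gene lies on the plus strand.
#' @param intergenic Range (min, max) of intergenic gap lengths in nt.
#' @param chromosome_length Optional fixed chromosome length; an error is
#'   raised when the genes and gaps of a chromosome do not fit.
#' @param seed Mandatory seed.
#' @return A `SimulationConfig` list.
#' @export
simulation_config <- function(n_chromosomes = 2L, n_genes = 20L,
                              gene_length_codons = c(60L, 200L),
                              strand_prob = 0.5,
                              intergenic = c(80L, 200L),
                              chromosome_length = NULL, seed) {
  if (missing(seed)) stop("seed is mandatory")
  stopifnot(n_chromosomes >= 1L, n_genes >= 0L,
            gene_length_codons[1L] >= 3L, strand_prob >= 0, strand_prob <= 1)
  structure(list(n_chromosomes = as.integer(n_chromosomes),
                 n_genes = as.integer(n_genes),
                 gene_length_codons = as.integer(gene_length_codons),
                 strand_prob = strand_prob,
                 intergenic = as.integer(intergenic),
                 chromosome_length = chromosome_length,
                 seed = as.integer(seed)),
            class = "SimulationConfig")
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

random_cds <- function(n_codons) {
  body <- sample(SENSE_CODONS, n_codons - 2L, replace = TRUE)
  paste(c("ATG", body, sample(STOP_CODONS, 1L)), collapse = "")
}

#' Simulate a toy genome with stranded genes
#'
#' Builds each chromosome as alternating random intergenic spacers and
#' complete single-exon genes (ATG start, stop end, length divisible by 3),
#' on either strand. Optionally writes FASTA and GFF3 files that round-trip
#' through [read_fasta()]/[read_gff3()].
#'
#' @param cfg A [simulation_config()].
#' @param out_dir Optional directory for `genome.fa` / `genes.gff3`.
#' @return List with `genome` (a `Genome`), `genes` (named `GeneModel`
#'   list), and `files` (paths, when written).
#' @export
simulate_genome <- function(cfg, out_dir = NULL) {
  stopifnot(inherits(cfg, "SimulationConfig"))
  set.seed(cfg$seed)
  per_chrom <- split(seq_len(cfg$n_genes),
                     rep(seq_len(cfg$n_chromosomes), length.out = cfg$n_genes))
  seqs <- character(cfg$n_chromosomes)
  names(seqs) <- paste0("chr", as.character(utils::as.roman(seq_len(cfg$n_chromosomes))))
  genes <- list()
  for (ci in seq_len(cfg$n_chromosomes)) {
    chrom <- names(seqs)[ci]
    pieces <- character(0)
    cursor <- 0L
    idxs <- if (ci <= length(per_chrom)) per_chrom[[ci]] else integer(0)
    for (gi in idxs) {
      gap <- sample(cfg$intergenic[1L]:cfg$intergenic[2L], 1L)
      pieces <- c(pieces, random_dna(gap))
      cursor <- cursor + gap
      n_codons <- sample(cfg$gene_length_codons[1L]:cfg$gene_length_codons[2L], 1L)
      cds <- random_cds(n_codons)
      strand <- if (stats::runif(1L) < cfg$strand_prob) "+" else "-"
      gseq <- if (strand == "-") revcomp(cds) else cds
      start <- cursor + 1L
      end <- cursor + nchar(gseq)
      gene_id <- sprintf("gene%03d", gi)
      genes[[gene_id]] <- GeneModel(gene_id, chrom, strand,
                                    data.frame(start = start, end = end),
                                    symbol = toupper(gene_id))
      pieces <- c(pieces, gseq)
      cursor <- end
    }
    tail_gap <- sample(cfg$intergenic[1L]:cfg$intergenic[2L], 1L)
    pieces <- c(pieces, random_dna(tail_gap))
    cursor <- cursor + tail_gap
    if (!is.null(cfg$chromosome_length)) {
      if (cursor > cfg$chromosome_length) {
        stop("infeasible packing: chromosome ", chrom, " needs ", cursor,
             " nt but chromosome_length is ", cfg$chromosome_length)
      }
      pieces <- c(pieces, random_dna(cfg$chromosome_length - cursor))
    }
    seqs[chrom] <- paste(pieces, collapse = "")
  }
  genome <- Genome(seqs)
  files <- NULL
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    fa <- file.path(out_dir, "genome.fa")
    gff <- file.path(out_dir, "genes.gff3")
    write_fasta(genome, fa)
    write_gff3(genes, gff)
    files <- list(fasta = fa, gff3 = gff)
  }
  list(genome = genome, genes = genes, files = files)
}

# --- planting helpers ---------------------------------------------------

.block_env <- function() {
  e <- new.env()
  e$blocked <- list()
  e
}

.is_blocked <- function(env, chrom, positions, pad = 3L) {
  span <- seq.int(min(positions) - pad, max(positions) + pad)
  any(span %in% env$blocked[[chrom]])
}

.block <- function(env, chrom, positions, pad = 3L) {
  span <- seq.int(min(positions) - pad, max(positions) + pad)
  env$blocked[[chrom]] <- c(env$blocked[[chrom]], span)
}

# enumerate single-base changes of the codon at ci matching a target
# category; returns list(within, ref_base, alt_base, ref_aa, alt_aa) or NULL
.codon_change_for <- function(cds_nt, ci, target, matrix) {
  codon <- substr(cds_nt, 3L * ci - 2L, 3L * ci)
  ref_aa <- translate_codon(codon)
  for (within in sample.int(3L)) {
    rb <- substr(codon, within, within)
    for (ab in sample(setdiff(c("A", "C", "G", "T"), rb))) {
      alt_codon <- codon
      substr(alt_codon, within, within) <- ab
      alt_aa <- translate_codon(alt_codon)
      ok <- switch(target,
        synonymous = alt_aa == ref_aa,
        nonsense = ref_aa != "*" && alt_aa == "*",
        sense = ref_aa == "*" && alt_aa != "*",
        start_loss = ci == 1L && codon == "ATG" && alt_aa != ref_aa,
        missense_conservative = ref_aa != "*" && alt_aa != "*" &&
          alt_aa != ref_aa && !(ci == 1L && codon == "ATG") &&
          substitution_score(matrix, ref_aa, alt_aa) >= matrix$threshold,
        missense_nonconservative = ref_aa != "*" && alt_aa != "*" &&
          alt_aa != ref_aa && !(ci == 1L && codon == "ATG") &&
          substitution_score(matrix, ref_aa, alt_aa) < matrix$threshold,
        FALSE)
      if (isTRUE(ok)) {
        return(list(within = within, ref_base = rb, alt_base = ab,
                    ref_aa = ref_aa, alt_aa = alt_aa))
      }
    }
  }
  NULL
}

# plant one substitution of the target category in gene g; NULL on failure
.plant_substitution <- function(g, cds, target, matrix, genome, env) {
  L <- cds$length_codons
  cand_ci <- switch(target,
    sense = L,
    start_loss = 1L,
    sample(2:(L - 1L), min(30L, L - 2L)))
  for (ci in cand_ci) {
    ch <- .codon_change_for(cds$nucleotides, ci, target, matrix)
    if (is.null(ch)) next
    offset <- 3L * (ci - 1L) + ch$within
    pos <- genomic_pos_of(g, offset)
    if (.is_blocked(env, g$chromosome, pos)) next
    ref <- if (g$strand == "-") comp_base(ch$ref_base) else ch$ref_base
    alt <- if (g$strand == "-") comp_base(ch$alt_base) else ch$alt_base
    stopifnot(genome_slice(genome, g$chromosome, pos, pos) == ref)
    .block(env, g$chromosome, pos)
    return(data.frame(chrom = g$chromosome, pos = pos, ref = ref, alt = alt,
                      gene_id = g$gene_id, category = target,
                      notation = paste0(ch$ref_aa, ci, ch$alt_aa)))
  }
  NULL
}

# plant an indel (frameshift or inframe_indel) fully inside the CDS body
.plant_indel <- function(g, cds, target, genome, env, tries = 40L) {
  nt <- cds$nucleotides
  n <- nchar(nt)
  len <- if (target == "inframe_indel") 3L else sample(1:2, 1L)
  for (t in seq_len(tries)) {
    insertion <- stats::runif(1L) < 0.5
    if (insertion) {
      p <- sample(4:(n - 4L), 1L)  # insert between CDS offsets p and p+1
      seq_t <- random_dna(len)
      # two-sided placement stability: the inserted run must not be
      # shiftable toward either flank, so its normalized placement is the
      # same on both strands
      if (substr(seq_t, len, len) == substr(nt, p, p)) next
      if (substr(seq_t, 1L, 1L) == substr(nt, p + 1L, p + 1L)) next
      if (g$strand == "+") {
        anchor <- genomic_pos_of(g, p)
        alt_seq <- seq_t
      } else {
        anchor <- genomic_pos_of(g, p) - 1L
        alt_seq <- revcomp(seq_t)
      }
      b <- genome_slice(genome, g$chromosome, anchor, anchor)
      row <- data.frame(chrom = g$chromosome, pos = anchor, ref = b,
                        alt = paste0(b, alt_seq), gene_id = g$gene_id,
                        category = target,
                        notation = sprintf("+%s %d/%d", seq_t, p, p + 1L))
      foot <- c(anchor, anchor + 1L)
    } else {
      p <- sample(4:(n - 3L - len), 1L)  # delete CDS offsets p..p+len-1
      # two-sided stability: the deleted run must not shift either way
      if (substr(nt, p, p) == substr(nt, p + len, p + len)) next
      if (substr(nt, p - 1L, p - 1L) == substr(nt, p + len - 1L, p + len - 1L)) next
      seq_t <- substr(nt, p, p + len - 1L)
      if (g$strand == "+") {
        gs <- genomic_pos_of(g, p)
        ge <- genomic_pos_of(g, p + len - 1L)
      } else {
        gs <- genomic_pos_of(g, p + len - 1L)
        ge <- genomic_pos_of(g, p)
      }
      anchor <- gs - 1L
      d <- genome_slice(genome, g$chromosome, gs, ge)
      b <- genome_slice(genome, g$chromosome, anchor, anchor)
      row <- data.frame(chrom = g$chromosome, pos = anchor,
                        ref = paste0(b, d), alt = b, gene_id = g$gene_id,
                        category = target,
                        notation = sprintf("-%s %d", seq_t, p))
      foot <- anchor:ge
    }
    if (.is_blocked(env, g$chromosome, foot)) next
    v <- normalize_variant(row$chrom, row$pos, row$ref, row$alt, genome)
    if (v$pos != row$pos || v$ref != row$ref || v$alt != row$alt) next
    .block(env, g$chromosome, foot)
    return(row)
  }
  NULL
}

.plant_intergenic <- function(genome, genes, spectrum, env, tries = 60L) {
  chroms <- names(genome)
  spans <- lapply(genes, gene_span)
  for (t in seq_len(tries)) {
    chrom <- sample(chroms, 1L)
    pos <- sample.int(chrom_length(genome, chrom), 1L)
    in_gene <- any(vapply(genes, function(g)
      g$chromosome == chrom && pos >= gene_span(g)[1L] &&
        pos <= gene_span(g)[2L], logical(1L)))
    if (in_gene || .is_blocked(env, chrom, pos)) next
    ref <- genome_slice(genome, chrom, pos, pos)
    if (ref == "N") next
    alt <- sample(colnames(spectrum$substitution), 1L,
                  prob = spectrum$substitution[ref, ])
    .block(env, chrom, pos)
    return(data.frame(chrom = chrom, pos = pos, ref = ref, alt = alt,
                      gene_id = NA_character_, category = "intergenic",
                      notation = NA_character_))
  }
  NULL
}

.draw_background <- function(genome, spectrum, env, tries = 60L) {
  chroms <- names(genome)
  for (t in seq_len(tries)) {
    chrom <- sample(chroms, 1L)
    n <- chrom_length(genome, chrom)
    pos <- sample.int(n - 5L, 1L) + 2L
    ref1 <- genome_slice(genome, chrom, pos, pos)
    if (ref1 == "N") next
    if (stats::runif(1L) < spectrum$indel_rate) {
      len <- sample(seq_along(spectrum$indel_length_probs), 1L,
                    prob = spectrum$indel_length_probs)
      if (stats::runif(1L) < 0.5) {
        row <- list(chrom = chrom, pos = pos, ref = ref1,
                    alt = paste0(ref1, random_dna(len)))
        foot <- c(pos, pos + 1L)
      } else {
        if (pos + len > n) next
        row <- list(chrom = chrom, pos = pos,
                    ref = paste0(ref1, genome_slice(genome, chrom, pos + 1L,
                                                    pos + len)),
                    alt = ref1)
        foot <- pos:(pos + len)
      }
    } else {
      alt <- sample(colnames(spectrum$substitution), 1L,
                    prob = spectrum$substitution[ref1, ])
      row <- list(chrom = chrom, pos = pos, ref = ref1, alt = alt)
      foot <- pos
    }
    v <- normalize_variant(row$chrom, row$pos, row$ref, row$alt, genome)
    foot <- min(v$pos, foot):max(foot, v$pos + nchar(v$ref) - 1L)
    if (.is_blocked(env, chrom, foot)) next
    .block(env, chrom, foot)
    return(data.frame(chrom = v$chrom, pos = v$pos, ref = v$ref, alt = v$alt))
  }
  NULL
}

#' Simulate NTG-like mutagenesis of a strain pair
#'
#' Emulates the structure of a mutate-and-screen experiment: parent and
#' mutant share a set of background variants (both called against the same
#' reference), and the mutant additionally carries private variants planted
#' with known consequence labels. With `category_coverage = TRUE` the
#' private set contains at least one synonymous, missense (conservative and
#' non-conservative), nonsense, sense (stop-loss), frameshift and in-frame
#' indel event. Planted variants avoid the start codon unless
#' `include_start_loss` is set, keep clear of each other (colliding draws
#' are re-drawn), and are emitted in normalized form, so
#' [differential_variants()] recovers exactly the private truth set.
#'
#' @param genome,genes Output of [simulate_genome()].
#' @param spectrum A [mutation_spectrum()].
#' @param n_background Shared background variants.
#' @param n_private Mutant-private variants (includes the coverage set).
#' @param seed Mandatory seed.
#' @param category_coverage Guarantee at least one of each category.
#' @param include_start_loss Also plant a start-loss event.
#' @param category_weights Named sampling weights for the private categories
#'   beyond the coverage set; the default mirrors an alkylating-mutagen
#'   coding spectrum (missense-dominated, few truncating events, some
#'   intergenic hits).
#' @param matrix A `SubstitutionMatrix` used to label missense plants.
#' @param out_dir Optional directory; writes `parent.vcf`, `mutant.vcf`,
#'   `truth.tsv`.
#' @return List with `parent`, `mutant` (`StrainVariantSet`s), `truth`
#'   (data frame: chrom, pos, ref, alt, gene_id, category, notation) and
#'   `files`.
#' @export
simulate_mutagenesis <- function(genome, genes, spectrum = mutation_spectrum(),
                                 n_background = 30L, n_private = 40L, seed,
                                 category_coverage = TRUE,
                                 include_start_loss = FALSE,
                                 category_weights = NULL,
                                 matrix = substitution_matrix(),
                                 out_dir = NULL) {
  if (missing(seed)) stop("seed is mandatory")
  set.seed(seed)
  if (is.null(category_weights)) {
    category_weights <- c(synonymous = 0.12, missense_conservative = 0.27,
                          missense_nonconservative = 0.25, nonsense = 0.08,
                          sense = 0.03, frameshift = 0.04,
                          inframe_indel = 0.06, intergenic = 0.15)
  }
  env <- .block_env()
  coding_genes <- Filter(function(g) g$coding_ok, genes)
  if (length(coding_genes) == 0L && n_private > 0L) {
    stop("no coding genes to plant variants in")
  }
  cds_cache <- lapply(coding_genes, function(g)
    suppressWarnings(extract_cds(g, genome)))

  targets <- character(0)
  if (category_coverage) {
    targets <- c("synonymous", "missense_conservative",
                 "missense_nonconservative", "nonsense", "sense",
                 "frameshift", "inframe_indel")
    if (include_start_loss) targets <- c(targets, "start_loss")
  }
  if (length(targets) > n_private) targets <- targets[seq_len(n_private)]
  if (n_private > length(targets)) {
    targets <- c(targets, sample(names(category_weights),
                                 n_private - length(targets),
                                 replace = TRUE, prob = category_weights))
  }

  truth <- list()
  for (target in targets) {
    planted <- NULL
    if (target == "intergenic") {
      planted <- .plant_intergenic(genome, genes, spectrum, env)
    } else {
      for (gi in sample(seq_along(coding_genes),
                        min(20L, length(coding_genes)))) {
        g <- coding_genes[[gi]]
        cds <- cds_cache[[gi]]
        planted <- if (target %in% c("frameshift", "inframe_indel")) {
          .plant_indel(g, cds, target, genome, env)
        } else {
          .plant_substitution(g, cds, target, matrix, genome, env)
        }
        if (!is.null(planted)) break
      }
    }
    if (is.null(planted)) {
      message("could not place a ", target, " variant; re-drawing skipped it")
      next
    }
    truth[[length(truth) + 1L]] <- planted
  }
  truth <- if (length(truth) > 0L) do.call(rbind, truth) else
    data.frame(chrom = character(0), pos = integer(0), ref = character(0),
               alt = character(0), gene_id = character(0),
               category = character(0), notation = character(0))

  bg <- list()
  for (i in seq_len(n_background)) {
    row <- .draw_background(genome, spectrum, env)
    if (!is.null(row)) bg[[length(bg) + 1L]] <- row
  }
  bg <- if (length(bg) > 0L) do.call(rbind, bg) else
    data.frame(chrom = character(0), pos = integer(0),
               ref = character(0), alt = character(0))

  parent <- variant_set("parent", bg, genome_id = "simulated")
  mutant <- variant_set("mutant",
                        rbind(bg, truth[, c("chrom", "pos", "ref", "alt")]),
                        genome_id = "simulated")
  files <- NULL
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    pv <- file.path(out_dir, "parent.vcf")
    mv <- file.path(out_dir, "mutant.vcf")
    tt <- file.path(out_dir, "truth.tsv")
    write_vcf(parent, genome, pv)
    write_vcf(mutant, genome, mv)
    utils::write.table(truth, tt, sep = "\t", row.names = FALSE,
                       quote = FALSE)
    files <- list(parent = pv, mutant = mv, truth = tt)
  }
  list(parent = parent, mutant = mutant, truth = truth, files = files)
}

#' Simulate a replicated two-condition expression matrix
#'
#' Per-probe baseline log2 intensities with planted log2 shifts in the
#' treated condition and Gaussian noise, mimicking a treated/control
#' microarray design with independent replicates.
#'
#' @param n_probes Number of probes.
#' @param n_up,n_down Planted up-/down-regulated probes.
#' @param effect Planted absolute log2 fold change (2 = fourfold).
#' @param noise_sd Gaussian noise standard deviation on the log2 scale.
#' @param n_reps Replicates per condition.
#' @param seed Mandatory seed.
#' @return List with `intensities` (linear-scale matrix), `condition`, and
#'   `truth` (data frame `probe`, `direction` for planted probes).
#' @export
simulate_expression <- function(n_probes = 1000L, n_up = 50L, n_down = 50L,
                                effect = 2, noise_sd = 0.1, n_reps = 3L,
                                seed) {
  if (missing(seed)) stop("seed is mandatory")
  stopifnot(effect > 0, n_up + n_down <= n_probes)
  set.seed(seed)
  probes <- sprintf("probe%05d", seq_len(n_probes))
  base <- stats::rnorm(n_probes, mean = 9, sd = 1)
  shift <- rep(0, n_probes)
  up_idx <- seq_len(n_up)
  down_idx <- n_up + seq_len(n_down)
  shift[up_idx] <- effect
  shift[down_idx] <- -effect
  logm <- matrix(base, n_probes, 2L * n_reps) +
    cbind(matrix(shift, n_probes, n_reps), matrix(0, n_probes, n_reps)) +
    matrix(stats::rnorm(n_probes * 2L * n_reps, sd = noise_sd),
           n_probes, 2L * n_reps)
  colnames(logm) <- c(paste0("treated_", seq_len(n_reps)),
                      paste0("control_", seq_len(n_reps)))
  rownames(logm) <- probes
  truth <- data.frame(
    probe = probes[c(up_idx, down_idx)],
    direction = c(rep("up", n_up), rep("down", n_down)))
  list(intensities = 2^logm,
       condition = sub("_.*$", "", colnames(logm)),
       truth = truth)
}

#' Compare planted truth with classified consequences
#'
#' Joins a truth table to [annotate_variants()] output on
#' (chrom, pos, ref, alt, gene) keys and reports the confusion matrix over
#' categories with per-category precision and recall, the fraction of
#' matching notations, and all mismatches. Errors when a truth variant has
#' no corresponding call.
#'
#' @param truth Truth table from [simulate_mutagenesis()].
#' @param ann Output of [annotate_variants()] over (at least) the same
#'   variants.
#' @return List with `confusion`, `per_category`, `notation_agreement`,
#'   `mismatches`.
#' @export
recovery_report <- function(truth, ann) {
  called_cat <- character(nrow(truth))
  called_not <- character(nrow(truth))
  for (i in seq_len(nrow(truth))) {
    if (is.na(truth$gene_id[i])) {
      hit <- ann$chrom == truth$chrom[i] & ann$pos == truth$pos[i] &
        ann$ref == truth$ref[i] & ann$alt == truth$alt[i] &
        ann$region == "intergenic"
      if (!any(hit)) stop("truth variant ", variant_key(truth[i, ]),
                          " (intergenic) has no matching call")
      called_cat[i] <- "intergenic"
      called_not[i] <- NA_character_
    } else {
      hit <- ann$chrom == truth$chrom[i] & ann$pos == truth$pos[i] &
        ann$ref == truth$ref[i] & ann$alt == truth$alt[i] &
        !is.na(ann$gene_id) & ann$gene_id == truth$gene_id[i]
      if (!any(hit)) stop("truth variant ", variant_key(truth[i, ]),
                          " has no matching call in gene ", truth$gene_id[i])
      called_cat[i] <- ann$category[which(hit)[1L]]
      called_not[i] <- ann$notation[which(hit)[1L]]
    }
  }
  levels_all <- c(CONSEQUENCE_CATEGORIES, "intergenic")
  confusion <- table(factor(truth$category, levels = levels_all),
                     factor(called_cat, levels = levels_all),
                     dnn = c("truth", "called"))
  present <- unique(truth$category)
  per <- do.call(rbind, lapply(present, function(cat) {
    n_true <- sum(truth$category == cat)
    n_called <- sum(called_cat == cat)
    tp <- sum(truth$category == cat & called_cat == cat)
    data.frame(category = cat, n_true = n_true, n_called = n_called,
               precision = if (n_called > 0) tp / n_called else NA_real_,
               recall = tp / n_true)
  }))
  has_not <- !is.na(truth$notation)
  notation_agreement <- if (any(has_not)) {
    mean(truth$notation[has_not] == called_not[has_not])
  } else NA_real_
  mism <- truth[truth$category != called_cat |
                  (has_not & truth$notation != called_not), , drop = FALSE]
  if (nrow(mism) > 0L) {
    mism$called_category <- called_cat[as.integer(rownames(mism))]
    mism$called_notation <- called_not[as.integer(rownames(mism))]
  }
  list(confusion = confusion, per_category = per,
       notation_agreement = notation_agreement, mismatches = mism)
}

#' Mirror a genome, its gene models and variants
#'
#' Reverse-complements every chromosome, remaps gene segments and flips
#' strands, and remaps variants onto the mirrored coordinates. Consequence
#' calls must be invariant under this transformation (after re-normalizing
#' the mirrored variants), which makes it a strong strand-handling check.
#'
#' @param genome A `Genome`.
#' @param genes Named list of `GeneModel` objects.
#' @param variants Data frame with `chrom`/`pos`/`ref`/`alt` (optional).
#' @return List with mirrored `genome`, `genes`, and `variants`.
#' @export
mirror_genome <- function(genome, genes, variants = NULL) {
  lens <- vapply(names(genome), function(ch) chrom_length(genome, ch),
                 integer(1L))
  mseqs <- vapply(unclass(genome), revcomp, character(1L))
  names(mseqs) <- names(genome)
  mgenome <- Genome(mseqs)
  mgenes <- lapply(genes, function(g) {
    L <- lens[[g$chromosome]]
    seg <- data.frame(start = L - g$segments$end + 1L,
                      end = L - g$segments$start + 1L)
    GeneModel(g$gene_id, g$chromosome,
              if (g$strand == "+") "-" else "+",
              seg, symbol = g$symbol, description = g$description)
  })
  names(mgenes) <- names(genes)
  mvars <- NULL
  if (!is.null(variants)) {
    mvars <- variants
    for (i in seq_len(nrow(mvars))) {
      L <- lens[[mvars$chrom[i]]]
      e <- mvars$pos[i] + nchar(mvars$ref[i]) - 1L
      mvars$pos[i] <- L - e + 1L
      mvars$ref[i] <- revcomp(mvars$ref[i])
      mvars$alt[i] <- revcomp(mvars$alt[i])
    }
  }
  list(genome = mgenome, genes = mgenes, variants = mvars)
}
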