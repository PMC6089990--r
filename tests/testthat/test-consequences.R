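test_that("BLOSUM62 wrapper is symmetric and splits conservativeness at 0", {
  m <- substitution_matrix()
  expect_identical(m$score, t(m$score))
  expect_identical(dim(m$score), c(20L, 20L))
  expect_identical(conseqr:::substitution_score(m, "V", "G"), -3L)
  expect_true(conseqr:::substitution_score(m, "D", "E") >= m$threshold)
})

test_that("substitutions classify to the full category set with correct notation", {
  # codon 5 is CAA (Q); C->T makes TAA: nonsense "Q5*"
  cds <- paste0("ATG", "GCT", "CTG", "AAA", "CAA", "TAT", "TAA")
  for (strand in c("+", "-")) {
    fx <- make_gene_fixture(cds, strand = strand)
    cs <- extract_cds(fx$gene, fx$genome)
    m <- substitution_matrix()
    offset <- 13L  # first base of codon 5
    pos <- conseqr:::genomic_pos_of(fx$gene, offset)
    ref <- if (strand == "-") "G" else "C"
    alt <- if (strand == "-") "A" else "T"
    got <- classify_substitution(fx$gene, cs, offset, ref, alt, m)
    expect_identical(got$category, "nonsense")
    expect_identical(got$notation, "Q5*")
  }

  fx <- make_gene_fixture(cds)
  cs <- extract_cds(fx$gene, fx$genome)
  m <- substitution_matrix()
  # CTG -> CTA: synonymous (L)
  syn <- classify_substitution(fx$gene, cs, 9L, "G", "A", m)
  expect_identical(syn$category, "synonymous")
  expect_identical(syn$notation, "L3L")
  # terminal TAA -> CAA: stop-loss ("sense")
  sl <- classify_substitution(fx$gene, cs, 19L, "T", "C", m)
  expect_identical(sl$category, "sense")
  expect_identical(sl$notation, "*7Q")
  # ATG codon 1 destroyed: start_loss
  st <- classify_substitution(fx$gene, cs, 2L, "T", "C", m)
  expect_identical(st$category, "start_loss")
  # AAA (K) -> AGA (R): conservative missense (BLOSUM62 K/R = 2)
  mc <- classify_substitution(fx$gene, cs, 11L, "A", "G", m)
  expect_identical(mc$category, "missense_conservative")
  expect_identical(mc$notation, "K4R")
})

test_that("a stop codon mutating to another stop is synonymous", {
  cds <- paste0("ATG", "GCT", "TAA")
  fx <- make_gene_fixture(cds)
  cs <- extract_cds(fx$gene, fx$genome)
  got <- classify_substitution(fx$gene, cs, 9L, "A", "G",
                               substitution_matrix())  # TAA -> TAG
  expect_identical(got$category, "synonymous")
})

test_that("indels classify by net length modulo 3 with CDS-level notation", {
  set.seed(31)
  cds <- paste(c("ATG", sample(conseqr:::SENSE_CODONS, 28, replace = TRUE),
                 "TAA"), collapse = "")
  fx <- make_gene_fixture(cds)
  cs <- extract_cds(fx$gene, fx$genome)
  g <- fx$gene
  # 3-nt insertion between offsets 10/11 -> in-frame
  loc <- data.frame(region = "CDS", gene_id = "g1", cds_offset = 10L,
                    boundary = FALSE)
  ins <- classify_indel(g, cs, loc, "A", "ATTG")
  expect_identical(ins$category, "inframe_indel")
  expect_identical(ins$notation, "+TTG 10/11")
  # 6-nt insertion stays in frame
  ins6 <- classify_indel(g, cs, loc, "A", "ATTGTTG")
  expect_identical(ins6$category, "inframe_indel")
  # 1-nt deletion at offset 10 -> frameshift
  del <- classify_indel(g, cs, loc, "AG", "A")
  expect_identical(del$category, "frameshift")
  expect_identical(substr(del$notation, 1, 1), "-")
  # boundary-spanning indel is complex
  locb <- data.frame(region = "CDS", gene_id = "g1", cds_offset = 1L,
                     boundary = TRUE)
  cx <- classify_indel(g, cs, locb, "AG", "A")
  expect_identical(cx$category, "complex")
  expect_true(nzchar(cx$notation))
})

test_that("locate_variant reports per-gene hits, intergenic, and minus offsets", {
  set.seed(37)
  cds <- paste(c("ATG", sample(conseqr:::SENSE_CODONS, 18, replace = TRUE),
                 "TAA"), collapse = "")
  fx <- make_gene_fixture(cds, strand = "-")
  # intergenic position (inside the left pad)
  iv <- locate_variant("chrI", 3L, substr(unclass(fx$genome)[[1]], 3, 3),
                       "A", fx$genes)
  iv_alt <- if (substr(unclass(fx$genome)[[1]], 3, 3) == "A") "G" else "A"
  iv <- locate_variant("chrI", 3L, substr(unclass(fx$genome)[[1]], 3, 3),
                       iv_alt, fx$genes)
  expect_identical(iv$region, "intergenic")

  # minus-strand offsets agree with the transcript-vector oracle
  tr <- oracle_transcript(fx$genome, fx$gene)
  for (k in c(1L, 7L, 30L, 60L)) {
    gp <- tr$gpos[k]
    got <- locate_variant("chrI", gp,
                          substr(unclass(fx$genome)[[1]], gp, gp), "N",
                          fx$genes)
    expect_identical(got$cds_offset, k)
  }

  # overlapping genes: one variant, two records
  g2 <- GeneModel("g2", "chrI", "+",
                  data.frame(start = fx$gene$segments$start,
                             end = fx$gene$segments$end))
  both <- locate_variant("chrI", fx$gene$segments$start + 5L, "N", "A",
                         list(g1 = fx$gene, g2 = g2))
  expect_identical(nrow(both), 2L)
  expect_setequal(both$gene_id, c("g1", "g2"))
})

test_that("MNVs decompose into per-base SNVs and codon collisions are flagged", {
  cds <- paste0("ATG", "GTT", "AAA", "TAA")  # V at codon 2, K at codon 3
  fx <- make_gene_fixture(cds)
  # two adjacent substituted bases inside codon 2: GTT -> GGC? change T5,T6
  vars <- data.frame(chrom = "chrI", pos = fx$offset0 + 5L,
                     ref = "TT", alt = "GC")
  ann <- annotate_variants(vars, fx$genome, fx$genes) |>
    suppressMessages()
  cl <- ann[ann$region == "CDS", ]
  expect_identical(nrow(cl), 2L)           # decomposed into two SNVs
  expect_true(all(cl$codon_shared))        # both hit codon 2
  expect_identical(sort(cl$pos), fx$offset0 + c(5L, 6L))
})

test_that("annotation of unclassifiable genes keeps location but no category", {
  genome <- Genome(c(chrI = paste0(strrep("TG", 10), "ATGGCTTA",
                                   strrep("CA", 10))))
  gene <- suppressWarnings(
    GeneModel("g", "chrI", "+", data.frame(start = 21, end = 28)))
  expect_false(gene$coding_ok)
  vars <- data.frame(chrom = "chrI", pos = 23L, ref = "G", alt = "A")
  ann <- annotate_variants(vars, genome, list(g = gene))
  expect_identical(ann$region, "CDS")
  expect_true(is.na(ann$category))
})

test_that("incremental classifier agrees with the re-translation oracle", {
  cfg <- simulation_config(n_chromosomes = 2, n_genes = 30, seed = 301)
  sim <- simulate_genome(cfg)
  mut <- simulate_mutagenesis(sim$genome, sim$genes, n_background = 0,
                              n_private = 120, seed = 302)
  ann <- suppressMessages(
    annotate_variants(mut$mutant, sim$genome, sim$genes))
  cl <- ann[ann$region == "CDS" & !is.na(ann$category), ]
  expect_gt(nrow(cl), 80)
  expect_identical(oracle_disagreements(ann, sim$genome, sim$genes), 0L)
})

test_that("consequences are invariant under genome mirroring", {
  cfg <- simulation_config(n_chromosomes = 2, n_genes = 20, seed = 311)
  sim <- simulate_genome(cfg)
  mut <- simulate_mutagenesis(sim$genome, sim$genes, n_background = 0,
                              n_private = 60, seed = 312)
  ann <- suppressMessages(
    annotate_variants(mut$mutant, sim$genome, sim$genes))
  mir <- mirror_genome(sim$genome, sim$genes, mut$mutant$variants)
  ann_m <- suppressMessages(
    annotate_variants(mir$variants, mir$genome, mir$genes))
  key <- function(a) {
    cl <- a[a$region == "CDS" & !is.na(a$category), ]
    sort(paste(cl$gene_id, cl$category, cl$notation))
  }
  expect_identical(key(ann_m), key(ann))
})

test_that("classification is order-independent and summaries add up", {
  cfg <- simulation_config(n_chromosomes = 1, n_genes = 12, seed = 321)
  sim <- simulate_genome(cfg)
  mut <- simulate_mutagenesis(sim$genome, sim$genes, n_background = 0,
                              n_private = 40, seed = 322)
  df <- mut$mutant$variants
  ann1 <- suppressMessages(annotate_variants(df, sim$genome, sim$genes))
  ann2 <- suppressMessages(
    annotate_variants(df[rev(seq_len(nrow(df))), ], sim$genome, sim$genes))
  expect_identical(ann1, ann2)

  s <- summarize_consequences(ann1)
  expect_identical(Reduce(`+`, s$counts), s$n_variants)
  miss <- s$counts$missense_conservative + s$counts$missense_nonconservative
  expect_identical(miss, sum(ann1$category %in%
    c("missense_conservative", "missense_nonconservative"), na.rm = TRUE))
})

test_that("summarize counts categories and inactivating calls", {
  ann <- data.frame(
    chrom = "chrI", pos = 1:4, ref = "A", alt = "G",
    region = "CDS", gene_id = c("g1", "g1", "g2", "g3"),
    symbol = NA, cds_offset = 1:4,
    category = c("missense_conservative", "missense_conservative",
                 "missense_nonconservative", "nonsense"),
    codon_index = 1L, ref_aa = "A", alt_aa = "G", notation = "A1G",
    inactivating = c(FALSE, FALSE, FALSE, TRUE), codon_shared = FALSE)
  s <- summarize_consequences(ann)
  expect_identical(s$counts$missense_conservative, 2L)
  expect_identical(s$counts$missense_nonconservative, 1L)
  expect_identical(s$counts$nonsense, 1L)
  expect_identical(s$n_inactivating, 1L)
  expect_identical(s$n_genes_affected, 3L)

  s0 <- summarize_consequences(ann[0, ])
  expect_identical(s0$n_variants, 0L)
  expect_true(all(unlist(s0$counts) == 0L))
})

test_that("inactivating policy switch moves in-frame indels", {
  expect_true(is_cds_inactivating("nonsense"))
  expect_false(is_cds_inactivating("missense_conservative"))
  expect_false(is_cds_inactivating("inframe_indel"))
  expect_true(is_cds_inactivating("inframe_indel", "include-inframe"))
  expect_error(inactivating_policy(c("nonsense", "bogus")), "unknown")
})

test_that("gene report joins variations in CDS order", {
  d <- demo_strain_pair()
  ann <- annotate_variants(differential_variants(d$mutant, d$parent),
                           d$genome, d$genes, policy = "include-inframe")
  rep <- format_gene_report(ann, d$genes, d$genome, inactivating_only = TRUE)
  expect_identical(rep$variation[rep$symbol == "GEP3"], "V373G; K376*")
  expect_identical(rep$variation[rep$symbol == "RPL33A"], "W25*")
  expect_identical(nrow(format_gene_report(ann[0, ], d$genes)), 0L)
})
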