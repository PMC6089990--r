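toy_genome <- function(seq = "TTAAAAGCCGGCCGGTACGTACGTACGT") {
  Genome(c(chrI = seq))
}

test_that("normalize_variant trims shared bases and left-aligns indels", {
  g <- Genome(c(chrI = paste0(strrep("ACGT", 30), "CACT", strrep("ACGT", 30))))
  # (pos 121, CA, CT) -> shared prefix trimmed -> (122, A, T)
  v <- normalize_variant("chrI", 121, "CA", "CT", g)
  expect_identical(v[c("pos", "ref", "alt")], list(pos = 122L, ref = "A", alt = "T"))

  # insertion at the right end of a homopolymer run shifts to its left edge:
  # T T A A A A G ... ; +A after pos 6 == +A anchored at pos 2
  g2 <- toy_genome("TTAAAAGCC")
  v2 <- normalize_variant("chrI", 6, "A", "AA", g2)
  expect_identical(v2[c("pos", "ref", "alt")], list(pos = 2L, ref = "T", alt = "TA"))

  # brute-force check: both representations produce the same mutated sequence
  apply_var <- function(seq, pos, ref, alt) {
    paste0(substr(seq, 1, pos - 1), alt,
           substr(seq, pos + nchar(ref), nchar(seq)))
  }
  expect_identical(apply_var("TTAAAAGCC", 6, "A", "AA"),
                   apply_var("TTAAAAGCC", 2, "T", "TA"))

  # deletion in the same run left-aligns too
  v3 <- normalize_variant("chrI", 5, "AA", "A", g2)
  expect_identical(v3[c("pos", "ref", "alt")], list(pos = 2L, ref = "TA", alt = "T"))
})

test_that("normalize_variant is idempotent on random indels", {
  set.seed(17)
  seq <- paste(sample(c("A", "C", "G", "T"), 500, replace = TRUE,
                      prob = c(0.4, 0.1, 0.1, 0.4)), collapse = "")
  g <- Genome(c(chrI = seq))
  for (i in 1:50) {
    pos <- sample(5:490, 1)
    b <- substr(seq, pos, pos)
    if (runif(1) < 0.5) {
      ref <- b; alt <- paste0(b, paste(sample(c("A", "C", "G", "T"),
                                              sample(1:3, 1), replace = TRUE),
                                       collapse = ""))
    } else {
      len <- sample(1:3, 1)
      ref <- substr(seq, pos, pos + len); alt <- b
    }
    v1 <- normalize_variant("chrI", pos, ref, alt, g)
    v2 <- normalize_variant(v1$chrom, v1$pos, v1$ref, v1$alt, g)
    expect_identical(v1, v2)
  }
})

test_that("read_variant_table maps columns, rejects pos 0, dedupes", {
  g <- toy_genome()
  tsv <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("Chr\tPosition\tRef\tAlt",
               "chrI\t3\tA\tG",
               "chrI\t7\tG\tT",
               "chrI\t10\tG\tA"), tsv)
  cols <- list(chrom = "Chr", pos = "Position", ref = "Ref", alt = "Alt")
  vs <- read_variant_table(tsv, g, columns = cols)
  expect_identical(nrow(vs$variants), 3L)

  writeLines(c("Chr\tPosition\tRef\tAlt", "chrI\t3\tA\tG", "chrI\t3\tA\tG"), tsv)
  expect_warning(vs2 <- read_variant_table(tsv, g, columns = cols), "duplicate")
  expect_identical(nrow(vs2$variants), 1L)

  writeLines(c("Chr\tPosition\tRef\tAlt", "chrI\t0\tA\tG"), tsv)
  expect_error(read_variant_table(tsv, g, columns = cols), "1-based")

  writeLines(c("Chr\tPos\tRef\tAlt", "chrI\t3\tA\tG"), tsv)
  expect_error(read_variant_table(tsv, g, columns = cols), "Position")
})

test_that("read_vcf splits multi-allelics, filters non-PASS, checks REF", {
  g <- toy_genome("TTAAAAGCCGGCCGGTACGTACGTACGT")
  vcf <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    sprintf("##contig=<ID=chrI,length=%d>", 28),
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO",
    "chrI\t3\t.\tA\tG,C\t.\tPASS\t.",
    "chrI\t7\t.\tG\tT\t.\tq10\t.",
    "chrI\t17\t.\tA\tG\t.\t.\t."
  ), vcf)
  vs <- read_vcf(vcf, g)
  expect_identical(nrow(vs$variants), 3L)  # 2 from the split + the '.' filter
  expect_setequal(vs$variants$alt[vs$variants$pos == 3], c("G", "C"))
  expect_false(7L %in% vs$variants$pos)
  vs_all <- read_vcf(vcf, g, keep_filtered = TRUE)
  expect_identical(nrow(vs_all$variants), 4L)

  writeLines(c(
    "##fileformat=VCFv4.2",
    "##contig=<ID=chrI,length=28>",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO",
    "chrI\t3\t.\tC\tG\t.\tPASS\t."
  ), vcf)
  expect_error(read_vcf(vcf, g), "REF allele disagrees")
})

test_that("VCF and table encodings of the same variants agree after normalization", {
  g <- toy_genome("TTAAAAGCCGGCCGGTACGTACGTACGT")
  vcf <- withr::local_tempfile(fileext = ".vcf")
  tsv <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##contig=<ID=chrI,length=28>",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO",
    "chrI\t6\t.\tA\tAA\t.\tPASS\t.",   # homopolymer insertion, right-anchored
    "chrI\t15\t.\tGT\tGG\t.\tPASS\t."  # padded SNV
  ), vcf)
  writeLines(c("chrom\tpos\tref\talt",
               "chrI\t2\tT\tTA",        # same insertion, left-anchored
               "chrI\t16\tT\tG"), tsv)
  a <- read_vcf(vcf, g)
  b <- read_variant_table(tsv, g)
  expect_identical(a$variants, b$variants)
})

test_that("differential_variants is the exact asymmetric set difference", {
  g <- toy_genome()
  v1 <- data.frame(chrom = "chrI", pos = 3L, ref = "A", alt = "G")
  v2 <- data.frame(chrom = "chrI", pos = 7L, ref = "G", alt = "T")
  v3 <- data.frame(chrom = "chrI", pos = 16L, ref = "G", alt = "C")
  mutant <- variant_set("m", rbind(v1, v2))
  parent <- variant_set("p", rbind(v2, v3))  # v3 is parent-private
  d <- differential_variants(mutant, parent)
  expect_identical(d$variants, variant_set("m", v1)$variants)
  expect_identical(nrow(differential_variants(mutant, mutant)$variants), 0L)

  # genome id mismatch is refused
  m2 <- variant_set("m", v1, genome_id = "R64")
  p2 <- variant_set("p", v2, genome_id = "R63")
  expect_error(differential_variants(m2, p2), "different references")
})

test_that("difference plus intersection reconstructs the mutant set", {
  set.seed(23)
  g <- toy_genome(paste(sample(c("A", "C", "G", "T"), 300, replace = TRUE),
                        collapse = ""))
  mk <- function(n) {
    pos <- sample(300, n)
    data.frame(chrom = "chrI", pos = pos,
               ref = substring(unclass(g)[[1]], pos, pos),
               alt = sample(c("A", "C", "G", "T"), n, replace = TRUE))
  }
  for (i in 1:10) {
    a <- mk(20); a <- a[a$ref != a$alt, ]
    b <- rbind(mk(15), a[sample(nrow(a), 5), ])
    b <- b[b$ref != b$alt, ]
    A <- suppressWarnings(variant_set("A", a))
    B <- suppressWarnings(variant_set("B", b))
    d <- differential_variants(A, B)
    inter <- A$variants[conseqr:::variant_key(A$variants) %in%
                          conseqr:::variant_key(B$variants), ]
    rebuilt <- suppressWarnings(variant_set("A", rbind(d$variants, inter)))
    expect_identical(rebuilt$variants, A$variants)
  }
})

test_that("write_vcf round-trips through read_vcf", {
  g <- toy_genome("TTAAAAGCCGGCCGGTACGTACGTACGT")
  vs <- variant_set("s", data.frame(
    chrom = "chrI", pos = c(3L, 2L, 17L),
    ref = c("A", "T", "AC"), alt = c("G", "TA", "A")))
  path <- withr::local_tempfile(fileext = ".vcf")
  write_vcf(vs, g, path)
  back <- read_vcf(path, g, strain = "s")
  expect_identical(back$variants, vs$variants)
})
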