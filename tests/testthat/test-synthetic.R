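test_that("mutation spectrum rows are proper probability distributions", {
  sp <- mutation_spectrum()
  expect_equal(unname(rowSums(sp$substitution)), rep(1, 4))
  expect_true(all(diag(sp$substitution) == 0))
  expect_equal(sp$substitution["G", "A"], 0.8)
  expect_equal(sp$substitution["C", "T"], 0.8)
  expect_equal(sum(sp$indel_length_probs), 1)
})

test_that("simulated genomes contain valid, placeable gene models", {
  cfg <- simulation_config(n_chromosomes = 1, n_genes = 5, seed = 401)
  sim <- simulate_genome(cfg)
  expect_length(sim$genes, 5L)
  for (g in sim$genes) {
    expect_true(g$coding_ok)
    cds <- extract_cds(g, sim$genome)
    expect_identical(substr(cds$nucleotides, 1, 3), "ATG")
    n <- nchar(cds$nucleotides)
    expect_true(substr(cds$nucleotides, n - 2, n) %in% c("TAA", "TAG", "TGA"))
  }
  all_plus <- simulate_genome(simulation_config(n_genes = 8, strand_prob = 1,
                                                seed = 402))
  expect_true(all(vapply(all_plus$genes, `[[`, character(1), "strand") == "+"))

  expect_error(
    simulate_genome(simulation_config(n_chromosomes = 1, n_genes = 10,
                                      chromosome_length = 500, seed = 403)),
    "infeasible packing")
})

test_that("mutagenesis shares background and plants labeled private variants", {
  cfg <- simulation_config(n_chromosomes = 2, n_genes = 25, seed = 411)
  sim <- simulate_genome(cfg)
  mut <- simulate_mutagenesis(sim$genome, sim$genes, n_background = 25,
                              n_private = 30, seed = 412)
  # parent is a subset of mutant; difference is exactly the truth set
  expect_true(all(conseqr:::variant_key(mut$parent$variants) %in%
                    conseqr:::variant_key(mut$mutant$variants)))
  d <- differential_variants(mut$mutant, mut$parent)
  expect_setequal(conseqr:::variant_key(d$variants),
                  conseqr:::variant_key(mut$truth))
  # category coverage
  expect_true(all(c("synonymous", "missense_conservative",
                    "missense_nonconservative", "nonsense", "sense",
                    "frameshift", "inframe_indel") %in% mut$truth$category))

  # no private variants: empty differential
  none <- simulate_mutagenesis(sim$genome, sim$genes, n_background = 10,
                               n_private = 0, seed = 413)
  expect_identical(
    nrow(differential_variants(none$mutant, none$parent)$variants), 0L)
})

test_that("pure-transition spectra only produce transitions", {
  cfg <- simulation_config(n_chromosomes = 1, n_genes = 10, seed = 421)
  sim <- simulate_genome(cfg)
  sp <- mutation_spectrum(gc_to_at = 1, transition = 1, indel_rate = 0)
  mut <- simulate_mutagenesis(sim$genome, sim$genes, spectrum = sp,
                              n_background = 60, n_private = 0, seed = 422)
  bg <- mut$parent$variants
  is_transition <- (bg$ref == "G" & bg$alt == "A") |
    (bg$ref == "C" & bg$alt == "T") |
    (bg$ref == "A" & bg$alt == "G") | (bg$ref == "T" & bg$alt == "C")
  expect_true(all(is_transition))
})

test_that("simulation is reproducible from its seed", {
  cfg <- simulation_config(n_chromosomes = 2, n_genes = 10, seed = 431)
  s1 <- simulate_genome(cfg)
  s2 <- simulate_genome(cfg)
  expect_identical(unclass(s1$genome), unclass(s2$genome))
  m1 <- simulate_mutagenesis(s1$genome, s1$genes, n_background = 10,
                             n_private = 15, seed = 432)
  m2 <- simulate_mutagenesis(s2$genome, s2$genes, n_background = 10,
                             n_private = 15, seed = 432)
  expect_identical(m1$truth, m2$truth)
  expect_identical(m1$parent$variants, m2$parent$variants)

  e1 <- simulate_expression(n_probes = 50, n_up = 5, n_down = 5, seed = 433)
  e2 <- simulate_expression(n_probes = 50, n_up = 5, n_down = 5, seed = 433)
  expect_identical(e1$intensities, e2$intensities)
})

test_that("noise-free null expression matrices yield no calls", {
  sim <- simulate_expression(n_probes = 100, n_up = 0, n_down = 0,
                             effect = 2, noise_sd = 1e-4, seed = 441)
  res <- de_filter(sim$intensities, sim$condition)
  expect_identical(sum(res$retained), 0L)
})

test_that("recovery_report exposes perfect runs, mislabels, and key errors", {
  cfg <- simulation_config(n_chromosomes = 1, n_genes = 10, seed = 451)
  sim <- simulate_genome(cfg)
  mut <- simulate_mutagenesis(sim$genome, sim$genes, n_background = 0,
                              n_private = 20, seed = 452)
  ann <- suppressMessages(
    annotate_variants(mut$mutant, sim$genome, sim$genes))
  rec <- recovery_report(mut$truth, ann)
  expect_true(all(rec$per_category$precision == 1))
  expect_true(all(rec$per_category$recall == 1))
  expect_identical(nrow(rec$mismatches), 0L)
  expect_identical(sum(rec$confusion) - sum(diag(rec$confusion)), 0L)

  # one deliberately mislabeled truth row shows up off-diagonal
  bad <- mut$truth
  i <- which(bad$category == "nonsense")[1]
  bad$category[i] <- "missense_conservative"
  rec2 <- recovery_report(bad, ann)
  expect_identical(nrow(rec2$mismatches), 1L)
  expect_identical(rec2$mismatches$called_category[1], "nonsense")

  # unmatched truth keys error
  bad2 <- mut$truth
  bad2$pos[1] <- bad2$pos[1] + 1000L
  expect_error(recovery_report(bad2, ann), "no matching call")
})
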