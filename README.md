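# conseqr

Codon-level consequence annotation and strain comparison for
mutate-and-screen experiments in yeast-like genomes.

## What it is for

Forward-genetic screens (e.g. nitrosoguanidine mutagenesis followed by
selection) end with two whole-genome variant call sets — a parent and a
selected mutant, both called against the same reference. `conseqr` takes
the analysis from there:

* **Differential variants** — the exact, normalized set difference
  mutant ∖ parent on `(chrom, pos, ref, alt)` keys, after trimming and
  left-aligning indels so VCFs and flat supplementary-style tables compare
  equal.
* **CDS consequences** — every differential variant is located against the
  gene models (both strands, spliced CDS, 1-based GFF3/VCF coordinates
  throughout) and classified at codon level:

  | category | rule | notation |
  |---|---|---|
  | synonymous | amino acid unchanged (incl. stop→stop) | `L3L` |
  | missense, conservative | BLOSUM62(ref, alt) ≥ 0 | `K4R` |
  | missense, non-conservative | BLOSUM62(ref, alt) < 0 | `V373G` |
  | nonsense (stop-gain) | sense → stop | `Q5*` |
  | sense (stop-loss) | stop → sense | `*7Q` |
  | start-loss | codon 1 ATG destroyed | `M1T` |
  | frameshift | CDS indel, length mod 3 ≠ 0 | `-G 3233` |
  | in-frame indel | CDS indel, length mod 3 = 0 | `+TTG 1211/1212` |

* **CDS-inactivating calls** — `{nonsense, frameshift, start-loss,
  stop-loss}` by default; a policy switch (`include-inframe`) adds
  in-frame indels, since published inactivating-lesion tables differ on
  this point.
* **Expression thresholding** — per-probe Welch t-tests on log2
  intensities combined with a strict linear fold-change cutoff
  (p < 0.01 and ratio > 2.0 by default), gene-set overlap counts, and
  transcriptome-fraction arithmetic.
* **Segregation statistics** — per-tetrad 2:2 conformity against a
  simulated two-gene null, and the exact two-sided binomial test for
  random-spore ratios.
* **Synthetic data with ground truth** — toy genomes, an NTG-like
  mutagenesis simulator whose planted variants carry known category and
  notation labels, and planted-effect expression matrices, so the whole
  pipeline is testable without downloads.

## Worked example

`demo_strain_pair()` builds a deterministic toy genome of 15 yeast-style
genes (realistic CDS lengths, both strands) and a parent/mutant pair whose
private lesions span the full inactivating spectrum:

```r
library(conseqr)

d    <- demo_strain_pair()
diff <- differential_variants(d$mutant, d$parent)
ann  <- annotate_variants(diff, d$genome, d$genes, policy = "include-inframe")
summarize_consequences(ann)
#> 16 coding variant-gene pair(s) affecting 15 coding sequence(s)
#>   missense: 1 (0 conservative, 1 non-conservative)
#>   nonsense: 9  sense (stop-loss): 0  start-loss: 0
#>   frameshift: 5  in-frame indel: 1  synonymous: 0  complex: 0
#>   CDS-inactivating: 15   intergenic variants: 0

head(format_gene_report(ann, d$genes, d$genome, inactivating_only = TRUE)[,
     c("chromosome", "symbol", "cds_length", "variation")], 5)
#>   chromosome symbol cds_length      variation
#> 1      chrII   CYC8        967 +TTG 1211/1212
#> 2      chrII   TBS1       1095        -G 3233
#> 3      chrIV   HTA1        133     +G 117/118
#> 4      chrIV   SEM1         90       +A 61/62
#> 5      chrIV  CDC40        456           E94*
```

16 variant–gene pairs hit 15 genes because one gene carries both a
missense (`V373G`) and a stop-gain (`K376*`); the report cell for that
gene reads `V373G; K376*`. Under the default policy (in-frame indels not
inactivating) the inactivating count drops from 15 to 14 — both tallies
are reported, neither is forced.

Segregation arithmetic for a random-spore experiment reported as
percentages of a stated total:

```r
k <- reconstruct_spore_counts(2300, 53)$n_resistant   # 1219
segregation_binomial_test(2300, k)
#> exact two-sided binomial p = 0.00427
```

A 53 % resistant fraction of 2,300 spores is nominally *not* 1:1 — the
package reports the exact p-value and leaves interpretation (e.g.
differential spore viability) to the user.

A file-based run uses a YAML config and writes a run directory with the
consequence table, per-gene report, summary JSON, normalized differential
VCF, and a manifest with input checksums:

```r
run_annotate("run.yaml")
```

A thin command-line wrapper with `annotate`, `simulate`, `segregation` and
`report` subcommands is installed at `inst/scripts/pipeline.R`.

## Scope

Variant calling, read alignment, probe summarization and GO enrichment are
upstream/downstream concerns and deliberately out of scope. Classification
covers CDS effects only (no splice-site/UTR/regulatory prediction), under
the standard nuclear genetic code. See the vignette
(`vignettes/consequence-annotation.Rmd`) for the model, parameter and
design discussion.
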