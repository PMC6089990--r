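---
title: "Classifying CDS consequences in mutagenized strain pairs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying CDS consequences in mutagenized strain pairs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(conseqr)
```

## The analysis problem

A classic mutate-and-screen experiment in budding yeast produces two
whole-genome call sets: the parental strain and a selected mutant, both
called against the same reference assembly. The scientific questions are
downstream of the variant caller:

1. Which variants are *private* to the mutant — i.e. distinguish it from
   its parent?
2. What does each private variant do to the coding sequences it touches —
   synonymous, missense (and how drastic an exchange), stop-gain, stop-loss,
   frameshift, in-frame indel?
3. Which genes carry *CDS-inactivating* lesions, the prime candidates for a
   recessive phenotype?
4. Do the selection phenotype and marker data segregate as a monogenic
   nuclear trait (2:2 in tetrads, ~1:1 in random spores)?
5. Which transcripts pass the expression-change thresholds, and how do they
   intersect curated gene sets (for instance a mitochondrial proteome)?

`conseqr` implements this pipeline end to end, together with a synthetic
data generator that makes every step testable against planted ground truth.

## The genome model and coordinate conventions

All coordinates are **1-based inclusive** throughout — the shared
convention of GFF3 and VCF — so no 0-based translation happens at any
module seam. Gene models are ordered sets of non-overlapping CDS segments
on one strand of one chromosome; minus-strand CDS are spliced in reverse
genomic order and reverse-complemented on extraction, so every offset
reported by the package is a 1-based position in the 5'→3' spliced CDS.

CDS length is reported in **codons including the stop codon**: a 270-nt CDS
is 90 codons and encodes an 89-residue mature protein. This matches how CDS
lengths are conventionally tabulated in yeast comparative-genomics
summaries. Genes whose total CDS length is not divisible by 3 (annotation
artifacts) are kept for *locating* variants but excluded from codon-level
classification, with a warning — failing soft on imperfect annotations
beats discarding the variant.

Only the standard nuclear genetic code is implemented. Translation never
stops early: internal stops render as `*` and are reported, and any codon
containing `N` renders as `X`.

## Variant normalization

Variants from different sources (VCF, flat supplementary-style tables) are
only comparable after normalization. The canonical form is: shared
suffix/prefix trimmed, indels **left-aligned** against the reference with
anchored (non-empty) alleles — the VCF community convention. Normalization
is idempotent, and `differential_variants()` is an exact set difference on
the normalized `(chrom, pos, ref, alt)` keys. Genotype and zygosity are
deliberately ignored: the strains are treated as haploid call sets, which
is how flat per-strain variant lists present them.

Multi-base equal-length substitutions (MNVs) are decomposed into per-base
SNVs and classified independently; consequences sharing a codon are flagged
in the `codon_shared` column so the user can inspect potential compound
codons.

## Consequence classification

For a substitution at spliced-CDS offset $o$, the affected codon is
$\lceil o/3 \rceil$; the codon is rebuilt with the strand-corrected
alternate base and both codons translated:

* amino acid unchanged (including stop→stop) — `synonymous`;
* codon 1 `ATG` destroyed — `start_loss`;
* stop → sense — `sense` (stop-loss / read-through);
* sense → stop — `nonsense` (stop-gain);
* otherwise missense, split by the BLOSUM62 score of the exchange:
  **conservative iff** $\mathrm{BLOSUM62}(a_\mathrm{ref}, a_\mathrm{alt})
  \ge 0$.

The BLOSUM62 matrix comes from `Biostrings`; the threshold 0 is the
standard reading of "conservative by BLOSUM62" (non-negative log-odds
means the exchange is at least as common as chance among related
proteins) and is configurable (`blosum_threshold`). "Sense mutation" is a
term some comparative-genomics tables use without definition; this package
explicitly interprets it as **stop-loss**, the only reading under which the
category is disjoint from missense and nonsense.

Indels fully inside a CDS classify by net length change modulo 3 —
`frameshift` when ≠ 0, `inframe_indel` otherwise — with nucleotide-level,
strand-corrected notation: insertions `+SEQ p/p+1` (between spliced-CDS
offsets `p` and `p+1`), deletions `-SEQ p`. Substitution notation is
`<refAA><codon><altAA>`, e.g. `Q5*` or `V373G`. Indels that span a CDS
boundary are classified `complex` and flagged rather than guessed at.
A variant overlapping $k$ genes yields $k$ consequences; summaries count
variant–gene pairs and distinct variants separately.

### The inactivating policy

The default CDS-inactivating set is `{nonsense, frameshift, start_loss,
sense}`. In-frame indels are excluded by default — deleting or inserting
whole codons often yields a functional protein — but published
inactivating-lesion tables sometimes include them, so
`policy = "include-inframe"` adds them. Keeping this a switch (rather than
hard-coding either convention) lets both tallies be reported side by side;
the package never forces the two conventions to agree. The bundled
`demo_strain_pair()` panel illustrates the difference: 15 inactivating
calls under `include-inframe`, 14 under the default.

## Segregation statistics

A recessive monogenic nuclear trait segregates 2:2 in every complete
tetrad and ~1:1 in random spores. `tetrad_pattern_test()` scores
per-tetrad conformity and contrasts the monogenic model (P(2:2) = 1) with
a two-unlinked-gene null, where tetrad types PD:NPD:T occur 1:1:4 and only
parental ditypes (probability 1/6) are 2:2. `segregation_binomial_test()`
is the exact two-sided binomial test (sum of outcome probabilities no more
likely than the observed one). "Nearly 1:1" claims are thereby quantified
rather than asserted: a 47%:53% split of 2,300 spores, for example, gives
an exact p ≈ 0.004 — nominally *inconsistent* with 1:1. The package
surfaces this rather than suppressing it; with published data the observed
count itself is usually reconstructed from a printed percentage
(`reconstruct_spore_counts()` reports both rounding candidates when the
reconstruction is inexact), and modest deviations are compatible with
differential spore viability rather than oligogenic inheritance.
Interpretation is left to the user.

## Expression thresholding

`de_filter()` applies the classic joint threshold — per-probe two-sided
t-test p < α **and** linear fold change > r (or < 1/r) — with both
inequalities strict, so a probe at exactly r is excluded. The t-test runs
on log2 intensities by default (Welch); a pooled-variance flag and a
linear-scale flag exist because published methods sections frequently do
not say which variant was used. No multiple-testing correction is applied,
matching the thresholding practice the filter models; the α = 0.01 default
is therefore a *screening* threshold, not a FWER guarantee.
`transcriptome_fraction()` rounds half-up to two decimals (372 of 5,841
probe sets → 6.37%). Probe summarization (e.g. PLIER) is upstream and out
of scope: the stage consumes an already-summarized positive intensity
matrix.

## What the generator emulates — and what it does not

`simulate_genome()` builds multi-chromosome genomes of complete
single-exon genes (ATG…stop, length divisible by 3) on both strands with
random intergenic spacers. Defaults: 60–200 codons per gene, 80–200 nt
gaps, strand probability 0.5. Multi-exon splicing is exercised through
hand-built fixtures in the test suite rather than the generator.

`simulate_mutagenesis()` emulates the *structure* of a mutagenesis screen:
a background variant set shared by parent and mutant (both called against
the same reference, so background subtracts out exactly) plus
mutant-private variants planted with known labels. The default
substitution spectrum puts 0.8 of the G/C substitution mass on G:C→A:T
transitions — the alkylation signature of nitrosoguanidine — and the
default private-category weights are missense-dominated with a minority of
truncating events and intergenic hits, echoing the composition such
screens report. The spectrum is a modelling choice (published screens
rarely quantify theirs) and every parameter is exposed.

Planted indels are placed with **two-sided placement stability** (the
inserted/deleted run cannot shift toward either flank), so the planted
representation is its own normal form on both strands and truth labels are
unambiguous. Start codons are avoided unless start-loss coverage is
requested. Colliding draws are re-drawn with a logged message.

What passing recovery tests on this generator shows: the classifier,
coordinate mapping, strand handling, normalization and set arithmetic are
internally consistent and agree with an independent full-ORF
re-translation oracle. What they do **not** show: robustness to real-world
annotation noise (overlapping isoforms, programmed frameshifts,
pseudogenes), caller artifacts, or repeat-mediated ambiguous indels —
real data can contain variants the generator deliberately never plants.

## Numerical and design choices

* Exact binomial p-values use the standard likelihood-ordering two-sided
  rule with the customary `1 + 1e-7` relative tolerance on ties.
* `transcriptome_fraction()` rounds half-up (not banker's rounding), so
  printed percentages match common spreadsheet behaviour.
* Non-PASS VCF records are excluded by default; flat tables have no FILTER
  column, so table input is never filtered.
* A substitution turning one stop codon into another is synonymous.
* Chromosome sort order in reports follows the genome file when one is
  supplied, otherwise lexicographic.
* The two-gene tetrad null is simulated (seeded) and also reported in
  closed form $(1/6)^n$.

## Problem sizes used in the validation suite

The bundled tests and the acceptance script run entirely on synthetic
data: genomes of 120–150 genes across 2–4 chromosomes, 400–1,050 planted
variants per run for oracle and recovery checks, 5,841-probe expression
matrices with 270 planted effects at fourfold / noise sd 0.1 / 3
replicates, 12–200 simulated tetrads, and 2,300-spore binomial tests.
These sizes were chosen to exercise every code path (both strands, every
category, repeat-adjacent indels) while keeping a full validation run in
well under a minute.

## Known limitations

* No splice-site, UTR, promoter or regulatory effect prediction; CDS only.
* One transcript per gene; overlapping genes are handled, alternative
  isoforms of the same gene are not modelled.
* Only the standard nuclear code; mitochondrial genes need a different
  code table and are out of scope.
* MNV decomposition classifies bases independently: a doubly substituted
  codon is reported as two consequences (flagged `codon_shared`), not as a
  single compound amino-acid change.
* The expression stage models two conditions with equal replicate counts;
  no batch structure, no correction for multiple testing.
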