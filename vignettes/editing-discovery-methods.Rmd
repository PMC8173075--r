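---
title: "Methods: discovering and comparing G-to-A RNA editing from pileups"
author: "gaedit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: discovering and comparing G-to-A RNA editing from pileups}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gaedit)
```

## The problem

RNA editing alters single bases of a transcript relative to its genomic
template. G-to-A editing — a genomically encoded G read as A on the
transcript strand — is a non-canonical editing class whose footprint in
RNA-seq is a low-frequency G>A substitution (or C>T on the genomic
strand of a minus-strand gene) that is *not* explained by germline
variation or alignment artifacts. Distinguishing true editing from those
two confounders is the whole game: a naive variant caller run on RNA-seq
reports editing, heterozygous SNPs, homopolymer slippage, splice-
junction misalignment and INDEL-adjacent noise as one undifferentiated
pile of SNVs.

`gaedit` implements the discovery recipe used in stress-model brain
transcriptomics (chronic social defeat stress, CSDS, with emotional-
stress and physical-stress variants, profiled in the ventral tegmental
area) as a general, tested pipeline that starts at samtools mpileup
text. Everything upstream — alignment, duplicate removal, base-quality
recalibration — is out of scope; everything downstream of the pileups is
implemented and tested here, on synthetic data whose ground truth is
known.

## Calling model

A pileup record is tokenized into per-read observations (base, strand,
Phred quality, attached insertion/deletion). Observations below the
base-quality floor are discarded; the quality-filtered depth is the
denominator for all allele fractions. A variant call at a site requires,
per sample:

* base quality ≥ 25 (`q_min`),
* quality-filtered depth ≥ 10 (`min_depth`),
* alternate-allele depth ≥ 2 (`min_alt_depth`),
* alternate allele frequency (AAF) ≥ 1% (`min_aaf`),

all inclusive. The AAF of a G-to-A site *is* its editing level. Two
pileup-computable false-positive checks follow, in the spirit of
VarScan's fpfilter: a strand-bias rule (all alternate reads on one
strand while reference reads occur on both, at alternate depth ≥ 4) and
a base-quality gap rule (mean alternate quality more than 10 below mean
reference quality). fpfilter's read-position and mapping-quality
criteria need read-level data that pileup text does not carry; the two
implemented checks are the pileup-computable subset, and both thresholds
are configurable. The AAF denominator is the quality-filtered depth
rather than the raw column-4 depth, matching how qualified reads are
counted by pileup-based callers; the deletion placeholder `*` counts
toward depth but toward no allele.

## The six-rule cascade

A candidate site is flagged, independently, when it is

1. inside the simple-repeat mask, or inside/immediately beside a
   homopolymer run of ≥ 5 nt,
2. on a mitochondrial contig,
3. within 6 nt of a splice junction (inclusive),
4. within 1 nt of an INDEL call in a sample that also carries the SNV,
5. a known germline variant (exact contig/position/ref/alt match), or
6. germline-patterned: more than 90% of the callable discovery samples
   sit at AAF = 100% or within [40%, 60%].

A site present in the known-editing catalogue is *rescued*: all six
flags are voided. Admission to the high-confidence set then requires a
genic location, transcript-strand edit type G-to-A, and detection in at
least 2 discovery samples **or** replication in at least one
reference-cohort sample at level ≥ 1%.

Decisions that were genuinely open, and how they were fixed:

* **Homopolymer adjacency.** A site is flagged when it is inside *or*
  within one base of a qualifying run, because substitution artifacts at
  run edges are the known failure mode; the adjacency radius is a
  parameter.
* **Genic = gene span.** Intronic positions count as genic; the
  consequence annotator later separates intron, UTR and CDS classes.
* **Filter-6 denominator.** "Samples" is read as *callable* samples
  (quality-filtered depth ≥ 10): a sample with no qualifying coverage
  carries no genotype evidence. An all-samples mode exists
  (`germline_denominator = "all"`).
* **dbSNP matching needs allele identity.** A catalogued A>C
  polymorphism at a position must not disqualify a G>A candidate there.
  Known-*editing* matching, by contrast, is positional only, because
  editing catalogues report transcript-strand events.
* **Detection is sample-level, flags are site-level.** The ≥ 2-samples
  rule counts post-fpfilter calls; the six flags are computed once per
  site.
* **Strand-ambiguous sites** (overlapping genes on both strands) are
  excluded from the G-to-A set and reported separately.
* **Replication cohort.** Cohort pileups go through the same calling
  thresholds and false-positive filter; only the ≥ 1% level threshold
  differs. Filter 6 is defined on the discovery samples, whose design
  it names.

### What filter 6 can and cannot do

The AAF-band rule is a *pattern* test, and its power depends strongly on
coverage. At depth $d$ and true heterozygous fraction 0.5, a single
sample lands in [0.40, 0.60] with probability
$P(0.4d \le X \le 0.6d), X \sim \mathrm{Bin}(d, 0.5)$ — about 0.80 at
depth 30 and 0.88 at depth 50 — and the rule requires *more than 90% of
samples* to land there, which with 9 discovery samples means all 9. At
the depths this package simulates by default, filter 6 alone therefore
removes only a minority of heterozygous SNPs (the all-9 probability at
depth 50 is ≈ 0.32); reliable germline removal comes from filter 6
*plus* the known-variant catalogue, which is how the cascade is
evaluated. Filter 6 earns its keep on homozygous sites, on deeply
covered sites, and on variants missing from the catalogue. The
simulator's default therefore lists all planted SNPs in the synthetic
dbSNP file — inbred mouse strains are densely catalogued — with the
listed fraction configurable for studying the uncatalogued case.

## Consequence annotation

For a CDS position the codon is rebuilt from the spliced CDS sequence
(reverse-complemented for minus-strand genes), the substitution applied
in transcript orientation, and both codons translated with the standard
genetic code: synonymous, missense, stop-gain or stop-lost. Exonic
non-CDS positions become 5'UTR/3'UTR by transcript orientation, exonic
positions of CDS-less genes non-coding-exon, and the rest intron. One
transcript per gene is modelled, with CDS spliced length required to be
a multiple of 3; splice-region and NMD subtleties of a full VEP are out
of scope. The annotator is verified exhaustively: all 64 codons × 3
positions × 3 substitutions against direct translation (576 cases),
which also confirms that G>A can create stop codons (TGG→TGA).

## Differential editing and enrichment

Editing levels of admitted events form an events × samples matrix with
explicit missingness (a sample that is not callable at a site
contributes `NA`, not 0). Group comparisons use the classic pooled-
variance Student's t-test, two-sided, significant at p < 0.05 with *no*
multiple-testing correction — matching the emulated study design; a
Benjamini–Hochberg mode (`fdr = TRUE`) and Welch's test (`welch =
TRUE`) are provided but off by default. With tiny group sizes a pooled
variance of exactly zero is possible; the convention is deterministic
and flagged: p = 1 for equal means, p = 0 otherwise.

PCA of the differential events runs on centered, unscaled levels with
event-wise mean imputation of missing entries (neither choice is
dictated by the design; centering without scaling keeps levels in their
natural units, and event-mean imputation is neutral on the sample
axis). Spearman correlation uses average ranks; a constant vector has
no defined rank correlation and yields `NA`.

The multi-event enrichment question — are genes with more than one
editing event likelier to carry a differential event? — is a 2×2 table
(gene differential or not × single- or multi-event) tested with a
two-sided Fisher's exact test implemented as the sum of hypergeometric
probabilities not exceeding the observed table's (with the conventional
1e-7 relative tie tolerance), plus the sample odds ratio
$\mathrm{OR} = ad/bc$ with a Woolf log-interval
$\exp(\ln \mathrm{OR} \pm z\sqrt{1/a + 1/b + 1/c + 1/d})$ and
Haldane–Anscombe correction (+0.5 per cell, flagged) when a cell is
zero. Woolf intervals reproduce the published one-decimal odds ratios
exactly but differ from the published interval bounds in the last
digit, so the interval method evidently differed; the bounds are
therefore not treated as a reproduction target. TPM is computed as
length-normalized rates scaled to sum to 10^6, and expression
comparisons run the same t machinery on log2(TPM + 1).

## The synthetic study

The generator emulates the study design rather than any particular
dataset: 3 control, 3 emotional-stress and 3 physical-stress discovery
samples plus an 8-sample reference cohort (configurable up to the
44-sample scale of the original reference set; admission logic is
size-agnostic). On a ~150 kb main contig it embeds 30 multi-exon genes
on both strands with CDS and UTRs, then plants, at mutually exclusive
exonic positions:

* 150 editing sites with levels cycling over 5–30%, equal in all
  groups, on the transcript strand of the host gene (genomic G>A on
  plus-strand genes, C>T on minus-strand genes, so both strand paths
  are exercised),
* 40 differential editing sites at 10% (control) vs 30% (ES and PS) —
  a Δ = 0.2 shift,
* 30 heterozygous (AAF 0.5 in every sample) and 15 homozygous (AAF
  1.0) germline SNPs, listed in the synthetic dbSNP VCF,
* 10 homopolymer-adjacent, 10 near-junction and 10 strand-biased
  artifact sites at 30% alternate fraction, 3 mitochondrial sites, and
  300 covered background positions.

Site depths are negative binomial (mean 50, size 10); alternate reads
are binomial at the sample's true level; every read independently
mutates to a uniform other base at rate 0.001; base qualities are
normal (mean 35, sd 4) clipped to [2, 40]; reads carry occasional
start/end marks so the parser sees realistic pileup grammar. Strand
bias is applied only to the dedicated strand-bias artifact class — if
every artifact were one-stranded, the false-positive filter would
remove them before filters 1 and 3 ever saw them. 30% of editing sites
are listed in the known-editing catalogue by default;
`edit_near_junction_frac` deliberately parks editing sites inside the
splice-filter zone to exercise rescue. Identical configuration and seed
give byte-identical output files.

What the generator does **not** emulate — and what passing tests
therefore cannot show: alignment-induced error correlation between
nearby sites, reference bias, mapping-quality structure, overlapping
genes (so strand-ambiguity handling is unit-tested, not
simulation-tested), multi-transcript genes, and editing hotspot
clustering. Recovery rates on this generator are a correctness check of
the pipeline's logic under its own noise model, not a sensitivity claim
for real tissue.

## Numerical choices and degenerate inputs

* Inclusive comparisons everywhere a threshold is named ("≥", "within
  6 nt" means ≤ 6).
* Band membership in filter 6 uses a 1e-9 absolute tolerance so that
  fractions like 20/50 compare as 0.40.
* Zero pooled variance: p ∈ {0, 1} with a `degenerate` flag, as above.
* Events with fewer than 2 non-missing levels in either group are
  reported untestable rather than silently dropped.
* A position overlapping several genes is attributed to the
  alphabetically first `gene_id` for per-gene counting (deterministic
  tie-break); all overlapping genes are retained in `gene_ids`.
* Empty inputs error early with named messages ("no samples", "no
  records", "empty gene counts").

## Problem sizes

The shipped configuration is chosen so that a full study — simulation,
17 samples of pileup calling, cascade, differential tests and scoring —
completes in about a minute: ~570 pileup records per sample, ~260
pooled candidates. The unit suite exercises the same code on reduced
configurations (10 genes, 3-sample cohort), and the Fisher
implementation is swept exhaustively against enumeration over all 2×2
tables with total N ≤ 60. These sizes are the package's own test
design; every component scales linearly in sites × samples.

## Known limitations

* Only the two pileup-computable false-positive checks of fpfilter are
  implemented; read-level criteria would need BAM input, which is out
  of scope by design.
* One transcript per gene; UTR classification assumes the single CDS.
* The germline AAF-band filter is underpowered at moderate depth (see
  above); germline removal leans on the variant catalogue.
* A-to-I or C-to-U modes are not claimed, although the machinery is
  general up to the admission edit-type argument.
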