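---
title: "Methods: models, parameters and design choices in coldacc"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, parameters and design choices in coldacc}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette is the package's own account of the statistics it
implements: the models and their assumptions, the parameters that matter,
what the synthetic-data generator does and does not emulate, and the
choices made where the design was genuinely open. The companion README
shows a worked example; the test suite and `scripts/acceptance.R` compute
every empirical claim made here.

## The study design being modelled

The pipeline targets a field design in which individual plants sampled
along an air-temperature gradient fall into a small number of temperature
groups (defaults `T2 = 2`, `T5 = 5`, `T10 = 10`, `T14 = 14`, `T18 = 18`
°C, 1–2 biological samples each). Genes responding to low temperature are
sought as those differentially expressed between a low group and **every**
warmer group; their functional profile is then tested against the
expressed-gene background; in parallel, transcriptome variants genotype
the same individuals for a genetic-structure analysis, and transcript
sequences are mined for SSR and InDel markers.

## Expression quantification and the saturation diagnostic

FPKM uses the plain definition with full transcript length
(`count · 10^9 / (length · total)`), not an effective-length or
expectation-maximisation estimate — quantification engines upstream can
supply counts however they like; this package only needs a consistent
length- and depth-normalised unit. A zero count is exactly zero FPKM, and
a sample with zero total is an error naming the sample.

The saturation diagnostic asks at what fraction of sequencing depth
expression estimates stabilise. The original procedure subsamples mapped
reads; without alignments, thinning each gene's count binomially at rate
`p/100` produces the identical gene-level distribution under uniform read
subsampling, so the desk-scale model is exact, not an approximation. At
each depth the reported value is the fraction of genes whose thinned FPKM
lies within a relative `tolerance` (default 0.10, i.e. 10%) of the
full-depth value, averaged over `n_reps` thinning replicates; at `p = 100`
the fraction is exactly 1 by construction. An FPKM floor
(`fpkm_threshold`, default off) restricts the gene set, mirroring the
observation that only genes above a few FPKM have stable estimates.
Low-count genes dominate the unsaturated part of the curve: a gene with a
single fragment is lost with probability 0.9 at 10% depth, and even when
its read survives its FPKM is an order of magnitude off, so it essentially
never counts as "within tolerance".

Per-group expression densities are histograms of log10 group-mean FPKM on
one fixed grid; zeros are excluded rather than offset, and the group mean
(not per-sample curves) is summarised because with 1–2 samples per group
the pooled mean is the stable quantity. Note one consequence verified in
the tests: planting extra expression in the low groups shifts the
responsive genes right but *depresses* the FPKM of every other gene
(totals grow), so the whole-transcriptome mean is not a monotone readout
of up-regulation — recovery checks therefore always condition on the truth
set.

qPCR quantification follows 2^−ΔΔCq: ΔCq = Cq(target) − Cq(reference)
within a sample, ΔΔCq subtracts the mean ΔCq of the calibrator-condition
samples for that gene. Missing reference or calibrator entries are errors,
not NAs, because silent gaps in a Cq table are almost always plate-layout
mistakes.

## Differential expression and the consistency filter

The DE engine is deliberately a *simplified* negative-binomial test — the
consistency logic downstream, not the engine, is the point, and
`test_pairwise(..., pvals = )` accepts per-gene p-values from any external
engine. The internal test:

* **Size factors** are median-of-ratios against the gene-wise
  geometric-mean reference, rescaled to geometric mean 1. Only factor
  *ratios* are identified (rescaling trades the absolute-scale property
  for a fixed overall scale; the ratio between two samples is unaffected).
  When no gene is positive in every sample, `pseudo_reference = TRUE`
  switches to a positive-count geometric mean rather than failing.
* **Dispersions** are method-of-moments on normalised counts, pooled
  within groups, with a `a0 + a1/mean` trend fitted across genes. With at
  least 3 replicates per group the working dispersion is the *maximum* of
  the gene-wise estimate and the trend — conservative sharing appropriate
  for small designs. With 1–2 replicates per group the gene-wise values
  are too noisy to use individually and the fitted trend itself is used;
  the gene-wise inputs to that fit still come from within-group spread
  whenever any group has 2 samples, so real between-group signal does not
  inflate the trend. Only with no replication at all is the spread taken
  blind across every sample.
* **The test** conditions on each gene's total: the two group sums are
  moment-matched to single NB variables and every split of the total no
  more probable than the observed one contributes to the two-sided
  p-value. All-zero genes get p = 1 and are excluded from the BH
  denominator (logged), since they carry no information and would only
  dilute the correction.
* **BH adjustment is per comparison**, because each low-vs-warm comparison
  is reported as its own DEG list before intersection.
* **Direction** is the sign of log2(low/high): "up at low temperature"
  means a positive fold change of the low group over the high group. Fold
  changes are moderated with a half-count offset so zeros do not produce
  infinities.

The consistency filter intersects the significant sets of the low group
against every warmer group and records the per-comparison directions; a
gene is flagged `consistent_direction` only when the sign agrees across
all comparisons. This is a set intersection, verified in the tests against
a naive gene-by-gene loop on randomised tables — exact equality, not
statistical agreement. The overlap report compares the two low groups'
consistent sets and counts how many members are also significant in the
direct low-vs-low comparison, with optional Venn pattern counts per
comparison.

## Resampling significance of functional groups

The observed number of DEGs in a functional group is referred to the
distribution of that count in 10000 random gene sets of the same size
drawn from the expressed-gene background. Design choices:

* **Without replacement** by default: a "random sample of genes" from a
  finite universe is a simple random sample, which makes the
  hypergeometric distribution the exact reference — the package ships
  `hypergeom_pvalue()` as an oracle and the tests require the empirical
  tail to sit within binomial Monte-Carlo error of it. A
  with-replacement mode exists behind `replace = TRUE` (binomial
  reference).
* **Two-sided** empirical p, `2·min(lower, upper)` capped at 1, because
  both over- and under-represented groups are scientifically meaningful
  (transporter activity enriched; general metabolism depleted). Add-one
  smoothing `(extreme + 1)/(n_iter + 1)` keeps p strictly positive.
* **Bonferroni** at `alpha / m` with `m` = the number of groups having at
  least one background gene: groups absent from the background cannot be
  tested and do not consume correction budget.
* **Direction** compares the observed count to the null mean.
* The functional grouping is taken as given (a fixed classification such
  as a GO slim); no DAG propagation is performed.
* "Expressed gene" for the background means FPKM > 0 in at least one
  sample (configurable); the stricter FPKM floor belongs to the
  saturation diagnostic, not the background definition.

## Genotyping and genetic structure

Variant records failing **either** QUAL < 30 or QD < 5 are removed — the
conventional strict reading of a joint quality filter; both thresholds are
arguments. Sites for genotyping must be biallelic with every sample
covered by ≥ 6 reads (the `min_samples_covered` argument relaxes this),
because a tree tip with no genotype is worse than a smaller site set.
IUPAC calls are heterozygous when both alleles reach a 0.2 fraction of the
site depth — the threshold is unstated in the field protocol this mirrors
and is exposed as `het_min_fraction`; at the default and ≥ 12× coverage
with 1% read error, simulated truth genotypes are recovered with < 1%
call error (measured in the acceptance checks). Zero-depth calls are
errors: they indicate the site filter was skipped.

Distances between genotype rows score each site by allele sharing:
identical allele pairs 0, one shared allele 0.5 (so `R` = A/G against
homozygous `A` scores ½), disjoint pairs 1; missing data is skipped
pairwise. This extends the stated base-vs-ambiguity rule to
ambiguity-vs-ambiguity pairs in the natural genotype-sharing way. The
tree is neighbour joining (via `ape::nj`) on those distances — a
deterministic desk-scale structure check standing in for full Bayesian
phylogenetics, which is out of scope; the NEXUS export preserves the
option of running such inference externally. Subsampling of sites (the
`n_subsample` argument mirrors analyses that draw, say, 90000 of ~10^5
eligible positions) is uniform without replacement under a seed.

Coding effects substitute the alternate base into its codon (reverse
complementing on minus-strand CDS) and compare translations under the
standard genetic code; CDS records whose length is not a multiple of 3
warn and lose their trailing partial codon. Per-gene non-synonymous /
synonymous ratios report `Inf` when synonymous = 0 with non-synonymous
> 0 and `NA` when both are 0 — keeping "no synonymous variation" distinct
from "no coding variation at all".

## SSR scanning

Perfect SSRs are maximal tandem runs of an irreducible unit of size 1–6
meeting the minimum repeat numbers 10, 6, 5, 5, 5, 5 (mono- through
hexanucleotide). Runs whose unit is itself a repetition of a smaller unit
are reported only at the smallest unit, the standard scanner behaviour.
Within a maximal periodic region the record is aligned to the leftmost
whole unit, and the span always satisfies
`end − start + 1 = unit_size × repeat_number`. Overlapping candidate runs
of different unit sizes are resolved longest-span-first, ties to the
smaller unit, then leftmost. Surviving SSRs separated by at most
`compound_max_gap` bases (default 100, the conventional interruption
distance; the protocols this mirrors only show that small gaps qualify)
merge into one compound record. `N` breaks runs. The test suite holds the
scanner to *exact* record-level equality with an independent
regular-expression oracle on a thousand planted 2-kb sequences, and
verifies canonicalisation (smallest string among rotations of the unit
and of its reverse complement) exhaustively over all 5460 units.

Marker filters: perfect SSRs with unit size ≥ 2 (mononucleotide runs and
compound SSRs genotype poorly in PCR), and for InDels, genes containing
exactly one biallelic InDel. Primer design is delegated: the marker table
carries flank coordinates for external tools.

## The synthetic-data generator

The generator produces every input the pipeline consumes, plus the truth
needed for recovery testing. What it emulates, and the defaults chosen as
the study conditions:

* **Counts**: negative binomial (dispersion 0.05) around gene-level
  expected values `q_g · m_g(group) · L_s`, with relative expression
  levels `q_g` gamma-distributed (shape 0.6, a realistic long tail),
  log-normal library sizes around 10^6 fragments (CV 0.3, forcing
  non-trivial normalisation), 5 temperature groups × 2 samples.
* **Response**: 10% of genes responsive, multiplied by `2^lfc` in groups
  below 10 °C, with |lfc| ~ Normal(2, 0.5) truncated at 0.25; 10% of
  responsive genes are down- rather than up-regulated (the direction
  logic must be exercised, even though up-regulation dominates in the
  cold), and half respond only in the coldest group, reproducing the
  asymmetry between the two low groups' candidate sets. Responsive genes
  are drawn from genes whose expected baseline is at least
  `responsive_min_count = 20` fragments per sample: a planted response on
  a gene sequenced at a couple of fragments is unobservable under any
  analysis and would only blur recovery metrics with noise floor effects.
* **Annotation**: 25 functional groups cycling through BP/CC/MF with base
  membership rates uniform on (0.02, 0.12); in planted groups the
  membership odds of responsive genes are multiplied by 10 (emulating a
  transporter-activity-like class concentrated among cold-responsive
  genes). Genes may carry zero groups and then count only in the
  background.
* **Pileups**: two populations × 4 samples; 30% of SNP sites fixed for
  different alleles between populations (an Fst-like divergence), the
  rest sharing a uniform (0.1, 0.9) allele frequency; Poisson coverage
  (mean 20), 1% per-read allele error; 5% of records are InDels and 5%
  carry failing QUAL/QD so the filters have work to do.
* **Transcripts**: 2-kb random backgrounds whose incidental tandem runs
  are capped *below* the detection thresholds (so background detections
  are impossible by construction), with planted SSRs (some close enough
  to merge into compounds), hard flank breaks so planted runs cannot
  extend, and planted open reading frames (ATG…stop, no internal stop, a
  fifth on the minus strand).

One top-level seed fans out to per-stage streams via a hash, so each
stage is independently reproducible and the manifest can record every
stage seed.

What the generator does **not** emulate: read-level error profiles and
mapping ambiguity (counts are drawn, not aligned), assembly artefacts and
isoform collapse, a real GO DAG topology (groups are independent given
responsiveness), linkage between variant sites, and batch or lane
effects. Passing recovery tests therefore demonstrate that the
implementations compute their statistics correctly under the stated
models — not that those models capture every failure mode of real
sequencing data.

## Numerical choices and problem sizes

Empirical p-values are add-one smoothed; exact-test p-values compare
probabilities with a `1 + 1e-7` slack factor so float rounding cannot
drop the observed outcome from its own tail. FPKM identities are asserted
to 1e-9 relative tolerance. NJ tie-breaking follows `ape`'s standard
implementation. The NEXUS writer strips the library's timestamp comment
so identical matrices give byte-identical files; pipeline manifests
record md5 checksums and contain no timestamps at all.

The shipped test and acceptance runs size their simulations for a
single-CPU desk run: 10000 genes × 10 samples for the default study,
10000 resampling iterations, 20 replicates for calibration loops,
500–600 variant sites × 8 samples for genotyping, 1000 × 2-kb sequences
for the scanner-oracle equivalence — each completing in seconds to a few
minutes while leaving Monte-Carlo error well inside the asserted bounds.

## Known limitations

The NB test is not a replacement for a mature DE engine on real data
(no outlier handling, no shrunken fold changes); it exists so the
consistency logic has a self-contained, calibrated driver. Saturation
thinning assumes uniform read subsampling within a sample. The
enrichment test treats groups independently (no term redundancy
reduction). Genotype distances ignore linkage and the NJ tree carries no
support values. The SSR scanner indexes perfect repeats only —
imperfect/approximate SSRs are out of scope.
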