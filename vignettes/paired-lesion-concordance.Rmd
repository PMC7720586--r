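---
title: "Comparing somatic mutation profiles of matched tumor lesions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparing somatic mutation profiles of matched tumor lesions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ctcmut)
library(data.table)
```

## The problem

Circulating tumor cells (CTCs) are shed from solid tumors into peripheral
blood and can be captured, cultured and exome-sequenced. If CTC genomes
faithfully mirrored the primary tumor, a blood draw could substitute for a
tissue biopsy in mutation follow-up. Whether they do is an empirical
question answered by sequencing matched pairs — one primary lesion and one
CTC sample per patient, each compared against the patient's normal — and
measuring, mutation by mutation, how much the two callsets share.

`ctcmut` implements that comparison. Its unit of analysis is the **paired
callset**: two sets of somatic calls keyed by exact genomic identity
(chrom, pos, ref, alt). Annotation (gene symbol, functional class,
trinucleotide context, read depths) travels with each record but never
enters the key, so a mutation observed in both lesions is *one* mutation
with two per-lesion measurements.

## Regional classification and concordance

For each case the key sets of the two lesions are partitioned into

* **common** — keys in both lesions (the intersection),
* **primary-specific** and **CTC-specific** — keys in exactly one lesion.

The concordance fraction is |common| divided by a denominator. Published
reports of "x% of mutations in a given case" rarely state whether the
denominator is the union or one lesion's total; we default to the
**union** (every mutation seen in the case) and always emit the per-lesion
variants alongside, so the three conventions can be compared directly.
Indels count toward abundance and concordance — they are exonic mutations
like any other — but are excluded from spectra and signatures, which are
defined only for single-base substitutions.

Cohort-level abundance correlation uses the Pearson product-moment
coefficient with the two-sided p from the t transform on n − 2 degrees of
freedom (a Spearman option exists). Pearson is the convention in which
such results are reported; the permutation null is used as an independent
oracle in the test suite rather than as the inferential method.

## The trunk-branch generative model

Matched primary/CTC callsets are essentially never deposited publicly, so
the package ships a first-class simulator rather than a toy fixture. It
encodes the standard clonal-evolution picture: a **trunk** of mutations
acquired before the lineages diverged (present in both lesions) and two
private **branches** acquired after.

Per case:

1. Trunk and branch sizes are drawn log-uniformly. Defaults — trunk
   10–150, branches 20–1400 — make per-lesion totals span roughly 30–1500
   with a median of a few hundred, the burden range typical of
   exome-sequenced bladder tumors. Log-uniform draws reproduce the heavy
   right skew of observed burdens.
2. Each SNV's trinucleotide context is drawn hierarchically: a signature
   from the category's mixture, then a 96-context cell from that
   signature. Defaults give the common trunk a flat/CpG background, weight
   the primary branch toward an APOBEC-like TpC signature and the CTC
   branch toward a C>T-enriched, C>G-free signature — the qualitative
   contrast the package is designed to detect. Half the SNVs are reported
   on the purine strand so that strand collapsing is genuinely exercised.
3. Indels are generated at a configurable rate (default 12% of mutations)
   with no context; they flow into abundance and concordance but never
   into spectra.
4. Each mutation has one true VAF ~ Beta(α, β) by category. Defaults:
   common (2, 8) (mean 0.2), lesion-specific (5, 5) (mean 0.5). The
   observed direction in paired-lesion studies is only qualitative —
   region-specific mutations run *higher* than shared ones — so the
   defaults state that direction with a clearly separated but overlapping
   pair of distributions; both are configurable.
5. Detection per lesion: depth ~ Poisson(100), alt reads ~ Binomial(depth,
   VAF), detected iff alt reads ≥ 3 and an independent Bernoulli
   sensitivity (default 1) succeeds. Trunk mutations undergo detection
   independently in each lesion, so a dropped trunk mutation *looks*
   lesion-specific downstream — the central confound the truth table makes
   measurable.

Because depth is Poisson and read support binomial, alt reads are
marginally Poisson(depth_mean × VAF); `detection_probability()` integrates
that tail over the Beta density, so the closed-form
`expected_concordance()` is exact, not approximate, for this generator.
With detection disabled, per-case concordance equals trunk/(trunk +
branches) exactly — an identity the tests assert.

**What a green test does and does not establish.** The generator draws
positions uniformly on one synthetic contig: no gene structure, exome
footprint, copy number, purity, contamination or sequencing error is
modeled, and the phylogeny is exactly one trunk and two branches. Green
simulator-based tests therefore establish that the *statistics* are
computed correctly under a known truth — not that real CTC data meet the
model's assumptions.

## Spectra and signature refitting

Substitutions are collapsed onto the pyrimidine strand (purine-reference
calls and their contexts reverse-complemented), giving 6 classes or 96
when flanked. Exposures against a catalog S (96 × k, columns summing to
one) solve

min ‖S e − v‖₂  subject to e ≥ 0

by a Lawson–Hanson active-set solver written for the package (no NNLS
implementation ships with base R or the declared dependencies). The
residual can never exceed the zero-exposure residual, noiseless mixtures
of linearly independent signatures are recovered to 1e-6, and the solver
is property-tested against closed-form least squares and grid search.
De novo signature extraction (NMF) is deliberately out of scope: the
package *refits* against a supplied catalog. A five-signature toy catalog
(APOBEC-like, CpG, flat, C>T-enriched, C>G-transversion) ships as a
fixture so tests need no download; real analyses should supply a COSMIC
catalog in the same TSV layout.

Exposure profiles are clustered with average linkage on Euclidean
distances between proportion-normalized profiles. Neither choice is
canonical; both are configurable arguments, and profiles are label-sorted
before clustering so ties resolve deterministically. Exposures fitted on
fewer than 50 SNVs are flagged low-confidence — refitting is an
ill-conditioned inverse problem on sparse spectra.

## Clonality and recurrence

VAF (alt/(alt+ref)) is a clonality proxy: unadjusted for purity, ploidy or
copy number, which is why the package compares *distributions between
categories within a lesion* rather than interpreting absolute values.
The comparison is a two-sided Mann–Whitney U with normal approximation and
tie correction, implemented directly so that degenerate all-tied groups
return p = 1 rather than NaN; no multiple-testing correction is applied
anywhere, and p-values are reported raw. A common mutation contributes its
primary-lesion VAF to the primary comparison and its CTC-lesion VAF to the
CTC comparison.

Gene recurrence counts *distinct cases* (never mutations) per gene per
regional category against a supplied gene list, with a ≥ 3-case default
threshold. Whether recurrence should be counted per category or across
categories is a reporting ambiguity; the table carries both (`n_cases`
within category, `n_total_cases` across).

## Cohort metadata

The packaged cohort table (20 bladder-cancer cases with stage, invasion
flags and immunophenotyped CTC counts from a 5 ml draw) is a transcription
of a published clinical table. Its summarizer groups sub-stages (T3a → T3)
and checks per row that the three immunophenotype counts sum to the
printed total. The transcription's stage tallies (3 Ta, 4 T1, 5 T2, 7 T3,
1 T4) disagree with the source's prose (4 T2, 2 T4) — a discrepancy in the
source itself; the summarizer reports what the rows contain and the tests
assert only the unambiguous counts.

## Numerical and design notes

* Mutation identity is exact; indels are not fuzzy-matched within a
  position window. Exact keying is reproducible and the simulator
  guarantees consistency; real cross-caller comparisons may need upstream
  normalization.
* Records failing VCF FILTER (anything but `PASS`/`.`) are dropped at load
  and counted in a report; chromosome labels are used verbatim with an
  opt-in `chr`-prefix strip/add.
* NS/S ratio defaults to missense/silent with a missense+nonsense
  numerator option; a category with zero silent mutations reports `NA`,
  never an error.
* All randomness descends from one seed through per-case streams
  (`seed`, case index) — cases are reproducible individually and bundles
  byte-identical across runs.
* Report tables are plain TSV with one commented header line carrying an
  MD5 manifest hash; MD5 (base R) is used because no SHA-256 is available
  in the dependency set and the hash is an integrity label, not a
  security boundary.

## Limitations

No purity/copy-number-aware clonality (CCF), no driver-enrichment
statistics, no de novo signatures, no multi-region (> 2 lesions)
generalization, no BAM/FASTQ handling — inputs are already-called,
annotated variants. The simulator's closed-form oracle covers the
detection model it implements; systematic artefacts (FFPE damage,
culture-induced mutations in CTC expansion, subclonal copy number) are
outside its stated world.
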