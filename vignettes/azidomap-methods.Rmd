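---
title: "Methods: mutant chemotyping and mutagen-aware candidate-gene mapping"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: mutant chemotyping and mutagen-aware candidate-gene mapping}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(azidomap)
```

# The problem

Saturation mutagenesis screens in plants identify biosynthetic genes by
phenotype: lines deficient in a metabolite class are collected, grouped by
their chemical profile ("chemotype"), and the disrupted gene is located
genetically. The avenacin pathway of oat roots is the motivating system: a
panel of sodium-azide mutants deficient in the antifungal saponins
avenacin A-1/A-2/B-1/B-2, binned by targeted LC/MS profiles into classes
corresponding to pathway steps, with the causal genes of unplaced classes
recovered by resequencing several independent mutant lines of the same
class and intersecting their variants.

This package implements that analysis chain as reusable, tested tabular
operations, together with a seeded generator that produces all inputs with
the statistical structure the analysis assumes. Everything downstream of
raw data acquisition is covered: variant filtering, interval mapping, codon
consequence calls, PCA chemotyping with marker ranking and segregation
tests, and MS/MS molecular networking with neutral-loss annotation. Read
alignment, SNV calling, peak integration and enzyme characterisation are
out of scope; the pipeline consumes VCF, CSV, and MGF.

# Models and procedures

## Mutagen-spectrum filtering

Sodium azide produces predominantly G:C→A:T transitions. On a
reference-stranded VCF this class is exactly the REF/ALT pairs G→A and
C→T; the complementary events on the other strand appear as the second
member of the pair, so the two-pair rule is strand-symmetric. The filter
is a pure subset operation (order preserved), which makes it idempotent
and monotone: tightening any policy field (transitions only, homozygosity,
minimum depth) can only shrink the retained set. Both properties are
asserted in the test suite. Depth and quality cutoffs applied upstream of
SNV calling are instrument- and pipeline-specific, so `min_depth` is left
unset by default.

## Sliding-window intersection mapping

Each mutant line in a class carries an independent induced allele of the
same gene, so the causal locus is a region where *every* line has at least
one filtered variant — variants need not share positions. The scan
enumerates windows of `window_size` (default 10 kb) at offsets
`s = 1, 1 + step, …` per chromosome and keeps windows where all required
lines are represented. The step defaults to 1 kb; a 10:1 window:step ratio
makes boundary effects negligible while keeping the enumeration cheap, and
both values are exposed. Qualifying windows are merged into maximal
disjoint intervals whose base union equals the union of the windows
(verified against a bitmap oracle), and genes become candidates when any
CDS segment overlaps an interval by at least one base. Internal
coordinates are 1-based inclusive (the VCF/GFF convention); BED export
converts to 0-based half-open.

`min_lines` defaults to `"all"`; an integer relaxation is available for
cohorts suspected to contain a mis-binned line. Statistical significance
of interval enrichment is deliberately not computed — this is intersection
mapping of independent induced alleles, not recombination mapping.

## Codon-level consequences

For a CDS substitution at 1-based position $p$, the residue index is
$\lfloor (p-1)/3 \rfloor + 1$ and the within-codon offset
$((p-1) \bmod 3) + 1$. Reference and alternate codons are translated with
the standard genetic code (nuclear plant genes; the code table is an
argument), and the change is classified synonymous / missense /
stop_gained / stop_lost. Premature stops are printed `W321stop` in the
short form, matching the field's tabular convention, while structured
fields carry `*`. Disruption of the ATG start codon is reported as a
missense of M1 with a `start_lost` flag and a warning — a deliberate
choice to keep the class set small; the flag preserves the information.
Genomic-to-CDS mapping accumulates segment lengths left-to-right on the
plus strand and right-to-left on the minus strand, returning the strand so
the caller can complement alleles. The whole caller is validated against a
whole-protein retranslation oracle over every substitution of random CDS
fixtures.

## PCA chemotyping

Peak tables are mean-centred and scaled to unit variance per metabolite
(autoscaling — the default of the chemometrics software this emulates)
before extracting two principal components; a `log10(x + 1)` transform is
available but off by default. Zero-variance columns are dropped with a
warning. Queries are assigned the chemotype of the nearest reference
centroid by Euclidean distance in score space. Mutant *lines* are the unit
of classification, so the pipeline averages replicate scores per line
before assignment; replicate-level assignment is available by passing the
raw scores. A query is `novel` when its distance to every centroid exceeds
`threshold_factor` (default 3) times the median within-reference
replicate-to-centroid distance — the screen's criterion for "clearly
distinct" profiles is qualitative, so the factor is a tunable with a
conservative default.

Marker *selection* ranks features by |Welch t| (ties by |log2 fold
change|): the selection statistic behind published "top marker peak" lists
is typically unstated, and the unequal-variance form is the safer ranking
statistic when class variances differ by construction. Hypothesis *tests*
against a control group use classical equal-variance Student's t, the test
the field's figure legends state. The Mendelian segregation check is a
Pearson chi-square goodness-of-fit (df = classes − 1) against the stated
ratio, delegated to `chisq.test`.

## Molecular networking

Peaks below a raw intensity of 25 are removed, intensities are square-root
transformed (standard practice to de-emphasise dominant fragments;
disable with `sqrt_transform = FALSE`) and L2-normalised so self-cosine is
1. The modified cosine treats a peak pair as matchable when fragment m/z
agree within 0.5 Da either directly or after shifting by the precursor
mass difference — linking fragments that retain versus lose a structural
modification. The score maximises the sum of intensity products over a
one-to-one matching; the implementation is greedy by descending product,
which matches common practice, and the suite asserts equality with an
exhaustive-matching oracle on all test instances of up to six peaks (the
greedy score can never exceed the optimum, so any divergence would surface
as an inequality there). Precursor deltas are computed directly on
[M−H]⁻ m/z since mass differences between like-charged deprotonated ions
equal neutral-fragment masses.

Edges require cosine ≥ 0.6 and ≥ 3 matched peaks; connected components
below `min_cluster_size = 2` are dropped. Within a component, nodes whose
precursors agree within 0.01 Da are treated as isomers and collapsed to
the highest-total-intensity representative, after which edges are
re-derived and the size filter re-applied. Edge |Δprecursor| values are
annotated against a library of diagnostic neutral losses — hexosyl
162.0528 (C6H10O5), N-methylanthraniloyl 133.0528 (C8H7NO), benzoyl
104.0262 (C7H4O), masses computed from the elemental formulas — within
0.1 Da, with the nominal integer loss also reported. Library entries
closer than twice the tolerance are rejected as ambiguous. Topological
edge pruning (top-K neighbour filtering as in some server pipelines) is
not implemented.

# The synthetic cohort generator

The generator exists so every stage is testable end to end at desk scale;
its defaults are the package's statement of the study conditions it
emulates.

* **Genome and genes**: 2 chromosomes × 5 Mb, 200 intron-less genes of
  1–5 kb placed in disjoint slots, each a valid CDS (ATG start, single
  terminal stop, codon-multiple length). Real genes have introns and UTRs;
  the GFF3 representation is segment-based so intron support can be added
  without changing the interval logic.
* **Variants**: per line, Poisson(50) background homozygous SNVs, 80% of
  them G:C→A:T, plus exactly one causal transition at a distinct CDS
  position of the shared causal gene. The 5 SNVs/Mb density sits at the
  dense end of reported azide screen loads in cereals and was chosen so
  that the expected number of genome-wide coincidence windows (10-kb
  regions where all four lines carry background variants by chance) is
  ~0.01–0.02: at that rate the scan returns a single interval in the large
  majority of cohorts, reproducing the qualitative single-interval
  behaviour of the real pipeline. Substantially denser surrogates (e.g.
  15 SNVs/Mb) make coincidence intervals the *expected* outcome on a 10-Mb
  toy genome — a scale artefact, since the real genome is two orders of
  magnitude larger at comparable per-line variant counts. Background
  density in the emulated screen is not published, so the value is a
  calibrated surrogate, exposed in the configuration.
* **Peak tables**: log-normal noise with CV 0.15 around class mean
  profiles, matching triplicate-scale variability. The profiles encode the
  pathway logic: end products m01–m04; monodeglucosyl intermediates
  m05/m06/m12; des-acyl intermediates m11/m25/m26; acyl-donor glucosides
  m19/m27/m28 (the pal2 profile uses the published reduction percentages:
  >65% for benzoyl and feruloyl glucosides, 17% for the anthranilate
  glucoside). Minor panel members co-vary with the class's overall pathway
  flux rather than being class-independent noise — real minor
  intermediates track flux, and a block of pure-noise autoscaled columns
  would both inflate within-class score scatter (weakening novelty
  detection) and, if zeroed only in scaffold-less mutants, hijack PC1 as a
  single-class axis. Within the qualitative constraints, relative
  amplitudes were set so the classes the screen distinguishes are
  separable in two components and the designed sad4 discriminants
  (5, 6, 11, 19, 27, 28) dominate the marker ranking: under
  CV-proportional noise the expected Welch t of any trace-to-elevated
  contrast saturates at √n/CV regardless of amplitude, so competing minor
  accumulations are kept at weak (≈3× trace) elevations.
* **Spectra**: a chain of [M−H]⁻ ions starting at m/z 959.4907 and
  stepping down by hexosyl, N-methylanthraniloyl and benzoyl losses.
  Derivatives share low-mass fragments unshifted and shift
  modification-bearing fragments by the loss, so consecutive members
  exceed the networking thresholds by construction; small intensity jitter
  and member-specific extra peaks keep cosines below 1.

What the generator does **not** emulate: read-level sequencing artefacts,
genotyping error, population structure, retention-time drift, peak
integration error, isotope patterns, and chimeric or noise MS/MS peaks.
Passing tests therefore demonstrate the correctness and calibration of the
analysis logic under the stated statistical structure, not robustness to
raw-data pathologies.

# Numerical and design choices

* Determinism: each generator reseeds from the configuration seed, so the
  same seed and configuration give byte-identical FASTA/GFF3/VCF/MGF/CSV
  outputs; the pipeline manifest hashes its outputs to make this
  checkable.
* Window qualification uses ≥1 variant per line per window; lines, not
  allele positions, are intersected (independent alleles sit at distinct
  positions).
* Nearest-centroid ties are broken by smallest distance, then
  lexicographic class id; PC signs are arbitrary, so tests compare scores
  up to per-component sign.
* Degenerate inputs: empty VCF bodies parse to empty tables; a line with
  zero filtered variants yields no qualifying windows (logged, not an
  error); zero-replicate peak tables keep their full header; group
  comparisons of two constant equal groups return t = 0, p = 1; spectra
  losing all peaks to the intensity floor are flagged and excluded from
  networking.
* The suite runs the cohort-scale checks (single-interval recovery,
  chemotype label recovery, marker identity) over fixed 20-seed grids at
  the generator defaults; problem sizes (10-Mb genomes, 3-replicate
  tables, 10-peak spectra) were chosen to keep the full suite in the
  one-to-two-minute range on a single core.

# Known limitations

* Novelty detection for a *single* query line against heterogeneous
  references is sensitive to the two-component projection: a chemotype
  whose distinguishing variance is not represented among the references
  can project close to an unrelated centroid. Line-level averaging and
  flux-informative minor metabolites mitigate this; classifying with more
  components or whitened distances would be the next step for real panels.
* The greedy modified-cosine matcher is not an optimal-assignment solver;
  it equals the exhaustive optimum on all tested small instances but can
  in principle fall below it on adversarial peak configurations.
* Consequence calls cover single-nucleotide substitutions in CDS only —
  no splice sites, indels, or deleteriousness scores.
* The interval mapper assumes selfed, homozygous mutant lines; residual
  heterozygosity is handled only by exclusion via the genotype filter.
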