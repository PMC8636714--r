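---
title: "Core SNP panels, fingerprints and core collections: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Core SNP panels, fingerprints and core collections: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gourdcore)
```

This vignette is the package's account of its statistical machinery: the
quantities it computes, the algorithms behind panel and core selection,
the synthetic data the tests run on, and the places where the design was
genuinely open and a choice had to be made.

## The data model

Everything operates on a genotype table: accessions × markers of
codominant biallelic calls `AA`, `AB`, `BB` or no-call, as produced by
KASP genotyping. Phase is never tracked (`BA` ≡ `AB`), positions are
1-based everywhere, and a no-call never contributes to allele counts.
Marker metadata (chromosome, position, allele pair, optional KASP primer
trio) travels with the table. The model targets inbred material:
heterozygous calls are expected to be rare and are treated as residual
signal, not as outcrossing structure.

## Per-locus statistics

With reference-allele frequency $p = (2n_{AA} + n_{AB}) / (2n_{called})$
and $q = 1 - p$:

* MAF $= \min(p, q)$; observed heterozygosity $H_o = n_{AB}/n_{called}$;
* gene diversity $H_e = 2pq$ (biallelic maximum 0.5);
* Botstein PIC $= 1 - (p^2 + q^2) - 2p^2q^2$ (biallelic maximum 0.375);
* effective alleles $N_e = 1/(p^2 + q^2)$.

Published per-marker "PIC" columns for KASP panels frequently reach
0.49–0.50, which exceeds the biallelic Botstein ceiling and exactly
matches $2pq$; such columns are gene diversity under another name. The
package therefore always computes **both** and uses $H_e$ wherever
printed per-marker tables are reproduced, keeping `pic_botstein` as the
textbook quantity. The shipped reference table regression confirms this:
$2 \cdot \mathrm{MAF} \cdot (1-\mathrm{MAF})$ at the printed MAFs
reproduces the printed informativeness column at printed precision at
all 22 markers. In the one-row core-collection report the convention is
reversed on the same evidence: there the published PIC (0.33) sits well
below the published HE (0.43), which is the Botstein-PIC signature, so
`evaluate_core()` reports mean Botstein PIC in its `PIC` column.

The published evaluation table also prints $N_e = 1$, which is impossible
for a polymorphic panel under $N_e = 1/\sum p^2$ (a locus at $p = 0.5$
alone gives 2). The package computes the standard per-locus formula and
averages it; the discrepancy is noted here rather than chased.

Shannon's index is computed in pooled form over all $2L$ (locus, allele)
frequencies, $SH = -\sum_{l,a} \frac{p_{la}}{L}\ln\frac{p_{la}}{L}$.
Per-locus averaging is bounded by $\ln 2 \approx 0.693$ and cannot reach
the values near 3 reported for 22-locus panels; the pooled form can
($\ln 44 \approx 3.78$ at all loci maximally diverse), which is why it is
the shipped definition.

## Genetic distances

An individual's within-locus allele-frequency vector is $(1,0)$, $(0.5,
0.5)$ or $(0,1)$ for the three genotypes. Over the $L'$ loci called in
both members of a pair (pairwise deletion; no imputation):

* modified Rogers: $\sqrt{\sum_{l,a}(x_{la}-y_{la})^2 / (2L')}$,
* Cavalli-Sforza–Edwards chord:
  $\sqrt{\sum_{l,a}(\sqrt{x_{la}}-\sqrt{y_{la}})^2 / (2L')}$,
* Nei standard: $-\ln\left(J_{xy}/\sqrt{J_x J_y}\right)$.

MR and CE live in $[0,1]$; both equal 1 for opposite homozygotes at a
single locus. Nei's distance is undefined when the pairwise identity sum
is zero (e.g. two opposite homozygotes with no shared allele anywhere) —
that is reported as an error naming the pair, not silently patched. A
pair with zero shared called loci is likewise an error. Exact symmetry
is enforced after the vectorised computation to cancel float noise, and
tests check the implementation against a naive per-pair, per-locus loop.

## Greedy discriminating panels

Panel selection is a set-cover-flavoured greedy: the universe is all
accession pairs, and a marker covers (resolves) a pair when both calls
are present and differ. Each step adds the marker with the largest
number of newly resolved pairs among markers whose chromosome quota
(default 2) is not exhausted; ties break by higher $H_e$, then by the
chromosome with fewest selected markers, then by marker id, making the
procedure fully deterministic. An exact minimal set cover is
deliberately **not** attempted — the exhaustive-search oracle in the test
suite shows the greedy panel matches the true optimum on 19/20 small
random instances and never undercuts it, which is the classic behaviour
of greedy set cover at this scale.

Two missing-data rules matter:

* a no-call never resolves a pair (authentication-safe: missingness must
  not fake a difference);
* in the saturation curve a no-call **is** a distinct symbol, so two
  accessions differing only in missingness occupy different fingerprint
  classes; such pairs are flagged separately (`missing_only_pairs`) as
  fragile distinctions.

`target_size` continues selection past full resolution (by the same
rule, now driven by the tie-breaks) to complete a balanced panel — e.g.
two markers on each of 11 chromosomes even when fewer markers already
resolve every pair. Both modes are exposed because a balanced panel of
fixed size and a minimal resolving panel are both legitimate readings of
common practice.

A $k$-marker codominant panel distinguishes at most $3^k$ multilocus
classes; `panel_capacity()` accumulates the product in exact integer
arithmetic ($3^{22} = 31{,}381{,}059{,}609$).

## Fingerprints, authentication, purity

Fingerprints are strings over `A`/`H`/`B`/`N` in panel order; the barcode
payload is the string itself (any Code128 renderer can consume it —
image generation is out of scope). Duplicate grouping links fingerprints
whose mismatch count (over positions called in both, by default) is at
most a tolerance, and takes connected components — single linkage, so a
chain of near-duplicates groups together.

Authentication compares sample and reference over loci called in both
and requires a completeness floor: with fewer than
$\lfloor 0.8 \cdot k \rfloor$ comparable loci the verdict is
*inconclusive* rather than a hollow *match*. The 0.8 floor and the
purity rule below are explicit stand-ins — published procedures state no
numeric acceptance rule — and are configurable.

Hybrid purity uses diagnostic loci where the parents are opposite
homozygotes, where a true F1 must be heterozygous. A seed is a true
hybrid when heterozygous at (by default) **all** of its called
diagnostic loci, selfed when it reproduces one parent's homozygote
throughout, off-type otherwise; purity is the true-hybrid fraction among
seeds with at least one called diagnostic locus.

## Core collections

The core selector treats 100% allele coverage as a **hard constraint**
and the mean entry-to-nearest-entry (E-NE) distance — a standard
core-sampling objective family — as the quantity to maximize. A weighted
multi-objective blend was deliberately avoided: a hard constraint plus a
single objective is testable (coverage is asserted post hoc, the
objective is compared against random cores), whereas blend weights are
not identifiable from published summaries.

Three phases: (1) greedy coverage — repeatedly add the accession covering
the most uncovered (locus, allele) pairs, ties to the candidate farther
on average from the current core, then to the smaller id; this either
attains full coverage or proves the target infeasible (the error reports
the greedy bound as the minimum feasible size); (2) farthest-point
completion to the target size; (3) first-improvement swap search over a
seeded shuffled remove/add neighbourhood, rejecting swaps that would
break coverage or evict forced accessions, capped at `max_swap_iters`
evaluated candidates (default 2000), best of `n_restarts` (default 2)
restarts kept. First-improvement over a shuffled neighbourhood was
chosen over steepest ascent: at $n \approx 206$ it reaches the same
plateau in far fewer objective evaluations, and the seeded shuffle keeps
it reproducible. Simulated annealing is unnecessary at this scale.
Forced inclusions model manual augmentation of an algorithmic core
(e.g. breeder-chosen additions) without pretending that step is
algorithmic.

## The synthetic panels

No raw genotypes are distributed with the collections this methodology
targets, so the package ships seeded simulators whose defaults **are**
the study conditions of the analyses: 206 inbred accessions in two
subpopulations at $F_{st} = 0.1$, 93 markers round-robin across 11
chromosomes, ancestral MAF floor 0.05, residual per-call heterozygosity
0.02 and missing rate 0.03. Subpopulation allele frequencies follow the
Balding–Nichols compound,
$p_k \sim \mathrm{Beta}\!\left(p_0\frac{1-F}{F},\ q_0\frac{1-F}{F}\right)$ —
the minimal standard model that yields a two-gene-pool structure without
claiming demographic realism. Accessions are fully inbred draws from
their subpopulation frequency, with heterozygosity and missingness
applied as independent per-call noise (the real generating process for
either is unknown; this is a labelled stand-in).

The MAGIC-style simulator builds 8 fully homozygous founders and 377
recombinant inbred lines as per-chromosome founder mosaics with
geometric block lengths (mean 5 markers). Marker-indexed mosaics were
chosen over genetic-map recombination because map positions are not
available; blocks reproduce the only downstream-relevant properties
(high homozygosity, intermediate MAF spectrum).

What the simulators do **not** model: linkage disequilibrium calibrated
to any genome, selection, geographic substructure beyond two pools, or
informative missingness. Passing tests therefore demonstrate algorithmic
correctness under the stated statistical structure, not performance on
any particular real collection.

One empirical gap is worth stating plainly: under $F_{st} = 0.1$ the
22-marker panel's k-means grouping agrees with the full 93-marker
panel's on about 69–94% of accessions across seeds (the full panel
recovers the true labels at 95–99%). Near-equality of the two marker
sets' clusterings — as reported for real collections with stronger
structure — is not attainable at this simulated differentiation, and the
test suite asserts the substantial-agreement level the conditions
support rather than pretending otherwise.

## Numerical and degenerate-input choices

* Strict filter thresholds (MAF > 0.05, missing < 0.05) with rates
  rounded to 12 decimals first, so exact boundary cases from integer
  counts (MAF exactly 0.05) classify as printed rather than by float
  representation.
* All-missing marker columns, empty cores, zero shared loci, zero
  diagnostic loci and identical parents are errors naming the offending
  marker/pair, never silent NA propagation.
* PCA imputes no-calls with the per-marker mean dosage (ordination
  only), and component signs are fixed by making each component's
  largest-magnitude loading positive, so results are deterministic
  across LAPACK builds and accession orderings.
* Negative neighbor-joining branch lengths are clamped to zero with the
  count recorded — the common convention.
* Every stochastic routine takes an explicit seed and restores the
  caller's RNG state; no function mutates global randomness.

## Problem sizes

The shipped tests and the acceptance script run at the study scale for
the end-to-end checks (five replicate 206 × 93 panels; core target 102;
panel target 22) and at deliberately small scales for oracle-backed
properties (exhaustive set-cover search at ≤ 12 markers and ≤ 10
accessions; brute-force distance loops at ≤ 8 accessions; parameter
recovery at 2,000 accessions × 200 markers). The full suite completes in
about half a minute on one CPU.

## Limitations

* Biallelic SNPs only; multiallelic records are rejected on input, and
  the statistics implement the biallelic specializations.
* The core optimizer is a local search: it guarantees feasibility and
  monotone improvement, not global optimality (tests bound its quality
  against random cores instead).
* The k-means-on-PCs grouping is a geometric stand-in for model-based
  admixture inference and yields hard labels, not ancestry fractions.
* Authentication and purity thresholds encode defensible defaults, not
  community standards; set them per application.
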