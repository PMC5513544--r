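---
title: "Mock-calibrated MOTU analysis of copepod metabarcoding data"
author: "motucal"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mock-calibrated MOTU analysis of copepod metabarcoding data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(motucal)
```

## The problem

Metabarcoding profiles a zooplankton community by amplifying and
sequencing a short marker — here the D2 expansion segment of the
nuclear 28S rRNA gene, roughly 300–420 bp in copepods — from a bulk
sample, clustering the reads into Molecular Operational Taxonomic
Units (MOTUs), and treating MOTUs as a proxy for species. Two
obstacles dominate in practice. First, sequencing error inflates
diversity: erroneous reads derived from abundant species form spurious
rare MOTUs, and the error regime differs by platform (per-base
substitutions on short-read instruments, homopolymer-length miscalls
on pyrosequencers). Second, the marker's species resolution is uneven:
some congeneric species differ by less than the clustering threshold
and collapse into one MOTU.

The remedy implemented here is calibration against a *mock community*:
an artificial sample of morphologically identified species (33 copepod
species in the study this package reproduces — 30 Calanoida, 1
Cyclopoida, 2 Poecilostomatoida) sequenced alongside the field
samples. Because the truth is known, the mock analysis yields (i) the
*expected MOTUs* — the partition obtained by clustering the reference
sequences themselves, so that near-identical species pairs are counted
correctly — and (ii) an *abundance threshold*: the read count of the
rarest MOTU that genuinely derives from a mock species. MOTUs below
that count are treated as noise. The threshold is expressed as a
per-sample fraction so it can be transferred across sequencing depths:
4 reads of 8,685 (0.046%) transfers to 11 reads of 23,556 (0.047%),
the smallest count whose fraction is at least the calibrated one.

## Pipeline

`runMotuPipeline()` chains the stages; each is exported separately.

1. **Quality control.** Paired-end data: Trimmomatic-style trimming
   (CROP 300, LEADING/TRAILING 20, a 30-base sliding window at mean
   quality 30 that truncates at the first failing window's start,
   MINLEN 100), then quality-aware ungapped merging (minimum 20 bp
   overlap, mismatch fraction at most 0.1, fewest mismatches wins with
   ties to the longest overlap; disagreements take the higher-quality
   base). Single-end pyrosequencing data instead pass a strict mean
   quality filter (> 27). Merged reads must then contain both primer
   sites within 3 mismatches each (both orientations are tried),
   primers are stripped, and the interior must have no ambiguous
   bases, lie within 300–420 bp, and contain no homopolymer run longer
   than 5 — read as the conventional maximum-run-length rule. Every
   rejected read carries exactly one reason (the first failing
   criterion), so reason counts always sum to input minus output.
2. **Taxonomic screening.** A word-presence naive-Bayes classifier
   (k = 8, the cited method's standard constants) trained on the
   reference set assigns each unique sequence a lineage with bootstrap
   confidence (100 draws of one eighth of the query's words);
   sequences are kept only if they match the target lineage prefix
   (Copepoda) with confidence strictly above 0.70. Both strands are
   scored and the better orientation used, making classification
   reverse-complement invariant. The screen runs again after
   denoising to catch contaminants surfacing late.
3. **Reference-anchored alignment.** Each query is globally aligned
   (match +1, mismatch −1, gap open −5, extend −1) to its nearest
   reference by shared 6-mers and threaded into the reference
   alignment's coordinate system; query-specific insertions are
   counted and projected out. Queries under 50% identity to every
   reference are set aside as unalignable. Primer stripping happens
   before distance computation in both platform modes; the original
   workflows differed in where they stripped primers, which does not
   change the interior sequence.
4. **Denoising.** Single-linkage preclustering absorbs each unique
   sequence into the cluster of the most abundant earlier sequence
   within 2 indel-excluded mismatches (about 0.5% of a 400 bp marker;
   the cited method's width is not stated, so the default is exposed
   as a parameter). Singleton preclusters are then removed — except in
   pyro mode, matching the earlier pyrosequencing workflow that kept
   them. A simplified two-parent chimera test flags a query when some
   single-breakpoint combination of two parents beats the best single
   parent's identity by at least 0.02, with both segments at least 80%
   identical and the combined model at least 97% identical to the
   query; the last condition keeps genuinely divergent rare species,
   which no two-parent model reconstructs, from being flagged. The
   test runs against the references and de novo against preclusters at
   least twice the query's abundance (so the most abundant sequence is
   exempt), and the union of flags is removed. This scorer is an
   approximation of the published reference/de-novo chimera detector,
   not a re-derivation; its thresholds are configurable.
5. **Rarefaction and clustering.** Counts are subsampled without
   replacement to the minimum per-sample depth, then clustered by the
   average-neighbor (mean over all cross-pairs of unique sequences)
   agglomerative algorithm at distance cutoffs 0.03 and 0.01
   (similarity 97% / 99%). Distances are *indel-excluded*: a column
   contributes only when both rows carry a base, and a pair sharing no
   columns is maximally distant (1.0) to keep clustering well defined.
   Merging proceeds while the minimum average linkage is at most the
   cutoff; ties break toward the smallest pair of cluster ids (a
   cluster's id is its smallest member's rank). Each MOTU's
   representative is its most abundant member sequence, ties resolved
   to the lexicographically smallest. Whether the published workflow
   clustered abundance-weighted duplicates as separate leaves is not
   stated; this implementation clusters unique sequences weighted by
   their counts and documents that choice.

## Calibration semantics

A MOTU is *selected* if its representative reaches the working
similarity threshold (97% or 99%) against at least one mock reference
— "reaches" read inclusively, so a representative exactly at 97.0% is
selected — using the same indel-excluded identity as clustering for
internal consistency (a raw-identity variant is available). The
abundance threshold is the minimum total count over selected MOTUs;
`countToFraction()` reports it against the subsampled depth (the
published per-sample percentages are consistent with the subsampled
totals, which is what this package uses), and `transferThreshold()`
moves it to another depth by taking the ceiling of the scaled
fraction. The threshold is applied per sample: a MOTU's count is
zeroed in samples where it falls below the threshold and the MOTU is
dropped only when zero everywhere, matching a threshold expressed as a
fraction "of total reads for a single sample". `detectionTable()`
then maps each selected MOTU to the expected MOTU containing its
best-match species, flagging undetected species and counting
overestimates.

## The synthetic data generator

Downstream validation needs data with known truth, so the generator is
first-class, tested code. Species sequences descend from one random
ancestor of the maximum interior length: founders receive random
substitutions (5–9% from the ancestor, resampled until all founder
pairs are at least 6% apart) and deletions bringing each interior to a
uniform draw from 340–420 bp, emulating the marker's length
variability. Because variation is deletion-only, the ancestor's
coordinates are a true multiple alignment, which downstream anchoring
uses. Near-identical species — the feature that makes expected MOTUs
interesting — are satellites mutated at exactly `round(radius × L)`
shared positions, disjoint within a group, so realised divergences
equal the request to within half a percentage point.
`mockCommunityReferences()` instantiates the 33-species structure with
its published near-identity groups (a Calanidae quartet within 3%, an
Undeuchaeta pair under 1%, Pareucalanus and Pleuromamma pairs between
1% and 3%); the sequences are synthetic stand-ins — only the
divergence structure and names follow the published community — and
the expected counts (27 MOTUs at 97%, 32 at 99%) are computed by the
package's own clustering, not asserted.

Reads are drawn from species with probability proportional to biomass
(the published analyses report a biomass–reads correlation, not a
mechanism; the exponent is configurable for sensitivity checks).
Substitutions are applied per base; pyro mode additionally perturbs
each homopolymer run of length L by ±1 with probability
`min(1, rate × L/4)` — scaled by run length and normalised so that the
rate parameter is the per-run probability for a 4-mer run. Chimeras
are bimeric only, matching the detector's two-parent model, joined at
a uniform breakpoint at least 40 bp from either end. Paired mode emits
overlapping 2 × 300 bp mates with linearly decaying, jittered
qualities. The published study states no quantitative platform error
rates, so the defaults (substitution 0.2–0.3%, per-run homopolymer
1%, chimera 1%) are module parameters chosen at realistic magnitudes,
not claims about the data. Real features deliberately not modelled:
learned quality profiles, PCR-cycle chimera kinetics, index hopping,
and multimeric chimeras — so passing tests demonstrate algorithmic
correctness under the stated error model, not performance on any
particular instrument run.

## Numerical and design choices

* All randomness flows from one integer seed through a seed-derivation
  helper; no function touches the caller's RNG state.
* Averaged distances are compared with a 1e-9 tolerance when finding
  the minimum linkage and applying the cutoff, so that
  algebraically-equal averages computed in different orders do not
  break the deterministic tie rule.
* The strict inequalities follow the sources: classifier confidence
  must exceed 0.70, mean pyrosequencing quality must exceed 27;
  selected-MOTU similarity is inclusive at the threshold.
* The classifier truncates lineages at the deepest rank whose
  confidence clears the threshold, and the target-group screen tests
  the prefix rank — the published workflow does not say whether its
  70% cutoff applied at a fixed or deepest rank.
* Degenerate inputs are defined, not special-cased: empty query sets
  produce empty aligned sets, a zero-variance profile is an explicit
  correlation error, depth larger than a sample's total is a
  subsampling error.
* Correlation vectors are outer-joined over the union of taxa with
  zeros for absences, because the compared methods detect different
  taxon sets; p-values are per-test with no multiplicity correction,
  as in the published tables. Correlations are computed per station,
  with a pooled value available and labelled as such.
* Wet-to-dry weight conversion factors are an editable table because
  the cited factor sources are not reprinted; the dominant-taxon table
  log-transforms percentages as `log(x + 1)` with the base
  configurable (natural log by default), the published figure's base
  being unstated.

## Problem sizes used in the shipped checks

The test-suite simulations are scaled to what the algorithms need
rather than to instrument output: the recovery checks use a 33-species
mock at 4,000–5,000 paired reads and a 10-species community at
600–800 reads; the platform contrast uses 50 replicate pairs of 300
single-end reads subsampled to 220. These sizes leave every stage's
behaviour (including singleton removal and thresholding) fully
exercised while keeping the whole suite quick to run.

## Limitations

The chimera scorer is deliberately simplified and will not match the
published detector call-for-call; the classifier's bootstrap
confidence is a frequency, not a calibrated probability; reference
anchoring projects out query insertions, so insertion-rich variation
between query and references is invisible to the distances (the
published distance treatment likewise excluded indels), and a chimera
whose two parents differ in indel structure can be distorted by
single-template anchoring before the scorer sees it — a limitation
shared by any template-bank alignment step; and the
synthetic generator's star-like divergence structure is simpler than
real copepod phylogeny, where rate variation among families changes
how much a fixed similarity threshold under- or over-splits.
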