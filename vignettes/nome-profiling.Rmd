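---
title: "Profiling nucleosome occupancy, CpG methylation and CpG density around promoters"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Profiling nucleosome occupancy, CpG methylation and CpG density around promoters}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The measurement and the quantities

NOME-seq treats chromatin with the M.CviPI methyltransferase, which methylates
GpC cytosines only where they are not wrapped in a nucleosome, then reads both
the endogenous CpG methylation and the exogenous GpC methylation from the same
bisulfite-converted reads. Three per-position quantities follow:

* **methylation level** at a site: methylated reads / total reads, undefined at
  zero coverage;
* **nucleosome occupancy** at a GpC site: 1 − GpC methylation level (the
  methyltransferase reaches only unprotected cytosines);
* **CpG density**: CpG sites per base pair within a window.

Site coordinates are 0-based and always refer to the cytosine of the
dinucleotide on the 5′→3′ strand — the first base of `CG` and the second base
of `GC`, because that is the base whose methylation the assay reports. `N`
bases break dinucleotides and are excluded from all frequency denominators;
soft-masked lowercase is treated as uppercase (no repeat masking is applied).

## Anchor-aligned averaging

Profiles are built over windows of ±1000 bp (2001 positions) around oriented
anchors — transcription start sites or control-region centers. The averaging
rules are:

* **masking**: at each relative position, occupancy and methylation means are
  taken over the windows that have a measurement there; windows without one
  are disregarded, and the number of contributing windows is recorded;
* **density denominator**: CpG density at a position is the number of windows
  with a CpG there divided by *all* windows in the set — it does not depend on
  sequencing coverage;
* **dedup**: when windows overlap, a genomic CpG is counted into the density
  of the first window containing it (windows taken in ascending genomic
  order) and excluded from later ones, so no site is double counted. The
  exclusion affects only the density numerator; occupancy and methylation are
  averaged in every window that measures them, and the window count
  denominator is unchanged;
* **smoothing**: each track is finally averaged in centered moving windows of
  30 bp (position *i* covers *i*−15…*i*+14 for the even default width). The
  window is truncated at the profile edges rather than padded, undefined
  positions are skipped, and count tracks are never smoothed.

Windows from minus-strand promoters are flipped so that positive relative
positions always mean downstream of the TSS; phased nucleosomes downstream of
active promoters only line up in an average when windows are oriented, which
is why orientation is the default (`orient = FALSE` disables it; control
regions are unstranded and always use the + orientation).

## Matched non-promoter control regions

To ask whether the promoter-like co-variation of density, methylation and
occupancy exists away from promoters, the matcher selects, for each promoter,
a non-promoter region with the *same number of CpG sites on each side of its
center*:

1. **clusters**: maximal runs of CpG sites with successive gaps < 20 bp;
   clusters closer than 50 bp are merged transitively;
2. **candidates**: a ±1000 bp region centered on the midpoint of each merged
   cluster (rounded down);
3. **exclusion zones**: merged ±1000 bp neighborhoods of every TSS; a control
   window may never intersect one;
4. **center shifting**: candidate centers are shifted — smallest |offset|
   first, negative offset first on ties, never further than ±1000 bp so the
   region stays attached to its cluster — until the counts of CpGs strictly
   left and strictly right of the center equal the promoter's counts (a CpG
   exactly at the center belongs to neither side, mirroring the TSS itself);
5. **assignment**: promoters are processed in ascending genomic order and
   take the first candidate (in genomic order) not already used; failure to
   match is reported, not an error.

Promoter side counts are taken in the promoter's orientation (left =
upstream). The search order and first-fit assignment are deterministic, so
runs are exactly reproducible.

By default accepted control regions may overlap each other (only promoter
neighborhoods are forbidden). For *profiling* the control set, this package
enforces the mutual-disjointness option (`disjoint = TRUE`): under the dedup
rule, overlapping control windows would surrender most of their CpGs to
earlier windows and the average density track would no longer describe a
typical control region. On a desk-scale simulated chromosome the candidate
pool is small enough that shifted windows frequently pile onto the same CpG
cluster, which makes disjointness necessary; on a genome-scale input with
millions of clusters the two settings give nearly identical profiles.

## Stratification and summaries

Strata follow the analysis conventions: the top and bottom expression strata
take the ⌊q·N⌋ highest / lowest promoters (default q = 0.05) with ties broken
by genomic order — a single deterministic rounding rule; threshold strata
("density below the all-promoter mean", "methylation below the all-control
mean") use strict `<`, with the threshold computed upstream from the full
set. Per-profile summary points use count-weighted means for the measured
tracks (consistent with how the per-position means are built) and unweighted
positional means for density.

## What the synthetic generator emulates

`simulate_nome()` produces a genome, promoter annotation and site table with
known ground truth:

* **composition**: an iid sequence at GC fraction 0.37 whose native CpG and
  GpC dinucleotides are first removed and then re-planted at controlled
  rates. CpGs are planted at 0.009/bp in the background — an order of
  magnitude below the ~0.034/bp that f(C)·f(G) would predict, i.e. a strongly
  CpG-under-represented genome — while GpCs are planted uniformly at
  0.034/bp, matching their C+G expectation. The GC fraction was chosen so
  that the observed/expected contrast itself (≈0.9% observed vs ≈3.4%
  expected) is realistic for a mammalian methylome. Planted dinucleotides
  keep a ≥3 bp spacing and flanking bases are adjusted so no unplanned site
  arises: the planted coordinates are *exactly* the sites of the emitted
  sequence, which is what makes exact parameter-recovery tests possible.
* **promoters**: TSSs on alternating slots along the chromosome (minimum
  spacing 5 kb), strands assigned ± with equal probability, expression drawn
  log-normally and mapped to a saturating weight e = x/(x + x₅₀) ∈ [0, 1].
* **CpG islands**: ±500 bp around each TSS, planted at a rate that grows with
  the expression weight (floor 0.15, maximum 0.08/bp), emulating the higher
  CpG density of highly expressed promoters. Uncoupled planting
  (`expr_density_coupling = FALSE`) is available for calibration tests.
* **decoy islands**: unannotated CpG islands between promoters, with density
  drawn from the same law but no TSS. Real genomes contain many CpG clusters
  away from annotated promoters — they are what the control matcher selects
  from — and a desk-scale chromosome needs them planted explicitly, otherwise
  the candidate pool would contain only sparse background clusters.
* **methylation**: a strictly decreasing logistic in local CpG density
  (window ±100 bp), m(ρ) = 0.85 − 0.75·logistic((ρ − 0.04)/0.008): saturated
  high methylation in sparse background, low methylation inside islands,
  midpoint at the typical mean promoter density of ≈0.04/bp.
* **occupancy**: background 0.75 everywhere except within ±1000 bp of a TSS,
  where O(x) = 0.75 − e·0.4·exp(−(x+150)²/(2·80²)) +
  e·0.12·cos(2πx/200)·e^(−x/600)·[x>0] — a nucleosome-decreased region
  centered 150 bp upstream whose depth scales with expression, followed by
  exponentially damped phased nucleosomes with a 200 bp repeat (a realistic
  human nucleosome repeat length that also sits exactly on a frequency bin of
  the 1000 bp downstream spectral window, so period recovery is
  unambiguous). Occupancy is clamped to [0, 1].
* **reads**: per site, total reads ~ Poisson(coverage 20), methylated reads ~
  Binomial(total, p) with p the true methylation at CpG sites and 1 − true
  occupancy at GpC sites.

The generator does **not** emulate read-level bisulfite conversion errors,
sequencing error, strand asymmetries, diploidy/SNPs, fragment-length effects,
or the long-range heterogeneity of real chromosomes (isochores, repeats,
imprinted regions). Passing recovery tests therefore demonstrates that the
pipeline's arithmetic — masking, orientation, dedup, matching, spectral
estimation — is correct under the assumed statistical structure, not that the
model captures all properties of real NOME-seq libraries.

## Numerical choices and degenerate inputs

* Zero-coverage sites are retained in site tables (their positions still count
  toward density) but yield missing levels; no minimum-coverage filter is
  applied by default (`min_total = 1` is exposed).
* An even smoothing window is centered left-heavy (i−15…i+14); width 1 is the
  identity.
* Cluster gaps use strict `<` thresholds: a gap of exactly 20 bp splits, a
  cluster distance of exactly 50 bp is not merged.
* Anchors or clusters whose window would leave the chromosome are flagged and
  skipped with a message, never silently dropped.
* Empty strata produce a warning and no profile; an empty window set is an
  error; a promoter with no possible control is reported as unmatched.
* The phasing period is estimated from the discrete power spectrum of the
  smoothed downstream occupancy (positions +1…+1000) after removing a 301 bp
  moving-average trend, searching periods of 50–500 bp.

## Problem sizes

The package's own test and acceptance runs use a 2 Mb chromosome with 200
promoters (300 for the parameter-recovery run) at coverage 20 — sizes chosen
so a full simulate–profile–match–stratify cycle completes in well under a
minute while every stratum still holds enough windows for stable profile
estimates. The NDR-recovery check profiles the top-25% expression stratum
rather than the 5% figure stratum: at these sample sizes a 5% stratum holds
too few windows for a stable minimum, and the expected depth ē·A_ndr adapts
to whichever stratum is profiled.

## Known limitations

* The matcher's first-fit assignment is order-dependent by design
  (deterministic), so inserting one promoter can change later assignments.
* Per-side counts for minus-strand promoters are taken in TSS orientation;
  chromosome-orientation counting would pair the same candidates differently.
* `dinucleotide_representation` defines "expected from C+G content" as
  f(C)·f(G) over non-N bases; other normalizations (e.g. per-strand or
  CpG-island-excluded) give different expected values.
* The bedGraph importer records totals as "unknown but positive", so
  coverage-weighted operations treat imported levels as single-read
  observations.
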