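---
title: "Estimating tumor methylated fraction from cfDNA methylation patterns"
author: "tmef authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating tumor methylated fraction from cfDNA methylation patterns}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tmef)
```

## Overview

`tmef` quantifies circulating tumor DNA (ctDNA) abundance in plasma
cell-free DNA (cfDNA) without a matched tumor biopsy, by counting
fragments that carry cancer-indicative methylation patterns. This
vignette is the package's own account of the method: the model, its
assumptions, the tunable parameters and their defaults, the numerical
choices, what the synthetic data generator does and does not emulate,
and the limitations that follow.

## Differentially methylated regions

A DMR here is a window of 5 contiguous CpG sites — contiguity on the
ordinal index of the assay's CpG map, not genomic distance — together
with a single binary methylation pattern over those sites (e.g.
`MMMMM`). A pattern qualifies during discovery when

1. it occurs in less than 0.1% of pooled non-cancer plasma fragments
   covering the window (`max_noise = 0.001`), with at least 100
   covering background fragments so the rate is meaningful
   (`min_background_n`), and
2. it occurs in at least 20% of covering fragments of at least one
   cancer tissue sample (`min_cancer_freq = 0.20`).

A fragment *covers* a window only when all five of its states there are
definite M/U calls; a no-call (`N`) at any window site removes the
fragment from both the numerator and the denominator. This keeps
no-call-rich fragments from biasing noise estimates downward.

Design choices where more than one reasonable rule exists:

* Only patterns actually observed in a cancer sample at a window are
  tested, not all 2^5; the background comparison is pattern-specific.
* When multiple patterns pass at a window, the one with the highest
  cancer frequency is kept (ties: lower noise, then lexicographic),
  so each window contributes a single candidate.
* Windows slide by one CpG ordinal; overlapping DMRs are allowed.
* Coordinates are 0-based half-open; CpG position is the forward-strand
  C. Reverse-strand calls are assumed collapsed upstream.

Per-sample calls are merged per cancer label; the empirical prevalence
of a DMR is the fraction of the label's samples in which it was called.
Heatmap structure uses Manhattan distance for samples and DMRs and
Spearman distance (1 − ρ, not 1 − |ρ|) for label mean profiles, with
average (UPGMA) linkage throughout — the distances are the method's,
the linkage is this package's choice. A constant profile makes the
Spearman correlation undefined; its distance is imputed as 1 and the
number of imputed pairs reported.

## Hematopoietic filtering and refinement

Solid-tumor DMR sets are filtered against the lymphoid, myeloid and
plasma-cell lineage sets: any solid DMR whose window shares at least
one CpG ordinal with a heme DMR window is removed, regardless of
pattern (a conservative definition — the published description does not
define "overlapping", and removing on any shared site errs on the side
of suppressing blood-derived interference). Heme labels themselves pass
through unchanged.

DMRs used for quantification are further refined to: noise rate below
`1e-4` (1/10,000), a strong pattern (`MMMMM` or `UUUUU`), autosomal
location, and a passing assay-performance flag. The assay flag is an
input (panel QC), not computed here, because "robust assay performance"
has no published operational definition. Both filters are idempotent.

## The observation model

The estimator's unit of data is a `(k, n)` pattern count per refined
DMR: `n` fragments cover the window, `k` match the pattern. Each DMR
`i` carries three annotations:

* `eps_i` — noise rate: the pattern's frequency among non-cancer
  plasma fragments;
* `rho_i` — prevalence: the probability that a tumor of this cancer
  label carries the DMR;
* `e_i` — pull-down efficiency: relative capture of the region in the
  targeted assay versus whole-genome sequencing, scaling how many
  tumor-derived fragments are observable.

A tumor either carries a DMR or it does not. Marginalizing carrier
status gives the per-locus likelihood

$$
L_i(\mathrm{TF}) \;=\; \rho_i\,\mathrm{Binom}\!\big(k_i;\, n_i,\,
  \min(1, \mathrm{TF}\cdot e_i + \epsilon_i)\big)
  \;+\; (1-\rho_i)\,\mathrm{Binom}\!\big(k_i;\, n_i,\, \epsilon_i\big),
$$

and loci are treated as independent, so the sample log-likelihood is
the sum of per-locus logs. **This likelihood is a reconstruction**: the
published description states the inputs (fragment counts, noise,
prevalence, efficiency, tumor fractions) and the outputs (posterior
median and 2.5/97.5 percentiles), but not the exact functional form,
which was in a non-public appendix. The mixture-binomial form uses
exactly the stated inputs and nothing else. The same applies to the
prevalence model below.

The posterior is computed on a fixed grid of 501 log-spaced TF values
from `1e-6` to `1` with a uniform prior over grid points. The floor of
`1e-6` leaves margin below the ~`1e-5` level where quantification
empirically tapers off. The point estimate is the posterior median; the
95% credible interval the 2.5/97.5 percentiles, both by linear
interpolation of the cumulative mass in log-TF.

TMeF is the posterior-median TF times a heterozygosity factor
`h = 0.5`: a typical cancer-derived small variant is heterozygous,
occupying one of two tumor alleles, so the allele fraction is about
half the fragment fraction. The factor's purpose is published; the
value 0.5 is this package's explicit default and is configurable.

### Prevalence estimation

Prevalence per DMR per label is estimated from training plasma samples
with known (externally estimated, here treated as fixed) tumor
fractions: each sample contributes
$L_j(\rho) = \rho\,\mathrm{Binom}(k_j; n_j, p_j) +
(1-\rho)\,\mathrm{Binom}(k_j; n_j, \epsilon)$ with
$p_j = \min(1, \mathrm{TF}_j e + \epsilon)$, a Beta(1, 1) prior, and a
uniform 1001-point grid on [0, 1]. TF uncertainty is not propagated —
the method conditions on the supplied estimates. Samples with
`TF = 0` contribute a constant in ρ, so they carry no information and
the posterior correctly reduces to the prior.

## Numerical choices

* All likelihood work is in log space; success probabilities are
  clamped to `[1e-12, 1 − 1e-12]`, and the binomial log-pmf is built
  from `lchoose` (log-gamma), so results are finite for depths up to
  `1e6`.
* The grid inner loop (grid × loci) is compiled (Rcpp): with the
  default 501 × ~5,000 problem a posterior costs tens of milliseconds,
  which is what makes the 3,000-estimate dilution experiment a
  minutes-scale computation.
* Grid quantiles use a midpoint convention (each point's mass centred
  at its value), so a uniform posterior on a symmetric grid has median
  exactly at the centre; quantiles interpolate linearly in log-TF.
* The posterior median is monotone in each `k_i` when `rho_i = 1`
  (monotone likelihood ratio). With `rho_i < 1` this is *not* a
  theorem of the model: one extra matching fragment at a
  low-prevalence, near-zero-noise locus is best explained by carriage
  at a *lower* TF (the single-fragment presence branch peaks at
  `TF ≈ 1/(n e)`), and can move the median down by a few percent. The
  tests assert monotonicity in the regime where the model guarantees
  it.
* Degenerate inputs: empty count tables error (no likelihood); a
  window with zero covering background fragments is flagged unusable
  rather than given rate 0; frequency-matrix cells with no coverage
  are 0 and flagged.

## The in-silico dilution laboratory

Accuracy at low ctDNA levels is measured by titration. Mixing operates
on per-DMR counts rather than raw reads — the statistically equivalent
desk-scale form of mixing sequencing data. For nominal fraction `r`,
the mixture keeps the background sample's depth profile, and each
retained fragment comes from the cancer sample with probability
proportional to `r` and the cancer sample's local coverage; fragments
inherit each source's empirical pattern rate (binomial thinning).
`r = 1` returns the undiluted cancer sample, which anchors the series:
the expected TMeF at each level is `r_corrected × neat TMeF`, with

$$
r_\mathrm{corrected} = \frac{r\,\mathrm{cov}_c}
  {r\,\mathrm{cov}_c + (1-r)\,\mathrm{cov}_b}
$$

correcting the nominal fraction for the depth difference between the
undiluted samples. This correction formula is likewise a
reconstruction of the published "post hoc corrected for the difference
in coverage". Using the neat *estimate* (not the generator truth) as
the anchor mirrors the published design, where no external truth
exists for a patient sample.

The linearity report interpolates each series' observed TMeF at fixed
expected levels (linear in log-log space), then reports the fraction
of series within 0.5- to 2-fold and the median |log2| fold deviation.
Cancer samples eligible for dilution have TF > 0.005, which the
cohort's TF range guarantees.

## Shedding scaling

`fit_scaling()` regresses log TMeF on log tumor size (maximum primary
dimension, cm): ordinary least squares for the slope, standard error
and two-sided p-value, confirmed by Huber M-estimation with default
tuning ("robust linear regression" is published; Huber is this
package's choice). Natural logs; the base cancels in the slope. A
slope near 2 is consistent with shedding proportional to tumor surface
area, near 3 with volume; a slope below 1 with `p >= 0.05` is reported
as no association. Samples below the non-cancer background cutoff are
excluded by default (their estimates sit on the unidentifiable
plateau; including them attenuates the slope).

## The synthetic cohort generator

Every input the pipeline needs can be generated: a CpG map laid out
over 22 autosomes, a panel of regions each carrying one planted
strong-pattern DMR with ground-truth `eps`, `rho`, `e`, fragment-level
tissue samples and a pooled non-cancer plasma background (with per-CpG
miscalls, no-calls, and partial-coverage fragments), and
targeted-methylation plasma counts at any tumor fraction. Carrier
status is drawn once per tumor and shared across everything generated
for it, including replicate dilutions.

Defaults describe the targeted-methylation regime the estimator is
meant for, chosen once as a realistic operating point: 5,000 panel
regions, negative-binomial depth with mean 1,000 fragments per region
(dispersion 10), noise rates Beta(0.5, 24.5) scaled to `[0, 1e-3]`
(mean `2e-5`), efficiencies Beta(8, 2) (mean 0.8), prevalences
Beta(0.8, 1.8) (wide, mean ~0.3), per-CpG miscall rate 0.003, and a
20% cancer-fragment frequency threshold cleared with margin
(`tissue_dmr_freq = 0.4`). With these settings the estimator's
quantification floor lands near a tumor fraction of `1e-5`. The
dilution experiment uses 100 cancer samples (TF log-uniform on
[0.005, 0.3]) × 3 backgrounds from a pool of 300 — sizes chosen to
give stable percentages at desk scale; `tmef_bench()` documents its
own smaller defaults for a fast end-to-end run.

What the generator does *not* emulate — and hence what passing tests
do not show about real data:

* annotation error: plasma counts are generated from the same
  `eps`, `rho`, `e` the estimator is given, so estimates of non-cancer
  samples sit at the grid's unidentifiable plateau (~`1e-6` TMeF) in a
  way real data, with imperfectly estimated annotations, will not;
  the real-data non-cancer background (and hence the 98th-percentile
  cutoff) is expected to be one to two orders of magnitude higher;
* fragment biology: no fragment-length or end-point structure, no
  sequence-context error profiles, no mapping artifacts;
* biological correlation between loci (co-methylation blocks,
  copy-number effects) — loci are independent given carrier status;
* cohort structure: one synthetic label at a time for count-level
  work; no stage, age or assay batch structure.

## Limitations

The likelihood, prior, grid, heterozygosity factor and coverage
correction are reconstructions where the published description is
incomplete; they are defensible and tested, but not guaranteed
identical to the original implementation. Tissue-free estimation
remains vulnerable to non-tumor sources of cancer-like methylation
(clonal hematopoiesis is mitigated, not eliminated, by heme
filtering). Multi-label estimation (when the cancer type is unknown)
and joint prevalence/TF inference are out of scope. Below a TF of
about `1e-5` the posterior median reflects the prior's plateau more
than the data, and estimates there should be treated as "below
quantification", not as measurements.
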