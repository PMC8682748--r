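---
title: "Auditing mitochondrial CpG methylation calls: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Auditing mitochondrial CpG methylation calls: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mtmethaudit)
```

## The problem

Whether the circular ~16.6 kb mitochondrial genome (mtDNA) carries CpG
methylation is easy to get wrong. Bisulfite sequencing selectively degrades
the cytosine-rich light (L) strand, producing strand-biased coverage and
spuriously elevated methylation where depth is low. Single-molecule
(nanopore) sequencing avoids the chemistry but introduces its own artifacts:
the signal-level caller emits a per-read log-likelihood ratio (LLR) per CpG
group, and that call is corrupted when the molecule's actual sequence differs
from the reference within the caller's k-mer window — which happens at every
haplogroup-defining variant — and contaminated by a residual background
signal that behaves like noise, not biology.

This package implements the audit machinery needed to decide whether an
apparent mtDNA methylation signal survives scrutiny: threshold calibration on
methylation controls, per-site quantification, artifact filtering (recurrent
false-positive blacklisting, variant-proximity masking, consensus-reference
recalling), background-noise modelling, per-strand bisulfite diagnostics, and
a synthetic-data generator that produces every input with known truth.

## Quantification model

Each call table row is one read x CpG-group observation carrying an LLR;
positive favours methylation. Calls are classified three ways at a threshold
`T` (default 5): methylated at `llr >= T`, unmethylated at `llr <= -T`,
uncalled in between. Uncalled rows are excluded from denominators, so with
symmetric class distributions the uncalled band does not bias frequencies.
Grouped calls (neighbouring CpGs joint-called; grouping gap 10 nt,
configurable) are fanned out to their member sites, each inheriting the group
LLR. Per site, `frequency = methylated / (methylated + unmethylated)`; the
genome summary is the unweighted mean of per-site frequencies (a
call-weighted mean is available but non-default, since the site-averaged
summary is the convention for genome-wide methylation percentages).

Threshold choice is a grid scan over labelled control calls: an ROC over
thresholds -20..20 (step 0.25, 161 points) and an accuracy scan over 0..10.
The reported tpr/fpr live on the requested grid, but the AUC is integrated
trapezoidally over the full empirical ROC (all distinct LLR values, with
(0,0) and (1,1) appended). On a coarse grid the trapezoid would cut corners;
on the empirical curve it equals the normalized Mann-Whitney U statistic with
half credit for ties, which the test suite verifies against `wilcox.test` as
an independent oracle. Ties at a threshold are predicted methylated
(`>=` semantics), matching the calling rule. Accuracy argmax ties go to the
smallest threshold.

## Artifact filters

Three mechanisms, deliberately partitioned by allele fraction:

* **Blacklist** — in an unmethylated control every nonzero frequency is
  artifact. Sites strictly above `mean + k * sd` (sample sd, n - 1; `k = 2`
  by default) of the negative-control frequencies are excluded everywhere.
  "Strictly above" means a site exactly at the cutoff survives.
* **Proximity mask** — a CpG within +/-5 nt (circular distance, boundary
  inclusive, measured from the called C — the caller's 11-mer is centred
  there) of a variant with allele fraction `< 0.9` is masked. Heteroplasmic
  variants cannot be fixed by changing the reference, because both alleles
  are present in the read population.
* **Consensus recalling** — variants at or above 0.9 are major alleles;
  substituting them into the reference (length preserved, CpG list
  rescanned) and recalling removes the false positives they induce.
  `consensus_recall_check()` verifies that reference-based positives near
  homoplasmic variants disappear under the consensus.

Filters only set flags; frequencies are never altered. Masked and
blacklisted sites are excluded from genome summaries by default.

## Background-noise model

Unmethylated data show apparent methylation that falls with read depth. The
relation is modelled as exponential decay,

  Y = m * exp(-t * x) + b,

with Y the genome-wide apparent methylation (%) and x the mean read depth.
Fitting is bounded Levenberg-Marquardt least squares (`minpack.lm::nlsLM`,
m, t, b >= 0), initialised at `m0 = max(y) - min(y)`, `t0 = 1 / median(x)`,
`b0 = min(y)`; several t0 magnitudes are tried before giving up. R-squared is
`1 - SS_res / SS_tot` (can be negative; reported as-is). A constant response,
or data on which optimisation cannot improve over a flat model, yields the
explicit degenerate fallback `m = t = 0`, `b = mean(y)` — never a silent
failure. A sample's verdict compares its observed mean (after filtering)
against the prediction at its own mean depth, strictly: `above_noise` only
when observed exceeds predicted.

One structural point discovered during design and worth stating plainly:
subsampling a *fixed* call table (read-thinning, `subsample_calls()`) cannot
produce a depth-dependent mean, because thinning preserves every per-call
rate — the expected per-site frequency is the same at every retained
fraction. Thinned unmethylated data therefore trace a near-flat curve whose
fitted asymptote `b` recovers the dataset's noise level, which is exactly
what the downstream verdict needs. The decay itself originates upstream of
the call table (in the signal/calling stage); the generator consequently
takes the decay law as a simulation input (below), and parameter recovery is
validated on points generated from the law via `simulate_noise_points()`.

## The synthetic-data generator

`generate_genome()` plants a requested density of CpG dinucleotides (default
0.03/base on 16,569 bases, mirroring the human mtDNA reference scale) on an
otherwise CpG-free random circle, so the site list is exact by construction
and verified by rescan. `plant_variants()` places homoplasmic
(fraction 1) and heteroplasmic variants, guaranteeing at least one of each
class within 5 nt of a CpG so the filters are exercised.
`simulate_reads()` models two library regimes: random fragmentation (uniform
starts) and single-cut linearisation (all reads start at the cut site, a
configurable fraction near-full-length, default 42%). Reads accumulate until
the aligned-base total meets the depth target, so realized mean depth tracks
the request to within one read regardless of genome size.

`simulate_methylation_calls()` draws per-read, per-group LLRs from two
Gaussians (defaults N(+8, 2) and N(-8, 2)). The paper-world caller's LLR
distribution is not published, so the class separation is a free parameter;
Gaussian classes keep every tail probability checkable in closed form
(e.g. a truly unmethylated call exceeds LLR 5 with probability
`pnorm(5, -8, 2, lower.tail = FALSE)` ~ 4e-11 at the defaults, so
defaults emulate well-separated controls). Artifact channels: per-site
recurrent false positives (`fp_positions`, `fp_rate`) and the global
depth-dependent background (`noise_m/t/b`, the decay law above, evaluated at
the dataset's realized mean depth). `simulate_wgbs_counts()` emulates
strand-asymmetric bisulfite coverage loss (Poisson depths, the L strand
attenuated by `loss_l`) with an optional constant count of spurious
methylated reads per site (`noise_reads`), which is what makes apparent
methylation depth-dependent in the bisulfite diagnostics.

What the generator does *not* emulate: sequence errors, alignment, raw
signal, within-read correlation of artifacts, and the mechanistic origin of
the background noise. Passing tests on synthetic data therefore demonstrate
the correctness of the audit logic under the stated statistical model — not
that real nanopore artifacts are Gaussian, nor that real background noise is
exactly exponential in depth.

## Coordinates and conventions

All in-memory and on-file positions are 1-based inclusive (the mitochondrial
community convention); circular arithmetic uses shortest-arc modular
distance. Read spans may extend past the genome end (`end > L` flags an
origin-spanning molecule). `rotate_coordinates()` translates between the
standard origin and a rotated reference (e.g. re-origined at base 14,259 to
keep enzyme-linearised molecules contiguous); it is an exact bijection with
`offset` defined as the new origin base minus one. Supplementary-alignment
rescue accepts a mitochondrial supplementary only on strand/orientation
agreement with the primary plus an origin junction within a 50 nt slack —
the slack is this package's choice (no published numeric rule exists);
small and symmetric, it tolerates clipped ends without accepting ligation
chimeras. Nuclear supplementaries discard the whole read as a possible NuMT;
a failing mitochondrial supplementary is rejected alone and the primary kept
(the conservative reading of the published exclusion rule).

## Problem sizes and determinism

Every stochastic routine takes an explicit seed and is byte-reproducible
under it. The test suite exercises mid-size genomes (2-8 kb, hundreds of
CpGs, depths 8-100x) for module tests, and the full 16,569-base scale with
at least 500 classified calls per site for the titration checks — the scale
at which binomial sampling error on a per-site frequency drops below one
percentage point. The end-to-end cohort audit runs three samples plus a
negative control at 60x with 13 planted recurrent false positives and
variant-adjacent artifacts, matching the structure (not the raw data) of the
study conditions.

## Known limitations

* The audit consumes caller output; nothing here re-analyses raw signal, so
  a systematic caller bias that equally affects positive and negative
  controls is invisible to it.
* The blacklist rule depends on the negative control sharing the sample's
  artifact-prone positions; a sample-specific artifact absent from the NC
  passes through (the variant-proximity mask exists precisely for the one
  class of such artifacts that is predictable).
* Achievable calibration accuracy (AUC, accuracy at a threshold) is a
  function of the simulated class separation; with the well-separated
  defaults both are ~1 and carry no information about real-world caller
  performance.
* Consensus building handles single-nucleotide substitutions only; indels
  would change coordinates and are out of scope.
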