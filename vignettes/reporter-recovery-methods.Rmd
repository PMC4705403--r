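---
title: "Quantifying transcription recovery from damaged reporter vectors: models and numerical choices"
author: "reporterQuant"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying transcription recovery from damaged reporter vectors}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(reporterQuant)
```

## The assay and what the package computes

A host-cell reactivation experiment transfects cells of a known DNA-repair
genotype (e.g. normal, XPA-/-, XPC-/-, CSB-/- fibroblasts) with a reporter
vector carrying a single site-specific bulky adduct — such as a polycyclic
aromatic hydrocarbon adduct on an adenine in the transcribed strand — in the
transcription unit of an inducible RFP gene, together with a constitutive
GFP gene that reports transfection efficiency. Recovery of RFP expression
over time after induction measures how well the cell removes the
transcription-blocking lesion (by global nucleotide excision repair,
transcription-coupled repair, or both). The readouts are RFP and GFP mRNA
by RT-qPCR, RFP protein by flow cytometry, and the sequence integrity of
the transcripts made by bypass of the lesion.

`reporterQuant` implements that quantitative chain end to end, plus seeded
generators that emulate each raw data type so every stage is testable
without instrument files.

## qPCR quantification

**Model.** Each baseline-subtracted amplification curve is fitted by
nonlinear least squares to the Richards sigmoid

$$F(x) = \frac{F_{max}}{\left(1 + e^{-(x - c)/b}\right)^{d}},$$

with plateau $F_{max}$, centre $c$ (cycles), slope scale $b$ (cycles) and
asymmetry $d$; $d = 1$ recovers the logistic. The family is flexible enough
to cover the asymmetric plateau approach of real probe chemistry while
keeping a closed form for everything downstream.

**Cy0.** The quantification cycle is the abscissa where the tangent at the
fitted curve's inflection point crosses zero fluorescence. For the Richards
model the inflection lies at $x = c + b\ln d$, giving

$$\mathrm{Cy0} = c + b \ln d - b\left(1 + \tfrac{1}{d}\right),$$

which reduces to $c - 2b$ for the logistic. Unlike a fixed-threshold Ct,
Cy0 does not shift when amplification efficiency varies between reactions,
which is why it pairs naturally with per-plate efficiency correction.
`computeCy0()` uses the closed form; the test suite checks it against a
brute-force numeric tangent construction to under 0.05 cycles across the
parameter family.

**Efficiency.** The per-reaction efficiency is $2^{m}$, where $m$ is the
least-squares slope of $\log_2 F$ against cycle over five cycles: the cycle
nearest Cy0, the two before and the two after. Per-plate amplicon
efficiencies ($Eff_{RFP}$, $Eff_{GFP}$) are the means of the per-reaction
values, in the spirit of window-of-linearity methods that use one average
efficiency per plate. Expression is then the relative quantity

$$\text{expression} = Eff^{-\mathrm{Cy0}},$$

so with perfect doubling one fewer Cy0 cycle means twice the input. The
slope-to-efficiency map is taken on the antilog scale ($Eff = 2^{m}$, fold
per cycle) because $Eff^{-\mathrm{Cy0}}$ needs a fold-per-cycle base;
duplicate reactions are quantified separately and averaged at the
expression-value level, one RFP and one GFP value per measurement.

**Bias of the window estimator.** The 5-cycle window straddles a region
where the curve is already bending away from pure exponential growth, so
the estimator carries a negative bias that grows with the curvature at
Cy0. The size of the bias depends strongly on the Richards asymmetry: for
logistic curves ($d = 1$) the Cy0 point sits only about $2b$ cycles below
the inflection and the bias reaches $\approx -0.17$ at a true efficiency of
2, while for strongly asymmetric curves ($d \approx 0.25$, inflection at
about 65% of plateau, i.e. a long log-linear exponential stretch below the
bend) the per-plate mean bias is $\approx -0.02$ to $-0.04$. Baseline-
subtracted hydrolysis-probe traces show exactly that long log-linear
stretch, which is the premise under which a window-of-linearity efficiency
is meaningful at all; the synthetic-plate generator therefore defaults to
$d = 0.25$. The residual bias is a property of the method, not of the
implementation, and it partially cancels in the RFP/GFP ratios because both
amplicons are corrected with efficiencies estimated the same way.

**Numerical choices.** Multi-start Levenberg-Marquardt (landmark-based
centre and plateau starts crossed with $b \in \{0.5, 1.5, 3\}$,
$d \in \{0.25, 1\}$), a fixed-$d = 1$ logistic fallback when the full fit
fails, and a convergence tolerance of $10^{-10}$ on the residual criterion.
A curve whose dynamic range does not rise at least 8-fold above its
early-cycle noise is declared non-amplifying; failed wells are reported
with `converged = FALSE` and excluded from plate means with a logged
reason, never imputed. Fits whose parameters are unphysical (non-positive
shape parameters, centre far outside the run, plateau extrapolated to more
than 5x the observed maximum) are treated as failures rather than trusted.

## Ratio normalization by pairwise combinations

GFP expression across independent transfections is well described by a
gamma distribution with shape below 2 (the generator's default shape is
1.5). The inverse of such a variable is heavy-tailed — its variance does
not even exist for shape below 2 — so simple per-measurement RFP/GFP ratios
at $n$ of 3–6 have an erratic, multimodal error distribution. Summing
pairs before dividing doubles the gamma shape of the denominator:

$$r_{ij} = \frac{R_i + R_j}{G_i + G_j}, \qquad 1 \le i < j \le n,$$

giving $\binom{n}{2}$ combination ratios whose denominators have shape
$2k > 2$ and hence a finite-variance inverse. These combination ratios are
the unit of all downstream statistics: group means and variances are
computed over them. The package treats them as exchangeable summaries of a
condition, not as independent observations — which is one reason the
downstream test is interpreted as an effect-size criterion (below) rather
than a sampling-theory test.

**Scaling.** Within each cell line, 100% is defined as the maximum over
time points of the control vector's per-time mean combination ratio; every
condition's ratios are divided by that reference and multiplied by 100.
This is the only reading of "the average maximum value attained by the
undamaged control" that forces the control series to peak at exactly 100%,
and it removes absolute expression differences between cell types so their
time courses can be compared on one scale. The standard error for a
time point with a single ratio is reported as missing, not zero.

## SMCV contrasts

For groups $i = 1, \dots, t$ with means $\bar Y_i$, variances $s_i$ and a
zero-sum contrast $c_1, \dots, c_t$, the method-of-moments estimate of the
standardized mean of the contrast variable is

$$\hat\lambda = \frac{\sum_i c_i \bar Y_i}{\sqrt{\sum_i c_i^2 s_i}},$$

with $s_i$ entering as a variance. A switch (`s_reading = "sd"`) provides
the alternative reading $\sqrt{\sum c_i^2 s_i^2}$ for sensitivity
analysis. Under a normal model of the contrast variable the
$c^+$-probability (the probability that the contrast variable is positive)
is $\Phi(\hat\lambda)$, and the one-sided p-value for the null hypothesis
that the SMCV is at most zero is $p = 1 - c^+ = \Phi(-\hat\lambda)$;
$p < 0.050$ (strictly) is flagged significant. No multiple-testing
correction is applied.

Because the denominator uses the group variances themselves — not the
variances of the group means — $\hat\lambda$ is an effect size: it
estimates a property of the populations that does not grow with $n$.
Consequently the derived test is conservative in sampling terms: under a
true null with $n = 6$ per group, $\hat\lambda$ concentrates at scale
$\sim 1/\sqrt{n}$ and the one-sided rejection rate at the 0.05 threshold
is of order $10^{-3}$, far below nominal. The test suite asserts this
conservativeness; significance calls from this statistic say "the effect
is large relative to the group spread", not merely "detectable at this
sample size". Contrasts in the shipped pipeline are evaluated per time
point on the control-scaled combination ratios, which supports the three
comparisons the assay design calls for: lesion vs control within a cell
line, lesion A vs lesion B within a cell line, and the same lesion across
cell lines after within-cell-type scaling.

## Flow cytometry

Observed detector intensities are modelled as true fluorophore signals
times a spillover matrix (unit diagonal, non-negative off-diagonal);
compensation right-multiplies by the matrix inverse. Negative compensated
values are preserved rather than clipped — clipping would bias low signals
upward — and the subsequent $\log_e(\mathrm{RFP}/\mathrm{GFP})$ stage
excludes (and counts) events with non-positive signals. Hand-drawn
autofluorescence gates are replaced by a reproducible rule: events pass
when their GFP exceeds the 0.99 quantile of an optional unstained-control
table (`autofluorescenceGate()`); with no unstained control supplied, all
events pass to the mixture stage.

The induced (doxycycline-responsive) population is isolated by a
two-component normal mixture on the log ratio, fitted by EM with k-means
initialization plus 10 seeded random restarts, a log-likelihood tolerance
of $10^{-8}$, and a monotonicity assertion on every EM trajectory. The
induced component is deterministically the one with the larger mean, so
component relabelling can never change which events are called induced.
Three degeneracy signals guard against forcing a split on unimodal data: a
component weight below 0.01, mean separation below 0.1 pooled SD, and a
BIC comparison against a single normal. The BIC check matters because EM
happily splits one normal into two overlapping halves with weights near
0.5 and separation near 1 SD — a configuration the first two rules cannot
see; with the check, a fully induced population is flagged degenerate and
every event is assigned to the single (induced) component.

Condition summaries back-transform each population's mean induced
log-ratio on the geometric scale (`exp` of the mean; an arithmetic
alternative is available by flag), express it as percent of the control
condition's mean, and compare conditions by one-way ANOVA with zero-sum
contrasts on the condition means (t statistics on the residual mean
square). Conditions with fewer than two independent populations are
excluded with a warning.

## Transcription-error calling

Amplicon reads are aligned to the expected transcript with a banded global
aligner (match +1, mismatch -1, gap open -2 for the first gapped position,
-1 per additional position, band ±5 around the diagonal; DNA input is
converted to RNA on ingestion). The aligned column at the lesion-opposite
position — the transcript base templated by the adducted base, a U for an
adenine adduct — determines the class: match, misincorporation (with the
observed base), deletion, or insertion for a read base inserted adjacent
to the lesion column on either side (gap placement next to the lesion is
otherwise ambiguous). Off-site substitutions count toward an edit budget
(more than 3 total differences makes a read unclassifiable) but are not
reported as lesion events, since abnormal transcripts are read out only in
the adduct's vicinity. The banded implementation is checked against an
independent full dynamic-programming aligner on every possible single-edit
read.

Frequencies are counts over classified reads, and a class is reported only
when its frequency is at least 10 times the background misincorporation
rate of 0.1% per base — an inclusive boundary, so a frequency of exactly
0.010 is retained. Raising the fold threshold can only remove classes,
never add them.

## What the generators emulate — and what they do not

* `simulateQpcrPlate()`: Richards curves positioned so the exponential
  phase extrapolates to the well's true initial quantity, per-cycle fold
  equal to the configured efficiency (which pins $b = d/\ln Eff$, so the
  configuration takes $F_{max}$ and $d$ and derives $b$), additive
  Gaussian fluorescence noise (default SD 5 on $F_{max} = 1000$, i.e.
  0.5%), 45 cycles. Not emulated: baseline drift (inputs are
  baseline-subtracted by contract), pipetting covariance between duplicate
  wells, inhibitor-dependent efficiency differences between wells.
* `simulateExpressionExperiment()`: GFP ~ Gamma(shape 1.5, scale 1e-4),
  RFP = GFP x condition effect x log-normal noise with 15% CV, at least 3
  replicates per condition. Effects enter only through the
  condition-effect surface; no repair kinetics are modelled.
* `simulateFlowEvents()`: a two-component log-ratio mixture over a
  log-normal GFP channel, linear spillover, log-normal APC
  autofluorescence. Not emulated: detector saturation, doublets,
  forward/side scatter.
* `simulateAmpliconReads()`: independent background substitutions at 0.1%
  per base at every position except the lesion-opposite one, plus at most
  one lesion-site event per read drawn from a configurable profile.
  Insertions are placed immediately 3' of the lesion-opposite base. Not
  emulated: sequencing quality gradients, indels outside the lesion site,
  PCR chimeras.

Passing tests on these generators therefore demonstrate the correctness of
the estimators and their stated statistical properties under the assay's
assumed error structure; they do not certify performance under instrument
pathologies the generators deliberately omit.

## Problem sizes and determinism

The shipped property checks run at the scale the statistics are quoted at:
200 random parameter sets for the Cy0 oracle sweep; plates of 16 wells
spanning four doublings for efficiency recovery at true efficiencies 1.8,
1.9 and 2.0; 1,000 simulated experiments of $n = 6$ for the
combination-ratio variance comparison; 2,000 null replicates for the SMCV
rejection-rate measurement; 10,000 events per induced fraction in
{0.3, 0.5, 0.7, 0.9} for mixture recovery; every possible single-edit read
for the aligner cross-check; and 50 full-pipeline runs at a 90%
suppression for the power measurement. Every source of randomness flows
from explicit seeds carried in the config objects — never from global
state — so identical configs reproduce identical outputs bit for bit.

## Known limitations

* The window-of-linearity efficiency inherits a small negative bias from
  curve bending (quantified above); it is shared by both amplicons and
  largely cancels in ratios, but absolute efficiencies near a true value
  of 2 are systematically low by up to ~0.04.
* The SMCV-based p-value is an effect-size criterion, conservative in the
  sampling sense; it should not be read as a calibrated type-I error rate.
* Combination ratios within a condition share measurements and are
  therefore correlated; their mean is unbiased but their nominal count
  $\binom{n}{2}$ overstates the effective information.
* The mixture gate assumes two normal components on the log-ratio scale;
  strongly skewed induced populations would need a different family.
* The aligner's ±5 band assumes reads within ±5 nt of the reference
  length, which holds for amplicon sequencing of a fixed locus but not for
  fragmented input.
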