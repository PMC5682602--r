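---
title: "Methods: summary metrics and normative scoring of DMN connectivity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: summary metrics and normative scoring of DMN connectivity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dmnmetrics)
```

## Overview

This package turns a parcel-averaged BOLD time series into a single-subject
summary of default mode network (DMN) function and scores it against
built-in normative constants. The pipeline is: frame censoring from motion
and signal-intensity spikes, nuisance residualization, band-pass filtering,
data-sufficiency checks, a Fisher-Z magnitude connectivity matrix, network
and sub-network averages (plus weighted-graph alternatives), reliability
estimation, and normative z-scoring. This vignette documents the model at
each stage, the parameters that matter, the numerical choices, and what the
synthetic-data generator does and does not establish.

## Frame censoring

Head motion is summarized per frame as framewise displacement (FD): the sum
of absolute values of the differentiated six rigid-body realignment
parameters, rotations converted to millimetres as arc length on a 50 mm
sphere (`rotationRadiusMm`, the conventional radius for this summary —
roughly the distance from the centre of the head to the cortex). Frames
with FD > 0.3 mm are motion spikes. Signal spikes are frames whose mean
squared intensity difference from the previous frame, divided by the grand
mean signal, exceeds 10. Around every spike at frame *t* a temporal mask of
four frames {*t*−1, *t*, *t*+1, *t*+2} is censored (`expand = "four"`),
reflecting that motion corrupts data shortly before and for several seconds
after the event; a two-frame variant {*t*, *t*+1} is available because both
conventions circulate. Expansions clip at series boundaries and — when
segment labels are supplied — at segment boundaries, since spikes in one
acquisition run say nothing about frames of the next. Overlapping
expansions merge, and the mask is a pure function of the spike vectors, so
censoring is idempotent.

A subject is usable when at least 300 un-censored frames remain overall;
the quintile-based internal-consistency analysis further requires at least
100 un-censored frames in each of the five contiguous segments. The five
"quintiles" are the five equal task blocks of the session (120 frames each
in the reference design of 600 frames at TR 2.5 s), not percentile cuts of
the un-censored frames — each quintile is then one task period, which is
what makes the internal-consistency interpretation meaningful.

## Residualization and filtering

Nuisance effects are removed per region by ordinary least squares. The
design always contains an intercept; the caller adds confounds (motion
parameters, tissue signals, task regressors) as columns, and censored
frames enter as one indicator column each, which forces their residuals to
exactly zero and removes their influence on the fit — the regression
analogue of frame deletion. Collinear columns are dropped with a warning
rather than erroring, since indicator columns plus run-constant confounds
are routinely rank deficient. Residualization is a projection (applying it
twice changes nothing), which the tests verify.

Band-pass filtering retains 0.009–0.08 Hz, the conventional resting-state
band: slow scanner drift sits below it, respiratory and cardiac aliases
mostly above. The filter is the zero-phase ideal (rectangular DFT) filter:
coefficients outside the band, including DC, are zeroed. The filter family
is a declared choice — an ideal filter is what the common resting-state
toolboxes apply, it is deterministic, linear (tested), and exact for
on-bin sinusoids. Because a DFT filter is undefined on a gapped series,
censored frames are linearly interpolated before filtering and remain
censored afterwards; their values never enter any correlation. The ordering
residualize → interpolate → filter → re-mask is likewise declared: filtering
after residualization avoids re-introducing nuisance energy, and the
interpolation only serves filter continuity.

## Connectivity and summary metrics

Pearson correlations are computed between every unordered pair of regions
over the un-censored frames, with one shared (listwise) mask for all
regions, so a single frame count applies to the whole matrix and the
correlation matrix is positive semi-definite before transformation. Each
entry is the magnitude of the Fisher-Z transform, z = ½ ln((1+r)/(1−r)):
the variance-stabilizing scale on which the norms are expressed.
Correlations of |r| ≥ 1 (possible only for degenerate, duplicated regions)
error by default; an opt-in clip at |r| = 0.999999 is provided and warns.

**Average connectivity** over a within-set specification is the mean of the
n(n−1)/2 unordered pairs (equivalently the upper triangle — averaging the
full symmetric matrix would give the same number); over a between-set
specification it is the mean of all |A| × |B| cross pairs. The three
canonical node sets come from the parcellation metadata: all `Default`
regions; the anterior set (frontal-lobe `Default` regions with
|centroid x| ≤ 15 mm, the boundary inclusive — inclusivity is a declared
decision since either reading is defensible and reproducibility demands
one); and the posterior-cingulate set, taken from the anatomy column of the
metadata table rather than recomputed from an atlas. For the reference
333-region scheme these sets have 41, 14 and 2 regions, and the loader
validates those counts when (and only when) the table declares itself as
that scheme.

**Graph metrics** operate on the proportionally thresholded graph: the
⌈retain · m⌉ strongest of the m possible edges are kept (retain ∈
{0.70, 0.75, 0.80} conventionally; 70% is typically the smallest fraction
leaving no isolated node). Rounding is by ceiling and ties at the cut
weight break by lexicographic node-pair order, making the graph
deterministic; nested retentions give nested edge sets barring ties. The
weighted global clustering coefficient is the transitivity-style ratio of
triplet values over closed triplets to all triplets, with a triplet valued
at the arithmetic mean of its two anchoring edge weights — the default of
the weighted-network package tradition this metric comes from; min, max and
geometric variants are options because the variant in use is rarely
reported. With the arithmetic variant the coefficient is scale invariant.
The characteristic path length uses edge cost weight^(−α) with α = 1 — the
simplest inversion turning strong connections into short distances; α is
exposed for sensitivity analyses. On a disconnected graph the mean is taken
over reachable pairs with the unreachable count attached and a warning,
matching the practical choice of thresholds that keep graphs usable rather
than erroring. Both metrics are verified exactly against brute-force
triplet enumeration and Floyd–Warshall oracles on hundreds of random small
graphs.

## Reliability

Internal consistency treats the five quintile estimates as parallel
measurements: Cronbach's α = k/(k−1) · (1 − Σᵢ varᵢ / var_total). The 95%
interval is the Feldt F-interval with (n−1) and (n−1)(k−1) degrees of
freedom; the interval method is a declared choice since several circulate.
Test–retest reliability is the two-way random-effects, absolute-agreement,
single-measure ICC — the standard reading of "agreement ICC" — computed
from the subjects × sessions ANOVA mean squares:
(MSR − MSE) / (MSR + (k−1)·MSE + (k/n)(MSC − MSE)). Absolute agreement
(not consistency) is the right form here because a systematic session
offset is a real failure of test–retest stability; the tests confirm the
agreement form is strictly penalized by an added offset while the
consistency form is not. For the confidence interval we use the F-based
interval with Satterthwaite degrees of freedom; of the two renderings of
the upper bound found in circulating implementations, we use the one that
reduces to the point estimate as the F quantile goes to 1, having verified
by simulation that it covers at the nominal rate while the other
over-covers.

Replication across samples is: a one-way ANOVA of subject-level metric
values across samples with p ≥ 0.05, and each non-reference sample's
reliability point estimate inside the reference sample's 95% CI.

## Normative scoring

`builtinNorms()` embeds the published normative table: mean, SD, 25th–75th
percentile band and n for each of the three networks in three strata (all
322 subjects; age ≤ 50, n = 253; age > 50, n = 69 — connectivity drops
after age 50, so age-stratified scoring is the default when an age is
supplied; the boundary is inclusive in the younger stratum per the table's
row labels). A value is scored as z = (value − mean)/sd. Reports print the
SD distance at one decimal ("1.9 SD below the normative mean") alongside
the exact value, plus two percentile renderings labeled by origin: the
normal-approximation percentile and the position relative to the empirical
25th–75th band (the published bands are empirical, so neither rendering is
privileged). Qualitative bands (|z| < 1.5 within normal limits, 1.5–2
borderline, > 2 abnormal) are provisional conventions of this package, so
labeled in every report, and configurable — the normative source reports SD
distances without clinical cutoffs.

The case-example route accepts raw Pearson correlations
(`personReport(..., pearson = TRUE)`) and scores against the all-subject
stratum when requested; published SD distances for the illustrative case
match the all-subject norms.

## Synthetic data: what it emulates and what it does not

`simSpec()` defaults encode the study conditions behind the norms: 41
regions of which 14 anterior and 2 posterior-cingulate; 600 frames as five
120-frame blocks at TR 2.5 s; block Pearson correlations 0.56 within the
anterior set and 0.44 for the posterior-to-anterior and within-PCC blocks
(Fisher-Z 0.63 and 0.47, the normative sub-network means) and 0.34
background, chosen once so the implied whole-network average is ≈ 0.39 (the
normative mean; `impliedAverages()` returns the exact implied values);
motion spikes at 1% of frames as 0.5 mm steps; and a subject-level metric
model mean 0.39, total SD 0.07 split to a design ICC of 0.62, the headline
test–retest value. Frames are i.i.d. multivariate normal draws, so sample
correlations converge to targets at the 1/√n rate (tested at two frame
counts); an optional AR(1) filter adds temporal autocorrelation (zero-lag
cross-correlations are preserved, but the default is off to keep the
closed-form targets exact).

`simulateCohort()` has two modes. The default `"panel"` mode draws the
metric values directly from the two-level model value = μ + b_subject +
e_condition, so the design ICC σ_b²/(σ_b² + σ_e²) and the Spearman-Brown
design α over k quintiles are known exactly — this is the mode used for the
parameter-recovery checks. The `"series"` mode generates a full time series
per subject/session by scaling the off-diagonal Fisher-Z targets to the
subject's level (a generative convenience, not a biophysical claim — kept
positive definite by construction and verified at build time); estimation
noise then adds to the within-subject variance, so realized reliability
falls below the design value unless frames are plentiful. Tests use series
mode at small n for plausibility only.

What passing tests therefore establish: the estimators recover known
population quantities from data with the assumed structure (stationary
Gaussian blocks, step-like motion, exchangeable subjects). What they do not
establish: behaviour under real BOLD non-stationarity, hemodynamic
autocorrelation, task-evoked structure, scanner drift, or distribution
shift between scanners and populations — the norms themselves are
provisional in exactly this sense. The bundled 333-region parcellation
table is likewise a labeled synthetic stand-in with the reference scheme's
structural counts (41 DMN, 14 anterior including one centroid exactly at
the 15 mm boundary, 2 PCC) and synthetic coordinates; real analyses must
supply the real parcellation metadata.

## Numerical choices and degenerate inputs

Problem sizes in the test and acceptance runs are chosen for tight Monte
Carlo error at interactive runtimes: reliability recovery uses cohorts of
500 subjects (ICC estimator SE ≈ 0.03 per cohort; the acceptance script
averages 20 independent cohorts), block-correlation recovery uses 2000
frames (per-pair Fisher-Z SE ≈ 0.022), and oracle equivalence uses 500
random graphs of at most 8 nodes, where exhaustive enumeration is exact.
Other handling of edge cases: zero-variance regions error naming the
region; an all-censored series errors; graphs without triplets error for
clustering, and edgeless graphs for path length; a degenerate reliability
ANOVA (zero error mean square) returns ICC 1 flagged degenerate rather than
dividing by zero; rank-deficient confound matrices drop columns with a
warning; matrix serialization round-trips at 10 significant digits.

## Known limitations

The intensity-spike statistic is defined on volume means; applied to parcel
channels it is an approximation (documented on `scaledIntensityDiff()`).
The exact weighted-clustering variant and distance exponent behind
published topology values are not identifiable from reported means, which
is one reason average connectivity — which has no such free choices — is
the normed metric. Confidence intervals for α assume the Feldt model;
bootstrap intervals would differ. The normative constants are transcribed
values for one scanner, one acquisition protocol and one mostly-Caucasian
adult cohort; z-scores against them inherit those restrictions.
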