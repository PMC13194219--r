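---
title: "Classifying and modelling trunk volatile emissions with trunkvoc"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying and modelling trunk volatile emissions with trunkvoc}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trunkvoc)
```

## The problem

Wood-boring quarantine pests such as the Asian longhorned beetle spend most
of their life as larvae hidden inside the trunk, where visual surveys
perform poorly. The trunk itself, however, emits volatile organic compounds
(VOCs), and herbivory changes that emission profile: some compounds appear
de novo, others are strongly upregulated, and even an undamaged neighboring
tree can respond to an infested one. trunkvoc implements a complete,
reproducible analysis of such longitudinal enclosure-sampling TD–GC–MS
studies: annotation of deconvoluted components by linear retention index,
calibrated quantification of emission rates, separation of trunk volatiles
from ambient air, rule-based classification of compounds into constitutive
and induced classes, and modelling of temporal emission dynamics.

The package also ships a synthetic study generator that emulates the
design of a three-tree infestation experiment, so that every stage of the
pipeline can be exercised and verified against a planted ground truth —
an important property because quarantine studies of this kind typically
cannot deposit raw instrument data.

## Study model

A study consists of enclosure sampling events ("samples") described by a
design table: tree, day since arrival, replicate, enclosed bark surface
(dm²), sampling duration (h), pump flow, location, and a background flag.
Two consecutive samples per tree and day ("double determinations") are the
norm; grouped statistics count them as two samples, while temporal
dynamics average them per day.

The timeline is split into three disjoint phases: acclimation (days 0–8),
abiotic stress after pruning and relocation into the quarantine room (days
9–19), and biotic stress after beetle exposure (days 20–188). Phase
assignment is a total function on the study window; a day outside every
phase is an error rather than a silent drop.

A deliberate encoding choice runs through the whole package: **a compound
that was not detected in a sample is a missing row, never a zero**. This
makes detection frequencies (DF) well defined — the denominator comes from
the design table, the numerator from the observation table — and keeps
censored observations from biasing means.

## Annotation by linear retention index

Retention times are normalized against a co-analysed n-alkane ladder
(C5–C17). For an analyte eluting at time $t$ between alkanes with carbon
numbers $n$ and $n+1$:

$$\mathrm{LRI} = 100\,n + 100\,\frac{t - t_n}{t_{n+1} - t_n}$$

The implementation generalises this to ladders with missing carbon numbers
by scaling with the carbon gap, is exact at every ladder alkane, and is
strictly increasing in retention time. By default, retention times outside
the ladder span are an error; an `extrapolate` flag enables linear
extrapolation from the terminal segment, which is how sub-C5 indices of
very volatile compounds (LRI < 500) are obtained.

Candidates are drawn from a reference library within a configurable index
tolerance (default 15 units — literature-vs-experiment offsets of up to
about 12 units are common for sesquiterpenes on nonpolar columns), ranked
by absolute index difference with a lexicographic tie-break so output
order is deterministic. Spectral match scores, where present from upstream
deconvolution software, are carried through but never override the index
filter. Each compound carries an identification tier (M = mass spectrum,
R = retention index, S = authentic standard).

## Quantification

Calibration curves are ordinary least squares lines (area on spiked mass)
per compound. The intercept is kept free rather than forcing the line
through the origin: adsorbent-tube spiking can carry a constant blank
contribution, and a free intercept absorbs it instead of biasing the
slope. Back-calculated masses below zero (areas below the fitted
intercept) are expected for trace peaks below the lowest calibration
level; they are floored at zero and flagged, not treated as errors.

Compounds without an authentic standard are tentatively quantified through
the calibration curve of a structurally related compound with similar
retention behaviour (surrogate standards); these rates are flagged
`tentative`. Compounds with neither a curve nor a surrogate stay in
component-area units, and report tables refuse to mix mass- and area-based
rates.

Emission rates are normalized to the enclosed bark surface and sampling
time, $\mathrm{rate} = \mathrm{amount}/(\mathrm{area}\cdot\mathrm{time})$,
in ng dm⁻² h⁻¹ (or area counts dm⁻² h⁻¹). Background samples are ambient
air with no enclosed surface and are never area-normalized.

Ambient ubiquitous compounds are removed by comparing, per feature, the
median trunk area against the median background area within matching
(location, phase) strata — undetected background samples enter the median
as zeros. A feature survives if its trunk median exceeds `factor` (default
2) times the background median in at least one stratum, or if it never
appears in background air at all. The factor-2 default is a package
choice; it is configurable.

## Classification rules

Classification operates on detection frequencies and fold changes, with
all thresholds inclusive:

1. **Retention**: only compounds with DF ≥ 10 % across all maple samples
   are processed (with one tree per treatment, consistency of detection is
   the reliability criterion).
2. **Constitutive core**: DF ≥ 50 % in the pre-biotic-stress phases at
   *every* tree. The rule is applied per tree by default (a pooled variant
   is available by option), reading "all trees" strictly: a compound
   abundant at two trees but rare at the third is not continuously emitted
   by the species under study.
3. **Period means**: a mean emission rate for a (tree, period) scope is
   defined only when DF ≥ 20 % there; otherwise ratios degenerate into
   symbolic marks — the tree name when the compound is exclusive to the
   numerator tree, "`>`" when the comparison tree detected it in fewer
   than 20 % of measurements, and "`ALB`" when a compound appeared de novo
   (pre-exposure DF < 20 %, post ≥ 20 %).
4. **Rules**, evaluated in priority order for non-core compounds:
   *stress-induced* — post/pre increase ≥ 2 at both quarantine trees, to a
   comparable extent; *herbivore-induced* — de novo at the infested tree,
   or post/pre ≥ 2 together with infested-vs-neighbor and
   infested-vs-control ratios ≥ 2 (symbolic marks count as satisfied);
   *neighbor-induced* — the same with the neighbor tree as numerator;
   otherwise *unclassified*.

Two genuinely open points were settled as follows. "To a comparable
extent" for the stress rule is operationalized as the two trees'
increase ratios lying within a factor 2 of each other (configurable); the
stress rule also requires both ratios to be numeric, since a band between
a number and a symbolic mark is undefined. And a constitutive compound
that additionally satisfies an induced rule keeps `constitutive` as its
primary label with the induced rule recorded as a secondary flag, so that
primary labels always partition the retained set while upregulation of
core compounds remains visible.

## Temporal dynamics

Per-day means with standard errors of the duplicate determinations feed a
four-parameter asymmetric peak model

$$y = y_0 + A\,e^{-e^{-z}-z+1},\qquad z = (x - x_c)/w$$

whose maximum $y_0 + A$ is attained exactly at $x_c$ and which decays to
the offset $y_0$ on both sides (faster on the left). Fitting is
Levenberg–Marquardt nonlinear least squares. Starting values come from a
robust single-peak heuristic — $x_c$ at the day of the series maximum,
$y_0$ at the minimum, $A$ as the range, $w$ as half the number of days
above half height, floored at one day — with a small deterministic set of
perturbed restarts on failure; no random numbers are involved, so fits
are reproducible without seed bookkeeping. Goodness of fit is the
adjusted $R^2$ with $p = 4$ parameters; non-convergence is reported as a
flag, never hidden. The package fits all requested series and reports
convergence rather than silently selecting fittable compounds; multi-peak
traces are out of scope for the single-peak model and simply fit poorly,
which the adjusted $R^2$ makes visible.

Emission dynamics are grouped by Kendall rank correlation. The tie-
corrected $\tau_b$ variant is used because censored days create ties;
pairs are computed on the intersection of detected days (dropping, not
zero-filling, undetected days — zero-filling would manufacture
correlation from shared censoring). Compounds are linked when
$\tau \ge 0.5$ and $p < 0.05$ (defaults motivated by typical in-group
ranges of 0.6–0.85 versus non-significant out-group values below 0.3),
and single-linkage connected components form the temporal-pattern groups.

Group comparisons of emission rates use the Kruskal–Wallis rank sum test
(tie-corrected, chi-square reference) followed by Dunn's post hoc test on
mean ranks with tie correction. Dunn comparisons are gatekept by the
Kruskal–Wallis p-value at the chosen level; p-value adjustment is off by
default with Holm available, matching the common reporting convention of
an unadjusted $P < 0.05$ gate. Completely tied data return $H = 0$,
$p = 1$ rather than an error.

## The synthetic study generator

The generator emulates the study conditions: three trees (control outside
the quarantine room; infested and neighbor inside), duplicate samples on
42 days over a 188-day window with the control truncated at day 138 and
sampling denser in the early phases, ~2 dm² enclosed bark, 90-minute
sampling, and background measurements at both locations. The planted
compound set comprises 30 constitutive compounds (aldehyde-dominated, as
trunk blends are, with monoterpenes responding to relocation through a
stress multiplier), 15 herbivore-induced compounds of which 5 appear de
novo, 6 neighbor-induced and 4 stress-induced compounds, plus ambient
features present in background air to exercise the background filter.

The mean emission of a compound at a tree and day is its baseline
(optionally stress-multiplied inside the quarantine room from the abiotic
phase on) plus a sum of peak-function kernels; kernel presets reproduce
the archetypal shapes of such studies — an early single monoterpene-like
pulse shortly after exposure, double peaks tracking egg hatching and
xylem feeding, broad late sesquiterpene-like maxima around ten weeks, and
delayed neighbor responses around eight weeks. Observations are the mean
times mean-one multiplicative lognormal noise (CV 0.2 by default —
positive, right-skewed, as emission data are), censored below a detection
threshold of 0.05 ng dm⁻² h⁻¹ by dropping the row. Retention times are
back-computed from each compound's planted index through the alkane
ladder, and areas through its calibration curve and the sample geometry,
so the pipeline must genuinely invert the whole measurement chain.

Configuration validation enforces that planted labels hold *by
construction*: the noiseless mean curves, censored at the threshold and
pushed through the classification rule cascade, must reproduce the
planted label. An induction kernel bleeding into the pre-exposure phases
or an amplitude too small for a twofold increase errors out instead of
silently corrupting the truth table.

What the generator does **not** emulate — and what passing tests
therefore do not demonstrate about real data: chromatographic artefacts
(coelution, deconvolution errors, drifting retention), day-to-day
environmental covariance (all noise is independent across samples),
emission trends within a phase other than the planted kernels, surrogate
quantification bias (synthetic areas are generated through the same curve
the pipeline applies), and trace emissions below the detection limit at
non-target trees, which are modelled as truly absent. The noise level is
deliberately such that classification recovery sits near, but not
reliably at, 100 % — a borderline twofold ratio can fall on either side —
so the recovery checks remain informative.

## Numerical choices and degenerate inputs

* DF thresholds and fold changes compare inclusively (≥).
* A ratio whose numerator mean is undefined is itself undefined and
  satisfies no rule; a ratio with both means undefined is an error.
* Censoring drops rows; zero areas are rejected at load time.
* `fit_extreme` requires ≥ 5 points and positive variance; flat series
  are an error, non-convergence is a reported flag.
* Kendall grouping requires ≥ 3 shared days per pair; pairs with fewer
  are simply not linked.
* Report contributions are per-sample shares (undetected = 0) averaged
  over samples, so each table sums to 100 % by construction and is
  invariant under rescaling all rates.

## Problem sizes

The default synthetic study holds 3 trees × 42 (or 34) days × 2
replicates plus 32 background samples (≈ 10 000 observation rows, 58
features) and runs through the full pipeline in a few seconds. The
verification suite uses 1 000 random ladders for the retention-index
oracle, 200 simulated series for peak-fit recovery, 500 instances for the
rank-correlation oracle, and 5 000 simulations for the Kruskal–Wallis
type-I error check.

## A worked run

```{r, eval = FALSE}
study <- generate_study(default_study_config(seed = 1))
res <- run_pipeline(study)
table(res$classification$label)
head(res$constitutive_table)
fit <- with(subset(res$emissions,
                   compound == "p-Cymene" & tree_id == "ApI"), {
  agg <- daily_aggregate(day, rate)
  fit_extreme(agg$day, agg$mean)
})
fit
```

## Limitations

One tree per treatment is a case-study design: the classification labels
describe these individuals, not the species, and no inferential claim
about treatment effects is attached to them. The rule engine presumes
exactly one tree per role. The peak model is single-peaked; series with
two or three pulses are represented in the generator but fitted only in
the sense that the dominant pulse is captured. Spectral deconvolution,
library searching of mass spectra, and instrument-level corrections are
upstream of this package and out of scope.
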