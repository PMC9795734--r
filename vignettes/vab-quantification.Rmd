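---
title: "Quantifying vibration attraction behavior from pose tracks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying vibration attraction behavior from pose tracks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vabtrack)
```

## The assay and its measures

Vibration attraction behavior (VAB) is a foraging response of *Astyanax
mexicanus*: fish — strongly in cave-adapted populations, weakly in surface
fish — approach a rod vibrating at 35–40 Hz. The assay records a fish for
3 minutes in a 10-cm cylindrical arena with the rod at the center, and a
markerless pose estimator yields per-frame `(x, y, likelihood)` coordinates
for five markers: left, center and right of the head, the caudal fin, and
the rod center.

From these tracks the pipeline computes, per session:

* **NOA** — number of approaches: entries of the head-center marker into a
  radius cutoff around the rod (default 1.3 cm), split into left- and
  right-sided approaches;
* **DIR / DOR** — time inside / outside the radius, each split by the facing
  side;
* **swim distance** — summed frame-to-frame head-center displacement.

An approach is *left-sided* when, at the entry frame, the head-left marker
is closer to the rod than the head-right marker, and vice versa. The same
proximity rule attributes each individual frame to a facing side, which is
how DIR and DOR are split. We attribute DIR side per frame rather than per
event because the facing side can change while the fish adheres to the rod;
on single-frame visits the two attributions coincide (this is
property-tested).

## Track quality control

Pose estimators produce occasional low-confidence mislocalizations. A frame
is unreliable when *any* of the five markers falls below the confidence
threshold (default 0.92, the value at which the good and corrupted
likelihood regimes separate). For every maximal run of unreliable frames
bounded by reliable ones, **all** markers' x and y are linearly interpolated
between the bounding frames — the whole frame is replaced, not only the
failing marker, because a frame with one failed marker cannot be trusted to
have the others right and whole-frame replacement keeps the five markers
geometrically coherent.

Two boundary decisions the interpolation rule itself does not determine:

* runs touching the session start or end have only one anchor; they are
  filled by constant extrapolation from the nearest reliable frame, with a
  warning carrying the run length;
* repaired frames get their likelihood stamped at the threshold value and
  are listed in the attached QC report, so the provenance of interpolated
  coordinates survives a write/read round-trip, and re-running the repair is
  the identity.

A session in which every frame is flagged is an error, not a silent guess.

## Event detection and its conventions

A frame is *inside* when the head-center–to-rod distance is at most the
radius (closed boundary — ties count as inside; the convention is fixed and
documented because trajectories do occasionally land on the boundary after
interpolation). Each maximal inside-run entered from outside is one
approach event; a session that starts inside contributes one event
classified at frame 0, so NOA and DIR stay consistent. An exact left–right
proximity tie at the entry frame inherits the side of the previous
classified frame, and a leading tie resolves to "left" — an arbitrary but
deterministic choice, exercised in tests. No debouncing or minimum gap
between events is applied by default.

Distances are always computed in centimeters after calibration, never in
pixels, so event detection is invariant under a joint rescaling of
coordinates and calibration (tested). Calibration comes either from an
explicit pixels-per-cm value or from the known 10-cm arena diameter divided
by the marker extent in pixels; when both are given and disagree by more
than 5% the explicit value wins with a warning.

## Radius-cutoff selection

The radius defining an approach is selected by recomputing per-fish NOA for
each candidate radius (default 0.5–2.5 cm in 0.1-cm steps) in a
low-response and a high-response group and scoring group separation at each
radius. The score is the rank-based two-sample AUC — the probability that a
randomly drawn high-response fish out-approaches a randomly drawn
low-response fish, ties counting one half. AUC is threshold-free,
insensitive to monotone transforms of NOA, and directly interprets "best
discriminates"; the full per-radius table is always returned so any
alternative score can be applied to it. Exact score ties resolve to the
smallest radius.

## Laterality statistics

Per fish, the left–right ratio of a measure is `right / (left + right)`;
ratios below 0.33 are classed as strong left preference, above 0.67 as
strong right preference, the closed interval between as balanced. The bias
index is `max(left, right) / (left + right)`, from 0.5 (symmetric) to 1
(fully one-sided), and equals `max(r, 1 - r)` — an identity the tests
enforce. A fish with zero on both sides has an *undefined* ratio: it is
kept in the records as `NA` and excluded from histograms and means, never
coerced to 0.5, since a fish that never approached expresses no preference.

**Repeatability.** Whether an individual's preference is a stable trait is
quantified by the single-rater intraclass correlation over a complete
fish-by-repeat matrix. From the two-way mean squares (between-fish MSR,
between-repeat MSC, residual MSE) we report the repeatability F statistic
`F = MSR/MSE` with degrees of freedom `n - 1` and `(n - 1)(k - 1)`, and
both single-rater ICC variants: *consistency*,
`(MSR - MSE) / (MSR + (k - 1) MSE)`, and *absolute agreement*
`(MSR - MSE) / (MSR + (k - 1) MSE + k (MSC - MSE) / n)`. The headline
kappa is the consistency variant because it is algebraically a function of
F alone — `kappa = (F - 1)/(F + k - 1)` — which makes published F/kappa
pairs mutually checkable; `icc_from_f()` inverts that identity (clipping
at 0 for reporting, since a sub-unity F means no detectable repeatability).
Published repeatability tables in this literature round F to one decimal,
so a kappa recomputed from a printed F can differ from the printed kappa
by ~0.01 — a rounding artifact, not a disagreement. Verbal labels follow
the conventional agreement-strength bins (&lt;0.2 none, 0.2–0.4 fair,
0.4–0.6 moderate, 0.6–0.8 substantial, ≥0.8 almost perfect, left-closed).
Missing cells are an error; no imputation.

**Correlations and contrasts.** Associations between neuromast counts (or
ablation fractions) and behavior use tie-corrected Kendall tau-b, a rank
statistic appropriate for small, tied, non-normal count data: exact null
p-values for small tie-free samples, the tie-corrected normal approximation
otherwise. Fasting effects are per-fish differences (after − before) of
matched fish — unmatched ids are an error listing them — tested by the
paired Wilcoxon signed-rank test with Holm step-down correction inside an
explicitly declared test family (families are never inferred silently). A
test whose paired differences are all zero is undefined and reported as
such, while still counting as a family member for the correction.

## The synthetic-data generator

Real videos cannot ship with a package, and a trained pose network is not
reproducible from code alone, so correctness is demonstrated on synthetic
sessions with known ground truth. The generator emulates the assay
geometry: a 10-cm arena, rod at the center, 3-minute sessions (default
20 fps, exposed as a parameter since recording hardware varies), image
coordinates with the origin top-left and y increasing downward, frames
indexed from 0.

The trajectory is smoothed random-waypoint wandering in the outer annulus,
interleaved with *scripted approach arcs*: the head-center travels along a
straight chord whose closest pass to the rod is offset 0.3 cm to the
intended side, dwells near the closest-pass point for a gamma-distributed
time (mean 1.5 s), and leaves along the same chord. Head-left/right markers
sit 0.35 cm either side of head-center, perpendicular to the instantaneous
heading (frame-to-frame displacement). This construction makes the proximity
rule coincide with the scripted side *by construction* — at the entry frame
the signed offset of the rod from the travel direction is exactly the
0.3-cm chord offset — and the noise-free path crosses the radius exactly
`n_events` times, giving unambiguous ground-truth events. Approach sides
are i.i.d. Bernoulli draws with probability `p_right`. Schedules that
cannot fit (dwell plus transit exceeding the session) fail loudly naming
the constraint.

Measurement imperfections are layered on top: Gaussian localization jitter
on every marker (default 1 px at 40 px/cm) and, optionally, dropout
corruption — each corrupted frame has one randomly chosen marker's
likelihood redrawn uniformly on [0, 0.92) and its coordinates displaced by
a large jump, while good frames draw likelihoods from [0.95, 1], so the
0.92 threshold separates the regimes exactly. Everything is a pure function
of the parameters and the seed.

What the generator does **not** emulate — and what passing tests therefore
cannot certify about real data: burst-and-glide swimming kinematics, wall-
and rod-following behavior, body bending (the marker triangle is rigid
here), pose-network error structure (real mislocalizations are correlated
in time and anatomy), multi-fish arenas, or any dependence of behavior on
the vibration stimulus itself. The synthetic cohort validates the
*computation*, not the biology.

## Problem sizes and numerical choices

The shipped tests run the full property sweeps at reduced session lengths —
30–60-s sessions for the thousand-session invariant sweep, 45-s sessions
for the 200-session event-recovery check, 3-min defaults elsewhere — sizes
chosen so the whole suite exercises every claim in well under a minute per
sweep while keeping per-sweep event counts in the hundreds. Fixed seeds
make every stochastic check reproducible; checks against closed-form
binomial bands use those pre-registered seeds, and purely statistical
regression guards use a 3-sigma band so that only systematic bias, not an
unlucky draw, can trip them. Track CSVs round-trip coordinates at full
double precision (`%.17g`).

## Known limitations

* Whole-frame interpolation is deliberately more destructive than
  per-marker repair; long dropout runs straighten corners of the true path.
  The bound on the resulting position error (tested) assumes smooth motion
  between anchors.
* The AUC radius score needs at least two fish per group and, like any
  rank statistic, saturates once groups separate completely — on strongly
  separated synthetic groups the scan returns the smallest radius by the
  tie rule rather than a unique interior optimum.
* `fps` and calibration are trusted inputs; the package cannot detect a
  wrong frame rate.
* The ICC assumes a complete crossed design; fish lost between repeats must
  be dropped before the matrix is built.
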