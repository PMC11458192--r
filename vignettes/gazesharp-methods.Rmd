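---
title: "Scoring radiographs by gaze: model, simulator and agreement methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring radiographs by gaze: model, simulator and agreement methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gazesharp)
```

## The reading model

The modified van der Heijde Sharp (mvdH) score grades rheumatoid arthritis
damage joint by joint: erosions on 16 sites per hand (capped at 5 points
each) and 6 per foot (capped at 10), joint space narrowing (JSN) on 15 sites
per hand and the same 6 per foot (capped at 4). `gazesharp` implements an
eye-tracking protocol for producing those grades: a reader trained with a
metronome dwells on each joint for a fixed 2 seconds per Sharp point, so the
total gaze fixation duration on a joint encodes its score. The conversion is

$$\text{score}_{\text{raw}} = \max\!\left(0,\; \frac{\text{ms}}{1000 \cdot 2} - 0.5\right),$$

one point per 2 s of fixation after subtracting the 1 s of baseline dwell a
reader spends inspecting any joint, pathological or not. The `max(0, \cdot)`
clip encodes that sub-baseline dwells mean "no lesion", never negative
damage. Raw scores are rounded to the nearest integer (ties rounded up,
since the protocol's quantum makes a half-point exactly ambiguous and the
score is a damage *detection* instrument) and clipped to the site's cap.
Integer scores are compared in seven ordinal classes, 0–5 and an open-ended
top class for 6 or more, and dichotomized as lesion yes/no.

## The joint atlas

`build_default_atlas()` enumerates the per-patient inventory: hands before
feet, right before left, and within a hand the erosion inventory (distal
radius, ulna, scaphoid, lunate, trapezium, first metacarpal base, MCP1–5,
IPP1–5) followed by the JSN-only carpal articulations and carpometacarpal
joints (scaphoid–radius, scaphoid–capitate, scaphoid–trapezium, MCC3–5).
Two inventory choices were genuinely open and are resolved as follows:

- **IPP1 is erosion-only.** The hand JSN location list would otherwise
  contain 16 entries while the score's composition is 15 JSN joints per
  hand; excluding the thumb interphalangeal from JSN matches the standard
  mvdH convention and restores the stated count.
- **Feet carry six joints: IP1 and MTP1–5.** A first-metatarsal-base row
  sometimes appears in per-joint summary tables of this protocol, but a
  seventh foot site is inconsistent with the six-joints-per-foot composition
  (and with 44 erosion sites per patient, 440 over a 10-patient study); the
  package treats "M1 base" as a hand site only.

Score caps are a convention of the instrument rather than something
recoverable from observed score ranges, so the atlas fixes them at the
standard values (hand erosion 5, foot erosion 10, JSN 4).

```{r atlas}
atlas <- build_default_atlas()
c(erosion = sum(atlas$erosion), jsn = sum(atlas$jsn))
```

Both per-patient totals are exposed; the package does not attempt to
reconcile the erosion count (440 over 10 patients) with the JSN count (420),
which differ by construction.

## The synthetic gaze generator

No raw gaze recordings ship with the package; `sim_config()` +
`simulate_true_scores()` + `simulate_reading()` generate fixation streams
with the statistical structure the analysis assumes, so the whole pipeline
is testable with known ground truth.

**Ground-truth scores.** Each (patient, site, lesion) score is drawn from a
discretized truncated normal on `0..cap`: integer `k` receives the normal
mass in `(k - 0.5, k + 0.5)` with the tails folded into 0 and the cap. The
per-site means and SDs default to a catalogue of per-joint values typical of
an early-RA cohort spanning normal to severe damage (e.g. MCP2 erosion mean
0.90, SD 1.12; foot MTP3 erosion mean 1.20, SD 1.99). Because folding the
negative tail into zero inflates the mean of a low-mean site by roughly 0.1
points, the latent normal mean is calibrated by root-finding so that the
*discretized* distribution hits the configured mean exactly; sample means
then recover the catalogue means without bias, which is what the generator's
recovery tests assert. Only the mean is calibrated — the realized SD tracks
the catalogue SD only approximately, which is acceptable because no
downstream statistic depends on matching second moments exactly.

**Durations.** A joint with true score $s$ receives total fixation time
$1000 + 2000s$ ms plus additive Gaussian noise (SD
`duration_noise_sd_ms`, default 300 ms), floored at 1 ms and split into
1.5 s chunks with jittered positions inside the joint's ROI. The default
300 ms models a metronome-trained reader: noise flips a rounded score only
when it exceeds half a point (1000 ms), so a trained reader almost never
misses — the README example shows how agreement degrades when the noise is
pushed to 800 ms. Fixation timestamps are sequential with 30–120 ms saccade
gaps, so streams are time-ordered and non-overlapping.

**ROI geometry and ambiguity.** The synthetic layout places each lesion's
sites as circles (default radius 30 px on a 1920x1080 canvas), in atlas
order, with consecutive sites within a region/side group forming *adjacent
pairs* whose centres sit 1.5 radii apart — close enough that the discs
overlap — while distinct pairs and rows are widely separated. Ordinary
fixations are jittered by at most a quarter radius, so they can never stray
into a neighbouring disc. With probability `ambiguity_rate` (default 0.05,
of the order of the 24-joint exclusions seen in a 440-joint study), a pair
containing at least one pathological joint (true score ≥ 1) is read
ambiguously: both joints' fixations land in the overlap of the two discs.
The event is defined at the *pair* level on disjoint pairs deliberately: a
pathological joint is then flagged exactly when its own pair draws the
event, so the expected fraction of non-analyzable pathological joints equals
`ambiguity_rate` — a per-joint event would overshoot via flagged neighbours.

**What the generator does not emulate.** Saccade kinematics, pupil and blink
signals, calibration drift, reader fatigue and learning, correlated severity
between adjacent joints, and the anatomy of a real radiograph (ROIs are an
abstract grid). Passing round-trip tests therefore demonstrate that the
*pipeline* is correct and internally consistent, not that a human reader
achieves any particular agreement on real films.

## Fixation processing

`assign_fixations()` uses closed-disc point membership (distance ≤ radius).
A fixation inside exactly one ROI contributes its duration there; inside two
or more, all the overlapped joints are flagged non-analyzable — and the flag
is sticky for the whole reading, because ambiguity makes the joint's *total*
time unattributable, matching the joint-level exclusions of the reading
protocol (ambiguous durations are also not counted toward any joint).
Fixations outside every ROI are background and are discarded; for
non-overlapping layouts, assigned plus discarded duration conserves the
stream total exactly. Assignment is order-independent, so exports may be
sorted or shuffled.

## Agreement statistics

`cohen_kappa()` computes unweighted Cohen's kappa
$\kappa = (p_o - p_e)/(1 - p_e)$ on the eye-tracking vs reference table,
with the large-sample Fleiss–Cohen–Everitt standard error and a
$\kappa \pm 1.96\,\mathrm{se}$ interval. The class analysis uses the 0–5/≥6
binning; `dichotomize()` pools all positive bins into lesion-present.
Joints non-analyzable in either reading are excluded pairwise before the
table is built (`pair_scores()` joins on the identifier columns both tables
share).

`icc()` is the two-way random-effects, absolute-agreement, single-measure
intraclass correlation, computed from the standard mean-square
decomposition with McGraw & Wong F-distribution confidence bounds. That
variant is chosen because replicate readings are the *same* reader re-reading
the same joints and the question is absolute reproducibility of a single
reading; a consistency-type ICC would forgive systematic drift between
replicates. Degenerate inputs (zero residual variance) return ICC 1 with a
collapsed interval rather than dividing by zero.

Both statistics are validated in the test suite against independent routes:
kappa against a first-principles computation from raw label pairs and
against `e1071::classAgreement()`, the ICC mean squares against `aov()`, and
ICC recovery on simulated replicates with known variance components
($\sigma^2_b = 4$, $\sigma^2_w = 0.25$, $n = 400$, expected
$4/4.25 \approx 0.941$, tolerance 0.015 ≈ 3 Monte-Carlo SE of that
experiment).

```{r kappa}
cohen_kappa(mvdh_table2("erosion"))
cohen_kappa(dichotomize(mvdh_table2("jsn")))
```

The packaged tables transcribe only the body cells of the published
contingency tables; their printed marginal "Total" rows are not sums of the
body and are deliberately not shipped. The erosion body sums to 414 joints
against a stated 416 analyzable — the two-joint gap is left as-is, and the
class-kappa check carries a correspondingly wider tolerance.

## Visualization

`render_heatmap()` deposits each fixation's duration through an isotropic
Gaussian kernel (default SD 15 px) evaluated on the pixel lattice within
±5 SD, so an interior fixation's total deposited mass equals its duration to
within the $<10^{-5}$ lattice-truncation error; grids are max-normalized for
display, with raw mass available for testing. `render_gaze_plot()` orders
fixations by onset and scales circle diameters linearly with duration
(default 0.02 px/ms). `render_score_overlay()` colours joints green below 1
point, yellow at exactly 1, and a single orange/red class at 2 or more — the
display ramp within that top class is continuous, but classification is
three-way.

## Problem sizes and numerical choices

The shipped tests simulate 2–3 patients for round-trip checks, 40 patients
for the ambiguity-rate recovery, and 2000 patients (truth table only) for
the score-mean recovery; the full suite runs in well under a minute. Integer
milliseconds and integer pixel coordinates are used throughout the export
dialect, which is what makes the noiseless round trip exact: with zero
timing noise and no ambiguity, generator → assignment → scoring reproduces
the ground-truth table bit for bit, and kappa against truth is exactly 1.
Ties in rounding are half-up; durations are floored at 1 ms; empty streams
produce all-zero summaries and an all-zero (unnormalized) heatmap.

## Limitations

The agreement surface of a real study is reproduced only through its
published contingency tables; per-joint raw readings are not available, so
study-level ICC and per-joint mean reading times are covered by
property-based simulation tests instead of numerical reproduction. The
synthetic canvas is geometric, not anatomical; transferring conclusions to
real radiographs requires real gaze recordings.
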