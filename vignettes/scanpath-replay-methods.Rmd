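---
title: "Quantifying scanpath replay: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying scanpath replay: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gazereplay)
```

## The problem

When people recall a previously seen image while looking at a blank
screen, their eyes spontaneously retrace parts of the scanpath they
produced during encoding. `gazereplay` quantifies that *sequential*
reinstatement — not merely whether gaze lands in the same regions, but
whether the ordered sequence of fixations and saccades is replayed — and
tests whether the fidelity of replay predicts the quality of the
recalled memory.

The pipeline has four stages:

1. **Scanpath comparison** (`compare_scanpaths()`): a vector-based
   similarity between two scanpaths over five spatio-temporal
   dimensions.
2. **Replay scoring** (`replay_scores()`): per-trial
   sequential encoding–recollection similarity (SERS), a
   within-participant cross-image baseline, and their difference — the
   replay score.
3. **Spatial reinstatement** (`aoi_profile()`, `spatial_overlap()`):
   the complementary order-free analysis over area-of-interest grids.
4. **Inference** (`fit_mixed()`, `backward_select()`,
   `run_study_models()`): crossed-random-effects mixed models with
   likelihood-ratio backward selection.

A synthetic-experiment generator (`generate_experiment()`) produces
full cohorts with known ground truth; every downstream claim the test
suite makes is validated against that ground truth.

## The comparison model

Scanpaths are ordered fixations (x, y in px, origin top-left, y
downward; duration in ms). Saccades are represented implicitly as the
displacement vectors between consecutive fixation centroids.

**Simplification.** Successive saccade pairs are merged — the
intervening fixation removed, the vectors summed — when they continue
within `direction_threshold` of each other (default 45°), or when both
are shorter than `amplitude_fraction` of the screen diagonal (default
10%) and the fixation between them is shorter than
`duration_threshold` (default 150 ms). Merging repeats left-to-right
to a fixpoint, so the result is deterministic. These defaults are the
standard settings of vector-based scanpath comparison; they are
config-exposed (`mm_params()`) and recorded in every output's metadata
rather than baked in.

**Temporal alignment.** Every saccadic vector of one scanpath is
compared with every vector of the other by the Euclidean norm of the
vector difference — a shape cost combining length and direction
(`mm_cost_matrix()`). The minimal-cost monotone path from the top-left
to the bottom-right cell (steps: right, down, diagonal; cost = sum of
entered cells including the start) aligns the two sequences
(`mm_align()`). Because the lattice is a DAG, dynamic programming
yields the same optimum a general shortest-path search would; the test
suite verifies optimality against exhaustive enumeration of all
monotone paths. Ties are broken diagonal-first, then right, then down,
so results are platform-independent. The alignment is relative: the
two scanpaths need not have equal numbers of saccades.

**Similarity.** For each aligned pair a normalised difference is
computed per dimension and similarity is one minus the mean:

| dimension | difference | normaliser |
|---|---|---|
| position | distance between terminating fixations | screen diagonal |
| duration | absolute duration difference | max of the pair |
| shape | norm of the vector difference | 2 × screen diagonal |
| direction | angular difference wrapped to [0, π] | π |
| length | absolute amplitude difference | screen diagonal |

All five scores lie in [0, 1]; self-comparison scores exactly 1.
Position (and to a lesser degree shape) depends on absolute screen
coordinates; direction, length and duration are translation-invariant,
which makes the method robust to the global offsets and rescaling that
are typical of blank-screen recall. Duration normalisation uses the
per-pair maximum (the cited method's convention; a global constant
would be an alternative but is not what the field uses).

## Replay scores

For participant *p* and image *i*, SERS is the comparison of *p*'s
encoding scanpath for *i* with *p*'s recall scanpath for *i*. The
baseline is the mean comparison of that encoding scanpath with *p*'s
recalls of all *other* images of the same type (scenes and object
arrangements are never mixed), weighting images equally. The replay
score is SERS − baseline, per dimension; values above zero indicate
sequential reinstatement beyond the participant's idiosyncratic
viewing tendencies. Trials with fewer than 2 fixations in either
phase, trials missing their counterpart phase, and trials with an
empty baseline set are excluded and reported with machine-readable
reason codes.

## Spatial reinstatement

The order-free analysis divides the screen into 4 (quadrants), 8, 12
or 16 equal cells and compares the proportion of fixations per cell
between encoding and recall. Cells are half-open with the last
row/column closed, so boundary fixations are assigned
deterministically. The default overlap metric is total-variation
similarity, `1 − Σ|p − q|/2`; a rank-correlation metric (rescaled to
[0, 1]) is selectable, and the metric used is attached to every
result so scores are never silently mixed. For a completely flat
profile the rank metric is undefined; it is defined here as 1 for
identical profiles and 0.5 otherwise.

## Inference

All models use crossed random intercepts for participant and image,
plus a participant-level random slope for image type; when the slope
makes a fit singular the model falls back to intercepts only and says
so. Gaussian models are fitted by REML for reporting with
Satterthwaite degrees of freedom (`lmerTest`); binomial models use the
logit link and Wald z. Likelihood-ratio comparisons always use
maximum-likelihood fits of nested fixed-effect structures with the
random structure held constant — the structure is settled on the
maximal model first, because comparing fits whose random structures
differ would make the degrees of freedom meaningless.

Backward selection starts from the maximal model and repeatedly drops
the least-significant removable term (largest LR p ≥ α, default .05),
respecting marginality: a main effect is never removed while an
interaction containing it survives. Ratings (0–100) are modelled on a
[0, 1] scale. No correction for multiple comparisons is applied across
the five similarity dimensions; reports note this.

**The SERS-versus-baseline contrast** is implemented two ways.
`replay_contrast(method = "lmm")` models the paired difference with
crossed random intercepts and reports the Satterthwaite test and LR
χ²; this mirrors the standard reporting style. However, replay records
within a participant are *negatively dependent by construction*: every
record's baseline shares pairwise comparisons with the other records,
and under a label-shuffled null the within-participant mean replay is
constrained toward zero. A record-level mixed model, which assumes
conditionally independent residuals, is then conservative (its
empirical type-I error is far below the nominal level).
`method = "participant"` — a one-sample t test on the per-participant
mean replay — is exactly calibrated under that dependence structure
and is what the calibration checks use. For effect *estimation* the
two agree closely; they differ in how they count evidence.

**The encoding-strength control** asks whether replay effects on
memory quality reduce to how well images were encoded: the cumulative
number of study fixations is added to the selected memory-quality
model (LR test reported), and then its interactions with every model
variable are added — each alone, and jointly as a block.
`encoding_strength_control()` reports the stepwise tests, the ML
likelihood-ratio block test, and Satterthwaite joint F tests of the
full block and of the replay-term interactions; the F form is the
preferred verdict because the ML likelihood ratio is anticonservative
when participants are few, and a joint test is used at all because
requiring several separate null tests to all exceed .05 simultaneously
would fail by chance alone in roughly one replicate in five.

One caveat belongs here: replay is a *measured* quantity whose
reliability grows with the number of fixations in the trial. The slope
of ratings on measured replay is therefore genuinely modulated by the
fixation count (less attenuation in longer trials) even when the
underlying memory process is not. In large samples the joint
interaction test will detect this measurement artifact; its detection
is not evidence that encoding strength moderates replay.

**Power.** `power_correlation()` gives the analytic power of the
two-sided test of a product-moment correlation via the Fisher-z
approximation; with n = 60, ρ = 0.5 and α = .05 it exceeds 90%, the
design target of a typical study of this kind.

## The synthetic generator

`simulation_config()` defines a full experiment: 60 participants × 36
images (18 scenes, 18 object arrangements), 5 s encoding, 7 s
blank-screen recall, ~15 fixations per encoding trial
(Poisson, minimum 3), lognormal fixation durations around 230 ms.
Image content is represented by latent anchor points shared across
participants — center-biased anchors for scenes, four well-separated
quadrant anchors for object arrangements; no pixels are ever rendered
because the pipeline never needs them.

Recall scanpaths are distorted copies of encoding scanpaths,
reproducing the phenomena documented for looking-at-nothing recall:
fixation durations are inflated (×1.6), the path is contracted about
its centroid (×0.8), globally offset (SD 60 px) and jittered. Three
latent per-trial fidelities, each Beta-distributed, drive both the
distortions and the ratings:

* **sequential (position) fidelity** — the probability each encoding
  fixation is retained in order; non-retained fixations are
  re-inserted at a uniformly random serial position. It additionally
  scales a low-frequency positional drift (up to 300 px at fidelity 0)
  that accumulates along the sequence: poorly remembered sequences
  wander from the encoded locations while local saccade geometry stays
  intact.
* **shape fidelity** — attenuates mean-one lognormal amplitude noise
  applied per saccade.
* **direction fidelity** — attenuates per-saccade rotation noise.

Each recall fixation is pulled back toward its remembered location
with weight 0.6 ("re-anchoring"). This reflects how memory-guided
gaze behaves — saccade errors do not compound into a random walk,
because successive fixations target remembered locations — and it is
what makes the three noise channels load predominantly on their own
similarity dimensions, so that ground truth is recoverable from the
measured replay scores. The channels remain correlated (as the real
dimensions are); recoverability of the *pattern* of effects, not
orthogonality, is the design goal, and the acceptance suite verifies
it at full scale.

Ratings: the latent memory quality is `intercept + scene advantage +
b_pos·(position fidelity − ½) + scene·b_shape·(shape fidelity − ½) +
arrangement·b_dir·(direction fidelity − ½)` plus participant and image
random intercepts, a participant random slope for image type, and
trial noise. The three subjective ratings add independent measurement
noise calibrated so their pairwise correlations are ≈ 0.9; the
mnemonic content score is their mean. Surprise-test outcomes (4AFC
accuracy, confidence, response time, gaze transitions between options)
are monotone links on the same latent value, oriented so that scenes
are easier than object arrangements.

Random streams are split per (participant, image, phase) through
hashed sub-seeds, so one seed fully determines the output and adding
participants does not perturb existing trials.

**What the generator does not emulate:** visual saliency, oculomotor
main-sequence dynamics, microsaccades, blinks, calibration drift, or
any pixel-level image content. Passing tests therefore show that the
pipeline recovers the statistical structure it assumes — not that real
eye-tracking data satisfy those assumptions.

## Numerical choices

* All similarity arithmetic is double precision; test comparisons use
  1e−9 where exactness is not structural.
* Angular differences are wrapped to [0, π] before normalising, so
  direction similarity is well defined for every angle pair.
* A duration pair (0, 0) contributes zero difference (the denominator
  guard); durations are required positive at construction anyway.
* Similarities are clamped to [0, 1] as a guard for off-screen
  fixations, which are retained with a warning at read time
  (exclusion is the caller's decision).
* Scanpaths with exactly one saccade are compared as-is; there is
  nothing to simplify.

## Problem sizes used in validation

The test suite exercises the pipeline at the scales the study design
implies: the effect-pattern recovery check runs 50 replicates at the
full 60 × 36 scale; null calibration uses 400 scaled-down replicates
(10 participants × 8 images) plus a 240-record shuffle check; the
fidelity–similarity monotonicity check uses 200 trials per grid point;
the encoding-strength control uses 50 replicates at 20 × 12. The
alignment optimality check enumerates all monotone paths for 100
random cost matrices up to 6 × 6.

## Known limitations

* The simplification thresholds are the cited community defaults, not
  values estimated from data; sensitivity to them is config-exposed
  but not swept automatically.
* The cross-image baseline is within-participant only; cross-participant
  baselining is out of scope.
* The spatial-overlap metric is a package decision (total variation by
  default); it honours the described quadrant comparison but is not a
  reimplementation of any particular published score.
* Mixed-model p-values rely on the Satterthwaite approximation as
  implemented in `lmerTest`; for binomial models only Wald z is
  available, and the report records which method was used.
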