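---
title: "Modelling and quantifying trunk neural crest chain migration"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling and quantifying trunk neural crest chain migration}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crestchain)
```

Zebrafish trunk neural crest (TNC) cells migrate ventrally between the
neural tube and the somites in single-file chains: a leader cell holds the
front and directs the group, trailing followers rearrange behind it.
`crestchain` provides (i) a discrete-element model of this process, (ii)
the five-criterion score used to decide whether a simulated chain behaves
like an in vivo one, (iii) exhaustive parameter sweeps over qualitative
low/medium/high settings, (iv) a trajectory metric suite shared by
simulated and tracked cells, (v) a two-class linear discriminant analysis
(LDA) ranking the features that separate migratory identities, and (vi)
cell-cycle phase-duration analysis with Gaussian-mixture quantification of
bimodality. Seeded generators reproduce the published summary statistics
of the in vivo measurements so that the whole pipeline is testable without
imaging data.

## The chain model

Cells are 2D discs with an identity (`leader` or `follower`), a position,
a unit heading, a radius and an intrinsic speed, confined to a reflective
dorsoventral corridor (`arena()`). The y axis increases ventrally; the
premigratory band occupies 0–25 µm, the neural tube/notochord boundary
sits at 65 µm (anchored to the 65.3 µm in vivo landmark) and the
migratory path ends at 150 µm. The corridor continues ventrally to
220 µm so that over-migration beyond the path end is observable, and
dorsally to −105 µm so that chains longer than the band can be
initialised with their front inside it. Walls act on the cell surface.

Each one-minute step applies, in this fixed order (the order is part of
the model contract): intrinsic motility, contact inhibition of locomotion
(CIL), co-attraction, volume exclusion, heading noise, boundary
reflection. The force laws are this package's own design, built to
realise the qualitative interaction definitions:

* **CIL** (unlike identities only, under the default `differential`
  mode). While two cells are in contact each recoils away from the
  partner at `cil_push_scale * theta` µm/min, and its heading is rotated
  towards the escape direction by at most its own turn angle `theta`;
  a repolarised heading is protected from noise for `cil_persist` steps.
  The turn angle is the identity's CIL-intensity level, so a leader (high
  setting) responds much more strongly than a follower (low setting).
* **Co-attraction** pulls together cells *at a distance*: a displacement
  of fixed magnitude (the co-attraction level, µm/min) towards the
  centroid of the nearest non-touching cell within range on each
  dorsoventral side of the focal cell. Touching neighbours exert no pull,
  and at most one neighbour per side contributes. A plain
  all-neighbour centroid rule was rejected during model development
  because the follower crowd then always outvotes the leader and the
  chain collapses into a cluster; the nearest-per-side rule keeps the
  "attraction at a distance" semantics while letting a single-file chain
  behave as a train of tension links.
* **Volume exclusion** is a soft repulsive spring: a fraction
  `exclusion_strength` of each pair's overlap is recovered per step.
  Cells are therefore effectively deformable — pressed cells compress by
  up to a few µm (documented tolerance `exclusion_tol = 6` µm) and can
  occasionally squeeze past one another in the narrow corridor, which is
  how follower rearrangements happen, as they do in vivo where cells
  deform around each other.
* **Noise**: the heading is rotated by a normal angle with SD `zeta`
  per step. All randomness flows from one seed through R's RNG in a
  fixed draw order, so trajectories are bit-reproducible.

### Why the chain migrates

The model contains no chemotactic field (none is known for this system).
Directionality is emergent: the front leader is repeatedly repolarised
ventrally by contacts with the follower behind it and escapes in runs;
each follower chases the nearest cell ahead through the co-attraction
band, so advance propagates rearwards as stretch–chase waves. Chains of a
single identity have no CIL interfaces under differential CIL and
therefore no motor: all-follower chains jostle near the premigratory area
and lose their front cell, and all-leader chains disperse with low
directionality — the in vivo phenotypes of Notch loss- and
gain-of-function. With leaders interleaved (1:1), every follower sits
next to a leader and the chain overshoots the path end within the
simulated 16 h, while 1:2/1:3 chains terminate near it.

### Calibration

Radii derive from the measured areas (leader 102 µm² → 5.70 µm;
follower 72 µm² → 4.79 µm, `sqrt(area/pi)`). The step is 1 min with
every 5th frame recorded, mirroring the 5-minute imaging cadence, and the
default duration (960 steps = 16 h) matches the length of the live
movies. All remaining constants — speeds (0.7/0.55 µm/min), noise
(`zeta = 0.17`), persistence (16 steps), recoil scale (0.45 µm/min per
radian), co-attraction levels (0.1/0.25/0.4 µm/min) and range (60 µm),
corridor width (15 µm, about 1.5 cell diameters, matching the
single-cell-wide path between somite and neural tube), exclusion
stiffness (0.4) and initial spacing (5 µm surface gaps) — are
calibration constants, chosen once so that default simulations reproduce
the qualitative in vivo chain behaviours (cohesive single-file advance
with a retained leader for 1:3 chains; the failure modes above for the
perturbed architectures), and frozen thereafter. They are not published
measurements.

The CIL-intensity ladder (low π/12, medium π/2, high 2.2 rad) places the
default leader setting at `medium`: the sweep can then probe a stronger
response than the default as well as a weaker one.

```{r simulate}
tr <- simulate_chain(composition_preset("1:3"), seed = 1)
tr
score_all(tr)
```

## The five-criterion score

`score_all()` aggregates: chain cohesion (no adjacent-cell distance above
57 µm, measured between dorsoventral-rank neighbours at every sampled
frame — strict by default because the published rule states a maximum;
a 5%-of-frames variant sits behind `cohesion_strict = FALSE`); single
file in at least 80% of frames (a pair is side-by-side when their
dorsoventral extents overlap, `|dy| < min(r)`, while laterally in
near-contact); at least one sustained follower–follower rank swap;
leader-front retention (the frame-0 front cell is most ventral in ≥ 95%
of frames and is never durably overtaken); and path completion (the
leader reaches 150 µm; the report also flags over-migration beyond one
leader diameter past the end). Overtakes and swaps must hold a 2 µm
ventral lead for 3 consecutive sampled frames (15 min) so that sampling
jitter does not count as a rank change. The 57 µm and 80% thresholds are
the published values; the remaining settings are robustness choices at
the 5-minute sampling.

## Parameter sweeps

`enumerate_grid()` builds the full factorial over leader CIL intensity,
co-attraction and leader cell size (low/medium/high; `level_map()` holds
the numeric values, and the cell-size ladder spans the follower radius to
1.2× the leader radius). `run_sweep()` scores `n_reps = 20` seeded
replicates per combination; a combination *matches* when every
criterion's pass fraction reaches `match_threshold = 0.7` (the published
analysis does not state its replicate handling; fraction-based matching
is this package's choice). Replicate seeds derive only from the master
seed and the combination index, so results are independent of execution
order. Under the default calibration no homogeneous chain matches all
five criteria while heterogeneous 1:3 chains do, with the matching
combinations concentrated at medium/high leader CIL — the count and the
exact level identities of matching combinations are sensitive to the
force-law constants and are not comparable across implementations.

## Trajectory metrics

`instantaneous_speed()` is exactly the tracking convention used for the
in vivo data (`sqrt(dx^2+dy^2+dz^2)/T * 60`, µm/hr), and `mean_speed`
averages it over consecutive frames rather than dividing net displacement
by total time, matching the per-step formula. Directionality is net
displacement over path length (computed in 3D; the published macro's
definition is not available, this is the field's standard definition) and
ventral distance is the final dorsoventral position relative to the
dorsal edge (y = 0 by default). `summarize_tracks()` applies the suite to
any track table — simulated chains export to the same format via
`as_track_table()` — and adds identity-level aggregates plus the
leader/follower mean-area ratio when areas are supplied.

## Identity LDA

`fit_lda()` implements the two-class Fisher discriminant on z-scored
features with a small ridge (`1e-6 * trace/p`) on the pooled within-class
scatter, appropriate for the tens-of-cells samples involved; the axis
equals `solve(Sw, mu1 - mu2)` and the tests verify this closed form (and
MASS's implementation) on random instances. Standardised coefficient
magnitudes define importance because the features mix units (µm, µm/hr,
dimensionless); raw-scale coefficients are reported alongside.
`random_control()` replaces every feature by standard normal draws with
the labels preserved (a label-shuffling variant is available), giving the
no-structure reference against which feature rankings are judged. With
two classes there is a single discriminant axis; any additional displayed
axes in this kind of analysis are residual principal axes, not
discriminants.

```{r lda}
tracks <- gen_tracks(15, 45, seed = 1)
sm <- summarize_tracks(tracks)
feat <- data.frame(ventral_distance = sm$cells$ventral_distance,
                   mean_speed = sm$cells$mean_speed,
                   directionality = sm$cells$directionality,
                   label = sm$cells$identity)
fit <- fit_lda(feat)
rank_features(fit)
```

## Cell-cycle analysis

`durations_from_states()` converts per-frame phase labels (as produced by
classifying PCNA nuclear patterns: uniform = G1, punctate = S, cleared
puncta = G2, PCNA-negative = M) into phase durations. A run's duration is
its frame count times the frame interval; only runs bounded on both sides
by a different known phase are reported (edge runs are censored, not
imputed), unknown frames inside a run are absorbed, and consecutive known
phases must follow G1 → S → G2 → M → G1. The total cycle is the time
between two successive M→G1 transitions, the between-mitoses convention.
Durations are quantised at the frame resolution (5 min), so round trips
through the generator agree within one frame per boundary.

`onset_phase()` maps the label at migration initiation to the two-colour
FUCCI classes (G1 versus S/G2, with M grouped into the geminin-positive
class). `fit_mixture()` fits one- and two-component Gaussian mixtures by
EM (10 seeded restarts, variance floor 1e-3 h² against degenerate
components) and selects k by BIC; the minor component's weight quantifies
the leader-like subpopulation in follower phase-duration distributions.
The published analysis reports histograms and peak proportions without
naming a method; the mixture fit is this package's operationalisation.

`auto_compare()` reproduces the normality-gated test-selection procedure:
every group is tested with the d'Agostino–Pearson K² omnibus test
(implemented from the published formulas; groups below n = 8, where K²
is undefined, gate on Shapiro–Wilk alone) followed by Shapiro–Wilk, both
at α = 0.05. All groups normal → unpaired two-tailed t-test (two
groups) or one-way ANOVA; otherwise Mann–Whitney U (two groups) or the
Brown–Forsythe and Welch ANOVA pair (the Welch p is reported as primary,
the Brown–Forsythe F* alongside). Its type-I error under a normal null
is verified to stay near the nominal 5%.

## Synthetic data

`generator_config()` carries the published summary statistics as
generator defaults: leader phase durations G1 3.2 ± 0.6 h, S
8.7 ± 1.3 h, G2 1.6 ± 0.4 h, M 0.6 ± 0.1 h; follower G2/M
1.5 ± 0.3 / 0.5 ± 0.1 h; follower G1 and S as two-component mixtures
whose minor components (26% and 31%) coincide with the leader peaks;
onset-in-S probabilities 0.79 (leaders) and 0.23 (followers, i.e. 77%
start in G1); division areas 102 ± 20 / 72 ± 9 µm² (asymmetric) and
87 ± 27 µm² (symmetric); and a Notch-inhibited variant in which all
cells draw from a single follower-like component with the dispersion cut
to 1.42 h (G1) and 1.38 h (S). Only means and SDs are published, so all
draws are truncated normals (> 0); this distributional form is an
assumption. The follower mixture majors are derived, not published: the
G1 major (8.9, 1.13) makes the 0.26/0.74 mixture reproduce the printed
overall 7.4 ± 2.7 h, and the S major mean 2.76 h reproduces the printed
overall mean 4.6 h (the printed overall SD of 2.8 h is not exactly
attainable with the published component constraints — the chosen major
SD of 1.0 gives 2.96 h).

Synthetic tracks are biased random walks at the 5-minute cadence whose
per-frame direction blends a ventral unit vector (weight = ventral bias)
with a noisy heading; leaders are faster, more biased and straighter.
The generator emulates the identity contrasts and sampling of the in
vivo tracks, not imaging noise, segmentation error, drift, or cell
divisions — passing tests therefore demonstrate that the pipeline
recovers known structure at realistic effect sizes and sample sizes, not
that it is robust to real imaging artefacts.

## Numerical choices and limitations

Problem sizes throughout the test suite are chosen to make the checks
sharp but quick: 50 seeded replicates per migration condition, 20
replicates per sweep combination, n = 200 per mixture fit with 100
repetitions, n = 10⁴ for generator-moment checks, and 1000 simulations
for the type-I calibration. Ties in feature ranking break
alphabetically; coincident cell centres take a seeded random escape
axis; degenerate mixture components are refloored rather than dropped.

Known limitations: the mechanics are 2D with isotropic discs, there is
no cell division or identity re-selection inside the simulator
(identities are inputs, as in the source model), the corridor is a
simple rectangle, and the force laws are phenomenological
reconstructions — quantities that depend on their exact form (such as
which and how many sweep combinations match) are calibration-dependent,
and only the qualitative contrasts between chain architectures should be
compared against data.
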