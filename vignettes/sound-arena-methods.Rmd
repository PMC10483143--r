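---
title: "The sound arena: model, readouts and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The sound arena: model, readouts and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(soundarena)
```

## The paradigm

The sound arena couples an animal's position to its acoustic environment.
A square open field (44 × 44 cm floor, 30 cm walls) is filmed from above at
20 fps and partitioned by its midlines into four virtual quadrants. Each
quadrant carries a *role*: Q1 is silent, Q2–Q4 each carry one pure tone
(ultrasound condition 20/24/28 kHz at 70 dB SPL; audible condition
8/12/16 kHz at 50 dB SPL — mice hear from roughly 1 kHz up past 80 kHz with
peak sensitivity near 20 kHz, where their social vocalizations live). A
session is 5 min of habituation — no sound whatever the animal does — then
30 min of exposure during which the tone assigned to the occupied quadrant
plays, and nothing plays while the animal sits in the silent quadrant. An
animal that finds the tones aversive can behaviorally "turn them off" by
relocating; time in the silent quadrant is therefore the assay's primary
readout of auditory avoidance.

Roles are deliberately decoupled from physical corners. The silent
quadrant's location (and, by default, the three tone placements too) is
randomized between animal pairs and held fixed within a pair, so innate
place preferences cancel at the cohort level. `counterbalance_assignments()`
implements this with balanced blocks of four: over any multiple of four
pairs, the silent role occupies each corner equally often; a remainder
block is sampled without replacement. All analysis is reported in role
space.

## Conventions and the closed-loop engine

**Coordinates.** Origin at the lower-left arena corner, units cm, y up.
Pixel input is converted by one linear scale (`px_per_cm`); no image flip
is applied. The config file records this convention.

**Midline ties.** Quadrant assignment uses half-open intervals — `[0, W/2)`
is left, `[W/2, W]` is right, and likewise for y — so the map is total and
deterministic; a point exactly on both midlines belongs to the upper-right
quadrant.

**Debounce.** Centroid jitter at a virtual boundary would otherwise flip
the active tone every frame. A quadrant change takes effect only after two
consecutive frames (100 ms at 20 fps) in the new quadrant: long enough to
absorb single-frame flicker, short relative to any plausible behavioral
time scale. The first position fix confirms immediately so a session never
starts in an undefined state.

**Latency and dropouts.** Actuation latency is modeled as zero (the real
rig's camera-to-speaker delay is a hardware property, not part of this
model), and tone switching is instantaneous on quadrant confirmation. When
the tracker loses the animal the engine holds the last confirmed quadrant —
a real-time controller cannot act on absent data — and analysis excludes
those frames from every denominator.

## Tracking

The bundled tracker is intentionally minimal: threshold segmentation
followed by an intensity-weighted center of mass, with the animal rendered
bright on a dark background (the assay is run in darkness; polarity is a
convention, not a claim about any particular camera). By default each frame
first passes through a 3 × 3 box mean. The kernel is symmetric, so it does
not bias the centroid of an interior blob, but it shrinks isolated
sensor-noise exceedances by a factor of three, which is what makes the
plain threshold usable at realistic noise levels (at a peak signal-to-noise
ratio of 5 the mean tracking error on rendered frames stays below half a
pixel, with no spurious dropouts). Dropout runs of up to 0.5 s are
forward-filled with the last valid position so the engine can keep running,
but remain flagged invalid. None of this attempts to emulate a production
tracker's smoothing or failure modes; it exists so that frame-stack input
has a tested, ground-truthed path into the pipeline.

## Behavioral readouts

For a window `[t0, t1)` the occupancy of role q is the number of valid
frames assigned to q times the frame period, and the fraction is taken over
valid frames only; fractions sum to one by construction.

**Preference index.** Exposure minus habituation time per quadrant, computed
on phase-time *fractions* and expressed in percentage points:
`PI_q = 100 (f_q^exp − f_q^hab)`. The phases differ six-fold in duration, so
subtracting raw seconds would be meaningless; fractions are the only
self-consistent reading, and they give the index its conservation property
`Σ_q PI_q = 0`.

**Time course and AUC.** The habituation phase forms one bin and the
exposure phase is cut into 5-min bins (1 + 6 on the default schedule). The
AUC of a role is the trapezoidal integral of its per-bin fraction against
the bin midpoints in minutes, over the exposure bins only — a constant
fraction f integrates to 25 f fraction·minutes, since the six midpoints
span 2.5–27.5 min. Whether an occupancy AUC should include the habituation
bin or integrate raw minutes is a genuine convention choice; both switches
exist (`binned_timecourse()` exposes the bins; `auc()` takes any role), and
the default — exposure only, fractions — is the one that makes the null
value independent of schedule length.

**Locomotion.** Distance is the sum of Euclidean steps between consecutive
valid frames, each step attributed to its starting quadrant. Steps implying
more than 100 cm/s — several times a mouse's sprint speed — are discarded as
tracking artifacts; the same filter naturally suppresses teleports across
dropout gaps.

## The statistical battery

The assay's designs are small and classical, so the battery wraps R's own
fitters rather than reimplementing them; the test suite checks every path
against independent hand-computed sums of squares.

- `students_t()` is the unpaired pooled-variance two-tailed test by default
  (two groups of 25 give t on 48 df, the pattern the assay's
  silent-vs-tone contrasts report even though the two summaries come from
  the same animals); a paired variant is available.
- `one_way_anova()` is the classical between/within decomposition with
  Tukey's studentized-range post-hocs. Note the four quadrant fractions of
  one animal are compositional — they sum to 1 and are not independent.
  The test is nevertheless run on them as is standard for this assay; the
  caveat travels in the result's `notes` field rather than being silently
  "corrected".
- `two_way_rm_anova()` handles the fully-within genotype-free designs
  (role × time-bin per animal): each effect is tested against its own
  subject-by-effect stratum. Sphericity is uncorrected by default, matching
  the commercial defaults such analyses are usually run under;
  `gg = TRUE` applies the Greenhouse–Geisser epsilon, computed from the
  covariance of orthonormalized within-subject contrasts.
- Summaries are mean ± 95 % t-based CI; 95 % is chosen as the overwhelming
  convention where the level is otherwise unstated.

## Simulators: what they emulate, and what they do not

Two generators exist on purpose.

**The agent model** (`simulate_agent()`) is a correlated random walk:
per-frame gamma step lengths (mean `mean_speed_cm_s / fps`, shape
`speed_shape`), wrapped-normal turning with SD `turn_sd_rad`, reflective
walls, started at the arena center where the animal is placed. The engine's
debounced quadrant logic runs inline, and while a tone is on — and the
session time has passed the first tone exposure plus `onset_latency_s` —
the heading resets toward the silent quadrant's centroid (plus noise) with
probability `avoidance_strength / fps` per frame. This is the simplest
mechanism that produces the avoidance phenotype class: silent-quadrant
enrichment that can emerge with a delay, with locomotion concentrated where
the animal spends its time. Defaults (4 cm/s mean speed, shape 2, turn SD
0.3 rad/frame) give open-field-plausible tracks: roughly 7,000–8,500 cm
traveled per 35-min session and a stationary distribution symmetric across
quadrants, so unbiased agents occupy each quadrant at 25 % in expectation.
The packaged `ko` profile (`inst/extdata/profiles.yaml`: avoidance 0.2/s,
onset latency 300 s) lands mean silent-quadrant exposure occupancy in the
mid-40s percent range; the `wt` profile is the same walker with avoidance
zero. Tuning constants live in the YAML, not in code.

**The dwell model** (`simulate_dwell()`) trades realism for exact control:
quadrant residencies are exponential with mean `mean_dwell_s`, successive
roles are drawn independently from the requested occupancy vector (so the
stationary distribution *equals* that vector, self-transitions merely
extending a dwell), and within a quadrant the position is a small folded
random walk. It exists for estimator-recovery tests: the pipeline's
occupancy estimate must converge to the generative vector as sessions
accumulate. At the default 15-s mean dwell a single 30-min session has a
silent-fraction standard deviation of about 5–6 percentage points, so
recovery checks average 50 sessions, which brings the Monte-Carlo error
under one point. The 15-s default is of the order of the agent model's own
quadrant residency under the default movement parameters.

Neither generator claims biological realism: there is no thigmotaxis, no
grooming or rearing, no inter-individual variability beyond the seed, no
habituation-phase novelty dynamics, and dwell-model positions jump between
quadrants. Passing tests therefore certify the *pipeline* — geometry,
gating, bookkeeping, estimators, statistics — not any claim about real
mice.

## Problem sizes and numerical choices

The test suite and the benchmark script size their simulations for a
desktop run: the null-baseline check averages 100 five-minute agents;
recovery checks average 50 full dwell sessions; the type-I calibration of
the one-way ANOVA (rejection rate 5 % ± 2 % at α = 0.05) uses 1,000 null
cohorts of 4 × 6 sixty-second dwell sessions — the rejection-rate property
is scale-free in session length, so short sessions serve. Oracle
equivalences (sums of squares, occupancy tallies, distance sums) are exact
to 1e-9 on random fixtures. All generators accept a seed, restore the
caller's RNG state, and fan per-session child seeds out of one master seed
by counter, so enlarging a cohort never reshuffles earlier sessions and
every pipeline run is bit-reproducible.

Degenerate inputs are handled explicitly: a fully constant one-way design
returns F = 0 rather than 0/0; zero within-group variance with real
between-group spread is refused as degenerate; empty analysis windows,
incomplete repeated-measures cells (named by subject and cell), time
regressions, and out-of-bounds or uncalibrated coordinates all raise typed
errors naming the offending quantity.

## Known limitations

- The engine models zero actuation latency and instantaneous tone
  switching; a physical rig adds camera, processing and speaker delays.
- The tracker assumes a single bright blob; it is not a multi-animal or
  pose tracker and has no occlusion handling.
- The repeated-measures layer requires complete balanced designs; animals
  with missing cells must be excluded upstream (as is standard for this
  analysis) rather than modeled.
- Compositional occupancy fractions are analyzed as published; a
  log-ratio reanalysis would be the principled alternative and is out of
  scope.
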