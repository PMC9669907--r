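---
title: "Simulating and measuring team coordination in a cooperative herding game"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating and measuring team coordination in a cooperative herding game}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(herdcomm)
```

`herdcomm` models a four-person cooperative herding task — three embodied
ground players and one drone operator with a veridical map but no physical
presence — and computes the coordination measures such experiments use:
talk-time magnitudes, categorical recurrence statistics of who-is-speaking
series, search-area overlap, and the repeated-measures / mixed-model
inference layer. This vignette documents the model, the parameters that
matter, the choices made where the design was genuinely open, and what the
synthetic data can and cannot tell you.

## The herding world

Target agents (TAs) are 1 kg point masses on a 500 × 500 m plane with the
containment circle (5 m radius) at the origin. Every second each TA receives
a fresh Brownian force — magnitude uniform on [0, 60] N, direction uniform —
held constant between resamples (a zero-order hold, matching a 1 Hz forcing
rate inside a 90 Hz server tick). A ground avatar within the 10 m threat
radius adds a repulsion directed straight away from the avatar with
magnitude `min(450, 450/d)` N. The game description pins the cap (450 N) and
the inverse-distance law but not the constant; we use a single-constant
kernel `k/d` with `k = 450` N·m so the cap engages at and below 1 m, and
expose `k` as `sim_params(repulsion_k=)`. Integration is semi-implicit Euler
at 90 Hz: `v ← v + (F/m)Δt` with the speed then clamped to 10 m·s⁻¹, and
`x ← x + vΔt`. There is no drag; the velocity clamp is the only dissipation,
consistent with forces applying "until terminal speed". With several
pursuers the per-player forces are summed before the clamp — the cap applies
per source and to speed, not to the summed force.

Three boundary cases are not fixed by the task description and are package
choices:

* **Field edge.** Reflective at ±250 m. Reflection keeps agents in-field
  without creating absorbing corners.
* **Coincident player and TA.** The repulsion direction is undefined at
  distance zero; we push at the capped force in a uniform-random direction
  drawn from the trial RNG.
* **Dynamics inside the containment circle.** Unstated, but decisive: a
  60 N Brownian kick on a 1 kg body reaches the 10 m·s⁻¹ cap within a tick,
  so freely forced TAs would leave the 5 m circle far too fast for any team
  to hold all of them there for the required 5 continuous seconds.
  Contained TAs are therefore docile: Brownian forcing is suppressed and
  velocity zeroed while inside the circle. Player repulsion still applies,
  so a careless avatar can knock a contained TA back out.

Trials follow the 2×2×2 within-team design: 9 or 18 TAs, clear visibility
or fog, and an optional late-spawn perturbation in which one extra TA
appears at a uniform-random time inside the final 90 s — or as soon as all
original TAs are contained, whichever comes first (its spawn location,
unstated in the task description, re-uses the uniform-disc spawn rule and
the trial RNG stream). TAs spawn uniformly within 180 m of the centre,
players within 100 m. A trial succeeds when every TA has been contained for
5 continuous seconds and otherwise fails at the 300 s ceiling, which is
also the duration recorded for failed trials.

## The scripted players

The original task was played by humans; synthesis needs a stand-in policy.
Each ground avatar moves at 10 m·s⁻¹ (5 m·s⁻¹ in fine control) and follows
a two-mode rule:

* **Search.** With no TA in sensing range, head for the current waypoint;
  on arrival draw the next. Under clear visibility waypoints are drawn in
  the player's own 120° sector — a clean division of labor coordinated by
  sight. Under fog the player has no visual basis for holding a partition
  and draws waypoints over the whole spawn disc. This single change is what
  makes fog trials produce larger search overlap.
* **Drive.** With TAs visible (sensing radius 150 m clear, 10 m fog — fog
  acts on the policy only through this radius), chase the nearest TA not
  already claimed by a closer visible teammate, steering for a *drive
  point* a standoff distance (default 3 m) behind the TA on the side away
  from the containment centre, leading the TA's motion by half the closing
  time. A player on the wrong (centre) side of the TA flanks tangentially
  around the threat radius rather than shoving the TA outward. Within 6 m
  of the TA the avatar drops to fine-control speed.

The operator has no physical embodiment; their influence exists only in the
speech channel below. Fog never changes the simulator physics.

## The speech generator

Each of the four speakers is an alternating-renewal on/off process at
30 Hz. Dwell times are geometric, so a speaker with mean utterance length
`m_on` and target talk proportion `p` gets mean silence `m_on(1−p)/p` and
converges to `p` exactly in the long run. Per-condition targets default to
the observed condition means of the modelled experiment (e.g. operator 0.63
under fog with 18 TAs and no perturbation versus 0.47 clear; ground players
0.19–0.24 throughout), with the reported SDs used as truncated-normal
between-trial jitter. Two interaction parameters give the series
conversational structure:

* `coupling` ∈ [0, 1] multiplies a silent speaker's onset hazard by
  `1 − coupling` while anyone else is speaking (turn-taking inhibition;
  default 0.3). Raising it suppresses simultaneous speech monotonically; it
  also drags realized proportions slightly below their nominal targets,
  uniformly across conditions.
* `response_hazard_boost` raises ground-player onset hazards (default
  ×2) for 1 s after the operator stops speaking, producing
  instruction–response sequencing.

Mean utterance length is role- and visibility-dependent: 0.8 s for ground
players, and 1.2 s (clear) versus 2.0 s (fog) for the operator, reflecting
the longer directive utterances of an operator guiding blind teammates.
Longer utterances lengthen speaking runs, which is what the determinism
statistic below responds to.

## Event coding and catRQA

Speaking series are integer-coded at three levels: operator (1 = speaking,
0 = silent), ground (player k alone → k, none → 0, two or more → 4,
operator ignored) and team (operator alone → 1, ground k alone → k+1, any
two or more speakers → 5). Which physical player gets which identifier is
irrelevant to the statistics — label permutations leave %REC and %DET
unchanged, and a test asserts this. Before recurrence analysis every
silence frame is rewritten with its own unique code so silence can never
recur; a deterministic decreasing negative counter implements the
"random non-repeating" requirement, because non-repetition is the only
property the analysis needs and determinism keeps trials replayable.

Recurrence is exact code equality (embedding dimension 1, delay 1, no
radius). Conventions the literature leaves to the implementer, fixed here
and exposed as parameters:

* the trivially recurrent line of identity is excluded from numerator and
  denominator, so %REC = 100·n_rec/(n²−n);
* minimum diagonal line length 2 for %DET;
* %DET of a plot with no recurrent points is defined as 0 rather than NaN,
  so condition averages never silently drop trials.

One consequence worth knowing: under the maximal-run convention a constant
series does not reach %DET = 100 exactly, because the two length-1 corner
diagonals of the plot fall below the minimum line length; %DET approaches
100 as the series grows. The implementation is an O(n²)-time, O(n)-memory
compiled diagonal scan, verified point-for-point (counts, percentages and
the full line-length histogram) against a brute-force double-loop oracle.

## Search polygons and overlap

Avatar trajectories are decimated to 5 Hz with the first second discarded
(a 300 s trial yields 299 s × 5 Hz = 1495 points; the final instant is
treated as an exclusive endpoint). The search polygon is an alpha shape:
Delaunay triangles whose circumradius exceeds a probe radius are discarded,
and the radius is shrunk by bisection (relative tolerance 10⁻³) to the
smallest value at which the surviving complex is still one edge-connected
piece touching every triangulated point. If no radius passes, the convex
hull is used and flagged (`convex_hull_fallback`). Interior voids are
reduced to the outer boundary and flagged per trial; whether such holes
should count as "searched" is genuinely ambiguous, and filling them keeps
the overlap proportion conservative. Overlap is the union of the three
pairwise intersections (triple-covered ground counts once) divided by the
union of all three polygons, computed with exact polygon clipping; a
1 cm grid-rasterisation oracle agrees to within 1% on random triples.

## Inference

Because every factor has two levels, each of the seven within-team effects
reduces to a paired t-test on the per-team effect contrast, and F = t² with
df (1, n−1) — the implementation computes exactly that and is checked to
10⁻¹⁰ against `aov` error strata. Sphericity is vacuous at two levels, so
every Greenhouse–Geisser ε is reported as 1 and corrected p equals raw p.
Partial η² is F/(F + df_den). Contrasts smaller than accumulated rounding
error are reported as exactly F = 0 rather than as a ratio of numerical
noise. When a team contributes several trials per cell they are averaged
first — the aggregation is not dictated by the design and the mean is the
exposed default. Multiple trials feed the mixed model instead: a
random-intercept-per-team regression of performance on each communication
measure, fitted by maximum likelihood (not REML, so the R² difference
underlying Cohen's f² compares like with like), with Wald z and 95% CI for
the communication coefficient and f² = (R²_full − R²_reduced)/(1 − R²_full)
using squared fitted–observed correlations. Outcomes are analyzed
untransformed, ceiling effects and all.

## The synthetic study and what it shows

`run_experiment()` simulates the default study: 10 teams × 8 cells × 2
trials (160 trials, ≈1 minute of compute), per-trial child seeds derived
arithmetically from the master seed so any trial can be replayed in
isolation, and trial order given by a seeded shuffle shared across teams by
default (matching a final-session design in which all teams played one
random order). On the defaults the study reproduces the directional
structure of the modelled findings: fog raises operator %REC/%DET, team
%REC/%DET, operator talk time, search overlap and trial duration, and
lowers ground-player %REC and containment rate. One detail is worth
flagging: the printed condition means we adopt as generator targets have
ground players talking slightly *less* under fog, so that is the direction
the synthetic study asserts for ground talk time.

These recoveries validate the pipeline, not the psychology: the fog effects
on communication are built into the generator targets, and the fog effects
on movement follow from the policy's sensing radius and waypoint rule. What
the synthetic data cannot exhibit: lexical content and addressees, human
motor variability and learning across sessions, genuinely emergent
conversational adaptation, or the empirical effect magnitudes — only their
signs. Tests therefore assert orderings and oracle agreement, never
reproduction of empirical F values.

## Numerical and scale choices

Problem sizes in the test suite are chosen to exercise every code path at
desk scale: recurrence oracles on 200 random series up to length 200,
overlap oracles on 50 polygon triples at 1 cm resolution, Monte-Carlo
calibration of the generator over 100 × 300 s trials (realized proportions
within ±0.02 of target at zero coupling), type-I calibration of the mixed
model over 100 null replicates, and one full default study for the
directional pattern. Bisection tolerances are 10⁻³ relative for the alpha
radius and 0.01 m for the repulsion-onset probe; polygon clipping snaps at
the clipper's integer scaling; all randomness flows through R's RNG,
including inside the compiled simulation and speech loops, so a single
`set.seed()` reproduces any object bit-for-bit.
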