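# herdcomm

Team coordination and communication dynamics in a cooperative multiplayer
herding game.

`herdcomm` is an end-to-end synthetic pipeline for studying how four-person
teams — three embodied *ground players* plus one map-reading *drone
operator* — coordinate speech and movement while corralling evasive targets.
It is aimed at researchers in team cognition and coordination dynamics who
want a fully seeded, tested stand-in for gameplay telemetry and
voice-activity data, together with the measures and models used to analyze
such experiments.

The package contains:

* **An agent-based simulator of the herding task.** Target agents (TAs) of
  mass 1 kg roam a 500 × 500 m field under Brownian forcing (uniform 0–60 N,
  resampled at 1 Hz) and flee players inside a 10 m threat radius with an
  inverse-distance repulsion *F(d) = min(450, 450/d)* N, both capped at a
  terminal speed of 10 m·s⁻¹. Trials follow a 2×2×2 within-team design —
  target number (9 vs 18), visibility (clear vs fog), late-spawn
  perturbation (none vs one extra TA in the final 90 s) — at a 90 Hz tick,
  with a 300 s ceiling and success after 5 continuous seconds of full
  containment in the central 10 m circle. A scripted search-and-drive policy
  stands in for human play; fog narrows its sensing radius from 150 m to
  10 m.
* **A coupled speech generator.** Per-speaker binary speaking series at
  30 Hz from an alternating-renewal (on/off) process whose talk-time targets
  are condition- and role-dependent, with a turn-taking inhibition parameter
  and an operator→ground response boost.
* **Categorical recurrence quantification (catRQA).** Event coding at the
  operator, ground-player and team levels, silence recoding with unique
  non-recurring codes, and recurrence statistics
  %REC = 100·|{(i,j): i≠j, cᵢ=cⱼ}| / (n²−n) and %DET, the share of
  recurrent points on diagonal lines of length ≥ 2 (repeated communication
  sequences).
* **Division-of-labor geometry.** Alpha-shape search polygons per player
  (Delaunay complex pruned by circumradius, bisected to the tightest single
  polygon; convex-hull fallback) and the overlap proportion: area covered by
  ≥ 2 players over the team's total search area.
* **The inferential layer.** 2×2×2 repeated-measures ANOVA (F, partial η²,
  Greenhouse–Geisser ε, Bonferroni helper) and the random-intercept mixed
  regression *yᵢ = β₀ + f(Xᵢ, β_X) + z β_z + uᵢ + εᵢ* with Wald z, 95% CI
  and Cohen's f² for the communication term.

## Worked example

```r
library(herdcomm)

design   <- condition_design(9, "fog", "none", seed = 42)
trial    <- run_trial(design)
trial
#> <trial_record> 9 TAs, fog, none: failure in 300.00 s (2/9 contained)

activity <- generate_activity(trial$duration, design, seed = 42)
activity
#> <speaker_activity> 300 s at 30 Hz; talk proportions operator=0.70
#>   gp1=0.13 gp2=0.24 gp3=0.28

catrqa_trial(activity, "team")
#> <rqa_result> n=9000: %REC=28.797 %DET=98.937 (23323274 points)

trial_overlap(trial)$overlap
#> <overlap_result> overlap 48920.06 / total 71101.31 m^2 = proportion 0.688

containment_rate(trial)
#> [1] 0.006666667
```

Under fog this team fails at the 300 s ceiling with 2 of 9 TAs contained
(containment rate 0.0067 TAs/s); the operator dominates the conversation
(70% talk time vs ~20% per ground player), the team-level communication is
highly recurrent and deterministic, and the ground players' search areas
overlap heavily (69%) because they cannot see far enough to partition the
field. A clear-visibility run of the same seed typically succeeds in
200–260 s with overlap below 30%.

A full synthetic study (10 teams × 16 trials, ≈1 minute) with its ANOVAs and
mixed regressions:

```r
ex <- run_experiment(experiment_config(master_seed = 1))
summarize_experiment(ex)          # condition means ± SE, long format
analyze_experiment(ex)            # effect tables + mixed-model results
write_experiment(ex, "results/")  # tidy CSV/JSON bundle
```

A thin command-line front-end with `simulate` / `analyze` / `summarize` /
`all` verbs lives at `inst/scripts/herdcomm-experiment.R`:

```sh
Rscript inst/scripts/herdcomm-experiment.R all --seed 1 --out results/
```

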