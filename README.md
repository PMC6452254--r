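# embodysim

A desk-scale R simulator of **embodied behaviour emergence** and **early
(fetal) sensorimotor development**. Two model families share one
principle: independent per-muscle controllers become functionally coupled
*only* through the physics of a shared body and its environment.

* **Insect robot.** A planar disc with 12 radially symmetric spring-loaded
  legs, each driven by its own chaotic map unit iterating
  `f(x) = 1 − αx²` (chaotic for `α ≥ 1.4011`) inside its sensory–motor
  loop, with weak self-feedback and mean-field input mixing. Legged
  locomotion and adaptation to walls emerge within seconds without
  learning, reward, or any inter-unit wiring.
* **Fetus model.** A sagittal 11-segment musculo-skeletal chain with 20
  antagonist muscles, 300 skin taxels and muscle proprioceptors, driven by
  independent Bonhoeffer–van der Pol (FitzHugh–Nagumo) oscillators — one
  per muscle, no cross-connections — inside a fluid-filled elastic uterus
  or on a flat plane under gravity. Receptor streams feed a scaled spiking
  cortical sheet (leaky integrate-and-fire neurons, 5:1
  excitatory:inhibitory, spike-timing-dependent plasticity) that
  self-organizes somatotopic body maps; a Hebbian tactile→motor spinal
  loop closes the developmental circle.

Analysis metrics include map Lyapunov exponents, phase-locking values
(PLV), detrended fluctuation analysis, jerky-movement and hand–face
contact event rates, and cortical response segregation and
multimodal-integration indices.

## Worked example: emergent locomotion and chaos onset

```r
library(embodysim)

# boundary of chaos of the controller map, found by bisection on the
# Lyapunov exponent sign
chaos_onset_alpha(1.3, 1.5)
#> [1] 1.401172

# one robot, one seed: chaotic controller, open plane
body <- build_insect_body(n_legs = 12, K = 0.08)
env  <- environment_spec("walled_arena", arena_half = Inf)
set.seed(200)
ctrl <- chaotic_controller(12, alpha = runif(12, 1.55, 1.85),
                           eps_self = 0.05, eps_mix = 0.02)
tr <- simulate_embodied(body, env, ctrl, duration = 60,
                        control_dt = 0.1, seed = 2)
xy <- tr$states[, 1:2]
sqrt(sum((xy[nrow(xy), ] - xy[1, ])^2))   # net displacement (m)
#> [1] 0.8358794

# inter-leg phase-locking value stabilizes within a few seconds
pl <- plv_timecourse(tr$u, window = 20, step = 10)
round(head(pl$plv, 6), 2)
#> [1] 0.73 0.99 0.99 0.99 0.98 0.99
```

The displacement of a passive robot is exactly zero (no controller, no
force), so any sustained displacement is emergent locomotion. The PLV
trace shows the inter-leg phase pattern settling — the same quantity that
collapses and re-forms when the robot hits an arena wall
(`run_wall_adaptation()`).

The developmental experiments are driven the same way:

```r
rep <- run_bodymap_experiment(seeds = 1:10, duration = 100)
rep$summary$p_value        # paired test: intrauterine > extrauterine
```

A command-line driver for all five experiment families is installed at
`inst/scripts/embodysim-cli.R`
(subcommands `insect-locomotion`, `wall-adaptation`, `bodymap`,
`multimodal`, `closedloop`; flags `--seed`, `--seeds`, `--outdir`,
`--config`, `--export-csv`, `--full`).

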