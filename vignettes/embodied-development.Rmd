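---
title: "Embodied emergence and fetal sensorimotor development: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Embodied emergence and fetal sensorimotor development: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(embodysim)
```

## What this package simulates

`embodysim` is a desk-scale simulator of two linked ideas from
developmental and embodied robotics:

1. **Behaviour can emerge without a controller that encodes it.** A bank
   of chaotic map units, one per actuator, with *no* signal connections
   between them, becomes functionally coupled through the physics of a
   shared body. Exploration (the diversifying property of chaos) and
   stabilization (entrainment onto body--environment resonances) are
   properties of the closed sensorimotor loop, not of any module.
2. **The prenatal environment structures the first sensory learning.**
   A simplified fetus, driven by independent per-muscle spinal
   oscillators, evokes tactile and proprioceptive signals whose
   *correlational structure* differs between the buoyant, fluid-filled
   uterus and a flat plane under gravity. A spiking cortical sheet that
   learns these streams acquires segregated body-part representations in
   the former and weaker, blurrier ones in the latter; a closed spinal
   Hebbian loop reproduces qualitative milestones of early motility.

Everything runs from R with compiled (Rcpp) inner loops; no external
physics engine or neural simulator is used, so every run is bit-for-bit
reproducible from a seed.

## The chaotic controller element

Each actuator has one unit iterating the quadratic map `f(x) = 1 - a x^2`,
chaotic for `a` above the band-merging onset at 1.4011 (the package
recovers this boundary by bisection on the orbit-averaged Lyapunov
exponent `mean(log|-2 a x|)`). The unit's input each control tick is a
convex combination of its sensor signal (weight `1 - eps_self - eps_mix`),
its own previous output (`eps_self`, default 0.05) and the mean previous
output of all units (`eps_mix`, default 0.05; the experiment drivers use
0.02). The sensor is the joint angle scaled by `theta_sensor_scale`;
choosing this scale close to the actuator's static deflection keeps the
*closed-loop* effective map inside the chaotic band — too small a scale
saturates the sensor and the loop falls onto a dead fixed point, too large
a scale contracts it below the chaos threshold. This interplay, not the
bare map, is where the behaviour lives.

The experiment drivers draw each leg's `a` uniformly from [1.55, 1.85]
per seed. With identical parameters the mean-field mixing pulls all units
onto the synchronization manifold, where (by the symmetry of the body)
leg thrusts cancel exactly and the robot cannot locomote; heterogeneous
parameters keep the units near, but not on, that manifold, which is what
lets a non-trivial stable phase pattern form.

## The insect robot and its ground model

The robot is a planar disc (top-down view) with 12 radially symmetric
rotary legs (spring constant `K = 0.08` N·m/rad, stroke `L1 = 0.05` m,
natural frequency ~12.7 Hz, damping ratio 0.3). The control tick is
0.1 s — about one map iteration per leg swing, so the body can follow the
map — and physics advances in 1 ms semi-implicit Euler substeps.

Feet interact with the ground by a *press-and-push* grip: the normal load
on a foot is proportional to `max(0, sin(theta))` (the extended foot
presses, the retracting foot is unloaded and slides freely), with
isotropic smoothed Coulomb friction at the contact. We first implemented
a velocity-anisotropic radial friction (more grip sliding outward than
inward) and found it provably inert: with saturated Coulomb friction the
cycle-averaged force per leg is independent of stroke amplitude and
phase, so the radially symmetric sum cancels for *any* leg pattern and
the residual isotropic term only brakes the body. Load modulation makes
per-leg thrust amplitude-dependent, so asymmetric oscillation patterns —
which the chaotic units explore spontaneously — produce net locomotion,
and the body's motion feeds back into every leg's friction torque, i.e.
into every unit's sensor. Locomotion at ~2–5 cm/s emerges within seconds
in most seeds, and the sliding-window phase-locking value (PLV) over the
12 map outputs stabilizes within a few seconds. On first wall contact the
phase pattern is disrupted (PLV drops), reorganizes within seconds, and
the robot leaves in a different direction.

## The fetus model

A sagittal chain of 11 segments (head, two trunk segments, and per side
upper arm, forearm+hand, thigh, shank+foot), 10 rotational joints, and an
antagonist flexor/extensor pair per joint (20 muscles). Segment lengths
and masses are set to plausible 32-week values (total ~1.85 kg,
crown--heel ~0.5 m) and scale linearly (lengths) and cubically (masses)
with gestational age over 24–42 weeks. Joint springs pull toward a
flexed rest posture with the hands near — but not at — the face. Muscle
torque is `sign * activation * tau_max * overlap(theta)` minus viscous
damping, `overlap` a Gaussian length--tension factor. Trunk joints are
weakly actuated (40% gain): with strong trunk muscles the whole upper
body moves as one unit and all receptor channels inherit a common-mode
signal that destroys the modular correlation structure the body-map
experiment depends on.

Joint dynamics are integrated per joint (inertia of the distal subtree
about the joint, precomputed at rest posture); contact forces on any
taxel are propagated as torques to every joint between that taxel's
segment and the root, and as forces to the base. Environments:

* `uterus_fluid` — neutral buoyancy cancels gravity; linear drag on the
  base and rotational fluid drag per joint; an elastic damping membrane
  wall (penalty force on taxels beyond the radius; `fit_uterus()` sizes
  the radius to the body with 8% slack).
* `flat_plane` — gravity on; per-taxel penalty ground contact with
  smoothed Coulomb friction. Contact stiffness is per-taxel (many taxels
  share the load), which bounds rest penetration at about 5–10 mm at the
  1 ms step; a stiffer contact is unstable for the low-inertia distal
  joints at this step size, and we prefer a fixed step over adaptive
  integration for reproducibility.

Skin taxels (default 300) are tagged face/hand/foot/other. The
human-like distribution concentrates 70% of them on face, hands and feet;
the uniform one allocates by segment length. Tactile input is the sum of
contact normal forces, an isotropic fluid term proportional to taxel
speed, a *leading-surface dynamic pressure* term (taxels alternate sides
of each limb; only the side facing the motion feels the flow), and
hand--face self-touch pseudo-contacts (taxel--taxel proximity below the
sum of the segment radii). The directional term matters: speed alone is
unsigned, so tactile activity correlates equally with both muscles of an
antagonist pair and no learned feedback can favour the ongoing stroke.

Spindle length and velocity are affine in joint angle and velocity (sign
per muscle), tendon tension is the muscle torque magnitude; a gamma gain
scales the spindle (not tendon) afferents.

## The spinal oscillators

Each muscle has its own Bonhoeffer--van der Pol (FitzHugh--Nagumo)
oscillator, `dv/dt = c(v - v^3/3 - w + I)`, `dw/dt = (v + a - b w)/c`
with the classic `a = 0.7, b = 0.8, c = 3` (of the many
parameterizations in the central-pattern-generator literature we adopt
the standard one). Zero drive rests at `v = -1.1994`; constant drive in
roughly (0.33, 1.4) yields a limit cycle. A `rate` factor of 4 maps one
cycle to ~2.4 s, a slow fetal movement cycle, and per-muscle rates are
jittered ±20% so limbs are not artificially synchronized. Oscillators are
initialized at independent random phases sampled along the attractor —
perturbing `v` alone is not enough, since a relaxation oscillator
collapses such perturbations back to the same phase within a cycle.
Muscle activation is a clipped linear squash of `v`. There are no
cross-muscle connections anywhere; all coordination is embodied.

## Receptor coding and the cortex

Receptor streams are *phasic*: each channel's rectified deviation from an
exponential running mean (time constant 1.5 s), scaled by the joint 95th
percentile. This models receptor adaptation and is essential: the fluid
environment produces strong tonic activity on every taxel, and pair-based
STDP integrates rate *products*, so with tonic coding the fluid condition
potentiates everything indiscriminately and no correlational contrast
survives. Channel values map to inhomogeneous Poisson spikes at up to
100 Hz.

The cortex is a unit-square sheet (default 1998 neurons — requests are
rounded down to a multiple of six so the excitatory:inhibitory count
ratio is exactly 5; spec-level "2000" is realized as 1998), 70%
somatosensory / 30% visual territory, Gaussian distance-dependent random
connectivity plus a small uniform long-range probability, lognormal
excitatory weights, fixed inhibitory weights (Dale's principle; only
E→E synapses are plastic). LIF parameters are standard (tau_m 20 ms,
15 mV threshold gap, 2 ms refractory, exponential synaptic currents).
Background Poisson noise with lognormal per-neuron amplitude produces
2–8 Hz resting activity whose log-rates are much closer to normal than
the raw rates, positive mean depolarization, and matched E/I population
rates.

Afferents: each channel projects to 10 neurons of its body-part cluster
*and* to 12 weak diffuse targets anywhere on the sheet ("exuberant"
projections). All afferent synapses start weak, so probe responsiveness
is substantially a *product of learning*. Afferent STDP is
potentiation-dominant with a hard cap; recurrent STDP is
depression-dominant (stability). Under the fluid condition's
within-part-correlated streams, a part's channels repeatedly co-drive
their cluster and potentiate strongly and selectively; under the plane's
weaker, globally-shared bursts the same learning is slower and more
diffuse. Probing each part then yields strong, well-separated maps after
intrauterine learning and weaker, more overlapping ones after
extrauterine learning — measured by the segregation index
(1 − mean pairwise cosine of rectified response maps).

## Experiments and their statistics

All condition contrasts are seed-paired (same body, same initial
cortex). Defaults: 10 paired seeds and 100 s learning sessions for the
body-map and multimodal experiments (full-scale 1000 s sessions are
reachable via the CLI `--full` flag); paired one-sided
t-test for the segregation contrast, one-sided sign test for the
multimodal contrast, significance 0.05. The multimodal probe transplants
each trained cortex onto a 40-week body on the plane (the taxel layout is
preserved, so channels remap one-to-one), generates a scripted arm sweep
in front of the eyes, and compares the norm of the combined-stimulus
response to the summed norms of the per-modality responses.

The closed-loop experiment activates many-to-many Hebbian (Oja)
tactile→motor learning. The learned drive splits into an oscillator
component (capped at 0.45 so the total drive stays inside the BVP
oscillation window — beyond the upper boundary the oscillator dies in
depolarization block) and an alpha component applied relative to the
motor-pool mean (reciprocal inhibition; a raw nonnegative drive saturates
every muscle into co-contraction and freezes the body). The feedback
engages after a 40 s warm-up that doubles as the behavioural baseline;
the tactile normalizer rises quickly and decays slowly so a lull in
movement cannot inflate the normalized feedback. Jerk events are brief
angular-acceleration bursts above 60 rad/s² (in this body these are
mostly ballistic strokes arrested at joint limits); hand--face contacts
are "firm" touches (compression beyond 40% of the combined segment
radii), debounced at 1 s. Gains ×1, ×2, ×3 scale the tactile→alpha
pathway linearly pre-squash.

Honest caveats. Two of the developmental effects are only partially
reproduced at this scale, and their acceptance checks are expected to be
red rather than weakened:

* *Multimodal integration.* The cross-modal binding substrate (diffuse
  visual-to-somatosensory afferents plus sparse cross-zone recurrent
  synapses) does not accumulate enough correlated visual--somatosensory
  experience in a 100 s spontaneous-movement session for the
  combined-probe response to become reliably superadditive; with probe
  noise reduced, the index is dominated by response-strength artifacts
  (weak, noise-level responses push the ratio toward its additive
  value). The intrauterine-trained index exceeds the
  extrauterine-trained one in only ~7 of 10 seeds, short of sign-test
  significance.
* *Closed-loop developmental cascade.* The jerk-rate increase after the
  feedback engages is robust (and larger for the human-like taxel
  distribution than for the uniform one), but the hand--face contact
  rate rises in only about half the runs, and the jerk-before-contact
  ordering holds only at some gains: the rare-event (contact) statistics
  of this 11-segment body over a few hundred seconds are too thin for
  the full ordering to be resolved.

## Synthetic fixtures

`synth_receptor_stream()` builds block-correlated Gaussian streams by a
latent-factor construction (global factor + per-block factor + channel
noise), which guarantees a positive semi-definite target and hits the
requested within/between-block correlations within 0.05 at 10^4 samples;
a +3 SD soft floor maps them to nonnegative receptor values with <0.2%
clipping. These fixtures exercise the cortex and metrics layers without
physics; they emulate only second-order correlation structure, so passing
fixture tests says nothing about higher-order temporal structure of real
receptor streams.

`synth_oscillatory_signals()` (sinusoids with fixed offsets and
random-walk phase jitter) calibrate the PLV metric, whose significance
claims use circular-shift surrogates at the 95th percentile throughout.

## Numerical choices and limitations

* Fixed-step semi-implicit Euler everywhere (1 ms physics, 10 ms control,
  1 ms neural); reproducibility over adaptive stepping.
* The Lyapunov estimator clamps visits within 1e-12 of the map's critical
  point to avoid `log(0)` on superstable orbits.
* PLV phases come from an FFT analytic signal (no installed package
  provides a Hilbert transform) or, optionally, zero-crossing
  interpolation; constant channels are flagged, not errored.
* DFA uses first-order detrending over ~12 logarithmic window sizes.
* 2D physics cannot represent out-of-plane motion, left/right limb
  collisions (left and right limbs overlap visually but interact with
  the environment independently), or fluid flow beyond linear drag and
  leading-surface dynamic pressure.
* The cortical sheet has no layers, areas, conduction delays or
  subcortical structures, and no motor output; it is a passive learner
  of receptor streams, probed by stimulation.
* Problem sizes (10 paired seeds × 100 s sessions; 3 seeds × 3 gains ×
  2 distributions × 200 s closed-loop runs; 5–8 insect seeds × 30–90 s)
  are the package's default desk-scale study conditions; all are plain
  function arguments.
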