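---
title: "Models and methods for HS-AFM channel-gating analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods for HS-AFM channel-gating analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(afmgating)
```

# Scope

`afmgating` quantifies ligand-dependent gating of a pentameric membrane
channel (CorA, the bacterial Mg²⁺ channel) in high-speed AFM height movies.
Because no public raw movies exist for this system, the package pairs every
analysis stage with a ground-truthed simulator that emulates the
experiment's imaging physics and gating dynamics; all quantitative tests run
against that simulator. This vignette documents the models, the tunable
parameters and their defaults, the numerical choices, and what the tests do
and do not establish about real data.

# The particle model

Each channel is drawn as five subunit caps on a membrane plane
(`membrane_top_height`, default 5 nm above the support). A subunit at
distance `d` from its center contributes
`h(d) = (H + o_k) exp(-(d/w)^4)` where `H` is the protrusion height
(`base_protrusion`, 7 nm), `o_k` a per-subunit elevation offset, and the cap
width `w` is tied to the outer diameter so a closed particle's half-maximum
footprint is `outer_diameter` (10.9 nm). Caps combine by pointwise maximum,
and an axial pore dip (depth 1.2 nm, lateral scale 1.4 nm, quartic profile)
is carved at the 5-fold axis.

Two calibration decisions deserve comment:

* **Cap shape.** Plain Gaussian lobes of width `ring_diameter/4` produce a
  deep inter-lobe trough: after tip convolution the closed particle would
  show a ~2.5 nm max−min relief in its 5 × 5 nm center window, whereas the
  closed-state ΔHeight signature in this kind of imaging is ~1 nm. The
  super-Gaussian (quartic) cap gives a plateau-like subunit body whose
  tip-convolved center-window relief is ~1 nm with the default pore dip.
  The published dimensional constraints are diameters and heights only, so
  the radial profile is the package's own choice, fixed once against the
  ~1 nm signature.
* **Pore dip.** The dip defaults to 0 for the open-II class: there the
  displaced subunit sits on the symmetry axis and occludes the pore, which
  is what produces the +1.5 nm center elevation (`apex_extra`) that
  distinguishes open-II topographically.

Class geometries: *closed* — all offsets equal, exact 72° symmetry, surface
maximum `membrane + base_protrusion` (12 nm above support with defaults);
*open-II* — one subunit moved onto the axis and raised by `apex_extra`
(1.5 nm); *open-I* — subunit ring contracted to 80% radius with narrower
caps, three adjacent subunits raised by `apex_extra`, two lowered (reduced
lateral extent, elongated elevated footprint); *open-+* — independent random
per-subunit offsets, drawn uniformly from −2.5 to +0.5 nm. The open-+ range
is deliberately below the elevated-apex threshold: the class stands in for
"asymmetric molecules of all kinds, even those without increased height",
with subunits sagging away from the assembly rather than standing up.

# Image formation

Frames are raster-scanned: scan line *i* of frame *f* renders the gating
state at time `f·frame_interval + i·line_time`, so dynamics faster than the
frame time appear as intra-frame mixtures. The finite tip is modeled as
grayscale dilation with a spherical-cap kernel (`tip_radius`, 2 nm): the
imaged height at a pixel is the highest apex position whose cap clears the
surface. Dilation never lowers a pixel, preserves heights at peaks the apex
can touch, and is the identity at zero radius — properties asserted in the
tests against a naive max-over-neighborhood oracle. Scanner drift is linear
(`drift_velocity`, default (0.05, 0.03) nm s⁻¹ — gentle, uncharacterized
drift of the kind routinely corrected away) and vertical noise is additive
Gaussian (`vertical_noise_sd`, default 0.1 nm, a typical HS-AFM height
noise). Sampling defaults are 0.5 nm px⁻¹ and 0.55 s per frame.

# Gating models

Two layers are provided:

* **Continuous-time model** (`gating_model`, `sample_gating`): the channel
  leaves the closed state at `k_off` (Mg²⁺ unbinding) and any open class
  returns at `k_on · [Mg²⁺]_free`, so closed occupancy at equilibrium is
  `c/(c + K_d)` with `K_d = k_off/k_on` (default 2 mM). Open classes
  exchange via a small rate matrix; open-+ sojourns are subdivided at the
  subunit flicker rate with fresh offsets. Free Mg²⁺ follows 1:1 EDTA
  mass balance (conditional `K_d(MgEDTA)` 0.1 mM, appropriate near pH 6,
  configurable); the positive quadratic root is validated against a
  bisection oracle. Paths are sampled exactly (Gillespie) within each
  concentration epoch.
* **Per-frame condition presets** (`condition_preset`, `sample_chain`): the
  occupancy/transition analyses compare frame *n* with frame *n+1*, so the
  four imaging conditions are specified directly as frame-to-frame jump
  chains. Each preset is built from two published summaries — the stationary
  class occupancies π and the aggregate conditional probability ρ that an
  open-class molecule returns to closed on the next frame — by setting
  `P(open_i→closed) = ρ`, distributing the remaining open mass by the
  open-conditional occupancy q, and solving the closed-exit probability from
  global balance (`α = ρ(1−π_closed)/π_closed`). This construction has
  stationary law exactly π and return probability exactly ρ. The headline
  values are: 10 mM — 91% closed; 3 mM — 50% open-+, ρ = 14%; 0 mM —
  ρ = 7%; re-addition of 25 mM — 35% closed. The cells those summaries do
  not pin down (the split among open classes, the closed shares at 3/0 mM)
  were fixed once at plausible values (e.g. open-I = open-II, remainder to
  open-+); note that global balance itself forces the closed share at 0 mM
  to be at least ρ/(1+ρ) ≈ 6.5%, so it is set to 8%.

# ΔHeight traces and idealization

ΔHeight is max − min height in the axis-aligned 5 × 5 nm (10 × 10 px) box
centered on the tracked molecule — exactly offset-invariant, never
interpolated across missing frames. Idealization follows the
step-transition/state-identification pattern: (1) noise is estimated from
the median absolute successive difference (`σ̂ = MAD_diff/(0.6745·√2)`),
robust to steps; (2) recursive binary segmentation accepts the split
maximizing the two-sample t statistic while `t > t_critical` (default 5)
and children hold `min_segment` (2) points; (3) segment means are merged
agglomeratively (duration-weighted centroids) to k levels; (4) the state
count minimizes the description length

DL(k) = (N/2)·ln(RSS_k/N) + (m/2 + k)·ln N,

with m retained change points. A BIC-like half-`ln N` cost per level was
evaluated first and found nearly indifferent between a true level and the
same level split in two (differences < 1 DL unit at the study's step/noise
ratio of 1.5 nm vs 0.2 nm), making model-order recovery seed-dependent; the
`ln N`-per-level cost restores stable recovery (k = 2 chosen on ≥ 95/100
two-level traces, k = 1 on pure noise) while leaving the change-point cost
untouched. The standard pipeline mode nonetheless forces k = 2, mirroring
the analysis convention of reducing all elevated conformations to one
"high" state. Segmentations on traces of ≤ 12 points are tested against
exhaustive enumeration of all equal-order segmentations.

# Dwell times, events, energies

Dwells are maximal constant-label runs; first/last dwells are censored and
excluded from means (the convention is stated rather than prescribed
anywhere; sensitivity is limited because censored dwells are < 10% of events
in the regimes analyzed). One-frame dwells are kept but flagged; no
missed-event correction is applied. Transition events are binned in
half-open 30-s windows and dwell means are smoothed over sliding 20-event
windows. The two-state free energy is `ΔG = −ln(τ_low/τ_high)` k_BT
(−0.69 k_BT for 60 s vs 30 s, printed as −0.7). Parameter recovery is tested
at rates (1/60, 1/30) s⁻¹ sampled at 0.55 s over 25 molecules × 1220 frames
(both means within 15%).

# Conformational classification

Manual state assignment is operationalized as a fixed decision list over
five features computed on a lightly smoothed patch (Gaussian σ = 0.75 nm;
smoothing makes the symmetry correlation reflect structure rather than
pixel noise): S5 (mean Pearson correlation with the four 72°·k rotations
about the particle center), apex height above the local membrane, apex
offset from the center, prominent-lobe count, and elevated-footprint
eccentricity. Three implementation details matter in crowded patches:

* **S5 domain.** Over a full patch the radially symmetric pedestal and
  membrane dominate the correlation and every class scores > 0.87; S5 is
  therefore evaluated over a centered 5-nm-radius disk covering the subunit
  ring, where asymmetric subunit rearrangements dominate the variance.
* **Membrane reference.** The local membrane is a low quantile (20%) of an
  annulus at 1.2–1.5× the outer radius; a median would be biased upward by
  neighboring particles clipping the annulus at ~14 nm packing.
* **Centering.** The rotation axis must sit within about half a pixel of
  the symmetry axis, so the supplied center is refined on the particle
  body's center of mass (accepting only small corrections, since a strongly
  asymmetric molecule legitimately has off-axis mass). Detection centroids
  similarly iterate over a disk that extends past the pedestal edge: on the
  tip-convolved plateau itself the gated weights carry no centring gradient.

The decision list (order matters): closed if `S5 ≥ 0.88` and apex below the
elevated threshold; open-II if the apex is elevated and within 0.9 nm of the
center; open-I if the apex is elevated with ≤ 3 lobes and footprint
eccentricity ≥ 0.6; otherwise open-+. The thresholds are calibrated on
simulator render feature distributions under the default noise (closed S5
≥ 0.95 vs ≤ 0.78 for all other classes; measured apexes — which sit below
their geometric values because of smoothing and the membrane reference —
separate at 7.3 nm with ≥ 0.7 nm margins on both sides). On noiseless
canonical renders the confusion matrix is the identity; through the full
pipeline at the 3 mM preset the per-frame confusion against ground truth
was also exact in a 1200-frame check.

Occupancies average per-molecule class fractions and report the s.e.m.
across molecules (matching error bars computed across molecules);
transition matrices are row-normalized so the open→closed "return
probability" reads as a conditional probability.

# Titration

A molecule is "dynamically asymmetric" when any 10-frame window is at least
half non-closed (the underlying definition is visual; both the window and
the fraction are configurable). Condition-level fractions carry binomial
standard errors and are fitted by weighted least squares to
`f(c) = 1 − cⁿ/(cⁿ + K_dⁿ)` with Hill n fixed to 1 by default — the channel
binds multiple Mg²⁺, so a free n is available but not the default, since
only an apparent K_d is being estimated. Confidence intervals are parametric
bootstrap over particles. Recovery tests: K_d within 25% from 7
concentrations × 100 particles; median within 5% at 500 particles/condition.

# Rod mechanics

TM1 (contour length `L` = 11 nm) is treated as a semiflexible rod with the
typical α-helix persistence length `L_p` = 100 nm. For uniform circular
curvature the elastic energy integral reduces to `E(r) = L_p·L/(2r²)` k_BT,
inverted exactly by `r(E) = √(L_p·L/2E)`; at 1 k_BT, r = 23.45 nm (~23 nm).
End deflection is reported in the circular-arc convention
`d = r(1 − cos(L/r))` = 2.53 nm by default, with the small-angle form
`L²/2r` = 2.58 nm as an option — the two agree within 5% at L/r ≈ 0.47, and
both round to the ~2–3 nm scale of subunit displacement seen in the movies.
Results are printed at one significant figure when quoted against "~"
estimates.

# Problem sizes and reproducibility

Condition-level analyses use 20-molecule patches over 100 frames (2000
molecular snapshots, matching the scale of "~20 molecules in ~80–100
frames"), and 120 frames where ≥ 2000 frame-to-frame pairs are wanted for
transition statistics. Dwell recovery uses 25 molecules × 1220 frames.
Monte-Carlo assertions fix their seeds; the simulator is exactly
reproducible (same seed ⇒ byte-identical movie). The acceptance script
derives all of its randomness from a single `--seed` argument.

# Limitations

* The simulator emulates geometry, gating kinetics, tip convolution, drift
  and Gaussian noise — not cantilever feedback artifacts, parachuting,
  line noise, scars, tip asymmetry/double tips, or molecular diffusion and
  rotation within the lattice. Passing tests therefore demonstrate the
  correctness of the analysis chain on data obeying the stated imaging
  model, not robustness to every instrument pathology.
* Tracking is greedy nearest-neighbor, adequate at ~14-nm packing with slow
  drift; it is not a global assignment and will not resolve fast crossing
  trajectories.
* Classification thresholds are calibrated to the parametric render family
  and the default noise; real data with different noise or tip sharpness
  would need recalibration against labeled snapshots.
* Periodicity detection uses the first off-zero autocorrelation maximum,
  chosen for short profiles (tens of samples) over FFT resolution.
* No kinetic (rate-constant) fitting of dwell distributions and no
  unsupervised conformational clustering are attempted; the package
  implements the supervised decision list only.
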