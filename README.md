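# afmgating

Single-molecule analysis of ligand-dependent ion-channel gating in
high-speed atomic force microscopy (HS-AFM) movies, built around the
Mg²⁺-gated pentameric channel CorA.

HS-AFM films membrane-embedded channels at ~1–2 frames s⁻¹ and 0.5 nm px⁻¹;
each pixel is a surface height in nm. In such movies CorA switches, as free
Mg²⁺ falls below its apparent affinity (K_d ≈ 2 mM), from a stable 5-fold
symmetric closed conformation to a family of asymmetric, elevated (putatively
open) conformations. This package provides the complete analysis chain used
to quantify that transition, plus a ground-truthed movie simulator so every
stage is testable without instrument data:

* **Simulator** — parametric pentamer surfaces (closed, open-I, open-II,
  open-+) on a crowded membrane patch, a Mg²⁺-dependent continuous-time
  Markov gating model (stationary closed occupancy `c/(c + K_d)`), free-Mg²⁺
  mass balance under EDTA chelation, raster-scan line-by-line image
  formation, spherical-cap tip convolution (grayscale dilation), scanner
  drift and vertical noise. Movies are written as 32-bit TIFF stacks with a
  JSON sidecar; ground truth as JSON lines.
* **Preprocessing** — first-order plane flattening (particle pixels masked
  by Otsu threshold), cross-correlation drift correction with subpixel
  refinement, particle detection/tracking, 5-fold rotational averaging,
  cross-section profiles (peak-to-peak heights, lattice periodicity) and
  height histograms.
* **Observables** — per-molecule ΔHeight(t) traces (max − min height in the
  5 × 5 nm window on the molecule center) and section kymographs.
* **State idealization** — step detection by recursive two-sample
  t-statistic segmentation, agglomerative level grouping, and minimum
  description length (MDL) selection of the state count; the standard mode
  forces two ΔHeight states (low ≈ closed, high ≈ any elevated conformation).
* **Gating statistics** — dwell times with censoring flags, up/down event
  binning (30-s bins), sliding 20-event dwell averages, the open fraction
  over time, and the dwell-ratio free energy `ΔG = −ln(τ_low/τ_high)` k_BT.
* **Conformational classification** — a feature-based decision list
  (5-fold rotational correlation S5, apex height/offset, lobe count,
  footprint eccentricity) assigning each snapshot to
  closed / open-I / open-II / open-+, with per-condition occupancy tables
  (s.e.m. across molecules), row-normalized 4×4 transition maps, block sums,
  the aggregate open→closed return probability, and Welch t tests between
  conditions.
* **Titration** — asymmetric-particle fractions with binomial errors and a
  weighted Hill–Langmuir fit `f(c) = 1 − cⁿ/(cⁿ + K_dⁿ)` for the apparent
  K_d (Hill n fixed to 1 by default).
* **Rod mechanics** — elastic-rod estimates for the long TM1 helix:
  circular-arc bending energy `E(r) = L_p·L/(2r²)` k_BT, its inverse
  `r(E) = √(L_p·L/2E)`, and the end deflection `d = r(1 − cos(L/r))`.

## Worked example

Simulate a 20-molecule patch for 100 frames at the intermediate (3 mM Mg²⁺)
condition, run the full pipeline (flatten → drift-correct → detect → track →
classify), and summarize:

```r
library(afmgating)
set.seed(1)
res <- run_condition("3mM", n_molecules = 20, n_frames = 100)
res$occupancy[, c("class", "mean_percent", "sem_percent")]
#>      class mean_percent sem_percent
#> 1   closed         20.2       1.426
#> 2    open1         14.7       0.715
#> 3    open2         14.5       1.001
#> 4 openplus         50.7       1.199
res$transitions
#> Frame-to-frame transitions (1980 pairs), row percentages:
#>          closed open1 open2 openplus
#> closed     42.9   9.5  10.8     36.8
#> open1      13.4  15.1  11.3     60.3
#> open2      14.9  17.7  15.6     51.7
#> openplus   14.7  15.8  16.3     53.2
return_to_closed_probability(res$transitions)
#> [1] 14.5
```

Half the snapshots pool in the unassigned open-+ class at this condition and
a molecule that has left the symmetric state returns to it on the next frame
only ~14–15% of the time — the signatures of the highly mobile intermediate
regime. At 10 mM the same pipeline reports ~91% closed occupancy; at 0 mM
the return probability drops to ~7%.

Idealizing a ΔHeight trace and extracting dwell statistics:

```r
set.seed(2)
lev <- rep(rep(c(1, 2.5), times = 5), rep(c(55, 36), 5))  # two-state gating
x   <- lev[1:450] + rnorm(450, sd = 0.2)                  # imaging noise
fit <- idealize(x, force_k = 2)
fit
#> State idealization: 450 points, k = 2 state(s), noise sd = 0.219 nm
#>   levels (nm): 1.02, 2.51
#>   9 change point(s)
```

The rod model reproduces the thermal-bending estimates for the 11-nm TM1
helix (persistence length 100 nm):

```r
rod <- rod_model(L_p = 100, L = 11)
radius_at_energy(rod, 1)                      # 23.45 nm -> "~23 nm at 1 kBT"
end_deflection(rod, radius_at_energy(rod, 1)) # 2.53 nm  -> "~2 nm end movement"
energy_difference(60, 30)                     # -0.69 kBT (closed favored)
```

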