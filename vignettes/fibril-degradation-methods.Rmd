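---
title: "Models and methods: adsorption kinetics and AFM nanomechanics of cellulose degradation"
author: "fibrildyn"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fibrildyn)
```

`fibrildyn` quantifies how two cellulolytic enzyme systems — dispersed
cellulases and the multi-enzyme cellulosome complex — interact with and
degrade bacterial cellulose fibrils. This vignette documents the models,
the tunable parameters and their defaults, the synthetic-data programs the
test suite relies on, and the numerical choices made where the design was
genuinely open. It states no empirical result that the package's tests and
acceptance script do not themselves compute.

## 1. The isotope-competition adsorption model

### Model structure

At *t* = 0 the enzyme is entirely adsorbed on unlabeled (¹²C) cellulose —
at the low enzyme-to-substrate ratio of the assay (E/S ≈ 0.83 mg/g,
substrate 1.0 mg/mL) the free-enzyme concentration is effectively zero —
and an equal concentration of ¹³C-labeled cellulose is added. Bound enzyme
is split into three pools:

* an **irreversible pool** $I = E_i\,E_T$ that never desorbs and stays on
  the unlabeled substrate;
* **reversible pools** $R_{12}, R_{13}$ with
  $\mathrm{d}R_j/\mathrm{d}t = k_{on} S_j F - k_{off} R_j$;
* **free enzyme** $F = E_T - I - R_{12} - R_{13}$ by conservation.

Glucose release from each substrate is proportional to the enzyme bound to
it, $\mathrm{d}G_j/\mathrm{d}t = k_{cat,app} \cdot (\text{bound on } j)$,
with the irreversible pool counted as catalytically active. That
assumption is forced by the observable: if irreversibly bound enzyme were
inactive, the release-rate ratio would always relax to unity and the
plateau above unity seen for partly irreversible systems could not occur.
With equal substrates the reversible pool equilibrates 50/50 and the
limiting ¹²C/¹³C release-rate ratio is $(1+E_i)/(1-E_i)$ — exactly 1 when
adsorption is fully reversible. `steady_state_ratio()` is this closed
form; the test suite verifies the ODE reproduces it at $t = 50/k_{off}$ to
within $10^{-4}$ relative, and checks the full forward simulation against
an independent closed-form oracle derived in the instantaneous-rebinding
limit.

Observed fractions are computed **per sampling interval** (incremental
glucose), matching how stacked per-timepoint isotope measurements are
reported; a cumulative mode is a design switch. Substrate depletion is
available for forward simulation (`deplete_substrate = TRUE`) but never
used in fitting, where the fit window keeps conversion low.

### What is fitted, and what is not

Only $(k_{off}, E_i)$ are estimated. $k_{on}$ is fixed large
(10⁴ mL mg⁻¹ min⁻¹): with free enzyme pinned near zero the adsorption
constant leaves no signature in the data and would be unidentifiable.
Fitting is bounded Levenberg–Marquardt (`minpack.lm::nls.lm`) on the
observed ¹²C fractions, $k_{off} \in [10^{-6}, 10]$ min⁻¹,
$E_i \in [0, 1]$; standard errors come from the Gauss–Newton Hessian at
the optimum and 95% t-intervals from the residual degrees of freedom. Two
guards matter in practice:

* **Identifiability flag.** If a four-fold perturbation of the fitted
  $k_{off}$ moves the predicted fractions by less than 1% of the fraction
  scale, or the estimate sits on a box bound, `k_off_identifiable` is
  `FALSE`. A series already at exchange equilibrium at its first sample
  (the disassembled-complex case) yields $E_i \approx 0$ with exactly this
  flag; only $E_i$ should be interpreted.
* **Convergence is reported**, never silently replaced by bound values.

### Assay design defaults and why

The default design samples every 30 min out to 720 min. The slowest
system simulated here has $k_{off} = 0.005$ min⁻¹ (relaxation time
200 min), so 720 min is ≈3.5 relaxation times and the plateau that
carries the $E_i$ information is actually observed. With a shorter
(6-hour) design the exchange is only ~83% complete and $E_i$ and
$k_{off}$ become partially confounded: Monte-Carlo recovery at
$E_i = 0.54$ then shows a systematic downward bias of several percentage
points. Sampling to near-equilibrium is how one would run the assay, and
it makes the estimator unbiased at the default 3% fraction noise — the
acceptance suite demonstrates mean recovery within ±5 percentage points
at both the cellulosome-like (54%) and cellulase-like (19%) operating
points over 20 replicates.

Truth values for the two operating points use $k_{off} = 0.005$ and
0.01 min⁻¹ respectively: slow dissociation in the minutes-to-hours range,
the regime the competition experiment is designed to resolve.

### Bulk-kinetics descriptors

`initial_rate()` (least-squares slope over an initial window, default
60 min), `rate_vs_conversion()` (central finite differences of conversion,
one-sided at the ends; linear fit of rate against conversion; stall
conversion $-b_0/b_1$ clipped to [0, 1], reported only when the fitted
decline exceeds 1% of the mean rate over the observed range),
`adsorbed_enzyme()` (mass balance) and `r_ads()` (specific rate of the
adsorbed enzyme, with first-order error propagation) complete the
biochemical toolkit.

## 2. The AFM nanomechanical pipeline

A time-lapse force-volume acquisition yields co-registered height (nm) and
elastic-modulus (MPa) maps every 5–10 min for ~120 min at ~2 nm lateral
resolution. `process_stack()` applies, in order:

1. **Plane leveling** (`level_plane`): least-squares plane fitted on
   background (substrate) pixels only, subtracted, then the residual
   background median removed, so the substrate sits at exactly 0 nm.
   Restricting the fit to the background keeps fiber topography unbiased;
   the operation is idempotent for a fixed mask.
2. **Drift registration** (`register_drift`): translation-only FFT
   cross-correlation, estimated sequentially between adjacent frames
   (which stay similar even late in a degradation run) and accumulated
   relative to the reference; subpixel refinement evaluates the
   cross-power spectrum on a locally upsampled DFT grid (default 10×).
   Frames are shifted by the rounded offsets and the stack is cropped to
   the common valid rectangle. Featureless images raise a
   registration-failure flag rather than a spurious shift. Known integer
   shifts are recovered exactly and subpixel shifts to ≤0.25 px in the
   oracle tests.
3. **Segmentation** (`segment_fiber`): threshold at background
   median + 5σ (or a fixed height), connected components via
   `EBImage::bwlabel`, keeping objects with ≥100 px and principal-axis
   elongation ≥3. Small or non-elongated residual objects (detached
   fragments, stray enzyme) are excluded from *both* masks so they never
   contaminate quantitative analysis.
4. **Stiffness normalization** (`normalize_modulus`): the modulus map is
   rescaled by one per-frame gain so the mean background (HOPG) modulus
   equals a nominal constant (default 100 MPa — only the per-frame ratio
   matters, and this keeps cellulose E\* in its usual 10–20 MPa range).
   Because the real HOPG modulus is constant, this cancels tip wear and
   laser drift exactly for any uniform multiplicative error; the suite
   checks E\*_av is flat under ±20% per-frame gain jitter.

Per-frame measurements are then: **fiber volume** (Σ height × pixel area
over the fiber mask), **E\*_av** (arithmetic mean of E\* over fiber pixels
in the nanodomain, requiring ≥2500 points ≈ 10,000 nm² at 2 nm/px, else
an exclusion flag — the mean is appropriate because within-domain E\*
distributions are unimodal and homogeneous, and it decomposes exactly
over ROI splits), **distribution summaries** (density mode, adjusted
Fisher–Pearson skewness via `e1071`, unimodality by counting prominent
modes of a Silverman-bandwidth kernel density; irregular distributions are
flagged for exclusion), and **relative activity**
$A(t_i) = 100\,(P(t_{i-1}) - P(t_i)) / (P(t_0)(t_i - t_{i-1}))$ where $P$
is the height pixel sum over a *fixed* region — the first frame's fiber
footprint held constant across the registered stack — so material thinned
below the segmentation threshold still counts until it is truly gone.
E\*_av series are linearly scaled to 0–100% for cross-experiment
comparison; the scaling is affine-invariant and flagged undefined for
constant series.

The pixel geometry default is 2 nm/px (2500 points per 10,000 nm², i.e.
4 nm²/point); a finer interpretation of the acquisition density is
configurable through `pixel_size` everywhere.

### The contact model

Force-distance curves follow the adhesive sphere-on-flat (DMT-form)
model: zero force out of contact and
$F(d) = \tfrac{4}{3} E_r \sqrt{R}\, d^{3/2} - F_{adh}$ in contact, with
$E_r = E/(1-\nu^2)$, ν = 0.3 by default, tip radius 5 nm, peak force 2 nN
(low enough to indent without damaging the fibril). `fit_contact_model()`
works on the retract segment: baseline from the far quarter of the ramp, a
no-contact error if the force never rises 5 noise-SD above it, then
*exact profiled least squares* — the model is linear in (prefactor,
adhesion) once the contact point is fixed, and the pull-off discontinuity
localizes the contact point, so a fine grid around the force minimum with
a linear solve per candidate finds the global optimum. A joint 3-parameter
nonlinear fit was rejected: the modulus/contact-point degeneracy roughly
triples the Monte-Carlo error. With 1024 samples per segment and a ramp of
about three contact depths (realistic capture density), moduli from 5 MPa
to 2 GPa are recovered within 1% at 1%-of-peak force noise, and exactly
(to 0.1%) without noise. Hertz (no adhesion) is an option.

## 3. Synthetic degradation experiments

### The fibril phantom

`gen_fibril_phantom()` renders a half-elliptical ridge — default 1000 nm
long, 30 nm wide, 20 nm tall on a flat substrate, closed-form volume
$\pi L W H / 4$ (rasterization agrees within 2% at 2 nm/px). Mechanics
follow the core–shell picture of the microfibril bundle: modulus ramps
linearly from the shell value (15 MPa, putting initial E\* in the
10–20 MPa range) to the core value (45 MPa) across a 9 nm shell, constant
below. A *linear* ramp is used deliberately instead of a logistic-type
sigmoid: a sigmoid has vanishing slope at the surface, which would make
early layer-by-layer frames look mechanically flat and could mislabel the
continuous mode as biphasic; the ramp keeps the exposed-surface stiffness
strictly increasing throughout shell removal and pins the construction
endpoints exactly (shell modulus at depth 0, core at the shell depth).
Softer segments (modulus ×0.6) recur every 200 nm along the fiber,
emulating twists, bends and fibril ends.

### Imaging corruptions

Both stack generators apply, after the degradation program: cumulative
lateral drift (default 4, 2 nm/frame), a residual tilt plane
(0.004/0.006 nm/px), per-frame multiplicative modulus gain jitter (±20%,
emulating tip and laser drift), Gaussian height noise (0.3 nm) and 5%
multiplicative modulus noise. Ground truth (volumes, surface-mean
modulus, masks, applied drift and gains) is recorded pre-corruption.

### Ablation mode (cellulase-like)

A uniform layer is removed each frame; the exposed surface takes the
depth-profile modulus, so the true surface-mean modulus rises
monotonically with volume loss. The erosion rate is, by default, coupled
to the softness of the currently exposed surface
($\propto (E_{core} - E(D))/(E_{core} - E_{shell})$, base rate 2 nm/frame)
— the layer-by-layer attack loses efficiency as it confronts the stiffer
core, which is precisely the cellulase slowdown the time-lapse analysis
is meant to detect. The default run is 13 frames at 10 min. Uncoupled
constant-rate erosion (`stiffness_coupling = FALSE`) is available for
controls, including complete fiber removal.

### Fragmentation mode (cellulosome-like)

Full-depth cavities open along the fiber and widen; the exposed surface of
the remaining material keeps its original shell modulus, so substantial
volume can be lost with almost no change in surface-mean stiffness — the
lag phase. Enzyme kinetics are budget-limited: a fixed total degradation
budget per frame (36 nm of cavity-length equivalent) is spent first on
consuming fragments already below the 150 nm threshold (eroding them
toward their crystalline cores, which persist — erosion caps at the shell
depth), then on opening new attack sites, then on widening cavities whose
ends border long fragments. This keeps the overall material-loss rate
roughly steady across both phases, reproducing the observed decoupling of
cellulosome activity from substrate stiffness. The first two degradation
frames open one attack site each at well-separated interior positions
(jittered thirds of the fiber), matching the distinct early attack loci
seen in time-lapse imaging and ensuring every run reaches the
short-fragment stage within the ~2 h acquisition; further sites follow a
Poisson process (intensity 0.5/frame) biased 3:1 toward soft segments and
respecting a minimum spacing, so short fragments arise by cavity *growth*
rather than by nucleation adjacent to an existing cavity. The default run
is 15 frames at 8 min. The recorded truth breakpoint is the volume loss at
which the first fragment drops below the threshold; across seeds it falls
around 25–47% loss, with the first 20% of loss changing the true
surface-mean modulus by less than 5%.

`gen_degradation_trajectory()` runs the same programs without imaging
corruption and adds measurement-level noise (1% on E\*_av — conservative
relative to the sub-percent scatter the full pipeline achieves after HOPG
normalization — and 1% on volume), providing hundreds of trajectories for
classifier studies at negligible cost.

### What the generators do not emulate

Tip-shape convolution, raster line artifacts, thermal noise spectra,
rotation or scan-size changes, piezo creep, and real heterogeneity of
crystallinity along a fibril. Passing tests therefore demonstrate that the
pipeline recovers known truth under translation drift, tilt, gain error
and pixel noise — not that it is robust to every artifact of a real
instrument.

## 4. Degradation-pattern classification

`classify_pattern()` works in the (percent volume loss, scaled E\*_av)
plane. It compares a straight line against a continuous two-segment
piecewise-linear model (breakpoint profiled over interior data points,
then refined continuously between neighbours) using AICc with the
two-segment model charged two extra parameters (second slope and
breakpoint). The label is **biphasic** only when the two-segment model
wins *and* the first segment is flat: its slope below 20% of the
second-segment slope, or statistically indistinguishable from zero
(within 2 SE). Flatness is judged against the second segment rather than
the overall fit because the overall slope of a trajectory with a long lag
badly understates the minor-versus-sharp contrast; the 2-SE clause stops
measurement noise on a genuinely flat lag from forcing a "continuous"
call. Parsimony is preserved: pure-noise trajectories are labelled
biphasic in ≤10% of Monte-Carlo runs (the suite checks ≤10% at n = 10),
and exactly linear trends are always continuous. Breakpoint estimates
tighten as noise shrinks (consistency is property-tested).

`correlate_rate_stiffness()` pairs same-frame relative activity with
scaled E\*_av (a configurable lag is provided but defaults to 0, as no
lag is specified by the underlying experiments) and reports the
least-squares slope plus Spearman's rank correlation, which is invariant
under the 0–100% rescaling. Note the sampling reality: with ~14 usable
frames a rank correlation has a standard deviation of ≈0.28 *under exact
independence*, so single-run correlations scatter widely; the acceptance
suite therefore averages the correlation over five replicate
fragmentation runs when checking decoupling, while asserting the label
and breakpoint per run.

## 5. Problem sizes and runtimes

The shipped test-suite configurations are: 20-replicate Monte-Carlo
recovery per operating point for the competition fits; one full
image-pipeline run per degradation mode plus five replicate fragmentation
stacks for the mode-signature checks (1000 nm phantom, 13–15 frames,
~55 × 540 px frames); 200 trajectory-level simulations per mode for
classifier recovery; and 10 noisy curves per modulus decade for the
contact-model round trip. These sizes give stable statistics while the
whole suite completes in well under a minute of compute per module.

## 6. Known limitations

* The competition model neglects substrate depletion inside the fit
  window and treats $k_{on}$ as unidentifiable by design; data collected
  at high free-enzyme concentrations would need the full model.
* Registration is translation-only; rotational drift would leak into the
  volume and E\*_av series.
* The unimodality test (mode counting on a kernel-smoothed density) is a
  pragmatic screen, not a formal dip test; borderline mixtures may pass.
* The biphasic/continuous classifier assumes a single breakpoint; a
  trajectory with two distinct regime changes would be summarized by the
  stronger one.
* E\*_av exclusion below 2500 fiber pixels means late, nearly consumed
  fibers drop out of the stiffness series; volume and activity remain
  defined.
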