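# fibrildyn

Enzymatic conversion of cellulose slows down long before the substrate is
used up, and the reason differs between the two major enzyme systems:
dispersed fungal **cellulases** peel crystalline fibrils layer by layer and
stall as they expose the stiffer, better-ordered fibril core, while the
bacterial **cellulosome** complex cuts fibers apart through cavities and
fragmentation but binds its substrate almost irreversibly and gets trapped
in unproductive states. `fibrildyn` implements the two quantitative
analyses that put numbers on those mechanisms:

1. **Isotope-competition adsorption kinetics.** Enzyme preloaded on
   unlabeled (¹²C) cellulose is challenged at *t* = 0 with an equal
   concentration of uniformly ¹³C-labeled cellulose; the isotope
   composition of released glucose tracks how the bound enzyme
   redistributes. The model splits bound enzyme into an irreversible pool
   *I* = *E*ᵢ·*E*_T fixed on the unlabeled substrate and reversible pools
   *R*₁₂, *R*₁₃ exchanging through free enzyme *F* (by conservation):

       dR_j/dt = k_on · S_j · F − k_off · R_j,    dG_j/dt = kcat_app · (bound on j)

   With equal substrates the long-time ¹²C/¹³C release-rate ratio is
   (1 + *E*ᵢ)/(1 − *E*ᵢ) — unity for fully reversible adsorption. Bounded
   Levenberg–Marquardt fitting of the observed ¹²C fractions estimates
   (*k*_off, *E*ᵢ) with confidence intervals and an identifiability flag.

2. **Time-lapse force-volume AFM nanomechanics.** Paired height/modulus
   maps of single fibril bundles on HOPG are plane-leveled against the
   substrate, drift-registered by upsampled phase correlation, segmented
   into elongated fiber objects, and normalized so the per-frame HOPG
   background modulus is constant — yielding the normalized stiffness E\*
   (MPa), its nanodomain mean E\*_av, fiber volume (Σ height × pixel
   area), and the relative degradation activity (% of the initial height
   pixel sum lost per minute). Trajectories of scaled E\*_av versus volume
   loss are classified **continuous** (layer-by-layer ablation) or
   **biphasic** (lag, then sharp rise — the fragmentation signature) by
   AICc comparison of a line against a continuous two-segment fit.

A synthetic-data layer generates every input with ground truth: noisy
competition series, core–shell fibril phantoms (soft surface shell over a
stiff crystalline core, softer segments at regular intervals), degradation
image stacks in both modes (with drift, tilt, per-frame gain jitter and
noise), and DMT contact-model force curves.

## Worked example

```r
library(fibrildyn)

## -- adsorption kinetics ------------------------------------------------
truth  <- adsorption_params(k_off = 0.005, E_i = 0.54)   # cellulosome-like
design <- competition_design(noise_sd = 0.03)            # 1.0 mg/mL each, E/S 0.83 mg/g
sim    <- gen_competition_data(truth, design, seed = 7)
fit_competition(sim$series, design)
#> Competition-model fit
#>   k_off = 0.005558 min^-1 (SE 0.00034)
#>   E_i   = 0.5877 (SE 0.017)
#>   RSS 0.0248 over 24 points; converged: TRUE
steady_state_ratio(truth)
#> [1] 3.347826

## -- AFM pipeline -------------------------------------------------------
phantom <- gen_fibril_phantom()                    # 1000 x 30 x 20 nm ridge
run     <- gen_fragmentation_stack(phantom, seed = 4)
proc    <- process_stack(run$stack)                # level, register, segment, normalize
traj    <- build_trajectory(proc)
classify_pattern(traj)
#> pattern: biphasic (breakpoint at 44.3% volume loss)
#>   slopes: first -0.0301, second 13.2, single-line 0.912
#>   delta AICc (two-segment - line): -71.77
```

The fitted `E_i = 0.588` recovers the generating irreversible fraction
0.54 from a single noisy assay (the 20-replicate mean lands within two
points of truth); the breakpoint is where short fiber
fragments (≤150 nm) begin near-complete degradation and the exposed
crystalline cores drive E\*_av upward.

Shell entry points wrapping these functions live in `inst/cli/`
(`simulate-competition.R`, `fit-competition.R`, `simulate-afm.R`,
`process-afm.R`, `analyze-degradation.R`).

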