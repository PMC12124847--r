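# epgspoil

Extended-phase-graph (EPG) simulation of RF spoiling in gradient-echo MRI,
with diffusion.

## What it is for

RF-spoiled gradient-echo sequences (FLASH / SPGR / T1-FFE) combine an
unbalanced gradient with a quadratic RF phase schedule
φ<sub>n</sub> = n(n+1)ψ/2 so that the steady-state signal approximates the
ideally spoiled Ernst response

    S⁺_Ernst(TR/T1, α) = M0 · (1 − E1) sin α / (1 − E1 cos α),   E1 = e^(−TR/T1),

whose maximum sits at the Ernst angle α_E = arccos E1. The approximation
depends on the phase difference increment ψ — vendors hard-code 50°, 115.4°,
117° or 150°, and 169° is advocated for T1 mapping — and it degrades badly
in free liquids, where long T2 and (de-)emphasized diffusion leave residual
T2 dependence in the signal. `epgspoil` is for MR physicists who need to
know how far a given protocol deviates from ideal spoiling: it simulates the
pseudo steady state with the EPG-with-diffusion formalism (configuration
states F_k, Z_k; per-interval b-values of the gradient waveform) and
quantifies the deviation with the spoiling-quality metric

    ε = (100/N) Σ_k |S⁺(α_k) − S⁺_Ernst(α_k)| / S⁺_Ernst(α_k)   [%],

averaged over N = 18 flip angles 5°–90°. An isochromat-ensemble oracle, an
Ernst-angle-normalized synthetic phantom pipeline with Rician ROI noise, and
parameter-space / resolution sweep drivers complete the chain.

## Worked example

Spoiling quality of the Bruker increment (ψ = 117°) for a silicone-oil
phantom (T1 = 1290 ms, T2 = 399 ms, D = 0.0055·10⁻³ mm²/s) on the default
protocol (TR = 20 ms, TE = 4 ms, 0.30 mm readout voxel, spoiler moments
3 and 3.76 cycles/voxel):

```r
library(epgspoil)
sch <- gre_protocol(tr = 20, te = 4)
oil <- phantom_presets()$SiliconeOil

curve <- signal_curve(sch, oil, spoiling_scheme(117), flips = seq(10, 60, 10))
round(curve[, c("flip_deg", "s_plus", "s_minus")], 4)
#>   flip_deg s_plus s_minus
#> 1       10 0.0882  0.0065
#> 2       20 0.0671  0.0197
#> 3       30 0.0521  0.0281
#> 4       40 0.0461  0.0299
#> 5       50 0.0405  0.0273
#> 6       60 0.0341  0.0230

ernst_angle(20 / 1290)                       # 10.1 deg
epsilon_for(sch, oil, spoiling_scheme(117))  # 13.78 %
```

`s_plus` is the steady-state magnitude right after the pulse (fraction of
M0) — the quantity ε compares against the Ernst curve; `s_minus` is the
magnitude at the end of the repetition interval. The signal peaks near the
Ernst angle (10.1°) and ε says the curve deviates from ideal spoiling by
13.8 % on average. Comparing all five increments for this phantom:

```r
for (p in c(50, 115.4, 117, 150, 169))
  cat(sprintf("psi = %5.1f  epsilon = %5.2f %%\n", p,
              epsilon_for(sch, oil, spoiling_scheme(p))))
#> psi =  50.0  epsilon = 18.75 %
#> psi = 115.4  epsilon =  9.39 %
#> psi = 117.0  epsilon = 13.78 %
#> psi = 150.0  epsilon = 19.53 %
#> psi = 169.0  epsilon =  9.71 %
```

so for this low-diffusion liquid ψ = 115.4° spoils best and the Philips
value ψ = 150° worst — a 2× spread in average deviation between scanners
running nominally the same sequence.

## Analysis pipeline

The numbered scripts under `analysis/` rebuild the full analysis chain and
write CSV tables (and optional PNG figures) into `results/`:

1. `01_substance_table.R` — ε for the reference substances (ratio condition
   T1 = T2 = 20·TR, both phantoms, grey matter) with and without diffusion,
   TR = 20/50 ms.
2. `02_parameter_grids.R` — ε over the log-spaced (T1/TR, T2/TR) plane for
   five ψ and two diffusion regimes, plus the best-ψ map (`--full` for the
   0.1-decade grid; cells are cached and resumable).
3. `03_voxel_size_sweep.R` — ε versus readout voxel size (0.075–1.2 mm) for
   three substances at TR = 20/50 ms.
4. `04_phantom_comparison.R` — synthetic noisy phantom measurements,
   Ernst-angle normalization, residuals against simulation and
   Rician-corrected ε estimates (`--seed` to vary the noise draw).

The methods vignette (`vignettes/spoiling-simulation.Rmd`) documents the
model, the numerical policies and the generator's scope.

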