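# mptbarrier

Multiple particle tracking (MPT) analysis of mucus barrier microstructure,
for researchers studying how nanoparticle exposure reshapes protective
mucus gels — and what that means for the penetration of viruses, toxic
particulates, or drug carriers.

The package takes 2-D probe-particle trajectories (or generates realistic
synthetic ones) and carries them through the complete analysis chain:

1. **Microrheology** — per-particle time-averaged mean squared
   displacements `⟨Δr²(τ)⟩ = ⟨[x(t+τ)−x(t)]² + [y(t+τ)−y(t)]²⟩ₜ`,
   effective diffusivities `D_eff = MSD/(4τ)` at τ = 1 s, anomalous
   exponents α (log–log MSD slope; 1 = free diffusion), and
   immobile-particle classification against the tracking-resolution floor.
2. **Pore-size inversion** — the obstruction-scaling model
   `D_g/D_o = exp(−(π/4)((r_s+r_f)/(r_g+r_f))²)` solved for the effective
   pore radius `r_g`, giving mesh-spacing statistics per condition.
3. **Barrier penetration** — first-passage Monte Carlo of the measured
   diffusivity ensemble across mucus slabs of physiological thickness,
   with the analytic oracle `erfc(L/√(4Dt))` and a calibration utility
   `D = L²/(4t·erfc⁻¹(p)²)`.
4. **Statistics** — exact (full-enumeration) one-tailed Wilcoxon
   signed-rank tests for small paired donor designs, inhaled-dose
   arithmetic for exposure scenarios, and the rheology phase angle
   `arctan(G″/G′)`.
5. **Synthetic studies** — a fractional-Brownian-motion generator that
   plants immobile fractions, ensemble exponents and log-normal
   diffusivity laws in a paired multi-donor design, so the entire
   pipeline is testable without raw video data.

## Worked example

```r
library(mptbarrier)

study <- generateStudy(studyDesign(seed = 7))   # 6 donors x 2 conditions x 100 particles
res   <- analyzeStudy(study)

aggregate(cbind(alpha, mean_deff_um2_s, immobile_fraction) ~ condition,
          res$ensembles, mean)
#>   condition alpha mean_deff_um2_s immobile_fraction
#> 1   control 0.346          0.0139              0.34
#> 2   treated 0.684          0.1360              0.19

res$foldChange          # mean D_eff fold change (treated/control)
#> 9.8
res$wilcoxon$p.value    # one-tailed exact signed-rank p, n = 6 donors
#> 0.015625
```

The ensemble exponent rises from 0.35 to 0.68 and the mean effective
diffusivity shifts ~10-fold — probes move much more freely in the treated
gel — while the immobile fraction drops from 34% to 19%. With all six
donors shifting in the same direction, the exact paired p-value reaches
its n = 6 minimum, 1/2⁶. Pore statistics and penetration predictions
follow from the same result object:

```r
res$poreStats$control$mean_spacing_nm   # 380 (+/- 10 SEM over donors)
res$poreStats$treated$mean_spacing_nm   # 632 (+/- 40)

d <- split(res$particles$deff_1s_um2_s, res$particles$condition)
penetrationTable(d$control, d$treated, thicknesses = c(10, 30), seed = 7)
#>   L_um fraction_control fraction_treated fold_ratio
#> 1   10           0.1302            0.441       3.39
#> 2   30           0.0202            0.162       8.02
```

A 10 µm slab that passes 13% of control-gel particles in an hour passes
44% after treatment — the microstructural loosening translates directly
into barrier failure. For reference, a particle in pure water calibrated
to cross 10 µm with probability 64% in an hour:

```r
D <- calibrateDiffusivity(0.64, L = 10, t = 3600)   # 0.0635 um^2/s
res30 <- simulateSlabPenetration(D, 30, duration = 3600,
                                 replicates = 20000, seed = 7)
100 * penetratedFraction(res30)
#> 15.8   # percent crossing 30 um in 1 hr
```

A command-line wrapper over the same functions lives in
`inst/scripts/mpt-pipeline.R` (`synth`, `analyze`, `penetrate`
subcommands driven by a YAML config). See the vignette
(`vignettes/mucus-barrier-microrheology.Rmd`) for the models,
assumptions, and numerical choices.

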