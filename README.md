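# tmskernels

Biophysical coupling from TMS-induced electric fields to the state
variables of cortical populations, for computational neuroscientists who
need a principled stimulation input for circuit models instead of an
arbitrary pulse.

Transcranial magnetic stimulation fires cortical axons with strong
directional and intensity sensitivity. `tmskernels` quantifies that
coupling in two stages:

1. **Axonal delay kernels.** Compartmental Hodgkin–Huxley cables are
   exposed to a field parameterized by polar angle θ (against the
   somatodendritic axis), azimuth φ, intensity |E| (V/m) and relative
   gradient Δ|E| (%/mm), scaled in time by a normalized biphasic pulse.
   Every axon-terminal spike arrival is histogrammed over soma-relative
   depth z′ and time; averaging over 60 azimuths, morphologies and
   subtype weights and cross-correlating with the cell-density profile
   d(z) gives the population kernel

   k(z, t) = corr(d(z), r(z′, t)) · (cell-count ratio),

   a spike density (ms⁻¹ µm⁻¹) over cortical depth and time.
2. **Synapto-dendritic currents.** k(z, t) for excitatory and inhibitory
   populations drives AMPA/NMDA/GABAa/GABAb conductances
   (double-exponential kernels, Mg²⁺-gated NMDA, g = (A/A_bin) · f ·
   K_SYN ⊛ K_z) on the dendrites of a sodium-quenched postsynaptic
   cell; the output is the baseline-subtracted axial current entering
   the soma, I(t) = −Σᵢ (Aᵢ/Rᵢ)(V_soma − Vᵢ)/Lᵢ, averaged over soma
   depths and morphologies.

A generalized polynomial chaos surrogate I(t, ξ) = Σᵢ cᵢ(t) Ψᵢ(ξ) over
six uniform parameters (θ, Δ|E|, |E|, f_NMDA, f_GABAa, f_ex) — with an
anisotropic truncation giving exactly 1642 orthonormal Legendre basis
functions — provides fast prediction plus time-resolved Sobol and
derivative sensitivities.

## Worked example

```r
library(tmskernels)

pre  <- lapply(1:2, function(i) generate_morphology(
  synthetic_morph_spec(n_axon_terminals = 12L, rng_seed = 100L + i)))
dens <- layer_density()                 # L2/3 band of a 2700-um column
fp   <- field_params(theta = 30, intensity = 1200)

ax <- run_axonal_stage(pre, fp, dens, count_ratio = 5.04, n_phi = 6L,
                       config = cable_config(dt = 0.025, duration = 3),
                       max_len = 30)
ax$population_kernel
#> <delay_kernel> 27 z-bins x 30 t-bins (cortical_z)
#>   z in [-2700, 0] um; t in [0, 3] ms; total spikes 60.48
```

Every terminal of both cells fired under this field (12 spikes per
cell); the correlation preserves the count and the 5.04 excitatory
count ratio scales it to 60.48 spikes delivered per postsynaptic cell.

```r
post <- compartmentalize(generate_morphology(
  synthetic_morph_spec(n_axon_terminals = 4L, n_dendrite_tips = 8L,
                       rng_seed = 151L)), 40)
inh  <- delay_kernel(0.4 * ax$population_kernel$values,
                     seq(-2700, 0, 100), ax$population_kernel$t_edges,
                     domain = "cortical_z")
cur  <- run_dendritic(post, ax$population_kernel, inh,
                      synapse_fractions(f_nmda = 0.5, f_gabaa = 0.95,
                                        f_ex = 0.65),
                      soma_depth = -1584,
                      config = cable_config(dt = 0.02, duration = 100))
max(cur$I)
#> peak current: 0.271 nA at t = 1.2 ms
```

The somatic current is inward (positive), peaks shortly after the spike
volley, and is exactly zero when both kernels are zero (the baseline is
recomputed and subtracted per run).

```r
sur <- run_surrogate_stage(seed = 1L)    # 4000 train / 1000 held out
sur$nrmsd
#> 0.245        # held-out NRMSD in percent
sort(sur$sobol$sobol_time_avg, decreasing = TRUE)[1:4]
#>   f_ex  intensity x f_ex  f_nmda  intensity
#>  0.727             0.217   0.024      0.009
```

The excitatory–inhibitory balance and its interaction with intensity
dominate the surrogate's output variance for the packaged analytic
current generator.

A thin CLI (`inst/cli/tmskernels-cli.R`) exposes the `fixtures`,
`axonal`, `dendritic` and `surrogate` stages for shell pipelines; see
`vignettes/coupling-model.Rmd` for the full model description.

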