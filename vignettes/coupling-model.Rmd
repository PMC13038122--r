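---
title: "From TMS electric fields to dendritic currents: the coupling model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From TMS electric fields to dendritic currents: the coupling model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tmskernels)
```

## The problem

Transcranial magnetic stimulation (TMS) induces an electric field in
cortex that fires axons, and the resulting synaptic bombardment changes
the state of downstream populations. Circuit-level models of TMS usually
shortcut this chain with an arbitrary pulse of input. `tmskernels`
implements the intermediate, biophysical link as two composable stages:

1. **Axonal stage.** A compartmental cable model of a presynaptic neuron
   is exposed to a parameterized field. Action potentials start at axon
   terminals, backpropagate through the arbor, and every terminal's
   arrival is histogrammed over soma-relative depth z' and time. Averaged
   over azimuthal rotations, morphologies, and subtypes, and correlated
   with the population's soma-depth density, this yields the *axonal
   delay kernel* k(z, t) — spikes per ms per um delivered at cortical
   depth z and time t per postsynaptic cell.
2. **Dendritic stage.** k(z, t) for an excitatory and an inhibitory
   population drives conductance-based AMPA/NMDA/GABAa/GABAb synapses on
   the dendrites of a sodium-quenched postsynaptic cell; the output is
   the baseline-subtracted axial current entering the soma, averaged over
   soma depths (density-weighted) and morphologies.

A generalized polynomial chaos (gPC) surrogate then represents the
dendritic current as a function of six uniformly distributed parameters —
field angle theta, relative gradient, intensity, and the synapse
fractions f_NMDA, f_GABAa, f_ex — and yields time-resolved Sobol and
derivative sensitivities directly from its coefficients.

## Field parameterization and coupling

The field at a cell is described by the polar angle theta against the
somatodendritic axis, an azimuthal angle phi, the intensity |E| (V/m)
and a relative gradient (%/mm) along z', anchored at the soma; only the
magnitude varies with depth, the direction is global. A biphasic coil
current is modeled as a peak-normalized damped sinusoid
`exp(-t/tau) sin(2 pi f t)` with f = 2.5 kHz and tau = 0.4 ms by
default — one dominant ~0.4 ms cycle, the shape of standard
figure-of-eight biphasic stimulators. The literature rarely prints the
analytic form of commercial pulses, so the family is configurable and
every run manifest records the parameters used.

The field couples to the cable through the extracellular quasipotential:
psi is minus the line integral of the field along the tree (midpoint rule
per compartment, continuous across branches), and `v_ext(t) = psi * w(t)`
enters the cable equation only through axial *differences*, so a global
constant — or a spatially uniform v_ext — provably leaves the membrane
untouched, a property the test suite checks to 1e-9 mV.

## The cable solver

Morphologies (read from SWC or generated synthetically) are discretized
into compartments no longer than a cap (20 um for the axonal stage by
default). The solver advances Hodgkin-Huxley gating by exact exponential
(Rush-Larsen) updates and the voltage by a theta-method step — backward
Euler for settling, Crank-Nicolson for transients — with one Hines
elimination over the tree per step, which is unconditionally stable and
conserves axial current to machine precision. Steady state is reached
with 100 implicit steps of 1e9 ms, after which gating variables sit
exactly on their voltage-clamped curves; a residual check (< 1e-9 mV/ms)
guards the contract. Default steps are 0.025 ms (axonal stage) and
0.01 ms over 100 ms (dendritic stage).

Channel kinetics are the classic squid Na/K/leak set with Q10 = 3
scaling from 6.3 C to the simulation temperature (37 C default). Two
deliberate choices:

* **Densities.** At 37 C the Q10-accelerated classic kinetics heat-block
  at squid densities (spikes no longer clear 0 mV). The package
  therefore defaults to cortical-axon-like densities (0.5 S/cm^2 Na on
  the axon, 0.25 on the soma), restoring robust initiation and
  propagation — the mechanism the axonal stage measures. Absolute
  activation thresholds consequently differ from detailed
  human-calibrated channel models (here roughly 700-900 V/m on the
  bundled synthetic cells); all acceptance checks are therefore either
  scale-free properties or qualitative recruitment behavior, never
  absolute thresholds.
* **Quenching.** For the dendritic stage the soma and axon sodium
  conductance is zeroed so the measured somatic current reflects
  synaptic drive and dendritic cable properties only.

## Kernels, averaging, and the population correlation

Arrivals are first upward 0 mV crossings per terminal (linearly
interpolated between samples; later crossings are ignored). Histograms
use 100 um x 0.1 ms bins with left-closed, right-open intervals (last
bin closed) and an explicit overflow tally. pchip (monotone cubic)
resampling refines kernels without negative overshoot.

The population kernel correlates the per-cell kernel r(z', t) with the
normalized soma-density d(z) along depth, per time column. The
implementation aligns the z' bin containing the soma (z' = 0) with the
density bin of each soma position, so a delta density at depth z0
reproduces the cell kernel re-based with its soma at z0; for z' grids
symmetric about zero this coincides with the conventional centred
'same'-mode crop of the full correlation, and the choice makes the
z-index-to-depth mapping physically meaningful rather than an artifact
of grid extents. The normalized density makes the correlation
count-preserving whenever the correlation support stays inside the
2700-um column; mass pushed outside is tallied, never silently lost.
Scaling by the presynaptic-to-postsynaptic count ratio (5.04 excitatory,
0.40 inhibitory for the superficial-to-deep example circuit) converts
per-cell output into drive per postsynaptic cell.

## Dendritic drive

Per 50-um depth bin, the partial integral of the kernel over the bin is
computed by exact piecewise-constant (histogram) integration — this, and
not a trapezoid on interpolated samples, conserves spike counts exactly
when bins tile the column, which the tests assert to 1e-12. Receptor
conductances convolve the bin's spike rate with peak-normalized
double-exponential kernels (AMPA 0.05/5.3 ms, NMDA 15/150 ms, GABAa
0.07/18.2 ms, GABAb 3.5/260.9 ms; reversal 0/0/-80/-93 mV; peaks
0.1/0.03/0.5/0.5 uS), dt-scaled so conductances stay in uS, split by the
mixture fractions, and area-weighted A/A_bin within each bin. The NMDA
conductance is multiplied each step by the magnesium gate
`1/(1 + 0.28 Mg exp(-0.062 v))` at the instantaneous local potential.
Kernel mass falling in bins without dendritic membrane is reported as
"unreceived input" in the run report. The somatic current sums
`-(A_i/R_i)(V_soma - V_i)/L_i` over soma-adjacent dendritic
compartments, inward positive, and subtracts a zero-input baseline
recomputed per morphology and depth (rather than any fixed global
constant, which would be specific to one morphology set).

## The surrogate and its truncation

Each of the 500 time points (0-100 ms, 0.2 ms step, half-open grid)
gets an independent expansion in products of orthonormal Legendre
polynomials of the six parameters mapped to [-1, 1]. The anisotropic
truncation keeps a multi-index when at most three entries are nonzero;
a lone entry is at most order 20 (6 for the gradient parameter); and
two or three interacting entries sum to at most 8. For six parameters
this gives exactly 1642 basis functions. Coefficients solve the least
squares problem via the SVD pseudoinverse (relative cutoff 1e-12, no
regularization); fidelity is the range-normalized RMS deviation averaged
over time points (NRMSD, %) on held-out draws. Sobol indices come from
sums of squared coefficients per support set; derivative sensitivities
are signed Monte-Carlo averages of the analytic basis derivatives
(1e4 draws by default).

## What the synthetic generator emulates — and what it does not

Synthetic cells have a branched axonal arbor built by recursive binary
splitting whose terminals land at depths drawn from a truncated normal
(spec-chosen mean/SD within z' in [-2000, 500] um), plus an apical trunk
with tufts and a basal spray. This reproduces the features the pipeline
depends on: terminals distributed over depth, branch-order-dependent
backpropagation delays, rotational variety in terminal orientation, and
dendritic membrane spread over cortical bins. It does *not* reproduce
reconstruction-specific geometry — tortuosity, diameter tapering,
en-passant boutons, myelination, or realistic arborization statistics —
so passing tests demonstrate correctness of the machinery and of
scale-free properties, not quantitative agreement with any particular
reconstructed dataset. Cell densities are truncated Gaussians confined
to layer bands of a 2700-um column (the superficial band at
-270 to -783 um); real laminar densities are multimodal.

The packaged analytic dendritic-current generator used to exercise the
surrogate at scale is a closed-form C-infinity function of all six
parameters designed before any surrogate was fitted to mirror the
simulated physics qualitatively: a tanh recruitment threshold in
intensity that is lowest for fields (anti)parallel to the
somatodendritic axis, a weak linear gradient modulation, an excitatory
double-exponential whose kinetics slow and early amplitude drops with
f_NMDA, and fast/slow inhibitory components split by f_GABAa, with the
excitatory-inhibitory balance scaling the two branches. Its variance is
dominated by f_ex and the intensity-f_ex interaction.

## Problem sizes and numerical choices

The shipped defaults balance fidelity against desk-scale runtimes: test
morphologies use 4-17 terminals and 20-40 um compartments; rotation
averages use 2-8 azimuths in tests (60 in the production default);
dendritic test runs use 10-60 ms windows at 0.02-0.05 ms steps; the
surrogate is exercised at its full production size (4000 training,
1000 held-out draws, 1642 coefficients, 500 time points) because the
analytic generator makes that cheap. Ties on histogram edges go to the
upper bin; arrival detection keeps only the first crossing per terminal
(repeated crossings under bursting are out of scope); convolutions are
causal and truncated at the simulation window. Degenerate inputs —
equal synaptic time constants, unnormalized densities, z'-domain kernels
passed to cortical-domain consumers, infeasible morphology specs — fail
fast with typed errors rather than propagating silently.

## Known limitations

* Channel models are classic HH, not human-calibrated cortical channel
  sets; absolute thresholds and spike shapes differ accordingly.
* The axonal and dendritic stages are feedforward: no synaptic
  plasticity, no backpropagating-spike feedback onto conductances, no
  background activity.
* Fields are uniform in direction with a linear magnitude gradient along
  z' only; microscale conductivity corrections are out of scope.
* The population correlation assumes x-y homogeneity of connectivity and
  that cells at all depths of a layer see the same field.
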