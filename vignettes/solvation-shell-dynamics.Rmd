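---
title: "Regional solvation-shell dynamics and protein flexibility"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Regional solvation-shell dynamics and protein flexibility}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(solvshell)
```

## The problem

Protein motions are Brownian: a helix or loop moves through the friction
of its immediate solvent cage. When the solvation layer around a region
is mobile, the region can move; when the layer is sluggish, the region
is damped. For enzymes used in organic solvents — where reduced
flexibility is the classic cause of reduced activity — the question of
*which* solvent slows down *which* region is practical, not academic.

`solvshell` quantifies this locally. Given a solute-plus-solvent
trajectory and a map of named regions (helices, sheets, loops,
connectors, each a set of residue ranges with an exposure label), it
measures, per region and solvent:

* **shell residence time** — how long a solvent molecule stays within
  the first solvation shell;
* **local diffusion coefficient** — mean-square-displacement diffusion
  of the molecules that start in the shell;
* **hydrogen-bond lifetime** — the 1/e time of the intermittent
  protein–solvent hydrogen-bond autocorrelation;
* **local viscosity and mobility descriptors** derived from these;
* **regional protein flexibility** (integrated RMSF) and its
  correlation with each descriptor; and
* **conformational transition rates** between metastable states of a
  1-D inter-region distance feature, via a coarse-grained Markov /
  hidden-Markov model.

Because the interesting quantities are all statistical estimators, every
one of them is paired with a synthetic generator whose ground truth is
known exactly; the test suite is built on parameter recovery rather than
on frozen numbers from any particular simulation.

## Shell definition

The first solvation shell of a region is defined by a *proximal* radial
distribution function: for each solvent molecule's reference site (the
water oxygen, the nitrile nitrogen, the hydroxyl oxygen of alcohols, or
the centre of geometry for apolar species) the distance to the *nearest*
region atom is histogrammed. Because the equal-nearest-distance shells
around an irregular atom cluster are not spherical, bin volumes are
estimated by Monte-Carlo insertion (default 1e5 points per analysed
frame, fixed seed). Two normalisations are provided and cross-checked:
dividing by the bulk site density (`proximal_mc`, the default) or by the
mean count density over the outermost 20% of bins (`plateau`). The shell
cutoff is the first local minimum after the first maximum of the
smoothed g(r) (centred 3-bin moving average; ties broken toward smaller
r), with the bin width as its uncertainty.

When detection is skipped, per-solvent defaults apply: 0.5 nm
(acetonitrile), 0.6 (n-butanol), 0.4 (tert-butanol), 0.7 (cyclohexane)
around exterior regions, each widened by 0.2 nm around interior regions.
Water deliberately uses 0.5/0.7 nm so that its shell spans two hydration
layers — this keeps aqueous residence times comparable with the
literature convention, while organic solvents use the first layer only.
Whether membership should consider all region atoms or side-chain atoms
only is genuinely open (proximal RDFs are conventionally computed around
side chains, while shell membership usually uses all atoms); both are
supported and all-atom is the default.

## Estimators and their conventions

**Residence time.** The survival correlation C_res(t) is the probability
that a molecule in the shell at a time origin is still *continuously*
inside a lag t later. The default treats the occupancy indicator as
absorbing (first-exit convention), making C_res monotone; a
re-entry-tolerant variant implements the literal product form
⟨h(t)h(0)⟩. Two estimators are reported: the 1/e crossing of C_res by
linear interpolation (`tau_corr`), and the mean of first-exit times over
all (molecule, entry) episodes (`tau_hist`), with censored episodes
(those touching the end of a block) dropped. An episode of L inside
frames exits somewhere in the frame interval ((L−1)·dt, L·dt]; the
histogram estimator assigns the midpoint (L−½)·dt, which removes the
O(dt) interval-censoring bias and leaves both estimators unbiased to
O(dt²) on exponential exits. On exponentially
distributed synthetic exits the two agree within sampling error; a curve
that never reaches 1/e is flagged as a lower bound rather than reported
as a number.

**Diffusion.** MSD is averaged over time origins and over the molecules
that are shell members *at the origin*; molecules are then tracked
through unwrapped coordinates for the full lag window even if they exit.
Evaluating membership at the origin only avoids survivorship bias toward
slow molecules (conditioning on remaining in the shell would
preferentially keep the slow ones). D is the least-squares slope over
the fit window divided by 6; the default window is 2–10 ps with origins
every frame, both configurable. Diffusion is reported in 1e-5 cm²/s
(1 nm²/ps = 1000 of these units).

**Hydrogen bonds.** The geometric criterion is donor–acceptor distance
≤ 0.35 nm and H–donor–acceptor angle ≤ 30°; the correlation is the
intermittent form ⟨h(0)h(t)⟩/⟨h⟩ (bonds may break and reform), and the
lifetime is its 1/e crossing. The forward/backward rate decomposition of
the full kinetic treatment is out of scope; only the 1/e time is
reported. Apolar solvents yield a not-applicable result rather than a
zero.

**Uncertainties.** Everything is block-averaged: estimates are computed
per consecutive time block and reported as mean ± t_{n−1,0.975}·s/√n.
Block length is a configuration parameter: production analyses of
100 ns trajectories would use 25 ns blocks; the package's own tests use
ps-scale blocks on synthetic data.

## Viscosity and mobility descriptors

In the Stokes–Einstein limit viscosity and diffusion are inversely
proportional at fixed radius, which gives the two scalings used
throughout:

* apparent model viscosity of a bulk solvent model,
  η_model = η_exp · D_exp / D_model;
* local (interfacial) viscosity of a shell,
  η_local = η_bulk · D_bulk / D_local, or equivalently from
  reorientation times, η_interface = η_bulk · τ₂,interface/τ₂,bulk.

Two dimensionless descriptors complete the set: the *solvent mobility
ratio* D_solvent,region/D_water,region (how the organic solvent moves
relative to water around the same region) and the *surface retardation
factor* D_solvent,region/D_solvent,bulk (how much the surface slows the
solvent relative to its own bulk). All descriptor arithmetic is done on
unrounded values and rounded only at report time (2 d.p. for
viscosities, 3 for diffusion), because the bundled reference table
itself contains printed-rounding inconsistencies that propagate if one
chains rounded values.

The Kramers high-friction rate, k ∝ (1/η_local)·exp(−H*/RT), ties the
descriptors to conformational kinetics: at equal barrier height, rates
scale inversely with the local viscosity. The package's double-well
Langevin generator provides the corresponding test bed — for the
overdamped equation, changing the friction γ is exactly a rescaling of
time, so the escape-rate ratio between two friction values equals the
inverse friction ratio up to sampling noise.

## Flexibility and correlation panels

RMSF is computed per atom about its time-mean position after a
least-squares rigid-body superposition; the reference is the
trajectory's own iterated mean structure (first-pass fit to frame 1,
then one refit to the mean) because RMSF measures fluctuation about the
mean, not distance from a crystal structure. Per-residue values are the
unweighted mean over the variant's atom set (all-atom, side-chain-only,
or Cα; mass weighting is available but off by default since the
convention is not universal). Regional flexibility is the plain sum of
per-residue RMSF over the region — a rectangle rule in residue index —
and flexibility ratios divide a solvent run by the water run, pinning
the water point at 1.

The correlation stage assembles one panel per region × RMSF variant ×
descriptor, with x one of {1/η_bulk, mobility ratio, retardation,
1/η_local} and y the flexibility ratio, and reports the Pearson r. The
water point is included by default (its y is 1 by construction and its
mobility-ratio x is exactly 1); a flag excludes it, since four-point and
five-point conventions both occur. No p-values are attached at n ≤ 5.

## Conformational kinetics

The 1-D feature is the minimum heavy-atom distance between two regions
(e.g. the two lids of a binding cleft). It is discretised into uniform
bins (default 60; empty bins removed, indices densely remapped),
transition counts are collected with a sliding window at the working
lag, restricted to the largest strongly connected microstate set, and
the reversible maximum-likelihood transition matrix is obtained by the
standard fixed-point iteration (likelihood tolerance 1e-10). Implied
timescales t_i(τ) = −τ/ln λ_i(τ) across lags diagnose Markovianity;
eigenvalues ≥ 1 are reported as an infinite (upper-bound-flagged)
timescale.

Three metastable states are fixed by design (closed / crystallographic /
open semantics). PCCA+ memberships come from the inner-simplex vertex
search on the top three eigenvectors; in the decoupled limit they are
crisp block indicators, and the stationary weights are floored at 1e-10
so that the exactly reducible limit remains computable. The
discrete-output hidden Markov refinement runs Baum–Welch on lag-strided
symbol sequences (all offsets contribute), initialised from the PCCA+
memberships. Convergence requires the log-likelihood gain to fall below
1e-8 *relative to the likelihood magnitude* — an absolute 1e-8 gain is
unattainable in bounded iterations once sequences reach ~1e5 symbols,
where |log L| itself is of order 1e5 — and hidden states are canonically
ordered by their mean observed feature value so that labels are
reproducible across runs and resamples.

Rates are first-order at the working lag, k_ij = T_ij(τ)/τ, reported in
1e-3 ns⁻¹; a generator-matrix logarithm is deliberately not attempted.
The linearisation biases rates low by roughly (state exit rate)·τ/2
relative, so the lag should be chosen with (exit rate)·τ ≲ 0.05 when
quantitative rates are needed; at larger lags the estimate converges to
exp(Kτ)/τ rather than K. Uncertainties come from
bootstrapping whole trajectories with replacement (default five
resamples, matching the five-data-set convention) and refitting the
entire chain, reported as per-element standard deviations.

## What the synthetic generators do and do not emulate

Each generator reproduces exactly the statistical structure one
estimator assumes: Brownian displacements for MSD fitting, exponential
shell exits, a stationary telegraph process for bond indicators, an
exactly simulated Markov jump process (exponential waiting times sampled
onto the frame grid — no discretisation bias) for the conformational
feature, isotropic harmonic fluctuations for RMSF, and overdamped
Euler–Maruyama dynamics in a quartic double well (stability guard
dt·γ < 0.1). They do *not* emulate realistic water structure,
hydrogen-bond geometry, force fields, or protein anharmonicity. Passing
recovery tests therefore demonstrates that the estimators are correct
and unbiased under their own assumptions at the stated sample sizes; it
does not certify behaviour on real MD data, where shell exits are not
exponential and features are not Markovian at all lags. The
reference-value tables bundled with the package carry published
per-helix observables for a lipase in five solvents so that the
descriptor arithmetic can be exercised end-to-end on realistic numbers.

## Numerical choices and problem sizes

* 1/e crossings are always linear interpolation between bracketing
  samples; no exponential fits.
* Minimum-image displacements use the round-to-nearest convention with
  components in (−L/2, L/2]; only orthorhombic boxes are supported.
* The superposition rank check rejects collinear fit-atom sets; SVD
  reflections are corrected by the determinant sign.
* All generator randomness flows from one explicit seed per call
  (default 7), and the caller's RNG state is restored afterwards.
* The recovery tests run at sizes chosen to hold estimator noise well
  inside the asserted tolerances: 1000 particles × 2000 frames for
  diffusion (5%), 1e4 molecules for residence times (5%), 1000 pairs ×
  4000 frames for bond lifetimes (10%), 80 residues × 5000 frames for
  RMSF (5%, r > 0.99), five 2e5-frame trajectories for the
  hidden-Markov rate recovery (within bootstrap 2σ), and two 3e6-step
  Langevin runs for the friction scaling (ratio 2 ± 15%).

## Limitations

Triclinic boxes, velocities/forces, Voronoi shell definitions, SASA
decompositions, Bayesian MSM posteriors, multi-dimensional featurisation
and frequency-dependent (Grote–Hynes) friction are out of scope. XTC
trajectories are not readable here — convert to DCD, multi-frame GRO or
the package's plain-text fixture format. Rates from T_ij(τ)/τ inherit a
small low bias growing with exit-rate·τ, and the hidden-Markov stage
assumes emission distributions that do not overlap too heavily between
metastable states.
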