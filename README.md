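# solvshell

Regional solvation-shell dynamics and protein flexibility from
molecular trajectories.

## What it is for

Protein regions move through the friction of their own solvation layer:
a helix surrounded by mobile solvent is free to fluctuate, one caged by
sluggish solvent is damped. For enzymes in organic media this is the
mechanism behind the classic loss of flexibility and activity, and it is
*local* — different solvents slow down different parts of the same
protein. `solvshell` is for structural-bioinformatics and
molecular-modelling work that needs this picture quantified per region:
given a solute + solvent trajectory and a map of named regions (residue
ranges labelled helix/sheet/loop/connector, exterior/interior), it
computes

- **first-shell definition**: proximal radial distribution functions
  g(r) of nearest-region-atom distances, Monte-Carlo shell volumes,
  first-minimum cutoff detection, per-frame shell membership;
- **shell solvent dynamics**: residence times from the survival
  correlation C_res(t) = ⟨h(t)h(0)⟩ (1/e time) and from first-exit
  histograms; local diffusion coefficients from the Einstein relation
  ⟨r²⟩ = 6Dt; hydrogen-bond lifetimes from the intermittent
  autocorrelation ⟨h(0)h(t)⟩/⟨h⟩; P₂ reorientation times — each with
  block-averaged student-t 95% CIs;
- **viscosity/mobility descriptors**: η_model = η_exp·D_exp/D_model,
  η_local = η_bulk·D_bulk/D_local (or the τ₂-ratio variant), solvent
  mobility ratio, surface retardation factor, Stokes–Einstein D_T/D_R,
  and Kramers high-friction rates k ∝ (1/η_local)·e^(−H*/RT);
- **protein flexibility**: Kabsch superposition, per-residue RMSF
  (all-atom / side-chain / Cα), regional integration and ratios versus
  the aqueous run, RMSD and radius-of-gyration sanity checks;
- **descriptor–flexibility correlation panels** (Pearson r per region ×
  variant × descriptor);
- **conformational kinetics**: a 1-D inter-region minimum-distance
  feature, microstate MSM (reversible MLE), implied timescales, PCCA+
  coarse-graining into three metastable states, a discrete-output
  hidden-Markov refinement, and transition rates k_ij = T_ij(τ)/τ in
  10⁻³ ns⁻¹ with bootstrap uncertainties.

Every estimator has a matching synthetic generator with exact ground
truth (`gen_brownian`, `gen_shell_exchange`, `gen_telegraph`,
`gen_jump_feature`, `gen_harmonic_protein`, `gen_double_well_langevin`,
`gen_solvated_fixture`), so correctness is established by parameter
recovery.

Units throughout: lengths nm, times ps, diffusion reported in
10⁻⁵ cm²/s, viscosity mPa·s, transition rates 10⁻³ ns⁻¹.

## Worked example

Bulk reference values for the five study solvents ship with the package;
the descriptor arithmetic runs off them directly:

```r
library(solvshell)
tab <- solvent_reference_table()
acn <- tab[tab$solvent == "acetonitrile", ]

## apparent viscosity of the acetonitrile model
model_viscosity(acn$eta_exp_mPas, acn$D_exp, acn$D_model)
#> [1] 0.3410390

## water-model diffusion error vs experiment (percent)
w <- tab[tab$solvent == "water", ]
percent_error(w$D_model, w$D_exp)
#> [1] 8.260870

## how much does cyclohexane slow down around the mobile alpha5 helix?
dyn <- calb_regional_dynamics()
D5 <- dyn$D[dyn$solvent == "cyclohexane" & dyn$helix == "alpha5"]
mobility_descriptors(D5, 1, tab$D_model[tab$solvent == "cyclohexane"])$retardation
#> [1] 0.9047619
```

So the acetonitrile model behaves like a 0.34 mPa·s fluid (its diffusion
runs fast relative to experiment, hence an apparent viscosity below the
experimental 0.39), the water model diffuses 8.3% faster than real
water, and cyclohexane around the α5 helix keeps ~90% of its bulk
mobility — one of the least-retarded shells in the reference set.

Estimator recovery on synthetic data works the same way:

```r
b <- gen_brownian(1e-3, n_particles = 1000, n_frames = 2000, dt = 1,
                  box = 6, seed = 101)
diffusion_coefficient(b$traj, fit_window = c(2, 10))$D_nm2ps
#> [1] 0.0009981882   # truth: 1e-3 nm^2/ps
```

An end-to-end run goes through one YAML config:
`run_pipeline("run.yaml")` writes the per-region dynamics table,
descriptor table, RMSF profiles and (optionally) MSM rates plus a
manifest with seeds and a config hash; `inst/scripts/solvshell.R` is a
thin command-line wrapper over the same functions.

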