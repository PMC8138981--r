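# foldsense

Tools for quantifying **co-translational protein folding** from spectral
imaging and simulation data, built around the question: does a domain fold
while it is being translated, and does a point mutation derail that
folding even when the finished protein could fold in vitro?

The package is aimed at structural and molecular biophysicists working
with fluorescent-protein FRET reporters, arrest-peptide (SecM) force
sensors, and conformational free-energy analysis of mutation sites. It
implements four connected analyses:

1. **Spectral FRET quantification** — non-negative least-squares unmixing
   of 32-band emission stacks against donor/acceptor references, integral
   and peak-ratio FRET indices, expression-window QC, and efficiency via
   saturating transfer functions `E(x) = a + b·x/(x + c)`. Two published
   calibrations ship as presets: `hek_cfp_yfp` (0.001, 1.0022, 2.11) and
   `bact_tfp_venus` (−0.9279, 1.9335, 0.6821).
2. **Förster theory** — overlap integral
   `J = ∫ f_D(λ) ε_A(λ) λ⁴ dλ`, Förster radius
   `R₀ = 0.211 (κ² n⁻⁴ Q_D J)^{1/6}` Å, the efficiency–distance law
   `E = 1/(1+(r/R₀)⁶)`, and derivation of transfer functions by forward
   simulation plus nonlinear fit.
3. **Conformational two-state analysis** — side-chain inclination angles
   from coordinates, N/T state classification, potentials of mean force by
   Boltzmann inversion (`F = −kT ln p`) and by WHAM over umbrella windows,
   pairwise Lennard-Jones/Coulomb interaction energies, and an ensemble
   Metropolis ΔΔG protocol (`ΔΔG = ΔG_mut − ΔG_ref`; positive means the
   reference binds more strongly).
4. **Force-profile analysis** — full-length-fraction readout of
   arrest-peptide construct libraries over tether lengths, replicate
   aggregation, peak-significance calls, and soluble-fraction
   densitometry.

A first-class **synthetic-data module** generates every input with known
ground truth — spectral mixtures at chosen efficiency, overdamped Langevin
trajectories of double-well angle landscapes, toy helix/side-chain/partner
structures, and stalling-release profiles — so the whole pipeline is
testable without external data. All stochastic functions take explicit
seeds; there is no hidden RNG state.

## Worked example

```r
library(foldsense)

## Calibrate an index-to-efficiency transfer function for a CFP/Citrine pair
cfp <- fluorophore_preset("mCFP")
cit <- fluorophore_preset("mCitrine")
pair <- forster_pair(cfp, cit)
pair
#> <forster_pair mCFP -> mCitrine: J = 1.78e+15 M-1cm-1nm4, R0 = 47.28 A (kappa2 = 0.667, n = 1.4)>
tf <- derive_transfer_function(pair)
tf
#> <transfer_function E(x) = 1.086e-10 + 1 * x/(x + 2.263), R^2 = 1.0000 [fitted(mCFP/mCitrine, laser 405 nm, 32 bands, 20-point E grid)]>

## Simulate cells at known efficiencies, unmix, and recover them
scene <- ground_truth_scene(c(0.05, 0.18, 0.40))
stack <- simulate_spectral_stack(cfp, cit, scene)
um <- unmix(stack, band_reference(cfp, stack$band_edges),
            band_reference(cit, stack$band_edges))
idx <- fret_index_integral(um)
round(data.frame(fret_index = idx, efficiency = apply_transfer(tf, idx)), 4)
#>   fret_index efficiency
#> 1     0.1191       0.05
#> 2     0.4967       0.18
#> 3     1.5085       0.40

## Two-state side-chain landscape: sample, classify, profile
traj <- simulate_double_well_trajectory(dw_preset("w344r"), dt = 0.5,
                                        n_steps = 2e5, seed = 42)
classify_states(traj, boundaries = "auto")
#> <state_assignment: boundary 73.6 deg; populations T = 0.946, N = 0.054; 97 transitions>

## Force profile: the reference library peaks at a 22-residue tether
prof <- build_profile(simulate_fpa_profile(fpa_preset("wt_cam"), seed = 42))
profile_peak(prof)
#> [1] 22

## Ensemble Metropolis ddG on the toy binding models
metropolis_ensemble_ddg(toy_model_preset("wt"), toy_model_preset("w344r"),
                        n_runs = 10, n_moves = 5000, seed = 42)
#> <ddg_result: ddG = -55.718 (dG_mut -75.606 - dG_wt -19.888), 10 runs, kT_mc = 1.2, SEM(paired) = 0.051>
```

The recovered efficiencies match the planted 0.05/0.18/0.40 exactly at
zero noise; the mutant-like landscape spends most of its time in the
tilted (T) orientation with frequent interconversion, while the `wt`
landscape (not shown) stays native with zero transitions; the negative
ΔΔG reflects the toy models' sign convention (the mutant-like bound state
is the more favourable one).

An end-to-end demonstration that chains all four analyses and writes CSV
tables, figures and a deterministic JSON summary:

```r
run_demo(run_config(seed = 1, out_dir = "foldsense_demo"))
```

See `vignettes/foldsense-methods.Rmd` for the models, defaults,
numerical choices and limitations.

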