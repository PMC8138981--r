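---
title: "Models and methods behind foldsense"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind foldsense}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(foldsense)
```

foldsense quantifies whether a protein domain folds during translation, by
three complementary computational readouts: FRET efficiency between
fluorescent reporters flanking the domain, force-profile analysis of
arrest-peptide construct libraries, and a two-state conformational
free-energy analysis of the side chain at a mutation site. Every readout is
exercisable on in-package synthetic data with known ground truth; this
vignette documents the underlying models, the defaults and why they were
chosen, the numerical choices, and what the synthetic tests do and do not
demonstrate about real data.

## The spectral FRET model

A spectral confocal detector records 32 contiguous 5-nm emission bands
covering 450–610 nm. For a pixel containing donor abundance $d$, acceptor
abundance $a$, and true transfer efficiency $E$, the noiseless band-$b$
signal is modelled as

$$
S_b = d\,X_D\,Q_D\,(1-E)\,F_{D,b}
    + \bigl(d\,X_D\,Q_A\,E + a\,X_A\,Q_A\bigr)\,F_{A,b},
$$

where $X_D, X_A$ are the excitation efficiencies of donor and acceptor at
the laser line, $Q_D, Q_A$ the quantum yields, and $F_{\cdot,b}$ the
fraction of the (unit-area) emission spectrum captured by band $b$. The
three terms are quenched donor emission, FRET-sensitized acceptor emission,
and direct cross-excitation of the acceptor at the donor laser line. The
cross-excitation term is configurable and on by default: the instrument's
noise statistics and background treatment are not documented for the
original acquisitions, so the forward model errs on the side of including
the physically present term.

`unmix()` decomposes each measured band vector into non-negative donor and
acceptor contributions by non-negative least squares against reference
emission shapes (the open equivalent of vendor unmixing software), with a
condition-number guard against near-collinear references. The **integral
FRET index** is the ratio of unmixed acceptor to donor emission areas; with
unit-area references it is simply the coefficient ratio. A **peak-ratio
index** (mean intensity over an acceptor band divided by a donor band,
half-open `[lo, hi)` windows on the 5-nm grid) serves fluorimeter spectra.
Samples are admitted by an inclusive expression window (default 20–170
arbitrary units in both the FRET and the direct-acceptor channel); the
boundary convention is documented as inclusive and configurable because
only the interval itself is standard.

### Index-to-efficiency transfer functions

The saturating map

$$ E(x) = a + b\,\frac{x}{x + c}, \qquad c > 0 $$

links the measured index $x$ to efficiency. Two published calibrations
ship as presets: `hek_cfp_yfp` with $(a,b,c) = (0.001,\,1.0022,\,2.11)$
for living-cell CFP/YFP imaging, and `bact_tfp_venus` with
$(-0.9279,\,1.9335,\,0.6821)$ for bacterial mTFP1/mcpVenus spectra. The
negative intercept of the second preset is physical — direct acceptor
cross-excitation produces a nonzero index even at zero transfer — and for
that reason clamping of efficiencies into $[0,1]$ is **off by default**,
with a `clamped` attribute recording any clipping when enabled.

`derive_transfer_function()` reproduces the calibration procedure: forward
simulate noiseless stacks on an efficiency grid (default $0$ to $0.95$ in
steps of $0.05$), unmix, compute indices, and fit $(a,b,c)$ by unweighted
nonlinear least squares started at $a=0$, $b=1$, $c=\mathrm{median}(x)$.
Under the forward model with 1:1 stoichiometry the map is exactly of this
form — with no cross-excitation $a=0$, $b=1$ and
$c = Q_A B_A / (Q_D B_D)$ in terms of band-capture fractions $B$ — so fits
achieve $R^2 > 0.99$ easily; the published parameter values themselves are
validated by functional form and round-trip behaviour, not by exact
parameter equality, because the original detection-band weighting is not
documented.

### Förster theory

The overlap integral $J = \int f_D(\lambda)\,\varepsilon_A(\lambda)\,
\lambda^4\,d\lambda$ (donor emission area-normalized, trapezoidal
quadrature after linear resampling to the finer grid) feeds the sixth-root
law $R_0 = 0.211\,(\kappa^2 n^{-4} Q_D J)^{1/6}$ Å with the conventional
defaults $\kappa^2 = 2/3$ and $n = 1.4$, and
$E(r) = 1/(1 + (r/R_0)^6)$. Units are fixed to
M$^{-1}$cm$^{-1}$nm$^4$ for $J$, matching the most common calculator
convention. The built-in fluorophores are **Gaussian stand-ins** (not
lognormal, not measured shapes) with literature quantum yields — 0.41
(mCFP), 0.74 (mCitrine), 0.85 (mTFP1), 0.64 (mcpVenus); measured spectra
can be supplied as CSV and flow through the same machinery, which is how
quantitative $R_0$ values for real pairs should be obtained.

## Conformational two-state analysis

The mutation-site side chain is described by its inclination angle
$\theta \in [0^\circ, 180^\circ]$ between the recognition-helix axis
(leading principal component of the C$\alpha$ trace, sign toward
increasing residue index) and the C$\alpha\to$tip vector. The tip rule is
explicit because no operational definition is standard: the six-membered
ring centroid for tryptophan, the guanidinium carbon for arginine, a `TIP`
pseudo-atom for toy structures, or any user-supplied atom set. $\theta$ is
an inclination between two vectors, hence non-periodic: all samplers use
reflective boundaries at 0° and 180°.

### Landscapes and sampling

The two-state landscape is a quartic double well parameterized directly by
the well positions, depths and barrier height — the minimal form carrying
the two-minima picture without claiming any particular microscopic shape.
Two presets encode the qualitative biology: a `wt`-like landscape (native
well at 95°, 5.0 kcal/mol deep; tilted well at 45°, 0.5 kcal/mol; barrier
2.0 kcal/mol above the shallow well) whose native-to-tilted barrier of
~6.5 kcal/mol (~11 kT) suppresses spontaneous escapes on any accessible
run length, and a `w344r`-like landscape (depths 1.0/2.0 kcal/mol, barrier
1.2) in which both states interconvert and the tilted state is favoured.
All free energies use $kT = 0.5925$ kcal/mol (298 K).

Sampling is overdamped Langevin (Euler–Maruyama),
$\theta \leftarrow \theta - U'(\theta)\,dt/\gamma +
\sqrt{2kT\,dt/\gamma}\,\xi$, a deliberate one-dimensional stand-in for
all-atom dynamics: it reproduces equilibrium populations and barrier
phenomenology of the input landscape but says nothing about molecular
kinetics in physical time. Seeds are mandatory arguments everywhere —
there is no hidden global state. The integrator refuses step sizes whose
deterministic drift near the start region or barrier exceeds 5°/step and
aborts if any realized step exceeds 30°.

### Free-energy estimation

`pmf_boltzmann()` is direct inversion $F = -kT\ln p$ with never-visited
bins reported as undefined (`NA`) rather than zero — an unexplored range
has infinite apparent free energy and must not masquerade as the global
minimum. `pmf_wham()` implements the standard self-consistent WHAM
iteration over harmonically biased windows (tolerance $10^{-7}$ kcal/mol
on window free energies, $10^5$ iteration cap, errors on non-convergence).
A single zero-bias window reduces WHAM exactly to inversion, which the
tests assert to $10^{-10}$. Both routes are provided because either
reweighted unbiased runs or umbrella windows may be the source data.
Umbrella spacing matters in practice: for the preset landscapes, windows
every 10° with spring 0.05 kcal/mol/deg² recover the quadrature-oracle
well-depth difference; halving the window density visibly biases the
reconstruction, and the package warns when adjacent windows share less
than 1% histogram mass.

### Interaction energies and the ensemble ddG

`nonbonded_energy()` scores pairwise Lennard-Jones plus Coulomb terms
(`332.0636` kcal·Å/mol·e²; geometric-mean $\epsilon$, summed rmin halves)
with a plain 12 Å cutoff. The toy systems are small and non-periodic, so
no Ewald treatment is attempted — this is a documented divergence from
production force-field practice, adequate for ranking toy configurations.

`metropolis_ensemble_ddg()` mirrors the structure of ensemble
mutation-scoring protocols: 50 independent runs by default, each a chain
of 50,000 single-coordinate perturbation moves accepted by the Metropolis
criterion at a dimensionless score temperature of 1.2 (applied to the toy
score directly, not a multiple of thermal kT), with coordinates saved
every `n_moves/10` so each run contributes 10 snapshots. True backrub
moves rigidly rotate backbone segments; the reduced model represents that
degree of freedom as harmonic nuisance coordinates perturbed by the same
move kernel, preserving the accept/reject protocol under test without an
internal-coordinate engine. A run's binding score is the snapshot mean of
$E_\mathrm{complex} - E_\mathrm{separated}$, and
$\Delta\Delta G = \overline{\Delta G}_\mathrm{mut} -
\overline{\Delta G}_\mathrm{ref}$: positive values mean the reference
binds more strongly. The toy interaction levels (−20/−10 kcal/mol for the
reference, −76/−16 for the mutant-like model, native/tilted) are
configuration constants chosen so the native orientation is the
binding-competent one and the mutant's bound state is the more favourable
— the protocol's machinery (reproducibility from matched seeds, null
behaviour, acceptance statistics, sign convention) is what the package
validates, not any particular ddG magnitude, which would require
production-scale all-atom scoring.

## Force-profile analysis

An arrest-peptide construct library varies the tether length between a
domain and the stalling sequence; folding-generated force relieves
stalling, so the ratio of C-terminal (acceptor) to N-terminal (donor)
reporter emission — the full-length fraction — peaks at the tether length
where folding happens at the tunnel. Tether lengths count from the
C-terminal conserved proline of the arrest peptide with the 17 AP residues
included; the construct table stores the post-Pro count directly to avoid
ambiguity. The default library is {18, 22, 24, 27, 34, 40, 50} residues.

The generator's profile shape is baseline + amplitude × (linear ramp from
onset to peak, then exponential decay), with Gaussian replicate noise
truncated at zero. Presets: `wt_cam` (onset 20, peak 22, decay 0.15/res,
amplitude 1.0, baseline 0.1, noise sd 0.05, three replicates), `w344r_cam`
(onset 24, plateau from 34 on, amplitude 0.35 — a broad damped response
with no sharp maximum), and `no_cam` (baseline only). Replicates aggregate
as mean ± sd (not SEM) because the sd feeds the significance rule.

When a profile "has a peak" is genuinely a judgement call, so the detector
makes its rule explicit: a point is a significant peak when it strictly
exceeds its two nearest profile points by at least $k$ pooled replicate
standard deviations ($k = 2$ default, pooled as root mean variance), and a
peak is reported only when exactly one point qualifies. Requiring two
comparisons for endpoints as well as interior points keeps the
false-positive rate of pure-noise profiles below ~2% at the default
settings; plateaus and flat profiles return "none". The rule is
configurable and should be recalibrated if real replicate structure
differs from the generator's i.i.d. Gaussian noise.

`soluble_fraction()` is the companion gel-densitometry readout,
SN/(SN + P) of band intensities.

## What the synthetic data does and does not show

The generators emulate: spectral mixtures at known efficiency under
Poisson or Gaussian noise; Langevin sampling of known angle landscapes;
idealized helix/side-chain/partner coordinate sets; and
stalling-release profiles with known peak structure. Passing tests
therefore demonstrate that the estimators are *correct* — unmixing is
exact on noiseless mixtures and oracle-consistent otherwise, the FRET
pipeline round-trips efficiencies to <0.02 at zero noise, WHAM matches
quadrature, Metropolis acceptance matches the Bernoulli oracle, peak
calls recover planted truth ≥95% of the time. They do not demonstrate
robustness to what real data adds: non-Gaussian spectral shapes,
background and bleed-through structure, detector nonlinearity, correlated
replicate error, or the full kinetics of molecular systems. The noise
statistics of the original spectral detector are not documented, so both
Gaussian and Poisson options are provided without asserting either
matches the instrument.

## Problem sizes and determinism

Default problem sizes are chosen so the full test suite and the
demonstration run complete in minutes on one CPU: $10^4$–$10^6$ Langevin
steps, 15 umbrella windows of $2\times 10^4$ steps, ensemble ddG at
reduced size (the 50 × 50,000 protocol defaults remain available), and
200-library peak-call calibrations. Every stochastic function takes an
explicit seed; `run_demo()` fans a single global seed out to per-stage
seeds as `seed × 100 + stage index`, so stages are independently
reproducible and the JSON summary is byte-identical across repeated runs.

## Known limitations

* Gaussian spectral stand-ins approximate real fluorophore shapes only
  coarsely; quantitative $R_0$ for real pairs requires measured spectra.
* The 1-D Langevin landscape is a phenomenological stand-in; its time
  axis is arbitrary and its barriers are inputs, not predictions.
* The ddG machinery validates protocol behaviour, not energetics; its
  scores are toy-model units.
* The cutoff-based pair energy ignores long-range electrostatics and
  periodicity.
* The peak-significance rule is a stated stand-in for a qualitative
  judgement; its constants are calibrated against the package's own noise
  model.
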