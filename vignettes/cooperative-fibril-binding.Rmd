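---
title: "Cooperative ligand binding to fibrils: model, numerics, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cooperative ligand binding to fibrils: model, numerics, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fibrilbind)
```

## The physical model and its assumptions

`fibrilbind` treats a protein fibril as a one-dimensional lattice of N
equivalent ligand binding sites — a lattice gas, or equivalently a spin
model with a chemical potential. The assumptions that define the model's
scope:

* **Equivalent sites.** Every site has the same intrinsic dissociation
  constant ($K_D$ for the radioligand, $K_I$ for an inhibitor). Fibril
  polymorphs with multiple inequivalent sites are out of scope.
* **Nearest-neighbor cooperativity only.** Two ligands on adjacent sites
  contribute one extra energy $C$ (kcal/mol), i.e. one multiplicative
  Boltzmann factor $\alpha = e^{-C/k_BT}$ per adjacent pair:
  $\alpha_L$ (L–L), $\alpha_I$ (I–I), $\chi$ (L–I). Energies are additive,
  so factors multiply along the fibril. Longer-range (delocalized)
  couplings are not modeled.
* **No ligand depletion.** Free concentrations $[L]$, $[I]$ are fixed;
  the lattice is in the grand-canonical ensemble with per-site activities
  $[L]/K_D$ and $[I]/K_I$.
* **Equilibrium readout.** The measured signal is proportional to the
  thermodynamic average occupancy, $CPM = B_{max}\langle f_L\rangle
  + ns\,[L] + b_0$, with non-specific binding linear in concentration.

With these assumptions the infinite-fibril saturation isotherm has the
closed form implemented in `saturation_fraction()`, with midpoint
$EC_{50} = K_D/\alpha_L$, midpoint log-slope $\sqrt{\alpha_L}/4$, and the
exact particle–hole symmetry $f(c) + f(1/(\alpha^2 c)) = 1$. The fully
saturated competition experiment reduces to a two-state lattice whose
displacement curve `competition_fraction()` depends only on
$x = [I]/IC_{50}$ and $\beta = \chi^2/(\alpha_L\alpha_I)$; the test-suite
verifies this reduction numerically against the full three-state transfer
matrix (`saturating_limit_check()`) rather than assuming it.

## Parameters that matter

| Parameter | Units | Meaning | Default / convention |
|---|---|---|---|
| $K_D$, $K_I$ | molar | intrinsic per-site affinity | — |
| $\alpha_L$, $\alpha_I$, $\chi$ | — | nearest-neighbor Boltzmann factors; $>1$ favorable | 1 (no cooperativity) |
| $C_L$ etc. | kcal/mol | the same cooperativities as energies | via `factor_from_energy()` |
| $T$ | K | temperature behind energy↔factor conversion | 298.15 |
| $k_B$ | kcal mol⁻¹ K⁻¹ | gas constant in energy-per-mole form | 1.987204259e−3 |
| $\beta$ | — | $\chi^2/(\alpha_L\alpha_I)$, competition shape | 1 |
| N | sites | fibril length | 1000 for simulator comparisons |
| $B_{max}$, $ns$, $b_0$ | CPM, CPM/M, CPM | signal model | — |

"Room temperature" is fixed at 298.15 K. The package states cooperativity
energies in kcal/mol; any temperature between 293 and 310 K rounds
$-k_BT\ln 10$ to the same one-decimal energy (−1.4 kcal/mol for a factor
of 10), so the choice does not affect reported energies at the precision
used in practice.

## Exact lattice numerics

**Infinite lattice.** The transfer matrix is built in the symmetric
convention $T(s,s') = \sqrt{w_s}\,p(s,s')\sqrt{w_{s'}}$ so that the
principal eigenpair is real and site probabilities are simply the squared
components of the normalized Perron eigenvector (equivalent to the
Hellmann–Feynman derivative $w_s\,\partial\ln\lambda/\partial w_s$).
Neighbor-pair probabilities are the bilinear form $v_sT(s,s')v_{s'}/\lambda$.

**Finite fibrils.** Free-boundary occupancies come from forward/backward
boundary-vector products, renormalized at every site so that only
probability ratios are ever formed — no partition function is materialized
and arbitrarily long fibrils cannot overflow (verified at $N = 10^5$ with
activities of $10^3$). Periodic fibrils use the eigendecomposition with
eigenvalue ratios $(d_j/d_{max})^N$ for the same reason. Free ends carry an
$O(1/N)$ edge bias relative to the bulk (about $10^{-3}$ at $N = 1000$ for
$\alpha_L = 10$ at the midpoint); rings converge exponentially in N. The
default boundary is `free` because a physical fibril has ends; periodic is
provided for convergence studies. A one-site "ring" is defined to have no
bond, matching enumeration.

**Bound-count distributions.** `occupancy_distribution()` runs a dynamic
program over (site, end state, running count), $O(N^2k^2)$, renormalized
per site; ring topologies condition on the first site's state and combine
branches in log scale. At $\alpha_L = 1$ the distribution is exactly
Binomial($N$, $[L]/(K_D+[L])$), which the tests assert to $10^{-10}$.

**Validation strategy.** Every exact routine is checked against a
brute-force enumeration oracle (`enumerate_oracle()`, capped at $10^6$
configurations) over hundreds of randomized models, both boundaries, two
and three states, at tolerance $10^{-12}$ — and against the closed forms
where they exist.

## The Monte Carlo simulator

`mcmc_sample()` is a single-site heat-bath (Gibbs) sampler in the
grand-canonical ensemble: each update redraws one site from its exact
conditional distribution given its neighbors; one sweep visits all N sites
in a freshly randomized order. The sampler is implemented in C++ and draws
all randomness from R's RNG, so a run is bitwise reproducible from its
seed and leaves the caller's RNG state untouched. Heat bath was chosen
over Metropolis because it mixes quickly for one-dimensional lattices and
is exactly specified (no proposal tuning). Uncertainty is reported as
batch-means standard errors over ~20 batches of the thinned post-burn-in
trace. The default run (5000 sweeps, 1000 burn-in, thinning 10) is
empirically sufficient for 3-SE agreement with the exact transfer-matrix
occupancies at $N = 1000$ for activities and cooperativities of order
0.1–10, which is the regime the comparison tests exercise.

## Fitting: protocol, weighting, and identifiability

**Effective Hill coefficients depend on the fitted range**, so the package
pins a protocol (`theoretical_curve()`): 200 log-spaced concentrations
spanning occupancies 0.01–0.99, unweighted least squares on the fraction
scale. Under this protocol the $\alpha_L = 10$ saturation isotherm fits an
effective $n \approx 2.75$ (the midpoint log-slope alternative,
$n = \sqrt{\alpha_L} \approx 3.16$, is steeper because the global fit
averages over shallower tails), and the $\beta = 1$ competition curve fits
$n = 1$ exactly.

**Model fits** (`fit_saturation()`, `fit_competition()`) use bounded
Levenberg–Marquardt with five seeded starts; $K_D$, $\alpha_L$, $B_{max}$,
$IC_{50}$, $\beta$ are optimized on the log10 scale, which enforces
positivity and makes Wald intervals act on ratios. Intervals use the
$t$ quantile with residual degrees of freedom. Noise that scales with the
signal (the usual situation for counting data at 5% proportional error)
should be fit with `weights = "proportional"` ($1/CPM^2$); the
parameter-recovery suite shows each of $K_D$, $\alpha_L$, $B_{max}$ is then
covered by its own 95% interval in $\ge 90$ of 100 replicates. Coverage is
assessed per parameter: simultaneous coverage of three marginal 95%
intervals is bounded near $0.95^3$ and is not a property nominal intervals
can promise. The non-specific regressor is internally rescaled to order
one so its molar-scale gradient column is not spuriously rank-deficient.

**Identifiability.** A competition curve determines only $(IC_{50},
\beta)$: `identifiability_profile()` re-derives the predicted curve through
the molecular parameterization while sliding $\alpha_L$ over orders of
magnitude at fixed $K_D/\alpha_L$ and shows a machine-flat objective ridge
— the experiment cannot split a midpoint into per-site affinity and
cooperativity, nor $\beta$ into its factors. Saturation data with a wide
dynamic range do break the degeneracy through curve shape, and the same
profile is visibly curved there. Data confined to the midpoint region
leave $(K_D, \alpha_L)$ strongly anti-correlated, which the fit flags.
Fitting the *unsaturated* three-state competition model to data is
deliberately not offered.

## Competition curve shapes and the $\beta = 3$ threshold

At the midpoint the displacement curve has log-slope $-1/(4\sqrt\beta)$
and third log-derivative $(3-\beta)/(16\beta^{3/2})$ (series expansion of
the closed form, reproduced numerically by central differences with two
Richardson levels; the curve's odd symmetry about the midpoint cancels
even-order error terms and a step sweep confirms stability). The third
derivative's sign change at $\beta = 3$ is the package's operational
criterion for the onset of the biphasic plateau — the visual flattening
around $f_L = 1/2$ at large cross-cooperativity, where the saturated
lattice alternates L/I along the fibril (the exact pair fractions and the
MCMC sampler both show >90% unlike neighbors at $\beta = 100$).
`critical_beta()` root-finds this sign change and returns 3 to within the
root tolerance.

## Detection limits

The detection condition $\lambda n_L [F] \ge M$ uses one documented
convention: counts per unit time per unit volume, fibrils at concentration
$[F]$ each contributing $\lambda n_L$. M and $[F]$ must share the volume
unit; every derived quantity used downstream ($n_C$, $[L]_{min}/K_D$,
detection probabilities) is a ratio, so the spatial normalization drops
out. Both criteria mentioned for the two timing regimes are exposed: the
instantaneous tail probability $P(n_L \ge n_C)$ from the exact count
distribution, and the time-averaged mean criterion
$\langle n_L\rangle \ge n_C$, whose boundary reproduces
$[L]_{min} = K_D n_C/(N - n_C)$ exactly in the non-cooperative case.

## What the synthetic data represent — and what they do not

The generator reproduces the assay signal model: log- or linear-spaced
concentration grids, $CPM = B_{max}f + ns[L] + b_0$, and seeded Gaussian
noise, absolute or proportional. Default study conditions used across the
test-suite: $K_D = 1$ nM, $\alpha_L = 10$ (a stacking energy of about
−1.4 kcal/mol), $B_{max} = 1000$ CPM, 12 log-spaced points spanning
1 pM–100 nM, 5% proportional noise, $N = 1000$ sites for simulator
comparisons — values chosen once to represent a realistic tracer assay at
bench scale. Negative noisy CPM values are kept, because truncation would
bias low-signal fits. What the generator does **not** emulate: ligand
depletion at high fibril density, brain-homogenate matrix effects,
inter-fibril length heterogeneity, counting (Poisson) statistics at very
low CPM, or multiple binding sites. Passing the recovery tests therefore
shows the estimators are correct under the stated error model, not that
real ex vivo data are this well behaved — published fits on linear
concentration grids are known to be harder, a point the design comparison
(log vs linear spacing) quantifies directly.

## Numerical and degenerate-input conventions

* $c = 0$ gives occupancy 0; $x = 0$ gives radioligand fraction 1;
  $\beta = 0$ with $x = 1$ takes the symmetric limit 1/2 — all continuous
  limits of the closed forms.
* Optimizer convergence tolerances are $10^{-14}$–$10^{-15}$ on the
  objective; zero-noise recovery is exact to $10^{-6}$ relative or better.
* Root finding for `critical_beta()` uses `uniroot` on (1.5, 10) at
  tolerance $10^{-10}$.
* Problem sizes in the test-suite — 200 random lattices at $N \le 8$ for
  the enumeration cross-check, 100 MCMC property cases at $N = 200$ plus
  four at $N = 1000$, 100 fit replicates — were chosen as the smallest
  sizes that exercise each claim convincingly.

## Known limitations

Beyond-nearest-neighbor coupling, two-dimensional or inter-protofilament
lattices, secondary binding sites, kinetic (non-equilibrium) binding, and
ligand depletion are all out of scope. The sampler is validated against
exact finite-N results, not against any external reference simulation.
Hill coefficients reported by `fit_hill()` are protocol-dependent
summaries, not molecular parameters.
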