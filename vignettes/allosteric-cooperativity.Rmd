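---
title: "Quantifying nucleotide-substrate binding cooperativity in a protein kinase"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying nucleotide-substrate binding cooperativity in a protein kinase}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(allokin)
```

## The scientific problem

The catalytic subunit of protein kinase A (PKA-C) binds ATP and substrate
with positive cooperativity: nucleotide loading in the N-lobe raises the
affinity of the substrate cleft at the lobe interface by two orders of
magnitude. This synergy is carried by an allosteric network threading the
hydrophobic core of the enzyme (the regulatory and catalytic "spines" and
their shell residues), and single point mutations in the αC-β4 loop can
sever it without impairing turnover. `allokin` implements the quantitative
analysis layer used to characterize this phenomenon: NMR chemical-shift
statistics that map the network (CSP, CONCISE, CHESCA), calorimetric and
kinetic fits that measure the thermodynamic coupling (Wiseman isotherm,
cooperativity coefficient σ, Michaelis-Menten efficiency), and ensemble
analytics that connect conformationally excited states seen in simulation
to those seen by relaxation-dispersion NMR (tICA, Markov state models,
kinetic Monte Carlo, Δω comparison).

Every analysis is paired with a seeded synthetic-data generator that
emulates its input, so the entire pipeline is testable end to end with no
experimental downloads.

## Chemical-shift analyses

### CSP

For two ligation states, the combined amide perturbation is
$\Delta\delta = \sqrt{\Delta\delta_H^2 + (0.154\,\Delta\delta_N)^2}$,
with 0.154 the conventional nitrogen scaling. The across-residue mean and
standard deviation are attached to the result, since the mean + 1 sd line
is the customary significance threshold. Residues missing from either
state (e.g. exchange-broadened peaks) are flagged rather than dropped:
fabricating shifts for broadened resonances would bias every downstream
covariance.

### Residue filtering

Covariance analyses should only see residues that actually respond. A
residue is retained when, in at least one dimension, its largest
shift excursion across states exceeds the mean linewidth of the two states
realizing that excursion, $|\Delta\delta| > \tfrac12(\Delta\nu_A +
\Delta\nu_B)$. The filter is monotone (broader lines never admit new
residues). Whether the test pair must be the pair realizing the maximum
excursion or any pair is genuinely ambiguous in common usage; both readings
are implemented (`rule = "max_pair"`, the default, and `"any_pair"`).

### CONCISE

Each residue observed in all states is reduced to its leading principal
direction in the scaled $(\delta_H, 0.154\,\delta_N)$ plane. The ratio of
the two singular values measures linearity; residues with
$\sigma_1/\sigma_2$ above a threshold are kept, their projections are
normalized affinely so the first-declared state (apo, "open") maps to 0
and the last (ternary, "closed") to 1, and each state's across-residue
position set is summarized by a normal fit. Design choices that the
method's description leaves open, fixed here once:

* **Linearity threshold** defaults to $\sigma_1/\sigma_2 \ge 3$. At the
  generator's default noise this cleanly separates collinear responders
  from round scatter (isotropic 4-point scatter has a median ratio near 2);
  it is exposed as a parameter.
* **Nitrogen scaling before the PCA** defaults to 0.154 for consistency
  with the CSP metric; `scale_N = 1` reproduces the unscaled variant.
* **Anchoring** uses the first and last states of the user-declared order,
  which encodes the open → closed axis; reversing the declared order flips
  positions to $1 - x$, and uniform ppm offsets cancel exactly.

### CHESCA

Each included residue's response across $k \ge 3$ states is condensed to
one number per state (default `combined`: $\delta_H + 0.154\,\delta_N$;
`max` picks the stronger of H-only/N-only correlations per pair), and the
matrix of pairwise Pearson correlations is thresholded. Correlation scores
count the fraction of admissible pairs with $|R_{ij}|$ above a cutoff
(0.98 at residue level, 0.8 at community level); absolute values are used
because anticorrelated residues are still networked, and a signed option is
retained. Clustering runs on the distance $1-|R|$ with deterministic
complete linkage. The community score between communities A and B is
$R_{A,B} = \#\{|R_{ij}|>R_{cutoff}\} / (n_A n_B)$ over cross pairs, and the
within-community diagonal uses the $n_A(n_A-1)$ ordered off-diagonal pairs.
Four states give the analysis its usual discriminating power; three are
accepted with a warning.

## Calorimetry and kinetics

### Wiseman isotherm

The differential heat per mole of injectant for 1:1 binding is
$$\frac{dQ}{dX_{tot}} = \Delta H V_0 \left[\frac12 +
\frac{1 - (1+r)/2 - R_m/2}{\sqrt{R_m^2 - 2R_m(1-r) + (1+r)^2}}\right],$$
with $r = K_d/[M]_{tot}$ and molar ratio $R_m$. The algebra satisfies the
defining limits — a step of height $\Delta H V_0$ ending at $R_m = 1$ for
tight binding, zero past saturation, and a removable singularity at
$(r{=}0, R_m{=}1)$ handled by its limit value $\Delta H V_0/2$ — and the
integral of the differential heat over $R_m \in [0,\infty)$ is exactly one
site equivalent, which the tests verify numerically.

Titration fitting does not use the differential form directly: it uses the
exact per-injection bookkeeping, with the displaced-volume convention
(each injection displaces a fraction $v/V_0$ of cell content before
mixing), matching low-volume perfusion instruments. $K_d$ is fit in log
space for positivity, from four spread start values, with `nls.lm`;
standard errors come from the residual-scaled inverse Hessian, delta-method
transformed for $K_d$. The heat of dilution can be a fitted constant, a
subtracted blank vector, or omitted when heats are already blank-corrected.
A c-value ($n[M]_{tot}/K_d$) outside [1, 1000] triggers an identifiability
warning; the nucleotide titrations of this system sit near $c \approx 1.2$,
which is why the recovery studies fix the stoichiometry at the known 1:1
value and treat dilution as blank-subtracted — freeing both at such low c
roughly quintuples the $K_d$ sampling spread without reducing bias.

Thermodynamics use the molar standard state, $\Delta G = RT\ln K_d$ (Kd in
M, $R = 1.9872\times10^{-3}$ kcal mol⁻¹ K⁻¹), so micromolar binders give
negative free energies, and $T\Delta S = \Delta H - \Delta G$ holds as an
identity. The cooperativity coefficient is defined strictly as
$\sigma = K_d^{apo}/K_d^{nucleotide}$ for the substrate-mimic titration;
its uncertainty propagates first-order in quadrature. Fold-change
statements computed against other reference states are left to the user:
the package reports σ and its inputs.

### Michaelis-Menten

`fit_mm()` is a plain nonlinear least-squares fit of
$v = V_{max}S/(K_M+S)$ with bounded parameters, reporting
$k_{cat} = V_{max}/E_0$ and the efficiency $k_{cat}/K_M$ in (μM·s)⁻¹ with
a covariance-propagated error. When the substrate grid sits entirely below
$K_M$ the individual parameters decouple but the efficiency stays pinned by
the linear-regime slope; the fit warns and the tests confirm the ratio is
still recovered within 5%.

## Ensemble analytics

Coordinate ensembles are superposed by the Kabsch algorithm (proper
rotations only; a quaternion implementation serves as an independent test
oracle) on a rigid alignment set — for this kinase, the αE and αF helices —
and featurized as flattened Cartesian deviations of reporter atoms
(R-spine and shell residues), so rigid-body motion maps to exactly zero
features.

tICA solves $C(\tau)v = \lambda C(0)v$ with the symmetrized lagged
covariance estimator; eigenvalues are therefore real and bounded by 1 in
magnitude up to numerical tolerance, a singular $C(0)$ is ridge-regularized
(reported), and component signs follow a largest-loading-positive
convention. Microstates come from seeded k-means; the MSM is estimated
from sliding-window transition counts at a fixed lag, restricted to the
largest strongly connected component. Reversibility is imposed by count
symmetrization $(C + C^T)/2$ — deterministic and exactly
detailed-balanced, with $\pi$ proportional to symmetrized row sums —
rather than by maximum-likelihood reversible estimation, which is noted as
an extension. Discrete-time models are used throughout (no continuous-time
rates), matching the kinetic-Monte-Carlo view of discrete jumps per lag.

Macrostate populations sum $\pi$ over user-mapped microstates; their
uncertainty comes from a block bootstrap (20 contiguous blocks resampled
with replacement, 200 replicates by default) so that the chain's
autocorrelation is respected. Rotamer mutual information discretizes χ₁
series into the three canonical wells ([0°,120°), [120°,240°),
[240°,360°) after shifting to [0,360)) and uses plug-in entropies in bits
without bias correction; below 100 frames a warning flags the positive
bias of the plug-in estimator. Δω between ground- and excited-state
ensembles is the absolute difference of snapshot means with a bootstrap
sd, and predicted-vs-experimental Δω sets are compared by ordinary least
squares.

## What the synthetic generators emulate

The generators produce data with exactly the statistical structure the
analyses assume, under the study's operating conditions:

* **Shift sets**: four states at reaction-coordinate positions 0, 0.4,
  0.6, 1.0 (apo → ADP → ATP-analogue → ternary, the open/intermediate/
  closed ordering), a configurable coordinated fraction moving on
  residue-specific lines, Gaussian peak noise, constant linewidths.
* **ITC**: exact displaced-volume heats plus constant molar dilution heat
  and Gaussian noise scaled to the first-injection heat. The reference
  protocols use a 300 μL cell at 80–100 μM protein, 25 × 2 μL injections
  of 1–2 mM titrant at 300 K, and 2% heat noise.
* **Velocities**: Michaelis-Menten with multiplicative noise on a log
  grid bracketing $K_M$.
* **Metastable trajectories**: a hidden Markov chain (GS/ES1/ES2) with
  Gaussian emissions; the reference chain has stationary populations
  82:12:6 and is built by a Metropolis construction (uniform proposal,
  move probability 0.2), the one-parameter reversible chain with that
  stationary vector.
* **Snapshot shifts**: per-state Gaussians, 500 snapshots per state at
  0.15 ppm spread and a 0.87 ppm GS/ES2 separation for the V104 reporter.

Noise magnitudes for peak positions and heats are package choices at
instrument-realistic levels, since the source measurements do not publish
them. What passing tests show is that the estimators are unbiased and
correctly calibrated *under these generative assumptions* — linear
trajectories, Gaussian noise, Markovian state dynamics, 1:1 binding. Real
spectra add peak overlap, assignment errors, non-constant linewidths, and
exchange broadening; real titrations add baseline drift; real dynamics
are not exactly Markovian at any finite lag. None of those failure modes
are exercised here.

## Problem sizes and numerical choices

The recovery studies are sized for a desk-scale rerun: 20 noise seeds per
ITC/kinetics condition, a 60,000-step kinetic Monte Carlo trajectory
(a 60-μs-equivalent at the 1-ns lag) for the MSM round trip, 500
snapshots per state for Δω, and 200 bootstrap replicates. At these sizes
the full suite and the acceptance script each run in minutes. Degenerate
inputs are handled explicitly: all-identical shift states report infinite
linearity with zero projections, zero-variance residues are excluded from
correlation with a warning, all-zero heats flag $K_d$ as unidentifiable,
empty k-means clusters trigger a logged re-seed, and disconnected
microstates are dropped to the largest strong component with a report.
All stochastic operations take explicit integer seeds and restore the
caller's RNG state.

## Known limitations

* Single-site binding only; competitive and multi-site ITC models are out
  of scope, as is baseline integration of raw thermograms.
* The reversible MSM estimator is the symmetrized-count one; for strongly
  non-equilibrium sampling a likelihood-based reversible estimator would
  differ.
* Peak lists are consumed as assigned tables; no peak picking or
  assignment transfer.
* Chemical-shift prediction from structure is consumed as precomputed
  tables, never computed.
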