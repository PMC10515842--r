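# allokin

Allosteric cooperativity analysis for protein kinases.

Protein kinase A's catalytic subunit (PKA-C) binds ATP and substrate
cooperatively: nucleotide loading in the N-lobe raises substrate affinity at
the lobe interface by roughly two orders of magnitude, and single mutations
in the αC-β4 loop can sever that coupling while leaving turnover intact.
`allokin` is for structural biophysicists quantifying this kind of
allosteric coupling from the standard measurements — amide NMR titrations,
isothermal titration calorimetry (ITC), steady-state kinetics, and
conformational-ensemble simulations.

## What it computes

**NMR chemical-shift statistics**

- Chemical shift perturbation per residue,
  Δδ = √(Δδ\_H² + (0.154·Δδ\_N)²), with the across-residue mean ± sd
  significance line and linewidth-based responder filtering
  (|Δδ| > ½(Δν\_A + Δν\_B)).
- CONCISE: per-residue PCA of shift trajectories across ligation states,
  linearity screening by singular-value ratio, and normal-fit
  equilibrium-position distributions along the open → closed axis.
- CHESCA: Pearson correlation matrices of per-state residue responses,
  correlation scores (fraction of pairs with |R\_ij| > 0.98),
  complete-linkage clustering on 1 − |R|, and community-level scores
  R\_{A,B} = #{|R\_ij| > 0.8}/(n\_A·n\_B).
- The replica-averaged chemical-shift restraint energy
  E = α·Σ\_k Σ\_l (δ\_exp − M⁻¹Σ\_m δ\_calc)².

**Binding thermodynamics and kinetics**

- Single-site Wiseman isotherm dQ/dX\_tot = ΔH·V₀·[½ + (1 − (1+r)/2 −
  R\_m/2)/√(R\_m² − 2R\_m(1−r) + (1+r)²)], exact per-injection heats with
  displaced-volume bookkeeping, log-scale K\_d fitting with standard
  errors, ΔG = RT·ln K\_d, TΔS = ΔH − ΔG, and the cooperativity
  coefficient σ = K\_d^apo / K\_d^nucleotide with propagated uncertainty.
- Michaelis–Menten fits reporting V\_max, K\_M, k\_cat and k\_cat/K\_M in
  (μM·s)⁻¹ with covariance-propagated errors.

**Ensemble analytics**

- Kabsch superposition, Cartesian-deviation featurization of reporter
  residues, tICA, seeded k-means microstates, Markov state models
  (reversible by count symmetrization, detailed balance exact), macrostate
  populations with block-bootstrap CIs, kinetic Monte Carlo sampling,
  principal modes, per-group RMSD, rotamer mutual information in bits, and
  ground-/excited-state Δω from snapshot shift ensembles.

Every input has a seeded synthetic generator (`gen_shift_states`,
`gen_itc`, `gen_mm_velocities`, `gen_markov_ensemble`,
`gen_snapshot_shifts`) carrying a ground-truth sidecar, so the whole
pipeline is testable without experimental data.

## Worked example

```r
library(allokin)

# Cooperativity from two synthetic titrations (apo vs nucleotide-saturated)
apo  <- gen_itc(true_Kd = 17,  dH = -5, cell_conc = 80, syringe_conc = 1000, seed = 1)
nucl <- gen_itc(true_Kd = 0.2, dH = -5, cell_conc = 80, syringe_conc = 1000, seed = 2)
fit_apo  <- fit_titration(apo,  fix = list(n_sites = 1), dilution = "none")
fit_nucl <- fit_titration(nucl, fix = list(n_sites = 1), dilution = "none")
fit_apo
#> single-site fit: Kd = 16.7 uM (se 1.6), dH = -4.96 kcal/mol, n = 1
#>   dG = -6.56, TdS = 1.6 kcal/mol; c = 4.8
sig <- cooperativity(fit_apo$Kd, fit_nucl$Kd, fit_apo$se[["Kd"]], fit_nucl$se[["Kd"]])
sprintf("sigma = %.1f +/- %.1f (%s cooperativity)", sig$sigma, sig$sd, sig$cooperativity)
#> "sigma = 76.1 +/- 18.8 (positive cooperativity)"

# CHESCA on a synthetic four-state shift set (60% coordinated residues)
set <- gen_shift_states(shift_gen_spec(n_residues = 60, coordinated_fraction = 0.6, seed = 7))
keep <- response_filter(set)
cm <- correlation_matrix(set, included = keep$residue[keep$included])
corr_score(cm, cutoff = 0.98)
#> [1] 0.6539683

# CONCISE equilibrium positions of the responding residues
concise_positions(fit_residue_trajectories(set),
                  residues = keep$residue[keep$included])
#> CONCISE positions over 36 residues
#>       state   mean      sd
#> 1       apo 0.0000 0.00000
#> 2       ADP 0.4002 0.01581
#> 3     ATPgN 0.5974 0.01734
#> 4 ATPgN_PKI 1.0000 0.00000

# Markov-state-model round trip through kinetic Monte Carlo
T <- transition_model(rbind(GS  = c(0.980, 0.015, 0.005),
                            ES1 = c(0.100, 0.890, 0.010),
                            ES2 = c(0.070, 0.020, 0.910)))
traj <- kmc_sample(T, 60000, seed = 11)
msm  <- estimate_msm(traj$states, lag = 1)
macrostate_population(msm, list(GS = "GS", ES1 = "ES1", ES2 = "ES2"), seed = 1)
#>   macro population  lower  upper
#> 1    GS     0.8095 0.7981 0.8227
#> 2   ES1     0.1266 0.1186 0.1350
#> 3   ES2     0.0639 0.0572 0.0715
```

The fitted Kd of 16.7 ± 1.6 μM recovers the generating 17 μM; σ ≈ 76 means
the nucleotide-saturated enzyme binds the pseudosubstrate ~76-fold tighter
than the apo enzyme (positive cooperativity). The CONCISE state means land
on the generating reaction-coordinate positions (0, 0.4, 0.6, 1.0), and the
MSM re-estimated from the sampled trajectory reproduces the prescribed
stationary populations within the bootstrap interval.

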