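# pocketensemble

Quantifying cryptic-pocket opening in protein conformational ensembles and
predicting ligand binding affinity by Boltzmann-weighted aggregation of
per-conformation docking scores over a Markov state model (MSM).

Many drug-binding sites are *cryptic*: closed in every ligand-free
experimental structure, but transiently open in solution. The classic
example addressed by this package is the blebbistatin pocket of the myosin-II
motor domain. For such a site, a single rigid structure cannot explain why
chemically near-identical isoforms are inhibited with potencies spanning
orders of magnitude — but the *equilibrium probability of pocket opening*,
and a pocket-aware average of docking scores over the conformational
ensemble, can.

The package is aimed at computational structural biologists who already have
conformational ensembles (MD trajectories or equivalent) and per-structure
docking scores, and want the statistics in between:

- **Grid pocket volumes.** A LIGSITE-style protein–solvent–protein scan:
  a grid point is protein-excluded iff its distance to some atom is below
  that atom's van der Waals radius plus a probe radius (default 1.4 Å); each
  solvent point's *rank* (0–7) counts scan directions (3 axes + 4 cube
  diagonals) with protein on both sides. Pocket points (rank ≥ 6, clusters
  ≥ 3 points) are filtered to within 2.5 Å of the ligand placed by local
  site alignment, and the largest single-linkage cluster (1.5 Å cutoff)
  defines the site volume.
- **Markov state models of the pocket.** Dihedral (sin/cos) features of
  binding-site residues → tICA with commute mapping (components scaled by
  √(t_i/2), retained to 90 % kinetic variance) → k-means microstates
  validated by cross-validated rank-10 VAMP-2 → reversible maximum-likelihood
  transition matrix (detailed balance enforced), plus the legacy
  1/n-pseudocount row-normalisation estimator.
- **Opening probability.** Each frame gets equilibrium weight π_s/N_s;
  p_open = Σ w_f over frames whose site volume reaches the holo reference
  volume. Uncertainty from 250-trial trajectory bootstrapping.
- **Ensemble docking free energy.** With best docking score g_f per sampled
  structure, K_f = exp(−g_f/RT) and

      ΔG_total = −RT · ln Σ_f (π_s(f) / N_s(f)) · K_f ,

  which for one structure per state reduces to −RT ln Σ_s π_s K_s. Kd
  follows as exp(ΔG_total/RT) (1 M standard state, R = 1.987204×10⁻³
  kcal·mol⁻¹·K⁻¹, default T = 310 K).
- **Experiment comparison.** IC50 → Ki under mixed inhibition
  (Ki = IC50·(Km/α + S)/(S + Km)), conversion to ΔG, and R²/RMSE against
  predictions.
- **Synthetic ensembles with closed-form ground truth** (hidden Markov
  chains with dihedral-like, volume and docking-score emissions), so every
  stage is testable without MD or a docking engine.

## Worked example

A three-state synthetic ensemble (10 trajectories × 20 000 frames) with
known stationary distribution, opening probability and aggregate free
energy, pushed through the full analysis:

```r
library(pocketensemble)

spec <- ensemble_spec(
  transition     = rbind(c(0.97, 0.02, 0.01),
                         c(0.04, 0.94, 0.02),
                         c(0.02, 0.04, 0.94)),
  dihedral_means = rbind(c(-2.0,  1.0,  0.5),
                         c( 0.5, -1.5,  2.5),
                         c( 2.5,  0.3, -2.0)),
  volume_mean = c(40, 160, 260), volume_sd = c(25, 30, 35),
  score_mean  = c(-3, -6.5, -8), score_sd  = c(0.3, 0.3, 0.3),
  n_traj = 10, n_frames = 20000, seed = 1)

gt  <- ensemble_ground_truth(spec, threshold = 150)
ens <- simulate_reference_ensemble(spec)

tica <- fit_tica(ens$features, lag = 10)
cl   <- cluster_assign(project_tica(tica, ens$features), k = 8, seed = 1)
msm  <- fit_msm(cl$dtrajs, lag = 5)
po   <- p_open(ens$volumes, frame_weights(msm, cl$dtrajs), 150)

samples <- sample_docking_structures(msm, cl$dtrajs, seed = 1)
scores  <- make_docking_table(spec, ens$states, samples, seed = 2)
rec     <- ingest_docking_scores(scores, cl$dtrajs, msm = msm)
est     <- aggregate_binding_free_energy(rec, msm, samples)

c(p_open = po$p_open, p_open_true = gt$p_open_true)
#>      p_open p_open_true
#>   0.3738126   0.3718654
print(est)
#> <affinity_estimate> dG = -7.12 kcal/mol (Kd = 9.55e-06 M) at 310 K
gt$dG_true
#> [1] -7.115429
```

The estimated opening probability is within 0.002 of the closed-form truth
and the aggregated free energy within 0.01 kcal/mol — the errors a
practitioner should expect at this sampling depth when the state space is
well resolved.

A thin command-line wrapper over the same functions is installed under
`inst/exec/pocketensemble` (subcommands `contacts`, `volumes`, `popen`,
`aggregate`, `run`).

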