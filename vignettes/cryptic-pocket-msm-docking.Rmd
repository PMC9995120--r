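---
title: "Cryptic-pocket opening and MSM-weighted ensemble docking"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cryptic-pocket opening and MSM-weighted ensemble docking}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pocketensemble)
```

## The model

A cryptic pocket is a binding site that is closed in every ligand-free
experimental structure but opens transiently in solution. This package
treats the conformational ensemble of such a site as a discrete-state
Markov process and derives two observables from it:

1. **The opening probability.** A conformation is *compatible* with the
   ligand when its site pocket volume $v$ reaches the volume of the
   ligand-bound (holo) reference structure, $v_{\mathrm{holo}}$. With
   frames assigned to Markov states $s$ with equilibrium probabilities
   $\pi_s$, each frame carries weight $w_f = \pi_{s(f)}/N_{s(f)}$
   ($N_s$ = frames in state $s$), and
   $p_\mathrm{open} = \sum_{f:\, v_f \ge v_\mathrm{holo}} w_f$. The
   comparison is inclusive.

2. **The ensemble binding free energy.** Docking one rigid ligand against
   one rigid receptor conformation yields a score $g_f$ in kcal/mol,
   interpreted as a micro binding free energy, hence a micro association
   constant $K_f = e^{-g_f/RT}$. Averaging the micro-constants with the
   same equilibrium weights gives the macro constant and

   $$\Delta G_\mathrm{total}
      = -RT \ln \sum_f \frac{\pi_{s(f)}}{N_{s(f)}}\, K_f ,$$

   which with one structure per state reduces to
   $-RT\ln\sum_s \pi_s K_s$. This construction charges the receptor's
   configurational entropy directly: an ensemble dominated by closed
   states (poor scores) yields a small macro-constant no matter how well
   the rare open state docks. $K_d = e^{\Delta G/RT}$ at 1 M standard
   state; $R = 1.987204\times10^{-3}$ kcal mol$^{-1}$ K$^{-1}$ and
   $T = 310$ K by default. 310 K is the simulation temperature of the
   ensembles this method targets, and it is the temperature at which a
   $-8.8$ kcal/mol prediction corresponds to a 0.67 µM dissociation
   constant; at 298 K the same pair is numerically inconsistent, so 310 K
   is used for experimental conversions as well, keeping predicted and
   experimental $\Delta G$ on one scale.

Useful identities (all verified property-style in the tests): the
aggregate is a soft minimum, $\min_f g_f \le \Delta G_\mathrm{total} \le
g_f + RT\ln(1/w_f)$ for every $f$; it is invariant under duplicating a
state's records with $N_s$ rescaled; and improving any single score can
only improve the aggregate.

## Pocket volumes on a grid

The detector follows the classic protein–solvent–protein (PSP) scanning
scheme. On a regular grid (default spacing 1.0 Å) a point is
*protein-excluded* iff its distance to some atom is less than that atom's
van der Waals radius plus the probe radius. Each remaining (solvent)
point's **rank** counts, over 7 scan lines — the 3 grid axes and 4 cube
diagonals — those with protein-excluded points on both sides. Scan lines
clip at the grid box; a direction with no protein on one side is not a PSP
event.

The site volume pipeline is: keep solvent points with rank ≥ 6; drop
26-neighbourhood connected components smaller than 3 points; keep points
within 2.5 Å of a ligand heavy atom (the ligand having been placed by a
local superposition of binding-site backbone atoms); single-linkage
cluster at 1.5 Å and keep the largest cluster, ties going to the cluster
whose centroid is nearest the ligand centroid; volume = point count ×
spacing³.

Parameter notes:

* **Probe radius 1.4 Å** is deliberately large so that only concavities
  relevant to ligand binding score as pocket; reported volumes are
  therefore the pocket *core*, smaller than the space available to a
  ligand.
* **Grid spacing 1.0 Å** (a free choice here) keeps the 1.5 Å linkage
  cutoff meaningful — face and edge neighbours (1 and √2 Å) connect,
  cube-corner neighbours (√3 Å) do not — and makes per-frame cost
  milliseconds. The small-component filter is applied before the ligand
  filter, matching a detector-then-site-filter reading of the procedure.
* **van der Waals radii** use a fixed element table (C 1.7, N 1.55,
  O 1.52, S 1.8, H 1.2, P 1.8 Å; 1.7 Å for unknown elements),
  configurable in `ligsite_params()`. The exact table behind any given
  legacy implementation varies; making it explicit keeps results
  reproducible.
* The grid box is recomputed per structure (bounding box + 2 Å padding).
  Exactness under translation therefore holds only for shifts that are
  grid multiples with a fixed box; in general a one-shell difference is
  possible, which the tests bound.

## The Markov state model of the pocket

Features are the backbone φ/ψ and side-chain χ1–χ4 dihedrals of residues
within 5 Å of the ligand, each encoded as a (sin, cos) pair so that
periodicity introduces no discontinuities. Contacts are defined on heavy
atoms by default — hydrogens are usually absent from the crystal
structures that define the site — with a flag to include them.

tICA solves the time-lagged generalised eigenproblem on symmetrised
covariances (lag 10 ns in the motivating application). Components are
scaled by $\sqrt{t_i/2}$, $t_i = -\tau/\ln|\lambda_i|$ (the commute map),
and the retained dimension is the smallest $n$ reaching 90 % of kinetic
variance, where component $i$'s share is proportional to $t_i/2$ — i.e.
the cut is computed jointly with the commute scaling. A ridge
(`regularization`, default 1e-10) absorbs duplicated or constant
features; eigenvalue magnitudes are clipped to $1 - 10^{-6}$ before
timescale conversion so a near-unit eigenvalue cannot dominate the
variance cut with an effectively infinite timescale.

Microstates come from k-means (10 restarts, best inertia, MacQueen
updates, fixed seed) in the commute-mapped space; every frame — fit or
held out — is assigned to the nearest centroid, ties to the lowest index.
The state count is selected by cross-validation: trajectories are split
50/50 into train/test (5 random splits by default; the split protocol is
a free choice), centroids are fitted on the training set, test
trajectories assigned, and the rank-10 VAMP-2 score — the sum of the 10
largest squared singular values of $C_{00}^{-1/2} C_{01} C_{11}^{-1/2}$
built from the *test* transition counts — scores each $k$.

The transition matrix uses sliding-window counts at the chosen lag,
restricted to the largest strongly connected set, and the reversible
maximum-likelihood estimator: the standard fixed-point iteration on the
symmetric flux matrix, converged when the stationary distribution moves
less than 1e-10 (cap $10^6$ iterations). Detailed balance
($\pi_i T_{ij} = \pi_j T_{ji}$) then holds to ~1e-8 by construction. The
legacy estimator — add a $1/k$ pseudocount, row-normalise, stationary
vector from the leading left eigenvector — is retained as
`estimator = "pseudocount_rownorm"` for compatibility with older state
decompositions. Implied timescales $t_i = -\tau/\ln\lambda_i$ over a lag
grid support the usual lag-convergence check.

## Docking-structure sampling and uncertainty

Per active state, $N_s = \max(3,\ \mathrm{round}(\pi_s \times 2000))$
structures are drawn uniformly without replacement (capped at the state's
frame count, with a warning). The rounding rule is a free choice;
`round()` is used. The docking box centre is the selection centroid of
the converged mean structure after iteratively aligning the ensemble on
binding-site backbone atoms — the alignment re-centres its reference each
iteration, so this centre is (0,0,0) in the aligned coordinate system,
and the procedure is idempotent: re-running on aligned output converges
in one pass.

Uncertainty comes from a trajectory-level bootstrap: 250 trials, each
drawing $N$ trajectories with replacement from the $N$ available,
re-fitting the transition matrix (cluster definitions fixed — re-running
the full clustering per trial is a different, far more expensive
estimator; the cheap variant is the default and the distinction matters
mainly when clustering itself is unstable), and recomputing the
statistic. The reported SEM is the standard deviation of the bootstrap
distribution. Trials with disconnected resamples are skipped and counted;
more than half skipped is an error.

## IC50 to Ki

For a mixed inhibitor binding one enzyme form tightly ($K_i$) and another
$\alpha$-fold more weakly, with substrate concentration $S$ and Michaelis
constant $K_m$,

$$\mathrm{IC50} = \frac{S + K_m}{K_m/(\alpha K_i) + S/K_i}
 \quad\Longleftrightarrow\quad
 K_i = \mathrm{IC50}\,\frac{K_m/\alpha + S}{S + K_m}.$$

At $\alpha = 1$ (pure noncompetitive) $K_i = \mathrm{IC50}$ exactly; as
$\alpha \to \infty$ the uncompetitive limit
$K_i \to \mathrm{IC50}/(1 + K_m/S)$ is recovered. At the motivating
values — $S = 43$ µM actin, $K_m = 24$ µM, $\alpha = 10$ — the ratio
IC50/$K_i$ is 1.48, i.e. IC50 is essentially $K_i$, which `mode = "equal"`
applies directly. This algebra is one standard form of the
mixed-inhibition relation; the underlying source states only the
conclusion, so the relation implemented here is flagged as an
interpretation. Prediction quality against experiment is summarised by
the squared Pearson correlation (headline) and the RMSE in kcal/mol; an
identity-line $R^2$ ($1 - SS_\mathrm{res}/SS_\mathrm{tot}$) is also
reported since the two can differ materially when predictions are offset.

## What the synthetic generator emulates — and what it does not

`ensemble_spec()` + `simulate_reference_ensemble()` produce hidden Markov
chains with state-conditional emissions: von Mises dihedral angles
(concentration κ = 8 by default, high enough that states are
geometrically separable — the premise that site dihedrals encode
open/closed states), pocket volumes from normals truncated at zero, and
Gaussian docking scores. Volume and score emissions are conditionally
independent given the state — the simplest structure under which both
$p_\mathrm{open}$ and $\Delta G$ have closed forms:

$$p_\mathrm{open}^\mathrm{true} = \sum_s \pi_s\,P(V \ge v_\mathrm{holo}\mid s),
\qquad
\Delta G^\mathrm{true} = -RT\ln\sum_s \pi_s\,
  e^{-\mu_s/RT + \sigma_s^2/(2(RT)^2)}.$$

`make_cavity_structure()` builds hollow pseudo-atom cages (Fibonacci
shell lattice) with an optional aperture and interior blocker emulating a
gating side chain, with an analytic interior volume.

What passing these tests shows: the estimators are unbiased and tight
when the state space is discrete, emissions are well separated, and
sampling is equilibrium. What they do not show: robustness to the things
real MD data add — continuous conformational heterogeneity within states,
non-Markovian memory at short lags, poorly separated or rare states,
force-field bias, and docking-score noise that correlates with
conformation. The cage fixtures likewise probe grid geometry, not
realistic protein surface topography.

## Problem sizes and numerical choices

The reference validation ensemble used by the tests and the acceptance
script is 3 hidden states, 10 trajectories × 20 000 frames (2×10⁵ frames
total), where the pipeline recovers $p_\mathrm{open}$ to well within 0.03
and $\Delta G$ within 0.2 kcal/mol; Markov-chain recovery uses 10⁵ steps
of a two-state chain (entries recovered within 0.02). Cage fixtures use
shell radii of 5–10 Å at 1.0 Å grid spacing. Degenerate inputs are
handled explicitly: empty pocket results return volume 0; k-means
empty-cluster failures are retried with fresh seeds and then error;
states outside the largest connected set carry zero weight; aggregation
uses log-sum-exp to avoid overflow at strongly negative scores; collinear
point sets are rejected by the superposition with a clear error.

## Known limitations

* Trajectory input formats are PDB (multi-model) and DCD; XTC must be
  converted upstream.
* The pipeline orchestrator (`run_pipeline()`) drives the synthetic
  workflow end to end; on real data the stage functions are composed
  directly, as in the README example.
* The bootstrap keeps clustering fixed (see above).
* $p_\mathrm{open}$ and the docking aggregation assume the MSM's
  stationary distribution is trustworthy; no correction for
  non-equilibrium or insufficient sampling is attempted beyond the
  bootstrap spread.
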