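# idpens

Integrative determination and comparison of conformational ensembles for
intrinsically disordered proteins (IDPs).

An IDP is described not by one structure but by an ensemble: a pool of
conformers with statistical weights. Experiments (SAXS, NMR chemical shifts,
smFRET, PRE) measure ensemble averages, so inferring the ensemble is an
underdetermined inverse problem: the answer depends on the prior conformer
pool and on the optimization method. `idpens` implements the full comparison
loop at desk scale, for method developers and for anyone who wants to see —
on a system with a known ground truth — how much of a "determined" ensemble
comes from the data and how much from the prior.

The package provides:

* **Synthetic priors** — self-avoiding 90-residue chains grown from a
  3-basin backbone-torsion library in three contrasting styles: statistical
  coil, coil with transient helices ("matched"), and a globally compacted
  variant (`generate_prior()`).
* **Forward models** — coarse-grained Debye SAXS on CA beads, a secondary
  structure chemical-shift surrogate, Förster-equation FRET, and a
  point-dipole PRE intensity-ratio model with r⁻⁶ ensemble averaging
  (`build_forward_matrix()`).
* **Bayesian Maximum Entropy reweighting** — minimizes
  ½χ²_TOTAL − θ·S_REL with χ²_TOTAL = χ²_SAXS + χ²_CS + Ω·χ²_FRET, solved in
  the dual multiplier parametrization with Newton polish; θ is scanned and
  chosen at the L-curve elbow or at the minimum of a held-out PRE validation
  score (`bme_solve()`, `theta_scan()`, `select_theta()`, `omega_scan()`).
* **Switching Monte-Carlo subset selection** — simulated annealing over
  M-conformer subsets with target-normalized pseudo-energies, adaptive
  restraint weights, PRE distance restraints, five-run combination and a
  held-out FRET z-test (`anneal_select()`, `run_replicates()`).
* **Weighted analytics** — 3-class DSSP propensities, inter-residue scaling
  maps against a random-coil reference, long-range H-bond PMFs, planar
  pi-contact counts, and weighted-bootstrap uncertainties
  (`ss_propensity()`, `scaling_map()`, `hbond_pmf()`, `pi_contacts()`,
  `bootstrap_sd()`).
* **Study orchestration** — `run_study()` runs the 3-prior × 2-method
  comparison end to end and `compare_report()` decomposes every summary
  statistic into between-prior versus between-method spread.

Ensembles exchange as multi-model PDB; observables and weights as TSV.

## Worked example

Reweight a compacted prior against synthetic SAXS + CS + FRET data generated
from a known expanded ground truth, and check recovery:

```r
library(idpens)

compact <- generate_prior("compact", default_sequence(), 1000, seed = 44)
truth   <- make_ground_truth(compact, "Rg", -2)    # expanding tilt
data    <- synthesize_experiments(compact, truth, seed = 1)

fms <- list(SAXS = build_forward_matrix(compact, data$saxs),
            CS   = build_forward_matrix(compact, data$cs),
            FRET = build_forward_matrix(compact, data$fret))

scan  <- theta_scan(fms, compact$weights, 10^seq(3, -2, length.out = 12),
                    omega = 75,
                    validation = list(ens = compact, pre = data$pre))
theta <- select_theta(scan, "elbow")
res   <- bme_solve(fms, compact$weights, as.numeric(theta), omega = 75)
res
```

```
BME reweighting: theta = 43.28761 omega = 75
  chi2 (reduced): SAXS 0.705, CS 0.929, FRET 0
  chi2_total = 191.709  S_rel = -0.2528  N_eff = 0.7767
```

```r
c(prior     = radius_of_gyration(compact),
  posterior = radius_of_gyration(compact, res$weights),
  truth     = radius_of_gyration(compact, truth$true_weights))
```

```
    prior posterior     truth
 2.242863  2.477012  2.579641
```

Reading this: the compact prior (mean Rg 2.24 nm) is reweighted at the
L-curve elbow (θ ≈ 43) to 2.48 nm, recovering the ground-truth mean of
2.58 nm to within twice the ±0.06 nm that the SAXS noise determines it
(Guinier error propagation, `saxs_guinier_rg()`), while keeping 78% of the
prior's effective conformers. The scan also shows the overfitting signature:
the held-out PRE score is 0.057 at the elbow but 0.50 at the smallest θ.

`run_study(default_config())` runs the full 6-way comparison (three priors,
both optimizers, shared synthetic data) in a few minutes and writes
`report.tsv` plus per-stage outputs; `compare_report()` on its result shows,
among other things, that mean helix propensity varies an order of magnitude
more between priors than between optimization methods.

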