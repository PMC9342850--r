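---
title: "Determining disordered-protein ensembles: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Determining disordered-protein ensembles: models, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(idpens)
```

## The problem

An intrinsically disordered protein (IDP) has no single native structure; its
solution state is a conformational ensemble — a set of 3D structures with
statistical weights. Experimental observables (SAXS profiles, NMR chemical
shifts, smFRET efficiencies, PRE intensity ratios) are ensemble averages, so
ensemble determination is badly underdetermined: many different ensembles
reproduce the same data. Two practical consequences follow. First, one always
starts from a *prior* pool of conformers (from molecular dynamics or from
statistical-coil generators) and perturbs it as little as the data require.
Second, the result depends both on the prior and on the optimization method,
and quantifying that dependence is itself a scientific question. This package
implements the whole comparison loop at desk scale: contrasting synthetic
priors, simplified forward models, two optimizers with opposite philosophies,
and weighted structural analytics of the resulting posteriors.

## Synthetic study system

Because real MD trajectories and beamline datasets are large and not
redistributable, the package generates its own study system:

* **Chain model.** A 90-residue disordered sequence (no negatively charged
  residues, Ser/Thr-rich, a few aromatics) built residue-by-residue from
  sampled backbone torsions with ideal peptide geometry (trans peptide bonds,
  Engh–Huber bond lengths and angles; atoms N, H, CA, C, O and CB). Coil
  statistics come from a 3-basin torsion library (helical, extended/PPII,
  left-handed, default probabilities 0.30/0.60/0.10 with 12° jitter);
  self-avoidance rejects any conformation with a nonadjacent CA–CA contact
  under 0.4 nm. With these defaults the coil ensemble reproduces
  excluded-volume Flory scaling (mean Rg within 15% of $0.19\,L^{0.588}$ nm).
* **Three prior styles.** `coil` is the bare statistical coil. `matched`
  adds three transient helical segments (residues 12–22, 40–50, 62–72 with
  per-conformer activation probabilities 0.45/0.35/0.45). `compact` uses the
  same helical segments but resamples an oversampled pool with probability
  $\propto e^{-3\,R_g/\mathrm{nm}}$, giving a globally compacted ensemble with
  otherwise identical chain statistics — the analogue of a force field with
  an overly compact bias. Implementing compaction as an exponential tilt
  (rather than attractive chain growth) keeps the bias analytically
  controlled.
* **Ground truth and synthetic data.** A known reweighting
  $w_i \propto w_i^0 e^{-c\,f_i}$ of a prior (feature $f$ = per-conformer Rg
  or end-to-end distance) defines the "true" ensemble; experimental datasets
  are the truth-weighted forward averages plus Gaussian noise. Defaults: 40
  SAXS points on $q \in [0.1, 3]\ \mathrm{nm^{-1}}$ with 2% relative noise;
  CA/CB chemical shifts with σ = 0.4 ppm; one FRET pair (residues 1–90,
  $R_0 = 6$ nm) with σ(E) = 0.03; six PRE label sites (1, 21, 38, 64, 83, 90)
  with σ(ratio) = 0.05. These magnitudes are typical of modern SEC-SAXS,
  secondary-shift predictors, smFRET and PRE experiments on IDPs. The
  construct-specific label positions of real experiments (an extra N-terminal
  residue, a C-terminal cysteine) are mapped onto chain residues in
  configuration rather than hard-coded; the defaults use residues 1 and 90.

What the generator deliberately does **not** emulate: side chains beyond CB,
solvent, dye linkers, force-field-specific contact propensities, and
correlated trajectory frames. Passing tests therefore demonstrate the
correctness and statistical behaviour of the machinery, not the accuracy of
any force field against real data.

## Forward models

* **SAXS** — Debye scattering over one Gaussian bead per residue (centred on
  CA, bead width 0.31 nm):
  $I(q) = f(q)^2 \left[ n + 2\sum_{i<j} \mathrm{sinc}(q\,r_{ij}) \right]$.
  This preserves the global-dimension information the restraint carries; a
  weighted least-squares scale and offset against the measured curve is
  re-fit whenever the ensemble average changes.
* **Chemical shifts** — random-coil reference values per residue type plus a
  secondary-structure offset from the 3-class DSSP assignment (+0.7 ppm on CA
  in helix, −0.7 ppm in extended, opposite signs on CB). A surrogate, not a
  trained predictor: its purpose is to carry local-structure information with
  a realistic information-to-noise ratio.
* **FRET** — Förster efficiency $E = 1/(1 + (r/R_0)^6)$ on the CA–CA distance
  of the labelled pair; the ensemble value is weight-linear in per-conformer
  efficiencies. No dye-linker cloud is modelled.
* **PRE** — the paramagnetic centre is placed on the CB atom of the label
  site; for each reporting residue $\langle r^{-6}\rangle$ is averaged over
  conformers, then
  $\Gamma_2 = K \langle r^{-6}\rangle\left(4\tau_c + \frac{3\tau_c}{1 + \omega_H^2\tau_c^2}\right)$,
  and the intensity ratio is
  $R_2 e^{-\Gamma_2 t_d} / (R_2 + \Gamma_2)$. Defaults: $\tau_c = 2$ ns,
  $t_d = 10$ ms, $R_2 = 10$ Hz, $\omega_H/2\pi = 500$ MHz, and the nitroxide
  point-dipole constant $K = 1.23\times10^{-32}\ \mathrm{cm^6 s^{-2}}$. A
  total correlation time $\tau_t = 0.5$ ns is stored with the parameters but
  unused by this simplified expression (no formula involving it is adopted
  here). The $r^{-6}$ kernel makes ensemble averages dominated by the most
  compact conformers — the property that makes held-out PRE a sensitive
  overfitting detector.

## Bayesian Maximum Entropy reweighting

The posterior weights minimize
$$\mathcal{L}(w) = \tfrac12 \chi^2_\mathrm{TOTAL}(w) - \theta\, S_\mathrm{REL}(w),
\qquad
\chi^2_\mathrm{TOTAL} = \chi^2_\mathrm{SAXS} + \chi^2_\mathrm{CS} + \Omega\, \chi^2_\mathrm{FRET},$$
with non-reduced $\chi^2$ sums, relative entropy
$S_\mathrm{REL} = -\sum_i w_i \ln (w_i / w_i^0) \le 0$ and effective ensemble
fraction $N_\mathrm{eff} = e^{S_\mathrm{REL}}$. The scalar $\Omega$
compensates the single FRET point for being outnumbered by hundreds of
SAXS/CS points; it enters exactly as
$\sigma_\mathrm{FRET} \to \sigma/\sqrt{\Omega}$.

**Numerics.** The solver works in the dual (Lagrange-multiplier)
parametrization: $w_i \propto w_i^0 \exp(-\sum_m \lambda_m F_{im})$, which
enforces positivity and the maximum-entropy exponential form by construction.
In sigma-scaled variables the dual objective has Hessian
$\mathrm{Cov}_w(\tilde F) + \theta I$, so an L-BFGS pass followed by damped
Newton iterations converges to gradient norms below $10^{-9}$ even at very
small θ — necessary because the scan-monotonicity properties (χ² and
$N_\mathrm{eff}$ both non-increasing as θ decreases) hold only at accurate
solutions. The SAXS scale/offset is re-fit against the current
weighted-average curve in an outer loop (tolerance $10^{-7}$ relative,
at most 30 iterations). Warm starts carry multipliers down the θ grid.

**Choosing θ.** The default grid is 12 log-spaced points from $10^3$ to
$10^{-2}$: the upper end is of the order of the total χ² itself (hundreds),
where the entropy term dominates and the posterior stays at the prior; the
lower end is far below 1, the Bayesian-consistent value when all sigmas are
exact, where the data dominate. The elbow selector normalizes the
$(\chi^2_\mathrm{TOTAL}, N_\mathrm{eff})$ polyline to the unit square and
picks the interior point farthest from the chord joining the endpoints. For
an ideal L shape this is exactly the maximum-curvature corner, but unlike
discrete curvature estimates it is insensitive to how densely the grid
samples each branch — pointwise Menger or turning-angle curvature on a
log-spaced grid tends to peak either where the spacing happens to be tight or
at the saturation corner where $N_\mathrm{eff}$ flattens against its floor.
A nearly linear trade-off (no elbow) triggers a warning. The alternative
`validation-minimum` mode picks the θ minimizing the held-out PRE score
(per-site RMSD of intensity ratios, root-mean-squared across sites). Ties
break toward larger θ, i.e. toward the prior.

**Choosing Ω.** `omega_scan` solves the problem at fixed θ along an Ω grid
(default 1–150) and selects the smallest Ω whose reduced FRET χ² falls below
a target (default 1) while the SAXS χ² stays within 10% of its Ω = 1 value —
the "improve FRET without worsening SAXS" rule.

## Subset selection by switching Monte Carlo

The second optimizer selects `M`-member subsets (default 100) under simulated
annealing, five independent runs being concatenated into a 500-conformer
ensemble with uniform weights. Each restraint carries a pseudo-energy
normalized by a target so that values below 1 count as "fit"; the run
terminates when every restraint is fit (or a trial budget of $5\times10^4$
expires, which flags but does not raise). Every trial swaps one subset member
against an outside pool conformer, with Metropolis acceptance at the current
temperature; temperatures follow $T_0\,\alpha^{k}$ with $T_0 = 1$ in
normalized-energy units, α = 0.95, and 200 trials per stage. Every 100
trials, restraints above their target get their weight multiplied by 1.2
(capped at $10^3$, so an unsatisfiable restraint cannot starve the others).
None of these schedule constants are printed in the sources this design
follows; they are exposed as configuration, and the defaults were chosen so
that planted-subset problems converge in a few thousand trials.

**Pseudo-energies.** SAXS and CS use the plain non-reduced χ² of the
uniform-weight subset average (no scale fit: the synthetic data share the
forward model's units, and a free offset would let compact subsets mimic the
SAXS curve of expanded ones). PRE data are treated as
$\langle r^{-6}\rangle^{-1/6}$ effective-distance restraints on the CB of the
label. Three regimes of the measured ratio are distinguished:

* informative mid-range ratios become two-sided harmonics at the
  back-converted distance, weighted by the per-point distance uncertainty
  propagated from the ratio uncertainty through the forward model (floored
  at 0.1 nm);
* bleached residues (ratio within 3σ of 0) become upper bounds — being even
  closer is equally consistent with a vanishing ratio;
* flat high ratios (above 0.95, including exactly 1 where no finite distance
  exists) become lower bounds at the distance of ratio 0.95 — the unbleached
  long-range information.

In addition, a finite subset of size M reproduces the pool's $r^{-6}$
averages only up to a sampling error that, for this extreme-value-dominated
statistic, exceeds typical measurement noise (random 100-subsets of a
1000-conformer pool show reduced χ² of 16–66 against their own pool's data
under measurement-noise weighting alone). The per-point standard deviation of
the effective distance across random M-subsets is therefore folded into the
tolerance, which makes the reduced-χ²-of-1 target attainable and puts the
"fit" threshold where it belongs: at the resolution a size-M ensemble can
represent at all.

**Post-fit decorrelation.** The first subset to satisfy all targets lies on
the boundary of the acceptable region, on the side it was approached from —
for a compact pool, the compact side — which biases combined ensembles. After
the stop criterion is met, a short constrained Metropolis walk (2000
proposals; moves that leave the fit region are rejected) moves the subset to
a more typical member of the acceptable set. The termination rule itself is
unchanged. The residual bias of the combined ensemble in held-out FRET
efficiency is of the order of the width of the acceptable region, which the
synthetic noise levels leave at roughly ±0.05 in E; the z-test against the
held-out efficiency reflects both this and the noise draw on the measured
value.

Pool replenishment (`replenish_pool`) replaces the most-selected conformers
with freshly generated ones, mirroring generate-and-select workflows where
the pool is not fixed.

## Structural analytics

All analytics accept arbitrary conformer weights.

* **DSSP (3-class).** Kabsch–Sander hydrogen-bond energies
  ($E = 0.084 \cdot 332 \,(1/r_{ON} + 1/r_{CH} - 1/r_{OH} - 1/r_{CN})$
  kcal/mol, bond below −0.5) define n-turns and bridges; two consecutive
  n-turns (n = 3, 4, 5) mark helix, parallel/antiparallel bridge patterns
  mark extended, everything else coil. Bulge subtleties of the full 8-state
  algorithm are omitted; an isolated strand with no partner is coil.
* **Geometric H-bonds.** H···O below 0.25 nm and N–H···O angle above 120°,
  with amide protons reconstructed geometrically when absent; the long-range
  filter |i−j| > 10 separates tertiary contacts from secondary structure.
  Counts per conformer accumulate into weighted probability mass functions.
* **Planar pi contacts.** Backbone amide planes (C, O, N of each peptide
  bond) always; side-chain planes (Arg guanidinium, Asn/Gln amide, Asp/Glu
  carboxyl, His/Phe/Tyr/Trp rings) when the atoms are present. Contact =
  centre distance ≤ 0.49 nm and normal–normal angle ≤ 40° (folded to
  [0°, 90°]), |i−j| > 10, classified sc–sc / bb–bb / sc–bb. Since generated
  conformers carry only backbone + CB, the side-chain classes are exercised
  with hand-built fixtures. This is a centre-and-normal simplification of
  published overlap-based detectors; both thresholds are configurable.
* **Scaling maps.** $D_{ij} = \langle r_{ij}\rangle_\mathrm{ens} /
  \langle r_{ij}\rangle_\mathrm{ref}$ over CA pairs, the reference being a
  random-coil ensemble averaged with its own weights; posterior maps use the
  optimized weights (consistent with every other weighted analysis here).
* **Global size.** Per-conformer Rg from CA coordinates with equal masses;
  ensemble $R_g^2 = \sum_i w_i r_{g,i}^2$, which satisfies the pairwise
  identity $R_g^2 = \frac{1}{2n^2}\sum_{ij}\langle r_{ij}^2\rangle$ to
  numerical precision.
* **Uncertainties.** Weighted bootstrap: B resamples of size N drawn with
  probabilities equal to the weights, the statistic evaluated on each
  resample with uniform weights (the resampling itself encodes the weights),
  and the standard deviation across resamples reported. Default B = 1000.

## The six-way study

`run_study()` generates the three priors (1000 conformers each), synthesizes
one shared dataset from a mild expanding tilt (coefficient −0.5 nm⁻¹ on Rg)
of the matched prior, and optimizes each prior with both methods under the
paper-style split: reweighting restrains SAXS + CS + FRET and is validated
against PRE; subset selection restrains SAXS + CS + PRE and is validated
against the held-out FRET efficiency. The report collects per-posterior
reduced χ² values, $N_\mathrm{eff}$ or trial counts, validation scores, mean
Rg, mean helix propensity, and long-range H-bond and pi-contact counts;
`compare_report()` decomposes each statistic into between-prior and
between-method spreads. With the defaults, helix propensity is strongly
prior-dominated (the optimizers barely move local structure), while
validation scores are method-dominated — the expected signature of an
underdetermined problem where priors carry the structural information.

Problem sizes used throughout (1000-conformer pools, 40-point SAXS curves,
~180 shifts, ~530 PRE points, 12-point θ grids, 5 × 100 selection runs) were
chosen so a full study completes in minutes on one core while keeping all
statistical behaviour — χ² distributions, bootstrap errors, annealing
convergence — in realistic regimes.

## Known limitations

* The chemical-shift surrogate cannot resolve anything the 3-class DSSP
  assignment cannot; real predictors carry more (and more correlated)
  information.
* FRET dyes are represented by CA positions; linker dynamics shift real
  efficiencies systematically.
* The compact prior differs from the matched prior only globally; real
  force-field biases also distort local geometry, which would make
  cross-prior differences larger, not smaller.
* The elbow of an L-curve is a heuristic; when the trade-off curve is nearly
  linear the package warns rather than pretending a corner exists.
* Subset selection reports ensembles, not uncertainties; only the
  replicate-to-replicate spread and the weighted bootstrap of the combined
  ensemble quantify its variability.
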