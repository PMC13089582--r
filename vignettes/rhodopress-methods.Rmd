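---
title: "Methods: property-partitioned codon models and pressure thermodynamics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: property-partitioned codon models and pressure thermodynamics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`rhodopress` implements a two-part analysis of pressure-tolerant protein
evolution: (1) maximum-likelihood codon substitution models in which
nonsynonymous changes are split into *radical* and *conservative* classes by
an amino-acid physicochemical property — here amino-acid compressibility K⁰
— with branch and site-mixture variants, partition selection by AIC, and an
ancestral convergence screen; and (2) trajectory-level thermodynamic
estimators for two-pressure molecular ensembles: isothermal compressibility
from volume fluctuations, per-residue RMSF, quasiharmonic entropy, and a
pressure free-energy decomposition. This vignette documents the models, the
numerical choices, and what the synthetic-data validation does and does not
establish.

## The substitution model

The instantaneous rate from sense codon $i$ to sense codon $j$ is

$$
q_{ij} =
\begin{cases}
0 & i, j \text{ differ at} > 1 \text{ position}\\
\pi_j & \text{synonymous transversion}\\
\kappa \pi_j & \text{synonymous transition}\\
\gamma_{ij}\,\omega_{ij}\, \pi_j & \text{nonsynonymous transversion}\\
\gamma_{ij}\,\omega_{ij}\, \kappa \pi_j & \text{nonsynonymous transition,}
\end{cases}
$$

with $(\gamma_{ij}, \omega_{ij}) = (1, \omega)$ for conservative pairs and
$(\gamma, 1)$ for radical pairs. $\kappa$ is the transition/transversion
ratio and $\pi_j$ the equilibrium frequency of codon $j$. Setting
$\gamma = \omega$ recovers the standard Goldman–Yang codon model, which is
the main internal consistency check: the engine is tested against an
independently coded GY94 likelihood under that constraint. The matrix is
rescaled to unit expected rate at stationarity, so branch lengths are
expected substitutions per codon and are comparable across partitions.

Stop codons are excluded entirely (changes to or from a stop have rate 0),
and only the standard nuclear code is used.

### The radical/conservative partition

Every nonsynonymous substitution reachable by a single nucleotide change is
enumerated (392 ordered events, 196 unordered codon-pair events under the
standard code) and ranked by $|\Delta K^0|$, the absolute difference in
amino-acid compressibility. The top $P\%$ are radical. Choices made where
the procedure was underdetermined:

* **Ranking unit.** Events are ranked as *unordered codon pairs*, so the
  classification is symmetric under reversal by construction; $P\%$ is
  measured over codon-pair events. Codon pairs sharing an amino-acid pair
  necessarily share $|\Delta K^0|$ and therefore a class.
* **Ties.** The threshold is inclusive: every event with
  $|\Delta K^0| \ge$ the cutoff magnitude is radical. This is deterministic
  and independent of sort order, at the cost of the radical fraction
  occasionally exceeding $P\%$ slightly when ties straddle the boundary.
* **The K⁰ scale.** The published per-residue compressibility values were
  not redistributable, so the packaged table
  (`inst/extdata/k0_scale_synthetic.tsv`) is a labelled *synthetic
  reconstruction*: it fixes the six pairwise differences that the rhodopsin
  convergence analysis constrains (A−S = −4.30, P−L = −8.4, V−I = −1.15,
  H−K = −1.50, L−F = −2.75, S−T = −1.16, in 10⁻¹⁵ m³ mol⁻¹ Pa⁻¹) and fills
  the remaining residues with plausible, mutually distinct magnitudes.
  Values are stored as magnitudes, so a negative $\Delta K^0$ is a decrease
  in compressibility. All partition machinery is property-agnostic and is
  tested against injected scales; any 20-value table can be supplied via
  `read_property_scale()`.

### Likelihood, fitting, and model comparison

Likelihoods are computed by Felsenstein pruning over site patterns, with
per-node rescaling against underflow, and matrix exponentials through the
symmetric similarity transform $\mathrm{diag}(\sqrt\pi)\, Q\,
\mathrm{diag}(1/\sqrt\pi)$ that time reversibility affords. The engine is
validated against brute-force enumeration of all internal-node states on
small trees, and is invariant to root placement, taxon order, and site
order.

The **branch model** contrasts a null with one shared $\gamma$ against an
alternative with $\gamma_{fg}$ on foreground branches (the deep-diving
clade stems) and $\gamma_{bg}$ elsewhere. The **site model** mixes four
classes combining $\omega_0 \le 1 < \omega_1$ with
$\gamma_0 \le 1 < \gamma_1$ — (i) $(\omega_0,\gamma_0)$, (ii)
$(\omega_0,\gamma_1)$, (iii) $(\omega_1,\gamma_0)$, (iv)
$(\omega_1,\gamma_1)$ — against a null with only the $\gamma_0$ classes (i)
and (iii). Per-site empirical-Bayes posteriors over the classes, and the
derived $P(\gamma_1) = P(\mathrm{ii}) + P(\mathrm{iv})$, feed the
convergence screen.

Numerical choices:

* **Frequencies** are empirical (F3X4 default, F61 option) and not counted
  as free parameters; this matches the AIC arithmetic of the original
  branch-model comparison (k = 105 = 101 branch lengths + κ + ω + γ_fg +
  γ_bg for a 52-taxon tree), which leaves no room for counted frequency
  parameters.
* **Branch lengths** default to the input tree's values with `k` adjusted
  accordingly; joint optimisation (`estimate_branch_lengths = TRUE`) is
  available and counts them in `k`. Fixed lengths keep the replicated
  simulation studies tractable in pure R; the likelihood code is identical
  in both modes.
* **Optimizer**: L-BFGS-B on log-transformed positive parameters, bounds
  $\omega_0, \gamma_0 \in (10^{-6}, 1]$, $\omega_1, \gamma_1 \in (1,
  10^3]$, $\kappa \in (10^{-3}, 10^3]$; mixture proportions through a
  softmax with the first class as reference. Default 3 jittered restarts
  under a fixed seed; the site-model alternative additionally warm-starts
  from the null optimum (with vanishing $\gamma_1$ classes) so the nested
  log-likelihood ordering survives flat mixture surfaces. If the
  alternative still lands below the null, the branch fit retries from the
  null optimum and the convergence flag is set in the diagnostics.
* **LRT** uses the plain $\chi^2$ approximation with
  $df = k_{alt} - k_{null}$ (1 for the branch test, 3 for the site test:
  $\gamma_1$ plus two extra mixture proportions). The boundary/mixture
  irregularity of the site test is acknowledged: the $\chi^2$ reference is
  conventional, not exact.
* **Partition sweep**: one fit per $P \in \{10, \dots, 90\}$, best
  partition by the alternative model's AIC; single-point failures are
  recorded and the sweep continues.

### Ancestral reconstruction and the convergence screen

Marginal posteriors over the 61 sense codons are computed at any node by
combining subtree ("down") and rest-of-tree ("up") partial likelihoods
under the fitted model; under a mixture, reconstructions are weighted by
the per-site class posteriors. The original analysis reconstructed
ancestral sequences under an external nucleotide model (TN+F+I+G4); this
package reconstructs under the fitted codon model for self-containment, so
exact agreement with the original node states is not expected — the output
metadata says so.

Per lineage (a parent/child node pair bounding a stem branch), a site
counts as a *compressibility-decreasing substitution* when the
most-probable parent and child amino acids differ **and** the
posterior-expected K⁰, $E[K^0] = \sum_c P(c)\, K^0(aa(c))$, decreases.
Requiring an actual state change keeps infinitesimal posterior drifts at
conserved sites from counting; the expectation (rather than the point
state) is what makes the same substitution yield slightly different
$\Delta K^0$ in different lineages. Candidates are the intersection of the
decreasing sites across lineages, further filtered to sites with
$P(\gamma_1) >$ 0.95 (configurable). With the threshold at 0 and a single
lineage, the screen reduces to that lineage's decreasing-substitution
list.

## Pressure thermodynamics

All estimators operate on the analysis window, a configurable tail
fraction of each trajectory (default the final 50%, mirroring a
100 ns production run analysed over 50–100 ns). Uncertainties are standard
deviations over non-overlapping blocks (default 5) — a methodological
substitution, since the original report does not state how its SDs were
computed.

* **Isothermal compressibility**:
  $\kappa_T = (\langle V^2\rangle - \langle V\rangle^2)/(k_B T \langle
  V\rangle)$, reported in GPa⁻¹; $T$ is the window-mean temperature. The
  reported statistic is the difference between the 30 MPa and 0.1 MPa
  conditions. The volume column is whatever the trajectory tool emits
  (typically the system volume) even though the definition concerns the
  solute volume; the two are not reconciled here either.
* **RMSF**: frames are least-squares superposed (Kabsch) onto an
  iteratively refined mean structure (2 passes), then
  $\mathrm{RMSF}_i = \sqrt{\langle |r_i - \langle r_i\rangle|^2\rangle}$.
  The default rhodopsin selection is residues 33–322 (helices I–VIII),
  excluding the poorly modelled termini; trajectories whose numbering does
  not overlap that window are analysed in full.
* **Quasiharmonic entropy**: the mass-weighted covariance of Cα
  fluctuations (uniform carbon mass) is eigendecomposed after
  superposition; each mode is a harmonic oscillator at
  $\omega_i = \sqrt{k_B T/\lambda_i}$ and contributes the quantum
  harmonic-oscillator entropy (classical variant behind a flag — the
  quasiharmonic literature uses both, and the original report does not
  say which). The six smallest-eigenvalue modes (rigid-body remnants) are
  dropped, as are modes below an eigenvalue floor, with a warning. Fewer
  frames than 3N also warns.
* **Conformational energy**: the per-frame sum of the bonded terms (bond,
  Urey–Bradley, proper/improper dihedral, CMAP) plus intramolecular
  short-range and 1–4 Coulomb and Lennard-Jones columns, averaged over the
  window.
* **Solvation**: the polar component is consumed as a precomputed input
  (an external Poisson–Boltzmann calculation; never computed here). The
  nonpolar part is $pV + \gamma_{st} A$ with the water surface tension
  $\gamma_{st} = 0.1032$ kcal mol⁻¹ Å⁻² at 300 K; the van der Waals term
  is omitted as negligible (<0.1%). A deterministic Shrake–Rupley SASA
  (probe 1.4 Å, 960 golden-spiral points) is provided for when no area
  column is supplied. Water dielectric constants at the two conditions
  (77.75 at 0.1 MPa, 78.83 at 30 MPa) ride along in `thermo_constants()`
  for the external polar step.
* **Free-energy assembly**: $\Delta G_p = \Delta E_{conf} - T\Delta S +
  \Delta\Delta\mu$ holds exactly by construction; component uncertainties
  propagate in quadrature.

Unit conventions: energies kcal/mol (kJ/mol convertible by 4.184), lengths
Å, pressures MPa on input, temperatures K.

## What the synthetic data do and do not show

The generators define the validation conditions:

* Codon alignments evolve by exact transition-matrix sampling down the
  tree (site classes drawn from the mixture, root states from π), with
  true site classes and ancestral states emitted. The default study tree
  has 12 taxa with two foreground-tagged "deep" clade stems — the original
  design at reduced scale. The branch-model recovery study runs at 300
  codons, κ = 6, ω = 0.77, γ_fg = 0.4, γ_bg = 0.2 (the published point
  estimates); medians over 10 replicates recover all four parameters, and
  the branch LRT holds its nominal 5% size under null simulations within
  the binomial acceptance region at 12 replicates. Site-mixture
  *proportions* are weakly identified on the 12-taxon tree (the likelihood
  surface is nearly flat in them even when the LRT has power), so the
  proportion-recovery study uses a 50-taxon tree at 350 codons, where
  $P(\gamma_1)$ is recovered to within a few percentage points.
* Volume series are i.i.d. Gaussian with variance
  $\sigma^2 = \kappa_T k_B T \mu_V$, so the compressibility estimator has
  a closed-form target (recovered within 3% at 10⁵ frames). Real volume
  series are autocorrelated; block SDs on synthetic data therefore
  understate nothing, but the oracle says nothing about equilibration.
* Harmonic trajectories fluctuate independently per atom with per-axis
  variance $k_B T/k$, giving analytic RMSF $\sqrt{3 k_B T/k}$ and an
  analytic mode spectrum for the entropy (both recovered within 2%).
  These validate the estimators, not MD physics: no solvent, no
  anharmonicity, no coupling between residues.

Consequently, passing tests establish estimator and inference-machinery
correctness under the stated models. They do not reproduce the original
study's data-scale results: the 52-taxon rhodopsin fits require the
genome-derived alignment (not shipped), and the MD-derived magnitudes of
$\kappa_T$, ΔRMSF and $\Delta G_p$ require 100 ns explicit-solvent
simulations. The published free-energy decompositions enter only as exact
assembly-identity fixtures (−56 + 14 + 285 = 243; 98 − 26 + 274 = 346;
2 − 1 + 251 = 252; −66 + 17 + 257 = 208 kcal mol⁻¹), and the published
branch-model table as AIC/LRT arithmetic checks.

## Known limitations

* Pure-R likelihoods: a 50-taxon mixture fit takes a couple of minutes;
  genome-scale sweeps would want a compiled pruning kernel.
* No rate variation beyond the ω×γ class structure, no topology search,
  and no joint (as opposed to marginal) ancestral reconstruction.
* The K⁰ scale is a constrained reconstruction (above); analyses that
  depend on the unconstrained residues' exact values should inject a
  measured scale.
* The site-model LRT's χ² reference is approximate at the boundary, and
  mixture proportions are unidentifiable on small trees — report
  $P(\gamma_1)$ with its LRT rather than individual proportions there.
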