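---
title: "Methods: non-equilibrium binding free energy analysis with neqbind"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: non-equilibrium binding free energy analysis with neqbind}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(neqbind)
```

# The model

## Non-equilibrium work and the Crooks fluctuation theorem

An alchemical transition couples or decouples a guest molecule's
interactions through a parameter $\lambda \in [0,1]$. A fast switch along
$\lambda$ performs work

$$ W = \int_0^1 \frac{\partial H}{\partial \lambda}\, d\lambda , $$

which fluctuates between repeats because the switch drives the system out
of equilibrium. `integrate_work()` evaluates this integral by trapezoidal
quadrature along the series' own $\lambda$ path: forward series (0→1) give
the forward work, reverse series (1→0) the reverse work, *as measured* — no
sign is flipped by the integration. Storing reverse works un-negated
matches what an MD engine emits; estimators negate internally where a
common work axis is required.

Forward and reverse work distributions are related by the Crooks
fluctuation theorem (CFT),

$$ \frac{P_f(W)}{P_r(W)} = e^{\beta (W - \Delta G)}, $$

where $P_r$ is the density of *negated* reverse works and
$\beta = 1/k_B T$. The maximum-likelihood estimator built on the CFT (the
Bennett acceptance ratio in its logistic-regression form) solves

$$ \sum_{i=1}^{n_f} \frac{1}{1 + e^{\beta(M + W^f_i - \Delta G)}}
 - \sum_{j=1}^{n_r} \frac{1}{1 + e^{-\beta(M + \bar W_j - \Delta G)}} = 0,
 \qquad M = \beta^{-1}\ln (n_f/n_r), $$

with $\bar W_j$ the negated reverse works. This function is strictly
monotone in $\Delta G$, so the root is unique; `estimate_cft_ml()` brackets
it by the range of all (forward-convention) works, expands the bracket
geometrically up to ten times its width if needed, and polishes the root to
$|f| < 10^{-10}$. Because the equation *always* has a root, lack of overlap
between the two work distributions cannot be detected as a bracketing
failure; it is instead detected up front as disjoint work supports, and
reported as an error with the two ranges and their gap rather than silently
extrapolated.

The default uncertainty is the asymptotic maximum-likelihood variance
(a sum of Fermi-function products over the pooled works); a within-direction
bootstrap (`bootstrap_stderr()`) is available and is what the acceptance
checks use, since the published uncertainties came from independent repeats
rather than a single asymptotic formula. Two companion estimators serve as
cross-checks: the Jarzynski exponential average
$\Delta G = -\beta^{-1}\ln \langle e^{-\beta W}\rangle$ (log-sum-exp
formulation; biased high in dissipative regimes, and bounded above by the
mean work — Jensen's inequality, asserted in the tests) and the Crooks
Gaussian intersection, the crossing point of Gaussians fitted to the two
work distributions (equal-variance case solved analytically as the midpoint
of the means; otherwise the quadratic root between the means).

## From transition free energies to binding free energies

The simulation campaign this package models used the double-system/single-box
(DSSB) construction: one guest bound in the host and a second copy in
solution, coupled in opposition, so the box's net charge never changes. The
sign chain from the transition free energy to the binding free energy
depends on which end state is called A; since that convention is easy to get
wrong silently, `assemble_binding()` takes it as an explicit argument. The
default, `"unbinding"`, means the A→B transition decouples the bound guest
(and couples the solution copy), so
$\Delta G_{bind} = -\Delta G_{trans} + \Delta G_{restr}$.

The decoupled guest is held in its pose by one distance, two angle and
three dihedral harmonic restraints. Releasing them to the standard-state
volume $V^0 = 1.6605\ \mathrm{nm^3}$ (1 M) contributes the analytical
correction

$$ \Delta G_{restr} = -k_B T \ln \frac{8\pi^2 V^0
 \sqrt{k_r k_{\theta_A} k_{\theta_B} k_{\phi_A} k_{\phi_B} k_{\phi_C}}}
 {r_0^2 \sin\theta_{A0} \sin\theta_{B0} (2\pi k_B T)^3}. $$

This formula is the stiff-spring limit of the restrained configurational
integral: the Jacobian $r^2 \sin\theta_A \sin\theta_B$ is evaluated at the
reference geometry and the Gaussians integrated over unbounded ranges. The
tests validate it two ways: against a quadrature of exactly that
stiff-spring integral at the campaign's force constants
(4184 kJ mol⁻¹ nm⁻², 41.84 kJ mol⁻¹ rad⁻²), and against the exact-Jacobian
integral across a random sweep. The second comparison is meaningful only
well inside the stiff regime: at $k \cdot \mathrm{scale}^2 / k_B T \approx
17$ (the campaign's angular constants, scale 1 rad) the anharmonic
$\sin\theta$ correction alone is ~0.14 kJ/mol, so the sweep samples
$k \cdot \mathrm{scale}^2 / k_B T \ge 200$, where the residual Jacobian
corrections stay below the 0.05 kJ/mol test band. This is a property of the
formula itself (it is the same approximation the original derivation
makes), not of this implementation.

Each host–guest system was probed in two orientations — polar group toward
the primary (one hydroxyl per sugar) or secondary (two hydroxyls) face of
the cyclodextrin. The orientations are mutually exclusive states, so
`combine_poses()` uses the Boltzmann sum
$\Delta G = -k_B T \ln \sum_i e^{-\beta \Delta G_i}$ over non-discarded
poses, with first-order error propagation through the Boltzmann weights
($\sigma^2 = \sum w_i^2 \sigma_i^2$). The combined value always lies
between the strongest pose and that pose minus $k_B T \ln(\text{number of
poses})$, which the tests assert on random inputs. A population-weighted
mean variant is available behind `method = "weighted-mean"` because the
literature formula the campaign cited is not spelled out; the Boltzmann sum
over mutually exclusive states is the default on physical grounds.

Repeats are averaged arithmetically with the SEM ($s/\sqrt n$, flagged
undefined at $n = 1$), then force fields are combined by the consensus mean
with quadrature propagation, $\tfrac{1}{n}\sqrt{\sum \sigma_i^2}$ — the
propagation formula is this package's choice, as the source campaign never
stated one. Relative free energies are all $n(n-1)/2$ host-pair differences
per guest (exactly cycle-consistent by construction), and benchmark metrics
are the average unsigned error and Pearson correlation with paired-bootstrap
uncertainties over systems (bootstrap over systems, not over repeats, is the
default — the alternative was left behind the `n_boot` machinery since the
published error-bar provenance is ambiguous).

## Conformational entropy and free-energy surfaces

The Schlitter estimator upper-bounds the conformational entropy from the
covariance $C$ of the superposed Cartesian coordinates:

$$ S = \frac{R}{2} \ln\det\!\left( \mathbf 1 +
 \frac{k_B T e^2}{\hbar^2} M^{1/2} C M^{1/2} \right). $$

`schlitter_entropy()` converts to SI (amu→kg, nm²→m²,
$\hbar = 1.054571817\times10^{-34}$ J s), symmetrizes the mass-weighted
covariance and sums $\log(1+\cdot)$ over its eigenvalues, so the determinant
argument is dimensionless and rank-deficient covariances (fewer frames than
coordinates) are exact thanks to the $+\mathbf 1$. Superposition
(`superpose()`, Kabsch rotations; default reference is the twice-iterated
mean structure) must remove rigid-body motion first — the function refuses
non-superposed input unless told otherwise, because external motion
inflates $C$ arbitrarily. The central oracle for this module: ensembles
sampled from a known covariance must reproduce the closed form computed
from that covariance's eigenvalues (within 1% at $5\times10^4$ frames,
10 atoms — the size the tests and acceptance script use; larger selections
only grow the eigenproblem cubically).

The entropy contribution to binding is reported as
$T(S_{holo} - S_{apo})$ in kcal/mol (1 kcal = 4184 J): negative when the
unbound host is conformationally richer, i.e. when binding costs entropy.
This sign convention reproduces every cell of the published apo/holo table
it is checked against; the source table never wrote the formula out, so the
interpretation is recorded here.

PCA (`fit_pca()`) diagonalizes the pooled, non-mass-weighted Cartesian
covariance of the selected atoms (heavy atoms of the unmodified sugars, in
the original study); pooling apo and holo ensembles puts all surfaces in the
same coordinates. Mass weighting is available but off by default — the
original figure caption specifies the selection, not the weighting.
Free-energy surfaces (`project_fes()`) histogram the first two projections
and set $\Delta G = -k_B T \ln(c/c_{max})$, so the modal bin is exactly zero,
occupied bins are non-negative, and empty bins are masked NA rather than
zero (a zero would claim a free-energy minimum where there are no samples).

## Event filtering

Repeats where the guest flips orientation or leaves the host must be
excluded before estimation, and unbound/surface-bound frames before FES
construction. `filter_events()` labels frames from the orientation cosine
and the host–guest COM distance with hysteresis: a state change is accepted
only when the new state's observable exceeds its band for a minimum number
of consecutive frames. Defaults — cosine band 0.2, unbind distance 1.5 nm,
persistence 50 frames — are exposed in `run_config()`; the source protocol
states that filtering occurred but no thresholds, so these are this
package's calibration, chosen so that a noise-free flip is located exactly
and a flip under cosine noise of 0.1 is located within ±20 frames (both
asserted over 100 seeds). The filter is deterministic and idempotent; an
all-noise series yields a verdict flagged low-confidence rather than an
error.

## Force-field dihedral linting

GAFF 2.x parameter files contain quadruples of atom types assigned several
distinct dihedral parameter sets — e.g. the sugar-ring `c3-c3-os-c3`
torsion, which carries both a general-purpose and a stiffer sugar-specific
set. `detect_overdefined()` flags a quadruple only when all three marks of
the pathology hold: no wildcard types, at least two sets sharing a
periodicity with different barrier or phase (sets with disjoint
periodicities are ordinary multi-term dihedrals), and non-sequential entry
(at least one unrelated line between the sets). Quadruples are
canonicalized as the lexicographic minimum of forward and reversed order,
so reversed duplicates group together. Barriers are converted to kJ/mol at
parse time (AMBER dialects are kcal/mol); AMBER continuation lines
(negative periodicity) join their predecessor's parameter set.

`apply_dihedral_policy()` implements the three observed interpretations:
*first-match* (keep the earliest set, as antechamber effectively does),
*preferred-variant* (default predicate: highest force constant — the
sugar-specific choice), and *all-variants* (stack every set's terms at
once, the PrimaDORAC interpretation). The transform replaces terms rather
than appending, so it is idempotent. Atom typing itself is out of scope:
reproducing antechamber-vs-PrimaDORAC type assignment would require a full
typing engine, and which atoms constitute a "side chain" for the ×0.81
charge-scaling experiment is user-supplied rather than inferred.

# Synthetic data: what it does and does not show

The generators reproduce the *statistical structure* the analysis relies
on: work sets that satisfy the CFT exactly in distribution (forward
$\mathcal N(\Delta G + \beta\sigma^2/2, \sigma^2)$, reverse measured along
1→0 $\mathcal N(-\Delta G + \beta\sigma^2/2, \sigma^2)$), Gaussian
coordinate ensembles with known covariance, geometry series with planted
events, and parameter files with injected duplicates. Defaults mirror the
study conditions: temperature 300.15 K (298 K for the modified protocol),
three repeats per pose, tens to 151 transitions per repeat and direction,
work spreads of order 1 kJ/mol.

Passing tests therefore demonstrate estimator correctness, unit
consistency, convention coherence and detector recall *under the generating
assumptions*. They do not demonstrate robustness to what real MD produces
and the generators omit: non-Gaussian work tails from slow degrees of
freedom, time-correlated frames (every generated frame is independent),
anharmonic multi-basin conformational distributions (the Schlitter bound is
exact only for Gaussians), or partial pose occupancy between flips. The
published challenge-level numbers (AUE ≈ 1.4 kcal/mol, weak Pearson
correlation) depend on those ensembles and are out of reach at desk scale
by design; the metrics operations are validated on their arithmetic and
bootstrap behaviour instead.

# Numerical choices

* $k_B = 0.0083144621$ kJ/(mol K) (the Gromacs constant), energies in
  kJ/mol internally, kcal only at reporting boundaries (×4.184 exactly).
* All log-sum-exp constructions (Jarzynski, pose combination) subtract the
  maximum before exponentiating; Fermi functions clamp their argument at
  700 to avoid overflow.
* CFT-ML root: `uniroot` followed by bisection polish to $|f| < 10^{-10}$;
  the degenerate all-equal-works case short-circuits at the exact root.
* CGI equal-variance degeneracy: relative variance difference below
  $10^{-12}$ switches to the analytic midpoint; otherwise the quadratic
  root between the means is preferred, falling back to the root nearest the
  inter-mean gap when binning noise pushes both roots outside.
* Eigen-decompositions are performed on explicitly symmetrized matrices;
  negative eigenvalues from roundoff are clipped at zero.
* Superposition rejects selections whose centred reference is rank
  deficient (collinear atoms make the rotation ill-defined); the Boresch
  formula rejects $\sin\theta_0 < 10^{-6}$.
* Seeds are explicit arguments everywhere; generators save and restore the
  caller's RNG state, so library calls never perturb a script's stream.
* Test problem sizes: $5\times10^4$ frames / 10 atoms for the Schlitter
  oracle, 500 + 500 works × 20 seeds for the estimator checks, 1000
  generated parameter files for the linter sweep, 30 transitions per
  direction and repeat for the end-to-end run. These sizes put sampling
  error comfortably below the asserted tolerances while keeping the suite
  quick.

# Known limitations

* Single-estimate uncertainties for Jarzynski are bootstrap-only; no
  analytic bias correction is applied (the estimator's bias at large
  $\beta\sigma^2$ is inherent).
* The Schlitter value is an upper bound, not the entropy; differences of
  upper bounds (apo − holo) carry no one-sided guarantee.
* The FES is a histogram estimate; bins are uniform and no kernel smoothing
  is applied, so sparsely occupied regions are noisy at high bin counts.
* The linter audits proper dihedrals only (GROMACS function types 1/9;
  AMBER DIHE); impropers, Lennard-Jones and bonded terms are out of scope,
  as is atom-type assignment.
* Multi-state estimators (MBAR), λ-schedule optimization and equilibrium
  thermodynamic integration are deliberately absent: the pipeline models a
  two-end-state non-equilibrium campaign.

# A minimal run

```{r example}
ws <- gen_gaussian_work(dg_true = -10, sigma = 2, n_forward = 500,
                        n_reverse = 500, temperature = 300.15, seed = 42)
estimate_cft_ml(ws)

restr <- restraint_definition(r0 = 0.5, thetaA0 = pi/2, thetaB0 = pi/2,
                              k_r = 4184, k_thetaA = 41.84, k_thetaB = 41.84,
                              k_phiA = 41.84, k_phiB = 41.84, k_phiC = 41.84)
restraint_correction(restr, 300.15)

entropy_contribution(s_holo = 458, s_apo = 643, temperature = 300.15)
```
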