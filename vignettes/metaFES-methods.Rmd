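---
title: "Free-energy landscapes, minimum free-energy paths and HDX reweighting with metaFES"
author: "metaFES authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{metaFES methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope and model

metaFES implements the computational chain that turns enhanced-sampling
simulations of a conformational transition — such as the outward-facing
(OF) to inward-facing (IF) alternating-access transition of a secondary
transporter — into quantitative observables: multidimensional free-energy
landscapes, two-dimensional projections with error maps, minimum
free-energy paths with barriers and intermediates, perturbative
free-energy shifts under modified interactions, and ensemble populations
reweighted against hydrogen-deuterium-exchange mass-spectrometry (HDX-MS)
data.

Because the method layer, not any particular molecular system, is the
package's subject, every input can be produced by the built-in synthetic
generators with known ground truth: analytic multi-well potentials sampled
by an overdamped Langevin integrator with metadynamics biasing and
Monte-Carlo replica exchange, idealized two-state structural ensembles,
and synthetic HDX datasets with known state populations and back-exchange.
All tests and the acceptance analysis run end-to-end on these generators.

## Collective variables

Three CV families are provided, evaluated on `StructureFrame` objects
(coordinates in nm):

* **Path variables.** Progress between two reference structures is
  \[
  \xi = \frac{e^{-\lambda d_1} + 2 e^{-\lambda d_2}}
             {e^{-\lambda d_1} + e^{-\lambda d_2}},
  \]
  where \(d_k\) is the mean-square difference (MSD, nm\(^2\)) of a chosen
  atom selection to reference \(k\) after optimal rigid-body (Kabsch)
  superposition, and \(\lambda\) (nm\(^{-2}\)) sets the switching
  sharpness.  Values lie strictly in (1, 2); a three-reference analogue
  ranges over (1, 3).  Superposition before the MSD is on by default (the
  conventional choice for structure-based progress variables) and can be
  disabled.  When \(\lambda\) is not given for a two-reference variable it
  is set to \(c / d_{12}\) with \(d_{12}\) the inter-reference MSD; the
  default \(c = 2.3\) makes the variable change by about 0.8 of its range
  between the references while keeping both endpoint values
  distinguishable.  Typical literature values for such variables are
  \(\lambda = 20\) nm\(^{-2}\) (global rearrangements, \(d_{12}\) of order
  0.1 nm\(^2\)) and \(\lambda = 200\) nm\(^{-2}\) (local gating motions);
  both are exercised in the tests.  All exponential mixtures use
  max-subtraction, so arbitrarily large \(\lambda d\) cannot overflow.

* **Hydration variables.** The hydration of an ion-binding site is
  \(\xi = \beta \ln \sum_j e^{\beta / r_j}\) over all water oxygens
  \(j\), with \(r_j\) the distance to the site centre (the ion when bound,
  otherwise the centre of mass of the coordinating protein oxygens) and
  \(\beta = 10\) nm by default.  The expression is dominated by the
  closest water and behaves as \(\beta^2 / r_{\min}\); it is implemented
  exactly in this printed form (prefactor \(\beta\) outside the
  logarithm), giving a length-valued variable.  A soft-max variant with a
  \(1/\beta\) prefactor would give a length of the order of
  \(r_{\min}\) itself; we deliberately do not silently substitute it, and
  no such variant is enabled by default.

* **Contact counts.** For residue sets A and B,
  \(S_C = \sum_{i \in A, j \in B} s(r_{ij})\) over C\(\alpha\)–C\(\alpha\)
  distances, with the rational switching function
  \(s(r) = [1-(r/r_0)^4]/[1-(r/r_0)^8]\) and \(r_0 = 0.7\) nm.  The
  implementation uses the algebraically equivalent factored form
  \(1/[1+(r/r_0)^4]\), which removes the \(r = r_0\) singularity
  (\(s(r_0) = 1/2\)); the two forms agree to better than \(10^{-9}\)
  everywhere else, which is asserted in the tests.

Water accessibility of a residue is counted as the water oxygens within
4.2 Å of any of its atoms; ensemble means with block errors come from
`reweightedAverage()`.

## Synthetic sampling engine

The generator integrates overdamped (Brownian) Langevin dynamics,
\[
x \leftarrow x - \frac{\Delta t}{\gamma} \nabla (U + V)
  + \mathcal{N}(0,\, 2 k_B T \Delta t / \gamma),
\]
on analytic multi-well potentials (sums of inverted Gaussians with
optional harmonic confinement), at 298 K with \(k_B =
0.0019872041\) kcal/(mol K) and nm/ps/kcal-per-mol units throughout.  The
overdamped form was chosen over underdamped dynamics because only the
configurational distribution matters for these tests.  An explicit
stability guard rejects \(\Delta t \cdot \gamma \ge 0.1\).  Noise comes
from R's RNG, so a single `set.seed()` makes every product of the package
bit-reproducible; the Euler–Maruyama discretization carries an
\(O(k\,\Delta t/\gamma)\) bias in stationary variances, which the tests
keep below their statistical resolution by using \(\Delta t \le
0.005\) ps.

Metadynamics deposits Gaussians of configurable height, width and pace
along a subset of coordinates; well-tempered rescaling is optional and
off by default (plain metadynamics makes the accumulated bias mirror the
negative free energy directly, which the estimators below rely on).
Bias-exchange runs several replicas with different biased subsets plus
optionally an unbiased replica, and attempts Monte-Carlo configuration
swaps between a random adjacent pair every fixed interval, accepted with
probability \(\min(1, e^{-\Delta\Delta V / k_B T})\) where
\(\Delta\Delta V\) is the change in total bias energy caused by the swap.
Each recorded frame carries the instantaneous bias potential and the bias
gradient \(\partial V / \partial \xi\) for the biased coordinates —
exactly the information a PLUMED COLVAR file provides, and the package
reads and writes that dialect.

The canonical test systems are `doubleWellPotential1D()` (asymmetric
double well, quadrature-computable populations) and
`threeWellPotential2D()` (three minima near (−0.8, −0.5), (0.8, −0.5) and
(0, 0.7) nm separated by ~3 kcal/mol saddles).  Their default depths,
widths and confinement were chosen once so that barriers are large enough
that unbiased dynamics cannot cross them on test timescales (making the
bias machinery load-bearing) yet small enough that a 4-replica
bias-exchange run of a few hundred thousand steps per replica converges
on one CPU in under a minute.

## Free-energy estimation

Frames are binned on uniform half-open grids (`[lo, hi)`; a value on an
interior edge belongs to the upper bin; frames outside the grid are
counted and excluded, never silently dropped).  Free energies are
estimated by a force-correction scheme in the spirit of mean-force-based
estimators:

1. per bin and per dimension, average the recorded bias gradient
   \(\partial V/\partial \xi_d\) over the frames in the bin, using only
   replicas in which that coordinate was biased; at metadynamics
   stationarity \(-\langle \partial V/\partial \xi_d \rangle\) estimates
   \(\partial F/\partial \xi_d\);
2. solve the discrete gradient system — for every face-adjacent pair of
   reliable bins, the free-energy difference equals the bin width times
   the midpoint average of the two gradient estimates — in the least
   squares sense over the largest connected component of reliable bins
   (default reliability: 20 force samples per dimension), with a sparse
   normal-equations solve; the residual is reported;
3. min-shift to zero; unvisited or unreliable bins carry `Inf`.

The numerical identity of this scheme with any published software is not
claimed; its contract is agreement with analytic oracles, which the tests
enforce: exact recovery for linear forces and constructed curl-free
fields, and RMSE below 0.3 kcal/mol against quadrature on the 2D
benchmark for bins with \(F < 4\) kcal/mol.

One property of the per-bin mean bias gradient deserves a note.  The
stationary metadynamics bias is not exactly \(-F\); it carries a static
ripple from the finite hill width, and the per-bin time average inherits
it.  On the 1D benchmark this leaves a root-mean-square discrepancy of
roughly half a kcal/mol/nm between \(-\langle \partial V/\partial x
\rangle\) and \(dF/dx\) even after pooling many independent runs, while
the *integrated* profile agrees with quadrature several times more
tightly because the ripple largely cancels under summation.  The tests
therefore check the gradient estimator at its achievable per-bin accuracy
and reserve the 0.3 kcal/mol bound for integrated free energies, where it
belongs.

An independent cross-check, `freeEnergyFromBias()`, negates the
accumulated bias of one replica on the same grid; the two estimators are
required to agree within 0.3 kcal/mol RMSE on converged benchmarks.

Frame weights follow the inverse-histogram Boltzmann form
\[
w_i \propto \frac{1}{N_{\alpha(i)}} e^{-F(\xi^{\alpha(i)}) / k_B T},
\]
with \(\alpha(i)\) the bin of frame \(i\) and \(N_{\alpha(i)}\) its total
frame count; frames in unreliable bins are excluded and counted.  Weights
are invariant to constant shifts of \(F\) (asserted to \(10^{-12}\)).  An
optional `discardFraction` drops an initial equilibration window per
trajectory before weighting; the default is 0, and the packaged analyses
discard the first 30% — the window over which the toy biases visibly
equilibrate — mirroring the universal practice of analysing only the
stationary tail of a metadynamics run.

Two-dimensional landscapes are reweighted histograms,
\(F(x,y) = -k_B T \ln \sum_{i \in \text{bin}} w_i\), min-shifted, with
per-bin standard errors from contiguous-block resampling (default 10
blocks; bins finite in every block).  Perturbative reweighting computes
perturbed state probabilities \(p'_S \propto \sum_{i \in S} w_i
e^{-\Delta U_i / k_B T}\) with max-subtraction (so constant shifts cancel
exactly), returns \(\Delta\Delta F\) with block errors, and warns when
the exponential average's effective sample size drops below 10% of the
frames.

## Minimum free-energy paths

On a binned landscape the "most probable path" is implemented as the
**minimax** path: among all face-adjacent bin paths between two
endpoints, the one minimizing the maximum \(F\) encountered, with ties
broken by the smaller cumulative \(\sum e^{F/k_B T}\).  The barrier is
the path maximum minus \(F\) at the start, and the saddle is the bin
attaining it.  This criterion was chosen because it is exactly
verifiable: the bottleneck value admits an independent exact oracle
(threshold connectivity — the lowest level at which the endpoints join
through sub-level bins), and the tests require exact agreement on 100
random grids plus full path enumeration on tiny grids.  Face adjacency
(no diagonal moves) keeps the oracle exact.  Because the minimax value
depends only on the ordering of \(F\), barriers and saddles are invariant
under monotone transformations of the landscape, which is asserted
property-style.  Path profiles report \(F\) against normalized arc length
in CV space; strict local minima between the endpoints are returned as
metastable intermediates with depths relative to the lower flanking
maximum.

## HDX forward model and maximum-entropy reweighting

Amide protection is modelled phenomenologically:
\(\ln P_r = \beta_c N_c + \beta_h N_h\), with \(N_c\) the heavy atoms
within 0.65 nm of the residue's amide nitrogen and \(N_h\) the O/N
acceptors within 0.24 nm of the amide hydrogen, excluding residues within
±2 sequence positions; \(\beta_c = 0.35\), \(\beta_h = 2.0\).  These are
the standard coefficients of the phenomenological protection model used
throughout the HDX-modelling literature; all are configurable, and the
run metadata records them as explicit package choices.  Intrinsic rates
\(k^{int}_r\) are accepted per residue (uniform in the synthetic
studies); sequence-based rate chemistry is out of scope.

The fragment-level forward model averages \(\ln P\) over the weighted
ensemble first (protection averaging), exponentiates, and predicts
\[
D_{f,t} = \rho\, \frac{1}{m}\sum_{r}
  \left[1 - e^{-k^{int}_r t / \bar P_r}\right]
\]
over the fragment's exchange-competent residues (the range minus its
first residue and minus prolines, the standard HDX-MS convention).  The
alternative convention — average the per-frame uptake instead — is
available behind the `averaging` flag.  \(\rho \in (0,1]\) is the
back-exchange retention (deuterium loss after quenching); it is fitted
per construct by the closed-form least squares \(\rho = \sum o p / \sum
p^2\), clipped to (0, 1], and refitted inside every reweighting
iteration.  Predicted fractions are monotone in time and bounded by
\(\rho\) (property-tested over 1000 random parameter draws).
Overlapping fragments deconvolve linearly:
\(D_{A \setminus B} = (m_A D_A - m_B D_B)/(m_A - m_B)\); out-of-range
results are flagged as noise and clipped with a warning.

Maximum-entropy reweighting minimizes
\[
J(w) = \frac{\gamma}{2} \sum_{f,t} (D^{pred}_{f,t}(w) - D^{obs}_{f,t})^2
  + \sum_i w_i \ln \frac{w_i}{w^0_i}
\]
over the simplex by damped exponential-gradient (mirror-descent)
iterations of the stationarity condition \(w_i \propto w^0_i
e^{-\gamma\, \partial \chi^2/2\, /\, \partial w_i}\), halving the step
when \(J\) increases and stopping when the relative change of \(J\) falls
below \(10^{-8}\).  \(\gamma = 0\) returns the prior exactly; the KL
divergence from the prior is non-decreasing in \(\gamma\) (asserted over
a ladder).  When no \(\gamma\) is given to `maxentScan()`, the knee of
the L-curve (KL versus log mean-square deviation) is selected by maximum
chord distance.  The packaged recovery study fixes \(\gamma = 1000\),
i.e. of the order of the inverse noise variance for measurement noise of
a few percent — at much larger \(\gamma\) the weights chase noise and the
population estimate degrades, which is visible in the study itself if one
raises \(\gamma\).

**Identifiability.** Populations and \(\rho\) are jointly identifiable
only if the data are rich enough: \(\rho\) rescales all predictions
while a population shift changes their pattern across fragments and
times.  With few fragments and times the two directions become nearly
degenerate and noise can drive the fit to an inverted solution.  The
default synthetic design therefore uses short fragments tiling the chain
(step 3) and six exposure times spanning 0.2–15 s with \(k^{int} = 3\)
s\(^{-1}\), under which the end-to-end study recovers populations
0.8/0.2 and \(\rho = 0.7\) from an equal-population prior to within
±0.05 on noise-free data and ±0.10 at noise s.d. 0.03.

## What the synthetic data do and do not show

The generators emulate the *structure* of the real problem — biased
sampling with known stationary distributions, two-state ensembles with
controllable geometry, HDX data with known ground truth — but not its
*hardness*: real landscapes are higher-dimensional, CVs imperfect,
force fields approximate, experimental noise structured.  Passing tests
demonstrate that the estimators are correct and self-consistent, not that
any particular molecular conclusion is right.  In particular the toy
barriers (~3 kcal/mol) are not the multi-microsecond barriers of a real
transporter, and the protection model is a deliberate phenomenological
stand-in.

## Problem sizes and numerical choices

The packaged analyses use 4 replicas × 400 000 steps (2D benchmark), a
36 × 36 grid, 16 × 250 000 steps for the pooled 1D mean-force study,
10\(^6\) steps for the equilibrium check, and 80-frame HDX ensembles —
sizes chosen so the full validation chain completes in minutes on one
CPU while leaving comfortable statistical margins.  Other defaults worth
knowing: empty-bin sentinel `Inf`; reliability threshold 20 force samples
per bin; contour export interval 1 kcal/mol; block count 10; convergence
tolerance \(10^{-8}\) on the maximum-entropy objective; temperature fixed
per run (no multi-temperature support); single-ion hydration centres and
C\(\alpha\)-only contact atoms.

## Known limitations

* The mean-force estimator uses instantaneous bias gradients; its per-bin
  accuracy is limited by the static hill-width ripple discussed above.
* Minimax paths live on the bin graph; no continuous-space string or
  nudged-elastic-band refinement is provided (a steepest-descent
  refinement of the saddle neighbourhood is a possible extension).
* WHAM/MBAR-style estimators are deliberately out of scope, as are
  trajectory formats requiring MD-engine libraries; COLVAR/HILLS, PDB,
  CSV and the RDS grid container are the interchange formats.
* The HDX module models fragment-level deuterated fractions only: no
  isotopic envelopes, no peptide mass spectra, no intrinsic-rate
  chemistry.
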