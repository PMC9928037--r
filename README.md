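# metaFES

Tools for turning **bias-exchange metadynamics** sampling into
free-energy landscapes and mechanistic observables, with a synthetic-data
layer that makes the whole chain testable against exact ground truth.

The package is aimed at computational structural biologists who study
large conformational transitions — the motivating case is the
alternating-access cycle of a secondary-active transporter, where an
outward-facing (OF) and an inward-facing (IF) state exchange over
multi-kcal/mol barriers — and who need the analysis machinery behind such
studies as reusable, validated components:

* **Collective variables** on coordinate frames: path progress variables
  ξ = [e^(−λd₁) + 2e^(−λd₂)] / [e^(−λd₁) + e^(−λd₂)] built on
  mean-square differences to reference structures after Kabsch
  superposition (two- and three-reference forms, values in (1,2) and
  (1,3)); binding-site hydration ξ = β ln Σⱼ exp(β/rⱼ) over water
  oxygens; soft contact counts S_C = Σ s(r) with the rational switching
  function s(r) = 1/[1+(r/r₀)⁴] (r₀ = 0.7 nm); water-accessibility
  counts.
* **Free-energy estimation** from biased replicas: binned mean
  bias-gradient estimates, least-squares integration of the discrete
  gradient field over the reliable-bin graph, the classic
  bias-negation estimate as an independent cross-check, and per-frame
  Boltzmann weights w_i ∝ N_α(i)⁻¹ exp(−F(ξ^α(i))/k_BT).
* **Landscapes and paths**: reweighted 2D free-energy maps with
  contiguous-block error maps; minimax minimum free-energy paths on the
  bin graph with barriers, saddles and metastable intermediates.
* **Hamiltonian-perturbation reweighting** (Zwanzig): ΔΔF between
  labeled states under per-frame energy changes, with effective-sample-
  size warnings and block errors.
* **HDX-MS ensemble reweighting**: a phenomenological protection-factor
  forward model (ln P = β_c·N_c + β_h·N_h), back-exchange retention ρ
  fitted per construct, overlapping-fragment deconvolution, and
  maximum-entropy reweighting of state populations against fragment
  deuteration data.
* **Synthetic data with known truth**: an Rcpp overdamped-Langevin engine
  with metadynamics hills and Metropolis replica exchange on analytic
  multi-well potentials; two-state structural ensembles; HDX datasets
  with known populations, protection factors and back-exchange.

File formats: PLUMED-style COLVAR/HILLS dialects (read/write), PDB
(read, via bio3d), HDX CSV tables, flat CSV exports and an RDS grid
container. A YAML-driven `runPipeline()` chains the stages end-to-end
and writes a manifest with a config hash so reruns are bit-identical.

## Worked example

Four-replica bias-exchange metadynamics on the canonical 2D three-well
potential, free-energy recovery, and the OF→IF minimum free-energy path:

```r
library(metaFES)

pot <- threeWellPotential2D()
sch <- function() metadSchedule(1:2, height = 0.12, sigma = 0.15, pace = 250)
set.seed(5)
bex <- runBiasExchange(pot, list(sch(), sch(), sch(), NULL),
  starts = rbind(c(-0.8, -0.5), c(0.8, -0.5), c(0, 0.7), c(-0.8, -0.5)),
  nSteps = 250000, exchangeInterval = 500, recordStride = 10)

edges <- gridEdges(c(-1.8, -1.8), c(1.8, 1.8), 36)
grid <- assignBins(bex$trajectories, edges)
grid <- estimateMeanForces(bex$trajectories, grid, discardFraction = 0.3)
grid <- integrateMeanForces(grid)
grid
#> CVGrid over cv1 x cv2: 36 x 36 bins, 1209 visited, 715 with finite F
#>   448 frame(s) fell outside the grid

ens <- frameWeights(grid, bex$trajectories, discardFraction = 0.3)
ens
#> WeightedEnsemble: 65868 frames (4132 excluded)
#>   effective sample size 27042.2 (41.1%)

mfep <- minimumFreeEnergyPath(grid, c(11, 14), c(27, 14),
                              labels = c("OF", "IF"))
mfep
#> FreeEnergyPath OF -> IF: 27 steps, barrier 3.199 kcal/mol
pathProfile(mfep)$intermediates
#>   index progress     F depth
#> 1    14    0.500 3.146 0.030
#> 2    26    0.962 0.685 0.191
```

The recovered barrier (3.2 kcal/mol) agrees with the analytic saddle of
the potential (~3.1–3.3 kcal/mol above the deepest well); the landscape
RMSE against quadrature over bins with F < 4 kcal/mol is below 0.3
kcal/mol (this is asserted by the test suite). The shallow intermediate
half-way along the path sits at the potential's third well.

Two-state HDX population recovery from an equal-population prior, with
the back-exchange retention fitted jointly:

```r
rec <- hdxRecoveryStudy(truePopulations = c(A = 0.8, B = 0.2),
                        rho = 0.7, seed = 5)
rec$result
#> MaxEntResult: gamma = 1000, KL = 0.1873, MSD = 7.602e-08, converged in 463 it.
#>   populations: A = 0.795, B = 0.205
#>   back-exchange retention: WT = 0.698
```

The generating truth (populations 0.8/0.2, ρ = 0.7) is recovered within
±0.01 on noise-free data.

The packaged end-to-end demo (simulation → landscape → path → HDX
recovery, all artifacts plus `manifest.json` on disk) runs with:

```r
runPipeline(system.file("extdata", "demo-config.yaml", package = "metaFES"),
            outputDir = "metafes-demo")
```

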