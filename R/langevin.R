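#' Metadynamics schedule
#'
#' Describes the Gaussian bias deposited along a subset of coordinates:
#' height, per-coordinate widths, deposition pace and (optionally)
#' well-tempered rescaling.  Plain (non-tempered) metadynamics is the
#' default, in which case the accumulated bias converges to (minus) the free
#' energy along the biased coordinates up to a fluctuating offset.
#'
#' @param biasedCVs integer indices (1-based) of the biased coordinates.
#' @param height Gaussian height, kcal/mol.
#' @param sigma Gaussian width per biased coordinate, nm (recycled).
#' @param pace deposition interval in steps.
#' @param biasFactor well-tempered bias factor (> 1) or `NA` for plain
#'   metadynamics (default).
#' @return a `MetadSchedule` list.
#' @export
metadSchedule <- function(biasedCVs, height = 0.1, sigma = 0.1, pace = 500,
                          biasFactor = NA) {
  stopifnot(length(biasedCVs) >= 1, height > 0, all(sigma > 0), pace >= 1,
            is.na(biasFactor) || biasFactor > 1)
  structure(list(biasedCVs = as.integer(biasedCVs), height = height,
                 sigma = rep_len(sigma, length(biasedCVs)),
                 pace = as.integer(pace), biasFactor = biasFactor),
            class = "MetadSchedule")
}

.checkLangevinParams <- function(timestep, friction, temperature, nSteps) {
  stopifnot(timestep > 0, friction > 0, temperature >= 0, nSteps >= 1)
  if (timestep * friction >= 0.1)
    stop("unstable parameters: timestep * friction must be < 0.1")
}

.emptyHills <- function(m) matrix(numeric(0), 0, if (m > 0) 2 * m + 2 else 1)

#' Metadynamics bias potential from deposited hills
#'
#' Evaluates the accumulated Gaussian bias (and its gradient) at arbitrary
#' points in the space of the biased coordinates.
#'
#' @param hills numeric hills matrix with columns `center_*`, `sigma_*`,
#'   `height`, `time` (as stored in a [ReplicaTrajectory-class] or read by
#'   [readHills()]).
#' @param points matrix (points x biased coordinates) or vector.
#' @return list with `bias` (kcal/mol) and `gradient`.
#' @export
biasFromHills <- function(hills, points) {
  if (is.vector(points)) points <- matrix(points, nrow = 1)
  points <- as.matrix(points)
  m <- ncol(points)
  if (nrow(hills) > 0 && ncol(hills) != 2 * m + 2)
    stop("hills matrix has ", ncol(hills), " columns; expected ", 2 * m + 2)
  if (nrow(hills) == 0)
    return(list(bias = numeric(nrow(points)),
                gradient = matrix(0, nrow(points), m)))
  .cpp_eval_bias(hills, points)
}

#' Overdamped Langevin sampling of a toy potential
#'
#' Integrates the Brownian (overdamped Langevin) equation
#' \deqn{x \leftarrow x - \frac{\Delta t}{\gamma}\nabla(U + V)
#'       + \mathcal{N}(0,\, 2 k_B T \Delta t / \gamma)}
#' on a [ToyPotential-class], optionally with a metadynamics bias \eqn{V}
#' acting on a coordinate subset.  Every recorded frame carries the
#' instantaneous bias potential and the bias gradient
#' \eqn{\partial V/\partial \xi} for the biased coordinates, mirroring what
#' a PLUMED COLVAR file provides.  Noise is drawn from R's RNG, so
#' `set.seed()` (or the `seed` argument) makes runs bit-reproducible.
#'
#' @param potential a [ToyPotential-class].
#' @param start numeric start position, nm.
#' @param nSteps number of integration steps.
#' @param timestep ps.
#' @param friction 1/ps; `timestep * friction` must be below 0.1.
#' @param temperature K; 0 disables noise.
#' @param bias a [metadSchedule()] or `NULL` for unbiased dynamics.
#' @param recordStride record every this many steps.
#' @param seed optional integer; if given, `set.seed(seed)` is called first.
#' @param replicaId integer label for the returned trajectory.
#' @return a [ReplicaTrajectory-class].
#' @export
langevinSimulate <- function(potential, start, nSteps, timestep = 0.005,
                             friction = 1, temperature = 298, bias = NULL,
                             recordStride = 10L, seed = NULL,
                             replicaId = 1L) {
  stopifnot(is(potential, "ToyPotential"))
  .checkLangevinParams(timestep, friction, temperature, nSteps)
  if (!is.null(seed)) set.seed(seed)
  D <- ncol(potential@centers)
  stopifnot(length(start) == D)
  kT <- kBoltzmann * temperature
  if (is.null(bias)) {
    biased <- integer(0); hills <- .emptyHills(0)
    height <- 0; sigma <- numeric(0); pace <- 0L; bf <- 0
  } else {
    stopifnot(inherits(bias, "MetadSchedule"))
    biased <- bias$biasedCVs; hills <- .emptyHills(length(biased))
    height <- bias$height; sigma <- bias$sigma; pace <- bias$pace
    bf <- if (is.na(bias$biasFactor)) 0 else bias$biasFactor
  }
  seg <- .cpp_langevin_segment(
    potential@centers, potential@depths, potential@widths,
    potential@confinement, potential@confinementCenter,
    as.numeric(start), as.integer(nSteps), timestep, friction, kT,
    biased - 1L, hills, height, sigma, as.integer(pace), bf,
    as.integer(recordStride), 0L)
  grad <- seg$biasGradient
  if (length(biased) == 0) grad <- matrix(numeric(0), length(seg$time), 0)
  new("ReplicaTrajectory", replicaId = as.integer(replicaId),
      biasedCVs = biased, time = seg$time, cv = seg$positions,
      biasPotential = seg$bias, biasGradient = grad,
      temperature = temperature, hills = seg$hills)
}

#' Bias-exchange metadynamics on a toy potential
#'
#' Runs several Langevin replicas on the same potential, each with its own
#' metadynamics bias on a (possibly different) coordinate subset, or
#' unbiased.  Every `exchangeInterval` steps a Monte-Carlo exchange of
#' configurations is attempted between a randomly chosen adjacent pair of
#' replicas and accepted with the Metropolis probability
#' \eqn{\min(1, e^{-\Delta\Delta V / k_B T})}, where \eqn{\Delta\Delta V} is
#' the change in total bias energy caused by the swap.
#'
#' @param potential a [ToyPotential-class].
#' @param replicas list whose elements are [metadSchedule()] objects or
#'   `NULL` (unbiased replica).
#' @param starts numeric matrix (replicas x dimensions) of start positions,
#'   or a single vector used for all.
#' @param nSteps total steps per replica.
#' @param exchangeInterval steps between exchange attempts.
#' @inheritParams langevinSimulate
#' @return list with `trajectories` (list of [ReplicaTrajectory-class]) and
#'   `swaps` (data.frame: time, pair indices, deltaBias, accepted).
#' @export
runBiasExchange <- function(potential, replicas, starts, nSteps,
                            exchangeInterval = 500L, timestep = 0.005,
                            friction = 1, temperature = 298,
                            recordStride = 10L, seed = NULL) {
  stopifnot(is(potential, "ToyPotential"), length(replicas) >= 2,
            exchangeInterval >= 1)
  .checkLangevinParams(timestep, friction, temperature, nSteps)
  if (!is.null(seed)) set.seed(seed)
  R <- length(replicas)
  D <- ncol(potential@centers)
  if (is.vector(starts)) starts <- matrix(starts, R, D, byrow = TRUE)
  kT <- kBoltzmann * temperature

  st <- lapply(seq_len(R), function(r) {
    b <- replicas[[r]]
    if (!is.null(b)) stopifnot(inherits(b, "MetadSchedule"))
    list(x = as.numeric(starts[r, ]),
         biased = if (is.null(b)) integer(0) else b$biasedCVs,
         hills = .emptyHills(if (is.null(b)) 0 else length(b$biasedCVs)),
         height = if (is.null(b)) 0 else b$height,
         sigma = if (is.null(b)) numeric(0) else b$sigma,
         pace = if (is.null(b)) 0L else b$pace,
         bf = if (is.null(b) || is.na(b$biasFactor)) 0 else b$biasFactor,
         time = list(), pos = list(), bias = list(), grad = list())
  })

  nSeg <- ceiling(nSteps / exchangeInterval)
  swaps <- vector("list", nSeg)
  stepOffset <- 0L
  for (s in seq_len(nSeg)) {
    segSteps <- min(exchangeInterval, nSteps - stepOffset)
    for (r in seq_len(R)) {
      z <- st[[r]]
      seg <- .cpp_langevin_segment(
        potential@centers, potential@depths, potential@widths,
        potential@confinement, potential@confinementCenter,
        z$x, as.integer(segSteps), timestep, friction, kT,
        z$biased - 1L, z$hills, z$height, z$sigma, as.integer(z$pace),
        z$bf, as.integer(recordStride), stepOffset)
      z$x <- seg$x
      z$hills <- seg$hills
      z$time[[s]] <- seg$time; z$pos[[s]] <- seg$positions
      z$bias[[s]] <- seg$bias; z$grad[[s]] <- seg$biasGradient
      st[[r]] <- z
    }
    stepOffset <- stepOffset + segSteps
    if (s < nSeg) {
      a <- if (R == 2) 1L else sample.int(R - 1L, 1L)
      b <- a + 1L
      att <- .attemptSwap(st[[a]], st[[b]], kT)
      if (att$accepted) {
        tmp <- st[[a]]$x; st[[a]]$x <- st[[b]]$x; st[[b]]$x <- tmp
      }
      swaps[[s]] <- data.frame(time = stepOffset * timestep, replicaA = a,
                               replicaB = b, deltaBias = att$deltaBias,
                               accepted = att$accepted)
    }
  }

  trajectories <- lapply(seq_len(R), function(r) {
    z <- st[[r]]
    grad <- do.call(rbind, z$grad)
    if (length(z$biased) == 0)
      grad <- matrix(numeric(0), length(unlist(z$time)), 0)
    new("ReplicaTrajectory", replicaId = as.integer(r), biasedCVs = z$biased,
        time = unlist(z$time), cv = do.call(rbind, z$pos),
        biasPotential = unlist(z$bias), biasGradient = grad,
        temperature = temperature, hills = z$hills)
  })
  list(trajectories = trajectories,
       swaps = do.call(rbind, swaps[!vapply(swaps, is.null, logical(1))]))
}

## one Metropolis exchange attempt between two replica states; consumes one
## uniform deviate from R's RNG
.attemptSwap <- function(stateA, stateB, kT) {
  vSelf <- .swapBias(stateA, stateA$x) + .swapBias(stateB, stateB$x)
  vSwap <- .swapBias(stateA, stateB$x) + .swapBias(stateB, stateA$x)
  dd <- vSwap - vSelf
  list(deltaBias = dd,
       accepted = runif(1) < exp(-dd / max(kT, .Machine$double.eps)))
}

## total bias energy a replica's hills exert on configuration x
.swapBias <- function(state, x) {
  if (length(state$biased) == 0 || nrow(state$hills) == 0) return(0)
  biasFromHills(state$hills, x[state$biased])$bias
}

#' Metropolis swap acceptance probability for a replica pair
#'
#' Closed-form acceptance probability for exchanging configurations `xA` and
#' `xB` between two replicas whose biases are given as hills matrices.  Used
#' both by the sampler and, on frozen configurations, as the analytic value
#' that empirical swap statistics are tested against.
#'
#' @param hillsA,hillsB hills matrices of the two replicas.
#' @param biasedA,biasedB integer coordinate subsets each bias acts on.
#' @param xA,xB full configurations of the two replicas.
#' @param temperature K.
#' @return acceptance probability in (0, 1].
#' @export
swapAcceptance <- function(hillsA, biasedA, hillsB, biasedB, xA, xB,
                           temperature = 298) {
  kT <- kBoltzmann * temperature
  vA <- function(x) if (length(biasedA)) biasFromHills(hillsA, x[biasedA])$bias else 0
  vB <- function(x) if (length(biasedB)) biasFromHills(hillsB, x[biasedB])$bias else 0
  dd <- (vA(xB) + vB(xA)) - (vA(xA) + vB(xB))
  min(1, exp(-dd / kT))
}
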