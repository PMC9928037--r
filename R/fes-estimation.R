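## Force-correction free-energy estimation on binned CV grids, Boltzmann
## frame weights, and perturbative (Zwanzig) reweighting.

.binIndex1D <- function(x, edges) {
  # half-open bins [lo, hi); values on an interior edge go to the upper bin
  i <- findInterval(x, edges, rightmost.closed = FALSE, all.inside = FALSE)
  i[x >= edges[length(edges)]] <- 0L  # top edge and beyond: outside
  i
}

## per-frame multi-dim bin index matrix (0 = outside) for one trajectory
.binIndices <- function(cv, edges, cvSubset) {
  idx <- vapply(seq_along(cvSubset), function(d)
    .binIndex1D(cv[, cvSubset[d]], edges[[d]]), integer(nrow(cv)))
  if (!is.matrix(idx)) idx <- matrix(idx, ncol = length(cvSubset))
  idx
}

.linearIndex <- function(idx, dims) {
  ok <- rowSums(idx == 0L) == 0L
  lin <- rep(NA_integer_, nrow(idx))
  if (any(ok)) {
    mult <- cumprod(c(1L, dims[-length(dims)]))
    lin[ok] <- as.integer(1L + (idx[ok, , drop = FALSE] - 1L) %*% mult)
  }
  lin
}

#' Uniform grid edges
#'
#' @param lower,upper numeric vectors of per-dimension bounds.
#' @param nBins bins per dimension (recycled).
#' @return list of bin-edge vectors usable as a grid specification.
#' @export
gridEdges <- function(lower, upper, nBins = 50L) {
  nBins <- rep_len(as.integer(nBins), length(lower))
  lapply(seq_along(lower), function(d)
    seq(lower[d], upper[d], length.out = nBins[d] + 1L))
}

#' Bin trajectory frames on a CV grid
#'
#' Assigns every frame of the given trajectories to a half-open
#' multidimensional bin `[lo, hi)` over the chosen CV subset and returns a
#' [CVGrid-class] holding the counts.  Frames outside the grid are counted
#' in the `outside` slot, never silently dropped.
#'
#' @param trajectories list of [ReplicaTrajectory-class] objects.
#' @param edges list of bin-edge vectors (e.g. from [gridEdges()]); edges
#'   must be strictly increasing and non-degenerate.
#' @param cvSubset integer indices of the CVs spanning the grid (default:
#'   all columns of the first trajectory).
#' @param cvNames names for the grid dimensions.
#' @param minCount reliability threshold stored with the grid (bins with
#'   fewer force samples are not used in integration); default 20.
#' @return a [CVGrid-class] with counts; `F` is all-`Inf` until estimated.
#' @export
assignBins <- function(trajectories, edges, cvSubset = NULL, cvNames = NULL,
                       minCount = 20L) {
  if (is(trajectories, "ReplicaTrajectory")) trajectories <- list(trajectories)
  if (is.null(cvSubset)) cvSubset <- seq_len(ncol(trajectories[[1]]@cv))
  if (any(vapply(edges, function(e) any(diff(e) <= 0), logical(1))))
    stop("zero-width or decreasing bins in grid specification")
  dims <- vapply(edges, function(e) length(e) - 1L, integer(1))
  counts <- array(0L, dim = dims)
  outside <- 0L
  for (tr in trajectories) {
    lin <- .linearIndex(.binIndices(tr@cv, edges, cvSubset), dims)
    outside <- outside + sum(is.na(lin))
    tab <- tabulate(lin[!is.na(lin)], nbins = prod(dims))
    counts <- counts + array(tab, dim = dims)
  }
  if (is.null(cvNames)) cvNames <- paste0("cv", cvSubset)
  new("CVGrid", edges = edges, cvNames = cvNames, counts = counts,
      F = array(Inf, dim = dims),
      meanForce = rep(list(array(NA_real_, dim = dims)), length(dims)),
      forceCount = rep(list(array(0L, dim = dims)), length(dims)),
      minCount = as.integer(minCount), outside = outside,
      metadata = list(cvSubset = cvSubset))
}

#' Per-bin mean bias-gradient estimates
#'
#' For each grid dimension, averages the recorded instantaneous bias
#' gradient \eqn{\partial V/\partial \xi_d} over the frames falling in each
#' bin, using only trajectories in which that CV was actually biased.  At
#' metadynamics stationarity the accumulated bias mirrors the negative free
#' energy, so minus this bin mean estimates the free-energy gradient there.
#'
#' @param trajectories list of [ReplicaTrajectory-class] objects.
#' @param grid a [CVGrid-class] from [assignBins()].
#' @param discardFraction initial fraction of each trajectory discarded as
#'   equilibration before averaging (default 0).
#' @return the grid with `meanForce` and `forceCount` filled.
#' @export
estimateMeanForces <- function(trajectories, grid, discardFraction = 0) {
  if (is(trajectories, "ReplicaTrajectory")) trajectories <- list(trajectories)
  cvSubset <- grid@metadata$cvSubset
  dims <- dim(grid@counts)
  nbin <- prod(dims)
  sums <- rep(list(numeric(nbin)), length(dims))
  ns <- rep(list(integer(nbin)), length(dims))
  any_force <- FALSE
  for (tr in trajectories) {
    if (length(tr@biasedCVs) == 0) next
    keep <- seq_len(nFrames(tr)) > floor(discardFraction * nFrames(tr))
    cv <- tr@cv[keep, , drop = FALSE]
    lin <- .linearIndex(.binIndices(cv, grid@edges, cvSubset), dims)
    ok <- !is.na(lin)
    for (d in seq_along(cvSubset)) {
      j <- match(cvSubset[d], tr@biasedCVs)
      if (is.na(j)) next
      any_force <- TRUE
      g <- tr@biasGradient[keep, j][ok]
      l <- lin[ok]
      rs <- rowsum(g, l)  # sorted unique bins as rownames
      add <- numeric(nbin)
      add[as.integer(rownames(rs))] <- rs[, 1]
      sums[[d]] <- sums[[d]] + add
      ns[[d]] <- ns[[d]] + tabulate(l, nbins = nbin)
    }
  }
  if (!any_force) stop("no trajectories with bias-force records")
  for (d in seq_along(dims)) {
    mf <- ifelse(ns[[d]] > 0, sums[[d]] / pmax(ns[[d]], 1L), NA_real_)
    grid@meanForce[[d]] <- array(mf, dim = dims)
    grid@forceCount[[d]] <- array(ns[[d]], dim = dims)
  }
  grid
}

#' Integrate binned mean forces into a free energy
#'
#' Solves the discrete gradient system in the least-squares sense: for every
#' pair of face-adjacent reliable bins, the free-energy difference equals
#' the bin-width times the average of the two bins' gradient estimates
#' (minus the mean bias gradient).  The solve runs over the largest
#' connected component of reliable bins; the result is min-shifted to 0 and
#' `Inf` elsewhere.  The normalized least-squares residual (RMS of equation
#' misfit, kcal/mol) and component sizes are stored in `metadata`.
#'
#' @param grid a [CVGrid-class] with mean forces
#'   (see [estimateMeanForces()]).
#' @param minCount per-dimension force-sample threshold for a bin to count
#'   as reliable; defaults to the grid's `minCount`.
#' @return the grid with `F` filled.
#' @export
integrateMeanForces <- function(grid, minCount = NULL) {
  if (is.null(minCount)) minCount <- grid@minCount
  dims <- dim(grid@counts)
  nd <- length(dims)
  nbin <- prod(dims)
  ncount <- vapply(grid@forceCount, as.integer, integer(nbin))
  reliable <- rowSums(ncount >= minCount) == nd
  if (!any(reliable)) stop("no reliable bins to integrate")
  grad <- vapply(seq_len(nd), function(d) -as.numeric(grid@meanForce[[d]]),
                 numeric(nbin))
  h <- vapply(grid@edges, function(e) diff(e)[1], numeric(1))
  mult <- cumprod(c(1L, dims[-nd]))

  # adjacency equations between reliable neighbours
  sub <- arrayInd(which(reliable), dims)
  linOf <- function(ind) as.integer(1L + (ind - 1L) %*% mult)
  relLin <- which(reliable)
  isRel <- logical(nbin); isRel[relLin] <- TRUE
  eqFrom <- integer(0); eqTo <- integer(0); eqRhs <- numeric(0)
  for (d in seq_len(nd)) {
    ok <- sub[, d] < dims[d]
    if (!any(ok)) next
    nb <- sub[ok, , drop = FALSE]
    nb[, d] <- nb[, d] + 1L
    a <- relLin[ok]
    b <- linOf(nb)
    keep <- isRel[b]
    a <- a[keep]; b <- b[keep]
    if (!length(a)) next
    eqFrom <- c(eqFrom, a); eqTo <- c(eqTo, b)
    eqRhs <- c(eqRhs, h[d] * 0.5 * (grad[a, d] + grad[b, d]))
  }
  if (!length(eqFrom)) stop("reliable bins are isolated: nothing to integrate")

  # largest connected component over the adjacency equations
  vmap <- match(seq_len(nbin), relLin)
  gph <- igraph::graph_from_edgelist(
    cbind(vmap[eqFrom], vmap[eqTo]), directed = FALSE)
  if (igraph::vcount(gph) < length(relLin))
    gph <- igraph::add_vertices(gph, length(relLin) - igraph::vcount(gph))
  cmp <- igraph::components(gph)
  keepComp <- which.max(cmp$csize)
  inComp <- relLin[cmp$membership == keepComp]
  useEq <- cmp$membership[vmap[eqFrom]] == keepComp
  eqFrom <- eqFrom[useEq]; eqTo <- eqTo[useEq]; eqRhs <- eqRhs[useEq]
  sizes <- cmp$csize

  idx <- match(seq_len(nbin), inComp)
  n <- length(inComp)
  nEq <- length(eqFrom)
  A <- Matrix::sparseMatrix(
    i = rep(seq_len(nEq), 2L),
    j = c(idx[eqTo], idx[eqFrom]),
    x = rep(c(1, -1), each = nEq), dims = c(nEq + 1L, n))
  # anchor the gauge freedom: fix the first bin at 0 with a soft row
  A[nEq + 1L, 1L] <- 1
  bvec <- c(eqRhs, 0)
  sol <- Matrix::solve(Matrix::crossprod(A), Matrix::crossprod(A, bvec))
  Fv <- as.numeric(sol)
  resid <- sqrt(mean((as.numeric(A %*% sol)[seq_len(nEq)] - eqRhs)^2))

  Fall <- rep(Inf, nbin)
  Fall[inComp] <- Fv - min(Fv)
  grid@F <- array(Fall, dim = dims)
  grid@metadata$residual <- resid
  grid@metadata$componentSizes <- as.integer(sizes)
  grid@metadata$minCountUsed <- as.integer(minCount)
  grid
}

#' Free energy as the negative of the accumulated bias
#'
#' Evaluates the metadynamics bias a replica deposited (its hills) at the
#' bin centres of a grid and returns \eqn{F = -V}, min-shifted to 0.  This
#' is the classic metadynamics estimate and serves as an independent
#' cross-check of [integrateMeanForces()].
#'
#' @param trajectory a biased [ReplicaTrajectory-class] with hills, or a
#'   list of such replicas biased on the same CVs, in which case the
#'   negated final biases are averaged (each min-shifted first), damping
#'   the temporal fluctuation any single replica's bias carries.
#' @param grid a [CVGrid-class] whose dimensions correspond, in order, to
#'   the trajectory's biased CVs.
#' @return the grid with `F` filled on all bins.
#' @export
freeEnergyFromBias <- function(trajectory, grid) {
  if (is.list(trajectory)) {
    trajectory <- Filter(function(t) length(t@biasedCVs) > 0, trajectory)
    if (length(trajectory) == 0) stop("no biased replicas: no hills to negate")
    Fs <- lapply(trajectory, function(t)
      freeEnergyFromBias(t, grid)@F)
    Fm <- Reduce(`+`, Fs) / length(Fs)
    grid@F <- array(Fm - min(Fm), dim = dim(grid@counts))
    return(grid)
  }
  if (nrow(trajectory@hills) == 0) {
    if (length(trajectory@biasedCVs) == 0)
      stop("trajectory is unbiased: no hills to negate")
    grid@F <- array(0, dim = dim(grid@counts))
    return(grid)
  }
  dims <- dim(grid@counts)
  centers <- lapply(grid@edges, function(e) (e[-1] + e[-length(e)]) / 2)
  pts <- as.matrix(expand.grid(centers))
  V <- biasFromHills(trajectory@hills, pts)$bias
  Fv <- -V
  grid@F <- array(Fv - min(Fv), dim = dims)
  grid
}

#' Boltzmann frame weights from a binned free energy
#'
#' Sets the weight of frame i to
#' \eqn{w_i \propto N_{\alpha(i)}^{-1} e^{-F(\xi^{\alpha(i)}) / k_B T}},
#' where \eqn{\alpha(i)} is the frame's bin and \eqn{N_{\alpha(i)}} the
#' total number of retained frames in that bin; weights are normalized to
#' sum 1.  Frames in bins with non-finite F (never visited or unreliable)
#' or outside the grid are excluded and counted.
#'
#' @param grid a [CVGrid-class] with `F` estimated.
#' @param trajectories list of [ReplicaTrajectory-class] objects.
#' @param temperature K (default 298).
#' @param discardFraction initial fraction of each trajectory discarded
#'   (default 0); must match what the free energy was estimated from.
#' @return a [WeightedEnsemble-class]; its `frames` data.frame identifies
#'   each retained frame by replica id and frame index.
#' @export
frameWeights <- function(grid, trajectories, temperature = 298,
                         discardFraction = 0) {
  if (is(trajectories, "ReplicaTrajectory")) trajectories <- list(trajectories)
  kT <- kBoltzmann * temperature
  cvSubset <- grid@metadata$cvSubset
  dims <- dim(grid@counts)
  Flin <- as.numeric(grid@F)
  repl <- integer(0); fr <- integer(0); lin <- integer(0)
  for (tr in trajectories) {
    keep <- which(seq_len(nFrames(tr)) > floor(discardFraction * nFrames(tr)))
    li <- .linearIndex(.binIndices(tr@cv[keep, , drop = FALSE], grid@edges,
                                   cvSubset), dims)
    repl <- c(repl, rep(tr@replicaId, length(keep)))
    fr <- c(fr, keep)
    lin <- c(lin, li)
  }
  ok <- !is.na(lin) & is.finite(Flin[lin])
  nExcluded <- sum(!ok)
  if (!any(ok)) stop("all frames excluded: no finite free energy anywhere")
  linOk <- lin[ok]
  Nbin <- tabulate(linOk, nbins = prod(dims))
  logw <- -Flin[linOk] / kT - log(Nbin[linOk])
  logw <- logw - logSumExp(logw)
  w <- exp(logw)
  w <- w / sum(w)
  new("WeightedEnsemble",
      frames = data.frame(replica = repl[ok], frame = fr[ok]),
      weights = w, nExcluded = as.integer(nExcluded))
}

#' Weighted ensemble average with block error
#'
#' \eqn{\sum_i w_i o_i} with a standard error from contiguous block
#' resampling: the frames are cut into `nBlocks` contiguous blocks, the
#' weighted mean is recomputed per block (weights renormalized within the
#' block), and the error is the standard deviation of block means divided
#' by \eqn{\sqrt{n_{blocks}}}.
#'
#' @param ensemble a [WeightedEnsemble-class].
#' @param observable numeric per-frame observable, same length/order as the
#'   ensemble's frames.
#' @param nBlocks number of contiguous blocks (default 10).
#' @return list with `value`, `stderr` and `blockMeans`.
#' @export
reweightedAverage <- function(ensemble, observable, nBlocks = 10L) {
  n <- nFrames(ensemble)
  stopifnot(length(observable) == n)
  if (n < nBlocks) stop("fewer frames (", n, ") than blocks (", nBlocks, ")")
  w <- ensemble@weights
  value <- sum(w * observable)
  blk <- cut(seq_len(n), nBlocks, labels = FALSE)
  bm <- vapply(seq_len(nBlocks), function(b) {
    i <- blk == b
    sum(w[i] * observable[i]) / sum(w[i])
  }, numeric(1))
  list(value = value, stderr = sd(bm) / sqrt(nBlocks), blockMeans = bm)
}

#' Perturbative (Zwanzig) reweighting of a state free-energy difference
#'
#' Estimates how the free-energy difference between two labeled states
#' shifts when the Hamiltonian is perturbed by a per-frame energy change
#' \eqn{\Delta U_i} (e.g. from scaling selected atomic charges): perturbed
#' state probabilities are \eqn{p'_S \propto \sum_{i \in S} w_i
#' e^{-\Delta U_i / k_B T}} and
#' \eqn{\Delta\Delta F = \Delta F'(A \to B) - \Delta F(A \to B)}.
#' Computed with max-subtraction, so constant shifts of \eqn{\Delta U}
#' cancel exactly.  A warning is raised when the exponential average's
#' effective sample size falls below 10% of the frames.
#'
#' @param ensemble a [WeightedEnsemble-class].
#' @param deltaU per-frame energy change, kcal/mol.
#' @param states per-frame state labels (character; frames not matching
#'   `stateA`/`stateB` are ignored for the state probabilities).
#' @param stateA,stateB the two labels to compare.
#' @param temperature K.
#' @param nBlocks contiguous blocks for the error estimate.
#' @return list with `ddF` (kcal/mol), `stderr`, `essFraction` and the
#'   perturbed/unperturbed state probabilities.
#' @export
perturbativeReweight <- function(ensemble, deltaU, states, stateA, stateB,
                                 temperature = 298, nBlocks = 10L) {
  n <- nFrames(ensemble)
  stopifnot(length(deltaU) == n, length(states) == n)
  kT <- kBoltzmann * temperature
  w <- ensemble@weights
  lse <- function(lw) if (length(lw)) logSumExp(lw) else -Inf
  ddFof <- function(idx) {
    wi <- w[idx] / sum(w[idx])
    du <- deltaU[idx] - min(deltaU[idx])
    st <- states[idx]
    iA <- st == stateA; iB <- st == stateB
    if (!any(iA) || !any(iB))
      stop("a labeled state has no frames (or zero weight) in a block")
    lpA <- lse(log(wi[iA]))
    lpB <- lse(log(wi[iB]))
    lpA2 <- lse(log(wi[iA]) - du[iA] / kT)
    lpB2 <- lse(log(wi[iB]) - du[iB] / kT)
    if (!is.finite(lpA2) || !is.finite(lpB2))
      stop("a labeled state received zero perturbed weight")
    (-kT * (lpB2 - lpA2)) - (-kT * (lpB - lpA))
  }
  ddF <- ddFof(seq_len(n))
  lw <- log(w) - (deltaU - min(deltaU)) / kT
  lw <- lw - logSumExp(lw)
  essFraction <- 1 / sum(exp(lw)^2) / n
  if (essFraction < 0.1)
    warning(sprintf(
      "effective sample size of the exponential average is %.1f%% of frames",
      100 * essFraction))
  blk <- cut(seq_len(n), nBlocks, labels = FALSE)
  bdd <- tryCatch(vapply(seq_len(nBlocks), function(b) ddFof(which(blk == b)),
                         numeric(1)), error = function(e) NULL)
  list(ddF = ddF,
       stderr = if (is.null(bdd)) NA_real_ else sd(bdd) / sqrt(nBlocks),
       essFraction = essFraction,
       blockValues = bdd)
}
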