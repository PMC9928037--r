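## Central S4 containers.  All coordinates are in nm, energies in kcal/mol,
## times in ps (simulation) or s (HDX exposure).

#' ToyPotential: analytic multi-well potential
#'
#' A sum of inverted Gaussian wells plus optional harmonic confinement,
#' \deqn{U(x) = -\sum_k D_k \exp\{-\sum_d (x_d - c_{kd})^2 / 2\sigma_{kd}^2\}
#'       + \tfrac{1}{2}\sum_d \kappa_d (x_d - x^0_d)^2,}
#' used as a desk-scale stand-in for a molecular energy surface: its value,
#' gradient and marginal free energies are all computable to arbitrary
#' precision, which makes it the ground truth for every sampling and
#' reweighting test in the package.
#'
#' @slot centers numeric matrix, one row per well (columns = dimensions), nm.
#' @slot depths numeric vector of well depths, kcal/mol (positive = attractive).
#' @slot widths numeric matrix of per-well per-dimension Gaussian widths, nm.
#' @slot confinement numeric vector of per-dimension harmonic spring constants,
#'   kcal/mol/nm^2 (0 = unconfined).
#' @slot confinementCenter numeric vector, nm.
#' @export
setClass("ToyPotential", representation(
  centers = "matrix", depths = "numeric", widths = "matrix",
  confinement = "numeric", confinementCenter = "numeric"
), validity = function(object) {
  msg <- character()
  d <- ncol(object@centers)
  if (nrow(object@centers) != length(object@depths))
    msg <- c(msg, "one depth per well required")
  if (!all(dim(object@widths) == dim(object@centers)))
    msg <- c(msg, "widths must match centers in shape")
  if (any(object@widths <= 0)) msg <- c(msg, "widths must be positive")
  if (length(object@confinement) != d || length(object@confinementCenter) != d)
    msg <- c(msg, "confinement vectors must match dimension")
  if (any(object@confinement < 0)) msg <- c(msg, "confinement must be >= 0")
  if (length(msg)) msg else TRUE
})

#' ReplicaTrajectory: biased time series from one replica
#'
#' Holds what a PLUMED-style COLVAR file holds: per-frame time, the values of
#' all collective variables, the instantaneous bias potential and the bias
#' gradient with respect to each biased variable.
#'
#' @slot replicaId integer label.
#' @slot biasedCVs integer indices (1-based) of the CVs this replica biases;
#'   empty for an unbiased replica.
#' @slot time numeric vector, ps, strictly increasing.
#' @slot cv numeric matrix, frames x CVs.
#' @slot biasPotential numeric vector, kcal/mol.
#' @slot biasGradient numeric matrix, frames x length(biasedCVs): dV/dxi.
#' @slot temperature numeric, K.
#' @slot hills numeric matrix of deposited Gaussians with columns
#'   `center_*`, `sigma_*`, `height`, `time` (0 rows if unbiased).
#' @export
setClass("ReplicaTrajectory", representation(
  replicaId = "integer", biasedCVs = "integer", time = "numeric",
  cv = "matrix", biasPotential = "numeric", biasGradient = "matrix",
  temperature = "numeric", hills = "matrix"
), validity = function(object) {
  msg <- character()
  n <- length(object@time)
  if (n > 1 && any(diff(object@time) <= 0))
    msg <- c(msg, "time must be strictly increasing")
  if (nrow(object@cv) != n) msg <- c(msg, "cv rows must match time")
  if (length(object@biasPotential) != n)
    msg <- c(msg, "biasPotential length must match time")
  if (length(object@biasedCVs) > 0 &&
      ncol(object@biasGradient) != length(object@biasedCVs))
    msg <- c(msg, "biasGradient columns must match biasedCVs")
  if (length(msg)) msg else TRUE
})

#' CVGrid: binned multidimensional free-energy container
#'
#' Uniform half-open bins `[lo, hi)` per dimension.  Carries per-bin frame
#' counts, the free energy (min-shifted to 0; `Inf` marks unvisited or
#' unreliable bins), and the per-bin per-dimension mean bias-gradient
#' estimates used by force-correction free-energy estimation.
#'
#' @slot edges list of numeric bin-edge vectors, one per dimension.
#' @slot cvNames character, one per dimension.
#' @slot counts integer array of per-bin frame counts.
#' @slot F numeric array, kcal/mol, `Inf` on empty/unreliable bins.
#' @slot meanForce list of numeric arrays (one per dimension): per-bin mean
#'   of the recorded bias gradient dV/dxi_d (NA where no force data).
#' @slot forceCount list of integer arrays, sample sizes behind `meanForce`.
#' @slot minCount integer, reliability threshold for bins.
#' @slot outside integer, number of frames that fell outside the grid.
#' @slot metadata list: integration residual, connected-component sizes, etc.
#' @export
setClass("CVGrid", representation(
  edges = "list", cvNames = "character", counts = "array", F = "array",
  meanForce = "list", forceCount = "list", minCount = "integer",
  outside = "integer", metadata = "list"
), validity = function(object) {
  msg <- character()
  nd <- length(object@edges)
  if (length(object@cvNames) != nd) msg <- c(msg, "one name per dimension")
  dims <- vapply(object@edges, function(e) length(e) - 1L, integer(1))
  if (!identical(dim(object@counts), dims) && !(nd == 1 &&
        length(object@counts) == dims[1]))
    msg <- c(msg, "counts shape must match edges")
  if (any(vapply(object@edges, function(e) any(diff(e) <= 0), logical(1))))
    msg <- c(msg, "bin edges must be strictly increasing")
  if (length(msg)) msg else TRUE
})

#' WeightedEnsemble: frames with normalized statistical weights
#'
#' @slot frames data.frame with columns `replica` and `frame` identifying
#'   each retained simulation frame.
#' @slot weights numeric vector, non-negative, summing to 1.
#' @slot nExcluded integer, frames dropped (outside grid / unreliable bins).
#' @export
setClass("WeightedEnsemble", representation(
  frames = "data.frame", weights = "numeric", nExcluded = "integer"
), validity = function(object) {
  msg <- character()
  if (nrow(object@frames) != length(object@weights))
    msg <- c(msg, "one weight per frame")
  if (any(object@weights < 0)) msg <- c(msg, "weights must be non-negative")
  if (length(object@weights) &&
      abs(sum(object@weights) - 1) > 1e-12 * length(object@weights))
    msg <- c(msg, "weights must sum to 1")
  if (length(msg)) msg else TRUE
})

#' StructureFrame: labelled 3D coordinates for CV evaluation
#'
#' Protein atoms (with 1-based residue index and atom name), water oxygens
#' and optional ion positions, all in nm.
#'
#' @slot atoms data.frame with columns `resid` (integer), `name` (character),
#'   `x`, `y`, `z` (nm).
#' @slot waters numeric matrix (n x 3) of water-oxygen coordinates, nm.
#' @slot ions numeric matrix (n x 3) with rownames naming each ion, nm.
#' @export
setClass("StructureFrame", representation(
  atoms = "data.frame", waters = "matrix", ions = "matrix"
), validity = function(object) {
  msg <- character()
  need <- c("resid", "name", "x", "y", "z")
  if (!all(need %in% names(object@atoms)))
    msg <- c(msg, "atoms needs columns resid, name, x, y, z")
  else if (!all(is.finite(as.matrix(object@atoms[, c("x", "y", "z")]))))
    msg <- c(msg, "atom coordinates must be finite")
  if (ncol(object@waters) != 3 && nrow(object@waters) > 0)
    msg <- c(msg, "waters must be n x 3")
  if (length(msg)) msg else TRUE
})

#' Landscape2D: projected two-dimensional free-energy landscape
#'
#' @slot xName,yName descriptor names.
#' @slot xEdges,yEdges numeric bin edges.
#' @slot F numeric matrix, kcal/mol, min-shifted to 0, `Inf` on empty bins.
#' @slot stderr numeric matrix of per-bin standard errors (NA where not
#'   estimable).
#' @slot contourInterval numeric, kcal/mol (used by exporters/plots).
#' @export
setClass("Landscape2D", representation(
  xName = "character", yName = "character", xEdges = "numeric",
  yEdges = "numeric", F = "matrix", stderr = "matrix",
  contourInterval = "numeric"
), validity = function(object) {
  msg <- character()
  if (!identical(dim(object@F),
                 c(length(object@xEdges) - 1L, length(object@yEdges) - 1L)))
    msg <- c(msg, "F shape must match edges")
  fin <- object@F[is.finite(object@F)]
  if (length(fin) && abs(min(fin)) > 1e-9)
    msg <- c(msg, "finite F must be min-shifted to 0")
  if (any(object@stderr[!is.na(object@stderr)] < 0))
    msg <- c(msg, "stderr must be non-negative")
  if (length(msg)) msg else TRUE
})

#' FreeEnergyPath: minimum free-energy path on a grid
#'
#' @slot bins integer matrix, one row per step, grid bin indices; consecutive
#'   rows differ by one step along exactly one dimension (face adjacency).
#' @slot midpoints numeric matrix of bin-centre CV coordinates along the path.
#' @slot arcLength numeric, normalized progress in CV space (0 to 1).
#' @slot F numeric, kcal/mol along the path.
#' @slot barrier numeric, max F on path minus F at the start.
#' @slot saddle integer vector, bin index of the highest point.
#' @slot endpointLabels character of length 2.
#' @export
setClass("FreeEnergyPath", representation(
  bins = "matrix", midpoints = "matrix", arcLength = "numeric",
  F = "numeric", barrier = "numeric", saddle = "integer",
  endpointLabels = "character"
), validity = function(object) {
  msg <- character()
  if (nrow(object@bins) != length(object@F))
    msg <- c(msg, "one F value per path step")
  if (nrow(object@bins) > 1) {
    d <- abs(diff(object@bins))
    if (any(rowSums(d) != 1))
      msg <- c(msg, "consecutive bins must be face-adjacent")
  }
  if (length(object@F) &&
      object@barrier < max(0, object@F[length(object@F)] - object@F[1]) - 1e-9)
    msg <- c(msg, "barrier must be >= max(0, F_end - F_start)")
  if (length(msg)) msg else TRUE
})

#' MaxEntResult: maximum-entropy reweighting outcome
#'
#' @slot weights optimized frame weights on the simplex.
#' @slot prior the prior weights.
#' @slot gamma regularization strength actually used.
#' @slot populations named numeric, per-state summed weights.
#' @slot kl Kullback-Leibler divergence of `weights` from `prior`.
#' @slot msd final mean-square deviation between predictions and observations.
#' @slot rho named numeric, fitted back-exchange retention per construct.
#' @slot converged logical.
#' @slot iterations integer.
#' @export
setClass("MaxEntResult", representation(
  weights = "numeric", prior = "numeric", gamma = "numeric",
  populations = "numeric", kl = "numeric", msd = "numeric", rho = "numeric",
  converged = "logical", iterations = "integer"
), validity = function(object) {
  msg <- character()
  if (any(object@weights < 0)) msg <- c(msg, "weights must be non-negative")
  if (abs(sum(object@weights) - 1) > 1e-8)
    msg <- c(msg, "weights must sum to 1")
  if (object@kl < -1e-12) msg <- c(msg, "KL divergence must be >= 0")
  if (length(object@populations) &&
      abs(sum(object@populations) - 1) > 1e-8)
    msg <- c(msg, "populations must sum to 1")
  if (length(msg)) msg else TRUE
})
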