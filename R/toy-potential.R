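#' Construct an analytic multi-well toy potential
#'
#' Builds a [ToyPotential-class]: a sum of inverted Gaussian wells with
#' optional harmonic confinement.  These surfaces play the role of the
#' molecular energy landscape in all synthetic-data tests: their gradient is
#' analytic and their marginal free energies can be computed by quadrature,
#' so sampling and reweighting machinery can be validated against exact
#' ground truth.
#'
#' @param centers numeric matrix (wells x dimensions) of well centres, nm.  A
#'   vector is taken as a single dimension with one centre per element only
#'   when `dimension = 1`; otherwise supply a matrix.
#' @param depths numeric vector of well depths, kcal/mol.
#' @param widths numeric matrix (or scalar/vector, recycled) of Gaussian
#'   widths, nm.
#' @param confinement per-dimension harmonic spring constant,
#'   kcal/mol/nm^2; scalar recycled.  Default 0 (none).
#' @param confinementCenter centre of the confinement, nm; default origin.
#' @return a [ToyPotential-class] object.
#' @examples
#' pot <- toyPotential(centers = rbind(-1, 1), depths = c(4, 3),
#'                     widths = 0.3, confinement = 5)
#' evaluatePotential(pot, cbind(c(-1, 0, 1)))
#' @export
toyPotential <- function(centers, depths, widths, confinement = 0,
                         confinementCenter = 0) {
  centers <- as.matrix(centers)
  d <- ncol(centers)
  if (length(widths) == 1) widths <- matrix(widths, nrow(centers), d)
  if (is.vector(widths) && length(widths) == d)
    widths <- matrix(widths, nrow(centers), d, byrow = TRUE)
  widths <- as.matrix(widths)
  confinement <- rep_len(confinement, d)
  confinementCenter <- rep_len(confinementCenter, d)
  new("ToyPotential", centers = centers, depths = as.numeric(depths),
      widths = widths, confinement = confinement,
      confinementCenter = confinementCenter)
}

#' Evaluate a toy potential and its analytic gradient
#'
#' @param potential a [ToyPotential-class].
#' @param points numeric matrix (points x dimensions) or a single vector.
#' @return list with `energy` (kcal/mol) and `gradient`
#'   (kcal/mol/nm, points x dimensions).
#' @export
evaluatePotential <- function(potential, points) {
  stopifnot(is(potential, "ToyPotential"))
  if (is.vector(points)) points <- matrix(points, nrow = 1)
  points <- as.matrix(points)
  if (ncol(points) != ncol(potential@centers))
    stop("point dimension (", ncol(points), ") does not match potential (",
         ncol(potential@centers), ")")
  .cpp_eval_potential(potential@centers, potential@depths, potential@widths,
                      potential@confinement, potential@confinementCenter,
                      points)
}

#' Marginal free energy of a toy potential by quadrature
#'
#' Computes \eqn{F(x_S) = -k_B T \ln \int e^{-U/k_B T} dx_{S^c}} on a grid
#' over the kept dimensions `dims`, integrating out the remaining dimensions
#' by dense trapezoidal quadrature.  Used as the exact oracle that sampled
#' and reweighted landscapes are compared against.
#'
#' @param potential a [ToyPotential-class].
#' @param dims integer indices of the dimensions to keep.
#' @param at numeric matrix of points (in the kept dimensions) at which to
#'   evaluate F.
#' @param temperature K.
#' @param range integration range for each integrated-out dimension, a
#'   2-vector (applied to all) or a 2-column matrix.
#' @param nQuad quadrature nodes per integrated-out dimension.
#' @param shift if `TRUE` (default) min-shift the result to 0 over `at`.
#' @return numeric vector of free energies, kcal/mol.
#' @export
freeEnergyQuadrature <- function(potential, dims, at, temperature = 298,
                                 range = c(-3, 3), nQuad = 201,
                                 shift = TRUE) {
  stopifnot(is(potential, "ToyPotential"))
  D <- ncol(potential@centers)
  if (is.vector(at)) at <- matrix(at, ncol = length(dims))
  at <- as.matrix(at)
  kT <- kBoltzmann * temperature
  rest <- setdiff(seq_len(D), dims)
  if (length(rest) == 0) {
    U <- evaluatePotential(potential, at)$energy
    Fv <- U
  } else {
    if (is.vector(range)) range <- matrix(range, length(rest), 2, byrow = TRUE)
    nodes <- lapply(seq_along(rest),
                    function(i) seq(range[i, 1], range[i, 2],
                                    length.out = nQuad))
    restGrid <- as.matrix(expand.grid(nodes))
    w <- lapply(nodes, function(x) {
      h <- diff(x)[1]
      ww <- rep(h, length(x)); ww[c(1, length(x))] <- h / 2; ww
    })
    wGrid <- Reduce(`*`, as.list(expand.grid(w)))
    Fv <- vapply(seq_len(nrow(at)), function(i) {
      pts <- matrix(0, nrow(restGrid), D)
      pts[, dims] <- matrix(at[i, ], nrow(restGrid), length(dims),
                            byrow = TRUE)
      pts[, rest] <- restGrid
      U <- evaluatePotential(potential, pts)$energy
      -kT * logSumExp(-U / kT + log(wGrid))
    }, numeric(1))
  }
  if (shift) Fv <- Fv - min(Fv)
  Fv
}

#' Well populations of a 1D toy potential by quadrature
#'
#' Boltzmann probability mass of each region of a one-dimensional potential,
#' integrating \eqn{e^{-U/k_B T}} with adaptive quadrature.  Serves as the
#' closed-form oracle for Langevin equilibrium tests.
#'
#' @param potential a one-dimensional [ToyPotential-class].
#' @param breaks numeric vector of region boundaries (including outer limits).
#' @param temperature K.
#' @return numeric vector of normalized region probabilities.
#' @export
wellPopulations <- function(potential, breaks, temperature = 298) {
  stopifnot(ncol(potential@centers) == 1)
  kT <- kBoltzmann * temperature
  f <- function(x) exp(-evaluatePotential(potential, cbind(x))$energy / kT)
  z <- vapply(seq_len(length(breaks) - 1), function(i)
    integrate(f, breaks[i], breaks[i + 1], rel.tol = 1e-10,
              subdivisions = 500L)$value, numeric(1))
  z / sum(z)
}

#' Canonical benchmark potentials
#'
#' `doubleWellPotential1D()` is a 1D double well (asymmetric by default:
#' depths 4 and 3 kcal/mol at -1 and +1 nm, widths 0.3 nm, harmonic
#' confinement 3 kcal/mol/nm^2), the workhorse for equilibrium and
#' metadynamics convergence checks.  `threeWellPotential2D()` has wells at
#' (-0.8, -0.5), (0.8, -0.5) and (0, 0.7) nm with depths 4.5/4/3.5
#' kcal/mol, widths 0.3 nm and confinement 2 kcal/mol/nm^2, giving three
#' distinct minima separated by ~3 kcal/mol saddles: the standard testbed
#' for bias-exchange free-energy recovery and path extraction.
#'
#' @return a [ToyPotential-class].
#' @export
doubleWellPotential1D <- function() {
  toyPotential(centers = rbind(-1, 1), depths = c(4, 3), widths = 0.3,
               confinement = 3)
}

#' @rdname doubleWellPotential1D
#' @export
threeWellPotential2D <- function() {
  toyPotential(centers = rbind(c(-0.8, -0.5), c(0.8, -0.5), c(0, 0.7)),
               depths = c(4.5, 4, 3.5), widths = 0.3, confinement = 2)
}
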