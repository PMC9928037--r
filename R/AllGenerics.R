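#' @name metaFES-generics
#' @title Accessor generics
#' @description Small accessor generics shared by the package's containers.
#' @param x a metaFES object.
#' @keywords internal
NULL

#' @rdname metaFES-generics
#' @export
setGeneric("freeEnergy", function(x) standardGeneric("freeEnergy"))

#' @rdname metaFES-generics
#' @export
setGeneric("binEdges", function(x) standardGeneric("binEdges"))

#' @rdname metaFES-generics
#' @export
setGeneric("binCounts", function(x) standardGeneric("binCounts"))

#' @rdname metaFES-generics
#' @export
setGeneric("barrier", function(x) standardGeneric("barrier"))

#' @rdname metaFES-generics
#' @export
setGeneric("populations", function(x) standardGeneric("populations"))

#' @rdname metaFES-generics
#' @export
setGeneric("cvValues", function(x) standardGeneric("cvValues"))

#' @rdname metaFES-generics
#' @export
setGeneric("nFrames", function(x) standardGeneric("nFrames"))

#' @rdname metaFES-generics
#' @export
setMethod("freeEnergy", "CVGrid", function(x) x@F)

#' @rdname metaFES-generics
#' @export
setMethod("freeEnergy", "Landscape2D", function(x) x@F)

#' @rdname metaFES-generics
#' @export
setMethod("freeEnergy", "FreeEnergyPath", function(x) x@F)

#' @rdname metaFES-generics
#' @export
setMethod("binEdges", "CVGrid", function(x) x@edges)

#' @rdname metaFES-generics
#' @export
setMethod("binEdges", "Landscape2D",
          function(x) list(x = x@xEdges, y = x@yEdges))

#' @rdname metaFES-generics
#' @export
setMethod("binCounts", "CVGrid", function(x) x@counts)

#' @rdname metaFES-generics
#' @export
setMethod("barrier", "FreeEnergyPath", function(x) x@barrier)

#' @rdname metaFES-generics
#' @export
setMethod("populations", "MaxEntResult", function(x) x@populations)

#' @rdname metaFES-generics
#' @export
setMethod("cvValues", "ReplicaTrajectory", function(x) x@cv)

#' @rdname metaFES-generics
#' @export
setMethod("nFrames", "ReplicaTrajectory", function(x) length(x@time))

#' @rdname metaFES-generics
#' @export
setMethod("nFrames", "WeightedEnsemble", function(x) length(x@weights))

#' Weights of a WeightedEnsemble
#' @param object a [WeightedEnsemble-class].
#' @param ... ignored.
#' @return numeric vector of normalized frame weights.
#' @export
setMethod("weights", "WeightedEnsemble", function(object, ...) object@weights)

setMethod("show", "ToyPotential", function(object) {
  cat(sprintf("ToyPotential: %d well(s) in %d dimension(s)\n",
              nrow(object@centers), ncol(object@centers)))
  if (any(object@confinement > 0))
    cat(sprintf("  harmonic confinement k = %s kcal/mol/nm^2\n",
                paste(signif(object@confinement, 3), collapse = ", ")))
})

setMethod("show", "ReplicaTrajectory", function(object) {
  cat(sprintf(
    "ReplicaTrajectory %d: %d frames, %d CV(s), biased on {%s}, T = %g K\n",
    object@replicaId, length(object@time), ncol(object@cv),
    paste(object@biasedCVs, collapse = ","), object@temperature))
  cat(sprintf("  %d hill(s) deposited\n", nrow(object@hills)))
})

setMethod("show", "CVGrid", function(object) {
  dims <- vapply(object@edges, function(e) length(e) - 1L, integer(1))
  fin <- sum(is.finite(object@F))
  cat(sprintf("CVGrid over %s: %s bins, %d visited, %d with finite F\n",
              paste(object@cvNames, collapse = " x "),
              paste(dims, collapse = " x "),
              sum(object@counts > 0), fin))
  if (object@outside > 0)
    cat(sprintf("  %d frame(s) fell outside the grid\n", object@outside))
})

setMethod("show", "WeightedEnsemble", function(object) {
  cat(sprintf("WeightedEnsemble: %d frames (%d excluded)\n",
              length(object@weights), object@nExcluded))
  if (length(object@weights)) {
    ess <- 1 / sum(object@weights^2)
    cat(sprintf("  effective sample size %.1f (%.1f%%)\n", ess,
                100 * ess / length(object@weights)))
  }
})

setMethod("show", "StructureFrame", function(object) {
  cat(sprintf("StructureFrame: %d atoms in %d residues, %d water oxygen(s), %d ion(s)\n",
              nrow(object@atoms), length(unique(object@atoms$resid)),
              nrow(object@waters), nrow(object@ions)))
})

setMethod("show", "Landscape2D", function(object) {
  cat(sprintf("Landscape2D %s vs %s: %d x %d bins, %d finite\n",
              object@xName, object@yName, nrow(object@F), ncol(object@F),
              sum(is.finite(object@F))))
  fin <- object@F[is.finite(object@F)]
  if (length(fin))
    cat(sprintf("  F range 0 - %.2f kcal/mol (contours every %g)\n",
                max(fin), object@contourInterval))
})

setMethod("show", "FreeEnergyPath", function(object) {
  cat(sprintf("FreeEnergyPath %s -> %s: %d steps, barrier %.3f kcal/mol\n",
              object@endpointLabels[1], object@endpointLabels[2],
              nrow(object@bins), object@barrier))
})

setMethod("show", "MaxEntResult", function(object) {
  cat(sprintf("MaxEntResult: gamma = %g, KL = %.4g, MSD = %.4g, %s in %d it.\n",
              object@gamma, object@kl, object@msd,
              if (object@converged) "converged" else "NOT converged",
              object@iterations))
  if (length(object@populations))
    cat("  populations:",
        paste(sprintf("%s = %.3f", names(object@populations),
                      object@populations), collapse = ", "), "\n")
  if (length(object@rho))
    cat("  back-exchange retention:",
        paste(sprintf("%s = %.3f", names(object@rho), object@rho),
              collapse = ", "), "\n")
})
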