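## Collective variables evaluated on StructureFrame objects: path variables
## built on mean-square differences to reference structures, binding-site
## hydration variables, contact counts, and water-accessibility counts.

#' Select atom coordinates from a StructureFrame
#'
#' @param frame a [StructureFrame-class].
#' @param selection data.frame with columns `resid` and `name`; see
#'   [atomSelection()].
#' @return numeric matrix (atoms x 3) in selection order, nm.
#' @export
selectAtoms <- function(frame, selection) {
  at <- frame@atoms
  key <- paste(at$resid, at$name)
  want <- paste(selection$resid, selection$name)
  idx <- match(want, key)
  if (anyNA(idx))
    stop("selection atoms missing from frame: ",
         paste(want[is.na(idx)], collapse = ", "))
  as.matrix(at[idx, c("x", "y", "z")])
}

#' Build an atom selection
#'
#' @param resids integer residue indices (1-based).
#' @param names atom names, recycled over `resids` (default `"CA"`).
#' @return data.frame usable as the `selection` of CV definitions.
#' @export
atomSelection <- function(resids, names = "CA") {
  data.frame(resid = as.integer(resids),
             name = rep_len(names, length(resids)))
}

#' Optimal rigid-body superposition (Kabsch)
#'
#' Finds the translation and proper rotation of `X` that minimize the mean
#' square deviation to `Y`, via the SVD of the covariance matrix with the
#' usual sign correction so the rotation has determinant +1.  With fewer
#' than 3 atoms, or a (near-)collinear selection, a proper rotation is not
#' determined; the function then falls back to translation-only and flags
#' it via the `degenerate` attribute.
#'
#' @param X,Y numeric n x 3 matrices (moving, target).
#' @return transformed copy of `X` with attribute `degenerate` (logical).
#' @export
kabschSuperpose <- function(X, Y) {
  stopifnot(nrow(X) == nrow(Y), ncol(X) == 3, ncol(Y) == 3)
  cx <- colMeans(X); cy <- colMeans(Y)
  X0 <- sweep(X, 2, cx); Y0 <- sweep(Y, 2, cy)
  degenerate <- FALSE
  if (nrow(X) < 3) {
    degenerate <- TRUE
    R <- diag(3)
  } else {
    H <- crossprod(X0, Y0)
    s <- svd(H)
    # rank < 2 => atoms (near-)collinear: rotation underdetermined
    if (s$d[2] < 1e-10 * max(s$d[1], 1e-300)) {
      degenerate <- TRUE
      R <- diag(3)
    } else {
      d <- sign(det(s$v %*% t(s$u)))
      R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
    }
  }
  out <- sweep(X0 %*% t(R), 2, cy, `+`)
  attr(out, "degenerate") <- degenerate
  out
}

#' Mean-square difference to a reference structure
#'
#' The structural-similarity metric underlying the path variables: the mean
#' of squared atomic deviations (nm^2) over a selection, optionally after
#' optimal rigid-body superposition of the frame onto the reference using
#' the same selection.
#'
#' @param frame,reference [StructureFrame-class] objects.
#' @param selection atom selection data.frame ([atomSelection()]).
#' @param superpose superpose before averaging (default `TRUE`).
#' @return MSD in nm^2, with attribute `degenerate` if the superposition
#'   fell back to translation-only.
#' @export
msdToReference <- function(frame, reference, selection, superpose = TRUE) {
  X <- selectAtoms(frame, selection)
  Y <- selectAtoms(reference, selection)
  degenerate <- FALSE
  if (superpose) {
    X <- kabschSuperpose(X, Y)
    degenerate <- attr(X, "degenerate")
    if (degenerate)
      warning("degenerate superposition: fell back to translation-only")
  }
  out <- mean(rowSums((X - Y)^2))
  attr(out, "degenerate") <- degenerate
  out
}

#' Path collective-variable definition
#'
#' Parameterizes a progress variable between two (or three) reference
#' structures: \eqn{\xi = \sum_k k e^{-\lambda d_k} / \sum_k e^{-\lambda
#' d_k}} with \eqn{d_k} the MSD (nm^2) of the frame to reference k over the
#' given atom selection.  Values lie strictly inside (1, 2) for two
#' references and (1, 3) for three.  For two references, if `lambda` is not
#' given it is set proportional to the inverse of the inter-reference MSD
#' \eqn{d_{12}} (`lambda = c / d12`, default `c = 2.3`), so the switch
#' between states stays sharp regardless of how far apart the references
#' are.
#'
#' @param selection atom selection data.frame.
#' @param references list of 2 or 3 [StructureFrame-class] objects.
#' @param lambda smoothing parameter, 1/nm^2; `NULL` derives it from d12
#'   (two-reference case only).
#' @param lambdaScale the proportionality constant `c` when `lambda` is
#'   derived.
#' @param superpose superpose before each MSD (default `TRUE`).
#' @return a `PathCVDefinition` list.
#' @export
pathCVDefinition <- function(selection, references, lambda = NULL,
                             lambdaScale = 2.3, superpose = TRUE) {
  stopifnot(length(references) %in% c(2L, 3L))
  for (r in references) stopifnot(is(r, "StructureFrame"))
  if (is.null(lambda)) {
    if (length(references) != 2)
      stop("automatic lambda from d12 requires exactly two references")
    d12 <- as.numeric(msdToReference(references[[1]], references[[2]],
                                     selection, superpose))
    lambda <- lambdaScale / d12
  }
  stopifnot(lambda > 0)
  structure(list(selection = selection, references = references,
                 lambda = lambda, superpose = superpose),
            class = "PathCVDefinition")
}

#' Path value from structural distances
#'
#' The closed form \eqn{\sum_k k e^{-\lambda d_k} / \sum_k e^{-\lambda
#' d_k}}, computed with max-subtraction so large \eqn{\lambda d} cannot
#' overflow.  Exposed separately so the algebra can be exercised directly
#' on given distances.
#'
#' @param d numeric vector of 2 or 3 squared-deviation values, nm^2.
#' @param lambda smoothing parameter, 1/nm^2.
#' @return dimensionless path value in (1, length(d)).
#' @export
pathValue <- function(d, lambda) {
  if (!all(is.finite(d))) stop("non-finite structural distances")
  a <- -lambda * d
  a <- a - max(a)
  e <- exp(a)
  sum(seq_along(d) * e) / sum(e)
}

.pathCV <- function(frame, definition, nref) {
  stopifnot(inherits(definition, "PathCVDefinition"))
  if (length(definition$references) != nref)
    stop("definition must have exactly ", nref, " references")
  d <- vapply(definition$references, function(ref)
    as.numeric(msdToReference(frame, ref, definition$selection,
                              definition$superpose)), numeric(1))
  pathValue(d, definition$lambda)
}

#' Two-state path collective variable
#'
#' Progress between two reference structures; ~1 near the first reference,
#' ~2 near the second.
#'
#' @param frame a [StructureFrame-class].
#' @param definition a two-reference [pathCVDefinition()].
#' @return dimensionless value in (1, 2).
#' @export
pathCVTwoState <- function(frame, definition) .pathCV(frame, definition, 2L)

#' Three-state path collective variable
#'
#' Progress across three progressively different reference structures
#' (e.g. closed, ajar, open); ranges over (1, 3).
#'
#' @param frame a [StructureFrame-class].
#' @param definition a three-reference [pathCVDefinition()].
#' @return dimensionless value in (1, 3).
#' @export
pathCVThreeState <- function(frame, definition) .pathCV(frame, definition, 3L)

#' Hydration-site definition
#'
#' The centre of the site is either a named ion present in the frame or the
#' centre of mass of a set of coordinating protein oxygen atoms (used when
#' the site is empty).
#'
#' @param ion character name of an ion (rowname of the frame's `ions`), or
#'   `NULL`.
#' @param oxygenSelection atom selection of coordinating protein oxygens
#'   (used when `ion` is `NULL`).
#' @param beta smoothing length, nm (default 10).
#' @return a `HydrationSiteDefinition` list.
#' @export
hydrationSite <- function(ion = NULL, oxygenSelection = NULL, beta = 10) {
  stopifnot(beta > 0, !is.null(ion) || !is.null(oxygenSelection))
  structure(list(ion = ion, oxygenSelection = oxygenSelection, beta = beta),
            class = "HydrationSiteDefinition")
}

#' Binding-site hydration collective variable
#'
#' \eqn{\xi = \beta \ln \sum_j e^{\beta / r_j}} over all water oxygens j,
#' with \eqn{r_j} the distance (nm) from the site centre.  Dominated by the
#' closest water, the variable grows as \eqn{\beta^2 / r_{min}}; it is
#' computed with log-sum-exp so near waters cannot overflow.
#'
#' @param frame a [StructureFrame-class] with at least one water oxygen.
#' @param site a [hydrationSite()].
#' @return hydration value, nm.
#' @export
hydrationCV <- function(frame, site) {
  stopifnot(inherits(site, "HydrationSiteDefinition"))
  if (nrow(frame@waters) == 0) stop("no water oxygens in frame")
  if (!is.null(site$ion)) {
    if (!site$ion %in% rownames(frame@ions))
      stop("ion '", site$ion, "' not present in frame")
    center <- frame@ions[site$ion, ]
  } else {
    center <- colMeans(selectAtoms(frame, site$oxygenSelection))
  }
  r <- sqrt(rowSums(sweep(frame@waters, 2, center)^2))
  if (any(r < 1e-12)) stop("water oxygen coincides with the site center")
  site$beta * logSumExp(site$beta / r)
}

#' Rational switching function for contact counting
#'
#' \eqn{s(r) = [1-(r/r_0)^4] / [1-(r/r_0)^8]}, evaluated in the
#' algebraically equivalent factored form \eqn{1 / [1+(r/r_0)^4]} so the
#' removable singularity at \eqn{r = r_0} (where s = 1/2) needs no special
#' casing.  The literal rational form is kept for cross-checks.
#'
#' @param r distance(s), nm.
#' @param r0 contact distance, nm (default 0.7).
#' @param form `"factored"` (default) or `"literal"`.
#' @return switching values in (0, 1].
#' @export
switchingFunction <- function(r, r0 = 0.7, form = c("factored", "literal")) {
  form <- match.arg(form)
  q <- (r / r0)^4
  if (form == "factored") 1 / (1 + q) else (1 - q) / (1 - q^2)
}

#' Contact-count descriptor
#'
#' @param residuesA,residuesB disjoint 1-based residue index sets.
#' @param r0 contact distance, nm (default 0.7).
#' @return a `ContactDescriptor` list (CA-CA distances).
#' @export
contactDescriptor <- function(residuesA, residuesB, r0 = 0.7) {
  stopifnot(r0 > 0)
  if (length(intersect(residuesA, residuesB)) > 0)
    stop("residue sets must be disjoint")
  structure(list(residuesA = as.integer(residuesA),
                 residuesB = as.integer(residuesB), r0 = r0),
            class = "ContactDescriptor")
}

#' Soft count of residue-residue contacts
#'
#' Sums the rational switching function over all CA-CA pairs between two
#' residue sets: \eqn{S_C = \sum_{i \in A, j \in B} s(r_{ij})}.
#'
#' @param frame a [StructureFrame-class] with CA atoms for every listed
#'   residue.
#' @param descriptor a [contactDescriptor()].
#' @return dimensionless contact count, >= 0.
#' @export
contactCount <- function(frame, descriptor) {
  stopifnot(inherits(descriptor, "ContactDescriptor"))
  A <- selectAtoms(frame, atomSelection(descriptor$residuesA))
  B <- selectAtoms(frame, atomSelection(descriptor$residuesB))
  d2 <- outer(rowSums(A^2), rowSums(B^2), `+`) - 2 * A %*% t(B)
  r <- sqrt(pmax(d2, 0))
  sum(switchingFunction(r, descriptor$r0))
}

#' Water molecules near a residue
#'
#' Counts water oxygens within `cutoff` of any atom of the residue, the
#' per-frame ingredient of solvent-accessibility profiles (ensemble means
#' are taken downstream with [reweightedAverage()]).
#'
#' @param frame a [StructureFrame-class].
#' @param residue 1-based residue index.
#' @param cutoff nm; default 0.42.
#' @return integer count.
#' @export
waterAccessibilityCount <- function(frame, residue, cutoff = 0.42) {
  at <- frame@atoms[frame@atoms$resid == residue, c("x", "y", "z")]
  if (nrow(at) == 0) stop("residue ", residue, " not present in frame")
  if (nrow(frame@waters) == 0) return(0L)
  X <- as.matrix(at)
  W <- frame@waters
  d2 <- outer(rowSums(W^2), rowSums(X^2), `+`) - 2 * W %*% t(X)
  sum(apply(d2, 1, min) <= cutoff^2)
}

#' Evaluate a collective variable on one frame
#'
#' Dispatches on the definition type: path definitions, hydration sites,
#' contact descriptors, or a plain `function(frame)`.
#'
#' @param frame a [StructureFrame-class].
#' @param definition a CV definition object.
#' @return scalar CV value.
#' @export
evaluateCV <- function(frame, definition) {
  if (inherits(definition, "PathCVDefinition"))
    .pathCV(frame, definition, length(definition$references))
  else if (inherits(definition, "HydrationSiteDefinition"))
    hydrationCV(frame, definition)
  else if (inherits(definition, "ContactDescriptor"))
    contactCount(frame, definition)
  else if (is.function(definition))
    definition(frame)
  else stop("unknown CV definition of class ", class(definition)[1])
}

#' Evaluate a table of collective variables over an ensemble
#'
#' One row per frame, one column per definition (in the given order), plus
#' a leading `frame` index column.  Per-frame failures are re-signalled
#' with the frame index attached.
#'
#' @param frames list of [StructureFrame-class] objects.
#' @param definitions named list of CV definitions ([pathCVDefinition()],
#'   [hydrationSite()], [contactDescriptor()] or functions).
#' @return data.frame of CV records.
#' @export
evaluateCVTable <- function(frames, definitions) {
  nm <- names(definitions)
  if (is.null(nm) || any(nm == ""))
    nm <- paste0("cv", seq_along(definitions))
  out <- matrix(NA_real_, length(frames), length(definitions),
                dimnames = list(NULL, nm))
  for (i in seq_along(frames)) {
    for (j in seq_along(definitions)) {
      out[i, j] <- tryCatch(evaluateCV(frames[[i]], definitions[[j]]),
                            error = function(e)
                              stop("frame ", i, ", CV '", nm[j], "': ",
                                   conditionMessage(e), call. = FALSE))
    }
  }
  cbind(data.frame(frame = seq_along(frames)), as.data.frame(out))
}
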