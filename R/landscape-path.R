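## 2D landscape projection with block error maps, and minimax minimum
## free-energy paths on binned grids.

.landscapeF <- function(x, y, w, xEdges, yEdges, kT) {
  ix <- .binIndex1D(x, xEdges)
  iy <- .binIndex1D(y, yEdges)
  nx <- length(xEdges) - 1L; ny <- length(yEdges) - 1L
  ok <- ix > 0L & iy > 0L
  W <- matrix(0, nx, ny)
  if (any(ok)) {
    lin <- ix[ok] + nx * (iy[ok] - 1L)
    acc <- rowsum(w[ok], lin)
    W[as.integer(rownames(acc))] <- acc[, 1]
  }
  Fm <- -kT * log(W)
  Fm[W <= 0] <- Inf
  fin <- Fm[is.finite(Fm)]
  if (length(fin)) Fm <- Fm - min(fin)
  list(F = Fm, mass = W, nOutside = sum(!ok))
}

#' Project a weighted ensemble onto two descriptors
#'
#' Builds the Fig.-style 2D free-energy landscape
#' \eqn{F(x, y) = -k_B T \ln \sum_{i \in bin} w_i}, min-shifted to 0, with
#' `Inf` on empty bins.
#'
#' @param ensemble a [WeightedEnsemble-class].
#' @param x,y numeric per-frame descriptor values (e.g. contact counts),
#'   same order as the ensemble's frames.
#' @param xEdges,yEdges bin-edge vectors.
#' @param xName,yName descriptor names.
#' @param temperature K.
#' @param contourInterval kcal/mol, stored for exporters (default 1).
#' @return a [Landscape2D-class].
#' @export
projectLandscape2D <- function(ensemble, x, y, xEdges, yEdges,
                               xName = "x", yName = "y", temperature = 298,
                               contourInterval = 1) {
  n <- nFrames(ensemble)
  stopifnot(length(x) == n, length(y) == n)
  kT <- kBoltzmann * temperature
  ls <- .landscapeF(x, y, ensemble@weights, xEdges, yEdges, kT)
  if (sum(ls$mass > 0) == 1)
    warning("degenerate landscape: all weight falls in a single bin")
  new("Landscape2D", xName = xName, yName = yName, xEdges = xEdges,
      yEdges = yEdges, F = ls$F,
      stderr = matrix(NA_real_, nrow(ls$F), ncol(ls$F)),
      contourInterval = contourInterval)
}

#' Block standard-error map for a 2D landscape
#'
#' Splits the ensemble into `nBlocks` contiguous blocks, recomputes the
#' landscape per block (block weights renormalized), and reports the
#' per-bin standard error of F across blocks on bins finite in every
#' block; other bins are `NA`.
#'
#' @inheritParams projectLandscape2D
#' @param landscape optionally, the [Landscape2D-class] whose `stderr` to
#'   fill; otherwise a full-data landscape is computed.
#' @param nBlocks number of contiguous blocks, >= 2 (default 10).
#' @return a [Landscape2D-class] with the `stderr` slot filled.
#' @export
blockErrorMap <- function(ensemble, x, y, xEdges, yEdges, nBlocks = 10L,
                          temperature = 298, landscape = NULL) {
  stopifnot(nBlocks >= 2)
  n <- nFrames(ensemble)
  kT <- kBoltzmann * temperature
  if (is.null(landscape))
    landscape <- projectLandscape2D(ensemble, x, y, xEdges, yEdges,
                                    temperature = temperature)
  blk <- cut(seq_len(n), nBlocks, labels = FALSE)
  w <- ensemble@weights
  Fs <- lapply(seq_len(nBlocks), function(b) {
    i <- blk == b
    wb <- w[i]
    if (sum(wb) <= 0) stop("block ", b, " has zero total weight")
    .landscapeF(x[i], y[i], wb / sum(wb), xEdges, yEdges, kT)$F
  })
  arr <- simplify2array(Fs)  # nx x ny x nBlocks
  finiteAll <- apply(is.finite(arr), c(1, 2), all)
  se <- matrix(NA_real_, nrow(landscape@F), ncol(landscape@F))
  se[finiteAll] <- apply(arr, c(1, 2), sd)[finiteAll] / sqrt(nBlocks)
  landscape@stderr <- se
  landscape
}

.neighbours <- function(ind, dims) {
  nd <- length(dims)
  out <- matrix(rep(ind, 2L * nd), ncol = nd, byrow = TRUE)
  k <- 0L
  res <- list()
  for (d in seq_len(nd)) for (s in c(-1L, 1L)) {
    nb <- ind
    nb[d] <- nb[d] + s
    if (nb[d] >= 1L && nb[d] <= dims[d]) res[[length(res) + 1L]] <- nb
  }
  do.call(rbind, res)
}

#' Minimax minimum free-energy path on a grid
#'
#' Finds the path between two bins, moving only across bin faces (no
#' diagonals), that minimizes the maximum free energy encountered; ties in
#' that bottleneck value are broken by the smaller cumulative
#' \eqn{\sum e^{F / k_B T}} along the path.  The barrier is the maximum F
#' on the path minus F at the start, and the saddle is the bin where that
#' maximum occurs.  The minimax criterion depends only on the ordering of
#' F values, so the barrier is invariant under monotone transformations
#' of F.
#'
#' @param grid a [CVGrid-class] with `F` estimated.
#' @param startBin,endBin integer vectors of per-dimension bin indices.
#' @param temperature K (enters only the tie-break sum).
#' @param labels endpoint labels, e.g. `c("OF", "IF")`.
#' @return a [FreeEnergyPath-class].
#' @export
minimumFreeEnergyPath <- function(grid, startBin, endBin, temperature = 298,
                                  labels = c("start", "end")) {
  dims <- dim(grid@counts)
  nd <- length(dims)
  stopifnot(length(startBin) == nd, length(endBin) == nd)
  kT <- kBoltzmann * temperature
  Flin <- as.numeric(grid@F)
  mult <- cumprod(c(1L, dims[-nd]))
  linOf <- function(ind) as.integer(1L + (ind - 1L) %*% mult)
  s <- linOf(matrix(startBin, 1)); e <- linOf(matrix(endBin, 1))
  if (!is.finite(Flin[s]) || !is.finite(Flin[e]))
    stop("start and end bins must have finite free energy")
  fref <- max(Flin[is.finite(Flin)])
  tie <- exp((Flin - fref) / kT)  # overflow-safe tie-break increments

  nbin <- prod(dims)
  bott <- rep(Inf, nbin)   # minimax value to reach each bin
  cum <- rep(Inf, nbin)    # tie-break sum along the chosen path
  pred <- rep(NA_integer_, nbin)
  done <- logical(nbin)
  bott[s] <- Flin[s]
  cum[s] <- tie[s]
  repeat {
    cand <- which(!done & is.finite(bott))
    if (!length(cand)) break
    u <- cand[order(bott[cand], cum[cand])[1]]
    if (u == e) break
    done[u] <- TRUE
    nbs <- .neighbours(arrayInd(u, dims)[1, ], dims)
    for (r in seq_len(nrow(nbs))) {
      v <- linOf(nbs[r, , drop = FALSE])
      if (done[v] || !is.finite(Flin[v])) next
      nb2 <- max(bott[u], Flin[v])
      nc <- cum[u] + tie[v]
      if (nb2 < bott[v] || (nb2 == bott[v] && nc < cum[v])) {
        bott[v] <- nb2; cum[v] <- nc; pred[v] <- u
      }
    }
  }
  if (!is.finite(bott[e]))
    stop("endpoints are not connected through finite-F bins")
  path <- e
  while (path[1] != s) path <- c(pred[path[1]], path)
  bins <- arrayInd(path, dims)
  centers <- lapply(grid@edges, function(ed) (ed[-1] + ed[-length(ed)]) / 2)
  mid <- vapply(seq_len(nd), function(d) centers[[d]][bins[, d]],
                numeric(nrow(bins)))
  if (!is.matrix(mid)) mid <- matrix(mid, ncol = nd)
  Fpath <- Flin[path]
  arc <- if (nrow(mid) > 1) {
    seg <- matrix(diff(mid), ncol = nd)
    c(0, cumsum(sqrt(rowSums(seg^2))))
  } else 0
  if (max(arc) > 0) arc <- arc / max(arc)
  imax <- which.max(Fpath)
  new("FreeEnergyPath", bins = bins, midpoints = mid, arcLength = arc,
      F = Fpath, barrier = max(Fpath) - Fpath[1],
      saddle = as.integer(bins[imax, ]), endpointLabels = labels)
}

#' Free-energy profile along a path with intermediates
#'
#' Returns F against the normalized arc length of the path in CV space and
#' reports strict local minima between the endpoints as metastable
#' intermediates, each with its depth relative to the lower of the two
#' flanking maxima.
#'
#' @param path a [FreeEnergyPath-class].
#' @return list with `profile` (data.frame: progress, F) and
#'   `intermediates` (data.frame: index, progress, F, depth).
#' @export
pathProfile <- function(path) {
  Fv <- path@F
  n <- length(Fv)
  prof <- data.frame(progress = path@arcLength, F = Fv)
  ints <- data.frame(index = integer(0), progress = numeric(0),
                     F = numeric(0), depth = numeric(0))
  if (n >= 3) {
    for (i in 2:(n - 1)) {
      if (Fv[i] < Fv[i - 1] && Fv[i] < Fv[i + 1]) {
        maxL <- max(Fv[1:i])
        maxR <- max(Fv[i:n])
        ints <- rbind(ints, data.frame(
          index = i, progress = path@arcLength[i], F = Fv[i],
          depth = min(maxL, maxR) - Fv[i]))
      }
    }
  }
  list(profile = prof, intermediates = ints)
}
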