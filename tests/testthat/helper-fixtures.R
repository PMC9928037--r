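# Shared fixtures.  Expensive simulations are run once per session and
# memoized here.

.fixtures <- new.env(parent = emptyenv())

# converged 1D metadynamics on the canonical double well: several
# independent runs pooled into one binned mean-force estimate
meta1DRun <- function() {
  if (is.null(.fixtures$meta1d)) {
    pot <- doubleWellPotential1D()
    trs <- lapply(1:16, function(s)
      langevinSimulate(pot, start = -1, nSteps = 250000,
                       bias = metadSchedule(1, height = 0.1, sigma = 0.1,
                                            pace = 200),
                       seed = 100 + s, recordStride = 10, replicaId = s))
    edges <- gridEdges(-2, 2, 50)
    grid <- assignBins(trs, edges)
    grid <- estimateMeanForces(trs, grid, discardFraction = 0.4)
    gridF <- integrateMeanForces(grid)
    .fixtures$meta1d <- list(pot = pot, trs = trs, edges = edges,
                             grid = grid, gridF = gridF)
  }
  .fixtures$meta1d
}

# 4-replica bias-exchange run on the canonical 2D three-well potential
bex2DRun <- function() {
  if (is.null(.fixtures$bex2d)) {
    pot <- threeWellPotential2D()
    sch <- function() metadSchedule(1:2, height = 0.12, sigma = 0.15,
                                    pace = 250)
    set.seed(5)
    bex <- runBiasExchange(
      pot, list(sch(), sch(), sch(), NULL),
      starts = rbind(c(-0.8, -0.5), c(0.8, -0.5), c(0, 0.7), c(-0.8, -0.5)),
      nSteps = 400000, exchangeInterval = 500, recordStride = 10)
    edges <- gridEdges(c(-1.8, -1.8), c(1.8, 1.8), 36)
    grid <- assignBins(bex$trajectories, edges)
    grid <- estimateMeanForces(bex$trajectories, grid, discardFraction = 0.4)
    grid <- integrateMeanForces(grid)
    ensemble <- frameWeights(grid, bex$trajectories, discardFraction = 0.4)
    .fixtures$bex2d <- list(pot = pot, bex = bex, edges = edges,
                            grid = grid, ensemble = ensemble)
  }
  .fixtures$bex2d
}

# per-frame values of one CV for the frames retained in a weighted ensemble
frameCVValues <- function(ensemble, trajectories, cvIndex) {
  byId <- setNames(trajectories, vapply(trajectories, function(t)
    as.character(t@replicaId), character(1)))
  vapply(seq_len(nFrames(ensemble)), function(i)
    byId[[as.character(ensemble@frames$replica[i])]]@cv[
      ensemble@frames$frame[i], cvIndex], numeric(1))
}

# exact 2D reference surface of a potential on bin centres (min-shifted)
referenceSurface2D <- function(pot, edges) {
  cx <- (edges[[1]][-1] + edges[[1]][-length(edges[[1]])]) / 2
  cy <- (edges[[2]][-1] + edges[[2]][-length(edges[[2]])]) / 2
  FU <- outer(cx, cy, function(a, b)
    evaluatePotential(pot, cbind(as.vector(a), as.vector(b)))$energy)
  FU - min(FU)
}

# tiny hand-made structure: nRes residues on a line, optional waters
lineFrame <- function(nRes = 4, spacing = 0.4, waters = NULL) {
  atoms <- data.frame(resid = seq_len(nRes), name = "CA",
                      x = spacing * (seq_len(nRes) - 1), y = 0, z = 0)
  if (is.null(waters)) waters <- matrix(numeric(0), 0, 3)
  structureFrame(atoms, waters = waters)
}

# random rigid motion applied to every coordinate of a frame
rigidMove <- function(frame, angle = 0.7, axis = c(0, 0, 1),
                      shift = c(0.3, -0.2, 0.5)) {
  axis <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, -axis[3], axis[2], axis[3], 0, -axis[1],
                -axis[2], axis[1], 0), 3, 3, byrow = TRUE)
  R <- diag(3) + sin(angle) * K + (1 - cos(angle)) * K %*% K
  mv <- function(m) sweep(as.matrix(m) %*% t(R), 2, shift, `+`)
  at <- frame@atoms
  at[, c("x", "y", "z")] <- mv(at[, c("x", "y", "z")])
  w <- frame@waters
  if (nrow(w) > 0) w <- mv(w)
  io <- frame@ions
  if (nrow(io) > 0) io <- mv(io)
  structureFrame(at, waters = w, ions = io)
}

# exhaustive minimax-path oracle by DFS over all simple paths (tiny grids)
bruteForceMinimax <- function(Fmat, start, end) {
  dims <- dim(Fmat)
  best <- list(bottleneck = Inf)
  visit <- function(pos, seen, curMax) {
    if (curMax >= best$bottleneck && !all(pos == end)) return(invisible())
    if (all(pos == end)) {
      if (curMax < best$bottleneck)
        best <<- list(bottleneck = curMax)
      return(invisible())
    }
    for (d in 1:2) for (s in c(-1L, 1L)) {
      nb <- pos; nb[d] <- nb[d] + s
      if (nb[1] < 1 || nb[1] > dims[1] || nb[2] < 1 || nb[2] > dims[2])
        next
      key <- nb[1] + dims[1] * (nb[2] - 1)
      if (seen[key] || !is.finite(Fmat[nb[1], nb[2]])) next
      seen[key] <- TRUE
      visit(nb, seen, max(curMax, Fmat[nb[1], nb[2]]))
      seen[key] <- FALSE
    }
  }
  seen <- logical(prod(dims))
  seen[start[1] + dims[1] * (start[2] - 1)] <- TRUE
  visit(start, seen, Fmat[start[1], start[2]])
  best$bottleneck
}

# exact threshold-connectivity oracle for the minimax bottleneck: the
# smallest F level at which start and end are connected through bins <= level
thresholdMinimax <- function(Fmat, start, end) {
  dims <- dim(Fmat)
  lin <- function(p) p[1] + dims[1] * (p[2] - 1)
  levels <- sort(unique(as.numeric(Fmat[is.finite(Fmat)])))
  levels <- levels[levels >= max(Fmat[start[1], start[2]],
                                 Fmat[end[1], end[2]])]
  for (lev in levels) {
    open <- is.finite(Fmat) & Fmat <= lev
    if (!open[start[1], start[2]] || !open[end[1], end[2]]) next
    # BFS flood fill
    q <- list(start)
    seen <- matrix(FALSE, dims[1], dims[2])
    seen[start[1], start[2]] <- TRUE
    while (length(q)) {
      p <- q[[1]]; q <- q[-1]
      if (all(p == end)) return(lev)
      for (d in 1:2) for (s in c(-1L, 1L)) {
        nb <- p; nb[d] <- nb[d] + s
        if (nb[1] < 1 || nb[1] > dims[1] || nb[2] < 1 || nb[2] > dims[2])
          next
        if (seen[nb[1], nb[2]] || !open[nb[1], nb[2]]) next
        seen[nb[1], nb[2]] <- TRUE
        q[[length(q) + 1]] <- nb
      }
    }
  }
  Inf
}

# wrap a 2D F matrix into a CVGrid for path tests
gridFromF <- function(Fmat, lo = c(0, 0), hi = dim(Fmat) / 10) {
  edges <- gridEdges(lo, hi, dim(Fmat))
  g <- new("CVGrid", edges = edges,
           cvNames = c("x", "y"),
           counts = array(1L, dim = dim(Fmat)), F = array(Fmat, dim(Fmat)),
           meanForce = rep(list(array(NA_real_, dim(Fmat))), 2),
           forceCount = rep(list(array(0L, dim(Fmat))), 2),
           minCount = 1L, outside = 0L,
           metadata = list(cvSubset = 1:2))
  g
}
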