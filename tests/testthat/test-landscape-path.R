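mkEnsemble <- function(w) {
  new("WeightedEnsemble",
      frames = data.frame(replica = 1L, frame = seq_along(w)),
      weights = w / sum(w), nExcluded = 0L)
}

test_that("2D projection: flat, ratio identity, shift invariance", {
  # one frame per bin, uniform weights -> flat F = 0
  en <- mkEnsemble(rep(1, 4))
  x <- c(0.25, 0.75, 0.25, 0.75); y <- c(0.25, 0.25, 0.75, 0.75)
  ed <- seq(0, 1, by = 0.5)
  ls <- projectLandscape2D(en, x, y, ed, ed)
  expect_true(all(ls@F == 0))
  # weight ratio 2:1 -> delta F = kT ln 2 = 0.4108 kcal/mol at 298 K
  en2 <- mkEnsemble(c(2, 1))
  ls2 <- projectLandscape2D(en2, c(0.25, 0.75), c(0.25, 0.25), ed, ed)
  expect_equal(ls2@F[2, 1] - ls2@F[1, 1], kBoltzmann * 298 * log(2),
               tolerance = 1e-12)
  expect_equal(kBoltzmann * 298 * log(2), 0.4108, tolerance = 1e-3)
  expect_true(all(is.infinite(ls2@F[, 2])))
  # degenerate landscape is flagged
  expect_warning(projectLandscape2D(mkEnsemble(c(1, 1)), c(0.2, 0.2),
                                    c(0.2, 0.2), ed, ed), "degenerate")
})

test_that("unbiased sampling of a shallow 2D toy reproduces its surface", {
  # shallow wells so unbiased dynamics crosses between basins many times
  pot <- toyPotential(centers = rbind(c(-0.8, -0.5), c(0.8, -0.5),
                                      c(0, 0.7)),
                      depths = c(2.2, 2, 1.8), widths = 0.3,
                      confinement = 2)
  tr <- langevinSimulate(pot, c(-0.8, -0.5), 400000, friction = 0.5,
                         seed = 19, recordStride = 10)
  n <- nFrames(tr)
  en <- new("WeightedEnsemble",
            frames = data.frame(replica = 1L, frame = seq_len(n)),
            weights = rep(1 / n, n), nExcluded = 0L)
  ed <- gridEdges(c(-1.8, -1.8), c(1.8, 1.8), 36)
  ls <- projectLandscape2D(en, tr@cv[, 1], tr@cv[, 2], ed[[1]], ed[[2]])
  FU <- referenceSurface2D(pot, ed)
  ok <- is.finite(ls@F) & FU < 2  # basins well sampled without bias
  expect_gt(sum(ok), 50)
  expect_lt(sqrt(mean((ls@F[ok] - FU[ok])^2)), 0.3)
})

test_that("block error maps: identical blocks give zero, two blocks give d/2", {
  ed <- seq(0, 1, by = 0.5)
  # identical blocks: same frames repeated
  en <- mkEnsemble(rep(1, 8))
  x <- rep(c(0.25, 0.75), 4); y <- rep(0.25, 8)
  ls <- blockErrorMap(en, x, y, ed, ed, nBlocks = 4)
  expect_true(all(ls@stderr[is.finite(ls@F)] == 0))
  # two blocks whose per-bin F differ by d -> error d / 2
  w <- c(3, 1, 1, 1) / 6
  en2 <- mkEnsemble(w)
  x2 <- c(0.25, 0.75, 0.25, 0.75); y2 <- rep(0.25, 4)
  ls2 <- blockErrorMap(en2, x2, y2, ed, ed, nBlocks = 2)
  kT <- kBoltzmann * 298
  d <- kT * log(3)  # block1 dF = kT ln 3, block2 dF = 0
  expect_equal(ls2@stderr[1, 1], 0, tolerance = 1e-12)
  expect_equal(ls2@stderr[2, 1], d / 2, tolerance = 1e-12)
  # zero-weight block errors out
  en3 <- mkEnsemble(c(1, 1, 0, 0))
  expect_error(blockErrorMap(en3, x2, y2, ed, ed, nBlocks = 2), "block")
})

test_that("error map is consistent with repeat-run scatter", {
  pot <- doubleWellPotential1D()
  runLandscape <- function(seed) {
    tr <- langevinSimulate(pot, -1, 60000, friction = 0.5, seed = seed,
                           recordStride = 10)
    n <- nFrames(tr)
    en <- new("WeightedEnsemble",
              frames = data.frame(replica = 1L, frame = seq_len(n)),
              weights = rep(1 / n, n), nExcluded = 0L)
    ed <- seq(-2, 2, by = 0.25)
    blockErrorMap(en, tr@cv[, 1], rep(0.5, n), ed, c(0, 1), nBlocks = 10)
  }
  maps <- lapply(c(101, 202, 303, 404), runLandscape)
  common <- Reduce(`&`, lapply(maps, function(m)
    is.finite(m@F) & !is.na(m@stderr)))
  expect_gte(sum(common), 3)
  scatter <- apply(simplify2array(lapply(maps, function(m) m@F)),
                   c(1, 2), sd)[common]
  predicted <- rowMeans(vapply(maps, function(m) m@stderr[common],
                               numeric(sum(common))))
  # same order of magnitude: within a factor ~3 on average
  rat <- mean(predicted) / mean(scatter)
  expect_gt(rat, 1 / 3)
  expect_lt(rat, 3)
})

test_that("minimax path: monotone 1D-like profiles and flat landscapes", {
  # single-row grid: path is the interval, barrier = F_end - F_start uphill
  Fm <- matrix(c(0, 0.5, 1, 1.5, 2), nrow = 5, ncol = 1)
  g <- gridFromF(cbind(Fm), lo = c(0, 0), hi = c(0.5, 0.1))
  p <- minimumFreeEnergyPath(g, c(1, 1), c(5, 1))
  expect_identical(p@bins[, 1], 1:5)
  expect_equal(p@barrier, 2)
  # flat landscape: barrier 0
  g0 <- gridFromF(matrix(1, 5, 5))
  p0 <- minimumFreeEnergyPath(g0, c(1, 1), c(5, 5))
  expect_equal(p0@barrier, 0)
  expect_equal(nrow(p0@bins), 9L)  # monotone adjacency path
  # path of length 1
  p1 <- minimumFreeEnergyPath(g0, c(2, 2), c(2, 2))
  expect_identical(nrow(p1@bins), 1L)
  expect_equal(p1@barrier, 0)
  # disconnected endpoints are an error
  Fd <- matrix(1, 3, 3); Fd[2, ] <- Inf
  expect_error(minimumFreeEnergyPath(gridFromF(Fd), c(1, 1), c(3, 3)),
               "not connected")
})

test_that("a constructed saddle is found exactly (exhaustive oracle on tiny grids)", {
  # two basins separated by a ridge column with one low crossing at (2,2)
  Fm <- cbind(c(0, 0.3, 0.8),      # left basin
              c(4, 1.2, 4.5),      # ridge, saddle at (2,2)
              c(0.5, 0.4, 0.9),
              c(0.5, 0.3, 0.2))    # right basin
  g <- gridFromF(Fm)
  p <- minimumFreeEnergyPath(g, c(1, 1), c(1, 4))
  expect_equal(max(p@F), bruteForceMinimax(Fm, c(1, 1), c(1, 4)))
  expect_equal(p@barrier, max(p@F) - Fm[1, 1])
  expect_equal(p@barrier, 1.2)
  # saddle bin is the argmax of F along the path
  expect_identical(p@saddle, c(2L, 2L))
})

test_that("minimax barrier and saddle match the exact threshold oracle on random 8x8 grids", {
  set.seed(55)
  for (i in 1:100) {
    Fm <- matrix(runif(64, 0, 5), 8, 8)
    Fm[1, 1] <- 0; Fm[8, 8] <- 0.2
    g <- gridFromF(Fm)
    p <- minimumFreeEnergyPath(g, c(1, 1), c(8, 8))
    expect_identical(max(p@F), thresholdMinimax(Fm, c(1, 1), c(8, 8)))
    # the saddle attains the bottleneck
    expect_identical(Fm[p@saddle[1], p@saddle[2]], max(p@F))
  }
})

test_that("minimax barrier is invariant under monotone transformations of F", {
  set.seed(77)
  for (i in 1:20) {
    Fm <- matrix(runif(48, 0, 4), 8, 6)
    Fm[1, 1] <- 0; Fm[8, 6] <- 0.1
    g1 <- gridFromF(Fm)
    p1 <- minimumFreeEnergyPath(g1, c(1, 1), c(8, 6))
    tf <- function(x) exp(0.8 * x) + 0.1 * x  # strictly increasing
    g2 <- gridFromF(tf(Fm) - min(tf(Fm)))
    p2 <- minimumFreeEnergyPath(g2, c(1, 1), c(8, 6))
    expect_identical(p2@saddle, p1@saddle)
    expect_equal(max(p2@F), tf(max(p1@F)) - min(tf(Fm)))
  }
})

test_that("path barriers are at least the basin free-energy difference", {
  set.seed(31)
  for (i in 1:20) {
    Fm <- matrix(runif(36, 0, 4), 6, 6)
    g <- gridFromF(Fm)
    s <- c(sample(6, 1), sample(6, 1)); e <- c(sample(6, 1), sample(6, 1))
    p <- minimumFreeEnergyPath(g, s, e)
    expect_gte(p@barrier + 1e-12, max(0, Fm[e[1], e[2]] - Fm[s[1], s[2]]))
  }
})

test_that("path profiles report intermediates with their depths", {
  # W-shaped profile along a single row
  Fv <- c(0, 3, 1, 2.5, 0.2)
  g <- gridFromF(cbind(matrix(Fv, 5, 1)), lo = c(0, 0), hi = c(0.5, 0.1))
  p <- minimumFreeEnergyPath(g, c(1, 1), c(5, 1))
  pr <- pathProfile(p)
  expect_identical(nrow(pr$intermediates), 1L)
  expect_equal(pr$intermediates$F, 1)
  expect_equal(pr$intermediates$depth, 1.5)  # min(3, 2.5) - 1
  # monotone profile: no intermediates
  gm <- gridFromF(cbind(matrix(0:4, 5, 1)), lo = c(0, 0), hi = c(0.5, 0.1))
  prm <- pathProfile(minimumFreeEnergyPath(gm, c(1, 1), c(5, 1)))
  expect_identical(nrow(prm$intermediates), 0L)
})
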