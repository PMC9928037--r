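mkTraj <- function(cv, biased = integer(0), grad = NULL, bias = NULL,
                   id = 1L) {
  cv <- as.matrix(cv)
  n <- nrow(cv)
  if (is.null(grad)) grad <- matrix(numeric(0), n, 0)
  if (is.null(bias)) bias <- numeric(n)
  new("ReplicaTrajectory", replicaId = as.integer(id),
      biasedCVs = as.integer(biased), time = as.numeric(seq_len(n)),
      cv = cv, biasPotential = bias, biasGradient = as.matrix(grad),
      temperature = 298, hills = metaFES:::.emptyHills(length(biased)))
}

test_that("bin assignment: counts, half-open convention, outside handling", {
  tr <- mkTraj(cbind(rep(0.5, 7)))
  g <- assignBins(tr, gridEdges(0, 1, 4))
  expect_identical(sum(g@counts), 7L)
  expect_identical(g@counts[3], 7L)  # 0.5 lies on the edge: upper bin
  # values outside the grid are counted, not dropped
  g2 <- assignBins(mkTraj(cbind(c(-0.1, 0.2, 1.0, 1.5))), gridEdges(0, 1, 4))
  expect_identical(sum(g2@counts), 1L)
  expect_identical(g2@outside, 3L)  # top edge itself is outside [lo, hi)
  expect_error(assignBins(tr, list(c(0, 0, 1))), "zero-width")
})

test_that("uniform sampling fills bins within the multinomial envelope", {
  set.seed(14)
  n <- 40000
  g <- assignBins(mkTraj(cbind(runif(n))), gridEdges(0, 1, 10))
  expected <- n / 10
  se <- sqrt(n * 0.1 * 0.9)
  expect_true(all(abs(g@counts - expected) < 4 * se))
})

test_that("mean forces average the recorded bias gradient per bin", {
  # hand-built frames with known gradients
  cv <- cbind(c(0.1, 0.1, 0.3, 0.3, 0.3))
  grad <- cbind(c(1, 3, -1, -2, -3))
  tr <- mkTraj(cv, biased = 1L, grad = grad)
  g <- assignBins(tr, gridEdges(0, 0.4, 2), minCount = 1L)
  g <- estimateMeanForces(tr, g)
  expect_equal(as.numeric(g@meanForce[[1]]), c(2, -2))
  expect_identical(as.integer(g@forceCount[[1]]), c(2L, 3L))
  # adding a constant to the bias potential changes no gradient
  tr2 <- mkTraj(cv, biased = 1L, grad = grad, bias = rep(5, 5))
  g2 <- estimateMeanForces(tr2, assignBins(tr2, gridEdges(0, 0.4, 2),
                                           minCount = 1L))
  expect_equal(g2@meanForce[[1]], g@meanForce[[1]])
  expect_error(estimateMeanForces(mkTraj(cv), assignBins(mkTraj(cv),
               gridEdges(0, 0.4, 2))), "force")
})

test_that("converged 1D metadynamics reproduces the analytic mean force and free energy", {
  fix <- meta1DRun()
  g <- fix$grid
  centers <- (fix$edges[[1]][-1] + fix$edges[[1]][-51]) / 2
  h <- 1e-5
  dFdx <- (evaluatePotential(fix$pot, cbind(centers + h))$energy -
             evaluatePotential(fix$pot, cbind(centers - h))$energy) / (2 * h)
  well <- as.integer(g@forceCount[[1]]) >= 1000 & abs(dFdx) < 8
  expect_gt(sum(well), 10)
  # -<dV/dx> tracks dF/dx on well-sampled bins; the pooled estimate still
  # carries the finite-hill-width ripple of the stationary bias, so the
  # per-bin agreement is sub-kcal while the integrated profile is tighter
  est <- -as.numeric(g@meanForce[[1]])
  expect_lt(sqrt(mean((est[well] - dFdx[well])^2)), 0.8)
  expect_gt(cor(est[well], dFdx[well]), 0.985)
  # integrating the mean forces recovers the quadrature free energy
  Fq <- freeEnergyQuadrature(fix$pot, 1, cbind(centers), shift = FALSE)
  ok <- is.finite(fix$gridF@F) & (Fq - min(Fq)) < 4
  Fi <- fix$gridF@F[ok] - min(fix$gridF@F[ok])
  Fr <- Fq[ok] - min(Fq[ok])
  expect_lt(sqrt(mean((Fi - Fr)^2)), 0.3)
})

test_that("mean-force integration is exact for linear forces and curl-free fields", {
  # 1D: dF/dx = k x sampled exactly at bin centres -> F = k x^2 / 2 on grid
  edges <- gridEdges(-1, 1, 20)
  centers <- (edges[[1]][-1] + edges[[1]][-21]) / 2
  k <- 3
  tr <- mkTraj(cbind(centers), biased = 1L, grad = cbind(-k * centers))
  g <- assignBins(tr, edges, minCount = 1L)
  g <- estimateMeanForces(tr, g)
  gi <- integrateMeanForces(g, minCount = 1L)
  Fexp <- k * centers^2 / 2
  # trapezoid integration of a linear gradient is exact
  expect_equal(as.numeric(gi@F), Fexp - min(Fexp), tolerance = 1e-12)
  expect_lt(gi@metadata$residual, 1e-12)

  # 2D: construct F, differentiate on the bin graph, re-integrate
  nx <- 8; ny <- 7
  ed2 <- gridEdges(c(0, 0), c(1, 1), c(nx, ny))
  cx <- (ed2[[1]][-1] + ed2[[1]][-(nx + 1)]) / 2
  cy <- (ed2[[2]][-1] + ed2[[2]][-(ny + 1)]) / 2
  Ftrue <- outer(cx, cy, function(a, b) sin(3 * a) + (b - 0.4)^2 + a * b)
  hx <- diff(cx)[1]; hy <- diff(cy)[1]
  # bin-point gradients consistent with midpoint-averaged differences:
  # solve for gradients whose pairwise means equal the finite differences
  gx <- matrix(0, nx, ny); gy <- matrix(0, nx, ny)
  for (j in seq_len(ny)) {
    d <- diff(Ftrue[, j]) / hx
    v <- numeric(nx); v[1] <- d[1]
    for (i in 2:nx) v[i] <- 2 * d[i - 1] - v[i - 1]
    gx[, j] <- v
  }
  for (i in seq_len(nx)) {
    d <- diff(Ftrue[i, ]) / hy
    v <- numeric(ny); v[1] <- d[1]
    for (j in 2:ny) v[j] <- 2 * d[j - 1] - v[j - 1]
    gy[i, ] <- v
  }
  pts <- as.matrix(expand.grid(cx, cy))
  tr2 <- mkTraj(pts, biased = 1:2,
                grad = cbind(-as.numeric(gx), -as.numeric(gy)))
  g2 <- assignBins(tr2, ed2, minCount = 1L)
  g2 <- estimateMeanForces(tr2, g2)
  gi2 <- integrateMeanForces(g2, minCount = 1L)
  expect_equal(as.numeric(gi2@F), as.numeric(Ftrue - min(Ftrue)),
               tolerance = 1e-8)

  # inconsistent (curl) noise: residual is reported, F still returned
  set.seed(3)
  tr3 <- mkTraj(pts, biased = 1:2,
                grad = cbind(-as.numeric(gx) + rnorm(nx * ny, sd = 0.5),
                             -as.numeric(gy) + rnorm(nx * ny, sd = 0.5)))
  g3 <- estimateMeanForces(tr3, assignBins(tr3, ed2, minCount = 1L))
  g3 <- integrateMeanForces(g3, minCount = 1L)
  expect_gt(g3@metadata$residual, 0)
  expect_true(all(is.finite(g3@F)))
})

test_that("bias negation: no hills -> flat, one hill -> minus the Gaussian", {
  edges <- gridEdges(-1, 1, 10)
  tr <- mkTraj(cbind(0), biased = 1L, grad = cbind(0))
  g <- assignBins(tr, edges)
  flat <- freeEnergyFromBias(tr, g)
  expect_true(all(flat@F == 0))
  trh <- tr
  trh@hills <- cbind(0.1, 0.3, 1.5, 1)  # centre, sigma, height, time
  gb <- freeEnergyFromBias(trh, g)
  centers <- (edges[[1]][-1] + edges[[1]][-11]) / 2
  expected <- -1.5 * exp(-(centers - 0.1)^2 / (2 * 0.3^2))
  expect_equal(as.numeric(gb@F), expected - min(expected), tolerance = 1e-9)
})

test_that("frame weights follow the inverse-count Boltzmann formula", {
  kT <- kBoltzmann * 298
  edges <- gridEdges(0, 1, 2)
  # uniform F, equal counts -> uniform weights
  tr <- mkTraj(cbind(c(0.2, 0.2, 0.7, 0.7)))
  g <- assignBins(tr, edges)
  g@F <- array(c(1, 1), dim = 2L)
  w <- frameWeights(g, tr)
  expect_equal(weights(w), rep(0.25, 4))
  # F difference kT ln 2 -> per-frame ratio exactly 2
  g@F <- array(c(0, kT * log(2)), dim = 2L)
  w2 <- weights(frameWeights(g, tr))
  expect_equal(w2[1] / w2[3], 2)
  # adding a constant to F leaves weights unchanged
  g@F <- g@F + 7
  expect_equal(weights(frameWeights(g, tr)), w2, tolerance = 1e-12)
  # frames in non-finite bins are excluded and counted
  g@F <- array(c(0, Inf), dim = 2L)
  w3 <- frameWeights(g, tr)
  expect_identical(w3@nExcluded, 2L)
  expect_equal(sum(weights(w3)), 1)
})

test_that("reweighted averages: constants, indicators, block errors", {
  tr <- mkTraj(cbind(seq(0.05, 0.95, length.out = 40)))
  g <- assignBins(tr, gridEdges(0, 1, 4))
  g@F <- array(0, dim = 4L)
  en <- frameWeights(g, tr)
  r <- reweightedAverage(en, rep(3.3, 40))
  expect_equal(r$value, 3.3)
  expect_equal(r$stderr, 0)
  ind <- as.numeric(seq_len(40) <= 10)
  expect_equal(reweightedAverage(en, ind)$value, sum(weights(en)[1:10]))
  expect_error(reweightedAverage(en, rep(1, 40), nBlocks = 50), "blocks")
})

test_that("toy-model reweighted mean position matches quadrature", {
  fix <- meta1DRun()
  en <- frameWeights(fix$gridF, fix$trs, discardFraction = 0.4)
  keep <- frameCVValues(en, fix$trs, 1)
  r <- reweightedAverage(en, keep)
  # quadrature expectation of x under the Boltzmann density
  kT <- kBoltzmann * 298
  f <- function(x) exp(-evaluatePotential(fix$pot, cbind(x))$energy / kT)
  Z <- integrate(f, -4, 4, rel.tol = 1e-10)$value
  Ex <- integrate(function(x) x * f(x), -4, 4, rel.tol = 1e-10)$value / Z
  expect_lt(abs(r$value - Ex), 3 * r$stderr + 0.05)
})

test_that("perturbative reweighting is exact in its degenerate limits and vs a Zwanzig oracle", {
  set.seed(23)
  n <- 200
  w <- runif(n); w <- w / sum(w)
  en <- new("WeightedEnsemble",
            frames = data.frame(replica = 1L, frame = seq_len(n)),
            weights = w, nExcluded = 0L)
  states <- sample(c("A", "B"), n, replace = TRUE)
  # zero and constant perturbations cancel exactly
  expect_identical(perturbativeReweight(en, rep(0, n), states, "A", "B")$ddF,
                   0)
  expect_identical(perturbativeReweight(en, rep(2.7, n), states, "A",
                                        "B")$ddF, 0)
  # state-dependent perturbation vs direct Zwanzig sums
  dU <- ifelse(states == "A", rnorm(n, 0.5, 0.3), rnorm(n, -0.2, 0.4))
  kT <- kBoltzmann * 298
  r <- perturbativeReweight(en, dU, states, "A", "B")
  pA <- sum(w[states == "A"]); pB <- sum(w[states == "B"])
  pA2 <- sum((w * exp(-dU / kT))[states == "A"])
  pB2 <- sum((w * exp(-dU / kT))[states == "B"])
  oracle <- (-kT * log(pB2 / pA2)) - (-kT * log(pB / pA))
  expect_lt(abs(r$ddF - oracle), 1e-10)
  # extreme perturbations trigger the effective-sample-size warning
  expect_warning(perturbativeReweight(en, dU * 100, states, "A", "B"),
                 "effective sample size")
})
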