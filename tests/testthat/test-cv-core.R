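test_that("MSD to reference is zero under identity and rigid motion", {
  refs <- referenceConformations(nResidues = 10)
  sel <- atomSelection(1:10)
  expect_equal(as.numeric(msdToReference(refs$A, refs$A, sel)), 0)
  shifted <- rigidMove(refs$A, angle = 0)  # pure translation
  expect_lt(as.numeric(msdToReference(shifted, refs$A, sel)), 1e-18)
  rotated <- rigidMove(refs$A, angle = 1.1, axis = c(1, 2, 3))
  expect_lt(as.numeric(msdToReference(rotated, refs$A, sel)), 1e-18)
  # without superposition the translation is not removed
  expect_gt(as.numeric(msdToReference(shifted, refs$A, sel,
                                      superpose = FALSE)), 0.01)
})

test_that("Kabsch superposition matches the bio3d least-squares oracle", {
  set.seed(17)
  for (rep in 1:5) {
    X <- matrix(rnorm(12), 4, 3)
    Y <- X + matrix(rnorm(12, sd = 0.1), 4, 3)
    fit <- kabschSuperpose(X, Y)
    ours <- mean(rowSums((fit - Y)^2))
    xy <- suppressWarnings(
      bio3d::fit.xyz(fixed = as.vector(t(Y)), mobile = as.vector(t(X))))
    theirs <- mean(rowSums((matrix(xy, ncol = 3, byrow = TRUE) - Y)^2))
    expect_lt(abs(ours - theirs), 1e-9)
  }
})

test_that("degenerate selections fall back to translation-only and are flagged", {
  # two collinear atoms cannot determine a rotation
  f1 <- lineFrame(2)
  f2 <- rigidMove(lineFrame(2), angle = 0.4)
  sel <- atomSelection(1:2)
  expect_warning(d <- msdToReference(f2, f1, sel), "degenerate")
  expect_true(attr(d, "degenerate"))
})

test_that("missing selection atoms are reported", {
  f <- lineFrame(3)
  expect_error(selectAtoms(f, atomSelection(5)), "missing")
})

test_that("path values obey symmetry, endpoint limits and the closed form", {
  # equal distances: exact midpoints
  expect_equal(pathValue(c(0.3, 0.3), 20), 1.5)
  expect_equal(pathValue(c(0.02, 0.02, 0.02), 200), 2)
  # endpoint limits under large lambda*d contrast
  expect_lt(abs(pathValue(c(0, 10), 20) - 1), 1e-12)
  expect_lt(abs(pathValue(c(10, 0), 20) - 2), 1e-12)
  expect_lt(abs(pathValue(c(10, 10, 0), 200) - 3), 1e-12)
  # closed-form spot values, verified against direct independent evaluation
  expect_equal(pathValue(c(0.05, 0.10), 20), 1.268941, tolerance = 1e-5)
  expect_equal(pathValue(c(0.02, 0.01, 0.005), 200), 2.670268,
               tolerance = 1e-5)
  # overflow safety: huge lambda*d must not produce NaN
  expect_false(is.nan(pathValue(c(0, 1e6), 200)))
  expect_error(pathValue(c(NaN, 1), 20), "non-finite")
})

test_that("path CVs stay within their open bounds on random ensembles", {
  refs <- referenceConformations(nResidues = 10)
  sel <- atomSelection(1:10)
  def2 <- pathCVDefinition(sel, list(refs$A, refs$B))
  ens <- generateTwoStateStructures(refs$A, refs$B, 30, 0.5, 0.05, seed = 2)
  v2 <- vapply(ens$frames, pathCVTwoState, numeric(1), definition = def2)
  expect_true(all(v2 > 1 & v2 < 2))
  # near the references the variable approaches its endpoints
  expect_lt(pathCVTwoState(refs$A, def2), 1.1)
  expect_gt(pathCVTwoState(refs$B, def2), 1.9)
  mid <- refs$A
  mid@atoms[, c("x", "y", "z")] <-
    (refs$A@atoms[, c("x", "y", "z")] + refs$B@atoms[, c("x", "y", "z")]) / 2
  def3 <- pathCVDefinition(sel, list(refs$A, mid, refs$B), lambda = 200)
  v3 <- vapply(ens$frames, pathCVThreeState, numeric(1), definition = def3)
  expect_true(all(v3 > 1 & v3 < 3))
})

test_that("automatic lambda scales inversely with the inter-reference distance", {
  refs <- referenceConformations(nResidues = 10)
  sel <- atomSelection(1:10)
  d12 <- as.numeric(msdToReference(refs$A, refs$B, sel))
  def <- pathCVDefinition(sel, list(refs$A, refs$B), lambdaScale = 2.3)
  expect_equal(def$lambda, 2.3 / d12)
})

test_that("hydration variable matches its closed forms and a brute-force sum", {
  site <- hydrationSite(oxygenSelection = atomSelection(1, "O"), beta = 10)
  at <- data.frame(resid = 1L, name = "O", x = 0, y = 0, z = 0)
  # single water at r: beta^2 / r exactly
  f1 <- structureFrame(at, waters = cbind(0.5, 0, 0))
  expect_equal(hydrationCV(f1, site), 10^2 / 0.5)
  # two waters both at r: beta * (ln 2 + beta / r)
  f2 <- structureFrame(at, waters = rbind(c(0.5, 0, 0), c(0, 0.5, 0)))
  expect_equal(hydrationCV(f2, site), 10 * (log(2) + 10 / 0.5))
  # 50 random waters: naive direct summation oracle
  set.seed(6)
  W <- matrix(runif(150, 0.3, 3), 50, 3)
  fr <- structureFrame(at, waters = W)
  r <- sqrt(rowSums(W^2))
  naive <- 10 * log(sum(exp(10 / r)))
  expect_equal(hydrationCV(fr, site), naive, tolerance = 1e-9)
  # ion-centred site
  fi <- structureFrame(at, waters = cbind(1.2, 1, 0),
                       ions = matrix(c(1.2, 0.5, 0), 1, 3,
                                     dimnames = list("CA1", NULL)))
  expect_equal(hydrationCV(fi, hydrationSite(ion = "CA1", beta = 10)),
               10^2 / 0.5)
  expect_error(hydrationCV(structureFrame(at), site), "water")
})

test_that("switching function: closed-form values and factored/literal equivalence", {
  expect_equal(switchingFunction(0.7, 0.7), 0.5)
  expect_equal(switchingFunction(0, 0.7), 1)
  expect_equal(switchingFunction(1.4, 0.7), 1 / 17)
  expect_lt(switchingFunction(70, 0.7), 1e-7)
  ratios <- c(seq(0.1, 0.99, by = 0.01), seq(1.01, 3, by = 0.01))
  r <- ratios * 0.7
  expect_equal(switchingFunction(r, 0.7, "factored"),
               switchingFunction(r, 0.7, "literal"), tolerance = 1e-9)
})

test_that("contact counts sum pairwise switching values", {
  at <- data.frame(resid = 1:4, name = "CA",
                   x = c(0, 0.7, 0, 1.4), y = c(0, 0, 0, 0), z = 0)
  f <- structureFrame(at)
  d <- contactDescriptor(c(1, 3), c(2, 4), r0 = 0.7)
  # pairs: (1,2)=0.7, (1,4)=1.4, (3,2)=0.7, (3,4)=1.4
  expect_equal(contactCount(f, d), 2 * 0.5 + 2 / 17)
  expect_error(contactDescriptor(1:2, 2:3), "disjoint")
})

test_that("water accessibility obeys the distance threshold and a brute-force count", {
  at <- data.frame(resid = 1L, name = c("CA", "N"),
                   x = c(0, 0.2), y = 0, z = 0)
  fNear <- structureFrame(at, waters = cbind(0.41, 0, 0))
  fFar <- structureFrame(at, waters = cbind(0.2 + 0.43, 0, 0))
  expect_identical(waterAccessibilityCount(fNear, 1), 1L)
  expect_identical(waterAccessibilityCount(fFar, 1), 0L)
  expect_identical(waterAccessibilityCount(structureFrame(at), 1), 0L)
  set.seed(12)
  W <- matrix(runif(90, -1, 1), 30, 3)
  f <- structureFrame(at, waters = W)
  brute <- 0L
  for (i in 1:30) {
    near <- FALSE
    for (j in 1:2) {
      dd <- sqrt(sum((W[i, ] - as.numeric(at[j, c("x", "y", "z")]))^2))
      if (dd <= 0.42) near <- TRUE
    }
    brute <- brute + near
  }
  expect_identical(waterAccessibilityCount(f, 1), as.integer(brute))
})

test_that("all CVs are invariant under global rigid motion", {
  refs <- referenceConformations(nResidues = 10)
  ens <- generateTwoStateStructures(refs$A, refs$B, 3, 0.5, 0.05, seed = 5)
  f <- ens$frames[[1]]
  g <- rigidMove(f, angle = 0.9, axis = c(2, -1, 1), shift = c(1, 2, -0.5))
  sel <- atomSelection(1:10)
  def <- pathCVDefinition(sel, list(refs$A, refs$B))
  expect_equal(pathCVTwoState(g, def), pathCVTwoState(f, def),
               tolerance = 1e-9)
  cd <- contactDescriptor(1:3, 6:8)
  expect_equal(contactCount(g, cd), contactCount(f, cd), tolerance = 1e-9)
  hs <- hydrationSite(oxygenSelection = atomSelection(2, "O"))
  expect_equal(hydrationCV(g, hs), hydrationCV(f, hs), tolerance = 1e-9)
  expect_identical(waterAccessibilityCount(g, 3),
                   waterAccessibilityCount(f, 3))
})

test_that("CV tables compose per-frame evaluations", {
  expect_identical(nrow(evaluateCVTable(list(), list(a = function(f) 1))), 0L)
  refs <- referenceConformations(nResidues = 10)
  cd <- contactDescriptor(1:3, 6:8)
  tab1 <- evaluateCVTable(list(refs$A), list(contacts = cd))
  expect_equal(tab1$contacts, contactCount(refs$A, cd))
  # two-state ensemble: contact histogram is bimodal at the reference values
  ens <- generateTwoStateStructures(refs$A, refs$B, 60, 0.5, 0.005, seed = 7)
  tab <- evaluateCVTable(ens$frames, list(contacts = cd))
  cA <- contactCount(refs$A, cd); cB <- contactCount(refs$B, cd)
  expect_false(isTRUE(all.equal(cA, cB)))
  grp <- ifelse(ens$states == "A", cA, cB)
  expect_lt(max(abs(tab$contacts - grp)), 0.2 * abs(cA - cB))
  # errors carry the frame index
  bad <- list(frames = list(refs$A, lineFrame(2)))
  expect_error(evaluateCVTable(bad$frames, list(contacts = cd)), "frame 2")
})
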