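## Forward-modelling of fragment deuteration from structural ensembles,
## back-exchange correction, overlapping-fragment deconvolution, and
## maximum-entropy reweighting of state populations against HDX-MS data.

#' Exchange-competent residues of a fragment
#'
#' A fragment's first residue loses its deuterium during proteolysis and
#' prolines have no amide hydrogen, so both are excluded (standard HDX-MS
#' convention).
#'
#' @param start,end 1-based inclusive residue range.
#' @param prolines integer residue indices of prolines.
#' @return integer vector of residues contributing to exchange.
#' @export
exchangeCompetentResidues <- function(start, end, prolines = integer(0)) {
  stopifnot(end >= start)
  setdiff(seq.int(start + 1L, length.out = end - start), prolines)
}

#' Amide environment counts for one residue
#'
#' Counts, around a residue's backbone amide, the two structural quantities
#' the phenomenological protection model uses: `Nc`, heavy atoms within
#' `contactCutoff` of the amide nitrogen, and `Nh`, O/N hydrogen-bond
#' acceptors within `hbondCutoff` of the amide hydrogen.  Atoms of residues
#' within `exclusionWindow` of the residue itself (sequence neighbours) are
#' excluded from both counts.  If the amide hydrogen is absent from the
#' frame, `Nh` is 0.
#'
#' @param frame a [StructureFrame-class].
#' @param residue 1-based residue index (must have an `N` atom).
#' @param contactCutoff nm, default 0.65.
#' @param hbondCutoff nm, default 0.24.
#' @param exclusionWindow sequence-neighbour window, default 2.
#' @return named integer vector `c(Nc, Nh)`.
#' @export
residueEnvironmentCounts <- function(frame, residue, contactCutoff = 0.65,
                                     hbondCutoff = 0.24,
                                     exclusionWindow = 2L) {
  at <- frame@atoms
  iN <- which(at$resid == residue & at$name == "N")
  if (length(iN) != 1)
    stop("amide N of residue ", residue, " not resolvable")
  iH <- which(at$resid == residue & at$name == "H")
  keep <- abs(at$resid - residue) > exclusionWindow
  other <- at[keep, , drop = FALSE]
  xyz <- as.matrix(other[, c("x", "y", "z")])
  heavy <- !startsWith(other$name, "H")
  pN <- as.numeric(at[iN, c("x", "y", "z")])
  d2N <- rowSums(sweep(xyz, 2, pN)^2)
  Nc <- sum(heavy & d2N <= contactCutoff^2)
  Nh <- 0L
  if (length(iH) == 1) {
    pH <- as.numeric(at[iH, c("x", "y", "z")])
    d2H <- rowSums(sweep(xyz, 2, pH)^2)
    acceptor <- startsWith(other$name, "O") | startsWith(other$name, "N")
    Nh <- sum(acceptor & d2H <= hbondCutoff^2)
  }
  c(Nc = as.integer(Nc), Nh = as.integer(Nh))
}

#' Phenomenological protection factors from environment counts
#'
#' \eqn{\ln P = \beta_c N_c + \beta_h N_h}: burial (heavy-atom contacts)
#' and hydrogen bonding both slow amide exchange; with non-negative counts
#' P >= 1 by construction.
#'
#' @param counts numeric vector `c(Nc, Nh)`, or a 2-column matrix of counts
#'   (one row per residue/frame).
#' @param betaC contact coefficient (default 0.35).
#' @param betaH hydrogen-bond coefficient (default 2.0).
#' @return ln P (same length as rows of `counts`).
#' @export
protectionFactors <- function(counts, betaC = 0.35, betaH = 2.0) {
  stopifnot(betaC >= 0, betaH >= 0)
  if (is.vector(counts)) counts <- matrix(counts, 1)
  betaC * counts[, 1] + betaH * counts[, 2]
}

#' Per-frame per-residue ln protection factors of an ensemble
#'
#' @param frames list of [StructureFrame-class] objects.
#' @param residues integer residue indices to evaluate.
#' @param betaC,betaH,contactCutoff,hbondCutoff,exclusionWindow model
#'   parameters, see [residueEnvironmentCounts()] and
#'   [protectionFactors()].
#' @return numeric matrix (frames x residues) of ln P, with residue indices
#'   as column names.
#' @export
ensembleProtectionFactors <- function(frames, residues, betaC = 0.35,
                                      betaH = 2.0, contactCutoff = 0.65,
                                      hbondCutoff = 0.24,
                                      exclusionWindow = 2L) {
  out <- matrix(NA_real_, length(frames), length(residues),
                dimnames = list(NULL, as.character(residues)))
  for (i in seq_along(frames))
    for (j in seq_along(residues))
      out[i, j] <- protectionFactors(
        residueEnvironmentCounts(frames[[i]], residues[j], contactCutoff,
                                 hbondCutoff, exclusionWindow),
        betaC, betaH)
  out
}

.lnPcols <- function(lnP, residues) {
  idx <- match(as.character(residues), colnames(lnP))
  if (anyNA(idx))
    stop("ln P matrix lacks residues: ",
         paste(residues[is.na(idx)], collapse = ", "))
  idx
}

#' Predicted fragment deuteration under ensemble weights
#'
#' Forward model: for each exchange-competent residue r of the fragment the
#' ensemble-averaged ln protection factor is exponentiated to
#' \eqn{\bar{P}_r}, and the predicted deuterated fraction at exposure time
#' t is \deqn{D = \rho \frac{1}{m} \sum_r [1 - e^{-k^{int}_r t /
#' \bar{P}_r}],} bounded by the back-exchange retention \eqn{\rho}.  With
#' `averaging = "deuteration"` the per-frame uptake is computed first and
#' then ensemble-averaged (the other common convention).
#'
#' @param weights normalized ensemble weights (one per frame).
#' @param lnP matrix (frames x residues) of ln protection factors with
#'   residue indices as column names, e.g. from
#'   [ensembleProtectionFactors()].
#' @param kInt per-residue intrinsic rates, 1/s: either a vector indexed by
#'   residue number or a scalar.
#' @param start,end fragment residue range.
#' @param time exposure time, s (vectorized).
#' @param rho back-exchange retention in (0, 1].
#' @param prolines integer proline positions.
#' @param averaging `"lnP"` (default) or `"deuteration"`.
#' @return predicted fraction(s) in `[0, rho]`.
#' @export
fragmentDeuteration <- function(weights, lnP, kInt, start, end, time,
                                rho = 1, prolines = integer(0),
                                averaging = c("lnP", "deuteration")) {
  averaging <- match.arg(averaging)
  stopifnot(all(time >= 0), rho > 0, rho <= 1,
            abs(sum(weights) - 1) < 1e-8)
  res <- exchangeCompetentResidues(start, end, prolines)
  if (length(res) == 0) stop("fragment has no exchange-competent residues")
  cols <- .lnPcols(lnP, res)
  k <- if (length(kInt) == 1) rep(kInt, length(res)) else kInt[res]
  vapply(time, function(t) {
    if (averaging == "lnP") {
      Pbar <- exp(as.numeric(weights %*% lnP[, cols, drop = FALSE]))
      rho * mean(1 - exp(-k * t / Pbar))
    } else {
      d <- sweep(1 - exp(-sweep(exp(-lnP[, cols, drop = FALSE]), 2, k * t,
                                `*`)), 1, weights, `*`)
      rho * mean(colSums(d))
    }
  }, numeric(1))
}

#' Predict a whole HDX table
#'
#' Applies [fragmentDeuteration()] to every row of an HDX data table,
#' pre-back-exchange (`rho = 1`) unless given.
#'
#' @param weights normalized frame weights.
#' @param lnP ln-protection-factor matrix (frames x residues).
#' @param kInt per-residue intrinsic rates (vector or scalar), 1/s.
#' @param data data.frame with `fragment_start`, `fragment_end`, `time_s`.
#' @param rho retention factor applied to all rows.
#' @param prolines integer proline positions.
#' @param averaging see [fragmentDeuteration()].
#' @return numeric vector of predictions aligned with `data` rows.
#' @export
predictHDX <- function(weights, lnP, kInt, data, rho = 1,
                       prolines = integer(0),
                       averaging = c("lnP", "deuteration")) {
  averaging <- match.arg(averaging)
  vapply(seq_len(nrow(data)), function(i)
    fragmentDeuteration(weights, lnP, kInt, data$fragment_start[i],
                        data$fragment_end[i], data$time_s[i], rho,
                        prolines, averaging), numeric(1))
}

#' Least-squares back-exchange retention factor
#'
#' Fits the scalar \eqn{\rho} relating observed fractions to
#' pre-back-exchange predictions, \eqn{\rho = \sum o p / \sum p^2},
#' clipped to (0, 1].
#'
#' @param predicted pre-\eqn{\rho} predicted fractions.
#' @param observed observed fractions.
#' @return fitted \eqn{\rho}.
#' @export
fitBackExchange <- function(predicted, observed) {
  stopifnot(length(predicted) == length(observed), length(predicted) >= 1)
  sp <- sum(predicted^2)
  if (sp <= 0) stop("all predictions are zero: rho is unidentifiable")
  min(1, max(sum(observed * predicted) / sp, 1e-6))
}

#' Deconvolve overlapping HDX fragments
#'
#' When fragment B is nested inside fragment A, the deuteration of the
#' region A minus B follows by linear combination:
#' \eqn{D = (m_A D_A - m_B D_B) / (m_A - m_B)} with m the
#' exchange-competent residue counts.  Noise can push the raw value outside
#' [0, 1]; such values are clipped with a warning and flagged.
#'
#' @param mA,mB exchange-competent residue counts (mA > mB).
#' @param DA,DB deuterated fractions of the two fragments.
#' @return deconvolved fraction with attribute `clipped` (logical).
#' @export
deconvolveFragments <- function(mA, DA, mB, DB) {
  if (mA == mB) stop("fragments have equal residue counts: nothing to deconvolve")
  stopifnot(mA > mB)
  raw <- (mA * DA - mB * DB) / (mA - mB)
  clipped <- raw < 0 || raw > 1
  if (clipped)
    warning(sprintf("deconvolved fraction %.4f outside [0,1]: clipped (noise)",
                    raw))
  out <- min(1, max(0, raw))
  attr(out, "clipped") <- clipped
  out
}

#' Maximum-entropy reweighting of an ensemble against HDX data
#'
#' Minimizes \deqn{J(w) = \frac{\gamma}{2} \sum_{f,t} (D^{pred}_{f,t}(w) -
#' D^{obs}_{f,t})^2 + \sum_i w_i \ln(w_i / w^0_i)} over the simplex by
#' damped exponential-gradient (mirror-descent) iterations
#' \eqn{w_i \propto w^0_i e^{-\gamma \partial \chi^2 / \partial w_i}}.  As
#' \eqn{\gamma \to 0} the prior is recovered; larger \eqn{\gamma} trades
#' entropy (closeness to the prior) for fit.  The back-exchange retention
#' \eqn{\rho} is refitted by [fitBackExchange()] inside every iteration
#' unless fixed.  State populations are reported by summing the optimized
#' weights over the supplied labels.
#'
#' @param prior prior weights on the simplex.
#' @param lnP ln-protection-factor matrix (frames x residues).
#' @param kInt per-residue intrinsic rates (vector or scalar), 1/s.
#' @param data HDX table: `fragment_start`, `fragment_end`, `time_s`,
#'   `fraction` (and optionally `construct`; \eqn{\rho} is fitted per
#'   construct).
#' @param gamma regularization strength, >= 0.
#' @param rho fixed retention factor(s); `NULL` (default) fits per
#'   construct each iteration.
#' @param stateLabels optional per-frame state labels for the population
#'   report.
#' @param prolines integer proline positions.
#' @param averaging see [fragmentDeuteration()].
#' @param maxIter,tol iteration cap and relative-change convergence
#'   threshold on J (defaults 5000 and 1e-8).
#' @param damping initial step size of the exponential-gradient update,
#'   halved whenever a step increases J.
#' @return a [MaxEntResult-class].
#' @export
maxentReweight <- function(prior, lnP, kInt, data, gamma, rho = NULL,
                           stateLabels = NULL, prolines = integer(0),
                           averaging = c("lnP", "deuteration"),
                           maxIter = 5000L, tol = 1e-8, damping = 1) {
  averaging <- match.arg(averaging)
  stopifnot(gamma >= 0, all(prior >= 0), abs(sum(prior) - 1) < 1e-8)
  n <- length(prior)
  obs <- data$fraction
  constructs <- if ("construct" %in% names(data)) as.character(data$construct)
                else rep("all", nrow(data))
  fitRho <- is.null(rho)
  rhoOf <- function(pred0) {
    if (!fitRho)
      return(setNames(rep_len(rho, length(unique(constructs))),
                      unique(constructs)))
    vapply(unique(constructs), function(cc) {
      i <- constructs == cc
      fitBackExchange(pred0[i], obs[i])
    }, numeric(1))
  }

  popsOf <- function(w) {
    if (is.null(stateLabels)) return(numeric(0))
    p <- vapply(split(w, stateLabels), sum, numeric(1))
    p / sum(p)
  }
  klOf <- function(w) {
    i <- w > 0
    sum(w[i] * log(w[i] / prior[i]))
  }

  if (gamma == 0) {
    pred0 <- predictHDX(prior, lnP, kInt, data, 1, prolines, averaging)
    rr <- rhoOf(pred0)
    pred <- pred0 * rr[constructs]
    return(new("MaxEntResult", weights = prior, prior = prior, gamma = gamma,
               populations = popsOf(prior), kl = 0,
               msd = mean((pred - obs)^2), rho = rr, converged = TRUE,
               iterations = 0L))
  }

  ## gradient of the chi^2 term wrt weights (lnP-averaging convention);
  ## for the deuteration convention the per-frame uptake enters linearly
  chi2grad <- function(w, rr) {
    g <- numeric(n)
    predAll <- numeric(nrow(data))
    for (i in seq_len(nrow(data))) {
      res <- exchangeCompetentResidues(data$fragment_start[i],
                                       data$fragment_end[i], prolines)
      cols <- .lnPcols(lnP, res)
      k <- if (length(kInt) == 1) rep(kInt, length(res)) else kInt[res]
      t <- data$time_s[i]
      r <- rr[constructs[i]]
      m <- length(res)
      if (averaging == "lnP") {
        lbar <- as.numeric(w %*% lnP[, cols, drop = FALSE])
        a <- k * t / exp(lbar)
        pred <- r * mean(1 - exp(-a))
        # d pred / d w_j = (r/m) sum_r exp(-a_r) * (-a_r) * lnP_{j,r}
        coef <- exp(-a) * (-a) * (r / m)
        dp <- as.numeric(lnP[, cols, drop = FALSE] %*% coef)
      } else {
        d <- 1 - exp(-sweep(exp(-lnP[, cols, drop = FALSE]), 2, k * t, `*`))
        perFrame <- rowMeans(d) * r
        pred <- sum(w * perFrame)
        dp <- perFrame
      }
      predAll[i] <- pred
      g <- g + (pred - obs[i]) * dp
    }
    list(grad = g, pred = predAll)
  }

  w <- prior
  pred0 <- predictHDX(w, lnP, kInt, data, 1, prolines, averaging)
  rr <- rhoOf(pred0)
  cg <- chi2grad(w, rr)
  J <- gamma / 2 * sum((cg$pred - obs)^2) + klOf(w)
  eta <- damping
  converged <- FALSE
  it <- 0L
  while (it < maxIter) {
    it <- it + 1L
    ## damped fixed-point of the stationarity condition
    ## w_i = w0_i exp(-gamma d(chi2/2)/dw_i) / Z
    lw <- (1 - eta) * log(pmax(w, 1e-300)) +
      eta * (log(pmax(prior, 1e-300)) - gamma * cg$grad)
    lw <- lw - logSumExp(lw)
    wNew <- exp(lw)
    wNew <- wNew / sum(wNew)
    pred0 <- predictHDX(wNew, lnP, kInt, data, 1, prolines, averaging)
    rrNew <- rhoOf(pred0)
    cgNew <- chi2grad(wNew, rrNew)
    Jnew <- gamma / 2 * sum((cgNew$pred - obs)^2) + klOf(wNew)
    if (Jnew > J + 1e-15 && eta > 1e-4) {
      eta <- eta / 2  # overshoot: retry smaller step from the same w
      next
    }
    dJ <- abs(Jnew - J) / max(abs(J), 1e-12)
    w <- wNew; rr <- rrNew; cg <- cgNew; J <- Jnew
    if (dJ < tol) { converged <- TRUE; break }
  }
  if (!converged)
    warning("maximum-entropy reweighting did not converge after ", it,
            " iterations; returning last iterate")
  new("MaxEntResult", weights = w, prior = prior, gamma = gamma,
      populations = popsOf(w), kl = klOf(w),
      msd = mean((cg$pred - obs)^2), rho = rr, converged = converged,
      iterations = it)
}

#' Scan the regularization ladder and pick the L-curve knee
#'
#' Runs [maxentReweight()] over a log-spaced ladder of \eqn{\gamma} values
#' and selects the knee of the L-curve (KL divergence versus log mean-square
#' deviation) as the point of maximum distance from the chord connecting
#' the curve's ends.
#'
#' @inheritParams maxentReweight
#' @param gammas numeric ladder (default `10^seq(-1, 5, by = 0.5)`).
#' @return list with `results` (one [MaxEntResult-class] per gamma),
#'   `gamma` (the knee) and `best` (its result).
#' @export
maxentScan <- function(prior, lnP, kInt, data, gammas = 10^seq(-1, 5, 0.5),
                       ...) {
  results <- lapply(gammas, function(g)
    maxentReweight(prior, lnP, kInt, data, gamma = g, ...))
  msd <- vapply(results, function(r) r@msd, numeric(1))
  kl <- vapply(results, function(r) r@kl, numeric(1))
  x <- log10(pmax(msd, 1e-300)); y <- kl
  x1 <- x[1]; y1 <- y[1]; x2 <- x[length(x)]; y2 <- y[length(y)]
  dd <- abs((x2 - x1) * (y1 - y) - (x1 - x) * (y2 - y1)) /
    sqrt((x2 - x1)^2 + (y2 - y1)^2 + 1e-300)
  knee <- which.max(dd)
  list(results = results, gamma = gammas[knee], best = results[[knee]],
       msd = msd, kl = kl)
}
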