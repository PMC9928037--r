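#' Construct a StructureFrame
#'
#' @param atoms data.frame with columns `resid` (1-based residue index),
#'   `name` (atom name), `x`, `y`, `z` (nm).
#' @param waters numeric n x 3 matrix of water-oxygen coordinates, nm.
#' @param ions numeric n x 3 matrix with rownames naming each ion, nm.
#' @return a [StructureFrame-class].
#' @export
structureFrame <- function(atoms, waters = matrix(numeric(0), 0, 3),
                           ions = matrix(numeric(0), 0, 3)) {
  atoms$resid <- as.integer(atoms$resid)
  new("StructureFrame", atoms = as.data.frame(atoms),
      waters = as.matrix(waters), ions = as.matrix(ions))
}

#' Idealized two-state reference conformations
#'
#' Builds a pair of reference conformations of a small helical-hairpin toy
#' protein: two helices whose separation differs between a "closed" (A) and
#' an "open" (B) state, emulating the kind of outward/inward-facing
#' structural contrast the pipeline is meant to resolve.  Each residue
#' carries CA, N, H and O atoms with simple chain geometry so that contact
#' counts, amide environments and water accessibility are all well defined.
#' State B additionally has water oxygens placed in the opened inter-helix
#' cleft; state A keeps a few surface waters only.
#'
#' @param nResidues total residues (split over the two helices); default 30.
#' @param opening extra inter-helix separation of state B, nm; default 0.8.
#' @param nWatersA,nWatersB water-oxygen placements per state.
#' @param seed integer seed for the deterministic water placement.
#' @return list with `A` and `B` ([StructureFrame-class]).
#' @export
referenceConformations <- function(nResidues = 30, opening = 0.8,
                                   nWatersA = 10, nWatersB = 40,
                                   seed = 1L) {
  half <- nResidues %/% 2
  helix <- function(n, origin, direction = 1) {
    i <- seq_len(n) - 1
    cbind(x = origin[1] + 0.23 * cos(i * 100 * pi / 180),
          y = origin[2] + 0.23 * sin(i * 100 * pi / 180),
          z = origin[3] + direction * 0.15 * i)
  }
  build <- function(sep) {
    ca <- rbind(helix(half, c(0, 0, 0), 1),
                helix(nResidues - half, c(sep, 0, 0.15 * (half - 1)), -1))
    n <- nrow(ca)
    prev <- rbind(ca[1, ] - c(0.1, 0.1, 0.1), ca[-n, ])
    nxt <- rbind(ca[-1, ], ca[n, ] + c(0.1, 0.1, 0.1))
    nPos <- 0.75 * ca + 0.25 * prev
    oPos <- 0.75 * ca + 0.25 * nxt
    perp <- cbind(-(nxt - prev)[, 2], (nxt - prev)[, 1], 0)
    perp <- perp / pmax(sqrt(rowSums(perp^2)), 1e-9)
    hPos <- nPos + 0.1 * perp
    atoms <- data.frame(
      resid = rep(seq_len(n), 4),
      name = rep(c("CA", "N", "H", "O"), each = n),
      rbind(ca, nPos, hPos, oPos))
    names(atoms)[3:5] <- c("x", "y", "z")
    atoms[order(atoms$resid), ]
  }
  refA <- build(0.55)
  refB <- build(0.55 + opening)
  set.seed(seed)
  boxA <- c(0.55 / 2, 0, 0.15 * half / 2)
  watersA <- sweep(matrix(rnorm(nWatersA * 3, sd = 0.6), ncol = 3), 2,
                   boxA + c(0, 0.8, 0), `+`)
  boxB <- c((0.55 + opening) / 2, 0, 0.15 * half / 2)
  watersB <- sweep(matrix(runif(nWatersB * 3, -0.5, 0.5), ncol = 3) *
                     matrix(c(opening, 0.8, 0.15 * half), nWatersB, 3,
                            byrow = TRUE), 2, boxB, `+`)
  list(A = structureFrame(refA, waters = watersA),
       B = structureFrame(refB, waters = watersB))
}

#' Generate a two-state structural ensemble
#'
#' Draws frames from two reference conformations: each frame picks state A
#' with probability `mixing`, then adds isotropic Gaussian jitter to every
#' atom (and water oxygen).  State labels and the generator settings are
#' returned with the frames, so downstream reweighting can be validated
#' against known ground truth.
#'
#' @param referenceA,referenceB [StructureFrame-class] references sharing
#'   atom count and ordering.
#' @param nFrames number of frames.
#' @param mixing probability of state A per frame.
#' @param jitter isotropic Gaussian jitter s.d., nm.
#' @param seed integer seed.
#' @return list with `frames` (list of [StructureFrame-class]), `states`
#'   (character vector "A"/"B") and `spec` (the generator settings).
#' @export
generateTwoStateStructures <- function(referenceA, referenceB, nFrames,
                                       mixing = 0.5, jitter = 0.02,
                                       seed = 1L) {
  stopifnot(is(referenceA, "StructureFrame"), is(referenceB, "StructureFrame"),
            nrow(referenceA@atoms) == nrow(referenceB@atoms),
            identical(referenceA@atoms$name, referenceB@atoms$name),
            mixing >= 0, mixing <= 1, jitter >= 0)
  set.seed(seed)
  states <- ifelse(runif(nFrames) < mixing, "A", "B")
  frames <- lapply(seq_len(nFrames), function(i) {
    ref <- if (states[i] == "A") referenceA else referenceB
    at <- ref@atoms
    na <- nrow(at)
    if (jitter > 0)
      at[, c("x", "y", "z")] <- at[, c("x", "y", "z")] +
        matrix(rnorm(3 * na, sd = jitter), na, 3)
    w <- ref@waters
    if (jitter > 0 && nrow(w) > 0)
      w <- w + matrix(rnorm(3 * nrow(w), sd = jitter), nrow(w), 3)
    structureFrame(at, waters = w, ions = ref@ions)
  })
  list(frames = frames, states = states,
       spec = list(nFrames = nFrames, mixing = mixing, jitter = jitter,
                   seed = seed))
}

#' Generate a synthetic HDX-MS dataset with known ground truth
#'
#' Simulates fragment-level deuterated fractions for a two-or-more-state
#' system with known state populations, per-state per-residue protection
#' factors, intrinsic exchange rates, and a back-exchange retention factor
#' \eqn{\rho}.  The observed fraction of a fragment at exposure time t is
#' \deqn{D = \rho \sum_s p_s \frac{1}{m}\sum_{r}
#'       \left[1 - e^{-k^{int}_r t / P_{s,r}}\right] + \epsilon,}
#' where the sum over r runs over the fragment's exchange-competent residues
#' (the range minus its first residue and minus prolines) and the Gaussian
#' noise \eqn{\epsilon} is clipped so fractions stay in [0, 1].  The
#' noise-free values and the generating parameters are returned as ground
#' truth.
#'
#' @param fragments data.frame with columns `start`, `end` (1-based,
#'   inclusive residue ranges).
#' @param times exposure times, s.
#' @param populations named numeric state populations summing to 1.
#' @param lnPByState named list (one entry per state) of per-residue ln
#'   protection factors (vectors indexed by residue, length >= max residue).
#' @param kInt per-residue intrinsic exchange rates, 1/s (scalar recycled).
#' @param rho back-exchange retention factor in (0, 1].
#' @param noiseSd Gaussian noise s.d. on fractions; 0 for noiseless.
#' @param prolines integer residue indices excluded from exchange.
#' @param construct label recorded in the output table.
#' @param seed integer seed.
#' @return list with `data` (data.frame: fragment_start, fragment_end,
#'   time_s, fraction, construct) and `truth` (populations, rho, noise-free
#'   fractions).
#' @export
generateHDXDataset <- function(fragments, times, populations, lnPByState,
                               kInt, rho = 1, noiseSd = 0,
                               prolines = integer(0), construct = "WT",
                               seed = 1L) {
  stopifnot(abs(sum(populations) - 1) < 1e-12, rho > 0, rho <= 1,
            all(names(populations) %in% names(lnPByState)))
  maxRes <- max(fragments$end)
  kInt <- rep_len(kInt, maxRes)
  set.seed(seed)
  rows <- expand.grid(frag = seq_len(nrow(fragments)), time = times)
  ## population-weighted mean over states of the fragment-averaged uptake
  pre <- vapply(seq_len(nrow(rows)), function(i) {
    fr <- fragments[rows$frag[i], ]
    res <- exchangeCompetentResidues(fr$start, fr$end, prolines)
    if (length(res) == 0) stop("fragment with no exchange-competent residues")
    t <- rows$time[i]
    sum(vapply(names(populations), function(s) {
      P <- exp(lnPByState[[s]][res])
      populations[[s]] * mean(1 - exp(-kInt[res] * t / P))
    }, numeric(1)))
  }, numeric(1))
  obs <- rho * pre
  if (noiseSd > 0) obs <- pmin(1, pmax(0, obs + rnorm(length(obs), sd = noiseSd)))
  data <- data.frame(fragment_start = fragments$start[rows$frag],
                     fragment_end = fragments$end[rows$frag],
                     time_s = rows$time, fraction = obs,
                     construct = construct)
  list(data = data,
       truth = list(populations = populations, rho = rho,
                    noiseFree = rho * pre, preBackExchange = pre))
}
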