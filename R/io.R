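## Readers/writers for the PLUMED-style COLVAR/HILLS dialects, PDB
## structures, HDX CSV tables and grid containers.

.readFields <- function(path) {
  lines <- readLines(path)
  if (length(lines) == 0 || !startsWith(lines[1], "#! FIELDS"))
    stop("malformed header: file must start with '#! FIELDS'")
  fields <- strsplit(trimws(sub("^#! FIELDS", "", lines[1])), "\\s+")[[1]]
  body <- lines[!startsWith(lines, "#")]
  body <- body[nzchar(trimws(body))]
  rows <- strsplit(trimws(body), "\\s+")
  lens <- lengths(rows)
  if (any(lens != length(fields))) {
    bad <- which(lens != length(fields))[1]
    badLine <- which(!startsWith(lines, "#") & nzchar(trimws(lines)))[bad]
    stop("ragged row at line ", badLine, ": expected ", length(fields),
         " fields, found ", lens[bad])
  }
  m <- matrix(as.numeric(unlist(rows)), ncol = length(fields), byrow = TRUE)
  colnames(m) <- fields
  as.data.frame(m)
}

.writeFields <- function(df, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste("#! FIELDS", paste(names(df), collapse = " ")), con)
  body <- do.call(paste, c(lapply(df, function(x) sprintf("%.17g", x)),
                           sep = " "))
  writeLines(body, con)
}

#' Read a COLVAR-dialect file
#'
#' Parses the PLUMED-style whitespace-separated table with a
#' `#! FIELDS time cv... bias` header.  Columns are mapped by name; any
#' extra columns are preserved.  A missing `bias` column is treated as zero
#' bias with a warning; a ragged row is an error naming the line.
#'
#' @param path file path.
#' @return data.frame with one column per field (`bias` always present).
#' @export
readColvar <- function(path) {
  df <- .readFields(path)
  if (!"time" %in% names(df)) stop("COLVAR file lacks a 'time' column")
  if (!"bias" %in% names(df)) {
    warning("no 'bias' column: bias treated as 0")
    df$bias <- 0
  }
  df
}

#' Write a trajectory in the COLVAR dialect
#'
#' Emits `time`, one column per CV, the instantaneous `bias`, and (for
#' biased CVs) `biasgrad_*` columns carrying the bias gradient, at full
#' double precision so round trips are exact to 1e-12 and better.
#'
#' @param trajectory a [ReplicaTrajectory-class].
#' @param path output file.
#' @param cvNames CV column names (default `cv1`, `cv2`, ...).
#' @return `path`, invisibly.
#' @export
writeColvar <- function(trajectory, path, cvNames = NULL) {
  cv <- trajectory@cv
  if (is.null(cvNames)) cvNames <- paste0("cv", seq_len(ncol(cv)))
  df <- data.frame(time = trajectory@time)
  for (j in seq_len(ncol(cv))) df[[cvNames[j]]] <- cv[, j]
  df$bias <- trajectory@biasPotential
  for (j in seq_along(trajectory@biasedCVs))
    df[[paste0("biasgrad_", cvNames[trajectory@biasedCVs[j]])]] <-
      trajectory@biasGradient[, j]
  .writeFields(df, path)
  invisible(path)
}

#' Convert a COLVAR table into a ReplicaTrajectory
#'
#' @param df data.frame from [readColvar()].
#' @param replicaId integer label.
#' @param biasedCVs integer indices of the biased CVs; inferred from
#'   `biasgrad_*` columns if `NULL`.
#' @param temperature K.
#' @param hills optional hills matrix from [readHills()].
#' @return a [ReplicaTrajectory-class].
#' @export
asReplicaTrajectory <- function(df, replicaId = 1L, biasedCVs = NULL,
                                temperature = 298, hills = NULL) {
  cvCols <- setdiff(names(df),
                    c("time", "bias", grep("^biasgrad_", names(df),
                                           value = TRUE)))
  gradCols <- grep("^biasgrad_", names(df), value = TRUE)
  if (is.null(biasedCVs))
    biasedCVs <- match(sub("^biasgrad_", "", gradCols), cvCols)
  grad <- if (length(gradCols)) as.matrix(df[gradCols])
          else matrix(numeric(0), nrow(df), 0)
  if (is.null(hills)) hills <- .emptyHills(length(biasedCVs))
  new("ReplicaTrajectory", replicaId = as.integer(replicaId),
      biasedCVs = as.integer(biasedCVs), time = df$time,
      cv = as.matrix(df[cvCols]), biasPotential = df$bias,
      biasGradient = grad, temperature = temperature, hills = hills)
}

#' Write deposited hills in the HILLS dialect
#'
#' Header `#! FIELDS time center_* sigma_* height`.
#'
#' @param hills hills matrix (as in a [ReplicaTrajectory-class]).
#' @param path output file.
#' @param cvNames names of the biased CVs.
#' @return `path`, invisibly.
#' @export
writeHills <- function(hills, path, cvNames = NULL) {
  m <- (ncol(hills) - 2L) %/% 2L
  if (is.null(cvNames)) cvNames <- paste0("cv", seq_len(m))
  df <- data.frame(time = hills[, 2 * m + 2])
  for (j in seq_len(m)) df[[paste0("center_", cvNames[j])]] <- hills[, j]
  for (j in seq_len(m)) df[[paste0("sigma_", cvNames[j])]] <- hills[, m + j]
  df$height <- hills[, 2 * m + 1]
  .writeFields(df, path)
  invisible(path)
}

#' Read a HILLS-dialect file
#'
#' @param path file path.
#' @return hills matrix with columns `center_*`, `sigma_*`, `height`,
#'   `time`, as used by [biasFromHills()].
#' @export
readHills <- function(path) {
  df <- .readFields(path)
  cn <- grep("^center_", names(df), value = TRUE)
  sn <- grep("^sigma_", names(df), value = TRUE)
  if (!length(cn) || length(cn) != length(sn) || !"height" %in% names(df) ||
      !"time" %in% names(df))
    stop("not a HILLS file: need center_*, sigma_*, height, time columns")
  as.matrix(cbind(df[cn], df[sn], df["height"], df["time"]))
}

#' Read the CV-relevant atoms of a PDB file
#'
#' Extracts, via `bio3d`, the protein atoms (with 1-based residue numbers
#' and atom names), water oxygens (residue names HOH/TIP3/WAT/SOL, atom
#' names O/OW/OH2) and common monatomic ions, keeping altloc 'A' or blank
#' records and converting Angstrom to nm.  Insertion codes are accepted
#' and flagged with a message.
#'
#' @param path PDB file path.
#' @return a [StructureFrame-class].
#' @export
readPDBCalpha <- function(path) {
  pdb <- bio3d::read.pdb(path)
  at <- pdb$atom
  at <- at[at$alt %in% c("", "A", NA), ]
  if (any(nzchar(at$insert) & !is.na(at$insert)))
    message("insertion codes present in ", basename(path), "; accepted as-is")
  waterRes <- c("HOH", "TIP3", "WAT", "SOL")
  ionRes <- c("NA", "CL", "K", "MG", "ZN", "SOD", "CLA", "POT", "CAL")
  isWater <- at$resid %in% waterRes & at$elety %in% c("O", "OW", "OH2")
  isIon <- at$resid %in% ionRes |
    (at$resid == "CA" & at$type == "HETATM" & at$elety == "CA")
  isProt <- at$type == "ATOM" & !(at$resid %in% waterRes) & !isIon
  prot <- at[isProt, ]
  if (!any(prot$elety == "CA")) stop("no C-alpha records in ", path)
  atoms <- data.frame(resid = as.integer(prot$resno), name = prot$elety,
                      x = prot$x / 10, y = prot$y / 10, z = prot$z / 10)
  waters <- as.matrix(at[isWater, c("x", "y", "z")]) / 10
  if (!is.matrix(waters) || nrow(at[isWater, ]) == 0)
    waters <- matrix(numeric(0), 0, 3)
  ionAt <- at[isIon & !isWater, ]
  ions <- as.matrix(ionAt[, c("x", "y", "z")]) / 10
  if (nrow(ionAt) == 0) ions <- matrix(numeric(0), 0, 3)
  else rownames(ions) <- make.unique(paste0(ionAt$resid, ionAt$resno))
  structureFrame(atoms, waters = waters, ions = ions)
}

#' Read / write HDX CSV tables
#'
#' Plain CSV with columns `fragment_start`, `fragment_end`, `time_s`,
#' `fraction`, `construct`.
#'
#' @param path file path.
#' @return data.frame (`readHDXTable`) or `path` invisibly
#'   (`writeHDXTable`).
#' @export
readHDXTable <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("fragment_start", "fragment_end", "time_s", "fraction")
  if (!all(need %in% names(df)))
    stop("HDX table must have columns ", paste(need, collapse = ", "))
  df
}

#' @rdname readHDXTable
#' @param data HDX data.frame.
#' @export
writeHDXTable <- function(data, path) {
  utils::write.csv(data, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Save / load a CVGrid container
#'
#' Self-describing single-object container (RDS) holding dimension names,
#' edges, counts, free energy and mean-force estimates.
#'
#' @param grid a [CVGrid-class].
#' @param path file path.
#' @return `path` invisibly (`writeCVGrid`) or the [CVGrid-class]
#'   (`readCVGrid`).
#' @export
writeCVGrid <- function(grid, path) {
  stopifnot(is(grid, "CVGrid"))
  saveRDS(grid, path)
  invisible(path)
}

#' @rdname writeCVGrid
#' @export
readCVGrid <- function(path) {
  grid <- readRDS(path)
  stopifnot(is(grid, "CVGrid"))
  validObject(grid)
  grid
}

#' Export a grid or landscape as flat CSV
#'
#' `exportGridCSV` writes one row per bin with the bin-centre coordinates,
#' free energy and count; `exportLandscapeCSV` writes
#' `x_center,y_center,F,stderr`; `exportPathCSV` writes the path steps with
#' bin indices, CV midpoints and F.  Infinite F is exported as empty.
#'
#' @param grid a [CVGrid-class].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
exportGridCSV <- function(grid, path) {
  centers <- lapply(grid@edges, function(e) (e[-1] + e[-length(e)]) / 2)
  df <- expand.grid(centers)
  names(df) <- paste0(grid@cvNames, "_center")
  df$F <- as.numeric(grid@F)
  df$count <- as.integer(grid@counts)
  df$F[!is.finite(df$F)] <- NA
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' @rdname exportGridCSV
#' @param landscape a [Landscape2D-class].
#' @export
exportLandscapeCSV <- function(landscape, path) {
  xc <- (landscape@xEdges[-1] + landscape@xEdges[-length(landscape@xEdges)]) / 2
  yc <- (landscape@yEdges[-1] + landscape@yEdges[-length(landscape@yEdges)]) / 2
  df <- expand.grid(x_center = xc, y_center = yc)
  df$F <- as.numeric(landscape@F)
  df$stderr <- as.numeric(landscape@stderr)
  df$F[!is.finite(df$F)] <- NA
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' @rdname exportGridCSV
#' @param fepath a [FreeEnergyPath-class].
#' @export
exportPathCSV <- function(fepath, path) {
  df <- data.frame(step = seq_len(nrow(fepath@bins)))
  for (d in seq_len(ncol(fepath@bins))) {
    df[[paste0("bin", d)]] <- fepath@bins[, d]
    df[[paste0("cv", d, "_mid")]] <- fepath@midpoints[, d]
  }
  df$progress <- fepath@arcLength
  df$F <- fepath@F
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
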