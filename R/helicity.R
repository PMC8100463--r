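# Per-residue helicity: backbone dihedrals, dihedral-window assignment,
# pooled helicity fractions, segment counts and helical wheels.

#' Backbone phi/psi dihedrals of the peptide
#'
#' Standard IUPAC sign convention; phi of residue 1 and psi of the last
#' residue are undefined (NA). A missing backbone atom is a hard error
#' naming the residue.
#'
#' @param traj a [Trajectory-class]
#' @param frames frame indices (default all)
#' @return array dim c(nResidues, 2, nFrames); columns "phi", "psi" (degrees)
#' @export
backboneDihedrals <- function(traj, frames = NULL) {
  topo <- traj@topology
  a <- topo@atoms
  nRes <- topo@peptideResidueCount
  if (is.null(frames)) frames <- seq_len(nFrames(traj))
  idx <- function(at) {
    i <- vapply(seq_len(nRes), function(r) {
      j <- which(a$molecule_class == "peptide" & a$residue_index == r &
                 a$atom_name == at)
      if (!length(j)) stop(sprintf("missing backbone atom %s in residue %d", at, r))
      j[1]
    }, integer(1))
    i
  }
  iN <- idx("N"); iCA <- idx("CA"); iC <- idx("C")
  out <- array(NA_real_, dim = c(nRes, 2, length(frames)),
               dimnames = list(NULL, c("phi", "psi"), NULL))
  for (fi in seq_along(frames)) {
    x <- traj@coords[, , frames[fi], drop = TRUE]
    N <- x[iN, , drop = FALSE]; CA <- x[iCA, , drop = FALSE]; C <- x[iC, , drop = FALSE]
    r2 <- 2:nRes
    out[r2, 1, fi] <- .dihedral(C[r2 - 1, , drop = FALSE], N[r2, , drop = FALSE],
                                CA[r2, , drop = FALSE], C[r2, , drop = FALSE])
    r1 <- 1:(nRes - 1)
    out[r1, 2, fi] <- .dihedral(N[r1, , drop = FALSE], CA[r1, , drop = FALSE],
                                C[r1, , drop = FALSE], N[r1 + 1, , drop = FALSE])
  }
  out
}

#' Assign per-residue helicity from dihedrals
#'
#' A residue is helical iff its (phi, psi) falls inside the helical window
#' and it belongs to a run of at least \code{minRun} consecutive in-window
#' residues. Residues with undefined phi or psi (chain termini) are never
#' helical.
#'
#' @param dihedrals output of [backboneDihedrals()] (or a single
#'   nRes x 2 matrix)
#' @param window c(phiMin, phiMax, psiMin, psiMax) in degrees
#' @param minRun minimum run length of in-window residues
#' @return logical matrix nFrames x nResidues
#' @export
assignHelical <- function(dihedrals,
                          window = c(phiMin = -100, phiMax = -30,
                                     psiMin = -80, psiMax = -5),
                          minRun = 3) {
  if (length(dim(dihedrals)) == 2) dim(dihedrals) <- c(dim(dihedrals), 1)
  nRes <- dim(dihedrals)[1]; F <- dim(dihedrals)[3]
  out <- matrix(FALSE, F, nRes)
  for (f in seq_len(F)) {
    phi <- dihedrals[, 1, f]; psi <- dihedrals[, 2, f]
    inw <- !is.na(phi) & !is.na(psi) &
           phi >= window[1] & phi <= window[2] &
           psi >= window[3] & psi <= window[4]
    r <- rle(inw)
    keep <- r$values & r$lengths >= minRun
    out[f, ] <- inverse.rle(list(lengths = r$lengths, values = keep))
  }
  out
}

#' Compute a helicity trace for a trajectory
#'
#' @param traj a [Trajectory-class]
#' @param ... passed to [assignHelical()]
#' @return object of class "HelicityTrace": list(trace = frames x residues
#'   logical matrix, label)
#' @export
helicityTrace <- function(traj, ...) {
  tr <- assignHelical(backboneDihedrals(traj), ...)
  structure(list(trace = tr, label = NA_character_), class = "HelicityTrace")
}

.traceMatrix <- function(x) {
  if (inherits(x, "HelicityTrace")) x$trace
  else if (is.matrix(x)) x
  else stop("expected a HelicityTrace or logical matrix")
}

#' Per-residue helicity fraction pooled over repeats
#'
#' The fraction of accumulated simulation time each residue is helical:
#' pooling across repeats is frame-weighted (all frames count equally).
#'
#' @param x a HelicityTrace, a logical matrix, or a list of either
#' @return numeric vector of per-residue fractions in [0, 1]
#' @export
helicityFraction <- function(x) {
  if (inherits(x, "HelicityTrace") || is.matrix(x)) x <- list(x)
  mats <- lapply(x, .traceMatrix)
  tot <- Reduce(`+`, lapply(mats, colSums))
  n <- sum(vapply(mats, nrow, integer(1)))
  if (n < 1) stop("need at least one frame")
  tot / n
}

#' Helical-residue counts per segment with final-window statistics
#'
#' Counts helical residues per frame in each segment (default the N-terminal
#' residues 1-19 and C-terminal 20-37) and summarizes mean and SD over the
#' final fraction of frames (default the last half, matching the analysis of
#' the last 0.5 us of 1 us runs).
#'
#' @param x a HelicityTrace or logical trace matrix
#' @param segments named list of residue index vectors
#' @param window final fraction of frames for the summary, in (0, 1]
#' @return list(series = frames x segments count matrix,
#'   summary = data.frame(segment, mean, sd, nFrames))
#' @export
segmentCounts <- function(x, segments = list(`1-19` = 1:19, `20-37` = 20:37),
                          window = 0.5) {
  if (window <= 0 || window > 1) stop("window must be in (0, 1]")
  tr <- .traceMatrix(x)
  F <- nrow(tr)
  counts <- vapply(segments, function(s) rowSums(tr[, s, drop = FALSE]),
                   numeric(F))
  if (is.null(dim(counts))) counts <- matrix(counts, nrow = F)
  colnames(counts) <- names(segments)
  wIdx <- (F - floor(window * F) + 1):F
  sm <- data.frame(
    segment = names(segments),
    mean = apply(counts[wIdx, , drop = FALSE], 2, mean),
    sd = apply(counts[wIdx, , drop = FALSE], 2, stats::sd),
    nFrames = length(wIdx),
    row.names = NULL
  )
  list(series = counts, summary = sm)
}

#' Per-repeat segment-count summary for a series
#'
#' @param series a [TrajectorySeries-class]
#' @param ... passed to [segmentCounts()] / [assignHelical()]
#' @inheritParams segmentCounts
#' @return data.frame(repeat, segment, mean, sd)
#' @export
segmentCountSummary <- function(series,
                                segments = list(`1-19` = 1:19, `20-37` = 20:37),
                                window = 0.5, ...) {
  out <- lapply(seq_along(series@repeats), function(i) {
    sc <- segmentCounts(helicityTrace(series@repeats[[i]], ...),
                        segments = segments, window = window)
    cbind(data.frame(repeat_ = i), sc$summary)
  })
  do.call(rbind, out)
}

#' Helical-wheel projection
#'
#' Projects residues onto the plane perpendicular to the helix axis at 100
#' degrees per residue and flags the hydrophobic face of the membrane-bound
#' IAPP helices (Ala8, Leu12, Phe15, Leu16, Phe23, Ile26, Leu27).
#'
#' @param residues residue index vector (e.g. 8:16)
#' @param startAngle angle of the first residue in degrees
#' @return data.frame(residue, name, angle, x, y, hydrophobic, face)
#' @export
helicalWheel <- function(residues, startAngle = 0) {
  if (!length(residues)) stop("empty residue range")
  sq <- iappSequence()
  ang <- (startAngle + (seq_along(residues) - 1) * 100) %% 360
  nm <- ifelse(residues >= 1 & residues <= 37, sq[residues], NA)
  data.frame(
    residue = residues,
    name = nm,
    angle = ang,
    x = cos(ang * pi / 180),
    y = sin(ang * pi / 180),
    hydrophobic = nm %in% .HYDROPHOBIC_AA,
    face = residues %in% .IAPP_FACE
  )
}
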