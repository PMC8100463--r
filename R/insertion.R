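# Insertion depth relative to the phosphate plane, per-condition profiles
# and between-condition delta profiles with Welch significance bands.

#' Phosphate-plane z coordinate per frame
#'
#' Arithmetic mean z of phospholipid phosphate beads, by default of the
#' peptide-bound leaflet only (a both-leaflet plane would sit mid-membrane).
#' Leaflet membership is taken from the first frame; the plane itself is
#' recomputed per frame.
#'
#' @param traj a [Trajectory-class]
#' @param mode "bound" (default) or "both"
#' @param frames frame indices (default all)
#' @return numeric vector of plane z (Angstrom) per frame
#' @export
phosphatePlaneZ <- function(traj, mode = c("bound", "both"), frames = NULL) {
  mode <- match.arg(mode)
  if (is.null(frames)) frames <- seq_len(nFrames(traj))
  topo <- traj@topology
  h <- .lipidHeads(topo)
  if (!length(h$phosIdx)) stop("no phosphate atoms in selection")
  asg <- assignLeaflets(traj, frames[1])
  sel <- if (mode == "both") seq_along(h$phosIdx) else {
    leafOfPhos <- asg$leaflet[as.character(h$phosMol)]
    which(leafOfPhos == asg$boundLeaflet)
  }
  if (!length(sel)) stop("no phosphate atoms in selection")
  pz <- traj@coords[h$phosIdx[sel], 3, frames, drop = FALSE]
  colMeans(matrix(pz, length(sel), length(frames)))
}

#' Per-residue time-averaged signed distance to the phosphate plane
#'
#' distance_i = mean over frames of the Calpha z minus the plane z, with
#' the sign oriented so that positive means above the plane toward water
#' and negative means inserted toward the acyl tails (for a peptide bound
#' to the lower leaflet the raw difference is negated accordingly).
#'
#' @param traj a [Trajectory-class]
#' @param mode plane mode, see [phosphatePlaneZ()]
#' @param perFrame if TRUE also return the frames x residues matrix
#' @return numeric vector of per-residue mean signed distances (Angstrom);
#'   with \code{perFrame=TRUE} a list(mean, perFrame)
#' @export
residueDepthProfile <- function(traj, mode = c("bound", "both"),
                                perFrame = FALSE) {
  mode <- match.arg(mode)
  topo <- traj@topology
  a <- topo@atoms
  nRes <- topo@peptideResidueCount
  caIdx <- vapply(seq_len(nRes), function(r) {
    j <- which(a$molecule_class == "peptide" & a$residue_index == r &
               a$atom_name == "CA")
    if (!length(j)) stop(sprintf("missing CA atom in residue %d", r))
    j[1]
  }, integer(1))
  plane <- phosphatePlaneZ(traj, mode)
  asg <- assignLeaflets(traj, 1)
  sgn <- if (identical(asg$boundLeaflet, "lower")) -1 else 1
  F <- nFrames(traj)
  caz <- matrix(traj@coords[caIdx, 3, ], nRes, F)
  d <- sgn * sweep(caz, 2, plane)
  m <- rowMeans(d)
  names(m) <- seq_len(nRes)
  if (perFrame) list(mean = m, perFrame = t(d)) else m
}

#' Residue insertion profile of a condition series
#'
#' @param series a [TrajectorySeries-class]
#' @param mode plane mode, see [phosphatePlaneZ()]
#' @return object of class "ResidueProfile": list(label, perRepeat
#'   (repeats x residues matrix of time-mean signed distances), mean, sd)
#' @export
residueProfile <- function(series, mode = c("bound", "both")) {
  mode <- match.arg(mode)
  pr <- t(vapply(series@repeats,
                 function(t) residueDepthProfile(t, mode),
                 numeric(topology(series)@peptideResidueCount)))
  structure(list(
    label = series@label,
    perRepeat = pr,
    mean = colMeans(pr),
    sd = apply(pr, 2, stats::sd)
  ), class = "ResidueProfile")
}

#' @export
print.ResidueProfile <- function(x, ...) {
  cat("ResidueProfile '", x$label, "': ", nrow(x$perRepeat), " repeats x ",
      ncol(x$perRepeat), " residues\n", sep = "")
  cat(sprintf("  mean depth range [%.2f, %.2f] Angstrom\n",
              min(x$mean), max(x$mean)))
  invisible(x)
}

.bandFromP <- function(p) {
  factor(ifelse(p <= 0.05, "significant",
                ifelse(p < 0.10, "marginal", "nonsignificant")),
         levels = c("significant", "marginal", "nonsignificant"))
}

#' Delta membrane-distance profile between two condition series
#'
#' Per residue, the difference of cross-repeat mean insertion depths
#' (B minus A) with a two-sample t test using the per-repeat time means as
#' the statistical observations (frames are autocorrelated; repeats are the
#' independent unit). Welch's unequal-variance test is the default. Bands:
#' significant p <= 0.05, marginal 0.05 < p < 0.10, nonsignificant
#' p >= 0.10.
#'
#' @param a,b "ResidueProfile" objects from [residueProfile()]
#' @param varEqual use the pooled-variance t test instead of Welch
#' @return object of class "ResidueDeltaProfile": data.frame(residue,
#'   delta, pooledSD, p, band) with attributes "labels"
#' @export
deltaProfile <- function(a, b, varEqual = FALSE) {
  stopifnot(inherits(a, "ResidueProfile"), inherits(b, "ResidueProfile"))
  if (nrow(a$perRepeat) < 2 || nrow(b$perRepeat) < 2)
    stop("the t test is undefined with fewer than 2 repeats per series")
  nRes <- ncol(a$perRepeat)
  delta <- numeric(nRes); p <- numeric(nRes); psd <- numeric(nRes)
  for (r in seq_len(nRes)) {
    xa <- a$perRepeat[, r]; xb <- b$perRepeat[, r]
    delta[r] <- mean(xb) - mean(xa)
    p[r] <- if (stats::sd(xa) == 0 && stats::sd(xb) == 0) {
      if (abs(delta[r]) < .Machine$double.eps^0.5) 1 else 0
    } else {
      stats::t.test(xb, xa, var.equal = varEqual)$p.value
    }
    na <- length(xa); nb <- length(xb)
    psd[r] <- sqrt(((na - 1) * stats::var(xa) + (nb - 1) * stats::var(xb)) /
                     (na + nb - 2))
  }
  out <- data.frame(residue = seq_len(nRes), delta = delta, pooledSD = psd,
                    p = p, band = .bandFromP(p))
  attr(out, "labels") <- c(a$label, b$label)
  class(out) <- c("ResidueDeltaProfile", "data.frame")
  out
}
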