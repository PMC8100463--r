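# Membrane physical properties: area per lipid, lateral diffusion from MSD,
# acyl-chain order parameter, bilayer thickness from phosphate density.

#' Area per lipid
#'
#' Lateral box area divided by the number of lipids per leaflet, averaged
#' over the two leaflets. Cholesterol is counted in the denominator by
#' default; set \code{countChol = FALSE} to restrict the count to
#' phospholipids (both conventions are in circulation).
#'
#' @param traj a [Trajectory-class]
#' @param countChol include phosphate-free lipids (sterols) in the count
#' @param frames frame indices (default all)
#' @return list(perFrame = numeric vector of APL per frame, mean)
#' @export
areaPerLipid <- function(traj, countChol = TRUE, frames = NULL) {
  if (is.null(frames)) frames <- seq_len(nFrames(traj))
  asg <- assignLeaflets(traj, frames[1])
  a <- traj@topology@atoms
  mols <- as.integer(names(asg$leaflet))
  if (!countChol) {
    h <- .lipidHeads(traj@topology)
    mols <- setdiff(mols, h$sterolMol)
  }
  leaf <- asg$leaflet[as.character(mols)]
  nUp <- sum(leaf == "upper"); nLo <- sum(leaf == "lower")
  if (nUp == 0 || nLo == 0) stop("empty leaflet")
  area <- traj@box[frames, 1] * traj@box[frames, 2]
  perFrame <- area * (1 / nUp + 1 / nLo) / 2
  list(perFrame = perFrame, mean = mean(perFrame))
}

## ---- mean squared displacement ----------------------------------------

# FFT-based per-signal MSD over all time origins:
# msd(tau) = S1(tau) - 2 S2(tau), S2 = autocorrelation.
.msd1d <- function(x) {
  N <- length(x)
  nf <- 2^ceiling(log2(2 * N))
  fx <- stats::fft(c(x, rep(0, nf - N)))
  s2 <- Re(stats::fft(fx * Conj(fx), inverse = TRUE))[1:N] / nf
  D <- x^2
  ss <- 2 * sum(D)
  s1 <- numeric(N)
  for (m in 0:(N - 1)) {
    if (m > 0) ss <- ss - D[m] - D[N - m + 1]
    s1[m + 1] <- ss / (N - m)
  }
  s1 - 2 * s2 / (N - 0:(N - 1))
}

.msdTracks <- function(xy, stride = 1L) {
  # xy: array nMol x 2 x F (unwrapped); returns mean MSD over molecules
  nMol <- dim(xy)[1]; F <- dim(xy)[3]
  if (stride == 1L) {
    tot <- numeric(F)
    for (m in seq_len(nMol)) {
      tot <- tot + .msd1d(xy[m, 1, ]) + .msd1d(xy[m, 2, ])
    }
    tot / nMol
  } else {
    lags <- 0:(F - 1)
    out <- numeric(F)
    for (li in seq_along(lags)) {
      tau <- lags[li]
      org <- seq(1, F - tau, by = stride)
      d1 <- xy[, 1, org + tau, drop = FALSE] - xy[, 1, org, drop = FALSE]
      d2 <- xy[, 2, org + tau, drop = FALSE] - xy[, 2, org, drop = FALSE]
      out[li] <- mean(d1 * d1 + d2 * d2)
    }
    out
  }
}

# unwrap wrapped lateral tracks by minimum-image increments
.unwrapTracks <- function(xy, box) {
  F <- dim(xy)[3]
  if (F < 2) return(xy)
  out <- xy
  for (ax in 1:2) {
    d <- xy[, ax, -1, drop = FALSE] - xy[, ax, -F, drop = FALSE]
    d <- .wrapHalf(d, box[ax])
    out[, ax, -1] <- out[, ax, 1] + aperm(apply(d, c(1, 2), cumsum), c(2, 3, 1))
  }
  out
}

#' Lateral mean squared displacement
#'
#' MSD(tau) = <|r_xy(t+tau) - r_xy(t)|^2> over molecules and time origins.
#' For a Trajectory the head bead of each lipid of the species is tracked,
#' coordinates are unwrapped by minimum-image increments, and the lateral
#' centre-of-mass drift of each leaflet is removed before accumulating
#' (leaflets can drift oppositely, inflating D otherwise). All time origins
#' are used by default (FFT accumulation); \code{originStride > 1} switches
#' to strided direct summation.
#'
#' @param x a [Trajectory-class], or an unwrapped track array
#'   dim c(nMol, 2, nFrames)
#' @param species lipid species to track (Trajectory input)
#' @param dt frame spacing in ps (required for array input; taken from the
#'   trajectory otherwise)
#' @param removeDrift remove per-leaflet lateral COM drift (Trajectory input)
#' @param originStride time-origin stride (1 = all origins)
#' @return object of class "MSDCurve": list(lag (ps), msd (A^2), species,
#'   nMolecules)
#' @export
lateralMSD <- function(x, species = NULL, dt = NULL, removeDrift = TRUE,
                       originStride = 1L) {
  if (is(x, "Trajectory")) {
    topo <- x@topology
    a <- topo@atoms
    if (is.null(species)) stop("species required for Trajectory input")
    if (!species %in% a$species) stop("species absent from topology: ", species)
    h <- .lipidHeads(topo)
    mols <- unique(a$molecule_id[a$species == species & a$molecule_class == "lipid"])
    headIdx <- vapply(mols, function(m) which(a$molecule_id == m)[1], integer(1))
    F <- nFrames(x)
    if (F < 2) stop("need at least 2 frames")
    xy <- array(0, dim = c(length(mols), 2, F))
    xy[, 1, ] <- x@coords[headIdx, 1, ]
    xy[, 2, ] <- x@coords[headIdx, 2, ]
    xy <- .unwrapTracks(xy, x@box[1, ])
    if (removeDrift) {
      asg <- assignLeaflets(x, 1)
      leaf <- asg$leaflet[as.character(mols)]
      for (lf in unique(leaf)) {
        # COM drift of the whole leaflet (all species), from head beads
        allMols <- as.integer(names(asg$leaflet))[asg$leaflet == lf]
        allIdx <- vapply(allMols, function(m) which(a$molecule_id == m)[1], integer(1))
        axy <- array(0, dim = c(length(allMols), 2, F))
        axy[, 1, ] <- x@coords[allIdx, 1, ]
        axy[, 2, ] <- x@coords[allIdx, 2, ]
        axy <- .unwrapTracks(axy, x@box[1, ])
        com <- apply(axy, c(2, 3), mean)
        sel <- which(leaf == lf)
        for (ax in 1:2)
          xy[sel, ax, ] <- xy[sel, ax, ] -
            matrix(com[ax, ] - com[ax, 1], length(sel), F, byrow = TRUE)
      }
    }
    if (is.null(dt)) dt <- if (F > 1) diff(x@times[1:2]) else 1
    nMol <- length(mols)
  } else {
    xy <- x
    if (length(dim(xy)) != 3 || dim(xy)[2] != 2)
      stop("track array must have dim c(nMol, 2, nFrames)")
    if (is.null(dt)) stop("dt required for track-array input")
    F <- dim(xy)[3]
    if (F < 2) stop("need at least 2 frames")
    nMol <- dim(xy)[1]
  }
  msd <- .msdTracks(xy, stride = as.integer(originStride))
  structure(list(lag = (0:(F - 1)) * dt, msd = msd,
                 species = if (is.null(species)) NA_character_ else species,
                 nMolecules = nMol),
            class = "MSDCurve")
}

#' Diffusion coefficient from an MSD curve
#'
#' Least-squares line over lags in the fit window (default 10-50% of the
#' maximum lag, avoiding short-time and poorly averaged long-lag regimes);
#' for lateral (2D) diffusion D = slope / 4, converted from A^2/ps to
#' cm^2/s (1 A^2/ps = 1e-4 cm^2/s).
#'
#' @param msd an "MSDCurve" from [lateralMSD()]
#' @param fitWindow c(lo, hi) as fractions of the maximum lag
#' @return list(D (cm^2/s), slope (A^2/ps), intercept, fitWindow, nLags);
#'   a negative fitted slope triggers a warning but is still reported
#' @export
diffusionCoefficient <- function(msd, fitWindow = c(0.1, 0.5)) {
  maxLag <- max(msd$lag)
  sel <- msd$lag >= fitWindow[1] * maxLag & msd$lag <= fitWindow[2] * maxLag
  if (sum(sel) < 2) stop("fewer than 2 lags in the fit window")
  fit <- stats::lm.fit(cbind(1, msd$lag[sel]), msd$msd[sel])
  slope <- fit$coefficients[2]
  if (slope < 0) warning("negative fitted MSD slope; reporting D < 0")
  list(D = unname(slope) / 4 * 1e-4, slope = unname(slope),
       intercept = unname(fit$coefficients[1]),
       fitWindow = fitWindow, nLags = sum(sel))
}

#' Acyl-chain orientational order parameter
#'
#' S = <(3 cos^2 theta - 1)/2> with theta the angle between a tail segment
#' vector and the bilayer normal (+z). For tails with at least three
#' positions the segment vector at position i is atom_{i-1} -> atom_{i+1};
#' sign is retained (S = 1 aligned, -0.5 perpendicular, 0 isotropic).
#'
#' @param traj a [Trajectory-class]
#' @param species lipid species (default: all lipid species pooled)
#' @param tailAtoms ordered atom names of the tail; default all atoms
#'   matching "T<number>" in the species
#' @param frames frame indices (default all)
#' @return list(perPosition (named numeric, one value per interior segment
#'   position), average, species)
#' @export
orderParameter <- function(traj, species = NULL, tailAtoms = NULL,
                           frames = NULL) {
  topo <- traj@topology
  a <- topo@atoms
  if (is.null(frames)) frames <- seq_len(nFrames(traj))
  sp <- if (is.null(species)) unique(a$species[a$molecule_class == "lipid"]) else species
  if (!all(sp %in% a$species)) stop("species absent: ",
                                    paste(setdiff(sp, a$species), collapse = ","))
  perPos <- list()
  for (s in sp) {
    ta <- tailAtoms
    if (is.null(ta)) {
      ta <- unique(a$atom_name[a$species == s & grepl("^T[0-9]+$", a$atom_name)])
      ta <- ta[order(as.integer(sub("T", "", ta)))]
    }
    if (length(ta) < 3)
      stop("fewer than 3 tail positions for the segment definition in ", s)
    mols <- unique(a$molecule_id[a$species == s & a$molecule_class == "lipid"])
    idx <- sapply(ta, function(at) vapply(mols, function(m)
      which(a$molecule_id == m & a$atom_name == at)[1], integer(1)))
    # idx: nMol x nTail matrix of atom rows
    nM <- nrow(idx)
    for (i in 2:(length(ta) - 1)) {
      v <- traj@coords[idx[, i + 1], , frames, drop = FALSE] -
           traj@coords[idx[, i - 1], , frames, drop = FALSE]
      # lateral minimum image: tail beads are wrapped independently
      for (ax in 1:2)
        v[, ax, ] <- .wrapHalf(v[, ax, ],
                               rep(traj@box[frames, ax], each = nM))
      c2 <- (v[, 3, ]^2) / (v[, 1, ]^2 + v[, 2, ]^2 + v[, 3, ]^2)
      key <- ta[i]
      perPos[[key]] <- c(perPos[[key]], mean((3 * c2 - 1) / 2))
    }
  }
  pp <- vapply(perPos, mean, numeric(1))
  list(perPosition = pp, average = mean(pp), species = sp)
}

#' Membrane thickness from phosphate density peaks
#'
#' Pools phosphate z over frames, histograms each leaflet (bin width default
#' 0.5 A), smooths with a Gaussian kernel (sigma default 1 A) and measures
#' the distance between the two leaflet density peaks with parabolic
#' sub-bin interpolation (removing bin-width bias).
#'
#' @param traj a [Trajectory-class]
#' @param binWidth histogram bin width (Angstrom)
#' @param smoothing Gaussian smoothing sigma (Angstrom)
#' @param frames frame indices (default all)
#' @return thickness in Angstrom (print in nm at the reporting layer)
#' @export
membraneThickness <- function(traj, binWidth = 0.5, smoothing = 1,
                              frames = NULL) {
  if (is.null(frames)) frames <- seq_len(nFrames(traj))
  topo <- traj@topology
  h <- .lipidHeads(topo)
  asg <- assignLeaflets(traj, frames[1])
  leafOfPhos <- asg$leaflet[as.character(h$phosMol)]
  if (!all(c("upper", "lower") %in% leafOfPhos))
    stop("phosphates required in both leaflets")
  pz <- matrix(traj@coords[h$phosIdx, 3, frames], length(h$phosIdx),
               length(frames))
  peakOf <- function(z) {
    br <- seq(min(z) - binWidth, max(z) + binWidth, by = binWidth)
    hh <- graphics::hist(z, breaks = br, plot = FALSE)
    dens <- hh$density
    # Gaussian smoothing
    if (smoothing > 0) {
      half <- max(1L, ceiling(3 * smoothing / binWidth))
      kx <- (-half:half) * binWidth
      ker <- exp(-kx^2 / (2 * smoothing^2))
      ker <- ker / sum(ker)
      dens <- stats::filter(c(rep(0, half), dens, rep(0, half)), ker,
                            sides = 2)[(half + 1):(half + length(hh$density))]
    }
    i <- which.max(dens)
    x0 <- hh$mids[i]
    if (i > 1 && i < length(dens)) {
      y1 <- dens[i - 1]; y2 <- dens[i]; y3 <- dens[i + 1]
      den <- (y1 - 2 * y2 + y3)
      if (abs(den) > 1e-12) x0 <- x0 + 0.5 * binWidth * (y1 - y3) / den
    }
    x0
  }
  zu <- as.vector(pz[leafOfPhos == "upper", ])
  zl <- as.vector(pz[leafOfPhos == "lower", ])
  abs(peakOf(zu) - peakOf(zl))
}

#' Membrane property table for a condition series
#'
#' One row per repeat with area per lipid, per-species diffusion
#' coefficients, average order parameter and membrane thickness, mirroring
#' per-simulation property summaries.
#'
#' @param series a [TrajectorySeries-class]
#' @param countChol convention for [areaPerLipid()]
#' @return data.frame with one row per repeat
#' @export
membraneProperties <- function(series, countChol = TRUE) {
  species <- unique(topology(series)@atoms$species[
    topology(series)@atoms$molecule_class == "lipid"])
  rows <- lapply(seq_along(series@repeats), function(i) {
    tr <- series@repeats[[i]]
    apl <- areaPerLipid(tr, countChol = countChol)$mean
    Ds <- vapply(species, function(s)
      diffusionCoefficient(lateralMSD(tr, species = s))$D, numeric(1))
    S <- orderParameter(tr)$average
    th <- membraneThickness(tr)
    df <- data.frame(repeat_ = i, apl_A2 = apl, order_parameter = S,
                     thickness_A = th, thickness_nm = th / 10)
    for (s in species) df[[paste0("D_", s, "_cm2s")]] <- Ds[[s]]
    df
  })
  out <- do.call(rbind, rows)
  attr(out, "label") <- series@label
  out
}
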