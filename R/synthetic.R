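# Synthetic membrane-peptide trajectory generator with planted ground truth.
#
# Lipids are coarse proxies: one head bead (phosphate "P" for phospholipids,
# hydroxyl "O3" for cholesterol) plus a straight run of tail beads realizing
# a sampled orientation. The peptide carries a full N/CA/C/O backbone so
# that dihedral-based helicity assignment is meaningful. Every planted
# quantity (depths, leaflets, loop states, enrichment, binding modes,
# diffusion) is recorded in the returned ground-truth list.

#' Synthetic system configuration
#'
#' Defaults emulate the studied conditions: an 80 x 80 A patch of a
#' DOPC/DOPS/CHOL 45-15-40 bilayer with leaflet phosphate planes at +-19 A
#' (3.8 nm thickness), species diffusion around 7, 5.5 and 3.5 x 1e-8
#' cm^2/s, a straight membrane-bound helix spanning residues 7-28, and a
#' two-state N-terminal loop with a diffuse remainder.
#'
#' @param box lateral box lengths c(Lx, Ly) in Angstrom
#' @param boxHeight box height (Angstrom)
#' @param nLipidsPerLeaflet total lipids per leaflet
#' @param composition named species fractions per leaflet, summing to 1
#' @param leafletZ phosphate plane position (+-leafletZ)
#' @param phosphateSigma Gaussian z spread of head beads (Angstrom)
#' @param diffusion named per-species lateral diffusion coefficients (cm^2/s)
#' @param dt frame spacing (ps)
#' @param nFrames number of frames
#' @param targetOrderParameter tail segment order parameter in [-0.5, 1]
#' @param tailBeads tail beads per lipid (>= 3 for segment-vector order
#'   parameters)
#' @param tailSpacing distance between consecutive tail beads (Angstrom)
#' @param conformation "straight" (helix 7-28) or "kinked" (7-18 and 23-28)
#' @param helicalSegments explicit list of c(first, last) residue ranges,
#'   overriding \code{conformation}
#' @param depthProfile per-residue Calpha depth (Angstrom, negative = below
#'   the bound-leaflet phosphate plane); default alternates -4/-1 mimicking
#'   the hydrophobic/hydrophilic zig-zag
#' @param peptideMode "helix" (backbone with true helical dihedrals; depths
#'   honoured on average) or "depth" (Calpha placed exactly at depthProfile
#'   plus noise; backbone decorative)
#' @param depthSigma per-frame coordinate noise in depth mode (Angstrom)
#' @param loopStateProbs stationary probabilities c(p1, p2) of the two
#'   planted loop orientations; remainder is a diffuse state
#' @param loopSwitchProb per-frame probability of redrawing the loop state
#' @param loopNoise Gaussian positional noise on loop atoms (Angstrom)
#' @param enrichment list(species=, factor=, radius=): acceptance-biased
#'   placement multiplying the probability of the target species occupying
#'   the shell within \code{radius} of peptide residues 1-19; factor 1
#'   disables. Enrichment switches lipid placement from Brownian walks to
#'   per-frame equilibrium placement.
#' @param placement "walk" (Brownian), "iid" (fresh uniform placement each
#'   frame) or "auto" (iid when enrichment is active)
#' @param bindingModes list of planted binding modes, each
#'   list(species=, residues=, distance=3.5, fraction=): one lipid of the
#'   species is teleported to contact the residue pattern in the stated
#'   fraction of frames
#' @param seed integer RNG seed; (config, seed) fully determines the output
#' @return a validated config (class "SyntheticConfig")
#' @export
syntheticConfig <- function(box = c(80, 80), boxHeight = 90,
                            nLipidsPerLeaflet = 100,
                            composition = c(DOPC = 0.45, DOPS = 0.15, CHOL = 0.40),
                            leafletZ = 19, phosphateSigma = 1,
                            diffusion = c(DOPC = 7e-8, DOPS = 5.5e-8, CHOL = 3.5e-8),
                            dt = 400, nFrames = 2500,
                            targetOrderParameter = 0.4,
                            tailBeads = 3, tailSpacing = 2.0,
                            conformation = c("straight", "kinked"),
                            helicalSegments = NULL,
                            depthProfile = rep(c(-4, -1), length.out = 37),
                            peptideMode = c("helix", "depth"),
                            depthSigma = 0.5,
                            loopStateProbs = c(0.38, 0.35),
                            loopSwitchProb = 0.1,
                            loopNoise = 0.3,
                            enrichment = list(species = NULL, factor = 1, radius = 7),
                            placement = c("auto", "walk", "iid"),
                            bindingModes = list(),
                            seed = 1L) {
  conformation <- match.arg(conformation)
  if (is.null(helicalSegments)) {
    helicalSegments <- if (conformation == "straight") list(c(7, 28))
                       else list(c(7, 18), c(23, 28))
  }
  cfg <- list(
    box = box, boxHeight = boxHeight, nLipidsPerLeaflet = nLipidsPerLeaflet,
    composition = composition, leafletZ = leafletZ,
    phosphateSigma = phosphateSigma, diffusion = diffusion, dt = dt,
    nFrames = nFrames, targetOrderParameter = targetOrderParameter,
    tailBeads = tailBeads, tailSpacing = tailSpacing,
    conformation = conformation, helicalSegments = helicalSegments,
    depthProfile = depthProfile, peptideMode = match.arg(peptideMode),
    depthSigma = depthSigma, loopStateProbs = loopStateProbs,
    loopSwitchProb = loopSwitchProb, loopNoise = loopNoise,
    enrichment = enrichment, placement = match.arg(placement),
    bindingModes = bindingModes, seed = as.integer(seed)
  )
  class(cfg) <- "SyntheticConfig"
  .validateSyntheticConfig(cfg)
  cfg
}

.validateSyntheticConfig <- function(cfg) {
  stopifnot(length(cfg$box) == 2, all(cfg$box > 0), cfg$boxHeight > 0)
  if (abs(sum(cfg$composition) - 1) > 1e-6)
    stop("species fractions must sum to 1 per leaflet")
  if (any(cfg$diffusion < 0)) stop("diffusion must be >= 0")
  if (!all(names(cfg$composition) %in% names(cfg$diffusion)))
    stop("every species needs a diffusion coefficient")
  if (cfg$targetOrderParameter < -0.5 || cfg$targetOrderParameter > 1)
    stop("targetOrderParameter must be in [-0.5, 1]")
  p <- cfg$loopStateProbs
  if (length(p) != 2 || any(p < 0) || sum(p) > 1 + 1e-9)
    stop("loopStateProbs must be two non-negative values with p1 + p2 <= 1")
  if (length(cfg$depthProfile) != 37)
    stop("depthProfile must have 37 values")
  if (cfg$dt <= 0) stop("dt must be > 0")
  if (prod(cfg$box) / cfg$nLipidsPerLeaflet < 60)
    stop(sprintf("box too small: %.1f A^2 per lipid < 60", prod(cfg$box) / cfg$nLipidsPerLeaflet))
  en <- cfg$enrichment
  if (!is.null(en$species) && en$factor != 1) {
    ft <- cfg$composition[[en$species]]
    if (en$factor < 0) stop("enrichment factor must be >= 0")
    if (en$factor * ft >= 1)
      stop("enrichment factor x bulk fraction must be < 1")
  }
  for (bm in cfg$bindingModes) {
    if (!bm$species %in% names(cfg$composition))
      stop("binding-mode species not in composition: ", bm$species)
    if (any(bm$residues < 1 | bm$residues > 19))
      stop("binding-mode residues must lie in 1..19")
  }
  invisible(cfg)
}

## ---- tail-vector sampling ---------------------------------------------

.SofLambda <- function(lambda) {
  if (abs(lambda) < 1e-12) return(0)
  den <- stats::integrate(function(c) exp(lambda * (c^2 - max(0, sign(lambda)))),
                          -1, 1, rel.tol = 1e-10)$value
  num <- stats::integrate(function(c) c^2 * exp(lambda * (c^2 - max(0, sign(lambda)))),
                          -1, 1, rel.tol = 1e-10)$value
  (3 * num / den - 1) / 2
}

.lambdaForS <- function(S) {
  lo <- -60; hi <- 600
  if (S <= .SofLambda(lo)) return(lo)
  if (S >= .SofLambda(hi)) return(hi)
  stats::uniroot(function(l) .SofLambda(l) - S, c(lo, hi), tol = 1e-9)$root
}

#' Sample unit tail vectors with a target orientational order parameter
#'
#' Draws cos(theta) from the one-parameter Maier-Saupe-type angular family
#' with density proportional to exp(lambda * cos^2 theta) on [-1, 1]; the
#' mapping lambda -> S = <(3 cos^2 theta - 1)/2> is inverted numerically, so
#' the sample order parameter converges to \code{targetS} as n grows.
#'
#' @param targetS desired order parameter in [-0.5, 1]
#' @param n number of vectors
#' @return n x 3 matrix of unit vectors (theta measured against +z)
#' @export
sampleTailVectors <- function(targetS, n) {
  if (targetS < -0.5 || targetS > 1) stop("targetS must be in [-0.5, 1]")
  if (targetS > 1 - 1e-9) {
    ct <- sample(c(-1, 1), n, replace = TRUE)
  } else if (targetS < -0.5 + 1e-9) {
    ct <- rep(0, n)
  } else if (abs(targetS) < 1e-12) {
    ct <- stats::runif(n, -1, 1)
  } else {
    lambda <- .lambdaForS(targetS)
    ct <- numeric(0)
    cmax2 <- if (lambda > 0) 1 else 0
    while (length(ct) < n) {
      m <- max(2L * (n - length(ct)), 1000L)
      prop <- stats::runif(m, -1, 1)
      keep <- stats::runif(m) < exp(lambda * (prop^2 - cmax2))
      ct <- c(ct, prop[keep])
    }
    ct <- ct[seq_len(n)]
  }
  st <- sqrt(pmax(0, 1 - ct^2))
  az <- stats::runif(n, 0, 2 * pi)
  cbind(st * cos(az), st * sin(az), ct)
}

#' Simulate lateral Brownian lipid tracks
#'
#' Per-axis Gaussian steps with variance 2 D dt, D converted from cm^2/s to
#' A^2/ps (1 cm^2/s = 1e4 A^2/ps). Positions are wrapped into the box; the
#' unwrapped tracks are returned alongside as the diffusion ground truth.
#'
#' @param nMol number of molecules
#' @param nFrames number of frames
#' @param D lateral diffusion coefficient (cm^2/s)
#' @param dt frame spacing (ps)
#' @param box lateral box lengths c(Lx, Ly)
#' @param start optional nMol x 2 start positions (default uniform)
#' @return list(wrapped, unwrapped): arrays of dim c(nMol, 2, nFrames)
#' @export
simulateLipidWalk <- function(nMol, nFrames, D, dt, box, start = NULL) {
  if (dt <= 0) stop("dt must be > 0")
  sd <- sqrt(2 * D * 1e4 * dt)
  if (is.null(start))
    start <- cbind(stats::runif(nMol, 0, box[1]), stats::runif(nMol, 0, box[2]))
  un <- array(0, dim = c(nMol, 2, nFrames))
  un[, , 1] <- start
  if (nFrames > 1) {
    steps <- array(stats::rnorm(nMol * 2 * (nFrames - 1), sd = sd),
                   dim = c(nMol, 2, nFrames - 1))
    cum <- apply(steps, c(1, 2), cumsum)
    if (nFrames == 2) dim(cum) <- c(1, dim(cum)) # cumsum of length 1 drops a dim
    cum <- aperm(cum, c(2, 3, 1))
    un[, , -1] <- cum + array(un[, , 1], dim = dim(cum))
  }
  wr <- un
  wr[, 1, ] <- .wrapBox(wr[, 1, ], box[1])
  wr[, 2, ] <- .wrapBox(wr[, 2, ], box[2])
  list(wrapped = wr, unwrapped = un)
}

## ---- peptide construction ---------------------------------------------

.BB <- list(bNCA = 1.458, bCAC = 1.525, bCN = 1.329, bCO = 1.231,
            aCNCA = 121.7, aNCAC = 111.2, aCACN = 116.2, aCACO = 120.8)

# helical dihedral window used to veto coil draws (matches assignHelical
# defaults)
.HELIX_WINDOW <- c(phiMin = -100, phiMax = -30, psiMin = -80, psiMax = -5)

# coil phi is drawn outside the helical phi window so a coil residue can
# never satisfy the dihedral criterion, whatever its psi
.drawCoilDihedral <- function() {
  repeat {
    phi <- stats::runif(1, -180, 180)
    if (phi < .HELIX_WINDOW[1] || phi > .HELIX_WINDOW[2])
      return(c(phi, stats::runif(1, -180, 180)))
  }
}

# forward NeRF continuation: given list bb with rows named e.g. N,CA,C for
# residue j, append residues with given (phi, psi); returns matrix of atoms
# (N, CA, C, O per added residue, in order)
.extendForward <- function(Nj, CAj, Cj, phis, psis) {
  out <- matrix(NA_real_, length(phis) * 4, 3)
  rn <- character(length(phis) * 4)
  for (k in seq_along(phis)) {
    N1 <- .nerf(Nj, CAj, Cj, .BB$bCN, .BB$aCACN, psis[k] - 0) # psi_j places N_{j+1}
    CA1 <- .nerf(CAj, Cj, N1, .BB$bNCA, .BB$aCNCA, 180)
    C1 <- .nerf(Cj, N1, CA1, .BB$bCAC, .BB$aNCAC, phis[k])
    O1 <- .nerf(N1, CA1, C1, .BB$bCO, .BB$aCACO, 180) # placeholder psi+180 set later
    i <- (k - 1) * 4
    out[i + 1, ] <- N1; out[i + 2, ] <- CA1; out[i + 3, ] <- C1; out[i + 4, ] <- O1
    rn[i + 1:4] <- c("N", "CA", "C", "O")
    Nj <- N1; CAj <- CA1; Cj <- C1
  }
  rownames(out) <- rn
  out
}

# backward NeRF: given anchor residue atoms (N1, CA1, C1) of residue j+1 and
# its phi, build residues j, j-1, ... with given (phi, psi) per residue,
# ordered from residue j downward. Returns list of per-residue matrices
# (rows N, CA, C, O).
.extendBackward <- function(N1, CA1, C1, phiAnchor, phis, psis) {
  out <- vector("list", length(phis))
  phiNext <- phiAnchor
  for (k in seq_along(phis)) {
    Cj <- .nerf(C1, CA1, N1, .BB$bCN, .BB$aCNCA, phiNext)
    CAj <- .nerf(CA1, N1, Cj, .BB$bCAC, .BB$aCACN, 180)
    Nj <- .nerf(N1, Cj, CAj, .BB$bNCA, .BB$aNCAC, psis[k])
    Oj <- .nerf(Nj, CAj, Cj, .BB$bCO, .BB$aCACO, psis[k] + 180)
    m <- rbind(N = Nj, CA = CAj, C = Cj, O = Oj)
    out[[k]] <- m
    N1 <- Nj; CA1 <- CAj; C1 <- Cj
    phiNext <- phis[k]
  }
  out
}

# Build the two rigid loop templates (residues 1..anchor-1) hanging off the
# helix anchor residue with fixed extended-like coil dihedrals; phi of the
# anchor residue is pinned at -57 so the anchor stays helical in both
# states. The second template is the first rotated half a turn about the
# helix-axis direction through the junction carbon: the junction bond and
# the anchor phi are preserved while the loop swings to the opposite
# lateral side, flipping the chirality sign exactly.
.loopTemplates <- function(anchorN, anchorCA, anchorC, nLoop, axisDir) {
  # coil phi far (>100 deg) from the helical phi window so positional noise
  # on the template can never push a loop residue into the window
  phis <- rep(150, nLoop)
  psis <- rep(145, nLoop)
  t1raw <- .extendBackward(anchorN, anchorCA, anchorC, -57, phis, psis)
  # residues come out anchor-1 .. 1; repack in residue order 1..anchor-1
  t1 <- do.call(rbind, rev(t1raw))
  Cjun <- t1[(nLoop - 1) * 4 + 3, ]  # C of residue anchor-1
  R <- .rotationAbout(axisDir, pi)
  t2 <- sweep(sweep(t1, 2, Cjun) %*% t(R), 2, Cjun, `+`)
  list(t1, t2)
}

## ---- topology ----------------------------------------------------------

.syntheticTopology <- function(cfg) {
  species <- names(cfg$composition)
  counts <- round(cfg$composition * cfg$nLipidsPerLeaflet)
  counts[1] <- counts[1] + (cfg$nLipidsPerLeaflet - sum(counts))
  seqs <- iappSequence()
  pep <- data.frame(
    atom_name = rep(c("N", "CA", "C", "O"), 37),
    residue_index = rep(1:37, each = 4),
    residue_name = rep(seqs, each = 4),
    molecule_id = 1L,
    molecule_class = "peptide",
    species = "IAPP",
    stringsAsFactors = FALSE
  )
  k <- cfg$tailBeads
  spLeaf <- rep(rep(species, times = counts), 2)  # upper leaflet then lower
  nLip <- length(spLeaf)
  headName <- ifelse(spLeaf == "CHOL", "O3", "P")
  lip <- data.frame(
    atom_name = as.vector(rbind(headName,
                                matrix(paste0("T", seq_len(k)), k, nLip))),
    residue_index = 1L,
    residue_name = rep(spLeaf, each = 1L + k),
    molecule_id = rep(seq_len(nLip) + 1L, each = 1L + k),
    molecule_class = "lipid",
    species = rep(spLeaf, each = 1L + k),
    stringsAsFactors = FALSE
  )
  atoms <- rbind(pep, lip)
  topo <- new("SystemTopology", atoms = atoms, phosphateAtoms = "P",
              peptideResidueCount = 37L)
  leafLabel <- rep(c("upper", "lower"),
                   times = c(sum(counts), sum(counts)))
  spLabel <- rep(rep(species, times = counts), 2)
  list(topo = topo, counts = counts,
       lipidLeaflet = leafLabel, lipidSpecies = spLabel)
}

## ---- peptide frames ----------------------------------------------------

# static parts of the peptide model shared by all frames
.peptideModel <- function(cfg) {
  cx <- cfg$box[1] / 2; cy <- cfg$box[2] / 2
  planeZ <- cfg$leafletZ
  segs <- cfg$helicalSegments
  helicalRes <- sort(unique(unlist(lapply(segs, function(s) s[1]:s[2]))))
  if (cfg$peptideMode == "depth") {
    ca <- cbind(cx + 3.8 * (1:37 - 19), cy, planeZ + cfg$depthProfile)
    xyz <- matrix(NA_real_, 148, 3)
    for (i in 1:37) {
      b <- (i - 1) * 4
      xyz[b + 1, ] <- ca[i, ] + c(-1.0, 0.9, 0.2)   # N
      xyz[b + 2, ] <- ca[i, ]                        # CA
      xyz[b + 3, ] <- ca[i, ] + c(1.1, 0.9, -0.2)    # C
      xyz[b + 4, ] <- ca[i, ] + c(1.2, 2.0, -0.3)    # O
    }
    return(list(mode = "depth", base = xyz, planeZ = planeZ))
  }
  seg1 <- segs[[1]]
  segRes <- seg1[1]:seg1[2]
  # hydrophobic face (residue 12 if inside the segment) points down (-z)
  faceRes <- if (12 %in% segRes) 12 else segRes[ceiling(length(segRes) / 2)]
  phase <- 180 - (faceRes - seg1[1]) * 100
  zAxis <- planeZ + mean(cfg$depthProfile[segRes])
  origin <- c(cx - 1.5 * (length(segRes) - 1) / 2, cy, zAxis)
  hx <- buildIdealHelix(segRes, axis = c(1, 0, 0), origin = origin,
                        phase = phase)
  bb <- hx$backbone
  getAtom <- function(res, at) {
    r <- bb[bb$residue == res & bb$atom == at, c("x", "y", "z")]
    as.numeric(r[1, ])
  }
  nLoop <- seg1[1] - 1L
  templates <- if (nLoop > 0) {
    .loopTemplates(getAtom(seg1[1], "N"), getAtom(seg1[1], "CA"),
                   getAtom(seg1[1], "C"), nLoop, c(1, 0, 0))
  } else NULL
  list(mode = "helix", seg1 = seg1, segs = segs, helicalRes = helicalRes,
       bb = bb, templates = templates, planeZ = planeZ,
       anchorEnd = list(N = getAtom(seg1[2], "N"), CA = getAtom(seg1[2], "CA"),
                        C = getAtom(seg1[2], "C")),
       loopAxisFrom = if (nLoop > 0) getAtom(seg1[1], "N") else NULL)
}

# one frame of peptide coordinates (148 x 3, atoms N,CA,C,O per residue)
.peptideFrame <- function(cfg, model, loopState) {
  if (model$mode == "depth") {
    return(model$base + matrix(stats::rnorm(148 * 3, sd = cfg$depthSigma), 148, 3))
  }
  xyz <- matrix(NA_real_, 148, 3)
  put <- function(res, at, p) xyz[(res - 1) * 4 + match(at, c("N", "CA", "C", "O")), ] <<- p
  # rigid first helical segment
  bb <- model$bb
  for (r in seq_len(nrow(bb))) put(bb$residue[r], bb$atom[r],
                                   as.numeric(bb[r, c("x", "y", "z")]))
  # N-terminal loop from the planted template
  seg1 <- model$seg1
  nLoop <- seg1[1] - 1L
  if (nLoop > 0) {
    tmpl <- model$templates[[if (loopState == 2) 2 else 1]]
    pos <- tmpl
    jun <- (nLoop - 1) * 4 + 3  # row of C of residue anchor-1
    if (loopState == 0) {
      # diffuse: swing the loop about the helix-axis direction through the
      # junction carbon (the same axis relating the two templates), keeping
      # at least 30 degrees away from the planted orientations (0 and pi)
      Cl <- tmpl[jun, ]
      ang <- stats::runif(1, pi / 6, 5 * pi / 6) +
             sample(c(0, pi), 1)
      R <- .rotationAbout(c(1, 0, 0), ang)
      pos <- sweep(sweep(tmpl, 2, Cl) %*% t(R), 2, Cl, `+`)
    }
    noise <- matrix(stats::rnorm(length(pos), sd = cfg$loopNoise), nrow(pos), 3)
    # the junction residue stays noise-free: its C pins the anchor's phi,
    # and its own (phi, psi) must never jitter into the helical window
    # (positional noise translates into large circular torsion noise)
    noise[(nLoop - 1) * 4 + 1:4, ] <- 0
    pos <- pos + noise
    for (res in seq_len(nLoop)) {
      for (ai in 1:4) put(res, c("N", "CA", "C", "O")[ai], pos[(res - 1) * 4 + ai, ])
    }
  }
  # remaining residues: coil (fresh each frame) and later helical segments
  cur <- model$anchorEnd
  j <- seg1[2]
  while (j < 37) {
    nextHel <- any(vapply(model$segs, function(s) (j + 1) >= s[1] && (j + 1) <= s[2],
                          logical(1)))
    jHel <- any(vapply(model$segs, function(s) j >= s[1] && j <= s[2], logical(1)))
    coil <- if (!nextHel || !jHel) .drawCoilDihedral() else c(-57, -47)
    # phi of the new residue j+1; psi of residue j (which seeds the extension)
    phi <- if (nextHel) -57 else coil[1]
    psiJ <- if (jHel) -47 else coil[2]
    N1 <- .nerf(cur$N, cur$CA, cur$C, .BB$bCN, .BB$aCACN, psiJ)
    CA1 <- .nerf(cur$CA, cur$C, N1, .BB$bNCA, .BB$aCNCA, 180)
    C1 <- .nerf(cur$C, N1, CA1, .BB$bCAC, .BB$aNCAC, phi)
    O1 <- .nerf(N1, CA1, C1, .BB$bCO, .BB$aCACO, 180)
    put(j + 1, "N", N1); put(j + 1, "CA", CA1); put(j + 1, "C", C1); put(j + 1, "O", O1)
    cur <- list(N = N1, CA = CA1, C = C1)
    j <- j + 1
  }
  xyz
}

# Markov chain over loop states 1, 2 and 0 (diffuse)
.loopStateChain <- function(cfg) {
  p <- c(cfg$loopStateProbs, 1 - sum(cfg$loopStateProbs))
  states <- c(1L, 2L, 0L)
  cur <- sample(states, 1, prob = p)
  out <- integer(cfg$nFrames)
  for (f in seq_len(cfg$nFrames)) {
    if (f > 1 && stats::runif(1) < cfg$loopSwitchProb)
      cur <- sample(states, 1, prob = p)
    out[f] <- cur
  }
  out
}

## ---- lipid placement ---------------------------------------------------

# minimum lateral (wrapped) distance from each xy row to any peptide atom
.minLateralDist <- function(xy, pepXY, box) {
  dx <- outer(xy[, 1], pepXY[, 1], "-")
  dy <- outer(xy[, 2], pepXY[, 2], "-")
  dx <- .wrapHalf(dx, box[1])
  dy <- .wrapHalf(dy, box[2])
  sqrt(.rowMins(dx * dx + dy * dy))
}

# per-frame equilibrium placement with optional in-shell acceptance bias.
# The in-shell criterion during placement is identical to the one the
# depletion-enrichment analysis measures (minimum 3D lateral-minimum-image
# distance from any lipid bead, head or tail, to any peptide atom of
# residues 1-19), so the planted in-shell composition equals
# factor x bulk for the measured quantity itself. weights: named
# per-species in-shell weight (1 = unbiased); applied to biased lipids
# only (others placed uniformly).
.placeIID <- function(cfg, speciesPerLipid, biased, weights, pepByFrame,
                      headZ, dirs, trackShell = TRUE) {
  L <- length(speciesPerLipid); F <- cfg$nFrames
  x <- matrix(0, L, F); y <- matrix(0, L, F)
  inShell <- matrix(FALSE, L, F)
  r <- cfg$enrichment$radius
  k <- cfg$tailBeads
  sp <- cfg$tailSpacing
  wmax <- max(1, weights)
  wOf <- ifelse(biased, weights[speciesPerLipid], 1)
  if (all(weights == 1) && !trackShell) {
    # unbiased and no truth flags requested: one vectorized draw
    x[] <- stats::runif(L * F, 0, cfg$box[1])
    y[] <- stats::runif(L * F, 0, cfg$box[2])
    return(list(x = x, y = y, inShell = inShell))
  }
  for (f in seq_len(F)) {
    pep <- pepByFrame[[f]]
    todo <- seq_len(L)
    while (length(todo)) {
      n <- length(todo)
      px <- stats::runif(n, 0, cfg$box[1])
      py <- stats::runif(n, 0, cfg$box[2])
      # bead positions of each proposal: head plus k tail beads
      bj <- 0:k
      bx <- px + outer(dirs[todo, f, 1] * sp, bj)
      by <- py + outer(dirs[todo, f, 2] * sp, bj)
      bz <- headZ[todo, f] + outer(dirs[todo, f, 3] * sp, bj)
      dx <- .wrapHalf(outer(as.vector(bx), pep[, 1], "-"), cfg$box[1])
      dy <- .wrapHalf(outer(as.vector(by), pep[, 2], "-"), cfg$box[2])
      dz <- outer(as.vector(bz), pep[, 3], "-")
      d2min <- .rowMins(dx * dx + dy * dy + dz * dz)
      molMin <- .rowMins(matrix(d2min, n, k + 1))
      inw <- molMin <= r * r
      w <- ifelse(inw, wOf[todo], 1)
      acc <- stats::runif(n) < w / wmax
      ok <- todo[acc]
      x[ok, f] <- px[acc]; y[ok, f] <- py[acc]; inShell[ok, f] <- inw[acc]
      todo <- todo[!acc]
    }
  }
  list(x = x, y = y, inShell = inShell)
}

## ---- system generation -------------------------------------------------

#' Generate a synthetic membrane-peptide trajectory with ground truth
#'
#' Builds a two-leaflet coarse-proxy bilayer and a 37-residue peptide
#' according to \code{config}, fully determined by \code{(config, seed)}.
#' See [syntheticConfig()] for the planted features.
#'
#' @param config a [syntheticConfig()] object
#' @return list with elements \code{trajectory} (a [Trajectory-class]) and
#'   \code{truth} (list of all planted quantities: loop states per frame,
#'   leaflet labels, unwrapped diffusion tracks, in-shell placement flags,
#'   binding-mode activity, helical residue schedule, depth profile)
#' @export
generateSystem <- function(config) {
  cfg <- .validateSyntheticConfig(config)
  .withSeed(cfg$seed, .generateSystemImpl(cfg))
}

.generateSystemImpl <- function(cfg) {
  tp <- .syntheticTopology(cfg)
  topo <- tp$topo
  F <- cfg$nFrames
  nat <- nAtoms(topo)
  k <- cfg$tailBeads
  L <- 2 * cfg$nLipidsPerLeaflet
  leafSign <- ifelse(tp$lipidLeaflet == "upper", 1, -1)
  # peptide
  model <- .peptideModel(cfg)
  loopStates <- if (model$mode == "helix") .loopStateChain(cfg) else rep(NA_integer_, F)
  pep <- array(0, dim = c(148, 3, F))
  for (f in seq_len(F)) pep[, , f] <- .peptideFrame(cfg, model, loopStates[f])
  pepSel <- which(topo@atoms$molecule_class == "peptide" &
                  topo@atoms$residue_index <= 19)
  # head z and tail directions are placement-independent; draw them first
  isChol <- tp$lipidSpecies == "CHOL"
  headZ0 <- ifelse(isChol, cfg$leafletZ - 3, cfg$leafletZ)
  lz <- matrix(leafSign * headZ0, L, F) +
        matrix(stats::rnorm(L * F, sd = cfg$phosphateSigma), L, F)
  dirs <- sampleTailVectors(cfg$targetOrderParameter, L * F)
  dim(dirs) <- c(L, F, 3)
  dirs[, , 3] <- -rep(leafSign, F) * abs(dirs[, , 3])
  # lateral placement
  en <- cfg$enrichment
  useIID <- cfg$placement == "iid" ||
    (cfg$placement == "auto" && !is.null(en$species) && en$factor != 1)
  tracks <- NULL; inShell <- NULL; weights <- NULL
  if (useIID) {
    pepByFrame <- lapply(seq_len(F), function(f) pep[pepSel, , f])
    biased <- tp$lipidLeaflet == .boundLeafletTruth(cfg)
    weights <- stats::setNames(rep(1, length(cfg$composition)), names(cfg$composition))
    if (!is.null(en$species) && en$factor != 1) {
      # unbiased pilot pass measures the shell's probability mass q; the
      # target's in-shell acceptance weight rho = G(1-q)/(1-Gq) with
      # G = factor(1-f)/(1-factor*f) then makes the in-shell composition
      # exactly factor x bulk in expectation (finite-shell-size correction)
      pilot <- .placeIID(cfg, tp$lipidSpecies, biased, weights, pepByFrame,
                         lz, dirs, trackShell = TRUE)
      q <- mean(pilot$inShell[biased, ])
      ft <- cfg$composition[[en$species]]
      G <- en$factor * (1 - ft) / (1 - en$factor * ft)
      if (G * q >= 1)
        stop("enrichment shell too large for the requested factor")
      weights[en$species] <- G * (1 - q) / (1 - G * q)
    }
    pl <- .placeIID(cfg, tp$lipidSpecies, biased, weights, pepByFrame, lz, dirs,
                    trackShell = any(weights != 1))
    lx <- pl$x; ly <- pl$y; inShell <- pl$inShell
  } else {
    lx <- matrix(0, L, F); ly <- matrix(0, L, F)
    tracks <- list()
    for (s in names(cfg$composition)) {
      i <- which(tp$lipidSpecies == s)
      if (!length(i)) next
      w <- simulateLipidWalk(length(i), F, cfg$diffusion[[s]], cfg$dt, cfg$box)
      lx[i, ] <- w$wrapped[, 1, ]
      ly[i, ] <- w$wrapped[, 2, ]
      tracks[[s]] <- list(indices = i, unwrapped = w$unwrapped)
    }
  }
  # planted binding modes: teleport designated lipids in active frames
  bmTruth <- list()
  if (length(cfg$bindingModes)) {
    used <- integer(0)
    for (m in seq_along(cfg$bindingModes)) {
      bm <- cfg$bindingModes[[m]]
      cand <- which(tp$lipidSpecies == bm$species &
                    tp$lipidLeaflet == .boundLeafletTruth(cfg))
      cand <- setdiff(cand, used)
      if (!length(cand)) stop("no free lipid available for binding mode ", m)
      li <- cand[1]; used <- c(used, li)
      active <- stats::runif(F) < bm$fraction
      d0 <- if (is.null(bm$distance)) 3.5 else bm$distance
      caIdx <- (bm$residues - 1) * 4 + 2  # CA rows in peptide block
      for (f in which(active)) {
        anchor <- colMeans(pep[caIdx, , f, drop = FALSE])
        pos <- anchor + d0 * c(0, 0.95, 0.31) +
               stats::rnorm(3, sd = 0.25)
        lx[li, f] <- pos[1]; ly[li, f] <- pos[2]; lz[li, f] <- pos[3]
        # the planted pose includes the tail orientation: straight down
        dirs[li, f, ] <- c(0, 0, -leafSign[li])
      }
      bmTruth[[m]] <- list(molecule = topo@atoms$molecule_id[
                             which(topo@atoms$molecule_class == "lipid")][ (li - 1) * (1 + k) + 1],
                           lipidRow = li, active = active,
                           residues = bm$residues, species = bm$species)
    }
  }
  # assemble coordinates
  arr <- array(0, dim = c(nat, 3, F))
  arr[1:148, , ] <- pep
  lipStart <- 148L
  headIdx <- lipStart + (seq_len(L) - 1L) * (1L + k) + 1L
  arr[headIdx, 1, ] <- .wrapBox(lx, cfg$box[1])
  arr[headIdx, 2, ] <- .wrapBox(ly, cfg$box[2])
  arr[headIdx, 3, ] <- lz
  for (j in seq_len(k)) {
    arr[headIdx + j, 1, ] <- .wrapBox(lx + j * cfg$tailSpacing * dirs[, , 1], cfg$box[1])
    arr[headIdx + j, 2, ] <- .wrapBox(ly + j * cfg$tailSpacing * dirs[, , 2], cfg$box[2])
    arr[headIdx + j, 3, ] <- lz + j * cfg$tailSpacing * dirs[, , 3]
  }
  box <- matrix(rep(c(cfg$box, cfg$boxHeight), each = F), nrow = F)
  traj <- new("Trajectory", topology = topo, coords = arr, box = box,
              times = (seq_len(F) - 1) * cfg$dt)
  lipMolIds <- unique(topo@atoms$molecule_id[topo@atoms$molecule_class == "lipid"])
  truth <- list(
    config = cfg, seed = cfg$seed,
    planeZ = c(upper = cfg$leafletZ, lower = -cfg$leafletZ),
    boundLeaflet = .boundLeafletTruth(cfg),
    lipidLeaflet = stats::setNames(tp$lipidLeaflet, lipMolIds),
    lipidSpecies = stats::setNames(tp$lipidSpecies, lipMolIds),
    loopStates = loopStates,
    helicalResidues = if (model$mode == "helix") {
      r <- rep(FALSE, 37); r[unlist(lapply(cfg$helicalSegments, function(s) s[1]:s[2]))] <- TRUE; r
    } else rep(FALSE, 37),
    depthProfile = cfg$depthProfile,
    tracks = tracks, inShell = inShell, enrichmentWeights = weights,
    bindingModes = bmTruth, headAtomRows = headIdx
  )
  list(trajectory = traj, truth = truth)
}

# the peptide is placed on the upper leaflet by construction
.boundLeafletTruth <- function(cfg) "upper"

#' Generate a repeat series for one condition
#'
#' @param config a [syntheticConfig()]
#' @param nRepeats number of repeats (the studied conditions use 4)
#' @param label condition label
#' @param seed base seed; each repeat uses a derived sub-seed
#' @return list(series = [TrajectorySeries-class], truths = list per repeat)
#' @export
syntheticSeries <- function(config, nRepeats = 4, label = "synthetic",
                            seed = config$seed) {
  sims <- lapply(seq_len(nRepeats), function(i) {
    cfg <- config
    cfg$seed <- .subSeed(seed, i)
    generateSystem(cfg)
  })
  series <- new("TrajectorySeries", label = label,
                repeats = lapply(sims, `[[`, "trajectory"))
  list(series = series, truths = lapply(sims, `[[`, "truth"))
}

#' Write a generated system to disk
#'
#' Writes the topology as a GRO file, the trajectory as a multi-frame GRO
#' file, and the ground truth (without bulky arrays) as a YAML sidecar.
#'
#' @param sim result of [generateSystem()]
#' @param dir output directory (created if needed)
#' @return the directory, invisibly
#' @export
writeSystem <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  traj <- sim$trajectory
  writeGro(traj@topology, traj@coords[, , 1], traj@box[1, ],
           file.path(dir, "topology.gro"))
  writeTrajectoryGro(traj, file.path(dir, "trajectory.gro"))
  tr <- sim$truth
  side <- list(
    seed = tr$seed,
    boundLeaflet = tr$boundLeaflet,
    planeZ = as.list(tr$planeZ),
    loopStates = as.integer(tr$loopStates),
    helicalResidues = which(tr$helicalResidues),
    depthProfile = tr$depthProfile,
    lipidLeaflet = as.list(tr$lipidLeaflet),
    config = tr$config[setdiff(names(tr$config), c("bindingModes", "helicalSegments"))]
  )
  yaml::write_yaml(side, file.path(dir, "ground_truth.yaml"))
  invisible(dir)
}
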