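# Lipid environment of the peptide: depletion-enrichment index with
# one-sample significance testing, rigid superposition, and 3D occupancy
# maps in the peptide-aligned frame.

# atom row indices of peptide residues (all atoms)
.peptideAtomRows <- function(topo, residues) {
  a <- topo@atoms
  which(a$molecule_class == "peptide" & a$residue_index %in% residues)
}

# per-species lipid atom rows grouped by molecule, with constant bead count
.lipidAtomLayout <- function(topo, mols) {
  a <- topo@atoms
  rows <- which(a$molecule_id %in% mols & a$molecule_class == "lipid")
  molOf <- a$molecule_id[rows]
  o <- order(match(molOf, mols), rows)
  rows <- rows[o]; molOf <- molOf[o]
  counts <- table(factor(molOf, levels = mols))
  if (length(unique(counts)) != 1L)
    stop("lipid molecules of one species must share an atom layout")
  list(rows = rows, mols = mols, beadsPerMol = unique(as.integer(counts)))
}

# minimum distance from each lipid molecule to any peptide atom, one frame.
# Returns named numeric per molecule (3D distance, lateral minimum image).
.molMinDist <- function(xyz, box, pepRows, layout) {
  dx <- .wrapHalf(outer(xyz[layout$rows, 1], xyz[pepRows, 1], "-"), box[1])
  dy <- .wrapHalf(outer(xyz[layout$rows, 2], xyz[pepRows, 2], "-"), box[2])
  dz <- outer(xyz[layout$rows, 3], xyz[pepRows, 3], "-")
  d2 <- dx * dx + dy * dy + dz * dz
  beadMin <- .rowMins(d2)
  k <- layout$beadsPerMol
  molMin <- .rowMins(t(matrix(beadMin, k, length(layout$mols))))
  sqrt(molMin)
}

#' Per-species lipid counts within a shell around the peptide
#'
#' A lipid is in-shell iff any of its atoms lies within \code{radius} of any
#' atom of the selected peptide residues (3D distances with lateral
#' minimum-image wrapping); each lipid counts once. Shells are cumulative
#' (0..r) by default; \code{innerRadius > 0} gives an annular shell.
#'
#' @param traj a [Trajectory-class]
#' @param radius shell radius (Angstrom)
#' @param peptideResidues residues defining the peptide selection (default
#'   1:19, the membrane-binding N-terminal part)
#' @param leafletScope "bound" (default), "upper", "lower" or "all"
#' @param innerRadius inner radius for annular shells (default 0)
#' @param frames frame indices (default all)
#' @return matrix nFrames x nSpecies of in-shell molecule counts
#' @export
shellComposition <- function(traj, radius, peptideResidues = 1:19,
                             leafletScope = "bound", innerRadius = 0,
                             frames = NULL) {
  if (radius <= 0) stop("radius must be > 0")
  if (is.null(frames)) frames <- seq_len(nFrames(traj))
  topo <- traj@topology
  a <- topo@atoms
  pepRows <- .peptideAtomRows(topo, peptideResidues)
  mols <- .leafletScopeMols(traj, leafletScope)
  spOf <- vapply(mols, function(m) a$species[a$molecule_id == m][1], character(1))
  species <- sort(unique(spOf))
  layouts <- lapply(species, function(s) .lipidAtomLayout(topo, mols[spOf == s]))
  names(layouts) <- species
  out <- matrix(0L, length(frames), length(species),
                dimnames = list(NULL, species))
  for (fi in seq_along(frames)) {
    xyz <- traj@coords[, , frames[fi], drop = TRUE]
    box <- traj@box[frames[fi], ]
    for (s in species) {
      md <- .molMinDist(xyz, box, pepRows, layouts[[s]])
      out[fi, s] <- sum(md <= radius & md > innerRadius)
    }
  }
  out
}

#' Depletion-enrichment index of lipid species around the peptide
#'
#' D-E(species, r) = [sum over frames of in-shell counts of the species /
#' sum of total in-shell counts] / [bulk fraction of the species in the
#' bound leaflet]. Counts are summed over frames before forming the ratio
#' (ratio of sums; per-frame ratios are unstable at small counts and
#' available via \code{aggregate = "per-frame"}). Values above 1 indicate
#' enrichment, below 1 depletion. Significance per (species, radius) is the
#' two-sided one-sample t test across repeats against 1.
#'
#' @param series a [TrajectorySeries-class] (>= 2 repeats for the test)
#' @param radii shell radii in Angstrom (default c(7, 14, 21), the three
#'   nearest lipid shells)
#' @param peptideResidues peptide selection (default 1:19)
#' @param leafletScope leaflet for both counts and bulk composition
#'   (default "bound")
#' @param annular use annular shells (0-7, 7-14, 14-21) instead of
#'   cumulative ones
#' @param aggregate "ratio-of-sums" (default) or "per-frame"
#' @param stride frame stride (default 1)
#' @return data.frame of class "DEIndexTable": one row per
#'   (species, radius) with per-repeat D-E columns, mean and p
#' @export
deIndex <- function(series, radii = c(7, 14, 21), peptideResidues = 1:19,
                    leafletScope = "bound", annular = FALSE,
                    aggregate = c("ratio-of-sums", "per-frame"), stride = 1L) {
  aggregate <- match.arg(aggregate)
  nRep <- length(series@repeats)
  topo <- topology(series)
  a <- topo@atoms
  asg <- assignLeaflets(series@repeats[[1]], 1)
  mols <- .leafletScopeMols(series@repeats[[1]], leafletScope, asg)
  spOf <- vapply(mols, function(m) a$species[a$molecule_id == m][1], character(1))
  bulk <- table(spOf) / length(spOf)
  species <- names(bulk)
  radSorted <- sort(radii)
  vals <- array(NA_real_, dim = c(length(species), length(radii), nRep),
                dimnames = list(species, as.character(radii), NULL))
  for (i in seq_len(nRep)) {
    tr <- series@repeats[[i]]
    frames <- seq(1, nFrames(tr), by = stride)
    for (ri in seq_along(radii)) {
      r <- radii[ri]
      inner <- if (annular) {
        pos <- match(r, radSorted)
        if (pos > 1) radSorted[pos - 1] else 0
      } else 0
      cnt <- shellComposition(tr, r, peptideResidues, leafletScope,
                              innerRadius = inner, frames = frames)
      cs <- colSums(cnt)
      tot <- sum(cs)
      for (s in species) {
        if (aggregate == "ratio-of-sums") {
          if (tot == 0) {
            warning(sprintf("empty %g A shell in all frames of repeat %d", r, i))
            next
          }
          vals[s, ri, i] <- (cs[[s]] / tot) / bulk[[s]]
        } else {
          totF <- rowSums(cnt)
          ok <- totF > 0
          if (!any(ok)) {
            warning(sprintf("empty %g A shell in all frames of repeat %d", r, i))
            next
          }
          vals[s, ri, i] <- mean(cnt[ok, s] / totF[ok]) / bulk[[s]]
        }
      }
    }
  }
  rows <- list()
  for (s in species) for (ri in seq_along(radii)) {
    v <- vals[s, ri, ]
    ok <- !is.na(v)
    p <- if (sum(ok) >= 2 && stats::sd(v[ok]) > 0)
      stats::t.test(v[ok], mu = 1)$p.value
    else NA_real_
    row <- data.frame(species = s, radius = radii[ri],
                      mean = mean(v[ok]), p = p)
    for (i in seq_len(nRep)) row[[paste0("rep", i)]] <- v[i]
    rows[[length(rows) + 1L]] <- row
  }
  out <- do.call(rbind, rows)
  attr(out, "label") <- series@label
  attr(out, "bulk") <- as.numeric(bulk)
  attr(out, "annular") <- annular
  class(out) <- c("DEIndexTable", "data.frame")
  out
}

#' Rigid superposition onto a reference selection
#'
#' Least-squares (Kabsch) superposition of selected atoms onto reference
#' coordinates, rotation + translation only (no reflection), applied to the
#' whole frame.
#'
#' @param xyz nAtoms x 3 frame coordinates
#' @param reference m x 3 reference coordinates
#' @param index atom row indices in \code{xyz} matching the reference rows
#' @return list(R, center, shift, rmsd, coords) with \code{coords} the full
#'   transformed frame
#' @export
alignToReference <- function(xyz, reference, index) {
  if (length(index) != nrow(reference))
    stop("index length must match reference rows")
  P <- xyz[index, , drop = FALSE]
  sv <- svd(sweep(P, 2, colMeans(P)))$d
  if (sv[2] < 1e-6 * sv[1]) stop("degenerate (collinear) selection")
  fit <- .kabsch(P, reference)
  fit$coords <- .applyTransform(xyz, fit)
  fit
}

# reference CA coordinates (residues 7-16) of the first frame of a series
.defaultReference <- function(series) {
  topo <- topology(series)
  idx <- which(topo@atoms$molecule_class == "peptide" &
               topo@atoms$atom_name == "CA" &
               topo@atoms$residue_index %in% 7:16)
  list(index = idx, coords = series@repeats[[1]]@coords[idx, , 1])
}

#' 3D occupancy maps of lipid species around the aligned peptide
#'
#' Every frame is rigidly aligned on the Calpha atoms of the helical core
#' (residues 7-16) onto a common reference; selected lipid atoms are binned
#' into a voxel grid and each voxel records the fraction of frames in which
#' at least one selected atom is present. Maps are computed separately per
#' loop-orientation label when \code{loopLabels} is given.
#'
#' @param series a [TrajectorySeries-class]
#' @param species lipid species to map
#' @param atomScope "all" lipid beads or "head" beads only
#' @param loopLabels optional list (one element per repeat) of per-frame
#'   orientation labels ("O1", "O2", "other"); maps are produced for O1 and
#'   O2
#' @param spacing voxel edge length (Angstrom)
#' @param margin grid margin beyond the peptide bounding box (Angstrom)
#' @param reference list(index, coords) as from the default (frame 1 of
#'   repeat 1)
#' @param stride frame stride
#' @return list of "OccupancyGrid" objects (one per orientation label):
#'   list(origin, spacing, dim, occupancy (3D array), species, label,
#'   nFrames)
#' @export
occupancyMap <- function(series, species, atomScope = c("all", "head"),
                         loopLabels = NULL, spacing = 1, margin = 15,
                         reference = NULL, stride = 1L) {
  atomScope <- match.arg(atomScope)
  topo <- topology(series)
  a <- topo@atoms
  if (!species %in% a$species) stop("species absent: ", species)
  if (is.null(reference)) reference <- .defaultReference(series)
  pepRows <- which(a$molecule_class == "peptide")
  # grid extent: peptide bounding box in the reference frame + margin
  refFrame <- series@repeats[[1]]@coords[, , 1]
  fit0 <- alignToReference(refFrame, reference$coords, reference$index)
  pb <- fit0$coords[pepRows, , drop = FALSE]
  lo <- floor((apply(pb, 2, min) - margin) / spacing) * spacing
  hi <- ceiling((apply(pb, 2, max) + margin) / spacing) * spacing
  dims <- as.integer(round((hi - lo) / spacing))
  lipRows <- which(a$species == species & a$molecule_class == "lipid")
  if (atomScope == "head") {
    mols <- unique(a$molecule_id[lipRows])
    lipRows <- vapply(mols, function(m) which(a$molecule_id == m)[1], integer(1))
  }
  labels <- if (is.null(loopLabels)) "all" else c("O1", "O2")
  grids <- list()
  for (lab in labels) {
    present <- array(0L, dim = dims)
    nF <- 0L
    for (ri in seq_along(series@repeats)) {
      tr <- series@repeats[[ri]]
      frames <- seq(1, nFrames(tr), by = stride)
      if (!is.null(loopLabels)) {
        lv <- loopLabels[[ri]]
        # labels are named by frame number when they come from a strided
        # clustering; fall back to positional lookup otherwise
        ll <- if (!is.null(names(lv))) lv[as.character(frames)] else lv[frames]
        frames <- frames[!is.na(ll) & ll == lab]
      }
      for (f in frames) {
        nF <- nF + 1L
        fit <- alignToReference(tr@coords[, , f], reference$coords,
                                reference$index)
        X <- fit$coords[lipRows, , drop = FALSE]
        ix <- floor((X[, 1] - lo[1]) / spacing) + 1
        iy <- floor((X[, 2] - lo[2]) / spacing) + 1
        iz <- floor((X[, 3] - lo[3]) / spacing) + 1
        ok <- ix >= 1 & ix <= dims[1] & iy >= 1 & iy <= dims[2] &
              iz >= 1 & iz <= dims[3]
        if (!any(ok)) next
        vox <- unique(cbind(ix[ok], iy[ok], iz[ok]))
        present[vox] <- present[vox] + 1L
      }
    }
    if (nF == 0L) warning("zero frames for orientation label ", lab)
    grids[[lab]] <- structure(list(
      origin = lo, spacing = spacing, dim = dims,
      occupancy = if (nF > 0) present / nF else present * 0,
      species = species, label = lab, nFrames = nF
    ), class = "OccupancyGrid")
  }
  grids
}

#' Write an occupancy grid in OpenDX format
#'
#' Plain-text OpenDX scalar grid loadable in standard molecular viewers.
#'
#' @param grid an "OccupancyGrid" from [occupancyMap()]
#' @param path output file
#' @export
writeOpenDX <- function(grid, path) {
  d <- grid$dim
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("# occupancy map: species %s, orientation %s, %d frames",
            grid$species, grid$label, grid$nFrames),
    sprintf("object 1 class gridpositions counts %d %d %d", d[1], d[2], d[3]),
    sprintf("origin %.3f %.3f %.3f", grid$origin[1], grid$origin[2], grid$origin[3]),
    sprintf("delta %.3f 0 0", grid$spacing),
    sprintf("delta 0 %.3f 0", grid$spacing),
    sprintf("delta 0 0 %.3f", grid$spacing),
    sprintf("object 2 class gridconnections counts %d %d %d", d[1], d[2], d[3]),
    sprintf("object 3 class array type double rank 0 items %d data follows",
            prod(d))
  ), con)
  # OpenDX expects z fastest
  v <- aperm(grid$occupancy, c(3, 2, 1))
  v <- as.vector(v)
  n3 <- length(v) %/% 3
  if (n3 > 0) {
    m <- matrix(v[seq_len(n3 * 3)], ncol = 3, byrow = TRUE)
    writeLines(sprintf("%.6g %.6g %.6g", m[, 1], m[, 2], m[, 3]), con)
  }
  rem <- length(v) - n3 * 3
  if (rem > 0)
    writeLines(paste(sprintf("%.6g", v[(n3 * 3 + 1):length(v)]), collapse = " "), con)
  writeLines(c('attribute "dep" string "positions"',
               'object "occupancy" class field',
               'component "positions" value 1',
               'component "connections" value 2',
               'component "data" value 3'), con)
  invisible(path)
}
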