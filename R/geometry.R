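# Periodic-boundary geometry and leaflet assignment.

#' Minimum-image displacement under lateral periodicity
#'
#' Returns the displacement \code{b - a} with the x and y components wrapped
#' into \code{[-L/2, L/2)}. The z component is left untouched: the bilayer
#' analyses are periodic laterally only, and wrapping z would spuriously
#' join the two leaflets.
#'
#' @param a,b 3-vectors or n x 3 matrices (Angstrom)
#' @param box lateral box lengths \code{c(Lx, Ly)} (a third element, if
#'   present, is ignored)
#' @return displacement(s), same shape as the inputs
#' @export
minimumImage <- function(a, b, box) {
  if (any(box[1:2] <= 0)) stop("box lengths must be > 0")
  if (is.null(dim(a))) a <- matrix(a, ncol = 3)
  if (is.null(dim(b))) b <- matrix(b, ncol = 3)
  d <- b - a
  d[, 1] <- .wrapHalf(d[, 1], box[1])
  d[, 2] <- .wrapHalf(d[, 2], box[2])
  if (nrow(d) == 1L) drop(d) else d
}

# phosphate z values per phospholipid molecule for one frame, plus the
# molecule ids of all lipids and of phosphate-free (sterol) lipids
.lipidHeads <- function(topo) {
  a <- topo@atoms
  lip <- a$molecule_class == "lipid"
  isP <- lip & a$atom_name %in% topo@phosphateAtoms
  phosMol <- a$molecule_id[isP]
  phosIdx <- which(isP)
  # first atom of each phosphate-free lipid molecule acts as its head proxy
  lipMol <- unique(a$molecule_id[lip])
  sterolMol <- setdiff(lipMol, phosMol)
  sterolIdx <- vapply(sterolMol, function(m) which(a$molecule_id == m)[1], integer(1))
  list(phosIdx = phosIdx, phosMol = phosMol,
       sterolIdx = sterolIdx, sterolMol = sterolMol, lipMol = lipMol)
}

#' Assign lipids to leaflets and identify the peptide-bound leaflet
#'
#' Phospholipids are split into upper and lower leaflets at the midpoint of
#' the largest gap in their phosphate z values; sterols (no phosphate) join
#' the leaflet of their nearest phospholipid phosphate. The bound leaflet is
#' the one whose phosphate-plane z is nearest the mean z of peptide Calpha
#' atoms of residues 7-16 (the stable helical core).
#'
#' @param traj a [Trajectory-class]
#' @param frame frame index (default 1)
#' @param minSeparation minimum z gap (Angstrom) required between leaflets;
#'   a smaller gap raises the "monolayer or unwrapped system" error
#' @return list with \code{leaflet} (named factor "upper"/"lower" per lipid
#'   molecule id), \code{boundLeaflet}, and \code{planeZ} (named mean
#'   phosphate z per leaflet)
#' @export
assignLeaflets <- function(traj, frame = 1, minSeparation = 8) {
  topo <- traj@topology
  xyz <- traj@coords[, , frame, drop = TRUE]
  h <- .lipidHeads(topo)
  if (length(h$phosIdx) < 2L) stop("need at least one phospholipid per leaflet")
  pz <- xyz[h$phosIdx, 3]
  o <- order(pz)
  gaps <- diff(pz[o])
  gi <- which.max(gaps)
  if (gaps[gi] < minSeparation)
    stop("monolayer or unwrapped system: phosphate z values are not bimodal")
  splitZ <- (pz[o][gi] + pz[o][gi + 1]) / 2
  side <- ifelse(pz > splitZ, "upper", "lower")
  if (length(unique(side)) < 2L)
    stop("monolayer or unwrapped system: all phosphates on one side")
  leaf <- stats::setNames(side, h$phosMol)
  # sterols: leaflet of nearest phosphate (3D minimum-image distance)
  if (length(h$sterolIdx)) {
    box <- traj@box[frame, ]
    P <- xyz[h$phosIdx, , drop = FALSE]
    for (k in seq_along(h$sterolIdx)) {
      d <- minimumImage(matrix(xyz[h$sterolIdx[k], ], nrow(P), 3, byrow = TRUE),
                        P, box)
      if (is.null(dim(d))) d <- matrix(d, ncol = 3)
      j <- which.min(rowSums(d * d))
      leaf[as.character(h$sterolMol[k])] <- side[j]
    }
  }
  planeZ <- c(upper = mean(pz[side == "upper"]), lower = mean(pz[side == "lower"]))
  a <- topo@atoms
  caIdx <- which(a$molecule_class == "peptide" & a$atom_name == "CA" &
                 a$residue_index >= 7 & a$residue_index <= 16)
  bound <- if (length(caIdx)) {
    names(planeZ)[which.min(abs(planeZ - mean(xyz[caIdx, 3])))]
  } else NA_character_
  list(leaflet = factor(leaf[as.character(h$lipMol)],
                        levels = c("upper", "lower")) |>
         stats::setNames(h$lipMol),
       boundLeaflet = bound, planeZ = planeZ)
}

# molecule ids of lipids in scope ("bound", "upper", "lower", "all")
.leafletScopeMols <- function(traj, scope = "bound", assignment = NULL) {
  if (scope == "all") {
    a <- traj@topology@atoms
    return(unique(a$molecule_id[a$molecule_class == "lipid"]))
  }
  if (is.null(assignment)) assignment <- assignLeaflets(traj, 1)
  want <- if (scope == "bound") assignment$boundLeaflet else scope
  as.integer(names(assignment$leaflet))[assignment$leaflet == want]
}
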