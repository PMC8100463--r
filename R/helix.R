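# Ideal alpha-helix construction and peptide sequence constants.

#' Human IAPP sequence (three-letter codes, residues 1-37)
#' @export
iappSequence <- function() {
  c("LYS", "CYS", "ASN", "THR", "ALA", "THR", "CYS", "ALA", "THR", "GLN",
    "ARG", "LEU", "ALA", "ASN", "PHE", "LEU", "VAL", "HIS", "SER", "SER",
    "ASN", "ASN", "PHE", "GLY", "ALA", "ILE", "LEU", "SER", "SER", "THR",
    "ASN", "VAL", "GLY", "SER", "ASN", "THR", "TYR")
}

# residues forming the hydrophobic face of the membrane-bound helices
.IAPP_FACE <- c(8L, 12L, 15L, 16L, 23L, 26L, 27L)

.HYDROPHOBIC_AA <- c("ALA", "VAL", "LEU", "ILE", "PHE", "MET", "TRP", "PRO")

# Cylindrical offsets of backbone N, C, O relative to the same-residue CA in
# a canonical alpha-helix (phi = -57, psi = -47, omega = 180; ideal bond
# lengths/angles). Columns: radius (A), phase offset (deg), axial offset (A).
.HELIX_BB_OFFSETS <- rbind(
  N = c(1.546093, -26.94173, -0.9187925),
  C = c(1.660522,  26.89981,  1.0690360),
  O = c(1.914220,  20.43560,  2.2566400)
)

#' Build an ideal alpha-helix backbone
#'
#' Places Calpha atoms on an exact circular helix (default rise 1.5 A, twist
#' 100 deg/residue, radius 2.3 A) and attaches backbone N, C and O atoms at
#' fixed cylindrical offsets so that the interior dihedrals are the
#' canonical alpha-helical (phi, psi) of approximately (-57, -47) degrees.
#'
#' @param residues integer vector of residue indices (e.g. 7:28)
#' @param rise axial rise per residue (Angstrom)
#' @param twist rotation per residue (degrees)
#' @param radius Calpha helix radius (Angstrom)
#' @param axis helix axis direction (default +x, i.e. lying in the membrane
#'   plane)
#' @param origin position of the axis point of the first residue
#' @param phase azimuth (degrees) of the first residue's Calpha about the
#'   axis; 0 places it along the reference direction perpendicular to the
#'   axis closest to +z
#' @return list with \code{ca} (n x 3 matrix) and \code{backbone}
#'   (data.frame: residue, atom, x, y, z including N, CA, C, O per residue)
#' @export
buildIdealHelix <- function(residues, rise = 1.5, twist = 100, radius = 2.3,
                            axis = c(1, 0, 0), origin = c(0, 0, 0),
                            phase = 0) {
  if (length(residues) == 0L) stop("empty residue range")
  n <- length(residues)
  om <- twist * pi / 180
  ph <- phase * pi / 180
  i <- seq_len(n) - 1
  atoms <- c("N", "CA", "C", "O")
  local <- vector("list", length(atoms))
  names(local) <- atoms
  for (at in atoms) {
    if (at == "CA") {
      r <- radius; dphi <- 0; dz <- 0
    } else {
      r <- .HELIX_BB_OFFSETS[at, 1]
      dphi <- .HELIX_BB_OFFSETS[at, 2] * pi / 180
      dz <- .HELIX_BB_OFFSETS[at, 3]
    }
    ang <- i * om + ph + dphi
    local[[at]] <- cbind(r * cos(ang), r * sin(ang), i * rise + dz)
  }
  # local frame: helix along +z with azimuth 0 along +x; rotate +z -> axis
  R <- .rotationBetween(c(0, 0, 1), axis)
  # choose the in-plane reference so azimuth 0 maps near +z when possible
  ref <- c(0, 0, 1) - sum(c(0, 0, 1) * axis) * axis / sum(axis^2)
  if (sqrt(sum(ref^2)) > 1e-8) {
    ref <- ref / sqrt(sum(ref^2))
    x1 <- as.vector(R %*% c(1, 0, 0))
    ang0 <- atan2(sum(.rowCross(matrix(x1, 1), matrix(ref, 1)) * axis /
                        sqrt(sum(axis^2))), sum(x1 * ref))
    R <- .rotationAbout(axis, ang0) %*% R
  }
  place <- function(m) sweep(m %*% t(R), 2, origin, `+`)
  bb <- do.call(rbind, lapply(atoms, function(at) {
    p <- place(local[[at]])
    data.frame(residue = residues, atom = at, x = p[, 1], y = p[, 2],
               z = p[, 3], stringsAsFactors = FALSE)
  }))
  bb <- bb[order(bb$residue, match(bb$atom, atoms)), ]
  rownames(bb) <- NULL
  list(ca = place(local[["CA"]]), backbone = bb)
}
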