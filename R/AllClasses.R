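#' @import methods
NULL

#' SystemTopology: static labelling of peptide and lipid atoms
#'
#' Holds one row per atom with its name, residue numbering (1-based within
#' each molecule; the peptide uses the conventional Lys1..Tyr37 numbering),
#' molecule membership, molecule class (\code{"peptide"} or \code{"lipid"})
#' and species label (e.g. \code{"DOPC"}, \code{"DOPS"}, \code{"CHOL"},
#' \code{"IAPP"}). It is the frame of reference for every analysis: atom
#' selections are expressed as (species, residue range, atom-name set)
#' triples against this table.
#'
#' @slot atoms data.frame with columns \code{atom_name}, \code{residue_index},
#'   \code{residue_name}, \code{molecule_id}, \code{molecule_class},
#'   \code{species}.
#' @slot phosphateAtoms character vector of atom names regarded as the
#'   phospholipid phosphate (default \code{"P"}). Species with no such atom
#'   (cholesterol) are treated as phosphate-free lipids.
#' @slot peptideResidueCount integer, number of peptide residues.
#'
#' @seealso [readTopology()]
#' @export
setClass("SystemTopology",
  representation(
    atoms = "data.frame",
    phosphateAtoms = "character",
    peptideResidueCount = "integer"
  )
)

setValidity("SystemTopology", function(object) {
  a <- object@atoms
  need <- c("atom_name", "residue_index", "residue_name", "molecule_id",
            "molecule_class", "species")
  if (!all(need %in% names(a)))
    return(paste("atoms must have columns:", paste(need, collapse = ", ")))
  if (nrow(a) == 0L) return("empty topology")
  if (!all(a$molecule_class %in% c("peptide", "lipid")))
    return("molecule_class must be 'peptide' or 'lipid'")
  pep <- unique(a$molecule_id[a$molecule_class == "peptide"])
  if (length(pep) != 1L)
    return(sprintf("exactly one peptide molecule required, found %d", length(pep)))
  # residue indices contiguous within each molecule
  byMol <- split(a$residue_index, a$molecule_id)
  ok <- vapply(byMol, function(r) {
    u <- unique(r)
    identical(sort(u), seq_len(max(u)))
  }, logical(1))
  if (!all(ok)) return("residue indices must be contiguous within molecules")
  # phosphate atoms may not occur in phosphate-free sterol species
  if ("CHOL" %in% a$species &&
      any(a$atom_name[a$species == "CHOL"] %in% object@phosphateAtoms))
    return("CHOL must not carry phosphate atoms")
  TRUE
})

#' Trajectory: time-ordered coordinate frames over one topology
#'
#' Coordinates are stored internally in Angstrom with the z axis as the
#' bilayer normal; the box is orthorhombic.
#'
#' @slot topology a [SystemTopology-class] object.
#' @slot coords numeric array, dim \code{c(nAtoms, 3, nFrames)}, Angstrom.
#' @slot box numeric matrix \code{nFrames x 3} of box lengths (Angstrom).
#' @slot times numeric vector of frame times in ps.
#'
#' @seealso [readTrajectory()], [generateSystem()]
#' @export
setClass("Trajectory",
  representation(
    topology = "SystemTopology",
    coords = "array",
    box = "matrix",
    times = "numeric"
  )
)

setValidity("Trajectory", function(object) {
  d <- dim(object@coords)
  if (length(d) != 3L || d[2] != 3L) return("coords must be nAtoms x 3 x nFrames")
  if (d[1] != nrow(object@topology@atoms))
    return(sprintf("coordinate count (%d) differs from topology atom count (%d)",
                   d[1], nrow(object@topology@atoms)))
  if (nrow(object@box) != d[3]) return("box must have one row per frame")
  if (any(object@box <= 0)) return("box lengths must be strictly positive")
  if (length(object@times) != d[3]) return("times must have one value per frame")
  TRUE
})

#' TrajectorySeries: repeated trajectories of one experimental condition
#'
#' A condition is a membrane composition combined with a starting peptide
#' conformation (e.g. \code{"PC/CHOL S"}); its repeats are independent
#' trajectories sharing a common topology schema.
#'
#' @slot label character condition label, unique within a study.
#' @slot repeats list of [Trajectory-class] objects.
#'
#' @export
setClass("TrajectorySeries",
  representation(label = "character", repeats = "list")
)

setValidity("TrajectorySeries", function(object) {
  if (length(object@label) != 1L || !nzchar(object@label))
    return("label must be a single non-empty string")
  if (length(object@repeats) < 1L) return("at least one repeat required")
  if (!all(vapply(object@repeats, is, logical(1), "Trajectory")))
    return("repeats must be Trajectory objects")
  n <- vapply(object@repeats, function(t) nrow(t@topology@atoms), integer(1))
  if (length(unique(n)) != 1L)
    return("all repeats must share one topology schema")
  TRUE
})
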