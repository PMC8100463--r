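#' Number of atoms
#' @param x a SystemTopology or Trajectory
#' @return integer
#' @export
setGeneric("nAtoms", function(x) standardGeneric("nAtoms"))

#' Number of frames
#' @param x a Trajectory or TrajectorySeries
#' @return integer (for a series, frames per repeat)
#' @export
setGeneric("nFrames", function(x) standardGeneric("nFrames"))

#' Topology accessor
#' @param x a Trajectory or TrajectorySeries
#' @return a SystemTopology
#' @export
setGeneric("topology", function(x) standardGeneric("topology"))

#' Coordinate accessor
#' @param x a Trajectory
#' @param frame optional frame index; if given, returns an nAtoms x 3 matrix
#' @return the full coordinate array, or one frame as a matrix
#' @export
setGeneric("coords", function(x, frame = NULL) standardGeneric("coords"))

#' Box dimensions accessor
#' @param x a Trajectory
#' @return nFrames x 3 matrix of box lengths (Angstrom)
#' @export
setGeneric("boxDims", function(x) standardGeneric("boxDims"))

#' Frame times accessor (ps)
#' @param x a Trajectory
#' @export
setGeneric("frameTimes", function(x) standardGeneric("frameTimes"))

#' Condition label accessor
#' @param x a TrajectorySeries
#' @export
setGeneric("conditionLabel", function(x) standardGeneric("conditionLabel"))

#' Repeat trajectories accessor
#' @param x a TrajectorySeries
#' @return list of Trajectory objects
#' @export
setGeneric("trajectoryRepeats", function(x) standardGeneric("trajectoryRepeats"))

#' @rdname nAtoms
#' @export
setMethod("nAtoms", "SystemTopology", function(x) nrow(x@atoms))

#' @rdname nAtoms
#' @export
setMethod("nAtoms", "Trajectory", function(x) dim(x@coords)[1])

#' @rdname nFrames
#' @export
setMethod("nFrames", "Trajectory", function(x) dim(x@coords)[3])

#' @rdname nFrames
#' @export
setMethod("nFrames", "TrajectorySeries",
          function(x) vapply(x@repeats, nFrames, integer(1)))

#' @rdname topology
#' @export
setMethod("topology", "Trajectory", function(x) x@topology)

#' @rdname topology
#' @export
setMethod("topology", "TrajectorySeries", function(x) x@repeats[[1]]@topology)

#' @rdname coords
#' @export
setMethod("coords", "Trajectory", function(x, frame = NULL) {
  if (is.null(frame)) return(x@coords)
  x@coords[, , frame, drop = TRUE]
})

#' @rdname boxDims
#' @export
setMethod("boxDims", "Trajectory", function(x) x@box)

#' @rdname frameTimes
#' @export
setMethod("frameTimes", "Trajectory", function(x) x@times)

#' @rdname conditionLabel
#' @export
setMethod("conditionLabel", "TrajectorySeries", function(x) x@label)

#' @rdname trajectoryRepeats
#' @export
setMethod("trajectoryRepeats", "TrajectorySeries", function(x) x@repeats)

setMethod("show", "SystemTopology", function(object) {
  a <- object@atoms
  sp <- table(a$species[!duplicated(a$molecule_id)])
  cat("SystemTopology:", nrow(a), "atoms,",
      length(unique(a$molecule_id)), "molecules\n")
  cat("  species:", paste(sprintf("%s (%d)", names(sp), sp), collapse = ", "), "\n")
  cat("  peptide residues:", object@peptideResidueCount,
      "| phosphate atoms:", paste(object@phosphateAtoms, collapse = ","), "\n")
})

setMethod("show", "Trajectory", function(object) {
  d <- dim(object@coords)
  cat("Trajectory:", d[3], "frames x", d[1], "atoms\n")
  cat(sprintf("  box %.1f x %.1f x %.1f Angstrom | t = %.0f..%.0f ps\n",
              object@box[1, 1], object@box[1, 2], object@box[1, 3],
              object@times[1], object@times[length(object@times)]))
})

setMethod("show", "TrajectorySeries", function(object) {
  cat("TrajectorySeries '", object@label, "': ", length(object@repeats),
      " repeats x ", nFrames(object@repeats[[1]]), " frames\n", sep = "")
})
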