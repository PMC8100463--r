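# Topology and trajectory reading/writing.
#
# Internally everything is Angstrom; GRO files are nm-native and converted on
# the way in/out. Multi-frame GRO files serve as the text trajectory format;
# DCD trajectories are read through bio3d.

.AMINO3 <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS",
             "HSD", "HSE", "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER",
             "THR", "TRP", "TYR", "VAL")

#' Default residue-name to species mapping
#'
#' Maps the twenty standard amino-acid residue names (plus CHARMM histidine
#' tautomer names) to the peptide species \code{"IAPP"}, and the lipid
#' residue names \code{DOPC}, \code{DOPS}, \code{CHOL} (and the CHARMM
#' cholesterol name \code{CHL1}) to their species.
#'
#' @return named character vector (residue name -> species)
#' @export
defaultSpeciesMap <- function() {
  m <- c(stats::setNames(rep("IAPP", length(.AMINO3)), .AMINO3),
         DOPC = "DOPC", DOPS = "DOPS", CHOL = "CHOL", CHL1 = "CHOL")
  m
}

.guessDialect <- function(path, choices) {
  ext <- toupper(tools::file_ext(path))
  if (ext %in% choices) ext else choices[1]
}

.parseGroBlock <- function(lines) {
  # lines: title, natoms, atom lines, box line
  natoms <- suppressWarnings(as.integer(trimws(lines[2])))
  if (is.na(natoms)) stop("malformed GRO atom count line: ", lines[2])
  al <- lines[3:(2 + natoms)]
  resid <- as.integer(substr(al, 1, 5))
  resname <- trimws(substr(al, 6, 10))
  atomname <- trimws(substr(al, 11, 15))
  x <- as.numeric(substr(al, 21, 28)) * 10
  y <- as.numeric(substr(al, 29, 36)) * 10
  z <- as.numeric(substr(al, 37, 44)) * 10
  box <- as.numeric(strsplit(trimws(lines[3 + natoms]), "\\s+")[[1]])[1:3] * 10
  tm <- regmatches(lines[1], regexpr("t=\\s*[-0-9.eE+]+", lines[1]))
  time <- if (length(tm)) as.numeric(sub("t=\\s*", "", tm)) else NA_real_
  list(natoms = natoms, resid = resid, resname = resname, atomname = atomname,
       xyz = cbind(x, y, z), box = box, time = time)
}

.buildTopology <- function(resid, resname, atomname, speciesMap,
                           peptideSpecies, phosphateAtoms) {
  species <- unname(speciesMap[resname])
  if (anyNA(species)) {
    bad <- unique(resname[is.na(species)])
    stop("unknown residue name(s) with no species_map entry: ",
         paste(bad, collapse = ", "))
  }
  cls <- ifelse(species %in% peptideSpecies, "peptide", "lipid")
  # file-order residue blocks: new residue whenever resid or resname changes
  resBlock <- cumsum(c(TRUE, resid[-1] != resid[-length(resid)] |
                               resname[-1] != resname[-length(resname)]))
  # molecules: each lipid residue is a molecule; consecutive peptide residues
  # form one molecule
  newMol <- c(TRUE, (resBlock[-1] != resBlock[-length(resBlock)]) &
                    !(cls[-1] == "peptide" & cls[-length(cls)] == "peptide"))
  molId <- cumsum(newMol)
  # residue index 1-based within each molecule
  residueIndex <- integer(length(resid))
  for (m in unique(molId)) {
    i <- which(molId == m)
    residueIndex[i] <- match(resBlock[i], unique(resBlock[i]))
  }
  atoms <- data.frame(
    atom_name = atomname, residue_index = residueIndex, residue_name = resname,
    molecule_id = molId, molecule_class = cls, species = species,
    stringsAsFactors = FALSE
  )
  pepCount <- if (any(cls == "peptide")) max(residueIndex[cls == "peptide"]) else 0L
  new("SystemTopology", atoms = atoms, phosphateAtoms = phosphateAtoms,
      peptideResidueCount = as.integer(pepCount))
}

#' Read a system topology from a GRO or PDB file
#'
#' Residue names are mapped to species via \code{speciesMap}; an unmapped
#' residue name is a hard error naming the residue. Atom order is preserved.
#'
#' @param path file path
#' @param dialect \code{"auto"} (from extension), \code{"GRO"} or \code{"PDB"}
#' @param speciesMap named character vector mapping residue names to species;
#'   see [defaultSpeciesMap()]
#' @param peptideSpecies species treated as the peptide (default "IAPP")
#' @param phosphateAtoms atom names regarded as the phospholipid phosphate
#' @return a [SystemTopology-class]; the frame-1 coordinates and box are
#'   attached as attributes \code{"xyz"} and \code{"box"} (Angstrom)
#' @export
readTopology <- function(path, dialect = c("auto", "GRO", "PDB"),
                         speciesMap = defaultSpeciesMap(),
                         peptideSpecies = "IAPP", phosphateAtoms = "P") {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file does not exist: ", path)
  if (dialect == "auto") dialect <- .guessDialect(path, c("GRO", "PDB"))
  if (dialect == "GRO") {
    lines <- readLines(path)
    if (length(lines) < 4) stop("empty or truncated GRO file: ", path)
    b <- .parseGroBlock(lines)
    topo <- .buildTopology(b$resid, b$resname, b$atomname, speciesMap,
                           peptideSpecies, phosphateAtoms)
    attr(topo, "xyz") <- b$xyz
    attr(topo, "box") <- b$box
  } else {
    pdb <- bio3d::read.pdb(path, verbose = FALSE)
    a <- pdb$atom
    if (nrow(a) == 0) stop("empty PDB file: ", path)
    topo <- .buildTopology(a$resno, a$resid, a$elety, speciesMap,
                           peptideSpecies, phosphateAtoms)
    attr(topo, "xyz") <- cbind(a$x, a$y, a$z)
    attr(topo, "box") <- NULL
  }
  topo
}

#' Read a coordinate trajectory
#'
#' Supports multi-frame GRO text trajectories and binary DCD files (via
#' bio3d). Frames are returned in time order with coordinates in Angstrom
#' regardless of the dialect-native unit (GRO is nm-native).
#'
#' @param path trajectory file
#' @param topo the matching [SystemTopology-class]
#' @param dialect \code{"auto"}, \code{"GRO"} or \code{"DCD"}
#' @param dt frame spacing in ps, used when the file stores no times
#' @param box fallback c(Lx, Ly, Lz) in Angstrom for dialects without box
#'   records
#' @return a [Trajectory-class]
#' @export
readTrajectory <- function(path, topo, dialect = c("auto", "GRO", "DCD"),
                           dt = 1, box = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file does not exist: ", path)
  if (dialect == "auto") dialect <- .guessDialect(path, c("GRO", "DCD"))
  nat <- nAtoms(topo)
  if (dialect == "GRO") {
    lines <- readLines(path)
    if (!length(lines)) stop("empty trajectory file: ", path)
    frames <- list(); boxes <- list(); times <- numeric()
    i <- 1L; k <- 0L
    while (i <= length(lines)) {
      while (i <= length(lines) && !nzchar(trimws(lines[i]))) i <- i + 1L
      if (i > length(lines)) break
      k <- k + 1L
      if (i + 1L > length(lines))
        stop(sprintf("truncated frame %d in %s", k, path))
      natF <- suppressWarnings(as.integer(trimws(lines[i + 1L])))
      if (is.na(natF))
        stop(sprintf("truncated or malformed frame %d in %s", k, path))
      if (natF != nat)
        stop(sprintf("atom-count mismatch: trajectory has %d atoms, topology has %d",
                     natF, nat))
      if (i + 2L + natF > length(lines))
        stop(sprintf("truncated frame %d in %s", k, path))
      b <- .parseGroBlock(lines[i:(i + 2L + natF)])
      frames[[k]] <- b$xyz
      boxes[[k]] <- b$box
      times[k] <- if (is.na(b$time)) (k - 1) * dt else b$time
      i <- i + 3L + natF
      while (i <= length(lines) && !nzchar(trimws(lines[i]))) i <- i + 1L
    }
    arr <- array(unlist(frames), dim = c(nat, 3, k))
    bx <- do.call(rbind, boxes)
  } else {
    xyz <- bio3d::read.dcd(path, verbose = FALSE)
    k <- nrow(xyz)
    natF <- ncol(xyz) / 3L
    if (natF != nat)
      stop(sprintf("atom-count mismatch: trajectory has %d atoms, topology has %d",
                   natF, nat))
    arr <- array(0, dim = c(nat, 3, k))
    for (f in seq_len(k)) arr[, , f] <- matrix(xyz[f, ], ncol = 3, byrow = TRUE)
    cell <- tryCatch(bio3d::read.dcd(path, cell = TRUE, verbose = FALSE),
                     error = function(e) NULL)
    bx <- if (!is.null(cell) && all(is.finite(cell[, 1:3])) && all(cell[, 1:3] > 0)) {
      unname(cell[, 1:3, drop = FALSE])
    } else if (!is.null(box)) {
      matrix(rep(box, each = k), nrow = k)
    } else stop("DCD file carries no box; supply box = c(Lx, Ly, Lz)")
    times <- (seq_len(k) - 1) * dt
  }
  new("Trajectory", topology = topo, coords = arr, box = bx, times = times)
}

.formatGroFrame <- function(topo, xyz, box, title) {
  a <- topo@atoms
  # global residue numbering for output
  key <- paste(a$molecule_id, a$residue_index)
  gres <- match(key, unique(key)) %% 100000L
  lines <- sprintf("%5d%-5s%5s%5d%8.3f%8.3f%8.3f",
                   gres, a$residue_name, a$atom_name,
                   seq_len(nrow(a)) %% 100000L,
                   xyz[, 1] / 10, xyz[, 2] / 10, xyz[, 3] / 10)
  c(title, sprintf("%5d", nrow(a)), lines,
    sprintf("%10.5f%10.5f%10.5f", box[1] / 10, box[2] / 10, box[3] / 10))
}

#' Write a single-frame GRO file
#'
#' @param topo a [SystemTopology-class]
#' @param xyz nAtoms x 3 coordinate matrix (Angstrom)
#' @param box c(Lx, Ly, Lz) in Angstrom
#' @param path output file
#' @param title GRO title line
#' @export
writeGro <- function(topo, xyz, box, path, title = "pepMembrane system") {
  writeLines(.formatGroFrame(topo, xyz, box, title), path)
  invisible(path)
}

#' Write a trajectory as a multi-frame GRO file
#'
#' @param traj a [Trajectory-class]
#' @param path output file
#' @export
writeTrajectoryGro <- function(traj, path) {
  topo <- traj@topology
  con <- file(path, "w")
  on.exit(close(con))
  for (f in seq_len(nFrames(traj))) {
    writeLines(.formatGroFrame(topo, traj@coords[, , f], traj@box[f, ],
                               sprintf("frame %d t= %.3f", f, traj@times[f])),
               con)
  }
  invisible(path)
}
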