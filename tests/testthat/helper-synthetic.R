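# Shared fixtures and independent brute-force oracles. The oracles share no
# code with the analysis modules: plain double loops and direct formulas.

smallConfig <- function(...) {
  args <- list(...)
  defaults <- list(nLipidsPerLeaflet = 30, nFrames = 50, seed = 1,
                   composition = c(DOPC = 0.6, DOPS = 0.2, CHOL = 0.2))
  do.call(syntheticConfig, utils::modifyList(defaults, args))
}

# brute-force wrapped lateral displacement
oracleWrap <- function(d, L) {
  while (d >= L / 2) d <- d - L
  while (d < -L / 2) d <- d + L
  d
}

# brute-force per-frame in-shell lipid count per species: plain loops over
# molecules, beads and peptide atoms
oracleShellCounts <- function(traj, frame, radius, residues = 1:19,
                              mols = NULL) {
  a <- traj@topology@atoms
  xyz <- traj@coords[, , frame]
  box <- traj@box[frame, ]
  pep <- which(a$molecule_class == "peptide" & a$residue_index %in% residues)
  if (is.null(mols))
    mols <- unique(a$molecule_id[a$molecule_class == "lipid"])
  allSp <- unique(a$species[a$molecule_class == "lipid"])
  counts <- stats::setNames(numeric(length(allSp)), allSp)
  for (m in mols) {
    rows <- which(a$molecule_id == m)
    hit <- FALSE
    for (r in rows) {
      for (p in pep) {
        dx <- oracleWrap(xyz[r, 1] - xyz[p, 1], box[1])
        dy <- oracleWrap(xyz[r, 2] - xyz[p, 2], box[2])
        dz <- xyz[r, 3] - xyz[p, 3]
        if (dx * dx + dy * dy + dz * dz <= radius^2) { hit <- TRUE; break }
      }
      if (hit) break
    }
    if (hit) {
      sp <- a$species[rows[1]]
      counts[sp] <- counts[sp] + 1
    }
  }
  counts
}

# brute-force MSD over all time origins (direct double loop)
oracleMSD <- function(xy) {
  nMol <- dim(xy)[1]; F <- dim(xy)[3]
  out <- numeric(F)
  for (tau in 0:(F - 1)) {
    acc <- 0; n <- 0
    for (t0 in 1:(F - tau)) {
      d <- xy[, , t0 + tau, drop = FALSE] - xy[, , t0, drop = FALSE]
      acc <- acc + sum(d * d)
      n <- n + nMol
    }
    out[tau + 1] <- acc / n
  }
  out
}

# a tiny hand-written GRO file (nm units) with the given residue layout
writeTinyGro <- function(path, residues, atoms = NULL) {
  # residues: data.frame(resname, n_atoms); atom names X1..Xk
  lines <- c("tiny system", "")
  n <- 0; body <- character(0)
  for (i in seq_len(nrow(residues))) {
    for (j in seq_len(residues$n_atoms[i])) {
      n <- n + 1
      nm <- if (is.null(atoms)) paste0("X", j) else atoms[[i]][j]
      body <- c(body, sprintf("%5d%-5s%5s%5d%8.3f%8.3f%8.3f",
                              i, residues$resname[i], nm, n,
                              i * 0.5, j * 0.3, 1.0))
    }
  }
  lines[2] <- sprintf("%5d", n)
  writeLines(c(lines, body, "   8.00000   8.00000   9.00000"), path)
  path
}

# build a minimal Trajectory directly from coordinate pieces: a 37-residue
# peptide backbone (CA-only geometry cheated with fixed offsets) plus
# explicit lipid bead positions per frame
manualTrajectory <- function(lipids, frames, box = c(80, 80, 90),
                             peptideZ = 15) {
  # lipids: data.frame(species, head_atom, n_tails); frames: list of
  # per-frame matrices of head xyz (one row per lipid); tails placed 2 A
  # straight below the head
  pepAtoms <- data.frame(
    atom_name = rep(c("N", "CA", "C", "O"), 37),
    residue_index = rep(1:37, each = 4),
    residue_name = rep(iappSequence(), each = 4),
    molecule_id = 1L, molecule_class = "peptide", species = "IAPP",
    stringsAsFactors = FALSE)
  lipAtoms <- do.call(rbind, lapply(seq_len(nrow(lipids)), function(i) {
    k <- lipids$n_tails[i]
    data.frame(atom_name = c(lipids$head_atom[i], if (k > 0) paste0("T", 1:k)),
               residue_index = 1L, residue_name = lipids$species[i],
               molecule_id = 1L + i, molecule_class = "lipid",
               species = lipids$species[i], stringsAsFactors = FALSE)
  }))
  topo <- new("SystemTopology", atoms = rbind(pepAtoms, lipAtoms),
              phosphateAtoms = "P", peptideResidueCount = 37L)
  nat <- nrow(topo@atoms)
  F <- length(frames)
  arr <- array(0, dim = c(nat, 3, F))
  hx <- buildIdealHelix(1:37, axis = c(1, 0, 0),
                        origin = c(box[1] / 2 - 27, box[2] / 2, peptideZ))
  bb <- as.matrix(hx$backbone[, c("x", "y", "z")])
  for (f in seq_len(F)) {
    arr[1:148, , f] <- bb
    row <- 148L
    for (i in seq_len(nrow(lipids))) {
      h <- frames[[f]][i, ]
      k <- lipids$n_tails[i]
      arr[row + 1, , f] <- h
      if (k > 0) for (j in 1:k) arr[row + 1 + j, , f] <- h - c(0, 0, 2 * j)
      row <- row + 1L + k
    }
  }
  new("Trajectory", topology = topo, coords = arr,
      box = matrix(rep(box, each = F), F), times = (seq_len(F) - 1) * 100)
}
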