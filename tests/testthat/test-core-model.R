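test_that("GRO topology reading preserves counts and maps species", {
  tmp <- tempfile(fileext = ".gro")
  res <- data.frame(resname = c(iappSequence(), rep("DOPC", 10)),
                    n_atoms = c(rep(4, 37), rep(3, 10)))
  atoms <- c(lapply(1:37, function(i) c("N", "CA", "C", "O")),
             lapply(1:10, function(i) c("P", "T1", "T2")))
  writeTinyGro(tmp, res, atoms)
  topo <- readTopology(tmp)
  expect_equal(nAtoms(topo), 37 * 4 + 10 * 3)
  expect_equal(length(unique(topo@atoms$molecule_id)), 11)
  expect_equal(sum(topo@atoms$molecule_class == "peptide"), 148)
  expect_equal(topo@peptideResidueCount, 37L)
  # atom order preserved
  expect_equal(topo@atoms$atom_name[1:4], c("N", "CA", "C", "O"))
})

test_that("unknown residue names are a hard error naming the residue", {
  tmp <- tempfile(fileext = ".gro")
  writeTinyGro(tmp, data.frame(resname = c("DOPC", "POPG"), n_atoms = c(2, 2)),
               list(c("P", "T1"), c("P", "T1")))
  expect_error(readTopology(tmp), "POPG")
})

test_that("PDB dialect maps CHL1 to CHOL", {
  tmp <- tempfile(fileext = ".pdb")
  lines <- c(
    sprintf("ATOM  %5d %-4s %-4sA%4d    %8.3f%8.3f%8.3f  1.00  0.00",
            1:4, c("N", "CA", "C", "O"), "LYS", 1,
            c(1, 2, 3, 4), c(0, 1, 0, 1), c(0, 0, 1, 1)),
    sprintf("ATOM  %5d %-4s %-4sA%4d    %8.3f%8.3f%8.3f  1.00  0.00",
            5:6, c("O3", "T1"), "CHL1", 2, c(8, 8), c(8, 8), c(10, 8)),
    "END")
  writeLines(lines, tmp)
  topo <- readTopology(tmp, dialect = "PDB",
                       speciesMap = c(defaultSpeciesMap()))
  expect_true("CHOL" %in% topo@atoms$species)
  expect_equal(sum(topo@atoms$species == "CHOL"), 2)
})

test_that("minimum-image displacement wraps laterally and passes z through", {
  expect_equal(minimumImage(c(0, 0, 0), c(79, 0, 0), c(80, 80)),
               c(-1, 0, 0))
  expect_equal(minimumImage(c(1, 2, 3), c(1, 2, 3), c(80, 80)), c(0, 0, 0))
  d <- minimumImage(c(0, 0, 5), c(0, 0, -30), c(80, 80))
  expect_equal(abs(d[3]), 35)  # z unwrapped
  expect_equal(d[1:2], c(0, 0))
})

test_that("minimum-image displacement is antisymmetric after wrapping", {
  set.seed(11)
  a <- matrix(runif(3000, -200, 200), ncol = 3)
  b <- matrix(runif(3000, -200, 200), ncol = 3)
  box <- c(80, 64)
  dab <- minimumImage(a, b, box)
  dba <- minimumImage(b, a, box)
  # componentwise negation up to re-wrapping at the half-box boundary
  rewrap <- function(d, L) d - L * floor(d / L + 0.5)
  expect_equal(rewrap(dab[, 1] + dba[, 1], box[1]), rep(0, 1000))
  expect_equal(rewrap(dab[, 2] + dba[, 2], box[2]), rep(0, 1000))
  expect_equal(dab[, 3], -dba[, 3])
})

test_that("leaflet assignment recovers generator truth incl. CHOL and bound leaflet", {
  sim <- generateSystem(smallConfig(seed = 21))
  asg <- assignLeaflets(sim$trajectory, 1)
  truth <- sim$truth$lipidLeaflet
  expect_equal(as.character(asg$leaflet[names(truth)]), unname(truth))
  expect_equal(asg$boundLeaflet, sim$truth$boundLeaflet)
  expect_lt(abs(asg$planeZ["upper"] - 19), 1)
  expect_lt(abs(asg$planeZ["lower"] + 19), 1)
})

test_that("leaflet assignment is stable under rigid z translation", {
  sim <- generateSystem(smallConfig(seed = 22, nFrames = 3))
  tr <- sim$trajectory
  tr2 <- tr
  tr2@coords[, 3, ] <- tr2@coords[, 3, ] + 7.5
  a1 <- assignLeaflets(tr, 2)
  a2 <- assignLeaflets(tr2, 2)
  expect_equal(a1$leaflet, a2$leaflet)
  expect_equal(a2$planeZ, a1$planeZ + 7.5)
})

test_that("a monolayer raises the dedicated error", {
  lip <- data.frame(species = rep("DOPC", 6), head_atom = "P", n_tails = 0)
  fr <- list(cbind(runif(6, 0, 80), runif(6, 0, 80), 19 + rnorm(6, 0, 0.5)))
  tr <- manualTrajectory(lip, fr)
  expect_error(assignLeaflets(tr, 1), "monolayer")
})

test_that("trajectory round trip reproduces coordinates within format precision", {
  sim <- generateSystem(smallConfig(seed = 23, nFrames = 4))
  d <- tempfile()
  writeSystem(sim, d)
  topo <- readTopology(file.path(d, "topology.gro"))
  tr <- readTrajectory(file.path(d, "trajectory.gro"), topo)
  expect_equal(nFrames(tr), 4)
  expect_lt(max(abs(tr@coords - sim$trajectory@coords)), 0.0051)
  expect_equal(tr@times, sim$trajectory@times)
})

test_that("trajectory reading enforces the atom-count contract", {
  sim <- generateSystem(smallConfig(seed = 24, nFrames = 2))
  d <- tempfile()
  writeSystem(sim, d)
  full <- readTopology(file.path(d, "topology.gro"))
  # a mismatched topology
  tmp <- tempfile(fileext = ".gro")
  writeTinyGro(tmp, data.frame(resname = c("LYS", "DOPC"), n_atoms = c(4, 2)),
               list(c("N", "CA", "C", "O"), c("P", "T1")))
  small <- readTopology(tmp)
  expect_error(readTrajectory(file.path(d, "trajectory.gro"), small),
               "atom-count mismatch")
  # truncated frame
  lines <- readLines(file.path(d, "trajectory.gro"))
  writeLines(lines[1:(length(lines) - 10)], tmp)
  expect_error(readTrajectory(tmp, full), "truncated")
})
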