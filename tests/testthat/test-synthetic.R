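test_that("ideal helix has canonical alpha-helical geometry", {
  h <- buildIdealHelix(1:20)
  dca <- sqrt(rowSums((h$ca[-1, ] - h$ca[-20, ])^2))
  expect_true(all(abs(dca - 3.8) < 0.1))
  # 100 deg twist: residues i and i+18 axially aligned (5 full turns)
  v1 <- h$ca[1, 2:3]; v19 <- h$ca[19, 2:3]  # axis along x: compare y,z phase
  ang <- acos(sum(v1 * v19) / sqrt(sum(v1^2) * sum(v19^2))) * 180 / pi
  expect_lt(ang, 1)
})

test_that("ideal helix backbone carries canonical dihedrals, agreeing with bio3d", {
  h <- buildIdealHelix(1:10)
  bb <- h$backbone
  g <- function(at) as.matrix(bb[bb$atom == at, c("x", "y", "z")])
  N <- g("N"); CA <- g("CA"); C <- g("C")
  phi <- pepMembrane:::.dihedral(C[4, , drop = FALSE], N[5, , drop = FALSE],
                                 CA[5, , drop = FALSE], C[5, , drop = FALSE])
  psi <- pepMembrane:::.dihedral(N[5, , drop = FALSE], CA[5, , drop = FALSE],
                                 C[5, , drop = FALSE], N[6, , drop = FALSE])
  expect_lt(abs(phi - (-57)), 2)
  expect_lt(abs(psi - (-47)), 2)
  # independent oracle: bio3d torsion on the same four atoms
  ref <- bio3d::torsion.xyz(as.vector(t(rbind(C[4, ], N[5, ], CA[5, ], C[5, ]))),
                            atm.inc = 4)
  expect_equal(unname(phi), unname(ref), tolerance = 1e-6)
  expect_error(buildIdealHelix(integer(0)), "empty")
})

test_that("lipid random walks have the prescribed step statistics", {
  # D = 0: stationary
  w0 <- pepMembrane:::.withSeed(5, simulateLipidWalk(4, 10, 0, 100, c(80, 80)))
  expect_equal(w0$unwrapped[, , 1], w0$unwrapped[, , 10])
  # unit conversion: D = 7e-8 cm^2/s, dt = 100 ps -> step SD 0.374 A
  sd_expect <- sqrt(2 * 7e-8 * 1e4 * 100)
  expect_equal(sd_expect, 0.3741657, tolerance = 1e-6)
  w <- pepMembrane:::.withSeed(6, simulateLipidWalk(100, 1001, 7e-8, 100, c(500, 500)))
  steps <- w$unwrapped[, , -1] - w$unwrapped[, , -1001]
  expect_lt(abs(var(as.vector(steps)) / (2 * 7e-8 * 1e4 * 100) - 1), 0.02)
})

test_that("tail vector sampling hits the target order parameter", {
  s1 <- pepMembrane:::.withSeed(7, sampleTailVectors(1, 1000))
  expect_true(all(abs(abs(s1[, 3]) - 1) < 1e-12))
  sPerp <- pepMembrane:::.withSeed(7, sampleTailVectors(-0.5, 1000))
  expect_true(all(abs(sPerp[, 3]) < 1e-12))
  sampS <- function(v) mean((3 * v[, 3]^2 - 1) / 2)
  s0 <- pepMembrane:::.withSeed(8, sampleTailVectors(0, 1e5))
  expect_lt(abs(sampS(s0)), 0.02)
  s4 <- pepMembrane:::.withSeed(9, sampleTailVectors(0.4, 1e6))
  expect_lt(abs(sampS(s4) - 0.4), 0.01)
  expect_error(sampleTailVectors(1.2, 10), "targetS")
})

test_that("generation is deterministic and conserves composition", {
  cfg <- smallConfig(seed = 31, nFrames = 8)
  s1 <- generateSystem(cfg)
  s2 <- generateSystem(cfg)
  expect_identical(s1$trajectory@coords, s2$trajectory@coords)
  expect_identical(s1$truth$loopStates, s2$truth$loopStates)
  # species counts per leaflet are frame-independent by construction;
  # check the topology realizes the configured fractions
  a <- s1$trajectory@topology@atoms
  mols <- !duplicated(a$molecule_id) & a$molecule_class == "lipid"
  expect_equal(sum(a$species[mols] == "DOPC"), 2 * round(0.6 * 30))
  # file round trip is byte-identical for identical config+seed
  d1 <- tempfile(); d2 <- tempfile()
  writeSystem(s1, d1); writeSystem(s2, d2)
  expect_identical(readLines(file.path(d1, "trajectory.gro")),
                   readLines(file.path(d2, "trajectory.gro")))
})

test_that("box too small for the lipid count is rejected", {
  expect_error(syntheticConfig(box = c(40, 40), nLipidsPerLeaflet = 40),
               "box too small")
})

test_that("planted enrichment passes the generator's own brute-force recount", {
  cfg <- smallConfig(seed = 33, nFrames = 250, nLipidsPerLeaflet = 40,
                     composition = c(DOPC = 0.55, DOPS = 0.15, CHOL = 0.30),
                     enrichment = list(species = "DOPS", factor = 2, radius = 7))
  sim <- generateSystem(cfg)
  tr <- sim$trajectory
  mols <- as.integer(names(sim$truth$lipidLeaflet))[
    sim$truth$lipidLeaflet == "upper"]
  tot <- NULL
  for (f in seq(1, 250, by = 5)) {
    cnt <- oracleShellCounts(tr, f, 7, mols = mols)
    tot <- if (is.null(tot)) cnt else tot + cnt
  }
  frac <- tot[["DOPS"]] / sum(tot)
  expect_lt(abs(frac / 0.15 - 2), 0.2)  # 2x bulk within 10%
})

test_that("null enrichment leaves the near-shell composition at bulk", {
  cfg <- smallConfig(seed = 34, nFrames = 250, nLipidsPerLeaflet = 40,
                     composition = c(DOPC = 0.5, DOPS = 0.5),
                     diffusion = c(DOPC = 7e-8, DOPS = 7e-8),
                     placement = "iid")
  sim <- generateSystem(cfg)
  mols <- as.integer(names(sim$truth$lipidLeaflet))[
    sim$truth$lipidLeaflet == "upper"]
  tot <- NULL
  for (f in seq(1, 250, by = 5)) {
    cnt <- oracleShellCounts(sim$trajectory, f, 7, mols = mols)
    tot <- if (is.null(tot)) cnt else tot + cnt
  }
  expect_lt(abs(tot[["DOPS"]] / sum(tot) - 0.5), 0.05)
})
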