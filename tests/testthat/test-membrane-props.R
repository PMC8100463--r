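test_that("area per lipid is the exact leaflet arithmetic", {
  cfg <- smallConfig(seed = 61, nFrames = 2, nLipidsPerLeaflet = 100,
                     box = c(80, 80))
  sim <- generateSystem(cfg)
  expect_equal(areaPerLipid(sim$trajectory)$mean, 64.0)
  # 60:40 PC:CHOL -- excluding CHOL scales the APL by 1/0.6
  cfg2 <- smallConfig(seed = 62, nFrames = 2, nLipidsPerLeaflet = 100,
                      box = c(90, 90),
                      composition = c(DOPC = 0.6, CHOL = 0.4))
  sim2 <- generateSystem(cfg2)
  withChol <- areaPerLipid(sim2$trajectory, countChol = TRUE)$mean
  without <- areaPerLipid(sim2$trajectory, countChol = FALSE)$mean
  expect_equal(withChol / without, 0.6)
})

test_that("MSD accumulators match the brute-force oracle and closed forms", {
  # stationary
  xy0 <- array(rep(c(3, 4), each = 5), dim = c(5, 2, 7))
  expect_equal(lateralMSD(xy0, dt = 1)$msd, rep(0, 7))
  # ballistic motion r = v t: MSD = |v|^2 t^2
  v <- c(0.3, -0.4)
  F <- 20
  xyb <- array(0, dim = c(1, 2, F))
  for (f in 1:F) xyb[1, , f] <- v * (f - 1)
  m <- lateralMSD(xyb, dt = 1)
  expect_equal(m$msd, sum(v^2) * (0:(F - 1))^2)
  # FFT path vs brute-force double loop on random tracks
  set.seed(63)
  xy <- array(rnorm(6 * 2 * 40), dim = c(6, 2, 40))
  expect_equal(lateralMSD(xy, dt = 1)$msd, oracleMSD(xy), tolerance = 1e-10)
  # strided direct path agrees at stride 1
  expect_equal(pepMembrane:::.msdTracks(xy, stride = 1L),
               pepMembrane:::.msdTracks(xy, stride = 2L), tolerance = 0.3)
  # time reversal leaves the estimator unchanged
  xyr <- xy[, , 40:1, drop = FALSE]
  expect_equal(lateralMSD(xy, dt = 1)$msd, lateralMSD(xyr, dt = 1)$msd,
               tolerance = 1e-10)
})

test_that("diffusion coefficients convert slopes exactly and recover plants", {
  msd <- structure(list(lag = (0:100) * 10, msd = 2.8e-3 * (0:100) * 10,
                        species = NA, nMolecules = 1), class = "MSDCurve")
  expect_equal(diffusionCoefficient(msd)$D, 7e-8)
  msd0 <- msd; msd0$msd[] <- 0
  expect_equal(diffusionCoefficient(msd0)$D, 0)
  # negative slope warns but reports
  msdn <- msd; msdn$msd <- rev(msd$msd)
  expect_warning(dn <- diffusionCoefficient(msdn), "negative")
  expect_lt(dn$D, 0)
  # two-species recovery from a generated membrane: the trajectory route
  # (wrapped coordinates, unwrapping, drift removal) must agree with the
  # ground-truth unwrapped tracks of the same realization, and both must
  # sit near the planted coefficients
  cfg <- smallConfig(seed = 64, nFrames = 1500, nLipidsPerLeaflet = 60,
                     composition = c(DOPC = 0.5, DOPS = 0.5),
                     diffusion = c(DOPC = 7e-8, DOPS = 3.5e-8),
                     dt = 200, placement = "walk")
  sim <- generateSystem(cfg)
  for (sp in c("DOPC", "DOPS")) {
    dTraj <- diffusionCoefficient(lateralMSD(sim$trajectory, species = sp))$D
    dTruth <- diffusionCoefficient(
      lateralMSD(sim$truth$tracks[[sp]]$unwrapped, dt = 200))$D
    expect_lt(abs(dTraj / dTruth - 1), 0.05)
    expect_lt(abs(dTraj / cfg$diffusion[[sp]] - 1), 0.2)
  }
  expect_error(lateralMSD(sim$trajectory, species = "POPE"), "absent")
})

test_that("order parameter hits the exact limits and planted targets", {
  lip <- data.frame(species = rep("DOPC", 8), head_atom = "P", n_tails = 3)
  heads <- cbind(seq(5, 75, length.out = 8), 40, 19)
  tr <- manualTrajectory(lip, list(heads))  # tails straight down
  expect_equal(orderParameter(tr)$average, 1)
  # perpendicular tails: rebuild beads along +x
  tr2 <- tr
  a <- tr2@topology@atoms
  for (m in unique(a$molecule_id[a$molecule_class == "lipid"])) {
    rows <- which(a$molecule_id == m)
    h <- tr2@coords[rows[1], , 1]
    for (j in 2:4) tr2@coords[rows[j], , 1] <- h + c(2 * (j - 1), 0, 0)
  }
  expect_equal(orderParameter(tr2)$average, -0.5)
  expect_error(orderParameter(tr, tailAtoms = c("T1", "T2")), "fewer than 3")
  # planted intermediate order from the generator
  cfg <- smallConfig(seed = 65, nFrames = 150, nLipidsPerLeaflet = 60,
                     targetOrderParameter = 0.4)
  sim <- generateSystem(cfg)
  expect_lt(abs(orderParameter(sim$trajectory)$average - 0.4), 0.02)
})

test_that("membrane thickness is recovered from phosphate density peaks", {
  cfg <- smallConfig(seed = 66, nFrames = 300, nLipidsPerLeaflet = 50,
                     leafletZ = 19, phosphateSigma = 1)
  sim <- generateSystem(cfg)
  th <- membraneThickness(sim$trajectory)
  expect_lt(abs(th - 38), 0.5)
  # rigid z shift leaves the thickness unchanged
  tr2 <- sim$trajectory
  tr2@coords[, 3, ] <- tr2@coords[, 3, ] + 6
  expect_equal(membraneThickness(tr2), th, tolerance = 1e-8)
  # symmetric noise broadening does not move the peaks (within resolution)
  cfg2 <- cfg; cfg2$phosphateSigma <- 2; cfg2$seed <- 67L
  th2 <- membraneThickness(generateSystem(cfg2)$trajectory)
  expect_lt(abs(th2 - th), 1)
})

test_that("the order parameter stays within its mathematical bounds", {
  for (s in c(-0.5, -0.2, 0, 0.3, 0.7, 1)) {
    v <- pepMembrane:::.withSeed(68, sampleTailVectors(s, 500))
    S <- mean((3 * v[, 3]^2 - 1) / 2)
    expect_gte(S, -0.5); expect_lte(S, 1)
  }
})

test_that("condition ordering by planted membrane properties is preserved", {
  # a fluid thin membrane vs an ordered thick one: the module must order
  # the conditions as planted (the qualitative CHOL pattern)
  fluid <- smallConfig(seed = 69, nFrames = 250, nLipidsPerLeaflet = 40,
                       composition = c(DOPC = 1), diffusion = c(DOPC = 7e-8),
                       targetOrderParameter = 0.3, leafletZ = 19,
                       dt = 200, placement = "walk")
  ordered <- smallConfig(seed = 70, nFrames = 250, nLipidsPerLeaflet = 40,
                         composition = c(DOPC = 0.6, CHOL = 0.4),
                         diffusion = c(DOPC = 3.5e-8, CHOL = 3.5e-8),
                         targetOrderParameter = 0.7, leafletZ = 20.5,
                         dt = 200, placement = "walk")
  tf <- generateSystem(fluid)$trajectory
  to <- generateSystem(ordered)$trajectory
  expect_gt(diffusionCoefficient(lateralMSD(tf, species = "DOPC"))$D,
            diffusionCoefficient(lateralMSD(to, species = "DOPC"))$D)
  expect_lt(orderParameter(tf)$average, orderParameter(to)$average)
  expect_lt(membraneThickness(tf), membraneThickness(to))
})
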