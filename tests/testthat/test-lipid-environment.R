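test_that("shell membership is closed at the radius and counts molecules once", {
  # one lipid with its head exactly at 6.9 A laterally from a peptide atom,
  # another entirely at 7.1 A
  lip0 <- data.frame(species = "DOPC", head_atom = "P", n_tails = 0)
  tr0 <- manualTrajectory(lip0, list(cbind(0, 0, 19)))
  a <- tr0@topology@atoms
  pep <- tr0@coords[a$molecule_class == "peptide" & a$residue_index <= 19, , 1]
  probe <- colMeans(pep) + c(0, -50, 0)
  dp <- sqrt(rowSums(sweep(pep, 2, probe)^2))
  A <- pep[which.min(dp), ]
  u <- (probe - A) / sqrt(sum((probe - A)^2))
  h1 <- A + 6.9 * u
  h2 <- A + 7.1 * u
  # confirm by plain loop that the crafted positions sit at the intended
  # minimum distances from the whole selection
  expect_equal(min(sqrt(rowSums(sweep(pep, 2, h1)^2))), 6.9, tolerance = 1e-8)
  expect_equal(min(sqrt(rowSums(sweep(pep, 2, h2)^2))), 7.1, tolerance = 1e-8)
  lip2 <- data.frame(species = c("DOPS", "DOPC", "DOPC", "DOPC"),
                     head_atom = "P", n_tails = 0)
  fr <- rbind(h1, h2, c(70, 70, 19), c(5, 5, -19))
  tr <- manualTrajectory(lip2, list(fr))
  cnt <- shellComposition(tr, 7, leafletScope = "all")
  expect_equal(cnt[1, "DOPS"], c(DOPS = 1))  # 6.9 A counted
  expect_equal(cnt[1, "DOPC"], c(DOPC = 0))  # 7.1 A not counted
})

test_that("accelerated shell counting matches the all-pairs oracle exactly", {
  sim <- generateSystem(smallConfig(seed = 71, nFrames = 6,
                                    nLipidsPerLeaflet = 25))
  tr <- sim$trajectory
  asg <- assignLeaflets(tr, 1)
  mols <- as.integer(names(asg$leaflet))[asg$leaflet == asg$boundLeaflet]
  for (f in c(1, 4, 6)) {
    fast <- shellComposition(tr, 7, frames = f)
    slow <- oracleShellCounts(tr, f, 7, mols = mols)
    for (s in colnames(fast))
      expect_equal(unname(fast[1, s]), unname(slow[[s]]))
  }
  # species counts sum to the total in-shell count by construction
  allR <- shellComposition(tr, 14)
  expect_true(all(rowSums(allR) >= rowSums(shellComposition(tr, 7))))
})

test_that("a single-species membrane has D-E exactly 1 at every radius", {
  cfg <- smallConfig(seed = 72, nFrames = 40, composition = c(DOPC = 1),
                     diffusion = c(DOPC = 7e-8))
  ss <- syntheticSeries(cfg, nRepeats = 2, label = "pure")
  de <- deIndex(ss$series)
  expect_equal(de$mean, rep(1, 3))
})

test_that("planted enrichment is recovered and attenuates with distance", {
  cfg <- smallConfig(seed = 73, nFrames = 400, nLipidsPerLeaflet = 50,
                     composition = c(DOPC = 0.55, DOPS = 0.15, CHOL = 0.30),
                     enrichment = list(species = "DOPS", factor = 2, radius = 7))
  ss <- syntheticSeries(cfg, nRepeats = 3, label = "enriched")
  de <- deIndex(ss$series)
  d7 <- de$mean[de$species == "DOPS" & de$radius == 7]
  d21 <- de$mean[de$species == "DOPS" & de$radius == 21]
  expect_lt(abs(d7 - 2), 0.2)
  expect_gt(d21, 1)
  expect_lt(d21, d7)  # dilution toward the bulk value
  expect_true(all(de$p[de$species == "DOPS"] <= 0.05))
})

test_that("D-E is invariant under uniform duplication of every lipid", {
  sim <- generateSystem(smallConfig(seed = 74, nFrames = 25))
  tr <- sim$trajectory
  # duplicate the whole lipid complement with tiny offsets
  a <- tr@topology@atoms
  lip <- which(a$molecule_class == "lipid")
  a2 <- a[lip, ]
  a2$molecule_id <- a2$molecule_id + max(a$molecule_id)
  topo2 <- new("SystemTopology", atoms = rbind(a, a2),
               phosphateAtoms = "P", peptideResidueCount = 37L)
  arr <- array(0, dim = c(nrow(a) + nrow(a2), 3, nFrames(tr)))
  arr[seq_len(nrow(a)), , ] <- tr@coords
  arr[nrow(a) + seq_len(nrow(a2)), , ] <- tr@coords[lip, , ] + 0.01
  tr2 <- new("Trajectory", topology = topo2, coords = arr, box = tr@box,
             times = tr@times)
  s1 <- new("TrajectorySeries", label = "x", repeats = list(tr, tr))
  s2 <- new("TrajectorySeries", label = "x", repeats = list(tr2, tr2))
  de1 <- deIndex(s1, radii = 7)
  de2 <- deIndex(s2, radii = 7)
  expect_equal(de2$mean, de1$mean, tolerance = 0.02)
})

test_that("rigid superposition recovers exact and noisy transforms", {
  set.seed(75)
  X <- matrix(rnorm(30, sd = 3), 10, 3)
  fit0 <- alignToReference(X, X, 1:10)
  expect_equal(fit0$R, diag(3), tolerance = 1e-10)
  expect_lt(fit0$rmsd, 1e-10)
  R <- pepMembrane:::.rotationAbout(c(0, 0, 1), pi / 2)
  Y <- X %*% t(R)
  fit <- alignToReference(Y, X, 1:10)
  expect_lt(fit$rmsd, 1e-10)
  expect_equal(fit$coords, X, tolerance = 1e-8)
  # noisy copy: superposition RMSD stays below 2 sigma
  for (k in 1:20) {
    Yn <- X + matrix(rnorm(30, sd = 0.5), 10, 3)
    expect_lt(alignToReference(Yn, X, 1:10)$rmsd, 1)
  }
  # collinear selection is degenerate
  Z <- cbind(1:10, 2 * (1:10), 3 * (1:10))
  expect_error(alignToReference(Z, Z, 1:10), "degenerate")
})

test_that("occupancy maps mark planted fixed positions and stay within [0,1]", {
  # a lipid bead at a fixed aligned-frame position every frame
  lip <- data.frame(species = c("DOPS", "DOPC", "DOPC"), head_atom = "P",
                    n_tails = 0)
  fixed <- c(45, 42, 17)
  frames <- lapply(1:30, function(f)
    rbind(fixed, c(runif(1, 0, 80), runif(1, 0, 80), 19), c(20, 20, -19)))
  tr <- manualTrajectory(lip, frames)
  ser <- new("TrajectorySeries", label = "occ", repeats = list(tr))
  g <- occupancyMap(ser, "DOPS", spacing = 1)$all
  expect_equal(max(g$occupancy), 1)
  am <- which(g$occupancy == 1, arr.ind = TRUE)[1, ]
  centre <- g$origin + (am - 0.5) * g$spacing
  expect_true(all(abs(centre - fixed) <= g$spacing))
  # occupancy is a frame fraction: never above 1 whatever the atom count
  g2 <- occupancyMap(ser, "DOPC", spacing = 2)$all
  expect_lte(max(g2$occupancy), 1)
  expect_equal(g$nFrames, 30)
})

test_that("a uniformly re-placed species yields no concentrated voxels", {
  cfg <- smallConfig(seed = 76, nFrames = 150, nLipidsPerLeaflet = 40,
                     placement = "iid")
  ss <- syntheticSeries(cfg, nRepeats = 1, label = "uniform")
  g <- occupancyMap(ss$series, "DOPC", spacing = 4)$all
  occ <- g$occupancy[g$occupancy > 0]
  expect_lt(max(occ), 5 * mean(occ))
})

test_that("occupancy grids are equivariant under a common rotation", {
  sim <- generateSystem(smallConfig(seed = 77, nFrames = 10))
  tr <- sim$trajectory
  ser <- new("TrajectorySeries", label = "a", repeats = list(tr))
  ref <- pepMembrane:::.defaultReference(ser)
  g1 <- occupancyMap(ser, "DOPS", reference = ref, spacing = 2)$all
  R <- pepMembrane:::.rotationAbout(c(0, 0, 1), 1.1)
  tr2 <- tr
  for (f in 1:10) tr2@coords[, , f] <- tr@coords[, , f] %*% t(R)
  ser2 <- new("TrajectorySeries", label = "a", repeats = list(tr2))
  g2 <- occupancyMap(ser2, "DOPS", reference = ref, spacing = 2)$all
  expect_equal(g2$occupancy, g1$occupancy)
})

test_that("OpenDX output round-trips its header and voxel count", {
  sim <- generateSystem(smallConfig(seed = 78, nFrames = 4))
  ser <- new("TrajectorySeries", label = "dx", repeats = list(sim$trajectory))
  g <- occupancyMap(ser, "CHOL", spacing = 3)$all
  f <- tempfile(fileext = ".dx")
  writeOpenDX(g, f)
  lines <- readLines(f)
  expect_true(any(grepl(sprintf("counts %d %d %d", g$dim[1], g$dim[2], g$dim[3]),
                        lines)))
  items <- as.integer(sub(".*items (\\d+) data.*", "\\1",
                          grep("items", lines, value = TRUE)))
  expect_equal(items, prod(g$dim))
})
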