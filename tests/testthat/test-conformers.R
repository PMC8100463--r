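test_that("loop chirality flips under reflection and vanishes on the axis", {
  sim <- generateSystem(smallConfig(seed = 81, nFrames = 6,
                                    loopStateProbs = c(1, 0)))
  tr <- sim$trajectory
  ch <- loopChirality(tr)
  # mirror the loop through the plane spanned by the fitted helix axis and
  # the membrane normal: reflection along the plane normal (z x u)
  a <- tr@topology@atoms
  loopRows <- which(a$molecule_class == "peptide" & a$residue_index <= 6)
  axisRows <- which(a$molecule_class == "peptide" & a$atom_name == "CA" &
                    a$residue_index %in% 7:16)
  tr2 <- tr
  for (f in 1:6) {
    X <- tr@coords[axisRows, , f]
    ctr <- colMeans(X)
    u <- svd(sweep(X, 2, ctr))$v[, 1]
    if (sum(u * (X[10, ] - X[1, ])) < 0) u <- -u
    nrm <- c(-u[2], u[1], 0)  # z x u
    nrm <- nrm / sqrt(sum(nrm^2))
    W <- sweep(tr@coords[loopRows, , f], 2, ctr)
    W <- W - 2 * (W %*% nrm) %*% t(nrm)
    tr2@coords[loopRows, , f] <- sweep(W, 2, ctr, `+`)
  }
  ch2 <- loopChirality(tr2)
  expect_equal(ch2, -ch, tolerance = 1e-6)
  # loop centred exactly on the axis line
  tr3 <- tr
  caLoop <- which(a$molecule_class == "peptide" & a$atom_name == "CA" &
                  a$residue_index <= 5)
  for (f in 1:6) {
    com <- colMeans(tr@coords[caLoop, , f])
    # shift loop CAs so their centroid projects onto the fitted axis
    X <- tr@coords[axisRows, , f]
    ctr <- colMeans(X)
    u <- svd(sweep(X, 2, ctr))$v[, 1]
    target <- ctr + sum((com - ctr) * u) * u
    tr3@coords[caLoop, , f] <- sweep(tr@coords[caLoop, , f], 2, com - target)
  }
  expect_lt(max(abs(loopChirality(tr3))), 1e-6)
})

test_that("chirality sign separates the planted loop orientations", {
  sim <- generateSystem(smallConfig(seed = 82, nFrames = 500,
                                    loopStateProbs = c(0.5, 0.5),
                                    loopSwitchProb = 0.3))
  ch <- loopChirality(sim$trajectory)
  st <- sim$truth$loopStates
  agree <- mean(c(ch[st == 1] > 0, ch[st == 2] < 0))
  expect_gte(agree, 0.99)
})

test_that("loop clustering recovers planted rigid geometries and fractions", {
  # zero noise, no diffuse state: exactly two clusters at the planted sizes
  cfg0 <- smallConfig(seed = 83, nFrames = 300, loopNoise = 0,
                      loopStateProbs = c(0.6, 0.4), loopSwitchProb = 1)
  ss0 <- syntheticSeries(cfg0, nRepeats = 1, label = "rigid")
  lc0 <- clusterLoop(ss0$series)
  expect_equal(length(lc0$sizes), 2)
  st <- ss0$truths[[1]]$loopStates
  expect_equal(sort(lc0$fractions, decreasing = TRUE),
               sort(c(mean(st == 1), mean(st == 2)), decreasing = TRUE))
  expect_setequal(lc0$orientationOf, c("O1", "O2"))
  # medoid is a member of its cluster
  for (k in seq_along(lc0$sizes))
    expect_equal(lc0$assignments[lc0$medoids[k]], k)
  # planted (0.40, 0.35, 0.25 diffuse) fractions recovered within 0.05
  cfg <- smallConfig(seed = 84, nFrames = 600, nLipidsPerLeaflet = 20,
                     loopStateProbs = c(0.40, 0.35), loopSwitchProb = 0.5)
  ss <- syntheticSeries(cfg, nRepeats = 2, label = "mix")
  lc <- clusterLoop(ss$series)
  truth <- unlist(lapply(ss$truths, function(t) t$loopStates))
  o1 <- lc$fractions[lc$orientationOf == "O1"][1]
  o2 <- lc$fractions[lc$orientationOf == "O2"][1]
  expect_lt(abs(o1 - mean(truth == 1)), 0.05)
  expect_lt(abs(o2 - mean(truth == 2)), 0.05)
  # duplicating every frame leaves fractions unchanged
  ser2 <- new("TrajectorySeries", label = "dup",
              repeats = c(ss0$series@repeats, ss0$series@repeats))
  lc2 <- clusterLoop(ser2)
  expect_equal(sort(lc2$fractions), sort(lc0$fractions))
})

test_that("pair fingerprints are capped min-distances matching a plain recount", {
  sim <- generateSystem(smallConfig(seed = 85, nFrames = 10,
                                    placement = "iid"))
  tr <- sim$trajectory
  pf <- pairFeatures(tr, frames = 1:10)
  expect_true(nrow(pf$meta) > 0)
  expect_true(all(pf$features <= 10))
  # plain recount of one emitted pair
  i <- 1
  f <- pf$meta$frame[i]; mol <- pf$meta$molecule[i]
  a <- tr@topology@atoms
  xyz <- tr@coords[, , f]
  box <- tr@box[f, ]
  lipRows <- which(a$molecule_id == mol)
  for (r in c(1, 5, 11, 19)) {
    pepRows <- which(a$molecule_class == "peptide" & a$residue_index == r)
    best <- Inf
    for (lr in lipRows) for (p in pepRows) {
      dx <- oracleWrap(xyz[lr, 1] - xyz[p, 1], box[1])
      dy <- oracleWrap(xyz[lr, 2] - xyz[p, 2], box[2])
      dz <- xyz[lr, 3] - xyz[p, 3]
      best <- min(best, sqrt(dx^2 + dy^2 + dz^2))
    }
    expect_equal(unname(pf$features[i, r]), min(best, 10), tolerance = 1e-10)
  }
  # a lipid hovering over one residue: the fingerprint equals the plain
  # per-residue minimum, and any true distance at or beyond the cap maps
  # to exactly the cap
  lip <- data.frame(species = "DOPS", head_atom = "P", n_tails = 0)
  tr1 <- manualTrajectory(lip, list(matrix(c(0, 0, 19), 1)))
  a1 <- tr1@topology@atoms
  ca11 <- which(a1$molecule_class == "peptide" & a1$residue_index == 11 &
                a1$atom_name == "CA")
  head <- which(a1$molecule_class == "lipid")[1]
  hpos <- tr1@coords[ca11, , 1] + c(0, 0, 3)
  tr1@coords[head, , 1] <- hpos
  pf1 <- pairFeatures(tr1, frames = 1, leafletScope = "all")
  trueMin <- vapply(1:19, function(r) {
    rows <- which(a1$molecule_class == "peptide" & a1$residue_index == r)
    min(sqrt(colSums((t(tr1@coords[rows, , 1]) - hpos)^2)))
  }, numeric(1))
  expect_equal(unname(pf1$features[1, ]), pmin(trueMin, 10), tolerance = 1e-10)
  expect_true(any(trueMin >= 10))
  expect_true(all(pf1$features[1, trueMin >= 10] == 10))
  expect_equal(which.min(pf1$features[1, ]), 11)
})

test_that("binding-mode clustering recovers planted modes and is order-invariant", {
  cfg <- smallConfig(seed = 86, nFrames = 400, nLipidsPerLeaflet = 40,
                     placement = "iid",
                     bindingModes = list(
                       list(species = "DOPC", residues = 8:10, fraction = 0.5),
                       list(species = "DOPS", residues = 12:14, fraction = 0.4),
                       list(species = "DOPC", residues = 16:18, fraction = 0.3)))
  sim <- generateSystem(cfg)
  pf <- pairFeatures(sim$trajectory, frames = seq(1, 400, by = 2))
  cat0 <- clusterBindingModes(pf$features, pf$meta)
  truth <- sim$truth$bindingModes
  tmode <- rep(NA_integer_, nrow(pf$meta))
  for (mi in seq_along(truth)) {
    tt <- truth[[mi]]
    tmode[pf$meta$molecule == tt$molecule & tt$active[pf$meta$frame]] <- mi
  }
  ok <- !is.na(tmode)
  tab <- table(tmode[ok], cat0$assignment[ok], useNA = "ifany")
  acc <- sum(apply(tab, 1, max)) / sum(tab)
  expect_gte(acc, 0.95)
  # each planted mode maps to a distinct cluster
  best <- apply(tab[, !is.na(colnames(tab)), drop = FALSE], 1, which.max)
  expect_equal(length(unique(best)), 3)
  # permuting the pair order relabels ids at most
  perm <- sample(nrow(pf$features))
  catP <- clusterBindingModes(pf$features[perm, , drop = FALSE],
                              pf$meta[perm, , drop = FALSE])
  expect_equal(sort(catP$modes$size), sort(cat0$modes$size))
  # single planted mode: one dominant cluster
  one <- clusterBindingModes(pf$features[ok & tmode == 1, , drop = FALSE])
  expect_equal(nrow(one$modes), 1)
  expect_equal(one$modes$frequency, 1)
})

test_that("empty pair sets give an empty catalog with a warning", {
  expect_warning(cat0 <- clusterBindingModes(matrix(0, 0, 19)), "no engaged")
  expect_equal(nrow(cat0$modes), 0)
})

test_that("per-series contribution rows are stochastic", {
  cfg <- smallConfig(seed = 87, nFrames = 150, placement = "iid",
                     bindingModes = list(
                       list(species = "DOPC", residues = 9:11, fraction = 0.6)))
  sA <- syntheticSeries(cfg, nRepeats = 1, label = "A", seed = 88)
  cfgB <- cfg; cfgB$seed <- 99L
  sB <- syntheticSeries(cfgB, nRepeats = 1, label = "B", seed = 89)
  pf <- collectPairFeatures(list(sA$series, sB$series), stride = 2)
  cat0 <- clusterBindingModes(pf$features, pf$meta)
  expect_true(all(abs(rowSums(cat0$contributions) - 1) < 1e-12))
})
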