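# Conformational clustering: N-terminal loop orientation states and
# peptide-lipid binding modes from distance fingerprints.

#' Signed chirality of the N-terminal loop relative to the helix axis
#'
#' The helix axis u is the least-squares line through Calpha 7-16 oriented
#' N-to-C; z is the membrane normal pointing toward the water phase of the
#' bound leaflet; the loop displacement v is the offset of the Calpha 1-5
#' centroid from its projection onto the axis. The chirality is
#' v . (z x u): positive when the loop points to the left of the helix seen
#' from the N-terminus looking along +u with water up, negative to the
#' right (fixed convention; mirror-image loops negate it exactly).
#'
#' @param traj a [Trajectory-class]
#' @param frames frame indices (default all)
#' @return numeric vector of signed chirality values per frame
#' @export
loopChirality <- function(traj, frames = NULL) {
  if (is.null(frames)) frames <- seq_len(nFrames(traj))
  topo <- traj@topology
  a <- topo@atoms
  caAxis <- which(a$molecule_class == "peptide" & a$atom_name == "CA" &
                  a$residue_index %in% 7:16)
  caLoop <- which(a$molecule_class == "peptide" & a$atom_name == "CA" &
                  a$residue_index %in% 1:5)
  if (length(caAxis) < 3 || !length(caLoop)) stop("Calpha 1-16 required")
  asg <- assignLeaflets(traj, frames[1])
  zhat <- if (identical(asg$boundLeaflet, "lower")) c(0, 0, -1) else c(0, 0, 1)
  out <- numeric(length(frames))
  for (fi in seq_along(frames)) {
    X <- traj@coords[caAxis, , frames[fi], drop = TRUE]
    ctr <- colMeans(X)
    X0 <- sweep(X, 2, ctr)
    sv <- svd(X0)
    if (sv$d[1] < 1e-6) stop("degenerate helix axis")
    u <- sv$v[, 1]
    nc <- X[nrow(X), ] - X[1, ]
    if (sum(u * nc) < 0) u <- -u
    com <- colMeans(traj@coords[caLoop, , frames[fi], drop = FALSE][, , 1])
    w <- com - ctr
    v <- w - sum(w * u) * u
    zu <- c(zhat[2] * u[3] - zhat[3] * u[2],
            zhat[3] * u[1] - zhat[1] * u[3],
            zhat[1] * u[2] - zhat[2] * u[1])
    out[fi] <- sum(v * zu)
  }
  out
}

# pooled, aligned loop Calpha coordinates for clustering
.pooledLoopFeatures <- function(seriesList, loopResidues = 1:7, stride = 1L,
                                reference = NULL) {
  if (is(seriesList, "TrajectorySeries")) seriesList <- list(seriesList)
  if (is.null(reference)) reference <- .defaultReference(seriesList[[1]])
  feats <- list(); meta <- list(); chir <- list()
  for (si in seq_along(seriesList)) {
    ser <- seriesList[[si]]
    topo <- topology(ser)
    a <- topo@atoms
    caLoop <- which(a$molecule_class == "peptide" & a$atom_name == "CA" &
                    a$residue_index %in% loopResidues)
    for (ri in seq_along(ser@repeats)) {
      tr <- ser@repeats[[ri]]
      frames <- seq(1, nFrames(tr), by = stride)
      ch <- loopChirality(tr, frames)
      M <- matrix(0, length(frames), 3 * length(caLoop))
      for (fi in seq_along(frames)) {
        fit <- alignToReference(tr@coords[, , frames[fi]],
                                reference$coords, reference$index)
        M[fi, ] <- as.vector(fit$coords[caLoop, , drop = FALSE])
      }
      feats[[length(feats) + 1L]] <- M
      meta[[length(meta) + 1L]] <- data.frame(
        series = ser@label, repeat_ = ri, frame = frames)
      chir[[length(chir) + 1L]] <- ch
    }
  }
  list(features = do.call(rbind, feats), meta = do.call(rbind, meta),
       chirality = unlist(chir), nAtoms = length(loopResidues))
}

#' Geometric clustering of the N-terminal loop into orientation states
#'
#' Pools frames across all given series, aligns them on Calpha 7-16,
#' performs average-linkage hierarchical clustering on pairwise RMSD of the
#' loop Calpha atoms (residues 1-7) and cuts the tree at
#' \code{rmsdCutoff}. The two largest clusters receive the orientation
#' labels O1/O2 by the sign of their median loop chirality (O1 positive);
#' remaining frames are labelled "other". The medoid of a cluster is the
#' member minimizing summed RMSD to its cluster.
#'
#' @param x a [TrajectorySeries-class] or list of them
#' @param rmsdCutoff tree cut height in Angstrom RMSD (default 2.5)
#' @param loopResidues loop residue indices (default 1:7)
#' @param stride frame stride for pooling
#' @param reference optional common alignment reference
#' @return object of class "LoopClustering": list(assignments (cluster id
#'   per pooled frame), labels (O1/O2/other per pooled frame), meta
#'   (series/repeat/frame table), sizes, fractions, orientationOf
#'   (cluster id -> label), medoids (pooled-frame index per cluster),
#'   chirality)
#' @export
clusterLoop <- function(x, rmsdCutoff = 2.5, loopResidues = 1:7, stride = 1L,
                        reference = NULL) {
  pool <- .pooledLoopFeatures(x, loopResidues, stride, reference)
  M <- pool$features
  n <- nrow(M)
  if (n < 2) stop("need at least 2 frames to cluster")
  dd <- stats::dist(M) / sqrt(pool$nAtoms)
  hc <- stats::hclust(dd, method = "average")
  cl <- stats::cutree(hc, h = rmsdCutoff)
  sizes <- table(cl)
  ord <- order(-as.integer(sizes), as.integer(names(sizes)))
  sizeRank <- stats::setNames(seq_along(ord), names(sizes)[ord])
  # relabel cluster ids by decreasing size (ties: lowest original id first)
  cl2 <- as.integer(sizeRank[as.character(cl)])
  sizes <- table(cl2)
  fractions <- as.numeric(sizes) / n
  # orientation labels for the two largest clusters by median chirality sign
  orientationOf <- rep("other", length(sizes))
  if (length(sizes) >= 1) {
    top <- seq_len(min(2L, length(sizes)))
    med <- vapply(top, function(k) stats::median(pool$chirality[cl2 == k]),
                  numeric(1))
    for (k in top) orientationOf[k] <- if (med[k] >= 0) "O1" else "O2"
    if (length(top) == 2 && orientationOf[1] == orientationOf[2]) {
      # same side: keep the larger as its sign label, demote the other
      orientationOf[2] <- "other"
    }
  }
  labels <- orientationOf[cl2]
  # medoids from the distance matrix
  dm <- as.matrix(dd)
  medoids <- vapply(seq_along(sizes), function(k) {
    mem <- which(cl2 == k)
    mem[which.min(colSums(dm[mem, mem, drop = FALSE]))]
  }, integer(1))
  structure(list(
    assignments = cl2, labels = labels, meta = pool$meta,
    sizes = as.integer(sizes), fractions = fractions,
    orientationOf = orientationOf, medoids = medoids,
    chirality = pool$chirality, rmsdCutoff = rmsdCutoff
  ), class = "LoopClustering")
}

#' @export
print.LoopClustering <- function(x, ...) {
  cat("LoopClustering:", length(x$assignments), "frames,",
      length(x$sizes), "clusters (cutoff", x$rmsdCutoff, "A RMSD)\n")
  top <- seq_len(min(5L, length(x$sizes)))
  for (k in top)
    cat(sprintf("  cluster %d [%s]: %.1f%%\n", k, x$orientationOf[k],
                100 * x$fractions[k]))
  invisible(x)
}

#' Per-frame orientation labels organized per repeat
#'
#' Reshapes pooled [clusterLoop()] labels into one per-frame label vector
#' per repeat of a given series, as consumed by [occupancyMap()].
#'
#' @param clustering a "LoopClustering"
#' @param seriesLabel the series to extract
#' @return list of per-frame label vectors, one per repeat
#' @export
loopLabelsByRepeat <- function(clustering, seriesLabel) {
  m <- clustering$meta
  reps <- sort(unique(m$repeat_[m$series == seriesLabel]))
  lapply(reps, function(r) {
    i <- which(m$series == seriesLabel & m$repeat_ == r)
    stats::setNames(clustering$labels[i], m$frame[i])
  })
}

#' Distance fingerprint of an engaged peptide-lipid pair
#'
#' Per-residue minimum atom-atom distance between the lipid molecule and
#' each selected peptide residue, capped at \code{cap}: the 19-component
#' feature vector on which binding modes are clustered.
#'
#' @param traj a [Trajectory-class]
#' @param frames frame indices (default all, typically strided)
#' @param peptideResidues residues fingerprinted (default 1:19)
#' @param engageCutoff a pair is emitted only if the lipid lies within this
#'   any-atom distance of the selection (default 4.5 Angstrom)
#' @param cap distance cap (default 10 Angstrom)
#' @param leafletScope lipids considered (default "bound")
#' @return list(features = pairs x residues matrix, meta = data.frame
#'   (frame, molecule, species))
#' @export
pairFeatures <- function(traj, frames = NULL, peptideResidues = 1:19,
                         engageCutoff = 4.5, cap = 10,
                         leafletScope = "bound") {
  if (is.null(frames)) frames <- seq_len(nFrames(traj))
  topo <- traj@topology
  a <- topo@atoms
  mols <- .leafletScopeMols(traj, leafletScope)
  spOf <- vapply(mols, function(m) a$species[a$molecule_id == m][1], character(1))
  resList <- peptideResidues
  pepRowsByRes <- lapply(resList, function(r) .peptideAtomRows(topo, r))
  nResSel <- length(resList)
  feats <- list(); meta <- list()
  layouts <- .lipidAtomLayout(topo, mols)
  k <- layouts$beadsPerMol
  for (f in frames) {
    xyz <- traj@coords[, , f, drop = TRUE]
    box <- traj@box[f, ]
    # residue-wise min distances for all molecules at once
    perRes <- matrix(0, length(mols), nResSel)
    for (ri in seq_len(nResSel)) {
      pr <- pepRowsByRes[[ri]]
      dx <- .wrapHalf(outer(xyz[layouts$rows, 1], xyz[pr, 1], "-"), box[1])
      dy <- .wrapHalf(outer(xyz[layouts$rows, 2], xyz[pr, 2], "-"), box[2])
      dz <- outer(xyz[layouts$rows, 3], xyz[pr, 3], "-")
      beadMin <- .rowMins(dx * dx + dy * dy + dz * dz)
      perRes[, ri] <- sqrt(.rowMins(t(matrix(beadMin, k, length(mols)))))
    }
    engaged <- which(apply(perRes, 1, min) <= engageCutoff)
    if (!length(engaged)) next
    fv <- pmin(perRes[engaged, , drop = FALSE], cap)
    feats[[length(feats) + 1L]] <- fv
    meta[[length(meta) + 1L]] <- data.frame(
      frame = f, molecule = mols[engaged], species = spOf[engaged])
  }
  if (!length(feats))
    return(list(features = matrix(0, 0, nResSel), meta = data.frame()))
  list(features = do.call(rbind, feats), meta = do.call(rbind, meta))
}

#' Collect pair fingerprints across a series (or several)
#'
#' @param x a [TrajectorySeries-class] or list of them
#' @param stride frame stride (default 10, taming autocorrelation and pool
#'   size)
#' @param ... passed to [pairFeatures()]
#' @return list(features, meta) with meta carrying series and repeat
#' @export
collectPairFeatures <- function(x, stride = 10L, ...) {
  if (is(x, "TrajectorySeries")) x <- list(x)
  feats <- list(); meta <- list()
  for (ser in x) {
    for (ri in seq_along(ser@repeats)) {
      tr <- ser@repeats[[ri]]
      pf <- pairFeatures(tr, frames = seq(1, nFrames(tr), by = stride), ...)
      if (!nrow(pf$meta)) next
      pf$meta$series <- ser@label
      pf$meta$repeat_ <- ri
      feats[[length(feats) + 1L]] <- pf$features
      meta[[length(meta) + 1L]] <- pf$meta
    }
  }
  if (!length(feats)) return(list(features = NULL, meta = data.frame()))
  list(features = do.call(rbind, feats), meta = do.call(rbind, meta))
}

#' Cluster peptide-lipid pairs into binding modes
#'
#' Average-linkage hierarchical clustering with the Euclidean metric on the
#' capped min-distance fingerprints; the tree is cut at
#' \code{linkageCutoff} and clusters holding at least \code{minSizeFrac} of
#' the pairs are catalogued (largest first, up to \code{maxModes}), the
#' rest forming the remainder. Phospholipids and cholesterol are typically
#' clustered separately by passing pre-filtered features.
#'
#' @param features pairs x residues fingerprint matrix
#' @param meta matching meta table (frame, molecule, species, series)
#' @param linkageCutoff tree cut height (Angstrom, default 8)
#' @param minSizeFrac minimum cluster size as a fraction of pairs
#' @param maxModes number of modes reported (default 5)
#' @return object of class "BindingModeCatalog": list(modes (data.frame id,
#'   size, frequency), assignment (mode id per pair, NA = remainder),
#'   medoids (fingerprint matrix), contributions (mode x series
#'   row-stochastic matrix), remainderFrequency, params)
#' @export
clusterBindingModes <- function(features, meta = NULL, linkageCutoff = 8,
                                minSizeFrac = 0.01, maxModes = 5) {
  if (is.null(features) || nrow(features) == 0) {
    warning("no engaged pairs; empty catalog")
    return(structure(list(modes = data.frame(), assignment = integer(0),
                          medoids = NULL, contributions = NULL,
                          remainderFrequency = NA_real_,
                          params = list(linkageCutoff = linkageCutoff,
                                        minSizeFrac = minSizeFrac)),
                     class = "BindingModeCatalog"))
  }
  n <- nrow(features)
  if (n == 1) {
    cl2 <- 1L
  } else {
    dd <- stats::dist(features)
    hc <- stats::hclust(dd, method = "average")
    cl <- stats::cutree(hc, h = linkageCutoff)
    sizes <- table(cl)
    ord <- order(-as.integer(sizes), as.integer(names(sizes)))
    rank <- stats::setNames(seq_along(ord), names(sizes)[ord])
    cl2 <- as.integer(rank[as.character(cl)])
  }
  sizes <- table(cl2)
  minSize <- max(1, ceiling(minSizeFrac * n))
  keep <- which(as.integer(sizes) >= minSize)
  keep <- keep[seq_len(min(maxModes, length(keep)))]
  assignment <- ifelse(cl2 %in% keep, cl2, NA_integer_)
  medoids <- NULL
  if (length(keep)) {
    medoids <- matrix(0, length(keep), ncol(features))
    for (ki in seq_along(keep)) {
      mem <- which(cl2 == keep[ki])
      if (length(mem) == 1) { medoids[ki, ] <- features[mem, ]; next }
      dm <- as.matrix(stats::dist(features[mem, , drop = FALSE]))
      medoids[ki, ] <- features[mem[which.min(colSums(dm))], ]
    }
    rownames(medoids) <- paste0("BM", seq_along(keep))
  }
  modes <- data.frame(
    id = paste0("BM", seq_along(keep)),
    size = as.integer(sizes[keep]),
    frequency = as.integer(sizes[keep]) / n
  )
  contributions <- NULL
  if (!is.null(meta) && nrow(modes) && "series" %in% names(meta)) {
    sers <- sort(unique(meta$series))
    contributions <- matrix(0, nrow(modes), length(sers),
                            dimnames = list(modes$id, sers))
    for (ki in seq_along(keep)) {
      tb <- table(factor(meta$series[cl2 == keep[ki]], levels = sers))
      contributions[ki, ] <- as.numeric(tb) / sum(tb)
    }
  }
  structure(list(
    modes = modes, assignment = assignment, medoids = medoids,
    contributions = contributions,
    remainderFrequency = 1 - sum(modes$frequency),
    params = list(linkageCutoff = linkageCutoff, minSizeFrac = minSizeFrac)
  ), class = "BindingModeCatalog")
}

#' @export
print.BindingModeCatalog <- function(x, ...) {
  cat("BindingModeCatalog:", nrow(x$modes), "modes,",
      length(x$assignment), "pairs\n")
  if (nrow(x$modes))
    for (i in seq_len(nrow(x$modes)))
      cat(sprintf("  %s: %d pairs (%.1f%%)\n", x$modes$id[i], x$modes$size[i],
                  100 * x$modes$frequency[i]))
  invisible(x)
}
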