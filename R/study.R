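# Study orchestration: generate or ingest all condition series, run every
# analysis stage and emit a report directory of TSV tables, OpenDX grids
# and a manifest.

.writeTSV <- function(df, path, params = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(params)) {
    kv <- paste(names(params), vapply(params, function(x)
      paste(format(x, trim = TRUE), collapse = ","), character(1)),
      sep = "=", collapse = " ")
    writeLines(paste0("# ", kv), con)
  }
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Assemble a study configuration
#'
#' A condition is either synthetic (a [syntheticConfig()] plus a repeat
#' count) or ingested (a topology path plus trajectory paths).
#'
#' @param conditions named list; each element is a list with either
#'   \code{config} (+ optional \code{nRepeats}, default 4) or
#'   \code{topology} and \code{trajectories}
#' @param comparePairs list of label pairs for delta profiles (default all
#'   pairs)
#' @param outDir output directory
#' @param seed base seed
#' @param params analysis parameter overrides (named list; recognised:
#'   segmentWindow, deRadii, loopRmsdCutoff, bmLinkageCutoff, pairStride,
#'   loopStride, occupancySpacing, countChol)
#' @return object of class "StudyConfig"
#' @export
studyConfig <- function(conditions, comparePairs = NULL, outDir = "report",
                        seed = 1L, params = list()) {
  if (is.null(names(conditions)) || any(!nzchar(names(conditions))))
    stop("conditions must be a named list (labels)")
  if (anyDuplicated(names(conditions))) stop("condition labels must be unique")
  defaults <- list(segmentWindow = 0.5, deRadii = c(7, 14, 21),
                   loopRmsdCutoff = 2.5, bmLinkageCutoff = 8,
                   pairStride = 10L, loopStride = 1L,
                   occupancySpacing = 1, countChol = TRUE)
  params <- utils::modifyList(defaults, params)
  structure(list(conditions = conditions, comparePairs = comparePairs,
                 outDir = outDir, seed = as.integer(seed), params = params),
            class = "StudyConfig")
}

.loadConditionSeries <- function(label, cond, seed, index) {
  if (!is.null(cond$config)) {
    nRep <- if (is.null(cond$nRepeats)) 4L else cond$nRepeats
    syntheticSeries(cond$config, nRepeats = nRep, label = label,
                    seed = .subSeed(seed, index))
  } else {
    topo <- readTopology(cond$topology)
    reps <- lapply(cond$trajectories, readTrajectory, topo = topo)
    list(series = new("TrajectorySeries", label = label, repeats = reps),
         truths = NULL)
  }
}

#' Run a complete study
#'
#' For every condition: helicity tables, insertion profiles,
#' membrane-property tables, depletion-enrichment tables; pooled across
#' conditions: loop-orientation clustering, orientation-conditioned 3D
#' occupancy maps and binding-mode catalogs (phospholipids and cholesterol
#' separately); for every requested pair of conditions: delta insertion
#' profiles with significance bands. All parameters, seeds and output
#' checksums are recorded in \code{manifest.yaml}. Reruns with the same
#' configuration and seed are byte-identical.
#'
#' @param config a [studyConfig()]
#' @return the report directory, invisibly
#' @export
runStudy <- function(config) {
  stopifnot(inherits(config, "StudyConfig"))
  out <- config$outDir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  p <- config$params
  labels <- names(config$conditions)
  message("loading/generating ", length(labels), " condition series")
  loaded <- lapply(seq_along(labels), function(i)
    .loadConditionSeries(labels[i], config$conditions[[i]], config$seed, i))
  names(loaded) <- labels
  seriesList <- lapply(loaded, `[[`, "series")
  profiles <- list()
  for (lab in labels) {
    ser <- seriesList[[lab]]
    safe <- gsub("[^A-Za-z0-9._-]", "_", lab)
    message("analysing condition ", lab)
    # helicity
    traces <- lapply(ser@repeats, helicityTrace)
    hf <- helicityFraction(traces)
    .writeTSV(data.frame(residue = seq_along(hf), fraction = hf),
              file.path(out, paste0("helicity_fraction_", safe, ".tsv")),
              list(condition = lab))
    .writeTSV(segmentCountSummary(ser, window = p$segmentWindow),
              file.path(out, paste0("segment_counts_", safe, ".tsv")),
              list(condition = lab, window = p$segmentWindow))
    # insertion
    pr <- residueProfile(ser)
    profiles[[lab]] <- pr
    tab <- data.frame(residue = seq_along(pr$mean), t(pr$perRepeat))
    names(tab)[-1] <- paste0("rep", seq_len(nrow(pr$perRepeat)))
    tab$mean <- pr$mean; tab$sd <- pr$sd
    .writeTSV(tab, file.path(out, paste0("depth_profile_", safe, ".tsv")),
              list(condition = lab, mode = "bound"))
    # membrane properties
    .writeTSV(membraneProperties(ser, countChol = p$countChol),
              file.path(out, paste0("membrane_properties_", safe, ".tsv")),
              list(condition = lab, countChol = p$countChol))
    # depletion-enrichment
    .writeTSV(as.data.frame(deIndex(ser, radii = p$deRadii)),
              file.path(out, paste0("de_index_", safe, ".tsv")),
              list(condition = lab, radii = p$deRadii))
  }
  # delta profiles
  pairs <- config$comparePairs
  if (is.null(pairs) && length(labels) > 1) {
    pairs <- utils::combn(labels, 2, simplify = FALSE)
  }
  for (pr2 in pairs) {
    dp <- deltaProfile(profiles[[pr2[1]]], profiles[[pr2[2]]])
    safe <- gsub("[^A-Za-z0-9._-]", "_",
                 paste0(pr2[1], "_vs_", pr2[2]))
    .writeTSV(as.data.frame(dp), file.path(out, paste0("delta_profile_", safe, ".tsv")),
              list(conditions = paste(pr2, collapse = " vs ")))
  }
  # loop clustering pooled over all conditions
  message("clustering loop orientations")
  lc <- clusterLoop(unname(seriesList), rmsdCutoff = p$loopRmsdCutoff,
                    stride = p$loopStride)
  lcTab <- data.frame(cluster = seq_along(lc$sizes),
                      orientation = lc$orientationOf,
                      size = lc$sizes, fraction = lc$fractions)
  .writeTSV(lcTab, file.path(out, "loop_clusters.tsv"),
            list(rmsdCutoff = p$loopRmsdCutoff))
  # per-series orientation distribution
  distTab <- do.call(rbind, lapply(labels, function(lab) {
    i <- lc$meta$series == lab
    tb <- table(factor(lc$labels[i], levels = c("O1", "O2", "other")))
    data.frame(series = lab, orientation = names(tb),
               fraction = as.numeric(tb) / sum(tb))
  }))
  .writeTSV(distTab, file.path(out, "loop_orientation_by_series.tsv"), NULL)
  # occupancy maps per species and orientation
  message("computing occupancy maps")
  reference <- .defaultReference(seriesList[[1]])
  dxFiles <- character(0)
  for (lab in labels) {
    ll <- loopLabelsByRepeat(lc, lab)
    topoL <- topology(seriesList[[lab]])
    condSpecies <- unique(topoL@atoms$species[topoL@atoms$molecule_class == "lipid"])
    for (s in condSpecies) {
      grids <- occupancyMap(seriesList[[lab]], s, loopLabels = ll,
                            spacing = p$occupancySpacing,
                            reference = reference, stride = p$loopStride)
      for (g in grids) {
        fn <- file.path(out, sprintf("occupancy_%s_%s_%s.dx",
                                     gsub("[^A-Za-z0-9._-]", "_", lab), s,
                                     g$label))
        writeOpenDX(g, fn)
        dxFiles <- c(dxFiles, fn)
      }
    }
  }
  # binding modes: phospholipids pooled vs sterols, across all conditions
  message("clustering binding modes")
  pf <- collectPairFeatures(unname(seriesList), stride = p$pairStride)
  phosSpecies <- unique(topology(seriesList[[1]])@atoms$species[
    topology(seriesList[[1]])@atoms$atom_name %in%
      topology(seriesList[[1]])@phosphateAtoms])
  for (cls in c("phospholipid", "CHOL")) {
    if (is.null(pf$features)) break
    sel <- if (cls == "phospholipid") pf$meta$species %in% phosSpecies
           else pf$meta$species == "CHOL"
    if (!any(sel)) next
    cat0 <- clusterBindingModes(pf$features[sel, , drop = FALSE],
                                pf$meta[sel, , drop = FALSE],
                                linkageCutoff = p$bmLinkageCutoff)
    tab <- cat0$modes
    if (nrow(tab) && !is.null(cat0$contributions)) {
      tab <- cbind(tab, as.data.frame(cat0$contributions))
    }
    .writeTSV(tab, file.path(out, paste0("binding_modes_", cls, ".tsv")),
              list(class = cls, linkageCutoff = p$bmLinkageCutoff,
                   stride = p$pairStride))
    if (!is.null(cat0$medoids)) {
      med <- data.frame(mode = rownames(cat0$medoids), cat0$medoids)
      names(med)[-1] <- paste0("res", seq_len(ncol(cat0$medoids)))
      .writeTSV(med, file.path(out, paste0("binding_mode_medoids_", cls, ".tsv")),
                NULL)
    }
  }
  # manifest
  files <- setdiff(list.files(out, full.names = TRUE), file.path(out, "manifest.yaml"))
  manifest <- list(
    seed = config$seed,
    parameters = config$params,
    conditions = lapply(seq_along(labels), function(i) {
      cond <- config$conditions[[i]]
      c(list(label = labels[i], seed = .subSeed(config$seed, i)),
        if (!is.null(cond$config)) list(
          synthetic = TRUE,
          nRepeats = if (is.null(cond$nRepeats)) 4L else cond$nRepeats,
          nFrames = cond$config$nFrames)
        else list(synthetic = FALSE, topology = cond$topology,
                  trajectories = cond$trajectories,
                  checksums = as.list(tools::md5sum(unique(c(cond$topology,
                                                             cond$trajectories)))))
      )
    }),
    outputs = as.list(stats::setNames(unname(tools::md5sum(sort(files))),
                                      basename(sort(files))))
  )
  yaml::write_yaml(manifest, file.path(out, "manifest.yaml"))
  invisible(out)
}
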