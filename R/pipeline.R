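# End-to-end orchestration: simulate -> preprocess -> distributions/KS ->
# clustering -> metabolomics, with a reproducible JSON run report.

#' Assemble a pipeline run configuration
#'
#' Analysis defaults match the emulated study where one exists: 1000
#' permutations per KS test, alpha = 0.05, volcano thresholds p < 0.05 and
#' |log2FC| > 0.05, mean cutoffs. Every analysis option that affects
#' results is carried here and echoed into the run report.
#'
#' @param outputDir run output directory.
#' @param cohort a \code{\link{cohortConfig}} for the simulated cohort.
#' @param cutoffMethod \code{"mean"} or \code{"median"}.
#' @param cutoffScope \code{"cohort"} (one ruler across all time points,
#'   default) or \code{"timepoint"}.
#' @param ksScheme \code{"exchange"} (unpaired) or \code{"flip"} (paired).
#' @param nPerm permutations per KS test.
#' @param alpha significance level.
#' @param grouping \code{"pooled"} or \code{"per_mouse"} stage aggregation.
#' @param volcanoP,volcanoLfc volcano significance thresholds.
#' @param seed root seed for the run.
#' @return a \code{RunConfig} list.
#' @export
pipelineConfig <- function(outputDir,
                           cohort = cohortConfig(),
                           cutoffMethod = "mean",
                           cutoffScope = c("cohort", "timepoint"),
                           ksScheme = c("exchange", "flip"),
                           nPerm = 1000, alpha = 0.05,
                           grouping = c("per_mouse", "pooled"),
                           volcanoP = 0.05, volcanoLfc = 0.05,
                           seed = 1L) {
  cutoffScope <- match.arg(cutoffScope)
  ksScheme <- match.arg(ksScheme)
  grouping <- match.arg(grouping)
  if (nPerm < 1 || alpha <= 0 || volcanoP <= 0 || volcanoLfc <= 0)
    stop("thresholds must be positive")
  structure(list(outputDir = outputDir, cohort = cohort,
                 cutoffMethod = cutoffMethod, cutoffScope = cutoffScope,
                 ksScheme = ksScheme, nPerm = as.integer(nPerm),
                 alpha = alpha, grouping = grouping, volcanoP = volcanoP,
                 volcanoLfc = volcanoLfc, seed = as.integer(seed)),
            class = "RunConfig")
}

#' A small two-arm demo configuration
#'
#' Resistant-like vs sensitive-like cohort sized to run the full pipeline
#' in well under five minutes on one CPU; the canonical fast fixture.
#'
#' @param outputDir run output directory.
#' @param seed root seed.
#' @return a \code{RunConfig}.
#' @export
demoConfig <- function(outputDir, seed = 1L) {
  pipelineConfig(
    outputDir,
    cohort = cohortConfig(nMice = 3,
                          arms = c("treated_resistant", "treated_sensitive"),
                          imagingDays = c(0L, 11L, 28L),
                          imageShape = c(48L, 48L), seed = seed),
    nPerm = 200, seed = seed)
}

#' Run the full analysis pipeline on a synthetic cohort
#'
#' Executes all stages in order — cohort simulation, frame correction and
#' calibration, trajectory staging, pooled-distribution KS comparisons,
#' 2x2 metabolic clustering with area fractions and stage ANOVA, and the
#' metabolomics normalization/volcano stage — writing every artifact
#' (CSV/TIFF) plus a JSON run report under \code{config$outputDir}.
#' Degenerate cohorts (too few mouse blocks for a permutation test) warn
#' and leave the corresponding report section empty rather than fail.
#'
#' @param config a \code{\link{pipelineConfig}}.
#' @return invisibly, the run report list (also written as
#'   \code{report.json}).
#' @export
runPipeline <- function(config) {
  stopifnot(inherits(config, "RunConfig"))
  out <- config$outputDir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  report <- list(config = config[setdiff(names(config), "cohort")],
                 cohort_config = unclass(config$cohort),
                 version = as.character(utils::packageVersion("omiHet")))

  # -- stage 1: simulate ----------------------------------------------------
  cohortDir <- file.path(out, "cohort")
  manifest <- simulateCohort(config$cohort, cohortDir)
  message("simulate: ", nrow(manifest), " probe bundles")

  # -- stage 2: preprocess --------------------------------------------------
  refDay <- min(config$cohort$imagingDays)
  refStd <- utils::read.csv(file.path(
    cohortDir, "standards", paste0(refDay, "_rhodamine.csv")))$standard_au[1]
  calDir <- file.path(out, "calibrated")
  dir.create(calDir, showWarnings = FALSE)
  calManifest <- NULL
  images <- list()
  for (i in seq_len(nrow(manifest))) {
    row <- manifest[i, ]
    bundle <- readImageBundle(cohortDir, row)
    img <- preprocessBundle(bundle, refStd)
    key <- paste(row$mouse, row$day, row$probe, sep = "|")
    images[[key]] <- img
    path <- file.path("calibrated",
                      paste0(row$mouse, "_", row$day, "_", row$probe, ".tif"))
    .writeFrame(img@values, file.path(out, path))
    calManifest <- rbind(calManifest, data.frame(
      mouse = row$mouse, day = row$day, arm = row$arm, probe = row$probe,
      path = path))
  }
  utils::write.csv(calManifest, file.path(out, "calibrated_manifest.csv"),
                   row.names = FALSE)

  calipers <- utils::read.csv(file.path(cohortDir, "calipers.csv"))
  armOf <- function(mouse)
    manifest$arm[match(mouse, manifest$mouse)]
  trajRows <- NULL
  stageOf <- list()
  for (mouse in unique(calipers$mouse)) {
    cm <- calipers[calipers$mouse == mouse, ]
    vols <- tumorVolume(cm$short_mm, cm$long_mm)
    traj <- new("TumorTrajectory", days = as.integer(cm$day),
                volumes = vols, arm = armOf(mouse), mouse = mouse,
                stages = character())
    traj <- classifyStages(traj)
    stageOf[[mouse]] <- stats::setNames(trajectoryStages(traj),
                                        trajectoryDays(traj))
    trajRows <- rbind(trajRows, data.frame(
      mouse = mouse, day = trajectoryDays(traj),
      volume_mm3 = trajectoryVolumes(traj),
      stage = trajectoryStages(traj)))
  }
  utils::write.csv(trajRows, file.path(out, "trajectories.csv"),
                   row.names = FALSE)
  message("preprocess: ", nrow(calManifest), " calibrated frames, ",
          length(stageOf), " trajectories")

  # -- stage 3: distributions + KS ------------------------------------------
  poolFor <- function(arm, day, probe) {
    sel <- calManifest$arm == arm & calManifest$day == day &
      calManifest$probe == probe
    if (!any(sel)) return(NULL)
    keys <- paste(calManifest$mouse[sel], calManifest$day[sel],
                  calManifest$probe[sel], sep = "|")
    poolPixels(images[keys], label = paste(arm, "D", day))
  }
  arms <- config$cohort$arms
  ksRows <- NULL
  ridgeRows <- NULL
  for (probe in .PROBES) {
    for (day in config$cohort$imagingDays) {
      for (arm in arms) {
        p <- poolFor(arm, day, probe)
        if (is.null(p)) next
        rb <- binForRidge(p, nBins = 40)
        ridgeRows <- rbind(ridgeRows, data.frame(
          probe = probe, arm = arm, day = day,
          bin_mid = (rb$bin_edges[-1] + rb$bin_edges[-length(rb$bin_edges)]) / 2,
          density = rb$densities, mean_line = rb$mean_line))
      }
      if (length(arms) >= 2) {
        a <- poolFor(arms[1], day, probe)
        b <- poolFor(arms[2], day, probe)
        if (is.null(a) || is.null(b)) next
        nBlocks <- length(unique(pixelBlocks(a))) +
          length(unique(pixelBlocks(b)))
        if (nBlocks < 2 ||
            (config$ksScheme == "flip" &&
             !setequal(unique(pixelBlocks(a)), unique(pixelBlocks(b))))) {
          warning("KS skipped for ", probe, " D", day,
                  ": insufficient blocks")
          next
        }
        res <- blockedPermutationTest(
          a, b, nPerm = config$nPerm, scheme = config$ksScheme,
          seed = deriveSeed(config$seed, "ks", probe, day))
        ksRows <- rbind(ksRows, data.frame(
          probe = probe, comparison = paste0(arms[1], "_vs_", arms[2], "_D", day),
          d_obs = res@dObs, p_perm = res@pPerm, n_perm = res@nPerm,
          scheme = res@scheme, exact = res@exact))
      }
    }
  }
  if (!is.null(ksRows))
    utils::write.csv(ksRows, file.path(out, "ks_results.csv"),
                     row.names = FALSE)
  else
    warning("no KS comparisons possible for this cohort ",
            "(fewer than two arms or insufficient mouse blocks)")
  utils::write.csv(ridgeRows, file.path(out, "ridge_bins.csv"),
                   row.names = FALSE)
  message("distributions: ", if (is.null(ksRows)) 0 else nrow(ksRows),
          " KS comparisons")

  # -- stage 4: clustering --------------------------------------------------
  maskDir <- file.path(out, "cluster_masks")
  dir.create(maskDir, showWarnings = FALSE)
  fracRows <- NULL
  anovaRows <- NULL
  for (arm in arms) {
    sel <- calManifest$arm == arm
    scopeDays <- if (config$cutoffScope == "cohort")
      list(unique(calManifest$day[sel])) else
        as.list(unique(calManifest$day[sel]))
    for (days in scopeDays) {
      keyset <- function(probe) {
        s <- sel & calManifest$day %in% days & calManifest$probe == probe
        paste(calManifest$mouse[s], calManifest$day[s],
              calManifest$probe[s], sep = "|")
      }
      cut <- computeCutoffs(
        poolPixels(images[keyset("NBDG60")], label = arm),
        poolPixels(images[keyset("TMRE60")], label = arm),
        method = config$cutoffMethod,
        poolingScope = paste0(arm, ":", config$cutoffScope))
      pairs <- unique(calManifest[sel & calManifest$day %in% days,
                                  c("mouse", "day")])
      for (j in seq_len(nrow(pairs))) {
        mouse <- pairs$mouse[j]; day <- pairs$day[j]
        mask <- assignClusters(
          images[[paste(mouse, day, "TMRE60", sep = "|")]],
          images[[paste(mouse, day, "NBDG60", sep = "|")]], cut)
        codes <- matrix(match(maskLabels(mask), .CLASSES),
                        nrow(maskLabels(mask)))
        suppressWarnings(tiff::writeTIFF(codes / 4,
          file.path(maskDir, paste0(mouse, "_", day, ".tif")),
          bits.per.sample = 8L))
        fr <- areaFractions(mask)
        fr$arm <- arm
        fr$stage <- unname(stageOf[[mouse]][as.character(day)])
        fracRows <- rbind(fracRows, fr)
      }
    }
  }
  utils::write.csv(fracRows, file.path(out, "area_fractions.csv"),
                   row.names = FALSE)
  # stage-aggregated fractions (per mouse), then ANOVA across arms at the
  # shared imaging days for each non-LL cluster
  for (cl in c("percent_HL", "percent_LH", "percent_HH")) {
    ok <- tryCatch({
      perMouse <- stats::aggregate(fracRows[[cl]],
        by = list(mouse = fracRows$mouse, arm = fracRows$arm), FUN = mean)
      res <- compareGroups(perMouse$x, perMouse$arm)
      anovaRows <- rbind(anovaRows, data.frame(
        cluster = cl, F = res$F, p = res$p,
        comparison = res$pairwise$comparison, p_adj = res$pairwise$p_adj))
      TRUE
    }, error = function(e) {
      warning("cluster ANOVA skipped for ", cl, ": ", conditionMessage(e))
      FALSE
    })
  }
  if (!is.null(anovaRows))
    utils::write.csv(anovaRows, file.path(out, "anova_tukey.csv"),
                     row.names = FALSE)
  message("cluster: ", nrow(fracRows), " area-fraction rows")

  # -- stage 5: metabolomics ------------------------------------------------
  metTable <- utils::read.csv(file.path(cohortDir, "metabolites.csv"),
                              check.names = FALSE)
  metCols <- setdiff(colnames(metTable), c("sample", "group", "batch"))
  ab <- as.matrix(metTable[, metCols])
  rownames(ab) <- metTable$sample
  mset <- MetaboliteSet(ab, group = metTable$group, batch = metTable$batch)
  mset <- paretoScale(logTransform(sumNormalize(mset)))
  groups <- unique(metTable$group)
  volc <- volcanoTable(mset, groups[1], groups[2],
                       pThresh = config$volcanoP,
                       lfcThresh = config$volcanoLfc)
  utils::write.csv(volc, file.path(out, "volcano.csv"), row.names = FALSE)
  metAnova <- tryCatch({
    centered <- batchCenter(mset)
    res <- compareMetabolite(centered, rownames(centered)[1])
    data.frame(metabolite = rownames(centered)[1], F = res$F, p = res$p,
               comparison = res$pairwise$comparison,
               p_adj = res$pairwise$p_adj)
  }, error = function(e) NULL)
  if (!is.null(metAnova))
    utils::write.csv(metAnova, file.path(out, "metabolite_anova.csv"),
                     row.names = FALSE)
  message("metabolomics: ", sum(volc$significant), " / ", nrow(volc),
          " metabolites significant")

  # -- report ---------------------------------------------------------------
  report$files <- list(
    manifest = "cohort/manifest.csv",
    calibrated_manifest = "calibrated_manifest.csv",
    trajectories = "trajectories.csv",
    ks_results = if (is.null(ksRows)) NULL else "ks_results.csv",
    ridge_bins = "ridge_bins.csv",
    area_fractions = "area_fractions.csv",
    anova_tukey = if (is.null(anovaRows)) NULL else "anova_tukey.csv",
    volcano = "volcano.csv")
  report$ks <- if (is.null(ksRows)) list() else ksRows
  report$stage_fractions <- stats::aggregate(
    fracRows[, c("percent_HL", "percent_LH", "percent_HH")],
    by = list(arm = fracRows$arm, stage = fracRows$stage), FUN = mean)
  report$volcano_significant <- sum(volc$significant)
  report$n_metabolites <- nrow(volc)
  jsonlite::write_json(report, file.path(out, "report.json"),
                       auto_unbox = TRUE, digits = 10, pretty = TRUE,
                       force = TRUE)
  invisible(report)
}
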