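# Synthetic-cohort generators: tumor trajectories, window-chamber image
# bundles with planted metabolic subpopulations, metabolite tables, and the
# on-disk cohort layout. Every artifact carries recorded ground truth.

#' Specify one planted metabolic subpopulation
#'
#' @param classLabel one of \code{"LL"}, \code{"HL"}, \code{"LH"},
#'   \code{"HH"} (first letter = 2-NBDG level, second = TMRE level).
#' @param areaWeight fraction of tumor area in [0, 1].
#' @param nbdgLevel,tmreLevel mean fluorescence (AU) of the subpopulation;
#'   must sit on the correct side of the planted cutoffs for the class.
#' @param blobScale characteristic blob radius (pixels).
#' @return a \code{SubpopSpec} list.
#' @export
subpopSpec <- function(classLabel, areaWeight, nbdgLevel, tmreLevel,
                       blobScale = 12) {
  if (!classLabel %in% .CLASSES) stop("unknown class label: ", classLabel)
  if (areaWeight < 0 || areaWeight > 1) stop("areaWeight outside [0, 1]")
  if (nbdgLevel < 0 || tmreLevel < 0) stop("levels must be >= 0")
  structure(list(classLabel = classLabel, areaWeight = areaWeight,
                 nbdgLevel = nbdgLevel, tmreLevel = tmreLevel,
                 blobScale = blobScale), class = "SubpopSpec")
}

# Planted cutoffs on the calibrated scale; class levels are placed with a
# wide margin (low 60, high 300 vs cutoff 180) so that the residual
# background gradient and per-mouse effects cannot flip a pixel's
# cutoff-relative class in the noiseless limit.
.PLANTED_CUTOFFS <- c(nbdg = 180, tmre = 180)
.CLASS_LEVELS <- list(
  LL = c(nbdg = 60, tmre = 60),
  HL = c(nbdg = 300, tmre = 60),
  LH = c(nbdg = 60, tmre = 300),
  HH = c(nbdg = 300, tmre = 300))

#' Default subpopulation mixes per treatment arm
#'
#' Treated-resistant tumors are oxidative-shifted (large
#' [2-NBDG_Low/TMRE_High] fraction); treated-sensitive and untreated
#' tumors are glycolytic ([2-NBDG_High/TMRE_Low]-dominated), with LL
#' absorbing background and vasculature.
#'
#' @param arm arm label.
#' @param blobScale blob radius passed to each spec (pixels).
#' @return list of \code{SubpopSpec}s with weights summing to 1.
#' @export
defaultSubpops <- function(arm, blobScale = 12) {
  w <- switch(arm,
    treated_resistant = c(LL = 0.25, HL = 0.15, LH = 0.45, HH = 0.15),
    treated_sensitive = c(LL = 0.25, HL = 0.55, LH = 0.10, HH = 0.10),
    untreated         = c(LL = 0.20, HL = 0.50, LH = 0.15, HH = 0.15),
    stop("unknown arm: ", arm))
  lapply(names(w), function(cl)
    subpopSpec(cl, w[[cl]], .CLASS_LEVELS[[cl]]["nbdg"],
               .CLASS_LEVELS[[cl]]["tmre"], blobScale))
}

#' Cohort configuration for the synthetic generators
#'
#' Defaults encode the emulated study conditions: imaging at key days of
#' the treatment response, modest additive read noise (5% of the
#' inter-class contrast), a low-amplitude smooth pre-injection background,
#' constant dark current, per-session light-source drift corrected by the
#' Rhodamine B standard, and a small lognormal per-mouse block effect.
#'
#' @param nMice mice per arm (>= 1).
#' @param arms subset of \code{"untreated"}, \code{"treated_sensitive"},
#'   \code{"treated_resistant"}.
#' @param imagingDays strictly increasing integer days.
#' @param imageShape c(rows, cols), at least 16 x 16.
#' @param noiseSd additive Gaussian read-noise sd (AU).
#' @param darkMean dark-current mean (AU).
#' @param bgAmp amplitude of the smooth pre-injection gradient (AU).
#' @param driftRange per-session standard multiplier range.
#' @param referenceStandard Rhodamine B reference reading (AU).
#' @param mouseEffectSd sd of the lognormal per-mouse signal factor.
#' @param blobScale subpopulation blob radius (pixels).
#' @param seed root seed; all randomness derives from it.
#' @return a \code{CohortConfig} list.
#' @export
cohortConfig <- function(nMice = 3,
                         arms = c("treated_resistant", "treated_sensitive"),
                         imagingDays = c(0L, 11L, 28L),
                         imageShape = c(64L, 64L),
                         noiseSd = 12, darkMean = 40, bgAmp = 12,
                         driftRange = c(0.8, 1.25),
                         referenceStandard = 100,
                         mouseEffectSd = 0.05,
                         blobScale = 12, seed = 1L) {
  if (nMice < 1) stop("nMice must be >= 1")
  if (!all(arms %in% .ARMS)) stop("unknown arm(s)")
  if (length(imagingDays) > 1 && any(diff(imagingDays) <= 0))
    stop("imaging days must be strictly increasing")
  if (any(imageShape < 16)) stop("image shape must be at least 16 x 16")
  if (noiseSd < 0) stop("noise sd must be >= 0")
  structure(list(nMice = as.integer(nMice), arms = arms,
                 imagingDays = as.integer(imagingDays),
                 imageShape = as.integer(imageShape), noiseSd = noiseSd,
                 darkMean = darkMean, bgAmp = bgAmp,
                 driftRange = driftRange,
                 referenceStandard = referenceStandard,
                 mouseEffectSd = mouseEffectSd, blobScale = blobScale,
                 seed = as.integer(seed)),
            class = "CohortConfig")
}

# Default caliper measurement days (twice-weekly cadence) per arm.
.defaultDays <- function(arm) {
  switch(arm,
    untreated = c(0L, 2L, 4L, 7L, 11L, 14L, 18L, 22L, 25L, 28L, 32L, 35L),
    treated_resistant = c(0L, 2L, 4L, 7L, 11L, 14L, 18L, 22L, 25L, 28L,
                          32L, 35L, 40L, 47L, 55L, 60L, 65L, 70L, 76L,
                          83L, 90L),
    treated_sensitive = c(0L, 2L, 4L, 7L, 11L, 14L, 18L, 22L, 28L, 35L,
                          45L, 60L, 75L, 90L, 105L, 120L),
    stop("unknown arm: ", arm))
}

#' Simulate a caliper tumor-volume trajectory
#'
#' Piecewise-exponential trajectories anchored at the reported response
#' waypoints. Treated-resistant (defaults): decay to 70% of baseline by D4
#' and 40% by D18, slower decline to a residual plateau (22% of baseline)
#' at D40, no growth through D60, then exponential regrowth toward the
#' primary size. Treated-sensitive: same early response, then sustained
#' decay with no regrowth through D120 (no palpable tumor). Untreated:
#' exponential growth. Multiplicative lognormal measurement noise is
#' applied per day with the given seed.
#'
#' @param arm one of \code{"untreated"}, \code{"treated_sensitive"},
#'   \code{"treated_resistant"}.
#' @param v0 baseline volume at D0 (mm^3, > 0); tumors enter treatment at
#'   ~150 mm^3.
#' @param seed integer seed for measurement noise.
#' @param days measurement days (defaults per arm, twice-weekly cadence).
#' @param noiseSd sd of lognormal measurement noise (0 disables).
#' @param growthRate untreated exponential growth rate per day.
#' @param regrowthRate recurrence regrowth rate per day.
#' @param mouse id stored in the result.
#' @return a \linkS4class{TumorTrajectory}.
#' @examples
#' tr <- simulateTrajectory("treated_resistant", v0 = 150, seed = 1,
#'                          noiseSd = 0)
#' trajectoryVolumes(tr)[trajectoryDays(tr) == 4]   # 105
#' trajectoryVolumes(tr)[trajectoryDays(tr) == 18]  # 60
#' @export
simulateTrajectory <- function(arm, v0 = 150, seed = 1L,
                               days = .defaultDays(arm), noiseSd = 0.08,
                               growthRate = 0.066, regrowthRate = NULL,
                               mouse = "m1") {
  if (!arm %in% .ARMS) stop("unknown arm: ", arm)
  if (!is.finite(v0) || v0 <= 0) stop("v0 must be > 0")
  days <- as.integer(days)
  meanVol <- function(t) {
    if (arm == "untreated") return(v0 * exp(growthRate * t))
    # shared early response: 0.7*v0 at D4, 0.4*v0 at D18
    r1 <- log(0.7) / 4
    r2 <- log(0.4 / 0.7) / 14
    early <- function(t) {
      ifelse(t <= 4, v0 * exp(r1 * t), 0.7 * v0 * exp(r2 * (t - 4)))
    }
    if (arm == "treated_sensitive") {
      rs <- -0.05
      return(ifelse(t <= 18, early(t), 0.4 * v0 * exp(rs * (t - 18))))
    }
    # treated_resistant: slow decline to plateau 0.22*v0 at D40, flat to
    # D60, regrowth toward primary size thereafter
    r3 <- log(0.22 / 0.4) / 22
    rg <- if (is.null(regrowthRate)) log(1 / 0.22) / 30 else regrowthRate
    ifelse(t <= 18, early(t),
      ifelse(t <= 40, 0.4 * v0 * exp(r3 * (t - 18)),
        ifelse(t <= 60, 0.22 * v0, 0.22 * v0 * exp(rg * (t - 60)))))
  }
  vols <- vapply(days, meanVol, 0)
  if (noiseSd > 0)
    vols <- withSeed(seed, vols * exp(stats::rnorm(length(vols), 0, noiseSd)))
  new("TumorTrajectory", days = days, volumes = vols, arm = arm,
      mouse = mouse, stages = character())
}

# Contiguous subpopulation layout: quantile level sets of a smoothed
# Gaussian random field. Thresholding the field at the cumulative area
# weights yields organic, spatially coherent blobs with exact pixel quotas
# (realized fractions match requested weights to within one pixel).
.subpopLayout <- function(subpops, shape, seed) {
  w <- vapply(subpops, function(s) s$areaWeight, 0)
  if (abs(sum(w) - 1) > 1e-9) stop("area weights must sum to 1")
  npix <- prod(shape)
  u <- withSeed(seed, .gaussBlur(matrix(stats::rnorm(npix), shape[1], shape[2]),
                                 subpops[[1]]$blobScale))
  rk <- rank(u, ties.method = "first")
  bounds <- round(cumsum(w) * npix)
  bounds[length(bounds)] <- npix
  idx <- findInterval(rk - 1, c(0, bounds[-length(bounds)]))
  matrix(vapply(subpops, function(s) s$classLabel, "")[idx],
         shape[1], shape[2])
}

#' Simulate one mouse-day session: raw frames for all probes plus truth
#'
#' Renders the planted subpopulations as contiguous blobs, then composes
#' per-probe raw frames as
#' \code{drift x (signal x mouseFactor + background) + dark + noise},
#' with matching dark-noise and pre-injection frames and a session
#' Rhodamine B standard reading scaled by the session drift. The truth
#' mask records each pixel's planted class; planted per-class fractions
#' match the requested weights to within one pixel.
#'
#' @param subpops list of \code{\link{subpopSpec}}s (weights sum to 1).
#' @param config a \code{\link{cohortConfig}}.
#' @param mouse,day identifiers.
#' @param seed artifact seed (defaults derive from the config seed).
#' @return list: \code{bundles} (named \linkS4class{RawImageBundle}s for
#'   TMRE60, NBDG60, BODIPY60), \code{truthMask}
#'   (\linkS4class{ClusterMask}), and \code{truth} (planted fractions,
#'   cutoffs, mouse factor, session drift).
#' @export
simulateImageBundle <- function(subpops, config, mouse = "m1", day = 0L,
                                seed = deriveSeed(config$seed, "img", mouse, day)) {
  shape <- config$imageShape
  if (any(shape < 16)) stop("degenerate image shape")
  layout <- .subpopLayout(subpops, shape, deriveSeed(seed, "layout"))
  levels <- list(
    nbdg = vapply(subpops, function(s) s$nbdgLevel, 0),
    tmre = vapply(subpops, function(s) s$tmreLevel, 0))
  names(levels$nbdg) <- names(levels$tmre) <-
    vapply(subpops, function(s) s$classLabel, "")
  # verify the class labels sit on the correct side of the planted cutoffs
  for (s in subpops) {
    nH <- substr(s$classLabel, 1, 1) == "H"
    tH <- substr(s$classLabel, 2, 2) == "H"
    if (nH != (s$nbdgLevel > .PLANTED_CUTOFFS["nbdg"]) ||
        tH != (s$tmreLevel > .PLANTED_CUTOFFS["tmre"]))
      stop("class label ", s$classLabel,
           " inconsistent with levels relative to the planted cutoffs")
  }
  # per-mouse block effect: constant for a mouse across days
  mouseFactor <- if (config$mouseEffectSd > 0)
    withSeed(deriveSeed(config$seed, "mouse", mouse),
             exp(stats::rnorm(1, 0, config$mouseEffectSd))) else 1
  # per-session light-source drift, one per imaging day
  drift <- withSeed(deriveSeed(config$seed, "drift", day),
                    stats::runif(1, config$driftRange[1], config$driftRange[2]))
  # smooth low-amplitude background gradient, one per session
  bg <- withSeed(deriveSeed(seed, "bg"), {
    co <- stats::runif(2, -1, 1)
    rows <- (seq_len(shape[1]) - 1) / max(shape[1] - 1, 1)
    cols <- (seq_len(shape[2]) - 1) / max(shape[2] - 1, 1)
    config$bgAmp * (co[1] * outer(rows, rep(1, shape[2])) +
                    co[2] * outer(rep(1, shape[1]), cols))
  })
  noise <- function(tag) {
    if (config$noiseSd == 0) return(0)
    withSeed(deriveSeed(seed, "noise", tag),
             matrix(stats::rnorm(prod(shape), 0, config$noiseSd),
                    shape[1], shape[2]))
  }
  mkBundle <- function(probe, signal) {
    raw <- drift * (signal * mouseFactor + bg) + config$darkMean +
      noise(paste0(probe, ":raw"))
    dark <- config$darkMean + matrix(0, shape[1], shape[2]) +
      noise(paste0(probe, ":dark"))
    pre <- drift * bg + config$darkMean + noise(paste0(probe, ":pre"))
    new("RawImageBundle", raw = raw, dark = dark, preinjection = pre,
        standardReading = drift * config$referenceStandard, probe = probe,
        mouse = mouse, day = as.integer(day),
        arm = attr(subpops, "arm") %||% "untreated")
  }
  sigN <- matrix(levels$nbdg[layout], shape[1], shape[2])
  sigT <- matrix(levels$tmre[layout], shape[1], shape[2])
  sigB <- matrix(150, shape[1], shape[2])  # fatty-acid uptake, class-flat
  bundles <- list(
    TMRE60 = mkBundle("TMRE60", sigT),
    NBDG60 = mkBundle("NBDG60", sigN),
    BODIPY60 = mkBundle("BODIPY60", sigB))
  truthCut <- new("CutoffPair",
                  cutoffNBDG = unname(.PLANTED_CUTOFFS["nbdg"]),
                  cutoffTMRE = unname(.PLANTED_CUTOFFS["tmre"]),
                  method = "mean", poolingScope = "planted")
  truthMask <- new("ClusterMask", labels = layout, mouse = mouse,
                   day = as.integer(day), cutoffs = truthCut)
  fr <- table(factor(layout, levels = .CLASSES)) / prod(shape)
  list(bundles = bundles, truthMask = truthMask,
       truth = list(fractions = as.list(as.numeric(fr) * 100) |>
                      stats::setNames(.CLASSES),
                    cutoffs = as.list(.PLANTED_CUTOFFS),
                    mouseFactor = mouseFactor, drift = drift))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Simulate a samples x metabolites abundance table with planted effects
#'
#' Abundances are lognormal around group means that differ by the planted
#' per-metabolite log2 fold changes (second group vs first); batch offsets
#' apply multiplicatively on top. With zero noise the sample log2 ratio of
#' group means equals the planted effect exactly.
#'
#' @param nPerGroup samples per group (>= 2; the emulated study uses 5
#'   tumors per group).
#' @param metabolites character vector of metabolite names.
#' @param plantedLog2fc named (or recycled) per-metabolite log2 fold
#'   change of group 2 vs group 1.
#' @param groups two group labels.
#' @param batchOffsets named per-batch additive offsets on the log scale.
#' @param batches batch label per sample (recycled; default alternates
#'   within group so batch and group are not confounded).
#' @param baseAbundance per-metabolite baseline abundance (recycled).
#' @param noiseSd lognormal noise sd on the natural-log scale.
#' @param seed integer seed.
#' @return list: \code{set} (a \linkS4class{MetaboliteSet}) and
#'   \code{truth} (planted effects, offsets, noise level).
#' @export
simulateMetabolomics <- function(nPerGroup = 5,
                                 metabolites = paste0("met", 1:20),
                                 plantedLog2fc = 0,
                                 groups = c("primary", "regressing"),
                                 batchOffsets = c(b1 = 0, b2 = 0),
                                 batches = NULL,
                                 baseAbundance = 1,
                                 noiseSd = 0.25, seed = 1L) {
  if (nPerGroup < 2) stop("nPerGroup must be >= 2")
  if (noiseSd < 0) stop("noiseSd must be >= 0")
  if (any(!is.finite(plantedLog2fc))) stop("non-finite planted effects")
  nm <- length(metabolites)
  fc <- rep_len(plantedLog2fc, nm)
  base <- rep_len(baseAbundance, nm)
  names(fc) <- names(base) <- metabolites
  n <- 2 * nPerGroup
  group <- rep(groups, each = nPerGroup)
  if (is.null(batches))
    batches <- rep_len(names(batchOffsets), n)
  batch <- rep_len(batches, n)
  mu <- outer(rep(1, n), log(base)) +
    outer(as.numeric(group == groups[2]), fc * log(2)) +
    outer(batchOffsets[batch], rep(1, nm))
  eps <- if (noiseSd > 0)
    withSeed(seed, matrix(stats::rnorm(n * nm, 0, noiseSd), n, nm)) else 0
  ab <- exp(mu + eps)
  dimnames(ab) <- list(paste0("s", seq_len(n)), metabolites)
  set <- MetaboliteSet(ab, group = group, batch = batch)
  list(set = set,
       truth = list(log2fc = fc, batchOffsets = batchOffsets,
                    noiseSd = noiseSd, groups = groups))
}

.writeFrame <- function(m, path) {
  v <- m / .AU_SCALE
  v[v < 0] <- 0
  v[v > 1] <- 1
  suppressWarnings(tiff::writeTIFF(v, path, bits.per.sample = 32L))
  invisible(path)
}

.readFrame <- function(path) tiff::readTIFF(path) * .AU_SCALE

#' Write a full synthetic cohort to disk
#'
#' Generates, for every mouse and imaging day, the three-probe raw frame
#' bundles (raw / dark / pre-injection TIFFs), per-day Rhodamine B
#' standard readings, a session manifest, caliper measurements derived
#' from the simulated trajectories, a metabolite table, and JSON truth
#' sidecars recording everything that was planted.
#'
#' @param config a \code{\link{cohortConfig}}.
#' @param dir destination directory (created if needed).
#' @param subpopsByArm optional named list of \code{SubpopSpec} lists; the
#'   defaults of \code{\link{defaultSubpops}} otherwise.
#' @return invisibly, the manifest data.frame.
#' @export
simulateCohort <- function(config, dir,
                           subpopsByArm = NULL) {
  stopifnot(inherits(config, "CohortConfig"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (d in c("images", "standards", "truth"))
    dir.create(file.path(dir, d), showWarnings = FALSE)
  manifest <- NULL
  calipers <- NULL
  truthAll <- list()
  for (arm in config$arms) {
    subpops <- subpopsByArm[[arm]] %||% defaultSubpops(arm, config$blobScale)
    attr(subpops, "arm") <- arm
    for (i in seq_len(config$nMice)) {
      mouse <- sprintf("%s_m%d", sub("treated_", "", arm), i)
      traj <- simulateTrajectory(arm, v0 = 150,
                                 seed = deriveSeed(config$seed, "traj", mouse),
                                 mouse = mouse)
      # invert volume = s^2 (l/2) with aspect ratio l = 1.5 s
      s <- (trajectoryVolumes(traj) / 0.75)^(1 / 3)
      calipers <- rbind(calipers, data.frame(
        mouse = mouse, day = trajectoryDays(traj),
        short_mm = round(s, 3), long_mm = round(1.5 * s, 3)))
      for (day in config$imagingDays) {
        sim <- simulateImageBundle(subpops, config, mouse, day)
        ddir <- file.path(dir, "images", mouse, day)
        dir.create(ddir, recursive = TRUE, showWarnings = FALSE)
        for (probe in .PROBES) {
          b <- sim$bundles[[probe]]
          paths <- file.path(ddir, paste0(probe, "_", c("raw", "dark", "preinj"), ".tif"))
          .writeFrame(b@raw, paths[1])
          .writeFrame(b@dark, paths[2])
          .writeFrame(b@preinjection, paths[3])
          manifest <- rbind(manifest, data.frame(
            mouse = mouse, day = day, arm = arm, probe = probe,
            raw_path = file.path("images", mouse, day, basename(paths[1])),
            dark_path = file.path("images", mouse, day, basename(paths[2])),
            preinj_path = file.path("images", mouse, day, basename(paths[3])),
            standard_path = file.path("standards",
                                      paste0(day, "_rhodamine.csv"))))
        }
        truthAll[[paste(mouse, day, sep = "_")]] <- sim$truth
        jsonlite::write_json(
          sim$truth,
          file.path(dir, "truth", paste0(mouse, "_", day, ".json")),
          auto_unbox = TRUE, digits = 10)
      }
    }
  }
  for (day in config$imagingDays) {
    drift <- withSeed(deriveSeed(config$seed, "drift", day),
                      stats::runif(1, config$driftRange[1], config$driftRange[2]))
    utils::write.csv(
      data.frame(day = day,
                 standard_au = drift * config$referenceStandard),
      file.path(dir, "standards", paste0(day, "_rhodamine.csv")),
      row.names = FALSE)
  }
  metaboliteNames <- c("pyruvate", "lactate", "citrate", "succinate",
                       "fumarate", "malate", "glutamate", "glutamine",
                       "alanine", "serine", "glycine", "aspartate",
                       paste0("met", 13:20))
  fc <- stats::setNames(rep(0, length(metaboliteNames)), metaboliteNames)
  fc[c("pyruvate", "citrate")] <- 1
  fc[c("lactate")] <- -1
  met <- simulateMetabolomics(
    nPerGroup = 5, metabolites = metaboliteNames, plantedLog2fc = fc,
    groups = c("primary", "regressing"),
    batchOffsets = c(b1 = 0, b2 = 0.3),
    noiseSd = 0.25, seed = deriveSeed(config$seed, "metabolomics"))
  ab <- t(assay(met$set, "abundance"))
  metTable <- data.frame(sample = rownames(ab),
                         group = colData(met$set)$sample_group,
                         batch = colData(met$set)$batch, ab,
                         check.names = FALSE)
  utils::write.csv(metTable, file.path(dir, "metabolites.csv"),
                   row.names = FALSE)
  jsonlite::write_json(met$truth, file.path(dir, "truth", "metabolites.json"),
                       auto_unbox = TRUE, digits = 10)
  utils::write.csv(manifest, file.path(dir, "manifest.csv"),
                   row.names = FALSE)
  utils::write.csv(calipers, file.path(dir, "calipers.csv"),
                   row.names = FALSE)
  invisible(manifest)
}

#' Read one probe bundle referenced by a cohort manifest row
#'
#' @param cohortDir cohort directory written by \code{\link{simulateCohort}}.
#' @param row one row of the manifest data.frame.
#' @return a \linkS4class{RawImageBundle}.
#' @export
readImageBundle <- function(cohortDir, row) {
  std <- utils::read.csv(file.path(cohortDir, row$standard_path))
  new("RawImageBundle",
      raw = .readFrame(file.path(cohortDir, row$raw_path)),
      dark = .readFrame(file.path(cohortDir, row$dark_path)),
      preinjection = .readFrame(file.path(cohortDir, row$preinj_path)),
      standardReading = std$standard_au[1], probe = row$probe,
      mouse = row$mouse, day = as.integer(row$day), arm = row$arm)
}
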