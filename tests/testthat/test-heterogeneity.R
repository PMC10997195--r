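# 2x2 metabolic clustering, area fractions, stage aggregation, ANOVA/Tukey.

test_that("cutoffs are the mean or median of the pooled pixel values", {
  nb <- pixelDist(c(1, 2, 3, 4), rep("m1", 4), probe = "NBDG60")
  tm <- pixelDist(c(1, 2, 3, 4), rep("m1", 4), probe = "TMRE60")
  cm <- computeCutoffs(nb, tm, method = "mean")
  expect_equal(cm@cutoffNBDG, 2.5)
  cd <- computeCutoffs(nb, tm, method = "median")
  expect_equal(cd@cutoffTMRE, 2.5)
  s <- pixelDist(5, "m1")
  expect_equal(computeCutoffs(s, s, "mean")@cutoffNBDG, 5)
  expect_equal(computeCutoffs(s, s, "median")@cutoffNBDG, 5)
})

test_that("pixels classify by strict cutoff exceedance with ties going Low", {
  cut <- new("CutoffPair", cutoffNBDG = 3, cutoffTMRE = 3,
             method = "mean", poolingScope = "test")
  nbdg <- calImage(matrix(c(5, 3, 4, 1), 2, 2), probe = "NBDG60")
  tmre <- calImage(matrix(c(1, 3, 4, 5), 2, 2), probe = "TMRE60")
  mask <- assignClusters(tmre, nbdg, cut)
  expect_equal(as.vector(maskLabels(mask)), c("HL", "LL", "HH", "LH"))
  # shape / provenance mismatches are rejected
  expect_error(assignClusters(calImage(matrix(1, 3, 3)), nbdg, cut), "shape")
  other <- calImage(matrix(1, 2, 2), probe = "NBDG60", mouse = "mX")
  expect_error(assignClusters(tmre, other, cut), "same mouse")
})

test_that("every pixel gets exactly one of the four labels", {
  set.seed(40)
  cut <- new("CutoffPair", cutoffNBDG = 0.5, cutoffTMRE = 0.5,
             method = "mean", poolingScope = "test")
  for (i in 1:20) {
    nb <- calImage(matrix(runif(64), 8, 8), probe = "NBDG60")
    tm <- calImage(matrix(runif(64), 8, 8), probe = "TMRE60")
    lab <- maskLabels(assignClusters(tm, nb, cut))
    counts <- table(factor(lab, levels = c("LL", "HL", "LH", "HH")))
    expect_equal(sum(counts), 64)
  }
})

test_that("raising the TMRE cutoff never flips a pixel toward TMRE-High", {
  set.seed(41)
  nb <- calImage(matrix(runif(100), 10, 10), probe = "NBDG60")
  tm <- calImage(matrix(runif(100), 10, 10), probe = "TMRE60")
  tHighAt <- function(ct) {
    cut <- new("CutoffPair", cutoffNBDG = 0.5, cutoffTMRE = ct,
               method = "mean", poolingScope = "test")
    maskLabels(assignClusters(tm, nb, cut)) %in% c("LH", "HH")
  }
  lo <- tHighAt(0.3)
  for (ct in c(0.4, 0.6, 0.9)) {
    hi <- tHighAt(ct)
    expect_true(all(lo | !hi))  # High set only shrinks
    lo <- hi
  }
})

test_that("area fractions exclude LL and sum to 100", {
  lab <- matrix(c(rep("LL", 60), rep("HL", 10), rep("LH", 10),
                  rep("HH", 20)), 10, 10)
  cut <- new("CutoffPair", cutoffNBDG = 1, cutoffTMRE = 1,
             method = "mean", poolingScope = "test")
  mask <- new("ClusterMask", labels = lab, mouse = "m1", day = 0L,
              cutoffs = cut)
  fr <- areaFractions(mask)
  expect_equal(c(fr$percent_HL, fr$percent_LH, fr$percent_HH),
               c(25, 25, 50))
  expect_equal(fr$n_nonLL, 40L)
  expect_equal(fr$percent_HL + fr$percent_LH + fr$percent_HH, 100,
               tolerance = 1e-6)
  lab2 <- matrix(c(rep("LH", 5), rep("LL", 4)), 3, 3)
  fr2 <- areaFractions(new("ClusterMask", labels = lab2, mouse = "m1",
                           day = 0L, cutoffs = cut))
  expect_equal(c(fr2$percent_HL, fr2$percent_LH, fr2$percent_HH),
               c(0, 100, 0))
  allLL <- new("ClusterMask", labels = matrix("LL", 3, 3), mouse = "m1",
               day = 0L, cutoffs = cut)
  expect_error(areaFractions(allLL), "no viable signal")
})

test_that("stage aggregation averages time points within a stage", {
  tabs <- data.frame(mouse = c("m1", "m1", "m1"), day = c(0, 4, 8),
                     percent_HL = c(50, 20, 40), percent_LH = c(30, 60, 40),
                     percent_HH = c(20, 20, 20), n_nonLL = 100L)
  sm <- c("0" = "primary", "4" = "regression", "8" = "regression")
  agg <- aggregateStageFractions(tabs, sm)
  expect_equal(agg$percent_HL[agg$stage == "regression"], 30)
  expect_equal(agg$percent_HL[agg$stage == "primary"], 50)
  # one time point per stage is the identity
  agg1 <- aggregateStageFractions(tabs[1, ], c("0" = "primary"))
  expect_equal(agg1$percent_LH, 30)
  # per-mouse grouping keeps one row per mouse and stage
  tabs2 <- rbind(tabs, transform(tabs, mouse = "m2"))
  agg2 <- aggregateStageFractions(tabs2, sm, grouping = "per_mouse")
  expect_equal(nrow(agg2), 4)
  expect_error(aggregateStageFractions(tabs, c("0" = "primary")),
               "unmapped")
})

test_that("one-way ANOVA with Tukey matches hand-computed sums of squares", {
  res <- compareGroups(c(1, 2, 3, 2, 3, 4, 3, 4, 5),
                       rep(c("a", "b", "c"), each = 3))
  expect_equal(res$F, 3)  # between MS 3, within MS 1
  expect_equal(unname(res$group_means), c(2, 3, 4))
  expect_equal(nrow(res$pairwise), 3)
  # smaller group gap => larger adjusted p
  pmap <- setNames(res$pairwise$p_adj, res$pairwise$comparison)
  expect_gt(pmap[["b-a"]], pmap[["c-a"]])
  # cross-check against stats::aov directly
  d <- data.frame(y = c(1, 2, 3, 2, 3, 4, 3, 4, 5),
                  g = factor(rep(c("a", "b", "c"), each = 3)))
  expect_equal(res$p, summary(aov(y ~ g, d))[[1]]["g", "Pr(>F)"])
})

test_that("degenerate ANOVA inputs follow the stated conventions", {
  res <- compareGroups(rep(c(1, 2, 3), 3), rep(c("a", "b", "c"), each = 3))
  expect_equal(res$F, 0)
  zero <- compareGroups(rep(5, 6), rep(c("a", "b"), each = 3))
  expect_equal(zero$F, 0)
  expect_equal(zero$p, 1)
  expect_true(all(zero$pairwise$p_adj == 1))
  expect_error(compareGroups(c(1, 2, 3), c("a", "a", "b")), "at least 2")
})

test_that("mean and median cutoffs preserve per-cluster group orderings", {
  # symmetric cohorts: subpopulation weights (LL=h, HL=.5-h, LH=.5-h,
  # HH=h) keep both per-probe pixel pools 50/50 high/low, hence symmetric,
  # so mean and median cutoffs sit in the same inter-mode gap
  cfg <- cohortConfig(imageShape = c(96L, 96L), noiseSd = 12,
                      driftRange = c(1, 1), mouseEffectSd = 0, seed = 13L)
  mixFor <- function(h) list(
    subpopSpec("LL", h, 60, 60), subpopSpec("HL", 0.5 - h, 300, 60),
    subpopSpec("LH", 0.5 - h, 60, 300), subpopSpec("HH", h, 300, 300))
  hs <- c(g1 = 0.35, g2 = 0.22, g3 = 0.10)
  imgs <- lapply(names(hs), function(g) {
    sim <- simulateImageBundle(mixFor(hs[[g]]), cfg, g, 0)
    list(T = preprocessBundle(sim$bundles$TMRE60, cfg$referenceStandard),
         N = preprocessBundle(sim$bundles$NBDG60, cfg$referenceStandard))
  })
  fracsFor <- function(method) {
    cut <- computeCutoffs(poolPixels(lapply(imgs, `[[`, "N")),
                          poolPixels(lapply(imgs, `[[`, "T")),
                          method = method)
    vapply(imgs, function(im) {
      fr <- areaFractions(assignClusters(im$T, im$N, cut))
      c(HL = fr$percent_HL, LH = fr$percent_LH, HH = fr$percent_HH)
    }, c(HL = 0, LH = 0, HH = 0))
  }
  fm <- fracsFor("mean"); fmed <- fracsFor("median")
  for (cl in c("HL", "LH", "HH"))
    expect_identical(rank(fm[cl, ]), rank(fmed[cl, ]))
})

test_that("planted area fractions are recovered within 2 pp under noise", {
  # noise sd at 10% of the 240 AU inter-class contrast
  cfg <- cohortConfig(imageShape = c(128L, 128L), noiseSd = 24,
                      driftRange = c(0.9, 1.1), mouseEffectSd = 0.05,
                      seed = 17L)
  sp <- list(subpopSpec("LL", 0.4, 60, 60), subpopSpec("HL", 0.3, 300, 60),
             subpopSpec("LH", 0.2, 60, 300), subpopSpec("HH", 0.1, 300, 300))
  for (mouse in c("m1", "m2")) {
    sim <- simulateImageBundle(sp, cfg, mouse, 0)
    imgT <- preprocessBundle(sim$bundles$TMRE60, cfg$referenceStandard)
    imgN <- preprocessBundle(sim$bundles$NBDG60, cfg$referenceStandard)
    est <- areaFractions(assignClusters(imgT, imgN, sim$truthMask@cutoffs))
    truth <- areaFractions(sim$truthMask)
    for (cl in c("percent_HL", "percent_LH", "percent_HH"))
      expect_lt(abs(est[[cl]] - truth[[cl]]), 2)
  }
})
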