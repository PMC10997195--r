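# Shared fixtures and independent oracles used across the suite.

# Brute-force KS oracle: scan every pooled sample point and take the
# largest ECDF gap. Kept deliberately naive and independent of
# ksStatistic()'s implementation.
bruteKS <- function(a, b) {
  d <- 0
  for (x in c(a, b)) {
    d <- max(d, abs(mean(a <= x) - mean(b <= x)))
  }
  d
}

# Minimal constant-frame bundle for the correction arithmetic.
constantBundle <- function(raw, dark, preinj, shape = c(4, 4),
                           standard = 100, probe = "TMRE60",
                           mouse = "m1", day = 0L, arm = "untreated") {
  new("RawImageBundle",
      raw = matrix(raw, shape[1], shape[2]),
      dark = matrix(dark, shape[1], shape[2]),
      preinjection = matrix(preinj, shape[1], shape[2]),
      standardReading = standard, probe = probe, mouse = mouse,
      day = day, arm = arm)
}

calImage <- function(values, probe = "TMRE60", mouse = "m1", day = 0L) {
  new("CalibratedImage", values = values, probe = probe, mouse = mouse,
      day = as.integer(day), arm = "untreated", stage = NA_character_)
}

pixelDist <- function(values, blocks, probe = "TMRE60", label = "") {
  new("PixelDistribution", values = values, blocks = blocks,
      probe = probe, label = label)
}

# Blocked two-group draw under the null: every block's pixels come from one
# common distribution with a per-block random effect.
nullBlockDraw <- function(nBlocksPerGroup = 5, pixelsPerBlock = 500,
                          blockSd = 0.3) {
  mk <- function(prefix) {
    vals <- c(); blocks <- c()
    for (i in seq_len(nBlocksPerGroup)) {
      mu <- rnorm(1, 0, blockSd)
      vals <- c(vals, abs(rnorm(pixelsPerBlock, 5 + mu, 1)))
      blocks <- c(blocks, rep(paste0(prefix, i), pixelsPerBlock))
    }
    pixelDist(vals, blocks)
  }
  list(a = mk("a"), b = mk("b"))
}

# Independent volcano recomputation: pooled-variance t and log2 fold change
# straight from the raw abundance table, bypassing the MetaboliteSet path.
independentVolcano <- function(ab, group, ga, gb, pThresh = 0.05,
                               lfcThresh = 0.05) {
  norm <- sweep(ab, 1, rowSums(ab), "/")
  ia <- group == ga; ib <- group == gb
  t(apply(norm, 2, function(col) {
    # Pareto scaling is an affine per-metabolite map, so the t statistic
    # on scaled values equals the t statistic on the log values.
    la <- log(col[ia]); lb <- log(col[ib])
    na <- length(la); nb <- length(lb)
    sp2 <- ((na - 1) * var(la) + (nb - 1) * var(lb)) / (na + nb - 2)
    tt <- (mean(la) - mean(lb)) / sqrt(sp2 * (1 / na + 1 / nb))
    p <- 2 * pt(-abs(tt), na + nb - 2)
    lfc <- mean(log2(col[ib])) - mean(log2(col[ia]))
    c(p = p, log2fc = lfc, significant = p < pThresh & abs(lfc) > lfcThresh)
  }))
}
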