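# Sum normalization, log transform, Pareto scaling, volcano, batch
# centering, single-metabolite ANOVA.

mset <- function(ab, group = rep(c("primary", "regressing"),
                                 each = nrow(ab) / 2),
                 batch = NULL) {
  MetaboliteSet(ab, group = group, batch = batch)
}

test_that("sum normalization makes rows sum to one and is idempotent", {
  m <- mset(rbind(c(1, 3), c(2, 2), c(5, 5), c(1, 7)))
  n1 <- sumNormalize(m)
  a <- t(SummarizedExperiment::assay(n1, "sumnorm"))
  expect_equal(unname(a[1, ]), c(0.25, 0.75))
  expect_equal(unname(rowSums(a)), rep(1, 4), tolerance = 1e-12)
  n2 <- sumNormalize(n1)
  expect_equal(SummarizedExperiment::assay(n2, "sumnorm"),
               SummarizedExperiment::assay(n1, "sumnorm"))
  expect_equal(processingStages(n1), c("raw", "sum"))
})

test_that("log transform requires sum normalization and shifts ratios", {
  m <- mset(rbind(c(1, 2), c(2, 4), c(3, 6), c(4, 8)))
  expect_error(logTransform(m), "requires the 'sum' stage")
  lg <- logTransform(sumNormalize(m))
  a <- SummarizedExperiment::assay(lg, "log")
  # within each sample both metabolites were normalized, ratio is constant
  expect_equal(unname(a[2, ] - a[1, ]), rep(log(2), 4))
  expect_error(logTransform(lg), "already applied")
})

test_that("Pareto scaling centers and divides by sqrt of the sd", {
  ab <- rbind(c(10, 90), c(30, 70), c(50, 50))
  m <- logTransform(sumNormalize(mset(ab, group = c("a", "a", "b"))))
  # overwrite the log assay with hand values through a fresh matrix:
  # columns [1,2,3] and [0,2,4] per metabolite across 3 samples
  a <- SummarizedExperiment::assay(m, "log")
  a[1, ] <- c(1, 2, 3)
  a[2, ] <- c(0, 2, 4)
  SummarizedExperiment::assay(m, "log") <- a
  p <- SummarizedExperiment::assay(paretoScale(m), "pareto")
  expect_equal(unname(p[1, ]), c(-1, 0, 1))                  # sd 1
  expect_equal(unname(p[2, ]), c(-2, 0, 2) / sqrt(2),
               tolerance = 1e-9)                             # sd 2, /sqrt(2)
  # closed form: output column sd equals sqrt(input sd)
  expect_equal(sd(p[2, ]), sqrt(2), tolerance = 1e-9)
})

test_that("zero-variance metabolites Pareto-scale to zeros with a warning", {
  ab <- rbind(c(1, 5), c(2, 10), c(4, 20))  # second column constant after
  m <- logTransform(sumNormalize(mset(ab, group = c("a", "a", "b"))))
  a <- SummarizedExperiment::assay(m, "log")
  a[2, ] <- 3
  SummarizedExperiment::assay(m, "log") <- a
  expect_warning(p <- paretoScale(m), "zero-variance")
  expect_true(all(SummarizedExperiment::assay(p, "pareto")[2, ] == 0))
})

test_that("volcano applies the dual significance threshold", {
  # plant balanced up/down effects (so sample totals stay comparable and
  # sum normalization does not leak the effect into flat metabolites)
  set.seed(50)
  ab <- cbind(strong = c(rep(1, 4), rep(4, 4)) * exp(rnorm(8, 0, 0.05)),
              strong_dn = c(rep(4, 4), rep(1, 4)) * exp(rnorm(8, 0, 0.05)),
              flat = exp(rnorm(8, 0, 0.05)),
              sapply(1:8, function(i)
                setNames(exp(rnorm(8, 0, 0.05)), NULL)))
  m <- paretoScale(logTransform(sumNormalize(
    mset(ab, group = rep(c("primary", "regressing"), each = 4)))))
  v <- volcanoTable(m, "primary", "regressing")
  expect_true(v$significant[v$metabolite == "strong"])
  expect_false(v$significant[v$metabolite == "flat"])
  # threshold semantics: large fc with large p, and tiny fc with tiny p,
  # are both non-significant
  expect_false(with(list(p = 0.30, fc = 0.50), p < 0.05 && abs(fc) > 0.05))
  expect_false(with(list(p = 0.01, fc = 0.04), p < 0.05 && abs(fc) > 0.05))
  expect_error(volcanoTable(m, "primary", "absent"), "at least 2")
})

test_that("volcano t-test matches the closed-form pooled-variance t", {
  # metabolite x takes log values 1..6 up to a constant shift (sample
  # totals are held constant so sum normalization is a pure shift, and the
  # Pareto map is affine per metabolite): groups [1,2,3] vs [4,5,6] give
  # the closed-form pooled-variance t = -3.674, df = 4, p = 0.0213.
  total <- exp(6) + 1
  ab <- cbind(x = exp(1:6), y = total - exp(1:6))
  m <- paretoScale(logTransform(sumNormalize(
    mset(ab, group = rep(c("a", "b"), each = 3)))))
  sp2 <- (2 * var(1:3) + 2 * var(4:6)) / 4
  tClosed <- (2 - 5) / sqrt(sp2 * (2 / 3))
  pClosed <- 2 * pt(tClosed, df = 4)
  expect_equal(tClosed, -3.674, tolerance = 1e-3)
  expect_equal(pClosed, 0.0213, tolerance = 1e-3)
  v <- volcanoTable(m, "a", "b")
  expect_equal(v$p[v$metabolite == "x"], pClosed, tolerance = 1e-9)
})

test_that("volcano decisions match an independent recomputation", {
  set.seed(51)
  mismatches <- 0
  for (i in 1:100) {
    nmet <- sample(4:10, 1)
    ab <- matrix(exp(rnorm(10 * nmet, 0, 0.5)), 10, nmet)
    ab[, 1] <- ab[, 1] * rep(c(1, 2^rnorm(1, 0, 1)), each = 5)
    colnames(ab) <- paste0("m", seq_len(nmet))
    grp <- rep(c("a", "b"), each = 5)
    v <- volcanoTable(paretoScale(logTransform(sumNormalize(
      mset(ab, group = grp)))), "a", "b")
    ref <- independentVolcano(ab, grp, "a", "b")
    mismatches <- mismatches +
      sum(v$significant != as.logical(ref[, "significant"])) +
      sum(abs(v$p - ref[, "p"]) > 1e-9) +
      sum(abs(v$log2fc - ref[, "log2fc"]) > 1e-9)
  }
  expect_equal(mismatches, 0)
})

test_that("batch centering zeroes the per-batch medians and is idempotent", {
  ab <- cbind(m1 = exp(c(1, 2, 11, 12)), m2 = exp(c(5, 6, 7, 8)))
  m <- logTransform(sumNormalize(
    mset(ab, group = c("a", "b", "a", "b"),
         batch = c("b1", "b1", "b2", "b2"))))
  c1 <- batchCenter(m)
  a <- SummarizedExperiment::assay(c1, "batchcentered")
  batch <- SummarizedExperiment::colData(c1)$batch
  for (b in c("b1", "b2"))
    expect_equal(unname(apply(a[, batch == b], 1, median)), c(0, 0),
                 tolerance = 1e-12)
  # the two batches collapse onto the same centered values
  expect_equal(unname(a[, 1:2]), unname(a[, 3:4]), tolerance = 1e-9)
  c2 <- batchCenter(c1)
  expect_equal(SummarizedExperiment::assay(c2, "batchcentered"), a)
})

test_that("single-metabolite ANOVA reuses the shared group contract", {
  ab <- cbind(pyruvate = exp(c(1, 2, 3, 2, 3, 4, 3, 4, 5) / 10),
              other = exp(rep(0.5, 9)))
  m <- logTransform(sumNormalize(
    mset(ab, group = rep(c("g1", "g2", "g3"), each = 3))))
  res <- compareMetabolite(m, "pyruvate")
  expect_true(is.finite(res$F))
  expect_equal(nrow(res$pairwise), 3)
  expect_error(compareMetabolite(m, "nope"), "unknown metabolite")
})

test_that("planted effects at n = 5 per group are detected reliably", {
  set.seed(52)
  nSim <- 60  # the full 500-replicate sweep runs in the acceptance suite
  hits <- 0; falses <- 0; nNull <- 0
  for (i in seq_len(nSim)) {
    sim <- simulateMetabolomics(
      nPerGroup = 5, metabolites = paste0("m", 1:20),
      plantedLog2fc = c(1, -1, rep(0, 18)),
      baseAbundance = c(1, 2, rep(1, 18)),
      noiseSd = 0.25, seed = 1000 + i)
    ab <- t(SummarizedExperiment::assay(sim$set, "abundance"))
    grp <- SummarizedExperiment::colData(sim$set)$sample_group
    v <- volcanoTable(paretoScale(logTransform(sumNormalize(
      MetaboliteSet(ab, group = grp)))), "primary", "regressing")
    hits <- hits + sum(v$significant[1:2])
    falses <- falses + sum(v$significant[3:20])
    nNull <- nNull + 18
  }
  expect_gte(hits / (2 * nSim), 0.8)
  expect_lt(abs(falses / nNull - 0.05), 0.03)
})
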