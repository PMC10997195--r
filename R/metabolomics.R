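# Targeted-metabolomics stage: sum normalization, log transform, Pareto
# scaling, volcano classification, batch centering, single-metabolite ANOVA.

.requireStage <- function(m, need, op) {
  st <- processingStages(m)
  if (!need %in% st)
    stop(op, " requires the '", need, "' stage first (applied: ",
         paste(st, collapse = " -> "), ")")
  invisible(st)
}

.forbidStage <- function(m, done, op) {
  if (done %in% processingStages(m))
    stop(op, ": stage '", done, "' already applied")
  invisible(NULL)
}

.advance <- function(m, assayName, values, stage) {
  a <- assays(m)
  a[[assayName]] <- values
  assays(m) <- a
  metadata(m)$stages <- c(metadata(m)$stages, stage)
  m
}

# Last processed assay in the canonical order.
.currentAssay <- function(m) {
  for (nm in c("batchcentered", "pareto", "log", "sumnorm", "abundance"))
    if (nm %in% assayNames(m)) return(assay(m, nm))
  stop("no assay found")
}

#' Normalize each sample by its total metabolite abundance
#'
#' Divides every sample by the sum of all its metabolite abundances, so
#' each sample's normalized abundances sum to 1. No data filtering or
#' imputation is performed at any stage. Numerically idempotent.
#'
#' @param m a \linkS4class{MetaboliteSet} in the raw stage.
#' @return the set with a \code{sumnorm} assay added.
#' @export
sumNormalize <- function(m) {
  stopifnot(is(m, "MetaboliteSet"))
  .forbidStage(m, "log", "sumNormalize")
  a <- if ("sumnorm" %in% assayNames(m)) assay(m, "sumnorm")
       else assay(m, "abundance")
  tot <- colSums(a)
  if (any(tot <= 0)) stop("non-positive sample total")
  out <- sweep(a, 2, tot, "/")
  if ("sumnorm" %in% assayNames(m)) {
    assay(m, "sumnorm") <- out
    return(m)
  }
  .advance(m, "sumnorm", out, "sum")
}

#' Natural-log transform sum-normalized abundances
#'
#' Element-wise natural log of the sum-normalized values. Fold changes are
#' nevertheless always reported in log2 (converted via log2 = ln / ln 2),
#' matching how volcano results are displayed.
#'
#' @param m a sum-normalized \linkS4class{MetaboliteSet}.
#' @return the set with a \code{log} assay added.
#' @export
logTransform <- function(m) {
  stopifnot(is(m, "MetaboliteSet"))
  .requireStage(m, "sum", "logTransform")
  .forbidStage(m, "log", "logTransform")
  a <- assay(m, "sumnorm")
  if (any(a <= 0)) stop("log transform needs strictly positive values")
  .advance(m, "log", log(a), "log")
}

#' Pareto-scale log-transformed abundances
#'
#' Per metabolite: center at the mean and divide by the square root of the
#' sample standard deviation, the usual compromise between unit variance
#' scaling and no scaling for metabolomics. Zero-variance metabolites map
#' to all-zeros with a warning.
#'
#' @param m a log-transformed \linkS4class{MetaboliteSet}.
#' @return the set with a \code{pareto} assay added.
#' @export
paretoScale <- function(m) {
  stopifnot(is(m, "MetaboliteSet"))
  .requireStage(m, "log", "paretoScale")
  .forbidStage(m, "pareto", "paretoScale")
  a <- assay(m, "log")
  if (ncol(a) < 2) stop("Pareto scaling needs at least 2 samples")
  mu <- rowMeans(a)
  sdv <- apply(a, 1, stats::sd)
  centered <- a - mu
  zero <- sdv < .Machine$double.eps
  if (any(zero)) {
    warning(sum(zero), " zero-variance metabolite(s) mapped to zeros")
    sdv[zero] <- 1
    centered[zero, ] <- 0
  }
  .advance(m, "pareto", centered / sqrt(sdv), "pareto")
}

#' Center each batch at zero per metabolite
#'
#' Subtracts, per metabolite, the within-batch median on the log scale, so
#' every batch's median is zero afterwards. Medians (not means) are used
#' for robustness to outlying samples. Idempotent.
#'
#' @param m a log-transformed \linkS4class{MetaboliteSet}.
#' @return the set with a \code{batchcentered} assay added (or updated).
#' @export
batchCenter <- function(m) {
  stopifnot(is(m, "MetaboliteSet"))
  .requireStage(m, "log", "batchCenter")
  batch <- colData(m)$batch
  if (any(is.na(batch) | batch == "")) stop("missing batch labels")
  a <- if ("batchcentered" %in% assayNames(m)) assay(m, "batchcentered")
       else assay(m, "log")
  out <- a
  for (b in unique(batch)) {
    idx <- batch == b
    med <- apply(a[, idx, drop = FALSE], 1, stats::median)
    out[, idx] <- a[, idx, drop = FALSE] - med
  }
  if ("batchcentered" %in% assayNames(m)) {
    assay(m, "batchcentered") <- out
    return(m)
  }
  .advance(m, "batchcentered", out, "batch")
}

#' Two-group volcano classification of metabolites
#'
#' Per metabolite: a two-sided two-sample t-test (pooled variance) on the
#' fully processed (Pareto-scaled) values, and a log2 fold change computed
#' as the difference of group means of log2 sum-normalized abundances —
#' Pareto scaling destroys fold-change units, so the fold change is taken
#' one stage earlier. A metabolite is significant when p < \code{pThresh}
#' and |log2FC| > \code{lfcThresh}.
#'
#' @param m a \linkS4class{MetaboliteSet} processed through Pareto scaling.
#' @param groupA,groupB the two \code{sample_group} labels to compare;
#'   fold change is \code{groupB - groupA}.
#' @param pThresh,lfcThresh significance thresholds (defaults 0.05, 0.05).
#' @return data.frame: \code{metabolite}, \code{log2fc}, \code{p},
#'   \code{significant}.
#' @export
volcanoTable <- function(m, groupA, groupB, pThresh = 0.05,
                         lfcThresh = 0.05) {
  stopifnot(is(m, "MetaboliteSet"))
  .requireStage(m, "pareto", "volcanoTable")
  grp <- colData(m)$sample_group
  ia <- grp == groupA
  ib <- grp == groupB
  if (sum(ia) < 2 || sum(ib) < 2)
    stop("both groups must be present with at least 2 samples")
  proc <- assay(m, "pareto")
  l2 <- log2(assay(m, "sumnorm"))
  p <- vapply(seq_len(nrow(proc)), function(i) {
    xa <- proc[i, ia]; xb <- proc[i, ib]
    if (stats::sd(c(xa, xb)) < .Machine$double.eps) return(1)
    stats::t.test(xa, xb, var.equal = TRUE)$p.value
  }, 0)
  log2fc <- rowMeans(l2[, ib, drop = FALSE]) - rowMeans(l2[, ia, drop = FALSE])
  data.frame(metabolite = rownames(proc), log2fc = unname(log2fc),
             p = p, significant = p < pThresh & abs(log2fc) > lfcThresh,
             row.names = NULL)
}

#' Compare one metabolite across three or more groups
#'
#' Same contract as \code{\link{compareGroups}} (one-way ANOVA + Tukey HSD),
#' applied to a single metabolite's processed values — typically after
#' \code{\link{batchCenter}} when groups span batches or cell lines.
#'
#' @param m a log-transformed \linkS4class{MetaboliteSet}.
#' @param metabolite metabolite (row) name.
#' @return list as returned by \code{\link{compareGroups}}.
#' @export
compareMetabolite <- function(m, metabolite) {
  stopifnot(is(m, "MetaboliteSet"))
  a <- .currentAssay(m)
  if (!metabolite %in% rownames(a)) stop("unknown metabolite: ", metabolite)
  compareGroups(a[metabolite, ], colData(m)$sample_group)
}
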