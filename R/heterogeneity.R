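# Pixel-wise 2x2 metabolic clustering, area fractions with LL exclusion,
# stage aggregation and ANOVA/Tukey group comparison.

#' Compute high/low segmentation cutoffs from pooled pixel values
#'
#' The cutoff for each probe is the mean (or median) of its pooled pixel
#' values. The pooling scope — by default all pixels across all mice and
#' time points of a cohort, so cluster labels are longitudinally comparable
#' — is recorded in the result for audit.
#'
#' @param nbdgPool,tmrePool \linkS4class{PixelDistribution}s of the 2-NBDG
#'   and TMRE pools used to set the cutoffs.
#' @param method \code{"mean"} (default) or \code{"median"}.
#' @param poolingScope descriptor recorded in the result.
#' @return a \linkS4class{CutoffPair}.
#' @export
computeCutoffs <- function(nbdgPool, tmrePool, method = c("mean", "median"),
                           poolingScope = "cohort") {
  method <- match.arg(method)
  stopifnot(is(nbdgPool, "PixelDistribution"), is(tmrePool, "PixelDistribution"))
  f <- if (method == "mean") mean else stats::median
  new("CutoffPair", cutoffNBDG = f(nbdgPool@values),
      cutoffTMRE = f(tmrePool@values), method = method,
      poolingScope = poolingScope)
}

#' Assign each pixel to one of four metabolic clusters
#'
#' Pixel-by-pixel 2x2 classification of co-registered frames: a pixel is
#' High for a probe when its value is strictly greater than that probe's
#' cutoff (ties go Low, a deterministic rule that is measure-zero for
#' continuous data). Labels: LL, HL, LH, HH with first letter = 2-NBDG
#' level, second = TMRE level, e.g. HL = [2-NBDG_High/TMRE_Low].
#'
#' @param tmre,nbdg \linkS4class{CalibratedImage}s of the same mouse-day.
#' @param cutoffs a \linkS4class{CutoffPair}.
#' @return a \linkS4class{ClusterMask}.
#' @export
assignClusters <- function(tmre, nbdg, cutoffs) {
  stopifnot(is(tmre, "CalibratedImage"), is(nbdg, "CalibratedImage"),
            is(cutoffs, "CutoffPair"))
  if (!identical(dim(tmre@values), dim(nbdg@values)))
    stop("TMRE and 2-NBDG frames differ in shape")
  if (tmre@mouse != nbdg@mouse || tmre@day != nbdg@day)
    stop("TMRE and 2-NBDG frames are not from the same mouse-day")
  nHigh <- nbdg@values > cutoffs@cutoffNBDG
  tHigh <- tmre@values > cutoffs@cutoffTMRE
  lab <- matrix("LL", nrow(nHigh), ncol(nHigh))
  lab[nHigh & !tHigh] <- "HL"
  lab[!nHigh & tHigh] <- "LH"
  lab[nHigh & tHigh] <- "HH"
  new("ClusterMask", labels = lab, mouse = tmre@mouse, day = tmre@day,
      cutoffs = cutoffs)
}

#' Area fractions of the non-LL metabolic clusters
#'
#' Each cluster's area fraction is its pixel count as a percentage of all
#' clustered (non-LL) pixels. LL pixels are excluded from the denominator
#' because they correspond primarily to background noise or vasculature;
#' they remain in the mask for visualization.
#'
#' @param mask a \linkS4class{ClusterMask}.
#' @return one-row data.frame: \code{mouse}, \code{day}, \code{percent_HL},
#'   \code{percent_LH}, \code{percent_HH}, \code{n_nonLL}.
#' @export
areaFractions <- function(mask) {
  stopifnot(is(mask, "ClusterMask"))
  tab <- table(factor(mask@labels, levels = .CLASSES))
  nNonLL <- sum(tab[c("HL", "LH", "HH")])
  if (nNonLL == 0)
    stop("no viable signal: all pixels are LL (background/vasculature)")
  data.frame(mouse = mask@mouse, day = mask@day,
             percent_HL = 100 * tab[["HL"]] / nNonLL,
             percent_LH = 100 * tab[["LH"]] / nNonLL,
             percent_HH = 100 * tab[["HH"]] / nNonLL,
             n_nonLL = as.integer(nNonLL))
}

#' Average per-image area fractions within disease stages
#'
#' The percentage reported for a cluster at a stage is the unweighted mean
#' of the per-time-point percentages mapped to that stage (e.g. regression
#' = mean over the regressing imaging days). Grouping can pool all mice or
#' keep per-mouse rows for mouse-level heterogeneity readouts.
#'
#' @param fractions data.frame of stacked \code{\link{areaFractions}} rows.
#' @param stageMap named character vector mapping day (as character) to
#'   stage, or a function \code{day -> stage}.
#' @param grouping \code{"pooled"} or \code{"per_mouse"}.
#' @return data.frame with one row per stage (and mouse when per-mouse).
#' @export
aggregateStageFractions <- function(fractions, stageMap,
                                    grouping = c("pooled", "per_mouse")) {
  grouping <- match.arg(grouping)
  stopifnot(is.data.frame(fractions))
  if (is.function(stageMap)) {
    stage <- vapply(fractions$day, stageMap, "")
  } else {
    stage <- unname(stageMap[as.character(fractions$day)])
  }
  if (any(is.na(stage)))
    stop("unmapped day(s): ",
         paste(unique(fractions$day[is.na(stage)]), collapse = ", "))
  keys <- if (grouping == "per_mouse")
    list(mouse = fractions$mouse, stage = stage) else list(stage = stage)
  agg <- stats::aggregate(
    fractions[, c("percent_HL", "percent_LH", "percent_HH")],
    by = keys, FUN = mean)
  agg$grouping <- grouping
  agg
}

#' One-way ANOVA with Tukey HSD post hoc comparison
#'
#' Shared group-comparison contract for cluster area fractions and single
#' metabolites: standard one-way ANOVA F and p, followed by Tukey's honest
#' significant difference adjusted pairwise p-values. A degenerate input
#' with zero total variance returns F = 0, p = 1 (this occurs legitimately
#' on noiseless synthetic fixtures).
#'
#' @param values numeric vector of observations.
#' @param groups group label per observation (>= 2 groups, each >= 2 obs).
#' @return list with \code{F}, \code{p}, \code{group_means}, and
#'   \code{pairwise} (data.frame: comparison, diff, p_adj).
#' @examples
#' compareGroups(c(1, 2, 3, 2, 3, 4, 3, 4, 5),
#'               rep(c("a", "b", "c"), each = 3))$F  # 3
#' @export
compareGroups <- function(values, groups) {
  groups <- as.character(groups)
  if (length(values) != length(groups)) stop("values/groups length mismatch")
  if (any(!is.finite(values))) stop("values must be finite")
  tab <- table(groups)
  if (length(tab) < 2) stop("need at least 2 groups")
  if (any(tab < 2)) stop("every group needs at least 2 observations")
  gm <- vapply(split(values, groups), mean, 0)
  if (stats::var(values) < .Machine$double.eps) {
    prs <- utils::combn(names(tab), 2)
    pairwise <- data.frame(
      comparison = paste(prs[2, ], prs[1, ], sep = "-"),
      diff = 0, p_adj = 1)
    return(list(F = 0, p = 1, group_means = gm, pairwise = pairwise))
  }
  d <- data.frame(y = values, g = factor(groups))
  fit <- stats::aov(y ~ g, data = d)
  an <- summary(fit)[[1]]
  tk <- stats::TukeyHSD(fit)$g
  pairwise <- data.frame(comparison = rownames(tk), diff = tk[, "diff"],
                         p_adj = tk[, "p adj"], row.names = NULL)
  list(F = an["g", "F value"], p = an["g", "Pr(>F)"],
       group_means = gm, pairwise = pairwise)
}
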