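# Pooled pixel distributions, KS statistics under mouse-blocked permutation
# nulls, and ridgeline-ready binned densities.

#' Pool pixels from calibrated images into one blocked distribution
#'
#' Concatenates all pixel values across images ("all pixels and all mice"),
#' tagging each value with its mouse id. Mice contribute proportionally to
#' their pixel counts; the block tags are what the permutation test uses to
#' respect within-animal dependence.
#'
#' @param images list of \linkS4class{CalibratedImage}s of a single probe.
#' @param label free-form group/time-point label for the pool.
#' @return a \linkS4class{PixelDistribution}.
#' @export
poolPixels <- function(images, label = "") {
  if (length(images) == 0) stop("empty image list")
  probes <- vapply(images, function(x) x@probe, "")
  if (length(unique(probes)) != 1)
    stop("cannot pool mixed probes: ", paste(unique(probes), collapse = ", "))
  values <- unlist(lapply(images, function(x) as.vector(x@values)),
                   use.names = FALSE)
  blocks <- unlist(lapply(images, function(x)
    rep(x@mouse, length(x@values))), use.names = FALSE)
  new("PixelDistribution", values = values, blocks = blocks,
      probe = probes[1], label = label)
}

#' Two-sample Kolmogorov-Smirnov statistic on unbinned values
#'
#' \code{D = sup_x |ECDF_a(x) - ECDF_b(x)|}, evaluated over the pooled
#' sample points (ties handled exactly). Computed on the raw pooled pixel
#' values; binning for display happens only after statistics.
#'
#' @param a,b \linkS4class{PixelDistribution}s or numeric vectors.
#' @return the KS statistic, a number in [0, 1].
#' @examples
#' ksStatistic(c(1, 2, 3, 4), c(2, 3, 4, 5))  # 0.25
#' @export
ksStatistic <- function(a, b) {
  va <- if (is(a, "PixelDistribution")) a@values else as.numeric(a)
  vb <- if (is(b, "PixelDistribution")) b@values else as.numeric(b)
  if (length(va) == 0 || length(vb) == 0) stop("empty input")
  x <- sort(unique(c(va, vb)))
  Fa <- findInterval(x, sort(va)) / length(va)
  Fb <- findInterval(x, sort(vb)) / length(vb)
  max(abs(Fa - Fb))
}

# Build the cumulative-count matrix used by the permutation engine: rows are
# the pooled sorted values, columns are blocks; entry [i, j] counts values of
# block j that are <= pooled_sorted[i]. Any group ECDF is then a weighted
# column sum, so D for thousands of block assignments reduces to one matrix
# product.
.blockCumCounts <- function(values, blocks) {
  ord <- order(values)
  bfac <- factor(blocks[ord])
  onehot <- matrix(0, length(values), nlevels(bfac))
  onehot[cbind(seq_along(values), as.integer(bfac))] <- 1
  B <- apply(onehot, 2, cumsum)
  colnames(B) <- levels(bfac)
  B
}

# D statistics for many block->group assignments at once. B: pooled cumcount
# matrix (P x K); counts: per-block totals; Z: K x nAssign 0/1 matrix, 1 =
# block assigned to group a.
.dForAssignments <- function(B, counts, Z) {
  A <- B %*% Z
  na <- as.vector(counts %*% Z)
  tot <- rowSums(B)
  nb <- sum(counts) - na
  Fa <- sweep(A, 2, na, "/")
  Fb <- sweep(tot - A, 2, nb, "/")
  M <- abs(Fa - Fb)
  apply(M, 2, max)
}

#' Blocked-permutation KS test
#'
#' Compares two pooled pixel distributions with the KS statistic, assessing
#' it against a null built by permuting whole mouse blocks (never single
#' pixels, which are dependent within an animal). Two schemes:
#' \describe{
#'   \item{exchange}{unpaired: mouse blocks are reassigned between the two
#'     groups, preserving the number of blocks per group. Default.}
#'   \item{flip}{paired (longitudinal): each mouse must appear in both
#'     groups; its two value sets are swapped with probability 1/2.}
#' }
#' When the number of distinct block assignments is at most \code{nPerm}
#' (and \code{exact != "never"}), the null is enumerated exhaustively and the
#' exact p-value is reported with \code{nPerm} set to the enumeration count.
#' Otherwise \code{nPerm} Monte-Carlo draws are used with the add-one
#' convention \code{p = (1 + #(D* >= D)) / (nPerm + 1)}.
#'
#' @param a,b \linkS4class{PixelDistribution}s.
#' @param nPerm number of random permutations (default 1000).
#' @param scheme \code{"exchange"} or \code{"flip"}.
#' @param seed integer seed for Monte-Carlo draws.
#' @param exact \code{"auto"} (enumerate when feasible), \code{"always"},
#'   or \code{"never"} (force Monte-Carlo).
#' @return a \linkS4class{KSTestResult}.
#' @export
blockedPermutationTest <- function(a, b, nPerm = 1000,
                                   scheme = c("exchange", "flip"),
                                   seed = 1L, exact = c("auto", "always", "never")) {
  scheme <- match.arg(scheme)
  exact <- match.arg(exact)
  stopifnot(is(a, "PixelDistribution"), is(b, "PixelDistribution"))
  blocksA <- unique(a@blocks)
  blocksB <- unique(b@blocks)
  dObs <- ksStatistic(a, b)

  if (scheme == "exchange") {
    # Disambiguate same-named mice across groups: the block unit is
    # (group, mouse).
    tagsA <- paste0("a:", a@blocks)
    tagsB <- paste0("b:", b@blocks)
    values <- c(a@values, b@values)
    blocks <- c(tagsA, tagsB)
    K <- length(unique(blocks))
    ka <- length(blocksA)
    if (K < 2) stop("need at least 2 blocks in total")
    B <- .blockCumCounts(values, blocks)
    counts <- as.vector(table(factor(blocks, levels = colnames(B))))
    nAssign <- choose(K, ka)
    useExact <- exact == "always" || (exact == "auto" && nAssign <= nPerm)
    if (useExact) {
      sel <- utils::combn(K, ka)
      Z <- matrix(0, K, ncol(sel))
      Z[cbind(as.vector(sel), rep(seq_len(ncol(sel)), each = ka))] <- 1
      d <- .dForAssignments(B, counts, Z)
      p <- sum(d >= dObs - 1e-12) / ncol(sel)
      return(new("KSTestResult", dObs = dObs, pPerm = p,
                 nPerm = as.integer(ncol(sel)), scheme = scheme,
                 exact = TRUE, seed = NA_integer_))
    }
    d <- withSeed(seed, {
      Z <- matrix(0, K, nPerm)
      for (j in seq_len(nPerm)) Z[sample.int(K, ka), j] <- 1
      .dForAssignments(B, counts, Z)
    })
    p <- (1 + sum(d >= dObs - 1e-12)) / (nPerm + 1)
    return(new("KSTestResult", dObs = dObs, pPerm = p,
               nPerm = as.integer(nPerm), scheme = scheme,
               exact = FALSE, seed = as.integer(seed)))
  }

  # flip scheme: paired by mouse id
  if (!setequal(blocksA, blocksB))
    stop("flip scheme requires the same mouse ids in both groups")
  mice <- sort(blocksA)
  m <- length(mice)
  if (m < 2) stop("need at least 2 paired blocks")
  values <- c(a@values, b@values)
  blocks <- c(paste0("a:", a@blocks), paste0("b:", b@blocks))
  B <- .blockCumCounts(values, blocks)
  counts <- as.vector(table(factor(blocks, levels = colnames(B))))
  ia <- match(paste0("a:", mice), colnames(B))
  ib <- match(paste0("b:", mice), colnames(B))
  K <- ncol(B)
  buildZ <- function(F) {
    # F: m x nAssign flip indicators; group a keeps mouse's a-block when
    # F == 0, takes its b-block when F == 1.
    nc <- ncol(F)
    Z <- matrix(0, K, nc)
    for (j in seq_len(nc)) {
      keep <- F[, j] == 0
      Z[c(ia[keep], ib[!keep]), j] <- 1
    }
    Z
  }
  nAssign <- 2^m
  useExact <- exact == "always" || (exact == "auto" && nAssign <= nPerm)
  if (useExact) {
    F <- as.matrix(expand.grid(rep(list(0:1), m)))
    d <- .dForAssignments(B, counts, buildZ(t(F)))
    p <- sum(d >= dObs - 1e-12) / nAssign
    return(new("KSTestResult", dObs = dObs, pPerm = p,
               nPerm = as.integer(nAssign), scheme = scheme,
               exact = TRUE, seed = NA_integer_))
  }
  d <- withSeed(seed, {
    F <- matrix(stats::rbinom(m * nPerm, 1, 0.5), m, nPerm)
    .dForAssignments(B, counts, buildZ(F))
  })
  p <- (1 + sum(d >= dObs - 1e-12)) / (nPerm + 1)
  new("KSTestResult", dObs = dObs, pPerm = p, nPerm = as.integer(nPerm),
      scheme = scheme, exact = FALSE, seed = as.integer(seed))
}

#' Bin a pixel distribution for ridgeline display
#'
#' Histogram densities normalized to integrate to 1, plus the arithmetic
#' mean of the unbinned values (the dashed mean line on ridge plots). All
#' statistics in this package are computed before binning; these bins exist
#' only for graphing.
#'
#' @param dist a \linkS4class{PixelDistribution}.
#' @param nBins number of equal-width bins (>= 2).
#' @return list with \code{bin_edges}, \code{densities}, \code{mean_line}.
#' @export
binForRidge <- function(dist, nBins = 50) {
  stopifnot(is(dist, "PixelDistribution"))
  if (nBins < 2) stop("nBins must be >= 2")
  v <- dist@values
  lo <- min(v); hi <- max(v)
  if (hi <= lo) { lo <- lo - 0.5; hi <- hi + 0.5 }
  edges <- seq(lo, hi, length.out = nBins + 1)
  h <- graphics::hist(v, breaks = edges, plot = FALSE)
  list(bin_edges = edges, densities = h$density, mean_line = mean(v))
}
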