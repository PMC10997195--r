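# Internal constants and helpers shared across the pipeline.

# Probe identifiers: 60-min summary endpoints for mitochondrial membrane
# potential (TMRE), glucose uptake (2-NBDG) and fatty-acid uptake (Bodipy).
.PROBES <- c("TMRE60", "NBDG60", "BODIPY60")

# Metabolic class labels: first letter = 2-NBDG level, second = TMRE level.
# HL = [2-NBDG_High/TMRE_Low] (glycolytic), LH = [2-NBDG_Low/TMRE_High]
# (oxidative), HH = both high, LL = both low (background/vasculature).
.CLASSES <- c("LL", "HL", "LH", "HH")

.STAGES <- c("primary", "early_regression", "late_regression",
             "residual", "recurrence", "untreated_growth")

.ARMS <- c("untreated", "treated_sensitive", "treated_resistant")

# Full-scale value (AU) used when encoding frames into TIFF samples; r-tiff
# stores samples on [0, 1], so frames are written as value / .AU_SCALE.
.AU_SCALE <- 4096

#' Derive a reproducible child seed from a root seed and a path of labels
#'
#' All randomness in the simulators flows from one root seed through this
#' polynomial string hash, so any single artifact (one mouse-day bundle, one
#' trajectory) can be regenerated in isolation. Result is always a valid
#' 32-bit R integer seed.
#'
#' @param root integer root seed.
#' @param ... character or numeric labels identifying the artifact.
#' @return an integer seed in [0, 2^31 - 20).
#' @export
deriveSeed <- function(root, ...) {
  parts <- paste(c(as.character(root), vapply(list(...), as.character, "")),
                 collapse = "/")
  h <- 0
  for (cp in utf8ToInt(parts)) h <- (h * 31 + cp) %% 2147483629
  as.integer(h)
}

# Evaluate expr with a local RNG state seeded at `seed`, restoring the
# caller's state afterwards.
withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

.gaussKernel1d <- function(sigma) {
  r <- max(1L, as.integer(ceiling(3 * sigma)))
  k <- stats::dnorm(seq(-r, r), sd = sigma)
  k / sum(k)
}

# Separable Gaussian blur with edge replication; used to turn white noise
# into a smooth random field with correlation length ~ sigma pixels.
.gaussBlur <- function(m, sigma) {
  k <- .gaussKernel1d(sigma)
  convCols <- function(x) {
    n <- nrow(x)
    r <- (length(k) - 1L) / 2L
    xp <- rbind(x[rep(1L, r), , drop = FALSE], x,
                x[rep(n, r), , drop = FALSE])
    out <- matrix(0, n, ncol(x))
    for (j in seq_along(k))
      out <- out + k[j] * xp[j:(j + n - 1L), , drop = FALSE]
    out
  }
  t(convCols(t(convCols(m))))
}

.assertFiniteMatrix <- function(m, what) {
  if (!is.matrix(m) || !is.numeric(m))
    stop(what, " must be a numeric matrix")
  if (any(!is.finite(m)))
    stop(what, " contains non-finite values")
  invisible(m)
}
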