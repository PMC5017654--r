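# Probabilistic primitives: hyperparameters, the collapsed Gaussian /
# normal-inverse-gamma observation model, CRP predictive weights and
# atom sufficient-statistic bookkeeping.

#' Construct model hyperparameters
#'
#' Defaults follow the values used for the CT experiments this model was
#' developed for: `alpha0 = 0.01` (per-image concentration, favors few
#' segments), `lam = 0.001` (weak spatial smoothing), `gamma = 1` (top-level
#' concentration). The normal-inverse-gamma base measure defaults are weakly
#' informative for standardized intensities: prior mean 0 with strength
#' `baseKappa0 = 0.1`, prior variance centered near `baseB0/(baseA0 - 1) = 1`.
#'
#' @param alpha0 positive per-image DP concentration.
#' @param gamma positive top-level DP concentration (joint mode only).
#' @param lam non-negative MRF smoothing weight.
#' @param baseMu0,baseKappa0,baseA0,baseB0 normal-inverse-gamma base-measure
#'   parameters (mean, mean strength, variance shape, variance scale).
#' @return a validated [Hyperparameters-class] object.
#' @examples
#' hp <- hyperParameters()
#' hp
#' @export
hyperParameters <- function(alpha0 = 0.01, gamma = 1, lam = 0.001,
                            baseMu0 = 0, baseKappa0 = 0.1, baseA0 = 2,
                            baseB0 = 1) {
  new("Hyperparameters", alpha0 = as.numeric(alpha0),
      gamma = as.numeric(gamma), lam = as.numeric(lam),
      baseMu0 = as.numeric(baseMu0), baseKappa0 = as.numeric(baseKappa0),
      baseA0 = as.numeric(baseA0), baseB0 = as.numeric(baseB0))
}

# parameter vector handed to the C++ samplers
.hpVector <- function(hp, lam = hp@lam) {
  c(hp@baseMu0, hp@baseKappa0, hp@baseA0, hp@baseB0, hp@alpha0, hp@gamma, lam)
}

setMethod("show", "Hyperparameters", function(object) {
  cat("Hyperparameters: alpha0 =", object@alpha0,
      " gamma =", object@gamma, " lambda =", object@lam, "\n",
      " NIG base: mu0 =", object@baseMu0, " kappa0 =", object@baseKappa0,
      " a0 =", object@baseA0, " b0 =", object@baseB0, "\n")
})

#' Standardize image intensities
#'
#' Centers and scales a 2-D intensity grid to sample mean 0 and standard
#' deviation 1, using the population convention (divide by n). A constant
#' image maps to all zeros. Standardization makes the fixed base-measure
#' constants meaningful regardless of the acquisition scale (8-bit, 16-bit,
#' Hounsfield-like), and is invariant to affine rescalings of the input.
#'
#' @param raw numeric matrix or [ImageSlice-class].
#' @return numeric matrix of the same shape.
#' @examples
#' standardizeIntensities(matrix(c(1, 2, 3), 1))
#' @export
standardizeIntensities <- function(raw) {
  if (is(raw, "ImageSlice")) raw <- raw@intensity
  if (!is.matrix(raw) || !is.numeric(raw) || length(raw) == 0L)
    stop("input must be a non-empty numeric matrix")
  bad <- which(!is.finite(raw), arr.ind = TRUE)
  if (nrow(bad) > 0L)
    stop("non-finite pixel(s) at (row, col): ",
         paste(sprintf("(%d,%d)", bad[, 1], bad[, 2]), collapse = " "))
  m <- mean(raw)
  s <- sqrt(mean((raw - m)^2))
  if (s == 0) return(array(0, dim(raw)))
  (raw - m) / s
}

# pooled standardization across a list of images (joint mode): preserves
# cross-image correspondence of class means
.standardizePooled <- function(imgs) {
  all <- unlist(imgs)
  if (any(!is.finite(all))) stop("non-finite pixel in image set")
  m <- mean(all)
  s <- sqrt(mean((all - m)^2))
  if (s == 0) return(lapply(imgs, function(x) array(0, dim(x))))
  lapply(imgs, function(x) (x - m) / s)
}

#' Chinese restaurant process predictive weights
#'
#' Given the sizes of the existing clusters and the concentration `alpha0`,
#' returns the CRP predictive weights for the next observation: proportional
#' to each cluster's size for joining it and to `alpha0` for opening a new
#' cluster, so the normalized new-cluster probability is
#' `alpha0 / (alpha0 + n)` with `n` the number of seated observations.
#'
#' @param atomCounts integer vector of positive cluster sizes (may be empty).
#' @param alpha0 positive concentration.
#' @param normalize if `TRUE`, return probabilities summing to 1.
#' @return numeric vector of length `length(atomCounts) + 1`; the last entry
#'   is the new-cluster weight.
#' @examples
#' crpWeights(c(5, 3), 0.01)
#' crpWeights(c(1, 1, 1), 1, normalize = TRUE)
#' @export
crpWeights <- function(atomCounts, alpha0, normalize = FALSE) {
  if (length(alpha0) != 1L || !is.finite(alpha0) || alpha0 <= 0)
    stop("'alpha0' must be a single positive number")
  if (length(atomCounts) && any(atomCounts <= 0))
    stop("all cluster counts must be positive; remove empty atoms first")
  w <- c(as.numeric(atomCounts), alpha0)
  if (normalize) w / sum(w) else w
}

#' Log posterior-predictive density of an intensity under an atom
#'
#' The collapsed Gaussian observation model: with the normal-inverse-gamma
#' base measure, the predictive density of a new value `x` given the
#' observations already in an atom is a scaled, shifted Student-t. With an
#' empty atom this is the prior predictive under the base measure.
#'
#' @param x numeric value(s), standardized intensity.
#' @param stats an [AtomStats-class] object (or a numeric vector
#'   `c(count, sumX, sumX2)`).
#' @param hp a [Hyperparameters-class] object.
#' @return log predictive density, same length as `x`.
#' @examples
#' hp <- hyperParameters(baseMu0 = 0, baseKappa0 = 1, baseA0 = 1, baseB0 = 1)
#' logPredictive(0, atomStats(), hp)  # Student-t(df 2, scale sqrt(2)) at 0
#' @export
logPredictive <- function(x, stats, hp) {
  s <- .statsTriple(stats)
  n <- s[1]; sx <- s[2]; sq <- s[3]
  k0 <- hp@baseKappa0; mu0 <- hp@baseMu0; a0 <- hp@baseA0; b0 <- hp@baseB0
  kn <- k0 + n
  an <- a0 + n / 2
  mun <- (k0 * mu0 + sx) / kn
  bn <- b0
  if (n > 0) {
    xb <- sx / n
    ss <- max(0, sq - sx^2 / n)
    bn <- bn + ss / 2 + k0 * n * (xb - mu0)^2 / (2 * kn)
  }
  nu <- 2 * an
  scale2 <- bn * (kn + 1) / (an * kn)
  z2 <- (x - mun)^2 / (nu * scale2)
  lgamma((nu + 1) / 2) - lgamma(nu / 2) - 0.5 * log(nu * pi * scale2) -
    (nu + 1) / 2 * log1p(z2)
}

.statsTriple <- function(stats) {
  if (is(stats, "AtomStats"))
    return(c(as.numeric(stats@count), stats@sumX, stats@sumX2))
  if (is.numeric(stats) && length(stats) == 3L) return(stats)
  stop("'stats' must be an AtomStats object or a numeric triple")
}

#' Atom sufficient statistics
#'
#' @param count non-negative integer number of assigned pixels.
#' @param sumX,sumX2 running sum and sum of squares of assigned intensities.
#' @return an [AtomStats-class] object.
#' @examples
#' s <- atomAdd(atomStats(), 2)
#' atomRemove(s, 2)
#' @export
atomStats <- function(count = 0L, sumX = 0, sumX2 = 0) {
  new("AtomStats", count = as.integer(count), sumX = as.numeric(sumX),
      sumX2 = as.numeric(sumX2))
}

#' @describeIn atomStats add one observation to an atom.
#' @param stats an [AtomStats-class] object.
#' @param x numeric observation.
#' @export
atomAdd <- function(stats, x) {
  stopifnot(is(stats, "AtomStats"), length(x) == 1L, is.finite(x))
  new("AtomStats", count = stats@count + 1L, sumX = stats@sumX + x,
      sumX2 = stats@sumX2 + x * x)
}

#' @describeIn atomStats remove one previously added observation; exact
#'   inverse of [atomAdd()] (integer count, sums within float tolerance).
#' @export
atomRemove <- function(stats, x) {
  stopifnot(is(stats, "AtomStats"), length(x) == 1L, is.finite(x))
  if (stats@count < 1L) stop("cannot remove from an empty atom")
  new("AtomStats", count = stats@count - 1L, sumX = stats@sumX - x,
      sumX2 = stats@sumX2 - x * x)
}

#' @rdname AtomStats-class
#' @param x an `AtomStats` object.
#' @export
setMethod("atomCount", "AtomStats", function(x) x@count)

setMethod("show", "AtomStats", function(object) {
  cat(sprintf("AtomStats: n = %d, sum = %g, sumsq = %g\n", object@count,
              object@sumX, object@sumX2))
})

#' @rdname ImageSlice-class
#' @param intensity numeric matrix.
#' @param spacing numeric length-2 pixel spacing.
#' @param source originating path (optional).
#' @export
imageSlice <- function(intensity, spacing = c(1, 1),
                       source = NA_character_) {
  new("ImageSlice", intensity = intensity, spacing = as.numeric(spacing),
      source = as.character(source))
}

#' @rdname ImageSlice-class
#' @export
setMethod("intensity", "ImageSlice", function(x) x@intensity)

setMethod("show", "ImageSlice", function(object) {
  d <- dim(object@intensity)
  cat(sprintf("ImageSlice %d x %d, spacing (%g, %g)%s\n", d[1], d[2],
              object@spacing[1], object@spacing[2],
              if (is.na(object@source)) "" else paste0(", from ",
                                                       object@source)))
})
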