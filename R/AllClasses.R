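# S4 classes for the model, sampler state and phantom fixtures.

#' Model hyperparameters
#'
#' Concentration, smoothing and base-measure parameters of the DP/HDP-MRF
#' segmentation model. `alpha0` is the per-image DP concentration, `gamma` the
#' top-level (franchise) concentration, `lam` the non-negative MRF smoothing
#' weight multiplying the neighbor-agreement sum. The base measure over atom
#' (intensity-class) parameters is a normal-inverse-gamma with prior mean
#' `baseMu0`, mean strength `baseKappa0`, variance shape `baseA0` and scale
#' `baseB0`; intensities are assumed standardized, so the defaults are weakly
#' informative around mean 0, variance ~1.
#'
#' @slot alpha0 positive numeric, per-image DP concentration.
#' @slot gamma positive numeric, top-level DP concentration.
#' @slot lam non-negative numeric, MRF smoothing weight.
#' @slot baseMu0 numeric, prior mean of an atom's mean.
#' @slot baseKappa0 positive numeric, prior strength on the mean.
#' @slot baseA0 positive numeric, inverse-gamma shape for the variance.
#' @slot baseB0 positive numeric, inverse-gamma scale for the variance.
#' @seealso [hyperParameters()]
#' @exportClass Hyperparameters
setClass("Hyperparameters",
  representation(alpha0 = "numeric", gamma = "numeric", lam = "numeric",
                 baseMu0 = "numeric", baseKappa0 = "numeric",
                 baseA0 = "numeric", baseB0 = "numeric"))

setValidity("Hyperparameters", function(object) {
  msg <- character()
  for (s in c("alpha0", "gamma", "lam", "baseMu0", "baseKappa0",
              "baseA0", "baseB0")) {
    v <- slot(object, s)
    if (length(v) != 1L || !is.finite(v))
      msg <- c(msg, sprintf("'%s' must be a single finite number", s))
  }
  if (length(msg)) return(msg)
  if (object@alpha0 <= 0) msg <- c(msg, "'alpha0' must be > 0")
  if (object@gamma <= 0) msg <- c(msg, "'gamma' must be > 0")
  if (object@lam < 0) msg <- c(msg, "'lam' must be >= 0")
  if (object@baseKappa0 <= 0) msg <- c(msg, "'baseKappa0' must be > 0")
  if (object@baseA0 <= 0) msg <- c(msg, "'baseA0' must be > 0")
  if (object@baseB0 <= 0) msg <- c(msg, "'baseB0' must be > 0")
  if (length(msg)) msg else TRUE
})

#' Sufficient statistics of one intensity atom
#'
#' Collapsed representation of a Gaussian intensity class: the number of
#' assigned pixels and the running sum and sum of squares of their
#' (standardized) intensities. With the conjugate normal-inverse-gamma base
#' measure these three numbers determine the posterior-predictive density,
#' so atom parameters never need to be instantiated.
#'
#' @slot count non-negative integer, pixels currently assigned.
#' @slot sumX numeric, sum of assigned intensities.
#' @slot sumX2 numeric, sum of squared assigned intensities.
#' @seealso [atomStats()], [atomAdd()], [logPredictive()]
#' @exportClass AtomStats
setClass("AtomStats",
  representation(count = "integer", sumX = "numeric", sumX2 = "numeric"))

setValidity("AtomStats", function(object) {
  if (length(object@count) != 1L || object@count < 0L)
    return("'count' must be a single non-negative integer")
  if (object@count > 0L) {
    # Cauchy-Schwarz: sum x^2 >= (sum x)^2 / n, up to float slack
    slack <- 1e-9 * max(1, abs(object@sumX2))
    if (object@sumX2 < object@sumX^2 / object@count - slack)
      return("inconsistent statistics: sumX2 < sumX^2/count")
  }
  TRUE
})

#' Pixel adjacency graph of a 2-D image lattice
#'
#' Symmetric 4- or 8-neighborhood of an `height` x `width` pixel grid with
#' uniform edge weights, stored in compressed sparse row form over the
#' column-major linear pixel index (the order R stores a matrix). This is the
#' interaction structure of the Potts MRF: the conditional of a pixel's label
#' depends only on the labels in this neighborhood (its Markov blanket).
#'
#' @slot height,width image dimensions (pixels).
#' @slot connectivity integer, 4 or 8.
#' @slot edgeWeightScheme character, currently `"uniform"` (all weights 1).
#' @slot ptr integer CSR row pointer, 0-based, length `height*width + 1`.
#' @slot idx integer CSR column index (neighbor pixel), 0-based.
#' @slot w numeric edge weights, parallel to `idx`.
#' @seealso [buildNeighborhood()], [neighborsOf()], [agreementSum()]
#' @exportClass NeighborhoodGraph
setClass("NeighborhoodGraph",
  representation(height = "integer", width = "integer",
                 connectivity = "integer", edgeWeightScheme = "character",
                 ptr = "integer", idx = "integer", w = "numeric"))

setValidity("NeighborhoodGraph", function(object) {
  n <- object@height * object@width
  if (object@height < 1L || object@width < 1L)
    return("height and width must be >= 1")
  if (!object@connectivity %in% c(4L, 8L))
    return("connectivity must be 4 or 8")
  if (length(object@ptr) != n + 1L) return("bad CSR pointer length")
  if (length(object@idx) != length(object@w)) return("idx/w length mismatch")
  if (any(object@w <= 0)) return("edge weights must be positive")
  TRUE
})

#' One 2-D grayscale image slice
#'
#' An intensity matrix plus minimal acquisition metadata (pixel spacing and
#' the source file it was read from, if any).
#'
#' @slot intensity numeric matrix of pixel intensities.
#' @slot spacing numeric length-2 pixel spacing (row, col), arbitrary units.
#' @slot source character, originating file path or `NA`.
#' @seealso [imageSlice()], [readImage()]
#' @exportClass ImageSlice
setClass("ImageSlice",
  representation(intensity = "matrix", spacing = "numeric",
                 source = "character"))

setValidity("ImageSlice", function(object) {
  if (!is.numeric(object@intensity) || length(dim(object@intensity)) != 2L)
    return("'intensity' must be a numeric matrix")
  if (length(object@spacing) != 2L || any(object@spacing <= 0))
    return("'spacing' must be two positive numbers")
  TRUE
})

#' Gibbs sampler settings
#'
#' @slot nSweeps total number of Gibbs sweeps.
#' @slot burnIn sweeps discarded before retaining samples (< `nSweeps`).
#' @slot thin retain every `thin`-th post-burn-in sweep.
#' @slot seed integer RNG seed; the whole run is reproducible given it.
#' @slot mode `"single_dp"` (each image its own DP-MRF) or `"joint_hdp"`
#'   (images share global atoms through the franchise).
#' @seealso [samplerConfig()], [runSampler()]
#' @exportClass SamplerConfig
setClass("SamplerConfig",
  representation(nSweeps = "integer", burnIn = "integer", thin = "integer",
                 seed = "integer", mode = "character"))

setValidity("SamplerConfig", function(object) {
  if (object@nSweeps < 1L) return("'nSweeps' must be >= 1")
  if (object@burnIn < 0L || object@burnIn >= object@nSweeps)
    return("'burnIn' must satisfy 0 <= burnIn < nSweeps")
  if (object@thin < 1L) return("'thin' must be >= 1")
  if (!object@mode %in% c("single_dp", "joint_hdp"))
    return("'mode' must be 'single_dp' or 'joint_hdp'")
  TRUE
})

#' Latent state of the Chinese-restaurant-franchise sampler
#'
#' Per image, each pixel sits at one local cluster ("table"); each table
#' serves one global atom ("dish") shared across images. Tables are numbered
#' 1..T within each image and atoms 1..K globally; empty tables and unserved
#' atoms are never represented.
#'
#' @slot tableOf list of integer matrices, per-pixel table index per image.
#' @slot tableAtom list of integer vectors, table -> global atom id per image.
#' @slot sweep integer, number of sweeps this state has undergone.
#' @slot seed integer, RNG seed recorded at initialization.
#' @seealso [initFranchiseState()], [gibbsSweepJoint()]
#' @exportClass FranchiseState
setClass("FranchiseState",
  representation(tableOf = "list", tableAtom = "list", sweep = "integer",
                 seed = "integer"))

setValidity("FranchiseState", function(object) {
  if (length(object@tableOf) != length(object@tableAtom))
    return("one tableAtom vector per image required")
  for (i in seq_along(object@tableOf)) {
    tv <- object@tableOf[[i]]
    ta <- object@tableAtom[[i]]
    if (!all(tv >= 1L & tv <= length(ta)))
      return(sprintf("image %d: table index out of range", i))
    if (!all(seq_along(ta) %in% tv))
      return(sprintf("image %d: empty table present", i))
  }
  atoms <- unlist(object@tableAtom)
  if (length(atoms) && !all(seq_len(max(atoms)) %in% atoms))
    return("atom ids must be dense 1..K with every atom served")
  TRUE
})

#' Result of a segmentation run
#'
#' @slot labels list of integer label matrices, one per image; in joint mode
#'   these are global atom ids consistent across images.
#' @slot atomMeans numeric, posterior mean standardized intensity per label
#'   of the final estimate.
#' @slot mapLabels list of label matrices for the retained sample with the
#'   highest log joint (an alternative "mode" summary).
#' @slot samples retained label samples (list of lists of matrices), or an
#'   empty list if not kept.
#' @slot trace numeric log-joint value at every sweep.
#' @slot config the [SamplerConfig-class] used.
#' @slot hyper the [Hyperparameters-class] used.
#' @seealso [runSampler()], [labelFields()], [scoreRun()]
#' @exportClass SegmentationResult
setClass("SegmentationResult",
  representation(labels = "list", atomMeans = "numeric", mapLabels = "list",
                 samples = "list", trace = "numeric",
                 config = "SamplerConfig", hyper = "Hyperparameters"))

setValidity("SegmentationResult", function(object) {
  if (length(object@trace) != object@config@nSweeps)
    return("trace length must equal nSweeps")
  if (!all(is.finite(object@trace)))
    return("log-joint trace contains non-finite values")
  TRUE
})

#' Specification of a synthetic phantom set
#'
#' Describes a family of CT-like test images: a common set of global
#' intensity classes (each a Gaussian with known mean and shared sd), a
#' per-image subset of those classes, and a spatial layout - either a fixed
#' geometric arrangement of organ-like regions (background, two lung
#' ellipses, a vertebra rectangle, an optional tumor disk) or an irregular
#' Potts-sampled mosaic.
#'
#' @slot nImages,height,width integers.
#' @slot classMeans numeric mean intensity per global class (standardized
#'   units); @slot classSd shared within-class sd.
#' @slot classNames character cosmetic names per class.
#' @slot subsets list of integer vectors: classes present in each image.
#' @slot layout `"geometric"` or `"potts"`.
#' @slot shapes for geometric layout: ordered list of regions, each a list
#'   with `shape` ("ellipse", "rectangle" or "disk"), `class`, `center`
#'   (row, col) and `radii` (half-extents; one number for a disk). Later
#'   shapes overwrite earlier ones; the first class in each subset fills the
#'   background.
#' @slot potts list with `beta` (inverse temperature) and `sweeps` for the
#'   Potts layout.
#' @slot jitter numeric, max uniform per-image shift (pixels) of each shape
#'   center, emulating similar-but-not-identical positioning across patients.
#' @slot seed integer RNG seed.
#' @seealso [phantomSpec()], [defaultLungSpec()], [generatePhantoms()]
#' @exportClass PhantomSpec
setClass("PhantomSpec",
  representation(nImages = "integer", height = "integer", width = "integer",
                 classMeans = "numeric", classSd = "numeric",
                 classNames = "character", subsets = "list",
                 layout = "character", shapes = "list", potts = "list",
                 jitter = "numeric", seed = "integer"))

setValidity("PhantomSpec", function(object) {
  K <- length(object@classMeans)
  if (K < 1L) return("at least one class required")
  if (object@nImages < 1L || object@height < 1L || object@width < 1L)
    return("nImages, height, width must be >= 1")
  if (object@classSd <= 0) return("'classSd' must be > 0")
  if (length(object@classNames) != K)
    return("one class name per class required")
  if (length(object@subsets) != object@nImages)
    return("one class subset per image required")
  for (s in object@subsets)
    if (!all(s %in% seq_len(K))) return("subset refers to unknown class")
  if (!all(seq_len(K) %in% unlist(object@subsets)))
    return("every class must appear in at least one image")
  if (!object@layout %in% c("geometric", "potts"))
    return("'layout' must be 'geometric' or 'potts'")
  if (object@layout == "geometric")
    for (sh in object@shapes) {
      if (!sh$shape %in% c("ellipse", "rectangle", "disk"))
        return("unknown shape type")
      if (any(sh$radii <= 0)) return("degenerate shape: zero radius")
      if (!sh$class %in% seq_len(K)) return("shape class unknown")
    }
  TRUE
})

#' A generated phantom set
#'
#' Synthetic images plus the ground-truth label fields (global class ids)
#' and an echo of the generating [PhantomSpec-class].
#'
#' @slot images list of numeric intensity matrices.
#' @slot truthLabels list of integer label matrices (global class ids).
#' @slot spec the generating spec.
#' @seealso [generatePhantoms()]
#' @exportClass PhantomSet
setClass("PhantomSet",
  representation(images = "list", truthLabels = "list",
                 spec = "PhantomSpec"))

setValidity("PhantomSet", function(object) {
  if (length(object@images) != length(object@truthLabels))
    return("one truth label field per image required")
  for (i in seq_along(object@images)) {
    if (!identical(dim(object@images[[i]]), dim(object@truthLabels[[i]])))
      return(sprintf("image %d: image/truth shape mismatch", i))
    if (!all(object@truthLabels[[i]] %in% object@spec@subsets[[i]]))
      return(sprintf("image %d: truth label outside declared subset", i))
  }
  TRUE
})

#' Correspondence between predicted and ground-truth labels
#'
#' The injective predicted-to-truth label mapping that maximizes total pixel
#' overlap, with the per-truth-object Jaccard index under that mapping
#' (unmatched truth objects score 0) and any predicted labels left unmatched.
#'
#' @slot mapping named integer vector: names are predicted label ids, values
#'   the matched truth label ids.
#' @slot jaccard named numeric vector, one entry per truth object, in [0,1].
#' @slot unmatchedPred integer vector of predicted labels with no match.
#' @seealso [matchLabels()]
#' @exportClass MatchResult
setClass("MatchResult",
  representation(mapping = "integer", jaccard = "numeric",
                 unmatchedPred = "integer"))

setValidity("MatchResult", function(object) {
  if (anyDuplicated(object@mapping)) return("mapping must be injective")
  if (any(object@jaccard < 0 | object@jaccard > 1))
    return("Jaccard values must lie in [0,1]")
  TRUE
})
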