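# Synthetic CT-like phantoms: shared global intensity classes across images,
# per-image class subsets, spatially coherent regions, Gaussian noise, and
# exact ground-truth label fields.

#' Construct a phantom specification
#'
#' See [PhantomSpec-class] for the slot semantics and
#' [defaultLungSpec()] for the canonical lung-like fixture.
#'
#' @param nImages,height,width integers.
#' @param classMeans numeric mean per global class (standardized units).
#' @param classSd positive shared within-class sd.
#' @param classNames optional cosmetic names (default `class1`, ...).
#' @param subsets list of per-image class-id vectors (default: all classes
#'   in every image).
#' @param layout `"geometric"` or `"potts"`.
#' @param shapes ordered region list for the geometric layout (see
#'   [PhantomSpec-class]).
#' @param potts list with `beta` and `sweeps` for the Potts layout.
#' @param jitter max per-image shape-center shift in pixels.
#' @param seed integer RNG seed.
#' @return a validated [PhantomSpec-class].
#' @export
phantomSpec <- function(nImages, height, width, classMeans, classSd,
                        classNames = paste0("class", seq_along(classMeans)),
                        subsets = rep(list(seq_along(classMeans)), nImages),
                        layout = c("geometric", "potts"), shapes = list(),
                        potts = list(beta = 1.2, sweeps = 40),
                        jitter = 0, seed = 1) {
  layout <- match.arg(layout)
  new("PhantomSpec", nImages = as.integer(nImages),
      height = as.integer(height), width = as.integer(width),
      classMeans = as.numeric(classMeans), classSd = as.numeric(classSd),
      classNames = as.character(classNames),
      subsets = lapply(subsets, as.integer), layout = layout,
      shapes = shapes, potts = potts, jitter = as.numeric(jitter),
      seed = as.integer(seed))
}

#' Minimum pairwise class separation in sd units
#'
#' @param spec a [PhantomSpec-class].
#' @return smallest |mean difference| / classSd over class pairs.
#' @export
meanSeparation <- function(spec) {
  if (length(spec@classMeans) < 2L) return(Inf)
  min(dist(spec@classMeans)) / spec@classSd
}

setMethod("show", "PhantomSpec", function(object) {
  cat(sprintf("PhantomSpec: %d image(s) %d x %d, %d global classes (%s), %s layout\n",
              object@nImages, object@height, object@width,
              length(object@classMeans),
              paste(object@classNames, collapse = ", "), object@layout))
  cat(sprintf("  class means: %s; sd %g; min separation %.2f sd\n",
              paste(object@classMeans, collapse = ", "), object@classSd,
              meanSeparation(object)))
})

#' Canonical lung-like phantom specification
#'
#' A 64 x 64, 4-class, CT-slice-like layout: a soft-tissue background, two
#' dark lung ellipses, a bright vertebra rectangle and a tumor disk inside
#' the right lung. Class means (lung -3, background -1, tumor +1,
#' vertebra +3) with sd 0.5 give at least 4 sd separation between any two
#' classes. With two or more images, image 2 lacks the tumor class,
#' exercising partial category sharing across images. Shape centers get a
#' small per-image jitter, mimicking similar-but-not-identical organ
#' positioning across patients.
#'
#' @param nImages number of images.
#' @param seed integer RNG seed.
#' @return a [PhantomSpec-class].
#' @examples
#' defaultLungSpec(4, seed = 1)
#' @export
defaultLungSpec <- function(nImages = 4, seed = 1) {
  nImages <- as.integer(nImages)
  subsets <- rep(list(1:4), nImages)
  if (nImages >= 2L) subsets[[2L]] <- 1:3
  shapes <- list(
    list(shape = "ellipse", class = 2L, center = c(32, 19),
         radii = c(17, 9)),
    list(shape = "ellipse", class = 2L, center = c(32, 46),
         radii = c(17, 9)),
    list(shape = "rectangle", class = 3L, center = c(52, 32),
         radii = c(6, 5)),
    list(shape = "disk", class = 4L, center = c(26, 45), radii = 5))
  phantomSpec(nImages = nImages, height = 64, width = 64,
              classMeans = c(-1, -3, 3, 1), classSd = 0.5,
              classNames = c("background", "lung", "vertebra", "tumor"),
              subsets = subsets, layout = "geometric", shapes = shapes,
              jitter = 2, seed = seed)
}

.rasterizeShape <- function(lab, sh, center) {
  h <- nrow(lab); w <- ncol(lab)
  r <- matrix(seq_len(h), h, w)
  cc <- matrix(rep(seq_len(w), each = h), h, w)
  inside <- switch(sh$shape,
    ellipse = ((r - center[1]) / sh$radii[1])^2 +
              ((cc - center[2]) / sh$radii[2])^2 <= 1,
    disk = (r - center[1])^2 + (cc - center[2])^2 <= sh$radii[1]^2,
    rectangle = abs(r - center[1]) <= sh$radii[1] &
                abs(cc - center[2]) <= sh$radii[length(sh$radii)])
  lab[inside] <- sh$class
  lab
}

# Potts label mosaic by single-site Gibbs at inverse temperature beta over
# the given classes (irregular spatially coherent regions)
.pottsLabels <- function(h, w, classes, beta, sweeps) {
  g <- buildNeighborhood(h, w, 4L)
  lab <- matrix(sample(classes, h * w, replace = TRUE), h, w)
  n <- h * w
  for (s in seq_len(sweeps)) {
    for (j in seq_len(n)) {
      nb <- neighborsOf(g, j)
      counts <- vapply(classes, function(k) sum(lab[nb$idx] == k), 1.0)
      p <- exp(beta * (counts - max(counts)))
      lab[j] <- classes[sample.int(length(classes), 1L, prob = p)]
    }
  }
  lab
}

#' Generate a synthetic phantom set
#'
#' Draws the image set described by a [PhantomSpec-class]: for each image a
#' ground-truth label field is laid out (geometric organ shapes, later
#' shapes overwriting earlier ones, with only the classes in that image's
#' subset drawn; or a Potts mosaic), then pixel intensities are sampled
#' independently as Normal(classMean, classSd^2). Deterministic given
#' `spec@seed`; the global RNG state is saved and restored.
#'
#' @param spec a [PhantomSpec-class].
#' @return a [PhantomSet-class].
#' @examples
#' ph <- generatePhantoms(defaultLungSpec(2, seed = 7))
#' ph
#' @export
generatePhantoms <- function(spec) {
  validObject(spec)
  oldSeed <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(oldSeed)) {
      if (exists(".Random.seed", globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", oldSeed, envir = globalenv())
  })
  set.seed(spec@seed)
  imgs <- vector("list", spec@nImages)
  labs <- vector("list", spec@nImages)
  for (i in seq_len(spec@nImages)) {
    sub <- spec@subsets[[i]]
    if (spec@layout == "geometric") {
      lab <- matrix(sub[1L], spec@height, spec@width)
      for (sh in spec@shapes) {
        jit <- if (spec@jitter > 0)
          round(runif(2, -spec@jitter, spec@jitter)) else c(0, 0)
        if (sh$class %in% sub)
          lab <- .rasterizeShape(lab, sh, sh$center + jit)
      }
    } else {
      lab <- .pottsLabels(spec@height, spec@width, sub,
                          spec@potts$beta, spec@potts$sweeps)
    }
    imgs[[i]] <- array(spec@classMeans[lab] +
                         rnorm(length(lab), 0, spec@classSd), dim(lab))
    labs[[i]] <- lab
  }
  new("PhantomSet", images = imgs, truthLabels = labs, spec = spec)
}

setMethod("show", "PhantomSet", function(object) {
  cat(sprintf("PhantomSet: %d image(s) %d x %d, %d global classes, min separation %.2f sd\n",
              length(object@images), object@spec@height, object@spec@width,
              length(object@spec@classMeans), meanSeparation(object@spec)))
})

#' @rdname PhantomSet-class
#' @param x a `PhantomSet`.
#' @export
setMethod("images", "PhantomSet", function(x) x@images)

#' @rdname PhantomSet-class
#' @export
setMethod("truthLabels", "PhantomSet", function(x) x@truthLabels)

#' @rdname PhantomSet-class
#' @export
setMethod("phantomSpecOf", "PhantomSet", function(x) x@spec)
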