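# Readers and writers: grayscale images (PNG/TIFF/NIfTI), 16-bit label maps
# with JSON palette sidecars, run configuration, and result serialization.

.fileExt <- function(path) {
  p <- tolower(path)
  if (grepl("\\.nii(\\.gz)?$", p)) return("nii")
  sub(".*\\.", "", p)
}

#' Read a 2-D grayscale image
#'
#' Accepts 8/16-bit grayscale PNG and TIFF and single-slice NIfTI (via the
#' RNifti package). Multi-channel color input is rejected unless all
#' channels are identical (in which case the first is used). Intensities are
#' returned on the scale the reader produces (PNG/TIFF map to [0, 1]);
#' downstream standardization is invariant to that affine scale.
#'
#' @param path file path.
#' @return an [ImageSlice-class].
#' @export
readImage <- function(path) {
  if (!file.exists(path)) stop("cannot read image: ", path)
  ext <- .fileExt(path)
  spacing <- c(1, 1)
  if (ext == "png") {
    img <- png::readPNG(path)
  } else if (ext %in% c("tif", "tiff")) {
    img <- tiff::readTIFF(path)
  } else if (ext == "nii") {
    if (!requireNamespace("RNifti", quietly = TRUE))
      stop("reading NIfTI requires the RNifti package")
    nim <- RNifti::readNifti(path)
    d <- dim(nim)
    if (length(d) > 2L && any(d[-(1:2)] > 1L))
      stop("only single-slice NIfTI volumes are supported")
    img <- matrix(as.numeric(nim), d[1], d[2])
    pd <- RNifti::pixdim(nim)
    spacing <- as.numeric(pd[1:2])
  } else stop("unsupported image format: .", ext)
  if (length(dim(img)) == 3L) {
    ch <- dim(img)[3]
    for (k in seq_len(ch)[-1])
      if (!isTRUE(all.equal(img[, , 1], img[, , k])))
        stop("color (multi-channel) input is not supported: ", path)
    img <- img[, , 1]
  }
  imageSlice(img, spacing = spacing, source = path)
}

#' Write / read a label map
#'
#' Label maps are stored as 16-bit grayscale TIFF (lossless for labels up to
#' 65535) together with a JSON sidecar (`<path>.json`) recording the image
#' dimensions and an optional palette mapping label ids to object names.
#' `readLabelmap()` restores the exact integer grid; 8/16-bit PNG label maps
#' are also read.
#'
#' @param path output `.tif` path.
#' @param labels integer label matrix (non-negative, < 65536).
#' @param palette optional named character vector, label id -> object name.
#' @return `writeLabelmap()` invisibly returns `path`; `readLabelmap()`
#'   returns an integer matrix with the palette (if present) in attribute
#'   `"palette"`.
#' @export
writeLabelmap <- function(path, labels, palette = NULL) {
  if (any(labels < 0) || any(labels > 65535))
    stop("label values overflow 16 bits")
  tiff::writeTIFF(labels / 65535, path, bits.per.sample = 16L)
  side <- list(height = nrow(labels), width = ncol(labels),
               maxLabel = max(labels))
  if (!is.null(palette)) side$palette <- as.list(palette)
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname writeLabelmap
#' @export
readLabelmap <- function(path) {
  ext <- .fileExt(path)
  raw <- if (ext == "png") png::readPNG(path) else tiff::readTIFF(path)
  if (length(dim(raw)) == 3L) raw <- raw[, , 1]
  lab <- array(as.integer(round(raw * 65535)), dim(raw))
  sidecar <- paste0(path, ".json")
  if (file.exists(sidecar)) {
    side <- jsonlite::read_json(sidecar)
    if (ext == "png" && !is.null(side$maxLabel) && side$maxLabel <= 255)
      lab <- array(as.integer(round(raw * 255)), dim(raw))
    if (!is.null(side$palette))
      attr(lab, "palette") <- unlist(side$palette)
  } else if (ext == "png" && max(raw) > 0 &&
             all(abs(raw * 255 - round(raw * 255)) < 1e-6)) {
    lab <- array(as.integer(round(raw * 255)), dim(raw))
  }
  lab
}

#' Write a phantom set to disk
#'
#' Images go to 16-bit TIFF (affinely mapped to [0, 1]; the mapping is
#' recorded in the JSON spec echo), truth labels to label maps, and the
#' generating spec to `spec.json`.
#'
#' @param set a [PhantomSet-class].
#' @param dir output directory (created if needed).
#' @return invisibly, the output directory.
#' @export
writePhantomSet <- function(set, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rng <- range(unlist(set@images))
  scale <- if (diff(rng) > 0) diff(rng) else 1
  for (i in seq_along(set@images)) {
    tiff::writeTIFF((set@images[[i]] - rng[1]) / scale,
                    file.path(dir, sprintf("image%02d.tif", i)),
                    bits.per.sample = 16L)
    writeLabelmap(file.path(dir, sprintf("truth%02d.tif", i)),
                  set@truthLabels[[i]],
                  setNames(set@spec@classNames,
                           seq_along(set@spec@classNames)))
  }
  sp <- set@spec
  jsonlite::write_json(list(
    nImages = sp@nImages, height = sp@height, width = sp@width,
    classMeans = sp@classMeans, classSd = sp@classSd,
    classNames = sp@classNames, subsets = sp@subsets, layout = sp@layout,
    jitter = sp@jitter, seed = sp@seed,
    intensityOffset = rng[1], intensityScale = scale),
    file.path(dir, "spec.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Write a segmentation result to disk
#'
#' One 16-bit label map per image plus a JSON sidecar with the atom summary
#' (final label ids and posterior mean intensities), the log-joint trace,
#' and an echo of the configuration and seed.
#'
#' @param result a [SegmentationResult-class].
#' @param dir output directory (created if needed).
#' @return invisibly, the output directory.
#' @export
writeSegmentationResult <- function(result, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (i in seq_along(result@labels))
    writeLabelmap(file.path(dir, sprintf("labels%02d.tif", i)),
                  result@labels[[i]])
  cfg <- result@config
  hp <- result@hyper
  jsonlite::write_json(list(
    atoms = list(id = as.integer(names(result@atomMeans)),
                 meanIntensity = as.numeric(result@atomMeans)),
    trace = result@trace,
    config = list(nSweeps = cfg@nSweeps, burnIn = cfg@burnIn,
                  thin = cfg@thin, seed = cfg@seed, mode = cfg@mode),
    hyper = list(alpha0 = hp@alpha0, gamma = hp@gamma, lam = hp@lam,
                 baseMu0 = hp@baseMu0, baseKappa0 = hp@baseKappa0,
                 baseA0 = hp@baseA0, baseB0 = hp@baseB0)),
    file.path(dir, "run.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a run configuration file
#'
#' Flat JSON mirroring the hyperparameter and sampler settings; every field
#' is validated against its class invariants before any computation. Fields
#' not present fall back to the package defaults.
#'
#' @param path JSON file path.
#' @return list with elements `hyper` ([Hyperparameters-class]), `sampler`
#'   ([SamplerConfig-class]), `connectivity`, `inputs`, `outDir`,
#'   `logLevel`.
#' @export
readRunConfig <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  pick <- function(name, default) if (!is.null(raw[[name]])) raw[[name]]
                                  else default
  hp <- hyperParameters(
    alpha0 = pick("alpha0", 0.01), gamma = pick("gamma", 1),
    lam = pick("lambda", 0.001), baseMu0 = pick("baseMu0", 0),
    baseKappa0 = pick("baseKappa0", 0.1), baseA0 = pick("baseA0", 2),
    baseB0 = pick("baseB0", 1))
  cfg <- samplerConfig(
    nSweeps = pick("nSweeps", 600), burnIn = pick("burnIn", 200),
    thin = pick("thin", 4), seed = pick("seed", 1),
    mode = pick("mode", "joint_hdp"))
  connectivity <- as.integer(pick("connectivity", 4))
  if (!connectivity %in% c(4L, 8L))
    stop("config: connectivity must be 4 or 8")
  list(hyper = hp, sampler = cfg, connectivity = connectivity,
       inputs = pick("inputs", character(0)),
       outDir = pick("outDir", "."), logLevel = pick("logLevel", "INFO"))
}
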