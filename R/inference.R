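# Collapsed Gibbs inference: sampler configuration, state initialization,
# R wrappers over the compiled sweep kernels, and mode-based label extraction.

#' Construct sampler settings
#'
#' Defaults (600 sweeps, 200 burn-in, thinning 4) are sized so that phantom
#' recovery runs in minutes on one CPU while retaining 100 label samples for
#' the mode estimate.
#'
#' @param nSweeps total Gibbs sweeps.
#' @param burnIn sweeps discarded before retention (`< nSweeps`).
#' @param thin keep every `thin`-th post-burn-in sweep.
#' @param seed integer RNG seed.
#' @param mode `"joint_hdp"` or `"single_dp"`.
#' @return a validated [SamplerConfig-class].
#' @export
samplerConfig <- function(nSweeps = 600, burnIn = 200, thin = 4, seed = 1,
                          mode = c("joint_hdp", "single_dp")) {
  mode <- match.arg(mode)
  new("SamplerConfig", nSweeps = as.integer(nSweeps),
      burnIn = as.integer(burnIn), thin = as.integer(thin),
      seed = as.integer(seed), mode = mode)
}

setMethod("show", "SamplerConfig", function(object) {
  cat(sprintf("SamplerConfig: %s, %d sweeps (burn-in %d, thin %d), seed %d\n",
              object@mode, object@nSweeps, object@burnIn, object@thin,
              object@seed))
})

# 1-based retained sweep indices for a config
.retainedSweeps <- function(cfg) {
  s <- seq.int(cfg@burnIn + 1L, cfg@nSweeps)
  s[(s - cfg@burnIn - 1L) %% cfg@thin == 0L]
}

# normalize image input to a plain list of numeric matrices
.asImageList <- function(images) {
  if (is(images, "PhantomSet")) return(images@images)
  if (is(images, "ImageSlice")) return(list(images@intensity))
  if (is.matrix(images)) return(list(images))
  if (is.list(images) && length(images) > 0L)
    return(lapply(images, function(x) {
      if (is(x, "ImageSlice")) x@intensity
      else if (is.matrix(x)) x
      else stop("each image must be a matrix or ImageSlice")
    }))
  stop("empty image list")
}

# deterministic initialization: pool standardized intensities and cut the
# pooled range into equal-width bins; bins become the initial atoms,
# per-image tables per bin. Equal-width (not quantile) bins are essential:
# they separate small high- or low-intensity classes from the dominant
# background regardless of class prevalence.
.initBins <- function(imgs, nBins = 8L) {
  v <- unlist(imgs)
  rng <- range(v)
  if (diff(rng) == 0) {
    bins <- lapply(imgs, function(x) array(1L, dim(x)))
  } else {
    br <- seq(rng[1], rng[2], length.out = nBins + 1L)
    bins <- lapply(imgs, function(x) {
      b <- findInterval(x, br[-c(1L, length(br))], left.open = TRUE) + 1L
      array(as.integer(b), dim(x))
    })
  }
  # dense atom relabeling over the bins actually used
  used <- sort(unique(unlist(bins)))
  lapply(bins, function(b) array(match(b, used), dim(b)))
}

#' Initialize a Chinese-restaurant-franchise state
#'
#' Bins the pooled standardized intensities of the image set into `nBins`
#' quantile bins; each bin becomes an initial global atom and each image gets
#' one table per bin it contains. The Gibbs dynamics (size-proportional
#' seating plus whole-table dish moves) then prune or split this coarse
#' start. A deterministic data-driven start is used because, at small
#' `alpha0`, nucleating a brand-new atom out of a single large cluster is a
#' rare event and a one-cluster start would mix impractically slowly.
#'
#' @param images list of (standardized) image matrices, an [ImageSlice-class]
#'   or a [PhantomSet-class].
#' @param nBins number of initial intensity bins.
#' @param seed integer recorded in the state (the init itself is
#'   deterministic).
#' @return a [FranchiseState-class].
#' @export
initFranchiseState <- function(images, nBins = 8, seed = 0) {
  imgs <- .asImageList(images)
  bins <- .initBins(imgs, as.integer(nBins))
  tableOf <- vector("list", length(imgs))
  tableAtom <- vector("list", length(imgs))
  for (i in seq_along(imgs)) {
    present <- sort(unique(as.vector(bins[[i]])))
    tableOf[[i]] <- array(match(bins[[i]], present), dim(bins[[i]]))
    tableAtom[[i]] <- as.integer(present)
  }
  new("FranchiseState", tableOf = tableOf, tableAtom = tableAtom,
      sweep = 0L, seed = as.integer(seed))
}

setMethod("show", "FranchiseState", function(object) {
  nT <- sum(vapply(object@tableAtom, length, 1L))
  nA <- length(unique(unlist(object@tableAtom)))
  cat(sprintf("FranchiseState: %d images, %d tables, %d global atoms, sweep %d\n",
              length(object@tableOf), nT, nA, object@sweep))
})

# recompute per-atom sufficient statistics from a franchise state (full
# recount; used by validity checks and tests)
.franchiseRecount <- function(state, imgs) {
  atoms <- sort(unique(unlist(state@tableAtom)))
  out <- matrix(0, length(atoms), 3,
                dimnames = list(atoms, c("count", "sumX", "sumX2")))
  for (i in seq_along(imgs)) {
    lab <- state@tableAtom[[i]][state@tableOf[[i]]]
    for (k in seq_along(atoms)) {
      sel <- lab == atoms[k]
      x <- imgs[[i]][sel]
      out[k, ] <- out[k, ] + c(length(x), sum(x), sum(x * x))
    }
  }
  out
}

.checkImagesState <- function(state, imgs) {
  if (length(imgs) != length(state@tableOf))
    stop("state inconsistency: image count does not match state")
  for (i in seq_along(imgs))
    if (!identical(dim(imgs[[i]]), dim(state@tableOf[[i]])))
      stop("state inconsistency: image ", i, " shape mismatch")
  validObject(state)
  n_state <- sum(vapply(state@tableOf, length, 1L))
  n_img <- sum(vapply(imgs, length, 1L))
  if (n_state != n_img)
    stop("state inconsistency: pixel recount mismatch")
  invisible(TRUE)
}

.graphsFor <- function(imgs, connectivity) {
  lapply(imgs, function(x)
    buildNeighborhood(nrow(x), ncol(x), connectivity))
}

.graphArgs <- function(graphs) {
  list(ptr = lapply(graphs, slot, "ptr"),
       idx = lapply(graphs, slot, "idx"),
       w = lapply(graphs, slot, "w"))
}

#' Full conditional distribution of one pixel's assignment
#'
#' Computes the normalized Gibbs conditional for a single pixel with its own
#' contribution removed: each choice is weighted by the product of its
#' CRP/franchise prior weight, the collapsed Student-t predictive of the
#' pixel's intensity under the choice's atom, and the Potts factor
#' `exp(lam * agreement)` over the pixel's neighbors. With `lam = 0` this is
#' exactly the plain collapsed DP (or HDP) mixture conditional.
#'
#' For the single-image model pass the current label matrix as `state`; the
#' return value is a named probability vector over the surviving labels plus
#' `"new"`. For the joint model pass a [FranchiseState-class] and the image
#' list; the return value is a list with the probability vector (existing
#' tables, then a new table per existing atom, then a brand-new atom) and the
#' choice bookkeeping.
#'
#' @param pixel 1-based column-major linear pixel index.
#' @param state label matrix (single mode) or [FranchiseState-class] (joint).
#' @param images a standardized image matrix, or list of matrices in joint
#'   mode.
#' @param graph a [NeighborhoodGraph-class] (single) or list of them (joint).
#' @param hp [Hyperparameters-class].
#' @param imageIndex which image the pixel belongs to (joint mode).
#' @return see Details.
#' @export
conditionalForPixel <- function(pixel, state, images, graph, hp,
                                imageIndex = 1L) {
  if (is(state, "FranchiseState")) {
    imgs <- .asImageList(images)
    .checkImagesState(state, imgs)
    if (is(graph, "NeighborhoodGraph")) graph <- list(graph)
    ga <- .graphArgs(graph)
    out <- cppJointConditional(
      lapply(imgs, as.vector), ga$ptr, ga$idx, ga$w, .hpVector(hp),
      lapply(state@tableOf, as.vector), state@tableAtom,
      as.integer(imageIndex), as.integer(pixel))
    nT <- out$nTables; nK <- out$nAtoms
    names(out$prob) <- c(if (nT) paste0("table", seq_len(nT)),
                         if (nK) paste0("newtable.atom", seq_len(nK)),
                         "new")
    return(out)
  }
  img <- if (is(images, "ImageSlice")) images@intensity else images
  if (!identical(dim(state), dim(img)))
    stop("state inconsistency: labels/image shape mismatch")
  g <- graph
  out <- cppSingleConditional(as.vector(img), g@ptr, g@idx, g@w,
                              .hpVector(hp), as.integer(as.vector(state)),
                              as.integer(pixel))
  p <- out$prob
  names(p) <- c(as.character(out$clusterLabels), "new")
  p
}

#' One or more Gibbs sweeps of the single-image DP-MRF sampler
#'
#' Resamples every pixel's cluster assignment once per sweep, in fixed
#' column-major scan order, from [conditionalForPixel()]; a draw of the
#' "new" choice opens a fresh atom, and emptied atoms are deleted
#' immediately. Uses R's RNG stream, so runs are reproducible after
#' `set.seed()`.
#'
#' @param labels integer label matrix (current state; labels must be dense
#'   1..K).
#' @param image standardized intensity matrix.
#' @param graph matching [NeighborhoodGraph-class].
#' @param hp [Hyperparameters-class].
#' @param nSweeps number of sweeps to run.
#' @return list with the updated `labels` matrix, the per-cluster `atomStats`
#'   matrix (count, sum, sum of squares) and the log-joint `trace`.
#' @export
gibbsSweepSingle <- function(labels, image, graph, hp, nSweeps = 1) {
  if (is(image, "ImageSlice")) image <- image@intensity
  if (!identical(dim(labels), dim(image)))
    stop("labels/image shape mismatch")
  out <- cppSingleRun(as.vector(image), graph@ptr, graph@idx, graph@w,
                      .hpVector(hp), as.integer(as.vector(labels)) - 1L,
                      as.integer(nSweeps), 0L, 1L, FALSE)
  list(labels = array(out$labels, dim(image)), atomStats = out$atomStats,
       trace = out$trace)
}

#' One or more Gibbs sweeps of the joint HDP-MRF franchise sampler
#'
#' Each sweep has two stages per image: (a) every pixel's table assignment is
#' resampled (existing tables by size x predictive x Potts factor; a new
#' table by `alpha0` times the franchise mixture over existing atoms
#' `m_k/(m + gamma)` and a fresh atom `gamma/(m + gamma)`, marginalized in
#' one categorical draw); (b) every table's atom is resampled by
#' `m_k` x the marginal likelihood of the table's data under the atom, times
#' the Potts factor of the table's boundary pixels, with `gamma` x the prior
#' marginal for a fresh atom. Emptied tables and unserved atoms are removed
#' immediately.
#'
#' @param state a [FranchiseState-class].
#' @param images list of standardized intensity matrices.
#' @param graphs list of matching [NeighborhoodGraph-class] objects.
#' @param hp [Hyperparameters-class].
#' @param nSweeps number of sweeps.
#' @return the updated [FranchiseState-class].
#' @export
gibbsSweepJoint <- function(state, images, graphs, hp, nSweeps = 1) {
  imgs <- .asImageList(images)
  .checkImagesState(state, imgs)
  if (is(graphs, "NeighborhoodGraph")) graphs <- list(graphs)
  ga <- .graphArgs(graphs)
  out <- cppJointRun(lapply(imgs, as.vector), ga$ptr, ga$idx, ga$w,
                     .hpVector(hp), lapply(state@tableOf, as.vector),
                     state@tableAtom, as.integer(nSweeps), 0L, 1L, FALSE,
                     FALSE)
  tableOf <- mapply(function(v, img) array(v, dim(img)), out$tableLabels,
                    imgs, SIMPLIFY = FALSE)
  new("FranchiseState", tableOf = tableOf, tableAtom = out$tableAtom,
      sweep = state@sweep + as.integer(nSweeps), seed = state@seed)
}

#' Run the full segmentation sampler
#'
#' End-to-end inference: standardizes the images (pooled across the set in
#' joint mode, per image in single mode), builds the neighborhood graphs,
#' initializes from pooled intensity bins, runs the collapsed Gibbs sampler,
#' and extracts the final label fields as the label-aligned per-pixel
#' majority over the retained samples ([modeEstimate()]). The retained
#' sample with the highest log joint is kept alongside as `mapLabels`.
#'
#' @param images matrix, [ImageSlice-class], [PhantomSet-class], or a list
#'   of matrices/slices.
#' @param hp [Hyperparameters-class].
#' @param cfg [SamplerConfig-class]; `cfg@seed` seeds all randomness.
#' @param connectivity 4 or 8.
#' @param standardize standardize intensities first (disable only if the
#'   input is already standardized).
#' @param nInitBins number of intensity bins for initialization.
#' @param keepSamples keep the retained label samples in the result.
#' @param verbose print sweep progress.
#' @return a [SegmentationResult-class].
#' @examples
#' ph <- generatePhantoms(defaultLungSpec(2, seed = 1))
#' res <- runSampler(ph, hyperParameters(),
#'                   samplerConfig(nSweeps = 60, burnIn = 20, seed = 1))
#' res
#' @export
runSampler <- function(images, hp = hyperParameters(),
                       cfg = samplerConfig(), connectivity = 4,
                       standardize = TRUE, nInitBins = 8,
                       keepSamples = FALSE, verbose = FALSE) {
  imgs <- .asImageList(images)
  for (x in imgs)
    if (!is.matrix(x) || length(dim(x)) != 2L)
      stop("images must be 2-D matrices")
  set.seed(cfg@seed)
  if (standardize) {
    imgs <- if (cfg@mode == "joint_hdp") .standardizePooled(imgs)
            else lapply(imgs, standardizeIntensities)
  }
  graphs <- .graphsFor(imgs, connectivity)
  kept <- .retainedSweeps(cfg)
  if (cfg@mode == "joint_hdp") {
    st0 <- initFranchiseState(imgs, nInitBins, cfg@seed)
    ga <- .graphArgs(graphs)
    out <- cppJointRun(lapply(imgs, as.vector), ga$ptr, ga$idx, ga$w,
                       .hpVector(hp), lapply(st0@tableOf, as.vector),
                       st0@tableAtom, cfg@nSweeps, cfg@burnIn, cfg@thin,
                       TRUE, FALSE)
    if (verbose)
      message(sprintf("joint sampler: %d sweeps, final atoms %d, log-joint %.2f",
                      cfg@nSweeps, nrow(out$atomStats),
                      out$trace[cfg@nSweeps]))
    samples <- .splitSamples(out$samplesAtom, imgs)
    finals <- modeEstimate(samples)
    mapIdx <- which.max(out$trace[kept])
    mapLabels <- samples[[mapIdx]]
    trace <- out$trace
  } else {
    samplesPer <- vector("list", length(imgs))
    finals <- vector("list", length(imgs))
    mapLabels <- vector("list", length(imgs))
    trace <- numeric(cfg@nSweeps)
    for (i in seq_along(imgs)) {
      init <- .initBins(imgs[i], nInitBins)[[1]]
      g <- graphs[[i]]
      out <- cppSingleRun(as.vector(imgs[[i]]), g@ptr, g@idx, g@w,
                          .hpVector(hp), as.vector(init) - 1L, cfg@nSweeps,
                          cfg@burnIn, cfg@thin, TRUE)
      if (verbose)
        message(sprintf("image %d: %d sweeps, final atoms %d, log-joint %.2f",
                        i, cfg@nSweeps, nrow(out$atomStats),
                        out$trace[cfg@nSweeps]))
      si <- lapply(seq_len(nrow(out$samples)), function(r)
        list(array(out$samples[r, ], dim(imgs[[i]]))))
      finals[i] <- modeEstimate(si)
      mapLabels[[i]] <- si[[which.max(out$trace[kept])]][[1]]
      samplesPer[[i]] <- si
      trace <- trace + out$trace
    }
    samples <- if (length(imgs) == 1L) samplesPer[[1]] else
      lapply(seq_along(samplesPer[[1]]), function(r)
        lapply(samplesPer, function(si) si[[r]][[1]]))
  }
  atomMeans <- .posteriorAtomMeans(finals, imgs)
  new("SegmentationResult", labels = finals, atomMeans = atomMeans,
      mapLabels = mapLabels,
      samples = if (keepSamples) samples else list(),
      trace = trace, config = cfg, hyper = hp)
}

# split a retained-sample matrix (rows = samples, columns = concatenated
# pixels) back into per-image label matrices
.splitSamples <- function(m, imgs) {
  sizes <- vapply(imgs, length, 1L)
  ends <- cumsum(sizes)
  starts <- c(1L, head(ends, -1L) + 1L)
  lapply(seq_len(nrow(m)), function(r)
    lapply(seq_along(imgs), function(i)
      array(m[r, starts[i]:ends[i]], dim(imgs[[i]]))))
}

.posteriorAtomMeans <- function(finals, imgs) {
  lab <- unlist(finals)
  val <- unlist(imgs)
  vapply(split(val, lab), mean, 1.0)
}

#' Mode-based label estimate from retained samples
#'
#' Aligns every retained sample's labels to the last sample by
#' maximum-overlap injective matching (labels present in a sample but absent
#' from the reference keep fresh ids), then takes the per-pixel majority
#' label; ties go to the smallest label id. This per-pixel marginal mode is
#' invariant to label permutations across samples and well defined even when
#' no single labeling dominates.
#'
#' @param samples list of retained samples; each sample is a label matrix or
#'   a list of per-image label matrices.
#' @return list of per-image label matrices (in the reference sample's ids).
#' @export
modeEstimate <- function(samples) {
  if (length(samples) == 0L) stop("at least one retained sample required")
  samples <- lapply(samples, function(s) if (is.list(s)) s else list(s))
  nImg <- length(samples[[1]])
  dims <- lapply(samples[[1]], dim)
  ref <- unlist(samples[[length(samples)]])
  refLabs <- unique(ref)
  maxLab <- max(refLabs)
  nPix <- length(ref)
  counts <- matrix(0L, nPix, maxLab)
  seqPix <- seq_len(nPix)
  for (s in samples) {
    v <- unlist(s)
    a <- .alignLabels(v, ref)
    if (max(a) > ncol(counts))
      counts <- cbind(counts,
                      matrix(0L, nPix, max(a) - ncol(counts)))
    ix <- cbind(seqPix, a)
    counts[ix] <- counts[ix] + 1L
  }
  winner <- max.col(counts, ties.method = "first")
  sizes <- vapply(dims, prod, 1.0)
  ends <- cumsum(sizes)
  starts <- c(1, head(ends, -1) + 1)
  lapply(seq_len(nImg), function(i)
    array(as.integer(winner[starts[i]:ends[i]]), dims[[i]]))
}

# relabel v so that its labels match ref's by maximum total overlap;
# unmatched labels of v get fresh ids above max(ref)
.alignLabels <- function(v, ref) {
  lv <- sort(unique(v))
  lr <- sort(unique(ref))
  if (identical(v, ref)) return(v)
  M <- table(factor(v, levels = lv), factor(ref, levels = lr))
  asg <- .maxAssignment(unclass(M))
  map <- integer(length(lv))
  fresh <- max(lr)
  for (k in seq_along(lv)) {
    if (is.na(asg[k])) {
      fresh <- fresh + 1L
      map[k] <- fresh
    } else map[k] <- lr[asg[k]]
  }
  map[match(v, lv)]
}

# exact maximum-weight injective assignment of rows to columns of a
# non-negative matrix; returns per-row column index or NA. Bitmask dynamic
# program over the smaller side (exact up to 12 labels; greedy beyond).
.maxAssignment <- function(M) {
  M <- as.matrix(M)
  nr <- nrow(M); nc <- ncol(M)
  transposed <- FALSE
  if (nc > nr) {
    M <- t(M); transposed <- TRUE
    tmp <- nr; nr <- nc; nc <- tmp
  }
  if (nc > 12L) {
    asg <- .greedyAssignment(M)
  } else {
    nMask <- bitwShiftL(1L, nc)
    masks <- seq_len(nMask) - 1L
    bits <- vapply(seq_len(nc), function(cc) bitwShiftL(1L, cc - 1L), 1L)
    f <- rep(-Inf, nMask); f[1] <- 0
    dec <- matrix(0L, nr, nMask)
    for (r in seq_len(nr)) {
      fn <- f  # default: skip row r (decision code 0)
      dn <- integer(nMask)
      for (cc in seq_len(nc)) {
        has <- bitwAnd(masks, bits[cc]) > 0L
        cand <- f[bitwXor(masks[has], bits[cc]) + 1L] + M[r, cc]
        upd <- which(is.finite(cand) & cand > fn[masks[has] + 1L])
        if (length(upd)) {
          at <- masks[has][upd] + 1L
          fn[at] <- cand[upd]
          dn[at] <- cc
        }
      }
      f <- fn
      dec[r, ] <- dn
    }
    best <- which.max(f) - 1L
    asg <- rep(NA_integer_, nr)
    mask <- best
    for (r in rev(seq_len(nr))) {
      cc <- dec[r, mask + 1L]
      if (cc > 0L) {
        asg[r] <- cc
        mask <- bitwXor(mask, bits[cc])
      }
    }
  }
  if (transposed) {
    out <- rep(NA_integer_, ncol(M))
    out[asg[!is.na(asg)]] <- which(!is.na(asg))
    out
  } else asg
}

.greedyAssignment <- function(M) {
  nr <- nrow(M); nc <- ncol(M)
  asg <- rep(NA_integer_, nr)
  usedC <- logical(nc); usedR <- logical(nr)
  o <- order(-as.vector(M))
  for (k in o) {
    if (M[k] <= 0) break
    r <- (k - 1L) %% nr + 1L
    cc <- (k - 1L) %/% nr + 1L
    if (!usedR[r] && !usedC[cc]) {
      asg[r] <- cc
      usedR[r] <- TRUE
      usedC[cc] <- TRUE
    }
  }
  asg
}

setMethod("show", "SegmentationResult", function(object) {
  K <- length(unique(unlist(object@labels)))
  cat(sprintf("SegmentationResult: %d image(s), %d label(s) in final estimate\n",
              length(object@labels), K))
  cat("  mode:", object@config@mode, " seed:", object@config@seed, "\n")
  cat(sprintf("  final log-joint: %.3f\n",
              object@trace[length(object@trace)]))
})

#' @rdname SegmentationResult-class
#' @param x a `SegmentationResult`.
#' @export
setMethod("labelFields", "SegmentationResult", function(x) x@labels)

#' @rdname SegmentationResult-class
#' @export
setMethod("atomMeans", "SegmentationResult", function(x) x@atomMeans)

#' @rdname SegmentationResult-class
#' @export
setMethod("logJointTrace", "SegmentationResult", function(x) x@trace)

#' @rdname SegmentationResult-class
#' @export
setMethod("retainedSamples", "SegmentationResult", function(x) x@samples)
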