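# Exact posterior by exhaustive enumeration on tiny instances. This is the
# independent reference the Gibbs samplers are validated against: it scores
# every label configuration by (exchangeable partition prior) x (collapsed
# marginal likelihood, evaluated through stats::dt) x (Potts factor) and
# normalizes, touching none of the compiled sampler code.

#' All set partitions of n items
#'
#' Partitions are returned in restricted-growth form: element `i` holds the
#' 1-based block index of item `i`, blocks numbered by first appearance.
#'
#' @param n number of items (kept small; Bell(n) grows fast).
#' @return list of integer vectors.
#' @examples
#' length(setPartitions(4))  # Bell number B4 = 15
#' @export
setPartitions <- function(n) {
  if (n < 1L) stop("'n' must be >= 1")
  res <- vector("list", 0L)
  rec <- function(v, maxv) {
    if (length(v) == n) {
      res[[length(res) + 1L]] <<- v
      return(invisible())
    }
    for (k in seq_len(maxv + 1L)) rec(c(v, k), max(maxv, k))
  }
  rec(integer(0), 0L)
  res
}

# Student-t predictive density via stats::dt (reference path)
.oraclePred <- function(x, vals, hp) {
  n <- length(vals)
  s <- sum(vals)
  k0 <- hp@baseKappa0; mu0 <- hp@baseMu0; a0 <- hp@baseA0; b0 <- hp@baseB0
  kn <- k0 + n
  an <- a0 + n / 2
  mun <- (k0 * mu0 + s) / kn
  bn <- b0
  if (n > 0) {
    xb <- s / n
    bn <- bn + sum((vals - xb)^2) / 2 + k0 * n * (xb - mu0)^2 / (2 * kn)
  }
  sc <- sqrt(bn * (kn + 1) / (an * kn))
  dt((x - mun) / sc, df = 2 * an) / sc
}

# log marginal likelihood of a value set: sequential product of predictives
.oracleLogMarg <- function(vals, hp) {
  out <- 0
  for (i in seq_along(vals))
    out <- out + log(.oraclePred(vals[i], vals[seq_len(i - 1L)], hp))
  out
}

# log CRP partition prior (exchangeable partition probability function)
.logEPPF <- function(sizes, conc) {
  n <- sum(sizes)
  length(sizes) * log(conc) + sum(lgamma(sizes)) -
    sum(log(conc + seq_len(n) - 1))
}

.rgs <- function(v) match(v, unique(v))

# canonical signature strings shared by the oracle and the empirical side
.sigSingle <- function(v) paste(.rgs(v), collapse = ".")
.sigJoint <- function(tablesPerImage, atomsConcat) {
  paste(paste(vapply(tablesPerImage, function(t)
    paste(.rgs(t), collapse = "."), ""), collapse = ";"),
    paste(.rgs(atomsConcat), collapse = "."), sep = "|")
}

#' Exact posterior over label configurations by brute force
#'
#' Enumerates every labeling of a tiny instance and scores it under the
#' DP-MRF (single image) or HDP-MRF franchise (multiple images) model:
#' CRP/franchise partition prior x collapsed Gaussian marginal likelihood x
#' Potts agreement factor, then normalizes. Guarded to at most 6 pixels in
#' total (the number of configurations grows like a product of Bell
#' numbers). Serves as the independent correctness reference for the Gibbs
#' samplers.
#'
#' In single mode the names of the returned vector are canonical partition
#' signatures of the pixels (restricted-growth labels joined by `.`). In
#' joint mode they are `tables|atoms` signatures: per-image table partitions
#' joined by `;`, then the global-atom partition of all pixels in
#' concatenated order.
#'
#' @param images numeric matrix or list of matrices (standardized values).
#' @param hp [Hyperparameters-class]; `hp@lam` supplies the Potts weight.
#' @param mode `"single_dp"` (one image) or `"joint_hdp"`.
#' @param connectivity lattice connectivity for the Potts edges.
#' @return named numeric vector of probabilities summing to 1.
#' @examples
#' hp <- hyperParameters(alpha0 = 1, lam = 0)
#' bruteForcePosterior(matrix(c(-1, 1), 1), hp, mode = "single_dp")
#' @export
bruteForcePosterior <- function(images, hp, mode = c("single_dp",
                                                     "joint_hdp"),
                                connectivity = 4) {
  mode <- match.arg(mode)
  imgs <- .asImageList(images)
  nPix <- vapply(imgs, length, 1L)
  if (sum(nPix) > 6L)
    stop("instance too large for enumeration (> 6 pixels)")
  graphs <- .graphsFor(imgs, connectivity)
  edges <- lapply(graphs, .edgeList)
  lam <- hp@lam
  if (mode == "single_dp") {
    if (length(imgs) != 1L)
      stop("single_dp oracle takes exactly one image")
    x <- as.vector(imgs[[1]])
    ed <- edges[[1]]
    parts <- setPartitions(length(x))
    lp <- vapply(parts, function(p) {
      sizes <- tabulate(p)
      pot <- if (nrow(ed)) sum(ed[, "w"] * (p[ed[, "a"]] == p[ed[, "b"]]))
             else 0
      .logEPPF(sizes, hp@alpha0) +
        sum(vapply(seq_len(max(p)), function(k)
          .oracleLogMarg(x[p == k], hp), 1.0)) + lam * pot
    }, 1.0)
    pr <- exp(lp - max(lp))
    pr <- pr / sum(pr)
    names(pr) <- vapply(parts, .sigSingle, "")
    return(pr)
  }
  # joint franchise mode
  xs <- lapply(imgs, as.vector)
  partsPer <- lapply(nPix, setPartitions)
  combos <- expand.grid(lapply(partsPer, seq_along))
  sigs <- character(0)
  lps <- numeric(0)
  for (r in seq_len(nrow(combos))) {
    tabs <- lapply(seq_along(xs), function(i)
      partsPer[[i]][[combos[r, i]]])
    # tables in canonical order: image by image, block index order
    tableData <- list()
    tableImage <- integer(0)
    for (i in seq_along(xs))
      for (b in seq_len(max(tabs[[i]]))) {
        tableData[[length(tableData) + 1L]] <- xs[[i]][tabs[[i]] == b]
        tableImage <- c(tableImage, i)
      }
    m <- length(tableData)
    lpriorImages <- sum(vapply(seq_along(xs), function(i)
      .logEPPF(tabulate(tabs[[i]]), hp@alpha0), 1.0))
    for (ap in setPartitions(m)) {
      atomSizes <- tabulate(ap)  # tables per atom
      lp <- lpriorImages + .logEPPF(atomSizes, hp@gamma)
      for (k in seq_len(max(ap)))
        lp <- lp + .oracleLogMarg(unlist(tableData[ap == k]), hp)
      # Potts on atom-level agreement within each image
      atomOfPix <- vector("list", length(xs))
      off <- 0L
      for (i in seq_along(xs)) {
        tOff <- sum(tableImage < i)
        atomOfPix[[i]] <- ap[tOff + tabs[[i]]]
      }
      if (lam != 0)
        for (i in seq_along(xs)) {
          ed <- edges[[i]]
          if (nrow(ed))
            lp <- lp + lam * sum(ed[, "w"] *
              (atomOfPix[[i]][ed[, "a"]] == atomOfPix[[i]][ed[, "b"]]))
        }
      sigs <- c(sigs, .sigJoint(tabs, unlist(atomOfPix)))
      lps <- c(lps, lp)
    }
  }
  pr <- exp(lps - max(lps))
  pr <- pr / sum(pr)
  out <- tapply(pr, sigs, sum)
  structure(as.numeric(out), names = names(out))
}

# empirical distribution over canonical signatures from sampler output
.empiricalSingle <- function(samples) {
  sigs <- apply(samples, 1L, .sigSingle)
  tab <- table(sigs) / length(sigs)
  structure(as.numeric(tab), names = names(tab))
}

.empiricalJoint <- function(samplesTable, samplesAtom, nPix) {
  ends <- cumsum(nPix)
  starts <- c(1L, head(ends, -1L) + 1L)
  sigs <- vapply(seq_len(nrow(samplesAtom)), function(r) {
    tabs <- lapply(seq_along(nPix), function(i)
      samplesTable[r, starts[i]:ends[i]])
    .sigJoint(tabs, samplesAtom[r, ])
  }, "")
  tab <- table(sigs) / length(sigs)
  structure(as.numeric(tab), names = names(tab))
}

# total variation distance between two named discrete distributions
.tvDistance <- function(p, q) {
  keys <- union(names(p), names(q))
  pv <- ifelse(keys %in% names(p), p[keys], 0)
  qv <- ifelse(keys %in% names(q), q[keys], 0)
  sum(abs(pv - qv)) / 2
}
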