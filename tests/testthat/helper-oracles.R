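# Independent reference implementations used only by the tests.

# total variation distance between named discrete distributions
tvDist <- function(p, q) {
  keys <- union(names(p), names(q))
  pv <- sapply(keys, function(k) if (k %in% names(p)) p[[k]] else 0)
  qv <- sapply(keys, function(k) if (k %in% names(q)) q[[k]] else 0)
  sum(abs(pv - qv)) / 2
}

# brute-force maximum total overlap over all injective row-to-column
# mappings (exponential; tiny instances only)
bruteBestOverlap <- function(M) {
  nr <- nrow(M); nc <- ncol(M)
  best <- 0
  rec <- function(r, used, acc) {
    if (acc > best) best <<- acc
    if (r > nr) return(invisible())
    rec(r + 1L, used, acc)
    for (cc in seq_len(nc)) if (!used[cc]) {
      used[cc] <- TRUE
      rec(r + 1L, used, acc + M[r, cc])
      used[cc] <- FALSE
    }
  }
  rec(1L, logical(nc), 0)
  best
}

# connected-component count of a binary mask (4-connectivity flood fill)
nComponents <- function(mask) {
  lab <- matrix(0L, nrow(mask), ncol(mask))
  nxt <- 0L
  for (start in which(mask)) {
    if (lab[start] != 0L) next
    nxt <- nxt + 1L
    queue <- start
    lab[start] <- nxt
    h <- nrow(mask)
    n <- length(mask)
    while (length(queue)) {
      j <- queue[1]; queue <- queue[-1]
      r <- (j - 1L) %% h + 1L
      nb <- c(if (r > 1L) j - 1L, if (r < h) j + 1L, j - h, j + h)
      nb <- nb[nb >= 1L & nb <= n]
      nb <- nb[mask[nb] & lab[nb] == 0L]
      lab[nb] <- nxt
      queue <- c(queue, nb)
    }
  }
  nxt
}

# plain collapsed DP conditional for a pixel, composed from the exported
# primitives (used to verify the lambda = 0 reduction)
plainDPConditional <- function(pixel, labels, image, hp) {
  v <- as.vector(image)
  lab <- as.vector(labels)
  x <- v[pixel]
  lab[pixel] <- NA
  labs <- sort(unique(lab[!is.na(lab)]))
  counts <- sapply(labs, function(k) sum(lab == k, na.rm = TRUE))
  w <- crpWeights(counts, hp@alpha0)
  lp <- sapply(seq_along(labs), function(k) {
    xs <- v[!is.na(lab) & lab == labs[k]]
    logPredictive(x, c(length(xs), sum(xs), sum(xs^2)), hp)
  })
  lw <- log(w) + c(lp, logPredictive(x, atomStats(), hp))
  p <- exp(lw - max(lw))
  setNames(p / sum(p), c(as.character(labs), "new"))
}
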