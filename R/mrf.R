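# Pixel lattice neighborhood graph and the Potts interaction term.

#' Build a pixel neighborhood graph
#'
#' Constructs the symmetric 4- or 8-neighborhood of a `height` x `width`
#' lattice with uniform unit edge weights and no wraparound: boundary pixels
#' simply have fewer neighbors. Pixels are addressed by their 1-based
#' column-major linear index, the order in which R stores a matrix.
#'
#' @param height,width image dimensions, at least 1.
#' @param connectivity 4 (rook) or 8 (queen, adds diagonals).
#' @return a [NeighborhoodGraph-class].
#' @examples
#' g <- buildNeighborhood(3, 3, 8)
#' nEdges(g)  # 20 undirected edges
#' @export
buildNeighborhood <- function(height, width, connectivity = 4) {
  height <- as.integer(height); width <- as.integer(width)
  if (is.na(height) || is.na(width) || height < 1L || width < 1L)
    stop("height and width must be integers >= 1")
  connectivity <- as.integer(connectivity)
  if (!connectivity %in% c(4L, 8L))
    stop("unsupported connectivity: ", connectivity, " (use 4 or 8)")
  off <- rbind(c(-1L, 0L), c(1L, 0L), c(0L, -1L), c(0L, 1L))
  if (connectivity == 8L)
    off <- rbind(off, c(-1L, -1L), c(-1L, 1L), c(1L, -1L), c(1L, 1L))
  rows <- rep(seq_len(height), times = width)
  cols <- rep(seq_len(width), each = height)
  from <- integer(0); to <- integer(0)
  for (k in seq_len(nrow(off))) {
    r2 <- rows + off[k, 1]; c2 <- cols + off[k, 2]
    ok <- r2 >= 1L & r2 <= height & c2 >= 1L & c2 <= width
    from <- c(from, which(ok))
    to <- c(to, (c2[ok] - 1L) * height + r2[ok])
  }
  o <- order(from, to)
  from <- from[o]; to <- to[o]
  n <- height * width
  ptr <- c(0L, cumsum(tabulate(from, nbins = n)))
  new("NeighborhoodGraph", height = height, width = width,
      connectivity = connectivity, edgeWeightScheme = "uniform",
      ptr = as.integer(ptr), idx = as.integer(to - 1L),
      w = rep(1, length(to)))
}

#' @rdname NeighborhoodGraph-class
#' @export
setMethod("neighborsOf", "NeighborhoodGraph", function(x, i) {
  n <- x@height * x@width
  if (i < 1L || i > n) stop("pixel index out of bounds")
  sel <- (x@ptr[i] + 1L):(x@ptr[i + 1L])
  if (x@ptr[i] == x@ptr[i + 1L])
    return(list(idx = integer(0), w = numeric(0)))
  list(idx = x@idx[sel] + 1L, w = x@w[sel])
})

#' @rdname NeighborhoodGraph-class
#' @export
setMethod("nEdges", "NeighborhoodGraph", function(x) length(x@idx) %/% 2L)

setMethod("show", "NeighborhoodGraph", function(object) {
  cat(sprintf("NeighborhoodGraph %d x %d, %d-connected, %d undirected edges (%s weights)\n",
              object@height, object@width, object@connectivity,
              nEdges(object), object@edgeWeightScheme))
})

#' Weighted neighbor agreement with a candidate label
#'
#' Sums the edge weights from pixel `i` to those neighbors currently
#' carrying `candidateLabel` -- the Markov-blanket statistic the Potts
#' interaction is built from. The pixel's own current label is irrelevant
#' (the conditional is on all labels but its own).
#'
#' @param i 1-based column-major linear pixel index.
#' @param candidateLabel integer label under consideration.
#' @param labels integer label matrix (or vector) for the image.
#' @param graph a [NeighborhoodGraph-class] matching the image shape.
#' @return non-negative numeric, at most the pixel's total neighbor weight.
#' @examples
#' g <- buildNeighborhood(2, 2)
#' agreementSum(1, 1L, matrix(1L, 2, 2), g)  # both neighbors agree -> 2
#' @export
agreementSum <- function(i, candidateLabel, labels, graph) {
  nb <- neighborsOf(graph, i)
  sum(nb$w[labels[nb$idx] == candidateLabel])
}

#' Log Potts factor for a given agreement
#'
#' The interaction term of the MRF-regularized model multiplies a label
#' choice's conditional weight by `exp(lam * agreement)`: configurations in
#' which neighboring pixels share a label are favored, with `lam = 0`
#' switching smoothing off. (Taken literally, an energy `+lam * agreement`
#' inside `exp(-H)` would penalize agreement; the sign is fixed here so the
#' field smooths, which is the stated purpose of the interaction.)
#'
#' @param agreement non-negative agreement sum from [agreementSum()].
#' @param lam non-negative smoothing weight.
#' @return `lam * agreement`, the log multiplicative boost.
#' @examples
#' mrfLogFactor(4, 0.001)
#' @export
mrfLogFactor <- function(agreement, lam) {
  if (any(lam < 0)) stop("'lam' must be non-negative")
  if (any(agreement < 0)) stop("'agreement' must be non-negative")
  lam * agreement
}

# undirected edge list (a < b) with weights, for the oracle and tests
.edgeList <- function(graph) {
  n <- graph@height * graph@width
  from <- rep.int(seq_len(n), diff(graph@ptr))
  to <- graph@idx + 1L
  keep <- from < to
  cbind(a = from[keep], b = to[keep], w = graph@w[keep])
}
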