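# Jaccard-index scoring with optimal label matching.

#' Jaccard index of two pixel sets
#'
#' `|A intersect B| / |A union B|`: 1 means perfect overlap, 0 no overlap.
#' Sets may be given as logical masks (matrices or vectors) or as integer
#' index vectors.
#'
#' @param A,B pixel sets.
#' @return numeric in [0, 1]; symmetric in its arguments.
#' @examples
#' jaccardIndex(c(1, 2, 3), c(2, 3, 4, 5))  # 2/5
#' @export
jaccardIndex <- function(A, B) {
  if (is.logical(A)) A <- which(A)
  if (is.logical(B)) B <- which(B)
  u <- length(union(A, B))
  if (u == 0L) stop("Jaccard index undefined: both sets are empty")
  length(intersect(A, B)) / u
}

#' Match predicted labels to ground-truth labels
#'
#' Finds the injective predicted-to-truth label correspondence maximizing
#' the total pixel overlap (optimal bipartite assignment on the intersection
#' counts), then reports the Jaccard index of every truth object under that
#' mapping. Truth objects left unmatched (e.g. when the segmentation merged
#' two objects into one label) score 0, so omissions are never silently
#' dropped from a score table.
#'
#' @param pred integer label matrix (predicted segmentation).
#' @param truth integer label matrix (ground truth), same shape.
#' @return a [MatchResult-class].
#' @examples
#' truth <- matrix(c(1, 1, 2, 2), 2)
#' pred <- matrix(c(5, 5, 9, 9), 2)
#' objectJaccard(matchLabels(pred, truth))  # both 1: labels only permuted
#' @export
matchLabels <- function(pred, truth) {
  if (!identical(dim(pred), dim(truth)))
    stop("pred/truth shape mismatch")
  lp <- sort(unique(as.vector(pred)))
  lt <- sort(unique(as.vector(truth)))
  M <- unclass(table(factor(pred, levels = lp),
                     factor(truth, levels = lt)))
  asg <- .maxAssignment(M)
  mapping <- integer(0)
  ji <- setNames(numeric(length(lt)), lt)
  for (k in seq_along(lp)) {
    if (!is.na(asg[k])) {
      t <- lt[asg[k]]
      mapping[as.character(lp[k])] <- t
      ji[as.character(t)] <- jaccardIndex(pred == lp[k], truth == t)
    }
  }
  new("MatchResult", mapping = mapping, jaccard = ji,
      unmatchedPred = lp[is.na(asg)])
}

#' @rdname MatchResult-class
#' @param x a `MatchResult`.
#' @export
setMethod("labelMapping", "MatchResult", function(x) x@mapping)

#' @rdname MatchResult-class
#' @export
setMethod("objectJaccard", "MatchResult", function(x) x@jaccard)

setMethod("show", "MatchResult", function(object) {
  cat("MatchResult:", length(object@mapping), "matched label(s),",
      length(object@unmatchedPred), "unmatched predicted\n")
  print(round(object@jaccard, 4))
})

#' Score a segmentation run against ground truth
#'
#' Matches each image's predicted labels to its ground-truth labels with
#' [matchLabels()] and tabulates the per-truth-object Jaccard indices, one
#' row per (image, object).
#'
#' @param result a [SegmentationResult-class] or list of label matrices.
#' @param truth list of ground-truth label matrices (or a
#'   [PhantomSet-class]).
#' @param objectNames optional character names per truth label id.
#' @return `data.frame` with columns `image`, `object`, `jaccard`.
#' @export
scoreRun <- function(result, truth, objectNames = NULL) {
  pred <- if (is(result, "SegmentationResult")) result@labels else result
  if (is(truth, "PhantomSet")) {
    if (is.null(objectNames)) objectNames <- truth@spec@classNames
    truth <- truth@truthLabels
  }
  if (length(pred) != length(truth))
    stop("image count mismatch between result and truth")
  rows <- do.call(rbind, lapply(seq_along(pred), function(i) {
    ji <- objectJaccard(matchLabels(pred[[i]], truth[[i]]))
    ids <- as.integer(names(ji))
    data.frame(image = i,
               object = if (is.null(objectNames)) as.character(ids)
                        else objectNames[ids],
               jaccard = as.numeric(ji))
  }))
  rownames(rows) <- NULL
  rows
}
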