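#' @include AllClasses.R
NULL

#' Set labels of an object
#' @param x a SetCollection, RegionPartition, IntersectionCountTable,
#'   EulerLayout or UpSetMatrix.
#' @return character vector of set labels in display order.
#' @export
setGeneric("setLabels", function(x) standardGeneric("setLabels"))

#' Number of sets
#' @param x an object with set labels.
#' @return integer scalar.
#' @export
setGeneric("nSets", function(x) standardGeneric("nSets"))

#' Element IDs of a collection
#' @param x a SetCollection.
#' @return sorted character vector of element IDs.
#' @export
setGeneric("elementIds", function(x) standardGeneric("elementIds"))

#' Element-to-membership map
#' @param x a SetCollection.
#' @return named list: element ID -> character vector of set labels.
#' @export
setGeneric("membershipList", function(x) standardGeneric("membershipList"))

#' Inclusive set sizes
#' @param x a SetCollection.
#' @return named integer vector, one size per set.
#' @export
setGeneric("setSizes", function(x) standardGeneric("setSizes"))

#' Region signatures
#' @param x a RegionPartition or UpSetMatrix.
#' @return character vector of canonical signatures.
#' @export
setGeneric("signatures", function(x) standardGeneric("signatures"))

#' Region counts
#' @param x a RegionPartition, IntersectionCountTable or UpSetMatrix.
#' @return named integer vector keyed by canonical signature.
#' @export
setGeneric("regionCounts", function(x) standardGeneric("regionCounts"))

#' Region element lists
#' @param x a RegionPartition.
#' @return named list: signature -> sorted element IDs.
#' @export
setGeneric("regionElements", function(x) standardGeneric("regionElements"))

#' Scene primitives
#' @param x a SceneGraph.
#' @return ordered list of primitive lists.
#' @export
setGeneric("scenePrimitives", function(x) standardGeneric("scenePrimitives"))

#' Scene bounding box
#' @param x a SceneGraph.
#' @return numeric (xmin, ymin, xmax, ymax).
#' @export
setGeneric("sceneBBox", function(x) standardGeneric("sceneBBox"))

## ---- accessors ----

#' @describeIn setLabels set labels of a collection
#' @export
setMethod("setLabels", "SetCollection", function(x) x@setLabels)
#' @describeIn setLabels set labels of a partition
#' @export
setMethod("setLabels", "RegionPartition", function(x) x@setLabels)
#' @describeIn setLabels set labels of a count table
#' @export
setMethod("setLabels", "IntersectionCountTable", function(x) x@setLabels)
#' @describeIn setLabels set labels of an Euler layout
#' @export
setMethod("setLabels", "EulerLayout", function(x) x@setLabels)
#' @describeIn setLabels set labels of an UpSet matrix
#' @export
setMethod("setLabels", "UpSetMatrix", function(x) x@setLabels)

#' @describeIn nSets number of sets
#' @export
setMethod("nSets", "ANY", function(x) length(setLabels(x)))

#' @describeIn elementIds elements of a collection
#' @export
setMethod("elementIds", "SetCollection", function(x) sort(names(x@membership), method = "radix"))

#' @describeIn membershipList the raw map
#' @export
setMethod("membershipList", "SetCollection", function(x) x@membership)

#' @describeIn setSizes inclusive sizes from a collection
#' @export
setMethod("setSizes", "SetCollection", function(x) {
  all <- unlist(x@membership, use.names = FALSE)
  n <- vapply(x@setLabels, function(s) sum(all == s), integer(1))
  names(n) <- x@setLabels
  n
})

#' @describeIn signatures signatures of a partition
#' @export
setMethod("signatures", "RegionPartition", function(x) names(x@counts))
#' @describeIn signatures column signatures of an UpSet matrix
#' @export
setMethod("signatures", "UpSetMatrix", function(x) x@signatures)

#' @describeIn regionCounts counts of a partition
#' @export
setMethod("regionCounts", "RegionPartition", function(x) x@counts)
#' @describeIn regionCounts rows of a count table
#' @export
setMethod("regionCounts", "IntersectionCountTable", function(x) x@counts)
#' @describeIn regionCounts column counts of an UpSet matrix
#' @export
setMethod("regionCounts", "UpSetMatrix", function(x) {
  structure(x@counts, names = x@signatures)
})

#' @describeIn regionElements element lists of a partition
#' @export
setMethod("regionElements", "RegionPartition", function(x) {
  if (x@countsOnly) stop("partition is counts-only; no element lists available")
  x@elements
})

#' @describeIn scenePrimitives primitives in draw order
#' @export
setMethod("scenePrimitives", "SceneGraph", function(x) x@primitives)
#' @describeIn sceneBBox bounding box
#' @export
setMethod("sceneBBox", "SceneGraph", function(x) x@bbox)

## ---- show ----

setMethod("show", "SetCollection", function(object) {
  cat("SetCollection with", length(object@setLabels), "sets and",
      length(object@membership), "elements\n")
  sz <- setSizes(object)
  cat("  sets:", paste0(names(sz), " (", sz, ")", collapse = ", "), "\n")
})

setMethod("show", "RegionPartition", function(object) {
  cat("RegionPartition over", length(object@setLabels), "sets;",
      length(object@counts), "non-empty regions",
      if (object@countsOnly) "(counts only)" else "", "\n")
  k <- utils::head(order(-object@counts), 5)
  for (i in k) cat("  ", names(object@counts)[i], ": ", object@counts[i], "\n", sep = "")
  if (length(object@counts) > 5) cat("  ...\n")
})

setMethod("show", "IntersectionCountTable", function(object) {
  cat("IntersectionCountTable (", object@semantics, ") with ",
      length(object@counts), " rows over ", length(object@setLabels),
      " sets\n", sep = "")
})

setMethod("show", "SceneGraph", function(object) {
  kinds <- table(vapply(object@primitives, `[[`, character(1), "kind"))
  cat("SceneGraph:", length(object@primitives), "primitives (",
      paste0(names(kinds), "=", kinds, collapse = ", "), ")\n")
  cat("  bbox: [", paste(signif(object@bbox, 4), collapse = ", "), "]\n")
})

setMethod("show", "BipartiteGraph", function(object) {
  cat("BipartiteGraph:", length(object@setNodes), "set nodes,",
      length(object@elementNodes), "element nodes,",
      nrow(object@edges), "edges\n")
})

setMethod("show", "EulerLayout", function(object) {
  cat("EulerLayout for", length(object@setLabels), "sets; stress =",
      format(object@stress, digits = 4), "\n")
  for (i in seq_along(object@radii))
    cat(sprintf("  %s: center (%.3f, %.3f), r = %.3f\n", object@setLabels[i],
                object@centers[i, 1], object@centers[i, 2], object@radii[i]))
})

setMethod("show", "VennTemplate", function(object) {
  cat("VennTemplate (", object@mode, ") for ", object@nSets, " sets\n", sep = "")
})

setMethod("show", "UpSetMatrix", function(object) {
  cat("UpSetMatrix:", length(object@signatures), "columns over",
      length(object@setLabels), "sets",
      if (object@keepEmpty) "(empty intersections kept)" else "", "\n")
})

setMethod("show", "FlowerSpec", function(object) {
  cat("FlowerSpec (", object@mode, "): core ", object@coreValue, ", ",
      length(object@petalSets), " petals\n", sep = "")
})

setMethod("show", "OverlapTest", function(object) {
  cat("Hypergeometric overlap test\n")
  cat(sprintf("  |A| = %d, |B| = %d, overlap = %d, universe = %d\n",
              object@sizeA, object@sizeB, object@overlap, object@universe))
  cat(sprintf("  expected overlap = %.3f, P(X >= %d) = %.4g\n",
              object@expectedOverlap, object@overlap, object@pValue))
})
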