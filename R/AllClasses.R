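#' @import methods
NULL

#' SetCollection: ordered named sets with an element-to-membership map
#'
#' The universal in-memory model for every diagram in the package. A
#' collection holds an ordered vector of set labels and, for every element
#' (gene, metabolite, OTU/ASV, ...), the non-empty subset of sets it belongs
#' to. Set order is the order of first appearance in the input and is stable
#' across all downstream views.
#'
#' @slot setLabels character vector of unique set labels, in display order.
#' @slot membership named list; one entry per element, each a character
#'   vector of set labels (a non-empty subset of \code{setLabels}).
#'
#' @seealso [readTwoColumn()], [readElementLists()], [exclusiveRegions()]
#' @export
setClass("SetCollection", representation(
  setLabels = "character",
  membership = "list"
))

setValidity("SetCollection", function(object) {
  msgs <- character()
  if (anyDuplicated(object@setLabels))
    msgs <- c(msgs, "set labels must be unique")
  if (length(object@membership)) {
    if (is.null(names(object@membership)) || anyDuplicated(names(object@membership)))
      msgs <- c(msgs, "membership must be uniquely named by element ID")
    ok <- vapply(object@membership, function(m) {
      length(m) >= 1L && !anyDuplicated(m) && all(m %in% object@setLabels)
    }, logical(1))
    if (!all(ok))
      msgs <- c(msgs, "every membership must be a non-empty, duplicate-free subset of the set labels")
  }
  if (length(msgs)) msgs else TRUE
})

#' RegionPartition: the exclusive (disjoint) regions of a set collection
#'
#' Holds the cells of the Venn diagram: every element belongs to exactly one
#' region, the one labelled by its full membership signature. Partitions may
#' also be counts-only, when built from an intersection count table rather
#' than from element-level data.
#'
#' @slot setLabels ordered set labels.
#' @slot elements named list mapping canonical signature to a sorted
#'   character vector of element IDs (empty when counts-only).
#' @slot counts named integer vector of region counts, parallel keys.
#' @slot countsOnly logical flag.
#'
#' @seealso [exclusiveRegions()], [partitionFromCounts()]
#' @export
setClass("RegionPartition", representation(
  setLabels = "character",
  elements = "list",
  counts = "integer",
  countsOnly = "logical"
))

setValidity("RegionPartition", function(object) {
  msgs <- character()
  if (any(object@counts < 0)) msgs <- c(msgs, "region counts must be non-negative")
  if (anyDuplicated(names(object@counts))) msgs <- c(msgs, "signatures must be unique")
  if (length(names(object@counts))) {
    subsets <- strsplit(names(object@counts), "&", fixed = TRUE)
    if (!all(vapply(subsets, function(s) length(s) > 0 && all(s %in% object@setLabels), logical(1))))
      msgs <- c(msgs, "every signature must be a non-empty subset of the set labels")
  }
  if (length(object@counts) > 2^length(object@setLabels) - 1)
    msgs <- c(msgs, "more signatures than possible regions")
  if (!object@countsOnly) {
    if (!identical(sort(names(object@elements)), sort(names(object@counts))))
      msgs <- c(msgs, "element lists and counts must share signatures")
    else if (!all(lengths(object@elements)[names(object@counts)] == object@counts))
      msgs <- c(msgs, "counts must equal element list lengths")
    allel <- unlist(object@elements, use.names = FALSE)
    if (anyDuplicated(allel))
      msgs <- c(msgs, "regions must be pairwise disjoint")
  }
  if (length(msgs)) msgs else TRUE
})

#' IntersectionCountTable: signature -> count rows
#'
#' Parsed from the "&"-notation two-column count matrix, or produced by the
#' Venn calculator. Semantics are either \code{"exclusive"} (counts are
#' disjoint Venn-region sizes) or \code{"inclusive"} (counts are full
#' intersection cardinalities, so \code{count(S) >= count(T)} whenever
#' \code{S} is a subset of \code{T}).
#'
#' @slot setLabels ordered set labels (union of names in any signature).
#' @slot counts named integer vector keyed by canonical signature.
#' @slot semantics "exclusive" or "inclusive".
#'
#' @seealso [readIntersectionCounts()], [partitionFromCounts()]
#' @export
setClass("IntersectionCountTable", representation(
  setLabels = "character",
  counts = "integer",
  semantics = "character"
))

setValidity("IntersectionCountTable", function(object) {
  msgs <- character()
  if (!object@semantics %in% c("exclusive", "inclusive"))
    msgs <- c(msgs, "semantics must be 'exclusive' or 'inclusive'")
  if (any(object@counts < 0)) msgs <- c(msgs, "counts must be non-negative")
  if (anyDuplicated(names(object@counts)))
    msgs <- c(msgs, "signatures must be unique after canonicalization")
  if (length(msgs)) msgs else TRUE
})

#' SceneGraph: ordered renderer-agnostic drawing primitives
#'
#' Every diagram emits one scene: a flat, ordered list of primitives
#' (circle, ellipse, polygon, line, rect, text) in abstract plot units with
#' a finite bounding box. [renderSVG()] maps a scene to an SVG 1.1
#' document.
#'
#' @slot primitives list of primitive lists; each has a \code{kind} field
#'   plus kind-specific geometry and style fields.
#' @slot bbox numeric (xmin, ymin, xmax, ymax) in plot units.
#' @slot metadata named list (seed, semantics flags, ...) embedded as a
#'   comment in exports.
#' @export
setClass("SceneGraph", representation(
  primitives = "list",
  bbox = "numeric",
  metadata = "list"
))

setValidity("SceneGraph", function(object) {
  msgs <- character()
  if (length(object@bbox) != 4 || any(!is.finite(object@bbox)))
    msgs <- c(msgs, "bbox must be 4 finite numbers (xmin, ymin, xmax, ymax)")
  else if (object@bbox[3] < object@bbox[1] || object@bbox[4] < object@bbox[2])
    msgs <- c(msgs, "bbox must be ordered (xmin <= xmax, ymin <= ymax)")
  if (length(msgs)) msgs else TRUE
})

#' BipartiteGraph: set nodes, element nodes and membership edges
#'
#' The Venn-network model: each set is a parent node and each element is
#' connected to the sets it belongs to. Element degree therefore encodes
#' membership multiplicity (degree n = in all sets, degree 1 = set-specific).
#'
#' @slot setNodes set labels.
#' @slot setColors one fill color per set node.
#' @slot elementNodes element IDs (each of degree >= 1).
#' @slot edges data.frame with columns \code{element}, \code{set}.
#' @export
setClass("BipartiteGraph", representation(
  setNodes = "character",
  setColors = "character",
  elementNodes = "character",
  edges = "data.frame"
))

setValidity("BipartiteGraph", function(object) {
  msgs <- character()
  if (length(object@setColors) != length(object@setNodes))
    msgs <- c(msgs, "one color per set node required")
  if (!all(c("element", "set") %in% names(object@edges)))
    msgs <- c(msgs, "edges must have 'element' and 'set' columns")
  else {
    if (!all(object@edges$set %in% object@setNodes))
      msgs <- c(msgs, "edge set labels must be set nodes")
    if (!all(object@elementNodes %in% object@edges$element))
      msgs <- c(msgs, "every element node must have degree >= 1")
  }
  if (length(msgs)) msgs else TRUE
})

#' EulerLayout: circles realizing an area-proportional Euler diagram
#'
#' @slot setLabels set labels (2 or 3).
#' @slot centers numeric matrix (n x 2) of circle centers, plot units.
#' @slot radii circle radii; radius^2 is proportional to set size.
#' @slot targetAreas named numeric, region counts scaled to drawn area.
#' @slot achievedAreas named numeric, sampled region areas of the layout.
#' @slot stress sum over signatures of (achieved - target)^2.
#' @slot stressTrace best-so-far objective value per optimizer iteration
#'   (non-increasing).
#' @export
setClass("EulerLayout", representation(
  setLabels = "character",
  centers = "matrix",
  radii = "numeric",
  targetAreas = "numeric",
  achievedAreas = "numeric",
  stress = "numeric",
  stressTrace = "numeric"
))

setValidity("EulerLayout", function(object) {
  msgs <- character()
  if (any(object@radii <= 0)) msgs <- c(msgs, "radii must be positive")
  if (nrow(object@centers) != length(object@radii))
    msgs <- c(msgs, "one center per radius required")
  if (any(!is.finite(object@centers))) msgs <- c(msgs, "centers must be finite")
  if (any(object@achievedAreas < 0)) msgs <- c(msgs, "achieved areas must be >= 0")
  if (length(object@stress) != 1 || object@stress < 0)
    msgs <- c(msgs, "stress must be a non-negative scalar")
  if (length(msgs)) msgs else TRUE
})

#' VennTemplate: fixed shapes realizing all 2^n - 1 regions
#'
#' A template is one shape per set (circles, ellipses, half-planes,
#' triangles or serpentine curves) with a total membership test over the
#' canvas; classic and Edwards constructions for 2-6 sets are provided.
#'
#' @slot nSets number of sets (2-6).
#' @slot shapes list of shape specifications (see [shapeContains()]).
#' @slot canvas numeric (xmin, ymin, xmax, ymax).
#' @slot mode "classic" or "edwards".
#' @export
setClass("VennTemplate", representation(
  nSets = "integer",
  shapes = "list",
  canvas = "numeric",
  mode = "character"
))

setValidity("VennTemplate", function(object) {
  msgs <- character()
  if (object@nSets < 2L || object@nSets > 6L) msgs <- c(msgs, "templates cover 2-6 sets")
  if (length(object@shapes) != object@nSets) msgs <- c(msgs, "one shape per set required")
  if (length(object@canvas) != 4) msgs <- c(msgs, "canvas must be (xmin, ymin, xmax, ymax)")
  if (length(msgs)) msgs else TRUE
})

#' UpSetMatrix: ordered exclusive-intersection columns plus set totals
#'
#' @slot setLabels set labels, matrix row order.
#' @slot setTotals named numeric of inclusive set sizes.
#' @slot signatures canonical signature per column, in display order.
#' @slot counts exclusive count per column.
#' @slot keepEmpty whether zero-count signatures are kept.
#' @export
setClass("UpSetMatrix", representation(
  setLabels = "character",
  setTotals = "numeric",
  signatures = "character",
  counts = "integer",
  keepEmpty = "logical"
))

setValidity("UpSetMatrix", function(object) {
  msgs <- character()
  if (length(object@signatures) != length(object@counts))
    msgs <- c(msgs, "one count per column required")
  if (!object@keepEmpty && any(object@counts == 0))
    msgs <- c(msgs, "zero-count columns present despite keepEmpty = FALSE")
  if (anyDuplicated(object@signatures)) msgs <- c(msgs, "duplicate columns")
  if (length(msgs)) msgs else TRUE
})

#' FlowerSpec: core value plus one petal value per set
#'
#' @slot coreValue count of elements present in all sets.
#' @slot petalSets set label per petal, in set order.
#' @slot petalValues per-set value: unique count (mode "unique") or set size
#'   minus core (mode "residual").
#' @slot mode "unique" or "residual".
#' @export
setClass("FlowerSpec", representation(
  coreValue = "integer",
  petalSets = "character",
  petalValues = "integer",
  mode = "character"
))

setValidity("FlowerSpec", function(object) {
  msgs <- character()
  if (length(object@petalSets) != length(object@petalValues))
    msgs <- c(msgs, "one value per petal required")
  if (any(object@petalValues < 0) || object@coreValue < 0)
    msgs <- c(msgs, "values must be non-negative")
  if (!object@mode %in% c("unique", "residual"))
    msgs <- c(msgs, "mode must be 'unique' or 'residual'")
  if (length(msgs)) msgs else TRUE
})

#' OverlapTest: hypergeometric significance of a pairwise overlap
#'
#' @slot sizeA,sizeB,overlap,universe the observed counts.
#' @slot pValue upper-tail probability P(X >= overlap).
#' @slot expectedOverlap sizeA * sizeB / universe.
#' @slot method description of the statistic used.
#' @export
setClass("OverlapTest", representation(
  sizeA = "integer", sizeB = "integer", overlap = "integer", universe = "integer",
  pValue = "numeric", expectedOverlap = "numeric", method = "character"
))

setValidity("OverlapTest", function(object) {
  msgs <- character()
  if (object@overlap > min(object@sizeA, object@sizeB))
    msgs <- c(msgs, "overlap cannot exceed the smaller set")
  if (max(object@sizeA, object@sizeB) > object@universe)
    msgs <- c(msgs, "set sizes cannot exceed the universe")
  if (object@pValue < 0 || object@pValue > 1) msgs <- c(msgs, "p-value out of [0, 1]")
  if (length(msgs)) msgs else TRUE
})
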