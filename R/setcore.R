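#' @include AllClasses.R signatures.R
NULL

#' Build a SetCollection from a membership map
#'
#' @param membership named list: element ID -> character vector of set
#'   labels. Duplicate labels within an element are collapsed.
#' @param setLabels optional explicit set order; defaults to order of first
#'   appearance across elements.
#' @return a [SetCollection-class] object.
#' @examples
#' SetCollection(list(g1 = c("A", "B"), g2 = "A"))
#' @export
SetCollection <- function(membership, setLabels = NULL) {
  membership <- lapply(membership, function(m) unique(as.character(m)))
  if (is.null(setLabels)) {
    setLabels <- unique(unlist(membership, use.names = FALSE))
  }
  setLabels <- as.character(setLabels)
  # store memberships in set-label order so equal collections are identical
  membership <- lapply(membership, function(m) m[order(match(m, setLabels))])
  new("SetCollection", setLabels = setLabels, membership = membership)
}

#' Compute the exclusive-region partition of a collection
#'
#' Assigns every element to exactly one region: the one labelled by the
#' element's full membership signature. Regions with zero elements are
#' omitted here; [vennCalculator()] enumerates them.
#'
#' @param collection a [SetCollection-class].
#' @return a [RegionPartition-class] with element lists.
#' @examples
#' x <- SetCollection(list(x = "A", y = c("A", "B")))
#' regionCounts(exclusiveRegions(x))
#' @export
exclusiveRegions <- function(collection) {
  stopifnot(is(collection, "SetCollection"))
  order <- collection@setLabels
  memb <- collection@membership
  if (length(memb) == 0L) {
    return(new("RegionPartition", setLabels = order, elements = list(),
               counts = integer(), countsOnly = FALSE))
  }
  sigs <- vapply(memb, function(m) canonicalSignature(m, order), character(1))
  elements <- split(names(memb), sigs)
  elements <- lapply(elements, sort, method = "radix")
  # order regions by degree then set order
  elements <- elements[signatureOrder(names(elements), order)]
  counts <- vapply(elements, length, integer(1))
  new("RegionPartition", setLabels = order, elements = elements,
      counts = counts, countsOnly = FALSE)
}

#' The Venn calculator: all intersection counts and element lists
#'
#' Enumerates every one of the 2^n - 1 signatures (zeros included, up to the
#' enumeration cap) and reports both semantics: the exclusive count (the
#' disjoint Venn region) and the inclusive count (the full intersection,
#' i.e. the sum of exclusive counts over supersets).
#'
#' @param collection a [SetCollection-class].
#' @param maxEnumerate enumerate zero-count signatures only up to this many
#'   sets (default 12; 2^n growth); beyond it only non-empty signatures are
#'   listed.
#' @return data.frame with columns \code{signature}, \code{degree},
#'   \code{exclusive}, \code{inclusive} and a list column \code{elements}
#'   holding the exclusive region members.
#' @examples
#' x <- SetCollection(list(x = "A", y = c("A", "B")))
#' vennCalculator(x)
#' @export
vennCalculator <- function(collection, maxEnumerate = 12L) {
  stopifnot(is(collection, "SetCollection"))
  if (length(collection@setLabels) < 1L) stop("collection has no sets")
  part <- exclusiveRegions(collection)
  n <- length(collection@setLabels)
  sigs <- if (n <= maxEnumerate) allSignatures(collection@setLabels) else names(part@counts)
  exc <- structure(integer(length(sigs)), names = sigs)
  exc[names(part@counts)] <- part@counts
  inc <- vapply(sigs, function(s) inclusiveSize(part, parseSignature(s)), integer(1))
  elements <- vector("list", length(sigs))
  names(elements) <- sigs
  elements[names(part@elements)] <- part@elements
  elements[vapply(elements, is.null, logical(1))] <- list(character())
  data.frame(signature = sigs, degree = signatureDegree(sigs),
             exclusive = unname(exc), inclusive = unname(inc),
             elements = I(unname(elements)),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Inclusive intersection size from a partition
#'
#' The inclusive size of a subset S of sets is the cardinality of the full
#' intersection of those sets: the sum of exclusive region counts over all
#' signatures that contain S.
#'
#' @param partition a [RegionPartition-class].
#' @param subset character vector of set labels (non-empty).
#' @return integer count.
#' @export
inclusiveSize <- function(partition, subset) {
  stopifnot(is(partition, "RegionPartition"))
  subset <- unique(trimws(subset))
  if (!length(subset)) stop("subset must be non-empty")
  if (!all(subset %in% partition@setLabels))
    stop("unknown set name(s): ",
         paste(setdiff(subset, partition@setLabels), collapse = ", "))
  sigSets <- strsplit(names(partition@counts), "&", fixed = TRUE)
  keep <- vapply(sigSets, function(s) all(subset %in% s), logical(1))
  sum(partition@counts[keep])
}

#' Build an IntersectionCountTable directly
#'
#' @param counts named numeric/integer vector; names are "&" signatures in
#'   any member order.
#' @param semantics "exclusive" (default; counts are disjoint region sizes)
#'   or "inclusive" (counts are full intersection cardinalities).
#' @param setLabels optional set order; defaults to first appearance in the
#'   signature names.
#' @return an [IntersectionCountTable-class].
#' @export
IntersectionCountTable <- function(counts, semantics = c("exclusive", "inclusive"),
                                   setLabels = NULL) {
  semantics <- match.arg(semantics)
  parts <- lapply(names(counts), parseSignature)
  if (is.null(setLabels)) setLabels <- unique(unlist(parts))
  sigs <- vapply(parts, function(p) canonicalSignature(p, setLabels), character(1))
  if (anyDuplicated(sigs))
    stop("duplicate signature after canonicalization: ",
         paste(unique(sigs[duplicated(sigs)]), collapse = ", "))
  cnt <- as.integer(counts)
  names(cnt) <- sigs
  new("IntersectionCountTable", setLabels = setLabels, counts = cnt,
      semantics = semantics)
}

#' Convert an intersection count table to a counts-only partition
#'
#' Exclusive tables are copied. Inclusive tables are inverted by
#' inclusion-exclusion over the subset lattice (Moebius inversion):
#' \code{exclusive(S) = sum over supersets T of S of (-1)^(|T|-|S|) *
#' inclusive(T)}, with missing inclusive rows treated as zero. Every
#' recovered exclusive count must be non-negative, otherwise the table is
#' inconsistent and an error names the offending signature.
#'
#' @param table an [IntersectionCountTable-class].
#' @param keepZero keep zero-count regions in the result (default FALSE).
#' @return a counts-only [RegionPartition-class].
#' @examples
#' tab <- IntersectionCountTable(c("A" = 3, "B" = 2, "A&B" = 1),
#'                               semantics = "inclusive")
#' regionCounts(partitionFromCounts(tab))  # A: 2, B: 1, A&B: 1
#' @export
partitionFromCounts <- function(table, keepZero = FALSE) {
  stopifnot(is(table, "IntersectionCountTable"))
  order <- table@setLabels
  n <- length(order)
  if (table@semantics == "exclusive") {
    counts <- table@counts
  } else {
    if (n > 20L) stop("inclusive inversion capped at 20 sets")
    sigs <- allSignatures(order)
    inc <- structure(numeric(length(sigs)), names = sigs)
    inc[names(table@counts)] <- table@counts
    masks <- vapply(strsplit(sigs, "&", fixed = TRUE),
                    function(s) sum(2^(match(s, order) - 1L)), numeric(1))
    deg <- signatureDegree(sigs)
    counts <- structure(integer(length(sigs)), names = sigs)
    for (i in seq_along(sigs)) {
      sup <- bitwAnd(as.integer(masks), as.integer(masks[i])) == as.integer(masks[i])
      val <- sum(inc[sup] * (-1)^(deg[sup] - deg[i]))
      if (val < 0)
        stop("inconsistent inclusive table: recovered exclusive count of '",
             sigs[i], "' is ", val)
      counts[i] <- as.integer(round(val))
    }
  }
  if (!keepZero) counts <- counts[counts > 0]
  new("RegionPartition", setLabels = order,
      elements = list(), counts = counts, countsOnly = TRUE)
}

#' Flower decomposition: core, unique and residual counts
#'
#' For each set: the unique count is the exclusive count of the singleton
#' region (elements in that set and no other); the residual count is the set
#' size minus the core, where the core is the number of elements common to
#' all sets.
#'
#' @param collection a [SetCollection-class].
#' @return list with \code{core} (integer), \code{unique} and
#'   \code{residual} (named integer vectors, one entry per set).
#' @export
flowerDecomposition <- function(collection) {
  stopifnot(is(collection, "SetCollection"))
  order <- collection@setLabels
  part <- exclusiveRegions(collection)
  core <- inclusiveSize(part, order)
  uniq <- vapply(order, function(s) {
    v <- part@counts[s]
    if (is.na(v)) 0L else as.integer(v)
  }, integer(1))
  names(uniq) <- order
  residual <- setSizes(collection) - core
  list(core = as.integer(core), unique = uniq, residual = residual)
}
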