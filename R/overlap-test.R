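#' @include AllClasses.R
NULL

#' Hypergeometric significance of a pairwise set overlap
#'
#' One-sided enrichment test (equivalent to Fisher's exact upper tail):
#' with X ~ Hypergeometric(universe, sizeA, sizeB), the p-value is
#' P(X >= overlap), computed via \code{phyper} in log-stable form. The
#' universe must be supplied explicitly: inferring it from the union of the
#' two sets silently inflates significance.
#'
#' @param sizeA,sizeB the two set sizes.
#' @param overlap observed intersection size.
#' @param universe total number of elements the sets are drawn from.
#' @return an [OverlapTest-class] with the p-value and the expected overlap
#'   \code{sizeA * sizeB / universe}.
#' @examples
#' overlapSignificance(5, 5, 5, 10)  # p = 1 / choose(10, 5)
#' @export
overlapSignificance <- function(sizeA, sizeB, overlap, universe) {
  sizeA <- as.integer(sizeA); sizeB <- as.integer(sizeB)
  overlap <- as.integer(overlap); universe <- as.integer(universe)
  if (any(c(sizeA, sizeB, overlap, universe) < 0L))
    stop("counts must be non-negative")
  if (max(sizeA, sizeB) > universe)
    stop("set sizes cannot exceed the universe")
  if (overlap > min(sizeA, sizeB))
    stop("overlap cannot exceed the smaller set")
  if (overlap < max(0L, sizeA + sizeB - universe))
    stop("overlap below the minimum forced by the universe size")
  p <- stats::phyper(overlap - 1L, sizeA, universe - sizeA, sizeB,
                     lower.tail = FALSE)
  new("OverlapTest", sizeA = sizeA, sizeB = sizeB, overlap = overlap,
      universe = universe, pValue = min(max(p, 0), 1),
      expectedOverlap = sizeA * as.numeric(sizeB) / universe,
      method = "hypergeometric upper tail (one-sided enrichment)")
}
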