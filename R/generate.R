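#' @include setcore.R
NULL

#' Generate a synthetic set collection
#'
#' Emulates the membership structure of typical multi-condition comparisons:
#' a fraction of elements shared by all sets (the core), a fraction unique
#' to single sets (spread round-robin), and the remainder assigned to
#' uniform random non-empty subsets. Deterministic for a fixed seed.
#'
#' @param nSets number of sets (>= 1).
#' @param nElements number of elements.
#' @param coreFraction expected fraction of elements in every set.
#' @param uniqueFraction expected fraction of elements in exactly one set.
#' @param seed integer seed.
#' @return a [SetCollection-class].
#' @examples
#' generateCollection(3, 50, coreFraction = 0.2, uniqueFraction = 0.3, seed = 1)
#' @export
generateCollection <- function(nSets, nElements, coreFraction = 0.2,
                               uniqueFraction = 0.2, seed = 1L) {
  if (nSets < 1L) stop("nSets must be >= 1")
  if (coreFraction < 0 || uniqueFraction < 0 || coreFraction + uniqueFraction > 1)
    stop("fractions must be in [0, 1] and sum to at most 1")
  labels <- paste0("S", seq_len(nSets))
  ids <- sprintf("e%0*d", nchar(nElements), seq_len(nElements))
  set.seed(seed)
  u <- stats::runif(nElements)
  membership <- vector("list", nElements)
  names(membership) <- ids
  kUnique <- 0L
  for (i in seq_len(nElements)) {
    if (u[i] < coreFraction) {
      membership[[i]] <- labels
    } else if (u[i] < coreFraction + uniqueFraction) {
      kUnique <- kUnique + 1L
      membership[[i]] <- labels[((kUnique - 1L) %% nSets) + 1L]
    } else {
      repeat {
        pick <- labels[stats::runif(nSets) < 0.5]
        if (length(pick)) break
      }
      membership[[i]] <- pick
    }
  }
  SetCollection(membership, setLabels = labels)
}
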