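#' @include AllClasses.R
NULL

#' Canonical "&"-signature of a subset of sets
#'
#' Region signatures use the "&" notation ("A&B" = the region of elements in
#' A and B). The canonical form sorts names by their position in the
#' collection's set order and joins them with "&" (no surrounding spaces);
#' input order is irrelevant.
#'
#' @param subset character vector of set labels (non-empty, no duplicates
#'   after trimming).
#' @param order the full ordered set labels defining positions.
#' @return length-1 character signature.
#' @examples
#' canonicalSignature(c("B", "A"), c("A", "B", "C"))  # "A&B"
#' @export
canonicalSignature <- function(subset, order) {
  subset <- unique(trimws(subset))
  if (length(subset) == 0L) stop("signature subset must be non-empty")
  idx <- match(subset, order)
  if (anyNA(idx))
    stop("unknown set name(s) in signature: ",
         paste(subset[is.na(idx)], collapse = ", "))
  paste(order[sort(idx)], collapse = "&")
}

#' Split a signature back into set labels
#'
#' @param signature a "&"-joined signature (surrounding spaces tolerated).
#' @return character vector of set labels.
#' @export
parseSignature <- function(signature) {
  trimws(strsplit(signature, "&", fixed = TRUE)[[1]])
}

# All 2^n - 1 canonical signatures over `order`, by degree then set order.
allSignatures <- function(order) {
  n <- length(order)
  out <- character(2^n - 1L)
  k <- 0L
  for (deg in seq_len(n)) {
    combs <- utils::combn(n, deg)
    for (j in seq_len(ncol(combs))) {
      k <- k + 1L
      out[k] <- paste(order[combs[, j]], collapse = "&")
    }
  }
  out
}

# degree (number of member sets) of each signature
signatureDegree <- function(signature) {
  lengths(strsplit(signature, "&", fixed = TRUE))
}

# order signatures by degree, then by member positions in `order`
# (lexicographic); matches allSignatures() enumeration without the 2^n cost
signatureOrder <- function(signature, order) {
  if (!length(signature)) return(integer(0))
  sets <- strsplit(as.character(signature), "&", fixed = TRUE)
  key <- vapply(sets, function(s) {
    paste(sprintf("%04d", sort(match(s, order))), collapse = "")
  }, character(1))
  base::order(lengths(sets), key, method = "radix")
}
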