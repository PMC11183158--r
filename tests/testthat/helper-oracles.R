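# Independent oracles used across the suite. These deliberately avoid the
# package's signature/partition code paths: membership is re-derived from
# per-set element vectors with %in%, and signatures are re-joined by hand.

# random membership structure as a logical incidence matrix
randomCollection <- function(seed, maxSets = 6L, maxElements = 200L) {
  set.seed(seed)
  k <- sample(1:maxSets, 1)
  n <- sample(1:maxElements, 1)
  labels <- LETTERS[seq_len(k)]
  m <- matrix(stats::runif(n * k) < stats::runif(1, 0.2, 0.7), n, k)
  empty <- rowSums(m) == 0
  m[cbind(which(empty), sample(k, sum(empty), replace = TRUE))] <- TRUE
  # the two-column dialect cannot encode empty sets; keep each set inhabited
  for (j in which(colSums(m) == 0)) m[sample(n, 1), j] <- TRUE
  ids <- sprintf("e%04d", seq_len(n))
  membership <- lapply(seq_len(n), function(i) labels[m[i, ]])
  names(membership) <- ids
  SetCollection(membership, setLabels = labels)
}

# brute-force region assignment via the (element x set) incidence table
bruteRegions <- function(collection) {
  labels <- setLabels(collection)
  memb <- membershipList(collection)
  el <- rep(names(memb), lengths(memb))
  st <- unlist(memb, use.names = FALSE)
  inc <- table(factor(el, levels = names(memb)),
               factor(st, levels = labels)) > 0
  sigs <- apply(inc, 1, function(r) paste(labels[r], collapse = "&"))
  lapply(split(rownames(inc), sigs), sort)
}

# brute-force inclusive intersection via Reduce(intersect)
bruteInclusive <- function(collection, subset) {
  memb <- membershipList(collection)
  perSet <- lapply(subset, function(s) {
    names(memb)[vapply(memb, function(m) s %in% m, logical(1))]
  })
  length(Reduce(intersect, perSet))
}

# brute-force hypergeometric pmf/upper tail via choose()
bruteHyperTail <- function(q, sizeA, sizeB, universe) {
  ks <- max(0, sizeA + sizeB - universe):min(sizeA, sizeB)
  pmf <- choose(sizeA, ks) * choose(universe - sizeA, sizeB - ks) /
    choose(universe, sizeB)
  sum(pmf[ks >= q])
}

# membership code of points under a template (mirrors grid logic only via
# the public shapeContains)
templateCode <- function(template, px, py) {
  code <- integer(length(px))
  for (i in seq_along(template@shapes)) {
    code <- code + shapeContains(template@shapes[[i]], px, py) * 2^(i - 1L)
  }
  code
}

sigBit <- function(sig, labels) {
  sum(2^(match(strsplit(sig, "&", fixed = TRUE)[[1]], labels) - 1L))
}
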