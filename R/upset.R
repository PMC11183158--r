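#' @include setcore.R scene.R colors.R
NULL

#' Build an UpSet intersection matrix
#'
#' Columns are the exclusive intersections of the partition, sorted by
#' count descending, ties broken by signature degree ascending, then by
#' canonical signature lexicographically (a total order, so shuffled input
#' rebuilds identically). With \code{keepEmpty} all 2^n - 1 signatures are
#' enumerated (capped at 12 sets); otherwise only non-empty ones.
#'
#' @param partition a [RegionPartition-class] over 3-40 sets.
#' @param keepEmpty keep zero-count intersections (requires <= 12 sets).
#' @param sortBy "count" (default order described above) or "degree"
#'   (degree ascending first, then count descending, then signature).
#' @return an [UpSetMatrix-class].
#' @export
buildUpSetMatrix <- function(partition, keepEmpty = FALSE,
                             sortBy = c("count", "degree")) {
  sortBy <- match.arg(sortBy)
  stopifnot(is(partition, "RegionPartition"))
  labels <- partition@setLabels
  n <- length(labels)
  if (n < 3L || n > 40L)
    stop("UpSet matrices cover 3 to 40 sets")
  if (keepEmpty && n > 12L)
    stop("keepEmpty enumerates 2^n - 1 intersections and is capped at 12 sets")
  if (keepEmpty) {
    sigs <- allSignatures(labels)
    counts <- structure(integer(length(sigs)), names = sigs)
    counts[names(partition@counts)] <- partition@counts
  } else {
    counts <- partition@counts[partition@counts > 0]
    sigs <- names(counts)
  }
  deg <- signatureDegree(sigs)
  ord <- if (sortBy == "count") {
    order(-counts, deg, sigs, method = "radix")
  } else {
    order(deg, -counts, sigs, method = "radix")
  }
  totals <- vapply(labels, function(s) inclusiveSize(partition, s), integer(1))
  new("UpSetMatrix", setLabels = labels,
      setTotals = as.numeric(totals),
      signatures = sigs[ord], counts = as.integer(counts[ord]),
      keepEmpty = keepEmpty)
}

#' Build the three-panel UpSet scene
#'
#' Top panel: vertical bars of the column counts, each printed above its
#' bar. Left panel: horizontal bars of the total elements per set. Bottom
#' right: the dot matrix, one filled dot per member set per column, with
#' consecutive member dots joined by a vertical segment. Bar extents are
#' linearly proportional to counts.
#'
#' @param matrix an [UpSetMatrix-class].
#' @param colors optional per-set colors for the left panel.
#' @return a [SceneGraph-class].
#' @export
upsetScene <- function(matrix, colors = NULL) {
  stopifnot(is(matrix, "UpSetMatrix"))
  labels <- matrix@setLabels
  n <- length(labels)
  m <- length(matrix@signatures)
  colors <- if (is.null(colors)) defaultSetColors(n)
            else interpolateColors(colors, n)
  # geometry: dot matrix occupies [0, m] x [0, n] (column i at x = i - 0.5,
  # set j at y = n - j + 0.5); top bars above y = n + gap; left bars at x < 0
  gap <- 0.6
  barH <- max(n * 0.9, 3)            # top bar panel height
  barW <- max(m * 0.35, 3)           # left bar panel width
  maxC <- max(matrix@counts, 1L)
  maxT <- max(matrix@setTotals, 1)
  fs <- 0.32
  prims <- list()
  # left panel: horizontal set-total bars
  for (j in seq_len(n)) {
    w <- matrix@setTotals[j] / maxT * barW
    y <- n - j + 0.5
    prims[[length(prims) + 1L]] <-
      scRect(-gap - w, y - 0.3, w, 0.6, fill = colors[j], opacity = 0.9)
    prims[[length(prims) + 1L]] <-
      scText(-gap - w - 0.2, y, matrix@setTotals[j], size = fs, anchor = "end")
    prims[[length(prims) + 1L]] <-
      scText(-gap - barW - 3.2, y, labels[j], size = fs, anchor = "start")
  }
  # top panel: vertical intersection bars with printed counts
  for (i in seq_len(m)) {
    h <- matrix@counts[i] / maxC * barH
    x <- i - 0.5
    prims[[length(prims) + 1L]] <-
      scRect(x - 0.3, n + gap, 0.6, h, fill = "#4D4D4D")
    prims[[length(prims) + 1L]] <-
      scText(x, n + gap + h + 0.45, matrix@counts[i], size = fs)
  }
  # dot matrix
  memberIdx <- lapply(strsplit(matrix@signatures, "&", fixed = TRUE),
                      match, table = labels)
  for (i in seq_len(m)) {
    x <- i - 0.5
    idx <- sort(memberIdx[[i]])
    ys <- n - idx + 0.5
    for (j in seq_len(n)) {
      y <- n - j + 0.5
      on <- j %in% idx
      prims[[length(prims) + 1L]] <-
        scCircle(x, y, 0.16, fill = if (on) "#1A1A1A" else "#D9D9D9",
                 stroke = "none")
    }
    if (length(ys) > 1) {
      for (k in seq_len(length(ys) - 1)) {
        prims[[length(prims) + 1L]] <-
          scLine(x, ys[k], x, ys[k + 1], stroke = "#1A1A1A",
                 strokeWidth = 0.07)
      }
    }
  }
  SceneGraph(prims, metadata = list(view = "upset",
                                    keepEmpty = matrix@keepEmpty))
}
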