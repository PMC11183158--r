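#' @include setcore.R scene.R colors.R
NULL

#' Flower plot values for a collection
#'
#' The central core is the number of elements present in all sets. In
#' "unique" mode, petal values are the exclusive singleton counts (elements
#' in that set only); in "residual" mode, each petal is the set size after
#' subtracting the common elements, so petal + core = set size for every
#' set.
#'
#' @param collection a [SetCollection-class] (3 or more sets; the view is
#'   aimed at collections beyond the 6-set Venn and 10-set UpSet comfort
#'   zone).
#' @param mode "unique" or "residual".
#' @return a [FlowerSpec-class].
#' @export
flowerValues <- function(collection, mode = c("unique", "residual")) {
  mode <- match.arg(mode)
  stopifnot(is(collection, "SetCollection"))
  if (length(collection@setLabels) < 3L)
    stop("flower plots need at least 3 sets")
  dec <- flowerDecomposition(collection)
  vals <- if (mode == "unique") dec$unique else dec$residual
  new("FlowerSpec", coreValue = dec$core,
      petalSets = collection@setLabels,
      petalValues = as.integer(vals), mode = mode)
}

#' Build the flower plot scene
#'
#' A central circle labelled with the core value, surrounded by n congruent
#' ellipse petals with centers on a fixed orbit; petal k is rotated by
#' 2*pi*k/n. Petal geometry scales with 1/sqrt(n) so large collections
#' (70+ sets) stay legible; each petal carries its value, and the set name
#' sits outside the petal tip rotated to the petal axis (flipped upright on
#' the left half).
#'
#' @param spec a [FlowerSpec-class].
#' @param colors optional per-petal colors (interpolated to the petal
#'   count).
#' @return a [SceneGraph-class].
#' @export
flowerScene <- function(spec, colors = NULL) {
  stopifnot(is(spec, "FlowerSpec"))
  n <- length(spec@petalSets)
  colors <- if (is.null(colors)) defaultSetColors(n)
            else interpolateColors(colors, n)
  orbit <- 0.55
  a <- 0.42                      # petal semi-major axis (radial)
  b <- min(0.22, 0.66 / sqrt(n))  # tangential semi-axis; ~1/sqrt(n)
  coreR <- 0.30
  fs <- min(0.07, 1.45 / n)      # label size shrinks with petal count
  prims <- list()
  for (k in seq_len(n)) {
    th <- 2 * pi * (k - 1) / n
    cx <- orbit * cos(th); cy <- orbit * sin(th)
    prims[[length(prims) + 1L]] <-
      scEllipse(cx, cy, a, b, rot = th, fill = colors[k],
                stroke = "#333333", opacity = 0.55, strokeWidth = 0.004)
  }
  prims[[length(prims) + 1L]] <-
    scCircle(0, 0, coreR, fill = "#F5E663", stroke = "#333333",
             opacity = 0.95, strokeWidth = 0.004)
  prims[[length(prims) + 1L]] <- scText(0, 0, spec@coreValue, size = 0.09)
  valR <- orbit + 0.55 * a       # petal value near the outer half of the petal
  nameR <- orbit + a + 2.0 * fs  # set name outside the petal tip
  for (k in seq_len(n)) {
    th <- 2 * pi * (k - 1) / n
    rot <- th
    upright <- cos(th) < 0       # flip labels on the left half
    if (upright) rot <- th + pi
    prims[[length(prims) + 1L]] <-
      scText(valR * cos(th), valR * sin(th), spec@petalValues[k],
             size = fs, rot = rot)
    prims[[length(prims) + 1L]] <-
      scText(nameR * cos(th), nameR * sin(th), spec@petalSets[k],
             size = fs, rot = rot)
  }
  SceneGraph(prims, metadata = list(view = "flower", mode = spec@mode))
}
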