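#' @include AllClasses.R signatures.R template-constants.R
NULL

#' Point-in-shape membership test
#'
#' Total over the canvas; vectorized over points. Shape kinds: \code{circle}
#' (cx, cy, r), \code{ellipse} (cx, cy, a, b, rot), \code{halfplane}
#' (nx, ny, c; inside where nx*x + ny*y >= c), \code{polygon} (x, y vertex
#' vectors; even-odd rule) and \code{wave} (a closed serpentine curve around
#' a circle: inside where the point's radius is below
#' R * (1 + A * cos(m * theta))).
#'
#' @param shape a shape specification list.
#' @param px,py point coordinates.
#' @return logical vector.
#' @export
shapeContains <- function(shape, px, py) {
  switch(shape$kind,
    circle = (px - shape$cx)^2 + (py - shape$cy)^2 <= shape$r^2,
    ellipse = {
      co <- cos(-shape$rot); si <- sin(-shape$rot)
      dx <- px - shape$cx; dy <- py - shape$cy
      qx <- co * dx - si * dy
      qy <- si * dx + co * dy
      (qx / shape$a)^2 + (qy / shape$b)^2 <= 1
    },
    halfplane = shape$nx * px + shape$ny * py >= shape$c,
    polygon = .pointInPolygon(px, py, shape$x, shape$y),
    wave = {
      dx <- px - shape$cx; dy <- py - shape$cy
      r <- sqrt(dx^2 + dy^2)
      th <- atan2(dy, dx)
      r <= shape$R * (1 + shape$A * cos(shape$m * th))
    },
    stop("unknown shape kind: ", shape$kind))
}

# even-odd ray casting, vectorized over points
.pointInPolygon <- function(px, py, vx, vy) {
  n <- length(vx)
  inside <- logical(length(px))
  j <- n
  for (i in seq_len(n)) {
    crosses <- ((vy[i] > py) != (vy[j] > py)) &
      (px < (vx[j] - vx[i]) * (py - vy[i]) / (vy[j] - vy[i]) + vx[i])
    inside <- xor(inside, crosses)
    j <- i
  }
  inside
}

#' Classic Venn template for 2-6 sets
#'
#' Fixed-shape constructions realizing all 2^n - 1 interior regions:
#' overlapping circles for 2 and 3 sets, rotated congruent ellipses for 4
#' and 5 sets, and a six-triangle arrangement for 6 sets. The shape
#' constants are frozen so every cell's sampled area stays above 0.2% of
#' the canvas.
#'
#' @param n number of sets, 2 to 6.
#' @return a [VennTemplate-class].
#' @export
classicTemplate <- function(n) {
  n <- as.integer(n)
  if (n < 2L || n > 6L) stop("classic templates cover 2 to 6 sets")
  shapes <- switch(as.character(n),
    "2" = list(
      list(kind = "circle", cx = -0.35, cy = 0, r = 0.72),
      list(kind = "circle", cx = 0.35, cy = 0, r = 0.72)),
    "3" = lapply(0:2, function(k) {
      th <- pi / 2 + 2 * pi * k / 3
      list(kind = "circle", cx = 0.4 * cos(th), cy = 0.4 * sin(th), r = 0.68)
    }),
    "4" = .classic4Shapes(),
    "5" = .classic5Shapes(),
    "6" = .classic6Shapes())
  new("VennTemplate", nSets = n, shapes = shapes,
      canvas = .templateCanvas(n, "classic"), mode = "classic")
}

#' Edwards-Venn template for 2-6 sets
#'
#' The Edwards construction: set 1 is a vertical half-plane split, set 2 a
#' horizontal one, set 3 a circle, and sets 4-6 closed serpentine curves
#' weaving across that circle with doubling frequency (2, 4, 8 lobes) and
#' decreasing amplitude. All 2^n - 1 interior regions are realized for any
#' n up to 6; the construction is particularly legible at 5-6 sets.
#'
#' @param n number of sets, 2 to 6.
#' @return a [VennTemplate-class].
#' @export
edwardsTemplate <- function(n) {
  n <- as.integer(n)
  if (n < 2L || n > 6L) stop("Edwards templates cover 2 to 6 sets")
  R <- .edwardsR
  all <- list(
    list(kind = "halfplane", nx = 1, ny = 0, c = 0),
    list(kind = "halfplane", nx = 0, ny = 1, c = 0),
    list(kind = "circle", cx = 0, cy = 0, r = R),
    list(kind = "wave", cx = 0, cy = 0, R = R, A = .edwardsAmp[1], m = 2L),
    list(kind = "wave", cx = 0, cy = 0, R = R, A = .edwardsAmp[2], m = 4L),
    list(kind = "wave", cx = 0, cy = 0, R = R, A = .edwardsAmp[3], m = 8L))
  new("VennTemplate", nSets = n, shapes = all[seq_len(n)],
      canvas = c(-1, -1, 1, 1), mode = "edwards")
}

# membership codes of grid points over the canvas; rows = y index
.templateGrid <- function(template, resolution = 500L) {
  cv <- template@canvas
  gx <- seq(cv[1], cv[3], length.out = resolution)
  gy <- seq(cv[2], cv[4], length.out = resolution)
  px <- rep(gx, times = resolution)
  py <- rep(gy, each = resolution)
  code <- integer(length(px))
  for (i in seq_along(template@shapes)) {
    code <- code + shapeContains(template@shapes[[i]], px, py) * 2^(i - 1L)
  }
  list(x = px, y = py, code = code, resolution = resolution)
}

#' Interior cell count of a template under grid sampling
#'
#' @param template a [VennTemplate-class].
#' @param resolution sampling grid side (default 500).
#' @return named integer vector: bit code -> sampled point count, for the
#'   non-outside codes present.
#' @export
templateCellCounts <- function(template, resolution = 500L) {
  g <- .templateGrid(template, resolution)
  tab <- tabulate(g$code + 1L, nbins = 2^template@nSets)[-1]
  names(tab) <- as.character(seq_len(2^template@nSets - 1L))
  tab
}

#' Region label positions for a template
#'
#' For every one of the 2^n - 1 signatures the position is the centroid of
#' the signature's sampled cell; when the centroid falls outside the cell
#' (non-convex cells), it snaps to a deep interior sample of the cell (by
#' erosion of the sampled mask) nearest the centroid.
#'
#' @param template a [VennTemplate-class].
#' @param labels set labels, one per template shape.
#' @param resolution sampling grid side (default 500).
#' @return named list: canonical signature -> c(x, y).
#' @export
regionLabelPositions <- function(template, labels = paste0("S", seq_len(template@nSets)),
                                 resolution = 500L) {
  stopifnot(length(labels) == template@nSets)
  g <- .templateGrid(template, resolution)
  res <- g$resolution
  sigs <- allSignatures(labels)
  masks <- vapply(strsplit(sigs, "&", fixed = TRUE),
                  function(s) sum(2^(match(s, labels) - 1L)), numeric(1))
  out <- vector("list", length(sigs))
  names(out) <- sigs
  for (k in seq_along(sigs)) {
    cell <- g$code == masks[k]
    if (!any(cell))
      stop("no sampled point for region '", sigs[k], "' at resolution ",
           res, "; increase the resolution")
    cx <- mean(g$x[cell]); cy <- mean(g$y[cell])
    # centroid may escape a non-convex cell: snap to a deep interior point
    ci <- .nearestIndex(cx, cy, template@canvas, res)
    if (!cell[ci]) {
      deep <- .erodeDeep(matrix(cell, nrow = res))
      idx <- which(deep)
      d2 <- (g$x[idx] - cx)^2 + (g$y[idx] - cy)^2
      pick <- idx[which.min(d2)]
      cx <- g$x[pick]; cy <- g$y[pick]
    }
    out[[k]] <- c(cx, cy)
  }
  out
}

.nearestIndex <- function(x, y, canvas, res) {
  ix <- round((x - canvas[1]) / (canvas[3] - canvas[1]) * (res - 1)) + 1
  iy <- round((y - canvas[2]) / (canvas[4] - canvas[2]) * (res - 1)) + 1
  ix <- min(max(ix, 1), res); iy <- min(max(iy, 1), res)
  as.integer((iy - 1) * res + ix)
}

# erode a logical mask (rows = x index, cols = y index as stored) until the
# next erosion would empty it; returns the last non-empty mask
.erodeDeep <- function(mask) {
  repeat {
    e <- mask
    e[-1, ] <- e[-1, ] & mask[-nrow(mask), ]
    e[-nrow(mask), ] <- e[-nrow(mask), ] & mask[-1, ]
    e[, -1] <- e[, -1] & mask[, -ncol(mask)]
    e[, -ncol(mask)] <- e[, -ncol(mask)] & mask[, -1]
    if (!any(e)) return(mask)
    mask <- e
  }
}
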