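#' @include templates.R setcore.R scene.R colors.R
NULL

# label-position cache: templates are fixed, so positions depend only on
# (mode, n, resolution)
.labelCache <- new.env(parent = emptyenv())

.cachedLabelPositions <- function(mode, n, labels, resolution = 500L) {
  key <- paste(mode, n, resolution, sep = ":")
  if (is.null(.labelCache[[key]])) {
    template <- if (mode == "classic") classicTemplate(n) else edwardsTemplate(n)
    .labelCache[[key]] <- regionLabelPositions(
      template, labels = paste0("S", seq_len(n)), resolution = resolution)
  }
  pos <- .labelCache[[key]]
  # re-key generic signatures to the requested labels
  names(pos) <- vapply(strsplit(names(pos), "&", fixed = TRUE), function(s) {
    paste(labels[as.integer(sub("^S", "", s))], collapse = "&")
  }, character(1))
  pos
}

#' Build a classic or Edwards Venn diagram scene
#'
#' Draws the fixed template for the partition's set count, fills each shape
#' with its set color at fixed opacity, and places the exclusive region
#' count at every one of the 2^n - 1 region positions (empty regions show
#' 0). The label values are exactly the partition's exclusive counts; the
#' scene never recomputes set logic.
#'
#' @param partition a [RegionPartition-class] over 2-6 sets.
#' @param mode "classic" or "edwards".
#' @param colors optional per-set colors (interpolated to the set count).
#' @param resolution label-placement grid side.
#' @return a [SceneGraph-class].
#' @export
vennScene <- function(partition, mode = c("classic", "edwards"),
                      colors = NULL, resolution = 500L) {
  mode <- match.arg(mode)
  stopifnot(is(partition, "RegionPartition"))
  labels <- partition@setLabels
  n <- length(labels)
  if (n > 6L)
    stop("Venn templates cover at most 6 sets; use the UpSet or flower views")
  if (n < 2L) stop("Venn scenes need at least 2 sets")
  template <- if (mode == "classic") classicTemplate(n) else edwardsTemplate(n)
  colors <- if (is.null(colors)) defaultSetColors(n)
            else interpolateColors(colors, n)
  cv <- template@canvas
  prims <- list()
  for (i in seq_len(n)) {
    prims[[length(prims) + 1L]] <-
      .shapePrimitive(template@shapes[[i]], cv, fill = colors[i],
                      opacity = 0.35)
  }
  pos <- .cachedLabelPositions(mode, n, labels, resolution)
  counts <- structure(integer(length(pos)), names = names(pos))
  counts[names(partition@counts)] <- partition@counts
  fs <- 0.035 * (cv[3] - cv[1])
  for (sig in names(pos)) {
    prims[[length(prims) + 1L]] <-
      scText(pos[[sig]][1], pos[[sig]][2], counts[[sig]], size = fs)
  }
  prims <- c(prims, .setNameLabels(template, labels, colors, fs))
  SceneGraph(prims, metadata = list(view = paste0("venn-", mode)))
}

# render one template shape as a scene primitive (half-planes and waves are
# polygonized; half-planes additionally clipped to the canvas rectangle)
.shapePrimitive <- function(shape, canvas, fill, opacity) {
  sw <- 0.006 * (canvas[3] - canvas[1])
  switch(shape$kind,
    circle = scCircle(shape$cx, shape$cy, shape$r, fill = fill,
                      stroke = "#333333", opacity = opacity, strokeWidth = sw),
    ellipse = scEllipse(shape$cx, shape$cy, shape$a, shape$b, shape$rot,
                        fill = fill, stroke = "#333333", opacity = opacity,
                        strokeWidth = sw),
    polygon = scPolygon(shape$x, shape$y, fill = fill, stroke = "#333333",
                        opacity = opacity, strokeWidth = sw),
    halfplane = {
      # clip {nx*x + ny*y >= c} to the canvas rectangle
      corners <- rbind(c(canvas[1], canvas[2]), c(canvas[3], canvas[2]),
                       c(canvas[3], canvas[4]), c(canvas[1], canvas[4]))
      poly <- .clipHalfplane(corners, shape$nx, shape$ny, shape$c)
      scPolygon(poly[, 1], poly[, 2], fill = fill, stroke = "#333333",
                opacity = opacity, strokeWidth = sw)
    },
    wave = {
      th <- seq(0, 2 * pi, length.out = 721L)[-721L]
      r <- shape$R * (1 + shape$A * cos(shape$m * th))
      scPolygon(shape$cx + r * cos(th), shape$cy + r * sin(th), fill = fill,
                stroke = "#333333", opacity = opacity, strokeWidth = sw)
    },
    stop("unknown shape kind: ", shape$kind))
}

# Sutherland-Hodgman clip of a convex polygon against one half-plane
.clipHalfplane <- function(poly, nx, ny, c) {
  out <- matrix(numeric(0), ncol = 2)
  m <- nrow(poly)
  for (i in seq_len(m)) {
    a <- poly[i, ]; b <- poly[(i %% m) + 1, ]
    ina <- nx * a[1] + ny * a[2] >= c
    inb <- nx * b[1] + ny * b[2] >= c
    if (ina) out <- rbind(out, a)
    if (xor(ina, inb)) {
      t <- (c - nx * a[1] - ny * a[2]) /
        (nx * (b[1] - a[1]) + ny * (b[2] - a[2]))
      out <- rbind(out, a + t * (b - a))
    }
  }
  out
}

.setNameLabels <- function(template, labels, colors, fs) {
  cv <- template@canvas
  prims <- list()
  legend <- character(0)
  for (i in seq_along(template@shapes)) {
    sh <- template@shapes[[i]]
    if (sh$kind %in% c("circle", "ellipse")) {
      # radially outside the shape, away from the canvas center
      mx <- (cv[1] + cv[3]) / 2; my <- (cv[2] + cv[4]) / 2
      dx <- sh$cx - mx; dy <- sh$cy - my
      nr <- sqrt(dx^2 + dy^2)
      if (nr < 1e-9) { dx <- 0; dy <- 1; nr <- 1 }
      ext <- if (sh$kind == "circle") sh$r else max(sh$a, sh$b)
      prims[[length(prims) + 1L]] <-
        scText(sh$cx + dx / nr * (ext + 1.5 * fs),
               sh$cy + dy / nr * (ext + 1.5 * fs),
               labels[i], size = fs, fill = colors[i])
    } else {
      legend <- c(legend, i)
    }
  }
  # shapes without a natural outward anchor go into a legend row below
  for (j in seq_along(legend)) {
    i <- as.integer(legend[j])
    x <- cv[1] + (j - 0.5) * (cv[3] - cv[1]) / max(length(legend), 1)
    prims[[length(prims) + 1L]] <-
      scText(x, cv[2] - 2.5 * fs, labels[i], size = fs, fill = colors[i])
  }
  prims
}
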