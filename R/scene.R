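#' @include AllClasses.R
NULL

# ---- primitive constructors (internal) ----
# Scenes use mathematical coordinates (y up); renderSVG flips the axis.

scCircle <- function(cx, cy, r, fill = "none", stroke = "#000000",
                     opacity = 1, strokeWidth = 0.01) {
  list(kind = "circle", cx = cx, cy = cy, r = r, fill = fill,
       stroke = stroke, opacity = opacity, strokeWidth = strokeWidth)
}

scEllipse <- function(cx, cy, a, b, rot = 0, fill = "none", stroke = "#000000",
                      opacity = 1, strokeWidth = 0.01) {
  list(kind = "ellipse", cx = cx, cy = cy, a = a, b = b, rot = rot,
       fill = fill, stroke = stroke, opacity = opacity,
       strokeWidth = strokeWidth)
}

scPolygon <- function(x, y, fill = "none", stroke = "#000000", opacity = 1,
                      strokeWidth = 0.01, closed = TRUE) {
  list(kind = "polygon", x = x, y = y, fill = fill, stroke = stroke,
       opacity = opacity, strokeWidth = strokeWidth, closed = closed)
}

scLine <- function(x1, y1, x2, y2, stroke = "#000000", strokeWidth = 0.01) {
  list(kind = "line", x1 = x1, y1 = y1, x2 = x2, y2 = y2, stroke = stroke,
       strokeWidth = strokeWidth)
}

scRect <- function(x, y, w, h, fill = "none", stroke = "none", opacity = 1,
                   strokeWidth = 0.01) {
  list(kind = "rect", x = x, y = y, w = w, h = h, fill = fill,
       stroke = stroke, opacity = opacity, strokeWidth = strokeWidth)
}

scText <- function(x, y, text, size = 0.05, fill = "#000000", rot = 0,
                   anchor = "middle") {
  list(kind = "text", x = x, y = y, text = as.character(text), size = size,
       fill = fill, rot = rot, anchor = anchor)
}

#' Construct a SceneGraph
#'
#' @param primitives ordered list of drawing primitives (internal
#'   constructors; see [scenePrimitives()] for the field layout).
#' @param bbox numeric (xmin, ymin, xmax, ymax); computed from the
#'   primitives when NULL.
#' @param metadata named list recorded with the scene.
#' @return a [SceneGraph-class].
#' @export
SceneGraph <- function(primitives = list(), bbox = NULL, metadata = list()) {
  if (is.null(bbox)) bbox <- .sceneExtent(primitives)
  new("SceneGraph", primitives = primitives, bbox = as.numeric(bbox),
      metadata = metadata)
}

.primExtent <- function(p) {
  switch(p$kind,
    circle = c(p$cx - p$r, p$cy - p$r, p$cx + p$r, p$cy + p$r),
    ellipse = {
      m <- max(p$a, p$b)
      c(p$cx - m, p$cy - m, p$cx + m, p$cy + m)
    },
    polygon = c(min(p$x), min(p$y), max(p$x), max(p$y)),
    line = c(min(p$x1, p$x2), min(p$y1, p$y2), max(p$x1, p$x2), max(p$y1, p$y2)),
    rect = c(p$x, p$y, p$x + p$w, p$y + p$h),
    text = {
      w <- 0.62 * p$size * nchar(p$text)
      c(p$x - w / 2, p$y - p$size / 2, p$x + w / 2, p$y + p$size / 2)
    },
    stop("unknown primitive kind: ", p$kind))
}

.sceneExtent <- function(primitives) {
  if (!length(primitives)) return(c(0, 0, 1, 1))
  ex <- vapply(primitives, .primExtent, numeric(4))
  c(min(ex[1, ]), min(ex[2, ]), max(ex[3, ]), max(ex[4, ]))
}

# all text labels in a scene, in order
sceneLabels <- function(scene) {
  prim <- scene@primitives
  vapply(prim[vapply(prim, function(p) p$kind == "text", logical(1))],
         `[[`, character(1), "text")
}
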