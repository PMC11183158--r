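#' @include scene.R
NULL

.xmlEscape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  x <- gsub(">", "&gt;", x, fixed = TRUE)
  x <- gsub('"', "&quot;", x, fixed = TRUE)
  x
}

.num <- function(x) sprintf("%.6g", x)

#' Render a scene graph to SVG 1.1
#'
#' Maps the scene's bounding box onto a square viewBox (default 600 x 600
#' user units) with the y axis pointing down, and emits exactly one SVG
#' element per primitive, in scene order. Text labels carry their exact
#' strings. An empty scene yields a minimal valid document.
#'
#' @param scene a [SceneGraph-class].
#' @param file optional output path.
#' @param width,height canvas size in SVG user units.
#' @return the SVG text; invisibly when \code{file} is given.
#' @export
renderSVG <- function(scene, file = NULL, width = 600, height = 600) {
  stopifnot(is(scene, "SceneGraph"))
  bb <- scene@bbox
  spanX <- max(bb[3] - bb[1], 1e-9)
  spanY <- max(bb[4] - bb[2], 1e-9)
  s <- min(width / spanX, height / spanY)
  # map math coords (y up) to SVG coords (y down)
  tx <- function(x) (x - bb[1]) * s + (width - spanX * s) / 2
  ty <- function(y) (bb[4] - y) * s + (height - spanY * s) / 2
  meta <- scene@metadata
  metaStr <- if (length(meta)) {
    paste0("<!-- ", .xmlEscape(paste(names(meta), unlist(meta), sep = "=",
                                     collapse = " ")), " -->")
  } else character(0)
  body <- vapply(scene@primitives, function(p) {
    switch(p$kind,
      circle = sprintf(
        '<circle cx="%s" cy="%s" r="%s" fill="%s" fill-opacity="%s" stroke="%s" stroke-width="%s"/>',
        .num(tx(p$cx)), .num(ty(p$cy)), .num(p$r * s), p$fill,
        .num(p$opacity), p$stroke, .num(p$strokeWidth * s)),
      ellipse = sprintf(
        '<ellipse cx="0" cy="0" rx="%s" ry="%s" transform="translate(%s %s) rotate(%s)" fill="%s" fill-opacity="%s" stroke="%s" stroke-width="%s"/>',
        .num(p$a * s), .num(p$b * s), .num(tx(p$cx)), .num(ty(p$cy)),
        .num(-p$rot * 180 / pi), p$fill, .num(p$opacity), p$stroke,
        .num(p$strokeWidth * s)),
      polygon = sprintf(
        '<%s points="%s" fill="%s" fill-opacity="%s" stroke="%s" stroke-width="%s"/>',
        if (isTRUE(p$closed)) "polygon" else "polyline",
        paste(.num(tx(p$x)), .num(ty(p$y)), sep = ",", collapse = " "),
        p$fill, .num(p$opacity), p$stroke, .num(p$strokeWidth * s)),
      line = sprintf(
        '<line x1="%s" y1="%s" x2="%s" y2="%s" stroke="%s" stroke-width="%s"/>',
        .num(tx(p$x1)), .num(ty(p$y1)), .num(tx(p$x2)), .num(ty(p$y2)),
        p$stroke, .num(p$strokeWidth * s)),
      rect = sprintf(
        '<rect x="%s" y="%s" width="%s" height="%s" fill="%s" fill-opacity="%s" stroke="%s" stroke-width="%s"/>',
        .num(tx(p$x)), .num(ty(p$y + p$h)), .num(p$w * s), .num(p$h * s),
        p$fill, .num(p$opacity), p$stroke, .num(p$strokeWidth * s)),
      text = sprintf(
        '<text x="0" y="0" transform="translate(%s %s) rotate(%s)" font-size="%s" font-family="sans-serif" text-anchor="%s" dominant-baseline="middle" fill="%s">%s</text>',
        .num(tx(p$x)), .num(ty(p$y)), .num(-p$rot * 180 / pi),
        .num(p$size * s), p$anchor, p$fill, .xmlEscape(p$text)),
      stop("unknown primitive kind: ", p$kind))
  }, character(1))
  doc <- paste(c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    sprintf('<svg xmlns="http://www.w3.org/2000/svg" version="1.1" width="%s" height="%s" viewBox="0 0 %s %s">',
            .num(width), .num(height), .num(width), .num(height)),
    metaStr, body, "</svg>"), collapse = "\n")
  if (!is.null(file)) {
    writeLines(doc, file)
    return(invisible(doc))
  }
  doc
}
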