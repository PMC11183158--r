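#' @include AllClasses.R
NULL

# fixed anchor palette for sets when the user supplies none
.setviewsPalette <- c("#E6B33C", "#E377C2", "#2CA02C", "#9467BD", "#1F77B4",
                      "#D62728", "#8C564B", "#17BECF")

#' Default per-set colors
#'
#' @param n number of sets.
#' @return character vector of n hex colors.
#' @export
defaultSetColors <- function(n) {
  interpolateColors(.setviewsPalette, n)
}

#' Expand or truncate a color list to one color per set
#'
#' When fewer colors than sets are supplied, intermediate colors are
#' generated by evenly spaced linear interpolation in RGB along the input
#' sequence (each channel rounded half up); when at least as many are
#' supplied, the first \code{nSets} are kept. A single input color is
#' replicated.
#'
#' @param colors non-empty character vector of colors (hex or R color
#'   names).
#' @param nSets target number of colors (>= 1).
#' @return character vector of \code{nSets} hex colors ("#RRGGBB").
#' @examples
#' interpolateColors(c("#000000", "#FFFFFF"), 3)  # midpoint #808080
#' @export
interpolateColors <- function(colors, nSets) {
  if (length(colors) == 0L) stop("colors must be non-empty")
  if (nSets < 1L) stop("nSets must be >= 1")
  rgb <- t(grDevices::col2rgb(colors))
  if (nrow(rgb) >= nSets) {
    out <- rgb[seq_len(nSets), , drop = FALSE]
  } else if (nrow(rgb) == 1L) {
    out <- rgb[rep(1L, nSets), , drop = FALSE]
  } else {
    # positions of inputs and outputs on [0, 1]; piecewise-linear channels
    xin <- seq(0, 1, length.out = nrow(rgb))
    xout <- seq(0, 1, length.out = nSets)
    out <- sapply(1:3, function(ch) {
      stats::approx(xin, rgb[, ch], xout = xout, method = "linear")$y
    })
    out <- floor(out + 0.5)  # round half up, per channel
  }
  grDevices::rgb(out[, 1], out[, 2], out[, 3], maxColorValue = 255)
}

# "#RRGGBB" with alpha suffix for SVG fill-opacity handled separately
.hexNoAlpha <- function(col) substr(grDevices::rgb(t(grDevices::col2rgb(col)),
                                                   maxColorValue = 255), 1, 7)
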