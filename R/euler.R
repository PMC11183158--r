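#' @include setcore.R scene.R colors.R
NULL

#' Area of the lens where two circles intersect
#'
#' Standard circle-circle intersection area: zero when the circles are
#' disjoint or externally tangent, the area of the smaller circle when one
#' contains the other, and the two-circular-segment closed form in between.
#'
#' @param r1,r2 circle radii (> 0).
#' @param d distance between centers (>= 0).
#' @return the intersection area.
#' @examples
#' lensArea(1, 1, 1)  # 2*pi/3 - sqrt(3)/2
#' @export
lensArea <- function(r1, r2, d) {
  stopifnot(r1 > 0, r2 > 0, d >= 0)
  if (d >= r1 + r2) return(0)
  if (d <= abs(r1 - r2)) return(pi * min(r1, r2)^2)
  a1 <- (d^2 + r1^2 - r2^2) / (2 * d * r1)
  a2 <- (d^2 + r2^2 - r1^2) / (2 * d * r2)
  a1 <- min(1, max(-1, a1)); a2 <- min(1, max(-1, a2))
  r1^2 * acos(a1) + r2^2 * acos(a2) -
    0.5 * sqrt(max(0, (-d + r1 + r2) * (d + r1 - r2) * (d - r1 + r2) * (d + r1 + r2)))
}

#' Center distance realizing a target overlap area
#'
#' Inverts [lensArea()] by bisection on \code{[|r1 - r2|, r1 + r2]}; the
#' lens area is monotone non-increasing in the distance, so bisection
#' converges unconditionally.
#'
#' @param r1,r2 circle radii.
#' @param target desired overlap area, in \code{[0, pi * min(r1, r2)^2]}.
#' @param tol area tolerance of the solution.
#' @return the center distance.
#' @export
solveDistance <- function(r1, r2, target, tol = 1e-9) {
  maxA <- pi * min(r1, r2)^2
  if (target < 0 || target > maxA + 1e-12)
    stop("target area out of range [0, ", format(maxA), "]")
  if (target <= 0) return(r1 + r2)
  if (target >= maxA) return(abs(r1 - r2))
  lo <- abs(r1 - r2); hi <- r1 + r2
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    a <- lensArea(r1, r2, mid)
    if (abs(a - target) <= tol) return(mid)
    if (a > target) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

# 2-D Halton sequence (bases 2 and 3), deterministic quasi-random points
.halton2 <- function(n, offset = 0L) {
  vdc <- function(i, base) {
    f <- 1; r <- 0
    while (any(i > 0)) {
      f <- f / base
      r <- r + f * (i %% base)
      i <- i %/% base
    }
    r
  }
  i <- seq_len(n) + as.integer(offset)
  cbind(vdc(i, 2L), vdc(i, 3L))
}

#' Numeric exclusive-region areas of a circle arrangement
#'
#' Quasi-random (Halton) sampling over the joint bounding box classifies
#' each point by the subset of circles containing it; region area is the
#' point fraction times the box area. Deterministic for a fixed sample
#' count and offset.
#'
#' @param centers numeric matrix (n x 2), n in 1..3.
#' @param radii numeric vector of n radii.
#' @param labels set labels naming the circles.
#' @param nPoints number of Halton points (default 200000).
#' @param offset index offset into the Halton sequence (the sampling
#'   "seed"; default 0).
#' @return named numeric vector: canonical signature -> area (absent
#'   regions are 0).
#' @export
regionAreas <- function(centers, radii, labels = paste0("S", seq_along(radii)),
                        nPoints = 200000L, offset = 0L) {
  stopifnot(nrow(centers) == length(radii), length(radii) >= 1,
            length(radii) <= 3)
  xmin <- min(centers[, 1] - radii); xmax <- max(centers[, 1] + radii)
  ymin <- min(centers[, 2] - radii); ymax <- max(centers[, 2] + radii)
  h <- .halton2(nPoints, offset)
  px <- xmin + h[, 1] * (xmax - xmin)
  py <- ymin + h[, 2] * (ymax - ymin)
  code <- integer(nPoints)
  for (i in seq_along(radii)) {
    inside <- (px - centers[i, 1])^2 + (py - centers[i, 2])^2 <= radii[i]^2
    code <- code + inside * 2^(i - 1L)
  }
  boxArea <- (xmax - xmin) * (ymax - ymin)
  tab <- tabulate(code + 1L, nbins = 2^length(radii))[-1]
  sigs <- allSignatures(labels)
  # allSignatures orders by degree; recompute bitmask per signature
  masks <- vapply(strsplit(sigs, "&", fixed = TRUE),
                  function(s) sum(2^(match(s, labels) - 1L)), numeric(1))
  out <- tab[masks] / nPoints * boxArea
  names(out) <- sigs
  out
}

# target drawn areas: counts scaled so that area per element matches the
# radius normalization (largest circle radius 1)
.targetAreas <- function(partition) {
  labels <- partition@setLabels
  sizes <- vapply(labels, function(s) inclusiveSize(partition, s), integer(1))
  if (max(sizes) == 0) stop("all sets are empty; nothing to lay out")
  k <- pi / max(sizes)  # area units per element
  sigs <- allSignatures(labels)
  counts <- structure(numeric(length(sigs)), names = sigs)
  counts[names(partition@counts)] <- partition@counts
  list(areas = counts * k, unit = k, sizes = sizes)
}

#' Area-proportional Euler layout for 2-3 sets
#'
#' Circle radii are proportional to the square root of the inclusive set
#' sizes (largest radius normalized to 1). For two sets the center distance
#' is solved exactly from the target overlap area; disjoint and fully
#' contained relationships come out naturally. For three sets the pairwise
#' distances are initialized from the exact two-circle solutions and the
#' centers are then refined by a deterministic Nelder-Mead search
#' minimizing the stress (sum of squared differences between achieved and
#' target region areas, both measured by Halton sampling). Area
#' specifications no circle arrangement can realize are rendered at minimum
#' stress with a warning.
#'
#' @param partition a [RegionPartition-class] over 2 or 3 sets (counts-only
#'   accepted).
#' @param nPointsOptim Halton points per objective evaluation during
#'   optimization (default 20000).
#' @param nPointsFinal Halton points for the reported achieved areas
#'   (default 200000).
#' @param stressWarn warn when final stress exceeds this fraction of the
#'   squared total target area (default 0.01).
#' @return an [EulerLayout-class].
#' @export
layoutEuler <- function(partition, nPointsOptim = 20000L,
                        nPointsFinal = 200000L, stressWarn = 0.01) {
  stopifnot(is(partition, "RegionPartition"))
  labels <- partition@setLabels
  n <- length(labels)
  if (n < 2 || n > 3)
    stop("Euler layouts cover 2 or 3 sets; use the Venn, UpSet or flower views for other set counts")
  tg <- .targetAreas(partition)
  radii <- sqrt(tg$sizes * tg$unit / pi)
  radii[radii <= 0] <- 1e-6
  sep <- 0.2 * max(radii)  # gap drawn between fully disjoint circles

  pairDistance <- function(i, j) {
    inter <- inclusiveSize(partition, labels[c(i, j)])
    if (inter == 0) return(radii[i] + radii[j] + sep)
    target <- inter * tg$unit
    maxA <- pi * min(radii[i], radii[j])^2
    solveDistance(radii[i], radii[j], min(target, maxA), tol = 1e-12)
  }

  trace <- numeric(0)
  if (n == 2) {
    d <- pairDistance(1, 2)
    centers <- rbind(c(0, 0), c(d, 0))
  } else {
    d12 <- pairDistance(1, 2); d13 <- pairDistance(1, 3); d23 <- pairDistance(2, 3)
    # triangle initialization (law of cosines; clamp if the inequality fails)
    x3 <- (d12^2 + d13^2 - d23^2) / (2 * max(d12, 1e-9))
    y3sq <- d13^2 - x3^2
    y3 <- sqrt(max(y3sq, 1e-6))
    init <- c(d12, x3, y3)
    targets <- tg$areas
    obj <- function(p) {
      centers <- rbind(c(0, 0), c(p[1], 0), c(p[2], p[3]))
      ach <- regionAreas(centers, radii, labels, nPoints = nPointsOptim)
      sum((ach - targets)^2)
    }
    best <- obj(init)
    trace <- best
    objTraced <- function(p) {
      v <- obj(p)
      best <<- min(best, v)
      trace <<- c(trace, best)
      v
    }
    fit <- stats::optim(init, objTraced, method = "Nelder-Mead",
                        control = list(maxit = 300, reltol = 1e-8))
    centers <- rbind(c(0, 0), c(fit$par[1], 0), c(fit$par[2], fit$par[3]))
  }

  ach <- regionAreas(centers, radii, labels, nPoints = nPointsFinal)
  stress <- sum((ach - tg$areas)^2)
  if (stress > stressWarn * sum(tg$areas)^2)
    warning("no circle arrangement realizes these region areas well; ",
            "drawing the minimum-stress layout (stress = ",
            format(stress, digits = 4), ")")
  new("EulerLayout", setLabels = labels, centers = centers, radii = radii,
      targetAreas = tg$areas, achievedAreas = ach, stress = stress,
      stressTrace = if (length(trace)) trace else stress)
}

#' Build the Euler diagram scene
#'
#' Circles are filled with per-set colors at fixed opacity; every non-empty
#' region is labelled with its count at the centroid of its sampled points
#' (snapped to the nearest in-region sample when the centroid falls
#' outside). Set names are placed outside their circles.
#'
#' @param layout an [EulerLayout-class].
#' @param partition the [RegionPartition-class] the layout was built from.
#' @param colors optional per-set colors (interpolated to the set count).
#' @param nPoints Halton points for centroid placement.
#' @return a [SceneGraph-class].
#' @export
eulerScene <- function(layout, partition, colors = NULL, nPoints = 50000L) {
  stopifnot(is(layout, "EulerLayout"), is(partition, "RegionPartition"))
  if (!identical(layout@setLabels, partition@setLabels))
    stop("layout and partition cover different sets")
  labels <- layout@setLabels
  n <- length(labels)
  colors <- if (is.null(colors)) defaultSetColors(n)
            else interpolateColors(colors, n)
  centers <- layout@centers; radii <- layout@radii
  prims <- list()
  for (i in seq_len(n)) {
    prims[[length(prims) + 1L]] <-
      scCircle(centers[i, 1], centers[i, 2], radii[i], fill = colors[i],
               stroke = "#333333", opacity = 0.45,
               strokeWidth = 0.01 * max(radii))
  }
  # classify Halton points once for centroids
  xmin <- min(centers[, 1] - radii); xmax <- max(centers[, 1] + radii)
  ymin <- min(centers[, 2] - radii); ymax <- max(centers[, 2] + radii)
  h <- .halton2(nPoints)
  px <- xmin + h[, 1] * (xmax - xmin)
  py <- ymin + h[, 2] * (ymax - ymin)
  code <- integer(nPoints)
  for (i in seq_len(n))
    code <- code + ((px - centers[i, 1])^2 + (py - centers[i, 2])^2 <= radii[i]^2) * 2^(i - 1L)
  fs <- 0.11 * max(radii)
  for (sig in names(partition@counts)) {
    cnt <- partition@counts[[sig]]
    mask <- sum(2^(match(parseSignature(sig), labels) - 1L))
    inreg <- code == mask
    if (!any(inreg)) next  # region not drawable (zero achieved area)
    cx <- mean(px[inreg]); cy <- mean(py[inreg])
    # snap to nearest in-region sample if centroid escaped the region
    ccode <- 0
    for (i in seq_len(n))
      ccode <- ccode + ((cx - centers[i, 1])^2 + (cy - centers[i, 2])^2 <= radii[i]^2) * 2^(i - 1L)
    if (ccode != mask) {
      k <- which.min((px[inreg] - cx)^2 + (py[inreg] - cy)^2)
      cx <- px[inreg][k]; cy <- py[inreg][k]
    }
    prims[[length(prims) + 1L]] <- scText(cx, cy, cnt, size = fs)
  }
  # set-name labels just outside each circle, away from the layout center
  mx <- mean(centers[, 1]); my <- mean(centers[, 2])
  for (i in seq_len(n)) {
    dx <- centers[i, 1] - mx; dy <- centers[i, 2] - my
    nr <- sqrt(dx^2 + dy^2)
    if (nr < 1e-9) { dx <- 0; dy <- 1; nr <- 1 }
    prims[[length(prims) + 1L]] <-
      scText(centers[i, 1] + dx / nr * (radii[i] + 1.6 * fs),
             centers[i, 2] + dy / nr * (radii[i] + 1.6 * fs),
             labels[i], size = fs, fill = colors[i])
  }
  SceneGraph(prims, metadata = list(view = "euler",
                                    stress = format(layout@stress, digits = 6)))
}
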