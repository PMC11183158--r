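#' @include setcore.R colors.R scene.R
NULL

#' Build the bipartite set-element network
#'
#' Every set becomes a parent node; every element is connected by one edge
#' to each set it belongs to, so element degree encodes membership
#' multiplicity. Display modes: \code{"all"} keeps every element;
#' \code{"flower_like"} keeps only elements common to all sets (degree n)
#' or specific to a single set (degree 1), mirroring the flower plot's
#' core-plus-unique reading.
#'
#' @param collection a [SetCollection-class].
#' @param mode "all" or "flower_like".
#' @param colors optional per-set node colors.
#' @return a [BipartiteGraph-class].
#' @export
buildGraph <- function(collection, mode = c("all", "flower_like"),
                       colors = NULL) {
  mode <- match.arg(mode)
  stopifnot(is(collection, "SetCollection"))
  labels <- collection@setLabels
  n <- length(labels)
  colors <- if (is.null(colors)) defaultSetColors(n)
            else interpolateColors(colors, n)
  memb <- collection@membership
  if (mode == "flower_like") {
    deg <- lengths(memb)
    memb <- memb[deg == n | deg == 1L]
  }
  edges <- data.frame(
    element = rep(names(memb), lengths(memb)),
    set = unlist(memb, use.names = FALSE),
    stringsAsFactors = FALSE)
  new("BipartiteGraph", setNodes = labels, setColors = colors,
      elementNodes = unique(names(memb)), edges = edges)
}

#' Deterministic force-directed layout of a bipartite graph
#'
#' Seeded Fruchterman-Reingold layout; disconnected components are laid out
#' independently and packed side by side so components never overlap.
#' Coincident coordinates are resolved by a deterministic jitter. Fixed
#' seed gives identical positions across runs.
#'
#' @param graph a [BipartiteGraph-class].
#' @param iterations force iterations (default 200).
#' @param seed integer seed.
#' @return numeric matrix with one row per node (sets first, then
#'   elements), columns x and y; rownames are node IDs.
#' @export
forceLayout <- function(graph, iterations = 200L, seed = 1L) {
  stopifnot(is(graph, "BipartiteGraph"))
  nodes <- c(graph@setNodes, setdiff(graph@elementNodes, graph@setNodes))
  if (!length(nodes)) stop("empty graph")
  ig <- igraph::graph_from_data_frame(
    graph@edges[, c("element", "set")], directed = FALSE,
    vertices = data.frame(name = nodes))
  comp <- igraph::components(ig)
  pos <- matrix(0, nrow = length(nodes), ncol = 2,
                dimnames = list(igraph::V(ig)$name, c("x", "y")))
  offsetX <- 0
  for (ci in seq_len(comp$no)) {
    vs <- which(comp$membership == ci)
    sub <- igraph::induced_subgraph(ig, vs)
    set.seed(seed + ci - 1L)
    xy <- igraph::layout_with_fr(sub, niter = iterations)
    xy[, 1] <- xy[, 1] - min(xy[, 1])
    xy[, 2] <- xy[, 2] - min(xy[, 2])
    pos[igraph::V(sub)$name, ] <- cbind(xy[, 1] + offsetX, xy[, 2])
    offsetX <- offsetX + max(xy[, 1]) + max(diff(range(xy[, 1])), 1) * 0.25 + 1
  }
  # deterministic jitter for exact coincidences
  key <- paste(pos[, 1], pos[, 2])
  dup <- duplicated(key)
  if (any(dup)) {
    k <- which(dup)
    pos[k, 1] <- pos[k, 1] + 1e-3 * seq_along(k)
    pos[k, 2] <- pos[k, 2] + 1e-3 * seq_along(k)
  }
  pos
}

#' Export a network as GraphML and JSON
#'
#' Both documents carry, for every node, its type ("set" or "element"),
#' color and layout coordinates, plus the edge list. The JSON form
#' round-trips through [importGraphJSON()].
#'
#' @param graph a [BipartiteGraph-class].
#' @param positions matrix from [forceLayout()] (rownames = node IDs).
#' @return list with character elements \code{graphml} and \code{json}.
#' @export
exportGraph <- function(graph, positions) {
  stopifnot(is(graph, "BipartiteGraph"))
  nodes <- rownames(positions)
  type <- ifelse(nodes %in% graph@setNodes, "set", "element")
  color <- ifelse(nodes %in% graph@setNodes,
                  graph@setColors[match(nodes, graph@setNodes)], "#B3B3B3")
  esc <- function(x) {
    x <- gsub("&", "&amp;", x, fixed = TRUE)
    x <- gsub("<", "&lt;", x, fixed = TRUE)
    gsub('"', "&quot;", x, fixed = TRUE)
  }
  nodeXml <- sprintf(
    '    <node id="%s"><data key="type">%s</data><data key="color">%s</data><data key="x">%.6g</data><data key="y">%.6g</data></node>',
    esc(nodes), type, color, positions[, 1], positions[, 2])
  edgeXml <- sprintf('    <edge source="%s" target="%s"/>',
                     esc(graph@edges$element), esc(graph@edges$set))
  graphml <- paste(c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    '<graphml xmlns="http://graphml.graphdrawing.org/xmlns">',
    '  <key id="type" for="node" attr.name="type" attr.type="string"/>',
    '  <key id="color" for="node" attr.name="color" attr.type="string"/>',
    '  <key id="x" for="node" attr.name="x" attr.type="double"/>',
    '  <key id="y" for="node" attr.name="y" attr.type="double"/>',
    '  <graph id="G" edgedefault="undirected">',
    nodeXml, edgeXml,
    '  </graph>', '</graphml>'), collapse = "\n")
  json <- jsonlite::toJSON(list(
    nodes = data.frame(id = nodes, type = type, color = color,
                       x = positions[, 1], y = positions[, 2],
                       stringsAsFactors = FALSE),
    edges = data.frame(source = graph@edges$element,
                       target = graph@edges$set,
                       stringsAsFactors = FALSE)),
    dataframe = "rows", auto_unbox = TRUE, digits = NA, pretty = TRUE)
  list(graphml = graphml, json = as.character(json))
}

#' Re-import a JSON network export
#'
#' @param json the JSON text written by [exportGraph()].
#' @return list with \code{graph} (a [BipartiteGraph-class]) and
#'   \code{positions}.
#' @export
importGraphJSON <- function(json) {
  obj <- jsonlite::fromJSON(json)
  setRows <- obj$nodes$type == "set"
  graph <- new("BipartiteGraph",
               setNodes = obj$nodes$id[setRows],
               setColors = obj$nodes$color[setRows],
               elementNodes = obj$nodes$id[!setRows],
               edges = data.frame(element = obj$edges$source,
                                  set = obj$edges$target,
                                  stringsAsFactors = FALSE))
  positions <- cbind(x = obj$nodes$x, y = obj$nodes$y)
  rownames(positions) <- obj$nodes$id
  list(graph = graph, positions = positions)
}

#' Network scene for SVG export
#'
#' Edges first, then element dots, then set nodes with labels.
#'
#' @param graph a [BipartiteGraph-class].
#' @param positions matrix from [forceLayout()].
#' @return a [SceneGraph-class].
#' @export
networkScene <- function(graph, positions) {
  stopifnot(is(graph, "BipartiteGraph"))
  span <- max(diff(range(positions[, 1])), diff(range(positions[, 2])), 1)
  prims <- list()
  for (i in seq_len(nrow(graph@edges))) {
    a <- positions[graph@edges$element[i], ]
    b <- positions[graph@edges$set[i], ]
    prims[[length(prims) + 1L]] <-
      scLine(a[1], a[2], b[1], b[2], stroke = "#BBBBBB",
             strokeWidth = 0.0015 * span)
  }
  for (e in setdiff(rownames(positions), graph@setNodes)) {
    prims[[length(prims) + 1L]] <-
      scCircle(positions[e, 1], positions[e, 2], 0.008 * span,
               fill = "#808080", stroke = "none")
  }
  for (s in graph@setNodes) {
    prims[[length(prims) + 1L]] <-
      scCircle(positions[s, 1], positions[s, 2], 0.03 * span,
               fill = graph@setColors[match(s, graph@setNodes)],
               stroke = "#333333", strokeWidth = 0.002 * span)
    prims[[length(prims) + 1L]] <-
      scText(positions[s, 1], positions[s, 2] + 0.05 * span, s,
             size = 0.03 * span)
  }
  SceneGraph(prims, metadata = list(view = "network"))
}
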