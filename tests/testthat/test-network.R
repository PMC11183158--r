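test_that("graph construction encodes membership as element degree", {
  coll <- SetCollection(list(x = c("A", "B")), setLabels = c("A", "B"))
  g <- buildGraph(coll, "all")
  expect_equal(sum(g@edges$element == "x"), 2L)
  # edge count = sum of membership degrees
  for (seed in 1:10) {
    coll <- randomCollection(seed, maxSets = 5L, maxElements = 50L)
    g <- buildGraph(coll, "all")
    expect_equal(nrow(g@edges), sum(lengths(membershipList(coll))))
  }
})

test_that("flower-like mode keeps only core and set-specific elements", {
  coll <- SetCollection(list(a = c("A", "B", "C"), b = c("A", "B"), c = "C"),
                        setLabels = c("A", "B", "C"))
  g <- buildGraph(coll, "flower_like")
  expect_setequal(g@elementNodes, c("a", "c"))
  # graph nodes = flower petal members plus core, exactly
  for (seed in 1:10) {
    coll <- randomCollection(seed + 5, maxSets = 5L, maxElements = 60L)
    g <- buildGraph(coll, "flower_like")
    part <- exclusiveRegions(coll)
    labels <- setLabels(coll)
    keep <- character(0)
    reg <- regionElements(part)
    for (sig in names(reg)) {
      k <- length(strsplit(sig, "&", fixed = TRUE)[[1]])
      if (k == 1L || k == length(labels)) keep <- c(keep, reg[[sig]])
    }
    expect_setequal(g@elementNodes, keep)
  }
})

test_that("degree structure mirrors the region partition", {
  for (seed in 1:8) {
    coll <- randomCollection(seed + 40, maxSets = 4L, maxElements = 50L)
    g <- buildGraph(coll, "all")
    part <- exclusiveRegions(coll)
    labels <- setLabels(coll)
    deg <- table(g@edges$element)
    n <- length(labels)
    fullSig <- paste(labels, collapse = "&")
    inAll <- names(deg)[deg == n]
    expect_setequal(inAll,
                    if (fullSig %in% names(regionCounts(part)))
                      regionElements(part)[[fullSig]] else character(0))
    singles <- unlist(regionElements(part)[intersect(names(regionCounts(part)), labels)],
                      use.names = FALSE)
    expect_setequal(names(deg)[deg == 1], singles)
  }
})

test_that("force layout is deterministic, separates components, no coincidences", {
  coll <- SetCollection(list(x = "A", y = "B"), setLabels = c("A", "B"))
  g <- buildGraph(coll, "all")
  p1 <- forceLayout(g, seed = 3)
  p2 <- forceLayout(g, seed = 3)
  expect_identical(p1, p2)
  expect_equal(nrow(p1), 4)
  expect_false(any(duplicated(paste(p1[, 1], p1[, 2]))))
  # two components (A-x, B-y) get disjoint x ranges
  xa <- range(p1[c("A", "x"), 1]); xb <- range(p1[c("B", "y"), 1])
  expect_true(xa[2] < xb[1] || xb[2] < xa[1])
})

test_that("elements cluster near their member sets", {
  memb <- c(structure(rep(list("A"), 15), names = paste0("a", 1:15)),
            structure(rep(list("B"), 15), names = paste0("b", 1:15)),
            list(shared = c("A", "B")))
  g <- buildGraph(SetCollection(memb, setLabels = c("A", "B")), "all")
  pos <- forceLayout(g, seed = 2)
  dist <- function(u, v) sqrt(sum((pos[u, ] - pos[v, ])^2))
  aToA <- mean(vapply(paste0("a", 1:15), dist, numeric(1), v = "A"))
  aToB <- mean(vapply(paste0("a", 1:15), dist, numeric(1), v = "B"))
  expect_lt(aToA, aToB)
})

test_that("exports round-trip through JSON and emit well-formed GraphML", {
  coll <- SetCollection(list(x = "A"), setLabels = "A")
  g <- buildGraph(coll, "all")
  pos <- forceLayout(g, seed = 1)
  out <- exportGraph(g, pos)
  expect_equal(length(gregexpr("<node ", out$graphml)[[1]]), 2)
  expect_equal(length(gregexpr("<edge ", out$graphml)[[1]]), 1)
  skip_if_not_installed("xml2")
  expect_silent(xml2::read_xml(out$graphml))
  back <- importGraphJSON(out$json)
  expect_identical(back$graph@setNodes, g@setNodes)
  expect_identical(sort(paste(back$graph@edges$element, back$graph@edges$set)),
                   sort(paste(g@edges$element, g@edges$set)))
  # larger round trip
  coll <- randomCollection(9, maxSets = 4L, maxElements = 40L)
  g <- buildGraph(coll, "all")
  out <- exportGraph(g, forceLayout(g, seed = 5))
  back <- importGraphJSON(out$json)
  expect_identical(sort(paste(back$graph@edges$element, back$graph@edges$set)),
                   sort(paste(g@edges$element, g@edges$set)))
})

test_that("the GO-process reconstruction yields the published degrees", {
  coll <- caseGoCollection()
  g <- buildGraph(coll, "all",
                  colors = c("pink", "green", "purple", "blue"))
  deg <- table(g@edges$element)
  expect_equal(unname(deg[["IMPTAPA2N19692_1"]]), 4L)
  expect_equal(unname(deg[["IMPTAPA2N21328_1"]]), 2L)
  expect_equal(unname(deg[["IMPTAPA2N33400_1"]]), 1L)
  expect_identical(g@setColors,
                   setviews::interpolateColors(c("pink", "green", "purple", "blue"), 4))
  exp <- exportGraph(g, forceLayout(g, seed = 1))
  for (col in g@setColors) expect_match(exp$json, col, fixed = TRUE)
})
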