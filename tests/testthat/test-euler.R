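test_that("lens area matches the closed form and its limits", {
  expect_equal(lensArea(1, 1, 2), 0)
  expect_equal(lensArea(1, 1, 2.5), 0)
  expect_equal(lensArea(1, 1, 0), pi)
  expect_equal(lensArea(1, 0.4, 0.1), pi * 0.4^2)
  expect_equal(lensArea(1, 1, 1), 2 * pi / 3 - sqrt(3) / 2, tolerance = 1e-12)
})

test_that("distance solving inverts the lens area by bisection", {
  expect_equal(solveDistance(1, 1, 0), 2)
  expect_equal(solveDistance(1, 0.5, pi * 0.25), 0.5)
  d <- solveDistance(1, 1, 2 * pi / 3 - sqrt(3) / 2, tol = 1e-9)
  expect_equal(d, 1, tolerance = 1e-6)
  expect_error(solveDistance(1, 1, 10), "out of range")
  for (seed in 1:20) {
    set.seed(seed)
    r1 <- runif(1, 0.2, 2); r2 <- runif(1, 0.2, 2)
    target <- runif(1, 0, pi * min(r1, r2)^2)
    d <- solveDistance(r1, r2, target, tol = 1e-10)
    expect_equal(lensArea(r1, r2, d), target, tolerance = 1e-8)
  }
})

test_that("sampled region areas agree with the analytic lens", {
  one <- regionAreas(matrix(c(0, 0), 1), 1, labels = "A")
  expect_equal(one[["A"]], pi, tolerance = 0.005)
  dis <- regionAreas(rbind(c(0, 0), c(3, 0)), c(1, 1), labels = c("A", "B"))
  expect_equal(dis[["A&B"]], 0)
  two <- regionAreas(rbind(c(0, 0), c(1, 0)), c(1, 1), labels = c("A", "B"))
  expect_equal(two[["A&B"]], 2 * pi / 3 - sqrt(3) / 2, tolerance = 0.005)
  expect_equal(two[["A"]], pi - (2 * pi / 3 - sqrt(3) / 2), tolerance = 0.005)
})

test_that("two-set layouts are exact; disjoint and containment draw correctly", {
  dis <- layoutEuler(partitionFromCounts(IntersectionCountTable(c(A = 30, B = 20))))
  d <- sqrt(sum((dis@centers[1, ] - dis@centers[2, ])^2))
  expect_gt(d, sum(dis@radii))
  expect_lt(dis@stress, 1e-6 * sum(dis@targetAreas)^2)
  # A strictly inside B: inclusive A&B = |A|
  con <- layoutEuler(partitionFromCounts(
    IntersectionCountTable(c(A = 20, B = 50, `A&B` = 20),
                           semantics = "inclusive")))
  d <- sqrt(sum((con@centers[1, ] - con@centers[2, ])^2))
  expect_lte(d, abs(diff(con@radii)) + 1e-9)
  part <- partitionFromCounts(IntersectionCountTable(c(A = 60, B = 40, `A&B` = 25)))
  lay <- layoutEuler(part)
  d <- sqrt(sum((lay@centers[1, ] - lay@centers[2, ])^2))
  achieved <- lensArea(lay@radii[[1]], lay@radii[[2]], d)
  expect_equal(achieved, lay@targetAreas[["A&B"]], tolerance = 1e-3)
})

test_that("three-set layouts are deterministic with non-increasing stress", {
  part <- partitionFromCounts(readIntersectionCounts(caseEulerCountsText(),
                                                     hasHeader = TRUE))
  a <- layoutEuler(part)
  b <- layoutEuler(part)
  expect_identical(a@centers, b@centers)
  expect_true(all(diff(a@stressTrace) <= 1e-12))
  # the three-way overlap is drawn as the smallest achieved area
  expect_equal(names(which.min(a@achievedAreas[a@achievedAreas > 0])),
               "GBM&NCCIT&eRMS")
  four <- generateCollection(4, 40, seed = 1)
  expect_error(layoutEuler(exclusiveRegions(four)), "2 or 3 sets")
})

test_that("euler scenes label every non-empty region inside the region", {
  part <- partitionFromCounts(readIntersectionCounts(caseEulerCountsText(),
                                                     hasHeader = TRUE))
  lay <- layoutEuler(part)
  scene <- eulerScene(lay, part)
  prim <- scenePrimitives(scene)
  texts <- prim[vapply(prim, function(p) p$kind == "text", logical(1))]
  labels <- setLabels(part)
  countTexts <- texts[vapply(texts, function(p) grepl("^[0-9]+$", p$text), logical(1))]
  # the label multiset equals the input count column
  expect_setequal(vapply(countTexts, `[[`, character(1), "text"),
                  as.character(regionCounts(part)))
  # each count label point lies inside exactly its region
  for (p in countTexts) {
    sig <- names(which(regionCounts(part) == as.integer(p$text)))[1]
    inside <- vapply(seq_along(lay@radii), function(i) {
      (p$x - lay@centers[i, 1])^2 + (p$y - lay@centers[i, 2])^2 <= lay@radii[i]^2
    }, logical(1))
    expect_identical(paste(labels[inside], collapse = "&"), sig)
  }
})
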