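test_that("upset columns enumerate, sort and total correctly", {
  coll <- SetCollection(list(`1` = "A", `2` = c("A", "B"), `3` = c("A", "B", "C")),
                        setLabels = c("A", "B", "C"))
  mat <- buildUpSetMatrix(exclusiveRegions(coll))
  expect_identical(signatures(mat), c("A", "A&B", "A&B&C"))
  expect_identical(unname(regionCounts(mat)), c(1L, 1L, 1L))
  expect_identical(unname(mat@setTotals), c(3, 2, 1))

  disjoint <- SetCollection(structure(as.list(LETTERS[1:5]),
                                      names = paste0("e", 1:5)),
                            setLabels = LETTERS[1:5])
  full <- buildUpSetMatrix(exclusiveRegions(disjoint), keepEmpty = TRUE)
  expect_length(signatures(full), 31)
  expect_equal(sum(regionCounts(full) == 0), 26)

  expect_error(buildUpSetMatrix(exclusiveRegions(generateCollection(2, 10, seed = 1))),
               "3 to 40")
  expect_error(buildUpSetMatrix(exclusiveRegions(generateCollection(13, 30, seed = 1)),
                                keepEmpty = TRUE), "capped at 12")
})

test_that("column order is total and stable under input shuffling", {
  for (seed in 1:10) {
    coll <- randomCollection(seed, maxSets = 5L, maxElements = 60L)
    if (nSets(coll) < 3) next
    part <- exclusiveRegions(coll)
    mat <- buildUpSetMatrix(part)
    # conservation
    expect_equal(sum(regionCounts(mat)), length(membershipList(coll)))
    # rebuild from shuffled membership
    memb <- membershipList(coll)
    set.seed(seed)
    shuffled <- SetCollection(memb[sample(names(memb))],
                              setLabels = setLabels(coll))
    mat2 <- buildUpSetMatrix(exclusiveRegions(shuffled))
    expect_identical(signatures(mat), signatures(mat2))
    # sort contract: count desc, degree asc, signature
    cnt <- unname(regionCounts(mat))
    deg <- lengths(strsplit(signatures(mat), "&", fixed = TRUE))
    key <- order(-cnt, deg, signatures(mat), method = "radix")
    expect_identical(key, seq_along(cnt))
    # horizontal bars = per-set sums of member columns
    for (j in seq_along(setLabels(coll))) {
      s <- setLabels(coll)[j]
      member <- vapply(strsplit(signatures(mat), "&", fixed = TRUE),
                       function(x) s %in% x, logical(1))
      expect_equal(mat@setTotals[j], sum(regionCounts(mat)[member]))
    }
  }
})

test_that("upset scenes carry k dots and k - 1 connectors per column", {
  for (seed in 1:5) {
    coll <- randomCollection(seed + 20, maxSets = 6L, maxElements = 50L)
    if (nSets(coll) < 3) next
    mat <- buildUpSetMatrix(exclusiveRegions(coll))
    scene <- upsetScene(mat)
    prims <- scenePrimitives(scene)
    lines <- sum(vapply(prims, function(p) p$kind == "line", logical(1)))
    degrees <- lengths(strsplit(signatures(mat), "&", fixed = TRUE))
    expect_equal(lines, sum(degrees - 1L))
    # filled dots = sum of degrees; total dots = n per column
    dots <- prims[vapply(prims, function(p) p$kind == "circle", logical(1))]
    filled <- sum(vapply(dots, function(p) p$fill == "#1A1A1A", logical(1)))
    expect_equal(filled, sum(degrees))
    expect_length(dots, nSets(coll) * length(signatures(mat)))
    # counts printed above bars
    txt <- vapply(prims[vapply(prims, function(p) p$kind == "text", logical(1))],
                  `[[`, character(1), "text")
    expect_true(all(as.character(regionCounts(mat)) %in% txt))
  }
})
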