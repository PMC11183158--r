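test_that("classic and Edwards templates realize all interior cells", {
  for (mode in c("classic", "edwards")) {
    for (n in 2:6) {
      t <- if (mode == "classic") classicTemplate(n) else edwardsTemplate(n)
      cc <- templateCellCounts(t, 350)
      expect_equal(sum(cc > 0), 2^n - 1,
                   info = paste(mode, n, "cells"))
    }
  }
  expect_error(classicTemplate(7), "2 to 6")
  expect_error(edwardsTemplate(1), "2 to 6")
})

test_that("smallest template cell stays above its documented area floor", {
  res <- 500L
  for (n in 2:5) {
    cc <- templateCellCounts(classicTemplate(n), res)
    expect_gt(min(cc) / res^2, 0.002, label = paste("classic", n, "min cell"))
    ce <- templateCellCounts(edwardsTemplate(n), res)
    expect_gt(min(ce) / res^2, 0.002, label = paste("edwards", n, "min cell"))
  }
  # six-set constructions carry intrinsic sliver cells; documented floors
  cc <- templateCellCounts(classicTemplate(6), res)
  expect_gt(min(cc) / res^2, 5e-5)
  ce <- templateCellCounts(edwardsTemplate(6), res)
  expect_gt(min(ce) / res^2, 5e-4)
})

test_that("every region label lies inside its region", {
  for (mode in c("classic", "edwards")) {
    for (n in c(2, 4, 6)) {
      t <- if (mode == "classic") classicTemplate(n) else edwardsTemplate(n)
      labels <- LETTERS[seq_len(n)]
      pos <- regionLabelPositions(t, labels, resolution = 400L)
      for (sig in names(pos)) {
        code <- templateCode(t, pos[[sig]][1], pos[[sig]][2])
        expect_equal(code, sigBit(sig, labels),
                     info = paste(mode, n, sig))
      }
    }
  }
})

test_that("raising the resolution never moves a label out of its region", {
  t <- classicTemplate(3)
  labels <- c("A", "B", "C")
  lo <- regionLabelPositions(t, labels, resolution = 200L)
  hi <- regionLabelPositions(t, labels, resolution = 500L)
  for (sig in names(hi)) {
    expect_equal(templateCode(t, hi[[sig]][1], hi[[sig]][2]),
                 sigBit(sig, labels))
    expect_equal(templateCode(t, lo[[sig]][1], lo[[sig]][2]),
                 sigBit(sig, labels))
  }
})

test_that("venn scenes print the exclusive counts, identically in both modes", {
  # five-set metabolite reconstruction: 119 in the 5-way region, 0 for FS4
  coll <- caseMetaboliteCollection()
  part <- exclusiveRegions(coll)
  for (mode in c("classic", "edwards")) {
    scene <- vennScene(part, mode = mode)
    prims <- scenePrimitives(scene)
    texts <- vapply(prims[vapply(prims, function(p) p$kind == "text", logical(1))],
                    `[[`, character(1), "text")
    counts <- texts[grepl("^[0-9]+$", texts)]
    expect_length(counts, 31)
    expect_true("119" %in% counts)
    expect_equal(sum(counts == "0"), 31 - length(regionCounts(part)))
  }
  # label multisets equal the venn calculator output for random collections
  for (seed in 1:5) {
    coll <- randomCollection(seed, maxSets = 4L, maxElements = 50L)
    if (nSets(coll) < 2) next
    calc <- vennCalculator(coll)
    sceneC <- vennScene(exclusiveRegions(coll), mode = "classic")
    sceneE <- vennScene(exclusiveRegions(coll), mode = "edwards")
    getCounts <- function(scene) {
      prims <- scenePrimitives(scene)
      txt <- vapply(prims[vapply(prims, function(p) p$kind == "text", logical(1))],
                    `[[`, character(1), "text")
      sort(txt[grepl("^[0-9]+$", txt)])
    }
    expect_identical(getCounts(sceneC), sort(as.character(calc$exclusive)))
    expect_identical(getCounts(sceneC), getCounts(sceneE))
  }
  expect_error(vennScene(exclusiveRegions(generateCollection(7, 30, seed = 1))),
               "at most 6")
})
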