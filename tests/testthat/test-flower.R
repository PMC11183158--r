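test_that("flower values select unique or residual petals", {
  same <- SetCollection(list(x = LETTERS[1:4], y = LETTERS[1:4]),
                        setLabels = LETTERS[1:4])
  for (mode in c("unique", "residual")) {
    spec <- flowerValues(same, mode)
    expect_equal(spec@coreValue, 2L)
    expect_true(all(spec@petalValues == 0L))
  }
  for (seed in 1:10) {
    coll <- randomCollection(seed, maxSets = 6L, maxElements = 60L)
    if (nSets(coll) < 3) next
    res <- flowerValues(coll, "residual")
    expect_equal(unname(res@petalValues + res@coreValue),
                 unname(setSizes(coll)))
    uq <- flowerValues(coll, "unique")
    part <- exclusiveRegions(coll)
    for (k in seq_along(uq@petalSets)) {
      s <- uq@petalSets[k]
      expected <- if (s %in% names(regionCounts(part)))
        regionCounts(part)[[s]] else 0L
      expect_equal(uq@petalValues[k], expected)
    }
  }
  expect_error(flowerValues(SetCollection(list(x = "A"))), "at least 3")
})

test_that("flower scenes place petals at 2*pi*k/n with matching labels", {
  coll <- generateCollection(4, 60, coreFraction = 0.3, uniqueFraction = 0.3,
                             seed = 5)
  spec <- flowerValues(coll, "unique")
  scene <- flowerScene(spec)
  prims <- scenePrimitives(scene)
  petals <- prims[vapply(prims, function(p) p$kind == "ellipse", logical(1))]
  expect_length(petals, 4)
  angles <- vapply(petals, function(p) atan2(p$cy, p$cx) %% (2 * pi), numeric(1))
  expect_equal(sort(angles), c(0, pi / 2, pi, 3 * pi / 2), tolerance = 1e-9)
  txt <- vapply(prims[vapply(prims, function(p) p$kind == "text", logical(1))],
                `[[`, character(1), "text")
  expect_true(all(as.character(spec@petalValues) %in% txt))
  expect_true(as.character(spec@coreValue) %in% txt)
  expect_true(all(spec@petalSets %in% txt))
})

test_that("a 70-petal scene keeps set-name labels from overlapping", {
  sets <- sprintf("G%02d", 1:70)
  memb <- c(list(core1 = sets, core2 = sets),
            structure(lapply(1:70, function(i) sets[i]),
                      names = paste0("u", 1:70)))
  spec <- flowerValues(SetCollection(memb, setLabels = sets), "unique")
  scene <- flowerScene(spec)
  prims <- scenePrimitives(scene)
  nameTexts <- prims[vapply(prims, function(p) {
    p$kind == "text" && p$text %in% sets
  }, logical(1))]
  expect_length(nameTexts, 70)
  boxes <- t(vapply(nameTexts, function(p) {
    w <- 0.62 * p$size * nchar(p$text); h <- p$size
    # rotated label: conservative axis-aligned bound
    cw <- abs(cos(p$rot)) * w + abs(sin(p$rot)) * h
    ch <- abs(sin(p$rot)) * w + abs(cos(p$rot)) * h
    c(p$x - cw / 2, p$y - ch / 2, p$x + cw / 2, p$y + ch / 2)
  }, numeric(4)))
  for (i in 1:69) for (j in (i + 1):70) {
    sep <- boxes[i, 3] <= boxes[j, 1] || boxes[j, 3] <= boxes[i, 1] ||
      boxes[i, 4] <= boxes[j, 2] || boxes[j, 4] <= boxes[i, 2]
    if (!sep) fail(sprintf("labels %d and %d overlap", i, j))
  }
  succeed()
})
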