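test_that("canonical signatures sort by set order and are idempotent", {
  expect_identical(canonicalSignature(c("B", "A"), c("A", "B", "C")), "A&B")
  expect_identical(
    canonicalSignature(c("FS5", "FS1", "FS3", "FS2", "FS4"), paste0("FS", 1:5)),
    "FS1&FS2&FS3&FS4&FS5")
  expect_error(canonicalSignature("X", c("A", "B")), "unknown set")
  for (seed in 1:20) {
    set.seed(seed)
    order <- LETTERS[1:6]
    sub <- sample(order, sample(6, 1))
    sig <- canonicalSignature(sub, order)
    expect_identical(canonicalSignature(parseSignature(sig), order), sig)
  }
})

test_that("exclusive regions assign each element to its full signature", {
  x <- SetCollection(list(x = "A", y = "A", z = c("A", "B")),
                     setLabels = c("A", "B"))
  part <- exclusiveRegions(x)
  expect_identical(regionCounts(part), c(A = 2L, `A&B` = 1L))
  expect_identical(regionElements(part)$A, c("x", "y"))
  empty <- exclusiveRegions(SetCollection(list(), setLabels = character()))
  expect_length(regionCounts(empty), 0)
})

test_that("venn calculator reports all signatures in both semantics", {
  x <- SetCollection(list(x = c("A", "B")), setLabels = c("A", "B", "C"))
  calc <- vennCalculator(x)
  expect_equal(nrow(calc), 7L)
  expect_equal(calc$inclusive[calc$signature == "A&B"], 1L)
  expect_equal(calc$exclusive[calc$signature == "A"], 0L)
  expect_equal(calc$inclusive[calc$signature == "A"], 1L)
  # inclusive = sum of exclusive over supersets, random collections
  for (seed in 1:25) {
    coll <- randomCollection(seed, maxSets = 5L, maxElements = 60L)
    calc <- vennCalculator(coll)
    labels <- setLabels(coll)
    sets <- strsplit(calc$signature, "&", fixed = TRUE)
    for (i in seq_len(nrow(calc))) {
      sup <- vapply(sets, function(s) all(sets[[i]] %in% s), logical(1))
      expect_equal(calc$inclusive[i], sum(calc$exclusive[sup]))
    }
  }
})

test_that("inclusive sizes equal direct set intersections", {
  for (seed in 1:25) {
    coll <- randomCollection(seed, maxSets = 5L, maxElements = 80L)
    part <- exclusiveRegions(coll)
    labels <- setLabels(coll)
    set.seed(seed + 1000)
    sub <- sample(labels, sample(length(labels), 1))
    expect_equal(inclusiveSize(part, sub), bruteInclusive(coll, sub))
  }
  part <- exclusiveRegions(SetCollection(list(x = "A"), setLabels = c("A", "B")))
  expect_error(inclusiveSize(part, "Z"), "unknown set")
})

test_that("count-table partitions copy exclusive and invert inclusive counts", {
  exc <- partitionFromCounts(IntersectionCountTable(c(A = 2, `A&B` = 1)))
  expect_identical(regionCounts(exc), c(A = 2L, `A&B` = 1L))
  inc <- partitionFromCounts(
    IntersectionCountTable(c(A = 3, B = 2, `A&B` = 1), semantics = "inclusive"))
  expect_identical(regionCounts(inc), c(A = 2L, B = 1L, `A&B` = 1L))
  expect_error(
    partitionFromCounts(
      IntersectionCountTable(c(A = 1, `A&B` = 2), semantics = "inclusive")),
    "inconsistent.*'A'")
})

test_that("flower decomposition conserves residual + core = set size", {
  same <- SetCollection(list(x = c("A", "B"), y = c("A", "B")))
  dec <- flowerDecomposition(same)
  expect_equal(dec$core, 2L)
  expect_true(all(dec$unique == 0L) && all(dec$residual == 0L))
  for (seed in 1:20) {
    coll <- randomCollection(seed, maxSets = 6L, maxElements = 80L)
    dec <- flowerDecomposition(coll)
    expect_equal(unname(dec$residual + dec$core), unname(setSizes(coll)))
  }
})

test_that("generated collections honour composition and determinism", {
  allcore <- generateCollection(4, 30, coreFraction = 1, uniqueFraction = 0, seed = 3)
  expect_true(all(lengths(membershipList(allcore)) == 4L))
  a <- generateCollection(3, 100, 0.3, 0.3, seed = 11)
  b <- generateCollection(3, 100, 0.3, 0.3, seed = 11)
  expect_identical(membershipList(a), membershipList(b))
  big <- generateCollection(4, 10000, coreFraction = 0.25, uniqueFraction = 0.25,
                            seed = 7)
  core <- sum(lengths(membershipList(big)) == 4L)
  # realized core within 4 sd of Binomial(10000, 0.25); non-core full
  # memberships are possible but rare (p = 1/16 of the remaining half)
  expect_gt(core, 2500 - 4 * sqrt(10000 * 0.25 * 0.75))
  expect_lt(core, 2500 + 4 * sqrt(10000 * 0.25 * 0.75) + 0.5 * 10000 / 16 + 100)
  expect_error(generateCollection(0, 10), "nSets")
})
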