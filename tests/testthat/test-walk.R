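test_that("site classification follows the walk's null orientation", {
  # primary == ortholog != paralog: the expected (null) state -> up
  expect_identical(classifySite("A", "C", "A"), "up")
  # primary == paralog != ortholog: conversion homogenisation -> down
  expect_identical(classifySite("A", "A", "C"), "down")
  expect_identical(classifySite("A", "A", "A"), "neutral")
  expect_identical(classifySite("A", "C", "G"), "neutral")
  expect_identical(classifySite("A", "C", "C"), "neutral")
})

test_that("triplet walks skip gaps, ambiguity and uncovered columns", {
  paralog <- makeParalog("ACGTACGTAC", "ACGTACGTAC")
  proj <- strsplit("ACGTTCGTAC", "")[[1]]
  w <- buildTripletWalk(paralog, proj, 1)
  # the one homogenised site (primary==paralog, ortholog differs) steps down
  expect_identical(c(w@m, w@n), c(0L, 1L))
  expect_identical(w@column, 5L)
  expect_identical(w@step, -1L)

  # identical triple: no informative sites
  w0 <- buildTripletWalk(paralog, strsplit("ACGTACGTAC", "")[[1]], 1)
  expect_identical(c(w0@m, w0@n), c(0L, 0L))

  # entirely uncovered projection: empty walk
  we <- buildTripletWalk(paralog, rep(NA_character_, 10), 1)
  expect_length(we@column, 0)

  # gap and N columns are non-informative
  pg <- makeParalog("AC-TAN", "ACTTAC")
  wg <- buildTripletWalk(pg, strsplit("GGGGGG", "")[[1]], 1)
  expect_false(any(wg@column %in% c(3L, 6L)))
})

test_that("quadruplet combination adds magnitudes and rejects contradictions", {
  w1 <- makeWalk(upCols = c(2, 5), downCols = 8, totalColumns = 10)
  w2 <- makeWalk(upCols = 2, downCols = c(8, 9), totalColumns = 10)
  comb <- combineQuadruplet(w1, w2)
  expect_identical(comb@column, c(2L, 5L, 8L, 9L))
  expect_identical(comb@magnitude, c(2L, 1L, 2L, 1L))
  expect_identical(c(comb@m, comb@n), c(3L, 3L))

  # combining with an empty walk is the identity
  we <- makeWalk(integer(0), integer(0), 10)
  expect_equal(combineQuadruplet(w1, we), w1)

  # combining a walk with itself doubles magnitudes and (m, n)
  dbl <- combineQuadruplet(w1, w1)
  expect_identical(dbl@magnitude, rep(2L, 3))
  expect_identical(c(dbl@m, dbl@n), c(2L * w1@m, 2L * w1@n))

  wup <- makeWalk(upCols = 4, downCols = integer(0), totalColumns = 10)
  wdn <- makeWalk(upCols = integer(0), downCols = 4, totalColumns = 10)
  expect_error(combineQuadruplet(wup, wdn), "does not occur")
})

test_that("maximum descent finds the leftmost deepest peak-to-trough drop", {
  # UUDD: walk 0,1,2,1,0 -> k=2 over the two down steps
  w <- makeWalk(upCols = c(1, 2), downCols = c(3, 4), totalColumns = 4)
  d <- maximumDescent(w)
  expect_identical(d$k, 2L)
  expect_identical(c(d$start_col, d$end_col), c(3L, 4L))

  # monotone up: no descent
  d2 <- maximumDescent(makeWalk(1:5, integer(0), 5))
  expect_identical(d2$k, 0L)

  # single down step
  d3 <- maximumDescent(makeWalk(integer(0), 3, 5))
  expect_identical(d3$k, 1L)
  expect_identical(c(d3$start_col, d3$end_col), c(3L, 3L))

  # tie: DDUUDD has two depth-2 descents; the leftmost is reported
  d4 <- maximumDescent(makeWalk(upCols = c(3, 4), downCols = c(1, 2, 5, 6),
                                totalColumns = 6))
  expect_identical(d4$k, 2L)
  expect_identical(c(d4$start_col, d4$end_col), c(1L, 2L))

  # empty walk
  d5 <- maximumDescent(makeWalk(integer(0), integer(0), 5))
  expect_identical(d5$k, 0L)
})

test_that("walk invariants hold on random walks", {
  set.seed(7)
  for (i in 1:25) {
    nU <- sample(0:15, 1); nD <- sample(0:15, 1)
    cols <- sort(sample(1:200, nU + nD))
    up <- sample(cols, nU)
    w <- makeWalk(up, setdiff(cols, up), 200)
    sc <- cumulativeScore(w)
    final <- if (length(sc)) sc[length(sc)] else 0
    expect_identical(as.integer(final), w@m - w@n)
    expect_lte(maximumDescent(w)$k, w@n)
  }
})

test_that("the exact max-descent P-value matches enumeration on small walks", {
  for (m in 0:4) for (n in 0:4) {
    if (m + n == 0) next
    for (k in 0:(n + 1)) {
      expect_equal(maxDescentPValue(m, n, k), oracleDescentP(m, n, k),
                   tolerance = 1e-12,
                   info = sprintf("m=%d n=%d k=%d", m, n, k))
    }
  }
  expect_equal(maxDescentPValue(5, 0, 1), 0)
  expect_equal(maxDescentPValue(3, 2, 0), 1)
  expect_equal(maxDescentPValue(2, 2, 2), 0.5)
  expect_equal(maxDescentPValue(0, 4, 4), 1)
  expect_error(maxDescentPValue(-1, 2, 1), "non-negative")
})

test_that("the max-descent P-value is monotone in k and valid for large walks", {
  for (mn in list(c(10, 10), c(50, 40), c(300, 250))) {
    p <- vapply(0:mn[2], function(k) maxDescentPValue(mn[1], mn[2], k),
                numeric(1))
    expect_true(all(diff(p) <= 1e-12))
    expect_true(all(p >= 0 & p <= 1))
  }
  # beyond the ~400-informative-site regime of naive enumeration
  p <- maxDescentPValue(800, 700, 80)
  expect_true(p > 0 && p < 1)
})

test_that("the binomial whole-paralog P-value matches its closed form", {
  r <- binomialCoveragePValue(3, 1)
  expect_equal(r$p, 0.25)
  expect_equal(r$p_value, 1 - 0.75^4, tolerance = 1e-12)  # 0.68359375
  expect_equal(binomialCoveragePValue(7, 0)$p_value, 1)
  expect_equal(binomialCoveragePValue(7, 0)$p, 0)
  r2 <- binomialCoveragePValue(0, 5)
  expect_equal(r2$p, 0.5)
  expect_equal(r2$p_value, 0.5^5, tolerance = 1e-12)      # 0.03125
  expect_error(binomialCoveragePValue(0, 0), "informative")
})

test_that("direction is called toward the paralog whose ortholog lost the tract", {
  # walk1 (primary = row1): 0/20 down; walk2 (primary = row2): 9/20 down
  w1 <- makeWalk(upCols = 1:20, downCols = integer(0), totalColumns = 40)
  w2 <- makeWalk(upCols = 21:31, downCols = 32:40, totalColumns = 40)
  shared <- list(start_col = 1L, end_col = 40L)
  r <- inferDirection(w1, w2, shared)
  oracleP <- fisher.test(matrix(c(20, 0, 11, 9), nrow = 2))$p.value
  expect_equal(r$direction_p, oracleP)
  expect_lt(r$direction_p, 0.05)
  # row2's triplet has the higher down proportion: row2 is the recipient
  expect_identical(r$direction, "par1->par2")

  # identical proportions: unknown
  r2 <- inferDirection(w1, w1, shared)
  expect_identical(r2$direction, "unknown")

  # no informative sites in the shared interval for one triplet: unknown
  we <- makeWalk(integer(0), integer(0), 40)
  expect_identical(inferDirection(w1, we, shared)$direction, "unknown")
})
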