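test_that("boundary similarity uses reciprocal overlap", {
  expect_true(boundariesSimilar(0, 100, 0, 100))
  expect_false(boundariesSimilar(0, 100, 200, 300))
  # [0,100) vs [40,140): overlap 60 of 100 on both sides -> 0.6 >= 0.5
  expect_equal(reciprocalOverlap(0, 100, 40, 140), 0.6)
  expect_true(boundariesSimilar(0, 100, 40, 140))
  expect_false(boundariesSimilar(0, 100, 40, 140, tolerance = 0.7))
})

test_that("Type (a): similar boundaries across outgroups share one event, smallest P kept", {
  obs <- rbind(
    makeObs("A", "B", 1e-3, c(100, 400), c(0, 1000), c(2000, 3000)),
    makeObs("A", "C", 1e-5, c(110, 390), c(0, 1000), c(2000, 3000)),
    makeObs("A", "D", 1e-4, c(95, 410), c(0, 1000), c(2000, 3000)))
  d <- deduplicate(obs)
  expect_identical(length(unique(d$full$event_id)), 1L)
  expect_identical(nrow(d$nonredundant), 1L)
  expect_equal(d$nonredundant$p_value, 1e-5)

  # dissimilar boundaries: separate, repeated conversions
  obs2 <- rbind(
    makeObs("A", "B", 1e-3, c(100, 300), c(0, 1000), c(2000, 3000)),
    makeObs("A", "B", 1e-4, c(600, 900), c(0, 1000), c(2000, 3000)))
  d2 <- deduplicate(obs2)
  expect_identical(nrow(d2$nonredundant), 2L)

  # single observation -> single event
  d3 <- deduplicate(makeObs("A", "B", 0.01, c(0, 50), c(0, 100), c(100, 200)))
  expect_identical(nrow(d3$nonredundant), 1L)
})

test_that("Type (b): merges across primaries only with matching outgroup and orthologous pairs", {
  tx <- strrep("ACGT", 250)
  orthology <- list(
    makeOrtholog(tx, tx, "A", "B", start1 = 0, start2 = 0),
    makeOrtholog(tx, tx, "A", "B", start1 = 2000, start2 = 2000))
  obsA <- makeObs("A", "C", 1e-4, c(100, 400), c(0, 1000), c(2000, 3000))
  obsB <- makeObs("B", "C", 1e-6, c(100, 400), c(0, 1000), c(2000, 3000))
  d <- deduplicate(rbind(obsA, obsB), orthology)
  expect_identical(nrow(d$nonredundant), 1L)
  expect_equal(d$nonredundant$p_value, 1e-6)

  # different outgroups: never merged by Type (b)
  obsB2 <- makeObs("B", "D", 1e-6, c(100, 400), c(0, 1000), c(2000, 3000))
  d2 <- deduplicate(rbind(obsA, obsB2), orthology)
  expect_identical(nrow(d2$nonredundant), 2L)

  # no orthology between the primaries: no merging
  d3 <- deduplicate(rbind(obsA, obsB), list())
  expect_identical(nrow(d3$nonredundant), 2L)
})

test_that("Type (c) similarity arbitration follows the S-rule", {
  expect_identical(classifyTypeC(0.99, 0.95, 0.95), "before-duplication")
  expect_identical(classifyTypeC(0.90, 0.99, 0.92), "pairwise-1")
  expect_identical(classifyTypeC(0.90, 0.92, 0.99), "pairwise-2")
  expect_warning(r <- classifyTypeC(0.95, 0.95, 0.90), "tie")
  expect_identical(r, "before-duplication")
})

test_that("Type (c): shared-target observations are arbitrated from sequence similarity", {
  set.seed(11)
  L <- 1000; tract <- 201:700
  x <- randSeq(L)

  buildCluster <- function(a1, a2, a3) {
    seqs <- list(a1 = a1, a2 = a2, a3 = a3)
    starts <- c(a1 = 0, a2 = 1000, a3 = 2000)
    mk <- function(p, q) {
      alignedPair("A", "A", starts[p], starts[p] + L, "+",
                  paste(seqs[[p]], collapse = ""),
                  "A", "A", starts[q], starts[q] + L, "+",
                  paste(seqs[[q]], collapse = ""),
                  kind = "paralog", srcLen1 = 3000, srcLen2 = 3000)
    }
    list(mk("a1", "a2"), mk("a1", "a3"), mk("a2", "a3"))
  }
  convIv <- c(2200, 2700)          # tract on A3 in genomic coordinates

  # actual conversion A1 <-> A3, with A2 a post-conversion-like duplicate of
  # A1 that drifted: S2 should be maximal and the A2->A3 observation dropped
  a1 <- x
  a3 <- mutateSeq(x, 0.15); a3[tract] <- mutateSeq(a1[tract], 0.01)
  a2 <- mutateSeq(a1, 0.06)
  pal <- buildCluster(a1, a2, a3)
  obs1 <- makeObs("A", "B", 1e-8, c(200, 700), c(0, 1000), c(2000, 3000),
                  conv2 = convIv)
  obs2 <- makeObs("A", "B", 1e-5, c(1200, 1700), c(1000, 2000),
                  c(2000, 3000), conv2 = convIv)
  d <- deduplicate(rbind(obs1, obs2), list(), pal)
  expect_identical(length(unique(d$full$event_id)), 1L)
  expect_identical(d$full$inferred_case[1], "pairwise-1")
  expect_identical(d$full$kept, c(TRUE, FALSE))
  expect_equal(d$nonredundant$p_value, 1e-8)

  # conversion before the A1/A2 duplication: S1 maximal, both observations
  # kept under one event id, minimum P as representative
  set.seed(12)
  x <- randSeq(L)
  a3anc <- mutateSeq(x, 0.15)
  anc <- x; anc[tract] <- a3anc[tract]
  a3 <- mutateSeq(a3anc, 0.05)
  a1 <- mutateSeq(anc, 0.02)
  a2 <- mutateSeq(anc, 0.02)
  pal <- buildCluster(a1, a2, a3)
  d2 <- deduplicate(rbind(obs1, obs2), list(), pal)
  expect_identical(length(unique(d2$full$event_id)), 1L)
  expect_identical(d2$full$inferred_case[1], "before-duplication")
  expect_identical(d2$full$kept, c(TRUE, TRUE))
  expect_equal(d2$nonredundant$p_value, 1e-8)

  # dissimilar boundaries on the shared target: two separate events
  obs2far <- makeObs("A", "B", 1e-5, c(1000, 1180), c(1000, 2000),
                     c(2000, 3000), conv2 = c(2000, 2180))
  d3 <- deduplicate(rbind(obs1, obs2far), list(), pal)
  expect_identical(nrow(d3$nonredundant), 2L)
})

test_that("deduplication is idempotent and bijective without redundancy", {
  obs <- rbind(
    makeObs("A", "B", 1e-3, c(100, 400), c(0, 1000), c(2000, 3000)),
    makeObs("A", "B", 1e-4, c(600, 900), c(0, 1000), c(2000, 3000)),
    makeObs("B", "C", 1e-5, c(0, 200), c(0, 1000), c(2000, 3000)))
  d1 <- deduplicate(obs)
  expect_identical(nrow(d1$nonredundant), 3L)          # bijection
  expect_identical(sort(unique(d1$full$event_id)), 1:3)
  d2 <- deduplicate(d1$full[, setdiff(names(d1$full),
                                      c("event_id", "kept",
                                        "inferred_case"))])
  expect_identical(d2$full$event_id, d1$full$event_id)
  expect_identical(d2$nonredundant$p_value, d1$nonredundant$p_value)

  # empty input -> empty output
  d0 <- deduplicate(emptyObs <- makeObs("A", "B", 1, c(0, 1), c(0, 1),
                                        c(1, 2))[0, ])
  expect_identical(nrow(d0$full), 0L)
  expect_identical(nrow(d0$nonredundant), 0L)
})
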