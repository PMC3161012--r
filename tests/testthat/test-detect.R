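test_that("criterion routing follows the strict 80% coverage rule", {
  # descent spanning 85 of 100 columns -> whole-paralog criterion candidate
  w <- makeWalk(upCols = 1:10, downCols = 11:95, totalColumns = 100)
  d <- maximumDescent(w)
  expect_identical(selectCriterion(w, d, 0.80), "criterion2_candidate")

  # 30% coverage -> ordinary max-descent criterion
  w2 <- makeWalk(upCols = c(1:30, 61:100), downCols = 31:60,
                 totalColumns = 100)
  d2 <- maximumDescent(w2)
  expect_identical(selectCriterion(w2, d2, 0.80), "criterion1")

  # exactly 80%: "over 80%" read strictly -> criterion 1
  w3 <- makeWalk(upCols = c(1:10, 91:100), downCols = 11:90,
                 totalColumns = 100)
  d3 <- maximumDescent(w3)
  expect_equal((d3$end_col - d3$start_col + 1) / w3@totalColumns, 0.80)
  expect_identical(selectCriterion(w3, d3, 0.80), "criterion1")

  # too few informative sites
  w4 <- makeWalk(1:3, 4:5, 100)
  expect_identical(selectCriterion(w4, maximumDescent(w4), 0.80, 10),
                   "rejected")
})

test_that("distinct-ortholog gating distinguishes pre- from post-speciation duplications", {
  paralog <- makeParalog(strrep("ACGT", 25), strrep("ACGT", 25),
                         start1 = 0, start2 = 500)
  tx <- strrep("ACGT", 25)
  # disjoint outgroup intervals -> distinct
  o1 <- makeOrtholog(tx, tx, start1 = 0, start2 = 100)
  o2 <- makeOrtholog(tx, tx, start1 = 500, start2 = 500)
  expect_true(distinctOrthologs(paralog, list(o1, o2), "B"))
  # both paralogs mapping to one outgroup region -> not distinct
  o2same <- makeOrtholog(tx, tx, start1 = 500, start2 = 100)
  expect_false(distinctOrthologs(paralog, list(o1, o2same), "B"))
  # one paralog without any ortholog -> not distinct
  expect_false(distinctOrthologs(paralog, list(o1), "B"))
})

test_that("Bonferroni cutoff arithmetic", {
  expect_equal(significanceCutoff(1, 0.05), 0.05)
  expect_equal(significanceCutoff(100, 0.05), 5e-4)
  expect_error(significanceCutoff(0, 0.05))
})

test_that("an implanted conversion yields one observation overlapping the truth", {
  out <- runScenario(implantScenario(seed = 101, start = 700))
  sim <- out$sim; res <- out$res
  tr <- sim$truth[sim$truth$kind == "conversion", ]
  obsA <- res$observations[res$observations$primary_species == "A", ]
  expect_gte(nrow(obsA), 1)
  # recipient paralog id 2 sits at offset 2000 in A; donor id 1 at 0
  hit <- any(
    vapply(seq_len(nrow(obsA)), function(i)
      reciprocalOverlap(obsA$conv_start[i], obsA$conv_end[i],
                        tr$start, tr$end) >= 0.5, logical(1)))
  expect_true(hit)
  ev <- evaluateDetection(res$events_nr, sim)
  expect_equal(ev$sensitivity, 1)
  expect_equal(ev$fdr, 0)
})

test_that("a null cluster produces no observation at the corrected level", {
  out <- runScenario(nullScenario(seed = 202))
  expect_identical(nrow(out$res$observations), 0L)
  expect_gt(out$res$manifest$n_tests_attempted, 0)
})

test_that("a whole-paralog conversion is recovered via criterion 2, gated on distinct orthologs", {
  out <- runScenario(implantScenario(seed = 303, tract = 2000L,
                                     root_length = 2000, start = 0))
  obs <- out$res$observations
  expect_gte(nrow(obs), 1)
  expect_true(any(obs$criterion == 2))

  # recent (post-speciation) duplication: paralogs lack distinct orthologs,
  # so the whole-length descent pattern must NOT become a criterion-2 call
  cfgDupA <- simConfig("((A:0.03,B:0.03):0.03,C:0.06);", root_length = 1500,
                       stem_length = 0, stem_duplications = 0,
                       dup_rate = 0, conv_rate = 0, seed = 404)
  simD <- simulateCluster(cfgDupA)
  # manufacture the recent pair directly: duplicate A's single paralog
  seqA <- simD$sequences[["A"]]
  paralog <- alignedPair("A", "A", 0, 1500, "+", seqA,
                         "A", "A", 1500, 3000, "+", seqA,
                         kind = "paralog", srcLen1 = 3000, srcLen2 = 3000)
  # only paralog 1 has an ortholog in B (the duplication is A-specific)
  orthAB <- Filter(function(a) a@species2 == "B" || a@species1 == "B",
                   simD$orthology)
  res <- scanCluster(list(paralog), orthAB, speciesTree(simD$tree))
  expect_identical(sum(res$observations$criterion == 2), 0L)
})

test_that("cluster scans iterate primaries and outgroups and validate species", {
  out <- runScenario(nullScenario(seed = 505))
  # 3 species x 1 pair x 2 outgroups
  expect_identical(out$res$manifest$n_tests_attempted, 6L)

  sim <- simulateCluster(nullScenario(seed = 506))
  tree <- speciesTree(sim$tree)
  badAln <- sim$paralogAlns[[1]]
  badAln@species1 <- "Z"; badAln@species2 <- "Z"
  expect_error(scanCluster(list(badAln), sim$orthology, tree), "Z")

  soloTree <- speciesTree(ape::read.tree(text = "(A:1);"))
  expect_warning(res <- scanCluster(sim$paralogAlns[1], list(), soloTree),
                 "outgroup")
  expect_identical(nrow(res$observations), 0L)
})

test_that("detection is invariant under reverse-complementing one species' cluster", {
  out <- runScenario(implantScenario(seed = 607, start = 700))
  sim <- out$sim
  L <- 2L * sim$root_length  # two paralogs per species
  # on the reverse-complemented cluster, a forward block [s,e)+ becomes the
  # mirrored minus-strand block [L-e,L-s)- with unchanged aligned text; the
  # constructor then renormalises row 1 back to plus strand
  flipA <- function(aln) {
    s1 <- aln@start1; e1 <- aln@end1; st1 <- aln@strand1
    s2 <- aln@start2; e2 <- aln@end2; st2 <- aln@strand2
    if (aln@species1 == "A") {
      s1 <- L - aln@end1; e1 <- L - aln@start1
      st1 <- if (st1 == "+") "-" else "+"
    }
    if (aln@species2 == "A") {
      s2 <- L - aln@end2; e2 <- L - aln@start2
      st2 <- if (st2 == "+") "-" else "+"
    }
    alignedPair(aln@species1, aln@chrom1, s1, e1, st1, aln@text1,
                aln@species2, aln@chrom2, s2, e2, st2, aln@text2,
                kind = aln@kind, srcLen1 = aln@srcLen1,
                srcLen2 = aln@srcLen2)
  }
  pal2 <- lapply(sim$paralogAlns, function(a)
    if (a@species1 == "A") flipA(a) else a)
  ort2 <- lapply(sim$orthology, function(a)
    if (a@species1 == "A" || a@species2 == "A") flipA(a) else a)
  tree <- speciesTree(sim$tree)
  r1 <- runPipeline(sim$paralogAlns, sim$orthology, tree)
  r2 <- runPipeline(pal2, ort2, tree)
  expect_identical(nrow(r1$observations), nrow(r2$observations))
  expect_equal(sort(r1$observations$p_value), sort(r2$observations$p_value))
  len1 <- r1$observations$conv_end - r1$observations$conv_start
  len2 <- r2$observations$conv_end - r2$observations$conv_start
  expect_identical(sort(len1), sort(len2))
})
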