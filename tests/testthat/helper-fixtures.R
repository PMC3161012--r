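# Shared fixtures: hand-built alignments and standard simulation scenarios.

# gapless paralog pair within one species
makeParalog <- function(text1, text2, species = "A", chrom = "A",
                        start1 = 0, start2 = 1000, srcLen = 4000) {
  u1 <- nchar(gsub("-", "", text1)); u2 <- nchar(gsub("-", "", text2))
  alignedPair(species, chrom, start1, start1 + u1, "+", text1,
              species, chrom, start2, start2 + u2, "+", text2,
              kind = "paralog", srcLen1 = srcLen, srcLen2 = srcLen)
}

makeOrtholog <- function(text1, text2, species1 = "A", species2 = "B",
                         start1 = 0, start2 = 0, srcLen = 4000) {
  u1 <- nchar(gsub("-", "", text1)); u2 <- nchar(gsub("-", "", text2))
  alignedPair(species1, species1, start1, start1 + u1, "+", text1,
              species2, species2, start2, start2 + u2, "+", text2,
              kind = "ortholog", srcLen1 = srcLen, srcLen2 = srcLen)
}

# walk with explicit up/down step columns
makeWalk <- function(upCols, downCols, totalColumns) {
  cols <- sort(c(upCols, downCols))
  conversionWalk <- getFromNamespace("conversionWalk", "paraconv")
  conversionWalk(cols, ifelse(cols %in% upCols, 1L, -1L),
                 rep(1L, length(cols)), totalColumns)
}

# brute-force maximum-descent P-value by enumerating all step orderings
oracleDescentP <- function(m, n, k) {
  if (k == 0) return(1)
  if (n == 0) return(0)
  total <- choose(m + n, n)
  combos <- utils::combn(m + n, n)
  hits <- 0
  for (i in seq_len(ncol(combos))) {
    s <- rep(1, m + n); s[combos[, i]] <- -1
    S <- c(0, cumsum(s))
    if (max(cummax(S) - S) >= k) hits <- hits + 1
  }
  hits / total
}

# hand-built observation row in the detector's output schema
makeObs <- function(primary, outgroup, p, conv, pair1, pair2, conv2 = conv,
                    chrom = primary, criterion = 1L, direction = "unknown") {
  data.frame(obs_id = NA_integer_, primary_species = primary, chrom = chrom,
             par1_start = pair1[1], par1_end = pair1[2],
             par2_start = pair2[1], par2_end = pair2[2],
             outgroup = outgroup, conv_start = conv[1], conv_end = conv[2],
             conv2_start = conv2[1], conv2_end = conv2[2],
             direction = direction, p_value = p, criterion = criterion,
             m = 10L, n = 10L, k = 5L, informative_sites = 20L,
             quadruplet = FALSE, out_chrom = NA_character_,
             out_start = NA_integer_, out_end = NA_integer_,
             stringsAsFactors = FALSE)
}

# random sequence and point-mutation helpers for constructed fixtures
randSeq <- function(n) sample(c("A", "C", "G", "T"), n, replace = TRUE)
mutateSeq <- function(x, p) {
  hit <- which(runif(length(x)) < p)
  for (i in hit) x[i] <- sample(setdiff(c("A", "C", "G", "T"), x[i]), 1)
  x
}

# --- standard simulation scenarios (the study conditions) ---

# three clock-like species, ancestral duplication on the stem, no conversion
nullScenario <- function(seed, root_length = 1000) {
  simConfig("((A:0.03,B:0.03):0.03,C:0.06);", root_length = root_length,
            stem_length = 0.05, stem_duplications = 1, seed = seed)
}

# one conversion implanted on the terminal branch of species A, after the
# A/B and A/C splits (the duplication is ancestral, so both are outgroups)
implantScenario <- function(seed, tract = 500L, root_length = 2000,
                            start = NA) {
  fc <- data.frame(branch = "A", at = 0.5, length = tract,
                   start = start, donor = 1L, recipient = 2L)
  simConfig("((A:0.03,B:0.03):0.03,C:0.06);", root_length = root_length,
            stem_length = 0.05, stem_duplications = 1,
            forced_conversions = fc, seed = seed)
}

runScenario <- function(cfg, config = detectionConfig()) {
  sim <- simulateCluster(cfg)
  tree <- speciesTree(sim$tree)
  res <- runPipeline(sim$paralogAlns, sim$orthology, tree, config)
  list(sim = sim, res = res)
}
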