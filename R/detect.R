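#' Detection configuration
#'
#' @param coverage_threshold descent-coverage fraction above which the
#'   max-descent test is skipped in favour of the whole-paralog binomial
#'   criterion (strictly greater than; default 0.80).
#' @param alpha family-wise significance level, Bonferroni-corrected over
#'   all (pair, outgroup) tests attempted in a run (default 0.05).
#' @param min_informative minimum informative sites to run a test; below
#'   it the combination is reported untested (default 10).
#' @param boundary_tol reciprocal-overlap fraction above which two converted
#'   intervals count as the same boundaries (default 0.5).
#' @param direction_alpha significance level of the direction call.
#' @return list of validated settings.
#' @export
detectionConfig <- function(coverage_threshold = 0.80, alpha = 0.05,
                            min_informative = 10, boundary_tol = 0.5,
                            direction_alpha = 0.05) {
  stopifnot(coverage_threshold > 0, coverage_threshold < 1,
            alpha > 0, alpha < 1, min_informative >= 0,
            boundary_tol > 0, boundary_tol <= 1)
  list(coverage_threshold = coverage_threshold, alpha = alpha,
       min_informative = min_informative, boundary_tol = boundary_tol,
       direction_alpha = direction_alpha)
}

#' Choose between the max-descent and whole-paralog criteria
#'
#' A maximum descent spanning more than `coverageThreshold` of the paralog
#' alignment columns leaves too little non-converted sequence for the
#' max-descent null (at full coverage its P-value degenerates to 1), so such
#' walks are routed to the binomial whole-paralog criterion instead.
#'
#' @param walk A [ConversionWalk-class].
#' @param descent output of [maximumDescent()] for `walk`.
#' @param coverageThreshold fraction (default 0.80); strictly-greater rule.
#' @param minInformative minimum informative sites; below it `"rejected"`.
#' @return `"criterion1"`, `"criterion2_candidate"` or `"rejected"`.
#' @export
selectCriterion <- function(walk, descent, coverageThreshold = 0.80,
                            minInformative = 10) {
  if (length(walk@column) < minInformative) return("rejected")
  if (descent$k == 0 || is.na(descent$start_col)) return("criterion1")
  coverage <- (descent$end_col - descent$start_col + 1) / walk@totalColumns
  if (coverage > coverageThreshold) "criterion2_candidate" else "criterion1"
}

# ortholog alignments in `orthology` linking interval
# (species, chrom, [start,end)) to `outgroup`; each hit records which row is
# the self (primary-species) row
orthologsFor <- function(orthology, species, chrom, start, end, outgroup) {
  hits <- list()
  for (aln in orthology) {
    for (selfRow in 1:2) {
      iv <- rowInterval(aln, selfRow)
      ov <- rowInterval(aln, 3 - selfRow)
      if (iv$species == species && iv$chrom == chrom &&
          ov$species == outgroup &&
          iv$start < end && iv$end > start) {
        hits[[length(hits) + 1]] <- list(aln = aln, selfRow = selfRow)
        break
      }
    }
  }
  hits
}

#' Do two paralogs map to distinct ortholog regions in an outgroup?
#'
#' Required for a criterion-2 call: distinct orthologs imply the duplication
#' predates the speciation, so whole-length similarity of the paralogs is
#' evidence of conversion rather than of a recent duplication.
#'
#' @param paralog intra-species [AlignedPair-class].
#' @param orthology list of ortholog [AlignedPair-class] objects.
#' @param outgroup outgroup species name.
#' @return TRUE iff both paralog rows have orthologs in `outgroup` and the
#'   two ortholog interval sets do not overlap each other.
#' @export
distinctOrthologs <- function(paralog, orthology, outgroup) {
  iv1 <- rowInterval(paralog, 1)
  iv2 <- rowInterval(paralog, 2)
  o1 <- orthologsFor(orthology, iv1$species, iv1$chrom, iv1$start, iv1$end,
                     outgroup)
  o2 <- orthologsFor(orthology, iv2$species, iv2$chrom, iv2$start, iv2$end,
                     outgroup)
  if (!length(o1) || !length(o2)) return(FALSE)
  ivs <- function(hits) lapply(hits, function(h) rowInterval(h$aln, 3 - h$selfRow))
  for (a in ivs(o1)) for (b in ivs(o2)) {
    if (a$chrom == b$chrom && a$start < b$end && a$end > b$start)
      return(FALSE)
  }
  TRUE
}

#' Bonferroni per-test significance threshold
#' @param numTests number of (pair, outgroup) tests attempted (>= 1).
#' @param alpha family-wise level.
#' @return per-test P-value threshold `alpha / numTests`.
#' @export
significanceCutoff <- function(numTests, alpha = 0.05) {
  if (numTests < 1) stop("numTests must be >= 1")
  alpha / numTests
}

mergeProjections <- function(projections, ncolumns) {
  out <- rep(NA_character_, ncolumns)
  for (p in projections) {
    fill <- is.na(out) & !is.na(p)
    out[fill] <- p[fill]
  }
  out
}

# map a genomic interval on the primary-species row of an ortholog hit to
# outgroup coordinates (0-based half-open); NA if nothing maps
mapToOutgroup <- function(hit, start, end) {
  selfPos <- columnGenomePos(hit$aln, hit$selfRow)
  otherPos <- columnGenomePos(hit$aln, 3 - hit$selfRow)
  inIv <- !is.na(selfPos) & selfPos >= start & selfPos < end & !is.na(otherPos)
  if (!any(inIv)) return(c(NA_integer_, NA_integer_))
  c(min(otherPos[inIv]), max(otherPos[inIv]) + 1L)
}

emptyObservations <- function() {
  data.frame(obs_id = integer(), primary_species = character(),
             chrom = character(), par1_start = integer(), par1_end = integer(),
             par2_start = integer(), par2_end = integer(),
             outgroup = character(), conv_start = integer(),
             conv_end = integer(), conv2_start = integer(),
             conv2_end = integer(), direction = character(),
             p_value = numeric(), criterion = integer(), m = integer(),
             n = integer(), k = integer(), informative_sites = integer(),
             quadruplet = logical(), out_chrom = character(),
             out_start = integer(), out_end = integer(),
             stringsAsFactors = FALSE)
}

# run the statistical test for one (paralog pair, outgroup) combination;
# returns list(row = candidate observation data.frame or NULL,
#              tested = was a P-value computed)
testPair <- function(paralog, outgroup, orthology, config) {
  iv1 <- rowInterval(paralog, 1)
  iv2 <- rowInterval(paralog, 2)
  nc <- alignmentNcol(paralog)
  o1 <- orthologsFor(orthology, iv1$species, iv1$chrom, iv1$start, iv1$end,
                     outgroup)
  o2 <- orthologsFor(orthology, iv2$species, iv2$chrom, iv2$start, iv2$end,
                     outgroup)
  proj1 <- if (length(o1))
    mergeProjections(lapply(o1, function(h)
      projectOntoParalogColumns(paralog, h$aln, 1)), nc) else NULL
  proj2 <- if (length(o2))
    mergeProjections(lapply(o2, function(h)
      projectOntoParalogColumns(paralog, h$aln, 2)), nc) else NULL
  have1 <- !is.null(proj1) && any(!is.na(proj1))
  have2 <- !is.null(proj2) && any(!is.na(proj2))
  if (!have1 && !have2)
    return(list(row = NULL, tested = FALSE))

  walk1 <- if (have1) buildTripletWalk(paralog, proj1, 1) else NULL
  walk2 <- if (have2) buildTripletWalk(paralog, proj2, 2) else NULL
  quad <- have1 && have2
  walk <- if (quad) combineQuadruplet(walk1, walk2)
          else if (have1) walk1 else walk2
  if (quad) {
    # significance is judged on one unit step per informative site (the
    # sign of the combined step): site step types are exchangeable under
    # the null, so the unit-step maximum-descent distribution is exact,
    # whereas expanding concordant sites into two correlated unit steps
    # would overstate descent depths
    walk <- conversionWalk(walk@column, walk@step,
                           rep(1L, length(walk@step)), walk@totalColumns)
  }

  descent <- maximumDescent(walk)
  route <- selectCriterion(walk, descent, config$coverage_threshold,
                           config$min_informative)
  if (route == "rejected") return(list(row = NULL, tested = FALSE))

  if (route == "criterion2_candidate") {
    if (!distinctOrthologs(paralog, orthology, outgroup))
      return(list(row = NULL, tested = TRUE))
    res <- binomialCoveragePValue(walk@m, walk@n)
    pval <- res$p_value
    criterion <- 2L
  } else {
    pval <- maxDescentPValue(walk@m, walk@n, descent$k)
    criterion <- 1L
  }

  if (descent$k > 0) {
    pos1 <- columnGenomePos(paralog, 1)
    pos2 <- columnGenomePos(paralog, 2)
    convStart <- pos1[descent$start_col]
    convEnd <- pos1[descent$end_col] + 1L
    p2 <- range(pos2[c(descent$start_col, descent$end_col)])
    conv2Start <- p2[1]
    conv2End <- p2[2] + 1L
  } else {
    convStart <- NA_integer_; convEnd <- NA_integer_
    conv2Start <- NA_integer_; conv2End <- NA_integer_
  }

  dir <- list(direction = "unknown", direction_p = NA_real_)
  if (quad && descent$k > 0)
    dir <- inferDirection(walk1, walk2, descent, config$direction_alpha)

  outMap <- c(NA_integer_, NA_integer_)
  outChrom <- NA_character_
  if (!is.na(convStart)) {
    for (h in c(o1, o2)) {
      hIv <- rowInterval(h$aln, h$selfRow)
      cand <- if (hIv$start <= convStart && hIv$end >= convEnd)
        mapToOutgroup(h, convStart, convEnd) else c(NA_integer_, NA_integer_)
      if (!is.na(cand[1])) {
        outMap <- cand
        outChrom <- rowInterval(h$aln, 3 - h$selfRow)$chrom
        break
      }
    }
  }

  row <- data.frame(obs_id = NA_integer_, primary_species = iv1$species,
                    chrom = iv1$chrom,
                    par1_start = iv1$start, par1_end = iv1$end,
                    par2_start = iv2$start, par2_end = iv2$end,
                    outgroup = outgroup,
                    conv_start = convStart, conv_end = convEnd,
                    conv2_start = conv2Start, conv2_end = conv2End,
                    direction = dir$direction, p_value = pval,
                    criterion = criterion,
                    m = walk@m, n = walk@n, k = descent$k,
                    informative_sites = length(walk@column),
                    quadruplet = quad,
                    out_chrom = outChrom,
                    out_start = outMap[1], out_end = outMap[2],
                    stringsAsFactors = FALSE)
  list(row = row, tested = TRUE)
}

#' Test one paralog pair against one outgroup
#'
#' Builds the triplet walk(s) for the pair, combines them into a quadruplet
#' when both paralogs have orthologs in the outgroup, routes the result
#' through [selectCriterion()] (criterion 2 additionally requires
#' [distinctOrthologs()]), and returns the significant observations at
#' `cutoff`.
#'
#' @param paralog intra-species [AlignedPair-class].
#' @param outgroup outgroup species name.
#' @param orthology list of ortholog [AlignedPair-class] objects.
#' @param config [detectionConfig()] list.
#' @param cutoff per-test P-value threshold (default `config$alpha`,
#'   i.e. uncorrected; [scanCluster()] applies the Bonferroni correction).
#' @return observation data.frame (zero or one row).
#' @export
detectPair <- function(paralog, outgroup, orthology,
                       config = detectionConfig(), cutoff = config$alpha) {
  res <- testPair(paralog, outgroup, orthology, config)
  if (is.null(res$row) || res$row$p_value > cutoff ||
      is.na(res$row$conv_start))
    return(emptyObservations())
  res$row
}

#' Scan a whole cluster for conversion observations
#'
#' Runs the conversion test for every (primary species, intra-species
#' paralog pair, outgroup species) combination, Bonferroni-corrects the
#' family-wise level over all tests attempted, and returns the significant
#' observations sorted by primary species, coordinates and outgroup.
#'
#' @param paralogAlns list of intra-species [AlignedPair-class] objects.
#' @param orthology list of ortholog [AlignedPair-class] objects.
#' @param tree A [SpeciesTree-class]; every aligned species must be a leaf.
#' @param config [detectionConfig()] list.
#' @return list with `observations` (data.frame), `tests_attempted`,
#'   and `cutoff` (the corrected per-test threshold).
#' @export
scanCluster <- function(paralogAlns, orthology, tree,
                        config = detectionConfig()) {
  sp <- unique(unlist(lapply(paralogAlns, function(a) a@species1)))
  missing <- setdiff(sp, speciesNames(tree))
  if (length(missing))
    stop("species present in alignments but absent from tree: ",
         paste(missing, collapse = ", "))
  outgroupsOf <- function(s) setdiff(speciesNames(tree), s)
  if (length(speciesNames(tree)) < 2)
    warning("single species in tree: no outgroups, nothing to test")

  rows <- list()
  attempted <- 0L
  for (paralog in paralogAlns) {
    for (outgroup in outgroupsOf(paralog@species1)) {
      res <- testPair(paralog, outgroup, orthology, config)
      if (res$tested) attempted <- attempted + 1L
      if (!is.null(res$row)) rows[[length(rows) + 1]] <- res$row
    }
  }
  if (attempted == 0L)
    return(list(observations = emptyObservations(), tests_attempted = 0L,
                cutoff = NA_real_))
  cutoff <- significanceCutoff(attempted, config$alpha)
  obs <- if (length(rows)) do.call(rbind, rows) else emptyObservations()
  obs <- obs[!is.na(obs$conv_start) & obs$p_value <= cutoff, , drop = FALSE]
  if (nrow(obs)) {
    obs <- obs[order(obs$primary_species, obs$chrom, obs$par1_start,
                     obs$par2_start, obs$outgroup), , drop = FALSE]
    obs$obs_id <- seq_len(nrow(obs))
    rownames(obs) <- NULL
  }
  list(observations = obs, tests_attempted = attempted, cutoff = cutoff)
}
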