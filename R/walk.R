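#' @useDynLib paraconv, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats pbinom fisher.test setNames rbinom rexp rgeom runif rpois
#' @importFrom utils write.table
NULL

NUCS <- c("A", "C", "G", "T")

conversionWalk <- function(column, step, magnitude, totalColumns) {
  new("ConversionWalk",
      column = as.integer(column), step = as.integer(step),
      magnitude = as.integer(magnitude),
      m = as.integer(sum(magnitude[step == 1L])),
      n = as.integer(sum(magnitude[step == -1L])),
      totalColumns = as.integer(totalColumns))
}

#' Classify an informative site
#'
#' A site contributes an up step when the primary sequence matches its
#' ortholog but not the paralog — the expected state when the duplication
#' predates the speciation, since the ortholog is the closer relative — and
#' a down step when it matches the paralog but not the ortholog, the
#' homogenisation signature of a conversion.  Under the no-conversion null
#' the walk therefore drifts upward and down steps are the rarer kind
#' (P(down) <= 0.5), so a deep maximum descent marks a converted tract.
#'
#' @param primary,paralog,ortholog single upper-case nucleotides; the caller
#'   must not pass gaps or ambiguity codes (they are non-informative and are
#'   filtered upstream).
#' @return `"up"`, `"down"` or `"neutral"` (vectorised).
#' @export
classifySite <- function(primary, paralog, ortholog) {
  ifelse(primary == ortholog & primary != paralog, "up",
    ifelse(primary == paralog & primary != ortholog, "down", "neutral"))
}

#' Build the triplet random walk for one paralog pair and one outgroup
#'
#' Iterates the paralog-alignment columns in order; columns with a gap, an
#' ambiguity code, or an uncovered ortholog projection contribute no step.
#'
#' @param paralog intra-species [AlignedPair-class].
#' @param projection ortholog bases per paralog column, from
#'   [projectOntoParalogColumns()] (through the primary row).
#' @param primaryRow which paralog row (1 or 2) is the primary sequence.
#' @return A [ConversionWalk-class] (possibly empty).
#' @export
buildTripletWalk <- function(paralog, projection, primaryRow = 1) {
  prim <- alignedRow(paralog, primaryRow)
  para <- alignedRow(paralog, 3 - primaryRow)
  stopifnot(length(projection) == length(prim))
  ok <- prim %in% NUCS & para %in% NUCS &
        !is.na(projection) & projection %in% NUCS
  cls <- rep("neutral", length(prim))
  cls[ok] <- classifySite(prim[ok], para[ok], projection[ok])
  idx <- which(cls != "neutral")
  conversionWalk(column = idx,
                 step = ifelse(cls[idx] == "up", 1L, -1L),
                 magnitude = rep(1L, length(idx)),
                 totalColumns = length(prim))
}

#' Combine the two triplet walks of a quadruplet test
#'
#' Both walks must be indexed by the same paralog-alignment columns.  At a
#' column where only one walk has a step it is kept as-is; where both walks
#' step in the same direction the magnitudes add (two up steps, or two down
#' steps).  Opposite steps at one column cannot occur, because both triplets
#' share the same pair of paralogous nucleotides.
#'
#' @param walk1,walk2 [ConversionWalk-class] objects over the same columns.
#' @return Combined [ConversionWalk-class].
#' @export
combineQuadruplet <- function(walk1, walk2) {
  stopifnot(walk1@totalColumns == walk2@totalColumns)
  cols <- sort(unique(c(walk1@column, walk2@column)))
  i1 <- match(cols, walk1@column)
  i2 <- match(cols, walk2@column)
  s1 <- walk1@step[i1]; g1 <- walk1@magnitude[i1]
  s2 <- walk2@step[i2]; g2 <- walk2@magnitude[i2]
  both <- !is.na(s1) & !is.na(s2)
  if (any(both & s1 != s2))
    stop("internal inconsistency: the combination of one up and one down ",
         "step does not occur in a quadruplet")
  step <- ifelse(is.na(s1), s2, s1)
  mag <- ifelse(is.na(g1), 0L, g1) + ifelse(is.na(g2), 0L, g2)
  conversionWalk(cols, step, mag, walk1@totalColumns)
}

#' Cumulative score of a walk
#' @param walk A [ConversionWalk-class].
#' @return numeric vector of heights after each step (excluding the 0 start).
#' @export
cumulativeScore <- function(walk) {
  cumsum(walk@step * walk@magnitude)
}

#' Maximum descent of a walk
#'
#' The largest peak-to-subsequent-trough drop of the cumulative score; its
#' interval (from the column after the peak to the trough column) is the
#' candidate converted region.  Among equally deep descents the leftmost is
#' reported.
#'
#' @param walk A [ConversionWalk-class].
#' @return list with `k` (descent depth in unit steps), `start_col`,
#'   `end_col` (alignment columns; `NA` when `k == 0`).
#' @export
maximumDescent <- function(walk) {
  if (length(walk@column) == 0)
    return(list(k = 0L, start_col = NA_integer_, end_col = NA_integer_))
  S <- c(0L, cumulativeScore(walk))            # S[1] = start height 0
  runmax <- cummax(S)
  drop <- runmax - S
  k <- max(drop)
  if (k == 0)
    return(list(k = 0L, start_col = NA_integer_, end_col = NA_integer_))
  jstar <- which(drop == k)[1]                 # trough position (in S index)
  peakVal <- runmax[jstar]
  # innermost peak: with peak/trough plateaus this keeps the interval
  # invariant under reversing the column order (mirror symmetry)
  istar <- max(which(S[seq_len(jstar)] == peakVal))
  # steps are indexed 1..N; S index i corresponds to after step i-1
  startStep <- istar                            # first step after the peak
  endStep <- jstar - 1L
  list(k = as.integer(k),
       start_col = walk@column[startStep],
       end_col = walk@column[endStep])
}

#' Up/down counts of a walk within a column window
#' @param walk A [ConversionWalk-class].
#' @param startCol,endCol inclusive alignment-column window.
#' @return list with `m` and `n` (unit-step totals inside the window).
#' @export
walkWindowCounts <- function(walk, startCol, endCol) {
  inw <- walk@column >= startCol & walk@column <= endCol
  list(m = sum(walk@magnitude[inw & walk@step == 1L]),
       n = sum(walk@magnitude[inw & walk@step == -1L]))
}

#' Exact maximum-descent P-value
#'
#' Probability, under uniformly random orderings of `m` up and `n` down unit
#' steps (the no-conversion null, where step order is exchangeable), that
#' the maximum descent is at least `k`.  Computed by an exact dynamic
#' programme over lattice paths; handles walks with thousands of informative
#' sites.  Magnitude-2 steps from quadruplet tests are expanded into two
#' unit steps of the same sign before `m`, `n` and `k` are formed.
#'
#' @param m,n non-negative up/down unit-step counts.
#' @param k non-negative descent depth.
#' @return probability in \[0, 1\].
#' @export
maxDescentPValue <- function(m, n, k) {
  if (m < 0 || n < 0 || k < 0) stop("m, n and k must be non-negative")
  descentPvalueCpp(as.integer(m), as.integer(n), as.integer(k))
}

#' Binomial tail P-value for whole-paralog conversion (criterion 2)
#'
#' When the descent pattern covers (nearly) the whole paralog pair the
#' max-descent P-value degenerates towards 1, so significance is instead
#' judged by the scarcity of down steps: with success probability
#' `p = min(0.5, n / (n + m))` (estimated from the observed steps, capped at
#' 0.5 because a duplication preceding the speciation makes up steps at
#' least as likely as down steps), the P-value is the upper binomial tail
#' `P(X >= n)` for `X ~ Binomial(m + n, p)`.
#'
#' @param m,n observed up/down unit-step counts; `m + n >= 1`.
#' @return list with `p_value` and the binomial parameter `p`.
#' @export
binomialCoveragePValue <- function(m, n) {
  if (m + n < 1) stop("criterion 2 requires at least one informative site")
  p <- min(0.5, n / (n + m))
  list(p_value = pbinom(n - 1, size = m + n, prob = p, lower.tail = FALSE),
       p = p)
}

#' Infer the direction of a conversion from a quadruplet
#'
#' Within the shared maximum-descent region, the triplet anchored on the
#' recipient paralog shows a higher down-step proportion than the triplet
#' anchored on the donor: the recipient's own ortholog still carries the
#' overwritten (pre-conversion) sequence and so diverged at paralog-age
#' distance in the tract, rarely matching — leaving few up steps.  The two
#' down-step proportions are compared with Fisher's exact test on the
#' up/down counts; if the difference is significant the primary row of the
#' higher-proportion walk is called the recipient, otherwise the direction
#' is unknown.
#'
#' @param walk1 triplet walk with row 1 as primary.
#' @param walk2 triplet walk with row 2 as primary.
#' @param shared maximum-descent interval (list with `start_col`, `end_col`)
#'   of the combined walk.
#' @param alpha significance level for the direction call.
#' @return list with `direction` (`"par1->par2"`, `"par2->par1"` or
#'   `"unknown"`) and `direction_p`.
#' @export
inferDirection <- function(walk1, walk2, shared, alpha = 0.05) {
  if (is.na(shared$start_col) || is.na(shared$end_col))
    return(list(direction = "unknown", direction_p = NA_real_))
  c1 <- walkWindowCounts(walk1, shared$start_col, shared$end_col)
  c2 <- walkWindowCounts(walk2, shared$start_col, shared$end_col)
  if (c1$m + c1$n == 0 || c2$m + c2$n == 0)
    return(list(direction = "unknown", direction_p = NA_real_))
  tab <- matrix(c(c1$m, c1$n, c2$m, c2$n), nrow = 2)
  pv <- fisher.test(tab)$p.value
  q1 <- c1$n / (c1$m + c1$n)
  q2 <- c2$n / (c2$m + c2$n)
  dir <- "unknown"
  if (pv < alpha && q1 != q2) {
    # recipient = primary of the walk with the higher down proportion
    dir <- if (q1 > q2) "par2->par1" else "par1->par2"
  }
  list(direction = dir, direction_p = pv)
}
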