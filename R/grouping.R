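#' Reciprocal overlap of two half-open intervals
#' @param s1,e1,s2,e2 interval bounds (0-based half-open).
#' @return min of the two overlap fractions (0 if disjoint).
#' @export
reciprocalOverlap <- function(s1, e1, s2, e2) {
  ov <- max(0, min(e1, e2) - max(s1, s2))
  if (ov == 0) return(0)
  min(ov / (e1 - s1), ov / (e2 - s2))
}

#' Are two converted intervals "the same boundaries"?
#'
#' Boundary similarity is judged by reciprocal overlap: both intervals must
#' cover at least `tolerance` of each other.
#'
#' @param s1,e1,s2,e2 interval bounds (0-based half-open, comparable
#'   coordinates).
#' @param tolerance reciprocal-overlap fraction (default 0.5).
#' @return logical.
#' @export
boundariesSimilar <- function(s1, e1, s2, e2, tolerance = 0.5) {
  reciprocalOverlap(s1, e1, s2, e2) >= tolerance
}

# minimal union-find
ufNew <- function(n) seq_len(n)
ufFind <- function(uf, i) { while (uf[i] != i) i <- uf[i]; i }
ufUnion <- function(uf, i, j) {
  ri <- ufFind(uf, i); rj <- ufFind(uf, j)
  if (ri != rj) uf[max(ri, rj)] <- min(ri, rj)
  uf
}

pairKey <- function(obs) {
  a <- paste(obs$par1_start, obs$par1_end)
  b <- paste(obs$par2_start, obs$par2_end)
  lo <- ifelse(a < b, a, b); hi <- ifelse(a < b, b, a)
  paste(obs$primary_species, obs$chrom, lo, hi)
}

#' Collapse redundant observations across outgroups (Type a)
#'
#' Within one (primary species, paralog pair), observations from different
#' outgroups with equal-or-similar boundaries are the same historical event;
#' dissimilar boundaries remain separate, repeated conversions.
#'
#' @param obs observation data.frame.
#' @param tolerance boundary reciprocal-overlap fraction.
#' @return `obs` with an `event_id` column added (provisional ids).
#' @export
collapseTypeA <- function(obs, tolerance = 0.5) {
  if (!nrow(obs)) { obs$event_id <- integer(0); return(obs) }
  uf <- ufNew(nrow(obs))
  key <- pairKey(obs)
  for (grp in split(seq_len(nrow(obs)), key)) {
    if (length(grp) < 2) next
    for (ii in seq_along(grp)) for (jj in seq_len(ii - 1L)) {
      i <- grp[ii]; j <- grp[jj]
      if (boundariesSimilar(obs$conv_start[i], obs$conv_end[i],
                            obs$conv_start[j], obs$conv_end[j], tolerance))
        uf <- ufUnion(uf, i, j)
    }
  }
  obs$event_id <- vapply(seq_len(nrow(obs)), function(i) ufFind(uf, i),
                         integer(1))
  obs
}

# map a genomic interval in one species to another species' coordinates
# via the ortholog alignments; NA if no alignment covers it
mapIntervalBetween <- function(orthology, species, chrom, start, end,
                               target) {
  hits <- orthologsFor(orthology, species, chrom, start, end, target)
  for (h in hits) {
    mapped <- mapToOutgroup(h, start, end)
    if (!is.na(mapped[1]))
      return(list(chrom = rowInterval(h$aln, 3 - h$selfRow)$chrom,
                  start = mapped[1], end = mapped[2]))
  }
  NULL
}

#' Collapse redundant observations across primary species (Type b)
#'
#' An event detected between paralogs in species A with outgroup C, and a
#' boundary-similar event between the orthologous paralogs in species B
#' detected with the same outgroup C, get one event id.  Observations using
#' different outgroups are never merged by this rule.
#'
#' @param obs observation data.frame with `event_id` (from
#'   [collapseTypeA()]).
#' @param orthology list of ortholog [AlignedPair-class] objects linking the
#'   primary species.
#' @param tolerance boundary reciprocal-overlap fraction.
#' @return `obs` with merged `event_id`s.
#' @export
collapseTypeB <- function(obs, orthology, tolerance = 0.5) {
  if (nrow(obs) < 2) return(obs)
  n <- nrow(obs)
  uf <- ufNew(n)
  # seed with existing event groups
  for (grp in split(seq_len(n), obs$event_id))
    if (length(grp) > 1)
      for (i in grp[-1]) uf <- ufUnion(uf, grp[1], i)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    if (obs$primary_species[i] == obs$primary_species[j]) next
    if (obs$outgroup[i] != obs$outgroup[j]) next
    mapped <- mapIntervalBetween(orthology, obs$primary_species[i],
                                 obs$chrom[i], obs$conv_start[i],
                                 obs$conv_end[i], obs$primary_species[j])
    if (is.null(mapped)) next
    if (mapped$chrom == obs$chrom[j] &&
        boundariesSimilar(mapped$start, mapped$end,
                          obs$conv_start[j], obs$conv_end[j], tolerance))
      uf <- ufUnion(uf, i, j)
  }
  obs$event_id <- vapply(seq_len(n), function(i) ufFind(uf, i), integer(1))
  obs
}

#' Classify shared-target redundancy (Type c)
#'
#' Two observations share a target paralog (A1 -> A3 and A2 -> A3) with
#' similar boundaries; the three pairwise percent identities inside the
#' conversion region decide whether one historical event explains both.
#'
#' @param S1 Sim(A1, A2); @param S2 Sim(A1, A3); @param S3 Sim(A2, A3),
#'   percent identities in the conversion region.
#' @return `"before-duplication"` (S1 maximal: the conversion predates the
#'   A1/A2 duplication), `"pairwise-1"` (S2 maximal: the real conversion is
#'   A1 - A3), or `"pairwise-2"` (S3 maximal: A2 - A3).  Exact ties are
#'   broken toward `"before-duplication"` with a warning.
#' @export
classifyTypeC <- function(S1, S2, S3) {
  mx <- max(S1, S2, S3)
  hits <- c(S1 == mx, S2 == mx, S3 == mx)
  if (sum(hits) > 1) {
    if (hits[1]) {
      warning("tie among type-c similarities; keeping before-duplication")
      return("before-duplication")
    }
    warning("tie among type-c similarities S2/S3; keeping pairwise-1")
    return("pairwise-1")
  }
  c("before-duplication", "pairwise-1", "pairwise-2")[which(hits)]
}

otherParalog <- function(obs, i, sharedRow) {
  if (sharedRow == 1L)
    c(obs$par2_start[i], obs$par2_end[i])
  else c(obs$par1_start[i], obs$par1_end[i])
}

convOnRow <- function(obs, i, row) {
  if (row == 1L) c(obs$conv_start[i], obs$conv_end[i])
  else c(obs$conv2_start[i], obs$conv2_end[i])
}

findParalogAln <- function(paralogAlns, species, chrom, ivA, ivB) {
  for (aln in paralogAlns) {
    if (aln@species1 != species || aln@chrom1 != chrom) next
    r1 <- c(aln@start1, aln@end1); r2 <- c(aln@start2, aln@end2)
    if (reciprocalOverlap(r1[1], r1[2], ivA[1], ivA[2]) > 0 &&
        reciprocalOverlap(r2[1], r2[2], ivB[1], ivB[2]) > 0)
      return(list(aln = aln, rowA = 1L))
    if (reciprocalOverlap(r2[1], r2[2], ivA[1], ivA[2]) > 0 &&
        reciprocalOverlap(r1[1], r1[2], ivB[1], ivB[2]) > 0)
      return(list(aln = aln, rowA = 2L))
  }
  NULL
}

pidInRegion <- function(aln, row, gStart, gEnd) {
  pos <- columnGenomePos(aln, row)
  cols <- which(!is.na(pos) & pos >= gStart & pos < gEnd)
  if (!length(cols)) return(NA_real_)
  suppressWarnings(percentIdentity(aln, c(min(cols), max(cols))))
}

#' Collapse and arbitrate all redundant observations
#'
#' Applies the removal rules in order: Type (a) across outgroups, Type (b)
#' across primary species, Type (c) across post-conversion duplicates
#' sharing a target paralog.  Event ids are renumbered in ascending
#' (primary species, converted-region start) order of the representatives.
#'
#' @param obs observation data.frame from [scanCluster()].
#' @param orthology list of ortholog [AlignedPair-class] objects.
#' @param paralogAlns list of intra-species [AlignedPair-class] objects
#'   (needed for the Type-c similarity triple; may be empty, in which case
#'   unclassifiable shared-target pairs stay separate).
#' @param tolerance boundary reciprocal-overlap fraction.
#' @return list with `full` (all observations, columns `event_id`, `kept`,
#'   `inferred_case` added) and `nonredundant` (one representative row per
#'   event, minimum P-value among kept observations).
#' @export
deduplicate <- function(obs, orthology = list(), paralogAlns = list(),
                        tolerance = 0.5) {
  if (!nrow(obs)) {
    obs$event_id <- integer(0); obs$kept <- logical(0)
    obs$inferred_case <- character(0)
    return(list(full = obs, nonredundant = obs))
  }
  obs <- collapseTypeA(obs, tolerance)
  obs <- collapseTypeB(obs, orthology, tolerance)
  obs$kept <- TRUE
  obs$inferred_case <- NA_character_

  # Type (c): same primary, shared target paralog, different partners
  n <- nrow(obs)
  uf <- ufNew(n)
  for (grp in split(seq_len(n), obs$event_id))
    if (length(grp) > 1)
      for (i in grp[-1]) uf <- ufUnion(uf, grp[1], i)
  if (n >= 2) {
    for (i in seq_len(n - 1L)) for (j in seq(i + 1L, n)) {
      if (obs$primary_species[i] != obs$primary_species[j] ||
          obs$chrom[i] != obs$chrom[j]) next
      if (ufFind(uf, i) == ufFind(uf, j)) next
      # find a shared paralog between the two pairs
      ivs <- function(o, q) list(`1` = c(o$par1_start[q], o$par1_end[q]),
                                 `2` = c(o$par2_start[q], o$par2_end[q]))
      ii <- ivs(obs, i); jj <- ivs(obs, j)
      shared <- NULL
      for (ri in 1:2) for (rj in 1:2) {
        a <- ii[[ri]]; b <- jj[[rj]]
        if (reciprocalOverlap(a[1], a[2], b[1], b[2]) >= tolerance &&
            is.null(shared))
          shared <- c(ri, rj)
      }
      if (is.null(shared)) next
      # the non-shared partners must be different paralogs
      pa <- otherParalog(obs, i, shared[1])
      pb <- otherParalog(obs, j, shared[2])
      if (reciprocalOverlap(pa[1], pa[2], pb[1], pb[2]) >= tolerance) next
      ci <- convOnRow(obs, i, shared[1])
      cj <- convOnRow(obs, j, shared[2])
      if (any(is.na(c(ci, cj)))) next
      if (!boundariesSimilar(ci[1], ci[2], cj[1], cj[2], tolerance)) next

      # similarity triple inside the conversion region:
      # A1 = partner of obs i, A2 = partner of obs j, A3 = shared target
      cOnA1 <- convOnRow(obs, i, 3L - shared[1])
      cOnA2 <- convOnRow(obs, j, 3L - shared[2])
      sp <- obs$primary_species[i]; ch <- obs$chrom[i]
      h12 <- findParalogAln(paralogAlns, sp, ch, pa, pb)
      h13 <- findParalogAln(paralogAlns, sp, ch, pa,
                            jj[[shared[2]]])
      h23 <- findParalogAln(paralogAlns, sp, ch, pb,
                            ii[[shared[1]]])
      if (is.null(h12) || is.null(h13) || is.null(h23)) next
      S1 <- pidInRegion(h12$aln, h12$rowA, cOnA1[1], cOnA1[2])
      S2 <- pidInRegion(h13$aln, h13$rowA, cOnA1[1], cOnA1[2])
      S3 <- pidInRegion(h23$aln, h23$rowA, cOnA2[1], cOnA2[2])
      if (any(is.na(c(S1, S2, S3)))) next
      case <- classifyTypeC(S1, S2, S3)
      uf <- ufUnion(uf, i, j)
      obs$inferred_case[c(i, j)] <- case
      if (case == "pairwise-1") obs$kept[j] <- FALSE
      if (case == "pairwise-2") obs$kept[i] <- FALSE
    }
  }
  obs$event_id <- vapply(seq_len(n), function(q) ufFind(uf, q), integer(1))

  # representatives: minimum P-value among kept observations of each event
  reps <- do.call(rbind, lapply(split(obs, obs$event_id), function(g) {
    cand <- g[g$kept, , drop = FALSE]
    if (!nrow(cand)) cand <- g
    cand[which.min(cand$p_value), , drop = FALSE]
  }))
  ord <- order(reps$primary_species, reps$chrom, reps$conv_start)
  reps <- reps[ord, , drop = FALSE]
  newId <- setNames(seq_len(nrow(reps)), reps$event_id)
  obs$event_id <- as.integer(newId[as.character(obs$event_id)])
  reps$event_id <- seq_len(nrow(reps))
  rownames(obs) <- NULL; rownames(reps) <- NULL
  list(full = obs, nonredundant = reps)
}
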