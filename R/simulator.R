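#' Simulation configuration for gene-cluster evolution
#'
#' The simulator evolves a cluster of paralogs down a species tree with
#' branch lengths in expected substitutions per site.  Substitutions follow
#' a single-rate symmetric (Jukes-Cantor-style) model; duplications insert a
#' full copy of one paralog adjacent to its source; conversions overwrite a
#' recipient tract with the donor's current sequence.  Indels and
#' rearrangements are not modelled, so the true alignments are gapless and
#' derived directly from the recorded copy history.
#'
#' @param tree a rooted `phylo` with branch lengths, or a Newick string.
#' @param root_length ancestral paralog length in bp (default 2000).
#' @param stem_length branch length of the stem above the root split, on
#'   which pre-speciation events (e.g. the ancestral duplication) occur.
#' @param stem_duplications number of duplications forced on the stem,
#'   evenly spaced (default 1: a cluster needs at least one paralog pair).
#' @param dup_rate,conv_rate Poisson rates of stochastic duplications /
#'   conversions per unit branch length (defaults 0: scripted events only).
#' @param conv_tract_mean mean of the geometric tract-length distribution
#'   for stochastic conversions (default 500 bp).
#' @param forced_conversions optional data.frame with columns `branch`
#'   (tip label, internal node number as character, or `"stem"`), `at`
#'   (fraction along the branch), `length` (tract bp; `NA` = geometric),
#'   `start` (tract start within the paralog; `NA` = uniform), and optional
#'   `donor`/`recipient` paralog ids (`NA` = uniform pair).
#' @param max_paralogs abort guard on runaway duplication (default 100).
#' @param seed integer seed fixing the full output; `NA` leaves the RNG
#'   state untouched.
#' @return validated configuration list.
#' @export
simConfig <- function(tree, root_length = 2000, stem_length = 0.05,
                      stem_duplications = 1, dup_rate = 0, conv_rate = 0,
                      conv_tract_mean = 500, forced_conversions = NULL,
                      max_paralogs = 100, seed = NA_integer_) {
  if (is.character(tree)) tree <- ape::read.tree(text = tree)
  stopifnot(inherits(tree, "phylo"), !is.null(tree$edge.length),
            root_length >= 10, stem_length >= 0, stem_duplications >= 0,
            dup_rate >= 0, conv_rate >= 0, conv_tract_mean >= 1)
  list(tree = tree, root_length = as.integer(root_length),
       stem_length = stem_length, stem_duplications = stem_duplications,
       dup_rate = dup_rate, conv_rate = conv_rate,
       conv_tract_mean = conv_tract_mean,
       forced_conversions = forced_conversions,
       max_paralogs = max_paralogs, seed = seed)
}

jcMutate <- function(seq, t) {
  if (t <= 0) return(seq)
  p <- 0.75 * (1 - exp(-4 * t / 3))
  hit <- which(runif(length(seq)) < p)
  if (length(hit)) {
    for (i in hit) seq[i] <- sample(setdiff(NUCS, seq[i]), 1)
  }
  seq
}

newTruthLog <- function() {
  data.frame(kind = character(), branch = character(), at = numeric(),
             src_id = integer(), new_id = integer(), donor_id = integer(),
             recipient_id = integer(), start = integer(), end = integer(),
             stringsAsFactors = FALSE)
}

truthRow <- function(kind, branch, at = NA_real_, src_id = NA_integer_,
                     new_id = NA_integer_, donor_id = NA_integer_,
                     recipient_id = NA_integer_, start = NA_integer_,
                     end = NA_integer_) {
  data.frame(kind = kind, branch = branch, at = at, src_id = src_id,
             new_id = new_id, donor_id = donor_id,
             recipient_id = recipient_id, start = start, end = end,
             stringsAsFactors = FALSE)
}

#' Simulate gene-cluster evolution down a species tree
#'
#' @param config a [simConfig()] list.
#' @return list with `sequences` (named character vector, one concatenated
#'   cluster per species), `paralogAlns` (true gapless intra-species
#'   [AlignedPair-class] objects for every paralog pair), `orthologAlns`
#'   (true inter-species alignments between positional orthologs, i.e.
#'   copies of the same paralog lineage), `orthology` (alias of
#'   `orthologAlns`), `paralogIndex` (data.frame species/paralog id/genomic
#'   interval), `truth` (ground-truth event log), and `tree` (the `phylo`).
#'   Deterministic given `config$seed`.
#' @export
simulateCluster <- function(config) {
  if (!is.na(config$seed)) set.seed(config$seed)
  phy <- config$tree
  L <- config$root_length
  env <- new.env()
  env$nextId <- 1L
  env$truth <- newTruthLog()
  env$leafState <- list()

  forced <- config$forced_conversions
  forcedFor <- function(branch) {
    if (is.null(forced)) return(NULL)
    f <- forced[forced$branch == branch, , drop = FALSE]
    if (nrow(f)) f else NULL
  }

  applyConversion <- function(state, branch, at, length = NA, start = NA,
                              donor = NA, recipient = NA) {
    if (length(state) < 2) return(state)
    ids <- vapply(state, function(p) p$id, integer(1))
    if (is.na(donor) || is.na(recipient) ||
        !(donor %in% ids) || !(recipient %in% ids)) {
      pick <- sample(seq_along(state), 2)
      di <- pick[1]; ri <- pick[2]
    } else {
      di <- match(donor, ids); ri <- match(recipient, ids)
    }
    len <- if (is.na(length)) min(L, rgeom(1, 1 / config$conv_tract_mean) + 1L)
           else as.integer(length)
    len <- min(len, L)
    s <- if (is.na(start)) sample.int(L - len + 1L, 1) - 1L
         else as.integer(start)
    s <- max(0L, min(s, L - len))
    state[[ri]]$seq[(s + 1):(s + len)] <- state[[di]]$seq[(s + 1):(s + len)]
    env$truth <- rbind(env$truth, truthRow(
      "conversion", branch, at, donor_id = state[[di]]$id,
      recipient_id = state[[ri]]$id, start = s, end = s + len))
    state
  }

  applyDuplication <- function(state, branch, at) {
    si <- sample(seq_along(state), 1)
    env$nextId <- env$nextId + 1L
    newP <- list(id = env$nextId, seq = state[[si]]$seq)
    state <- append(state, list(newP), after = si)
    if (length(state) > config$max_paralogs)
      stop("duplication rate produced more than ", config$max_paralogs,
           " paralogs; lower dup_rate or raise max_paralogs")
    env$truth <- rbind(env$truth, truthRow(
      "duplication", branch, at, src_id = state[[si]]$id,
      new_id = env$nextId))
    state
  }

  evolveBranch <- function(state, blen, branch, forcedDups = 0) {
    events <- data.frame(at = numeric(), kind = character(),
                         idx = integer(), stringsAsFactors = FALSE)
    if (forcedDups > 0)
      events <- rbind(events, data.frame(
        at = seq_len(forcedDups) / (forcedDups + 1), kind = "dup",
        idx = NA_integer_, stringsAsFactors = FALSE))
    if (config$dup_rate > 0 && blen > 0) {
      nd <- rpois(1, config$dup_rate * blen)
      if (nd) events <- rbind(events, data.frame(
        at = runif(nd), kind = "dup", idx = NA_integer_,
        stringsAsFactors = FALSE))
    }
    if (config$conv_rate > 0 && blen > 0) {
      nc <- rpois(1, config$conv_rate * blen)
      if (nc) events <- rbind(events, data.frame(
        at = runif(nc), kind = "conv", idx = NA_integer_,
        stringsAsFactors = FALSE))
    }
    fc <- forcedFor(branch)
    if (!is.null(fc))
      events <- rbind(events, data.frame(
        at = ifelse(is.na(fc$at), 0.5, fc$at), kind = "fconv",
        idx = seq_len(nrow(fc)), stringsAsFactors = FALSE))
    events <- events[order(events$at), , drop = FALSE]

    tPrev <- 0
    if (nrow(events)) for (e in seq_len(nrow(events))) {
      dt <- (events$at[e] - tPrev) * blen
      state <- lapply(state, function(p) { p$seq <- jcMutate(p$seq, dt); p })
      tPrev <- events$at[e]
      if (events$kind[e] == "dup") {
        state <- applyDuplication(state, branch, events$at[e])
      } else if (events$kind[e] == "conv") {
        state <- applyConversion(state, branch, events$at[e])
      } else {
        f <- fc[events$idx[e], ]
        state <- applyConversion(state, branch, events$at[e],
                                 length = f$length,
                                 start = if ("start" %in% names(f)) f$start else NA,
                                 donor = if ("donor" %in% names(f)) f$donor else NA,
                                 recipient = if ("recipient" %in% names(f)) f$recipient else NA)
      }
    }
    dt <- (1 - tPrev) * blen
    lapply(state, function(p) { p$seq <- jcMutate(p$seq, dt); p })
  }

  recurse <- function(node, state) {
    nTip <- length(phy$tip.label)
    kids <- phy$edge[phy$edge[, 1] == node, 2]
    if (!length(kids)) {
      env$leafState[[phy$tip.label[node]]] <- state
      return(invisible(NULL))
    }
    env$truth <- rbind(env$truth, truthRow("speciation",
                                           as.character(node)))
    for (child in kids) {
      blen <- phy$edge.length[which(phy$edge[, 1] == node &
                                    phy$edge[, 2] == child)[1]]
      branch <- if (child <= nTip) phy$tip.label[child]
                else as.character(child)
      recurse(child, evolveBranch(state, blen, branch))
    }
  }

  rootSeq <- sample(NUCS, L, replace = TRUE)
  state <- list(list(id = 1L, seq = rootSeq))
  state <- evolveBranch(state, config$stem_length, "stem",
                        forcedDups = config$stem_duplications)
  root <- setdiff(phy$edge[, 1], phy$edge[, 2])[1]
  recurse(root, state)

  # assemble outputs: concatenated cluster per species, index, alignments
  leafState <- env$leafState[sort(names(env$leafState))]
  idx <- do.call(rbind, lapply(names(leafState), function(sp) {
    st <- leafState[[sp]]
    data.frame(species = sp,
               paralog_id = vapply(st, function(p) p$id, integer(1)),
               start = (seq_along(st) - 1L) * L,
               end = seq_along(st) * L, stringsAsFactors = FALSE)
  }))
  seqs <- vapply(leafState, function(st)
    paste(vapply(st, function(p) paste(p$seq, collapse = ""), character(1)),
          collapse = ""), character(1))

  paralogAlns <- list()
  for (sp in names(leafState)) {
    st <- leafState[[sp]]
    total <- length(st) * L
    if (length(st) >= 2)
      for (i in seq_len(length(st) - 1L)) for (j in seq(i + 1L, length(st))) {
        paralogAlns[[length(paralogAlns) + 1]] <- alignedPair(
          sp, sp, (i - 1L) * L, i * L, "+",
          paste(st[[i]]$seq, collapse = ""),
          sp, sp, (j - 1L) * L, j * L, "+",
          paste(st[[j]]$seq, collapse = ""),
          kind = "paralog", srcLen1 = total, srcLen2 = total)
      }
  }

  orthologAlns <- list()
  sps <- names(leafState)
  if (length(sps) >= 2)
    for (a in seq_len(length(sps) - 1L)) for (b in seq(a + 1L, length(sps))) {
      stA <- leafState[[sps[a]]]; stB <- leafState[[sps[b]]]
      idsA <- vapply(stA, function(p) p$id, integer(1))
      idsB <- vapply(stB, function(p) p$id, integer(1))
      for (id in intersect(idsA, idsB)) {
        i <- match(id, idsA); j <- match(id, idsB)
        orthologAlns[[length(orthologAlns) + 1]] <- alignedPair(
          sps[a], sps[a], (i - 1L) * L, i * L, "+",
          paste(stA[[i]]$seq, collapse = ""),
          sps[b], sps[b], (j - 1L) * L, j * L, "+",
          paste(stB[[j]]$seq, collapse = ""),
          kind = "ortholog",
          srcLen1 = length(stA) * L, srcLen2 = length(stB) * L)
      }
    }

  list(sequences = seqs, paralogAlns = paralogAlns,
       orthologAlns = orthologAlns, orthology = orthologAlns,
       paralogIndex = idx, truth = env$truth, tree = phy,
       root_length = L)
}

#' Write simulator outputs to standard files
#'
#' Emits per-species FASTA, paralog and ortholog MAFs, the Newick tree and
#' a tab-separated ground-truth log into a directory.
#'
#' @param sim output of [simulateCluster()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
writeSimulation <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (sp in names(sim$sequences))
    writeFastaSeqs(setNames(sim$sequences[sp], sp),
                   file.path(dir, paste0(sp, ".fa")))
  writeMaf(sim$paralogAlns, file.path(dir, "paralogs.maf"))
  writeMaf(sim$orthologAlns, file.path(dir, "orthologs.maf"))
  ape::write.tree(sim$tree, file.path(dir, "species.nwk"))
  write.table(sim$truth, file.path(dir, "truth.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(dir)
}

leavesBelow <- function(phy, branch) {
  nTip <- length(phy$tip.label)
  if (branch == "stem") return(phy$tip.label)
  if (branch %in% phy$tip.label) return(branch)
  node <- as.integer(branch)
  tips <- character(0)
  stack <- node
  while (length(stack)) {
    nd <- stack[1]; stack <- stack[-1]
    kids <- phy$edge[phy$edge[, 1] == nd, 2]
    if (!length(kids)) tips <- c(tips, phy$tip.label[nd])
    else stack <- c(stack, kids)
  }
  tips
}

#' Score detections against the simulated ground truth
#'
#' A detected event matches a true conversion if its converted interval
#' reciprocally overlaps (>= `matchRule`) the true tract placed on either
#' paralog of the converted pair, in a species carrying the conversion.
#' Sensitivity is computed over true conversions detectable in principle:
#' those whose converted pair has a positional ortholog in at least one
#' species outside the carrying clade (the duplication predates an
#' available outgroup split).  With no detections the false discovery rate
#' is reported as 0 by convention.
#'
#' @param observations observation (or non-redundant event) data.frame with
#'   `primary_species`, `conv_start`, `conv_end`.
#' @param sim output of [simulateCluster()].
#' @param matchRule reciprocal-overlap fraction (default 0.5).
#' @return list with `sensitivity`, `fdr`, `boundary_errors` (bp, one per
#'   matched true conversion), `median_boundary_error`, and the underlying
#'   counts.
#' @export
evaluateDetection <- function(observations, sim, matchRule = 0.5) {
  truth <- sim$truth[sim$truth$kind == "conversion", , drop = FALSE]
  idx <- sim$paralogIndex
  phy <- sim$tree
  offsets <- function(sp, pid) {
    r <- idx[idx$species == sp & idx$paralog_id == pid, , drop = FALSE]
    if (nrow(r)) r$start[1] else NA_integer_
  }
  nTrue <- nrow(truth)
  detectable <- logical(nTrue)
  matched <- logical(nTrue)
  obsMatched <- rep(FALSE, nrow(observations))
  boundaryErr <- rep(NA_real_, nTrue)

  if (nTrue) for (t in seq_len(nTrue)) {
    carriers <- leavesBelow(phy, truth$branch[t])
    others <- setdiff(phy$tip.label, carriers)
    pids <- c(truth$donor_id[t], truth$recipient_id[t])
    detectable[t] <- any(vapply(others, function(o)
      any(!is.na(vapply(pids, function(p) offsets(o, p), integer(1)))),
      logical(1)))
    for (sp in carriers) {
      for (pid in pids) {
        off <- offsets(sp, pid)
        if (is.na(off)) next
        ts <- off + truth$start[t]; te <- off + truth$end[t]
        if (!nrow(observations)) next
        hit <- which(observations$primary_species == sp &
          vapply(seq_len(nrow(observations)), function(q)
            reciprocalOverlap(observations$conv_start[q],
                              observations$conv_end[q], ts, te) >= matchRule,
            logical(1)))
        if (length(hit)) {
          matched[t] <- TRUE
          obsMatched[hit] <- TRUE
          errs <- (abs(observations$conv_start[hit] - ts) +
                   abs(observations$conv_end[hit] - te)) / 2
          boundaryErr[t] <- min(boundaryErr[t], min(errs), na.rm = TRUE)
        }
      }
    }
  }
  nDet <- nrow(observations)
  sens <- if (any(detectable)) sum(matched & detectable) / sum(detectable)
          else NA_real_
  fdr <- if (nDet) sum(!obsMatched) / nDet else 0
  be <- boundaryErr[matched]
  list(sensitivity = sens, fdr = fdr, boundary_errors = be,
       median_boundary_error = if (length(be)) stats::median(be) else NA_real_,
       n_true = nTrue, n_detectable = sum(detectable),
       n_matched = sum(matched & detectable), n_detections = nDet)
}
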