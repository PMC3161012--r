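#' Run the full detection pipeline on in-memory inputs
#'
#' Scan every (primary, paralog pair, outgroup) combination, collapse
#' redundant observations into events, and place each event on the species
#' tree.
#'
#' @param paralogAlns list of intra-species [AlignedPair-class] objects.
#' @param orthology list of ortholog [AlignedPair-class] objects.
#' @param tree A [SpeciesTree-class].
#' @param config [detectionConfig()] list.
#' @return list with `observations`, `events` (full table with event ids and
#'   branches), `events_nr` (non-redundant representatives), `manifest`.
#' @export
runPipeline <- function(paralogAlns, orthology, tree,
                        config = detectionConfig()) {
  scan <- scanCluster(paralogAlns, orthology, tree, config)
  dedup <- deduplicate(scan$observations, orthology, paralogAlns,
                       config$boundary_tol)
  timed <- annotateBranches(dedup, tree)
  manifest <- list(
    config = config,
    version = as.character(utils::packageVersion("paraconv")),
    n_paralog_pairs = length(paralogAlns),
    n_tests_attempted = scan$tests_attempted,
    cutoff = scan$cutoff,
    n_observations = nrow(scan$observations),
    n_events = nrow(timed$nonredundant))
  list(observations = scan$observations, events = timed$full,
       events_nr = timed$nonredundant, manifest = manifest)
}

userFacing <- function(df) {
  # 1-based inclusive coordinates in all reports
  out <- df
  for (col in c("par1_start", "par2_start", "conv_start", "conv2_start",
                "out_start")) {
    if (col %in% names(out)) out[[col]] <- out[[col]] + 1L
  }
  keep <- intersect(c("event_id", "primary_species", "chrom", "par1_start",
                      "par1_end", "par2_start", "par2_end", "outgroup",
                      "conv_start", "conv_end", "direction", "p_value",
                      "criterion", "m", "n", "k", "kept", "inferred_case",
                      "branch"), names(out))
  out[, keep, drop = FALSE]
}

writeTsv <- function(df, path) {
  tmp <- paste0(path, ".tmp")
  write.table(df, tmp, sep = "\t", quote = FALSE, row.names = FALSE)
  file.rename(tmp, path)
  invisible(path)
}

#' Run the pipeline from files and write result tables
#'
#' @param mafDir directory of MAF files; paralog (intra-species) and
#'   ortholog (inter-species) blocks are classified per block.
#' @param treePath Newick species-tree file.
#' @param outDir output directory.
#' @param config [detectionConfig()] list.
#' @param fastaDir optional directory of per-species FASTA (recorded in the
#'   manifest; the detector itself consumes alignments).
#' @return the [runPipeline()] result, invisibly.  Writes
#'   `observations.tsv`, `events.tsv`, `events_nr.tsv`, `manifest.json` and
#'   `species_numbered.nwk` (1-based inclusive coordinates).
#' @export
runAll <- function(mafDir, treePath, outDir, config = detectionConfig(),
                   fastaDir = NULL) {
  tree <- readSpeciesTree(treePath)
  mafs <- list.files(mafDir, pattern = "\\.maf$", full.names = TRUE)
  alns <- unlist(lapply(sort(mafs), readMaf), recursive = FALSE)
  if (is.null(alns)) alns <- list()
  kinds <- vapply(alns, function(a) a@kind, character(1))
  paralogAlns <- alns[kinds == "paralog"]
  orthology <- alns[kinds == "ortholog"]
  if (!length(paralogAlns))
    warning("no paralog alignment blocks found in ", mafDir)
  res <- runPipeline(paralogAlns, orthology, tree, config)
  res$manifest$inputs <- list(maf_dir = mafDir, tree = treePath,
                              fasta_dir = fastaDir)
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  writeTsv(userFacing(res$observations), file.path(outDir, "observations.tsv"))
  writeTsv(userFacing(res$events), file.path(outDir, "events.tsv"))
  writeTsv(userFacing(res$events_nr), file.path(outDir, "events_nr.tsv"))
  jsonlite::write_json(res$manifest, file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  writeNumberedTree(tree, file.path(outDir, "species_numbered.nwk"))
  invisible(res)
}

#' Summarise events over a cluster
#'
#' Reports (i) the fraction of paralog pairs carrying at least one event,
#' (ii) the fraction of duplicated bases (bases covered by any paralog
#' alignment row) involved in >= 1, >= 2 and >= 4 events as donor or
#' recipient, and (iii) per-annotation-feature event counts (hot-spot
#' table), if a BED annotation is given.
#'
#' @param events non-redundant event data.frame (internal 0-based
#'   coordinates, e.g. `runPipeline()$events_nr`).
#' @param paralogAlns the paralog alignments that were scanned.
#' @param bed optional annotation data.frame from [readBedFeatures()].
#' @return list with `pair_fraction`, `base_fractions` (named, tiers
#'   `ge1`/`ge2`/`ge4`), `duplicated_bases` and `hotspots` (data.frame, or
#'   NULL without annotations).
#' @export
summarizeEvents <- function(events, paralogAlns, bed = NULL) {
  pairHasEvent <- vapply(paralogAlns, function(aln) {
    if (!nrow(events)) return(FALSE)
    any(events$primary_species == aln@species1 &
        events$chrom == aln@chrom1 &
        vapply(seq_len(nrow(events)), function(i)
          reciprocalOverlap(events$par1_start[i], events$par1_end[i],
                            aln@start1, aln@end1) > 0 &&
          reciprocalOverlap(events$par2_start[i], events$par2_end[i],
                            aln@start2, aln@end2) > 0, logical(1)))
  }, logical(1))
  pairFraction <- if (length(paralogAlns)) mean(pairHasEvent) else NA_real_

  # per-species coverage counting of duplicated and converted bases
  cov <- list()
  dup <- list()
  ensure <- function(sp, len) {
    if (is.null(cov[[sp]]) || length(cov[[sp]]) < len) {
      old <- cov[[sp]]
      cov[[sp]] <<- integer(len); dupOld <- dup[[sp]]
      dup[[sp]] <<- logical(len)
      if (!is.null(old)) {
        cov[[sp]][seq_along(old)] <<- old
        dup[[sp]][seq_along(dupOld)] <<- dupOld
      }
    }
  }
  for (aln in paralogAlns) {
    sp <- aln@species1
    ensure(sp, max(aln@end1, aln@end2))
    dup[[sp]][(aln@start1 + 1):aln@end1] <- TRUE
    dup[[sp]][(aln@start2 + 1):aln@end2] <- TRUE
  }
  if (nrow(events)) for (i in seq_len(nrow(events))) {
    sp <- events$primary_species[i]
    for (iv in list(c(events$conv_start[i], events$conv_end[i]),
                    c(events$conv2_start[i], events$conv2_end[i]))) {
      if (any(is.na(iv))) next
      ensure(sp, iv[2])
      cov[[sp]][(iv[1] + 1):iv[2]] <- cov[[sp]][(iv[1] + 1):iv[2]] + 1L
    }
  }
  dupTotal <- sum(vapply(dup, sum, integer(1)))
  tier <- function(thr) {
    if (dupTotal == 0) return(NA_real_)
    conv <- sum(vapply(names(dup), function(sp)
      sum(cov[[sp]][dup[[sp]]] >= thr), integer(1)))
    conv / dupTotal
  }
  baseFractions <- c(ge1 = tier(1), ge2 = tier(2), ge4 = tier(4))

  hotspots <- NULL
  if (!is.null(bed) && nrow(bed)) {
    counts <- vapply(seq_len(nrow(bed)), function(f) {
      sp <- bed$chrom[f]
      if (!sp %in% events$chrom && !sp %in% events$primary_species) {
        warning("annotation sequence '", sp, "' matches no events; skipped")
        return(NA_integer_)
      }
      sum(events$chrom == sp &
          pmax(events$conv_start, bed$start[f]) <
          pmin(events$conv_end, bed$end[f]))
    }, integer(1))
    hotspots <- data.frame(name = bed$name, chrom = bed$chrom,
                           events = counts, stringsAsFactors = FALSE)
    hotspots <- hotspots[!is.na(hotspots$events), , drop = FALSE]
    hotspots <- hotspots[order(-hotspots$events), , drop = FALSE]
    rownames(hotspots) <- NULL
  }
  list(pair_fraction = pairFraction, base_fractions = baseFractions,
       duplicated_bases = dupTotal, hotspots = hotspots)
}
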