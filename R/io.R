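#' Read sequences from a FASTA file
#'
#' Thin wrapper over [Biostrings::readBStringSet()] returning uppercase
#' character sequences with names preserved.  Ambiguity codes are retained
#' (they are treated as non-informative by the tests).
#'
#' @param path FASTA file.
#' @return Named character vector of uppercase sequences (possibly empty).
#' @export
readFastaSeqs <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  nonEmpty <- which(nzchar(trimws(lines)))
  if (length(nonEmpty) == 0) return(setNames(character(0), character(0)))
  if (!startsWith(trimws(lines[nonEmpty[1]]), ">"))
    stop("malformed FASTA record at line ", nonEmpty[1],
         ": expected '>' header")
  ss <- Biostrings::readBStringSet(path)
  setNames(toupper(as.character(ss)), names(ss))
}

#' Write sequences to a FASTA file
#' @param seqs named character vector.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeFastaSeqs <- function(seqs, path) {
  Biostrings::writeXStringSet(Biostrings::BStringSet(seqs), path)
  invisible(path)
}

splitSrc <- function(src) {
  dot <- regexpr(".", src, fixed = TRUE)
  if (dot > 0)
    c(substr(src, 1, dot - 1), substr(src, dot + 1, nchar(src)))
  else c(src, src)
}

#' Read pairwise alignment blocks from a MAF file
#'
#' Each `a` block must contain exactly two `s` rows.  MAF
#' start/size/strand/srcSize coordinates are converted to the internal
#' 0-based half-open forward-strand convention, and blocks are normalised so
#' that row 1 is plus-strand.  `s`-line source names of the form
#' `species.chrom` are split at the first dot; names without a dot use the
#' whole name for both.
#'
#' @param path MAF file.
#' @param kind force `"paralog"`/`"ortholog"`; by default inferred per block
#'   from whether the two species names are equal.
#' @return list of [AlignedPair-class] objects.
#' @export
readMaf <- function(path, kind = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  out <- list()
  i <- 1
  while (i <= length(lines)) {
    line <- trimws(lines[i])
    if (startsWith(line, "a")) {
      srows <- list()
      j <- i + 1
      while (j <= length(lines) && nzchar(trimws(lines[j])) &&
             !startsWith(trimws(lines[j]), "a")) {
        l <- trimws(lines[j])
        if (startsWith(l, "s ") || startsWith(l, "s\t")) {
          f <- strsplit(l, "[ \t]+")[[1]]
          if (length(f) < 7)
            stop("malformed MAF s-line at line ", j, " of ", path)
          srows[[length(srows) + 1]] <- list(
            src = f[2], start = as.integer(f[3]), size = as.integer(f[4]),
            strand = f[5], srcSize = as.integer(f[6]), text = f[7], line = j)
        }
        j <- j + 1
      }
      if (length(srows) != 2)
        stop("MAF block at line ", i, " has ", length(srows),
             " 's' rows; exactly 2 are required")
      rows <- lapply(srows, function(r) {
        if (nchar(gsub("-", "", r$text, fixed = TRUE)) != r$size)
          stop("MAF size mismatch with gapped text at line ", r$line)
        sc <- splitSrc(r$src)
        if (r$strand == "+") {
          start <- r$start; end <- r$start + r$size
        } else {
          start <- r$srcSize - r$start - r$size
          end <- r$srcSize - r$start
        }
        list(species = sc[1], chrom = sc[2], start = start, end = end,
             strand = r$strand, text = r$text, srcLen = r$srcSize)
      })
      blockKind <- if (!is.null(kind)) kind
        else if (rows[[1]]$species == rows[[2]]$species) "paralog"
        else "ortholog"
      out[[length(out) + 1]] <- alignedPair(
        rows[[1]]$species, rows[[1]]$chrom, rows[[1]]$start, rows[[1]]$end,
        rows[[1]]$strand, rows[[1]]$text,
        rows[[2]]$species, rows[[2]]$chrom, rows[[2]]$start, rows[[2]]$end,
        rows[[2]]$strand, rows[[2]]$text,
        kind = blockKind,
        srcLen1 = rows[[1]]$srcLen, srcLen2 = rows[[2]]$srcLen)
      i <- j
    } else i <- i + 1
  }
  out
}

mafRowFields <- function(aln, row) {
  iv <- rowInterval(aln, row)
  srcLen <- if (row == 1) aln@srcLen1 else aln@srcLen2
  text <- if (row == 1) aln@text1 else aln@text2
  size <- iv$end - iv$start
  start <- if (iv$strand == "+") iv$start else srcLen - iv$end
  src <- if (iv$chrom == iv$species) iv$species
         else paste0(iv$species, ".", iv$chrom)
  sprintf("s %s %d %d %s %d %s", src, start, size, iv$strand, srcLen, text)
}

#' Write AlignedPair blocks to a MAF file
#' @param alns list of [AlignedPair-class] objects.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeMaf <- function(alns, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##maf version=1", con)
  for (aln in alns) {
    writeLines("a", con)
    writeLines(mafRowFields(aln, 1), con)
    writeLines(mafRowFields(aln, 2), con)
    writeLines("", con)
  }
  invisible(path)
}

#' Read a BED file of features
#'
#' Uses [rtracklayer::import.bed()] and returns a plain data.frame in the
#' internal 0-based half-open convention, for annotation-based summaries.
#'
#' @param path BED file.
#' @return data.frame with columns chrom, start (0-based), end, name.
#' @export
readBedFeatures <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  gr <- rtracklayer::import(path, format = "bed")
  nm <- if (!is.null(gr$name)) as.character(gr$name)
        else paste0("feature_", seq_along(gr))
  data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr) - 1L,
             end = GenomicRanges::end(gr),
             name = nm, stringsAsFactors = FALSE)
}
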