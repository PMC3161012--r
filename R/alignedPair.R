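#' Construct an AlignedPair
#'
#' Coordinates are 0-based half-open on the forward strand.  If row 1 is on
#' the minus strand the whole block is reverse-complemented so that row 1 is
#' always plus-strand; the statistical tests are orientation-invariant, so
#' all downstream logic ignores strand.
#'
#' @param species1,chrom1,start1,end1,strand1,text1 row 1 fields.
#' @param species2,chrom2,start2,end2,strand2,text2 row 2 fields.
#' @param kind `"paralog"` (intra-species) or `"ortholog"` (inter-species).
#' @param srcLen1,srcLen2 source sequence lengths; default the interval ends.
#' @return An [AlignedPair-class] object.
#' @export
alignedPair <- function(species1, chrom1, start1, end1, strand1, text1,
                        species2, chrom2, start2, end2, strand2, text2,
                        kind = c("paralog", "ortholog"),
                        srcLen1 = NA_integer_, srcLen2 = NA_integer_) {
  kind <- match.arg(kind)
  if (is.na(srcLen1)) srcLen1 <- as.integer(end1)
  if (is.na(srcLen2)) srcLen2 <- as.integer(end2)
  text1 <- toupper(text1); text2 <- toupper(text2)
  if (strand1 == "-") {
    text1 <- revcompGapped(text1)
    text2 <- revcompGapped(text2)
    strand1 <- "+"
    strand2 <- if (strand2 == "-") "+" else "-"
  }
  new("AlignedPair",
      species1 = species1, chrom1 = chrom1,
      start1 = as.integer(start1), end1 = as.integer(end1), strand1 = strand1,
      text1 = text1,
      species2 = species2, chrom2 = chrom2,
      start2 = as.integer(start2), end2 = as.integer(end2), strand2 = strand2,
      text2 = text2,
      srcLen1 = as.integer(srcLen1), srcLen2 = as.integer(srcLen2),
      kind = kind)
}

revcompGapped <- function(x) {
  chartr("ACGTRYKMBDHVacgtrykmbdhv", "TGCAYRMKVHDBtgcayrmkvhdb",
         paste(rev(strsplit(x, "")[[1]]), collapse = ""))
}

#' Number of alignment columns
#' @param aln An [AlignedPair-class].
#' @return integer(1).
#' @export
alignmentNcol <- function(aln) nchar(aln@text1)

#' Alignment rows as character vectors
#' @param aln An [AlignedPair-class].
#' @param row 1 or 2.
#' @return character vector of column characters.
#' @export
alignedRow <- function(aln, row) {
  strsplit(if (row == 1) aln@text1 else aln@text2, "")[[1]]
}

rowInterval <- function(aln, row) {
  if (row == 1)
    list(species = aln@species1, chrom = aln@chrom1, start = aln@start1,
         end = aln@end1, strand = aln@strand1)
  else
    list(species = aln@species2, chrom = aln@chrom2, start = aln@start2,
         end = aln@end2, strand = aln@strand2)
}

#' Column-to-genome map of one alignment row
#'
#' For each alignment column, the 0-based forward-strand genomic position of
#' that row's base, or `NA` at gap columns.  Minus-strand rows map from the
#' interval end downwards.
#'
#' @param aln An [AlignedPair-class].
#' @param row 1 or 2.
#' @return integer vector, one entry per alignment column.
#' @export
columnGenomePos <- function(aln, row) {
  chars <- alignedRow(aln, row)
  iv <- rowInterval(aln, row)
  pos <- rep(NA_integer_, length(chars))
  nongap <- chars != "-"
  idx <- cumsum(nongap) - 1L  # 0-based index among non-gap chars
  if (iv$strand == "+") {
    pos[nongap] <- iv$start + idx[nongap]
  } else {
    pos[nongap] <- iv$end - 1L - idx[nongap]
  }
  pos
}

#' Percent identity of a pairwise alignment
#'
#' Fraction of matching columns among columns where both rows carry an
#' unambiguous nucleotide; gap and ambiguity columns are excluded from the
#' denominator, so the value reflects substitution identity only.
#'
#' @param aln An [AlignedPair-class].
#' @param window optional `c(first, last)` alignment-column window
#'   (1-based inclusive).
#' @return Fraction in \[0, 1\], or `NA_real_` (with a warning) if the window
#'   contains no comparable columns.
#' @export
percentIdentity <- function(aln, window = NULL) {
  c1 <- alignedRow(aln, 1)
  c2 <- alignedRow(aln, 2)
  if (!is.null(window)) {
    stopifnot(length(window) == 2, window[1] >= 1,
              window[2] <= length(c1), window[1] <= window[2])
    keep <- seq(window[1], window[2])
    c1 <- c1[keep]; c2 <- c2[keep]
  }
  ok <- c1 %in% c("A", "C", "G", "T") & c2 %in% c("A", "C", "G", "T")
  if (!any(ok)) {
    warning("percent identity undefined: no comparable columns in window")
    return(NA_real_)
  }
  sum(c1[ok] == c2[ok]) / sum(ok)
}

#' Project an ortholog alignment onto paralog-alignment columns
#'
#' For each column of the paralog alignment whose chosen row carries a real
#' nucleotide at genomic position g, returns the outgroup base aligned to g
#' in the ortholog alignment, or `NA` ("uncovered") where g is outside the
#' ortholog alignment or gapped in the outgroup row.  Columns where the
#' chosen paralog row is gapped are `NA` as well.
#'
#' @param paralog intra-species [AlignedPair-class].
#' @param ortholog inter-species [AlignedPair-class]; one of its rows must be
#'   in the paralog's species on the same sequence.
#' @param whichRow which paralog row (1 or 2) the ortholog maps through.
#' @return character vector of outgroup bases (or `NA`), one per paralog
#'   alignment column.  Zero overlap yields an all-`NA` projection.
#' @export
projectOntoParalogColumns <- function(paralog, ortholog, whichRow = 1) {
  piv <- rowInterval(paralog, whichRow)
  # identify which ortholog row lives in the paralog's species/sequence
  o1 <- rowInterval(ortholog, 1)
  o2 <- rowInterval(ortholog, 2)
  selfRow <- if (o1$species == piv$species && o1$chrom == piv$chrom) 1L
             else if (o2$species == piv$species && o2$chrom == piv$chrom) 2L
             else stop("ortholog alignment has no row in species '",
                       piv$species, "' on sequence '", piv$chrom, "'")
  otherRow <- 3L - selfRow

  selfPos <- columnGenomePos(ortholog, selfRow)
  outChars <- alignedRow(ortholog, otherRow)
  outChars[outChars == "-"] <- NA_character_
  # bases must be expressed in the reading orientation of the paralog row:
  # if the ortholog block reads the shared species on the opposite strand,
  # complement the projected characters (positions are handled by the
  # per-strand column-to-genome maps)
  if (rowInterval(ortholog, selfRow)$strand != piv$strand)
    outChars <- chartr("ACGTRYKMBDHV", "TGCAYRMKVHDB", outChars)
  # genomic position -> outgroup base (NA where outgroup is gapped)
  covered <- !is.na(selfPos)
  map <- outChars[covered]
  names(map) <- as.character(selfPos[covered])

  parPos <- columnGenomePos(paralog, whichRow)
  out <- rep(NA_character_, length(parPos))
  hit <- !is.na(parPos)
  out[hit] <- map[as.character(parPos[hit])]
  unname(out)
}
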