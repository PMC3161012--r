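#' @import methods
NULL

#' Gapped alignment of two genomic intervals
#'
#' An `AlignedPair` holds one pairwise alignment block: two gapped sequence
#' rows, each anchored to a genomic interval (species, sequence name, 0-based
#' half-open coordinates, strand).  `kind` distinguishes intra-species
#' (`"paralog"`) from inter-species (`"ortholog"`) alignments.  Minus-strand
#' rows are normalised at construction so that downstream logic is
#' strand-free; row coordinates always refer to the forward strand.
#'
#' @slot species1,species2 character(1) species names.
#' @slot chrom1,chrom2 character(1) sequence (chromosome/contig) names.
#' @slot start1,end1,start2,end2 integer(1) 0-based half-open interval bounds.
#' @slot strand1,strand2 character(1), `"+"` or `"-"` (orientation of the
#'   aligned text relative to the forward strand).
#' @slot text1,text2 character(1) gapped sequence rows (equal length, `-` gaps).
#' @slot srcLen1,srcLen2 integer(1) full source sequence lengths (MAF srcSize;
#'   needed to express minus-strand rows in MAF coordinates).
#' @slot kind character(1), `"paralog"` or `"ortholog"`.
#'
#' @seealso [alignedPair()], [percentIdentity()], [readMaf()]
#' @export
setClass("AlignedPair",
  representation(
    species1 = "character", chrom1 = "character",
    start1 = "integer", end1 = "integer", strand1 = "character",
    text1 = "character",
    species2 = "character", chrom2 = "character",
    start2 = "integer", end2 = "integer", strand2 = "character",
    text2 = "character",
    srcLen1 = "integer", srcLen2 = "integer",
    kind = "character"
  )
)

setValidity("AlignedPair", function(object) {
  msg <- character()
  if (nchar(object@text1) != nchar(object@text2))
    msg <- c(msg, "gapped rows must have equal length")
  u1 <- nchar(gsub("-", "", object@text1, fixed = TRUE))
  u2 <- nchar(gsub("-", "", object@text2, fixed = TRUE))
  if (object@start1 < 0L || object@start1 >= object@end1)
    msg <- c(msg, "row 1 interval must satisfy 0 <= start < end")
  if (object@start2 < 0L || object@start2 >= object@end2)
    msg <- c(msg, "row 2 interval must satisfy 0 <= start < end")
  if (u1 != object@end1 - object@start1)
    msg <- c(msg, "row 1 ungapped length does not match its interval")
  if (u2 != object@end2 - object@start2)
    msg <- c(msg, "row 2 ungapped length does not match its interval")
  if (!object@strand1 %in% c("+", "-") || !object@strand2 %in% c("+", "-"))
    msg <- c(msg, "strands must be '+' or '-'")
  if (object@end1 > object@srcLen1 || object@end2 > object@srcLen2)
    msg <- c(msg, "intervals must lie within their source sequences")
  if (!object@kind %in% c("paralog", "ortholog"))
    msg <- c(msg, "kind must be 'paralog' or 'ortholog'")
  c1 <- strsplit(object@text1, "")[[1]]
  c2 <- strsplit(object@text2, "")[[1]]
  if (length(c1) && any(c1 == "-" & c2 == "-"))
    msg <- c(msg, "gap-gap columns are not allowed")
  if (object@kind == "paralog" && object@species1 != object@species2)
    msg <- c(msg, "paralog alignments must be intra-species")
  if (object@kind == "ortholog" && object@species1 == object@species2)
    msg <- c(msg, "ortholog alignments must be inter-species")
  if (length(msg)) msg else TRUE
})

#' Species tree with stable edge numbering
#'
#' Wraps a rooted `ape::phylo` object and assigns every edge a stable integer
#' identifier in depth-first post-order (the order of
#' `ape::reorder.phylo(phy, "postorder")`).  Each edge is keyed by its child
#' node; the root has no parent edge.  Edge 0 is reserved as a virtual
#' "above the root" marker used when an event predates the root split.
#'
#' @slot phy the rooted `phylo` tree.
#' @slot edgeId integer vector parallel to `phy$edge` rows.
#'
#' @seealso [readSpeciesTree()], [speciesTree()], [edgeTable()]
#' @export
setClass("SpeciesTree",
  representation(phy = "ANY", edgeId = "integer")
)

setValidity("SpeciesTree", function(object) {
  msg <- character()
  phy <- object@phy
  if (!inherits(phy, "phylo")) msg <- c(msg, "phy must be a phylo object")
  else {
    if (anyDuplicated(phy$tip.label))
      msg <- c(msg, "duplicate leaf labels")
    if (!ape::is.rooted(phy))
      msg <- c(msg, "tree must be rooted")
    if (length(object@edgeId) != nrow(phy$edge))
      msg <- c(msg, "edgeId must have one entry per edge")
    if (anyDuplicated(object@edgeId))
      msg <- c(msg, "edge ids must be unique")
  }
  if (length(msg)) msg else TRUE
})

#' Up/down step series over paralog-alignment columns
#'
#' The cumulative-score random walk underlying the conversion tests.  Each
#' informative site contributes an up step (+1, primary matches the paralog
#' but not the ortholog) or a down step (-1, primary matches the ortholog but
#' not the paralog).  Quadruplet combination can produce steps of magnitude 2.
#' `m` and `n` are the total up and down magnitudes (unit-step counts).
#'
#' @slot column integer vector, strictly increasing alignment columns (1-based).
#' @slot step integer vector of +1/-1 signs.
#' @slot magnitude integer vector of step magnitudes (1 or 2).
#' @slot m,n integer(1) total up/down unit steps.
#' @slot totalColumns integer(1) paralog alignment length in columns.
#'
#' @seealso [buildTripletWalk()], [combineQuadruplet()], [maximumDescent()]
#' @export
setClass("ConversionWalk",
  representation(
    column = "integer", step = "integer", magnitude = "integer",
    m = "integer", n = "integer", totalColumns = "integer"
  )
)

setValidity("ConversionWalk", function(object) {
  msg <- character()
  k <- length(object@column)
  if (length(object@step) != k || length(object@magnitude) != k)
    msg <- c(msg, "column, step and magnitude must have equal length")
  if (k > 1 && any(diff(object@column) <= 0))
    msg <- c(msg, "column indices must be strictly increasing")
  if (k && !all(object@step %in% c(-1L, 1L)))
    msg <- c(msg, "steps must be +1 or -1")
  if (k && any(object@magnitude < 1L))
    msg <- c(msg, "magnitudes must be positive")
  up <- sum(object@magnitude[object@step == 1L])
  dn <- sum(object@magnitude[object@step == -1L])
  if (object@m != up || object@n != dn)
    msg <- c(msg, "m/n must equal the total up/down magnitudes")
  if (length(msg)) msg else TRUE
})

setMethod("show", "AlignedPair", function(object) {
  cat(sprintf("AlignedPair (%s), %d columns\n", object@kind,
              nchar(object@text1)))
  cat(sprintf("  row1: %s %s:%d-%d (%s)\n", object@species1, object@chrom1,
              object@start1 + 1L, object@end1, object@strand1))
  cat(sprintf("  row2: %s %s:%d-%d (%s)\n", object@species2, object@chrom2,
              object@start2 + 1L, object@end2, object@strand2))
})

setMethod("show", "SpeciesTree", function(object) {
  cat(sprintf("SpeciesTree: %d species, %d numbered edges\n",
              length(object@phy$tip.label), nrow(object@phy$edge)))
  cat("  species:", paste(sort(object@phy$tip.label), collapse = ", "), "\n")
})

setMethod("show", "ConversionWalk", function(object) {
  cat(sprintf("ConversionWalk: %d steps (m = %d up, n = %d down) over %d columns\n",
              length(object@column), object@m, object@n, object@totalColumns))
})
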