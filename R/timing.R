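#' Upper (earliest-possible) bound edge of a conversion event
#'
#' Detection with an outgroup places the conversion after the
#' primary/outgroup split.  Per primary species the closest detecting
#' outgroup (fewest edges on the leaf-to-leaf path; topology only) gives the
#' tightest bound: the edge immediately below that split on the primary's
#' lineage.  With several carrying primaries, the most recent of these edges
#' that is still ancestral to all of them is returned.  Absence of detection
#' in a species never contributes to a bound.
#'
#' @param eventObs data.frame of all observations of one event (columns
#'   `primary_species`, `outgroup`).
#' @param tree A [SpeciesTree-class].
#' @return integer edge id, or `NA` if no candidate edge is ancestral to all
#'   carrying primaries (a data inconsistency).
#' @export
upperBoundEdge <- function(eventObs, tree) {
  primaries <- unique(eventObs$primary_species)
  candidates <- integer(0)
  for (p in primaries) {
    outs <- unique(eventObs$outgroup[eventObs$primary_species == p])
    d <- vapply(outs, function(o) topoDistance(tree, p, o), integer(1))
    closest <- outs[which.min(d)]
    mrca <- lcaNode(tree, c(p, closest))
    chain <- ancestorChain(tree, tipNode(tree, p))
    below <- chain[match(mrca, chain) - 1L]   # node just under the split
    candidates <- c(candidates, edgeAbove(tree, below))
  }
  tips <- tipNode(tree, primaries)
  ok <- vapply(candidates, function(e) {
    nd <- nodeBelowEdge(tree, e)
    all(vapply(tips, function(t) isAncestorOrSelf(tree, nd, t), logical(1)))
  }, logical(1))
  if (!any(ok)) return(NA_integer_)
  cand <- candidates[ok]
  # most recent = the candidate deepest in the tree (longest root chain)
  depth <- vapply(cand, function(e)
    length(ancestorChain(tree, nodeBelowEdge(tree, e))), integer(1))
  cand[which.max(depth)]
}

#' Lower (latest-possible) bound edge of a conversion event
#'
#' Carriage of the same event in several primary species means the
#' conversion predates their split, so the latest possible edge is the edge
#' above their last common ancestor.  A single carrying primary gives its
#' terminal edge.  If the carriers' LCA is the root, the virtual pre-root
#' edge 0 is returned.
#'
#' @param eventObs data.frame of all observations of one event.
#' @param tree A [SpeciesTree-class].
#' @return integer edge id (0 = above the root).
#' @export
lowerBoundEdge <- function(eventObs, tree) {
  primaries <- unique(eventObs$primary_species)
  edgeAbove(tree, lcaNode(tree, primaries))
}

#' Assign a conversion event to a sub-lineage of the species tree
#'
#' The event's possible placement is the connected path of edges from the
#' upper-bound edge (just below the closest detecting outgroup's split) down
#' to the lower-bound edge (just above the carriers' last common ancestor).
#' If the bounds are inconsistent — the upper-bound edge is not ancestral to
#' the lower-bound edge — the conflict marker `"?"` is returned.
#'
#' @param eventObs data.frame of all observations of one event.
#' @param tree A [SpeciesTree-class].
#' @return character: hyphen-joined edge ids from earliest to latest
#'   possible edge (e.g. `"4-6"`), or `"?"`.
#' @export
assignBranch <- function(eventObs, tree) {
  ub <- upperBoundEdge(eventObs, tree)
  lb <- lowerBoundEdge(eventObs, tree)
  if (is.na(ub)) return("?")
  if (lb == 0L) {
    # carriers span the root: only consistent if the upper bound does too
    return(if (ub == 0L) "0" else "?")
  }
  ubNode <- nodeBelowEdge(tree, ub)
  lbNode <- nodeBelowEdge(tree, lb)
  chain <- ancestorChain(tree, lbNode)       # lbNode .. root
  pos <- match(ubNode, chain)
  if (is.na(pos)) return("?")                # not on the same lineage
  nodes <- chain[seq_len(pos)]               # lbNode up to ubNode
  edges <- vapply(rev(nodes), function(nd) edgeAbove(tree, nd), integer(1))
  paste(edges, collapse = "-")
}

#' Append branch assignments to deduplicated event tables
#'
#' @param dedup output of [deduplicate()].
#' @param tree A [SpeciesTree-class].
#' @return `dedup` with a `branch` column added to both tables (computed per
#'   event from all of its observations).
#' @export
annotateBranches <- function(dedup, tree) {
  full <- dedup$full
  nr <- dedup$nonredundant
  if (!nrow(nr)) {
    full$branch <- character(0); nr$branch <- character(0)
    return(list(full = full, nonredundant = nr))
  }
  branches <- vapply(nr$event_id, function(id)
    assignBranch(full[full$event_id == id, , drop = FALSE], tree),
    character(1))
  nr$branch <- branches
  full$branch <- branches[match(full$event_id, nr$event_id)]
  list(full = full, nonredundant = nr)
}
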