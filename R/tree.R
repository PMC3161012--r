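#' Build a SpeciesTree from an ape phylo object
#'
#' Edges are numbered deterministically in depth-first post-order (the edge
#' order of `ape::reorder.phylo(phy, "postorder")`); numbering is stable
#' across runs for a given topology.  Each edge is keyed by its child node.
#'
#' @param phy a rooted `phylo` object with unique tip labels.
#' @return A [SpeciesTree-class].
#' @export
speciesTree <- function(phy) {
  if (!inherits(phy, "phylo")) stop("phy must be a phylo object")
  if (!ape::is.rooted(phy))
    stop("the species tree is unrooted (trifurcating root); ",
         "please root the tree before use")
  po <- ape::reorder.phylo(phy, "postorder")
  edgeId <- match(phy$edge[, 2], po$edge[, 2])
  new("SpeciesTree", phy = phy, edgeId = as.integer(edgeId))
}

#' Read a species tree from a Newick file
#' @param path Newick file.
#' @return A [SpeciesTree-class].
#' @export
readSpeciesTree <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  phy <- ape::read.tree(path)
  if (is.null(phy)) stop("could not parse Newick tree from ", path)
  speciesTree(phy)
}

#' Species (leaf) names of a SpeciesTree
#' @param tree A [SpeciesTree-class].
#' @return character vector.
#' @export
speciesNames <- function(tree) tree@phy$tip.label

#' Edge table of a SpeciesTree
#'
#' @param tree A [SpeciesTree-class].
#' @return data.frame with columns `edge_id`, `parent`, `child` (node
#'   numbers) and `child_label` (species name for leaf edges, `""` otherwise).
#' @export
edgeTable <- function(tree) {
  phy <- tree@phy
  lab <- ifelse(phy$edge[, 2] <= length(phy$tip.label),
                phy$tip.label[phy$edge[, 2]], "")
  df <- data.frame(edge_id = tree@edgeId, parent = phy$edge[, 1],
                   child = phy$edge[, 2], child_label = lab,
                   stringsAsFactors = FALSE)
  df[order(df$edge_id), , drop = FALSE]
}

tipNode <- function(tree, species) {
  i <- match(species, tree@phy$tip.label)
  if (any(is.na(i))) stop("species not in tree: ",
                          paste(species[is.na(i)], collapse = ", "))
  i
}

parentNode <- function(tree, node) {
  i <- match(node, tree@phy$edge[, 2])
  if (is.na(i)) NA_integer_ else tree@phy$edge[i, 1]
}

#' Edge id of the edge above a node (0 for the root)
#' @param tree A [SpeciesTree-class].
#' @param node node number.
#' @return integer edge id; 0 denotes the virtual pre-root edge.
#' @export
edgeAbove <- function(tree, node) {
  i <- match(node, tree@phy$edge[, 2])
  if (is.na(i)) 0L else tree@edgeId[i]
}

nodeBelowEdge <- function(tree, edgeId) {
  if (edgeId == 0L) return(rootNode(tree))
  i <- match(edgeId, tree@edgeId)
  if (is.na(i)) stop("no edge with id ", edgeId)
  tree@phy$edge[i, 2]
}

rootNode <- function(tree) {
  setdiff(tree@phy$edge[, 1], tree@phy$edge[, 2])[1]
}

# chain of nodes from `node` up to the root (inclusive)
ancestorChain <- function(tree, node) {
  chain <- node
  repeat {
    p <- parentNode(tree, node)
    if (is.na(p)) break
    chain <- c(chain, p)
    node <- p
  }
  chain
}

#' Last common ancestor node of a set of species
#' @param tree A [SpeciesTree-class].
#' @param species character vector of leaf labels (length >= 1).
#' @return node number.
#' @export
lcaNode <- function(tree, species) {
  tips <- tipNode(tree, unique(species))
  if (length(tips) == 1) return(tips)
  ape::getMRCA(tree@phy, tips)
}

# TRUE iff node a is an ancestor of (or equal to) node b
isAncestorOrSelf <- function(tree, a, b) {
  a %in% ancestorChain(tree, b)
}

#' Topological distance (edge count) between two species
#' @param tree A [SpeciesTree-class].
#' @param sp1,sp2 species names.
#' @return integer number of edges on the leaf-to-leaf path.
#' @export
topoDistance <- function(tree, sp1, sp2) {
  length(ape::nodepath(tree@phy, tipNode(tree, sp1), tipNode(tree, sp2))) - 1L
}

#' Export the species tree with edge numbers as Newick
#'
#' Writes a copy of the tree in which every node label carries the id of the
#' edge above that node (`name#id` for leaves), so that branch assignments in
#' the event tables can be read against the tree.
#'
#' @param tree A [SpeciesTree-class].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeNumberedTree <- function(tree, path) {
  phy <- tree@phy
  nTip <- length(phy$tip.label)
  ids <- vapply(seq_len(nTip + phy$Nnode), function(nd) edgeAbove(tree, nd),
                integer(1))
  phy$tip.label <- paste0(phy$tip.label, "#", ids[seq_len(nTip)])
  phy$node.label <- paste0("#", ids[(nTip + 1):(nTip + phy$Nnode)])
  ape::write.tree(phy, file = path)
  invisible(path)
}
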