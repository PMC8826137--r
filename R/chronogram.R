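#' Read and validate a time-calibrated ultrametric tree
#'
#' Reads a Newick chronogram (branch lengths in Myr), checks that it is
#' rooted, binary, ultrametric within tolerance, and that all branch lengths
#' are positive. Node ages are measured backwards from the present (tips at
#' age 0). When the tip-depth spread is below `tol`, tips are extended to the
#' maximum depth so the tree is exactly ultrametric after floating-point
#' round-trips.
#'
#' @param path path to a Newick file.
#' @param tol ultrametricity tolerance in Myr.
#' @return an `ape::phylo` tree that passes [validate_chronogram()].
#' @export
read_chronogram <- function(path, tol = 1e-6) {
  phy <- ape::read.tree(path)
  if (is.null(phy)) stop("could not parse a Newick tree from ", path)
  validate_chronogram(phy, tol = tol)
}

#' Write a chronogram to a Newick file
#' @param phy an ultrametric `phylo` tree.
#' @param path output path.
#' @export
write_chronogram <- function(phy, path) {
  ape::write.tree(phy, file = path, digits = 12)
  invisible(path)
}

#' Validate a chronogram and make it exactly ultrametric
#'
#' @param phy a `phylo` tree.
#' @param tol ultrametricity tolerance in Myr; deviations below it are
#'   repaired by extending terminal branches, larger deviations are an error.
#' @return the (possibly tip-extended) tree.
#' @export
validate_chronogram <- function(phy, tol = 1e-6) {
  if (!inherits(phy, "phylo")) stop("not a phylo object")
  if (is.null(phy$edge.length)) stop("tree has no branch lengths")
  if (!ape::is.rooted(phy)) stop("tree must be rooted")
  if (!ape::is.binary(phy)) stop("tree must be fully bifurcating")
  if (anyDuplicated(phy$tip.label)) stop("duplicate tip labels")
  if (any(phy$edge.length <= 0)) stop("all branch lengths must be > 0")
  depth <- ape::node.depth.edgelength(phy)
  tipd <- depth[seq_len(ape::Ntip(phy))]
  dev <- max(tipd) - min(tipd)
  if (dev > tol)
    stop("tree is not ultrametric: tip depth spread ", signif(dev, 4),
         " Myr exceeds tolerance ", tol)
  if (dev > 0) {
    # extend terminal branches so every tip sits exactly at the present
    term <- match(seq_len(ape::Ntip(phy)), phy$edge[, 2])
    phy$edge.length[term] <- phy$edge.length[term] + (max(tipd) - tipd)
  }
  phy
}

#' Node ages of a chronogram
#'
#' Ages in Ma before present for all tips and internal nodes, indexed by the
#' `phylo` node numbering (tips `1..Ntip`, then internal nodes).
#'
#' @param phy an ultrametric `phylo` tree.
#' @return numeric vector of length `Ntip + Nnode`.
#' @export
node_ages <- function(phy) {
  depth <- ape::node.depth.edgelength(phy)
  age <- max(depth[seq_len(ape::Ntip(phy))]) - depth
  age[seq_len(ape::Ntip(phy))][abs(age[seq_len(ape::Ntip(phy))]) < 1e-9] <- 0
  age
}

#' Crown (root) age of a chronogram in Ma
#' @param phy an ultrametric `phylo` tree.
#' @export
crown_age <- function(phy) {
  node_ages(phy)[ape::Ntip(phy) + 1L]
}

# branch table: one row per edge, child node id, parent node id, ages
branch_table <- function(phy) {
  age <- node_ages(phy)
  data.frame(child = phy$edge[, 2], parent = phy$edge[, 1],
             young = age[phy$edge[, 2]], old = age[phy$edge[, 1]])
}

#' Total branch length falling inside a time bin
#'
#' Sums, over all branches, the overlap between the branch's time interval
#' and the bin `[young, old]`, in lineage-Myr. Used as the denominator of the
#' per-bin colonization, emigration and immigration rates.
#'
#' @param phy an ultrametric `phylo` tree.
#' @param old,young bin edges in Ma (`old > young`).
#' @return lineage-Myr of tree length inside the bin.
#' @examples
#' tr <- ape::read.tree(text = "(t1:2,t2:2);")
#' branch_length_in_bin(tr, old = 1, young = 0)  # 2 lineages x 1 Myr
#' @export
branch_length_in_bin <- function(phy, old, young) {
  if (old <= young) stop("bin edges must satisfy old > young")
  bt <- branch_table(phy)
  sum(pmax(0, pmin(bt$old, old) - pmax(bt$young, young)))
}

#' Restrict a tree to the taxa of a geography table
#'
#' Drops named outgroup tips and any tip without a row in the geography
#' table, the standard pre-filter before range-evolution analyses.
#'
#' @param phy a `phylo` tree.
#' @param geog a [geography_table()].
#' @param outgroups character vector of tip labels to drop first.
#' @return the pruned tree, whose tips exactly match the geography rows
#'   present on the tree.
#' @export
prune_to_geography <- function(phy, geog, outgroups = character()) {
  keep <- setdiff(phy$tip.label, outgroups)
  keep <- keep[keep %in% rownames(geog$presence)]
  if (length(keep) < 2L) stop("fewer than two tips remain after pruning")
  ape::keep.tip(phy, keep)
}
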