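#' Jitter node ages of a chronogram
#'
#' Emulates divergence-time uncertainty by perturbing every internal node
#' age multiplicatively with a lognormal factor of coefficient of variation
#' `cv`, then restoring the parent-older-than-child order by clamping each
#' node just below its (already jittered) parent in a root-to-tip sweep.
#' Tips stay at the present, so the tree remains ultrametric.
#'
#' @param phy ultrametric `phylo` tree.
#' @param cv relative standard deviation of the age perturbation (>= 0).
#' @param seed optional integer seed (same seed, same tree).
#' @return a jittered chronogram passing [validate_chronogram()].
#' @export
jitter_node_ages <- function(phy, cv, seed = NULL) {
  if (cv < 0) stop("cv must be >= 0")
  if (!is.null(seed)) set.seed(seed)
  if (cv == 0) return(phy)
  phy <- validate_chronogram(phy)
  ntip <- ape::Ntip(phy)
  age <- node_ages(phy)
  sdlog <- sqrt(log(1 + cv^2))
  new_age <- age
  int <- (ntip + 1L):(ntip + phy$Nnode)
  new_age[int] <- age[int] * stats::rlnorm(length(int), -sdlog^2 / 2, sdlog)
  # root-to-tip sweep: child strictly younger than its parent
  pre <- rev(ape::postorder(phy))
  for (k in pre) {
    p <- phy$edge[k, 1]; ch <- phy$edge[k, 2]
    if (ch > ntip && new_age[ch] >= new_age[p])
      new_age[ch] <- new_age[p] * (1 - 1e-8)
  }
  phy$edge.length <- new_age[phy$edge[, 1]] - new_age[phy$edge[, 2]]
  validate_chronogram(phy)
}

#' Graft unsampled tips onto a chronogram
#'
#' Emulates missing taxa: each new tip is attached at a uniform-random age
#' along a uniform-random branch within its attachment clade (the clade
#' spanned by the given tip labels), with the pendant branch reaching the
#' present so the tree stays ultrametric. The range of a grafted taxon is
#' not invented here; supply it in the geography table used downstream.
#'
#' @param phy ultrametric `phylo` tree.
#' @param specs list of specifications, each a list with `tip` (new tip
#'   label) and `clade` (character vector of existing tip labels whose MRCA
#'   subtree is the attachment clade; a single label attaches along that
#'   terminal branch).
#' @param seed optional integer seed.
#' @return the augmented chronogram.
#' @export
graft_missing_tips <- function(phy, specs, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (!length(specs)) return(phy)
  for (sp in specs) {
    phy <- validate_chronogram(phy)
    age <- node_ages(phy)
    lab <- sp$clade
    miss <- setdiff(lab, phy$tip.label)
    if (length(miss)) stop("attachment clade tips not in tree: ",
                           paste(miss, collapse = ", "))
    if (length(lab) == 1L) {
      cand <- match(lab, phy$tip.label)
    } else {
      mrca <- ape::getMRCA(phy, lab)
      desc <- phangorn_descendants(phy, mrca)
      cand <- desc[desc != mrca]  # nodes whose parent branch is inside the clade
    }
    # choose a branch weighted by its length, then an age uniform along it
    blen <- age[phy$edge[match(cand, phy$edge[, 2]), 1]] - age[cand]
    node <- cand[sample_prob(blen)]
    edge_k <- match(node, phy$edge[, 2])
    attach_age <- age[node] + stats::runif(1) * blen[match(node, cand)]
    tipphy <- structure(list(edge = matrix(c(2L, 1L), 1, 2),
                             tip.label = sp$tip,
                             edge.length = attach_age, Nnode = 1L),
                        class = "phylo")
    phy <- ape::bind.tree(phy, tipphy, where = node,
                          position = attach_age - age[node])
  }
  validate_chronogram(phy)
}

phangorn_descendants <- function(phy, node) {
  # all nodes (internal and tips) descending from `node`, including it
  todo <- node
  out <- integer(0)
  while (length(todo)) {
    cur <- todo[1]; todo <- todo[-1]
    out <- c(out, cur)
    todo <- c(todo, phy$edge[phy$edge[, 1] == cur, 2])
  }
  out
}

#' Generate a pseudoreplicate tree set
#'
#' Produces `n` chronograms by age-jittering (and optionally tip-grafting)
#' a base tree, the replicate set over which stochastic mappings are run to
#' propagate dating and sampling uncertainty into the event counts.
#'
#' @param phy base chronogram.
#' @param n number of trees.
#' @param jitter_cv relative SD of node-age jitter.
#' @param graft_specs optional list of graft specifications
#'   (see [graft_missing_tips()]).
#' @param seed integer seed; tree `i` uses `seed + i`.
#' @return an object of class `"tree_set"`: list of trees with a
#'   `provenance` attribute recording the parameters.
#' @export
build_tree_set <- function(phy, n, jitter_cv = 0.05, graft_specs = NULL,
                           seed = 1) {
  trees <- vector("list", n)
  for (i in seq_len(n)) {
    tr <- jitter_node_ages(phy, jitter_cv, seed = seed + i)
    if (length(graft_specs)) tr <- graft_missing_tips(tr, graft_specs)
    trees[[i]] <- tr
  }
  structure(trees, class = "tree_set",
            provenance = list(n = n, jitter_cv = jitter_cv,
                              n_grafts = length(graft_specs), seed = seed))
}

#' @export
print.tree_set <- function(x, ...) {
  pv <- attr(x, "provenance")
  cat("Tree set: ", length(x), " pseudoreplicate chronograms (jitter cv = ",
      pv$jitter_cv, ", ", pv$n_grafts, " grafted tips, seed ", pv$seed,
      ")\n", sep = "")
  invisible(x)
}
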