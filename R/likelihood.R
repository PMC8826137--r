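# Internal likelihood machinery: a prepared model context (tree traversal
# order, epoch segments per branch, tip states, cladogenesis table) built
# once, plus an engine evaluating the pruning likelihood at given (d, e),
# optionally storing every intermediate needed for ancestral-state
# estimation and stochastic mapping.

prep_model <- function(phy, geog, family, epoch, space) {
  phy <- validate_chronogram(phy)
  ntip <- ape::Ntip(phy)
  nnode <- phy$Nnode
  if (is.null(epoch)) epoch <- uniform_epoch_model(space$n_areas,
                                                   top_age = crown_age(phy) + 1)
  if (length(epoch$areas) != space$n_areas)
    stop("epoch model and state space disagree on the number of areas")
  tipm <- tip_masks(geog, phy$tip.label)
  tipidx <- state_index(space, tipm)
  if (anyNA(tipidx))
    stop("observed tip range exceeds max_range_size for: ",
         paste(phy$tip.label[is.na(tipidx)], collapse = ", "))
  po <- ape::reorder.phylo(phy, "postorder")
  age <- node_ages(phy)
  edges <- po$edge
  seglist <- vector("list", ntip + nnode)  # segments of the branch above each node
  for (k in seq_len(nrow(edges)))
    seglist[[edges[k, 2]]] <- branch_segments(epoch, age[edges[k, 1]],
                                              age[edges[k, 2]])
  kids <- matrix(0L, ntip + nnode, 2L)
  for (k in seq_len(nrow(edges))) {
    p <- edges[k, 1]
    kids[p, if (kids[p, 1] == 0L) 1L else 2L] <- edges[k, 2]
  }
  tab <- clado_table(space, family)
  K <- space$n_states
  Cmat <- Matrix::sparseMatrix(i = tab$anc, j = seq_along(tab$anc),
                               x = tab$w, dims = c(K, length(tab$anc)))
  list(phy = phy, ntip = ntip, nnode = nnode, root = ntip + 1L, age = age,
       edges = edges, seglist = seglist, kids = kids, tipidx = tipidx,
       family = family, epoch = epoch, space = space, tab = tab, Cmat = Cmat)
}

# combine the two daughters' branch-propagated conditionals through the
# cladogenesis table: cond[G] = sum_events w * AL[left] * AR[right]
combine_clado <- function(prep, AL, AR) {
  as.vector(prep$Cmat %*% (AL[prep$tab$left] * AR[prep$tab$right]))
}

lik_engine <- function(prep, d, e, store = FALSE) {
  space <- prep$space
  K <- space$n_states
  nn <- prep$ntip + prep$nnode
  Qs <- lapply(seq_len(prep$epoch$n_slices), function(s)
    build_rate_matrix(space, d, e, prep$epoch, s))
  props <- lapply(Qs, make_propagator)
  A <- matrix(NA_real_, K, nn)      # conditionals propagated to the parent end
  cond <- matrix(NA_real_, K, nn)   # pre-cladogenesis conditionals per node
  logscale <- 0
  Pbranch <- if (store) vector("list", nn) else NULL
  Pseg <- if (store) vector("list", nn) else NULL
  for (i in seq_len(prep$ntip)) {
    v <- numeric(K); v[prep$tipidx[i]] <- 1
    cond[, i] <- v
  }
  impossible <- FALSE
  node_cond <- function(v_id) {
    # internal node: both kids' A columns exist by postorder
    cv <- combine_clado(prep, A[, prep$kids[v_id, 1L]], A[, prep$kids[v_id, 2L]])
    s <- max(cv)
    if (s <= 0 || !is.finite(s)) { impossible <<- TRUE; return(cv) }
    logscale <<- logscale + log(s)
    cv / s
  }
  edges <- prep$edges
  for (k in seq_len(nrow(edges))) {
    ch <- edges[k, 2]
    if (ch > prep$ntip) cond[, ch] <- node_cond(ch)
    if (impossible) break
    segs <- prep$seglist[[ch]]
    if (store) {
      M <- NULL
      Ps_list <- vector("list", nrow(segs))
      for (s in seq_len(nrow(segs))) {
        Ps <- props[[segs$slice[s]]](segs$old[s] - segs$young[s])
        Ps_list[[s]] <- Ps
        M <- if (is.null(M)) Ps else M %*% Ps
      }
      Pbranch[[ch]] <- M
      Pseg[[ch]] <- Ps_list
      A[, ch] <- as.vector(M %*% cond[, ch])
    } else {
      v <- cond[, ch]
      for (s in rev(seq_len(nrow(segs))))
        v <- as.vector(props[[segs$slice[s]]](segs$old[s] - segs$young[s]) %*% v)
      A[, ch] <- v
    }
  }
  if (!impossible) cond[, prep$root] <- node_cond(prep$root)
  if (impossible)
    return(list(lnL = -Inf, impossible = TRUE))
  rootv <- cond[, prep$root]
  lik <- sum(rootv[space$nonempty]) / length(space$nonempty)
  lnL <- log(lik) + logscale
  out <- list(lnL = lnL, impossible = !is.finite(lnL))
  if (store) {
    out$A <- A; out$cond <- cond; out$Pbranch <- Pbranch; out$Pseg <- Pseg
    out$Qs <- Qs; out$props <- props; out$d <- d; out$e <- e
  }
  out
}

#' Log-likelihood of tip ranges under a range-evolution model
#'
#' Felsenstein pruning over the range state space: tip conditionals are
#' indicators of the observed ranges, internal nodes combine their daughters
#' through the cladogenetic event distribution, branches are propagated
#' segment-by-segment with the slice-specific transition matrices, and the
#' root likelihood averages the root conditionals under a flat prior over
#' non-empty ranges.
#'
#' @param phy ultrametric `phylo` chronogram.
#' @param geog a [geography_table()] covering all tips.
#' @param d,e dispersal and extirpation rates (per lineage-Myr).
#' @param family `"DEC"`, `"DIVALIKE"` or `"BAYAREALIKE"`.
#' @param epoch an [epoch_model()] or `NULL` for the unconstrained model.
#' @param max_range_size cap on range size; default all areas.
#' @return the log-likelihood (scalar; `-Inf` when the data are impossible,
#'   e.g. several distinct single-area tips under `d = e = 0`).
#' @examples
#' tr <- ape::read.tree(text = "(t1:1,t2:1);")
#' g <- geography_table(matrix(c(1, 1, 0, 0), 2, 2,
#'        dimnames = list(c("t1", "t2"), c("A", "B"))))
#' exp(tree_log_likelihood(tr, g, d = 0, e = 0))  # 1/3
#' @export
tree_log_likelihood <- function(phy, geog, d, e, family = "DEC", epoch = NULL,
                                max_range_size = NULL) {
  n_areas <- length(geog$areas)
  if (is.null(max_range_size)) max_range_size <- n_areas
  space <- build_state_space(n_areas, max_range_size, areas = geog$areas)
  prep <- prep_model(phy, geog, family, epoch, space)
  lik_engine(prep, d, e)$lnL
}
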