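#' Marginal ancestral range probabilities
#'
#' Computes, for every node of the fitted tree, the marginal posterior
#' probability of each non-empty range immediately before cladogenesis at
#' that node, by the standard two-pass (up-down) algorithm: downpass
#' conditionals from the pruning recursion are combined with rootward
#' contributions passed through the cladogenetic event distribution and the
#' branch transition matrices. Tip rows equal the observed indicator.
#'
#' Two "single most probable area" summaries are reported: the MAP range
#' (the highest-probability range state, ties broken by the deterministic
#' state order) and the MAP area (the area maximizing the summed probability
#' of all ranges containing it).
#'
#' @param fit a [fit_range_model()] object.
#' @param d,e optionally override the fitted rates.
#' @return an object of class `"ancestral_ranges"`: list with `probs`
#'   (nodes x non-empty states matrix, rows summing to 1), `map_range`,
#'   `map_area`, `age`, `is_tip`, and the state `space`.
#' @export
ancestral_ranges <- function(fit, d = fit$d, e = fit$e) {
  prep <- fit$prep
  eng <- lik_engine(prep, d, e, store = TRUE)
  if (eng$impossible) stop("data impossible under the supplied rates")
  space <- prep$space
  K <- space$n_states
  nn <- prep$ntip + prep$nnode
  tab <- prep$tab
  nE <- length(tab$anc)
  Lmat <- Matrix::sparseMatrix(i = tab$left, j = seq_len(nE), x = tab$w,
                               dims = c(K, nE))
  Rmat <- Matrix::sparseMatrix(i = tab$right, j = seq_len(nE), x = tab$w,
                               dims = c(K, nE))
  up <- matrix(0, K, nn)
  prior <- numeric(K); prior[space$nonempty] <- 1 / length(space$nonempty)
  up[, prep$root] <- prior
  marg <- matrix(0, K, nn)
  normalize <- function(v) {
    s <- sum(v)
    if (s <= 0) stop("all-zero marginal: propagated impossibility at a node")
    v / s
  }
  marg[, prep$root] <- normalize(up[, prep$root] * eng$cond[, prep$root])
  # preorder = reverse postorder over edges
  for (k in rev(seq_len(nrow(prep$edges)))) {
    v <- prep$edges[k, 1]; ch <- prep$edges[k, 2]
    sib <- if (prep$kids[v, 1L] == ch) prep$kids[v, 2L] else prep$kids[v, 1L]
    up_anc <- up[tab$anc, v]
    if (prep$kids[v, 1L] == ch) {
      u_top <- as.vector(Lmat %*% (up_anc * eng$A[tab$right, sib]))
    } else {
      u_top <- as.vector(Rmat %*% (up_anc * eng$A[tab$left, sib]))
    }
    u_ch <- as.vector(Matrix::crossprod(eng$Pbranch[[ch]], u_top))
    if (sum(u_ch) > 0) u_ch <- u_ch / sum(u_ch)  # rescale against underflow
    up[, ch] <- u_ch
    marg[, ch] <- normalize(up[, ch] * eng$cond[, ch])
  }
  probs <- t(marg[space$nonempty, , drop = FALSE])
  colnames(probs) <- space$labels[space$nonempty]
  map_idx <- apply(probs, 1, which.max)
  memb <- vapply(seq_len(space$n_areas), function(a)
    as.numeric(bitwAnd(space$masks[space$nonempty], bitwShiftL(1L, a - 1L)) != 0L),
    numeric(length(space$nonempty)))
  area_mass <- probs %*% memb
  colnames(area_mass) <- space$areas
  structure(list(
    probs = probs,
    map_range = colnames(probs)[map_idx],
    map_area = space$areas[apply(area_mass, 1, which.max)],
    area_mass = area_mass,
    age = prep$age, is_tip = seq_len(nn) <= prep$ntip,
    space = space, phy = prep$phy
  ), class = "ancestral_ranges")
}

#' @export
print.ancestral_ranges <- function(x, n = 10, ...) {
  int <- which(!x$is_tip)
  cat("Ancestral range estimates at", length(int), "internal nodes\n")
  top <- t(apply(x$probs[int, , drop = FALSE], 1, function(p) {
    o <- order(p, decreasing = TRUE)[1:3]
    sprintf("%s(%.2f)", colnames(x$probs)[o], p[o])
  }))
  df <- data.frame(node = int, age_Ma = round(x$age[int], 3),
                   map_range = x$map_range[int], map_area = x$map_area[int],
                   top3 = apply(top, 1, paste, collapse = " "))
  print(utils::head(df, n), row.names = FALSE)
  if (length(int) > n) cat("  ... (", length(int) - n, " more nodes)\n", sep = "")
  invisible(x)
}

#' Write per-node ancestral range estimates as TSV
#'
#' One row per node: node id, age, MAP range, MAP area, and the top three
#' range states with probabilities.
#'
#' @param x an [ancestral_ranges()] object.
#' @param path output path.
#' @export
write_ancestral <- function(x, path) {
  nn <- nrow(x$probs)
  top <- t(apply(x$probs, 1, function(p) {
    o <- order(p, decreasing = TRUE)[1:3]
    c(rbind(colnames(x$probs)[o], sprintf("%.6g", p[o])))
  }))
  df <- data.frame(node = seq_len(nn), is_tip = x$is_tip,
                   age_Ma = x$age, map_range = x$map_range,
                   map_area = x$map_area,
                   state1 = top[, 1], p1 = top[, 2], state2 = top[, 3],
                   p2 = top[, 4], state3 = top[, 5], p3 = top[, 6])
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Plot a chronogram with most-probable ancestral ranges at nodes
#'
#' @param x an [ancestral_ranges()] object.
#' @param what `"range"` (MAP range state) or `"area"` (MAP single area).
#' @param cex label size.
#' @param ... passed to [ape::plot.phylo()].
#' @export
plot.ancestral_ranges <- function(x, what = c("range", "area"), cex = 0.7, ...) {
  what <- match.arg(what)
  lab <- if (what == "range") x$map_range else x$map_area
  ape::plot.phylo(x$phy, cex = cex, ...)
  ape::nodelabels(lab[!x$is_tip], cex = cex, frame = "rect", bg = "lightyellow")
  invisible(x)
}
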