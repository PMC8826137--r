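#' Biogeographic stochastic mapping
#'
#' Samples complete biogeographic histories (anagenetic range expansions and
#' contractions along branches, plus a cladogenetic event at every node)
#' conditional on the observed tip ranges and the fitted model. The root
#' state is drawn from its joint posterior, cladogenetic events are drawn
#' conditional on the parent state and the daughters' conditional
#' likelihoods, and branch paths are drawn endpoint-conditioned by
#' uniformization (with a forward-rejection fallback on numerically
#' degenerate branches).
#'
#' @param fit a [fit_range_model()] object.
#' @param n number of histories to sample.
#' @param seed optional integer seed; the same seed reproduces the same
#'   histories exactly.
#' @param d,e optionally override the fitted rates.
#' @param max_retries retries per branch before a hard failure.
#' @return a list of class `"bio_history_set"` whose elements are
#'   `"bio_history"` objects: lists with `events` (anagenetic event table:
#'   `branch`, `age`, `type`, `area`, `from`, `to`), `clado` (cladogenetic
#'   event table: `node`, `age`, `type`, `anc`, `left`, `right`),
#'   `node_state` (pre-cladogenesis range per node), `branch_start` /
#'   `branch_end` (range at the top and bottom of the branch above each
#'   node), and the tree.
#' @export
stochastic_map <- function(fit, n = 1, seed = NULL, d = fit$d, e = fit$e,
                           max_retries = 1000) {
  if (!is.null(seed)) set.seed(seed)
  prep <- fit$prep
  eng <- lik_engine(prep, d, e, store = TRUE)
  if (eng$impossible) stop("data impossible under the supplied rates")
  unif <- lapply(eng$Qs, make_uniformizer)
  out <- replicate(n, sample_one_history(prep, eng, unif, max_retries),
                   simplify = FALSE)
  class(out) <- "bio_history_set"
  out
}

#' @export
print.bio_history_set <- function(x, ...) {
  ne <- vapply(x, function(h) nrow(h$events), 0L)
  cat("Biogeographic stochastic mapping: ", length(x), " histories, ",
      "mean ", round(mean(ne), 2), " anagenetic events per history\n", sep = "")
  invisible(x)
}

sample_one_history <- function(prep, eng, unif, max_retries) {
  space <- prep$space
  tab <- prep$tab
  nn <- prep$ntip + prep$nnode
  node_state <- integer(nn)       # pre-cladogenesis state index at nodes
  branch_start <- integer(nn)     # state at the old (parent) end of branch above node
  branch_end <- integer(nn)       # state at the young (node) end
  ev_list <- list()
  clado_rows <- list()
  # root draw from joint posterior
  prior <- numeric(space$n_states)
  prior[space$nonempty] <- 1
  node_state[prep$root] <- sample_prob(prior * eng$cond[, prep$root])
  # preorder descent
  clado_done <- logical(nn)
  for (k in rev(seq_len(nrow(prep$edges)))) {
    v <- prep$edges[k, 1]; ch <- prep$edges[k, 2]
    if (!clado_done[v]) {
      clado_done[v] <- TRUE
      # first visit to a daughter of v: draw the cladogenetic event at v now
      gi <- node_state[v]
      sel <- which(tab$anc == gi)
      L <- prep$kids[v, 1L]; R <- prep$kids[v, 2L]
      pr <- tab$w[sel] * eng$A[tab$left[sel], L] * eng$A[tab$right[sel], R]
      e_idx <- sel[sample_prob(pr)]
      branch_start[L] <- tab$left[e_idx]
      branch_start[R] <- tab$right[e_idx]
      clado_rows[[length(clado_rows) + 1L]] <- data.frame(
        node = v, age = prep$age[v],
        type = classify_clado(space$masks[gi], space$masks[tab$left[e_idx]],
                              space$masks[tab$right[e_idx]]),
        anc = space$labels[gi],
        left = space$labels[tab$left[e_idx]],
        right = space$labels[tab$right[e_idx]])
    }
    # sample the branch path from branch_start[ch] down to the node/tip
    a <- branch_start[ch]
    targ <- eng$cond[, ch]  # tip indicator or node conditionals
    b <- sample_prob(eng$Pbranch[[ch]][a, ] * targ)
    branch_end[ch] <- b
    if (ch > prep$ntip) node_state[ch] <- b
    path <- sample_branch_path(prep, eng, unif, ch, a, b, max_retries)
    if (nrow(path)) {
      path$branch <- ch
      ev_list[[length(ev_list) + 1L]] <- path
    }
  }
  # hard assertion: sampled tip states equal the observed data
  stopifnot(identical(branch_end[seq_len(prep$ntip)], prep$tipidx))
  events <- if (length(ev_list)) do.call(rbind, ev_list) else
    data.frame(age = numeric(0), type = character(0), area = character(0),
               from = character(0), to = character(0), branch = integer(0))
  events <- events[order(-events$age), c("branch", "age", "type", "area",
                                         "from", "to")]
  rownames(events) <- NULL
  clado <- do.call(rbind, clado_rows)
  structure(list(events = events, clado = clado,
                 node_state = space$labels[pmax(node_state, 1L)],
                 branch_start = space$labels[pmax(branch_start, 1L)],
                 branch_end = space$labels[pmax(branch_end, 1L)],
                 phy = prep$phy, age = prep$age, ntip = prep$ntip,
                 areas = space$areas),
            class = "bio_history")
}

#' @export
print.bio_history <- function(x, ...) {
  cat("Biogeographic history: ", nrow(x$events), " anagenetic events (",
      sum(x$events$type == "expansion"), " expansions, ",
      sum(x$events$type == "contraction"), " contractions), ",
      nrow(x$clado), " cladogenetic events\n", sep = "")
  invisible(x)
}

sample_prob <- function(w) {
  s <- sum(w)
  if (!is.finite(s) || s <= 0) stop("cannot sample from an all-zero weight vector")
  sample.int(length(w), 1L, prob = w)
}

# sample the anagenetic path along the branch above node `ch`, conditioned on
# state a at the parent end and b at the child end; returns an event table
sample_branch_path <- function(prep, eng, unif, ch, a, b, max_retries) {
  segs <- prep$seglist[[ch]]
  ns <- nrow(segs)
  Ps <- eng$Pseg[[ch]]
  # suffix products to condition the state at each segment boundary
  suffix <- vector("list", ns)  # suffix[[s]] = P_s %*% ... %*% P_ns
  suffix[[ns]] <- Ps[[ns]]
  if (ns > 1L) for (s in (ns - 1L):1L) suffix[[s]] <- Ps[[s]] %*% suffix[[s + 1L]]
  rows <- list()
  cur <- a
  for (s in seq_len(ns)) {
    endst <- if (s == ns) b else
      sample_prob(Ps[[s]][cur, ] * suffix[[s + 1L]][, b])
    seg_ev <- sample_segment_path(unif[[segs$slice[s]]], Ps[[s]], cur, endst,
                                  segs$old[s], segs$young[s], max_retries,
                                  prep$space)
    if (nrow(seg_ev)) rows[[length(rows) + 1L]] <- seg_ev
    cur <- endst
  }
  if (length(rows)) do.call(rbind, rows) else
    data.frame(age = numeric(0), type = character(0), area = character(0),
               from = character(0), to = character(0))
}

# uniformization machinery for one slice rate matrix
make_uniformizer <- function(Q) {
  mu <- max(-diag(Q))
  K <- nrow(Q)
  R <- if (mu > 0) diag(K) + Q / mu else diag(K)
  env <- new.env(parent = emptyenv())
  env$pows <- list(diag(K), R)   # pows[[n+1]] = R^n
  rpow <- function(n) {
    while (length(env$pows) < n + 1L)
      env$pows[[length(env$pows) + 1L]] <-
        env$pows[[length(env$pows)]] %*% R
    env$pows[[n + 1L]]
  }
  list(Q = Q, mu = mu, R = R, rpow = rpow)
}

sample_segment_path <- function(un, P, a, b, old, young, max_retries, space) {
  Tlen <- old - young
  empty <- data.frame(age = numeric(0), type = character(0),
                      area = character(0), from = character(0),
                      to = character(0))
  if (un$mu == 0 || Tlen <= 0) {
    if (a != b) stop("impossible segment: zero event rate but endpoints differ")
    return(empty)
  }
  pab <- P[a, b]
  if (pab <= 0) stop("impossible segment: endpoint pair has probability 0")
  # draw the number of uniformized jumps
  n <- {
    u <- stats::runif(1) * pab
    acc <- 0; nmax <- max(20L, stats::qpois(1 - 1e-12, un$mu * Tlen) + 10L)
    n_drawn <- NA_integer_
    for (m in 0:nmax) {
      acc <- acc + stats::dpois(m, un$mu * Tlen) * un$rpow(m)[a, b]
      if (acc >= u) { n_drawn <- m; break }
    }
    if (is.na(n_drawn)) nmax else n_drawn
  }
  if (n == 0L) return(empty)
  # jump states given endpoints
  states <- integer(n + 1L); states[1L] <- a; states[n + 1L] <- b
  if (n > 1L) for (i in 2:n) {
    w <- un$R[states[i - 1L], ] * un$rpow(n + 1L - i)[, b]
    states[i] <- sample_prob(w)
  }
  # check feasibility of the final step (guaranteed up to numerics)
  if (n >= 1L && un$R[states[n], b] <= 0)
    return(reject_segment_path(un, a, b, old, young, max_retries, space))
  ages <- old - sort(stats::runif(n)) * Tlen
  real <- which(states[-1L] != states[-(n + 1L)])
  if (!length(real)) return(empty)
  from_m <- space$masks[states[real]]
  to_m <- space$masks[states[real + 1L]]
  describe_transitions(space, from_m, to_m, ages[real])
}

describe_transitions <- function(space, from_m, to_m, ages) {
  gained <- bitwAnd(to_m, bitwNot(from_m))
  lost <- bitwAnd(from_m, bitwNot(to_m))
  type <- ifelse(gained != 0L, "expansion", "contraction")
  area <- vapply(ifelse(gained != 0L, gained, lost), function(m)
    space$areas[mask_areas(m)[1]], character(1))
  data.frame(age = ages, type = type, area = area,
             from = space$labels[state_index(space, from_m)],
             to = space$labels[state_index(space, to_m)])
}

# forward-rejection fallback for numerically degenerate segments
reject_segment_path <- function(un, a, b, old, young, max_retries, space) {
  Q <- un$Q
  for (try in seq_len(max_retries)) {
    cur <- a; t <- old
    st <- integer(0); tm <- numeric(0)
    repeat {
      rate <- -Q[cur, cur]
      if (rate <= 0) break
      t <- t - stats::rexp(1, rate)
      if (t <= young) break
      nxt <- sample_prob(pmax(Q[cur, ], 0))
      st <- c(st, nxt); tm <- c(tm, t)
      cur <- nxt
    }
    if (cur == b) {
      if (!length(st)) return(data.frame(age = numeric(0), type = character(0),
                                         area = character(0), from = character(0),
                                         to = character(0)))
      from_states <- c(a, st[-length(st)])
      return(describe_transitions(space, space$masks[from_states],
                                  space$masks[st], tm))
    }
  }
  stop("could not sample a path consistent with the branch endpoints after ",
       max_retries, " retries")
}
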