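# Independent brute-force oracle for the range-evolution likelihood and
# marginals: enumerates every assignment of (pre-split state, cladogenetic
# event) over the internal nodes and sums the complete-data probabilities.
# Deliberately written from the model definition, sharing no code with the
# package's pruning recursion.

oracle_states <- function(n_areas, max_size = n_areas) {
  st <- list()
  for (k in 1:max_size)
    st <- c(st, combn(n_areas, k, simplify = FALSE))
  st
}

oracle_events <- function(g, family, states) {
  eq <- function(a, b) identical(as.integer(sort(a)), as.integer(sort(b)))
  if (length(g) == 1L || family == "BAYAREALIKE") {
    ev <- list(list(g, g))
  } else if (family == "DEC") {
    ev <- list()
    for (a in g) {
      ev <- c(ev, list(list(a, g), list(g, a)))
      rest <- setdiff(g, a)
      ev <- c(ev, list(list(a, rest), list(rest, a)))
    }
    # drop duplicate events (two-area vicariance arises twice)
    keep <- !duplicated(vapply(ev, function(e)
      paste(paste(e[[1]], collapse = ","), paste(e[[2]], collapse = ","),
            sep = "|"), ""))
    ev <- ev[keep]
  } else { # DIVALIKE
    ev <- list()
    for (k in 1:(length(g) - 1L)) for (s in combn(g, k, simplify = FALSE))
      ev <- c(ev, list(list(s, setdiff(g, s))))
  }
  # both daughters must be representable states
  in_space <- function(a) any(vapply(states, function(s) eq(s, a), TRUE))
  ev <- Filter(function(e) in_space(e[[1]]) && in_space(e[[2]]), ev)
  ev
}

oracle_Q <- function(states, d, e, mult) {
  K <- length(states)
  Q <- matrix(0, K, K)
  eq <- function(a, b) identical(as.integer(sort(a)), as.integer(sort(b)))
  for (i in 1:K) for (j in 1:K) {
    if (i == j) next
    gi <- states[[i]]; gj <- states[[j]]
    if (length(gj) == length(gi) + 1L && all(gi %in% gj)) {
      b <- setdiff(gj, gi)
      Q[i, j] <- d * sum(mult[gi, b])
    } else if (length(gj) == length(gi) - 1L && all(gj %in% gi)) {
      Q[i, j] <- e
    }
  }
  # contraction of single-area ranges leaves the non-empty space entirely;
  # account for it on the diagonal only (absorbing null state)
  extra <- vapply(states, function(g) if (length(g) == 1L) e else 0, 0)
  diag(Q) <- -(rowSums(Q) + extra)
  Q
}

oracle_P_branch <- function(states, d, e, epoch_bounds, mults, old, young) {
  # split [young, old] at epoch boundaries; multiply oldest-first
  cuts <- epoch_bounds[epoch_bounds < old & epoch_bounds > young]
  edges <- c(old, cuts, young)
  P <- diag(length(states))
  for (s in seq_len(length(edges) - 1L)) {
    mid <- (edges[s] + edges[s + 1L]) / 2
    slice <- max(1L, min(length(mults),
                         findInterval(-mid, -epoch_bounds,
                                      rightmost.closed = TRUE)))
    Q <- oracle_Q(states, d, e, mults[[slice]])
    P <- P %*% as.matrix(Matrix::expm(Q * (edges[s] - edges[s + 1L])))
  }
  P
}

# full enumeration of (state, event) assignments over internal nodes
oracle_lnL_marg <- function(phy, tipranges, d, e, family = "DEC",
                            epoch_bounds = NULL, mults = NULL,
                            max_size = NULL, n_areas = NULL) {
  if (is.null(n_areas))
    n_areas <- max(max(unlist(tipranges)),
                   if (!is.null(mults)) nrow(mults[[1]]) else 0)
  if (is.null(max_size)) max_size <- n_areas
  states <- oracle_states(n_areas, max_size)
  K <- length(states)
  ntip <- ape::Ntip(phy)
  nnode <- phy$Nnode
  dep <- ape::node.depth.edgelength(phy)
  age <- max(dep[1:ntip]) - dep
  if (is.null(epoch_bounds)) {
    epoch_bounds <- c(age[ntip + 1L] + 1, 0)
    mults <- list(matrix(1, n_areas, n_areas))
  }
  eq <- function(a, b) identical(as.integer(sort(a)), as.integer(sort(b)))
  sidx <- function(g) which(vapply(states, function(s) eq(s, g), TRUE))
  Pb <- vector("list", ntip + nnode)
  for (k in seq_len(nrow(phy$edge))) {
    ch <- phy$edge[k, 2]
    Pb[[ch]] <- oracle_P_branch(states, d, e, epoch_bounds, mults,
                                age[phy$edge[k, 1]], age[ch])
  }
  intn <- (ntip + 1L):(ntip + nnode)
  choices <- lapply(intn, function(v) {
    out <- list()
    for (i in 1:K) {
      for (ev in oracle_events(states[[i]], family, states))
        out <- c(out, list(list(state = i, left = sidx(ev[[1]]),
                                right = sidx(ev[[2]]),
                                w = 1 / length(oracle_events(states[[i]],
                                                             family, states)))))
    }
    out
  })
  kids <- lapply(seq_len(ntip + nnode), function(v)
    phy$edge[phy$edge[, 1] == v, 2])
  tipstate <- vapply(seq_len(ntip), function(i)
    sidx(tipranges[[phy$tip.label[i]]]), 0L)
  total <- 0
  marg <- matrix(0, ntip + nnode, K)
  nint <- length(intn)
  idx <- rep(1L, nint)
  lens <- vapply(choices, length, 0L)
  repeat {
    pick <- lapply(seq_len(nint), function(q) choices[[q]][[idx[q]]])
    names(pick) <- as.character(intn)
    pr <- 1 / K   # flat root prior over the non-empty states
    for (q in seq_len(nint)) {
      v <- intn[q]; pc <- pick[[q]]
      pr <- pr * pc$w
      dts <- kids[[v]]
      starts <- c(pc$left, pc$right)
      for (j in 1:2) {
        ch <- dts[j]
        endst <- if (ch <= ntip) tipstate[ch] else
          pick[[as.character(ch)]]$state
        pr <- pr * Pb[[ch]][starts[j], endst]
        if (pr == 0) break
      }
      if (pr == 0) break
    }
    if (pr > 0) {
      total <- total + pr
      for (q in seq_len(nint)) marg[intn[q], pick[[q]]$state] <-
          marg[intn[q], pick[[q]]$state] + pr
    }
    # advance the odometer
    q <- 1L
    while (q <= nint) {
      idx[q] <- idx[q] + 1L
      if (idx[q] <= lens[q]) break
      idx[q] <- 1L; q <- q + 1L
    }
    if (q > nint) break
  }
  marg[intn, ] <- marg[intn, , drop = FALSE] / total
  for (i in seq_len(ntip)) marg[i, tipstate[i]] <- 1
  list(lnL = log(total), marg = marg,
       labels = vapply(states, function(s) paste(LETTERS[s], collapse = ""), ""))
}
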