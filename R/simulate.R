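#' Simulation configuration for synthetic range-evolution data
#'
#' Bundles all parameters of the forward simulator: a birth-death
#' chronogram conditioned on a tip count and rescaled to a crown age, and a
#' range-evolution process (anagenetic CTMC along branches, cladogenetic
#' draws at nodes) run forward from a fixed root range.
#'
#' @param n_tips number of extant tips.
#' @param birth,death birth-death rates per lineage-Myr used for the tree
#'   shape (the tree is rescaled to `crown_age`, so only their ratio shapes
#'   node depths).
#' @param crown_age target root age in Ma.
#' @param n_areas number of areas.
#' @param d,e dispersal and extirpation rates.
#' @param epoch an [epoch_model()] or `NULL` for unit multipliers.
#' @param family cladogenetic model family.
#' @param root_range root range label, e.g. `"B"`.
#' @param max_range_size range-size cap.
#' @param seed integer seed.
#' @return a list of class `"sim_config"`.
#' @export
sim_config <- function(n_tips = 134, birth = 0.55, death = 0.06,
                       crown_age = 8.6, n_areas = 6, d = 0.16, e = 0.01,
                       epoch = NULL, family = "DEC", root_range = "B",
                       max_range_size = n_areas, seed = 1) {
  stopifnot(n_tips >= 2, birth > 0, death >= 0, crown_age > 0,
            d >= 0, e >= 0, nchar(root_range) >= 1)
  structure(list(n_tips = n_tips, birth = birth, death = death,
                 crown_age = crown_age, n_areas = n_areas, d = d, e = e,
                 epoch = epoch, family = family, root_range = root_range,
                 max_range_size = max_range_size, seed = seed),
            class = "sim_config")
}

#' Default Neotropical-style simulation scenario
#'
#' The package's reference scenario for end-to-end runs: 134 tips, six
#' areas (A North America, B Caribbean-Mesoamerica, C Amazonia, D Dry
#' diagonal, E Andes, F Atlantic Forest), crown age 8.6 Ma, a
#' Caribbean-Mesoamerican root range, and the packaged two-slice (11-7 and
#' 7-0 Ma) dispersal multiplier matrix encoding area adjacency, water
#' barriers, and the pre-Andean corridor between the Mesoamerican lowlands
#' and the young northern Andes.
#'
#' @param seed integer seed.
#' @param ... overrides passed to [sim_config()].
#' @export
neotropical_preset <- function(seed = 1, ...) {
  em <- read_multipliers(system.file("extdata", "dispersal_multipliers.txt",
                                     package = "decrates", mustWork = TRUE))
  args <- list(n_tips = 134, crown_age = 8.6, n_areas = 6, d = 0.16,
               e = 0.01, epoch = em, family = "DEC", root_range = "B",
               seed = seed)
  over <- list(...)
  args[names(over)] <- over
  do.call(sim_config, args)
}

#' Simulate a chronogram conditioned on tip count and crown age
#'
#' Constant-rate birth-death tree conditioned on the number of extant tips
#' (via [ape::rphylo()]), rescaled so the crown age matches the target.
#'
#' @param config a [sim_config()].
#' @return an ultrametric `phylo` tree with `config$n_tips` tips and root
#'   age `config$crown_age`.
#' @export
simulate_chronogram <- function(config) {
  set.seed(config$seed)
  for (try in 1:50) {
    phy <- tryCatch(ape::rphylo(config$n_tips, config$birth, config$death),
                    error = function(e) NULL)
    if (!is.null(phy)) break
  }
  if (is.null(phy)) stop("birth-death simulation failed repeatedly")
  phy$edge.length <- phy$edge.length * (config$crown_age / crown_age(phy))
  phy$tip.label <- sprintf("t%03d", seq_len(config$n_tips))
  validate_chronogram(phy)
}

#' Forward-simulate range evolution on a chronogram
#'
#' Runs the range-evolution process forward in time from the configured
#' root range: a cladogenetic event is drawn at every node (equal weights
#' over the family's allowed events) and the anagenetic CTMC with the
#' slice-specific rate matrix runs along every branch.
#'
#' Observable data cannot contain empty ranges, so the null range needs a
#' policy. The default, `null_range = "forbid"`, removes last-area loss
#' from the generator (a single-area lineage cannot contract), the usual
#' survivorship conditioning when simulating datasets that look like
#' observed ones. `"resimulate"` runs the unrestricted process and redraws
#' the whole realization whenever any lineage hits the null range — at
#' realistic extirpation rates on large trees this conditions on a rare
#' event and can fail. `"keep"` retains such realizations, recording the
#' affected tips as extinct in place, for stress testing.
#'
#' @param phy chronogram to simulate on.
#' @param config a [sim_config()].
#' @param null_range `"forbid"` (default), `"resimulate"` or `"keep"`.
#' @param keep_null deprecated shorthand for `null_range = "keep"`.
#' @param max_retries redraws allowed under `"resimulate"`.
#' @return list with `geography` (a [geography_table()]), `history` (the
#'   truth log, a `"bio_history"` in the same schema as stochastic-mapping
#'   output), `null_hit` (whether any lineage hit the null range) and
#'   `extinct_tips`.
#' @export
simulate_ranges <- function(phy, config,
                            null_range = c("forbid", "resimulate", "keep"),
                            keep_null = FALSE, max_retries = 100) {
  null_range <- if (keep_null) "keep" else match.arg(null_range)
  set.seed(config$seed + 1L)
  space <- build_state_space(config$n_areas, config$max_range_size)
  epoch <- config$epoch
  if (is.null(epoch)) epoch <- uniform_epoch_model(config$n_areas,
                                                   top_age = crown_age(phy) + 1)
  tab <- clado_table(space, config$family)
  Qs <- lapply(seq_len(epoch$n_slices), function(s)
    build_rate_matrix(space, config$d, config$e, epoch, s))
  if (null_range == "forbid") {
    Qs <- lapply(Qs, function(Q) {
      Q[, 1] <- 0
      diag(Q) <- 0
      diag(Q) <- -rowSums(Q)
      Q
    })
  }
  root_idx <- state_index(space, label_mask(space, config$root_range))
  if (is.na(root_idx)) stop("root range not in the state space")
  for (try in seq_len(max_retries)) {
    out <- forward_once(phy, space, epoch, tab, Qs, root_idx)
    if (!out$null_hit || null_range == "keep") {
      pres <- t(vapply(out$tip_mask, function(m) {
        v <- integer(space$n_areas)
        v[mask_areas(m)] <- 1L
        v
      }, integer(space$n_areas)))
      rownames(pres) <- phy$tip.label
      colnames(pres) <- space$areas
      # extinct-in-place tips (null range) are flagged and dropped from the
      # observable geography; the truth log retains them
      keep <- rowSums(pres) > 0L
      return(list(geography = geography_table(pres[keep, , drop = FALSE]),
                  history = out$history, null_hit = out$null_hit,
                  extinct_tips = phy$tip.label[!keep]))
    }
  }
  stop("a lineage hit the null range in every of ", max_retries,
       " forward simulations; increase d or decrease e")
}

forward_once <- function(phy, space, epoch, tab, Qs, root_idx) {
  ntip <- ape::Ntip(phy)
  nn <- ntip + phy$Nnode
  age <- node_ages(phy)
  root <- ntip + 1L
  node_state <- integer(nn); node_state[root] <- root_idx
  branch_start <- integer(nn); branch_end <- integer(nn)
  ev_rows <- list(); clado_rows <- list()
  null_hit <- FALSE
  edges <- ape::reorder.phylo(phy, "postorder")$edge
  kids <- matrix(0L, nn, 2L)
  for (k in seq_len(nrow(edges))) {
    p <- edges[k, 1]
    kids[p, if (kids[p, 1] == 0L) 1L else 2L] <- edges[k, 2]
  }
  clado_done <- logical(nn)
  for (k in rev(seq_len(nrow(edges)))) {
    v <- edges[k, 1]; ch <- edges[k, 2]
    if (!clado_done[v]) {
      clado_done[v] <- TRUE
      gi <- node_state[v]
      if (gi == 1L) { # extinct-in-place lineage: daughters inherit null
        branch_start[kids[v, ]] <- 1L
      } else {
        sel <- which(tab$anc == gi)
        e_idx <- sel[sample.int(length(sel), 1L)]
        branch_start[kids[v, 1L]] <- tab$left[e_idx]
        branch_start[kids[v, 2L]] <- tab$right[e_idx]
        clado_rows[[length(clado_rows) + 1L]] <- data.frame(
          node = v, age = age[v],
          type = classify_clado(space$masks[gi], space$masks[tab$left[e_idx]],
                                space$masks[tab$right[e_idx]]),
          anc = space$labels[gi], left = space$labels[tab$left[e_idx]],
          right = space$labels[tab$right[e_idx]])
      }
    }
    # anagenetic walk down the branch
    cur <- branch_start[ch]
    t <- age[v]
    segs <- branch_segments(epoch, age[v], age[ch])
    for (s in seq_len(nrow(segs))) {
      Q <- Qs[[segs$slice[s]]]
      lo <- segs$young[s]
      repeat {
        rate <- -Q[cur, cur]
        if (rate <= 0) { t <- lo; break }
        t2 <- t - stats::rexp(1, rate)
        if (t2 <= lo) { t <- lo; break }
        t <- t2
        nxt <- sample_prob(pmax(Q[cur, ], 0))
        ev_rows[[length(ev_rows) + 1L]] <-
          cbind(describe_transitions(space, space$masks[cur],
                                     space$masks[nxt], t),
                branch = ch)
        cur <- nxt
        if (cur == 1L) { null_hit <- TRUE; break }
      }
      if (cur == 1L) break
    }
    branch_end[ch] <- cur
    if (ch > ntip) node_state[ch] <- cur
  }
  events <- if (length(ev_rows)) do.call(rbind, ev_rows) else
    data.frame(age = numeric(0), type = character(0), area = character(0),
               from = character(0), to = character(0), branch = integer(0))
  events <- events[order(-events$age), c("branch", "age", "type", "area",
                                         "from", "to")]
  rownames(events) <- NULL
  history <- structure(list(events = events,
                            clado = do.call(rbind, clado_rows),
                            node_state = space$labels[pmax(node_state, 1L)],
                            branch_start = space$labels[pmax(branch_start, 1L)],
                            branch_end = space$labels[pmax(branch_end, 1L)],
                            phy = phy, age = age, ntip = ntip,
                            areas = space$areas),
                       class = "bio_history")
  list(history = history, tip_mask = as.list(space$masks[pmax(branch_end[seq_len(ntip)], 1L)]),
       null_hit = null_hit)
}
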