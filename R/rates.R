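# reconstruct the range of every lineage alive at a given age in a history
history_states_at <- function(h, age) {
  bt <- branch_table(h$phy)
  alive <- bt$old > age & bt$young <= age
  out <- character(0)
  for (i in which(alive)) {
    ch <- bt$child[i]
    st <- h$branch_start[ch]
    ev <- h$events[h$events$branch == ch & h$events$age > age, , drop = FALSE]
    if (nrow(ev)) st <- ev$to[which.min(ev$age)]
    out <- c(out, st)
  }
  out
}

#' Lineage counts per area at a given age
#'
#' For each history, counts the branches alive at the given age whose
#' current range contains each area (multi-area lineages count once per
#' occupied area).
#'
#' @param histories a `"bio_history_set"`, list of histories, or a single
#'   `"bio_history"`.
#' @param age age in Ma.
#' @return matrix (histories x areas) of lineage counts; a single history
#'   gives a one-row matrix.
#' @export
lineages_in_area_at <- function(histories, age) {
  if (inherits(histories, "bio_history")) histories <- list(histories)
  areas <- histories[[1]]$areas
  t(vapply(histories, function(h) {
    if (age < 0 || age > max(h$age)) stop("age outside the tree span")
    st <- history_states_at(h, age)
    vapply(areas, function(a) sum(grepl(a, st, fixed = TRUE)), 0L)
  }, integer(length(areas))))
}

#' Dispersal and speciation rates through time
#'
#' Computes, for every replicate history and every time bin, the four
#' per-bin rate statistics and summarizes them across replicates by the
#' median and the 0.25/0.75 quantiles:
#'
#' * in situ speciation rate `lambda_X = s_X / L_X(t0)`, speciation events
#'   in `X` during the bin divided by the number of lineages occupying `X`
#'   at the bin's old edge;
#' * colonization rate `c_XY = d_XY / Br`, dispersals from `X` to `Y`
#'   divided by the total branch length (lineage-Myr) in the bin;
#' * emigration rate `E_X = df_X / Br`;
#' * immigration rate `I_X = dt_X / Br`.
#'
#' Rates whose denominator is zero (no lineage in the area, or a bin older
#' than the replicate's root) are missing and excluded from the quantiles.
#'
#' @param histories a `"bio_history_set"` or list of `"bio_history"`
#'   objects, each carrying its tree.
#' @param bin_width bin width in Myr.
#' @param area_restricted_br if `TRUE`, divide `E_X`, `I_X` and `c_XY` by
#'   the branch length of lineages occupying the source area instead of the
#'   whole-tree branch length.
#' @return an object of class `"rate_series"`: list with `bins`, `summary`
#'   (long data.frame: `statistic`, `area`, `dest`, `bin`, `old`, `young`,
#'   `median`, `q25`, `q75`), and the per-replicate arrays `lambda`, `E`,
#'   `I` (rep x area x bin) and `c` (rep x from x to x bin).
#' @export
rates_through_time <- function(histories, bin_width = 0.5,
                               area_restricted_br = FALSE) {
  if (inherits(histories, "bio_history")) histories <- list(histories)
  nrep <- length(histories)
  if (nrep < 2) warning("quartile bands need >= 2 replicate histories")
  areas <- histories[[1]]$areas
  na <- length(areas)
  maxroot <- max(vapply(histories, function(h) max(h$age), 0))
  breaks <- seq(0, bin_width * ceiling(maxroot / bin_width - 1e-9),
                by = bin_width)
  nb <- length(breaks) - 1L
  lam <- array(NA_real_, c(nrep, na, nb))
  Em <- array(NA_real_, c(nrep, na, nb))
  Im <- array(NA_real_, c(nrep, na, nb))
  cxy <- array(NA_real_, c(nrep, na, na, nb))
  for (r in seq_len(nrep)) {
    h <- histories[[r]]
    ec <- count_events(h, breaks = breaks)
    for (b in seq_len(nb)) {
      old <- breaks[b + 1L]; young <- breaks[b]
      if (young >= max(h$age)) next
      Br <- branch_length_in_bin(h$phy, old, young)
      L0age <- min(old, max(h$age))
      L0 <- lineages_in_area_at(h, L0age)[1, ]
      if (area_restricted_br) {
        stf <- history_states_at(h, (old + young) / 2)
        Brx <- vapply(areas, function(a)
          sum(grepl(a, stf, fixed = TRUE)) * (old - young), 0)
      }
      for (x in seq_len(na)) {
        if (L0[x] > 0) lam[r, x, b] <- ec$s[x, b] / L0[x]
        den <- if (area_restricted_br) Brx[x] else Br
        if (den > 0) {
          Em[r, x, b] <- ec$df[x, b] / den
          cxy[r, x, , b] <- ec$disp[x, , b] / den
        }
        if (Br > 0) Im[r, x, b] <- ec$dt[x, b] / Br
      }
    }
  }
  qs <- function(v) {
    v <- v[!is.na(v)]
    if (!length(v)) return(c(NA_real_, NA_real_, NA_real_))
    stats::quantile(v, c(0.5, 0.25, 0.75), names = FALSE)
  }
  rows <- list()
  add_stat <- function(name, arr3) {
    for (x in seq_len(na)) for (b in seq_len(nb)) {
      q <- qs(arr3[, x, b])
      rows[[length(rows) + 1L]] <<- data.frame(
        statistic = name, area = areas[x], dest = NA_character_, bin = b,
        old = breaks[b + 1L], young = breaks[b],
        median = q[1], q25 = q[2], q75 = q[3])
    }
  }
  add_stat("lambda", lam)
  add_stat("emigration", Em)
  add_stat("immigration", Im)
  for (x in seq_len(na)) for (y in seq_len(na)) {
    if (x == y) next
    for (b in seq_len(nb)) {
      q <- qs(cxy[, x, y, b])
      rows[[length(rows) + 1L]] <- data.frame(
        statistic = "colonization", area = areas[x], dest = areas[y], bin = b,
        old = breaks[b + 1L], young = breaks[b],
        median = q[1], q25 = q[2], q75 = q[3])
    }
  }
  structure(list(bins = data.frame(bin = seq_len(nb), old = breaks[-1L],
                                   young = breaks[-length(breaks)]),
                 summary = do.call(rbind, rows),
                 lambda = lam, E = Em, I = Im, c = cxy,
                 areas = areas, bin_width = bin_width, n_rep = nrep),
            class = "rate_series")
}

#' @export
print.rate_series <- function(x, ...) {
  cat("Rates through time: ", x$n_rep, " replicates, ", nrow(x$bins),
      " bins of ", x$bin_width, " Myr, areas ",
      paste(x$areas, collapse = ""), "\n", sep = "")
  invisible(x)
}

#' Write a rate series as long-format TSV
#' @param x a [rates_through_time()] object.
#' @param path output path.
#' @export
write_rates <- function(x, path) {
  utils::write.table(x$summary, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Plot median rates through time with quartile ribbons
#'
#' One panel per statistic, time running from the root towards the present;
#' one line per area with its interquartile ribbon.
#'
#' @param x a [rates_through_time()] object.
#' @param statistics which statistics to draw.
#' @param ... ignored.
#' @export
plot.rate_series <- function(x, statistics = c("lambda", "emigration",
                                               "immigration"), ...) {
  op <- graphics::par(mfrow = c(length(statistics), 1), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  mid <- (x$bins$old + x$bins$young) / 2
  cols <- grDevices::hcl.colors(length(x$areas), "Dark 3")
  for (st in statistics) {
    d <- x$summary[x$summary$statistic == st & is.na(x$summary$dest), ]
    ylim <- range(c(0, d$q75), na.rm = TRUE)
    graphics::plot(NA, xlim = rev(range(c(x$bins$old, 0))), ylim = ylim,
                   xlab = "age (Ma)", ylab = st, main = st)
    for (i in seq_along(x$areas)) {
      di <- d[d$area == x$areas[i], ]
      ok <- !is.na(di$median)
      if (!any(ok)) next
      graphics::polygon(c(mid[ok], rev(mid[ok])),
                        c(di$q25[ok], rev(di$q75[ok])),
                        col = grDevices::adjustcolor(cols[i], 0.2), border = NA)
      graphics::lines(mid[ok], di$median[ok], col = cols[i], lwd = 2)
    }
    graphics::legend("topleft", legend = x$areas, col = cols, lwd = 2,
                     bty = "n", cex = 0.8)
  }
  invisible(x)
}

#' Relay summary: which area leads each rate through time
#'
#' For every time bin, finds the area with the maximal median in situ
#' speciation, emigration and immigration rate, and reports the contiguous
#' time intervals over which each area holds each maximum — the "relay"
#' phases and their changeover ages. Ties are reported explicitly.
#'
#' @param series a [rates_through_time()] object.
#' @return an object of class `"relay_summary"`: list with `by_bin`
#'   (data.frame: `statistic`, `bin`, `old`, `young`, `leader`, `tie`) and
#'   `phases` (contiguous runs: `statistic`, `leader`, `from_age`,
#'   `to_age`, `n_bins`).
#' @export
relay_summary <- function(series) {
  sm <- series$summary[is.na(series$summary$dest), ]
  out <- list(); phases <- list()
  for (st in unique(sm$statistic)) {
    d <- sm[sm$statistic == st, ]
    for (b in sort(unique(d$bin))) {
      db <- d[d$bin == b, ]
      if (all(is.na(db$median))) {
        leader <- NA_character_; tie <- FALSE
      } else {
        mx <- max(db$median, na.rm = TRUE)
        lead <- db$area[!is.na(db$median) & db$median == mx]
        leader <- lead[1]; tie <- length(lead) > 1
      }
      out[[length(out) + 1L]] <- data.frame(
        statistic = st, bin = b, old = db$old[1], young = db$young[1],
        leader = leader, tie = tie)
    }
  }
  by_bin <- do.call(rbind, out)
  for (st in unique(by_bin$statistic)) {
    d <- by_bin[by_bin$statistic == st, ]
    d <- d[order(-d$old), ]  # oldest bin first
    keep <- !is.na(d$leader)
    d <- d[keep, , drop = FALSE]
    if (!nrow(d)) next
    run_id <- cumsum(c(1L, as.integer(d$leader[-1] != d$leader[-nrow(d)])))
    for (g in split(d, run_id)) {
      phases[[length(phases) + 1L]] <- data.frame(
        statistic = st, leader = g$leader[1],
        from_age = max(g$old), to_age = min(g$young), n_bins = nrow(g))
    }
  }
  structure(list(by_bin = by_bin, phases = do.call(rbind, phases)),
            class = "relay_summary")
}

#' @export
print.relay_summary <- function(x, ...) {
  cat("Relay phases (contiguous intervals where one area leads a rate):\n")
  print(x$phases, row.names = FALSE)
  if (any(x$by_bin$tie, na.rm = TRUE))
    cat("note: ties occurred in ", sum(x$by_bin$tie), " bin(s)\n", sep = "")
  invisible(x)
}
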