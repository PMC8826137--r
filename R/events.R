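#' Classify and count biogeographic events per time bin
#'
#' Tallies a sampled (or simulated) history into per-time-bin counts:
#'
#' * `disp[X, Y, bin]` — dispersal events with source `X` and destination
#'   `Y`. A range expansion gaining area `b` from prior range `G` counts one
#'   dispersal into `b`, with source mass `1/|G|` attributed to each
#'   occupied area of `G`, so totals are conserved.
#' * `df[X, bin]` — total dispersal out of `X` (`sum_Y disp[X, Y, bin]`).
#' * `dt[Y, bin]` — total dispersal into `Y` (integer: one per expansion).
#' * `s[X, bin]` — in situ speciation: a cladogenetic event counts in `X`
#'   when the ancestor range contains `X` and at least one daughter range
#'   retains `X`.
#' * `extirpation[X, bin]` — range contractions losing area `X`.
#'
#' @param history a `"bio_history"` (from [stochastic_map()] or
#'   [simulate_ranges()]).
#' @param bin_width bin width in Myr (bins run from the present backwards).
#' @param breaks optional explicit bin edges in Ma (ascending, starting
#'   at 0); overrides `bin_width`.
#' @return an object of class `"event_counts"`: list with `bins`
#'   (data.frame `old`, `young`), `disp` (areas x areas x bins), `s`, `df`,
#'   `dt`, `extirpation` (areas x bins), and `areas`.
#' @export
count_events <- function(history, bin_width = 0.5, breaks = NULL) {
  areas <- history$areas
  na <- length(areas)
  root_age <- max(history$age)
  if (is.null(breaks))
    breaks <- seq(0, bin_width * ceiling(root_age / bin_width - 1e-9),
                  by = bin_width)
  if (breaks[1] != 0) stop("breaks must start at 0 (the present)")
  nb <- length(breaks) - 1L
  bin_of <- function(age) pmin(pmax(findInterval(age, breaks,
                                                 left.open = TRUE,
                                                 rightmost.closed = FALSE),
                                    1L), nb)
  disp <- array(0, c(na, na, nb), dimnames = list(areas, areas, NULL))
  s <- matrix(0, na, nb, dimnames = list(areas, NULL))
  ext <- matrix(0, na, nb, dimnames = list(areas, NULL))
  ev <- history$events
  for (i in seq_len(nrow(ev))) {
    b <- bin_of(ev$age[i])
    if (ev$type[i] == "expansion") {
      src <- strsplit(ev$from[i], "")[[1]]
      gained <- ev$area[i]
      disp[src, gained, b] <- disp[src, gained, b] + 1 / length(src)
    } else {
      ext[ev$area[i], b] <- ext[ev$area[i], b] + 1
    }
  }
  cl <- history$clado
  for (i in seq_len(nrow(cl))) {
    b <- bin_of(cl$age[i])
    anc <- strsplit(cl$anc[i], "")[[1]]
    kept <- unique(c(strsplit(cl$left[i], "")[[1]], strsplit(cl$right[i], "")[[1]]))
    hit <- intersect(anc, kept)
    s[hit, b] <- s[hit, b] + 1
  }
  structure(list(bins = data.frame(old = breaks[-1L], young = breaks[-length(breaks)]),
                 disp = disp, s = s,
                 df = apply(disp, c(1, 3), sum),
                 dt = apply(disp, c(2, 3), sum),
                 extirpation = ext, areas = areas),
            class = "event_counts")
}

#' @export
print.event_counts <- function(x, ...) {
  cat("Event counts over ", nrow(x$bins), " bins: ",
      round(sum(x$disp), 2), " dispersals, ", sum(x$s), " in situ speciations, ",
      sum(x$extirpation), " extirpations\n", sep = "")
  invisible(x)
}

#' Average dispersal flows across stochastic-mapping replicates
#'
#' Means and quartiles, across histories, of the total number of dispersal
#' events for each ordered area pair, and of the per-area totals out of
#' (emigration) and into (immigration) each area; identifies each area's
#' largest source and the overall source/sink ranking.
#'
#' @param histories a `"bio_history_set"` (or list of `"bio_history"`).
#' @param bin_width passed to [count_events()] (flows are summed over bins).
#' @return an object of class `"flow_summary"`: list with `pair_mean`
#'   (areas x areas matrix of mean flows), `pair_q25`/`pair_q75`, `out_mean`,
#'   `in_mean`, `largest_source_of` (for each destination, the area sending
#'   most migrants), and `areas`.
#' @export
summarize_flows <- function(histories, bin_width = 0.5) {
  stopifnot(length(histories) >= 1)
  counts <- lapply(histories, function(h) {
    ec <- count_events(h, bin_width = bin_width)
    apply(ec$disp, c(1, 2), sum)
  })
  arr <- simplify2array(counts)  # areas x areas x n
  areas <- rownames(counts[[1]])
  pair_mean <- apply(arr, c(1, 2), mean)
  structure(list(
    pair_mean = pair_mean,
    pair_q25 = apply(arr, c(1, 2), stats::quantile, 0.25),
    pair_q75 = apply(arr, c(1, 2), stats::quantile, 0.75),
    out_mean = rowSums(pair_mean),
    in_mean = colSums(pair_mean),
    largest_source_of = apply(pair_mean, 2, function(col)
      areas[which.max(col)]),
    n = length(histories), areas = areas
  ), class = "flow_summary")
}

#' @export
print.flow_summary <- function(x, digits = 2, ...) {
  cat("Dispersal flows averaged over", x$n, "histories\n")
  cat("mean events (rows = source, cols = destination):\n")
  print(round(x$pair_mean, digits))
  cat("largest source: ", x$areas[which.max(x$out_mean)],
      "   largest sink: ", x$areas[which.max(x$in_mean)], "\n", sep = "")
  invisible(x)
}

#' Write sampled histories as a tab-separated event log
#'
#' One row per event across all replicates, anagenetic and cladogenetic,
#' with columns `replicate`, `branch_id`, `age_Ma`, `event_type`,
#' `range_before`, `range_after`.
#'
#' @param histories a `"bio_history_set"` (or list).
#' @param path output path.
#' @seealso [read_event_log()]
#' @export
write_event_log <- function(histories, path) {
  rows <- lapply(seq_along(histories), function(r) {
    h <- histories[[r]]
    ana <- h$events
    cl <- h$clado
    rbind(
      if (nrow(ana)) data.frame(replicate = r, branch_id = ana$branch,
                                age_Ma = ana$age, event_type = ana$type,
                                range_before = ana$from, range_after = ana$to),
      if (!is.null(cl) && nrow(cl)) data.frame(replicate = r, branch_id = cl$node,
                                               age_Ma = cl$age, event_type = cl$type,
                                               range_before = cl$anc,
                                               range_after = paste(cl$left, cl$right,
                                                                   sep = "|"))
    )
  })
  df <- do.call(rbind, rows)
  df <- df[order(df$replicate, -df$age_Ma), ]
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a tab-separated event log written by [write_event_log()]
#' @param path path to the TSV.
#' @return data.frame with the log's columns.
#' @export
read_event_log <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
}
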