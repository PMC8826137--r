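#' Time-stratified dispersal multiplier model
#'
#' An epoch model partitions the time axis (ages in Ma before present) into
#' slices, each with its own area-by-area dispersal multiplier matrix. The
#' anagenetic dispersal rate from area `a` to area `b` within a slice is the
#' base rate `d` scaled by the slice's multiplier `m[a, b]`.
#'
#' @param boundaries numeric vector of slice boundaries in Ma, strictly
#'   descending and ending at 0, e.g. `c(11, 7, 0)` for slices 11-7 Ma and
#'   7-0 Ma (oldest slice first). Ages older than the first boundary fall in
#'   the oldest slice.
#' @param multipliers a single matrix (recycled across slices) or a list of
#'   square non-negative matrices, oldest slice first; diagonals are forced
#'   to 1.
#' @param areas optional area codes; taken from matrix dimnames otherwise.
#' @return an object of class `"epoch_model"` with elements `boundaries`,
#'   `multipliers` (list, oldest first), `n_slices`, `areas`.
#' @examples
#' em <- uniform_epoch_model(3)
#' em2 <- epoch_model(c(11, 7, 0), list(matrix(1, 3, 3), matrix(1, 3, 3)))
#' @export
epoch_model <- function(boundaries, multipliers, areas = NULL) {
  boundaries <- as.numeric(boundaries)
  if (length(boundaries) < 2L) stop("need at least two boundaries")
  if (any(diff(boundaries) >= 0)) stop("boundaries must be strictly descending")
  if (boundaries[length(boundaries)] != 0)
    stop("the youngest boundary must be 0 (the present)")
  n_slices <- length(boundaries) - 1L
  if (is.matrix(multipliers)) multipliers <- rep(list(multipliers), n_slices)
  if (length(multipliers) != n_slices)
    stop("need one multiplier matrix per slice (", n_slices, ")")
  multipliers <- lapply(multipliers, function(m) {
    m <- as.matrix(m)
    if (nrow(m) != ncol(m)) stop("multiplier matrix must be square")
    if (any(m < 0)) stop("multiplier entries must be >= 0")
    diag(m) <- 1
    m
  })
  na <- nrow(multipliers[[1]])
  if (any(vapply(multipliers, nrow, 0L) != na))
    stop("all multiplier matrices must have the same dimension")
  if (is.null(areas)) areas <- rownames(multipliers[[1]])
  if (is.null(areas)) areas <- LETTERS[seq_len(na)]
  multipliers <- lapply(multipliers, function(m) {
    dimnames(m) <- list(areas, areas); m
  })
  structure(list(boundaries = boundaries, multipliers = multipliers,
                 n_slices = n_slices, areas = areas),
            class = "epoch_model")
}

#' Single-slice epoch model with all multipliers equal to one
#'
#' The neutral (unconstrained) model: one slice spanning all of time with a
#' unit multiplier matrix, so dispersal is homogeneous in time and symmetric
#' across area pairs.
#'
#' @param n_areas number of areas.
#' @param top_age age of the older slice edge in Ma (any age at or above the
#'   root works; ages above it are treated as belonging to the oldest slice).
#' @param areas optional area codes.
#' @export
uniform_epoch_model <- function(n_areas, top_age = 1e6, areas = NULL) {
  epoch_model(c(top_age, 0), matrix(1, n_areas, n_areas), areas = areas)
}

#' @export
print.epoch_model <- function(x, ...) {
  cat("Epoch model: ", x$n_slices, " slice(s) over ",
      paste(x$boundaries, collapse = "-"), " Ma, ",
      length(x$areas), " areas\n", sep = "")
  invisible(x)
}

# slice index for an age (1 = oldest); ages >= boundaries[1] use slice 1
slice_at_age <- function(em, age) {
  idx <- findInterval(-age, -em$boundaries, rightmost.closed = TRUE)
  pmin(pmax(idx, 1L), em$n_slices)
}

# split the branch interval [young_age, old_age] at slice boundaries;
# returns data.frame(old, young, slice) ordered oldest segment first
branch_segments <- function(em, old_age, young_age) {
  if (old_age < young_age) stop("ages out of order")
  cuts <- em$boundaries[em$boundaries < old_age & em$boundaries > young_age]
  edges <- c(old_age, cuts, young_age)
  old <- edges[-length(edges)]
  young <- edges[-1L]
  mid <- (old + young) / 2
  data.frame(old = old, young = young, slice = slice_at_age(em, mid))
}

#' Read a time-stratified dispersal multiplier file
#'
#' The file holds one block per time slice, youngest slice first (oldest
#' last). Each block is a header line `<old_age>-<young_age>`, then one row
#' of multipliers per area, then a line `END`. An optional header line of
#' area codes before the first block names the areas.
#'
#' @param path path to the multiplier file.
#' @param areas optional area codes, overriding any in the file.
#' @return an [epoch_model()].
#' @seealso [write_multipliers()]
#' @export
read_multipliers <- function(path, areas = NULL) {
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[!grepl("^#", lines)]
  lines <- lines[nzchar(lines)]
  i <- 1L
  file_areas <- NULL
  if (length(lines) && !grepl("^[0-9.]+\\s*-\\s*[0-9.]+$", lines[1L])) {
    file_areas <- strsplit(lines[1L], "\\s+")[[1]]
    i <- 2L
  }
  blocks <- list()
  spans <- list()
  while (i <= length(lines)) {
    hd <- lines[i]
    if (!grepl("^[0-9.]+\\s*-\\s*[0-9.]+$", hd))
      stop("line ", i, ": expected a slice header '<old>-<young>', got '", hd, "'")
    ages <- as.numeric(strsplit(hd, "-")[[1]])
    if (ages[1] <= ages[2]) stop("line ", i, ": slice ages must be old-young")
    i <- i + 1L
    rows <- list()
    while (i <= length(lines) && lines[i] != "END") {
      rows[[length(rows) + 1L]] <- as.numeric(strsplit(lines[i], "\\s+")[[1]])
      i <- i + 1L
    }
    if (i > length(lines)) stop("missing END for slice ", hd)
    i <- i + 1L  # consume END
    nr <- length(rows)
    if (nr == 0L || any(lengths(rows) != nr))
      stop("slice ", hd, ": multiplier block must be square")
    blocks[[length(blocks) + 1L]] <- do.call(rbind, rows)
    spans[[length(spans) + 1L]] <- ages
  }
  if (!length(blocks)) stop("no multiplier blocks found")
  # file order is youngest first; reorder oldest first and check contiguity
  ord <- order(vapply(spans, `[`, 0, 1L), decreasing = TRUE)
  spans <- spans[ord]; blocks <- blocks[ord]
  bounds <- c(vapply(spans, `[`, 0, 1L), spans[[length(spans)]][2])
  for (k in seq_along(spans)[-1L]) {
    if (spans[[k - 1L]][2] != spans[[k]][1])
      stop("slices are not contiguous: ", spans[[k - 1L]][2], " vs ",
           spans[[k]][1])
  }
  if (bounds[length(bounds)] != 0) stop("youngest slice must end at the present (0)")
  if (is.null(areas)) areas <- file_areas
  epoch_model(bounds, blocks, areas = areas)
}

#' Write a time-stratified dispersal multiplier file
#'
#' Inverse of [read_multipliers()]: blocks youngest first, each terminated by
#' `END`, preceded by a line of area codes.
#'
#' @param em an [epoch_model()].
#' @param path output path.
#' @export
write_multipliers <- function(em, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(em$areas, collapse = " "), con)
  for (k in rev(seq_len(em$n_slices))) {
    writeLines(paste0(format_age(em$boundaries[k]), "-",
                      format_age(em$boundaries[k + 1L])), con)
    m <- em$multipliers[[k]]
    for (r in seq_len(nrow(m)))
      writeLines(paste(format(m[r, ], trim = TRUE, scientific = FALSE),
                       collapse = " "), con)
    writeLines("END", con)
  }
  invisible(path)
}

format_age <- function(x) {
  format(x, trim = TRUE, scientific = FALSE, drop0trailing = TRUE)
}
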