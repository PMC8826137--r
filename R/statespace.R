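#' Enumerate the geographic range state space
#'
#' Builds the ordered set of geographic ranges (non-empty subsets of areas,
#' up to a maximum range size) used as the state space of the range-evolution
#' Markov process. The null (empty) range is carried internally as state 1 so
#' that extirpation out of a single-area range has an absorbing target; tips
#' are never observed in the null range.
#'
#' States are ordered deterministically: the null range first, then non-empty
#' ranges by increasing size and, within a size class, lexicographically by
#' area labels. All downstream indices (rate matrices, partial likelihoods,
#' cladogenesis tables) refer to this ordering.
#'
#' @param n_areas number of areas (>= 1).
#' @param max_range_size largest permitted range size; defaults to `n_areas`.
#' @param areas optional character vector of single-letter area codes; defaults
#'   to `LETTERS[1:n_areas]`.
#' @return an object of class `"range_space"`: a list with elements `n_areas`,
#'   `max_range_size`, `areas`, `masks` (integer bitmasks, `masks[1] == 0`),
#'   `labels` (e.g. `"A"`, `"BE"`), `n_states`, and `nonempty` (indices of the
#'   non-empty states).
#' @examples
#' sp <- build_state_space(3)
#' sp$labels
#' @export
build_state_space <- function(n_areas, max_range_size = n_areas, areas = NULL) {
  n_areas <- as.integer(n_areas)
  max_range_size <- as.integer(max_range_size)
  if (is.na(n_areas) || n_areas < 1) stop("n_areas must be >= 1")
  if (max_range_size < 1 || max_range_size > n_areas)
    stop("max_range_size must be in [1, n_areas]")
  if (is.null(areas)) areas <- LETTERS[seq_len(n_areas)]
  if (length(areas) != n_areas || anyDuplicated(areas))
    stop("areas must be ", n_areas, " unique codes")
  all_masks <- seq_len(2^n_areas - 1L)
  sizes <- vapply(all_masks, mask_size, integer(1))
  keep <- all_masks[sizes <= max_range_size]
  # order by size, then lexicographically by member area indices
  keys <- t(vapply(keep, function(m) {
    a <- mask_areas(m)
    c(length(a), a, rep.int(n_areas + 1L, n_areas - length(a)))
  }, integer(n_areas + 1L)))
  ord <- do.call(order, as.data.frame(keys))
  masks <- c(0L, keep[ord])
  labels <- vapply(masks, function(m) {
    if (m == 0L) "0" else paste(areas[mask_areas(m)], collapse = "")
  }, character(1))
  idx_lookup <- integer(2^n_areas)
  idx_lookup[masks + 1L] <- seq_along(masks)
  structure(list(
    n_areas = n_areas, max_range_size = max_range_size, areas = areas,
    masks = masks, labels = labels, n_states = length(masks),
    nonempty = seq_along(masks)[-1L], idx_lookup = idx_lookup
  ), class = "range_space")
}

#' @export
print.range_space <- function(x, ...) {
  cat("Range state space: ", x$n_areas, " areas (",
      paste(x$areas, collapse = ""), "), max range size ", x$max_range_size,
      ", ", x$n_states - 1L, " non-empty states\n", sep = "")
  invisible(x)
}

# -- bitmask helpers (area i <-> bit 2^(i-1)) --------------------------------

mask_size <- function(m) {
  n <- 0L
  while (m > 0L) { n <- n + (m %% 2L); m <- m %/% 2L }
  n
}

mask_areas <- function(m) {
  which(bitwAnd(m, bitwShiftL(1L, 0:30)) != 0L)
}

areas_mask <- function(idx) {
  if (length(idx) == 0L) return(0L)
  sum(bitwShiftL(1L, idx - 1L))
}

state_index <- function(space, mask) {
  i <- space$idx_lookup[mask + 1L]
  i[i == 0L] <- NA_integer_  # mask 0 maps to index 1, set in the constructor
  i
}

label_mask <- function(space, label) {
  if (label %in% c("0", "")) return(0L)
  idx <- match(strsplit(label, "")[[1]], space$areas)
  if (anyNA(idx)) stop("unknown area code in range label '", label, "'")
  areas_mask(idx)
}
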