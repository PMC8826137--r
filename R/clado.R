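#' Cladogenetic event distribution for an ancestral range
#'
#' Enumerates the daughter-range pairs allowed at a speciation event under
#' each model family, with equal weights summing to one:
#'
#' * `DEC`: a single-area ancestor is copied to both daughters. A wider
#'   ancestor `G` undergoes either subset sympatry (one daughter is a single
#'   area of `G`, the other inherits all of `G`) or strict vicariance (one
#'   daughter is a single area `a`, the other gets `G - {a}`); both
#'   left/right assignments are distinct events.
#' * `DIVALIKE`: a single-area ancestor is copied; a wider ancestor splits by
#'   vicariance into any two disjoint non-empty parts (both assignments), with
#'   no subset sympatry.
#' * `BAYAREALIKE`: the ancestor range is copied to both daughters, whatever
#'   its size (no cladogenetic range change).
#'
#' @param range_label ancestral range as an area-label string (e.g. `"AB"`)
#'   or an integer state index into `space`.
#' @param family `"DEC"`, `"DIVALIKE"` or `"BAYAREALIKE"`.
#' @param space a [build_state_space()] object.
#' @return data.frame with columns `left`, `right` (range labels) and
#'   `weight`.
#' @examples
#' sp <- build_state_space(3)
#' cladogenesis_events("AB", "DEC", sp)  # 6 events, weight 1/6 each
#' @export
cladogenesis_events <- function(range_label, family, space) {
  i <- if (is.character(range_label)) {
    state_index(space, label_mask(space, range_label))
  } else as.integer(range_label)
  if (is.na(i) || i < 1L || i > space$n_states || space$masks[i] == 0L)
    stop("ancestor range must be a non-empty state of the space")
  tab <- clado_table(space, family)
  sel <- tab$anc == i
  data.frame(left = space$labels[tab$left[sel]],
             right = space$labels[tab$right[sel]],
             weight = tab$w[sel])
}

# Full cladogenesis table over all non-empty ancestor states, as parallel
# index vectors (anc, left, right, w) for fast likelihood combination.
clado_table <- function(space, family) {
  family <- match.arg(family, c("DEC", "DIVALIKE", "BAYAREALIKE"))
  anc <- integer(0); left <- integer(0); right <- integer(0); w <- numeric(0)
  for (i in space$nonempty) {
    g <- space$masks[i]
    occ <- mask_areas(g)
    ev <- if (length(occ) == 1L || family == "BAYAREALIKE") {
      list(c(i, i))
    } else if (family == "DEC") {
      out <- list()
      for (a in occ) {
        sa <- state_index(space, bitwShiftL(1L, a - 1L))
        rest <- state_index(space, bitwAnd(g, bitwNot(bitwShiftL(1L, a - 1L))))
        # subset sympatry: {a} vs G, both assignments
        out <- c(out, list(c(sa, i), c(i, sa)))
        # strict vicariance: {a} vs G - {a}, both assignments
        out <- c(out, list(c(sa, rest), c(rest, sa)))
      }
      out
    } else { # DIVALIKE: all ordered vicariant bipartitions
      out <- list()
      sub <- bitwAnd(g, seq_len(2L^space$n_areas - 1L))
      sub <- unique(sub[sub > 0L & sub < g])
      for (s in sub) {
        comp <- bitwAnd(g, bitwNot(s))
        si <- state_index(space, s); ci <- state_index(space, comp)
        if (!is.na(si) && !is.na(ci)) out <- c(out, list(c(si, ci)))
      }
      out
    }
    m <- do.call(rbind, ev)
    keep <- !is.na(m[, 1]) & !is.na(m[, 2])
    # for two-area ranges the vicariance events generated from each area
    # coincide pairwise; collapse duplicates so each distinct event counts once
    m <- unique(m[keep, , drop = FALSE])
    if (!nrow(m)) stop("no cladogenetic event possible for state ",
                       space$labels[i], " (max_range_size too small?)")
    anc <- c(anc, rep.int(i, nrow(m)))
    left <- c(left, m[, 1]); right <- c(right, m[, 2])
    w <- c(w, rep.int(1 / nrow(m), nrow(m)))
  }
  list(anc = anc, left = left, right = right, w = w, family = family)
}

# classify a sampled event by its daughter ranges
classify_clado <- function(anc_mask, left_mask, right_mask) {
  if (left_mask == anc_mask && right_mask == anc_mask) return("sympatry-copy")
  if (bitwAnd(left_mask, right_mask) == 0L) return("vicariance")
  "subset-sympatry"
}
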