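#' Anagenetic rate matrix over range states for one time slice
#'
#' Builds the instantaneous rate matrix of the range-evolution process.
#' Range expansion `G -> G + {b}` (b not in G) proceeds at rate
#' `d * sum_{a in G} m[a, b]`, where `m` is the slice's dispersal multiplier
#' matrix; expansions that would exceed the maximum range size are forbidden.
#' Range contraction `G -> G - {a}` proceeds at rate `e` per occupied area;
#' a single-area range contracts into the absorbing null range. Rows sum to
#' zero.
#'
#' @param space a [build_state_space()] object.
#' @param d dispersal (range-expansion) rate per lineage-Myr.
#' @param e extirpation (range-contraction) rate per lineage-Myr.
#' @param epoch an [epoch_model()] (or `NULL` for unit multipliers).
#' @param slice slice index into the epoch model (1 = oldest).
#' @return dense `n_states x n_states` rate matrix, state 1 = null range.
#' @export
build_rate_matrix <- function(space, d, e, epoch = NULL, slice = 1L) {
  if (d < 0 || e < 0) stop("rates must be >= 0")
  mult <- if (is.null(epoch)) matrix(1, space$n_areas, space$n_areas)
          else epoch$multipliers[[slice]]
  if (nrow(mult) != space$n_areas)
    stop("multiplier matrix does not match the number of areas")
  K <- space$n_states
  Q <- matrix(0, K, K, dimnames = list(space$labels, space$labels))
  for (i in space$nonempty) {
    g <- space$masks[i]
    occ <- mask_areas(g)
    # expansions
    if (length(occ) < space$max_range_size) {
      for (b in setdiff(seq_len(space$n_areas), occ)) {
        j <- state_index(space, bitwOr(g, bitwShiftL(1L, b - 1L)))
        if (!is.na(j)) Q[i, j] <- Q[i, j] + d * sum(mult[occ, b])
      }
    }
    # contractions (single-area ranges fall into the null state)
    for (a in occ) {
      j <- state_index(space, bitwAnd(g, bitwNot(bitwShiftL(1L, a - 1L))))
      Q[i, j] <- Q[i, j] + e
    }
  }
  diag(Q) <- -rowSums(Q)
  Q
}

#' Transition probabilities of the range process over a time interval
#'
#' Matrix exponential `exp(Q t)` of a dense range-evolution rate matrix.
#'
#' @param Q rate matrix from [build_rate_matrix()].
#' @param t elapsed time in Myr (>= 0).
#' @return row-stochastic probability matrix.
#' @export
transition_probabilities <- function(Q, t) {
  if (t < 0) stop("t must be >= 0")
  if (t == 0) return(diag(nrow(Q)))
  P <- as.matrix(Matrix::expm(Q * t))
  dimnames(P) <- dimnames(Q)
  clamp_stochastic(P)
}

clamp_stochastic <- function(P) {
  P[P < 0] <- 0
  P / rowSums(P)
}

# Eigendecomposition-based propagator: factorizes Q once so that P(t) for
# many branch durations costs two small matrix products each. Falls back to
# scaling-and-squaring when Q is numerically defective.
make_propagator <- function(Q) {
  eg <- tryCatch(eigen(Q), error = function(e) NULL)
  ok <- FALSE
  if (!is.null(eg)) {
    Vi <- tryCatch(solve(eg$vectors), error = function(e) NULL)
    if (!is.null(Vi)) {
      err <- max(abs(Re(eg$vectors %*% (eg$values * Vi)) - Q))
      ok <- is.finite(err) && err < 1e-8 * max(1, max(abs(Q)))
    }
  }
  if (ok) {
    V <- eg$vectors; lam <- eg$values
    function(t) {
      if (t == 0) return(diag(nrow(Q)))
      P <- Re(V %*% (exp(lam * t) * Vi))
      clamp_stochastic(P)
    }
  } else {
    function(t) transition_probabilities(Q, t)
  }
}
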