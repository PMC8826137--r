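#' Fit a range-evolution model by maximum likelihood
#'
#' Estimates the dispersal rate `d` and extirpation rate `e` of a
#' dispersal-extinction-cladogenesis style model on a chronogram with
#' observed tip ranges, optionally time-stratified by an epoch model of
#' dispersal multipliers. The founder-event weight `j` is carried in the
#' interface for completeness but fixed at 0 (the supported model families
#' have no founder-event speciation); the fit therefore has two free
#' parameters.
#'
#' Optimization is deterministic: bounded L-BFGS-B on `log(d), log(e)` from a
#' fixed start (`d = e = 0.01`) with box `[1e-9, 5]` on the natural scale.
#'
#' @param phy ultrametric `phylo` chronogram (branch lengths in Myr).
#' @param geog a [geography_table()] covering all tips of `phy`.
#' @param family `"DEC"`, `"DIVALIKE"` or `"BAYAREALIKE"`.
#' @param epoch an [epoch_model()] of dispersal multipliers, or `NULL` for
#'   the unconstrained (single-slice, unit-multiplier) model.
#' @param max_range_size cap on range size; default: number of areas.
#' @param j founder-event weight; only 0 is supported.
#' @param start,lower,upper optimizer start and box on the natural scale.
#' @return an object of class `"range_fit"` with components `d`, `e`, `lnL`,
#'   `n_params`, `family`, `constrained`, `convergence`, and the inputs;
#'   methods: [print.range_fit()], [summary.range_fit()], [coef.range_fit()],
#'   [logLik.range_fit()] (so `AIC()` works), [ancestral_ranges()],
#'   [stochastic_map()].
#' @examples
#' \donttest{
#' cfg <- sim_config(n_tips = 40, n_areas = 3, d = 0.05, e = 0.02,
#'                   crown_age = 10, seed = 1)
#' tr <- simulate_chronogram(cfg)
#' sim <- simulate_ranges(tr, cfg)
#' fit <- fit_range_model(tr, sim$geography, family = "DEC")
#' fit
#' }
#' @export
fit_range_model <- function(phy, geog, family = c("DEC", "DIVALIKE", "BAYAREALIKE"),
                            epoch = NULL, max_range_size = NULL, j = 0,
                            start = c(d = 0.01, e = 0.01),
                            lower = 1e-9, upper = 5) {
  family <- match.arg(family)
  if (j != 0) stop("founder-event speciation (j > 0) is not supported; j must be 0")
  n_areas <- length(geog$areas)
  if (is.null(max_range_size)) max_range_size <- n_areas
  space <- build_state_space(n_areas, max_range_size, areas = geog$areas)
  prep <- prep_model(phy, geog, family, epoch, space)
  nll <- function(lp) {
    v <- lik_engine(prep, exp(lp[1]), exp(lp[2]))$lnL
    if (!is.finite(v)) 1e10 else -v
  }
  opt <- stats::optim(log(start), nll, method = "L-BFGS-B",
                      lower = rep(log(lower), 2), upper = rep(log(upper), 2),
                      control = list(maxit = 500))
  d_hat <- exp(opt$par[1]); e_hat <- exp(opt$par[2])
  lnL <- -opt$value
  constrained <- prep$epoch$n_slices > 1L ||
    any(vapply(prep$epoch$multipliers, function(m) any(m != 1), logical(1)))
  structure(list(
    call = match.call(), family = family, constrained = constrained,
    d = unname(d_hat), e = unname(e_hat), j = 0, lnL = lnL, n_params = 2L,
    n_tips = prep$ntip, convergence = opt$convergence,
    optim_counts = opt$counts, phy = prep$phy, geog = geog,
    epoch = prep$epoch, space = space, prep = prep
  ), class = "range_fit")
}

#' @export
print.range_fit <- function(x, ...) {
  cat("Range-evolution model fit (", x$family,
      if (x$constrained) ", time-stratified multipliers" else ", unconstrained",
      ")\n", sep = "")
  cat(sprintf("  tips: %d   areas: %d   states: %d\n", x$n_tips,
              x$space$n_areas, x$space$n_states - 1L))
  cat(sprintf("  d = %.4g  e = %.4g   lnL = %.4f\n", x$d, x$e, x$lnL))
  cat(sprintf("  AIC = %.2f   AICc = %.2f (n = %d tips)\n",
              stats::AIC(x), aicc(x$lnL, x$n_params, x$n_tips), x$n_tips))
  if (x$convergence != 0)
    cat("  WARNING: optimizer did not report convergence (code ",
        x$convergence, "); values are best found\n", sep = "")
  invisible(x)
}

#' @export
coef.range_fit <- function(object, ...) c(d = object$d, e = object$e)

#' @export
logLik.range_fit <- function(object, ...) {
  structure(object$lnL, df = object$n_params, nobs = object$n_tips,
            class = "logLik")
}

#' @export
summary.range_fit <- function(object, ...) {
  out <- list(fit = object,
              aic = stats::AIC(object),
              aicc = aicc(object$lnL, object$n_params, object$n_tips))
  class(out) <- "summary.range_fit"
  out
}

#' @export
print.summary.range_fit <- function(x, ...) {
  print(x$fit)
  rs <- rowSums(x$fit$geog$presence)
  cat("  tip ranges: ", sum(rs == 1), " single-area, ", sum(rs > 1),
      " multi-area\n", sep = "")
  invisible(x)
}

aicc <- function(lnL, k, n) {
  if (n <= k + 1) return(NA_real_)
  (2 * k - 2 * lnL) + 2 * k * (k + 1) / (n - k - 1)
}

#' Akaike weights from information-criterion differences
#'
#' @param delta vector of IC differences from the best model
#'   (`delta = IC - min(IC)`).
#' @return normalized weights `exp(-delta/2) / sum(exp(-delta/2))`.
#' @examples
#' akaike_weights(c(7.48, 252.54, 115.07, 0, 26.66, 101.27))
#' @export
akaike_weights <- function(delta) {
  w <- exp(-delta / 2)
  w / sum(w)
}

#' Compare fitted range-evolution models by AIC and AICc
#'
#' Builds the standard model-comparison table: log-likelihood, parameter
#' count, fitted rates, AIC, AICc, differences from the best model and
#' Akaike weights (both criteria). The AICc sample size is the number of
#' tips.
#'
#' @param fits list of [fit_range_model()] objects, or a data.frame with
#'   columns `model`, `constrained`, `lnL`, `n_params` (optionally `d`, `e`).
#' @param n_obs AICc sample size; default: tip count of the first fit.
#' @return a data.frame of class `"model_table"`, one row per model, sorted
#'   as given, with columns `model`, `constrained`, `lnL`, `n_params`, `d`,
#'   `e`, `j`, `AIC`, `dAIC`, `AIC_wt`, `AICc`, `dAICc`, `AICc_wt`.
#' @export
model_selection <- function(fits, n_obs = NULL) {
  if (is.data.frame(fits)) {
    df <- fits
    if (is.null(df$d)) df$d <- NA_real_
    if (is.null(df$e)) df$e <- NA_real_
    if (is.null(n_obs)) stop("n_obs is required when passing a data.frame")
  } else {
    if (inherits(fits, "range_fit")) fits <- list(fits)
    df <- do.call(rbind, lapply(fits, function(f)
      data.frame(model = f$family,
                 constrained = f$constrained,
                 lnL = f$lnL, n_params = f$n_params, d = f$d, e = f$e)))
    if (is.null(n_obs)) n_obs <- fits[[1]]$n_tips
  }
  if (n_obs <= max(df$n_params) + 1)
    stop("AICc undefined: n_obs must exceed n_params + 1")
  df$j <- 0
  df$AIC <- 2 * df$n_params - 2 * df$lnL
  df$dAIC <- df$AIC - min(df$AIC)
  df$AIC_wt <- akaike_weights(df$dAIC)
  df$AICc <- mapply(aicc, df$lnL, df$n_params, n_obs)
  df$dAICc <- df$AICc - min(df$AICc)
  df$AICc_wt <- akaike_weights(df$dAICc)
  attr(df, "n_obs") <- n_obs
  class(df) <- c("model_table", "data.frame")
  df
}

#' @export
print.model_table <- function(x, digits = 4, ...) {
  cat("Model comparison (AICc sample size n =", attr(x, "n_obs"), "tips)\n")
  y <- as.data.frame(x)
  y$AIC_wt <- signif(y$AIC_wt, 3)
  y$AICc_wt <- signif(y$AICc_wt, 3)
  num <- vapply(y, is.numeric, logical(1)) & !(names(y) %in% c("AIC_wt", "AICc_wt"))
  y[num] <- lapply(y[num], round, digits = 2)
  print(y, row.names = FALSE, ...)
  invisible(x)
}

#' Write a model-comparison table as TSV
#' @param x a `"model_table"`.
#' @param path output path.
#' @export
write_model_table <- function(x, path) {
  utils::write.table(as.data.frame(x), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
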