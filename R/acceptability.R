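#' Fit the acceptability measurement model to questionnaire data
#'
#' One call runs the whole measurement pipeline on a respondent x item table
#' of raw ordinal responses:
#' rescaling onto the common 1-3 scale with neutral imputation of missing
#' cells; suitability diagnostics (sample size, Bartlett sphericity, KMO);
#' then, by the factor-analysis method, principal-factor extraction with
#' eigenvalue retention, rotation, cross-loading pruning, factor naming, a
#' maximum-likelihood confirmatory fit with the full fit-index panel and the
#' reliability/validity battery; or, by the simple-arithmetic method,
#' normalization to equal-sized constructs and the additive 0-100 index
#' formula. `method = "auto"` tries factor analysis first and falls back to
#' the arithmetic method when the data are unsuitable or do not yield three
#' nameable factors — the fallback the measurement tool prescribes.
#'
#' @param responses data.frame of raw response labels (one row per
#'   respondent, columns = codebook item ids) or a path to such a CSV.
#' @param cb a [codebook()] or a path readable by [load_codebook()].
#' @param method `"auto"`, `"factor_analysis"` or `"arithmetic"`.
#' @param k_per_construct indicators kept per construct for the arithmetic
#'   method (default 6).
#' @param rotation factor rotation for the exploratory step (default
#'   `"varimax"`).
#' @param threshold salience threshold for pruning, naming and indicator
#'   selection (default 0.4).
#' @param orientation index orientation, see
#'   [arithmetic_construct_index()].
#' @return An object of class `acceptability` holding every pipeline stage:
#'   `rescaled`, `suitability`, `efa`, `sem`, `tests`, `reliability`,
#'   `indices`, `method` (the method actually used) and `notes`. Methods:
#'   [print()], [summary()], [coef()] (standardized loadings), [predict()]
#'   (indices for new respondents), [plot()] (scree).
#' @examples
#' fx <- reach_fixture(seed = 42)
#' fit <- acceptability(fx$responses, fx$codebook, method = "arithmetic")
#' fit
#' @export
acceptability <- function(responses, cb,
                          method = c("auto", "factor_analysis", "arithmetic"),
                          k_per_construct = 6L, rotation = "varimax",
                          threshold = 0.4,
                          orientation = c("verbatim", "favorable_low")) {
  method <- match.arg(method)
  orientation <- match.arg(orientation)
  if (is.character(cb)) cb <- load_codebook(cb)
  if (is.character(responses)) responses <- read_responses(responses)
  m <- rescale_responses(responses, cb)
  suit <- fa_suitability(m)
  notes <- character()
  out <- list(codebook = cb, rescaled = m, suitability = suit,
              call = match.call(), orientation = orientation,
              threshold = threshold)

  try_fa <- method %in% c("auto", "factor_analysis")
  if (try_fa && !suit$fa_suitable) {
    if (method == "factor_analysis")
      stop("data fail the factor-analysis suitability rule; ",
           "use method = \"arithmetic\"")
    notes <- c(notes, "data unsuitable for factor analysis; arithmetic method used")
    try_fa <- FALSE
  }
  if (try_fa) {
    fa <- tryCatch({
      r <- principal_factor_extract(correlation_matrix(m))
      r <- retain_factors(r)
      r <- rotate(r, rotation)
      r <- prune_crossloadings(r, cb, threshold)
      r <- name_factors(r, cb, threshold)
      mod <- build_model(r, cb, threshold)
      fit <- fit_ml(mod, m)
      if (!isTRUE(fit$converged)) stop("ML estimation did not converge")
      list(efa = r, model = mod, fit = fit)
    }, error = function(e) e, warning = function(w) w)
    if (inherits(fa, "condition")) {
      if (method == "factor_analysis")
        stop("factor-analysis method failed: ", conditionMessage(fa))
      notes <- c(notes, paste0("factor-analysis method failed (",
                               conditionMessage(fa),
                               "); arithmetic method used"))
      try_fa <- FALSE
    } else {
      out$efa <- fa$efa
      out$model <- fa$model
      out$sem <- fa$fit
      out$tests <- hypothesis_tests(fa$fit)
      out$reliability <- reliability_validity(fa$fit, m)
      out$indices <- acceptability_indices(m, fa$efa, "factor_based",
                                           orientation, threshold)
      out$method <- "factor_analysis"
    }
  }
  if (!try_fa) {
    mn <- normalize_constructs(m, cb, k_per_construct)
    out$rescaled_normalized <- mn
    out$arith_suitability <- check_arith_suitability(mn, cb)
    out$indices <- acceptability_indices(mn, method = "arithmetic",
                                         orientation = orientation)
    out$method <- "arithmetic"
  }
  out$notes <- notes
  structure(out, class = "acceptability")
}

#' @export
print.acceptability <- function(x, ...) {
  cat(sprintf("Acceptability measurement fit (%s method)\n",
              sub("_", "-", x$method)))
  cat(sprintf("  %d respondents, %d items; %d missing cell(s) imputed to neutral\n",
              nrow(x$rescaled$scores), ncol(x$rescaled$scores),
              x$rescaled$missing_count))
  if (x$method == "factor_analysis") {
    cat(sprintf("  KMO %.3f, Bartlett p %.3g; %d factors retained (%.0f%% of variability)\n",
                x$suitability$kmo_overall, x$suitability$bartlett_p,
                x$efa$retained_k, 100 * x$efa$cumulative[x$efa$retained_k]))
    f <- x$sem$fit
    cat(sprintf("  SEM chi2(%d) = %.2f; RMSEA %.3f CFI %.3f TLI %.3f SRMR %.3f\n",
                x$sem$df, x$sem$chi2, f$rmsea, f$cfi, f$tli, f$srmr))
  }
  print(x$indices$summary, row.names = FALSE)
  for (nt in x$notes) cat("  note:", nt, "\n")
  invisible(x)
}

#' @export
summary.acceptability <- function(object, ...) {
  build_report(object)
}

#' @describeIn acceptability standardized loadings of the confirmatory fit
#'   (`NULL` for an arithmetic-method fit).
#' @param object,... method arguments.
#' @export
coef.acceptability <- function(object, ...) {
  if (is.null(object$sem)) return(NULL)
  e <- object$sem$estimates
  stats::setNames(e$std_loading, sprintf("%s->%s", e$item, e$construct))
}

#' @describeIn acceptability per-respondent indices for new raw responses
#'   scored with the fitted pipeline's codebook, item sets and orientation.
#' @param newdata data.frame of raw response labels (codebook columns).
#' @export
predict.acceptability <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(object$indices$per_respondent)
  m <- rescale_responses(newdata, object$codebook)
  if (object$method == "factor_analysis") {
    ind <- acceptability_indices(m, object$efa, "factor_based",
                                 object$orientation, object$threshold)
  } else {
    mn <- normalize_constructs(m, object$codebook,
                               length(object$indices$item_sets[[1L]]))
    ind <- acceptability_indices(mn, method = "arithmetic",
                                 orientation = object$orientation)
  }
  ind$per_respondent
}

#' @describeIn acceptability scree plot of the exploratory eigenvalues
#'   (factor-analysis fits) or a histogram of the overall index.
#' @param x an `acceptability` object.
#' @param y ignored.
#' @export
plot.acceptability <- function(x, y, ...) {
  if (!is.null(x$efa)) {
    ev <- x$efa$eigenvalues
    graphics::plot(seq_along(ev), ev, type = "b", xlab = "Factor",
                   ylab = "Eigenvalue", main = "Scree plot", ...)
    graphics::abline(h = 1, lty = 2)
  } else {
    graphics::hist(x$indices$per_respondent$overall,
                   xlab = "Overall acceptability index (%)",
                   main = "Overall index distribution", ...)
  }
  invisible(x)
}

#' @describeIn acceptability standardized residual covariances of the
#'   confirmatory fit (sample minus model-implied, on the correlation
#'   scale); `NULL` for arithmetic fits.
#' @export
residuals.acceptability <- function(object, ...) {
  if (is.null(object$sem)) return(NULL)
  sds <- sqrt(diag(object$sem$S))
  (object$sem$S - object$sem$Sigma) / tcrossprod(sds)
}
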