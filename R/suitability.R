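#' Pearson correlation matrix of rescaled scores
#'
#' @param m a `rescaled_matrix` (or a plain numeric matrix of scores).
#' @return An object of class `corr_matrix`: list with `R` (p x p Pearson
#'   correlation matrix) and `n_obs`.
#' @details Correlations are ordinary Pearson correlations on the integer
#'   scores, the convention of the survey-analysis workflow this package
#'   mirrors; polychoric correlation is deliberately out of scope.
#' @export
correlation_matrix <- function(m) {
  X <- if (inherits(m, "rescaled_matrix")) m$scores else as.matrix(m)
  if (nrow(X) < 2L) stop("need at least 2 respondents")
  sds <- apply(X, 2L, stats::sd)
  if (any(sds == 0))
    stop("constant item(s): ", paste(colnames(X)[sds == 0], collapse = ", "))
  structure(list(R = stats::cor(X), n_obs = nrow(X)), class = "corr_matrix")
}

as_corr <- function(R, n_obs) {
  if (inherits(R, "corr_matrix")) return(R)
  structure(list(R = R, n_obs = n_obs), class = "corr_matrix")
}

#' Bartlett's test of sphericity
#'
#' Tests the null hypothesis that the item correlation matrix is the
#' identity, i.e. the items share no common variance worth factoring:
#' \deqn{\chi^2 = -\left[(n-1) - \frac{2p+5}{6}\right] \ln\det R,
#'       \quad df = p(p-1)/2.}
#'
#' @param R a `corr_matrix` (from [correlation_matrix()]) or a correlation
#'   matrix with `n_obs` supplied.
#' @param n_obs number of observations; taken from `R` when it is a
#'   `corr_matrix`.
#' @return list with `chi2`, `df`, `p_value`.
#' @export
bartlett_sphericity <- function(R, n_obs = NULL) {
  cm <- as_corr(R, n_obs)
  Rm <- cm$R
  n <- cm$n_obs
  p <- ncol(Rm)
  detR <- det(Rm)
  if (!is.finite(detR) || detR <= 0)
    stop("correlation matrix is singular; sphericity statistic undefined")
  chi2 <- -((n - 1) - (2 * p + 5) / 6) * log(detR)
  df <- p * (p - 1) / 2
  list(chi2 = chi2, df = df,
       p_value = stats::pchisq(chi2, df, lower.tail = FALSE))
}

#' Kaiser-Meyer-Olkin measure of sampling adequacy
#'
#' Compares squared correlations to squared anti-image partial correlations:
#' the overall KMO is \eqn{\sum r_{ij}^2 / (\sum r_{ij}^2 + \sum a_{ij}^2)}
#' over off-diagonal pairs, where \eqn{a_{ij}} is the partial correlation of
#' items i and j given all others, obtained from the scaled inverse of R.
#' Values near 1 indicate compact correlation patterns well suited to factor
#' analysis; below 0.5, factoring is inadvisable.
#'
#' @inheritParams bartlett_sphericity
#' @return list with `overall` and `per_item` (named vector).
#' @export
kmo <- function(R, n_obs = NULL) {
  Rm <- as_corr(R, n_obs)$R
  p <- ncol(Rm)
  Rinv <- tryCatch(solve(Rm), error = function(e)
    stop("correlation matrix is not invertible; KMO undefined"))
  d <- 1 / sqrt(diag(Rinv))
  A <- -Rinv * tcrossprod(d)          # anti-image partial correlations
  diag(A) <- 0
  R0 <- Rm
  diag(R0) <- 0
  r2 <- sum(R0^2)
  a2 <- sum(A^2)
  if (r2 + a2 == 0)
    stop("all off-diagonal correlations are zero; KMO undefined (0/0)")
  r2_i <- rowSums(R0^2)
  a2_i <- rowSums(A^2)
  list(overall = r2 / (r2 + a2),
       per_item = stats::setNames(r2_i / (r2_i + a2_i), colnames(Rm)))
}

#' Suitability of the data for factor-analysis index formation
#'
#' Applies the three-way rule used to decide whether factor analysis may
#' form the indices: sample size above 250, Bartlett sphericity p below 0.05,
#' and overall KMO above 0.50. All three must hold.
#'
#' @param m a `rescaled_matrix` or `corr_matrix`.
#' @param n_min minimum sample size (default 250).
#' @param bartlett_alpha significance level for sphericity (default 0.05).
#' @param kmo_min minimum overall KMO (default 0.50).
#' @return An object of class `suitability_report`.
#' @export
fa_suitability <- function(m, n_min = 250, bartlett_alpha = 0.05,
                           kmo_min = 0.50) {
  cm <- if (inherits(m, "corr_matrix")) m else correlation_matrix(m)
  bt <- bartlett_sphericity(cm)
  km <- kmo(cm)
  checks <- list(
    sample_size = list(value = cm$n_obs, rule = sprintf("> %g", n_min),
                       pass = cm$n_obs > n_min),
    bartlett_p = list(value = bt$p_value, rule = sprintf("< %g", bartlett_alpha),
                      pass = bt$p_value < bartlett_alpha),
    kmo = list(value = km$overall, rule = sprintf("> %g", kmo_min),
               pass = km$overall > kmo_min))
  structure(list(n_obs = cm$n_obs,
                 bartlett_chi2 = bt$chi2, bartlett_df = bt$df,
                 bartlett_p = bt$p_value,
                 kmo_overall = km$overall, kmo_per_item = km$per_item,
                 fa_suitable = all(vapply(checks, `[[`, TRUE, "pass")),
                 checks = checks),
            class = "suitability_report")
}

#' @export
print.suitability_report <- function(x, ...) {
  cat("Suitability for factor-analysis index formation\n")
  cat(sprintf("  Sample size           %6d   (rule %s)  %s\n",
              x$n_obs, x$checks$sample_size$rule,
              verdict_mark(x$checks$sample_size$pass)))
  cat(sprintf("  Bartlett chi2(%d) = %.2f, p = %.4g   (rule %s)  %s\n",
              x$bartlett_df, x$bartlett_chi2, x$bartlett_p,
              x$checks$bartlett_p$rule, verdict_mark(x$checks$bartlett_p$pass)))
  cat(sprintf("  Overall KMO           %6.3f   (rule %s)  %s\n",
              x$kmo_overall, x$checks$kmo$rule, verdict_mark(x$checks$kmo$pass)))
  cat(sprintf("  => factor analysis %s\n",
              if (x$fa_suitable) "suitable" else "NOT suitable"))
  invisible(x)
}

verdict_mark <- function(ok) if (ok) "pass" else "FAIL"

#' Suitability of the data for the simple-arithmetic index
#'
#' The arithmetic index needs normalized inputs: every construct with the
#' same number of indicators, all items on the common ordinal scale, and a
#' sample at least as large as a configurable floor. The default floor
#' follows the reference rule "3 x number of items x number of scale
#' points" (e.g. 3 x 18 x 3 = 162 for six indicators per construct on a
#' three-point scale).
#'
#' @param m a `rescaled_matrix` whose columns are the retained indicators.
#' @param cb the [codebook()].
#' @param n_min optional explicit minimum sample size; when `NULL`, the
#'   default rule above is applied.
#' @return list with `arith_suitable` (logical) and `reasons` (per-rule
#'   verdicts).
#' @export
check_arith_suitability <- function(m, cb, n_min = NULL) {
  stopifnot(inherits(m, "rescaled_matrix"))
  cons <- m$constructs
  cnt <- table(factor(cons, levels = CONSTRUCTS))
  equal <- length(unique(as.integer(cnt))) == 1L && all(cnt > 0)
  n_scale <- m$scale$max_score - m$scale$min_score + 1L
  if (is.null(n_min)) n_min <- 3L * ncol(m$scores) * n_scale
  on_scale <- all(m$scores >= m$scale$min_score & m$scores <= m$scale$max_score)
  n_obs <- nrow(m$scores)
  reasons <- list(
    equal_items = list(value = paste(as.integer(cnt), collapse = "/"),
                       rule = "equal items per construct", pass = equal),
    common_scale = list(value = sprintf("%d-%d", m$scale$min_score, m$scale$max_score),
                        rule = "all scores on the common scale", pass = on_scale),
    sample_size = list(value = n_obs, rule = sprintf(">= %d", n_min),
                       pass = n_obs >= n_min))
  list(arith_suitable = all(vapply(reasons, `[[`, TRUE, "pass")),
       n_obs = n_obs, reasons = reasons)
}
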