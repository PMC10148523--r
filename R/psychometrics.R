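#' Cronbach's alpha
#'
#' Internal-consistency reliability of an item set:
#' \eqn{\alpha = \frac{k}{k-1}\left(1 - \frac{\sum_i s_i^2}{s_T^2}\right)},
#' where \eqn{s_i^2} are item variances and \eqn{s_T^2} the variance of the
#' item sum.
#'
#' @param m a `rescaled_matrix` or numeric matrix of scores.
#' @param items optional character vector restricting to an item subset.
#' @return alpha (scalar).
#' @export
cronbach_alpha <- function(m, items = NULL) {
  X <- if (inherits(m, "rescaled_matrix")) m$scores else as.matrix(m)
  if (!is.null(items)) X <- X[, items, drop = FALSE]
  k <- ncol(X)
  if (k < 2L) stop("alpha needs at least 2 items")
  if (nrow(X) < 2L) stop("alpha needs at least 2 respondents")
  total_var <- stats::var(rowSums(X))
  if (total_var == 0) stop("zero total-score variance; alpha undefined")
  k / (k - 1) * (1 - sum(apply(X, 2L, stats::var)) / total_var)
}

#' Average variance extracted (AVE)
#'
#' Mean squared standardized loading of a construct: the share of indicator
#' variance the construct captures. AVE above 0.5 indicates good convergent
#' validity. Invariant to loading signs.
#'
#' @param loadings numeric vector of standardized loadings.
#' @return AVE (scalar).
#' @examples
#' ave_extracted(c(0.92, 0.88, 0.54))  # 0.64
#' @export
ave_extracted <- function(loadings) {
  if (!length(loadings)) stop("no loadings supplied")
  mean(loadings^2)
}

#' Composite reliability (CR)
#'
#' \eqn{CR = (\sum \lambda)^2 / [(\sum \lambda)^2 + \sum (1 - \lambda^2)]}
#' on standardized loadings. The signed loadings are summed as estimated, so
#' a mixed-sign construct can have near-zero CR even with sizable loadings —
#' a diagnostic worth seeing, not hiding. Set `absolute = TRUE` to sum
#' absolute values instead.
#'
#' @param loadings numeric vector of standardized loadings (|loading| <= 1).
#' @param absolute sum |loadings| instead of signed loadings (default FALSE).
#' @return CR (scalar).
#' @examples
#' composite_reliability(c(0.47, 0.44, -0.86))  # ~0.001
#' @export
composite_reliability <- function(loadings, absolute = FALSE) {
  if (!length(loadings)) stop("no loadings supplied")
  if (any(abs(loadings) > 1))
    stop("|loading| > 1: loadings must be standardized")
  l <- if (absolute) abs(loadings) else loadings
  s2 <- sum(l)^2
  s2 / (s2 + sum(1 - loadings^2))
}

#' Maximum shared variance (MSV)
#'
#' Per construct, the largest squared correlation with any other construct.
#' Discriminant validity is achieved when each construct's AVE exceeds its
#' MSV — the construct shares more variance with its own indicators than
#' with any other construct.
#'
#' @param phi latent correlation matrix (constructs x constructs).
#' @return named vector of MSV values, one per construct.
#' @export
msv <- function(phi) {
  phi <- as.matrix(phi)
  if (ncol(phi) < 2L) stop("MSV needs at least 2 constructs")
  out <- vapply(seq_len(ncol(phi)), function(i)
    max(phi[i, -i]^2), numeric(1))
  stats::setNames(out, colnames(phi))
}

#' Reliability and validity verdicts
#'
#' Bands: alpha ideal > 0.70, acceptable 0.45-0.70, else weak; convergent
#' validity good if AVE > 0.50, borderline 0.35-0.50, else poor;
#' discriminant validity achieved iff AVE > MSV.
#'
#' @param alpha,cr,ave,msv equal-length numeric vectors (one entry per
#'   construct), optionally named.
#' @return An object of class `reliability_validity`: data.frame with the
#'   values and verdict columns `alpha_band`, `convergent`, `discriminant`.
#' @export
validity_assessment <- function(alpha, cr, ave, msv) {
  k <- length(alpha)
  stopifnot(length(cr) == k, length(ave) == k, length(msv) == k)
  nm <- names(alpha) %||% paste0("construct", seq_len(k))
  df <- data.frame(
    construct = nm, alpha = alpha, cr = cr, ave = ave, msv = msv,
    alpha_band = ifelse(alpha > 0.70, "ideal",
                        ifelse(alpha >= 0.45, "acceptable", "weak")),
    convergent = ifelse(ave > 0.50, "good",
                        ifelse(ave >= 0.35, "borderline", "poor")),
    discriminant = ifelse(ave > msv, "achieved", "failed"),
    row.names = NULL)
  structure(df, class = c("reliability_validity", "data.frame"))
}

#' Full reliability/validity battery from a fitted measurement model
#'
#' Computes, per construct: Cronbach's alpha on the construct's indicator
#' scores, CR and AVE from the standardized loadings, and MSV from the
#' latent correlations, then applies the verdict bands of
#' [validity_assessment()].
#'
#' @param fit a converged `sem_fit`.
#' @param m the `rescaled_matrix` the model was fitted to.
#' @return A `reliability_validity` report.
#' @export
reliability_validity <- function(fit, m) {
  if (!isTRUE(fit$converged)) stop("model did not converge")
  sets <- fit$model$constructs
  a <- vapply(names(sets), function(g) cronbach_alpha(m, sets[[g]]), numeric(1))
  lam <- split(fit$estimates$std_loading, fit$estimates$construct)[names(sets)]
  cr <- vapply(lam, composite_reliability, numeric(1))
  av <- vapply(lam, ave_extracted, numeric(1))
  ms <- msv(fit$phi)[names(sets)]
  validity_assessment(stats::setNames(a, names(sets)), cr, av, ms)
}

#' @export
print.reliability_validity <- function(x, digits = 3, ...) {
  cat("Reliability and validity per construct\n")
  y <- as.data.frame(x)
  num <- vapply(y, is.numeric, TRUE)
  y[num] <- lapply(y[num], function(v) signif(v, digits))
  print(y, row.names = FALSE)
  invisible(x)
}
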