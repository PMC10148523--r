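#' Principal-factor extraction
#'
#' Non-iterated principal-axis factoring: the diagonal of the correlation
#' matrix is replaced by squared-multiple-correlation (SMC) communality
#' estimates and the reduced matrix is eigendecomposed. Loadings are taken
#' from the factors with positive eigenvalues. Variance proportions divide
#' each eigenvalue by the sum of *all* eigenvalues, negative ones included,
#' so the cumulative column can exceed 1 before returning to exactly 1.00 at
#' the last factor — the signature of this convention.
#'
#' @param R a `corr_matrix` from [correlation_matrix()] (or a correlation
#'   matrix plus `n_obs`).
#' @param k_max maximum number of factors for which loadings are stored
#'   (default: all positive-eigenvalue factors).
#' @param n_obs sample size when `R` is a bare matrix.
#' @return An object of class `efa_result` with `eigenvalues`, `proportion`,
#'   `cumulative`, `loadings` (unrotated), `communalities`, `smc`,
#'   `retained_k` (filled by [retain_factors()]), `dropped_items` and the
#'   source correlation matrix (for re-extraction after pruning).
#' @export
principal_factor_extract <- function(R, k_max = Inf, n_obs = NULL) {
  cm <- as_corr(R, n_obs)
  Rm <- cm$R
  p <- ncol(Rm)
  if (is.null(colnames(Rm))) colnames(Rm) <- rownames(Rm) <- paste0("V", 1:p)
  Rinv <- tryCatch(solve(Rm), error = function(e)
    stop("correlation matrix is singular; cannot extract factors"))
  smc <- 1 - 1 / diag(Rinv)
  Rr <- Rm
  diag(Rr) <- smc
  ed <- eigen(Rr, symmetric = TRUE)
  ev <- ed$values
  npos <- sum(ev > .Machine$double.eps^0.5)
  k <- min(npos, k_max)
  L <- if (k > 0) {
    ed$vectors[, seq_len(k), drop = FALSE] %*% diag(sqrt(ev[seq_len(k)]), k)
  } else {
    matrix(0, p, 0)
  }
  rownames(L) <- colnames(Rm)
  if (k > 0) colnames(L) <- paste0("Factor", seq_len(k))
  prop <- ev / sum(ev)
  structure(list(eigenvalues = ev, proportion = prop,
                 cumulative = cumsum(prop),
                 loadings = L, rotated = NULL, rotation = "none",
                 communalities = stats::setNames(rowSums(L^2), colnames(Rm)),
                 smc = stats::setNames(smc, colnames(Rm)),
                 retained_k = NA_integer_, cumulative_ok = NA,
                 dropped_items = list(), factor_names = NULL,
                 corr = cm),
            class = "efa_result")
}

#' Retain factors by the eigenvalue rule
#'
#' Retains every factor whose eigenvalue exceeds `ev_min` (default 1.0) and
#' flags the result when the retained factors explain less than `cum_min`
#' (default 60%) of the correlation-matrix variability. Zero retained
#' factors raises an explicit "not factorable" error.
#'
#' @param r an `efa_result`.
#' @param ev_min eigenvalue threshold (default 1.0).
#' @param cum_min required cumulative proportion (default 0.60).
#' @return `r` with `retained_k` and `cumulative_ok` filled in.
#' @export
retain_factors <- function(r, ev_min = 1.0, cum_min = 0.60) {
  stopifnot(inherits(r, "efa_result"))
  k <- sum(r$eigenvalues > ev_min)
  if (k == 0L)
    stop("no eigenvalue exceeds ", ev_min, ": data not factorable by this rule")
  r$retained_k <- k
  r$cumulative_ok <- r$cumulative[k] >= cum_min
  if (!r$cumulative_ok)
    warning(sprintf("retained factors explain %.1f%% < %.0f%% of variability",
                    100 * r$cumulative[k], 100 * cum_min))
  r
}

#' Rotate retained factor loadings
#'
#' Orthogonal (varimax) or oblique (promax) rotation of the retained
#' loadings; communalities are unchanged by varimax. `"none"` stores the
#' unrotated loadings as the rotated solution.
#'
#' @param r an `efa_result` after [retain_factors()].
#' @param method `"none"`, `"varimax"` or `"promax"`.
#' @return `r` with `rotated` loadings and `rotation` set.
#' @export
rotate <- function(r, method = c("varimax", "promax", "none")) {
  stopifnot(inherits(r, "efa_result"))
  method <- match.arg(method)
  k <- r$retained_k
  if (is.na(k) || k < 1L) stop("call retain_factors() before rotate()")
  L <- r$loadings[, seq_len(k), drop = FALSE]
  r$rotated <- switch(method,
    none = L,
    varimax = if (k == 1L) L else unclass(stats::varimax(L)$loadings)[, , drop = FALSE],
    promax = if (k == 1L) L else unclass(stats::promax(L)$loadings)[, , drop = FALSE])
  dimnames(r$rotated) <- list(rownames(L), colnames(L))
  r$rotation <- method
  r
}

retained_loadings <- function(r) {
  k <- r$retained_k
  if (is.na(k)) stop("factors not yet retained")
  if (!is.null(r$rotated)) r$rotated
  else r$loadings[, seq_len(k), drop = FALSE]
}

# Fix each factor's sign so its largest-|loading| entry is positive.
align_signs <- function(L) {
  for (j in seq_len(ncol(L))) {
    i <- which.max(abs(L[, j]))
    if (L[i, j] < 0) L[, j] <- -L[, j]
  }
  L
}

#' Remove cross-loading items and re-extract
#'
#' An item loading at or above `threshold` (absolute value) on two or more
#' retained factors blurs the factor-construct correspondence. Removal is
#' iterative, one item per pass: among current cross-loaders, the item whose
#' construct is in the minority on its primary factor goes first (ties broken
#' by smallest communality); the factor solution is then re-extracted and
#' re-retained, until no cross-loader remains. Pruning refuses to shrink any
#' construct below three items.
#'
#' @param r an `efa_result` after [retain_factors()] (rotation optional;
#'   pruning decisions use the current loadings).
#' @param cb the [codebook()], for construct membership.
#' @param threshold salience threshold (default 0.4).
#' @return `efa_result` for the pruned item set; `dropped_items` logs each
#'   removal with its loadings and reason.
#' @export
prune_crossloadings <- function(r, cb, threshold = 0.4) {
  stopifnot(inherits(r, "efa_result"))
  if (is.na(r$retained_k)) stop("call retain_factors() before pruning")
  cons <- item_constructs(cb)
  dropped <- r$dropped_items
  repeat {
    L <- retained_loadings(r)
    sal <- abs(L) >= threshold
    cross <- rownames(L)[rowSums(sal) >= 2L]
    if (!length(cross)) break
    # primary factor of each item = factor with its largest |loading|
    primary <- apply(abs(L), 1L, which.max)
    pick <- vapply(cross, function(it) {
      f <- primary[[it]]
      on_f <- rownames(L)[sal[, f]]
      tab <- table(cons[on_f])
      as.integer(tab[cons[[it]]])    # how many construct-mates share the factor
    }, 1L)
    cand <- cross[pick == min(pick)]
    if (length(cand) > 1L) {
      comm <- rowSums(L[cand, , drop = FALSE]^2)
      cand <- cand[which.min(comm)]
    }
    drop_it <- cand[1L]
    keep <- setdiff(rownames(L), drop_it)
    remaining <- table(factor(cons[keep], levels = CONSTRUCTS))
    if (any(remaining < 3L))
      stop(sprintf("removing %s would leave construct %s with %d item(s); pruning stopped",
                   drop_it, names(remaining)[which.min(remaining)], min(remaining)))
    dropped <- c(dropped, list(list(
      item = drop_it,
      loadings = L[drop_it, ],
      reason = sprintf("|loading| >= %.2f on %d factors; construct in the minority on its primary factor",
                       threshold, sum(sal[drop_it, ])))))
    cm_new <- as_corr(r$corr$R[keep, keep], r$corr$n_obs)
    rot <- r$rotation
    r <- retain_factors(principal_factor_extract(cm_new))
    if (rot != "none") r <- rotate(r, rot)
  }
  r$dropped_items <- dropped
  r
}

#' Name retained factors by their dominant construct
#'
#' Each retained factor is named after the construct owning the majority of
#' its salient items (|loading| at or above `threshold`). Factor signs are
#' aligned first (largest |loading| positive) since the sign of a factor is
#' arbitrary. A factor with no salient loading stays unnamed; two factors
#' claiming the same construct raise an ambiguity error.
#'
#' @param r an `efa_result` after pruning/rotation.
#' @param cb the [codebook()].
#' @param threshold salience threshold (default 0.4).
#' @return `r` with `factor_names` (named character vector, possibly
#'   containing `NA` for unnamed factors) and sign-aligned rotated loadings.
#' @export
name_factors <- function(r, cb, threshold = 0.4) {
  stopifnot(inherits(r, "efa_result"))
  cons <- item_constructs(cb)
  L <- align_signs(retained_loadings(r))
  if (!is.null(r$rotated)) r$rotated <- L else
    r$loadings[, seq_len(r$retained_k)] <- L
  nm <- character(ncol(L))
  for (j in seq_len(ncol(L))) {
    sal <- rownames(L)[abs(L[, j]) >= threshold]
    if (!length(sal)) { nm[j] <- NA_character_; next }
    tab <- sort(table(cons[sal]), decreasing = TRUE)
    nm[j] <- names(tab)[1L]
  }
  dup <- nm[!is.na(nm)][duplicated(nm[!is.na(nm)])]
  if (length(dup))
    stop("ambiguous naming: construct(s) ", paste(unique(dup), collapse = ", "),
         " dominate more than one factor")
  r$factor_names <- stats::setNames(nm, colnames(L))
  r
}

#' Salient items of each named factor
#' @param r a named `efa_result`.
#' @param threshold salience threshold (default 0.4).
#' @return named list construct -> character vector of item ids.
#' @export
factor_item_sets <- function(r, threshold = 0.4) {
  if (is.null(r$factor_names)) stop("call name_factors() first")
  L <- retained_loadings(r)
  out <- list()
  for (j in seq_len(ncol(L))) {
    nm <- r$factor_names[[j]]
    if (is.na(nm)) next
    out[[nm]] <- rownames(L)[abs(L[, j]) >= threshold]
  }
  out
}

#' @export
print.efa_result <- function(x, digits = 2, ...) {
  p <- length(x$eigenvalues)
  cat(sprintf("Principal-factor extraction (%d items, n = %d)\n",
              p, x$corr$n_obs))
  tab <- data.frame(Eigenvalue = round(x$eigenvalues, digits),
                    Proportion = round(x$proportion, digits),
                    Cumulative = round(x$cumulative, digits))
  rownames(tab) <- paste0("Factor", seq_len(p))
  print(utils::head(tab, max(10L, if (is.na(x$retained_k)) 0L else x$retained_k + 2L)))
  if (!is.na(x$retained_k))
    cat(sprintf("Retained factors = %d (rotation: %s); cumulative %.2f\n",
                x$retained_k, x$rotation, x$cumulative[x$retained_k]))
  if (length(x$dropped_items))
    cat("Dropped items:",
        paste(vapply(x$dropped_items, `[[`, "", "item"), collapse = ", "), "\n")
  if (!is.null(x$factor_names))
    cat("Factor names:", paste(sprintf("%s = %s", names(x$factor_names),
                                       x$factor_names), collapse = ", "), "\n")
  invisible(x)
}

#' Export scree data (factor number vs eigenvalue)
#' @param r an `efa_result`.
#' @param path optional CSV destination; when `NULL`, the data frame is
#'   returned only.
#' @return data.frame with columns `factor`, `eigenvalue`.
#' @export
scree_data <- function(r, path = NULL) {
  df <- data.frame(factor = seq_along(r$eigenvalues),
                   eigenvalue = r$eigenvalues)
  if (!is.null(path)) utils::write.csv(df, path, row.names = FALSE)
  df
}

#' Export a loadings table, blanking sub-threshold entries
#' @param r an `efa_result` (rotated loadings if available).
#' @param display_min entries with |loading| below this are blanked
#'   (default 0.4).
#' @param path optional CSV destination.
#' @return data.frame of loadings (as character, blanks for suppressed) plus
#'   a `Uniqueness` column.
#' @export
loadings_table <- function(r, display_min = 0.4, path = NULL) {
  L <- retained_loadings(r)
  disp <- format(round(L, 2))
  disp[abs(L) < display_min] <- ""
  df <- data.frame(Variable = rownames(L), disp,
                   Uniqueness = round(1 - rowSums(L^2), 2),
                   check.names = FALSE, row.names = NULL)
  if (!is.null(path)) utils::write.csv(df, path, row.names = FALSE)
  df
}
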