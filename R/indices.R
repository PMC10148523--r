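#' Simple-arithmetic acceptability index for one construct
#'
#' Evaluates the additive composite index
#' \deqn{\mathrm{index} = \frac{n\,\max(P_k) + 1 - \sum_{i=1}^n P_i}
#'                             {n\,[\max(P_k) - \min(P_k)] + 1} \times 100}
#' verbatim, where the \eqn{P_i} are a respondent's n indicator scores for
#' the construct and min/max are the scale bounds. Note the orientation this
#' implies: all scores at the scale *minimum* give 100 and all at the
#' maximum give the floor \eqn{100/(n(\max-\min)+1)} (about 7.69 for six
#' indicators on the 1-3 scale). Because favorable answers are rescaled to
#' the *highest* scores, callers who want "higher index = more acceptable"
#' should pass `orientation = "favorable_low"`, which recodes scores as
#' \eqn{s \mapsto (\min + \max) - s} before the formula. The default applies
#' the formula exactly as printed and leaves interpretation to the caller.
#'
#' @param scores integer vector (one respondent) or respondent x item matrix
#'   of scores for a single construct; `NA` scores make that respondent's
#'   index `NA`.
#' @param scale a [scale_spec()].
#' @param orientation `"verbatim"` (default) or `"favorable_low"` (reflect
#'   scores first so that favorable responses raise the index).
#' @return index value(s) on (0, 100], one per respondent.
#' @examples
#' arithmetic_construct_index(rep(1, 6), scale_spec())  # 100
#' arithmetic_construct_index(rep(3, 6), scale_spec())  # 7.69
#' @export
arithmetic_construct_index <- function(scores, scale = scale_spec(),
                                       orientation = c("verbatim", "favorable_low")) {
  orientation <- match.arg(orientation)
  X <- if (is.matrix(scores)) scores else matrix(scores, nrow = 1L)
  n <- ncol(X)
  if (n < 3L) stop("a construct index needs at least 3 indicators")
  rng <- range(X, na.rm = TRUE)
  if (is.finite(rng[1]) &&
      (rng[1] < scale$min_score || rng[2] > scale$max_score))
    stop(sprintf("scores outside the %d-%d scale", scale$min_score,
                 scale$max_score))
  if (orientation == "favorable_low")
    X <- (scale$min_score + scale$max_score) - X
  hi <- scale$max_score
  lo <- scale$min_score
  idx <- (n * hi + 1 - rowSums(X)) / (n * (hi - lo) + 1) * 100
  if (is.matrix(scores)) idx else idx[[1L]]
}

#' Overall acceptability index
#'
#' Arithmetic mean of the three construct indices; respondents missing any
#' construct index get `NA` (excluded from the overall summary).
#'
#' @param provider,healthcare,community construct index vectors (percent).
#' @return overall index vector.
#' @export
overall_index <- function(provider, healthcare, community) {
  (provider + healthcare + community) / 3
}

#' Per-respondent acceptability indices
#'
#' Computes the Provider, Healthcare and Community indices and their overall
#' mean for every respondent.
#'
#' For `method = "arithmetic"` the matrix must already be normalized to
#' equal-sized constructs ([normalize_constructs()]); every construct uses
#' all of its columns. For `method = "factor_based"` the indicator sets come
#' from the retained, named factors of an EFA — a documented surrogate: the
#' same arithmetic formula applied to each construct's retained indicators
#' (the original factor-analysis index construction is not reproducible from
#' its description, so this variant is tagged and should be interpreted
#' accordingly).
#'
#' @param m a `rescaled_matrix`.
#' @param efa a named `efa_result`, required for `method = "factor_based"`.
#' @param method `"arithmetic"` or `"factor_based"`.
#' @param orientation passed to [arithmetic_construct_index()].
#' @param threshold salience threshold for the factor-based item sets.
#' @return An object of class `acceptability_indices`: data.frame
#'   `per_respondent` (respondent_id, provider, healthcare, community,
#'   overall), `summary` (via [index_summary()]), `method`, `item_sets`.
#' @export
acceptability_indices <- function(m, efa = NULL,
                                  method = c("arithmetic", "factor_based"),
                                  orientation = c("verbatim", "favorable_low"),
                                  threshold = 0.4) {
  method <- match.arg(method)
  orientation <- match.arg(orientation)
  stopifnot(inherits(m, "rescaled_matrix"))
  cons <- m$constructs
  if (method == "arithmetic") {
    sets <- split(names(cons), factor(cons, levels = CONSTRUCTS))
    if (length(unique(lengths(sets))) != 1L)
      stop("arithmetic method needs equal-sized constructs; run normalize_constructs()")
  } else {
    if (is.null(efa)) stop("factor_based method needs a named efa_result")
    sets <- factor_item_sets(efa, threshold)
    short <- names(sets)[lengths(sets) < 3L]
    if (length(short))
      stop("construct(s) with fewer than 3 retained items: ",
           paste(short, collapse = ", "))
    sets <- sets[CONSTRUCTS]
  }
  one <- function(g) arithmetic_construct_index(
    m$scores[, sets[[g]], drop = FALSE], m$scale, orientation)
  prov <- one("Provider"); heal <- one("Healthcare"); comm <- one("Community")
  per <- data.frame(respondent_id = rownames(m$scores) %||%
                      paste0("R", seq_len(nrow(m$scores))),
                    provider = prov, healthcare = heal, community = comm,
                    overall = overall_index(prov, heal, comm),
                    row.names = NULL)
  structure(list(per_respondent = per, summary = index_summary(per),
                 method = method, orientation = orientation,
                 item_sets = sets, scale = m$scale),
            class = "acceptability_indices")
}

#' Summary table of acceptability indices
#'
#' Observation counts, mean, sample standard deviation (n-1 denominator),
#' min and max per construct index and for the overall index. Mean and SD
#' are rounded to 2 decimals, min and max to integers, matching the usual
#' presentation of these indices.
#'
#' @param per data.frame with columns `provider`, `healthcare`, `community`,
#'   `overall` (`NA` allowed; excluded per column).
#' @return data.frame with columns `variable`, `obs`, `mean`, `sd`, `min`,
#'   `max` and an `sd_flag` note for single-observation columns.
#' @export
index_summary <- function(per) {
  cols <- c(provider = "Provider index", healthcare = "Healthcare index",
            community = "Community index", overall = "Maternal healthcare index")
  rows <- lapply(names(cols), function(cl) {
    v <- per[[cl]]
    v <- v[!is.na(v)]
    n <- length(v)
    if (!n) return(data.frame(variable = cols[[cl]], obs = 0L, mean = NA,
                              sd = NA, min = NA, max = NA, sd_flag = ""))
    data.frame(variable = cols[[cl]], obs = n,
               mean = round(mean(v), 2),
               sd = if (n > 1L) round(stats::sd(v), 2) else 0,
               min = round(min(v)), max = round(max(v)),
               sd_flag = if (n > 1L) "" else "single observation",
               row.names = NULL)
  })
  do.call(rbind, rows)
}

#' @export
print.acceptability_indices <- function(x, ...) {
  cat(sprintf("Acceptability indices (%s method, %s orientation), %d respondents\n",
              x$method, x$orientation, nrow(x$per_respondent)))
  print(x$summary, row.names = FALSE)
  invisible(x)
}

#' Write per-respondent indices to CSV
#' @param ind an `acceptability_indices` object.
#' @param path destination CSV.
#' @return `path`, invisibly.
#' @export
write_indices <- function(ind, path) {
  utils::write.csv(ind$per_respondent, path, row.names = FALSE)
  invisible(path)
}
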