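#' Read a respondent-by-item response table
#'
#' CSV with a header row of item ids and one row per respondent; an optional
#' leading `respondent_id` column carries opaque respondent identifiers
#' (generated as `R1..Rn` when absent). Empty cells and `NA` are missing.
#'
#' @param path CSV file path.
#' @return data.frame of raw response labels (character), row names set to
#'   respondent ids.
#' @export
read_responses <- function(path) {
  if (!file.exists(path)) stop("response file not found: ", path)
  df <- utils::read.csv(path, check.names = FALSE, colClasses = "character",
                        na.strings = c("", "NA"))
  if (!nrow(df)) stop("response file has no rows: ", path)
  if (identical(names(df)[1L], "respondent_id")) {
    rn <- df[[1L]]
    df <- df[-1L]
    rownames(df) <- rn
  } else {
    rownames(df) <- paste0("R", seq_len(nrow(df)))
  }
  df
}

#' Write raw responses back to CSV
#' @param raw data.frame of response labels (row names = respondent ids).
#' @param path destination CSV.
#' @return `path`, invisibly.
#' @export
write_responses <- function(raw, path) {
  out <- cbind(respondent_id = rownames(raw), raw)
  utils::write.csv(out, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Rescale raw responses onto the common ordinal scale
#'
#' Maps every raw label through the item's codebook `response_map`, so all
#' items land on the common 1-3 scale with the favorable answer at the
#' maximum regardless of item wording. Missing cells are imputed to the
#' neutral score and flagged; the total missing count is recorded.
#'
#' @param raw data.frame or matrix of raw response labels, columns matching
#'   the codebook item ids (order-insensitive; output follows codebook order).
#' @param cb a [codebook()].
#' @return An object of class `rescaled_matrix`: list with `scores` (integer
#'   respondent x item matrix), `imputed` (logical matrix of the same shape),
#'   `missing_count`, `scale` and `constructs` (item -> construct map).
#' @examples
#' cb <- codebook(list(
#'   item_spec("P1", "Provider", response_map = c(no = 1, unsure = 2, yes = 3)),
#'   item_spec("P2", "Provider", response_map = c(no = 1, unsure = 2, yes = 3)),
#'   item_spec("P3", "Provider", response_map = c(no = 1, unsure = 2, yes = 3)),
#'   item_spec("H1", "Healthcare", response_map = c(no = 1, unsure = 2, yes = 3)),
#'   item_spec("H2", "Healthcare", response_map = c(no = 1, unsure = 2, yes = 3)),
#'   item_spec("H3", "Healthcare", response_map = c(no = 1, unsure = 2, yes = 3)),
#'   item_spec("C1", "Community", response_map = c(no = 1, unsure = 2, yes = 3)),
#'   item_spec("C2", "Community", response_map = c(no = 1, unsure = 2, yes = 3)),
#'   item_spec("C3", "Community", response_map = c(no = 1, unsure = 2, yes = 3))))
#' raw <- as.data.frame(matrix("yes", 4, 9, dimnames = list(NULL, item_ids(cb))))
#' raw[2, "H1"] <- NA
#' m <- rescale_responses(raw, cb)
#' m$missing_count
#' @export
rescale_responses <- function(raw, cb) {
  raw <- as.data.frame(raw, stringsAsFactors = FALSE)
  ids <- item_ids(cb)
  missing_cols <- setdiff(ids, names(raw))
  extra_cols <- setdiff(names(raw), ids)
  if (length(missing_cols) || length(extra_cols))
    stop("response columns do not match the codebook",
         if (length(missing_cols)) paste0("; absent: ", paste(missing_cols, collapse = ", ")),
         if (length(extra_cols)) paste0("; unknown: ", paste(extra_cols, collapse = ", ")))
  raw <- raw[ids]
  n <- nrow(raw)
  scores <- matrix(NA_integer_, n, length(ids),
                   dimnames = list(rownames(raw), ids))
  for (it in cb$items) {
    v <- as.character(raw[[it$item_id]])
    miss <- is.na(v)
    mapped <- unname(it$response_map[v[!miss]])
    if (anyNA(mapped)) {
      bad <- unique(v[!miss][is.na(unname(it$response_map[v[!miss]]))])
      stop(sprintf("item %s: unmapped response label(s): %s",
                   it$item_id, paste(bad, collapse = ", ")))
    }
    col <- rep(NA_integer_, n)
    col[!miss] <- as.integer(mapped)
    scores[, it$item_id] <- col
  }
  imputed <- is.na(scores)
  scores[imputed] <- cb$scale$neutral_score
  structure(list(scores = scores, imputed = imputed,
                 missing_count = sum(imputed), scale = cb$scale,
                 constructs = item_constructs(cb)),
            class = "rescaled_matrix")
}

#' @export
print.rescaled_matrix <- function(x, ...) {
  cat(sprintf("Rescaled responses: %d respondents x %d items on the %d-%d scale; %d cell(s) imputed to neutral (%.2f%%)\n",
              nrow(x$scores), ncol(x$scores), x$scale$min_score,
              x$scale$max_score, x$missing_count,
              100 * x$missing_count / length(x$scores)))
  invisible(x)
}

#' Restrict a rescaled matrix to equal-sized constructs
#'
#' The arithmetic index requires every construct to contribute the same
#' number of indicators. By default the first `k` items of each construct in
#' codebook order are kept (the convention of the source instrument); an
#' explicit item list may override the selection.
#'
#' @param m a [rescale_responses()] result.
#' @param cb the [codebook()] used to build `m`.
#' @param k indicators to keep per construct.
#' @param items optional character vector of item ids overriding the
#'   first-`k` rule; must contain exactly `k` items of each construct.
#' @return A `rescaled_matrix` with `3 * k` columns.
#' @export
normalize_constructs <- function(m, cb, k, items = NULL) {
  stopifnot(inherits(m, "rescaled_matrix"))
  k <- as.integer(k)
  cons <- item_constructs(cb)
  cons <- cons[names(cons) %in% colnames(m$scores)]
  if (is.null(items)) {
    keep <- unlist(lapply(CONSTRUCTS, function(g) {
      in_g <- names(cons)[cons == g]
      if (length(in_g) < k)
        stop(sprintf("construct %s has %d item(s), fewer than k = %d",
                     g, length(in_g), k))
      in_g[seq_len(k)]
    }))
  } else {
    keep <- items
    if (!all(keep %in% names(cons)))
      stop("unknown item(s) in selection: ",
           paste(setdiff(keep, names(cons)), collapse = ", "))
    cnt <- table(factor(cons[keep], levels = CONSTRUCTS))
    if (any(cnt != k))
      stop("explicit selection must hold exactly k = ", k,
           " items per construct")
  }
  out <- m
  out$scores <- m$scores[, keep, drop = FALSE]
  out$imputed <- m$imputed[, keep, drop = FALSE]
  out$missing_count <- sum(out$imputed)
  out$constructs <- m$constructs[keep]
  out
}

#' Write / read a rescaled matrix (lossless round trip)
#'
#' Serializes to CSV with a `respondent_id` column; cells imputed from
#' missing raw responses carry a trailing `*` so provenance survives the
#' round trip.
#'
#' @param m a `rescaled_matrix`.
#' @param path destination CSV.
#' @return `path`, invisibly.
#' @export
write_rescaled <- function(m, path) {
  chr <- matrix(as.character(m$scores), nrow(m$scores),
                dimnames = dimnames(m$scores))
  chr[m$imputed] <- paste0(chr[m$imputed], "*")
  df <- data.frame(respondent_id = rownames(m$scores), chr,
                   check.names = FALSE)
  attr_line <- sprintf("# scale %d %d %d | constructs %s",
                       m$scale$min_score, m$scale$neutral_score,
                       m$scale$max_score,
                       paste(m$constructs, collapse = ","))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(attr_line, con)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_rescaled
#' @export
read_rescaled <- function(path) {
  header <- readLines(path, n = 1L)
  meta <- regmatches(header, regexec(
    "^# scale (\\d+) (\\d+) (\\d+) \\| constructs (.*)$", header))[[1L]]
  if (length(meta) != 5L) stop("not a rescaled-matrix file: ", path)
  df <- utils::read.csv(path, skip = 1L, check.names = FALSE,
                        colClasses = "character")
  rn <- df$respondent_id
  df <- df[setdiff(names(df), "respondent_id")]
  chr <- as.matrix(df)
  rownames(chr) <- rn
  imputed <- matrix(grepl("\\*$", chr), nrow(chr), dimnames = dimnames(chr))
  scores <- matrix(as.integer(sub("\\*$", "", chr)), nrow(chr),
                   dimnames = dimnames(chr))
  constructs <- stats::setNames(strsplit(meta[5L], ",")[[1L]], colnames(chr))
  structure(list(scores = scores, imputed = imputed,
                 missing_count = sum(imputed),
                 scale = scale_spec(as.integer(meta[2L]), as.integer(meta[3L]),
                                    as.integer(meta[4L])),
                 constructs = constructs),
            class = "rescaled_matrix")
}
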