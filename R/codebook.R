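#' Response-scale specification
#'
#' Defines the common ordinal scale every indicator is rescaled onto. The
#' default is the three-point scale used throughout the package: 1 (least
#' favorable), 2 (neutral), 3 (most favorable). The neutral score must be the
#' arithmetic midpoint of the bounds because missing responses are imputed to
#' it.
#'
#' @param min_score lowest attainable score (default 1).
#' @param neutral_score midpoint score used for neutral answers and for
#'   imputation of missing cells (default 2).
#' @param max_score highest attainable score (default 3).
#' @return An object of class `scale_spec`.
#' @examples
#' scale_spec()
#' @export
scale_spec <- function(min_score = 1L, neutral_score = 2L, max_score = 3L) {
  min_score <- as.integer(min_score)
  neutral_score <- as.integer(neutral_score)
  max_score <- as.integer(max_score)
  if (!(min_score < neutral_score && neutral_score < max_score))
    stop("scale must satisfy min_score < neutral_score < max_score")
  if (neutral_score * 2L != min_score + max_score)
    stop("neutral_score must be the arithmetic midpoint of min_score and max_score")
  structure(list(min_score = min_score, neutral_score = neutral_score,
                 max_score = max_score),
            class = "scale_spec")
}

#' @export
print.scale_spec <- function(x, ...) {
  cat(sprintf("Ordinal response scale: %d (min) / %d (neutral) / %d (max)\n",
              x$min_score, x$neutral_score, x$max_score))
  invisible(x)
}

CONSTRUCTS <- c("Provider", "Healthcare", "Community")

#' Single questionnaire item specification
#'
#' @param item_id short item code, e.g. `"P9"`, `"H4"`, `"C1"`.
#' @param construct one of `"Provider"`, `"Healthcare"`, `"Community"`.
#' @param wording full question text.
#' @param polarity `"favorable_high"` when agreement/affirmation is the
#'   favorable answer, `"favorable_low"` for reverse-worded items. Polarity is
#'   informational: the `response_map` must already send the favorable answer
#'   to the maximum score, so downstream code never handles orientation.
#' @param response_map named numeric vector mapping raw response labels to
#'   scores. Must contain the scale minimum and maximum; the neutral score is
#'   optional (binary yes/no items omit it and only receive a neutral score by
#'   imputation). No score may be used by more than one label.
#' @return An object of class `item_spec`.
#' @export
item_spec <- function(item_id, construct, wording = "",
                      polarity = c("favorable_high", "favorable_low"),
                      response_map) {
  polarity <- match.arg(polarity)
  construct <- match.arg(construct, CONSTRUCTS)
  if (!is.character(item_id) || length(item_id) != 1L || !nzchar(item_id))
    stop("item_id must be a non-empty string")
  rm_ <- unlist(response_map)
  if (is.null(names(rm_)) || any(!nzchar(names(rm_))))
    stop(sprintf("item %s: response_map must be a named label -> score mapping", item_id))
  structure(list(item_id = item_id, construct = construct, wording = wording,
                 polarity = polarity, response_map = rm_),
            class = "item_spec")
}

#' Questionnaire codebook
#'
#' A codebook binds the item specifications (construct membership, wording,
#' polarity and label-to-score maps) to a common response scale. Item order is
#' meaningful: construct normalization keeps the *first* k items of each
#' construct in codebook order.
#'
#' @param items list of [item_spec()] objects.
#' @param scale a [scale_spec()].
#' @param min_items_per_construct validation floor for construct sizes
#'   (default 3, the reference minimum of the measurement tool).
#' @return An object of class `codebook`.
#' @seealso [load_codebook()], [write_codebook()]
#' @export
codebook <- function(items, scale = scale_spec(), min_items_per_construct = 3L) {
  if (!inherits(scale, "scale_spec")) stop("scale must be a scale_spec")
  if (length(items) == 0L) stop("codebook has no items")
  items <- lapply(items, function(it) {
    if (!inherits(it, "item_spec")) stop("items must be item_spec objects")
    it
  })
  ids <- vapply(items, `[[`, "", "item_id")
  dup <- ids[duplicated(ids)]
  if (length(dup))
    stop("duplicate item_id: ", paste(unique(dup), collapse = ", "))
  allowed <- c(scale$min_score, scale$neutral_score, scale$max_score)
  for (it in items) {
    sc <- it$response_map
    bad <- setdiff(sc, allowed)
    if (length(bad))
      stop(sprintf("item %s: response_map scores outside the scale: %s",
                   it$item_id, paste(bad, collapse = ", ")))
    if (anyDuplicated(sc))
      stop(sprintf("item %s: a score is assigned to more than one label", it$item_id))
    if (!all(c(scale$min_score, scale$max_score) %in% sc))
      stop(sprintf("item %s: response_map must cover the scale minimum and maximum",
                   it$item_id))
  }
  counts <- table(factor(vapply(items, `[[`, "", "construct"), levels = CONSTRUCTS))
  low <- names(counts)[counts < min_items_per_construct]
  if (length(low))
    stop("constructs below the minimum of ", min_items_per_construct,
         " items: ", paste(sprintf("%s (%d)", low, counts[low]), collapse = ", "))
  structure(list(items = items, scale = scale), class = "codebook")
}

#' @export
print.codebook <- function(x, ...) {
  cnt <- construct_counts(x)
  cat(sprintf("Codebook: %d items (%s)\n", length(x$items),
              paste(sprintf("%s %d", names(cnt), cnt), collapse = ", ")))
  print(x$scale)
  invisible(x)
}

#' Item identifiers of a codebook
#' @param cb a [codebook()].
#' @return character vector in codebook order.
#' @export
item_ids <- function(cb) vapply(cb$items, `[[`, "", "item_id")

#' Construct membership of each item
#' @param cb a [codebook()].
#' @return named character vector (item_id -> construct), in codebook order.
#' @export
item_constructs <- function(cb) {
  stats::setNames(vapply(cb$items, `[[`, "", "construct"), item_ids(cb))
}

#' Items per construct
#' @param cb a [codebook()].
#' @return named integer vector over Provider/Healthcare/Community.
#' @export
construct_counts <- function(cb) {
  tab <- table(factor(item_constructs(cb), levels = CONSTRUCTS))
  stats::setNames(as.integer(tab), names(tab))
}

#' Read a codebook from YAML or JSON
#'
#' The file holds a `scale` block (`min_score`, `neutral_score`, `max_score`,
#' all optional, defaulting to 1/2/3) and an `items` list; each item carries
#' `item_id`, `construct`, `wording`, `polarity` and a `response_map` of
#' label: score pairs. Validation rejects duplicate ids, unknown constructs,
#' scores off the scale and constructs with fewer than three items, naming the
#' offending item in the error.
#'
#' @param path path to a `.yaml`/`.yml` or `.json` codebook file.
#' @return A validated [codebook()].
#' @export
load_codebook <- function(path) {
  if (!file.exists(path)) stop("codebook file not found: ", path)
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = FALSE)
  } else {
    yaml::read_yaml(path)
  }
  if (is.null(raw) || !length(raw)) stop("codebook file is empty: ", path)
  if (is.null(raw$items)) stop("codebook file has no 'items' block: ", path)
  sc <- raw$scale
  scale <- scale_spec(min_score = sc$min_score %||% 1L,
                      neutral_score = sc$neutral_score %||% 2L,
                      max_score = sc$max_score %||% 3L)
  items <- lapply(raw$items, function(it) {
    if (is.null(it$item_id)) stop("an item entry lacks item_id")
    if (is.null(it$construct))
      stop(sprintf("item %s: missing construct", it$item_id))
    if (is.null(it$response_map))
      stop(sprintf("item %s: missing response_map", it$item_id))
    item_spec(item_id = it$item_id, construct = it$construct,
              wording = it$wording %||% "",
              polarity = it$polarity %||% "favorable_high",
              response_map = it$response_map)
  })
  codebook(items, scale)
}

#' Write a codebook to YAML or JSON
#' @param cb a [codebook()].
#' @param path destination path; format chosen by extension (`.json` vs yaml).
#' @return `path`, invisibly.
#' @export
write_codebook <- function(cb, path) {
  out <- list(
    scale = list(min_score = cb$scale$min_score,
                 neutral_score = cb$scale$neutral_score,
                 max_score = cb$scale$max_score),
    items = lapply(cb$items, function(it) {
      list(item_id = it$item_id, construct = it$construct,
           wording = it$wording, polarity = it$polarity,
           response_map = as.list(it$response_map))
    })
  )
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(out, path, auto_unbox = TRUE, pretty = TRUE)
  } else {
    yaml::write_yaml(out, path)
  }
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
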