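report_row <- function(block, label, observed, reference, verdict = "n/a") {
  list(block = block, label = label, observed = observed,
       reference = reference, verdict = verdict)
}

band2 <- function(value, ideal, acceptable) {
  if (!is.finite(value)) return("n/a")
  if (ideal(value)) "ideal" else if (acceptable(value)) "acceptable" else "fail"
}
band1 <- function(value, ok) {
  if (!is.finite(value)) return("n/a")
  if (ok(value)) "acceptable" else "fail"
}

#' Assemble the measurement-tool report
#'
#' Builds the standardized report card for an acceptability measurement run:
#' general information, suitability, exploratory/confirmatory results,
#' reliability, validity and the acceptability-index block, each observed
#' value paired with its reference band and a verdict
#' (ideal / acceptable / fail / n-a). Reference bands: KMO above 0.50;
#' Bartlett p below 0.05; n of 250 or more for factor analysis; cumulative
#' variability of 0.60 or more; CFI/TLI above 0.95 ideal, above 0.90
#' acceptable; RMSEA below 0.05 ideal, 0.05-0.08 acceptable; SRMR below
#' 0.05 ideal, 0.05-0.10 acceptable; alpha and CR above 0.70 ideal,
#' 0.45-0.70 acceptable; AVE above 0.50 and above MSV. When fewer
#' or more than three factors were retained, the report carries the
#' redirection note to the arithmetic method.
#'
#' @param fit an [acceptability()] object (or a list with the same stage
#'   fields; a missing stage raises an error naming it).
#' @param header optional list with `institution`, `service`, `period`.
#' @return An object of class `measurement_tool_report`.
#' @export
build_report <- function(fit, header = list()) {
  method <- fit$method
  if (is.null(method)) stop("missing upstream stage: method")
  need <- function(stage) {
    if (is.null(fit[[stage]])) stop("missing upstream stage: ", stage)
    fit[[stage]]
  }
  m <- need("rescaled")
  cb <- need("codebook")
  rows <- list()
  add <- function(...) rows[[length(rows) + 1L]] <<- report_row(...)

  cnt <- construct_counts(cb)
  n_obs <- nrow(m$scores)
  n_scale <- m$scale$max_score - m$scale$min_score + 1L
  for (g in CONSTRUCTS)
    add("General information",
        sprintf("Number of included indicators for \"%s\" construct", g),
        cnt[[g]], "Minimum 3", band1(cnt[[g]], function(v) v >= 3))
  add("General information", "Number of indicator response options (scale)",
      n_scale, "Minimum 3", band1(n_scale, function(v) v >= 3))

  if (method == "factor_analysis") {
    suit <- need("suitability")
    efa <- need("efa")
    sem <- need("sem")
    rel <- need("reliability")
    add("General information", "Number of participants (sample size)",
        n_obs, ">= 250", band1(n_obs, function(v) v >= 250))
    add("Suitability", "Correlation matrix Bartlett's test p-value",
        signif(suit$bartlett_p, 3), "< 0.05",
        band1(suit$bartlett_p, function(v) v < 0.05))
    add("Suitability", "Kaiser-Meyer-Olkin (KMO) measure of sampling adequacy",
        round(suit$kmo_overall, 2), "> 0.50",
        band1(suit$kmo_overall, function(v) v > 0.50))
    add("Exploratory factor analysis", "Number of retained factors",
        efa$retained_k, "3",
        if (efa$retained_k == 3L) "acceptable" else "fail")
    cum <- efa$cumulative[efa$retained_k]
    add("Exploratory factor analysis", "Percentage of variability explained",
        round(cum, 3), ">= 0.60", band1(cum, function(v) v >= 0.60))
    f <- sem$fit
    add("SEM fitness", "chi-square p-value", signif(sem$p_value, 3), "< 0.05",
        band1(sem$p_value, function(v) v < 0.05))
    add("SEM fitness", "Root mean square error of approximation (RMSEA)",
        round(f$rmsea, 3), "< 0.05 (ideal); 0.05-0.08 (acceptable)",
        band2(f$rmsea, function(v) v < 0.05, function(v) v <= 0.08))
    add("SEM fitness", "Comparative fit index (CFI)", round(f$cfi, 3),
        "> 0.95 (ideal); > 0.90 (acceptable)",
        band2(f$cfi, function(v) v > 0.95, function(v) v > 0.90))
    add("SEM fitness", "Tucker-Lewis index (TLI)", round(f$tli, 3),
        "> 0.95 (ideal); > 0.90 (acceptable)",
        band2(f$tli, function(v) v > 0.95, function(v) v > 0.90))
    add("SEM fitness", "Standardized root mean residual (SRMR)",
        round(f$srmr, 3), "< 0.05 (ideal); 0.05-0.10 (acceptable)",
        band2(f$srmr, function(v) v < 0.05, function(v) v <= 0.10))
    for (i in seq_len(nrow(rel))) {
      g <- rel$construct[i]
      add("Reliability", sprintf("Composite reliability (CR): %s", g),
          round(rel$cr[i], 3), "> 0.70 (ideal); 0.45-0.70 (acceptable)",
          band2(rel$cr[i], function(v) v > 0.70, function(v) v >= 0.45))
    }
    for (i in seq_len(nrow(rel))) {
      g <- rel$construct[i]
      add("Reliability", sprintf("Cronbach's alpha: %s", g),
          round(rel$alpha[i], 3), "> 0.70 (ideal); 0.45-0.70 (acceptable)",
          band2(rel$alpha[i], function(v) v > 0.70, function(v) v >= 0.45))
    }
    for (i in seq_len(nrow(rel))) {
      g <- rel$construct[i]
      add("Validity", sprintf("Convergent validity (AVE): %s", g),
          round(rel$ave[i], 3), "> 0.50",
          band1(rel$ave[i], function(v) v > 0.50))
    }
    for (i in seq_len(nrow(rel))) {
      g <- rel$construct[i]
      add("Validity", sprintf("Discriminant validity (AVE vs MSV): %s", g),
          sprintf("AVE %.3f, MSV %.4f", rel$ave[i], rel$msv[i]),
          "AVE > MSV", if (rel$discriminant[i] == "achieved") "acceptable" else "fail")
    }
  } else if (method == "arithmetic") {
    arith <- need("arith_suitability")
    mn <- need("rescaled_normalized")
    n_floor <- 3L * ncol(mn$scores) * n_scale
    add("General information", "Number of participants (sample size)",
        n_obs, sprintf(">= %d (3 x items x scale points)", n_floor),
        band1(n_obs, function(v) v >= n_floor))
    add("Suitability", "Normalized indicators",
        if (arith$reasons$common_scale$pass) "Yes" else "No", "Yes",
        band1(as.numeric(arith$reasons$common_scale$pass), function(v) v == 1))
    add("Suitability", "Equal number of indicators per construct",
        if (arith$reasons$equal_items$pass) "Yes" else "No", "Yes",
        band1(as.numeric(arith$reasons$equal_items$pass), function(v) v == 1))
  } else stop("unknown method: ", method)

  ind <- need("indices")
  for (i in seq_len(nrow(ind$summary))) {
    s <- ind$summary[i, ]
    add("Acceptability index", s$variable,
        sprintf("obs %d, mean %.2f, sd %.2f, min %d, max %d",
                s$obs, s$mean, s$sd, s$min, s$max),
        "scale range 1-100%", "n/a")
  }
  sets <- ind$item_sets
  for (g in names(sets))
    add("Indicators included", sprintf("%s construct variables", g),
        paste(sets[[g]], collapse = ", "), "", "n/a")
  add("Dataset availability", "Confirmation of dataset availability",
      "Yes", "Yes", "acceptable")

  footnotes <- character()
  if (method == "factor_analysis" && fit$efa$retained_k != 3L ||
      method == "arithmetic" && length(fit$notes))
    footnotes <- c(footnotes, paste(
      "If the number of retained factors differs from 3 (Provider,",
      "Healthcare, Community), use the simple-arithmetic method to",
      "calculate the acceptability indices."))
  footnotes <- c(footnotes, paste(
    "RMSEA reference band applied as < 0.05 (ideal) / 0.05-0.08",
    "(acceptable), the conventional scale for this index."))

  structure(list(method = method,
                 header = list(institution = header$institution %||% "",
                               service = header$service %||% "",
                               period = header$period %||% ""),
                 rows = rows, footnotes = footnotes),
            class = "measurement_tool_report")
}

#' Render a measurement-tool report
#'
#' Deterministic serialization of a [build_report()] result.
#'
#' @param report a `measurement_tool_report`.
#' @param format `"text"` (block layout), `"json"` or `"csv"` (flat rows).
#' @param path optional destination file; when `NULL` the rendering is
#'   returned as a character string.
#' @return The serialized report as a single string (invisibly when written
#'   to `path`).
#' @export
render <- function(report, format = c("text", "json", "csv"), path = NULL) {
  stopifnot(inherits(report, "measurement_tool_report"))
  format <- match.arg(format)
  out <- switch(format,
    text = {
      lines <- c(sprintf("Healthcare acceptability measurement tool using %s",
                         if (report$method == "factor_analysis")
                           "factor analysis" else "simple arithmetic analysis"),
                 sprintf("Health institution: %s", report$header$institution),
                 sprintf("Service: %s", report$header$service),
                 sprintf("Data collection period: %s", report$header$period))
      blk <- ""
      for (r in report$rows) {
        if (r$block != blk) {
          blk <- r$block
          lines <- c(lines, "", paste0("== ", blk, " =="))
        }
        lines <- c(lines, sprintf("  %-60s %-28s %-24s %s", r$label,
                                  as.character(r$observed),
                                  as.character(r$reference), r$verdict))
      }
      if (length(report$footnotes))
        lines <- c(lines, "", paste0("Note: ", report$footnotes))
      paste(lines, collapse = "\n")
    },
    json = jsonlite::toJSON(list(method = report$method,
                                 header = report$header,
                                 rows = report$rows,
                                 footnotes = report$footnotes),
                            auto_unbox = TRUE, pretty = TRUE, digits = NA),
    csv = {
      df <- do.call(rbind, lapply(report$rows, function(r)
        data.frame(block = r$block, label = r$label,
                   observed = as.character(r$observed),
                   reference = as.character(r$reference),
                   verdict = r$verdict)))
      tc <- textConnection("csvout", "w", local = TRUE)
      utils::write.csv(df, tc, row.names = FALSE)
      close(tc)
      paste(csvout, collapse = "\n")
    })
  if (!is.null(path)) {
    writeLines(out, path)
    return(invisible(out))
  }
  out
}

#' Parse a JSON-rendered report back into a `measurement_tool_report`
#' @param json JSON string or file path produced by [render()].
#' @return a `measurement_tool_report`.
#' @export
parse_report_json <- function(json) {
  x <- jsonlite::fromJSON(json, simplifyVector = FALSE)
  structure(list(method = x$method, header = x$header,
                 rows = x$rows, footnotes = unlist(x$footnotes)),
            class = "measurement_tool_report")
}

#' @export
print.measurement_tool_report <- function(x, ...) {
  cat(render(x, "text"), "\n")
  invisible(x)
}
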