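#' Simulation configuration for ordinal questionnaire data
#'
#' Describes a three-factor latent model for ordinal items: each item's
#' continuous response is a linear combination of the three latent factors
#' (rows of `loadings`) plus unique normal noise with variance
#' \eqn{1 - \sum_j \lambda_{ij}^2}, discretized into scores 1/2/3 at the
#' item's thresholds. Default thresholds are the standard-normal tertiles
#' (equal-probability categories).
#'
#' @param n_respondents sample size.
#' @param loadings items x 3 matrix of true loadings (row names = item ids).
#' @param phi 3 x 3 latent correlation matrix (default identity).
#' @param thresholds length-2 increasing cut points, or an items x 2 matrix
#'   for per-item thresholds; default `qnorm(c(1/3, 2/3))`.
#' @param missing_rate probability a cell is masked missing (MCAR).
#' @param seed integer RNG seed.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_respondents, loadings, phi = diag(3),
                       thresholds = stats::qnorm(c(1/3, 2/3)),
                       missing_rate = 0, seed = 1L) {
  loadings <- as.matrix(loadings)
  if (ncol(loadings) != 3L) stop("loadings must have 3 columns (factors)")
  if (any(abs(loadings) > 1)) stop("|loading| must be <= 1")
  comm <- rowSums(loadings^2)
  if (any(comm > 1))
    stop("communality > 1 for item(s): ",
         paste(rownames(loadings)[comm > 1], collapse = ", "))
  if (any(eigen(phi, symmetric = TRUE, only.values = TRUE)$values <= 0))
    stop("latent correlation matrix must be positive definite")
  if (is.matrix(thresholds)) {
    if (ncol(thresholds) != 2L || nrow(thresholds) != nrow(loadings))
      stop("per-item thresholds must be an items x 2 matrix")
    if (any(thresholds[, 1] >= thresholds[, 2]))
      stop("thresholds must be strictly increasing")
  } else {
    if (length(thresholds) != 2L || thresholds[1] >= thresholds[2])
      stop("thresholds must be 2 strictly increasing cut points")
    thresholds <- matrix(thresholds, nrow(loadings), 2, byrow = TRUE)
  }
  if (missing_rate < 0 || missing_rate >= 1) stop("missing_rate must be in [0, 1)")
  if (is.null(rownames(loadings)))
    rownames(loadings) <- paste0("V", seq_len(nrow(loadings)))
  structure(list(n_respondents = as.integer(n_respondents),
                 loadings = loadings, phi = phi, thresholds = thresholds,
                 missing_rate = missing_rate, seed = as.integer(seed)),
            class = "sim_config")
}

#' Simulate ordinal questionnaire responses
#'
#' Draws correlated latent factors, forms each item's continuous response
#' from its loadings plus communality-consistent unique noise, discretizes
#' at the thresholds into labels `"unfavorable"` / `"neutral"` /
#' `"favorable"` (scores 1/2/3 under the matching codebook), and masks cells
#' missing completely at random at `missing_rate`. Fully reproducible for a
#' given seed.
#'
#' @param cfg a [sim_config()].
#' @param labels length-3 character vector of response labels for scores
#'   1, 2, 3.
#' @return data.frame of response labels (`NA` = missing), row names
#'   `R1..Rn`, columns named after the loading-matrix rows.
#' @export
simulate_responses <- function(cfg,
                               labels = c("unfavorable", "neutral", "favorable")) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  n <- cfg$n_respondents
  p <- nrow(cfg$loadings)
  F <- MASS::mvrnorm(n, mu = rep(0, 3), Sigma = cfg$phi)
  uniq_sd <- sqrt(1 - rowSums(cfg$loadings^2))
  X <- F %*% t(cfg$loadings) +
    matrix(stats::rnorm(n * p), n, p) %*% diag(uniq_sd, p)
  S <- matrix(NA_integer_, n, p)
  for (j in seq_len(p))
    S[, j] <- findInterval(X[, j], cfg$thresholds[j, ]) + 1L
  if (cfg$missing_rate > 0)
    S[matrix(stats::runif(n * p) < cfg$missing_rate, n, p)] <- NA_integer_
  out <- as.data.frame(matrix(labels[S], n, p), stringsAsFactors = FALSE)
  names(out) <- rownames(cfg$loadings)
  rownames(out) <- paste0("R", seq_len(n))
  out
}

# Table-style instrument: 25 items, 12 Provider / 7 Healthcare / 6 Community,
# reverse-worded items flagged favorable_low (their favorable answer still
# maps to the top score).
fixture_item_table <- function() {
  data.frame(
    item_id = c(paste0("P", 1:12), paste0("H", 1:7), paste0("C", 1:6)),
    construct = rep(c("Provider", "Healthcare", "Community"), c(12, 7, 6)),
    polarity = c("favorable_high", "favorable_low", "favorable_high",
                 "favorable_high", "favorable_high", "favorable_low",
                 "favorable_high", "favorable_low", "favorable_low",
                 "favorable_low", "favorable_low", "favorable_high",
                 "favorable_low", "favorable_high", "favorable_high",
                 "favorable_high", "favorable_high", "favorable_high",
                 "favorable_high",
                 rep("favorable_high", 6)),
    wording = c(
      "The health workers explained what to expect when giving birth",
      "It is a problem that the health workers do not speak my language",
      "Was your privacy respected?",
      "The health workers understood the difficulty of being in labour and assisted me where possible",
      "Were you offered fluids?",
      "I did not receive sufficient pain relief during my labour",
      "In this clinic are you able to talk to the doctors or nurses in private?",
      "The health workers were too busy to listen to my problems",
      "Were you shouted at during labour?",
      "Were you ever hit, slapped or pinched during labour?",
      "Some staff do not treat patients with sufficient respect",
      "The health workers I saw cared about me",
      "The facilities (including waiting area and toilets) are dirty",
      "Were you allowed to have a companion during your labour?",
      "How satisfied were you with the service today?",
      "Did you get referred for follow up care for you and the baby?",
      "For birth registration, did you get all the necessary documents?",
      "Were you told about the child-care grant and where to go for it if you qualify?",
      "Do you think your delivery was well-managed?",
      "I had all the support that I needed during my pregnancy from the father of the child",
      "I had all the support that I needed from my family",
      "I had all the support that I needed from my friends",
      "I received financial help from the father of the child",
      "I received financial help from my family",
      "I received financial help from my friends"),
    stringsAsFactors = FALSE)
}

#' Synthetic three-construct survey fixture
#'
#' A self-contained stand-in for a maternal-healthcare acceptability survey:
#' a 25-item codebook (12 Provider, 7 Healthcare, 6 Community items on a
#' 1-3 scale) plus 359 simulated respondents. The generating model has three
#' weakly correlated latent factors (correlation 0.05); within each
#' construct, three marker items (P9, P11, P12 / H4, H5, H6 / C1, C4, C5)
#' load at 0.8 on their factor and the remaining items at 0.25, emulating an
#' instrument where only a core of items carries the construct signal.
#' About 1.77% of cells are masked missing at random.
#'
#' @param seed integer RNG seed.
#' @param n_respondents sample size (default 359).
#' @param missing_rate MCAR masking probability (default 0.0177).
#' @param lambda_marker,lambda_other true loadings of marker and non-marker
#'   items (defaults 0.8 and 0.25).
#' @param phi_offdiag latent correlation between constructs (default 0.05).
#' @return list with `codebook` (a [codebook()]) and `responses` (raw label
#'   data.frame as from [simulate_responses()]).
#' @export
reach_fixture <- function(seed = 1L, n_respondents = 359L,
                          missing_rate = 0.0177,
                          lambda_marker = 0.8, lambda_other = 0.25,
                          phi_offdiag = 0.05) {
  tab <- fixture_item_table()
  markers <- c("P9", "P11", "P12", "H4", "H5", "H6", "C1", "C4", "C5")
  L <- matrix(0, nrow(tab), 3, dimnames = list(tab$item_id, CONSTRUCTS))
  for (i in seq_len(nrow(tab))) {
    lam <- if (tab$item_id[i] %in% markers) lambda_marker else lambda_other
    L[i, tab$construct[i]] <- lam
  }
  phi <- matrix(phi_offdiag, 3, 3)
  diag(phi) <- 1
  cfg <- sim_config(n_respondents, L, phi, missing_rate = missing_rate,
                    seed = seed)
  responses <- simulate_responses(cfg)
  items <- lapply(seq_len(nrow(tab)), function(i)
    item_spec(tab$item_id[i], tab$construct[i], tab$wording[i],
              tab$polarity[i],
              response_map = c(unfavorable = 1, neutral = 2, favorable = 3)))
  list(codebook = codebook(items), responses = responses)
}
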