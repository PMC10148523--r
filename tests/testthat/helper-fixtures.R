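# Shared fixture builders: everything is generated in code at test time.

std_map <- c(unfavorable = 1, neutral = 2, favorable = 3)

# Wrap a bare correlation matrix + n as the package's corr_matrix container.
as_corr_fixture <- function(R, n_obs) {
  if (is.null(colnames(R)))
    colnames(R) <- rownames(R) <- paste0("V", seq_len(ncol(R)))
  structure(list(R = R, n_obs = n_obs), class = "corr_matrix")
}

# Minimal codebook: n_p/n_h/n_c items per construct, all on the same
# label -> score map.
make_codebook <- function(n_p = 3, n_h = 3, n_c = 3) {
  mk <- function(prefix, n, construct)
    lapply(seq_len(n), function(i)
      item_spec(paste0(prefix, i), construct, response_map = std_map))
  codebook(c(mk("P", n_p, "Provider"), mk("H", n_h, "Healthcare"),
             mk("C", n_c, "Community")))
}

# Turn an integer score matrix into the raw label data.frame the codebook
# above maps back onto those scores.
scores_to_raw <- function(scores, cb) {
  labels <- names(std_map)
  df <- as.data.frame(matrix(labels[scores], nrow(scores),
                             dimnames = dimnames(scores)),
                      stringsAsFactors = FALSE)
  df[item_ids(cb)]
}

# Continuous indicators from a factor model (no discretization): n x p data
# with loadings L (p x k) and latent correlation phi.
simulate_continuous <- function(n, L, phi = diag(ncol(L)), seed = 1) {
  set.seed(seed)
  F <- MASS::mvrnorm(n, rep(0, ncol(L)), phi)
  X <- F %*% t(L) + matrix(rnorm(n * nrow(L)), n) %*%
    diag(sqrt(1 - rowSums(L^2)), nrow(L))
  colnames(X) <- rownames(L)
  X
}

# Marker-structure loading matrix: 3 factors, k markers each at lambda.
marker_loadings <- function(lambda = 0.7, k = 3,
                            ids = c(paste0("P", 1:k), paste0("H", 1:k),
                                    paste0("C", 1:k))) {
  L <- kronecker(diag(3), matrix(lambda, k, 1))
  rownames(L) <- ids
  L
}

# Align estimated loading columns to a target pattern by best permutation
# and sign.
align_to_pattern <- function(L, target) {
  k <- ncol(target)
  perms <- function(v) if (length(v) == 1) list(v) else
    unlist(lapply(seq_along(v), function(i)
      lapply(perms(v[-i]), function(p) c(v[i], p))), recursive = FALSE)
  best <- NULL
  best_err <- Inf
  for (pm in perms(seq_len(k))) {
    Lp <- L[, pm, drop = FALSE]
    for (j in seq_len(k)) if (sum(Lp[, j] * target[, j]) < 0) Lp[, j] <- -Lp[, j]
    err <- max(abs(Lp - target))
    if (err < best_err) { best_err <- err; best <- Lp }
  }
  best
}

# The published extraction's 24 eigenvalues (used as printed inputs).
published_eigenvalues <- c(2.31, 1.58, 1.30, 0.79, 0.56, 0.51, 0.43, 0.25,
                           0.19, 0.16, 0.14, 0.06, 0.00, -0.07, -0.09, -0.10,
                           -0.12, -0.13, -0.17, -0.20, -0.22, -0.27, -0.30,
                           -0.34)

# Published standardized loadings per construct (reliability table).
published_loadings <- list(Healthcare = c(0.92, 0.88, 0.54),
                           Provider = c(0.47, 0.44, -0.86),
                           Community = c(0.56, 0.98, -0.45))
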