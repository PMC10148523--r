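#' Build the three-construct measurement model
#'
#' Takes the named, pruned exploratory solution and turns each factor's
#' salient items (|loading| >= `threshold`) into the indicator set of its
#' construct. Identification is by standardized latents: every latent
#' variance is fixed to 1 and all loadings are free, so the latent
#' covariances are correlations. Latent covariances are free.
#'
#' @param efa a named `efa_result` (after [name_factors()]).
#' @param cb the [codebook()].
#' @param threshold salience threshold for indicator inclusion (default 0.4).
#' @return An object of class `measurement_model`: `constructs` (named list
#'   construct -> item ids), `items`, and a lavaan-style `syntax` string.
#' @export
build_model <- function(efa, cb, threshold = 0.4) {
  if (is.null(efa$factor_names)) stop("EFA factors must be named first")
  nm <- efa$factor_names[!is.na(efa$factor_names)]
  k <- efa$retained_k
  if (k != 3L)
    stop(sprintf(paste("%d factors retained instead of 3 (Provider, Healthcare,",
                       "Community): consider the simple-arithmetic method instead"), k))
  if (length(nm) != 3L)
    stop("all three retained factors must be named to build the model")
  sets <- factor_item_sets(efa, threshold)
  short <- names(sets)[vapply(sets, length, 1L) < 3L]
  if (length(short))
    stop("construct(s) with fewer than 3 indicators: ",
         paste(short, collapse = ", "))
  sets <- sets[intersect(CONSTRUCTS, names(sets))]
  syntax <- paste(vapply(names(sets), function(g)
    sprintf("%s =~ %s", g, paste(sets[[g]], collapse = " + ")), ""),
    collapse = "\n")
  structure(list(constructs = sets, items = unlist(sets, use.names = FALSE),
                 syntax = syntax),
            class = "measurement_model")
}

#' Specify a measurement model directly
#'
#' Escape hatch next to [build_model()]: supply the construct -> indicator
#' map yourself (e.g. for a single-construct model or a model not derived
#' from an exploratory solution).
#'
#' @param constructs named list, construct name -> character vector of item
#'   ids (no item may serve two constructs).
#' @return A `measurement_model`.
#' @export
measurement_model <- function(constructs) {
  items <- unlist(constructs, use.names = FALSE)
  if (anyDuplicated(items))
    stop("cross-construct indicator(s): ",
         paste(unique(items[duplicated(items)]), collapse = ", "))
  syntax <- paste(vapply(names(constructs), function(g)
    sprintf("%s =~ %s", g, paste(constructs[[g]], collapse = " + ")), ""),
    collapse = "\n")
  structure(list(constructs = constructs, items = items, syntax = syntax),
            class = "measurement_model")
}

#' @export
print.measurement_model <- function(x, ...) {
  cat("Measurement model (standardized latents, free latent covariances):\n")
  cat(x$syntax, "\n")
  invisible(x)
}

# Model-implied covariance from the parameter vector.
# theta = c(lambda[p], z[ng(ng-1)/2] (atanh latent correlations, upper
# triangle column-wise), log_psi[p])
implied_sigma <- function(theta, p, groups, ng = max(groups)) {
  nz <- ng * (ng - 1) / 2
  lambda <- theta[seq_len(p)]
  psi <- exp(theta[p + nz + seq_len(p)])
  phi <- diag(ng)
  if (nz > 0) phi[upper.tri(phi)] <- tanh(theta[p + seq_len(nz)])
  phi[lower.tri(phi)] <- t(phi)[lower.tri(phi)]
  L <- matrix(0, p, ng)
  L[cbind(seq_len(p), groups)] <- lambda
  L %*% phi %*% t(L) + diag(psi, p)
}

ml_discrepancy <- function(S, Sigma) {
  p <- ncol(S)
  cS <- tryCatch(chol(Sigma), error = function(e) NULL)
  if (is.null(cS)) return(NA_real_)
  logdetSig <- 2 * sum(log(diag(cS)))
  logdetSig + sum(diag(S %*% chol2inv(cS))) - determinant(S)$modulus[1] - p
}

#' Fit the measurement model by maximum likelihood
#'
#' Minimizes the normal-theory ML discrepancy between the sample covariance
#' of the rescaled scores and the model-implied covariance
#' \eqn{\Sigma = \Lambda \Phi \Lambda' + \Theta} (quasi-Newton over free
#' loadings, latent correlations and unique variances). Standard errors come
#' from the inverse observed information; standardized loadings and their
#' delta-method standard errors are reported alongside the raw solution. The
#' baseline for incremental fit indices is the independence model with free
#' variances.
#'
#' @param model a [build_model()] result.
#' @param m a `rescaled_matrix` (or a numeric matrix of scores) containing
#'   the model's items.
#' @return An object of class `sem_fit`: coefficient table (`estimates`),
#'   latent correlation matrix (`phi`), `chi2`, `df`, `p_value`, baseline
#'   chi-square/df, the fit-index panel (`fit`) and a `converged` flag.
#' @export
fit_ml <- function(model, m) {
  X <- if (inherits(m, "rescaled_matrix")) m$scores else as.matrix(m)
  miss <- setdiff(model$items, colnames(X))
  if (length(miss)) stop("data lack model items: ", paste(miss, collapse = ", "))
  X <- X[stats::complete.cases(X[, model$items, drop = FALSE]),
         model$items, drop = FALSE]
  n <- nrow(X)
  p <- ncol(X)
  if (n <= p) stop("need more respondents than indicators")
  S <- stats::cov(X)
  ng <- length(model$constructs)
  groups <- rep(seq_len(ng), vapply(model$constructs, length, 1L))

  # starts: first principal component of each construct's covariance block
  lam0 <- numeric(p)
  psi0 <- numeric(p)
  for (g in seq_along(model$constructs)) {
    idx <- which(groups == g)
    Sg <- S[idx, idx, drop = FALSE]
    eg <- eigen(Sg, symmetric = TRUE)
    l <- eg$vectors[, 1L] * sqrt(max(eg$values[1L], 1e-6))
    if (sum(l) < 0) l <- -l
    lam0[idx] <- l * 0.9
    psi0[idx] <- pmax(diag(Sg) - lam0[idx]^2, 0.05 * diag(Sg))
  }
  nz <- ng * (ng - 1) / 2
  start <- c(lam0, rep(0, nz), log(psi0))

  nll <- function(theta) {
    Sigma <- implied_sigma(theta, p, groups, ng)
    F <- ml_discrepancy(S, Sigma)
    if (!is.finite(F)) return(1e10)
    (n - 1) / 2 * F
  }
  opt <- stats::optim(start, nll, method = "BFGS",
                      control = list(maxit = 1000, reltol = 1e-12))
  converged <- opt$convergence == 0 && is.finite(opt$value)
  theta <- opt$par
  Sigma <- implied_sigma(theta, p, groups, ng)
  Fmin <- ml_discrepancy(S, Sigma)
  chi2 <- max((n - 1) * Fmin, 0)
  nfree <- length(theta)
  df <- p * (p + 1) / 2 - nfree
  if (!converged)
    return(structure(list(converged = FALSE, n_obs = n, model = model),
                     class = "sem_fit"))

  H <- stats::optimHess(theta, nll)
  V <- tryCatch(solve(H), error = function(e) matrix(NA_real_, nfree, nfree))
  lambda <- theta[seq_len(p)]
  se_lambda <- sqrt(pmax(diag(V)[seq_len(p)], 0))

  std_fun <- function(th) {
    Sg <- implied_sigma(th, p, groups, ng)
    th[seq_len(p)] / sqrt(diag(Sg))
  }
  J <- num_jacobian(std_fun, theta)
  Vstd <- J %*% V %*% t(J)
  std <- std_fun(theta)
  se_std <- sqrt(pmax(diag(Vstd), 0))

  phi <- diag(ng)
  if (nz > 0) phi[upper.tri(phi)] <- tanh(theta[p + seq_len(nz)])
  phi[lower.tri(phi)] <- t(phi)[lower.tri(phi)]
  dimnames(phi) <- list(names(model$constructs), names(model$constructs))
  Theta <- diag(exp(theta[p + nz + seq_len(p)]), p)
  dimnames(Theta) <- dimnames(S)

  # baseline (independence) model: diagonal covariance
  Rs <- stats::cov2cor(S)
  chi2_b <- max(-(n - 1) * determinant(Rs)$modulus[1], 0)
  df_b <- p * (p - 1) / 2

  est <- data.frame(
    item = model$items,
    construct = rep(names(model$constructs),
                    vapply(model$constructs, length, 1L)),
    loading = lambda, se = se_lambda,
    std_loading = std, std_se = se_std,
    z = std / se_std,
    p_value = 2 * stats::pnorm(-abs(std / se_std)),
    row.names = NULL)

  fit_panel <- fit_indices(chi2, df, chi2_b, df_b, n,
                           S = S, Sigma = Sigma, Theta = Theta)
  structure(list(converged = TRUE, n_obs = n, model = model,
                 estimates = est, phi = phi, Theta = Theta,
                 S = S, Sigma = Sigma,
                 chi2 = chi2, df = df,
                 p_value = stats::pchisq(chi2, df, lower.tail = FALSE),
                 chi2_baseline = chi2_b, df_baseline = df_b,
                 fit = fit_panel),
            class = "sem_fit")
}

num_jacobian <- function(f, x, eps = 1e-6) {
  f0 <- f(x)
  J <- matrix(0, length(f0), length(x))
  for (j in seq_along(x)) {
    h <- eps * max(1, abs(x[j]))
    xp <- x; xp[j] <- x[j] + h
    xm <- x; xm[j] <- x[j] - h
    J[, j] <- (f(xp) - f(xm)) / (2 * h)
  }
  J
}

#' Goodness-of-fit index panel
#'
#' Computes the standard covariance-structure fit panel from the model and
#' baseline chi-squares:
#' \itemize{
#' \item RMSEA \eqn{= \sqrt{\max(\chi^2_m - df_m, 0) / (df_m (n-1))}}, with a
#'   90% confidence interval from the noncentral chi-square and
#'   `pclose` = P(RMSEA <= 0.05);
#' \item CFI \eqn{= 1 - \max(\chi^2_m - df_m, 0) / \max(\chi^2_b - df_b,
#'   \chi^2_m - df_m, 0)};
#' \item TLI \eqn{= [(\chi^2_b/df_b) - (\chi^2_m/df_m)] / [(\chi^2_b/df_b) - 1]},
#'   clamped to \[0, 1\];
#' \item SRMR: root mean square of the standardized residual covariances,
#'   diagonal included (requires `S` and `Sigma`);
#' \item CD \eqn{= 1 - \det\Theta / \det\Sigma}, clamped to \[0, 1\] (requires
#'   `Theta` and `Sigma`).
#' }
#'
#' @param chi2_m,df_m model chi-square and degrees of freedom.
#' @param chi2_b,df_b baseline (independence) chi-square and df.
#' @param n sample size.
#' @param S,Sigma,Theta optional sample covariance, model-implied covariance
#'   and unique-variance matrix; SRMR and CD are `NA` without them.
#' @return list with `rmsea`, `rmsea_ci` (length-2), `pclose`, `cfi`, `tli`,
#'   `srmr`, `cd`.
#' @export
fit_indices <- function(chi2_m, df_m, chi2_b, df_b, n,
                        S = NULL, Sigma = NULL, Theta = NULL) {
  N1 <- n - 1
  excess_m <- max(chi2_m - df_m, 0)
  rmsea <- if (df_m > 0) sqrt(excess_m / (df_m * N1)) else 0
  ci <- c(0, 0)
  pclose <- NA_real_
  if (df_m > 0) {
    ncp_at <- function(q) {   # ncp with pchisq(chi2_m, df_m, ncp) = q
      if (stats::pchisq(chi2_m, df_m) < q) return(0)
      stats::uniroot(function(l) stats::pchisq(chi2_m, df_m, ncp = l) - q,
                     lower = 0, upper = max(chi2_m * 3, 100),
                     extendInt = "downX", tol = 1e-8)$root
    }
    ci <- sqrt(c(ncp_at(0.95), ncp_at(0.05)) / (df_m * N1))
    pclose <- stats::pchisq(chi2_m, df_m, ncp = 0.05^2 * df_m * N1,
                            lower.tail = FALSE)
  }
  denom <- max(chi2_b - df_b, chi2_m - df_m, 0)
  cfi <- if (denom == 0) 1 else 1 - excess_m / denom
  tli <- if (df_m == 0) 1 else {
    rb <- chi2_b / df_b
    rm_ <- chi2_m / df_m
    min(max((rb - rm_) / (rb - 1), 0), 1)
  }
  srmr <- NA_real_
  if (!is.null(S) && !is.null(Sigma)) {
    sds <- sqrt(diag(S))
    E <- (S - Sigma) / tcrossprod(sds)
    srmr <- sqrt(mean(E[upper.tri(E, diag = TRUE)]^2))
  }
  cd <- NA_real_
  if (!is.null(Theta) && !is.null(Sigma))
    cd <- min(max(1 - det(Theta) / det(Sigma), 0), 1)
  list(rmsea = rmsea, rmsea_ci = ci, pclose = pclose,
       cfi = min(max(cfi, 0), 1), tli = tli, srmr = srmr, cd = cd)
}

#' Hypothesis tests on the standardized loadings
#'
#' Per indicator-construct relationship: standardized coefficient, z
#' statistic (coefficient / delta-method SE), two-sided p value, 95%
#' confidence interval, and a rejection verdict for the null hypothesis of
#' no relationship (rejected when p < `alpha` and the interval excludes 0).
#'
#' @param fit a converged `sem_fit`.
#' @param alpha significance level (default 0.01).
#' @param conf_level confidence level for the interval (default 0.95).
#' @return data.frame with one row per loading.
#' @export
hypothesis_tests <- function(fit, alpha = 0.01, conf_level = 0.95) {
  if (!isTRUE(fit$converged)) stop("model did not converge; no tests available")
  e <- fit$estimates
  zq <- stats::qnorm(1 - (1 - conf_level) / 2)
  lo <- e$std_loading - zq * e$std_se
  hi <- e$std_loading + zq * e$std_se
  data.frame(relationship = sprintf("%s -> %s", e$item, e$construct),
             std_coef = e$std_loading, z = e$z, p_value = e$p_value,
             ci_lower = lo, ci_upper = hi,
             rejected = e$p_value < alpha & (lo > 0 | hi < 0),
             row.names = NULL)
}

#' @export
print.sem_fit <- function(x, digits = 3, ...) {
  if (!isTRUE(x$converged)) {
    cat("SEM fit: DID NOT CONVERGE\n")
    return(invisible(x))
  }
  cat(sprintf("SEM measurement model, n = %d\n", x$n_obs))
  cat(sprintf("  chi2(%d) = %.2f, p = %.4g   [baseline chi2(%d) = %.2f]\n",
              x$df, x$chi2, x$p_value, x$df_baseline, x$chi2_baseline))
  f <- x$fit
  cat(sprintf("  RMSEA %.3f (90%% CI %.3f-%.3f, pclose %.3f)  CFI %.3f  TLI %.3f  SRMR %.3f  CD %.3f\n",
              f$rmsea, f$rmsea_ci[1], f$rmsea_ci[2], f$pclose,
              f$cfi, f$tli, f$srmr, f$cd))
  est <- x$estimates
  est[, sapply(est, is.numeric)] <- round(est[, sapply(est, is.numeric)], digits)
  print(est)
  invisible(x)
}
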