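fit_fixture_efa <- function(seed = 4) {
  fx <- reach_fixture(seed = seed)
  m <- rescale_responses(fx$responses, fx$codebook)
  r <- rotate(retain_factors(principal_factor_extract(correlation_matrix(m))),
              "varimax")
  list(efa = name_factors(prune_crossloadings(r, fx$codebook), fx$codebook),
       cb = fx$codebook, m = m)
}

test_that("build_model maps each named factor to its salient indicators", {
  x <- fit_fixture_efa()
  mod <- build_model(x$efa, x$cb)
  expect_setequal(mod$constructs$Healthcare, c("H4", "H5", "H6"))
  expect_setequal(mod$constructs$Provider, c("P9", "P11", "P12"))
  expect_setequal(mod$constructs$Community, c("C1", "C4", "C5"))
  expect_match(mod$syntax, "Provider =~ ")

  # a construct falling under 3 indicators is rejected
  expect_error(build_model(x$efa, x$cb, threshold = 0.9), "fewer than 3")

  # retained != 3 redirects to the arithmetic method
  r2 <- x$efa
  r2$retained_k <- 4L
  expect_error(build_model(r2, x$cb), "simple-arithmetic")
})

test_that("a just-identified single-construct model matches the closed-form triad solution", {
  lam <- c(0.8, 0.7, 0.6)
  L <- cbind(lam, 0, 0)
  rownames(L) <- c("A1", "A2", "A3")
  X <- simulate_continuous(2000, L, seed = 7)
  mod <- measurement_model(list(A = c("A1", "A2", "A3")))
  f <- fit_ml(mod, X)
  expect_true(f$converged)
  expect_equal(f$df, 0)
  expect_lt(f$chi2, 1e-4)

  S <- cov(X)
  triad <- c(sqrt(S[1, 2] * S[1, 3] / S[2, 3]),
             sqrt(S[1, 2] * S[2, 3] / S[1, 3]),
             sqrt(S[1, 3] * S[2, 3] / S[1, 2]))
  expect_equal(f$estimates$loading, triad, tolerance = 1e-3)

  # df = 0 guard: RMSEA 0, CFI 1
  expect_equal(f$fit$rmsea, 0)
  expect_equal(f$fit$cfi, 1)
})

test_that("data generated from the fitted model yield near-perfect fit", {
  L <- marker_loadings(0.7)
  phi <- matrix(0.3, 3, 3); diag(phi) <- 1
  mod <- measurement_model(list(Provider = paste0("P", 1:3),
                                Healthcare = paste0("H", 1:3),
                                Community = paste0("C", 1:3)))
  for (s in 1:5) {
    X <- simulate_continuous(5000, L, phi, seed = 300 + s)
    f <- fit_ml(mod, X)
    expect_true(f$converged)
    expect_gte(f$fit$cfi, 0.99)
    expect_lte(f$fit$rmsea, 0.02)
    expect_equal(f$df, 24)   # 45 moments - 9 loadings - 3 corr - 9 uniques
  }
})

test_that("standardized loadings recover generating values (median over 20 seeds)", {
  L <- marker_loadings(0.7)
  phi <- matrix(0.2, 3, 3); diag(phi) <- 1
  mod <- measurement_model(list(Provider = paste0("P", 1:3),
                                Healthcare = paste0("H", 1:3),
                                Community = paste0("C", 1:3)))
  fits <- lapply(1:20, function(s) {
    X <- simulate_continuous(1000, L, phi, seed = 400 + s)
    fit_ml(mod, X)
  })
  errs <- vapply(fits, function(f)
    max(abs(f$estimates$std_loading - 0.7)), numeric(1))
  expect_lte(median(errs), 0.10)
  # latent correlations are recovered on average across the same seeds
  phis <- vapply(fits, function(f) mean(f$phi[upper.tri(f$phi)]), numeric(1))
  expect_equal(mean(phis), 0.2, tolerance = 0.03)
})

test_that("fit_indices reproduces the published panel from its printed chi-squares", {
  f <- fit_indices(51.47, 27, 874.102, 36, 359)
  expect_equal(round(f$cfi, 3), 0.971)
  expect_equal(round(f$tli, 3), 0.961)
  expect_equal(round(f$rmsea, 2), 0.05)
  expect_equal(round(f$rmsea_ci, 3), c(0.029, 0.071))
  expect_equal(round(f$pclose, 3), 0.461)
})

test_that("fit_indices guards the degenerate cases", {
  # chi2 = df: zero population error
  f <- fit_indices(27, 27, 874.102, 36, 359)
  expect_equal(f$rmsea, 0)
  expect_equal(f$cfi, 1)

  # SRMR = 0 when the sample covariance equals the implied covariance
  S <- matrix(c(1, 0.4, 0.4, 1), 2)
  f2 <- fit_indices(10, 5, 100, 10, 200, S = S, Sigma = S)
  expect_equal(f2$srmr, 0)

  # CD clamps to [0, 1]
  Theta <- diag(c(0.5, 0.5))
  f3 <- fit_indices(10, 5, 100, 10, 200, S = S, Sigma = S, Theta = Theta)
  expect_gte(f3$cd, 0)
  expect_lte(f3$cd, 1)
})

test_that("hypothesis tests reject exactly when p is small and the CI excludes zero", {
  x <- fit_fixture_efa(seed = 12)
  f <- fit_ml(build_model(x$efa, x$cb), x$m)
  tt <- hypothesis_tests(f)
  expect_equal(nrow(tt), 9L)
  expect_true(all(tt$rejected))
  expect_true(all(tt$ci_lower > 0 | tt$ci_upper < 0))
  expect_equal(tt$z, tt$std_coef / f$estimates$std_se, tolerance = 1e-12)

  # a null coefficient with a wide CI is not rejected
  f0 <- f
  f0$estimates$std_loading[1] <- 0
  f0$estimates$std_se[1] <- 0.5
  f0$estimates$z[1] <- 0
  f0$estimates$p_value[1] <- 1
  tt0 <- hypothesis_tests(f0)
  expect_false(tt0$rejected[1])
})

test_that("a true-zero loading is rejected at close to the nominal rate", {
  L <- marker_loadings(0.7)
  L["P3", 1] <- 0       # null loading inside the Provider set
  # correlated factors keep the two remaining Provider indicators identified
  phi <- matrix(0.3, 3, 3); diag(phi) <- 1
  mod <- measurement_model(list(Provider = paste0("P", 1:3),
                                Healthcare = paste0("H", 1:3),
                                Community = paste0("C", 1:3)))
  reps <- 200
  p05 <- logical(reps)
  strict <- logical(reps)
  for (s in seq_len(reps)) {
    X <- simulate_continuous(2000, L, phi, seed = 1000 + s)
    f <- fit_ml(mod, X)
    tt <- hypothesis_tests(f)
    i <- which(tt$relationship == "P3 -> Provider")
    p05[s] <- tt$p_value[i] < 0.05
    strict[s] <- tt$rejected[i]
  }
  # 0.05-level two-sided rate within ~3.3 binomial SDs of nominal
  expect_gte(mean(p05), 0.05 - 3.3 * sqrt(0.05 * 0.95 / reps))
  expect_lte(mean(p05), 0.05 + 3.3 * sqrt(0.05 * 0.95 / reps))
  # the stricter verdict (p < 0.01 and 95% CI excluding 0) is rarer still
  expect_lte(mean(strict), 0.06)
})

test_that("fit_ml validates its inputs", {
  mod <- measurement_model(list(A = c("A1", "A2", "A3")))
  X <- matrix(rnorm(30), 10, 3, dimnames = list(NULL, c("A1", "A2", "B9")))
  expect_error(fit_ml(mod, X), "lack model items: A3")
  expect_error(measurement_model(list(A = c("A1", "A2"), B = c("A2", "A3"))),
               "cross-construct")
})
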