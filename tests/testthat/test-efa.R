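test_that("principal-factor extraction matches an independent eigendecomposition", {
  # one strong factor, nine items
  L <- matrix(0.8, 9, 1)
  rownames(L) <- paste0("V", 1:9)
  X <- simulate_continuous(2000, cbind(L, 0, 0), seed = 3)
  cm <- correlation_matrix(X)
  r <- principal_factor_extract(cm)

  # oracle: rebuild the reduced matrix by hand and eigendecompose it
  R <- cm$R
  smc <- 1 - 1 / diag(solve(R))
  Rr <- R; diag(Rr) <- smc
  ed <- eigen(Rr, symmetric = TRUE)
  expect_equal(r$eigenvalues, ed$values, tolerance = 1e-8)
  expect_gt(r$eigenvalues[1], 4 * abs(r$eigenvalues[2]))  # dominant factor
  expect_equal(abs(r$loadings[, 1]),
               abs(ed$vectors[, 1] * sqrt(ed$values[1])), tolerance = 1e-8,
               ignore_attr = TRUE)

  # trace identity: sum of eigenvalues = sum of SMC
  expect_equal(sum(r$eigenvalues), sum(smc), tolerance = 1e-8)
  # cumulative returns to exactly 1 at p
  expect_equal(r$cumulative[length(r$cumulative)], 1, tolerance = 1e-12)
  # proportions use the full (signed) eigenvalue sum
  expect_equal(r$proportion, r$eigenvalues / sum(r$eigenvalues))
})

test_that("an identity correlation matrix yields nothing to extract", {
  r <- principal_factor_extract(as_corr_fixture(diag(6), 100))
  expect_equal(unname(r$smc), rep(0, 6))
  expect_equal(r$eigenvalues, rep(0, 6))
  expect_equal(ncol(r$loadings), 0L)
  expect_error(retain_factors(r), "not factorable")
})

test_that("retention counts eigenvalues above 1 and flags weak cumulative", {
  skel <- function(ev) structure(
    list(eigenvalues = ev, proportion = ev / sum(ev),
         cumulative = cumsum(ev / sum(ev))), class = "efa_result")

  r <- retain_factors(skel(c(2.31, 1.58, 1.30, 0.79, 0.40)))
  expect_equal(r$retained_k, 3L)
  expect_true(r$cumulative_ok)

  expect_error(retain_factors(skel(c(0.9, 0.5, 0.2))), "not factorable")

  # retained but under the 60% cumulative rule
  expect_warning(r2 <- retain_factors(skel(c(1.2, 1.1, 0.9, 0.9, 0.9, 0.8))),
                 "< 60%")
  expect_equal(r2$retained_k, 2L)
  expect_false(r2$cumulative_ok)
})

test_that("rotation preserves communalities (varimax) and reduces to varimax for orthogonal structure", {
  L <- marker_loadings(0.7)
  X <- simulate_continuous(1500, L, seed = 9)
  r <- retain_factors(principal_factor_extract(correlation_matrix(X)))
  rv <- rotate(r, "varimax")
  # orthogonal rotation: row sums of squared loadings unchanged
  expect_equal(rowSums(rv$rotated^2),
               rowSums(r$loadings[, 1:r$retained_k]^2), tolerance = 1e-10)

  rp <- rotate(r, "promax")
  A <- align_to_pattern(rp$rotated, rv$rotated)
  expect_lt(max(abs(A - rv$rotated)), 0.05)

  rn <- rotate(r, "none")
  expect_equal(rn$rotated, r$loadings[, 1:r$retained_k])

  expect_error(rotate(r, "quartimax"), "'arg' should be one of")
})

test_that("a planted cross-loader is pruned and the solution re-extracted", {
  cb <- make_codebook(4, 3, 3)
  ids <- item_ids(cb)
  L <- matrix(0, 10, 3, dimnames = list(ids, NULL))
  L[paste0("P", 1:3), 1] <- 0.75
  L[paste0("H", 1:3), 2] <- 0.75
  L[paste0("C", 1:3), 3] <- 0.75
  L["P4", 1] <- 0.5
  L["P4", 2] <- 0.55    # planted cross-loader on the Healthcare factor
  X <- simulate_continuous(3000, L, seed = 21)
  r <- rotate(retain_factors(principal_factor_extract(correlation_matrix(X))),
              "varimax")
  pruned <- prune_crossloadings(r, cb)
  expect_equal(vapply(pruned$dropped_items, `[[`, "", "item"), "P4")
  expect_false("P4" %in% rownames(pruned$rotated))

  # clean structure: pruning is the identity
  X0 <- simulate_continuous(3000, marker_loadings(0.75), seed = 22)
  cb0 <- make_codebook()
  r0 <- rotate(retain_factors(principal_factor_extract(correlation_matrix(X0))),
               "varimax")
  p0 <- prune_crossloadings(r0, cb0)
  expect_length(p0$dropped_items, 0)
  expect_equal(p0$rotated, r0$rotated)
})

test_that("pruning refuses to shrink a construct below three items", {
  cb <- make_codebook()
  ids <- item_ids(cb)
  L <- matrix(0, 9, 3, dimnames = list(ids, NULL))
  L[paste0("P", 1:3), 1] <- 0.75
  L[paste0("H", 1:3), 2] <- 0.75
  L[paste0("C", 1:3), 3] <- 0.75
  L["P3", 2] <- 0.55    # cross-loader, but Provider has only 3 items
  X <- simulate_continuous(3000, L, seed = 23)
  r <- rotate(retain_factors(principal_factor_extract(correlation_matrix(X))),
              "varimax")
  expect_error(prune_crossloadings(r, cb), "fewer than 3|with 2 item")
})

test_that("factors are named by the construct owning their salient items", {
  fx <- reach_fixture(seed = 4)
  cb <- fx$codebook
  m <- rescale_responses(fx$responses, cb)
  r <- rotate(retain_factors(principal_factor_extract(correlation_matrix(m))),
              "varimax")
  r <- name_factors(prune_crossloadings(r, cb), cb)
  expect_setequal(unname(r$factor_names), c("Provider", "Healthcare", "Community"))
  sets <- factor_item_sets(r)
  expect_setequal(sets$Healthcare, c("H4", "H5", "H6"))
  expect_setequal(sets$Provider, c("P9", "P11", "P12"))
  expect_setequal(sets$Community, c("C1", "C4", "C5"))

  # a factor with no salient loading stays unnamed
  weak <- r
  weak$rotated <- r$rotated * 0.3
  weak2 <- name_factors(weak, cb)
  expect_true(all(is.na(weak2$factor_names)))
})

test_that("three-factor structure is recovered across seeds (continuous, lambda 0.7)", {
  L <- marker_loadings(0.7)
  hits <- 0L
  load_ok <- 0L
  for (s in 1:20) {
    X <- simulate_continuous(1000, L, seed = 100 + s)
    r <- tryCatch(retain_factors(principal_factor_extract(correlation_matrix(X))),
                  error = function(e) NULL, warning = function(w) NULL)
    if (is.null(r) || r$retained_k != 3L) next
    hits <- hits + 1L
    rv <- rotate(r, "varimax")
    A <- align_to_pattern(rv$rotated, L)
    if (max(abs(A - L)) < 0.15) load_ok <- load_ok + 1L
  }
  expect_gte(hits, 18L)
  expect_gte(load_ok, 18L)
})

test_that("scree and loadings exports carry the published table shapes", {
  fx <- reach_fixture(seed = 6)
  m <- rescale_responses(fx$responses, fx$codebook)
  r <- rotate(retain_factors(principal_factor_extract(correlation_matrix(m))),
              "varimax")
  sd_ <- scree_data(r)
  expect_equal(names(sd_), c("factor", "eigenvalue"))
  expect_equal(nrow(sd_), 25L)
  expect_equal(sd_$eigenvalue, r$eigenvalues)

  lt <- loadings_table(r, display_min = 0.4)
  expect_true(all(c("Variable", "Uniqueness") %in% names(lt)))
  shown <- suppressWarnings(as.numeric(as.matrix(lt[, 2:4])))
  expect_true(all(is.na(shown) | abs(shown) >= 0.4))
})
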