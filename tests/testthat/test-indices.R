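sc <- scale_spec()

test_that("the arithmetic index evaluates the printed formula verbatim", {
  # six indicators on the 1-3 scale
  expect_equal(arithmetic_construct_index(rep(3, 6), sc), 100 / 13)  # ~7.69
  expect_equal(arithmetic_construct_index(rep(1, 6), sc), 100)
  expect_equal(arithmetic_construct_index(rep(2, 6), sc), 700 / 13)  # ~53.85
  # published min/max after rounding: 8 and 100
  expect_equal(round(arithmetic_construct_index(rep(3, 6), sc)), 8)
  expect_equal(round(arithmetic_construct_index(rep(1, 6), sc)), 100)

  expect_error(arithmetic_construct_index(c(0, 2, 3), sc), "outside")
  expect_error(arithmetic_construct_index(c(2, 3), sc), "at least 3")
})

test_that("the index is strictly decreasing, permutation-invariant and hits 100 only at the minimum", {
  set.seed(31)
  for (rep_i in 1:20) {
    s <- sample(1:3, 6, replace = TRUE)
    base <- arithmetic_construct_index(s, sc)
    expect_equal(arithmetic_construct_index(sample(s), sc), base)
    j <- sample(6, 1)
    if (s[j] < 3) {
      s2 <- s; s2[j] <- s2[j] + 1L
      expect_lt(arithmetic_construct_index(s2, sc), base)
    }
    expect_identical(base == 100, all(s == 1))
  }
  # attainable endpoints for n = 6 on the 1-3 scale
  expect_equal(range(sapply(0:12, function(extra)
    arithmetic_construct_index(c(rep(1, 6)) + tabulate(rep(1:6, length.out = extra), 6), sc))),
    c(100 / 13, 100))
})

test_that("favorable_low orientation reflects the scores before the formula", {
  expect_equal(arithmetic_construct_index(rep(3, 6), sc, "favorable_low"), 100)
  expect_equal(arithmetic_construct_index(rep(1, 6), sc, "favorable_low"),
               100 / 13)
  s <- c(1, 2, 3, 3, 2, 1)
  expect_equal(arithmetic_construct_index(s, sc, "favorable_low"),
               arithmetic_construct_index(4 - s, sc))
})

test_that("the overall index is the mean of the three construct indices", {
  expect_equal(overall_index(100, 100, 100), 100)
  expect_equal(overall_index(100 / 13, 100 / 13, 100 / 13), 100 / 13)
  expect_equal(overall_index(30, 60, 90), 60)
  expect_true(is.na(overall_index(NA, 60, 90)))
})

test_that("factor-based indices use the retained three-item sets", {
  fx <- reach_fixture(seed = 4)
  m <- rescale_responses(fx$responses, fx$codebook)
  r <- rotate(retain_factors(principal_factor_extract(correlation_matrix(m))),
              "varimax")
  r <- name_factors(prune_crossloadings(r, fx$codebook), fx$codebook)
  ind <- acceptability_indices(m, r, method = "factor_based")
  expect_equal(ind$method, "factor_based")
  expect_equal(lengths(ind$item_sets), c(Provider = 3L, Healthcare = 3L,
                                         Community = 3L))
  # all-max / all-min respondents hit the 3-item endpoints 100/7 and 100
  m2 <- m
  m2$scores[1, ] <- 3L
  m2$scores[2, ] <- 1L
  ind2 <- acceptability_indices(m2, r, method = "factor_based")
  expect_equal(ind2$per_respondent$provider[1], 100 / 7)
  expect_equal(ind2$per_respondent$overall[1], 100 / 7)
  expect_equal(ind2$per_respondent$provider[2], 100)

  # permuting respondents permutes indices identically
  perm <- sample(nrow(m$scores))
  m3 <- m
  m3$scores <- m$scores[perm, ]
  ind3 <- acceptability_indices(m3, r, method = "factor_based")
  expect_equal(ind3$per_respondent$overall, ind$per_respondent$overall[perm])
})

test_that("arithmetic indices demand equal-sized constructs", {
  fx <- reach_fixture(seed = 4)
  m <- rescale_responses(fx$responses, fx$codebook)
  expect_error(acceptability_indices(m, method = "arithmetic"),
               "equal-sized")
  mn <- normalize_constructs(m, fx$codebook, 6)
  ind <- acceptability_indices(mn, method = "arithmetic")
  expect_equal(nrow(ind$per_respondent), 359L)
  expect_equal(ind$summary$obs, rep(359L, 4))
})

test_that("index summaries match a spreadsheet-style computation", {
  set.seed(9)
  per <- data.frame(provider = round(runif(10, 10, 90), 1),
                    healthcare = round(runif(10, 10, 90), 1),
                    community = round(runif(10, 10, 90), 1))
  per$overall <- (per$provider + per$healthcare + per$community) / 3
  per$overall[c(3, 7)] <- NA
  s <- index_summary(per)
  expect_equal(s$obs, c(10L, 10L, 10L, 8L))
  v <- per$provider
  expect_equal(s$mean[1], round(sum(v) / 10, 2))
  expect_equal(s$sd[1], round(sqrt(sum((v - mean(v))^2) / 9), 2))
  expect_equal(s$min[1], round(min(v)))
  expect_equal(s$max[1], round(max(v)))
  ov <- per$overall[!is.na(per$overall)]
  expect_equal(s$mean[4], round(mean(ov), 2))

  # degenerate cases
  one <- index_summary(data.frame(provider = 50, healthcare = 50,
                                  community = 50, overall = 50))
  expect_equal(one$sd, rep(0, 4))
  expect_equal(one$sd_flag, rep("single observation", 4))
  const <- index_summary(data.frame(provider = c(40, 40), healthcare = c(40, 40),
                                    community = c(40, 40), overall = c(40, 40)))
  expect_equal(const$sd, rep(0, 4))
})
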