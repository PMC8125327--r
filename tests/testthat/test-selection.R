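test_that("Kruskal-Wallis H and p match the closed form", {
  kw <- kruskal_wallis(list(c(1, 2, 3), c(4, 5, 6)))
  # rank sums 6 and 15: H = 12/(6*7) * (36/3 + 225/3) - 3*7 = 27/7
  expect_equal(kw$H, 27 / 7, tolerance = 1e-12)
  expect_equal(kw$p_value, pchisq(27 / 7, df = 1, lower.tail = FALSE),
               tolerance = 1e-12)
  expect_equal(round(kw$p_value, 4), 0.0495)
  expect_equal(kw$group_sizes, c(3L, 3L))
})

test_that("identical groups give H = 0, p = 1", {
  kw <- kruskal_wallis(list(c(2, 7, 7, 9), c(2, 7, 7, 9)))
  expect_equal(kw$H, 0, tolerance = 1e-12)
  expect_equal(kw$p_value, 1)
  # fully constant data (the all-ties degenerate case)
  kw0 <- kruskal_wallis(list(rep(4, 5), rep(4, 6)))
  expect_equal(kw0$H, 0)
  expect_equal(kw0$p_value, 1)
})

test_that("H agrees with the brute-force midrank oracle, with ties", {
  set.seed(77)
  for (i in 1:30) {
    k <- sample(2:4, 1)
    groups <- lapply(seq_len(k), function(j) {
      round(rnorm(sample(4:15, 1), mean = j * runif(1)), 1)  # discretized -> ties
    })
    if (length(unique(unlist(groups))) == 1L) next
    kw <- kruskal_wallis(groups)
    o <- oracle_kw(groups)
    expect_equal(kw$H, o$H, tolerance = 1e-10)
    expect_equal(kw$p_value, o$p, tolerance = 1e-10)
  }
})

test_that("invalid groupings are rejected", {
  expect_error(kruskal_wallis(list(1:3)), "2 groups")
  expect_error(kruskal_wallis(list(1:3, numeric(0))), "non-empty")
  expect_error(kruskal_wallis(list(1, 2)), ">= 3")
})

test_that("p-values are invariant under strictly increasing transforms", {
  set.seed(91)
  a <- rlnorm(20); b <- rlnorm(25, meanlog = 0.8)
  p1 <- kruskal_wallis(list(a, b))$p_value
  p2 <- kruskal_wallis(list(exp(a), exp(b)))$p_value
  p3 <- kruskal_wallis(list(sqrt(a), sqrt(b)))$p_value
  expect_equal(p1, p2, tolerance = 1e-12)
  expect_equal(p1, p3, tolerance = 1e-12)
})

test_that("feature ranking puts variance and std at identical p-values", {
  coh <- generate_cohort(10, seed = 55)
  ft <- build_feature_table(normalize_segments(segment_cohort(coh)))
  rk <- rank_features(ft, grouping = "two_class")
  expect_s3_class(rk, "stf_ranking")
  expect_equal(nrow(rk), 17L)
  expect_false(is.unsorted(rk$p_value))
  pv <- setNames(rk$p_value, rk$feature)
  # std is a strictly increasing transform of variance on positives
  expect_equal(pv[["variance"]], pv[["std"]], tolerance = 1e-12)
  # three-scenario grouping also runs
  rk3 <- rank_features(ft, grouping = "three_scenario")
  expect_equal(nrow(rk3), 17L)
})

test_that("selection honours alpha, top_k and the exclusion list", {
  rk <- data.frame(
    feature = c("variance", "std", "median", "smr", "kurtosis"),
    H = 5:1,
    p_value = c(1e-6, 1e-6, 2e-6, 3e-6, 0.4),
    stringsAsFactors = FALSE
  )
  expect_equal(select_features(rk, top_k = 2), c("variance", "std"))
  expect_equal(select_features(rk, top_k = 2, exclude = c("variance", "std")),
               c("median", "smr"))
  expect_equal(select_features(rk, alpha = 1, top_k = 10,
                               exclude = c("median", "smr")),
               c("variance", "std", "kurtosis"))
  expect_error(select_features(rk, alpha = 0), "alpha")
  # a constant feature column never passes: p = 1 >= any alpha < 1
  rk1 <- data.frame(feature = "mode", H = 0, p_value = 1)
  expect_error(select_features(rk1, alpha = 0.01), "alpha")
})
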