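test_that("hand-computed features of x = 1:4 reproduce exactly", {
  f <- extract_stf(c(1, 2, 3, 4))
  smr <- ((1 + sqrt(2) + sqrt(3) + 2) / 4)^2
  expect_equal(f[["mean"]], 2.5)
  expect_equal(f[["variance"]], 1.25)
  expect_equal(f[["std"]], sqrt(1.25))
  expect_equal(f[["rms"]], sqrt(7.5))
  expect_equal(f[["range"]], 3)
  expect_equal(f[["skewness"]], 0)
  expect_equal(f[["moment5"]], 0)
  expect_equal(f[["kurtosis"]], 10.25 / (4 * 56.25))
  expect_equal(f[["moment6"]], (22.8125 / 4) / 7.5^3)
  expect_equal(f[["impulse_factor"]], 1.6)
  expect_equal(f[["crest_factor"]], 4 / sqrt(7.5))
  expect_equal(f[["smr"]], smr)
  expect_equal(f[["sf_rms"]], sqrt(7.5) / 2.5)
  expect_equal(f[["sf_smr"]], smr / 2.5)
  expect_equal(f[["latitude_factor"]], 4 / smr)
  expect_equal(f[["median"]], 2.5)
})

test_that("grouped mode interpolates by neighbour count differences", {
  # counts (2, 10, 6) over bins of width 1 starting at 0; modal class
  # [1, 2): d- = 8, d+ = 4 -> 1 + 8/12
  x <- c(0, 0.8,
         seq(1.05, 1.95, length.out = 10),
         seq(2.05, 2.95, length.out = 5), 3)
  expect_equal(grouped_mode(x, bins = 3), 1 + 8 / 12)
  # all mass in the middle bin, empty flanks: midpoint fallback
  y <- c(0, rep(1.5, 10), 3)
  expect_equal(grouped_mode(y, bins = 3), 1.5)
  # constant sample: the constant itself
  expect_equal(grouped_mode(rep(2.2, 50)), 2.2)
})

test_that("implementation matches the literal-transcription oracle", {
  set.seed(404)
  for (i in 1:25) {
    n <- sample(50:500, 1)
    x <- switch(1 + i %% 3,
                rnorm(n), rlnorm(n), round(rt(n, df = 3), 2))
    f <- extract_stf(x)
    o <- oracle_stf(x)
    expect_equal(f, o, tolerance = 1e-12)
  }
})

test_that("degenerate windows are rejected", {
  expect_error(extract_stf(numeric(0)), "samples")
  expect_error(extract_stf(5), "samples")
  expect_error(extract_stf(rep(0, 100)), "all-zero")
})

test_that("shape and moment features are scale-invariant", {
  set.seed(11)
  x <- rnorm(300)
  a <- 17.3
  inv <- c("impulse_factor", "sf_smr", "sf_rms", "crest_factor",
           "latitude_factor", "skewness", "kurtosis", "moment5", "moment6")
  expect_equal(extract_stf(a * x)[inv], extract_stf(x)[inv],
               tolerance = 1e-10)
})

test_that("RMS-normalized moments relate to conventional ones by (std/rms) powers", {
  set.seed(12)
  x <- rlnorm(400)
  f <- extract_stf(x)
  m <- mean(x)
  sk_conv <- mean((x - m)^3) / f[["std"]]^3
  ku_conv <- mean((x - m)^4) / f[["std"]]^4
  r <- f[["std"]] / f[["rms"]]
  expect_equal(f[["skewness"]], sk_conv * r^3, tolerance = 1e-12)
  expect_equal(f[["kurtosis"]], ku_conv * r^4, tolerance = 1e-12)
  expect_equal(f[["std"]]^2, f[["variance"]], tolerance = 1e-14)
})

test_that("feature tables have one row and 17 values per segment", {
  coh <- generate_cohort(1, seed = 30)
  segs <- normalize_segments(segment_cohort(coh))
  ft <- build_feature_table(segs)
  expect_equal(nrow(ft), 5L)
  expect_equal(sum(names(ft) %in% stf_names), 17L)
  expect_equal(names(ft)[-(1:4)], stf_names)
  ft1 <- build_feature_table(segs[1])
  expect_equal(nrow(ft1) * 17, 17)
  # CSV round-trip
  f <- tempfile(fileext = ".csv")
  write_feature_table(ft, f)
  ft2 <- read_feature_table(f)
  expect_equal(as.matrix(ft2[, stf_names]), as.matrix(ft[, stf_names]),
               tolerance = 1e-12)
  unlink(f)
})
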