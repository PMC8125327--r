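# deterministic 2-D two-cluster toy, well separated
toy_data <- function(n_per = 25, gap = 10, seed = 123) {
  set.seed(seed)
  X <- rbind(matrix(rnorm(2 * n_per), ncol = 2),
             matrix(rnorm(2 * n_per, mean = gap), ncol = 2))
  y <- rep(c("NSC", "SC"), each = n_per)
  list(X = X, y = y)
}

test_that("kernel functions evaluate their closed forms", {
  expect_equal(make_kernel(kernel_spec("linear", 2))(c(1, 2), c(3, 4)), 11)
  expect_equal(make_kernel(kernel_spec("quadratic", 2))(c(1, 2), c(3, 4)),
               144)
  expect_equal(make_kernel(kernel_spec("cubic", 2))(c(1, 0), c(1, 0)), 8)
  g <- make_kernel(kernel_spec("gaussian", 2))
  expect_equal(g(c(0.3, -2), c(0.3, -2)), 1)
  expect_equal(g(c(0, 0), c(1, 0)), exp(-1 / 2))  # medium scale sqrt(2)
})

test_that("gaussian scale presets follow the fine/medium/coarse convention", {
  P <- 2
  expect_equal(kernel_spec("gaussian", P, preset = "fine")$scale, sqrt(P) / 4)
  expect_equal(kernel_spec("gaussian", P, preset = "medium")$scale, sqrt(P))
  expect_equal(kernel_spec("gaussian", P, preset = "coarse")$scale, 4 * sqrt(P))
  expect_equal(kernel_spec("gaussian", P, preset = "coarse",
                           literal = TRUE)$scale, 4 * P)
  expect_length(default_kernels(2), 6L)
})

test_that("the SVM separates a linearly separable toy exactly", {
  d <- toy_data()
  fit <- train_svm(d$X, d$y, kernel_spec("linear", 2))
  out <- decision_values(fit, d$X)
  expect_equal(as.character(out$label), d$y)
  expect_true(all(out$decision[d$y == "SC"] > 0))
  expect_true(all(out$decision[d$y == "NSC"] < 0))
})

test_that("SVM decision function is reproducible from the dual solution", {
  d <- toy_data(gap = 3)
  for (fam in c("linear", "cubic", "gaussian")) {
    spec <- kernel_spec(fam, 2)
    fit <- train_svm(d$X, d$y, spec)
    K <- make_kernel(spec)
    sv <- fit$fit$SV
    coefs <- as.numeric(fit$fit$coefs)
    manual <- vapply(seq_len(nrow(d$X)), function(i) {
      sum(coefs * vapply(seq_len(nrow(sv)), function(j) {
        K(sv[j, ], d$X[i, ])
      }, numeric(1))) - fit$fit$rho
    }, numeric(1))
    if (fit$flip) manual <- -manual
    dv <- decision_values(fit, d$X)$decision
    expect_equal(manual, dv, tolerance = 1e-8)
  }
})

test_that("free support vectors sit on the margin (KKT)", {
  d <- toy_data(gap = 2, seed = 7)
  fit <- train_svm(d$X, d$y, kernel_spec("linear", 2), box_constraint = 1)
  # decision values at the support vectors, from the stored model
  sv_dv <- decision_values(fit, fit$fit$SV)$decision
  free <- abs(as.numeric(fit$fit$coefs)) < 1 - 1e-8
  expect_gt(sum(free), 0)
  expect_true(all(abs(abs(sv_dv[free]) - 1) < 1e-4))
})

test_that("single-class training data is rejected", {
  X <- matrix(rnorm(20), ncol = 2)
  expect_error(train_svm(X, rep("SC", 10), kernel_spec("linear", 2)),
               "both classes")
  expect_error(train_mlp(X, rep("NSC", 10)), "both classes")
})

test_that("confusion metrics evaluate their formulas", {
  m <- confusion_metrics(40, 0, 9, 1)
  expect_equal(m$accuracy, 98)
  expect_equal(m$sensitivity, 100)
  expect_equal(m$specificity, 90)
})

test_that("stratified folds validate each sample once with balanced classes", {
  y <- rep(c("NSC", "SC"), c(10, 40))
  folds <- make_folds(y, 10, seed = 3)
  expect_equal(sort(unique(folds)), 1:10)
  expect_equal(unname(table(folds)), rep(5L, 10), ignore_attr = TRUE)
  for (f in 1:10) {
    expect_equal(sum(y[folds == f] == "NSC"), 1L)
  }
  expect_error(make_folds(y, 11, seed = 1), "smallest class")
})

test_that("cross-validation is perfect on separable data and deterministic", {
  d <- toy_data()
  rep1 <- crossvalidate(d$X, d$y, kernel_spec("cubic", 2), folds = 10,
                        seed = 42)
  rep2 <- crossvalidate(d$X, d$y, kernel_spec("cubic", 2), folds = 10,
                        seed = 42)
  expect_equal(rep1$accuracy, 100)
  expect_equal(rep1$auc, 1)
  expect_identical(rep1$decision, rep2$decision)
  expect_equal(rep1$accuracy,
               with(rep1, 100 * (TP + TN) / (TP + TN + FP + FN)))
})

test_that("pooled AUC matches the rank formula and is monotone-invariant", {
  d <- toy_data(gap = 1.5, seed = 9)
  rep1 <- crossvalidate(d$X, d$y, kernel_spec("linear", 2), folds = 5,
                        seed = 10)
  expect_equal(rep1$auc, oracle_auc(rep1$decision, d$y), tolerance = 1e-12)
  # AUC depends on decision values only through their ranks
  expect_equal(oracle_auc(tanh(rep1$decision / 3), d$y), rep1$auc,
               tolerance = 1e-12)
})

test_that("the MLP is deterministic, fits separable data, and degrades to majority", {
  d <- toy_data(n_per = 20)
  m1 <- train_mlp(d$X, d$y, seed = 5)
  m2 <- train_mlp(d$X, d$y, seed = 5)
  expect_identical(m1$W1, m2$W1)
  expect_identical(m1$W2, m2$W2)
  rep1 <- crossvalidate(d$X, d$y, mlp_spec(), folds = 5, seed = 6)
  expect_gte(rep1$accuracy, 95)
  # constant features carry no information: majority-class accuracy
  Xc <- matrix(1, 50, 2)
  yc <- rep(c("NSC", "SC"), c(10, 40))
  repc <- crossvalidate(Xc, yc, mlp_spec(), folds = 5, seed = 7,
                        standardize = FALSE)
  expect_equal(repc$accuracy, 80)
})
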