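#' Kernel specification for the SVM
#'
#' The six classifier configurations compared in the study: linear,
#' quadratic and cubic polynomial kernels, and Gaussian (RBF) kernels
#' at three bandwidth presets derived from the predictor count P --
#' fine `sqrt(P)/4`, medium `sqrt(P)`, coarse `4*sqrt(P)`. With
#' `literal = TRUE` the presets become `P/4`, `P`, `4P` instead.
#'
#' @param family One of `"linear"`, `"quadratic"`, `"cubic"`,
#'   `"gaussian"`.
#' @param P Number of predictors (columns of the design matrix).
#' @param preset Gaussian bandwidth preset: `"fine"`, `"medium"`,
#'   `"coarse"`; ignored for non-Gaussian families.
#' @param scale Explicit Gaussian bandwidth, overriding the preset.
#' @param literal Use the literal `P/4, P, 4P` scale convention.
#' @return An object of class `kernel_spec`.
#' @export
kernel_spec <- function(family = c("linear", "quadratic", "cubic", "gaussian"),
                        P = 2, preset = c("medium", "fine", "coarse"),
                        scale = NULL, literal = FALSE) {
  family <- match.arg(family)
  preset <- match.arg(preset)
  if (P < 1) stop("`P` must be >= 1", call. = FALSE)
  if (family == "gaussian" && is.null(scale)) {
    base <- if (literal) P else sqrt(P)
    scale <- switch(preset, fine = base / 4, medium = base, coarse = 4 * base)
  }
  if (family == "gaussian" && scale <= 0) {
    stop("gaussian `scale` must be > 0", call. = FALSE)
  }
  structure(list(family = family, P = P, preset = preset, scale = scale),
            class = "kernel_spec")
}

#' The six study kernels for a given predictor count
#'
#' @param P Number of predictors.
#' @param literal Passed to [kernel_spec()].
#' @return A named list of six `kernel_spec`s.
#' @export
default_kernels <- function(P = 2, literal = FALSE) {
  list(
    linear = kernel_spec("linear", P),
    quadratic = kernel_spec("quadratic", P),
    cubic = kernel_spec("cubic", P),
    fine_gaussian = kernel_spec("gaussian", P, preset = "fine", literal = literal),
    medium_gaussian = kernel_spec("gaussian", P, preset = "medium", literal = literal),
    coarse_gaussian = kernel_spec("gaussian", P, preset = "coarse", literal = literal)
  )
}

#' Materialize a kernel function K(u, v)
#'
#' Linear `u . v`; polynomial `(1 + u . v)^d` with d = 2 (quadratic) or
#' 3 (cubic); Gaussian `exp(-||u - v||^2 / scale^2)`.
#'
#' @param spec A `kernel_spec`.
#' @return A function of two numeric vectors.
#' @export
make_kernel <- function(spec) {
  stopifnot(inherits(spec, "kernel_spec"))
  switch(spec$family,
    linear = function(u, v) sum(u * v),
    quadratic = function(u, v) (1 + sum(u * v))^2,
    cubic = function(u, v) (1 + sum(u * v))^3,
    gaussian = {
      s2 <- spec$scale^2
      function(u, v) exp(-sum((u - v)^2) / s2)
    }
  )
}

as_label_factor <- function(y) {
  y <- factor(as.character(y), levels = c("NSC", "SC"))
  if (anyNA(y)) stop("labels must be 'NSC' or 'SC'", call. = FALSE)
  y
}

#' Train a support vector machine
#'
#' Soft-margin binary SVM on the selected features, solved to KKT
#' optimality by the libsvm dual solver (via \pkg{e1071}) with the
#' kernel mapped from `spec`. Inputs are used as-is (standardize before
#' calling, or let [crossvalidate()] do it fold-wise).
#'
#' @param X Numeric matrix, one row per segment, `ncol(X) == spec$P`.
#' @param y Labels, `"NSC"`/`"SC"`.
#' @param spec A [kernel_spec()].
#' @param box_constraint Soft-margin cost C (default 1); every dual
#'   coefficient satisfies `|alpha_i| <= C`.
#' @param tolerance Dual termination tolerance (default 1e-6).
#' @return A `trained_svm` with the e1071 fit, the spec, and a
#'   decision-value orientation such that positive values favour `SC`.
#' @export
train_svm <- function(X, y, spec, box_constraint = 1, tolerance = 1e-6) {
  X <- as.matrix(X)
  y <- as_label_factor(y)
  if (nlevels(droplevels(y)) < 2L) {
    stop("training data must contain both classes", call. = FALSE)
  }
  stopifnot(inherits(spec, "kernel_spec"))
  if (ncol(X) != spec$P) stop("ncol(X) must equal spec$P", call. = FALSE)
  args <- switch(spec$family,
    linear = list(kernel = "linear"),
    quadratic = list(kernel = "polynomial", degree = 2, gamma = 1, coef0 = 1),
    cubic = list(kernel = "polynomial", degree = 3, gamma = 1, coef0 = 1),
    gaussian = list(kernel = "radial", gamma = 1 / spec$scale^2)
  )
  fit <- do.call(e1071::svm, c(list(
    x = X, y = y, type = "C-classification", cost = box_constraint,
    scale = FALSE, tolerance = tolerance
  ), args))
  # libsvm's positive class in the decision values is named first in
  # the "A/B" column label; flip so that positive always means SC
  dv_name <- colnames(fit$decision.values)[1]
  flip <- !identical(strsplit(dv_name, "/")[[1]][1], "SC")
  structure(list(fit = fit, spec = spec, flip = flip,
                 box_constraint = box_constraint),
            class = "trained_svm")
}

#' Decision values and predicted labels
#'
#' @param model A `trained_svm` or `trained_mlp`.
#' @param X Matrix of inputs on the training scale.
#' @return A list with `label` (factor NSC/SC) and `decision` (numeric,
#'   positive favours SC).
#' @export
decision_values <- function(model, X) UseMethod("decision_values")

#' @export
decision_values.trained_svm <- function(model, X) {
  X <- as.matrix(X)
  pred <- predict(model$fit, X, decision.values = TRUE)
  dv <- as.numeric(attr(pred, "decision.values"))
  if (model$flip) dv <- -dv
  list(label = factor(as.character(pred), levels = c("NSC", "SC")),
       decision = dv)
}

#' Multilayer perceptron specification (for cross-validation)
#'
#' @param hidden Hidden-layer width (default 10).
#' @param max_epochs Maximum damped Gauss-Newton iterations.
#' @return An object of class `mlp_spec`.
#' @export
mlp_spec <- function(hidden = 10, max_epochs = 200) {
  structure(list(hidden = hidden, max_epochs = max_epochs), class = "mlp_spec")
}

mlp_unpack <- function(theta, p, h, o) {
  i <- 0L
  W1 <- matrix(theta[i + seq_len(h * p)], h, p); i <- i + h * p
  b1 <- theta[i + seq_len(h)]; i <- i + h
  W2 <- matrix(theta[i + seq_len(o * h)], o, h); i <- i + o * h
  b2 <- theta[i + seq_len(o)]
  list(W1 = W1, b1 = b1, W2 = W2, b2 = b2)
}

mlp_forward <- function(w, X) {
  H <- tanh(sweep(X %*% t(w$W1), 2, w$b1, "+"))
  O <- sweep(H %*% t(w$W2), 2, w$b2, "+")
  list(H = H, O = O)
}

mlp_jacobian <- function(w, X, H) {
  n <- nrow(X); p <- ncol(X); h <- ncol(H); o <- nrow(w$W2)
  nw <- h * p + h + o * h + o
  sech2 <- 1 - H^2
  J <- matrix(0, n * o, nw)
  for (k in seq_len(o)) {
    rows <- (k - 1L) * n + seq_len(n)
    # W1[j, m] block (column-major over j then m)
    for (m in seq_len(p)) {
      cols <- (m - 1L) * h + seq_len(h)
      J[rows, cols] <- sech2 * matrix(w$W2[k, ], n, h, byrow = TRUE) * X[, m]
    }
    # b1
    J[rows, h * p + seq_len(h)] <- sech2 * matrix(w$W2[k, ], n, h, byrow = TRUE)
    # W2[k, j]: parameter index h*p + h + (j-1)*o + k
    J[rows, h * p + h + (seq_len(h) - 1L) * o + k] <- H
    # b2[k]
    J[rows, h * p + h + o * h + k] <- 1
  }
  J
}

#' Train the MLP comparator
#'
#' A 2-layer perceptron with `hidden` tanh (bipolar sigmoid) units and
#' two linear output units (one per class, targets +/-1), trained by a
#' damped Gauss-Newton (Levenberg-Marquardt) least-squares scheme with
#' analytic Jacobian: damping starts at 1e-3 and is divided/multiplied
#' by 10 on accepted/rejected steps. The predicted class is the argmax
#' of the two outputs; the decision value is `output_SC - output_NSC`.
#' Weight initialization is seeded, so training is deterministic.
#'
#' @param X Numeric matrix of inputs.
#' @param y Labels `"NSC"`/`"SC"`.
#' @param hidden Hidden-layer width (default 10).
#' @param seed Integer seed for weight initialization.
#' @param max_epochs Maximum outer iterations (default 200).
#' @return A `trained_mlp` with the weight matrices.
#' @export
train_mlp <- function(X, y, hidden = 10, seed = 1L, max_epochs = 200) {
  X <- as.matrix(X)
  y <- as_label_factor(y)
  if (nlevels(droplevels(y)) < 2L) {
    stop("training data must contain both classes", call. = FALSE)
  }
  n <- nrow(X); p <- ncol(X); h <- hidden; o <- 2L
  targets <- matrix(-1, n, o)
  targets[cbind(seq_len(n), as.integer(y))] <- 1
  nw <- h * p + h + o * h + o
  theta <- with_seed(seed, rnorm(nw, sd = 0.5))

  sse_of <- function(th) {
    w <- mlp_unpack(th, p, h, o)
    fw <- mlp_forward(w, X)
    r <- as.vector(fw$O - targets)
    list(w = w, fw = fw, r = r, sse = sum(r^2))
  }
  cur <- sse_of(theta)
  lambda <- 1e-3
  for (epoch in seq_len(max_epochs)) {
    J <- mlp_jacobian(cur$w, X, cur$fw$H)
    g <- crossprod(J, cur$r)
    JtJ <- crossprod(J)
    improved <- FALSE
    while (lambda <= 1e10) {
      delta <- tryCatch(solve(JtJ + lambda * diag(nw), g), error = function(e) NULL)
      if (!is.null(delta)) {
        cand <- sse_of(theta - as.vector(delta))
        if (cand$sse < cur$sse) {
          theta <- theta - as.vector(delta)
          gain <- cur$sse - cand$sse
          cur <- cand
          lambda <- max(lambda / 10, 1e-12)
          improved <- TRUE
          if (gain < 1e-12) improved <- FALSE  # converged
          break
        }
      }
      lambda <- lambda * 10
    }
    if (!improved) break
  }
  w <- cur$w
  structure(list(W1 = w$W1, b1 = w$b1, W2 = w$W2, b2 = w$b2,
                 levels = levels(y), sse = cur$sse),
            class = "trained_mlp")
}

#' @export
decision_values.trained_mlp <- function(model, X) {
  fw <- mlp_forward(model, as.matrix(X))
  cls <- model$levels[max.col(fw$O, ties.method = "first")]
  list(label = factor(cls, levels = c("NSC", "SC")),
       decision = fw$O[, 2] - fw$O[, 1])
}

fit_classifier <- function(model, X, y, seed = 1L, box_constraint = 1) {
  if (inherits(model, "kernel_spec")) {
    train_svm(X, y, model, box_constraint = box_constraint)
  } else if (inherits(model, "mlp_spec")) {
    train_mlp(X, y, hidden = model$hidden, seed = seed,
              max_epochs = model$max_epochs)
  } else {
    stop("unknown classifier specification", call. = FALSE)
  }
}

#' Stratified, seeded k-fold assignment
#'
#' @param y Label vector.
#' @param k Number of folds.
#' @param seed Integer seed for the shuffle.
#' @param stratified Keep fold class proportions within one sample of
#'   the global proportions (default TRUE).
#' @return Integer vector of fold ids in 1..k, one per sample.
#' @export
make_folds <- function(y, k = 10, seed = 1L, stratified = TRUE) {
  y <- as.factor(y)
  n <- length(y)
  if (k < 2) stop("`k` must be >= 2", call. = FALSE)
  if (stratified && k > min(table(y))) {
    stop("`k` exceeds the smallest class size; cannot stratify", call. = FALSE)
  }
  if (!stratified && k > n) stop("`k` exceeds the sample size", call. = FALSE)
  folds <- integer(n)
  with_seed(seed, {
    if (stratified) {
      for (lv in levels(y)) {
        idx <- sample(which(y == lv))
        folds[idx] <- rep_len(seq_len(k), length(idx))
      }
    } else {
      folds[sample.int(n)] <- rep_len(seq_len(k), n)
    }
  })
  folds
}

#' Cross-validate a classifier configuration
#'
#' Stratified k-fold cross-validation with seeded shuffling: each
#' sample is validated exactly once, per-fold confusion counts are
#' accumulated, and the overall accuracy, sensitivity (true-positive
#' rate on the stress class SC), specificity (true-negative rate on
#' rest) and AUC are computed from the pooled out-of-fold predictions.
#' AUC uses the rank (trapezoidal) method on the pooled decision
#' values. Features are standardized with each training fold's mean and
#' standard deviation before fitting, so the two inputs (variance and
#' standard deviation of the normalized window) contribute comparably
#' to the kernel.
#'
#' @param X Numeric feature matrix (rows = segments).
#' @param y Labels `"NSC"`/`"SC"`.
#' @param model A [kernel_spec()] or [mlp_spec()].
#' @param folds Number of folds k (default 10).
#' @param seed Integer seed for fold shuffling (and MLP init).
#' @param stratified Stratify folds by class (default TRUE).
#' @param standardize Fold-wise z-scoring of the columns (default TRUE).
#' @param box_constraint SVM soft-margin cost.
#' @return A `cv_report`: list with `fold_confusion` (data frame of
#'   per-fold TP/FN/TN/FP and accuracy), totals, `accuracy`,
#'   `sensitivity`, `specificity` (percent), `auc`, and the pooled
#'   decision values.
#' @export
crossvalidate <- function(X, y, model, folds = 10, seed = 1L,
                          stratified = TRUE, standardize = TRUE,
                          box_constraint = 1) {
  X <- as.matrix(X)
  y <- as_label_factor(y)
  fold_id <- make_folds(y, folds, seed = seed, stratified = stratified)
  fold_seeds <- derive_seeds(seed, folds)
  pooled_dv <- numeric(length(y))
  pooled_label <- character(length(y))
  per_fold <- vector("list", folds)
  for (f in seq_len(folds)) {
    tr <- fold_id != f
    te <- !tr
    Xtr <- X[tr, , drop = FALSE]; Xte <- X[te, , drop = FALSE]
    if (standardize) {
      mu <- colMeans(Xtr)
      sg <- apply(Xtr, 2, sd)
      sg[sg == 0] <- 1
      Xtr <- sweep(sweep(Xtr, 2, mu), 2, sg, "/")
      Xte <- sweep(sweep(Xte, 2, mu), 2, sg, "/")
    }
    fit <- fit_classifier(model, Xtr, y[tr], seed = fold_seeds[f],
                          box_constraint = box_constraint)
    out <- decision_values(fit, Xte)
    pooled_dv[te] <- out$decision
    pooled_label[te] <- as.character(out$label)
    tp <- sum(out$label == "SC" & y[te] == "SC")
    fn <- sum(out$label == "NSC" & y[te] == "SC")
    tn <- sum(out$label == "NSC" & y[te] == "NSC")
    fp <- sum(out$label == "SC" & y[te] == "NSC")
    per_fold[[f]] <- data.frame(fold = f, TP = tp, FN = fn, TN = tn, FP = fp,
                                accuracy = 100 * (tp + tn) / sum(te))
  }
  fold_df <- do.call(rbind, per_fold)
  tot <- colSums(fold_df[, c("TP", "FN", "TN", "FP")])
  auc <- as.numeric(pROC::auc(pROC::roc(
    response = y, predictor = pooled_dv,
    levels = c("NSC", "SC"), direction = "<", quiet = TRUE
  )))
  structure(c(
    list(fold_confusion = fold_df, decision = pooled_dv,
         predicted = factor(pooled_label, levels = c("NSC", "SC")),
         auc = auc, folds = folds, seed = seed),
    confusion_metrics(tot[["TP"]], tot[["FN"]], tot[["TN"]], tot[["FP"]])
  ), class = "cv_report")
}

#' Confusion-matrix metrics
#'
#' Accuracy, sensitivity (TP rate on the stress class) and specificity
#' (TN rate on rest), in percent.
#'
#' @param tp,fn,tn,fp Confusion counts with SC as the positive class.
#' @return List with `TP`, `FN`, `TN`, `FP`, `accuracy`, `sensitivity`,
#'   `specificity`.
#' @export
confusion_metrics <- function(tp, fn, tn, fp) {
  list(TP = tp, FN = fn, TN = tn, FP = fp,
       accuracy = 100 * (tp + tn) / (tp + fn + tn + fp),
       sensitivity = 100 * tp / (tp + fn),
       specificity = 100 * tn / (tn + fp))
}

#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf(
    "%d-fold CV: accuracy %.1f%%, sensitivity %.1f%%, specificity %.1f%%, AUC %.3f\n",
    x$folds, x$accuracy, x$sensitivity, x$specificity, x$auc))
  invisible(x)
}
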