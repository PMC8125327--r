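#' Configuration for the end-to-end stress-detection study
#'
#' @param n_subjects Cohort size (default 10).
#' @param seed Master seed driving cohort generation, fold shuffling
#'   and MLP initialization.
#' @param model A [stress_model()].
#' @param window_minutes Window lengths (minutes) for the
#'   window-length study; default 1..5.
#' @param kernels Named list of [kernel_spec()]s; default the six study
#'   kernels via [default_kernels()] (P taken from `top_k`).
#' @param alpha Kruskal-Wallis significance threshold (default 0.01).
#' @param top_k Number of features selected (default 2).
#' @param exclude Features barred from selection; by default the
#'   median and SMR, whose between-condition overlap makes them poor
#'   classifier inputs despite small p-values.
#' @param folds CV folds (default 10).
#' @param normalization `"rest_baseline"` or `"self"`.
#' @param box_constraint SVM soft-margin cost.
#' @param fs Sampling frequency (Hz).
#' @param cohort_dir Optional directory of recording/annotation CSV
#'   pairs to analyse instead of a synthetic cohort.
#' @return A `study_config` list.
#' @export
study_config <- function(n_subjects = 10, seed = 1L, model = stress_model(),
                         window_minutes = 1:5, kernels = NULL, alpha = 0.01,
                         top_k = 2, exclude = c("median", "smr"), folds = 10,
                         normalization = c("rest_baseline", "self"),
                         box_constraint = 1, fs = 15.5, cohort_dir = NULL) {
  normalization <- match.arg(normalization)
  if (any(window_minutes <= 0) || any(window_minutes > 5)) {
    stop("window lengths must lie in (0, 5] minutes", call. = FALSE)
  }
  if (folds < 2) stop("`folds` must be >= 2", call. = FALSE)
  if (is.null(kernels)) kernels <- default_kernels(P = top_k)
  structure(
    list(n_subjects = n_subjects, seed = as.integer(seed), model = model,
         window_minutes = sort(window_minutes), kernels = kernels,
         alpha = alpha, top_k = top_k, exclude = exclude, folds = folds,
         normalization = normalization, box_constraint = box_constraint,
         fs = fs, cohort_dir = cohort_dir),
    class = "study_config"
  )
}

load_cohort_dir <- function(dir) {
  rec_files <- sort(list.files(dir, pattern = "_recording\\.csv$",
                               full.names = TRUE))
  if (length(rec_files) == 0L) stop("no *_recording.csv files in ", dir,
                                    call. = FALSE)
  lapply(rec_files, function(f) {
    ann_f <- sub("_recording\\.csv$", "_annotation.csv", f)
    list(recording = read_recording(f), annotation = read_annotations(ann_f))
  })
}

study_cohort <- function(cfg) {
  if (!is.null(cfg$cohort_dir)) {
    load_cohort_dir(cfg$cohort_dir)
  } else {
    generate_cohort(cfg$n_subjects, cfg$model, seed = cfg$seed, fs = cfg$fs)
  }
}

# segment at `minutes`, normalize per config, return feature table
study_features <- function(cohort, minutes, cfg) {
  segs <- segment_cohort(cohort, window_minutes = max(cfg$window_minutes))
  segs <- lapply(segs, truncate_segment, minutes = minutes)
  segs <- normalize_segments(segs, method = cfg$normalization)
  build_feature_table(segs)
}

#' Run the full driver-stress study
#'
#' Generates (or loads) the cohort, extracts and normalizes the
#' analysis windows, computes the 17-feature table, ranks features with
#' the Kruskal-Wallis test (NSC vs SC), selects the discriminant
#' features at the full window length, then cross-validates every
#' kernel at every window length and compares the best SVM against the
#' MLP. All stages are deterministic given `cfg$seed`.
#'
#' @param cfg A [study_config()].
#' @param out_dir Optional directory; when given, the feature tables
#'   per window length, the p-value ranking, the selection, the
#'   accuracy matrix, the classifier comparison and a JSON report are
#'   written there.
#' @return A `study_report` list: `pvalues` (ranked Kruskal-Wallis
#'   table), `selected` (feature names), `accuracy` (kernel x length
#'   matrix, percent), `comparison` (SVM vs MLP accuracy/AUC),
#'   `best_kernel`, `reports` (per-kernel `cv_report`s at the full
#'   length), `feature_table` (full-length), and the config.
#' @export
run_study <- function(cfg, out_dir = NULL) {
  stopifnot(inherits(cfg, "study_config"))
  cohort <- study_cohort(cfg)
  max_len <- max(cfg$window_minutes)

  ft_full <- study_features(cohort, max_len, cfg)
  ranking <- rank_features(ft_full, grouping = "two_class")
  selected <- select_features(ranking, alpha = cfg$alpha, top_k = cfg$top_k,
                              exclude = cfg$exclude)

  n_k <- length(cfg$kernels); n_l <- length(cfg$window_minutes)
  cv_seeds <- matrix(derive_seeds(cfg$seed, n_k * n_l + 1L)[-1], n_k, n_l)
  acc <- matrix(NA_real_, n_k, n_l,
                dimnames = list(names(cfg$kernels),
                                paste0(cfg$window_minutes, "min")))
  reports <- list()
  tables <- list()
  for (j in seq_len(n_l)) {
    len <- cfg$window_minutes[j]
    ft <- if (len == max_len) ft_full else study_features(cohort, len, cfg)
    tables[[paste0(len, "min")]] <- ft
    X <- as.matrix(ft[, selected, drop = FALSE])
    y <- ft$label
    for (i in seq_len(n_k)) {
      rep_ij <- crossvalidate(X, y, cfg$kernels[[i]], folds = cfg$folds,
                              seed = cv_seeds[i, j],
                              box_constraint = cfg$box_constraint)
      acc[i, j] <- rep_ij$accuracy
      if (len == max_len) reports[[names(cfg$kernels)[i]]] <- rep_ij
    }
  }

  best_kernel <- names(cfg$kernels)[which.max(acc[, n_l])]
  comparison <- compare_fitted(ft_full, selected, cfg, best_kernel)

  report <- structure(
    list(pvalues = ranking, selected = selected, accuracy = acc,
         comparison = comparison, best_kernel = best_kernel,
         reports = reports, feature_table = ft_full, config = cfg),
    class = "study_report"
  )
  if (!is.null(out_dir)) write_study_report(report, tables, out_dir)
  report
}

compare_fitted <- function(ft, selected, cfg, best_kernel) {
  X <- as.matrix(ft[, selected, drop = FALSE])
  y <- ft$label
  seeds <- derive_seeds(cfg$seed + 1L, 2L)
  svm_rep <- crossvalidate(X, y, cfg$kernels[[best_kernel]], folds = cfg$folds,
                           seed = seeds[1], box_constraint = cfg$box_constraint)
  mlp_rep <- crossvalidate(X, y, mlp_spec(hidden = 10), folds = cfg$folds,
                           seed = seeds[2])
  data.frame(
    classifier = c(paste0("SVM (", best_kernel, ")"), "MLP"),
    accuracy = c(svm_rep$accuracy, mlp_rep$accuracy),
    auc = c(svm_rep$auc, mlp_rep$auc),
    sensitivity = c(svm_rep$sensitivity, mlp_rep$sensitivity),
    specificity = c(svm_rep$specificity, mlp_rep$specificity),
    stringsAsFactors = FALSE
  )
}

#' Cross-validated SVM-vs-MLP comparison
#'
#' Runs the pipeline at the full window length and reports accuracy,
#' AUC, sensitivity and specificity for the best SVM kernel and the
#' 2-10-2 MLP under the same stratified folds scheme.
#'
#' @param cfg A [study_config()].
#' @return A data frame with one row per classifier.
#' @export
compare_classifiers <- function(cfg) {
  stopifnot(inherits(cfg, "study_config"))
  cohort <- study_cohort(cfg)
  ft <- study_features(cohort, max(cfg$window_minutes), cfg)
  ranking <- rank_features(ft, grouping = "two_class")
  selected <- select_features(ranking, alpha = cfg$alpha, top_k = cfg$top_k,
                              exclude = cfg$exclude)
  # pick the best kernel by full-length CV accuracy
  X <- as.matrix(ft[, selected, drop = FALSE])
  seeds <- derive_seeds(cfg$seed, length(cfg$kernels))
  accs <- vapply(seq_along(cfg$kernels), function(i) {
    crossvalidate(X, ft$label, cfg$kernels[[i]], folds = cfg$folds,
                  seed = seeds[i], box_constraint = cfg$box_constraint)$accuracy
  }, numeric(1))
  compare_fitted(ft, selected, cfg, names(cfg$kernels)[which.max(accs)])
}

write_study_report <- function(report, tables, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write.csv(report$pvalues, file.path(out_dir, "pvalues.csv"),
            row.names = FALSE, quote = FALSE)
  write.csv(data.frame(kernel = rownames(report$accuracy), report$accuracy,
                       check.names = FALSE),
            file.path(out_dir, "accuracy_matrix.csv"), row.names = FALSE,
            quote = FALSE)
  write.csv(report$comparison, file.path(out_dir, "comparison.csv"),
            row.names = FALSE, quote = FALSE)
  for (nm in names(tables)) {
    write_feature_table(tables[[nm]], file.path(out_dir,
                                                paste0("features_", nm, ".csv")))
  }
  jsonlite::write_json(
    list(selected = report$selected, best_kernel = report$best_kernel,
         seed = report$config$seed,
         accuracy = as.data.frame(report$accuracy),
         comparison = report$comparison),
    file.path(out_dir, "report.json"), auto_unbox = TRUE, digits = NA
  )
  invisible(out_dir)
}

#' @export
print.study_report <- function(x, ...) {
  cat("Driver-stress study report\n")
  cat("  selected features:", paste(x$selected, collapse = ", "), "\n")
  cat("  best kernel:", x$best_kernel, "\n")
  cat("  accuracy matrix (%):\n")
  print(round(x$accuracy, 1))
  cat("  classifier comparison:\n")
  print(x$comparison, row.names = FALSE)
  invisible(x)
}
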