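#' Kruskal-Wallis rank test for one feature
#'
#' Tie-corrected Kruskal-Wallis H with a chi-square upper-tail p-value
#' on `length(groups) - 1` degrees of freedom (the standard large-sample
#' approximation). Used to rank features by how well they separate the
#' condition groups without any distributional assumption -- EMG-derived
#' features are markedly non-Gaussian, which rules out ANOVA.
#'
#' The fully degenerate case where every observation is identical (all
#' midranks tie) is reported as H = 0, p = 1: such a feature carries no
#' group information.
#'
#' @param groups A list of >= 2 non-empty numeric vectors.
#' @return A list of class `kw_result` with `H`, `p_value` and
#'   `group_sizes`.
#' @export
kruskal_wallis <- function(groups) {
  if (!is.list(groups) || length(groups) < 2L) {
    stop("need >= 2 groups", call. = FALSE)
  }
  sizes <- lengths(groups)
  if (any(sizes == 0L)) stop("every group must be non-empty", call. = FALSE)
  x <- unlist(groups, use.names = FALSE)
  if (length(x) < 3L) stop("need a total of >= 3 observations", call. = FALSE)
  g <- factor(rep.int(seq_along(groups), sizes))
  if (length(unique(x)) == 1L) {
    H <- 0
    p <- 1
  } else {
    kt <- kruskal.test(x, g)
    H <- unname(kt$statistic)
    p <- kt$p.value
  }
  structure(list(H = H, p_value = p, group_sizes = as.integer(sizes)),
            class = "kw_result")
}

#' Rank all features of a feature table by Kruskal-Wallis p-value
#'
#' @param table A feature table from [build_feature_table()].
#' @param grouping `"two_class"` pools city and highway windows into a
#'   single stress group against rest (NSC vs SC); `"three_scenario"`
#'   keeps rest, city and highway apart.
#' @return A data frame of class `stf_ranking` with columns `feature`,
#'   `H`, `p_value`, sorted by ascending p-value (ties keep the
#'   canonical feature order).
#' @export
rank_features <- function(table, grouping = c("two_class", "three_scenario")) {
  grouping <- match.arg(grouping)
  key <- if (grouping == "two_class") table$label else table$scenario
  lv <- unique(key)
  if (length(lv) < 2L || any(tabulate(factor(key, levels = lv)) == 0L)) {
    stop("every condition group needs at least one segment", call. = FALSE)
  }
  res <- lapply(stf_names, function(f) {
    kw <- kruskal_wallis(split(table[[f]], key))
    data.frame(feature = f, H = kw$H, p_value = kw$p_value,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out <- out[order(out$p_value), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("stf_ranking", "data.frame")
  out
}

#' Select the most discriminant features
#'
#' Keeps the `top_k` features with the smallest p-values among those
#' significant at `alpha`, after removing an explicit exclusion list.
#' The exclusions encode a visual-overlap veto: a feature can reach a
#' small p-value yet still overlap between conditions enough to hurt
#' the classifier (in the reference analysis this removes the median
#' and the SMR); there is no quantitative rule for this judgement, so
#' it is configuration, not inference.
#'
#' @param ranking An `stf_ranking` from [rank_features()].
#' @param alpha Significance threshold on the p-value (default 0.01).
#' @param top_k Number of features to keep (default 2).
#' @param exclude Character vector of feature names barred from
#'   selection.
#' @return Character vector of selected feature names (ranked order).
#' @export
select_features <- function(ranking, alpha = 0.01, top_k = 2,
                            exclude = character()) {
  stopifnot(is.data.frame(ranking))
  cand <- ranking[!(ranking$feature %in% exclude) & ranking$p_value < alpha, ,
                  drop = FALSE]
  if (nrow(cand) == 0L) {
    stop("no feature passes the alpha = ", alpha, " threshold", call. = FALSE)
  }
  head(cand$feature, top_k)
}
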