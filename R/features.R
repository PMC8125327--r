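#' Names of the 17 statistical time features, in canonical order
#' @export
stf_names <- c(
  "mode", "mean", "range", "variance", "std", "impulse_factor", "smr",
  "sf_smr", "rms", "sf_rms", "crest_factor", "latitude_factor",
  "skewness", "kurtosis", "moment5", "moment6", "median"
)

#' Grouped (binned) mode of a sample
#'
#' Histograms the sample and interpolates the mode inside the modal
#' class: `mode = L + c * d_minus / (d_minus + d_plus)`, where `L` is
#' the lower limit of the modal class, `c` its width, and `d_minus`,
#' `d_plus` the count differences between the modal class and its left
#' and right neighbours (a missing neighbour counts 0). Ties between
#' modal classes break to the leftmost; when both neighbour differences
#' are zero the modal-class midpoint is returned. A constant sample
#' returns that constant.
#'
#' @param x Numeric vector, length >= 2.
#' @param bins Number of histogram bins; default is the Sturges rule
#'   `ceiling(1 + log2(length(x)))`.
#' @return The interpolated modal value.
#' @export
grouped_mode <- function(x, bins = NULL) {
  if (length(x) < 2L) stop("need >= 2 samples", call. = FALSE)
  lo <- min(x); hi <- max(x)
  if (lo == hi) return(lo)
  if (is.null(bins)) bins <- ceiling(1 + log2(length(x)))
  bins <- as.integer(bins)
  if (bins < 1L) stop("`bins` must be >= 1", call. = FALSE)
  width <- (hi - lo) / bins
  idx <- pmin(floor((x - lo) / width) + 1L, bins)
  counts <- tabulate(idx, nbins = bins)
  m <- which.max(counts)  # leftmost on ties
  d_minus <- counts[m] - if (m > 1L) counts[m - 1L] else 0L
  d_plus <- counts[m] - if (m < bins) counts[m + 1L] else 0L
  L <- lo + (m - 1L) * width
  if (d_minus + d_plus == 0) return(L + width / 2)
  L + width * d_minus / (d_minus + d_plus)
}

#' Extract the 17 statistical time features from a window
#'
#' Computes, on the raw (typically normalized) samples of one analysis
#' window: grouped mode, mean, range (max - min), population variance
#' and standard deviation, impulse factor, square mean root (SMR),
#' shape factor over SMR, RMS, shape factor over RMS, crest factor,
#' latitude factor, and the 3rd--6th central moments normalized by RMS
#' powers (skewness, kurtosis, 5th and 6th moments), plus the median.
#' All moments use the population (1/N) convention; the peak value in
#' the impulse, crest and latitude factors is `max(abs(x))`, and the
#' SMR uses square roots of absolute amplitudes so that signed
#' (normalized) signals are handled.
#'
#' @param x An `emg_segment` or a numeric vector of length >= 2.
#' @param bins Histogram bin count passed to [grouped_mode()].
#' @return A named numeric vector of length 17, in [stf_names] order.
#' @export
extract_stf <- function(x, bins = NULL) {
  if (inherits(x, "emg_segment")) x <- x$samples
  if (!is.numeric(x) || length(x) < 2L) {
    stop("need a numeric window with >= 2 samples", call. = FALSE)
  }
  n <- length(x)
  m <- mean(x)
  abs_x <- abs(x)
  mean_abs <- mean(abs_x)
  peak <- max(abs_x)
  variance <- mean((x - m)^2)
  rms <- sqrt(mean(x^2))
  smr <- mean(sqrt(abs_x))^2
  if (rms == 0) {
    stop("all-zero window: RMS-normalized features are undefined", call. = FALSE)
  }
  c(
    mode = grouped_mode(x, bins),
    mean = m,
    range = max(x) - min(x),
    variance = variance,
    std = sqrt(variance),
    impulse_factor = peak / mean_abs,
    smr = smr,
    sf_smr = smr / mean_abs,
    rms = rms,
    sf_rms = rms / mean_abs,
    crest_factor = peak / rms,
    latitude_factor = peak / smr,
    skewness = mean((x - m)^3) / rms^3,
    kurtosis = mean((x - m)^4) / rms^4,
    moment5 = mean((x - m)^5) / rms^5,
    moment6 = mean((x - m)^6) / rms^6,
    median = median(x)
  )
}

#' Assemble the per-segment feature table
#'
#' One row per segment with identifying columns (`subject_id`,
#' `segment_index`, `scenario`, `label`) followed by the 17 feature
#' columns in [stf_names] order. A 10-subject cohort under the default
#' protocol gives 50 rows, i.e. 850 feature values.
#'
#' @param segments A non-empty list of `emg_segment`s.
#' @param bins Histogram bin count passed to [extract_stf()].
#' @return A `data.frame` feature table.
#' @export
build_feature_table <- function(segments, bins = NULL) {
  if (length(segments) == 0L) stop("no segments", call. = FALSE)
  feats <- t(vapply(segments, extract_stf, numeric(17), bins = bins))
  out <- data.frame(
    subject_id = vapply(segments, `[[`, character(1), "subject_id"),
    segment_index = vapply(segments, `[[`, numeric(1), "segment_index"),
    scenario = vapply(segments, `[[`, character(1), "scenario"),
    label = vapply(segments, `[[`, character(1), "label"),
    stringsAsFactors = FALSE
  )
  cbind(out, as.data.frame(feats))
}

#' Write / read a feature table as CSV
#' @param table A feature table from [build_feature_table()].
#' @param path File path.
#' @return `path` invisibly (writer) or the feature table (reader).
#' @export
write_feature_table <- function(table, path) {
  write.csv(table, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  ft <- read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(stf_names, names(ft))
  if (length(missing)) {
    stop("feature table lacks columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  ft
}
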