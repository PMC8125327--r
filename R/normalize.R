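#' Rest-baseline normalization statistics
#'
#' Computes the mean and population (1/N) standard deviation of a
#' subject's rest window. These are the z-score parameters used to put
#' all of that subject's windows on a common dimensionless scale,
#' removing the per-subject amplitude offset and scale introduced by
#' electrode placement, skin impedance and similar factors.
#'
#' @param rest_segment An `emg_segment` with `scenario == "rest"` and at
#'   least two samples.
#' @return A `normalization_params` list with fields `mu` and `sigma`.
#' @export
baseline_stats <- function(rest_segment) {
  stopifnot(inherits(rest_segment, "emg_segment"))
  if (rest_segment$scenario != "rest") {
    stop("baseline must be computed from the rest segment", call. = FALSE)
  }
  x <- rest_segment$samples
  if (length(x) < 2L) stop("need >= 2 samples for a baseline", call. = FALSE)
  mu <- mean(x)
  sigma <- sqrt(mean((x - mu)^2))
  if (sigma == 0) stop("constant rest segment: zero baseline variance", call. = FALSE)
  structure(list(mu = mu, sigma = sigma), class = "normalization_params")
}

#' z-score a segment with given baseline parameters
#'
#' Replaces every sample x by (x - mu) / sigma. The result is
#' dimensionless; metadata is preserved.
#'
#' @param segment An `emg_segment`.
#' @param params A `normalization_params` object (`sigma > 0`).
#' @return The normalized `emg_segment`.
#' @export
normalize_segment <- function(segment, params) {
  stopifnot(inherits(segment, "emg_segment"),
            inherits(params, "normalization_params"))
  if (params$sigma <= 0) stop("`sigma` must be > 0", call. = FALSE)
  segment$samples <- (segment$samples - params$mu) / params$sigma
  segment
}

#' Normalize a cohort's segments
#'
#' With `method = "rest_baseline"` (the default) each subject's five
#' windows are z-scored with the mean and population standard deviation
#' of that subject's rest window, so the rest window maps exactly to
#' mean 0 / std 1 while stress windows retain their variance ratio to
#' rest -- the quantity the downstream feature selection discriminates
#' on. With `method = "self"` every window is z-scored by its own
#' statistics, which forces unit variance everywhere and is provided
#' only for comparison.
#'
#' @param segments A list of `emg_segment`s covering one or more
#'   subjects; under `rest_baseline` each subject must contribute
#'   exactly one rest segment.
#' @param method `"rest_baseline"` or `"self"`.
#' @return The list of normalized segments, in input order.
#' @export
normalize_segments <- function(segments, method = c("rest_baseline", "self")) {
  method <- match.arg(method)
  if (method == "self") {
    return(lapply(segments, function(s) {
      p <- structure(list(mu = mean(s$samples),
                          sigma = sqrt(mean((s$samples - mean(s$samples))^2))),
                     class = "normalization_params")
      if (p$sigma == 0) stop("constant segment cannot be self-normalized",
                             call. = FALSE)
      normalize_segment(s, p)
    }))
  }
  subjects <- vapply(segments, `[[`, character(1), "subject_id")
  out <- segments
  for (sid in unique(subjects)) {
    idx <- which(subjects == sid)
    rest_idx <- idx[vapply(segments[idx], function(s) s$scenario == "rest",
                           logical(1))]
    if (length(rest_idx) != 1L) {
      stop("subject ", sid, " must have exactly one rest segment", call. = FALSE)
    }
    params <- baseline_stats(segments[[rest_idx]])
    out[idx] <- lapply(segments[idx], normalize_segment, params = params)
  }
  out
}
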