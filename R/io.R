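#' Write / read a recording as single-column CSV
#'
#' The file starts with a comment header `# subject_id=<id> fs=<Hz>`
#' followed by an `amplitude` column, one sample per line.
#'
#' @param recording An `emg_recording`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_recording <- function(recording, path) {
  stopifnot(inherits(recording, "emg_recording"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# subject_id=%s fs=%.10g", recording$subject_id,
                     recording$fs), con)
  writeLines("amplitude", con)
  writeLines(format(recording$samples, digits = 17, trim = TRUE,
                    scientific = FALSE), con)
  invisible(path)
}

#' @rdname write_recording
#' @export
read_recording <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  header <- readLines(path, n = 1L)
  m <- regmatches(header,
                  regexec("^# subject_id=(\\S+) fs=([0-9.eE+-]+)$", header))[[1]]
  if (length(m) != 3L) stop("malformed recording header: ", header, call. = FALSE)
  fs <- as.numeric(m[3])
  if (!is.finite(fs) || fs <= 0) stop("invalid fs in header", call. = FALSE)
  vals <- read.csv(path, skip = 1L, colClasses = "character")
  x <- suppressWarnings(as.numeric(vals$amplitude))
  if (anyNA(x)) stop("non-numeric amplitude value in ", path, call. = FALSE)
  structure(list(subject_id = m[2], fs = fs, samples = x),
            class = "emg_recording")
}

#' Write / read scenario annotations
#'
#' CSV with columns `scenario,start_s,end_s`; times are 0-based seconds
#' and intervals are half-open `[start_s, end_s)`.
#'
#' @param annotation A `scenario_annotation` data frame.
#' @param path File path.
#' @return `path` invisibly (writer) or a validated
#'   `scenario_annotation` (reader).
#' @export
write_annotations <- function(annotation, path) {
  stopifnot(is.data.frame(annotation))
  write.csv(as.data.frame(annotation)[, c("scenario", "start_s", "end_s")],
            path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_annotations
#' @export
read_annotations <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  ann <- read.csv(path, stringsAsFactors = FALSE)
  validate_annotation(ann)
}

validate_annotation <- function(ann) {
  if (!all(c("scenario", "start_s", "end_s") %in% names(ann))) {
    stop("annotation needs scenario,start_s,end_s columns", call. = FALSE)
  }
  if (!all(ann$scenario %in% c("rest", "city", "highway"))) {
    stop("unknown scenario label in annotation", call. = FALSE)
  }
  if (any(ann$end_s <= ann$start_s)) {
    stop("annotation intervals must satisfy end_s > start_s", call. = FALSE)
  }
  o <- order(ann$start_s)
  so <- ann[o, ]
  if (nrow(so) > 1L && any(so$start_s[-1] < so$end_s[-nrow(so)])) {
    stop("annotation intervals overlap", call. = FALSE)
  }
  structure(ann, class = unique(c("scenario_annotation", class(ann))))
}

new_segment <- function(subject_id, scenario, samples, fs, segment_index) {
  structure(
    list(subject_id = subject_id, scenario = scenario,
         label = if (scenario == "rest") "NSC" else "SC",
         samples = samples, fs = fs, segment_index = segment_index),
    class = "emg_segment"
  )
}

#' Cut scenario-labelled analysis windows from a recording
#'
#' Extracts the first `window_minutes` of each annotated scenario
#' interval. Under the default protocol this yields exactly five
#' segments per recording: one rest window labelled `NSC` (no stress
#' condition) and four driving windows labelled `SC` (stress
#' condition).
#'
#' @param recording An `emg_recording`.
#' @param annotation A `scenario_annotation` with exactly one rest, two
#'   city and two highway intervals, each at least `window_minutes`
#'   long.
#' @param window_minutes Window length in minutes (default 5).
#' @return A list of `emg_segment` objects, one per interval, in
#'   annotation order.
#' @export
extract_segments <- function(recording, annotation, window_minutes = 5) {
  stopifnot(inherits(recording, "emg_recording"))
  ann <- validate_annotation(as.data.frame(annotation))
  counts <- table(factor(ann$scenario, levels = c("rest", "city", "highway")))
  if (!(counts[["rest"]] == 1L && counts[["city"]] == 2L &&
        counts[["highway"]] == 2L)) {
    stop("annotation must contain exactly 1 rest, 2 city and 2 highway intervals",
         call. = FALSE)
  }
  if (window_minutes <= 0) stop("`window_minutes` must be > 0", call. = FALSE)
  n_win <- round_half_up(window_minutes * 60 * recording$fs)
  lapply(seq_len(nrow(ann)), function(i) {
    if (ann$end_s[i] - ann$start_s[i] < window_minutes * 60) {
      stop(sprintf("interval %d (%s) is shorter than the %g-min window",
                   i, ann$scenario[i], window_minutes), call. = FALSE)
    }
    i0 <- floor(ann$start_s[i] * recording$fs) + 1
    if (i0 + n_win - 1 > length(recording$samples)) {
      stop("interval extends past the end of the recording", call. = FALSE)
    }
    new_segment(recording$subject_id, ann$scenario[i],
                recording$samples[i0:(i0 + n_win - 1)], recording$fs, i)
  })
}

#' Truncate a segment for the window-length study
#'
#' Keeps the first `minutes` of an extracted segment, preserving
#' subject, scenario and label metadata.
#'
#' @param segment An `emg_segment`.
#' @param minutes Target length in minutes; must not exceed the
#'   segment's current length.
#' @return An `emg_segment` of `round(minutes * 60 * fs)` samples.
#' @export
truncate_segment <- function(segment, minutes) {
  stopifnot(inherits(segment, "emg_segment"))
  n <- round_half_up(minutes * 60 * segment$fs)
  if (n < 1 || n > length(segment$samples)) {
    stop("truncation length exceeds segment length", call. = FALSE)
  }
  segment$samples <- segment$samples[seq_len(n)]
  segment
}

#' Segment every recording of a cohort
#'
#' @param cohort A list of `list(recording, annotation)` pairs as
#'   produced by [generate_cohort()].
#' @param window_minutes Window length in minutes.
#' @return A flat list of `emg_segment`s (5 per recording under the
#'   default protocol).
#' @export
segment_cohort <- function(cohort, window_minutes = 5) {
  segs <- lapply(cohort, function(x) {
    extract_segments(x$recording, x$annotation, window_minutes)
  })
  do.call(c, segs)
}
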