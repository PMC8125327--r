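#' Subject profile for the synthetic EMG generator
#'
#' Captures the per-subject amplitude idiosyncrasies of surface EMG:
#' electrode placement, skin impedance and muscle physiology shift and
#' scale the recorded amplitude differently for every participant, so
#' raw feature values are not comparable across subjects until a
#' baseline normalization is applied.
#'
#' @param subject_id Character identifier, e.g. `"S01"`.
#' @param baseline_scale Positive amplitude scale (arbitrary EMG units):
#'   the standard deviation of the rest-period signal.
#' @param baseline_offset Additive amplitude offset (same units).
#' @param burst_rate Expected number of transient muscle-activity bursts
#'   per minute (>= 0). The default 0 produces a stationary Gaussian
#'   signal, convenient for moment-recovery checks.
#' @return An object of class `subject_profile`.
#' @export
subject_profile <- function(subject_id = "S01", baseline_scale = 20,
                            baseline_offset = 100, burst_rate = 0) {
  stopifnot(is.character(subject_id), length(subject_id) == 1L)
  if (!is.numeric(baseline_scale) || baseline_scale <= 0) {
    stop("`baseline_scale` must be > 0", call. = FALSE)
  }
  if (!is.numeric(burst_rate) || burst_rate < 0) {
    stop("`burst_rate` must be >= 0", call. = FALSE)
  }
  structure(
    list(subject_id = subject_id, baseline_scale = baseline_scale,
         baseline_offset = baseline_offset, burst_rate = burst_rate),
    class = "subject_profile"
  )
}

#' Stress effect model for the synthetic cohort
#'
#' Encodes the single statistical effect the analysis relies on: driving
#' under stress raises the amplitude variability of the trapezius EMG
#' relative to rest, more so on the highway (high stress) than in the
#' city (medium stress). Magnitudes are free generator parameters; only
#' the direction (multipliers >= 1) is fixed.
#'
#' @param variance_multiplier_city Variance of city driving relative to
#'   rest (>= 1). Default 2.
#' @param variance_multiplier_highway Variance of highway driving
#'   relative to rest (>= 1). Default 3.
#' @param burst_amplitude_gain Peak multiplicative gain of the noise
#'   envelope during a transient burst (>= 1). Default 6.
#' @return An object of class `stress_model`.
#' @export
stress_model <- function(variance_multiplier_city = 2,
                         variance_multiplier_highway = 3,
                         burst_amplitude_gain = 6) {
  if (variance_multiplier_city < 1 || variance_multiplier_highway < 1) {
    stop("variance multipliers must be >= 1 (city/highway are stress conditions)",
         call. = FALSE)
  }
  if (burst_amplitude_gain < 1) {
    stop("`burst_amplitude_gain` must be >= 1", call. = FALSE)
  }
  structure(
    list(variance_multiplier_city = variance_multiplier_city,
         variance_multiplier_highway = variance_multiplier_highway,
         burst_amplitude_gain = burst_amplitude_gain),
    class = "stress_model"
  )
}

#' Default driving protocol
#'
#' One rest interval followed by two city and two highway driving
#' intervals, giving the five annotated scenario intervals from which
#' one analysis window each is extracted (1 rest + 2 city + 2 highway
#' segments per subject).
#'
#' @return A `driving_protocol` data frame with columns `scenario`
#'   (`rest`/`city`/`highway`) and `minutes`.
#' @export
default_protocol <- function() {
  proto <- data.frame(
    scenario = c("rest", "city", "highway", "city", "highway"),
    minutes  = c(15, 13, 8, 13, 8),
    stringsAsFactors = FALSE
  )
  class(proto) <- c("driving_protocol", "data.frame")
  proto
}

validate_protocol <- function(protocol) {
  if (!is.data.frame(protocol) || nrow(protocol) == 0L) {
    stop("protocol must be a non-empty data frame", call. = FALSE)
  }
  if (!all(c("scenario", "minutes") %in% names(protocol))) {
    stop("protocol needs `scenario` and `minutes` columns", call. = FALSE)
  }
  if (!all(protocol$scenario %in% c("rest", "city", "highway"))) {
    stop("unknown scenario in protocol", call. = FALSE)
  }
  if (any(protocol$minutes <= 0)) stop("protocol durations must be > 0", call. = FALSE)
  invisible(protocol)
}

scenario_multiplier <- function(scenario, model) {
  vapply(scenario, function(s) {
    switch(s,
      rest = 1,
      city = model$variance_multiplier_city,
      highway = model$variance_multiplier_highway
    )
  }, numeric(1))
}

#' Generate one synthetic EMG recording
#'
#' Simulates a single-channel EMG amplitude series over a driving
#' protocol. The signal is zero-mean Gaussian envelope noise with
#' per-scenario standard deviation `baseline_scale * sqrt(multiplier)`,
#' shifted by the subject's amplitude offset. Transient bursts arrive as
#' a Poisson process at `profile$burst_rate` per minute; each burst is a
#' 0.5--2 s raised-cosine envelope that multiplies the local noise
#' standard deviation up to `model$burst_amplitude_gain`, giving the
#' heavy-tailed excursions real EMG shows.
#'
#' @param profile A [subject_profile()].
#' @param model A [stress_model()].
#' @param protocol A protocol data frame, default [default_protocol()].
#' @param fs Sampling frequency in Hz (default 15.5).
#' @param seed Integer seed; identical arguments give bitwise-identical
#'   samples.
#' @return A list with elements `recording` (class `emg_recording`) and
#'   `annotation` (class `scenario_annotation`).
#' @export
generate_recording <- function(profile, model, protocol = default_protocol(),
                               fs = 15.5, seed = 1L) {
  stopifnot(inherits(profile, "subject_profile"), inherits(model, "stress_model"))
  if (!is.numeric(fs) || fs <= 0) stop("`fs` must be > 0", call. = FALSE)
  validate_protocol(protocol)

  end_s <- cumsum(protocol$minutes * 60)
  start_s <- c(0, head(end_s, -1))
  total_s <- end_s[length(end_s)]
  n_total <- round_half_up(total_s * fs)
  t_sec <- (seq_len(n_total) - 1) / fs

  # per-sample scenario std
  idx_interval <- findInterval(t_sec, start_s)
  sigma <- profile$baseline_scale *
    unname(sqrt(scenario_multiplier(protocol$scenario, model)))[idx_interval]

  samples <- with_seed(seed, {
    env <- rep(1, n_total)
    if (profile$burst_rate > 0 && model$burst_amplitude_gain > 1) {
      n_bursts <- rpois(1, profile$burst_rate * total_s / 60)
      if (n_bursts > 0) {
        onsets <- runif(n_bursts, 0, total_s)
        durs <- runif(n_bursts, 0.5, 2)
        for (b in seq_len(n_bursts)) {
          u <- (t_sec - onsets[b]) / durs[b]
          inside <- u >= 0 & u <= 1
          shape <- 0.5 * (1 - cos(2 * pi * u[inside]))  # raised cosine 0->1->0
          env[inside] <- pmax(env[inside],
                              1 + (model$burst_amplitude_gain - 1) * shape)
        }
      }
    }
    profile$baseline_offset + sigma * env * rnorm(n_total)
  })

  recording <- structure(
    list(subject_id = profile$subject_id, fs = fs, samples = samples),
    class = "emg_recording"
  )
  annotation <- structure(
    data.frame(scenario = protocol$scenario, start_s = start_s, end_s = end_s,
               stringsAsFactors = FALSE),
    class = c("scenario_annotation", "data.frame")
  )
  list(recording = recording, annotation = annotation)
}

#' Generate a synthetic EMG cohort
#'
#' Draws `n_subjects` subject profiles from seeded distributions and
#' simulates one recording per subject under a common stress model and
#' protocol. Baseline scales and offsets are log-normal across subjects,
#' reproducing the wide inter-subject amplitude spread of real surface
#' EMG that motivates rest-baseline normalization; burst rates are
#' uniform on 1--3 events/min, so short analysis windows see a highly
#' variable number of transients while long windows average them out.
#'
#' @param n_subjects Number of subjects (>= 1); 10 matches the study
#'   cohort size.
#' @param model A [stress_model()].
#' @param seed Master integer seed for the whole cohort.
#' @param protocol Protocol shared by all subjects.
#' @param fs Sampling frequency in Hz.
#' @return A list of length `n_subjects`; each element is the
#'   `list(recording, annotation)` pair of [generate_recording()], with
#'   the generating `subject_profile` attached as element `profile`.
#' @export
generate_cohort <- function(n_subjects = 10, model = stress_model(), seed = 1L,
                            protocol = default_protocol(), fs = 15.5) {
  if (!is.numeric(n_subjects) || n_subjects < 1) {
    stop("`n_subjects` must be >= 1", call. = FALSE)
  }
  n_subjects <- as.integer(n_subjects)
  profiles <- with_seed(seed, {
    scales <- rlnorm(n_subjects, meanlog = log(20), sdlog = 0.6)
    offsets <- rlnorm(n_subjects, meanlog = log(100), sdlog = 0.5)
    rates <- runif(n_subjects, 1, 3)
    lapply(seq_len(n_subjects), function(i) {
      subject_profile(sprintf("S%02d", i), baseline_scale = scales[i],
                      baseline_offset = offsets[i], burst_rate = rates[i])
    })
  })
  rec_seeds <- derive_seeds(seed, n_subjects)
  lapply(seq_len(n_subjects), function(i) {
    out <- generate_recording(profiles[[i]], model, protocol, fs = fs,
                              seed = rec_seeds[i])
    out$profile <- profiles[[i]]
    out
  })
}
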