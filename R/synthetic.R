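# Synthetic paired PPG/ABP generator.
#
# The ABP beat is a raised-cosine systolic upstroke over the first 30% of
# the beat followed by an exponential diastolic decay back to the trough,
# so each beat's maximum is exactly the systolic target and its minimum
# exactly the diastolic target before noise. The PPG pulse is a Gaussian
# systolic wave plus a dicrotic (secondary) wave; its width grows with SBP
# and its dicrotic depth shrinks with DBP, an affine coupling that gives a
# classifier a learnable morphological signal without claiming hemodynamic
# realism.

#' Subject profile for waveform synthesis
#'
#' @param sbp_target,dbp_target Systolic/diastolic targets in mmHg
#'   (`sbp_target > dbp_target > 0`).
#' @param heart_rate Beats per minute, in `[30, 220]`.
#' @param wander_amplitude Respiratory baseline-wander amplitude as a
#'   fraction of the pulse amplitude (>= 0).
#' @param wander_frequency Wander frequency in Hz, in the respiratory band
#'   `[0.1, 0.5]`.
#' @param noise_sd Additive Gaussian noise SD as a fraction of the pulse
#'   amplitude (>= 0).
#' @param seed Integer seed; generation is deterministic given the profile.
#' @return A `subject_profile` object.
#' @examples
#' subject_profile(110, 72, heart_rate = 60, noise_sd = 0)
#' @export
subject_profile <- function(sbp_target, dbp_target, heart_rate = 75,
                            wander_amplitude = 0.1, wander_frequency = 0.25,
                            noise_sd = 0.02, seed = 1L) {
  if (!(sbp_target > dbp_target && dbp_target > 0))
    stop("require sbp_target > dbp_target > 0")
  if (heart_rate < 30 || heart_rate > 220)
    stop("heart_rate must lie in [30, 220] beats/min")
  if (wander_frequency < 0.1 || wander_frequency > 0.5)
    stop("wander_frequency must lie in the respiratory band [0.1, 0.5] Hz")
  if (wander_amplitude < 0 || noise_sd < 0)
    stop("wander_amplitude and noise_sd must be >= 0")
  structure(list(sbp_target = sbp_target, dbp_target = dbp_target,
                 heart_rate = heart_rate,
                 wander_amplitude = wander_amplitude,
                 wander_frequency = wander_frequency,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "subject_profile")
}

#' @export
print.subject_profile <- function(x, ...) {
  cat(sprintf(
    "<subject_profile> %g/%g mmHg, %g bpm, wander %g @ %g Hz, noise %g, seed %d\n",
    x$sbp_target, x$dbp_target, x$heart_rate, x$wander_amplitude,
    x$wander_frequency, x$noise_sd, x$seed))
  invisible(x)
}

# Beat onsets (in samples, first at 1) with <=2% per-beat period jitter,
# covering at least n_samples. Deterministic given the profile seed.
beat_schedule <- function(profile, n_samples, fs) {
  period <- fs * 60 / profile$heart_rate
  with_seed(profile$seed, {
    onsets <- 1
    while (utils::tail(onsets, 1) < n_samples + period) {
      jit <- stats::runif(1, -0.02, 0.02)
      onsets <- c(onsets, utils::tail(onsets, 1) + period * (1 + jit))
    }
    onsets
  })
}

#' Generate a synthetic ABP series
#'
#' Quasi-periodic beat train whose per-beat maxima equal `sbp_target` and
#' minima equal `dbp_target` before noise. Deterministic given the profile
#' seed.
#'
#' @param profile A [subject_profile()].
#' @param n_samples Series length in samples (at least one beat period).
#' @param fs Sampling rate in Hz.
#' @return Numeric ABP series in mmHg, length `n_samples`.
#' @export
generate_abp <- function(profile, n_samples, fs = 125) {
  stopifnot(inherits(profile, "subject_profile"))
  period <- fs * 60 / profile$heart_rate
  if (n_samples < period)
    stop(sprintf(
      "n_samples (%d) is shorter than one beat period (%.1f samples at %g bpm)",
      n_samples, period, profile$heart_rate))
  onsets <- round(beat_schedule(profile, n_samples, fs))
  sbp <- profile$sbp_target; dbp <- profile$dbp_target
  pp <- sbp - dbp
  abp <- numeric(max(onsets))
  k_decay <- 3
  for (b in seq_len(length(onsets) - 1L)) {
    lb <- onsets[b + 1L] - onsets[b]
    if (lb < 2) next
    tau <- (seq_len(lb) - 1) / lb
    up <- tau < 0.3
    beat <- numeric(lb)
    beat[up] <- dbp + pp * 0.5 * (1 - cos(pi * tau[up] / 0.3))
    s <- (tau[!up] - 0.3) / 0.7
    beat[!up] <- dbp + pp * (exp(-k_decay * s) - exp(-k_decay)) /
      (1 - exp(-k_decay))
    beat[pmin(lb, round(0.3 * lb) + 1L)] <- sbp  # exact systolic sample
    abp[onsets[b]:(onsets[b + 1L] - 1L)] <- beat
  }
  abp <- abp[seq_len(n_samples)]
  if (profile$noise_sd > 0)
    abp <- abp + with_seed(profile$seed + 31L,
                           stats::rnorm(n_samples, 0, profile$noise_sd * pp))
  abp
}

# affine BP -> pulse-morphology coupling (dimensionless)
ppg_morphology <- function(sbp, dbp) {
  list(width = min(max(0.06 + 8e-4 * (sbp - 100), 0.03), 0.15),
       dicrotic = min(max(0.45 - 4e-3 * (dbp - 70), 0.05), 0.8),
       amp = 1 + 4e-3 * (sbp - 110))
}

#' Generate a synthetic PPG series synchronised with an ABP series
#'
#' Detects the beats of `abp` and renders one PPG pulse per beat: a Gaussian
#' systolic wave whose relative width grows affinely with that beat's
#' systolic pressure, plus a dicrotic wave whose depth falls affinely with
#' the diastolic pressure, so that normal and abnormal blood-pressure
#' regimes are morphologically separable. Sinusoidal baseline wander at the
#' profile's respiratory frequency and Gaussian noise are added on top.
#' Deterministic given the profile seed.
#'
#' @param abp ABP series (mmHg) to synchronise with; nonempty.
#' @param profile A [subject_profile()].
#' @param fs Sampling rate in Hz.
#' @return Numeric PPG series (arbitrary units), same length as `abp`.
#' @export
generate_ppg <- function(abp, profile, fs = 125) {
  stopifnot(inherits(profile, "subject_profile"))
  if (!length(abp)) stop("abp must be nonempty")
  n <- length(abp)
  pt <- detect_peaks_troughs(abp, fs)
  # beat boundaries: troughs, extended to the series edges
  bounds <- unique(c(1L, pt$troughs, n + 1L))
  ppg <- numeric(n)
  for (b in seq_len(length(bounds) - 1L)) {
    i0 <- bounds[b]; i1 <- bounds[b + 1L] - 1L
    lb <- i1 - i0 + 1L
    if (lb < 2) next
    seg <- abp[i0:i1]
    mo <- ppg_morphology(max(seg), min(seg))
    tau <- (seq_len(lb) - 1) / lb
    ppg[i0:i1] <- mo$amp * (exp(-((tau - 0.2) / mo$width)^2) +
                            mo$dicrotic * exp(-((tau - 0.55) / 0.1)^2))
  }
  base_amp <- ppg_morphology(profile$sbp_target, profile$dbp_target)$amp
  tt <- (seq_len(n) - 1) / fs
  with_seed(profile$seed + 17L, {
    if (profile$wander_amplitude > 0) {
      phase <- stats::runif(1, 0, 2 * pi)
      ppg <- ppg + profile$wander_amplitude * base_amp *
        sin(2 * pi * profile$wander_frequency * tt + phase)
    }
    if (profile$noise_sd > 0)
      ppg <- ppg + stats::rnorm(n, 0, profile$noise_sd * base_amp)
  })
  ppg
}

#' Generate a paired PPG/ABP record
#'
#' @param profile A [subject_profile()].
#' @param duration_s Record duration in seconds.
#' @param fs Sampling rate in Hz (default 125).
#' @return A `waveform_record`: list with `ppg`, `abp`, `fs`, `n_samples`,
#'   `profile`.
#' @examples
#' rec <- generate_record(subject_profile(110, 72, 60, noise_sd = 0,
#'                                        wander_amplitude = 0), 10)
#' @export
generate_record <- function(profile, duration_s = 24, fs = 125) {
  n <- as.integer(round(duration_s * fs))
  abp <- generate_abp(profile, n, fs)
  ppg <- generate_ppg(abp, profile, fs)
  structure(list(ppg = ppg, abp = abp, fs = fs, n_samples = n,
                 profile = profile),
            class = "waveform_record")
}

#' @export
print.waveform_record <- function(x, ...) {
  cat(sprintf("<waveform_record> %d samples @ %g Hz (%.1f s), target %g/%g mmHg\n",
              x$n_samples, x$fs, x$n_samples / x$fs,
              x$profile$sbp_target, x$profile$dbp_target))
  invisible(x)
}

#' Inject a signal artifact into a record
#'
#' Corrupts `span` samples starting at `start` in one channel (or both):
#' `flatline` holds the channel at its value at `start`, `dropout` zeroes
#' it, `spike` adds a large triangular transient (10 times the channel
#' range). `span = 0` returns the record unchanged.
#'
#' @param record A `waveform_record`.
#' @param kind One of `"flatline"`, `"dropout"`, `"spike"`.
#' @param start First affected sample (1-based).
#' @param span Number of affected samples.
#' @param channel `"ppg"`, `"abp"`, or `"both"`.
#' @return The modified `waveform_record`.
#' @export
inject_artifact <- function(record, kind = c("flatline", "dropout", "spike"),
                            start, span, channel = c("ppg", "abp", "both")) {
  kind <- match.arg(kind)
  channel <- match.arg(channel)
  stopifnot(inherits(record, "waveform_record"))
  if (span < 0 || start < 1 || start + span - 1 > record$n_samples)
    stop("artifact span [start, start + span) must lie within the record")
  if (span == 0) return(record)
  idx <- start:(start + span - 1L)
  chans <- if (channel == "both") c("ppg", "abp") else channel
  for (ch in chans) {
    x <- record[[ch]]
    x[idx] <- switch(kind,
      flatline = x[start],
      dropout = 0,
      spike = {
        mag <- 10 * max(diff(range(x)), 1)
        x[idx] + mag * (1 - abs(2 * (seq_along(idx) - 1) /
                                  max(span - 1, 1) - 1))
      })
    record[[ch]] <- x
  }
  record
}

# sampling boxes for per-category BP targets; margins of >= 2 mmHg from the
# ACC/AHA thresholds so that labels recovered from the waveform (accurate to
# ~1 mmHg in the noiseless case) match the intended category
.category_boxes <- list(
  NORMAL   = list(sbp = c(100, 117), dbp = c(62, 77)),
  ELEVATED = list(sbp = c(122, 127), dbp = c(62, 77)),
  STAGE1   = list(sbp = c(132, 137), dbp = c(82, 87)),
  STAGE2   = list(sbp = c(142, 172), dbp = c(92, 105)))

# proportions of the four categories in an ICU-style labelled pool
# (normal : elevated : stage 1 : stage 2 = 1641 : 1739 : 2692 : 334)
.default_mix <- c(NORMAL = 1641, ELEVATED = 1739, STAGE1 = 2692,
                  STAGE2 = 334) / 6406

#' Generate a labelled cohort of synthetic records
#'
#' Draws per-record blood-pressure targets inside category-specific boxes
#' (kept clear of the ACC/AHA thresholds so recovered labels match the
#' intended ones), apportions `n_records` over the four categories by
#' largest remainder, and derives each record's seed as
#' `base_seed + record index`.
#'
#' @param n_records Number of records.
#' @param category_mix Nonnegative proportions over
#'   (NORMAL, ELEVATED, STAGE1, STAGE2); normalised to sum to 1. The default
#'   mirrors the prevalence of the four categories in ICU waveform data.
#' @param base_seed Integer base seed.
#' @param duration_s Duration of each record in seconds.
#' @param fs Sampling rate in Hz.
#' @param wander_amplitude,wander_frequency,noise_sd Profile noise settings
#'   applied to every record (see [subject_profile()]).
#' @param heart_rate_range Range from which each record's heart rate is
#'   drawn uniformly.
#' @return List of `waveform_record` objects.
#' @export
generate_dataset <- function(n_records, category_mix = .default_mix,
                             base_seed = 1L, duration_s = 24, fs = 125,
                             wander_amplitude = 0.1, wander_frequency = 0.25,
                             noise_sd = 0.02, heart_rate_range = c(55, 95)) {
  if (length(category_mix) != 4 || any(!is.finite(category_mix)) ||
      any(category_mix < 0) || sum(category_mix) <= 0)
    stop("category_mix must be 4 nonnegative proportions with a positive sum")
  if (n_records == 0) return(list())
  mix <- category_mix / sum(category_mix)
  # largest-remainder apportionment
  raw <- n_records * mix
  counts <- floor(raw)
  rem <- n_records - sum(counts)
  if (rem > 0) {
    up <- order(raw - counts, decreasing = TRUE)[seq_len(rem)]
    counts[up] <- counts[up] + 1
  }
  cats <- rep(.bp_levels, counts)
  lapply(seq_len(n_records), function(i) {
    seed_i <- as.integer(base_seed) + i
    box <- .category_boxes[[cats[i]]]
    pars <- with_seed(seed_i, list(
      sbp = stats::runif(1, box$sbp[1], box$sbp[2]),
      dbp = stats::runif(1, box$dbp[1], box$dbp[2]),
      hr = stats::runif(1, heart_rate_range[1], heart_rate_range[2])))
    prof <- subject_profile(pars$sbp, pars$dbp, heart_rate = pars$hr,
                            wander_amplitude = wander_amplitude,
                            wander_frequency = wander_frequency,
                            noise_sd = noise_sd, seed = seed_i)
    generate_record(prof, duration_s, fs)
  })
}

#' Write / read a waveform record
#'
#' Plain-text persistence: a two-column CSV (`ppg`, `abp`) plus a JSON
#' sidecar (`<path>.json`) holding the sampling rate and the full subject
#' profile.
#'
#' @param record A `waveform_record`.
#' @param path CSV file path.
#' @return `write_record` returns `path` invisibly; `read_record` returns
#'   the reconstructed `waveform_record`.
#' @export
write_record <- function(record, path) {
  stopifnot(inherits(record, "waveform_record"))
  utils::write.csv(data.frame(ppg = record$ppg, abp = record$abp),
                   path, row.names = FALSE)
  meta <- list(fs = record$fs, n_samples = record$n_samples,
               profile = unclass(record$profile))
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_record
#' @export
read_record <- function(path) {
  dat <- utils::read.csv(path)
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  prof <- do.call(subject_profile, c(
    meta$profile[c("sbp_target", "dbp_target", "heart_rate",
                   "wander_amplitude", "wander_frequency", "noise_sd")],
    list(seed = meta$profile$seed)))
  structure(list(ppg = dat$ppg, abp = dat$abp, fs = as.numeric(meta$fs),
                 n_samples = as.integer(meta$n_samples), profile = prof),
            class = "waveform_record")
}
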