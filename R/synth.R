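#' Configuration for the synthetic swallow-signal generator
#'
#' Builds the parameter set that defines a synthetic drinking-protocol cohort:
#' two-channel (left/right sternohyoid) surface-EMG recordings in which each
#' swallow appears as a band-limited burst whose amplitude and duration grow
#' with the ingested sip volume, on top of Gaussian baseline noise.
#'
#' The protocol emulated is: per subject, 5 saliva swallows, 5 sips each from
#' cup, bottle and straw (volumes drawn from container-specific distributions,
#' straw sips smallest), and one maximum-capacity swallow of the largest cup
#' volume plus 5 mL. Each recording is 10 s at 1 kHz.
#'
#' @param sampling_rate_hz Sampling rate in Hz.
#' @param recording_s Recording length in seconds.
#' @param noise_sigma_uV SD of the additive Gaussian baseline noise (uV).
#' @param burst_base_uV Peak burst envelope amplitude at zero volume (uV);
#'   saliva swallows owe their (small) burst to this term.
#' @param burst_gain_uV_per_mL Increase of peak envelope amplitude per mL.
#' @param burst_dur_ms Length-2 numeric `c(base, slope)`: burst duration in ms
#'   is `base + slope * volume_mL`, capped at 1500 ms. The default puts
#'   typical sips near 1.5 s, the nominal swallow-burst duration the 1500 ms
#'   analysis window is sized for.
#' @param container_volume_dists Named list with entries `cup`, `bottle`,
#'   `straw`, each `c(mean, sd)` in mL. Means must be ordered
#'   straw < cup <= bottle; draws are truncated at 1 mL.
#' @param saliva_effective_mL Effective volume driving the saliva burst's
#'   amplitude/duration; the recorded sip volume of a saliva swallow stays 0.
#' @param lr_asymmetry Gain ratio of the right channel relative to the left.
#' @return A list of class `synth_config`.
#' @examples
#' cfg <- synth_config()
#' rec <- generate_recording(cfg, volume_mL = 15, task = "cup")
#' @export
synth_config <- function(sampling_rate_hz = 1000,
                         recording_s = 10,
                         noise_sigma_uV = 6,
                         burst_base_uV = 15,
                         burst_gain_uV_per_mL = 2.5,
                         burst_dur_ms = c(1400, 5),
                         container_volume_dists = list(
                           cup = c(15, 5), bottle = c(18, 6), straw = c(8, 3)
                         ),
                         saliva_effective_mL = 1.5,
                         lr_asymmetry = 0.85) {
  if (sampling_rate_hz <= 0) stop("sampling_rate_hz must be positive")
  if (recording_s <= 0) stop("recording_s must be positive")
  scales <- c(noise_sigma_uV, burst_base_uV, burst_gain_uV_per_mL,
              burst_dur_ms[1], saliva_effective_mL, lr_asymmetry)
  if (any(scales <= 0)) stop("all scale parameters must be positive")
  need <- c("cup", "bottle", "straw")
  if (!all(need %in% names(container_volume_dists)))
    stop("container_volume_dists needs cup, bottle and straw entries")
  mu <- vapply(container_volume_dists[need], `[`, numeric(1), 1L)
  if (!(mu["straw"] < mu["cup"] && mu["cup"] <= mu["bottle"]))
    stop("container means must be ordered straw < cup <= bottle")
  structure(list(
    sampling_rate_hz = sampling_rate_hz,
    recording_s = recording_s,
    noise_sigma_uV = noise_sigma_uV,
    burst_base_uV = burst_base_uV,
    burst_gain_uV_per_mL = burst_gain_uV_per_mL,
    burst_dur_ms = burst_dur_ms,
    container_volume_dists = container_volume_dists,
    saliva_effective_mL = saliva_effective_mL,
    lr_asymmetry = lr_asymmetry
  ), class = "synth_config")
}

# Band-limited Gaussian noise of length n, unit SD, with all spectral power
# inside [low_hz, high_hz]: white noise is synthesized in the frequency domain
# and bins outside the band are zeroed, so the band limit is exact.
band_limited_noise <- function(n, fs, low_hz = 20, high_hz = 400) {
  x <- stats::rnorm(n)
  X <- stats::fft(x)
  f <- (seq_len(n) - 1) * fs / n
  f <- pmin(f, fs - f)                      # fold to [0, fs/2]
  X[f < low_hz | f > high_hz] <- 0
  y <- Re(stats::fft(X, inverse = TRUE)) / n
  y / stats::sd(y)
}

#' Generate one synthetic two-channel swallow recording
#'
#' Each channel is Gaussian white noise plus one swallow burst: band-limited
#' (20-400 Hz) Gaussian noise shaped by a Hann envelope whose duration and peak
#' amplitude scale linearly with the sip volume. The burst centre is drawn
#' uniformly at least 2 s from either edge of the recording; the right channel
#' is the left burst scaled by the configured asymmetry, with independent
#' noise. The true burst centre is kept as ground truth for segmentation tests
#' only and is never read by the analysis pipeline.
#'
#' @param config A [synth_config()].
#' @param volume_mL Sip volume in mL; must be 0 for `task = "saliva"` (the
#'   saliva burst is driven by `config$saliva_effective_mL` instead).
#' @param task One of `"saliva"`, `"cup"`, `"bottle"`, `"straw"`, `"maxcap"`.
#' @param subject_id Identifier stored in the recording.
#' @return A list of class `emg_recording` with elements `left`, `right`
#'   (numeric, uV), `sampling_rate_hz`, `subject_id`, `task`, `sip_volume_mL`
#'   and `true_burst_center_s`.
#' @export
generate_recording <- function(config, volume_mL, task, subject_id = "S1") {
  stopifnot(inherits(config, "synth_config"))
  task <- match.arg(task, c("saliva", "cup", "bottle", "straw", "maxcap"))
  if (volume_mL < 0) stop("volume_mL must be non-negative")
  if ((task == "saliva") != (volume_mL == 0))
    stop("sip volume must be 0 exactly for saliva swallows")
  fs <- config$sampling_rate_hz
  n <- round(config$recording_s * fs)

  eff <- if (task == "saliva") config$saliva_effective_mL else volume_mL
  amp <- config$burst_base_uV + config$burst_gain_uV_per_mL * eff
  dur_ms <- min(config$burst_dur_ms[1] + config$burst_dur_ms[2] * eff, 1500)
  m <- max(round(dur_ms / 1000 * fs), 8)

  center_s <- stats::runif(1, 2, config$recording_s - 2)
  c_idx <- round(center_s * fs)
  env <- 0.5 * (1 - cos(2 * pi * (seq_len(m) - 1) / (m - 1)))   # Hann
  burst <- amp * env * band_limited_noise(m, fs)
  idx <- (c_idx - floor(m / 2)) + seq_len(m) - 1

  left <- stats::rnorm(n, sd = config$noise_sigma_uV)
  right <- stats::rnorm(n, sd = config$noise_sigma_uV)
  left[idx] <- left[idx] + burst
  right[idx] <- right[idx] + config$lr_asymmetry * burst

  structure(list(
    left = left, right = right,
    sampling_rate_hz = fs,
    subject_id = subject_id, task = task,
    sip_volume_mL = volume_mL,
    true_burst_center_s = c_idx / fs
  ), class = "emg_recording")
}

# Normal draw truncated below at `lower` by rejection (vectorized over n).
rtrunc_norm <- function(n, mean, sd, lower = 1) {
  out <- stats::rnorm(n, mean, sd)
  while (any(bad <- out < lower)) out[bad] <- stats::rnorm(sum(bad), mean, sd)
  out
}

#' Generate the 21 recordings of one subject's drinking protocol
#'
#' Produces 5 saliva swallows, 5 sips each from cup, bottle and straw with
#' volumes drawn from the configured container distributions (truncated at
#' 1 mL), and one maximum-capacity swallow whose volume is the largest cup
#' volume plus 5 mL.
#'
#' @inheritParams generate_recording
#' @return List of 21 `emg_recording` objects in task order
#'   (saliva, cup, bottle, straw, maxcap).
#' @export
generate_subject <- function(config, subject_id = "S1") {
  stopifnot(inherits(config, "synth_config"))
  vols <- list(
    cup = rtrunc_norm(5, config$container_volume_dists$cup[1],
                      config$container_volume_dists$cup[2]),
    bottle = rtrunc_norm(5, config$container_volume_dists$bottle[1],
                         config$container_volume_dists$bottle[2]),
    straw = rtrunc_norm(5, config$container_volume_dists$straw[1],
                        config$container_volume_dists$straw[2])
  )
  recs <- c(
    lapply(1:5, function(i) generate_recording(config, 0, "saliva", subject_id)),
    lapply(vols$cup, function(v) generate_recording(config, v, "cup", subject_id)),
    lapply(vols$bottle, function(v) generate_recording(config, v, "bottle", subject_id)),
    lapply(vols$straw, function(v) generate_recording(config, v, "straw", subject_id)),
    list(generate_recording(config, max(vols$cup) + 5, "maxcap", subject_id))
  )
  recs
}

#' Generate a seeded cohort of synthetic subjects
#'
#' Each subject gets a reproducible sub-seed derived from `seed`, so cohorts
#' are identical across runs and subjects have distinct noise realizations.
#'
#' @inheritParams generate_recording
#' @param n_subjects Number of subjects (>= 1).
#' @param seed Integer seed controlling the whole cohort.
#' @return A list with `recordings` (flat list of `emg_recording`) and
#'   `metadata` (data.frame: subject, task, volume_mL, recording index).
#' @export
generate_cohort <- function(config, n_subjects, seed) {
  stopifnot(inherits(config, "synth_config"), n_subjects >= 1)
  recs <- vector("list", 0L)
  for (s in seq_len(n_subjects)) {
    set.seed((seed + 7919L * s) %% .Machine$integer.max)
    recs <- c(recs, generate_subject(config, sprintf("S%02d", s)))
  }
  meta <- data.frame(
    recording = seq_along(recs),
    subject = vapply(recs, `[[`, character(1), "subject_id"),
    task = vapply(recs, `[[`, character(1), "task"),
    volume_mL = vapply(recs, `[[`, numeric(1), "sip_volume_mL"),
    stringsAsFactors = FALSE
  )
  list(recordings = recs, metadata = meta)
}

#' Write a cohort to disk as per-recording CSV files plus a metadata table
#'
#' Each recording becomes `<subject>_<task>_<k>.csv` with columns
#' `time_s, left_uV, right_uV`; the cohort metadata (subject, task, volume,
#' file) goes to `metadata.csv` in the same directory.
#'
#' @param cohort Result of [generate_cohort()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the metadata data.frame including file names.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  meta <- cohort$metadata
  counts <- stats::ave(seq_len(nrow(meta)), meta$subject, meta$task,
                       FUN = seq_along)
  meta$file <- sprintf("%s_%s_%d.csv", meta$subject, meta$task, counts)
  for (i in seq_len(nrow(meta))) {
    r <- cohort$recordings[[i]]
    df <- data.frame(
      time_s = (seq_along(r$left) - 1) / r$sampling_rate_hz,
      left_uV = r$left, right_uV = r$right
    )
    utils::write.csv(df, file.path(dir, meta$file[i]), row.names = FALSE)
  }
  utils::write.csv(meta, file.path(dir, "metadata.csv"), row.names = FALSE)
  invisible(meta)
}

#' Read one recording CSV written by [write_cohort()]
#'
#' @param path CSV with columns `time_s`, `left_uV`, `right_uV`.
#' @param subject_id,task,volume_mL Metadata to attach.
#' @return An `emg_recording` (without ground-truth burst centre).
#' @export
read_recording <- function(path, subject_id = NA_character_,
                           task = NA_character_, volume_mL = NA_real_) {
  df <- utils::read.csv(path)
  need <- c("time_s", "left_uV", "right_uV")
  if (!all(need %in% names(df)))
    stop("recording CSV must have columns time_s, left_uV, right_uV")
  fs <- 1 / stats::median(diff(df$time_s))
  structure(list(
    left = df$left_uV, right = df$right_uV,
    sampling_rate_hz = round(fs),
    subject_id = subject_id, task = task, sip_volume_mL = volume_mL,
    true_burst_center_s = NA_real_
  ), class = "emg_recording")
}
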