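#' Paradigm configuration for a seven-button oddball flash speller
#'
#' Holds the constants of the stimulation and acquisition setup: seven
#' directional buttons that flash (toggle to a highlight colour) for 100 ms
#' and back for 100 ms, 30 flashes per button during training selections and
#' 20 during online selections, 15 online selections per environment, and a
#' 7-channel dry-electrode montage (Fz, Pz, Oz, P3, P4, PO7, PO8) sampled at
#' 300 Hz against a left-ear reference.
#'
#' @param n_buttons Number of selectable buttons (>= 2).
#' @param flash_on_ms,flash_off_ms Highlight on/off durations in ms; their sum
#'   is the stimulus-onset asynchrony.
#' @param blinks_training,blinks_online Flashes per button in one training /
#'   online selection.
#' @param selections_per_env Online selections played per environment.
#' @param sampling_rate_hz Acquisition sampling rate in Hz.
#' @param channels Ordered, unique channel labels.
#' @param reference_label Label of the reference electrode (left ear).
#' @return An object of class `paradigm_config`.
#' @export
paradigm_config <- function(n_buttons = 7L,
                            flash_on_ms = 100,
                            flash_off_ms = 100,
                            blinks_training = 30L,
                            blinks_online = 20L,
                            selections_per_env = 15L,
                            sampling_rate_hz = 300,
                            channels = c("Fz", "Pz", "Oz", "P3", "P4", "PO7", "PO8"),
                            reference_label = "A1") {
  stopifnot_scalar_count(n_buttons, "n_buttons", min = 2)
  if (flash_on_ms + flash_off_ms <= 0) {
    stop("flash_on_ms + flash_off_ms must be positive", call. = FALSE)
  }
  if (anyDuplicated(channels)) stop("channel labels must be unique", call. = FALSE)
  if (sampling_rate_hz <= 0) stop("sampling_rate_hz must be positive", call. = FALSE)
  structure(list(
    n_buttons = as.integer(n_buttons),
    flash_on_ms = flash_on_ms,
    flash_off_ms = flash_off_ms,
    blinks_training = as.integer(blinks_training),
    blinks_online = as.integer(blinks_online),
    selections_per_env = as.integer(selections_per_env),
    sampling_rate_hz = sampling_rate_hz,
    channels = as.character(channels),
    reference_label = reference_label,
    soa_s = (flash_on_ms + flash_off_ms) / 1000
  ), class = "paradigm_config")
}

#' P300 response template
#'
#' Parametric target response added to the EEG at every target flash: a
#' Gaussian positivity with given peak amplitude, post-stimulus peak latency
#' and full width at half maximum, scaled per channel by a topography weight.
#' Defaults follow the grand-average P300 of the seven-button drone-selection
#' task this package models (5.09 microvolt peak at 415.88 ms) with a
#' parietally-dominant topography (maximal at Pz).
#'
#' @param peak_amplitude_uv Peak amplitude in microvolts (on a weight-1 channel).
#' @param peak_latency_ms Post-stimulus peak latency in ms; must lie inside the
#'   1 s epoch together with the width.
#' @param width_ms Full width at half maximum of the Gaussian bump, ms.
#' @param channel_weights Named per-channel scalars in \[0, 1\].
#' @return An object of class `erp_template`.
#' @export
erp_template <- function(peak_amplitude_uv = 5.09,
                         peak_latency_ms = 415.88,
                         width_ms = 60,
                         channel_weights = c(Fz = 0.5, Pz = 1.0, Oz = 0.7,
                                             P3 = 0.8, P4 = 0.8,
                                             PO7 = 0.6, PO8 = 0.6)) {
  if (width_ms <= 0) stop("width_ms must be positive", call. = FALSE)
  if (peak_latency_ms <= 0 || peak_latency_ms + width_ms > 1000) {
    stop("peak latency + width must fit inside the 1 s epoch", call. = FALSE)
  }
  if (!any(channel_weights > 0)) {
    stop("at least one channel weight must be positive", call. = FALSE)
  }
  structure(list(
    peak_amplitude_uv = peak_amplitude_uv,
    peak_latency_ms = peak_latency_ms,
    width_ms = width_ms,
    channel_weights = channel_weights
  ), class = "erp_template")
}

#' Background noise model for synthetic EEG
#'
#' Additive, seeded noise components chosen to exercise every preprocessing
#' stage: pink (1/f) background, broadband white noise, an alpha rhythm
#' (individual frequency drawn from 8.5-11.5 Hz, random phase, per channel),
#' a slow random-walk drift (removed by the
#' highpass), and optional localized high-amplitude transients emulating
#' electrode artifacts. Amplitudes are standard deviations (or, for alpha and
#' artifacts, peak amplitudes) in microvolts. The default level is calibrated
#' so that the full simulated decoder operates at roughly 85-95% selection
#' accuracy, the range reported for dry-electrode P300 BCIs of this design.
#'
#' In addition to the additive background, the model carries the
#' trial-to-trial variability of the evoked response itself — the main
#' reason real single-trial decoding is imperfect even when the averaged
#' ERP is clean: a per-flash multiplicative amplitude gain (lognormal, mean
#' 1, coefficient of variation `trial_gain_cv`) and a per-flash latency
#' jitter (Gaussian, SD `trial_jitter_ms`). Both average out over the
#' hundreds of target flashes that form an ERP waveform but degrade
#' single-selection classification. Set them to zero (with all amplitudes
#' zero) for a fully deterministic response.
#'
#' @param pink_sd_uv,white_sd_uv,drift_sd_uv Component standard deviations, uV.
#' @param alpha_amplitude_uv Peak amplitude of the alpha rhythm, uV.
#' @param artifact_rate_per_min Expected artifact transients per minute.
#' @param artifact_amplitude_uv Peak amplitude of one artifact transient, uV.
#' @param trial_gain_cv Coefficient of variation of the per-flash response
#'   gain (0 = deterministic amplitude).
#' @param trial_jitter_ms SD of the per-flash response latency jitter, ms.
#' @param seed Integer seed from which all noise draws flow.
#' @return An object of class `noise_model`.
#' @export
noise_model <- function(pink_sd_uv = 1.5,
                        white_sd_uv = 10,
                        alpha_amplitude_uv = 3,
                        drift_sd_uv = 1.5,
                        artifact_rate_per_min = 2,
                        artifact_amplitude_uv = 120,
                        trial_gain_cv = 0.5,
                        trial_jitter_ms = 5,
                        seed = 1L) {
  amps <- c(pink_sd_uv, white_sd_uv, alpha_amplitude_uv, drift_sd_uv,
            artifact_amplitude_uv, trial_gain_cv, trial_jitter_ms)
  if (any(amps < 0) || artifact_rate_per_min < 0) {
    stop("noise amplitudes and rates must be non-negative", call. = FALSE)
  }
  structure(list(
    pink_sd_uv = pink_sd_uv,
    white_sd_uv = white_sd_uv,
    alpha_amplitude_uv = alpha_amplitude_uv,
    drift_sd_uv = drift_sd_uv,
    artifact_rate_per_min = artifact_rate_per_min,
    artifact_amplitude_uv = artifact_amplitude_uv,
    trial_gain_cv = trial_gain_cv,
    trial_jitter_ms = trial_jitter_ms,
    seed = as.integer(seed)
  ), class = "noise_model")
}

#' Generate a random flash schedule for one selection
#'
#' Produces the ordered flash events of one selection: every button flashes
#' `n_blinks` times with a fixed stimulus-onset asynchrony
#' (`flash_on_ms + flash_off_ms`). Randomization is blockwise: each
#' consecutive round of `n_buttons` events is an independent permutation of
#' all buttons, which guarantees equal counts and bounds target-to-target
#' spacing (standard speller practice).
#'
#' @param config A [paradigm_config()].
#' @param n_blinks Flashes per button (30 training, 20 online).
#' @param target_button Attended button, 0-based index in `0:(n_buttons-1)`.
#' @param seed Integer seed; identical seeds give identical schedules.
#' @param selection_id Identifier copied onto every event.
#' @param environment One of `"VR"`, `"AR"`, `"NA"`.
#' @return A `bci_schedule`: a data frame with columns `onset_s`, `button`
#'   (0-based), `is_target`, `selection_id`, `environment`.
#' @export
generate_flash_schedule <- function(config, n_blinks, target_button, seed,
                                    selection_id = "sel1",
                                    environment = c("NA", "VR", "AR")) {
  environment <- match.arg(environment)
  stopifnot_scalar_count(n_blinks, "n_blinks", min = 1)
  if (!is.numeric(target_button) || length(target_button) != 1 ||
      target_button < 0 || target_button >= config$n_buttons) {
    stop(sprintf("target_button must be in 0..%d", config$n_buttons - 1),
         call. = FALSE)
  }
  nb <- config$n_buttons
  buttons <- with_seed(seed, {
    unlist(lapply(seq_len(n_blinks), function(i) sample.int(nb) - 1L))
  })
  n_events <- nb * as.integer(n_blinks)
  sched <- data.frame(
    onset_s = (seq_len(n_events) - 1) * config$soa_s,
    button = as.integer(buttons),
    is_target = as.integer(buttons) == as.integer(target_button),
    selection_id = as.character(selection_id),
    environment = environment,
    stringsAsFactors = FALSE
  )
  class(sched) <- c("bci_schedule", "data.frame")
  sched
}

# Target button of a single-selection schedule (NA if no target events).
schedule_target <- function(schedule) {
  t <- unique(schedule$button[schedule$is_target])
  if (length(t) == 0) NA_integer_ else t[1]
}

# One channel of background noise; draw order is fixed so the stream is
# reproducible and independent of which amplitudes are zero.
noise_channel <- function(n, fs, noise) {
  t <- (seq_len(n) - 1) / fs
  pink_raw <- stats::rnorm(n)
  white_raw <- stats::rnorm(n)
  phase <- stats::runif(1, 0, 2 * pi)
  # individual alpha frequency per channel; a rhythm at exactly half the
  # flash rate would be phase-locked to the stimuli and never average out
  freq <- stats::runif(1, 8.5, 11.5)
  drift_raw <- stats::rnorm(n)
  out <- numeric(n)
  if (noise$pink_sd_uv > 0) {
    f <- abs(seq(0, fs, length.out = n + 1)[seq_len(n)])
    f[f > fs / 2] <- fs - f[f > fs / 2]
    scale <- c(0, 1 / sqrt(f[-1]))
    p <- Re(stats::fft(stats::fft(pink_raw) * scale, inverse = TRUE)) / n
    out <- out + p / stats::sd(p) * noise$pink_sd_uv
  }
  if (noise$white_sd_uv > 0) out <- out + white_raw * noise$white_sd_uv
  if (noise$alpha_amplitude_uv > 0) {
    out <- out + noise$alpha_amplitude_uv * sin(2 * pi * freq * t + phase)
  }
  if (noise$drift_sd_uv > 0) {
    out <- out + cumsum(drift_raw) * noise$drift_sd_uv / sqrt(fs)
  }
  out
}

#' Synthesize a multi-channel EEG recording for a flash schedule
#'
#' Builds `channels x samples` EEG (in microvolts) containing the seeded
#' background noise of `noise` on every channel plus, at each target flash
#' onset, the Gaussian P300 bump of `template` scaled by the per-channel
#' topography weights. Non-target flashes add nothing. A separate reference
#' channel carries noise only. The recording extends 1.1 s past the last
#' onset so every epoch fits.
#'
#' @param schedule A `bci_schedule` for one selection.
#' @param template An [erp_template()].
#' @param noise A [noise_model()]; all randomness flows from `noise$seed`.
#' @param config A [paradigm_config()].
#' @param max_duration_s Refuse schedules longer than this (safety cap).
#' @return A `bci_recording`: list with `data` (channels x samples matrix),
#'   `sampling_rate_hz`, `channel_labels`, `reference` (noise-only series),
#'   `reference_label`, and the `schedule`.
#' @export
synthesize_recording <- function(schedule, template, noise, config,
                                 max_duration_s = 600) {
  fs <- config$sampling_rate_hz
  duration <- max(schedule$onset_s) + 1.1
  if (duration > max_duration_s) {
    stop(sprintf("schedule duration %.1f s exceeds max_duration_s = %.1f s",
                 duration, max_duration_s), call. = FALSE)
  }
  if (template$peak_latency_ms + template$width_ms > 1000) {
    stop("template latency + width must fit inside the 1 s epoch", call. = FALSE)
  }
  nc <- length(config$channels)
  n <- ceiling(duration * fs)
  chans <- with_seed(noise$seed, {
    lapply(seq_len(nc + 1), function(i) noise_channel(n, fs, noise))
  })
  data <- do.call(rbind, chans[seq_len(nc)])
  rownames(data) <- config$channels
  reference <- chans[[nc + 1]]

  w <- template$channel_weights[config$channels]
  w[is.na(w)] <- 0
  sigma_s <- template$width_ms / (2 * sqrt(2 * log(2))) / 1000
  ep_len <- round(fs)  # 1 s epoch
  if (template$peak_amplitude_uv != 0) {
    onsets <- schedule$onset_s[schedule$is_target]
    # per-flash response variability (mean-1 lognormal gain, latency jitter),
    # seeded independently of the channel-noise stream
    sdlog <- sqrt(log(1 + noise$trial_gain_cv^2))
    trial <- with_seed(derive_seed(noise$seed, 424243L), list(
      gain = exp(stats::rnorm(length(onsets), 0, sdlog) - sdlog^2 / 2),
      jitter = stats::rnorm(length(onsets), 0, noise$trial_jitter_ms)
    ))
    for (k in seq_along(onsets)) {
      i0 <- round(onsets[k] * fs) + 1
      idx <- i0:min(i0 + ep_len - 1, n)
      t_rel <- (idx - i0) / fs
      lat_s <- min(max(template$peak_latency_ms + trial$jitter[k],
                       template$width_ms),
                   1000 - template$width_ms) / 1000
      bump <- template$peak_amplitude_uv * trial$gain[k] *
        exp(-0.5 * ((t_rel - lat_s) / sigma_s)^2)
      data[, idx] <- data[, idx] + outer(as.numeric(w), bump)
    }
  }
  structure(list(
    data = data,
    sampling_rate_hz = fs,
    channel_labels = config$channels,
    reference = reference,
    reference_label = config$reference_label,
    schedule = schedule
  ), class = "bci_recording")
}

#' Add localized high-amplitude artifact transients to a recording
#'
#' Inserts seeded 100 ms half-sine transients of amplitude
#' `noise$artifact_amplitude_uv` on randomly chosen single channels, with an
#' expected count of `noise$artifact_rate_per_min` per minute (Poisson). A
#' rate of zero returns the recording unchanged. Used to exercise the
#' downstream amplitude-threshold rejection rules.
#'
#' @param recording A `bci_recording`.
#' @param noise A [noise_model()]; draws flow from a sub-seed of `noise$seed`.
#' @return The recording with artifacts added.
#' @export
inject_artifacts <- function(recording, noise) {
  if (noise$artifact_rate_per_min == 0) return(recording)
  fs <- recording$sampling_rate_hz
  n <- ncol(recording$data)
  nc <- nrow(recording$data)
  dur <- max(2, round(0.1 * fs))
  minutes <- n / fs / 60
  with_seed(derive_seed(noise$seed, 9973L), {
    k <- stats::rpois(1, noise$artifact_rate_per_min * minutes)
    if (k > 0) {
      shape <- noise$artifact_amplitude_uv * sin(pi * (seq_len(dur) - 1) / (dur - 1))
      for (j in seq_len(k)) {
        ch <- sample.int(nc, 1)
        start <- sample.int(n - dur + 1, 1)
        recording$data[ch, start:(start + dur - 1)] <-
          recording$data[ch, start:(start + dur - 1)] + shape
      }
    }
  })
  recording
}
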