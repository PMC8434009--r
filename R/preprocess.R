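#' Signal-processing pipeline configuration
#'
#' Constants of the six-stage decoding pipeline: re-referencing, 0.1-30 Hz
#' 5th-order Butterworth bandpass, 0-1000 ms epoching, whole-epoch baseline
#' correction, consecutive averaging of 20 epochs, and decimation to 100 Hz.
#'
#' `avg_mode` selects how "averaged continuously by 20 epochs" is realized:
#' `"sliding"` (step-1 overlapping windows; 30 training flashes per button
#' give 11 averaged exemplars) or `"block"` (non-overlapping; the 20 online
#' flashes per button give exactly one averaged epoch). `causal_filtering`
#' selects forward-only filtering (what an online system could compute, the
#' default) versus zero-phase forward-backward filtering (conventional for
#' offline ERP waveform analysis, since it does not delay the peak).
#'
#' @param band_low_hz,band_high_hz Bandpass edges in Hz.
#' @param filter_order Butterworth order of each edge filter.
#' @param epoch_start_ms,epoch_end_ms Epoch window relative to flash onset, ms.
#' @param avg_window Number of consecutive epochs per average.
#' @param avg_mode `"sliding"` or `"block"` (see Details).
#' @param resample_to_hz Target rate; must divide the sampling rate evenly.
#' @param causal_filtering Logical; forward-only filtering when `TRUE`.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(band_low_hz = 0.1,
                            band_high_hz = 30,
                            filter_order = 5L,
                            epoch_start_ms = 0,
                            epoch_end_ms = 1000,
                            avg_window = 20L,
                            avg_mode = c("sliding", "block"),
                            resample_to_hz = 100,
                            causal_filtering = TRUE) {
  avg_mode <- match.arg(avg_mode)
  if (band_low_hz <= 0 || band_low_hz >= band_high_hz) {
    stop("need 0 < band_low_hz < band_high_hz", call. = FALSE)
  }
  if (epoch_end_ms <= epoch_start_ms) {
    stop("epoch_end_ms must exceed epoch_start_ms", call. = FALSE)
  }
  stopifnot_scalar_count(avg_window, "avg_window", min = 1)
  structure(list(
    band_low_hz = band_low_hz,
    band_high_hz = band_high_hz,
    filter_order = as.integer(filter_order),
    epoch_start_ms = epoch_start_ms,
    epoch_end_ms = epoch_end_ms,
    avg_window = as.integer(avg_window),
    avg_mode = avg_mode,
    resample_to_hz = resample_to_hz,
    causal_filtering = causal_filtering
  ), class = "pipeline_config")
}

# Internal constructor for epoch sets.
new_epoch_set <- function(epochs, button, is_target, selection_id, environment,
                          fs, channel_labels, n_skipped = 0L) {
  structure(list(
    epochs = epochs,                 # n x channels x samples
    button = as.integer(button),
    is_target = as.logical(is_target),
    selection_id = as.character(selection_id),
    environment = as.character(environment),
    sampling_rate_hz = fs,
    channel_labels = channel_labels,
    n_skipped = as.integer(n_skipped)
  ), class = "bci_epochs")
}

#' Number of epochs in an epoch set
#' @param x A `bci_epochs` object.
#' @return Integer count.
#' @export
n_epochs <- function(x) dim(x$epochs)[1]

#' Concatenate epoch sets
#'
#' Binds epoch sets with identical channel layout and sampling rate along the
#' epoch dimension, preserving order.
#'
#' @param ... `bci_epochs` objects.
#' @return A combined `bci_epochs`.
#' @export
bind_epochs <- function(...) {
  sets <- list(...)
  if (length(sets) == 1 && is.list(sets[[1]]) && !inherits(sets[[1]], "bci_epochs")) {
    sets <- sets[[1]]
  }
  stopifnot(length(sets) >= 1)
  fs <- sets[[1]]$sampling_rate_hz
  labs <- sets[[1]]$channel_labels
  for (s in sets) {
    if (!identical(s$channel_labels, labs) || s$sampling_rate_hz != fs) {
      stop("epoch sets to bind must share channels and sampling rate", call. = FALSE)
    }
  }
  arr <- do.call(abind_epochs, lapply(sets, function(s) s$epochs))
  new_epoch_set(arr,
                unlist(lapply(sets, `[[`, "button")),
                unlist(lapply(sets, `[[`, "is_target")),
                unlist(lapply(sets, `[[`, "selection_id")),
                unlist(lapply(sets, `[[`, "environment")),
                fs, labs,
                sum(vapply(sets, `[[`, integer(1), "n_skipped")))
}

# rbind for n x ch x s arrays
abind_epochs <- function(...) {
  arrs <- list(...)
  d <- dim(arrs[[1]])[-1]
  total <- sum(vapply(arrs, function(a) dim(a)[1], numeric(1)))
  out <- array(0, dim = c(total, d))
  at <- 0
  for (a in arrs) {
    k <- dim(a)[1]
    if (k > 0) out[at + seq_len(k), , ] <- a
    at <- at + k
  }
  out
}

#' Re-reference a recording to its reference channel
#'
#' Subtracts the (left-ear) reference series from every channel; the
#' reference is removed from the output.
#'
#' @param recording A `bci_recording` with a `reference` series.
#' @return The re-referenced recording (reference set to `NULL`).
#' @export
rereference <- function(recording) {
  if (is.null(recording$reference)) {
    stop("recording has no reference channel to re-reference against", call. = FALSE)
  }
  if (length(recording$reference) != ncol(recording$data)) {
    stop("reference series length must match the data", call. = FALSE)
  }
  recording$data <- sweep(recording$data, 2, recording$reference, `-`)
  # keep the element (as NULL) so later `$reference` access cannot
  # partially match `reference_label`
  recording["reference"] <- list(NULL)
  recording
}

# Cascaded Butterworth design. A single 2*order transfer-function bandpass
# with a 0.1 Hz edge at 300 Hz is numerically unstable, so the band is
# realized as highpass(order) followed by lowpass(order).
design_bandpass <- function(config, fs) {
  if (config$band_high_hz >= fs / 2) {
    stop("band_high_hz must be below the Nyquist frequency", call. = FALSE)
  }
  list(
    hp = signal::butter(config$filter_order, config$band_low_hz / (fs / 2),
                        type = "high"),
    lp = signal::butter(config$filter_order, config$band_high_hz / (fs / 2),
                        type = "low")
  )
}

#' Bandpass-filter a continuous recording
#'
#' Applies the 0.1-30 Hz Butterworth bandpass (as a stable cascade of a
#' highpass and a lowpass of `filter_order` each) along time to every
#' channel. Forward-only (causal) by default; forward-backward (zero-phase)
#' when `config$causal_filtering` is `FALSE`.
#'
#' @param recording A `bci_recording` sampled above 60 Hz.
#' @param config A [pipeline_config()].
#' @return The filtered recording (same length).
#' @export
bandpass <- function(recording, config) {
  fs <- recording$sampling_rate_hz
  if (fs <= 60) stop("recording must be sampled above 60 Hz", call. = FALSE)
  flt <- design_bandpass(config, fs)
  apply_flt <- if (isTRUE(config$causal_filtering)) {
    function(x) as.numeric(signal::filter(flt$lp, signal::filter(flt$hp, x)))
  } else {
    function(x) as.numeric(signal::filtfilt(flt$lp, signal::filtfilt(flt$hp, x)))
  }
  recording$data <- t(apply(recording$data, 1, apply_flt))
  rownames(recording$data) <- recording$channel_labels
  if (!is.null(recording$reference)) {
    recording$reference <- apply_flt(recording$reference)
  }
  recording
}

#' Segment a recording into per-flash epochs
#'
#' Cuts one epoch per schedule event, `epoch_start_ms`-`epoch_end_ms`
#' relative to flash onset (default 0-1000 ms: 300 samples at 300 Hz, first
#' sample at the onset sample). Events whose epoch would run past the end of
#' the recording are skipped with a warning; the skip count is kept on the
#' result.
#'
#' @param recording A `bci_recording` with a schedule.
#' @param config A [pipeline_config()].
#' @return A `bci_epochs` with per-epoch button/target/provenance labels.
#' @export
extract_epochs <- function(recording, config) {
  fs <- recording$sampling_rate_hz
  sched <- recording$schedule
  ns <- round((config$epoch_end_ms - config$epoch_start_ms) / 1000 * fs)
  off <- round(config$epoch_start_ms / 1000 * fs)
  nc <- nrow(recording$data)
  ntot <- ncol(recording$data)
  i0 <- round(sched$onset_s * fs) + 1 + off
  keep <- i0 >= 1 & (i0 + ns - 1) <= ntot
  if (any(!keep)) {
    warning(sprintf("%d event(s) truncated by the recording end were skipped",
                    sum(!keep)))
  }
  idx_keep <- which(keep)
  arr <- array(0, dim = c(length(idx_keep), nc, ns))
  for (j in seq_along(idx_keep)) {
    s <- i0[idx_keep[j]]
    arr[j, , ] <- recording$data[, s:(s + ns - 1)]
  }
  new_epoch_set(arr,
                sched$button[idx_keep],
                sched$is_target[idx_keep],
                sched$selection_id[idx_keep],
                sched$environment[idx_keep],
                fs, recording$channel_labels,
                n_skipped = sum(!keep))
}

#' Baseline-correct epochs by whole-epoch mean subtraction
#'
#' Subtracts, per epoch and per channel, the temporal mean over the whole
#' epoch window. With a 0 ms epoch start there is no pre-stimulus interval,
#' so the entire 0-1000 ms window serves as the baseline; this compensates
#' the random amplitude shifts (impedance changes, drift) that dry
#' electrodes are prone to. Idempotent.
#'
#' @param epochs A `bci_epochs`.
#' @return Baseline-corrected `bci_epochs` (every epoch-channel mean is 0).
#' @export
baseline_correct <- function(epochs) {
  if (n_epochs(epochs) == 0) return(epochs)
  means <- apply(epochs$epochs, c(1, 2), mean)
  epochs$epochs <- epochs$epochs - as.vector(means)  # recycles over dim 3
  epochs
}

#' Average consecutive epochs within each button's sequence
#'
#' Groups epochs by (selection, button) in onset order and averages
#' `avg_window` consecutive epochs to improve signal-to-noise ratio. In
#' `"sliding"` mode overlapping windows step by 1 (m epochs yield
#' `max(m - avg_window + 1, 0)` averages); in `"block"` mode windows do not
#' overlap (m = avg_window yields exactly one). Groups smaller than the
#' window contribute no output. Averaging never crosses selections.
#'
#' @param epochs A `bci_epochs`.
#' @param config A [pipeline_config()].
#' @return A `bci_epochs` of averaged epochs with inherited labels.
#' @export
consecutive_average <- function(epochs, config) {
  W <- config$avg_window
  n <- n_epochs(epochs)
  nc <- dim(epochs$epochs)[2]
  ns <- dim(epochs$epochs)[3]
  out <- list(); lab <- list()
  sels <- unique(epochs$selection_id)
  for (s in sels) {
    for (b in sort(unique(epochs$button[epochs$selection_id == s]))) {
      idx <- which(epochs$selection_id == s & epochs$button == b)
      m <- length(idx)
      starts <- if (config$avg_mode == "sliding") {
        if (m >= W) seq_len(m - W + 1) else integer(0)
      } else {
        if (m >= W) seq(1, m - W + 1, by = W) else integer(0)
      }
      if (length(starts) == 0 && m > 0) {
        message(sprintf("group (%s, button %d): %d epoch(s) < window %d, no output",
                        s, b, m, W))
      }
      for (st in starts) {
        win <- idx[st:(st + W - 1)]
        out[[length(out) + 1]] <-
          colMeans(epochs$epochs[win, , , drop = FALSE], dims = 1)
        lab[[length(lab) + 1]] <- list(
          button = b,
          is_target = epochs$is_target[idx[1]],
          selection_id = s,
          environment = epochs$environment[idx[1]]
        )
      }
    }
  }
  k <- length(out)
  arr <- array(0, dim = c(k, nc, ns))
  for (j in seq_len(k)) arr[j, , ] <- out[[j]]
  new_epoch_set(arr,
                vapply(lab, `[[`, numeric(1), "button"),
                vapply(lab, `[[`, logical(1), "is_target"),
                vapply(lab, `[[`, character(1), "selection_id"),
                vapply(lab, `[[`, character(1), "environment"),
                epochs$sampling_rate_hz, epochs$channel_labels,
                epochs$n_skipped)
}

#' Decimate epochs to a lower sampling rate
#'
#' Keeps every k-th sample starting at the first (k = original rate /
#' `resample_to_hz`, which must be an integer). No additional anti-alias
#' filtering is applied: the preceding 30 Hz lowpass already bounds the
#' content well below the new Nyquist frequency.
#'
#' @param epochs A `bci_epochs`.
#' @param config A [pipeline_config()].
#' @return Decimated `bci_epochs` at `resample_to_hz`.
#' @export
resample_epochs <- function(epochs, config) {
  k <- epochs$sampling_rate_hz / config$resample_to_hz
  if (abs(k - round(k)) > 1e-9) {
    stop("sampling rate must be an integer multiple of resample_to_hz", call. = FALSE)
  }
  k <- round(k)
  idx <- seq(1, dim(epochs$epochs)[3], by = k)
  epochs$epochs <- epochs$epochs[, , idx, drop = FALSE]
  epochs$sampling_rate_hz <- config$resample_to_hz
  epochs
}

#' Run the full six-stage preprocessing pipeline
#'
#' Composition, in order: [rereference()], [bandpass()], [extract_epochs()],
#' [baseline_correct()], [consecutive_average()], [resample_epochs()].
#' Produces the classifier-ready feature epochs (7 channels x 100 samples
#' under the defaults).
#'
#' @param recording A `bci_recording` with schedule and reference.
#' @param config A [pipeline_config()].
#' @return A `bci_epochs` of averaged, decimated feature epochs.
#' @export
run_pipeline <- function(recording, config) {
  recording |>
    rereference() |>
    bandpass(config) |>
    extract_epochs(config) |>
    baseline_correct() |>
    consecutive_average(config) |>
    resample_epochs(config)
}
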