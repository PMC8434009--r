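#' Write flash schedules to an events file
#'
#' Tab-separated events with a header row and columns `onset_s` (6
#' decimals), `button`, `is_target`, `selection_id`, `environment`.
#'
#' @param schedules One `bci_schedule` or a list of them.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_events <- function(schedules, path) {
  if (inherits(schedules, "bci_schedule")) schedules <- list(schedules)
  df <- do.call(rbind, lapply(schedules, as.data.frame))
  df$onset_s <- sprintf("%.6f", df$onset_s)
  df$is_target <- as.integer(df$is_target)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read flash schedules from an events file
#'
#' Parses the tab-separated events dialect of [write_events()], validates
#' per-selection invariants (strictly increasing onsets; target flags
#' consistent with a single target button), and splits by selection.
#'
#' @param path Events file path.
#' @return A single `bci_schedule` if the file holds one selection, else a
#'   list of them (in order of appearance).
#' @export
read_events <- function(path) {
  df <- tryCatch(
    utils::read.delim(path, stringsAsFactors = FALSE,
                      colClasses = c(onset_s = "numeric", button = "integer",
                                     is_target = "integer",
                                     selection_id = "character",
                                     environment = "character")),
    error = function(e) stop(sprintf("malformed events file '%s': %s",
                                     path, conditionMessage(e)), call. = FALSE)
  )
  need <- c("onset_s", "button", "is_target", "selection_id", "environment")
  if (!all(need %in% names(df))) {
    stop(sprintf("events file must have columns: %s", paste(need, collapse = ", ")),
         call. = FALSE)
  }
  df$is_target <- as.logical(df$is_target)
  out <- list()
  for (sid in unique(df$selection_id)) {
    s <- df[df$selection_id == sid, need]
    rownames(s) <- NULL
    if (nrow(s) > 1 && any(diff(s$onset_s) <= 0)) {
      bad <- which(diff(s$onset_s) <= 0)[1] + 1
      stop(sprintf("non-increasing onset at line %d (selection %s)",
                   bad + 1, sid), call. = FALSE)
    }
    tb <- unique(s$button[s$is_target])
    if (length(tb) > 1 || (length(tb) == 1 && !identical(s$is_target, s$button == tb))) {
      stop(sprintf("inconsistent target flags in selection %s", sid), call. = FALSE)
    }
    class(s) <- c("bci_schedule", "data.frame")
    out[[length(out) + 1]] <- s
  }
  if (length(out) == 1) out[[1]] else out
}

#' Load the packaged per-subject result tables
#'
#' Reads the two packaged per-subject CSV transcriptions — accuracy /
#' 3D-sickness / preference, and P300 peak latency / amplitude per
#' environment — and joins them by subject id into one record per subject
#' (17 subjects; 3 of the original 20 were excluded for heavy EEG noise).
#'
#' @param dir Directory holding `table3.csv` and `table4.csv`; defaults to
#'   the copies shipped with the package.
#' @return Data frame with one row per subject: `subject`, `acc_vr`,
#'   `acc_ar`, `sickness_vr`, `sickness_ar`, `preference`, `lat_vr`,
#'   `lat_ar`, `amp_vr`, `amp_ar`.
#' @export
read_fixture_tables <- function(dir = system.file("extdata", package = "erpbci")) {
  f3 <- file.path(dir, "table3.csv")
  f4 <- file.path(dir, "table4.csv")
  if (!file.exists(f3) || !file.exists(f4)) {
    stop("both table3.csv and table4.csv must be present", call. = FALSE)
  }
  t3 <- utils::read.csv(f3, stringsAsFactors = FALSE)
  t4 <- utils::read.csv(f4, stringsAsFactors = FALSE)
  if (anyDuplicated(t3$subject) || anyDuplicated(t4$subject)) {
    stop("duplicated subject id in fixture tables", call. = FALSE)
  }
  if (!setequal(t3$subject, t4$subject)) {
    only <- c(setdiff(t3$subject, t4$subject), setdiff(t4$subject, t3$subject))
    stop(sprintf("subject(s) present in one table only: %s",
                 paste(only, collapse = ", ")), call. = FALSE)
  }
  merge(t3, t4, by = "subject", sort = FALSE)
}

#' Write a recording to plain files
#'
#' Saves the sample matrix as CSV (samples x channels, with the reference as
#' a final `REF` column when present), a YAML metadata sidecar (sampling
#' rate, channel labels, reference label), and the schedule as an events
#' file.
#'
#' @param recording A `bci_recording`.
#' @param prefix Path prefix; writes `<prefix>.csv`, `<prefix>.yaml`,
#'   `<prefix>.events.tsv`.
#' @return `prefix`, invisibly.
#' @export
write_recording <- function(recording, prefix) {
  df <- as.data.frame(t(recording$data))
  names(df) <- recording$channel_labels
  if (!is.null(recording$reference)) df$REF <- recording$reference
  utils::write.csv(df, paste0(prefix, ".csv"), row.names = FALSE)
  yaml::write_yaml(list(
    sampling_rate_hz = recording$sampling_rate_hz,
    channel_labels = as.list(recording$channel_labels),
    reference_label = recording$reference_label,
    has_reference = !is.null(recording$reference)
  ), paste0(prefix, ".yaml"))
  write_events(recording$schedule, paste0(prefix, ".events.tsv"))
  invisible(prefix)
}

#' Read a recording written by [write_recording()]
#'
#' @param prefix Path prefix used at write time.
#' @return A `bci_recording`.
#' @export
read_recording <- function(prefix) {
  meta <- yaml::read_yaml(paste0(prefix, ".yaml"))
  df <- utils::read.csv(paste0(prefix, ".csv"), check.names = FALSE)
  labels <- unlist(meta$channel_labels)
  reference <- if (isTRUE(meta$has_reference)) df$REF else NULL
  data <- t(as.matrix(df[, labels, drop = FALSE]))
  rownames(data) <- labels
  sched <- read_events(paste0(prefix, ".events.tsv"))
  if (is.list(sched) && !inherits(sched, "bci_schedule")) sched <- sched[[1]]
  structure(list(
    data = data,
    sampling_rate_hz = meta$sampling_rate_hz,
    channel_labels = labels,
    reference = reference,
    reference_label = meta$reference_label,
    schedule = sched
  ), class = "bci_recording")
}

#' Write an epoch set to a directory
#'
#' Persists epochs as `epochs.csv` (one row per epoch, flattened
#' channels-fastest), `labels.csv` (button, target flag, provenance) and a
#' `meta.yaml` sidecar (dimensions, rate, channel labels).
#'
#' @param epochs A `bci_epochs`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_epochs <- function(epochs, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  X <- flatten_epochs(epochs)
  utils::write.table(X, file.path(dir, "epochs.csv"), sep = ",",
                     row.names = FALSE, col.names = FALSE)
  utils::write.csv(data.frame(
    button = epochs$button,
    is_target = as.integer(epochs$is_target),
    selection_id = epochs$selection_id,
    environment = epochs$environment,
    stringsAsFactors = FALSE
  ), file.path(dir, "labels.csv"), row.names = FALSE)
  yaml::write_yaml(list(
    n_epochs = n_epochs(epochs),
    n_channels = dim(epochs$epochs)[2],
    n_samples = dim(epochs$epochs)[3],
    sampling_rate_hz = epochs$sampling_rate_hz,
    channel_labels = as.list(epochs$channel_labels),
    n_skipped = epochs$n_skipped
  ), file.path(dir, "meta.yaml"))
  invisible(dir)
}

#' Read an epoch set written by [write_epochs()]
#'
#' @param dir Directory written by [write_epochs()].
#' @return A `bci_epochs`.
#' @export
read_epochs <- function(dir) {
  meta <- yaml::read_yaml(file.path(dir, "meta.yaml"))
  lab <- utils::read.csv(file.path(dir, "labels.csv"), stringsAsFactors = FALSE)
  X <- as.matrix(utils::read.table(file.path(dir, "epochs.csv"), sep = ","))
  arr <- array(X, dim = c(meta$n_epochs, meta$n_channels, meta$n_samples))
  new_epoch_set(arr, lab$button, as.logical(lab$is_target), lab$selection_id,
                lab$environment, meta$sampling_rate_hz,
                unlist(meta$channel_labels), meta$n_skipped)
}

#' Serialize a trained discriminant model to one portable JSON file
#'
#' @param model A `bci_lda`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_model <- function(model, path) {
  jsonlite::write_json(list(
    weights = model$weights,
    bias = model$bias,
    feature_shape = model$feature_shape,
    regularization = model$regularization,
    shrinkage = model$shrinkage,
    channel_labels = model$channel_labels
  ), path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' Read a discriminant model written by [write_model()]
#'
#' @param path Model file path.
#' @return A `bci_lda`.
#' @export
read_model <- function(path) {
  m <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(
    weights = as.numeric(m$weights),
    bias = m$bias,
    feature_shape = as.integer(m$feature_shape),
    regularization = m$regularization,
    shrinkage = m$shrinkage,
    channel_labels = m$channel_labels
  ), class = "bci_lda")
}
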