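#' Quality-control configuration
#'
#' Thresholds of the three-level noise-rejection rules: an epoch is bad when
#' its maximum absolute amplitude strictly exceeds 80 microvolts (beyond the
#' conventional P300 range); a selection is contaminated when bad epochs
#' strictly exceed 50% of its epochs; a subject is excluded when at least 10
#' of the 15 selections in either environment are contaminated.
#'
#' @param epoch_amp_threshold_uv Amplitude threshold in microvolts (strict).
#' @param selection_bad_fraction Fraction of bad epochs above which a
#'   selection is contaminated (strict).
#' @param subject_bad_selections Contaminated-selection count at or above
#'   which a subject is excluded (inclusive).
#' @param selections_per_env Selections per environment.
#' @return An object of class `qc_config`.
#' @export
qc_config <- function(epoch_amp_threshold_uv = 80,
                      selection_bad_fraction = 0.5,
                      subject_bad_selections = 10L,
                      selections_per_env = 15L) {
  if (epoch_amp_threshold_uv <= 0) stop("threshold must be positive", call. = FALSE)
  if (selection_bad_fraction <= 0 || selection_bad_fraction >= 1) {
    stop("selection_bad_fraction must be in (0, 1)", call. = FALSE)
  }
  if (subject_bad_selections <= 0 || subject_bad_selections > selections_per_env) {
    stop("subject_bad_selections must be in 1..selections_per_env", call. = FALSE)
  }
  structure(list(
    epoch_amp_threshold_uv = epoch_amp_threshold_uv,
    selection_bad_fraction = selection_bad_fraction,
    subject_bad_selections = as.integer(subject_bad_selections),
    selections_per_env = as.integer(selections_per_env)
  ), class = "qc_config")
}

#' Flag poorly measured epochs by amplitude threshold
#'
#' An epoch is bad iff the maximum absolute value over all its channels and
#' samples strictly exceeds the threshold (80 microvolts by default; a max of
#' exactly 80 is good). Applied to baseline-corrected, pre-averaging epochs,
#' where artifacts are not yet diluted.
#'
#' @param epochs A `bci_epochs`.
#' @param qc A [qc_config()].
#' @return Logical vector, one flag per epoch.
#' @export
flag_bad_epochs <- function(epochs, qc = qc_config()) {
  n <- n_epochs(epochs)
  if (n == 0) stop("no epochs to flag", call. = FALSE)
  vapply(seq_len(n),
         function(i) max(abs(epochs$epochs[i, , ])) > qc$epoch_amp_threshold_uv,
         logical(1))
}

#' Is a selection noise-contaminated?
#'
#' A selection is contaminated iff its bad-epoch count strictly exceeds
#' `selection_bad_fraction` of its total epochs (70 of 140 is clean, 71 is
#' contaminated).
#'
#' @param flags Logical per-epoch bad flags for one selection.
#' @param qc A [qc_config()].
#' @return Single logical.
#' @export
flag_contaminated_selection <- function(flags, qc = qc_config()) {
  sum(flags) > qc$selection_bad_fraction * length(flags)
}

#' Should a subject be excluded?
#'
#' A subject is excluded iff, in at least one environment, the number of
#' contaminated selections reaches `subject_bad_selections` (at least 10 of
#' 15 by default; inclusive).
#'
#' @param contaminated_by_env Named list (or list-like) of logical
#'   contaminated flags per environment.
#' @param qc A [qc_config()].
#' @return Single logical.
#' @export
should_exclude_subject <- function(contaminated_by_env, qc = qc_config()) {
  any(vapply(contaminated_by_env,
             function(f) sum(f) >= qc$subject_bad_selections, logical(1)))
}

#' Full three-level quality-control report
#'
#' Applies the epoch, selection, and subject rules to a set of
#' (baseline-corrected, pre-averaging) epochs spanning one subject's
#' selections, grouped by environment and selection id.
#'
#' @param epochs A `bci_epochs` with selection/environment provenance.
#' @param qc A [qc_config()].
#' @return A `bci_qc_report`: per-epoch flags, a per-selection table
#'   (environment, selection, epoch counts, contaminated), contaminated
#'   counts per environment, and the subject exclusion verdict.
#' @export
qc_report <- function(epochs, qc = qc_config()) {
  bad <- flag_bad_epochs(epochs, qc)
  key <- paste(epochs$environment, epochs$selection_id, sep = "\r")
  sel_keys <- unique(key)
  sel <- data.frame(
    environment = vapply(strsplit(sel_keys, "\r"), `[[`, character(1), 1),
    selection_id = vapply(strsplit(sel_keys, "\r"), `[[`, character(1), 2),
    n_epochs = vapply(sel_keys, function(k) sum(key == k), integer(1)),
    n_bad = vapply(sel_keys, function(k) sum(bad[key == k]), integer(1)),
    row.names = NULL, stringsAsFactors = FALSE
  )
  sel$contaminated <- vapply(seq_len(nrow(sel)), function(i) {
    flag_contaminated_selection(bad[key == sel_keys[i]], qc)
  }, logical(1))
  envs <- unique(sel$environment)
  cont_by_env <- lapply(envs, function(e) sel$contaminated[sel$environment == e])
  names(cont_by_env) <- envs
  structure(list(
    epoch_bad = bad,
    selections = sel,
    contaminated_per_env = vapply(cont_by_env, sum, integer(1)),
    subject_excluded = should_exclude_subject(cont_by_env, qc),
    n_epochs = length(bad),
    n_bad_epochs = sum(bad)
  ), class = "bci_qc_report")
}
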