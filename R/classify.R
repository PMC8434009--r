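# Flatten an n x channels x samples epoch array into an n x (channels*samples)
# feature matrix (channel-fastest order, matching the array layout).
flatten_epochs <- function(epochs) {
  d <- dim(epochs$epochs)
  matrix(epochs$epochs, nrow = d[1], ncol = d[2] * d[3])
}

#' Train a two-class linear discriminant on target/non-target epochs
#'
#' Fits a binary linear discriminant analysis (LDA) on the flattened
#' (channels x samples) feature epochs, oriented so that larger discriminant
#' outputs mean "more target-like". Because the feature dimension (700 under
#' the default pipeline) far exceeds the number of averaged training
#' exemplars, the pooled covariance is regularized by analytic Ledoit-Wolf
#' shrinkage toward the scaled identity (`regularization = "shrinkage"`,
#' default); a Moore-Penrose pseudo-inverse of the pooled sample covariance
#' is available for comparison (`"pseudo-inverse"`).
#'
#' @param features A `bci_epochs` containing both target and non-target
#'   epochs (the training session's averaged exemplars).
#' @param regularization `"shrinkage"` or `"pseudo-inverse"`.
#' @return A `bci_lda` model: `weights` over the flattened feature space,
#'   `bias`, `feature_shape`, `regularization`, and the fitted shrinkage
#'   intensity.
#' @export
train_lda <- function(features, regularization = c("shrinkage", "pseudo-inverse")) {
  regularization <- match.arg(regularization)
  y <- features$is_target
  if (length(unique(y)) < 2) {
    stop("training requires both target and non-target epochs", call. = FALSE)
  }
  X <- flatten_epochs(features)
  p <- ncol(X)
  mu1 <- colMeans(X[y, , drop = FALSE])
  mu0 <- colMeans(X[!y, , drop = FALSE])
  Xc <- X
  Xc[y, ] <- sweep(X[y, , drop = FALSE], 2, mu1, `-`)
  Xc[!y, ] <- sweep(X[!y, , drop = FALSE], 2, mu0, `-`)
  n <- nrow(X)
  S <- crossprod(Xc) / n
  rho <- NA_real_
  if (regularization == "shrinkage") {
    m <- sum(diag(S)) / p
    norm_S2 <- sum(S * S)
    d2 <- norm_S2 - p * m^2
    if (d2 <= .Machine$double.eps) {
      # covariance already (a multiple of) the identity; nothing to shrink
      Sstar <- S + diag(max(m, 1e-12) * 1e-8, p)
      rho <- 0
    } else {
      sq <- rowSums(Xc^2)
      b2bar <- sum(sq^2) / n^2 - norm_S2 / n
      rho <- max(0, min(1, b2bar / d2))
      Sstar <- (1 - rho) * S
      diag(Sstar) <- diag(Sstar) + rho * m
    }
    w <- solve(Sstar, mu1 - mu0)
  } else {
    w <- MASS::ginv(S) %*% (mu1 - mu0)
    w <- as.numeric(w)
  }
  if (!all(is.finite(w))) stop("non-finite discriminant weights", call. = FALSE)
  bias <- -sum(w * (mu1 + mu0)) / 2
  structure(list(
    weights = as.numeric(w),
    bias = bias,
    feature_shape = dim(features$epochs)[2:3],
    regularization = regularization,
    shrinkage = rho,
    channel_labels = features$channel_labels
  ), class = "bci_lda")
}

#' Score epochs with a trained discriminant
#'
#' Affine discriminant output per epoch: `weights . flattened_epoch + bias`.
#' Larger scores are more target-like.
#'
#' @param model A `bci_lda`.
#' @param features A `bci_epochs` whose epoch shape matches
#'   `model$feature_shape`.
#' @return Numeric vector of per-epoch scores.
#' @export
score_epochs <- function(model, features) {
  d <- dim(features$epochs)[2:3]
  if (!all(d == model$feature_shape)) {
    stop(sprintf("epoch shape (%d x %d) does not match model feature shape (%d x %d)",
                 d[1], d[2], model$feature_shape[1], model$feature_shape[2]),
         call. = FALSE)
  }
  as.numeric(flatten_epochs(features) %*% model$weights + model$bias)
}

#' Decide the selected button from per-epoch scores
#'
#' Sums the discriminant outputs over each button's epochs and selects the
#' button with the highest sum; exact ties break to the lowest button index.
#'
#' @param scores Numeric per-epoch scores.
#' @param buttons Per-epoch 0-based button labels (same length as `scores`).
#' @param true_button Optional attended button for later accuracy scoring.
#' @param n_buttons Number of buttons that must all be represented.
#' @return A `bci_selection`: summed `scores` (named by button),
#'   `predicted_button`, `true_button`, `n_epochs_used`.
#' @export
decide_selection <- function(scores, buttons, true_button = NULL, n_buttons = 7L) {
  stopifnot(length(scores) == length(buttons))
  all_b <- seq_len(n_buttons) - 1L
  missing <- setdiff(all_b, unique(as.integer(buttons)))
  if (length(missing) > 0) {
    stop(sprintf("no scored epochs for button(s): %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  sums <- vapply(all_b, function(b) sum(scores[buttons == b]), numeric(1))
  counts <- vapply(all_b, function(b) sum(buttons == b), integer(1))
  names(sums) <- names(counts) <- all_b
  structure(list(
    scores = sums,
    predicted_button = all_b[which.max(sums)],  # first max = lowest index
    true_button = if (is.null(true_button)) NA_integer_ else as.integer(true_button),
    n_epochs_used = counts
  ), class = "bci_selection")
}

#' Selection accuracy as a percentage
#'
#' `100 * (#correct / #selections)`, reported to 2 decimals (half away from
#' zero). Every result must carry a true button.
#'
#' @param results List of `bci_selection` objects with `true_button` set.
#' @return Accuracy percentage (2 dp).
#' @export
evaluate_accuracy <- function(results) {
  if (length(results) == 0) stop("no selection results to evaluate", call. = FALSE)
  truth <- vapply(results, `[[`, integer(1), "true_button")
  if (anyNA(truth)) stop("every selection result needs a true_button", call. = FALSE)
  pred <- vapply(results, `[[`, integer(1), "predicted_button")
  round_half_up(100 * mean(pred == truth), 2)
}
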