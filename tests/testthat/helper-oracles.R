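# Independent brute-force oracles and small construction helpers shared by
# the test files. The oracles deliberately use direct enumeration, never the
# package's own algorithms.

# Two-sided signed-rank p by full enumeration of all 2^n sign assignments
# (midranks for tied |d|; zero differences must be removed by the caller).
oracle_signed_rank <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  W <- sum(r[d > 0])
  ws <- vapply(0:(2^n - 1), function(mask) {
    signs <- bitwAnd(bitwShiftR(mask, 0:(n - 1)), 1L) == 1L
    sum(r[signs])
  }, numeric(1))
  p_le <- mean(ws <= W + 1e-9)
  p_ge <- mean(ws >= W - 1e-9)
  list(W = W, p = min(1, 2 * min(p_le, p_ge)))
}

# Two-sided rank-sum p by full enumeration of all choose(N, na) labelings.
oracle_rank_sum <- function(a, b) {
  na <- length(a)
  r <- rank(c(a, b))
  W <- sum(r[seq_len(na)])
  combs <- utils::combn(length(r), na)
  ws <- apply(combs, 2, function(idx) sum(r[idx]))
  p_le <- mean(ws <= W + 1e-9)
  p_ge <- mean(ws >= W - 1e-9)
  list(W = W, p = min(1, 2 * p_le, 2 * p_ge))
}

# Hand step-up Benjamini-Hochberg: sort, p * m / i, running minimum from the
# largest rank down, cap at 1, restore input order.
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- p[o] * m / seq_len(m)
  q <- rev(cummin(rev(q)))
  q <- pmin(q, 1)
  out <- numeric(m)
  out[o] <- q
  out
}

# Construct a bci_epochs object from an n x channels x samples array.
make_epochs <- function(arr, button = rep(0L, dim(arr)[1]),
                        is_target = rep(TRUE, dim(arr)[1]),
                        selection_id = rep("s1", dim(arr)[1]),
                        environment = rep("NA", dim(arr)[1]),
                        fs = 100,
                        channel_labels = paste0("ch", seq_len(dim(arr)[2]))) {
  erpbci:::new_epoch_set(arr, button, is_target, selection_id, environment,
                         fs, channel_labels)
}

# Construct a minimal bci_recording.
make_recording <- function(data, fs = 300, reference = NULL, schedule = NULL,
                           channel_labels = paste0("ch", seq_len(nrow(data)))) {
  rownames(data) <- channel_labels
  structure(list(
    data = data,
    sampling_rate_hz = fs,
    channel_labels = channel_labels,
    reference = reference,
    reference_label = "A1",
    schedule = schedule
  ), class = "bci_recording")
}

# Hand-built flash schedule (bypasses the generator's invariants on purpose).
make_schedule <- function(onset_s, button, target_button,
                          selection_id = "s1", environment = "NA") {
  sched <- data.frame(
    onset_s = onset_s,
    button = as.integer(button),
    is_target = as.integer(button) == as.integer(target_button),
    selection_id = rep_len(selection_id, length(onset_s)),
    environment = rep_len(environment, length(onset_s)),
    stringsAsFactors = FALSE
  )
  class(sched) <- c("bci_schedule", "data.frame")
  sched
}

# All-zero noise model (deterministic response, no background).
silent_noise <- function(seed = 1L) {
  noise_model(0, 0, 0, 0, 0, 0, trial_gain_cv = 0, trial_jitter_ms = 0,
              seed = seed)
}
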