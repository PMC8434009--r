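test_that("re-referencing subtracts the ear channel and drops it", {
  rec <- make_recording(rbind(c(3, 5), c(1, 2)), reference = c(1, 2))
  out <- rereference(rec)
  expect_equal(out$data[1, ], c(2, 3))
  expect_equal(out$data[2, ], c(0, 0))   # channel identical to the reference
  expect_null(out$reference)
  rec0 <- make_recording(rbind(c(3, 5)), reference = c(0, 0))
  expect_equal(rereference(rec0)$data[1, ], c(3, 5))  # zero reference: identity
  expect_error(rereference(make_recording(rbind(c(1, 2)))), "reference")
})

test_that("bandpass matches its own transfer function at 10 and 60 Hz and kills DC", {
  fs <- 300
  cfg <- pipeline_config()
  n <- fs * 30
  t <- (0:(n - 1)) / fs
  # oracle: evaluate the designed cascade's magnitude response directly
  hp <- signal::butter(5, 0.1 / (fs / 2), type = "high")
  lp <- signal::butter(5, 30 / (fs / 2), type = "low")
  gain <- function(f) {
    H <- function(flt) {
      z <- exp(-1i * 2 * pi * f / fs * (seq_along(flt$b) - 1))
      abs(sum(flt$b * z) / sum(flt$a * z))
    }
    H(hp) * H(lp)
  }
  for (f in c(10, 60)) {
    rec <- make_recording(rbind(sin(2 * pi * f * t)), fs = fs)
    out <- bandpass(rec, cfg)
    meas <- max(abs(out$data[1, (n / 2):n]))  # steady state
    expect_equal(meas, gain(f), tolerance = 0.05)
  }
  expect_lt(gain(60), 0.05)
  # DC input decays toward zero (0 Hz steady-state gain is 0)
  rec <- make_recording(rbind(rep(50, n)), fs = fs)
  out <- bandpass(rec, cfg)
  early <- max(abs(out$data[1, (5 * fs):(6 * fs)]))
  late <- max(abs(out$data[1, (29 * fs):n]))
  expect_lt(late, 0.1)          # < 0.2% of the 50 uV input after 29 s
  expect_lt(late, early / 50)   # and still decaying
})

test_that("bandpass rejects incompatible rates and band edges", {
  expect_error(bandpass(make_recording(rbind(1:10), fs = 50), pipeline_config()),
               "60 Hz")
  expect_error(bandpass(make_recording(rbind(1:100), fs = 300),
                        pipeline_config(band_high_hz = 160)), "Nyquist")
})

test_that("epoch extraction yields one 300-sample epoch per event and skips truncated ones", {
  cfg <- paradigm_config()
  pc <- pipeline_config()
  sched <- generate_flash_schedule(cfg, 20, 0, seed = 8)
  rec <- synthesize_recording(sched, erp_template(), silent_noise(), cfg)
  ep <- extract_epochs(rec, pc)
  expect_equal(n_epochs(ep), 140)
  expect_equal(dim(ep$epochs)[2:3], c(7, 300))
  expect_equal(ep$button, sched$button)
  # first epoch sample is the sample at flash onset
  i0 <- round(sched$onset_s[5] * 300) + 1
  expect_equal(ep$epochs[5, , 1], unname(rec$data[, i0]))
  # cut the recording so the last event cannot fill its epoch
  short <- rec
  short$data <- short$data[, seq_len(round((max(sched$onset_s) + 0.9) * 300))]
  expect_warning(ep2 <- extract_epochs(short, pc), "skipped")
  expect_equal(n_epochs(ep2), 139)
  expect_equal(ep2$n_skipped, 1L)
})

test_that("baseline correction zeroes channel means, is idempotent and shift-invariant", {
  set.seed(1)
  arr <- array(rnorm(10 * 3 * 50), dim = c(10, 3, 50))
  ep <- make_epochs(arr)
  out <- baseline_correct(ep)
  expect_lt(max(abs(apply(out$epochs, c(1, 2), mean))), 1e-9)
  expect_equal(baseline_correct(out)$epochs, out$epochs, tolerance = 1e-12)
  shifted <- make_epochs(arr + 7.3)
  expect_equal(baseline_correct(shifted)$epochs, out$epochs, tolerance = 1e-12)
  const <- make_epochs(array(4, dim = c(1, 2, 10)))
  expect_true(all(baseline_correct(const)$epochs == 0))
})

test_that("consecutive averaging: sliding and block window counts and values", {
  set.seed(2)
  # one button, 30 epochs of a single sample so windows are easy to enumerate
  vals <- rnorm(30)
  arr <- array(vals, dim = c(30, 1, 1))
  ep <- make_epochs(arr, button = rep(0L, 30), is_target = rep(TRUE, 30))
  sl <- consecutive_average(ep, pipeline_config(avg_mode = "sliding"))
  expect_equal(n_epochs(sl), 11)  # 30 - 20 + 1
  # brute-force window means as the oracle
  expect_equal(as.numeric(sl$epochs[, 1, 1]),
               vapply(1:11, function(i) mean(vals[i:(i + 19)]), numeric(1)))
  bl <- consecutive_average(ep, pipeline_config(avg_mode = "block"))
  expect_equal(n_epochs(bl), 1)
  expect_equal(bl$epochs[1, 1, 1], mean(vals[1:20]))
  # identical epochs average to themselves
  same <- make_epochs(array(3.5, dim = c(20, 2, 4)))
  av <- consecutive_average(same, pipeline_config())
  expect_equal(n_epochs(av), 1)
  expect_true(all(av$epochs == 3.5))
  # groups smaller than the window produce no output
  few <- make_epochs(array(1, dim = c(5, 1, 2)))
  expect_message(out <- consecutive_average(few, pipeline_config()), "no output")
  expect_equal(n_epochs(out), 0)
})

test_that("averaging never crosses selection boundaries", {
  arr <- array(rep(c(1, 100), each = 20), dim = c(40, 1, 1))
  ep <- make_epochs(arr, button = rep(0L, 40), is_target = rep(TRUE, 40),
                    selection_id = rep(c("a", "b"), each = 20))
  av <- consecutive_average(ep, pipeline_config(avg_mode = "sliding"))
  expect_equal(n_epochs(av), 2)
  expect_equal(sort(as.numeric(av$epochs)), c(1, 100))
})

test_that("decimation keeps every third sample from the first", {
  arr <- aperm(array(1:300, dim = c(300, 1, 2)), c(3, 2, 1))  # value = sample index
  ep <- make_epochs(arr, fs = 300)
  out <- resample_epochs(ep, pipeline_config())
  expect_equal(dim(out$epochs)[3], 100)
  expect_equal(out$sampling_rate_hz, 100)
  expect_equal(as.numeric(out$epochs[1, 1, ]), seq(1, 298, by = 3))
  const <- make_epochs(array(2.5, dim = c(1, 1, 300)), fs = 300)
  expect_true(all(resample_epochs(const, pipeline_config())$epochs == 2.5))
  expect_error(resample_epochs(ep, pipeline_config(resample_to_hz = 90)),
               "integer multiple")
})

test_that("run_pipeline equals the manual six-stage composition and keeps shape", {
  cfg <- paradigm_config()
  pc <- pipeline_config()
  sched <- generate_flash_schedule(cfg, 20, 4, seed = 21)
  rec <- synthesize_recording(sched, erp_template(), noise_model(seed = 21), cfg)
  auto <- run_pipeline(rec, pc)
  manual <- rec |>
    rereference() |>
    bandpass(pc) |>
    extract_epochs(pc) |>
    baseline_correct() |>
    consecutive_average(pc) |>
    resample_epochs(pc)
  expect_equal(auto$epochs, manual$epochs, tolerance = 1e-12)
  expect_equal(dim(auto$epochs)[2:3], c(7, 100))
  expect_equal(n_epochs(auto), 7)  # block of 20 per button... sliding: 1 per button
})

test_that("the pipeline is linear in its input recording", {
  cfg <- paradigm_config()
  pc <- pipeline_config()
  sched <- generate_flash_schedule(cfg, 3, 0, seed = 31)
  r1 <- synthesize_recording(sched, erp_template(), noise_model(seed = 1), cfg)
  r2 <- synthesize_recording(sched, erp_template(peak_amplitude_uv = 0),
                             noise_model(seed = 2), cfg)
  mix <- r1
  mix$data <- 2 * r1$data - 0.5 * r2$data
  mix$reference <- 2 * r1$reference - 0.5 * r2$reference
  out_mix <- run_pipeline(mix, pc)
  o1 <- run_pipeline(r1, pc)
  o2 <- run_pipeline(r2, pc)
  expect_equal(out_mix$epochs, 2 * o1$epochs - 0.5 * o2$epochs,
               tolerance = 1e-6)
})

test_that("an empty schedule flows through as an empty epoch set", {
  cfg <- paradigm_config()
  sched <- make_schedule(numeric(0), integer(0), target_button = 0)
  rec <- make_recording(matrix(rnorm(7 * 600), 7, 600), fs = 300,
                        reference = rnorm(600), schedule = sched,
                        channel_labels = cfg$channels)
  out <- run_pipeline(rec, pipeline_config())
  expect_equal(n_epochs(out), 0)
})
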