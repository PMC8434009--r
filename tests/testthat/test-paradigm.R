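test_that("flash schedules have equal counts, blockwise rounds, fixed SOA", {
  cfg <- paradigm_config()
  sched <- generate_flash_schedule(cfg, n_blinks = 20, target_button = 3, seed = 42)
  expect_equal(nrow(sched), 140)  # 20 x 7 flashes per selection
  expect_true(all(table(sched$button) == 20))
  expect_equal(diff(sched$onset_s), rep(0.2, 139), tolerance = 1e-12)
  expect_identical(sched$is_target, sched$button == 3L)
  # each consecutive round of 7 events is a permutation of all buttons
  for (blk in split(sched$button, rep(1:20, each = 7))) {
    expect_setequal(blk, 0:6)
  }
  one <- generate_flash_schedule(cfg, n_blinks = 1, target_button = 0, seed = 9)
  expect_equal(nrow(one), 7)
  expect_setequal(one$button, 0:6)
})

test_that("schedules and recordings are reproducible from their seeds", {
  cfg <- paradigm_config()
  s1 <- generate_flash_schedule(cfg, 5, 2, seed = 11)
  s2 <- generate_flash_schedule(cfg, 5, 2, seed = 11)
  s3 <- generate_flash_schedule(cfg, 5, 2, seed = 12)
  expect_identical(s1, s2)
  expect_false(identical(s1$button, s3$button))
  nm <- noise_model(seed = 5)
  r1 <- synthesize_recording(s1, erp_template(), nm, cfg)
  r2 <- synthesize_recording(s1, erp_template(), nm, cfg)
  expect_identical(r1$data, r2$data)
  expect_identical(r1$reference, r2$reference)
})

test_that("invalid target button is rejected", {
  cfg <- paradigm_config()
  expect_error(generate_flash_schedule(cfg, 5, 7, seed = 1), "target_button")
  expect_error(generate_flash_schedule(cfg, 5, -1, seed = 1), "target_button")
})

test_that("noise-free synthesis adds the template exactly at target onsets", {
  cfg <- paradigm_config()
  tpl <- erp_template(peak_amplitude_uv = 10, peak_latency_ms = 400,
                      width_ms = 60,
                      channel_weights = c(Pz = 1.0, Fz = 0.5))
  # one target at 0 s, one non-target far enough away that no bump reaches it
  sched <- make_schedule(c(0, 1.4), c(0, 1), target_button = 0)
  rec <- synthesize_recording(sched, tpl, silent_noise(), cfg)
  fs <- cfg$sampling_rate_hz
  pz <- rec$data["Pz", ]
  expect_equal(pz[round(0.4 * fs) + 1], 10)                    # peak sample
  expect_equal(unname(rec$data["Fz", round(0.4 * fs) + 1]), 5)          # weighted
  expect_true(all(rec$data["Oz", ] == 0))                       # no weight
  # non-target epoch is identically zero
  nt <- rec$data[, (round(1.4 * fs) + 1):(round(1.4 * fs) + fs)]
  expect_true(all(nt == 0))
  expect_true(all(rec$reference == 0))
})

test_that("template must fit inside the epoch and long schedules are refused", {
  expect_error(erp_template(peak_latency_ms = 980, width_ms = 60), "fit inside")
  cfg <- paradigm_config()
  sched <- make_schedule(c(0, 700), c(0, 1), target_button = 0)
  expect_error(
    synthesize_recording(sched, erp_template(), silent_noise(), cfg,
                         max_duration_s = 600),
    "max_duration_s")
})

test_that("noise and signal superpose elementwise under a shared seed", {
  cfg <- paradigm_config()
  sched <- generate_flash_schedule(cfg, 3, 1, seed = 4)
  tpl <- erp_template()
  nm <- noise_model(seed = 77)
  signal_only <- noise_model(0, 0, 0, 0, 0, 0,
                             trial_gain_cv = nm$trial_gain_cv,
                             trial_jitter_ms = nm$trial_jitter_ms, seed = 77)
  full <- synthesize_recording(sched, tpl, nm, cfg)
  noise_only <- synthesize_recording(sched, erp_template(peak_amplitude_uv = 0),
                                     nm, cfg)
  sig <- synthesize_recording(sched, tpl, signal_only, cfg)
  expect_equal(full$data, noise_only$data + sig$data, tolerance = 1e-12)
})

test_that("zero-noise target/non-target contrast recovers the template", {
  cfg <- paradigm_config()
  tpl <- erp_template(peak_amplitude_uv = 6, peak_latency_ms = 350,
                      width_ms = 80)
  # spaced onsets so no epoch overlaps another flash's response
  onsets <- seq(0, by = 1.2, length.out = 14)
  sched <- make_schedule(onsets, rep(0:6, 2), target_button = 2)
  rec <- synthesize_recording(sched, tpl, silent_noise(), cfg)
  pc <- pipeline_config()
  ep <- extract_epochs(rec, pc)
  tm <- apply(ep$epochs[ep$is_target, , , drop = FALSE], c(2, 3), mean)
  nm_ <- apply(ep$epochs[!ep$is_target, , , drop = FALSE], c(2, 3), mean)
  fs <- cfg$sampling_rate_hz
  sigma <- tpl$width_ms / (2 * sqrt(2 * log(2))) / 1000
  t_rel <- (0:(fs - 1)) / fs
  bump <- 6 * exp(-0.5 * ((t_rel - 0.35) / sigma)^2)
  contrast <- tm - nm_
  expect_equal(contrast[which(cfg$channels == "Pz"), ], bump, tolerance = 1e-12)
  expect_equal(contrast[which(cfg$channels == "Fz"), ], 0.5 * bump,
               tolerance = 1e-12)
})

test_that("artifact injection is a zero-rate identity and trips the QC flags", {
  cfg <- paradigm_config()
  sched <- generate_flash_schedule(cfg, 5, 0, seed = 3)
  rec <- synthesize_recording(sched, erp_template(), noise_model(seed = 3), cfg)
  no_art <- noise_model(seed = 3, artifact_rate_per_min = 0)
  expect_identical(inject_artifacts(rec, no_art)$data, rec$data)
  heavy <- noise_model(seed = 3, artifact_rate_per_min = 60,
                       artifact_amplitude_uv = 400)
  dirty <- inject_artifacts(rec, heavy)
  pc <- pipeline_config()
  ep <- baseline_correct(extract_epochs(bandpass(rereference(dirty), pc), pc))
  expect_true(any(flag_bad_epochs(ep, qc_config())))
})
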