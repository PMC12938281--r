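test_that("generation is byte-identical under a fixed seed", {
  spec <- sim_spec(n_trials_per_class = 3, seed = 7)
  a <- generate_recording(spec)
  b <- generate_recording(spec)
  expect_identical(a$recording$data, b$recording$data)
  expect_identical(a$recording$events, b$recording$events)
  expect_identical(a$labels, b$labels)
})

test_that("invalid simulation specs name the offending field", {
  expect_error(sim_spec(n_trials_per_class = 0), "n_trials_per_class")
  expect_error(sim_spec(erd_depth = 1), "erd_depth")
  expect_error(sim_spec(mi_window = c(5, 9)), "mi_window")
  expect_error(sim_spec(classes = c("a", "a")), "classes")
  expect_error(sim_spec(classes = letters[1:4]), "classes")
})

# mu-band power on one channel inside a window, per trial
trial_band_power <- function(rec, window = c(3.5, 5.5), channel = 3,
                             band = c(8, 12)) {
  es <- epoch_recording(rec, window[1] - 0.5, window[2] + 0.5)
  fs <- es$sampling_rate
  idx <- (round(0.5 * fs) + 1):(round(0.5 * fs) + diff(window) * fs)
  vapply(seq_len(n_trials(es)), function(i) {
    x <- bandpass_zero_phase(es$data[i, channel, ], band[1], band[2],
                             sampling_rate = fs, order = 4)
    mean(x[idx]^2)
  }, numeric(1))
}

test_that("zero modulation depth yields statistically indistinguishable classes", {
  sim <- generate_recording(sim_spec(n_trials_per_class = 50,
                                     erd_depth = 0, ers_gain = 0,
                                     seed = 3))
  p <- trial_band_power(sim$recording)
  pv <- t.test(p[sim$labels == "left"], p[sim$labels == "relax"])$p.value
  expect_gt(pv, 0.01)
})

test_that("contralateral mu suppression is recovered across seeds", {
  hits <- vapply(1:20, function(s) {
    sim <- generate_recording(sim_spec(n_trials_per_class = 50,
                                       erd_depth = 0.6, seed = s))
    p <- trial_band_power(sim$recording)        # C4, contralateral to left
    mean(p[sim$labels == "left"]) < mean(p[sim$labels == "relax"])
  }, logical(1))
  expect_gte(sum(hits), 19)
})

test_that("background noise follows the configured 1/f slope", {
  sim <- generate_recording(sim_spec(n_trials_per_class = 5,
                                     rhythm_amplitudes = c(mu = 0, beta = 0),
                                     noise_exponent = 1, seed = 5))
  x <- sim$recording$data[1, ]
  ps <- spec.pgram(ts(x, frequency = 250), spans = c(25, 25), plot = FALSE,
                   taper = 0.1)
  sel <- ps$freq >= 2 & ps$freq <= 40
  slope <- coef(lm(log(ps$spec[sel]) ~ log(ps$freq[sel])))[2]
  expect_lt(abs(slope - (-1)), 0.2)
})

test_that("class-dependent modulation is confined to the imagery window", {
  sim <- generate_recording(sim_spec(n_trials_per_class = 50, seed = 9))
  # 1.0-3.0 s: before the modulation window opens
  p <- trial_band_power(sim$recording, window = c(1, 3))
  pv <- t.test(p[sim$labels == "left"], p[sim$labels == "relax"])$p.value
  expect_gt(pv, 0.01)
})

test_that("artifact injection hits the requested peak and nothing else", {
  sim <- generate_recording(sim_spec(n_trials_per_class = 5, seed = 13,
                                     erd_depth = 0, ers_gain = 0))
  rec <- inject_artifact(sim$recording, 3, 500)
  es <- epoch_recording(rec, 1, 5)
  expect_gte(max(abs(es$data[3, , ])), 500)
  others <- setdiff(seq_len(n_trials(es)), 3)
  expect_lt(max(abs(es$data[others, , ])), 100)
  expect_identical(inject_artifact(sim$recording, 2, 0), sim$recording)
  expect_error(inject_artifact(sim$recording, 99, 100), "out of range")
})

test_that("an injected transient is exactly the trial the rejection rule removes", {
  sim <- generate_recording(sim_spec(n_trials_per_class = 5, seed = 13,
                                     erd_depth = 0, ers_gain = 0))
  es0 <- epoch_recording(sim$recording, 1, 5)
  expect_lt(max(abs(es0$data)), 80)       # clean background precondition
  rec <- inject_artifact(sim$recording, 4, 500)
  es <- epoch_recording(rec, 1, 5)
  cleaned <- reject_artifacts(es, 100)
  rep <- attr(cleaned, "rejection")
  expect_identical(rep$index, 4L)
  expect_identical(n_trials(cleaned), n_trials(es) - 1L)
})

test_that("the artifact_rate field injects transients the cleaner removes", {
  sim <- generate_recording(sim_spec(n_trials_per_class = 10,
                                     artifact_rate = 0.3,
                                     artifact_amplitude = 300, seed = 21))
  es <- epoch_recording(sim$recording, 1, 5)
  cleaned <- reject_artifacts(es, 100)
  expect_gt(nrow(attr(cleaned, "rejection")), 0)
})
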