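# shared fixtures; generated in code, cached across test files

.fixtures <- new.env(parent = emptyenv())

# small preprocessed two-class recording (imagery vs rest)
cached_sim <- function(key = "default", n = 40, classes = c("left", "relax"),
                       seed = 11, ...) {
  if (is.null(.fixtures[[key]])) {
    sim <- generate_recording(sim_spec(n_trials_per_class = n,
                                       classes = classes, seed = seed, ...))
    es <- preprocess_recording(sim$recording)
    .fixtures[[key]] <- list(sim = sim, epochs = es)
  }
  .fixtures[[key]]
}

# trials whose channel covariance is proportional to diag(d)
diag_cov_trials <- function(n_trials, d, n_samples = 500) {
  lapply(seq_len(n_trials), function(i) {
    t(vapply(sqrt(d), function(s) s * rnorm(n_samples),
             numeric(n_samples)))
  })
}

# two well-separated 2-d Gaussian clouds
separable_2d <- function(n_per_class = 20, gap = 6, sd = 0.5, seed = 42) {
  set.seed(seed)
  x <- rbind(cbind(rnorm(n_per_class, -gap / 2, sd),
                   rnorm(n_per_class, 0, sd)),
             cbind(rnorm(n_per_class, gap / 2, sd),
                   rnorm(n_per_class, 0, sd)))
  list(x = x, y = factor(rep(c("a", "b"), each = n_per_class)))
}

# epoch_set holding pure-tone trials (for filter-bank energy checks)
tone_epochs <- function(freq_hz, n_trials = 3, fs = 250, dur_s = 4,
                        noise_sd = 0) {
  tt <- (seq_len(fs * dur_s) - 1) / fs
  arr <- array(0, c(n_trials, 3, length(tt)))
  set.seed(1)
  for (i in seq_len(n_trials)) for (ch in 1:3)
    arr[i, ch, ] <- sin(2 * pi * freq_hz * tt + runif(1, 0, 2 * pi)) +
      noise_sd * rnorm(length(tt))
  epoch_set(arr, rep("x", n_trials), fs, c("C3", "Cz", "C4"))
}

# epoch_set whose only class-dependent structure is a band-limited rhythm
# on one channel; broadband variance is dominated by a class-independent
# per-trial, per-channel amplitude nuisance, so only decoders that look
# inside the rhythm band see a clean contrast
band_confined_epochs <- function(n_per_class = 30, band = c(8, 12),
                                 gain = 2.5, fs = 250, dur_s = 4,
                                 seed = 1, nuisance = c(1, 1)) {
  set.seed(seed)
  n <- fs * dur_s
  nt <- 2 * n_per_class
  y <- factor(rep(c("a", "b"), each = n_per_class))
  arr <- array(0, c(nt, 3, n))
  filt <- signal::butter(4, band / (fs / 2), type = "pass")
  for (i in seq_len(nt)) {
    for (ch in 1:3)
      arr[i, ch, ] <- runif(1, nuisance[1], nuisance[2]) * rnorm(n)
    rhythm <- signal::filtfilt(filt, rnorm(n))
    rhythm <- rhythm / sd(rhythm)
    g <- if (y[i] == "a") gain else 1
    arr[i, 3, ] <- arr[i, 3, ] + g * rhythm
  }
  epoch_set(arr, y, fs, c("C3", "Cz", "C4"))
}
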