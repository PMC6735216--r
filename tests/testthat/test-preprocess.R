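test_that("EOG removal keeps 63 channels in order and cannot run twice", {
  ses <- small_session()
  out <- drop_eog(ses)
  expect_equal(nrow(out$signal), 63L)
  expect_identical(out$channel_labels, setdiff(ses$channel_labels, "EOG"))
  expect_error(drop_eog(out), "already absent")
  expect_error(drop_eog(toy_session(matrix(rnorm(50), 5, 10)),
                        eog_index = 9), "out of range")
})

test_that("average reference zeroes the channel mean and is idempotent", {
  withr::with_seed(1, sig <- matrix(rnorm(5 * 200), 5, 200))
  ses <- toy_session(sig)
  ref <- average_reference(ses)
  expect_lt(max(abs(colMeans(ref$signal))), 1e-9)
  ## constant offset across channels vanishes entirely
  const <- toy_session(matrix(7.5, 4, 100))
  expect_equal(max(abs(average_reference(const)$signal)), 0)
  ## idempotence: re-referencing changes nothing
  expect_equal(average_reference(ref)$signal, ref$signal, tolerance = 1e-12)
  expect_error(average_reference(toy_session(matrix(1, 1, 10))),
               "at least 2")
})

test_that("FIR band-pass keeps in-band tones and rejects 0.5x/1.5x edges", {
  fs <- 500
  t <- (0:(20 * fs - 1)) / fs
  sig <- rbind(sin(2 * pi * 10 * t),         # in-band
               sin(2 * pi * 60 * t),         # 1.5x the high edge
               sin(2 * pi * 0.5 * t) + 3)    # 0.5x the low edge plus DC
  out <- bandpass_fir(toy_session(sig, fs = fs))$signal
  mid <- (5 * fs):(15 * fs)                  # away from the edges
  amp <- function(x) sqrt(2 * mean(x^2))
  expect_gt(amp(out[1, mid]), 0.95)
  expect_lt(amp(out[1, mid]), 1.05)
  expect_lt(amp(out[2, mid]), 0.1)           # >= 20 dB down
  expect_lt(amp(out[3, mid]), 0.1)           # DC and 0.5 Hz both gone
  expect_error(bandpass_fir(toy_session(sig, fs = fs), low = 10, high = 5),
               "invalid band")
  expect_error(bandpass_fir(toy_session(sig, fs = fs), low = 1, high = 300),
               "invalid band")
})

test_that("epoching cuts one 220500-point epoch per trial mark", {
  ep <- small_epochs()
  expect_equal(n_trials(ep), 8L)
  expect_equal(dim(ep$data)[2:3], c(63L, 3500L))
  expect_equal(prod(dim(ep$data)[2:3]), 220500L)
  expect_equal(sort(unique(ep$labels)), c("attempt", "blank"))

  ## no events -> empty epoch set
  empty <- epoch_trials(toy_session(matrix(0, 2, 1000)))
  expect_equal(n_trials(empty), 0L)

  ## a final trial that runs past the recording is dropped with a warning
  ev <- tibble::tibble(sample = c(1L, 800L), code = "trial_start",
                       kind = "attempt")
  short <- toy_session(matrix(rnorm(2 * 1200), 2, 1200), fs = 100,
                       events = ev)
  expect_warning(ep2 <- epoch_trials(short, trial_length = 7), "truncated")
  expect_equal(n_trials(ep2), 1L)
})

test_that("baseline removal zeroes the baseline mean and ignores offsets", {
  ep <- toy_epochs(n_per_class = 2, n_ch = 3, n_samp = 500, fs = 100)
  out <- remove_baseline(ep, baseline = c(0, 1))
  base <- out$data[, , 1:100, drop = FALSE]
  expect_lt(max(abs(apply(base, c(1, 2), mean))), 1e-12)
  ## constant epochs become exactly zero
  const <- epoch_set(array(4.2, c(1, 2, 300)), "attempt", 100,
                     c("a", "b"))
  expect_equal(max(abs(remove_baseline(const)$data)), 0)
  ## shift invariance
  shifted <- ep
  shifted$data <- ep$data + 11.1
  expect_equal(remove_baseline(shifted)$data, out$data, tolerance = 1e-9)
})

test_that("amplitude rejection removes exactly the contaminated trials", {
  ep <- toy_epochs(n_per_class = 3, n_ch = 2, n_samp = 200, fs = 100)
  expect_equal(n_trials(reject_artifact_trials(ep, Inf)), 6L)
  spiked <- ep
  spiked$data[4, 1, 50] <- 500
  out <- reject_artifact_trials(spiked, 100)
  expect_equal(n_trials(out), 5L)
  expect_identical(which(!out$kept_mask), 4L)
  expect_equal(n_trials(out) + sum(!out$kept_mask), n_trials(ep))
  expect_error(reject_artifact_trials(spiked, 1e-6), "threshold")
})

test_that("downsampling halves the sample count and keeps the first sample", {
  ep <- toy_epochs(n_per_class = 2, n_ch = 2, n_samp = 400, fs = 100)
  out <- downsample_epochs(ep, 4L)
  expect_equal(dim(out$data)[3], 100L)
  expect_equal(out$sampling_rate, 25)
  expect_equal(out$data[1, 1, 1], ep$data[1, 1, 1])
  expect_identical(downsample_epochs(ep, 1L), ep)
})
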