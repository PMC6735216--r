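test_that("schedules have the configured counts, randomized order and ITIs", {
  cfg <- sim_config(seed = 1)
  sched <- build_schedule(cfg)
  expect_equal(nrow(sched), 40L)
  expect_equal(sum(sched$kind == "attempt"), 20L)
  expect_equal(sum(sched$kind == "blank"), 20L)
  expect_true(all(diff(sched$onset) > 0))
  gaps <- diff(sched$onset) - attr(sched, "trial_length")
  expect_true(all(gaps >= cfg$iti_range[1] - 1e-9))
  expect_true(all(gaps <= cfg$iti_range[2] + 1e-9))
  ## the order is a permutation, not a block design
  expect_false(all(sched$kind == c(rep("attempt", 20), rep("blank", 20))))
  expect_identical(sched, build_schedule(sim_config(seed = 1)))
  expect_false(identical(sched$kind, build_schedule(sim_config(seed = 2))$kind))

  tiny <- build_schedule(sim_config(n_attempt = 1, n_blank = 1))
  expect_setequal(tiny$kind, c("attempt", "blank"))
  expect_error(sim_config(n_attempt = 0), "counts")
})

test_that("synthesized sessions are seed-deterministic with correct marks", {
  ses <- small_session()
  ses2 <- synthesize_session(
    sim_config(n_attempt = 4, n_blank = 4, seed = 42),
    truth = erd_ground_truth(small_truth_channels, band = "alpha",
                             depth = 0.6)
  )
  expect_identical(ses$signal, ses2$signal)
  expect_identical(ses$events, ses2$events)
  expect_equal(nrow(ses$signal), 64L)
  expect_equal(sum(ses$events$code == "trial_start"), 8L)
  ## cue marks only on attempt trials, one second grid after trial start
  cues <- ses$events[ses$events$code == "cue", ]
  expect_equal(nrow(cues), 4L)
  expect_true(all(cues$kind == "attempt"))

  expect_error(
    synthesize_session(sim_config(n_attempt = 1, n_blank = 1),
                       truth = erd_ground_truth("Nope")),
    "Nope"
  )
})

test_that("injected ERD attenuates band power by 1 - depth (filter oracle)", {
  ## long session so the empirical move/rest ratio is stable
  cfg <- sim_config(n_attempt = 100, n_blank = 1, seed = 11)
  truth <- erd_ground_truth("C3", band = "alpha", depth = 0.5)
  ses <- synthesize_session(cfg, truth = truth)
  sched <- build_schedule(cfg)
  onsets <- sched$onset[sched$kind == "attempt"]
  fs <- cfg$sampling_rate
  mv <- unlist(lapply(onsets, function(o) {
    (floor((o + 4) * fs) + 1):floor((o + 7) * fs)
  }))
  rs <- unlist(lapply(onsets, function(o) {
    (floor((o + 1) * fs) + 1):floor((o + 3) * fs)
  }))
  bp <- function(x, band) {
    signal::filtfilt(signal::butter(4, band / (fs / 2), type = "pass"), x)
  }
  ratio <- function(x) var(x[mv]) / var(x[rs])
  a_c3 <- bp(ses$signal["C3", ], c(8, 13))
  expect_gt(ratio(a_c3), 0.45)
  expect_lt(ratio(a_c3), 0.55)
  ## a non-truth channel and the non-truth band stay flat
  a_c4 <- bp(ses$signal["C4", ], c(8, 13))
  expect_gt(ratio(a_c4), 0.9)
  expect_lt(ratio(a_c4), 1.1)
  b_c3 <- bp(ses$signal["C3", ], c(13, 30))
  expect_gt(ratio(b_c3), 0.9)
  expect_lt(ratio(b_c3), 1.1)
})

test_that("depth zero leaves attempt and blank trials indistinguishable", {
  cfg <- sim_config(n_attempt = 10, n_blank = 10, seed = 9)
  ses <- synthesize_session(
    cfg, truth = erd_ground_truth("C3", band = "alpha", depth = 0)
  )
  fs <- cfg$sampling_rate
  sched <- build_schedule(cfg)
  bp <- signal::butter(4, c(8, 13) / (fs / 2), type = "pass")
  x <- signal::filtfilt(bp, ses$signal["C3", ])
  win_var <- function(kind) {
    onsets <- sched$onset[sched$kind == kind]
    idx <- unlist(lapply(onsets, function(o) {
      (floor((o + 4) * fs) + 1):floor((o + 7) * fs)
    }))
    var(x[idx])
  }
  expect_gt(win_var("attempt") / win_var("blank"), 0.75)
  expect_lt(win_var("attempt") / win_var("blank"), 1.33)
})

test_that("optional spatial mixing preserves shape and determinism", {
  cfg <- sim_config(n_attempt = 1, n_blank = 1, seed = 3,
                    spatial_mixing = 0.3)
  ses <- synthesize_session(cfg)
  expect_equal(dim(ses$signal), dim(synthesize_session(cfg)$signal))
  expect_identical(ses$signal, synthesize_session(cfg)$signal)
  ## mixing correlates neighboring channels more than the unmixed session
  unmixed <- synthesize_session(sim_config(n_attempt = 1, n_blank = 1,
                                           seed = 3))
  expect_gt(cor(ses$signal["C3", ], ses$signal["C1", ]),
            cor(unmixed$signal["C3", ], unmixed$signal["C1", ]))
})
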