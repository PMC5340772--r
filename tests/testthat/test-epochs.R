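make_rec <- function(dur = 500, fs = 200, hfs_start = 100, n_trains = 10) {
  ev <- gen_stim_schedule(n_trains, 10, 0.025, dur, hfs_start_s = hfs_start)
  recording(numeric(dur * fs), fs, ev)
}

test_that("the five analysis windows tile 100 s each around HFS onset", {
  wins <- locate_windows(make_rec())
  expect_equal(wins$label, c("pre", "during", "post1", "post2", "post3"))
  expect_equal(wins$start_s, c(0, 100, 200, 300, 400))
  expect_true(all(wins$duration_s == 100))
  # all train events fall inside `during`: last onset 190 s + 75 ms < 200 s
  r <- make_rec()
  hfs <- r$events[r$events$kind == "hfs_train", ]
  expect_true(all(hfs$time_s >= 100 & hfs$time_s + hfs$duration_s < 200))
})

test_that("window placement needs a tetanus and a long enough recording", {
  r <- recording(numeric(500 * 200), 200,
                 stim_event(100, "test_pulse", 2e-4))
  expect_error(locate_windows(r), "tetanus")
  expect_error(locate_windows(make_rec(dur = 450)), "post windows")
  expect_error(locate_windows(make_rec(hfs_start = 50)), "baseline")
})

test_that("window placement is equivariant to a shift of the schedule", {
  w1 <- locate_windows(make_rec(dur = 500, hfs_start = 100))
  w2 <- locate_windows(make_rec(dur = 537, hfs_start = 137))
  expect_equal(w2$start_s, w1$start_s + 37)
})

test_that("artifact mask flags amplitude excursions and event intervals", {
  expect_false(any(detect_artifacts(numeric(1000), 200)))
  set.seed(1)
  x <- rnorm(2000)
  x[801:820] <- 10 * sqrt(mean(x^2))
  mask <- detect_artifacts(x, 200)
  expect_true(all(mask[801:820]))
  ev <- stim_event(2, "hfs_train", 0.075)
  m2 <- detect_artifacts(numeric(2000), 200, ev, guard_s = 0.05)
  flagged <- which(m2)
  expect_true(all(flagged >= floor(1.95 * 200) + 1))
  expect_true(all(flagged <= ceiling(2.125 * 200) + 1))
  expect_gt(sum(m2), 0)
})

test_that("clean windows yield ten epochs starting at their sub-windows", {
  r <- make_rec()
  win <- locate_windows(r)[1, ]
  eps <- extract_epochs(r, win, rep(FALSE, length(r$samples)))
  expect_length(eps, 10)
  expect_equal(vapply(eps, function(e) e$start_s, numeric(1)),
               seq(0, 90, by = 10))
  expect_equal(vapply(eps, function(e) e$sub_window_index, integer(1)), 0:9)
  expect_true(all(vapply(eps, function(e) length(e$samples), numeric(1)) ==
                    round(4.1 * r$fs_hz)))
})

test_that("a sub-window blocked by a long artifact contributes nothing", {
  r <- make_rec()
  win <- locate_windows(r)[1, ]
  mask <- rep(FALSE, length(r$samples))
  # 7 s artifact in the middle of sub-window 3 ([30, 40) s): longest clean
  # run is 3 s < 4.1 s
  mask[(31.5 * 200):(38.5 * 200)] <- TRUE
  eps <- suppressMessages(extract_epochs(r, win, mask))
  expect_length(eps, 9)
  expect_false(3 %in% vapply(eps, function(e) e$sub_window_index, integer(1)))
  expect_error(extract_epochs(r, win, rep(TRUE, length(r$samples))),
               "no artifact-free")
})

test_that("extraction matches an exhaustive earliest-clean-run search", {
  fs <- 100
  n_ep <- round(4.1 * fs)
  r <- recording(numeric(100 * fs), fs,
                 stim_event(0, "hfs_train", 0.075))
  win <- data.frame(label = "pre", start_s = 0, duration_s = 100)
  for (s in 1:15) {
    mask <- random_mask(100 * fs, n_art = sample(3:12, 1), max_len = 900,
                        rng_seed = s)
    got <- suppressMessages(tryCatch(extract_epochs(r, win, mask),
                                     error = function(e) list()))
    got_idx <- vapply(got, function(e) e$sub_window_index, integer(1))
    for (i in 0:9) {
      seg <- mask[(i * 10 * fs + 1):((i + 1) * 10 * fs)]
      expected <- brute_earliest_clean(seg, n_ep)
      if (is.na(expected)) {
        expect_false(i %in% got_idx)
      } else {
        ep <- got[[which(got_idx == i)]]
        expect_equal(round(ep$start_s * fs) - i * 10 * fs + 1L, expected)
        expect_false(any(mask[round(ep$start_s * fs) +
                                seq_len(length(ep$samples))]))
      }
    }
  }
})

test_that("epochs dodge the guard margin around HFS trains", {
  r <- make_rec(fs = 200)
  mask <- detect_artifacts(r$samples, 200, r$events, guard_s = 0.05)
  win <- locate_windows(r)[2, ]  # during
  eps <- extract_epochs(r, win, mask)
  expect_length(eps, 10)
  # each train sits at its sub-window start, so epochs start just after the
  # guarded train
  starts_rel <- vapply(eps, function(e) e$start_s, numeric(1)) -
    (100 + 10 * (0:9))
  expect_true(all(starts_rel >= 0.075 + 0.05 - 1e-9))
  expect_true(all(starts_rel < 0.2))
})

test_that("down-sampling preserves in-band amplitude and refuses aliasing", {
  t <- (0:(10 * 2000 - 1)) / 2000
  r <- recording(sin(2 * pi * 8 * t), 2000,
                 stim_event(1, "hfs_train", 0.075))
  d <- downsample(r, 1000)
  expect_equal(d$fs_hz, 1000)
  expect_equal(sqrt(mean(d$samples^2)), sqrt(mean(r$samples^2)),
               tolerance = 0.01)
  expect_identical(d$events, r$events)
  expect_identical(downsample(r, 2000), r)
  expect_error(downsample(r, 200, analysis_top_hz = 100), "Nyquist")
  expect_error(downsample(r, 300, analysis_top_hz = 100), "divide")
})
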