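tone <- function(f, dur = 4.1, fs = 1000, amp = 1) {
  amp * sin(2 * pi * f * (0:(round(dur * fs) - 1)) / fs)
}

test_that("the notch removes line power and leaves the passband intact", {
  fs <- 2000
  x50 <- tone(50, fs = fs)
  y50 <- notch_filter(x50, fs)
  expect_lt(mean(y50^2) / mean(x50^2), 0.10)
  x8 <- tone(8, fs = fs)
  y8 <- notch_filter(x8, fs)
  expect_lt(abs(sqrt(mean(y8^2)) / sqrt(mean(x8^2)) - 1), 0.02)
  expect_identical(notch_filter(numeric(1000), fs), numeric(1000))
  expect_error(notch_filter(x8, 100), "too low")
})

test_that("a second notch application barely touches the passband", {
  fs <- 2000
  x8 <- tone(8, fs = fs)
  once <- notch_filter(x8, fs)
  twice <- notch_filter(once, fs)
  expect_lt(abs(sqrt(mean(twice^2)) / sqrt(mean(once^2)) - 1), 0.01)
})

test_that("a pure tone concentrates its power within one FFT bin", {
  sp <- power_spectrum(tone(8), 1000)
  pk <- which.max(sp$power)
  expect_lt(abs(sp$freqs[pk] - 8), 1000 / 2048)
  expect_gte(sum(sp$power[(pk - 1):(pk + 1)]) / sum(sp$power), 0.95)
})

test_that("integrated spectra satisfy Parseval against signal variance", {
  for (s in 1:8) {
    set.seed(s)
    x <- rnorm(4100, sd = runif(1, 0.5, 3)) + tone(sample(5:40, 1), amp = 2)
    sp <- power_spectrum(x, 1000)
    expect_equal(sum(sp$power), var(x), tolerance = 0.10)
  }
  expect_true(all(power_spectrum(numeric(4100), 1000)$power == 0))
  expect_error(power_spectrum(tone(8), 1000, nfft = 0), "nfft")
})

test_that("absolute powers scale with amplitude squared, relative powers cancel", {
  set.seed(2)
  x <- rnorm(4100)
  p1 <- power_spectrum(x, 1000)$power
  p2 <- power_spectrum(3 * x, 1000)$power
  expect_equal(p2, 9 * p1, tolerance = 1e-9)
})

test_that("band power isolates the band that holds the oscillation", {
  sp <- power_spectrum(tone(8), 1000)
  bands <- band_definitions()
  bp <- vapply(seq_len(nrow(bands)), function(b) band_power(sp, bands[b, ]),
               numeric(1))
  names(bp) <- bands$name
  expect_true(all(bp["theta"] > 10 * bp[c("delta", "alpha", "beta", "gamma")]))
  expect_error(band_power(sp, list(name = "ultra", f_low = 600, f_high = 700)),
               "no spectrum bins")
})

test_that("relative power is 100% against itself and errors on zero baseline", {
  p <- c(delta = 1, theta = 4, gamma = 2)
  expect_equal(unname(relative_power(p, p)), rep(100, 3))
  expect_equal(unname(relative_power(2.25 * p, p)), rep(225, 3))
  expect_error(relative_power(p, c(delta = 1, theta = 0, gamma = 2)), "theta")
})

mk_epochs <- function(n, amp_theta, fs = 1000, seed_base = 0, f = 8) {
  lapply(seq_len(n), function(i) {
    set.seed(seed_base + i)
    x <- amp_theta * sin(2 * pi * f * (0:4099) / fs + runif(1, 0, 2 * pi)) +
      rnorm(4100, sd = 0.3)
    ltposc:::new_epoch(x, fs, "x", i - 1L, 0)
  })
}

test_that("a known theta suppression is recovered from relative band power", {
  ebw <- list(pre = mk_epochs(10, 1, seed_base = 0),
              during = mk_epochs(10, 1 / sqrt(2), seed_base = 100))
  tab <- band_power_table(ebw, notch = FALSE)
  pre_theta <- tab$relative_power_pct[tab$window_label == "pre" &
                                        tab$band_name == "theta"]
  dur_theta <- tab$relative_power_pct[tab$window_label == "during" &
                                        tab$band_name == "theta"]
  expect_equal(pre_theta, 100)
  expect_equal(dur_theta, 50, tolerance = 0.08)
  # scale invariance: doubling every epoch leaves relative power unchanged
  ebw2 <- lapply(ebw, function(eps) lapply(eps, function(e) {
    e$samples <- 2 * e$samples
    e
  }))
  tab2 <- band_power_table(ebw2, notch = FALSE)
  expect_equal(tab2$relative_power_pct, tab$relative_power_pct,
               tolerance = 1e-9)
  expect_equal(tab2$absolute_power, 4 * tab$absolute_power, tolerance = 1e-9)
})

test_that("the theta profile tracks per-frequency suppression as amplitude squared", {
  ebw <- list(pre = mk_epochs(10, 1, seed_base = 0, f = 9),
              during = mk_epochs(10, 0.3, seed_base = 100, f = 9))
  prof <- theta_profile(ebw, notch = FALSE)
  at9 <- prof$relative_power_pct[prof$window_label == "during" &
                                   prof$freq_hz == 9]
  expect_equal(at9, 9, tolerance = 0.25)
  # stationary noise alone stays near 100% at every frequency
  nse <- list(pre = mk_epochs(20, 0, seed_base = 0),
              during = mk_epochs(20, 0, seed_base = 300))
  pn <- theta_profile(nse, notch = FALSE)
  # ~10% spread per frequency ratio at 20 epochs; 45 is a >4 sigma bound
  # for the worst of the 12 window x frequency cells
  expect_true(all(abs(pn$relative_power_pct - 100) < 45))
  zeros <- list(pre = mk_epochs(3, 0, seed_base = 0),
                during = mk_epochs(3, 0, seed_base = 5))
  zeros$pre <- lapply(zeros$pre, function(e) { e$samples[] <- 0; e })
  expect_error(theta_profile(zeros, notch = FALSE), "zero baseline")
})
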