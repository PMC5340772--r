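test_that("morlet filtering recovers the tone envelope and rejects out-of-band", {
  fs <- 1000
  t <- (0:4099) / fs
  x <- sin(2 * pi * 8 * t)
  env8 <- Mod(morlet_filter(x, fs, 8))
  core <- 600:3500  # 4+ wavelet SDs clear of the edge cones
  expect_true(all(abs(env8[core] - 1) < 0.05))
  env78 <- Mod(morlet_filter(x, fs, 78))
  expect_true(all(env78[core] < 0.05))
  expect_true(all(Mod(morlet_filter(numeric(1000), fs, 8)) == 0))
  expect_error(morlet_filter(x, fs, 500), "Nyquist")
})

test_that("morlet phase matches the analytic phase of the tone", {
  fs <- 1000
  t <- (0:4099) / fs
  x <- cos(2 * pi * 8 * t)
  ph <- Arg(morlet_filter(x, fs, 8))[500:3600]
  expected <- Arg(exp(1i * 2 * pi * 8 * t))[500:3600]
  expect_lt(max(abs(Arg(exp(1i * (ph - expected))))), 0.02)
})

test_that("raw ESC is a bounded correlation with exact degenerate cases", {
  set.seed(1)
  x <- rnorm(500)
  expect_equal(esc(x, x), 1)
  expect_equal(esc(x, -x + 5), -1)
  for (s in 1:20) {
    set.seed(s)
    a <- rnorm(50)
    b <- rnorm(50)
    v <- esc(a, b)
    expect_gte(v, -1)
    expect_lte(v, 1)
  }
  d <- esc(rep(1, 10), rnorm(10))
  expect_equal(as.numeric(d), 0)
  expect_true(attr(d, "degenerate"))
  expect_error(esc(1:3, 1:4), "lengths")
})

test_that("noise-free coupled signals give near-perfect ESC with signed phase lags", {
  p0 <- coupled_series(0.8, seed = 1, noise = 0)
  expect_gt(esc(p0$x, p0$y), 0.95)
  ppi <- coupled_series(0.8, seed = 1, noise = 0, lag = pi)
  expect_lt(esc(ppi$x, ppi$y), -0.95)
})

test_that("morlet-envelope ESC agrees with the band-pass + Hilbert oracle", {
  trim <- ceiling(morlet_sigma_t(8) * 2000)
  for (s in 1:10) {
    set.seed(s)
    d <- runif(1, 0.4, 0.9)
    p <- coupled_series(d, seed = s, noise = runif(1, 5, 25))
    esc_oracle <- oracle_esc(p$samples, p$fs, 8, 78, trim)
    expect_lt(abs(esc(p$x, p$y) - esc_oracle), 0.05)
    # the two envelope constructions themselves agree
    env_o <- Mod(hilbert_fft(butter_bandpass(p$samples, p$fs, 78)))
    idx <- (trim + 1):(length(p$samples) - trim)
    expect_gt(cor(p$y, env_o[idx]), 0.95)
  }
})

test_that("surrogate z is seeded-deterministic and separates coupled from null", {
  p <- coupled_series(0.8, seed = 3)
  nb <- ltposc:::surrogate_n_blocks(length(p$x), p$fs, 78)
  r <- esc(p$x, p$y)
  z1 <- surrogate_normalize(r, p$x, p$y, 200, seed = 11, n_blocks = nb)
  z2 <- surrogate_normalize(r, p$x, p$y, 200, seed = 11, n_blocks = nb)
  expect_identical(as.numeric(z1), as.numeric(z2))
  expect_gt(as.numeric(z1), 3)
  expect_error(surrogate_normalize(r, p$x, p$y, 1), "n_shuffles")
  flat <- surrogate_normalize(0, rep(1, 100), rnorm(100), 50, seed = 1)
  expect_true(is.na(as.numeric(flat)))
})

test_that("comodulograms only fill the envelope-above-signal triangle", {
  p <- coupled_series(0.8, seed = 2)
  cm <- comodulogram(p$samples, fs_hz = p$fs, n_shuffles = 50, seed = 4)
  centers <- cm$centers
  for (i in seq_along(centers)) for (j in seq_along(centers)) {
    if (centers[i] <= centers[j]) {
      expect_true(is.na(cm$z[i, j]))
    } else {
      expect_false(is.na(cm$z[i, j]))
    }
  }
  expect_setequal(cm$notch_flagged, c(48, 53))
  pk <- which(cm$raw == max(cm$raw, na.rm = TRUE), arr.ind = TRUE)[1, ]
  expect_lte(abs(as.numeric(rownames(cm$raw)[pk[1]]) - 78), 5)
  expect_lte(abs(as.numeric(colnames(cm$raw)[pk[2]]) - 8), 5)
})

test_that("pooled theta-gamma scores rise with coupling depth and vanish at zero", {
  scores <- vapply(c(0, 0.4, 0.8), function(d) {
    p <- coupled_series(d, seed = 5)
    theta_gamma_score(p$samples, fs_hz = p$fs, n_shuffles = 50,
                      seed = 6)$score_raw
  }, numeric(1))
  expect_true(all(diff(scores) > 0))
  expect_lt(abs(scores[1]), 0.15)
  s1 <- theta_gamma_score(coupled_series(0.6, seed = 7)$samples, fs_hz = 2000,
                          n_shuffles = 50, seed = 8)
  s2 <- theta_gamma_score(coupled_series(0.6, seed = 7)$samples, fs_hz = 2000,
                          n_shuffles = 50, seed = 8)
  expect_identical(s1$score_z, s2$score_z)
})

test_that("identical HFS epochs give identical per-epoch coupling scores", {
  p <- coupled_series(0.6, seed = 9)
  ep <- ltposc:::new_epoch(p$samples, p$fs, "during", 0L, 0)
  eps <- lapply(0:3, function(i) { e <- ep; e$sub_window_index <- i; e })
  tc <- hfs_coupling_timecourse(eps, list(ep), n_shuffles = 50, seed = 10)
  expect_equal(tc$epochs$epoch_index, 0:3)
  expect_true(all(abs(tc$epochs$score_raw - tc$epochs$score_raw[1]) < 1e-12))
  expect_equal(tc$epochs$score_rel_baseline[1],
               100 * tc$epochs$score_raw[1] / tc$baseline_raw)
})

test_that("a second-half coupling drop shows up in the epoch time course", {
  fs <- 2000
  mk_ep <- function(d, i, s) {
    p <- coupled_series(d, seed = s)
    ltposc:::new_epoch(p$samples, fs, "during", i, 0)
  }
  during <- c(lapply(0:4, function(i) mk_ep(0.7, i, 20 + i)),
              lapply(5:9, function(i) mk_ep(0.35, i, 20 + i)))
  base <- lapply(1:3, function(i) mk_ep(0.7, i, 40 + i))
  tc <- hfs_coupling_timecourse(during, base, n_shuffles = 50, seed = 30)
  first <- tc$epochs$score_raw[tc$epochs$epoch_index <= 4]
  second <- tc$epochs$score_raw[tc$epochs$epoch_index >= 5]
  expect_lt(mean(second), mean(first))
  expect_lt(suppressWarnings(wilcox.test(first, second,
                                         alternative = "greater")$p.value),
            0.05)
})
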