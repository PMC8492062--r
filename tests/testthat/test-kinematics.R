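test_that("episode detection finds threshold crossings and gaps", {
  t <- seq(0, 3000)
  x <- numeric(length(t))
  expect_equal(nrow(detect_episodes(x, t)), 0)
  x[t >= 1000 & t <= 1250] <- 1
  ep <- detect_episodes(x, t, 0.5)
  expect_equal(nrow(ep), 1)
  expect_equal(ep$duration, 250)
  x[t >= 2000 & t <= 2100] <- 1
  ep2 <- detect_episodes(x, t, 0.5)
  expect_equal(nrow(ep2), 2)
  expect_equal(inter_episode_intervals(ep2), 750)
  # durations plus gaps tile the active span exactly
  expect_equal(sum(ep2$duration) + sum(inter_episode_intervals(ep2)),
               max(ep2$end) - min(ep2$start))
})

test_that("tail-beat frequencies recover a known sinusoid", {
  t <- seq(0, 2000, by = 1)
  y <- sin(2 * pi * 30 * t / 1000)          # 30 Hz, amplitude 1
  f <- tail_beat_frequencies(y, t, threshold = 0.5)
  expect_gt(length(f), 50)
  expect_true(all(abs(f - 30) < 1.5))
  # scaling the displacement does not change the frequencies
  f2 <- tail_beat_frequencies(2 * y, t, threshold = 0.5)
  expect_equal(mean(f2), mean(f), tolerance = 0.02)
  # intervals longer than 100 ms are discarded
  y3 <- numeric(length(t))
  y3[c(100, 250, 450)] <- 1                  # "beats" 150 and 200 ms apart
  y3[c(170, 320, 520)] <- -1
  f3 <- tail_beat_frequencies(y3, t, threshold = 0.5)
  expect_equal(length(f3), 0)
  expect_equal(length(tail_beat_frequencies(numeric(10), 1:10)), 0)
})

test_that("left-right cross-correlation separates synchrony and alternation", {
  t <- seq(0, 1000)
  base <- pmax(0, sin(2 * pi * 25 * t / 1000))
  expect_equal(min_lr_crosscorr(base, base, 1, 0), 1)
  # identical constant-positive signals stay 1 at all lags
  expect_equal(min_lr_crosscorr(rep(2, 500), rep(2, 500), 1, 10), 1,
               tolerance = 0.05)
  # perfectly alternating non-overlapping half-waves approach 0
  alt <- pmax(0, -sin(2 * pi * 25 * t / 1000))
  expect_lt(min_lr_crosscorr(base, alt, 1, 10), 0.1)
  # symmetric in its arguments
  expect_equal(min_lr_crosscorr(base, alt, 1, 10),
               min_lr_crosscorr(alt, base, 1, 10))
  expect_true(is.na(min_lr_crosscorr(base, numeric(length(base)), 1, 10)))
})

test_that("phase delays recover constructed shifts", {
  t <- seq(0, 2000)
  ref <- sin(2 * pi * t / 100)               # 100 ms period
  expect_equal(phase_delay(ref, ref, 1), 0)
  quarter <- sin(2 * pi * (t - 25) / 100)    # quarter-period lag
  expect_equal(abs(phase_delay(ref, quarter, 1)), pi / 2, tolerance = 0.1)
  half <- sin(2 * pi * (t - 50) / 100)
  expect_equal(abs(phase_delay(ref, half, 1)), pi, tolerance = 0.1)
  # override period normalization used by the coiling analyses
  expect_equal(phase_delay(ref, quarter, 1, period_override = 100),
               2 * pi * 25 / 100, tolerance = 0.1)
  expect_true(is.na(phase_delay(numeric(100) + 1, numeric(100), 1)))
})

test_that("coil classifier pairs, truncates and reports proportions", {
  t <- seq(0, 6000)
  nseg <- 10
  th <- matrix(0, length(t), nseg)
  bump <- function(center, width) exp(-((t - center) / width)^2)
  # full left coil at 1 s and full right coil at 1.5 s -> one double event
  for (s in 1:nseg) th[, s] <- th[, s] - 0.8 * bump(1000, 150)
  for (s in 1:nseg) th[, s] <- th[, s] + 0.8 * bump(1500, 150)
  # isolated full right coil at 3.5 s -> single
  for (s in 1:nseg) th[, s] <- th[, s] + 0.8 * bump(3500, 150)
  # rostral-only left bend at 5 s -> truncated
  for (s in 1:3) th[, s] <- th[, s] - 0.8 * bump(5000, 150)
  cc <- classify_coils(th, t, amplitude_threshold = 0.5,
                       pairing_window = 1000)
  expect_equal(sort(cc$events$class), c("double", "single", "truncated"))
  expect_equal(cc$events$n_coils[cc$events$class == "double"], 2L)
  expect_equal(sum(cc$proportions), 1)
  # truncated coil has partial caudal reach
  tr <- cc$coils[cc$coils$reach < 2 / 3, ]
  expect_equal(nrow(tr), 1)
  # out-of-window opposite coils stay single
  cc2 <- classify_coils(th, t, amplitude_threshold = 0.5,
                        pairing_window = 300)
  expect_equal(sum(cc2$events$class == "double"), 0)
})

test_that("locomotor summary excludes the settling period", {
  set.seed(9)
  sim <- simulate_circuit(build_beat_and_glide("base"), 3000,
                          record_V = FALSE)
  s <- summarize_locomotion(sim, start_at = 200)
  expect_true(all(s$episodes$start >= 200))
  expect_equal(s$analyzed_ms[1], 200)
  expect_s3_class(s, "locomotor_summary")
  expect_output(print(s), "episodes")
})
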