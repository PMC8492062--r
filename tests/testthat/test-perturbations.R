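test_that("perturbation plans validate their epochs and targets", {
  expect_error(silence_population("IC", 100, 50), "start < end")
  expect_error(silence_population("IC", epochs = rbind(c(0, 100), c(50, 200))),
               "non-overlapping")
  p <- silence_population("IC", 100, 200)
  expect_s3_class(p, "perturbation")
  circ <- build_single_coiling()
  expect_error(
    simulate_circuit(circ, 300, perturbations = silence_population("dI6", 0,
                                                                   100)),
    "unknown population")
  expect_error(
    simulate_circuit(circ, 300,
                     perturbations = silence_population("IC", 0, 500)),
    "within the simulation duration")
})

test_that("an empty perturbation leaves the run unchanged", {
  circ <- build_single_coiling()
  a <- simulate_circuit(circ, 1200, seed = 4, record_V = FALSE)
  b <- simulate_circuit(circ, 1200, seed = 4, record_V = FALSE,
                        perturbations = list())
  expect_identical(a$muscle_V, b$muscle_V)
  expect_identical(a$spikes, b$spikes)
})

test_that("silencing ICs blocks activity in all spinal neurons", {
  circ <- build_single_coiling()
  sim <- simulate_circuit(circ, 3000, seed = 1, record_V = FALSE,
                          perturbations = silence_population("IC", 0, 3000))
  expect_equal(sum(vapply(sim$spikes, length, 1L)), 0L)
})

test_that("silencing V0ds spares single coiling without multiple coils", {
  circ <- build_single_coiling()
  sim <- simulate_circuit(circ, 10000, seed = 1, record_V = FALSE,
                          perturbations = silence_population("V0d", 0,
                                                             10000))
  cc <- classify_coils(sim$theta, sim$time)
  expect_gte(sum(cc$events$class == "single"), 4)
  expect_equal(sum(cc$events$class %in% c("double", "multiple")), 0)
})

test_that("three-epoch V2a silencing abolishes episodes then recovers", {
  set.seed(21)
  res <- three_epoch_protocol(build_beat_and_glide("base"),
                              silence_population("V2a", 0, 1),
                              epoch_ms = 4000, seed = 21)
  st <- res$stats
  expect_equal(st$n_episodes[2], 0)
  expect_gt(st$n_episodes[3], 0)
  # restoration: epoch 3 statistics overlap epoch 1 within 2 sd
  d13 <- abs(st$episode_duration_mean[1] - st$episode_duration_mean[3])
  spread <- 2 * (st$episode_duration_sd[1] + st$episode_duration_sd[3])
  expect_lt(d13, pmax(spread, 100))
})

test_that("V0v silencing shortens episodes; V1 silencing lengthens them", {
  set.seed(21)
  v0v <- three_epoch_protocol(build_beat_and_glide("base"),
                              silence_population("V0v", 0, 1),
                              epoch_ms = 4000, seed = 21)$stats
  expect_lt(v0v$episode_duration_mean[2], v0v$episode_duration_mean[1])
  set.seed(21)
  v1 <- three_epoch_protocol(build_beat_and_glide("base"),
                             silence_population("V1", 0, 1),
                             epoch_ms = 4000, seed = 21)$stats
  expect_gt(v1$episode_duration_mean[2], v1$episode_duration_mean[1])
  expect_lt(v1$interval_mean[2], v1$interval_mean[1])
})

test_that("glycine blockade yields near-continuous swimming", {
  set.seed(21)
  res <- three_epoch_protocol(build_beat_and_glide("base"),
                              block_transmitter("glycinergic", 0, 1),
                              epoch_ms = 4000, seed = 21)$stats
  expect_gt(res$episode_duration_mean[2], 2 * res$episode_duration_mean[1])
  # swimming becomes one long bout: the inter-episode interval either
  # shrinks or disappears entirely
  expect_true(is.na(res$interval_mean[2]) ||
              res$interval_mean[2] < res$interval_mean[1])
})

test_that("transmitter blocks leave gap junctions untouched", {
  # single coiling runs on gap junctions alone: blocking both transmitter
  # classes must not abolish coiling
  circ <- build_single_coiling()
  sim <- simulate_circuit(
    circ, 6000, seed = 1, record_V = FALSE,
    perturbations = list(block_transmitter("glycinergic", 0, 6000),
                         block_transmitter("glutamatergic", 0, 6000)))
  expect_gt(sum(vapply(spike_times(sim, "MN"), length, 1L)), 100)
})
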