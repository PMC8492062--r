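test_that("identical model, seed and duration give bit-identical results", {
  circ <- build_beat_and_glide("base")
  a <- simulate_circuit(circ, 1500, seed = 3, sigma_d = 0.2)
  b <- simulate_circuit(circ, 1500, seed = 3, sigma_d = 0.2)
  expect_identical(a$V, b$V)
  expect_identical(a$spikes, b$spikes)
  expect_identical(a$muscle_V, b$muscle_V)
  expect_identical(a$theta, b$theta)
})

test_that("zero drive means zero spikes and a resting network", {
  circ <- build_single_coiling(
    overrides = list("populations.IC.I_drive" = 0))
  sim <- simulate_circuit(circ, 2000, seed = 1)
  expect_equal(sum(vapply(sim$spikes, length, 1L)), 0L)
  expect_true(all(abs(sim$V - rep(circ$neurons$Vr,
                                  each = nrow(sim$V))) < 1e-9))
})

test_that("chemical currents are off during the initial settling window", {
  # strong drive makes the presynaptic neuron spike immediately; the
  # postsynaptic neuron must stay exactly at rest until 50 ms plus delay
  circ <- toy_circuit(kind = "glut", weight = 5, delay_dist = 0.8,
                      drive = 50, cv = 2)
  sim <- simulate_circuit(circ, 200, seed = 1, record_dt = 0.1)
  expect_gt(length(sim$spikes[[1]]), 0)
  expect_lt(sim$spikes[[1]][1], 50)
  pre50 <- sim$time < 50
  expect_true(all(sim$V[pre50, 2] == circ$neurons$Vr[2]))
  expect_gt(max(abs(sim$V[, 2] - circ$neurons$Vr[2])), 0.01)
})

test_that("postsynaptic current onset lags the crossing by distance / cv", {
  for (dist in c(2, 6)) {
    # drive chosen so the first presynaptic spike happens well after the
    # 50 ms settling window, giving a clean delay measurement
    circ <- toy_circuit(kind = "glut", weight = 5, delay_dist = dist,
                        drive = 5, cv = 2)
    sim <- simulate_circuit(circ, 600, seed = 1, record_dt = 0.1)
    v <- sim$V[, 1]
    up <- which(v[-1] >= -15 & v[-length(v)] < -15)
    t_cross <- sim$time[up[1] + 1]
    expect_gt(t_cross, 55)
    dep <- which(abs(sim$V[, 2] - circ$neurons$Vr[2]) > 1e-9)
    t_onset <- sim$time[dep[1]]
    # current starts one step after the delayed trigger (zero at t = t0)
    expect_equal(t_onset - t_cross, dist / 2 + 0.2, tolerance = 0.11)
  }
})

test_that("delayed synaptic current matches a brute-force kernel oracle", {
  circ <- toy_circuit(kind = "glut", weight = 0.5, delay_dist = 2,
                      drive = 15, cv = 2)
  sim <- simulate_circuit(circ, 600, seed = 1, record_dt = 0.1)
  v <- sim$V[, 1]
  up <- which(v[-1] >= -15 & v[-length(v)] < -15) + 1
  triggers <- sim$time[up] + circ$connections$delay[1]
  # oracle: renewal kernel evaluated with the recorded postsynaptic trace
  # (kernels triggered before 50 ms persist; only the current is gated),
  # then integrated with the same Euler scheme
  I <- ref_chem_current(triggers, sim$time, sim$V[, 2], Erev = 0, W = 0.5)
  I[sim$time < 50] <- 0
  p <- izhikevich_params("MN", "single_coiling")
  V <- p[["Vr"]]; u <- 0
  Vref <- numeric(length(sim$time)); Vref[1] <- V
  for (i in seq_len(length(sim$time) - 1)) {
    st <- euler_step(V, u, p, I[i], 0.1)
    V <- st$V; u <- st$u
    Vref[i + 1] <- st$V_trace
  }
  expect_lt(max(abs(Vref - sim$V[, 2])), 0.05)
})

test_that("a second presynaptic crossing resets the kernel clock", {
  # two triggers closer together than the kernel memory: the current trace
  # must equal the single-t0 formula piecewise (renewal, no superposition)
  circ <- toy_circuit(kind = "glut", weight = 0.3, delay_dist = 0.4,
                      drive = 30, cv = 2)
  sim <- simulate_circuit(circ, 400, seed = 1, record_dt = 0.1)
  v <- sim$V[, 1]
  up <- which(v[-1] >= -15 & v[-length(v)] < -15) + 1
  triggers <- sim$time[up] + circ$connections$delay[1]
  expect_gt(length(triggers), 2)
  I <- ref_chem_current(triggers, sim$time, sim$V[, 2], Erev = 0, W = 0.3)
  I[sim$time < 50] <- 0
  p <- izhikevich_params("MN", "single_coiling")
  V <- p[["Vr"]]; u <- 0
  Vref <- numeric(length(sim$time)); Vref[1] <- V
  for (i in seq_len(length(sim$time) - 1)) {
    st <- euler_step(V, u, p, I[i], 0.1)
    V <- st$V; u <- st$u
    Vref[i + 1] <- st$V_trace
  }
  expect_lt(max(abs(Vref - sim$V[, 2])), 0.05)
})

test_that("gap current conventions behave as documented", {
  # difference form: a resting pair stays at rest
  circ <- toy_circuit(kind = "gap", weight = 0.2, delay_dist = 1.6,
                      drive = 0)
  sim <- simulate_circuit(circ, 300, seed = 1)
  expect_true(all(abs(sim$V[, 2] - circ$neurons$Vr[2]) < 1e-12))
  # printed absolute form injects Vpre * G and pulls the pair off rest
  simp <- simulate_circuit(circ, 300, seed = 1, gap_form = "printed")
  expect_gt(max(abs(simp$V[, 2] - circ$neurons$Vr[2])), 1)
  # a driven presynaptic neuron depolarizes its partner through the junction
  circ2 <- toy_circuit(kind = "gap", weight = 0.2, delay_dist = 1.6,
                       drive = 20)
  sim2 <- simulate_circuit(circ2, 500, seed = 1)
  expect_gt(max(sim2$V[, 2]), circ2$neurons$Vr[2] + 1)
})

test_that("IC firing precedes ipsilateral MN and V0d firing in coils", {
  sim <- simulate_circuit(build_single_coiling(), 4000, seed = 1,
                          record_V = FALSE)
  first_after <- function(kind, t0) {
    s <- sort(unlist(spike_times(sim, kind, "left")))
    s[s >= t0][1]
  }
  ic <- sort(unlist(spike_times(sim, "IC", "left")))
  gaps <- which(diff(ic) > 500)
  burst_starts <- ic[c(1, gaps + 1)]
  for (t0 in burst_starts[1:2]) {
    expect_lt(t0, first_after("MN", t0 - 50))
    expect_lt(t0, first_after("V0d", t0 - 50))
  }
})

test_that("drive noise perturbs the trajectory but respects the seed", {
  circ <- build_single_coiling()
  base <- simulate_circuit(circ, 1000, seed = 2, sigma_d = 0)
  noisy <- simulate_circuit(circ, 1000, seed = 2, sigma_d = 0.5)
  noisy2 <- simulate_circuit(circ, 1000, seed = 2, sigma_d = 0.5)
  expect_false(identical(base$V, noisy$V))
  expect_identical(noisy$V, noisy2$V)
})
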