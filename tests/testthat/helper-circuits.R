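# tiny two-neuron circuit used by engine-level tests: one driven presynaptic
# neuron and one quiet postsynaptic neuron joined by a single connection
toy_circuit <- function(kind = "glut", weight = 1, delay_dist = 4,
                        drive = 10, cv = 2) {
  sheet <- model_param_sheet("single_coiling")
  p <- sheet$populations$MN
  nr <- do.call(rbind, lapply(1:2, function(i) {
    data.frame(kind = "MN", side = c("left", "right")[i], index = 1L,
               segment = 1L, x = c(0, delay_dist)[i], y = c(-1, -1)[i],
               a = p$a, b = p$b, c = p$c, d = p$d, Vmax = p$Vmax, Vr = p$Vr,
               Vt = p$Vt, k = p$k, C = p$C,
               I_drive = c(drive, 0)[i], drive_onset = 0,
               stringsAsFactors = FALSE)
  }))
  nr$id <- 1:2
  conns <- data.frame(pre = 1L, post = 2L, kind = kind, weight = weight,
                      rule = "toy", distance = delay_dist,
                      delay = delay_dist / cv, stringsAsFactors = FALSE)
  muscles <- data.frame(cell = c(1L, 1L), side = c("left", "right"),
                        mn_id = c(1L, 2L), weight = 0,
                        stringsAsFactors = FALSE)
  structure(list(
    name = "toy", variant = "toy", n_somites = 1,
    neurons = nr, connections = conns, muscles = muscles,
    constants = sheet$constants, muscle = sheet$muscle, body = sheet$body,
    rule_info = data.frame(name = "toy", pre = "MN", mode = "all",
                           stringsAsFactors = FALSE),
    meta = list(variant = "single_coiling", n_somites = 1, overrides = NULL)
  ), class = "spinal_circuit")
}

# reference dual-exponential synaptic current with unit-peak normalization,
# renewal semantics (latest trigger only), evaluated on the recorded grid
ref_chem_current <- function(trigger_times, t, Vpost, Erev, tau_r = 0.5,
                             tau_f = 1.0, W = 1) {
  tpk <- log(tau_f / tau_r) * tau_r * tau_f / (tau_f - tau_r)
  kscale <- 1 / (exp(-tpk / tau_f) - exp(-tpk / tau_r))
  out <- numeric(length(t))
  for (i in seq_along(t)) {
    past <- trigger_times[trigger_times <= t[i]]
    if (length(past) == 0) next
    d <- t[i] - max(past)
    out[i] <- W * (Vpost[i] - Erev) * (exp(-d / tau_r) - exp(-d / tau_f)) *
      kscale
  }
  out
}

cv_isi <- function(spikes, from = 100) {
  s <- spikes[spikes >= from]
  if (length(s) < 3) return(NA_real_)
  isi <- diff(s)
  stats::sd(isi) / mean(isi)
}
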