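proto20 <- test_protocol()

test_that("a flat trace contains no spikes", {
  d <- detect_spikes(flat_sweep(-70), proto20)
  expect_equal(nrow(d$aps), 0)
  expect_equal(d$n_in + d$n_pre + d$n_post, 0)
})

test_that("spikes before onset are counted in the pre-window", {
  spec <- trace_spec(spike_times_s = list(`200` = c(0.05, 0.3)),
                     ap_shape = test_ap_shape(), noise_sd_mV = 0)
  ss <- generate_sweep_set(spec, proto20)
  sw <- ss$sweeps[[which(sapply(ss$sweeps, `[[`, "current_pA") == 200)]]
  d <- detect_spikes(sw, proto20)
  expect_equal(d$n_pre, 1)
  expect_equal(d$n_in, 1)
})

test_that("passive features recover planted membrane parameters", {
  spec <- trace_spec(resting_potential_mV = -70,
                     input_resistance_MOhm = 50,
                     membrane_tau_ms = 20, noise_sd_mV = 0)
  ss <- generate_sweep_set(spec, proto20)
  p <- passive_features(ss)
  expect_equal(p$v_rest, -70, tolerance = 1e-6)
  expect_equal(p$r_input, 50, tolerance = 1e-3)
  expect_equal(p$tau, 20, tolerance = 0.02 * 20)
})

test_that("input resistance is the median over hyperpolarizing sweeps", {
  # two hand-built sweeps with plateaus implying 40 and 60 MOhm
  proto <- test_protocol()
  s1 <- square_sweep(rest = -70, level = -74, current = -100)  # 40 MOhm
  s2 <- square_sweep(rest = -70, level = -76, current = -100)  # 60 MOhm
  ss <- sweep_set(list(s1[c(1, 3:5)], s2[c(1, 3:5)]), proto)
  p <- passive_features(ss)
  expect_equal(p$r_input, 50, tolerance = 1e-9)
})

test_that("passive features are flagged without hyperpolarizing sweeps", {
  proto <- test_protocol(steps = c(100, 200))
  ss <- generate_sweep_set(test_spiking_spec(), proto)
  p <- passive_features(ss)
  expect_true(is.na(p$v_rest))
  expect_match(p$flag, "hyperpolarizing")
})

test_that("rheobase is the x-intercept of the count-current line", {
  ss <- generate_sweep_set(test_spiking_spec(), proto20)
  # counts 1..5 at 120..200 pA, zero at 100 -> intercept 100, inside
  expect_equal(rheobase(ss), 100, tolerance = 1e-6)
})

test_that("a single spiking sweep falls back to that current", {
  spec <- trace_spec(spike_times_s = list(`300` = 0.3),
                     ap_shape = test_ap_shape(), noise_sd_mV = 0)
  ss <- generate_sweep_set(spec, test_protocol())
  expect_equal(rheobase(ss), 300)
})

test_that("an out-of-interval intercept is clamped", {
  # counts rising steeply from 60 pA; line crosses zero below the highest
  # zero-spike current (40 pA) -> clamp to the interval edge
  spec <- trace_spec(spike_times_s = list(
    `60` = seq(0.15, 0.55, length.out = 5),
    `80` = seq(0.15, 0.55, length.out = 6),
    `100` = seq(0.15, 0.55, length.out = 7)),
    ap_shape = test_ap_shape(), noise_sd_mV = 0)
  ss <- generate_sweep_set(spec, test_protocol())
  rb <- rheobase(ss)
  # intercept of the line through (60,5),(80,6),(100,7) is -40 -> clamp
  expect_gte(rb, 40)
  expect_lte(rb, 60)
})

test_that("AP shape features match the planted template", {
  shape <- test_ap_shape()
  ss <- generate_sweep_set(test_spiking_spec(), proto20)
  f <- ap_shape_features(ss)
  dt_ms <- 1000 / proto20$sample_rate_hz
  expect_equal(f$ap_threshold, shape$threshold_mV, tolerance = 0.5)
  expect_equal(f$ap_amplitude, shape$amplitude_mV, tolerance = 0.5)
  expect_equal(f$ap_width, shape$halfwidth_ms, tolerance = dt_ms)
  expect_equal(f$ahp, shape$ahp_mV, tolerance = 0.5)
  expect_equal(f$udr, shape$udr, tolerance = 0.05 * shape$udr)
  # first spike planted at 0.15 s, onset 0.1 s -> latency 50 ms
  expect_equal(f$latency, 50, tolerance = 2 * dt_ms)
  # 120 pA is the lowest spiking current; latency at 140 pA sweep
  expect_equal(f$latency_20, 50, tolerance = 2 * dt_ms)
})

test_that("amplitude and UDR scale with the template parameters", {
  shape <- test_ap_shape(amplitude_mV = 60, upstroke_Vps = 300,
                         halfwidth_ms = 0.8, ahp_mV = 15)
  spec <- test_spiking_spec(ap_shape = shape)
  f <- ap_shape_features(generate_sweep_set(spec, proto20))
  expect_equal(f$ap_amplitude, 60, tolerance = 1)
  expect_equal(f$udr, shape$udr, tolerance = 0.05 * shape$udr)
  expect_equal(f$ahp, 15, tolerance = 0.5)
})

test_that("the template half-width/downstroke constraint is enforced", {
  sh <- ap_template(amplitude_mV = 50, upstroke_Vps = 200,
                    downstroke_Vps = -100)
  expect_equal(sh$halfwidth_ms, 25 / 200 + 25 / 100)
  expect_equal(sh$udr, 2)
  expect_error(ap_template(amplitude_mV = 50, upstroke_Vps = 200,
                           halfwidth_ms = 0.1), "too small")
})

test_that("ISI adaptation indices follow their definitions", {
  # spikes at 0.15, 0.25, 0.45: ISIs 0.1, 0.2 -> ratio 2.0
  spec <- trace_spec(spike_times_s = list(`200` = c(0.15, 0.25, 0.45)),
                     ap_shape = test_ap_shape(), noise_sd_mV = 0)
  a <- adaptation_features(generate_sweep_set(spec, proto20))
  expect_equal(a$isi_adapt, 2, tolerance = 0.01)
  expect_equal(a$isi_avg_adapt, 2, tolerance = 0.01)
  # perfectly regular train -> both indices 1, identical templates ->
  # amplitude indices 1
  spec2 <- trace_spec(spike_times_s = list(`200` = seq(0.15, 0.55, 0.1)),
                      ap_shape = test_ap_shape(), noise_sd_mV = 0)
  a2 <- adaptation_features(generate_sweep_set(spec2, proto20))
  expect_equal(a2$isi_adapt, 1, tolerance = 0.01)
  expect_equal(a2$isi_avg_adapt, 1, tolerance = 0.01)
  expect_equal(a2$amp_adapt, 1, tolerance = 0.01)
  expect_equal(a2$amp_avg_adapt, 1, tolerance = 0.01)
})

test_that("the highest firing trace excludes out-of-window firing", {
  # counts 2 at 100, 8 at 120 and 140 -> first max wins (120)
  mk <- function(extra = list()) {
    spikes <- c(list(`100` = c(0.2, 0.4),
                     `120` = seq(0.15, 0.64, length.out = 8),
                     `140` = seq(0.15, 0.64, length.out = 8)), extra)
    trace_spec(spike_times_s = spikes, ap_shape = test_ap_shape(),
               noise_sd_mV = 0)
  }
  ss <- generate_sweep_set(mk(), proto20)
  det <- patchseqr:::detect_all(ss)
  i <- select_highest_firing_trace(ss, det)
  expect_equal(ss$sweeps[[i]]$current_pA, 120)
  # a sweep with a pre-window AP is excluded even with the highest count
  spikes_wild <- list(`160` = c(0.05, seq(0.15, 0.64, length.out = 9)))
  ss2 <- generate_sweep_set(mk(spikes_wild), proto20)
  det2 <- patchseqr:::detect_all(ss2)
  i2 <- select_highest_firing_trace(ss2, det2)
  expect_equal(ss2$sweeps[[i2]]$current_pA, 120)
  expect_equal(wildness(ss2, det2), 9 - 8)
})

test_that("wildness is zero without out-of-window firing", {
  ss <- generate_sweep_set(test_spiking_spec(), proto20)
  expect_identical(wildness(ss), 0)
})

test_that("firing statistics follow their definitions", {
  # 10 spikes: 6 in the first half of the window, 4 in the second
  spikes <- c(seq(0.12, 0.38, length.out = 6),
              seq(0.45, 0.68, length.out = 4))
  spec <- trace_spec(spike_times_s = list(`200` = spikes),
                     ap_shape = test_ap_shape(), noise_sd_mV = 0)
  f <- firing_statistics(generate_sweep_set(spec, proto20))
  expect_equal(f$max_num_aps, 10)
  expect_equal(f$sfa, 4 / 6, tolerance = 1e-9)
  # perfectly regular ISIs -> CV 0
  spec2 <- trace_spec(spike_times_s = list(`200` = seq(0.15, 0.65, 0.05)),
                      ap_shape = test_ap_shape(), noise_sd_mV = 0)
  f2 <- firing_statistics(generate_sweep_set(spec2, proto20))
  expect_lt(f2$isi_cv, 0.01)
  expect_lt(f2$ap_cv, 0.01)
})

test_that("a long Poisson train has ISI CV near one", {
  set.seed(42)
  isi <- rexp(30000, rate = 50)
  st <- cumsum(isi)
  s <- isi_statistics(st)
  expect_equal(s$isi_cv, 1, tolerance = 0.02)
})

test_that("sag features follow the ratio definition and zeroing rule", {
  # rectangular excursion: rest -70, steady -80, trough -85 for 20 ms
  proto <- test_protocol()
  sw <- square_sweep(rest = -70, level = -80, current = -100)
  t <- sw$t
  sag_idx <- t >= proto$onset_s + 0.01 & t < proto$onset_s + 0.03
  sw$voltage_mV[sag_idx] <- -85
  ss <- sweep_set(list(sw[c(1, 3:5)]), proto)
  s <- sag_features(ss)
  expect_equal(s$sag_ratio, 1.5, tolerance = 0.01)
  expect_equal(s$sag_time, 20, tolerance = 0.2)
  expect_equal(s$sag_area, 100, tolerance = 2)

  # trough within 4 mV of steady state -> exact zeros
  sw2 <- square_sweep(rest = -70, level = -80, current = -100)
  sw2$voltage_mV[sag_idx] <- -82
  ss2 <- sweep_set(list(sw2[c(1, 3:5)]), proto)
  s2 <- sag_features(ss2)
  expect_identical(s2$sag_time, 0)
  expect_identical(s2$sag_area, 0)
  expect_equal(s2$sag_ratio, 1.2, tolerance = 0.01)
})

test_that("rebound features follow the averaging and zeroing rules", {
  proto <- test_protocol()
  # post-offset plateau at -65 with rest -70 -> rebound 5
  sw <- square_sweep(rest = -70, level = -80, current = -100)
  sw$voltage_mV[sw$t >= proto$offset_s] <- -65
  ss <- sweep_set(list(sw[c(1, 3:5)]), proto)
  r <- rebound_features(ss)
  expect_equal(r$rebound, 5, tolerance = 0.01)
  expect_equal(r$rebound_aps, 0)

  # voltage stays below rest for 300 ms -> exact zero
  sw2 <- square_sweep(rest = -70, level = -80, current = -100)
  sw2$voltage_mV[sw2$t >= proto$offset_s] <- -75
  ss2 <- sweep_set(list(sw2[c(1, 3:5)]), proto)
  expect_identical(rebound_features(ss2)$rebound, 0)
})

test_that("rebound APs are counted and planted rebound is recovered", {
  spec <- trace_spec(resting_potential_mV = -70,
                     input_resistance_MOhm = 50, membrane_tau_ms = 15,
                     rebound_mV = 6,
                     spike_times_s = list(`-200` = c(0.75, 0.78)),
                     ap_shape = test_ap_shape(), noise_sd_mV = 0)
  ss <- generate_sweep_set(spec, proto20)
  r <- rebound_features(ss)
  expect_equal(r$rebound_aps, 2)
  expect_gt(r$rebound, 0)
})

test_that("burst detection finds detour-direct transitions", {
  # long ISIs dip below the fast trough (detour); short ISIs sit on the
  # inter-spike plateau (direct). Sequence detour, direct, direct,
  # detour -> one burst of the two short ISIs.
  spec <- trace_spec(resting_potential_mV = -70,
                     input_resistance_MOhm = 150,
                     spike_times_s = list(
                       `100` = c(0.15, 0.30, 0.31, 0.32, 0.45, 0.6)),
                     ap_shape = test_ap_shape(), noise_sd_mV = 0)
  ss <- generate_sweep_set(spec, test_protocol(steps = c(-200, 100)))
  b <- burstiness(ss)
  f_in <- 1 / 0.01; f_out <- 1 / 0.13
  expect_equal(b, (f_in - f_out) / (f_in + f_out), tolerance = 0.05)
  # a regular non-bursting train scores exactly zero
  spec2 <- test_spiking_spec()
  expect_identical(burstiness(generate_sweep_set(spec2, proto20)), 0)
})

test_that("features are invariant to sweep ordering", {
  ss <- generate_sweep_set(test_spiking_spec(sag_amplitude_mV = 6,
                                             rebound_mV = 3),
                           proto20)
  f1 <- extract_ephys_features(ss)
  ss2 <- ss
  set.seed(1)
  ss2$sweeps <- ss2$sweeps[sample(length(ss2$sweeps))]
  f2 <- extract_ephys_features(ss2)
  expect_equal(f1, f2)
})

test_that("the full 29-feature record is named and complete", {
  ss <- generate_sweep_set(test_spiking_spec(sag_amplitude_mV = 6,
                                             rebound_mV = 3), proto20)
  f <- extract_ephys_features(ss)
  expect_length(f, 29)
  expect_named(f)
  # this cell defines every feature except none
  expect_true(all(is.finite(f[c("v_rest", "r_input", "rheobase",
                                "ap_threshold", "max_num_aps", "tau",
                                "sag_ratio", "rebound", "isi_cv")])))
})

test_that("the analysis vector keeps 17 features and log-transforms four", {
  ss <- generate_sweep_set(test_spiking_spec(), proto20)
  f <- extract_ephys_features(ss)
  av <- assemble_analysis_vector(f)
  expect_length(av, 17)
  expect_equal(unname(av["latency"]), log(unname(f["latency"])))
  expect_equal(unname(av["isi_adapt"]), log(unname(f["isi_adapt"])))
  expect_false("sag_time" %in% names(av))
  expect_false("wildness" %in% names(av))
  # a cell with an undefined feature is flagged incomplete
  f2 <- f
  f2["rheobase"] <- NA
  av2 <- assemble_analysis_vector(f2)
  expect_false(attr(av2, "complete"))
})

test_that("zeroing rules return exact zeros, not small floats", {
  spec <- trace_spec(resting_potential_mV = -70,
                     input_resistance_MOhm = 20, membrane_tau_ms = 10,
                     spike_times_s = list(`200` = seq(0.15, 0.6, 0.09)),
                     ap_shape = test_ap_shape(), noise_sd_mV = 0)
  ss <- generate_sweep_set(spec, proto20)
  f <- extract_ephys_features(ss)
  # sag excursion of a 20 MOhm cell is ~4 mV total, trough ~ steady
  expect_identical(unname(f["sag_time"]), 0)
  expect_identical(unname(f["sag_area"]), 0)
  expect_identical(unname(f["rebound"]), 0)
  expect_identical(unname(f["wildness"]), 0)
})
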