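# Branched-cable solver: resting stability, analytic passive behavior, spike
# generation, opsin coupling, impedance.

test_that("dark membrane stays at rest and never spikes spontaneously", {
  segs <- mini_segments(mini_pyramidal(), "soma", 1)
  sim <- simulate_cell(segs, membrane_model(), stimulus_protocol(pd = 10,
                                                                 i_fiber = 0))
  expect_false(sim$spike)
  expect_lt(max(sim$v_soma) - min(sim$v_soma), 0.5)
  expect_true(all(is.finite(sim$v_soma)))
  expect_equal(sum(sim$i_integral), 0) # no light, no photocurrent
})

test_that("steady-state attenuation matches the infinite-cable closed form", {
  cab <- straight_cable(n = 320, n_lambda = 5)
  mem <- passive_membrane(settle = 0)
  stim <- stimulus_protocol(pd = 1, t0 = 0, i_fiber = 0)
  stim$t_end <- 300 # ~90 membrane time constants: fully settled
  sim <- simulate_cell(cab$segments, mem, stim,
                       inj = list(seg = 1, amp = 0.05, t0 = 0, dur = 300),
                       record_segments = seq_len(nrow(cab$segments)))
  dv <- sim$v_rec[nrow(sim$v_rec), ] - (-70)
  x <- cab$segments$x - cab$segments$x[1]
  sel <- x <= 2 * cab$lambda
  pred <- dv[1] * exp(-x / cab$lambda)
  expect_lt(max(abs(dv[sel] - pred[sel]) / pred[sel]), 0.02)
})

test_that("suprathreshold somatic injection elicits a spike; dt-robust", {
  sc <- single_compartment(20, 20)
  mem <- membrane_model(g_na = c(soma = 0.12, axon = 0, dend = 0),
                        g_k = c(soma = 0.036, axon = 0, dend = 0),
                        g_leak = 3e-4)
  stim <- stimulus_protocol(pd = 1, t0 = 0, i_fiber = 0)
  stim$t_end <- 100
  coarse <- simulate_cell(sc, mem, stim, dt = 0.025,
                          inj = list(seg = 1, amp = 0.05, t0 = 10, dur = 80))
  fine <- simulate_cell(sc, mem, stim, dt = 0.001,
                        inj = list(seg = 1, amp = 0.05, t0 = 10, dur = 80))
  expect_true(coarse$spike && fine$spike)
  # fine-dt oracle: same peak height and timing to solver accuracy
  expect_equal(coarse$v_peak, fine$v_peak, tolerance = 0.02)
  expect_equal(coarse$t[which.max(coarse$v_soma)],
               fine$t[which.max(fine$v_soma)], tolerance = 0.02)
  # subthreshold current: no spike
  sub <- simulate_cell(sc, mem, stim, dt = 0.025,
                       inj = list(seg = 1, amp = 0.005, t0 = 10, dur = 80))
  expect_false(sub$spike)
})

test_that("spike detection uses a strict -10 mV somatic crossing", {
  expect_false(detect_spike(rep(-70, 100)))
  expect_true(detect_spike(c(rep(-70, 50), 30, rep(-70, 10))))
  expect_false(detect_spike(c(rep(-70, 50), -10)))
  expect_error(detect_spike(numeric(0)), "empty")
})

test_that("threshold titration refines by < 2% under 4x finer time steps", {
  segs <- mini_segments(mini_pyramidal(), "soma", 1)
  mem <- membrane_model()
  i_th <- vapply(c(0.1, 0.025), function(dtv) {
    titrate_threshold(function(i) detect_spike(
      simulate_cell(segs, mem, stimulus_protocol(pd = 10, i_fiber = i),
                    dt = dtv, early_stop = TRUE)), n_iter = 12)$i_th
  }, numeric(1))
  expect_equal(i_th[1], i_th[2], tolerance = 0.02)
})

test_that("spike occurrence is monotone in the fiber irradiance", {
  segs <- mini_segments(mini_pyramidal(), "soma", 1)
  mem <- membrane_model()
  i_grid <- 10^seq(0, 2, length.out = 13)
  spikes <- vapply(i_grid, function(i) detect_spike(
    simulate_cell(segs, mem, stimulus_protocol(pd = 10, i_fiber = i),
                  early_stop = TRUE)), logical(1))
  expect_true(all(diff(spikes) >= 0)) # once spiking, always spiking
  expect_true(any(spikes) && !all(spikes))
})

test_that("opsin-driven depolarization scales with expression and couples
           through the light field", {
  py <- mini_pyramidal()
  mem <- membrane_model()
  stim <- stimulus_protocol(pd = 10, i_fiber = 5)
  v_peak <- vapply(c(0.3, 1, 3), function(gm)
    simulate_cell(mini_segments(py, "soma", gm), mem, stim)$v_peak,
    numeric(1))
  expect_true(all(diff(v_peak) > 0))
  # a fiber far away delivers less light than the uniform field
  f <- cached_field()
  stim_far <- stimulus_protocol(pd = 10, i_fiber = 5,
                                fiber = fiber_spec(pitch = pi / 2,
                                                   position = c(2000, 0)))
  segs <- mini_segments(py, "soma", 1)
  near <- simulate_cell(segs, mem, stim)$v_peak
  far <- simulate_cell(segs, mem, stim_far, field = f)$v_peak
  expect_lt(far, near)
})

test_that("TAC from recorded traces equals the solver's running integral", {
  segs <- mini_segments(mini_pyramidal(), "allsec", 1)
  mem <- membrane_model()
  stim <- stimulus_protocol(pd = 10, i_fiber = 2)
  sim <- simulate_cell(segs, mem, stim, record_currents = TRUE)
  tac_trace <- compute_tac(sim$i_rec, sim$t, segs$area, pd = 10)
  tac_solver <- sum(sim$i_integral) / 10
  expect_equal(tac_trace, tac_solver, tolerance = 1e-9)
  expect_lt(tac_solver, 0) # net inward photocurrent
})

test_that("input impedance matches the analytic passive formula and scaling", {
  sc <- single_compartment(diam = 50, length = 100)
  z <- input_impedance(sc, passive_membrane(g_leak = 3e-4), seg = 1)
  expect_true(z$valid)
  analytic <- 1 / (3e-4 * pi * 50 * 100 * 1e-8) / 1e6
  expect_equal(z$impedance, analytic, tolerance = 0.02)
  # doubling leak halves the impedance
  z2 <- input_impedance(sc, passive_membrane(g_leak = 6e-4), seg = 1)
  expect_equal(z2$impedance, analytic / 2, tolerance = 0.02)
  # distal thin dendrite has a higher impedance than the soma
  py <- mini_pyramidal()
  segs <- morphology_segments(py, 40)
  mem <- membrane_model()
  z_soma <- input_impedance(segs, mem, region = "soma")
  apic_ids <- segs$seg_id[segs$region == "apic"]
  distal <- apic_ids[which.max(segs$z[segs$region == "apic"])]
  z_dend <- input_impedance(segs, mem, seg = distal)
  expect_gt(z_dend$impedance, z_soma$impedance)
})
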