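# Conductance-based membrane model and the coupling of the opsin photocurrent
# into the branched-cable solver. The channel set is a deliberately simple
# stand-in (transient Na, delayed-rectifier K, leak) with per-region density
# scaling (axon > soma > dendrites), enough to give the cells a stable rest
# and a clean spike threshold.

#' Membrane model parameters
#'
#' @param cm Specific capacitance, uF/cm^2.
#' @param ra Axial resistivity, Ohm cm.
#' @param g_leak Leak conductance density, S/cm^2.
#' @param e_leak Leak reversal, mV.
#' @param g_na,g_k Named vectors of channel conductance densities (S/cm^2) per
#'   region (`soma`, `axon`, `basal`, `apic`, `dend`); unnamed regions fall
#'   back to the `dend` entry.
#' @param e_na,e_k Channel reversals, mV.
#' @param na_scale,k_scale Global multipliers on the Na and K densities: the
#'   knob for exploring the depolarizing/hyperpolarizing channel-ratio.
#' @param v_init Initialization potential, mV.
#' @param settle Settling time before the protocol starts, ms.
#' @return A `membrane_model` list.
#' @export
membrane_model <- function(cm = 1, ra = 150, g_leak = 1e-4, e_leak = -70,
                           g_na = c(soma = 0.08, axon = 0.4, basal = 0.012,
                                    apic = 0.012, dend = 0.012),
                           g_k = c(soma = 0.02, axon = 0.12, basal = 0.004,
                                   apic = 0.004, dend = 0.004),
                           e_na = 50, e_k = -77,
                           na_scale = 1, k_scale = 1,
                           v_init = -70, settle = 100) {
  stopifnot(cm > 0, ra > 0, g_leak >= 0, all(g_na >= 0), all(g_k >= 0),
            na_scale >= 0, k_scale >= 0, settle >= 0)
  structure(list(cm = cm, ra = ra, g_leak = g_leak, e_leak = e_leak,
                 g_na = g_na * na_scale, g_k = g_k * k_scale,
                 e_na = e_na, e_k = e_k, v_init = v_init, settle = settle),
            class = "membrane_model")
}

#' Optical stimulus protocol
#'
#' A single rectangular light pulse. The simulation horizon is
#' `t_end = max(500 ms, t0 + pd + 100 ms)` so channel closure after the pulse
#' is always included.
#'
#' @param pd Pulse duration, ms (> 0).
#' @param t0 Pulse onset, ms.
#' @param i_fiber Irradiance at the fiber face, mW/mm^2 (>= 0).
#' @param fiber [fiber_spec()]; ignored in uniform-field mode.
#' @param roll Cell rotation about its somato-dendritic axis, radians.
#' @return A `stimulus_protocol` list including the derived `t_end`.
#' @export
stimulus_protocol <- function(pd = 10, t0 = 0, i_fiber = 1,
                              fiber = fiber_spec(), roll = 0) {
  stopifnot(pd > 0, i_fiber >= 0, t0 >= 0)
  structure(list(pd = pd, t0 = t0, i_fiber = i_fiber, fiber = fiber,
                 roll = roll, t_end = max(500, t0 + pd + 100)),
            class = "stimulus_protocol")
}

density_by_region <- function(dens, regions) {
  fallback <- if ("dend" %in% names(dens)) dens[["dend"]] else 0
  out <- unname(dens[regions])
  out[is.na(out)] <- fallback
  out
}

pack_opsin_params <- function(p) {
  c(p$rect_a, p$rect_k, p$e_chr2,
    p$oinf_b, p$oinf_c, p$rinf_a, p$rinf_b, p$rinf_c,
    p$tauO_a, p$tauO_b, p$tauO_c, p$tauOV_a, p$tauOV_v0, p$tauOV_k,
    p$tauR_a, p$tauR_b1, p$tauR_c1, p$tauR_d1,
    p$tauR_b2, p$tauR_c2, p$tauR_d2,
    p$tauRV_a, p$tauRV_v0, p$tauRV_k)
}

#' Simulate a multicompartment cell under optical stimulation
#'
#' Backward-Euler integration of the branched cable with Na/K/leak membrane
#' dynamics and the ChR2 photocurrent in every opsin-bearing segment. Each
#' segment receives `I_fiber` times the light-field gain at its centroid
#' (uniform-field mode when `field` is `NULL`: every segment receives
#' `I_fiber`). Gates are advanced by exponential Euler, staggered with the
#' voltage solve; initialization is at `v_init` with a settling period before
#' the protocol clock starts.
#'
#' @param segments Segments tibble (from [morphology_segments()], optionally
#'   with a `g_chr2` column from [distribute_opsin()]).
#' @param membrane [membrane_model()].
#' @param stimulus [stimulus_protocol()].
#' @param field A `fluence_field`, or `NULL` for uniform irradiance.
#' @param opsin [opsin_params()] constant set (the conductance density comes
#'   from the `g_chr2` column, not from `opsin$g_chr2`).
#' @param dt Time step, ms.
#' @param inj Optional current injection: list with `seg`, `amp` (nA), `t0`,
#'   `dur` (ms).
#' @param record_segments Segment ids whose voltage traces to keep.
#' @param record_currents Keep the full per-segment opsin current-density
#'   traces (memory scales with segments x time; intended for small cells).
#' @return A `cable_sim` object: `t`, `v_soma`, optional recorded traces, the
#'   per-segment opsin current integral (nA ms), the peak voltage anywhere,
#'   and `spike` (soma crossing of -10 mV).
#' @export
simulate_cell <- function(segments, membrane = membrane_model(),
                          stimulus = stimulus_protocol(), field = NULL,
                          opsin = opsin_params(), dt = 0.025, inj = NULL,
                          record_segments = integer(0),
                          record_currents = FALSE, early_stop = FALSE) {
  n <- nrow(segments)
  if (!"g_chr2" %in% names(segments)) segments$g_chr2 <- rep(0, n)
  area_cm2 <- segments$area * 1e-8
  c_nF <- membrane$cm * area_cm2 * 1e3
  # axial conductance to parent: two half-segment resistances in series
  half_res <- function(i) {
    membrane$ra * (segments$length[i] / 2 * 1e-4) /
      (pi * (segments$diam[i] / 2 * 1e-4)^2)
  }
  hr <- half_res(seq_len(n))
  par <- segments$parent_seg
  g_ax <- numeric(n)
  nz <- which(par > 0)
  g_ax[nz] <- 1e6 / (hr[nz] + hr[par[nz]])
  gain <- if (is.null(field)) rep(1, n) else {
    ff <- to_fiber_frame(as.matrix(segments[, c("x", "y", "z")]),
                         stimulus$fiber, stimulus$roll)
    irradiance_at(field, ff$r / 1000, ff$z_fiber / 1000)
  }
  inj_seg <- if (is.null(inj)) -1L else as.integer(inj$seg - 1)
  res <- cable_simulate_cpp(
    parent = as.integer(par - 1), area_cm2 = area_cm2, c_nF = c_nF,
    g_axial_uS = g_ax,
    g_leak_uS = membrane$g_leak * area_cm2 * 1e6, e_leak = membrane$e_leak,
    g_na_uS = density_by_region(membrane$g_na, segments$region) *
      area_cm2 * 1e6,
    e_na = membrane$e_na,
    g_k_uS = density_by_region(membrane$g_k, segments$region) *
      area_cm2 * 1e6,
    e_k = membrane$e_k,
    g_chr2_Scm2 = segments$g_chr2, opsin_par = pack_opsin_params(opsin),
    irr_gain = gain, i_fiber = stimulus$i_fiber,
    t0 = stimulus$t0, pd = stimulus$pd, t_end = stimulus$t_end, dt = dt,
    v_init = membrane$v_init, settle = membrane$settle,
    inj_seg = inj_seg,
    inj_amp = if (is.null(inj)) 0 else inj$amp,
    inj_t0 = if (is.null(inj)) 0 else inj$t0,
    inj_dur = if (is.null(inj)) 0 else inj$dur,
    record_seg = as.integer(record_segments - 1),
    record_currents = record_currents,
    early_stop = early_stop, stop_threshold = -10
  )
  keep <- seq_len(res$n_samp)
  structure(list(
    t = res$t[keep], v_soma = res$v_soma[keep],
    v_rec = if (nrow(res$v_rec)) res$v_rec[keep, , drop = FALSE] else res$v_rec,
    # currents are recorded as absolute nA; expose densities (mA/cm^2)
    i_rec = if (nrow(res$i_rec))
      sweep(res$i_rec[keep, , drop = FALSE], 2, segments$area * 1e-2, "/")
    else res$i_rec,
    i_integral = res$i_integral, v_peak = res$v_peak,
    spike = res$spiked,
    segments = segments, stimulus = stimulus, dt = dt
  ), class = "cable_sim")
}

#' @export
print.cable_sim <- function(x, ...) {
  cat("<cable_sim>", length(x$t), "samples,", nrow(x$segments), "segments,",
      "I_fiber =", x$stimulus$i_fiber, "mW/mm^2, pd =", x$stimulus$pd,
      "ms\n  spike:", x$spike, " peak V:", signif(x$v_peak, 4), "mV\n")
  invisible(x)
}

#' @export
tidy.cable_sim <- function(x, ...) tibble::tibble(t = x$t, v_soma = x$v_soma)

#' @export
autoplot.cable_sim <- function(object, ...) {
  ggplot2::ggplot(tidy(object), ggplot2::aes(x = .data$t, y = .data$v_soma)) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = -10, linetype = "dashed") +
    ggplot2::labs(x = "time (ms)", y = "soma V (mV)")
}

#' Action-potential detection
#'
#' A spike is a somatic crossing of -10 mV, strictly, anywhere in the trace.
#'
#' @param trace A `cable_sim` or a numeric voltage trace (mV).
#' @param threshold Detection threshold, mV.
#' @return Logical scalar.
#' @export
detect_spike <- function(trace, threshold = -10) {
  v <- if (inherits(trace, "cable_sim")) trace$v_soma else trace
  if (length(v) == 0) stop("empty voltage trace")
  any(v > threshold)
}

#' Input impedance at 0 Hz
#'
#' A small hyperpolarizing current step is injected at the chosen segment
#' after the membrane has settled from its -70 mV initialization, and the
#' impedance is the steady voltage deflection per injected current (MOhm =
#' mV/nA). If the step elicits a spike the measurement is flagged invalid.
#'
#' @param segments Segments tibble.
#' @param membrane [membrane_model()].
#' @param seg Segment id at which to inject and record; defaults to the first
#'   segment of `region`.
#' @param region Region whose first segment to probe when `seg` is `NULL`.
#' @param amp Step amplitude, nA (negative: hyperpolarizing).
#' @param step_dur Step duration, ms (long enough to reach steady state).
#' @param dt Time step, ms.
#' @return A list with `impedance` (MOhm), `seg`, `valid`.
#' @export
input_impedance <- function(segments, membrane = membrane_model(), seg = NULL,
                            region = "soma", amp = -0.02, step_dur = 300,
                            dt = 0.025) {
  if (is.null(seg)) {
    idx <- which(region_mask(segments, region))
    if (!length(idx)) stop("region '", region, "' not present")
    seg <- segments$seg_id[idx[1]]
  }
  t0 <- 50
  stim <- stimulus_protocol(pd = 1, t0 = 0, i_fiber = 0)
  stim$t_end <- t0 + step_dur + 50
  sim <- simulate_cell(segments, membrane, stim, dt = dt,
                       inj = list(seg = seg, amp = amp, t0 = t0,
                                  dur = step_dur),
                       record_segments = seg)
  v <- sim$v_rec[, 1]
  pre <- v[max(which(sim$t < t0))]
  at_end <- v[max(which(sim$t < t0 + step_dur))]
  list(impedance = (at_end - pre) / amp, seg = seg,
       valid = !detect_spike(sim))
}
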