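# ChR2(H134R) photocurrent model: a "double two-state" scheme with two
# independent first-order gates, O (channel opening/closing) and R (dark-light
# adaptation). Each gate relaxes toward an irradiance-dependent steady state
# with a time constant combined harmonically from an irradiance- and a
# voltage-dependent component. Units: Irr mW/mm^2, V mV, tau ms, i mA/cm^2.

#' ChR2(H134R) double two-state opsin parameters
#'
#' Returns the full constant set of the photocurrent model ("chr2_h134r_rsrs_final"):
#' the specific conductance, the reversal parameter and every numeric constant of
#' the steady-state and time-constant expressions. All sigmoids in irradiance
#' share the pattern `a / (1 + exp(b) * Irr^c)`; the voltage sigmoids are
#' `a / (1 + exp(-(V - v0)/k))`.
#'
#' @param g_chr2 Specific conductance in S/cm^2 (non-negative).
#' @param e_chr2 Reversal parameter in mV (default 0). Note the rectification
#'   makes the actual zero-current potential `44.52 * log(1.25)` mV above it.
#' @param ... Overrides for individual model constants (see the returned list
#'   for names). Exposed so a revised calibration is a configuration change.
#'
#' @return An object of class `opsin_params`: a named list of constants.
#' @export
#' @examples
#' p <- opsin_params(g_chr2 = 0.1)
#' opsin_steady_states(1, p)
opsin_params <- function(g_chr2 = 1, e_chr2 = 0, ...) {
  p <- list(
    g_chr2 = g_chr2,
    e_chr2 = e_chr2,
    # rectification D(V) = 1 - rect_a * exp(-(V - e_chr2)/rect_k)
    rect_a = 1.25, rect_k = 44.52,
    # O_inf(Irr) = 1 / (1 + exp(oinf_b) * Irr^oinf_c)
    oinf_b = 5.45, oinf_c = -0.70,
    # R_inf(Irr) = 1 - rinf_a / (1 + exp(rinf_b) * Irr^rinf_c)
    rinf_a = 0.77, rinf_b = 16.33, rinf_c = -3.62,
    # tau_O(Irr) = tauO_a / (1 + exp(tauO_b) * Irr^tauO_c)           [ms]
    tauO_a = 0.021, tauO_b = 1.55, tauO_c = 0.37,
    # tau_O(V)  = tauOV_a / (1 + exp(-(V - tauOV_v0)/tauOV_k))       [ms]
    tauOV_a = 23.14, tauOV_v0 = -0.39, tauOV_k = 13.19,
    # tau_R(Irr) = tauR_a * (1 - tauR_b1/(1 + exp(tauR_c1) * Irr^tauR_d1)
    #                          - tauR_b2/(1 + exp(tauR_c2) * Irr^tauR_d2))
    tauR_a = 10, tauR_b1 = 0.56, tauR_c1 = -1.82, tauR_d1 = -0.50,
    tauR_b2 = 0.44, tauR_c2 = 17.82, tauR_d2 = -3.95,
    # tau_R(V) = tauRV_a / (1 + exp(-(V - tauRV_v0)/tauRV_k))        [ms]
    tauRV_a = 99.74, tauRV_v0 = -38.69, tauRV_k = 12.02
  )
  dots <- list(...)
  if (length(dots)) {
    bad <- setdiff(names(dots), names(p))
    if (length(bad)) stop("unknown opsin constant(s): ", paste(bad, collapse = ", "))
    p[names(dots)] <- dots
  }
  stopifnot(p$g_chr2 >= 0, p$tauO_a > 0, p$tauOV_a > 0, p$tauR_a > 0, p$tauRV_a > 0)
  structure(p, class = "opsin_params")
}

#' Rectification of the ChR2 conductance
#'
#' The photocurrent is `i = g_chr2 * G(V) * (O * R) * (V - e_chr2)` with
#' `G(V) = (1 - 1.25 * exp(-(V - e_chr2)/44.52)) / (V - e_chr2)`. The numerator
#' `D(V) = G(V) * (V - e_chr2)` is finite everywhere and is what the current
#' uses, so the removable singularity of `G` at `V = e_chr2` never arises in a
#' simulation; `G` itself is returned as `NaN` there.
#'
#' @param v Membrane potential(s), mV.
#' @param params An [opsin_params()] object.
#' @return A list with numeric vectors `d` and `g` (`g = d / (v - e_chr2)`).
#' @export
#' @examples
#' opsin_rectification(-68.83)$g # ~0.07: the conductance reduction at rest
opsin_rectification <- function(v, params = opsin_params()) {
  dv <- v - params$e_chr2
  d <- 1 - params$rect_a * exp(-dv / params$rect_k)
  list(d = d, g = d / dv)
}

#' Steady states of the opsin gates
#'
#' `O_inf` rises sigmoidally with irradiance from 0 to 1; `R_inf` falls from 1
#' to `1 - rinf_a` (0.23 with default constants), expressing dark-light
#' adaptation of the photocurrent under sustained illumination. Both depend on
#' irradiance only.
#'
#' @param irr Irradiance(s), mW/mm^2, non-negative.
#' @inheritParams opsin_rectification
#' @return A list with numeric vectors `o_inf` and `r_inf`, both in \[0, 1\].
#' @export
opsin_steady_states <- function(irr, params = opsin_params()) {
  if (any(irr < 0)) stop("irradiance must be non-negative")
  o_inf <- 1 / (1 + exp(params$oinf_b) * irr^params$oinf_c)
  r_inf <- 1 - params$rinf_a / (1 + exp(params$rinf_b) * irr^params$rinf_c)
  # Irr -> 0 limits: Irr^c with c < 0 diverges, so O_inf -> 0, R_inf -> 1.
  o_inf[irr == 0] <- 0
  r_inf[irr == 0] <- 1
  list(o_inf = o_inf, r_inf = r_inf)
}

#' Gate time constants
#'
#' Each gate's time constant combines an irradiance- and a voltage-dependent
#' component harmonically: `tau = 1 / (1/tau(Irr) + 1/tau(V))`, so the combined
#' value never exceeds either component.
#'
#' @inheritParams opsin_steady_states
#' @param v Membrane potential(s), mV.
#' @return A list with numeric vectors `tau_o` and `tau_r` (ms).
#' @export
opsin_time_constants <- function(irr, v, params = opsin_params()) {
  if (any(irr < 0)) stop("irradiance must be non-negative")
  p <- params
  tau_o_irr <- p$tauO_a / (1 + exp(p$tauO_b) * irr^p$tauO_c)
  tau_o_v <- p$tauOV_a / (1 + exp(-(v - p$tauOV_v0) / p$tauOV_k))
  tau_r_irr <- p$tauR_a * (1 - p$tauR_b1 / (1 + exp(p$tauR_c1) * irr^p$tauR_d1)
                             - p$tauR_b2 / (1 + exp(p$tauR_c2) * irr^p$tauR_d2))
  tau_r_irr[irr == 0] <- p$tauR_a # both sigmoids vanish in the dark limit
  tau_r_v <- p$tauRV_a / (1 + exp(-(v - p$tauRV_v0) / p$tauRV_k))
  list(
    tau_o = 1 / (1 / tau_o_irr + 1 / tau_o_v),
    tau_r = 1 / (1 / tau_r_irr + 1 / tau_r_v)
  )
}

#' Dark-adapted initial opsin state
#'
#' The `Irr -> 0` steady state `(O, R) = (0, 1)`: the condition of a cell at
#' rest before any optical stimulation.
#'
#' @param n Number of segments the state is replicated over.
#' @return A list with numeric vectors `o` and `r`.
#' @export
opsin_state_dark <- function(n = 1) list(o = rep(0, n), r = rep(1, n))

#' Advance the opsin gates one time step
#'
#' Exponential-Euler update `X <- X_inf + (X - X_inf) * exp(-dt/tau_X)` per
#' gate; exact for inputs held constant over the step, and unconditionally
#' stable for the stiff opening gate at high irradiance.
#'
#' @param state List with elements `o`, `r` (fractions in \[0, 1\]).
#' @inheritParams opsin_time_constants
#' @param dt Time step, ms (> 0).
#' @return Updated state list.
#' @export
opsin_step <- function(state, irr, v, dt, params = opsin_params()) {
  stopifnot(dt > 0)
  ss <- opsin_steady_states(irr, params)
  tau <- opsin_time_constants(irr, v, params)
  list(
    o = ss$o_inf + (state$o - ss$o_inf) * exp(-dt / tau$tau_o),
    r = ss$r_inf + (state$r - ss$r_inf) * exp(-dt / tau$tau_r)
  )
}

#' Opsin photocurrent density
#'
#' `i_ChR2 = g_chr2 * D(V) * O * R` in mA/cm^2, with `D(V)` the rectification
#' numerator. Negative values are inward (depolarizing) current; the sign of
#' the current equals the sign of `D(V)`, whose zero sits at
#' `e_chr2 + 44.52 * log(1.25)` (~9.93 mV).
#'
#' @inheritParams opsin_step
#' @param v Membrane potential(s), mV.
#' @return Numeric vector of current densities, mA/cm^2.
#' @export
opsin_photocurrent <- function(state, v, params = opsin_params()) {
  params$g_chr2 * opsin_rectification(v, params)$d * state$o * state$r
}

#' Voltage-clamp light-pulse protocol
#'
#' Integrates the gates from the dark-adapted state under a clamped membrane
#' potential and a rectangular light pulse, and reports the current trace with
#' peak and steady-state magnitudes. Mirrors the standard characterization
#' protocol: at high irradiance and long pulses the current is biphasic, with
#' an early peak decaying to a plateau as the adaptation gate relaxes.
#'
#' @param v_clamp Clamped potential, mV.
#' @param irr Pulse irradiance, mW/mm^2.
#' @param pd Pulse duration, ms (> 0).
#' @param t0 Pulse onset, ms.
#' @param t_end End of the simulation, ms.
#' @param dt Time step, ms.
#' @inheritParams opsin_rectification
#' @return An object of class `opsin_clamp`: a list with `trace` (tibble with
#'   columns `t`, `irr`, `o`, `r`, `i`), `peak` and `steady` (magnitudes,
#'   mA/cm^2), and the protocol settings.
#' @export
opsin_voltage_clamp <- function(v_clamp = -70, irr = 10, pd = 100, t0 = 10,
                                t_end = t0 + pd + 100, dt = 0.025,
                                params = opsin_params()) {
  stopifnot(pd > 0, t_end > t0 + pd, dt > 0)
  t <- seq(0, t_end, by = dt)
  n <- length(t)
  irr_t <- ifelse(t >= t0 & t < t0 + pd, irr, 0)
  o <- r <- numeric(n)
  st <- opsin_state_dark(1)
  o[1] <- st$o; r[1] <- st$r
  for (k in seq_len(n - 1)) {
    st <- opsin_step(st, irr_t[k], v_clamp, dt, params)
    o[k + 1] <- st$o; r[k + 1] <- st$r
  }
  i <- params$g_chr2 * opsin_rectification(v_clamp, params)$d * o * r
  on_pulse <- t >= t0 & t <= t0 + pd
  peak <- max(abs(i[on_pulse]))
  steady <- abs(i[which(t <= t0 + pd)[sum(t <= t0 + pd)]]) # value at pulse end
  structure(
    list(
      trace = tibble::tibble(t = t, irr = irr_t, o = o, r = r, i = i),
      peak = peak, steady = steady,
      v_clamp = v_clamp, irr = irr, pd = pd, t0 = t0, dt = dt
    ),
    class = "opsin_clamp"
  )
}

#' @export
print.opsin_clamp <- function(x, ...) {
  cat("<opsin_clamp> V =", x$v_clamp, "mV, Irr =", x$irr, "mW/mm^2, pd =",
      x$pd, "ms\n  |peak| =", signif(x$peak, 4), "mA/cm^2, |steady| =",
      signif(x$steady, 4), "mA/cm^2\n")
  invisible(x)
}

#' @importFrom generics tidy
#' @export
tidy.opsin_clamp <- function(x, ...) x$trace

#' @importFrom ggplot2 autoplot
#' @export
autoplot.opsin_clamp <- function(object, ...) {
  ggplot2::ggplot(object$trace, ggplot2::aes(x = .data$t, y = .data$i)) +
    ggplot2::geom_line() +
    ggplot2::labs(
      x = "time (ms)", y = expression(i[ChR2] ~ (mA / cm^2)),
      title = sprintf("Voltage clamp %g mV, %g mW/mm^2, %g ms pulse",
                      object$v_clamp, object$irr, object$pd)
    )
}

#' Serialize the opsin parameter set
#'
#' Writes the constant block as JSON under the name `chr2_h134r_rsrs_final`,
#' and reads it back.
#'
#' @param params An [opsin_params()] object.
#' @param path File path.
#' @return `write_opsin_params()` returns `path` invisibly;
#'   `read_opsin_params()` returns an `opsin_params` object.
#' @export
write_opsin_params <- function(params, path) {
  jsonlite::write_json(list(chr2_h134r_rsrs_final = unclass(params)), path,
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_opsin_params
#' @export
read_opsin_params <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)$chr2_h134r_rsrs_final
  do.call(opsin_params, x)
}
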