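# Double two-state ChR2(H134R) photocurrent model.

test_that("rectification matches its analytic landmarks", {
  p <- opsin_params()
  expect_equal(opsin_rectification(0, p)$d, -0.25)
  expect_equal(round(opsin_rectification(-68.83, p)$g, 2), 0.07)
  v_zero <- 44.52 * log(1.25)
  expect_equal(opsin_rectification(v_zero, p)$d, 0, tolerance = 1e-12)
  # finite D everywhere, G undefined only at the reversal
  expect_true(is.finite(opsin_rectification(0, p)$d))
  expect_false(is.finite(opsin_rectification(0, p)$g))
})

test_that("steady states hit their limits and are monotone", {
  p <- opsin_params()
  ss0 <- opsin_steady_states(0, p)
  expect_equal(ss0$o_inf, 0)
  expect_equal(ss0$r_inf, 1)
  ss_inf <- opsin_steady_states(1e12, p)
  expect_equal(ss_inf$o_inf, 1, tolerance = 1e-6)
  expect_equal(ss_inf$r_inf, 1 - p$rinf_a, tolerance = 1e-6)
  expect_equal(opsin_steady_states(1, p)$o_inf, 1 / (1 + exp(5.45)))
  irr <- 10^seq(-3, 4, length.out = 60)
  ss <- opsin_steady_states(irr, p)
  expect_true(all(diff(ss$o_inf) >= 0))
  expect_true(all(diff(ss$r_inf) <= 0))
  expect_true(all(ss$o_inf >= 0 & ss$o_inf <= 1))
  expect_true(all(ss$r_inf >= 0 & ss$r_inf <= 1))
  expect_error(opsin_steady_states(-1, p), "non-negative")
})

test_that("time constants combine harmonically and saturate", {
  p <- opsin_params()
  # harmonic mean of equal components halves them: engineered via overrides
  tc <- opsin_time_constants(0, 1e6, opsin_params(tauO_a = 2, tauOV_a = 2,
                                                  tauR_a = 2, tauRV_a = 2))
  expect_equal(tc$tau_o, 1, tolerance = 1e-6)
  # combined tau never exceeds either component
  for (irr in c(0, 0.5, 10, 500)) for (v in c(-90, -70, 0, 40)) {
    tc <- opsin_time_constants(irr, v, p)
    tau_o_v <- p$tauOV_a / (1 + exp(-(v - p$tauOV_v0) / p$tauOV_k))
    expect_lt(tc$tau_o, tau_o_v + 1e-12)
    expect_gt(tc$tau_o, 0)
    expect_gt(tc$tau_r, 0)
  }
  # V -> +inf limit of the voltage-dependent opening component saturates
  expect_equal(p$tauOV_a / (1 + exp(-(1e6 - p$tauOV_v0) / p$tauOV_k)), 23.14,
               tolerance = 1e-9)
})

test_that("exponential Euler is a fixed point at steady state and exact", {
  p <- opsin_params()
  # dark-adapted state under darkness never moves
  st <- opsin_state_dark()
  for (k in 1:20) st <- opsin_step(st, 0, -70, 0.5, p)
  expect_equal(st$o, 0)
  expect_equal(st$r, 1)
  # iterated update equals the closed form under constant input
  irr <- 10; v <- -70
  ss <- opsin_steady_states(irr, p)
  tau <- opsin_time_constants(irr, v, p)
  st <- opsin_state_dark()
  nstep <- 400; dt <- 0.025
  for (k in seq_len(nstep)) st <- opsin_step(st, irr, v, dt, p)
  t_tot <- nstep * dt
  expect_equal(st$o, ss$o_inf + (0 - ss$o_inf) * exp(-t_tot / tau$tau_o),
               tolerance = 1e-12)
  expect_equal(st$r, ss$r_inf + (1 - ss$r_inf) * exp(-t_tot / tau$tau_r),
               tolerance = 1e-12)
})

test_that("integrator agrees with a fine-step explicit-Euler oracle", {
  p <- opsin_params()
  irr <- 10; v <- -70
  dt_c <- 0.025; t_tot <- 10
  # exponential-Euler trajectory
  n_c <- round(t_tot / dt_c)
  o_c <- r_c <- numeric(n_c)
  st <- opsin_state_dark()
  for (k in seq_len(n_c)) {
    st <- opsin_step(st, irr, v, dt_c, p)
    o_c[k] <- st$o; r_c[k] <- st$r
  }
  # brute-force explicit Euler at dt = 1e-5 ms
  dt_f <- 1e-5
  ss <- opsin_steady_states(irr, p)
  tau <- opsin_time_constants(irr, v, p)
  sub <- round(dt_c / dt_f)
  o <- 0; r <- 1
  o_f <- r_f <- numeric(n_c)
  for (k in seq_len(n_c)) {
    for (j in seq_len(sub)) {
      o <- o + dt_f * (ss$o_inf - o) / tau$tau_o
      r <- r + dt_f * (ss$r_inf - r) / tau$tau_r
    }
    o_f[k] <- o; r_f[k] <- r
  }
  expect_lt(max(abs(o_c - o_f)), 1e-6)
  expect_lt(max(abs(r_c - r_f)), 1e-6)
})

test_that("state stays boxed and relaxes monotonically", {
  p <- opsin_params()
  set.seed(7)
  for (rep in 1:8) {
    irr <- 10^runif(1, -2, 3); v <- runif(1, -90, 30)
    st <- list(o = runif(1), r = runif(1))
    ss <- opsin_steady_states(irr, p)
    o_prev <- st$o; r_prev <- st$r
    signs_o <- sign(ss$o_inf - o_prev)
    for (k in 1:100) {
      st <- opsin_step(st, irr, v, 0.05, p)
      expect_true(st$o >= 0 && st$o <= 1 && st$r >= 0 && st$r <= 1)
      # monotone approach toward the steady state
      expect_gte(sign(st$o - o_prev) * signs_o, 0)
      o_prev <- st$o
    }
  }
})

test_that("photocurrent density follows g * D(V) * O * R", {
  p <- opsin_params(g_chr2 = 1)
  expect_equal(opsin_photocurrent(list(o = 0, r = 1), -70, p), 0)
  v_zero <- 44.52 * log(1.25)
  expect_equal(opsin_photocurrent(list(o = 0.5, r = 0.8), v_zero, p), 0,
               tolerance = 1e-12)
  i <- opsin_photocurrent(list(o = 1, r = 1), -70, p)
  expect_lt(i, 0) # inward at rest
  expect_equal(i, 1 - 1.25 * exp(70 / 44.52))
})

test_that("voltage clamp: biphasic onset, saturation, zero-light silence", {
  p <- opsin_params(g_chr2 = 1)
  z <- opsin_voltage_clamp(-70, 0, pd = 50, t0 = 5, params = p)
  expect_true(all(z$trace$i == 0))
  vc <- opsin_voltage_clamp(-70, 10, pd = 100, t0 = 10, params = p)
  expect_gt(vc$peak / vc$steady, 1)
  # peak magnitude nondecreasing in irradiance and bounded by g*|D(-70)|
  irr_grid <- c(0.1, 1, 10, 100, 1000)
  peaks <- vapply(irr_grid, function(irr)
    opsin_voltage_clamp(-70, irr, pd = 100, t0 = 10, params = p)$peak,
    numeric(1))
  expect_true(all(diff(peaks) > 0))
  expect_true(all(peaks <= abs(1 - 1.25 * exp(70 / 44.52))))
  # strong dark-light adaptation at high irradiance: clearly biphasic
  hi <- opsin_voltage_clamp(-70, 1000, pd = 100, t0 = 10, params = p)
  expect_gt(hi$peak / hi$steady, 1.5)
})

test_that("parameter set round-trips through JSON", {
  p <- opsin_params(g_chr2 = 0.123, tauO_a = 0.05)
  path <- tempfile(fileext = ".json")
  write_opsin_params(p, path)
  q <- read_opsin_params(path)
  expect_equal(unclass(q), unclass(p))
  expect_error(opsin_params(nonsense = 1), "unknown opsin constant")
  expect_error(opsin_params(g_chr2 = -1))
})
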