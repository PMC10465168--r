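# Titration arithmetic, TAC closed forms, SoFPAN semantics and bounds,
# optimal/worst positions — on analytic fixtures.

test_that("bisection titration reproduces its exact interval arithmetic", {
  # spike iff I >= 3.7, bracket [1, 10]: the midpoint sequence is fixed
  oracle <- function(i) i >= 3.7
  res <- titrate_threshold(oracle, cap_lo = 1e-3, cap_hi = 1e3)
  expect_equal(res$bracket[2] - res$bracket[1], 9 / 2^7)
  expect_lt(abs(res$i_th - 3.7), 9 / 2^7)
  # the deterministic 7-step midpoint sequence from [1, 10]
  a <- 1; b <- 10; cm <- NA
  for (k in 1:7) { cm <- (a + b) / 2; if (oracle(cm)) b <- cm else a <- cm }
  expect_equal(res$i_th, cm)
})

test_that("titration shifts the bracket down when everything spikes", {
  oracle <- function(i) i >= 1e-5
  res <- titrate_threshold(oracle, cap_lo = 1e-3, cap_hi = 1e3)
  expect_lte(abs(res$i_th - 1e-5), 9e-6 / 2^7 + 1e-18)
  # dense-scan cross-check of the bracket
  expect_true(res$bracket[1] <= 1e-5 && res$bracket[2] >= 1e-5)
})

test_that("titration returns the sentinel when the cap never spikes", {
  res <- titrate_threshold(function(i) FALSE)
  expect_true(is.na(res$i_th))
})

test_that("TAC closed forms: constant pulse, zero current, 1/pd scaling", {
  t <- seq(0, 500, by = 0.5)
  pd <- 20; area <- 1000
  i <- ifelse(t >= 0 & t <= pd, -0.05, 0) # mA/cm^2 during the pulse
  tac <- compute_tac(matrix(i, ncol = 1), t, area, pd)
  # (1/pd) * A * i * pd = A * i (to trapezoid edge accuracy)
  expect_equal(tac, -0.05 * area * 1e-8 * 1e6, tolerance = 0.03)
  expect_equal(compute_tac(matrix(0, length(t), 1), t, area, pd), 0)
  # halving pd with the same total charge doubles the TAC
  tac_half <- compute_tac(matrix(i, ncol = 1), t, area, pd / 2)
  expect_equal(tac_half, 2 * tac)
  expect_error(compute_tac(matrix(i, ncol = 1), t, c(1, 2), pd), "mismatch")
  expect_error(compute_tac(matrix(i, ncol = 1), t[t < 100], area, pd),
               "cover")
})

test_that("the full position grid is the 121-point layout", {
  for (pitch in c(0, pi / 2, pi)) {
    g <- position_grid(pitch)
    expect_equal(length(g$x) * length(g$z), 121)
    expect_equal(g$z, seq(-400, 700, length.out = 11))
  }
  expect_equal(position_grid(pi / 2)$x, seq(-1000, 4000, by = 500))
  expect_equal(position_grid(0)$x, seq(0, 2500, by = 250))
  expect_equal(position_grid(pi / 2)$cell_area, 110 * 500)
  expect_equal(position_grid(0)$cell_area, 110 * 250)
})

test_that("SoFPAN semantics: all-true, none-true, single-point, doubling", {
  all_true <- fixture_map(matrix(0.1, 11, 11), pitch = pi / 2)
  s <- sofpan(all_true, 1)
  expect_equal(s$lower, 5.5)
  expect_equal(s$estimate, 5.5)
  expect_equal(s$upper, 5.5)
  none <- sofpan(all_true, 0.05) # I_fiber below every threshold
  expect_equal(none$lower + none$estimate + none$upper, 0)
  # single interior true point: lower 0, upper > estimate > 0
  m <- matrix(10, 11, 11); m[6, 6] <- 0.1
  s1 <- sofpan(fixture_map(m, pi / 2), 1)
  expect_equal(s1$lower, 0)
  expect_equal(s1$estimate, 0.055)
  expect_equal(s1$upper, 4 * 0.055)
  expect_true(s1$lower <= s1$estimate && s1$estimate <= s1$upper)
  # pitches 0 and pi double the half-plane result
  all0 <- fixture_map(matrix(0.1, 11, 11), pitch = 0)
  s0 <- sofpan(all0, 1)
  expect_equal(s0$estimate, 5.5) # 100 cells x 0.0275 mm^2 x 2
  expect_equal(s0$upper, 5.5)
  # sentinel thresholds never activate
  sent <- fixture_map(matrix(NA_real_, 11, 11), pi / 2)
  expect_equal(sofpan(sent, 1e6)$estimate, 0)
})

test_that("SoFPAN bounds are ordered and monotone on random fixtures", {
  set.seed(42)
  for (rep in 1:10) {
    m <- matrix(10^runif(121, -1, 3), 11, 11)
    map <- fixture_map(m, sample(c(0, pi / 2, pi), 1))
    crv <- sofpan_curve(map)
    expect_true(all(crv$lower <= crv$estimate + 1e-12))
    expect_true(all(crv$estimate <= crv$upper + 1e-12))
    expect_true(all(diff(crv$lower) >= 0))
    expect_true(all(diff(crv$estimate) >= 0))
    expect_true(all(diff(crv$upper) >= 0))
    expect_true(all(crv$upper <= 5.5 + 1e-12))
  }
})

test_that("uniform-approximation error handles the degenerate quotients", {
  expect_equal(sofpan_relative_error(2, 2), 0)
  expect_equal(sofpan_relative_error(1.2, 1.0), 0.2)
  expect_equal(sofpan_relative_error(0.5, 0), Inf)
  expect_equal(sofpan_relative_error(0, 0.5), -1)
  expect_equal(sofpan_relative_error(0, 0), 0)
})

test_that("uniform-field point-cell map divides the threshold by the gain", {
  f <- cached_field()
  umap <- sofpan_uniform_map(5, f, pitch = pi / 2, nx = 5, nz = 5)
  expect_s3_class(umap, "threshold_map")
  # at the fiber position facing the soma the gain is near 1 from very close
  close_pos <- umap[umap$x == 250 & umap$z == 150, ]
  expect_true(is.finite(close_pos$i_th))
  # unreachable positions carry the sentinel
  expect_true(any(is.na(umap$i_th)) || all(umap$i_th > 0))
})

test_that("optimal/worst z positions follow depth of activation and the TAC
           tie-break", {
  m <- matrix(10, 3, 3) # x by z
  m[, 2] <- 0.1 # middle z row fully activated
  map <- fixture_map(m, pi / 2)
  ow <- optimal_worst_positions(map, 1)
  expect_equal(ow$z_opt, sort(unique(map$z))[2])
  expect_true(ow$z_worst != ow$z_opt)
  # tie on depth: lower mean TAC wins optimal, higher wins worst
  m2 <- matrix(0.1, 3, 3)
  map2 <- fixture_map(m2, pi / 2)
  map2$tac <- rep(c(3, 1, 2), each = 3) # per-z mean TAC
  ow2 <- optimal_worst_positions(map2, 1)
  zs <- sort(unique(map2$z))
  expect_equal(ow2$z_opt, zs[2]) # lowest TAC
  expect_equal(ow2$z_worst, zs[1]) # highest TAC
  # constant map: both default to the first grid z
  map3 <- fixture_map(matrix(0.1, 3, 3), pi / 2)
  map3$tac <- rep(1, 9)
  ow3 <- optimal_worst_positions(map3, 1)
  expect_equal(ow3$z_opt, zs[1])
  expect_equal(ow3$z_worst, zs[1])
  expect_error(optimal_worst_positions(fixture_map(matrix(NA_real_, 3, 3)),
                                       1), "sentinel")
})
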