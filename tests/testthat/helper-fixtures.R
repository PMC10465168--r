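# Shared fixtures: scaled-down synthetic cells and cached light fields so the
# suite stays fast while exercising the full pipeline.

mini_pyramidal <- function(seed = 1) {
  generate_pyramidal(params = list(
    axon_length = 300, basal_n_stem = 2, basal_depth = 1, basal_len = 70,
    trunk_len = 200, oblique_n = 2, oblique_len = 100,
    tuft_n_stem = 2, tuft_depth = 1, tuft_len = 90
  ), seed = seed, name = "pyr_mini")
}

mini_basket <- function(seed = 2) {
  generate_interneuron(params = list(
    dend_n_stem = 4, dend_depth = 1, dend_len = 90,
    axon_n_stem = 2, axon_depth = 2, axon_len = 120
  ), seed = seed, preset = "basket", name = "int_mini")
}

mini_segments <- function(morph, region = "soma", g_max = 1,
                          max_seg_len = 40) {
  distribute_opsin(morphology_segments(morph, max_seg_len), region, g_max)
}

# single passive compartment with known analytic impedance
single_compartment <- function(diam = 50, length = 100) {
  tibble::tibble(seg_id = 1L, sec_id = 1L, region = "soma", x = 0, y = 0,
                 z = 0, length = length, diam = diam,
                 area = pi * diam * length, parent_seg = 0L)
}

# unbranched passive cable: n segments of total length `n_lambda` space
# constants
straight_cable <- function(n = 320, diam = 2, g_leak = 3e-4, ra = 150,
                           n_lambda = 5) {
  lambda_um <- sqrt((1 / g_leak) * (diam * 1e-4) / (4 * ra)) * 1e4
  len <- n_lambda * lambda_um / n
  list(
    segments = tibble::tibble(
      seg_id = seq_len(n), sec_id = 1L, region = "dend",
      x = (seq_len(n) - 0.5) * len, y = 0, z = 0, length = len, diam = diam,
      area = pi * diam * len, parent_seg = c(0L, seq_len(n - 1))),
    lambda = lambda_um
  )
}

passive_membrane <- function(g_leak = 3e-4, settle = 100) {
  membrane_model(g_leak = g_leak,
                 g_na = c(soma = 0, axon = 0, dend = 0),
                 g_k = c(soma = 0, axon = 0, dend = 0),
                 settle = settle)
}

# session-cached fields (built once per test run)
.field_cache <- new.env()

cached_field <- function(name = "default", builder = NULL) {
  if (is.null(.field_cache[[name]])) {
    .field_cache[[name]] <- if (is.null(builder))
      simulate_fluence_field(n_photons = 1e5, seed = 42) else builder()
  }
  .field_cache[[name]]
}

# hand-built threshold map for SoFPAN fixtures: `i_th` is an nx x nz matrix
fixture_map <- function(i_th, pitch = pi / 2) {
  nx <- nrow(i_th); nz <- ncol(i_th)
  grid <- position_grid(pitch, nx, nz)
  out <- tibble::tibble(x = rep(grid$x, times = nz),
                        z = rep(grid$z, each = nx),
                        i_th = as.vector(i_th), tac = NA_real_)
  structure(out, class = c("threshold_map", class(out)),
            pitch = pitch, pd = 10, nx = nx, nz = nz,
            cell_area = grid$cell_area, region = "fixture")
}

# exact-enumeration oracle for the one-sided paired Wilcoxon signed-rank
# p-value (no ties, n <= 10): enumerates all 2^n sign assignments
wilcoxon_enum_p <- function(x, y) {
  d <- x - y
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  v_obs <- sum(r[d > 0])
  total <- 0
  for (mask in 0:(2^n - 1)) {
    signs <- bitwAnd(bitwShiftR(mask, 0:(n - 1)), 1L) == 1L
    if (sum(r[signs]) >= v_obs) total <- total + 1
  }
  total / 2^n
}
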