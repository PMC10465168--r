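# End-to-end experiment recipes: the uniform-field study (thresholds, TAC,
# regression, scoring), the Monte Carlo-field study (threshold maps, SoFPAN
# curves and bounds, optimal/worst positions, uniform-approximation error),
# and the elementary-effects sensitivity screen.

#' Experiment configuration
#'
#' Bundles cells, opsin regions, stimulation grids, optics and seeds for the
#' study recipes. Defaults follow the study conditions: G_max on 8 log-spaced
#' points in \[0.1, 10^1.5\] uS, pd on 5 log-spaced points in \[1, 100\] ms
#' (9 in \[0.1, 1000\] ms for uniform-field runs), 9 log-spaced fiber
#' intensities in \[0.1, 1000\] mW/mm^2, and the 11 x 11 fiber-position grid.
#'
#' @param cells Named list of `morphology` objects.
#' @param regions Opsin regions to test (skipped silently for cells lacking
#'   them, e.g. `basal` on interneurons).
#' @param g_max_grid,pd_grid Stimulation grids (uS, ms).
#' @param pitches Fiber pitches to sweep.
#' @param i_fibers Fiber-intensity grid, mW/mm^2.
#' @param optics [optical_properties()].
#' @param n_photons Photons for the light field.
#' @param nx,nz Fiber-position grid resolution.
#' @param mc_pd,mc_g_max The (pd, G_max) setup used for threshold maps.
#' @param ee_i_fiber Fiber intensity at which the sensitivity screen
#'   evaluates the SoFPAN.
#' @param membrane [membrane_model()].
#' @param opsin [opsin_params()].
#' @param max_seg_len Segment discretization, um.
#' @param dt Solver time step, ms.
#' @param cap_hi Titration intensity cap, mW/mm^2.
#' @param seed Master seed; stages derive their seeds from it.
#' @return An `experiment_config` list.
#' @export
experiment_config <- function(cells,
                              regions = c("allsec", "soma"),
                              g_max_grid = 10^seq(-1, 1.5, length.out = 8),
                              pd_grid = 10^seq(0, 2, length.out = 5),
                              pitches = c(0, pi / 2, pi),
                              i_fibers = i_fiber_grid(),
                              optics = optical_properties(),
                              n_photons = 1e6, nx = 11, nz = 11,
                              mc_pd = 10, mc_g_max = 1.179,
                              ee_i_fiber = 10,
                              membrane = membrane_model(),
                              opsin = opsin_params(),
                              max_seg_len = 20, dt = 0.025, cap_hi = 1e3,
                              seed = 1) {
  stopifnot(length(cells) >= 1, length(regions) >= 1,
            length(g_max_grid) >= 1, length(pd_grid) >= 1,
            length(pitches) >= 1, length(i_fibers) >= 1,
            all(g_max_grid > 0), all(pd_grid > 0))
  if (is.null(names(cells)))
    names(cells) <- vapply(cells, `[[`, character(1), "name")
  structure(list(
    cells = cells, regions = regions, g_max_grid = g_max_grid,
    pd_grid = pd_grid, pitches = pitches, i_fibers = i_fibers,
    optics = optics, n_photons = n_photons, nx = nx, nz = nz,
    mc_pd = mc_pd, mc_g_max = mc_g_max, ee_i_fiber = ee_i_fiber,
    membrane = membrane, opsin = opsin, max_seg_len = max_seg_len,
    dt = dt, cap_hi = cap_hi, seed = seed
  ), class = "experiment_config")
}

config_hash <- function(config) rlang::hash(unclass(config))

cell_region_segments <- function(config, cell_name, region, g_max) {
  morph <- config$cells[[cell_name]]
  segs <- morphology_segments(morph, config$max_seg_len)
  if (!any(region_mask(segs, region))) return(NULL)
  out <- distribute_opsin(segs, region, g_max)
  attr(out, "region") <- region
  out
}

uniform_titrate <- function(segments, config, pd) {
  spike_at <- function(i_fiber) {
    stim <- stimulus_protocol(pd = pd, t0 = 0, i_fiber = i_fiber)
    detect_spike(simulate_cell(segments, config$membrane, stim,
                               opsin = config$opsin, dt = config$dt,
                               early_stop = TRUE))
  }
  tit <- titrate_threshold(spike_at, cap_hi = config$cap_hi)
  tac <- if (is.na(tit$i_th)) NA_real_ else {
    stim <- stimulus_protocol(pd = pd, t0 = 0, i_fiber = tit$i_th)
    sim_tac(simulate_cell(segments, config$membrane, stim,
                          opsin = config$opsin, dt = config$dt))
  }
  list(i_th = tit$i_th, tac = tac)
}

#' Uniform-field excitability study
#'
#' Every cell section receives the fiber irradiance directly. For each cell,
#' opsin region, pulse duration and expression level, the intensity threshold
#' is titrated and the TAC evaluated at threshold; per cell-region class the
#' two-step regression (Lapicque on TAC, then the log-linear threshold model)
#' is fit, and classes are scored with paired one-sided Wilcoxon signed-rank
#' tests on the threshold. Sentinel rows ("no threshold below the cap") stay
#' in the threshold table and are excluded from the regression.
#'
#' @param config [experiment_config()].
#' @return A list: `thresholds` (tibble cell/region/pd/g_max/i_th/tac),
#'   `fits` (per-class regression parameters), `scores`
#'   ([excitability_scores()] or `NULL` when no complete pairing exists),
#'   `config_hash`, `seed`.
#' @export
run_uniform_field_study <- function(config) {
  rows <- list()
  for (cn in names(config$cells)) for (rg in config$regions) {
    segs <- cell_region_segments(config, cn, rg, 1)
    if (is.null(segs)) next
    for (gm in config$g_max_grid) {
      segs_g <- distribute_opsin(segs, rg, gm)
      for (pd in config$pd_grid) {
        res <- tryCatch(uniform_titrate(segs_g, config, pd),
                        error = function(e) {
                          warning(cn, "/", rg, " pd=", pd, " failed: ",
                                  conditionMessage(e))
                          list(i_th = NA_real_, tac = NA_real_)
                        })
        rows[[length(rows) + 1]] <- tibble::tibble(
          cell = cn, region = rg, pd = pd, g_max = gm,
          i_th = res$i_th, tac = res$tac)
      }
    }
  }
  thresholds <- dplyr::bind_rows(rows)
  fits <- thresholds |>
    dplyr::filter(!is.na(.data$i_th)) |>
    dplyr::group_by(.data$cell, .data$region) |>
    dplyr::group_modify(function(df, key) {
      if (length(unique(df$g_max)) < 2 || length(unique(df$pd)) < 3)
        return(tibble::tibble())
      lap <- lapicque_fit(df$pd, df$tac)
      reg <- threshold_regression(df$g_max, abs(predict(lap, df$pd)),
                                  df$i_th)
      tibble::tibble(tac_0 = lap$tac_0, tau = lap$tau,
                     adj_r2_tac = lap$adj_r2,
                     a_g = reg$a_g, a_pd = reg$a_pd, c = reg$c,
                     adj_r2_tot = reg$adj_r2)
    }) |>
    dplyr::ungroup()
  scored <- thresholds |>
    dplyr::mutate(class = paste(.data$cell, .data$region, sep = "/"),
                  key = paste(.data$pd, .data$g_max))
  complete_keys <- scored |>
    dplyr::filter(!is.na(.data$i_th)) |>
    dplyr::count(.data$key) |>
    dplyr::filter(.data$n == length(unique(scored$class)))
  scores <- if (nrow(complete_keys) >= 5) {
    excitability_scores(
      dplyr::filter(scored, .data$key %in% complete_keys$key),
      direction = "less", value = "i_th")
  } else NULL
  list(thresholds = thresholds, fits = fits, scores = scores,
       config_hash = config_hash(config), seed = config$seed)
}

#' Monte Carlo-field excitability study
#'
#' Builds (or reuses) the fiber light field, sweeps the fiber-position grid
#' per cell, region and pitch at the configured (pd, G_max) setup, and
#' derives SoFPAN curves with bounds, optimal/worst fiber positions, and the
#' relative error of the uniform-field (point-cell) approximation.
#'
#' @param config [experiment_config()].
#' @param field Optional pre-built `fluence_field` (cached between calls).
#' @return A list: `field`, `maps` (named list of `threshold_map`s),
#'   `sofpan` (tibble with curves per setup), `positions` (optimal/worst per
#'   setup and intensity), `uniform_error` (tibble of relative errors),
#'   `config_hash`, `seed`.
#' @export
run_mc_field_study <- function(config, field = NULL) {
  if (is.null(field))
    field <- simulate_fluence_field(config$optics,
                                    n_photons = config$n_photons,
                                    seed = config$seed)
  maps <- list(); sof <- list(); pos <- list(); uerr <- list()
  for (cn in names(config$cells)) for (rg in config$regions) {
    segs <- cell_region_segments(config, cn, rg, config$mc_g_max)
    if (is.null(segs)) next
    unif <- tryCatch(uniform_titrate(segs, config, config$mc_pd),
                     error = function(e) list(i_th = NA_real_))
    for (pitch in config$pitches) {
      key <- paste(cn, rg, signif(pitch, 3), sep = "/")
      map <- sweep_positions(segs, config$membrane, field, pitch = pitch,
                             pd = config$mc_pd, nx = config$nx,
                             nz = config$nz, dt = config$dt,
                             opsin = config$opsin, cap_hi = config$cap_hi)
      maps[[key]] <- map
      crv <- sofpan_curve(map, config$i_fibers)
      sof[[key]] <- dplyr::mutate(crv, cell = cn, region = rg, pitch = pitch)
      pos[[key]] <- dplyr::bind_rows(lapply(config$i_fibers, function(i_f) {
        ow <- tryCatch(optimal_worst_positions(map, i_f),
                       error = function(e) list(z_opt = NA_real_,
                                                z_worst = NA_real_))
        tibble::tibble(cell = cn, region = rg, pitch = pitch, i_fiber = i_f,
                       z_opt = ow$z_opt, z_worst = ow$z_worst)
      }))
      if (!is.na(unif$i_th)) {
        umap <- sofpan_uniform_map(unif$i_th, field, pitch = pitch,
                                   nx = config$nx, nz = config$nz)
        ucrv <- sofpan_curve(umap, config$i_fibers)
        uerr[[key]] <- tibble::tibble(
          cell = cn, region = rg, pitch = pitch,
          i_fiber = config$i_fibers,
          sofpan_mc = crv$estimate, sofpan_uniform = ucrv$estimate,
          rel_error = sofpan_relative_error(ucrv$estimate, crv$estimate))
      }
    }
  }
  list(field = field, maps = maps,
       sofpan = dplyr::bind_rows(sof),
       positions = dplyr::bind_rows(pos),
       uniform_error = dplyr::bind_rows(uerr),
       config_hash = config_hash(config), seed = config$seed)
}

#' Elementary-effects sensitivity study
#'
#' Screens the six uncertain factors (mu_a, mu_s', G_max, cell, opsin
#' location, roll) for their influence on the SoFPAN estimate at the
#' configured (pd, I_fiber) setup. Light fields are rebuilt when the optics
#' change and cached across model evaluations.
#'
#' @param config [experiment_config()]; `config$cells` supplies the discrete
#'   cell classes and `config$regions` the location classes.
#' @param r Elementary effects per factor.
#' @param factors Optional list of [ee_factor()] overrides.
#' @return An `ee_result` tibble (plus `config_hash`, `seed` attributes).
#' @export
run_sensitivity_study <- function(config, r = 16, factors = NULL) {
  if (is.null(factors))
    factors <- default_ee_factors(cells = names(config$cells),
                                  locations = config$regions)
  cache <- new.env()
  get_field <- function(mu_a, mu_s_prime) {
    key <- paste(signif(mu_a, 8), signif(mu_s_prime, 8))
    if (!is.null(cache[[key]])) return(cache[[key]])
    optics <- optical_properties(mu_a = mu_a,
                                 mu_s = mu_s_prime / (1 - config$optics$g),
                                 g = config$optics$g, n = config$optics$n)
    f <- simulate_fluence_field(optics, n_photons = config$n_photons,
                                seed = config$seed)
    cache[[key]] <- f
    f
  }
  model <- function(x) {
    field <- get_field(x$mu_a, x$mu_s_prime)
    segs <- cell_region_segments(config, x$cell, x$location,
                                 max(x$g_max, 1e-6))
    if (is.null(segs)) return(0)
    map <- sweep_positions(segs, config$membrane, field,
                           pitch = config$pitches[1], pd = config$mc_pd,
                           roll = x$roll, nx = config$nx, nz = config$nz,
                           dt = config$dt, opsin = config$opsin,
                           cap_hi = config$cap_hi)
    sofpan(map, config$ee_i_fiber)$estimate
  }
  out <- elementary_effects(model, factors, r = r, seed = config$seed + 1)
  attr(out, "config_hash") <- config_hash(config)
  out
}
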