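# Monte Carlo simulated light field of a flat-tip optical fiber in homogeneous
# gray matter, recorded on a cylindrical (r, z) grid as an irradiance gain:
# local irradiance per unit irradiance at the fiber face.

#' Tissue optical properties
#'
#' Defaults are in-vivo gray matter at 470 nm: absorption 0.42 mm^-1,
#' scattering 11.33 mm^-1, anisotropy 0.88, refractive index 1.36. The derived
#' reduced scattering coefficient `mu_s_prime = mu_s * (1 - g)` is included.
#'
#' @param mu_a Absorption coefficient, mm^-1.
#' @param mu_s Scattering coefficient, mm^-1.
#' @param g Henyey-Greenstein anisotropy factor, in (-1, 1).
#' @param n Refractive index, >= 1.
#' @return An `optical_properties` list.
#' @export
optical_properties <- function(mu_a = 0.42, mu_s = 11.33, g = 0.88, n = 1.36) {
  stopifnot(mu_a >= 0, mu_s >= 0, g > -1, g < 1, n >= 1)
  structure(list(mu_a = mu_a, mu_s = mu_s, g = g, n = n,
                 mu_s_prime = mu_s * (1 - g)),
            class = "optical_properties")
}

#' Optical fiber specification
#'
#' @param radius Fiber radius, um (default 100).
#' @param na Numerical aperture (default 0.39); must be below the tissue
#'   refractive index.
#' @param pitch Fiber-axis orientation relative to the somato-dendritic (z)
#'   axis: one of 0, pi/2, pi radians.
#' @param position Fiber-tip position `c(x, z)` in the cell frame, um.
#' @return A `fiber_spec` list.
#' @export
fiber_spec <- function(radius = 100, na = 0.39, pitch = pi / 2,
                       position = c(0, 0)) {
  stopifnot(radius > 0, na > 0, length(position) == 2)
  if (!any(abs(pitch - c(0, pi / 2, pi)) < 1e-12))
    stop("pitch must be one of 0, pi/2, pi")
  structure(list(radius = radius, na = na, pitch = pitch,
                 position = as.numeric(position)),
            class = "fiber_spec")
}

#' Henyey-Greenstein polar-angle sampling
#'
#' Inverse-transform sample of the scattering-angle cosine for anisotropy `g`;
#' degenerates to the isotropic `2u - 1` at `g = 0`. `E[cos theta] = g`.
#'
#' @param g Anisotropy factor.
#' @param u Uniform variates in \[0, 1).
#' @return Cosines in \[-1, 1\].
#' @export
sample_hg_cos <- function(g, u) {
  stopifnot(all(u >= 0), all(u < 1))
  if (abs(g) < 1e-12) return(2 * u - 1)
  frac <- (1 - g^2) / (1 - g + 2 * g * u)
  pmin(1, pmax(-1, (1 + g^2 - frac^2) / (2 * g)))
}

#' Simulate the fiber light field by Monte Carlo photon transport
#'
#' Photons are launched uniformly over the fiber disk with directions uniform
#' in the acceptance cone (half-angle `asin(NA/n)`), random-walk through the
#' homogeneous medium with Henyey-Greenstein scattering, and deposit absorbed
#' weight at each interaction site. Fluence rate per voxel is deposited energy
#' divided by `mu_a` times voxel volume; dividing by the fiber-face irradiance
#' gives a unitless gain. The grid boundary absorbs (escape is tallied) and
#' photons below the roulette threshold play Russian roulette so the energy
#' balance closes exactly.
#'
#' @param optics [optical_properties()].
#' @param fiber [fiber_spec()] (only radius and NA are used here).
#' @param n_photons Number of photon packets.
#' @param seed Integer seed; the field is bit-identical for identical seeds.
#' @param r_max,z_min,z_max Grid extent, mm (defaults span \[0,5\] x \[-4,6\]).
#' @param dr,dz Voxel size, mm. The desk-scale default is 10 um; the full
#'   tabulated setting (5 um, 1e7 photons) is a configuration change.
#' @param roulette_threshold,roulette_survival Russian-roulette settings.
#' @return A `fluence_field` object: gain matrix on (r, z) voxel centers plus
#'   optics, fiber, seed and the energy-balance tallies.
#' @export
simulate_fluence_field <- function(optics = optical_properties(),
                                   fiber = fiber_spec(),
                                   n_photons = 1e6, seed = 1,
                                   r_max = 5, z_min = -4, z_max = 6,
                                   dr = 0.010, dz = 0.010,
                                   roulette_threshold = 1e-4,
                                   roulette_survival = 0.1) {
  set.seed(seed)
  radius_mm <- fiber$radius / 1000
  raw <- mc_transport_cpp(optics$mu_a, optics$mu_s, optics$g, optics$n,
                          radius_mm, fiber$na,
                          r_max, z_min, z_max, dr, dz, as.integer(n_photons),
                          roulette_threshold, roulette_survival)
  r_centers <- (seq_len(raw$nr) - 0.5) * dr
  z_centers <- z_min + (seq_len(raw$nz) - 0.5) * dz
  # cylindrical shell volumes, mm^3
  r_edges <- seq(0, by = dr, length.out = raw$nr + 1)
  vol <- pi * (r_edges[-1]^2 - r_edges[-length(r_edges)]^2) * dz
  # gain = fluence rate per unit fiber-face irradiance
  gain <- raw$deposit / (n_photons * optics$mu_a * vol) * (pi * radius_mm^2)
  structure(list(
    gain = gain, r = r_centers, z = z_centers, dr = dr, dz = dz,
    r_max = r_max, z_min = z_min, z_max = z_max,
    optics = optics, fiber = fiber, n_photons = n_photons, seed = seed,
    balance = list(absorbed = raw$absorbed, escaped = raw$escaped,
                   roulette_killed = raw$roulette_killed,
                   roulette_gained = raw$roulette_gained,
                   launched = raw$launched)
  ), class = "fluence_field")
}

#' Energy-balance residual of a Monte Carlo run
#'
#' Relative residual of `absorbed + escaped + roulette_killed -
#' roulette_gained - launched`; closes to machine precision by construction.
#'
#' @param field A `fluence_field`.
#' @return Relative residual (scalar).
#' @export
energy_balance <- function(field) {
  b <- field$balance
  abs(b$absorbed + b$escaped + b$roulette_killed - b$roulette_gained -
        b$launched) / b$launched
}

#' @export
print.fluence_field <- function(x, ...) {
  cat("<fluence_field>", dim(x$gain)[1], "x", dim(x$gain)[2],
      "voxels, dr =", x$dr * 1000, "um,", format(x$n_photons, big.mark = ","),
      "photons, seed", x$seed, "\n  energy-balance residual:",
      signif(energy_balance(x), 3), "\n")
  invisible(x)
}

#' Interpolate the irradiance gain
#'
#' Bilinear interpolation on voxel centers; queries outside the recorded grid
#' return 0, and queries at a voxel center return the stored value exactly.
#'
#' @param field A `fluence_field`.
#' @param r,z Query coordinates, mm (vectors of equal length; `r >= 0`).
#' @return Numeric vector of gains (>= 0).
#' @export
irradiance_at <- function(field, r, z) {
  stopifnot(length(r) == length(z))
  out <- numeric(length(r))
  inside <- r >= 0 & r < field$r_max & z >= field$z_min & z < field$z_max
  if (!any(inside)) return(out)
  ri <- r[inside]; zi <- z[inside]
  rc <- field$r; zc <- field$z
  # clamp to the center range: constant extrapolation across the half-voxel rim
  rq <- pmin(pmax(ri, rc[1]), rc[length(rc)])
  zq <- pmin(pmax(zi, zc[1]), zc[length(zc)])
  i0 <- pmin(findInterval(rq, rc), length(rc) - 1)
  j0 <- pmin(findInterval(zq, zc), length(zc) - 1)
  fr <- (rq - rc[i0]) / field$dr
  fz <- (zq - zc[j0]) / field$dz
  g <- field$gain
  val <- (1 - fr) * (1 - fz) * g[cbind(i0, j0)] +
    fr * (1 - fz) * g[cbind(i0 + 1, j0)] +
    (1 - fr) * fz * g[cbind(i0, j0 + 1)] +
    fr * fz * g[cbind(i0 + 1, j0 + 1)]
  out[inside] <- val
  out
}

#' Map cell-frame points into the fiber frame
#'
#' The cell frame has the soma at the origin and the somato-dendritic axis on
#' z. The fiber sits at `position = c(x, z)` in the plane `y = 0`. Pitch 0
#' points the beam along +z, pitch pi along -z, and pitch pi/2 along -x (light
#' travels toward the cell from `x = position[1]`). `roll` first rotates the
#' morphology about the z axis.
#'
#' @param points Numeric matrix (n x 3) of cell-frame coordinates, um.
#' @param fiber [fiber_spec()] including pitch and position (um).
#' @param roll Rotation of the cell about z, radians.
#' @return A tibble with columns `r`, `z_fiber` in um.
#' @export
to_fiber_frame <- function(points, fiber, roll = 0) {
  points <- as.matrix(points)
  stopifnot(ncol(points) == 3)
  if (roll != 0) {
    cr <- cos(roll); sr <- sin(roll)
    points <- cbind(cr * points[, 1] - sr * points[, 2],
                    sr * points[, 1] + cr * points[, 2],
                    points[, 3])
  }
  fx <- fiber$position[1]; fz <- fiber$position[2]
  p <- fiber$pitch
  if (abs(p - pi / 2) < 1e-12) {
    z_f <- fx - points[, 1]
    r <- sqrt(points[, 2]^2 + (points[, 3] - fz)^2)
  } else if (abs(p) < 1e-12) {
    z_f <- points[, 3] - fz
    r <- sqrt((points[, 1] - fx)^2 + points[, 2]^2)
  } else if (abs(p - pi) < 1e-12) {
    z_f <- fz - points[, 3]
    r <- sqrt((points[, 1] - fx)^2 + points[, 2]^2)
  } else {
    stop("pitch must be one of 0, pi/2, pi")
  }
  tibble::tibble(r = r, z_fiber = z_f)
}

#' Persist a fluence field as plain text
#'
#' Writes the gain matrix as CSV plus a JSON sidecar with grid axes, optics,
#' fiber and seed metadata; `read_fluence_field()` restores the object.
#'
#' @param field A `fluence_field`.
#' @param path Base path; `.csv` and `.json` files are written next to it.
#' @return The base path, invisibly.
#' @export
write_fluence_field <- function(field, path) {
  utils::write.csv(as.data.frame(field$gain), paste0(path, ".csv"),
                   row.names = FALSE)
  meta <- field[c("r", "z", "dr", "dz", "r_max", "z_min", "z_max",
                  "n_photons", "seed", "balance")]
  meta$optics <- unclass(field$optics)
  meta$fiber <- unclass(field$fiber)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_fluence_field
#' @export
read_fluence_field <- function(path) {
  gain <- as.matrix(utils::read.csv(paste0(path, ".csv")))
  dimnames(gain) <- NULL
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  structure(list(
    gain = gain, r = meta$r, z = meta$z, dr = meta$dr, dz = meta$dz,
    r_max = meta$r_max, z_min = meta$z_min, z_max = meta$z_max,
    optics = do.call(optical_properties,
                     meta$optics[c("mu_a", "mu_s", "g", "n")]),
    fiber = do.call(fiber_spec, meta$fiber),
    n_photons = meta$n_photons, seed = meta$seed,
    balance = as.list(meta$balance)
  ), class = "fluence_field")
}

#' @export
autoplot.fluence_field <- function(object, trans = "log10", floor = 1e-8, ...) {
  df <- expand.grid(r = object$r, z = object$z)
  df$gain <- pmax(as.vector(object$gain), floor)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$r, y = .data$z,
                                   fill = .data$gain)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(trans = trans, name = "gain") +
    ggplot2::labs(x = "r (mm)", y = "z (mm)")
}
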