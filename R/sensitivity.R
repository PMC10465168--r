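# Morris elementary-effects screening with a radial design built on a Sobol
# low-discrepancy sequence. Factors live in the unit hypercube and are mapped
# through their inverse distributions, so elementary effects of heterogeneous
# factor types (normal optics, uniform roll, discrete cell/location classes)
# share a comparable unit-hypercube denominator.

# -- Sobol sequence ---------------------------------------------------------
# Direction-number table (primitive polynomial degree s, coefficient a,
# initial m values) for dimensions 2..16; dimension 1 is the van der Corput
# sequence in base 2.
sobol_table <- list(
  list(s = 1, a = 0, m = c(1)),
  list(s = 2, a = 1, m = c(1, 3)),
  list(s = 3, a = 1, m = c(1, 3, 1)),
  list(s = 3, a = 2, m = c(1, 1, 1)),
  list(s = 4, a = 1, m = c(1, 1, 3, 3)),
  list(s = 4, a = 4, m = c(1, 3, 5, 13)),
  list(s = 5, a = 2, m = c(1, 1, 5, 5, 17)),
  list(s = 5, a = 4, m = c(1, 1, 5, 5, 5)),
  list(s = 5, a = 7, m = c(1, 1, 7, 11, 19)),
  list(s = 5, a = 11, m = c(1, 1, 5, 1, 1)),
  list(s = 5, a = 13, m = c(1, 1, 1, 3, 11)),
  list(s = 5, a = 14, m = c(1, 3, 5, 5, 31)),
  list(s = 6, a = 1, m = c(1, 3, 3, 9, 7, 49)),
  list(s = 6, a = 13, m = c(1, 1, 1, 15, 21, 21)),
  list(s = 6, a = 16, m = c(1, 3, 1, 13, 27, 49))
)

sobol_directions <- function(dim, nbits = 31) {
  v <- integer(nbits)
  if (dim == 1) {
    for (k in seq_len(nbits)) v[k] <- bitwShiftL(1L, nbits - k)
    return(v)
  }
  e <- sobol_table[[dim - 1]]
  s <- e$s; a <- e$a
  m <- c(e$m, integer(max(0, nbits - s)))
  if (nbits > s) {
    for (k in (s + 1):nbits) {
      mk <- bitwXor(m[k - s], bitwShiftL(m[k - s], s))
      for (j in seq_len(s - 1)) {
        if (bitwAnd(bitwShiftR(a, s - 1 - j), 1L) == 1L)
          mk <- bitwXor(mk, bitwShiftL(m[k - j], j))
      }
      m[k] <- mk
    }
  }
  for (k in seq_len(nbits)) v[k] <- bitwShiftL(m[k], nbits - k)
  v
}

#' Sobol low-discrepancy sequence
#'
#' Gray-code generator with standard direction numbers for up to 16
#' dimensions. The first dimension is the van der Corput sequence in base 2
#' (1/2, 3/4, 1/4, ...); the zero point is skipped.
#'
#' @param n Number of points.
#' @param dim Dimension (<= 16).
#' @return An `n` x `dim` matrix of points in (0, 1).
#' @export
sobol_sequence <- function(n, dim) {
  stopifnot(n >= 1, dim >= 1, dim <= 16)
  nbits <- 31
  v <- vapply(seq_len(dim), sobol_directions, integer(nbits), nbits = nbits)
  x <- integer(dim)
  out <- matrix(0, n, dim)
  for (i in seq_len(n)) {
    # index of the lowest zero bit of (i - 1)
    c_bit <- 1L; ii <- i - 1L
    while (bitwAnd(ii, 1L) == 1L) { ii <- bitwShiftR(ii, 1L); c_bit <- c_bit + 1L }
    x <- bitwXor(x, v[c_bit, ])
    out[i, ] <- x / 2^nbits
  }
  out
}

# -- factor specifications --------------------------------------------------

#' Uncertain-factor specification for elementary effects
#'
#' @param name Factor name.
#' @param type `"normal"` (mean and coefficient of variation, truncated at
#'   `trunc` standard deviations to keep optics physical), `"uniform"`
#'   (`min`, `max`), or `"discrete"` (uniform over `classes`).
#' @param mean,cv Normal parameters (sd = cv * mean).
#' @param min,max Uniform bounds.
#' @param classes Vector of discrete class labels.
#' @param trunc Truncation, in standard deviations, for normal factors.
#' @return An `ee_factor` list with a `quantile` function mapping (0,1) to
#'   the factor's scale.
#' @export
ee_factor <- function(name, type = c("normal", "uniform", "discrete"),
                      mean = NULL, cv = NULL, min = NULL, max = NULL,
                      classes = NULL, trunc = 4) {
  type <- match.arg(type)
  q <- switch(type,
    normal = {
      stopifnot(cv > 0)
      sd <- cv * mean
      p_lo <- stats::pnorm(mean - trunc * sd, mean, sd)
      p_hi <- stats::pnorm(mean + trunc * sd, mean, sd)
      function(u) stats::qnorm(p_lo + u * (p_hi - p_lo), mean, sd)
    },
    uniform = {
      stopifnot(max > min)
      function(u) min + u * (max - min)
    },
    discrete = {
      if (!length(classes)) stop("discrete factor needs nonempty classes")
      k <- length(classes)
      function(u) classes[pmin(k, floor(u * k) + 1L)]
    }
  )
  structure(list(name = name, type = type, mean = mean, cv = cv, min = min,
                 max = max, classes = classes, quantile = q),
            class = "ee_factor")
}

#' The six uncertain factors of the sensitivity screen
#'
#' Absorption and reduced scattering coefficients and expression level are
#' normal (means 0.42 mm^-1, 1.36 mm^-1, 1 uS; CV 0.15 each); roll is uniform
#' over \[-pi, pi); cell and opsin location are discrete-uniform.
#'
#' @param cells Discrete cell classes.
#' @param locations Discrete opsin-location classes.
#' @return A list of [ee_factor()] specifications.
#' @export
default_ee_factors <- function(cells = c("pyr_1", "pyr_2"),
                               locations = c("allsec", "axon", "soma",
                                             "basal")) {
  list(
    ee_factor("mu_a", "normal", mean = 0.42, cv = 0.15),
    ee_factor("mu_s_prime", "normal", mean = 11.33 * (1 - 0.88), cv = 0.15),
    ee_factor("g_max", "normal", mean = 1, cv = 0.15),
    ee_factor("cell", "discrete", classes = cells),
    ee_factor("location", "discrete", classes = locations),
    ee_factor("roll", "uniform", min = -pi, max = pi)
  )
}

map_point <- function(factors, u) {
  out <- lapply(seq_along(factors), function(j) factors[[j]]$quantile(u[j]))
  names(out) <- vapply(factors, `[[`, character(1), "name")
  out
}

#' Elementary-effects screening (Morris, radial design)
#'
#' `r` repetitions are sampled with the radial design on a Sobol sequence in
#' `2 d` dimensions: repetition `i` uses row `i` for the base point and the
#' second half of row `i + shift` for the one-at-a-time steps. Each factor's
#' elementary effect is the output difference divided by the unit-hypercube
#' step; for a discrete factor whose step lands in the same class, the class
#' advances cyclically so every step is a real perturbation. `mu_star` is the
#' mean absolute elementary effect, `sigma` their standard deviation
#' (interactions/non-linearity). A digital shift drawn from `seed` randomizes
#' the sequence, so results are deterministic given the seed.
#'
#' @param model Function taking a named list of factor values, returning a
#'   scalar.
#' @param factors List of [ee_factor()] specifications.
#' @param r Number of elementary effects per factor (default 16).
#' @param seed Integer seed.
#' @param shift Row offset between base and auxiliary points.
#' @return An `ee_result` tibble: `factor`, `mu_star`, `sigma`, `mean_ee`,
#'   `rank` (1 = most influential); the raw effects matrix is attached as
#'   attribute `ee`.
#' @export
elementary_effects <- function(model, factors, r = 16, seed = 1, shift = 4) {
  d <- length(factors)
  stopifnot(r >= 2, d >= 1, 2 * d <= 16)
  set.seed(seed)
  dig <- stats::runif(2 * d)
  s <- (sobol_sequence(r + shift, 2 * d) + rep(dig, each = r + shift)) %% 1
  ee <- matrix(NA_real_, r, d)
  eval_model <- function(u) {
    pt <- map_point(factors, u)
    val <- tryCatch(model(pt), error = function(e)
      stop("model failed at point (", paste(signif(u, 4), collapse = ", "),
           "): ", conditionMessage(e)))
    if (!is.finite(val)) stop("model returned non-finite value at point (",
                              paste(signif(u, 4), collapse = ", "), ")")
    val
  }
  for (i in seq_len(r)) {
    a <- s[i, 1:d]
    b <- s[i + shift, (d + 1):(2 * d)]
    f_a <- eval_model(a)
    for (j in seq_len(d)) {
      bj <- b[j]
      fac <- factors[[j]]
      if (fac$type == "discrete") {
        k <- length(fac$classes)
        ca <- floor(a[j] * k); cb <- floor(bj * k)
        if (ca == cb) { # same class: advance to the next one cyclically
          cb <- (cb + 1) %% k
          bj <- (cb + 0.5) / k
        }
      }
      if (abs(bj - a[j]) < 1e-12) { ee[i, j] <- 0; next }
      u2 <- a; u2[j] <- bj
      ee[i, j] <- (eval_model(u2) - f_a) / (bj - a[j])
    }
  }
  out <- tibble::tibble(
    factor = vapply(factors, `[[`, character(1), "name"),
    mu_star = colMeans(abs(ee)),
    sigma = apply(ee, 2, stats::sd),
    mean_ee = colMeans(ee)
  )
  out$rank <- rank(-out$mu_star, ties.method = "min")
  structure(out, class = c("ee_result", class(out)), ee = ee, r = r,
            seed = seed)
}

#' @export
autoplot.ee_result <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$mu_star, y = .data$sigma,
                                       label = .data$factor)) +
    ggplot2::geom_point() +
    ggplot2::geom_text(vjust = -0.6) +
    ggplot2::labs(x = expression(mu * "*"), y = expression(sigma))
}

#' @export
tidy.ee_result <- function(x, ...) tibble::as_tibble(x)
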