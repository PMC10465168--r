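# Synthetic CA1-like multicompartment morphologies. A morphology is a tree of
# sections (polylines with per-point diameters and a region label); sections
# are discretized into segments of bounded length for the cable solver.
# Regions: soma, axon, basal, apic (pyramidal) or soma, axon, dend
# (interneuron); composites dend = basal U apic and allsec = everything.

REGIONS_COMPOSITE <- c("dend", "alldend", "allsec", "all")

new_morphology <- function(sections, cell_type, name = cell_type) {
  stopifnot(is.data.frame(sections),
            all(c("sec_id", "region", "parent", "points") %in% names(sections)))
  structure(list(sections = sections, cell_type = cell_type, name = name),
            class = "morphology")
}

#' @export
print.morphology <- function(x, ...) {
  segs <- morphology_segments(x)
  cat("<morphology>", x$name, "(", x$cell_type, "):",
      nrow(x$sections), "sections,", nrow(segs), "segments\n")
  print(morphology_summary(x))
  invisible(x)
}

# ---------------------------------------------------------------------------
# generation helpers

#' @keywords internal
rotate_towards <- function(axis, theta, phi) {
  # unit vector at polar angle theta from `axis`, azimuth phi
  axis <- axis / sqrt(sum(axis^2))
  ref <- if (abs(axis[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
  e1 <- ref - sum(ref * axis) * axis
  e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(axis[2] * e1[3] - axis[3] * e1[2],
          axis[3] * e1[1] - axis[1] * e1[3],
          axis[1] * e1[2] - axis[2] * e1[1])
  cos(theta) * axis + sin(theta) * (cos(phi) * e1 + sin(phi) * e2)
}

grow_tree <- function(env, origin, dir, region, parent_id, n_children, depth,
                      len, len_cv, diam, taper, spread_deg) {
  for (k in seq_len(n_children)) {
    theta <- if (is.na(spread_deg)) acos(stats::runif(1, -1, 1)) else
      stats::runif(1, 0.15, spread_deg * pi / 180)
    d <- rotate_towards(dir, theta, stats::runif(1, 0, 2 * pi))
    L <- len * exp(stats::rnorm(1, 0, len_cv))
    p_end <- origin + d * L
    p_mid <- origin + d * L / 2 +
      rotate_towards(d, pi / 2, stats::runif(1, 0, 2 * pi)) * L * 0.05
    d_end <- diam * taper
    env$sec_id <- env$sec_id + 1
    id <- env$sec_id
    env$sections[[id]] <- list(
      sec_id = id, region = region, parent = parent_id,
      points = cbind(rbind(origin, p_mid, p_end),
                     c(diam, (diam + d_end) / 2, d_end))
    )
    if (depth > 0)
      grow_tree(env, p_end, d, region, id, 2, depth - 1,
                len, len_cv, d_end, taper, 40)
  }
  invisible(env)
}

make_section_env <- function() {
  env <- new.env()
  env$sections <- list()
  env$sec_id <- 0
  env
}

finish_morphology <- function(env, cell_type, name) {
  secs <- env$sections
  tbl <- tibble::tibble(
    sec_id = vapply(secs, `[[`, integer(1) + 0, "sec_id"),
    region = vapply(secs, `[[`, character(1), "region"),
    parent = vapply(secs, `[[`, integer(1) + 0, "parent"),
    points = lapply(secs, function(s) {
      m <- s$points
      dimnames(m) <- list(NULL, c("x", "y", "z", "diam"))
      m
    })
  )
  if (any(vapply(tbl$points, function(m) any(m[, "diam"] <= 0), logical(1))))
    stop("degenerate parameters: non-positive diameter")
  new_morphology(tbl, cell_type, name)
}

#' Generate a synthetic CA1-like pyramidal cell
#'
#' Soma and axon plus a stochastic binary basal tree directed into the -z
#' hemisphere and an apical trunk along +z carrying oblique branches and a
#' tuft. Default parameters are calibrated so the per-region membrane areas
#' fall inside the bands spanned by reconstructed CA1 pyramidal cells (soma
#' roughly 400-1,400 um^2, dendrites in the low tens of thousands of um^2).
#'
#' @param params Named list overriding any default listed in the function
#'   body (counts, lengths, diameters, tapers).
#' @param seed Integer seed; the same seed reproduces the morphology exactly.
#' @param name Cell label carried through result tables.
#' @return A `morphology` object.
#' @export
generate_pyramidal <- function(params = list(), seed = 1, name = "pyr_syn") {
  p <- utils::modifyList(list(
    soma_length = 20, soma_diam = 12,
    axon_length = 600, axon_diam = 0.8,
    basal_n_stem = 4, basal_depth = 2, basal_len = 90, basal_len_cv = 0.15,
    basal_diam = 1.3, basal_taper = 0.75, basal_spread = 55,
    trunk_len = 350, trunk_diam = 2.4, trunk_taper = 0.7,
    oblique_n = 5, oblique_len = 150, oblique_diam = 1.0,
    tuft_n_stem = 2, tuft_depth = 2, tuft_len = 130, tuft_diam = 1.1,
    tuft_taper = 0.8
  ), params)
  if (any(unlist(p[c("soma_length", "soma_diam", "axon_length", "axon_diam",
                     "basal_len", "trunk_len")]) <= 0))
    stop("degenerate parameters: lengths and diameters must be positive")
  set.seed(seed)
  env <- make_section_env()
  # soma: cylinder along z, centered at the origin
  env$sec_id <- 1
  env$sections[[1]] <- list(
    sec_id = 1, region = "soma", parent = 0,
    points = cbind(rbind(c(0, 0, -p$soma_length / 2),
                         c(0, 0, p$soma_length / 2)),
                   c(p$soma_diam, p$soma_diam))
  )
  soma_bottom <- c(0, 0, -p$soma_length / 2)
  soma_top <- c(0, 0, p$soma_length / 2)
  # axon: descending, slight jitter
  ax_dir <- rotate_towards(c(0, 0, -1), 0.1, stats::runif(1, 0, 2 * pi))
  env$sec_id <- 2
  env$sections[[2]] <- list(
    sec_id = 2, region = "axon", parent = 1,
    points = cbind(rbind(soma_bottom,
                         soma_bottom + ax_dir * p$axon_length / 2,
                         soma_bottom + ax_dir * p$axon_length),
                   rep(p$axon_diam, 3))
  )
  # basal tree: stems into the -z hemisphere
  if (p$basal_n_stem > 0)
    grow_tree(env, soma_bottom, c(0, 0, -1), "basal", 1,
              p$basal_n_stem, p$basal_depth, p$basal_len, p$basal_len_cv,
              p$basal_diam, p$basal_taper, p$basal_spread)
  # apical trunk straight up
  env$sec_id <- env$sec_id + 1
  trunk_id <- env$sec_id
  trunk_end_diam <- p$trunk_diam * p$trunk_taper
  env$sections[[trunk_id]] <- list(
    sec_id = trunk_id, region = "apic", parent = 1,
    points = cbind(rbind(soma_top,
                         soma_top + c(0, 0, p$trunk_len / 2),
                         soma_top + c(0, 0, p$trunk_len)),
                   c(p$trunk_diam, (p$trunk_diam + trunk_end_diam) / 2,
                     trunk_end_diam))
  )
  # obliques from along the trunk
  for (k in seq_len(p$oblique_n)) {
    frac <- stats::runif(1, 0.2, 0.9)
    o0 <- soma_top + c(0, 0, p$trunk_len * frac)
    grow_tree(env, o0, rotate_towards(c(0, 0, 1), pi / 2.2,
                                      stats::runif(1, 0, 2 * pi)),
              "apic", trunk_id, 1, 0, p$oblique_len, 0.2, p$oblique_diam,
              0.8, NA)
  }
  # tuft on the trunk end
  grow_tree(env, soma_top + c(0, 0, p$trunk_len), c(0, 0, 1), "apic",
            trunk_id, p$tuft_n_stem, p$tuft_depth, p$tuft_len, 0.15,
            p$tuft_diam, p$tuft_taper, 45)
  finish_morphology(env, "pyramidal", name)
}

#' Generate a synthetic CA1-like interneuron
#'
#' Soma, undifferentiated dendrites (region `dend`), and a large axonal arbor.
#' The `bistratified` preset carries an axon arbor an order of magnitude
#' larger than its dendritic tree (~1e5 um^2); the `basket` preset has an
#' axon area comparable to (slightly above) its dendrites (~2.5e4 um^2).
#'
#' @inheritParams generate_pyramidal
#' @param preset `"bistratified"` or `"basket"`.
#' @return A `morphology` object.
#' @export
generate_interneuron <- function(params = list(), seed = 1,
                                 preset = c("bistratified", "basket"),
                                 name = NULL) {
  preset <- match.arg(preset)
  base <- list(
    soma_length = 25, soma_diam = 14,
    dend_n_stem = 8, dend_depth = 2, dend_len = 135, dend_len_cv = 0.15,
    dend_diam = 1.2, dend_taper = 0.78,
    axon_diam = 0.6, axon_len_cv = 0.1
  )
  if (preset == "bistratified") {
    base$axon_n_stem <- 6; base$axon_depth <- 4; base$axon_len <- 300
  } else {
    base$axon_n_stem <- 4; base$axon_depth <- 3; base$axon_len <- 240
  }
  p <- utils::modifyList(base, params)
  set.seed(seed)
  env <- make_section_env()
  env$sec_id <- 1
  env$sections[[1]] <- list(
    sec_id = 1, region = "soma", parent = 0,
    points = cbind(rbind(c(0, 0, -p$soma_length / 2),
                         c(0, 0, p$soma_length / 2)),
                   c(p$soma_diam, p$soma_diam))
  )
  soma_bottom <- c(0, 0, -p$soma_length / 2)
  # undifferentiated dendrites: isotropic stems
  grow_tree(env, c(0, 0, 0), c(0, 0, 1), "dend", 1,
            p$dend_n_stem, p$dend_depth, p$dend_len, p$dend_len_cv,
            p$dend_diam, p$dend_taper, NA)
  # axonal arbor (no taper: thin axonal cable throughout)
  grow_tree(env, soma_bottom, c(0, 0, -1), "axon", 1,
            p$axon_n_stem, p$axon_depth, p$axon_len, p$axon_len_cv,
            p$axon_diam, 1.0, NA)
  finish_morphology(env, "interneuron",
                    name %||% paste0("int_", substr(preset, 1, 4)))
}

# ---------------------------------------------------------------------------
# discretization and areas

# lateral frustum area of the sub-span [s1, s2] (arc length) of a polyline
frustum_area_span <- function(pts, s_edges, s1, s2) {
  area <- 0
  for (e in seq_len(nrow(pts) - 1)) {
    a <- s_edges[e]; b <- s_edges[e + 1]
    lo <- max(a, s1); hi <- min(b, s2)
    if (hi <= lo) next
    f1 <- (lo - a) / (b - a); f2 <- (hi - a) / (b - a)
    r1 <- (pts[e, 4] * (1 - f1) + pts[e + 1, 4] * f1) / 2
    r2 <- (pts[e, 4] * (1 - f2) + pts[e + 1, 4] * f2) / 2
    dl <- hi - lo
    area <- area + pi * (r1 + r2) * sqrt(dl^2 + (r1 - r2)^2)
  }
  area
}

#' Discretize a morphology into segments
#'
#' Splits every section into segments of at most `max_seg_len` (um) equal arc
#' length, computing per-segment centroid, length, diameter, lateral membrane
#' area (summed conical frusta) and parent connectivity (parent index always
#' precedes the child: the ordering the cable solver requires).
#'
#' @param morph A `morphology`.
#' @param max_seg_len Maximum segment length, um (default 20).
#' @return A tibble with one row per segment: `seg_id`, `sec_id`, `region`,
#'   `x`, `y`, `z`, `length`, `diam`, `area` (um^2), `parent_seg` (0 for the
#'   root).
#' @export
morphology_segments <- function(morph, max_seg_len = 20) {
  stopifnot(inherits(morph, "morphology"), max_seg_len > 0)
  secs <- morph$sections
  out <- vector("list", nrow(secs))
  seg_count <- 0
  for (si in seq_len(nrow(secs))) {
    pts <- secs$points[[si]]
    edge_len <- sqrt(rowSums((pts[-1, 1:3, drop = FALSE] -
                                pts[-nrow(pts), 1:3, drop = FALSE])^2))
    s_edges <- c(0, cumsum(edge_len))
    L <- s_edges[length(s_edges)]
    nseg <- max(1L, ceiling(L / max_seg_len))
    bounds <- seq(0, L, length.out = nseg + 1)
    interp <- function(s, col) {
      stats::approx(s_edges, pts[, col], xout = s, rule = 2)$y
    }
    mid <- (bounds[-1] + bounds[-length(bounds)]) / 2
    par_sec <- secs$parent[si]
    parent0 <- if (par_sec == 0) 0L else {
      # attach to the spatially nearest segment of the parent section, so
      # mid-section branches (e.g. obliques on the trunk) couple correctly
      ptab <- out[[par_sec]]
      d2 <- (ptab$x - pts[1, 1])^2 + (ptab$y - pts[1, 2])^2 +
        (ptab$z - pts[1, 3])^2
      ptab$seg_id[which.min(d2)]
    }
    seg_ids <- seg_count + seq_len(nseg)
    out[[si]] <- tibble::tibble(
      seg_id = seg_ids,
      sec_id = secs$sec_id[si],
      region = secs$region[si],
      x = interp(mid, 1), y = interp(mid, 2), z = interp(mid, 3),
      length = diff(bounds),
      diam = interp(mid, 4),
      area = vapply(seq_len(nseg), function(k)
        frustum_area_span(pts, s_edges, bounds[k], bounds[k + 1]), numeric(1)),
      parent_seg = c(parent0, seg_ids[-nseg])
    )
    seg_count <- seg_count + nseg
  }
  dplyr::bind_rows(out)
}

region_mask <- function(segments, region, cell_type = NULL) {
  reg <- segments$region
  has_split <- any(reg %in% c("basal", "apic"))
  switch(region,
    allsec = , all = rep(TRUE, length(reg)),
    dend = , alldend = if (has_split) reg %in% c("basal", "apic")
             else reg == "dend",
    reg == region
  )
}

#' Total membrane surface area of a subcellular region
#'
#' Sums the frustum lateral areas of all segments in the region. Composites:
#' `dend` (basal plus apical for pyramidal cells, the undifferentiated
#' dendrites for interneurons) and `allsec` (everything).
#'
#' @param morph A `morphology` or a segments tibble from
#'   [morphology_segments()].
#' @param region Region name: `soma`, `axon`, `basal`, `apic`, `dend`,
#'   `allsec`.
#' @return Area in um^2.
#' @export
region_area <- function(morph, region) {
  segments <- if (inherits(morph, "morphology")) morphology_segments(morph)
              else morph
  known <- c("soma", "axon", "basal", "apic", unique(segments$region),
             REGIONS_COMPOSITE)
  if (!region %in% known)
    stop("unknown region '", region, "'; available: ",
         paste(sort(unique(c(segments$region, REGIONS_COMPOSITE))),
               collapse = ", "))
  mask <- region_mask(segments, region)
  if (!any(mask))
    stop("region '", region, "' has no sections in this morphology")
  sum(segments$area[mask])
}

#' Per-region summary of a morphology
#'
#' @param morph A `morphology`.
#' @param max_seg_len Segment length used for the summary, um.
#' @return A tibble with `region`, `area` (um^2) and `n_segments`, including
#'   the `dend` and `allsec` composites.
#' @export
morphology_summary <- function(morph, max_seg_len = 20) {
  segs <- morphology_segments(morph, max_seg_len)
  base <- dplyr::summarise(dplyr::group_by(segs, .data$region),
                           area = sum(.data$area),
                           n_segments = dplyr::n(), .groups = "drop")
  dmask <- region_mask(segs, "dend")
  comp <- tibble::tibble(
    region = c("dend", "allsec"),
    area = c(sum(segs$area[dmask]), sum(segs$area)),
    n_segments = c(sum(dmask), nrow(segs))
  )
  dplyr::bind_rows(base[base$region %in% c("soma", "axon", "basal", "apic"), ],
                   comp)
}

#' Align the somato-dendritic axis to z
#'
#' Rotates the morphology so the first principal component of the 3D positions
#' of all non-axon compartments lies on the z axis (apical mean toward +z for
#' pyramidal cells), with the soma centroid moved to the origin.
#'
#' @param morph A `morphology`.
#' @return The aligned `morphology`.
#' @export
align_somatodendritic_axis <- function(morph) {
  segs <- morphology_segments(morph)
  keep <- segs$region != "axon"
  pts <- as.matrix(segs[keep, c("x", "y", "z")])
  if (nrow(pts) < 3) stop("degenerate geometry: need >= 3 non-axon points")
  soma_c <- colMeans(as.matrix(segs[segs$region == "soma", c("x", "y", "z")]))
  pc <- stats::prcomp(pts, center = TRUE)
  if (pc$sdev[2] / pc$sdev[1] > 1 - 1e-9 && pc$sdev[1] == 0)
    stop("degenerate geometry: collinear points")
  ax <- pc$rotation[, 1]
  # orient: apical (or overall dendritic) mass toward +z
  ref <- if (any(segs$region == "apic")) segs$region == "apic" else keep
  centr <- colMeans(as.matrix(segs[ref, c("x", "y", "z")]))
  if (sum((centr - soma_c) * ax) < 0) ax <- -ax
  e1 <- pc$rotation[, 2]
  e1 <- e1 - sum(e1 * ax) * ax
  e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(ax[2] * e1[3] - ax[3] * e1[2],
          ax[3] * e1[1] - ax[1] * e1[3],
          ax[1] * e1[2] - ax[2] * e1[1])
  rot <- rbind(e1, e2, ax) # rows: new x, y, z axes
  secs <- morph$sections
  secs$points <- lapply(secs$points, function(m) {
    xyz <- sweep(m[, 1:3, drop = FALSE], 2, soma_c) %*% t(rot)
    out <- cbind(xyz, m[, 4])
    dimnames(out) <- list(NULL, c("x", "y", "z", "diam"))
    out
  })
  new_morphology(secs, morph$cell_type, morph$name)
}

#' Distribute opsin over a subcellular region
#'
#' Spreads a preset total maximum conductance `G_max` uniformly over the
#' region: every member segment receives the same specific conductance
#' `g_chr2 = G_max / A_region`, zero elsewhere, so that the area-weighted sum
#' recovers `G_max` exactly.
#'
#' @param segments A segments tibble ([morphology_segments()]) or a
#'   `morphology`.
#' @param region Subcellular region name.
#' @param g_max Total maximum conductance, uS (> 0).
#' @return The segments tibble with a `g_chr2` column in S/cm^2.
#' @export
distribute_opsin <- function(segments, region, g_max) {
  stopifnot(g_max > 0)
  if (inherits(segments, "morphology"))
    segments <- morphology_segments(segments)
  mask <- region_mask(segments, region)
  a <- sum(segments$area[mask])
  if (!any(mask) || a <= 0)
    stop("region '", region, "' has zero membrane area")
  # uS/um^2 -> S/cm^2 is a factor 100
  segments$g_chr2 <- ifelse(mask, g_max / a * 100, 0)
  segments
}

# ---------------------------------------------------------------------------
# SWC import/export (standard 7-column format, 1-based ids)

SWC_TYPES <- c("soma" = 1, "axon" = 2, "basal" = 3, "apic" = 4)

#' Read a morphology from an SWC file
#'
#' Standard 7-column SWC (`id type x y z radius parent`). Type codes map 1 ->
#' soma, 2 -> axon, 3 -> basal, 4 -> apic; for `cell_type = "interneuron"`
#' codes 3 and 4 collapse to the undifferentiated `dend` region. A
#' single-point soma is expanded to a z-aligned cylinder of length equal to
#' its diameter.
#'
#' @param path SWC file path.
#' @param cell_type `"pyramidal"` or `"interneuron"`.
#' @param name Cell label.
#' @return A `morphology`.
#' @export
read_swc <- function(path, cell_type = c("pyramidal", "interneuron"),
                     name = basename(path)) {
  cell_type <- match.arg(cell_type)
  df <- utils::read.table(path, comment.char = "#",
                          col.names = c("id", "type", "x", "y", "z", "radius",
                                        "parent"))
  type_names <- names(SWC_TYPES)[match(df$type, SWC_TYPES)]
  if (anyNA(type_names)) stop("unsupported SWC type code(s): ",
                              paste(unique(df$type[is.na(type_names)]),
                                    collapse = ", "))
  if (cell_type == "interneuron")
    type_names[type_names %in% c("basal", "apic")] <- "dend"
  idx <- match(df$id, df$id)
  parent_row <- match(df$parent, df$id)
  n_children <- tabulate(parent_row[!is.na(parent_row)], nbins = nrow(df))
  # section starts: roots, children of branch points, and type changes
  is_start <- is.na(parent_row) | n_children[parent_row] > 1 |
    type_names != type_names[ifelse(is.na(parent_row), idx, parent_row)]
  sec_of <- cumsum(is_start)
  sections <- list()
  sec_parent <- integer(max(sec_of))
  for (s in seq_len(max(sec_of))) {
    rows <- which(sec_of == s)
    first <- rows[1]
    pr <- parent_row[first]
    pts <- cbind(df$x[rows], df$y[rows], df$z[rows], 2 * df$radius[rows])
    if (!is.na(pr)) {
      # prepend the attachment point when it is spatially distinct, carrying
      # the child's diameter (the connection edge is child cable, not soma)
      gap <- sqrt((df$x[pr] - pts[1, 1])^2 + (df$y[pr] - pts[1, 2])^2 +
                    (df$z[pr] - pts[1, 3])^2)
      if (gap > 1e-6)
        pts <- rbind(c(df$x[pr], df$y[pr], df$z[pr], pts[1, 4]), pts)
    }
    if (nrow(pts) == 1 && type_names[first] == "soma" &&
        sum(type_names == "soma") == 1) {
      # classic one-point soma: expand to a z-aligned cylinder
      d <- pts[1, 4]
      pts <- rbind(c(pts[1, 1:2], pts[1, 3] - d / 2, d),
                   c(pts[1, 1:2], pts[1, 3] + d / 2, d))
    }
    dimnames(pts) <- list(NULL, c("x", "y", "z", "diam"))
    sections[[s]] <- list(sec_id = s, region = type_names[first],
                          parent = if (is.na(pr)) 0L else sec_of[pr],
                          points = pts)
  }
  # a root section reduced to a single junction node carries no membrane:
  # merge it into its first same-region child, which becomes the root
  singles <- which(vapply(sections, function(x)
    nrow(x$points) == 1 && x$parent == 0, logical(1)))
  drop <- integer(0)
  for (sid in singles) {
    kids <- which(vapply(sections, function(x) x$parent == sid, logical(1)))
    same <- kids[vapply(kids, function(k)
      sections[[k]]$region == sections[[sid]]$region, logical(1))]
    if (!length(same)) next
    adopt <- same[1]
    sections[[adopt]]$parent <- 0L
    for (k in setdiff(kids, adopt)) sections[[k]]$parent <- adopt
    drop <- c(drop, sid)
  }
  if (length(drop)) {
    keep_ids <- setdiff(seq_along(sections), drop)
    remap <- integer(length(sections)); remap[keep_ids] <- seq_along(keep_ids)
    sections <- lapply(sections[keep_ids], function(x) {
      x$sec_id <- remap[x$sec_id]
      if (x$parent > 0) x$parent <- remap[x$parent]
      x
    })
  }
  env <- new.env(); env$sections <- sections; env$sec_id <- length(sections)
  finish_morphology(env, cell_type, name)
}

#' Write a morphology to an SWC file
#'
#' @param morph A `morphology`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_swc <- function(morph, path) {
  rows <- list(); id <- 0
  node_ids <- vector("list", nrow(morph$sections)) # node ids per section
  node_xyz <- vector("list", nrow(morph$sections))
  for (si in seq_len(nrow(morph$sections))) {
    sec <- morph$sections[si, ]
    pts <- sec$points[[1]]
    type <- SWC_TYPES[[if (sec$region == "dend") "basal" else sec$region]]
    if (sec$parent == 0) {
      par_id <- -1
      start <- 1
    } else {
      # attach to the spatially nearest node of the parent section; skip the
      # duplicated first point when it coincides with that node
      # attach to the spatially nearest node of the parent section; the
      # section's own first point is always written (a duplicate-position
      # node spans a zero-length, zero-area edge but preserves the taper)
      pxyz <- node_xyz[[sec$parent]]
      d2 <- colSums((t(pxyz) - pts[1, 1:3])^2)
      par_id <- node_ids[[sec$parent]][which.min(d2)]
      start <- 1
    }
    ids <- integer(0)
    for (k in seq(start, nrow(pts))) {
      id <- id + 1
      rows[[id]] <- c(id, type, pts[k, 1], pts[k, 2], pts[k, 3],
                      pts[k, 4] / 2, par_id)
      par_id <- id
      ids <- c(ids, id)
    }
    keep <- seq(start, nrow(pts))
    node_ids[[sec$sec_id]] <- ids
    node_xyz[[sec$sec_id]] <- pts[keep, 1:3, drop = FALSE]
  }
  m <- do.call(rbind, rows)
  utils::write.table(m, path, row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
  invisible(path)
}
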