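# Synthetic morphologies: tree validity, areas, alignment, opsin spreading,
# SWC round trip.

test_that("pyramidal generator hits the calibration bands and is seeded", {
  py <- generate_pyramidal(seed = 1)
  expect_gte(region_area(py, "soma"), 400)
  expect_lte(region_area(py, "soma"), 1400)
  # within +-50% of the reconstructed-cell ranges
  expect_gt(region_area(py, "basal"), 5930 * 0.5)
  expect_lt(region_area(py, "basal"), 10670 * 1.5)
  expect_gt(region_area(py, "apic"), 13631 * 0.5)
  expect_lt(region_area(py, "apic"), 14787 * 1.5)
  expect_gt(region_area(py, "axon"), 1051 * 0.5)
  expect_lt(region_area(py, "axon"), 1641 * 1.5)
  # apical trunk toward +z, basal toward -z
  segs <- morphology_segments(py)
  expect_gt(mean(segs$z[segs$region == "apic"]), 0)
  expect_lt(mean(segs$z[segs$region == "basal"]), 0)
  expect_identical(generate_pyramidal(seed = 3)$sections$points,
                   generate_pyramidal(seed = 3)$sections$points)
  expect_false(identical(generate_pyramidal(seed = 3)$sections$points,
                         generate_pyramidal(seed = 4)$sections$points))
})

test_that("interneuron presets reproduce the axon/dendrite area relations", {
  bis <- generate_interneuron(seed = 1, preset = "bistratified")
  bas <- generate_interneuron(seed = 1, preset = "basket")
  a_bis <- region_area(bis, "axon")
  a_bas <- region_area(bas, "axon")
  expect_gt(a_bis, 2 * region_area(bis, "dend")) # arbor dwarfs the dendrites
  expect_lt(a_bas, 2 * region_area(bas, "dend")) # basket axon ~ dendrites
  expect_gt(a_bis, 2.5e4); expect_lt(a_bis, 1.6e5)
  expect_gt(a_bas, 1.2e4); expect_lt(a_bas, 5e4)
  expect_gt(a_bis, a_bas)
  # no basal/apic split in interneurons
  expect_false(any(morphology_segments(bis)$region %in% c("basal", "apic")))
})

test_that("degenerate generator inputs are rejected or error informatively", {
  expect_error(generate_pyramidal(params = list(soma_diam = -1)),
               "degenerate")
  py0 <- generate_pyramidal(params = list(basal_n_stem = 0), seed = 1)
  expect_error(region_area(py0, "basal"), "no sections")
  expect_error(region_area(py0, "nucleus"), "unknown region")
})

test_that("segment discretization preserves area and tree structure", {
  py <- mini_pyramidal()
  for (msl in c(10, 20, 50)) {
    segs <- morphology_segments(py, msl)
    expect_true(all(segs$length <= msl + 1e-9))
    # parent ordering (solver prerequisite) and a single root
    expect_true(all(segs$parent_seg < segs$seg_id))
    expect_equal(sum(segs$parent_seg == 0), 1)
    # discretization-invariant total area
    expect_equal(sum(segs$area), sum(morphology_segments(py, 20)$area),
                 tolerance = 1e-9)
  }
  # single cylinder: pi * d * L
  segs <- single_compartment(diam = 2, length = 100)
  expect_equal(segs$area, pi * 2 * 100)
})

test_that("composite region areas satisfy the partition identities", {
  py <- generate_pyramidal(seed = 2)
  expect_equal(region_area(py, "dend"),
               region_area(py, "basal") + region_area(py, "apic"))
  expect_equal(region_area(py, "allsec"),
               region_area(py, "dend") + region_area(py, "soma") +
                 region_area(py, "axon"))
  it <- generate_interneuron(seed = 2, preset = "basket")
  expect_equal(region_area(it, "allsec"),
               region_area(it, "dend") + region_area(it, "soma") +
                 region_area(it, "axon"))
})

test_that("somato-dendritic alignment recovers z after a random rotation", {
  py <- generate_pyramidal(seed = 1)
  # idempotence: re-aligning an aligned morphology changes nothing
  al0 <- align_somatodendritic_axis(py)
  al00 <- align_somatodendritic_axis(al0)
  expect_equal(morphology_segments(al00)$z, morphology_segments(al0)$z,
               tolerance = 1e-6)
  # scramble with a rotation and an offset, then re-align
  theta <- 0.8; phi <- 0.5
  rx <- rbind(c(1, 0, 0), c(0, cos(theta), -sin(theta)),
              c(0, sin(theta), cos(theta)))
  ry <- rbind(c(cos(phi), 0, sin(phi)), c(0, 1, 0),
              c(-sin(phi), 0, cos(phi)))
  rot <- rx %*% ry
  sc <- py
  sc$sections$points <- lapply(sc$sections$points, function(m) {
    out <- cbind(sweep(m[, 1:3] %*% t(rot), 2, c(-10, -20, -30)), m[, 4])
    dimnames(out) <- list(NULL, c("x", "y", "z", "diam"))
    out
  })
  al <- align_somatodendritic_axis(sc)
  segs <- morphology_segments(al)
  non_axon <- segs[segs$region != "axon", ]
  pc <- prcomp(as.matrix(non_axon[, c("x", "y", "z")]))
  expect_gt(abs(pc$rotation[3, 1]), 0.999) # first PC back on z
  expect_gt(mean(segs$z[segs$region == "apic"]), 0) # apical +z
  soma_c <- colMeans(as.matrix(segs[segs$region == "soma", c("x", "y", "z")]))
  expect_lt(max(abs(soma_c)), 1e-6)
})

test_that("opsin distribution is uniform, confined and conserves G_max", {
  py <- generate_pyramidal(seed = 1)
  segs <- morphology_segments(py)
  d <- distribute_opsin(segs, "soma", 1)
  # unit conversion: 1 uS over the soma area
  a_soma <- region_area(py, "soma")
  expect_equal(unique(d$g_chr2[d$region == "soma"]), 100 / a_soma)
  expect_true(all(d$g_chr2[d$region != "soma"] == 0))
  # the worked example: 1 uS over a 699.46 um^2 soma is ~0.143 S/cm^2
  expect_equal(1e-6 / (699.46 * 1e-8), 0.143, tolerance = 0.002)
  for (rg in c("soma", "basal", "dend", "allsec")) {
    d <- distribute_opsin(segs, rg, 2.5)
    expect_equal(sum(d$g_chr2 * d$area / 100), 2.5, tolerance = 1e-9)
  }
  d_all <- distribute_opsin(segs, "allsec", 1)
  expect_true(all(d_all$g_chr2 > 0))
  # smaller region -> locally higher conductance density
  d_soma <- distribute_opsin(segs, "soma", 1)
  expect_gt(max(d_soma$g_chr2), max(d_all$g_chr2))
  expect_error(distribute_opsin(segs, "soma", 0))
})

test_that("SWC round trip preserves regions, areas and connectivity", {
  # all attachments at section endpoints: the round trip is exact
  clean <- generate_pyramidal(params = list(oblique_n = 0), seed = 5)
  path0 <- tempfile(fileext = ".swc")
  write_swc(clean, path0)
  back0 <- read_swc(path0, "pyramidal")
  for (rg in c("soma", "axon", "basal", "apic"))
    expect_equal(region_area(back0, rg), region_area(clean, rg),
                 tolerance = 1e-9)
  # interior attachments (obliques) gain one connection edge per branch in
  # the 7-column format: areas agree to a few percent
  py <- mini_pyramidal()
  path <- tempfile(fileext = ".swc")
  write_swc(py, path)
  back <- read_swc(path, "pyramidal")
  for (rg in c("soma", "axon", "basal", "apic"))
    expect_equal(region_area(back, rg), region_area(py, rg),
                 tolerance = 0.08)
  # interneuron import collapses the dendrite split
  it <- read_swc(path, "interneuron")
  segs <- morphology_segments(it)
  expect_false(any(segs$region %in% c("basal", "apic")))
  expect_equal(region_area(it, "dend"), region_area(py, "dend"),
               tolerance = 0.08)
})
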