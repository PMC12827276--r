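# Scene construction and Monte Carlo transport properties.

test_that("named scenes carry the device-stack defaults", {
  ac <- build_scene("acute")
  expect_equal(ac$layers$medium,
               c("sapphire", "parylene", "window", "white", "grey"))
  expect_equal(ac$layers$thickness[1:4], c(0.150, 0.007, 0.150, 0.150))
  ch <- build_scene("chronic")
  expect_equal(ch$layers$medium, c("sapphire", "parylene", "white", "grey"))
  expect_equal(ch$layers$thickness[2], 0.015)
  # z = 0 sits at the tissue surface in both
  expect_equal(ac$z_bounds[ac$tissue_boundary + 1], 0)
  expect_equal(ch$z_bounds[ch$tissue_boundary + 1], 0)
})

test_that("invalid media and thicknesses are rejected", {
  expect_error(build_scene("custom",
                           layers = data.frame(medium = "unobtainium",
                                               thickness = 1)),
               "unknown medium")
  expect_error(build_scene("custom",
                           layers = data.frame(medium = "grey",
                                               thickness = -1)),
               "positive")
  expect_error(optical_medium("m", -1, 0, 0, 1.3), "mu_s")
  expect_error(optical_medium("m", 1, 0, 2, 1.3), "g must")
  expect_error(optical_medium("m", 1, 0, 0, 0.5), "refractive")
})

test_that("interposer slab is inserted with a clear via", {
  st <- build_scene("chronic",
                    interposer = list(thickness = 0.080,
                                      via_diameter = 0.080))
  expect_true("silicon" %in% st$layers$medium)
  i <- which(st$layers$medium == "silicon")
  expect_equal(st$via_r[i], 0.040)
  # interposer truncates the beam: surface spot narrower than open stack
  open <- reference_trace("chronic", n_photons = 2e5, seed = 21)
  collim <- trace_photons(st, n_photons = 2e5, seed = 21)
  expect_lt(surface_metrics(collim$grid)$spot_diameter_surface,
            surface_metrics(open$grid)$spot_diameter_surface)
})

test_that("weight is conserved and traces are seed-deterministic", {
  for (scene in c("acute", "chronic")) {
    tr <- trace_photons(build_scene(scene), n_photons = 2e4, seed = 3)
    expect_lt(abs(weight_total(tr$batch) - 1), 1e-6)
  }
  a <- trace_photons(build_scene("chronic"), n_photons = 2e4, seed = 11)
  b <- trace_photons(build_scene("chronic"), n_photons = 2e4, seed = 11)
  expect_identical(a$grid$values, b$grid$values)
  expect_identical(a$batch$weight_escaped, b$batch$weight_escaped)
  c <- trace_photons(build_scene("chronic"), n_photons = 2e4, seed = 12)
  expect_false(identical(a$grid$values, c$grid$values))
})

test_that("scattering-free transmission follows Beer-Lambert", {
  st <- absorber_stack(mu_a = 2, thickness = 1)
  tr <- trace_photons(st, n_photons = 2e5, seed = 3, z_max = 1, r_max = 0.2)
  trans <- unname(tr$batch$weight_escaped["bottom"])
  expect_lt(abs(trans / exp(-2) - 1), 0.01)
})

test_that("irradiance metrics are exactly linear in delivered power", {
  tr <- reference_trace("chronic", n_photons = 1e5, seed = 5)
  g1 <- set_delivered_power(tr$grid, 1)
  g3 <- set_delivered_power(tr$grid, 3)
  expect_equal(g3$values, 3 * g1$values)
  expect_equal(grid_csi(g3, 0.27), 3 * grid_csi(g1, 0.27))
  w1 <- threshold_contour(g3, level = 3)$widths
  w2 <- threshold_contour(g1, level = 1)$widths
  expect_equal(w1, w2)
})

test_that("contour metrics handle empty and super-threshold cases", {
  tr <- reference_trace("chronic", n_photons = 1e5, seed = 5)
  g <- set_delivered_power(tr$grid, 1)
  over <- threshold_contour(g, level = 10 * max(g$values))
  expect_equal(over$max_depth, 0)
  expect_true(all(over$widths == 0))
  expect_error(threshold_contour(g, level = -1), "level")
  ct <- threshold_contour(g, level = 1, surface_irradiance = 20.4,
                          spot_diameter = 0.270)
  expect_gt(ct$max_depth, 0)
  expect_gt(ct$width_at_depth(0.15), 0)
})

test_that("spot-diameter standard error shrinks with photon count", {
  # replicate traces at two problem sizes; SE should drop roughly sqrt(16)
  d_small <- vapply(1:6, function(s)
    surface_metrics(trace_photons(build_scene("chronic"), 1e4,
                                  seed = 100 + s)$grid)$spot_diameter_surface,
    0)
  d_large <- vapply(1:6, function(s)
    surface_metrics(trace_photons(build_scene("chronic"), 1.6e5,
                                  seed = 200 + s)$grid)$spot_diameter_surface,
    0)
  ratio <- stats::sd(d_small) / stats::sd(d_large)
  expect_gt(ratio, 4 / 2.5)   # sqrt(16) = 4 within a generous factor
  expect_lt(ratio, 4 * 2.5)
})

test_that("superposition is linear and grows the activated volume", {
  g <- reference_trace("chronic", n_photons = 2e5, seed = 21)$grid
  f1 <- superpose(g, rbind(c(0, 0)), per_emitter_power = 0.4)
  f2 <- superpose(g, rbind(c(0, 0), c(0, 0)), per_emitter_power = 0.4)
  expect_equal(f2$values, 2 * f1$values)
  expect_error(superpose(g, matrix(numeric(0), ncol = 2)), "non-empty")
  pitch <- 0.200
  offs <- function(k) as.matrix(expand.grid(x = (seq_len(k) - (k + 1) / 2) * pitch,
                                            y = (seq_len(k) - (k + 1) / 2) * pitch))
  v1 <- activated_volume(superpose(g, offs(1), per_emitter_power = 0.4), 1)
  v2 <- activated_volume(superpose(g, offs(2), per_emitter_power = 0.4), 1)
  v3 <- activated_volume(superpose(g, offs(3), per_emitter_power = 0.4), 1)
  expect_gt(v2, v1)
  expect_gt(v3, v2)
})

test_that("detector and brain scale factors behave as power fractions", {
  lab <- build_scene("custom",
                     layers = data.frame(medium = "air", thickness = 5))
  brain <- build_scene("chronic")
  # enclosing detector on a lossless path collects everything
  sf <- scale_factors(lab, brain, detector = list(z = 0.5, radius = 50),
                      n_photons = 2e4, seed = 5)
  expect_gt(sf$DSF, 0.99)
  expect_lte(sf$DSF, 1)
  expect_gt(sf$BSF, 0)
  expect_lt(sf$BSF, 1)
  # shrinking the aperture monotonically decreases DSF (same photon paths)
  d <- vapply(c(0.25, 0.5, 1, 2), function(r)
    scale_factors(lab, brain, detector = list(z = 2, radius = r),
                  n_photons = 2e4, seed = 5)$DSF, 0)
  expect_true(all(diff(d) > 0))
  expect_error(scale_factors(lab, brain, detector = list(z = 2, radius = 0)),
               "radius")
  # acute and chronic BSF agree within Monte Carlo error (lossless device
  # layers differ only by sub-percent Fresnel terms)
  ba <- trace_photons(build_scene("acute"), 1e5, seed = 2)$batch$weight_into_tissue
  bc <- trace_photons(build_scene("chronic"), 1e5, seed = 2)$batch$weight_into_tissue
  expect_lt(abs(ba - bc) / ba, 0.05)
})
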