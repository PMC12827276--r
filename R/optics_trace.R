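#' Trace photons through a layer stack
#'
#' Runs the Monte Carlo photon-transport simulation for a single micro-LED:
#' cosine-weighted (Lambertian) launch over the emitter square backed by a
#' perfect mirror, exponential step sampling, Henyey-Greenstein deflection,
#' weight deposition by the single-collision albedo, unpolarised Fresnel
#' reflection/refraction at every index step, and Russian-roulette
#' termination (threshold 1e-4, survival 0.1).  Absorbed energy is scored on
#' a cylindrical (r, z) grid over the tissue half-space; the fluence rate
#' follows from the collision estimator phi = A / (mu_a V).
#'
#' The returned grid is normalised per 1 mW of optical power delivered into
#' the tissue (net weight crossing the z = 0 surface), so
#' `values * delivered_power` is the irradiance field in mW mm^-2.
#'
#' @param stack a `layer_stack` from [build_scene()].
#' @param n_photons number of photon packets (>= 1).
#' @param seed integer RNG seed; each photon derives an independent
#'   counter-based stream from it, so runs are bit-reproducible.
#' @param dr,dz voxel size, mm.
#' @param r_max,z_max grid extent, mm.
#' @param r_kill lateral kill radius beyond which photons are tallied as
#'   escaped, mm.
#' @param detector optional list `list(z, radius)` (mm): plane below the
#'   device that absorbs and tallies photons within `radius` of the axis.
#' @return A list with `grid` (a `fluence_grid`) and `batch`
#'   (a `photon_batch`) holding the weight ledger.
#' @export
trace_photons <- function(stack, n_photons = 1e6, seed = 1,
                          dr = 0.010, dz = 0.010, r_max = 1.5, z_max = 1.5,
                          r_kill = 3.0, detector = NULL) {
  stopifnot(inherits(stack, "layer_stack"), n_photons >= 1)
  z_bot <- stack$z_bounds[length(stack$z_bounds)]
  if (z_bot < z_max)
    stop("scoring grid extends below the layer stack; thicken the terminal ",
         "layer or reduce z_max")
  k <- stack_constants(stack)
  nr <- as.integer(round(r_max / dr))
  nz <- as.integer(round(z_max / dz))
  det_z <- if (is.null(detector)) 0 else detector$z
  det_r <- if (is.null(detector)) -1 else detector$radius
  if (!is.null(detector) && det_r <= 0) stop("detector radius must be > 0")
  res <- mc_trace_cpp(stack$z_bounds, k$mu_s, k$mu_a, k$g, k$n,
                      stack$via_r, stack$emitter_side,
                      ifelse(stack$emission == "collimated", 1L, 0L),
                      TRUE, stack$tissue_boundary,
                      n_photons, seed, dr, dz, nr, nz, r_kill, det_z, det_r)
  np <- res$n_launched
  absorbed <- res$absorbed / np
  names(absorbed) <- stack$layers$medium
  batch <- structure(list(
    n_launched = np, seed = seed,
    weight_absorbed_per_layer = absorbed,
    weight_escaped = c(top = res$escaped_top, bottom = res$escaped_bottom,
                       side = res$escaped_side, detector = res$detector),
    weight_roulette = res$roulette_net,
    weight_into_tissue = res$into_tissue), class = "photon_batch")

  # normalisation per 1 mW delivered into tissue
  r_edges <- seq(0, r_max, by = dr)
  z_edges <- seq(0, z_max, by = dz)
  ring <- pi * diff(r_edges^2)                             # mm^2 per ring
  vol <- outer(ring, rep(dz, nz))                          # mm^3 per voxel
  mu_a_z <- tissue_mu_a(stack, (z_edges[-1] + z_edges[-length(z_edges)]) / 2)
  delivered <- res$into_tissue
  norm <- function(m) if (delivered > 0) m / np / delivered else m * 0
  # irradiance: downward weight flux through the plane at each voxel top
  values <- sweep(norm(res$E), 1, ring, "/")
  footprint <- norm(res$S) / ring
  fluence <- sweep(norm(res$A) / vol, 2, mu_a_z, "/")
  grid <- structure(list(values = values, footprint = footprint,
                         fluence = fluence,
                         r_edges = r_edges, z_edges = z_edges,
                         delivered_power = 1, seed = seed),
                    class = "fluence_grid")
  list(grid = grid, batch = batch)
}

# absorption coefficient of the tissue layer at depth z (z >= 0)
tissue_mu_a <- function(stack, z) {
  k <- stack_constants(stack)
  zb <- stack$z_bounds
  idx <- findInterval(pmin(z, zb[length(zb)] - 1e-12), zb,
                      rightmost.closed = TRUE)
  mu <- k$mu_a[idx]
  mu[mu <= 0] <- NA  # fluence undefined where nothing absorbs
  mu
}

#' Weight-conservation check for a photon batch
#'
#' @param batch a `photon_batch`.
#' @return The total accounted weight fraction (absorbed + escaped +
#'   roulette residual); equals 1 up to floating-point accumulation.
#' @export
weight_total <- function(batch) {
  sum(batch$weight_absorbed_per_layer) + sum(batch$weight_escaped) +
    batch$weight_roulette
}

#' @export
#' @method print photon_batch
print.photon_batch <- function(x, ...) {
  cat("<photon_batch>", format(x$n_launched, big.mark = ","),
      "photons, seed", x$seed, "\n")
  cat("  absorbed:", sum(x$weight_absorbed_per_layer),
      " escaped:", sum(x$weight_escaped),
      " into tissue (net):", x$weight_into_tissue, "\n")
  invisible(x)
}

#' Rescale a fluence grid to a given delivered power
#'
#' Irradiance is linear in delivered power, so rescaling is exact.
#'
#' @param grid a `fluence_grid`.
#' @param delivered_power optical power delivered into tissue, mW.
#' @return The rescaled `fluence_grid`.
#' @export
set_delivered_power <- function(grid, delivered_power) {
  stopifnot(inherits(grid, "fluence_grid"), delivered_power >= 0)
  sc <- delivered_power / grid$delivered_power
  grid$values <- grid$values * sc
  grid$footprint <- grid$footprint * sc
  grid$fluence <- grid$fluence * sc
  grid$delivered_power <- delivered_power
  grid
}

# radial profile of the illuminated spot on the cortical surface: weight at
# the first (ballistic) downward crossing of z = 0
surface_profile <- function(grid) {
  list(r = (grid$r_edges[-1] + grid$r_edges[-length(grid$r_edges)]) / 2,
       irradiance = grid$footprint)
}

# central cortical-surface irradiance: area-weighted mean of the innermost
# footprint bins, which averages down single-voxel Monte Carlo noise
central_surface_irradiance <- function(grid, n_bins = 3) {
  w <- diff(grid$r_edges[seq_len(n_bins + 1)]^2)
  sum(grid$footprint[seq_len(n_bins)] * w) / sum(w)
}

#' Surface spot metrics of a fluence grid
#'
#' Measures the illuminated spot on the cortical surface from the radial
#' profile of the ballistic footprint (weight at first downward crossing of
#' z = 0).  The spot diameter is where the profile falls to a stated
#' fraction of its central value, found by linear interpolation; the 1/e
#' level is the default definition (it reproduces the calibrated spot sizes
#' of both device configurations; FWHM and 1/e^2 are selectable).
#'
#' @param grid a `fluence_grid`.
#' @param definition `"1/e"`, `"fwhm"` or `"1/e2"`.
#' @return A list with `spot_diameter_surface` (mm), `definition`,
#'   `central_irradiance` (mW mm^-2 at the grid's delivered power) and the
#'   radial `profile`.
#' @export
surface_metrics <- function(grid, definition = c("1/e", "fwhm", "1/e2")) {
  stopifnot(inherits(grid, "fluence_grid"))
  definition <- match.arg(definition)
  frac <- switch(definition, "1/e" = exp(-1), fwhm = 0.5, "1/e2" = exp(-2))
  p <- surface_profile(grid)
  if (all(p$irradiance == 0)) stop("surface irradiance is identically zero")
  c0 <- central_surface_irradiance(grid)
  lev <- c0 * frac
  below <- which(p$irradiance < lev)
  below <- below[below > 1]
  if (!length(below)) stop("cut level not reached within the grid")
  i <- below[1]
  r_cut <- p$r[i - 1] + (p$r[i] - p$r[i - 1]) *
    (p$irradiance[i - 1] - lev) / (p$irradiance[i - 1] - p$irradiance[i])
  list(spot_diameter_surface = 2 * r_cut,
       definition = definition,
       central_irradiance = c0,
       profile = p)
}

#' Cortical surface irradiance of a grid
#'
#' The calibration-equation definition: delivered power divided by the area
#' of the illuminated spot disc, CSI = P * 4 / (pi d^2).
#'
#' @param grid a `fluence_grid`.
#' @param spot_diameter spot diameter d, mm; default measures the 1/e
#'   diameter from the grid's surface footprint.
#' @return Surface irradiance, mW mm^-2.
#' @export
grid_csi <- function(grid, spot_diameter = NULL) {
  if (is.null(spot_diameter))
    spot_diameter <- surface_metrics(grid)$spot_diameter_surface
  stopifnot(spot_diameter > 0)
  grid$delivered_power * 4 / (pi * spot_diameter^2)
}

#' Iso-irradiance contour metrics
#'
#' Scales the field so that the cortical surface irradiance (calibration
#' convention: delivered power over the spot-disc area, see [grid_csi()])
#' equals `surface_irradiance`, then measures the maximum depth reached by
#' the `level` iso-contour and the lateral width of the super-threshold
#' region at each depth (sub-voxel accuracy by linear interpolation in r).
#'
#' @param grid a `fluence_grid`.
#' @param level contour level, mW mm^-2 (> 0).
#' @param surface_irradiance cortical-surface irradiance to scale to,
#'   mW mm^-2; `NULL` keeps the grid's own scaling.
#' @param spot_diameter spot diameter used in the irradiance/power
#'   conversion, mm; default measures the 1/e diameter from the grid
#'   (pass the device calibration constant, e.g.
#'   [spot_diameter_default()], to replicate the bench calibration).
#' @return A list with `level`, `max_depth` (mm), `width_at_depth`
#'   (function depth -> lateral width, mm), `widths` (per z row),
#'   `delivered_power` (mW implied by the scaling) and
#'   `spot_diameter_surface`.  When `level` exceeds the peak irradiance the
#'   contour is empty: `max_depth` is 0 and all widths are 0.
#' @export
threshold_contour <- function(grid, level, surface_irradiance = NULL,
                              spot_diameter = NULL) {
  stopifnot(inherits(grid, "fluence_grid"))
  if (!is.finite(level) || level <= 0) stop("contour level must be > 0")
  if (!is.null(surface_irradiance)) {
    if (is.null(spot_diameter))
      spot_diameter <- surface_metrics(grid)$spot_diameter_surface
    grid <- set_delivered_power(grid,
                                surface_irradiance * pi * spot_diameter^2 / 4)
  }
  r_mid <- (grid$r_edges[-1] + grid$r_edges[-length(grid$r_edges)]) / 2
  z_mid <- (grid$z_edges[-1] + grid$z_edges[-length(grid$z_edges)]) / 2
  widths <- vapply(seq_along(z_mid), function(j) {
    v <- grid$values[, j]
    above <- which(v >= level)
    if (!length(above)) return(0)
    i <- max(above)
    if (i == length(v)) return(2 * r_mid[i])
    # interpolate the outer crossing
    r_c <- r_mid[i] + (r_mid[i + 1] - r_mid[i]) *
      (v[i] - level) / max(v[i] - v[i + 1], .Machine$double.eps)
    2 * r_c
  }, 0)
  # contour depth from the on-axis (central-disc) profile: the deepest
  # contour point lies on the axis, and the area-weighted central mean is a
  # far less noisy depth statistic than a per-column maximum
  nb <- min(10, length(r_mid))
  w_area <- diff(grid$r_edges[seq_len(nb + 1)]^2)
  cen <- as.vector(crossprod(grid$values[seq_len(nb), , drop = FALSE],
                             w_area)) / sum(w_area)
  ab <- which(cen >= level)
  if (length(ab)) {
    j <- max(ab)
    max_depth <- if (j < length(cen) && cen[j] > cen[j + 1])
      z_mid[j] + (z_mid[j + 1] - z_mid[j]) *
        (cen[j] - level) / (cen[j] - cen[j + 1])
    else z_mid[j]
  } else max_depth <- 0
  reached <- widths > 0
  wfun <- if (any(reached))
    stats::approxfun(z_mid, widths, rule = 2)
  else function(depth) rep(0, length(depth))
  sd0 <- tryCatch(surface_metrics(grid)$spot_diameter_surface,
                  error = function(e) NA_real_)
  list(level = level, max_depth = max_depth, width_at_depth = wfun,
       widths = widths, z = z_mid,
       delivered_power = grid$delivered_power,
       spot_diameter_surface = sd0)
}

#' Superpose shifted copies of a single-emitter field
#'
#' Light transport is linear, so the field of several simultaneously driven
#' micro-LEDs is the sum of laterally shifted single-emitter fields.  The
#' axisymmetric (r, z) grid is resampled onto a 3D Cartesian lattice and the
#' shifted copies are summed, each carrying `per_emitter_power`.
#'
#' @param grid a single-emitter `fluence_grid`.
#' @param offsets matrix (n x 2) or list of (x, y) lateral displacements, mm.
#' @param per_emitter_power delivered power per emitter, mW.
#' @param dx lattice spacing, mm.
#' @param half_extent lateral half-extent of the lattice, mm.
#' @return A list with `x`, `y`, `z` lattice coordinates and `values`
#'   (3D array, mW mm^-2), plus `voxel_volume` (mm^3).
#' @export
superpose <- function(grid, offsets, per_emitter_power = 1,
                      dx = 0.020, half_extent = 1.2) {
  stopifnot(inherits(grid, "fluence_grid"))
  if (is.list(offsets) && !is.data.frame(offsets))
    offsets <- do.call(rbind, lapply(offsets, as.numeric))
  offsets <- as.matrix(offsets)
  if (!nrow(offsets)) stop("offsets must be non-empty")
  stopifnot(ncol(offsets) == 2)
  xs <- seq(-half_extent, half_extent, by = dx)
  z_mid <- (grid$z_edges[-1] + grid$z_edges[-length(grid$z_edges)]) / 2
  r_mid <- (grid$r_edges[-1] + grid$r_edges[-length(grid$r_edges)]) / 2
  scale <- per_emitter_power / grid$delivered_power
  vals <- array(0, dim = c(length(xs), length(xs), length(z_mid)))
  for (e in seq_len(nrow(offsets))) {
    r_e <- sqrt(outer((xs - offsets[e, 1])^2, (xs - offsets[e, 2])^2, "+"))
    idx <- pmin(pmax(findInterval(r_e, grid$r_edges), 1), length(r_mid))
    for (j in seq_along(z_mid))
      vals[, , j] <- vals[, , j] + scale * grid$values[idx, j]
  }
  list(x = xs, y = xs, z = z_mid, values = vals,
       voxel_volume = dx * dx * (grid$z_edges[2] - grid$z_edges[1]))
}

#' Super-threshold volume of a 3D field
#'
#' @param field output of [superpose()].
#' @param level irradiance threshold, mW mm^-2.
#' @return Volume (mm^3) of the region at or above `level`.
#' @export
activated_volume <- function(field, level) {
  sum(field$values >= level) * field$voxel_volume
}

#' Detector and brain scale factors
#'
#' DSF is the fraction of emitted optical power reaching the laboratory
#' power-meter aperture; BSF is the fraction delivered into brain tissue.
#' Both are escaped-weight fractions from dedicated Monte Carlo runs: the
#' lab-geometry stack with an absorbing detector plane for DSF, and the
#' brain-facing stack's net weight crossing the cortical surface for BSF.
#'
#' @param lab_stack `layer_stack` for the laboratory geometry (tissue
#'   replaced by air).
#' @param brain_stack `layer_stack` for the implanted geometry.
#' @param detector list `list(z, radius)`, mm: aperture position and radius.
#' @param n_photons,seed Monte Carlo settings.
#' @return A list with `DSF` and `BSF`, both in (0, 1\].
#' @export
scale_factors <- function(lab_stack, brain_stack, detector,
                          n_photons = 1e5, seed = 1) {
  if (is.null(detector$radius) || detector$radius <= 0)
    stop("detector aperture must have positive radius")
  lab <- trace_photons(lab_stack, n_photons = n_photons, seed = seed,
                       detector = detector)
  brain <- trace_photons(brain_stack, n_photons = n_photons, seed = seed)
  list(DSF = unname(lab$batch$weight_escaped["detector"]),
       BSF = brain$batch$weight_into_tissue)
}
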