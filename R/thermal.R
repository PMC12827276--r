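#' Thermal material table
#'
#' Standard handbook properties for the materials in the implanted device
#' stack; brain tissue is approximated by water.
#'
#' @return data.frame with conductivity (W m^-1 K^-1), density (kg m^-3)
#'   and specific heat (J kg^-1 K^-1) per material.
#' @export
thermal_materials <- function() {
  m <- rbind(
    data.frame(name = "GaN",      k = 130,   rho = 6150, cp = 490),
    data.frame(name = "sapphire", k = 35,    rho = 3980, cp = 760),
    data.frame(name = "parylene", k = 0.084, rho = 1290, cp = 1000),
    data.frame(name = "polyimide",k = 0.12,  rho = 1420, cp = 1090),
    data.frame(name = "copper",   k = 400,   rho = 8960, cp = 385),
    data.frame(name = "gold",     k = 315,   rho = 19300, cp = 129),
    data.frame(name = "epoxy",    k = 0.2,   rho = 1200, cp = 1000),
    data.frame(name = "cement",   k = 0.3,   rho = 1500, cp = 1000),
    data.frame(name = "brain",    k = 0.6,   rho = 1000, cp = 4186),
    data.frame(name = "air",      k = 0.026, rho = 1.2,  cp = 1005))
  stopifnot(all(m$k > 0), all(m$rho > 0), all(m$cp > 0))
  m
}

# graded 1D mesh: cell edges from 0 to `extent`, fine spacing `h0` out to
# `fine_to`, then geometric growth
graded_edges <- function(extent, h0, fine_to, grow = 1.18) {
  e <- seq(0, fine_to, by = h0)
  h <- h0
  while (e[length(e)] < extent) {
    h <- min(h * grow, extent / 8)
    e <- c(e, e[length(e)] + h)
  }
  e[length(e)] <- extent
  e
}

#' Build an axisymmetric thermal scene
#'
#' Meshes a 2D rotationally symmetric (r, z) domain for the implanted
#' micro-LED device.  z increases downward with z = 0 at the device/tissue
#' interface; the device occupies z < 0 (parylene on the face, sapphire,
#' the GaN source layer, polyimide PCB, cement atop), brain tissue (water
#' properties) fills z > 0.  The `"in_air"` preset replaces the brain and
#' cement with air to mirror the infrared-imaging bench geometry.  The far
#' boundary is clamped at dT = 0 (Dirichlet).
#'
#' @param preset `"implanted"`, `"in_air"`, or `"water_bath"` (homogeneous
#'   water, used for analytic verification).
#' @param r_extent,z_extent domain half-extent, mm (>= 5 mm recommended so
#'   the clamped boundary does not bias the core).
#' @param h0 finest cell size, mm.
#' @param chip_radius equivalent radius of the 2 mm square chip, mm.
#' @return An object of class `axisym_scene` with cell edges, per-cell
#'   material indices and revolved cell volumes.
#' @export
build_axisym_scene <- function(preset = c("implanted", "in_air", "water_bath"),
                               r_extent = 5, z_extent = 5,
                               h0 = 0.005, chip_radius = 1.128) {
  preset <- match.arg(preset)
  mats <- thermal_materials()
  # device stack thicknesses (mm), bottom (tissue-facing) upward
  t_par <- 0.015; t_sap <- 0.150; t_gan <- 0.005; t_pcb <- 0.100
  dev_top <- t_par + t_sap + t_gan + t_pcb   # |z| of PCB top
  if (z_extent <= dev_top + 1) stop("z_extent too small for the device stack")

  r_edges <- graded_edges(r_extent, h0, 0.35)
  z_dev <- graded_edges(dev_top, h0, dev_top)      # uniform over the device
  z_brain <- graded_edges(z_extent, h0, 0.30)
  z_above <- graded_edges(z_extent - dev_top, 0.05, 0.2)
  z_edges <- sort(unique(c(-dev_top - z_above, -rev(z_dev), z_brain)))
  # force the material-layer boundaries into the mesh, dropping any edge
  # that would leave a sliver cell
  zb <- c(-t_par, -(t_par + t_sap), -(t_par + t_sap + t_gan))
  for (b in zb) z_edges <- z_edges[abs(z_edges - b) > 2e-4]
  z_edges <- sort(c(z_edges, zb))

  nr <- length(r_edges) - 1; nz <- length(z_edges) - 1
  r_mid <- (r_edges[-1] + r_edges[-length(r_edges)]) / 2
  z_mid <- (z_edges[-1] + z_edges[-length(z_edges)]) / 2
  mat <- matrix(NA_character_, nr, nz)
  below <- if (preset == "in_air") "air" else "brain"
  if (preset == "water_bath") {
    mat[] <- "brain"
  } else {
    for (j in seq_len(nz)) {
      z <- z_mid[j]
      if (z > 0) {
        mat[, j] <- below
      } else if (z > -t_par) {
        mat[, j] <- ifelse(r_mid <= chip_radius, "parylene",
                           if (preset == "in_air") "air" else "cement")
      } else if (z > -(t_par + t_sap)) {
        mat[, j] <- ifelse(r_mid <= chip_radius, "sapphire",
                           if (preset == "in_air") "air" else "cement")
      } else if (z > -(t_par + t_sap + t_gan)) {
        mat[, j] <- ifelse(r_mid <= chip_radius, "GaN",
                           if (preset == "in_air") "air" else "cement")
      } else if (z > -dev_top) {
        mat[, j] <- ifelse(r_mid <= chip_radius, "polyimide",
                           if (preset == "in_air") "air" else "cement")
      } else {
        mat[, j] <- if (preset == "in_air") "air" else "cement"
      }
    }
  }
  if (!any(mat == below)) stop("scene contains no bulk region below the device")
  vol <- outer(pi * diff((r_edges * 1e-3)^2), diff(z_edges * 1e-3))  # m^3
  structure(list(preset = preset, r_edges = r_edges, z_edges = z_edges,
                 mat = mat, materials = mats, volume = vol,
                 gan_z = c(-(t_par + t_sap + t_gan), -(t_par + t_sap)),
                 chip_radius = chip_radius),
            class = "axisym_scene")
}

#' Heat-source specification for micro-LED patterns
#'
#' The thermal power of a driven micro-LED is its electrical power minus the
#' optical power it emits.  A rotationally symmetric model cannot hold a
#' square emitter, so the centre LED becomes a cylinder of equal volume and
#' off-centre LEDs become a concentric ring whose volume equals the summed
#' LED volumes (8 LEDs for the 3x3 ring at the 0.2 mm row pitch, 4 LEDs for
#' the 2x2 ring at the half-diagonal radius).
#'
#' @param pattern `"single"`, `"2x2"` or `"3x3"`.
#' @param current_mA drive current per LED, mA.
#' @param li_model list with functions `electrical_mW(I)` and
#'   `optical_mW(I)` of current in mA; see [default_li_model()].
#' @param rate_hz,duty,n_pulses pulse-train parameters (20 Hz, 50% duty,
#'   10 pulses is the in vivo protocol).
#' @param led_side,led_thickness emitter dimensions, mm.
#' @param pitch array pitch, mm.
#' @return An object of class `source_spec`: list of source elements
#'   (`cylinder` / `ring` with geometry and power share) plus the waveform.
#' @export
make_source <- function(pattern = c("single", "2x2", "3x3"), current_mA,
                        li_model = default_li_model(),
                        rate_hz = 20, duty = 0.5, n_pulses = 10,
                        led_side = 0.040, led_thickness = 0.005,
                        pitch = 0.200) {
  pattern <- match.arg(pattern)
  stopifnot(current_mA >= 0, duty > 0, duty <= 1, n_pulses >= 1)
  p_el <- li_model$electrical_mW(current_mA)
  p_opt <- li_model$optical_mW(current_mA)
  if (p_opt > p_el)
    stop("optical power exceeds electrical power; non-physical L-I model")
  amp <- p_el - p_opt                       # thermal power per LED, mW
  v_led <- led_side^2 * led_thickness       # mm^3
  elements <- switch(pattern,
    single = list(list(type = "cylinder", radius = led_side / sqrt(pi),
                       volume = v_led, n_led = 1)),
    "2x2" = list(list(type = "ring", radius = pitch * sqrt(2) / 2,
                      volume = 4 * v_led, n_led = 4)),
    "3x3" = list(list(type = "cylinder", radius = led_side / sqrt(pi),
                      volume = v_led, n_led = 1),
                 list(type = "ring", radius = pitch,
                      volume = 8 * v_led, n_led = 8)))
  structure(list(pattern = pattern, elements = elements,
                 amplitude_per_led_mW = amp,
                 total_mW = amp * sum(vapply(elements, `[[`, 0, "n_led")),
                 rate_hz = rate_hz, duty = duty, n_pulses = n_pulses,
                 led_thickness = led_thickness),
            class = "source_spec")
}

# power waveform (mW) at time t (s): pulse train, on at the start of each period
source_power <- function(source, t) {
  period <- 1 / source$rate_hz
  on <- (t %/% period < source$n_pulses) & ((t %% period) < source$duty * period)
  ifelse(t >= 0 & on, source$total_mW, 0)
}

# exact energy (mW * s) emitted over [a, b]: sum of overlaps with on-phases
source_energy <- function(source, a, b) {
  period <- 1 / source$rate_hz
  k <- seq_len(source$n_pulses) - 1
  on0 <- k * period
  on1 <- on0 + source$duty * period
  source$total_mW * sum(pmax(0, pmin(b, on1) - pmax(a, on0)))
}

# map source elements onto scene cells inside the GaN layer; returns a
# per-cell power-density weight matrix summing to 1
source_weights <- function(scene, source) {
  r_mid <- (scene$r_edges[-1] + scene$r_edges[-length(scene$r_edges)]) / 2
  z_mid <- (scene$z_edges[-1] + scene$z_edges[-length(scene$z_edges)]) / 2
  in_gan_z <- z_mid > scene$gan_z[1] & z_mid < scene$gan_z[2]
  if (!any(in_gan_z)) stop("mesh has no cells in the source layer")
  W <- matrix(0, length(r_mid), length(z_mid))
  total_n <- sum(vapply(source$elements, `[[`, 0, "n_led"))
  for (el in source$elements) {
    if (el$type == "cylinder") {
      in_r <- r_mid <= el$radius
      if (!any(in_r)) in_r <- seq_along(r_mid) == 1
    } else {
      # ring: annulus of equal cross-section area centred at el$radius
      area <- el$volume / (2 * pi * el$radius * source$led_thickness)
      half_w <- area / 2
      in_r <- abs(r_mid - el$radius) <= half_w
      if (!any(in_r)) in_r <- seq_along(r_mid) == which.min(abs(r_mid - el$radius))
    }
    v <- scene$volume[in_r, in_gan_z, drop = FALSE]
    W[in_r, in_gan_z] <- W[in_r, in_gan_z] +
      (el$n_led / total_n) * v / sum(v)
  }
  W / sum(W)
}

# assemble the FV conductance matrix K (W/K) and capacity vector C (J/K)
assemble_fv <- function(scene) {
  mats <- scene$materials
  kmat <- matrix(mats$k[match(scene$mat, mats$name)],
                 nrow(scene$mat), ncol(scene$mat))
  rcv <- matrix((mats$rho * mats$cp)[match(scene$mat, mats$name)],
                nrow(scene$mat), ncol(scene$mat))
  r_e <- scene$r_edges * 1e-3; z_e <- scene$z_edges * 1e-3   # m
  nr <- length(r_e) - 1; nz <- length(z_e) - 1
  r_mid <- (r_e[-1] + r_e[-length(r_e)]) / 2
  dz <- diff(z_e); dr <- diff(r_e)
  idx <- function(i, j) i + (j - 1) * nr
  # radial faces (vectorised over the i+1/2 face lattice)
  ir <- rep(seq_len(nr - 1), nz); jr <- rep(seq_len(nz), each = nr - 1)
  Ar <- 2 * pi * r_e[ir + 1] * dz[jr]
  gr <- Ar / (dr[ir] / 2 / kmat[cbind(ir, jr)] +
              dr[ir + 1] / 2 / kmat[cbind(ir + 1, jr)])
  ar <- idx(ir, jr); br <- idx(ir + 1, jr)
  # axial faces
  iz <- rep(seq_len(nr), nz - 1); jz <- rep(seq_len(nz - 1), each = nr)
  Az <- pi * (r_e[iz + 1]^2 - r_e[iz]^2)
  gz <- Az / (dz[jz] / 2 / kmat[cbind(iz, jz)] +
              dz[jz + 1] / 2 / kmat[cbind(iz, jz + 1)])
  az <- idx(iz, jz); bz <- idx(iz, jz + 1)
  a_all <- c(ar, az); b_all <- c(br, bz); g_all <- c(gr, gz)
  # Dirichlet dT = 0: outer radius and both z extremes
  bnd_g <- numeric(nr * nz)
  jb <- seq_len(nz)
  bnd_g[idx(nr, jb)] <- 2 * pi * r_e[nr + 1] * dz[jb] /
    (dr[nr] / 2 / kmat[cbind(nr, jb)])
  ib <- seq_len(nr)
  Ab <- pi * (r_e[ib + 1]^2 - r_e[ib]^2)
  bnd_g[idx(ib, 1)] <- bnd_g[idx(ib, 1)] + Ab / (dz[1] / 2 / kmat[cbind(ib, 1)])
  bnd_g[idx(ib, nz)] <- bnd_g[idx(ib, nz)] + Ab / (dz[nz] / 2 / kmat[cbind(ib, nz)])
  acc <- rowsum(c(g_all, g_all), c(a_all, b_all))
  diag_acc <- bnd_g
  diag_acc[as.integer(rownames(acc))] <- diag_acc[as.integer(rownames(acc))] + acc[, 1]
  ii <- c(a_all, b_all); jj <- c(b_all, a_all); vv <- c(-g_all, -g_all)
  K <- Matrix::sparseMatrix(i = c(ii, seq_len(nr * nz)),
                            j = c(jj, seq_len(nr * nz)),
                            x = c(vv, diag_acc), dims = c(nr * nz, nr * nz))
  C <- as.vector(rcv * scene$volume)
  list(K = K, C = C, boundary_g = bnd_g, nr = nr, nz = nz)
}

#' Solve the transient axisymmetric heat equation
#'
#' Conservative finite-volume discretisation in cylindrical coordinates with
#' harmonic-mean interface conductivities and backward-Euler time stepping
#' (the constant system matrix is Cholesky-factorised once).  With
#' `steady = TRUE` the stationary problem K dT = S is solved instead, using
#' the time-averaged source power.
#'
#' @param scene an `axisym_scene`.
#' @param source a `source_spec`.
#' @param t_end simulated time, s.
#' @param dt time step, s (> 0).
#' @param steady solve the stationary problem instead.
#' @param store `"all"` keeps every step; `"peak"` keeps the running
#'   per-cell maximum plus the final state (memory-light).
#' @return An object of class `temperature_field`: dT in kelvin on the
#'   scene mesh, with `times`, per-cell `peak`, and an `energy` ledger
#'   (injected, stored, through-boundary, J).
#' @export
solve_heat <- function(scene, source, t_end = 0.5, dt = 0.0025,
                       steady = FALSE, store = c("peak", "all")) {
  stopifnot(inherits(scene, "axisym_scene"), inherits(source, "source_spec"))
  store <- match.arg(store)
  if (!steady && (!is.finite(dt) || dt <= 0)) stop("dt must be > 0")
  fv <- assemble_fv(scene)
  w <- as.vector(source_weights(scene, source))
  if (steady) {
    p_avg <- source$total_mW * 1e-3 * source$duty       # W
    T <- as.vector(Matrix::solve(fv$K, w * p_avg))
    if (any(!is.finite(T))) stop("linear solve failed (non-finite solution)")
    res <- fv$K %*% T - w * p_avg
    if (max(abs(res)) > 1e-8 * max(p_avg, 1e-12))
      stop("steady solve did not converge; residual ", max(abs(res)))
    field <- list(times = Inf, dT = matrix(T, ncol = 1),
                  peak = T, energy = NULL)
  } else {
    n_steps <- ceiling(t_end / dt)
    Asys <- fv$K + Matrix::Diagonal(x = fv$C / dt)
    ch <- Matrix::Cholesky(methods::as(Matrix::forceSymmetric(Asys),
                                       "CsparseMatrix"), LDL = FALSE)
    T <- numeric(length(fv$C)); peak <- T
    injected <- flux_out <- 0
    keep <- if (store == "all") matrix(0, length(T), n_steps) else NULL
    times <- seq_len(n_steps) * dt
    for (s in seq_len(n_steps)) {
      # interval-averaged power keeps the injected energy exact for any dt
      p <- source_energy(source, times[s] - dt, times[s]) / dt * 1e-3  # W
      b <- fv$C / dt * T + w * p
      T <- as.vector(Matrix::solve(ch, b, system = "A"))
      if (any(!is.finite(T))) stop("implicit step failed (non-finite solution)")
      peak <- pmax(peak, T)
      injected <- injected + p * dt
      flux_out <- flux_out + sum(fv$boundary_g * T) * dt
      if (store == "all") keep[, s] <- T
    }
    stored <- sum(fv$C * T)
    field <- list(times = times,
                  dT = if (store == "all") keep else matrix(T, ncol = 1),
                  peak = peak,
                  energy = c(injected = injected, stored = stored,
                             boundary = flux_out))
  }
  structure(c(field, list(scene = scene, source = source)),
            class = "temperature_field")
}

#' Peak temperature rise versus cortical depth
#'
#' Per-depth maximum (over time) of dT on the axis (innermost radial cell),
#' restricted to the tissue region z >= 0.
#'
#' @param field a `temperature_field` from [solve_heat()].
#' @return data.frame with `depth_mm` and `dT_peak_K`.
#' @export
peak_profile <- function(field) {
  stopifnot(inherits(field, "temperature_field"))
  scene <- field$scene
  below <- if (scene$preset == "in_air") "air" else "brain"
  z_mid <- (scene$z_edges[-1] + scene$z_edges[-length(scene$z_edges)]) / 2
  nr <- length(scene$r_edges) - 1
  tissue <- which(z_mid > 0 & scene$mat[1, ] == below)
  if (scene$preset == "in_air" || !length(tissue))
    stop("field has no brain region; peak profile undefined")
  pk <- matrix(field$peak, nrow = nr)
  data.frame(depth_mm = z_mid[tissue], dT_peak_K = pk[1, tissue])
}

#' On-axis temperature rise at a given depth
#'
#' @param field a `temperature_field`.
#' @param depth_mm cortical depth, mm.
#' @return Peak dT (K) at the axis cell nearest `depth_mm`.
#' @export
peak_at_depth <- function(field, depth_mm) {
  pp <- peak_profile(field)
  pp$dT_peak_K[which.min(abs(pp$depth_mm - depth_mm))]
}
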