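#' Optical medium
#'
#' A homogeneous optical medium characterised by its scattering coefficient,
#' absorption coefficient, Henyey-Greenstein anisotropy and refractive index.
#'
#' @param name character label.
#' @param mu_s scattering coefficient, mm^-1 (>= 0).
#' @param mu_a absorption coefficient, mm^-1 (>= 0).
#' @param g scattering anisotropy (mean cosine of the deflection angle),
#'   in \[-1, 1\].
#' @param n refractive index (>= 1).
#' @return An object of class `optical_medium`.
#' @export
optical_medium <- function(name, mu_s, mu_a, g, n) {
  stopifnot(is.character(name), length(name) == 1)
  if (!is.finite(mu_s) || mu_s < 0) stop("mu_s must be >= 0")
  if (!is.finite(mu_a) || mu_a < 0) stop("mu_a must be >= 0")
  if (!is.finite(g) || g < -1 || g > 1) stop("g must lie in [-1, 1]")
  if (!is.finite(n) || n < 1) stop("refractive index must be >= 1")
  structure(list(name = name, mu_s = mu_s, mu_a = mu_a, g = g, n = n),
            class = "optical_medium")
}

#' Built-in optical media table
#'
#' Tissue constants are the grey/white-matter values used throughout the
#' optical model (white: mu_s 50 mm^-1, mu_a 0.14 mm^-1, g 0.78; grey:
#' mu_s 11 mm^-1, mu_a 0.07 mm^-1, g 0.88; n = 1.33, water); device-layer
#' refractive indices are standard handbook values (these layers neither
#' scatter nor absorb appreciably at 450 nm over the thicknesses involved).
#'
#' @return Named list of [optical_medium()] objects.
#' @export
optics_media <- function() {
  list(
    sapphire   = optical_medium("sapphire",     0,  0, 0,    1.77),
    parylene   = optical_medium("parylene",     0,  0, 0,    1.64),
    window     = optical_medium("window",       0,  0, 0,    1.52),
    white      = optical_medium("white",       50,  0.14, 0.78, 1.33),
    grey       = optical_medium("grey",        11,  0.07, 0.88, 1.33),
    air        = optical_medium("air",          0,  0, 0,    1.00),
    water      = optical_medium("water",        0,  0.0002, 0, 1.33),
    silicon    = optical_medium("silicon",      0,  0, 0,    1.00)  # opaque; used only as interposer body
  )
}

#' Build a device/tissue layer stack
#'
#' Constructs the ordered stack of optical media a photon traverses from the
#' 40 um square micro-LED emitter down into brain tissue.  Named scenes
#' reproduce the two experimental configurations: `"acute"` (150 um sapphire,
#' 7 um parylene-C, 150 um cortical window, then tissue) and `"chronic"`
#' (150 um sapphire, 15 um parylene-C directly on tissue).  In both, the
#' tissue is a 150 um white-matter layer over thick grey matter.
#' `"lab_detector"` replaces tissue with air for detector-geometry runs.
#'
#' @param scene one of `"acute"`, `"chronic"`, `"lab_detector"`, `"custom"`.
#' @param layers for `"custom"`: a data.frame with columns `medium`
#'   (name in the built-in media table) and `thickness` (mm, > 0).
#' @param emitter_side emitter square side, mm.
#' @param emission `"lambertian"` or `"collimated"`.
#' @param grey_thickness thickness of the terminal grey-matter layer used as
#'   a proxy for a semi-infinite half space, mm.
#' @param interposer optional list `list(thickness, via_diameter)` (mm)
#'   inserting an opaque collimating slab with a clear cylindrical via
#'   between the parylene and the tissue (or window).
#' @param media optional replacement media table (named list of
#'   `optical_medium`).
#' @return An object of class `layer_stack`: layers with boundaries placed so
#'   that z = 0 at the tissue surface (device layers occupy z < 0).
#' @export
build_scene <- function(scene = c("acute", "chronic", "lab_detector", "custom"),
                        layers = NULL, emitter_side = 0.040,
                        emission = c("lambertian", "collimated"),
                        grey_thickness = 3.0, interposer = NULL,
                        media = optics_media()) {
  scene <- match.arg(scene)
  emission <- match.arg(emission)
  stopifnot(emitter_side > 0)
  def <- function(medium, thickness)
    data.frame(medium = medium, thickness = thickness, stringsAsFactors = FALSE)
  if (scene == "acute") {
    layers <- rbind(def("sapphire", 0.150), def("parylene", 0.007),
                    def("window", 0.150),
                    def("white", 0.150), def("grey", grey_thickness))
    tissue_from <- "white"
  } else if (scene == "chronic") {
    layers <- rbind(def("sapphire", 0.150), def("parylene", 0.015),
                    def("white", 0.150), def("grey", grey_thickness))
    tissue_from <- "white"
  } else if (scene == "lab_detector") {
    layers <- rbind(def("sapphire", 0.150), def("parylene", 0.007),
                    def("air", 10))
    tissue_from <- "air"
  } else {
    if (is.null(layers) || !all(c("medium", "thickness") %in% names(layers)))
      stop("custom scene requires a layers data.frame with medium, thickness")
    tissue_from <- attr(layers, "tissue_from")
    if (is.null(tissue_from)) tissue_from <- layers$medium[nrow(layers)]
  }
  unknown <- setdiff(layers$medium, names(media))
  if (length(unknown))
    stop("unknown medium name: ", paste(unknown, collapse = ", "))
  if (any(!is.finite(layers$thickness) | layers$thickness <= 0))
    stop("layer thicknesses must be positive")

  via_r <- rep(-1, nrow(layers))
  if (!is.null(interposer)) {
    stopifnot(interposer$thickness > 0, interposer$via_diameter > 0)
    # insert below the last device layer that precedes the tissue block
    it <- match(tissue_from, layers$medium)
    ins <- data.frame(medium = "silicon", thickness = interposer$thickness,
                      stringsAsFactors = FALSE)
    layers <- rbind(layers[seq_len(it - 1), ], ins,
                    layers[it:nrow(layers), ])
    via_r <- rep(-1, nrow(layers))
    via_r[it] <- interposer$via_diameter / 2
  }

  # boundaries with z = 0 at the top of the tissue block
  it <- match(tissue_from, layers$medium)
  z <- cumsum(c(0, layers$thickness))
  z <- z - z[it]
  structure(list(layers = layers, media = media, z_bounds = z,
                 tissue_boundary = it - 1L,   # 0-based index of the z = 0 boundary
                 via_r = via_r,
                 emitter_side = emitter_side, emission = emission,
                 scene = scene),
            class = "layer_stack")
}

#' @export
#' @method print layer_stack
print.layer_stack <- function(x, ...) {
  cat("<layer_stack> scene:", x$scene, " emitter:",
      x$emitter_side * 1e3, "um", x$emission, "\n")
  for (i in seq_len(nrow(x$layers)))
    cat(sprintf("  %-10s %8.3f mm  [%.3f, %.3f]\n", x$layers$medium[i],
                x$layers$thickness[i], x$z_bounds[i], x$z_bounds[i + 1]))
  invisible(x)
}

# per-layer optical constant vectors for the C++ core
stack_constants <- function(stack) {
  m <- stack$media[stack$layers$medium]
  list(mu_s = vapply(m, `[[`, 0, "mu_s"),
       mu_a = vapply(m, `[[`, 0, "mu_a"),
       g    = vapply(m, `[[`, 0, "g"),
       n    = vapply(m, `[[`, 0, "n"))
}
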