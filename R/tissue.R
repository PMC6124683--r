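#' Optical layer of a tissue model
#'
#' One homogeneous layer of a layered tissue model. The final layer of a
#' model may be semi-infinite (`thickness_mm = Inf`), representing muscle
#' extending beyond the probing depth.
#'
#' @param thickness_mm layer thickness in mm, or `Inf` for semi-infinite.
#' @param mu_a absorption coefficient, mm^-1 (>= 0).
#' @param mu_s scattering coefficient, mm^-1 (>= 0); `mu_a + mu_s` must be
#'   positive.
#' @param g scattering anisotropy (Henyey-Greenstein), in (-1, 1).
#' @param n refractive index, >= 1.
#' @param name optional layer label.
#' @return an `optical_layer` list.
#' @export
optical_layer <- function(thickness_mm, mu_a, mu_s, g = 0.9, n = 1.4,
                          name = NA_character_) {
  if (!is.numeric(thickness_mm) || thickness_mm <= 0)
    stop("layer thickness must be positive (Inf for semi-infinite)")
  if (mu_a < 0) stop("mu_a must be >= 0")
  if (mu_s < 0) stop("mu_s must be >= 0")
  if (mu_a + mu_s <= 0)
    stop("layer has zero total interaction coefficient (mu_a + mu_s == 0)")
  if (g <= -1 || g >= 1) stop("anisotropy g must lie in (-1, 1)")
  if (n < 1) stop("refractive index must be >= 1")
  structure(list(thickness_mm = thickness_mm, mu_a = mu_a, mu_s = mu_s,
                 g = g, n = n, name = name),
            class = "optical_layer")
}

#' Layered tissue model
#'
#' An ordered stack of [optical_layer()]s from the surface downward. Only
#' the last layer may be semi-infinite; a finite last layer gives a slab
#' through which photons can be transmitted.
#'
#' @param layers list of [optical_layer()], surface first.
#' @param n_ambient refractive index of the medium above the surface.
#' @return a `tissue_model` list with layer boundary depths precomputed.
#' @export
tissue_model <- function(layers, n_ambient = 1.0) {
  if (length(layers) < 1) stop("tissue model needs at least one layer")
  if (!all(vapply(layers, inherits, logical(1), "optical_layer")))
    stop("all layers must be optical_layer objects")
  thick <- vapply(layers, `[[`, numeric(1), "thickness_mm")
  if (any(!is.finite(thick[-length(thick)])))
    stop("only the last layer may be semi-infinite")
  if (n_ambient < 1) stop("n_ambient must be >= 1")
  z_top <- cumsum(c(0, head(thick, -1)))
  z_bot <- z_top + thick
  structure(list(layers = layers, n_ambient = n_ambient,
                 z_top_mm = z_top, z_bot_mm = z_bot),
            class = "tissue_model")
}

#' Reflectance probe geometry
#'
#' Source at the origin with a collimated pencil beam normal to the surface;
#' circular detector apertures centred at the given separations along the
#' surface. Distinct apertures must not overlap each other or the source;
#' exactly duplicated separations are allowed (the same aperture scored
#' twice).
#'
#' @param separations_cm detector centre distances from the source, cm.
#' @param detector_radius_mm aperture radius, mm.
#' @return a `probe_geometry` list.
#' @export
probe_geometry <- function(separations_cm = 2.0, detector_radius_mm = 1.5) {
  if (length(separations_cm) < 1 || any(separations_cm <= 0))
    stop("detector separations must be positive")
  if (detector_radius_mm <= 0) stop("detector radius must be positive")
  sep_mm <- separations_cm * 10
  if (any(sep_mm <= detector_radius_mm))
    stop("detector aperture overlaps the source")
  u <- sort(unique(sep_mm))
  if (length(u) > 1 && any(diff(u) < 2 * detector_radius_mm))
    stop("detector apertures overlap")
  structure(list(separations_cm = separations_cm,
                 detector_radius_mm = detector_radius_mm),
            class = "probe_geometry")
}

#' Default layer optical properties
#'
#' Literature-typical optical properties (versioned table "v1") for the
#' three-layer calf model — 0.3 mm dermis, 1 mm subdermis, semi-infinite
#' muscle — at the three device wavelengths. The probe-design study gives
#' only the geometry; absorption/scattering values are representative
#' mid-range values from published tissue-optics compilations and every
#' simulation entry point accepts overrides.
#'
#' @return data frame with columns `layer`, `wavelength_nm`, `thickness_mm`,
#'   `mu_a`, `mu_s`, `g`, `n` (coefficients in mm^-1).
#' @export
tissue_optics_defaults <- function() {
  out <- rbind(
    data.frame(layer = "dermis",    wavelength_nm = c(735, 805, 850),
               thickness_mm = 0.3, mu_a = c(0.030, 0.025, 0.023),
               mu_s = c(22, 20, 19), g = 0.9, n = 1.40),
    data.frame(layer = "subdermis", wavelength_nm = c(735, 805, 850),
               thickness_mm = 1.0, mu_a = c(0.011, 0.010, 0.011),
               mu_s = c(13, 12, 11), g = 0.9, n = 1.44),
    data.frame(layer = "muscle",    wavelength_nm = c(735, 805, 850),
               thickness_mm = Inf, mu_a = c(0.025, 0.022, 0.024),
               mu_s = c(7.0, 6.6, 6.2), g = 0.9, n = 1.37))
  attr(out, "version") <- "v1"
  out
}

#' Default three-layer calf tissue model at a device wavelength
#'
#' @param wavelength_nm one of 735, 805, 850 (or any wavelength present in
#'   `optics`).
#' @param optics properties table as from [tissue_optics_defaults()].
#' @param n_ambient refractive index above the surface.
#' @return a [tissue_model()].
#' @export
default_tissue_model <- function(wavelength_nm = 805,
                                 optics = tissue_optics_defaults(),
                                 n_ambient = 1.0) {
  sub <- optics[optics$wavelength_nm == wavelength_nm, , drop = FALSE]
  if (nrow(sub) == 0)
    stop("no optical properties at ", wavelength_nm, " nm")
  layers <- lapply(seq_len(nrow(sub)), function(i)
    optical_layer(sub$thickness_mm[i], sub$mu_a[i], sub$mu_s[i],
                  g = sub$g[i], n = sub$n[i], name = sub$layer[i]))
  tissue_model(layers, n_ambient = n_ambient)
}
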