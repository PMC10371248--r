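# Incident-light boundary conditions and leaf optical properties.
#
# Clear-sky formulation: extraterrestrial PAR constant
# I0 = 1367 W m-2 (solar constant) x 0.45 (PAR fraction) x 4.57 umol J-1
# ~= 2811 umol m-2 s-1 on a plane normal to the beam; the direct beam is
# attenuated by tau^m with air mass m = 1/cos(zenith); half of the
# scattered flux is assumed to reach the ground as diffuse sky light.

PAR_EXTRATERRESTRIAL <- 1367 * 0.45 * 4.57  # umol m-2 s-1, beam-normal

#' Solar position from date, hour and latitude
#'
#' Standard astronomical geometry: declination from day of year (Spencer's
#' Fourier series) and hour angle from local solar time (15 degrees per
#' hour from solar noon). Azimuth is degrees clockwise from north.
#'
#' @param date a `Date` or "YYYY-MM-DD" string.
#' @param hour local solar hour (0-24, fractional allowed).
#' @param latitude degrees north.
#' @param longitude degrees east; kept for interface completeness, hours
#'   are interpreted as local solar time.
#' @return list with `zenith`, `azimuth`, `declination` (degrees).
#' @export
solar_position <- function(date, hour, latitude, longitude = NULL) {
  date <- as.Date(date)
  doy <- as.integer(strftime(date, "%j"))
  g <- 2 * pi * (doy - 1) / 365
  decl <- 0.006918 - 0.399912 * cos(g) + 0.070257 * sin(g) -
    0.006758 * cos(2 * g) + 0.000907 * sin(2 * g) -
    0.002697 * cos(3 * g) + 0.00148 * sin(3 * g)   # radians
  phi <- deg2rad(latitude)
  H <- deg2rad(15 * (hour - 12))
  cosz <- sin(phi) * sin(decl) + cos(phi) * cos(decl) * cos(H)
  cosz <- min(max(cosz, -1), 1)
  zenith <- rad2deg(acos(cosz))
  east <- -cos(decl) * sin(H)
  north <- cos(phi) * sin(decl) - sin(phi) * cos(decl) * cos(H)
  azimuth <- (rad2deg(atan2(east, north)) + 360) %% 360
  list(zenith = zenith, azimuth = azimuth, declination = rad2deg(decl))
}

#' Direct and diffuse PPFD for a clear sky
#'
#' Attenuates the extraterrestrial PAR beam by `transmittance^m` along the
#' air-mass path (m = 1/cos zenith) and sends half of the scattered flux to
#' the ground as diffuse light. Both outputs are fluxes on a horizontal
#' plane; `beam_ppfd` is the direct flux on a plane normal to the beam.
#' Night (zenith >= 90 degrees) yields zeros.
#'
#' @param zenith solar zenith angle (degrees).
#' @param azimuth solar azimuth (degrees from north, clockwise).
#' @param transmittance atmospheric transmittance per unit air mass
#'   (default 0.7).
#' @param par_constant extraterrestrial PAR on a beam-normal plane
#'   (umol m-2 s-1).
#' @return a `SkyCondition` list: `zenith`, `azimuth`, `direct_ppfd`,
#'   `diffuse_ppfd`, `beam_ppfd`, `transmittance`.
#' @export
incident_ppfd <- function(zenith, azimuth = 180,
                          transmittance = 0.7,
                          par_constant = PAR_EXTRATERRESTRIAL) {
  if (transmittance <= 0 || transmittance > 1)
    stopf("transmittance must be in (0, 1]")
  if (zenith >= 90) {
    beam <- direct <- diffuse <- 0
  } else {
    cosz <- cos(deg2rad(zenith))
    m <- 1 / cosz
    beam <- par_constant * transmittance^m
    direct <- beam * cosz
    diffuse <- 0.5 * par_constant * (1 - transmittance^m) * cosz
  }
  structure(list(zenith = zenith, azimuth = azimuth,
                 direct_ppfd = direct, diffuse_ppfd = diffuse,
                 beam_ppfd = beam, transmittance = transmittance),
            class = "SkyCondition")
}

#' Sky condition for a site, date and hour
#'
#' Convenience wrapper combining [solar_position()] and [incident_ppfd()].
#'
#' @inheritParams solar_position
#' @inheritParams incident_ppfd
#' @return a `SkyCondition` with the solar position attached.
#' @export
sky_condition <- function(date, hour, latitude, longitude = NULL,
                          transmittance = 0.7,
                          par_constant = PAR_EXTRATERRESTRIAL) {
  sp <- solar_position(date, hour, latitude, longitude)
  sky <- incident_ppfd(sp$zenith, sp$azimuth, transmittance, par_constant)
  sky$date <- as.Date(date)
  sky$hour <- hour
  sky
}

#' Leaf optical properties
#'
#' @param reflectance,transmittance PAR-band fractions, `R + T <= 1`.
#' @param spad optional SPAD reading the values were derived from.
#' @return object of class `LeafOpticalProperties` with `absorptance`
#'   = 1 - R - T.
#' @export
leaf_optics <- function(reflectance, transmittance, spad = NULL) {
  if (reflectance < 0 || transmittance < 0)
    stopf("reflectance and transmittance must be >= 0")
  if (reflectance + transmittance > 1)
    stopf("R + T must be <= 1")
  structure(list(reflectance = reflectance, transmittance = transmittance,
                 absorptance = 1 - reflectance - transmittance, spad = spad),
            class = "LeafOpticalProperties")
}

#' @export
print.LeafOpticalProperties <- function(x, ...) {
  cat(sprintf("LeafOpticalProperties: R = %.4f, T = %.4f, absorptance = %.4f\n",
              x$reflectance, x$transmittance, x$absorptance))
  invisible(x)
}

#' PAR-weighted broadband optics from spectra
#'
#' Weights spectral reflectance/transmittance by the incident solar
#' spectrum over 400-700 nm inclusive with a plain (non-trapezoidal) sum:
#' R = sum(R_i I_i) / sum(I_i), and likewise for T.
#'
#' @param wavelength_nm wavelength grid (nm); must cover 400-700 nm.
#' @param R_i,T_i spectral reflectance/transmittance (fractions); either
#'   may be `NULL` (reported as 0).
#' @param I_i incident spectral irradiance weights.
#' @return a [leaf_optics()] object.
#' @export
weighted_optics <- function(wavelength_nm, R_i = NULL, T_i = NULL, I_i) {
  if (min(wavelength_nm) > 400 || max(wavelength_nm) < 700)
    stopf("spectra must cover 400-700 nm (got %g-%g)",
          min(wavelength_nm), max(wavelength_nm))
  sel <- wavelength_nm >= 400 & wavelength_nm <= 700
  wsum <- sum(I_i[sel])
  if (wsum <= 0) stopf("incident spectrum must have positive weight in PAR")
  R <- if (is.null(R_i)) 0 else sum(R_i[sel] * I_i[sel]) / wsum
  T <- if (is.null(T_i)) 0 else sum(T_i[sel] * I_i[sel]) / wsum
  leaf_optics(R, T)
}

#' Leaf optics from a SPAD chlorophyll reading
#'
#' Empirical percent-valued regressions: transmittance (both varieties)
#' t = 0.006319 SPAD^2 - 0.8241 SPAD + 29.49; reflectance
#' r = 0.002478 SPAD^2 - 0.3554 SPAD + 16.66 for A619 and
#' r = -0.04863 SPAD + 8.856 for W64A. Percentages are converted to
#' fractions and clamped to the unit interval with a warning if clamping occurs.
#'
#' @param spad SPAD reading; a warning is issued outside 0..80.
#' @param variety "W64A" or "A619" (selects the reflectance model).
#' @return a [leaf_optics()] object.
#' @export
spad_to_optics <- function(spad, variety = c("W64A", "A619")) {
  variety <- match.arg(variety)
  if (spad < 0 || spad > 80)
    warnf("SPAD %.1f outside the calibration window [0, 80]", spad)
  t_pct <- 0.006319 * spad^2 - 0.8241 * spad + 29.49
  r_pct <- switch(variety,
                  A619 = 0.002478 * spad^2 - 0.3554 * spad + 16.66,
                  W64A = -0.04863 * spad + 8.856)
  tt <- t_pct / 100
  rr <- r_pct / 100
  if (tt < 0 || tt > 1 || rr < 0 || rr > 1) {
    warnf("SPAD-derived optics clamped to [0, 1]")
    tt <- min(max(tt, 0), 1)
    rr <- min(max(rr, 0), 1)
  }
  leaf_optics(rr, tt, spad = spad)
}
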