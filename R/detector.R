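# Detector and acquisition specifications; in-window detection weights.

#' Detector specification
#'
#' Standard NaI(Tl) camera detector.  Defaults reproduce the standard
#' condition used throughout: 9.5 mm (3/8 inch) crystal, 3.8 mm intrinsic
#' resolution, 9.8 % energy resolution (FWHM at 140 keV), 76 mm
#' backscatter material, 1 mm cover.
#'
#' @param crystal_thickness crystal thickness (mm).
#' @param intrinsic_resolution intrinsic resolution (mm FWHM).
#' @param energy_resolution_140 fractional energy resolution (FWHM) at
#'   140 keV; must lie in (0, 0.3).
#' @param backscatter_thickness backscatter material thickness (mm).
#' @param cover_thickness cover thickness (mm).
#' @return object of class `"detector_spec"`.
#' @export
detector_spec <- function(crystal_thickness = 9.5,
                          intrinsic_resolution = 3.8,
                          energy_resolution_140 = 0.098,
                          backscatter_thickness = 76,
                          cover_thickness = 1.0) {
  vals <- c(crystal_thickness, intrinsic_resolution, energy_resolution_140,
            backscatter_thickness, cover_thickness)
  if (any(vals <= 0)) stop("all detector parameters must be positive")
  if (energy_resolution_140 >= 0.3)
    stop("energy_resolution_140 must be in (0, 0.3)")
  structure(list(crystal_thickness = crystal_thickness,
                 intrinsic_resolution = intrinsic_resolution,
                 energy_resolution_140 = energy_resolution_140,
                 backscatter_thickness = backscatter_thickness,
                 cover_thickness = cover_thickness),
            class = "detector_spec")
}

#' Acquisition specification
#'
#' @param matrix image matrix (pixels per side, >= 64).
#' @param pixel_size pixel size (mm).
#' @param window_center photopeak window centre (keV).
#' @param window_halfwidth fractional half-width of the energy window
#'   (0.10 = +/- 10 %).
#' @param total_photons photon budget per view: photons emitted into the
#'   collimator's geometric acceptance.  The default 1e7 is the
#'   desk-scale equivalent of the full-transport budget.
#' @param source_distance phantom mid-plane to collimator face (mm),
#'   identical for both views.
#' @param seed base RNG seed for Poisson sampling.
#' @return object of class `"acquisition_spec"`.
#' @export
acquisition_spec <- function(matrix = 256, pixel_size = 2.21,
                             window_center = 159, window_halfwidth = 0.10,
                             total_photons = 1e7, source_distance = 50,
                             seed = 1L) {
  if (matrix < 64) stop("matrix must be >= 64")
  if (window_halfwidth <= 0 || window_halfwidth >= 1)
    stop("window_halfwidth must be in (0, 1)")
  if (total_photons <= 0) stop("total_photons must be positive")
  structure(list(matrix = as.integer(matrix), pixel_size = pixel_size,
                 window_center = window_center,
                 window_halfwidth = window_halfwidth,
                 total_photons = total_photons,
                 source_distance = source_distance,
                 seed = as.integer(seed)),
            class = "acquisition_spec")
}

#' In-window detection weight of an emission line
#'
#' Probability that an emitted photon of the given energy, having reached
#' the detector, produces a count inside the photopeak window.  Two
#' channels are modelled:
#'
#' * photopeak: full-energy capture `1 - exp(-mu_NaI(E) T)` times the
#'   in-window fraction of a Gaussian photopeak whose FWHM scales as
#'   `energy_resolution_140 * sqrt(140/E)`;
#' * downscatter (lines above 400 keV): partial-energy events, dominated
#'   by photons that traverse the crystal, backscatter off the material
#'   behind it (backscatter energy `E/(1 + 2E/511)`, close to the window
#'   for the I-123 high-energy lines) and are captured on return.  The
#'   in-window fraction of this continuum is taken proportional to the
#'   window width (50 keV reference), so the weight vanishes with the
#'   window.
#'
#' @param det a [detector_spec()].
#' @param energy_kev line energy (keV).
#' @param acq an [acquisition_spec()] (window definition).
#' @return detection weight in \[0, 1).
#' @export
detection_weight <- function(det, energy_kev, acq = acquisition_spec()) {
  t_mm <- det$crystal_thickness
  lo <- acq$window_center * (1 - acq$window_halfwidth)
  hi <- acq$window_center * (1 + acq$window_halfwidth)
  width <- hi - lo

  mu_e <- mu_linear("nai", energy_kev)
  capture <- 1 - exp(-mu_e * t_mm)
  fwhm <- det$energy_resolution_140 * sqrt(140 / energy_kev) * energy_kev
  sigma <- fwhm / (2 * sqrt(2 * log(2)))
  in_window <- stats::pnorm(hi, energy_kev, sigma) -
    stats::pnorm(lo, energy_kev, sigma)
  w <- capture * in_window

  if (energy_kev > 400) {
    e_back <- energy_kev / (1 + 2 * energy_kev / 511)
    mu_b <- mu_linear("nai", e_back)
    bs_material <- (1 - exp(-0.02 * det$backscatter_thickness)) /
      (1 - exp(-0.02 * 76))
    w <- w + (width / 50) * exp(-mu_e * t_mm) * (1 - exp(-mu_b * t_mm)) *
      bs_material
  }
  unname(w)
}
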