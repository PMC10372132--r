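# Analytic multi-energy planar projector with Poisson noise.
#
# Stands in for stochastic photon transport: the expected image is an
# analytic composition of Beer-Lambert projections, collimator/detector
# blur, septal-penetration tails and in-phantom scatter, and the
# measured image is an independent Poisson sample of it.  First-order
# physics only: attenuation, geometric + intrinsic blur, energy window,
# high-energy septal penetration and downscatter.
#
# Per emission line E the relative sensitivity of the two collimator
# channels is
#   geometric:    eps_g(E)                       (narrow Gaussian core)
#   penetration:  alpha * p(E) * sqrt(eps_g(E))  (broad tail)
# where p(E) is the minimal-path septal penetration and sqrt(eps_g) is
# the collimator's one-dimensional angular acceptance: penetrating
# photons are accepted over an angular cap comparable to the geometric
# acceptance angle, while bypassing the open-area bottleneck.  alpha is
# the single calibrated constant of the camera model (see
# `penetration_gain` below); it was fixed once against the printed
# simulated coefficients of the three Discovery collimators and is not a
# per-run fit.

# Calibrated penetration-channel gain (dimensionless).  Frozen; see the
# methods vignette for the calibration protocol.
.penetration_gain_default <- 0.54

# In-phantom scatter: fraction of 159 keV events redistributed by a broad
# Gaussian (FWHM mm).  Second-order for a 50 mm slab; fixed, documented.
.scatter_weight_default <- 0.1
.scatter_fwhm_mm <- 100

# High-energy downscatter kernel (FWHM mm): in-window events from the
# > 400 keV lines are dominated by backscatter returns off the material
# behind the crystal, so their positional correlation is largely lost and
# one broad diffuse kernel is used for every collimator.
.downscatter_fwhm_mm <- 250

.fft_size <- function(n) stats::nextn(2L * n - 1L, c(2, 3, 5))

.gauss_kernel <- function(sigma_px, max_half) {
  m <- max(1L, min(as.integer(ceiling(4 * sigma_px)), max_half))
  i <- (-m):m
  k1 <- exp(-i^2 / (2 * sigma_px^2))
  k <- outer(k1, k1)
  k / sum(k)
}

.exp_kernel <- function(scale_px, max_half) {
  m <- max(2L, min(as.integer(ceiling(5 * scale_px)), max_half))
  i <- (-m):m
  r <- sqrt(outer(i^2, i^2, "+"))
  k <- exp(-r / scale_px)
  k / sum(k)
}

# kernel centred at the origin of a P x P wrap-around grid, then FFT'd
.kernel_fft <- function(k, P) {
  m <- (nrow(k) - 1L) / 2L
  pk <- matrix(0, P, P)
  idx <- function(i) ((i + P) %% P) + 1L
  pk[idx((-m):m), idx((-m):m)] <- k
  stats::fft(pk)
}

.pad_fft <- function(img, P) {
  pi_ <- matrix(0, P, P)
  pi_[seq_len(nrow(img)), seq_len(ncol(img))] <- img
  stats::fft(pi_)
}

#' System point-spread function
#'
#' Normalized two-component PSF of a collimator/detector pair at one
#' energy: a Gaussian core with FWHM `sqrt(geometric^2 + intrinsic^2)`
#' carrying weight `1 - p`, plus a broad septal-penetration tail with
#' weight `p = septal_penetration(col, energy)`.  The tail has an
#' exponential radial profile whose scale follows the angular
#' transmission of the septa,
#' `r0 = (b + L) (d + t) / (mu_Pb(E) L t)`.
#'
#' @param col a [collimator()].
#' @param det a [detector_spec()].
#' @param energy_kev photon energy (keV).
#' @param source_distance source-to-face distance (mm).
#' @param pixel_size pixel size (mm).
#' @param max_half maximum kernel half-size (pixels).
#' @param penetration override for the tail weight (e.g. 0 to force a
#'   pure Gaussian).
#' @return normalized kernel matrix (sums to 1).
#' @export
system_psf <- function(col, det, energy_kev, source_distance = 50,
                       pixel_size = 2.21, max_half = 255L,
                       penetration = NULL) {
  p <- if (is.null(penetration)) septal_penetration(col, energy_kev)
       else penetration
  fwhm <- sqrt(geometric_fwhm(col, energy_kev, source_distance)^2 +
                 det$intrinsic_resolution^2)
  core <- .gauss_kernel(fwhm / (2 * sqrt(2 * log(2))) / pixel_size, max_half)
  if (p == 0) return(core)
  tail <- .exp_kernel(.pen_tail_scale(col, energy_kev, source_distance) /
                        pixel_size, max_half)
  m <- max((nrow(core) - 1L) / 2L, (nrow(tail) - 1L) / 2L)
  emb <- function(k) {
    km <- (nrow(k) - 1L) / 2L
    out <- matrix(0, 2L * m + 1L, 2L * m + 1L)
    sel <- (m - km + 1L):(m + km + 1L)
    out[sel, sel] <- k
    out
  }
  (1 - p) * emb(core) + p * emb(tail)
}

.pen_tail_scale <- function(col, energy_kev, source_distance) {
  mu <- mu_linear("lead", energy_kev, density = col$density)
  (source_distance + col$length) *
    (col$hole_diameter + col$septal_thickness) /
    (mu * col$length * col$septal_thickness)
}

# abundance-weighted line bookkeeping: the principal line plus one
# effective high-energy line grouping the four > 400 keV lines
.line_channels <- function(col, det, acq) {
  sp <- i123_spectrum()
  pr <- sp[sp$energy_kev < 400, ]
  he <- sp[sp$energy_kev > 400, ]
  w_pr <- detection_weight(det, pr$energy_kev, acq)
  w_he <- vapply(he$energy_kev, detection_weight, numeric(1), det = det,
                 acq = acq)
  p_he <- vapply(he$energy_kev, septal_penetration, numeric(1), col = col)
  e_eff <- sum(he$abundance * he$energy_kev) / sum(he$abundance)
  list(e_pr = pr$energy_kev, a_pr = pr$abundance, w_pr = w_pr,
       p_pr = septal_penetration(col, pr$energy_kev),
       e_he = e_eff,
       aw_he = sum(he$abundance * w_he),
       awp_he = sum(he$abundance * w_he * p_he),
       a_total = sum(sp$abundance))
}

#' Expected (noise-free) planar image
#'
#' Deterministic expectation of [simulate_planar()]: line-by-line
#' Beer-Lambert projections convolved with the geometric/intrinsic core,
#' the in-phantom scatter kernel (159 keV) and the septal-penetration
#' tails, combined with abundance, in-window detection weight and
#' collimator channel sensitivities, then scaled so that an ideal
#' detector would record `total_photons` counts per unit abundance (the
#' budget counts photons emitted into the collimator's geometric
#' acceptance).
#'
#' @inheritParams system_psf
#' @param phantom a [build_phantom()] result.
#' @param acq an [acquisition_spec()].
#' @param view `"anterior"` or `"posterior"`.
#' @param penetration_gain penetration-channel gain alpha; the default is
#'   the frozen calibrated constant.
#' @param scatter_weight 159 keV scatter fraction.
#' @param .cache optional environment reusing projection FFTs across
#'   collimators for the same phantom/acquisition (used by the grid
#'   pipeline).
#' @return a `planar_image` whose `counts` are expected values.
#' @export
expected_planar <- function(phantom, col, det, acq,
                            view = c("anterior", "posterior"),
                            penetration_gain = NULL,
                            scatter_weight = NULL, .cache = NULL) {
  view <- match.arg(view)
  if (is.null(penetration_gain)) penetration_gain <- .penetration_gain_default
  if (is.null(scatter_weight)) scatter_weight <- .scatter_weight_default
  n <- phantom$grid_shape[1]
  stopifnot(n == acq$matrix)
  P <- .fft_size(n)
  max_half <- n - 1L
  px <- phantom$pixel_size
  b <- acq$source_distance
  ch <- .line_channels(col, det, acq)

  proj_fft <- function(energy) {
    key <- paste0(view, "_", round(energy, 1))
    if (!is.null(.cache) && !is.null(.cache[[key]])) return(.cache[[key]])
    pf <- .pad_fft(ideal_project(phantom, view, energy), P)
    if (!is.null(.cache)) .cache[[key]] <- pf
    pf
  }
  kf <- function(k) .kernel_fft(k, P)
  gauss <- function(energy) {
    fwhm <- sqrt(geometric_fwhm(col, energy, b)^2 +
                   det$intrinsic_resolution^2)
    .gauss_kernel(fwhm / (2 * sqrt(2 * log(2))) / px, max_half)
  }
  tailk <- function(energy)
    .exp_kernel(.pen_tail_scale(col, energy, b) / px, max_half)

  eps_pr <- geometric_efficiency(col, ch$e_pr)
  eps_he <- geometric_efficiency(col, ch$e_he)
  pf_pr <- proj_fft(ch$e_pr)
  pf_he <- proj_fft(ch$e_he)

  w_core_pr <- ch$a_pr * ch$w_pr * (1 - scatter_weight) * eps_pr
  w_scat    <- ch$a_pr * ch$w_pr * scatter_weight * eps_pr
  w_pen_pr  <- penetration_gain * ch$a_pr * ch$w_pr * ch$p_pr * sqrt(eps_pr)
  w_core_he <- ch$aw_he * eps_he
  w_pen_he  <- penetration_gain * ch$awp_he * sqrt(eps_he)

  acc <- w_core_pr * kf(gauss(ch$e_pr)) * pf_pr +
    w_scat * kf(.gauss_kernel(.scatter_fwhm_mm / (2 * sqrt(2 * log(2))) / px,
                              max_half)) * pf_pr +
    w_pen_pr * kf(tailk(ch$e_pr)) * pf_pr +
    w_core_he * kf(gauss(ch$e_he)) * pf_he +
    w_pen_he * kf(.gauss_kernel(.downscatter_fwhm_mm / (2 * sqrt(2 * log(2))) /
                                  px, max_half)) * pf_he

  img <- Re(stats::fft(acc, inverse = TRUE))[seq_len(n), seq_len(n)] / P^2
  img[img < 0] <- 0
  # normalize per emitted photon: activity maps are per-layer emission
  # densities, so the emission total is the sum over layers and pixels
  act_total <- sum(vapply(phantom$activity_layers, sum, numeric(1)))
  img <- img * acq$total_photons / (eps_pr * ch$a_total * act_total)

  structure(list(counts = img, pixel_size = px, view = view,
                 metadata = list(collimator = col$label,
                                 hole_diameter = col$hole_diameter,
                                 septal_thickness = col$septal_thickness,
                                 length = col$length,
                                 total_photons = acq$total_photons,
                                 penetration_gain = penetration_gain,
                                 expected = TRUE, seed = NA_integer_)),
            class = "planar_image")
}

#' Simulate a planar view
#'
#' Poisson realization of [expected_planar()].  With the same inputs and
#' seed the image is bit-identical.
#'
#' @inheritParams expected_planar
#' @param noise draw Poisson counts (`TRUE`) or return the expectation.
#' @param seed RNG seed; defaults to `acq$seed`.
#' @param expectation optional precomputed [expected_planar()] result for
#'   this view (replicates then reuse it).
#' @return a `planar_image` of counts.
#' @export
simulate_planar <- function(phantom, col, det, acq,
                            view = c("anterior", "posterior"),
                            noise = TRUE, seed = acq$seed,
                            expectation = NULL,
                            penetration_gain = NULL, scatter_weight = NULL,
                            .cache = NULL) {
  view <- match.arg(view)
  if (is.null(expectation))
    expectation <- expected_planar(phantom, col, det, acq, view,
                                   penetration_gain = penetration_gain,
                                   scatter_weight = scatter_weight,
                                   .cache = .cache)
  img <- expectation
  rois <- tryCatch(place_rois(phantom), error = function(e) NULL)
  if (!is.null(rois)) {
    hp <- .roi_heart_pixels(rois, dim(img$counts))
    ex <- img$counts
    if (view == "posterior") ex <- ex[, rev(seq_len(ncol(ex)))]
    if (sum(ex[hp]) < 100)
      warning("heart ROI expectation below 100 counts; ",
              "increase total_photons")
  }
  if (noise) {
    set.seed(seed)
    img$counts <- matrix(stats::rpois(length(img$counts),
                                      lambda = img$counts),
                         nrow(img$counts), ncol(img$counts))
    img$metadata$seed <- as.integer(seed)
    img$metadata$expected <- FALSE
  }
  img
}

#' @export
print.planar_image <- function(x, ...) {
  cat(sprintf("<planar_image %s %dx%d, %.3g counts%s>\n", x$view,
              nrow(x$counts), ncol(x$counts), sum(x$counts),
              if (isTRUE(x$metadata$expected)) " (expected)" else ""))
  invisible(x)
}

#' Write a planar image to plain-text files
#'
#' Counts as a headerless CSV matrix plus a JSON sidecar with pixel
#' size, view and acquisition metadata; optionally a PNG preview.
#'
#' @param img a `planar_image`.
#' @param path output stem; writes `<path>.csv` and `<path>.json` (and
#'   `<path>.png` if `preview` and the png package is available).
#' @param preview write a PNG preview.
#' @return `path`, invisibly.
#' @export
write_planar <- function(img, path, preview = FALSE) {
  utils::write.table(img$counts, paste0(path, ".csv"), sep = ",",
                     row.names = FALSE, col.names = FALSE)
  meta <- img$metadata
  meta$pixel_size <- img$pixel_size
  meta$view <- img$view
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  if (preview && requireNamespace("png", quietly = TRUE)) {
    z <- img$counts / max(img$counts, 1)
    png::writePNG(z, paste0(path, ".png"))
  }
  invisible(path)
}
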