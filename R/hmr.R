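# ROI placement, HMR computation, conversion coefficients, compensation
# and the septal-penetration exclusion filter.
#
# The conversion coefficient maps a camera/collimator system onto a
# standard HMR scale:
#   cc = ((HMR_ant + HMR_post)/2 - 1) / ((2.6 + 3.5)/2 - 1)
# where 2.6 and 3.5 are the phantom's designated anterior and posterior
# HMRs.  Simulated coefficients are mapped onto the experimental scale
# with the compensation line Y = 1.27 X - 0.15.

#' Place standardized ROIs on the phantom compartments
#'
#' Circular heart ROI centred on the heart-mask centroid with radius 0.8
#' times the centroid-to-boundary inscribed radius; rectangular
#' mediastinal ROI centred on the mediastinum-mask centroid (default
#' 10 x 30 pixels, shrunk to fit the mask).  ROIs are defined in the
#' anterior orientation; posterior images are mirrored back before ROI
#' extraction.
#'
#' @param phantom a [build_phantom()] result.
#' @param width,height mediastinal rectangle size (pixels).
#' @param radius_fraction heart radius as a fraction of the inscribed
#'   radius.
#' @return object of class `"roi_set"`: `heart` (centre, radius, px) and
#'   `mediastinum` (rows, cols).
#' @export
place_rois <- function(phantom, width = 10L, height = 30L,
                       radius_fraction = 0.8) {
  heart <- .mask_of(phantom, "heart")
  med <- .mask_of(phantom, "mediastinum")
  if (!any(heart) || !any(med))
    stop("roi placement failed: empty heart or mediastinum mask")
  n <- phantom$grid_shape

  hw <- which(heart, arr.ind = TRUE)
  hc <- colMeans(hw)
  out <- which(!heart, arr.ind = TRUE)
  r_in <- sqrt(min((out[, 1] - hc[1])^2 + (out[, 2] - hc[2])^2)) - 1
  radius <- radius_fraction * r_in
  if (radius < 2)
    stop("roi placement failed: heart compartment too small for a ",
         "circular ROI (inscribed radius ", round(r_in, 2), " px)")

  mw <- which(med, arr.ind = TRUE)
  mc <- round(colMeans(mw))
  mrows <- range(mw[, 1]); mcols <- range(mw[, 2])
  h <- min(height, floor(0.8 * (mrows[2] - mrows[1] + 1)))
  w <- min(width, floor(0.8 * (mcols[2] - mcols[1] + 1)))
  rows <- seq.int(mc[1] - h %/% 2, length.out = h)
  cols <- seq.int(mc[2] - w %/% 2, length.out = w)

  rois <- structure(list(heart = list(centre = hc, radius = radius),
                         mediastinum = list(rows = rows, cols = cols)),
                    class = "roi_set")
  hp <- .roi_heart_pixels(rois, n)
  if (!all(heart[hp]))
    stop("roi placement failed: heart ROI exits the heart mask")
  if (!all(med[as.matrix(expand.grid(rows, cols))]))
    stop("roi placement failed: mediastinal ROI exits the mediastinum mask")
  rois
}

.roi_heart_pixels <- function(rois, grid_shape) {
  hc <- rois$heart$centre; r <- rois$heart$radius
  rr <- max(1L, floor(hc[1] - r)):min(grid_shape[1], ceiling(hc[1] + r))
  cc <- max(1L, floor(hc[2] - r)):min(grid_shape[2], ceiling(hc[2] + r))
  px <- as.matrix(expand.grid(row = rr, col = cc))
  px[(px[, 1] - hc[1])^2 + (px[, 2] - hc[2])^2 <= r^2, , drop = FALSE]
}

.roi_mean_heart <- function(img, rois)
  mean(img[.roi_heart_pixels(rois, dim(img))])

.roi_mean_med <- function(img, rois)
  mean(img[rois$mediastinum$rows, rois$mediastinum$cols])

.roi_hmr <- function(img, rois) {
  m <- .roi_mean_med(img, rois)
  if (m <= 0) stop("mediastinal ROI mean is zero; cannot form an HMR")
  .roi_mean_heart(img, rois) / m
}

#' Heart-to-mediastinum ratio of a planar image
#'
#' Mean counts in the circular heart ROI divided by mean counts in the
#' rectangular mediastinal ROI.  Posterior images (as produced by the
#' projector, mirrored left-right) are un-mirrored before extraction so
#' one anterior-frame ROI set serves both views.
#'
#' @param img a `planar_image` (or plain matrix, taken as anterior).
#' @param rois a [place_rois()] result.
#' @return dimensionless HMR.
#' @export
compute_hmr <- function(img, rois) {
  if (inherits(img, "planar_image")) {
    m <- img$counts
    if (identical(img$view, "posterior")) m <- m[, rev(seq_len(ncol(m)))]
  } else m <- img
  .roi_hmr(m, rois)
}

#' Conversion coefficient from an HMR pair
#'
#' `((hmr_ant + hmr_post)/2 - 1) / ((2.6 + 3.5)/2 - 1)`; equals 1 at the
#' designated HMRs and 0 for a contrast-free image.
#'
#' @param hmr_ant,hmr_post anterior and posterior HMRs (> 0).
#' @param designated designated anterior/posterior HMRs of the phantom.
#' @return dimensionless conversion coefficient.
#' @export
conversion_coefficient <- function(hmr_ant, hmr_post,
                                   designated = c(2.6, 3.5)) {
  if (any(c(hmr_ant, hmr_post) <= 0)) stop("HMRs must be positive")
  ((hmr_ant + hmr_post) / 2 - 1) / (mean(designated) - 1)
}

#' Compensation line
#'
#' Linear map from simulated onto experimental conversion coefficients.
#' The default constants (slope 1.27, intercept -0.15) are the printed
#' regression of experimental on simulated coefficients (R^2 = 0.96);
#' [fit_compensation()] refits them from user data.
#'
#' @param slope,intercept line coefficients (slope > 0).
#' @param r_squared coefficient of determination (metadata).
#' @return object of class `"compensation_line"`.
#' @export
compensation_line <- function(slope = 1.27, intercept = -0.15,
                              r_squared = NA_real_) {
  if (slope <= 0) stop("compensation slope must be positive")
  structure(list(slope = slope, intercept = intercept,
                 r_squared = r_squared),
            class = "compensation_line")
}

#' Apply the compensation line
#'
#' @param raw raw (simulated-scale) conversion coefficient(s).
#' @param line a [compensation_line()].
#' @return compensated coefficient(s), `slope * raw + intercept`.
#' @export
compensate <- function(raw, line = compensation_line()) {
  line$slope * raw + line$intercept
}

#' Fit a compensation line
#'
#' Ordinary least squares of experimental on simulated conversion
#' coefficients.
#'
#' @param simulated,experimental paired coefficients (>= 3 pairs).
#' @return a [compensation_line()] with the fitted slope, intercept and
#'   R^2.
#' @export
fit_compensation <- function(simulated, experimental) {
  if (length(simulated) != length(experimental) || length(simulated) < 3)
    stop("need >= 3 paired coefficients")
  if (stats::var(simulated) == 0)
    stop("degenerate fit: simulated coefficients have zero variance")
  fit <- stats::lm(experimental ~ simulated)
  # built directly: a refit may legitimately return a ~zero slope
  structure(list(slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 r_squared = summary(fit)$r.squared),
            class = "compensation_line")
}

#' Septal-penetration exclusion filter
#'
#' Retains records whose 159 keV penetration fraction does not exceed the
#' threshold; strictly greater values are excluded (> 1.0 % excluded,
#' exactly 1.0 % retained).
#'
#' @param records data.frame with a `penetration_159` column.
#' @param threshold penetration threshold (fraction).
#' @return the retained rows.
#' @export
penetration_filter <- function(records, threshold = 0.01) {
  stopifnot("penetration_159" %in% names(records))
  records[records$penetration_159 <= threshold, , drop = FALSE]
}

#' Simulate a conversion record for one collimator
#'
#' Runs `n_replicates` seeded anterior/posterior acquisitions sharing one
#' expectation per view, computes the per-replicate conversion
#' coefficient, applies the compensation line and reports replicate mean
#' and SD together with the 159 keV penetration fraction.
#'
#' @inheritParams expected_planar
#' @param n_replicates Poisson replicates (paired views per replicate).
#' @param seed base seed; replicate r, posterior view uses
#'   `seed + 2 (r - 1) + 1`.
#' @param line a [compensation_line()].
#' @param rois optional precomputed [place_rois()] result.
#' @param noise Poisson sampling on/off (off: replicates are identical
#'   and the record is deterministic).
#' @return one-row data.frame: label, collimator parameters, mean HMRs,
#'   raw and compensated coefficients, `penetration_159`, replicate count
#'   and SD.
#' @export
simulate_conversion <- function(phantom, col, det, acq, n_replicates = 5,
                                seed = acq$seed, line = compensation_line(),
                                rois = NULL, noise = TRUE,
                                penetration_gain = NULL,
                                scatter_weight = NULL, .cache = NULL) {
  if (is.null(rois)) rois <- place_rois(phantom)
  exp_a <- expected_planar(phantom, col, det, acq, "anterior",
                           penetration_gain = penetration_gain,
                           scatter_weight = scatter_weight, .cache = .cache)
  exp_p <- expected_planar(phantom, col, det, acq, "posterior",
                           penetration_gain = penetration_gain,
                           scatter_weight = scatter_weight, .cache = .cache)
  cc <- hma <- hmp <- numeric(n_replicates)
  for (r in seq_len(n_replicates)) {
    sa <- seed + 2L * (r - 1L)
    ia <- simulate_planar(phantom, col, det, acq, "anterior", noise = noise,
                          seed = sa, expectation = exp_a)
    ip <- simulate_planar(phantom, col, det, acq, "posterior", noise = noise,
                          seed = sa + 1L, expectation = exp_p)
    hma[r] <- compute_hmr(ia, rois)
    hmp[r] <- compute_hmr(ip, rois)
    cc[r] <- conversion_coefficient(hma[r], hmp[r])
  }
  data.frame(label = col$label,
             hole_diameter = col$hole_diameter,
             septal_thickness = col$septal_thickness,
             length = col$length,
             hmr_ant = mean(hma), hmr_post = mean(hmp),
             raw_cc = mean(cc),
             compensated_cc = compensate(mean(cc), line),
             penetration_159 = septal_penetration(col, 159),
             n_replicates = n_replicates,
             cc_sd = if (n_replicates > 1) stats::sd(cc) else 0,
             seed = seed,
             total_photons = acq$total_photons,
             stringsAsFactors = FALSE)
}
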