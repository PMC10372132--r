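# Digital three-layer calibration phantom.
#
# The phantom is a flat 380 x 380 x 50 mm PMMA slab carrying a
# three-layer activity map: a basal layer holding the uniform background
# and two organ layers (layer1, layer2) holding heart, lung, liver and
# thyroid activity.  Layers are stacked along the depth axis; the basal
# layer faces the anterior camera (the slab rests face-down on the
# anterior detector).  Compartments are parameterized 2-D primitives --
# the statistic downstream depends on ROI means, not anatomical fidelity.

.compartment_codes <- c(heart = 1L, mediastinum = 2L, liver = 3L,
                        lung_left = 4L, lung_right = 5L, thyroid = 6L,
                        background = 7L)

#' Default phantom configuration
#'
#' Geometry and activity parameters of the digital calibration phantom.
#' Lateral footprint 380 x 380 mm, depth 50 mm split into a basal
#' (background) layer facing the anterior camera and two organ layers.
#' Compartment positions are in mm relative to the phantom centre
#' (x right, y up on the anterior view).  Organ activity concentrations
#' are expressed relative to the mean heart concentration; the two heart
#' layer concentrations themselves are the free parameters fixed by
#' [calibrate_phantom()].
#'
#' @param matrix acquisition matrix (pixels per side).
#' @param pixel_size pixel size (mm).
#' @param footprint_mm lateral extent of the PMMA slab (mm).
#' @param layer_thicknesses named numeric: depths (mm) of `basal`,
#'   `layer1`, `layer2`, anterior to posterior; must sum to the phantom
#'   depth (50 mm by default).
#' @param density PMMA-equivalent density (g/cm^3).
#' @param heart,mediastinum,liver,lung_left,lung_right,thyroid
#'   compartment geometry lists (`centre`, and `radius` for discs or
#'   `width`/`height` for rectangles), in mm.
#' @param background_activity basal-layer activity concentration.
#' @param heart_layer1,heart_layer2 heart activity concentrations in the
#'   two organ layers (overwritten by calibration).
#' @param lung_ratio,liver_ratio,thyroid_ratio organ concentrations
#'   relative to the mean heart concentration, split equally over the
#'   two organ layers.
#' @return configuration list of class `"phantom_config"`.
#' @export
phantom_config <- function(matrix = 256, pixel_size = 2.21,
                           footprint_mm = 380,
                           layer_thicknesses = c(basal = 10, layer1 = 14,
                                                 layer2 = 26),
                           density = 1.19,
                           heart = list(centre = c(-50, -25), radius = 45),
                           mediastinum = list(centre = c(0, 70), width = 40,
                                              height = 110),
                           liver = list(centre = c(65, -95), width = 130,
                                        height = 90),
                           lung_left = list(centre = c(-75, 80), width = 90,
                                            height = 110),
                           lung_right = list(centre = c(75, 80), width = 90,
                                             height = 110),
                           thyroid = list(centre = c(0, 155), radius = 18),
                           background_activity = 1.0,
                           heart_layer1 = 1.9, heart_layer2 = 0.1,
                           lung_ratio = 0.25, liver_ratio = 0.9,
                           thyroid_ratio = 1.2) {
  if (matrix < 64) stop("matrix must be >= 64")
  if (pixel_size <= 0) stop("pixel_size must be positive")
  stopifnot(all(layer_thicknesses > 0),
            all(c("basal", "layer1", "layer2") %in% names(layer_thicknesses)))
  cfg <- list(matrix = as.integer(matrix), pixel_size = pixel_size,
              footprint_mm = footprint_mm,
              layer_thicknesses = layer_thicknesses, density = density,
              compartments = list(heart = heart, mediastinum = mediastinum,
                                  liver = liver, lung_left = lung_left,
                                  lung_right = lung_right, thyroid = thyroid),
              background_activity = background_activity,
              heart_layer1 = heart_layer1, heart_layer2 = heart_layer2,
              lung_ratio = lung_ratio, liver_ratio = liver_ratio,
              thyroid_ratio = thyroid_ratio)
  class(cfg) <- "phantom_config"
  cfg
}

#' Read a phantom configuration from JSON
#'
#' @param path JSON file whose keys are [phantom_config()] arguments.
#' @return a `phantom_config`.
#' @export
phantom_config_from_json <- function(path) {
  keys <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!is.null(keys$layer_thicknesses))
    keys$layer_thicknesses <- unlist(keys$layer_thicknesses)
  do.call(phantom_config, keys)
}

# pixel-centre coordinate grids (mm), +x right, +y up
.pixel_grid <- function(n, px) {
  centre <- (n + 1) / 2
  x <- (seq_len(n) - centre) * px          # by column
  y <- (centre - seq_len(n)) * px          # by row
  list(x = matrix(x, n, n, byrow = TRUE), y = matrix(y, n, n))
}

.disc_mask <- function(g, centre, radius)
  (g$x - centre[1])^2 + (g$y - centre[2])^2 <= radius^2

.rect_mask <- function(g, centre, width, height)
  abs(g$x - centre[1]) <= width / 2 & abs(g$y - centre[2]) <= height / 2

.compartment_mask <- function(g, comp) {
  if (!is.null(comp$radius)) .disc_mask(g, comp$centre, comp$radius)
  else .rect_mask(g, comp$centre, comp$width, comp$height)
}

.compartment_extent <- function(comp) {
  if (!is.null(comp$radius))
    c(comp$centre[1] - comp$radius, comp$centre[1] + comp$radius,
      comp$centre[2] - comp$radius, comp$centre[2] + comp$radius)
  else
    c(comp$centre[1] - comp$width / 2, comp$centre[1] + comp$width / 2,
      comp$centre[2] - comp$height / 2, comp$centre[2] + comp$height / 2)
}

#' Build the digital calibration phantom
#'
#' Rasterizes the compartment geometry of a [phantom_config()] onto the
#' acquisition grid and fills the three activity layers: uniform
#' background in the basal layer only; heart, lungs, liver and thyroid in
#' the two organ layers.  The density map is uniform PMMA over the
#' phantom footprint.
#'
#' @param config a [phantom_config()].
#' @return object of class `"digital_phantom"` with fields `grid_shape`,
#'   `pixel_size`, `layer_thicknesses`, `activity_layers` (list of three
#'   matrices), `density_map`, `compartment_masks` (labelled integer
#'   matrix) and `config`.
#' @export
build_phantom <- function(config = phantom_config()) {
  n <- config$matrix
  px <- config$pixel_size
  g <- .pixel_grid(n, px)
  half <- config$footprint_mm / 2
  grid_half <- n * px / 2
  if (half > grid_half + px)
    stop("invalid geometry: phantom footprint exceeds the acquisition grid")
  footprint <- abs(g$x) <= half & abs(g$y) <= half

  comps <- config$compartments
  for (nm in names(comps)) {
    ext <- .compartment_extent(comps[[nm]])
    if (ext[1] < -half || ext[2] > half || ext[3] < -half || ext[4] > half)
      stop("invalid geometry: compartment '", nm,
           "' extends outside the phantom footprint")
  }
  masks <- lapply(comps, .compartment_mask, g = g)
  if (any(masks$heart & masks$mediastinum))
    stop("invalid geometry: heart and mediastinum masks overlap")
  nm <- names(masks)
  for (i in seq_along(masks)) for (j in seq_len(i - 1L)) {
    if (any(masks[[i]] & masks[[j]]))
      stop("invalid geometry: compartments '", nm[i], "' and '", nm[j],
           "' overlap")
  }

  labelled <- matrix(0L, n, n)
  labelled[footprint] <- .compartment_codes[["background"]]
  for (cn in names(masks)) labelled[masks[[cn]]] <- .compartment_codes[[cn]]

  basal <- matrix(0, n, n)
  basal[footprint] <- config$background_activity
  heart_mean <- (config$heart_layer1 + config$heart_layer2) / 2
  organ <- matrix(0, n, n)
  organ[masks$lung_left | masks$lung_right] <- config$lung_ratio * heart_mean
  organ[masks$liver] <- config$liver_ratio * heart_mean
  organ[masks$thyroid] <- config$thyroid_ratio * heart_mean
  layer1 <- organ
  layer2 <- organ
  layer1[masks$heart] <- config$heart_layer1
  layer2[masks$heart] <- config$heart_layer2

  density <- matrix(0, n, n)
  density[footprint] <- config$density

  structure(list(grid_shape = c(n, n), pixel_size = px,
                 layer_thicknesses = config$layer_thicknesses,
                 activity_layers = list(basal = basal, layer1 = layer1,
                                        layer2 = layer2),
                 density_map = density,
                 compartment_masks = labelled,
                 config = config),
            class = "digital_phantom")
}

#' @export
print.digital_phantom <- function(x, ...) {
  cat(sprintf(paste0("<digital_phantom %dx%d @ %.2f mm, layers ",
                     "%.0f/%.0f/%.0f mm, heart %.3f/%.3f>\n"),
              x$grid_shape[1], x$grid_shape[2], x$pixel_size,
              x$layer_thicknesses[["basal"]], x$layer_thicknesses[["layer1"]],
              x$layer_thicknesses[["layer2"]],
              x$config$heart_layer1, x$config$heart_layer2))
  invisible(x)
}

.mask_of <- function(phantom, name)
  phantom$compartment_masks == .compartment_codes[[name]]

# per-layer depth intervals measured from the anterior face
.layer_depths <- function(phantom) {
  th <- phantom$layer_thicknesses[c("basal", "layer1", "layer2")]
  z1 <- cumsum(c(0, th))[1:3]
  cbind(z1 = z1, z2 = z1 + th)
}

# mean transmission of a uniform-activity layer toward the given camera
.layer_transmission <- function(phantom, energy_kev, view) {
  mu <- mu_linear("pmma", energy_kev, density = phantom$config$density)
  d <- .layer_depths(phantom)
  total <- sum(phantom$layer_thicknesses)
  if (view == "posterior") d <- cbind(z1 = total - d[, "z2"],
                                      z2 = total - d[, "z1"])
  (exp(-mu * d[, "z1"]) - exp(-mu * d[, "z2"])) / (mu * (d[, "z2"] - d[, "z1"]))
}

#' Ideal (degradation-free) projection of the phantom
#'
#' Beer-Lambert projection through the layer stack with a delta PSF: each
#' pixel is the sum over layers of activity times the exact within-layer
#' attenuation integral toward the camera.  The posterior view reverses
#' the layer order and mirrors the image left-right, consistent with a
#' camera behind the phantom.
#'
#' @param phantom a [build_phantom()] result.
#' @param view `"anterior"` or `"posterior"`.
#' @param energy_kev projection energy (keV).
#' @return fluence image (matrix, arbitrary units).
#' @export
ideal_project <- function(phantom, view = c("anterior", "posterior"),
                          energy_kev = 159) {
  view <- match.arg(view)
  tr <- .layer_transmission(phantom, energy_kev, view)
  img <- phantom$activity_layers$basal * tr[1] +
    phantom$activity_layers$layer1 * tr[2] +
    phantom$activity_layers$layer2 * tr[3]
  if (view == "posterior") img <- img[, rev(seq_len(ncol(img))), drop = FALSE]
  img
}

#' Ideal anterior/posterior HMR pair of a phantom
#'
#' HMRs computed from the ideal (blur-, penetration- and noise-free)
#' projections with the standardized ROI set.
#'
#' @param phantom a [build_phantom()] result.
#' @return named numeric `c(anterior = , posterior = )`.
#' @export
ideal_hmr <- function(phantom) {
  rois <- place_rois(phantom)
  ant <- .roi_hmr(ideal_project(phantom, "anterior"), rois)
  post <- .roi_hmr(ideal_project(phantom, "posterior")[, rev(seq_len(phantom$grid_shape[2]))],
                   rois)
  c(anterior = ant, posterior = post)
}

#' Calibrate heart activities to the designated HMR pair
#'
#' Solves for the two heart-layer concentrations so that the ideal
#' anterior and posterior HMRs equal the designated values (2.6 and 3.5).
#' The two-view constraint is linear in the two unknowns, so the solve is
#' exact; lung, liver and thyroid concentrations are then re-set at their
#' configured ratios to the calibrated mean heart concentration.
#'
#' @param phantom a [build_phantom()] result with nonzero background.
#' @param target_ant,target_post designated anterior/posterior HMRs
#'   (both > 1).
#' @return a calibrated `digital_phantom`.
#' @export
calibrate_phantom <- function(phantom, target_ant = 2.6, target_post = 3.5) {
  if (target_ant <= 1 || target_post <= 1)
    stop("designated HMRs must exceed 1")
  if (all(phantom$activity_layers$basal == 0))
    stop("phantom has no background activity")
  rois <- place_rois(phantom)
  heart <- .mask_of(phantom, "heart")

  roi_means <- function(ph, view) {
    img <- ideal_project(ph, view)
    if (view == "posterior") img <- img[, rev(seq_len(ncol(img)))]
    c(h = .roi_mean_heart(img, rois), m = .roi_mean_med(img, rois))
  }
  # basis responses: unit heart concentration in layer1 / layer2 / the rest
  base <- phantom
  base$activity_layers$layer1[heart] <- 0
  base$activity_layers$layer2[heart] <- 0
  u1 <- phantom; u1$activity_layers <- lapply(phantom$activity_layers, function(m) m * 0)
  u1$activity_layers$layer1[heart] <- 1
  u2 <- phantom; u2$activity_layers <- lapply(phantom$activity_layers, function(m) m * 0)
  u2$activity_layers$layer2[heart] <- 1

  co <- function(view) {
    b0 <- roi_means(base, view); b1 <- roi_means(u1, view); b2 <- roi_means(u2, view)
    list(b0 = b0, b1 = b1, b2 = b2)
  }
  A <- co("anterior"); P <- co("posterior")
  M <- rbind(c(A$b1["h"] - target_ant * A$b1["m"],
               A$b2["h"] - target_ant * A$b2["m"]),
             c(P$b1["h"] - target_post * P$b1["m"],
               P$b2["h"] - target_post * P$b2["m"]))
  rhs <- c(target_ant * A$b0["m"] - A$b0["h"],
           target_post * P$b0["m"] - P$b0["h"])
  sol <- tryCatch(solve(M, rhs), error = function(e)
    stop("calibration failed: singular two-view system"))
  if (any(sol < 0)) {
    r1 <- (P$b1["h"] / P$b0["m"]) / (A$b1["h"] / A$b0["m"])
    r2 <- (P$b2["h"] / P$b0["m"]) / (A$b2["h"] / A$b0["m"])
    stop(sprintf(paste0("calibration infeasible: designated contrast ratio ",
                        "(HMR_post-1)/(HMR_ant-1) = %.3f outside the ",
                        "attainable range [%.3f, %.3f]"),
                 (target_post - 1) / (target_ant - 1),
                 min(r1, r2), max(r1, r2)))
  }
  cfg <- phantom$config
  cfg$heart_layer1 <- unname(sol[1])
  cfg$heart_layer2 <- unname(sol[2])
  out <- build_phantom(cfg)
  attr(out, "calibrated") <- TRUE
  out
}

#' Serialize a phantom to a directory of plain-text files
#'
#' Per-layer activity matrices and the labelled compartment mask as
#' headerless CSV matrices plus a JSON sidecar with grid metadata.
#'
#' @param phantom a `digital_phantom`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_phantom <- function(phantom, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wr <- function(m, f) utils::write.table(m, file.path(dir, f), sep = ",",
                                          row.names = FALSE, col.names = FALSE)
  for (nm in names(phantom$activity_layers))
    wr(phantom$activity_layers[[nm]], paste0("activity_", nm, ".csv"))
  wr(phantom$compartment_masks, "compartment_masks.csv")
  wr(phantom$density_map, "density_map.csv")
  meta <- list(grid_shape = phantom$grid_shape, pixel_size = phantom$pixel_size,
               layer_thicknesses = as.list(phantom$layer_thicknesses),
               compartment_codes = as.list(.compartment_codes))
  jsonlite::write_json(meta, file.path(dir, "phantom.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a serialized phantom
#'
#' @param dir directory written by [write_phantom()].
#' @return a `digital_phantom` (without the generating config).
#' @export
read_phantom <- function(dir) {
  rd <- function(f) as.matrix(utils::read.csv(file.path(dir, f), header = FALSE))
  meta <- jsonlite::read_json(file.path(dir, "phantom.json"),
                              simplifyVector = TRUE)
  layers <- lapply(c(basal = "activity_basal.csv", layer1 = "activity_layer1.csv",
                     layer2 = "activity_layer2.csv"), rd)
  layers <- lapply(layers, unname)
  masks <- unname(rd("compartment_masks.csv"))
  storage.mode(masks) <- "integer"
  structure(list(grid_shape = meta$grid_shape, pixel_size = meta$pixel_size,
                 layer_thicknesses = unlist(meta$layer_thicknesses),
                 activity_layers = layers,
                 density_map = unname(rd("density_map.csv")),
                 compartment_masks = masks,
                 config = list(density = 1.19)),
            class = "digital_phantom")
}
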