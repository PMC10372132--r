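# Shared fixtures, built once per test run.

.fixtures <- new.env(parent = emptyenv())

default_phantom <- function() {
  if (is.null(.fixtures$phantom)) .fixtures$phantom <- build_phantom()
  .fixtures$phantom
}

calibrated_phantom <- function() {
  if (is.null(.fixtures$cal))
    .fixtures$cal <- calibrate_phantom(default_phantom())
  .fixtures$cal
}

standard_detector <- function() detector_spec()

fast_acq <- function(total_photons = 1e6, ...)
  acquisition_spec(total_photons = total_photons, ...)

# small synthetic feature table shaped like grid records, for model
# plumbing tests that do not need the simulator
make_table_for_validation <- function(n = 40, seed = 19) {
  set.seed(seed)
  g <- simulation_grid()[sample.int(864, n), ]
  g$compensated_cc <- 0.45 + 0.3 * g$septal_thickness -
    0.02 * g$hole_diameter + 0.001 * g$length
  rownames(g) <- NULL
  g
}

# deterministic compensated coefficient for one collimator (no noise)
noisefree_cc <- function(col, det = standard_detector(),
                         acq = fast_acq(), ...) {
  simulate_conversion(calibrated_phantom(), col, det, acq,
                      n_replicates = 1, noise = FALSE, ...)$compensated_cc
}
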