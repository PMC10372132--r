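# Photon cross-section tables and linear attenuation coefficients.

.hmrconv_env <- new.env(parent = emptyenv())

.material_density <- c(lead = 11.34, nai = 3.667, pmma = 1.19)

#' Photon mass-attenuation table
#'
#' Embedded coarse table of mass attenuation coefficients (total, with
#' coherent scattering) for the three materials the camera model needs:
#' collimator lead, NaI(Tl) crystal and the PMMA phantom medium.  Values
#' follow standard photon cross-section compilations over 100-600 keV and
#' are interpolated log-log between tabulated energies.
#'
#' @return data.frame with columns `energy_kev`, `material`
#'   (`"lead"`, `"nai"`, `"pmma"`) and `mu_over_rho_cm2_g`.
#' @export
attenuation_table <- function() {
  if (is.null(.hmrconv_env$att)) {
    path <- system.file("extdata", "attenuation_mu_over_rho.csv",
                        package = "hmrconv", mustWork = TRUE)
    .hmrconv_env$att <- utils::read.csv(path, stringsAsFactors = FALSE)
  }
  .hmrconv_env$att
}

#' Linear attenuation coefficient
#'
#' Log-log interpolation of the embedded cross-section table, multiplied by
#' the material density.  Energies must lie within the tabulated range
#' (100-600 keV); values outside it are a domain error, not an
#' extrapolation.
#'
#' @param material one of `"lead"`, `"nai"`, `"pmma"`.
#' @param energy_kev photon energy (keV); may be a vector.
#' @param density override density in g/cm^3 (defaults: lead 11.34,
#'   NaI 3.667, PMMA 1.19).
#' @return linear attenuation coefficient(s) in mm^-1.
#' @export
mu_linear <- function(material = c("lead", "nai", "pmma"), energy_kev,
                      density = NULL) {
  material <- match.arg(material)
  tab <- attenuation_table()
  tab <- tab[tab$material == material, ]
  rng <- range(tab$energy_kev)
  if (any(energy_kev < rng[1] | energy_kev > rng[2])) {
    stop("energy ", paste(energy_kev, collapse = ", "),
         " keV outside attenuation table range [", rng[1], ", ", rng[2], "]")
  }
  if (is.null(density)) density <- .material_density[[material]]
  mu_rho <- exp(stats::approx(log(tab$energy_kev), log(tab$mu_over_rho_cm2_g),
                              xout = log(energy_kev), rule = 1)$y)
  # cm^2/g * g/cm^3 = cm^-1; /10 -> mm^-1
  mu_rho * density / 10
}
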