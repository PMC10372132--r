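# I-123 emission lines relevant to photopeak imaging.

#' I-123 gamma emission spectrum
#'
#' The principal 159 keV line plus the four high-energy lines above
#' 400 keV that drive collimator septal penetration, with abundances from
#' published I-123 decay tables.  Low-energy X-rays (< 35 keV) are omitted:
#' they cannot reach the 159 keV +/- 10 % photopeak window.
#'
#' @return data.frame with columns `energy_kev` (ascending) and
#'   `abundance` (photons per decay).
#' @export
i123_spectrum <- function() {
  data.frame(
    energy_kev = c(159.0, 440.0, 505.3, 529.0, 538.5),
    abundance  = c(0.833, 0.00428, 0.00316, 0.0139, 0.00385)
  )
}
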