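# Modified Beer-Lambert law ----------------------------------------------
#
# OD_lambda = (eps_HbO(lambda) HbO + eps_HbR(lambda) HbR) * d * DPF(lambda)
# with Hb in Molar, d the emitter-detector separation in mm, and eps the
# molar extinction coefficient in mm^-1 M^-1. Inverting the 2x2 extinction
# system per channel yields HbO/HbR concentration changes.

#' Default molar extinction coefficients
#'
#' Standard tabulated values for hemoglobin at 690 and 830 nm, expressed
#' in mm^-1 M^-1 (tables are usually printed in cm^-1 M^-1; divided by 10).
#'
#' @return 2x2 matrix, rows wavelengths (690, 830), columns c(HbO, HbR).
#' @export
extinction_defaults <- function() {
  matrix(c(27.6, 205.2,
           97.4, 69.3),
         nrow = 2, byrow = TRUE,
         dimnames = list(c("690", "830"), c("HbO", "HbR")))
}

#' Default differential pathlength factors
#'
#' Age-adapted neonatal values for 690 and 830 nm.
#' @return Named numeric vector.
#' @export
dpf_defaults <- function() c("690" = 5.4, "830" = 4.7)

#' Forward model: Hb concentrations to optical density
#'
#' @param hbo,hbr Channel x time matrices of concentration change in Molar.
#' @param separation_mm Per-channel separations.
#' @param dpf Per-wavelength DPF (named for 690/830 nm).
#' @param extinction 2x2 extinction matrix (see [extinction_defaults()]).
#' @return List of two channel x time OD matrices, `od690` and `od830`.
#' @export
hb_to_od <- function(hbo, hbr, separation_mm,
                     dpf = dpf_defaults(), extinction = extinction_defaults()) {
  stopifnot(nrow(hbo) == length(separation_mm), dim(hbo) == dim(hbr))
  pl1 <- separation_mm * dpf[["690"]]
  pl2 <- separation_mm * dpf[["830"]]
  list(od690 = (extinction[1, 1] * hbo + extinction[1, 2] * hbr) * pl1,
       od830 = (extinction[2, 1] * hbo + extinction[2, 2] * hbr) * pl2)
}

#' Inverse model: dual-wavelength optical density to Hb concentrations
#'
#' @param od690,od830 Channel x time OD matrices.
#' @param separation_mm Per-channel separations.
#' @param dpf,extinction As in [hb_to_od()].
#' @return List of channel x time matrices `hbo` and `hbr` in micromolar.
#' @export
od_to_hb <- function(od690, od830, separation_mm,
                     dpf = dpf_defaults(), extinction = extinction_defaults()) {
  if (abs(det(extinction)) < 1e-12)
    stop("extinction matrix is singular; cannot unmix HbO/HbR")
  einv <- solve(extinction)
  n1 <- od690 / (separation_mm * dpf[["690"]])   # recycles by row
  n2 <- od830 / (separation_mm * dpf[["830"]])
  list(hbo = 1e6 * (einv[1, 1] * n1 + einv[1, 2] * n2),
       hbr = 1e6 * (einv[2, 1] * n1 + einv[2, 2] * n2))
}
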