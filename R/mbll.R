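# Modified Beer-Lambert law (MBLL) conversion between optical density and
# chromophore concentration changes.
#
# The same pinned extinction-coefficient table is used by the forward model
# in the simulator and by the inverse here, so forward/inverse round trips
# are exact up to floating point.

#' Molar extinction coefficients for HbO2 and HHb at 730 and 850 nm
#'
#' Literature-compilation molar extinction coefficients in
#' cm^-1 (mol/L)^-1, pinned as the package's versioned constants table.
#' Rows are wavelengths (`"730"`, `"850"`), columns chromophores
#' (`"HbO2"`, `"HHb"`).
#'
#' @return 2x2 numeric matrix.
#' @export
extinction_table <- function() {
  matrix(c(450.0, 1299.0,
           1058.0, 691.6),
         nrow = 2, byrow = TRUE,
         dimnames = list(c("730", "850"), c("HbO2", "HHb")))
}

#' MBLL conversion parameters
#'
#' @param dpf Differential path length factor (unitless), applied at both
#'   wavelengths. Default 6.0.
#' @param separation Source-detector separation in cm. Default 3.0.
#' @param extinction 2x2 extinction matrix as from [extinction_table()].
#' @return A list of class `mbll_params`.
#' @export
mbll_params <- function(dpf = 6.0, separation = 3.0,
                        extinction = extinction_table()) {
  stopifnot(dpf > 0, separation > 0, is.matrix(extinction),
            all(dim(extinction) == 2))
  if (kappa(extinction) >= 1e3)
    stop("extinction matrix is ill-conditioned (condition number >= 1e3)")
  structure(list(dpf = dpf, separation = separation, extinction = extinction),
            class = "mbll_params")
}

#' Forward MBLL: concentration changes to optical-density changes
#'
#' Maps hemoglobin concentration changes (micromol/L) to optical-density
#' changes at the two measurement wavelengths:
#' `dOD(lambda) = (eps_HbO2(lambda) dHbO2 + eps_HHb(lambda) dHHb) * d * DPF`
#' with concentrations converted to mol/L.
#'
#' @param conc Numeric array `[time, channel, chromophore]` with chromophores
#'   `HbO2`, `HHb` in micromol/L, or a `time x channel` matrix interpreted as
#'   HbO2 with HHb = 0.
#' @param params An [mbll_params()] object.
#' @return Array `[time, channel, wavelength]` of dOD (unitless).
#' @export
mbll_forward <- function(conc, params = mbll_params()) {
  if (is.matrix(conc)) {
    conc <- array(c(conc, 0 * conc), dim = c(dim(conc), 2))
  }
  stopifnot(length(dim(conc)) == 3, dim(conc)[3] == 2)
  E <- params$extinction * params$separation * params$dpf * 1e-6
  od <- array(0, dim = dim(conc),
              dimnames = list(NULL, NULL, rownames(params$extinction)))
  # od[,,wl] = E[wl,1]*HbO2 + E[wl,2]*HHb
  for (wl in 1:2)
    od[, , wl] <- conc[, , 1] * E[wl, 1] + conc[, , 2] * E[wl, 2]
  od
}

#' Inverse MBLL: optical-density changes to concentration changes
#'
#' Solves, per sample and channel, the 2x2 linear system relating dOD at the
#' two wavelengths to the HbO2 and HHb concentration changes. The operation
#' is exactly linear in its input.
#'
#' @param od Array `[time, channel, wavelength]` of dOD as produced by
#'   [intensity_to_od()] or [mbll_forward()].
#' @param params An [mbll_params()] object.
#' @return Array `[time, channel, chromophore]` in micromol/L, chromophores
#'   named `HbO2`, `HHb`.
#' @export
mbll <- function(od, params = mbll_params()) {
  stopifnot(length(dim(od)) == 3, dim(od)[3] == 2)
  E <- params$extinction * params$separation * params$dpf * 1e-6
  Einv <- solve(E)
  conc <- array(0, dim = dim(od), dimnames = list(NULL, NULL, c("HbO2", "HHb")))
  conc[, , 1] <- od[, , 1] * Einv[1, 1] + od[, , 2] * Einv[1, 2]
  conc[, , 2] <- od[, , 1] * Einv[2, 1] + od[, , 2] * Einv[2, 2]
  conc
}
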