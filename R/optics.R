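# Multi-photon excitation acquisition optics: Nyquist sampling distances and
# the diffraction-limited resolution, used as a quality-control calculator.

#' Nyquist sampling distances for multi-photon imaging
#'
#' Lateral: dx = dy = lambda_ex / (4 k n sin(alpha)); axial:
#' dz = lambda_ex / (2 k n (1 - cos(alpha))), where n is the lens-medium
#' refractive index, k the number of excitation photons, lambda_ex the
#' excitation wavelength and alpha the half-aperture angle of the objective
#' (sin(alpha) = NA / n).
#'
#' @param lambdaEx excitation wavelength in nm.
#' @param numericalAperture objective numerical aperture (must be < n).
#' @param refractiveIndex lens-medium refractive index (1.338 for water).
#' @param photonCount number of excitation photons (2 for MPE).
#' @return named numeric: \code{dxy} and \code{dz} in nm.
#' @export
nyquistSampling <- function(lambdaEx, numericalAperture,
                            refractiveIndex = 1.338, photonCount = 2) {
  stopifnot(lambdaEx > 0, numericalAperture > 0, photonCount >= 1)
  if (numericalAperture >= refractiveIndex)
    stop("undefined half-aperture angle: numerical aperture must be smaller ",
         "than the refractive index")
  sinA <- numericalAperture / refractiveIndex
  cosA <- sqrt(1 - sinA^2)
  c(dxy = lambdaEx / (4 * photonCount * refractiveIndex * sinA),
    dz = lambdaEx / (2 * photonCount * refractiveIndex * (1 - cosA)))
}

#' Diffraction-limited lateral resolution of MPE microscopy
#'
#' The two-point (Rayleigh) resolution for multi-photon excitation, where
#' only the excitation wavelength matters and the single-photon value
#' improves by sqrt(2): r = 0.61 lambda / (NA sqrt(2)).
#'
#' @param lambdaEx excitation wavelength in nm.
#' @param numericalAperture objective numerical aperture.
#' @return resolution limit in nm.
#' @export
mpeResolutionLimit <- function(lambdaEx, numericalAperture) {
  stopifnot(lambdaEx > 0, numericalAperture > 0)
  0.61 * lambdaEx / (numericalAperture * sqrt(2))
}

#' Check acquisition sampling against the Nyquist distances
#'
#' An axis passes when its sampling interval does not exceed the
#' corresponding Nyquist distance.
#'
#' @param pixelXY lateral pixel size in nm.
#' @param stepZ focal-plane interval in nm.
#' @param lambdaEx,numericalAperture,refractiveIndex,photonCount optics
#'   parameters, see \code{\link{nyquistSampling}}.
#' @return list with logical \code{lateral_pass}, \code{axial_pass} and the
#'   Nyquist distances used.
#' @export
checkSampling <- function(pixelXY, stepZ, lambdaEx, numericalAperture,
                          refractiveIndex = 1.338, photonCount = 2) {
  stopifnot(pixelXY > 0, stepZ > 0)
  ny <- nyquistSampling(lambdaEx, numericalAperture, refractiveIndex,
                        photonCount)
  list(lateral_pass = pixelXY <= ny[["dxy"]],
       axial_pass = stepZ <= ny[["dz"]],
       nyquist_dxy = ny[["dxy"]], nyquist_dz = ny[["dz"]])
}
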