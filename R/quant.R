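#' Expected receptors per nanodisc
#'
#' Mean number of receptors captured per disc when receptors are spread
#' uniformly at surface density `density` and each disc excises a circular
#' membrane patch of the given diameter:
#' \eqn{\lambda = \mathrm{density} \times \pi (d/2)^2}, with the nm-to-um
#' conversion handled internally.
#'
#' @param density Receptor surface density in molecules per square micron.
#' @param diameter_nm Disc diameter in nanometers (~25 for DIBMALPs).
#' @return Expected molecule count per disc (dimensionless).
#' @examples
#' expected_per_disc(253, 25)  # ~0.124 at physiological EphA2 density
#' @export
expected_per_disc <- function(density, diameter_nm) {
  if (!is.numeric(density) || any(density < 0))
    stop("`density` must be >= 0 molecules/um^2", call. = FALSE)
  if (!is.numeric(diameter_nm) || any(diameter_nm <= 0))
    stop("`diameter_nm` must be > 0", call. = FALSE)
  density * pi * (diameter_nm / 2000)^2
}

#' Probability of random co-capture in an occupied nanodisc
#'
#' Under spatially uniform (Poisson) placement with mean `lambda` receptors
#' per disc, the probability that an imaged (i.e. occupied) disc holds two
#' or more non-interacting receptors is
#' \deqn{P(K \ge 2 \mid K \ge 1) =
#'       \frac{1 - e^{-\lambda} - \lambda e^{-\lambda}}{1 - e^{-\lambda}}.}
#' This is the chance that a spot called a "dimer" is a coincidence rather
#' than a true complex. The raw mean `lambda` is reported alongside for
#' users who prefer the unconditional reading.
#'
#' @inheritParams expected_per_disc
#' @return A list with `lambda` (expected count per disc) and
#'   `p_cocapture` (the conditional probability above; 0 when lambda = 0).
#' @examples
#' cocapture_probability(253, 25)  # ~6% of occupied 25-nm discs
#' @export
cocapture_probability <- function(density, diameter_nm) {
  lam <- expected_per_disc(density, diameter_nm)
  p <- ifelse(lam == 0, 0,
              (-expm1(-lam) - lam * exp(-lam)) / (-expm1(-lam)))
  list(lambda = lam, p_cocapture = p)
}

#' Receptor surface density from a calibrated GPMV measurement
#'
#' Converts a blank-subtracted GFP fluorescence intensity measured over a
#' giant plasma membrane vesicle (GPMV) into a receptor surface density, by
#' comparison against a purified GFP standard of known concentration imaged
#' in a known volume. The per-molecule intensity is
#' `calibration_intensity / (calibration_concentration * N_A *
#' calibration_volume)` and the imaged membrane area is modeled as the
#' spherical zone sectioned by the confocal slice: area = pi * vesicle
#' diameter * slice thickness (a zone of a sphere has area independent of
#' where the slice cuts), clamped to the full sphere area pi * d^2 when the
#' slice is thicker than the vesicle.
#'
#' @param roi_intensity Blank-subtracted fluorescence of the vesicle ROI.
#'   Small negative values (blank over-subtraction) are clamped to 0 with a
#'   warning.
#' @param vesicle_diameter GPMV diameter in microns.
#' @param slice_thickness Optical section thickness in microns.
#' @param calibration_intensity Fluorescence of the GFP standard (same
#'   imaging settings), must be > 0.
#' @param calibration_concentration Molar concentration of the standard
#'   (e.g. 100e-9 for 100 nM).
#' @param calibration_volume Observation volume of the standard measurement
#'   in cubic microns.
#' @return Receptor density in molecules per square micron.
#' @export
density_from_gpmv <- function(roi_intensity, vesicle_diameter,
                              slice_thickness, calibration_intensity,
                              calibration_concentration,
                              calibration_volume) {
  if (calibration_intensity <= 0)
    stop("calibration error: `calibration_intensity` must be > 0",
         call. = FALSE)
  if (calibration_concentration <= 0 || calibration_volume <= 0)
    stop("calibration error: standard concentration and volume must be > 0",
         call. = FALSE)
  if (vesicle_diameter <= 0 || slice_thickness <= 0)
    stop("vesicle diameter and slice thickness must be > 0", call. = FALSE)
  if (roi_intensity < 0) {
    warning("negative blank-subtracted ROI intensity clamped to 0",
            call. = FALSE)
    roi_intensity <- 0
  }
  avogadro <- 6.02214076e23
  # molar concentration x volume in um^3: 1 um^3 = 1e-15 L
  molecules_std <- calibration_concentration * avogadro *
    calibration_volume * 1e-15
  intensity_per_molecule <- calibration_intensity / molecules_std
  molecules_roi <- roi_intensity / intensity_per_molecule
  h <- min(slice_thickness, vesicle_diameter)
  area <- pi * vesicle_diameter * h
  molecules_roi / area
}

#' Internal-standard lipid quantitation
#'
#' Converts an LC-HRMS peak-area ratio into picomoles of lipid using a
#' spiked internal standard of known concentration:
#' pmol = C(standard) x (peak area lipid / peak area standard) x extract
#' volume.
#'
#' @param internal_standard_concentration Standard concentration in
#'   pmol/uL.
#' @param peak_area_lipid,peak_area_standard Integrated peak areas
#'   (arbitrary units); the standard's area must be > 0.
#' @param extract_volume Extract volume in uL (default 40).
#' @return Lipid amount in pmol.
#' @examples
#' lipid_pmol(0.5, 1000, 1000)  # 20 pmol
#' @export
lipid_pmol <- function(internal_standard_concentration, peak_area_lipid,
                       peak_area_standard, extract_volume = 40) {
  if (peak_area_standard <= 0)
    stop("division error: `peak_area_standard` must be > 0", call. = FALSE)
  if (internal_standard_concentration < 0 || peak_area_lipid < 0 ||
      extract_volume < 0)
    stop("concentrations, peak areas and volumes must be >= 0",
         call. = FALSE)
  internal_standard_concentration *
    (peak_area_lipid / peak_area_standard) * extract_volume
}
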