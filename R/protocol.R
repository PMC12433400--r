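#' Kinetic energy of the head-impact compactor
#'
#' KE = m v^2 / 2. The protocol's 50 g compactor at 7.4 m/s carries
#' about 1.37 J.
#'
#' @param massKg compactor mass (kg), default 0.050.
#' @param velocityMs impact velocity (m/s), default 7.4.
#' @return energy in joules.
#' @export
impactKineticEnergy <- function(massKg = 0.050, velocityMs = 7.4) {
  stopUnless(massKg > 0 && velocityMs >= 0,
             "mass must be > 0 and velocity >= 0")
  0.5 * massKg * velocityMs^2
}

#' Ferumoxytol injection volume for a target blood concentration
#'
#' Blood volume is taken as 7% of body weight at 1 g/mL; the iron dose is
#' target concentration x blood volume, delivered from the stock solution.
#'
#' @param bodyWeightG body weight (g).
#' @param bloodFraction blood fraction of body weight, default 0.07.
#' @param targetUgMl target blood concentration (ug Fe/mL), default 200.
#' @param stockMgMl stock concentration (mg Fe/mL), default 6.
#' @return list: bloodVolumeMl, feMassMg, injectionVolumeMl.
#' @export
ferumoxytolDoseVolume <- function(bodyWeightG, bloodFraction = 0.07,
                                  targetUgMl = 200, stockMgMl = 6) {
  stopUnless(bodyWeightG > 0, "body weight must be positive")
  stopUnless(bloodFraction > 0 && bloodFraction < 0.15,
             "blood fraction must lie in (0, 0.15)")
  stopUnless(targetUgMl > 0 && stockMgMl > 0,
             "concentrations must be positive")
  bloodMl <- bloodFraction * bodyWeightG      # 1 g blood ~ 1 mL
  feMg <- targetUgMl * bloodMl / 1000
  list(bloodVolumeMl = bloodMl, feMassMg = feMg,
       injectionVolumeMl = feMg / stockMgMl)
}

#' Elemental-iron mass concentration to molarity
#'
#' mmol/L = (ug/mL) / 55.845 (molar mass of Fe); 200 ug/mL is 3.58
#' mmol/L.
#'
#' @param ugPerMl mass concentration (ug Fe / mL).
#' @return concentration in mmol/L.
#' @export
feMolarConcentration <- function(ugPerMl) {
  stopUnless(all(ugPerMl >= 0), "concentration must be >= 0")
  ugPerMl / 55.845
}

#' Voxel size from field of view and matrix size
#'
#' size = FOV / matrix per axis; e.g. 30 mm / 180 = 0.1667 mm (167 um)
#' and 30 mm / 96 = 0.3125 mm.
#'
#' @param fovMm field of view per axis (mm).
#' @param matrixSize acquisition matrix per axis (integer >= 1).
#' @return voxel size(s) in mm.
#' @export
voxelGeometry <- function(fovMm, matrixSize) {
  stopUnless(all(fovMm > 0), "FOV must be positive")
  stopUnless(all(matrixSize >= 1 & matrixSize == round(matrixSize)),
             "matrix size must be integer >= 1")
  fovMm / matrixSize
}

#' Protocol worked-example table
#'
#' Evaluates the closed-form protocol calculators at their defaults and
#' returns a table rounded to 3 significant figures for display.
#'
#' @return data.frame quantity, value, unit.
#' @export
protocolTable <- function() {
  dose <- ferumoxytolDoseVolume(250)
  data.frame(
    quantity = c("impact kinetic energy", "Fe molarity at 200 ug/mL",
                 "QUTE-CE voxel size", "DWI in-plane voxel size",
                 "injection volume (250 g rat)"),
    value = signif(c(impactKineticEnergy(),
                     feMolarConcentration(200),
                     voxelGeometry(30, 180) * 1000,
                     voxelGeometry(30, 96),
                     dose$injectionVolumeMl), 3),
    unit = c("J", "mmol/L", "um", "mm", "mL"))
}
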