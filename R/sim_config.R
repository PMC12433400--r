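#' Simulation configuration for a synthetic study
#'
#' Collects every knob of the synthetic-study generators in one validated
#' list. Defaults mirror the study design the package targets: two groups
#' (sham n = 6, head-impacted n = 8), 200-volume TR = 1 s BOLD with modular
#' inter-regional covariance weakened in the impacted group, pre- plus five
#' post-contrast scans over 30 min with region-specific linear CBV drift
#' (leak) in a minority of impacted-animal regions, and 10-direction
#' b = 1000 s/mm2 + b0 DWI from region-group tensors with group shifts
#' (basal ganglia MD -10% / FA +15%, thalamus MD -8%, cerebellum FA -10%).
#'
#' @param seed integer master seed; each modality derives its own substream.
#' @param nSham,nImpacted group sizes.
#' @param grid 3-vector of atlas grid dimensions (voxels).
#' @param voxelSizeMm voxel size of the phantom grid.
#' @param nRegions total atlas regions including one blood-pool label.
#' @param trS,nVolumes BOLD repetition time (s) and number of volumes.
#' @param boldBaseCor within-module correlation c of region signals.
#' @param boldSubjectSdZ between-subject SD of c on the Fisher-Z scale.
#' @param boldAttenuation multiplicative attenuation of c in affected
#'   region groups of impacted subjects (in (0, 1]).
#' @param boldAffectedGroups region groups whose coupling is attenuated.
#' @param boldMotionAmp,boldWmCsfAmp,boldDriftAmp,boldNOutliers,boldSpikeAmp
#'   nuisance-mixing amplitudes (signal-SD units) and outlier count.
#' @param boldBaseline,boldAmplitude,boldVoxelNoiseSd voxelwise BOLD
#'   rendering: baseline intensity, signal amplitude, i.i.d. voxel noise.
#' @param postScanTimesS post-contrast scan times (s), >= 3 scans.
#' @param tissueBaseline,bloodBaseline,contrastStep QUTE-CE intensities:
#'   pre-contrast tissue/blood baselines and the blood-signal step after
#'   the contrast bolus.
#' @param cbv0Range range of true baseline CBV fractions per region.
#' @param leakSlope true permeability slope beta (CBV fraction per s) in
#'   leak regions.
#' @param qcbvNoiseSd per-voxel intensity noise expressed in qCBV units
#'   (intensity SD = qcbvNoiseSd * contrastStep).
#' @param nLeakRegionsImpacted,nLeakSubjectsImpacted,nLeakRegionsSham,nLeakSubjectsSham
#'   leak template: how many regions leak in how many subjects per group.
#' @param bValue DWI b value (s/mm2).
#' @param dwiS0,dwiNoiseSd,dwiNoiseModel b0 signal, noise SD, and noise
#'   model ("gaussian" or "rician").
#' @param dwiShifts named list of per-region-group multiplicative MD/FA
#'   shifts applied to the impacted group, each c(md = ..., fa = ...).
#' @param dwiAreaJitter,dwiSubjectJitter multiplicative log-normal SDs of
#'   area-level and subject-level MD/FA variation.
#' @param arenaWidthCm,arenaHeightCm,borderCm open-field geometry; the
#'   peripheral zone is the 8 cm band inside the walls.
#' @param trackDurationS,trackHz,trackStepSd,trackCenterBias random-walk
#'   track parameters.
#' @param norExpectedIr expected novel-object investigation ratio (both
#'   groups; the null group-difference scenario).
#' @param norContactMeanS mean total object-contact time (s).
#' @return A validated list of class \code{simConfig}.
#' @export
simConfig <- function(seed = 1L,
                      nSham = 6L, nImpacted = 8L,
                      grid = c(24L, 24L, 24L),
                      voxelSizeMm = c(0.5, 0.5, 0.5),
                      nRegions = 60L,
                      trS = 1, nVolumes = 200L,
                      boldBaseCor = 0.4,
                      boldSubjectSdZ = 0.1,
                      boldAttenuation = 0.5,
                      boldAffectedGroups = c("cerebrum", "hippocampus",
                                             "cerebellum", "thalamus"),
                      boldMotionAmp = 0.3, boldWmCsfAmp = 0.3,
                      boldDriftAmp = 0.2, boldNOutliers = 3L,
                      boldSpikeAmp = 3,
                      boldBaseline = 1000, boldAmplitude = 10,
                      boldVoxelNoiseSd = 2,
                      postScanTimesS = seq(0, 1800, by = 450),
                      tissueBaseline = 100, bloodBaseline = 100,
                      contrastStep = 200,
                      cbv0Range = c(0.02, 0.06),
                      leakSlope = 3e-5,
                      qcbvNoiseSd = 0.002,
                      nLeakRegionsImpacted = 12L,
                      nLeakSubjectsImpacted = 4L,
                      nLeakRegionsSham = 2L,
                      nLeakSubjectsSham = 2L,
                      bValue = 1000,
                      dwiS0 = 500, dwiNoiseSd = 5,
                      dwiNoiseModel = c("gaussian", "rician"),
                      dwiShifts = list(
                        "basal ganglia" = c(md = 0.90, fa = 1.15),
                        "thalamus"      = c(md = 0.92, fa = 1.00),
                        "cerebellum"    = c(md = 1.00, fa = 0.90)),
                      dwiAreaJitter = 0.03, dwiSubjectJitter = 0.02,
                      arenaWidthCm = 60.9, arenaHeightCm = 69.2,
                      borderCm = 8,
                      trackDurationS = 300, trackHz = 10,
                      trackStepSd = 2, trackCenterBias = 0.02,
                      norExpectedIr = 0.65, norContactMeanS = 40) {
  dwiNoiseModel <- match.arg(dwiNoiseModel)
  cfg <- as.list(environment())
  stopUnless(cfg$nSham >= 1 && cfg$nImpacted >= 1, "group sizes must be >= 1")
  stopUnless(length(grid) == 3 && all(grid >= 2), "grid must be 3 dims >= 2")
  stopUnless(cfg$nRegions >= 6,
             "need >= 6 regions (5 region groups plus a blood label)")
  stopUnless(cfg$boldAttenuation > 0 && cfg$boldAttenuation <= 1,
             "boldAttenuation must be in (0, 1]")
  stopUnless(cfg$boldBaseCor >= 0 && cfg$boldBaseCor < 1,
             "boldBaseCor must be in [0, 1)")
  stopUnless(length(cfg$postScanTimesS) >= 3,
             "need >= 3 post-contrast scan times")
  stopUnless(all(diff(cfg$postScanTimesS) > 0),
             "postScanTimesS must be strictly increasing")
  stopUnless(cfg$qcbvNoiseSd >= 0 && cfg$dwiNoiseSd >= 0 &&
             cfg$boldVoxelNoiseSd >= 0, "noise SDs must be >= 0")
  stopUnless(cfg$bValue > 0, "bValue must be positive")
  stopUnless(all(cfg$cbv0Range > 0) && all(cfg$cbv0Range < 1),
             "cbv0Range must lie in (0, 1)")
  maxCbv <- cfg$cbv0Range[2] + cfg$leakSlope * max(cfg$postScanTimesS)
  stopUnless(maxCbv < 1,
             "unphysical: CBV0 + beta * t_max reaches 1")
  stopUnless(cfg$leakSlope >= 0, "leakSlope must be >= 0")
  stopUnless(cfg$borderCm >= 0 &&
             cfg$borderCm < min(cfg$arenaWidthCm, cfg$arenaHeightCm) / 2,
             "border must be < half the smallest arena dimension")
  class(cfg) <- "simConfig"
  cfg
}

# canonical area counts per region group (Fig.-style: thalamus 18,
# hippocampus 9, basal ganglia 10, cerebellum 19) plus a cerebrum rest
canonicalGroupWeights <- c("thalamus" = 18, "hippocampus" = 9,
                           "basal ganglia" = 10, "cerebellum" = 19,
                           "cerebrum" = 3)

# allocate nBrain areas over the canonical groups, >= 1 each,
# largest-remainder apportionment
allocateGroups <- function(nBrain) {
  w <- canonicalGroupWeights
  raw <- w / sum(w) * nBrain
  n <- floor(raw)
  n[n < 1] <- 1
  while (sum(n) > nBrain) {          # shrink overflow from the largest
    i <- which.max(n)
    n[i] <- n[i] - 1L
  }
  rem <- raw - floor(raw)
  while (sum(n) < nBrain) {
    i <- which.max(rem)
    n[i] <- n[i] + 1L
    rem[i] <- -1
  }
  n
}
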