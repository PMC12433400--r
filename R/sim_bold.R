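#' Simulate a resting-state BOLD study with modular connectivity
#'
#' Region signals follow a shared-factor model: within module m with
#' within-module correlation c, region r has
#' \deqn{s_r(t) = \sqrt{c}\, f_m(t) + \sqrt{1-c}\, e_r(t)}
#' with i.i.d. standard-normal factor and noise series, so every pair of
#' regions in the module has population correlation exactly c and pairs in
#' different modules are uncorrelated. Modules are the atlas region groups
#' (the blood label forms its own, uncoupled module). Impacted subjects
#' have c multiplied by \code{boldAttenuation} in the configured affected
#' groups. Each subject's c is additionally jittered on the Fisher-Z scale
#' (SD \code{boldSubjectSdZ}) to emulate between-animal variability.
#'
#' Known nuisance structure is mixed into every region signal: six
#' random-walk motion regressors, white-matter and CSF mean signals, a
#' linear low-frequency drift, and spike artifacts at flagged outlier
#' volumes; the mixing coefficients are recorded so nuisance regression can
#' be validated exactly.
#'
#' @param config \code{\link{simConfig}}.
#' @param atlas \code{\link{makePhantomAtlas}} output (or compatible).
#' @param voxelwise if TRUE also render per-subject 4D
#'   \linkS4class{VolumeSeries} (baseline + amplitude x signal + voxel
#'   noise) on the atlas grid.
#' @return list with \code{subjects} (per subject: \code{id}, \code{group},
#'   \code{signals} R x T matrix with region labels as rownames,
#'   \code{nuisance} list(motion T x 6, wm, csf, outliers logical),
#'   optionally \code{volume}), \code{groundTruth} (region module map and
#'   per-subject per-module true correlation), and the \code{atlas}.
#' @export
simulateBoldStudy <- function(config, atlas, voxelwise = FALSE) {
  set.seed(subSeed(config$seed, 101L))
  reg <- atlas@regions
  modules <- reg$region_group
  names(modules) <- reg$label_id
  T <- config$nVolumes
  R <- nrow(reg)
  ids <- c(paste0("sham_", seq_len(config$nSham)),
           paste0("impacted_", seq_len(config$nImpacted)))
  grp <- c(rep("sham", config$nSham), rep("impacted", config$nImpacted))
  modNames <- unique(modules)
  truthRows <- list()
  subjects <- vector("list", length(ids))
  names(subjects) <- ids
  for (s in seq_along(ids)) {
    cMod <- setNames(rep(config$boldBaseCor, length(modNames)), modNames)
    if (grp[s] == "impacted")
      cMod[names(cMod) %in% config$boldAffectedGroups] <-
        cMod[names(cMod) %in% config$boldAffectedGroups] *
          config$boldAttenuation
    cMod["blood"] <- 0
    # between-subject variability on the Fisher-Z scale
    jit <- stats::rnorm(length(cMod), 0, config$boldSubjectSdZ)
    cSub <- tanh(pmax(0, atanh(pmin(cMod, 0.99)) + jit))
    cSub <- pmin(cSub, 0.95)
    names(cSub) <- names(cMod)
    cSub[cMod == 0] <- 0
    fac <- matrix(stats::rnorm(length(modNames) * T), length(modNames), T,
                  dimnames = list(modNames, NULL))
    eps <- matrix(stats::rnorm(R * T), R, T)
    cR <- cSub[modules]
    signals <- sqrt(cR) * fac[modules, , drop = FALSE] +
               sqrt(1 - cR) * eps
    rownames(signals) <- reg$label_id
    # nuisance structure with known coefficients
    motion <- apply(matrix(stats::rnorm(T * 6), T, 6), 2,
                    function(x) { w <- cumsum(x); (w - mean(w)) / stats::sd(w) })
    wm <- stats::rnorm(T); csf <- stats::rnorm(T)
    drift <- seq_len(T); drift <- (drift - mean(drift)) / stats::sd(drift)
    outliers <- rep(FALSE, T)
    if (config$boldNOutliers > 0)
      outliers[sample(T, config$boldNOutliers)] <- TRUE
    coefM <- matrix(stats::rnorm(R * 6, 0, config$boldMotionAmp), R, 6)
    coefW <- stats::rnorm(R, 0, config$boldWmCsfAmp)
    coefC <- stats::rnorm(R, 0, config$boldWmCsfAmp)
    coefD <- stats::rnorm(R, 0, config$boldDriftAmp)
    signals <- signals + coefM %*% t(motion) +
      outer(coefW, wm) + outer(coefC, csf) + outer(coefD, drift)
    if (any(outliers))
      signals[, outliers] <- signals[, outliers] +
        matrix(stats::rnorm(R * sum(outliers), 0, config$boldSpikeAmp),
               R, sum(outliers))
    subj <- list(id = ids[s], group = grp[s], signals = signals,
                 nuisance = list(motion = motion, wm = wm, csf = csf,
                                 outliers = outliers))
    if (voxelwise) {
      vol <- array(0, dim = c(dim(atlas@labels), T))
      lab <- as.vector(atlas@labels)
      flat <- matrix(config$boldBaseline +
                       stats::rnorm(length(lab) * T, 0,
                                    config$boldVoxelNoiseSd),
                     length(lab), T)
      for (r in seq_len(R)) {
        vox <- which(lab == reg$label_id[r])
        if (length(vox))
          flat[vox, ] <- flat[vox, ] +
            rep(config$boldAmplitude * signals[r, ], each = length(vox))
      }
      vol[] <- flat
      subj$volume <- VolumeSeries(vol, voxelSizeMm = atlas@voxelSizeMm,
                                  timesS = (seq_len(T) - 1) * config$trS)
    }
    subjects[[s]] <- subj
    truthRows[[s]] <- data.frame(subject_id = ids[s], group = grp[s],
                                 module = names(cSub), true_cor = cSub,
                                 row.names = NULL)
  }
  list(subjects = subjects,
       groundTruth = list(moduleOf = modules,
                          corBySubject = do.call(rbind, truthRows)),
       atlas = atlas, config = config)
}
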