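#' Simulate a pre/post-contrast QUTE-CE permeability study
#'
#' Each subject gets one pre-contrast scan and K >= 3 post-contrast scans.
#' The blood-pool region's intensity is raised by \code{contrastStep}
#' after the bolus; a tissue voxel in region r of subject s at
#' post-contrast time t has noiseless intensity
#' \deqn{I'(t) = I + (CBV_0 + \beta t)\,(I'_B - I_B)}
#' so the regional qCBV recovered by \code{\link{computeQcbv}} is exactly
#' \eqn{CBV_0 + \beta t}. The leak slope \eqn{\beta} is positive only in
#' the configured leak template: \code{nLeakRegionsImpacted} regions in
#' \code{nLeakSubjectsImpacted} impacted subjects and
#' \code{nLeakRegionsSham} regions in \code{nLeakSubjectsSham} shams.
#' Gaussian voxel noise has SD \code{qcbvNoiseSd * contrastStep} (i.e. the
#' stated noise SD on the per-voxel qCBV scale).
#'
#' @param config \code{\link{simConfig}}.
#' @param atlas LabelAtlas with a blood label.
#' @param voxelwise if TRUE render full \linkS4class{VolumeSeries}
#'   (pre 3D + post 4D) per subject; if FALSE return regional mean
#'   intensities directly (same model, noise scaled by 1/sqrt(n_voxels)).
#' @return list with \code{regional} (data.frame subject_id, group,
#'   label_id, region_group, time_s, pre_mean, post_mean, n_voxels),
#'   \code{subjects} (when voxelwise: per subject pre/post VolumeSeries),
#'   \code{groundTruth} (subject x region cbv0, beta, leak flag), and the
#'   scan times.
#' @export
simulateQuteceStudy <- function(config, atlas, voxelwise = FALSE) {
  set.seed(subSeed(config$seed, 202L))
  reg <- atlas@regions
  blood <- bloodLabel(atlas)
  tiss <- reg$label_id[reg$label_id != blood]
  times <- config$postScanTimesS
  K <- length(times)
  ids <- c(paste0("sham_", seq_len(config$nSham)),
           paste0("impacted_", seq_len(config$nImpacted)))
  grp <- c(rep("sham", config$nSham), rep("impacted", config$nImpacted))
  stopUnless(config$nLeakSubjectsImpacted <= config$nImpacted &&
             config$nLeakSubjectsSham <= config$nSham,
             "leak-subject counts exceed group sizes")
  stopUnless(config$nLeakRegionsImpacted <= length(tiss) &&
             config$nLeakRegionsSham <= length(tiss),
             "leak-region counts exceed available regions")
  cbv0 <- stats::runif(length(tiss), config$cbv0Range[1], config$cbv0Range[2])
  names(cbv0) <- tiss
  leakRegImp <- sample(tiss, config$nLeakRegionsImpacted)
  leakRegSham <- sample(tiss, config$nLeakRegionsSham)
  leakSubj <- c(sample(ids[grp == "sham"], config$nLeakSubjectsSham),
                sample(ids[grp == "impacted"], config$nLeakSubjectsImpacted))
  sdI <- config$qcbvNoiseSd * config$contrastStep
  lab <- as.vector(atlas@labels)
  nVox <- table(factor(lab[lab != 0], levels = reg$label_id))
  truth <- list(); regional <- list(); subjects <- list()
  for (s in seq_along(ids)) {
    id <- ids[s]
    beta <- setNames(rep(0, length(tiss)), tiss)
    if (id %in% leakSubj) {
      lr <- if (grp[s] == "sham") leakRegSham else leakRegImp
      beta[as.character(lr)] <- config$leakSlope
    }
    truth[[s]] <- data.frame(subject_id = id, group = grp[s],
                             label_id = as.integer(tiss),
                             cbv0 = unname(cbv0), beta = unname(beta),
                             leak = unname(beta > 0))
    # noiseless regional means
    preMean <- setNames(rep(config$tissueBaseline, nrow(reg)), reg$label_id)
    preMean[as.character(blood)] <- config$bloodBaseline
    postMean <- matrix(rep(preMean, K), nrow(reg), K,
                       dimnames = list(reg$label_id, NULL))
    postMean[as.character(blood), ] <-
      config$bloodBaseline + config$contrastStep
    postMean[as.character(tiss), ] <-
      config$tissueBaseline +
      outer(cbv0, rep(1, K)) * config$contrastStep +
      outer(beta, times) * config$contrastStep
    if (voxelwise) {
      d <- dim(atlas@labels)
      preArr <- array(stats::rnorm(prod(d), 0, sdI), dim = d)
      preFlat <- as.vector(preArr)
      postFlat <- matrix(stats::rnorm(prod(d) * K, 0, sdI), prod(d), K)
      for (r in seq_len(nrow(reg))) {
        vox <- which(lab == reg$label_id[r])
        preFlat[vox] <- preFlat[vox] + preMean[r]
        postFlat[vox, ] <- postFlat[vox, ] +
          rep(postMean[r, ], each = length(vox))
      }
      preArr[] <- preFlat
      postArr <- array(postFlat, dim = c(d, K))
      subjects[[id]] <- list(
        id = id, group = grp[s],
        pre = VolumeSeries(preArr, voxelSizeMm = atlas@voxelSizeMm),
        post = VolumeSeries(postArr, voxelSizeMm = atlas@voxelSizeMm,
                            timesS = times))
      pre_m <- extractRegionSeries(subjects[[id]]$pre, atlas, id)
      post_m <- extractRegionSeries(subjects[[id]]$post, atlas, id)
      regional[[s]] <- data.frame(
        subject_id = id, group = grp[s],
        label_id = post_m$label_id,
        region_group = post_m$region_group,
        time_s = post_m$time_s,
        pre_mean = pre_m$mean_intensity[match(post_m$label_id,
                                              pre_m$label_id)],
        post_mean = post_m$mean_intensity,
        n_voxels = post_m$n_voxels)
    } else {
      n <- as.numeric(nVox[as.character(reg$label_id)])
      regional[[s]] <- data.frame(
        subject_id = id, group = grp[s],
        label_id = rep(reg$label_id, each = K),
        region_group = rep(reg$region_group, each = K),
        time_s = rep(times, nrow(reg)),
        pre_mean = rep(preMean + stats::rnorm(nrow(reg), 0, sdI / sqrt(n)),
                       each = K),
        post_mean = as.vector(t(postMean +
          matrix(stats::rnorm(nrow(reg) * K, 0,
                              rep(sdI / sqrt(n), K)), nrow(reg), K))),
        n_voxels = rep(as.integer(n), each = K))
    }
  }
  list(regional = do.call(rbind, regional),
       subjects = if (voxelwise) subjects else NULL,
       groundTruth = do.call(rbind, truth),
       scanTimesS = times, atlas = atlas, config = config)
}
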