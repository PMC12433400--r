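#' Fixed 10-direction single-shell gradient table
#'
#' Ten non-collinear unit gradient directions obtained by electrostatic
#' repulsion on the sphere (antipodally symmetric energy), preceded by one
#' b = 0 measurement. Returned as a \code{BTable} list with \code{bvals}
#' (s/mm2) and \code{bvecs} (3 x N).
#'
#' @param bValue shell b value, default 1000 s/mm2.
#' @return list(bvals, bvecs) of class \code{BTable}.
#' @export
defaultBTable <- function(bValue = 1000) {
  dirs <- matrix(c(
     0.954033, -0.042490,  0.296674,
    -0.505665, -0.383310, -0.772901,
     0.137304, -0.817923, -0.558703,
     0.388545, -0.474367,  0.789942,
    -0.468201, -0.550652,  0.691064,
     0.720419,  0.690892,  0.060538,
     0.857731, -0.127017, -0.498160,
     0.205463, -0.129239, -0.970094,
     0.691285, -0.722367,  0.017621,
     0.019834,  0.976450, -0.214830), ncol = 3, byrow = TRUE)
  dirs <- dirs / sqrt(rowSums(dirs^2))
  bt <- list(bvals = c(0, rep(bValue, 10)),
             bvecs = cbind(0, t(dirs)))
  class(bt) <- "BTable"
  bt
}

#' Validate a b-table
#' @param bt list(bvals, bvecs).
#' @return bt, invisibly; errors on non-unit directions or b <= 0 shells.
#' @export
validateBTable <- function(bt) {
  stopUnless(length(bt$bvals) == ncol(bt$bvecs),
             "bvals/bvecs length mismatch")
  dwi <- bt$bvals > 0
  stopUnless(any(bt$bvals == 0), "b-table needs a b = 0 entry")
  nrm <- sqrt(colSums(bt$bvecs[, dwi, drop = FALSE]^2))
  stopUnless(all(abs(nrm - 1) < 1e-6),
             "gradient directions must be unit-norm")
  invisible(bt)
}

#' Write FSL-style bval/bvec text files
#' @param bt BTable; @param prefix path prefix (writes prefix.bval/.bvec).
#' @return prefix, invisibly.
#' @export
writeBTable <- function(bt, prefix) {
  writeLines(paste(format(bt$bvals, trim = TRUE), collapse = " "),
             paste0(prefix, ".bval"))
  writeLines(apply(format(bt$bvecs, digits = 8, trim = TRUE), 1,
                   paste, collapse = " "),
             paste0(prefix, ".bvec"))
  invisible(prefix)
}

#' Read FSL-style bval/bvec text files
#' @param prefix path prefix.
#' @return BTable list.
#' @export
readBTable <- function(prefix) {
  bvals <- scan(paste0(prefix, ".bval"), quiet = TRUE)
  bvecs <- do.call(rbind,
                   lapply(readLines(paste0(prefix, ".bvec")),
                          function(l) scan(text = l, quiet = TRUE)))
  bt <- list(bvals = bvals, bvecs = bvecs)
  class(bt) <- "BTable"
  validateBTable(bt)
  bt
}

# axially symmetric eigenvalues with given mean diffusivity and FA
evalsFromMdFa <- function(md, fa) {
  stopUnless(all(fa >= 0 & fa < 1), "FA must lie in [0, 1)")
  f <- fa * sqrt(3 / (9 - 6 * fa^2))
  cbind(md * (1 + 2 * f), md * (1 - f), md * (1 - f))
}

# deterministic-ish random rotation matrix from the current RNG stream
randomRotation <- function() {
  q <- qr.Q(qr(matrix(stats::rnorm(9), 3, 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

# baseline per-region-group diffusion parameters (mm2/s, unitless FA)
dwiGroupBaselines <- function() {
  data.frame(
    region_group = c("thalamus", "hippocampus", "basal ganglia",
                     "cerebellum", "cerebrum", "blood"),
    md = c(0.75e-3, 0.80e-3, 0.75e-3, 0.70e-3, 0.75e-3, 2.5e-3),
    fa = c(0.30, 0.20, 0.25, 0.35, 0.25, 0.05))
}

#' Simulate a single-shell DWI study
#'
#' Per voxel the noiseless signal follows the mono-exponential tensor
#' model \eqn{S(g) = S_0 \exp(-b\, g^T D g)}. Each atlas area gets an
#' axially symmetric tensor built from its region group's baseline MD/FA
#' (log-normal area-level jitter, fixed random orientation), with
#' additional subject-level jitter; impacted subjects apply the configured
#' multiplicative MD/FA group shifts. Noise is Gaussian by default or
#' Rician (\code{dwiNoiseModel = "rician"}).
#'
#' @param config \code{\link{simConfig}}.
#' @param atlas LabelAtlas.
#' @return list with \code{subjects} (per subject: id, group,
#'   \code{volume} 4D VolumeSeries of 11 volumes), \code{btable},
#'   \code{groundTruth} (subject x area true MD/FA), and the atlas.
#' @export
simulateDwiStudy <- function(config, atlas) {
  set.seed(subSeed(config$seed, 303L))
  bt <- defaultBTable(config$bValue)
  validateBTable(bt)
  reg <- atlas@regions
  base <- dwiGroupBaselines()
  gi <- match(reg$region_group, base$region_group)
  stopUnless(!anyNA(gi), "atlas has region groups without DWI baselines")
  nA <- nrow(reg)
  # fixed area-level parameters
  mdA <- base$md[gi] * exp(stats::rnorm(nA, 0, config$dwiAreaJitter))
  faA <- pmin(0.95, base$fa[gi] * exp(stats::rnorm(nA, 0, config$dwiAreaJitter)))
  rotA <- lapply(seq_len(nA), function(i) randomRotation())
  ids <- c(paste0("sham_", seq_len(config$nSham)),
           paste0("impacted_", seq_len(config$nImpacted)))
  grp <- c(rep("sham", config$nSham), rep("impacted", config$nImpacted))
  lab <- as.vector(atlas@labels)
  d <- dim(atlas@labels)
  nMeas <- length(bt$bvals)
  bg <- t(bt$bvecs) * sqrt(bt$bvals)   # rows: sqrt(b) * g
  subjects <- list(); truth <- list()
  for (s in seq_along(ids)) {
    mdS <- mdA * exp(stats::rnorm(nA, 0, config$dwiSubjectJitter))
    faS <- pmin(0.95, faA * exp(stats::rnorm(nA, 0, config$dwiSubjectJitter)))
    if (grp[s] == "impacted") {
      for (g in names(config$dwiShifts)) {
        sel <- reg$region_group == g
        mdS[sel] <- mdS[sel] * config$dwiShifts[[g]]["md"]
        faS[sel] <- pmin(0.95, faS[sel] * config$dwiShifts[[g]]["fa"])
      }
    }
    ev <- evalsFromMdFa(mdS, faS)
    flat <- matrix(0, prod(d), nMeas)
    for (r in seq_len(nA)) {
      D <- rotA[[r]] %*% diag(ev[r, ]) %*% t(rotA[[r]])
      adcMeas <- rowSums((bg %*% D) * bg)          # b * g' D g per volume
      sig <- config$dwiS0 * exp(-adcMeas)
      vox <- which(lab == reg$label_id[r])
      flat[vox, ] <- rep(sig, each = length(vox))
    }
    inBrain <- lab != 0
    if (config$dwiNoiseSd > 0) {
      if (config$dwiNoiseModel == "gaussian") {
        flat[inBrain, ] <- flat[inBrain, ] +
          stats::rnorm(sum(inBrain) * nMeas, 0, config$dwiNoiseSd)
      } else {
        n1 <- stats::rnorm(sum(inBrain) * nMeas, 0, config$dwiNoiseSd)
        n2 <- stats::rnorm(sum(inBrain) * nMeas, 0, config$dwiNoiseSd)
        flat[inBrain, ] <- sqrt((flat[inBrain, ] + n1)^2 + n2^2)
      }
    }
    subjects[[ids[s]]] <- list(
      id = ids[s], group = grp[s],
      volume = VolumeSeries(array(flat, dim = c(d, nMeas)),
                            voxelSizeMm = atlas@voxelSizeMm,
                            timesS = seq_len(nMeas) - 1))
    truth[[s]] <- data.frame(subject_id = ids[s], group = grp[s],
                             label_id = reg$label_id,
                             region_group = reg$region_group,
                             md_true = mdS, fa_true = faS)
  }
  list(subjects = subjects, btable = bt,
       groundTruth = do.call(rbind, truth), atlas = atlas, config = config)
}
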