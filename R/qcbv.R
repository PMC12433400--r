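#' Quantitative cerebral blood volume from pre/post-contrast intensities
#'
#' qCBV = (I'_M - I_M) / (I'_B - I_B): the tissue intensity change after
#' an intravascular contrast bolus, normalized by the blood-pool intensity
#' change. Applied voxelwise for maps or regionwise for timecourses. The
#' ratio is invariant to a common additive offset or multiplicative
#' rescaling of all intensities.
#'
#' @param postM,preM tissue intensity after/before contrast (vectorized).
#' @param postB,preB blood-pool intensity after/before contrast.
#' @param context label used in the error message (subject/scan).
#' @return qCBV fraction(s).
#' @export
computeQcbv <- function(postM, preM, postB, preB, context = "scan") {
  if (any(postB - preB <= 0))
    stop("blood intensity change is not positive for ", context,
         call. = FALSE)
  (postM - preM) / (postB - preB)
}

#' Permeability slope of a regional CBV-vs-time curve
#'
#' Ordinary least-squares slope of qCBV on scan time, with a one-tailed
#' p-value for H1: slope > 0 from the t distribution with n - 2 degrees
#' of freedom. A perfectly constant curve yields slope 0 and p = 0.5; a
#' noiseless increasing line yields p = 0.
#'
#' @param timesS scan times (s), >= 3 and strictly increasing.
#' @param qcbv qCBV values, one per scan.
#' @return list(slope, p, t, n).
#' @export
permeabilitySlope <- function(timesS, qcbv) {
  n <- length(timesS)
  stopUnless(n >= 3 && length(qcbv) == n, "need >= 3 scans")
  stopUnless(stats::var(timesS) > 0, "zero time variance")
  tc <- timesS - mean(timesS)
  slope <- sum(tc * qcbv) / sum(tc^2)
  res <- qcbv - mean(qcbv) - slope * tc
  s2 <- sum(res^2) / (n - 2)
  se <- sqrt(s2 / sum(tc^2))
  tstat <- if (se == 0) { if (slope == 0) 0 else sign(slope) * Inf }
           else slope / se
  p <- stats::pt(tstat, df = n - 2, lower.tail = FALSE)
  list(slope = slope, p = p, t = tstat, n = n)
}

#' Two-stage Benjamini-Krieger-Yekutieli adaptive FDR decisions
#'
#' Stage 1 runs Benjamini-Hochberg at q' = q / (1 + q); the number of
#' stage-1 rejections r1 estimates the null count m0 = m - r1. If r1 = 0
#' nothing is rejected; if r1 = m everything is; otherwise stage 2 reruns
#' BH at level q' * m / m0 and returns its decisions.
#'
#' @param pvalues p-values in [0, 1].
#' @param q target false discovery rate (default 0.1).
#' @return logical rejection vector.
#' @export
fdrBkyTwoStage <- function(pvalues, q = 0.1) {
  stopUnless(length(pvalues) >= 1 && all(pvalues >= 0 & pvalues <= 1),
             "p-values must lie in [0, 1]")
  m <- length(pvalues)
  qp <- q / (1 + q)
  bh <- function(p, level) {
    o <- order(p)
    thr <- level * seq_len(m) / m
    k <- which(p[o] <= thr)
    rej <- rep(FALSE, m)
    if (length(k)) rej[o[seq_len(max(k))]] <- TRUE
    rej
  }
  r1 <- sum(bh(pvalues, qp))
  if (r1 == 0) return(rep(FALSE, m))
  if (r1 == m) return(rep(TRUE, m))
  bh(pvalues, qp * m / (m - r1))
}

#' Per-subject BBB-permeability screen over all regions
#'
#' For every subject, fits the permeability slope in each (non-blood)
#' region, computes one-tailed p-values, and calls a region permeable when
#' its raw p < \code{pRaw} AND it survives the two-stage BKY correction at
#' rate \code{q} within that subject's family of regions. Subjects missing
#' part of the common region set are skipped with a warning.
#'
#' @param qcbvTc data.frame with columns subject_id, group, label_id,
#'   time_s, qcbv (as from \code{\link{qcbvRegionalTimecourse}}).
#' @param q FDR rate (default 0.1).
#' @param pRaw raw p-value gate (default 0.05).
#' @return list with \code{calls} (subject x region slope, p, decision)
#'   and \code{summary} (per group: subjects with >= 1 call, mean regions
#'   called per subject).
#' @export
subjectPermeabilityScreen <- function(qcbvTc, q = 0.1, pRaw = 0.05) {
  regions <- sort(unique(qcbvTc$label_id))
  calls <- list()
  for (id in unique(qcbvTc$subject_id)) {
    sub <- qcbvTc[qcbvTc$subject_id == id, ]
    if (!setequal(unique(sub$label_id), regions)) {
      warning("subject ", id, " skipped: incomplete region set",
              call. = FALSE)
      next
    }
    res <- lapply(split(sub, sub$label_id), function(d) {
      d <- d[order(d$time_s), ]
      fit <- permeabilitySlope(d$time_s, d$qcbv)
      data.frame(subject_id = id, group = d$group[1],
                 label_id = d$label_id[1], slope = fit$slope,
                 p = fit$p, n = fit$n)
    })
    res <- do.call(rbind, res)
    res$rejected <- fdrBkyTwoStage(res$p, q) & res$p < pRaw
    calls[[id]] <- res
  }
  calls <- do.call(rbind, calls)
  rownames(calls) <- NULL
  perSubj <- stats::aggregate(calls$rejected,
                              by = list(subject_id = calls$subject_id,
                                        group = calls$group),
                              FUN = sum)
  names(perSubj)[3] <- "n_regions_called"
  summary <- do.call(rbind, lapply(split(perSubj, perSubj$group),
    function(d) data.frame(group = d$group[1],
                           n_subjects = nrow(d),
                           subjects_with_call = sum(d$n_regions_called > 0),
                           mean_regions_called = mean(d$n_regions_called))))
  rownames(summary) <- NULL
  list(calls = calls, summary = summary, perSubject = perSubj)
}

#' Regional qCBV timecourses from a simulated or extracted study table
#'
#' Converts per-region pre/post mean intensities into qCBV values using
#' the blood-pool region of the same subject and scan as the reference.
#'
#' @param regional data.frame subject_id, group, label_id, time_s,
#'   pre_mean, post_mean (as from \code{\link{simulateQuteceStudy}} or
#'   built from \code{\link{extractRegionSeries}} outputs).
#' @param blood label id of the blood-pool region.
#' @return data.frame subject_id, group, label_id, time_s, qcbv (blood
#'   region excluded).
#' @export
qcbvRegionalTimecourse <- function(regional, blood) {
  out <- list()
  for (id in unique(regional$subject_id)) {
    sub <- regional[regional$subject_id == id, ]
    bl <- sub[sub$label_id == blood, ]
    stopUnless(nrow(bl) > 0, paste("no blood region for subject", id))
    bl <- bl[order(bl$time_s), ]
    ts <- sub[sub$label_id != blood, ]
    bi <- match(ts$time_s, bl$time_s)
    qc <- computeQcbv(ts$post_mean, ts$pre_mean,
                      bl$post_mean[bi], bl$pre_mean[bi],
                      context = paste("subject", id))
    out[[id]] <- data.frame(subject_id = id, group = ts$group,
                            label_id = ts$label_id, time_s = ts$time_s,
                            qcbv = qc)
  }
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Group comparison of regional mean qCBV
#'
#' Two-sample pooled-variance t-test per region on subject-level mean
#' qCBV, with two-stage BKY decisions across regions (raw p < pRaw AND
#' BKY survival at rate q). Regions with zero variance in both groups get
#' p = 1 with a warning.
#'
#' @param meanQcbv data.frame subject_id, group, label_id, mean_qcbv.
#' @param q,pRaw decision thresholds as in
#'   \code{\link{subjectPermeabilityScreen}}.
#' @return data.frame per region: t, p, rejected.
#' @export
groupCbvTTests <- function(meanQcbv, q = 0.1, pRaw = 0.05) {
  gs <- sort(unique(meanQcbv$group))
  stopUnless(length(gs) == 2, "need exactly 2 groups")
  res <- lapply(split(meanQcbv, meanQcbv$label_id), function(d) {
    x <- d$mean_qcbv[d$group == gs[1]]
    y <- d$mean_qcbv[d$group == gs[2]]
    stopUnless(length(x) >= 2 && length(y) >= 2,
               "need >= 2 subjects per group")
    if (stats::var(x) == 0 && stats::var(y) == 0) {
      warning("zero variance in both groups for region ", d$label_id[1],
              call. = FALSE)
      return(data.frame(label_id = d$label_id[1], t = 0, p = 1))
    }
    tt <- stats::t.test(x, y, var.equal = TRUE)
    data.frame(label_id = d$label_id[1], t = unname(tt$statistic),
               p = tt$p.value)
  })
  res <- do.call(rbind, res)
  res$rejected <- fdrBkyTwoStage(res$p, q) & res$p < pRaw
  rownames(res) <- NULL
  res
}
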