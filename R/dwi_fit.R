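#' Log-linear least-squares diffusion-tensor fit
#'
#' Solves, per voxel, \eqn{\ln S = \ln S_0 - b\, g^T D g} by ordinary
#' least squares on the 7-parameter design (intercept plus the six unique
#' tensor elements). The estimator is deterministic; voxels with any
#' nonpositive signal are flagged and excluded from the fit (their rows
#' are NA), and voxels whose fitted tensor has a negative eigenvalue are
#' flagged for the QC mask (eigenvalues are clamped to zero downstream
#' when computing FA).
#'
#' @param signals numeric vector (one voxel) or voxels x measurements
#'   matrix of DWI signals, measurement order matching the b-table.
#' @param btable b-table list(bvals, bvecs) as from
#'   \code{\link{defaultBTable}}; needs >= 7 measurements including a b0.
#' @param excludeVolumes optional integer indices of acquisition volumes
#'   to drop (e.g. motion-artifact screening) before fitting.
#' @return A \linkS4class{TensorFit}.
#' @export
fitTensorLogLinear <- function(signals, btable, excludeVolumes = NULL) {
  if (is.vector(signals)) signals <- matrix(signals, nrow = 1)
  validateBTable(btable)
  keep <- setdiff(seq_along(btable$bvals), excludeVolumes)
  stopUnless(length(keep) >= 7 && any(btable$bvals[keep] == 0),
             "need >= 7 retained measurements including a b0")
  signals <- signals[, keep, drop = FALSE]
  b <- btable$bvals[keep]
  g <- t(btable$bvecs[, keep, drop = FALSE])
  X <- cbind(1, -b * g[, 1]^2, -b * g[, 2]^2, -b * g[, 3]^2,
             -2 * b * g[, 1] * g[, 2], -2 * b * g[, 1] * g[, 3],
             -2 * b * g[, 2] * g[, 3])
  qrX <- qr(X)
  stopUnless(qrX$rank == 7L, "rank-deficient gradient design")
  nVox <- nrow(signals)
  bad <- apply(signals, 1, function(s) any(!is.finite(s) | s <= 0))
  tensors <- matrix(NA_real_, nVox, 6)
  colnames(tensors) <- c("dxx", "dyy", "dzz", "dxy", "dxz", "dyz")
  s0 <- rep(NA_real_, nVox)
  evals <- matrix(NA_real_, nVox, 3)
  flag <- rep(1L, nVox)
  if (any(!bad)) {
    coef <- qr.coef(qrX, t(log(signals[!bad, , drop = FALSE])))
    s0[!bad] <- exp(coef[1, ])
    tensors[!bad, ] <- t(coef[2:7, , drop = FALSE])
    ok <- which(!bad)
    for (i in ok) {
      d6 <- tensors[i, ]
      D <- matrix(c(d6[1], d6[4], d6[5],
                    d6[4], d6[2], d6[6],
                    d6[5], d6[6], d6[3]), 3, 3)
      ev <- eigen(D, symmetric = TRUE, only.values = TRUE)$values
      evals[i, ] <- sort(ev, decreasing = TRUE)
      flag[i] <- if (any(ev < 0)) 2L else 0L
    }
  }
  new("TensorFit", tensors = tensors, s0 = s0, evals = evals, flag = flag)
}

#' ADC and FA scalar maps from a tensor fit
#'
#' ADC is the mean diffusivity \eqn{(\lambda_1+\lambda_2+\lambda_3)/3}.
#' FA is \eqn{\sqrt{3/2}\,\sqrt{\sum_i(\lambda_i-\bar\lambda)^2} /
#' \sqrt{\sum_i \lambda_i^2}} computed on eigenvalues clamped at zero, so
#' FA lies in [0, 1]; an all-zero tensor is assigned FA = 0. Excluded
#' voxels stay NA.
#'
#' @param fit \linkS4class{TensorFit}.
#' @return list with numeric vectors \code{adc} (mm2/s) and \code{fa},
#'   one entry per fitted voxel.
#' @export
scalarMaps <- function(fit) {
  ev <- fit@evals
  adc <- rowMeans(ev)
  evc <- pmax(ev, 0)
  mn <- rowMeans(evc)
  num <- rowSums((evc - mn)^2)
  den <- rowSums(evc^2)
  fa <- sqrt(3 / 2) * sqrt(num / den)
  fa[is.finite(den) & den == 0] <- 0
  list(adc = adc, fa = fa)
}

#' Per-area mean ADC/FA for one subject
#'
#' Averages the scalar maps over each atlas area's voxels; areas absent
#' from the label map are omitted with a warning. Flag-excluded voxels do
#' not contribute.
#'
#' @param maps list(adc, fa) of voxelwise values laid out on the atlas
#'   grid (as from fitting every grid voxel in array order).
#' @param atlas LabelAtlas.
#' @param subjectId,group carried into the output table.
#' @return data.frame subject_id, group, label_id, area_name,
#'   region_group, mean_adc, mean_fa, n_voxels.
#' @export
aggregateRegionalScalars <- function(maps, atlas, subjectId = "subj",
                                     group = NA_character_) {
  lab <- as.vector(atlas@labels)
  stopUnless(length(maps$adc) == length(lab),
             "map and atlas grids differ")
  reg <- atlas@regions
  idx <- split(seq_along(lab), lab)
  idx[["0"]] <- NULL
  missing <- setdiff(reg$label_id, as.integer(names(idx)))
  if (length(missing))
    warning("areas with zero voxels omitted: ",
            paste(missing, collapse = ", "), call. = FALSE)
  rows <- lapply(names(idx), function(l) {
    v <- idx[[l]]
    data.frame(label_id = as.integer(l),
               mean_adc = mean(maps$adc[v], na.rm = TRUE),
               mean_fa = mean(maps$fa[v], na.rm = TRUE),
               n_voxels = length(v))
  })
  out <- do.call(rbind, rows)
  m <- match(out$label_id, reg$label_id)
  data.frame(subject_id = subjectId, group = group,
             label_id = out$label_id,
             area_name = reg$area_name[m],
             region_group = reg$region_group[m],
             mean_adc = out$mean_adc, mean_fa = out$mean_fa,
             n_voxels = out$n_voxels)
}

#' Nonparametric regional group comparison (Kruskal-Wallis + Wilcoxon)
#'
#' Follows the dot-plot granularity of regional analyses: within each
#' region group, the observations are area-level values, with subjects
#' first averaged within experimental group per area. A Kruskal-Wallis
#' test (critical value 0.05) across groups is followed, where it
#' rejects, by post hoc pairwise Wilcoxon rank-sum tests; the direction
#' of the effect (sign of impacted minus sham median) is reported.
#'
#' @param tbl data.frame with columns \code{group}, \code{label_id},
#'   \code{region_group}, and the value column.
#' @param value name of the value column (e.g. "mean_adc").
#' @param alpha Kruskal-Wallis critical value gating the post hoc test.
#' @return data.frame per region group: n_areas, kw_h, kw_p, wilcox_w,
#'   wilcox_p (NA unless KW rejects), direction, flagged.
#' @export
compareRegionsNonparametric <- function(tbl, value = "mean_adc",
                                        alpha = 0.05) {
  stopUnless(length(unique(tbl$group)) >= 2, "need >= 2 groups")
  # subject-averaged area values per group
  agg <- stats::aggregate(tbl[[value]],
                          by = list(group = tbl$group,
                                    label_id = tbl$label_id,
                                    region_group = tbl$region_group),
                          FUN = mean)
  names(agg)[4] <- "value"
  out <- list()
  for (rg in unique(agg$region_group)) {
    sub <- agg[agg$region_group == rg, ]
    counts <- table(sub$group)
    if (any(counts < 2)) {
      warning("region group '", rg,
              "' skipped: fewer than 2 areas in a group", call. = FALSE)
      next
    }
    kw <- stats::kruskal.test(sub$value, factor(sub$group))
    wp <- NA_real_; ww <- NA_real_
    if (is.finite(kw$p.value) && kw$p.value < alpha) {
      gs <- sort(unique(sub$group))
      wt <- stats::wilcox.test(sub$value[sub$group == gs[1]],
                               sub$value[sub$group == gs[2]],
                               exact = TRUE)
      wp <- wt$p.value; ww <- unname(wt$statistic)
    }
    med <- tapply(sub$value, sub$group, stats::median)
    dir <- if ("impacted" %in% names(med) && "sham" %in% names(med))
      sign(med[["impacted"]] - med[["sham"]]) else NA_real_
    out[[rg]] <- data.frame(
      region_group = rg, n_areas = nrow(sub) / length(counts),
      kw_h = unname(kw$statistic), kw_p = kw$p.value,
      wilcox_w = ww, wilcox_p = wp,
      direction = dir,
      flagged = is.finite(kw$p.value) && kw$p.value < alpha)
  }
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
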