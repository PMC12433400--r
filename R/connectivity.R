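#' Nuisance regression and band-pass filtering of region signals
#'
#' Per region: OLS residual after regressing on the nuisance design
#' (intercept + six motion parameters + one indicator column per flagged
#' outlier volume + white-matter + CSF means), then a zero-phase
#' forward-backward Butterworth band-pass (2nd order each way, 4th order
#' effective) over \code{band} Hz. Output signals are zero-mean.
#'
#' @param signals R x T matrix of region signals (regions in rows).
#' @param nuisance list with any of \code{motion} (T x 6), \code{wm},
#'   \code{csf} (length-T), \code{outliers} (logical length-T); NULL for
#'   filtering only.
#' @param band band-pass edges in Hz, default c(0.01, 0.1).
#' @param trS repetition time in seconds.
#' @return R x T matrix of residual, filtered, zero-mean signals.
#' @export
preprocessTimeseries <- function(signals, nuisance = NULL,
                                 band = c(0.01, 0.1), trS = 1) {
  T <- ncol(signals)
  nyq <- 0.5 / trS
  stopUnless(band[1] > 0 && band[2] > band[1] && band[2] < nyq,
             "band must lie inside (0, Nyquist)")
  X <- matrix(1, T, 1)
  if (!is.null(nuisance)) {
    if (!is.null(nuisance$motion)) {
      stopUnless(nrow(nuisance$motion) == T, "motion length mismatch")
      X <- cbind(X, nuisance$motion)
    }
    if (!is.null(nuisance$outliers) && any(nuisance$outliers)) {
      spikes <- which(nuisance$outliers)
      ind <- matrix(0, T, length(spikes))
      ind[cbind(spikes, seq_along(spikes))] <- 1
      X <- cbind(X, ind)
    }
    if (!is.null(nuisance$wm)) X <- cbind(X, nuisance$wm)
    if (!is.null(nuisance$csf)) X <- cbind(X, nuisance$csf)
  }
  stopUnless(qr(X)$rank < T, "nuisance design rank must be < T")
  res <- t(stats::lm.fit(X, t(signals))$residuals)
  bf <- signal::butter(2, band / nyq, type = "pass")
  filt <- t(apply(res, 1, function(x) signal::filtfilt(bf, x)))
  sweep(filt, 1, rowMeans(filt))
}

#' Pearson correlation and Fisher-Z connectivity matrices
#'
#' r_ij is the Pearson correlation of the residual signals of regions i
#' and j; z = atanh(r) with r clipped to +/-(1 - 1e-7) so self- and
#' perfect correlations stay finite. Constant signals get a zero row/column
#' with a warning. An N-node network has N(N-1)/2 unique pairs.
#'
#' @param signals R x T matrix with region labels as rownames.
#' @return list(r, z) of \linkS4class{ConnectivityMatrix}, plus
#'   \code{nPairs}.
#' @export
pearsonFisherMatrix <- function(signals) {
  stopUnless(ncol(signals) >= 3, "need >= 3 time points")
  sds <- apply(signals, 1, stats::sd)
  const <- sds == 0
  if (any(const))
    warning(sum(const), " constant signal(s); rows set to 0",
            call. = FALSE)
  r <- suppressWarnings(stats::cor(t(signals)))
  if (any(const)) { r[const, ] <- 0; r[, const] <- 0 }
  diag(r) <- 0
  labs <- rownames(signals) %||% as.character(seq_len(nrow(signals)))
  rc <- pmin(pmax(r, -(1 - 1e-7)), 1 - 1e-7)
  z <- atanh(rc)
  diag(z) <- 0
  n <- nrow(r)
  list(r = ConnectivityMatrix(r, "r", labs),
       z = ConnectivityMatrix(z, "z", labs),
       nPairs = n * (n - 1) / 2)
}

#' Group-level edge Z matrix from subject Fisher-Z matrices
#'
#' Per edge, a one-sample t-test of the subjects' z values against zero;
#' the t statistic is converted to a signed standard-normal deviate
#' through the t cumulative distribution (computed in log space so far
#' tails survive). Zero-variance edges get a +/- \code{sentinel} value and
#' are flagged.
#'
#' @param zmats list of >= 2 \linkS4class{ConnectivityMatrix} (kind "z").
#' @param sentinel value assigned to zero-variance edges (default 10).
#' @return \linkS4class{ConnectivityMatrix} of kind "group_z" with a
#'   logical \code{flagged} attribute matrix.
#' @export
groupEdgeZ <- function(zmats, sentinel = 10) {
  stopUnless(length(zmats) >= 2, "need >= 2 subjects")
  labs <- nodeLabels(zmats[[1]])
  arr <- vapply(zmats, cmValues, cmValues(zmats[[1]]))
  n <- length(zmats)
  mu <- apply(arr, c(1, 2), mean)
  sdv <- apply(arr, c(1, 2), stats::sd)
  tmat <- matrix(0, nrow(mu), ncol(mu))
  nz <- sdv > 0
  tmat[nz] <- mu[nz] / (sdv[nz] / sqrt(n))
  gz <- tToNormal(tmat, df = n - 1)
  flagged <- !nz & mu != 0
  gz[flagged] <- sign(mu[flagged]) * sentinel
  gz[!nz & mu == 0] <- 0
  diag(gz) <- 0
  out <- ConnectivityMatrix(gz, "group_z", labs)
  attr(out, "flagged") <- flagged
  out
}

# signed t -> standard normal deviate via matched tail probabilities,
# log-space for numerical stability in far tails
tToNormal <- function(tmat, df) {
  out <- tmat
  pos <- tmat >= 0
  out[pos] <- -stats::qnorm(stats::pt(tmat[pos], df, lower.tail = FALSE,
                                      log.p = TRUE), log.p = TRUE)
  out[!pos] <- stats::qnorm(stats::pt(tmat[!pos], df, log.p = TRUE),
                            log.p = TRUE)
  out
}

#' Threshold and binarize a connectivity matrix
#'
#' Keeps edges with |Z| >= \code{zthr} (ties kept), zero diagonal.
#'
#' @param mat \linkS4class{ConnectivityMatrix}.
#' @param zthr threshold, default 2.3.
#' @return binary \linkS4class{ConnectivityMatrix}.
#' @export
thresholdBinarize <- function(mat, zthr = 2.3) {
  a <- (abs(cmValues(mat)) >= zthr) * 1
  diag(a) <- 0
  ConnectivityMatrix(a, "binary", nodeLabels(mat))
}

#' Graph metrics of a binarized connectivity network
#'
#' Degree centrality C_D(j) = sum_i A_ij (row sums of the adjacency
#' matrix), average degree 2E/N, graph density 2E/(N(N-1)), and average
#' path length: the mean shortest-path length over all connected ordered
#' node pairs (disconnected pairs are excluded and counted). An edgeless
#' graph has undefined path length (NA).
#'
#' @param bin binary \linkS4class{ConnectivityMatrix}.
#' @return list: degree (named), nNodes, nEdges, averageDegree, density,
#'   averagePathLength, nDisconnectedPairs.
#' @export
networkMetrics <- function(bin) {
  stopUnless(cmKind(bin) == "binary", "need a binary matrix")
  a <- cmValues(bin)
  deg <- rowSums(a)
  names(deg) <- nodeLabels(bin)
  n <- nrow(a)
  e <- sum(a) / 2
  g <- igraph::graph_from_adjacency_matrix(a, mode = "undirected")
  dmat <- igraph::distances(g)
  off <- dmat[upper.tri(dmat)]
  finite <- is.finite(off)
  apl <- if (e == 0 || !any(finite)) NA_real_ else mean(off[finite])
  stopifnot(sum(deg) == 2 * e)    # handshake identity, checked every run
  list(degree = deg, nNodes = n, nEdges = e,
       averageDegree = 2 * e / n,
       density = if (n > 1) 2 * e / (n * (n - 1)) else NA_real_,
       averagePathLength = apl,
       nDisconnectedPairs = 2 * sum(!finite))
}

#' Module assignment by k-nearest-neighbor graph components
#'
#' Builds a symmetric (union) k-nearest-neighbor graph on nodes using
#' the normalized distance 1 - |Z| / max|Z| and returns its connected
#' components as modules. Deterministic given the matrix.
#'
#' @param groupZ \linkS4class{ConnectivityMatrix} (group_z).
#' @param k neighbors per node, 0 < k < N.
#' @return integer module assignment named by node label.
#' @export
clusterNodes <- function(groupZ, k) {
  v <- abs(cmValues(groupZ))
  n <- nrow(v)
  stopUnless(k > 0 && k < n, "k must satisfy 0 < k < N")
  dist <- 1 - v / max(v)
  diag(dist) <- Inf
  adj <- matrix(0, n, n)
  for (i in seq_len(n)) {
    nn <- order(dist[i, ])[seq_len(k)]
    adj[i, nn] <- 1
  }
  adj <- pmax(adj, t(adj))            # union kNN graph
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  comp <- igraph::components(g)$membership
  names(comp) <- nodeLabels(groupZ)
  comp
}

#' Region-wise paired comparison of node degrees between two networks
#'
#' Pairs node degrees of two group networks by node label. Within each
#' region group with >= \code{minAreas} areas, a Shapiro-Wilk test on the
#' paired differences gates the test: paired t when normality is not
#' rejected (p > 0.05), Wilcoxon signed-rank otherwise. Differences that
#' are all equal and nonzero have zero variance (the paired t is
#' undefined) and fall back to the exact sign-based floor of the
#' signed-rank distribution, two-sided p = 2 * (1/2)^n. Identical
#' networks are reported unflagged with p = 1. A global comparison over
#' all nodes uses the same gate.
#'
#' @param metrics1,metrics2 \code{\link{networkMetrics}} results for the
#'   two networks (e.g. sham and impacted).
#' @param regions atlas region table mapping node label_id to
#'   region_group.
#' @param alpha significance gate for flagging, default 0.05.
#' @param minAreas minimum areas per region group, default 3.
#' @return list(byRegion = data.frame, global = data.frame); direction is
#'   the sign of mean(network2 - network1) degree.
#' @export
compareDegreeByRegion <- function(metrics1, metrics2, regions,
                                  alpha = 0.05, minAreas = 3) {
  d1 <- metrics1$degree; d2 <- metrics2$degree
  stopUnless(setequal(names(d1), names(d2)), "node sets differ")
  d2 <- d2[names(d1)]
  rg <- regions$region_group[match(as.integer(names(d1)),
                                   regions$label_id)]
  pairedTest <- function(diff) {
    n <- length(diff)
    if (all(diff == 0))
      return(data.frame(test = "none", p = 1, sw_p = NA_real_,
                        direction = 0))
    if (stats::sd(diff) == 0)          # degenerate: exact sign floor
      return(data.frame(test = "signed_rank_floor",
                        p = min(1, 2 * 0.5^n), sw_p = NA_real_,
                        direction = sign(mean(diff))))
    sw <- tryCatch(stats::shapiro.test(diff)$p.value,
                   error = function(e) 0)
    if (is.na(sw)) sw <- 0
    if (sw > 0.05) {
      tt <- stats::t.test(diff, mu = 0)
      data.frame(test = "paired_t", p = tt$p.value, sw_p = sw,
                 direction = sign(mean(diff)))
    } else {
      wt <- suppressWarnings(stats::wilcox.test(diff, mu = 0))
      data.frame(test = "wilcoxon_signed_rank", p = wt$p.value,
                 sw_p = sw, direction = sign(mean(diff)))
    }
  }
  rows <- list()
  for (g in unique(rg[!is.na(rg)])) {
    sel <- which(rg == g)
    if (length(sel) < minAreas) next
    res <- pairedTest(d2[sel] - d1[sel])
    rows[[g]] <- cbind(data.frame(region_group = g,
                                  n_areas = length(sel),
                                  mean_degree_1 = mean(d1[sel]),
                                  mean_degree_2 = mean(d2[sel])),
                       res, flagged = res$p < alpha)
  }
  byRegion <- do.call(rbind, rows)
  rownames(byRegion) <- NULL
  gres <- pairedTest(d2 - d1)
  global <- cbind(data.frame(n_nodes = length(d1),
                             mean_degree_1 = mean(d1),
                             mean_degree_2 = mean(d2)),
                  gres, flagged = gres$p < alpha)
  list(byRegion = byRegion, global = global)
}

#' Full per-group connectivity pipeline on a simulated BOLD study
#'
#' Preprocess every subject's region signals, form r/z matrices, build
#' each group's group-Z matrix, binarize at \code{zthr}, and compute
#' network metrics.
#'
#' @param study \code{\link{simulateBoldStudy}} output.
#' @param band,zthr pipeline parameters (defaults 0.01-0.1 Hz, 2.3).
#' @param preprocess set FALSE to correlate raw generator signals.
#' @return list per group: groupZ, binary, metrics; plus subject z list.
#' @export
connectivityByGroup <- function(study, band = c(0.01, 0.1), zthr = 2.3,
                                preprocess = TRUE) {
  cfg <- study$config
  zByGroup <- list(sham = list(), impacted = list())
  for (s in study$subjects) {
    sig <- if (preprocess)
      preprocessTimeseries(s$signals, s$nuisance, band, cfg$trS)
    else s$signals
    pf <- pearsonFisherMatrix(sig)
    zByGroup[[s$group]][[s$id]] <- pf$z
  }
  out <- list()
  for (g in names(zByGroup)) {
    gz <- groupEdgeZ(zByGroup[[g]])
    bin <- thresholdBinarize(gz, zthr)
    out[[g]] <- list(groupZ = gz, binary = bin,
                     metrics = networkMetrics(bin))
  }
  out$subjectZ <- zByGroup
  out
}
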