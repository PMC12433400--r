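#' Simulate open-field tracks and novel-object contact times
#'
#' Open-field tracks are reflected random walks inside the arena with a
#' configurable pull toward the arena centre (\code{trackCenterBias});
#' both groups share the same movement statistics, matching the null
#' group-difference scenario for locomotion. Novel-object-recognition
#' (NOR) contact times are drawn so both groups have the same expected
#' investigation ratio \code{norExpectedIr} > 0.5: total contact time is
#' gamma-distributed with mean \code{norContactMeanS} and the novel-object
#' share is Beta-distributed around the expected IR.
#'
#' @param config \code{\link{simConfig}}.
#' @return list with \code{tracks} (named list of data.frames
#'   \code{t, x, y} in s/cm, one per subject, with a \code{group}
#'   attribute), \code{nor} (data.frame subject_id, group, novel_s,
#'   familiar_s), and \code{arena} (list width, height, border in cm).
#' @export
simulateBehaviorTracks <- function(config) {
  set.seed(subSeed(config$seed, 404L))
  stopUnless(config$trackDurationS > 0 && config$norContactMeanS > 0,
             "durations must be positive")
  W <- config$arenaWidthCm; H <- config$arenaHeightCm
  dt <- 1 / config$trackHz
  n <- round(config$trackDurationS * config$trackHz)
  ids <- c(paste0("sham_", seq_len(config$nSham)),
           paste0("impacted_", seq_len(config$nImpacted)))
  grp <- c(rep("sham", config$nSham), rep("impacted", config$nImpacted))
  reflect <- function(p, lo, hi) {     # fold back across the walls
    span <- hi - lo
    p <- (p - lo) %% (2 * span)
    lo + ifelse(p > span, 2 * span - p, p)
  }
  tracks <- vector("list", length(ids))
  names(tracks) <- ids
  for (s in seq_along(ids)) {
    x <- numeric(n); y <- numeric(n)
    x[1] <- W / 2; y[1] <- H / 2
    sx <- stats::rnorm(n - 1, 0, config$trackStepSd)
    sy <- stats::rnorm(n - 1, 0, config$trackStepSd)
    for (i in 2:n) {
      x[i] <- reflect(x[i - 1] + sx[i - 1] +
                        config$trackCenterBias * (W / 2 - x[i - 1]), 0, W)
      y[i] <- reflect(y[i - 1] + sy[i - 1] +
                        config$trackCenterBias * (H / 2 - y[i - 1]), 0, H)
    }
    tr <- data.frame(t = (seq_len(n) - 1) * dt, x = x, y = y)
    attr(tr, "group") <- grp[s]
    tracks[[s]] <- tr
  }
  total <- stats::rgamma(length(ids), shape = 16,
                         rate = 16 / config$norContactMeanS)
  k <- 30                               # Beta concentration of the IR draw
  irDraw <- stats::rbeta(length(ids), config$norExpectedIr * k,
                         (1 - config$norExpectedIr) * k)
  nor <- data.frame(subject_id = ids, group = grp,
                    novel_s = total * irDraw,
                    familiar_s = total * (1 - irDraw))
  list(tracks = tracks, nor = nor,
       arena = list(width = W, height = H, border = config$borderCm))
}
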