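#' Open-field zone metrics from a position track
#'
#' The peripheral zone is the \code{border}-cm band inside the arena
#' walls; the central zone is the remaining interior rectangle. Distance
#' traveled is the sum of Euclidean steps. Zone times use sample-and-hold
#' membership: each sample contributes the interval to the next sample,
#' so center time + periphery time equals the track duration exactly.
#' The true geometric central-area fraction is reported (it depends on
#' the arena, and is only 40% for particular arena sizes).
#'
#' @param track data.frame with columns t (s), x, y (cm), time-ordered.
#' @param arena list(width, height, border) in cm.
#' @return list: distanceCm, centerTimeS, peripheryTimeS, durationS,
#'   centralAreaFraction.
#' @export
openFieldMetrics <- function(track, arena) {
  stopUnless(all(diff(track$t) > 0), "track times must be increasing")
  b <- arena$border
  stopUnless(b >= 0 && b < min(arena$width, arena$height) / 2,
             "border must be < half the smallest arena dimension")
  bad <- which(track$x < 0 | track$x > arena$width |
               track$y < 0 | track$y > arena$height)
  if (length(bad))
    stop("track points outside the arena at indices: ",
         paste(utils::head(bad, 10), collapse = ", "), call. = FALSE)
  dist <- sum(sqrt(diff(track$x)^2 + diff(track$y)^2))
  inCenter <- track$x >= b & track$x <= arena$width - b &
              track$y >= b & track$y <= arena$height - b
  dt <- diff(track$t)                     # sample-and-hold: last sample
  centerT <- sum(dt[inCenter[-length(inCenter)]])
  duration <- track$t[length(track$t)] - track$t[1]
  list(distanceCm = dist,
       centerTimeS = centerT,
       peripheryTimeS = duration - centerT,
       durationS = duration,
       centralAreaFraction = (arena$width - 2 * b) *
         (arena$height - 2 * b) / (arena$width * arena$height))
}

#' Novel-object investigation ratios and chance-level test
#'
#' IR = novel contact time / total contact time, in [0, 1] and invariant
#' to rescaling of the contact durations. Subjects with zero total
#' contact are excluded with a warning. Each group's IRs are tested
#' against the chance level 0.5 with a single-sample two-tailed t-test;
#' a between-group two-sample t-test is also reported.
#'
#' @param contacts data.frame subject_id, group, novel_s, familiar_s.
#' @return list: perSubject (with ir column), byGroup (mean IR, t, p vs
#'   0.5 per group), betweenGroups (two-sample t, p).
#' @export
norInvestigation <- function(contacts) {
  total <- contacts$novel_s + contacts$familiar_s
  drop <- total <= 0
  if (any(drop)) {
    warning("excluding subjects with zero contact: ",
            paste(contacts$subject_id[drop], collapse = ", "),
            call. = FALSE)
    contacts <- contacts[!drop, ]
    total <- total[!drop]
  }
  stopUnless(nrow(contacts) > 0, "no subjects with positive contact time")
  contacts$ir <- contacts$novel_s / total
  byGroup <- do.call(rbind, lapply(split(contacts, contacts$group),
    function(d) {
      if (nrow(d) >= 2 && stats::sd(d$ir) > 0) {
        tt <- stats::t.test(d$ir, mu = 0.5)
        data.frame(group = d$group[1], n = nrow(d), mean_ir = mean(d$ir),
                   t = unname(tt$statistic), p = tt$p.value)
      } else data.frame(group = d$group[1], n = nrow(d),
                        mean_ir = mean(d$ir), t = NA_real_, p = NA_real_)
    }))
  rownames(byGroup) <- NULL
  between <- NULL
  gs <- unique(contacts$group)
  if (length(gs) == 2) {
    tt <- stats::t.test(contacts$ir[contacts$group == gs[1]],
                        contacts$ir[contacts$group == gs[2]],
                        var.equal = TRUE)
    between <- data.frame(t = unname(tt$statistic), p = tt$p.value)
  }
  list(perSubject = contacts, byGroup = byGroup, betweenGroups = between)
}
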