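#' Build a deterministic blocky phantom atlas
#'
#' Partitions the grid into contiguous cubic blocks and assigns the first
#' \code{nRegions} blocks as labelled areas; leftover blocks and the
#' integer-division remainder stay background. Areas are apportioned over
#' the canonical region groups (thalamus, hippocampus, basal ganglia,
#' cerebellum, cerebrum) and the last label is the dedicated blood-pool
#' reference region. Hemisphere is assigned from the block centre's
#' position relative to the mid-sagittal plane.
#'
#' The construction is fully deterministic: the same config always yields
#' the identical label map and table.
#'
#' @param config a \code{\link{simConfig}}.
#' @return A \linkS4class{LabelAtlas}.
#' @export
makePhantomAtlas <- function(config) {
  grid <- as.integer(config$grid)
  nReg <- as.integer(config$nRegions)
  stopUnless(nReg <= prod(grid),
             "grid too small for the requested number of regions")
  nb <- ceiling(nReg^(1 / 3))
  stopUnless(all(grid >= nb),
             "grid too small: fewer voxels per axis than blocks needed")
  bs <- grid %/% nb                       # block edge in voxels
  labels <- array(0L, dim = grid)
  groups <- allocateGroups(nReg - 1L)
  groupOf <- c(rep(names(groups), groups), "blood")
  hemi <- character(nReg)
  mid <- (grid[1] + 1) / 2
  lab <- 0L
  for (k in seq_len(nb)) for (j in seq_len(nb)) for (i in seq_len(nb)) {
    if (lab >= nReg) break
    lab <- lab + 1L
    xs <- ((i - 1L) * bs[1] + 1L):(i * bs[1])
    ys <- ((j - 1L) * bs[2] + 1L):(j * bs[2])
    zs <- ((k - 1L) * bs[3] + 1L):(k * bs[3])
    labels[xs, ys, zs] <- lab
    cx <- mean(xs)
    hemi[lab] <- if (abs(cx - mid) < 0.75) "midline"
                 else if (cx < mid) "left" else "right"
  }
  grp <- groupOf[seq_len(nReg)]
  cnt <- stats::ave(seq_len(nReg), grp, FUN = seq_along)
  regions <- data.frame(
    label_id = seq_len(nReg),
    area_name = paste0(gsub(" ", "_", grp), "_", cnt, "_",
                       substr(hemi, 1, 1)),
    hemisphere = hemi,
    region_group = grp,
    stringsAsFactors = FALSE)
  LabelAtlas(labels, regions, voxelSizeMm = config$voxelSizeMm)
}

#' Blood-pool label of an atlas
#'
#' @param atlas LabelAtlas.
#' @return Integer label id of the blood region.
#' @export
bloodLabel <- function(atlas) {
  id <- atlas@regions$label_id[atlas@regions$region_group == "blood"]
  stopUnless(length(id) == 1L, "atlas must have exactly one blood label")
  id
}
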