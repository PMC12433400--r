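#' Read a NIfTI volume or label atlas
#'
#' Reads a NIfTI-1 file as a \linkS4class{VolumeSeries}, or — for
#' \code{kind = "atlas"} — as a \linkS4class{LabelAtlas} whose region table
#' is taken from the sibling CSV \code{<path minus .nii[.gz]>_regions.csv}
#' (columns \code{label_id,area_name,hemisphere,region_group}).
#'
#' Voxel geometry comes from the header pixdims; for 4D images acquisition
#' times are \code{0, TR, 2 TR, ...} with TR read from the 4th pixdim.
#' Atlas voxels must be integer-valued; any voxel label absent from the
#' region table is an error reporting the offending ids.
#'
#' @param path NIfTI file (.nii or .nii.gz).
#' @param kind "image" or "atlas".
#' @param regionsCsv region-table path override (atlas only).
#' @return A \code{VolumeSeries} or \code{LabelAtlas}.
#' @export
readLabeledVolume <- function(path, kind = c("image", "atlas"),
                              regionsCsv = NULL) {
  kind <- match.arg(kind)
  stopUnless(file.exists(path), paste("file not found:", path))
  img <- RNifti::readNifti(path)
  hdr <- RNifti::niftiHeader(img)
  arr <- array(as.numeric(img), dim = dim(img))
  vox <- abs(hdr$pixdim[2:4])
  vox[vox <= 0] <- 1
  if (kind == "image") {
    nd <- length(dim(arr))
    times <- numeric()
    if (nd == 4L) {
      tr <- hdr$pixdim[5]
      if (!is.finite(tr) || tr <= 0) tr <- 1
      times <- (seq_len(dim(arr)[4]) - 1) * tr
    }
    return(VolumeSeries(arr, voxelSizeMm = vox, timesS = times))
  }
  if (is.null(regionsCsv))
    regionsCsv <- paste0(sub("\\.nii(\\.gz)?$", "", path), "_regions.csv")
  stopUnless(file.exists(regionsCsv),
             paste("region table not found:", regionsCsv))
  if (max(abs(arr - round(arr))) > 0)
    stop("atlas volume contains non-integer values", call. = FALSE)
  regions <- utils::read.csv(regionsCsv, stringsAsFactors = FALSE)
  voxLabels <- unique(as.vector(arr))
  voxLabels <- voxLabels[voxLabels != 0]
  orphan <- setdiff(voxLabels, regions$label_id)
  if (length(orphan))
    stop("atlas labels missing from region table: {",
         paste(sort(orphan), collapse = ", "), "}", call. = FALSE)
  LabelAtlas(round(arr), regions, voxelSizeMm = vox)
}

#' Write a VolumeSeries or LabelAtlas to NIfTI
#'
#' Atlases additionally write their region table to
#' \code{<path minus .nii[.gz]>_regions.csv}.
#'
#' @param x VolumeSeries or LabelAtlas.
#' @param path output .nii or .nii.gz path.
#' @return \code{path}, invisibly.
#' @export
writeLabeledVolume <- function(x, path) {
  dir.create(dirname(path), showWarnings = FALSE, recursive = TRUE)
  if (is(x, "LabelAtlas")) {
    img <- RNifti::asNifti(x@labels)
    RNifti::pixdim(img) <- x@voxelSizeMm
    RNifti::writeNifti(img, path)
    utils::write.csv(x@regions,
                     paste0(sub("\\.nii(\\.gz)?$", "", path), "_regions.csv"),
                     row.names = FALSE)
  } else if (is(x, "VolumeSeries")) {
    nd <- length(dim(x@data))
    tr <- if (nd == 4L && length(x@timesS) > 1) diff(x@timesS)[1] else 1
    img <- RNifti::asNifti(x@data)
    RNifti::pixdim(img) <- if (nd == 4L) c(x@voxelSizeMm, tr) else x@voxelSizeMm
    RNifti::writeNifti(img, path)
  } else stop("unsupported object")
  invisible(path)
}

#' Extract per-region intensity timecourses
#'
#' For every atlas region present in the label map, computes the mean and
#' median intensity over that region's voxels at each time point. The
#' mean-minus-median difference is retained as a skewness diagnostic of the
#' regional intensity distribution. Regions in the table with zero voxels
#' in the map are dropped with a warning.
#'
#' @param image VolumeSeries (3D or 4D), same grid as the atlas.
#' @param atlas LabelAtlas.
#' @param subjectId subject identifier carried into the output.
#' @return data.frame with one row per region x time point:
#'   \code{subject_id, label_id, area_name, region_group, time_s,
#'   mean_intensity, median_intensity, skew_diag, n_voxels}.
#' @export
extractRegionSeries <- function(image, atlas, subjectId = "subj") {
  d <- dim(image@data)
  stopUnless(all(d[1:3] == dim(atlas@labels)),
             "image and atlas grids differ")
  nT <- if (length(d) == 4L) d[4] else 1L
  times <- if (length(image@timesS)) image@timesS else rep(0, nT)
  if (length(times) != nT) times <- seq_len(nT) - 1
  lab <- as.vector(atlas@labels)
  mat <- matrix(image@data, nrow = prod(d[1:3]), ncol = nT)
  idx <- split(seq_along(lab), lab)
  idx[["0"]] <- NULL
  present <- as.integer(names(idx))
  missing <- setdiff(atlas@regions$label_id, present)
  if (length(missing))
    warning("regions with zero voxels omitted: ",
            paste(missing, collapse = ", "), call. = FALSE)
  rows <- lapply(names(idx), function(l) {
    sub <- mat[idx[[l]], , drop = FALSE]
    m <- colMeans(sub)
    md <- apply(sub, 2, stats::median)
    data.frame(subject_id = subjectId, label_id = as.integer(l),
               time_s = times, mean_intensity = m, median_intensity = md,
               skew_diag = m - md, n_voxels = nrow(sub))
  })
  out <- do.call(rbind, rows)
  info <- atlas@regions[match(out$label_id, atlas@regions$label_id),
                        c("area_name", "region_group")]
  out <- cbind(out[, c("subject_id", "label_id")], info,
               out[, c("time_s", "mean_intensity", "median_intensity",
                       "skew_diag", "n_voxels")])
  rownames(out) <- NULL
  out
}

#' Correct B1 coil-sensitivity variation along the slice (Z) axis
#'
#' Slice-wise division by the mean-normalized phantom intensity profile:
#' slice z is divided by \code{profile[z] / mean(profile)}, the minimal
#' multiplicative-gain model for a phantom-measured sensitivity profile.
#' A flat profile therefore leaves the image unchanged.
#'
#' @param image VolumeSeries.
#' @param phantomProfile positive numeric vector, one entry per Z slice.
#' @return Corrected VolumeSeries.
#' @export
b1ZAxisCorrect <- function(image, phantomProfile) {
  d <- dim(image@data)
  nz <- d[3]
  stopUnless(length(phantomProfile) == nz,
             "profile length must equal number of Z slices")
  stopUnless(all(phantomProfile > 0), "profile entries must be positive")
  gain <- phantomProfile / mean(phantomProfile)
  out <- image@data
  if (length(d) == 3L) {
    for (z in seq_len(nz)) out[, , z] <- out[, , z] / gain[z]
  } else {
    for (z in seq_len(nz)) out[, , z, ] <- out[, , z, ] / gain[z]
  }
  VolumeSeries(out, voxelSizeMm = image@voxelSizeMm, timesS = image@timesS)
}
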