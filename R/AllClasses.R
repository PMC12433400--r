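#' @import methods
NULL

#' Labelled brain atlas
#'
#' A 3D integer label map together with its region table. Label 0 is
#' background and never appears in the table. The region table partitions
#' brain areas into anatomical region groups (thalamus, hippocampus,
#' basal ganglia, cerebellum, cerebrum) plus a dedicated blood-pool label
#' used as the intravascular reference for quantitative CBV.
#'
#' @slot labels 3D integer array; 0 = background.
#' @slot regions data.frame with columns \code{label_id}, \code{area_name},
#'   \code{hemisphere} (one of left/right/midline), \code{region_group}.
#' @slot voxelSizeMm numeric(3), voxel edge lengths in mm.
#'
#' @export
setClass("LabelAtlas",
  representation(labels = "array", regions = "data.frame",
                 voxelSizeMm = "numeric"),
  validity = function(object) {
    msg <- character()
    if (length(dim(object@labels)) != 3L)
      msg <- c(msg, "labels must be a 3D array")
    if (!is.integer(object@labels) &&
        any(object@labels != round(object@labels)))
      msg <- c(msg, "labels must be integer-valued")
    req <- c("label_id", "area_name", "hemisphere", "region_group")
    if (!all(req %in% names(object@regions)))
      msg <- c(msg, paste("region table needs columns:",
                          paste(req, collapse = ", ")))
    else {
      ids <- object@regions$label_id
      if (anyDuplicated(ids)) msg <- c(msg, "duplicate label ids in table")
      if (any(ids <= 0)) msg <- c(msg, "label ids must be positive")
      if (!all(object@regions$hemisphere %in%
               c("left", "right", "midline")))
        msg <- c(msg, "hemisphere must be left/right/midline")
      vox <- unique(as.vector(object@labels))
      vox <- vox[vox != 0]
      orphan <- setdiff(vox, ids)
      if (length(orphan))
        msg <- c(msg, paste("voxel labels missing from region table:",
                            paste(sort(orphan), collapse = ", ")))
    }
    if (length(object@voxelSizeMm) != 3L || any(object@voxelSizeMm <= 0))
      msg <- c(msg, "voxelSizeMm must be 3 positive values")
    if (length(msg)) msg else TRUE
  })

#' 3D or 4D image volume with voxel geometry
#'
#' @slot data numeric array with 3 (single volume) or 4 (volume series)
#'   dimensions.
#' @slot voxelSizeMm numeric(3), mm.
#' @slot timesS acquisition times in seconds, one per 4th-dimension volume
#'   (length 0 for a single 3D volume); strictly increasing.
#'
#' @export
setClass("VolumeSeries",
  representation(data = "array", voxelSizeMm = "numeric",
                 timesS = "numeric"),
  validity = function(object) {
    msg <- character()
    nd <- length(dim(object@data))
    if (!nd %in% c(3L, 4L)) msg <- c(msg, "data must be 3D or 4D")
    if (!all(is.finite(object@data))) msg <- c(msg, "data must be finite")
    if (length(object@voxelSizeMm) != 3L || any(object@voxelSizeMm <= 0))
      msg <- c(msg, "voxelSizeMm must be 3 positive values")
    nt <- length(object@timesS)
    if (nd == 4L && nt > 0 && nt != dim(object@data)[4])
      msg <- c(msg, "timesS length must match 4th dimension")
    if (nt > 1 && any(diff(object@timesS) <= 0))
      msg <- c(msg, "timesS must be strictly increasing")
    if (length(msg)) msg else TRUE
  })

#' Region-to-region connectivity matrix
#'
#' Symmetric node-by-node matrix of Pearson r, Fisher Z, group-level Z, or
#' binarized adjacency values, carrying node labels (atlas area ids).
#'
#' @slot values symmetric numeric matrix; diagonal fixed at 0.
#' @slot kind one of \code{"r"}, \code{"z"}, \code{"group_z"},
#'   \code{"binary"}.
#' @slot nodeLabels character or integer node labels (length = nrow).
#'
#' @export
setClass("ConnectivityMatrix",
  representation(values = "matrix", kind = "character",
                 nodeLabels = "character"),
  validity = function(object) {
    msg <- character()
    v <- object@values
    if (nrow(v) != ncol(v)) msg <- c(msg, "matrix must be square")
    else {
      if (max(abs(v - t(v))) > 1e-12) msg <- c(msg, "matrix must be symmetric")
      if (any(diag(v) != 0)) msg <- c(msg, "diagonal must be zero")
    }
    if (!object@kind %in% c("r", "z", "group_z", "binary"))
      msg <- c(msg, "kind must be r/z/group_z/binary")
    if (object@kind == "r" && any(abs(v) > 1 + 1e-12))
      msg <- c(msg, "r values must lie in [-1, 1]")
    if (object@kind == "binary" && !all(v %in% c(0, 1)))
      msg <- c(msg, "binary matrix must be 0/1")
    if (length(object@nodeLabels) != nrow(v))
      msg <- c(msg, "nodeLabels length must equal matrix dimension")
    if (length(msg)) msg else TRUE
  })

#' Voxelwise diffusion-tensor fit
#'
#' Result of the log-linear tensor fit: per-voxel unique tensor elements
#' (order xx, yy, zz, xy, xz, yz), S0 estimate, sorted eigenvalues, and a
#' QC flag marking voxels excluded (nonpositive signal) or with negative
#' eigenvalues.
#'
#' @slot tensors n-voxel x 6 matrix (mm^2/s).
#' @slot s0 numeric vector of fitted b=0 signals.
#' @slot evals n-voxel x 3 matrix, eigenvalues sorted decreasing.
#' @slot flag integer vector: 0 ok, 1 excluded (bad signal), 2 negative
#'   eigenvalue (clamped for FA).
#'
#' @export
setClass("TensorFit",
  representation(tensors = "matrix", s0 = "numeric", evals = "matrix",
                 flag = "integer"),
  validity = function(object) {
    n <- nrow(object@tensors)
    if (ncol(object@tensors) != 6L) return("tensors must have 6 columns")
    if (nrow(object@evals) != n || ncol(object@evals) != 3L)
      return("evals must be n x 3")
    if (length(object@s0) != n || length(object@flag) != n)
      return("s0/flag length mismatch")
    TRUE
  })

## ---- constructors ----

#' @rdname LabelAtlas-class
#' @param labels,regions,voxelSizeMm see slots.
#' @export
LabelAtlas <- function(labels, regions, voxelSizeMm = c(1, 1, 1)) {
  storage.mode(labels) <- "integer"
  regions$area_name <- as.character(regions$area_name)
  regions$hemisphere <- as.character(regions$hemisphere)
  regions$region_group <- as.character(regions$region_group)
  regions$label_id <- as.integer(regions$label_id)
  new("LabelAtlas", labels = labels, regions = regions,
      voxelSizeMm = as.numeric(voxelSizeMm))
}

#' @rdname VolumeSeries-class
#' @param data,voxelSizeMm,timesS see slots.
#' @export
VolumeSeries <- function(data, voxelSizeMm = c(1, 1, 1),
                         timesS = numeric()) {
  new("VolumeSeries", data = data, voxelSizeMm = as.numeric(voxelSizeMm),
      timesS = as.numeric(timesS))
}

#' @rdname ConnectivityMatrix-class
#' @param values,kind,nodeLabels see slots.
#' @export
ConnectivityMatrix <- function(values, kind,
                               nodeLabels = as.character(seq_len(nrow(values)))) {
  diag(values) <- 0
  values <- (values + t(values)) / 2   # kill rounding asymmetry
  new("ConnectivityMatrix", values = values, kind = kind,
      nodeLabels = as.character(nodeLabels))
}

## ---- accessors ----

#' @rdname LabelAtlas-class
#' @param x a LabelAtlas
#' @export
atlasLabels <- function(x) x@labels
#' @rdname LabelAtlas-class
#' @export
atlasRegions <- function(x) x@regions
#' @rdname VolumeSeries-class
#' @param x a VolumeSeries
#' @export
volData <- function(x) x@data
#' @rdname VolumeSeries-class
#' @export
voxelSize <- function(x) x@voxelSizeMm
#' @rdname VolumeSeries-class
#' @export
scanTimes <- function(x) x@timesS
#' @rdname ConnectivityMatrix-class
#' @param x a ConnectivityMatrix
#' @export
cmValues <- function(x) x@values
#' @rdname ConnectivityMatrix-class
#' @export
cmKind <- function(x) x@kind
#' @rdname ConnectivityMatrix-class
#' @export
nodeLabels <- function(x) x@nodeLabels
#' @rdname TensorFit-class
#' @param x a TensorFit
#' @export
tensorEvals <- function(x) x@evals
#' @rdname TensorFit-class
#' @export
tensorFlags <- function(x) x@flag

setMethod("show", "LabelAtlas", function(object) {
  cat("LabelAtlas:", paste(dim(object@labels), collapse = " x "),
      "voxels,", nrow(object@regions), "regions in",
      length(unique(object@regions$region_group)), "groups\n")
})

setMethod("show", "VolumeSeries", function(object) {
  d <- dim(object@data)
  cat("VolumeSeries:", paste(d, collapse = " x "),
      if (length(d) == 4L) sprintf("(%d timepoints)", d[4]) else "(3D)",
      sprintf("voxel %.3g x %.3g x %.3g mm\n", object@voxelSizeMm[1],
              object@voxelSizeMm[2], object@voxelSizeMm[3]))
})

setMethod("show", "ConnectivityMatrix", function(object) {
  cat(sprintf("ConnectivityMatrix (%s): %d nodes, %d unique pairs\n",
              object@kind, nrow(object@values),
              nrow(object@values) * (nrow(object@values) - 1) / 2))
})

setMethod("show", "TensorFit", function(object) {
  cat(sprintf("TensorFit: %d voxels (%d excluded, %d clamped)\n",
              nrow(object@tensors), sum(object@flag == 1L),
              sum(object@flag == 2L)))
})
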