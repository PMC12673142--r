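#' @include AllClasses.R utils.R
NULL

#' Segment the first reflection of every A-scan in a C-scan
#'
#' For each A-scan, selects the smallest axial index whose intensity
#' reaches the threshold (the first "white" pixel along the imaging
#' direction). A-scans with no such voxel are flagged invalid, never
#' zero-filled. The default threshold is Otsu's value on the volume
#' histogram, a deterministic stand-in for manual annotation of "white".
#'
#' @param vol an \linkS4class{OctVolume}.
#' @param threshold absolute intensity threshold; NULL for Otsu.
#' @param medianFilter apply a 3 x 3 median filter to the index map
#'   (off by default).
#' @return a \linkS4class{SurfaceMap} with 0-based axial indices.
#' @export
segmentCscanSurface <- function(vol, threshold = NULL, medianFilter = FALSE) {
  if (is.null(threshold))
    threshold <- otsuThreshold(vol@intensity, vol@intensityRange)
  if (threshold < vol@intensityRange[1] || threshold > vol@intensityRange[2])
    stop("threshold outside the declared intensity range")
  d <- dim(vol@intensity)
  bright <- vol@intensity >= threshold
  # first TRUE along the axial (third) axis per A-scan
  idx <- apply(bright, c(1, 2), function(a) {
    w <- which(a)
    if (length(w)) w[1] - 1L else NA_integer_
  })
  if (all(is.na(idx)))
    warning("all A-scans are below the threshold (all-invalid map)")
  if (medianFilter) idx <- medianFilter3x3(idx)
  new("SurfaceMap", index = idx, voxelDims = vol@voxelDims,
      depthPx = as.integer(d[3]))
}

## 3x3 median filter on the index map, NA-aware; edges use the available
## neighbourhood
medianFilter3x3 <- function(idx) {
  nx <- nrow(idx); ny <- ncol(idx)
  out <- idx
  for (i in seq_len(nx)) for (j in seq_len(ny)) {
    nb <- idx[max(1, i - 1):min(nx, i + 1), max(1, j - 1):min(ny, j + 1)]
    v <- nb[!is.na(nb)]
    if (length(v) && !is.na(idx[i, j]))
      out[i, j] <- as.integer(round(median(v)))
  }
  out
}

#' Convert a surface index map to a point cloud
#'
#' Places one point per valid A-scan at
#' \code{(ix * dx, iy * dy, -iz * dz)} in mm (0-based voxel indices, point
#' at the voxel centre; the axial index maps to -z so retinal clouds open
#' upward). Invalid A-scans are omitted. Point order is row-major
#' (fast lateral axis first).
#'
#' @param map a \linkS4class{SurfaceMap}.
#' @param frame frame tag for the cloud.
#' @return a \linkS4class{PointCloud3D}.
#' @export
surfaceToCloud <- function(map, frame = "oct") {
  idx <- map@index
  nx <- nrow(idx); ny <- ncol(idx)
  ix <- rep(seq_len(nx) - 1L, times = ny)
  iy <- rep(seq_len(ny) - 1L, each = nx)
  iz <- as.vector(idx)
  ok <- !is.na(iz)
  if (!any(ok)) stop("surface map has no valid A-scans")
  vd <- map@voxelDims
  pointCloud(cbind(ix[ok] * vd[1], iy[ok] * vd[2], -iz[ok] * vd[3]),
             frame = frame)
}

#' Segment an M-scan into per-column distances
#'
#' Temporally consecutive A-scans (columns) are thresholded as in
#' \code{\link{segmentCscanSurface}}; the distance of column i is the
#' first-bright axial index times the axial pixel size. All-dark columns
#' are returned as NA.
#'
#' @param mscan depth x time intensity matrix.
#' @param threshold absolute intensity threshold; NULL for Otsu on the
#'   image.
#' @param dz axial pixel size in mm.
#' @return numeric vector of distances (mm), NA where invalid.
#' @export
segmentMscan <- function(mscan, threshold = NULL, dz) {
  if (is.null(threshold)) threshold <- otsuThreshold(mscan)
  firstBright <- apply(mscan >= threshold, 2, function(a) {
    w <- which(a)
    if (length(w)) w[1] - 1L else NA_integer_
  })
  firstBright * dz
}

#' Reconstruct iiOCT surface points from probe poses
#'
#' Each sample contributes the point
#' \eqn{p_i = x_i + d_i\, v_i / \|v_i\|}: the probe tip position advanced
#' along the normalised beam direction by the measured distance. The
#' result is invariant to the scale of the orientation vectors.
#'
#' @param log a \linkS4class{ProbeLog}.
#' @return a \linkS4class{PointCloud3D} in the robot frame, one point per
#'   sample in log order.
#' @export
reconstructIioct <- function(log) {
  s <- log@samples
  if (nrow(s) == 0) stop("probe log is empty")
  v <- as.matrix(s[, c("vx", "vy", "vz")])
  nrm <- rowNorms(v)
  if (any(nrm == 0))
    stop("zero-norm orientation at sample index(es): ",
         paste(head(which(nrm == 0), 5), collapse = ", "))
  pts <- as.matrix(s[, c("x", "y", "z")]) + s$d / nrm * v
  pointCloud(pts, frame = "robot")
}

#' Calibrate the lateral scan field from fiducial markers
#'
#' The nominal scan field only holds for flat surfaces; the effective
#' lateral scale is measured by counting voxels between fiducial markers
#' of known physical distance.
#'
#' @param voxelCount voxels spanned between the markers (> 0).
#' @param knownDistanceMm physical marker distance in mm (> 0).
#' @return lateral scale in mm/voxel.
#' @examples
#' calibrateScanField(205, 5.0)  # 0.02439 mm/voxel
#' @export
calibrateScanField <- function(voxelCount, knownDistanceMm) {
  if (voxelCount <= 0 || knownDistanceMm <= 0)
    stop("voxel count and known distance must be positive")
  knownDistanceMm / voxelCount
}

#' Axial pixel size of an OCT system
#'
#' @param depthMm imaging depth (or working-distance range) in mm.
#' @param nPixels axial pixel count of one A-scan.
#' @return axial sampling in micrometres per pixel.
#' @examples
#' axialPixelSize(12.8, 1024)  # 12.5 um
#' axialPixelSize(2.9, 1024)   # about 2.8 um
#' @export
axialPixelSize <- function(depthMm, nPixels) {
  if (depthMm <= 0 || nPixels <= 0) stop("inputs must be positive")
  depthMm / nPixels * 1000
}
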