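#' @useDynLib retinareg, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @import methods
#' @importFrom stats rnorm sd t.test optim approx median quantile
#' @importFrom utils read.csv write.csv head tail
NULL

## Internal length unit is millimetres throughout the package; micrometres
## appear only in on-disk sidecars and in reported metrics.

#' PointCloud3D: ordered 3D points in millimetres
#'
#' Container for an ordered set of 3D points with optional per-point
#' category labels (e.g. \code{"retina"} / \code{"fiducial"}) and a
#' coordinate-frame tag (\code{"oct"}, \code{"iioct"} or \code{"robot"}).
#' Point order is meaningful (it encodes acquisition order and index-wise
#' correspondence with deformation fields) and is never permuted by any
#' operation in this package.
#'
#' @slot coords numeric matrix, n x 3, finite coordinates in mm.
#' @slot labels character vector of length 0 (unlabelled) or n.
#' @slot frame single character frame tag.
#' @export
setClass("PointCloud3D",
  representation(coords = "matrix", labels = "character", frame = "character"),
  prototype(coords = matrix(numeric(0), 0, 3), labels = character(0), frame = "oct"))

setValidity("PointCloud3D", function(object) {
  msg <- character(0)
  if (ncol(object@coords) != 3L)
    msg <- c(msg, "coords must have exactly 3 columns")
  if (nrow(object@coords) && !all(is.finite(object@coords)))
    msg <- c(msg, "all coordinates must be finite")
  if (length(object@labels) && length(object@labels) != nrow(object@coords))
    msg <- c(msg, "labels, when present, must have one entry per point")
  if (length(object@frame) != 1L)
    msg <- c(msg, "frame must be a single tag")
  if (length(msg)) msg else TRUE
})

#' Construct a PointCloud3D
#'
#' @param coords numeric matrix (n x 3) or 3-vector, coordinates in mm.
#' @param labels optional character vector of per-point labels.
#' @param frame coordinate-frame tag; one of \code{"oct"}, \code{"iioct"},
#'   \code{"robot"}.
#' @return A \linkS4class{PointCloud3D}.
#' @examples
#' pc <- pointCloud(rbind(c(0, 0, 0), c(1, 0, 0)))
#' nPoints(pc)
#' @export
pointCloud <- function(coords, labels = character(0), frame = "oct") {
  if (is.null(dim(coords))) coords <- matrix(coords, ncol = 3, byrow = TRUE)
  coords <- as.matrix(coords)
  storage.mode(coords) <- "double"
  dimnames(coords) <- NULL
  if (is.null(labels)) labels <- character(0)
  new("PointCloud3D", coords = coords, labels = as.character(labels),
      frame = frame)
}

#' OctVolume: OCT intensity volume with voxel geometry
#'
#' A C-scan intensity grid. The array is indexed \code{[ix, iy, iz]} with
#' \code{ix} the fast lateral axis, \code{iy} the slow lateral axis and
#' \code{iz} the axial (A-scan depth) axis. Voxel dimensions are stored in
#' millimetres.
#'
#' @slot intensity 3D numeric array, dims \code{c(nx, ny, depthPx)}.
#' @slot voxelDims numeric(3), voxel size (dx, dy, dz) in mm.
#' @slot intensityRange numeric(2), declared intensity range.
#' @export
setClass("OctVolume",
  representation(intensity = "array", voxelDims = "numeric",
                 intensityRange = "numeric"))

setValidity("OctVolume", function(object) {
  msg <- character(0)
  if (length(dim(object@intensity)) != 3L)
    msg <- c(msg, "intensity must be a 3D array (nx, ny, depthPx)")
  if (length(object@voxelDims) != 3L || any(object@voxelDims <= 0))
    msg <- c(msg, "voxelDims must be 3 positive values (mm)")
  if (length(object@intensityRange) != 2L ||
      diff(object@intensityRange) <= 0)
    msg <- c(msg, "intensityRange must be an increasing pair")
  rng <- range(object@intensity)
  if (length(msg) == 0 &&
      (rng[1] < object@intensityRange[1] - 1e-9 ||
       rng[2] > object@intensityRange[2] + 1e-9))
    msg <- c(msg, "intensities fall outside the declared range")
  if (length(msg)) msg else TRUE
})

#' Construct an OctVolume
#'
#' @param intensity 3D array \code{[nx, ny, depthPx]}.
#' @param voxelDims voxel size (dx, dy, dz) in mm.
#' @param intensityRange declared intensity range, default \code{c(0, 1)}.
#' @return An \linkS4class{OctVolume}.
#' @export
octVolume <- function(intensity, voxelDims, intensityRange = c(0, 1)) {
  new("OctVolume", intensity = intensity, voxelDims = as.numeric(voxelDims),
      intensityRange = as.numeric(intensityRange))
}

#' ProbeLog: time series of iiOCT probe samples
#'
#' Each row holds the probe tip position \code{x} (mm, robot frame), an
#' orientation vector \code{v} (direction of the sensing beam, not
#' necessarily unit norm) and the measured distance \code{d} (mm) from the
#' tip to the retina, with a timestamp \code{t} (s).
#'
#' @slot samples data.frame with columns t, x, y, z, vx, vy, vz, d.
#' @export
setClass("ProbeLog", representation(samples = "data.frame"))

setValidity("ProbeLog", function(object) {
  s <- object@samples
  need <- c("t", "x", "y", "z", "vx", "vy", "vz", "d")
  if (!all(need %in% names(s)))
    return(paste("probe log must have columns", paste(need, collapse = ", ")))
  msg <- character(0)
  if (nrow(s)) {
    if (any(s$d < 0)) msg <- c(msg, "measured distances d must be >= 0")
    vn <- sqrt(s$vx^2 + s$vy^2 + s$vz^2)
    if (any(vn == 0)) msg <- c(msg, "orientation vectors must be non-zero")
    if (is.unsorted(s$t)) msg <- c(msg, "timestamps must be non-decreasing")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a ProbeLog
#'
#' @param samples data.frame with columns t, x, y, z, vx, vy, vz, d.
#' @return A \linkS4class{ProbeLog}.
#' @export
probeLog <- function(samples) new("ProbeLog", samples = as.data.frame(samples))

#' Landmarks: fovea, optic nerve head and fiducial markers
#'
#' @slot fovea numeric(3), fovea coordinate in mm.
#' @slot onh numeric(3), optic nerve head coordinate in mm.
#' @slot fiducials numeric matrix k x 3 with unique rownames (labels); may
#'   have zero rows.
#' @export
setClass("Landmarks",
  representation(fovea = "numeric", onh = "numeric", fiducials = "matrix"))

setValidity("Landmarks", function(object) {
  msg <- character(0)
  if (length(object@fovea) != 3L || length(object@onh) != 3L)
    msg <- c(msg, "fovea and onh must be 3-vectors")
  else if (all(object@fovea == object@onh))
    msg <- c(msg, "fovea and onh must differ")
  if (ncol(object@fiducials) != 3L)
    msg <- c(msg, "fiducials must be a k x 3 matrix")
  if (nrow(object@fiducials)) {
    lb <- rownames(object@fiducials)
    if (is.null(lb) || anyDuplicated(lb))
      msg <- c(msg, "fiducial labels must be present and unique")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a Landmarks object
#'
#' @param fovea,onh 3-vectors in mm.
#' @param fiducials k x 3 matrix of fiducial coordinates with unique
#'   rownames, or NULL.
#' @return A \linkS4class{Landmarks}.
#' @export
landmarks <- function(fovea, onh, fiducials = NULL) {
  if (is.null(fiducials)) {
    fiducials <- matrix(numeric(0), 0, 3)
  } else {
    fiducials <- as.matrix(fiducials)
    storage.mode(fiducials) <- "double"
  }
  new("Landmarks", fovea = as.numeric(fovea), onh = as.numeric(onh),
      fiducials = fiducials)
}

#' SphereFit: geometric least-squares sphere
#'
#' Result of fitting a sphere with centre \eqn{c} and radius \eqn{r}
#' minimising \eqn{\sum_i (\|p_i - c\| - r)^2}.
#'
#' @slot center numeric(3), mm.
#' @slot radius positive scalar, mm.
#' @slot rmsResidual root-mean-square geometric residual, mm.
#' @slot nPoints number of points used in the fit.
#' @export
setClass("SphereFit",
  representation(center = "numeric", radius = "numeric",
                 rmsResidual = "numeric", nPoints = "integer"))

setValidity("SphereFit", function(object) {
  msg <- character(0)
  if (length(object@center) != 3L) msg <- c(msg, "center must be a 3-vector")
  if (object@radius <= 0) msg <- c(msg, "radius must be positive")
  if (object@rmsResidual < 0) msg <- c(msg, "residual must be >= 0")
  if (length(msg)) msg else TRUE
})

#' Construct a SphereFit directly
#'
#' Mainly useful for analytically known spheres; data-driven fits come from
#' \code{\link{fitSphere}}.
#'
#' @param center 3-vector, mm.
#' @param radius positive radius, mm.
#' @param rmsResidual RMS geometric residual, mm.
#' @param nPoints number of supporting points.
#' @return A \linkS4class{SphereFit}.
#' @export
sphereFit <- function(center, radius, rmsResidual = 0, nPoints = 0L) {
  new("SphereFit", center = as.numeric(center), radius = as.numeric(radius),
      rmsResidual = as.numeric(rmsResidual), nPoints = as.integer(nPoints))
}

#' DeformationField: per-point correction vectors
#'
#' One correction vector per point of a source cloud; adding the vectors to
#' the source coordinates yields the corrected cloud. Carries the sphere
#' fits that generated it.
#'
#' @slot vectors numeric matrix n x 3, mm.
#' @slot sourceFit,targetFit \linkS4class{SphereFit} metadata.
#' @export
setClass("DeformationField",
  representation(vectors = "matrix", sourceFit = "SphereFit",
                 targetFit = "SphereFit"))

setValidity("DeformationField", function(object) {
  if (ncol(object@vectors) != 3L) "vectors must be n x 3" else TRUE
})

#' RigidTransform: rotation plus translation
#'
#' @slot rotation 3 x 3 orthonormal matrix with determinant +1.
#' @slot translation numeric(3), mm.
#' @export
setClass("RigidTransform",
  representation(rotation = "matrix", translation = "numeric"),
  prototype(rotation = diag(3), translation = c(0, 0, 0)))

setValidity("RigidTransform", function(object) {
  R <- object@rotation
  if (!all(dim(R) == c(3, 3))) return("rotation must be 3 x 3")
  if (max(abs(crossprod(R) - diag(3))) > 1e-9)
    return("rotation must be orthonormal (R'R = I within 1e-9)")
  if (abs(det(R) - 1) > 1e-9)
    return("rotation must be proper (det = +1)")
  if (length(object@translation) != 3L) return("translation must be a 3-vector")
  TRUE
})

#' Construct a RigidTransform
#'
#' @param rotation 3 x 3 rotation matrix.
#' @param translation 3-vector in mm.
#' @return A \linkS4class{RigidTransform}.
#' @export
rigidTransform <- function(rotation = diag(3), translation = c(0, 0, 0)) {
  new("RigidTransform", rotation = rotation,
      translation = as.numeric(translation))
}

#' Trajectory: ordered robot probe-tip poses
#'
#' @slot tipPositions n x 3 matrix, mm.
#' @slot orientations n x 3 matrix of unit beam directions.
#' @slot pattern tag: grid, spiral, patch or composite.
#' @slot nominalSpacing nominal consecutive-point spacing, mm.
#' @slot metadata list (field size, pitch, ...).
#' @export
setClass("Trajectory",
  representation(tipPositions = "matrix", orientations = "matrix",
                 pattern = "character", nominalSpacing = "numeric",
                 metadata = "list"))

setValidity("Trajectory", function(object) {
  msg <- character(0)
  if (ncol(object@tipPositions) != 3L || ncol(object@orientations) != 3L)
    msg <- c(msg, "tipPositions and orientations must be n x 3")
  if (nrow(object@tipPositions) != nrow(object@orientations))
    msg <- c(msg, "one orientation per tip position required")
  if (nrow(object@orientations)) {
    nrm <- sqrt(rowSums(object@orientations^2))
    if (any(abs(nrm - 1) > 1e-6))
      msg <- c(msg, "orientations must be unit vectors")
  }
  if (length(object@nominalSpacing) != 1L || object@nominalSpacing <= 0)
    msg <- c(msg, "nominalSpacing must be a positive scalar")
  if (length(msg)) msg else TRUE
})

#' TimingModel: velocity / frequency / spacing relation
#'
#' Spacing between consecutive samples equals velocity divided by the A-scan
#' frequency. Give any two of the three; the third is derived.
#'
#' @slot frequency Hz.
#' @slot velocity mm/s.
#' @slot spacing mm.
#' @export
setClass("TimingModel",
  representation(frequency = "numeric", velocity = "numeric",
                 spacing = "numeric"))

setValidity("TimingModel", function(object) {
  if (any(c(object@frequency, object@velocity, object@spacing) <= 0))
    return("frequency, velocity and spacing must be positive")
  if (abs(object@spacing - object@velocity / object@frequency) >
      1e-9 * object@spacing)
    return("spacing must equal velocity / frequency")
  TRUE
})

#' Construct a TimingModel
#'
#' @param frequency scanning frequency in Hz (default 40).
#' @param velocity probe-tip velocity in mm/s.
#' @param spacing sample spacing in mm.
#' @return A \linkS4class{TimingModel}.
#' @examples
#' timingModel(frequency = 40, velocity = 2)  # 50 um spacing
#' @export
timingModel <- function(frequency = 40, velocity = NULL, spacing = NULL) {
  if (is.null(velocity) && is.null(spacing))
    stop("give at least one of velocity and spacing")
  if (is.null(velocity)) velocity <- spacing * frequency
  if (is.null(spacing)) spacing <- velocity / frequency
  new("TimingModel", frequency = frequency, velocity = velocity,
      spacing = spacing)
}

#' SurfaceMap: per-A-scan first-reflection indices
#'
#' The axial pixel index of the first bright voxel of each A-scan
#' (0-based), or NA where no voxel exceeded the threshold.
#'
#' @slot index nx x ny integer matrix (NA = invalid A-scan).
#' @slot voxelDims voxel dimensions of the source volume, mm.
#' @slot depthPx axial pixel count of the source volume.
#' @export
setClass("SurfaceMap",
  representation(index = "matrix", voxelDims = "numeric", depthPx = "integer"))

setValidity("SurfaceMap", function(object) {
  idx <- object@index[!is.na(object@index)]
  if (length(idx) && (any(idx < 0) || any(idx >= object@depthPx)))
    return("indices must lie in [0, depthPx)")
  TRUE
})
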