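#' @include AllClasses.R
NULL

#' Number of points in an object
#' @param x a PointCloud3D, Trajectory or ProbeLog.
#' @return integer count.
#' @export
setGeneric("nPoints", function(x) standardGeneric("nPoints"))

#' Point coordinates (n x 3 matrix, mm)
#' @param x an object holding 3D points.
#' @return numeric matrix n x 3.
#' @export
setGeneric("coords", function(x) standardGeneric("coords"))

#' Per-point labels
#' @param x a PointCloud3D.
#' @return character vector (length 0 when unlabelled).
#' @export
setGeneric("pointLabels", function(x) standardGeneric("pointLabels"))

#' Coordinate-frame tag
#' @param x a PointCloud3D.
#' @return single character tag.
#' @export
setGeneric("frameTag", function(x) standardGeneric("frameTag"))

#' Apply a rigid transform
#'
#' Maps points p to R p + t. For clouds, labels and frame tag are kept; pass
#' \code{frame} to retag. For Trajectory objects orientations are rotated.
#'
#' @param transform a \linkS4class{RigidTransform}.
#' @param x a PointCloud3D, Trajectory, Landmarks object or n x 3 matrix.
#' @param frame optional new frame tag for clouds.
#' @return object of the same class as \code{x}.
#' @export
setGeneric("applyTransform",
           function(transform, x, frame = NULL) standardGeneric("applyTransform"))

#' @rdname nPoints
#' @export
setMethod("nPoints", "PointCloud3D", function(x) nrow(x@coords))
#' @rdname nPoints
#' @export
setMethod("nPoints", "Trajectory", function(x) nrow(x@tipPositions))
#' @rdname nPoints
#' @export
setMethod("nPoints", "ProbeLog", function(x) nrow(x@samples))

#' @rdname coords
#' @export
setMethod("coords", "PointCloud3D", function(x) x@coords)
#' @rdname coords
#' @export
setMethod("coords", "Trajectory", function(x) x@tipPositions)

#' @rdname pointLabels
#' @export
setMethod("pointLabels", "PointCloud3D", function(x) x@labels)

#' @rdname frameTag
#' @export
setMethod("frameTag", "PointCloud3D", function(x) x@frame)

#' Accessors for sphere fits
#' @param x a \linkS4class{SphereFit}.
#' @return centre (3-vector, mm) or radius (mm).
#' @export
setGeneric("sphereCenter", function(x) standardGeneric("sphereCenter"))
#' @rdname sphereCenter
#' @export
setGeneric("sphereRadius", function(x) standardGeneric("sphereRadius"))
#' @rdname sphereCenter
#' @export
setMethod("sphereCenter", "SphereFit", function(x) x@center)
#' @rdname sphereCenter
#' @export
setMethod("sphereRadius", "SphereFit", function(x) x@radius)

#' Deformation vectors of a DeformationField
#' @param x a \linkS4class{DeformationField}.
#' @return n x 3 matrix of correction vectors (mm).
#' @export
setGeneric("deformationVectors", function(x) standardGeneric("deformationVectors"))
#' @rdname deformationVectors
#' @export
setMethod("deformationVectors", "DeformationField", function(x) x@vectors)

#' Probe log accessors
#' @param x a \linkS4class{ProbeLog}.
#' @return matrix or vector of the requested component.
#' @export
setGeneric("tipPositions", function(x) standardGeneric("tipPositions"))
#' @rdname tipPositions
#' @export
setGeneric("orientations", function(x) standardGeneric("orientations"))
#' @rdname tipPositions
#' @export
setGeneric("distances", function(x) standardGeneric("distances"))
#' @rdname tipPositions
#' @export
setMethod("tipPositions", "ProbeLog",
          function(x) as.matrix(x@samples[, c("x", "y", "z")]))
#' @rdname tipPositions
#' @export
setMethod("tipPositions", "Trajectory", function(x) x@tipPositions)
#' @rdname tipPositions
#' @export
setMethod("orientations", "ProbeLog",
          function(x) as.matrix(x@samples[, c("vx", "vy", "vz")]))
#' @rdname tipPositions
#' @export
setMethod("orientations", "Trajectory", function(x) x@orientations)
#' @rdname tipPositions
#' @export
setMethod("distances", "ProbeLog", function(x) x@samples$d)

setMethod("show", "PointCloud3D", function(object) {
  cat(sprintf("PointCloud3D: %d points [frame: %s]%s\n", nPoints(object),
              object@frame,
              if (length(object@labels))
                sprintf(" (labels: %s)",
                        paste(names(table(object@labels)), collapse = ", "))
              else ""))
  if (nPoints(object)) {
    rng <- apply(object@coords, 2, range)
    cat(sprintf("  extent x [%.3f, %.3f] y [%.3f, %.3f] z [%.3f, %.3f] mm\n",
                rng[1, 1], rng[2, 1], rng[1, 2], rng[2, 2], rng[1, 3], rng[2, 3]))
  }
})

setMethod("show", "OctVolume", function(object) {
  d <- dim(object@intensity)
  cat(sprintf("OctVolume: %d x %d A-scans, %d axial px; voxel %.4g x %.4g x %.4g mm\n",
              d[1], d[2], d[3], object@voxelDims[1], object@voxelDims[2],
              object@voxelDims[3]))
})

setMethod("show", "SphereFit", function(object) {
  cat(sprintf("SphereFit: r = %.4f mm, c = (%.4f, %.4f, %.4f), RMS residual %.3g mm (n = %d)\n",
              object@radius, object@center[1], object@center[2],
              object@center[3], object@rmsResidual, object@nPoints))
})

setMethod("show", "RigidTransform", function(object) {
  cat("RigidTransform:\n  R =\n")
  print(round(object@rotation, 6))
  cat(sprintf("  t = (%.4f, %.4f, %.4f) mm\n", object@translation[1],
              object@translation[2], object@translation[3]))
})

setMethod("show", "Trajectory", function(object) {
  cat(sprintf("Trajectory [%s]: %d poses, nominal spacing %.3g mm, path length %.2f mm\n",
              object@pattern, nPoints(object), object@nominalSpacing,
              pathLength(object)))
})

setMethod("show", "ProbeLog", function(object) {
  cat(sprintf("ProbeLog: %d samples, t in [%.3g, %.3g] s\n", nPoints(object),
              if (nPoints(object)) min(object@samples$t) else NA,
              if (nPoints(object)) max(object@samples$t) else NA))
})

setMethod("show", "Landmarks", function(object) {
  cat(sprintf("Landmarks: fovea (%.3f, %.3f, %.3f), ONH (%.3f, %.3f, %.3f), %d fiducials\n",
              object@fovea[1], object@fovea[2], object@fovea[3],
              object@onh[1], object@onh[2], object@onh[3],
              nrow(object@fiducials)))
})

setMethod("show", "SurfaceMap", function(object) {
  cat(sprintf("SurfaceMap: %d x %d A-scans, %d invalid\n",
              nrow(object@index), ncol(object@index),
              sum(is.na(object@index))))
})

#' @rdname applyTransform
#' @export
setMethod("applyTransform", signature("RigidTransform", "matrix"),
  function(transform, x, frame = NULL) {
    t(transform@rotation %*% t(x)) +
      matrix(transform@translation, nrow(x), 3, byrow = TRUE)
  })

#' @rdname applyTransform
#' @export
setMethod("applyTransform", signature("RigidTransform", "PointCloud3D"),
  function(transform, x, frame = NULL) {
    pointCloud(applyTransform(transform, x@coords), labels = x@labels,
               frame = if (is.null(frame)) x@frame else frame)
  })

#' @rdname applyTransform
#' @export
setMethod("applyTransform", signature("RigidTransform", "numeric"),
  function(transform, x, frame = NULL) {
    as.numeric(transform@rotation %*% x + transform@translation)
  })

#' @rdname applyTransform
#' @export
setMethod("applyTransform", signature("RigidTransform", "Landmarks"),
  function(transform, x, frame = NULL) {
    fid <- x@fiducials
    if (nrow(fid)) {
      lb <- rownames(fid)
      fid <- applyTransform(transform, unname(fid))
      rownames(fid) <- lb
    }
    landmarks(applyTransform(transform, x@fovea),
              applyTransform(transform, x@onh),
              if (nrow(fid)) fid else NULL)
  })

#' @rdname applyTransform
#' @export
setMethod("applyTransform", signature("RigidTransform", "Trajectory"),
  function(transform, x, frame = NULL) {
    new("Trajectory",
        tipPositions = applyTransform(transform, x@tipPositions),
        orientations = t(transform@rotation %*% t(x@orientations)),
        pattern = x@pattern, nominalSpacing = x@nominalSpacing,
        metadata = x@metadata)
  })

#' Compose and invert rigid transforms
#'
#' \code{composeTransform(b, a)} returns the transform applying \code{a}
#' first, then \code{b}.
#'
#' @param b,a RigidTransform objects.
#' @return a \linkS4class{RigidTransform}.
#' @export
composeTransform <- function(b, a) {
  rigidTransform(b@rotation %*% a@rotation,
                 as.numeric(b@rotation %*% a@translation + b@translation))
}

#' @rdname composeTransform
#' @param x a RigidTransform to invert.
#' @export
invertTransform <- function(x) {
  rigidTransform(t(x@rotation), as.numeric(-t(x@rotation) %*% x@translation))
}
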