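#' @include AllClasses.R utils.R curvature.R
NULL

#' EyePhantomSpec: synthetic eye phantom description
#'
#' Describes a spherical retina with superimposed relief features (foveal
#' pit, optic nerve head, vessel ridges, fiducial wires), the apparent
#' radius of its curvature-flattened diagnostic scan, and the iiOCT
#' distance-noise level. All reliefs are positive offsets of the surface
#' towards the sphere centre (the convention in which retinal clouds open
#' upward and the centre lies above the surface).
#'
#' @slot radius true retinal sphere radius, mm.
#' @slot apparentRadius fitted radius of the flattened diagnostic scan, mm.
#' @slot foveaDepth,foveaWidth Gaussian foveal pit amplitude / sd, mm.
#' @slot onhOffset lateral (x, y) offset of the ONH from the fovea, mm.
#' @slot onhDepth,onhWidth Gaussian ONH cup amplitude / sd, mm.
#' @slot vesselSpec list of vessel ridge segments
#'   (\code{list(start, end, height, width)}, lateral mm).
#' @slot wireSpec list of fiducial wire segments (same fields).
#' @slot wireCrossings k x 2 matrix of lateral wire crossing coordinates
#'   (the validation points).
#' @slot noiseSd additive iiOCT distance noise, mm.
#' @slot seed integer RNG seed for the stochastic sampling.
#' @slot mode \code{"lankenau"} or \code{"porcine"}.
#' @export
setClass("EyePhantomSpec",
  representation(radius = "numeric", apparentRadius = "numeric",
                 foveaDepth = "numeric", foveaWidth = "numeric",
                 onhOffset = "numeric", onhDepth = "numeric",
                 onhWidth = "numeric", vesselSpec = "list",
                 wireSpec = "list", wireCrossings = "matrix",
                 noiseSd = "numeric", seed = "integer", mode = "character"))

setValidity("EyePhantomSpec", function(object) {
  msg <- character(0)
  if (object@radius <= 0) msg <- c(msg, "radius must be positive")
  if (object@apparentRadius < object@radius)
    msg <- c(msg, "apparentRadius must be >= radius")
  if (object@foveaDepth >= object@radius / 10)
    msg <- c(msg, "foveal pit depth must be < radius/10")
  if (object@noiseSd < 0) msg <- c(msg, "noiseSd must be >= 0")
  if (length(msg)) msg else TRUE
})

setMethod("show", "EyePhantomSpec", function(object) {
  cat(sprintf("EyePhantomSpec [%s]: r = %.2f mm (apparent %.2f mm), %d vessels, %d wires, noise sd %.4g mm, seed %d\n",
              object@mode, object@radius, object@apparentRadius,
              length(object@vesselSpec), length(object@wireSpec),
              object@noiseSd, object@seed))
})

## triangular fiducial arrangement: three wires of the given length laid
## along the edges of an equilateral triangle; the triangle vertices are the
## wire crossings used as validation points.
wireTriangle <- function(center = c(0.3, 0), circumradius = 1.2,
                         wireLength = 5, height = 0.05, width = 0.05) {
  ang <- pi / 2 + (0:2) * 2 * pi / 3
  v <- cbind(center[1] + circumradius * cos(ang),
             center[2] + circumradius * sin(ang))
  wires <- lapply(1:3, function(k) {
    a <- v[k, ]; b <- v[k %% 3 + 1, ]
    mid <- (a + b) / 2
    dir <- unitize(c(b - a, 0))[1:2]
    list(start = mid - dir * wireLength / 2,
         end = mid + dir * wireLength / 2,
         height = height, width = width)
  })
  list(wires = wires, crossings = v)
}

#' Build an eye phantom specification
#'
#' Defaults emulate a model eye with realistic geometry: a 10 mm retinal
#' sphere whose diagnostic scan appears flattened to a 22 mm radius
#' (apparent/true ratio about 2.2), a 0.2 mm foveal pit, an ONH cup about
#' 4 mm from the fovea, four vessel ridges radiating from the ONH, and a
#' triangle of three 5 mm x 50 um fiducial wires in the macular area whose
#' crossings serve as validation points. The porcine mode drops the foveal
#' pit (absent in porcine eyes) and uses a central substitute wire plus six
#' stitched 2 mm x 100 um wires as fiducials.
#'
#' @param mode \code{"lankenau"} (model eye) or \code{"porcine"}.
#' @param radius true retinal radius, mm.
#' @param apparentRadius flattened diagnostic-scan radius, mm.
#' @param foveaDepth,foveaWidth pit amplitude and Gaussian sd, mm.
#' @param onhOffset lateral ONH offset from the fovea, mm.
#' @param onhDepth,onhWidth ONH amplitude and Gaussian sd, mm.
#' @param vesselSpec vessel ridge list; NULL for the mode default.
#' @param wireSpec fiducial wire list; NULL for the mode default.
#' @param wireCrossings k x 2 lateral crossing coordinates; NULL for default.
#' @param noiseSd iiOCT distance noise sd, mm (default 0.0125 mm, the
#'   iiOCT axial sampling).
#' @param seed RNG seed.
#' @return an \linkS4class{EyePhantomSpec}.
#' @export
eyePhantomSpec <- function(mode = c("lankenau", "porcine"), radius = 10,
                           apparentRadius = 22, foveaDepth = 0.2,
                           foveaWidth = 0.75, onhOffset = c(4, 0.8),
                           onhDepth = 0.35, onhWidth = 0.8,
                           vesselSpec = NULL, wireSpec = NULL,
                           wireCrossings = NULL, noiseSd = 0.0125,
                           seed = 1L) {
  mode <- match.arg(mode)
  onh <- onhOffset
  if (is.null(vesselSpec)) {
    ends <- list(c(-4.5, 3.5), c(-4.5, -3.0), c(3.0, 4.5), c(3.0, -4.0))
    vesselSpec <- lapply(ends, function(e)
      list(start = onh, end = e, height = 0.05, width = 0.12))
  }
  if (mode == "porcine") foveaDepth <- 0
  if (is.null(wireSpec)) {
    if (mode == "lankenau") {
      wt <- wireTriangle()
      wireSpec <- wt$wires
      wireCrossings <- wt$crossings
    } else {
      # central substitute wire plus six stitched short wires
      ang <- (0:5) * pi / 3
      ctr <- rbind(c(0, 0), cbind(1.5 * cos(ang), 1.5 * sin(ang)))
      wireSpec <- lapply(seq_len(nrow(ctr)), function(i) {
        d <- if (i == 1) c(1, 0) else unitize(c(ctr[i, ], 0))[1:2]
        list(start = ctr[i, ] - d, end = ctr[i, ] + d,
             height = 0.1, width = 0.1)
      })
      wireCrossings <- ctr
    }
  }
  if (is.null(wireCrossings)) wireCrossings <- matrix(numeric(0), 0, 2)
  new("EyePhantomSpec", radius = radius, apparentRadius = apparentRadius,
      foveaDepth = foveaDepth, foveaWidth = foveaWidth,
      onhOffset = as.numeric(onhOffset), onhDepth = onhDepth,
      onhWidth = onhWidth, vesselSpec = vesselSpec, wireSpec = wireSpec,
      wireCrossings = as.matrix(wireCrossings), noiseSd = noiseSd,
      seed = as.integer(seed), mode = mode)
}

## lateral distance from points (x, y) to a 2D segment a--b
segmentDistance <- function(x, y, a, b) {
  ab <- b - a
  len2 <- sum(ab^2)
  tt <- if (len2 == 0) rep(0, length(x)) else
    pmin(1, pmax(0, ((x - a[1]) * ab[1] + (y - a[2]) * ab[2]) / len2))
  sqrt((x - (a[1] + tt * ab[1]))^2 + (y - (a[2] + tt * ab[2]))^2)
}

## relief height (offset towards the sphere centre) at lateral positions
phantomRelief <- function(spec, x, y, wires = TRUE) {
  h <- spec@foveaDepth * exp(-(x^2 + y^2) / (2 * spec@foveaWidth^2))
  ox <- x - spec@onhOffset[1]; oy <- y - spec@onhOffset[2]
  h <- h + spec@onhDepth * exp(-(ox^2 + oy^2) / (2 * spec@onhWidth^2))
  for (vs in spec@vesselSpec) {
    d <- segmentDistance(x, y, vs$start, vs$end)
    h <- h + vs$height * exp(-d^2 / (2 * vs$width^2))
  }
  if (wires) h <- h + phantomWireRelief(spec, x, y)
  h
}

phantomWireRelief <- function(spec, x, y) {
  h <- numeric(length(x))
  for (ws in spec@wireSpec) {
    d <- segmentDistance(x, y, ws$start, ws$end)
    h <- h + ws$height * exp(-d^2 / (2 * ws$width^2))
  }
  h
}

#' Analytic phantom surface height
#'
#' Height field of the true retinal surface,
#' \eqn{z(x, y) = R - \sqrt{R^2 - x^2 - y^2} + h(x, y)}, with the fovea
#' base point at the origin, the sphere centre at (0, 0, R) and relief
#' \eqn{h} (pit + ONH + vessels + wires) added as vertical offsets.
#'
#' @param spec an \linkS4class{EyePhantomSpec}.
#' @param x,y lateral coordinates, mm.
#' @param wires include fiducial wire relief.
#' @return surface z in mm (NA outside the spherical dome).
#' @export
phantomSurfaceHeight <- function(spec, x, y, wires = TRUE) {
  r2 <- x^2 + y^2
  z <- rep(NA_real_, length(x))
  ok <- r2 < spec@radius^2
  z[ok] <- spec@radius - sqrt(spec@radius^2 - r2[ok])
  z[ok] <- z[ok] + phantomRelief(spec, x[ok], y[ok], wires = wires)
  z
}

#' Generate the true phantom surface and its landmarks
#'
#' Samples the analytic surface on a regular lateral grid (x fast, y slow)
#' and returns the cloud together with exact landmark coordinates. The
#' fovea and ONH landmarks mark the feature centres at the reference
#' (base-sphere) surface level; fiducial landmarks are the wire crossing
#' points on the relief surface. Grid points within one wire width of a
#' wire centreline are labelled \code{"fiducial"}, all others
#' \code{"retina"}.
#'
#' @param spec an \linkS4class{EyePhantomSpec}.
#' @param fieldMm lateral field size (square), mm.
#' @param lateralSpacingMm grid spacing, mm.
#' @param frame frame tag for the returned cloud.
#' @return list with \code{cloud} (\linkS4class{PointCloud3D}) and
#'   \code{landmarks} (\linkS4class{Landmarks}).
#' @export
generateTrueSurface <- function(spec, fieldMm = 10, lateralSpacingMm = 0.1,
                                frame = "robot") {
  if (fieldMm <= 0 || lateralSpacingMm <= 0)
    stop("field and spacing must be positive")
  if (fieldMm * sqrt(2) / 2 >= spec@radius)
    stop("field too large for sphere: corner radius ",
         format(fieldMm * sqrt(2) / 2), " mm >= radius ", spec@radius, " mm")
  g <- seq(-fieldMm / 2, fieldMm / 2, by = lateralSpacingMm)
  x <- rep(g, times = length(g))
  y <- rep(g, each = length(g))
  z <- phantomSurfaceHeight(spec, x, y)
  wr <- numeric(length(x))
  for (ws in spec@wireSpec)
    wr <- pmax(wr, as.numeric(segmentDistance(x, y, ws$start, ws$end) <=
                                ws$width))
  labs <- ifelse(wr > 0, "fiducial", "retina")
  cloud <- pointCloud(cbind(x, y, z), labels = labs, frame = frame)
  cr <- spec@wireCrossings
  fid <- NULL
  if (nrow(cr)) {
    fid <- cbind(cr, phantomSurfaceHeight(spec, cr[, 1], cr[, 2]))
    rownames(fid) <- paste0("c", seq_len(nrow(cr)))
  }
  onhBase <- c(spec@onhOffset,
               spec@radius - sqrt(spec@radius^2 - sum(spec@onhOffset^2)))
  lm <- landmarks(fovea = c(0, 0, 0), onh = onhBase, fiducials = fid)
  list(cloud = cloud, landmarks = lm)
}

#' Forward curvature-flattening distortion
#'
#' Maps each point of a true-geometry cloud onto a flattened version whose
#' spherical base has the apparent radius, tangent to the true base sphere
#' at the fovea. Each point keeps its signed radial offset
#' \eqn{h = R - \|p - c\|} to the true sphere, re-applied along the ray
#' from the apparent-sphere centre through the point:
#' \eqn{p' = c_a - (R_a - h)\,(c_a - p)/\|c_a - p\|}. The fovea is a fixed
#' point; the displacement grows towards the periphery, emulating the
#' flattened appearance of the retina in parallel-A-scan rendering.
#'
#' @param cloud a \linkS4class{PointCloud3D} in the phantom frame (fovea
#'   base point at the origin, centre on +z).
#' @param spec the \linkS4class{EyePhantomSpec} (uses radius and
#'   apparentRadius).
#' @return the distorted cloud (frame \code{"oct"}), same point order.
#' @export
distortSurface <- function(cloud, spec) {
  m <- asCoordMatrix(cloud)
  n <- nrow(m)
  cTrue <- c(0, 0, spec@radius)
  cApp <- c(0, 0, spec@apparentRadius)
  h <- spec@radius - rowNorms(m - matrix(cTrue, n, 3, byrow = TRUE))
  w <- matrix(cApp, n, 3, byrow = TRUE) - m
  wn <- rowNorms(w)
  if (any(wn == 0)) stop("point coincides with the apparent sphere centre")
  out <- matrix(cApp, n, 3, byrow = TRUE) - (spec@apparentRadius - h) / wn * w
  pointCloud(out,
             labels = if (is(cloud, "PointCloud3D")) pointLabels(cloud)
                      else character(0),
             frame = "oct")
}

#' Sample iiOCT distance measurements along a robot trajectory
#'
#' Casts a ray from every trajectory pose along its beam orientation onto
#' the analytic phantom surface, returning a probe log with the measured
#' distances (plus seeded Gaussian noise) and the ground-truth contact
#' cloud. Rays that do not intersect the surface are flagged invalid and
#' excluded; their count is reported.
#'
#' @param spec an \linkS4class{EyePhantomSpec}.
#' @param trajectory a \linkS4class{Trajectory} of tip poses above the
#'   surface.
#' @param noiseSd distance noise sd in mm (default from spec).
#' @param seed RNG seed (default from spec).
#' @param frequency A-scan rate in Hz used for the timestamps.
#' @return list with \code{log} (\linkS4class{ProbeLog}), \code{contact}
#'   (noise-free contact \linkS4class{PointCloud3D}, frame "robot") and
#'   \code{nInvalid}.
#' @export
sampleIioct <- function(spec, trajectory, noiseSd = spec@noiseSd,
                        seed = spec@seed, frequency = 40) {
  tips <- tipPositions(trajectory)
  dirs <- orientations(trajectory)
  n <- nrow(tips)
  if (n == 0) stop("trajectory is empty")
  tmax <- 2 * spec@radius
  nCoarse <- 160L
  tsGrid <- seq(0, tmax, length.out = nCoarse)
  below <- function(tt) {
    pos <- tips + dirs * tt
    r2 <- pos[, 1]^2 + pos[, 2]^2
    inside <- r2 < (0.999 * spec@radius)^2
    zs <- rep(Inf, n)
    zs[inside] <- spec@radius - sqrt(spec@radius^2 - r2[inside]) +
      phantomRelief(spec, pos[inside, 1], pos[inside, 2])
    inside & pos[, 3] <= zs
  }
  lo <- rep(NA_real_, n)
  hi <- rep(NA_real_, n)
  found <- rep(FALSE, n)
  prev <- rep(0, n)
  for (k in 2:nCoarse) {
    hit <- !found & below(rep(tsGrid[k], n))
    lo[hit] <- prev[hit]
    hi[hit] <- tsGrid[k]
    found <- found | hit
    prev[!found] <- tsGrid[k]
    if (all(found)) break
  }
  valid <- found
  if (any(valid)) {
    idx <- which(valid)
    l <- lo[idx]; u <- hi[idx]
    tv <- tips[idx, , drop = FALSE]
    dv <- dirs[idx, , drop = FALSE]
    gfun <- function(tt) {
      pos <- tv + dv * tt
      r2 <- pos[, 1]^2 + pos[, 2]^2
      zs <- spec@radius - sqrt(pmax(spec@radius^2 - r2, 0)) +
        phantomRelief(spec, pos[, 1], pos[, 2])
      pos[, 3] - zs
    }
    for (it in 1:60) {
      mid <- (l + u) / 2
      gm <- gfun(mid)
      up <- gm > 0
      l[up] <- mid[up]
      u[!up] <- mid[!up]
    }
    dTrue <- (l + u) / 2
  } else {
    dTrue <- numeric(0)
    idx <- integer(0)
  }
  set.seed(seed)
  noise <- rnorm(length(dTrue), 0, noiseSd)
  tstamp <- (seq_len(n) - 1) / frequency
  log <- probeLog(data.frame(t = tstamp[idx],
                             x = tips[idx, 1], y = tips[idx, 2],
                             z = tips[idx, 3],
                             vx = dirs[idx, 1], vy = dirs[idx, 2],
                             vz = dirs[idx, 3],
                             d = dTrue + noise))
  contact <- pointCloud(tips[idx, , drop = FALSE] +
                          dirs[idx, , drop = FALSE] * dTrue,
                        frame = "robot")
  list(log = log, contact = contact, nInvalid = sum(!valid))
}

#' Rasterise a surface cloud into a synthetic OCT volume
#'
#' Builds a C-scan intensity volume in which, for every A-scan, voxels at
#' and below the surface (towards -z, the imaging direction) are bright
#' and voxels above are dark, so that the first bright voxel per A-scan is
#' the quantised surface. A-scan lateral positions are
#' \code{origin + index * voxelDim}; the axial index of a surface point at
#' height z is \code{round((zTop - z) / dz)}, placing the extracted
#' surface within dz/2 of the input.
#'
#' @param cloud surface \linkS4class{PointCloud3D}, one point per A-scan
#'   (grid-sampled).
#' @param voxelDims voxel size (dx, dy, dz), mm.
#' @param depthPx axial pixel count.
#' @param zTop z coordinate of axial index 0 (default: max surface z plus
#'   one voxel).
#' @param bright,dark intensity values.
#' @return list with \code{volume} (\linkS4class{OctVolume}), \code{zTop}
#'   and the lateral \code{origin} used.
#' @export
rasterizeVolume <- function(cloud, voxelDims, depthPx, zTop = NULL,
                            bright = 1, dark = 0) {
  m <- asCoordMatrix(cloud)
  if (nrow(m) == 0) stop("cannot rasterise an empty cloud")
  vd <- as.numeric(voxelDims)
  origin <- c(min(m[, 1]), min(m[, 2]))
  ix <- as.integer(round((m[, 1] - origin[1]) / vd[1]))
  iy <- as.integer(round((m[, 2] - origin[2]) / vd[2]))
  nx <- max(ix) + 1L
  ny <- max(iy) + 1L
  if (is.null(zTop)) zTop <- max(m[, 3]) + vd[3]
  iz <- as.integer(round((zTop - m[, 3]) / vd[3]))
  badz <- iz < 0 | iz >= depthPx
  if (any(badz))
    stop("surface outside axial range for A-scan index(es): ",
         paste(head(which(badz), 5), collapse = ", "))
  vol <- array(dark, dim = c(nx, ny, depthPx))
  surf <- matrix(NA_integer_, nx, ny)
  surf[cbind(ix + 1L, iy + 1L)] <- iz
  for (j in seq_len(ny)) {
    s <- surf[, j]
    ok <- which(!is.na(s))
    for (i in ok) vol[i, j, (s[i] + 1L):depthPx] <- bright
  }
  list(volume = octVolume(vol, voxelDims = vd,
                          intensityRange = range(c(dark, bright))),
       zTop = zTop, origin = origin)
}

#' Synthesise an iiOCT M-scan image from distances
#'
#' Builds the 2D intensity image (depth x time) whose columns are
#' temporally consecutive A-scans: pixels at and beyond the measured
#' distance are bright. The first bright pixel of column i is
#' \code{round(d_i / dz)}, so segmentation recovers the distances to
#' within dz/2.
#'
#' @param distances tip-to-retina distances, mm.
#' @param dz axial pixel size, mm.
#' @param depthPx axial pixel count.
#' @param bright,dark intensity values.
#' @return depthPx x length(distances) matrix.
#' @export
makeMscan <- function(distances, dz, depthPx, bright = 1, dark = 0) {
  idx <- as.integer(round(distances / dz))
  if (any(idx < 0 | idx >= depthPx))
    stop("distance outside axial range for column(s): ",
         paste(head(which(idx < 0 | idx >= depthPx), 5), collapse = ", "))
  img <- matrix(dark, depthPx, length(distances))
  for (i in seq_along(idx)) img[(idx[i] + 1L):depthPx, i] <- bright
  img
}
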