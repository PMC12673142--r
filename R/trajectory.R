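#' @include AllClasses.R utils.R
NULL

newTrajectory <- function(tips, dirs = NULL, pattern, spacing,
                          metadata = list()) {
  tips <- as.matrix(tips)
  if (is.null(dirs)) dirs <- matrix(rep(c(0, 0, -1), each = nrow(tips)),
                                    ncol = 3)
  new("Trajectory", tipPositions = tips, orientations = dirs,
      pattern = pattern, nominalSpacing = spacing, metadata = metadata)
}

#' Polyline path length of a trajectory
#'
#' @param traj a \linkS4class{Trajectory}.
#' @return total length of the tip polyline in mm.
#' @export
pathLength <- function(traj) {
  m <- tipPositions(traj)
  if (nrow(m) < 2) return(0)
  sum(rowNorms(m[-1, , drop = FALSE] - m[-nrow(m), , drop = FALSE]))
}

#' Serpentine raster grid trajectory
#'
#' Parallel scan lines at the given pitch covering a square field,
#' serpentine-connected, sampled at the pitch along track so consecutive
#' points (including the single transit point step between lines) are one
#' pitch apart. When the pitch divides the field evenly both boundary
#' lines are included (a 10 mm field at 50 um pitch gives 201 lines);
#' otherwise lines start at the field edge and stop at the last multiple
#' of the pitch inside the field. The planar grid lies at z = 0 until
#' projected onto a sphere.
#'
#' @param fieldMm square field side length, mm.
#' @param pitchMm point and line spacing, mm.
#' @param center lateral (x, y) centre of the field.
#' @return a \linkS4class{Trajectory} with pattern \code{"grid"}.
#' @export
makeGridTrajectory <- function(fieldMm, pitchMm, center = c(0, 0)) {
  if (pitchMm <= 0) stop("pitch must be positive")
  if (pitchMm > fieldMm) stop("pitch must not exceed the field size")
  g <- seq(0, fieldMm + 1e-9, by = pitchMm)
  g <- g[g <= fieldMm + 1e-9] - fieldMm / 2
  nl <- length(g)
  xs <- vector("list", nl)
  for (k in seq_len(nl)) {
    xk <- g
    if (k %% 2 == 0) xk <- rev(xk)
    xs[[k]] <- cbind(xk + center[1], g[k] + center[2])
  }
  tips <- do.call(rbind, xs)
  newTrajectory(cbind(tips, 0), pattern = "grid", spacing = pitchMm,
                metadata = list(field = fieldMm, pitch = pitchMm,
                                nLines = nl, center = center))
}

#' Archimedean spiral trajectory
#'
#' Spiral \eqn{r(\theta) = r_{max}\,\theta / (2\pi n)} starting at the
#' centre and ending at the final radius after \code{nCoils} coils,
#' resampled to uniform arc-length spacing. The start and end points are
#' always included.
#'
#' @param nCoils number of coils (>= 1).
#' @param rMax final radius, mm.
#' @param spacing arc-length sample spacing, mm.
#' @param center lateral (x, y) centre.
#' @return a \linkS4class{Trajectory} with pattern \code{"spiral"}.
#' @export
makeSpiralTrajectory <- function(nCoils, rMax, spacing, center = c(0, 0)) {
  if (nCoils < 1 || rMax <= 0 || spacing <= 0)
    stop("nCoils >= 1, rMax > 0 and spacing > 0 required")
  thetaMax <- 2 * pi * nCoils
  a <- rMax / thetaMax
  # dense parameter grid, cumulative arc length, inverse interpolation
  th <- seq(0, thetaMax, length.out = max(2000L, 200L * nCoils))
  seg <- sqrt(diff(a * th * cos(th))^2 + diff(a * th * sin(th))^2)
  s <- c(0, cumsum(seg))
  total <- s[length(s)]
  sOut <- unique(c(seq(0, total, by = spacing), total))
  thOut <- approx(s, th, xout = sOut, ties = "ordered")$y
  r <- a * thOut
  tips <- cbind(r * cos(thOut) + center[1], r * sin(thOut) + center[2], 0)
  newTrajectory(tips, pattern = "spiral", spacing = spacing,
                metadata = list(nCoils = nCoils, rMax = rMax,
                                center = center))
}

#' Concatenate trajectories into a composite
#'
#' @param ... \linkS4class{Trajectory} objects, traversed in order.
#' @param pattern tag for the result.
#' @return a composite \linkS4class{Trajectory}; the nominal spacing is
#'   taken from the first part.
#' @export
composeTrajectories <- function(..., pattern = "composite") {
  parts <- list(...)
  newTrajectory(do.call(rbind, lapply(parts, tipPositions)),
                do.call(rbind, lapply(parts, orientations)),
                pattern = pattern, spacing = parts[[1]]@nominalSpacing,
                metadata = list(parts = lapply(parts, function(p) p@pattern)))
}

#' Project a planar trajectory onto a sphere
#'
#' Maps each lateral position onto the lower (retina-side) hemisphere of
#' the sphere and retracts the tip by the standoff along the inward
#' normal, so tips sit at distance \code{radius - standoff} from the
#' centre, close to the retinal surface. Beam orientations point from the
#' tip radially towards the surface (away from the sphere centre).
#'
#' @param traj planar \linkS4class{Trajectory} (z ignored).
#' @param sphere target \linkS4class{SphereFit}.
#' @param standoffMm tip standoff above the surface, mm.
#' @return a \linkS4class{Trajectory} of tilted poses.
#' @export
projectToSphere <- function(traj, sphere, standoffMm = 1) {
  tips <- tipPositions(traj)
  ctr <- sphereCenter(sphere)
  r <- sphereRadius(sphere)
  dx <- tips[, 1] - ctr[1]
  dy <- tips[, 2] - ctr[2]
  rho2 <- dx^2 + dy^2
  out <- rho2 >= r^2
  if (any(out))
    stop("trajectory point(s) outside the sphere equator: ",
         paste(head(which(out), 5), collapse = ", "))
  zs <- ctr[3] - sqrt(r^2 - rho2)
  surf <- cbind(tips[, 1], tips[, 2], zs)
  outward <- (surf - matrix(ctr, nrow(surf), 3, byrow = TRUE)) / r
  newTrajectory(surf - standoffMm * outward, outward,
                pattern = traj@pattern, spacing = traj@nominalSpacing,
                metadata = c(traj@metadata,
                             list(standoff = standoffMm,
                                  sphereRadius = r)))
}

#' Subsample a trajectory to a larger spacing
#'
#' Greedy arc-length rule: walk the polyline and keep a point whenever the
#' cumulative distance since the last kept point reaches the target. The
#' first point is always kept. Emulates higher tip velocities at a fixed
#' A-scan frequency.
#'
#' @param traj a \linkS4class{Trajectory}.
#' @param targetSpacing requested spacing, mm (>= native spacing).
#' @return the subsampled \linkS4class{Trajectory}.
#' @export
subsampleSpacing <- function(traj, targetSpacing) {
  if (targetSpacing < traj@nominalSpacing)
    stop("target spacing must be >= the native spacing")
  if (targetSpacing == traj@nominalSpacing) return(traj)
  m <- tipPositions(traj)
  n <- nrow(m)
  keep <- logical(n)
  keep[1] <- TRUE
  acc <- 0
  for (i in 2:n) {
    acc <- acc + vnorm(m[i, ] - m[i - 1, ])
    if (acc >= targetSpacing - 1e-12) {
      keep[i] <- TRUE
      acc <- 0
    }
  }
  newTrajectory(m[keep, , drop = FALSE],
                orientations(traj)[keep, , drop = FALSE],
                pattern = traj@pattern, spacing = targetSpacing,
                metadata = c(traj@metadata,
                             list(subsampledFrom = traj@nominalSpacing)))
}

#' Acquisition time of a trajectory
#'
#' Total polyline path length divided by the tip velocity. When the
#' timing model lacks an explicit velocity it is derived as spacing times
#' frequency (e.g. 50 um at 40 Hz gives 2 mm/s).
#'
#' @param traj a \linkS4class{Trajectory}.
#' @param timing a \linkS4class{TimingModel}.
#' @return acquisition time in seconds.
#' @examples
#' t1 <- makeGridTrajectory(10, 0.05)
#' acquisitionTime(t1, timingModel(40, velocity = 2))  # 1010 s
#' @export
acquisitionTime <- function(traj, timing) {
  if (timing@velocity <= 0) stop("velocity must be positive")
  pathLength(traj) / timing@velocity
}
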