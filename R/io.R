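#' @include AllClasses.R utils.R
NULL

## On-disk formats. All coordinates are written in mm. ASCII PLY uses
## float64 vertex properties plus an optional uchar label property whose
## code table is kept in a "comment label_map" header line, so labelled
## clouds round-trip losslessly. Point order is preserved exactly.

#' Read a point cloud from ASCII PLY or CSV
#'
#' @param path file path.
#' @param format \code{"ply"} or \code{"csv"}; default guessed from the
#'   file extension.
#' @return a \linkS4class{PointCloud3D} preserving file point order.
#' @export
readPointCloud <- function(path, format = c("auto", "ply", "csv")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.ply$", path, ignore.case = TRUE)) "ply" else "csv"
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "ply") readPly(path) else readCloudCsv(path)
}

readPly <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) == 0 || trimws(lines[1]) != "ply")
    stop("parse error at line 1: not a PLY file: ", path)
  endHdr <- which(trimws(lines) == "end_header")[1]
  if (is.na(endHdr)) stop("parse error: PLY header without end_header: ", path)
  hdr <- lines[seq_len(endHdr)]
  nv <- NA_integer_
  props <- character(0)
  frame <- "oct"
  labelMap <- NULL
  for (i in seq_along(hdr)) {
    tok <- strsplit(trimws(hdr[i]), "\\s+")[[1]]
    if (length(tok) == 0) next
    if (tok[1] == "format" && tok[2] != "ascii")
      stop("parse error at line ", i, ": only ASCII PLY is supported")
    if (tok[1] == "element" && tok[2] == "vertex") nv <- as.integer(tok[3])
    if (tok[1] == "property") props <- c(props, tok[3])
    if (tok[1] == "comment" && length(tok) >= 3 && tok[2] == "frame")
      frame <- tok[3]
    if (tok[1] == "comment" && length(tok) >= 3 && tok[2] == "label_map") {
      kv <- strsplit(tok[-(1:2)], "=")
      labelMap <- vapply(kv, `[`, "", 2)
      names(labelMap) <- vapply(kv, `[`, "", 1)
    }
  }
  if (is.na(nv)) stop("parse error: PLY header lacks 'element vertex': ", path)
  if (nv == 0) stop("empty cloud in ", path)
  if (!all(c("x", "y", "z") %in% props))
    stop("parse error: PLY vertex needs x, y, z properties: ", path)
  body <- lines[(endHdr + 1):length(lines)]
  body <- body[nzchar(trimws(body))]
  if (length(body) < nv)
    stop("parse error at line ", endHdr + length(body) + 1,
         ": expected ", nv, " vertices, found ", length(body))
  fields <- strsplit(trimws(body[seq_len(nv)]), "\\s+")
  npr <- length(props)
  bad <- which(lengths(fields) != npr)
  if (length(bad))
    stop("parse error at line ", endHdr + bad[1], ": expected ", npr,
         " fields")
  vals <- matrix(suppressWarnings(as.numeric(unlist(fields))), nv, npr,
                 byrow = TRUE)
  if (anyNA(vals[, match(c("x", "y", "z"), props)]))
    stop("parse error: non-numeric vertex coordinate in ", path)
  xyz <- vals[, match(c("x", "y", "z"), props), drop = FALSE]
  labs <- character(0)
  if ("label" %in% props) {
    code <- as.character(as.integer(vals[, match("label", props)]))
    labs <- if (is.null(labelMap)) code else unname(labelMap[code])
  }
  pointCloud(xyz, labels = labs, frame = frame)
}

readCloudCsv <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("x", "y", "z")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("parse error in ", path, ": missing column(s) ",
         paste(miss, collapse = ", "))
  if (nrow(df) == 0) stop("empty cloud in ", path)
  xyz <- as.matrix(df[, need])
  if (anyNA(xyz)) stop("parse error in ", path, ": non-numeric coordinate")
  pointCloud(xyz,
             labels = if ("label" %in% names(df)) as.character(df$label)
                      else character(0))
}

#' Write a point cloud to ASCII PLY or CSV
#'
#' Lossless to full double precision (17 significant digits). A label
#' column/property is emitted when the cloud is labelled.
#'
#' @param cloud a non-empty \linkS4class{PointCloud3D}.
#' @param path output path.
#' @param format \code{"ply"} or \code{"csv"}; default from extension.
#' @return \code{path}, invisibly.
#' @export
writePointCloud <- function(cloud, path, format = c("auto", "ply", "csv")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.ply$", path, ignore.case = TRUE)) "ply" else "csv"
  if (nPoints(cloud) == 0) stop("refusing to write an empty cloud")
  m <- coords(cloud)
  labs <- pointLabels(cloud)
  if (format == "csv") {
    df <- data.frame(x = m[, 1], y = m[, 2], z = m[, 3])
    if (length(labs)) df$label <- labs
    write.csv(format(df, digits = 17, trim = TRUE), path, row.names = FALSE,
              quote = FALSE)
    return(invisible(path))
  }
  hdr <- c("ply", "format ascii 1.0",
           paste("comment frame", frameTag(cloud)))
  fmt <- function(v) sprintf("%.17g", v)
  if (length(labs)) {
    lev <- sort(unique(labs))
    code <- match(labs, lev) - 1L
    hdr <- c(hdr, paste("comment label_map",
                        paste(seq_along(lev) - 1L, lev, sep = "=",
                              collapse = " ")))
  }
  hdr <- c(hdr, paste("element vertex", nrow(m)),
           "property double x", "property double y", "property double z")
  if (length(labs)) hdr <- c(hdr, "property uchar label")
  body <- if (length(labs))
    paste(fmt(m[, 1]), fmt(m[, 2]), fmt(m[, 3]), code)
  else paste(fmt(m[, 1]), fmt(m[, 2]), fmt(m[, 3]))
  writeLines(c(hdr, "end_header", body), path)
  invisible(path)
}

#' Read an OCT volume from multi-page TIFF plus JSON sidecar
#'
#' The TIFF stores one page per slow-lateral (y) position; each page is a
#' depthPx x nx matrix (rows axial, columns fast lateral). The sidecar
#' declares \code{nx}, \code{ny}, \code{depth_px} and the voxel dimensions
#' \code{dx_um}, \code{dy_um}, \code{dz_um} in micrometres, plus the
#' intensity \code{range}.
#'
#' @param pathTiff TIFF path.
#' @param pathJson sidecar path.
#' @return an \linkS4class{OctVolume}; voxel dimensions are converted to mm.
#' @export
readOctVolume <- function(pathTiff, pathJson) {
  if (!file.exists(pathJson)) stop("missing sidecar: ", pathJson)
  if (!file.exists(pathTiff)) stop("missing volume: ", pathTiff)
  meta <- jsonlite::fromJSON(pathJson)
  need <- c("nx", "ny", "depth_px", "dx_um", "dy_um", "dz_um")
  miss <- setdiff(need, names(meta))
  if (length(miss))
    stop("sidecar lacks field(s): ", paste(miss, collapse = ", "))
  pages <- tiff::readTIFF(pathTiff, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  tiffShape <- c(ncol(pages[[1]]), length(pages), nrow(pages[[1]]))
  declShape <- c(meta$nx, meta$ny, meta$depth_px)
  if (!all(tiffShape == declShape))
    stop(sprintf("shape mismatch: TIFF is (nx=%d, ny=%d, depth=%d) but sidecar declares (nx=%d, ny=%d, depth=%d)",
                 tiffShape[1], tiffShape[2], tiffShape[3],
                 declShape[1], declShape[2], declShape[3]))
  rng <- if (!is.null(meta$range)) as.numeric(meta$range) else c(0, 1)
  vol <- array(0, dim = declShape)
  for (j in seq_len(meta$ny))
    vol[, j, ] <- t(pages[[j]])  # page rows = axial -> third array index
  vol <- rng[1] + vol * diff(rng)
  octVolume(vol, voxelDims = c(meta$dx_um, meta$dy_um, meta$dz_um) / 1000,
            intensityRange = rng)
}

#' Write an OCT volume as multi-page TIFF plus JSON sidecar
#'
#' Stored as a 32-bit multi-page TIFF; intensities are mapped to [0, 1]
#' by the declared range and quantised to 32 bits, so round trips are
#' exact to about 2e-10 of the declared range.
#'
#' @param vol an \linkS4class{OctVolume}.
#' @param pathTiff,pathJson output paths.
#' @return \code{pathTiff}, invisibly.
#' @export
writeOctVolume <- function(vol, pathTiff, pathJson) {
  d <- dim(vol@intensity)
  rng <- vol@intensityRange
  pages <- lapply(seq_len(d[2]), function(j)
    t((vol@intensity[, j, ] - rng[1]) / diff(rng)))
  tiff::writeTIFF(pages, pathTiff, bits.per.sample = 32L)
  meta <- list(nx = d[1], ny = d[2], depth_px = d[3],
               dx_um = vol@voxelDims[1] * 1000,
               dy_um = vol@voxelDims[2] * 1000,
               dz_um = vol@voxelDims[3] * 1000,
               range = rng)
  jsonlite::write_json(meta, pathJson, auto_unbox = TRUE, digits = NA)
  invisible(pathTiff)
}

#' Read an iiOCT probe log from CSV
#'
#' Expects columns \code{t, x, y, z, vx, vy, vz, d}: timestamp (s), tip
#' position (mm, robot frame), beam orientation vector (not normalised
#' here; reconstruction normalises) and measured tip-to-retina distance
#' (mm). Rows are kept in file order.
#'
#' @param path CSV path.
#' @return a \linkS4class{ProbeLog}; negative distances or zero orientation
#'   vectors raise a validation error.
#' @export
readProbeLog <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- read.csv(path)
  need <- c("t", "x", "y", "z", "vx", "vy", "vz", "d")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("parse error in ", path, ": missing column(s) ",
         paste(miss, collapse = ", "))
  probeLog(df[, need])
}

#' Write an iiOCT probe log to CSV
#'
#' @param log a \linkS4class{ProbeLog}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeProbeLog <- function(log, path) {
  write.csv(format(log@samples, digits = 17, trim = TRUE), path,
            row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read landmark annotations from JSON
#'
#' Format: \code{\{"fovea": [x,y,z], "onh": [x,y,z],
#' "fiducials": \{"label": [x,y,z], ...\}\}}, coordinates in mm.
#'
#' @param path JSON path.
#' @return a \linkS4class{Landmarks}.
#' @export
readLandmarks <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  j <- jsonlite::fromJSON(path)
  if (is.null(j$fovea) || is.null(j$onh))
    stop("landmark file must contain fovea and onh: ", path)
  fid <- NULL
  if (!is.null(j$fiducials) && length(j$fiducials)) {
    fid <- do.call(rbind, j$fiducials)
    rownames(fid) <- names(j$fiducials)
  }
  landmarks(j$fovea, j$onh, fid)
}

#' Write landmark annotations to JSON
#'
#' @param lm a \linkS4class{Landmarks}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeLandmarks <- function(lm, path) {
  fid <- lapply(seq_len(nrow(lm@fiducials)),
                function(i) as.numeric(lm@fiducials[i, ]))
  names(fid) <- rownames(lm@fiducials)
  jsonlite::write_json(list(fovea = lm@fovea, onh = lm@onh, fiducials = fid),
                       path, auto_unbox = FALSE, digits = NA)
  invisible(path)
}
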