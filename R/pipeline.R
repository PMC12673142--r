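#' @include AllClasses.R phantom.R extract.R curvature.R register.R evaluate.R trajectory.R
NULL

#' Pipeline configuration for the synthetic end-to-end experiment
#'
#' Bundles every stage setting of the phantom registration experiment:
#' the eye phantom, the diagnostic-scan resolution, the robot trajectory
#' (T1: 10 mm grid; T2: 5 mm fovea grid plus 2 mm ONH patch; spiral),
#' the sample spacing (S1/S2/S3 are 50/150/300 um, derived from the dense
#' 50 um scan by subsampling), the frame offset separating the diagnostic
#' from the robot frame, and the registration settings. All randomness
#' derives from the single \code{seed}.
#'
#' The ICP correspondence threshold defaults to
#' \code{max(20 um, 2 x spacing)}: nearest-neighbour distances to a
#' target sampled at spacing S cannot fall below about S/2 even under
#' perfect alignment, so the dense-scan default of 20 um is widened to
#' the sampling scale of the run.
#'
#' @param seed top-level RNG seed.
#' @param trajectory \code{"T1"}, \code{"T2"} or \code{"spiral"}.
#' @param spacing iiOCT sample spacing in mm (0.05, 0.15 or 0.30).
#' @param cc apply curvature correction.
#' @param method fine registration: \code{"icp"} or \code{"cpd"}.
#' @param phantom an \linkS4class{EyePhantomSpec}.
#' @param octField,octSpacing lateral field and grid spacing of the
#'   diagnostic scan, mm.
#' @param denseSpacing native spacing of the dense robot scan, mm.
#' @param standoff probe-tip standoff above the retina, mm.
#' @param octOffset \linkS4class{RigidTransform} carrying the diagnostic
#'   cloud out of the robot frame (what initial alignment must undo);
#'   NULL for the default (10 deg z-rotation, 2 deg tilt, a few mm of
#'   translation).
#' @param icp an \code{\link{icpControl}} list; its correspondence
#'   threshold is widened to \code{max(threshold, 2 x spacing)}.
#' @param cpd a \code{\link{cpdControl}} list.
#' @return a named list of class \code{"pipelineConfig"}.
#' @export
pipelineConfig <- function(seed = 1L, trajectory = "T1", spacing = 0.05,
                           cc = TRUE, method = c("icp", "cpd"),
                           phantom = NULL, octField = 10, octSpacing = 0.1,
                           denseSpacing = 0.05, standoff = 1,
                           octOffset = NULL, icp = icpControl(),
                           cpd = cpdControl()) {
  method <- match.arg(method)
  if (is.null(phantom)) phantom <- eyePhantomSpec(seed = seed)
  if (is.null(octOffset))
    octOffset <- rigidTransform(
      rotationAboutAxis(c(0, 0, 1), 10 * pi / 180) %*%
        rotationAboutAxis(c(1, 0, 0), 2 * pi / 180),
      c(1.0, -0.5, 0.3))
  structure(list(seed = as.integer(seed), trajectory = trajectory,
                 spacing = spacing, cc = cc, method = method,
                 phantom = phantom, octField = octField,
                 octSpacing = octSpacing, denseSpacing = denseSpacing,
                 standoff = standoff, octOffset = octOffset, icp = icp,
                 cpd = cpd),
            class = "pipelineConfig")
}

## ---- internal stage builders (shared between runPipeline and runAblation)

## diagnostic-OCT side: true surface, distorted cloud, frame offset,
## landmarks in both frames
buildOctSide <- function(config) {
  spec <- config$phantom
  tr <- generateTrueSurface(spec, config$octField, config$octSpacing)
  trueLm <- tr$landmarks
  distorted <- distortSurface(tr$cloud, spec)
  lmPts <- rbind(trueLm@fovea, trueLm@onh, trueLm@fiducials)
  lmDist <- coords(distortSurface(pointCloud(unname(lmPts)), spec))
  octCloud <- applyTransform(config$octOffset, distorted, frame = "oct")
  lmOff <- applyTransform(config$octOffset, lmDist)
  fid <- lmOff[-(1:2), , drop = FALSE]
  rownames(fid) <- rownames(trueLm@fiducials)
  octLm <- landmarks(lmOff[1, ], lmOff[2, ],
                     if (nrow(fid)) fid else NULL)
  retina <- pointLabels(octCloud) != "fiducial"
  list(spec = spec, trueCloud = tr$cloud, trueLm = trueLm,
       octCloud = octCloud, octLm = octLm, retinaIdx = which(retina),
       octFit = fitSphere(coords(octCloud)[retina, , drop = FALSE]))
}

## robot trajectory for a named pattern, planar then sphere-projected
buildTrajectory <- function(config, spec) {
  base <- switch(config$trajectory,
    T1 = makeGridTrajectory(10, config$denseSpacing),
    T2 = composeTrajectories(
      makeGridTrajectory(5, config$denseSpacing),
      makeGridTrajectory(2, config$denseSpacing, center = spec@onhOffset),
      pattern = "patch"),
    spiral = makeSpiralTrajectory(5, 5, config$denseSpacing),
    stop("unknown trajectory: ", config$trajectory))
  projectToSphere(base, sphereFit(c(0, 0, spec@radius), spec@radius),
                  standoffMm = config$standoff)
}

## iiOCT side: dense sampling then spacing subsampling of the log
buildIioctSide <- function(config, octSide) {
  traj <- buildTrajectory(config, octSide$spec)
  samp <- sampleIioct(octSide$spec, traj, seed = config$seed + 77L)
  log <- samp$log
  if (config$spacing > config$denseSpacing) {
    keep <- subsampleIndices(tipPositions(log), config$spacing)
    log <- probeLog(log@samples[keep, ])
  }
  cloud <- reconstructIioct(log)
  list(traj = traj, log = log, cloud = cloud, fit = fitSphere(cloud),
       nInvalid = samp$nInvalid)
}

subsampleIndices <- function(m, targetSpacing) {
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
  which(keep)
}

## curvature correction + initial alignment + fine registration + metrics
registerAndEvaluate <- function(config, octSide, iiSide) {
  octCloud <- octSide$octCloud
  octLm <- octSide$octLm
  octFit <- octSide$octFit
  field <- NULL
  if (config$cc) {
    target <- buildTargetSphere(octFit, octLm@fovea,
                                sphereRadius(iiSide$fit))
    ccRes <- correctCurvature(octCloud, octFit, target, fovea = octLm@fovea)
    octCloud <- ccRes$cloud
    field <- ccRes$field
    lmPts <- rbind(octLm@fovea, octLm@onh, octLm@fiducials)
    lmCC <- correctCurvature(pointCloud(unname(lmPts)), octFit, target,
                             fovea = octLm@fovea)$cloud
    fid <- coords(lmCC)[-(1:2), , drop = FALSE]
    rownames(fid) <- rownames(octLm@fiducials)
    octLm <- landmarks(coords(lmCC)[1, ], coords(lmCC)[2, ],
                       if (nrow(fid)) fid else NULL)
    octFit <- fitSphere(coords(octCloud)[octSide$retinaIdx, , drop = FALSE])
  }
  ia <- initialAlign(octCloud, octLm, octFit, landmarks(
         octSide$trueLm@fovea, octSide$trueLm@onh), iiSide$fit)
  aligned <- ia$cloud
  alignedRetina <- coords(aligned)[octSide$retinaIdx, , drop = FALSE]
  markers <- applyTransform(ia$transform, unname(octLm@fiducials))
  thr <- max(config$icp$correspondenceThreshold, 2 * config$spacing)
  ctl <- config$icp
  ctl$correspondenceThreshold <- thr
  if (config$method == "icp") {
    normals <- estimateNormals(iiSide$cloud, k = ctl$normalK)
    icp <- icpPointToPlane(alignedRetina, iiSide$cloud, normals,
                           control = ctl)
    finalRetina <- coords(icp$cloud)
    markers <- applyTransform(icp$transform, markers)
    fineInfo <- list(method = "icp", iterations = nrow(icp$history),
                     finalRmseUm = tail(icp$history$rmse, 1) * 1000,
                     transform = composeTransform(icp$transform,
                                                  ia$transform))
  } else {
    sparse <- voxelDownsample(alignedRetina, config$cpd$downsampleSpacing)
    cpd <- suppressWarnings(
      cpdNonrigid(sparse, coords(iiSide$cloud), control = config$cpd))
    dense <- densifyDeformation(alignedRetina, sparse, cpd$displacements,
                                knn = config$cpd$knnDensify)
    finalRetina <- alignedRetina + dense
    markers <- markers + densifyDeformation(markers, sparse,
                                            cpd$displacements,
                                            knn = config$cpd$knnDensify)
    fineInfo <- list(method = "cpd", iterations = cpd$iterations,
                     converged = cpd$converged, sigma2 = cpd$sigma2,
                     transform = ia$transform)
  }
  # a diverged registration can carry the cloud off the shared axis; the
  # Chamfer distance is then reported uncropped (and is accordingly large)
  crop <- tryCatch(cropCylinder(pointCloud(finalRetina), iiSide$cloud,
                                octSide$trueLm@fovea),
                   error = function(e) list(a = pointCloud(finalRetina),
                                            b = iiSide$cloud,
                                            cropRadius = NA_real_))
  cd <- chamferDistance(crop$a, crop$b)
  perPoint <- knnSearch(iiSide$cloud, finalRetina, 1L)$distance[, 1] * 1000
  mf <- mfme(markers, octSide$trueLm@fiducials)
  list(report = list(
         trajectory = config$trajectory,
         spacingUm = config$spacing * 1000,
         cc = config$cc, method = config$method,
         rIioct = sphereRadius(iiSide$fit),
         rOctBefore = sphereRadius(octSide$octFit),
         rOctAfter = sphereRadius(octFit),
         mfmeUm = mf, chamferUm = cd, cropRadiusMm = crop$cropRadius,
         nPointsOct = nPoints(octSide$octCloud),
         nPointsIioct = nPoints(iiSide$cloud),
         nInvalidRays = iiSide$nInvalid,
         correspondenceThresholdMm = thr,
         fine = fineInfo[setdiff(names(fineInfo), "transform")]),
       markers = markers, perPointUm = perPoint,
       finalCloud = pointCloud(finalRetina, frame = "robot"),
       transform = fineInfo$transform, field = field, octLm = octLm)
}

#' Run the full synthetic registration pipeline
#'
#' Generates the phantom, the distorted diagnostic scan and the robotic
#' iiOCT sampling, then runs feature extraction (probe-pose
#' reconstruction), optional curvature correction, landmark initial
#' alignment, fine registration and evaluation. With an output directory
#' the stage artifacts (clouds as PLY, transform and metrics as JSON, the
#' deformation field as CSV when CC is on, and a run log) are written.
#'
#' @param config a \code{\link{pipelineConfig}}.
#' @param outDir optional output directory (created if needed).
#' @return list with \code{report} (metrics and stage summaries),
#'   \code{perPointUm} (per-OCT-point nearest-neighbour distances),
#'   \code{markers}, \code{finalCloud}, \code{transform} and (CC runs)
#'   \code{field}.
#' @export
runPipeline <- function(config = pipelineConfig(), outDir = NULL) {
  octSide <- buildOctSide(config)
  iiSide <- buildIioctSide(config, octSide)
  res <- registerAndEvaluate(config, octSide, iiSide)
  if (!is.null(outDir)) {
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    writePointCloud(octSide$octCloud, file.path(outDir, "oct_input.ply"))
    writePointCloud(iiSide$cloud, file.path(outDir, "iioct.ply"))
    writePointCloud(res$finalCloud, file.path(outDir, "oct_registered.ply"))
    writeProbeLog(iiSide$log, file.path(outDir, "probe_log.csv"))
    writeLandmarks(octSide$trueLm, file.path(outDir, "landmarks_robot.json"))
    tf <- res$transform
    jsonlite::write_json(list(rotationRowMajor = as.vector(t(tf@rotation)),
                              translation = tf@translation),
                         file.path(outDir, "transform.json"),
                         auto_unbox = TRUE, digits = NA)
    if (!is.null(res$field)) {
      v <- deformationVectors(res$field)
      write.csv(data.frame(idx = seq_len(nrow(v)), ex = v[, 1],
                           ey = v[, 2], ez = v[, 3]),
                file.path(outDir, "deformation.csv"), row.names = FALSE)
    }
    jsonlite::write_json(res$report, file.path(outDir, "metrics.json"),
                         auto_unbox = TRUE, digits = 10, pretty = TRUE)
    writeLines(c(sprintf("retinareg %s", as.character(utils::packageVersion("retinareg"))),
                 sprintf("seed %d", config$seed),
                 sprintf("trajectory %s spacing %g mm cc %s method %s",
                         config$trajectory, config$spacing, config$cc,
                         config$method),
                 sprintf("icp threshold %g mm (configured %g mm)",
                         res$report$correspondenceThresholdMm,
                         config$icp$correspondenceThreshold),
                 sprintf("cpd alpha %g beta %g w %g cap %d",
                         config$cpd$alpha, config$cpd$beta, config$cpd$w,
                         config$cpd$maxEmIterations)),
               file.path(outDir, "run_log.txt"))
  }
  res
}

#' Run a trajectory/spacing/CC ablation
#'
#' Executes the pipeline for every requested combination of trajectory,
#' spacing and curvature-correction flag on one shared phantom (matched
#' seeds), mirroring a with/without-CC comparison table: one row per
#' variant with MFME and Chamfer distance, and, on CC rows, the error
#' reduction relative to the matched non-CC run,
#' \code{100 * (without - with) / without}. Failed variants yield NA rows
#' and the run continues.
#'
#' @param config base \code{\link{pipelineConfig}} (trajectory, spacing
#'   and cc fields are overridden per variant).
#' @param variants data.frame with columns \code{trajectory},
#'   \code{spacing}, \code{cc} and optionally \code{method}.
#' @param outCsv optional path for the comparison table.
#' @return data.frame with one row per variant: trajectory, spacingUm,
#'   cc, method, mfmeUm, chamferUm, mfmeReductionPct, cdReductionPct.
#' @export
runAblation <- function(config = pipelineConfig(), variants = NULL,
                        outCsv = NULL) {
  if (is.null(variants))
    variants <- expand.grid(trajectory = c("T1", "T2"),
                            spacing = c(0.05, 0.15, 0.30),
                            cc = c(FALSE, TRUE),
                            stringsAsFactors = FALSE)
  if (is.null(variants$method)) variants$method <- config$method
  if (nrow(variants) < 2) stop("need at least 2 variants")
  octSide <- buildOctSide(config)
  iiCache <- list()
  rows <- vector("list", nrow(variants))
  for (i in seq_len(nrow(variants))) {
    v <- variants[i, ]
    cfg <- config
    cfg$trajectory <- v$trajectory
    cfg$spacing <- v$spacing
    cfg$cc <- v$cc
    cfg$method <- v$method
    key <- paste(v$trajectory, v$spacing)
    rows[[i]] <- tryCatch({
      if (is.null(iiCache[[key]]))
        iiCache[[key]] <- buildIioctSide(cfg, octSide)
      r <- registerAndEvaluate(cfg, octSide, iiCache[[key]])$report
      data.frame(trajectory = v$trajectory, spacingUm = v$spacing * 1000,
                 cc = v$cc, method = v$method, mfmeUm = r$mfmeUm,
                 chamferUm = r$chamferUm)
    }, error = function(e) {
      warning("variant ", key, " cc=", v$cc, " failed: ",
              conditionMessage(e))
      data.frame(trajectory = v$trajectory, spacingUm = v$spacing * 1000,
                 cc = v$cc, method = v$method, mfmeUm = NA_real_,
                 chamferUm = NA_real_)
    })
  }
  tab <- do.call(rbind, rows)
  tab$mfmeReductionPct <- NA_real_
  tab$cdReductionPct <- NA_real_
  for (i in which(tab$cc)) {
    j <- which(!tab$cc & tab$trajectory == tab$trajectory[i] &
                 tab$spacingUm == tab$spacingUm[i] &
                 tab$method == tab$method[i])
    if (length(j) == 1 && is.finite(tab$chamferUm[j])) {
      tab$mfmeReductionPct[i] <- 100 * (tab$mfmeUm[j] - tab$mfmeUm[i]) /
        tab$mfmeUm[j]
      tab$cdReductionPct[i] <- 100 * (tab$chamferUm[j] - tab$chamferUm[i]) /
        tab$chamferUm[j]
    }
  }
  if (!is.null(outCsv)) write.csv(tab, outCsv, row.names = FALSE)
  tab
}
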