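# shared fixture builders; everything is generated in code

# points on a sphere cap (upper polar angles), deterministic under seed
sphereSample <- function(n, center = c(0, 0, 0), radius = 1, seed = 1,
                         capAngle = pi / 2) {
  set.seed(seed)
  th <- runif(n, 0, capAngle)
  ph <- runif(n, 0, 2 * pi)
  cbind(center[1] + radius * sin(th) * cos(ph),
        center[2] + radius * sin(th) * sin(ph),
        center[3] + radius * cos(th))
}

# featureless phantom: a pure sphere, no pit/ONH/vessels/wires
bareSpec <- function(...) {
  eyePhantomSpec(foveaDepth = 0, onhDepth = 0, vesselSpec = list(),
                 wireSpec = list(),
                 wireCrossings = matrix(numeric(0), 0, 2), ...)
}

# geometric sphere-fit cost (the quantity fitSphere minimises)
sphereCost <- function(par, m) {
  sum((sqrt(rowSums((m - matrix(par[1:3], nrow(m), 3, byrow = TRUE))^2)) -
         par[4])^2)
}

# fraction of a displacement field not explained by its best-fit rigid
# motion (Kabsch), relative to the raw field magnitude
rigidityRatio <- function(Y, disp) {
  X <- Y + disp
  cy <- colMeans(Y)
  cx <- colMeans(X)
  S <- crossprod(sweep(Y, 2, cy), sweep(X, 2, cx))
  sv <- svd(S)
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  pred <- sweep(sweep(Y, 2, cy) %*% t(R), 2, cx, "+")
  mean(sqrt(rowSums((X - pred)^2))) / mean(sqrt(rowSums(disp^2)))
}

# distance from each point to a sphere surface measured along the line from
# the point towards lineCenter, using the fovea-side (retinal) intersection;
# independent oracle for feature-offset preservation checks
offsetAlongLine <- function(pts, lineCenter, sphere, fovea) {
  u <- sphereCenter(sphere) - fovea
  u <- u / sqrt(sum(u^2))
  vapply(seq_len(nrow(pts)), function(i) {
    hit <- lineSphereIntersect(pts[i, ], lineCenter - pts[i, ], sphere,
                               hemisphereAxis = u)
    j <- hit$points[hit$retinal, , drop = FALSE]
    if (nrow(j) == 0) return(NA_real_)
    min(sqrt(rowSums((j - matrix(pts[i, ], nrow(j), 3, byrow = TRUE))^2)))
  }, numeric(1))
}
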