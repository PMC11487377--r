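# Synthetic three-view knee phantom.
#
# One latent 3-D scene per exam: an ellipsoidal "joint" background (intensity
# 0.3) crossed by a bright diagonal band (the ligament, intensity 1.0) whose
# endpoints are jittered per exam.  A torn exam (label 1) interrupts the band
# with a gap of `gapLength` voxels -- the gap interior reverts to the
# background value -- and adds a small hyperintense blob (intensity 1.25)
# displaced perpendicular to the band beside the gap.  The three views are
# axis-permuted, slice-subsampled renderings of the same scene plus
# independent Gaussian noise, so they are correlated but not identical.

.PHANTOM_BG <- 0.3
.PHANTOM_BAND <- 1.0
.PHANTOM_BLOB <- 1.25

# Per-exam random geometry (all draws from the caller's RNG stream).
.phantom_geometry <- function(params, label) {
  S <- params@spatialSize
  a <- c(0.18, 0.18, 0.32) * S + stats::runif(3, -0.05, 0.05) * S
  b <- c(0.82, 0.82, 0.68) * S + stats::runif(3, -0.05, 0.05) * S
  t0 <- stats::runif(1, 0.35, 0.55)
  list(a = a, b = b, t0 = t0, label = label)
}

# Squared distance of every voxel to the segment a-b plus the projection
# parameter t in [0, 1]; vectorized over the full grid.
.segment_field <- function(S, a, b) {
  g <- seq_len(S)
  xs <- rep(g, times = S * S)
  ys <- rep(rep(g, each = S), times = S)
  zs <- rep(g, each = S * S)
  d <- b - a
  len2 <- sum(d * d)
  t <- ((xs - a[1]) * d[1] + (ys - a[2]) * d[2] + (zs - a[3]) * d[3]) / len2
  tc <- pmin(pmax(t, 0), 1)
  dx <- xs - (a[1] + tc * d[1])
  dy <- ys - (a[2] + tc * d[2])
  dz <- zs - (a[3] + tc * d[3])
  list(dist2 = dx * dx + dy * dy + dz * dz, t = t)
}

.ellipsoid_mask <- function(S) {
  g <- seq_len(S)
  ctr <- (S + 1) / 2
  ax <- c(0.44, 0.38, 0.31) * S
  xs <- rep(g, times = S * S)
  ys <- rep(rep(g, each = S), times = S)
  zs <- rep(g, each = S * S)
  ((xs - ctr) / ax[1])^2 + ((ys - ctr) / ax[2])^2 +
    ((zs - ctr) / ax[3])^2 <= 1
}

# Render the noiseless latent scene for a given geometry.
.phantom_scene <- function(params, geom) {
  S <- params@spatialSize
  scene <- numeric(S^3)
  scene[.ellipsoid_mask(S)] <- .PHANTOM_BG
  sf <- .segment_field(S, geom$a, geom$b)
  band <- sf$dist2 <= (params@bandWidth / 2)^2
  if (geom$label == 1) {
    path_len <- sqrt(sum((geom$b - geom$a)^2))
    gap_frac <- params@gapLength / path_len
    in_gap <- sf$t >= geom$t0 & sf$t <= geom$t0 + gap_frac
    band <- band & !in_gap                      # gap reverts to background
  }
  scene[band] <- .PHANTOM_BAND
  if (geom$label == 1) {
    # hyperintense blob displaced perpendicular to the band at the gap center
    path_len <- sqrt(sum((geom$b - geom$a)^2))
    gap_frac <- params@gapLength / path_len
    tm <- geom$t0 + gap_frac / 2
    ctr <- geom$a + tm * (geom$b - geom$a)
    dirv <- (geom$b - geom$a) / path_len
    perp <- c(dirv[2], -dirv[1], 0)
    perp <- perp / sqrt(sum(perp^2))
    bc <- ctr + perp * (params@bandWidth + 3)
    g <- seq_len(S)
    xs <- rep(g, times = S * S)
    ys <- rep(rep(g, each = S), times = S)
    zs <- rep(g, each = S * S)
    blob <- (xs - bc[1])^2 + (ys - bc[2])^2 + (zs - bc[3])^2 <= 2.5^2
    scene[blob] <- pmax(scene[blob], .PHANTOM_BLOB)
  }
  dim(scene) <- c(S, S, S)
  scene
}

.slice_indices <- function(S, L) round(seq(1, S, length.out = L))

# Extract an L x S x S view from the scene along one axis.
.render_view <- function(scene, view, L) {
  S <- dim(scene)[1]
  idx <- .slice_indices(S, L)
  vol <- switch(view,
    axial    = aperm(scene[, , idx, drop = FALSE], c(3, 1, 2)),
    coronal  = aperm(scene[, idx, , drop = FALSE], c(2, 1, 3)),
    sagittal = scene[idx, , , drop = FALSE])
  vol
}

#' Generate one synthetic three-view exam
#'
#' Renders three correlated views (axial, coronal, sagittal) of one latent
#' phantom scene.  The per-view slice count L is drawn uniformly from
#' \code{layerRange(params)}; each view receives independent additive noise.
#'
#' @param params a \linkS4class{PhantomParams}.
#' @param label 0 (intact band) or 1 (torn: gap plus hyperintense blob).
#' @param seed optional integer; when given, generation is a deterministic
#'   function of \code{(params, label, seed)} and the caller's RNG state is
#'   left untouched.
#' @param examId identifier attached to the three volumes.
#' @return Named list of three \linkS4class{ExamVolume}s with the exam
#'   geometry in \code{attr(, "geometry")}.
#' @examples
#' ex <- generateExam(phantomParams(spatialSize = 32), label = 1, seed = 1)
#' sapply(ex, nLayers)
#' @export
generateExam <- function(params, label, seed = NULL, examId = "exam") {
  stopifnot(label %in% c(0, 1))
  gen <- function() {
    geom <- .phantom_geometry(params, label)
    scene <- .phantom_scene(params, geom)
    out <- list()
    for (v in .VIEWS) {
      L <- sample(seq(params@layerRange[1], params@layerRange[2]), 1L)
      vol <- .render_view(scene, v, L)
      if (params@noiseSd > 0)
        vol <- vol + array(stats::rnorm(length(vol), sd = params@noiseSd),
                           dim(vol))
      out[[v]] <- examVolume(vol, view = v, examId = examId)
    }
    attr(out, "geometry") <- geom
    out
  }
  if (is.null(seed)) gen() else withSubstream(seed, paste0("exam_", examId), gen())
}

#' Noiseless scene and band-path intensity profile
#'
#' Diagnostic helper: renders the latent scene for a given geometry-less
#' draw and returns the intensity sampled along the band's center path.  For
#' an intact exam the profile is uniformly at the band intensity; for a torn
#' exam its minimum drops to the background level inside the gap.
#'
#' @inheritParams generateExam
#' @param nSamples number of path sample points.
#' @return List with \code{scene} (S x S x S array), \code{profile}
#'   (intensity along the path) and \code{geometry}.
#' @export
scenePathProfile <- function(params, label, seed = 1, nSamples = 200) {
  geom <- withSubstream(seed, paste0("exam_", "exam"),
                        .phantom_geometry(params, label))
  scene <- .phantom_scene(params, geom)
  S <- params@spatialSize
  ts <- seq(0, 1, length.out = nSamples)
  pts <- t(sapply(ts, function(t) geom$a + t * (geom$b - geom$a)))
  pts <- pmin(pmax(round(pts), 1), S)
  profile <- scene[cbind(pts[, 1], pts[, 2], pts[, 3])]
  list(scene = scene, profile = profile, geometry = geom)
}

#' Analytic band mask for one view
#'
#' Logical mask of the full (gap-free) band in a rendered view, computed
#' from the exam geometry.  The mean intensity inside this mask is a
#' sufficient statistic separating torn from intact phantoms and serves as
#' the sanity floor for downstream learning tests.
#'
#' @param params a \linkS4class{PhantomParams}.
#' @param geometry geometry list from \code{attr(generateExam(...), "geometry")}.
#' @param view view name.
#' @param L slice count of the rendered view volume.
#' @return Logical \code{L x S x S} array.
#' @export
bandMask <- function(params, geometry, view, L) {
  S <- params@spatialSize
  sf <- .segment_field(S, geometry$a, geometry$b)
  band <- sf$dist2 <= (params@bandWidth / 2)^2
  dim(band) <- c(S, S, S)
  .render_view(band, view, L) > 0
}

#' Generate a synthetic dataset on disk
#'
#' Writes \code{n} exams (three volume files each) plus a CSV manifest into
#' \code{dir}.  The number of positives is \code{round(n * posFraction)} and
#' label order is shuffled deterministically under \code{seed}.
#'
#' @param n number of exams (>= 1).
#' @param params a \linkS4class{PhantomParams}.
#' @param dir output directory (created if needed).
#' @param seed integer master seed.
#' @return The \linkS4class{DatasetManifest} (also written to
#'   \code{file.path(dir, "manifest.csv")}).
#' @export
generateDataset <- function(n, params = phantomParams(), dir, seed = 1) {
  stopifnot(n >= 1)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  npos <- round(n * params@posFraction)
  labels <- c(rep(1L, npos), rep(0L, n - npos))
  labels <- withSubstream(seed, "dataset_labels", sample(labels))
  ids <- sprintf("exam_%04d", seq_len(n))
  paths <- matrix("", n, 3, dimnames = list(NULL, .VIEWS))
  for (i in seq_len(n)) {
    ex <- generateExam(params, labels[i], seed = seed, examId = ids[i])
    for (v in .VIEWS) {
      p <- file.path(dir, sprintf("%s_%s.npy", ids[i], v))
      writeVolume(ex[[v]], p)
      paths[i, v] <- p
    }
  }
  df <- data.frame(exam_id = ids, label = labels,
                   axial = paths[, "axial"], coronal = paths[, "coronal"],
                   sagittal = paths[, "sagittal"],
                   stringsAsFactors = FALSE)
  manifest <- datasetManifest(df)
  writeManifest(manifest, file.path(dir, "manifest.csv"))
  manifest
}
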