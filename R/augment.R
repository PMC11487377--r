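# Dual-scale data augmentation: random crop, normalization, and
# erasing / mixup at the in-plane (spatial) and whole-slice (layer) scales.
# Labels are never touched; augmentation only perturbs intensities.

.block_side <- function(side, ratio, mode) {
  s <- if (mode == "area") side * sqrt(ratio) else side * ratio
  max(0L, min(side, as.integer(round(s))))
}

.draw_beta <- function(alpha) stats::rbeta(1, alpha, alpha)

.as_vol <- function(x) if (is(x, "ExamVolume")) x@data else x

.rewrap <- function(vol, data) {
  if (is(vol, "ExamVolume")) examVolume(data, vol@view, vol@examId) else data
}

#' Random spatial crop
#'
#' Crops all slices of a volume with one shared spatial window whose corner
#' is drawn uniformly among valid positions (e.g. 256 x 256 down to
#' 224 x 224).
#'
#' @param vol an \linkS4class{ExamVolume} or \code{L x H x W} array.
#' @param size crop side in pixels; must not exceed either spatial side.
#' @param center logical; \code{TRUE} takes the deterministic center window
#'   (used at evaluation time).
#' @return Cropped volume of the same class as the input, \code{L x size x
#'   size}.
#' @export
randomCrop <- function(vol, size, center = FALSE) {
  x <- .as_vol(vol)
  d <- dim(x)
  if (size > d[2] || size > d[3])
    stop("crop size ", size, " exceeds input side ", min(d[2], d[3]))
  if (center) {
    oh <- (d[2] - size) %/% 2L
    ow <- (d[3] - size) %/% 2L
  } else {
    oh <- sample.int(d[2] - size + 1L, 1L) - 1L
    ow <- sample.int(d[3] - size + 1L, 1L) - 1L
  }
  .rewrap(vol, x[, oh + seq_len(size), ow + seq_len(size), drop = FALSE])
}

#' Standardize voxel intensities
#'
#' Maps every voxel p to (p - m) / std with statistics computed on the
#' training split (not per volume).
#'
#' @param vol volume (\linkS4class{ExamVolume} or array).
#' @param stats a \linkS4class{NormStats}.
#' @return Normalized volume of the same class as the input.
#' @export
normalizeVolume <- function(vol, stats) {
  if (stats@std <= 0) stop("std must be > 0")
  x <- .as_vol(vol)
  .rewrap(vol, (x - stats@m) / stats@std)
}

#' Training-split normalization statistics
#'
#' @param volumes list of volumes (arrays or \linkS4class{ExamVolume}s).
#' @return A \linkS4class{NormStats} with the pooled mean and SD.
#' @export
computeNormStats <- function(volumes) {
  v <- unlist(lapply(volumes, function(x) as.vector(.as_vol(x))))
  normStats(mean(v), stats::sd(v))
}

# Draw a top-left offset so that an s-sided block lies fully inside an
# n-sided image (uniform over valid positions).
.block_offset <- function(n, s) if (s >= n) 0L else sample.int(n - s + 1L, 1L) - 1L

#' Spatial-scale erasing
#'
#' For every slice, zeroes a square block of side \code{round(side * ratio)}
#' (side convention; see \linkS4class{AugmentConfig}) placed uniformly among
#' positions fully inside the slice.
#'
#' @param vol volume.
#' @param ratio erasing ratio in [0, 1].
#' @param blockMode \code{"side"} or \code{"area"}.
#' @param layers indices of the slices to touch (default: all).
#' @return Augmented volume of the same class as the input.
#' @export
spatialErase <- function(vol, ratio, blockMode = "side", layers = NULL) {
  stopifnot(ratio >= 0, ratio <= 1)
  x <- .as_vol(vol)
  d <- dim(x)
  if (is.null(layers)) layers <- seq_len(d[1])
  s <- .block_side(min(d[2], d[3]), ratio, blockMode)
  if (s > 0L) {
    for (l in layers) {
      oh <- .block_offset(d[2], s)
      ow <- .block_offset(d[3], s)
      x[l, oh + seq_len(s), ow + seq_len(s)] <- 0
    }
  }
  .rewrap(vol, x)
}

#' Spatial-scale mixup
#'
#' For every slice, replaces a square block by the convex combination
#' \code{lambda * self + (1 - lambda) * donor}, where the donor block comes
#' from a uniformly chosen *different* slice of the same view at an
#' independently drawn position, and \code{lambda ~ Beta(betaAlpha,
#' betaAlpha)} per slice.
#'
#' @param vol volume with at least 2 slices.
#' @param ratio block-side ratio in [0, 1].
#' @param betaAlpha Beta shape for the mixing weight.
#' @param lambda optional fixed mixing weight (used in tests/ablations);
#'   \code{NULL} draws per slice.
#' @param blockMode \code{"side"} or \code{"area"}.
#' @param layers indices of the slices to touch (default: all).
#' @return Augmented volume; per-slice bookkeeping (donor layer, offsets,
#'   lambda) is attached as \code{attr(, "mixupDetails")}.
#' @export
spatialMixup <- function(vol, ratio, betaAlpha = 0.4, lambda = NULL,
                         blockMode = "side", layers = NULL) {
  stopifnot(ratio >= 0, ratio <= 1)
  x0 <- .as_vol(vol)
  d <- dim(x0)
  if (d[1] < 2L) stop("spatial mixup needs at least 2 slices (no donor layer)")
  if (is.null(layers)) layers <- seq_len(d[1])
  x <- x0
  s <- .block_side(min(d[2], d[3]), ratio, blockMode)
  details <- list()
  if (s > 0L) {
    for (l in layers) {
      oh <- .block_offset(d[2], s); ow <- .block_offset(d[3], s)
      donor <- sample(setdiff(seq_len(d[1]), l), 1L)
      dh <- .block_offset(d[2], s); dw <- .block_offset(d[3], s)
      lam <- if (is.null(lambda)) .draw_beta(betaAlpha) else lambda
      x[l, oh + seq_len(s), ow + seq_len(s)] <-
        lam * x0[l, oh + seq_len(s), ow + seq_len(s)] +
        (1 - lam) * x0[donor, dh + seq_len(s), dw + seq_len(s)]
      details[[length(details) + 1L]] <-
        list(layer = l, offset = c(oh, ow), donor = donor,
             donorOffset = c(dh, dw), lambda = lam)
    }
  }
  out <- .rewrap(vol, x)
  attr(out, "mixupDetails") <- details
  out
}

# Nearest-neighbour resize of a 2-D slice.
.resize_nn <- function(m, h, w) {
  m[round(seq(1, nrow(m), length.out = h)),
    round(seq(1, ncol(m), length.out = w)), drop = FALSE]
}

#' Layer-scale erasing / mixup
#'
#' Selects \code{k = round(L * layerRatio)} distinct slices uniformly.  With
#' \code{op = "erase"} the selected slices are zeroed entirely; with
#' \code{op = "mixup"} each selected slice is mixed (\code{lambda ~ Beta})
#' with a uniformly chosen slice from a uniformly chosen *other view*,
#' resized (nearest neighbour) to match if necessary.
#'
#' @param vol volume to augment.
#' @param op \code{"erase"} or \code{"mixup"}.
#' @param layerRatio fraction of slices touched.
#' @param donorViews named list of volumes from the other views (required
#'   for mixup).
#' @param betaAlpha Beta shape for the mixing weight.
#' @param lambda optional fixed mixing weight.
#' @return Augmented volume; selected slices and draws in
#'   \code{attr(, "layerDetails")}.
#' @export
layerScaleApply <- function(vol, op = c("erase", "mixup"), layerRatio,
                            donorViews = NULL, betaAlpha = 0.4,
                            lambda = NULL) {
  op <- match.arg(op)
  stopifnot(layerRatio >= 0, layerRatio <= 1)
  x <- .as_vol(vol)
  d <- dim(x)
  k <- round(d[1] * layerRatio)
  details <- list(selected = integer(0))
  if (k > 0L) {
    sel <- sample.int(d[1], k)
    details$selected <- sort(sel)
    if (op == "erase") {
      x[sel, , ] <- 0
    } else {
      if (is.null(donorViews) || length(donorViews) == 0L)
        stop("layer-scale mixup requires donor views")
      draws <- vector("list", length(sel))
      for (i in seq_along(sel)) {
        dv <- sample(seq_along(donorViews), 1L)
        donor <- .as_vol(donorViews[[dv]])
        dl <- sample.int(dim(donor)[1], 1L)
        slice <- .resize_nn(donor[dl, , ], d[2], d[3])
        lam <- if (is.null(lambda)) .draw_beta(betaAlpha) else lambda
        x[sel[i], , ] <- lam * x[sel[i], , ] + (1 - lam) * slice
        draws[[i]] <- list(layer = sel[i], donorView = names(donorViews)[dv],
                           donorLayer = dl, lambda = lam)
      }
      details$draws <- draws
    }
  }
  out <- .rewrap(vol, x)
  attr(out, "layerDetails") <- details
  out
}

#' Full augmentation pipeline for one exam
#'
#' Applies, per view: random crop, normalization, then at most one of
#' erasing or mixup at one scale, drawn according to the configured
#' probabilities (\code{pErase}/\code{pMixup} pick the op, or none;
#' \code{pLayerScale} picks the scale).  The class label is never modified.
#' Each stage draws from its own named substream of \code{seed}, so
#' disabling one stage does not perturb the draws of another.
#'
#' @param views named list of the exam's \linkS4class{ExamVolume}s.
#' @param cfg an \linkS4class{AugmentConfig}.
#' @param stats a \linkS4class{NormStats} (training-split statistics).
#' @param seed integer seed for this exam's augmentation.
#' @param which optional subset of view names to augment (all by default);
#'   the remaining views still serve as layer-mixup donors.
#' @return Named list of augmented volumes (the requested views).
#' @export
augmentPipeline <- function(views, cfg, stats, seed = 1, which = NULL) {
  if (is.null(which)) which <- names(views)
  out <- views[which]
  for (v in which) {
    vol <- withSubstream(seed, paste0("crop_", v),
                         randomCrop(views[[v]], cfg@cropSize))
    vol <- normalizeVolume(vol, stats)
    choice <- withSubstream(seed, paste0("mode_", v), {
      u <- stats::runif(1)
      op <- if (u < cfg@pErase) "erase"
            else if (u < cfg@pErase + cfg@pMixup) "mixup" else "none"
      scale <- if (stats::runif(1) < cfg@pLayerScale) "layer" else "spatial"
      list(op = op, scale = scale)
    })
    if (choice$op != "none") {
      donors <- NULL
      if (choice$scale == "layer" && choice$op == "mixup") {
        donors <- views[setdiff(names(views), v)]
        donors <- lapply(donors, function(d)
          normalizeVolume(withSubstream(seed, paste0("crop_donor_", v),
                                        randomCrop(d, cfg@cropSize)), stats))
      }
      vol <- withSubstream(seed, paste0("aug_", v), {
        if (choice$scale == "spatial") {
          # spatial-scale ops touch a layerRatio subset of slices
          L <- dim(.as_vol(vol))[1]
          touched <- sample.int(L, max(1L, round(L * cfg@layerRatio)))
          if (choice$op == "erase")
            spatialErase(vol, cfg@eraseRatio, cfg@blockMode, layers = touched)
          else spatialMixup(vol, cfg@mixupRatio, cfg@betaAlpha,
                            blockMode = cfg@blockMode, layers = touched)
        } else {
          layerScaleApply(vol, choice$op, cfg@layerRatio,
                          donorViews = donors, betaAlpha = cfg@betaAlpha)
        }
      })
    }
    attr(vol, "mixupDetails") <- NULL
    attr(vol, "layerDetails") <- NULL
    out[[v]] <- vol
  }
  out
}
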