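#' @import methods
NULL

.VIEWS <- c("axial", "coronal", "sagittal")

#' One view of a stacked-slice MRI exam
#'
#' An \code{ExamVolume} holds the slice stack of a single acquisition plane
#' (axial, coronal or sagittal) of one exam: an \code{L x H x W} numeric
#' array, where \code{L} is the number of slices.
#'
#' @slot data numeric 3-D array, \code{L x H x W}, finite values.
#' @slot view one of \code{"axial"}, \code{"coronal"}, \code{"sagittal"}.
#' @slot examId exam identifier.
#' @export
setClass("ExamVolume",
  representation(data = "array", view = "character", examId = "character"),
  validity = function(object) {
    d <- dim(object@data)
    if (length(d) != 3L) return("data must be a 3-D array (L x H x W)")
    if (d[1] < 1L) return("at least one slice required")
    if (!all(is.finite(object@data))) return("all intensities must be finite")
    if (!object@view %in% .VIEWS)
      return(sprintf("view must be one of %s", paste(.VIEWS, collapse = ", ")))
    TRUE
  })

#' Construct an ExamVolume
#'
#' @param data numeric 3-D array \code{L x H x W}; integer input is promoted
#'   to double.
#' @param view acquisition plane, one of \code{"axial"}, \code{"coronal"},
#'   \code{"sagittal"}.
#' @param examId exam identifier string.
#' @return An \linkS4class{ExamVolume}.
#' @examples
#' v <- examVolume(array(0, c(4, 8, 8)), "axial", "ex1")
#' nLayers(v)
#' @export
examVolume <- function(data, view = "axial", examId = "exam") {
  if (length(dim(data)) != 3L)
    stop("data must be a 3-D array (L x H x W), got ",
         length(dim(data)), " dimensions")
  storage.mode(data) <- "double"
  new("ExamVolume", data = data, view = view, examId = examId)
}

#' @describeIn examVolume Number of slices L.
#' @param x an \code{ExamVolume}.
#' @export
nLayers <- function(x) dim(x@data)[1]

#' @describeIn examVolume The raw intensity array.
#' @export
volumeData <- function(x) x@data

#' @describeIn examVolume The acquisition plane tag.
#' @export
examView <- function(x) x@view

#' @describeIn examVolume The exam identifier.
#' @export
examId <- function(x) x@examId

setMethod("show", "ExamVolume", function(object) {
  d <- dim(object@data)
  cat(sprintf("ExamVolume '%s' [%s view]: %d slices of %d x %d\n",
              object@examId, object@view, d[1], d[2], d[3]))
  cat(sprintf("  intensity range [%.4g, %.4g]\n",
              min(object@data), max(object@data)))
})

#' Label manifest of a dataset
#'
#' A \code{DatasetManifest} is an ordered table of exam records: one row per
#' exam with the binary ACL-tear label (1 = tear) and the per-view volume
#' file paths.
#'
#' @slot records data.frame with columns \code{exam_id}, \code{label},
#'   \code{axial}, \code{coronal}, \code{sagittal}.
#' @slot splitTag one of \code{"train"}, \code{"tune"}, \code{"valid"}.
#' @export
setClass("DatasetManifest",
  representation(records = "data.frame", splitTag = "character"),
  validity = function(object) {
    r <- object@records
    need <- c("exam_id", "label", .VIEWS)
    if (!all(need %in% names(r)))
      return(sprintf("records must have columns %s", paste(need, collapse = ", ")))
    if (anyDuplicated(r$exam_id))
      return("duplicate exam_id in manifest")
    if (!all(r$label %in% c(0, 1)))
      return("labels must be 0 or 1")
    if (!object@splitTag %in% c("train", "tune", "valid"))
      return("splitTag must be train, tune or valid")
    TRUE
  })

#' Construct a DatasetManifest
#'
#' @param records data.frame with columns \code{exam_id}, \code{label} (0/1),
#'   and one path column per view (\code{axial}, \code{coronal},
#'   \code{sagittal}).
#' @param splitTag which split the manifest describes.
#' @return A \linkS4class{DatasetManifest}.
#' @export
datasetManifest <- function(records, splitTag = "train") {
  records$exam_id <- as.character(records$exam_id)
  records$label <- as.integer(records$label)
  new("DatasetManifest", records = records, splitTag = splitTag)
}

#' @describeIn datasetManifest The record table.
#' @param x a \code{DatasetManifest}.
#' @export
manifestRecords <- function(x) x@records

setMethod("length", "DatasetManifest", function(x) nrow(x@records))

setMethod("show", "DatasetManifest", function(object) {
  n <- nrow(object@records)
  npos <- sum(object@records$label)
  cat(sprintf("DatasetManifest [%s]: %d exams, %d with ACL tear (%.1f%%)\n",
              object@splitTag, n, npos, 100 * npos / max(n, 1)))
})

#' Synthetic knee-phantom parameters
#'
#' Parameters of the three-view synthetic phantom generator.  The phantom is
#' an ellipsoidal "joint" background crossed by a bright diagonal band (the
#' ligament); the positive class interrupts the band with a gap and adds a
#' hyperintense blob beside the gap, mimicking the fiber discontinuity and
#' signal abnormality a tear shows on MRI.
#'
#' @slot spatialSize in-plane/through-plane scene size in voxels (>= 16).
#' @slot layerRange integer interval for the per-view slice count L.
#' @slot bandWidth band thickness in voxels.
#' @slot gapLength length of the torn-class gap along the band, voxels.
#' @slot noiseSd additive Gaussian noise standard deviation.
#' @slot posFraction fraction of positive (torn) exams in a dataset.
#' @export
setClass("PhantomParams",
  representation(spatialSize = "integer", layerRange = "integer",
                 bandWidth = "numeric", gapLength = "numeric",
                 noiseSd = "numeric", posFraction = "numeric"),
  validity = function(object) {
    if (object@spatialSize < 16L) return("spatialSize must be >= 16")
    if (length(object@layerRange) != 2L || object@layerRange[1] < 4L ||
        object@layerRange[2] < object@layerRange[1])
      return("layerRange must be an increasing interval with min >= 4")
    if (object@noiseSd < 0) return("noiseSd must be >= 0")
    if (object@posFraction < 0 || object@posFraction > 1)
      return("posFraction must be in [0, 1]")
    if (object@bandWidth <= 0 || object@gapLength <= 0)
      return("bandWidth and gapLength must be positive")
    TRUE
  })

#' Construct phantom parameters
#'
#' Defaults give a 64-voxel scene with 16-24 slices per view and the
#' positive prevalence of a typical clinical training cohort (18.4%).
#'
#' @param spatialSize scene edge length in voxels.
#' @param layerRange integer vector \code{c(min, max)} for slice counts.
#' @param bandWidth band thickness in voxels.
#' @param gapLength gap length for torn exams, voxels.
#' @param noiseSd additive noise SD (intensity units; band is 1.0).
#' @param posFraction dataset fraction of torn exams.
#' @return A \linkS4class{PhantomParams}.
#' @export
phantomParams <- function(spatialSize = 64L, layerRange = c(16L, 24L),
                          bandWidth = 5, gapLength = 10, noiseSd = 0.05,
                          posFraction = 0.184) {
  new("PhantomParams", spatialSize = as.integer(spatialSize),
      layerRange = as.integer(layerRange), bandWidth = bandWidth,
      gapLength = gapLength, noiseSd = noiseSd, posFraction = posFraction)
}

#' Normalization statistics
#'
#' Mean and standard deviation used to standardize voxel intensities;
#' computed on the training split and frozen.
#'
#' @slot m mean intensity.
#' @slot std standard deviation (> 0).
#' @export
setClass("NormStats", representation(m = "numeric", std = "numeric"),
  validity = function(object) {
    if (object@std <= 0) return("std must be > 0")
    TRUE
  })

#' @rdname NormStats-class
#' @param m mean intensity.
#' @param std standard deviation, must be positive.
#' @export
normStats <- function(m, std) new("NormStats", m = m, std = std)

#' Dual-scale augmentation configuration
#'
#' Controls the augmentation pipeline: random crop, normalization, then
#' erasing or mixup applied at the in-plane (spatial) scale or the
#' whole-slice (layer) scale.  \code{eraseRatio}/\code{mixupRatio} follow the
#' side convention: the erased/mixed square has side
#' \code{round(side * ratio)}, so ratio 0.5 touches 25% of the pixels.  Set
#' \code{blockMode = "area"} to make the ratio an area fraction instead.
#'
#' @slot cropSize spatial crop side in pixels.
#' @slot eraseRatio block-side ratio for erasing.
#' @slot mixupRatio block-side ratio for mixup.
#' @slot layerRatio fraction of slices touched by layer-scale ops.
#' @slot betaAlpha shape of the Beta(alpha, alpha) mixing-weight draw.
#' @slot pErase probability a sample gets the erasing op.
#' @slot pMixup probability a sample gets the mixup op (erase/mixup/none are
#'   mutually exclusive per sample, as are the two scales).
#' @slot pLayerScale probability the chosen op acts at the layer scale.
#' @slot blockMode \code{"side"} or \code{"area"}.
#' @export
setClass("AugmentConfig",
  representation(cropSize = "integer", eraseRatio = "numeric",
                 mixupRatio = "numeric", layerRatio = "numeric",
                 betaAlpha = "numeric", pErase = "numeric",
                 pMixup = "numeric", pLayerScale = "numeric",
                 blockMode = "character"),
  validity = function(object) {
    rs <- c(object@eraseRatio, object@mixupRatio, object@layerRatio,
            object@pErase, object@pMixup, object@pLayerScale)
    if (any(rs < 0 | rs > 1)) return("ratios and probabilities must be in [0, 1]")
    if (object@pErase + object@pMixup > 1)
      return("pErase + pMixup must not exceed 1")
    if (object@betaAlpha <= 0) return("betaAlpha must be > 0")
    if (!object@blockMode %in% c("side", "area"))
      return("blockMode must be 'side' or 'area'")
    TRUE
  })

#' Construct an augmentation configuration
#'
#' Defaults reflect the ablation-selected settings: erasing ratio 0.5,
#' mixup ratio 0.25, crop 256 -> 224.
#'
#' @param cropSize crop side (must not exceed the input side at use time).
#' @param eraseRatio,mixupRatio,layerRatio,betaAlpha,pErase,pMixup,pLayerScale,blockMode
#'   see \linkS4class{AugmentConfig}.
#' @return An \linkS4class{AugmentConfig}.
#' @export
augmentConfig <- function(cropSize = 224L, eraseRatio = 0.5,
                          mixupRatio = 0.25, layerRatio = 0.25,
                          betaAlpha = 0.4, pErase = 0.5, pMixup = 0.5,
                          pLayerScale = 0.5, blockMode = "side") {
  new("AugmentConfig", cropSize = as.integer(cropSize),
      eraseRatio = eraseRatio, mixupRatio = mixupRatio,
      layerRatio = layerRatio, betaAlpha = betaAlpha, pErase = pErase,
      pMixup = pMixup, pLayerScale = pLayerScale, blockMode = blockMode)
}

#' Loss parameters
#'
#' Class-balance weight and focusing exponent of the combined weighted +
#' focal training loss.
#'
#' @slot alpha class-balance weight in (0, 1); the positive class is
#'   weighted by \code{alpha}, the negative by \code{1 - alpha}.
#' @slot gamma focusing exponent (>= 0); 0 recovers the plain weighted loss.
#' @export
setClass("LossParams", representation(alpha = "numeric", gamma = "numeric"),
  validity = function(object) {
    if (object@alpha <= 0 || object@alpha >= 1) return("alpha must be in (0, 1)")
    if (object@gamma < 0) return("gamma must be >= 0")
    TRUE
  })

#' @rdname LossParams-class
#' @param alpha class-balance weight in (0,1).
#' @param gamma focusing exponent, >= 0.
#' @export
lossParams <- function(alpha = 0.5, gamma = 2) {
  new("LossParams", alpha = alpha, gamma = gamma)
}

#' Classification metrics report
#'
#' Confusion counts plus accuracy, sensitivity (true-positive rate on torn
#' exams), specificity (true-negative rate on intact exams), and optionally
#' AUC.
#'
#' @slot TP,FP,TN,FN confusion counts.
#' @slot accuracy,sensitivity,specificity,auc fractions in [0, 1]
#'   (\code{auc} is \code{NA} when no scores were supplied).
#' @export
setClass("MetricsReport",
  representation(TP = "integer", FP = "integer", TN = "integer",
                 FN = "integer", accuracy = "numeric",
                 sensitivity = "numeric", specificity = "numeric",
                 auc = "numeric"))

setMethod("show", "MetricsReport", function(object) {
  cat(sprintf("MetricsReport: TP=%d FP=%d TN=%d FN=%d\n",
              object@TP, object@FP, object@TN, object@FN))
  cat(sprintf("  ACC=%.4f SEN=%.4f SPE=%.4f AUC=%s\n",
              object@accuracy, object@sensitivity, object@specificity,
              ifelse(is.na(object@auc), "NA", sprintf("%.4f", object@auc))))
})

#' @rdname MetricsReport-class
#' @param x a \code{MetricsReport}.
#' @return \code{metricsAsList}: named list of counts and metric values.
#' @export
metricsAsList <- function(x) {
  list(TP = x@TP, FP = x@FP, TN = x@TN, FN = x@FN,
       accuracy = x@accuracy, sensitivity = x@sensitivity,
       specificity = x@specificity, auc = x@auc)
}
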