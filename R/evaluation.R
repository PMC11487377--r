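# Metrics, stratified cross-validation, and ablation experiments.

#' Confusion-matrix metrics
#'
#' Treats torn exams (label 1) as positive: sensitivity is the recall on
#' tears, specificity the recall on intact knees.
#'
#' @param yTrue,yPred binary vectors of equal length.
#' @param scores optional continuous tear scores; when given, AUC is
#'   included.
#' @return A \linkS4class{MetricsReport}.
#' @examples
#' confusionMetrics(c(1, 1, 0, 0), c(1, 0, 0, 1))
#' @export
confusionMetrics <- function(yTrue, yPred, scores = NULL) {
  stopifnot(length(yTrue) == length(yPred))
  if (!any(yTrue == 1)) stop("sensitivity undefined: no positive cases")
  if (!any(yTrue == 0)) stop("specificity undefined: no negative cases")
  TP <- sum(yTrue == 1 & yPred == 1); FN <- sum(yTrue == 1 & yPred == 0)
  TN <- sum(yTrue == 0 & yPred == 0); FP <- sum(yTrue == 0 & yPred == 1)
  new("MetricsReport", TP = as.integer(TP), FP = as.integer(FP),
      TN = as.integer(TN), FN = as.integer(FN),
      accuracy = (TP + TN) / length(yTrue),
      sensitivity = TP / (TP + FN), specificity = TN / (TN + FP),
      auc = if (is.null(scores)) NA_real_ else aucScore(yTrue, scores))
}

#' Area under the ROC curve
#'
#' Rank-based (Mann-Whitney) AUC with midrank tie handling: the probability
#' that a random positive outscores a random negative, counting ties as 1/2.
#'
#' @param yTrue binary labels.
#' @param scores continuous scores (larger = more tear-like).
#' @return AUC in [0, 1].
#' @export
aucScore <- function(yTrue, scores) {
  stopifnot(length(yTrue) == length(scores))
  npos <- sum(yTrue == 1); nneg <- sum(yTrue == 0)
  if (npos == 0 || nneg == 0) stop("AUC undefined: single-class input")
  r <- rank(scores)
  (sum(r[yTrue == 1]) - npos * (npos + 1) / 2) / (npos * nneg)
}

#' ROC curve points
#'
#' @inheritParams aucScore
#' @return data.frame with columns \code{fpr}, \code{tpr}, \code{threshold},
#'   suitable for CSV export and plotting.
#' @export
rocCurve <- function(yTrue, scores) {
  ord <- order(scores, decreasing = TRUE)
  y <- yTrue[ord]; s <- scores[ord]
  tpr <- cumsum(y == 1) / sum(y == 1)
  fpr <- cumsum(y == 0) / sum(y == 0)
  keep <- !duplicated(s, fromLast = TRUE)
  data.frame(fpr = c(0, fpr[keep]), tpr = c(0, tpr[keep]),
             threshold = c(Inf, s[keep]))
}

#' Stratified k-fold plan with train/tune sub-split
#'
#' Exam ids are split into k stratified folds (per-fold positive fraction
#' within one case of the global fraction).  Within each fold's training
#' portion, a stratified 0.8/0.2 train/tune split is drawn.  Deterministic
#' under \code{seed}.
#'
#' @param manifest a \linkS4class{DatasetManifest}.
#' @param k number of folds (>= 2).
#' @param tuneFrac tune fraction of each training portion.
#' @param seed integer seed.
#' @return List with one element per fold: \code{valid}, \code{train},
#'   \code{tune} (exam-id character vectors).
#' @export
makeFolds <- function(manifest, k = 5L, tuneFrac = 0.2, seed = 1) {
  stopifnot(k >= 2L)
  r <- manifest@records
  for (cl in c(0L, 1L)) {
    if (sum(r$label == cl) < k)
      stop("class ", cl, " has fewer members than folds")
  }
  assign_folds <- withSubstream(seed, "folds", {
    fold <- integer(nrow(r))
    for (cl in c(0L, 1L)) {
      idx <- sample(which(r$label == cl))
      fold[idx] <- rep(seq_len(k), length.out = length(idx))
    }
    fold
  })
  lapply(seq_len(k), function(f) {
    valid <- r$exam_id[assign_folds == f]
    pool <- which(assign_folds != f)
    tune_idx <- withSubstream(seed, paste0("tune_", f), {
      sel <- integer(0)
      for (cl in c(0L, 1L)) {
        idx <- sample(pool[r$label[pool] == cl])
        sel <- c(sel, idx[seq_len(round(tuneFrac * length(idx)))])
      }
      sel
    })
    list(valid = valid,
         train = r$exam_id[setdiff(pool, tune_idx)],
         tune = r$exam_id[tune_idx])
  })
}

## ---- experiments -----------------------------------------------------------

.toggle_config <- function(config, dda, sg) {
  config$augment$enabled <- dda
  config$sg$enabled <- sg
  config
}

#' Train and evaluate one module toggle set on one fold
#'
#' Trains one model per requested view with the given module toggles and
#' scores the fold's validation exams.
#'
#' @param exams loaded exam list (see [trainViewModel()]).
#' @param labels binary labels.
#' @param fold one element of [makeFolds()] output mapped to indices.
#' @param views views to train.
#' @param config run configuration.
#' @param dda,sg module toggles.
#' @param stats training-split \linkS4class{NormStats}.
#' @param seed integer seed.
#' @return List with per-view \code{scores}, \code{models}, and the fold's
#'   \code{validIdx}.
#' @export
trainToggleSet <- function(exams, labels, fold, views, config, dda, sg,
                           stats, seed = 1) {
  cfg <- .toggle_config(config, dda, sg)
  models <- list(); scores <- list()
  for (v in views) {
    m <- trainViewModel(exams, labels, v, fold$trainIdx, fold$tuneIdx,
                        stats, cfg, seed = seed)
    models[[v]] <- m
    scores[[v]] <- scoreExams(exams, fold$validIdx, v, m,
                              cfg$augment$crop_size, stats)
  }
  list(models = models, scores = scores, validIdx = fold$validIdx)
}

.fold_to_idx <- function(fold, ids) {
  list(trainIdx = match(fold$train, ids), tuneIdx = match(fold$tune, ids),
       validIdx = match(fold$valid, ids))
}

#' Module ablation on a dataset
#'
#' Mirrors the module-efficacy experiment: per view, rows for Base,
#' Base+DDA, and Base+DDA+SG, plus one fused row combining the three views'
#' full models -- 10 rows in total for three views.
#'
#' @param manifest a \linkS4class{DatasetManifest} whose paths are readable.
#' @param config run configuration (see [defaultConfig()]).
#' @param seed integer seed.
#' @param views views to include.
#' @param toggles list of \code{c(dda, sg)} logical pairs defining the rows.
#' @return List with \code{table} (metrics data.frame) and \code{roc}
#'   (named list of ROC data.frames).
#' @export
runAblation <- function(manifest, config = defaultConfig(), seed = 1,
                        views = .VIEWS,
                        toggles = list(c(FALSE, FALSE), c(TRUE, FALSE),
                                       c(TRUE, TRUE))) {
  r <- manifest@records
  exams <- lapply(seq_len(nrow(r)), function(i) .load_exam_views(r[i, ]))
  labels <- r$label
  folds <- makeFolds(manifest, k = config$eval$folds, seed = seed)
  fold <- .fold_to_idx(folds[[1]], r$exam_id)
  stats <- computeNormStats(unlist(lapply(exams[fold$trainIdx],
                                          function(e) e), recursive = FALSE))
  yv <- labels[fold$validIdx]
  rows <- list(); roc <- list()
  last <- NULL
  for (tg in toggles) {
    res <- trainToggleSet(exams, labels, fold, views, config, tg[1], tg[2],
                          stats, seed = seed)
    last <- res
    for (v in views) {
      sc <- res$scores[[v]]
      rep <- confusionMetrics(yv, as.integer(sc[, 2] >= 0.5), sc[, 2])
      rows[[length(rows) + 1L]] <- data.frame(
        view = v, base = TRUE, dda = tg[1], sg = tg[2], fusion = FALSE,
        acc = rep@accuracy, sen = rep@sensitivity, spe = rep@specificity,
        auc = rep@auc)
      if (tg[1] && tg[2]) roc[[v]] <- rocCurve(yv, sc[, 2])
    }
  }
  if (length(views) >= 2L) {
    fus <- fuseViews(last$scores)
    rep <- confusionMetrics(yv, fus$label, fus$score)
    rows[[length(rows) + 1L]] <- data.frame(
      view = "all", base = TRUE, dda = TRUE, sg = TRUE, fusion = TRUE,
      acc = rep@accuracy, sen = rep@sensitivity, spe = rep@specificity,
      auc = rep@auc)
    roc[["fused"]] <- rocCurve(yv, fus$score)
  }
  list(table = do.call(rbind, rows), roc = roc)
}

#' Desk-scale phantom study
#'
#' The package's end-to-end experiment: generates a synthetic phantom
#' dataset, trains the baseline (backbone only) and the full model
#' (DDA + SG) per view on one stratified fold, and fuses the full model's
#' views.  Used by the acceptance checks of the qualitative module ordering.
#'
#' @param seed integer master seed.
#' @param nExams dataset size.
#' @param dir dataset directory (default: a session temp dir).
#' @param config run configuration; \code{NULL} takes [defaultConfig()] with
#'   the desk-scale experiment block applied.
#' @param verbose print progress?
#' @return List with per-view base/full AUCs, fused metrics, the metrics
#'   table, and the raw scores.
#' @export
runPhantomStudy <- function(seed = 1, nExams = 400L, dir = NULL,
                            config = NULL, verbose = FALSE) {
  if (is.null(config)) config <- phantomStudyConfig()
  if (is.null(dir)) dir <- file.path(tempdir(), sprintf("phantom_%d", seed))
  params <- phantomParams(spatialSize = config$data$spatial_size,
                          layerRange = unlist(config$data$layer_range),
                          posFraction = config$data$pos_fraction,
                          noiseSd = config$data$noise_sd)
  manifest <- generateDataset(nExams, params, dir, seed = seed)
  r <- manifest@records
  exams <- lapply(seq_len(nrow(r)), function(i) .load_exam_views(r[i, ]))
  labels <- r$label
  folds <- makeFolds(manifest, k = config$eval$folds, seed = seed)
  fold <- .fold_to_idx(folds[[1]], r$exam_id)
  stats <- computeNormStats(unlist(lapply(exams[fold$trainIdx],
                                          function(e) e), recursive = FALSE))
  yv <- labels[fold$validIdx]

  run_set <- function(dda, sg) {
    if (verbose) message(sprintf("training toggle set dda=%s sg=%s", dda, sg))
    trainToggleSet(exams, labels, fold, .VIEWS, config, dda, sg, stats,
                   seed = seed)
  }
  base <- run_set(FALSE, FALSE)
  full <- run_set(TRUE, TRUE)

  view_metrics <- function(res) {
    sapply(.VIEWS, function(v) {
      sc <- res$scores[[v]]
      c(auc = aucScore(yv, sc[, 2]),
        acc = mean(as.integer(sc[, 2] >= 0.5) == yv))
    })
  }
  mb <- view_metrics(base); mf <- view_metrics(full)
  fus <- fuseViews(full$scores)
  fus_rep <- confusionMetrics(yv, fus$label, fus$score)
  list(baseAuc = mb["auc", ], fullAuc = mf["auc", ],
       baseAcc = mb["acc", ], fullAcc = mf["acc", ],
       fusedMetrics = fus_rep,
       bestSingleAcc = max(mf["acc", ]),
       yValid = yv, baseScores = base$scores, fullScores = full$scores,
       fusedScore = fus$score, fusedLabel = fus$label)
}
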