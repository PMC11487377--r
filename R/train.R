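# Training of per-view models.
#
# Volumes in a batch are collated to the batch-median slice count by
# edge-replicating (or cropping) slices, then stacked into a B x L x H x W
# array.  Optimization is Adam with decoupled weight decay; the learning
# rate is multiplied by `plateauFactor` when the tune loss has not improved
# for `plateauPatience` epochs.

#' Collate volumes to a common slice count
#'
#' Pads (by repeating the final slice) or center-crops each volume's layer
#' axis to the batch-median slice count and stacks them.
#'
#' @param vols list of volumes (\linkS4class{ExamVolume}s or arrays) with
#'   identical spatial size.
#' @return Numeric array \code{B x L x H x W}.
#' @export
collateVolumes <- function(vols) {
  arrs <- lapply(vols, .as_vol)
  Ls <- vapply(arrs, function(a) dim(a)[1], 0L)
  L <- as.integer(round(stats::median(Ls)))
  d <- dim(arrs[[1]])
  out <- array(0, c(length(arrs), L, d[2], d[3]))
  for (i in seq_along(arrs)) {
    Li <- dim(arrs[[i]])[1]
    idx <- if (Li >= L) {
      off <- (Li - L) %/% 2L
      off + seq_len(L)
    } else c(seq_len(Li), rep(Li, L - Li))
    out[i, , , ] <- arrs[[i]][idx, , , drop = FALSE]
  }
  out
}

.load_exam_views <- function(record) {
  out <- list()
  for (v in .VIEWS) out[[v]] <- readVolume(record[[v]], view = v,
                                           examId = record$exam_id)
  out
}

# Evaluation-time preprocessing: center crop + normalize, single view.
.prep_eval <- function(vol, cropSize, stats) {
  normalizeVolume(randomCrop(vol, cropSize, center = TRUE), stats)
}

#' Train one per-view model
#'
#' @param exams list of per-exam named view lists (\code{exams[[i]]$axial}
#'   etc.), already loaded; all views are kept available so layer-scale
#'   mixup can borrow donor slices from the other views.
#' @param labels binary labels aligned with \code{exams}.
#' @param view which view this model consumes.
#' @param trainIdx,tuneIdx index vectors into \code{exams}.
#' @param stats training-split \linkS4class{NormStats}.
#' @param config run configuration list (see [defaultConfig()]); honoured
#'   keys: \code{model}, \code{sg}, \code{augment}, \code{optim}.
#' @param seed integer seed (weights, shuffling and augmentation draw from
#'   named substreams of it).
#' @param verbose print per-epoch progress?
#' @return The trained model with an attached \code{history} data.frame.
#' @export
trainViewModel <- function(exams, labels, view, trainIdx, tuneIdx, stats,
                           config = defaultConfig(), seed = 1,
                           verbose = FALSE) {
  mcfg <- config$model; ocfg <- config$optim
  scfg <- config$sg; acfg <- config$augment
  sg_on <- isTRUE(scfg$enabled)
  dda_on <- isTRUE(acfg$enabled)
  aug <- augmentConfig(cropSize = acfg$crop_size,
                       eraseRatio = acfg$erase_ratio,
                       mixupRatio = acfg$mixup_ratio,
                       layerRatio = acfg$layer_ratio,
                       betaAlpha = acfg$beta_alpha,
                       pErase = acfg$p_erase, pMixup = acfg$p_mixup,
                       pLayerScale = acfg$p_layer_scale,
                       blockMode = acfg$block_mode)
  model <- initModel(mcfg$arch, mcfg$out_channels, sgEnabled = sg_on,
                     groupSizes = unlist(scfg$group_sizes),
                     reduction = scfg$reduction, seed = seed, view = view)
  lp <- lossParams(alpha = if (is.null(ocfg$alpha))
    1 - mean(labels[trainIdx]) else ocfg$alpha, gamma = ocfg$gamma)
  params <- .collect_params(model)
  opt <- .adam_new(params, lr = ocfg$lr, weight_decay = ocfg$weight_decay)

  best_tune <- Inf; wait <- 0L
  history <- data.frame()
  bs <- ocfg$batch_size
  for (epoch in seq_len(ocfg$epochs)) {
    ord <- withSubstream(seed, sprintf("shuffle_%s_%d", view, epoch),
                         sample(trainIdx))
    ep_loss <- 0; nb <- 0L
    for (start in seq(1L, length(ord), by = bs)) {
      idx <- ord[start:min(start + bs - 1L, length(ord))]
      vols <- lapply(idx, function(i) {
        if (dda_on) {
          augmentPipeline(exams[[i]], aug, stats,
                          seed = .substream_seed(seed, sprintf("aug_%d_%d",
                                                               epoch, i)),
                          which = view)[[view]]
        } else .prep_eval(exams[[i]][[view]], aug@cropSize, stats)
      })
      xb <- collateVolumes(vols)
      .td_zero_grads(params)
      logits <- .td_model_forward(xb, model)
      loss <- .td_loss_total(logits, labels[idx], lp@alpha, lp@gamma)
      .td_backward(loss)
      .adam_step(opt)
      ep_loss <- ep_loss + loss$value; nb <- nb + 1L
    }
    tune_loss <- evalLoss(exams, labels, tuneIdx, view, model, aug@cropSize,
                          stats, lp, max(bs, 16L))
    history <- rbind(history, data.frame(epoch = epoch,
                                         train_loss = ep_loss / nb,
                                         tune_loss = tune_loss,
                                         lr = opt$lr))
    if (verbose)
      message(sprintf("[%s] epoch %d train %.4f tune %.4f lr %.2g",
                      view, epoch, ep_loss / nb, tune_loss, opt$lr))
    if (tune_loss < best_tune - 1e-6) {
      best_tune <- tune_loss; wait <- 0L
    } else {
      wait <- wait + 1L
      if (wait >= ocfg$plateau_patience) {
        opt$lr <- opt$lr * ocfg$plateau_factor
        wait <- 0L
      }
    }
  }
  model$history <- history
  model
}

#' Mean total loss of a model on an index set
#'
#' @inheritParams trainViewModel
#' @param idx exam indices to evaluate.
#' @param model trained model.
#' @param cropSize evaluation center-crop side.
#' @param lp loss parameters.
#' @param batchSize forward batch size.
#' @return Mean per-sample total loss.
#' @export
evalLoss <- function(exams, labels, idx, view, model, cropSize, stats, lp,
                     batchSize = 8L) {
  tot <- 0
  for (start in seq(1L, length(idx), by = batchSize)) {
    ii <- idx[start:min(start + batchSize - 1L, length(idx))]
    xb <- collateVolumes(lapply(ii, function(i)
      .prep_eval(exams[[i]][[view]], cropSize, stats)))
    p <- predictModel(xb, model)
    tot <- tot + sum(totalLoss(p, labels[ii], lp))
  }
  tot / length(idx)
}

#' Per-view scores on an index set
#'
#' @inheritParams evalLoss
#' @return \code{length(idx) x 2} probability matrix.
#' @export
scoreExams <- function(exams, idx, view, model, cropSize, stats,
                       batchSize = 8L) {
  out <- matrix(0, length(idx), 2L)
  for (start in seq(1L, length(idx), by = batchSize)) {
    pos <- start:min(start + batchSize - 1L, length(idx))
    xb <- collateVolumes(lapply(idx[pos], function(i)
      .prep_eval(exams[[i]][[view]], cropSize, stats)))
    out[pos, ] <- predictModel(xb, model)
  }
  out
}

## ---- checkpoints -----------------------------------------------------------

.strip_params <- function(x) {
  if (inherits(x, "sgTensor")) x$value
  else if (is.list(x)) lapply(x, .strip_params)
  else x
}

.restore_params <- function(tmpl, values) {
  if (inherits(tmpl, "sgTensor")) .param(values)
  else if (is.list(tmpl)) {
    out <- tmpl
    for (i in seq_along(tmpl))
      out[i] <- list(.restore_params(tmpl[[i]], values[[i]]))
    out
  } else values
}

#' Save / load a model checkpoint
#'
#' The checkpoint stores parameter values, the run configuration and the
#' RNG state, so evaluation after a reload reproduces the pre-save scores
#' exactly.
#'
#' @param model trained model (or named list of per-view models).
#' @param config run configuration.
#' @param path output path.
#' @param stats the \linkS4class{NormStats} used in training.
#' @return \code{path} (\code{saveCheckpoint}) or the restored list
#'   (\code{loadCheckpoint}).
#' @export
saveCheckpoint <- function(model, config, stats, path) {
  saveRDS(list(values = .strip_params(model), config = config,
               stats = c(m = stats@m, std = stats@std),
               rng_state = if (exists(".Random.seed", globalenv()))
                 get(".Random.seed", globalenv())), path)
  invisible(path)
}

#' @rdname saveCheckpoint
#' @param template a freshly initialized model of the same architecture used
#'   to re-type the stored values; when \code{NULL} the stored structure is
#'   rebuilt from the stored config via [initModel()].
#' @export
loadCheckpoint <- function(path, template = NULL) {
  ck <- readRDS(path)
  if (is.null(template)) {
    mcfg <- ck$config$model; scfg <- ck$config$sg
    template <- if (!is.null(ck$values$view))
      initModel(mcfg$arch, mcfg$out_channels, isTRUE(scfg$enabled),
                unlist(scfg$group_sizes), scfg$reduction, seed = 1,
                view = ck$values$view)
    else {
      tpl <- lapply(names(ck$values), function(v)
        initModel(mcfg$arch, mcfg$out_channels, isTRUE(scfg$enabled),
                  unlist(scfg$group_sizes), scfg$reduction, seed = 1,
                  view = v))
      names(tpl) <- names(ck$values)
      tpl
    }
  }
  model <- .restore_params(template, ck$values)
  list(model = model, config = ck$config,
       stats = normStats(ck$stats[["m"]], ck$stats[["std"]]))
}
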