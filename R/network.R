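# Per-slice backbone, per-view classification head, and the training loss.
#
# Each slice of a volume passes through a shared 2-D convolution stack; the
# per-slice feature maps are stacked along the layer axis into a
# B x L x C x H' x W' map.  The head average-pools each slice spatially,
# takes the element-wise maximum over slices (so a finding visible in any
# slice drives the prediction, and slice count may vary), and applies a
# fully connected layer with a 2-class softmax.

## ---- backbone --------------------------------------------------------------

#' Initialize a backbone
#'
#' \code{"small_cnn"}: three strided 3x3/5x5 convolution blocks with ReLU,
#' ending at \code{outChannels} channels; the default architecture for
#' desk-scale (CPU) experiments.  \code{"mrnet_alexnet_like"}: an
#' AlexNet-style feature stack (11/5/3/3/3 kernels with max pooling, 256
#' output channels) recreated with random initialization -- no pretrained
#' weights are shipped or downloaded.
#'
#' @param arch architecture name.
#' @param outChannels output channel count C (>= 8) for \code{small_cnn}.
#' @return Parameter list with an \code{arch} tag.
#' @export
initBackbone <- function(arch = c("small_cnn", "mrnet_alexnet_like"),
                         outChannels = 32L) {
  arch <- match.arg(arch)
  if (arch == "small_cnn") {
    C <- as.integer(outChannels)
    if (C < 8L) stop("outChannels must be >= 8")
    c1 <- max(2L, C %/% 4L); c2 <- max(4L, C %/% 2L)
    # max pooling after the first two blocks keeps small, bright findings
    # salient through the head's spatial average pooling
    list(arch = arch, outChannels = C,
         layers = list(
           list(W = .param(.init_array(c(5L, 5L, 1L, c1), 25)),
                b = .param(numeric(c1)), stride = 2L, pad = 2L, pool = TRUE),
           list(W = .param(.init_array(c(3L, 3L, c1, c2), 9 * c1)),
                b = .param(numeric(c2)), stride = 1L, pad = 1L, pool = TRUE),
           list(W = .param(.init_array(c(3L, 3L, c2, C), 9 * c2)),
                b = .param(numeric(C)), stride = 1L, pad = 1L)))
  } else {
    chans <- c(64L, 192L, 384L, 256L, 256L)
    kern <- c(11L, 5L, 3L, 3L, 3L)
    strd <- c(4L, 1L, 1L, 1L, 1L)
    pads <- c(2L, 2L, 1L, 1L, 1L)
    cin <- c(1L, chans[-5])
    layers <- lapply(seq_along(chans), function(i)
      list(W = .param(.init_array(c(kern[i], kern[i], cin[i], chans[i]),
                                  kern[i]^2 * cin[i])),
           b = .param(numeric(chans[i])), stride = strd[i], pad = pads[i],
           pool = i %in% c(1L, 2L, 5L)))
    list(arch = arch, outChannels = 256L, layers = layers)
  }
}

# Slice batch (H, W, 1, N) node -> feature node (Ho, Wo, C, N).
.td_backbone_slices <- function(x, backbone) {
  for (layer in backbone$layers) {
    x <- .td_relu(.td_conv2d(x, layer$W, layer$b, layer$stride, layer$pad))
    if (isTRUE(layer$pool)) x <- .td_maxpool2d(x, 3L, 2L)
  }
  x
}

# Volume batch array (B, L, H, W) -> feature node (B, L, C, Ho, Wo).
.td_backbone_forward <- function(xarr, backbone) {
  d <- dim(xarr)
  B <- d[1]; L <- d[2]; H <- d[3]; W <- d[4]
  xs <- aperm(xarr, c(3L, 4L, 2L, 1L))           # (H, W, L, B)
  dim(xs) <- c(H, W, 1L, L * B)                  # slices as batch, l fastest
  x <- .tconst(xs)                               # leaf: no input gradient
  f <- .td_backbone_slices(x, backbone)
  fd <- dim(f$value)                             # (Ho, Wo, C, L*B)
  f <- .td_reshape(f, c(fd[1], fd[2], fd[3], L, B))
  .td_aperm(f, c(5L, 4L, 3L, 1L, 2L))            # (B, L, C, Ho, Wo)
}

#' Backbone forward pass
#'
#' Runs every slice of each view's collated batch through the shared 2-D
#' convolution stack and stacks the results along the layer axis.
#'
#' @param views named list of numeric arrays \code{B x L x H x W} (one per
#'   view), or a single such array.
#' @param backbone parameters from [initBackbone()] (a single backbone is
#'   shared across the supplied views' arrays; per-view models hold their
#'   own backbone).
#' @return Named list of feature arrays \code{B x L x C x H' x W'} (or a
#'   single array if \code{views} is an array).
#' @export
backboneForward <- function(views, backbone) {
  one <- function(x) {
    if (min(dim(x)[3:4]) < 8L) stop("spatial size below minimum receptive field")
    .td_backbone_forward(x, backbone)$value
  }
  if (is.array(views)) one(views) else lapply(views, one)
}

## ---- head ------------------------------------------------------------------

#' Initialize the classification head
#'
#' @param C feature channel count.
#' @return Parameter list (one fully connected layer C -> 2).
#' @export
initHead <- function(C) {
  list(W = .param(.init_array(c(C, 2L), C)), b = .param(numeric(2L)))
}

# Feature node (B, L, C, H, W) -> logits node (B, 2).
.td_head_forward <- function(f, head) {
  pooled <- .td_mean_dim(.td_mean_dim(f, 5L), 4L)  # (B, L, C)
  mx <- .td_max_dim(pooled, 2L)                    # (B, C)
  .td_affine(mx, head$W, head$b)
}

#' Head forward pass
#'
#' Spatial average pool per slice, element-wise max over slices, fully
#' connected layer, softmax: one 2-class confidence score per batch item.
#'
#' @param f numeric feature array \code{B x L x C x H x W}.
#' @param head parameters from [initHead()].
#' @return \code{B x 2} matrix of class probabilities (columns: no-tear,
#'   tear), each row summing to 1.
#' @export
headForward <- function(f, head) {
  logits <- .td_head_forward(.tconst(f), head)$value
  e <- exp(logits - apply(logits, 1L, max))
  e / rowSums(e)
}

## ---- losses ----------------------------------------------------------------

.pt_at <- function(p, y, lp) {
  p <- if (is.matrix(p)) p[, 2] else p
  pt <- ifelse(y == 1, p, 1 - p)
  list(pt = pmin(pmax(pt, 1e-12), 1),
       at = ifelse(y == 1, lp@alpha, 1 - lp@alpha))
}

#' Class-balanced weighted cross-entropy
#'
#' \code{-alpha_t * log(p_t)} with \code{p_t = p} for torn exams and
#' \code{1 - p} for intact ones, \code{alpha_t = alpha} resp.
#' \code{1 - alpha}.  \code{p} is clamped at 1e-12 before the log.
#'
#' @param p estimated tear probability (vector), or a \code{n x 2}
#'   score matrix whose second column is the tear probability.
#' @param y binary labels (1 = tear).
#' @param lp a \linkS4class{LossParams}.
#' @return Vector of per-sample losses.
#' @export
weightedLoss <- function(p, y, lp = lossParams()) {
  w <- .pt_at(p, y, lp)
  -w$at * log(w$pt)
}

#' Focal loss
#'
#' \code{-alpha_t * (1 - p_t)^gamma * log(p_t)}: down-weights well-classified
#' examples so training focuses on the hard ones; \code{gamma = 0} recovers
#' [weightedLoss()] exactly.
#'
#' @inheritParams weightedLoss
#' @return Vector of per-sample losses.
#' @export
focalLoss <- function(p, y, lp = lossParams()) {
  w <- .pt_at(p, y, lp)
  -w$at * (1 - w$pt)^lp@gamma * log(w$pt)
}

#' Total training loss
#'
#' Sum of the weighted and focal components.
#'
#' @inheritParams weightedLoss
#' @return Vector of per-sample losses.
#' @export
totalLoss <- function(p, y, lp = lossParams()) {
  weightedLoss(p, y, lp) + focalLoss(p, y, lp)
}

## ---- full per-view model ---------------------------------------------------

#' Initialize a per-view model
#'
#' Backbone + optional selective group attention + head, with weights drawn
#' from the \code{"init_<view>"} substream of \code{seed} (separate weights
#' per view).
#'
#' @param arch backbone architecture.
#' @param outChannels backbone channel count.
#' @param sgEnabled attach the selective group attention module?
#' @param groupSizes branch layer-group sizes for the SG module.
#' @param reduction bottleneck reduction of the SG gating FC.
#' @param seed integer seed.
#' @param view view tag (keys the init substream).
#' @return Model parameter list.
#' @export
initModel <- function(arch = "small_cnn", outChannels = 32L,
                      sgEnabled = TRUE, groupSizes = c(1L, 2L, 4L),
                      reduction = 4L, seed = 1, view = "axial") {
  withSubstream(seed, paste0("init_", view), {
    backbone <- initBackbone(arch, outChannels)
    C <- backbone$outChannels
    list(backbone = backbone,
         sg = if (sgEnabled) initSelectiveAttention(C, groupSizes, reduction),
         head = initHead(C),
         view = view)
  })
}

# Batch array (B, L, H, W) -> logits node.
.td_model_forward <- function(xarr, model) {
  f <- .td_backbone_forward(xarr, model$backbone)
  if (!is.null(model$sg)) f <- .td_selective(f, model$sg)
  .td_head_forward(f, model$head)
}

#' Model forward pass (probabilities)
#'
#' @param xarr numeric array \code{B x L x H x W} of collated, normalized
#'   slices for one view.
#' @param model parameters from [initModel()].
#' @return \code{B x 2} matrix of class probabilities.
#' @export
predictModel <- function(xarr, model) {
  logits <- .td_model_forward(xarr, model)$value
  e <- exp(logits - apply(logits, 1L, max))
  e / rowSums(e)
}
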