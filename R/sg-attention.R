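# Selective group attention.
#
# The backbone emits a 5-D feature map X (B x L x C x H x W).  A *group
# module* folds slices into channels in contiguous blocks of n (a "crop
# group" of shape L/n x C*n x H x W per batch item), computes directional
# (height / width) attention from 1-D average pools through a shared 1x1
# convolution and sigmoids, forms the rank-1 map A' = A_H' (x) A_W', gates it
# with a global branch (depthwise 3x3 convolution + global average pool),
# and modulates the crop group:  out = C_n * sigmoid(A' * g).  The
# *selective attention* module runs K group modules with different n, sums
# their outputs, squeezes a per-channel descriptor through a bottleneck FC,
# and softmax-gates the branches per channel (selective-kernel style):
# out = sum_k z_k * F_k.

## ---- group reshape ---------------------------------------------------------

.pad_layers_idx <- function(L, n) {
  Lp <- as.integer(ceiling(L / n) * n)
  if (Lp == L) seq_len(L) else c(seq_len(L), rep(L, Lp - L))
}

# (B, L, C, H, W) node -> (B, G, C*n, H, W) node; layers folded into channels
# in contiguous blocks of n (channel index = c + C * (j - 1) for layer j of
# the block).  L not divisible by n is padded by repeating the final layer.
.td_group <- function(x, n) {
  d <- dim(x$value)
  B <- d[1]; L <- d[2]; C <- d[3]; H <- d[4]; W <- d[5]
  idx <- .pad_layers_idx(L, n)
  if (length(idx) > L) x <- .td_gather(x, 2L, idx)
  Lp <- length(idx); G <- Lp %/% n
  x <- .td_reshape(x, c(B, n, G, C, H, W))
  x <- .td_aperm(x, c(1L, 3L, 4L, 2L, 5L, 6L))   # (B, G, C, n, H, W)
  .td_reshape(x, c(B, G, C * n, H, W))
}

# Inverse of .td_group; drops padded layers to restore length L.
.td_ungroup <- function(x, n, C, L) {
  d <- dim(x$value)
  B <- d[1]; G <- d[2]; H <- d[4]; W <- d[5]
  x <- .td_reshape(x, c(B, G, C, n, H, W))
  x <- .td_aperm(x, c(1L, 4L, 2L, 3L, 5L, 6L))   # (B, n, G, C, H, W)
  x <- .td_reshape(x, c(B, n * G, C, H, W))
  if (n * G > L) x <- .td_gather(x, 2L, seq_len(L))
  x
}

#' Fold slices into channel crop groups
#'
#' Reshapes a \code{B x L x C x H x W} feature map into crop groups of layer
#' size \code{n}: shape \code{B x L/n x (C*n) x H x W}, padding L to a
#' multiple of n by repeating the final slice.  \code{groupUnreshape}
#' inverts the operation exactly.
#'
#' @param x numeric 5-D array \code{B x L x C x H x W}.
#' @param n layer-group size (>= 1).
#' @return The folded array (\code{groupReshape}) or the restored 5-D array
#'   (\code{groupUnreshape}).
#' @export
groupReshape <- function(x, n) {
  stopifnot(n >= 1)
  .td_group(.tconst(x), as.integer(n))$value
}

#' @rdname groupReshape
#' @param C,L original channel and layer counts.
#' @export
groupUnreshape <- function(x, n, C, L) {
  .td_ungroup(.tconst(x), as.integer(n), C, L)$value
}

## ---- parameters ------------------------------------------------------------

#' Initialize group-module parameters
#'
#' @param C backbone channel count.
#' @param n layer-group size of this branch.
#' @return List of tape parameters: \code{W1,b1} (shared 1x1 convolution of
#'   the pooled descriptor, \code{C*n} channels) and \code{Wg,bg} (depthwise
#'   3x3 convolution of the global branch).
#' @export
initGroupModule <- function(C, n) {
  Cn <- C * n
  list(n = as.integer(n),
       W1 = .param(.init_array(c(Cn, Cn), Cn)),
       b1 = .param(numeric(Cn)),
       Wg = .param(.init_array(c(3L, 3L, Cn), 9)),
       bg = .param(numeric(Cn)))
}

#' Initialize selective-attention parameters
#'
#' @param C backbone channel count.
#' @param groupSizes integer vector of branch layer-group sizes n_k.
#' @param reduction bottleneck reduction ratio r of the gating FC.
#' @param minWidth minimum bottleneck width.
#' @return List with per-branch group modules and the gating FCs.
#' @export
initSelectiveAttention <- function(C, groupSizes = c(1L, 2L, 4L),
                                   reduction = 4L, minWidth = 8L) {
  if (length(groupSizes) < 1L) stop("groupSizes must be non-empty")
  Cb <- max(minWidth, C %/% reduction)
  list(groupSizes = as.integer(groupSizes),
       branches = lapply(groupSizes, function(n) initGroupModule(C, n)),
       Wfc1 = .param(.init_array(c(C, Cb), C)),
       bfc1 = .param(numeric(Cb)),
       Wfc2 = lapply(seq_along(groupSizes), function(k)
         .param(.init_array(c(Cb, C), Cb))),
       bfc2 = lapply(seq_along(groupSizes), function(k) .param(numeric(C))))
}

## ---- forward (tape) --------------------------------------------------------

# Directional attention of one crop group node (B, G, Cn, H, W):
# returns list(AH, AW, Aprime) nodes.
.td_directional <- function(cg, W1, b1) {
  d <- dim(cg$value)
  B <- d[1]; G <- d[2]; Cn <- d[3]; H <- d[4]; W <- d[5]
  CnH <- .td_mean_dim(cg, 5L)                    # (B, G, Cn, H): pool over W
  CnW <- .td_mean_dim(cg, 4L)                    # (B, G, Cn, W): pool over H
  A <- .td_concat_last(CnH, CnW)                 # (B, G, Cn, H + W)
  A <- .td_aperm(A, c(1L, 2L, 4L, 3L))           # (B, G, T, Cn)
  A <- .td_reshape(A, c(B * G * (H + W), Cn))
  A <- .td_affine(A, W1, b1)                     # shared 1x1 conv over channels
  A <- .td_reshape(A, c(B, G, H + W, Cn))
  A <- .td_aperm(A, c(1L, 2L, 4L, 3L))           # (B, G, Cn, T)
  AH <- .td_sigmoid(.td_slice_last(A, seq_len(H)))
  AW <- .td_sigmoid(.td_slice_last(A, H + seq_len(W)))
  Ap <- .td_outer_last(AH, AW)
  list(AH = AH, AW = AW, Aprime = Ap)
}

# Global branch: depthwise 3x3 conv + global spatial average -> (B, G, Cn).
.td_global_branch <- function(cg, Wg, bg) {
  .td_dwconv_globalpool(cg, Wg, bg)
}

# Full group module on a (B, L, C, H, W) node.
.td_group_module <- function(x, params) {
  d <- dim(x$value)
  C <- d[3]; L <- d[2]; H <- d[4]; W <- d[5]
  n <- params$n
  cg <- .td_group(x, n)
  att <- .td_directional(cg, params$W1, params$b1)
  g <- .td_global_branch(cg, params$Wg, params$bg)
  gb <- .td_expand_trailing(g, c(H, W))          # broadcast to (B,G,Cn,H,W)
  M <- .td_sigmoid(.td_mul(att$Aprime, gb))
  out <- .td_mul(cg, M)
  .td_ungroup(out, n, C, L)
}

# Selective attention on a (B, L, C, H, W) node.
.td_selective <- function(x, params) {
  d <- dim(x$value)
  B <- d[1]; L <- d[2]; C <- d[3]; H <- d[4]; W <- d[5]
  K <- length(params$branches)
  Fk <- lapply(params$branches, function(br) .td_group_module(x, br))
  Fsum <- .td_addn(Fk)
  Fpp <- .td_mean_dim(.td_mean_dim(.td_mean_dim(Fsum, 5L), 4L), 2L) # (B, C)
  hid <- .td_relu(.td_affine(Fpp, params$Wfc1, params$bfc1))
  logits <- lapply(seq_len(K), function(k)
    .td_reshape(.td_affine(hid, params$Wfc2[[k]], params$bfc2[[k]]),
                c(B, C, 1L)))
  zall <- .td_softmax_last(Reduce(.td_concat_last, logits))  # (B, C, K)
  terms <- lapply(seq_len(K), function(k) {
    zk <- .td_reshape(.td_slice_last(zall, k), c(B, C))
    .td_scale_channels(Fk[[k]], zk)
  })
  out <- .td_addn(terms)
  attr(out, "z") <- zall$value
  out
}

## ---- numeric front ends ----------------------------------------------------

#' Directional attention maps of a crop group
#'
#' Computes the height/width attention of a crop group: 1-D average pools
#' over width and height, a shared 1x1 convolution over the concatenated
#' descriptor, a split back into the two directions, sigmoids, and the
#' rank-1 outer product \code{A'[h, w] = A_H'[h] * A_W'[w]} per group-layer
#' and channel.
#'
#' @param cropGroup numeric array \code{B x G x Cn x H x W}.
#' @param params group-module parameters from [initGroupModule()].
#' @return List with arrays \code{AH} (\code{B x G x Cn x H}), \code{AW}
#'   (\code{B x G x Cn x W}) and \code{Aprime} (\code{B x G x Cn x H x W}).
#' @export
directionalAttention <- function(cropGroup, params) {
  att <- .td_directional(.tconst(cropGroup), params$W1, params$b1)
  list(AH = att$AH$value, AW = att$AW$value, Aprime = att$Aprime$value)
}

#' Cross-layer group attention
#'
#' Applies one group module (layer-group size \code{n}) to a feature map and
#' returns a gated feature map of identical shape.
#'
#' @param x numeric array \code{B x L x C x H x W}.
#' @param n layer-group size; \code{params} must have been initialized with
#'   the same \code{n} (when \code{params} is missing, fresh parameters are
#'   drawn from the current RNG state).
#' @param params parameters from [initGroupModule()].
#' @return Array of the same shape as \code{x}.
#' @export
groupModule <- function(x, n, params = NULL) {
  d <- dim(x)
  stopifnot(length(d) == 5L)
  if (is.null(params)) params <- initGroupModule(d[3], n)
  stopifnot(params$n == n)
  .td_group_module(.tconst(x), params)$value
}

#' Selective group attention
#'
#' Runs K group modules with different layer-group sizes, fuses them by
#' element-wise summation, and softmax-gates the branches per channel from a
#' pooled descriptor:  \code{out = sum_k z_k * F_k} with
#' \code{sum_k z_k = 1} per channel.
#'
#' @param x numeric array \code{B x L x C x H x W}.
#' @param groupSizes integer vector of branch sizes n_k (ignored when
#'   \code{params} given).
#' @param params parameters from [initSelectiveAttention()].
#' @return Array of the same shape as \code{x}; the branch weights are
#'   attached as \code{attr(, "z")} (\code{B x C x K}).
#' @export
selectiveAttention <- function(x, groupSizes = c(1L, 2L, 4L), params = NULL) {
  d <- dim(x)
  stopifnot(length(d) == 5L)
  if (length(groupSizes) < 1L && is.null(params))
    stop("groupSizes must be non-empty")
  if (is.null(params)) params <- initSelectiveAttention(d[3], groupSizes)
  node <- .td_selective(.tconst(x), params)
  out <- node$value
  attr(out, "z") <- attr(node, "z")
  out
}
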