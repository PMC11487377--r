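# Internal reverse-mode tape over plain R arrays.
#
# Every node is an environment holding `value` (a numeric array), the list of
# parent nodes and a `backfn` that maps the gradient at the node onto
# gradients for its parents.  This is deliberately minimal: only the
# operations the backbone, attention and head need are provided, and each
# operation's gradient is checked against finite differences in the test
# suite.  Convolutions call the compiled kernels in src/conv.cpp.

.td_state <- new.env(parent = emptyenv())
.td_state$counter <- 0L

.tensor <- function(value, parents = list(), backfn = NULL) {
  node <- new.env(parent = emptyenv())
  node$value <- value
  node$parents <- parents
  node$backfn <- backfn
  node$grad <- NULL
  .td_state$counter <- .td_state$counter + 1L
  node$id <- .td_state$counter
  class(node) <- "sgTensor"
  node
}

.param <- function(value) {
  node <- .tensor(value)
  node$is_param <- TRUE
  node
}

.tconst <- function(value) .tensor(value)

.tval <- function(x) if (inherits(x, "sgTensor")) x$value else x

# Topological order of the sub-graph below `root` (parents first).
.td_topo <- function(root) {
  seen <- new.env(parent = emptyenv())
  order <- vector("list", 0L)
  stack <- list(list(node = root, next_parent = 1L))
  while (length(stack) > 0L) {
    top <- stack[[length(stack)]]
    node <- top$node
    key <- as.character(node$id)
    parents <- node$parents
    if (top$next_parent <= length(parents)) {
      stack[[length(stack)]]$next_parent <- top$next_parent + 1L
      child <- parents[[top$next_parent]]
      if (is.null(seen[[as.character(child$id)]])) {
        seen[[as.character(child$id)]] <- TRUE
        stack[[length(stack) + 1L]] <- list(node = child, next_parent = 1L)
      }
    } else {
      order[[length(order) + 1L]] <- node
      stack[[length(stack)]] <- NULL
    }
  }
  order
}

.td_backward <- function(root) {
  order <- .td_topo(root)
  for (node in order) node$grad <- NULL
  root$grad <- if (is.null(dim(root$value))) 1 else array(1, dim(root$value))
  for (node in rev(order)) {
    if (is.null(node$backfn) || is.null(node$grad)) next
    grads <- node$backfn(node$grad)
    for (i in seq_along(node$parents)) {
      g <- grads[[i]]
      if (is.null(g)) next
      p <- node$parents[[i]]
      p$grad <- if (is.null(p$grad)) g else p$grad + g
    }
  }
  invisible(root)
}

.td_zero_grads <- function(params) {
  for (p in params) p$grad <- NULL
  invisible(params)
}

## ---- elementwise -----------------------------------------------------------

.td_add <- function(a, b) {
  .tensor(a$value + b$value, list(a, b), function(g) list(g, g))
}

.td_addn <- function(nodes) Reduce(.td_add, nodes)

.td_mul <- function(a, b) {
  av <- a$value; bv <- b$value
  .tensor(av * bv, list(a, b), function(g) list(g * bv, g * av))
}

.td_smul <- function(a, s) {
  .tensor(a$value * s, list(a), function(g) list(g * s))
}

.td_sigmoid <- function(a) {
  s <- 1 / (1 + exp(-a$value))
  .tensor(s, list(a), function(g) list(g * s * (1 - s)))
}

.td_relu <- function(a) {
  m <- a$value > 0
  .tensor(a$value * m, list(a), function(g) list(g * m))
}

## ---- shape -----------------------------------------------------------------

.td_reshape <- function(a, newdim) {
  olddim <- dim(a$value)
  v <- a$value
  dim(v) <- newdim
  .tensor(v, list(a), function(g) { dim(g) <- olddim; list(g) })
}

.td_aperm <- function(a, perm) {
  if (all(perm == seq_along(perm))) return(a)
  .tensor(aperm(a$value, perm), list(a),
          function(g) list(aperm(g, order(perm))))
}

# TRUE when gradients must flow into this node (parameters or interior nodes).
.td_needs_grad <- function(a) !is.null(a$backfn) || isTRUE(a$is_param)

# Insert a broadcast axis of length n at position `pos` of the output dims.
.td_expand <- function(a, pos, n) {
  d <- dim(a$value)
  k <- length(d)
  v <- array(a$value, c(d, n))                   # replicate along last axis
  outperm <- append(seq_len(k), k + 1L, after = pos - 1L)
  if (pos <= k) v <- aperm(v, outperm)           # move new axis into place
  .tensor(v, list(a), function(g) {
    if (pos <= k) g <- aperm(g, order(outperm))  # new axis back to last
    dim(g) <- c(prod(d), n)
    g <- rowSums(g)
    dim(g) <- d
    list(g)
  })
}

# Broadcast by appending trailing axes `extra` (no transposition needed:
# column-major replication along trailing dims is plain recycling).
.td_expand_trailing <- function(a, extra) {
  d <- dim(a$value)
  nrep <- prod(extra)
  v <- array(a$value, c(d, extra))
  .tensor(v, list(a), function(g) {
    g <- rowSums(matrix(g, prod(d), nrep))
    dim(g) <- d
    list(g)
  })
}

# Rank-1 outer product over the two trailing axes:
# out[..., h, w] = aH[..., h] * aW[..., w].
.td_outer_last <- function(aH, aW) {
  dH <- dim(aH$value); dW <- dim(aW$value)
  k <- length(dH)
  H <- dH[k]; W <- dW[k]
  pre <- prod(dH[-k])
  a1 <- array(aH$value, c(dH, W))
  iw <- rep(seq_len(W) - 1L, each = pre * H)
  idx <- rep(seq_len(pre), times = H * W) + pre * iw
  a2 <- aW$value[idx]
  dim(a2) <- c(dH, W)
  .tensor(a1 * a2, list(aH, aW), function(g) {
    gH <- rowSums(matrix(g * a2, pre * H, W))
    dim(gH) <- dH
    v <- g * a1
    dim(v) <- c(pre, H, W)
    gW <- v[, 1, , drop = FALSE]
    for (h in seq_len(H)[-1]) gW <- gW + v[, h, , drop = FALSE]
    dim(gW) <- dW
    list(gH, gW)
  })
}

# Per-channel scaling of a (B, L, C, H, W) map by weights (B, C):
# out[b, l, c, h, w] = x[b, l, c, h, w] * z[b, c].
.td_scale_channels <- function(x, z) {
  d <- dim(x$value)
  B <- d[1]; L <- d[2]; C <- d[3]; HW <- d[4] * d[5]
  ib <- rep(seq_len(B), times = L * C * HW)
  ic <- rep(rep(seq_len(C) - 1L, each = B * L), times = HW)
  idx <- ib + B * ic
  zfac <- z$value[idx]
  dim(zfac) <- d
  xv <- x$value
  .tensor(xv * zfac, list(x, z), function(g) {
    v <- rowSums(matrix(g * xv, B * L * C, HW))
    dim(v) <- c(B, L, C)
    gz <- v[, 1, , drop = FALSE]
    for (l in seq_len(L)[-1]) gz <- gz + v[, l, , drop = FALSE]
    dim(gz) <- c(B, C)
    list(g * zfac, gz)
  })
}

# Global branch of the group module, fused: depthwise KxK conv (same
# padding) followed by global spatial averaging.
# cg: (B, G, Cn, H, W) node -> (B, G, Cn) node.
.td_dwconv_globalpool <- function(cg, w, b) {
  d <- dim(cg$value)
  B <- d[1]; G <- d[2]; Cn <- d[3]; H <- d[4]; W <- d[5]
  N <- B * G
  xt <- t(matrix(cg$value, N * Cn, H * W))       # (H*W, N*Cn) -> (H,W,N,Cn)
  dim(xt) <- c(H, W, N, Cn)
  wv <- w$value
  y <- .cpp_dwconv_nc_fwd(xt, wv, b$value)
  m <- colMeans(matrix(y, H * W, N * Cn))        # (N, Cn) with b fastest
  dim(m) <- c(B, G, Cn)
  .tensor(m, list(cg, w, b), function(g) {
    dy <- rep(as.vector(g) / (H * W), each = H * W)
    dim(dy) <- c(H, W, N, Cn)
    gr <- .cpp_dwconv_nc_bwd(xt, wv, dy)
    dx <- t(matrix(gr$dx, H * W, N * Cn))
    dim(dx) <- d
    list(dx, gr$dw, gr$db)
  })
}

# Move dimension dm to the last position (plain arrays).
.move_last <- function(v, dm) {
  k <- length(dim(v))
  if (dm == k) v else aperm(v, c(setdiff(seq_len(k), dm), dm))
}

.td_mean_dim <- function(a, dm) {
  d <- dim(a$value)
  k <- length(d)
  perm <- c(setdiff(seq_len(k), dm), dm)
  rest <- d[-dm]
  m <- rowMeans(matrix(.move_last(a$value, dm), prod(rest), d[dm]))
  dim(m) <- rest
  .tensor(m, list(a), function(g) {
    gf <- array(g / d[dm], c(rest, d[dm]))
    list(aperm(gf, order(perm)))
  })
}

.td_max_dim <- function(a, dm) {
  d <- dim(a$value)
  k <- length(d)
  perm <- c(setdiff(seq_len(k), dm), dm)
  rest <- d[-dm]
  m <- matrix(.move_last(a$value, dm), prod(rest), d[dm])
  idx <- max.col(m, ties.method = "first")
  v <- m[cbind(seq_len(nrow(m)), idx)]
  dim(v) <- rest
  .tensor(v, list(a), function(g) {
    gm <- matrix(0, prod(rest), d[dm])
    gm[cbind(seq_len(nrow(gm)), idx)] <- as.vector(g)
    dim(gm) <- c(rest, d[dm])
    list(aperm(gm, order(perm)))
  })
}

# Gather slices `idx` along dimension dm (with scatter-add backward, so a
# repeated index, e.g. edge-replicated padding, accumulates correctly).
.td_gather <- function(a, dm, idx) {
  d <- dim(a$value)
  k <- length(d)
  perm <- c(setdiff(seq_len(k), dm), dm)
  rest <- d[-dm]
  m <- matrix(.move_last(a$value, dm), prod(rest), d[dm])
  v <- m[, idx, drop = FALSE]
  dim(v) <- c(rest, length(idx))
  outdim_perm <- order(perm)
  v <- aperm(v, outdim_perm)
  .tensor(v, list(a), function(g) {
    g <- aperm(g, perm)
    dim(g) <- c(prod(rest), length(idx))
    gm <- matrix(0, prod(rest), d[dm])
    for (j in seq_along(idx)) gm[, idx[j]] <- gm[, idx[j]] + g[, j]
    dim(gm) <- c(rest, d[dm])
    list(aperm(gm, outdim_perm))
  })
}

.td_concat_last <- function(a, b) {
  da <- dim(a$value); db <- dim(b$value)
  k <- length(da)
  v <- c(a$value, b$value)
  dim(v) <- c(da[-k], da[k] + db[k])
  .tensor(v, list(a, b), function(g) {
    ga <- g[seq_len(prod(da))]
    gb <- g[prod(da) + seq_len(prod(db))]
    dim(ga) <- da; dim(gb) <- db
    list(ga, gb)
  })
}

.td_slice_last <- function(a, idx) {
  k <- length(dim(a$value))
  .td_gather(a, k, idx)
}

.td_softmax_last <- function(a) {
  d <- dim(a$value)
  k <- length(d)
  m <- matrix(a$value, prod(d[-k]), d[k])
  e <- exp(m - apply(m, 1L, max))
  s <- e / rowSums(e)
  sv <- s
  dim(sv) <- d
  .tensor(sv, list(a), function(g) {
    gm <- matrix(g, prod(d[-k]), d[k])
    out <- s * (gm - rowSums(gm * s))
    dim(out) <- d
    list(out)
  })
}

## ---- linear / convolution --------------------------------------------------

.td_affine <- function(x, W, b) {
  xv <- x$value; Wv <- W$value
  v <- xv %*% Wv
  v <- sweep(v, 2L, b$value, "+")
  .tensor(v, list(x, W, b), function(g) {
    list(g %*% t(Wv), crossprod(xv, g), colSums(g))
  })
}

.td_conv2d <- function(x, w, b, stride = 1L, pad = 0L) {
  xv <- x$value; wv <- w$value
  need_dx <- .td_needs_grad(x)
  v <- .cpp_conv2d_fwd(xv, wv, b$value, as.integer(stride), as.integer(pad))
  .tensor(v, list(x, w, b), function(g) {
    gr <- .cpp_conv2d_bwd(xv, wv, g, as.integer(stride), as.integer(pad),
                          need_dx)
    list(gr$dx, gr$dw, gr$db)
  })
}

.td_dwconv <- function(x, w, b) {
  xv <- x$value; wv <- w$value
  v <- .cpp_dwconv_fwd(xv, wv, b$value)
  .tensor(v, list(x, w, b), function(g) {
    gr <- .cpp_dwconv_bwd(xv, wv, g)
    list(gr$dx, gr$dw, gr$db)
  })
}

# Non-overlapping-ish max pooling with kernel k and stride s (edge columns /
# rows that do not fit a full window are dropped, as in common CNN stacks).
.td_maxpool2d <- function(x, k, s) {
  xv <- x$value
  d <- dim(xv)                                  # (H, W, C, N)
  H <- d[1]; W <- d[2]
  Ho <- (H - k) %/% s + 1L
  Wo <- (W - k) %/% s + 1L
  ho <- (seq_len(Ho) - 1L) * s
  wo <- (seq_len(Wo) - 1L) * s
  best <- array(-Inf, c(Ho, Wo, d[3], d[4]))
  argh <- array(1L, dim(best)); argw <- array(1L, dim(best))
  for (ki in seq_len(k)) {
    for (kj in seq_len(k)) {
      cand <- xv[ho + ki, wo + kj, , , drop = FALSE]
      upd <- cand > best
      best[upd] <- cand[upd]
      argh[upd] <- ki; argw[upd] <- kj
    }
  }
  .tensor(best, list(x), function(g) {
    dx <- array(0, d)
    for (ki in seq_len(k)) {
      for (kj in seq_len(k)) {
        sel <- (argh == ki) & (argw == kj)
        if (!any(sel)) next
        gsub <- array(0, dim(best))
        gsub[sel] <- g[sel]
        dx[ho + ki, wo + kj, , ] <- dx[ho + ki, wo + kj, , , drop = FALSE] + gsub
      }
    }
    list(dx)
  })
}

## ---- loss ------------------------------------------------------------------

# Combined weighted + focal loss on logits; mean over the batch.
# logits: (n x 2) node; y: 0/1 vector; see weightedLoss()/focalLoss() for the
# scalar formulas this differentiates.
.td_loss_total <- function(logits, y, alpha, gamma, eps = 1e-12) {
  z <- logits$value
  zm <- z - apply(z, 1L, max)
  e <- exp(zm)
  p1 <- e[, 2] / rowSums(e)
  pt <- ifelse(y == 1, p1, 1 - p1)
  pt <- pmin(pmax(pt, eps), 1)
  at <- ifelse(y == 1, alpha, 1 - alpha)
  n <- length(y)
  loss <- mean(-at * log(pt) - at * (1 - pt)^gamma * log(pt))
  .tensor(loss, list(logits), function(g) {
    focal_term <- ifelse(1 - pt < 1e-12, 0,
                         -gamma * (1 - pt)^(gamma - 1) * log(pt))
    dpt <- -at * (1 / pt + focal_term + (1 - pt)^gamma / pt)
    dp1 <- dpt * ifelse(y == 1, 1, -1)
    base <- dp1 * p1 * (1 - p1) * (as.numeric(g) / n)
    list(cbind(-base, base))
  })
}

## ---- parameter utilities ---------------------------------------------------

.init_array <- function(d, fan_in) {
  array(stats::rnorm(prod(d), sd = sqrt(2 / fan_in)), d)
}

.collect_params <- function(x) {
  out <- list()
  rec <- function(v) {
    if (inherits(v, "sgTensor")) out[[length(out) + 1L]] <<- v
    else if (is.list(v)) for (el in v) rec(el)
  }
  rec(x)
  out
}

## ---- Adam ------------------------------------------------------------------

.adam_new <- function(params, lr = 1e-3, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8, weight_decay = 0) {
  st <- new.env(parent = emptyenv())
  st$params <- params
  st$lr <- lr; st$beta1 <- beta1; st$beta2 <- beta2
  st$eps <- eps; st$wd <- weight_decay
  st$t <- 0L
  st$m <- lapply(params, function(p) array(0, dim(p$value) %||% length(p$value)))
  st$v <- lapply(params, function(p) array(0, dim(p$value) %||% length(p$value)))
  st
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.adam_step <- function(st) {
  st$t <- st$t + 1L
  b1 <- st$beta1; b2 <- st$beta2
  for (i in seq_along(st$params)) {
    p <- st$params[[i]]
    g <- p$grad
    if (is.null(g)) next
    if (st$wd > 0) g <- g + st$wd * p$value
    st$m[[i]] <- b1 * st$m[[i]] + (1 - b1) * g
    st$v[[i]] <- b2 * st$v[[i]] + (1 - b2) * g * g
    mhat <- st$m[[i]] / (1 - b1^st$t)
    vhat <- st$v[[i]] / (1 - b2^st$t)
    p$value <- p$value - st$lr * mhat / (sqrt(vhat) + st$eps)
  }
  invisible(st)
}
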