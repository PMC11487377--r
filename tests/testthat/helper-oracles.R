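# Independent reference implementations used to cross-check the package.
# Everything here is written as plain nested loops / direct formula
# evaluation, deliberately sharing no code with the package internals.

# sigmoid
.sg <- function(x) 1 / (1 + exp(-x))

# Nested-loop evaluation of the group module for one batch item.
# x: (L, C, H, W); returns (L, C, H, W).
oracle_group_module_one <- function(x, n, W1, b1, Wg, bg) {
  d <- dim(x); L <- d[1]; C <- d[2]; H <- d[3]; W <- d[4]
  Lp <- ceiling(L / n) * n
  xp <- array(0, c(Lp, C, H, W))
  for (l in seq_len(Lp)) xp[l, , , ] <- x[min(l, L), , , ]
  G <- Lp / n
  Cn <- C * n
  out <- array(0, c(Lp, C, H, W))
  for (g in seq_len(G)) {
    crop <- array(0, c(Cn, H, W))
    for (j in seq_len(n)) for (c in seq_len(C))
      crop[c + C * (j - 1), , ] <- xp[(g - 1) * n + j, c, , ]
    # directional descriptors
    D <- matrix(0, Cn, H + W)
    for (ch in seq_len(Cn)) {
      for (h in seq_len(H)) D[ch, h] <- mean(crop[ch, h, ])
      for (w in seq_len(W)) D[ch, H + w] <- mean(crop[ch, , w])
    }
    A <- matrix(0, Cn, H + W)
    for (co in seq_len(Cn)) for (t in seq_len(H + W))
      A[co, t] <- sum(D[, t] * W1[, co]) + b1[co]
    AH <- .sg(A[, seq_len(H), drop = FALSE])
    AW <- .sg(A[, H + seq_len(W), drop = FALSE])
    # global branch: depthwise 3x3 same-padding conv + global average
    gvec <- numeric(Cn)
    for (ch in seq_len(Cn)) {
      y <- matrix(0, H, W)
      for (h in seq_len(H)) for (w in seq_len(W)) {
        acc <- bg[ch]
        for (ki in 1:3) for (kj in 1:3) {
          hh <- h + ki - 2; ww <- w + kj - 2
          if (hh >= 1 && hh <= H && ww >= 1 && ww <= W)
            acc <- acc + crop[ch, hh, ww] * Wg[ki, kj, ch]
        }
        y[h, w] <- acc
      }
      gvec[ch] <- mean(y)
    }
    for (ch in seq_len(Cn)) {
      for (h in seq_len(H)) for (w in seq_len(W)) {
        M <- .sg(AH[ch, h] * AW[ch, w] * gvec[ch])
        crop[ch, h, w] <- crop[ch, h, w] * M
      }
    }
    for (j in seq_len(n)) for (c in seq_len(C))
      out[(g - 1) * n + j, c, , ] <- crop[c + C * (j - 1), , ]
  }
  out[seq_len(L), , , , drop = FALSE]
}

oracle_group_module <- function(x, params) {
  d <- dim(x)
  out <- array(0, d)
  for (b in seq_len(d[1]))
    out[b, , , , ] <- oracle_group_module_one(
      array(x[b, , , , ], d[-1]), params$n,
      params$W1$value, params$b1$value, params$Wg$value, params$bg$value)
  out
}

# Nested-loop selective attention (uses the group-module oracle per branch).
oracle_selective <- function(x, sg) {
  d <- dim(x); B <- d[1]; L <- d[2]; C <- d[3]
  K <- length(sg$branches)
  Fk <- lapply(sg$branches, function(br) oracle_group_module(x, br))
  Fsum <- Reduce(`+`, Fk)
  out <- array(0, d)
  for (b in seq_len(B)) {
    Fpp <- sapply(seq_len(C), function(c) mean(Fsum[b, , c, , ]))
    hid <- pmax(0, as.vector(Fpp %*% sg$Wfc1$value) + sg$bfc1$value)
    logits <- sapply(seq_len(K), function(k)
      as.vector(hid %*% sg$Wfc2[[k]]$value) + sg$bfc2[[k]]$value)  # C x K
    for (c in seq_len(C)) {
      e <- exp(logits[c, ] - max(logits[c, ]))
      z <- e / sum(e)
      for (k in seq_len(K))
        out[b, , c, , ] <- out[b, , c, , ] + z[k] * Fk[[k]][b, , c, , ]
    }
  }
  out
}

# Direct scalar evaluation of the fuzzy-distance fusion for one sample.
# S: views x classes matrix.
oracle_fuse_one <- function(S) {
  nc <- ncol(S)
  I <- numeric(nc)
  for (j in seq_len(nc)) {
    P <- 1 - S[, j]
    PE <- sqrt(sum(P^2))
    PM <- sum(abs(P))
    s <- S[, j]
    PC <- if (sum(s^2) == 0) 1
          else 1 - sum(s * 1) / (sqrt(sum(s^2)) * sqrt(nrow(S)))
    I[j] <- PE * PM * PC
  }
  which(I == min(I))[1]
}

# Exhaustive pairwise AUC (positives vs negatives, ties count 1/2).
oracle_auc <- function(y, s) {
  pos <- s[y == 1]; neg <- s[y == 0]
  tot <- 0
  for (p in pos) for (q in neg)
    tot <- tot + (p > q) + 0.5 * (p == q)
  tot / (length(pos) * length(neg))
}

# Random exam volumes for quick tests.
rand_volume <- function(L = 4, H = 16, W = 16, view = "axial", id = "ex") {
  examVolume(array(stats::rnorm(L * H * W), c(L, H, W)), view, id)
}

rand_views <- function(L = 6, H = 16, W = 16, id = "ex") {
  out <- list()
  for (v in c("axial", "coronal", "sagittal"))
    out[[v]] <- rand_volume(L, H, W, v, id)
  out
}

# Finite-difference gradient of a scalar tape build against its backward.
fd_max_err <- function(build, params, h = 1e-6, npick = 4) {
  ns <- asNamespace("sgknee")
  loss <- build()
  ns$.td_backward(loss)
  maxerr <- 0
  for (p in params) {
    if (is.null(p$grad)) return(Inf)
    idx <- sample(length(p$value), min(npick, length(p$value)))
    for (i in idx) {
      v0 <- p$value[i]
      p$value[i] <- v0 + h; lp <- build()$value
      p$value[i] <- v0 - h; lm <- build()$value
      p$value[i] <- v0
      num <- (lp - lm) / (2 * h)
      maxerr <- max(maxerr, abs(num - p$grad[i]) / max(1, abs(num)))
    }
  }
  maxerr
}
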