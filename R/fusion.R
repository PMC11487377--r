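# Decision-level fusion of per-view confidence scores.
#
# For each class j, the three views' confidences are compared with the ideal
# solution vector 1 = (1, 1, 1).  Three measures are combined by product:
#   P_j  = (1 - S_aj, 1 - S_cj, 1 - S_sj)
#   I_j  = ||P_j||_2  *  sum|P_j|  *  (1 - cos((S_aj, S_cj, S_sj), 1))
# and the predicted class is argmin_j I_j (ties -> lowest class index).
# A degenerate all-zero score triple gets maximal cosine distance (1).

#' Distance vector to the ideal solution
#'
#' Component-wise \code{1 - S} for class \code{j} across the views.
#'
#' @param scores numeric matrix, one row per view, one column per class;
#'   each row a confidence score summing to 1.
#' @param j class index (1-based).
#' @return Numeric vector of length \code{nrow(scores)}.
#' @export
distanceVector <- function(scores, j) {
  if (j < 1 || j > ncol(scores)) stop("class index out of range")
  1 - scores[, j]
}

.fuse_one <- function(scores) {
  nclass <- ncol(scores)
  nview <- nrow(scores)
  I <- numeric(nclass); PE <- numeric(nclass); PM <- numeric(nclass)
  PC <- numeric(nclass)
  for (j in seq_len(nclass)) {
    P <- 1 - scores[, j]
    PE[j] <- sqrt(sum(P^2))
    PM[j] <- sum(abs(P))
    s <- scores[, j]
    ns <- sqrt(sum(s^2))
    PC[j] <- if (nview < 2L) 0
             else if (ns == 0) 1
             else 1 - sum(s) / (ns * sqrt(nview))
    I[j] <- PE[j] * PM[j] * PC[j]
  }
  if (nview < 2L) {
    # single-view mode: the cosine term vanishes for scalars, collapsing
    # I_j; fall back to the view's own argmax
    y <- which.max(scores[1, ])
  } else {
    y <- which(I == min(I))[1]
  }
  list(class = y, I = I, PE = PE, PM = PM, PC = PC)
}

#' Fuse per-view confidence scores
#'
#' Applies the fuzzy-distance rule per sample.  For ROC purposes a fused
#' continuous tear score is also returned: since I_j is a distance (smaller
#' is better), the tear score is \code{I_0 / (I_0 + I_1)} -- a package
#' convention for threshold-free evaluation, not part of the decision rule.
#'
#' @param scoresByView named list of \code{n x nclass} probability matrices
#'   (one per view, same row order); a single matrix engages single-view
#'   mode.
#' @return List with \code{class} (1-based predicted class per sample),
#'   \code{label} (\code{class - 1}, the binary tear label),
#'   \code{I} (\code{n x nclass} distance products) and \code{score}
#'   (fused tear score in [0, 1]).
#' @examples
#' sa <- matrix(c(0.2, 0.8), 1); sc <- matrix(c(0.3, 0.7), 1)
#' ss <- matrix(c(0.4, 0.6), 1)
#' fuseViews(list(axial = sa, coronal = sc, sagittal = ss))$label  # 1
#' @export
fuseViews <- function(scoresByView) {
  if (is.matrix(scoresByView)) scoresByView <- list(scoresByView)
  n <- nrow(scoresByView[[1]])
  nclass <- ncol(scoresByView[[1]])
  cls <- integer(n)
  I <- matrix(NA_real_, n, nclass)
  score <- numeric(n)
  for (i in seq_len(n)) {
    S <- do.call(rbind, lapply(scoresByView, function(m) m[i, ]))
    r <- .fuse_one(S)
    cls[i] <- r$class
    I[i, ] <- r$I
    score[i] <- if (nrow(S) < 2L) S[1, 2]
                else if (sum(r$I[1:2]) == 0) 0.5
                else r$I[1] / (r$I[1] + r$I[2])
  }
  list(class = cls, label = cls - 1L, I = I, score = score)
}
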