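# Image-quality losses: mean absolute error (reference-based) and the
# MEF-SSIM no-reference structural score, plus the task-level composites.
#
# MEF-SSIM construction (per the original multi-exposure fusion quality
# index): every sliding window of every source patch x_k is decomposed into
# mean mu_k, contrast c_k = ||x_k - mu_k|| and unit structure s_k. The
# desired patch has the strongest contrast among the sources
# (c_hat = max_k c_k) and a structure that is the contrast-weighted,
# renormalized combination of the source structures (weights c_k^p). The
# fused patch is compared against this desired patch by a mean-removed,
# structure/contrast-only similarity; the luminance term is deliberately
# absent, so the score ignores global intensity offsets.

#' MEF-SSIM parameters
#'
#' @param window Side length of the square sliding window (default 8).
#' @param stride Window stride in pixels (default 1).
#' @param L Dynamic range of the luminance values (1 for unit-interval data).
#' @param K Stability constant factor; `C = (K * L)^2` with `K = 0.03`.
#' @param p Structure-weight exponent: source structures are combined with
#'   weights proportional to `contrast^p` (default 4, frozen here as the
#'   package's convention).
#' @param eps Regularizer for norms of (near-)constant patches.
#' @return A `mef_ssim_params` list.
#' @export
mef_ssim_params <- function(window = 8L, stride = 1L, L = 1, K = 0.03,
                            p = 4, eps = 1e-12) {
  stopifnot(window >= 2L, stride >= 1L, L > 0, K > 0)
  structure(list(window = as.integer(window), stride = as.integer(stride),
                 L = L, C = (K * L)^2, p = p, eps = eps),
            class = "mef_ssim_params")
}

# linear indices of every sliding window: nwin x window^2, column-major
# within the window so the patch layout matches matrix(x[idx], ...)
win_index <- function(H, W, window, stride) {
  tops <- seq(1L, H - window + 1L, by = stride)
  lefts <- seq(1L, W - window + 1L, by = stride)
  base <- as.vector(outer(0:(window - 1L), (0:(window - 1L)) * H, "+"))
  starts <- as.vector(outer(tops, (lefts - 1L) * H, "+"))
  outer(starts, base, "+")
}

# desired-patch construction from the sources (constants w.r.t. the fused
# image): returns the mean-removed desired patch matrix and window geometry
mef_ssim_prepare <- function(sources, params) {
  if (!is.list(sources) || length(sources) < 1L) {
    stop("sources must be a non-empty list of luminance planes")
  }
  d <- dim(sources[[1]])
  H <- d[1]; W <- d[2]
  if (H < params$window || W < params$window) {
    stop("image smaller than the MEF-SSIM window")
  }
  for (s in sources) if (!identical(dim(s), d)) stop("source shapes differ")
  idx <- win_index(H, W, params$window, params$stride)
  wsz <- ncol(idx)
  eps <- params$eps
  p <- params$p

  chat <- NULL     # desired contrast: max_k c_k
  sbar <- NULL     # weighted structure sum
  wsum <- NULL
  for (s in sources) {
    P <- matrix(s[idx], nrow(idx), wsz)
    Pc <- P - rowMeans(P)
    ck <- sqrt(rowSums(Pc * Pc))
    chat <- if (is.null(chat)) ck else pmax(chat, ck)
    wk <- ck^p + eps
    contrib <- Pc * (wk / (ck + eps))
    sbar <- if (is.null(sbar)) contrib else sbar + contrib
    wsum <- if (is.null(wsum)) wk else wsum + wk
  }
  sbar <- sbar / wsum
  snorm <- sqrt(rowSums(sbar * sbar))
  shat <- sbar / (snorm + eps)
  xhat <- shat * chat           # mean-zero desired patch per window
  list(xhat = xhat, idx = idx, H = H, W = W,
       Cn = params$C * wsz, vx = rowSums(xhat * xhat))
}

#' MEF-SSIM no-reference fusion quality score
#'
#' Scores how well `fused` preserves, window by window, the strongest
#' structure present among the `sources`. 1 is a perfect match of the desired
#' structure; the score is symmetric in the source order and insensitive to a
#' constant intensity offset of the fused image.
#'
#' @param sources List of K `H x W` luminance matrices on `[0, 1]`.
#' @param fused `H x W` fused luminance matrix.
#' @param params A [mef_ssim_params()].
#' @return Scalar score in `[-1, 1]`.
#' @export
mef_ssim <- function(sources, fused, params = mef_ssim_params()) {
  prep <- mef_ssim_prepare(sources, params)
  if (!identical(dim(fused), c(prep$H, prep$W))) {
    stop("fused image shape differs from the sources")
  }
  F0 <- matrix(fused[prep$idx], nrow(prep$idx), ncol(prep$idx))
  Fc <- F0 - rowMeans(F0)
  cross <- rowSums(Fc * prep$xhat)
  vy <- rowSums(Fc * Fc)
  mean((2 * cross + prep$Cn) / (prep$vx + vy + prep$Cn))
}

#' MEF-SSIM loss
#'
#' `1 - mef_ssim(sources, fused)`; ranges over `[0, 2]`.
#'
#' @inheritParams mef_ssim
#' @return Scalar loss.
#' @export
mef_ssim_loss <- function(sources, fused, params = mef_ssim_params()) {
  1 - mef_ssim(sources, fused, params)
}

# tape version: fused is a node holding an H*W (x1) value; sources are plain.
# Returns a scalar loss node 1 - score, differentiable in the fused image.
nd_mef_ssim_loss <- function(tp, sources, fused_node, params) {
  prep <- mef_ssim_prepare(sources, params)
  F0 <- nd_gather(fused_node, prep$idx)
  Fc <- nd_subcol(F0, nd_rowMeans(F0))
  cross <- nd_rowSums(nd_mulc(Fc, prep$xhat))
  vy <- nd_rowSums(nd_mul(Fc, Fc))
  num <- nd_addc(nd_mulc(cross, 2), prep$Cn)
  den <- nd_addc(vy, prep$vx + prep$Cn)
  score <- nd_mean(nd_div(num, den))
  nd_addc(nd_mulc(score, -1), 1)
}

#' Mean absolute error
#'
#' @param fused,reference Arrays of identical shape.
#' @return Scalar `mean(|fused - reference|)`.
#' @export
mae_loss <- function(fused, reference) {
  if (!identical(dim(fused), dim(reference))) {
    stop("fused and reference shapes differ")
  }
  mean(abs(fused - reference))
}

nd_mae_loss <- function(tp, fused_node, reference) {
  nd_mean(nd_abs(nd_addc(fused_node, -as.vector(reference))))
}

#' Task loss weights
#'
#' Supervised tasks (multi-exposure, multi-focus) balance the reference MAE
#' and the no-reference MEF-SSIM losses equally (`lambda1 = lambda2 = 0.5`)
#' with EWC weight `lambda3 = 2e4`. Unsupervised tasks (medical,
#' infrared/visible) use the MEF-SSIM loss alone (`lambda1 = 1`) with EWC
#' weight `lambda2 = 2e4`; the first task trained in a curriculum gets EWC
#' weight 0.
#'
#' @param supervised Logical.
#' @param lambda1,lambda2,lambda3 Optional overrides of the defaults above.
#' @return A `loss_weights` list.
#' @export
loss_weights <- function(supervised, lambda1 = NULL, lambda2 = NULL,
                         lambda3 = NULL) {
  if (supervised) {
    w <- list(supervised = TRUE,
              lambda1 = lambda1 %||% 0.5,
              lambda2 = lambda2 %||% 0.5,
              lambda3 = lambda3 %||% 2e4)
  } else {
    w <- list(supervised = FALSE,
              lambda1 = lambda1 %||% 1,
              lambda2 = lambda2 %||% 2e4,
              lambda3 = NA_real_)
  }
  stopifnot(w$lambda1 >= 0, w$lambda2 >= 0)
  structure(w, class = "loss_weights")
}

#' Composite task loss
#'
#' Supervised: `lambda1 * MAE + lambda2 * (1 - MEF-SSIM) + lambda3 * Lewc`.
#' Unsupervised: `lambda1 * (1 - MEF-SSIM) + lambda2 * Lewc`.
#'
#' @param fused Fused luminance plane.
#' @param sources List of source luminance planes.
#' @param reference Ground-truth plane (required iff supervised).
#' @param ewc_penalty Scalar EWC penalty value (see [ewc_penalty()]).
#' @param weights A [loss_weights()].
#' @param params A [mef_ssim_params()].
#' @return Scalar loss.
#' @export
total_loss <- function(fused, sources, reference = NULL, ewc_penalty = 0,
                       weights, params = mef_ssim_params()) {
  nref <- mef_ssim_loss(sources, fused, params)
  if (weights$supervised) {
    if (is.null(reference)) stop("supervised loss requires a reference image")
    weights$lambda1 * mae_loss(fused, reference) +
      weights$lambda2 * nref + weights$lambda3 * ewc_penalty
  } else {
    weights$lambda1 * nref + weights$lambda2 * ewc_penalty
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a
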