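# The arity-agnostic, permutation-invariant fusion network.
#
# N input luminance planes ("streams") are processed by eight fusion blocks.
# Every convolution is applied with ONE shared weight set to all streams
# (streams are folded into the batch dimension), so the parameter count is
# independent of N. Each block pools its per-stream features by element-wise
# max across streams and concatenates the pooled plane back onto every
# stream, which is the only place information crosses streams; since max is
# symmetric the whole network is exactly permutation-invariant and unchanged
# by duplicated streams.
#
# Layout: per-stream feature maps are stored as a single matrix of shape
# (N*H*W) x C, stream-major (rows 1..HW = stream 1, etc.), pixels in R's
# column-major matrix order. Convolution is im2col + one BLAS matmul.

#' Network configuration
#'
#' @param base_channels Feature width `c` of every block (32 in the reference
#'   architecture; smaller values give faithful scaled-down networks).
#' @param pool Stream aggregator: `"max"` (default; exact permutation
#'   invariance with salient-feature selection) or `"sum"` (kept for the
#'   pooling ablation).
#' @param tail_batchnorm If `TRUE`, the final 32->1 convolution is followed by
#'   ReLU + batch normalization like every other block; the default `FALSE`
#'   uses a bare biased convolution and clips to `[0,1]`, which avoids
#'   normalizing a single-channel output image.
#' @param skip_pairing Named integer map from phase-2 block (5..8) to the
#'   phase-1 block (1..4) whose pre-concatenation features enter its output
#'   concatenation. Default is the mirrored U-shape `c(5,6,7,8) -> c(4,3,2,1)`.
#' @param bn_momentum,bn_eps Batch-normalization running-statistics momentum
#'   and variance stabilizer.
#' @return A `fusenet_config` list.
#' @export
net_config <- function(base_channels = 32L, pool = c("max", "sum"),
                       tail_batchnorm = FALSE,
                       skip_pairing = c(`5` = 4L, `6` = 3L, `7` = 2L, `8` = 1L),
                       bn_momentum = 0.1, bn_eps = 1e-5) {
  pool <- match.arg(pool)
  stopifnot(base_channels >= 1L)
  sp <- as.integer(skip_pairing)
  names(sp) <- names(skip_pairing)
  if (!setequal(names(sp), as.character(5:8)) || !setequal(sp, 1:4)) {
    stop("skip_pairing must be a bijection from blocks 5..8 to blocks 1..4")
  }
  structure(list(
    base_channels = as.integer(base_channels),
    kernel = 3L,
    pool = pool,
    tail_batchnorm = isTRUE(tail_batchnorm),
    skip_pairing = sp,
    bn_momentum = bn_momentum,
    bn_eps = bn_eps
  ), class = "fusenet_config")
}

# layer table: one row per learnable layer, in forward order.
# type "conv_bn" = conv (no bias) -> ReLU -> BN; "conv" = biased conv only.
net_layers <- function(config) {
  c0 <- config$base_channels
  tail2 <- if (config$tail_batchnorm) "conv_bn" else "conv"
  rows <- list(
    list(name = "block1", type = "conv_bn", cin = 1L,      cout = c0),
    list(name = "block2", type = "conv_bn", cin = 2L * c0, cout = c0),
    list(name = "block3", type = "conv_bn", cin = 2L * c0, cout = c0),
    list(name = "block4", type = "conv_bn", cin = 2L * c0, cout = c0),
    list(name = "bottleneck1", type = "conv_bn", cin = 2L * c0, cout = c0),
    list(name = "bottleneck2", type = "conv_bn", cin = c0, cout = c0),
    list(name = "bottleneck3", type = "conv",    cin = c0, cout = c0),
    list(name = "block5", type = "conv_bn", cin = c0,      cout = c0),
    list(name = "block6", type = "conv_bn", cin = 3L * c0, cout = c0),
    list(name = "block7", type = "conv_bn", cin = 3L * c0, cout = c0),
    list(name = "block8", type = "conv_bn", cin = 3L * c0, cout = c0),
    list(name = "tail1",  type = "conv_bn", cin = 3L * c0, cout = c0),
    list(name = "tail2",  type = tail2,     cin = c0,      cout = 1L)
  )
  rows
}

#' Per-layer trainable parameter counts
#'
#' Counting convention: `Conv+ReLU+BN` layers have `kH*kW*Cin*Cout`
#' convolution weights (no bias, since the normalization offset absorbs it)
#' plus `2*Cout` normalization gain/offset; bare convolution layers have
#' `kH*kW*Cin*Cout + Cout` (bias retained). With `base_channels = 32` this
#' reproduces the reference architecture's printed counts
#' (352 / 18,496 / 27,712 / 9,280 / 9,248).
#'
#' @param config A [net_config()].
#' @return `data.frame` with columns `layer`, `type`, `cin`, `cout`, `params`.
#' @export
count_parameters <- function(config = net_config()) {
  k2 <- config$kernel^2
  rows <- net_layers(config)
  out <- do.call(rbind, lapply(rows, function(r) {
    n <- k2 * r$cin * r$cout +
      if (r$type == "conv_bn") 2L * r$cout else r$cout
    data.frame(layer = r$name, type = r$type, cin = r$cin, cout = r$cout,
               params = n, stringsAsFactors = FALSE)
  }))
  out
}

#' Initialize the fusion network
#'
#' He-normal convolution weights (`sd = sqrt(2 / (9 * Cin))`), unit
#' normalization gains, zero offsets and biases, except the final output
#' convolution whose bias starts at 0.5 (mid-gray) so early training is not
#' stuck against the `[0,1]` output clamp.
#'
#' @param config A [net_config()].
#' @param seed Integer seed; initialization is deterministic per seed.
#' @return A `fusenet_model`: list with `config`, flat named `params` list and
#'   flat named `buffers` list (batch-norm running statistics).
#' @export
init_fusion_net <- function(config = net_config(), seed = 1L) {
  rng <- local_rng(seed)
  on.exit(rng())
  params <- list()
  buffers <- list()
  for (r in net_layers(config)) {
    fan_in <- 9L * r$cin
    params[[paste0(r$name, ".W")]] <-
      matrix(stats::rnorm(fan_in * r$cout, 0, sqrt(2 / fan_in)),
             fan_in, r$cout)
    if (r$type == "conv_bn") {
      params[[paste0(r$name, ".gamma")]] <- rep(1, r$cout)
      params[[paste0(r$name, ".beta")]] <- rep(0, r$cout)
      buffers[[paste0(r$name, ".rmean")]] <- rep(0, r$cout)
      buffers[[paste0(r$name, ".rvar")]] <- rep(1, r$cout)
    } else {
      bias <- rep(0, r$cout)
      if (r$name == "tail2") bias[] <- 0.5
      params[[paste0(r$name, ".b")]] <- bias
    }
  }
  structure(list(config = config, params = params, buffers = buffers),
            class = "fusenet_model")
}

#' @export
print.fusenet_model <- function(x, ...) {
  tab <- count_parameters(x$config)
  cat("<fusenet_model> base_channels =", x$config$base_channels,
      "pool =", x$config$pool, "\n")
  cat("  layers:", nrow(tab), " trainable parameters:", sum(tab$params), "\n")
  invisible(x)
}

# ---- convolution plumbing ---------------------------------------------------

# 3x3 neighborhoods with zero padding for an H x W plane: an HW x 9 integer
# matrix, 0 marking out-of-frame taps. Offset order: dx (column) outer,
# dy (row) inner, so tap 5 is the center.
conv_neighbors <- function(H, W) {
  rows <- rep(seq_len(H), W)
  cols <- rep(seq_len(W), each = H)
  nb <- matrix(0L, H * W, 9L)
  j <- 0L
  for (dx in -1:1) {
    for (dy in -1:1) {
      j <- j + 1L
      r <- rows + dy
      cc <- cols + dx
      ok <- r >= 1L & r <= H & cc >= 1L & cc <= W
      v <- integer(H * W)
      v[ok] <- r[ok] + (cc[ok] - 1L) * H
      nb[, j] <- v
    }
  }
  nb
}

im2col3 <- function(X, nb) {
  cin <- ncol(X)
  Xp <- rbind(X, 0)
  zero_row <- nrow(Xp)
  out <- matrix(0, nrow(X), 9L * cin)
  for (j in 1:9) {
    idx <- nb[, j]
    idx[idx == 0L] <- zero_row
    out[, ((j - 1L) * cin + 1L):(j * cin)] <- Xp[idx, , drop = FALSE]
  }
  out
}

# Shared-weight 3x3 convolution over N stacked streams (autodiff op).
# W rows are ordered tap-major: row (j-1)*Cin + ci is tap j, input channel ci.
# Each stream is convolved by its own fixed-height matmul so every stream's
# result is bit-identical regardless of how many streams accompany it (a
# single stacked matmul would let the BLAS choose different blocking, and
# with it different rounding, for different N).
nd_conv3 <- function(x, Wn, bn = NULL, nb = NULL, n_streams = 1L) {
  Wv <- Wn$v
  cin <- ncol(x$v)
  HW <- nrow(x$v) %/% n_streams
  xcols <- vector("list", n_streams)
  outs <- vector("list", n_streams)
  for (n in seq_len(n_streams)) {
    rows <- (n - 1L) * HW + seq_len(HW)
    xcols[[n]] <- im2col3(x$v[rows, , drop = FALSE], nb)
    outs[[n]] <- xcols[[n]] %*% Wv
  }
  out <- if (n_streams == 1L) outs[[1]] else do.call(rbind, outs)
  if (!is.null(bn)) out <- out + matrix(bn$v, nrow(out), ncol(out), byrow = TRUE)
  parents <- if (is.null(bn)) list(x, Wn) else list(x, Wn, bn)
  node_new(tape_of(x), out, parents, function(g) {
    dW <- 0
    dX <- zeros_like(x$v)
    for (n in seq_len(n_streams)) {
      rows <- (n - 1L) * HW + seq_len(HW)
      gn <- g[rows, , drop = FALSE]
      dW <- dW + crossprod(xcols[[n]], gn)
      dXcol <- gn %*% t(Wv)
      for (j in 1:9) {
        idx <- nb[, j]
        keep <- idx > 0L
        blk <- dXcol[, ((j - 1L) * cin + 1L):(j * cin), drop = FALSE]
        dX[rows[idx[keep]], ] <- dX[rows[idx[keep]], , drop = FALSE] +
          blk[keep, , drop = FALSE]
      }
    }
    if (is.null(bn)) list(dX, dW) else list(dX, dW, colSums(g))
  })
}

# batch normalization per feature channel (columns); statistics are taken over
# all rows, i.e. streams folded into the batch times the spatial extent.
nd_bn <- function(x, gamma, beta, layer, benv, training, update_stats,
                  momentum, eps) {
  xv <- x$v
  n <- nrow(xv)
  gam <- gamma$v
  if (training) {
    mu <- colMeans(xv)
    xc <- sweep(xv, 2L, mu, "-")
    va <- colMeans(xc * xc)
    invstd <- 1 / sqrt(va + eps)
    xhat <- sweep(xc, 2L, invstd, "*")
    if (update_stats) {
      rm_key <- paste0(layer, ".rmean"); rv_key <- paste0(layer, ".rvar")
      benv[[rm_key]] <- (1 - momentum) * benv[[rm_key]] + momentum * mu
      benv[[rv_key]] <- (1 - momentum) * benv[[rv_key]] + momentum * va
    }
    out <- sweep(sweep(xhat, 2L, gam, "*"), 2L, beta$v, "+")
    node_new(tape_of(x), out, list(x, gamma, beta), function(g) {
      dgamma <- colSums(g * xhat)
      dbeta <- colSums(g)
      dxhat <- sweep(g, 2L, gam, "*")
      s1 <- colSums(dxhat)
      s2 <- colSums(dxhat * xhat)
      dx <- sweep(dxhat, 2L, s1 / n, "-") -
        sweep(xhat, 2L, s2 / n, "*")
      dx <- sweep(dx, 2L, invstd, "*")
      list(dx, dgamma, dbeta)
    })
  } else {
    rmu <- benv[[paste0(layer, ".rmean")]]
    rva <- benv[[paste0(layer, ".rvar")]]
    invstd <- 1 / sqrt(rva + eps)
    xhat <- sweep(sweep(xv, 2L, rmu, "-"), 2L, invstd, "*")
    out <- sweep(sweep(xhat, 2L, gam, "*"), 2L, beta$v, "+")
    node_new(tape_of(x), out, list(x, gamma, beta), function(g) {
      list(sweep(g, 2L, gam * invstd, "*"), colSums(g * xhat), colSums(g))
    })
  }
}

# element-wise max over the stream axis: (N*HW) x C -> HW x C.
# Gradient routes each element to the first stream attaining the max.
nd_pool_streams <- function(x, N, HW, type = "max") {
  xv <- x$v
  C <- ncol(xv)
  if (type == "sum") {
    out <- xv[seq_len(HW), , drop = FALSE]
    if (N > 1L) {
      for (n in 2:N) out <- out + xv[(n - 1L) * HW + seq_len(HW), , drop = FALSE]
    }
    return(node_new(tape_of(x), out, list(x), function(g) {
      dx <- zeros_like(xv)
      for (n in seq_len(N)) dx[(n - 1L) * HW + seq_len(HW), ] <- g
      list(dx)
    }))
  }
  best <- xv[seq_len(HW), , drop = FALSE]
  amax <- matrix(1L, HW, C)
  if (N > 1L) {
    for (n in 2:N) {
      cur <- xv[(n - 1L) * HW + seq_len(HW), , drop = FALSE]
      m <- cur > best
      best[m] <- cur[m]
      amax[m] <- n
    }
  }
  node_new(tape_of(x), best, list(x), function(g) {
    dx <- zeros_like(xv)
    rowv <- (as.vector(amax) - 1L) * HW + rep(seq_len(HW), C)
    colv <- rep(seq_len(C), each = HW)
    dx[cbind(rowv, colv)] <- as.vector(g)
    list(dx)
  })
}

# replicate a pooled HW x C plane onto all N streams -> (N*HW) x C
nd_rep_streams <- function(x, N) {
  xv <- x$v
  HW <- nrow(xv)
  out <- xv[rep(seq_len(HW), N), , drop = FALSE]
  node_new(tape_of(x), out, list(x), function(g) {
    dx <- g[seq_len(HW), , drop = FALSE]
    if (N > 1L) {
      for (n in 2:N) dx <- dx + g[(n - 1L) * HW + seq_len(HW), , drop = FALSE]
    }
    list(dx)
  })
}

# ---- forward pass -----------------------------------------------------------

# conv -> ReLU -> BN (or bare biased conv) for one named layer
layer_apply <- function(tp, x, layer, type, pnodes, benv, nb, n_streams,
                        training, update_stats, config) {
  if (type == "conv_bn") {
    h <- nd_conv3(x, pnodes[[paste0(layer, ".W")]], NULL, nb, n_streams)
    h <- nd_relu(h)
    nd_bn(h, pnodes[[paste0(layer, ".gamma")]], pnodes[[paste0(layer, ".beta")]],
          layer, benv, training, update_stats, config$bn_momentum, config$bn_eps)
  } else {
    nd_conv3(x, pnodes[[paste0(layer, ".W")]], pnodes[[paste0(layer, ".b")]],
             nb, n_streams)
  }
}

# Build the full forward graph on an existing tape. `stack` is a list of N
# H x W matrices; `pnodes` a named list of parameter nodes; `benv` an
# environment holding the running statistics (mutated when update_stats).
# Returns the output node (HW x 1).
net_forward_node <- function(tp, stack, pnodes, config, benv,
                             training = FALSE, update_stats = training,
                             clamp = TRUE, pool = NULL) {
  if (length(stack) < 1L) stop("need at least one input stream")
  d <- dim(stack[[1]])
  H <- d[1]; W <- d[2]
  if (H < config$kernel || W < config$kernel) {
    stop("input smaller than the convolution kernel")
  }
  for (s in stack) {
    if (!identical(dim(s), d)) stop("input planes differ in size")
  }
  N <- length(stack)
  HW <- H * W
  if (is.null(pool)) pool <- config$pool
  nb1 <- conv_neighbors(H, W)

  x <- nd_leaf(tp, matrix(unlist(stack, use.names = FALSE), N * HW, 1L))

  skips <- vector("list", 4L)
  for (k in 1:4) {
    h <- layer_apply(tp, x, paste0("block", k), "conv_bn", pnodes, benv,
                     nb1, N, training, update_stats, config)
    skips[[k]] <- h
    pooled <- nd_pool_streams(h, N, HW, pool)
    x <- nd_cbind(list(h, nd_rep_streams(pooled, N)))
  }

  x <- layer_apply(tp, x, "bottleneck1", "conv_bn", pnodes, benv, nb1, N,
                   training, update_stats, config)
  x <- layer_apply(tp, x, "bottleneck2", "conv_bn", pnodes, benv, nb1, N,
                   training, update_stats, config)
  x <- layer_apply(tp, x, "bottleneck3", "conv", pnodes, benv, nb1, N,
                   training, update_stats, config)

  for (k in 5:8) {
    h <- layer_apply(tp, x, paste0("block", k), "conv_bn", pnodes, benv,
                     nb1, N, training, update_stats, config)
    pooled <- nd_pool_streams(h, N, HW, pool)
    skip <- skips[[config$skip_pairing[[as.character(k)]]]]
    x <- nd_cbind(list(h, nd_rep_streams(pooled, N), skip))
  }

  h <- layer_apply(tp, x, "tail1", "conv_bn", pnodes, benv, nb1, N,
                   training, update_stats, config)
  pooled <- nd_pool_streams(h, N, HW, pool)
  tail_type <- if (config$tail_batchnorm) "conv_bn" else "conv"
  out <- layer_apply(tp, pooled, "tail2", tail_type, pnodes, benv, nb1, 1L,
                     training, update_stats, config)
  if (clamp) out <- nd_clamp01(out)
  out
}

param_nodes <- function(tp, params, requires_grad = FALSE) {
  nodes <- lapply(params, function(p) nd_leaf(tp, p, requires_grad))
  names(nodes) <- names(params)
  nodes
}

#' Fuse a stack of luminance planes
#'
#' Runs the network forward in inference mode (batch-norm running statistics,
#' no gradient bookkeeping kept). The output is exactly invariant to the order
#' and to duplication of the input planes.
#'
#' @param model A `fusenet_model`.
#' @param stack List of N `H x W` luminance matrices on `[0, 1]` (N >= 2 for
#'   a genuine fusion; N = 1 is accepted and useful for identity checks).
#' @param training Use batch statistics of the current stack instead of the
#'   running statistics (training-mode normalization).
#' @param clamp Clip the output to `[0, 1]` (default).
#' @param pool Override the configured stream aggregator (`"max"`/`"sum"`).
#' @return Fused `H x W` matrix.
#' @export
net_forward <- function(model, stack, training = FALSE, clamp = TRUE,
                        pool = NULL) {
  tp <- tape_new()
  benv <- list2env(model$buffers, parent = emptyenv())
  pn <- param_nodes(tp, model$params, requires_grad = FALSE)
  out <- net_forward_node(tp, stack, pn, model$config, benv,
                          training = training, update_stats = FALSE,
                          clamp = clamp, pool = pool)
  d <- dim(stack[[1]])
  matrix(out$v, d[1], d[2])
}

# forward + gradient of a scalar loss w.r.t. all parameters.
# loss_builder(tp, out_node) must return a scalar node.
net_loss_grad <- function(model, stack, loss_builder, training = TRUE,
                          update_stats = TRUE, clamp = TRUE, pool = NULL,
                          benv = NULL) {
  tp <- tape_new()
  own_benv <- is.null(benv)
  if (own_benv) benv <- list2env(model$buffers, parent = emptyenv())
  pn <- param_nodes(tp, model$params, requires_grad = TRUE)
  out <- net_forward_node(tp, stack, pn, model$config, benv,
                          training = training, update_stats = update_stats,
                          clamp = clamp, pool = pool)
  loss <- loss_builder(tp, out)
  tape_backward(tp, loss)
  grads <- lapply(names(model$params), function(nm) {
    g <- pn[[nm]]$g
    if (is.null(g)) zeros_like(model$params[[nm]]) else g
  })
  names(grads) <- names(model$params)
  list(loss = loss$v, grads = grads, output = out$v,
       buffers = if (own_benv) as.list(benv) else NULL)
}

# ---- checkpoints ------------------------------------------------------------

#' Save / load a model checkpoint
#'
#' A checkpoint is a single RDS archive holding a format tag, the network
#' configuration, all weights keyed by layer name, the batch-norm running
#' statistics, and (optionally) the EWC state under its own entry.
#'
#' @param model A `fusenet_model`.
#' @param path Destination file.
#' @param ewc_state Optional [ewc_state()] saved alongside the weights.
#' @return `path` (save) or a list with `model` and `ewc_state` (load).
#' @export
save_checkpoint <- function(model, path, ewc_state = NULL) {
  obj <- list(format = "setfuse-checkpoint-1",
              config = model$config,
              params = model$params,
              buffers = model$buffers,
              ewc_state = ewc_state)
  saveRDS(obj, path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  obj <- readRDS(path)
  if (!identical(obj$format, "setfuse-checkpoint-1")) {
    stop("not a setfuse checkpoint: ", path)
  }
  model <- structure(list(config = obj$config, params = obj$params,
                          buffers = obj$buffers), class = "fusenet_model")
  list(model = model, ewc_state = obj$ewc_state)
}

# seed a private RNG stream, returning a restorer for on.exit
local_rng <- function(seed) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else NULL
  set.seed(seed)
  function() {
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }
}
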