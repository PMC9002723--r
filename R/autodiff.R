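# Minimal reverse-mode automatic differentiation over base-R arrays.
#
# A tape records nodes in creation order (which is a valid topological order
# because values are never mutated); the backward sweep walks the tape in
# reverse, calling each node's pullback to accumulate gradients into its
# parents. Values are plain numeric vectors/matrices/arrays; gradients always
# carry the shape of the value they differentiate.
#
# The engine is internal: it exposes exactly the operations the fusion
# network, the MEF-SSIM loss and the EWC machinery need, nothing more.

tape_new <- function() {
  tp <- new.env(parent = emptyenv())
  tp$nodes <- vector("list", 256L)
  tp$n <- 0L
  tp
}

node_new <- function(tp, value, parents = list(), pback = NULL) {
  nd <- new.env(parent = emptyenv())
  nd$tp <- tp
  nd$v <- value
  nd$req <- length(parents) > 0L &&
    any(vapply(parents, function(p) p$req, logical(1)))
  nd$parents <- parents
  nd$pback <- pback
  nd$g <- NULL
  tp$n <- tp$n + 1L
  if (tp$n > length(tp$nodes)) {
    tp$nodes <- c(tp$nodes, vector("list", length(tp$nodes)))
  }
  tp$nodes[[tp$n]] <- nd
  nd
}

# leaf: a constant (requires_grad = FALSE) or a differentiable input/parameter
nd_leaf <- function(tp, value, requires_grad = FALSE) {
  nd <- node_new(tp, value)
  nd$req <- requires_grad
  nd
}

nd_value <- function(nd) nd$v

zeros_like <- function(x) {
  if (is.null(dim(x))) numeric(length(x)) else array(0, dim(x))
}

# Reverse sweep from `root` (typically a scalar loss). Gradients end up in
# each node's $g; read them off the leaves you kept references to.
tape_backward <- function(tp, root, seed = 1) {
  for (i in seq_len(tp$n)) tp$nodes[[i]]$g <- NULL
  g0 <- zeros_like(root$v) + seed
  root$g <- g0
  for (i in rev(seq_len(tp$n))) {
    nd <- tp$nodes[[i]]
    if (!nd$req || is.null(nd$g) || is.null(nd$pback)) next
    gs <- nd$pback(nd$g)
    ps <- nd$parents
    for (j in seq_along(ps)) {
      p <- ps[[j]]
      if (!p$req || is.null(gs[[j]])) next
      p$g <- if (is.null(p$g)) gs[[j]] else p$g + gs[[j]]
    }
  }
  invisible(root)
}

# ---- elementwise ops (operands must share shape) ---------------------------

nd_add <- function(a, b) {
  node_new(tape_of(a, b), a$v + b$v, list(a, b), function(g) list(g, g))
}

nd_sub <- function(a, b) {
  node_new(tape_of(a, b), a$v - b$v, list(a, b), function(g) list(g, -g))
}

nd_mul <- function(a, b) {
  av <- a$v; bv <- b$v
  node_new(tape_of(a, b), av * bv, list(a, b),
           function(g) list(g * bv, g * av))
}

nd_div <- function(a, b) {
  av <- a$v; bv <- b$v
  node_new(tape_of(a, b), av / bv, list(a, b),
           function(g) list(g / bv, -g * av / (bv * bv)))
}

# add / multiply by a plain constant (scalar or same-shape array)
nd_addc <- function(a, k) {
  node_new(tape_of(a), a$v + k, list(a), function(g) list(g))
}

nd_mulc <- function(a, k) {
  node_new(tape_of(a), a$v * k, list(a), function(g) list(g * k))
}

nd_abs <- function(a) {
  s <- sign(a$v)
  node_new(tape_of(a), abs(a$v), list(a), function(g) list(g * s))
}

nd_sqrt <- function(a) {
  out <- sqrt(a$v)
  node_new(tape_of(a), out, list(a), function(g) list(g * 0.5 / out))
}

nd_relu <- function(a) {
  m <- a$v > 0
  node_new(tape_of(a), a$v * m, list(a), function(g) list(g * m))
}

# clamp to [0,1]; subgradient zero outside the interval
nd_clamp01 <- function(a) {
  m <- a$v > 0 & a$v < 1
  node_new(tape_of(a), pmin(pmax(a$v, 0), 1), list(a), function(g) list(g * m))
}

# ---- reductions ------------------------------------------------------------

nd_sum <- function(a) {
  d <- a$v
  node_new(tape_of(a), sum(d), list(a),
           function(g) list(zeros_like(d) + g))
}

nd_mean <- function(a) {
  d <- a$v
  n <- length(d)
  node_new(tape_of(a), sum(d) / n, list(a),
           function(g) list(zeros_like(d) + g / n))
}

nd_rowSums <- function(a) {
  k <- ncol(a$v)
  node_new(tape_of(a), rowSums(a$v), list(a),
           function(g) list(matrix(g, length(g), k)))
}

nd_rowMeans <- function(a) {
  k <- ncol(a$v)
  node_new(tape_of(a), rowMeans(a$v), list(a),
           function(g) list(matrix(g / k, length(g), k)))
}

# subtract a per-row vector m (length nrow(a)) from every column of matrix a
nd_subcol <- function(a, m) {
  node_new(tape_of(a, m), a$v - m$v, list(a, m),
           function(g) list(g, -rowSums(g)))
}

# multiply every column of matrix a by a per-row vector m
nd_mulcol <- function(a, m) {
  av <- a$v; mv <- m$v
  node_new(tape_of(a, m), av * mv, list(a, m),
           function(g) list(g * mv, rowSums(g * av)))
}

# ---- structural ops --------------------------------------------------------

nd_matmul <- function(a, b) {
  av <- a$v; bv <- b$v
  node_new(tape_of(a, b), av %*% bv, list(a, b),
           function(g) list(g %*% t(bv), crossprod(av, g)))
}

nd_cbind <- function(nodes) {
  vals <- lapply(nodes, function(n) n$v)
  widths <- vapply(vals, ncol, integer(1))
  ends <- cumsum(widths)
  starts <- ends - widths + 1L
  node_new(tape_of_list(nodes), do.call(cbind, vals), nodes, function(g) {
    lapply(seq_along(nodes), function(j) g[, starts[j]:ends[j], drop = FALSE])
  })
}

# elementwise max over a list of same-shape nodes; ties route the gradient to
# the first attaining element (documented subgradient convention)
nd_vmax <- function(nodes) {
  best <- nodes[[1]]$v
  which_max <- zeros_like(best) + 1
  for (k in seq_along(nodes)[-1]) {
    m <- nodes[[k]]$v > best
    best[m] <- nodes[[k]]$v[m]
    which_max[m] <- k
  }
  node_new(tape_of_list(nodes), best, nodes, function(g) {
    lapply(seq_along(nodes), function(k) g * (which_max == k))
  })
}

# gather: value[r, c] = x$v[idx[r, c]] where x's value is indexed linearly.
# Within each column of idx the indices are assumed distinct; across columns
# they may repeat (overlapping windows), so the pullback scatter-adds
# column by column.
nd_gather <- function(x, idx) {
  xv <- x$v
  # index linearly (a 2-column integer matrix would otherwise be taken as
  # row/column pairs)
  val <- matrix(xv[as.vector(idx)], nrow(idx), ncol(idx))
  node_new(tape_of(x), val, list(x), function(g) {
    dx <- zeros_like(xv)
    for (j in seq_len(ncol(idx))) {
      dx[idx[, j]] <- dx[idx[, j]] + g[, j]
    }
    list(dx)
  })
}

# ---- helpers ---------------------------------------------------------------

tape_of <- function(...) {
  for (n in list(...)) if (!is.null(n$tp)) return(n$tp)
  stop("internal: node without tape")
}

tape_of_list <- function(nodes) tape_of(nodes[[1]])
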