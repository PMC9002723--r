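test_that("parameter counts match the reference architecture exactly", {
  tab <- count_parameters(net_config())
  counts <- setNames(tab$params, tab$layer)
  expect_equal(counts[["block1"]], 352)
  expect_equal(counts[["block2"]], 18496)
  expect_equal(counts[["block6"]], 27712)
  expect_equal(counts[["bottleneck2"]], 9280)
  expect_equal(counts[["bottleneck3"]], 9248)
  expect_equal(counts[["block5"]], 9280)
  expect_equal(counts[["tail1"]], 27712)
  # initialized weights agree with the declared counts, layer by layer
  m <- init_fusion_net(net_config(), seed = 1)
  for (r in seq_len(nrow(tab))) {
    nm <- tab$layer[r]
    keys <- grep(paste0("^", nm, "\\."), names(m$params), value = TRUE)
    expect_equal(sum(lengths(m$params[keys])), tab$params[r], info = nm)
  }
})

test_that("forward output is bit-identical under stream permutations", {
  for (seed in 1:4) {
    m <- tiny_model(base = 4L, seed = seed)
    stack <- rand_stack(4, 12, 12, seed = seed + 100)
    ref <- net_forward(m, stack)
    for (perm in list(c(2, 1, 3, 4), c(4, 3, 2, 1), c(3, 1, 4, 2))) {
      expect_identical(net_forward(m, stack[perm]), ref)
    }
  }
})

test_that("a model runs unchanged for any arity and ignores duplicated streams", {
  m <- tiny_model(base = 4L, seed = 2)
  base_stack <- rand_stack(8, 10, 10, seed = 50)
  shapes <- lapply(1:8, function(n) dim(net_forward(m, base_stack[seq_len(n)])))
  for (s in shapes) expect_equal(s, c(10L, 10L))
  # duplication idempotence
  two <- base_stack[1:2]
  expect_identical(net_forward(m, two), net_forward(m, c(two, two)))
  expect_identical(net_forward(m, base_stack[1]),
                   net_forward(m, base_stack[c(1, 1, 1)]))
})

test_that("N identical streams equal the single-stream result at every scale", {
  m <- tiny_model(base = 4L, seed = 7)
  img <- rand_plane(16, 16, seed = 8)
  one <- net_forward(m, list(img))
  for (n in c(2, 5)) {
    expect_identical(net_forward(m, rep(list(img), n)), one)
  }
})

test_that("spatial size is preserved, including odd sizes", {
  m <- tiny_model(base = 4L, seed = 3)
  for (d in list(c(16L, 16L), c(33L, 47L))) {
    out <- net_forward(m, rand_stack(2, d[1], d[2], seed = 4))
    expect_equal(dim(out), d)
  }
  expect_error(net_forward(m, list(matrix(0, 8, 8), matrix(0, 9, 8))), "size")
})

test_that("a center-tap identity kernel rectifies the input through a bare conv", {
  set.seed(60)
  x <- matrix(rnorm(25), 5, 5)
  tp <- setfuse:::tape_new()
  W <- matrix(0, 9, 1); W[5, 1] <- 1  # tap 5 = kernel center
  xn <- setfuse:::nd_leaf(tp, matrix(as.vector(x), 25, 1))
  wn <- setfuse:::nd_leaf(tp, W)
  nb <- setfuse:::conv_neighbors(5, 5)
  out <- setfuse:::nd_relu(setfuse:::nd_conv3(xn, wn, NULL, nb))
  expect_equal(matrix(out$v, 5, 5), pmax(x, 0), tolerance = 1e-14)
})

test_that("hand conv oracle: im2col convolution equals direct 3x3 convolution", {
  set.seed(61)
  x <- matrix(rnorm(35), 5, 7)
  W <- matrix(rnorm(9), 9, 1)
  tp <- setfuse:::tape_new()
  out <- setfuse:::nd_conv3(setfuse:::nd_leaf(tp, matrix(as.vector(x), 35, 1)),
                            setfuse:::nd_leaf(tp, W), NULL,
                            setfuse:::conv_neighbors(5, 7))
  got <- matrix(out$v, 5, 7)
  # direct evaluation with zero padding; tap order: dx outer, dy inner
  direct <- matrix(0, 5, 7)
  xp <- matrix(0, 7, 9); xp[2:6, 2:8] <- x
  j <- 0
  for (dx in -1:1) for (dy in -1:1) {
    j <- j + 1
    direct <- direct + W[j] * xp[2:6 + dy, 2:8 + dx]
  }
  expect_equal(got, direct, tolerance = 1e-12)
})

test_that("autodiff parameter gradients match finite differences end to end", {
  m <- tiny_model(base = 4L, seed = 5)
  stack <- rand_stack(1, 8, 8, seed = 6)
  res <- setfuse:::net_loss_grad(m, stack, function(tp, out) setfuse:::nd_sum(out),
                                 training = TRUE, update_stats = FALSE,
                                 clamp = FALSE)
  val <- function(model) sum(net_forward(model, stack, training = TRUE,
                                         clamp = FALSE))
  for (nm in c("block1.W", "bottleneck3.W", "block7.W", "tail2.b",
               "block4.gamma")) {
    k <- min(2L, length(m$params[[nm]]))
    m2 <- m; m2$params[[nm]][k] <- m2$params[[nm]][k] + 1e-5
    m3 <- m; m3$params[[nm]][k] <- m3$params[[nm]][k] - 1e-5
    fd <- (val(m2) - val(m3)) / 2e-5
    expect_equal(res$grads[[nm]][k], fd, tolerance = 1e-4, info = nm)
  }
})

test_that("checkpoints round-trip the model and EWC state", {
  m <- tiny_model(base = 4L, seed = 9)
  st <- ewc_accumulate(ewc_state(), lapply(m$params, function(p) p * 0 + 1),
                       m$params)
  f <- withr::local_tempfile(fileext = ".rds")
  save_checkpoint(m, f, ewc_state = st)
  back <- load_checkpoint(f)
  expect_identical(back$model$params, m$params)
  expect_identical(back$model$buffers, m$buffers)
  expect_equal(back$ewc_state$tasks_seen, 1L)
  stack <- rand_stack(2, 9, 9, seed = 1)
  expect_identical(net_forward(back$model, stack), net_forward(m, stack))
})

test_that("alternative skip pairings are configurable and change the output", {
  cfg2 <- net_config(base_channels = 4L,
                     skip_pairing = c(`5` = 1L, `6` = 2L, `7` = 3L, `8` = 4L))
  m1 <- tiny_model(base = 4L, seed = 11)
  m2 <- init_fusion_net(cfg2, seed = 11)
  stack <- rand_stack(2, 10, 10, seed = 12)
  expect_false(identical(net_forward(m1, stack), net_forward(m2, stack)))
  expect_error(net_config(skip_pairing = c(`5` = 1L, `6` = 1L, `7` = 3L, `8` = 4L)),
               "bijection")
})
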