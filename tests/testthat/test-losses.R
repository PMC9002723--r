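test_that("MAE matches hand-computed values and metric axioms", {
  expect_equal(mae_loss(matrix(0.5, 3, 3), matrix(0.5, 3, 3)), 0)
  expect_equal(mae_loss(matrix(0.5, 4, 7), matrix(0.25, 4, 7)), 0.25)
  a <- matrix(c(0, 1, 1, 0), 2, 2)
  b <- matrix(c(1, 0, 1, 0), 2, 2)
  expect_equal(mae_loss(a, b), 0.5)
  # metric axioms on seeded random triples
  set.seed(21)
  for (i in 1:5) {
    x <- matrix(runif(16), 4, 4); y <- matrix(runif(16), 4, 4)
    z <- matrix(runif(16), 4, 4)
    expect_equal(mae_loss(x, y), mae_loss(y, x))
    expect_equal(mae_loss(x, x), 0)
    expect_lte(mae_loss(x, z), mae_loss(x, y) + mae_loss(y, z) + 1e-12)
  }
  expect_error(mae_loss(matrix(0, 2, 2), matrix(0, 3, 3)), "shape")
})

test_that("MEF-SSIM scores 1 for a perfect single-source fusion", {
  x <- rand_plane(12, 12, seed = 30)
  p <- mef_ssim_params()
  expect_equal(mef_ssim(list(x), x, p), 1, tolerance = 1e-6)
  expect_equal(mef_ssim(list(x, x, x), x, p), 1, tolerance = 1e-6)
  expect_equal(mef_ssim_loss(list(x), x, p), 0, tolerance = 1e-6)
})

test_that("MEF-SSIM matches the single-window negation closed form", {
  s <- rand_plane(8, 8, seed = 31)
  p <- mef_ssim_params()
  prep <- setfuse:::mef_ssim_prepare(list(s), p)
  xhat <- as.vector(prep$xhat)        # one window, mean-zero desired patch
  fused <- matrix(0.5 - xhat, 8, 8)   # fused patch = const - xhat
  sig2 <- sum(xhat^2) / 64
  want <- (-2 * sig2 + p$C) / (2 * sig2 + p$C)
  expect_equal(mef_ssim(list(s), fused, p), want, tolerance = 1e-6)
})

test_that("MEF-SSIM is source-order invariant and offset invariant", {
  srcs <- rand_stack(3, 12, 12, seed = 32)
  fused <- rand_plane(12, 12, seed = 33)
  p <- mef_ssim_params()
  expect_equal(mef_ssim(srcs, fused, p), mef_ssim(rev(srcs), fused, p),
               tolerance = 1e-12)
  expect_equal(mef_ssim(srcs, fused, p), mef_ssim(srcs, fused + 0.1, p),
               tolerance = 1e-6)
})

test_that("constant-source windows score 1 iff the fused patch is constant", {
  flat <- matrix(0.4, 8, 8)
  p <- mef_ssim_params()
  expect_equal(mef_ssim(list(flat, flat), matrix(0.9, 8, 8), p), 1,
               tolerance = 1e-6)
  noisy <- matrix(0.4, 8, 8) + rand_plane(8, 8, seed = 34) * 0.3
  expect_lt(mef_ssim(list(flat, flat), noisy, p), 1)
})

test_that("the desired mosaic scores at least as high as blurred versions of it", {
  p <- mef_ssim_params()
  for (seed in 1:5) {
    srcs <- list(make_synthetic_raw(seed, c(16, 16)),
                 make_synthetic_raw(seed + 50, c(16, 16)))
    # a high-quality fusion candidate: pixel-wise max-contrast source
    cand <- pmax(srcs[[1]], srcs[[2]])
    blurred <- gaussian_blur(cand, 1.5)
    expect_gte(mef_ssim(srcs, cand, p), mef_ssim(srcs, blurred, p))
  }
})

test_that("MEF-SSIM loss gradient matches finite differences", {
  srcs <- rand_stack(2, 8, 8, seed = 35)
  f0 <- rand_plane(8, 8, seed = 36)
  p <- mef_ssim_params()
  tp <- setfuse:::tape_new()
  fn <- setfuse:::nd_leaf(tp, matrix(as.vector(f0), 64, 1), requires_grad = TRUE)
  loss <- setfuse:::nd_mef_ssim_loss(tp, srcs, fn, p)
  expect_equal(loss$v, mef_ssim_loss(srcs, f0, p), tolerance = 1e-12)
  setfuse:::tape_backward(tp, loss)
  val <- function(fv) mef_ssim_loss(srcs, matrix(fv, 8, 8), p)
  for (k in c(1, 20, 45, 64)) {
    fd <- fd_grad(val, as.vector(f0), k)
    expect_equal(fn$g[k], fd, tolerance = 1e-4 * max(1, abs(fd)))
  }
})

test_that("composite task losses follow the stated arithmetic", {
  x <- rand_plane(10, 10, seed = 37)
  # all components zero
  w_sup <- loss_weights(TRUE)
  expect_equal(total_loss(x, list(x), reference = x, ewc_penalty = 0,
                          weights = w_sup), 0, tolerance = 1e-6)
  # supervised: 0.5*MAE + 0.5*(1-MEFSSIM) + 2e4*Lewc
  ref <- x + 0.2
  got <- total_loss(x, list(x), reference = ref, ewc_penalty = 1e-6,
                    weights = w_sup)
  expect_equal(got, 0.5 * 0.2 + 0.5 * mef_ssim_loss(list(x), x) + 2e4 * 1e-6,
               tolerance = 1e-8)
  # unsupervised: 1*(1-MEFSSIM) + 2e4*Lewc
  w_un <- loss_weights(FALSE)
  fused <- rand_plane(10, 10, seed = 38)
  expect_equal(total_loss(fused, list(x), ewc_penalty = 1e-6, weights = w_un),
               mef_ssim_loss(list(x), fused) + 0.02, tolerance = 1e-8)
  expect_error(total_loss(x, list(x), weights = w_sup), "reference")
  # default weights
  expect_equal(unlist(w_sup[c("lambda1", "lambda2", "lambda3")]),
               c(lambda1 = 0.5, lambda2 = 0.5, lambda3 = 2e4))
  expect_equal(unlist(w_un[c("lambda1", "lambda2")]),
               c(lambda1 = 1, lambda2 = 2e4))
})
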