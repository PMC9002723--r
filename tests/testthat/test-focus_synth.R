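test_that("basal masks partition the frame into 1..4 connected regions", {
  parts <- make_basal_masks(c(128L, 128L))
  expect_length(parts, 4)
  for (k in 1:4) {
    expect_length(parts[[k]], k)
    total <- Reduce(`+`, parts[[k]])
    expect_true(all(total == 1))
  }
  # vertical split of 128 gives two 128x64 halves
  expect_equal(sum(parts[[2]][[1]]), 128 * 64)
  expect_equal(sum(parts[[2]][[2]]), 128 * 64)
  expect_error(make_basal_masks(c(4L, 4L)), "8 x 8")
})

test_that("shape masks are deterministic, binary, and cover 15-60% of the frame", {
  m1 <- make_shape_mask(c(128L, 128L), seed = 99)
  m2 <- make_shape_mask(c(128L, 128L), seed = 99)
  expect_identical(m1, m2)
  covs <- vapply(1:100, function(s) {
    m <- make_shape_mask(c(128L, 128L), seed = s)
    expect_true(all(m %in% c(0, 1)))
    mean(m)
  }, numeric(1))
  expect_true(all(covs >= 0.15 & covs <= 0.60))
})

test_that("composed partitions have exactly M disjoint parts covering the frame", {
  basal <- make_basal_masks(c(64L, 64L))
  shape <- make_shape_mask(c(64L, 64L), seed = 7)
  expect_identical(sort(unique(as.vector(shape))), c(0, 1))
  # M = 2 from a shape is the complement pair
  p2 <- compose_partition(2L, basal[[1]], shape, seed = 1)
  expect_true(all(Reduce(`+`, p2) == 1))
  areas <- sort(vapply(p2, sum, numeric(1)))
  expect_equal(areas, sort(c(sum(shape), 64 * 64 - sum(shape))))
  # exhaustive pixel check across M and basal choices
  for (M in c(2L, 4L, 8L)) {
    for (b in c(2L, 4L)) {
      parts <- compose_partition(M, basal[[b]], shape, seed = M + b)
      expect_length(parts, M)
      expect_true(all(Reduce(`+`, parts) == 1))
      expect_true(all(vapply(parts, sum, numeric(1)) >= 0.01 * 64 * 64))
    }
  }
  expect_error(compose_partition(9L, basal[[1]], shape), "between 2 and 8")
})

test_that("defocus blending selects clear or blurred pixel-for-pixel", {
  clear <- make_synthetic_raw(5, c(32, 32))
  fs <- synthesize_focus_set(clear, M = 3, sigma = 1.5, seed = 11)
  expect_equal(fs$sigma, 1.5)
  for (i in seq_len(3)) {
    P <- fs$masks[[i]]
    D <- fs$defocused[[i]]
    expect_identical(D[P == 1], clear[P == 1])
    expect_identical(D[P == 0], fs$blurred[P == 0])
  }
  # degenerate masks: all-ones keeps the clear image, all-zeros the blur
  all1 <- clear * 1 + fs$blurred * 0
  expect_identical(all1, clear)
  # mask-selection reconstruction is exact: sum_i D_i * P_i = I_clear
  rec <- Reduce(`+`, Map(`*`, fs$defocused, fs$masks))
  expect_identical(rec, clear)
  # drawn sigma stays in [1, 2]
  sig <- vapply(1:20, function(s) {
    synthesize_focus_set(clear, M = 2, seed = s)$sigma
  }, numeric(1))
  expect_true(all(sig >= 1 & sig <= 2))
})

test_that("Gaussian blur matches a brute-force direct convolution with mirrored borders", {
  set.seed(23)
  x <- matrix(runif(15 * 11), 15, 11)
  sigma <- 1.3
  got <- gaussian_blur(x, sigma)
  k <- setfuse:::gaussian_taps(sigma)
  r <- (length(k) - 1) / 2
  refl <- function(i, n) { while (i < 1 || i > n) { if (i < 1) i <- 2 - i; if (i > n) i <- 2 * n - i }; i }
  want <- matrix(0, 15, 11)
  for (i in 1:15) for (j in 1:11) {
    acc <- 0
    for (a in -r:r) for (b in -r:r) {
      acc <- acc + k[a + r + 1] * k[b + r + 1] *
        x[refl(i + a, 15), refl(j + b, 11)]
    }
    want[i, j] <- acc
  }
  expect_equal(got, want, tolerance = 1e-12)
})

test_that("synthetic raw images are textured, deterministic, and in range", {
  a <- make_synthetic_raw(77, c(32, 32))
  expect_identical(a, make_synthetic_raw(77, c(32, 32)))
  expect_true(all(a >= 0 & a <= 1))
  ge <- function(x) mean(abs(diff(x))) + mean(abs(t(diff(t(x)))))
  expect_lt(ge(gaussian_blur(a, 2)), ge(a))
})

test_that("exposure stacks are gain-monotone with near-complete coverage", {
  es <- make_exposure_set(3, c(32, 32), K = 3)
  expect_length(es$ldr, 3)
  # gain 1 never clips: first frame equals the radiance rendering
  expect_identical(es$ldr[[1]], es$radiance * es$gains[1])
  for (k in 2:3) {
    expect_true(all(es$ldr[[k]] >= es$ldr[[k - 1]] - 1e-12))
  }
  covs <- vapply(1:20, function(s) {
    e <- make_exposure_set(s, c(32, 32), K = 3)
    ok <- Reduce(`|`, lapply(e$ldr, function(l) l > 1 / 255 & l < 1))
    mean(ok)
  }, numeric(1))
  expect_true(all(covs >= 0.95))
})

test_that("dataset generation is reproducible and partition-exact on every set", {
  d1 <- make_focus_dataset(4, c(24, 24), seed = 3, min_m = 2, max_m = 4)
  d2 <- make_focus_dataset(4, c(24, 24), seed = 3, min_m = 2, max_m = 4)
  expect_identical(d1, d2)
  for (s in d1) {
    expect_true(all(Reduce(`+`, s$masks) == 1))
    rec <- Reduce(`+`, Map(`*`, s$sources, s$masks))
    expect_identical(rec, s$reference)
  }
})
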