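# Synthetic training-data simulator for multi-focus fusion.
#
# A scene's M defocused variants are built from one clear image: binary
# complementary masks P_i (an exact partition of the frame) decide which
# region each variant keeps sharp, and everything else is replaced by a
# Gaussian-blurred copy:
#   D_i = I_clear * P_i + I_blur * (1 - P_i).
# The clear image is the ground truth; selecting each pixel from the variant
# whose mask covers it reconstructs the clear image exactly.
#
# Masks are composed from two ingredients: "basal" masks that split the frame
# into 1..4 coarse connected regions, and free-form "shape" masks (procedural
# superellipse figures covering 15-60% of the frame) intersected with the
# basal regions; deterministic merging/splitting then yields exactly M parts.

#' Basal frame partitions
#'
#' Four partitions of an `H x W` frame into 1, 2, 3 and 4 connected regions
#' (whole frame; vertical halves; vertical thirds; quadrants). Every
#' partition covers each pixel exactly once.
#'
#' @param size Integer vector `c(H, W)`, both at least 8.
#' @return List of 4 partitions; partition `k` is a list of `k` binary
#'   matrices summing to 1 at every pixel.
#' @export
make_basal_masks <- function(size = c(128L, 128L)) {
  H <- size[1]; W <- size[2]
  if (H < 8L || W < 8L) stop("frame must be at least 8 x 8")
  ones <- matrix(1, H, W)
  colmask <- function(from, to) {
    m <- matrix(0, H, W); m[, from:to] <- 1; m
  }
  w2 <- W %/% 2L
  w3a <- W %/% 3L; w3b <- 2L * (W %/% 3L)
  h2 <- H %/% 2L
  quad <- function(r, cset) {
    m <- matrix(0, H, W); m[r, cset] <- 1; m
  }
  list(
    list(ones),
    list(colmask(1L, w2), colmask(w2 + 1L, W)),
    list(colmask(1L, w3a), colmask(w3a + 1L, w3b), colmask(w3b + 1L, W)),
    list(quad(1:h2, 1:w2), quad(1:h2, (w2 + 1L):W),
         quad((h2 + 1L):H, 1:w2), quad((h2 + 1L):H, (w2 + 1L):W))
  )
}

#' Procedural shape mask
#'
#' A single connected superellipse figure (`|x/a|^q + |y/b|^q <= 1` with
#' `q` in {1, 2, 4}: diamond, ellipse, rounded square), fully inside the
#' frame, covering 15-60% of it. Deterministic per seed.
#'
#' @param size Integer vector `c(H, W)`.
#' @param seed Integer seed.
#' @return Binary `H x W` matrix.
#' @export
make_shape_mask <- function(size = c(128L, 128L), seed = 1L) {
  H <- size[1]; W <- size[2]
  rng <- local_rng(seed)
  on.exit(rng())
  q <- sample(c(1, 2, 4), 1L)
  # analytic area of a superellipse: 4ab * gamma(1+1/q)^2 / gamma(1+2/q)
  gq <- gamma(1 + 1 / q)^2 / gamma(1 + 2 / q)
  u <- stats::runif(1, 0.18, 0.42)        # target coverage fraction
  ab <- u * H * W / (4 * gq)
  t <- stats::runif(1, 0.6, 1.6)          # aspect jitter
  a <- sqrt(ab * t)                        # semi-axis along columns
  a <- min(a, W / 2 - 1)
  b <- min(ab / a, H / 2 - 1)
  a <- ab / b                              # restore area if b was clamped
  a <- min(a, W / 2 - 1)
  cx <- stats::runif(1, a + 1, W - a)
  cy <- stats::runif(1, b + 1, H - b)
  xs <- matrix(rep(seq_len(W), each = H), H, W)
  ys <- matrix(rep(seq_len(H), W), H, W)
  inside <- (abs(xs - cx) / a)^q + (abs(ys - cy) / b)^q <= 1
  m <- matrix(0, H, W)
  m[inside] <- 1
  m
}

#' Compose an exact M-part partition from a basal partition and a shape mask
#'
#' Each basal region is intersected with the shape mask and its complement;
#' the resulting pieces are deterministically merged (smallest first) or
#' split (largest piece cut along its pixel ordering) until exactly `M`
#' parts remain, each holding at least 1% of the pixels. The output order is
#' shuffled by `seed`.
#'
#' @param M Number of parts, 2..8.
#' @param basal A partition from [make_basal_masks()] (list of binary masks).
#' @param shape A binary matrix from [make_shape_mask()].
#' @param seed Integer seed (used only to permute the output order).
#' @return List of `M` binary matrices summing to 1 at every pixel.
#' @export
compose_partition <- function(M, basal, shape, seed = 1L) {
  if (M < 2L || M > 8L) stop("M must be between 2 and 8")
  d <- dim(basal[[1]])
  if (!identical(dim(shape), d)) stop("shape mask size differs from basal")
  npix <- prod(d)
  minpix <- max(1L, ceiling(0.01 * npix))

  pieces <- list()
  for (R in basal) {
    r <- which(R > 0)
    s1 <- r[shape[r] > 0]
    s0 <- r[shape[r] == 0]
    if (length(s1) > 0L) pieces[[length(pieces) + 1L]] <- s1
    if (length(s0) > 0L) pieces[[length(pieces) + 1L]] <- s0
  }

  sizes <- function() vapply(pieces, length, integer(1))
  merge_into <- function(i, j) {          # absorb piece i into piece j
    pieces[[j]] <<- c(pieces[[j]], pieces[[i]])
    pieces[[i]] <<- NULL
  }
  # absorb under-1% fragments first (into the currently smallest other piece)
  repeat {
    sz <- sizes()
    small <- which(sz < minpix)
    if (length(small) == 0L || length(pieces) <= 1L) break
    i <- small[1]
    j <- setdiff(order(sz), i)[1]
    merge_into(i, j)
  }
  while (length(pieces) > M) {
    sz <- sizes()
    o <- order(sz)
    merge_into(o[1], o[2])
  }
  while (length(pieces) < M) {
    sz <- sizes()
    i <- which.max(sz)
    px <- sort(pieces[[i]])               # column-major order: vertical cut
    half <- length(px) %/% 2L
    pieces[[i]] <- px[seq_len(half)]
    pieces[[length(pieces) + 1L]] <- px[(half + 1L):length(px)]
  }

  rng <- local_rng(seed)
  on.exit(rng())
  pieces <- pieces[sample.int(length(pieces))]
  lapply(pieces, function(px) {
    m <- matrix(0, d[1], d[2])
    m[px] <- 1
    m
  })
}

# ---- Gaussian blur (separable, reflective borders) -------------------------

gaussian_taps <- function(sigma) {
  r <- ceiling(3 * sigma)
  k <- exp(-(seq(-r, r))^2 / (2 * sigma^2))
  k / sum(k)
}

# n x n one-dimensional blur operator with reflective (mirror) borders
blur_operator <- function(n, sigma) {
  k <- gaussian_taps(sigma)
  r <- (length(k) - 1L) / 2L
  B <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (o in seq_along(k)) {
      j <- i + o - r - 1L
      while (j < 1L || j > n) {           # mirror at both edges
        if (j < 1L) j <- 2L - j
        if (j > n) j <- 2L * n - j
      }
      B[i, j] <- B[i, j] + k[o]
    }
  }
  B
}

#' Gaussian blur with reflective borders
#'
#' Separable Gaussian filter, kernel radius `ceil(3*sigma)`, mirror-reflected
#' at the frame edges.
#'
#' @param img `H x W` matrix.
#' @param sigma Standard deviation in pixels.
#' @return Blurred matrix of the same size.
#' @export
gaussian_blur <- function(img, sigma) {
  d <- dim(img)
  blur_operator(d[1], sigma) %*% img %*% t(blur_operator(d[2], sigma))
}

#' Synthesize one multi-focus set
#'
#' Draws a partition into `M` complementary masks, blurs the clear image with
#' one `sigma ~ U[1, 2]` (or the given value), and assembles each defocused
#' variant as `D_i = I_clear * P_i + I_blur * (1 - P_i)` exactly.
#'
#' @param clear `H x W` matrix on `[0, 1]` (the all-in-focus ground truth).
#' @param M Number of defocused variants (2..8); drawn uniformly if `NULL`.
#' @param sigma Blur standard deviation; drawn from `U[1, 2]` if `NULL`.
#' @param seed Integer seed; the whole set is deterministic per seed.
#' @return A `focus_set`: list with `defocused` (list of M matrices), `clear`,
#'   `blurred`, `masks` (list of M binary matrices), `sigma`, `M`.
#' @export
synthesize_focus_set <- function(clear, M = NULL, sigma = NULL, seed = 1L) {
  stopifnot(min(clear) >= 0, max(clear) <= 1)
  d <- dim(clear)
  rng <- local_rng(seed)
  on.exit(rng())
  if (is.null(M)) M <- sample(2:8, 1L)
  if (M < 2L || M > 8L) stop("M must be between 2 and 8")
  if (is.null(sigma)) sigma <- stats::runif(1, 1, 2)
  basal_idx <- sample.int(4L, 1L)
  shape_seed <- sample.int(.Machine$integer.max - 1L, 1L)
  order_seed <- sample.int(.Machine$integer.max - 1L, 1L)
  basal <- make_basal_masks(d)[[basal_idx]]
  shape <- make_shape_mask(d, shape_seed)
  masks <- compose_partition(M, basal, shape, order_seed)
  blurred <- pmin(pmax(gaussian_blur(clear, sigma), 0), 1)
  defocused <- lapply(masks, function(P) clear * P + blurred * (1 - P))
  structure(list(defocused = defocused, clear = clear, blurred = blurred,
                 masks = masks, sigma = sigma, M = M),
            class = "focus_set")
}

#' Procedural textured raw image
#'
#' Broadband synthetic stand-in for a natural-image crop: smooth gradients,
#' a few superellipse figures at random intensities, sinusoidal texture and
#' smoothed noise, rescaled to `[0, 1]`. Blurring it measurably reduces its
#' gradient energy, so defocus is detectable.
#'
#' @param seed Integer seed.
#' @param size Integer vector `c(H, W)`.
#' @return `H x W` matrix on `[0, 1]`.
#' @export
make_synthetic_raw <- function(seed = 1L, size = c(128L, 128L)) {
  H <- size[1]; W <- size[2]
  rng <- local_rng(seed)
  on.exit(rng())
  xs <- matrix(rep(seq_len(W), each = H), H, W) / W
  ys <- matrix(rep(seq_len(H), W), H, W) / H
  img <- stats::runif(1, 0.2, 0.8) +
    stats::runif(1, -0.5, 0.5) * xs + stats::runif(1, -0.5, 0.5) * ys
  for (i in seq_len(4L)) {
    sh <- make_shape_mask(size, sample.int(.Machine$integer.max - 1L, 1L))
    img <- img + stats::runif(1, -0.6, 0.6) * sh
  }
  f1 <- stats::runif(1, 4, 12); f2 <- stats::runif(1, 4, 12)
  img <- img + 0.15 * sin(2 * pi * (f1 * xs + f2 * ys))
  noise <- matrix(stats::rnorm(H * W), H, W)
  img <- img + 0.1 * gaussian_blur(noise, 1)
  rng01(img)
}

rng01 <- function(x) {
  r <- range(x)
  if (r[2] - r[1] < 1e-12) return(x * 0 + 0.5)
  (x - r[1]) / (r[2] - r[1])
}

#' Procedural bracketed-exposure stack
#'
#' Renders a latent radiance map at `K` exposure gains with clipping at the
#' sensor limits, plus a tone-mapped reference. The gains are spaced so that
#' nearly every pixel is well exposed in at least one frame.
#'
#' @param seed Integer seed.
#' @param size Integer vector `c(H, W)`.
#' @param K Number of exposures (>= 2).
#' @return List with `ldr` (list of K matrices on `[0,1]`), `reference`
#'   (tone-mapped radiance on `[0,1]`), `radiance`, `gains`.
#' @export
make_exposure_set <- function(seed = 1L, size = c(128L, 128L), K = 3L) {
  if (K < 2L) stop("need at least two exposures")
  raw <- make_synthetic_raw(seed, size)
  radiance <- exp(4 * raw - 4)            # in [e^-4, 1]
  gains <- 2^seq(0, 4, length.out = K)
  ldr <- lapply(gains, function(g) pmin(pmax(radiance * g, 0), 1))
  reference <- rng01(radiance / (1 + radiance))
  list(ldr = ldr, reference = reference, radiance = radiance, gains = gains)
}

# ---- dataset builders ------------------------------------------------------

set_seeds <- function(master_seed, n) {
  rng <- local_rng(master_seed)
  on.exit(rng())
  sample.int(.Machine$integer.max - 1L, n)
}

#' In-memory synthetic datasets
#'
#' `make_focus_dataset()` builds `n_sets` multi-focus sets (sources =
#' defocused variants, reference = clear image); `make_exposure_dataset()`
#' builds exposure stacks (sources = LDR frames, reference = tone-mapped
#' radiance). Both are bit-reproducible per master seed.
#'
#' @param n_sets Number of scenes.
#' @param size Frame size `c(H, W)`.
#' @param seed Master seed.
#' @param min_m,max_m Range of the number of defocused variants per set.
#' @param K Exposures per stack.
#' @return List of sets; each set is `list(sources, reference, ...)`.
#' @export
make_focus_dataset <- function(n_sets = 8L, size = c(128L, 128L), seed = 1L,
                               min_m = 2L, max_m = 8L) {
  stopifnot(min_m >= 2L, max_m <= 8L, min_m <= max_m)
  seeds <- set_seeds(seed, 2L * n_sets)
  lapply(seq_len(n_sets), function(i) {
    clear <- make_synthetic_raw(seeds[2L * i - 1L], size)
    rng <- local_rng(seeds[2L * i])
    # sample() would treat a length-1 vector as 1:n
    m <- if (min_m == max_m) min_m else sample(seq(min_m, max_m), 1L)
    rng()
    fs <- synthesize_focus_set(clear, M = m, seed = seeds[2L * i])
    list(sources = fs$defocused, reference = fs$clear, masks = fs$masks,
         sigma = fs$sigma, M = fs$M)
  })
}

#' @rdname make_focus_dataset
#' @export
make_exposure_dataset <- function(n_sets = 8L, size = c(128L, 128L),
                                  seed = 1L, K = 3L) {
  seeds <- set_seeds(seed, n_sets)
  lapply(seq_len(n_sets), function(i) {
    es <- make_exposure_set(seeds[i], size, K)
    list(sources = es$ldr, reference = es$reference, gains = es$gains)
  })
}

#' Write a multi-focus dataset to disk
#'
#' Layout: `<root>/set_<id>/D_<i>.png`, `clear.png`, `mask_<i>.png` plus a
#' JSON `manifest.json` recording the master seed and each set's seed, M and
#' sigma. Byte-reproducible per master seed.
#'
#' @param root Output directory (created if needed).
#' @param n_sets,size,seed,min_m,max_m As in [make_focus_dataset()].
#' @return The manifest, invisibly.
#' @export
write_focus_dataset <- function(root, n_sets = 8L, size = c(128L, 128L),
                                seed = 1L, min_m = 2L, max_m = 8L) {
  dir.create(root, recursive = TRUE, showWarnings = FALSE)
  sets <- make_focus_dataset(n_sets, size, seed, min_m, max_m)
  entries <- lapply(seq_along(sets), function(i) {
    s <- sets[[i]]
    dir <- file.path(root, sprintf("set_%03d", i))
    dir.create(dir, showWarnings = FALSE)
    for (j in seq_along(s$sources)) {
      write_image(s$sources[[j]], file.path(dir, sprintf("D_%d.png", j)))
      write_image(s$masks[[j]], file.path(dir, sprintf("mask_%d.png", j)))
    }
    write_image(s$reference, file.path(dir, "clear.png"))
    list(id = i, M = s$M, sigma = s$sigma)
  })
  manifest <- list(seed = seed, size = size, n_sets = n_sets,
                   sets = entries)
  jsonlite::write_json(manifest, file.path(root, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}
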