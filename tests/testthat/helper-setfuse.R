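# shared tiny fixtures; everything is generated in code, seeded

tiny_model <- function(base = 4L, seed = 1L, ...) {
  init_fusion_net(net_config(base_channels = base, ...), seed = seed)
}

rand_plane <- function(h, w, seed) {
  set.seed(seed)
  matrix(runif(h * w), h, w)
}

rand_stack <- function(n, h, w, seed) {
  set.seed(seed)
  lapply(seq_len(n), function(i) matrix(runif(h * w), h, w))
}

rand_rgb <- function(h, w, seed) {
  set.seed(seed)
  array(runif(h * w * 3), c(h, w, 3))
}

# central finite difference of f at x, perturbing element k
fd_grad <- function(f, x, k, h = 1e-6) {
  xp <- x; xp[k] <- xp[k] + h
  xm <- x; xm[k] <- xm[k] - h
  (f(xp) - f(xm)) / (2 * h)
}
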