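# Evaluation metrics: histogram entropy, mutual information between each
# source and the fused image, and MEF-SSIM (shared kernel with the loss).
# All metrics operate on the luminance channel.

#' Shannon entropy of an image histogram
#'
#' Values on `[0, 1]` are quantized to `bins` uniform levels; empty bins
#' contribute nothing. At 256 bins the result is bounded by 8 bits.
#'
#' @param image Numeric matrix/array on `[0, 1]`.
#' @param bins Number of histogram bins (default 256).
#' @return Entropy in bits.
#' @export
img_entropy <- function(image, bins = 256L) {
  q <- quantize_levels(image, bins)
  p <- tabulate(q + 1L, nbins = bins)
  p <- p[p > 0] / length(q)
  -sum(p * log2(p))
}

quantize_levels <- function(image, bins) {
  v <- as.vector(image)
  pmin(pmax(floor(v * bins), 0), bins - 1L)
}

#' Mutual information between sources and fused image
#'
#' Sum over the sources of `I(source_k; fused)`, each term computed from the
#' joint `bins x bins` histogram as `H(X) + H(Y) - H(X, Y)`. With this
#' convention, fusing two nearly identical sources scores about twice the
#' fused image's entropy.
#'
#' @param sources List of K matrices on `[0, 1]` (a single matrix is
#'   promoted to a one-element list).
#' @param fused Matrix on `[0, 1]`, same shape as the sources.
#' @param bins Histogram bins per axis (default 256).
#' @return Mutual information in bits, `>= 0` up to float rounding.
#' @export
mutual_information <- function(sources, fused, bins = 256L) {
  if (!is.list(sources)) sources <- list(sources)
  qf <- quantize_levels(fused, bins)
  hf <- entropy_of_counts(tabulate(qf + 1L, nbins = bins))
  tot <- 0
  for (s in sources) {
    if (length(s) != length(qf)) stop("source and fused shapes differ")
    qs <- quantize_levels(s, bins)
    hs <- entropy_of_counts(tabulate(qs + 1L, nbins = bins))
    joint <- tabulate(qs * bins + qf + 1L, nbins = bins * bins)
    hj <- entropy_of_counts(joint)
    tot <- tot + max(hs + hf - hj, 0)
  }
  tot
}

entropy_of_counts <- function(counts) {
  p <- counts[counts > 0]
  p <- p / sum(p)
  -sum(p * log2(p))
}

#' Fuse one scene (luminance + chroma)
#'
#' Converts RGB sources to luma/chroma, fuses the luminance planes with the
#' network and the chroma planes with the weighted chroma rule
#' ([fuse_chroma()]), and reassembles. All-grayscale input yields a grayscale
#' output.
#'
#' @param images List of images (matrices or `H x W x 3` arrays on `[0,1]`).
#' @param model A `fusenet_model`.
#' @return Fused image: matrix if all inputs were grayscale, else RGB array.
#' @export
fuse_scene <- function(images, model) {
  if (length(images) < 1L) stop("need at least one image")
  if (length(images) == 1L) warning("fusing a single image (N = 1)")
  is_rgb <- vapply(images, function(x) length(dim(x)) == 3L, logical(1))
  lumas <- lapply(images, as_luma)
  fy <- net_forward(model, lumas)
  if (!any(is_rgb)) return(fy)
  neutral <- matrix(128, nrow(fy), ncol(fy))
  cbs <- lapply(images, function(x) {
    if (length(dim(x)) == 3L) rgb_to_ycbcr(x)$Cb else neutral
  })
  crs <- lapply(images, function(x) {
    if (length(dim(x)) == 3L) rgb_to_ycbcr(x)$Cr else neutral
  })
  ycbcr_to_rgb(list(Y = fy, Cb = fuse_chroma(cbs), Cr = fuse_chroma(crs)))
}

#' Evaluate every scene under a directory
#'
#' Directory convention: one subdirectory per scene; its lexicographically
#' sorted PNG/TIFF files are the sources (files named `mask_*` are skipped;
#' a `clear.*` file is treated as ground truth, not as a source). Each scene
#' is fused and scored by entropy, mutual information and MEF-SSIM (plus MAE
#' against the ground truth when present). Scene failures are recorded in
#' the `error` column, not fatal.
#'
#' @param root Dataset directory.
#' @param model A `fusenet_model`, or a checkpoint path.
#' @param out Optional CSV path for the per-scene report.
#' @param fuse_fn Optional override `function(images, scene_dir)` returning
#'   the fused luminance plane (e.g. an oracle); default uses the model.
#' @param mef_params A [mef_ssim_params()].
#' @return `data.frame` with one row per scene.
#' @export
evaluate_directory <- function(root, model = NULL, out = NULL, fuse_fn = NULL,
                               mef_params = mef_ssim_params()) {
  if (is.character(model)) model <- load_checkpoint(model)$model
  scenes <- sort(list.dirs(root, recursive = FALSE))
  rows <- list()
  for (scene in scenes) {
    files <- sort(list.files(scene, pattern = "\\.(png|tif|tiff)$",
                             ignore.case = TRUE, full.names = TRUE))
    srcs <- files[!grepl("^(mask_|clear\\.)", basename(files))]
    ref_file <- files[grepl("^clear\\.", basename(files))]
    row <- data.frame(scene = basename(scene), n_sources = length(srcs),
                      entropy = NA_real_, mutual_information = NA_real_,
                      mef_ssim = NA_real_, mae = NA_real_,
                      error = NA_character_)
    res <- try({
      if (length(srcs) < 1L) stop("no source images")
      images <- lapply(srcs, read_image)
      lumas <- lapply(images, as_luma)
      fused <- if (is.null(fuse_fn)) {
        as_luma(fuse_scene(images, model))
      } else {
        fuse_fn(images, scene)
      }
      row$entropy <- img_entropy(fused)
      row$mutual_information <- mutual_information(lumas, fused)
      row$mef_ssim <- mef_ssim(lumas, fused, mef_params)
      if (length(ref_file) == 1L) {
        row$mae <- mae_loss(fused, as_luma(read_image(ref_file)))
      }
    }, silent = TRUE)
    if (inherits(res, "try-error")) {
      row$error <- conditionMessage(attr(res, "condition"))
    }
    rows[[length(rows) + 1L]] <- row
  }
  report <- if (length(rows)) do.call(rbind, rows) else
    data.frame(scene = character(), n_sources = integer(),
               entropy = numeric(), mutual_information = numeric(),
               mef_ssim = numeric(), mae = numeric(), error = character())
  if (!is.null(out)) utils::write.csv(report, out, row.names = FALSE)
  report
}
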