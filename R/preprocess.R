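# Marker-controlled watershed (MCW) preprocessing.
#
# Pipeline per image: grayscale conversion -> gradient magnitude (Sobel
# by default) -> foreground markers (regional maxima of opening/closing
# by reconstruction, with h-maxima suppression) -> background markers
# (ridge lines of the distance transform of the thresholded background)
# -> marker-seeded watershed flooding of the gradient -> rendering ->
# resize to the network input size. All morphology uses 4-connectivity.

#' Parameters of the MCW preprocessing pipeline
#'
#' @param operator gradient operator: `"sobel"` (default), `"prewitt"` or
#'   `"roberts"`.
#' @param fg_radius disk radius (pixels, >= 1) of the structuring element
#'   used by opening/closing by reconstruction for foreground markers.
#' @param h_max h-maxima height in `(0, 1)`: regional maxima shallower
#'   than this are suppressed.
#' @param threshold background threshold method; only `"otsu"` is
#'   implemented.
#' @param mode rendering mode: `"overlay"` (default), `"masked"` or
#'   `"label_rgb"`, see [render_segmentation()]. Overlay keeps the
#'   original opacity intensities — the discriminative signal — and adds
#'   the watershed ridges as explicit boundary evidence; the rank-keyed
#'   `label_rgb` colouring discards absolute intensity and is intended
#'   for visual inspection.
#' @param target_height,target_width output size (>= 8), the network
#'   input size.
#' @return a `preprocess_params` list.
#' @export
preprocess_params <- function(operator = "sobel", fg_radius = 4L,
                              h_max = 0.08, threshold = "otsu",
                              mode = "overlay",
                              target_height = 100L, target_width = 100L) {
  operator <- match.arg(operator, c("sobel", "prewitt", "roberts"))
  threshold <- match.arg(threshold, "otsu")
  if (!mode %in% c("label_rgb", "overlay", "masked")) {
    stopf("unknown rendering mode '%s'", mode)
  }
  if (fg_radius < 1L) stopf("fg_radius must be >= 1")
  if (h_max <= 0 || h_max >= 1) stopf("h_max must lie in (0, 1)")
  if (target_height < 8L || target_width < 8L) {
    stopf("target size must be at least 8x8")
  }
  structure(list(operator = operator, fg_radius = as.integer(fg_radius),
    h_max = h_max, threshold = threshold, mode = mode,
    target_height = as.integer(target_height),
    target_width = as.integer(target_width)), class = "preprocess_params")
}

#' Convert an image sample to a grayscale matrix
#'
#' Three-channel images are reduced with the standard luminance weights
#' 0.299/0.587/0.114.
#'
#' @param image an [image_sample] or `[H, W]`/`[H, W, C]` array.
#' @return an `[H, W]` intensity matrix.
#' @export
to_gray <- function(image) {
  px <- if (inherits(image, "image_sample")) image$pixels else image
  if (is.matrix(px)) return(px)
  if (dim(px)[3L] == 1L) return(px[, , 1L])
  0.299 * px[, , 1L] + 0.587 * px[, , 2L] + 0.114 * px[, , 3L]
}

# Reflected-border padding by `k` pixels on every side.
pad_reflect <- function(x, k) {
  n <- nrow(x)
  m <- ncol(x)
  ri <- c(rev(seq_len(k) + 1L), seq_len(n), n - seq_len(k))
  ci <- c(rev(seq_len(k) + 1L), seq_len(m), m - seq_len(k))
  x[ri, ci, drop = FALSE]
}

# Correlate a (2k+1)x(2k+1) kernel against a reflect-padded image.
correlate_odd <- function(x, kern) {
  k <- (nrow(kern) - 1L) %/% 2L
  p <- pad_reflect(x, k)
  n <- nrow(x)
  m <- ncol(x)
  out <- matrix(0, n, m)
  for (dr in seq_len(nrow(kern))) {
    for (dc in seq_len(ncol(kern))) {
      w <- kern[dr, dc]
      if (w == 0) next
      out <- out + w * p[(dr - 1L) + seq_len(n), (dc - 1L) + seq_len(m)]
    }
  }
  out
}

#' Gradient magnitude of a single-channel image
#'
#' Computes `sqrt(Gx^2 + Gy^2)` with the named operator's kernels
#' (unnormalized 3x3 Sobel/Prewitt, 2x2 Roberts cross) and
#' reflected-border handling, so a constant image has zero gradient
#' everywhere including the border.
#'
#' @param image `[H, W]` intensity matrix (use [to_gray()] first for
#'   multi-channel input).
#' @param operator `"sobel"`, `"prewitt"` or `"roberts"`.
#' @return an object of class `gradient_image`: list with `magnitude`
#'   (same shape, nonnegative) and `operator`.
#' @export
gradient_magnitude <- function(image, operator = "sobel") {
  if (inherits(image, "image_sample")) {
    if (dim(image$pixels)[3L] != 1L) {
      stopf("gradient_magnitude needs a single-channel image; convert with to_gray() first")
    }
    image <- image$pixels[, , 1L]
  }
  if (!is.matrix(image)) {
    stopf("gradient_magnitude needs a single-channel image; convert with to_gray() first")
  }
  if (nrow(image) < 3L || ncol(image) < 3L) stopf("image must be at least 3x3")
  operator <- match.arg(operator, c("sobel", "prewitt", "roberts"))
  if (operator == "roberts") {
    # 2x2 cross differences; reflect the far edge so shape is preserved
    p <- pad_reflect(image, 1L)
    n <- nrow(image)
    m <- ncol(image)
    a <- p[1L + seq_len(n), 1L + seq_len(m)]        # (r, c)
    b <- p[2L + seq_len(n), 2L + seq_len(m)]        # (r+1, c+1)
    cc <- p[1L + seq_len(n), 2L + seq_len(m)]       # (r, c+1)
    d <- p[2L + seq_len(n), 1L + seq_len(m)]        # (r+1, c)
    g1 <- a - b
    g2 <- cc - d
  } else {
    base <- if (operator == "sobel") c(1, 2, 1) else c(1, 1, 1)
    gx <- outer(base, c(-1, 0, 1))   # column gradient
    g1 <- correlate_odd(image, gx)
    g2 <- correlate_odd(image, t(gx))
  }
  structure(list(magnitude = sqrt(g1^2 + g2^2), operator = operator),
    class = "gradient_image")
}

# Grayscale reconstruction wrappers (4-connectivity).
reconstruct_dilate <- function(marker, mask) cpp_reconstruct_dilate(marker, mask)
reconstruct_erode <- function(marker, mask) {
  -cpp_reconstruct_dilate(-marker, -mask)
}

disk_brush <- function(radius) {
  EBImage::makeBrush(2L * as.integer(radius) + 1L, "disc")
}

gray_erode <- function(x, brush) t(EBImage::imageData(
  EBImage::erode(EBImage::Image(t(x)), brush)))
gray_dilate <- function(x, brush) t(EBImage::imageData(
  EBImage::dilate(EBImage::Image(t(x)), brush)))

#' Foreground (object) markers
#'
#' Smooths the image with opening-by-reconstruction followed by
#' closing-by-reconstruction (disk of radius `fg_radius`), suppresses
#' maxima shallower than `h_max`, and returns the regional maxima of the
#' result as the foreground marker mask. On a perfectly flat image the
#' whole domain is one regional maximum, so the marker covers the image.
#'
#' @param image `[H, W]` intensity matrix in `[0, 1]` (or a
#'   single-channel [image_sample]).
#' @param params a [preprocess_params].
#' @return a logical `[H, W]` marker mask with attribute `role =
#'   "foreground"`.
#' @export
foreground_markers <- function(image, params = preprocess_params()) {
  img <- to_gray(image)
  se <- disk_brush(params$fg_radius)
  iobr <- reconstruct_dilate(gray_erode(img, se), img)
  iobrcbr <- reconstruct_erode(gray_dilate(iobr, se), iobr)
  hmx <- reconstruct_dilate(iobrcbr - params$h_max, iobrcbr)
  mask <- cpp_regional_maxima(hmx)
  structure(mask, role = "foreground")
}

#' Background markers
#'
#' Thresholds the image (Otsu), takes the distance transform of the dark
#' region, and floods it from the bright objects; the resulting watershed
#' ridge lines form a thin skeleton running between objects and are
#' returned as the background marker mask. Pixels that coincide with the
#' foreground markers are removed so the two masks are always disjoint.
#' A fully bright (or fully dark) threshold result yields an empty mask.
#'
#' @param image `[H, W]` intensity matrix in `[0, 1]` (or a
#'   single-channel [image_sample]).
#' @param params a [preprocess_params].
#' @param fg optional precomputed [foreground_markers()] mask; computed
#'   internally when missing.
#' @return a logical `[H, W]` marker mask with attribute `role =
#'   "background"`.
#' @export
background_markers <- function(image, params = preprocess_params(),
                               fg = NULL) {
  img <- to_gray(image)
  t0 <- EBImage::otsu(EBImage::Image(t(img)), range = c(0, 1))
  bw <- img > t0
  if (all(bw) || !any(bw)) {
    mask <- matrix(FALSE, nrow(img), ncol(img))
    return(structure(mask, role = "background"))
  }
  dist <- t(EBImage::imageData(EBImage::distmap(EBImage::Image(t(!bw)))))
  seeds <- cpp_label4(bw)
  ridge <- cpp_watershed(dist, seeds) == 0L
  if (is.null(fg)) fg <- foreground_markers(img, params)
  ridge[fg] <- FALSE
  structure(ridge, role = "background")
}

#' Marker-seeded watershed segmentation
#'
#' Imposes the markers as the only minima of the gradient surface by
#' flooding it from the marker components alone (Meyer's ordered-queue
#' algorithm, 4-connectivity). Every connected foreground component and
#' every connected background component becomes one catchment basin;
#' pixels where two basins meet are ridge pixels and keep label 0.
#'
#' @param gradient a [gradient_magnitude()] result (or a plain `[H, W]`
#'   matrix used directly as the flooding surface).
#' @param fg logical foreground marker mask with at least one `TRUE`.
#' @param bg logical background marker mask (may be empty).
#' @return an object of class `segmentation_result`: list with `labels`
#'   (`[H, W]` integers in `0..K`), `K` (region count), `region_sizes`,
#'   and `n_fg_regions` (how many regions stem from foreground markers).
#' @export
watershed_segment <- function(gradient, fg, bg = NULL) {
  surf <- if (inherits(gradient, "gradient_image")) gradient$magnitude else gradient
  if (!any(fg)) stopf("no markers")
  if (!all(dim(surf) == dim(fg))) stopf("gradient and marker shapes differ")
  if (is.null(bg)) bg <- matrix(FALSE, nrow(surf), ncol(surf))
  if (!all(dim(surf) == dim(bg))) stopf("gradient and marker shapes differ")
  if (any(fg & bg)) stopf("foreground and background markers overlap")
  seeds <- cpp_label4(fg)
  kf <- max(seeds)
  if (any(bg)) {
    bgl <- cpp_label4(bg)
    seeds[bg] <- bgl[bg] + kf
  }
  labels <- cpp_watershed(surf, seeds)
  k <- max(labels)
  sizes <- tabulate(labels[labels > 0L], nbins = k)
  structure(list(labels = labels, K = k, region_sizes = sizes,
    n_fg_regions = kf), class = "segmentation_result")
}

#' @export
print.segmentation_result <- function(x, ...) {
  cat(sprintf("<segmentation_result> %dx%d, %d regions (%d foreground), %d ridge pixels\n",
    nrow(x$labels), ncol(x$labels), x$K, x$n_fg_regions,
    sum(x$labels == 0L)))
  invisible(x)
}

#' Render a segmentation as a three-channel image
#'
#' Modes: `"label_rgb"` paints each region with a deterministic colour
#' keyed by the region's rank of mean original intensity (ridge pixels
#' black); `"overlay"` keeps the original pixels and paints ridge pixels
#' green; `"masked"` multiplies the original intensities by each region's
#' mean intensity (ridge pixels zero).
#'
#' @param image original `[H, W]` intensity matrix (or single-channel
#'   [image_sample]).
#' @param seg a [watershed_segment()] result.
#' @param mode rendering mode.
#' @return numeric `[H, W, 3]` array in `[0, 1]`.
#' @export
render_segmentation <- function(image, seg, mode = "label_rgb") {
  img <- to_gray(image)
  if (!all(dim(img) == dim(seg$labels))) stopf("image and segmentation shapes differ")
  if (!mode %in% c("label_rgb", "overlay", "masked")) {
    stopf("unknown rendering mode '%s'", mode)
  }
  h <- nrow(img)
  w <- ncol(img)
  lab <- seg$labels
  if (mode == "overlay") {
    out <- array(img, c(h, w, 3L))
    ridge <- lab == 0L
    out[, , 1L][ridge] <- 0
    out[, , 2L][ridge] <- 1
    out[, , 3L][ridge] <- 0
    return(out)
  }
  k <- seg$K
  means <- vapply(seq_len(k), function(i) mean(img[lab == i]), numeric(1L))
  if (mode == "masked") {
    wts <- c(0, clip01(means))  # index 1 = ridge weight 0
    out1 <- img * matrix(wts[lab + 1L], h, w)
    return(array(out1, c(h, w, 3L)))
  }
  # label_rgb: colour by rank of mean intensity, ties broken by label
  ranks <- order(order(means, seq_len(k)))
  cols <- grDevices::hsv(h = (ranks - 1) / k, s = 0.8, v = 1)
  rgb <- grDevices::col2rgb(cols) / 255
  lut <- cbind(0, rgb)  # column 1 = ridge = black
  out <- array(0, c(h, w, 3L))
  for (ch in 1:3) out[, , ch] <- matrix(lut[ch, lab + 1L], h, w)
  out
}

#' Resize an image to a target size
#'
#' Bilinear interpolation, output clipped to `[0, 1]`. A no-op when the
#' image already has the target size.
#'
#' @param image an [image_sample] or `[H, W]`/`[H, W, C]` array.
#' @param height,width target size (>= 8).
#' @return same type as the input, resized.
#' @export
resize_image <- function(image, height, width) {
  if (height < 8L || width < 8L) stopf("target size must be at least 8x8")
  px <- if (inherits(image, "image_sample")) image$pixels else image
  was_mat <- is.matrix(px)
  if (was_mat) dim(px) <- c(dim(px), 1L)
  d <- dim(px)
  if (d[1L] == height && d[2L] == width) {
    out <- px
  } else {
    out <- array(0, c(height, width, d[3L]))
    for (ch in seq_len(d[3L])) {
      # EBImage's first axis is our first (row) axis here, untransposed
      out[, , ch] <- EBImage::imageData(EBImage::resize(
        EBImage::Image(px[, , ch]), w = height, h = width))
    }
    out <- clip01(out)
  }
  if (was_mat) dim(out) <- dim(out)[1:2]
  if (inherits(image, "image_sample")) {
    image_sample(out, image$label, image$id, image$source_path)
  } else {
    out
  }
}

#' Full MCW preprocessing of one sample
#'
#' Grayscale conversion, gradient magnitude, foreground and background
#' markers, marker-seeded watershed, rendering and resizing to the target
#' size. Label and id are preserved; stage failures are re-raised with
#' the stage name attached.
#'
#' @param image an [image_sample].
#' @param params a [preprocess_params].
#' @return an [image_sample] of size `target_height x target_width x 3`.
#' @export
mcw_preprocess <- function(image, params = preprocess_params()) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stopf("mcw_preprocess stage '%s' failed for sample '%s': %s",
        name, image$id, conditionMessage(e))
    })
  }
  gray <- stage("grayscale", to_gray(image))
  grad <- stage("gradient", gradient_magnitude(gray, params$operator))
  fg <- stage("foreground_markers", foreground_markers(gray, params))
  bg <- stage("background_markers", background_markers(gray, params, fg = fg))
  seg <- stage("watershed", watershed_segment(grad, fg, bg))
  rend <- stage("render", render_segmentation(gray, seg, params$mode))
  out <- stage("resize", resize_image(rend, params$target_height,
    params$target_width))
  image_sample(out, image$label, image$id, image$source_path)
}

#' Apply MCW preprocessing to every sample of a dataset
#'
#' @param dataset a [labeled_dataset].
#' @param params a [preprocess_params].
#' @param verbose print a progress line every 25 images.
#' @return a [labeled_dataset] of preprocessed samples.
#' @export
preprocess_dataset <- function(dataset, params = preprocess_params(),
                               verbose = FALSE) {
  out <- vector("list", length(dataset$samples))
  for (i in seq_along(dataset$samples)) {
    out[[i]] <- mcw_preprocess(dataset$samples[[i]], params)
    if (verbose && i %% 25L == 0L) {
      message(sprintf("preprocessed %d/%d", i, length(out)))
    }
  }
  labeled_dataset(out, dataset$class_names)
}
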