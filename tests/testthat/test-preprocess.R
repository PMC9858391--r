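# Gradient operators, markers, watershed and the MCW pipeline.

two_disk_image <- function(hw = 40L) {
  r <- matrix(seq_len(hw), hw, hw)
  c <- matrix(seq_len(hw), hw, hw, byrow = TRUE)
  img <- matrix(0.1, hw, hw)
  img[(r - hw * 0.3)^2 + (c - hw * 0.3)^2 <= (hw * 0.15)^2] <- 0.9
  img[(r - hw * 0.7)^2 + (c - hw * 0.7)^2 <= (hw * 0.15)^2] <- 0.9
  img
}

test_that("gradient magnitude matches direct convolution oracles", {
  # constant image -> zero everywhere (reflected borders included)
  for (op in c("sobel", "prewitt", "roberts")) {
    g <- gradient_magnitude(matrix(0.4, 9, 9), op)
    expect_equal(max(abs(g$magnitude)), 0)
    expect_identical(dim(g$magnitude), c(9L, 9L))
  }
  # unit-slope horizontal ramp: uniform interior magnitude 8 (sobel),
  # 6 (prewitt) with the unnormalized kernels
  ramp <- matrix(seq_len(12), 12, 12, byrow = TRUE)
  expect_equal(unique(as.vector(gradient_magnitude(ramp, "sobel")$magnitude[2:11, 2:11])), 8)
  expect_equal(unique(as.vector(gradient_magnitude(ramp, "prewitt")$magnitude[2:11, 2:11])), 6)
  # full sobel field vs brute-force convolution at every interior pixel
  set.seed(21)
  img <- matrix(runif(100), 10, 10)
  g <- gradient_magnitude(img, "sobel")$magnitude
  kx <- outer(c(1, 2, 1), c(-1, 0, 1))
  for (r in 2:9) for (cc in 2:9) {
    w <- img[(r - 1):(r + 1), (cc - 1):(cc + 1)]
    expect_equal(g[r, cc], sqrt(sum(w * kx)^2 + sum(w * t(kx))^2),
      tolerance = 1e-12)
  }
  # single bright pixel: support confined to its 3x3 neighbourhood
  spot <- matrix(0, 11, 11)
  spot[6, 6] <- 1
  gs <- gradient_magnitude(spot, "sobel")$magnitude
  nz <- which(gs > 0, arr.ind = TRUE)
  expect_true(all(abs(nz[, 1] - 6) <= 1 & abs(nz[, 2] - 6) <= 1))
})

test_that("gradient refuses multi-channel input", {
  s <- image_sample(array(0.5, c(8, 8, 3)), "a", "x")
  expect_error(gradient_magnitude(s), "to_gray")
})

test_that("foreground markers sit inside bright objects; flat image is one marker", {
  img <- two_disk_image()
  p <- preprocess_params(fg_radius = 2L, h_max = 0.1)
  fg <- foreground_markers(img, p)
  comps <- aclnet:::cpp_label4(fg)
  expect_gte(max(comps), 2L)
  # every marker component intersects a disk, and markers are bright
  expect_true(all(img[fg] >= mean(img)))
  for (k in seq_len(max(comps))) expect_true(all(img[comps == k] > 0.5))
  flat <- matrix(0.3, 20, 20)
  expect_true(all(foreground_markers(flat, p)))
})

test_that("background markers avoid objects and are disjoint from foreground", {
  img <- two_disk_image()
  p <- preprocess_params(fg_radius = 2L)
  fg <- foreground_markers(img, p)
  bg <- background_markers(img, p, fg = fg)
  expect_true(any(bg))
  expect_true(all(img[bg] < 0.5))     # outside both disks
  expect_false(any(bg & fg))
  # fully bright image: no background
  expect_false(any(background_markers(matrix(0.9, 16, 16) +
    diag(16) * 0.05, p)))
})

test_that("watershed equals the brute-force flooding oracle on random fixtures", {
  set.seed(77)
  for (rep in 1:12) {
    h <- sample(6:20, 1)
    w <- sample(6:20, 1)
    fx <- random_ws_fixture(h, w, sample(2:5, 1))
    got <- aclnet:::cpp_watershed(fx$P, fx$seeds)
    want <- ws_oracle(fx$P, fx$seeds)
    expect_identical(got, matrix(as.integer(want), h, w))
  }
})

test_that("flat surface with two point markers splits along the midline", {
  P <- matrix(0, 9, 9)
  seeds <- matrix(0L, 9, 9)
  seeds[5, 2] <- 1L
  seeds[5, 8] <- 2L
  lab <- aclnet:::cpp_watershed(P, seeds)
  expect_true(all(lab[, 1:4] == 1L))
  expect_true(all(lab[, 6:9] == 2L))
  expect_true(all(lab[, 5] == 0L))  # equidistant ridge column
})

test_that("watershed_segment honours marker structure and partitions the image", {
  img <- two_disk_image()
  p <- preprocess_params(fg_radius = 2L)
  grad <- gradient_magnitude(img)
  fg <- foreground_markers(img, p)
  bg <- background_markers(img, p, fg = fg)
  seg <- watershed_segment(grad, fg, bg)
  expect_s3_class(seg, "segmentation_result")
  expect_partition(seg)
  expect_true(all(seg$region_sizes > 0))
  # each fg marker component lies wholly inside one region
  comps <- aclnet:::cpp_label4(fg)
  for (k in seq_len(max(comps))) {
    expect_length(unique(seg$labels[comps == k]), 1L)
    expect_gt(unique(seg$labels[comps == k]), 0L)
  }
  # single marker -> one region, no ridge
  one <- matrix(FALSE, 10, 10)
  one[5, 5] <- TRUE
  s1 <- watershed_segment(matrix(runif(100), 10), one)
  expect_identical(s1$K, 1L)
  expect_true(all(s1$labels == 1L))
  expect_error(watershed_segment(matrix(0, 5, 5), matrix(FALSE, 5, 5)),
    "no markers")
})

test_that("adding a constant to the image leaves the MCW stages unchanged", {
  img <- two_disk_image(24L)
  img2 <- img * 0.5 + 0.05  # affine is too strong a claim; test the shift
  shift <- img * 1 + 0.05
  p <- preprocess_params(fg_radius = 2L)
  expect_equal(gradient_magnitude(shift)$magnitude,
    gradient_magnitude(img)$magnitude, tolerance = 1e-12)
  expect_identical(foreground_markers(shift, p) * 1L,
    foreground_markers(img, p) * 1L)
  fg <- foreground_markers(img, p)
  seg1 <- watershed_segment(gradient_magnitude(img), fg,
    background_markers(img, p, fg = fg))
  seg2 <- watershed_segment(gradient_magnitude(shift), fg,
    background_markers(shift, p, fg = fg))
  expect_identical(seg1$labels, seg2$labels)
})

test_that("render_segmentation obeys its mode contracts", {
  img <- two_disk_image()
  p <- preprocess_params(fg_radius = 2L)
  fg <- foreground_markers(img, p)
  seg <- watershed_segment(gradient_magnitude(img), fg,
    background_markers(img, p, fg = fg))
  lr <- render_segmentation(img, seg, "label_rgb")
  expect_identical(dim(lr), c(dim(img), 3L))
  cols <- unique(apply(matrix(lr, ncol = 3L), 1, paste, collapse = ","))
  non_black <- setdiff(cols, "0,0,0")
  expect_length(non_black, seg$K)
  ov <- render_segmentation(img, seg, "overlay")
  ridge <- seg$labels == 0L
  for (ch in 1:3) {
    expect_equal(ov[, , ch][!ridge], img[!ridge])
  }
  expect_true(all(ov[, , 2][ridge] == 1))
  mk <- render_segmentation(img, seg, "masked")
  expect_true(all(mk[, , 1][ridge] == 0))
  expect_identical(render_segmentation(img, seg, "label_rgb"), lr)
  expect_error(render_segmentation(img, seg, "fancy"), "unknown rendering mode")
})

test_that("resize_image is exact on identity and constants, bilinear otherwise", {
  img <- matrix(0.37, 30, 20)
  r <- resize_image(img, 10L, 12L)
  expect_identical(dim(r), c(10L, 12L))
  expect_equal(unique(as.vector(r)), 0.37)
  big <- array(runif(200 * 200 * 3), c(200L, 200L, 3L))
  expect_identical(dim(resize_image(big, 100L, 100L)), c(100L, 100L, 3L))
  same <- array(runif(100 * 100 * 3), c(100L, 100L, 3L))
  expect_identical(resize_image(same, 100L, 100L), same)
  s <- image_sample(array(runif(1200), c(20L, 20L, 3L)), "a", "x")
  rs <- resize_image(s, 10L, 10L)
  expect_s3_class(rs, "image_sample")
  expect_identical(rs$label, "a")
})

test_that("mcw_preprocess yields 100x100x3 deterministically and names failing stages", {
  set.seed(6)
  p <- default_class_profiles()$pneumonia
  set.seed(8)
  img <- generate_image(p, 64L, 64L)
  out <- mcw_preprocess(img)
  expect_identical(dim(out$pixels), c(100L, 100L, 3L))
  expect_true(min(out$pixels) >= 0 && max(out$pixels) <= 1)
  expect_identical(out$label, img$label)
  expect_identical(out$id, img$id)
  out2 <- mcw_preprocess(img)
  expect_identical(out$pixels, out2$pixels)
})

test_that("label_rgb distinct-colour count matches the segmentation region count", {
  img <- two_disk_image(32L)
  s <- image_sample(img, "a", "x")
  p <- preprocess_params(fg_radius = 2L, target_height = 32L,
    target_width = 32L)
  fg <- foreground_markers(img, p)
  seg <- watershed_segment(gradient_magnitude(img, p$operator), fg,
    background_markers(img, p, fg = fg))
  rend <- render_segmentation(img, seg, "label_rgb")
  cols <- unique(apply(matrix(rend, ncol = 3L), 1, paste, collapse = ","))
  expect_length(setdiff(cols, "0,0,0"), seg$K)
})

test_that("preprocess_params validates ranges", {
  expect_error(preprocess_params(mode = "psychedelic"), "unknown rendering mode")
  expect_error(preprocess_params(fg_radius = 0L), "fg_radius")
  expect_error(preprocess_params(h_max = 1.5), "h_max")
  expect_error(preprocess_params(target_height = 4L), "8x8")
})
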