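# Seeded synthetic radiograph generator.
#
# Each image is a dark background with two bright ellipse "lung fields";
# class-dependent blob patterns (count, size, brightness, placement) stand
# in for the diffuse and focal opacities that distinguish healthy,
# COVID-like and pneumonia-like radiographs, and Gaussian pixel noise is
# added on top. Blob geometry is recorded in a per-sample generation log
# so tests can audit the generator.

#' Default class profiles for the synthetic generator
#'
#' Three separable profiles: `normal` has at most one faint blob,
#' `covid` has several small bright peripheral blobs, and `pneumonia` has
#' one or two large bright central blobs. Counts, radii and intensities
#' are ranges sampled uniformly per image.
#'
#' @return named list of class profiles.
#' @export
default_class_profiles <- function() {
  list(
    covid = synth_profile("covid", count_range = c(3L, 6L),
      radius_range = c(3, 7), intensity_range = c(0.30, 0.50),
      placement = "peripheral"),
    normal = synth_profile("normal", count_range = c(0L, 1L),
      radius_range = c(3, 6), intensity_range = c(0.06, 0.12),
      placement = "any"),
    pneumonia = synth_profile("pneumonia", count_range = c(1L, 2L),
      radius_range = c(12, 18), intensity_range = c(0.30, 0.50),
      placement = "central")
  )
}

#' Construct a synthetic class profile
#'
#' @param name class name.
#' @param count_range integer range of blob counts per image.
#' @param radius_range blob radius range in pixels.
#' @param intensity_range additive blob brightness range (image units).
#' @param placement `"any"`, `"peripheral"` (near the lung-field border)
#'   or `"central"` (near the lung-field centre).
#' @return a `synth_profile` list.
#' @export
synth_profile <- function(name, count_range, radius_range, intensity_range,
                          placement = c("any", "peripheral", "central")) {
  placement <- match.arg(placement)
  stopifnot(length(count_range) == 2L, count_range[1L] <= count_range[2L],
    count_range[1L] >= 0, radius_range[1L] > 0,
    radius_range[1L] <= radius_range[2L],
    intensity_range[1L] > 0, intensity_range[1L] <= intensity_range[2L])
  structure(list(name = name, count_range = as.integer(count_range),
    radius_range = radius_range, intensity_range = intensity_range,
    placement = placement), class = "synth_profile")
}

#' Configuration of the synthetic dataset generator
#'
#' @param n_per_class images generated per class (>= 1).
#' @param height,width image size in pixels (>= 32).
#' @param classes named list of three [synth_profile]s with pairwise
#'   different blob-count ranges.
#' @param background background intensity.
#' @param lung_intensity brightness of the two elliptical lung fields.
#' @param noise_sd standard deviation of additive Gaussian pixel noise.
#' @param seed master seed; each image draws from an independent
#'   substream derived from the seed and the image index.
#' @return a `synth_config` list.
#' @export
synth_config <- function(n_per_class, height = 128L, width = 128L,
                         classes = default_class_profiles(),
                         background = 0.08, lung_intensity = 0.40,
                         noise_sd = 0.02, seed = 1L) {
  if (n_per_class < 1L) stopf("n_per_class must be >= 1")
  if (height < 32L || width < 32L) stopf("image size must be at least 32x32")
  if (noise_sd < 0) stopf("noise_sd must be >= 0")
  if (length(classes) != 3L || is.null(names(classes))) {
    stopf("exactly 3 named class profiles are required")
  }
  cr <- lapply(classes, function(p) p$count_range)
  for (i in 1:2) for (j in (i + 1):3) {
    if (identical(cr[[i]], cr[[j]])) {
      stopf("blob-count ranges of profiles '%s' and '%s' are identical",
        names(classes)[i], names(classes)[j])
    }
  }
  structure(list(n_per_class = as.integer(n_per_class),
    height = as.integer(height), width = as.integer(width),
    classes = classes, background = background,
    lung_intensity = lung_intensity, noise_sd = noise_sd,
    seed = as.integer(seed)), class = "synth_config")
}

# Two elliptical lung fields on a dark background. Returns list(base,
# in_lung) where in_lung marks pixels inside either ellipse.
lung_field_base <- function(height, width, background, lung_intensity) {
  r <- matrix(seq_len(height), height, width)
  c <- matrix(seq_len(width), height, width, byrow = TRUE)
  ell <- function(cy, cx, ay, ax) {
    ((r - cy) / ay)^2 + ((c - cx) / ax)^2 <= 1
  }
  left <- ell(0.52 * height, 0.30 * width, 0.34 * height, 0.16 * width)
  right <- ell(0.52 * height, 0.70 * width, 0.34 * height, 0.16 * width)
  in_lung <- left | right
  base <- matrix(background, height, width)
  base[in_lung] <- lung_intensity
  list(base = base, in_lung = in_lung,
    centers = rbind(c(0.52 * height, 0.30 * width),
                    c(0.52 * height, 0.70 * width)),
    axes = rbind(c(0.34 * height, 0.16 * width),
                 c(0.34 * height, 0.16 * width)))
}

# Sample a blob centre inside one of the two lung ellipses according to
# the placement rule. Peripheral blobs sit at 55-90% of the ellipse
# radius, central ones within 45%.
sample_blob_center <- function(lf, placement) {
  k <- sample.int(2L, 1L)
  ctr <- lf$centers[k, ]
  ax <- lf$axes[k, ]
  rho <- switch(placement,
    any = sqrt(runif(1L, 0, 0.81)),
    peripheral = runif(1L, 0.55, 0.90),
    central = sqrt(runif(1L, 0, 0.45^2))
  )
  th <- runif(1L, 0, 2 * pi)
  c(ctr[1L] + rho * ax[1L] * sin(th) * 0.92,
    ctr[2L] + rho * ax[2L] * cos(th) * 0.92)
}

#' Generate one synthetic radiograph-like image
#'
#' Draws from the current R random stream: seeding the stream identically
#' reproduces the image bit for bit. Blob centres are rejection-sampled so
#' blobs do not overlap (falls back to the last candidate after 200
#' tries); each blob is an additive compact-support bump
#' `a * (1 - (d/r)^2)` clipped at radius `r`. The returned sample carries
#' a `gen_log` attribute with the drawn blob centres, radii and
#' amplitudes.
#'
#' @param profile a [synth_profile].
#' @param height,width image size.
#' @param background,lung_intensity,noise_sd scene parameters, see
#'   [synth_config()].
#' @param label,id label and id of the produced sample.
#' @return an [image_sample] (single channel) with a `gen_log` attribute.
#' @export
generate_image <- function(profile, height = 128L, width = 128L,
                           background = 0.08, lung_intensity = 0.40,
                           noise_sd = 0.02, label = profile$name,
                           id = profile$name) {
  lf <- lung_field_base(height, width, background, lung_intensity)
  img <- lf$base
  n_blob <- if (profile$count_range[1L] == profile$count_range[2L]) {
    profile$count_range[1L]
  } else {
    sample(seq(profile$count_range[1L], profile$count_range[2L]), 1L)
  }
  centers <- matrix(numeric(0), 0L, 2L)
  radii <- numeric(0)
  amps <- numeric(0)
  rmat <- matrix(seq_len(height), height, width)
  cmat <- matrix(seq_len(width), height, width, byrow = TRUE)
  if (n_blob > 0L) {
    for (b in seq_len(n_blob)) {
      rad <- runif(1L, profile$radius_range[1L], profile$radius_range[2L])
      amp <- runif(1L, profile$intensity_range[1L], profile$intensity_range[2L])
      ok <- FALSE
      for (try in seq_len(200L)) {
        ctr <- sample_blob_center(lf, profile$placement)
        if (nrow(centers) == 0L ||
            all(sqrt((centers[, 1L] - ctr[1L])^2 +
                     (centers[, 2L] - ctr[2L])^2) > radii + rad + 2)) {
          ok <- TRUE
          break
        }
      }
      centers <- rbind(centers, ctr)
      radii <- c(radii, rad)
      amps <- c(amps, amp)
      d2 <- (rmat - ctr[1L])^2 + (cmat - ctr[2L])^2
      bump <- amp * pmax(0, 1 - d2 / rad^2)
      img <- img + bump
    }
  }
  if (noise_sd > 0) {
    img <- img + matrix(rnorm(height * width, sd = noise_sd), height, width)
  }
  s <- image_sample(clip01(img), label = label, id = id)
  attr(s, "gen_log") <- list(n_blobs = n_blob, centers = centers,
    radii = radii, amplitudes = amps)
  s
}

#' Generate a class-balanced synthetic dataset
#'
#' Produces exactly `n_per_class` images for each of the three class
#' profiles. Every image draws from its own substream derived from the
#' master seed and the image's global index, so regenerating any subset is
#' reproducible independently of order.
#'
#' @param config a [synth_config].
#' @return a [labeled_dataset] with `3 * n_per_class` samples.
#' @export
generate_dataset <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  samples <- list()
  idx <- 0L
  for (cl in names(config$classes)) {
    profile <- config$classes[[cl]]
    for (i in seq_len(config$n_per_class)) {
      idx <- idx + 1L
      old <- if (exists(".Random.seed", globalenv())) {
        get(".Random.seed", globalenv())
      }
      set.seed(derive_seed(config$seed, idx))
      s <- generate_image(profile,
        height = config$height, width = config$width,
        background = config$background,
        lung_intensity = config$lung_intensity,
        noise_sd = config$noise_sd,
        label = cl, id = sprintf("%s/%s_%04d", cl, cl, i))
      if (!is.null(old)) assign(".Random.seed", old, globalenv())
      samples[[idx]] <- s
    }
  }
  labeled_dataset(samples, sort(names(config$classes)))
}
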