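# Dataset containers and disk I/O.
#
# A dataset on disk is one directory per class, holding PNG or JPEG
# images: root/<class_name>/<image>.{png,jpg,jpeg}. In memory an image is
# an `image_sample` ([H, W, C] array in [0, 1]) and a dataset is a
# `labeled_dataset` (ordered list of samples plus the sorted class names).

#' Construct an image sample
#'
#' @param pixels numeric array `[height, width, channels]` (a plain matrix
#'   is promoted to one channel) with finite values in `[0, 1]`.
#' @param label class name.
#' @param id unique sample identifier.
#' @param source_path optional path the image was read from.
#' @return an object of class `image_sample`.
#' @export
image_sample <- function(pixels, label, id, source_path = NULL) {
  if (is.matrix(pixels)) dim(pixels) <- c(dim(pixels), 1L)
  d <- dim(pixels)
  if (length(d) != 3L || !(d[3L] %in% c(1L, 3L))) {
    stopf("unsupported image format: expected 1 or 3 channels, got %s",
      paste(d, collapse = "x"))
  }
  if (d[1L] < 3L || d[2L] < 3L) stopf("image too small: %dx%d", d[1L], d[2L])
  if (!all(is.finite(pixels))) stopf("non-finite pixel values in sample '%s'", id)
  if (min(pixels) < 0 || max(pixels) > 1) {
    stopf("pixel values outside [0, 1] in sample '%s'", id)
  }
  if (!is.character(id) || nchar(id) == 0L) stopf("sample id must be nonempty")
  structure(
    list(pixels = pixels, label = as.character(label), id = id,
         source_path = source_path),
    class = "image_sample"
  )
}

#' @export
print.image_sample <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("<image_sample '%s'> %dx%dx%d, label '%s'\n",
    x$id, d[1L], d[2L], d[3L], x$label))
  invisible(x)
}

#' Construct a labeled dataset
#'
#' @param samples list of [image_sample] objects.
#' @param class_names ordered character vector of class names; defaults to
#'   the sorted unique sample labels.
#' @return an object of class `labeled_dataset`.
#' @export
labeled_dataset <- function(samples, class_names = NULL) {
  labels <- vapply(samples, function(s) s$label, character(1L))
  ids <- vapply(samples, function(s) s$id, character(1L))
  if (is.null(class_names)) class_names <- sort(unique(labels))
  if (length(class_names) == 0L) stopf("empty dataset: no classes")
  if (anyDuplicated(class_names)) stopf("duplicate class names")
  if (anyDuplicated(ids)) {
    stopf("duplicate sample ids: %s",
      paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  bad <- setdiff(unique(labels), class_names)
  if (length(bad)) stopf("sample labels outside class_names: %s",
    paste(bad, collapse = ", "))
  structure(list(samples = samples, class_names = as.character(class_names)),
    class = "labeled_dataset")
}

#' @export
print.labeled_dataset <- function(x, ...) {
  tab <- table(factor(dataset_labels(x), levels = x$class_names))
  cat(sprintf("<labeled_dataset> %d samples, %d classes\n",
    length(x$samples), length(x$class_names)))
  for (cl in x$class_names) cat(sprintf("  %s: %d\n", cl, tab[[cl]]))
  invisible(x)
}

#' @export
length.labeled_dataset <- function(x) length(x$samples)

#' Labels of all samples in a dataset
#' @param dataset a [labeled_dataset].
#' @return character vector of per-sample labels.
#' @export
dataset_labels <- function(dataset) {
  vapply(dataset$samples, function(s) s$label, character(1L))
}

#' Ids of all samples in a dataset
#' @param dataset a [labeled_dataset].
#' @return character vector of per-sample ids.
#' @export
dataset_ids <- function(dataset) {
  vapply(dataset$samples, function(s) s$id, character(1L))
}

subset_dataset <- function(dataset, idx) {
  labeled_dataset(dataset$samples[idx], dataset$class_names)
}

#' Load an image dataset from a class-per-subfolder directory
#'
#' Reads every PNG/JPEG under `root/<class>/`, scales intensities to
#' `[0, 1]` (8-bit images are divided by 255), and labels each sample with
#' its subdirectory name. Class names are sorted lexicographically (C
#' locale) so the label-to-index mapping is platform independent.
#'
#' @param root dataset directory.
#' @return a [labeled_dataset].
#' @export
load_dataset <- function(root) {
  if (!dir.exists(root)) stopf("empty dataset: directory '%s' does not exist", root)
  old <- Sys.getlocale("LC_COLLATE")
  on.exit(Sys.setlocale("LC_COLLATE", old), add = TRUE)
  Sys.setlocale("LC_COLLATE", "C")
  classes <- sort(list.dirs(root, full.names = FALSE, recursive = FALSE))
  if (length(classes) == 0L) stopf("empty dataset: no class subfolders in '%s'", root)
  samples <- list()
  for (cl in classes) {
    files <- sort(list.files(file.path(root, cl),
      pattern = "\\.(png|jpg|jpeg)$", ignore.case = TRUE, full.names = TRUE))
    if (length(files) == 0L) stopf("empty dataset: class folder '%s' has no images", cl)
    for (f in files) {
      px <- tryCatch(from_ebimage(EBImage::readImage(f)),
        error = function(e) stopf("cannot decode image file '%s': %s", f,
          conditionMessage(e)))
      if (length(dim(px)) == 3L && dim(px)[3L] > 3L) {
        px <- px[, , 1:3, drop = FALSE]  # drop alpha
      }
      id <- paste0(cl, "/", tools::file_path_sans_ext(basename(f)))
      samples[[length(samples) + 1L]] <-
        image_sample(clip01(px), label = cl, id = id, source_path = f)
    }
  }
  labeled_dataset(samples, classes)
}

#' Replicate a grayscale image to three channels
#'
#' A one-channel sample gets its channel copied to all three output
#' channels; a three-channel sample passes through unchanged.
#'
#' @param image an [image_sample].
#' @return an [image_sample] with three channels.
#' @export
to_rgb <- function(image) {
  d <- dim(image$pixels)
  if (d[3L] == 3L) return(image)
  if (d[3L] != 1L) stopf("unsupported image format: %d channels", d[3L])
  px <- array(image$pixels[, , 1L], dim = c(d[1L], d[2L], 3L))
  image_sample(px, image$label, image$id, image$source_path)
}

#' Save a dataset in class-per-subfolder PNG layout
#'
#' Writes one 8-bit PNG per sample under `root/<class>/` and a run
#' manifest. Re-loading reproduces labels and ids and pixels up to 8-bit
#' quantization (absolute error at most 1/255).
#'
#' @param dataset a [labeled_dataset] with at least one sample.
#' @param root output directory (created if missing).
#' @param config optional list echoed into the manifest.
#' @param seed optional seed echoed into the manifest.
#' @return the written [run_manifest], invisibly.
#' @export
save_dataset <- function(dataset, root, config = list(), seed = NULL) {
  if (length(dataset$samples) == 0L) stopf("refusing to save an empty dataset")
  ok <- dir.create(root, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(root)) stopf("cannot create output directory '%s'", root)
  paths <- character(0)
  for (s in dataset$samples) {
    cdir <- file.path(root, s$label)
    dir.create(cdir, showWarnings = FALSE)
    fname <- paste0(gsub("[^A-Za-z0-9._-]", "_", basename(s$id)), ".png")
    path <- file.path(cdir, fname)
    px <- s$pixels
    img <- if (dim(px)[3L] == 1L) as_ebimage(px[, , 1L]) else as_ebimage(px)
    tryCatch(EBImage::writeImage(img, path, bits.per.sample = 8L),
      error = function(e) stopf("cannot write '%s': %s", path,
        conditionMessage(e)))
    paths <- c(paths, path)
  }
  manifest <- run_manifest(
    config = config, seed = seed,
    inputs = list(), outputs = list(root = root),
    artifacts = as.list(tools::md5sum(paths))
  )
  write_manifest(manifest, file.path(root, "manifest.yaml"))
  invisible(manifest)
}

#' Construct a run manifest
#'
#' A manifest records the effective configuration, seed, input/output
#' paths, artifact checksums and a timestamp for one pipeline run; it
#' serializes to YAML and round-trips losslessly.
#'
#' @param config list of configuration values.
#' @param seed integer seed or `NULL`.
#' @param inputs,outputs named lists of paths.
#' @param artifacts named list of checksums.
#' @return an object of class `run_manifest`.
#' @export
run_manifest <- function(config = list(), seed = NULL, inputs = list(),
                         outputs = list(), artifacts = list()) {
  structure(
    list(
      config = config,
      seed = if (is.null(seed)) NULL else as.integer(seed),
      inputs = inputs, outputs = outputs, artifacts = artifacts,
      timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
    ),
    class = "run_manifest"
  )
}

#' Write a run manifest to a YAML file
#' @param manifest a [run_manifest].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(manifest, path) {
  yaml::write_yaml(unclass(manifest), path)
  invisible(path)
}

#' Read a run manifest from a YAML file
#' @param path manifest file written by [write_manifest()].
#' @return a [run_manifest].
#' @export
read_manifest <- function(path) {
  x <- yaml::read_yaml(path)
  structure(x, class = "run_manifest")
}
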