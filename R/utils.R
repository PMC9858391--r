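# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

#' Derive a child seed from a master seed
#'
#' Deterministic integer hash used to give independent, reproducible
#' random substreams to per-image generation, per-epoch shuffling and
#' similar consumers. Stays inside the 32-bit signed integer range.
#'
#' @param seed master seed (integer).
#' @param index substream index (integer >= 0).
#' @return an integer seed.
#' @keywords internal
derive_seed <- function(seed, index) {
  as.integer((as.numeric(seed) * 48271 + as.numeric(index) * 7919 + 11) %%
    2147483647)
}

sigmoid <- function(x) 1 / (1 + exp(-x))

# Convert an internal [H, W] or [H, W, C] array to an EBImage Image and
# back. EBImage stores the x (width) axis first.
as_ebimage <- function(px) {
  if (length(dim(px)) == 2L) {
    EBImage::Image(t(px))
  } else {
    EBImage::Image(aperm(px, c(2L, 1L, 3L)),
      colormode = if (dim(px)[3L] >= 3L) "Color" else "Grayscale"
    )
  }
}

from_ebimage <- function(img) {
  d <- EBImage::imageData(img)
  if (length(dim(d)) == 2L) t(d) else aperm(d, c(2L, 1L, 3L))
}

clip01 <- function(x) {
  x[x < 0] <- 0
  x[x > 1] <- 1
  x
}
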