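# Layer semantics: softmax, the LSTM cell and the attention gate.
#
# These are the single-sample reference operations; the batched network
# engine in acl_model.R reuses the same arithmetic.

#' Shift-stabilized softmax
#'
#' `S_k = exp(x_k) / sum_i exp(x_i)`, computed after subtracting the
#' maximum so large scores do not overflow. Components are positive and
#' sum to one.
#'
#' @param scores numeric vector of finite class scores.
#' @return probability vector of the same length.
#' @export
softmax <- function(scores) {
  if (!all(is.finite(scores))) stopf("softmax requires finite scores")
  e <- exp(scores - max(scores))
  e / sum(e)
}

# Row-wise softmax for a score matrix (N x K).
softmax_rows <- function(m) {
  e <- exp(m - apply(m, 1L, max))
  e / rowSums(e)
}

#' LSTM cell weights
#'
#' Gate weight blocks act on the concatenation `[x_t, h_{t-1}, C_{t-1}]`
#' (the previous cell state enters every gate), so each block is
#' `hidden x (input + 2 * hidden)`.
#'
#' @param W_f,W_i,W_c,W_o gate weight blocks.
#' @param b_f,b_i,b_c,b_o gate biases, length `hidden`.
#' @return a `lstm_weights` list with `hidden` and `input_size` recorded.
#' @export
lstm_weights <- function(W_f, W_i, W_c, W_o, b_f, b_i, b_c, b_o) {
  hidden <- nrow(W_f)
  input_size <- ncol(W_f) - 2L * hidden
  if (input_size < 1L) stopf("weight block narrower than 2*hidden columns")
  for (w in list(W_i, W_c, W_o)) {
    if (!all(dim(w) == dim(W_f))) stopf("LSTM weight blocks differ in shape")
  }
  for (b in list(b_f, b_i, b_c, b_o)) {
    if (length(b) != hidden) stopf("LSTM bias length must equal hidden size")
  }
  structure(list(W_f = W_f, W_i = W_i, W_c = W_c, W_o = W_o,
    b_f = b_f, b_i = b_i, b_c = b_c, b_o = b_o,
    hidden = hidden, input_size = as.integer(input_size)),
    class = "lstm_weights")
}

#' One LSTM cell step
#'
#' Gates are sigmoids of an affine map of `z = [x_t, h_{t-1}, C_{t-1}]`:
#' `f = sigma(W_f z + b_f)`, `i = sigma(W_i z + b_i)`,
#' `o = sigma(W_o z + b_o)`; the cell update is
#' `C_t = f * C_{t-1} + i * tanh(W_c z + b_c)` and the output
#' `h_t = o * tanh(C_t)`.
#'
#' @param x_t input vector.
#' @param state list with `h` and `C`, the previous hidden and cell
#'   vectors (equal length).
#' @param w an [lstm_weights].
#' @return list with the new `h` and `C` and a `gates` attribute holding
#'   `f`, `i`, `o`.
#' @export
lstm_cell_step <- function(x_t, state, w) {
  if (length(x_t) != w$input_size) {
    stopf("input length %d does not match weight input size %d",
      length(x_t), w$input_size)
  }
  if (length(state$h) != w$hidden || length(state$C) != w$hidden) {
    stopf("state length does not match hidden size %d", w$hidden)
  }
  z <- c(x_t, state$h, state$C)
  f <- sigmoid(drop(w$W_f %*% z) + w$b_f)
  i <- sigmoid(drop(w$W_i %*% z) + w$b_i)
  o <- sigmoid(drop(w$W_o %*% z) + w$b_o)
  cand <- tanh(drop(w$W_c %*% z) + w$b_c)
  C_t <- f * state$C + i * cand
  h_t <- o * tanh(C_t)
  out <- list(h = h_t, C = C_t)
  attr(out, "gates") <- list(f = f, i = i, o = o)
  out
}

#' Attention gate weights
#'
#' All transforms are 1x1 (per-pixel channel mixing): `w_x` maps the
#' feature map's channels and `w_g` the gating signal's channels to an
#' intermediate dimension, and `phi` maps the intermediate vector to one
#' scalar per pixel.
#'
#' @param w_x `Cx x Ci` matrix applied to the feature map.
#' @param w_g `Cg x Ci` matrix applied to the gating signal.
#' @param b_g additive-stage bias, length `Ci`.
#' @param phi scalar-stage weights, length `Ci`.
#' @param b_phi scalar-stage bias.
#' @return an `attention_weights` list.
#' @export
attention_weights <- function(w_x, w_g, b_g, phi, b_phi) {
  ci <- ncol(w_x)
  if (ncol(w_g) != ci) stopf("w_x and w_g intermediate dimensions differ")
  if (length(b_g) != ci || length(phi) != ci) {
    stopf("b_g and phi must have length %d", ci)
  }
  if (length(b_phi) != 1L) stopf("b_phi must be a scalar")
  structure(list(w_x = w_x, w_g = w_g, b_g = b_g, phi = phi, b_phi = b_phi),
    class = "attention_weights")
}

#' Additive attention gate
#'
#' Per pixel `p`: `alpha_p = sigma(phi' (w_x' x_p + w_g' g_p + b_g) +
#' b_phi)` and `out_p = alpha_p * x_p` broadcast over the feature map's
#' channels. The coefficient `alpha` lies strictly in `(0, 1)`.
#'
#' @param x feature map `[H, W, Cx]`.
#' @param g gating map `[H, W, Cg]`, spatially aligned with `x`.
#' @param w an [attention_weights].
#' @return gated feature map `[H, W, Cx]`, with the coefficient map as
#'   attribute `alpha`.
#' @export
attention_gate <- function(x, g, w) {
  dx <- dim(x)
  dg <- dim(g)
  if (length(dx) != 3L || length(dg) != 3L || any(dx[1:2] != dg[1:2])) {
    stopf("x and g must be [H, W, C] arrays with equal spatial size")
  }
  if (dx[3L] != nrow(w$w_x) || dg[3L] != nrow(w$w_g)) {
    stopf("channel counts do not match the attention weights")
  }
  np <- dx[1L] * dx[2L]
  xm <- matrix(x, np, dx[3L])   # pixel-major, channels in columns
  gm <- matrix(g, np, dg[3L])
  a <- xm %*% w$w_x + gm %*% w$w_g
  a <- sweep(a, 2L, w$b_g, "+")
  alpha <- sigmoid(drop(a %*% w$phi) + w$b_phi)
  out <- x * array(alpha, dx)
  attr(out, "alpha") <- matrix(alpha, dx[1L], dx[2L])
  out
}
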