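# The ACL network: a 28-layer attention-CNN-LSTM graph.
#
# The full variant is: sequence input -> fold -> two conv/BN/ReLU/maxpool
# stages -> conv3/ReLU/conv4/maxpool -> attention branch
# (conv5/ReLU/conv6 -> sigmoid) -> element-wise multiplication with the
# pooled trunk -> unfold -> flatten -> LSTM(100) -> FC(100) -> ReLU ->
# 40% dropout -> FC(n_classes) -> softmax -> classification output.
# Ablation variants: case1 removes the attention gate and the LSTM,
# case2 removes the attention gate, case3 removes the LSTM.
#
# Convolutions are 3x3, stride 1, padding 0, except the two attention
# branch convolutions which use "same" padding so the sigmoid gate is
# shape-compatible with the trunk it multiplies. When the branch is
# removed (case1/case2) those convolutions revert to padding 0.
#
# Each image is treated as a length-1 sequence: fold/unfold are identity
# bookkeeping layers and the LSTM executes exactly one step from a zero
# state.

ACL_VARIANTS <- c("full", "case1", "case2", "case3")

layer_desc <- function(.name, .kind, .input = NULL, ...) {
  c(list(name = .name, kind = .kind, input = .input), list(...))
}

#' Build the layer graph of an ACL network variant
#'
#' @param variant `"full"`, `"case1"` (no attention, no LSTM), `"case2"`
#'   (LSTM only) or `"case3"` (attention only).
#' @param input_dim input size `c(height, width, channels)`.
#' @param n_classes number of output classes.
#' @param attention_mode `"table"` (default) multiplies the sigmoid of
#'   the conv5/ReLU/conv6 branch with the pooled trunk; `"eq10"` replaces
#'   the branch with an additive attention gate whose gating signal is
#'   the conv4 output.
#' @param hidden LSTM hidden size.
#' @return an object of class `acl_spec` with the ordered layer list and
#'   the inferred shape at every layer.
#' @export
acl_spec <- function(variant = "full", input_dim = c(100L, 100L, 3L),
                     n_classes = 3L, attention_mode = c("table", "eq10"),
                     hidden = 100L) {
  if (!variant %in% ACL_VARIANTS) {
    stopf("unknown variant '%s' (expected one of %s)", variant,
      paste(ACL_VARIANTS, collapse = ", "))
  }
  attention_mode <- match.arg(attention_mode)
  has_attention <- variant %in% c("full", "case3")
  has_lstm <- variant %in% c("full", "case2")
  branch_pad <- if (has_attention && attention_mode == "table") 1L else 0L

  L <- list(
    layer_desc("input", "input", NULL,
      info = sprintf("Sequence input with %d x %d x %d dimensions",
        input_dim[1L], input_dim[2L], input_dim[3L])),
    layer_desc("fold", "fold", "input", info = "Sequence folding"),
    layer_desc("convInp2d_1", "conv", "fold", filters = 16L, k = 3L, pad = 0L),
    layer_desc("batchnorm_1", "bn", "convInp2d_1", info = "BN with 16 channels"),
    layer_desc("relu1", "relu", "batchnorm_1"),
    layer_desc("maxpool2d_1", "maxpool", "relu1", k = 3L, stride = 1L),
    layer_desc("convInp2d_2", "conv", "maxpool2d_1", filters = 16L, k = 3L, pad = 0L),
    layer_desc("batchnorm_2", "bn", "convInp2d_2", info = "BN with 16 channels"),
    layer_desc("relu2", "relu", "batchnorm_2"),
    layer_desc("maxpool2d2", "maxpool", "relu2", k = 3L, stride = 1L),
    layer_desc("convInp2d_3", "conv", "maxpool2d2", filters = 16L, k = 3L, pad = 0L),
    layer_desc("relu_2_1_1_5", "relu", "convInp2d_3"),
    layer_desc("convInp2d_4", "conv", "relu_2_1_1_5", filters = 16L, k = 3L, pad = 0L),
    layer_desc("maxpool2d_2", "maxpool", "convInp2d_4", k = 3L, stride = 1L)
  )
  if (has_attention && attention_mode == "eq10") {
    L <- c(L, list(
      layer_desc("attgate_1", "attgate",
        c("maxpool2d_2", "convInp2d_4"), inter = 16L,
        info = "Additive attention gate (gating signal from convInp2d_4)")
    ))
    head_in <- "attgate_1"
  } else {
    L <- c(L, list(
      layer_desc("convInp2d_5", "conv", "maxpool2d_2", filters = 16L,
        k = 3L, pad = branch_pad),
      layer_desc("relu_2_1_1_6", "relu", "convInp2d_5"),
      layer_desc("convInp2d_6", "conv", "relu_2_1_1_6", filters = 16L,
        k = 3L, pad = branch_pad)
    ))
    if (has_attention) {
      L <- c(L, list(
        layer_desc("sigmoid_1_1_1_3", "sigmoid", "convInp2d_6"),
        layer_desc("mul_1_1_1_3", "mul",
          c("sigmoid_1_1_1_3", "maxpool2d_2"),
          info = "Element Wise Multiplication of 2 inputs")
      ))
      head_in <- "mul_1_1_1_3"
    } else {
      head_in <- "convInp2d_6"
    }
  }
  L <- c(L, list(
    layer_desc("unfold", "unfold", head_in, info = "Sequence unfolding"),
    layer_desc("flatten", "flatten", "unfold")
  ))
  fc_in <- "flatten"
  if (has_lstm) {
    L <- c(L, list(layer_desc("lstm", "lstm", "flatten",
      hidden = as.integer(hidden),
      info = sprintf("LSTM with %d hidden units", hidden))))
    fc_in <- "lstm"
  }
  L <- c(L, list(
    layer_desc("fc0", "fc", fc_in, units = 100L, info = "100 FC layer"),
    layer_desc("ReLu2", "relu", "fc0"),
    layer_desc("drop1", "dropout", "ReLu2", rate = 0.4, info = "40% dropout"),
    layer_desc("fc1", "fc", "drop1", units = as.integer(n_classes),
      info = sprintf("%d FC layer", n_classes)),
    layer_desc("softmax", "softmax", "fc1"),
    layer_desc("class_output", "output", "softmax", info = "crossentropyex")
  ))
  spec <- structure(list(layers = L, variant = variant,
    input_dim = as.integer(input_dim), n_classes = as.integer(n_classes),
    attention_mode = attention_mode, hidden = as.integer(hidden)),
    class = "acl_spec")
  spec$shapes <- infer_shapes(spec)
  spec
}

# Propagate tensor shapes through the graph; errors on any inconsistency
# (in particular on a shape-mismatched element-wise multiplication).
infer_shapes <- function(spec) {
  shapes <- list()
  for (ly in spec$layers) {
    s <- switch(ly$kind,
      input = spec$input_dim,
      fold = ,
      unfold = ,
      relu = ,
      sigmoid = ,
      dropout = ,
      softmax = ,
      output = ,
      bn = shapes[[ly$input[1L]]],
      conv = {
        si <- shapes[[ly$input]]
        ho <- si[1L] + 2L * ly$pad - ly$k + 1L
        wo <- si[2L] + 2L * ly$pad - ly$k + 1L
        if (ho < 1L || wo < 1L) {
          stopf("layer '%s': convolution output would be empty", ly$name)
        }
        c(ho, wo, ly$filters)
      },
      maxpool = {
        si <- shapes[[ly$input]]
        c((si[1L] - ly$k) %/% ly$stride + 1L,
          (si[2L] - ly$k) %/% ly$stride + 1L, si[3L])
      },
      mul = {
        a <- shapes[[ly$input[1L]]]
        b <- shapes[[ly$input[2L]]]
        if (!identical(a, b)) {
          stopf("layer '%s': element-wise multiplication inputs differ in shape (%s vs %s)",
            ly$name, paste(a, collapse = "x"), paste(b, collapse = "x"))
        }
        a
      },
      attgate = {
        a <- shapes[[ly$input[1L]]]
        g <- shapes[[ly$input[2L]]]
        if (any(g[1:2] < a[1:2])) {
          stopf("layer '%s': gating map smaller than feature map", ly$name)
        }
        a
      },
      flatten = prod(shapes[[ly$input]]),
      lstm = ly$hidden,
      fc = ly$units,
      stopf("unknown layer kind '%s'", ly$kind)
    )
    shapes[[ly$name]] <- as.integer(s)
  }
  shapes
}

glorot <- function(dims, fan_in, fan_out) {
  lim <- sqrt(6 / (fan_in + fan_out))
  array(runif(prod(dims), -lim, lim), dims)
}

# Draw all learnable parameters for a spec. The RNG stream is seeded
# once, and layers are visited in graph order, so initialization is a
# deterministic function of (spec, seed).
init_acl_params <- function(spec, seed) {
  set.seed(as.integer(seed))
  params <- list()
  for (ly in spec$layers) {
    p <- switch(ly$kind,
      conv = {
        cin <- spec$shapes[[ly$input]][3L]
        list(
          W = glorot(c(ly$k, ly$k, cin, ly$filters),
            ly$k * ly$k * cin, ly$k * ly$k * ly$filters),
          b = numeric(ly$filters)
        )
      },
      bn = {
        ch <- spec$shapes[[ly$input]][3L]
        list(gamma = rep(1, ch), beta = numeric(ch),
          run_mean = numeric(ch), run_var = rep(1, ch))
      },
      lstm = {
        dx <- spec$shapes[[ly$input]]
        h <- ly$hidden
        zw <- dx + 2L * h
        # unit-variance gate pre-activations for inputs with RMS ~0.3
        # (image-intensity scale), so the gates start responsive instead
        # of near-linear: sd(W z) = lim/sqrt(3) * 0.3 * sqrt(zw) = 1
        lim <- sqrt(3) / (0.3 * sqrt(zw))
        blocks <- lapply(1:4, function(i) {
          matrix(runif(h * zw, -lim, lim), h, zw)
        })
        # forget-gate bias 1 keeps the memory path open at the start
        list(W_f = blocks[[1L]], W_i = blocks[[2L]], W_c = blocks[[3L]],
          W_o = blocks[[4L]], b_f = rep(1, h), b_i = numeric(h),
          b_c = numeric(h), b_o = numeric(h))
      },
      fc = {
        nin <- spec$shapes[[ly$input]]
        list(W = glorot(c(ly$units, nin), nin, ly$units),
          b = numeric(ly$units))
      },
      attgate = {
        cx <- spec$shapes[[ly$input[1L]]][3L]
        cg <- spec$shapes[[ly$input[2L]]][3L]
        ci <- ly$inter
        list(
          w_x = glorot(c(cx, ci), cx, ci),
          w_g = glorot(c(cg, ci), cg, ci),
          b_g = numeric(ci),
          phi = drop(glorot(c(ci, 1L), ci, 1L)),
          b_phi = 0
        )
      },
      NULL
    )
    if (!is.null(p)) params[[ly$name]] <- p
  }
  params
}

#' Build an ACL network model
#'
#' Constructs the layer graph for the requested variant and initializes
#' its parameters from the seed (Glorot-uniform convolution/FC weights,
#' uniform `1/sqrt(fan_in)` LSTM blocks with a unit forget-gate bias).
#'
#' @inheritParams acl_spec
#' @param seed initialization seed.
#' @return an object of class `acl_model`: list with `spec`, `params`
#'   and `seed`.
#' @export
build_acl <- function(variant = "full", input_dim = c(100L, 100L, 3L),
                      n_classes = 3L, seed = 1L,
                      attention_mode = c("table", "eq10"), hidden = 100L) {
  spec <- acl_spec(variant, input_dim, n_classes, attention_mode, hidden)
  structure(list(spec = spec, params = init_acl_params(spec, seed),
    seed = as.integer(seed)), class = "acl_model")
}

#' Number of learnable parameters of a model
#' @param model an [build_acl()] model.
#' @param by_layer return a named per-layer vector instead of the total.
#' @return integer count (BN running statistics are not counted).
#' @export
n_params <- function(model, by_layer = FALSE) {
  per <- vapply(names(model$params), function(nm) {
    p <- model$params[[nm]]
    p$run_mean <- NULL
    p$run_var <- NULL
    sum(vapply(p, length, integer(1L)))
  }, integer(1L))
  if (by_layer) per else sum(per)
}

layer_info <- function(ly, shape) {
  if (!is.null(ly$info)) return(ly$info)
  switch(ly$kind,
    conv = sprintf("16 3 x 3 convolutions with stride: 1 and padding: %s",
      if (ly$pad > 0L) "same" else "0"),
    maxpool = sprintf("%d x %d max pooling with stride: %d and padding: 0",
      ly$k, ly$k, ly$stride),
    relu = "ReLU",
    sigmoid = "sigmoidLayer",
    flatten = "Flatten",
    softmax = "softmax",
    ly$kind
  )
}

#' @export
print.acl_spec <- function(x, ...) {
  cat(sprintf("<acl_spec> variant '%s' (%s attention), %d layers, input %s, %d classes\n",
    x$variant, x$attention_mode, length(x$layers),
    paste(x$input_dim, collapse = "x"), x$n_classes))
  invisible(x)
}

#' Print the layer table of a network
#'
#' One row per layer: index, name, kind, description and output shape.
#'
#' @param spec an [acl_spec] or [build_acl()] model.
#' @return the table as a data.frame, invisibly.
#' @export
describe_acl <- function(spec) {
  if (inherits(spec, "acl_model")) spec <- spec$spec
  df <- data.frame(
    layer = seq_along(spec$layers),
    name = vapply(spec$layers, `[[`, character(1L), "name"),
    kind = vapply(spec$layers, `[[`, character(1L), "kind"),
    info = vapply(spec$layers, function(ly) {
      layer_info(ly, spec$shapes[[ly$name]])
    }, character(1L)),
    output = vapply(spec$layers, function(ly) {
      paste(spec$shapes[[ly$name]], collapse = " x ")
    }, character(1L)),
    stringsAsFactors = FALSE
  )
  fmt <- sprintf("%%3d  %%-16s %%-8s %%-58s %%s\n")
  for (i in seq_len(nrow(df))) {
    cat(sprintf(fmt, df$layer[i], df$name[i], df$kind[i], df$info[i],
      df$output[i]))
  }
  invisible(df)
}

#' @export
print.acl_model <- function(x, ...) {
  cat(sprintf("<acl_model> variant '%s', %d layers, %s parameters, seed %d\n",
    x$spec$variant, length(x$spec$layers),
    format(n_params(x), big.mark = ","), x$seed))
  invisible(x)
}

# Convert a dataset / sample list / array into the (H, W, C, N) batch
# array the network consumes. Grayscale samples are replicated to three
# channels at model input.
batch_array <- function(x, input_dim) {
  if (inherits(x, "labeled_dataset")) x <- x$samples
  if (is.list(x)) {
    arrs <- lapply(x, function(s) to_rgb(s)$pixels)
    for (a in arrs) {
      if (!identical(as.integer(dim(a)), as.integer(input_dim))) {
        stopf("input images are %s but the network expects %s",
          paste(dim(a), collapse = "x"), paste(input_dim, collapse = "x"))
      }
    }
    x <- array(unlist(arrs), c(input_dim, length(arrs)))
  }
  if (length(dim(x)) == 3L) dim(x) <- c(dim(x), 1L)
  if (!identical(as.integer(dim(x)[1:3]), as.integer(input_dim))) {
    stopf("input images are %s but the network expects %s",
      paste(dim(x)[1:3], collapse = "x"), paste(input_dim, collapse = "x"))
  }
  x
}

crop_center <- function(x, th, tw) {
  d <- dim(x)
  r0 <- (d[1L] - th) %/% 2L
  c0 <- (d[2L] - tw) %/% 2L
  x[r0 + seq_len(th), c0 + seq_len(tw), , , drop = FALSE]
}

# ---------------------------------------------------------------------------
# Forward pass.
#
# Returns list(probs, outs, extras): `outs` holds every layer output
# (kept only when keep_cache = TRUE), `extras` holds what backward needs
# (pool argmaxes, BN batch statistics, dropout masks, LSTM internals).
acl_forward <- function(model, x, training = FALSE, keep_cache = training,
                        bn_momentum = 0.1) {
  spec <- model$spec
  x <- batch_array(x, spec$input_dim)
  n <- dim(x)[4L]
  outs <- list()
  extras <- list()
  new_run <- list()
  cur <- NULL
  for (ly in spec$layers) {
    p <- model$params[[ly$name]]
    inp <- if (is.null(ly$input)) NULL else outs[[ly$input[1L]]]
    out <- switch(ly$kind,
      input = x,
      fold = ,
      unfold = ,
      output = inp,
      conv = cpp_conv2d_fwd(inp, p$W, p$b, ly$pad),
      bn = {
        d <- dim(inp)
        out <- inp
        eps <- 1e-5
        if (training) {
          mu <- numeric(d[3L])
          va <- numeric(d[3L])
          for (ch in seq_len(d[3L])) {
            sl <- inp[, , ch, , drop = FALSE]
            mu[ch] <- mean(sl)
            va[ch] <- mean((sl - mu[ch])^2)
            out[, , ch, ] <- p$gamma[ch] * (sl - mu[ch]) /
              sqrt(va[ch] + eps) + p$beta[ch]
          }
          extras[[ly$name]] <- list(mu = mu, va = va, eps = eps)
          new_run[[ly$name]] <- list(
            run_mean = (1 - bn_momentum) * p$run_mean + bn_momentum * mu,
            run_var = (1 - bn_momentum) * p$run_var + bn_momentum * va)
        } else {
          for (ch in seq_len(d[3L])) {
            out[, , ch, ] <- p$gamma[ch] * (inp[, , ch, , drop = FALSE] -
              p$run_mean[ch]) / sqrt(p$run_var[ch] + eps) + p$beta[ch]
          }
        }
        out
      },
      relu = pmax(inp, 0),
      sigmoid = sigmoid(inp),
      maxpool = {
        r <- cpp_maxpool_fwd(inp, ly$k, ly$stride)
        extras[[ly$name]] <- list(argmax = r$argmax, in_dim = dim(inp))
        r$Y
      },
      mul = outs[[ly$input[1L]]] * outs[[ly$input[2L]]],
      attgate = {
        xa <- outs[[ly$input[1L]]]
        ga <- crop_center(outs[[ly$input[2L]]], dim(xa)[1L], dim(xa)[2L])
        dxa <- dim(xa)
        np <- prod(dxa[c(1L, 2L, 4L)])
        xm <- matrix(aperm(xa, c(1L, 2L, 4L, 3L)), np, dxa[3L])
        gm <- matrix(aperm(ga, c(1L, 2L, 4L, 3L)), np, dim(ga)[3L])
        s <- sweep(xm %*% p$w_x + gm %*% p$w_g, 2L, p$b_g, "+")
        alpha <- sigmoid(drop(s %*% p$phi) + p$b_phi)
        am <- aperm(array(alpha, dxa[c(1L, 2L, 4L, 3L)]), c(1L, 2L, 4L, 3L))
        extras[[ly$name]] <- list(xm = xm, gm = gm, s = s, alpha = alpha,
          g_dim = dim(outs[[ly$input[2L]]]))
        xa * am
      },
      flatten = {
        d <- dim(inp)
        t(matrix(inp, prod(d[1:3]), d[4L]))
      },
      lstm = {
        h <- ly$hidden
        z <- cbind(inp, matrix(0, n, 2L * h))
        # C_{t-1} = 0 for a length-1 sequence, so the forget gate
        # multiplies zero and is skipped: C_t = i * tanh(W_c z + b_c)
        pi_ <- sigmoid(sweep(tcrossprod(z, p$W_i), 2L, p$b_i, "+"))
        po <- sigmoid(sweep(tcrossprod(z, p$W_o), 2L, p$b_o, "+"))
        cand <- tanh(sweep(tcrossprod(z, p$W_c), 2L, p$b_c, "+"))
        C <- pi_ * cand
        tC <- tanh(C)
        extras[[ly$name]] <- list(z = z, i = pi_, o = po,
          cand = cand, C = C, tC = tC)
        po * tC
      },
      fc = sweep(tcrossprod(inp, p$W), 2L, p$b, "+"),
      dropout = {
        if (training) {
          mask <- matrix((runif(length(inp)) >= ly$rate) / (1 - ly$rate),
            nrow(inp), ncol(inp))
          extras[[ly$name]] <- list(mask = mask)
          inp * mask
        } else {
          inp
        }
      },
      softmax = softmax_rows(inp),
      stopf("unknown layer kind '%s'", ly$kind)
    )
    outs[[ly$name]] <- out
    cur <- out
  }
  res <- list(probs = cur, new_run = new_run)
  if (keep_cache) {
    res$outs <- outs
    res$extras <- extras
  }
  res
}

#' Forward pass: class probabilities for a batch
#'
#' Runs the network in inference mode (dropout off, batch-norm using its
#' running statistics). Each image is a one-step sequence through the
#' fold/unfold/LSTM machinery. Rows of the result are probability
#' vectors; outputs are deterministic for fixed parameters and
#' independent across samples.
#'
#' @param model an [build_acl()] model.
#' @param x a [labeled_dataset], list of [image_sample]s, or an
#'   `[H, W, C, N]` (or single `[H, W, C]`) array matching the model's
#'   input size.
#' @param batch_size samples per forward chunk.
#' @return `N x n_classes` probability matrix (columns named when the
#'   model was trained with class names).
#' @export
predict_proba <- function(model, x, batch_size = 32L) {
  x <- batch_array(x, model$spec$input_dim)
  n <- dim(x)[4L]
  probs <- matrix(0, n, model$spec$n_classes)
  i <- 1L
  while (i <= n) {
    j <- min(i + batch_size - 1L, n)
    probs[i:j, ] <- acl_forward(model, x[, , , i:j, drop = FALSE],
      training = FALSE, keep_cache = FALSE)$probs
    i <- j + 1L
  }
  if (!is.null(model$class_names)) colnames(probs) <- model$class_names
  probs
}

# ---------------------------------------------------------------------------
# Backward pass: gradients of the mean cross-entropy loss with respect to
# every learnable parameter. `cache` is the result of a training-mode
# forward with keep_cache = TRUE; `y_idx` are 1-based true class indices.
acl_backward <- function(model, cache, y_idx) {
  spec <- model$spec
  outs <- cache$outs
  extras <- cache$extras
  n <- length(y_idx)
  probs <- cache$probs
  dlogits <- probs
  dlogits[cbind(seq_len(n), y_idx)] <-
    dlogits[cbind(seq_len(n), y_idx)] - 1
  dlogits <- dlogits / n

  grads_out <- list()
  pgrads <- list()
  gacc <- function(nm, g) {
    grads_out[[nm]] <<- if (is.null(grads_out[[nm]])) g else grads_out[[nm]] + g
  }
  # seed: gradient at the input of the softmax layer (the class scores)
  sm <- Filter(function(ly) ly$kind == "softmax", spec$layers)[[1L]]
  gacc(sm$input, dlogits)

  for (ly in rev(spec$layers)) {
    if (ly$kind %in% c("softmax", "output", "input")) next
    g <- grads_out[[ly$name]]
    if (is.null(g)) next
    p <- model$params[[ly$name]]
    inm <- ly$input[1L]
    switch(ly$kind,
      fold = ,
      unfold = gacc(inm, g),
      relu = gacc(inm, g * (outs[[ly$name]] > 0)),
      sigmoid = {
        o <- outs[[ly$name]]
        gacc(inm, g * o * (1 - o))
      },
      dropout = {
        m <- extras[[ly$name]]$mask
        gacc(inm, if (is.null(m)) g else g * m)
      },
      conv = {
        r <- cpp_conv2d_bwd(outs[[inm]], p$W, g, ly$pad)
        pgrads[[ly$name]] <- list(W = r$dW, b = r$db)
        gacc(inm, r$dX)
      },
      maxpool = {
        e <- extras[[ly$name]]
        gacc(inm, cpp_maxpool_bwd(e$argmax, g, e$in_dim))
      },
      mul = {
        gacc(ly$input[1L], g * outs[[ly$input[2L]]])
        gacc(ly$input[2L], g * outs[[ly$input[1L]]])
      },
      bn = {
        e <- extras[[ly$name]]
        xin <- outs[[inm]]
        d <- dim(xin)
        m <- prod(d[c(1L, 2L, 4L)])
        dx <- xin
        dgamma <- numeric(d[3L])
        dbeta <- numeric(d[3L])
        for (ch in seq_len(d[3L])) {
          xc <- xin[, , ch, , drop = FALSE] - e$mu[ch]
          sd_ <- sqrt(e$va[ch] + e$eps)
          gc_ <- g[, , ch, , drop = FALSE]
          dgamma[ch] <- sum(gc_ * xc / sd_)
          dbeta[ch] <- sum(gc_)
          dxh <- gc_ * p$gamma[ch]
          dvar <- sum(dxh * xc) * (-0.5) / sd_^3
          dmu <- -sum(dxh) / sd_ + dvar * mean(-2 * xc)
          dx[, , ch, ] <- dxh / sd_ + dvar * 2 * xc / m + dmu / m
        }
        pgrads[[ly$name]] <- list(gamma = dgamma, beta = dbeta)
        gacc(inm, dx)
      },
      flatten = {
        d <- dim(outs[[inm]])
        gi <- t(g)
        dim(gi) <- d
        gacc(inm, gi)
      },
      lstm = {
        e <- extras[[ly$name]]
        do_ <- g * e$tC
        dC <- g * e$o * (1 - e$tC^2)
        di <- dC * e$cand
        dcand <- dC * e$i
        # df would multiply C_{t-1} = 0, so the forget path carries no
        # gradient for a length-1 sequence
        dpre_i <- di * e$i * (1 - e$i)
        dpre_o <- do_ * e$o * (1 - e$o)
        dpre_c <- dcand * (1 - e$cand^2)
        dz <- dpre_i %*% p$W_i + dpre_o %*% p$W_o + dpre_c %*% p$W_c
        dx_ <- dz[, seq_len(ncol(e$z) - 2L * ly$hidden), drop = FALSE]
        # W_f / b_f receive exactly zero gradient (forget gate multiplies
        # the zero initial cell state) and are omitted
        pgrads[[ly$name]] <- list(
          W_i = crossprod(dpre_i, e$z),
          W_c = crossprod(dpre_c, e$z),
          W_o = crossprod(dpre_o, e$z),
          b_i = colSums(dpre_i),
          b_c = colSums(dpre_c),
          b_o = colSums(dpre_o)
        )
        gacc(inm, dx_)
      },
      fc = {
        pgrads[[ly$name]] <- list(W = crossprod(g, outs[[inm]]),
          b = colSums(g))
        gacc(inm, g %*% p$W)
      },
      attgate = {
        e <- extras[[ly$name]]
        xa <- outs[[ly$input[1L]]]
        dxa <- dim(xa)
        np <- prod(dxa[c(1L, 2L, 4L)])
        gm_out <- matrix(aperm(g, c(1L, 2L, 4L, 3L)), np, dxa[3L])
        dalpha <- rowSums(gm_out * e$xm)
        du <- dalpha * e$alpha * (1 - e$alpha)
        ds <- du %o% p$phi
        dxm <- gm_out * e$alpha + ds %*% t(p$w_x)
        dgm <- ds %*% t(p$w_g)
        pgrads[[ly$name]] <- list(
          w_x = crossprod(e$xm, ds), w_g = crossprod(e$gm, ds),
          b_g = colSums(ds), phi = drop(crossprod(e$s, du)),
          b_phi = sum(du))
        dx_arr <- aperm(array(dxm, dxa[c(1L, 2L, 4L, 3L)]), c(1L, 2L, 4L, 3L))
        gacc(ly$input[1L], dx_arr)
        gd <- e$g_dim
        dg_full <- array(0, gd)
        r0 <- (gd[1L] - dxa[1L]) %/% 2L
        c0 <- (gd[2L] - dxa[2L]) %/% 2L
        dg_crop <- aperm(array(dgm, c(dxa[1L], dxa[2L], dxa[4L], gd[3L])),
          c(1L, 2L, 4L, 3L))
        dg_full[r0 + seq_len(dxa[1L]), c0 + seq_len(dxa[2L]), , ] <- dg_crop
        gacc(ly$input[2L], dg_full)
      },
      stopf("no backward rule for layer kind '%s'", ly$kind)
    )
    grads_out[[ly$name]] <- NULL  # free as we go
  }
  pgrads
}

cross_entropy_loss <- function(probs, y_idx) {
  -mean(log(pmax(probs[cbind(seq_along(y_idx), y_idx)], 1e-12)))
}

#' Save / load a trained model
#'
#' The layer graph and metadata go to `spec.yaml`; the parameter arrays
#' go to a binary blob (`params.rds`).
#'
#' @param model an [build_acl()] model.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
save_acl <- function(model, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  meta <- list(variant = model$spec$variant,
    input_dim = model$spec$input_dim, n_classes = model$spec$n_classes,
    attention_mode = model$spec$attention_mode, hidden = model$spec$hidden,
    seed = model$seed, class_names = model$class_names,
    layers = lapply(model$spec$layers, function(ly) {
      ly$input <- as.list(ly$input)
      ly
    }))
  yaml::write_yaml(meta, file.path(dir, "spec.yaml"))
  saveRDS(model$params, file.path(dir, "params.rds"))
  invisible(dir)
}

#' @rdname save_acl
#' @param dir directory written by [save_acl()].
#' @export
load_acl <- function(dir) {
  meta <- yaml::read_yaml(file.path(dir, "spec.yaml"))
  model <- build_acl(meta$variant, unlist(meta$input_dim), meta$n_classes,
    seed = meta$seed %||% 1L, attention_mode = meta$attention_mode,
    hidden = meta$hidden)
  model$params <- readRDS(file.path(dir, "params.rds"))
  model$class_names <- unlist(meta$class_names)
  model
}
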