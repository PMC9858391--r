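# Stratified splitting, SGDM optimization and the ablation runner.

#' Training options
#'
#' Defaults follow the reference protocol: initial learning rate 0.001,
#' 5 epochs, validation every 30 iterations, minibatches of 32, SGDM
#' with momentum 0.9, shuffling every epoch.
#'
#' @param initial_lr learning rate (> 0).
#' @param momentum momentum coefficient in `[0, 1)`.
#' @param max_epochs number of epochs (>= 1).
#' @param minibatch minibatch size (>= 1).
#' @param validation_frequency iterations between validation points.
#' @param split_ratio one of `"70-30"`, `"80-20"`, `"90-10"`.
#' @param seed master seed for shuffling and dropout.
#' @param shuffle reshuffle the training set every epoch.
#' @return a `train_config` list.
#' @export
train_config <- function(initial_lr = 0.001, momentum = 0.9,
                         max_epochs = 5L, minibatch = 32L,
                         validation_frequency = 30L,
                         split_ratio = "90-10", seed = 1L,
                         shuffle = TRUE) {
  if (initial_lr <= 0) stopf("initial_lr must be > 0")
  if (momentum < 0 || momentum >= 1) stopf("momentum must lie in [0, 1)")
  if (max_epochs < 1L) stopf("max_epochs must be >= 1")
  if (minibatch < 1L) stopf("minibatch must be >= 1")
  parse_split_ratio(split_ratio)  # validate
  structure(list(initial_lr = initial_lr, momentum = momentum,
    max_epochs = as.integer(max_epochs), minibatch = as.integer(minibatch),
    validation_frequency = as.integer(validation_frequency),
    split_ratio = split_ratio, seed = as.integer(seed),
    shuffle = isTRUE(shuffle)), class = "train_config")
}

# "90-10" -> 0.9; also accepts a numeric train fraction in (0, 1).
parse_split_ratio <- function(ratio) {
  if (is.numeric(ratio)) {
    if (ratio <= 0 || ratio >= 1) stopf("split ratio must lie in (0, 1)")
    return(ratio)
  }
  parts <- strsplit(as.character(ratio), "-", fixed = TRUE)[[1L]]
  if (length(parts) == 2L && !anyNA(suppressWarnings(as.numeric(parts)))) {
    p <- as.numeric(parts)
    if (abs(sum(p) - 100) < 1e-9 && p[1L] > 0 && p[1L] < 100) {
      return(p[1L] / 100)
    }
  }
  stopf("cannot parse split ratio '%s' (expected e.g. \"90-10\")", ratio)
}

#' Stratified train/test split
#'
#' Splits each class independently: the per-class test count is the
#' round-half-up share of the test fraction, at least 1. The per-class
#' permutation is drawn from a seeded stream over the id-sorted samples,
#' so the split is invariant to the input ordering of the dataset.
#'
#' @param dataset a [labeled_dataset]; every class needs >= 2 samples.
#' @param ratio train share: `"70-30"`, `"80-20"`, `"90-10"` or a numeric
#'   fraction in (0, 1).
#' @param seed split seed.
#' @return list with `train` and `test` datasets (disjoint, union =
#'   input).
#' @export
stratified_split <- function(dataset, ratio, seed = 1L) {
  frac <- parse_split_ratio(ratio)
  labels <- dataset_labels(dataset)
  ids <- dataset_ids(dataset)
  test_ids <- character(0)
  for (ci in seq_along(dataset$class_names)) {
    cl <- dataset$class_names[ci]
    cl_ids <- sort(ids[labels == cl])
    n <- length(cl_ids)
    if (n < 2L) stopf("class '%s' has %d sample(s); need at least 2", cl, n)
    n_test <- floor(n * (1 - frac) + 0.5)
    n_test <- max(1L, min(n - 1L, n_test))
    set.seed(derive_seed(seed, ci))
    test_ids <- c(test_ids, cl_ids[sample.int(n, n_test)])
  }
  in_test <- ids %in% test_ids
  list(train = subset_dataset(dataset, which(!in_test)),
       test = subset_dataset(dataset, which(in_test)))
}

#' One SGDM update
#'
#' `v <- momentum * v - lr * grad; params <- params + v`, applied
#' elementwise. `params`, `grads` and `velocity` may be numeric arrays or
#' arbitrarily nested lists of them with matching structure.
#'
#' @param params parameters.
#' @param grads gradients, same structure as `params`.
#' @param velocity velocity state, same structure (use zeros initially).
#' @param lr learning rate.
#' @param momentum momentum coefficient.
#' @return list with updated `params` and `velocity`.
#' @export
sgdm_update <- function(params, grads, velocity, lr, momentum) {
  if (is.list(params)) {
    for (nm in names(grads)) {
      r <- sgdm_update(params[[nm]], grads[[nm]], velocity[[nm]], lr, momentum)
      params[[nm]] <- r$params
      velocity[[nm]] <- r$velocity
    }
    return(list(params = params, velocity = velocity))
  }
  if (length(params) != length(grads)) stopf("parameter/gradient shape mismatch")
  v <- momentum * velocity - lr * grads
  list(params = params + v, velocity = v)
}

zero_like <- function(x) {
  if (is.list(x)) lapply(x, zero_like) else x * 0
}

deep_copy <- function(x) {
  if (is.list(x)) lapply(x, deep_copy) else x + 0
}

# In-place SGDM walk used by the training loop: mutates the (privately
# owned) parameter and velocity arrays through the compiled kernel to
# avoid reallocating hundreds of MB per iteration. Semantically equal to
# sgdm_update().
sgdm_step_inplace <- function(params, grads, velocity, lr, momentum) {
  for (nm in names(grads)) {
    if (is.list(grads[[nm]])) {
      sgdm_step_inplace(params[[nm]], grads[[nm]], velocity[[nm]], lr, momentum)
    } else {
      cpp_sgdm_step(params[[nm]], grads[[nm]], velocity[[nm]], lr, momentum)
    }
  }
  invisible(NULL)
}

# Recompute the batch-norm running statistics as population statistics
# over the training set, one BN layer at a time in graph order (each
# finalized layer feeds the next one's inputs in inference mode).
finalize_bn_stats <- function(model, x, batch_size = 32L) {
  bn_layers <- Filter(function(ly) ly$kind == "bn", model$spec$layers)
  n <- dim(x)[4L]
  for (ly in bn_layers) {
    ch <- model$spec$shapes[[ly$input]][3L]
    s1 <- numeric(ch)
    s2 <- numeric(ch)
    cnt <- 0
    i <- 1L
    while (i <= n) {
      j <- min(i + batch_size - 1L, n)
      fw <- acl_forward(model, x[, , , i:j, drop = FALSE],
        training = FALSE, keep_cache = TRUE)
      xin <- fw$outs[[ly$input]]
      d <- dim(xin)
      cnt <- cnt + prod(d[c(1L, 2L, 4L)])
      for (c_ in seq_len(ch)) {
        sl <- xin[, , c_, , drop = FALSE]
        s1[c_] <- s1[c_] + sum(sl)
        s2[c_] <- s2[c_] + sum(sl^2)
      }
      i <- j + 1L
    }
    mu <- s1 / cnt
    model$params[[ly$name]]$run_mean <- mu
    model$params[[ly$name]]$run_var <- pmax(s2 / cnt - mu^2, 0)
  }
  model
}

#' Train an ACL model with SGDM
#'
#' Minimizes the mean categorical cross-entropy of the softmax outputs
#' over shuffled minibatches. The epoch shuffle and the dropout masks are
#' reseeded per epoch from the master seed, so training is fully
#' reproducible. Validation accuracy is recorded every
#' `validation_frequency` iterations and after the last one. After the
#' final iteration the batch-norm running statistics are recomputed as
#' population statistics over the training set.
#'
#' @param model an [build_acl()] model.
#' @param train_set a [labeled_dataset] of images matching the model
#'   input size; its classes must match the model's class count.
#' @param config a [train_config].
#' @param validation optional [labeled_dataset] used for the validation
#'   trace.
#' @return list with the trained `model` and a `history` (class
#'   `train_history`: per-iteration `loss`, validation points, epoch
#'   boundaries).
#' @export
train_model <- function(model, train_set, config = train_config(),
                        validation = NULL) {
  if (length(train_set$samples) == 0L) stopf("empty training set")
  class_names <- train_set$class_names
  if (length(class_names) != model$spec$n_classes) {
    stopf("training set has %d classes but the model expects %d",
      length(class_names), model$spec$n_classes)
  }
  x <- batch_array(train_set, model$spec$input_dim)
  y <- match(dataset_labels(train_set), class_names)
  model$class_names <- class_names
  # private copy: the update loop mutates parameter arrays in place
  model$params <- deep_copy(model$params)
  n <- length(y)
  bs <- config$minibatch
  n_batches <- ceiling(n / bs)

  velocity <- NULL
  losses <- numeric(0)
  val_iter <- integer(0)
  val_acc <- numeric(0)
  epoch_bounds <- integer(0)
  iter <- 0L

  validate <- function() {
    if (is.null(validation)) return(invisible())
    probs <- predict_proba(model, validation)
    pred <- max.col(probs, ties.method = "first")
    truth <- match(dataset_labels(validation), class_names)
    val_iter <<- c(val_iter, iter)
    val_acc <<- c(val_acc, mean(pred == truth))
  }

  for (epoch in seq_len(config$max_epochs)) {
    set.seed(derive_seed(config$seed, 1000L + epoch))
    ord <- if (config$shuffle) sample.int(n) else seq_len(n)
    for (b in seq_len(n_batches)) {
      idx <- ord[((b - 1L) * bs + 1L):min(b * bs, n)]
      xb <- x[, , , idx, drop = FALSE]
      yb <- y[idx]
      fw <- acl_forward(model, xb, training = TRUE, keep_cache = TRUE)
      for (nm in names(fw$new_run)) {
        model$params[[nm]]$run_mean <- fw$new_run[[nm]]$run_mean
        model$params[[nm]]$run_var <- fw$new_run[[nm]]$run_var
      }
      loss <- cross_entropy_loss(fw$probs, yb)
      if (!is.finite(loss)) {
        stopf("non-finite training loss at iteration %d; try a lower learning rate",
          iter + 1L)
      }
      grads <- acl_backward(model, fw, yb)
      if (is.null(velocity)) velocity <- zero_like(grads)
      sgdm_step_inplace(model$params, grads, velocity,
        config$initial_lr, config$momentum)
      iter <- iter + 1L
      losses <- c(losses, loss)
      if (iter %% config$validation_frequency == 0L) validate()
    }
    epoch_bounds <- c(epoch_bounds, iter)
  }
  model <- finalize_bn_stats(model, x, batch_size = bs)
  if (length(val_iter) == 0L || val_iter[length(val_iter)] != iter) validate()

  history <- structure(list(
    loss = losses,
    validation = data.frame(iteration = val_iter, accuracy = val_acc),
    epoch_boundaries = epoch_bounds,
    config = config
  ), class = "train_history")
  list(model = model, history = history)
}

#' @export
print.train_history <- function(x, ...) {
  cat(sprintf("<train_history> %d iterations, final loss %.4f",
    length(x$loss), x$loss[length(x$loss)]))
  if (nrow(x$validation)) {
    cat(sprintf(", final validation accuracy %.3f",
      x$validation$accuracy[nrow(x$validation)]))
  }
  cat("\n")
  invisible(x)
}

#' Attention/LSTM ablation study
#'
#' Trains the four network variants (`case1` = plain CNN, `case2` = LSTM
#' only, `case3` = attention only, `full`) on identical stratified splits
#' for every requested ratio and seed, evaluating each on its held-out
#' test set. The split, the parameter initialization and the shuffling
#' depend only on (dataset, ratio, seed), so all four variants of one
#' cell see exactly the same data.
#'
#' @param dataset a [labeled_dataset] of network-input-sized images.
#' @param ratios character vector of split ratios.
#' @param seeds integer vector of seeds.
#' @param config a [train_config] (its `split_ratio`/`seed` fields are
#'   overridden per cell).
#' @param variants variants to run (default all four cases).
#' @param verbose print one line per trained cell.
#' @return an `ablation_result`: list of per-cell records (variant,
#'   ratio, seed, test ids, [evaluate_model()] report); see
#'   [report_tables()] for the tabular view.
#' @export
run_ablation <- function(dataset, ratios = c("70-30", "80-20", "90-10"),
                         seeds = 1L, config = train_config(),
                         variants = c("case1", "case2", "case3", "full"),
                         verbose = FALSE) {
  input_dim <- dim(to_rgb(dataset$samples[[1L]])$pixels)
  records <- list()
  for (seed in seeds) {
    for (ratio in ratios) {
      sp <- stratified_split(dataset, ratio, seed = seed)
      for (variant in variants) {
        cfg <- config
        cfg$seed <- as.integer(seed)
        cfg$split_ratio <- ratio
        model <- build_acl(variant, input_dim,
          n_classes = length(dataset$class_names), seed = seed)
        tr <- train_model(model, sp$train, cfg, validation = sp$test)
        rep <- evaluate_model(tr$model, sp$test)
        if (verbose) {
          message(sprintf("ablation: %s %s seed %d -> accuracy %.3f",
            variant, ratio, seed, rep$accuracy))
        }
        records[[length(records) + 1L]] <- list(
          variant = variant, ratio = ratio, seed = as.integer(seed),
          test_ids = dataset_ids(sp$test), report = rep,
          history = tr$history)
      }
    }
  }
  structure(list(records = records), class = "ablation_result")
}
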