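# Layer semantics (softmax, LSTM cell, attention gate) and the network
# graph: architecture conformance, shape propagation, forward contracts.

test_that("softmax is symmetric, shift-invariant and matches direct evaluation", {
  expect_equal(softmax(c(0, 0, 0)), rep(1 / 3, 3))
  set.seed(4)
  for (i in 1:20) {
    x <- rnorm(sample(2:6, 1), sd = 5)
    s <- softmax(x)
    expect_true(all(s > 0))
    expect_equal(sum(s), 1, tolerance = 1e-12)
    expect_equal(softmax(x + runif(1, -100, 100)), s, tolerance = 1e-9)
  }
  expect_equal(softmax(c(1, 2, 3)), exp(1:3) / sum(exp(1:3)), tolerance = 1e-12)
  expect_equal(round(softmax(c(1, 2, 3)), 4), c(0.0900, 0.2447, 0.6652))
  expect_error(softmax(c(1, NA)), "finite")
  # stability at large magnitudes
  expect_equal(sum(softmax(c(1000, 1001, 999))), 1)
})

random_lstm_weights <- function(hidden, input) {
  zw <- input + 2L * hidden
  lstm_weights(
    matrix(rnorm(hidden * zw), hidden), matrix(rnorm(hidden * zw), hidden),
    matrix(rnorm(hidden * zw), hidden), matrix(rnorm(hidden * zw), hidden),
    rnorm(hidden), rnorm(hidden), rnorm(hidden), rnorm(hidden))
}

test_that("lstm_cell_step matches the scalar oracle and saturation limits", {
  # zero weights, zero state -> zero outputs
  w0 <- lstm_weights(matrix(0, 2, 8), matrix(0, 2, 8), matrix(0, 2, 8),
    matrix(0, 2, 8), rep(0, 2), rep(0, 2), rep(0, 2), rep(0, 2))
  st <- lstm_cell_step(c(1, 1, 1, 1), list(h = c(0, 0), C = c(0, 0)), w0)
  expect_equal(st$h, c(0, 0))
  expect_equal(st$C, c(0, 0))
  g <- attr(st, "gates")
  expect_equal(g$f, c(0.5, 0.5))
  # saturated forget gate, closed input gate -> memory carried through
  wsat <- lstm_weights(matrix(0, 2, 8), matrix(0, 2, 8), matrix(0, 2, 8),
    matrix(0, 2, 8), rep(20, 2), rep(-20, 2), rep(0, 2), rep(0, 2))
  C0 <- c(0.7, -0.2)
  st2 <- lstm_cell_step(runif(4), list(h = c(0.1, 0.1), C = C0), wsat)
  expect_equal(st2$C, C0, tolerance = 1e-6)
  # hidden size 1, all weights 1, x = 1, zero state: hand evaluation
  w1 <- lstm_weights(matrix(1, 1, 3), matrix(1, 1, 3), matrix(1, 1, 3),
    matrix(1, 1, 3), 0, 0, 0, 0)
  st3 <- lstm_cell_step(1, list(h = 0, C = 0), w1)
  sig1 <- 1 / (1 + exp(-1))
  C_hand <- sig1 * tanh(1)
  expect_equal(st3$C, C_hand, tolerance = 1e-9)
  expect_equal(st3$h, sig1 * tanh(C_hand), tolerance = 1e-9)
  # random tensors against the scalar loop oracle
  set.seed(12)
  for (i in 1:25) {
    hid <- sample(1:4, 1)
    din <- sample(1:5, 1)
    w <- random_lstm_weights(hid, din)
    x <- rnorm(din)
    h <- rnorm(hid)
    C <- rnorm(hid)
    got <- lstm_cell_step(x, list(h = h, C = C), w)
    want <- lstm_oracle(x, h, C, w)
    expect_equal(got$h, want$h, tolerance = 1e-12)
    expect_equal(got$C, want$C, tolerance = 1e-12)
    gates <- attr(got, "gates")
    expect_true(all(gates$f > 0 & gates$f < 1))
    expect_true(all(gates$i > 0 & gates$i < 1))
    expect_true(all(gates$o > 0 & gates$o < 1))
  }
  expect_error(lstm_cell_step(c(1, 1), list(h = 0, C = 0), w1), "input length")
})

test_that("attention_gate matches per-pixel evaluation and its limiting cases", {
  set.seed(31)
  # x = 0 -> out = 0 whatever the weights
  w <- attention_weights(matrix(rnorm(6), 2), matrix(rnorm(9), 3),
    rnorm(3), rnorm(3), rnorm(1))
  zx <- array(0, c(4, 4, 2))
  g <- array(rnorm(48), c(4, 4, 3))
  expect_equal(attention_gate(zx, g, w), zx, ignore_attr = TRUE)
  # all-zero weights: alpha = 0.5 everywhere, out = x/2
  w0 <- attention_weights(matrix(0, 2, 3), matrix(0, 3, 3), rep(0, 3),
    rep(0, 3), 0)
  x <- array(rnorm(32), c(4, 4, 2))
  out0 <- attention_gate(x, g, w0)
  expect_equal(out0, 0.5 * x, ignore_attr = TRUE)
  expect_true(all(attr(out0, "alpha") == 0.5))
  # random tensors vs the scalar oracle
  for (i in 1:25) {
    cx <- sample(1:3, 1)
    cg <- sample(1:3, 1)
    ci <- sample(1:3, 1)
    w <- attention_weights(matrix(rnorm(cx * ci), cx),
      matrix(rnorm(cg * ci), cg), rnorm(ci), rnorm(ci), rnorm(1))
    x <- array(rnorm(4 * 4 * cx), c(4, 4, cx))
    g <- array(rnorm(4 * 4 * cg), c(4, 4, cg))
    got <- attention_gate(x, g, w)
    want <- attention_oracle(x, g, w)
    expect_equal(got, want$out, tolerance = 1e-12, ignore_attr = TRUE)
    a <- attr(got, "alpha")
    expect_equal(a, want$alpha, tolerance = 1e-12)
    expect_true(all(a > 0 & a < 1))
  }
  expect_error(attention_gate(array(0, c(3, 3, 2)), array(0, c(4, 4, 2)), w0),
    "equal spatial size")
})

test_that("the full variant reproduces the 28-row layer table", {
  m <- build_acl("full", seed = 1)
  spec <- m$spec
  expect_length(spec$layers, 28L)
  kinds <- vapply(spec$layers, `[[`, character(1), "kind")
  expect_identical(sum(kinds == "conv"), 6L)
  expect_identical(sum(kinds == "bn"), 2L)
  expect_identical(sum(kinds == "maxpool"), 3L)
  lstm <- spec$layers[[which(kinds == "lstm")]]
  expect_identical(lstm$hidden, 100L)
  mul <- spec$layers[[which(kinds == "mul")]]
  expect_length(mul$input, 2L)
  expect_setequal(mul$input, c("sigmoid_1_1_1_3", "maxpool2d_2"))
  drop <- spec$layers[[which(kinds == "dropout")]]
  expect_equal(drop$rate, 0.4)
  expect_identical(spec$shapes$input, c(100L, 100L, 3L))
  expect_identical(spec$shapes$fc1, 3L)
  # multiplication inputs shape-consistent by construction
  expect_identical(spec$shapes$sigmoid_1_1_1_3, spec$shapes$maxpool2d_2)
})

test_that("ablation variants drop exactly the advertised structures", {
  k <- function(m) vapply(m$spec$layers, `[[`, character(1), "kind")
  c1 <- build_acl("case1", seed = 1)
  expect_false(any(k(c1) %in% c("sigmoid", "mul", "lstm")))
  c2 <- build_acl("case2", seed = 1)
  expect_false(any(k(c2) %in% c("sigmoid", "mul")))
  expect_true("lstm" %in% k(c2))
  c3 <- build_acl("case3", seed = 1)
  expect_true(all(c("sigmoid", "mul") %in% k(c3)))
  expect_false("lstm" %in% k(c3))
  expect_error(build_acl("case9"), "unknown variant")
})

test_that("parameter counts are deterministic and strictly ordered across variants", {
  n <- vapply(c("case1", "case2", "case3", "full"), function(v)
    n_params(build_acl(v, seed = 3)), integer(1))
  expect_lt(n[["case1"]], n[["case2"]])
  expect_lt(n[["case1"]], n[["case3"]])
  expect_lt(n[["case2"]], n[["full"]])
  expect_lt(n[["case3"]], n[["full"]])
  expect_identical(n_params(build_acl("full", seed = 1)),
    n_params(build_acl("full", seed = 2)))
})

test_that("forward produces exchangeable per-sample probability rows", {
  m <- build_acl("full", c(24L, 24L, 3L), 3L, seed = 5, hidden = 8L)
  set.seed(10)
  x <- array(runif(24 * 24 * 3 * 4), c(24, 24, 3, 4))
  p <- predict_proba(m, x)
  expect_identical(dim(p), c(4L, 3L))
  expect_true(all(p >= 0))
  expect_equal(rowSums(p), rep(1, 4), tolerance = 1e-6)
  # permuting the batch permutes outputs identically
  perm <- c(3, 1, 4, 2)
  p2 <- predict_proba(m, x[, , , perm])
  expect_equal(p2, p[perm, ], tolerance = 1e-12)
  # determinism
  expect_identical(predict_proba(m, x), p)
  expect_error(predict_proba(m, array(0.1, c(10, 10, 3, 1))), "expects")
})

test_that("identical seeds give identical models; the eq10 gate is available", {
  a <- build_acl("full", c(24L, 24L, 3L), seed = 7, hidden = 4L)
  b <- build_acl("full", c(24L, 24L, 3L), seed = 7, hidden = 4L)
  expect_identical(a$params, b$params)
  e <- build_acl("full", c(24L, 24L, 3L), seed = 7, hidden = 4L,
    attention_mode = "eq10")
  kinds <- vapply(e$spec$layers, `[[`, character(1), "kind")
  expect_true("attgate" %in% kinds)
  expect_false("mul" %in% kinds)
  x <- array(runif(24 * 24 * 3), c(24, 24, 3, 1))
  expect_equal(sum(predict_proba(e, x)), 1, tolerance = 1e-9)
})

test_that("convolution and pooling backward match a double-precision reference", {
  set.seed(41)
  conv_ref <- function(x, W, b, pad) {
    d <- dim(x)
    k <- dim(W)[1]
    Ho <- d[1] + 2 * pad - k + 1
    Wo <- d[2] + 2 * pad - k + 1
    xp <- array(0, c(d[1] + 2 * pad, d[2] + 2 * pad, d[3], d[4]))
    xp[pad + seq_len(d[1]), pad + seq_len(d[2]), , ] <- x
    out <- array(0, c(Ho, Wo, dim(W)[4], d[4]))
    for (n in seq_len(d[4])) for (co in seq_len(dim(W)[4])) {
      for (ho in seq_len(Ho)) for (wo in seq_len(Wo)) {
        out[ho, wo, co, n] <- sum(xp[ho:(ho + k - 1), wo:(wo + k - 1), , n] *
          W[, , , co]) + b[co]
      }
    }
    out
  }
  x <- array(runif(7 * 8 * 3 * 2), c(7, 8, 3, 2))
  W <- array(runif(3 * 3 * 3 * 4, -0.5, 0.5), c(3, 3, 3, 4))
  b <- runif(4)
  for (pad in 0:1) {
    want <- conv_ref(x, W, b, pad)
    got <- aclnet:::cpp_conv2d_fwd(x, W, b, pad)
    expect_equal(got, want, tolerance = 1e-5)
    dY <- array(rnorm(length(want)), dim(want))
    r <- aclnet:::cpp_conv2d_bwd(x, W, dY, pad)
    loss <- function(x_, W_, b_) sum(conv_ref(x_, W_, b_, pad) * dY)
    eps <- 1e-6
    for (i in sample(length(W), 6)) {
      Wp <- W; Wp[i] <- W[i] + eps
      Wm <- W; Wm[i] <- W[i] - eps
      expect_equal(r$dW[i], (loss(x, Wp, b) - loss(x, Wm, b)) / (2 * eps),
        tolerance = 1e-4)
    }
    for (i in sample(length(x), 6)) {
      xp <- x; xp[i] <- x[i] + eps
      xm <- x; xm[i] <- x[i] - eps
      expect_equal(r$dX[i], (loss(xp, W, b) - loss(xm, W, b)) / (2 * eps),
        tolerance = 1e-4)
    }
    for (co in 1:4) {
      bp <- b; bp[co] <- b[co] + eps
      bm <- b; bm[co] <- b[co] - eps
      expect_equal(r$db[co], (loss(x, W, bp) - loss(x, W, bm)) / (2 * eps),
        tolerance = 1e-4)
    }
  }
  # maxpool: forward against apply(), backward against finite differences
  x2 <- array(runif(6 * 6 * 2 * 2), c(6, 6, 2, 2))
  mp <- aclnet:::cpp_maxpool_fwd(x2, 3L, 1L)
  for (n in 1:2) for (c_ in 1:2) for (ho in 1:4) for (wo in 1:4) {
    expect_identical(mp$Y[ho, wo, c_, n],
      max(x2[ho:(ho + 2), wo:(wo + 2), c_, n]))
  }
  dY2 <- array(rnorm(length(mp$Y)), dim(mp$Y))
  dX2 <- aclnet:::cpp_maxpool_bwd(mp$argmax, dY2, dim(x2))
  eps <- 1e-7
  for (i in sample(length(x2), 10)) {
    xp <- x2; xp[i] <- x2[i] + eps
    xm <- x2; xm[i] <- x2[i] - eps
    num <- (sum(aclnet:::cpp_maxpool_fwd(xp, 3L, 1L)$Y * dY2) -
      sum(aclnet:::cpp_maxpool_fwd(xm, 3L, 1L)$Y * dY2)) / (2 * eps)
    expect_equal(dX2[i], num, tolerance = 1e-5)
  }
})

test_that("network backward matches directional numerical derivatives", {
  # Two regimes. Parameters downstream of every convolution (LSTM, FC,
  # attention gate) see a bit-identical convolutional forward on both
  # sides of the perturbation, so per-coordinate finite differences are
  # tight. Perturbing convolution/BN parameters re-rounds the
  # single-precision conv GEMMs (~1e-7 loss noise) and flips max-pool
  # argmax near-ties, so those are checked in aggregate (directional
  # derivative over all parameters) at a coarse tolerance; the exact
  # double-precision kernel oracles above carry the tight conv checks.
  check_variant <- function(variant, amode = "table") {
    m <- build_acl(variant, c(20L, 20L, 3L), 3L, seed = 2,
      attention_mode = amode, hidden = 6L)
    set.seed(9)
    n <- 3L
    x <- array(runif(20 * 20 * 3 * n), c(20, 20, 3, n))
    y <- sample.int(3L, n, replace = TRUE)
    loss_for <- function(params) {
      m2 <- m
      m2$params <- params
      set.seed(77) # fixes the dropout mask
      f <- aclnet:::acl_forward(m2, x, training = TRUE)
      aclnet:::cross_entropy_loss(f$probs, y)
    }
    set.seed(77)
    fw <- aclnet:::acl_forward(m, x, training = TRUE, keep_cache = TRUE)
    gr <- aclnet:::acl_backward(m, fw, y)

    # tight per-coordinate check on the post-convolution layers
    eps <- 1e-5
    downstream <- intersect(names(gr), c("lstm", "fc0", "fc1", "attgate_1"))
    worst_coord <- 0
    for (lnm in downstream) {
      for (pnm in names(gr[[lnm]])) {
        g <- gr[[lnm]][[pnm]]
        idx <- sample(length(g), min(3L, length(g)))
        for (i in idx) {
          p2 <- m$params
          p2[[lnm]][[pnm]][i] <- p2[[lnm]][[pnm]][i] + eps
          lp <- loss_for(p2)
          p2[[lnm]][[pnm]][i] <- p2[[lnm]][[pnm]][i] - 2 * eps
          lm <- loss_for(p2)
          num <- (lp - lm) / (2 * eps)
          worst_coord <- max(worst_coord, abs(num - g[i]) /
            max(1e-6, abs(num) + abs(g[i])))
        }
      }
    }
    expect_lt(worst_coord, 1e-3)

    # aggregate directional check across all parameters
    worst_dir <- 0
    for (trial in 1:5) {
      set.seed(4000 + trial)
      dirs <- lapply(gr, function(pl) lapply(pl, function(g) {
        d <- rnorm(length(g))
        if (!is.null(dim(g))) dim(d) <- dim(g)
        d
      }))
      ana <- sum(unlist(Map(function(pl, dl) {
        sum(unlist(Map(function(g, d) sum(g * d), pl, dl)))
      }, gr, dirs)))
      shift <- function(sgn) {
        p <- m$params
        for (lnm in names(dirs)) {
          for (pnm in names(dirs[[lnm]])) {
            p[[lnm]][[pnm]] <- p[[lnm]][[pnm]] + sgn * eps * dirs[[lnm]][[pnm]]
          }
        }
        p
      }
      num <- (loss_for(shift(1)) - loss_for(shift(-1))) / (2 * eps)
      worst_dir <- max(worst_dir, abs(num - ana) / max(1e-6, abs(num) + abs(ana)))
    }
    expect_lt(worst_dir, 0.15)
  }
  for (v in c("full", "case1", "case3")) check_variant(v)
  check_variant("full", "eq10")
})

test_that("models survive a save/load round-trip", {
  m <- build_acl("case3", c(24L, 24L, 3L), seed = 4, hidden = 4L)
  m$class_names <- c("a", "b", "c")
  dir <- withr::local_tempdir()
  save_acl(m, dir)
  expect_true(file.exists(file.path(dir, "spec.yaml")))
  back <- load_acl(dir)
  expect_identical(back$spec$variant, "case3")
  expect_identical(back$class_names, c("a", "b", "c"))
  x <- array(runif(24 * 24 * 3 * 2), c(24, 24, 3, 2))
  expect_equal(predict_proba(back, x), predict_proba(m, x), tolerance = 1e-12)
})
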