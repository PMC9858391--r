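# Independent reference implementations used as test oracles. These are
# deliberately written as plain, slow R: loops and linear scans, no
# shared code with the package internals.

# Brute-force marker-seeded flooding: same algorithm contract as the
# package watershed (ascending priority, FIFO on ties, 4-connectivity
# with neighbours ordered up/down/left/right, column-major initial scan,
# ridge pixels non-propagating) realized with a linear-scan frontier.
ws_oracle <- function(P, seeds) {
  H <- nrow(P)
  W <- ncol(P)
  lab <- seeds # 0 undecided, -1 ridge
  nbrs <- function(i) {
    r <- (i - 1L) %% H + 1L
    c <- (i - 1L) %/% H + 1L
    out <- integer(0)
    if (r > 1L) out <- c(out, i - 1L)
    if (r < H) out <- c(out, i + 1L)
    if (c > 1L) out <- c(out, i - H)
    if (c < W) out <- c(out, i + H)
    out
  }
  cap <- 16L * H * W
  q_idx <- integer(cap)
  q_pr <- numeric(cap)
  q_seq <- numeric(cap)
  q_live <- logical(cap)
  qn <- 0L
  sq <- 0
  push <- function(i) {
    qn <<- qn + 1L
    q_idx[qn] <<- i
    q_pr[qn] <<- P[i]
    q_seq[qn] <<- sq
    q_live[qn] <<- TRUE
    sq <<- sq + 1
  }
  for (i in seq_len(H * W)) { # column-major scan
    if (lab[i] == 0L && any(lab[nbrs(i)] > 0L)) push(i)
  }
  repeat {
    live <- which(q_live[seq_len(qn)])
    if (length(live) == 0L) break
    mp <- min(q_pr[live])
    cand <- live[q_pr[live] == mp]
    j <- cand[which.min(q_seq[cand])]
    q_live[j] <- FALSE
    i <- q_idx[j]
    if (lab[i] != 0L) next
    nl <- lab[nbrs(i)]
    nl <- unique(nl[nl > 0L])
    if (length(nl) == 1L) {
      lab[i] <- nl
      for (k in nbrs(i)) if (lab[k] == 0L) push(k)
    } else if (length(nl) > 1L) {
      lab[i] <- -1L
    }
  }
  lab[lab < 0L] <- 0L
  lab
}

# Direct per-pixel evaluation of the additive attention gate.
attention_oracle <- function(x, g, w) {
  d <- dim(x)
  out <- array(0, d)
  alpha <- matrix(0, d[1L], d[2L])
  for (r in seq_len(d[1L])) {
    for (cc in seq_len(d[2L])) {
      xv <- x[r, cc, ]
      gv <- g[r, cc, ]
      inner <- drop(t(w$w_x) %*% xv) + drop(t(w$w_g) %*% gv) + w$b_g
      a <- 1 / (1 + exp(-(sum(w$phi * inner) + w$b_phi)))
      alpha[r, cc] <- a
      out[r, cc, ] <- a * xv
    }
  }
  list(out = out, alpha = alpha)
}

# Scalar-loop evaluation of one LSTM cell step.
lstm_oracle <- function(x, h, C, w) {
  z <- c(x, h, C)
  hid <- length(w$b_f)
  sig <- function(v) 1 / (1 + exp(-v))
  f <- i <- o <- cd <- numeric(hid)
  for (k in seq_len(hid)) {
    f[k] <- sig(sum(w$W_f[k, ] * z) + w$b_f[k])
    i[k] <- sig(sum(w$W_i[k, ] * z) + w$b_i[k])
    o[k] <- sig(sum(w$W_o[k, ] * z) + w$b_o[k])
    cd[k] <- tanh(sum(w$W_c[k, ] * z) + w$b_c[k])
  }
  Cn <- f * C + i * cd
  list(h = o * tanh(Cn), C = Cn, f = f, i = i, o = o)
}

# Counting oracle for the one-vs-rest metrics: per-sample tallies in
# integer arithmetic.
metrics_oracle <- function(true, pred, classes) {
  out <- list()
  for (cl in classes) {
    tp <- sum(true == cl & pred == cl)
    fn <- sum(true == cl & pred != cl)
    fp <- sum(true != cl & pred == cl)
    tn <- sum(true != cl & pred != cl)
    div <- function(a, b) if (b == 0) NA_real_ else a / b
    out[[cl]] <- c(Se = div(tp, tp + fn), Sp = div(tn, tn + fp),
      Pr = div(tp, tp + fp), F_score = div(2 * tp, 2 * tp + fp + fn))
  }
  out
}

# Mann-Whitney AUC: P(score_pos > score_neg) + 0.5 P(tie), by explicit
# pairwise comparison.
auc_oracle <- function(scores, positive) {
  sp <- scores[positive]
  sn <- scores[!positive]
  tot <- 0
  for (a in sp) for (b in sn) tot <- tot + (a > b) + 0.5 * (a == b)
  tot / (length(sp) * length(sn))
}

# Random small watershed fixture: smooth-ish priority surface plus k
# marker points.
random_ws_fixture <- function(h, w, n_seeds) {
  P <- matrix(stats::runif(h * w), h, w)
  P <- (P + P[c(1L, seq_len(h - 1L)), ] + P[, c(1L, seq_len(w - 1L))]) / 3
  seeds <- matrix(0L, h, w)
  pos <- sample.int(h * w, n_seeds)
  seeds[pos] <- seq_len(n_seeds)
  list(P = P, seeds = seeds)
}

# Tiny dataset of noiseless two-blob images for fast training tests.
tiny_training_dataset <- function(n_per_class = 6L, hw = 24L, seed = 5L) {
  profiles <- list(
    a = synth_profile("a", c(0L, 0L), c(3, 4), c(0.3, 0.4)),
    b = synth_profile("b", c(2L, 2L), c(2.5, 3.5), c(0.4, 0.5)),
    c = synth_profile("c", c(5L, 5L), c(2, 3), c(0.4, 0.5))
  )
  samples <- list()
  idx <- 0L
  for (cl in names(profiles)) {
    for (i in seq_len(n_per_class)) {
      idx <- idx + 1L
      set.seed(seed * 1000L + idx)
      samples[[idx]] <- generate_image(profiles[[cl]], hw, hw,
        noise_sd = 0.01, label = cl, id = sprintf("%s/%03d", cl, i))
    }
  }
  labeled_dataset(samples, names(profiles))
}

expect_partition <- function(seg) {
  expect_equal(sum(seg$region_sizes) + sum(seg$labels == 0L),
    length(seg$labels))
}
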