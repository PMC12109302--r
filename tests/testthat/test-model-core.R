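test_that("convolution length arithmetic matches the branch shapes", {
  # default first-layer banks on a 3000-sample epoch
  expect_equal(conv_out_len(3000, 50, 20), 148L)
  expect_equal(conv_out_len(3000, 20, 5), 597L)
  cfg <- mscnn_config()
  expect_equal(unname(cfg$lengths$large["conv1"]), 148L)
  expect_equal(unname(cfg$lengths$small["conv1"]), 597L)
  expect_equal(unname(cfg$lengths$large["pool1"]), 37L)
  expect_equal(unname(cfg$lengths$small["pool1"]), 149L)
  # cross-check the compiled kernel against the arithmetic
  set.seed(1)
  x <- array(rnorm(3000 * 2), c(1, 3000, 2))
  w <- array(rnorm(50 * 3), c(1, 50, 3))
  y <- multisess:::conv1d_fwd_cpp(x, w, numeric(3), 20L)
  expect_equal(dim(y), c(3, 148, 2))
  y2 <- multisess:::conv1d_fwd_cpp(x, array(rnorm(20 * 3), c(1, 20, 3)),
                                   numeric(3), 5L)
  expect_equal(dim(y2), c(3, 597, 2))
})

test_that("strided convolution matches a direct loop evaluation", {
  set.seed(4)
  x <- array(rnorm(2 * 40 * 3), c(2, 40, 3))
  w <- array(rnorm(2 * 5 * 4), c(2, 5, 4))
  b <- rnorm(4)
  y <- multisess:::conv1d_fwd_cpp(x, w, b, 3L)
  ref <- array(0, dim(y))
  for (bb in 1:3) for (t in seq_len(dim(y)[2])) for (o in 1:4) {
    acc <- b[o]
    for (k in 1:5) for (c in 1:2) {
      acc <- acc + x[c, (t - 1) * 3 + k, bb] * w[c, k, o]
    }
    ref[o, t, bb] <- acc
  }
  expect_equal(y, ref, tolerance = 1e-12)
  # zero weights and biases give a zero feature map
  y0 <- multisess:::conv1d_fwd_cpp(x, array(0, c(2, 5, 4)), numeric(4), 3L)
  expect_true(all(y0 == 0))
  expect_error(multisess:::conv1d_fwd_cpp(array(0, c(1, 4, 1)), w, b, 1L))
})

test_that("mscnn output has the aligned length and rejects short inputs", {
  cfg <- tiny_mscnn()
  set.seed(2)
  p <- multisess:::mscnn_params(cfg)
  x <- matrix(rnorm(3 * 240), 3, 240)
  y <- mscnn_forward(x, p, cfg)
  expect_equal(dim(y), c(cfg$channels_out, cfg$t_out, 3))
  expect_error(mscnn_forward(matrix(0, 2, 100), p, cfg), "epoch length")
})

test_that("SE squeeze is the temporal mean, excitation stays in (0,1), recalibration scales", {
  set.seed(8)
  U <- array(rnorm(6 * 5 * 3), c(6, 5, 3))
  z <- se_squeeze(U)
  # brute-force mean oracle
  for (c in 1:6) for (b in 1:3) {
    expect_equal(z[c, b], mean(U[c, , b]), tolerance = 1e-12)
  }
  Uc <- array(7, c(4, 9, 2))
  expect_true(all(se_squeeze(Uc) == 7))
  expect_equal(se_squeeze(array(c(1, 2, 3, 4), c(1, 4, 1)))[1, 1], 2.5)

  p <- se_params(4, r = 2)
  s <- se_excite(z[1:4, , drop = FALSE], p)
  expect_true(all(s > 0 & s < 1))
  p0 <- list(W1 = matrix(0, 2, 4), W2 = matrix(0, 4, 2))
  expect_true(all(se_excite(matrix(rnorm(8), 4, 2), p0) == 0.5))

  # hand-set weights vs scalar-loop evaluation
  set.seed(10)
  p2 <- list(W1 = matrix(rnorm(8) / 2, 2, 4), W2 = matrix(rnorm(8) / 2, 4, 2))
  zz <- matrix(rnorm(4), 4, 1)
  manual <- numeric(4)
  hidden <- pmax(as.vector(p2$W1 %*% zz), 0)
  for (c in 1:4) manual[c] <- 1 / (1 + exp(-sum(p2$W2[c, ] * hidden)))
  expect_equal(as.vector(se_excite(zz, p2)), manual, tolerance = 1e-10)

  sc <- matrix(runif(6 * 3), 6, 3)
  X <- se_recalibrate(U, sc)
  for (c in 1:6) for (b in 1:3) {
    expect_equal(X[c, , b], sc[c, b] * U[c, , b], tolerance = 1e-12)
  }
  expect_equal(se_recalibrate(U, matrix(1, 6, 3)), U)
  expect_true(all(se_recalibrate(U, matrix(0, 6, 3)) == 0))
  expect_error(se_params(10, r = 16), "not divisible")
})

test_that("attention rows sum to one for 1-3 modalities and degenerate cases are exact", {
  for (M in 1:3) {
    set.seed(M)
    h <- lapply(seq_len(M), function(i) matrix(rnorm(4 * 6), 4, 6))
    a <- ssm_attention_weights(h)
    sums <- apply(a, c(1, 3), sum)
    expect_equal(as.vector(sums), rep(1, M * 6), tolerance = 1e-12)
  }
  # M = 1 collapses to alpha = 1
  a1 <- ssm_attention_weights(list(matrix(rnorm(8), 4, 2)))
  expect_equal(as.vector(a1), c(1, 1))
  # identical states give uniform attention
  h <- matrix(rnorm(12), 4, 3)
  au <- ssm_attention_weights(list(h, h, h))
  expect_equal(as.vector(au), rep(1 / 3, 3 * 3 * 3), tolerance = 1e-12)
  # closed-form softmax for orthogonal two-modality states
  h1 <- matrix(c(1, 0), 2, 1); h2 <- matrix(c(0, 1), 2, 1)
  a2 <- ssm_attention_weights(list(h1, h2))
  s <- 1 / sqrt(2)  # self score 1/sqrt(H), cross score 0
  expect_equal(a2[1, 1, 1], exp(s) / (exp(s) + 1), tolerance = 1e-12)
  expect_equal(a2[1, 2, 1], 1 / (exp(s) + 1), tolerance = 1e-12)
})

test_that("coupling step has the zero fixed point and loses cross-modal term when S = 0", {
  H <- 3L; D <- 4L; B <- 2L
  p <- ssm_params(2, D, H)
  h0 <- list(matrix(0, H, B), matrix(0, H, B))
  x0 <- list(matrix(0, D, B), matrix(0, D, B))
  p0 <- p; p0$B[] <- 0
  st <- ssm_couple_step(h0, x0, p0)
  expect_true(all(vapply(st$h, function(h) all(h == 0), logical(1))))

  # S_n = 0: h_n = tanh(B x_n), identical across modalities sharing x
  pS <- p; pS$S <- lapply(pS$S, function(s) s * 0)
  x <- matrix(rnorm(D * B), D, B)
  hp <- list(matrix(rnorm(H * B), H, B), matrix(rnorm(H * B), H, B))
  st2 <- ssm_couple_step(hp, list(x, x), pS)
  expect_equal(st2$h[[1]], tanh(pS$B %*% x), tolerance = 1e-12)
  expect_equal(st2$h[[1]], st2$h[[2]], tolerance = 1e-12)
  expect_true(all(abs(unlist(st2$h)) < 1))
  expect_error(ssm_couple_step(hp[1], list(x, x), p), "modality count")
})

test_that("coupling recurrence matches a scalar-loop reference over three steps", {
  # independent reference: plain R loops over every index, following the
  # two-pass update (pre-activation states -> attention -> refined states)
  ref_forward <- function(X, p) {
    M <- length(X); Tn <- dim(X[[1]])[2]; B <- dim(X[[1]])[3]
    H <- nrow(p$B); D <- ncol(p$B)
    h <- lapply(seq_len(M), function(n) matrix(0, H, B))
    for (t in seq_len(Tn)) {
      xh <- lapply(seq_len(M), function(n) {
        out <- matrix(0, D, B)
        for (b in seq_len(B)) {
          v <- X[[n]][, t, b]
          out[, b] <- p$gamma[[n]] * (v - mean(v)) /
            sqrt(mean((v - mean(v))^2) + 1e-5) + p$beta[[n]]
        }
        out
      })
      pre <- vector("list", M)
      for (n in seq_len(M)) {
        pre[[n]] <- matrix(0, H, B)
        for (b in seq_len(B)) {
          hsum <- numeric(H)
          for (m in seq_len(M)) hsum <- hsum + h[[m]][, b]
          pre[[n]][, b] <- tanh(as.vector(t(p$S[[n]]) %*% hsum) +
                                  as.vector(p$B %*% xh[[n]][, b]))
        }
      }
      hn <- vector("list", M)
      for (n in seq_len(M)) {
        hn[[n]] <- matrix(0, H, B)
        for (b in seq_len(B)) {
          sc <- vapply(seq_len(M), function(m)
            sum(pre[[n]][, b] * pre[[m]][, b]) / sqrt(H), numeric(1))
          al <- exp(sc - max(sc)); al <- al / sum(al)
          g <- numeric(H)
          for (m in seq_len(M)) g <- g + al[m] * h[[m]][, b]
          hn[[n]][, b] <- tanh(as.vector(t(p$S[[n]]) %*% g) +
                                 as.vector(p$B %*% xh[[n]][, b]))
        }
      }
      h <- hn
    }
    Y <- matrix(0, ncol(p$E), B)
    for (n in seq_len(M)) Y <- Y + p$W[n] * t(p$E) %*% h[[n]]
    Y / M
  }

  set.seed(33)
  H <- 2L; D <- 2L; B <- 2L; Tn <- 3L; M <- 2L
  p <- ssm_params(M, D, H)
  p$W <- c(0.7, 1.3)
  X <- lapply(1:M, function(n) array(rnorm(D * Tn * B), c(D, Tn, B)))
  out <- ssm_couple_forward(X, p)
  expect_equal(out$Y, ref_forward(X, p), tolerance = 1e-10)
  expect_true(all(abs(unlist(out$h_final)) < 1))

  # single modality, W = 1, E = identity: output is the final hidden state
  p1 <- ssm_params(1, 2, 2)
  p1$E <- diag(2); p1$W <- 1
  X1 <- list(array(rnorm(2 * 3 * 2), c(2, 3, 2)))
  o1 <- ssm_couple_forward(X1, p1)
  expect_equal(o1$Y, o1$h_final[[1]], tolerance = 1e-12)

  # zero fusion weights annihilate the output
  pz <- ssm_params(2, 2, 2); pz$W <- c(0, 0)
  oz <- ssm_couple_forward(lapply(1:2, function(n) array(rnorm(12), c(2, 3, 2))), pz)
  expect_true(all(oz$Y == 0))

  expect_error(ssm_couple_forward(list(array(0, c(2, 3, 1)),
                                       array(0, c(2, 4, 1))), p),
               "time steps")
})

test_that("swapping modalities together with their parameter blocks leaves Y unchanged", {
  set.seed(12)
  p <- ssm_params(2, 3, 4)
  p$W <- c(0.5, 1.5)
  p$gamma <- list(rep(1.2, 3), rep(0.8, 3))
  p$beta <- list(rep(0.1, 3), rep(-0.2, 3))
  X <- lapply(1:2, function(n) array(rnorm(3 * 2 * 2), c(3, 2, 2)))
  y1 <- ssm_couple_forward(X, p)$Y
  ps <- p
  ps$S <- p$S[2:1]; ps$W <- p$W[2:1]
  ps$gamma <- p$gamma[2:1]; ps$beta <- p$beta[2:1]
  y2 <- ssm_couple_forward(X[2:1], ps)$Y
  expect_equal(y1, y2, tolerance = 1e-12)
})

test_that("model forward produces valid, deterministic probability rows", {
  for (v in c("multisess", "mscnn_se", "ssm_only")) {
    cfg <- tiny_model_config(v)
    p <- init_params(cfg, seed = 6)
    set.seed(60)
    x <- tiny_batch(5)
    probs <- model_forward(x, p, cfg)
    expect_equal(dim(probs), c(5L, 5L))
    expect_equal(rowSums(probs), rep(1, 5), tolerance = 1e-6)
    expect_true(all(probs >= 0 & probs <= 1))
    # identical epochs give identical rows; repeated calls are deterministic
    x2 <- x; x2[2, , ] <- x2[1, , ]
    probs2 <- model_forward(x2, p, cfg)
    expect_equal(probs2[1, ], probs2[2, ], tolerance = 1e-12)
    expect_equal(model_forward(x, p, cfg), probs, tolerance = 1e-15)
  }
  cfg <- tiny_model_config()
  expect_error(model_forward(array(0, c(2, 3, 240)), init_params(cfg, 1), cfg),
               "batch of shape")
})

test_that("the full network composes its individually tested blocks", {
  cfg <- tiny_model_config("multisess")
  cfg$dropout <- 0
  p <- init_params(cfg, seed = 14)
  set.seed(15)
  x <- tiny_batch(2)
  probs <- model_forward(x, p, cfg)
  # reference composition from the exported block functions
  x_mod <- multisess:::batch_to_modalities(x, cfg)
  feats <- lapply(1:2, function(m) {
    U <- mscnn_forward(matrix(x[, m, ], nrow = 2), p$mscnn[[m]], cfg$mscnn)
    se_recalibrate(U, se_excite(se_squeeze(U), p$se[[m]]))
  })
  Y <- ssm_couple_forward(feats, p$ssm)$Y
  h1 <- pmax(p$head$W1 %*% Y + p$head$b1, 0)
  logits <- p$head$W2 %*% h1 + p$head$b2
  ref <- t(apply(logits, 2, function(z) exp(z - max(z)) / sum(exp(z - max(z)))))
  expect_equal(probs, ref, tolerance = 1e-10)
})

test_that("analytic gradients agree with finite differences on all variants", {
  for (v in c("multisess", "mscnn_se", "ssm_only")) {
    cfg <- tiny_model_config(v)
    p <- init_params(cfg, seed = 3)
    set.seed(44)
    x <- tiny_batch(4)
    x_mod <- multisess:::batch_to_modalities(x, cfg)
    y <- c(0L, 2L, 4L, 1L)
    w <- class_weights(c(3, 1, 4, 2, 2))
    set.seed(45)
    gc <- gradient_check(x_mod, y, p, cfg, w, n_checked = 250L)
    expect_lt(gc$max_rel_err, 1e-4)
  }
})

test_that("generic convolution and pooling backward passes match finite differences", {
  set.seed(71)
  x <- array(rnorm(2 * 30 * 2), c(2, 30, 2))
  w <- array(rnorm(2 * 5 * 3) * 0.3, c(2, 5, 3))
  b <- rnorm(3)
  stride <- 2L
  # scalar objective: weighted sum of outputs, fixed random weights
  wt <- array(rnorm(prod(dim(multisess:::conv1d_fwd_cpp(x, w, b, stride)))),
              dim(multisess:::conv1d_fwd_cpp(x, w, b, stride)))
  loss <- function(xx, ww, bb) sum(wt * multisess:::conv1d_fwd_cpp(xx, ww, bb, stride))
  g <- multisess:::conv1d_bwd_cpp(x, w, wt, stride)
  eps <- 1e-6
  for (i in sample(length(x), 10)) {
    xp <- x; xp[i] <- xp[i] + eps; xm <- x; xm[i] <- xm[i] - eps
    expect_equal(g$dx[i], (loss(xp, w, b) - loss(xm, w, b)) / (2 * eps),
                 tolerance = 1e-6)
  }
  for (i in sample(length(w), 10)) {
    wp <- w; wp[i] <- wp[i] + eps; wm <- w; wm[i] <- wm[i] - eps
    expect_equal(g$dw[i], (loss(x, wp, b) - loss(x, wm, b)) / (2 * eps),
                 tolerance = 1e-6)
  }
  expect_equal(as.vector(g$db), vapply(1:3, function(o) {
    bp <- b; bp[o] <- bp[o] + eps; bm <- b; bm[o] <- bm[o] - eps
    (loss(x, w, bp) - loss(x, w, bm)) / (2 * eps)
  }, numeric(1)), tolerance = 1e-6)

  # segment pooling: scatter returns each gradient to the argmax position
  starts <- c(1L, 11L, 21L); ends <- c(10L, 20L, 30L)
  pf <- multisess:::segment_pool_fwd_cpp(x, starts, ends)
  dy <- array(rnorm(2 * 3 * 2), c(2, 3, 2))
  dx <- multisess:::segment_pool_bwd_cpp(dy, pf$idx, 30L)
  for (i in sample(length(x), 12)) {
    xp <- x; xp[i] <- xp[i] + eps; xm <- x; xm[i] <- xm[i] - eps
    num <- (sum(dy * multisess:::segment_pool_fwd_cpp(xp, starts, ends)$y) -
              sum(dy * multisess:::segment_pool_fwd_cpp(xm, starts, ends)$y)) / (2 * eps)
    expect_equal(dx[i], num, tolerance = 1e-6)
  }
})
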