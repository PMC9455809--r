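test_that("the published architecture has the stated shapes", {
  clf <- build_rhythm_cnn(c("NSR", "AF", "Other", "Noise"))
  expect_equal(clf$input_len, 21600)       # 60 s at 360 Hz
  expect_equal(clf$n_conv, 7)
  # first ConvUnit: 128 kernels of width 3 over 1 channel
  expect_equal(dim(clf$params$conv[[1]]$W), c(3, 128))
  expect_equal(dim(clf$params$conv[[2]]$W), c(3 * 128, 128))
  # 3 fully connected layers at widths 256/64/|labels|
  expect_length(clf$params$fc, 3)
  expect_equal(ncol(clf$params$fc[[1]]$W), 256)
  expect_equal(ncol(clf$params$fc[[2]]$W), 64)
  expect_equal(ncol(clf$params$fc[[3]]$W), 4)
})

test_that("an untrained network outputs per-label sigmoids in (0,1)", {
  clf <- build_rhythm_cnn(c("A", "B", "C"), segment_length_s = 4,
                          input_fs = 32, n_filters = 6, n_conv = 3,
                          fc = c(8, 4), seed = 2)
  x <- matrix(rnorm(2 * clf$input_len), 2)
  p <- predict_rhythm_cnn(clf, x)
  expect_equal(dim(p), c(2, 3))
  expect_true(all(p > 0 & p < 1))
  expect_identical(colnames(p), c("A", "B", "C"))
})

test_that("analytic gradients match finite differences", {
  clf <- build_rhythm_cnn(c("A", "B"), segment_length_s = 1,
                          input_fs = 32, n_filters = 3, n_conv = 2,
                          fc = c(4), dropout = 0, seed = 2)
  B <- 3
  set.seed(3)
  x <- matrix(rnorm(B * clf$input_len), B)
  tgt <- matrix(c(1, 0, 0, 1, 1, 0), B, 2, byrow = TRUE)

  loss_of <- function(cl) {
    H0 <- NULL
    res <- vector("list", B)
    for (bi in 1:B) {
      masks <- lapply(1:cl$n_conv, function(l) {
        matrix(1, cl$input_len %/% (2L^l), cl$n_filters)
      })
      res[[bi]] <- segbeat:::conv_forward_sample(
        matrix(x[bi, ], ncol = 1), cl, TRUE, masks)
      fl <- as.numeric(res[[bi]]$out)
      if (is.null(H0)) H0 <- matrix(0, B, length(fl))
      H0[bi, ] <- fl
    }
    ff <- segbeat:::fc_forward(H0, cl$params$fc, train = TRUE)
    p <- 1 / (1 + exp(-ff$out))
    list(loss = -sum(tgt * log(p) + (1 - tgt) * log(1 - p)) / (B * 2),
         p = p, ff = ff, res = res)
  }
  r <- loss_of(clf)
  dOut <- (r$p - tgt) / (B * 2)
  fb <- segbeat:::fc_backward(dOut, clf$params$fc, r$ff$caches)
  grads <- segbeat:::zero_grads(clf$params)
  for (bi in 1:B) {
    d0 <- matrix(fb$dH0[bi, ], nrow = nrow(r$res[[bi]]$out),
                 ncol = ncol(r$res[[bi]]$out))
    grads <- segbeat:::conv_backward_sample(d0, clf, r$res[[bi]]$caches,
                                            grads)
  }
  eps <- 1e-6
  # spot-check a handful of coordinates in each parameter group
  check <- function(getter, setter, analytic) {
    vals <- getter(clf)
    idx <- seq_len(min(6, length(vals)))
    for (i in idx) {
      cp <- setter(clf, i, eps); lp <- loss_of(cp)$loss
      cm <- setter(clf, i, -eps); lm <- loss_of(cm)$loss
      num <- (lp - lm) / (2 * eps)
      expect_equal(analytic[i], num, tolerance = 1e-4)
    }
  }
  check(function(c) c$params$conv[[1]]$W,
        function(c, i, e) { c$params$conv[[1]]$W[i] <- c$params$conv[[1]]$W[i] + e; c },
        grads$conv[[1]]$W)
  check(function(c) c$params$fc[[2]]$W,
        function(c, i, e) { c$params$fc[[2]]$W[i] <- c$params$fc[[2]]$W[i] + e; c },
        fb$grads[[2]]$W)
  check(function(c) c$params$fc[[1]]$gamma,
        function(c, i, e) { c$params$fc[[1]]$gamma[i] <- c$params$fc[[1]]$gamma[i] + e; c },
        fb$grads[[1]]$gamma)
})

test_that("training fits a separable two-pattern task", {
  clf <- build_rhythm_cnn(c("A", "B"), segment_length_s = 2,
                          input_fs = 32, n_filters = 8, n_conv = 3,
                          fc = c(16, 8), dropout = 0, seed = 2)
  n <- 40
  set.seed(1)
  pa <- sin(2 * pi * seq_len(clf$input_len) / 8)
  pb <- sin(2 * pi * seq_len(clf$input_len) / 16)
  x <- rbind(t(replicate(n / 2, pa + 0.1 * rnorm(clf$input_len))),
             t(replicate(n / 2, pb + 0.1 * rnorm(clf$input_len))))
  y <- rep(c("A", "B"), each = n / 2)
  fit <- train_rhythm_cnn(clf, x, y, epochs = 20, batch_size = 8, seed = 3)
  p <- predict_rhythm_cnn(fit, x)
  expect_gte(mean(fit$label_set[max.col(p)] == y), 0.95)
  # determinism given identical seeds
  fit2 <- train_rhythm_cnn(clf, x, y, epochs = 20, batch_size = 8, seed = 3)
  expect_equal(predict_rhythm_cnn(fit2, x), p)
})

test_that("a cnn classifier labels record segments end to end", {
  blocks <- data.frame(label = c("NSR", "AFIB_LIKE"),
                       duration_s = c(60, 60))
  g <- generate_ecg(synth_config(seed = 21, rhythm_blocks = blocks,
                                 noise_sd = 0.05), "CN1")
  clf <- build_rhythm_cnn(c("NSR", "AFIB_LIKE"), input_fs = 36,
                          n_filters = 4, fc = c(8, 4), seed = 1)
  lab <- assign_segment_labels(g$record, clf, length_s = 60,
                               overlap = "none")
  expect_equal(nrow(lab$segments), 2)
  expect_true(all(lab$beat$label_id %in% 1:2))
})
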