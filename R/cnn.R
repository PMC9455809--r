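# Trainable 1-D convolutional rhythm classifier, implemented in base
# R matrix code: a stack of ConvUnits (convolution with `n_filters`
# kernels of width 3, ReLU, max-pooling of size 2, dropout 0.5)
# followed by three fully connected layers, each with batch
# normalization, and a per-label sigmoid head (the label set can be
# multi-label, so no softmax). Loss is binary cross-entropy, optimized
# with Adam. Forward/backward passes use im2col so the inner products
# run through BLAS.

#' Build a trainable 1-D CNN segment classifier
#'
#' Defaults follow the published architecture: 7 ConvUnits of 128
#' filters (kernel 3, max-pool 2, dropout 0.5), fully connected widths
#' 256 and 64, sigmoid output per label, 60 s of single-lead ECG at
#' 360 Hz (21600 x 1 input). Smaller instances (fewer filters, lower
#' input rate) train in minutes on a CPU and are used for the scaled
#' demonstrations in this package.
#'
#' @param label_set Ordered rhythm label names.
#' @param segment_length_s Segment length the classifier expects, s.
#' @param input_fs Input rate, Hz.
#' @param n_filters Filters per convolutional layer.
#' @param n_conv Number of ConvUnits.
#' @param kernel Convolution kernel width.
#' @param fc FC layer widths before the output layer.
#' @param dropout Dropout rate inside each ConvUnit.
#' @param seed Seed for weight initialization.
#' @return A `segment_classifier` of subclass `cnn_segment_classifier`.
#' @export
build_rhythm_cnn <- function(label_set, segment_length_s = 60,
                             input_fs = 360, n_filters = 128,
                             n_conv = 7, kernel = 3, fc = c(256, 64),
                             dropout = 0.5, seed = 1L) {
  input_len <- as.integer(round(segment_length_s * input_fs))
  n_out <- length(label_set)
  params <- with_local_rng(as.integer(seed), {
    conv <- list()
    c_in <- 1L
    len <- input_len
    for (l in seq_len(n_conv)) {
      fan_in <- kernel * c_in
      conv[[l]] <- list(
        W = matrix(stats::rnorm(fan_in * n_filters, 0,
                                sqrt(2 / fan_in)), fan_in, n_filters),
        b = numeric(n_filters))
      c_in <- n_filters
      len <- len %/% 2L
    }
    flat <- len * n_filters
    dims <- c(flat, fc, n_out)
    fcl <- lapply(seq_len(length(dims) - 1), function(l) {
      list(W = matrix(stats::rnorm(dims[l] * dims[l + 1], 0,
                                   sqrt(2 / dims[l])),
                      dims[l], dims[l + 1]),
           b = numeric(dims[l + 1]),
           gamma = rep(1, dims[l + 1]), beta = numeric(dims[l + 1]),
           run_mean = numeric(dims[l + 1]),
           run_var = rep(1, dims[l + 1]))
    })
    list(conv = conv, fc = fcl)
  })
  structure(list(label_set = label_set,
                 segment_length_s = segment_length_s,
                 input_fs = input_fs, input_len = input_len,
                 n_filters = n_filters, n_conv = n_conv, kernel = kernel,
                 dropout = dropout, params = params, trained = FALSE,
                 seed = as.integer(seed)),
            class = c("cnn_segment_classifier", "segment_classifier"))
}

im2col <- function(x_mat, kernel) {
  # x_mat: L x C; returns L x (kernel*C) with 'same' zero padding
  L <- nrow(x_mat); C <- ncol(x_mat)
  half <- (kernel - 1L) %/% 2L
  xp <- rbind(matrix(0, half, C), x_mat, matrix(0, kernel - 1L - half, C))
  do.call(cbind, lapply(seq_len(kernel), function(k) {
    xp[k:(k + L - 1L), , drop = FALSE]
  }))
}

col2im_grad <- function(d_xc, kernel, L, C) {
  half <- (kernel - 1L) %/% 2L
  dxp <- matrix(0, L + kernel - 1L, C)
  for (k in seq_len(kernel)) {
    cols <- ((k - 1L) * C + 1L):(k * C)
    dxp[k:(k + L - 1L), ] <- dxp[k:(k + L - 1L), ] +
      d_xc[, cols, drop = FALSE]
  }
  dxp[(half + 1L):(half + L), , drop = FALSE]
}

conv_forward_sample <- function(x_mat, clf, train, masks = NULL) {
  caches <- vector("list", clf$n_conv)
  h <- x_mat
  for (l in seq_len(clf$n_conv)) {
    p <- clf$params$conv[[l]]
    xc <- im2col(h, clf$kernel)
    z <- sweep(xc %*% p$W, 2, p$b, `+`)
    a <- pmax(z, 0)
    L2 <- nrow(a) %/% 2L
    i1 <- 2L * seq_len(L2) - 1L
    take_first <- a[i1, , drop = FALSE] >= a[i1 + 1L, , drop = FALSE]
    pooled <- ifelse(take_first, a[i1, , drop = FALSE],
                     a[i1 + 1L, , drop = FALSE])
    if (train) {
      mask <- masks[[l]]
      pooled <- pooled * mask
    } else {
      mask <- NULL
    }
    caches[[l]] <- list(xc = xc, relu = z > 0, take_first = take_first,
                        L = nrow(z), mask = mask)
    h <- pooled
  }
  list(out = h, caches = caches)
}

conv_backward_sample <- function(d_out, clf, caches, grads) {
  d <- d_out
  for (l in rev(seq_len(clf$n_conv))) {
    cc <- caches[[l]]
    if (!is.null(cc$mask)) d <- d * cc$mask
    L2 <- nrow(d)
    da <- matrix(0, cc$L, ncol(d))
    i1 <- 2L * seq_len(L2) - 1L
    # route pooled gradient back to the argmax positions
    for (ch in seq_len(ncol(d))) {
      rows <- ifelse(cc$take_first[, ch], i1, i1 + 1L)
      da[rows, ch] <- d[, ch]
    }
    dz <- da * cc$relu
    p <- clf$params$conv[[l]]
    grads$conv[[l]]$W <- grads$conv[[l]]$W + crossprod(cc$xc, dz)
    grads$conv[[l]]$b <- grads$conv[[l]]$b + colSums(dz)
    if (l > 1L) {
      d_xc <- dz %*% t(p$W)
      c_in <- as.integer(nrow(p$W) / clf$kernel)
      d <- col2im_grad(d_xc, clf$kernel, cc$L, c_in)
    }
  }
  grads
}

fc_forward <- function(H, fcl, train, momentum = 0.9, eps = 1e-5) {
  caches <- vector("list", length(fcl))
  n_fc <- length(fcl)
  for (l in seq_len(n_fc)) {
    p <- fcl[[l]]
    z <- sweep(H %*% p$W, 2, p$b, `+`)
    if (train) {
      mu <- colMeans(z)
      v <- colMeans(sweep(z, 2, mu)^2)
      fcl[[l]]$run_mean <- momentum * p$run_mean + (1 - momentum) * mu
      fcl[[l]]$run_var <- momentum * p$run_var + (1 - momentum) * v
    } else {
      mu <- p$run_mean
      v <- p$run_var
    }
    xhat <- sweep(sweep(z, 2, mu), 2, sqrt(v + eps), `/`)
    y <- sweep(sweep(xhat, 2, p$gamma, `*`), 2, p$beta, `+`)
    a <- if (l < n_fc) pmax(y, 0) else y
    caches[[l]] <- list(H = H, xhat = xhat, v = v, y = y, a = a)
    H <- a
  }
  list(out = H, caches = caches, fcl = fcl)
}

fc_backward <- function(dA, fcl, caches, eps = 1e-5) {
  n_fc <- length(fcl)
  grads <- vector("list", n_fc)
  for (l in rev(seq_len(n_fc))) {
    cc <- caches[[l]]
    p <- fcl[[l]]
    dY <- if (l < n_fc) dA * (cc$y > 0) else dA
    dgamma <- colSums(dY * cc$xhat)
    dbeta <- colSums(dY)
    B <- nrow(dY)
    inv_sd <- 1 / sqrt(cc$v + eps)
    dXhat <- sweep(dY, 2, p$gamma, `*`)
    dZ <- sweep(dXhat - matrix(colMeans(dXhat), B, ncol(dY), byrow = TRUE) -
                  cc$xhat * matrix(colMeans(dXhat * cc$xhat), B,
                                   ncol(dY), byrow = TRUE),
                2, inv_sd, `*`)
    grads[[l]] <- list(W = crossprod(cc$H, dZ), b = colSums(dZ),
                       gamma = dgamma, beta = dbeta)
    dA <- dZ %*% t(p$W)
  }
  list(grads = grads, dH0 = dA)
}

zero_grads <- function(params) {
  list(conv = lapply(params$conv, function(p) {
    list(W = p$W * 0, b = p$b * 0)
  }))
}

adam_init <- function(params) {
  rapply(params, function(x) x * 0, how = "replace")
}

adam_update <- function(x, g, m, v, lr, t, b1 = 0.9, b2 = 0.999,
                        eps = 1e-8) {
  m <- b1 * m + (1 - b1) * g
  v <- b2 * v + (1 - b2) * g^2
  mh <- m / (1 - b1^t)
  vh <- v / (1 - b2^t)
  list(x = x - lr * mh / (sqrt(vh) + eps), m = m, v = v)
}

#' Train a CNN segment classifier
#'
#' Mini-batch Adam on binary cross-entropy; targets are the one-hot
#' (or multi-hot) encoding of the segment labels over the classifier's
#' label set.
#'
#' @param clf A [build_rhythm_cnn()] classifier.
#' @param x Matrix of preprocessed segments (rows = segments, columns
#'   = `clf$input_len` samples), e.g. from [preprocess_segment()].
#' @param labels Character vector (single label per segment) or 0/1
#'   matrix with `length(clf$label_set)` columns.
#' @param epochs Training epochs.
#' @param batch_size Mini-batch size.
#' @param lr Adam learning rate.
#' @param seed Seed for shuffling and dropout.
#' @param verbose Print the per-epoch loss.
#' @return The trained classifier.
#' @export
train_rhythm_cnn <- function(clf, x, labels, epochs = 30, batch_size = 16,
                             lr = 0.001, seed = 1L, verbose = FALSE) {
  stopifnot(inherits(clf, "cnn_segment_classifier"),
            ncol(x) == clf$input_len)
  targets <- if (is.matrix(labels)) labels else {
    tm <- matrix(0, nrow(x), length(clf$label_set))
    tm[cbind(seq_len(nrow(x)), match(labels, clf$label_set))] <- 1
    tm
  }
  n <- nrow(x)
  mstate <- adam_init(clf$params)
  vstate <- adam_init(clf$params)
  step <- 0L
  with_local_rng(as.integer(seed), {
    for (ep in seq_len(epochs)) {
      ord <- sample.int(n)
      ep_loss <- 0
      for (start in seq(1, n, by = batch_size)) {
        idx <- ord[start:min(start + batch_size - 1L, n)]
        B <- length(idx)
        conv_res <- vector("list", B)
        H0 <- NULL
        for (bi in seq_len(B)) {
          xm <- matrix(x[idx[bi], ], ncol = 1)
          msk <- lapply(seq_len(clf$n_conv), function(l) {
            lenl <- clf$input_len %/% (2L^l)
            matrix(stats::rbinom(lenl * clf$n_filters, 1,
                                 1 - clf$dropout) / (1 - clf$dropout),
                   lenl, clf$n_filters)
          })
          conv_res[[bi]] <- conv_forward_sample(xm, clf, TRUE, msk)
          flat <- as.numeric(conv_res[[bi]]$out)
          if (is.null(H0)) H0 <- matrix(0, B, length(flat))
          H0[bi, ] <- flat
        }
        ff <- fc_forward(H0, clf$params$fc, train = TRUE)
        clf$params$fc <- ff$fcl
        p <- 1 / (1 + exp(-ff$out))
        tgt <- targets[idx, , drop = FALSE]
        eps_p <- 1e-12
        ep_loss <- ep_loss - sum(tgt * log(p + eps_p) +
                                   (1 - tgt) * log(1 - p + eps_p))
        dOut <- (p - tgt) / (B * ncol(p))
        fb <- fc_backward(dOut, clf$params$fc, ff$caches)
        grads <- zero_grads(clf$params)
        for (bi in seq_len(B)) {
          d0 <- matrix(fb$dH0[bi, ],
                       nrow = nrow(conv_res[[bi]]$out),
                       ncol = ncol(conv_res[[bi]]$out))
          grads <- conv_backward_sample(d0, clf, conv_res[[bi]]$caches,
                                        grads)
        }
        # Adam step
        step <- step + 1L
        for (l in seq_len(clf$n_conv)) {
          for (nm in c("W", "b")) {
            g <- grads$conv[[l]][[nm]] / 1  # summed over batch, matches dOut scale
            u <- adam_update(clf$params$conv[[l]][[nm]], g,
                             mstate$conv[[l]][[nm]], vstate$conv[[l]][[nm]],
                             lr, step)
            clf$params$conv[[l]][[nm]] <- u$x
            mstate$conv[[l]][[nm]] <- u$m
            vstate$conv[[l]][[nm]] <- u$v
          }
        }
        for (l in seq_along(clf$params$fc)) {
          for (nm in c("W", "b", "gamma", "beta")) {
            u <- adam_update(clf$params$fc[[l]][[nm]], fb$grads[[l]][[nm]],
                             mstate$fc[[l]][[nm]], vstate$fc[[l]][[nm]],
                             lr, step)
            clf$params$fc[[l]][[nm]] <- u$x
            mstate$fc[[l]][[nm]] <- u$m
            vstate$fc[[l]][[nm]] <- u$v
          }
        }
      }
      if (verbose) {
        message(sprintf("epoch %d: bce %.4f", ep, ep_loss / n))
      }
    }
  })
  clf <- calibrate_bn_stats(clf, x)
  clf$trained <- TRUE
  clf
}

# replace the exponentially-averaged batch-norm statistics with exact
# population statistics over the training set (deterministic inference)
calibrate_bn_stats <- function(clf, x) {
  H <- NULL
  for (bi in seq_len(nrow(x))) {
    cr <- conv_forward_sample(matrix(x[bi, ], ncol = 1), clf, FALSE)
    flat <- as.numeric(cr$out)
    if (is.null(H)) H <- matrix(0, nrow(x), length(flat))
    H[bi, ] <- flat
  }
  eps <- 1e-5
  n_fc <- length(clf$params$fc)
  for (l in seq_len(n_fc)) {
    p <- clf$params$fc[[l]]
    z <- sweep(H %*% p$W, 2, p$b, `+`)
    mu <- colMeans(z)
    v <- colMeans(sweep(z, 2, mu)^2)
    clf$params$fc[[l]]$run_mean <- mu
    clf$params$fc[[l]]$run_var <- v
    xhat <- sweep(sweep(z, 2, mu), 2, sqrt(v + eps), `/`)
    y <- sweep(sweep(xhat, 2, p$gamma, `*`), 2, p$beta, `+`)
    H <- if (l < n_fc) pmax(y, 0) else y
  }
  clf
}

#' Predict label probabilities for preprocessed segments
#'
#' @param clf A `cnn_segment_classifier`.
#' @param x Matrix of preprocessed segments (rows = segments).
#' @return Matrix (segments x labels) of sigmoid probabilities in
#'   (0, 1).
#' @export
predict_rhythm_cnn <- function(clf, x) {
  stopifnot(inherits(clf, "cnn_segment_classifier"),
            ncol(x) == clf$input_len)
  out <- matrix(0, nrow(x), length(clf$label_set),
                dimnames = list(NULL, clf$label_set))
  H0 <- NULL
  for (bi in seq_len(nrow(x))) {
    cr <- conv_forward_sample(matrix(x[bi, ], ncol = 1), clf, FALSE)
    flat <- as.numeric(cr$out)
    if (is.null(H0)) H0 <- matrix(0, nrow(x), length(flat))
    H0[bi, ] <- flat
  }
  ff <- fc_forward(H0, clf$params$fc, train = FALSE)
  1 / (1 + exp(-ff$out)) -> p
  dimnames(p) <- list(NULL, clf$label_set)
  p
}

#' @export
predict_segments.cnn_segment_classifier <- function(clf, rec, bounds) {
  lead <- attr(clf, "lead") %||% 1L
  y <- remove_baseline(rec$signal[, lead], rec$fs)
  scale <- max(abs(y))
  segs <- t(vapply(seq_len(nrow(bounds)), function(i) {
    preprocess_segment(
      rec$signal[bounds$start_sample[i]:bounds$end_sample[i], lead],
      rec$fs, out_fs = clf$input_fs, out_len = clf$input_len,
      scale = scale)
  }, numeric(clf$input_len)))
  predict_rhythm_cnn(clf, segs)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Build a preprocessed segment training set from records
#'
#' Segments each record (no overlap), preprocesses every segment for
#' the classifier, and labels it with the rhythm block covering the
#' majority of the segment.
#'
#' @param dataset Named list of `list(record, truth)` entries from
#'   [generate_dataset()].
#' @param clf The target classifier (fixes input rate and length).
#' @param length_s Segment length in seconds.
#' @return List with `x` (matrix segments x input_len) and `labels`
#'   (character).
#' @export
cnn_training_segments <- function(dataset, clf,
                                  length_s = clf$segment_length_s) {
  xs <- list(); labs <- character(0)
  for (entry in dataset) {
    rec <- entry$record
    bounds <- segment_record(rec, length_s, "none")
    orc <- oracle_classifier(entry$truth, label_set = clf$label_set)
    probs <- predict_segments(orc, rec, bounds)
    lab <- clf$label_set[max.col(probs, ties.method = "first")]
    y <- remove_baseline(rec$signal[, 1], rec$fs)
    scale <- max(abs(y))
    for (i in seq_len(nrow(bounds))) {
      xs[[length(xs) + 1]] <- preprocess_segment(
        rec$signal[bounds$start_sample[i]:bounds$end_sample[i], 1],
        rec$fs, out_fs = clf$input_fs, out_len = clf$input_len,
        scale = scale)
      labs <- c(labs, lab[i])
    }
  }
  list(x = do.call(rbind, xs), labels = labs)
}
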