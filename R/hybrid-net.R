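#' Configuration of the hybrid dense + convolutional classifier
#'
#' Architecture operating on an n x n inter-ROI distance matrix per subject:
#' a flat branch sends the flattened matrix (n^2 values) through one linear
#' layer to 256 features; a convolutional branch applies three 3x3 "same"
#' convolutions with 16, 32 and 64 filters, one 2x2 max-pool, two further
#' convolutions with 128 and 256 filters, then global average pooling to
#' 256 features (ReLU throughout). The concatenated 512-vector passes dense
#' layers of 128, 64 and 32 units (ReLU, dropout 0.2 each) into a 2-way
#' softmax trained with cross-entropy.
#'
#' @param conv_filters_block1,conv_filters_block2 Filter counts of the two
#'   convolutional blocks.
#' @param kernel_size Convolution kernel size (square).
#' @param pool_size Max-pool window between the blocks.
#' @param flat_branch_width Output width of the flat branch.
#' @param dense_widths Widths of the shared dense head.
#' @param dropout Dropout rate of the dense head, in [0, 1).
#' @param early_stopping_patience Epochs without validation improvement
#'   before stopping.
#' @param max_epochs Training epoch cap.
#' @param lr Default learning rate when no search is run.
#' @param batch_size Default batch size when no search is run.
#' @param val_fraction Subject fraction held out of training for early
#'   stopping.
#' @param optimizer `"adam"` or `"sgd"` default when no search is run.
#' @param lr_range,batch_choices,split_choices,optimizer_choices,n_trials
#'   Random-search space: learning-rate range (log-uniform), batch sizes,
#'   held-out test fractions, optimizers, and the number of trials.
#' @param seed Integer seed.
#' @return List of class `hybrid_net_config`.
#' @export
hybrid_net_config <- function(conv_filters_block1 = c(16, 32, 64),
                              conv_filters_block2 = c(128, 256),
                              kernel_size = 3,
                              pool_size = 2,
                              flat_branch_width = 256,
                              dense_widths = c(128, 64, 32),
                              dropout = 0.2,
                              early_stopping_patience = 10,
                              max_epochs = 100,
                              lr = 1e-3,
                              batch_size = 16,
                              val_fraction = 0.2,
                              optimizer = "adam",
                              lr_range = c(1e-4, 1e-1),
                              batch_choices = c(4, 8, 16, 32),
                              split_choices = c(0.2, 0.25, 0.3),
                              optimizer_choices = c("sgd", "adam"),
                              n_trials = 20,
                              seed = 1) {
  stopifnot(all(conv_filters_block1 > 0), all(conv_filters_block2 > 0),
            kernel_size >= 1, all(dense_widths > 0),
            dropout >= 0, dropout < 1, lr > 0)
  structure(list(conv_filters_block1 = as.integer(conv_filters_block1),
                 conv_filters_block2 = as.integer(conv_filters_block2),
                 kernel_size = as.integer(kernel_size),
                 pool_size = as.integer(pool_size),
                 flat_branch_width = as.integer(flat_branch_width),
                 dense_widths = as.integer(dense_widths),
                 dropout = dropout,
                 early_stopping_patience = as.integer(early_stopping_patience),
                 max_epochs = as.integer(max_epochs),
                 lr = lr, batch_size = as.integer(batch_size),
                 val_fraction = val_fraction,
                 optimizer = match.arg(optimizer, c("adam", "sgd")),
                 lr_range = lr_range, batch_choices = as.integer(batch_choices),
                 split_choices = split_choices,
                 optimizer_choices = optimizer_choices,
                 n_trials = as.integer(n_trials),
                 seed = as.integer(seed)),
            class = "hybrid_net_config")
}

# ---- minimal tensor layers (arrays are H x W x C x B) --------------------

conv_im2col <- function(xp, H, W, C, B, k) {
  # xp: zero-padded array (H+k-1) x (W+k-1) x C x B (pad (k-1)/2 each side)
  cols <- matrix(0, H * W * B, k * k * C)
  col <- 1L
  for (dx in seq_len(k)) for (dy in seq_len(k)) {
    block <- xp[dy:(dy + H - 1), dx:(dx + W - 1), , , drop = FALSE]
    # rows ordered (h, w, b); channels as columns
    cols[, col:(col + C - 1)] <- matrix(aperm(block, c(1, 2, 4, 3)), H * W * B, C)
    col <- col + C
  }
  cols
}

conv_forward <- function(x, w, b, k) {
  d <- dim(x); H <- d[1]; W <- d[2]; C <- d[3]; B <- d[4]
  p <- (k - 1L) %/% 2L
  xp <- array(0, c(H + 2 * p, W + 2 * p, C, B))
  xp[p + seq_len(H), p + seq_len(W), , ] <- x
  cols <- conv_im2col(xp, H, W, C, B, k)
  out <- sweep(cols %*% w, 2, b, "+")            # (H*W*B) x F
  f <- length(b)
  y <- aperm(array(out, c(H, W, B, f)), c(1, 2, 4, 3))
  list(y = y, cols = cols, dims = c(H, W, C, B))
}

conv_backward <- function(dy, w, cache, k) {
  H <- cache$dims[1]; W <- cache$dims[2]; C <- cache$dims[3]; B <- cache$dims[4]
  f <- ncol(w)
  dmat <- matrix(aperm(dy, c(1, 2, 4, 3)), H * W * B, f)
  dw <- crossprod(cache$cols, dmat)
  db <- colSums(dmat)
  dcols <- tcrossprod(dmat, w)                   # (H*W*B) x (k*k*C)
  p <- (k - 1L) %/% 2L
  dxp <- array(0, c(H + 2 * p, W + 2 * p, C, B))
  col <- 1L
  for (dx in seq_len(k)) for (dy_ in seq_len(k)) {
    blk <- aperm(array(dcols[, col:(col + C - 1)], c(H, W, B, C)), c(1, 2, 4, 3))
    dxp[dy_:(dy_ + H - 1), dx:(dx + W - 1), , ] <-
      dxp[dy_:(dy_ + H - 1), dx:(dx + W - 1), , , drop = FALSE] + blk
    col <- col + C
  }
  dx <- dxp[p + seq_len(H), p + seq_len(W), , , drop = FALSE]
  list(dx = dx, dw = dw, db = db)
}

maxpool_forward <- function(x, pool) {
  d <- dim(x); H <- d[1]; W <- d[2]
  Ho <- H %/% pool; Wo <- W %/% pool
  slices <- vector("list", pool * pool)
  s <- 1L
  for (dx in seq_len(pool)) for (dy in seq_len(pool)) {
    slices[[s]] <- x[seq(dy, by = pool, length.out = Ho),
                     seq(dx, by = pool, length.out = Wo), , , drop = FALSE]
    s <- s + 1L
  }
  y <- slices[[1]]; which_max <- array(1L, dim(y))
  for (s in 2:(pool * pool)) {
    gt <- slices[[s]] > y
    y[gt] <- slices[[s]][gt]
    which_max[gt] <- s
  }
  list(y = y, which_max = which_max, in_dim = d)
}

maxpool_backward <- function(dy, cache, pool) {
  dx <- array(0, cache$in_dim)
  Ho <- dim(dy)[1]; Wo <- dim(dy)[2]
  s <- 1L
  for (dx_off in seq_len(pool)) for (dy_off in seq_len(pool)) {
    mask <- cache$which_max == s
    blk <- array(0, dim(dy)); blk[mask] <- dy[mask]
    dx[seq(dy_off, by = pool, length.out = Ho),
       seq(dx_off, by = pool, length.out = Wo), , ] <-
      dx[seq(dy_off, by = pool, length.out = Ho),
         seq(dx_off, by = pool, length.out = Wo), , , drop = FALSE] + blk
    s <- s + 1L
  }
  dx
}

# ---- network assembly -----------------------------------------------------

init_dense <- function(n_in, n_out, rng_sd = sqrt(2 / n_in)) {
  list(w = matrix(rnorm(n_in * n_out, sd = rng_sd), n_in, n_out),
       b = rep(0, n_out))
}

init_conv <- function(k, c_in, c_out) {
  fan_in <- k * k * c_in
  list(w = matrix(rnorm(fan_in * c_out, sd = sqrt(2 / fan_in)), fan_in, c_out),
       b = rep(0, c_out))
}

init_hybrid_net <- function(n, config) {
  cf <- c(config$conv_filters_block1, config$conv_filters_block2)
  chans <- c(1L, cf)
  convs <- lapply(seq_along(cf), function(i)
    init_conv(config$kernel_size, chans[i], chans[i + 1]))
  head_in <- config$flat_branch_width + cf[length(cf)]
  widths <- c(head_in, config$dense_widths, 2L)
  dense <- lapply(seq_len(length(widths) - 1), function(i)
    init_dense(widths[i], widths[i + 1]))
  list(n = n, config = config,
       flat = init_dense(n * n, config$flat_branch_width),
       convs = convs, dense = dense)
}

#' Parameter count of the hybrid network
#'
#' Closed-form count implied by the layer specification, used to guard the
#' architecture against drift.
#'
#' @param n Side length of the input matrix.
#' @param config A [hybrid_net_config()].
#' @return Integer number of trainable parameters.
#' @export
hybrid_net_param_count <- function(n, config = hybrid_net_config()) {
  k <- config$kernel_size
  cf <- c(config$conv_filters_block1, config$conv_filters_block2)
  chans <- c(1L, cf)
  conv_p <- sum((k * k * chans[-length(chans)] + 1) * cf)
  flat_p <- (n * n + 1) * config$flat_branch_width
  widths <- c(config$flat_branch_width + cf[length(cf)],
              config$dense_widths, 2L)
  dense_p <- sum((widths[-length(widths)] + 1) * widths[-1])
  as.integer(conv_p + flat_p + dense_p)
}

count_net_params <- function(net) {
  layers <- c(list(net$flat), net$convs, net$dense)
  sum(vapply(layers, function(l) length(l$w) + length(l$b), numeric(1)))
}

relu <- function(x) { x[x < 0] <- 0; x }

hybrid_forward <- function(net, xb, training = FALSE, dropout_masks = NULL) {
  # xb: array H x W x 1 x B
  cfg <- net$config
  B <- dim(xb)[4]; n <- net$n
  caches <- list()

  flat_in <- t(matrix(xb, n * n, B))             # B x n^2
  z_flat <- sweep(flat_in %*% net$flat$w, 2, net$flat$b, "+")
  a_flat <- relu(z_flat)
  caches$flat <- list(x = flat_in, z = z_flat)

  a <- xb
  nb1 <- length(cfg$conv_filters_block1)
  conv_caches <- vector("list", length(net$convs))
  pool_cache <- NULL
  for (i in seq_along(net$convs)) {
    cv <- conv_forward(a, net$convs[[i]]$w, net$convs[[i]]$b, cfg$kernel_size)
    z <- cv$y
    a <- relu(z)
    conv_caches[[i]] <- list(cols = cv$cols, dims = cv$dims, z = z)
    if (i == nb1) {
      pc <- maxpool_forward(a, cfg$pool_size)
      a <- pc$y
      pool_cache <- pc
    }
  }
  gap_d <- dim(a)                                # H' x W' x F x B
  a_gap <- t(apply(a, c(3, 4), mean))            # B x F
  caches$convs <- conv_caches; caches$pool <- pool_cache; caches$gap_dim <- gap_d

  h <- cbind(a_flat, a_gap)                      # B x (256 + F)
  dense_caches <- vector("list", length(net$dense))
  masks <- vector("list", length(net$dense) - 1L)
  for (i in seq_along(net$dense)) {
    z <- sweep(h %*% net$dense[[i]]$w, 2, net$dense[[i]]$b, "+")
    if (i < length(net$dense)) {
      aa <- relu(z)
      if (training && cfg$dropout > 0) {
        mask <- if (!is.null(dropout_masks)) dropout_masks[[i]]
                else matrix(stats::rbinom(length(aa), 1, 1 - cfg$dropout),
                            nrow(aa)) / (1 - cfg$dropout)
        aa <- aa * mask
        masks[[i]] <- mask
      }
      dense_caches[[i]] <- list(x = h, z = z)
      h <- aa
    } else {
      dense_caches[[i]] <- list(x = h, z = z)
      h <- z
    }
  }
  # softmax
  zmax <- apply(h, 1, max)
  ez <- exp(h - zmax)
  probs <- ez / rowSums(ez)
  caches$dense <- dense_caches; caches$masks <- masks
  caches$concat_split <- ncol(a_flat)
  list(probs = probs, caches = caches)
}

hybrid_backward <- function(net, xb, y_onehot, fwd) {
  cfg <- net$config
  B <- dim(xb)[4]; n <- net$n
  grads <- list(flat = NULL, convs = vector("list", length(net$convs)),
                dense = vector("list", length(net$dense)))
  dh <- (fwd$probs - y_onehot) / B               # B x 2

  for (i in rev(seq_along(net$dense))) {
    cache <- fwd$caches$dense[[i]]
    if (i < length(net$dense)) {
      mask <- fwd$caches$masks[[i]]
      if (!is.null(mask)) dh <- dh * mask
      dh <- dh * (cache$z > 0)
    }
    grads$dense[[i]] <- list(dw = crossprod(cache$x, dh), db = colSums(dh))
    dh <- tcrossprod(dh, net$dense[[i]]$w)
  }
  split <- fwd$caches$concat_split
  d_flat <- dh[, seq_len(split), drop = FALSE]
  d_gap <- dh[, -seq_len(split), drop = FALSE]   # B x F

  # flat branch
  fc <- fwd$caches$flat
  d_flat <- d_flat * (fc$z > 0)
  grads$flat <- list(dw = crossprod(fc$x, d_flat), db = colSums(d_flat))

  # conv branch: un-GAP
  gd <- fwd$caches$gap_dim                       # H' W' F B
  scale <- 1 / (gd[1] * gd[2])
  da <- array(0, gd)
  for (bb in seq_len(B))
    da[, , , bb] <- rep(d_gap[bb, ] * scale, each = gd[1] * gd[2])

  nb1 <- length(cfg$conv_filters_block1)
  for (i in rev(seq_along(net$convs))) {
    if (i == nb1) da <- maxpool_backward(da, fwd$caches$pool, cfg$pool_size)
    cache <- fwd$caches$convs[[i]]
    da <- da * (cache$z > 0)
    bk <- conv_backward(da, net$convs[[i]]$w, cache, cfg$kernel_size)
    grads$convs[[i]] <- list(dw = bk$dw, db = bk$db)
    da <- bk$dx
  }
  grads
}

make_optimizer <- function(net, kind, lr) {
  state <- NULL
  if (kind == "adam") {
    zero_like <- function(l) list(mw = l$w * 0, vw = l$w * 0,
                                  mb = l$b * 0, vb = l$b * 0)
    state <- list(flat = zero_like(net$flat),
                  convs = lapply(net$convs, zero_like),
                  dense = lapply(net$dense, zero_like), t = 0)
  }
  list(kind = kind, lr = lr, state = state,
       beta1 = 0.9, beta2 = 0.999, eps = 1e-8)
}

apply_update <- function(layer, grad, opt, st) {
  if (opt$kind == "sgd") {
    layer$w <- layer$w - opt$lr * grad$dw
    layer$b <- layer$b - opt$lr * grad$db
    list(layer = layer, st = st)
  } else {
    st$mw <- opt$beta1 * st$mw + (1 - opt$beta1) * grad$dw
    st$vw <- opt$beta2 * st$vw + (1 - opt$beta2) * grad$dw^2
    st$mb <- opt$beta1 * st$mb + (1 - opt$beta1) * grad$db
    st$vb <- opt$beta2 * st$vb + (1 - opt$beta2) * grad$db^2
    c1 <- 1 - opt$beta1^opt$state$t; c2 <- 1 - opt$beta2^opt$state$t
    layer$w <- layer$w - opt$lr * (st$mw / c1) / (sqrt(st$vw / c2) + opt$eps)
    layer$b <- layer$b - opt$lr * (st$mb / c1) / (sqrt(st$vb / c2) + opt$eps)
    list(layer = layer, st = st)
  }
}

sgd_adam_step <- function(net, grads, opt) {
  if (opt$kind == "adam") opt$state$t <- opt$state$t + 1
  up <- apply_update(net$flat, grads$flat, opt, opt$state$flat)
  net$flat <- up$layer; opt$state$flat <- up$st
  for (i in seq_along(net$convs)) {
    up <- apply_update(net$convs[[i]], grads$convs[[i]], opt,
                       opt$state$convs[[i]])
    net$convs[[i]] <- up$layer; opt$state$convs[[i]] <- up$st
  }
  for (i in seq_along(net$dense)) {
    up <- apply_update(net$dense[[i]], grads$dense[[i]], opt,
                       opt$state$dense[[i]])
    net$dense[[i]] <- up$layer; opt$state$dense[[i]] <- up$st
  }
  list(net = net, opt = opt)
}

cross_entropy <- function(probs, y_onehot) {
  -mean(log(pmax(rowSums(probs * y_onehot), 1e-12)))
}

stack_matrices <- function(matrices) {
  n <- nrow(matrices[[1]])
  x <- array(0, c(n, n, 1, length(matrices)))
  for (i in seq_along(matrices)) x[, , 1, i] <- matrices[[i]]
  x
}

train_hybrid_once <- function(x, y01, train_idx, val_idx, config,
                              lr, batch_size, optimizer) {
  n <- dim(x)[1]
  net <- init_hybrid_net(n, config)
  opt <- make_optimizer(net, optimizer, lr)
  onehot <- cbind(1 - y01, y01)
  best <- list(loss = Inf, net = net, epoch = 0L)
  patience_left <- config$early_stopping_patience
  xval <- x[, , , val_idx, drop = FALSE]
  oh_val <- onehot[val_idx, , drop = FALSE]
  history <- numeric(0)
  for (epoch in seq_len(config$max_epochs)) {
    perm <- sample(train_idx)
    batches <- split(perm, ceiling(seq_along(perm) / batch_size))
    for (bt in batches) {
      xb <- x[, , , bt, drop = FALSE]
      fwd <- hybrid_forward(net, xb, training = TRUE)
      grads <- hybrid_backward(net, xb, onehot[bt, , drop = FALSE], fwd)
      step <- sgd_adam_step(net, grads, opt)
      net <- step$net; opt <- step$opt
    }
    vfwd <- hybrid_forward(net, xval, training = FALSE)
    vloss <- cross_entropy(vfwd$probs, oh_val)
    history <- c(history, vloss)
    if (vloss < best$loss - 1e-6) {
      best <- list(loss = vloss, net = net, epoch = epoch)
      patience_left <- config$early_stopping_patience
    } else {
      patience_left <- patience_left - 1L
      if (patience_left <= 0L) break
    }
  }
  list(net = best$net, val_loss = best$loss, epochs = length(history),
       history = history)
}

#' Fit the hybrid dense + convolutional classifier
#'
#' Trains the architecture of [hybrid_net_config()] on one inter-ROI
#' distance matrix per subject. Subjects are split by ID into training and
#' held-out sets; a further validation slice of the training subjects
#' drives early stopping. Inputs are standardised (z-scored) with statistics
#' computed on the training subjects only. With `search = "random"` a seeded
#' random search
#' over the configured learning-rate range, batch sizes, split ratios and
#' optimizers runs for `n_trials` trials, keeping the trial with the lowest
#' validation loss; `search = "none"` trains once with the config defaults.
#'
#' @param matrices Named list of n x n matrices (names = subject ids), or a
#'   tibble with `subject_id` and `wd` list-columns.
#' @param labels Named vector (or vector aligned with `matrices`) of binary
#'   class labels.
#' @param config A [hybrid_net_config()].
#' @param search `"none"` or `"random"`.
#' @return Object of class `topofc_hybrid` with the trained network, the
#'   trial table, and held-out metrics; see [tidy()]/[glance()].
#' @export
fit_hybrid_net <- function(matrices, labels, config = hybrid_net_config(),
                           search = c("none", "random")) {
  search <- match.arg(search)
  if (is.data.frame(matrices)) {
    labels_in <- labels
    mats <- matrices$wd
    names(mats) <- matrices$subject_id
    matrices <- mats
    if (!is.null(names(labels_in))) labels <- labels_in
  }
  sizes <- vapply(matrices, function(m) nrow(m), integer(1))
  if (length(unique(sizes)) != 1L ||
      any(vapply(matrices, ncol, integer(1)) != sizes))
    abort("all matrices must be square and of identical size",
          class = "topofc_validation_error")
  subj <- names(matrices) %||% as.character(seq_along(matrices))
  if (!is.null(names(labels))) labels <- labels[subj]
  y <- factor(labels)
  if (nlevels(y) != 2L)
    abort("exactly two classes required", class = "topofc_validation_error")
  y01 <- as.numeric(y) - 1

  x <- stack_matrices(matrices)
  nsub <- length(subj)

  with_preserved_rng({
    set.seed(config$seed)
    run_trial <- function(lr, batch_size, test_fraction, optimizer) {
      test_idx <- stratified_split(y, test_fraction)
      train_all <- setdiff(seq_len(nsub), test_idx)
      val_idx <- stratified_split(droplevels(y[train_all]),
                                  config$val_fraction)
      val_idx <- train_all[val_idx]
      tr_idx <- setdiff(train_all, val_idx)
      # standardise inputs with training-set statistics only
      mu <- mean(x[, , , tr_idx]); sdev <- stats::sd(x[, , , tr_idx])
      if (sdev == 0) sdev <- 1
      xs <- (x - mu) / sdev
      fit <- train_hybrid_once(xs, y01, tr_idx, val_idx, config,
                               lr, batch_size, optimizer)
      fit$scale <- c(mu = mu, sd = sdev)
      pf <- hybrid_forward(fit$net, xs[, , , test_idx, drop = FALSE])
      pred <- levels(y)[1 + (pf$probs[, 2] > 0.5)]
      list(fit = fit, test_idx = test_idx, train_idx = tr_idx,
           val_idx = val_idx,
           accuracy = mean(pred == as.character(y[test_idx])),
           lr = lr, batch_size = batch_size,
           test_fraction = test_fraction, optimizer = optimizer)
    }

    if (search == "none") {
      trials <- list(run_trial(config$lr, config$batch_size,
                               config$split_choices[1], config$optimizer))
    } else {
      trials <- lapply(seq_len(config$n_trials), function(i) {
        lr <- exp(runif(1, log(config$lr_range[1]), log(config$lr_range[2])))
        run_trial(lr,
                  sample(config$batch_choices, 1),
                  sample(config$split_choices, 1),
                  sample(config$optimizer_choices, 1))
      })
    }
    losses <- vapply(trials, function(t) t$fit$val_loss, numeric(1))
    best <- trials[[which.min(losses)]]
    trial_tbl <- dplyr::bind_rows(lapply(seq_along(trials), function(i) {
      t <- trials[[i]]
      tibble(trial = i, lr = t$lr, batch_size = t$batch_size,
             test_fraction = t$test_fraction, optimizer = t$optimizer,
             val_loss = t$fit$val_loss, epochs = t$fit$epochs,
             holdout_accuracy = t$accuracy)
    }))
    structure(list(net = best$fit$net, scale = best$fit$scale,
                   config = config,
                   trials = trial_tbl,
                   best_trial = which.min(losses),
                   levels = levels(y),
                   train_subjects = subj[best$train_idx],
                   val_subjects = subj[best$val_idx],
                   test_subjects = subj[best$test_idx],
                   holdout = tibble(accuracy = best$accuracy,
                                    n_test = length(best$test_idx))),
              class = "topofc_hybrid")
  })
}

#' @export
print.topofc_hybrid <- function(x, ...) {
  cat("<topofc_hybrid>\n")
  cat(sprintf("  input %dx%d, %d parameters\n", x$net$n, x$net$n,
              count_net_params(x$net)))
  cat(sprintf("  held-out accuracy %.3f (n_test = %d, trial %d/%d)\n",
              x$holdout$accuracy, x$holdout$n_test, x$best_trial,
              nrow(x$trials)))
  invisible(x)
}

#' @rdname fit_hybrid_net
#' @param x A fitted `topofc_hybrid`.
#' @param ... Unused.
#' @export
tidy.topofc_hybrid <- function(x, ...) x$trials

#' @rdname fit_hybrid_net
#' @export
glance.topofc_hybrid <- function(x, ...) {
  tibble(accuracy = x$holdout$accuracy, n_test = x$holdout$n_test,
         n_parameters = count_net_params(x$net),
         best_trial = x$best_trial, n_trials = nrow(x$trials),
         seed = x$config$seed)
}

#' Class probabilities from a fitted hybrid network
#'
#' @param object A `topofc_hybrid`.
#' @param newdata List of n x n matrices.
#' @param ... Unused.
#' @return Matrix of class probabilities (rows sum to 1).
#' @export
predict.topofc_hybrid <- function(object, newdata, ...) {
  if (is.matrix(newdata)) newdata <- list(newdata)
  x <- stack_matrices(newdata)
  x <- (x - object$scale[["mu"]]) / object$scale[["sd"]]
  p <- hybrid_forward(object$net, x)$probs
  colnames(p) <- object$levels
  p
}
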