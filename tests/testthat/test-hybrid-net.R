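planted_matrices <- function(n_subj, n, effect, seed) {
  # two classes of symmetric "distance" matrices; class b carries an extra
  # block of elevated distances between the first and second halves of ROIs
  set.seed(seed)
  y <- rep(c("a", "b"), each = n_subj / 2)
  mats <- lapply(seq_len(n_subj), function(i) {
    m <- matrix(abs(rnorm(n * n, 1, 0.3)), n)
    m <- (m + t(m)) / 2
    if (y[i] == "b") {
      half <- seq_len(n %/% 2)
      m[half, -half] <- m[half, -half] + effect
      m[-half, half] <- t(m[half, -half])
    }
    diag(m) <- 0
    m
  })
  names(mats) <- sprintf("S%03d", seq_len(n_subj))
  list(mats = mats, y = setNames(y, names(mats)))
}

test_that("the parameter count matches the closed-form layer arithmetic", {
  cfg <- hybrid_net_config()
  for (n in c(10, 21, 34)) {
    net <- topofc:::init_hybrid_net(n, cfg)
    expect_equal(topofc:::count_net_params(net), hybrid_net_param_count(n, cfg))
  }
  # spot-check the formula itself for the default stack at n = 34
  conv <- (1 * 9 + 1) * 16 + (16 * 9 + 1) * 32 + (32 * 9 + 1) * 64 +
    (64 * 9 + 1) * 128 + (128 * 9 + 1) * 256
  flat <- (34^2 + 1) * 256
  dense <- (512 + 1) * 128 + (128 + 1) * 64 + (64 + 1) * 32 + (32 + 1) * 2
  expect_equal(hybrid_net_param_count(34), conv + flat + dense)
})

test_that("forward pass emits a probability simplex", {
  cfg <- hybrid_net_config(seed = 2)
  set.seed(2)
  net <- topofc:::init_hybrid_net(34, cfg)
  x <- topofc:::stack_matrices(list(matrix(abs(rnorm(34 * 34)), 34)))
  p <- topofc:::hybrid_forward(net, x)$probs
  expect_equal(dim(p), c(1, 2))
  expect_equal(sum(p), 1, tolerance = 1e-6)
  expect_true(all(p >= 0))
})

test_that("analytic conv/dense gradients match finite differences", {
  cfg <- hybrid_net_config(conv_filters_block1 = c(2, 3),
                           conv_filters_block2 = c(4),
                           flat_branch_width = 5, dense_widths = c(6),
                           dropout = 0, seed = 3)
  set.seed(3)
  n <- 6
  net <- topofc:::init_hybrid_net(n, cfg)
  x <- topofc:::stack_matrices(list(matrix(rnorm(n * n), n),
                                    matrix(rnorm(n * n), n)))
  onehot <- rbind(c(1, 0), c(0, 1))
  loss_at <- function(net) {
    fwd <- topofc:::hybrid_forward(net, x, training = FALSE)
    topofc:::cross_entropy(fwd$probs, onehot)
  }
  fwd <- topofc:::hybrid_forward(net, x, training = FALSE)
  grads <- topofc:::hybrid_backward(net, x, onehot, fwd)
  eps <- 1e-5
  # a few coordinates from each layer family
  check_coord <- function(get, set, gval) {
    n1 <- net; n1 <- set(n1, eps)
    n2 <- net; n2 <- set(n2, -eps)
    fd <- (loss_at(n1) - loss_at(n2)) / (2 * eps)
    expect_equal(gval, fd, tolerance = 1e-4)
  }
  check_coord(NULL, function(nn, e) { nn$convs[[1]]$w[1, 1] <- nn$convs[[1]]$w[1, 1] + e; nn },
              grads$convs[[1]]$dw[1, 1])
  check_coord(NULL, function(nn, e) { nn$convs[[2]]$b[2] <- nn$convs[[2]]$b[2] + e; nn },
              grads$convs[[2]]$db[2])
  check_coord(NULL, function(nn, e) { nn$flat$w[3, 2] <- nn$flat$w[3, 2] + e; nn },
              grads$flat$dw[3, 2])
  check_coord(NULL, function(nn, e) { nn$dense[[1]]$w[1, 4] <- nn$dense[[1]]$w[1, 4] + e; nn },
              grads$dense[[1]]$dw[1, 4])
  check_coord(NULL, function(nn, e) { nn$dense[[2]]$b[1] <- nn$dense[[2]]$b[1] + e; nn },
              grads$dense[[2]]$db[1])
})

test_that("single-class training sets are rejected and sizes validated", {
  pm <- planted_matrices(8, 6, 1, seed = 4)
  expect_error(fit_hybrid_net(pm$mats, rep("a", 8)),
               class = "topofc_validation_error")
  bad <- pm$mats
  bad[[3]] <- matrix(0, 5, 5)
  expect_error(fit_hybrid_net(bad, pm$y),
               class = "topofc_validation_error")
})

test_that("training separates planted block structure and is reproducible", {
  pm <- planted_matrices(32, 10, effect = 1.5, seed = 6)
  cfg <- hybrid_net_config(max_epochs = 30, seed = 7)
  fit <- fit_hybrid_net(pm$mats, pm$y, cfg)
  expect_gte(glance(fit)$accuracy, 0.75)
  expect_length(intersect(fit$train_subjects, fit$test_subjects), 0)
  expect_length(intersect(fit$val_subjects, fit$test_subjects), 0)
  fit2 <- fit_hybrid_net(pm$mats, pm$y, cfg)
  expect_identical(glance(fit), glance(fit2))
  p <- predict(fit, pm$mats[1:3])
  expect_equal(rowSums(p), rep(1, 3), tolerance = 1e-6)
})

test_that("random search explores the configured space deterministically", {
  pm <- planted_matrices(24, 8, effect = 1.5, seed = 8)
  cfg <- hybrid_net_config(max_epochs = 8, n_trials = 3, seed = 9,
                           early_stopping_patience = 3)
  fit <- fit_hybrid_net(pm$mats, pm$y, cfg, search = "random")
  tt <- tidy(fit)
  expect_equal(nrow(tt), 3)
  expect_true(all(tt$lr >= cfg$lr_range[1] & tt$lr <= cfg$lr_range[2]))
  expect_true(all(tt$batch_size %in% cfg$batch_choices))
  expect_true(all(tt$optimizer %in% cfg$optimizer_choices))
  fit2 <- fit_hybrid_net(pm$mats, pm$y, cfg, search = "random")
  expect_identical(tidy(fit), tidy(fit2))
})
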