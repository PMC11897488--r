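test_that("top-k lifespans sort, pad and respect the essential policy", {
  d <- tibble::tibble(dimension = 1L, birth = c(1, 2), death = c(4, 3),
                      kind = "ordinary")
  expect_equal(top_k_lifespans(d, k = 10), c(3, 1, rep(0, 8)))
  empty <- d[0, ]
  expect_equal(top_k_lifespans(empty, k = 10), rep(0, 10))
  # extended convention (birth >= death) uses |death - birth|
  ext <- tibble::tibble(dimension = 1L, birth = c(7, 5), death = c(4, 5),
                        kind = "extended")
  expect_equal(top_k_lifespans(ext, k = 3), c(3, 0, 0))
  # twelve points: exactly the ten largest survive, cross-checked by sort
  set.seed(61)
  big <- random_diagram(12)
  expect_equal(top_k_lifespans(big, k = 10),
               sort(big$death - big$birth, decreasing = TRUE)[1:10])
  # essential points: dropped by default, kept when truncated
  with_ess <- tibble::tibble(dimension = 0L, birth = c(0, 1),
                             death = c(5, Inf), kind = "ordinary")
  expect_equal(top_k_lifespans(with_ess, k = 2), c(5, 0))
  expect_equal(top_k_lifespans(with_ess, k = 2, essential = "truncate"),
               c(5, 4))
})

test_that("RFE keeps a planted informative feature", {
  hits <- 0L
  for (seed in 1:20) {
    set.seed(seed)
    n <- 200
    y <- rep(c("a", "b"), each = n / 2)
    x <- matrix(rnorm(n * 10), n)
    x[, 4] <- x[, 4] + ifelse(y == "a", 0, 2)   # the informative column
    colnames(x) <- sprintf("f%02d", 1:10)
    sel <- rfe_select(x, y, n_selected = 5, seed = seed)
    hits <- hits + (4L %in% sel)
  }
  expect_gte(hits, 19L)
})

test_that("RFE identity, determinism and degenerate input handling", {
  set.seed(62)
  x <- matrix(rnorm(40 * 10), 40)
  y <- rep(c("a", "b"), 20)
  expect_equal(rfe_select(x, y, n_selected = 10, seed = 1), 1:10)
  expect_identical(rfe_select(x, y, 5, seed = 9), rfe_select(x, y, 5, seed = 9))
  expect_error(rfe_select(x, rep("a", 40), 5),
               class = "topofc_validation_error")
})

test_that("duplicated informative columns never both lose to noise", {
  wins <- 0L
  for (seed in 1:10) {
    set.seed(seed)
    n <- 120
    y <- rep(c("a", "b"), each = n / 2)
    info <- rnorm(n) + ifelse(y == "a", 0, 2)
    x <- cbind(info, info, matrix(rnorm(n * 6), n))
    colnames(x) <- sprintf("f%02d", 1:8)
    sel <- rfe_select(x, y, n_selected = 4, seed = seed)
    wins <- wins + any(c(1L, 2L) %in% sel)
  }
  expect_equal(wins, 10L)
})

test_that("the stacked ensemble nails separable data and stays reproducible", {
  set.seed(63)
  n <- 60
  y <- rep(c("a", "b"), each = n / 2)
  x <- matrix(rnorm(n * 5), n)
  x[, 1] <- x[, 1] + ifelse(y == "a", -4, 4)
  rownames(x) <- sprintf("S%03d", 1:n)
  cfg <- ensemble_config(seed = 5)
  fit <- fit_stacked_ensemble(x, y, cfg)
  expect_equal(glance(fit)$accuracy, 1.0)
  fit2 <- fit_stacked_ensemble(x, y, cfg)
  expect_identical(tidy(fit), tidy(fit2))
  expect_identical(glance(fit), glance(fit2))
  # ranking covers the configured roster, stacking the configured count
  expect_setequal(tidy(fit)$model, cfg$base_model_roster)
  expect_equal(sum(tidy(fit)$stacked), cfg$n_stack_members)
  # substitutions are declared
  expect_true(all(c("gradient_boosting", "lightgbm", "catboost", "adaboost")
                  %in% names(fit$substitutions)))
  # train/test subject separation
  expect_length(intersect(fit$train_subjects, fit$test_subjects), 0)
  # prediction API round-trips
  expect_equal(as.character(predict(fit, x[1:5, ])),
               as.character(factor(y[1:5])))
})

test_that("ensemble held-out accuracy sits at chance on pure noise", {
  set.seed(64)
  accs <- vapply(1:15, function(seed) {
    n <- 40
    y <- rep(c("a", "b"), each = n / 2)
    x <- matrix(rnorm(n * 5), n)
    glance(fit_stacked_ensemble(x, y, ensemble_config(seed = seed)))$accuracy
  }, numeric(1))
  n_test <- 8
  se <- sqrt(0.25 / (15 * n_test))
  expect_lt(abs(mean(accs) - 0.5), 3.5 * se + 0.05)
})

test_that("class-size validation fires before fitting", {
  x <- matrix(rnorm(12 * 3), 12)
  y <- c(rep("a", 9), rep("b", 3))
  expect_error(fit_stacked_ensemble(x, y, ensemble_config(cv_folds = 5)),
               class = "topofc_validation_error")
})
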