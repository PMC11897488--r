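#' Configuration for the stacked ensemble classifier
#'
#' Reproduces the rank-select-stack procedure: ten base classifiers are
#' scored by stratified K-fold cross-validation accuracy on the training
#' split, the top `n_stack_members` are stacked under a random-forest
#' meta-model fed with their out-of-fold class probabilities, and held-out
#' accuracy is reported on a stratified `test_fraction` split.
#'
#' Three roster entries (gradient_boosting, lightgbm, catboost) are realised
#' as gradient-boosting variants of xgboost with distinct hyperparameter
#' profiles, and adaboost as SAMME boosting over decision stumps; the fitted
#' object records these substitutions.
#'
#' @param base_model_roster Character vector of base learner names; the
#'   default is the full ten-model roster (see [ensemble_roster()]).
#' @param n_selected_features Features kept by RFE before fitting.
#' @param n_stack_members Number of top-ranked models stacked.
#' @param meta_model Only `"random_forest"` is implemented.
#' @param cv_folds Stratified CV folds for ranking and stacking.
#' @param test_fraction Held-out fraction of subjects.
#' @param seed Integer seed controlling the split, folds and learners.
#' @return List of class `ensemble_config`.
#' @export
ensemble_config <- function(base_model_roster = names(ensemble_roster()),
                            n_selected_features = 5,
                            n_stack_members = 5,
                            meta_model = "random_forest",
                            cv_folds = 5,
                            test_fraction = 0.2,
                            seed = 1) {
  if (!all(base_model_roster %in% names(ensemble_roster())))
    abort(paste0("unknown base model(s): ",
                 paste(setdiff(base_model_roster, names(ensemble_roster())),
                       collapse = ", ")))
  n_stack_members <- assert_count(n_stack_members, "n_stack_members")
  if (n_stack_members > length(base_model_roster))
    abort("n_stack_members exceeds roster size")
  structure(list(base_model_roster = base_model_roster,
                 n_selected_features = assert_count(n_selected_features,
                                                    "n_selected_features"),
                 n_stack_members = n_stack_members,
                 meta_model = match.arg(meta_model, "random_forest"),
                 cv_folds = assert_count(cv_folds, "cv_folds", min = 2L),
                 test_fraction = assert_prob(test_fraction, "test_fraction"),
                 seed = as.integer(seed)),
            class = "ensemble_config")
}

#' The base-learner roster
#'
#' Named list of fit/predict closures for the ten base classifiers. Each
#' `fit(x, y)` returns a fitted model, each `prob(model, x)` the probability
#' of the second factor level. The `substitution` field marks learners
#' realised by an equivalent gradient-boosting implementation.
#'
#' @return Named list of learner definitions.
#' @keywords internal
#' @export
ensemble_roster <- function() {
  xgb_fit <- function(params, nrounds) function(x, y) {
    dm <- xgboost::xgb.DMatrix(x, label = as.numeric(y) - 1)
    xgboost::xgb.train(params = c(params, list(objective = "binary:logistic",
                                               nthread = 1)),
                       data = dm, nrounds = nrounds, verbose = 0)
  }
  xgb_prob <- function(model, x) predict(model, xgboost::xgb.DMatrix(x))
  list(
    svc = list(
      fit = function(x, y) e1071::svm(x, y, kernel = "radial",
                                      probability = TRUE),
      prob = function(m, x) {
        p <- attr(predict(m, x, probability = TRUE), "probabilities")
        p[, levels(m$fitted)[2]]
      },
      substitution = NA_character_),
    random_forest = list(
      fit = function(x, y) randomForest::randomForest(x, y, ntree = 300),
      prob = function(m, x) predict(m, x, type = "prob")[, 2],
      substitution = NA_character_),
    gradient_boosting = list(
      fit = xgb_fit(list(max_depth = 3, eta = 0.1, subsample = 0.8), 100),
      prob = xgb_prob,
      substitution = "xgboost (depth-3, eta 0.1) standing in for sklearn-style gradient boosting"),
    xgboost = list(
      fit = xgb_fit(list(max_depth = 6, eta = 0.3), 50),
      prob = xgb_prob,
      substitution = NA_character_),
    adaboost = list(
      fit = function(x, y) fit_adaboost_stumps(x, y, n_rounds = 50),
      prob = function(m, x) predict_adaboost_stumps(m, x),
      substitution = "hand-rolled SAMME AdaBoost over rpart stumps"),
    extra_trees = list(
      fit = function(x, y) {
        colnames(x) <- sprintf("f%03d", seq_len(ncol(x)))
        ranger::ranger(x = as.data.frame(x), y = y, num.trees = 300,
                       splitrule = "extratrees", probability = TRUE,
                       num.random.splits = 1, seed = 1)
      },
      prob = function(m, x) {
        colnames(x) <- sprintf("f%03d", seq_len(ncol(x)))
        predict(m, as.data.frame(x))$predictions[, 2]
      },
      substitution = NA_character_),
    logistic_regression = list(
      fit = function(x, y) suppressWarnings(
        stats::glm.fit(cbind(1, x), as.numeric(y) - 1,
                       family = stats::binomial())),
      prob = function(m, x) {
        beta <- m$coefficients
        beta[is.na(beta)] <- 0
        eta <- cbind(1, x) %*% beta
        as.numeric(1 / (1 + exp(-eta)))
      },
      substitution = NA_character_),
    knn = list(
      fit = function(x, y) caret::knn3(x, y, k = min(5, nrow(x) - 1)),
      prob = function(m, x) predict(m, x, type = "prob")[, 2],
      substitution = NA_character_),
    lightgbm = list(
      fit = xgb_fit(list(max_depth = 0, grow_policy = "lossguide",
                         max_leaves = 31, eta = 0.1,
                         tree_method = "hist"), 100),
      prob = xgb_prob,
      substitution = "xgboost (leaf-wise hist) standing in for LightGBM"),
    catboost = list(
      fit = xgb_fit(list(max_depth = 6, eta = 0.05,
                         colsample_bytree = 0.8), 150),
      prob = xgb_prob,
      substitution = "xgboost (depth-6, eta 0.05) standing in for CatBoost")
  )
}

# SAMME AdaBoost.M1 with depth-1 rpart stumps (binary labels)
fit_adaboost_stumps <- function(x, y, n_rounds = 50) {
  y <- factor(y)
  n <- nrow(x)
  colnames(x) <- sprintf("f%03d", seq_len(ncol(x)))
  df <- data.frame(.y = y, x, check.names = FALSE)
  w <- rep(1 / n, n)
  stumps <- list(); alphas <- numeric(0)
  for (r in seq_len(n_rounds)) {
    fit <- rpart::rpart(.y ~ ., data = df, weights = w,
                        control = rpart::rpart.control(maxdepth = 1,
                                                       cp = -1, minsplit = 2,
                                                       xval = 0))
    pred <- predict(fit, df, type = "class")
    err <- sum(w * (pred != y)) / sum(w)
    if (err >= 0.5 || err <= 1e-10) {
      if (err <= 1e-10) { stumps[[r]] <- fit; alphas[r] <- 10 }
      break
    }
    alpha <- 0.5 * log((1 - err) / err)
    stumps[[r]] <- fit; alphas[r] <- alpha
    w <- w * exp(alpha * ifelse(pred != y, 1, -1))
    w <- w / sum(w)
  }
  if (length(stumps) == 0L) { stumps[[1]] <- fit; alphas[1] <- 1 }
  list(stumps = stumps, alphas = alphas, levels = levels(y))
}

predict_adaboost_stumps <- function(model, x) {
  colnames(x) <- sprintf("f%03d", seq_len(ncol(x)))
  df <- data.frame(x, check.names = FALSE)
  score <- rep(0, nrow(df))
  for (r in seq_along(model$stumps)) {
    pred <- predict(model$stumps[[r]], df, type = "class")
    score <- score + model$alphas[r] * ifelse(pred == model$levels[2], 1, -1)
  }
  1 / (1 + exp(-2 * score))   # logistic squash of the additive score
}

stratified_folds <- function(y, k) {
  idx <- seq_along(y)
  folds <- integer(length(y))
  for (lv in levels(y)) {
    ii <- sample(idx[y == lv])
    folds[ii] <- rep(seq_len(k), length.out = length(ii))
  }
  folds
}

stratified_split <- function(y, test_fraction) {
  test <- integer(0)
  for (lv in levels(y)) {
    ii <- which(y == lv)
    n_test <- max(1L, round(length(ii) * test_fraction))
    test <- c(test, sample(ii, n_test))
  }
  sort(test)
}

#' Fit the stacked ensemble classifier
#'
#' Runs the full procedure on a feature matrix: stratified train/test split,
#' CV ranking of the roster, stacking of the top models under a
#' random-forest meta-model on out-of-fold probabilities, and held-out
#' evaluation. Reproducible given `(config, seed)`.
#'
#' @param x Numeric feature matrix (subjects x features), rownames treated
#'   as subject ids.
#' @param y Binary class labels (factor or character).
#' @param config An [ensemble_config()].
#' @return Object of class `topofc_ensemble` with `cv_ranking`, `holdout`,
#'   `selected_models`, `substitutions`, `config`; see [tidy()] and
#'   [glance()] methods.
#' @export
fit_stacked_ensemble <- function(x, y, config = ensemble_config()) {
  x <- as.matrix(x)
  y <- factor(y)
  if (nlevels(y) != 2L) abort("exactly two classes required",
                              class = "topofc_validation_error")
  if (min(table(y)) < config$cv_folds)
    abort("class too small for stratified cross-validation",
          class = "topofc_validation_error")
  roster <- ensemble_roster()[config$base_model_roster]

  with_preserved_rng({
    set.seed(config$seed)
    test_idx <- stratified_split(y, config$test_fraction)
    train_idx <- setdiff(seq_along(y), test_idx)
    xtr <- x[train_idx, , drop = FALSE]; ytr <- droplevels(y[train_idx])
    xte <- x[test_idx, , drop = FALSE];  yte <- y[test_idx]

    folds <- stratified_folds(ytr, config$cv_folds)

    # rank the roster by stratified-CV accuracy on the training split
    cv_acc <- vapply(names(roster), function(nm) {
      correct <- 0L
      for (f in seq_len(config$cv_folds)) {
        tr <- folds != f
        model <- roster[[nm]]$fit(xtr[tr, , drop = FALSE], ytr[tr])
        p <- roster[[nm]]$prob(model, xtr[!tr, , drop = FALSE])
        pred <- levels(ytr)[1 + (p > 0.5)]
        correct <- correct + sum(pred == as.character(ytr[!tr]))
      }
      correct / length(ytr)
    }, numeric(1))
    ranking <- tibble(model = names(cv_acc), cv_accuracy = unname(cv_acc))
    ranking <- dplyr::arrange(ranking, dplyr::desc(.data$cv_accuracy),
                              .data$model)
    selected <- ranking$model[seq_len(config$n_stack_members)]

    # out-of-fold probabilities of the selected models = meta features
    meta_tr <- matrix(NA_real_, length(ytr), length(selected),
                      dimnames = list(NULL, selected))
    for (nm in selected) {
      for (f in seq_len(config$cv_folds)) {
        tr <- folds != f
        model <- roster[[nm]]$fit(xtr[tr, , drop = FALSE], ytr[tr])
        meta_tr[!tr, nm] <- roster[[nm]]$prob(model, xtr[!tr, , drop = FALSE])
      }
    }
    meta_model <- randomForest::randomForest(meta_tr, ytr, ntree = 300)

    # refit bases on the full training split for test-time probabilities
    base_models <- lapply(selected, function(nm)
      roster[[nm]]$fit(xtr, ytr))
    names(base_models) <- selected
    meta_te <- vapply(selected, function(nm)
      roster[[nm]]$prob(base_models[[nm]], xte), numeric(length(yte)))
    meta_te <- matrix(meta_te, nrow = length(yte),
                      dimnames = list(NULL, selected))
    pred <- predict(meta_model, meta_te)
    holdout_acc <- mean(pred == yte)

    subs <- vapply(roster, function(r) r$substitution, character(1))
    structure(
      list(config = config, cv_ranking = ranking,
           selected_models = selected,
           substitutions = subs[!is.na(subs)],
           base_models = base_models, meta_model = meta_model,
           levels = levels(y),
           train_subjects = rownames(x)[train_idx],
           test_subjects = rownames(x)[test_idx],
           holdout = tibble(accuracy = holdout_acc,
                            n_train = length(ytr), n_test = length(yte))),
      class = "topofc_ensemble")
  })
}

#' @export
print.topofc_ensemble <- function(x, ...) {
  cat("<topofc_ensemble>\n")
  cat("  stacked:", paste(x$selected_models, collapse = ", "), "\n")
  cat(sprintf("  held-out accuracy %.3f (n_test = %d)\n",
              x$holdout$accuracy, x$holdout$n_test))
  invisible(x)
}

#' @rdname fit_stacked_ensemble
#' @param x A fitted `topofc_ensemble`.
#' @param ... Unused.
#' @export
tidy.topofc_ensemble <- function(x, ...) {
  dplyr::mutate(x$cv_ranking,
                stacked = .data$model %in% x$selected_models)
}

#' @rdname fit_stacked_ensemble
#' @export
glance.topofc_ensemble <- function(x, ...) {
  tibble(accuracy = x$holdout$accuracy,
         n_train = x$holdout$n_train, n_test = x$holdout$n_test,
         n_stacked = length(x$selected_models),
         cv_folds = x$config$cv_folds, seed = x$config$seed)
}

#' Predict from a fitted stacked ensemble
#'
#' @param object A `topofc_ensemble`.
#' @param newdata Feature matrix with the training columns.
#' @param ... Unused.
#' @return Factor of predicted labels.
#' @export
predict.topofc_ensemble <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  roster <- ensemble_roster()
  meta <- vapply(object$selected_models, function(nm)
    roster[[nm]]$prob(object$base_models[[nm]], newdata),
    numeric(nrow(newdata)))
  meta <- matrix(meta, nrow = nrow(newdata),
                 dimnames = list(NULL, object$selected_models))
  predict(object$meta_model, meta)
}
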