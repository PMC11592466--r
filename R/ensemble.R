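#' The six base learners
#'
#' @return Character vector of the recognized learner names: support
#'   vector machine (`svm`), logistic regression (`lr`), decision tree
#'   (`dt`), random forest (`rf`), `adaboost` and `xgboost`.
#' @export
base_learner_names <- function() c("svm", "lr", "dt", "rf", "adaboost", "xgboost")

#' Default hyperparameters for the base learners
#'
#' Reference-implementation defaults: RBF-kernel SVM with probability
#' estimates, unpenalized logistic regression, CART decision tree, random
#' forest with 500 trees, AdaBoost with 50 depth-1 stumps, and XGBoost
#' with 100 rounds of depth-3 trees at learning rate 0.3. All exposed so
#' any of them can be overridden per learner.
#'
#' @return Named list of hyperparameter lists, one per learner.
#' @export
default_learner_specs <- function() {
  list(
    svm = list(kernel = "radial", cost = 1),
    lr = list(),
    dt = list(cp = 0.01, minsplit = 20),
    rf = list(ntree = 500),
    adaboost = list(n_rounds = 50, maxdepth = 1),
    xgboost = list(nrounds = 100, max_depth = 3, eta = 0.3)
  )
}

# ---- AdaBoost (discrete, exponential-loss boosting of CART stumps) ------
# No boosting-of-stumps implementation is exported by the package's
# dependencies, so the classic discrete algorithm is provided here:
# T rounds of weighted stumps, alpha_t = 0.5 log((1-err)/err), probability
# through the logistic link of the additive margin.
fit_adaboost <- function(X, y, n_rounds = 50, maxdepth = 1) {
  n <- nrow(X)
  w <- rep(1 / n, n)
  df <- data.frame(X, .y = factor(y, levels = c(0, 1)))
  stumps <- vector("list", n_rounds)
  alphas <- numeric(n_rounds)
  used <- 0
  for (t in seq_len(n_rounds)) {
    fit <- rpart::rpart(.y ~ ., data = df, weights = w, method = "class",
                        control = rpart::rpart.control(
                          maxdepth = maxdepth, cp = -1, minsplit = 2,
                          minbucket = 1, xval = 0))
    pred <- as.integer(as.character(stats::predict(fit, df, type = "class")))
    err <- sum(w * (pred != y))
    if (err >= 0.5) break
    err <- max(err, 1e-10)
    alpha <- 0.5 * log((1 - err) / err)
    used <- t
    stumps[[t]] <- fit
    alphas[t] <- alpha
    h <- ifelse(pred == 1, 1, -1)
    yy <- ifelse(y == 1, 1, -1)
    w <- w * exp(-alpha * yy * h)
    w <- w / sum(w)
    if (err < 1e-9) break
  }
  if (used == 0) {                      # single stump already separates
    stumps[[1]] <- fit
    alphas[1] <- 1
    used <- 1
  }
  structure(list(stumps = stumps[seq_len(used)], alphas = alphas[seq_len(used)]),
            class = "adaboost_fit")
}

predict_adaboost <- function(object, X) {
  df <- as.data.frame(X)
  f <- rowSums(vapply(seq_along(object$stumps), function(t) {
    pred <- as.integer(as.character(
      stats::predict(object$stumps[[t]], df, type = "class")))
    object$alphas[t] * ifelse(pred == 1, 1, -1)
  }, numeric(nrow(df))))
  1 / (1 + exp(-2 * f))                 # logistic link of the margin
}

fit_one_learner <- function(name, X, y, spec, seed) {
  df <- data.frame(X, .y = factor(y, levels = c(0, 1)))
  withr::with_seed(seed, switch(name,
    svm = e1071::svm(.y ~ ., data = df, kernel = spec$kernel,
                     cost = spec$cost, probability = TRUE),
    lr = suppressWarnings(
      stats::glm(.y ~ ., data = df, family = stats::binomial())
    ),
    dt = rpart::rpart(.y ~ ., data = df, method = "class",
                      control = rpart::rpart.control(
                        cp = spec$cp, minsplit = spec$minsplit, xval = 0)),
    rf = randomForest::randomForest(.y ~ ., data = df, ntree = spec$ntree),
    adaboost = fit_adaboost(X, y, n_rounds = spec$n_rounds,
                            maxdepth = spec$maxdepth),
    xgboost = xgboost::xgb.train(
      params = list(objective = "binary:logistic", max_depth = spec$max_depth,
                    eta = spec$eta, nthread = 1),
      data = xgboost::xgb.DMatrix(as.matrix(X), label = y),
      nrounds = spec$nrounds, verbose = 0
    ),
    stop(sprintf("unknown learner '%s'", name), call. = FALSE)
  ))
}

predict_one_learner <- function(name, fit, X) {
  df <- as.data.frame(X)
  p <- switch(name,
    svm = {
      pr <- attr(stats::predict(fit, df, probability = TRUE), "probabilities")
      pr[, "1"]
    },
    lr = suppressWarnings(
      stats::predict(fit, df, type = "response")
    ),
    dt = stats::predict(fit, df, type = "prob")[, "1"],
    rf = stats::predict(fit, df, type = "prob")[, "1"],
    adaboost = predict_adaboost(fit, X),
    xgboost = stats::predict(fit, xgboost::xgb.DMatrix(as.matrix(X)))
  )
  unname(pmin(pmax(as.numeric(p), 0), 1))
}

#' Train the six base learners
#'
#' Fits SVM, logistic regression, decision tree, random forest, AdaBoost
#' and XGBoost on the numeric feature columns of a labeled training table.
#' Every randomized learner is seeded (a per-learner seed is derived from
#' `seed`), so refitting with the same seed reproduces identical
#' predictions.
#'
#' @param train Tibble with binary `label` and numeric features.
#' @param seed Integer seed.
#' @param specs Hyperparameters, see [default_learner_specs()].
#' @param columns Feature columns; defaults to [feature_columns()].
#' @return A `wmcm_ensemble` object holding the six fits.
#' @export
train_base_learners <- function(train, seed = 1,
                                specs = default_learner_specs(),
                                columns = NULL) {
  if (is.null(columns)) columns <- feature_columns(train)
  y <- train$label
  if (length(unique(y)) < 2) {
    stop("training data contains a single class", call. = FALSE)
  }
  X <- as.data.frame(train[, columns])
  names_ <- base_learner_names()
  fits <- lapply(seq_along(names_), function(k) {
    fit_one_learner(names_[k], X, y, specs[[names_[k]]], seed + k)
  })
  names(fits) <- names_
  structure(list(fits = fits, columns = columns, specs = specs,
                 seed = seed, n_train = nrow(train)),
            class = "wmcm_ensemble")
}

#' @export
print.wmcm_ensemble <- function(x, ...) {
  cat(sprintf("<wmcm_ensemble: %s; trained on %d rows, %d features>\n",
              paste(names(x$fits), collapse = ", "),
              x$n_train, length(x$columns)))
  invisible(x)
}

#' Positive-class probability panel
#'
#' @param model A `wmcm_ensemble` from [train_base_learners()].
#' @param newdata Feature tibble.
#' @return Tibble with one probability column per learner
#'   (`p_svm`, ..., `p_xgboost`), rows aligned with `newdata`.
#' @export
predict_panel <- function(model, newdata) {
  stopifnot(inherits(model, "wmcm_ensemble"))
  X <- as.data.frame(newdata[, model$columns])
  cols <- lapply(names(model$fits), function(nm) {
    predict_one_learner(nm, model$fits[[nm]], X)
  })
  names(cols) <- paste0("p_", names(model$fits))
  tibble::as_tibble(cols)
}

#' Normalize per-learner accuracies into ensemble weights
#'
#' @param accuracy Named non-negative accuracy vector.
#' @return Weights proportional to accuracy, summing to 1; uniform (with a
#'   warning) if every accuracy is zero.
#' @export
weights_from_accuracy <- function(accuracy) {
  if (sum(accuracy) == 0) {
    warning("all accuracies zero; falling back to uniform weights",
            call. = FALSE)
    return(stats::setNames(rep(1 / length(accuracy), length(accuracy)),
                           names(accuracy)))
  }
  accuracy / sum(accuracy)
}

#' Derive ensemble weights from cross-validated accuracy
#'
#' Performance-based weighting for the weighted-averaging combiner: each
#' learner's weight is proportional to its out-of-fold accuracy under
#' stratified 5-fold cross-validation on the training set (no test-set
#' leakage), normalized to sum to one.
#'
#' @param model A `wmcm_ensemble` (supplies hyperparameters and columns).
#' @param train The training tibble the model was fitted on.
#' @param seed Integer seed for fold assignment and refits.
#' @param folds Number of folds (default 5).
#' @return Named weight vector over the six learners, summing to 1; the
#'   out-of-fold accuracies are attached as attribute `"cv_accuracy"`.
#' @export
derive_weights <- function(model, train, seed = 1, folds = 5) {
  stopifnot(inherits(model, "wmcm_ensemble"))
  y <- train$label
  fold_id <- withr::with_seed(seed, {
    id <- integer(length(y))
    for (cls in unique(y)) {
      rows <- which(y == cls)
      id[rows] <- sample(rep(seq_len(folds), length.out = length(rows)))
    }
    id
  })
  names_ <- names(model$fits)
  hits <- stats::setNames(numeric(length(names_)), names_)
  for (f in seq_len(folds)) {
    tr <- train[fold_id != f, , drop = FALSE]
    te <- train[fold_id == f, , drop = FALSE]
    X <- as.data.frame(tr[, model$columns])
    Xte <- as.data.frame(te[, model$columns])
    for (k in seq_along(names_)) {
      fit <- fit_one_learner(names_[k], X, tr$label,
                             model$specs[[names_[k]]], seed + 100 * f + k)
      p <- predict_one_learner(names_[k], fit, Xte)
      hits[k] <- hits[k] + sum((p >= 0.5) == (te$label == 1))
    }
  }
  acc <- hits / length(y)
  w <- weights_from_accuracy(acc)
  attr(w, "cv_accuracy") <- acc
  w
}

#' Weighted-average ensemble
#'
#' The ensemble score of a sample is the weight-by-weight sum of the base
#' learners' positive-class probabilities; the label is 1 when the score
#' reaches the threshold.
#'
#' @param panel Probability tibble/matrix, one column per learner.
#' @param weights Non-negative weights, one per column, summing to 1.
#' @param threshold Decision threshold (default 0.5; ties go to class 1).
#' @return Tibble with `score` and `label`.
#' @export
weighted_average <- function(panel, weights, threshold = 0.5) {
  P <- as.matrix(panel)
  if (ncol(P) != length(weights)) {
    stop("one weight per learner column is required", call. = FALSE)
  }
  if (abs(sum(weights) - 1) > 1e-9) {
    stop("ensemble weights must sum to 1", call. = FALSE)
  }
  score <- as.numeric(P %*% weights)
  tibble::tibble(score = score, label = as.integer(score >= threshold))
}

#' Soft-voting ensemble
#'
#' Unweighted mean of the learners' probabilities — identical to
#' [weighted_average()] with uniform weights.
#'
#' @inheritParams weighted_average
#' @return Tibble with `score` and `label`.
#' @export
soft_vote <- function(panel, threshold = 0.5) {
  weighted_average(panel, rep(1 / ncol(as.matrix(panel)), ncol(as.matrix(panel))),
                   threshold = threshold)
}

#' Hard-voting ensemble
#'
#' Majority vote over the learners' 0/1 predictions. A tie (three of six
#' learners each way) is resolved toward class 1 — in a relapse-screening
#' setting the cost of a missed positive dominates, so ties favour
#' sensitivity. The `score` column is the fraction of positive votes,
#' usable as a coarse ranking score for ROC analysis.
#'
#' @param votes 0/1 matrix or tibble, one column per learner; probability
#'   panels are thresholded at 0.5 first.
#' @return Tibble with `score` (positive-vote fraction) and `label`.
#' @export
hard_vote <- function(votes) {
  V <- as.matrix(votes)
  if (any(V > 1 | V < 0)) stop("votes must be 0/1 or probabilities", call. = FALSE)
  if (any(V != floor(V))) V <- (V >= 0.5) * 1
  frac <- rowMeans(V)
  tibble::tibble(score = frac, label = as.integer(frac >= 0.5))
}
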