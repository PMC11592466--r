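blobs <- make_blobs()

test_that("all six base learners emit valid probabilities and separate blobs", {
  sp <- stratified_split(blobs, 0.8, seed = 1)
  model <- train_base_learners(sp$train, seed = 5)
  expect_named(model$fits, base_learner_names())
  panel <- predict_panel(model, sp$test)
  expect_equal(dim(panel), c(nrow(sp$test), 6))
  expect_true(all(as.matrix(panel) >= 0 & as.matrix(panel) <= 1))
  for (nm in base_learner_names()) {
    acc <- mean((panel[[paste0("p_", nm)]] >= 0.5) == (sp$test$label == 1))
    expect_gte(acc, 0.95)
  }
})

test_that("refitting with the same seed reproduces identical predictions", {
  sp <- stratified_split(blobs, 0.8, seed = 1)
  m1 <- train_base_learners(sp$train, seed = 5)
  m2 <- train_base_learners(sp$train, seed = 5)
  expect_identical(predict_panel(m1, sp$test), predict_panel(m2, sp$test))
  expect_error(train_base_learners(dplyr::filter(blobs, label == 1)),
               "single class")
})

test_that("accuracy-proportional weights normalize and handle edge cases", {
  expect_equal(weights_from_accuracy(c(a = 0.9, b = 0.1)), c(a = 0.9, b = 0.1))
  expect_equal(unname(weights_from_accuracy(rep(0.8, 6))), rep(1 / 6, 6))
  expect_warning(w0 <- weights_from_accuracy(c(a = 0, b = 0)), "uniform")
  expect_equal(unname(w0), c(0.5, 0.5))
})

test_that("cross-validated ensemble weights sum to one and are seeded", {
  sp <- stratified_split(blobs, 0.8, seed = 1)
  model <- train_base_learners(sp$train, seed = 5)
  w1 <- derive_weights(model, sp$train, seed = 2, folds = 3)
  expect_equal(sum(w1), 1)
  expect_true(all(w1 >= 0))
  expect_named(w1, base_learner_names())
  expect_identical(w1, derive_weights(model, sp$train, seed = 2, folds = 3))
  expect_true(all(attr(w1, "cv_accuracy") >= 0.9))  # separable blobs
})

test_that("weighted averaging computes the weighted probability sum", {
  panel <- tibble::tibble(a = c(1.0, 0.6, 0.2), b = c(0.0, 0.6, 0.1))
  out <- weighted_average(panel, c(0.7, 0.3))
  expect_equal(out$score, c(0.7, 0.6, 0.17))
  expect_equal(out$label, c(1L, 1L, 0L))
  # one-hot weights reduce to that learner
  expect_equal(weighted_average(panel, c(1, 0))$score, panel$a)
  # linear in the panel
  w <- c(0.25, 0.75)
  expect_equal(weighted_average(2 * panel, w)$score,
               2 * weighted_average(panel, w)$score, tolerance = 1e-12)
  # invariant to matched column/weight reordering
  expect_equal(weighted_average(panel[, c("b", "a")], rev(w))$score,
               weighted_average(panel, w)$score)
  expect_error(weighted_average(panel, c(0.5, 0.3)), "sum to 1")
  expect_error(weighted_average(panel, c(1, 0, 0)), "one weight per learner")
})

test_that("soft voting is exactly uniform weighted averaging", {
  panel <- withr::with_seed(3, tibble::tibble(
    a = runif(20), b = runif(20), c = runif(20)
  ))
  expect_equal(soft_vote(panel), weighted_average(panel, rep(1 / 3, 3)))
  # threshold tie goes to class 1
  two <- tibble::tibble(a = 0.9, b = 0.1)
  expect_equal(soft_vote(two)$score, 0.5)
  expect_equal(soft_vote(two)$label, 1L)
  one_col <- tibble::tibble(a = c(0.3, 0.8))
  expect_equal(soft_vote(one_col)$score, one_col$a)
})

test_that("hard voting follows the majority with positive tie-break", {
  votes <- rbind(c(1, 1, 1, 1, 0, 0),
                 c(0, 0, 0, 0, 1, 1),
                 c(1, 1, 1, 0, 0, 0))
  out <- hard_vote(votes)
  expect_equal(out$label, c(1L, 0L, 1L))
  expect_equal(out$score, c(4 / 6, 2 / 6, 3 / 6))
  # probability panels are thresholded at 0.5 first
  expect_equal(hard_vote(cbind(0.9, 0.2, 0.6))$label, 1L)
})

test_that("hard and soft votes agree when learners are unanimous-sided", {
  withr::with_seed(4, {
    for (i in 1:20) {
      p <- matrix(runif(18), 3, 6)
      side <- matrix(rep(sample(c(0, 1), 3, TRUE), 6), 3, 6)
      p <- p * 0.49 + side * 0.51  # strictly one side of 0.5 per row
      expect_equal(hard_vote(p)$label, soft_vote(p)$label)
    }
  })
})

test_that("tidy and glance summarize a fitted panel", {
  sp <- stratified_split(blobs, 0.8, seed = 1)
  model <- train_base_learners(sp$train, seed = 5)
  w <- derive_weights(model, sp$train, seed = 2, folds = 3)
  td <- tidy(model, weights = w)
  expect_equal(td$learner, base_learner_names())
  expect_equal(sum(td$weight), 1)
  gl <- glance(model)
  expect_equal(gl$n_learners, 6L)
  expect_equal(gl$n_train, nrow(sp$train))
})
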