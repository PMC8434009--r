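test_that("learned discriminant direction matches the closed-form Fisher solution", {
  set.seed(5)
  n <- 200
  A <- chol(matrix(c(1, 0.5, 0.5, 1), 2))
  x0 <- matrix(rnorm(2 * n), n) %*% A
  x1 <- sweep(matrix(rnorm(2 * n), n) %*% A, 2, c(2, 1), `+`)
  X <- rbind(x0, x1)
  arr <- array(X, dim = c(2 * n, 1, 2))  # 1 channel x 2 samples
  ep <- make_epochs(arr, is_target = rep(c(FALSE, TRUE), each = n))
  # closed-form oracle on the same sample: pooled covariance inverse times
  # the mean difference
  m0 <- colMeans(x0); m1 <- colMeans(x1)
  Sp <- (crossprod(sweep(x0, 2, m0)) + crossprod(sweep(x1, 2, m1))) / (2 * n)
  w_star <- solve(Sp, m1 - m0)
  for (reg in c("shrinkage", "pseudo-inverse")) {
    model <- train_lda(ep, regularization = reg)
    cosang <- sum(model$weights * w_star) /
      sqrt(sum(model$weights^2) * sum(w_star^2))
    expect_gt(cosang, cos(5 * pi / 180))
  }
})

test_that("no class signal means chance-level held-out accuracy", {
  set.seed(6)
  arr <- array(rnorm(400 * 2 * 5), dim = c(400, 2, 5))
  lab <- rep(c(TRUE, FALSE), 200)
  tr <- make_epochs(arr[1:200, , , drop = FALSE], is_target = lab[1:200])
  te <- make_epochs(arr[201:400, , , drop = FALSE], is_target = lab[201:400])
  model <- train_lda(tr)
  acc <- mean((score_epochs(model, te) > 0) == te$is_target)
  expect_lt(abs(acc - 0.5), 0.125)  # ~3.5 binomial SDs at n = 200
})

test_that("a linearly separable toy set is classified perfectly", {
  base <- rbind(c(2, 0), c(3, 1), c(2.5, -1), c(3.5, 0.5))
  X <- rbind(base, -base)
  ep <- make_epochs(array(X, dim = c(8, 1, 2)),
                    is_target = rep(c(TRUE, FALSE), each = 4))
  model <- train_lda(ep)
  expect_identical(score_epochs(model, ep) > 0, ep$is_target)
})

test_that("training refuses single-class input", {
  ep <- make_epochs(array(rnorm(20), dim = c(10, 1, 2)),
                    is_target = rep(TRUE, 10))
  expect_error(train_lda(ep), "both target and non-target")
})

test_that("epoch scores are the affine discriminant outputs", {
  set.seed(7)
  arr <- array(rnorm(5 * 2 * 3), dim = c(5, 2, 3))
  ep <- make_epochs(arr)
  zero_model <- structure(list(weights = rep(0, 6), bias = 2.5,
                               feature_shape = c(2L, 3L)), class = "bci_lda")
  expect_equal(score_epochs(zero_model, ep), rep(2.5, 5))
  w <- rnorm(6)
  m <- structure(list(weights = w, bias = 0, feature_shape = c(2L, 3L)),
                 class = "bci_lda")
  self <- make_epochs(array(w, dim = c(1, 2, 3)))
  expect_equal(score_epochs(m, self), sum(w^2))
  # concatenation of sets scores to the concatenation of scores
  both <- bind_epochs(ep, self)
  expect_equal(score_epochs(m, both), c(score_epochs(m, ep), score_epochs(m, self)))
  bad <- make_epochs(array(0, dim = c(1, 3, 3)))
  expect_error(score_epochs(m, bad), "shape")
})

test_that("selection decision sums per button, breaks ties low, flags gaps", {
  scores <- c(2, 2, rep(0, 12))
  buttons <- c(3, 3, rep(setdiff(0:6, 3), 2))
  res <- decide_selection(scores, buttons)
  expect_equal(res$predicted_button, 3L)
  expect_equal(unname(res$scores["3"]), 4)
  # exact tie between buttons 1 and 5 resolves to 1
  s2 <- rep(0, 7); s2[c(2, 6)] <- 5
  res2 <- decide_selection(s2, 0:6)
  expect_equal(res2$predicted_button, 1L)
  expect_error(decide_selection(1:6, 0:5), "button")
  # random scores agree with an independent per-button summation oracle
  set.seed(8)
  for (i in 1:20) {
    sc <- rnorm(140)
    bt <- sample(rep(0:6, 20))
    res3 <- decide_selection(sc, bt)
    sums <- tapply(sc, bt, sum)
    expect_equal(unname(res3$scores), as.numeric(sums[as.character(0:6)]))
    best <- as.integer(names(sums)[which.max(sums)])
    expect_equal(res3$predicted_button, best)
  }
})

test_that("decisions are invariant to positive scaling and per-epoch shifts", {
  set.seed(9)
  sc <- rnorm(70)
  bt <- sample(rep(0:6, 10))
  base <- decide_selection(sc, bt)$predicted_button
  expect_equal(decide_selection(3.7 * sc, bt)$predicted_button, base)
  expect_equal(decide_selection(sc + 11, bt)$predicted_button, base)  # equal counts
})

test_that("accuracy is the correct percentage at two decimals", {
  mk <- function(pred, true) {
    structure(list(predicted_button = as.integer(pred),
                   true_button = as.integer(true)), class = "bci_selection")
  }
  all_right <- lapply(1:15, function(i) mk(3, 3))
  expect_equal(evaluate_accuracy(all_right), 100.00)
  one_wrong <- c(lapply(1:14, function(i) mk(3, 3)), list(mk(1, 3)))
  expect_equal(evaluate_accuracy(one_wrong), 93.33)
  ten_right <- c(lapply(1:10, function(i) mk(2, 2)), lapply(1:5, function(i) mk(0, 2)))
  expect_equal(evaluate_accuracy(ten_right), 66.67)
  expect_error(evaluate_accuracy(list()), "no selection")
  expect_error(evaluate_accuracy(list(mk(1, NA))), "true_button")
})
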