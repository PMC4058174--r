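# small synthetic feature problem shared across blocks
make_problem <- function(n_pos, n_neg, delta = 0.3, seed = 1) {
  d <- generate_sequences(n_pos, n_neg, delta = delta, seed = seed)
  list(x = feature_matrix(d$records), y = d$labels)
}

test_that("initial negative weights are uniform and sum to one", {
  expect_equal(initial_weights(4), rep(0.25, 4))
  expect_equal(initial_weights(1), 1)
  expect_equal(sum(initial_weights(137)), 1)
  expect_error(initial_weights(0), "negative sample")
})

test_that("weighted negative sampling follows the distribution", {
  w <- c(0, 0, 1, 0)
  expect_equal(sample_negatives(w, 5, seed = 1), rep(3L, 5))
  idx <- sample_negatives(rep(1 / 8, 8), 20, seed = 2)
  expect_length(idx, 20L)
  expect_true(all(idx >= 1 & idx <= 8))
  expect_error(sample_negatives(rep(0.5, 2), 0), "at least 1")

  # Monte-Carlo: empirical frequencies within 3 standard errors
  w <- c(0.5, 0.3, 0.15, 0.05)
  n <- 100000
  freq <- tabulate(sample_negatives(w, n, seed = 3), 4) / n
  se <- sqrt(w * (1 - w) / n)
  expect_true(all(abs(freq - w) < 3 * se))
})

test_that("the weight-increase factor behaves as specified", {
  expect_equal(weight_factor(0.5, 100), 1)
  expect_equal(weight_factor(0.25, 100), log(300, base = 100))
  expect_equal(weight_factor(0.25, 100), 1.2386, tolerance = 1e-4)
  # clamping keeps f finite at the extremes
  expect_true(is.finite(weight_factor(0, 100)))
  expect_true(is.finite(weight_factor(1, 100)))
  expect_equal(weight_factor(0, 100), weight_factor(1 / 200, 100))
  # strictly decreasing in the error rate; >1 iff below chance
  eps <- seq(0.05, 0.95, by = 0.05)
  f <- vapply(eps, weight_factor, 0, size = 200)
  expect_true(all(diff(f) < 0))
  expect_true(all(f[eps < 0.5] > 1) && all(f[eps > 0.5] < 1))
  expect_error(weight_factor(0.3, 1), "at least 2")
})

test_that("weight updates inflate the misclassified and renormalize", {
  w <- rep(0.25, 4)
  expect_equal(update_weights(w, integer(0), 2), w)
  expect_equal(update_weights(w, 1:4, 3), w)       # uniform scaling cancels
  expect_equal(update_weights(c(0.5, 0.5), 1, 3), c(0.75, 0.25))
  expect_error(update_weights(w, 5, 2), "out of range")
})

test_that("a single-round ensemble reduces to its base learner", {
  p <- make_problem(20, 60, seed = 8)
  m <- unbalanced_adaboost(p$x, p$y, registry = tiny_registry(),
                           T = 1, seed = 4)
  expect_s3_class(m, "unbalanced_adaboost")
  expect_equal(m$T, 1L)
  pr <- predict(m, p$x)
  direct <- predict_base_learner(m$rounds[[1]]$fit, p$x)
  expect_equal(pr$label, direct)
  expect_equal(abs(pr$score), rep(1, nrow(p$x)))
})

test_that("training is reproducible and keeps the full weight history", {
  p <- make_problem(15, 80, seed = 9)
  m1 <- unbalanced_adaboost(p$x, p$y, registry = tiny_registry(),
                            T = 6, seed = 11)
  m2 <- unbalanced_adaboost(p$x, p$y, registry = tiny_registry(),
                            T = 6, seed = 11)
  expect_identical(m1$W, m2$W)
  expect_identical(predict(m1, p$x), predict(m2, p$x))
  expect_equal(dim(m1$W), c(7L, 80L))
  expect_equal(rowSums(m1$W), rep(1, 7))   # weight conservation
  # alphas finite and within the clamp
  a <- vapply(m1$rounds, `[[`, 0, "alpha")
  expect_true(all(is.finite(a) & a >= 0 & a <= 10))
})

test_that("misclassified negatives gain relative weight when f >= 1", {
  p <- make_problem(15, 60, seed = 10)
  m <- unbalanced_adaboost(p$x, p$y, registry = tiny_registry(),
                           T = 4, seed = 5)
  for (r in m$rounds) {
    if (r$f < 1) next
    t <- r$t
    ratio <- m$W[t + 1, ] / m$W[t, ]
    # all misclassified share one (maximal) ratio, correct ones a lower one
    expect_true(max(ratio) - min(ratio) >= 0 &&
                  all(abs(ratio - max(ratio)) < 1e-12 |
                        abs(ratio - min(ratio)) < 1e-12))
  }
})

test_that("weighted vote scores combine as alpha-weighted label averages", {
  # three constant voters via the majority-baseline learner
  vote_round <- function(t, label, alpha) {
    fit <- structure(list(kind = "zero_r", fit = list(label = label),
                          seed = 1L, colnames = c("f1", "f2")),
                     class = "dbp_base_fit")
    list(t = t, kind = "zero_r", fit = fit, alpha = alpha,
         eps = 0.5, f = 1, train_error = 0.5)
  }
  model <- structure(
    list(rounds = list(vote_round(1, 1, 2), vote_round(2, -1, 1),
                       vote_round(3, -1, 1)),
         T = 3L, T_requested = 3L, W = NULL, n_pos = 1, n_neg = 1,
         d = 2L, feature_names = c("f1", "f2"), vote = "weighted",
         seed = 1L, format_version = "1"),
    class = "unbalanced_adaboost")
  x <- matrix(0, nrow = 2, ncol = 2)
  pr <- predict(model, x)
  expect_equal(pr$score, c(0, 0))          # (2 - 1 - 1) / 4
  expect_equal(pr$label, c(-1, -1))        # tie -> negative class
  # unanimous positive vote
  model$rounds <- list(vote_round(1, 1, 2), vote_round(2, 1, 1))
  pr <- predict(model, x)
  expect_equal(pr$score, c(1, 1))
  expect_equal(pr$label, c(1, 1))
})

test_that("dimension mismatches are rejected with a clear message", {
  p <- make_problem(10, 30, seed = 12)
  m <- unbalanced_adaboost(p$x, p$y, registry = tiny_registry(),
                           T = 1, seed = 1)
  expect_error(predict(m, p$x[, 1:10]), "188")
})

test_that("degenerate inputs are rejected", {
  p <- make_problem(10, 30, seed = 13)
  expect_error(unbalanced_adaboost(p$x, rep(1, nrow(p$x)),
                                   registry = tiny_registry()),
               "negative")
  expect_error(unbalanced_adaboost(p$x, p$y, registry = list()),
               "registry")
  expect_error(unbalanced_adaboost(p$x, p$y, registry = tiny_registry(),
                                   T = 0), "at least 1")
})

test_that("model archives round-trip through save/load", {
  p <- make_problem(10, 30, seed = 14)
  m <- unbalanced_adaboost(p$x, p$y, registry = tiny_registry(),
                           T = 2, seed = 2)
  path <- withr::local_tempfile(fileext = ".rds")
  save_model(m, path)
  back <- load_model(path)
  expect_identical(predict(back, p$x), predict(m, p$x))
  saveRDS(list(), path)
  expect_error(load_model(path), "archive")
})
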