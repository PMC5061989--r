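test_that("fuzzy c-means recovers blob structure and normalises memberships", {
  # all points identical, one cluster
  same <- matrix(rep(c(2, -1), each = 10), 10, 2)
  f1 <- fcm_cluster(same, 1, seed = 1)
  expect_equal(unname(f1$centers[1, ]), c(2, -1), tolerance = 1e-9)

  # two tight blobs at 0 and 10: centres recovered within 0.2 of blob means
  set.seed(21)
  blob <- rbind(matrix(rnorm(60, 0, 0.1), 30, 2),
                matrix(rnorm(60, 10, 0.1), 30, 2))
  means <- rbind(colMeans(blob[1:30, ]), colMeans(blob[31:60, ]))
  f2 <- fcm_cluster(blob, 2, seed = 2)
  got <- f2$centers[order(f2$centers[, 1]), ]
  expect_lt(max(abs(got - means[order(means[, 1]), ])), 0.2)

  # membership rows sum to 1 on arbitrary data
  set.seed(22)
  X <- matrix(rnorm(80), 20, 4)
  f3 <- fcm_cluster(X, 3, seed = 3)
  expect_equal(rowSums(f3$memberships), rep(1, 20), tolerance = 1e-9)
  expect_true(all(f3$memberships >= 0 & f3$memberships <= 1))

  expect_error(fcm_cluster(X[1:2, ], 3), class = "fnnbci_too_few_points")
})

test_that("the FCM objective is non-increasing and the run is seeded", {
  set.seed(23)
  X <- matrix(rnorm(200), 50, 4)
  f <- fcm_cluster(X, 4, seed = 7)
  expect_true(all(diff(f$objective_trace) <= 1e-9))
  f2 <- fcm_cluster(X, 4, seed = 7)
  expect_identical(f$centers, f2$centers)
  expect_identical(f$iterations, f2$iterations)
})

test_that("FCM agrees with an independent implementation on separated blobs", {
  skip_if_not_installed("e1071")
  set.seed(24)
  blob <- rbind(matrix(rnorm(80, 0, 0.2), 40, 2),
                matrix(rnorm(80, 5, 0.2), 40, 2))
  ours <- fcm_cluster(blob, 2, seed = 5)
  set.seed(5)
  ref <- e1071::cmeans(blob, 2, m = 2, iter.max = 300)
  expect_lt(max(abs(ours$centers[order(ours$centers[, 1]), ] -
                    ref$centers[order(ref$centers[, 1]), ])), 0.05)
})

test_that("antecedent widths follow the nearest-centre rule", {
  # two centres at distance d, alpha = 0.5 -> all widths d/2
  fcm <- list(centers = rbind(c(0, 0), c(3, 4)), data_sd = c(1, 1))
  ants <- init_antecedents(fcm, alpha = 0.5, floor = 0.01)
  expect_equal(unname(ants$widths), matrix(2.5, 2, 2))
  expect_equal(ants$centers, t(fcm$centers))

  # coincident centres carry no scale: per-dimension data SD, floored
  co <- list(centers = rbind(c(1, 1), c(1, 1)), data_sd = c(0.02, 0.6))
  expect_equal(unname(init_antecedents(co, floor = 0.05)$widths),
               matrix(c(0.05, 0.6), 2, 2))
  # a near-duplicate neighbour is skipped in favour of the distinct one
  tri <- list(centers = rbind(c(0, 0), c(0, 0.001), c(0, 4)),
              data_sd = c(1, 1))
  expect_equal(unname(init_antecedents(tri)$widths[1, ]), c(2, 2, 2),
               tolerance = 1e-3)

  # single rule: per-dimension data standard deviation
  one <- list(centers = rbind(c(0, 0)), data_sd = c(0.3, 0.6))
  expect_equal(unname(init_antecedents(one)$widths),
               matrix(c(0.3, 0.6), 2, 1))
})

test_that("consequent initialisation is uniform on [-1,1] and seeded", {
  c1 <- init_consequents(10, 4, 3, seed = 42)
  c2 <- init_consequents(10, 4, 3, seed = 42)
  expect_identical(c1, c2)
  c3 <- init_consequents(10, 4, 3, seed = 43)
  expect_false(identical(c1$a, c3$a))
  all_vals <- c(c1$a, c1$b, c1$w)
  expect_true(all(all_vals >= -1 & all_vals <= 1))
  expect_identical(dim(c1$a), c(10L, 4L))
  expect_identical(dim(c1$w), c(4L, 3L))
})

test_that("the per-sample error is the half squared deviation", {
  expect_equal(sample_error(c(1, 0), c(1, 0)), 0)
  expect_equal(sample_error(c(0, 0), c(1, 0)), 0.5)
  set.seed(25)
  for (i in 1:10)
    expect_gte(sample_error(rnorm(4), rnorm(4)), 0)
})

test_that("analytic gradients match central differences on random instances", {
  set.seed(11)
  for (k in 1:20) {
    model <- random_model(3, 2, 2, seed = 100 + k)
    x <- runif(3)
    u_d <- runif(2)
    g <- fnn_gradients(x, u_d, model)
    analytic <- c(g$centers, g$widths, g$a, g$b, g$w)
    f <- function(p) sample_error(fnn_forward(x, unpack_model(model, p)), u_d)
    numeric_g <- numerical_gradient(f, pack_model(model))
    # relative where the gradient is appreciable, absolute near zero
    expect_lt(max(abs(analytic - numeric_g) / pmax(abs(numeric_g), 1e-3)),
              1e-5)
  }
})

test_that("gradients vanish at a perfect fit and mixing gradients have the right sign", {
  model <- random_model(3, 2, 2, seed = 31)
  x <- runif(3)
  u_d <- fnn_forward(x, model)                 # targets = current outputs
  g <- fnn_gradients(x, u_d, model)
  expect_lt(max(abs(c(g$centers, g$widths, g$a, g$b, g$w))), 1e-12)

  set.seed(32)
  for (i in 1:10) {
    model <- random_model(2, 3, 2, seed = 200 + i)
    x <- runif(2)
    u_d <- runif(2)
    g <- fnn_gradients(x, u_d, model)
    u <- fnn_forward(x, model)
    mu <- firing_strengths(x, model)
    y1 <- (mu / sum(mu)) * consequent_outputs(x, model)
    expected_sign <- sign(outer(y1, u - u_d))  # sign of (u_k - u_k^d) y1_j
    nonzero <- abs(g$w) > 1e-12
    expect_identical(sign(g$w)[nonzero], expected_sign[nonzero])
  }
})

test_that("training with zero epochs returns the initialised network", {
  fm <- scale_features(small_feature_set(duration_s = 10, k = 20))
  cfg <- training_config(epochs = 0, r = 3, seed = 5)
  fit <- fnn_train(fm, cfg)
  ants <- init_antecedents(fcm_cluster(fm$values, 3,
                                       seed = fnnbci:::sub_seed(5, "fcm")),
                           cfg$width_scale, cfg$width_floor)
  cons <- init_consequents(20, 3, 6, seed = fnnbci:::sub_seed(5, "init"))
  expect_equal(fit$model$centers, ants$centers)
  expect_equal(fit$model$a, cons$a)
  expect_identical(nrow(fit$history), 0L)
})

test_that("training is bitwise reproducible given a seed", {
  fm <- scale_features(small_feature_set(duration_s = 10, k = 20))
  cfg <- training_config(epochs = 40, r = 3, seed = 9)
  f1 <- fnn_train(fm, cfg)
  f2 <- fnn_train(fm, cfg)
  expect_identical(f1$history, f2$history)
  expect_identical(f1$model$centers, f2$model$centers)
  expect_identical(f1$model$w, f2$model$w)
})

test_that("recorded training RMSE never rises above its first-epoch value", {
  fm <- scale_features(small_feature_set(duration_s = 10, k = 20))
  for (seed in c(3, 17)) {
    h <- fnn_train(fm, training_config(epochs = 60, r = 4, seed = seed))$history
    expect_true(all(diff(h$train_rmse) <= 1e-12))
    expect_lte(h$train_rmse[nrow(h)], h$train_rmse[1])
  }
})

test_that("a same-shape network recovers a teacher's function", {
  ts <- make_teacher_student()
  lab_fm <- feature_matrix(ts$X, paste0("f", 1:ts$m))
  # regression targets, so drive the trainer core directly
  fcm <- fcm_cluster(ts$X, ts$r, seed = 5)
  ants <- init_antecedents(fcm)
  cons <- init_consequents(ts$m, ts$r, ts$n, seed = 6)
  set.seed(7)
  ord <- t(vapply(1:1000, function(e) sample.int(nrow(ts$X)),
                  integer(nrow(ts$X))))
  fit <- fnnbci:::fnn_train_cpp(ts$X, ts$U, matrix(0, 0, ts$m),
                                matrix(0, 0, ts$n), ants$centers,
                                ants$widths, cons$a, cons$b, cons$w, ord,
                                0.01, 0.9, 1.05, 0.7, 0.05, FALSE)
  expect_lt(tail(fit$train_rmse, 1), 0.05)
})

test_that("RMSE definitions are internally consistent", {
  expect_equal(rmse(c(1, 0), c(1, 0)), 0)
  expect_equal(rmse(0.5, 1), 0.5)
  set.seed(26)
  U <- matrix(rnorm(12), 4, 3)
  U_d <- matrix(rnorm(12), 4, 3)
  total_half_error <- sum(vapply(1:4, function(i)
    sample_error(U[i, ], U_d[i, ]), numeric(1)))
  expect_equal(rmse(U, U_d)^2 * 4 * 3 / 2, total_half_error)
})

test_that("cross-validation folds partition windows with balanced classes", {
  fm <- small_feature_set(duration_s = 10, k = 20)
  cfg <- training_config(epochs = 25, r = 3, seed = 2)
  cv <- cross_validate(fm, cfg, folds = 3)
  # every window tested exactly once
  expect_identical(sort(unique(cv$predictions$fold)), 1:3)
  expect_identical(nrow(cv$predictions), nrow(fm$values))
  # per-class fold sizes differ by at most 1
  sizes <- table(cv$predictions$truth, cv$predictions$fold)
  expect_true(all(apply(sizes, 1, function(s) diff(range(s))) <= 1))
  # accuracy consistent with the confusion matrix
  expect_equal(cv$accuracy, sum(diag(cv$confusion)) / sum(cv$confusion))
  expect_identical(cv$correct + cv$incorrect, nrow(fm$values))
  expect_identical(dim(cv$confusion), c(6L, 6L))
})

test_that("a class rarer than the fold count triggers a warning", {
  set.seed(27)
  vals <- matrix(rnorm(40), 20, 2)
  fm <- feature_matrix(vals, c("a", "b"),
                       labels = c(rep("x", 18), "y", "y"))
  w <- capture_warnings(
    cross_validate(fm, training_config(epochs = 2, r = 2, seed = 1),
                   folds = 5))
  expect_true(any(grepl("fewer than", w)))
})

test_that("training configuration validates its arguments", {
  expect_error(training_config(lambda = 1), class = "fnnbci_bad_config")
  expect_error(training_config(gamma = 0), class = "fnnbci_bad_config")
  expect_error(training_config(epochs = -1), class = "fnnbci_bad_config")
})
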