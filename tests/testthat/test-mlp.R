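toy_features <- function(n = 20, seed = 42, sep = 3) {
  # linearly separable two-class table on the first two features
  withr::with_seed(seed, {
    grades <- rep(c("benign", "grade5"), each = n)
    m <- matrix(rnorm(2 * n * 11), 2 * n, 11)
    colnames(m) <- histotex:::feature_names()
    m[grades == "grade5", 1:2] <- m[grades == "grade5", 1:2] + sep
    dplyr::bind_cols(
      tibble::tibble(id = sprintf("t%02d", seq_len(2 * n)),
                     label = factor(grades, levels = c("benign", "grade3",
                                                       "grade4", "grade5")),
                     level = 1L),
      tibble::as_tibble(m)
    )
  })
}

test_that("the forward pass squashes through sigmoid layers", {
  zero_net <- list(list(W = matrix(0, 2, 3), b = rep(0, 2)),
                   list(W = matrix(0, 2, 2), b = rep(0, 2)))
  expect_equal(mlp_forward(zero_net, c(1, -2, 3)), c(0.5, 0.5))
  one <- list(list(W = matrix(1, 1, 1), b = 0))
  expect_equal(mlp_forward(one, 1), 1 / (1 + exp(-1)), tolerance = 1e-12)
  net <- list(list(W = matrix(rnorm(6), 2, 3), b = rnorm(2)))
  x <- rnorm(3)
  expect_identical(mlp_forward(net, x), mlp_forward(net, x))
  expect_true(all(mlp_forward(net, x) > 0 & mlp_forward(net, x) < 1))
})

test_that("backpropagated gradients match central differences", {
  withr::with_seed(314, {
    for (rep in 1:5) {
      sizes <- c(sample(2:5, 1), sample(2:4, 1), sample(2:4, 1), 2)
      weights <- histotex:::init_mlp_weights(sizes)
      x <- rnorm(sizes[1])
      y <- as.numeric(sample(0:1, 2))
      acts <- histotex:::mlp_forward_pass(weights, x)
      analytic <- histotex:::mlp_gradients(weights, acts, y)
      numeric <- numeric_mlp_gradient(weights, x, y)
      for (l in seq_along(weights)) {
        denom <- max(abs(numeric[[l]]$W), 1e-8)
        expect_lt(max(abs(analytic[[l]]$W - numeric[[l]]$W)) / denom, 1e-6)
        expect_lt(max(abs(analytic[[l]]$b - numeric[[l]]$b)) /
                    max(abs(numeric[[l]]$b), 1e-8), 1e-6)
      }
    }
  })
})

test_that("training is reproducible and reduces the loss on separable data", {
  feats <- toy_features()
  cfg <- mlp_config(seed = 9, epochs = 300)
  fit1 <- mlp_fit(feats, "benign_vs_grade5", cfg)
  fit2 <- mlp_fit(feats, "benign_vs_grade5", cfg)
  expect_identical(fit1$weights, fit2$weights)
  expect_identical(fit1$metrics, fit2$metrics)
  # epoch-averaged loss trends down: late epochs beat early ones
  expect_lt(mean(tail(fit1$loss_trace, 30)), mean(head(fit1$loss_trace, 30)))
  expect_gt(fit1$metrics$accuracy, 90)
  # a different seed gives a different network
  fit3 <- mlp_fit(feats, "benign_vs_grade5", mlp_config(seed = 10,
                                                        epochs = 300))
  expect_false(identical(fit1$weights, fit3$weights))
})

test_that("the stratified split respects the 7:3 ratio and both classes", {
  fit <- mlp_fit(toy_features(n = 20), "benign_vs_grade5",
                 mlp_config(seed = 2, epochs = 5))
  expect_equal(fit$n_train, 28)
  expect_equal(fit$n_test, 12)
  expect_setequal(unique(fit$test$truth), c(0, 1))
  expect_error(
    mlp_fit(toy_features(n = 2), "benign_vs_grade5",
            mlp_config(seed = 2, epochs = 1, train_frac = 0.9)),
    "missing a class"
  )
})

test_that("contrast definitions cover the five published groupings", {
  ct <- grade_contrasts()
  expect_equal(nrow(ct), 5)
  for (i in seq_len(nrow(ct))) {
    expect_length(intersect(ct$positive[[i]], ct$negative[[i]]), 0)
  }
  expect_setequal(grade_contrasts("benign_vs_malignant")$positive[[1]],
                  c("grade3", "grade4", "grade5"))
  expect_setequal(grade_contrasts("grade3_vs_grade45")$positive[[1]],
                  c("grade4", "grade5"))
  expect_error(grade_contrasts("benign_vs_grade6"), "unknown contrast")
})

test_that("run_contrasts yields the 5 x 5 metrics table", {
  feats <- dplyr::filter(small_features(), level == 1)
  run <- run_contrasts(feats, mlp_config(seed = 3, epochs = 150))
  expect_equal(dim(run$metrics), c(5L, 6L))  # contrast + five metrics
  expect_setequal(names(run$metrics)[-1],
                  c("accuracy", "sensitivity", "specificity", "f1", "mcc"))
  expect_equal(run$metrics$contrast, grade_contrasts()$contrast)
  expect_true(all(run$metrics$accuracy >= 0 & run$metrics$accuracy <= 100))
  # seeded end-to-end reproducibility
  run2 <- run_contrasts(feats, mlp_config(seed = 3, epochs = 150))
  expect_equal(run$metrics, run2$metrics)
})

test_that("a saved model restores and predicts identically", {
  feats <- toy_features()
  fit <- mlp_fit(feats, "benign_vs_grade5", mlp_config(seed = 5, epochs = 50))
  path <- withr::local_tempfile(fileext = ".json")
  write_mlp(fit, path)
  back <- read_mlp(path)
  expect_equal(back$weights, fit$weights, tolerance = 1e-12)
  expect_equal(predict(back, feats, type = "score"),
               predict(fit, feats, type = "score"), tolerance = 1e-12)
  expect_equal(predict(back, feats), predict(fit, feats))
})

test_that("tidiers expose the loss trace and test metrics", {
  fit <- mlp_fit(toy_features(), "benign_vs_grade5",
                 mlp_config(seed = 1, epochs = 20))
  td <- tidy(fit)
  expect_equal(names(td), c("epoch", "loss"))
  expect_equal(nrow(td), 20)
  gl <- glance(fit)
  expect_equal(gl$contrast, "benign_vs_grade5")
  expect_true(all(c("accuracy", "mcc") %in% names(gl)))
})
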