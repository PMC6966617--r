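#' Multilayer perceptron configuration
#'
#' The default architecture is the 11-4-3-2 network: 11 input features, two
#' sigmoid hidden layers of 4 and 3 units, and a 2-unit sigmoid output layer
#' (one-hot binary coding). Training is per-sample stochastic gradient
#' descent on the squared error with a momentum term; weights are initialized
#' uniform(-0.5, 0.5) from the seed, and features are z-standardized using
#' training-split statistics.
#'
#' @param hidden Integer vector of hidden layer sizes.
#' @param learn_rate Learning rate eta (> 0); default 0.3.
#' @param momentum Momentum coefficient in \[0, 1); default 0.2.
#' @param epochs Training epochs; default 500.
#' @param train_frac Training fraction of the stratified split; default 0.7.
#' @param seed Integer seed for the split, class balancing, initialization
#'   and epoch shuffling.
#' @param balance If `TRUE` (default), subsample the majority class to the
#'   minority size before splitting, so imbalanced contrasts (e.g. benign vs
#'   the three malignant grades) train on balanced data.
#' @return A list of class `mlp_config`.
#' @export
mlp_config <- function(hidden = c(4, 3), learn_rate = 0.3, momentum = 0.2,
                       epochs = 500, train_frac = 0.7, seed = 1,
                       balance = TRUE) {
  if (learn_rate <= 0) stop("`learn_rate` must be > 0", call. = FALSE)
  if (momentum < 0 || momentum >= 1) {
    stop("`momentum` must be in [0, 1)", call. = FALSE)
  }
  if (train_frac <= 0 || train_frac >= 1) {
    stop("`train_frac` must be in (0, 1)", call. = FALSE)
  }
  structure(list(hidden = as.integer(hidden), learn_rate = learn_rate,
                 momentum = momentum, epochs = as.integer(epochs),
                 train_frac = train_frac, seed = as.integer(seed),
                 balance = isTRUE(balance)),
            class = "mlp_config")
}

#' The five binary grade contrasts
#'
#' Benign tissue corresponds to Gleason grades 1-2; grades 3-5 are malignant.
#' The five standard contrasts compare benign against malignant as a whole,
#' benign against each malignant grade, and grade 3 against grades 4/5. The
#' positive class is always the higher-grade (more malignant) side.
#'
#' @param name Optional single contrast name; if omitted all five are
#'   returned.
#' @return A tibble with `contrast`, `positive` (list of labels), `negative`
#'   (list of labels).
#' @export
grade_contrasts <- function(name = NULL) {
  tbl <- tibble(
    contrast = c("benign_vs_malignant", "benign_vs_grade3",
                 "benign_vs_grade4", "benign_vs_grade5",
                 "grade3_vs_grade45"),
    positive = list(c("grade3", "grade4", "grade5"), "grade3", "grade4",
                    "grade5", c("grade4", "grade5")),
    negative = list("benign", "benign", "benign", "benign", "grade3")
  )
  if (is.null(name)) {
    return(tbl)
  }
  out <- tbl[tbl$contrast == name, ]
  if (nrow(out) == 0) {
    stop("unknown contrast '", name, "'; see grade_contrasts()",
         call. = FALSE)
  }
  out
}

# --- network internals ------------------------------------------------------

sigmoid <- function(z) 1 / (1 + exp(-z))

init_mlp_weights <- function(sizes) {
  n_layers <- length(sizes) - 1
  lapply(seq_len(n_layers), function(l) {
    list(W = matrix(runif(sizes[l + 1] * sizes[l], -0.5, 0.5),
                    nrow = sizes[l + 1], ncol = sizes[l]),
         b = runif(sizes[l + 1], -0.5, 0.5))
  })
}

# forward pass for a single input vector; returns activations per layer
mlp_forward_pass <- function(weights, x) {
  acts <- vector("list", length(weights) + 1)
  acts[[1]] <- x
  for (l in seq_along(weights)) {
    z <- drop(weights[[l]]$W %*% acts[[l]]) + weights[[l]]$b
    acts[[l + 1]] <- sigmoid(z)
  }
  acts
}

# backprop of L = 0.5 * sum((a_out - y)^2); returns gradient lists
mlp_gradients <- function(weights, acts, y) {
  L <- length(weights)
  grads <- vector("list", L)
  a_out <- acts[[L + 1]]
  delta <- (a_out - y) * a_out * (1 - a_out)
  for (l in L:1) {
    grads[[l]] <- list(W = outer(delta, acts[[l]]), b = delta)
    if (l > 1) {
      a <- acts[[l]]
      delta <- drop(crossprod(weights[[l]]$W, delta)) * a * (1 - a)
    }
  }
  grads
}

# one pass of per-sample SGD with momentum over the rows of X (in `order`)
mlp_sgd_epoch <- function(weights, velocity, X, Y, order, eta, mom) {
  loss <- 0
  for (i in order) {
    acts <- mlp_forward_pass(weights, X[i, ])
    y <- Y[i, ]
    loss <- loss + 0.5 * sum((acts[[length(acts)]] - y)^2)
    grads <- mlp_gradients(weights, acts, y)
    for (l in seq_along(weights)) {
      velocity[[l]]$W <- mom * velocity[[l]]$W - eta * grads[[l]]$W
      velocity[[l]]$b <- mom * velocity[[l]]$b - eta * grads[[l]]$b
      weights[[l]]$W <- weights[[l]]$W + velocity[[l]]$W
      weights[[l]]$b <- weights[[l]]$b + velocity[[l]]$b
    }
  }
  list(weights = weights, velocity = velocity, loss = loss / length(order))
}

#' Forward pass of a fitted (or hand-built) network
#'
#' @param model An `mlp_fit` object, or a bare list of layers each holding
#'   `W` (matrix) and `b` (vector).
#' @param x Numeric feature vector (already on the scale the network was
#'   trained on; for an `mlp_fit`, raw features are standardized internally).
#' @return Numeric vector of output-layer scores in (0, 1); for the default
#'   two-output binary network, `c(negative, positive)` class scores.
#' @export
mlp_forward <- function(model, x) {
  if (inherits(model, "mlp_fit")) {
    x <- (x - model$center) / model$scale
    model <- model$weights
  }
  acts <- mlp_forward_pass(model, x)
  acts[[length(acts)]]
}

#' Train the MLP on one binary grade contrast
#'
#' Filters the feature table to the contrast's labels, optionally balances
#' the classes, performs a seeded stratified train/test split (default 7:3),
#' z-standardizes the features with training-split statistics, and trains the
#' network by per-sample stochastic gradient descent with momentum on the
#' squared error of one-hot targets.
#'
#' @param features Single-level feature tibble (see [extract_features()];
#'   filter to one `level` first, or pass `level`).
#' @param contrast A contrast name or one-row tibble from
#'   [grade_contrasts()].
#' @param config An [mlp_config()].
#' @param level Wavelet level to use if `features` holds several.
#' @param feature_cols Feature columns to train on; default the 11 standard
#'   features present in the table.
#' @return An object of class `mlp_fit`: weights, scaling, loss trace, the
#'   held-out test predictions (`$test` tibble with `id`, `truth`, `pred`,
#'   `score`), and the confusion counts and metrics on the test split.
#' @export
mlp_fit <- function(features, contrast, config = mlp_config(), level = NULL) {
  if (is.character(contrast)) contrast <- grade_contrasts(contrast)
  stopifnot(nrow(contrast) == 1)
  if ("level" %in% names(features)) {
    lv <- level %||% min(features$level)
    features <- dplyr::filter(features, .data$level == !!lv)
  }
  fn <- intersect(feature_names(), names(features))
  if (length(fn) == 0) stop("no feature columns found", call. = FALSE)

  pos <- contrast$positive[[1]]
  neg <- contrast$negative[[1]]
  df <- dplyr::filter(features, .data$label %in% c(pos, neg))
  df$y <- ifelse(as.character(df$label) %in% pos, 1L, 0L)

  withr::with_seed(config$seed, {
    # balance classes by subsampling the majority
    if (config$balance) {
      n_min <- min(table(df$y))
      df <- df |>
        dplyr::group_by(.data$y) |>
        dplyr::slice_sample(n = n_min) |>
        dplyr::ungroup()
    }
    # stratified 7:3 split
    idx <- seq_len(nrow(df))
    train_idx <- unlist(lapply(split(idx, df$y), function(ii) {
      sample(ii, round(length(ii) * config$train_frac))
    }), use.names = FALSE)
    test_idx <- setdiff(idx, train_idx)
    if (length(unique(df$y[train_idx])) < 2 ||
        length(unique(df$y[test_idx])) < 2) {
      stop("a split is missing a class; increase the cohort size",
           call. = FALSE)
    }

    X <- as.matrix(df[, fn])
    center <- colMeans(X[train_idx, , drop = FALSE])
    scale <- apply(X[train_idx, , drop = FALSE], 2, sd)
    scale[scale == 0] <- 1
    Xs <- sweep(sweep(X, 2, center), 2, scale, "/")
    Y <- cbind(1 - df$y, df$y)  # one-hot: (negative, positive)

    sizes <- c(length(fn), config$hidden, 2L)
    weights <- init_mlp_weights(sizes)
    velocity <- lapply(weights, function(w) {
      list(W = w$W * 0, b = w$b * 0)
    })
    loss_trace <- numeric(config$epochs)
    for (ep in seq_len(config$epochs)) {
      ord <- sample(train_idx)
      st <- mlp_sgd_epoch(weights, velocity, Xs, Y, ord,
                          config$learn_rate, config$momentum)
      weights <- st$weights
      velocity <- st$velocity
      loss_trace[ep] <- st$loss
    }
  })
  # drop the feature dimnames the updates pick up from the data matrix
  weights <- lapply(weights, function(w) list(W = unname(w$W), b = unname(w$b)))

  scores <- t(apply(Xs[test_idx, , drop = FALSE], 1, function(x) {
    acts <- mlp_forward_pass(weights, x)
    acts[[length(acts)]]
  }))
  # argmax over (negative, positive); ties go to the positive class
  pred <- as.integer(scores[, 2] >= scores[, 1])
  test <- tibble(id = df$id[test_idx], truth = df$y[test_idx],
                 pred = pred, score = scores[, 2])
  counts <- confusion_counts(test$truth, test$pred)

  structure(list(
    contrast = contrast$contrast, feature_cols = fn, config = config,
    weights = weights, center = center, scale = scale,
    loss_trace = loss_trace, n_train = length(train_idx),
    n_test = length(test_idx), test = test,
    confusion = counts, metrics = classification_metrics(counts)
  ), class = "mlp_fit")
}

#' @export
predict.mlp_fit <- function(object, newdata, type = c("class", "score"),
                            ...) {
  type <- match.arg(type)
  X <- as.matrix(newdata[, object$feature_cols])
  Xs <- sweep(sweep(X, 2, object$center), 2, object$scale, "/")
  scores <- t(apply(Xs, 1, function(x) {
    acts <- mlp_forward_pass(object$weights, x)
    acts[[length(acts)]]
  }))
  if (type == "score") {
    return(scores[, 2])
  }
  as.integer(scores[, 2] >= scores[, 1])
}

#' @export
print.mlp_fit <- function(x, ...) {
  sizes <- c(length(x$feature_cols), x$config$hidden, 2L)
  cat("MLP fit:", x$contrast, "\n")
  cat("  architecture:", paste(sizes, collapse = "-"),
      " epochs:", x$config$epochs,
      " eta:", x$config$learn_rate, " momentum:", x$config$momentum, "\n")
  cat("  train/test:", x$n_train, "/", x$n_test, "\n")
  m <- x$metrics
  cat(sprintf("  test accuracy %.1f%%, sensitivity %.1f%%, specificity %.1f%%\n",
              m$accuracy, m$sensitivity, m$specificity))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.mlp_fit <- function(x, ...) {
  tibble(epoch = seq_along(x$loss_trace), loss = x$loss_trace)
}

#' @exportS3Method generics::glance
glance.mlp_fit <- function(x, ...) {
  dplyr::bind_cols(tibble(contrast = x$contrast, n_train = x$n_train,
                          n_test = x$n_test), x$metrics)
}

#' Train and evaluate all five grade contrasts
#'
#' @inheritParams mlp_fit
#' @param contrasts Contrast tibble (default all five from
#'   [grade_contrasts()]).
#' @return An object of class `contrast_run`: list with `metrics` (tibble,
#'   one row per contrast with the five metrics in percent) and `fits`.
#' @export
run_contrasts <- function(features, config = mlp_config(), level = NULL,
                          contrasts = grade_contrasts()) {
  fits <- purrr::map(seq_len(nrow(contrasts)), function(i) {
    cfg <- config
    cfg$seed <- derive_seed(config$seed, 97L, i)
    mlp_fit(features, contrasts[i, ], config = cfg, level = level)
  })
  names(fits) <- contrasts$contrast
  metrics <- purrr::map_dfr(fits, glance) |>
    dplyr::select("contrast", "accuracy", "sensitivity", "specificity",
                  "f1", "mcc")
  structure(list(metrics = metrics, fits = fits), class = "contrast_run")
}

#' @export
print.contrast_run <- function(x, ...) {
  cat("MLP classification over", nrow(x$metrics), "binary contrasts\n\n")
  print(as.data.frame(x$metrics), row.names = FALSE, digits = 4)
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.contrast_run <- function(x, ...) x$metrics

#' Save / load a fitted MLP as JSON
#'
#' @param fit An `mlp_fit`.
#' @param path JSON file path.
#' @return `write_mlp()` invisibly returns `path`; `read_mlp()` returns the
#'   restored `mlp_fit` (weights, scaling, config, contrast; not the test
#'   predictions).
#' @export
write_mlp <- function(fit, path) {
  stopifnot(inherits(fit, "mlp_fit"))
  obj <- list(
    contrast = fit$contrast, feature_cols = fit$feature_cols,
    config = unclass(fit$config), center = fit$center, scale = fit$scale,
    weights = lapply(fit$weights, function(w) {
      list(W = w$W, b = w$b)
    })
  )
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_mlp
#' @export
read_mlp <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  weights <- lapply(seq_len(if (is.data.frame(obj$weights)) {
    nrow(obj$weights)
  } else {
    length(obj$weights)
  }), function(l) {
    w <- if (is.data.frame(obj$weights)) {
      list(W = obj$weights$W[[l]], b = obj$weights$b[[l]])
    } else {
      obj$weights[[l]]
    }
    list(W = as.matrix(w$W), b = as.numeric(w$b))
  })
  structure(list(
    contrast = obj$contrast, feature_cols = obj$feature_cols,
    config = do.call(mlp_config, obj$config[c("hidden", "learn_rate",
                                              "momentum", "epochs",
                                              "train_frac", "seed",
                                              "balance")]),
    weights = weights,
    center = stats::setNames(as.numeric(obj$center), obj$feature_cols),
    scale = stats::setNames(as.numeric(obj$scale), obj$feature_cols)
  ), class = "mlp_fit")
}
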