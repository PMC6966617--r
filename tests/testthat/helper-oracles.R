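# Independent brute-force oracles and shared fixtures.

# 2-D Haar level by explicit sums over non-overlapping 2x2 blocks
# (orthonormal: each output = (+-a +-b +-c +-d) / 2).
brute_haar_level <- function(x) {
  m <- nrow(x) / 2
  n <- ncol(x) / 2
  LL <- LH <- HL <- HH <- matrix(0, m, n)
  for (i in seq_len(m)) {
    for (j in seq_len(n)) {
      a <- x[2 * i - 1, 2 * j - 1]  # top-left
      b <- x[2 * i - 1, 2 * j]      # top-right
      c <- x[2 * i, 2 * j - 1]      # bottom-left
      d <- x[2 * i, 2 * j]          # bottom-right
      LL[i, j] <- (a + b + c + d) / 2
      LH[i, j] <- (a - b + c - d) / 2  # high along rows, low along columns
      HL[i, j] <- (a + b - c - d) / 2  # low along rows, high along columns
      HH[i, j] <- (a - b - c + d) / 2
    }
  }
  list(LL = LL, LH = LH, HL = HL, HH = HH)
}

# texture statistics by explicit double loop over GLCM cells
brute_glcm_stats <- function(P) {
  G <- nrow(P)
  px <- rowSums(P); py <- colSums(P)
  mu_x <- sum((0:(G - 1)) * px); mu_y <- sum((0:(G - 1)) * py)
  sd_x <- sqrt(sum(((0:(G - 1)) - mu_x)^2 * px))
  sd_y <- sqrt(sum(((0:(G - 1)) - mu_y)^2 * py))
  con <- hom <- ene <- ent <- dis <- 0
  cor_num <- 0
  for (i in 0:(G - 1)) {
    for (j in 0:(G - 1)) {
      p <- P[i + 1, j + 1]
      con <- con + abs(i - j)^2 * p
      hom <- hom + p / (1 + (i - j)^2)
      ene <- ene + p^2
      if (p > 0) ent <- ent - p * log(p)
      dis <- dis + abs(i - j) * p
      cor_num <- cor_num + p * (i - mu_x) * (j - mu_y)
    }
  }
  corr <- if (sd_x == 0 || sd_y == 0) NA_real_ else cor_num / (sd_x * sd_y)
  c(contrast = con, homogeneity = hom, correlation = corr,
    energy = ene, entropy = ent, dissimilarity = dis)
}

# one-way ANOVA F from explicit sums of squares
brute_anova_f <- function(y, g) {
  g <- factor(g)
  grand <- mean(y)
  ss_between <- sum(tapply(y, g, function(v) length(v) * (mean(v) - grand)^2))
  ss_within <- sum(tapply(y, g, function(v) sum((v - mean(v))^2)))
  df1 <- nlevels(g) - 1
  df2 <- length(y) - nlevels(g)
  (ss_between / df1) / (ss_within / df2)
}

# random normalized GLCM
random_glcm <- function(G, seed) {
  withr::with_seed(seed, {
    P <- matrix(stats::rexp(G * G), G, G)
    P / sum(P)
  })
}

# random feature table with 11 feature columns and the grade labels
random_feature_tbl <- function(n_per_class, seed, shift = 0) {
  grades <- c("benign", "grade3", "grade4", "grade5")
  withr::with_seed(seed, {
    rows <- do.call(rbind, lapply(seq_along(grades), function(k) {
      m <- matrix(rnorm(n_per_class * 11, mean = shift * k), n_per_class, 11)
      colnames(m) <- histotex:::feature_names()
      m
    }))
    dplyr::bind_cols(
      tibble::tibble(
        id = sprintf("s%03d", seq_len(nrow(rows))),
        label = factor(rep(grades, each = n_per_class), levels = grades),
        level = 1L
      ),
      tibble::as_tibble(rows)
    )
  })
}

# central-difference gradient of L = 0.5 * sum((forward(x) - y)^2) in every
# weight and bias of a bare layer list
numeric_mlp_gradient <- function(weights, x, y, eps = 1e-6) {
  loss <- function(w) {
    out <- mlp_forward(w, x)
    0.5 * sum((out - y)^2)
  }
  lapply(seq_along(weights), function(l) {
    gW <- weights[[l]]$W
    for (r in seq_len(nrow(gW))) {
      for (cc in seq_len(ncol(gW))) {
        wp <- weights; wp[[l]]$W[r, cc] <- wp[[l]]$W[r, cc] + eps
        wm <- weights; wm[[l]]$W[r, cc] <- wm[[l]]$W[r, cc] - eps
        gW[r, cc] <- (loss(wp) - loss(wm)) / (2 * eps)
      }
    }
    gb <- weights[[l]]$b
    for (r in seq_along(gb)) {
      wp <- weights; wp[[l]]$b[r] <- wp[[l]]$b[r] + eps
      wm <- weights; wm[[l]]$b[r] <- wm[[l]]$b[r] - eps
      gb[r] <- (loss(wp) - loss(wm)) / (2 * eps)
    }
    list(W = gW, b = gb)
  })
}

# small cohort shared across tests (computed once per run)
.fixture_env <- new.env(parent = emptyenv())

small_cohort <- function() {
  if (is.null(.fixture_env$small_cohort)) {
    .fixture_env$small_cohort <- generate_cohort(
      cohort_spec(images_per_grade = 8, image_size = 64, seed = 2024)
    )
  }
  .fixture_env$small_cohort
}

small_features <- function() {
  if (is.null(.fixture_env$small_features)) {
    .fixture_env$small_features <- extract_features(
      small_cohort(), levels = c(1, 2), glcm_levels = c(32, 16)
    )
  }
  .fixture_env$small_features
}

# the full-size two-class slice of the default study cohort (benign and
# grade5 at 100 images/grade, 256 px), with level-1 features; expensive, so
# cached for the acceptance tests
default_b5_features <- function() {
  if (is.null(.fixture_env$b5_features)) {
    cohort <- generate_cohort(cohort_spec(seed = 404))
    b5 <- dplyr::filter(cohort, label %in% c("benign", "grade5"))
    .fixture_env$b5_features <- extract_features(b5, levels = 1)
  }
  .fixture_env$b5_features
}
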