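worked_band <- matrix(c(0, 0, 1, 1,
                        0, 0, 1, 1,
                        0, 2, 2, 2,
                        2, 2, 3, 3), 4, 4, byrow = TRUE)

test_that("quantization maps the band range linearly onto the bins", {
  expect_true(all(quantize_band(matrix(5, 3, 3), 64) == 0))
  # full 8-bit range onto 128 bins collapses adjacent intensity pairs
  v <- matrix(0:255, 16, 16)
  q <- quantize_band(v, 128)
  expect_equal(as.vector(q)[1:255], floor((0:254) / 2))
  expect_equal(q[256], 127)
  # idempotent on already-binned input with matching G
  b <- matrix(c(0:15, 15:0), 4, 8)
  expect_equal(quantize_band(b, 16), b, ignore_attr = TRUE)
  expect_error(quantize_band(matrix(1, 2, 2), 1), ">= 2")
})

test_that("the hand-counted horizontal GLCM is reproduced", {
  g <- glcm(worked_band, direction = 0, levels = 4)
  expect_equal(g$n_pairs, 12)
  counts <- g$probs * 12
  expect_equal(counts[1, 1], 2)  # p(0,0)
  expect_equal(counts[1, 2], 2)  # p(0,1)
  expect_equal(counts[2, 2], 2)  # p(1,1)
  expect_equal(counts[1, 3], 1)  # p(0,2)
  expect_equal(counts[3, 3], 3)  # p(2,2)
  expect_equal(counts[3, 4], 1)  # p(2,3)
  expect_equal(counts[4, 4], 1)  # p(3,3)
  expect_equal(sum(counts), 12)
})

test_that("GLCMs are normalized joint distributions in every direction", {
  withr::with_seed(41, {
    band <- matrix(sample(0:7, 100, replace = TRUE), 10, 10)
    for (d in c(0, 45, 90, 135)) {
      g <- glcm(band, direction = d, levels = 8)
      expect_true(all(g$probs >= 0))
      expect_equal(sum(g$probs), 1)
    }
    # symmetric variant doubles the pair count and symmetrizes
    gs <- glcm(band, direction = 0, levels = 8, symmetric = TRUE)
    expect_equal(gs$probs, t(gs$probs))
  })
  const <- glcm(matrix(0L, 4, 4), direction = 90, levels = 4)
  expect_equal(const$probs[1, 1], 1)
  expect_equal(sum(const$probs), 1)
  expect_error(glcm(matrix(0L, 1, 1), direction = 0, levels = 2), "small")
  expect_error(glcm(worked_band, direction = 30, levels = 4), "direction")
})

test_that("texture statistics match their closed forms", {
  # degenerate single-entry distribution
  P <- matrix(0, 4, 4); P[1, 1] <- 1
  st <- glcm_stats(P)
  expect_equal(st$contrast, 0)
  expect_equal(st$homogeneity, 1)
  expect_equal(st$energy, 1)
  expect_equal(st$entropy, 0)
  expect_equal(st$dissimilarity, 0)
  expect_true(is.na(st$correlation))  # sigma_x = sigma_y = 0: undefined
  # the worked 4x4 example
  stw <- glcm_stats(glcm(worked_band, direction = 0, levels = 4))
  expect_equal(stw$energy, 1 / 6)
  expect_equal(stw$contrast, 7 / 12)
  # uniform diagonal
  G <- 8
  std <- glcm_stats(diag(G) / G)
  expect_equal(std$contrast, 0)
  expect_equal(std$homogeneity, 1)
  expect_equal(std$energy, 1 / G)
  expect_equal(std$entropy, log(G))
  expect_equal(std$correlation, 1)
  expect_equal(glcm_stats(diag(G) / G, log_base = 2)$entropy, log2(G))
})

test_that("statistics agree with the double-loop oracle on random GLCMs", {
  for (s in 1:20) {
    P <- random_glcm(8, seed = 500 + s)
    got <- glcm_stats(P)
    want <- brute_glcm_stats(P)
    expect_equal(unlist(got), want, tolerance = 1e-12)
  }
})

test_that("transposition preserves the symmetric statistics", {
  P <- random_glcm(8, seed = 77)
  a <- glcm_stats(P)
  b <- glcm_stats(t(P))
  for (f in c("contrast", "homogeneity", "energy", "entropy",
              "dissimilarity", "correlation")) {
    expect_equal(a[[f]], b[[f]])
  }
})

test_that("dissimilarity is bounded by the square root of contrast", {
  for (s in 1:25) {
    st <- glcm_stats(random_glcm(6, seed = 900 + s))
    expect_lte(st$dissimilarity, sqrt(st$contrast) + 1e-12)
  }
})

test_that("per-level aggregation averages the 16 band-direction statistics", {
  img <- array(rep(c(120L, 60L, 200L), each = 64), dim = c(8, 8, 3))
  pyr <- haar_decompose(rgb_to_gray(img), levels = 2)
  for (lv in 1:2) {
    tf <- texture_features(pyr, level = lv, glcm_levels = 4)
    expect_equal(tf$contrast, 0)
    expect_equal(tf$dissimilarity, 0)
    expect_equal(tf$entropy, 0)
    expect_equal(tf$homogeneity, 1)
    expect_equal(tf$energy, 1)
  }
  # the detail table has 16 rows and averages back to the aggregate
  pyr2 <- haar_decompose(matrix(runif(64, 0, 255), 8, 8), levels = 1)
  long <- texture_features(pyr2, level = 1, glcm_levels = 8, detail = TRUE)
  expect_equal(nrow(long), 16)
  agg <- texture_features(pyr2, level = 1, glcm_levels = 8)
  expect_equal(agg$contrast, mean(long$contrast))
  expect_equal(agg$correlation, mean(long$correlation, na.rm = TRUE))
})

test_that("synthetic grade5 texture is coarser than benign at level 1", {
  feats <- small_features() |> dplyr::filter(level == 1)
  con_b <- feats$contrast[feats$label == "benign"]
  con_5 <- feats$contrast[feats$label == "grade5"]
  expect_gt(mean(con_5), mean(con_b))
  pooled <- sqrt((var(con_b) + var(con_5)) / 2)
  d <- abs(mean(con_5) - mean(con_b)) / pooled
  expect_gt(d, 1)  # the class contrast the generator is built to provide
})
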