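#' Quantize a sub-band image to G gray levels
#'
#' Linearly maps the band's own \[min, max\] range onto the integer bins
#' `0 .. G-1` (detail sub-bands contain negative coefficients, so each band is
#' scaled from its own range). A constant band maps wholly to bin 0.
#' Quantization is idempotent: an image already holding the integers
#' `0 .. G-1` with full range is returned unchanged.
#'
#' @param band Numeric matrix.
#' @param levels Number of gray levels `G` (>= 2).
#' @return Integer matrix with values in `0 .. G-1`.
#' @examples
#' quantize_band(matrix(0:255, 16, 16), levels = 128)[1:4]
#' @export
quantize_band <- function(band, levels) {
  stopifnot_matrix(band, "band")
  if (levels < 2) stop("`levels` must be >= 2", call. = FALSE)
  r <- range(band)
  if (r[1] == r[2]) {
    q <- matrix(0L, nrow(band), ncol(band))
    return(q)
  }
  q <- floor((band - r[1]) / (r[2] - r[1]) * levels)
  q[q >= levels] <- levels - 1
  storage.mode(q) <- "integer"
  q
}

glcm_offset <- function(direction) {
  key <- as.character(direction)
  switch(key,
         "0"   = c(0L, 1L),
         "45"  = c(-1L, 1L),
         "90"  = c(-1L, 0L),
         "135" = c(-1L, -1L),
         stop("`direction` must be one of 0, 45, 90, 135 (degrees)",
              call. = FALSE))
}

#' Gray-level co-occurrence matrix
#'
#' Counts ordered (reference, neighbour) pairs of quantized gray levels at
#' unit distance in one of the four standard directions, with pixel offsets
#' 0 deg = (0, 1), 45 deg = (-1, 1), 90 deg = (-1, 0), 135 deg = (-1, -1)
#' (row, column); neighbours falling outside the image are excluded. Counts
#' are normalized by the total pair count, so all entries lie in \[0, 1\] and
#' sum to 1. The matrix is asymmetric (ordered pairs) by default.
#'
#' @param band Integer matrix of quantized bins (see [quantize_band()]), all
#'   values `< levels`.
#' @param direction One of 0, 45, 90, 135 (degrees).
#' @param levels Number of gray levels `G`; the matrix is `G x G`.
#' @param symmetric If `TRUE`, each pair is also counted in reverse order.
#' @return An object of class `glcm`: list with `probs` (G x G matrix),
#'   `levels`, `direction`, `n_pairs`.
#' @examples
#' m <- matrix(c(0, 0, 1, 1,
#'               0, 0, 1, 1,
#'               0, 2, 2, 2,
#'               2, 2, 3, 3), 4, 4, byrow = TRUE)
#' glcm(m, direction = 0, levels = 4)$probs * 12
#' @export
glcm <- function(band, direction = 0, levels, symmetric = FALSE) {
  stopifnot_matrix(band, "band")
  if (any(band < 0) || any(band >= levels)) {
    stop("`band` must hold integer bins in 0 .. levels-1", call. = FALSE)
  }
  off <- glcm_offset(direction)
  nr <- nrow(band); nc <- ncol(band)
  rows <- seq_len(nr)
  cols <- seq_len(nc)
  rr <- rows[rows + off[1] >= 1 & rows + off[1] <= nr]
  cc <- cols[cols + off[2] >= 1 & cols + off[2] <= nc]
  if (length(rr) == 0 || length(cc) == 0) {
    stop("image too small for the requested offset", call. = FALSE)
  }
  i <- band[rr, cc, drop = FALSE]
  j <- band[rr + off[1], cc + off[2], drop = FALSE]
  idx <- as.vector(i) * levels + as.vector(j) + 1
  counts <- tabulate(idx, nbins = levels * levels)
  if (symmetric) {
    counts <- counts + tabulate(as.vector(j) * levels + as.vector(i) + 1,
                                nbins = levels * levels)
  }
  probs <- matrix(counts / sum(counts), levels, levels, byrow = TRUE)
  structure(list(probs = probs, levels = levels, direction = direction,
                 n_pairs = length(i) * (1L + symmetric)),
            class = "glcm")
}

# cache of |i-j|, (i-j)^2 etc. weight matrices keyed by G
.glcm_weights <- new.env(parent = emptyenv())

glcm_weight_mats <- function(G) {
  key <- as.character(G)
  w <- .glcm_weights[[key]]
  if (is.null(w)) {
    d <- outer(0:(G - 1), 0:(G - 1), "-")
    w <- list(absd = abs(d), sqd = d^2, homo = 1 / (1 + d^2),
              i = matrix(0:(G - 1), G, G), j = matrix(0:(G - 1), G, G,
                                                      byrow = TRUE))
    .glcm_weights[[key]] <- w
  }
  w
}

#' Haralick-style texture statistics of a GLCM
#'
#' Computes contrast, homogeneity, correlation, energy, entropy and
#' dissimilarity from a normalized co-occurrence matrix `p(i, j)`:
#' contrast `= sum |i-j|^2 p`, homogeneity `= sum p / (1 + (i-j)^2)`,
#' correlation `= sum p (i - mu_x)(j - mu_y) / (sigma_x sigma_y)`,
#' energy `= sum p^2`, entropy `= -sum p log p` (natural log by default,
#' `0 log 0 = 0`), dissimilarity `= sum |i-j| p`.
#'
#' When either marginal standard deviation is zero the correlation is
#' undefined and returned as `NA` (never silently 0).
#'
#' @param x A `glcm` object or a normalized probability matrix.
#' @param log_base Base for the entropy logarithm (default `exp(1)`).
#' @return A one-row tibble with the six statistics.
#' @examples
#' glcm_stats(diag(4) / 4)  # uniform diagonal: correlation 1, entropy log 4
#' @export
glcm_stats <- function(x, log_base = exp(1)) {
  v <- glcm_stats_num(x, log_base)
  tibble::new_tibble(as.list(v), nrow = 1L)
}

# hot path: same statistics as a named numeric vector
glcm_stats_num <- function(x, log_base = exp(1)) {
  P <- if (inherits(x, "glcm")) x$probs else x
  stopifnot_matrix(P, "x")
  if (nrow(P) != ncol(P)) stop("GLCM must be square", call. = FALSE)
  G <- nrow(P)
  w <- glcm_weight_mats(G)
  px <- rowSums(P)
  py <- colSums(P)
  lev <- 0:(G - 1)
  mu_x <- sum(lev * px)
  mu_y <- sum(lev * py)
  sd_x <- sqrt(sum((lev - mu_x)^2 * px))
  sd_y <- sqrt(sum((lev - mu_y)^2 * py))
  corr <- if (sd_x == 0 || sd_y == 0) {
    NA_real_
  } else {
    sum(P * (w$i - mu_x) * (w$j - mu_y)) / (sd_x * sd_y)
  }
  nz <- P > 0
  c(contrast = sum(w$sqd * P),
    homogeneity = sum(w$homo * P),
    correlation = corr,
    energy = sum(P^2),
    entropy = -sum(P[nz] * log(P[nz], base = log_base)),
    dissimilarity = sum(w$absd * P))
}

#' Per-level aggregated GLCM texture features
#'
#' For each of the level's four sub-bands (LL, LH, HL, HH) and each of the
#' four directions (0, 45, 90, 135 degrees), the band is quantized to
#' `glcm_levels` gray levels and the six texture statistics are computed; each
#' statistic is then averaged over the 16 band-direction combinations,
#' yielding one 6-vector per image per level. Undefined correlations are
#' excluded from the correlation average. Default quantization follows the
#' sub-band side length of a 256-pixel patch: 128 levels at level 1, 64 at
#' level 2.
#'
#' @param pyramid A `wavelet_pyramid` from [haar_decompose()].
#' @param level 1 or 2.
#' @param glcm_levels Number of gray levels; default `128` for level 1,
#'   `64` for level 2.
#' @param detail If `TRUE`, return the per-band, per-direction long table
#'   instead of the aggregate.
#' @return A one-row tibble of the six averaged statistics, or the long
#'   tibble (`band`, `direction`, six statistics) when `detail = TRUE`.
#' @export
texture_features <- function(pyramid, level = 1, glcm_levels = NULL,
                             detail = FALSE) {
  stopifnot(inherits(pyramid, "wavelet_pyramid"))
  if (!level %in% c(1, 2)) stop("`level` must be 1 or 2", call. = FALSE)
  bands <- pyramid[[paste0("level", level)]]
  if (is.null(bands)) {
    stop("pyramid does not contain level ", level, call. = FALSE)
  }
  G <- glcm_levels %||% c(128L, 64L)[level]
  dirs <- c(0, 45, 90, 135)
  combos <- expand.grid(direction = dirs, band = names(bands),
                        stringsAsFactors = FALSE)
  qbands <- lapply(bands, quantize_band, levels = G)
  stats <- t(mapply(function(bn, d) {
    glcm_stats_num(glcm(qbands[[bn]], direction = d, levels = G))
  }, combos$band, combos$direction))
  if (detail) {
    return(dplyr::bind_cols(
      tibble(band = combos$band, direction = combos$direction),
      as_tibble(stats)
    ))
  }
  tibble::new_tibble(as.list(colMeans(stats, na.rm = TRUE)), nrow = 1L)
}
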