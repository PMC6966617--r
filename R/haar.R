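#' Convert an RGB patch to 8-bit grayscale
#'
#' Uses the standard luma weights 0.299 R + 0.587 G + 0.114 B, rounded half
#' away from zero to an integer in \[0, 255\].
#'
#' @param image Integer RGB array (`rows x cols x 3`, 8-bit).
#' @return An integer matrix of gray intensities.
#' @examples
#' img <- array(c(255, 0, 0), dim = c(1, 1, 3))  # pure red pixel
#' rgb_to_gray(img)  # 76
#' @export
rgb_to_gray <- function(image) {
  stopifnot_image(image)
  g <- 0.299 * image[, , 1] + 0.587 * image[, , 2] + 0.114 * image[, , 3]
  out <- floor(g + 0.5)  # values are non-negative
  storage.mode(out) <- "integer"
  out
}

haar_scale <- function(normalization) {
  switch(normalization, orthonormal = sqrt(2), average = 2,
         stop("`normalization` must be 'orthonormal' or 'average'",
              call. = FALSE))
}

#' One level of the 2-D Haar wavelet transform
#'
#' Separable filter-and-downsample over non-overlapping 2x2 blocks: the
#' two-tap low-pass (sum) and high-pass (difference) filters are applied along
#' rows, then along columns. With the default orthonormal normalization the
#' filter taps are (1, 1)/sqrt(2) and (1, -1)/sqrt(2), so the transform is
#' energy preserving (Parseval) and exactly invertible; `"average"` uses the
#' running-average taps (1, 1)/2 and (1, -1)/2 instead.
#'
#' Band naming: `LL` approximation, `LH` row-high/column-low (horizontal
#' detail), `HL` row-low/column-high (vertical detail), `HH` diagonal.
#' Conventions for "horizontal"/"vertical" differ across texts; here the
#' letters record (row filter, column filter).
#'
#' @param x Numeric matrix with even dimensions.
#' @param normalization `"orthonormal"` (default) or `"average"`.
#' @return Named list of four matrices `LL`, `LH`, `HL`, `HH`, each half the
#'   input size.
#' @examples
#' haar_level(matrix(1:4, 2, 2, byrow = TRUE))
#' @export
haar_level <- function(x, normalization = "orthonormal") {
  stopifnot_matrix(x)
  if (nrow(x) %% 2 != 0 || ncol(x) %% 2 != 0) {
    stop("haar_level() requires even dimensions", call. = FALSE)
  }
  s <- haar_scale(normalization)
  oc <- seq(1, ncol(x), by = 2)
  # filter along rows (adjacent column pairs)
  lo <- (x[, oc, drop = FALSE] + x[, oc + 1, drop = FALSE]) / s
  hi <- (x[, oc, drop = FALSE] - x[, oc + 1, drop = FALSE]) / s
  or <- seq(1, nrow(x), by = 2)
  # filter along columns (adjacent row pairs)
  list(
    LL = (lo[or, , drop = FALSE] + lo[or + 1, , drop = FALSE]) / s,
    LH = (hi[or, , drop = FALSE] + hi[or + 1, , drop = FALSE]) / s,
    HL = (lo[or, , drop = FALSE] - lo[or + 1, , drop = FALSE]) / s,
    HH = (hi[or, , drop = FALSE] - hi[or + 1, , drop = FALSE]) / s
  )
}

#' Invert one level of the 2-D Haar transform
#'
#' @param bands Named list `LL`, `LH`, `HL`, `HH` as returned by
#'   [haar_level()].
#' @inheritParams haar_level
#' @return The reconstructed matrix (exact up to floating-point rounding for
#'   `"orthonormal"`).
#' @export
haar_inverse <- function(bands, normalization = "orthonormal") {
  s <- haar_scale(normalization)
  inv <- if (normalization == "orthonormal") s / 2 else 1 / s * 2
  # undo the column filtering
  lo <- rbind_interleave((bands$LL + bands$HL) * inv,
                         (bands$LL - bands$HL) * inv)
  hi <- rbind_interleave((bands$LH + bands$HH) * inv,
                         (bands$LH - bands$HH) * inv)
  # undo the row filtering
  cbind_interleave((lo + hi) * inv, (lo - hi) * inv)
}

rbind_interleave <- function(a, b) {
  out <- matrix(0, nrow(a) * 2, ncol(a))
  out[seq(1, nrow(out), 2), ] <- a
  out[seq(2, nrow(out), 2), ] <- b
  out
}

cbind_interleave <- function(a, b) {
  out <- matrix(0, nrow(a), ncol(a) * 2)
  out[, seq(1, ncol(out), 2)] <- a
  out[, seq(2, ncol(out), 2)] <- b
  out
}

#' Multi-level Haar wavelet pyramid
#'
#' Level 1 decomposes the input; level 2 decomposes the level-1 approximation
#' band `LL1` (which is retained in the pyramid). A 256 x 256 input yields
#' 128 x 128 level-1 and 64 x 64 level-2 sub-bands.
#'
#' @param x Numeric matrix (typically from [rgb_to_gray()]); dimensions must
#'   be divisible by `2^levels`.
#' @param levels 1 or 2.
#' @inheritParams haar_level
#' @return An object of class `wavelet_pyramid`: a list with elements
#'   `level1` (and `level2` if requested), each a named list of the four
#'   sub-band matrices, plus the `normalization` used.
#' @examples
#' pyr <- haar_decompose(matrix(runif(64), 8, 8), levels = 2)
#' dim(pyr$level2$LL)
#' @export
haar_decompose <- function(x, levels = 2, normalization = "orthonormal") {
  stopifnot_matrix(x)
  if (!levels %in% c(1, 2)) {
    stop("`levels` must be 1 or 2", call. = FALSE)
  }
  if (any(c(nrow(x), ncol(x)) %% (2^levels) != 0)) {
    stop("image dimensions must be divisible by 2^levels", call. = FALSE)
  }
  pyr <- list(level1 = haar_level(x, normalization))
  if (levels == 2) {
    pyr$level2 <- haar_level(pyr$level1$LL, normalization)
  }
  pyr$normalization <- normalization
  structure(pyr, class = "wavelet_pyramid")
}

#' Write a pyramid's sub-bands as an 8-bit PNG mosaic
#'
#' Each band is min-max scaled independently; the mosaic mirrors the usual
#' nested wavelet layout (approximation top-left).
#'
#' @param pyramid A `wavelet_pyramid`.
#' @param path Output PNG path.
#' @return Invisibly, `path`.
#' @export
write_pyramid_png <- function(pyramid, path) {
  stopifnot(inherits(pyramid, "wavelet_pyramid"))
  scale01 <- function(m) {
    r <- range(m)
    if (r[1] == r[2]) matrix(0, nrow(m), ncol(m)) else (m - r[1]) / diff(r)
  }
  l1 <- lapply(pyramid$level1, scale01)
  top_left <- if (!is.null(pyramid$level2)) {
    l2 <- lapply(pyramid$level2, scale01)
    rbind(cbind(l2$LL, l2$LH), cbind(l2$HL, l2$HH))
  } else {
    l1$LL
  }
  mosaic <- rbind(cbind(top_left, l1$LH), cbind(l1$HL, l1$HH))
  png::writePNG(mosaic, path)
  invisible(path)
}
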