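#' Split an RGB patch into its three channels
#'
#' @param image Integer RGB array.
#' @return Named list of three integer matrices `R`, `G`, `B`.
#' @export
split_channels <- function(image) {
  stopifnot_image(image)
  out <- list(R = image[, , 1], G = image[, , 2], B = image[, , 3])
  lapply(out, function(m) {
    storage.mode(m) <- "integer"
    m
  })
}

#' Per-channel 256-bin colour histograms
#'
#' @param image Integer RGB array (8-bit).
#' @return A tibble with columns `channel` (R/G/B), `bin` (0-255), `count`;
#'   per-channel counts sum to the pixel count.
#' @export
colour_histogram <- function(image) {
  ch <- split_channels(image)
  purrr::map_dfr(names(ch), function(k) {
    tibble(channel = k, bin = 0:255,
           count = tabulate(as.vector(ch[[k]]) + 1L, nbins = 256))
  })
}

#' Colour percentage of each RGB channel
#'
#' Share of the total intensity mass carried by each channel:
#' `100 * sum(channel) / sum(all channels)`. The three percentages sum to
#' 100. For an all-black image the shares are undefined and returned as `NA`.
#' `method = "dominant"` instead counts, per channel, the pixels whose
#' largest component is that channel (ties split equally).
#'
#' @param image Integer RGB array.
#' @param method `"intensity"` (default) or `"dominant"`.
#' @return Named numeric vector `c(R =, G =, B =)` of percentages.
#' @examples
#' img <- array(rep(c(200, 100, 100), each = 4), dim = c(2, 2, 3))
#' colour_percentage(img)  # 50, 25, 25
#' @export
colour_percentage <- function(image, method = c("intensity", "dominant")) {
  stopifnot_image(image)
  method <- match.arg(method)
  if (method == "intensity") {
    sums <- c(R = sum(as.double(image[, , 1])),
              G = sum(as.double(image[, , 2])),
              B = sum(as.double(image[, , 3])))
    tot <- sum(sums)
    if (tot == 0) {
      warning("all-black image: colour percentages undefined")
      return(c(R = NA_real_, G = NA_real_, B = NA_real_))
    }
    return(sums / tot * 100)
  }
  flat <- matrix(image, ncol = 3)
  mx <- apply(flat, 1, max)
  is_max <- flat == mx
  shares <- is_max / rowSums(is_max)
  out <- colSums(shares) / nrow(flat) * 100
  names(out) <- c("R", "G", "B")
  out
}

#' Colour moments of one channel
#'
#' Population moments in the paper-facing root form: mean `sum(p)/N`,
#' variance `sum((p - mu)^2)/N`, standard deviation its square root, skewness
#' the *signed cube root* of the third central moment `sum((p - mu)^3)/N`,
#' and kurtosis the fourth root of `sum((p - mu)^4)/N` (hence always >= 0).
#' With `standardized = TRUE` the conventional dimensionless skewness
#' `m3/sd^3` and kurtosis `m4/sd^4` are returned instead.
#'
#' @param channel Numeric matrix or vector of pixel values.
#' @param standardized Use standardized moments instead of root forms.
#' @return One-row tibble: `mean`, `sd`, `variance`, `skewness`, `kurtosis`.
#' @examples
#' colour_moments(c(0, 2, 2, 4))  # mean 2, variance 2, kurtosis 8^(1/4)
#' @export
colour_moments <- function(channel, standardized = FALSE) {
  p <- as.double(channel)
  if (length(p) < 1) stop("channel must contain at least one pixel",
                          call. = FALSE)
  n <- length(p)
  mu <- sum(p) / n
  d <- p - mu
  m2 <- sum(d^2) / n
  m3 <- sum(d^3) / n
  m4 <- sum(d^4) / n
  if (standardized) {
    s <- sqrt(m2)
    skew <- if (s == 0) 0 else m3 / s^3
    kurt <- if (s == 0) 0 else m4 / s^4
  } else {
    skew <- sign(m3) * abs(m3)^(1 / 3)
    kurt <- m4^(1 / 4)
  }
  tibble(mean = mu, sd = sqrt(m2), variance = m2,
         skewness = skew, kurtosis = kurt)
}

#' Aggregated five-moment colour vector of a patch
#'
#' Computes the five colour moments per channel and averages each across R,
#' G and B, yielding the 5 colour features that join the 6 texture features
#' in the 11-dimensional record.
#'
#' @inheritParams split_channels
#' @inheritParams colour_moments
#' @param per_channel If `TRUE`, return the 3 x 5 per-channel long table
#'   instead of the channel average.
#' @return One-row tibble of the five averaged moments (or the long table).
#' @export
colour_vector <- function(image, standardized = FALSE, per_channel = FALSE) {
  ch <- split_channels(image)
  long <- purrr::map_dfr(names(ch), function(k) {
    dplyr::bind_cols(tibble(channel = k),
                     colour_moments(ch[[k]], standardized = standardized))
  })
  if (per_channel) {
    return(long)
  }
  dplyr::summarise(long, dplyr::across(
    c("mean", "sd", "variance", "skewness", "kurtosis"), mean
  ))
}
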