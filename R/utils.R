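# Shared internal helpers.

# Round half away from zero to `digits` decimals (the convention under which
# the published performance tables are self-consistent; base::round() rounds
# half to even and cannot reproduce e.g. 96.75 -> 96.8).
round_half_away <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# Truncate toward zero to `digits` decimals.
trunc_to <- function(x, digits = 1) {
  p <- 10^digits
  trunc(x * p) / p
}

# Derive a per-task RNG seed from a master seed and small integer indices,
# staying inside the 32-bit integer range.
derive_seed <- function(seed, ...) {
  idx <- c(...)
  s <- as.double(seed) %% 2147483647
  for (k in idx) {
    s <- (s * 48271 + as.double(k) * 1009 + 1) %% 2147483647
  }
  as.integer(s)
}

stopifnot_image <- function(img, arg = "image") {
  if (!is.array(img) || length(dim(img)) != 3L || dim(img)[3] != 3L) {
    stop("`", arg, "` must be an RGB array with dim c(rows, cols, 3)",
         call. = FALSE)
  }
  invisible(img)
}

stopifnot_matrix <- function(x, arg = "x") {
  if (!is.matrix(x) || !is.numeric(x)) {
    stop("`", arg, "` must be a numeric matrix", call. = FALSE)
  }
  invisible(x)
}
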