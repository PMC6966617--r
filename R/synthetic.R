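#' Default generator parameters for one tumour grade
#'
#' Parameters controlling the synthetic H&E-like patch generator for a single
#' grade class. The defaults encode the canonical histological progression:
#' going from benign tissue to Gleason grade 5, glands (near-white lumina)
#' shrink and fragment while nuclei (dark basophilic discs) become denser, and
#' the eosin-stained stroma darkens slightly. Gland radius is therefore
#' monotone decreasing and nuclei density monotone increasing across
#' `benign < grade3 < grade4 < grade5`.
#'
#' @param grade One of `"benign"`, `"grade3"`, `"grade4"`, `"grade5"`.
#' @param gland_radius_mean Mean lumen semi-axis in pixels.
#' @param gland_count_mean Mean number of gland lumina per patch.
#' @param nuclei_density Expected nuclei per 1000 px^2.
#' @param stroma_rgb_mean Length-3 vector, 8-bit mean stroma (eosin) colour.
#' @param nuclei_rgb_mean Length-3 vector, 8-bit mean nuclei (haematoxylin)
#'   colour.
#' @param noise_sd Standard deviation of the additive Gaussian pixel noise, in
#'   8-bit intensity units.
#' @return A list of class `grade_params`.
#' @examples
#' grade_params("benign")
#' grade_params("grade5")$nuclei_density
#' @export
grade_params <- function(grade = c("benign", "grade3", "grade4", "grade5"),
                         gland_radius_mean = NULL,
                         gland_count_mean = NULL,
                         nuclei_density = NULL,
                         stroma_rgb_mean = NULL,
                         nuclei_rgb_mean = NULL,
                         noise_sd = 8) {
  grade <- match.arg(grade)
  defaults <- list(
    benign = list(gland_radius_mean = 24, gland_count_mean = 7,
                  nuclei_density = 0.8,
                  stroma_rgb_mean = c(228, 172, 208),
                  nuclei_rgb_mean = c(72, 52, 122)),
    grade3 = list(gland_radius_mean = 14, gland_count_mean = 12,
                  nuclei_density = 1.8,
                  stroma_rgb_mean = c(218, 162, 202),
                  nuclei_rgb_mean = c(68, 50, 120)),
    grade4 = list(gland_radius_mean = 8, gland_count_mean = 16,
                  nuclei_density = 2.8,
                  stroma_rgb_mean = c(208, 152, 196),
                  nuclei_rgb_mean = c(64, 48, 118)),
    grade5 = list(gland_radius_mean = 4, gland_count_mean = 20,
                  nuclei_density = 4.0,
                  stroma_rgb_mean = c(198, 142, 190),
                  nuclei_rgb_mean = c(60, 46, 116))
  )[[grade]]
  p <- list(
    grade_label = grade,
    gland_radius_mean = gland_radius_mean %||% defaults$gland_radius_mean,
    gland_count_mean = gland_count_mean %||% defaults$gland_count_mean,
    nuclei_density = nuclei_density %||% defaults$nuclei_density,
    stroma_rgb_mean = stroma_rgb_mean %||% defaults$stroma_rgb_mean,
    nuclei_rgb_mean = nuclei_rgb_mean %||% defaults$nuclei_rgb_mean,
    noise_sd = noise_sd
  )
  validate_grade_params(p)
  structure(p, class = "grade_params")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

validate_grade_params <- function(p) {
  if (p$gland_radius_mean <= 0 || p$nuclei_density < 0 ||
      p$gland_count_mean < 0 || p$noise_sd < 0) {
    stop("grade_params: radii must be positive; counts, densities and ",
         "noise_sd must be non-negative", call. = FALSE)
  }
  rgb <- c(p$stroma_rgb_mean, p$nuclei_rgb_mean)
  if (length(p$stroma_rgb_mean) != 3L || length(p$nuclei_rgb_mean) != 3L ||
      any(rgb < 0) || any(rgb > 255)) {
    stop("grade_params: RGB means must be length-3 vectors in [0, 255]",
         call. = FALSE)
  }
  invisible(p)
}

#' Specification of a synthetic four-grade cohort
#'
#' @param images_per_grade Number of patches per grade class (default 100,
#'   i.e. a 400-image cohort split equally over the four classes).
#' @param image_size Side length in pixels; must be a positive multiple of 4
#'   so that two dyadic wavelet levels exist. Default 256.
#' @param seed Master seed; per-image seeds are derived deterministically from
#'   it together with the class and replicate index, so cohorts are
#'   reproducible and order-independent.
#' @param params Named list of four [grade_params()] objects
#'   (`benign`, `grade3`, `grade4`, `grade5`).
#' @return A list of class `cohort_spec`.
#' @export
cohort_spec <- function(images_per_grade = 100, image_size = 256, seed = 1,
                        params = NULL) {
  if (image_size <= 0 || image_size %% 4 != 0) {
    stop("`image_size` must be a positive multiple of 4", call. = FALSE)
  }
  if (images_per_grade < 1) {
    stop("`images_per_grade` must be >= 1", call. = FALSE)
  }
  grades <- c("benign", "grade3", "grade4", "grade5")
  params <- params %||% lapply(stats::setNames(grades, grades), grade_params)
  stopifnot(identical(sort(names(params)), sort(grades)))
  structure(list(images_per_grade = as.integer(images_per_grade),
                 image_size = as.integer(image_size),
                 seed = as.integer(seed), params = params[grades]),
            class = "cohort_spec")
}

#' Generate one synthetic H&E-like tissue patch
#'
#' Draws a pink stroma background, near-white elliptical gland lumina, and
#' dark nuclei discs, then adds Gaussian pixel noise clipped to \[0, 255\].
#' The generator targets the statistical contract the downstream pipeline
#' assumes — grade classes separable in both texture and colour — rather than
#' visual realism.
#'
#' @param params A [grade_params()] object.
#' @param size Patch side length in pixels (>= 16).
#' @param seed Integer seed; the patch is bit-identical for a fixed seed.
#' @return An integer array `size x size x 3` in \[0, 255\] with attributes
#'   `label` (the grade) and `nuclei_fraction` (fraction of pixels covered by
#'   nuclei discs before noise, the generator-side ground truth).
#' @examples
#' p <- generate_patch(grade_params("benign"), size = 64, seed = 7)
#' dim(p)
#' attr(p, "label")
#' @export
generate_patch <- function(params, size = 256, seed = 1) {
  validate_grade_params(params)
  if (size < 16) stop("`size` must be >= 16", call. = FALSE)
  withr::with_seed(as.integer(seed), {
    ch <- lapply(params$stroma_rgb_mean, function(m) {
      matrix(m, nrow = size, ncol = size)
    })

    # gland lumina: near-white ellipses
    n_gland <- rpois(1, params$gland_count_mean)
    lumen_rgb <- c(246, 242, 248)
    if (n_gland > 0) {
      for (g in seq_len(n_gland)) {
        cx <- runif(1, 1, size)
        cy <- runif(1, 1, size)
        a <- max(2, rnorm(1, params$gland_radius_mean,
                          params$gland_radius_mean / 4))
        b <- max(2, rnorm(1, params$gland_radius_mean,
                          params$gland_radius_mean / 4))
        th <- runif(1, 0, pi)
        mask <- ellipse_mask(size, cx, cy, a, b, th)
        for (k in 1:3) ch[[k]][mask] <- lumen_rgb[k]
      }
    }

    # nuclei: small dark discs
    n_nuc <- rpois(1, params$nuclei_density * size^2 / 1000)
    nuc_mask <- matrix(FALSE, size, size)
    if (n_nuc > 0) {
      for (g in seq_len(n_nuc)) {
        cx <- runif(1, 1, size)
        cy <- runif(1, 1, size)
        r <- runif(1, 2, 4)
        jit <- rnorm(3, 0, 6)
        mask <- ellipse_mask(size, cx, cy, r, r, 0)
        nuc_mask <- nuc_mask | mask
        for (k in 1:3) {
          ch[[k]][mask] <- min(255, max(0, params$nuclei_rgb_mean[k] + jit[k]))
        }
      }
    }
    nuclei_fraction <- mean(nuc_mask)

    img <- array(0, dim = c(size, size, 3))
    for (k in 1:3) {
      x <- ch[[k]]
      if (params$noise_sd > 0) {
        x <- x + rnorm(size^2, 0, params$noise_sd)
      }
      img[, , k] <- pmin(255, pmax(0, floor(x + 0.5)))
    }
    storage.mode(img) <- "integer"
    attr(img, "label") <- params$grade_label
    attr(img, "nuclei_fraction") <- nuclei_fraction
    img
  })
}

# Pixel mask of an ellipse centred at (cx, cy) with semi-axes a, b rotated
# by theta; only the bounding box is evaluated.
ellipse_mask <- function(size, cx, cy, a, b, theta) {
  r <- max(a, b)
  rows <- max(1, floor(cy - r)):min(size, ceiling(cy + r))
  cols <- max(1, floor(cx - r)):min(size, ceiling(cx + r))
  dy <- rows - cy
  dx <- cols - cx
  ct <- cos(theta); st <- sin(theta)
  # rotated coordinates on the bounding-box grid
  u <- outer(dy * st, dx * ct, "+")   # x' = x cos + y sin
  v <- outer(dy * ct, -dx * st, "+")  # y' = y cos - x sin
  inside <- (u / a)^2 + (v / b)^2 <= 1
  mask <- matrix(FALSE, size, size)
  mask[rows, cols] <- inside
  mask
}

#' Generate a labelled synthetic cohort
#'
#' @param spec A [cohort_spec()].
#' @return A tibble with one row per patch: `id`, `label` (factor with levels
#'   benign, grade3, grade4, grade5), `nuclei_fraction`, and an `image`
#'   list-column of integer RGB arrays. Exactly `images_per_grade` rows per
#'   class, in class order, replicates in order.
#' @examples
#' cohort <- generate_cohort(cohort_spec(images_per_grade = 2, image_size = 32))
#' dplyr::count(cohort, label)
#' @export
generate_cohort <- function(spec = cohort_spec()) {
  stopifnot(inherits(spec, "cohort_spec"))
  grades <- names(spec$params)
  rows <- purrr::map2_dfr(grades, seq_along(grades), function(g, gi) {
    purrr::map_dfr(seq_len(spec$images_per_grade), function(r) {
      s <- derive_seed(spec$seed, gi, r)
      img <- generate_patch(spec$params[[g]], size = spec$image_size, seed = s)
      tibble(
        id = sprintf("%s_%03d", g, r),
        label = g,
        nuclei_fraction = attr(img, "nuclei_fraction"),
        image = list(img)
      )
    })
  })
  rows$label <- factor(rows$label, levels = grades)
  rows
}

#' Write a cohort to disk as PNG files plus a labels manifest
#'
#' @param cohort A cohort tibble from [generate_cohort()] or [read_cohort()].
#' @param dir Output directory (created if absent).
#' @return Invisibly, the manifest tibble (`filename`, `label`).
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- purrr::map2_dfr(cohort$id, cohort$image, function(id, img) {
    fn <- paste0(id, ".png")
    png::writePNG(img / 255, file.path(dir, fn))
    tibble(filename = fn)
  })
  manifest$label <- as.character(cohort$label)
  write.csv(manifest, file.path(dir, "labels.csv"), row.names = FALSE)
  invisible(manifest)
}

#' Read a cohort written by [write_cohort()]
#'
#' @param dir Directory containing PNG patches and `labels.csv`.
#' @return A cohort tibble (without `nuclei_fraction`, which is
#'   generator-side ground truth and not recoverable from pixels).
#' @export
read_cohort <- function(dir) {
  manifest <- utils::read.csv(file.path(dir, "labels.csv"),
                              stringsAsFactors = FALSE)
  imgs <- purrr::map(manifest$filename, function(fn) {
    x <- png::readPNG(file.path(dir, fn))
    if (length(dim(x)) == 2L) x <- array(rep(x, 3), dim = c(dim(x), 3))
    img <- array(as.integer(floor(x[, , 1:3] * 255 + 0.5)), dim = dim(x)[1:3])
    img
  })
  tibble(
    id = sub("\\.png$", "", manifest$filename),
    label = factor(manifest$label,
                   levels = c("benign", "grade3", "grade4", "grade5")),
    image = imgs
  )
}
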