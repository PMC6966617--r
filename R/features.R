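feature_names <- function() {
  c("contrast", "homogeneity", "correlation", "energy", "entropy",
    "dissimilarity", "mean", "sd", "variance", "skewness", "kurtosis")
}

#' Build the per-image 11-feature table
#'
#' For every patch in the cohort and every requested wavelet level, computes
#' the six aggregated GLCM texture statistics over that level's sub-bands and
#' the five channel-averaged colour moments (which do not depend on the
#' wavelet level), giving one 11-feature row per image per level.
#'
#' Undefined GLCM correlations (a sub-band with zero marginal variance in all
#' 16 band-direction combinations) are imputed with the per-class mean of the
#' defined values and flagged in the `imputed` attribute.
#'
#' @param cohort Cohort tibble with `id`, `label` and `image` columns
#'   ([generate_cohort()] / [read_cohort()]).
#' @param levels Wavelet levels to extract, subset of `c(1, 2)`.
#' @param glcm_levels Length-2 vector of gray-level counts for levels 1 and 2
#'   (default `c(128, 64)`, the sub-band side lengths of a 256-pixel patch).
#' @param normalization Haar filter normalization, see [haar_level()].
#' @return Tibble with `id`, `label`, `level` and the 11 feature columns.
#' @export
extract_features <- function(cohort, levels = c(1, 2),
                             glcm_levels = c(128, 64),
                             normalization = "orthonormal") {
  stopifnot(all(levels %in% c(1, 2)), nrow(cohort) > 0)
  max_level <- max(levels)
  rows <- purrr::map2_dfr(cohort$id, seq_len(nrow(cohort)), function(id, k) {
    img <- cohort$image[[k]]
    gray <- rgb_to_gray(img)
    pyr <- haar_decompose(gray, levels = max_level,
                          normalization = normalization)
    colour <- colour_vector(img)
    purrr::map_dfr(levels, function(lv) {
      tex <- texture_features(pyr, level = lv, glcm_levels = glcm_levels[lv])
      dplyr::bind_cols(
        tibble(id = id, label = cohort$label[k], level = lv),
        tex, colour
      )
    })
  })
  impute_correlation(rows)
}

# replace NaN/NA correlations by the per-(label, level) mean; record which
impute_correlation <- function(rows) {
  bad <- !is.finite(rows$correlation)
  if (!any(bad)) {
    return(rows)
  }
  flagged <- rows[bad, c("id", "label", "level")]
  rows <- rows |>
    dplyr::group_by(.data$label, .data$level) |>
    dplyr::mutate(correlation = ifelse(
      is.finite(.data$correlation), .data$correlation,
      mean(.data$correlation[is.finite(.data$correlation)])
    )) |>
    dplyr::ungroup()
  attr(rows, "imputed") <- flagged
  rows
}

#' MANOVA / ANOVA significance screen of the feature table
#'
#' Runs a one-way MANOVA of the 11 features against the grade label (Pillai's
#' trace, with Wilks' lambda alongside, and the standard approximate F), plus
#' a univariate one-way ANOVA per feature. Features with univariate
#' `P < alpha` form the selected set. By default all features are *reported*
#' but none dropped (`select = FALSE`): the screen informs rather than
#' filters, since the full 11-feature vector is what the classifier consumes.
#'
#' If the feature table holds both wavelet levels the screen is run within
#' each level.
#'
#' @param features Feature tibble from [extract_features()].
#' @param alpha Significance threshold for the per-feature selection
#'   (default 0.05).
#' @param select If `TRUE`, `selected_features()` on the result (and
#'   downstream use of `$features`) keeps only significant features.
#' @return An object of class `feature_screen` with elements `anova`
#'   (per-level, per-feature F and P), `manova` (per-level Pillai/Wilks
#'   statistics), `alpha`, `select`.
#' @export
feature_screen <- function(features, alpha = 0.05, select = FALSE) {
  fn <- feature_names()
  stopifnot(all(fn %in% names(features)), "label" %in% names(features))
  if (!"level" %in% names(features)) features$level <- 1L
  lv_split <- split(features, features$level)

  res <- purrr::map(lv_split, function(df) {
    g <- droplevels(factor(df$label))
    if (nlevels(g) < 2 || any(table(g) < 2)) {
      stop("feature_screen() needs >= 2 groups with >= 2 records each",
           call. = FALSE)
    }
    Y <- as.matrix(df[, fn])
    uni <- purrr::map_dfr(fn, function(f) {
      fit <- aov(df[[f]] ~ g)
      s <- summary(fit)[[1]]
      tibble(feature = f, f_value = s$`F value`[1], p_value = s$`Pr(>F)`[1])
    })
    mv <- tryCatch({
      fit <- manova(Y ~ g)
      pil <- summary(fit, test = "Pillai")$stats
      wlk <- summary(fit, test = "Wilks")$stats
      tibble(
        statistic = c("Pillai", "Wilks"),
        value = c(pil[1, "Pillai"], wlk[1, "Wilks"]),
        approx_f = c(pil[1, "approx F"], wlk[1, "approx F"]),
        p_value = c(pil[1, "Pr(>F)"], wlk[1, "Pr(>F)"])
      )
    }, error = function(e) {
      warning("MANOVA failed (", conditionMessage(e),
              "); falling back to the univariate screen", call. = FALSE)
      NULL
    })
    list(anova = uni, manova = mv)
  })

  anova_tbl <- purrr::imap_dfr(res, function(r, lv) {
    dplyr::bind_cols(tibble(level = as.integer(lv)), r$anova)
  })
  anova_tbl$selected <- anova_tbl$p_value < alpha
  manova_tbl <- purrr::imap_dfr(res, function(r, lv) {
    if (is.null(r$manova)) return(tibble())
    dplyr::bind_cols(tibble(level = as.integer(lv)), r$manova)
  })
  structure(list(anova = anova_tbl, manova = manova_tbl,
                 alpha = alpha, select = select),
            class = "feature_screen")
}

#' Features retained by a screen
#'
#' @param screen A `feature_screen`.
#' @param level Wavelet level to query (default 1).
#' @return Character vector of feature names: all 11 when the screen was run
#'   with `select = FALSE`, otherwise those with `P < alpha`.
#' @export
selected_features <- function(screen, level = 1) {
  stopifnot(inherits(screen, "feature_screen"))
  tbl <- dplyr::filter(screen$anova, .data$level == !!level)
  if (!screen$select) {
    return(tbl$feature)
  }
  tbl$feature[tbl$selected]
}

#' @exportS3Method generics::tidy
tidy.feature_screen <- function(x, ...) x$anova

#' @exportS3Method generics::glance
glance.feature_screen <- function(x, ...) {
  dplyr::filter(x$manova, .data$statistic == "Pillai") |>
    dplyr::select("level", pillai = "value", "approx_f", "p_value")
}

#' @export
print.feature_screen <- function(x, ...) {
  cat("Feature significance screen (alpha =", x$alpha, ")\n")
  if (nrow(x$manova)) {
    cat("\nMANOVA:\n")
    print(as.data.frame(x$manova), row.names = FALSE)
  }
  cat("\nPer-feature one-way ANOVA:\n")
  print(as.data.frame(x$anova), row.names = FALSE)
  invisible(x)
}
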