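#' Confusion counts of a binary prediction
#'
#' @param truth,pred Equal-length vectors coercible to 0/1 (1 = positive).
#' @param positive Value treated as the positive class (default `1`).
#' @return One-row tibble of non-negative integers `tp`, `fn`, `fp`, `tn`.
#' @export
confusion_counts <- function(truth, pred, positive = 1) {
  if (length(truth) != length(pred)) {
    stop("`truth` and `pred` must have the same length", call. = FALSE)
  }
  t1 <- truth == positive
  p1 <- pred == positive
  tibble(
    tp = sum(t1 & p1), fn = sum(t1 & !p1),
    fp = sum(!t1 & p1), tn = sum(!t1 & !p1)
  )
}

#' The five classification performance metrics
#'
#' Computes accuracy, sensitivity (recall), specificity, F1-score and
#' Matthews correlation coefficient from the four confusion counts, all as
#' percentages (MCC in \[-100, 100\], the rest in \[0, 100\]):
#' \deqn{Accuracy = (TP+TN)/(TP+TN+FP+FN) \times 100}
#' \deqn{Sensitivity = TP/(TP+FN),\quad Specificity = TN/(TN+FP)}
#' \deqn{F1 = 2 \cdot Prec \cdot Rec / (Prec + Rec), \quad Prec = TP/(TP+FP)}
#' \deqn{MCC = (TP \cdot TN - FP \cdot FN)/\sqrt{(TP+FN)(TP+FP)(TN+FN)(TN+FP)}}
#' A metric whose denominator is zero is reported as `NA`, never silently 0.
#'
#' @param counts One-row tibble/list with `tp`, `fn`, `fp`, `tn` (as from
#'   [confusion_counts()]); alternatively give the four counts separately.
#' @param tp,fn,fp,tn Optional separate counts.
#' @return One-row tibble: `accuracy`, `sensitivity`, `specificity`, `f1`,
#'   `mcc`, in percent.
#' @examples
#' classification_metrics(tp = 29, fn = 0, fp = 1, tn = 30)
#' @export
classification_metrics <- function(counts = NULL, tp = NULL, fn = NULL,
                                   fp = NULL, tn = NULL) {
  if (is.null(counts)) counts <- list(tp = tp, fn = fn, fp = fp, tn = tn)
  tp <- as.double(counts$tp); fn <- as.double(counts$fn)
  fp <- as.double(counts$fp); tn <- as.double(counts$tn)
  if (any(c(tp, fn, fp, tn) < 0)) {
    stop("confusion counts must be non-negative", call. = FALSE)
  }
  total <- tp + fn + fp + tn
  if (total == 0) stop("empty confusion matrix", call. = FALSE)
  safe_div <- function(num, den) if (den == 0) NA_real_ else num / den
  sens <- safe_div(tp, tp + fn)
  spec <- safe_div(tn, tn + fp)
  prec <- safe_div(tp, tp + fp)
  f1 <- if (is.na(prec) || is.na(sens) || prec + sens == 0) {
    NA_real_
  } else {
    2 * prec * sens / (prec + sens)
  }
  mcc_den <- sqrt((tp + fn) * (tp + fp) * (tn + fn) * (tn + fp))
  mcc <- if (mcc_den == 0) NA_real_ else (tp * tn - fp * fn) / mcc_den
  tibble(accuracy = (tp + tn) / total * 100,
         sensitivity = sens * 100, specificity = spec * 100,
         f1 = f1 * 100, mcc = mcc * 100)
}

#' Recover integer confusion counts from printed metrics
#'
#' Published performance tables usually print accuracy, sensitivity and
#' specificity to one decimal but not the underlying confusion matrix. This
#' audit utility searches every integer matrix
#' `(TP, FN, FP, TN)` with `TP+FN+FP+TN = total` whose recomputed three
#' metrics round to the printed values, and reports the unique solution or
#' the full candidate set.
#'
#' Two rounding conventions are supported: `"half_away"` (round half away
#' from zero, the default) and `"truncate"` (toward zero); published tables
#' are not always consistent about which they used, so an inconsistent row
#' under one convention is worth re-checking under the other.
#'
#' @param accuracy,sensitivity,specificity Printed percentages (one decimal).
#' @param total Total test-set size (<= 200).
#' @param rounding `"half_away"` or `"truncate"`.
#' @param digits Decimals the table was printed to (default 1).
#' @return A tibble of candidate matrices (`tp`, `fn`, `fp`, `tn`) with their
#'   exact recomputed five metrics, and attributes `unique` (logical) and
#'   `n_candidates`. Zero rows mean the printed triple is inconsistent with
#'   every integer matrix of that total.
#' @examples
#' infer_confusion(98.3, 100.0, 96.8, total = 60)  # unique: 29/0/1/30
#' @export
infer_confusion <- function(accuracy, sensitivity, specificity, total,
                            rounding = c("half_away", "truncate"),
                            digits = 1) {
  rounding <- match.arg(rounding)
  if (total < 2 || total > 200) {
    stop("`total` must be in [2, 200]", call. = FALSE)
  }
  rnd <- if (rounding == "half_away") {
    function(x) round_half_away(x, digits)
  } else {
    function(x) trunc_to(x, digits)
  }
  eq <- function(a, b) abs(a - b) < 10^(-digits) / 2 * 1e-6 + 1e-9

  # grid over P = TP+FN; sensitivity fixes candidate TPs, specificity TNs
  out <- purrr::map_dfr(seq_len(total - 1), function(P) {
    N <- total - P
    tp <- 0:P
    tp <- tp[eq(rnd(tp / P * 100), sensitivity)]
    tn <- 0:N
    tn <- tn[eq(rnd(tn / N * 100), specificity)]
    if (length(tp) == 0 || length(tn) == 0) return(tibble())
    grid <- expand.grid(tp = tp, tn = tn)
    acc <- (grid$tp + grid$tn) / total * 100
    grid <- grid[eq(rnd(acc), accuracy), , drop = FALSE]
    if (nrow(grid) == 0) return(tibble())
    tibble(tp = grid$tp, fn = P - grid$tp, fp = N - grid$tn, tn = grid$tn)
  })
  if (nrow(out) > 0) {
    out <- dplyr::bind_cols(out, purrr::pmap_dfr(out, function(tp, fn, fp, tn) {
      classification_metrics(tp = tp, fn = fn, fp = fp, tn = tn)
    }))
  }
  attr(out, "unique") <- nrow(out) == 1
  attr(out, "n_candidates") <- nrow(out)
  out
}

#' Format a metrics table the way published tables print it
#'
#' @param metrics Tibble with the five metric columns (percent).
#' @param digits Decimals (default 1); rounding is half away from zero.
#' @return The tibble with metric columns rounded.
#' @export
format_metrics <- function(metrics, digits = 1) {
  cols <- intersect(c("accuracy", "sensitivity", "specificity", "f1", "mcc"),
                    names(metrics))
  dplyr::mutate(metrics,
                dplyr::across(dplyr::all_of(cols),
                              ~ round_half_away(.x, digits)))
}
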