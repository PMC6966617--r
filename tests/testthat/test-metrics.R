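test_that("confusion counting is exact and convention-symmetric", {
  truth <- rep(c(1, 0), each = 10)
  expect_equal(unlist(confusion_counts(truth, truth)),
               c(tp = 10, fn = 0, fp = 0, tn = 10))
  expect_equal(unlist(confusion_counts(truth, rep(1, 20))),
               c(tp = 10, fn = 0, fp = 10, tn = 0))
  withr::with_seed(6, {
    pred <- sample(0:1, 20, replace = TRUE)
    a <- confusion_counts(truth, pred, positive = 1)
    b <- confusion_counts(truth, pred, positive = 0)
    expect_equal(c(a$tp, a$fn, a$fp, a$tn), c(b$tn, b$fp, b$fn, b$tp))
  })
  expect_error(confusion_counts(truth, 1), "length")
})

test_that("the five metrics reproduce the published worked rows", {
  # benign vs grade 5, level 1: printed 98.3 / 100.0 / 96.8 / 98.3 / 96.7
  m <- classification_metrics(tp = 29, fn = 0, fp = 1, tn = 30)
  printed <- c(98.3, 100.0, 96.8, 98.3, 96.7)
  expect_true(all(abs(unlist(m) - printed) <= 0.05 + 1e-9))
  # benign vs malignant, level 1: printed 95.0 / 96.5 / 93.5 / 94.9 / 90.0;
  # the exact sensitivity and MCC (96.552, 90.050) sit within one unit of
  # the last printed digit
  m2 <- classification_metrics(tp = 28, fn = 1, fp = 2, tn = 29)
  printed2 <- c(95.0, 96.5, 93.5, 94.9, 90.0)
  expect_true(all(abs(unlist(m2) - printed2) <= 0.1 + 1e-9))
  expect_equal(m2$accuracy, 95)
  # pure chance
  m3 <- classification_metrics(tp = 5, fn = 5, fp = 5, tn = 5)
  expect_equal(m3$accuracy, 50)
  expect_equal(m3$mcc, 0)
})

test_that("zero denominators yield missing metrics, not zeros or errors", {
  m <- classification_metrics(tp = 0, fn = 0, fp = 2, tn = 8)
  expect_true(is.na(m$sensitivity))
  expect_true(is.na(m$f1))
  expect_true(is.na(m$mcc))
  expect_equal(m$specificity, 80)
  expect_error(classification_metrics(tp = 0, fn = 0, fp = 0, tn = 0),
               "empty")
  expect_error(classification_metrics(tp = -1, fn = 0, fp = 0, tn = 1),
               "non-negative")
})

test_that("accuracy is the prevalence-weighted mean of sens and spec", {
  withr::with_seed(9, {
    for (i in 1:20) {
      cts <- as.list(stats::setNames(sample(1:30, 4), c("tp","fn","fp","tn")))
      m <- classification_metrics(cts)
      P <- cts$tp + cts$fn; N <- cts$fp + cts$tn
      expect_equal(m$accuracy,
                   (m$sensitivity * P + m$specificity * N) / (P + N))
      # F1 lies between precision and recall
      prec <- 100 * cts$tp / (cts$tp + cts$fp)
      rec <- m$sensitivity
      expect_gte(m$f1, min(prec, rec) - 1e-9)
      expect_lte(m$f1, max(prec, rec) + 1e-9)
    }
  })
})

test_that("MCC vanishes exactly when truth and prediction are independent", {
  # all confusion matrices with total <= 20 and proportional rows
  for (total in 4:20) {
    for (tp in 0:total) for (fn in 0:(total - tp)) {
      for (fp in 0:(total - tp - fn)) {
        tn <- total - tp - fn - fp
        if (tp * tn == fp * fn) {
          m <- classification_metrics(tp = tp, fn = fn, fp = fp, tn = tn)
          if (!is.na(m$mcc)) expect_equal(m$mcc, 0)
        }
      }
    }
  }
})

test_that("unique confusion matrices are recovered from printed metrics", {
  got <- infer_confusion(98.3, 100.0, 96.8, total = 60)
  expect_true(attr(got, "unique"))
  expect_equal(unlist(got[, c("tp", "fn", "fp", "tn")]),
               c(tp = 29, fn = 0, fp = 1, tn = 30))
  # under truncation-rounding this published row also resolves uniquely
  got2 <- infer_confusion(95.0, 93.5, 96.5, total = 60, rounding = "truncate")
  expect_true(attr(got2, "unique"))
  expect_equal(unlist(got2[, c("tp", "fn", "fp", "tn")]),
               c(tp = 29, fn = 2, fp = 1, tn = 28))
})

test_that("degenerate or inconsistent printed rows are flagged", {
  perfect <- infer_confusion(100, 100, 100, total = 60)
  expect_false(attr(perfect, "unique"))
  expect_equal(attr(perfect, "n_candidates"), 59)  # every P split, FP=FN=0
  expect_true(all(perfect$fn == 0 & perfect$fp == 0))
  # the published grade3 vs grade4/5 row admits no n=60 matrix
  none <- infer_confusion(85.0, 95.4, 76.9, total = 60)
  expect_equal(attr(none, "n_candidates"), 0)
  expect_error(infer_confusion(90, 90, 90, total = 500), "200")
})

test_that("metrics -> inference -> metrics round-trips integer matrices", {
  withr::with_seed(123, {
    for (i in 1:30) {
      total <- sample(20:100, 1)
      tp <- sample(0:total, 1)
      fn <- sample(0:(total - tp), 1)
      fp <- sample(0:(total - tp - fn), 1)
      tn <- total - tp - fn - fp
      if (tp + fn == 0 || fp + tn == 0) next
      m <- classification_metrics(tp = tp, fn = fn, fp = fp, tn = tn)
      cand <- infer_confusion(histotex:::round_half_away(m$accuracy),
                              histotex:::round_half_away(m$sensitivity),
                              histotex:::round_half_away(m$specificity),
                              total = total)
      expect_gte(nrow(cand), 1)
      hit <- cand$tp == tp & cand$fn == fn & cand$fp == fp & cand$tn == tn
      expect_true(any(hit))
      # every candidate reproduces the printed three metrics
      expect_true(all(histotex:::round_half_away(cand$accuracy) ==
                        histotex:::round_half_away(m$accuracy)))
    }
  })
})

test_that("table formatting rounds half away from zero to one decimal", {
  tbl <- tibble::tibble(accuracy = 96.75, sensitivity = 28 / 29 * 100,
                        specificity = 93.449, f1 = 58 / 59 * 100,
                        mcc = -0.25)
  out <- format_metrics(tbl)
  expect_equal(unlist(out), c(accuracy = 96.8, sensitivity = 96.6,
                              specificity = 93.4, f1 = 98.3, mcc = -0.3))
})
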