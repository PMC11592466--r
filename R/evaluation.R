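#' Binary confusion matrix
#'
#' Counts of true positives (`ta`), true negatives (`tb`), false
#' positives (`fa`) and false negatives (`fb`) for binary labels with
#' class 1 as positive (relapse).
#'
#' @param y_true,y_pred Equal-length 0/1 vectors.
#' @return A `confusion_matrix` list with integer `ta`, `tb`, `fa`, `fb`.
#' @examples
#' confusion(c(1, 0, 1), c(1, 0, 1))
#' @export
confusion <- function(y_true, y_pred) {
  if (length(y_true) != length(y_pred)) {
    stop("`y_true` and `y_pred` must have equal length", call. = FALSE)
  }
  if (length(y_true) == 0) stop("empty input", call. = FALSE)
  if (!all(y_true %in% c(0, 1)) || !all(y_pred %in% c(0, 1))) {
    stop("labels must be binary 0/1", call. = FALSE)
  }
  confusion_matrix(
    ta = sum(y_true == 1 & y_pred == 1),
    tb = sum(y_true == 0 & y_pred == 0),
    fa = sum(y_true == 0 & y_pred == 1),
    fb = sum(y_true == 1 & y_pred == 0)
  )
}

#' @rdname confusion
#' @param ta,tb,fa,fb Non-negative integer counts.
#' @export
confusion_matrix <- function(ta, tb, fa, fb) {
  counts <- c(ta = ta, tb = tb, fa = fa, fb = fb)
  if (any(counts < 0) || any(counts != floor(counts))) {
    stop("counts must be non-negative integers", call. = FALSE)
  }
  counts <- stats::setNames(as.integer(counts), c("ta", "tb", "fa", "fb"))
  structure(as.list(counts), class = "confusion_matrix")
}

#' @export
print.confusion_matrix <- function(x, ...) {
  cat(sprintf("<confusion_matrix: TP=%d TN=%d FP=%d FN=%d>\n",
              x$ta, x$tb, x$fa, x$fb))
  invisible(x)
}

#' Round half away from zero
#'
#' Decimal rounding with halves going up (2.345 -> 2.35), the convention
#' used when matching published 2-decimal percentage tables; R's
#' `round()` rounds halves to even instead.
#'
#' @param x Numeric vector.
#' @param digits Decimal digits.
#' @return Rounded vector.
#' @export
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  floor(x * p + 0.5 + 1e-9) / p
}

safe_ratio <- function(num, den) if (den > 0) num / den else NA_real_

#' Classification metrics from a confusion matrix
#'
#' Computes accuracy, precision, sensitivity (recall), specificity,
#' F-value and the Matthews correlation coefficient, all expressed as
#' percentages (MCC in `[-100, 100]`). The standard formulas are used:
#' `F = 2 TP / (2 TP + FP + FN)` and
#' `MCC = (TP*TN - FP*FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN))`.
#' A metric whose denominator is zero is reported as `NA`.
#'
#' @param cm A `confusion_matrix`.
#' @param f_value `"standard"` (default) or `"literal"`, which uses the
#'   degenerate denominator `2 TP + 2 FN` for audit purposes only (it is
#'   inconsistent with any published F column we have checked).
#' @return One-row tibble: `accuracy`, `precision`, `sensitivity`,
#'   `specificity`, `f_value`, `mcc` (percent, full precision — round for
#'   reporting with [round_half_up()]).
#' @export
compute_metrics <- function(cm, f_value = c("standard", "literal")) {
  f_value <- match.arg(f_value)
  stopifnot(inherits(cm, "confusion_matrix"))
  ta <- cm$ta; tb <- cm$tb; fa <- cm$fa; fb <- cm$fb
  total <- ta + tb + fa + fb
  if (total == 0) stop("confusion matrix is empty", call. = FALSE)
  fden <- if (f_value == "standard") 2 * ta + fa + fb else 2 * ta + 2 * fb
  mden2 <- prod(c(ta + fa, ta + fb, tb + fa, tb + fb))
  tibble::tibble(
    accuracy = 100 * (ta + tb) / total,
    precision = 100 * safe_ratio(ta, ta + fa),
    sensitivity = 100 * safe_ratio(ta, ta + fb),
    specificity = 100 * safe_ratio(tb, tb + fa),
    f_value = 100 * safe_ratio(2 * ta, fden),
    mcc = if (mden2 > 0) 100 * (ta * tb - fa * fb) / sqrt(mden2) else NA_real_
  )
}

#' ROC curve and AUC by the rank statistic
#'
#' AUC is computed as the probability that a uniformly chosen positive
#' sample outscores a uniformly chosen negative one, with ties counting
#' one half — the Mann–Whitney form, which equals the trapezoidal area
#' under the empirical ROC step curve. Invariant under strictly
#' increasing transformations of the scores.
#'
#' @param scores Numeric ranking scores (higher means more positive).
#' @param y_true 0/1 truth vector; both classes must be present.
#' @return List with `auc` and `roc`, a tibble `fpr, tpr, threshold`
#'   ordered from (0, 0) to (1, 1).
#' @export
roc_auc <- function(scores, y_true) {
  if (length(scores) != length(y_true)) {
    stop("`scores` and `y_true` must have equal length", call. = FALSE)
  }
  pos <- y_true == 1
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0 || n0 == 0) {
    stop("both classes must be present for ROC analysis", call. = FALSE)
  }
  r <- rank(scores)
  auc <- (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  thr <- sort(unique(scores), decreasing = TRUE)
  pts <- t(vapply(thr, function(t) {
    c(fpr = sum(!pos & scores >= t) / n0, tpr = sum(pos & scores >= t) / n1)
  }, numeric(2)))
  roc <- tibble::tibble(
    fpr = c(0, pts[, "fpr"], 1),
    tpr = c(0, pts[, "tpr"], 1),
    threshold = c(Inf, thr, -Inf)
  )
  structure(list(auc = auc, roc = roc), class = "roc_curve")
}

#' @export
print.roc_curve <- function(x, ...) {
  cat(sprintf("<roc_curve: AUC %.3f, %d points>\n", x$auc, nrow(x$roc)))
  invisible(x)
}

#' Recover integer confusion matrices from printed percentage metrics
#'
#' Published performance tables usually print accuracy, precision,
#' sensitivity and specificity to two decimals but not the underlying
#' counts. This utility inverts the rounding: it enumerates every integer
#' quadruple `(ta, fa, fb, tb)` with total at most `max_total` whose four
#' rates round (half up, 2 dp) to the printed values. A unique solution
#' pins down the confusion matrix exactly, after which any other metric
#' (F-value, MCC) can be recomputed and checked against the table.
#'
#' @param accuracy,precision,sensitivity,specificity Printed percentages
#'   (2 dp).
#' @param max_total Largest total sample count to consider (default 60).
#' @return Tibble of solutions with columns `ta, fa, fb, tb, total`;
#'   zero rows signal inconsistent inputs. Attribute `"unique"` is `TRUE`
#'   when exactly one solution exists.
#' @export
infer_confusion_matrix <- function(accuracy, precision, sensitivity,
                                   specificity, max_total = 60) {
  ok2 <- function(x, target) !is.na(x) & abs(round_half_up(x, 2) - target) < 1e-6
  # ta/fb from sensitivity
  tafb <- tidyr::crossing(ta = 0:max_total, fb = 0:max_total) |>
    dplyr::filter(.data$ta + .data$fb <= max_total, .data$ta + .data$fb > 0) |>
    dplyr::filter(ok2(100 * .data$ta / (.data$ta + .data$fb), sensitivity))
  # join in fa from precision
  sols <- tidyr::crossing(tafb, fa = 0:max_total) |>
    dplyr::filter(.data$ta + .data$fb + .data$fa <= max_total,
                  .data$ta + .data$fa > 0) |>
    dplyr::filter(ok2(100 * .data$ta / (.data$ta + .data$fa), precision)) |>
    tidyr::crossing(tb = 0:max_total) |>
    dplyr::filter(.data$ta + .data$fb + .data$fa + .data$tb <= max_total,
                  .data$tb + .data$fa > 0) |>
    dplyr::filter(ok2(100 * .data$tb / (.data$tb + .data$fa), specificity)) |>
    dplyr::mutate(total = .data$ta + .data$fa + .data$fb + .data$tb) |>
    dplyr::filter(ok2(100 * (.data$ta + .data$tb) / .data$total, accuracy)) |>
    dplyr::select("ta", "fa", "fb", "tb", "total")
  attr(sols, "unique") <- nrow(sols) == 1
  sols
}

#' The published performance tables
#'
#' Printed two-decimal percentage results of nine classification systems
#' (six base learners, three ensemble combiners) reported for an 80:20
#' held-out evaluation of a HER2-positive breast-cancer relapse cohort.
#' Bundled as reference inputs for the table-consistency audit
#' ([audit_published_metrics()]); they are not recomputed from image data
#' here.
#'
#' @return Tibble with columns `system`, `stage` (`"base"`/`"ensemble"`),
#'   `accuracy`, `precision`, `sensitivity`, `specificity`, `f_value`,
#'   `mcc` (percent).
#' @export
published_metrics <- function() {
  tibble::tribble(
    ~system, ~stage, ~accuracy, ~precision, ~sensitivity, ~specificity, ~f_value, ~mcc,
    "svm", "base", 78.85, 83.33, 85.71, 64.71, 84.51, 51.25,
    "lr", "base", 76.92, 80.56, 85.29, 61.11, 82.86, 47.83,
    "dt", "base", 80.77, 86.11, 86.11, 68.75, 86.11, 54.86,
    "rf", "base", 82.69, 86.11, 88.57, 70.59, 87.32, 60.13,
    "adaboost", "base", 82.69, 86.49, 88.89, 68.75, 87.67, 58.72,
    "xgboost", "base", 84.62, 86.84, 91.67, 68.75, 89.19, 62.87,
    "weighted_averaging", "ensemble", 88.46, 89.74, 94.59, 73.33, 92.11, 71.07,
    "soft_voting", "ensemble", 84.62, 86.11, 91.18, 72.22, 88.57, 65.35,
    "hard_voting", "ensemble", 86.54, 86.49, 94.12, 72.22, 90.14, 69.66
  )
}

#' Audit published metric rows for internal consistency
#'
#' For each row of a printed metrics table, recovers the integer
#' confusion matrix from the four rate metrics via
#' [infer_confusion_matrix()], recomputes every metric from the recovered
#' counts, and flags whether the recomputed F-value and MCC agree with
#' the printed columns to within `tol`.
#'
#' @param table Tibble in the format of [published_metrics()].
#' @param max_total Enumeration bound for [infer_confusion_matrix()].
#' @param tol Agreement tolerance in percentage points (default 0.01,
#'   i.e. exact at the printed 2-dp precision).
#' @return Tibble with one row per input row: the recovered counts,
#'   `n_solutions`, recomputed `f_value_rec` / `mcc_rec` / `accuracy_rec`,
#'   and logical `consistent`.
#' @export
audit_published_metrics <- function(table = published_metrics(),
                                    max_total = 60, tol = 0.01) {
  purrr::pmap_dfr(table, function(system, accuracy, precision, sensitivity,
                                  specificity, f_value, mcc, ...) {
    sols <- infer_confusion_matrix(accuracy, precision, sensitivity,
                                   specificity, max_total = max_total)
    if (nrow(sols) == 0) {
      return(tibble::tibble(system = system, n_solutions = 0L,
                            ta = NA_integer_, fa = NA_integer_,
                            fb = NA_integer_, tb = NA_integer_,
                            total = NA_integer_, accuracy_rec = NA_real_,
                            f_value_rec = NA_real_, mcc_rec = NA_real_,
                            consistent = FALSE))
    }
    s <- sols[1, ]
    rec <- compute_metrics(confusion_matrix(s$ta, s$tb, s$fa, s$fb))
    tibble::tibble(
      system = system, n_solutions = nrow(sols),
      ta = s$ta, fa = s$fa, fb = s$fb, tb = s$tb, total = s$total,
      accuracy_rec = round_half_up(rec$accuracy, 2),
      f_value_rec = round_half_up(rec$f_value, 2),
      mcc_rec = round_half_up(rec$mcc, 2),
      consistent = nrow(sols) == 1 &&
        abs(round_half_up(rec$f_value, 2) - f_value) <= tol + 1e-9 &&
        abs(round_half_up(rec$mcc, 2) - mcc) <= tol + 1e-9
    )
  })
}
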