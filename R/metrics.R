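# Micro- and macro-averaged F1 for single-label multiclass prediction.
# Per class: precision = TP / (TP + FP), recall = TP / (TP + FN),
# F1 = 2 * precision * recall / (precision + recall). Micro-averages pool
# the TP/FP/FN counts across classes; the macro F1 is the unweighted mean
# of the per-class F1 values. Undefined 0/0 ratios (in particular the
# precision of a never-predicted class) are set to 0 so every class
# contributes a value.

#' Build per-class confusion counts
#'
#' @param true_labels,predicted_labels equal-length vectors of labels, all
#'   drawn from `classes`.
#' @param classes ordered class list; fixes the report order.
#' @return object of class `confusion_counts` with integer vectors `tp`,
#'   `fp`, `fn` named by class.
#' @export
confusion_counts <- function(true_labels, predicted_labels, classes) {
  if (length(true_labels) != length(predicted_labels)) {
    stop("label vectors differ in length")
  }
  classes <- as.character(classes)
  unknown <- setdiff(unique(c(true_labels, predicted_labels)), classes)
  if (length(unknown)) {
    stop("label(s) not in class list: ", paste(unknown, collapse = ", "))
  }
  tl <- factor(true_labels, levels = classes)
  pl <- factor(predicted_labels, levels = classes)
  hit <- !is.na(tl) & tl == pl
  tp <- table(tl[hit])
  fn <- table(tl[!hit])
  fp <- table(pl[!hit])
  structure(list(classes = classes,
                 tp = stats::setNames(as.integer(tp), classes),
                 fp = stats::setNames(as.integer(fp), classes),
                 fn = stats::setNames(as.integer(fn), classes)),
            class = "confusion_counts")
}

#' Assemble confusion counts from known per-class totals
#'
#' @param tp,fp,fn non-negative integer vectors, one entry per class.
#' @param classes class names, same length.
#' @return a `confusion_counts` object.
#' @export
confusion_from_counts <- function(tp, fp, fn, classes) {
  stopifnot(length(tp) == length(classes), length(fp) == length(classes),
            length(fn) == length(classes), all(tp >= 0), all(fp >= 0),
            all(fn >= 0))
  classes <- as.character(classes)
  structure(list(classes = classes,
                 tp = stats::setNames(as.integer(tp), classes),
                 fp = stats::setNames(as.integer(fp), classes),
                 fn = stats::setNames(as.integer(fn), classes)),
            class = "confusion_counts")
}

safe_ratio <- function(num, den) ifelse(den > 0, num / den, 0)

#' Per-class precision, recall and F1
#'
#' Applies the class-wise formulas with the degenerate-class convention:
#' a ratio with zero denominator (e.g. the precision of a class that was
#' never predicted) is set to 0, as is the F1 of a class with
#' precision + recall = 0.
#'
#' @param counts a `confusion_counts` object.
#' @return data frame with one row per class: `class`, `tp`, `fp`, `fn`,
#'   `precision`, `recall`, `f1` (unrounded).
#' @export
class_metrics <- function(counts) {
  stopifnot(inherits(counts, "confusion_counts"))
  precision <- safe_ratio(counts$tp, counts$tp + counts$fp)
  recall <- safe_ratio(counts$tp, counts$tp + counts$fn)
  f1 <- safe_ratio(2 * precision * recall, precision + recall)
  data.frame(class = counts$classes,
             tp = unname(counts$tp), fp = unname(counts$fp),
             fn = unname(counts$fn),
             precision = unname(precision), recall = unname(recall),
             f1 = unname(f1), stringsAsFactors = FALSE)
}

#' Micro-averaged precision, recall and F1
#'
#' Pools TP/FP/FN over all classes before applying the formulas; the same
#' zero-denominator convention applies.
#'
#' @param counts a `confusion_counts` object.
#' @return named numeric vector `precision_micro`, `recall_micro`,
#'   `f1_micro`.
#' @export
micro_f1 <- function(counts) {
  stopifnot(inherits(counts, "confusion_counts"))
  tp <- sum(counts$tp); fp <- sum(counts$fp); fn <- sum(counts$fn)
  p <- safe_ratio(tp, tp + fp)
  r <- safe_ratio(tp, tp + fn)
  c(precision_micro = p, recall_micro = r,
    f1_micro = safe_ratio(2 * p * r, p + r))
}

#' Macro-averaged F1
#'
#' The unweighted mean of (unrounded) per-class F1 values.
#'
#' @param per_class_f1 non-empty numeric vector of per-class F1 values.
#' @return the macro F1.
#' @export
macro_f1 <- function(per_class_f1) {
  if (!length(per_class_f1)) stop("per-class F1 list is empty")
  mean(per_class_f1)
}

#' Full metrics report
#'
#' @param counts a `confusion_counts` object.
#' @return object of class `metrics_report`: the per-class table plus
#'   micro precision/recall/F1 and macro F1 (all unrounded).
#' @export
metrics_report <- function(counts) {
  per_class <- class_metrics(counts)
  mic <- micro_f1(counts)
  structure(list(per_class = per_class,
                 precision_micro = unname(mic["precision_micro"]),
                 recall_micro = unname(mic["recall_micro"]),
                 f1_micro = unname(mic["f1_micro"]),
                 f1_macro = macro_f1(per_class$f1),
                 n_classes = length(counts$classes)),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, digits = 2, ...) {
  print(report_table(x, digits = digits))
  invisible(x)
}

#' Per-class performance table
#'
#' One row per class with counts and rounded precision/recall/F1, plus
#' micro and macro summary rows. Classes whose (unrounded) F1 lies below
#' the unweighted class average are flagged in the `below_average` column,
#' mirroring the bold marking convention of per-class report tables.
#'
#' @param x a `metrics_report` or `confusion_counts` object.
#' @param digits rounding applied to the displayed values (default 2);
#'   all averaging uses unrounded intermediates.
#' @return data frame with columns `class`, `tp`, `fp`, `fn`, `precision`,
#'   `recall`, `f1`, `below_average`.
#' @export
report_table <- function(x, digits = 2) {
  if (inherits(x, "confusion_counts")) x <- metrics_report(x)
  stopifnot(inherits(x, "metrics_report"))
  pc <- x$per_class
  avg <- mean(pc$f1)
  rows <- data.frame(class = pc$class, tp = pc$tp, fp = pc$fp, fn = pc$fn,
                     precision = round(pc$precision, digits),
                     recall = round(pc$recall, digits),
                     f1 = round(pc$f1, digits),
                     below_average = pc$f1 < avg,
                     stringsAsFactors = FALSE)
  footer <- data.frame(
    class = c("micro average", "macro average"),
    tp = c(sum(pc$tp), NA), fp = c(sum(pc$fp), NA), fn = c(sum(pc$fn), NA),
    precision = c(round(x$precision_micro, digits), NA),
    recall = c(round(x$recall_micro, digits), NA),
    f1 = round(c(x$f1_micro, x$f1_macro), digits),
    below_average = c(NA, NA), stringsAsFactors = FALSE)
  rbind(rows, footer)
}
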