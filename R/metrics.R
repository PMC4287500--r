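# Segmentation evaluation.
#
# Area-overlap scores compare the automatic mask A_a with the manual
# (reference) mask A_m pixel by pixel:
#   TPR = |A_a intersect A_m| / |A_m|        (fraction of reference covered)
#   FPR = |A_a \ A_m| / |A_a|                (fraction of automatic spill-over)
#   ACC = (tp + tn) / (tp + tn + fp + fn)    (pixel-level accuracy)
# plus the Dice coefficient 2|A_a intersect A_m| / (|A_a| + |A_m|).
# Diagnosis-level sensitivity/specificity aggregate case counts (pathology
# present/absent vs diagnosed/not).

#' Area-overlap segmentation metrics
#'
#' @param auto_mask Logical matrix, the automatic segmentation.
#' @param manual_mask Logical matrix, the manual reference; must be nonempty.
#' @return A one-row tibble with `tpr`, `fpr`, `acc`, `dice` and the four
#'   pixel counts `tp`, `fp`, `fn`, `tn`.
#' @examples
#' a <- matrix(FALSE, 4, 4); a[1:2, 1:2] <- TRUE
#' overlap_metrics(a, a)  # perfect agreement
#' @export
overlap_metrics <- function(auto_mask, manual_mask) {
  auto_mask <- as_binary_mask(auto_mask, "auto_mask")
  manual_mask <- as_binary_mask(manual_mask, "manual_mask")
  if (!all(dim(auto_mask) == dim(manual_mask))) {
    stop("masks must have identical dimensions", call. = FALSE)
  }
  if (!any(manual_mask)) {
    stop("manual mask is empty: overlap metrics undefined", call. = FALSE)
  }
  tp <- sum(auto_mask & manual_mask)
  fp <- sum(auto_mask & !manual_mask)
  fn <- sum(!auto_mask & manual_mask)
  tn <- sum(!auto_mask & !manual_mask)
  na <- tp + fp
  tibble(
    tpr = tp / (tp + fn),
    fpr = if (na > 0) fp / na else 0,
    acc = (tp + tn) / (tp + fp + fn + tn),
    dice = 2 * tp / (na + tp + fn),
    tp = tp, fp = fp, fn = fn, tn = tn
  )
}

#' Diagnosis-level sensitivity and specificity
#'
#' Aggregates case counts from a blind pathology reading: true positives are
#' cases with pathology present and diagnosed, true negatives absent and not
#' diagnosed.
#'
#' @param tp,fp,fn,tn Non-negative case counts; `tp + fn` and `tn + fp`
#'   must be positive.
#' @return A one-row tibble with `sensitivity` and `specificity`.
#' @examples
#' diagnostic_metrics(tp = 47, fp = 3, fn = 3, tn = 44)
#' @export
diagnostic_metrics <- function(tp, fp, fn, tn) {
  counts <- c(tp = tp, fp = fp, fn = fn, tn = tn)
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("counts must be non-negative integers", call. = FALSE)
  }
  if (tp + fn == 0) stop("no pathology-present cases: sensitivity undefined",
                         call. = FALSE)
  if (tn + fp == 0) stop("no pathology-absent cases: specificity undefined",
                         call. = FALSE)
  tibble(sensitivity = tp / (tp + fn), specificity = tn / (tn + fp))
}

#' Cohort-level summary of per-image segmentation metrics
#'
#' @param results A tibble (or list of one-row tibbles) of per-image metrics
#'   as returned by [overlap_metrics()], optionally with an `id` column.
#' @return An object of class `cohort_report`: list with `per_image` (tibble)
#'   and `summary` (one-row tibble of means over tpr/fpr/acc/dice).
#' @export
cohort_report <- function(results) {
  if (is.data.frame(results)) {
    per <- as_tibble(results)
  } else if (is.list(results) && length(results) > 0) {
    per <- do.call(rbind, lapply(results, as_tibble))
  } else {
    stop("results must be a nonempty tibble or list of metric rows",
         call. = FALSE)
  }
  if (nrow(per) < 1L) stop("results must contain at least one row", call. = FALSE)
  if (!"id" %in% names(per)) per <- cbind(tibble(id = seq_len(nrow(per))), per)
  metric_cols <- intersect(c("tpr", "fpr", "acc", "dice"), names(per))
  summ <- as_tibble(as.list(colMeans(per[metric_cols])))
  structure(list(per_image = as_tibble(per), summary = summ,
                 n = nrow(per)), class = "cohort_report")
}

#' @export
print.cohort_report <- function(x, ...) {
  cat(sprintf("<cohort_report> %d images\n", x$n))
  cat("  mean:",
      paste(sprintf("%s=%.4f", names(x$summary), as.numeric(x$summary[1, ])),
            collapse = "  "), "\n")
  invisible(x)
}

#' @export
glance.cohort_report <- function(x, ...) cbind(tibble(n = x$n), x$summary)

#' Write a cohort report to CSV
#'
#' Writes the per-image rows followed by a `mean` row.
#'
#' @param report A `cohort_report`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_cohort_report <- function(report, path) {
  stopifnot(inherits(report, "cohort_report"))
  per <- report$per_image
  mean_row <- per[1, ]
  mean_row[] <- NA
  mean_row$id <- "mean"
  per$id <- as.character(per$id)
  for (cn in names(report$summary)) mean_row[[cn]] <- report$summary[[cn]]
  utils::write.csv(rbind(per, mean_row), path, row.names = FALSE)
  invisible(path)
}
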