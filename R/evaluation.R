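#' Pixel-level confusion counts
#'
#' Accumulates true-positive, false-positive and false-negative pixel
#' counts over aligned prediction/ground-truth mask pairs:
#' `tp = |pred & gt|`, `fp = |pred & !gt|`, `fn = |!pred & gt|`, summed
#' over all slices. True negatives are not tracked — background dominates
#' medical slices and plays no role in the reported metrics.
#'
#' @param pred_masks,gt_masks lists of matching binary matrices (a single
#'   matrix is accepted for either).
#' @return object of class `pixel_confusion` with integer fields `tp`,
#'   `fp`, `fn`.
#' @export
pixel_confusion <- function(pred_masks, gt_masks) {
  if (is.matrix(pred_masks)) pred_masks <- list(pred_masks)
  if (is.matrix(gt_masks)) gt_masks <- list(gt_masks)
  if (length(pred_masks) != length(gt_masks))
    stop("prediction and ground-truth lists differ in length")
  tp <- fp <- fn <- 0
  for (i in seq_along(pred_masks)) {
    p <- pred_masks[[i]] != 0
    g <- gt_masks[[i]] != 0
    if (!identical(dim(p), dim(g)))
      stop("shape mismatch at slice ", i)
    tp <- tp + sum(p & g)
    fp <- fp + sum(p & !g)
    fn <- fn + sum(!p & g)
  }
  confusion_counts(tp, fp, fn)
}

#' Build a confusion object from raw counts
#'
#' @param tp,fp,fn nonnegative pixel counts.
#' @return a `pixel_confusion`.
#' @export
confusion_counts <- function(tp, fp, fn) {
  tp <- as.numeric(tp); fp <- as.numeric(fp); fn <- as.numeric(fn)
  stopifnot(tp >= 0, fp >= 0, fn >= 0)
  structure(list(tp = tp, fp = fp, fn = fn), class = "pixel_confusion")
}

#' @export
print.pixel_confusion <- function(x, ...) {
  cat(sprintf("<pixel_confusion: tp %s, fp %s, fn %s>\n",
              format(x$tp), format(x$fp), format(x$fn)))
  invisible(x)
}

#' Segmentation metrics from a pixel confusion
#'
#' Precision `tp/(tp+fp)`, recall `tp/(tp+fn)`, F1 (harmonic mean of the
#' two) and Dice `2tp/(2tp+fp+fn)`, expressed as percentages in full
#' precision. At pixel level F1 and Dice are algebraically identical, which
#' is why per-fold reports print the two columns equal. Metrics with an
#' empty denominator are `NA` ("not applicable"), never coerced to 0 or
#' 100; an all-zero confusion errors.
#'
#' @param conf a [pixel_confusion()].
#' @return object of class `fold_metrics` with fields `precision`,
#'   `recall`, `f1`, `dice` (percent).
#' @export
metrics_from_confusion <- function(conf) {
  stopifnot(inherits(conf, "pixel_confusion"))
  tp <- conf$tp; fp <- conf$fp; fn <- conf$fn
  if (tp + fp + fn == 0)
    stop("all-zero confusion: metrics undefined")
  precision <- if (tp + fp > 0) 100 * tp / (tp + fp) else NA_real_
  recall <- if (tp + fn > 0) 100 * tp / (tp + fn) else NA_real_
  f1 <- if (!is.na(precision) && !is.na(recall) && precision + recall > 0)
    2 * precision * recall / (precision + recall) else NA_real_
  dice <- 100 * 2 * tp / (2 * tp + fp + fn)
  fold_metrics(precision, recall, f1, dice)
}

#' Construct fold metrics directly
#'
#' Used for externally reported per-fold values (e.g. re-aggregating a
#' published per-fold table) as well as internally by
#' [metrics_from_confusion()].
#'
#' @param precision,recall,f1,dice percentages in `[0, 100]` (or `NA`).
#' @return object of class `fold_metrics`.
#' @export
fold_metrics <- function(precision, recall, f1 = NULL, dice = NULL) {
  if (is.null(f1)) f1 <- 2 * precision * recall / (precision + recall)
  if (is.null(dice)) dice <- f1
  m <- list(precision = precision, recall = recall, f1 = f1, dice = dice)
  for (v in m) if (!is.na(v) && (v < -1e-9 || v > 100 + 1e-9))
    stop("metrics must lie in [0, 100]")
  structure(m, class = "fold_metrics")
}

# report-time rounding: half-up to 2 decimals
round2 <- function(x) round_half_up(x * 100) / 100

#' @export
print.fold_metrics <- function(x, ...) {
  fmt <- function(v) if (is.na(v)) "n/a" else sprintf("%.2f", round2(v))
  cat(sprintf("precision %s%%  recall %s%%  F1 %s%%  Dice %s%%\n",
              fmt(x$precision), fmt(x$recall), fmt(x$f1), fmt(x$dice)))
  invisible(x)
}

#' Aggregate per-fold metrics
#'
#' Unweighted arithmetic mean of each metric across folds (the
#' cross-validation summary); computed in full precision, rounded only at
#' report time.
#'
#' @param ms nonempty list of [fold_metrics()].
#' @return a `fold_metrics` of means.
#' @export
aggregate_folds <- function(ms) {
  if (length(ms) == 0L) stop("no folds to aggregate")
  g <- function(f) mean(vapply(ms, `[[`, numeric(1), f))
  fold_metrics(g("precision"), g("recall"), g("f1"), g("dice"))
}

#' Render fold metrics as a report table
#'
#' @param ms named list of [fold_metrics()] (e.g. one per fold, or per size
#'   category); a mean row is appended when `add_mean` is `TRUE`.
#' @param add_mean append the [aggregate_folds()] row.
#' @return data frame with columns `precision`, `recall`, `f1`, `dice`,
#'   rounded half-up to 2 decimals; undefined entries are `NA`.
#' @export
metrics_table <- function(ms, add_mean = FALSE) {
  if (is.null(names(ms)) || anyDuplicated(names(ms)) || any(names(ms) == ""))
    names(ms) <- sprintf("fold%d", seq_along(ms) - 1L)
  if (add_mean) ms <- c(ms, list(mean = aggregate_folds(ms)))
  out <- do.call(rbind, lapply(ms, function(m)
    data.frame(precision = round2(m$precision), recall = round2(m$recall),
               f1 = round2(m$f1), dice = round2(m$dice))))
  rownames(out) <- names(ms)
  out
}

#' Size-stratified pixel metrics
#'
#' Splits the pixel confusion by physical lesion size. Each ground-truth
#' component is assigned a category from its own equivalent diameter
#' ([size_category()]); its pixels contribute `tp`/`fn` to that category.
#' Predicted pixels overlapping a ground-truth component are credited to
#' that component's category, so per-category `tp` sums to the whole-set
#' `tp`. Predicted pixels overlapping no ground truth are false positives
#' attributed to the category of the *predicted* component's own physical
#' size — the attribution the size-stratified report needs so small-lesion
#' precision reflects small false detections.
#'
#' @param pred_masks,gt_masks lists of aligned binary matrices (one pair
#'   per slice).
#' @param spacing in-plane `(sx, sy)` mm.
#' @param t a [size_thresholds()].
#' @return named list `small`/`medium`/`large` of [pixel_confusion()]s;
#'   convert with [metrics_from_confusion()] / [metrics_table()]. Empty
#'   categories have all-zero counts.
#' @export
stratified_confusion <- function(pred_masks, gt_masks, spacing,
                                 t = size_thresholds()) {
  if (is.matrix(pred_masks)) pred_masks <- list(pred_masks)
  if (is.matrix(gt_masks)) gt_masks <- list(gt_masks)
  stopifnot(length(pred_masks) == length(gt_masks))
  cats <- c("small", "medium", "large")
  tp <- fp <- fn <- stats::setNames(numeric(3), cats)
  for (i in seq_along(gt_masks)) {
    g <- (gt_masks[[i]] != 0) * 1
    p <- (pred_masks[[i]] != 0) * 1
    if (!identical(dim(g), dim(p))) stop("shape mismatch at slice ", i)
    glab <- label_components(g)
    for (kg in seq_len(max(glab))) {
      comp <- (glab == kg) * 1
      cat_g <- size_category(comp, spacing, t)
      tp[cat_g] <- tp[cat_g] + sum(comp * p)
      fn[cat_g] <- fn[cat_g] + sum(comp * (1 - p))
    }
    # false-positive pixels, attributed by predicted-component size
    spill <- p * (1 - g)
    if (any(spill != 0)) {
      plab <- label_components(p)
      for (kp in seq_len(max(plab))) {
        pcomp <- (plab == kp) * 1
        n_fp <- sum(pcomp * spill)
        if (n_fp == 0) next
        cat_p <- size_category(pcomp, spacing, t)
        fp[cat_p] <- fp[cat_p] + n_fp
      }
    }
  }
  stats::setNames(lapply(cats, function(cc)
    confusion_counts(tp[cc], fp[cc], fn[cc])), cats)
}

#' Size-stratified metrics table
#'
#' Convenience wrapper: [stratified_confusion()] followed by
#' [metrics_from_confusion()] per nonempty category.
#'
#' @inheritParams stratified_confusion
#' @return named list of [fold_metrics()] for categories with any pixels;
#'   empty categories are omitted.
#' @export
stratified_metrics <- function(pred_masks, gt_masks, spacing,
                               t = size_thresholds()) {
  conf <- stratified_confusion(pred_masks, gt_masks, spacing, t)
  conf <- Filter(function(cc) cc$tp + cc$fp + cc$fn > 0, conf)
  lapply(conf, metrics_from_confusion)
}

#' Write an evaluation report
#'
#' Emits per-fold metrics (plus the mean row) and, when given, the per-size
#' table, each as CSV and JSON.
#'
#' @param fold_ms named list of per-fold [fold_metrics()].
#' @param size_ms optional named list of per-category [fold_metrics()].
#' @param dir output directory.
#' @return character vector of written paths, invisibly.
#' @export
write_report <- function(fold_ms, size_ms = NULL, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- character()
  tab <- metrics_table(fold_ms, add_mean = TRUE)
  fcsv <- file.path(dir, "metrics_per_fold.csv")
  utils::write.csv(cbind(fold = rownames(tab), tab), fcsv, row.names = FALSE)
  fjson <- file.path(dir, "metrics_per_fold.json")
  jsonlite::write_json(tab, fjson, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", na = "null")
  paths <- c(fcsv, fjson)
  if (!is.null(size_ms) && length(size_ms)) {
    stab <- metrics_table(size_ms)
    scsv <- file.path(dir, "metrics_by_size.csv")
    utils::write.csv(cbind(size = rownames(stab), stab), scsv,
                     row.names = FALSE)
    sjson <- file.path(dir, "metrics_by_size.json")
    jsonlite::write_json(stab, sjson, auto_unbox = TRUE, digits = NA,
                         dataframe = "rows", na = "null")
    paths <- c(paths, scsv, sjson)
  }
  invisible(paths)
}
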