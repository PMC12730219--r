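# translate a binary mask by (dr, dc) pixels, zero fill
shift_mask <- function(m, dr, dc) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(0, nr, nc)
  rs <- max(1, 1 + dr):min(nr, nr + dr)
  cs <- max(1, 1 + dc):min(nc, nc + dc)
  out[rs, cs] <- m[rs - dr, cs - dc]
  out
}

#' Run the full pipeline on a synthetic cohort
#'
#' Headless end-to-end driver used for desk-scale validation: simulate a
#' cohort ([generate_cohort()]), preprocess it into normalized PNG slice
#' pairs ([preprocess_cohort()]), build patient-level folds and per-fold
#' COCO files ([make_folds()], [emit_fold_files()]), run a scripted
#' [mock_backend()] over the validation slices, apply the size-aware
#' proposal filter ([filter_proposals()]), and evaluate pixel-level metrics
#' per fold and per size category ([pixel_confusion()],
#' [stratified_metrics()], [write_report()]).
#'
#' The mock detector's manifest is derived from the ground truth: each
#' lesion component on a validation slice becomes one proposal whose mask
#' is the component itself, with a high confidence for medium/large
#' components and a mid-range confidence (below the base threshold, above
#' the small-object threshold) for small ones — exercising the small-object
#' rescue path. With probability `fp_rate` a spurious low-confidence
#' background box is added per slice; the size-aware filter must remove it.
#'
#' @param work_dir working directory (created); subdirectories `nifti/`,
#'   `slices/`, `coco/`, `reports/` are populated.
#' @param n_aneurysmal,n_healthy cohort composition (default 10 / 5, a
#'   reduced-scale mirror of a 161 / 286 clinical cohort).
#' @param k number of folds.
#' @param seed master seed for cohort, folds and scripted detections.
#' @param encoding COCO segmentation encoding.
#' @param fp_rate probability of a scripted false-positive proposal per
#'   validation slice.
#' @param augment apply offline augmentation to one training fold's slices
#'   (smoke coverage of the operators; augmented copies are not re-entered
#'   into the COCO build, which indexes source slices).
#' @return list with `cohort`, `folds`, `fold_files`, `fold_metrics`
#'   (per-fold [fold_metrics()]), `mean_metrics`, `size_metrics`,
#'   `report_files`.
#' @export
run_pipeline <- function(work_dir, n_aneurysmal = 10, n_healthy = 5, k = 5,
                         seed = 1L, encoding = c("bitmask", "polygon"),
                         fp_rate = 0.05, augment = TRUE) {
  encoding <- match.arg(encoding)
  nifti_dir <- file.path(work_dir, "nifti")
  slice_dir <- file.path(work_dir, "slices")
  coco_dir <- file.path(work_dir, "coco")
  report_dir <- file.path(work_dir, "reports")

  cohort <- generate_cohort(n_aneurysmal, n_healthy, nifti_dir, seed = seed)
  spacing <- RNifti::pixdim(RNifti::readNifti(cohort$image_files[1]))[1:2]

  pre <- preprocess_cohort(nifti_dir, slice_dir)
  if (nrow(pre$report) > 0L)
    stop("inconsistent image/mask pairs: ",
         paste(pre$report$identifier, collapse = ", "))
  subjects <- group_subjects(pre$records)
  folds <- make_folds(subjects, k = k, seed = seed)
  fold_files <- emit_fold_files(subjects, folds, coco_dir, encoding)

  if (augment) {
    spec <- augmentation_spec(noise_sigma = 5, seed = seed)
    first_train <- names(folds$assignment)[folds$assignment != 0][1]
    subj <- subjects[[first_train]]
    aug_dir <- file.path(work_dir, "augmented")
    with_mask <- Filter(function(r) !is.null(r$mask_path), subj$slices)
    for (rec in with_mask[seq_len(min(2L, length(with_mask)))])
      augment_record(rec, spec, aug_dir, spacing)
  }

  # scripted detections for every validation slice, from the ground truth
  manifest <- with_seed(seed, {
    man <- list()
    for (sid in names(folds$assignment)) {
      for (rec in subjects[[sid]]$slices) {
        gt <- (png::readPNG(rec$mask_path) > 0.5) * 1
        lab <- label_components(gt)
        ps <- list()
        for (kc in seq_len(max(lab))) {
          comp <- (lab == kc) * 1
          small <- size_category(comp, spacing) == "small"
          # small lesions score lower (occasionally under even the reduced
          # threshold); larger lesions score high but localize imperfectly
          score <- if (small) stats::runif(1, 0.55, 0.85)
                   else stats::runif(1, 0.96, 0.995)
          pm <- comp
          if (stats::runif(1) < 0.7) {
            sh <- sample(c(-1L, 1L), 2, replace = TRUE)
            pm <- shift_mask(comp, sh[1], sh[2])
            if (sum(pm) == 0) pm <- comp
          }
          ps[[length(ps) + 1L]] <- proposal(mask_bbox(pm), score,
                                            rec$identifier, pm)
        }
        if (stats::runif(1) < fp_rate) {
          fpm <- matrix(0, nrow(gt), ncol(gt))
          r0 <- sample(nrow(gt) - 12, 1); c0 <- sample(ncol(gt) - 12, 1)
          fpm[r0:(r0 + 11), c0:(c0 + 11)] <- 1  # 12x12 px: above the gate
          ps[[length(ps) + 1L]] <- proposal(mask_bbox(fpm),
                                            stats::runif(1, 0.3, 0.55),
                                            rec$identifier, fpm)
        }
        if (length(ps)) man[[rec$identifier]] <- ps
      }
    }
    man
  })
  backend <- mock_backend(manifest)
  handle <- backend$train(fold_files$train_json, default_config())

  thresholds <- size_thresholds()
  fold_ms <- list()
  all_pred <- list(); all_gt <- list()
  for (f in 0:(k - 1L)) {
    val_ids <- names(folds$assignment)[folds$assignment == f]
    pred_masks <- list(); gt_masks <- list()
    for (sid in val_ids) {
      for (rec in subjects[[sid]]$slices) {
        gt <- (png::readPNG(rec$mask_path) > 0.5) * 1
        kept <- filter_proposals(backend$predict(rec$identifier, handle),
                                 spacing, thresholds)
        pred <- matrix(0, nrow(gt), ncol(gt))
        for (p in kept) if (!is.null(p$mask)) pred <- pmax(pred, p$mask)
        pred_masks[[length(pred_masks) + 1L]] <- pred
        gt_masks[[length(gt_masks) + 1L]] <- gt
      }
    }
    fold_ms[[sprintf("fold%d", f)]] <-
      metrics_from_confusion(pixel_confusion(pred_masks, gt_masks))
    all_pred <- c(all_pred, pred_masks)
    all_gt <- c(all_gt, gt_masks)
  }
  size_ms <- stratified_metrics(all_pred, all_gt, spacing, thresholds)
  report_files <- write_report(fold_ms, size_ms, report_dir)

  list(cohort = cohort, folds = folds, fold_files = fold_files,
       fold_metrics = fold_ms, mean_metrics = aggregate_folds(fold_ms),
       size_metrics = size_ms, report_files = report_files)
}
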