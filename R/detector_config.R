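# Map between internal field names and the upstream-style config keys used
# in the serialized document.
.config_keys <- c(
  base_lr = "BASE_LR",
  max_iter = "MAX_ITER",
  ims_per_batch = "IMS_PER_BATCH",
  roi_batch_size_per_image = "ROI_BATCH_SIZE_PER_IMAGE",
  score_thresh_test = "SCORE_THRESH_TEST",
  rpn_nms_thresh = "RPN_NMS_THRESH",
  lr_decay_steps = "LR_DECAY_STEPS",
  lr_gamma = "LR_GAMMA",
  amp_enabled = "AMP_ENABLED",
  anchor_sizes = "ANCHOR_SIZES",
  anchor_aspect_ratios = "ANCHOR_ASPECT_RATIOS",
  rpn_iou_thresholds = "RPN_IOU_THRESHOLDS",
  rpn_batch_per_image = "RPN_BATCH_PER_IMAGE",
  rpn_positive_fraction = "RPN_POSITIVE_FRACTION",
  mask_format = "MASK_FORMAT",
  pretrained_weights_tag = "PRETRAINED_WEIGHTS"
)

#' Default detector training/inference configuration
#'
#' The optimized Mask R-CNN configuration found by Bayesian search plus
#' manual refinement, returned as a typed object. Highlights: a low base
#' learning rate (0.00110) with decay steps at iterations 4000 and 5500
#' (factor 0.1) over 6212 iterations; a strict inference score threshold
#' (0.9457) to suppress low-confidence false positives; five small-biased
#' anchor sizes (8-128 px) with aspect ratios 0.5/1.0/1.5 to cover tiny
#' lesions; RPN IoU thresholds 0.3/0.7 with 512 proposals per image at
#' positive fraction 0.5; a ROI-head batch of 256 per image; and bitmask
#' ground-truth encoding. The AMP flag and pretrained-weight tag are opaque
#' metadata for the backend adapter; no numerical behavior in this package
#' depends on them.
#'
#' @return object of class `training_config`.
#' @export
default_config <- function() {
  cfg <- structure(
    list(
      base_lr = 0.00110,
      max_iter = 6212L,
      ims_per_batch = 2L,
      roi_batch_size_per_image = 256L,
      score_thresh_test = 0.9457,
      rpn_nms_thresh = 0.5203,
      lr_decay_steps = c(4000L, 5500L),
      lr_gamma = 0.1,
      amp_enabled = TRUE,
      anchor_sizes = c(8L, 16L, 32L, 64L, 128L),
      anchor_aspect_ratios = c(0.5, 1.0, 1.5),
      rpn_iou_thresholds = c(0.3, 0.7),
      rpn_batch_per_image = 512L,
      rpn_positive_fraction = 0.5,
      mask_format = "bitmask",
      pretrained_weights_tag = "R-50-ImageNet"
    ),
    class = "training_config"
  )
  validate_config(cfg)
  cfg
}

#' Validate a training configuration
#'
#' Checks the structural invariants, naming the offending field in every
#' error: decay steps strictly increasing and below `max_iter`; score and
#' NMS thresholds in `[0, 1]`; anchor sizes strictly increasing; positive
#' fraction strictly inside `(0, 1)`; mask format one of
#' `"bitmask"`/`"polygon"`.
#'
#' @param cfg a `training_config`.
#' @return `cfg`, invisibly.
#' @export
validate_config <- function(cfg) {
  need <- names(.config_keys)
  missing <- setdiff(need, names(cfg))
  if (length(missing)) stop("missing config field(s): ",
                            paste(missing, collapse = ", "))
  extra <- setdiff(names(cfg), need)
  if (length(extra)) stop("unknown config field(s): ",
                          paste(extra, collapse = ", "))
  if (cfg$base_lr <= 0) stop("invalid base_lr: must be positive")
  if (cfg$max_iter < 1) stop("invalid max_iter: must be >= 1")
  if (any(diff(cfg$lr_decay_steps) <= 0))
    stop("invalid lr_decay_steps: must be strictly increasing")
  if (any(cfg$lr_decay_steps >= cfg$max_iter))
    stop("invalid lr_decay_steps: every step must be < max_iter")
  for (f in c("score_thresh_test", "rpn_nms_thresh", "lr_gamma")) {
    if (cfg[[f]] < 0 || cfg[[f]] > 1)
      stop("invalid ", f, ": must lie in [0, 1]")
  }
  if (any(cfg$rpn_iou_thresholds < 0 | cfg$rpn_iou_thresholds > 1))
    stop("invalid rpn_iou_thresholds: must lie in [0, 1]")
  if (any(diff(cfg$anchor_sizes) <= 0))
    stop("invalid anchor_sizes: must be strictly increasing")
  if (cfg$rpn_positive_fraction <= 0 || cfg$rpn_positive_fraction >= 1)
    stop("invalid rpn_positive_fraction: must lie in (0, 1)")
  if (!cfg$mask_format %in% c("bitmask", "polygon"))
    stop("invalid mask_format: must be \"bitmask\" or \"polygon\"")
  invisible(cfg)
}

#' Serialize a training configuration
#'
#' Human-readable flat key/value YAML using the upstream-style names
#' (`BASE_LR`, `MAX_ITER`, `SCORE_THRESH_TEST`, ...), suitable for drop-in
#' use with the detection framework. [parse_config()] round-trips
#' losslessly.
#'
#' @param cfg a `training_config`.
#' @param path optional path; when given the text is also written there.
#' @return the YAML text, invisibly when `path` is given.
#' @export
serialize_config <- function(cfg, path = NULL) {
  validate_config(cfg)
  doc <- stats::setNames(unclass(cfg), .config_keys[names(cfg)])
  txt <- yaml::as.yaml(doc, precision = 12)
  if (!is.null(path)) {
    writeLines(txt, path)
    return(invisible(txt))
  }
  txt
}

#' Parse a serialized training configuration
#'
#' Inverse of [serialize_config()]. Unknown keys are rejected with the
#' offending key named; the parsed object is re-validated, so invariant
#' violations (e.g. a decay step beyond `max_iter`) error out.
#'
#' @param text YAML text, or `NULL` to read from `path`.
#' @param path path to a serialized config file.
#' @return a `training_config`.
#' @export
parse_config <- function(text = NULL, path = NULL) {
  doc <- if (!is.null(text)) yaml::yaml.load(paste(text, collapse = "\n"))
         else yaml::read_yaml(path)
  unknown <- setdiff(names(doc), unname(.config_keys))
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  fields <- names(.config_keys)[match(names(doc), .config_keys)]
  cfg <- stats::setNames(doc, fields)
  int_fields <- c("max_iter", "ims_per_batch", "roi_batch_size_per_image",
                  "rpn_batch_per_image", "lr_decay_steps", "anchor_sizes")
  for (f in intersect(int_fields, names(cfg)))
    cfg[[f]] <- as.integer(cfg[[f]])
  for (f in c("anchor_aspect_ratios", "rpn_iou_thresholds"))
    if (!is.null(cfg[[f]])) cfg[[f]] <- as.numeric(cfg[[f]])
  cfg <- structure(cfg[names(.config_keys)[names(.config_keys) %in%
                                             names(cfg)]],
                   class = "training_config")
  validate_config(cfg)
  cfg
}

#' @export
print.training_config <- function(x, ...) {
  cat("<training_config>\n")
  cat(serialize_config(x))
  invisible(x)
}

#' Scripted mock detector backend
#'
#' A backend adapter whose `predict()` returns pre-scripted proposals
#' verbatim, keyed by slice identifier, and whose `train()` is a no-op
#' returning a handle embedding the manifest. It satisfies the same
#' contract as a real detector binding — `train(dataset_files, config) ->
#' handle`; `predict(slice_ref, handle) -> list of proposals` — so the
#' dataset builder, size-aware filter and evaluator can be exercised end to
#' end on one CPU with no deep-learning framework. Slices absent from the
#' manifest yield an empty proposal list.
#'
#' @param manifest named list mapping slice identifiers to lists of
#'   [proposal()]s.
#' @return object of class `backend_adapter` with function fields `train`
#'   and `predict`.
#' @export
mock_backend <- function(manifest = list()) {
  stopifnot(is.list(manifest))
  structure(
    list(
      train = function(dataset_files, config = default_config()) {
        validate_config(config)
        structure(list(manifest = manifest, config = config,
                       dataset_files = dataset_files),
                  class = "mock_model_handle")
      },
      predict = function(slice_ref, handle) {
        ps <- handle$manifest[[slice_ref]]
        if (is.null(ps)) list() else ps
      }
    ),
    class = "backend_adapter"
  )
}
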