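#' Group slice records into subject records
#'
#' @param records list of [slice_record()]s.
#' @return list of `subject_record` objects, each with `subject_id`,
#'   `slices` (the records of that subject) and `label` (`"aneurysmal"` if
#'   any slice has a mask path, else `"healthy"`).
#' @export
group_subjects <- function(records) {
  ids <- vapply(records, function(r) r$subject_id, character(1))
  lapply(split(records, ids)[unique(ids)], function(slices) {
    has_mask <- any(vapply(slices, function(r) !is.null(r$mask_path),
                           logical(1)))
    structure(
      list(subject_id = slices[[1]]$subject_id, slices = slices,
           label = if (has_mask) "aneurysmal" else "healthy"),
      class = "subject_record"
    )
  })
}

#' Patient-level fold assignment
#'
#' Randomly shuffles the aneurysmal subjects under `seed` and assigns them
#' round-robin to `k` mutually exclusive folds, so fold sizes differ by at
#' most one and every slice of a subject lands in the same fold — the
#' patient-level separation that prevents leakage of correlated anatomy
#' between training and test sets. Healthy subjects are excluded from the
#' assignment entirely; they are injected into every training split (never
#' a validation split) by [emit_fold_files()].
#'
#' @param subjects list of `subject_record`s (see [group_subjects()]), or a
#'   character vector of aneurysmal subject ids.
#' @param k number of folds (>= 2), default 5.
#' @param seed integer seed for the shuffle.
#' @return object of class `fold_assignment`: list with `k`, `seed` and
#'   `assignment`, a named integer vector mapping aneurysmal subject id to
#'   fold index in `0 .. k-1`.
#' @export
make_folds <- function(subjects, k = 5, seed = 1L) {
  if (is.character(subjects)) {
    ids <- subjects
  } else {
    lab <- vapply(subjects, function(s) s$label, character(1))
    ids <- vapply(subjects, function(s) s$subject_id, character(1))[
      lab == "aneurysmal"]
  }
  k <- as.integer(k)
  if (k < 2L) stop("k must be >= 2")
  if (length(ids) < k)
    stop("need at least k = ", k, " aneurysmal subjects, got ", length(ids))
  shuffled <- with_seed(seed, sample(ids))
  assignment <- (seq_along(shuffled) - 1L) %% k
  names(assignment) <- shuffled
  structure(list(k = k, seed = as.integer(seed), assignment = assignment),
            class = "fold_assignment")
}

#' @export
print.fold_assignment <- function(x, ...) {
  cat(sprintf("<fold_assignment: %d subjects in %d folds (sizes %s), seed %d>\n",
              length(x$assignment), x$k,
              paste(tabulate(x$assignment + 1L, x$k), collapse = "/"),
              x$seed))
  invisible(x)
}

#' Build a COCO dataset from slice records
#'
#' One image entry per record; aneurysmal slices with nonempty masks yield
#' one annotation per 8-connected mask component, while healthy slices (and
#' empty-mask slices of aneurysmal subjects, kept as extra negatives for
#' false-positive suppression) appear with zero annotation entries. The
#' single category is `"aneurysm"`.
#'
#' Per annotation: `bbox` is the tight axis-aligned extent of the component
#' in 0-based `[x, y, w, h]`; `area` is the component's foreground pixel
#' count; `segmentation` is either the outer-contour polygon
#' ([mask_to_polygons()], holes filled) or a lossless uncompressed RLE
#' bitmask ([rle_encode_mask()] of the single component) depending on
#' `encoding`. Bitmask is the training default. Referential integrity
#' (annotations -> images -> categories) is validated before return.
#'
#' @param records list of [slice_record()]s (pre-validated with
#'   [validate_pairs()]).
#' @param encoding `"bitmask"` (default) or `"polygon"`.
#' @return object of class `coco_dataset`: list with `images`,
#'   `annotations`, `categories`.
#' @export
build_coco <- function(records, encoding = c("bitmask", "polygon")) {
  encoding <- match.arg(encoding)
  images <- list()
  annotations <- list()
  ann_id <- 0L
  for (i in seq_along(records)) {
    rec <- records[[i]]
    if (!file.exists(rec$image_path))
      stop("unreadable image file: ", rec$image_path)
    img <- png::readPNG(rec$image_path)
    images[[i]] <- list(id = i, file_name = basename(rec$image_path),
                        width = ncol(img), height = nrow(img))
    if (is.null(rec$mask_path)) next
    mask <- (png::readPNG(rec$mask_path) > 0.5) * 1
    if (length(dim(mask)) == 3L) mask <- mask[, , 1]
    lab <- label_components(mask)
    ncomp <- max(lab)
    if (ncomp == 0L) next
    for (kcomp in seq_len(ncomp)) {
      comp <- (lab == kcomp) * 1
      seg <- if (encoding == "polygon") {
        polys <- mask_to_polygons(comp)
        if (length(polys) == 0L) next
        lapply(polys, function(p) as.numeric(t(p)))  # x1,y1,x2,y2,...
      } else {
        rle_encode_mask(comp)
      }
      ann_id <- ann_id + 1L
      annotations[[ann_id]] <- list(
        id = ann_id, image_id = i, category_id = 1L,
        segmentation = seg, bbox = mask_bbox(comp),
        area = sum(comp), iscrowd = 0L)
    }
  }
  ds <- structure(
    list(images = images, annotations = annotations,
         categories = list(list(id = 1L, name = "aneurysm"))),
    class = "coco_dataset"
  )
  validate_coco(ds)
  ds
}

#' Validate COCO referential integrity
#'
#' Checks every annotation references an existing image and category, has a
#' positive area, and a bbox enclosing its segmentation; errors on the
#' first violation.
#'
#' @param ds a `coco_dataset`.
#' @return `TRUE`, invisibly.
#' @export
validate_coco <- function(ds) {
  img_ids <- vapply(ds$images, `[[`, numeric(1), "id")
  cat_ids <- vapply(ds$categories, `[[`, numeric(1), "id")
  if (anyDuplicated(img_ids)) stop("duplicate image ids")
  for (a in ds$annotations) {
    if (!a$image_id %in% img_ids)
      stop("annotation ", a$id, " references missing image ", a$image_id)
    if (!a$category_id %in% cat_ids)
      stop("annotation ", a$id, " references missing category")
    if (a$area <= 0) stop("annotation ", a$id, " has nonpositive area")
    if (a$bbox[3] <= 0 || a$bbox[4] <= 0)
      stop("annotation ", a$id, " has degenerate bbox")
    if (is.list(a$segmentation) && !is.null(a$segmentation$size)) {
      m <- rle_decode_mask(a$segmentation)
      bb <- mask_bbox(m)
      if (is.null(bb) || any(bb[1:2] < a$bbox[1:2]) ||
          any(bb[1:2] + bb[3:4] > a$bbox[1:2] + a$bbox[3:4]))
        stop("annotation ", a$id, ": bbox does not enclose segmentation")
    }
  }
  invisible(TRUE)
}

#' @export
print.coco_dataset <- function(x, ...) {
  neg <- length(x$images) -
    length(unique(vapply(x$annotations, `[[`, numeric(1), "image_id")))
  cat(sprintf("<coco_dataset: %d images (%d without annotations), %d annotations, 1 category>\n",
              length(x$images), neg, length(x$annotations)))
  invisible(x)
}

#' Write a COCO dataset to JSON
#'
#' @param ds a `coco_dataset`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_coco <- function(ds, path) {
  validate_coco(ds)
  jsonlite::write_json(unclass(ds), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a COCO dataset from JSON
#'
#' @param path path to a COCO JSON file.
#' @return a `coco_dataset`.
#' @export
read_coco <- function(path) {
  ds <- jsonlite::read_json(path, simplifyVector = FALSE)
  ds$annotations <- lapply(ds$annotations, function(a) {
    a$bbox <- as.numeric(a$bbox)
    if (!is.null(a$segmentation$counts)) {
      a$segmentation$size <- as.integer(a$segmentation$size)
      a$segmentation$counts <- as.integer(a$segmentation$counts)
    } else {
      a$segmentation <- lapply(a$segmentation, as.numeric)
    }
    a
  })
  structure(ds, class = "coco_dataset")
}

#' Emit per-fold train/validation COCO files
#'
#' For each fold `f`, the training file holds the slices of the other
#' `k - 1` folds plus all healthy subjects (training-only negatives), and
#' the validation file holds only the held-out fold's aneurysmal subjects.
#' The subject-level disjointness of each train/validation pair is asserted
#' programmatically on every build.
#'
#' @param subjects list of `subject_record`s from [group_subjects()].
#' @param folds a [make_folds()] assignment.
#' @param dir output directory.
#' @param encoding `"bitmask"` or `"polygon"` (see [build_coco()]).
#' @return data frame with one row per fold: `fold`, `train_json`,
#'   `val_json`.
#' @export
emit_fold_files <- function(subjects, folds, dir,
                            encoding = c("bitmask", "polygon")) {
  encoding <- match.arg(encoding)
  stopifnot(inherits(folds, "fold_assignment"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  lab <- vapply(subjects, function(s) s$label, character(1))
  ids <- vapply(subjects, function(s) s$subject_id, character(1))
  healthy <- subjects[lab == "healthy"]
  rows <- vector("list", folds$k)
  for (f in 0:(folds$k - 1L)) {
    val_ids <- names(folds$assignment)[folds$assignment == f]
    train_ids <- names(folds$assignment)[folds$assignment != f]
    if (length(intersect(train_ids, val_ids)) > 0L)
      stop("patient-level leakage detected in fold ", f)  # unreachable
    train_subj <- c(subjects[match(train_ids, ids)], healthy)
    val_subj <- subjects[match(val_ids, ids)]
    train_rec <- unlist(lapply(train_subj, `[[`, "slices"), recursive = FALSE)
    val_rec <- unlist(lapply(val_subj, `[[`, "slices"), recursive = FALSE)
    tj <- file.path(dir, sprintf("dataset_fold%d_train.json", f))
    vj <- file.path(dir, sprintf("dataset_fold%d_val.json", f))
    write_coco(build_coco(train_rec, encoding), tj)
    write_coco(build_coco(val_rec, encoding), vj)
    rows[[f + 1L]] <- data.frame(fold = f, train_json = tj, val_json = vj)
  }
  do.call(rbind, rows)
}
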