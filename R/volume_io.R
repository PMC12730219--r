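#' Construct a voxel grid
#'
#' A `voxel_grid` bundles a 3D intensity lattice with its physical voxel
#' spacing (mm per voxel along in-plane x, in-plane y and the slice axis),
#' the subject it came from, and whether it is a binary lesion mask. The
#' slice (axial) axis is always the third lattice axis.
#'
#' @param data 3D numeric array.
#' @param spacing numeric length-3, `(sx, sy, sz)` in mm, all > 0.
#' @param subject_id subject token, e.g. `"sub_05"`.
#' @param is_mask logical; masks must contain only values 0 and 1.
#' @return object of class `voxel_grid`.
#' @export
voxel_grid <- function(data, spacing, subject_id, is_mask = FALSE) {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("expected 3 axes, got ", length(dim(data)))
  if (any(dim(data) < 1L)) stop("every axis must have length >= 1")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("spacing must be 3 positive values (mm)")
  if (isTRUE(is_mask) && !is_binary(data))
    stop("mask grids may only contain values 0 and 1")
  structure(
    list(data = data, spacing = spacing, subject_id = as.character(subject_id),
         is_mask = isTRUE(is_mask)),
    class = "voxel_grid"
  )
}

#' @export
print.voxel_grid <- function(x, ...) {
  cat(sprintf("<voxel_grid %s%s: %s voxels, spacing %s mm>\n",
              x$subject_id, if (x$is_mask) " (mask)" else "",
              paste(dim(x$data), collapse = "x"),
              paste(format(x$spacing), collapse = " x ")))
  invisible(x)
}

#' Read a NIfTI volume
#'
#' Reads a 3D NIfTI file (`.nii` or `.nii.gz`) and returns a [voxel_grid()]
#' whose spacing comes from the file header (never a fabricated default).
#' Skull stripping, if wanted, is expected to have been applied upstream to
#' the supplied file; the toolkit does not call external brain-extraction
#' binaries.
#'
#' @param path path to a NIfTI file.
#' @param subject_id subject token; by default derived from the file name by
#'   stripping the extension and any trailing `"_mask"`.
#' @param is_mask logical; when `TRUE` the data are validated (and coerced
#'   from \{0, nonzero\}) to a binary mask.
#' @return a [voxel_grid()].
#' @export
read_volume <- function(path, subject_id = NULL, is_mask = FALSE) {
  if (!file.exists(path)) stop("no such file: ", path)
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) != 3L)
    stop("expected 3 axes, got ", length(d), " in ", path)
  spacing <- RNifti::pixdim(img)[1:3]
  if (is.null(subject_id)) {
    subject_id <- sub("\\.nii(\\.gz)?$", "", basename(path))
    subject_id <- sub("_mask$", "", subject_id)
  }
  data <- as.array(img)
  dim(data) <- d
  if (is_mask) data <- (data != 0) * 1
  voxel_grid(data, spacing, subject_id, is_mask = is_mask)
}

#' Write a voxel grid to NIfTI
#'
#' @param vol a [voxel_grid()].
#' @param path output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path) {
  stopifnot(inherits(vol, "voxel_grid"))
  img <- RNifti::asNifti(vol$data)
  RNifti::pixdim(img) <- vol$spacing
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Construct an axial slice
#'
#' One 2D axial plane cut from a [voxel_grid()], carrying the in-plane
#' spacing and its 0-based slice index.
#'
#' @param pixels 2D numeric matrix.
#' @param in_plane_spacing `(sx, sy)` in mm.
#' @param subject_id subject token.
#' @param slice_index 0-based integer.
#' @param kind `"image"` or `"mask"`; mask slices must be binary.
#' @return object of class `axial_slice`.
#' @export
axial_slice <- function(pixels, in_plane_spacing, subject_id, slice_index,
                        kind = c("image", "mask")) {
  kind <- match.arg(kind)
  if (!is.matrix(pixels)) stop("pixels must be a matrix")
  in_plane_spacing <- as.numeric(in_plane_spacing)
  if (length(in_plane_spacing) != 2L || any(in_plane_spacing <= 0))
    stop("in_plane_spacing must be 2 positive values (mm)")
  slice_index <- as.integer(slice_index)
  if (is.na(slice_index) || slice_index < 0L)
    stop("slice_index must be a nonnegative integer")
  if (kind == "mask" && !is_binary(pixels))
    stop("mask slices must be binary")
  structure(
    list(pixels = pixels, in_plane_spacing = in_plane_spacing,
         subject_id = as.character(subject_id), slice_index = slice_index,
         kind = kind),
    class = "axial_slice"
  )
}

#' @export
print.axial_slice <- function(x, ...) {
  cat(sprintf("<axial_slice %s [%s]: %dx%d px, %s mm>\n",
              make_identifier(x$subject_id, x$slice_index), x$kind,
              nrow(x$pixels), ncol(x$pixels),
              paste(format(x$in_plane_spacing), collapse = " x ")))
  invisible(x)
}

#' Slice a volume along the axial axis
#'
#' Cuts a [voxel_grid()] into one [axial_slice()] per index along the third
#' lattice axis, preserving order; each slice carries the in-plane spacing
#' and a 0-based `slice_index`.
#'
#' @param vol a [voxel_grid()].
#' @return list of [axial_slice()] objects, indices `0 .. nz-1`.
#' @export
slice_axial <- function(vol) {
  stopifnot(inherits(vol, "voxel_grid"))
  nz <- dim(vol$data)[3]
  kind <- if (vol$is_mask) "mask" else "image"
  lapply(seq_len(nz), function(k) {
    axial_slice(vol$data[, , k, drop = TRUE], vol$spacing[1:2],
                vol$subject_id, k - 1L, kind)
  })
}

#' Re-stack axial slices into a volume
#'
#' Inverse of [slice_axial()]; mainly used to verify lossless slicing.
#'
#' @param slices list of [axial_slice()] objects with consecutive indices.
#' @param spacing_z slice-axis spacing in mm.
#' @return a [voxel_grid()].
#' @export
stack_axial <- function(slices, spacing_z) {
  stopifnot(length(slices) >= 1L)
  s1 <- slices[[1]]
  data <- array(0, dim = c(dim(s1$pixels), length(slices)))
  for (i in seq_along(slices)) data[, , i] <- slices[[i]]$pixels
  voxel_grid(data, c(s1$in_plane_spacing, spacing_z), s1$subject_id,
             is_mask = s1$kind == "mask")
}

#' Min-max intensity normalization to 0-255
#'
#' Rescales an image slice to 8-bit range:
#' \deqn{I_{norm} = round((I - I_{min}) / (I_{max} - I_{min}) \times 255)}
#' with the minimum and maximum taken over the slice itself, and rounding
#' half-up. A constant slice (\eqn{I_{max} = I_{min}}, e.g. pure background)
#' maps to all zeros rather than raising an error, so batch processing never
#' aborts on empty slices.
#'
#' The statistics are per-slice, not per-volume; pass a re-stacked volume
#' through [normalize_volume()] if per-volume statistics are wanted.
#'
#' @param s an [axial_slice()] of kind `"image"`.
#' @return an [axial_slice()] with integer pixels in `[0, 255]`.
#' @export
normalize_intensity <- function(s) {
  stopifnot(inherits(s, "axial_slice"))
  if (s$kind != "image") stop("normalize_intensity applies to image slices")
  rng <- range(s$pixels)
  px <- if (rng[2] > rng[1]) {
    round_half_up((s$pixels - rng[1]) / (rng[2] - rng[1]) * 255)
  } else {
    array(0, dim = dim(s$pixels))
  }
  s$pixels <- matrix(px, nrow(s$pixels), ncol(s$pixels))
  s
}

#' Min-max normalization with volume-wide statistics
#'
#' Variant of [normalize_intensity()] using the minimum and maximum of the
#' whole volume for every slice, for users who prefer cross-slice
#' comparability over per-slice dynamic range.
#'
#' @param vol a non-mask [voxel_grid()].
#' @return a [voxel_grid()] with integer voxels in `[0, 255]`.
#' @export
normalize_volume <- function(vol) {
  stopifnot(inherits(vol, "voxel_grid"), !vol$is_mask)
  rng <- range(vol$data)
  vol$data <- if (rng[2] > rng[1]) {
    round_half_up((vol$data - rng[1]) / (rng[2] - rng[1]) * 255)
  } else {
    array(0, dim = dim(vol$data))
  }
  vol
}

slice_png_name <- function(s, variant = NULL) {
  base <- make_identifier(s$subject_id, s$slice_index)
  if (!is.null(variant) && nzchar(variant)) base <- paste0(base, "__", variant)
  paste0(base, if (s$kind == "mask") "_mask", ".png")
}

#' Write an axial slice as an 8-bit grayscale PNG
#'
#' Image slices must already be normalized to integers in `[0, 255]`; mask
#' slices are stored with foreground 255 / background 0 and re-binarized on
#' read. The round-trip through [read_slice_png()] is lossless.
#'
#' File names follow the identifier grammar:
#' `sub_<id>_slice_<k>.png` and `sub_<id>_slice_<k>_mask.png`, with an
#' optional `__<variant>` tag before the suffix for augmented copies.
#'
#' @param s an [axial_slice()].
#' @param dir output directory (created if absent).
#' @param variant optional tag for augmented variants, e.g. `"rot15"`.
#' @return path of the written file, invisibly.
#' @export
write_slice_png <- function(s, dir, variant = NULL) {
  stopifnot(inherits(s, "axial_slice"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  px <- s$pixels
  if (s$kind == "image") {
    if (any(px < 0 | px > 255)) stop("image slice not in [0, 255]; normalize first")
    val <- px / 255
  } else {
    val <- (px != 0) * 1
  }
  path <- file.path(dir, slice_png_name(s, variant))
  png::writePNG(val, path)
  invisible(path)
}

#' Read an axial slice back from PNG
#'
#' @param path path to a PNG written by [write_slice_png()].
#' @param in_plane_spacing `(sx, sy)` mm; PNG carries no physical spacing,
#'   so it must be supplied (default `c(1, 1)`).
#' @return an [axial_slice()]; `kind` and identity are recovered from the
#'   file name (masks are re-binarized to \{0, 1\}).
#' @export
read_slice_png <- function(path, in_plane_spacing = c(1, 1)) {
  px <- png::readPNG(path)
  if (length(dim(px)) == 3L) px <- px[, , 1]  # tolerate gray+alpha
  base <- sub("\\.png$", "", basename(path))
  is_mask <- grepl("_mask$", base)
  base <- sub("_mask$", "", base)
  base <- sub("__[A-Za-z0-9+-]+$", "", base)  # strip augmentation tag
  id <- parse_identifier(base)
  px <- if (is_mask) (px > 0.5) * 1 else round_half_up(px * 255)
  axial_slice(matrix(px, nrow(px), ncol(px)), in_plane_spacing,
              id$subject_id, id$slice_index,
              kind = if (is_mask) "mask" else "image")
}

#' Construct a slice record
#'
#' A `slice_record` points at a written image PNG and (for aneurysmal
#' slices) its mask PNG, keyed by the subject-slice identifier.
#'
#' @param image_path path to the image PNG.
#' @param mask_path path to the mask PNG, or `NULL` for healthy slices.
#' @param subject_id,slice_index identity; defaults parsed from
#'   `image_path`'s file name.
#' @return object of class `slice_record` with fields `image_path`,
#'   `mask_path`, `subject_id`, `slice_index`, `identifier`.
#' @export
slice_record <- function(image_path, mask_path = NULL,
                         subject_id = NULL, slice_index = NULL) {
  if (is.null(subject_id) || is.null(slice_index)) {
    base <- sub("\\.png$", "", basename(image_path))
    base <- sub("__[A-Za-z0-9+-]+$", "", base)
    id <- parse_identifier(base)
    subject_id <- id$subject_id
    slice_index <- id$slice_index
  }
  structure(
    list(image_path = image_path, mask_path = mask_path,
         subject_id = subject_id, slice_index = as.integer(slice_index),
         identifier = make_identifier(subject_id, slice_index)),
    class = "slice_record"
  )
}

#' Validate image/mask pairing of slice records
#'
#' Reports records whose expected mask file is missing on disk or whose mask
#' dimensions differ from the image. A clean record set yields a zero-row
#' report; callers may drop the flagged records before dataset building.
#'
#' @param records list of [slice_record()]s.
#' @return data frame with columns `identifier` and `problem`
#'   (`"missing_mask"` or `"dim_mismatch"`); zero rows when all consistent.
#' @export
validate_pairs <- function(records) {
  rows <- list()
  for (rec in records) {
    if (is.null(rec$mask_path)) next  # healthy: no mask expected
    if (!file.exists(rec$mask_path)) {
      rows[[length(rows) + 1L]] <- data.frame(
        identifier = rec$identifier, problem = "missing_mask")
      next
    }
    di <- dim(png::readPNG(rec$image_path))[1:2]
    dm <- dim(png::readPNG(rec$mask_path))[1:2]
    if (!identical(di, dm)) {
      rows[[length(rows) + 1L]] <- data.frame(
        identifier = rec$identifier, problem = "dim_mismatch")
    }
  }
  if (length(rows) == 0L)
    return(data.frame(identifier = character(), problem = character()))
  do.call(rbind, rows)
}

#' Preprocess one volume (and optional mask) into PNG slice pairs
#'
#' Slices the volume axially, normalizes every image slice to 0-255
#' ([normalize_intensity()], or volume-wide statistics with
#' `per_volume_norm = TRUE`), writes image and mask PNGs, and returns one
#' [slice_record()] per axial index.
#'
#' @param vol a non-mask [voxel_grid()].
#' @param mask matching mask [voxel_grid()] or `NULL` for healthy volumes.
#' @param dir output directory.
#' @param per_volume_norm use volume-wide min/max instead of per-slice.
#' @return list of [slice_record()]s.
#' @export
preprocess_volume <- function(vol, mask = NULL, dir, per_volume_norm = FALSE) {
  stopifnot(inherits(vol, "voxel_grid"), !vol$is_mask)
  if (!is.null(mask)) {
    stopifnot(inherits(mask, "voxel_grid"), mask$is_mask)
    if (!identical(dim(vol$data), dim(mask$data)))
      stop("image and mask dimensions differ for ", vol$subject_id)
  }
  if (per_volume_norm) vol <- normalize_volume(vol)
  slices <- slice_axial(vol)
  mslices <- if (!is.null(mask)) slice_axial(mask)
  records <- vector("list", length(slices))
  for (i in seq_along(slices)) {
    s <- if (per_volume_norm) slices[[i]] else normalize_intensity(slices[[i]])
    ip <- write_slice_png(s, dir)
    mp <- if (!is.null(mslices)) write_slice_png(mslices[[i]], dir)
    records[[i]] <- slice_record(ip, mp, s$subject_id, s$slice_index)
  }
  records
}

#' Preprocess a directory of NIfTI volumes
#'
#' Expects `sub_XX.nii(.gz)` image volumes with optional `sub_XX_mask`
#' companions (in `masks_dir`, defaulting to `input_dir`); subjects without
#' a mask file are treated as healthy. Returns all slice records plus a
#' pairing report from [validate_pairs()].
#'
#' @param input_dir directory of image volumes.
#' @param output_dir directory for PNG slices.
#' @param masks_dir directory of mask volumes (default: `input_dir`).
#' @param per_volume_norm see [preprocess_volume()].
#' @return list with `records` (list of [slice_record()]) and `report`
#'   (data frame from [validate_pairs()]).
#' @export
preprocess_cohort <- function(input_dir, output_dir, masks_dir = input_dir,
                              per_volume_norm = FALSE) {
  files <- list.files(input_dir, pattern = "\\.nii(\\.gz)?$", full.names = TRUE)
  files <- files[!grepl("_mask\\.nii(\\.gz)?$", files)]
  if (length(files) == 0L) stop("no NIfTI volumes found in ", input_dir)
  records <- list()
  for (f in sort(files)) {
    vol <- read_volume(f)
    mf <- file.path(masks_dir,
                    sub("\\.nii(\\.gz)?$", "_mask.nii\\1", basename(f)))
    mask <- if (file.exists(mf)) read_volume(mf, vol$subject_id, is_mask = TRUE)
    records <- c(records,
                 preprocess_volume(vol, mask, output_dir, per_volume_norm))
  }
  list(records = records, report = validate_pairs(records))
}
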