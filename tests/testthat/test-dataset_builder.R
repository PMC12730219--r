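test_that("round-robin fold assignment balances 161 subjects into 33/32/32/32/32", {
  ids <- sprintf("sub_%03d", 1:161)
  folds <- make_folds(ids, k = 5, seed = 3)
  sizes <- sort(tabulate(folds$assignment + 1L, 5), decreasing = TRUE)
  expect_equal(sizes, c(33, 32, 32, 32, 32))
  expect_setequal(names(folds$assignment), ids)
  expect_true(all(folds$assignment >= 0 & folds$assignment < 5))
})

test_that("fold assignment is seed-reproducible, excludes healthy subjects and requires k subjects", {
  sl <- fixture_slices()
  subjects <- group_subjects(sl$pre$records)
  labels <- vapply(subjects, `[[`, character(1), "label")
  expect_equal(sum(labels == "aneurysmal"), 6)
  expect_equal(sum(labels == "healthy"), 2)

  f1 <- make_folds(subjects, k = 3, seed = 5)
  f2 <- make_folds(subjects, k = 3, seed = 5)
  expect_identical(f1$assignment, f2$assignment)
  healthy_ids <- vapply(subjects[labels == "healthy"], `[[`, character(1),
                        "subject_id")
  expect_length(intersect(names(f1$assignment), healthy_ids), 0)
  expect_error(make_folds(subjects, k = 7, seed = 1), "at least k")
  expect_error(make_folds(sprintf("sub_%02d", 1:4), k = 2, seed = 1), NA)
})

test_that("mask_to_polygons traces components whose rasterization is exact", {
  expect_length(mask_to_polygons(matrix(0, 10, 10)), 0)

  # filled 3x3 square at rows/cols 5..7 (0-based 4..6)
  m <- matrix(0, 12, 12); m[5:7, 5:7] <- 1
  polys <- mask_to_polygons(m)
  expect_length(polys, 1)
  expect_gte(nrow(polys[[1]]), 3)
  expect_equal(polygons_to_mask(polys, 12, 12), m)

  # two disjoint blobs -> two polygons
  m2 <- matrix(0, 20, 20); m2[2:4, 2:4] <- 1; m2[10:15, 10:14] <- 1
  expect_length(mask_to_polygons(m2), 2)

  # random blobs: rasterize-back covers the source (holes filled), and the
  # round-trip is idempotent after one cycle
  set.seed(12)
  for (i in 1:20) {
    mm <- matrix(rbinom(625, 1, 0.35), 25, 25)
    pp <- mask_to_polygons(mm)
    back <- polygons_to_mask(pp, 25, 25)
    expect_true(all(back >= mm))
    back2 <- polygons_to_mask(mask_to_polygons(back), 25, 25)
    expect_equal(back2, back)
  }
})

test_that("bitmask RLE encoding is lossless including holes", {
  m <- matrix(0, 15, 15)
  m[4:10, 4:10] <- 1
  m[6:8, 6:8] <- 0  # hole: preserved by bitmask, filled by polygons
  r <- rle_encode_mask(m)
  expect_identical(rle_decode_mask(r), m)
  filled <- polygons_to_mask(mask_to_polygons(m), 15, 15)
  expect_true(all(filled[6:8, 6:8] == 1))
})

test_that("build_coco yields per-component annotations with correct bbox and area", {
  d <- tempfile("coco")
  img <- axial_slice(matrix(128, 16, 16), c(1, 1), "sub_01", 0)
  mask <- matrix(0, 16, 16)
  mask[5:7, 5:7] <- 1       # 3x3 square, 0-based corner (4,4)
  mask[12:13, 2:3] <- 1     # second component
  ip <- write_slice_png(img, d)
  mp <- write_slice_png(axial_slice(mask, c(1, 1), "sub_01", 0, "mask"), d)
  ds <- build_coco(list(slice_record(ip, mp)), encoding = "bitmask")
  expect_length(ds$images, 1)
  expect_length(ds$annotations, 2)
  sq <- Filter(function(a) a$area == 9, ds$annotations)[[1]]
  expect_equal(sq$bbox, c(4, 4, 3, 3))
  expect_equal(rle_decode_mask(sq$segmentation) +
                 rle_decode_mask(ds$annotations[[
                   which(vapply(ds$annotations, `[[`, numeric(1), "area") == 4)
                 ]]$segmentation), mask)
  expect_equal(vapply(ds$categories, `[[`, character(1), "name"), "aneurysm")
})

test_that("healthy and empty-mask slices appear as images with zero annotations", {
  d <- tempfile("coco2")
  img1 <- axial_slice(matrix(50, 16, 16), c(1, 1), "sub_01", 0)
  img2 <- axial_slice(matrix(60, 16, 16), c(1, 1), "sub_02", 0)
  empty_mask <- axial_slice(matrix(0, 16, 16), c(1, 1), "sub_02", 0, "mask")
  healthy <- slice_record(write_slice_png(img1, d), NULL)
  emptyrec <- slice_record(write_slice_png(img2, d),
                           write_slice_png(empty_mask, d))
  ds <- build_coco(list(healthy, emptyrec))
  expect_length(ds$images, 2)
  expect_length(ds$annotations, 0)
  f <- tempfile(fileext = ".json")
  write_coco(ds, f)
  parsed <- jsonlite::read_json(f)
  expect_length(parsed$annotations, 0)
  expect_length(parsed$images, 2)
})

test_that("polygon-encoded dataset re-rasterizes with IoU >= 0.95 for components >= 10 px", {
  d <- tempfile("coco3")
  img <- axial_slice(matrix(128, 40, 40), c(1, 1), "sub_01", 3)
  mask <- disk_mask(40, 7)
  ip <- write_slice_png(img, d)
  mp <- write_slice_png(axial_slice(mask, c(1, 1), "sub_01", 3, "mask"), d)
  ds <- build_coco(list(slice_record(ip, mp)), encoding = "polygon")
  seg <- ds$annotations[[1]]$segmentation
  polys <- lapply(seg, function(v) matrix(v, ncol = 2, byrow = TRUE))
  back <- polygons_to_mask(polys, 40, 40)
  iou <- sum(back & mask) / sum(back | mask)
  expect_gte(iou, 0.95)
})

test_that("COCO JSON written to disk survives a read round-trip and validates", {
  sl <- fixture_slices()
  subjects <- group_subjects(sl$pre$records)
  recs <- subjects[[1]]$slices
  ds <- build_coco(recs, encoding = "bitmask")
  f <- tempfile(fileext = ".json")
  write_coco(ds, f)
  back <- read_coco(f)
  expect_true(validate_coco(back))
  expect_length(back$images, length(ds$images))
  expect_length(back$annotations, length(ds$annotations))
  if (length(ds$annotations)) {
    expect_identical(rle_decode_mask(back$annotations[[1]]$segmentation),
                     rle_decode_mask(ds$annotations[[1]]$segmentation))
  }
})

test_that("emit_fold_files enforces patient-level separation and negative-only healthy use", {
  sl <- fixture_slices()
  subjects <- group_subjects(sl$pre$records)
  labels <- vapply(subjects, `[[`, character(1), "label")
  healthy_ids <- vapply(subjects[labels == "healthy"], `[[`, character(1),
                        "subject_id")
  folds <- make_folds(subjects, k = 3, seed = 2)
  d <- tempfile("folds")
  files <- emit_fold_files(subjects, folds, d, "bitmask")
  expect_equal(nrow(files), 3)

  subj_of <- function(json) {
    ds <- read_coco(json)
    unique(vapply(ds$images, function(im)
      parse_identifier(sub("\\.png$", "", im$file_name))$subject_id,
      character(1)))
  }
  val_union <- character()
  for (i in seq_len(nrow(files))) {
    tr <- subj_of(files$train_json[i])
    va <- subj_of(files$val_json[i])
    expect_length(intersect(tr, va), 0)        # zero leakage
    expect_true(all(healthy_ids %in% tr))       # healthy in every train set
    expect_length(intersect(va, healthy_ids), 0)
    val_union <- c(val_union, va)
  }
  # validation folds partition the aneurysmal subjects exactly once
  expect_setequal(val_union, names(folds$assignment))
  expect_equal(anyDuplicated(val_union), 0)
})
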