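test_that("zero rotation is the identity on image and mask", {
  img <- matrix(sample(0:255, 100, replace = TRUE), 10, 10)
  mask <- disk_mask(10, 3)
  r <- rotate_pair(img, mask, 0)
  expect_equal(r$image, img)
  expect_equal(r$mask, mask)
})

test_that("90-degree rotation matches a brute-force coordinate-remap oracle", {
  # oracle: forward-map every source pixel through the rotation matrix
  # about the center and place it at the rounded destination
  oracle_rot <- function(px, theta) {
    n <- nrow(px); out <- matrix(0, n, ncol(px))
    cx <- (ncol(px) - 1) / 2; cy <- (n - 1) / 2
    th <- theta * pi / 180
    for (r in seq_len(n)) for (c in seq_len(ncol(px))) {
      x <- c - 1 - cx; y <- r - 1 - cy
      xd <- round(cos(th) * x - sin(th) * y + cx)
      yd <- round(sin(th) * x + cos(th) * y + cy)
      if (xd >= 0 && xd < ncol(px) && yd >= 0 && yd < n)
        out[yd + 1, xd + 1] <- px[r, c]
    }
    out
  }
  for (hot in list(c(1, 2), c(3, 3), c(2, 1))) {
    px <- matrix(0, 3, 3); px[hot[1], hot[2]] <- 1
    r <- rotate_pair(px * 255, px, 90)
    expect_equal(r$mask, oracle_rot(px, 90))
    expect_equal(r$image / 255, oracle_rot(px, 90))
  }
})

test_that("rotating +15 then -15 degrees recovers at least 90% of mask foreground", {
  mask <- disk_mask(50, 12)
  once <- rotate_pair(mask * 255, mask, 15)
  back <- rotate_pair(once$image, once$mask, -15)
  recovered <- sum(back$mask * mask) / sum(mask)
  expect_gte(recovered, 0.90)
  expect_true(all(back$mask %in% c(0, 1)))
})

test_that("rotation preserves mask foreground count within 15% on a disk", {
  mask <- disk_mask(50, 12)
  rot <- rotate_pair(mask * 255, mask, 15)
  expect_lt(abs(sum(rot$mask) - sum(mask)) / sum(mask), 0.15)
})

test_that("contrast adjustment applies alpha*I + beta with clipping, exhaustively", {
  I <- matrix(0:255, 1)
  out <- adjust_contrast(I, 0.5, -100)
  expect_equal(out, floor(pmin(pmax(0.5 * I - 100, 0), 255) + 0.5))
  expect_equal(adjust_contrast(matrix(200), 0.5, -100)[1, 1], 0)
  expect_equal(adjust_contrast(matrix(50), 0.5, -100)[1, 1], 0)  # clipped
  expect_equal(adjust_contrast(I, 1, 0), I)  # identity
  expect_true(all(out >= 0 & out <= 255))
})

test_that("gamma correction matches direct scalar evaluation with fixed points", {
  I <- matrix(0:255, 1)
  out <- gamma_correct(I, 2.0)
  expect_equal(out, floor(255 * (I / 255)^(1 / 2) + 0.5))
  expect_equal(out[1, 1], 0)      # I = 0 fixed point
  expect_equal(out[1, 256], 255)  # I = 255 fixed point
  expect_equal(gamma_correct(matrix(64), 2.0)[1, 1], 128)
  expect_equal(gamma_correct(I, 1), I)  # gamma 1 identity
  for (g in c(0.5, 1.7, 3)) {
    o <- gamma_correct(I, g)
    expect_equal(o[1, 1], 0)
    expect_equal(o[1, 256], 255)
    expect_true(all(o >= 0 & o <= 255))
  }
})

test_that("gaussian noise is seeded, reproducible and calibrated", {
  img <- matrix(128, 256, 256)
  expect_equal(add_gaussian_noise(img, 0), img)  # sigma 0 identity
  a <- add_gaussian_noise(img, 5, seed = 9)
  b <- add_gaussian_noise(img, 5, seed = 9)
  expect_identical(a, b)
  expect_true(sd(a) > 4 && sd(a) < 6)
  expect_true(all(a >= 0 & a <= 255))
})

test_that("augment_record expands a slice into the operator set, masks consistent, no reflections", {
  d <- tempfile("aug")
  img <- axial_slice(matrix(sample(0:255, 2500, replace = TRUE), 50, 50),
                     c(0.5, 0.5), "sub_03", 7)
  mask <- axial_slice(disk_mask(50, 8), c(0.5, 0.5), "sub_03", 7, "mask")
  rec <- slice_record(write_slice_png(img, d), write_slice_png(mask, d))
  spec <- augmentation_spec(noise_sigma = 5, seed = 2)
  out <- augment_record(rec, spec, d, c(0.5, 0.5))
  # +15, -15, contrast, gamma, noise
  expect_length(out, 5)
  tags <- sub("^.*__([A-Za-z0-9+-]+)\\.png$", "\\1",
              vapply(out, `[[`, character(1), "image_path"))
  expect_setequal(tags, c("rot+15", "rot-15", "contrast", "gamma", "noise"))
  expect_false(any(grepl("flip|mirror", tags)))

  src_img <- read_slice_png(rec$image_path)$pixels
  src_mask <- read_slice_png(rec$mask_path)$pixels
  for (r in out) {
    tag <- sub("^.*__([A-Za-z0-9+-]+)\\.png$", "\\1", r$image_path)
    m <- read_slice_png(r$mask_path)$pixels
    aug <- read_slice_png(r$image_path)$pixels
    expect_true(all(m %in% c(0, 1)))
    if (tag %in% c("contrast", "gamma", "noise")) {
      # photometric ops pass the mask through bit-identically
      expect_identical(m, src_mask)
    } else {
      expect_lt(abs(sum(m) - sum(src_mask)) / sum(src_mask), 0.15)
    }
    # no mirrored variant hiding under any tag
    expect_false(identical(aug, src_img[, ncol(src_img):1]))
    expect_false(identical(aug, src_img[nrow(src_img):1, ]))
  }
})

test_that("healthy records (no mask) augment to images only", {
  d <- tempfile("aug2")
  img <- axial_slice(matrix(sample(0:255, 100, replace = TRUE), 10, 10),
                     c(1, 1), "sub_04", 0)
  rec <- slice_record(write_slice_png(img, d), NULL)
  out <- augment_record(rec, augmentation_spec(), d)
  expect_length(out, 4)  # two rotations + contrast + gamma, no noise
  expect_true(all(vapply(out, function(r) is.null(r$mask_path), logical(1))))
})

test_that("augmentation spec validates its parameters", {
  expect_error(augmentation_spec(alpha = 0))
  expect_error(augmentation_spec(gamma = -1))
  expect_error(augmentation_spec(noise_sigma = -2))
})
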