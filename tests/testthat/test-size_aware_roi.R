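test_that("physical area scales with bbox and voxel spacing", {
  p <- proposal(c(0, 0, 10, 10), 0.9, "sub_00_slice_00")
  expect_equal(physical_area(p, c(0.5, 0.5)), 25)
  expect_equal(physical_area(proposal(c(3, 4, 1, 1), 0.5, "x"), c(1, 1)), 1)
  expect_equal(physical_area(p, c(1, 1)), 4 * physical_area(p, c(0.5, 0.5)))
  # translation invariance
  expect_equal(physical_area(proposal(c(40, 17, 10, 10), 0.9, "x"),
                             c(0.5, 0.5)), 25)
  expect_error(physical_area(p, c(0, 0.5)), "positive")
})

test_that("small-object gate uses strict inequality at 28 mm^2", {
  t <- size_thresholds()
  expect_equal(t$small_area_mm2, 28)
  sp <- c(0.5, 0.5)
  expect_true(is_small(proposal(c(0, 0, 10, 10), 0.9, "x"), sp, t))   # 25 mm2
  # exactly 28 mm2: 14 x 8 px at 0.5 mm -> 14*8*0.25 = 28
  expect_false(is_small(proposal(c(0, 0, 14, 8), 0.9, "x"), sp, t))
  expect_false(is_small(proposal(c(0, 0, 20, 20), 0.9, "x"), sp, t))  # 100 mm2
})

test_that("dual-threshold filtering rescues small proposals and only adds to the base cut", {
  t <- size_thresholds()  # tau_base 0.9457, tau_small 0.60
  sp <- c(0.5, 0.5)
  small_p <- proposal(c(0, 0, 10, 10), 0.70, "a")       # 25 mm2 < 28
  big_p <- proposal(c(0, 0, 20, 20), 0.70, "b")         # 100 mm2
  kept <- filter_proposals(list(small_p, big_p), sp, t)
  expect_length(kept, 1)
  expect_identical(kept[[1]]$slice_ref, "a")
  expect_length(filter_proposals(list(), sp, t), 0)

  # 1000 random proposals vs brute-force oracle, plus superset property
  set.seed(8)
  ps <- lapply(1:1000, function(i) {
    proposal(c(stats::runif(2, 0, 50),
               stats::runif(1, 1, 25), stats::runif(1, 1, 25)),
             stats::runif(1), sprintf("s%d", i))
  })
  kept <- filter_proposals(ps, sp, t)
  oracle_keep <- vapply(ps, function(p) {
    area <- p$bbox[3] * p$bbox[4] * 0.25
    if (area < 28) p$score >= 0.60 else p$score >= t$tau_base
  }, logical(1))
  expect_identical(vapply(kept, `[[`, character(1), "slice_ref"),
                   vapply(ps[oracle_keep], `[[`, character(1), "slice_ref"))
  base_cut <- vapply(ps, function(p) p$score >= t$tau_base, logical(1))
  expect_true(all(which(base_cut) %in% which(oracle_keep)))

  # with tau_small = tau_base the filter equals the uniform cut
  tu <- size_thresholds(tau_base = 0.8, tau_small = 0.8)
  kept_u <- filter_proposals(ps, sp, tu)
  expect_length(kept_u, sum(vapply(ps, `[[`, numeric(1), "score") >= 0.8))
})

test_that("threshold monotonicity: raising tau_base never adds, lowering tau_small never removes", {
  set.seed(15)
  sp <- c(0.6, 0.6)
  ps <- lapply(1:300, function(i)
    proposal(c(0, 0, stats::runif(1, 1, 20), stats::runif(1, 1, 20)),
             stats::runif(1), sprintf("s%d", i)))
  refs <- function(kk) vapply(kk, `[[`, character(1), "slice_ref")
  k1 <- filter_proposals(ps, sp, size_thresholds(tau_base = 0.7,
                                                 tau_small = 0.5))
  k2 <- filter_proposals(ps, sp, size_thresholds(tau_base = 0.9,
                                                 tau_small = 0.5))
  expect_true(all(refs(k2) %in% refs(k1)))
  k3 <- filter_proposals(ps, sp, size_thresholds(tau_base = 0.7,
                                                 tau_small = 0.3))
  expect_true(all(refs(k1) %in% refs(k3)))
})

test_that("pooling directives route small proposals to P2-P3 at 14x14", {
  sp <- c(0.5, 0.5)
  small_d <- pooling_plan(proposal(c(0, 0, 8, 8), 0.9, "x"), sp)  # 16 mm2
  expect_equal(small_d$fpn_levels, c("P2", "P3"))
  expect_equal(small_d$pool_resolution, 14L)
  big_d <- pooling_plan(proposal(c(0, 0, 30, 30), 0.9, "x"), sp)
  expect_equal(big_d$pool_resolution, 7L)
  expect_gte(length(big_d$fpn_levels), 1)
})

test_that("proposal stream round-trips through JSON lines, pooling included", {
  mask <- matrix(0, 20, 20); mask[5:8, 5:9] <- 1
  ps <- list(proposal(c(4, 4, 5, 4), 0.8123, "sub_01_slice_03", mask),
             proposal(c(0, 0, 3, 3), 0.42, "sub_01_slice_04"))
  sp <- c(0.5, 0.5)
  pooling <- lapply(ps, pooling_plan, spacing = sp)
  f <- tempfile(fileext = ".jsonl")
  write_proposals(ps, f, pooling)
  back <- read_proposals(f)
  expect_length(back, 2)
  expect_equal(back[[1]]$bbox, ps[[1]]$bbox)
  expect_equal(back[[1]]$score, ps[[1]]$score)
  expect_identical(back[[1]]$mask, mask)
  expect_null(back[[2]]$mask)
  expect_equal(attr(back, "pooling")[[1]], pooling[[1]])
  # filters chain: re-emitted stream is identical
  f2 <- tempfile(fileext = ".jsonl")
  write_proposals(back, f2, attr(back, "pooling"))
  expect_identical(readLines(f), readLines(f2))
})

test_that("size categories follow the 3/5 mm equivalent-diameter bounds", {
  # A = 9 mm^2 -> d = 2*sqrt(9/pi) = 3.385 -> medium
  m9 <- matrix(0, 10, 10); m9[1:3, 1:3] <- 1
  expect_equal(size_category(m9, c(1, 1)), "medium")
  # A = 25 mm^2 -> d = 5.642 -> large
  m25 <- matrix(0, 10, 10); m25[1:5, 1:5] <- 1
  expect_equal(size_category(m25, c(1, 1)), "large")
  expect_equal(equivalent_diameter(m25, c(1, 1)), 2 * sqrt(25 / pi))
  # diameter-level boundary conventions: d = 5 medium, d > 5 large, d < 3 small
  expect_equal(size_category_from_diameter(c(2, 2.999, 3, 5, 5.001)),
               c("small", "small", "medium", "medium", "large"))
  expect_error(size_category(matrix(0, 4, 4), c(1, 1)), "empty")
})

test_that("size_category is monotone in mask area and uses the max-area slice in 3D", {
  sp <- c(0.5, 0.5)
  prev <- 0
  for (r in c(2, 4, 6, 8, 10)) {
    d <- equivalent_diameter(disk_mask(30, r), sp)
    expect_gt(d, prev)
    prev <- d
  }
  arr <- array(0, dim = c(30, 30, 3))
  arr[, , 1][disk_mask(30, 3) == 1] <- 1
  arr[, , 2][disk_mask(30, 9) == 1] <- 1
  expect_equal(equivalent_diameter(arr, sp),
               equivalent_diameter(disk_mask(30, 9), sp))
})

test_that("size_thresholds presets and invariants hold", {
  expect_equal(size_thresholds()$tau_base, 0.9457)
  expect_equal(size_thresholds(preset = "baseline")$tau_base, 0.90)
  expect_equal(size_thresholds()$tau_small, 0.60)
  expect_error(size_thresholds(tau_base = 0.5, tau_small = 0.7))
  expect_error(size_thresholds(small_area_mm2 = -1))
})
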