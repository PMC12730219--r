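# Shared fixtures, built lazily once per test run.

.fixtures <- new.env(parent = emptyenv())

# a binary disk mask of given pixel radius on an n x n grid
disk_mask <- function(n, radius, center = c((n + 1) / 2, (n + 1) / 2)) {
  d2 <- outer((seq_len(n) - center[1])^2, (seq_len(n) - center[2])^2, `+`)
  (d2 <= radius^2) * 1
}

# small synthetic cohort on disk, reused across dataset-building tests
fixture_cohort <- function() {
  if (is.null(.fixtures$cohort)) {
    dir <- file.path(tempdir(), "mraseg-fixture-cohort")
    .fixtures$cohort <- list(
      dir = dir,
      res = generate_cohort(6, 2, dir, seed = 7,
                            shape = c(48, 48, 16),
                            spacing = c(0.5, 0.5, 0.8))
    )
  }
  .fixtures$cohort
}

# the fixture cohort preprocessed into PNG slice pairs
fixture_slices <- function() {
  if (is.null(.fixtures$slices)) {
    co <- fixture_cohort()
    dir <- file.path(tempdir(), "mraseg-fixture-slices")
    .fixtures$slices <- list(dir = dir,
                             pre = preprocess_cohort(co$dir, dir))
  }
  .fixtures$slices
}

# the full desk-scale pipeline run (study-condition cohort: 10 aneurysmal,
# 5 healthy subjects, 5 folds), shared by the end-to-end checks
fixture_pipeline <- function() {
  if (is.null(.fixtures$pipeline)) {
    dir <- file.path(tempdir(), "mraseg-fixture-pipeline")
    .fixtures$pipeline <- run_pipeline(dir, n_aneurysmal = 10, n_healthy = 5,
                                       k = 5, seed = 11)
    .fixtures$pipeline$work_dir <- dir
  }
  .fixtures$pipeline
}

# per-fold segmentation metrics reported for the tuned detector on the
# clinical cohort (precision/recall/F1/Dice, percent)
reported_fold_table <- function() {
  data.frame(
    fold = 1:5,
    precision = c(94.04, 88.37, 89.20, 90.10, 89.75),
    recall = c(86.05, 86.77, 87.40, 85.90, 86.20),
    f1 = c(89.87, 87.56, 88.29, 87.94, 87.93),
    dice = c(89.87, 87.56, 88.29, 87.94, 87.93)
  )
}
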