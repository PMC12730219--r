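#' Specification of a synthetic TOF-MRA phantom
#'
#' Describes a desk-scale vascular phantom: bright tubular vessels on a
#' dark background with optional hyperintense spherical lesions of
#' controlled physical diameter. Defaults (96 x 96 x 48 voxels at 0.5 x 0.5
#' x 0.8 mm) keep a full cohort buildable in seconds while leaving room for
#' sub-3 mm lesions that intersect only one or two axial slices — the hard
#' case for small-object detection.
#'
#' Coordinates are physical mm with the center of voxel `(i, j, k)`
#' (0-based) at `(i * sx, j * sy, k * sz)`.
#'
#' @param shape `(nx, ny, nz)` voxel counts.
#' @param spacing `(sx, sy, sz)` mm.
#' @param n_vessels number of vessel tubes.
#' @param lesions list of `list(center = c(x, y, z) mm, diameter = mm)`.
#' @param background_level,vessel_level,lesion_level intensities in
#'   arbitrary acquisition units; must satisfy background < vessel <=
#'   lesion (hyperintense flow signal).
#' @param noise_sigma additive Gaussian noise std (same units).
#' @param seed integer seed; the phantom is fully reproducible from it.
#' @return object of class `phantom_spec`.
#' @export
phantom_spec <- function(shape = c(96, 96, 48), spacing = c(0.5, 0.5, 0.8),
                         n_vessels = 3, lesions = list(),
                         background_level = 40, vessel_level = 320,
                         lesion_level = 400, noise_sigma = 10, seed = 1L) {
  shape <- as.integer(shape); spacing <- as.numeric(spacing)
  stopifnot(length(shape) == 3L, all(shape >= 1L),
            length(spacing) == 3L, all(spacing > 0),
            n_vessels >= 0, noise_sigma >= 0)
  if (!(background_level < vessel_level && vessel_level <= lesion_level))
    stop("need background_level < vessel_level <= lesion_level")
  extent <- (shape - 1L) * spacing
  for (l in lesions) {
    if (l$diameter <= 0) stop("lesion diameter must be > 0")
    r <- l$diameter / 2
    if (any(l$center - r < 0) || any(l$center + r > extent))
      stop("lesion at (", paste(format(l$center), collapse = ", "),
           ") mm extends outside the volume")
  }
  if (length(lesions) > 1L) {
    for (i in seq_len(length(lesions) - 1L)) {
      for (j in (i + 1L):length(lesions)) {
        d <- sqrt(sum((lesions[[i]]$center - lesions[[j]]$center)^2))
        if (d < (lesions[[i]]$diameter + lesions[[j]]$diameter) / 2)
          stop("lesions ", i, " and ", j,
               " overlap; per-lesion ground truth would be ambiguous")
      }
    }
  }
  structure(
    list(shape = shape, spacing = spacing, n_vessels = as.integer(n_vessels),
         lesions = lesions, background_level = background_level,
         vessel_level = vessel_level, lesion_level = lesion_level,
         noise_sigma = noise_sigma, seed = as.integer(seed)),
    class = "phantom_spec"
  )
}

# random-walk vessel centerlines: one (x, y) mm position per axial slice
# per vessel, drifting with slice-to-slice std `drift` mm, reflected at the
# margins.
vessel_centerlines <- function(spec, drift = 0.6, margin = 3) {
  nz <- spec$shape[3]
  ext <- (spec$shape[1:2] - 1L) * spec$spacing[1:2]
  lapply(seq_len(spec$n_vessels), function(v) {
    xy <- matrix(0, nz, 2)
    xy[1, ] <- stats::runif(2, margin, ext - margin)
    if (nz > 1) for (k in 2:nz) {
      step <- xy[k - 1, ] + stats::rnorm(2, 0, drift)
      xy[k, ] <- pmin(pmax(step, margin), ext - margin)
    }
    xy
  })
}

#' Generate one synthetic TOF-MRA phantom
#'
#' Renders `n_vessels` bright tubes (random-walk centerlines running along
#' the slice axis, fixed 0.8 mm radius), then stamps each requested lesion
#' as a solid hyperintense ball of its stated physical diameter, and
#' finally adds Gaussian noise to the image (never the mask). The
#' ground-truth mask is the union of the lesion balls only — vessels are
#' background anatomy. Everything is reproducible from `spec$seed`.
#'
#' For cohort generation lesions are seeded on a vessel wall; arbitrary
#' centers passed in `spec$lesions` are rendered as given.
#'
#' @param spec a [phantom_spec()].
#' @return list with `image` and `mask` ([voxel_grid()]s) and `manifest`, a
#'   data frame with one row per lesion: center (mm), true diameter (mm),
#'   expected size category (from the true diameter), and the 0-based span
#'   of axial slices the ball intersects.
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  with_seed(spec$seed, {
    sx <- spec$spacing[1]; sy <- spec$spacing[2]; sz <- spec$spacing[3]
    nx <- spec$shape[1]; ny <- spec$shape[2]; nz <- spec$shape[3]
    img <- array(spec$background_level, dim = spec$shape)
    xs <- (0:(nx - 1)) * sx
    ys <- (0:(ny - 1)) * sy
    # vessels: in-plane disk of radius r_v around the centerline per slice
    r_v <- 0.8
    for (cl in vessel_centerlines(spec)) {
      for (k in seq_len(nz)) {
        d2 <- outer((xs - cl[k, 1])^2, (ys - cl[k, 2])^2, `+`)
        img[, , k][d2 <= r_v^2] <- spec$vessel_level
      }
    }
    mask <- array(0, dim = spec$shape)
    man <- list()
    for (li in seq_along(spec$lesions)) {
      l <- spec$lesions[[li]]
      r <- l$diameter / 2
      kz <- which(abs((0:(nz - 1)) * sz - l$center[3]) <= r)
      for (k in kz) {
        rk2 <- r^2 - ((k - 1) * sz - l$center[3])^2
        d2 <- outer((xs - l$center[1])^2, (ys - l$center[2])^2, `+`)
        sel <- d2 <= rk2
        img[, , k][sel] <- spec$lesion_level
        mask[, , k][sel] <- 1
      }
      man[[li]] <- data.frame(
        lesion = li, center_x_mm = l$center[1], center_y_mm = l$center[2],
        center_z_mm = l$center[3], diameter_mm = l$diameter,
        expected_category = size_category_from_diameter(l$diameter),
        slice_min = min(kz) - 1L, slice_max = max(kz) - 1L)
    }
    if (spec$noise_sigma > 0) {
      img <- img + array(stats::rnorm(length(img), 0, spec$noise_sigma),
                         dim = spec$shape)
      img <- pmax(img, 0)
    }
    list(
      image = voxel_grid(img, spec$spacing, "sub_00"),
      mask = voxel_grid(mask, spec$spacing, "sub_00", is_mask = TRUE),
      manifest = if (length(man)) do.call(rbind, man) else
        data.frame(lesion = integer(), center_x_mm = numeric(),
                   center_y_mm = numeric(), center_z_mm = numeric(),
                   diameter_mm = numeric(), expected_category = character(),
                   slice_min = integer(), slice_max = integer())
    )
  })
}

# deterministic largest-remainder allocation of n items to proportions
allocate_mix <- function(n, mix) {
  raw <- n * mix / sum(mix)
  base <- floor(raw)
  rem <- n - sum(base)
  if (rem > 0) {
    order_rem <- order(raw - base, decreasing = TRUE)
    base[order_rem[seq_len(rem)]] <- base[order_rem[seq_len(rem)]] + 1
  }
  stats::setNames(as.integer(base), names(mix))
}

# representative diameter bands per category, kept clear of the 3/5 mm
# bounds so rasterization cannot flip the expected category
.diameter_bands <- list(small = c(2.0, 2.6), medium = c(3.8, 4.4),
                        large = c(5.8, 6.4))

#' Generate a synthetic cohort of NIfTI volumes
#'
#' Writes `n_aneurysmal` phantoms with one lesion each (placed on a vessel
#' wall) plus `n_healthy` lesion-free phantoms, as `sub_XX.nii.gz` with
#' `sub_XX_mask.nii.gz` companions for the aneurysmal subjects only, and a
#' `manifest.csv` listing every lesion with its true diameter and expected
#' size category. Lesion categories follow `size_mix` by deterministic
#' largest-remainder allocation (e.g. proportions 0.5/0.3/0.2 over 10
#' lesions give exactly 5/3/2), with diameters drawn from
#' category-representative bands (about 2, 4 and 6.1 mm). The same seed
#' reproduces the cohort byte for byte.
#'
#' @param n_aneurysmal number of aneurysmal subjects (>= 1).
#' @param n_healthy number of lesion-free subjects.
#' @param out_dir output directory for the NIfTI files and manifest.
#' @param size_mix named proportions over `small`/`medium`/`large`.
#' @param seed integer master seed.
#' @param shape,spacing phantom geometry, see [phantom_spec()].
#' @return list with `manifest` (data frame, one row per lesion, including
#'   `subject_id`), `image_files`, `mask_files`, `manifest_file`.
#' @export
generate_cohort <- function(n_aneurysmal, n_healthy, out_dir,
                            size_mix = c(small = 0.4, medium = 0.4,
                                         large = 0.2),
                            seed = 1L, shape = c(96, 96, 48),
                            spacing = c(0.5, 0.5, 0.8)) {
  stopifnot(n_aneurysmal >= 1, n_healthy >= 0)
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  counts <- allocate_mix(n_aneurysmal, size_mix)
  categories <- rep(names(counts), counts)
  manifest <- list()
  image_files <- character()
  mask_files <- character()
  n_total <- n_aneurysmal + n_healthy
  for (s in seq_len(n_total) - 1L) {
    sid <- sprintf("sub_%02d", s)
    sub_seed <- as.integer((as.numeric(seed) * 1000 + s) %% 2147483647)
    aneurysmal <- s < n_aneurysmal
    lesions <- list()
    lesion_cat <- if (aneurysmal) categories[s + 1L] else NA_character_
    if (aneurysmal) {
      lesions <- with_seed(sub_seed + 500L, {
        band <- .diameter_bands[[lesion_cat]]
        diam <- stats::runif(1, band[1], band[2])
        # center on a vessel wall: a point at vessel-radius offset from a
        # mid-volume centerline position of vessel 1
        spec0 <- phantom_spec(shape, spacing, seed = sub_seed)
        cl <- with_seed(sub_seed, vessel_centerlines(spec0))[[1]]
        kz <- max(1L, round(nrow(cl) / 2))
        ang <- stats::runif(1, 0, 2 * pi)
        ctr <- c(cl[kz, 1] + 0.8 * cos(ang), cl[kz, 2] + 0.8 * sin(ang),
                 (kz - 1) * spacing[3])
        ext <- (shape - 1L) * spacing
        ctr <- pmin(pmax(ctr, diam / 2 + 0.1), ext - diam / 2 - 0.1)
        list(list(center = ctr, diameter = diam))
      })
    }
    spec <- phantom_spec(shape, spacing, lesions = lesions, seed = sub_seed)
    ph <- generate_phantom(spec)
    ph$image$subject_id <- sid
    imgf <- file.path(out_dir, paste0(sid, ".nii.gz"))
    write_volume(ph$image, imgf)
    image_files <- c(image_files, imgf)
    if (aneurysmal) {
      ph$mask$subject_id <- sid
      maskf <- file.path(out_dir, paste0(sid, "_mask.nii.gz"))
      write_volume(ph$mask, maskf)
      mask_files <- c(mask_files, maskf)
      manifest[[length(manifest) + 1L]] <-
        cbind(subject_id = sid, ph$manifest)
    }
  }
  manifest <- do.call(rbind, manifest)
  manifest_file <- file.path(out_dir, "manifest.csv")
  utils::write.csv(manifest, manifest_file, row.names = FALSE)
  list(manifest = manifest, image_files = image_files,
       mask_files = mask_files, manifest_file = manifest_file)
}
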