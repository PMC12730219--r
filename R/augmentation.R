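#' Augmentation parameter set
#'
#' Bundles the parameters of the augmentation operators applied during
#' offline dataset expansion: rotation angles (degrees), the linear
#' contrast/brightness pair, the gamma coefficient, and an optional
#' Gaussian-noise level. Defaults are the settings used for training:
#' rotations of +15 and -15 degrees, contrast `alpha = 0.5` with brightness
#' `beta = -100` (damps dominant bright vessels and lifts low-contrast
#' lesions into view), and `gamma = 2.0`. Reflections are deliberately not
#' part of the operator set: brain anatomy is not mirror-symmetric between
#' patients, so flipped copies are off-distribution.
#'
#' @param theta_degrees numeric vector of rotation angles.
#' @param alpha contrast factor, > 0.
#' @param beta brightness offset on the 0-255 scale.
#' @param gamma gamma coefficient, > 0.
#' @param noise_sigma Gaussian noise std on the 0-255 scale, >= 0; 0
#'   disables the noise variant.
#' @param seed integer seed for the noise draws.
#' @return object of class `augmentation_spec`.
#' @export
augmentation_spec <- function(theta_degrees = c(15, -15), alpha = 0.5,
                              beta = -100, gamma = 2.0, noise_sigma = 0,
                              seed = 1L) {
  stopifnot(alpha > 0, gamma > 0, noise_sigma >= 0,
            length(theta_degrees) >= 1L)
  structure(
    list(theta_degrees = as.numeric(theta_degrees), alpha = alpha,
         beta = beta, gamma = gamma, noise_sigma = noise_sigma,
         seed = as.integer(seed)),
    class = "augmentation_spec"
  )
}

# Backward-mapped rotation about the geometric center ((n-1)/2 in 0-based
# pixel coordinates), output shape unchanged, out-of-frame filled with
# `fill`. interp = "bilinear" for images, "nearest" for masks.
rotate_grid <- function(px, theta, interp = c("bilinear", "nearest"),
                        fill = 0) {
  interp <- match.arg(interp)
  nr <- nrow(px); nc <- ncol(px)
  th <- theta * pi / 180
  cx <- (nc - 1) / 2; cy <- (nr - 1) / 2
  # destination pixel centers, 0-based (x = column, y = row)
  xd <- rep(0:(nc - 1), each = nr) - cx
  yd <- rep(0:(nr - 1), times = nc) - cy
  # source = R(-theta) applied to destination offsets
  xs <- cos(th) * xd + sin(th) * yd + cx
  ys <- -sin(th) * xd + cos(th) * yd + cy
  out <- matrix(fill, nr, nc)
  if (interp == "nearest") {
    xi <- round_half_up(xs); yi <- round_half_up(ys)
    ok <- xi >= 0 & xi < nc & yi >= 0 & yi < nr
    out[ok] <- px[cbind(yi[ok] + 1, xi[ok] + 1)]
  } else {
    x0 <- floor(xs); y0 <- floor(ys)
    fx <- xs - x0; fy <- ys - y0
    # sample with zero fill outside the frame
    at <- function(r, c) {
      v <- numeric(length(r))
      ok <- r >= 0 & r < nr & c >= 0 & c < nc
      v[ok] <- px[cbind(r[ok] + 1, c[ok] + 1)]
      v
    }
    v <- (1 - fx) * (1 - fy) * at(y0, x0) +
         fx       * (1 - fy) * at(y0, x0 + 1) +
         (1 - fx) * fy       * at(y0 + 1, x0) +
         fx       * fy       * at(y0 + 1, x0 + 1)
    inside <- xs >= 0 & xs <= nc - 1 & ys >= 0 & ys <= nr - 1
    v[!inside] <- fill
    out[] <- v
  }
  out
}

#' Rotate an image (and its mask) about the image center
#'
#' Applies the planar rotation
#' \deqn{M = \begin{pmatrix} \cos\theta & -\sin\theta \\ \sin\theta &
#'   \cos\theta \end{pmatrix}}
#' about the geometric center of the frame, with translation terms chosen so
#' the center is preserved and the output shape unchanged. Images are
#' resampled bilinearly and re-quantized to integers in `[0, 255]`; masks are
#' resampled nearest-neighbor so they stay strictly binary. Pixels mapped
#' from outside the frame are filled with 0.
#'
#' @param image 2D numeric matrix on the 0-255 scale.
#' @param mask matching binary matrix, or `NULL`.
#' @param theta rotation angle in degrees.
#' @return list with elements `image` and `mask` (`NULL` if no mask given).
#' @export
rotate_pair <- function(image, mask = NULL, theta) {
  stopifnot(is.matrix(image))
  if (!is.null(mask) && !identical(dim(image), dim(mask)))
    stop("image and mask shapes differ")
  img <- clip_round_255(rotate_grid(image, theta, "bilinear"))
  msk <- if (!is.null(mask)) rotate_grid(mask, theta, "nearest")
  list(image = img, mask = msk)
}

#' Linear contrast / brightness adjustment
#'
#' Per-pixel `alpha * I + beta`, clipped to `[0, 255]` and rounded half-up.
#' The default pair `alpha = 0.5`, `beta = -100` maps intensity 200 exactly
#' to 0 and sends everything below to the floor, which suppresses dominant
#' hyperintense vessels while spreading out the upper intensity range where
#' lesions live.
#'
#' @param image 2D numeric matrix on the 0-255 scale.
#' @param alpha contrast factor, > 0.
#' @param beta brightness offset.
#' @return adjusted integer matrix in `[0, 255]`.
#' @export
adjust_contrast <- function(image, alpha = 0.5, beta = -100) {
  stopifnot(is.matrix(image), alpha > 0)
  clip_round_255(alpha * image + beta)
}

#' Gamma correction
#'
#' Per-pixel `255 * (I / 255)^(1/gamma)`, rounded half-up. 0 and 255 are
#' fixed points for every gamma; `gamma = 2` (the default used in training)
#' brightens the mid-range, enhancing visibility of bright structures.
#'
#' @param image 2D numeric matrix on the 0-255 scale.
#' @param gamma gamma coefficient, > 0.
#' @return corrected integer matrix in `[0, 255]`.
#' @export
gamma_correct <- function(image, gamma = 2.0) {
  stopifnot(is.matrix(image), gamma > 0)
  clip_round_255(255 * (pmax(image, 0) / 255)^(1 / gamma))
}

#' Additive Gaussian noise
#'
#' Adds i.i.d. zero-mean Gaussian draws of standard deviation `sigma` (on
#' the 0-255 scale), clips to `[0, 255]` and rounds. The same seed always
#' reproduces the same output; `sigma = 0` is the identity.
#'
#' @param image 2D numeric matrix on the 0-255 scale.
#' @param sigma noise standard deviation, >= 0.
#' @param seed integer seed, or `NULL` to draw from the current RNG stream.
#' @return noisy integer matrix in `[0, 255]`.
#' @export
add_gaussian_noise <- function(image, sigma = 5, seed = NULL) {
  stopifnot(is.matrix(image), sigma >= 0)
  if (sigma == 0) return(image)
  noise <- with_seed(seed, stats::rnorm(length(image), 0, sigma))
  clip_round_255(image + matrix(noise, nrow(image), ncol(image)))
}

#' Expand one slice record into its augmented variants
#'
#' Offline dataset expansion: each source slice yields one derived record
#' per single operator — a rotated copy per angle in the spec (image and
#' mask both rotated), a contrast-adjusted copy, a gamma-corrected copy,
#' and, when `noise_sigma > 0`, a noisy copy. Photometric operators never
#' touch the mask: the derived records reuse the original mask file
#' unchanged. Healthy records (no mask) yield augmented images only. No
#' reflection operator exists, so the output never contains mirrored
#' variants.
#'
#' @param rec a [slice_record()] whose files exist on disk.
#' @param spec an [augmentation_spec()].
#' @param dir output directory for the derived PNGs.
#' @param in_plane_spacing `(sx, sy)` mm carried onto the derived slices.
#' @return list of derived [slice_record()]s (the original is not
#'   re-emitted).
#' @export
augment_record <- function(rec, spec, dir,
                           in_plane_spacing = c(1, 1)) {
  stopifnot(inherits(rec, "slice_record"), inherits(spec, "augmentation_spec"))
  s <- read_slice_png(rec$image_path, in_plane_spacing)
  m <- if (!is.null(rec$mask_path)) read_slice_png(rec$mask_path,
                                                   in_plane_spacing)
  out <- list()
  emit <- function(img_px, mask_px, tag) {
    si <- s; si$pixels <- img_px
    ip <- write_slice_png(si, dir, variant = tag)
    mp <- NULL
    if (!is.null(m)) {
      sm <- m; sm$pixels <- mask_px
      mp <- write_slice_png(sm, dir, variant = tag)
    }
    out[[length(out) + 1L]] <<- slice_record(ip, mp, s$subject_id,
                                             s$slice_index)
  }
  for (th in spec$theta_degrees) {
    r <- rotate_pair(s$pixels, if (!is.null(m)) m$pixels, th)
    emit(r$image, r$mask, sprintf("rot%+d", as.integer(round(th))))
  }
  emit(adjust_contrast(s$pixels, spec$alpha, spec$beta),
       if (!is.null(m)) m$pixels, "contrast")
  emit(gamma_correct(s$pixels, spec$gamma),
       if (!is.null(m)) m$pixels, "gamma")
  if (spec$noise_sigma > 0) {
    emit(add_gaussian_noise(s$pixels, spec$noise_sigma, spec$seed),
         if (!is.null(m)) m$pixels, "noise")
  }
  out
}
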