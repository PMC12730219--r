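# Connected-component machinery shared by the COCO builder, the size-aware
# ROI logic and the evaluator. Instance separation uses 8-connectivity
# in-plane, the standard choice for small bright blobs.

#' Label 8-connected foreground components
#'
#' @param mask 2D binary matrix.
#' @return integer matrix of the same shape; 0 = background, components
#'   numbered 1..n in scan order of their first pixel.
#' @export
label_components <- function(mask) {
  stopifnot(is.matrix(mask), is_binary(mask))
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  cur <- 0L
  offs <- cbind(dr = c(-1, -1, -1, 0, 0, 1, 1, 1),
                dc = c(-1, 0, 1, -1, 1, -1, 0, 1))
  fg <- which(mask != 0)
  for (start in fg) {
    if (lab[start] != 0L) next
    cur <- cur + 1L
    queue <- start
    lab[start] <- cur
    while (length(queue) > 0L) {
      p <- queue[length(queue)]
      queue <- queue[-length(queue)]
      r <- ((p - 1L) %% nr) + 1L
      c <- ((p - 1L) %/% nr) + 1L
      rr <- r + offs[, 1]; cc <- c + offs[, 2]
      ok <- rr >= 1 & rr <= nr & cc >= 1 & cc <= nc
      nb <- (cc[ok] - 1L) * nr + rr[ok]
      nb <- nb[mask[nb] != 0 & lab[nb] == 0L]
      if (length(nb)) {
        lab[nb] <- cur
        queue <- c(queue, nb)
      }
    }
  }
  lab
}

# Outer boundary of one component as a closed polygon over pixel *corners*
# (half-integer 0-based coordinates). Directed edges keep the interior on
# the right (clockwise in image coordinates, y down); chaining prefers the
# right turn at pinch points so 8-connected diagonal contacts stay on one
# loop. Returns an n x 2 matrix of (x, y); holes are ignored (outer loop
# only).
trace_outer_boundary <- function(comp) {
  nr <- nrow(comp); nc <- ncol(comp)
  idx <- which(comp != 0, arr.ind = TRUE)
  fg <- function(r, c) r >= 1 && r <= nr && c >= 1 && c <= nc && comp[r, c] != 0
  # directed boundary edges keyed by start corner "x,y"
  edges <- new.env(parent = emptyenv())
  add_edge <- function(x0, y0, x1, y1) {
    key <- paste0(x0, ",", y0)
    cur <- if (!is.null(edges[[key]])) edges[[key]] else list()
    cur[[length(cur) + 1L]] <- c(x1, y1)
    edges[[key]] <- cur
  }
  for (i in seq_len(nrow(idx))) {
    r <- idx[i, 1]; c <- idx[i, 2]
    x <- c - 1; y <- r - 1  # 0-based pixel center
    if (!fg(r - 1, c)) add_edge(x - 0.5, y - 0.5, x + 0.5, y - 0.5)  # top, ->
    if (!fg(r, c + 1)) add_edge(x + 0.5, y - 0.5, x + 0.5, y + 0.5)  # right, v
    if (!fg(r + 1, c)) add_edge(x + 0.5, y + 0.5, x - 0.5, y + 0.5)  # bottom, <-
    if (!fg(r, c - 1)) add_edge(x - 0.5, y + 0.5, x - 0.5, y - 0.5)  # left, ^
  }
  # start at the top-left-most corner of the component (always on the outer
  # loop), with a rightward edge
  r0 <- min(idx[, 1]); c0 <- min(idx[idx[, 1] == r0, 2])
  start <- c(c0 - 1 - 0.5, r0 - 1 - 0.5)
  poly <- list(start)
  prev_dir <- NULL
  cur <- start
  repeat {
    key <- paste0(cur[1], ",", cur[2])
    cand <- edges[[key]]
    if (is.null(cand) || length(cand) == 0L)
      stop("boundary tracing failed (open chain)")  # cannot happen on valid masks
    if (length(cand) == 1L) {
      nxt <- cand[[1]]
      edges[[key]] <- list()
    } else {
      # pinch point: prefer the rightmost turn relative to the incoming
      # direction (cross product in y-down coords: negative = right turn)
      dirs <- vapply(cand, function(p) p - cur, numeric(2))
      cross <- prev_dir[1] * dirs[2, ] - prev_dir[2] * dirs[1, ]
      pick <- which.min(cross)
      nxt <- cand[[pick]]
      edges[[key]] <- cand[-pick]
    }
    prev_dir <- nxt - cur
    if (all(nxt == start)) break
    poly[[length(poly) + 1L]] <- nxt
    cur <- nxt
  }
  out <- do.call(rbind, poly)
  colnames(out) <- c("x", "y")
  simplify_collinear(out)
}

# drop vertices interior to straight runs (closed polygon)
simplify_collinear <- function(poly) {
  n <- nrow(poly)
  if (n <= 3) return(poly)
  keep <- logical(n)
  for (i in seq_len(n)) {
    p0 <- poly[if (i == 1) n else i - 1, ]
    p1 <- poly[i, ]
    p2 <- poly[if (i == n) 1 else i + 1, ]
    keep[i] <- (p1[1] - p0[1]) * (p2[2] - p0[2]) !=
               (p1[2] - p0[2]) * (p2[1] - p0[1])
  }
  poly[keep, , drop = FALSE]
}

#' Trace foreground components into COCO-style polygons
#'
#' Labels 8-connected components and traces the outer boundary of each as a
#' closed polygon over pixel corners (half-integer, 0-based coordinates, x =
#' column, y = row). Interior holes are filled — aneurysm masks are solid
#' blobs, and callers who must preserve holes exactly should use the bitmask
#' encoding instead ([rle_encode_mask()]). Degenerate components with fewer
#' than 3 traceable vertices are dropped with a warning (cannot occur with
#' corner tracing on nonempty components, but guarded for safety).
#'
#' @param mask 2D binary matrix.
#' @return list of polygons, each an `n x 2` matrix with columns `x`, `y`;
#'   empty list for an empty mask.
#' @seealso [polygons_to_mask()] for rasterization back to pixels.
#' @export
mask_to_polygons <- function(mask) {
  lab <- label_components(mask)
  n <- max(lab)
  if (n == 0L) return(list())
  polys <- list()
  for (k in seq_len(n)) {
    poly <- trace_outer_boundary((lab == k) * 1)
    if (nrow(poly) < 3L) {
      warning("dropping component ", k, ": fewer than 3 traceable vertices")
      next
    }
    polys[[length(polys) + 1L]] <- poly
  }
  polys
}

#' Rasterize polygons back to a binary mask
#'
#' Even-odd (crossing-number) rasterization of pixel centers at integer
#' 0-based coordinates. Polygons produced by [mask_to_polygons()] have
#' half-integer vertices, so no pixel center ever lies on an edge and the
#' round-trip mask -> polygons -> mask is exact for hole-free components.
#'
#' @param polys list of `n x 2` polygon matrices (columns x, y).
#' @param nrow,ncol output mask shape.
#' @return binary matrix of the requested shape.
#' @export
polygons_to_mask <- function(polys, nrow, ncol) {
  out <- matrix(0, nrow, ncol)
  for (poly in polys) {
    xs <- poly[, 1]; ys <- poly[, 2]
    n <- length(xs)
    xr <- range(xs); yr <- range(ys)
    cols <- max(0, ceiling(xr[1])):min(ncol - 1, floor(xr[2]))
    rows <- max(0, ceiling(yr[1])):min(nrow - 1, floor(yr[2]))
    if (length(cols) == 0L || length(rows) == 0L) next
    px <- rep(cols, each = length(rows))
    py <- rep(rows, times = length(cols))
    inside <- logical(length(px))
    j <- n
    for (i in seq_len(n)) {
      crosses <- which((ys[i] > py) != (ys[j] > py))
      if (length(crosses)) {
        xint <- xs[i] + (py[crosses] - ys[i]) / (ys[j] - ys[i]) *
          (xs[j] - xs[i])
        flip <- crosses[px[crosses] < xint]
        inside[flip] <- !inside[flip]
      }
      j <- i
    }
    out[cbind(py[inside] + 1, px[inside] + 1)] <- 1
  }
  out
}

#' Encode a binary mask as uncompressed COCO RLE
#'
#' Column-major (Fortran-order) run lengths, first count for background, as
#' in the COCO `"counts"`/`"size"` convention. Lossless: [rle_decode_mask()]
#' reproduces the mask exactly, holes included.
#'
#' @param mask 2D binary matrix.
#' @return list with `size = c(nrow, ncol)` and integer vector `counts`.
#' @export
rle_encode_mask <- function(mask) {
  stopifnot(is.matrix(mask), is_binary(mask))
  v <- as.integer(mask)  # as.integer of a matrix is column-major
  r <- rle(v)
  counts <- r$lengths
  if (length(r$values) > 0L && r$values[1] == 1L) counts <- c(0L, counts)
  list(size = c(nrow(mask), ncol(mask)), counts = as.integer(counts))
}

#' Decode uncompressed COCO RLE to a binary mask
#'
#' @param rle list with `size` and `counts` as from [rle_encode_mask()].
#' @return binary matrix.
#' @export
rle_decode_mask <- function(rle) {
  counts <- as.integer(rle$counts)
  vals <- rep_len(c(0, 1), length(counts))
  matrix(rep(vals, counts), rle$size[1], rle$size[2])
}

# tight 0-based [x, y, w, h] bbox of a binary matrix (COCO convention)
mask_bbox <- function(mask) {
  idx <- which(mask != 0, arr.ind = TRUE)
  if (nrow(idx) == 0L) return(NULL)
  r <- range(idx[, 1]); c <- range(idx[, 2])
  c(c[1] - 1, r[1] - 1, c[2] - c[1] + 1, r[2] - r[1] + 1)
}
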