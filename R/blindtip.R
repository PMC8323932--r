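# Blind tip reconstruction: morphology-based outer-bound estimation of the
# probe shape directly from a height map, with a noise threshold.

#' Grayscale erosion / dilation of an image by a tip
#'
#' Morphological erosion `min_d(img[x + d] - tip[d])` and dilation
#' `max_d(img[x - d] + tip[d])` of a height map by a tip surface (heights
#' relative to the apex, apex 0 at the window center).  Image borders use
#' the valid overlap only.
#'
#' @param img height matrix or [afm_image].
#' @param tip a `tip_surface` (or matrix of non-positive tip heights).
#' @return A height matrix of the image shape.
#' @export
image_erode <- function(img, tip) {
  h <- if (inherits(img, "afm_image")) img$heights else as.matrix(img)
  p <- tip_matrix(tip)
  k <- (nrow(p) - 1) / 2
  nr <- nrow(h); nc <- ncol(h)
  out <- matrix(Inf, nr, nc)
  for (di in -k:k) {
    ri <- max(1, 1 - di):min(nr, nr - di)
    for (dj in -k:k) {
      cj <- max(1, 1 - dj):min(nc, nc - dj)
      cand <- h[ri + di, cj + dj, drop = FALSE] - p[di + k + 1, dj + k + 1]
      out[ri, cj] <- pmin(out[ri, cj, drop = FALSE], cand)
    }
  }
  out
}

#' @rdname image_erode
#' @export
image_dilate <- function(img, tip) {
  h <- if (inherits(img, "afm_image")) img$heights else as.matrix(img)
  p <- tip_matrix(tip)
  k <- (nrow(p) - 1) / 2
  nr <- nrow(h); nc <- ncol(h)
  out <- matrix(-Inf, nr, nc)
  for (di in -k:k) {
    ri <- max(1, 1 - di):min(nr, nr - di)
    for (dj in -k:k) {
      cand <- h[ri, , drop = FALSE] + p[di + k + 1, dj + k + 1]
      cjs <- max(1, 1 - dj):min(nc, nc - dj)
      out[ri + di, cjs + dj] <- pmax(out[ri + di, cjs + dj, drop = FALSE],
                                     cand[, cjs, drop = FALSE])
    }
  }
  out
}

tip_matrix <- function(tip) {
  if (inherits(tip, "tip_surface")) return(-tip$depth)  # heights <= 0
  as.matrix(tip)
}

#' Blind tip reconstruction from a height map
#'
#' Estimates an outer bound on the probe-tip geometry directly from an
#' image by mathematical morphology, without assuming a tip model
#' (classic fixed-point refinement).  The estimate starts from a flat
#' (uninformative) tip and is tightened iteratively: each image position
#' must have at least one feasible tip-sample contact point, and the
#' worst case over those contacts bounds every tip pixel from above; the
#' estimate is monotonically non-increasing and stops at a fixed point or
#' after `max_iter` passes.  The `threshold` parameter relaxes every
#' bound by the allowed noise violation depth, making the estimate
#' blunter but less noise-sensitive.  Positions closer than a full
#' window to the image border give no certain constraint, so the image
#' must be at least `2 * tip_window - 1` pixels in each direction.
#'
#' @param img an [afm_image] or height matrix.
#' @param tip_window odd window edge length in pixels.
#' @param threshold allowed violation depth in nm (>= 0).
#' @param max_iter maximum refinement passes.
#' @return An object of class `tip_surface`: list with `depth` (matrix of
#'   tip depth below the apex, apex 0 at the center, values >= 0),
#'   `pixel_size` and `threshold`.
#' @export
blind_tip_estimate <- function(img, tip_window = 11, threshold = 0,
                               max_iter = 10) {
  h <- if (inherits(img, "afm_image")) img$heights else as.matrix(img)
  px <- if (inherits(img, "afm_image")) img$pixel_size else 1
  if (tip_window %% 2 != 1 || tip_window < 1)
    stop("tip_window must be odd and positive")
  if (2 * tip_window - 1 > min(dim(h)))
    stop("tip window larger than the image allows (need >= 2w-1 pixels)")
  if (threshold < 0) stop("threshold must be >= 0")
  p <- cpp_blind_tip(h, as.integer(tip_window), threshold,
                     as.integer(max_iter))
  structure(list(depth = -p, pixel_size = px, threshold = threshold),
            class = "tip_surface")
}

#' @export
print.tip_surface <- function(x, ...) {
  cat(sprintf("tip_surface: %d x %d window, max depth %.3f nm (threshold %.2f nm)\n",
              nrow(x$depth), ncol(x$depth), max(x$depth), x$threshold))
  invisible(x)
}

#' Apex cross-sections of a tip surface
#'
#' Tip depth profiles through the apex along the X and Y axes, for
#' comparison with a parametric tip model.
#'
#' @param tip a `tip_surface`.
#' @return List with numeric vectors `x` and `y` (depth below apex, nm).
#' @export
tip_cross_sections <- function(tip) {
  k <- (nrow(tip$depth) - 1) / 2 + 1
  list(x = tip$depth[k, ], y = tip$depth[, k])
}
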