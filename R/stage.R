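# Stage-plane estimation/correction and background-noise statistics for
# experimental height maps.

pixel_centers <- function(img) {
  h <- img$heights
  x <- img$origin[1] + (seq_len(ncol(h)) - 0.5) * img$pixel_size
  y <- img$origin[2] + (seq_len(nrow(h)) - 0.5) * img$pixel_size
  list(x = matrix(x, nrow(h), ncol(h), byrow = TRUE),
       y = matrix(y, nrow(h), ncol(h)))
}

#' Background masks for stage estimation
#'
#' `mask_background` selects pixels below a height quantile (automatic
#' background rule); `mask_rectangles` builds a mask from a list of 1-based
#' inclusive pixel rectangles `c(row0, row1, col0, col1)` (manual
#' background selection).
#'
#' @param img an [afm_image].
#' @param prob height quantile below which pixels count as background.
#' @param rects list of `c(row0, row1, col0, col1)` vectors.
#' @return A logical matrix of the image shape.
#' @export
mask_background <- function(img, prob = 0.25) {
  img$heights <= quantile(img$heights, prob)
}

#' @rdname mask_background
#' @export
mask_rectangles <- function(img, rects) {
  m <- matrix(FALSE, nrow(img$heights), ncol(img$heights))
  for (r in rects) m[r[1]:r[2], r[3]:r[4]] <- TRUE
  m
}

#' Fit a tilted stage plane to background pixels
#'
#' Ordinary least squares of pixel height on the pixel-center X and Y
#' coordinates (nm), `z = a x + b y + c`, over the masked background
#' pixels.  The supporting stage is nearly, but not exactly, parallel to
#' the scanner XY plane, so the fitted plane is subtracted before any
#' quantitative use of the heights.
#'
#' @param img an [afm_image].
#' @param mask logical matrix selecting background pixels; default:
#'   [mask_background].
#' @return An object of class `plane_fit`: list with slopes `a`, `b`
#'   (nm/nm), intercept `c` (nm) and `residual_sd` (nm).
#' @export
fit_stage_plane <- function(img, mask = NULL) {
  mask <- mask %||% mask_background(img)
  if (sum(mask) < 3) stop("degenerate mask: need at least 3 pixels")
  pc <- pixel_centers(img)
  d <- data.frame(z = img$heights[mask], x = pc$x[mask], y = pc$y[mask])
  if (length(unique(d$x)) == 1L && length(unique(d$y)) == 1L)
    stop("degenerate mask: collinear pixel positions")
  fit <- lm(z ~ x + y, data = d)
  cf <- coef(fit)
  cf[is.na(cf)] <- 0  # collinear-in-one-direction masks: slope 0
  structure(list(a = unname(cf["x"]), b = unname(cf["y"]),
                 c = unname(cf["(Intercept)"]),
                 residual_sd = sd(fit$residuals)),
            class = "plane_fit")
}

#' @export
print.plane_fit <- function(x, ...) {
  cat(sprintf("stage plane: z = %.4gx %+.4gy %+.4g (nm), residual sd %.4g nm\n",
              x$a, x$b, x$c, x$residual_sd))
  invisible(x)
}

#' Subtract a fitted stage plane from a height map
#'
#' Per-pixel height minus the plane value; heights are not clipped at 0,
#' so the background keeps its symmetric noise distribution.
#'
#' @param img an [afm_image].
#' @param fit a [fit_stage_plane] result.
#' @return The corrected [afm_image].
#' @export
subtract_plane <- function(img, fit) {
  pc <- pixel_centers(img)
  afm_image(img$heights - (fit$a * pc$x + fit$b * pc$y + fit$c),
            img$pixel_size, img$origin)
}

#' Background noise standard deviation
#'
#' Standard deviation of the residuals of the masked background pixels
#' around the fitted stage plane (moment estimate of the Gaussian noise
#' level).
#'
#' @inheritParams fit_stage_plane
#' @return Noise standard deviation in nm.
#' @export
noise_sd <- function(img, mask = NULL) {
  mask <- mask %||% mask_background(img)
  if (sum(mask) < 3) stop("degenerate mask: need at least 3 pixels")
  fit <- fit_stage_plane(img, mask)
  pc <- pixel_centers(img)
  res <- img$heights[mask] -
    (fit$a * pc$x[mask] + fit$b * pc$y[mask] + fit$c)
  sd(res)
}

#' Least-squares uniform scale/shift between two images
#'
#' Finds `(s, t)` minimizing `sum((s * sim + t - ref)^2)` over all pixels,
#' for post-hoc comparison of a best-fit pseudo image with an experimental
#' image when the specimen may be uniformly compressed.  Modes restrict
#' the transform to scale only or shift only; the shift can be constrained
#' to be non-positive (compression toward the stage).
#'
#' @param img [afm_image] to be rescaled (the pseudo image).
#' @param ref reference [afm_image] of the same shape.
#' @param mode `"both"`, `"scale"` or `"shift"`.
#' @param nonpositive_shift constrain `t <= 0`.
#' @return List with `scale`, `shift` and the rescaled [afm_image].
#' @export
affine_rescale <- function(img, ref, mode = c("both", "scale", "shift"),
                           nonpositive_shift = FALSE) {
  mode <- match.arg(mode)
  s <- as.vector(img$heights); r <- as.vector(ref$heights)
  if (length(s) != length(r)) stop("images must have the same shape")
  if (mode == "shift") {
    sc <- 1
    t <- mean(r - s)
  } else if (mode == "scale") {
    if (all(s == 0)) stop("zero-variance image: scale is undefined")
    sc <- sum(s * r) / sum(s^2)
    t <- 0
  } else {
    v <- sum((s - mean(s))^2)
    if (v == 0) stop("zero-variance image: scale is undefined")
    sc <- sum((s - mean(s)) * (r - mean(r))) / v
    t <- mean(r) - sc * mean(s)
  }
  if (nonpositive_shift && t > 0) {
    t <- 0
    if (mode == "both") {  # refit scale with shift pinned at 0
      sc <- sum(s * r) / sum(s^2)
    }
  }
  list(scale = sc, shift = t,
       image = afm_image(sc * img$heights + t, img$pixel_size, img$origin))
}
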