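# Pseudo-AFM image generation: probe model, collision heights, noise, I/O.

#' Probe tip shape
#'
#' The probe tip is modeled as a hemisphere of radius `radius` capped by a
#' circular cone frustum whose flank makes the half-apex angle `angle` with
#' the vertical axis; the frustum extends upward indefinitely (specimen
#' heights never reach a realistic frustum top).
#'
#' @param radius tip radius in nm (> 0).
#' @param angle half-apex angle in degrees (0 < angle < 90).
#' @return An object of class `probe_shape`.
#' @export
probe_shape <- function(radius, angle) {
  if (!is.finite(radius) || radius <= 0) stop("probe radius must be > 0")
  if (!is.finite(angle) || angle <= 0 || angle >= 90)
    stop("half-apex angle must be in (0, 90) degrees")
  structure(list(radius = radius, angle = angle), class = "probe_shape")
}

#' @export
print.probe_shape <- function(x, ...) {
  cat(sprintf("probe_shape: %.2f nm / %.1f degree\n", x$radius, x$angle))
  invisible(x)
}

#' AFM height map
#'
#' A rectangular grid of pixel heights in nm.  Row 1 is the lowest Y; pixel
#' `(i, j)` (1-based) has its center at
#' `origin + (j - 0.5, i - 0.5) * pixel_size`.
#'
#' @param heights numeric matrix of heights (nm).
#' @param pixel_size pixel edge length in nm (> 0).
#' @param origin XY coordinates (nm) of the lower-left corner of the grid.
#' @return An object of class `afm_image`.
#' @export
afm_image <- function(heights, pixel_size = 1, origin = c(0, 0)) {
  heights <- as.matrix(heights)
  storage.mode(heights) <- "double"
  if (!all(is.finite(heights))) stop("heights must be finite")
  if (!is.finite(pixel_size) || pixel_size <= 0)
    stop("pixel_size must be > 0")
  structure(list(heights = heights, pixel_size = pixel_size,
                 origin = as.numeric(origin[1:2])),
            class = "afm_image")
}

#' @export
print.afm_image <- function(x, ...) {
  cat(sprintf("afm_image: %d x %d pixels, %.3g nm/pixel, heights %.3g..%.3g nm\n",
              nrow(x$heights), ncol(x$heights), x$pixel_size,
              min(x$heights), max(x$heights)))
  invisible(x)
}

#' @export
dim.afm_image <- function(x) dim(x$heights)

#' Probe apex height at first contact with an atom
#'
#' Height of the tip apex when the probe, descending along a vertical axis
#' at lateral distance `d` from a spherical atom (center height `atom_z`,
#' radius `atom_radius`), first touches the atom.  Contact is on the
#' hemisphere when `d <= (r + r_a) cos(theta)` and on the cone flank
#' otherwise; the two branches agree at the boundary.  Vectorized over `d`,
#' `atom_z` and `atom_radius`.
#'
#' @param probe a [probe_shape].
#' @param atom_z atom center height(s) above the stage (nm).
#' @param atom_radius atom collision radius/radii (nm).
#' @param d lateral distance(s) from the probe axis (nm, >= 0).
#' @return Apex height(s) in nm.  Because the cone flank extends upward
#'   indefinitely, contact always occurs; far from the atom the value is
#'   far below the stage and rendering floors it at 0.
#' @export
tip_height_over_atom <- function(probe, atom_z, atom_radius, d) {
  if (any(d < 0)) stop("lateral distance d must be >= 0")
  th <- probe$angle * pi / 180
  R <- probe$radius + atom_radius
  sphere <- d <= R * cos(th)
  ifelse(sphere,
         atom_z + sqrt(pmax(R^2 - d^2, 0)) - probe$radius,
         atom_z + (atom_radius + probe$radius - d * cos(th)) / sin(th) -
           probe$radius)
}

# Lateral reach of the probe around an atom (largest d with apex >= stage),
# used to size the rendering frame.  Overestimates are harmless.
probe_reach <- function(probe, atom_z, atom_radius) {
  th <- probe$angle * pi / 180
  R <- probe$radius + atom_radius
  dz <- probe$radius - atom_z
  ds <- ifelse(dz <= 0, R, ifelse(dz < R, sqrt(pmax(R^2 - dz^2, 0)), 0))
  dc <- (atom_radius + probe$radius - dz * sin(th)) / cos(th)
  pmax(ds, dc, 0)
}

#' Render a pseudo-AFM image
#'
#' For each pixel, the probe is centred on the pixel center and lowered
#' until it first touches any atom; the pixel height is the apex height at
#' contact, floored at the stage plane (0 nm).  Pixels out of reach of all
#' atoms are 0.
#'
#' @param model an [afm_model] (typically grounded, see
#'   [ground_on_stage]).
#' @param probe a [probe_shape].
#' @param pixel_size pixel edge in nm.
#' @param frame optional frame specification `list(origin = c(x, y),
#'   nx =, ny =)`; by default a frame covering the full tip-dilated
#'   footprint of the model is used.
#' @param margin extra zero-height pixels added on every side of the
#'   automatic frame.
#' @return An [afm_image].
#' @export
render_afm <- function(model, probe, pixel_size = 1, frame = NULL,
                       margin = 0) {
  if (!is.finite(pixel_size) || pixel_size <= 0)
    stop("pixel_size must be > 0")
  if (is.null(frame)) {
    if (nrow(model$xyz) == 0L)
      return(afm_image(matrix(0, 1, 1), pixel_size))
    pad <- max(probe_reach(probe, model$xyz[, 3], model$radii)) + pixel_size
    ox <- min(model$xyz[, 1]) - pad - margin * pixel_size
    oy <- min(model$xyz[, 2]) - pad - margin * pixel_size
    nx <- ceiling((max(model$xyz[, 1]) + pad + margin * pixel_size - ox) /
                    pixel_size)
    ny <- ceiling((max(model$xyz[, 2]) + pad + margin * pixel_size - oy) /
                    pixel_size)
  } else {
    ox <- frame$origin[1]; oy <- frame$origin[2]
    nx <- frame$nx; ny <- frame$ny
  }
  h <- cpp_render(model$xyz, model$radii, probe$radius, probe$angle,
                  pixel_size, ox, oy, as.integer(nx), as.integer(ny))
  afm_image(h, pixel_size, origin = c(ox, oy))
}

#' Add Gaussian pixel noise to a height map
#'
#' Spatially independent Gaussian noise with mean 0 and standard deviation
#' `sigma` is added to every pixel.  Heights are not clipped at 0: the
#' background keeps a symmetric noise distribution around the stage.
#'
#' @param img an [afm_image].
#' @param sigma noise standard deviation in nm (>= 0).
#' @param seed optional integer seed for reproducibility; the caller's RNG
#'   state is preserved.
#' @return The noisy [afm_image].
#' @export
add_noise <- function(img, sigma, seed = NULL) {
  if (sigma < 0) stop("sigma must be >= 0")
  if (sigma == 0) return(img)
  noise <- with_seed(seed,
                     matrix(rnorm(length(img$heights), 0, sigma),
                            nrow(img$heights), ncol(img$heights)))
  afm_image(img$heights + noise, img$pixel_size, img$origin)
}

#' Read and write height maps as plain text
#'
#' The text format is a tab-separated matrix of heights in nm, one image
#' row per line (row 1 = lowest Y first), preceded by optional header lines
#' `# pixel_size_nm=...` and `# origin_nm=x,y`.  The reader also accepts
#' comma-separated values.  Heights are written at 1e-4 nm resolution, so a
#' written file round-trips bit-identically through read/write.
#'
#' @param img an [afm_image].
#' @param path file path.
#' @return `read_afm_image` returns an [afm_image]; `write_afm_image`
#'   invisibly returns `path`.
#' @export
write_afm_image <- function(img, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# pixel_size_nm=%.6g", img$pixel_size),
               sprintf("# origin_nm=%.6g,%.6g", img$origin[1],
                       img$origin[2])), con)
  apply(img$heights, 1, function(row)
    writeLines(paste(sprintf("%.4f", row), collapse = "\t"), con))
  invisible(path)
}

#' @rdname write_afm_image
#' @export
read_afm_image <- function(path) {
  lines <- readLines(path)
  hdr <- grepl("^\\s*#", lines)
  px <- 1; orig <- c(0, 0)
  for (l in lines[hdr]) {
    if (grepl("pixel_size_nm=", l))
      px <- as.numeric(sub(".*pixel_size_nm=", "", l))
    if (grepl("origin_nm=", l))
      orig <- as.numeric(strsplit(sub(".*origin_nm=", "", l), ",")[[1]])
  }
  body <- lines[!hdr & nzchar(trimws(lines))]
  if (length(body) == 0L) stop("no data rows in height-map file")
  rows <- lapply(body, function(l)
    as.numeric(strsplit(trimws(l), "[\t,]+")[[1]]))
  ncols <- unique(vapply(rows, length, integer(1)))
  if (length(ncols) != 1L) stop("ragged rows in height-map file")
  afm_image(do.call(rbind, rows), px, orig)
}
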