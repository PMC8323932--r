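# Image similarity cost functions with the bounding-rectangle trimming rule.

#' Penalty-score parameters
#'
#' Defaults follow the favourable-region thickness of 1.2 nm with weights
#' `k_penalty = 10` (pseudo-image pixel protruding above the reference) and
#' `k_reward = 1` (pixel just beneath the reference surface).
#'
#' @param thickness favourable-region thickness in nm.
#' @param k_penalty cost added per protruding pixel.
#' @param k_reward cost subtracted per pixel within the favourable band.
#' @return An object of class `penalty_params`.
#' @export
penalty_params <- function(thickness = 1.2, k_penalty = 10, k_reward = 1) {
  if (any(c(thickness, k_penalty, k_reward) <= 0))
    stop("penalty parameters must be > 0")
  structure(list(thickness = thickness, k_penalty = k_penalty,
                 k_reward = k_reward), class = "penalty_params")
}

#' Score-input container: a pair of equal-shape image windows
#'
#' Builds the container consumed by the score functions from two
#' equal-shape height windows directly.  Normally produced by [trim_pair];
#' the direct constructor is useful for desk checks on hand-built windows.
#'
#' @param sim,ref equal-shape numeric matrices (heights in nm).
#' @return An object of class `trimmed_pair` with elements `sim`, `ref`
#'   and `n` (pixel count).
#' @export
trimmed_pair <- function(sim, ref) {
  sim <- as.matrix(sim); ref <- as.matrix(ref)
  if (!all(dim(sim) == dim(ref)))
    stop("sim and ref windows must have the same shape")
  structure(list(sim = sim, ref = ref, n = length(sim)),
            class = "trimmed_pair")
}

#' Trim a pseudo/reference image pair
#'
#' Cuts both images to the minimum bounding rectangle of strictly positive
#' pixels of the pseudo-AFM image, with the pseudo image placed inside the
#' reference at an integer pixel offset.  Only the pseudo image defines the
#' window; noisy reference pixels play no role in the trimming.
#'
#' @param sim pseudo-AFM [afm_image] (or height matrix).
#' @param ref reference [afm_image] (or height matrix) of at least the same
#'   size.
#' @param offset integer `(row, col)` 0-based offset of `sim`'s grid within
#'   `ref`'s grid.
#' @return An object of class `trimmed_pair`: list with elements `sim` and
#'   `ref` (equal-shape height matrices) and `n` (pixel count).
#' @export
trim_pair <- function(sim, ref, offset = c(0, 0)) {
  s <- if (inherits(sim, "afm_image")) sim$heights else as.matrix(sim)
  r <- if (inherits(ref, "afm_image")) ref$heights else as.matrix(ref)
  nz <- which(s > 0, arr.ind = TRUE)
  if (nrow(nz) == 0L)
    stop(structure(class = c("afmrigid_empty_window", "error", "condition"),
                   list(message = "pseudo-AFM image has no non-zero pixel",
                        call = sys.call(-1))))
  r0 <- min(nz[, 1]); r1 <- max(nz[, 1])
  c0 <- min(nz[, 2]); c1 <- max(nz[, 2])
  rr0 <- r0 + offset[1]; rr1 <- r1 + offset[1]
  cc0 <- c0 + offset[2]; cc1 <- c1 + offset[2]
  if (rr0 < 1 || cc0 < 1 || rr1 > nrow(r) || cc1 > ncol(r))
    stop("placement puts the trimming window outside the reference image")
  trimmed_pair(s[r0:r1, c0:c1, drop = FALSE],
               r[rr0:rr1, cc0:cc1, drop = FALSE])
}

#' Cosine similarity between trimmed images
#'
#' Inner product of pixel heights over the product of their Euclidean
#' norms.  1 for identical images, 0 for images with disjoint support;
#' invariant under uniform scaling of either image but not under uniform
#' shifting.  The associated cost is `1 - similarity`.
#'
#' @param pair a [trim_pair] result.
#' @return Similarity in `[0, 1]` (for non-negative images).
#' @export
cosine_similarity <- function(pair) {
  s <- pair$sim; r <- pair$ref
  ns <- sqrt(sum(s^2)); nr <- sqrt(sum(r^2))
  if (ns == 0 || nr == 0)
    stop("undefined cosine similarity: zero-norm window")
  sum(s * r) / (ns * nr)
}

#' Correlation coefficient between trimmed images
#'
#' Pearson correlation of pixel heights: 1 for identical images, -1 for
#' images related by negation; invariant under uniform scaling and uniform
#' shifting.  The associated cost is `1 - coefficient`.
#'
#' @param pair a [trim_pair] result.
#' @return Correlation in `[-1, 1]`.
#' @export
correlation_coefficient <- function(pair) {
  s <- as.vector(pair$sim); r <- as.vector(pair$ref)
  if (sd(s) == 0 || sd(r) == 0)
    stop("undefined correlation: zero-variance window")
  sum((s - mean(s)) * (r - mean(r))) /
    sqrt(sum((s - mean(s))^2) * sum((r - mean(r))^2))
}

#' Pixel-RMSD between trimmed images
#'
#' Root of the mean squared pixel height difference, in nm.  0 for
#' identical images; sensitive to both uniform scaling and shifting.
#'
#' @param pair a [trim_pair] result.
#' @return RMSD cost in nm (>= 0).
#' @export
pixel_rmsd <- function(pair) {
  sqrt(mean((pair$sim - pair$ref)^2))
}

#' Penalty cost between trimmed images
#'
#' Per-pixel piecewise sum: `+k_penalty` where the pseudo image protrudes
#' above the reference (`sim > ref`), `-k_reward` where it lies within the
#' favourable band just beneath the reference
#' (`ref - thickness < sim <= ref`), and 0 where it is deeper than the
#' band.  Asymmetric in (sim, ref) by construction.
#'
#' @param pair a [trim_pair] result.
#' @param params a [penalty_params].
#' @return Penalty cost (unbounded).
#' @export
penalty_cost <- function(pair, params = penalty_params()) {
  s <- pair$sim; r <- pair$ref
  pen <- s > r
  rew <- !pen & (s > r - params$thickness)
  params$k_penalty * sum(pen) - params$k_reward * sum(rew)
}

score_id <- function(score) {
  match(match.arg(score, c("cosine", "correlation", "pixel_rmsd",
                           "penalty")),
        c("cosine", "correlation", "pixel_rmsd", "penalty"))
}

#' Unified cost of a trimmed pair
#'
#' Evaluates the cost function named by `score` (`1 - similarity` for
#' cosine and correlation, the RMSD itself, or the penalty sum).  Windows
#' on which a score is undefined (zero norm or zero variance) yield `Inf`,
#' the worst possible cost, so the search can skip them without NaN
#' propagation.
#'
#' @param pair a [trim_pair] result.
#' @param score one of `"cosine"`, `"correlation"`, `"pixel_rmsd"`,
#'   `"penalty"`.
#' @param params a [penalty_params] (penalty score only).
#' @return The scalar cost.
#' @export
score_cost <- function(pair, score = c("cosine", "correlation",
                                       "pixel_rmsd", "penalty"),
                       params = penalty_params()) {
  score <- match.arg(score)
  tryCatch(switch(score,
                  cosine = 1 - cosine_similarity(pair),
                  correlation = 1 - correlation_coefficient(pair),
                  pixel_rmsd = pixel_rmsd(pair),
                  penalty = penalty_cost(pair, params)),
           error = function(e) Inf)
}
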