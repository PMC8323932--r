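# Independent oracles used across the test files.  These deliberately
# re-derive results by brute force (dense sampling, explicit loops) and
# never call the code paths they check.

# Tip contact height by dense sampling of the analytic tip surface: the
# tip profile z_s(rho) (height above the apex at lateral offset rho) is
# sampled finely and the apex height at first contact with the atom sphere
# is the maximum over surface points of atom_z + sqrt(r_a^2 - h^2) - z_s,
# h being the horizontal distance from the surface point to the atom axis.
descent_tip_height <- function(probe, atom_z, atom_radius, d, n = 40001) {
  r <- probe$radius
  th <- probe$angle * pi / 180
  span <- d + atom_radius + 2 * r + 1
  rho <- seq(-span, span, length.out = n)
  zs <- ifelse(abs(rho) <= r * cos(th),
               r - sqrt(pmax(r^2 - rho^2, 0)),
               r - r * sin(th) + (abs(rho) - r * cos(th)) / tan(th))
  h <- d - rho
  ok <- abs(h) <= atom_radius
  max(atom_z + sqrt(pmax(atom_radius^2 - h[ok]^2, 0)) - zs[ok])
}

# Per-pixel / per-atom double-loop renderer.
naive_render <- function(model, probe, img) {
  out <- matrix(0, nrow(img$heights), ncol(img$heights))
  px <- img$pixel_size
  for (i in seq_len(nrow(out))) {
    for (j in seq_len(ncol(out))) {
      x <- img$origin[1] + (j - 0.5) * px
      y <- img$origin[2] + (i - 0.5) * px
      d <- sqrt((x - model$xyz[, 1])^2 + (y - model$xyz[, 2])^2)
      out[i, j] <- max(0, tip_height_over_atom(probe, model$xyz[, 3],
                                               model$radii, d))
    }
  }
  out
}

# Naive quadruple-loop fit: explicit enumeration over orientation, probe,
# row-major XY offset and Z offset, scored with the R score functions.
# Returns the per-(orientation, probe) best-cost matrix plus the global
# argmin.
naive_fit <- function(model, ref, probes, angle_step, z_step, score) {
  rots <- orientation_grid(angle_step)
  K <- dim(rots)[3]
  refh <- ref$heights
  costs <- matrix(Inf, K, nrow(probes))
  best <- list(cost = Inf)
  for (k in seq_len(K)) {
    m <- transform_model(model, rots[, , k])
    m$xyz[, 3] <- m$xyz[, 3] - min(m$xyz[, 3] - m$radii)
    for (p in seq_len(nrow(probes))) {
      pb <- probe_shape(probes$radius[p], probes$angle[p])
      s <- render_afm(m, pb, ref$pixel_size)$heights
      nz <- which(s > 0, arr.ind = TRUE)
      if (nrow(nz) == 0) next
      W <- s[min(nz[, 1]):max(nz[, 1]), min(nz[, 2]):max(nz[, 2]),
             drop = FALSE]
      h <- nrow(W); w <- ncol(W)
      if (h > nrow(refh) || w > ncol(refh)) next
      zo <- if (max(W) >= max(refh)) 0 else
        (0:floor((max(refh) - max(W)) / z_step)) * z_step
      for (or in 0:(nrow(refh) - h)) {
        for (oc in 0:(ncol(refh) - w)) {
          R <- refh[or + seq_len(h), oc + seq_len(w), drop = FALSE]
          for (zi in seq_along(zo)) {
            W2 <- W
            W2[W2 > 0] <- W2[W2 > 0] + zo[zi]
            cost <- score_cost(trimmed_pair(W2, R), score)
            if (cost < costs[k, p]) costs[k, p] <- cost
            if (cost < best$cost)
              best <- list(cost = cost, orientation = k, probe = p,
                           off_row = or, off_col = oc, z_idx = zi - 1)
          }
        }
      }
    }
  }
  list(costs = costs, best = best)
}

# Random strictly positive height window (support everywhere).
random_window <- function(nr, nc, lo = 0.1, hi = 5) {
  matrix(runif(nr * nc, lo, hi), nr, nc)
}
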