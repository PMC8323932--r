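# Atomic models, rigid transforms, OBB grounding and structure-RMSD.

# Per-element van der Waals radii in nm; standard values used by
# collision-detection AFM simulators.
.vdw_nm <- c(C = 0.170, N = 0.155, O = 0.152, S = 0.180, H = 0.120,
             P = 0.180)
.default_radius_nm <- 0.170
.water_resid <- c("HOH", "WAT", "DOD", "SOL", "TIP", "TIP3", "TIP4", "H2O")

#' Atomic model
#'
#' A rigid collection of spherical atoms: coordinates in nm and a per-atom
#' collision radius in nm, plus an optional opaque label table (chain,
#' residue, atom name) carried through transforms untouched.
#'
#' @param xyz numeric n x 3 matrix of coordinates (nm).
#' @param radii numeric vector of collision radii (nm), length n, all > 0.
#' @param atom optional data.frame of per-atom labels with n rows.
#' @return An object of class `afm_model`.
#' @export
afm_model <- function(xyz, radii, atom = NULL) {
  xyz <- as.matrix(xyz)
  if (ncol(xyz) != 3L) stop("xyz must be an n x 3 matrix")
  storage.mode(xyz) <- "double"
  if (!all(is.finite(xyz))) stop("coordinates must be finite")
  radii <- as.numeric(radii)
  if (length(radii) == 1L) radii <- rep(radii, nrow(xyz))
  if (length(radii) != nrow(xyz))
    stop("length(radii) must equal the number of atoms")
  if (!all(is.finite(radii)) || any(radii <= 0))
    stop("radii must be finite and > 0")
  if (!is.null(atom) && nrow(atom) != nrow(xyz))
    stop("atom table must have one row per atom")
  structure(list(xyz = xyz, radii = radii, atom = atom),
            class = "afm_model")
}

#' @export
print.afm_model <- function(x, ...) {
  cat(sprintf("afm_model: %d atoms, radii %.3f-%.3f nm\n",
              nrow(x$xyz), min(x$radii), max(x$radii)))
  ext <- apply(x$xyz, 2, function(v) diff(range(v)))
  cat(sprintf("  extent (nm): %.2f x %.2f x %.2f\n", ext[1], ext[2], ext[3]))
  invisible(x)
}

#' Number of atoms in a model
#' @param model an `afm_model`.
#' @return Integer atom count.
#' @export
n_atoms <- function(model) nrow(model$xyz)

infer_element <- function(elety) {
  e <- toupper(gsub("[^A-Za-z].*$", "", gsub("^[0-9]+", "", elety)))
  two <- substr(e, 1, 2)
  one <- substr(e, 1, 1)
  ifelse(two %in% names(.vdw_nm), two,
         ifelse(one %in% names(.vdw_nm), one, e))
}

#' Read an atomic structure from a PDB file
#'
#' Parses ATOM/HETATM records, converts coordinates from angstrom to nm and
#' assigns per-atom collision radii.  Waters are excluded by default; other
#' HETATM records are kept.
#'
#' @param path path to a PDB file.
#' @param radius_scheme `"vdw"` for per-element van der Waals radii
#'   (C 0.170, N 0.155, O 0.152, S 0.180, H 0.120, P 0.180 nm; unknown
#'   elements fall back to 0.170 nm with a warning), or `"uniform"`.
#' @param uniform_radius radius in nm used when `radius_scheme = "uniform"`.
#' @param include_hetatm keep non-water HETATM records.
#' @return An [afm_model].
#' @export
read_structure <- function(path, radius_scheme = c("vdw", "uniform"),
                           uniform_radius = 0.2, include_hetatm = TRUE) {
  radius_scheme <- match.arg(radius_scheme)
  pdb <- tryCatch(bio3d::read.pdb(path, verbose = FALSE),
                  error = function(e)
                    stop("cannot parse PDB file '", path, "': ",
                         conditionMessage(e)))
  at <- pdb$atom
  keep <- !(toupper(at$resid) %in% .water_resid)
  if (!include_hetatm) keep <- keep & at$type == "ATOM"
  at <- at[keep, , drop = FALSE]
  if (nrow(at) == 0L) stop("no atoms left after filtering: empty input")
  xyz <- cbind(at$x, at$y, at$z) / 10  # angstrom -> nm
  if (radius_scheme == "uniform") {
    radii <- rep(uniform_radius, nrow(at))
  } else {
    elem <- at$elesy
    if (is.null(elem) || all(is.na(elem)) || all(elem == ""))
      elem <- infer_element(at$elety)
    elem[is.na(elem) | elem == ""] <- infer_element(at$elety[is.na(elem) | elem == ""])
    elem <- toupper(trimws(elem))
    radii <- unname(.vdw_nm[elem])
    if (anyNA(radii)) {
      warning("unknown element(s) ",
              paste(unique(elem[is.na(radii)]), collapse = ", "),
              "; using default radius ", .default_radius_nm, " nm")
      radii[is.na(radii)] <- .default_radius_nm
    }
  }
  afm_model(xyz, radii, atom = at)
}

#' Write an atomic model to a PDB file
#'
#' Coordinates are converted from nm back to angstrom.  Original labels are
#' reused when the model was read from a PDB file.
#'
#' @param model an [afm_model].
#' @param path output file path.
#' @return Invisibly, `path`.
#' @export
write_structure <- function(model, path) {
  xyz <- as.vector(t(model$xyz * 10))  # nm -> angstrom
  if (!is.null(model$atom)) {
    at <- model$atom
    bio3d::write.pdb(file = path, xyz = xyz,
                     type = at$type, resno = at$resno, resid = at$resid,
                     eleno = at$eleno, elety = at$elety,
                     chain = at$chain)
  } else {
    n <- nrow(model$xyz)
    bio3d::write.pdb(file = path, xyz = xyz,
                     resno = seq_len(n), resid = rep("BLB", n),
                     eleno = seq_len(n), elety = rep("C", n),
                     chain = rep("A", n))
  }
  invisible(path)
}

#' Elementary rotation matrices
#'
#' Proper rotations about the coordinate axes or an arbitrary axis, in
#' degrees, acting on column vectors.
#'
#' @param deg rotation angle in degrees.
#' @param axis length-3 axis vector (need not be normalized).
#' @return A 3 x 3 rotation matrix.
#' @export
rot_z <- function(deg) {
  a <- deg * pi / 180
  matrix(c(cos(a), sin(a), 0, -sin(a), cos(a), 0, 0, 0, 1), 3, 3)
}

#' @rdname rot_z
#' @export
rot_x <- function(deg) {
  a <- deg * pi / 180
  matrix(c(1, 0, 0, 0, cos(a), sin(a), 0, -sin(a), cos(a)), 3, 3)
}

#' @rdname rot_z
#' @export
rot_y <- function(deg) {
  a <- deg * pi / 180
  matrix(c(cos(a), 0, -sin(a), 0, 1, 0, sin(a), 0, cos(a)), 3, 3)
}

#' @rdname rot_z
#' @export
rot_axis <- function(axis, deg) {
  u <- axis / sqrt(sum(axis^2))
  a <- deg * pi / 180
  K <- matrix(c(0, u[3], -u[2], -u[3], 0, u[1], u[2], -u[1], 0), 3, 3)
  diag(3) + sin(a) * K + (1 - cos(a)) * (K %*% K)
}

# Rotation taking the +Z axis onto unit vector u (shortest arc; for
# u = -Z a half-turn about X is used).
align_z_to <- function(u) {
  u <- u / sqrt(sum(u^2))
  c2 <- u[3]
  ax <- c(-u[2], u[1], 0)
  s <- sqrt(sum(ax^2))
  if (s < 1e-12) {
    if (c2 > 0) return(diag(3))
    return(diag(c(1, -1, -1)))  # half turn about X
  }
  rot_axis(ax, atan2(s, c2) * 180 / pi)
}

#' Apply a rigid transform to a model
#'
#' Computes `x' = R x + t` for every atom; radii and labels are untouched.
#'
#' @param model an [afm_model].
#' @param rotation 3 x 3 proper rotation matrix.
#' @param translation length-3 translation vector (nm).
#' @return The transformed [afm_model].
#' @export
transform_model <- function(model, rotation = diag(3),
                            translation = c(0, 0, 0)) {
  stopifnot(all(dim(rotation) == c(3, 3)), length(translation) == 3)
  if (max(abs(crossprod(rotation) - diag(3))) > 1e-6 ||
      det(rotation) < 0)
    stop("rotation must be a proper orthonormal matrix")
  xyz <- model$xyz %*% t(rotation)
  xyz <- sweep(xyz, 2, translation, "+")
  afm_model(xyz, model$radii, model$atom)
}

# Deterministic sign convention for a unit vector: the entry with the
# largest magnitude is made positive.
fix_sign <- function(v) {
  i <- which.max(abs(v))
  if (v[i] < 0) -v else v
}

#' Ground a model on the stage by its oriented bounding box
#'
#' Builds the oriented-bounding-box axes from principal component analysis
#' of the atom coordinates (axis 1 = first PC, axis 2 = second PC
#' re-orthogonalized to axis 1, axis 3 = axis1 x axis2), rotates the model
#' so the largest OBB face (spanned by axes 1 and 2) is parallel to the XY
#' plane, and translates it so that `min(z - radius) = 0`, i.e. the lowest
#' atom sphere rests on the stage plane z = 0.  The XY centroid is moved to
#' the origin.  PC signs are fixed deterministically, so grounding is
#' idempotent.
#'
#' @param model an [afm_model] with at least 3 non-collinear atoms.
#' @return The grounded [afm_model].
#' @export
ground_on_stage <- function(model) {
  X <- model$xyz
  if (nrow(X) < 3) stop("grounding needs at least 3 atoms")
  ctr <- colMeans(X)
  Xc <- sweep(X, 2, ctr)
  sv <- svd(Xc)
  if (sv$d[2] < 1e-9 * max(sv$d[1], 1e-12))
    stop("degenerate (collinear or coincident) atom coordinates")
  a1 <- fix_sign(sv$v[, 1])
  a2 <- sv$v[, 2] - sum(sv$v[, 2] * a1) * a1
  a2 <- fix_sign(a2 / sqrt(sum(a2^2)))
  a3 <- c(a1[2] * a2[3] - a1[3] * a2[2],
          a1[3] * a2[1] - a1[1] * a2[3],
          a1[1] * a2[2] - a1[2] * a2[1])
  R <- unname(rbind(a1, a2, a3))  # world -> OBB frame, det = +1
  Y <- Xc %*% t(R)
  dz <- -min(Y[, 3] - model$radii)
  Y[, 3] <- Y[, 3] + dz
  out <- afm_model(Y, model$radii, model$atom)
  attr(out, "transform") <- list(rotation = unname(R),
                                 translation = c(-(R %*% ctr)[1:2], dz -
                                                   (R %*% ctr)[3]))
  out
}

#' Structure RMSD between two placements
#'
#' Root-mean-square of per-atom Euclidean distances between two models with
#' matched atom order.  No superposition is performed: the deviation is
#' measured in the common (stage) frame.
#'
#' @param a,b [afm_model]s with equal atom counts and matched order.
#' @return RMSD in nm.
#' @export
structure_rmsd <- function(a, b) {
  if (nrow(a$xyz) != nrow(b$xyz))
    stop("atom counts differ: ", nrow(a$xyz), " vs ", nrow(b$xyz))
  sqrt(mean(rowSums((a$xyz - b$xyz)^2)))
}

#' Windowed structure RMSD against a longer filament
#'
#' For a k-mer fitted into an image of an m-mer (m >= k) filament, computes
#' the structure RMSD against every consecutive k-monomer window of the
#' longer ground-truth filament and returns the minimum.
#'
#' @param pred fitted [afm_model] (k monomers).
#' @param truth ground-truth [afm_model] (m monomers, same monomer).
#' @param atoms_per_monomer number of atoms in one monomer.
#' @return Minimum windowed RMSD in nm.
#' @export
windowed_filament_rmsd <- function(pred, truth, atoms_per_monomer) {
  np <- nrow(pred$xyz); nt <- nrow(truth$xyz)
  if (np %% atoms_per_monomer != 0 || nt %% atoms_per_monomer != 0)
    stop("atom counts must be multiples of atoms_per_monomer")
  k <- np / atoms_per_monomer
  m <- nt / atoms_per_monomer
  if (k > m) stop("prediction window is longer than the ground truth")
  vals <- vapply(0:(m - k), function(s) {
    idx <- (s * atoms_per_monomer + 1):((s + k) * atoms_per_monomer)
    sqrt(mean(rowSums((pred$xyz - truth$xyz[idx, , drop = FALSE])^2)))
  }, numeric(1))
  min(vals)
}
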