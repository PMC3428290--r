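# Rigid-body superposition and the per-frame / per-atom descriptors used as
# landscape coordinates and stability measures.

#' Kabsch least-squares superposition
#'
#' Finds the proper rotation and translation minimising the (optionally
#' weighted) RMSD between two coordinate sets, via the SVD of the weighted
#' cross-covariance matrix with the usual sign correction that excludes
#' reflections.
#'
#' @param mobile,reference `n x 3` coordinate matrices, `n >= 3`.
#' @param weights per-atom weights (e.g. masses), or `NULL` for unit
#'   weights.
#' @return list of class `kabsch_fit`: `rotation` (3x3, det = +1),
#'   `translation` (length 3), `rmsd` (Angstrom, weighted). The fitted
#'   mobile copy is `mobile %*% t(rotation) + translation` (rows).
#' @export
kabsch <- function(mobile, reference, weights = NULL) {
  mobile <- as.matrix(mobile)
  reference <- as.matrix(reference)
  if (!all(dim(mobile) == dim(reference)) || ncol(mobile) != 3) {
    stop("mobile and reference must be equal-sized n x 3 matrices")
  }
  n <- nrow(mobile)
  if (n < 3) stop("superposition needs at least 3 atoms")
  w <- if (is.null(weights)) rep(1, n) else as.numeric(weights)
  stopifnot(length(w) == n, all(w >= 0), sum(w) > 0)
  w <- w / sum(w)

  cm <- colSums(mobile * w)
  cr <- colSums(reference * w)
  x <- sweep(mobile, 2, cm)
  y <- sweep(reference, 2, cr)
  if (max(abs(x)) < 1e-12 && max(abs(y)) < 1e-12) {
    stop("degenerate input: all points coincident")
  }
  h <- t(x * w) %*% y
  s <- svd(h)
  # smallest singular value ~ 0 for collinear sets: rotation about the line
  # is unconstrained, flag as degenerate rather than return an arbitrary fit
  if (s$d[1] > 0 && s$d[2] / s$d[1] < 1e-10) {
    stop("degenerate input: points are collinear")
  }
  d <- sign(det(s$v %*% t(s$u)))
  rot <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  fitted <- x %*% t(rot)
  rmsd <- sqrt(sum(w * rowSums((fitted - y)^2)))
  structure(
    list(
      rotation = rot,
      translation = as.numeric(cr - cm %*% t(rot)),
      rmsd = rmsd
    ),
    class = "kabsch_fit"
  )
}

#' Apply a superposition transform to coordinates
#'
#' @param fit a `kabsch_fit`.
#' @param coords `n x 3` matrix.
#' @return transformed `n x 3` matrix.
#' @export
apply_transform <- function(fit, coords) {
  sweep(as.matrix(coords) %*% t(fit$rotation), 2, fit$translation, `+`)
}

# Weighted RMSD between already-aligned coordinate sets.
.raw_rmsd <- function(a, b, w = NULL) {
  n <- nrow(a)
  w <- if (is.null(w)) rep(1 / n, n) else w / sum(w)
  sqrt(sum(w * rowSums((a - b)^2)))
}

#' Per-frame RMSD series after superposition
#'
#' Each frame is superposed onto the reference over the selection, and the
#' RMSD over that same selection is reported (fit set = measurement set).
#' Unweighted by default, matching the convention of single-atom-type RMSD
#' traces such as C5' RMSD of a duplex; set `mass_weighted` for the
#' mass-weighted variant.
#'
#' @param traj an `md_traj`.
#' @param ref reference coordinates: an `n_sel x 3` matrix over the
#'   selection, or a full `n_atoms x 3` frame from which the selection is
#'   taken.
#' @param sel an `md_selection` (or `NULL` for all atoms).
#' @param mass_weighted logical; weight fit and RMSD by atomic mass.
#' @return data.frame of class `descriptor_series` with columns `time_ps`,
#'   `value` and attributes `label`, `unit`.
#' @export
rmsd_series <- function(traj, ref, sel = NULL, mass_weighted = FALSE) {
  idx <- select_atoms(traj, sel)
  if (length(idx) == 0) stop("empty selection")
  ref <- as.matrix(ref)
  if (nrow(ref) == n_atoms(traj)) ref <- ref[idx, , drop = FALSE]
  if (nrow(ref) != length(idx)) {
    stop("reference has ", nrow(ref), " rows; selection has ", length(idx))
  }
  w <- if (mass_weighted) traj$atoms$mass[idx] else NULL
  vals <- vapply(seq_len(n_frames(traj)), function(f) {
    kabsch(traj$xyz[idx, , f], ref, weights = w)$rmsd
  }, numeric(1))
  descriptor_series(frame_times(traj), vals, label = "rmsd")
}

#' Iterative average structure
#'
#' Superposes every frame onto the running mean and recomputes the mean
#' until it moves less than `tol` (max per-coordinate displacement),
#' starting from the first frame. Iterated means depend weakly on the seed
#' frame; the first frame is used so results are reproducible.
#'
#' @param traj an `md_traj`.
#' @param sel an `md_selection` or `NULL`.
#' @param tol convergence threshold in Angstrom (default 1e-6).
#' @param max_iter iteration cap; exceeding it is an error.
#' @return `n_sel x 3` matrix of mean coordinates.
#' @export
average_structure <- function(traj, sel = NULL, tol = 1e-6, max_iter = 100) {
  idx <- select_atoms(traj, sel)
  if (length(idx) == 0) stop("empty selection")
  nf <- n_frames(traj)
  mean_xyz <- traj$xyz[idx, , 1, drop = TRUE]
  if (nf == 1) return(mean_xyz)
  for (it in seq_len(max_iter)) {
    acc <- matrix(0, length(idx), 3)
    for (f in seq_len(nf)) {
      fit <- kabsch(traj$xyz[idx, , f], mean_xyz)
      acc <- acc + apply_transform(fit, traj$xyz[idx, , f])
    }
    new_mean <- acc / nf
    shift <- max(abs(new_mean - mean_xyz))
    mean_xyz <- new_mean
    if (shift < tol) return(mean_xyz)
  }
  stop(
    "average structure did not converge after ", max_iter,
    " iterations (last shift ", format(shift, digits = 3), " A)"
  )
}

#' Per-atom root-mean-square fluctuation
#'
#' Frames are superposed onto the iterative average structure over the
#' selection; each atom's RMSF is the root-mean-square deviation of its
#' superposed positions from its time-average position. For isotropic
#' Gaussian jitter of per-axis width sigma this converges to sigma*sqrt(3).
#'
#' @inheritParams rmsd_series
#' @return data.frame of class `fluctuation_profile` with columns `chain`,
#'   `resid`, `resname`, `name`, `rmsf_A`.
#' @export
rmsf <- function(traj, sel = NULL, mass_weighted = FALSE) {
  idx <- select_atoms(traj, sel)
  if (length(idx) == 0) stop("empty selection")
  nf <- n_frames(traj)
  if (nf < 2) stop("RMSF needs at least 2 frames")
  avg <- average_structure(traj, sel)
  w <- if (mass_weighted) traj$atoms$mass[idx] else NULL
  fitted <- array(0, dim = c(length(idx), 3, nf))
  for (f in seq_len(nf)) {
    fit <- kabsch(traj$xyz[idx, , f], avg, weights = w)
    fitted[, , f] <- apply_transform(fit, traj$xyz[idx, , f])
  }
  mean_pos <- apply(fitted, c(1, 2), mean)
  dev2 <- vapply(
    seq_len(nf),
    function(f) rowSums((fitted[, , f] - mean_pos)^2),
    numeric(length(idx))
  )
  vals <- sqrt(rowMeans(dev2))
  at <- traj$atoms[idx, ]
  structure(
    data.frame(
      chain = at$chain, resid = at$resid, resname = at$resname,
      name = at$name, rmsf_A = vals, stringsAsFactors = FALSE
    ),
    class = c("fluctuation_profile", "data.frame")
  )
}

#' Mass-weighted center of mass
#'
#' @param coords `n x 3` matrix.
#' @param masses per-atom masses; unit masses if `NULL`.
#' @return length-3 numeric vector.
#' @export
center_of_mass <- function(coords, masses = NULL) {
  coords <- as.matrix(coords)
  if (nrow(coords) == 0) stop("center of mass of an empty atom set")
  m <- if (is.null(masses)) rep(1, nrow(coords)) else as.numeric(masses)
  colSums(coords * m) / sum(m)
}

#' Radius of gyration of a coordinate set
#'
#' Mass-weighted RMS distance of the atoms from their center of mass
#' (the standard convention).
#'
#' @param coords `n x 3` matrix.
#' @param masses per-atom masses; unit masses if `NULL`.
#' @return Rg in Angstrom.
#' @export
radius_of_gyration <- function(coords, masses = NULL) {
  coords <- as.matrix(coords)
  if (nrow(coords) == 0) stop("empty selection")
  m <- if (is.null(masses)) rep(1, nrow(coords)) else as.numeric(masses)
  com <- center_of_mass(coords, m)
  sqrt(sum(m * rowSums(sweep(coords, 2, com)^2)) / sum(m))
}

#' Per-frame radius-of-gyration series
#'
#' @inheritParams rmsd_series
#' @return `descriptor_series` data.frame (`time_ps`, `value`).
#' @export
rg_series <- function(traj, sel = NULL) {
  idx <- select_atoms(traj, sel)
  if (length(idx) == 0) stop("empty selection")
  m <- traj$atoms$mass[idx]
  vals <- vapply(seq_len(n_frames(traj)), function(f) {
    radius_of_gyration(traj$xyz[idx, , f], m)
  }, numeric(1))
  descriptor_series(frame_times(traj), vals, label = "rg")
}

#' Construct a descriptor time series
#'
#' @param time_ps frame times (ps).
#' @param value one scalar per frame.
#' @param label descriptor label (e.g. `"rmsd"`, `"rg"`).
#' @return data.frame of class `descriptor_series`.
#' @export
descriptor_series <- function(time_ps, value, label = "") {
  stopifnot(length(time_ps) == length(value))
  structure(
    data.frame(time_ps = time_ps, value = value),
    label = label, class = c("descriptor_series", "data.frame")
  )
}
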