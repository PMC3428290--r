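# Core containers: topology (atom table + chain classification) and
# trajectory (topology + frame coordinates + sampling metadata).

#' Build a topology from an atom table
#'
#' The topology is the static half of a trajectory: one row per atom with
#' identity, residue membership and mass. Chains are classified as protein
#' or RNA from their residue-name vocabulary; a chain whose residues belong
#' to neither vocabulary is an error rather than being skipped silently.
#'
#' @param atoms data.frame with columns `serial`, `name`, `resname`,
#'   `resid`, `chain`, and optionally `element` and `mass`. Element is
#'   inferred from the atom name when absent; mass from the element.
#' @return object of class `md_topology`: the atom data.frame (with
#'   `element` and `mass` filled in) carrying a `chain_class` attribute,
#'   a named character vector mapping chain id to `"protein"` or `"rna"`.
#' @export
topology <- function(atoms) {
  req <- c("serial", "name", "resname", "resid", "chain")
  miss <- setdiff(req, names(atoms))
  if (length(miss) > 0) {
    stop("atom table lacks column(s): ", paste(miss, collapse = ", "))
  }
  atoms <- as.data.frame(atoms, stringsAsFactors = FALSE)
  atoms$name <- trimws(atoms$name)
  atoms$resname <- toupper(trimws(atoms$resname))
  if (is.null(atoms$element) || all(!nzchar(trimws(atoms$element)))) {
    atoms$element <- .element_from_name(atoms$name)
  } else {
    blank <- !nzchar(trimws(atoms$element))
    atoms$element[blank] <- .element_from_name(atoms$name[blank])
    atoms$element <- toupper(trimws(atoms$element))
  }
  if (is.null(atoms$mass)) atoms$mass <- element_mass(atoms$element)
  if (any(atoms$mass <= 0)) stop("all atomic masses must be positive")

  key <- paste(atoms$chain, atoms$resid, atoms$name)
  if (anyDuplicated(key)) {
    stop(
      "duplicate (chain, resid, name) atom key(s): ",
      paste(utils::head(unique(key[duplicated(key)]), 3), collapse = "; ")
    )
  }

  chain_class <- vapply(split(atoms$resname, atoms$chain), function(rn) {
    rn <- unique(rn)
    if (all(rn %in% .PROTEIN_RESNAMES)) return("protein")
    if (all(!is.na(base_identity(rn)))) return("rna")
    stop(
      "chain contains residue names outside the protein and RNA ",
      "vocabularies: ", paste(utils::head(setdiff(rn, .PROTEIN_RESNAMES), 5),
        collapse = ", "
      )
    )
  }, character(1))

  structure(atoms, chain_class = chain_class, class = c("md_topology", "data.frame"))
}

#' Chain classification of a topology
#'
#' @param topo an `md_topology`.
#' @return named character vector: `"protein"` or `"rna"` per chain id.
#' @export
chain_class <- function(topo) attr(topo, "chain_class")

#' Number of atoms in a topology or trajectory
#' @param x an `md_topology` or `md_traj`.
#' @return integer atom count.
#' @export
n_atoms <- function(x) {
  if (inherits(x, "md_traj")) nrow(x$atoms) else nrow(x)
}

#' Construct a trajectory
#'
#' A trajectory is a topology plus an ordered stack of coordinate frames at
#' a fixed sampling interval. By convention the first frame sits at
#' `t0 = dt`: a run of duration D sampled every s yields frames at
#' s, 2s, ..., D (so 50 ns at 10 ps gives exactly 5000 frames).
#'
#' @param topo an `md_topology` (or atom data.frame coercible to one).
#' @param xyz coordinates in Angstrom: an `n_atoms x 3 x n_frames` array, a
#'   single `n_atoms x 3` matrix (one frame), or a list of such matrices.
#' @param dt sampling interval in ps (> 0); default 10.
#' @param t0 time of the first frame in ps; defaults to `dt`.
#' @return object of class `md_traj`: a list with elements `atoms`, `xyz`
#'   (always a 3D array), `dt`, `t0`.
#' @export
trajectory <- function(topo, xyz, dt = 10, t0 = dt) {
  if (!inherits(topo, "md_topology")) topo <- topology(topo)
  if (is.list(xyz) && !is.array(xyz)) {
    xyz <- array(unlist(xyz), dim = c(nrow(xyz[[1]]), 3, length(xyz)))
  }
  if (is.matrix(xyz)) xyz <- array(xyz, dim = c(nrow(xyz), 3, 1))
  stopifnot(length(dim(xyz)) == 3, dim(xyz)[2] == 3)
  if (dim(xyz)[1] != nrow(topo)) {
    stop(
      "coordinate frames have ", dim(xyz)[1], " atoms but topology has ",
      nrow(topo)
    )
  }
  if (dim(xyz)[3] < 1) stop("trajectory needs at least one frame")
  if (!is.numeric(dt) || length(dt) != 1 || dt <= 0) {
    stop("dt must be a single positive number (ps)")
  }
  structure(
    list(atoms = topo, xyz = xyz, dt = as.numeric(dt), t0 = as.numeric(t0)),
    class = "md_traj"
  )
}

#' @export
print.md_traj <- function(x, ...) {
  cc <- chain_class(x$atoms)
  cat(
    "<md_traj> ", n_frames(x), " frame(s) x ", n_atoms(x), " atoms; dt = ",
    x$dt, " ps; t = [", min(frame_times(x)), ", ", max(frame_times(x)),
    "] ps\n  chains: ",
    paste(sprintf("%s(%s)", names(cc), cc), collapse = ", "), "\n",
    sep = ""
  )
  invisible(x)
}

#' Number of frames in a trajectory
#' @param traj an `md_traj`.
#' @return integer frame count.
#' @export
n_frames <- function(traj) dim(traj$xyz)[3]

#' Frame times in ps
#' @param traj an `md_traj`.
#' @return numeric vector `t0, t0 + dt, ...`, one entry per frame.
#' @export
frame_times <- function(traj) traj$t0 + (seq_len(n_frames(traj)) - 1) * traj$dt

#' Coordinates of one frame
#' @param traj an `md_traj`.
#' @param frame frame index (1-based).
#' @return `n_atoms x 3` numeric matrix (Angstrom).
#' @export
frame_coords <- function(traj, frame = 1) {
  stopifnot(frame >= 1, frame <= n_frames(traj))
  traj$xyz[, , frame, drop = TRUE]
}

#' Restrict a trajectory to a time window
#'
#' @param traj an `md_traj`.
#' @param t_start,t_end window bounds in ps (inclusive); `NULL` means
#'   unbounded on that side.
#' @return `md_traj` containing the frames with `t_start <= t <= t_end`.
#' @export
time_window <- function(traj, t_start = NULL, t_end = NULL) {
  tt <- frame_times(traj)
  keep <- rep(TRUE, length(tt))
  if (!is.null(t_start)) keep <- keep & tt >= t_start
  if (!is.null(t_end)) keep <- keep & tt <= t_end
  if (!any(keep)) stop("time window [", t_start, ", ", t_end, "] contains no frames")
  trajectory(traj$atoms, traj$xyz[, , keep, drop = FALSE],
    dt = traj$dt, t0 = tt[which(keep)[1]]
  )
}

#' Subsample a trajectory at a coarser interval
#'
#' Keeps the first frame and every frame an integer multiple of
#' `interval_ps` later, so subsampling at the native interval is the
#' identity and nested subsampling collapses: subsampling at `a` then `b`
#' equals subsampling at `b` whenever `b` is a multiple of `a`.
#'
#' @param traj an `md_traj`.
#' @param interval_ps new sampling interval in ps; must be a positive
#'   integer multiple of `traj$dt`.
#' @return `md_traj` with `dt = interval_ps`.
#' @export
subsample <- function(traj, interval_ps) {
  r <- interval_ps / traj$dt
  if (interval_ps <= 0 || abs(r - round(r)) > 1e-9) {
    stop(
      "interval_ps (", interval_ps, ") must be a positive integer multiple ",
      "of the trajectory dt (", traj$dt, ")"
    )
  }
  r <- as.integer(round(r))
  idx <- seq(1L, n_frames(traj), by = r)
  trajectory(traj$atoms, traj$xyz[, , idx, drop = FALSE],
    dt = interval_ps, t0 = traj$t0
  )
}
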