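# Multi-model PDB input/output. Parsing and column formatting are delegated
# to bio3d; this layer builds the package's topology model on top, validates
# frame consistency, and owns the time metadata (which PDB does not carry).

#' Read a (multi-model) PDB file as a trajectory
#'
#' Each MODEL block becomes one frame; a file without MODEL records is a
#' single-frame trajectory. PDB files carry no time axis, so the sampling
#' interval is taken from `dt`; when `dt` is omitted the conventional 10 ps
#' snapshot interval is assumed and a warning is issued.
#'
#' @param path path to a PDB file.
#' @param dt sampling interval in ps, or `NULL` to default to 10 with a
#'   warning.
#' @param t0 time of the first frame (ps); defaults to `dt`.
#' @return an [trajectory()] (`md_traj`).
#' @export
read_pdb <- function(path, dt = NULL, t0 = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  if (is.null(dt)) {
    warning("no sampling interval supplied for ", basename(path),
      "; assuming dt = 10 ps",
      call. = FALSE
    )
    dt <- 10
  }
  .check_pdb_lines(path)
  pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
  at <- pdb$atom
  atoms <- data.frame(
    serial = at$eleno,
    name = at$elety,
    resname = at$resid,
    resid = at$resno,
    chain = ifelse(is.na(at$chain), " ", at$chain),
    element = ifelse(is.na(at$elesy) | !nzchar(trimws(at$elesy)), "",
      trimws(at$elesy)
    ),
    stringsAsFactors = FALSE
  )
  nf <- nrow(pdb$xyz)
  xyz <- array(NA_real_, dim = c(nrow(atoms), 3, nf))
  for (f in seq_len(nf)) {
    xyz[, , f] <- matrix(pdb$xyz[f, ], ncol = 3, byrow = TRUE)
  }
  if (anyNA(xyz)) stop("models in ", path, " differ in atom count")
  trajectory(topology(atoms), xyz, dt = dt, t0 = if (is.null(t0)) dt else t0)
}

# Pre-scan of ATOM/HETATM records: coordinate fields must parse as numbers
# and every MODEL must contain the same number of atoms. bio3d recycles
# short models silently, so this check runs first and reports line numbers.
.check_pdb_lines <- function(path) {
  lines <- readLines(path, warn = FALSE)
  rec <- substr(lines, 1, 6)
  is_atom <- rec %in% c("ATOM  ", "HETATM")
  if (!any(is_atom)) stop("no ATOM/HETATM records in ", path)
  coords <- cbind(
    substr(lines[is_atom], 31, 38),
    substr(lines[is_atom], 39, 46),
    substr(lines[is_atom], 47, 54)
  )
  vals <- suppressWarnings(matrix(as.numeric(coords), ncol = 3))
  bad <- which(rowSums(is.na(vals) | !nzchar(trimws(coords))) > 0)
  if (length(bad) > 0) {
    stop(
      "malformed coordinate field at line ", which(is_atom)[bad[1]],
      " of ", path
    )
  }
  n_model <- sum(startsWith(lines, "MODEL"))
  if (n_model > 1) {
    counts <- table(cumsum(startsWith(lines, "MODEL"))[is_atom])
    if (length(unique(as.integer(counts))) > 1) {
      stop("models in ", path, " differ in atom count")
    }
  }
  invisible(TRUE)
}

#' Write a trajectory as a (multi-model) PDB file
#'
#' A single-frame trajectory is written without MODEL records; multi-frame
#' trajectories get one MODEL/ENDMDL block per frame. Coordinates are fixed
#' width with three decimals (the PDB format's precision, hence the 1e-3 A
#' round-trip tolerance).
#'
#' @param traj an `md_traj`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_pdb <- function(traj, path) {
  at <- traj$atoms
  nf <- n_frames(traj)
  # bio3d expects frames as rows of (x1,y1,z1,x2,...)
  xyz <- t(vapply(
    seq_len(nf),
    function(f) as.numeric(t(traj$xyz[, , f])),
    numeric(3 * n_atoms(traj))
  ))
  ok <- tryCatch(
    {
      bio3d::write.pdb(
        xyz = xyz, file = path,
        type = rep("ATOM", nrow(at)), eleno = at$serial, elety = at$name,
        resid = at$resname, chain = at$chain, resno = at$resid,
        elesy = at$element
      )
      TRUE
    },
    error = function(e) e
  )
  if (!isTRUE(ok)) stop("cannot write PDB to ", path, ": ", conditionMessage(ok))
  invisible(path)
}

#' Atom selection expression
#'
#' A selection is a conjunction of optional filters over chain id, residue
#' number, atom name and molecule class; `NULL` filters match everything.
#' Selections compose with [sel_union()] and [sel_intersect()], and are
#' resolved against a topology with [select_atoms()].
#'
#' @param chain character vector of chain ids, or `NULL`.
#' @param resid integer vector of residue numbers, or `NULL`.
#' @param name character vector of atom names (e.g. `"C5'"`, `"CA"`, `"P"`),
#'   or `NULL`.
#' @param molecule `"protein"`, `"rna"`, or `NULL`.
#' @return object of class `md_selection`.
#' @export
selection <- function(chain = NULL, resid = NULL, name = NULL, molecule = NULL) {
  if (!is.null(molecule)) molecule <- match.arg(molecule, c("protein", "rna"))
  structure(
    list(op = "leaf", chain = chain, resid = resid, name = name,
         molecule = molecule),
    class = "md_selection"
  )
}

#' @rdname selection
#' @param a,b selections to combine.
#' @export
sel_union <- function(a, b) {
  structure(list(op = "union", a = a, b = b), class = "md_selection")
}

#' @rdname selection
#' @export
sel_intersect <- function(a, b) {
  structure(list(op = "intersect", a = a, b = b), class = "md_selection")
}

#' Resolve a selection against a topology
#'
#' @param topo an `md_topology` or `md_traj`.
#' @param sel an `md_selection`, or `NULL` for all atoms.
#' @return integer vector of matching atom indices in topology order; empty
#'   selections are legal and return `integer(0)`.
#' @export
select_atoms <- function(topo, sel = NULL) {
  if (inherits(topo, "md_traj")) topo <- topo$atoms
  if (is.null(sel)) return(seq_len(nrow(topo)))
  stopifnot(inherits(sel, "md_selection"))
  if (sel$op == "union") {
    return(sort(union(select_atoms(topo, sel$a), select_atoms(topo, sel$b))))
  }
  if (sel$op == "intersect") {
    return(sort(intersect(select_atoms(topo, sel$a), select_atoms(topo, sel$b))))
  }
  keep <- rep(TRUE, nrow(topo))
  if (!is.null(sel$chain)) keep <- keep & topo$chain %in% sel$chain
  if (!is.null(sel$resid)) keep <- keep & topo$resid %in% sel$resid
  if (!is.null(sel$name)) keep <- keep & topo$name %in% sel$name
  if (!is.null(sel$molecule)) {
    cc <- chain_class(topo)
    keep <- keep & topo$chain %in% names(cc)[cc == sel$molecule]
  }
  which(keep)
}
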