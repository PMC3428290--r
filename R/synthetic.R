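# Deterministic, seeded generators for idealized duplex structures and
# trajectories. These are deliberately coarse models -- only the atoms the
# analysis layer touches are emitted (P, C5', base heavy-atom proxies,
# protein backbone + side-chain proxies), with standard PDB naming so that
# selections and the contact census behave exactly as on real files. They
# are not stereochemically valid RNA and are not simulation input.

# Base heavy-atom proxies (5 per base, subsets of the full base tables so
# base-COM logic and the donor/acceptor tables both apply).
.SYN_BASE_ATOMS <- list(
  A = c("N9", "C8", "N7", "C6", "N6"),
  G = c("N9", "C8", "N7", "C6", "O6"),
  C = c("N1", "C2", "O2", "C4", "N4"),
  U = c("N1", "C2", "O2", "C4", "O4")
)

.COMPLEMENT <- c(A = "U", U = "A", G = "C", C = "G")

#' Specification of an idealized RNA duplex
#'
#' Defaults describe the study system: a 13-bp AU-rich duplex (an mRNA
#' AU-rich-element fragment paired with a microRNA) on an A-form-like
#' helix. Nucleotides are numbered continuously 1..2n: strand chain A
#' (mRNA-like) is 1..n in 5'->3' order, strand chain B (miRNA-like) is
#' n+1..2n in 5'->3' order, so pair k joins A:k with B:(2n+1-k) and the
#' terminal pair at the mRNA 3' end / miRNA 5' end is pair n.
#'
#' @param n_bp number of base pairs (default 13).
#' @param sequence strand-A sequence 5'->3' (length `n_bp`); strand B is
#'   its reverse complement.
#' @param rise helical rise in Angstrom per base pair (default 2.81,
#'   A-form-like).
#' @param twist helical twist in degrees per base pair (default 32.7).
#' @param d0 base-COM separation of a closed pair in Angstrom
#'   (default 5.5, matching the 5-6 A intact-pair range).
#' @return list of class `duplex_spec`.
#' @export
duplex_spec <- function(n_bp = 13, sequence = NULL, rise = 2.81,
                        twist = 32.7, d0 = 5.5) {
  if (n_bp < 2) stop("a duplex needs at least 2 base pairs")
  if (is.null(sequence)) {
    sequence <- paste(
      rep(c("U", "A", "U", "U", "A", "U", "U", "U", "A", "U", "G", "C", "A"),
        length.out = n_bp
      ),
      collapse = ""
    )
  }
  bases <- strsplit(toupper(sequence), "")[[1]]
  if (length(bases) != n_bp) stop("sequence length must equal n_bp")
  if (!all(bases %in% names(.COMPLEMENT))) {
    stop("sequence may contain only A, U, G, C")
  }
  structure(
    list(
      n_bp = n_bp, seq1 = bases,
      seq2 = rev(unname(.COMPLEMENT[bases])), # chain B, 5'->3'
      rise = rise, twist = twist, d0 = d0
    ),
    class = "duplex_spec"
  )
}

# Place k atoms in a ring of radius `rad` in the plane spanned by (e1, e2),
# shifted so their mass-weighted COM is exactly `center`.
.cluster_at <- function(center, masses, e1, e2, rad = 1.2) {
  k <- length(masses)
  if (k == 1) return(matrix(center, 1, 3))
  ang <- 2 * pi * (seq_len(k) - 1) / k
  raw <- outer(cos(ang) * rad, e1) + outer(sin(ang) * rad, e2)
  raw <- sweep(raw, 2, colSums(raw * masses) / sum(masses))
  sweep(raw, 2, center, `+`)
}

#' Build an idealized duplex structure
#'
#' Two antiparallel strands on a regular helix. Each nucleotide carries a
#' backbone phosphorus (except at the 5' termini), a C5' atom, and a
#' 5-atom coarse base whose center of mass sits exactly `d0` from its
#' partner's. Chains are `"A"` (mRNA-like) and `"B"` (miRNA-like).
#'
#' @param spec a [duplex_spec()].
#' @return single-frame `md_traj`.
#' @export
make_duplex <- function(spec = duplex_spec()) {
  n <- spec$n_bp
  r_base <- spec$d0 / 2
  r_bb <- 9.4
  atoms <- list()
  coords <- list()
  serial <- 0L
  add_atom <- function(name, resname, resid, chain, xyz) {
    serial <<- serial + 1L
    atoms[[serial]] <<- data.frame(
      serial = serial, name = name, resname = resname, resid = resid,
      chain = chain, stringsAsFactors = FALSE
    )
    coords[[serial]] <<- xyz
  }

  for (strand in 1:2) {
    chain <- c("A", "B")[strand]
    seqs <- if (strand == 1) spec$seq1 else spec$seq2
    for (s in seq_len(n)) { # s = position along the strand, 5'->3'
      k <- if (strand == 1) s else n + 1 - s # pair index
      resid <- if (strand == 1) s else n + s
      base <- seqs[s]
      th <- (k - 1) * spec$twist * pi / 180
      z <- (k - 1) * spec$rise
      u <- c(cos(th), sin(th), 0) * (if (strand == 1) 1 else -1)
      v <- c(-sin(th), cos(th), 0)
      center <- r_base * u + c(0, 0, z)

      # phosphate bridges to the previous nucleotide: absent at 5' termini
      if (s > 1) {
        zp <- z + (if (strand == 1) -spec$rise / 2 else spec$rise / 2)
        thp <- th + (if (strand == 1) 1 else -1) * 8 * pi / 180
        up <- c(cos(thp), sin(thp), 0) * (if (strand == 1) 1 else -1)
        add_atom("P", base, resid, chain, (r_bb + 0.6) * up + c(0, 0, zp))
      }
      thc <- th + (if (strand == 1) 1 else -1) * 15 * pi / 180
      uc <- c(cos(thc), sin(thc), 0) * (if (strand == 1) 1 else -1)
      add_atom("C5'", base, resid, chain, r_bb * uc + c(0, 0, z))

      bnames <- .SYN_BASE_ATOMS[[base]]
      bmass <- element_mass(.element_from_name(bnames))
      # cluster extends along the pair axis (u) so the closed duplex has
      # inter-strand heavy atoms within native-contact range
      bxyz <- .cluster_at(center, bmass, u, v, rad = 1.5)
      for (a in seq_along(bnames)) {
        add_atom(bnames[a], base, resid, chain, bxyz[a, ])
      }
    }
  }
  topo <- topology(do.call(rbind, atoms))
  xyz <- do.call(rbind, coords)
  trajectory(topo, xyz, dt = 10)
}

#' Specification of coarse protein residues anchored to a duplex
#'
#' Each row places one residue so that the center of mass of its relevant
#' group sits at a stated distance from an anchor point on the duplex:
#' the anchor nucleotide's base COM (`target = "base"`, used by the
#' hydrophobic and hydrogen-bond censuses) or its backbone phosphorus
#' (`target = "P"`; for Arg/Lys the charged group is centred there, the
#' geometry probed by the electrostatic census).
#'
#' @param residues data.frame with columns `resname`, `resid`,
#'   `anchor_chain`, `anchor_resid`, `target` (`"base"` or `"P"`),
#'   `offset` (Angstrom, > 0).
#' @param chain chain id for the placed residues (default `"K"`).
#' @return list of class `domain_spec`.
#' @export
domain_spec <- function(residues, chain = "K") {
  req <- c("resname", "resid", "anchor_chain", "anchor_resid", "target", "offset")
  stopifnot(all(req %in% names(residues)))
  if (any(residues$offset <= 0)) stop("offsets must be positive")
  if (!all(residues$target %in% c("base", "P"))) {
    stop("target must be 'base' or 'P'")
  }
  structure(
    list(residues = as.data.frame(residues), chain = chain),
    class = "domain_spec"
  )
}

#' Place coarse protein residues around a duplex
#'
#' Residues are built from backbone atoms (N, CA, C, O) plus the standard
#' side-chain heavy atoms for their type, positioned radially outward from
#' the duplex centroid through the anchor point. The relevant group COM
#' (side chain, charged group, or CA for glycine) lands exactly at the
#' requested offset. Placements closer than 1 Angstrom to any existing
#' atom are an error.
#'
#' @param spec a [domain_spec()].
#' @param duplex a single-frame `md_traj` from [make_duplex()].
#' @return merged single-frame `md_traj` (duplex + placed residues).
#' @export
make_protein_patch <- function(spec, duplex) {
  topo <- duplex$atoms
  xyz <- frame_coords(duplex, 1)
  centroid <- colMeans(xyz)
  new_atoms <- list()
  new_xyz <- list()
  serial <- max(topo$serial)

  for (i in seq_len(nrow(spec$residues))) {
    r <- spec$residues[i, ]
    resname <- toupper(r$resname)
    if (r$target == "P") {
      aidx <- .res_atoms(topo, r$anchor_chain, r$anchor_resid, "P")
      if (length(aidx) == 0) {
        stop("anchor nucleotide ", r$anchor_chain, r$anchor_resid,
          " has no P atom")
      }
      anchor <- xyz[aidx, ]
    } else {
      aidx <- .base_atoms(topo, r$anchor_chain, r$anchor_resid)
      if (length(aidx) == 0) {
        stop("anchor nucleotide ", r$anchor_chain, r$anchor_resid,
          " not found")
      }
      anchor <- center_of_mass(xyz[aidx, , drop = FALSE], topo$mass[aidx])
    }
    dir <- anchor - centroid
    dir <- dir / sqrt(sum(dir^2))
    e1 <- c(-dir[2], dir[1], 0)
    if (sum(e1^2) < 1e-8) e1 <- c(1, 0, 0)
    e1 <- e1 / sqrt(sum(e1^2))
    e2 <- c(
      dir[2] * e1[3] - dir[3] * e1[2],
      dir[3] * e1[1] - dir[1] * e1[3],
      dir[1] * e1[2] - dir[2] * e1[1]
    )
    target <- anchor + r$offset * dir

    sc_names <- .SIDECHAIN_ATOMS[[resname]]
    if (is.null(sc_names)) stop("unsupported residue type: ", resname)
    grp_names <- if (r$target == "P" && resname %in% names(.CHARGED_GROUP)) {
      .CHARGED_GROUP[[resname]]
    } else {
      sc_names
    }

    place <- function(names, center, rad) {
      if (length(names) == 0) return(NULL)
      m <- element_mass(.element_from_name(names))
      p <- .cluster_at(center, m, e1, e2, rad)
      rownames(p) <- names
      p
    }
    pos <- list()
    if (length(sc_names) == 0) {
      # glycine: CA is the side-chain proxy, so it takes the target point
      pos$bb <- rbind(
        CA = target,
        N = target + 1.6 * dir + 0.4 * e1,
        C = target + 2.2 * dir - 0.4 * e1,
        O = target + 3.0 * dir
      )
    } else {
      grp <- place(grp_names, target, rad = 0.8)
      rest_names <- setdiff(sc_names, grp_names)
      rest <- place(rest_names, target + 1.6 * dir, rad = 0.8)
      bb_base <- target + (1.6 * (length(rest_names) > 0) + 1.9) * dir
      bb <- rbind(
        CA = bb_base,
        N = bb_base + 1.2 * dir + 0.5 * e1,
        C = bb_base + 1.2 * dir - 0.5 * e1,
        O = bb_base + 2.0 * dir
      )
      pos <- list(grp = grp, rest = rest, bb = bb)
    }
    res_xyz <- do.call(rbind, pos[!vapply(pos, is.null, logical(1))])

    existing <- rbind(xyz, do.call(rbind, c(list(matrix(0, 0, 3)), new_xyz)))
    for (a in seq_len(nrow(res_xyz))) {
      dmin <- min(sqrt(rowSums(sweep(existing, 2, res_xyz[a, ])^2)))
      if (dmin < 1) {
        stop(
          "placement clash: atom ", rownames(res_xyz)[a], " of ", resname,
          " ", r$resid, " within 1 A of an existing atom"
        )
      }
    }
    for (a in seq_len(nrow(res_xyz))) {
      serial <- serial + 1L
      new_atoms[[length(new_atoms) + 1]] <- data.frame(
        serial = serial, name = rownames(res_xyz)[a], resname = resname,
        resid = r$resid, chain = spec$chain, stringsAsFactors = FALSE
      )
      new_xyz[[length(new_xyz) + 1]] <- res_xyz[a, ]
    }
  }

  all_atoms <- rbind(
    topo[, c("serial", "name", "resname", "resid", "chain")],
    do.call(rbind, new_atoms)
  )
  all_xyz <- rbind(xyz, do.call(rbind, new_xyz))
  trajectory(topology(all_atoms), all_xyz, dt = duplex$dt)
}

#' Motion specification for a synthetic trajectory
#'
#' @param n_frames number of frames.
#' @param dt sampling interval in ps (default 10).
#' @param jitter_sigma per-axis isotropic Gaussian positional noise in
#'   Angstrom (default 0).
#' @param opening list of opening events, each a list with `pair` (pair
#'   index), `extra` (target extra separation in Angstrom) and `tau_ns`
#'   (time constant); see [default_opening_schedule()].
#' @param rigid_drift optional list with `rot_z_deg` (rotation increment
#'   about the z axis per frame, degrees) and/or `trans` (translation per
#'   frame, length-3 Angstrom) applied cumulatively to whole frames.
#' @param seed RNG seed; a fixed seed makes the generator byte-identical.
#' @return list of class `motion_spec`.
#' @export
motion_spec <- function(n_frames, dt = 10, jitter_sigma = 0, opening = NULL,
                        rigid_drift = NULL, seed = 1) {
  stopifnot(n_frames >= 1, dt > 0, jitter_sigma >= 0)
  for (op in opening) {
    stopifnot(op$tau_ns > 0, op$extra >= 0)
  }
  structure(
    list(
      n_frames = as.integer(n_frames), dt = dt, jitter_sigma = jitter_sigma,
      opening = opening, rigid_drift = rigid_drift, seed = seed
    ),
    class = "motion_spec"
  )
}

#' Terminally ordered opening schedule of the study system
#'
#' Emulates the opening of the three pairs at the mRNA 3' end / microRNA
#' 5' end of a 13-bp duplex: from a closed baseline of ~5.5 A, the
#' terminal pair gains 12 A (to ~17.5 A), the next 10.5 A (to ~16 A) and
#' the third 6.5 A (to ~12 A), with time constants increasing inward so
#' the strand unzips terminal-first with an overall time constant of
#' ~5 ns.
#'
#' @param n_bp duplex length the schedule refers to (default 13).
#' @return list of opening events for [motion_spec()].
#' @export
default_opening_schedule <- function(n_bp = 13) {
  list(
    list(pair = n_bp, extra = 12, tau_ns = 4.96),
    list(pair = n_bp - 1, extra = 10.5, tau_ns = 6.5),
    list(pair = n_bp - 2, extra = 6.5, tau_ns = 8.5)
  )
}

#' Generate a trajectory from a structure and a motion specification
#'
#' Frame k at time `t_k = k * dt` is the input structure plus (in order):
#' programmed opening displacement of the strand-2 nucleotide of each
#' opening pair along its pair axis by `extra * (1 - exp(-t_k / tau))`,
#' isotropic Gaussian jitter, and optional cumulative rigid drift. The
#' output is a pure function of (structure, spec): identical seeds give
#' identical coordinates.
#'
#' @param structure single-frame `md_traj` (e.g. [make_duplex()] output,
#'   optionally with protein patches).
#' @param motion a [motion_spec()].
#' @param pairs a [pair_map()] for resolving opening pair indices;
#'   inferred from the RNA chains when `NULL`.
#' @return `md_traj` with `motion$n_frames` frames.
#' @export
make_trajectory <- function(structure, motion, pairs = NULL) {
  topo <- structure$atoms
  base_xyz <- frame_coords(structure, 1)
  nf <- motion$n_frames
  tt <- (seq_len(nf)) * motion$dt # ps; frame 1 at t = dt

  open_moves <- list()
  if (length(motion$opening) > 0) {
    if (is.null(pairs)) pairs <- pair_map(topo)
    for (op in motion$opening) {
      row <- pairs[pairs$pair == op$pair, ]
      if (nrow(row) != 1) stop("opening refers to unknown pair ", op$pair)
      i1 <- .base_atoms(topo, row$chain1, row$resid1)
      i2 <- .base_atoms(topo, row$chain2, row$resid2)
      c1 <- center_of_mass(base_xyz[i1, , drop = FALSE], topo$mass[i1])
      c2 <- center_of_mass(base_xyz[i2, , drop = FALSE], topo$mass[i2])
      axis <- (c2 - c1) / sqrt(sum((c2 - c1)^2))
      moved <- which(topo$chain == row$chain2 & topo$resid == row$resid2)
      open_moves[[length(open_moves) + 1]] <- list(
        atoms = moved, axis = axis,
        extra = op$extra, tau_ps = op$tau_ns * 1000
      )
    }
  }

  old_seed <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  }
  on.exit(
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv())
  )
  set.seed(motion$seed)

  xyz <- array(0, dim = c(nrow(topo), 3, nf))
  for (f in seq_len(nf)) {
    fr <- base_xyz
    for (mv in open_moves) {
      disp <- mv$extra * (1 - exp(-tt[f] / mv$tau_ps))
      fr[mv$atoms, ] <- fr[mv$atoms, ] +
        matrix(mv$axis * disp, length(mv$atoms), 3, byrow = TRUE)
    }
    if (motion$jitter_sigma > 0) {
      fr <- fr + matrix(
        stats::rnorm(length(fr), sd = motion$jitter_sigma),
        nrow(fr), 3
      )
    }
    if (!is.null(motion$rigid_drift)) {
      rd <- motion$rigid_drift
      if (!is.null(rd$rot_z_deg)) {
        a <- f * rd$rot_z_deg * pi / 180
        rot <- matrix(
          c(cos(a), sin(a), 0, -sin(a), cos(a), 0, 0, 0, 1), 3, 3
        )
        ctr <- colMeans(base_xyz)
        fr <- sweep(sweep(fr, 2, ctr) %*% rot, 2, ctr, `+`)
      }
      if (!is.null(rd$trans)) {
        fr <- sweep(fr, 2, f * rd$trans, `+`)
      }
    }
    xyz[, , f] <- fr
  }
  trajectory(topo, xyz, dt = motion$dt)
}

#' Generate a synthetic Qb decay trace
#'
#' `y_k = A * exp(-t_k / tau) + B + noise`, sampled at `t_k = k * dt`.
#'
#' @param A amplitude (fraction).
#' @param tau_ns decay time constant in ns.
#' @param B offset (fraction).
#' @param n number of samples (>= 4).
#' @param dt_ps sampling interval in ps (default 10).
#' @param sigma Gaussian noise sd (default 0).
#' @param seed RNG seed (used only when `sigma > 0`).
#' @return `qb_series` data.frame (`time_ps`, `qb`).
#' @export
make_qb_trace <- function(A, tau_ns, B, n, dt_ps = 10, sigma = 0, seed = 1) {
  stopifnot(n >= 4, tau_ns > 0)
  t_ps <- seq_len(n) * dt_ps
  y <- A * exp(-t_ps / (tau_ns * 1000)) + B
  if (sigma > 0) {
    old_seed <- if (exists(".Random.seed", globalenv())) {
      get(".Random.seed", globalenv())
    }
    on.exit(
      if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv())
    )
    set.seed(seed)
    y <- y + stats::rnorm(n, sd = sigma)
  }
  structure(
    data.frame(time_ps = t_ps, qb = y),
    class = c("qb_series", "data.frame")
  )
}

#' Write a synthetic system with a provenance sidecar
#'
#' Writes the trajectory as a multi-model PDB plus `<path>.json` recording
#' the generator specifications and seed, so any emitted file can be
#' regenerated exactly.
#'
#' @param traj an `md_traj`.
#' @param path output PDB path.
#' @param provenance named list (specs, seed, notes) stored as JSON.
#' @return `path`, invisibly.
#' @export
write_system <- function(traj, path, provenance = list()) {
  write_pdb(traj, path)
  provenance$dt_ps <- traj$dt
  provenance$n_frames <- n_frames(traj)
  jsonlite::write_json(
    provenance, paste0(path, ".json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE, force = TRUE
  )
  invisible(path)
}
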