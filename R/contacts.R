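# Three-class residue-nucleotide interaction census with per-frame presence
# and trajectory occupancy ("population"). Classes:
#   hydrophobic   - side-chain COM vs base COM, distance < 6.5 A
#   electrostatic - charged-group COM vs backbone phosphate P, distance < 11 A
#   hbond         - heavy donor-acceptor pairs <= 3.5 A (+ angle when H present)
# Distance comparisons at the hydrophobic/electrostatic cutoffs are strict
# (<); occupancy filtering is strict (>), following "higher than 50%".

#' Contact census configuration
#'
#' @param hydrophobic_cutoff side-chain-COM / base-COM cutoff in Angstrom
#'   (default 6.5).
#' @param electrostatic_cutoff charged-group-COM / phosphate-P cutoff in
#'   Angstrom (default 11).
#' @param hbond_da_cutoff heavy donor-acceptor distance cutoff in Angstrom
#'   (default 3.5).
#' @param hbond_angle_min minimum donor-H-acceptor angle in degrees,
#'   applied only when an attached hydrogen is present (default 135).
#' @param population_threshold occupancy threshold for
#'   [filter_by_population()] (default 0.5; strictly greater-than).
#' @param hydrophobic_residues residue names counted as hydrophobic.
#' @param include_his count histidine among the positively charged residues
#'   (default `FALSE`; the canonical set is Arg + Lys).
#' @return list of class `contact_config`.
#' @export
contact_config <- function(hydrophobic_cutoff = 6.5,
                           electrostatic_cutoff = 11,
                           hbond_da_cutoff = 3.5,
                           hbond_angle_min = 135,
                           population_threshold = 0.5,
                           hydrophobic_residues = .HYDROPHOBIC_RESNAMES,
                           include_his = FALSE) {
  stopifnot(
    hydrophobic_cutoff > 0, electrostatic_cutoff > 0, hbond_da_cutoff > 0,
    population_threshold >= 0, population_threshold <= 1
  )
  structure(
    list(
      hydrophobic_cutoff = hydrophobic_cutoff,
      electrostatic_cutoff = electrostatic_cutoff,
      hbond_da_cutoff = hbond_da_cutoff,
      hbond_angle_min = hbond_angle_min,
      population_threshold = population_threshold,
      hydrophobic_residues = toupper(hydrophobic_residues),
      charged_residues = c("ARG", "LYS", if (include_his) "HIS")
    ),
    class = "contact_config"
  )
}

# Residue table: one row per residue with molecule class.
.residues <- function(topo) {
  cc <- chain_class(topo)
  key <- paste(topo$chain, topo$resid)
  first <- !duplicated(key)
  data.frame(
    chain = topo$chain[first], resid = topo$resid[first],
    resname = topo$resname[first],
    molecule = unname(cc[topo$chain[first]]),
    stringsAsFactors = FALSE
  )
}

# Atom indices of one residue, optionally restricted to a name set.
.res_atoms <- function(topo, chain, resid, names = NULL) {
  idx <- which(topo$chain == chain & topo$resid == resid)
  if (!is.null(names)) idx <- idx[topo$name[idx] %in% names]
  idx
}

# Side-chain atom indices: everything off the backbone; Gly falls back to CA.
.sidechain_atoms <- function(topo, chain, resid) {
  idx <- .res_atoms(topo, chain, resid)
  sc <- idx[!topo$name[idx] %in% .PROTEIN_BACKBONE &
    !startsWith(topo$name[idx], "H")]
  if (length(sc) == 0) sc <- idx[topo$name[idx] == "CA"]
  sc
}

# Base-moiety atom indices of a nucleotide.
.base_atoms <- function(topo, chain, resid) {
  base <- base_identity(topo$resname[.res_atoms(topo, chain, resid)][1])
  .res_atoms(topo, chain, resid, .BASE_ATOMS[[base]])
}

# Per-frame COM trace of an atom group: n_frames x 3 matrix.
.com_trace <- function(traj, idx) {
  m <- traj$atoms$mass[idx]
  t(vapply(
    seq_len(n_frames(traj)),
    function(f) center_of_mass(matrix(traj$xyz[idx, , f], ncol = 3), m),
    numeric(3)
  ))
}

# Census over (protein group, rna group) pairs given per-frame COM traces.
# Returns the standard contact record table with a `present` list column.
.census_from_traces <- function(class, prot, rna, prot_traces, rna_traces,
                                cutoff, nf, strict = TRUE) {
  out <- list()
  for (i in seq_len(nrow(prot))) {
    for (j in seq_len(nrow(rna))) {
      d <- sqrt(rowSums((prot_traces[[i]] - rna_traces[[j]])^2))
      present <- if (strict) d < cutoff else d <= cutoff
      if (!any(present)) next
      out[[length(out) + 1]] <- .contact_record(
        class, prot[i, ], rna[j, ], present
      )
    }
  }
  .bind_contacts(out, nf)
}

.contact_record <- function(class, prot_row, rna_row, present) {
  data.frame(
    class = class,
    protein_chain = prot_row$chain, protein_resid = prot_row$resid,
    protein_resname = prot_row$resname,
    rna_chain = rna_row$chain, rna_resid = rna_row$resid,
    base = base_identity(rna_row$resname),
    population = mean(present),
    present = I(list(present)),
    stringsAsFactors = FALSE
  )
}

.bind_contacts <- function(records, nf) {
  out <- if (length(records) == 0) {
    data.frame(
      class = character(0), protein_chain = character(0),
      protein_resid = integer(0), protein_resname = character(0),
      rna_chain = character(0), rna_resid = integer(0),
      base = character(0), population = numeric(0),
      present = I(list()), stringsAsFactors = FALSE
    )
  } else {
    do.call(rbind, records)
  }
  out$n_frames <- rep(nf, nrow(out))
  class(out) <- c("contact_census", "data.frame")
  out
}

.check_protein_rna <- function(traj) {
  cc <- chain_class(traj$atoms)
  if (!any(cc == "protein") || !any(cc == "rna")) {
    stop("contact census needs at least one protein and one RNA chain")
  }
}

#' Hydrophobic contact census
#'
#' A hydrophobic residue and a nucleotide are in contact in a frame when
#' the center of mass of the residue's side chain lies closer than the
#' cutoff to the center of mass of the nucleotide's base moiety (ring heavy
#' atoms plus exocyclic N/O; no sugar or phosphate). Only pairs present in
#' at least one frame are returned.
#'
#' @param traj an `md_traj` with at least one protein and one RNA chain.
#' @param cfg a [contact_config()].
#' @return `contact_census` data.frame (one row per residue-nucleotide
#'   pair) with columns `class`, `protein_chain`, `protein_resid`,
#'   `protein_resname`, `rna_chain`, `rna_resid`, `base`, `population`,
#'   `present` (list of per-frame logicals), `n_frames`.
#' @export
hydrophobic_contacts <- function(traj, cfg = contact_config()) {
  .check_protein_rna(traj)
  res <- .residues(traj$atoms)
  prot <- res[res$molecule == "protein" &
    res$resname %in% cfg$hydrophobic_residues, ]
  rna <- res[res$molecule == "rna", ]
  pt <- lapply(seq_len(nrow(prot)), function(i) {
    .com_trace(traj, .sidechain_atoms(traj$atoms, prot$chain[i], prot$resid[i]))
  })
  rt <- lapply(seq_len(nrow(rna)), function(j) {
    .com_trace(traj, .base_atoms(traj$atoms, rna$chain[j], rna$resid[j]))
  })
  .census_from_traces(
    "hydrophobic", prot, rna, pt, rt,
    cfg$hydrophobic_cutoff, n_frames(traj)
  )
}

#' Electrostatic contact census
#'
#' A positively charged residue (Arg/Lys, optionally His) contacts a
#' nucleotide in a frame when the center of mass of its charged group
#' (guanidinium nitrogens for Arg, NZ for Lys) lies closer than the cutoff
#' to that nucleotide's backbone phosphorus. Nucleotides without a P atom
#' (5' termini) are skipped.
#'
#' @inheritParams hydrophobic_contacts
#' @return `contact_census` data.frame; see [hydrophobic_contacts()].
#' @export
electrostatic_contacts <- function(traj, cfg = contact_config()) {
  .check_protein_rna(traj)
  res <- .residues(traj$atoms)
  prot <- res[res$molecule == "protein" & res$resname %in% cfg$charged_residues, ]
  rna <- res[res$molecule == "rna", ]
  has_p <- vapply(seq_len(nrow(rna)), function(j) {
    length(.res_atoms(traj$atoms, rna$chain[j], rna$resid[j], "P")) == 1
  }, logical(1))
  rna <- rna[has_p, ]
  pt <- lapply(seq_len(nrow(prot)), function(i) {
    grp <- .res_atoms(
      traj$atoms, prot$chain[i], prot$resid[i],
      .CHARGED_GROUP[[prot$resname[i]]]
    )
    if (length(grp) == 0) {
      grp <- .sidechain_atoms(traj$atoms, prot$chain[i], prot$resid[i])
    }
    .com_trace(traj, grp)
  })
  rt <- lapply(seq_len(nrow(rna)), function(j) {
    .com_trace(traj, .res_atoms(traj$atoms, rna$chain[j], rna$resid[j], "P"))
  })
  .census_from_traces(
    "electrostatic", prot, rna, pt, rt,
    cfg$electrostatic_cutoff, n_frames(traj)
  )
}

#' Hydrogen-bond census
#'
#' Donor and acceptor heavy atoms are taken from built-in per-residue
#' tables (protein backbone N/O plus polar side-chain atoms; base exocyclic
#' N/O plus ribose/phosphate oxygens). A residue-nucleotide pair is bonded
#' in a frame when any (donor, acceptor) atom pair across the interface is
#' within the distance cutoff and, if the topology carries a hydrogen
#' attached to the donor (within 1.2 A), the D-H...A angle exceeds the
#' angular minimum. Heavy-atom-only topologies use the distance criterion
#' alone.
#'
#' @inheritParams hydrophobic_contacts
#' @return `contact_census` data.frame; see [hydrophobic_contacts()].
#' @export
hydrogen_bonds <- function(traj, cfg = contact_config()) {
  .check_protein_rna(traj)
  topo <- traj$atoms
  res <- .residues(topo)
  prot <- res[res$molecule == "protein", ]
  rna <- res[res$molecule == "rna", ]
  nf <- n_frames(traj)

  prot_da <- lapply(seq_len(nrow(prot)), function(i) {
    idx <- .res_atoms(topo, prot$chain[i], prot$resid[i])
    nm <- topo$name[idx]
    list(
      d = idx[nm %in% c(.PROTEIN_DONORS$.backbone,
                        .PROTEIN_DONORS[[prot$resname[i]]])],
      a = idx[nm %in% c(.PROTEIN_ACCEPTORS$.backbone,
                        .PROTEIN_ACCEPTORS[[prot$resname[i]]])]
    )
  })
  rna_da <- lapply(seq_len(nrow(rna)), function(j) {
    idx <- .res_atoms(topo, rna$chain[j], rna$resid[j])
    nm <- topo$name[idx]
    base <- base_identity(rna$resname[j])
    list(
      d = idx[nm %in% c(.RNA_DONORS$.sugar, .RNA_DONORS[[base]])],
      a = idx[nm %in% c(.RNA_ACCEPTORS$.backbone, .RNA_ACCEPTORS[[base]])]
    )
  })
  h_idx <- which(topo$element == "H")

  records <- list()
  for (i in seq_len(nrow(prot))) {
    for (j in seq_len(nrow(rna))) {
      da <- rbind(
        expand.grid(d = prot_da[[i]]$d, a = rna_da[[j]]$a),
        expand.grid(d = rna_da[[j]]$d, a = prot_da[[i]]$a)
      )
      if (nrow(da) == 0) next
      present <- vapply(seq_len(nf), function(f) {
        xyz <- traj$xyz[, , f]
        dd <- sqrt(rowSums((xyz[da$d, , drop = FALSE] -
          xyz[da$a, , drop = FALSE])^2))
        ok <- dd <= cfg$hbond_da_cutoff
        if (!any(ok) || length(h_idx) == 0) return(any(ok))
        any(vapply(which(ok), function(k) {
          .hbond_angle_ok(xyz, da$d[k], da$a[k], h_idx, cfg$hbond_angle_min)
        }, logical(1)))
      }, logical(1))
      if (!any(present)) next
      records[[length(records) + 1]] <-
        .contact_record("hbond", prot[i, ], rna[j, ], present)
    }
  }
  .bind_contacts(records, nf)
}

# Angle criterion for one candidate D...A pair: satisfied vacuously when the
# donor has no attached hydrogen, else some attached H must give
# angle(D-H-A) >= min.
.hbond_angle_ok <- function(xyz, d, a, h_idx, angle_min) {
  dh <- sqrt(rowSums((xyz[h_idx, , drop = FALSE] -
    matrix(xyz[d, ], length(h_idx), 3, byrow = TRUE))^2))
  att <- h_idx[dh <= 1.2]
  if (length(att) == 0) return(TRUE)
  any(vapply(att, function(h) {
    v1 <- xyz[d, ] - xyz[h, ]
    v2 <- xyz[a, ] - xyz[h, ]
    ang <- acos(max(-1, min(1, sum(v1 * v2) /
      sqrt(sum(v1^2) * sum(v2^2))))) * 180 / pi
    ang >= angle_min
  }, logical(1)))
}

#' Filter a contact census by occupancy
#'
#' Keeps records whose population is strictly greater than the threshold
#' ("higher than 50%"), sorted by descending population and then partner
#' order.
#'
#' @param contacts a `contact_census`.
#' @param threshold occupancy threshold in `[0, 1]` (default 0.5).
#' @return filtered, sorted `contact_census`.
#' @export
filter_by_population <- function(contacts, threshold = 0.5) {
  keep <- contacts[contacts$population > threshold, ]
  ord <- order(-keep$population, keep$protein_chain, keep$protein_resid,
    keep$rna_chain, keep$rna_resid
  )
  out <- keep[ord, ]
  rownames(out) <- NULL
  class(out) <- c("contact_census", "data.frame")
  out
}

#' Compare two contact censuses
#'
#' Outer join on (class, protein partner, RNA partner): each record is
#' flagged `common` when present in both ensembles, else `a_only` /
#' `b_only`, with the occupancy from each ensemble (0 where absent).
#'
#' @param a,b `contact_census` tables (e.g. two binding modes).
#' @return data.frame with partner columns plus `population_a`,
#'   `population_b`, `status`.
#' @export
compare_censuses <- function(a, b) {
  keys <- c(
    "class", "protein_chain", "protein_resid", "protein_resname",
    "rna_chain", "rna_resid", "base"
  )
  ka <- a[, c(keys, "population")]
  kb <- b[, c(keys, "population")]
  names(ka)[names(ka) == "population"] <- "population_a"
  names(kb)[names(kb) == "population"] <- "population_b"
  m <- merge(ka, kb, by = keys, all = TRUE)
  m$population_a[is.na(m$population_a)] <- 0
  m$population_b[is.na(m$population_b)] <- 0
  m$status <- ifelse(m$population_a > 0 & m$population_b > 0, "common",
    ifelse(m$population_a > 0, "a_only", "b_only")
  )
  m[order(m$class, m$protein_chain, m$protein_resid, m$rna_resid), ,
    drop = FALSE
  ]
}
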