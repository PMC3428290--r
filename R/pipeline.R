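# Full-pipeline orchestration: one configuration drives superposition
# descriptors, the contact census, base-pair traces, the free-energy
# landscape and native-contact kinetics, writing TSVs plus a JSON manifest
# that fully determines reproduction.

#' Load a pipeline configuration from YAML or JSON
#'
#' Format is auto-detected from the extension (`.yml`/`.yaml` vs
#' `.json`).
#'
#' @param path configuration file.
#' @return configuration list for [run_pipeline()].
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("no such config file: ", path)
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
}

.default_config <- function() {
  list(
    dt_ps = 10,
    rmsd_atom = "C5'",
    window = list(t_start = NULL, t_end = NULL),
    contacts = list(),
    landscape_bins = 8,
    kinetics = list(cutoff = 4.5, tolerance_factor = 1.2),
    opening = list(delta = 3, sustain = 50),
    stages = list(
      descriptors = TRUE, contacts = TRUE, basepairs = TRUE,
      landscape = TRUE, kinetics = TRUE
    ),
    outdir = "results",
    seed = 1
  )
}

.load_traj_input <- function(x, dt_ps) {
  if (inherits(x, "md_traj")) return(x)
  if (is.character(x)) {
    if (!file.exists(x)) stop("missing input file: ", x)
    return(read_pdb(x, dt = dt_ps))
  }
  stop("trajectory input must be a path or an md_traj")
}

#' Run the full analysis pipeline
#'
#' Executes, in order: RMSD/RMSF/Rg descriptors, the three-class contact
#' census with occupancy filtering, base-pair distance traces with opening
#' detection (plus the holo-vs-apo distance-difference landscape when a
#' second trajectory is given), the 2D RMSD x Rg free-energy landscape,
#' and Qb kinetics with the exponential fit. Stages are independently
#' skippable via `cfg$stages`. All outputs land under `cfg$outdir` with
#' fixed names, together with `manifest.json` recording inputs, parameter
#' values, package version, seed and per-stage status. The first hard
#' stage error still writes the manifest (naming the failed stage), then
#' propagates.
#'
#' @param cfg configuration list or path to a YAML/JSON file. Recognised
#'   fields: `trajectory` (path or `md_traj`, required), `apo_trajectory`
#'   (optional second system), `dt_ps`, `rmsd_atom`, `window`
#'   (`t_start`/`t_end`, ps), `contacts` (arguments to
#'   [contact_config()]), `pairs` (explicit pair table), `landscape_bins`,
#'   `kinetics` (`cutoff`, `tolerance_factor`), `opening` (`delta`,
#'   `sustain`), `stages`, `outdir`, `seed`.
#' @return manifest list, invisibly.
#' @export
run_pipeline <- function(cfg) {
  if (is.character(cfg)) cfg <- load_config(cfg)
  cfg <- utils::modifyList(.default_config(), cfg)
  dir.create(cfg$outdir, showWarnings = FALSE, recursive = TRUE)

  manifest <- list(
    package = "duplexmd",
    version = as.character(utils::packageVersion("duplexmd")),
    seed = cfg$seed,
    parameters = cfg[setdiff(names(cfg), c("trajectory", "apo_trajectory"))],
    inputs = list(
      trajectory = if (is.character(cfg$trajectory)) cfg$trajectory else "<in-memory>",
      apo_trajectory = if (is.character(cfg$apo_trajectory)) {
        cfg$apo_trajectory
      } else if (!is.null(cfg$apo_trajectory)) "<in-memory>"
    ),
    stages = list()
  )
  finish <- function(stage, status, outputs = character(0)) {
    manifest$stages[[stage]] <<- list(status = status, outputs = outputs)
  }
  fail <- function(stage, err) {
    finish(stage, paste0("failed: ", conditionMessage(err)))
    .write_manifest(manifest, cfg$outdir)
    stop("pipeline stage '", stage, "' failed: ", conditionMessage(err),
      call. = FALSE
    )
  }
  prov <- function(...) {
    c(
      paste0("duplexmd ", manifest$version, "; seed=", cfg$seed),
      ...
    )
  }
  out <- function(name) file.path(cfg$outdir, name)

  traj <- tryCatch(
    {
      x <- .load_traj_input(cfg$trajectory, cfg$dt_ps)
      time_window(x, cfg$window$t_start, cfg$window$t_end)
    },
    error = function(e) fail("input", e)
  )
  finish("input", "ok")
  apo <- NULL
  if (!is.null(cfg$apo_trajectory)) {
    apo <- tryCatch(
      {
        x <- .load_traj_input(cfg$apo_trajectory, cfg$dt_ps)
        time_window(x, cfg$window$t_start, cfg$window$t_end)
      },
      error = function(e) fail("input", e)
    )
  }

  rna_sel <- selection(name = cfg$rmsd_atom, molecule = "rna")
  rmsd_tab <- NULL
  rg_tab <- NULL

  if (isTRUE(cfg$stages$descriptors)) {
    res <- tryCatch(
      {
        avg <- average_structure(traj, rna_sel)
        rmsd_tab <- rmsd_series(traj, avg, rna_sel)
        rg_tab <- rg_series(traj, selection(molecule = "rna"))
        fl <- rmsf(traj, rna_sel)
        write_tsv(
          data.frame(time_ps = rmsd_tab$time_ps, rmsd_A = rmsd_tab$value),
          out("rmsd.tsv"),
          prov(paste0("rmsd vs average structure; atom=", cfg$rmsd_atom))
        )
        write_tsv(
          data.frame(time_ps = rg_tab$time_ps, rg_A = rg_tab$value),
          out("rg.tsv"), prov("mass-weighted radius of gyration, RNA atoms")
        )
        write_tsv(fl, out("rmsf.tsv"),
          prov(paste0("rmsf about iterative mean; atom=", cfg$rmsd_atom))
        )
        c("rmsd.tsv", "rg.tsv", "rmsf.tsv")
      },
      error = function(e) fail("descriptors", e)
    )
    finish("descriptors", "ok", res)
  } else {
    finish("descriptors", "skipped")
  }

  if (isTRUE(cfg$stages$contacts)) {
    res <- tryCatch(
      {
        ccfg <- do.call(contact_config, cfg$contacts)
        census <- rbind(
          hydrogen_bonds(traj, ccfg),
          hydrophobic_contacts(traj, ccfg),
          electrostatic_contacts(traj, ccfg)
        )
        kept <- filter_by_population(census, ccfg$population_threshold)
        cuts <- paste0(
          "cutoffs: hydrophobic<", ccfg$hydrophobic_cutoff,
          "A electrostatic<", ccfg$electrostatic_cutoff,
          "A hbond<=", ccfg$hbond_da_cutoff, "A; population>",
          ccfg$population_threshold
        )
        write_tsv(census, out("contacts_all.tsv"), prov(cuts))
        write_tsv(kept, out("contacts_filtered.tsv"), prov(cuts))
        outs <- c("contacts_all.tsv", "contacts_filtered.tsv")
        if (!is.null(apo) && any(chain_class(apo$atoms) == "protein")) {
          census_apo <- rbind(
            hydrogen_bonds(apo, ccfg),
            hydrophobic_contacts(apo, ccfg),
            electrostatic_contacts(apo, ccfg)
          )
          cmp <- compare_censuses(
            filter_by_population(census, ccfg$population_threshold),
            filter_by_population(census_apo, ccfg$population_threshold)
          )
          write_tsv(cmp, out("contacts_compare.tsv"), prov(cuts))
          outs <- c(outs, "contacts_compare.tsv")
        }
        outs
      },
      error = function(e) fail("contacts", e)
    )
    finish("contacts", "ok", res)
  } else {
    finish("contacts", "skipped")
  }

  if (isTRUE(cfg$stages$basepairs)) {
    res <- tryCatch(
      {
        pm <- if (is.null(cfg$pairs)) {
          pair_map(traj)
        } else {
          pair_map(pairs = as.data.frame(cfg$pairs))
        }
        bp <- basepair_distances(traj, pm)
        rep_open <- detect_opening(bp,
          delta = cfg$opening$delta, sustain = cfg$opening$sustain
        )
        write_tsv(bp, out("basepairs.tsv"),
          prov("base-moiety COM distance per pair")
        )
        write_tsv(rep_open$pairs, out("opening.tsv"), prov(paste0(
          "opening: delta=", cfg$opening$delta, "A sustain=",
          cfg$opening$sustain, " frames; ordered=", rep_open$ordered
        )))
        outs <- c("basepairs.tsv", "opening.tsv")
        if (!is.null(apo)) {
          dd <- distance_difference_landscape(traj, apo, cfg$rmsd_atom)
          ddf <- data.frame(nucleotide = rownames(dd),
            as.data.frame(dd, check.names = FALSE))
          write_tsv(ddf, out("distance_difference.tsv"),
            prov(paste0("mean pairwise ", cfg$rmsd_atom,
              " distance, holo - apo"))
          )
          outs <- c(outs, "distance_difference.tsv")
        }
        outs
      },
      error = function(e) fail("basepairs", e)
    )
    finish("basepairs", "ok", res)
  } else {
    finish("basepairs", "skipped")
  }

  if (isTRUE(cfg$stages$landscape)) {
    res <- tryCatch(
      {
        if (is.null(rmsd_tab)) {
          avg <- average_structure(traj, rna_sel)
          rmsd_tab <- rmsd_series(traj, avg, rna_sel)
          rg_tab <- rg_series(traj, selection(molecule = "rna"))
        }
        ls <- energy_landscape(rmsd_tab, rg_tab, cfg$landscape_bins)
        write_tsv(landscape_table(ls), out("landscape.tsv"), prov(paste0(
          "G=-ln(P/Pmax) [kT]; ", cfg$landscape_bins, "x",
          cfg$landscape_bins, " bins over rmsd x rg"
        )))
        list(outs = "landscape.tsv", basin = ls$basin)
      },
      error = function(e) fail("landscape", e)
    )
    manifest$basin <- res$basin
    finish("landscape", "ok", res$outs)
  } else {
    finish("landscape", "skipped")
  }

  if (isTRUE(cfg$stages$kinetics)) {
    res <- tryCatch(
      {
        nat <- native_contacts(traj, cutoff = cfg$kinetics$cutoff)
        qb <- qb_series(traj, nat, cfg$kinetics$tolerance_factor)
        fit <- fit_exponential(qb)
        write_tsv(qb, out("qb.tsv"), prov(paste0(
          "native contacts: inter-strand heavy atoms <",
          cfg$kinetics$cutoff, "A in first frame; retention <=",
          cfg$kinetics$tolerance_factor, "x"
        )))
        jsonlite::write_json(
          list(
            A = fit$A, tau_ns = fit$tau, t_half_ns = fit$t_half, B = fit$B,
            rss = fit$rss, converged = fit$converged, n = fit$n
          ),
          out("qb_fit.json"),
          auto_unbox = TRUE, digits = NA
        )
        c("qb.tsv", "qb_fit.json")
      },
      error = function(e) fail("kinetics", e)
    )
    finish("kinetics", "ok", res)
  } else {
    finish("kinetics", "skipped")
  }

  .write_manifest(manifest, cfg$outdir)
  invisible(manifest)
}

.write_manifest <- function(manifest, outdir) {
  jsonlite::write_json(
    manifest, file.path(outdir, "manifest.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE, force = TRUE, null = "null"
  )
}
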