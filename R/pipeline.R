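# End-to-end orchestration: the per-system flexibility/confidence
# comparison table and the full complex analysis (distance map, RIN,
# per-ligand contact frequencies, cross-ligand matrix), with a manifest for
# reproducibility.

#' Run configuration for the full complex analysis
#'
#' @param ensemble a `flexrin_ensemble`, or a path to a multi-model PDB.
#' @param ligand_map optional named map from `HETATM` residue names to
#'   ligand labels (used when `ensemble` is a path).
#' @param dialect a [contact_dialect()].
#' @param stride frame stride for per-frame RINs.
#' @param tail_fraction trailing fraction for RMSD summaries.
#' @param targets ligand labels to analyse (default: all in the ensemble).
#' @param confidence_json optional path to a confidence JSON (for the
#'   PAE-vs-distance-map similarity stage).
#' @param seed integer seed recorded in the manifest and used by any
#'   stochastic stage.
#' @param out_dir output directory.
#' @return an object of class `run_config`.
#' @export
run_config <- function(ensemble, ligand_map = NULL,
                       dialect = contact_dialect(), stride = 1L,
                       tail_fraction = 0.1, targets = NULL,
                       confidence_json = NULL, seed = 1L, out_dir = NULL) {
  if (is.character(ensemble) && !file.exists(ensemble))
    stop("ensemble path does not exist: ", ensemble)
  if (!is.null(confidence_json) && !file.exists(confidence_json))
    stop("confidence file does not exist: ", confidence_json)
  cfg <- list(ensemble = ensemble, ligand_map = ligand_map,
              dialect = dialect, stride = as.integer(stride),
              tail_fraction = tail_fraction, targets = targets,
              confidence_json = confidence_json, seed = as.integer(seed),
              out_dir = out_dir)
  class(cfg) <- "run_config"
  cfg
}

resolve_ensemble <- function(x, ligand_map = NULL) {
  if (inherits(x, "flexrin_ensemble")) return(x)
  read_multimodel_pdb(x, ligand_labels = ligand_map)
}

#' Per-system comparison of ensemble flexibility with predicted confidence
#'
#' For each system (an ensemble plus a confidence profile) computes the
#' RMSF profile, the reverse-normalised confidence score, their Pearson
#' concordance, and the trailing-mean RMSD to the first frame -- one row
#' per system, in the shape of a flexibility-vs-confidence comparison
#' table.  A failing system is reported in its row's `error` column; the
#' batch continues.
#'
#' @param systems named list; each element a list with `ensemble` (a
#'   `flexrin_ensemble` or PDB path), and either `plddt` (a
#'   `residue_profile`) or nothing (the profile is then read from the first
#'   frame's B-factors).
#' @param tail_fraction trailing fraction for the RMSD summary.
#' @param out_dir optional directory; when given, writes `systems.csv`,
#'   `systems.json` and per-system `overlay_<label>.csv` (residue, RMSF,
#'   confidence score) for plotting.
#' @return list with `table` (data frame) and `overlays` (named list of
#'   data frames).
#' @export
run_system_comparison <- function(systems, tail_fraction = 0.1,
                                  out_dir = NULL) {
  stopifnot(length(systems) >= 1L)
  labels <- names(systems) %||% as.character(seq_along(systems))
  rows <- list(); overlays <- list()
  for (k in seq_along(systems)) {
    lab <- labels[k]
    res <- tryCatch({
      sys <- systems[[k]]
      ens <- resolve_ensemble(sys$ensemble)
      plddt <- sys$plddt %||% extract_plddt(get_frame(ens, 1L))
      fx <- rmsf(ens, selection = "calpha", do_superpose = TRUE)
      if (nrow(plddt) != nrow(fx))
        stop("confidence profile length does not match residue count")
      sc <- af2_score(plddt)
      cc <- pearson_concordance(sc, fx)
      tm <- tail_mean(rmsd_series(ens, 1L), tail_fraction)
      overlays[[lab]] <- data.frame(
        chain = fx$chain, seq_id = fx$seq_id, res_name = fx$res_name,
        rmsf = fx$value, af2_score = sc$value, stringsAsFactors = FALSE)
      data.frame(system = lab,
                 n_frames = n_frames(ens), n_residues = nrow(fx),
                 rmsf_mean = mean(fx$value), rmsf_sd = stats::sd(fx$value),
                 pcc = cc$pcc, p_value = cc$p_value,
                 rmsd_tail_mean = tm$mean, rmsd_tail_sd = tm$sd,
                 error = NA_character_, stringsAsFactors = FALSE)
    }, error = function(e) {
      data.frame(system = lab, n_frames = NA_integer_,
                 n_residues = NA_integer_, rmsf_mean = NA_real_,
                 rmsf_sd = NA_real_, pcc = NA_real_, p_value = NA_real_,
                 rmsd_tail_mean = NA_real_, rmsd_tail_sd = NA_real_,
                 error = conditionMessage(e), stringsAsFactors = FALSE)
    })
    rows[[k]] <- res
  }
  tab <- do.call(rbind, rows)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(format_numeric(tab), file.path(out_dir, "systems.csv"),
                     row.names = FALSE, quote = FALSE)
    jsonlite::write_json(tab, file.path(out_dir, "systems.json"),
                         dataframe = "rows", na = "null", digits = NA)
    for (lab in names(overlays)) {
      utils::write.csv(format_numeric(overlays[[lab]]),
                       file.path(out_dir, paste0("overlay_", lab, ".csv")),
                       row.names = FALSE, quote = FALSE)
    }
  }
  list(table = tab, overlays = overlays)
}

# Stable decimal formatting so repeated runs produce byte-identical files.
format_numeric <- function(d, digits = 9L) {
  for (nm in names(d)) {
    if (is.numeric(d[[nm]]) && !is.integer(d[[nm]]))
      d[[nm]] <- formatC(signif(d[[nm]], digits), format = "g",
                         digits = digits)
  }
  d
}

#' Full complex analysis of one ensemble with ligand groups
#'
#' Runs the whole contact pipeline on one system: the final-frame distance
#' map (dense CSV), the final-frame RIN edge list (TSV), one
#' contact-frequency table per ligand target (CSV), the residue x ligand
#' percentage matrix (CSV), the trailing RMSD summary, and -- when a
#' confidence file with a PAE matrix is supplied -- the rank similarity
#' between the final-frame polymer distance map and the PAE map.  A
#' manifest (JSON) records the configuration, package version, seed and
#' timestamp; any requested ligand targets missing from the ensemble are
#' listed there while the remaining targets are processed.
#'
#' @param config a [run_config()] with a non-`NULL` `out_dir`.
#' @return (invisibly) list with `tables`, `cross_matrix`, `rin`,
#'   `rmsd_tail`, `pae_similarity` (or `NULL`), `missing_targets`,
#'   `manifest`.
#' @export
run_full_complex_analysis <- function(config) {
  stopifnot(inherits(config, "run_config"))
  out_dir <- config$out_dir
  if (is.null(out_dir)) stop("run_full_complex_analysis needs an out_dir")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  ens <- resolve_ensemble(config$ensemble, config$ligand_map)
  have <- ligand_labels(ens$atoms)
  want <- config$targets %||% have
  missing_targets <- setdiff(want, have)
  targets <- intersect(want, have)

  final <- get_frame(ens, n_frames(ens))
  dmap <- distance_map(final, config$dialect)
  utils::write.csv(format_numeric(as.data.frame(dmap$matrix)),
                   file.path(out_dir, "distance_map_final.csv"),
                   row.names = TRUE, quote = FALSE)
  rin <- build_rin(final, config$dialect)
  write_rin_edges(rin, file.path(out_dir, "rin_edges_final.tsv"))

  report <- NULL
  if (length(targets)) {
    report <- ligand_report(ens, config$dialect, targets, config$stride)
    for (tg in targets) {
      tb <- report$tables[[tg]]
      utils::write.csv(format_numeric(tb$rows),
                       file.path(out_dir, paste0("freq_", tg, ".csv")),
                       row.names = FALSE, quote = FALSE)
    }
    cm <- as.data.frame(report$cross_matrix)
    cm <- cbind(residue = rownames(cm), format_numeric(cm))
    utils::write.csv(cm, file.path(out_dir, "cross_ligand_matrix.csv"),
                     row.names = FALSE, quote = FALSE)
  }

  rmsd_tail <- if (n_frames(ens) >= 2L)
    tail_mean(rmsd_series(ens, 1L), config$tail_fraction) else NULL

  pae_sim <- NULL
  if (!is.null(config$confidence_json)) {
    conf <- read_confidence_json(config$confidence_json)
    if (!is.null(conf$pae)) {
      pol_map <- distance_map(final, config$dialect, include_ligands = FALSE)
      if (nrow(pol_map$matrix) == nrow(conf$pae)) {
        pae_sim <- map_similarity(pol_map$matrix, conf$pae)
        jsonlite::write_json(list(spearman = pae_sim),
                             file.path(out_dir, "pae_similarity.json"),
                             auto_unbox = TRUE, digits = NA)
      } else {
        missing_targets <- c(missing_targets,
                             "PAE dimension mismatch: similarity skipped")
      }
    }
  }

  manifest <- list(
    package = "flexrin",
    version = as.character(utils::packageVersion("flexrin")),
    seed = config$seed,
    dialect = config$dialect$mode,
    cutoff = config$dialect$cutoff,
    stride = config$stride,
    tail_fraction = config$tail_fraction,
    n_frames = n_frames(ens),
    targets_processed = as.list(targets),
    targets_missing = as.list(missing_targets),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)

  invisible(list(tables = if (is.null(report)) list() else report$tables,
                 cross_matrix = if (is.null(report)) NULL else report$cross_matrix,
                 rin = rin, rmsd_tail = rmsd_tail,
                 pae_similarity = pae_sim,
                 missing_targets = missing_targets,
                 manifest = manifest))
}
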