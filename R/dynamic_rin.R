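# Per-frame RINs over an ensemble and ligand-interaction frequency
# statistics: which residues a cofactor or substrate touches, in what
# percentage of frames, and how many partners it has on average.

#' Build one RIN per selected frame of an ensemble
#'
#' Frames 1, 1 + stride, 1 + 2*stride, ... are selected; all returned
#' graphs share one vertex set.
#'
#' @param ensemble a `flexrin_ensemble`.
#' @param dialect a [contact_dialect()].
#' @param stride frame stride (>= 1).
#' @param exclude_bonded drop sequence-adjacent polymer edges.
#' @return list of `rin_graph` objects.
#' @export
per_frame_rins <- function(ensemble, dialect = contact_dialect(),
                           stride = 1L, exclude_bonded = FALSE) {
  nf <- n_frames(ensemble)
  if (nf < 1L) stop("empty ensemble")
  if (stride < 1L) stop("stride must be >= 1")
  sel <- seq(1L, nf, by = stride)
  lapply(sel, function(t)
    build_rin(get_frame(ensemble, t), dialect,
              exclude_bonded = exclude_bonded))
}

#' Ligand-interaction frequency table over a series of RINs
#'
#' For one ligand vertex: the percentage of frames in which each polymer
#' residue has an edge to it, plus the per-frame partner count (degree of
#' the ligand restricted to polymer vertices) summarised as mean and
#' population standard deviation.  Rows are sorted by decreasing
#' percentage, ties broken by residue position, and only residues with a
#' non-zero percentage appear.
#'
#' @param rins list of `rin_graph` objects sharing one vertex set.
#' @param target ligand group label.
#' @return object of class `freq_table`: list with `target`, `rows` (data
#'   frame `key`, `res_name`, `class`, `percent`), `partner_count_mean`,
#'   `partner_count_sd`, `n_frames`.
#' @export
interaction_frequency <- function(rins, target) {
  if (!length(rins)) stop("no RINs supplied")
  v <- rins[[1L]]$vertices
  ti <- match(target, v$key)
  if (is.na(ti)) stop("target vertex not found: ", target)
  pol <- which(v$kind == "polymer")
  nf <- length(rins)
  counts <- numeric(length(pol))
  partners <- numeric(nf)
  for (k in seq_len(nf)) {
    g <- rins[[k]]
    if (nrow(g$vertices) != nrow(v) || any(g$vertices$key != v$key))
      stop("RINs do not share one vertex set")
    row <- g$adjacency[ti, pol]
    counts <- counts + row
    partners[k] <- sum(row)
  }
  percent <- 100 * counts / nf
  keep <- which(percent > 0)
  ord <- keep[order(-percent[keep], v$chain[pol][keep],
                    v$seq_id[pol][keep])]
  rows <- data.frame(key = v$key[pol][ord],
                     res_name = v$name[pol][ord],
                     class = v$class[pol][ord],
                     percent = percent[ord],
                     stringsAsFactors = FALSE)
  out <- list(target = target, rows = rows,
              partner_count_mean = mean(partners),
              partner_count_sd = sqrt(mean((partners - mean(partners))^2)),
              n_frames = nf)
  class(out) <- "freq_table"
  out
}

#' @export
print.freq_table <- function(x, ...) {
  cat(sprintf("<freq_table '%s': %d interacting residue(s) over %d frames; partners %.2f +/- %.2f>\n",
              x$target, nrow(x$rows), x$n_frames,
              x$partner_count_mean, x$partner_count_sd))
  if (nrow(x$rows)) print(utils::head(x$rows, 10L))
  invisible(x)
}

#' Filter a frequency table at a percentage threshold
#'
#' Keeps rows with `percent` strictly above the threshold, order and class
#' annotation preserved.
#'
#' @param table a `freq_table`.
#' @param threshold_percent threshold in \[0, 100\].
#' @return data frame of the retained rows.
#' @export
rank_partners <- function(table, threshold_percent = 50) {
  stopifnot(threshold_percent >= 0, threshold_percent <= 100)
  table$rows[table$rows$percent > threshold_percent, , drop = FALSE]
}

#' Ligand-interaction report across several targets
#'
#' One frequency table per ligand, plus a residue x ligand matrix of
#' contact percentages over the union of interacting residues -- this is
#' what exposes shared binders, residues contacting several ligands at
#' once.
#'
#' @param ensemble a `flexrin_ensemble` containing the target ligand groups.
#' @param dialect a [contact_dialect()].
#' @param targets character vector of ligand group labels.
#' @param stride frame stride.
#' @param exclude_bonded drop sequence-adjacent polymer edges.
#' @return list with `tables` (named list of `freq_table`), `cross_matrix`
#'   (residues x ligands, percent), `n_frames`.
#' @export
ligand_report <- function(ensemble, dialect = contact_dialect(),
                          targets = ligand_labels(ensemble$atoms),
                          stride = 1L, exclude_bonded = FALSE) {
  rins <- per_frame_rins(ensemble, dialect, stride, exclude_bonded)
  tables <- lapply(targets, function(tg) interaction_frequency(rins, tg))
  names(tables) <- targets
  all_keys <- unique(unlist(lapply(tables, function(tb) tb$rows$key)))
  v <- rins[[1L]]$vertices
  all_keys <- v$key[v$key %in% all_keys]    # restore chain order
  cm <- matrix(0, length(all_keys), length(targets),
               dimnames = list(all_keys, targets))
  for (tg in targets) {
    rws <- tables[[tg]]$rows
    cm[rws$key, tg] <- rws$percent
  }
  list(tables = tables, cross_matrix = cm, n_frames = length(rins))
}
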