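# Template-based cofactor/ligand grafting: pair residues by global sequence
# alignment, superpose the template onto the model over paired C-alpha
# atoms, and map the template's ligand groups rigidly into the model frame.

#' Pair residues of two chains by global sequence alignment
#'
#' Needleman-Wunsch global alignment with linear gap penalty; aligned
#' non-gap columns become residue pairs.  Traceback ties are resolved
#' diagonal > up (gap in the second sequence) > left, which makes the
#' pairing deterministic.
#'
#' @param template_seq,model_seq 1-letter sequences (character scalars).
#' @param match,mismatch,gap alignment scores (defaults 1, 0, -1).
#' @return object of class `residue_pairing`: list with `pairs` (2-column
#'   integer matrix of 1-based template/model positions) and `score`.
#' @export
pair_by_alignment <- function(template_seq, model_seq,
                              match = 1, mismatch = 0, gap = -1) {
  s1 <- strsplit(template_seq, "")[[1L]]
  s2 <- strsplit(model_seq, "")[[1L]]
  n <- length(s1); m <- length(s2)
  if (!n || !m) stop("empty sequence")
  F <- matrix(0, n + 1L, m + 1L)
  F[, 1L] <- gap * (0:n)
  F[1L, ] <- gap * (0:m)
  sub <- (outer(s1, s2, "==")) * (match - mismatch) + mismatch
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      F[i + 1L, j + 1L] <- max(F[i, j] + sub[i, j],
                               F[i, j + 1L] + gap,
                               F[i + 1L, j] + gap)
    }
  }
  # traceback, ties: diagonal > up > left
  i <- n; j <- m
  ti <- integer(); mi <- integer()
  while (i > 0L && j > 0L) {
    if (F[i + 1L, j + 1L] == F[i, j] + sub[i, j]) {
      ti <- c(i, ti); mi <- c(j, mi)
      i <- i - 1L; j <- j - 1L
    } else if (F[i + 1L, j + 1L] == F[i, j + 1L] + gap) {
      i <- i - 1L
    } else {
      j <- j - 1L
    }
  }
  out <- list(pairs = cbind(template = ti, model = mi),
              score = F[n + 1L, m + 1L])
  class(out) <- "residue_pairing"
  out
}

#' @export
print.residue_pairing <- function(x, ...) {
  cat(sprintf("<residue_pairing: %d pairs, score %g>\n",
              nrow(x$pairs), x$score))
  invisible(x)
}

# C-alpha coordinates of the polymer residues, in residue order.
polymer_ca_xyz <- function(frame) {
  rt <- residue_table(frame$atoms)
  a <- frame$atoms
  keys <- paste0(a$chain, ":", a$seq_id)
  idx <- vapply(rt$key, function(k) {
    sel <- which(keys == k & a$kind == "polymer" & a$name == "CA")
    if (!length(sel)) NA_integer_ else sel[1L]
  }, integer(1L))
  if (anyNA(idx)) stop("polymer residue without C-alpha")
  frame$xyz[idx, , drop = FALSE]
}

#' Graft template ligands into a model frame by rigid superposition
#'
#' Computes the Kabsch transform taking the template's paired C-alpha atoms
#' onto the model's, applies it to every atom of every template ligand
#' group, and appends the transformed groups to a copy of the model frame.
#' Internal ligand geometry is preserved exactly (the map is rigid).  The
#' transferred atoms keep their template residue names, so downstream
#' ligand grouping works unchanged.
#'
#' @param template_frame holo `flexrin_frame` carrying ligand groups.
#' @param model_frame apo `flexrin_frame` to receive them.
#' @param pairing optional [pair_by_alignment()] result; defaults to
#'   aligning the two polymer sequences.
#' @param ligands optional subset of template ligand labels to transfer.
#' @return list with `frame` (the model with ligands appended),
#'   `transform` (the `rigid_transform` used) and `rmsd` (C-alpha
#'   superposition RMSD over the pairing).
#' @export
transfer_ligands <- function(template_frame, model_frame, pairing = NULL,
                             ligands = NULL) {
  labs <- ligand_labels(template_frame$atoms)
  if (!is.null(ligands)) {
    missing <- setdiff(ligands, labs)
    if (length(missing))
      stop("template has no ligand group(s): ", paste(missing, collapse = ", "))
    labs <- ligands
  }
  if (!length(labs)) stop("template frame has no ligand groups to transfer")
  if (is.null(pairing)) {
    pairing <- pair_by_alignment(polymer_sequence(template_frame),
                                 polymer_sequence(model_frame))
  }
  if (nrow(pairing$pairs) < 3L)
    stop("need at least 3 paired residues for superposition")
  tmpl_ca <- polymer_ca_xyz(template_frame)
  model_ca <- polymer_ca_xyz(model_frame)
  tf <- superpose(tmpl_ca[pairing$pairs[, 1L], , drop = FALSE],
                  model_ca[pairing$pairs[, 2L], , drop = FALSE])
  lig_idx <- which(template_frame$atoms$kind == "ligand" &
                   template_frame$atoms$group %in% labs)
  lig_atoms <- template_frame$atoms[lig_idx, , drop = FALSE]
  lig_xyz <- apply_transform(template_frame$xyz[lig_idx, , drop = FALSE], tf)
  ma <- model_frame$atoms
  lig_atoms$serial <- max(ma$serial) + seq_len(nrow(lig_atoms))
  new_atoms <- rbind(ma, lig_atoms)
  new_xyz <- rbind(model_frame$xyz, lig_xyz)
  rownames(new_atoms) <- NULL
  out_frame <- structure_frame(new_atoms, new_xyz,
                               frame_label = model_frame$frame_label)
  list(frame = out_frame, transform = tf, rmsd = tf$rmsd)
}

#' Heavy-atom clashes between a placed ligand and the polymer
#'
#' Lists all (ligand atom, polymer atom) heavy-atom pairs closer than the
#' cutoff, sorted by distance; an empty result means an acceptable
#' placement.  The default 2.0 Angstrom is the shortest plausible
#' non-bonded heavy-atom approach.
#'
#' @param frame a `flexrin_frame` containing the ligand.
#' @param ligand ligand group label.
#' @param clash_cutoff distance cutoff, Angstrom (> 0... `0` disables).
#' @return data frame with columns `ligand_atom`, `protein_atom`
#'   (`"chain:seq_id:name"`), `distance`.
#' @export
clash_check <- function(frame, ligand, clash_cutoff = 2.0) {
  if (clash_cutoff < 0) stop("clash cutoff must be >= 0")
  a <- frame$atoms
  li <- which(a$kind == "ligand" & a$group == ligand & a$element != "H")
  if (!length(li)) stop("no such ligand group: ", ligand)
  pi <- which(a$kind == "polymer" & a$element != "H")
  empty <- data.frame(ligand_atom = character(), protein_atom = character(),
                      distance = numeric(), stringsAsFactors = FALSE)
  if (!length(pi) || clash_cutoff == 0) return(empty)
  p <- frame$xyz[li, , drop = FALSE]
  q <- frame$xyz[pi, , drop = FALSE]
  d2 <- outer(rowSums(p^2), rowSums(q^2), "+") - 2 * tcrossprod(p, q)
  d2[d2 < 0] <- 0
  hit <- which(sqrt(d2) < clash_cutoff, arr.ind = TRUE)
  if (!nrow(hit)) return(empty)
  d <- sqrt(d2[hit])
  out <- data.frame(
    ligand_atom = a$name[li[hit[, 1L]]],
    protein_atom = paste(a$chain[pi[hit[, 2L]]], a$seq_id[pi[hit[, 2L]]],
                         a$name[pi[hit[, 2L]]], sep = ":"),
    distance = d, stringsAsFactors = FALSE)
  out[order(out$distance), , drop = FALSE]
}

#' Binding-site residues of each ligand in one frame
#'
#' Residues in contact with each ligand group under the dialect; the
#' single-frame view of the dynamic contact frequencies.
#'
#' @param frame a `flexrin_frame` with ligand groups.
#' @param dialect a [contact_dialect()].
#' @return named list (per ligand label) of residue keys in contact.
#' @export
binding_site_residues <- function(frame, dialect = contact_dialect()) {
  labs <- ligand_labels(frame$atoms)
  if (!length(labs)) stop("frame has no ligand groups")
  rin <- build_rin(frame, dialect)
  v <- rin$vertices
  out <- lapply(labs, function(lab) {
    ti <- match(lab, v$key)
    nb <- which(rin$adjacency[ti, ] == 1L & v$kind == "polymer")
    v$key[nb]
  })
  names(out) <- labs
  out
}
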