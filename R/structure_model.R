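# Domain containers and I/O for multi-model structures, ligand groups and
# per-residue confidence tracks.

AA3TO1 <- c(
  ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C", GLN = "Q",
  GLU = "E", GLY = "G", HIS = "H", ILE = "I", LEU = "L", LYS = "K",
  MET = "M", PHE = "F", PRO = "P", SER = "S", THR = "T", TRP = "W",
  TYR = "Y", VAL = "V"
)

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Construct a single structure frame
#'
#' A frame is one conformer: a snapshot from a trajectory or one predicted
#' model.  It couples an atom table (identity, residue membership, element,
#' B-factor/pLDDT, polymer vs ligand kind) with an `n_atoms x 3` coordinate
#' matrix in Angstrom.
#'
#' @param atoms data frame with columns `serial`, `name`, `element`, `chain`,
#'   `seq_id`, `res_name`, `kind` (`"polymer"` or `"ligand"`), `group`
#'   (ligand group label, `NA` for polymer atoms), `occupancy`, `bfactor`.
#' @param xyz numeric matrix, `nrow(atoms)` rows and 3 columns, Angstrom.
#' @param frame_label identifier (model number or time label).
#' @return an object of class `flexrin_frame`.
#' @export
structure_frame <- function(atoms, xyz, frame_label = "1") {
  atoms <- as.data.frame(atoms, stringsAsFactors = FALSE)
  xyz <- as.matrix(xyz)
  storage.mode(xyz) <- "double"
  validate_atoms(atoms, xyz)
  fr <- list(atoms = atoms, xyz = xyz, frame_label = as.character(frame_label))
  class(fr) <- "flexrin_frame"
  fr
}

validate_atoms <- function(atoms, xyz) {
  need <- c("serial", "name", "element", "chain", "seq_id", "res_name",
            "kind", "group", "occupancy", "bfactor")
  missing_cols <- setdiff(need, names(atoms))
  if (length(missing_cols))
    stop("atom table lacks columns: ", paste(missing_cols, collapse = ", "))
  if (nrow(atoms) == 0L) stop("atom table is empty")
  if (nrow(xyz) != nrow(atoms) || ncol(xyz) != 3L)
    stop("coordinate matrix must be ", nrow(atoms), " x 3")
  if (!all(is.finite(xyz))) stop("non-finite coordinates")
  if (any(!nzchar(atoms$element))) stop("empty element symbols")
  if (!all(atoms$kind %in% c("polymer", "ligand")))
    stop("atom kind must be 'polymer' or 'ligand'")
  # polymer residues strictly increasing within each chain
  pol <- atoms[atoms$kind == "polymer", , drop = FALSE]
  if (nrow(pol)) {
    for (ch in unique(pol$chain)) {
      s <- unique(pol$seq_id[pol$chain == ch])
      if (any(diff(s) <= 0L))
        stop("polymer residue numbering not strictly increasing in chain ", ch)
    }
  }
  invisible(TRUE)
}

#' @export
print.flexrin_frame <- function(x, ...) {
  rt <- residue_table(x$atoms)
  cat(sprintf("<flexrin_frame '%s': %d atoms, %d polymer residues, %d ligand group(s)>\n",
              x$frame_label, nrow(x$atoms), nrow(rt),
              length(ligand_labels(x$atoms))))
  invisible(x)
}

#' Assemble frames into an ensemble
#'
#' All frames must share one topology (same residues, atom names and
#' ordering); coordinates are stacked into an `n_atoms x 3 x n_frames`
#' array.  The atom table (including B-factors) is taken from the first
#' frame; confidence tracks for an ensemble therefore come from its first
#' model or from a separate confidence file.
#'
#' @param frames list of [structure_frame()] objects.
#' @param source `"trajectory"` or `"model_population"`.
#' @return an object of class `flexrin_ensemble`.
#' @export
as_ensemble <- function(frames, source = c("trajectory", "model_population")) {
  source <- match.arg(source)
  if (!length(frames)) stop("an ensemble needs at least one frame")
  ref <- frames[[1L]]
  sig <- function(a) paste(a$kind, a$chain, a$seq_id, a$res_name, a$name)
  ref_sig <- sig(ref$atoms)
  for (k in seq_along(frames)[-1L]) {
    s <- sig(frames[[k]]$atoms)
    if (length(s) != length(ref_sig) || any(s != ref_sig)) {
      bad <- if (length(s) != length(ref_sig)) {
        min(length(s), length(ref_sig)) + 1L
      } else which(s != ref_sig)[1L]
      bad <- min(bad, length(ref_sig))
      stop(sprintf(
        "inconsistent topology: frame %d diverges from frame 1 at residue %s:%s %s",
        k, ref$atoms$chain[bad], ref$atoms$seq_id[bad], ref$atoms$res_name[bad]))
    }
  }
  xyz <- array(0, dim = c(nrow(ref$atoms), 3L, length(frames)))
  for (k in seq_along(frames)) xyz[, , k] <- frames[[k]]$xyz
  ens <- list(
    atoms = ref$atoms,
    xyz = xyz,
    frame_labels = vapply(frames, function(f) f$frame_label, character(1L)),
    source = source
  )
  class(ens) <- "flexrin_ensemble"
  ens
}

#' @export
print.flexrin_ensemble <- function(x, ...) {
  cat(sprintf("<flexrin_ensemble (%s): %d frames, %d atoms, %d polymer residues, %d ligand group(s)>\n",
              x$source, n_frames(x), nrow(x$atoms),
              nrow(residue_table(x$atoms)), length(ligand_labels(x$atoms))))
  invisible(x)
}

#' Number of frames in an ensemble
#' @param ensemble a `flexrin_ensemble`.
#' @export
n_frames <- function(ensemble) dim(ensemble$xyz)[3L]

#' Extract one frame from an ensemble
#' @param ensemble a `flexrin_ensemble`.
#' @param i frame index (1-based).
#' @export
get_frame <- function(ensemble, i) {
  if (i < 1L || i > n_frames(ensemble)) stop("frame index out of range")
  structure_frame(ensemble$atoms, ensemble$xyz[, , i],
                  frame_label = ensemble$frame_labels[i])
}

# --- residue bookkeeping ----------------------------------------------------

# Polymer residues, in order of appearance.  key is "chain:seq_id".
residue_table <- function(atoms) {
  pol <- atoms[atoms$kind == "polymer", , drop = FALSE]
  if (!nrow(pol)) {
    return(data.frame(chain = character(), seq_id = integer(),
                      res_name = character(), key = character(),
                      stringsAsFactors = FALSE))
  }
  keys <- paste0(pol$chain, ":", pol$seq_id)
  first <- !duplicated(keys)
  data.frame(chain = pol$chain[first], seq_id = pol$seq_id[first],
             res_name = pol$res_name[first], key = keys[first],
             stringsAsFactors = FALSE)
}

residue_key <- function(chain, seq_id) paste0(chain, ":", seq_id)

ligand_labels <- function(atoms) {
  unique(atoms$group[atoms$kind == "ligand"])
}

# Indices of the atoms of each polymer residue (list named by key).
residue_atom_index <- function(atoms, heavy_only = FALSE) {
  sel <- atoms$kind == "polymer"
  if (heavy_only) sel <- sel & atoms$element != "H"
  idx <- which(sel)
  split(idx, paste0(atoms$chain[idx], ":", atoms$seq_id[idx]))[
    unique(paste0(atoms$chain[idx], ":", atoms$seq_id[idx]))]
}

ligand_atom_index <- function(atoms, heavy_only = TRUE) {
  sel <- atoms$kind == "ligand"
  if (heavy_only) sel <- sel & atoms$element != "H"
  idx <- which(sel)
  if (!length(idx)) return(list())
  split(idx, atoms$group[idx])[unique(atoms$group[idx])]
}

#' One-letter amino-acid sequence of a frame's polymer chain
#' @param frame a `flexrin_frame`.
#' @return character scalar; unknown residue names map to `"X"`.
#' @export
polymer_sequence <- function(frame) {
  rt <- residue_table(frame$atoms)
  s <- AA3TO1[rt$res_name]
  s[is.na(s)] <- "X"
  paste(s, collapse = "")
}

# --- PDB I/O ----------------------------------------------------------------

#' Read a multi-model PDB file into an ensemble
#'
#' Each `MODEL`/`ENDMDL` block becomes one frame; a file without `MODEL`
#' records is a single-frame ensemble.  `HETATM` residues are grouped into
#' ligand groups by residue name (or by an explicit map), waters (`HOH`,
#' `WAT`) are dropped, and alternate locations are resolved to the
#' highest-occupancy copy (ties to the alphabetically first altloc).
#' B-factors (conventionally carrying pLDDT for predicted models) are taken
#' from the first model.
#'
#' @param path path to a PDB file.
#' @param ligand_labels optional named character vector mapping `HETATM`
#'   residue names to group labels, e.g. `c(FSA = "FS4A", FSB = "FS4B")`.
#' @param source ensemble source tag, `"trajectory"` or `"model_population"`.
#' @return a `flexrin_ensemble`.
#' @export
read_multimodel_pdb <- function(path, ligand_labels = NULL,
                                source = c("trajectory", "model_population")) {
  source <- match.arg(source)
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  rec <- substr(lines, 1L, 6L)
  model_starts <- which(trimws(rec) == "MODEL")
  frames <- list()
  if (!length(model_starts)) {
    frames[[1L]] <- parse_pdb_block(lines, seq_along(lines), "1", ligand_labels)
  } else {
    model_ends <- which(trimws(rec) == "ENDMDL")
    if (length(model_ends) < length(model_starts))
      model_ends <- c(model_ends, length(lines))
    for (k in seq_along(model_starts)) {
      rng <- seq(model_starts[k], model_ends[k])
      label <- trimws(substr(lines[model_starts[k]], 7L, 80L))
      if (!nzchar(label)) label <- as.character(k)
      frames[[k]] <- parse_pdb_block(lines, rng, label, ligand_labels)
    }
  }
  as_ensemble(frames, source = source)
}

parse_pdb_block <- function(lines, rng, label, ligand_labels) {
  sub <- lines[rng]
  rec <- substr(sub, 1L, 6L)
  is_atom <- trimws(rec) %in% c("ATOM", "HETATM")
  if (!any(is_atom)) stop("no ATOM/HETATM records in model ", label)
  ln <- sub[is_atom]
  lineno <- rng[is_atom]
  x <- suppressWarnings(as.numeric(substr(ln, 31L, 38L)))
  y <- suppressWarnings(as.numeric(substr(ln, 39L, 46L)))
  z <- suppressWarnings(as.numeric(substr(ln, 47L, 54L)))
  bad <- which(!is.finite(x) | !is.finite(y) | !is.finite(z))
  if (length(bad))
    stop("unparseable ATOM record at line ", lineno[bad[1L]], " of PDB input")
  occ <- suppressWarnings(as.numeric(substr(ln, 55L, 60L)))
  occ[!is.finite(occ)] <- 1
  bf <- suppressWarnings(as.numeric(substr(ln, 61L, 66L)))
  bf[!is.finite(bf)] <- 0
  name <- trimws(substr(ln, 13L, 16L))
  elem <- trimws(substr(ln, 77L, 78L))
  # element fallback: first alphabetic character of the atom name
  guess <- toupper(gsub("[^A-Za-z].*$", "", gsub("^[0-9]+", "", name)))
  guess <- substr(guess, 1L, 1L)
  elem <- ifelse(nzchar(elem), elem, guess)
  atoms <- data.frame(
    serial = suppressWarnings(as.integer(substr(ln, 7L, 11L))),
    name = name,
    element = elem,
    altloc = substr(ln, 17L, 17L),
    chain = substr(ln, 22L, 22L),
    seq_id = suppressWarnings(as.integer(substr(ln, 23L, 26L))),
    res_name = trimws(substr(ln, 18L, 20L)),
    kind = ifelse(trimws(substr(ln, 1L, 6L)) == "ATOM", "polymer", "ligand"),
    occupancy = occ,
    bfactor = bf,
    stringsAsFactors = FALSE
  )
  xyz <- cbind(x, y, z)
  keep <- !(atoms$res_name %in% c("HOH", "WAT"))
  atoms <- atoms[keep, , drop = FALSE]
  xyz <- xyz[keep, , drop = FALSE]
  # altloc resolution: highest occupancy, ties to first altloc letter
  if (any(atoms$altloc != " ")) {
    id <- paste(atoms$chain, atoms$seq_id, atoms$res_name, atoms$name)
    ord <- order(id, -atoms$occupancy, atoms$altloc)
    keep2 <- ord[!duplicated(id[ord])]
    keep2 <- sort(keep2)
    atoms <- atoms[keep2, , drop = FALSE]
    xyz <- xyz[keep2, , drop = FALSE]
  }
  atoms$altloc <- NULL
  atoms$group <- NA_character_
  lig <- atoms$kind == "ligand"
  if (any(lig)) {
    lab <- atoms$res_name[lig]
    if (!is.null(ligand_labels)) {
      mapped <- ligand_labels[lab]
      lab <- ifelse(is.na(mapped), lab, mapped)
    }
    atoms$group[lig] <- lab
  }
  rownames(atoms) <- NULL
  structure_frame(atoms, xyz, frame_label = label)
}

#' Write an ensemble (or a single frame) as a multi-model PDB file
#'
#' Coordinates are written at the PDB fixed-width precision (3 decimals);
#' polymer atoms as `ATOM`, ligand atoms as `HETATM` with their residue
#' names, so ligand groups survive a round trip.
#'
#' @param x a `flexrin_ensemble` or `flexrin_frame`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_multimodel_pdb <- function(x, path) {
  if (inherits(x, "flexrin_frame")) {
    x <- as_ensemble(list(x))
  }
  stopifnot(inherits(x, "flexrin_ensemble"))
  con <- file(path, "w")
  on.exit(close(con))
  a <- x$atoms
  namef <- ifelse(nchar(a$name) < 4L, sprintf(" %-3s", a$name),
                  sprintf("%-4s", a$name))
  recf <- ifelse(a$kind == "polymer", "ATOM", "HETATM")
  nf <- n_frames(x)
  for (k in seq_len(nf)) {
    if (nf > 1L) writeLines(sprintf("MODEL     %4d", k), con)
    xyz <- x$xyz[, , k, drop = FALSE]
    writeLines(sprintf(
      "%-6s%5d %s %-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
      recf, a$serial, namef, a$res_name, a$chain, a$seq_id,
      xyz[, 1L, 1L], xyz[, 2L, 1L], xyz[, 3L, 1L],
      a$occupancy, a$bfactor, a$element), con)
    if (nf > 1L) writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

# --- confidence tracks ------------------------------------------------------

new_profile <- function(chain, seq_id, res_name, value, kind) {
  p <- data.frame(chain = chain, seq_id = seq_id, res_name = res_name,
                  value = as.numeric(value), stringsAsFactors = FALSE)
  class(p) <- c("residue_profile", "data.frame")
  attr(p, "kind") <- kind
  p
}

#' @export
print.residue_profile <- function(x, ...) {
  cat(sprintf("<residue_profile [%s]: %d residues>\n",
              attr(x, "kind") %||% "?", nrow(x)))
  NextMethod()
}

profile_kind <- function(p) attr(p, "kind") %||% "unknown"

#' Extract the per-residue pLDDT profile stored in a frame's B-factors
#'
#' Predicted models conventionally store pLDDT in the B-factor column.  The
#' per-residue value is the C-alpha B-factor; residues without a C-alpha
#' fall back to the mean over their atoms.  Values outside \[0, 100\] are
#' clamped, with a warning.
#'
#' @param frame a `flexrin_frame`.
#' @param per_residue_mean if `TRUE`, always average over the residue's
#'   atoms instead of reading the C-alpha.
#' @return a `residue_profile` of kind `"plddt"`.
#' @export
extract_plddt <- function(frame, per_residue_mean = FALSE) {
  a <- frame$atoms
  rt <- residue_table(a)
  if (!nrow(rt)) stop("frame has no polymer residues")
  keys <- paste0(a$chain, ":", a$seq_id)
  vals <- vapply(rt$key, function(k) {
    sel <- which(keys == k & a$kind == "polymer")
    ca <- sel[a$name[sel] == "CA"]
    if (!per_residue_mean && length(ca)) a$bfactor[ca[1L]]
    else mean(a$bfactor[sel])
  }, numeric(1L))
  if (any(vals < 0 | vals > 100)) {
    warning("pLDDT values outside [0, 100] were clamped")
    vals <- pmin(pmax(vals, 0), 100)
  }
  new_profile(rt$chain, rt$seq_id, rt$res_name, vals, "plddt")
}

#' Read an AF2-style confidence JSON file
#'
#' Expects a per-residue pLDDT array under `plddt` (or
#' `confidenceScore`), and optionally a square PAE matrix under `pae` or
#' `predicted_aligned_error`.
#'
#' @param path path to a JSON file.
#' @param frame optional `flexrin_frame`; when given, residue keys are taken
#'   from it and the profile length must match its polymer residue count.
#' @return list with elements `plddt` (a `residue_profile`) and `pae`
#'   (numeric matrix or `NULL`).
#' @export
read_confidence_json <- function(path, frame = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  j <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  plddt <- j$plddt %||% j$confidenceScore
  if (is.null(plddt)) stop("no per-residue pLDDT array in ", path)
  plddt <- as.numeric(plddt)
  pae <- j$pae %||% j$predicted_aligned_error
  if (!is.null(pae)) {
    pae <- as.matrix(pae)
    if (nrow(pae) != ncol(pae))
      stop("PAE matrix is not square: ", nrow(pae), " x ", ncol(pae))
    if (nrow(pae) != length(plddt))
      stop("PAE dimension (", nrow(pae), ") does not match pLDDT length (",
           length(plddt), ")")
    storage.mode(pae) <- "double"
  }
  if (!is.null(frame)) {
    rt <- residue_table(frame$atoms)
    if (nrow(rt) != length(plddt))
      stop("pLDDT length (", length(plddt),
           ") does not match structure residue count (", nrow(rt), ")")
    prof <- new_profile(rt$chain, rt$seq_id, rt$res_name, plddt, "plddt")
  } else {
    prof <- new_profile(rep("A", length(plddt)), seq_along(plddt),
                        rep(NA_character_, length(plddt)), plddt, "plddt")
  }
  if (any(prof$value < 0 | prof$value > 100))
    stop("pLDDT values outside [0, 100] in ", path)
  list(plddt = prof, pae = pae)
}

#' Write a residue profile as CSV
#'
#' Columns `chain,seq_id,res_name,value`; values at 8 significant digits so
#' a write/read cycle is lossless well below 1e-6 relative precision.
#'
#' @param profile a `residue_profile`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_profile_csv <- function(profile, path) {
  if (!nrow(profile)) stop("refusing to write an empty profile")
  out <- data.frame(chain = profile$chain, seq_id = profile$seq_id,
                    res_name = profile$res_name,
                    value = signif(profile$value, 8L))
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a residue profile written by [write_profile_csv()]
#' @param path CSV path.
#' @param kind profile kind tag to attach (`"plddt"`, `"rmsf"`, `"af2"`, ...).
#' @return a `residue_profile`.
#' @export
read_profile_csv <- function(path, kind = "unknown") {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  new_profile(as.character(d$chain), as.integer(d$seq_id),
              as.character(d$res_name), d$value, kind)
}
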