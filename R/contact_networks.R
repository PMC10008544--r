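# Distance maps, binary contact maps and residue interaction networks (RINs)
# with ligand groups as single vertices.
#
# Two contact dialects are supported: the classic C-beta / 8 Angstrom rule
# (C-alpha for Gly), and the all-heavy-atom minimum-distance rule with a 3.5
# Angstrom cutoff -- motivated by hydrogen-bond geometry (X...Y around 2-3
# Angstrom, up to ~3.5 for C-H...O), which avoids the false contact
# assignments the C-beta rule makes when sidechains touch but C-betas are
# far apart.

#' Contact dialect
#'
#' @param mode `"heavy_min"` (minimum distance over all heavy-atom pairs)
#'   or `"cbeta"` (C-beta to C-beta, C-alpha for Gly).
#' @param cutoff contact cutoff in Angstrom; defaults to 3.5 for
#'   `heavy_min` and 8.0 for `cbeta`.  An edge requires the distance to be
#'   strictly below the cutoff.
#' @return an object of class `contact_dialect`.
#' @export
contact_dialect <- function(mode = c("heavy_min", "cbeta"), cutoff = NULL) {
  mode <- match.arg(mode)
  cutoff <- cutoff %||% if (mode == "heavy_min") 3.5 else 8.0
  if (cutoff <= 0) stop("cutoff must be positive")
  d <- list(mode = mode, cutoff = cutoff)
  class(d) <- "contact_dialect"
  d
}

heavy_xyz <- function(frame, idx) {
  frame$xyz[idx, , drop = FALSE]
}

#' Minimum heavy-atom distance between two residues or ligand groups
#'
#' The distance between two vertices is the minimum Euclidean distance over
#' all pairs of their heavy (non-hydrogen) atoms.
#'
#' @param frame a `flexrin_frame`.
#' @param a,b residue keys (`"chain:seq_id"`) or ligand group labels.
#' @return distance in Angstrom.
#' @export
residue_min_distance <- function(frame, a, b) {
  idx <- vertex_atom_index(frame$atoms)
  for (k in c(a, b)) if (is.null(idx[[k]]))
    stop("unknown vertex or no heavy atoms: ", k)
  min_cross_distance(frame$xyz[idx[[a]], , drop = FALSE],
                     frame$xyz[idx[[b]], , drop = FALSE])
}

min_cross_distance <- function(p, q) {
  # full cross distance via the expansion |p - q|^2 = |p|^2 + |q|^2 - 2 p.q
  pp <- rowSums(p^2); qq <- rowSums(q^2)
  d2 <- outer(pp, qq, "+") - 2 * tcrossprod(p, q)
  sqrt(max(0, min(d2)))
}

# Heavy-atom indices per vertex: polymer residues (keyed "chain:seq_id", in
# order), then ligand groups (keyed by label).
vertex_atom_index <- function(atoms) {
  c(residue_atom_index(atoms, heavy_only = TRUE),
    ligand_atom_index(atoms, heavy_only = TRUE))
}

vertex_info <- function(atoms, include_ligands = TRUE) {
  rt <- residue_table(atoms)
  v <- data.frame(key = rt$key, name = rt$res_name, kind = "polymer",
                  chain = rt$chain, seq_id = rt$seq_id,
                  stringsAsFactors = FALSE)
  if (include_ligands) {
    for (lab in ligand_labels(atoms)) {
      v <- rbind(v, data.frame(key = lab, name = lab, kind = "ligand",
                               chain = NA_character_, seq_id = NA_integer_,
                               stringsAsFactors = FALSE))
    }
  }
  v$class <- residue_class(v$name)
  v$class[v$kind == "ligand"] <- "ligand"
  v
}

#' Chemical class of a residue name
#'
#' Positively charged: Lys, Arg; negatively charged: Glu, Asp; aromatic:
#' His, Tyr, Phe, Trp; everything else: other.
#'
#' @param res_name character vector of 3-letter residue names.
#' @return character vector in `{"positive","negative","aromatic","other"}`.
#' @export
residue_class <- function(res_name) {
  out <- rep("other", length(res_name))
  out[res_name %in% c("LYS", "ARG")] <- "positive"
  out[res_name %in% c("GLU", "ASP")] <- "negative"
  out[res_name %in% c("HIS", "TYR", "PHE", "TRP")] <- "aromatic"
  out
}

#' Residue/ligand distance map of one frame
#'
#' Symmetric matrix of inter-vertex distances under a dialect.  In
#' `heavy_min` mode ligand groups are included as single vertices (distance
#' to a group = minimum over all its heavy atoms); in `cbeta` mode ligands
#' have no C-beta and are excluded, with a warning if any were requested.
#'
#' @param frame a `flexrin_frame`.
#' @param dialect a [contact_dialect()].
#' @param include_ligands include ligand groups as vertices (`heavy_min`
#'   only).
#' @return object of class `distance_map`: list with `vertices` (data
#'   frame), `matrix` (symmetric, zero diagonal, Angstrom), `dialect`.
#' @export
distance_map <- function(frame, dialect = contact_dialect(),
                         include_ligands = TRUE) {
  stopifnot(inherits(dialect, "contact_dialect"))
  a <- frame$atoms
  if (dialect$mode == "cbeta" && include_ligands &&
      length(ligand_labels(a))) {
    warning("cbeta dialect has no ligand vertices; ligand groups excluded")
    include_ligands <- FALSE
  }
  v <- vertex_info(a, include_ligands)
  nv <- nrow(v)
  if (dialect$mode == "heavy_min") {
    idx <- vertex_atom_index(a)[v$key]
    n_per <- lengths(idx)
    if (any(n_per == 0L)) stop("vertex without heavy atoms: ",
                               v$key[which(n_per == 0L)[1L]])
    flat <- unlist(idx, use.names = FALSE)
    grp <- rep.int(seq_len(nv), n_per)
    D <- as.matrix(stats::dist(frame$xyz[flat, , drop = FALSE]))
    M <- matrix(0, nv, nv)
    rows <- split(seq_along(flat), grp)
    for (i in seq_len(nv - 1L)) {
      Di <- D[rows[[i]], , drop = FALSE]
      for (j in seq((i + 1L), nv)) {
        M[i, j] <- M[j, i] <- min(Di[, rows[[j]]])
      }
    }
  } else {
    pts <- matrix(NA_real_, nv, 3L)
    keys <- paste0(a$chain, ":", a$seq_id)
    for (i in seq_len(nv)) {
      sel <- which(keys == v$key[i] & a$kind == "polymer")
      pick <- sel[a$name[sel] == "CB"]
      if (!length(pick)) pick <- sel[a$name[sel] == "CA"]
      if (!length(pick))
        stop("residue ", v$key[i], " has neither C-beta nor C-alpha")
      pts[i, ] <- frame$xyz[pick[1L], ]
    }
    M <- as.matrix(stats::dist(pts))
    dimnames(M) <- NULL
  }
  dimnames(M) <- list(v$key, v$key)
  out <- list(vertices = v, matrix = M, dialect = dialect)
  class(out) <- "distance_map"
  out
}

#' @export
print.distance_map <- function(x, ...) {
  cat(sprintf("<distance_map [%s, cutoff %.1f]: %d vertices>\n",
              x$dialect$mode, x$dialect$cutoff, nrow(x$vertices)))
  invisible(x)
}

#' Binary contact map from a distance map
#'
#' `adjacency[i, j] = 1` iff `0 < d_ij < cutoff` (strict inequality at the
#' cutoff); the diagonal is 0.  Sequence-adjacent polymer pairs are kept as
#' edges but flagged in the `"bonded"` attribute so callers can drop them.
#'
#' @param dmap a `distance_map`.
#' @return binary symmetric matrix with a logical `"bonded"` attribute
#'   matrix marking polymer pairs adjacent in sequence.
#' @export
contact_map <- function(dmap) {
  M <- dmap$matrix
  adj <- (M > 0 & M < dmap$dialect$cutoff) * 1L
  diag(adj) <- 0L
  v <- dmap$vertices
  bonded <- matrix(FALSE, nrow(v), nrow(v))
  pol <- which(v$kind == "polymer")
  if (length(pol) > 1L) {
    same_chain <- outer(v$chain[pol], v$chain[pol], "==")
    dseq <- abs(outer(v$seq_id[pol], v$seq_id[pol], "-"))
    bonded[pol, pol] <- same_chain & dseq == 1L
  }
  dimnames(bonded) <- dimnames(adj)
  attr(adj, "bonded") <- bonded
  adj
}

#' Residue interaction network of one frame
#'
#' Vertices are the polymer residues plus each ligand group as a single
#' vertex; edges are contacts under the dialect.  Vertex attributes carry
#' the chemical class (positive, negative, aromatic, other; ligands as
#' `"ligand"`).
#'
#' @param frame a `flexrin_frame`.
#' @param dialect a [contact_dialect()].
#' @param include_ligands include ligand groups as vertices.
#' @param exclude_bonded drop edges between sequence-adjacent polymer
#'   residues.
#' @return object of class `rin_graph`: list with `vertices`, `adjacency`
#'   (binary symmetric, zero diagonal), `dialect`.
#' @export
build_rin <- function(frame, dialect = contact_dialect(),
                      include_ligands = TRUE, exclude_bonded = FALSE) {
  dmap <- distance_map(frame, dialect, include_ligands)
  adj <- contact_map(dmap)
  if (exclude_bonded) adj[attr(adj, "bonded")] <- 0L
  bonded <- attr(adj, "bonded")
  attr(adj, "bonded") <- NULL
  g <- list(vertices = dmap$vertices, adjacency = adj, bonded = bonded,
            dialect = dmap$dialect)
  class(g) <- "rin_graph"
  g
}

#' @export
print.rin_graph <- function(x, ...) {
  cat(sprintf("<rin_graph [%s, cutoff %.1f]: %d vertices, %d edges>\n",
              x$dialect$mode, x$dialect$cutoff, nrow(x$vertices),
              sum(x$adjacency) / 2L))
  invisible(x)
}

#' Convert a RIN to an igraph object
#'
#' Requires the `igraph` package; vertex attributes `kind` and `class` are
#' carried over.
#'
#' @param rin a `rin_graph`.
#' @return an `igraph` graph.
#' @export
as_igraph <- function(rin) {
  if (!requireNamespace("igraph", quietly = TRUE))
    stop("the igraph package is required for as_igraph()")
  g <- igraph::graph_from_adjacency_matrix(rin$adjacency, mode = "undirected")
  igraph::vertex_attr(g, "kind") <- rin$vertices$kind
  igraph::vertex_attr(g, "class") <- rin$vertices$class
  g
}

#' Write a RIN edge list as TSV
#'
#' Columns `vertex_a`, `vertex_b`, plus the vertex classes; one row per
#' undirected edge (upper triangle).
#'
#' @param rin a `rin_graph`.
#' @param path output path.
#' @export
write_rin_edges <- function(rin, path) {
  idx <- which(upper.tri(rin$adjacency) & rin$adjacency == 1L,
               arr.ind = TRUE)
  d <- data.frame(vertex_a = rin$vertices$key[idx[, 1L]],
                  vertex_b = rin$vertices$key[idx[, 2L]],
                  class_a = rin$vertices$class[idx[, 1L]],
                  class_b = rin$vertices$class[idx[, 2L]],
                  bonded = rin$bonded[idx],
                  stringsAsFactors = FALSE)
  d <- d[order(d$vertex_a, d$vertex_b), , drop = FALSE]
  utils::write.table(d, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Rank-based similarity between two square maps
#'
#' Spearman rank correlation over the strict upper-triangle entries.  Used
#' to quantify how well a structural distance map mirrors a predicted
#' aligned error (PAE) map: both express which residue pairs are mutually
#' constrained, on different scales, so a rank statistic is the natural
#' comparison.
#'
#' @param a,b square numeric matrices of equal dimension (a `distance_map`
#'   is also accepted).
#' @return Spearman correlation in \[-1, 1\].
#' @export
map_similarity <- function(a, b) {
  if (inherits(a, "distance_map")) a <- a$matrix
  if (inherits(b, "distance_map")) b <- b$matrix
  a <- as.matrix(a); b <- as.matrix(b)
  if (!all(dim(a) == dim(b))) stop("maps differ in dimension")
  ut <- upper.tri(a)
  stats::cor(a[ut], b[ut], method = "spearman")
}
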