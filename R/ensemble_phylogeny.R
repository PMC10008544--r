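# Pairwise structural RMSD matrix over frames/models and its conversion to
# a neighbor-joining tree with Newick output.

#' Pairwise C-alpha RMSD matrix over frames
#'
#' Entry (i, j) is the C-alpha RMSD after Kabsch superposition of frame j
#' onto frame i; each pair is computed once, so the matrix is symmetric by
#' construction.  Note RMSD after independent pairwise superpositions is
#' not a metric -- no triangle inequality is implied.
#'
#' @param frames a `flexrin_ensemble` or list of `flexrin_frame` objects
#'   with identical polymer topology.
#' @return object of class `rmsd_matrix`: list with `labels` and `matrix`
#'   (symmetric, zero diagonal, Angstrom).
#' @export
pairwise_rmsd_matrix <- function(frames) {
  if (inherits(frames, "flexrin_ensemble")) {
    ens <- frames
  } else {
    ens <- as_ensemble(frames)
  }
  nf <- n_frames(ens)
  if (nf < 3L) stop("need at least 3 frames")
  ca <- ca_indices(ens$atoms)
  if (length(ca) < 3L) stop("need at least 3 C-alpha atoms")
  M <- matrix(0, nf, nf)
  for (i in seq_len(nf - 1L)) {
    ref <- ens$xyz[ca, , i]
    for (j in seq((i + 1L), nf)) {
      M[i, j] <- M[j, i] <- superpose(ens$xyz[ca, , j], ref)$rmsd
    }
  }
  dimnames(M) <- list(ens$frame_labels, ens$frame_labels)
  out <- list(labels = ens$frame_labels, matrix = M)
  class(out) <- "rmsd_matrix"
  out
}

#' Mean and sd of the off-diagonal entries of a distance matrix
#'
#' The overall pairwise structural spread of a set of models: mean +/- sd
#' over all unordered pairs.
#'
#' @param dm an `rmsd_matrix` or square symmetric matrix.
#' @return list with `mean` and `sd`.
#' @export
matrix_summary <- function(dm) {
  M <- if (inherits(dm, "rmsd_matrix")) dm$matrix else as.matrix(dm)
  v <- M[upper.tri(M)]
  list(mean = mean(v), sd = stats::sd(v))
}

#' Neighbor-joining tree from a distance matrix
#'
#' Saitou-Nei neighbor joining: iteratively join the pair minimising
#' `Q(i, j) = (n - 2) d(i, j) - sum_k d(i, k) - sum_k d(j, k)`, with branch
#' lengths from the standard NJ formulas.  Ties in Q are broken by the
#' lexicographically smallest label pair, making the output deterministic.
#' Negative branch lengths (possible on non-additive input) are clamped to
#' zero with a warning.  NJ reconstructs any additive (tree-derived)
#' distance matrix exactly.
#'
#' @param dm an `rmsd_matrix`, or a square symmetric matrix with labelled
#'   rows/columns.
#' @return an unrooted `phylo` tree (ape format).
#' @export
neighbor_joining <- function(dm) {
  if (inherits(dm, "rmsd_matrix")) {
    M <- dm$matrix; labels <- dm$labels
  } else {
    M <- as.matrix(dm)
    labels <- rownames(M) %||% as.character(seq_len(nrow(M)))
  }
  n <- nrow(M)
  if (n < 3L) stop("neighbor joining needs at least 3 labels")
  if (max(abs(M - t(M))) > 1e-8) stop("distance matrix is not symmetric")
  storage.mode(M) <- "double"

  n_tips <- n
  next_node <- n_tips + 1L          # internal node ids grow upward
  active_id <- seq_len(n_tips)      # node ids of active rows of M
  active_lab <- labels              # labels used for tie-breaking
  edges <- matrix(0L, 0L, 2L)
  lens <- numeric(0L)
  add_edge <- function(parent, child, len) {
    edges <<- rbind(edges, c(parent, child))
    lens <<- c(lens, len)
  }

  while (length(active_id) > 3L) {
    nn <- length(active_id)
    r <- rowSums(M)
    Q <- (nn - 2) * M - outer(r, r, "+")
    diag(Q) <- Inf
    qmin <- min(Q)
    cand <- which(Q - qmin <= 1e-12 * max(1, abs(qmin)), arr.ind = TRUE)
    cand <- cand[cand[, 1L] < cand[, 2L], , drop = FALSE]
    key <- vapply(seq_len(nrow(cand)), function(k) {
      pr <- sort(c(active_lab[cand[k, 1L]], active_lab[cand[k, 2L]]))
      paste(pr, collapse = "\r")
    }, character(1L))
    pick <- cand[order(key)[1L], ]
    i <- min(pick); j <- max(pick)
    dij <- M[i, j]
    li <- dij / 2 + (r[i] - r[j]) / (2 * (nn - 2))
    lj <- dij - li
    u <- next_node; next_node <- next_node + 1L
    add_edge(u, active_id[i], li)
    add_edge(u, active_id[j], lj)
    du <- (M[i, ] + M[j, ] - dij) / 2
    keep <- setdiff(seq_len(nn), c(i, j))
    M <- rbind(cbind(M[keep, keep, drop = FALSE], du[keep]),
               c(du[keep], 0))
    active_id <- c(active_id[keep], u)
    active_lab <- c(active_lab[keep],
                    paste0("\001", sprintf("%06d", u)))  # internal labels sort last
  }

  # final trifurcation: three-point formulas
  d12 <- M[1L, 2L]; d13 <- M[1L, 3L]; d23 <- M[2L, 3L]
  u <- next_node
  add_edge(u, active_id[1L], (d12 + d13 - d23) / 2)
  add_edge(u, active_id[2L], (d12 + d23 - d13) / 2)
  add_edge(u, active_id[3L], (d13 + d23 - d12) / 2)

  if (any(lens < 0)) {
    warning("negative neighbor-joining branch length(s) clamped to 0")
    lens[lens < 0] <- 0
  }

  # renumber internal nodes so the final join is n_tips + 1 (ape root
  # convention) and the rest follow in preorder
  n_internal <- next_node - n_tips
  new_id <- integer(next_node)
  new_id[seq_len(n_tips)] <- seq_len(n_tips)
  counter <- n_tips + 1L
  assign_ids <- function(node) {
    new_id[node] <<- counter
    counter <<- counter + 1L
    for (child in edges[edges[, 1L] == node, 2L]) {
      if (child > n_tips) assign_ids(child)
    }
  }
  assign_ids(u)
  tree <- list(edge = cbind(new_id[edges[, 1L]], new_id[edges[, 2L]]),
               edge.length = lens,
               tip.label = labels,
               Nnode = n_internal)
  class(tree) <- "phylo"
  attr(tree, "order") <- NULL
  ape::reorder.phylo(tree, "cladewise")
}

#' Write a tree in Newick format
#'
#' Branch lengths at 6 significant digits; labels containing spaces or
#' Newick metacharacters are single-quoted so the file parses back
#' (e.g. with `ape::read.tree`) to an isomorphic tree.
#'
#' @param tree a `phylo` tree.
#' @param path output path.
#' @return the Newick string, invisibly.
#' @export
write_newick <- function(tree, path) {
  stopifnot(inherits(tree, "phylo"))
  n_tips <- length(tree$tip.label)
  kids <- split(seq_len(nrow(tree$edge)), tree$edge[, 1L])
  quote_label <- function(x) {
    if (grepl("[][ ():;,']", x)) {
      paste0("'", gsub("'", "''", x), "'")
    } else x
  }
  fmt_len <- function(l) {
    if (is.null(l) || is.na(l)) "" else paste0(":", signif(l, 6L))
  }
  rec <- function(node, len) {
    if (node <= n_tips) {
      paste0(quote_label(tree$tip.label[node]), fmt_len(len))
    } else {
      ch <- kids[[as.character(node)]]
      inner <- vapply(ch, function(e)
        rec(tree$edge[e, 2L], tree$edge.length[e]), character(1L))
      paste0("(", paste(inner, collapse = ","), ")", fmt_len(len))
    }
  }
  root <- n_tips + 1L
  nwk <- paste0(rec(root, NA_real_), ";")
  writeLines(nwk, path)
  invisible(nwk)
}

#' Bipartitions (splits) of an unrooted tree, with branch lengths
#'
#' Every edge of the tree splits the leaf set in two; the side not
#' containing the first tip, written as a sorted label set, is a canonical
#' representation of the split.  Two unrooted trees are isomorphic iff
#' their split sets match; used for topology comparison in tests and
#' reporting.
#'
#' @param tree a `phylo` tree.
#' @return data frame with columns `split` (semicolon-joined sorted labels)
#'   and `length`.
#' @export
tree_bipartitions <- function(tree) {
  n_tips <- length(tree$tip.label)
  kids <- split(seq_len(nrow(tree$edge)), tree$edge[, 1L])
  below <- function(node) {
    if (node <= n_tips) return(tree$tip.label[node])
    unlist(lapply(kids[[as.character(node)]],
                  function(e) below(tree$edge[e, 2L])))
  }
  anchor <- sort(tree$tip.label)[1L]
  splits <- character(nrow(tree$edge))
  for (e in seq_len(nrow(tree$edge))) {
    side <- sort(below(tree$edge[e, 2L]))
    if (anchor %in% side)
      side <- sort(setdiff(tree$tip.label, side))
    splits[e] <- paste(side, collapse = ";")
  }
  d <- data.frame(split = splits, length = tree$edge.length,
                  stringsAsFactors = FALSE)
  # merge the two root-adjacent edges of a rooted representation: not
  # needed for our unrooted trifurcating trees, but tolerate duplicates by
  # summing lengths (the unrooted view of a rooted tree)
  agg <- stats::aggregate(length ~ split, data = d, FUN = sum)
  agg <- agg[agg$split != "", , drop = FALSE]
  agg[order(agg$split), , drop = FALSE]
}
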