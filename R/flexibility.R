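# RMSF, RMSD series, the reverse-normalised confidence score, and the
# Pearson concordance between predicted confidence and observed flexibility.

#' Least-squares rigid superposition (Kabsch)
#'
#' Finds the proper rotation `R` (det = +1) and translation `t` minimising
#' the RMSD between `mobile %*% t(R) + t` and `reference` over the paired
#' points.  The reflection branch of the SVD solution is corrected by a sign
#' flip on the smallest singular vector, so mirror-image inputs yield a
#' genuine rotation with a non-zero residual rather than an improper
#' transform.
#'
#' @param mobile n x 3 coordinate matrix to be moved.
#' @param reference n x 3 coordinate matrix to move onto.
#' @param pairing optional 2-column integer matrix of (mobile, reference)
#'   row pairs; default pairs rows 1:1.
#' @return object of class `rigid_transform`: list with `rotation` (3 x 3),
#'   `translation` (length 3) and `rmsd` over the pairing.
#' @export
superpose <- function(mobile, reference, pairing = NULL) {
  mobile <- as.matrix(mobile); reference <- as.matrix(reference)
  if (is.null(pairing)) {
    if (nrow(mobile) != nrow(reference))
      stop("mobile and reference differ in size; supply a pairing")
    pairing <- cbind(seq_len(nrow(mobile)), seq_len(nrow(reference)))
  }
  m <- mobile[pairing[, 1L], , drop = FALSE]
  r <- reference[pairing[, 2L], , drop = FALSE]
  if (nrow(m) < 3L) stop("superposition needs at least 3 paired points")
  mc <- colMeans(m); rc <- colMeans(r)
  m0 <- sweep(m, 2L, mc); r0 <- sweep(r, 2L, rc)
  sv_m <- svd(m0)$d
  if (sv_m[2L] < 1e-9 * max(sv_m[1L], 1e-12))
    stop("degenerate geometry: paired points are collinear")
  H <- crossprod(m0, r0)           # sum over pairs of m_i r_i^T
  s <- svd(H)
  d <- sign(det(s$v %*% t(s$u)))
  if (d == 0) d <- 1
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  tr <- rc - as.vector(R %*% mc)
  moved <- m %*% t(R) + matrix(tr, nrow(m), 3L, byrow = TRUE)
  rmsd <- sqrt(mean(rowSums((moved - r)^2)))
  out <- list(rotation = R, translation = tr, rmsd = rmsd)
  class(out) <- "rigid_transform"
  out
}

#' @export
print.rigid_transform <- function(x, ...) {
  cat(sprintf("<rigid_transform: rmsd %.4g Angstrom>\n", x$rmsd))
  invisible(x)
}

#' Apply a rigid transform to coordinates
#' @param xyz n x 3 matrix.
#' @param transform a `rigid_transform`.
#' @return transformed n x 3 matrix.
#' @export
apply_transform <- function(xyz, transform) {
  xyz <- as.matrix(xyz)
  xyz %*% t(transform$rotation) +
    matrix(transform$translation, nrow(xyz), 3L, byrow = TRUE)
}

#' Compose two rigid transforms
#'
#' `compose_transforms(b, a)` is the transform "first `a`, then `b`".
#' @param b,a `rigid_transform` objects.
#' @export
compose_transforms <- function(b, a) {
  out <- list(rotation = b$rotation %*% a$rotation,
              translation = as.vector(b$rotation %*% a$translation) +
                b$translation,
              rmsd = NA_real_)
  class(out) <- "rigid_transform"
  out
}

ca_indices <- function(atoms) {
  which(atoms$kind == "polymer" & atoms$name == "CA")
}

# Superpose every frame of an ensemble onto a reference frame using all
# C-alpha atoms; returns the ensemble with transformed coordinates.
superpose_ensemble <- function(ensemble, reference_frame = 1L) {
  ca <- ca_indices(ensemble$atoms)
  if (length(ca) < 3L) stop("need at least 3 C-alpha atoms to superpose")
  ref <- ensemble$xyz[ca, , reference_frame]
  out <- ensemble
  for (t in seq_len(n_frames(ensemble))) {
    tf <- superpose(ensemble$xyz[ca, , t], ref)
    out$xyz[, , t] <- apply_transform(ensemble$xyz[, , t], tf)
  }
  out
}

#' Per-residue root-mean-square fluctuation of an ensemble
#'
#' `RMSF_i = sqrt(mean_t |r_i(t) - rbar_i|^2)` with `rbar_i` the
#' across-frame mean position of residue `i`'s selected atom(s).  By default
#' every frame is first superposed onto the first frame over all C-alpha
#' atoms, so global rigid drift does not inflate the profile.  With
#' `selection = "heavy"` the per-atom RMSF is averaged over the residue's
#' heavy atoms.
#'
#' @param ensemble a `flexrin_ensemble` with >= 2 frames.
#' @param selection `"calpha"` or `"heavy"`.
#' @param do_superpose superpose frames onto frame 1 first (default `TRUE`).
#' @return a `residue_profile` of kind `"rmsf"` (Angstrom).
#' @export
rmsf <- function(ensemble, selection = c("calpha", "heavy"),
                 do_superpose = TRUE) {
  selection <- match.arg(selection)
  if (n_frames(ensemble) < 2L)
    stop("RMSF needs at least 2 frames")
  if (do_superpose) ensemble <- superpose_ensemble(ensemble, 1L)
  a <- ensemble$atoms
  rt <- residue_table(a)
  atom_rmsf <- function(idx) {
    # per-atom fluctuation about the across-frame mean position
    vapply(idx, function(j) {
      p <- ensemble$xyz[j, , , drop = FALSE]   # 1 x 3 x nf
      mu <- rowMeans(p[1L, , ])
      sqrt(mean(colSums((p[1L, , ] - mu)^2)))
    }, numeric(1L))
  }
  if (selection == "calpha") {
    ca <- ca_indices(a)
    keys <- paste0(a$chain[ca], ":", a$seq_id[ca])
    vals <- atom_rmsf(ca)[match(rt$key, keys)]
  } else {
    idx_by_res <- residue_atom_index(a, heavy_only = TRUE)
    vals <- vapply(rt$key, function(k) mean(atom_rmsf(idx_by_res[[k]])),
                   numeric(1L))
  }
  new_profile(rt$chain, rt$seq_id, rt$res_name, vals, "rmsf")
}

#' Reverse min-max normalised confidence score
#'
#' `score_i = (plddt_max - plddt_i) / (plddt_max - plddt_min)`, with the
#' extrema taken over the profile itself.  High score means low confidence,
#' i.e. predicted flexibility; the score is invariant under any positive
#' affine rescaling of the confidence profile and spans \[0, 1\] whenever
#' the input is non-constant.  A constant profile maps to all zeros (with a
#' warning) so pipelines on degenerate fragments do not abort.
#'
#' @param plddt a `residue_profile` of confidence values.
#' @return a `residue_profile` of kind `"af2"`.
#' @export
af2_score <- function(plddt) {
  if (!nrow(plddt)) stop("empty confidence profile")
  v <- plddt$value
  rng <- max(v) - min(v)
  if (rng == 0) {
    warning("constant confidence profile: scores set to 0")
    s <- rep(0, length(v))
  } else {
    s <- (max(v) - v) / rng
  }
  new_profile(plddt$chain, plddt$seq_id, plddt$res_name, s, "af2")
}

#' Pearson concordance between two residue profiles
#'
#' Sample Pearson correlation with a two-sided p-value from
#' `t = r * sqrt((n - 2) / (1 - r^2))` against Student's t with `n - 2`
#' degrees of freedom.  Both profiles must cover the same residues, in the
#' same order, and be non-constant.
#'
#' @param a,b `residue_profile` objects over identical residue keys.
#' @return list with `pcc`, `p_value`, `n` (class `concordance_result`).
#' @export
pearson_concordance <- function(a, b) {
  if (nrow(a) != nrow(b) ||
      any(a$chain != b$chain) || any(a$seq_id != b$seq_id))
    stop("profiles cover different residues")
  n <- nrow(a)
  if (n < 3L) stop("concordance needs at least 3 residues")
  if (stats::sd(a$value) == 0 || stats::sd(b$value) == 0)
    stop("correlation undefined for a constant profile")
  r <- stats::cor(a$value, b$value)
  if (abs(r) >= 1) {
    p <- 0
  } else {
    tstat <- r * sqrt((n - 2) / (1 - r^2))
    p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  }
  out <- list(pcc = r, p_value = p, n = n)
  class(out) <- "concordance_result"
  out
}

#' @export
print.concordance_result <- function(x, ...) {
  cat(sprintf("<concordance: PCC %.3f, p %.3g, n %d>\n",
              x$pcc, x$p_value, x$n))
  invisible(x)
}

#' Per-frame C-alpha RMSD against a reference frame
#'
#' Each frame is superposed onto the reference over all C-alpha atoms; the
#' value for the reference frame itself is 0.
#'
#' @param ensemble a `flexrin_ensemble`.
#' @param reference_frame index of the reference frame (default 1).
#' @return data frame (class `rmsd_series`) with columns `frame_label`,
#'   `rmsd`.
#' @export
rmsd_series <- function(ensemble, reference_frame = 1L) {
  nf <- n_frames(ensemble)
  if (reference_frame < 1L || reference_frame > nf)
    stop("reference frame index out of range")
  ca <- ca_indices(ensemble$atoms)
  if (length(ca) < 3L) stop("need at least 3 C-alpha atoms")
  ref <- ensemble$xyz[ca, , reference_frame]
  vals <- vapply(seq_len(nf), function(t) {
    if (t == reference_frame) return(0)
    superpose(ensemble$xyz[ca, , t], ref)$rmsd
  }, numeric(1L))
  out <- data.frame(frame_label = ensemble$frame_labels, rmsd = vals,
                    stringsAsFactors = FALSE)
  class(out) <- c("rmsd_series", "data.frame")
  out
}

#' Mean and sd over the trailing part of an RMSD series
#'
#' Summarises the equilibrated tail of a trajectory: the trailing
#' `ceil(tail_fraction * n)` entries.
#'
#' @param series an `rmsd_series` (or numeric vector).
#' @param tail_fraction fraction of the series to keep, in (0, 1\].
#' @return list with `mean` and `sd` (Angstrom; `sd` is the sample sd, 0
#'   for a single entry).
#' @export
tail_mean <- function(series, tail_fraction = 0.1) {
  v <- if (is.data.frame(series)) series$rmsd else as.numeric(series)
  if (!length(v)) stop("empty series")
  if (tail_fraction <= 0 || tail_fraction > 1)
    stop("tail_fraction must be in (0, 1]")
  k <- ceiling(tail_fraction * length(v))
  tl <- v[(length(v) - k + 1L):length(v)]
  list(mean = mean(tl), sd = if (length(tl) > 1L) stats::sd(tl) else 0)
}
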