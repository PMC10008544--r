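# Synthetic conformer ensembles with known ground truth: a clash-free helical
# base fold, rigid-residue Gaussian jitter with a prescribed per-residue sigma
# profile, confidence profiles anti-correlated with that sigma, and ligand
# groups whose contacts with chosen residues occur in an exact fraction of
# frames.

# Run `expr` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  eval.parent(substitute(expr))
}

#' Per-residue fluctuation profile with rigid core and flexible termini
#'
#' Builds the ground-truth per-residue displacement scale `sigma_i` (Angstrom,
#' per coordinate): `sigma_core` in the folded core, ramping linearly up to
#' `sigma_term` over the `ramp_len` residues at each terminus.  This is the
#' shape of fluctuation profiles seen in well-folded globular proteins, where
#' loops and termini move and the core does not.
#'
#' @param n_residues chain length.
#' @param sigma_core core per-coordinate sd, Angstrom.
#' @param sigma_term terminal per-coordinate sd, Angstrom.
#' @param ramp_len number of residues over which sigma ramps at each end.
#' @return numeric vector of length `n_residues`.
#' @export
sigma_profile <- function(n_residues, sigma_core = 0.3, sigma_term = 1.5,
                          ramp_len = 10L) {
  stopifnot(n_residues >= 1L, sigma_core > 0, sigma_term > 0, ramp_len >= 1L)
  i <- seq_len(n_residues)
  dist_end <- pmin(i - 1L, n_residues - i)
  w <- pmax(0, 1 - dist_end / ramp_len)
  sigma_core + (sigma_term - sigma_core) * w
}

#' Specification of a synthetic ensemble
#'
#' Bundles everything needed to generate a deterministic ground-truth
#' ensemble: chain length, per-residue sigma profile, frame count, seed,
#' the confidence-model parameters (`plddt = clamp(95 - slope * sigma +
#' noise, 0, 100)`), and ligand contact schedules.
#'
#' @param n_residues chain length (>= 2).
#' @param n_frames number of frames (>= 1).
#' @param seed integer seed; the whole generation is a pure function of it.
#' @param sigma per-residue sd vector (Angstrom); default [sigma_profile()].
#' @param plddt_slope confidence lost per Angstrom of sigma (> 0).
#' @param plddt_noise_sd sd of the Gaussian noise added to the confidence.
#' @param ligand_schedules list of [ligand_schedule()] entries.
#' @return an object of class `synth_spec`.
#' @export
synth_spec <- function(n_residues = 60L, n_frames = 100L, seed = 1L,
                       sigma = sigma_profile(n_residues),
                       plddt_slope = 10, plddt_noise_sd = 5,
                       ligand_schedules = list()) {
  stopifnot(n_residues >= 2L, n_frames >= 1L, length(sigma) == n_residues,
            all(sigma > 0), plddt_slope > 0, plddt_noise_sd >= 0)
  for (s in ligand_schedules) stopifnot(inherits(s, "ligand_schedule"))
  sp <- list(n_residues = as.integer(n_residues),
             n_frames = as.integer(n_frames), seed = as.integer(seed),
             sigma = as.numeric(sigma), plddt_slope = plddt_slope,
             plddt_noise_sd = plddt_noise_sd,
             ligand_schedules = ligand_schedules)
  class(sp) <- "synth_spec"
  sp
}

#' Ligand contact schedule
#'
#' Prescribes that a rigid ligand group sits at distance `d_on` (< 3.5
#' Angstrom, i.e. in contact) from a target residue in an exact fraction `f`
#' of frames, and at `d_off` (> 3.5, out of contact) otherwise.  Contact
#' frames are drawn without replacement from a seeded RNG, so the realised
#' contact count is exactly `round(f * n_frames)`.
#'
#' @param label ligand group label (e.g. `"BVQ"`).
#' @param target_seq `seq_id` of the target polymer residue.
#' @param fraction contact fraction `f` in \[0, 1\].
#' @param d_on contact distance, Angstrom (must be < 3.5).
#' @param d_off off distance, Angstrom (must be > 3.5).
#' @param res_name 3-letter residue name used in PDB output (default: first
#'   3 characters of `label`).
#' @param chain target chain id.
#' @export
ligand_schedule <- function(label, target_seq, fraction, d_on = 3.0,
                            d_off = 6.0, res_name = NULL, chain = "A") {
  stopifnot(fraction >= 0, fraction <= 1, d_on < 3.5, d_off > 3.5, d_on > 0)
  res_name <- res_name %||% toupper(substr(label, 1L, 3L))
  s <- list(label = label, target_seq = as.integer(target_seq),
            fraction = fraction, d_on = d_on, d_off = d_off,
            res_name = res_name, chain = chain)
  class(s) <- "ligand_schedule"
  s
}

#' Build an idealised helical base fold
#'
#' Lays C-alpha atoms on an alpha-helical trace (rise 1.5 Angstrom, radius
#' 2.3 Angstrom, 100 degrees per residue).  The backbone N and C of each
#' residue sit on the same helical sweep a third of a residue before and
#' after the C-alpha, the carbonyl O points radially outward from C, and a
#' C-beta sidechain pseudo-atom (omitted for GLY) sits 1.5 Angstrom
#' radially outward from the C-alpha.  The construction gives consecutive
#' C-alpha spacing of ~3.83 Angstrom, plausible bond lengths, and no
#' non-bonded heavy-atom pair closer than 2.0 Angstrom, so contact
#' analyses on the unperturbed fold see only genuine neighbours.
#'
#' @param n_residues chain length (>= 2).
#' @param seed seed used to draw the residue-name sequence.
#' @param res_names optional explicit 3-letter residue names (length
#'   `n_residues`); overrides the seeded draw.
#' @return a `flexrin_frame`.
#' @export
make_base_fold <- function(n_residues, seed = 1L, res_names = NULL) {
  if (n_residues < 2L) stop("n_residues must be >= 2")
  if (is.null(res_names)) {
    res_names <- with_seed(seed,
      sample(names(AA3TO1), n_residues, replace = TRUE))
  }
  stopifnot(length(res_names) == n_residues)
  rise <- 1.5; radius <- 2.3; twist <- 100 * pi / 180
  helix <- function(s) c(radius * cos(s * twist), radius * sin(s * twist),
                         s * rise)
  outward <- function(s) c(cos(s * twist), sin(s * twist), 0)
  atoms <- list(); xyz <- list(); serial <- 0L
  for (r in seq_len(n_residues)) {
    s <- r - 1
    nm <- c("N", "CA", "C", "O")
    el <- c("N", "C", "C", "O")
    pos <- rbind(
      helix(s - 0.33),
      helix(s),
      helix(s + 0.33),
      helix(s + 0.33) + 1.23 * outward(s + 0.33)
    )
    if (res_names[r] != "GLY") {
      nm <- c(nm, "CB"); el <- c(el, "C")
      pos <- rbind(pos, helix(s) + 1.5 * outward(s))
    }
    k <- length(nm)
    atoms[[r]] <- data.frame(
      serial = serial + seq_len(k), name = nm, element = el,
      chain = "A", seq_id = r, res_name = res_names[r], kind = "polymer",
      group = NA_character_, occupancy = 1, bfactor = 0,
      stringsAsFactors = FALSE)
    xyz[[r]] <- pos
    serial <- serial + k
  }
  structure_frame(do.call(rbind, atoms), do.call(rbind, xyz),
                  frame_label = "base")
}

#' Sample a conformer ensemble around a base fold
#'
#' Frame `t`, residue `i`: all atoms of residue `i` are displaced by one
#' shared draw from an isotropic Gaussian with per-coordinate sd `sigma_i`
#' (rigid-residue jitter).  With this construction the exact expected RMSF
#' (without superposition) is `sqrt(3) * sigma_i`.  Ligand schedules in the
#' spec are then realised by [place_ligand_schedule()].  The whole ensemble
#' is a deterministic function of `spec$seed`.
#'
#' @param base a `flexrin_frame` from [make_base_fold()] (polymer only).
#' @param spec a [synth_spec()].
#' @return a `flexrin_ensemble` with source `"trajectory"`.
#' @export
sample_ensemble <- function(base, spec) {
  stopifnot(inherits(base, "flexrin_frame"), inherits(spec, "synth_spec"))
  rt <- residue_table(base$atoms)
  if (nrow(rt) != spec$n_residues || length(spec$sigma) != nrow(rt))
    stop("sigma profile length does not match the residue count of the base fold")
  nf <- spec$n_frames
  nres <- nrow(rt)
  res_of_atom <- match(paste0(base$atoms$chain, ":", base$atoms$seq_id), rt$key)
  # displacement draws: residue-major within frame, frames in order
  disp <- with_seed(spec$seed, {
    array(stats::rnorm(nres * 3L * nf, sd = rep(spec$sigma, times = 3L * nf)),
          dim = c(nres, 3L, nf))
  })
  xyz <- array(0, dim = c(nrow(base$atoms), 3L, nf))
  for (t in seq_len(nf)) {
    xyz[, , t] <- base$xyz + disp[res_of_atom, , t]
  }
  ens <- list(atoms = base$atoms, xyz = xyz,
              frame_labels = as.character(seq_len(nf)),
              source = "trajectory")
  class(ens) <- "flexrin_ensemble"
  for (k in seq_along(spec$ligand_schedules)) {
    ens <- place_ligand_schedule(base, ens, spec$ligand_schedules[[k]],
                                 seed = spec$seed + 1000L * k)
  }
  ens
}

#' Place a scheduled ligand group into an ensemble
#'
#' Appends a rigid 3-atom ligand group.  In exactly `round(f * n_frames)`
#' frames (a seeded draw without replacement) its nearest heavy atom sits at
#' `d_on` from the target residue's C-beta (C-alpha for GLY) along the
#' outward radial direction of the helix; in all other frames at `d_off`.
#' The placement follows the jittered anchor, so realised contact distances
#' are exact in every frame.
#'
#' @param base the base fold the ensemble was sampled from.
#' @param ensemble a `flexrin_ensemble` over the same polymer topology.
#' @param schedule a [ligand_schedule()].
#' @param seed seed for the contact-frame draw.
#' @return a new `flexrin_ensemble` including the ligand group.
#' @export
place_ligand_schedule <- function(base, ensemble, schedule, seed = 1L) {
  stopifnot(inherits(schedule, "ligand_schedule"))
  a <- ensemble$atoms
  rt <- residue_table(a)
  key <- residue_key(schedule$chain, schedule$target_seq)
  if (!key %in% rt$key)
    stop("target residue ", key, " not present in the ensemble")
  is_gly <- rt$res_name[rt$key == key] == "GLY"
  anchor_name <- if (is_gly) "CA" else "CB"
  anchor_idx <- which(a$kind == "polymer" &
                      a$chain == schedule$chain &
                      a$seq_id == schedule$target_seq &
                      a$name == anchor_name)
  if (!length(anchor_idx))
    stop("target residue ", key, " has no ", anchor_name, " anchor atom")
  anchor_idx <- anchor_idx[1L]
  nf <- n_frames(ensemble)
  n_on <- round(schedule$fraction * nf)
  on_frames <- if (n_on > 0L) with_seed(seed, sort(sample.int(nf, n_on)))
               else integer()
  # rigid internal geometry in the (outward radial, z) frame of the anchor
  offsets <- rbind(c(0, 0), c(1.4, 0), c(1.4, 1.4))  # (along u, along z)
  lig_atoms <- data.frame(
    serial = max(a$serial) + 1:3,
    name = c("L1", "L2", "L3"),
    element = c("C", "C", "O"),
    chain = "L",
    seq_id = max(a$seq_id) + 1L,
    res_name = schedule$res_name,
    kind = "ligand", group = schedule$label,
    occupancy = 1, bfactor = 0, stringsAsFactors = FALSE)
  n_old <- nrow(a)
  xyz <- array(0, dim = c(n_old + 3L, 3L, nf))
  xyz[seq_len(n_old), , ] <- ensemble$xyz
  for (t in seq_len(nf)) {
    p <- ensemble$xyz[anchor_idx, , t]
    u <- c(p[1L], p[2L], 0)
    nu <- sqrt(sum(u^2))
    u <- if (nu > 1e-9) u / nu else c(1, 0, 0)
    d <- if (t %in% on_frames) schedule$d_on else schedule$d_off
    base_pt <- p + d * u
    xyz[n_old + 1:3, , t] <-
      rep(base_pt, each = 3L) + outer(offsets[, 1L], u) +
      outer(offsets[, 2L], c(0, 0, 1))
  }
  out <- list(atoms = rbind(a, lig_atoms), xyz = xyz,
              frame_labels = ensemble$frame_labels, source = ensemble$source)
  class(out) <- "flexrin_ensemble"
  out
}

#' Synthesise a confidence profile anti-correlated with flexibility
#'
#' `plddt_i = clamp(95 - slope * sigma_i + eta_i, 0, 100)` with `eta_i ~
#' N(0, noise_sd^2)`, seeded.  With `noise_sd = 0` the profile is an exact
#' decreasing affine function of `sigma`, so the reverse-normalised
#' confidence score correlates perfectly with the ground-truth flexibility.
#'
#' @param sigma per-residue sd vector (Angstrom).
#' @param slope confidence lost per Angstrom (> 0).
#' @param noise_sd Gaussian noise sd.
#' @param seed RNG seed.
#' @param base a `flexrin_frame` supplying residue keys, or `NULL` for
#'   generic keys.
#' @return a `residue_profile` of kind `"plddt"`.
#' @export
synth_plddt <- function(sigma, slope = 10, noise_sd = 0, seed = 1L,
                        base = NULL) {
  stopifnot(slope > 0, noise_sd >= 0)
  n <- length(sigma)
  eta <- if (noise_sd > 0) with_seed(seed, stats::rnorm(n, sd = noise_sd))
         else numeric(n)
  vals <- pmin(pmax(95 - slope * sigma + eta, 0), 100)
  if (!is.null(base)) {
    rt <- residue_table(base$atoms)
    stopifnot(nrow(rt) == n)
    new_profile(rt$chain, rt$seq_id, rt$res_name, vals, "plddt")
  } else {
    new_profile(rep("A", n), seq_len(n), rep(NA_character_, n), vals, "plddt")
  }
}
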