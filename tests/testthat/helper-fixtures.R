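# Shared fixtures and independent brute-force oracles.

# Minimal atom-table row constructor.
atom_row <- function(serial, name, element, chain, seq_id, res_name,
                     kind = "polymer", group = NA_character_,
                     occupancy = 1, bfactor = 0) {
  data.frame(serial = serial, name = name, element = element, chain = chain,
             seq_id = seq_id, res_name = res_name, kind = kind,
             group = group, occupancy = occupancy, bfactor = bfactor,
             stringsAsFactors = FALSE)
}

# A hand-built frame: residue list of lists(name, res_name, atoms = data
# frame with name, element, x, y, z), plus optional ligand groups.
toy_frame <- function(residues, ligands = list(), chain = "A") {
  atoms <- list(); xyz <- list(); serial <- 0L
  seq_id <- 0L
  for (r in residues) {
    seq_id <- seq_id + 1L
    k <- nrow(r$atoms)
    atoms[[length(atoms) + 1L]] <- atom_row(
      serial + seq_len(k), r$atoms$name, r$atoms$element, chain, seq_id,
      r$res_name, bfactor = r$bfactor %||% 0)
    xyz[[length(xyz) + 1L]] <- as.matrix(r$atoms[, c("x", "y", "z")])
    serial <- serial + k
  }
  for (lg in ligands) {
    seq_id <- seq_id + 1L
    k <- nrow(lg$atoms)
    atoms[[length(atoms) + 1L]] <- atom_row(
      serial + seq_len(k), lg$atoms$name, lg$atoms$element, "L", seq_id,
      lg$res_name %||% lg$label, kind = "ligand", group = lg$label)
    xyz[[length(xyz) + 1L]] <- as.matrix(lg$atoms[, c("x", "y", "z")])
    serial <- serial + k
  }
  structure_frame(do.call(rbind, atoms), do.call(rbind, xyz))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

res_atoms <- function(names, elements, coords) {
  data.frame(name = names, element = elements,
             x = coords[, 1], y = coords[, 2], z = coords[, 3],
             stringsAsFactors = FALSE)
}

# Random compact frame for oracle tests: residues scattered in a box, a few
# atoms each (some hydrogens, which contact analysis must ignore), plus
# optional multi-atom ligand groups.
random_frame <- function(n_res, n_lig = 0L, seed = 1L, box = 25) {
  set.seed(seed)
  residues <- lapply(seq_len(n_res), function(r) {
    centre <- runif(3, 0, box)
    k <- sample(3:5, 1L)
    names <- c("CA", paste0("X", seq_len(k - 1L)))
    el <- c("C", sample(c("C", "N", "O", "S"), k - 1L, replace = TRUE))
    coords <- matrix(rep(centre, each = k), k, 3) +
      matrix(runif(3 * k, -1.2, 1.2), k, 3)
    at <- res_atoms(names, el, coords)
    if (runif(1) < 0.3) {   # hydrogen that must not affect contacts
      at <- rbind(at, data.frame(name = "H1", element = "H",
                                 x = centre[1], y = centre[2], z = centre[3],
                                 stringsAsFactors = FALSE))
    }
    list(res_name = sample(names(flexrin:::AA3TO1), 1L), atoms = at)
  })
  ligands <- lapply(seq_len(n_lig), function(g) {
    centre <- runif(3, 0, box)
    k <- sample(2:4, 1L)
    coords <- matrix(rep(centre, each = k), k, 3) +
      matrix(runif(3 * k, -1.2, 1.2), k, 3)
    list(label = paste0("LG", g),
         atoms = res_atoms(paste0("L", seq_len(k)),
                           rep("C", k), coords))
  })
  toy_frame(residues, ligands)
}

# Brute-force minimum heavy-atom distance: explicit loop over the atoms of
# one vertex, plain arithmetic against the other's.
oracle_min_dist <- function(xyz_a, xyz_b) {
  best <- Inf
  for (i in seq_len(nrow(xyz_a))) {
    d <- sqrt((xyz_b[, 1] - xyz_a[i, 1])^2 +
              (xyz_b[, 2] - xyz_a[i, 2])^2 +
              (xyz_b[, 3] - xyz_a[i, 3])^2)
    best <- min(best, min(d))
  }
  best
}

# Brute-force RIN adjacency over all heavy-atom pairs of all vertex pairs.
oracle_adjacency <- function(frame, cutoff = 3.5) {
  a <- frame$atoms
  heavy <- a$element != "H"
  pol_keys <- unique(paste0(a$chain, ":", a$seq_id)[a$kind == "polymer"])
  lig_keys <- unique(a$group[a$kind == "ligand"])
  keys <- c(pol_keys, lig_keys)
  idx <- lapply(keys, function(k) {
    if (k %in% lig_keys) which(a$kind == "ligand" & a$group == k & heavy)
    else {
      parts <- strsplit(k, ":")[[1]]
      which(a$kind == "polymer" & a$chain == parts[1] &
            a$seq_id == as.integer(parts[2]) & heavy)
    }
  })
  nv <- length(keys)
  adj <- matrix(0L, nv, nv, dimnames = list(keys, keys))
  for (i in seq_len(nv - 1L)) {
    for (j in (i + 1L):nv) {
      d <- oracle_min_dist(frame$xyz[idx[[i]], , drop = FALSE],
                           frame$xyz[idx[[j]], , drop = FALSE])
      if (d > 0 && d < cutoff) adj[i, j] <- adj[j, i] <- 1L
    }
  }
  adj
}

# Uniformly random proper rotation.
random_rotation <- function(seed) {
  set.seed(seed)
  A <- qr.Q(qr(matrix(rnorm(9), 3)))
  if (det(A) < 0) A[, 1] <- -A[, 1]
  A
}

# Apply a rigid motion to every frame of an ensemble.
move_ensemble <- function(ens, R, tvec) {
  for (t in seq_len(n_frames(ens)))
    ens$xyz[, , t] <- ens$xyz[, , t] %*% t(R) +
      matrix(tvec, dim(ens$xyz)[1], 3, byrow = TRUE)
  ens
}

# Profile with given values over generic residue keys.
num_profile <- function(values, kind = "plddt") {
  flexrin:::new_profile(rep("A", length(values)), seq_along(values),
                        rep("ALA", length(values)), values, kind)
}

# Exhaustive global-alignment score by recursion (tiny sequences only).
oracle_global_score <- function(s1, s2, match = 1, mismatch = 0, gap = -1) {
  a <- strsplit(s1, "")[[1]]; b <- strsplit(s2, "")[[1]]
  rec <- function(i, j) {
    if (i == 0 && j == 0) return(0)
    best <- -Inf
    if (i > 0 && j > 0)
      best <- max(best, rec(i - 1, j - 1) +
                  if (a[i] == b[j]) match else mismatch)
    if (i > 0) best <- max(best, rec(i - 1, j) + gap)
    if (j > 0) best <- max(best, rec(i, j - 1) + gap)
    best
  }
  rec(length(a), length(b))
}
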