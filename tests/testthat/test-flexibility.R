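test_that("Kabsch superposition recovers known rigid motions and rejects reflections", {
  set.seed(1)
  P <- matrix(rnorm(30), 10, 3)
  tf <- superpose(P, P)
  expect_equal(tf$rotation, diag(3), tolerance = 1e-9)
  expect_lt(tf$rmsd, 1e-12)

  ang <- pi / 2
  R <- rbind(c(cos(ang), -sin(ang), 0), c(sin(ang), cos(ang), 0), c(0, 0, 1))
  Q <- P %*% t(R) + matrix(c(1, 2, 3), 10, 3, byrow = TRUE)
  tf <- superpose(Q, P)
  expect_lt(tf$rmsd, 1e-9)
  expect_lt(max(abs(apply_transform(Q, tf) - P)), 1e-9)

  # chiral 4-point set vs its mirror image: residual > 0, det stays +1
  chiral <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))
  mirror <- chiral %*% diag(c(-1, 1, 1))
  tf <- superpose(mirror, chiral)
  expect_gt(tf$rmsd, 0.1)
  expect_equal(det(tf$rotation), 1, tolerance = 1e-9)

  expect_error(superpose(P[1:2, ], P[1:2, ]), "3 paired points")
  line <- cbind(1:5, 0, 0)
  expect_error(superpose(line, line), "collinear")
})

test_that("superposition agrees with bio3d's least-squares fit", {
  set.seed(42)
  P <- matrix(rnorm(45), 15, 3)
  Q <- P %*% t(random_rotation(7)) +
    matrix(c(3, -1, 2), 15, 3, byrow = TRUE) + matrix(rnorm(45, sd = 0.3), 15, 3)
  tf <- superpose(Q, P)
  ref <- suppressWarnings(
    bio3d::fit.xyz(fixed = as.vector(t(P)), mobile = as.vector(t(Q))))
  ref_rmsd <- bio3d::rmsd(as.vector(t(P)), ref)   # bio3d rounds to 3 digits
  expect_equal(tf$rmsd, ref_rmsd, tolerance = 2e-3)
})

test_that("transform composition matches sequential application", {
  set.seed(3)
  P <- matrix(rnorm(24), 8, 3)
  A <- list(rotation = random_rotation(1), translation = c(1, -2, 0.5))
  B <- list(rotation = random_rotation(2), translation = c(-3, 0, 2))
  class(A) <- class(B) <- "rigid_transform"
  seq_applied <- apply_transform(apply_transform(P, A), B)
  composed <- apply_transform(P, compose_transforms(B, A))
  expect_equal(seq_applied, composed, tolerance = 1e-12)
})

test_that("RMSF: identical frames give zero; two frames give d/2; rigid motion is removed", {
  base <- make_base_fold(10, seed = 1)
  static <- as_ensemble(list(base, base, base))
  expect_equal(rmsf(static)$value, rep(0, 10))

  # displace one residue by exactly d between two frames -> RMSF d/2
  f2 <- base
  idx <- which(f2$atoms$seq_id == 5)
  f2 <- structure_frame(f2$atoms,
                        f2$xyz + outer(seq_len(nrow(f2$xyz)) %in% idx,
                                       c(2, 0, 0)), "2")
  two <- as_ensemble(list(base, f2))
  fx <- rmsf(two, do_superpose = FALSE)
  expect_equal(fx$value[5], 1.0, tolerance = 1e-9)
  expect_equal(fx$value[-5], rep(0, 9), tolerance = 1e-12)

  # a global rigid motion applied to every frame changes nothing when
  # superposition is on
  spec <- synth_spec(10, n_frames = 30, seed = 5,
                     sigma = sigma_profile(10, ramp_len = 3))
  ens <- sample_ensemble(base, spec)
  moved <- move_ensemble(ens, random_rotation(4), c(10, -5, 3))
  expect_equal(rmsf(ens, do_superpose = TRUE)$value,
               rmsf(moved, do_superpose = TRUE)$value, tolerance = 1e-9)

  expect_error(rmsf(as_ensemble(list(base))), "2 frames")
})

test_that("RMSF agrees with bio3d on C-alpha coordinates", {
  base <- make_base_fold(12, seed = 6)
  spec <- synth_spec(12, n_frames = 40, seed = 6,
                     sigma = sigma_profile(12, ramp_len = 4))
  ens <- sample_ensemble(base, spec)
  ca <- which(ens$atoms$name == "CA")
  mat <- t(vapply(seq_len(n_frames(ens)),
                  function(t) as.vector(t(ens$xyz[ca, , t])),
                  numeric(3 * length(ca))))
  ref <- bio3d::rmsf(mat)   # bio3d uses the n-1 divisor; rescale to n
  nf <- n_frames(ens)
  expect_equal(rmsf(ens, do_superpose = FALSE)$value,
               ref * sqrt((nf - 1) / nf), tolerance = 1e-6)
})

test_that("heavy-atom RMSF averages the per-atom fluctuation over the residue", {
  base <- make_base_fold(8, seed = 2)
  spec <- synth_spec(8, n_frames = 60, seed = 2, sigma = rep(0.8, 8))
  ens <- sample_ensemble(base, spec)
  # rigid-residue jitter: every atom of a residue moves identically, so the
  # heavy-atom average equals the C-alpha value
  expect_equal(rmsf(ens, selection = "heavy", do_superpose = FALSE)$value,
               rmsf(ens, selection = "calpha", do_superpose = FALSE)$value,
               tolerance = 1e-9)
})

test_that("reverse-normalised confidence score matches direct substitution", {
  p <- num_profile(c(90, 70, 50))
  s <- af2_score(p)
  expect_equal(s$value, c(0, 0.5, 1.0))

  expect_warning(s0 <- af2_score(num_profile(c(80, 80, 80))), "constant")
  expect_equal(s0$value, c(0, 0, 0))

  # affine invariance and [0, 1] span
  set.seed(8)
  v <- runif(20, 40, 95)
  s1 <- af2_score(num_profile(v))
  s2 <- af2_score(num_profile(2.5 * v + 7))
  expect_equal(s1$value, s2$value, tolerance = 1e-12)
  expect_equal(range(s1$value), c(0, 1))
})

test_that("Pearson concordance: closed-form cases and cor.test agreement", {
  a <- num_profile(c(1, 2, 3, 4), "rmsf")
  b <- num_profile(c(1, 3, 2, 4), "rmsf")
  cc <- pearson_concordance(a, b)
  expect_equal(cc$pcc, 0.8, tolerance = 1e-12)
  t_expected <- 0.8 * sqrt(2 / 0.36)
  expect_equal(cc$p_value, 2 * pt(-t_expected, df = 2), tolerance = 1e-12)
  ref <- cor.test(a$value, b$value)
  expect_equal(cc$pcc, unname(ref$estimate), tolerance = 1e-12)
  expect_equal(cc$p_value, ref$p.value, tolerance = 1e-9)

  lin <- num_profile(2 * a$value + 1, "rmsf")
  expect_equal(pearson_concordance(a, lin)$pcc, 1.0)
  neg <- num_profile(-a$value, "rmsf")
  expect_equal(pearson_concordance(a, neg)$pcc, -1.0)

  expect_error(pearson_concordance(a, num_profile(rep(1, 4))), "constant")
  expect_error(pearson_concordance(a, num_profile(1:3)), "residues")
})

test_that("RMSD series is zero for the reference and rigid-motion frames", {
  base <- make_base_fold(10, seed = 1)
  moved <- structure_frame(base$atoms,
                           base$xyz %*% t(random_rotation(2)) +
                             matrix(c(4, 4, 4), nrow(base$xyz), 3,
                                    byrow = TRUE), "2")
  # one residue displaced: compare against the direct per-atom formula
  disp <- base$xyz
  ca5 <- which(base$atoms$seq_id == 5 & base$atoms$name == "CA")
  disp[ca5, ] <- disp[ca5, ] + c(3, 0, 0)
  f3 <- structure_frame(base$atoms, disp, "3")
  ens <- as_ensemble(list(base, moved, f3))
  s <- rmsd_series(ens, 1)
  expect_equal(s$rmsd[1], 0)
  expect_lt(s$rmsd[2], 1e-9)
  n_ca <- sum(base$atoms$name == "CA")
  expect_lte(s$rmsd[3], 3 / sqrt(n_ca) + 1e-9)
  # oracle: superposition of frame 3 is the minimum over rigid motions, so
  # it cannot exceed the unsuperposed RMSD
  raw <- sqrt(mean(rowSums((disp[flexrin:::ca_indices(base$atoms), ] -
                            base$xyz[flexrin:::ca_indices(base$atoms), ])^2)))
  expect_lte(s$rmsd[3], raw + 1e-12)
  expect_error(rmsd_series(ens, 9), "range")
})

test_that("tail_mean summarises the trailing fraction", {
  expect_equal(tail_mean(rep(2.5, 8), 0.25), list(mean = 2.5, sd = 0))
  tm <- tail_mean(c(1, 2, 3, 4), 0.5)
  expect_equal(tm$mean, 3.5)
  expect_equal(tail_mean(c(1, 2, 3, 4), 1.0)$mean, 2.5)
  expect_error(tail_mean(numeric(0), 0.5), "empty")
  expect_error(tail_mean(1:3, 0), "tail_fraction")
})
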