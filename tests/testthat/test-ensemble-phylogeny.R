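test_that("pairwise RMSD matrix: duplicates, rigid motions, and per-pair oracle", {
  base <- make_base_fold(12, seed = 1)
  moved <- structure_frame(base$atoms,
                           base$xyz %*% t(random_rotation(5)) +
                             matrix(c(2, 2, 2), nrow(base$xyz), 3,
                                    byrow = TRUE), "2")
  spec <- synth_spec(12, n_frames = 2, seed = 8,
                     sigma = sigma_profile(12, ramp_len = 4))
  jit <- sample_ensemble(base, spec)
  frames <- list(base, moved, get_frame(jit, 1), get_frame(jit, 2))
  frames <- lapply(seq_along(frames), function(i) {
    f <- frames[[i]]; f$frame_label <- paste0("m", i); f
  })
  dm <- pairwise_rmsd_matrix(frames)
  expect_equal(dm$matrix, t(dm$matrix))
  expect_equal(diag(dm$matrix), rep(0, 4), ignore_attr = TRUE)
  expect_lt(dm$matrix[1, 2], 1e-9)          # rigid motion only
  expect_true(all(dm$matrix >= 0))
  # cross-check every entry against an independent superpose call
  ca <- which(base$atoms$name == "CA")
  for (i in 1:3) for (j in (i + 1):4) {
    ref <- superpose(frames[[j]]$xyz[ca, ], frames[[i]]$xyz[ca, ])$rmsd
    expect_equal(dm$matrix[i, j], ref, tolerance = 1e-12)
  }
  summ <- matrix_summary(dm)
  ut <- dm$matrix[upper.tri(dm$matrix)]
  expect_equal(summ$mean, mean(ut))
  expect_equal(summ$sd, sd(ut))
})

test_that("neighbor joining solves the 3-leaf worked example", {
  dm <- matrix(c(0, 2, 4, 2, 0, 4, 4, 4, 0), 3, 3,
               dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tr <- neighbor_joining(dm)
  bp <- tree_bipartitions(tr)
  expect_equal(bp$length[bp$split == "B"], 1)
  expect_equal(bp$length[bp$split == "C"], 3)
  expect_equal(bp$length[bp$split == "B;C"], 1)  # terminal branch of A
})

test_that("neighbor joining inverts a known 4-leaf additive tree exactly", {
  # tree ((A:1,B:2):1,(C:3,D:1)): additive distances by path length
  D <- matrix(0, 4, 4, dimnames = list(LETTERS[1:4], LETTERS[1:4]))
  D["A", "B"] <- D["B", "A"] <- 3
  D["A", "C"] <- D["C", "A"] <- 5
  D["A", "D"] <- D["D", "A"] <- 3
  D["B", "C"] <- D["C", "B"] <- 6
  D["B", "D"] <- D["D", "B"] <- 4
  D["C", "D"] <- D["D", "C"] <- 4
  tr <- neighbor_joining(D)
  bp <- tree_bipartitions(tr)
  # splits: four terminal branches (A's edge appears as its complement
  # "B;C;D") and the single internal edge AB|CD, canonically "C;D"
  expect_setequal(bp$split, c("B", "C", "D", "B;C;D", "C;D"))
  expect_equal(bp$length[bp$split == "C;D"], 1, tolerance = 1e-12)
  expect_equal(bp$length[bp$split == "B;C;D"], 1, tolerance = 1e-12)
  expect_equal(bp$length[bp$split == "B"], 2, tolerance = 1e-12)
  expect_equal(bp$length[bp$split == "C"], 3, tolerance = 1e-12)
  expect_equal(bp$length[bp$split == "D"], 1, tolerance = 1e-12)
})

test_that("an ultrametric 3-leaf matrix yields equal terminal branches", {
  dm <- matrix(2, 3, 3, dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  diag(dm) <- 0
  bp <- tree_bipartitions(neighbor_joining(dm))
  expect_equal(bp$length, rep(1, 3))
})

test_that("neighbor joining matches ape::nj on random additive and noisy input", {
  set.seed(10)
  for (k in 1:10) {
    n <- sample(4:10, 1)
    t0 <- ape::unroot(ape::rtree(n, br = function(m) runif(m, 0.1, 5)))
    D <- ape::cophenetic.phylo(t0)
    mine <- neighbor_joining(D)
    expect_equal(ape::dist.topo(mine, ape::nj(D)), 0, ignore_attr = TRUE)
  }
  # non-additive (noisy) matrices: topologies still agree with ape
  # (negative-branch clamping may warn here; that path is tested separately)
  for (k in 1:5) {
    n <- 6
    M <- matrix(0, n, n, dimnames = list(letters[1:n], letters[1:n]))
    M[upper.tri(M)] <- runif(n * (n - 1) / 2, 1, 10)
    M <- M + t(M)
    mine <- suppressWarnings(neighbor_joining(M))
    expect_equal(ape::dist.topo(mine, ape::nj(M)), 0, ignore_attr = TRUE)
  }
})

test_that("negative NJ branch lengths are clamped with a warning", {
  M <- matrix(c(0.0, 3.4, 4.3, 9.2,
                3.4, 0.0, 6.2, 2.8,
                4.3, 6.2, 0.0, 9.1,
                9.2, 2.8, 9.1, 0.0), 4, 4,
              dimnames = list(LETTERS[1:4], LETTERS[1:4]))
  expect_warning(tr <- neighbor_joining(M), "clamped")
  expect_true(all(tr$edge.length >= 0))
})

test_that("validation: too-few labels and asymmetry are rejected", {
  M <- matrix(c(0, 1, 1, 0), 2, 2, dimnames = list(c("A", "B"), c("A", "B")))
  expect_error(neighbor_joining(M), "at least 3")
  M3 <- matrix(c(0, 1, 2, 9, 0, 3, 2, 3, 0), 3, 3,
               dimnames = list(LETTERS[1:3], LETTERS[1:3]))
  expect_error(neighbor_joining(M3), "symmetric")
})

test_that("Newick output round-trips to an isomorphic tree with equal lengths", {
  set.seed(20)
  for (k in 1:5) {
    # branch lengths kept below 1 (including the two root edges merged by
    # unroot) so the 6-significant-digit serialisation is exact to 1e-6
    t0 <- ape::unroot(ape::rtree(10, br = function(m) runif(m, 0.05, 0.45)))
    D <- ape::cophenetic.phylo(t0)
    tr <- neighbor_joining(D)
    path <- withr::local_tempfile(fileext = ".nwk")
    write_newick(tr, path)
    back <- ape::read.tree(path)
    b1 <- tree_bipartitions(tr); b2 <- tree_bipartitions(back)
    expect_equal(b1$split, b2$split)
    expect_lt(max(abs(b1$length - b2$length)), 1e-6)
  }
})

test_that("Newick labels with spaces are quoted and parse back", {
  dm <- matrix(c(0, 2, 4, 2, 0, 4, 4, 4, 0), 3, 3)
  dimnames(dm) <- list(c("sys 1", "B", "C"), c("sys 1", "B", "C"))
  path <- withr::local_tempfile(fileext = ".nwk")
  nwk <- write_newick(neighbor_joining(dm), path)
  expect_match(nwk, "'sys 1'", fixed = TRUE)
  back <- ape::read.tree(path)
  # ape keeps the quote characters; strip them before comparing
  expect_setequal(gsub("^'|'$", "", back$tip.label), c("sys 1", "B", "C"))
})
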