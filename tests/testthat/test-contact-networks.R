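test_that("minimum heavy-atom distance matches hand-placed cases", {
  fr <- toy_frame(list(
    list(res_name = "ALA",
         atoms = res_atoms("CA", "C", rbind(c(0, 0, 0)))),
    list(res_name = "ALA",
         atoms = res_atoms("CA", "C", rbind(c(3, 0, 0)))),
    list(res_name = "SER",
         atoms = res_atoms(c("CA", "OG", "H"), c("C", "O", "H"),
                           rbind(c(10, 0, 0), c(3.4, 0, 1),
                                 c(3.05, 0, 0))))))
  expect_equal(residue_min_distance(fr, "A:1", "A:2"), 3.0)
  # min over many pairs; the 3.05 hydrogen must be ignored
  expect_equal(residue_min_distance(fr, "A:2", "A:3"),
               sqrt(0.4^2 + 1), tolerance = 1e-12)
  expect_equal(residue_min_distance(fr, "A:1", "A:1"), 0)
})

test_that("distance map equals a hand computation on a 3-residue toy chain", {
  fr <- toy_frame(list(
    list(res_name = "ALA", atoms = res_atoms(c("N", "CA"), c("N", "C"),
         rbind(c(0, 0, 0), c(1.4, 0, 0)))),
    list(res_name = "GLY", atoms = res_atoms("CA", "C", rbind(c(5, 0, 0)))),
    list(res_name = "TRP", atoms = res_atoms(c("CA", "CZ"), c("C", "C"),
         rbind(c(5, 6, 0), c(5, 2, 0))))))
  dm <- distance_map(fr, contact_dialect("heavy_min"))
  manual <- matrix(0, 3, 3)
  manual[1, 2] <- manual[2, 1] <- 5 - 1.4
  manual[1, 3] <- manual[3, 1] <- sqrt((5 - 1.4)^2 + 2^2)
  manual[2, 3] <- manual[3, 2] <- 2
  expect_equal(unname(dm$matrix), manual, tolerance = 1e-12)
})

test_that("cbeta dialect uses CB (CA for Gly) and excludes ligands with a warning", {
  fr <- toy_frame(list(
    list(res_name = "ALA", atoms = res_atoms(c("CA", "CB"), c("C", "C"),
         rbind(c(0, 0, 0), c(1.5, 0, 0)))),
    list(res_name = "GLY", atoms = res_atoms("CA", "C", rbind(c(6, 0, 0))))),
    ligands = list(list(label = "LIG",
                        atoms = res_atoms("L1", "C", rbind(c(3, 1, 0))))))
  expect_warning(dm <- distance_map(fr, contact_dialect("cbeta")),
                 "ligand")
  expect_equal(nrow(dm$vertices), 2L)
  expect_equal(dm$matrix[1, 2], 4.5)  # CB of res 1 to CA of Gly
})

test_that("contact cutoffs are strict and the boundary case yields no edge", {
  mk <- function(d) toy_frame(list(
    list(res_name = "ALA", atoms = res_atoms("CA", "C", rbind(c(0, 0, 0)))),
    list(res_name = "ALA", atoms = res_atoms("CA", "C", rbind(c(d, 0, 0))))))
  dial <- contact_dialect("heavy_min", 3.5)
  edge_at <- function(d) contact_map(distance_map(mk(d), dial))[1, 2]
  expect_equal(edge_at(3.4), 1L)
  expect_equal(edge_at(3.5), 0L)   # strictly-below rule
  expect_equal(edge_at(5.0), 0L)
})

test_that("RIN adjacency equals the brute-force heavy-atom oracle on random frames", {
  for (seed in 1:12) {
    fr <- random_frame(n_res = sample(8:25, 1), n_lig = sample(0:2, 1),
                       seed = seed)
    rin <- build_rin(fr, contact_dialect("heavy_min", 3.5))
    expect_identical(unname(rin$adjacency),
                     unname(oracle_adjacency(fr, 3.5)),
                     label = paste("seed", seed))
  }
})

test_that("adjacency is symmetric, zero-diagonal, and monotone in the cutoff", {
  fr <- random_frame(20, 1, seed = 31)
  g1 <- build_rin(fr, contact_dialect("heavy_min", 3.5))
  expect_identical(g1$adjacency, t(g1$adjacency))
  expect_true(all(diag(g1$adjacency) == 0))
  g2 <- build_rin(fr, contact_dialect("heavy_min", 6.0))
  expect_true(all(g2$adjacency >= g1$adjacency))
})

test_that("the two dialects can disagree when sidechains touch but CBs are far", {
  # long sidechains reaching toward each other: heavy_min sees 3.2 A,
  # CB-CB is 9 A
  fr <- toy_frame(list(
    list(res_name = "ARG", atoms = res_atoms(c("CA", "CB", "NH1"),
         c("C", "C", "N"),
         rbind(c(0, 0, 0), c(1.5, 0, 0), c(4.4, 0, 0)))),
    list(res_name = "GLU", atoms = res_atoms(c("CA", "CB", "OE1"),
         c("C", "C", "O"),
         rbind(c(12, 0, 0), c(10.5, 0, 0), c(7.6, 0, 0))))))
  heavy <- build_rin(fr, contact_dialect("heavy_min"))
  cb <- build_rin(fr, contact_dialect("cbeta"))
  expect_equal(heavy$adjacency[1, 2], 1L)   # 7.6 - 4.4 = 3.2 < 3.5
  expect_equal(cb$adjacency[1, 2], 0L)      # CB-CB = 9 > 8
})

test_that("RIN vertices carry kind and chemical class; ligands are single vertices", {
  fr <- toy_frame(list(
    list(res_name = "HIS", atoms = res_atoms("CA", "C", rbind(c(0, 0, 0)))),
    list(res_name = "LYS", atoms = res_atoms("CA", "C", rbind(c(4, 0, 0)))),
    list(res_name = "ASP", atoms = res_atoms("CA", "C", rbind(c(8, 0, 0)))),
    list(res_name = "VAL", atoms = res_atoms("CA", "C", rbind(c(12, 0, 0))))),
    ligands = list(list(label = "BVQ",
      atoms = res_atoms(c("C1", "C2"), c("C", "C"),
                        rbind(c(0, 3, 0), c(0, 4, 0))))))
  rin <- build_rin(fr)
  expect_equal(nrow(rin$vertices), 5L)
  expect_equal(rin$vertices$class,
               c("aromatic", "positive", "negative", "other", "ligand"))
  expect_equal(rin$adjacency["A:1", "BVQ"], 1L)
  expect_equal(sum(rin$adjacency[, "BVQ"]), 1L)
})

test_that("bonded neighbours are flagged and removable", {
  fr <- toy_frame(list(
    list(res_name = "ALA", atoms = res_atoms("CA", "C", rbind(c(0, 0, 0)))),
    list(res_name = "ALA", atoms = res_atoms("CA", "C", rbind(c(3, 0, 0)))),
    list(res_name = "ALA", atoms = res_atoms("CA", "C", rbind(c(30, 0, 0))))))
  rin <- build_rin(fr)
  expect_equal(rin$adjacency[1, 2], 1L)
  expect_true(rin$bonded[1, 2])
  rin2 <- build_rin(fr, exclude_bonded = TRUE)
  expect_equal(rin2$adjacency[1, 2], 0L)
})

test_that("map similarity is rank-invariant and near zero under permutation", {
  fr <- random_frame(15, seed = 17)
  dm <- distance_map(fr)
  expect_equal(map_similarity(dm, dm), 1.0)
  expect_equal(map_similarity(dm, exp(dm$matrix / 3)), 1.0)

  # permutation null at ~4000 upper-triangle entries
  set.seed(5)
  n <- 90
  M <- matrix(0, n, n)
  M[upper.tri(M)] <- runif(n * (n - 1) / 2)
  M <- M + t(M)
  P <- matrix(0, n, n)
  P[upper.tri(P)] <- sample(M[upper.tri(M)])
  P <- P + t(P)
  expect_lt(abs(map_similarity(M, P)), 0.1)
  expect_error(map_similarity(M, P[1:10, 1:10]), "dimension")
})

test_that("a RIN converts to an igraph with attributes intact", {
  fr <- random_frame(10, 1, seed = 3)
  rin <- build_rin(fr)
  g <- as_igraph(rin)
  expect_equal(igraph::vcount(g), nrow(rin$vertices))
  expect_equal(igraph::ecount(g), sum(rin$adjacency) / 2)
  expect_equal(igraph::vertex_attr(g, "class"), rin$vertices$class)
})
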