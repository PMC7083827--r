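test_that("geometric median handles Fermat, vertex-rule and collinear cases", {
  # equilateral triangle: Fermat point is the centroid
  expect_equal(geometric_median(rbind(c(0, 0), c(1, 0), c(0.5, 0.866025))),
               c(0.5, 0.288675), tolerance = 1e-6)
  # apex angle > 120 degrees: the apex itself is the median
  expect_equal(geometric_median(rbind(c(0, 0), c(1, 0), c(0.5, 0.1))),
               c(0.5, 0.1), tolerance = 1e-9)
  # collinear points: the 1-D median
  expect_equal(geometric_median(rbind(c(0, 0), c(1, 0), c(5, 0))),
               c(1, 0), tolerance = 1e-9)
  expect_equal(geometric_median(matrix(c(3, 4), 1, 2)), c(3, 4))
  # weights shift the optimum: heavy vertex wins once its weight dominates
  expect_equal(geometric_median(rbind(c(0, 0), c(1, 0), c(0, 1)),
                                weights = c(5, 1, 1)),
               c(0, 0), tolerance = 1e-9)
  expect_error(geometric_median(rbind(c(0, 0), c(1, 0)), weights = c(1, -1)),
               "positive")
})

test_that("minimum-distance alignment recovers exact transforms", {
  withr::local_seed(5)
  ref <- random_shape(6, scale = 2)
  copy <- transform_config(ref, theta = 0.7, shift = c(0.3, -0.4))
  lm <- lm_table(list(ref = ref, same = ref, rot = copy))
  ra <- minimum_distance_align(lm, "ref")
  expect_equal(config_of(ra$transformed, "ref"), ref, ignore_attr = TRUE)
  expect_lt(ra$objective$objective[ra$objective$specimen == "same"], 1e-10)
  expect_lt(ra$objective$objective[ra$objective$specimen == "rot"], 1e-8)
  expect_equal(config_of(ra$transformed, "rot"), ref,
               tolerance = 1e-7, ignore_attr = TRUE)
  expect_error(minimum_distance_align(lm, "nope"), "unknown reference")
})

test_that("minimum-distance objective matches the rotation/translation grid
           oracle on a 4-point pair", {
  X <- rbind(c(0, 0), c(1, 0), c(1.1, 0.8), c(0.2, 1))
  ref <- rbind(c(0.1, -0.1), c(0.8, 0.2), c(1.3, 0.9), c(-0.2, 0.9))
  lm <- lm_table(list(ref = ref, x = X))
  ra <- minimum_distance_align(lm, "ref")
  solver_obj <- ra$objective$objective[ra$objective$specimen == "x"]
  oracle_obj <- oracle_min_dist(X, ref)
  expect_lt(solver_obj, oracle_obj + 1e-6)   # never worse than the grid
  expect_equal(solver_obj, oracle_obj, tolerance = 1e-4)
})

test_that("two-terminal reconstruction is the summed inter-terminal distance
           with midpoint ancestors", {
  withr::local_seed(6)
  A <- random_shape(4); B <- random_shape(4)
  tr <- read_newick_tree(text = "(A,B);")
  recon <- reconstruct_ancestral(lm_table(list(A = A, B = B)), tr)
  expect_equal(recon$tree_length, sum(sqrt(rowSums((A - B)^2))),
               tolerance = 1e-8)
  anc <- dplyr::arrange(recon$ancestral, point)
  expect_equal(cbind(anc$x, anc$y), (A + B) / 2, tolerance = 1e-5,
               ignore_attr = TRUE)
  expect_equal(consistency_index(recon), 1, tolerance = 1e-9)
})

test_that("a 3-leaf equilateral star recovers the Fermat point", {
  side <- rbind(c(0, 0), c(1, 0), c(0.5, sqrt(3) / 2))
  configs <- lapply(1:3, function(i) rbind(side[i, ], c(10, 10), c(11, 10)))
  names(configs) <- c("A", "B", "C")
  tr <- read_newick_tree(text = "(A,B,C);")
  recon <- reconstruct_ancestral(lm_table(configs), tr)
  expect_equal(recon$per_landmark_lengths$length[1], sqrt(3), tolerance = 1e-6)
  anc <- dplyr::filter(recon$ancestral, point == 1)
  expect_equal(c(anc$x, anc$y), c(0.5, sqrt(3) / 6), tolerance = 1e-6)
})

test_that("the 4-leaf unit square realizes the Steiner minimal tree", {
  corners <- list(A = c(0, 0), B = c(0, 1), C = c(1, 0), D = c(1, 1))
  configs <- lapply(corners, function(p) rbind(p, c(10, 10), c(11, 10)))
  tr <- read_newick_tree(text = "((A,B),(C,D));")
  recon <- reconstruct_ancestral(lm_table(configs), tr)
  expect_equal(recon$per_landmark_lengths$length[1], 1 + sqrt(3),
               tolerance = 1e-6)
  anc <- dplyr::filter(dplyr::arrange(recon$ancestral, node), point == 1)
  expect_equal(sort(unique(round(anc$y, 6))), 0.5, tolerance = 1e-6)
  expect_equal(range(anc$x), c(1 / (2 * sqrt(3)), 1 - 1 / (2 * sqrt(3))),
               tolerance = 1e-6)
})

test_that("solver length matches the exhaustive grid oracle on random
           single-landmark instances", {
  withr::local_seed(123)
  for (i in 1:8) {
    inst <- random_weber_instance()
    solver_len <- solver_weber_length(inst$tree, inst$tip_xy)
    oracle <- oracle_weber_grid(inst$tree, inst$tip_xy, seed = i)
    expect_lt(solver_len, oracle$length + 1e-6)
    expect_lt(abs(solver_len - oracle$length), 1e-3)  # grid resolution bound
  }
})

test_that("tree length decomposes over landmarks and branches exactly", {
  withr::local_seed(14)
  spec <- default_fixture_spec()
  pair <- simulate_dataset(spec)
  recon <- reconstruct_ancestral(
    minimum_distance_align(gpa_align(pair$astragalus_only, spec$scheme),
                           spec$reference),
    spec$tree)
  expect_equal(sum(recon$branch_lengths$length), recon$tree_length,
               tolerance = 1e-9)
  expect_equal(sum(recon$per_landmark_lengths$length), recon$tree_length,
               tolerance = 1e-9)
  expect_true(all(recon$branch_lengths$length >= 0))
  # subset extraction: full set over one branch equals that branch's total
  b <- find_branch(spec$tree, spec$focal_clade)
  expect_equal(branch_subset_length(recon, b, 1:11),
               sum(recon$branch_lengths$length[recon$branch_lengths$branch == b]))
  expect_equal(branch_subset_length(recon, b, integer()), 0)
  expect_error(branch_subset_length(recon, b, c(0, 5)), "out of range")
  expect_error(branch_subset_length(recon, 9999, 1:3), "no such branch")
})

test_that("the objective is root-invariant and satisfies the zero-subgradient
           certificate", {
  withr::local_seed(15)
  spec <- default_fixture_spec()
  pair <- simulate_dataset(spec)
  ra <- minimum_distance_align(gpa_align(pair$astragalus_plus_centrale,
                                         spec$scheme), spec$reference)
  recon <- reconstruct_ancestral(ra, spec$tree)
  rerooted <- ape::root(spec$tree, outgroup = "f3", resolve.root = TRUE)
  recon2 <- reconstruct_ancestral(ra, rerooted)
  expect_equal(recon$tree_length, recon2$tree_length, tolerance = 1e-9)

  # certificate: at each internal node, summed unit vectors to neighbours
  # nearly vanish unless the node sits on a neighbour
  tr <- spec$tree
  n_tip <- length(tr$tip.label)
  pos <- array(NA_real_, c(n_tip + tr$Nnode, 2, 11))
  arr <- centrale:::lm_array(ra$transformed)
  for (i in seq_len(n_tip)) pos[i, , ] <- t(arr[, , tr$tip.label[i]])
  for (nd in unique(recon$ancestral$node)) {
    d <- dplyr::arrange(dplyr::filter(recon$ancestral, node == nd), point)
    pos[nd, 1, ] <- d$x; pos[nd, 2, ] <- d$y
  }
  for (nd in unique(recon$ancestral$node)) {
    nbrs <- c(tr$edge[tr$edge[, 1] == nd, 2], tr$edge[tr$edge[, 2] == nd, 1])
    for (l in 1:11) {
      dv <- t(pos[nbrs, , l]) - pos[nd, , l]
      dn <- sqrt(colSums(dv^2))
      if (any(dn < 1e-7)) next
      resid <- rowSums(sweep(dv, 2, dn, `/`))
      expect_lt(sqrt(sum(resid^2)), 1e-5)
    }
  }
})

test_that("the smoothed objective descends monotonically within each level", {
  withr::local_seed(16)
  spec <- default_fixture_spec()
  pair <- simulate_dataset(spec)
  recon <- reconstruct_ancestral(
    minimum_distance_align(gpa_align(pair$astragalus_only, spec$scheme),
                           spec$reference), spec$tree)
  tr <- recon$convergence$trace
  by_run <- split(tr$objective, interaction(tr$point, tr$eps, drop = TRUE))
  for (obj in by_run) {
    expect_true(all(diff(obj) <= 1e-12))
  }
})

test_that("homoplasy lowers the consistency index", {
  # convergent displacement on both cherries of a 4-leaf tree: the realized
  # length (2) doubles the single-landmark MST bound (1), so CI = 1/2
  pts <- list(A = c(0, 0), B = c(1, 0), C = c(0, 0), D = c(1, 0))
  configs <- lapply(pts, function(p) rbind(p, c(9, 9), c(10, 9)))
  tr <- read_newick_tree(text = "((A,B),(C,D));")
  recon <- reconstruct_ancestral(lm_table(configs), tr)
  expect_equal(recon$tree_length, 2, tolerance = 1e-6)
  expect_equal(consistency_index(recon), 0.5, tolerance = 1e-6)
  # collinear star where the optimum attains the MST: CI = 1
  lin <- list(A = c(0, 0), B = c(1, 0), C = c(5, 0))
  configs2 <- lapply(lin, function(p) rbind(p, c(9, 9), c(10, 9)))
  tr2 <- read_newick_tree(text = "(A,B,C);")
  recon2 <- reconstruct_ancestral(lm_table(configs2), tr2)
  expect_equal(consistency_index(recon2), 1, tolerance = 1e-6)
  # identical terminals: zero-length tree, CI defined as 1
  same <- lm_table(list(A = rbind(c(0, 0), c(1, 0), c(0, 1)),
                        B = rbind(c(0, 0), c(1, 0), c(0, 1))))
  recon3 <- reconstruct_ancestral(same, read_newick_tree(text = "(A,B);"))
  expect_equal(recon3$tree_length, 0)
  expect_equal(consistency_index(recon3), 1)
})

test_that("squared-change option solves the harmonic reconstruction", {
  A <- rbind(c(0, 0), c(1, 0), c(0, 1))
  B <- rbind(c(2, 0), c(3, 0), c(2, 1))
  tr <- read_newick_tree(text = "(A,B);")
  recon <- reconstruct_ancestral(lm_table(list(A = A, B = B)), tr,
                                 objective = "squared")
  anc <- dplyr::arrange(recon$ancestral, point)
  expect_equal(cbind(anc$x, anc$y), (A + B) / 2, tolerance = 1e-10,
               ignore_attr = TRUE)
})

test_that("reconstruction requires data for every leaf", {
  lm <- lm_table(list(A = random_shape(4), B = random_shape(4)))
  tr <- read_newick_tree(text = "(A,(B,C));")
  expect_error(reconstruct_ancestral(lm, tr), "C")
})
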