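spec_fix <- default_fixture_spec()

test_that("an injected focal-branch medial displacement increases the focal
           medial length relative to the same realization without it", {
  spec_on <- spec_fix
  spec_off <- spec_fix
  spec_off$delta <- 0  # same seed: identical Brownian draws, no injection
  pair_on <- simulate_dataset(spec_on)
  pair_off <- simulate_dataset(spec_off)
  res_on <- run_configuration(pair_on$astragalus_plus_centrale, spec_fix$scheme,
                              spec_fix$tree, spec_fix$reference,
                              spec_fix$focal_clade)
  res_off <- run_configuration(pair_off$astragalus_plus_centrale, spec_fix$scheme,
                               spec_fix$tree, spec_fix$reference,
                               spec_fix$focal_clade)
  expect_gt(res_on$focal_branch_medial_length,
            res_off$focal_branch_medial_length)
})

test_that("specimen input order does not affect any pipeline output", {
  pair <- simulate_dataset(spec_fix)
  lm <- pair$astragalus_only
  run <- function(d) run_configuration(d, spec_fix$scheme, spec_fix$tree,
                                       spec_fix$reference, spec_fix$focal_clade)
  r1 <- run(lm)
  withr::with_seed(3, {
    perm <- lm[sample(nrow(lm)), ]
  })
  r2 <- run(perm)
  expect_equal(r1$tree_length, r2$tree_length, tolerance = 1e-9)
  expect_equal(r1$focal_branch_medial_length, r2$focal_branch_medial_length,
               tolerance = 1e-9)
  expect_equal(r1$sum_of_variances, r2$sum_of_variances, tolerance = 1e-9)
  expect_equal(r1$consistency_index, r2$consistency_index, tolerance = 1e-9)
})

test_that("identical configurations across taxa yield a zero-length tree and
           zero disparity", {
  m <- default_ancestor_shape()
  configs <- setNames(lapply(1:8, function(i) m), spec_fix$tree$tip.label)
  res <- run_configuration(lm_table(configs), spec_fix$scheme, spec_fix$tree,
                           spec_fix$reference, spec_fix$focal_clade)
  expect_lt(res$tree_length, 1e-9)
  expect_lt(res$sum_of_variances, 1e-20)
})

test_that("taxon/leaf mismatches are reported with the set difference", {
  pair <- simulate_dataset(spec_fix)
  lm <- dplyr::filter(pair$astragalus_only, specimen != "f4")
  expect_error(run_configuration(lm, spec_fix$scheme, spec_fix$tree,
                                 spec_fix$reference, spec_fix$focal_clade),
               "f4")
})

test_that("the decision rule prefers the configuration with the smaller focal
           medial length and reports ties as inconclusive", {
  pair <- simulate_dataset(spec_fix)
  rc <- run_configuration(pair$astragalus_plus_centrale, spec_fix$scheme,
                          spec_fix$tree, spec_fix$reference, spec_fix$focal_clade,
                          configuration_label = "astragalus_plus_centrale",
                          topology_label = "sim")
  ra <- run_configuration(pair$astragalus_only, spec_fix$scheme,
                          spec_fix$tree, spec_fix$reference, spec_fix$focal_clade,
                          configuration_label = "astragalus_only",
                          topology_label = "sim")
  cmp <- compare_hypotheses(rc, ra)
  expect_equal(cmp$preferred,
               if (cmp$focal_medial_combined < cmp$focal_medial_astragalus)
                 "astragalus_plus_centrale" else "astragalus_only")
  # forced tie
  ra2 <- ra
  ra2$focal_branch_medial_length <- rc$focal_branch_medial_length
  tie <- compare_hypotheses(rc, ra2)
  expect_equal(tie$preferred, "inconclusive")
  expect_equal(tie$hypothesis, "inconclusive")
  # guard rails
  ra3 <- ra
  ra3$topology_label <- "other"
  expect_error(compare_hypotheses(rc, ra3), "different topologies")
  expect_error(compare_hypotheses(rc, rc), "same configuration")
})

test_that("displacement vectors reproduce the stored branch lengths", {
  pair <- simulate_dataset(spec_fix)
  res <- run_configuration(pair$astragalus_plus_centrale, spec_fix$scheme,
                           spec_fix$tree, spec_fix$reference,
                           spec_fix$focal_clade)
  recon <- res$reconstruction
  for (b in c(res$focal_branch, 1L)) {  # an internal branch and a terminal one
    dv <- displacement_vectors(recon, b)
    stored <- dplyr::arrange(
      dplyr::filter(recon$branch_lengths, branch == b), point)
    expect_equal(dv$length, stored$length, tolerance = 1e-9)
    expect_equal(sqrt(dv$dx^2 + dv$dy^2), dv$length, tolerance = 1e-12)
  }
  # zero-length branch gives zero vectors
  same <- lm_table(list(A = default_ancestor_shape(),
                        B = default_ancestor_shape()))
  rec0 <- reconstruct_ancestral(same, read_newick_tree(text = "(A,B);"))
  expect_lt(max(displacement_vectors(rec0, 1L)$length), 1e-9)
})

test_that("under the fusion generative model the combined configuration shows
           the smaller focal-branch medial vectors", {
  spec <- simulation_spec(scenario = "fusion", delta = 0.5, seed = 103)
  pair <- simulate_dataset(spec)
  rc <- run_configuration(pair$astragalus_plus_centrale, spec$scheme,
                          spec$tree, spec$reference, spec$focal_clade,
                          configuration_label = "astragalus_plus_centrale",
                          topology_label = "sim")
  ra <- run_configuration(pair$astragalus_only, spec$scheme, spec$tree,
                          spec$reference, spec$focal_clade,
                          configuration_label = "astragalus_only",
                          topology_label = "sim")
  med <- spec$scheme$subsets$medial
  norm_c <- displacement_vectors(rc$reconstruction, rc$focal_branch)$length[med]
  norm_a <- displacement_vectors(ra$reconstruction, ra$focal_branch)$length[med]
  expect_lt(sum(norm_c), sum(norm_a))
  expect_equal(compare_hypotheses(rc, ra)$hypothesis, "fusion")
})

test_that("reports assemble the 2x2 design, round-trip through JSON, and are
           byte-stable", {
  pair <- simulate_dataset(spec_fix)
  trees <- list(t1 = spec_fix$tree,
                t2 = read_newick_tree(text = "((o1,(o2,o3)),(p1,((f1,f2),(f3,f4))));"))
  results <- list()
  for (tp in names(trees)) {
    for (cf in names(pair)) {
      results[[paste(tp, cf)]] <- run_configuration(
        pair[[cf]], spec_fix$scheme, trees[[tp]], spec_fix$reference,
        spec_fix$focal_clade, configuration_label = cf, topology_label = tp)
    }
  }
  rep1 <- comparison_report(results)
  expect_equal(nrow(rep1$table), 4L)
  expect_equal(sort(unique(rep1$table$topology)), c("t1", "t2"))
  # preferred configuration is consistent with the stored focal lengths
  for (i in seq_len(nrow(rep1$preferred_per_topology))) {
    row <- rep1$preferred_per_topology[i, ]
    if (row$preferred != "inconclusive") {
      expect_equal(row$preferred,
                   if (row$focal_medial_combined < row$focal_medial_astragalus)
                     "astragalus_plus_centrale" else "astragalus_only")
    }
  }
  # focal medial length never exceeds the tree length
  expect_true(all(rep1$table$focal_branch_medial_length <=
                    rep1$table$tree_length + 1e-12))

  dir1 <- withr::local_tempdir()
  paths <- write_report(rep1, dir1)
  back <- read_report(paths[1])
  expect_equal(back$table$tree_length, rep1$table$tree_length,
               tolerance = 1e-12)
  expect_equal(back$preferred_per_topology$preferred,
               rep1$preferred_per_topology$preferred)
  # byte-identical on re-write (no timestamps, no hidden state)
  dir2 <- withr::local_tempdir()
  paths2 <- write_report(rep1, dir2)
  expect_identical(readLines(paths[1]), readLines(paths2[1]))
})
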