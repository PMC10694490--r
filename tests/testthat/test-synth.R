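test_that("simulated trees are deterministic, valid, and scale with branch_scale", {
  t1 <- simulate_tree(100, seed = 7)
  t2 <- simulate_tree(100, seed = 7)
  expect_identical(t1$newick, t2$newick)
  expect_equal(t1$n_tip, 100L)
  t3 <- simulate_tree(2, seed = 1)
  expect_equal(t3$n_tip, 2L)
  expect_error(simulate_tree(1, seed = 1), "n_leaves")
  ## mean depth tracks the branch-length scale (10x scale ~ 10x depth)
  ratio <- mean(vapply(1:20, function(s) {
    d1 <- mean(tip_to_root_depths(simulate_tree(50, s, 0.05))$depth)
    d10 <- mean(tip_to_root_depths(simulate_tree(50, s, 0.5))$depth)
    d10 / d1
  }, 0.0))
  expect_gt(ratio, 8); expect_lt(ratio, 12)
})

test_that("placement generator honors its contracts", {
  tr <- simulate_tree(150, seed = 31, branch_scale = 0.15)
  sim <- simulate_placements(tr, 40, dispersion = 0.01,
                             min_separation = 0.5, seed = 31)
  ## cardinality: 40 alleles x 5 primers
  expect_length(sim$pset$records, 200L)
  expect_equal(nrow(sim$truth), 200L)
  expect_equal(length(unique(sim$truth$allele)), 40L)
  ## source leaves pairwise >= min_separation
  leaves <- node_of_leaf(tr, unique(sim$truth$allele))
  for (i in 1:10) for (j in 30:40)
    if (i != j)
      expect_gte(phylobin:::.node_dist(tr, leaves[i], leaves[j]), 0.5)
  ## every mass point within `dispersion` of the source leaf
  for (id in names(sim$pset$records)) {
    leaf <- node_of_leaf(tr, sim$truth$allele[sim$truth$asv_id == id])
    m <- to_mass(sim$pset$records[[id]])
    for (k in seq_len(nrow(m)))
      expect_lte(path_distance(tr, tree_point(m$edge_num[k], m$offset[k]),
                               tree_point(tr$edge_num[leaf], 0)),
                 0.01 + 1e-9)
  }
  ## determinism down to the serialized bytes
  sim2 <- simulate_placements(tr, 40, dispersion = 0.01,
                              min_separation = 0.5, seed = 31)
  f1 <- withr::local_tempfile(); f2 <- withr::local_tempfile()
  write_jplace(sim$pset, f1); write_jplace(sim2$pset, f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("dispersion 0 collapses each ASV to a point mass at its leaf", {
  tr <- simulate_tree(60, seed = 5, branch_scale = 0.2)
  sim <- simulate_placements(tr, 5, primers = "p1", dispersion = 0,
                             min_separation = 0.3, seed = 5)
  for (id in names(sim$pset$records)) {
    m <- to_mass(sim$pset$records[[id]])
    expect_equal(nrow(m), 1L)
    leaf <- node_of_leaf(tr, sim$truth$allele[sim$truth$asv_id == id])
    expect_equal(m$edge_num, tr$edge_num[leaf])
    expect_equal(m$offset, 0)
  }
})

test_that("an impossible separation demand fails with advice", {
  tr <- simulate_tree(20, seed = 9, branch_scale = 0.01)
  expect_error(simulate_placements(tr, 15, dispersion = 0,
                                   min_separation = 5, seed = 9),
               "fewer alleles")
})

test_that("simulated counts hit the exact depth with one primer per specimen", {
  tr <- simulate_tree(80, seed = 13, branch_scale = 0.15)
  sim <- simulate_placements(tr, 10, dispersion = 0.005,
                             min_separation = 0.4, seed = 13)
  counts <- simulate_counts(sim$truth, n_specimens = 8, depth = 5000,
                            seed = 13)
  expect_true(all(rowSums(counts) == 5000L))
  expect_identical(colnames(counts), sim$truth$asv_id)
  ## each specimen's reads stay within its own primer's ASVs
  for (s in seq_len(nrow(counts))) {
    used <- colnames(counts)[counts[s, ] > 0]
    expect_length(unique(sim$truth$primer[match(used, sim$truth$asv_id)]),
                  1L)
  }
  ## sampling noise shrinks with depth: with sigma = 0 the expected
  ## proportions are uniform, and KL(empirical || uniform) must drop
  ## between the 454-like and MiSeq-like depths
  sim1 <- simulate_placements(tr, 6, primers = "p1", dispersion = 0.005,
                              min_separation = 0.4, seed = 14)
  kl <- function(depth, seed) {
    cc <- simulate_counts(sim1$truth, 1, depth = depth, seed = seed,
                          sigma = 0)
    p <- (cc[1, ] + 0.5) / sum(cc[1, ] + 0.5)
    sum(p * log(p * length(p)))
  }
  kls_lo <- mean(vapply(1:20, function(s) kl(5000, s), 0.0))
  kls_hi <- mean(vapply(1:20, function(s) kl(50000, s), 0.0))
  expect_lt(kls_hi, kls_lo)
  ## single allele: every read lands on its ASV
  sim_one <- list(truth = data.frame(asv_id = "a1", allele = "L0001",
                                     primer = "p1"))
  cone <- simulate_counts(sim_one$truth, 2, depth = 100, seed = 1)
  expect_true(all(cone == 100L))
})

test_that("lumping and splitting metrics recognize ideal and broken binnings", {
  truth <- data.frame(asv_id = sprintf("a%d", 1:6),
                      allele = rep(c("x", "y"), each = 3),
                      primer = rep(c("p1", "p2", "p3"), 2))
  perfect <- setNames(rep(c("pt01__00001", "pt01__00002"), each = 3),
                      truth$asv_id)
  expect_equal(alleles_per_phylotype(perfect, truth)$mean, 1.0)
  expect_equal(phylotypes_per_allele(perfect, truth)$mean, 1.0)
  lumped <- setNames(rep("pt01__00001", 6), truth$asv_id)
  expect_equal(alleles_per_phylotype(lumped, truth)$mean, 2.0)
  expect_equal(phylotypes_per_allele(lumped, truth)$mean, 1.0)  # blind
  split_all <- setNames(sprintf("pt01__%05d", 1:6), truth$asv_id)
  expect_equal(alleles_per_phylotype(split_all, truth)$mean, 1.0)
  expect_equal(phylotypes_per_allele(split_all, truth)$mean, 3.0)
  expect_error(alleles_per_phylotype(c(zz = "pt01__00001"), truth),
               "missing from the truth map")
})

test_that("growing dispersion eventually lumps alleles together", {
  ## qualitative degradation on a shallow tree where allele separations
  ## sit near the floor: as placement spread passes half the separation,
  ## amplicons from different alleles start sharing phylotypes
  lump <- vapply(c(0.005, 0.25, 0.4), function(disp) {
    mean(vapply(1:6, function(s) {
      tr <- simulate_tree(40, seed = s, branch_scale = 0.08)
      sim <- simulate_placements(tr, 8, primers = paste0("p", 1:5),
                                 dispersion = disp, min_separation = 0.4,
                                 seed = s)
      suppressMessages(m <- bin_phylotypes(sim$pset, 0.1))
      alleles_per_phylotype(m, sim$truth)$mean
    }, 0.0))
  }, 0.0)
  expect_equal(lump[1], 1.0)
  expect_true(all(diff(lump) >= 0))
  expect_gt(lump[3], 1.0)
})

test_that("rarefaction is exact at full depth and monotone in expectation", {
  withr::with_seed(23, {
    counts <- matrix(rpois(80, 3), nrow = 4,
                     dimnames = list(sprintf("s%d", 1:4),
                                     sprintf("f%02d", 1:20)))
  })
  n_nonzero <- sum(colSums(counts) > 0)
  total <- sum(counts)
  rc <- rarefaction_curve(counts, c(1, 10, 50, total), reps = 100, seed = 1)
  expect_equal(rc$mean_features[rc$depth == total], n_nonzero)
  expect_lte(rc$mean_features[rc$depth == 1], 1)
  expect_true(all(diff(rc$mean_features) >= 0))
  expect_warning(rarefaction_curve(counts, total + 10, reps = 5, seed = 1),
                 "capped")
  ## deterministic under a fixed seed
  expect_identical(rarefaction_curve(counts, c(5, 25), reps = 20, seed = 9),
                   rarefaction_curve(counts, c(5, 25), reps = 20, seed = 9))
})
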