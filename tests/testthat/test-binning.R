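test_that("pregrouping joins ASVs sharing mass-bearing edges, transitively", {
  tr <- toy_tree()
  ps <- placement_set(tr, list(
    make_record("r1", 0),
    make_record("r2", c(0, 1), lwr = c(0.5, 0.5)),
    make_record("r3", 3)))
  g <- pregroup(ps)
  expect_length(g, 2L)
  sizes <- unname(sort(lengths(lapply(g, `[[`, "members"))))
  expect_equal(sizes, c(1L, 2L))
  big <- g[[which.max(lengths(lapply(g, `[[`, "members")))]]
  expect_setequal(big$members, c("r1", "r2"))
  expect_equal(big$mass_edges, c(0L, 1L))
  ## chain r1~r2 (edge 1), r2~r3 (edge 3), r1 and r3 disjoint
  ps2 <- placement_set(tr, list(
    make_record("r1", c(0, 1), lwr = c(0.5, 0.5)),
    make_record("r2", c(1, 3), lwr = c(0.5, 0.5)),
    make_record("r3", c(3, 4), lwr = c(0.5, 0.5))))
  g2 <- pregroup(ps2)
  expect_length(g2, 1L)
  expect_setequal(g2[[1]]$members, c("r1", "r2", "r3"))
  ## fully disjoint records -> singletons
  ps3 <- placement_set(tr, list(make_record("a", 0), make_record("b", 1),
                                make_record("c", 3)))
  expect_length(pregroup(ps3), 3L)
})

test_that("pre-groups merge iff LCA separation is strictly below threshold", {
  tr <- toy_tree()
  ps <- placement_set(tr, list(
    make_record("a1", 0), make_record("a2", 1),
    make_record("b1", 3), make_record("b2", 4)))
  ## two pre-groups anchored at the A/B and C/D parents: separation 0.9
  mk_group <- function(members, edges) {
    list(members = members, mass_edges = edges,
         lca_node = placement_lca(tr, ps$records[members]))
  }
  g <- list(mk_group(c("a1", "a2"), c(0L, 1L)),
            mk_group(c("b1", "b2"), c(3L, 4L)))
  expect_length(merge_pregroups(tr, g, threshold = 0.1), 2L)  # 0.9 >= 0.1
  merged <- merge_pregroups(tr, g, threshold = 1.0)           # 0.9 < 1.0
  expect_length(merged, 1L)
  expect_setequal(merged[[1]]$members, c("a1", "a2", "b1", "b2"))
  expect_equal(merged[[1]]$lca_node, tr$root)
  expect_length(merge_pregroups(tr, g[1], threshold = 0.5), 1L)
  ## strictness: separation exactly equal to threshold does not merge
  ps_ab <- placement_set(tr, list(make_record("a", 0), make_record("b", 1)))
  gg <- pregroup(ps_ab)   # two singletons, LCA sep 0.1 + 0.2 = 0.3
  expect_length(merge_pregroups(tr, gg, threshold = 0.3), 2L)
  expect_length(merge_pregroups(tr, gg, threshold = 0.3 + 1e-9), 1L)
})

test_that("within-group clustering cuts strictly at the threshold", {
  tr <- toy_tree()
  ps <- placement_set(tr, list(make_record("a", 0), make_record("b", 1)))
  grp <- list(members = c("a", "b"), mass_edges = c(0L, 1L),
              lca_node = placement_lca(tr, ps$records))
  expect_length(cluster_group(tr, grp, ps, threshold = 0.5), 1L)  # 0.3 < 0.5
  expect_length(cluster_group(tr, grp, ps, threshold = 0.1), 2L)  # 0.3 >= 0.1
  expect_length(cluster_group(tr, grp, ps, threshold = 0.3), 2L)  # strict
  single <- list(members = "a", mass_edges = 0L,
                 lca_node = node_of_leaf(tr, "A"))
  expect_equal(cluster_group(tr, single, ps, threshold = 0.1), list("a"))
})

test_that("binning recovers well-separated alleles and trivial limits", {
  tr <- simulate_tree(150, seed = 21, branch_scale = 0.15)
  sim <- simulate_placements(tr, 2, primers = paste0("p", 1:5),
                             dispersion = 0.005, min_separation = 0.9,
                             seed = 21)
  m <- bin_phylotypes(sim$pset, 0.1)
  expect_length(m$phylotypes, 2L)
  ## members match the truth map exactly
  truth_split <- split(sim$truth$asv_id, sim$truth$allele)
  got_split <- lapply(m$phylotypes, sort)
  expect_setequal(lapply(truth_split, sort), unname(got_split))
  ## threshold above tree diameter -> one phylotype
  diam <- 2 * max(tip_to_root_depths(tr)$depth)
  m1 <- bin_phylotypes(sim$pset, min(diam + 1, 9.9))
  expect_length(m1$phylotypes, 1L)
  ## single ASV -> one phylotype
  ps1 <- placement_set(toy_tree(), list(make_record("only", 0)))
  mone <- bin_phylotypes(ps1, 0.1)
  expect_length(mone$phylotypes, 1L)
  expect_equal(mone$phylotypes[[1]], "only")
})

test_that("every ASV lands in exactly one phylotype", {
  tr <- simulate_tree(100, seed = 33, branch_scale = 0.15)
  ps <- random_pset(tr, 80, seed = 34)
  for (thr in c(0.05, 0.2, 0.8)) {
    m <- bin_phylotypes(ps, thr)
    members <- unlist(m$phylotypes, use.names = FALSE)
    expect_setequal(members, names(ps$records))
    expect_equal(length(members), length(ps$records))
    expect_true(all(lengths(m$phylotypes) > 0))
    expect_identical(unname(m$asv_to_phylotype[members]),
                     rep(names(m$phylotypes), lengths(m$phylotypes)))
  }
})

test_that("divide-and-conquer equals brute force on separated clades", {
  for (seed in 1:6) {
    tr <- simulate_tree(100, seed = seed, branch_scale = 0.15)
    sim <- simulate_placements(tr, 15, primers = paste0("p", 1:4),
                               dispersion = 0.005, min_separation = 0.3,
                               seed = seed)
    dc <- bin_phylotypes(sim$pset, 0.1)
    bf <- brute_force_bin(sim$pset, 0.1)
    expect_equal(adjusted_rand(dc$asv_to_phylotype, bf$asv_to_phylotype), 1.0)
    expect_identical(dc$phylotypes, bf$phylotypes)
  }
})

test_that("cross-group distances are bounded below by LCA separation", {
  ## soundness of skipping cross-group pairs: for groups whose mass sits
  ## in disjoint clades every cross-pair KR distance >= the groups' LCA
  ## separation, so pairs in unmerged groups can never fall below the
  ## threshold
  checked <- 0L
  for (seed in 1:4) {
    tr <- simulate_tree(100, seed = seed, branch_scale = 0.15)
    sim <- simulate_placements(tr, 8, primers = paste0("p", 1:3),
                               dispersion = 0, min_separation = 0.4,
                               seed = seed + 50)
    groups <- merge_pregroups(tr, pregroup(sim$pset), 0.1)
    if (length(groups) < 2L) next
    lcas <- vapply(groups, `[[`, 0L, "lca_node")
    for (i in 1:(length(groups) - 1)) for (j in (i + 1):length(groups)) {
      anc <- phylobin:::.lca2(tr, lcas[i], lcas[j])
      if (anc == lcas[i] || anc == lcas[j]) next
      sep <- phylobin:::.node_dist(tr, lcas[i], lcas[j])
      for (ra in sim$pset$records[groups[[i]]$members])
        for (rb in sim$pset$records[groups[[j]]$members]) {
          expect_gte(kr_distance(tr, to_mass(ra), to_mass(rb)),
                     sep - 1e-9)
          checked <- checked + 1L
        }
    }
  }
  expect_gt(checked, 100L)
})

test_that("phylotype count is non-increasing in threshold (single linkage)", {
  tr <- simulate_tree(120, seed = 41, branch_scale = 0.15)
  sim <- simulate_placements(tr, 25, dispersion = 0.01,
                             min_separation = 0.2, seed = 41)
  thresholds <- c(0.01, 0.05, 0.1, 0.2, 0.5, 1.0)
  counts <- vapply(thresholds, function(t)
    length(bin_phylotypes(sim$pset, t)$phylotypes), 0L)
  expect_true(all(diff(counts) <= 0))
})

test_that("binning is deterministic", {
  tr <- simulate_tree(80, seed = 55)
  ps <- random_pset(tr, 40, seed = 56)
  m1 <- bin_phylotypes(ps, 0.2)
  m2 <- bin_phylotypes(ps, 0.2)
  expect_identical(m1, m2)
  tf1 <- withr::local_tempfile(); tf2 <- withr::local_tempfile()
  write_phylotype_model(m1, tf1); write_phylotype_model(m2, tf2)
  expect_identical(readLines(tf1), readLines(tf2))
})

test_that("phylotype names follow the pt<TT>__<IIIII> grammar", {
  part <- list(c("a1", "a2", "a3"), c("b1", "b2"), "c1")
  expect_equal(name_phylotypes(part, 0.5),
               c("pt05__00001", "pt05__00002", "pt05__00003"))
  expect_equal(name_phylotypes(part, 0.1)[1], "pt01__00001")
  expect_equal(name_phylotypes(part, 1.0)[1], "pt10__00001")
  expect_error(name_phylotypes(part, 10), "two-digit")
  ## abundance ordering: counts flip the ranking
  counts <- matrix(c(1, 1, 1, 50, 50, 900), nrow = 1,
                   dimnames = list("s1", c("a1", "a2", "a3", "b1", "b2",
                                           "c1")))
  expect_equal(name_phylotypes(part, 0.5, counts),
               c("pt05__00003", "pt05__00002", "pt05__00001"))
  ## tie-break: equal sizes ordered by smallest member id
  tie <- list(c("zz1", "zz2"), c("aa1", "aa2"))
  expect_equal(name_phylotypes(tie, 0.1), c("pt01__00002", "pt01__00001"))
})

test_that("model JSON round trips", {
  tr <- simulate_tree(60, seed = 61)
  ps <- random_pset(tr, 20, seed = 62)
  m <- bin_phylotypes(ps, 0.3)
  tf <- withr::local_tempfile(fileext = ".json")
  write_phylotype_model(m, tf)
  m2 <- read_phylotype_model(tf)
  expect_identical(m2$phylotypes, m$phylotypes)
  expect_identical(m2$tree_digest, m$tree_digest)
  expect_equal(m2$threshold, m$threshold)
  expect_identical(m2$linkage, m$linkage)
  expect_identical(as.integer(m2$phylotype_lca),
                   unname(m$phylotype_lca))
})

test_that("brute force guards against oversized inputs", {
  tr <- toy_tree()
  ps <- placement_set(tr, list(make_record("a", 0)))
  ## guard triggers on record count, not on actually building the set
  expect_error(
    {fake <- ps; fake$records <- rep(fake$records, 5001); brute_force_bin(fake, 0.1)},
    "5,000")
})
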