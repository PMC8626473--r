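test_that("fixed seed gives byte-identical simulated gene trees", {
  net <- read_enewick("((A:1,B:1):1,C:2);")
  cfg <- sim_config(seed = 11, n_trees = 25)
  t1 <- simulate_msc_gene_trees(net, cfg)
  t2 <- simulate_msc_gene_trees(net, cfg)
  expect_identical(vapply(t1, write_newick, character(1)),
                   vapply(t2, write_newick, character(1)))
})

test_that("3-taxon topology frequencies follow the coalescent closed form", {
  # t = 0: exchangeable, each resolution at 1/3
  net0 <- read_enewick("((A:1,B:1):0,C:1);")
  n <- 12000
  cnt0 <- triplet_topology_counts(
    simulate_msc_gene_trees(net0, sim_config(seed = 21, n_trees = n)))
  se <- sqrt((1 / 3) * (2 / 3) / n)
  for (x in cnt0 / n) expect_lt(abs(x - 1 / 3), 3 * se)

  # t = 1: each discordant topology at (1/3) e^-1
  net1 <- read_enewick("((A:1,B:1):1,C:2);")
  cnt1 <- triplet_topology_counts(
    simulate_msc_gene_trees(net1, sim_config(seed = 22, n_trees = n)))
  p_disc <- exp(-1) / 3
  se1 <- sqrt(p_disc * (1 - p_disc) / n)
  expect_lt(abs(cnt1[["A"]] / n - p_disc), 3 * se1)
  expect_lt(abs(cnt1[["B"]] / n - p_disc), 3 * se1)
  # chi-square goodness of fit against the full closed form
  expected <- c(A = p_disc, B = p_disc, C = 1 - 2 * p_disc)
  gof <- stats::chisq.test(as.numeric(cnt1[names(expected)]),
                           p = as.numeric(expected))
  expect_gt(gof$p.value, 0.001)
})

test_that("a gamma = 1 reticulation reproduces the pruned tree exactly", {
  s <- "((A:1,(B:1)#H1:1::1):1,(#H1:1::0,C:2):1);"
  net <- suppressWarnings(read_enewick(s))
  pruned <- prune_reticulations(net)
  cfg <- sim_config(seed = 33, n_trees = 40)
  t_net <- suppressWarnings(simulate_msc_gene_trees(net, cfg))
  t_tree <- simulate_msc_gene_trees(pruned, cfg)
  expect_identical(vapply(t_net, write_newick, character(1)),
                   vapply(t_tree, write_newick, character(1)))
})

test_that("gene trees honor the sampling request and support model", {
  net <- read_enewick("((A:1,B:1):1,C:2);")
  trees <- simulate_msc_gene_trees(net, sim_config(seed = 4, n_trees = 5),
                                   samples_per_species = c(A = 2, B = 1, C = 3))
  for (tr in trees) {
    expect_equal(sort(table(tip_species(tr))[c("A", "B", "C")]),
                 sort(c(A = 2, B = 1, C = 3)), ignore_attr = TRUE)
    expect_true(all(tree_support(tr) == 100))
    expect_true(all(tr$edge.length >= 0))
  }
  trees_b <- simulate_msc_gene_trees(
    net, sim_config(seed = 4, n_trees = 5,
                    support_model = list(type = "beta", mean = 0.8, conc = 10)))
  sup <- unlist(lapply(trees_b, tree_support))
  expect_true(all(sup >= 0 & sup <= 100))
  expect_gt(stats::sd(sup), 0)
})

test_that("mutation_scale rescales branch lengths linearly", {
  net <- read_enewick("((A:1,B:1):1,C:2);")
  t1 <- simulate_msc_gene_trees(net, sim_config(seed = 9, n_trees = 10))
  t2 <- simulate_msc_gene_trees(net, sim_config(seed = 9, n_trees = 10,
                                                mutation_scale = 2.5))
  for (i in seq_along(t1))
    expect_equal(t2[[i]]$edge.length, 2.5 * t1[[i]]$edge.length,
                 tolerance = 1e-12)
})

test_that("null site patterns are ABBA/BABA symmetric", {
  cfg <- sim_config(seed = 41, block_count = 100, sites_per_block = 250)
  b <- simulate_site_patterns(gamma = 0, config = cfg)
  tt <- stats::t.test(b$nABBA, b$nBABA, paired = TRUE)
  expect_gt(tt$p.value, 0.001)
  expect_error(simulate_site_patterns(gamma = -0.1, config = cfg), "gamma")
  expect_error(simulate_site_patterns(gamma = 1.2, config = cfg), "gamma")
})

test_that("site-pattern blocks respect the requested layout and determinism", {
  cfg <- sim_config(seed = 13, block_count = 8, sites_per_block = 50)
  b1 <- simulate_site_patterns(gamma = 0.2, config = cfg, keep_genotypes = TRUE)
  b2 <- simulate_site_patterns(gamma = 0.2, config = cfg, keep_genotypes = TRUE)
  expect_equal(nrow(b1), 8)
  expect_true(all(b1$n_sites == 50))
  expect_true(all(b1$nABBA + b1$nBABA <= b1$n_sites))
  expect_identical(attr(b1, "genotypes"), attr(b2, "genotypes"))
})

test_that("simulated Ks families obey the low-copy filter and noise limits", {
  # noiseless all-WGD families of size 2: every pairwise Ks equals wgd_ks
  fams <- simulate_ks_families(20, wgd_ks = 0.9, wgd_fraction = 1,
                               noise_sigma = 0, config = sim_config(seed = 6),
                               sizes = 2)
  for (f in fams) expect_equal(f$ks[1, 2], 0.9)
  expect_error(simulate_ks_families(5, 0.9, 0.6, 0.1, sizes = 1), "1 < n < 5")
  expect_error(simulate_ks_families(5, 0.9, 0.6, 0.1, sizes = 5), "1 < n < 5")
  expect_error(simulate_ks_families(5, -1, 0.6, 0.1), "wgd_ks")

  # deeper duplication nodes carry larger true Ks; trees are ultrametric
  fams4 <- simulate_ks_families(30, 0.9, 0.5, 0.1,
                                config = sim_config(seed = 7), sizes = 4)
  for (f in fams4) {
    expect_equal(f$true_node_ks, sort(f$true_node_ks))
    d <- ape::cophenetic.phylo(f$tree)
    expect_equal(max(d), max(f$true_node_ks), tolerance = 1e-9)
  }
  # determinism
  a <- simulate_ks_families(10, 0.9, 0.6, 0.1, config = sim_config(seed = 8))
  b <- simulate_ks_families(10, 0.9, 0.6, 0.1, config = sim_config(seed = 8))
  expect_identical(lapply(a, `[[`, "ks"), lapply(b, `[[`, "ks"))
})

test_that("LTR divergences cluster at the burst value", {
  expect_equal(simulate_ltr_divergences(5, 0.03, 0), rep(0.03, 5))
  expect_error(simulate_ltr_divergences(5, -1, 0.01), "burst_k")
  k <- simulate_ltr_divergences(10000, 0.03, 0.005, seed = 12)
  expect_true(all(k >= 0))
  dens <- stats::density(k)
  expect_lt(abs(dens$x[which.max(dens$y)] - 0.03), 0.002)
})
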