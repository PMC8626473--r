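test_that("triplet extraction restricts trees correctly", {
  tr <- read_newick("((a:1,b:1):0.5,c:1.5);")
  obs <- extract_triplets(list(tr), list(c("a", "b", "c")))
  expect_equal(obs$odd, "c")
  expect_equal(obs$t, 0.5)

  # star-like: zero internal branch recorded, not dropped
  tr0 <- read_newick("((a:1,b:1):0,c:1);")
  obs0 <- extract_triplets(list(tr0), list(c("a", "b", "c")))
  expect_equal(nrow(obs0), 1)
  expect_equal(obs0$t, 0)
})

test_that("all triplets of a caterpillar match path-based computation", {
  cat6 <- make_caterpillar(6)
  trips <- utils::combn(cat6$tip.label, 3, simplify = FALSE)
  obs <- extract_triplets(list(cat6), trips)
  expect_equal(nrow(obs), 20)
  # independent oracle via ape node depths
  depths <- ape::node.depth.edgelength(cat6)
  for (i in seq_len(nrow(obs))) {
    trip <- c(obs$sp1[i], obs$sp2[i], obs$sp3[i])
    tix <- match(trip, cat6$tip.label)
    mr <- ape::getMRCA(cat6, tix)
    pair <- setdiff(trip, obs$odd[i])
    mp <- ape::getMRCA(cat6, match(pair, cat6$tip.label))
    # odd species: its two pairings share the overall MRCA
    expect_equal(obs$t[i], depths[mp] - depths[mr])
    expect_true(depths[mp] > depths[mr])
    # on a caterpillar the odd species is always the highest-index tip
    expect_equal(obs$odd[i],
                 trip[which.max(as.integer(substring(trip, 2)))])
  }
})

test_that("multi-copy species pick the tightest representative set", {
  smap <- c(a1 = "A", a2 = "A", b1 = "B", c1 = "C", d1 = "D")
  tr <- read_newick("(((a1:1,b1:1):1,(a2:1,d1:1):1):1,c1:3);",
                    species_map = smap)
  obs <- extract_triplets(list(tr), list(c("A", "B", "C")))
  expect_equal(nrow(obs), 1)  # uses a1 (closest to b1), not a2
  expect_equal(obs$odd, "C")
  # missing species are skipped and counted
  obs2 <- extract_triplets(list(tr), list(c("A", "B", "Z")))
  expect_equal(nrow(obs2), 0)
  expect_equal(attr(obs2, "n_skipped"), 1)
})

test_that("mixture fit refuses degenerate and undersized input", {
  expect_error(fit_branch_mixture(rep(0.5, 10)), "insufficient")
  expect_error(fit_branch_mixture(rep(0, 30)), "degenerate")
  expect_error(fit_branch_mixture(c(rep(1, 25), -0.1)), "non-negative")
})

test_that("two-component likelihood never falls below the one-component fit", {
  set.seed(314)
  for (rep in 1:12) {
    t <- switch(1 + rep %% 4,
                rexp(60),
                rexp(60, 5),
                c(rexp(30), 3 + rexp(30)),
                rgamma(60, 2, 1))
    f <- fit_branch_mixture(t)
    expect_gte(f$logL2, f$logL1)
    expect_gte(f$pi, 0)
    expect_lte(f$pi, 1)
    expect_gte(f$shift, 0)
  }
})

test_that("the mixture fit recovers planted parameters", {
  set.seed(2718)
  t <- c(rexp(250), 2 + rexp(250))
  f <- fit_branch_mixture(t)
  expect_equal(f$decision, "mixture")
  expect_lt(abs(f$pi - 0.5), 0.1)
  expect_lt(abs(f$shift - 2), 0.3)
  expect_equal(f$ratio, (1 - f$pi) / f$pi)
})

test_that("pure exponential data is called ILS-only", {
  set.seed(5)
  calls <- replicate(20, fit_branch_mixture(rexp(500))$decision)
  expect_lte(mean(calls == "mixture"), 0.05)
})

test_that("ILS-only simulation yields exponential discordant branch lengths", {
  # under the MSC, discordant triplet internal branches are Exp(1) in
  # coalescent units (memoryless property)
  net <- read_enewick("((A:1,B:1):1,C:2);")
  trees <- simulate_msc_gene_trees(net, sim_config(seed = 77, n_trees = 4000))
  obs <- extract_triplets(trees, list(c("A", "B", "C")))
  disc <- obs$t[obs$odd != "C"]
  expect_gt(length(disc), 500)
  expect_equal(mean(disc), 1, tolerance = 0.15)
  f <- fit_branch_mixture(disc)
  expect_equal(f$decision, "ILS-only")
  expect_equal(f$lambda1, 1, tolerance = 0.15)
})

test_that("the resampling protocol is deterministic and validates input", {
  net <- read_enewick("((A:1,B:1):0.5,C:1.5);")
  trees <- simulate_msc_gene_trees(net, sim_config(seed = 55, n_trees = 120))
  p1 <- run_triplet_protocol(trees, net, n_runs = 1, trees_per_run = 120,
                             seed = 3)
  p2 <- run_triplet_protocol(trees, net, n_runs = 1, trees_per_run = 120,
                             seed = 3)
  expect_identical(p1$fits, p2$fits)
  expect_identical(p1$pairs, p2$pairs)
  expect_error(run_triplet_protocol(trees, net, trees_per_run = 500),
               "exceeds")
})

test_that("an introgression pulse flags the admixed pair and only it", {
  # gamma = 0.4 reticulation moving B into C's lineage: deep species
  # divergences keep ILS discordance rare, so trees uniting B and C are
  # dominated by the older introgression cohort
  s <- "(((A:1,(B:0.5)#H1:0.5::0.6):2,(#H1:0.5::0.4,C:1):2):2,D:5);"
  net <- read_enewick(s)
  trees <- simulate_msc_gene_trees(net, sim_config(seed = 101, n_trees = 900))
  prot <- run_triplet_protocol(trees, network_major_tree(net),
                               triplets = list(c("A", "B", "C")),
                               n_runs = 2, trees_per_run = 700, seed = 5)
  flagged <- prot$pairs$pair[prot$pairs$flagged]
  expect_true("B~C" %in% flagged)
  expect_false("A~C" %in% flagged)
})
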