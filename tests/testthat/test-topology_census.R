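# trees over the toy 7-tip system: 2 CM, 2 monocots, 2 eudicots, 1 outgroup
toy_tree <- function(newick, supports = TRUE) {
  tr <- read_newick(newick)
  gene_tree(ape::as.phylo(tr),
            species = stats::setNames(tr$tip.label, tr$tip.label))
}

test_that("classify_tree identifies the three diagnostic clades", {
  sch <- toy_scheme(); defs <- toy_defs()
  # Type I: CM sister to (MO,EU)
  t1 <- toy_tree("(out:1,((cm1:1,cm2:1)100:1,((mo1:1,mo2:1)100:1,(eu1:1,eu2:1)100:1)100:1)100:1);")
  expect_equal(classify_tree(t1, sch, defs), "I")
  # Type II: (CM,EU) vs MO
  t2 <- toy_tree("(out:1,((mo1:1,mo2:1)100:1,((cm1:1,cm2:1)100:1,(eu1:1,eu2:1)100:1)100:1)100:1);")
  expect_equal(classify_tree(t2, sch, defs), "II")
  # Type III: (CM,MO) vs EU
  t3 <- toy_tree("(out:1,((eu1:1,eu2:1)100:1,((cm1:1,cm2:1)100:1,(mo1:1,mo2:1)100:1)100:1)100:1);")
  expect_equal(classify_tree(t3, sch, defs), "III")
})

test_that("the bootstrap filter demotes weak diagnostic clades to 'other'", {
  sch <- toy_scheme(); defs <- toy_defs()
  t2 <- toy_tree("(out:1,((mo1:1,mo2:1)100:1,((cm1:1,cm2:1)100:1,(eu1:1,eu2:1)100:1)65:1)100:1);")
  expect_equal(classify_tree(t2, sch, defs, support_threshold = 70), "other")
  expect_equal(classify_tree(t2, sch, defs, support_threshold = 60), "II")
})

test_that("classification errors when a focal group is absent", {
  sch <- toy_scheme(); defs <- toy_defs()
  t_no_eu <- toy_tree("(out:1,((cm1:1,cm2:1)90:1,(mo1:1,mo2:1)90:1)90:1);")
  expect_error(classify_tree(t_no_eu, sch, defs), "EU")
})

test_that("classification agrees with exhaustive clade evaluation on a panel", {
  sch <- toy_scheme(); defs <- toy_defs()
  oracle_classify <- function(tree) {
    sp <- tip_species(tree)
    grp <- unname(sch$groups[sp])
    focal <- names(sp)[grp %in% c("CM", "MO", "EU")]
    lab_of <- function(want) {
      target <- sort(names(sp)[grp %in% want])
      any(vapply(oracle_clades(tree), function(cl)
        identical(sort(intersect(cl, focal)), target), logical(1)))
    }
    if (lab_of(c("MO", "EU"))) return("I")
    if (lab_of(c("CM", "EU"))) return("II")
    if (lab_of(c("CM", "MO"))) return("III")
    "other"
  }
  set.seed(99)
  labels <- c("cm1", "cm2", "mo1", "mo2", "eu1", "eu2", "out")
  for (i in 1:25) {
    phy <- ape::rtree(7, tip.label = sample(labels))
    tr <- gene_tree(phy, species = stats::setNames(phy$tip.label, phy$tip.label))
    expect_equal(classify_tree(tr, sch, defs, support_threshold = 0),
                 oracle_classify(tr), label = write_newick(phy))
  }
})

test_that("census aggregates counts, proportions and monophyly fractions", {
  sch <- toy_scheme(); defs <- toy_defs()
  t1 <- toy_tree("(out:1,((cm1:1,cm2:1)100:1,((mo1:1,mo2:1)100:1,(eu1:1,eu2:1)100:1)100:1)100:1);")
  t2 <- toy_tree("(out:1,((mo1:1,mo2:1)100:1,((cm1:1,cm2:1)100:1,(eu1:1,eu2:1)100:1)100:1)100:1);")
  # type II with CM non-monophyletic
  t2b <- toy_tree("(out:1,((mo1:1,mo2:1)100:1,((cm1:1,eu1:1)100:1,(cm2:1,eu2:1)100:1)100:1)100:1);")
  res <- census(list(t1, t2, t2, t2b), sch, defs)
  tab <- res$table
  expect_equal(tab$count_bs_pass, c(1L, 3L, 0L))
  expect_equal(sum(tab$count_bs_pass), res$n_typed)
  expect_equal(sum(tab$proportion), 1)
  expect_equal(tab$monophyly_fraction[tab$type == "II"], 2 / 3)
  expect_equal(tab$monophyly_fraction[tab$type == "I"], 1)
  # order invariance
  res2 <- census(list(t2b, t2, t1, t2), sch, defs)
  expect_equal(res2$table$count_bs_pass, tab$count_bs_pass)
  expect_error(census(list(), sch, defs), "no trees")
})

test_that("census arithmetic reproduces printed-count summaries", {
  cs <- census_summary(c(sister = 454, other = 288))
  expect_equal(cs$percent[cs$type == "sister"], 61)
  cs2 <- census_summary(c(I = 316, II = 496, III = 203),
                        monophyly_counts = c(I = 168, II = 297, III = 122))
  expect_equal(cs2$monophyly_percent, c(53.2, 59.9, 60.1))
})

test_that("chromosome homogeneity test matches the Pearson formula", {
  # identical distributions: statistic 0, p = 1
  res0 <- chromosome_homogeneity_test(list(
    I = rep(c("chr1", "chr2"), c(10, 20)),
    II = rep(c("chr1", "chr2"), c(10, 20))))
  expect_equal(res0$statistic, 0)
  expect_equal(res0$p.value, 1)
  # hand-computed 2x2 Pearson chi-square
  res <- chromosome_homogeneity_test(list(
    I = rep(c("chr1", "chr2"), c(10, 20)),
    II = rep(c("chr1", "chr2"), c(20, 10))))
  expect_equal(res$statistic, 6.6667, tolerance = 1e-4)
  expect_equal(res$df, 1)
  expect_equal(res$p.value, 0.009823, tolerance = 1e-4)
  # all-zero category dropped with warning, df reduced
  expect_warning(
    res2 <- chromosome_homogeneity_test(list(
      I = factor(rep(c("chr1", "chr2"), c(5, 5)), levels = c("chr1", "chr2", "chr9")),
      II = factor(rep(c("chr1", "chr2"), c(4, 6)), levels = c("chr1", "chr2", "chr9")))),
    "zero total")
  expect_equal(res2$df, 1)
  expect_equal(ncol(res2$table), 2)
  expect_error(chromosome_homogeneity_test(list(I = "chr1")), "two types")
})
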