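test_that("NG86 handles the textbook cases", {
  s <- "ATGGCTAAGGCT"
  expect_equal(ng86_ks(s, s)$Ks, 0)
  # two glycine codons differing at a 4-fold degenerate third position
  r <- ng86_ks("GGTGGC", "GGCGGC")
  expect_equal(r$S, 2)
  expect_equal(r$Sd, 1)
  expect_equal(r$pS, 0.5)
  expect_equal(r$Ks, -0.75 * log(1 / 3), tolerance = 1e-10)
  expect_equal(r$Ks, 0.8239, tolerance = 1e-4)
})

test_that("NG86 validates its input", {
  expect_error(ng86_ks("ATGG", "ATGG"), "divisible by 3")
  expect_error(ng86_ks("ATG", "ATGATG"), "equal length")
  expect_error(ng86_ks("TAAGGG", "TAAGGG"), "stop")
  # saturation guard: every synonymous site differs
  expect_error(ng86_ks("TCTTCTTCT", "TCATCATCA"), "saturat")
})

test_that("NG86 agrees with an independent pathway-averaging oracle on all codon pairs", {
  codons <- names(Biostrings::GENETIC_CODE)[Biostrings::GENETIC_CODE != "*"]
  set.seed(61)
  # every pair once is ~3.7k comparisons; exhaustive but cheap
  for (c1 in codons) {
    for (c2 in codons) {
      o <- oracle_ng86(c1, c2)
      if (is.null(o$Sd) || is.na(o$Sd)) next  # all pathways stop-blocked
      got <- tryCatch(ng86_ks(c1, c2), error = function(e) e)
      if (inherits(got, "error")) {
        # only the saturation guard may fire on single codons
        expect_match(conditionMessage(got), "saturat")
        next
      }
      expect_equal(got$S, o$S, tolerance = 1e-10,
                   label = paste(c1, c2, "S"))
      expect_equal(got$Sd, o$Sd, tolerance = 1e-10,
                   label = paste(c1, c2, "Sd"))
      expect_equal(got$Nd, o$Nd, tolerance = 1e-10,
                   label = paste(c1, c2, "Nd"))
    }
  }
})

test_that("NG86 on a long simulated pair equals the per-codon oracle sum", {
  set.seed(67)
  codons <- names(Biostrings::GENETIC_CODE)[Biostrings::GENETIC_CODE != "*"]
  n <- 300
  c1 <- sample(codons, n, replace = TRUE)
  c2 <- c1
  mut <- sample(n, 60)
  c2[mut] <- sample(codons, 60, replace = TRUE)
  ok <- vapply(seq_len(n), function(i) {
    o <- oracle_ng86(c1[i], c2[i])
    !is.null(o$Sd) && !is.na(o$Sd)
  }, logical(1))
  c1 <- c1[ok]; c2 <- c2[ok]
  got <- ng86_ks(paste(c1, collapse = ""), paste(c2, collapse = ""))
  oS <- 0; oSd <- 0
  for (i in seq_along(c1)) {
    o <- oracle_ng86(c1[i], c2[i])
    oS <- oS + o$S; oSd <- oSd + o$Sd
  }
  expect_equal(got$S, oS, tolerance = 1e-10)
  expect_equal(got$Sd, oSd, tolerance = 1e-10)
  expect_equal(got$Ks, -0.75 * log(1 - 4 / 3 * oSd / oS), tolerance = 1e-10)
})

test_that("node weighting yields n(n-1)/2 records of total weight n-1", {
  # family of 2: one record, weight 1
  f2 <- gene_family("f2", matrix(c(0, 0.4, 0.4, 0), 2, 2,
                                 dimnames = list(c("A", "B"), c("A", "B"))))
  w2 <- weight_family(f2)
  expect_equal(nrow(w2), 1)
  expect_equal(w2$weight, 1)
  expect_equal(w2$ks, 0.4)

  # family of 4 with tree ((A,B),(C,D))
  genes <- c("A", "B", "C", "D")
  ks <- matrix(1, 4, 4, dimnames = list(genes, genes))
  ks[1, 2] <- ks[2, 1] <- 0.2
  ks[3, 4] <- ks[4, 3] <- 0.3
  diag(ks) <- 0
  f4 <- gene_family("f4", ks)
  tree <- read_newick("((A:0.1,B:0.1):0.4,(C:0.15,D:0.15):0.35);")
  w4 <- weight_family(f4, tree = ape::as.phylo(tree))
  expect_equal(nrow(w4), 6)
  expect_equal(sum(w4$weight), 3)
  byn <- tapply(w4$weight, w4$node, sum)
  expect_true(all(abs(byn - 1) < 1e-12))
  root_records <- w4[w4$weight == 0.25, ]
  expect_equal(nrow(root_records), 4)
  expect_setequal(paste(root_records$gene_i, root_records$gene_j),
                  c("A C", "A D", "B C", "B D"))

  # family of 3: weights 1, 1/2, 1/2
  ks3 <- matrix(c(0, 0.2, 1, 0.2, 0, 1, 1, 1, 0), 3, 3,
                dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  w3 <- weight_family(gene_family("f3", ks3))
  expect_equal(sort(w3$weight), c(0.5, 0.5, 1))
  expect_equal(nrow(w3), 3)
})

test_that("weighting invariants hold for every simulated family", {
  fams <- simulate_ks_families(60, 0.9, 0.6, 0.15,
                               config = sim_config(seed = 73))
  for (f in fams) {
    n <- length(f$genes)
    w <- weight_family(f)
    expect_equal(nrow(w), n * (n - 1) / 2)
    expect_equal(sum(w$weight), n - 1)
    byn <- tapply(w$weight, w$node, sum)
    expect_true(all(abs(byn - 1) < 1e-12))
  }
})

test_that("family-size and matrix validation is enforced", {
  expect_error(gene_family("x", matrix(0, 1, 1)), "1 < n < 5")
  expect_error(gene_family("x", matrix(0, 5, 5)), "1 < n < 5")
  bad <- matrix(c(0, 1, 2, 0), 2, 2)
  expect_error(gene_family("x", bad), "symmetric")
})

test_that("UPGMA family trees join closest pairs and honor ultrametric input", {
  genes <- c("A", "B", "C", "D")
  ks <- matrix(c(0, 0.2, 1.0, 1.0,
                 0.2, 0, 1.0, 1.0,
                 1.0, 1.0, 0, 0.5,
                 1.0, 1.0, 0.5, 0), 4, 4, dimnames = list(genes, genes))
  tr <- build_family_tree(gene_family("fx", ks))
  expect_true(ape::is.monophyletic(tr, c("A", "B")))
  expect_true(ape::is.monophyletic(tr, c("C", "D")))
  # ultrametric matrix reproduced exactly by the UPGMA fixed point
  d <- ape::cophenetic.phylo(tr)
  expect_equal(d[genes, genes], ks, tolerance = 1e-10)
  expect_error(build_family_tree(matrix(c(0, NA, NA, 0), 2, 2,
                                        dimnames = list(c("a", "b"),
                                                        c("a", "b")))),
               "NA")
})

test_that("UPGMA matches the phangorn reference implementation", {
  set.seed(83)
  for (rep in 1:10) {
    n <- sample(3:4, 1)
    genes <- paste0("g", seq_len(n))
    # near-ultrametric random matrix
    tr0 <- ape::rcoal(n, tip.label = genes)
    d0 <- ape::cophenetic.phylo(tr0)
    d <- d0 * matrix(runif(n * n, 0.98, 1.02), n)
    d <- (d + t(d)) / 2; diag(d) <- 0
    mine <- build_family_tree(d)
    ref <- phangorn::upgma(stats::as.dist(d))
    expect_equal(ape::dist.topo(ape::unroot(mine), ape::unroot(ref)), 0,
                 ignore_attr = TRUE)
  }
})

test_that("ks_peak finds point masses, warns on bimodality, is weight-linear", {
  rec1 <- data.frame(ks = rep(0.9, 50), weight = 1)
  expect_equal(ks_peak(rec1)$mode, 0.9, tolerance = 0.005)
  # duplicating every record at half weight leaves the mode unchanged
  rec_half <- rbind(transform(rec1, weight = 0.5),
                    transform(rec1, weight = 0.5))
  expect_equal(ks_peak(rec_half, bw = 0.05)$mode,
               ks_peak(rec1, bw = 0.05)$mode)
  # two equal cohorts: multimodality warning, global mode reported
  rec2 <- data.frame(ks = c(rep(0.3, 50), rep(1.2, 50)), weight = 1)
  expect_warning(pk <- ks_peak(rec2, bw = 0.03), "multimodal")
  expect_true(abs(pk$mode - 0.3) < 0.01 || abs(pk$mode - 1.2) < 0.01)
  expect_error(ks_peak(data.frame(ks = c(3, 4), weight = 1)), "interval")
})

test_that("the weighted pipeline recovers a planted WGD peak", {
  fams <- simulate_ks_families(400, wgd_ks = 0.9, wgd_fraction = 0.6,
                               noise_sigma = 0.1,
                               config = sim_config(seed = 97))
  rec <- do.call(rbind, lapply(fams, weight_family))
  pk <- suppressWarnings(ks_peak(rec))
  expect_lt(abs(pk$mode - 0.9), 0.05)
  # and the observed weighted mode tracks the true node values
  true_rec <- data.frame(ks = unlist(lapply(fams, `[[`, "true_node_ks")),
                         weight = 1)
  pk_true <- suppressWarnings(ks_peak(true_rec))
  expect_lt(abs(pk$mode - pk_true$mode), 0.05)
})

test_that("molecular ages follow T = K / (2r)", {
  expect_equal(molecular_age(0.03, 1.51e-9), 9933775, tolerance = 1e-6)
  expect_equal(round(molecular_age(0.03, 1.51e-9) / 1e6, 1), 9.9)
  expect_equal(molecular_age(0.0302, 1.51e-9), 1e7)
  expect_equal(molecular_age(0), 0)
  expect_error(molecular_age(-0.1), "K must")
  expect_error(molecular_age(0.03, r = 0), "r must")
})
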