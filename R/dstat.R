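## ABBA-BABA D-statistics with block-jackknife standard errors.

#' Count ABBA/BABA site patterns into blocks
#'
#' Sites are rows of a 0/1 derived-allele matrix over (P1, P2, P3, O); a site
#' is ABBA iff the pattern is (0,1,1,0) and BABA iff (1,0,1,0).  All other
#' patterns are ignored; rows containing values other than 0/1 (or NA) are
#' skipped and counted.
#'
#' @param genotypes matrix or data frame with 4 columns (P1, P2, P3, O).
#' @param block_size number of consecutive sites per block.
#' @param taxa taxon names in (P1, P2, P3, O) order.
#' @return `site_pattern_blocks`: data frame `block`, `nABBA`, `nBABA`,
#'   `n_sites`, with attributes `taxa` and `n_skipped`.
#' @export
count_patterns <- function(genotypes, block_size,
                           taxa = colnames(genotypes)) {
  g <- as.matrix(genotypes)
  if (ncol(g) != 4) stop("genotypes must have 4 columns (P1, P2, P3, O)")
  if (is.null(taxa)) taxa <- c("P1", "P2", "P3", "O")
  n <- nrow(g)
  ok <- rowSums(is.na(g) | (g != 0 & g != 1)) == 0
  n_skipped <- sum(!ok)
  abba <- ok & g[, 1] == 0 & g[, 2] == 1 & g[, 3] == 1 & g[, 4] == 0
  baba <- ok & g[, 1] == 1 & g[, 2] == 0 & g[, 3] == 1 & g[, 4] == 0
  block <- (seq_len(n) - 1L) %/% block_size + 1L
  out <- data.frame(
    block = seq_len(max(block)),
    nABBA = as.vector(tapply(abba, block, sum)),
    nBABA = as.vector(tapply(baba, block, sum)),
    n_sites = as.vector(tapply(ok, block, length))
  )
  structure(out, class = c("site_pattern_blocks", "data.frame"),
            taxa = taxa, n_skipped = n_skipped)
}

#' Construct site-pattern blocks from counts
#' @param nABBA,nBABA integer vectors of per-block counts.
#' @param n_sites optional per-block site totals.
#' @param taxa taxon names in (P1, P2, P3, O) order.
#' @return `site_pattern_blocks`.
#' @export
site_pattern_blocks <- function(nABBA, nBABA, n_sites = nABBA + nBABA,
                                taxa = c("P1", "P2", "P3", "O")) {
  if (any(nABBA < 0) || any(nBABA < 0)) stop("counts must be >= 0")
  if (any(nABBA + nBABA > n_sites))
    stop("nABBA + nBABA cannot exceed n_sites in a block")
  structure(data.frame(block = seq_along(nABBA), nABBA = nABBA,
                       nBABA = nBABA, n_sites = n_sites),
            class = c("site_pattern_blocks", "data.frame"), taxa = taxa)
}

#' ABBA-BABA D-statistic with block-jackknife Z-score
#'
#' D = (sum ABBA - sum BABA) / (sum ABBA + sum BABA); the standard error is
#' the delete-one block jackknife SE and Z = D / SE.  |Z| > `z_threshold`
#' (default 3) is called significant.
#'
#' @param blocks a `site_pattern_blocks` object (>= 2 informative blocks).
#' @param z_threshold significance threshold on |Z|.
#' @return object of class `dstat_result`: list with `nABBA`, `nBABA`, `D`,
#'   `se`, `Z`, `significant`, `n_blocks`.
#' @export
d_statistic <- function(blocks, z_threshold = 3) {
  a <- blocks$nABBA; b <- blocks$nBABA
  A <- sum(a); B <- sum(b)
  if (A + B == 0)
    stop("no informative (ABBA/BABA) sites; D is undefined")
  informative <- (a + b) > 0
  if (sum(informative) < 2)
    stop("all informative sites fall in a single block; ",
         "the jackknife requires >= 2 informative blocks")
  D <- (A - B) / (A + B)
  m <- length(a)
  Di <- vapply(seq_len(m), function(i)
    (A - a[i] - (B - b[i])) / (A - a[i] + B - b[i]), numeric(1))
  se <- sqrt((m - 1) / m * sum((Di - mean(Di))^2))
  Z <- if (se == 0) {
    if (D == 0) 0 else {
      warning("degenerate jackknife: all leave-one-out estimates identical; ",
              "Z undefined")
      NaN
    }
  } else D / se
  structure(list(taxa = attr(blocks, "taxa"), nABBA = A, nBABA = B,
                 D = D, se = se, Z = Z,
                 significant = isTRUE(abs(Z) > z_threshold),
                 n_blocks = m),
            class = "dstat_result")
}

#' @export
print.dstat_result <- function(x, ...) {
  cat(sprintf("D = %.4f  (ABBA = %d, BABA = %d, %d blocks)\n",
              x$D, x$nABBA, x$nBABA, x$n_blocks))
  cat(sprintf("jackknife SE = %.4g, Z = %.2f%s\n", x$se, x$Z,
              if (x$significant) "  *significant*" else ""))
  invisible(x)
}

#' Does a quartet conform to the species tree?
#'
#' TRUE iff the rooted arrangement (((P1,P2),P3),O) matches the species-tree
#' topology restricted to the four taxa.  The D-statistic convention of the
#' source analyses only retains quartets passing this filter.
#'
#' @param quartet character vector (P1, P2, P3, O).
#' @param species_tree rooted `phylo` or `species_network` (major tree used).
#' @return logical.
#' @export
conformity_filter <- function(quartet, species_tree) {
  if (inherits(species_tree, "species_network"))
    species_tree <- network_major_tree(species_tree)
  if (length(quartet) != 4) stop("quartet must name 4 taxa")
  miss <- setdiff(quartet, species_tree$tip.label)
  if (length(miss) > 0)
    stop("taxa absent from species tree: ", paste(miss, collapse = ", "))
  idx <- .tree_index(species_tree)
  tip <- match(quartet, species_tree$tip.label)
  m12 <- .mrca2(idx, tip[1], tip[2])
  m13 <- .mrca2(idx, tip[1], tip[3])
  m23 <- .mrca2(idx, tip[2], tip[3])
  m123 <- .mrca2(idx, m12, tip[3])
  m_all <- .mrca2(idx, m123, tip[4])
  ## (P1,P2) must join below the join with P3, which must be below O's join
  idx$depth[m12] > idx$depth[m123] &&
    m13 == m123 && m23 == m123 &&
    idx$depth[m123] > idx$depth[m_all]
}
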