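## Unlinked biallelic site patterns under the 4-taxon MSC with an optional
## introgression pulse (P3 -> P2), the generating model behind the
## ABBA-BABA D-statistic.

#' Simulate site-pattern blocks for a 4-taxon D-statistic test
#'
#' For each unlinked site a genealogy is drawn under the multispecies
#' coalescent on (((P1,P2),P3),O); with probability `gamma` the P2 lineage
#' follows the introgression edge into P3's population at time `tau_gf`.
#' One mutation is placed uniformly on the genealogy (infinite sites), and
#' sites are grouped into consecutive blocks.
#'
#' @param tree4 a 4-taxon `species_network`/`phylo` of shape
#'   (((P1,P2),P3),O), branch lengths in coalescent units, or `NULL` to give
#'   split times directly via `tau12`, `tau123`, `tau_root`.
#' @param gamma introgression probability in `[0, 1]`.
#' @param config a [sim_config()]; `block_count`, `sites_per_block` and
#'   `seed` are used.
#' @param taxa character vector naming (P1, P2, P3, O); defaults to the order
#'   implied by the tree shape.
#' @param tau_gf time of the introgression pulse (default: half of the
#'   P1-P2 split time).
#' @param tau12,tau123,tau_root split times when `tree4` is `NULL`.
#' @param keep_genotypes retain the per-site 0/1 derived-allele matrix.
#' @return a `site_pattern_blocks` object: data frame of `block`, `nABBA`,
#'   `nBABA`, `n_sites`, with the taxon order and (optionally) genotypes as
#'   attributes.
#' @export
simulate_site_patterns <- function(tree4 = NULL, gamma = 0, config = sim_config(),
                                   taxa = NULL, tau_gf = NULL,
                                   tau12 = 1, tau123 = 2, tau_root = 3,
                                   keep_genotypes = FALSE) {
  if (gamma < 0 || gamma > 1) stop("gamma must lie in [0, 1]")
  if (!is.null(tree4)) {
    if (inherits(tree4, "species_network")) tree4 <- network_major_tree(tree4)
    if (length(tree4$tip.label) != 4) stop("tree4 must have exactly 4 taxa")
    idx <- .tree_index(tree4)
    ## identify the nested cherry (P1,P2), then P3 and the outgroup O
    sets <- .clade_tip_sets(tree4)
    sizes <- lengths(sets)
    sizes[seq_len(4)] <- 0L  # ignore tips
    three <- which(sizes == 3)
    if (length(three) != 1) stop("tree4 must be a pectinate 4-taxon tree")
    cherry <- which(sizes == 2)
    cherry <- cherry[cherry != three]
    if (length(cherry) != 1) stop("tree4 must be a pectinate 4-taxon tree")
    p12 <- sets[[cherry]]
    p3 <- setdiff(sets[[three]], p12)
    o <- setdiff(seq_len(4), sets[[three]])
    taxa <- tree4$tip.label[c(p12, p3, o)]
    tau_root <- max(idx$depth)  # tips contemporaneous; ages above the tips
    tau12 <- tau_root - idx$depth[cherry]
    tau123 <- tau_root - idx$depth[three]
  }
  if (is.null(taxa)) taxa <- c("P1", "P2", "P3", "O")
  if (!(tau12 <= tau123 && tau123 <= tau_root))
    stop("split times must satisfy tau12 <= tau123 <= tau_root")
  if (is.null(tau_gf)) tau_gf <- tau12 / 2
  if (tau_gf < 0 || tau_gf > tau123)
    stop("tau_gf must lie in [0, tau123]")
  n_sites <- config$block_count * config$sites_per_block
  set.seed(config$seed)
  geno <- .sim_site_patterns_cpp(n_sites, gamma, tau_gf, tau12, tau123,
                                 tau_root)
  colnames(geno) <- taxa
  blocks <- count_patterns(geno, block_size = config$sites_per_block,
                           taxa = taxa)
  if (keep_genotypes) attr(blocks, "genotypes") <- geno
  blocks
}
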