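## Synthetic gene families with a WGD-derived duplication cohort plus
## small-scale-duplication background, and LTR divergence samples clustered
## around a burst value.

## random rooted binary topology over n genes by sequential random joins;
## returns for each internal node (1..n-1, in join order) its two children
## (negative = tip index), so later joins are deeper.
.random_join_tree <- function(n) {
  active <- -seq_len(n)
  c1 <- integer(n - 1); c2 <- integer(n - 1)
  for (k in seq_len(n - 1)) {
    pair <- sample.int(length(active), 2)
    c1[k] <- active[pair[1]]; c2[k] <- active[pair[2]]
    active <- c(active[-pair], k)
  }
  list(c1 = c1, c2 = c2)
}

#' Simulate gene families with a WGD cohort
#'
#' Family sizes are drawn from {2, 3, 4} (the low-copy filter 1 < n < 5) with
#' probabilities `size_probs`.  Each duplication node is WGD-derived with
#' probability `wgd_fraction` (true pairwise Ks = `wgd_ks`) or background
#' (true Ks ~ Uniform(0.05, 2)); node values are sorted along the tree so
#' deeper duplication nodes carry larger Ks.  Observed pairwise Ks values are
#' the true value of the pair's duplication node times multiplicative
#' LogNormal(0, `noise_sigma`) noise.
#'
#' @param n_families number of families.
#' @param wgd_ks true pairwise Ks of the WGD cohort (> 0).
#' @param wgd_fraction probability a duplication node is WGD-derived.
#' @param noise_sigma lognormal sigma of the multiplicative noise.
#' @param config a [sim_config()] (seed).
#' @param size_probs probabilities of family sizes 2, 3, 4.
#' @param sizes optional explicit vector of family sizes (must lie in 2..4).
#' @return list of [gene_family()] objects; each carries the true family
#'   tree (`$tree`), per-node true Ks (`$true_node_ks`) and cohort labels
#'   (`$true_node_type`).
#' @export
simulate_ks_families <- function(n_families, wgd_ks, wgd_fraction,
                                 noise_sigma, config = sim_config(),
                                 size_probs = c(0.5, 0.3, 0.2),
                                 sizes = NULL) {
  if (wgd_ks <= 0) stop("wgd_ks must be > 0")
  if (wgd_fraction < 0 || wgd_fraction > 1)
    stop("wgd_fraction must lie in [0, 1]")
  if (noise_sigma < 0) stop("noise_sigma must be >= 0")
  set.seed(config$seed)
  if (is.null(sizes)) {
    sizes <- sample(2:4, n_families, replace = TRUE, prob = size_probs)
  } else {
    if (any(sizes < 2 | sizes > 4))
      stop("family sizes must satisfy 1 < n < 5 (low-copy filter)")
    sizes <- rep_len(sizes, n_families)
  }
  lapply(seq_len(n_families), function(f) {
    n <- sizes[f]
    top <- .random_join_tree(n)
    is_wgd <- stats::runif(n - 1) < wgd_fraction
    vals <- ifelse(is_wgd, wgd_ks, stats::runif(n - 1, 0.05, 2.0))
    ## deeper nodes (later joins) must carry larger Ks
    vals <- sort(vals)
    genes <- sprintf("f%d_g%d", f, seq_len(n))
    ## true pairwise Ks = value at the pair's MRCA join
    node_of <- matrix(NA_integer_, n, n)
    sets <- vector("list", n - 1)
    for (k in seq_len(n - 1)) {
      get <- function(id) if (id < 0) -id else sets[[id]]
      L <- get(top$c1[k]); R <- get(top$c2[k])
      sets[[k]] <- c(L, R)
      for (a in L) for (b in R) node_of[a, b] <- node_of[b, a] <- k
    }
    ksmat <- matrix(0, n, n, dimnames = list(genes, genes))
    for (a in seq_len(n - 1)) for (b in (a + 1):n) {
      obs <- vals[node_of[a, b]] *
        (if (noise_sigma > 0) stats::rlnorm(1, 0, noise_sigma) else 1)
      ksmat[a, b] <- ksmat[b, a] <- obs
    }
    ## true tree as phylo with node heights = true Ks / 2
    phy <- .join_tree_to_phylo(top, genes, vals / 2)
    fam <- gene_family(sprintf("fam%d", f), ksmat, tree = phy)
    fam$true_node_ks <- vals
    fam$true_node_type <- ifelse(vals == wgd_ks, "wgd", "bg")
    fam
  })
}

.join_tree_to_phylo <- function(top, genes, heights) {
  n <- length(genes)
  nint <- n - 1L
  imap <- integer(nint)
  imap[nint] <- n + 1L
  if (nint > 1) imap[seq_len(nint - 1L)] <- n + 1L + seq_len(nint - 1L)
  conv <- function(id) if (id < 0) -id else imap[id]
  edge <- matrix(0L, 2L * nint, 2L)
  elen <- numeric(2L * nint)
  h <- function(id) if (id < 0) 0 else heights[id]
  for (k in seq_len(nint)) {
    edge[2 * k - 1, ] <- c(imap[k], conv(top$c1[k]))
    edge[2 * k, ] <- c(imap[k], conv(top$c2[k]))
    elen[2 * k - 1] <- heights[k] - h(top$c1[k])
    elen[2 * k] <- heights[k] - h(top$c2[k])
  }
  phy <- list(edge = edge, edge.length = elen, tip.label = genes,
              Nnode = nint)
  class(phy) <- "phylo"
  phy
}

#' Simulate LTR 5'/3' divergence values around a burst
#'
#' K ~ Normal(`burst_k`, `sd`) truncated at zero, emulating a burst of LTR
#' retrotransposon insertions whose terminal repeats have diverged for the
#' same amount of time.
#'
#' @param n number of elements.
#' @param burst_k burst divergence (> 0).
#' @param sd standard deviation (>= 0).
#' @param seed integer seed.
#' @return numeric vector of divergences.
#' @export
simulate_ltr_divergences <- function(n, burst_k, sd, seed = 1L) {
  if (burst_k <= 0) stop("burst_k must be > 0")
  if (sd < 0) stop("sd must be >= 0")
  set.seed(seed)
  if (sd == 0) return(rep(burst_k, n))
  out <- numeric(0)
  while (length(out) < n) {
    x <- stats::rnorm(n, burst_k, sd)
    out <- c(out, x[x >= 0])
  }
  out[seq_len(n)]
}
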