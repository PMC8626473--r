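## Node-weighted Ks distributions for whole-genome-duplication detection, and
## molecular age dating T = K / (2r) shared with LTR insertion-time analysis.
##
## A gene family of n members yields n(n-1)/2 pairwise Ks estimates but only
## n-1 duplication events; following the redundancy correction, each of the m
## cross-pairs spanning a duplication node enters the distribution with
## weight 1/m, so every node contributes total weight one.

#' Construct a gene family
#'
#' @param family_id identifier.
#' @param ks symmetric non-negative matrix of pairwise Ks values with gene
#'   ids as dimnames (2 <= n <= 4 members, the low-copy filter 1 < n < 5).
#' @param tree optional rooted binary `phylo` over the member genes.
#' @return object of class `gene_family`.
#' @export
gene_family <- function(family_id, ks, tree = NULL) {
  ks <- as.matrix(ks)
  n <- nrow(ks)
  if (n < 2 || n > 4)
    stop("family size must satisfy 1 < n < 5 (got n = ", n, ")")
  if (is.null(rownames(ks))) rownames(ks) <- colnames(ks) <-
      paste0("g", seq_len(n))
  if (!isSymmetric(unname(ks), tol = 1e-8))
    stop("ks matrix must be symmetric")
  if (any(ks[upper.tri(ks)] < 0) || anyNA(ks[upper.tri(ks)]))
    stop("ks values must be present and >= 0 for every pair")
  structure(list(family_id = family_id, genes = rownames(ks), ks = ks,
                 tree = tree),
            class = "gene_family")
}

#' UPGMA family tree from the pairwise Ks matrix
#'
#' Average-linkage agglomeration on the Ks distances; rows/columns are first
#' sorted lexicographically by gene id so ties break deterministically.
#'
#' @param family a `gene_family` or a symmetric Ks matrix.
#' @return rooted binary `phylo` over the member genes.
#' @export
build_family_tree <- function(family) {
  ks <- if (inherits(family, "gene_family")) family$ks else as.matrix(family)
  if (anyNA(ks)) stop("NaN/NA distances in Ks matrix")
  ord <- order(rownames(ks))
  ks <- ks[ord, ord, drop = FALSE]
  hc <- stats::hclust(stats::as.dist(ks), method = "average")
  ape::as.phylo(hc)
}

#' Node-weighted Ks records for one family
#'
#' For every duplication node with child clades L and R, emits the |L| x |R|
#' cross pairs, each with weight 1/(|L| x |R|): per node the weights sum to
#' one and per family the total weight is n - 1.
#'
#' @param family a `gene_family`.
#' @param tree rooted binary `phylo` over the genes; defaults to
#'   `family$tree` or, failing that, [build_family_tree()].
#' @return data frame: `family_id`, `node`, `gene_i`, `gene_j`, `ks`,
#'   `weight`.
#' @export
weight_family <- function(family, tree = NULL) {
  if (is.null(tree)) tree <- family$tree
  if (is.null(tree)) tree <- build_family_tree(family)
  ks <- family$ks
  ntip <- length(tree$tip.label)
  if (!setequal(tree$tip.label, family$genes))
    stop("family tree tips do not match the family genes")
  sets <- .clade_tip_sets(tree)
  kids <- split(tree$edge[, 2], tree$edge[, 1])
  rows <- list()
  for (v in (ntip + 1):(ntip + tree$Nnode)) {
    ch <- kids[[as.character(v)]]
    if (length(ch) != 2) stop("family tree must be binary")
    L <- tree$tip.label[unlist(sets[ch[1]])]
    R <- tree$tip.label[unlist(sets[ch[2]])]
    m <- length(L) * length(R)
    for (a in L) for (b in R) {
      if (is.na(ks[a, b]))
        stop("missing pairwise Ks entry for ", a, " - ", b)
      rows[[length(rows) + 1L]] <- data.frame(
        family_id = family$family_id, node = v, gene_i = a, gene_j = b,
        ks = ks[a, b], weight = 1 / m, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

## weighted Gaussian KDE evaluated on a grid
.weighted_kde <- function(x, w, grid, bw) {
  w <- w / sum(w)
  vapply(grid, function(g)
    sum(w * stats::dnorm((g - x) / bw)) / bw, numeric(1))
}

## Silverman's rule on the weighted sample with effective sample size
.weighted_bw <- function(x, w) {
  w <- w / sum(w)
  mu <- sum(w * x)
  sdw <- sqrt(sum(w * (x - mu)^2))
  neff <- 1 / sum(w^2)
  qs <- .weighted_quantile(x, w, c(0.25, 0.75))
  iqr <- qs[2] - qs[1]
  s <- min(sdw, if (iqr > 0) iqr / 1.34 else sdw)
  if (s <= 0) s <- max(sdw, 1e-3)
  0.9 * s * neff^(-1 / 5)
}

.weighted_quantile <- function(x, w, probs) {
  o <- order(x)
  x <- x[o]; w <- w[o] / sum(w)
  cw <- cumsum(w)
  vapply(probs, function(p) x[which(cw >= p)[1]], numeric(1))
}

#' Weighted-KDE mode of a node-weighted Ks distribution
#'
#' Gaussian kernel density with record weights; the mode is the argmax on a
#' fixed-step grid over the search interval.  The lower bound of the default
#' interval excludes the allelic/very-recent-duplicate spike near Ks = 0.
#'
#' @param records data frame with columns `ks` and `weight` (e.g. rbind-ed
#'   output of [weight_family()]).
#' @param bw kernel bandwidth; default Silverman's rule on the weighted
#'   sample.
#' @param interval search interval (default (0.05, 2.0]).
#' @param step grid step (default 0.005).
#' @return object of class `ks_peak`: `mode`, `bw`, `grid`, `density`,
#'   `n_modes` (a warning is emitted when the density has several local
#'   maxima).
#' @export
ks_peak <- function(records, bw = NULL, interval = c(0.05, 2.0),
                    step = 0.005) {
  x <- records$ks; w <- records$weight
  if (is.null(w)) w <- rep(1, length(x))
  keep <- x >= interval[1] & x <= interval[2]
  if (!any(keep) || sum(w[keep]) <= 0)
    stop("no Ks records inside the search interval")
  if (is.null(bw)) bw <- .weighted_bw(x[keep], w[keep])
  grid <- seq(interval[1], interval[2], by = step)
  dens <- .weighted_kde(x[keep], w[keep], grid, bw)
  mode_i <- which.max(dens)
  interior <- seq(2, length(dens) - 1)
  localmax <- interior[dens[interior] > dens[interior - 1] &
                         dens[interior] >= dens[interior + 1]]
  ## only count substantial secondary peaks, not noise wiggles
  localmax <- localmax[dens[localmax] >= 0.25 * dens[mode_i]]
  n_modes <- length(localmax) + (mode_i == 1) + (mode_i == length(dens))
  if (n_modes > 1)
    warning("Ks density is multimodal (", n_modes,
            " local maxima); reporting the global mode")
  structure(list(mode = grid[mode_i], bw = bw, grid = grid, density = dens,
                 n_modes = max(n_modes, 1L)),
            class = "ks_peak")
}

#' @export
print.ks_peak <- function(x, ...) {
  cat(sprintf("weighted Ks peak: mode = %.3f (bandwidth %.4f)\n",
              x$mode, x$bw))
  invisible(x)
}

#' Molecular age from a divergence value
#'
#' T = K / (2 r): used both for LTR insertion times (K = divergence of the
#' 5'/3' terminal repeats) and for converting a Ks peak into a WGD age.
#'
#' @param K synonymous divergence (Ks) or substitution divergence, >= 0.
#' @param r substitutions per site per year (default 1.51e-9).
#' @return age in years (vectorized over `K`).
#' @export
molecular_age <- function(K, r = 1.51e-9) {
  if (any(K < 0)) stop("K must be >= 0")
  if (r <= 0) stop("substitution rate r must be > 0")
  K / (2 * r)
}
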