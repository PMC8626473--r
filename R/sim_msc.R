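## Multispecies-coalescent simulation of gene trees on species trees and
## networks.  Time is measured in coalescent units (2N generations); within a
## population carrying k lineages the waiting time to the next coalescence is
## Exponential(k(k-1)/2) and the merging pair is uniform.  At a reticulate
## node each lineage independently follows a parent edge with its inheritance
## probability.  Remaining lineages coalesce above the root.

#' Simulation configuration
#'
#' @param seed integer master seed; fixed seed implies byte-identical output.
#' @param n_trees number of gene trees to simulate.
#' @param mutation_scale substitutions per coalescent unit applied to output
#'   branch lengths (default 1).
#' @param support_model simulated bootstrap supports: either
#'   `list(type = "constant", value = 100)` (default, so that support filters
#'   are inert on synthetic data) or `list(type = "beta", mean, conc)` giving
#'   `100 * Beta(mean * conc, (1 - mean) * conc)` noise.
#' @param block_count,sites_per_block block layout for site-pattern
#'   simulation.
#' @return object of class `sim_config`.
#' @export
sim_config <- function(seed = 1L, n_trees = 1L, mutation_scale = 1,
                       support_model = list(type = "constant", value = 100),
                       block_count = 200L, sites_per_block = 250L) {
  if (n_trees < 1) stop("n_trees must be >= 1")
  if (mutation_scale <= 0) stop("mutation_scale must be > 0")
  structure(list(seed = as.integer(seed), n_trees = as.integer(n_trees),
                 mutation_scale = mutation_scale,
                 support_model = support_model,
                 block_count = as.integer(block_count),
                 sites_per_block = as.integer(sites_per_block)),
            class = "sim_config")
}

.sim_supports <- function(model, n) {
  if (identical(model$type, "constant")) return(rep(model$value, n))
  if (identical(model$type, "beta")) {
    a <- model$mean * model$conc
    b <- (1 - model$mean) * model$conc
    return(100 * stats::rbeta(n, a, b))
  }
  stop("unknown support model type: ", model$type)
}

## Coalesce `lins` (indices) in a population open during [t0, t1]; merge
## events are appended to the environment `g` (gene-tree builder).
.coalesce <- function(lins, t0, t1, g) {
  k <- length(lins)
  t <- t0
  while (k >= 2) {
    w <- stats::rexp(1, rate = k * (k - 1) / 2)
    if (t + w > t1) break
    t <- t + w
    pair <- sample.int(k, 2)
    g$m <- g$m + 1L
    g$c1[g$m] <- lins[pair[1]]
    g$c2[g$m] <- lins[pair[2]]
    g$time[g$m + g$ntip] <- t
    lins <- c(lins[-pair], g$m + g$ntip)
    k <- k - 1L
  }
  lins
}

## One gene tree under the network MSC; returns a gene_tree.
.sim_one_tree <- function(net, topo, age, samples, mutation_scale,
                          support_model, tree_id,
                          kids = split(seq_len(nrow(net$edges)),
                                       net$edges$parent),
                          pedges = split(seq_len(nrow(net$edges)),
                                         net$edges$child)) {
  leaves <- which(net$is_leaf)
  tip_sp <- character(0); tip_lab <- character(0)
  tips_of <- vector("list", length(net$label))
  nt <- 0L
  for (v in leaves) {
    k <- samples[[net$label[v]]]
    ids <- nt + seq_len(k)
    nt <- nt + k
    tips_of[[v]] <- ids
    sp <- net$label[v]
    tip_sp <- c(tip_sp, rep(sp, k))
    tip_lab <- c(tip_lab, if (k == 1) sp else paste0(sp, "_", seq_len(k)))
  }
  g <- new.env(parent = emptyenv())
  g$ntip <- nt
  g$m <- 0L
  g$c1 <- integer(nt - 1L); g$c2 <- integer(nt - 1L)
  g$time <- numeric(2L * nt - 1L)
  edge_lineages <- vector("list", nrow(net$edges))
  for (v in topo) {
    if (net$is_leaf[v]) {
      arriving <- tips_of[[v]]
    } else {
      arriving <- integer(0)
      for (e in kids[[as.character(v)]]) {
        ch <- net$edges$child[e]
        lin <- edge_lineages[[e]]
        if (is.null(lin)) lin <- integer(0)
        arriving <- c(arriving,
                      .coalesce(lin, age[ch], age[v], g))
      }
    }
    pe <- pedges[[as.character(v)]]
    if (is.null(pe)) {                    # root: coalesce to completion
      .coalesce(arriving, age[v], Inf, g)
    } else if (length(pe) == 1) {
      edge_lineages[[pe]] <- arriving
    } else {                              # reticulate: route by gamma
      gam <- net$edges$gamma[pe]
      if (gam[1] >= 1 || gam[2] <= 0) {
        to1 <- rep(TRUE, length(arriving))
      } else if (gam[1] <= 0 || gam[2] >= 1) {
        to1 <- rep(FALSE, length(arriving))
      } else {
        to1 <- stats::runif(length(arriving)) < gam[1]
      }
      edge_lineages[[pe[1]]] <- arriving[to1]
      edge_lineages[[pe[2]]] <- arriving[!to1]
    }
  }
  ## assemble phylo: tips 1..nt, root nt+1; internal creation order k maps to
  ## nt+1+k except the last merge (the gene-tree root) which maps to nt+1
  nint <- g$m
  imap <- integer(nint)
  imap[nint] <- nt + 1L
  if (nint > 1) imap[seq_len(nint - 1L)] <- nt + 1L + seq_len(nint - 1L)
  remap <- function(x) ifelse(x > nt, imap[x - nt], x)
  edge <- matrix(0L, 2L * nint, 2L)
  elen <- numeric(2L * nint)
  for (k in seq_len(nint)) {
    p <- imap[k]
    for (j in 1:2) {
      ch <- if (j == 1) g$c1[k] else g$c2[k]
      row <- 2L * (k - 1L) + j
      edge[row, ] <- c(p, remap(ch))
      elen[row] <- (g$time[nt + k] - g$time[ch]) * mutation_scale
    }
  }
  sup <- .sim_supports(support_model, nint)
  phy <- list(edge = edge, edge.length = elen, tip.label = tip_lab,
              Nnode = nint,
              node.label = formatC(sup, format = "g", digits = 6))
  class(phy) <- "phylo"
  gene_tree(phy, species = stats::setNames(tip_sp, tip_lab),
            tree_id = tree_id)
}

#' Simulate gene trees under the network multispecies coalescent
#'
#' @param network a `species_network` (a plain species tree is a network with
#'   no reticulations), branch lengths in coalescent units.
#' @param config a [sim_config()]; `n_trees` and `mutation_scale` are used.
#' @param samples_per_species optional named integer vector of lineages
#'   sampled per species (default one each).
#' @return list of `gene_tree` objects with branch lengths in coalescent
#'   units times `mutation_scale`.
#' @export
simulate_msc_gene_trees <- function(network, config,
                                    samples_per_species = NULL) {
  if (inherits(network, "phylo")) network <- as_species_network(network)
  validate_species_network(network)
  species <- network_species(network)
  if (length(species) == 0) stop("network has no species")
  if (is.null(samples_per_species))
    samples_per_species <- stats::setNames(rep(1L, length(species)), species)
  missing <- setdiff(species, names(samples_per_species))
  if (length(missing) > 0)
    samples_per_species[missing] <- 1L
  age <- .network_ages(network)
  topo <- .network_topo_order(network, age)
  kids <- split(seq_len(nrow(network$edges)), network$edges$parent)
  pedges <- split(seq_len(nrow(network$edges)), network$edges$child)
  samples <- as.list(samples_per_species)
  set.seed(config$seed)
  lapply(seq_len(config$n_trees), function(i)
    .sim_one_tree(network, topo, age, samples,
                  config$mutation_scale, config$support_model, i,
                  kids = kids, pedges = pedges))
}

## children-before-parents order, deterministic: by (age, id)
.network_topo_order <- function(net, age = .network_ages(net)) {
  nnode <- length(net$label)
  nkids <- tabulate(net$edges$parent, nnode)
  done <- integer(nnode)
  ready <- rep(FALSE, nnode)
  ready[nkids == 0L] <- TRUE
  out <- integer(0)
  processed <- rep(FALSE, nnode)
  while (length(out) < nnode) {
    cand <- which(ready & !processed)
    if (length(cand) == 0) stop("cycle detected in network")
    v <- cand[order(age[cand], cand)][1]
    processed[v] <- TRUE
    out <- c(out, v)
    for (e in which(net$edges$child == v)) {
      p <- net$edges$parent[e]
      done[p] <- done[p] + 1L
      if (done[p] >= nkids[p]) ready[p] <- TRUE
    }
  }
  out
}

#' Observed rooted-triplet topology counts
#'
#' Counts, over a list of 3-tip gene trees, how often each species is the
#' "odd one out" (sister to the other two).
#'
#' @param trees list of 3-tip `gene_tree` objects.
#' @return named integer vector, one entry per species observed as outgroup.
#' @export
triplet_topology_counts <- function(trees) {
  odd <- vapply(trees, function(tr) {
    idx <- .tree_index(tr)
    obs <- .triplet_from_index(idx, match(unique(tip_species(tr)),
                                          tip_species(tr)))
    if (is.na(obs$odd)) NA_character_ else tip_species(tr)[obs$odd]
  }, character(1))
  table(factor(odd))
}
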