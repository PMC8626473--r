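## Triplet branch-length test separating incomplete lineage sorting from
## hybridization.  For each species triplet and observed rooted topology, the
## internal branch lengths across gene trees are fit with a one-component
## exponential (pure ILS) and a two-component shifted-exponential mixture
## (ILS plus a second, older cohort); the models are compared by BIC with a
## strict Delta-BIC > 10 decision rule.

## light per-tree index: parent pointers and root-to-node path lengths
.tree_index <- function(phy) {
  ntip <- length(phy$tip.label)
  nn <- ntip + phy$Nnode
  par <- integer(nn)
  plen <- numeric(nn)
  par[phy$edge[, 2]] <- phy$edge[, 1]
  plen[phy$edge[, 2]] <- if (is.null(phy$edge.length))
    0 else phy$edge.length
  root <- ntip + 1L
  depth <- rep(NA_real_, nn)
  depth[root] <- 0
  ## preorder fill
  eo <- ape::reorder.phylo(phy, "postorder")$edge
  for (k in rev(seq_len(nrow(eo)))) {
    depth[eo[k, 2]] <- depth[eo[k, 1]] + plen[eo[k, 2]]
  }
  ## number of edges from root (for MRCA walking)
  lev <- rep(0L, nn)
  for (k in rev(seq_len(nrow(eo)))) lev[eo[k, 2]] <- lev[eo[k, 1]] + 1L
  list(ntip = ntip, parent = par, depth = depth, level = lev, root = root)
}

.mrca2 <- function(idx, a, b) {
  while (a != b) {
    if (idx$level[a] >= idx$level[b]) a <- idx$parent[a] else b <- idx$parent[b]
  }
  a
}

## rooted triplet of three tip indices: which is the odd one out, and the
## internal branch length (depth difference of the two nested MRCAs)
.triplet_from_index <- function(idx, tips) {
  m12 <- .mrca2(idx, tips[1], tips[2])
  m13 <- .mrca2(idx, tips[1], tips[3])
  m23 <- .mrca2(idx, tips[2], tips[3])
  m_all <- .mrca2(idx, m12, tips[3])
  d <- idx$depth[c(m12, m13, m23)]
  dall <- idx$depth[m_all]
  nodes <- c(m12, m13, m23)
  deeper <- which(nodes != m_all)
  if (length(deeper) != 1) {
    ## true polytomy (all three pairwise MRCAs coincide) -> unresolved
    if (length(unique(nodes)) == 1) return(list(odd = NA, t = NA_real_))
    ## zero-length but binary: pick the pair whose MRCA differs
    deeper <- which(d == max(d))[1]
  }
  odd <- tips[c(3L, 2L, 1L)[deeper]]
  list(odd = odd, t = d[deeper] - dall)
}

#' Extract rooted-triplet observations from gene trees
#'
#' For each tree and requested species triplet, restricts the tree to one tip
#' per species (for multi-copy species, the copy set minimizing the total
#' pairwise path length) and records the observed topology -- identified by
#' the "odd" species sister to the other two -- and the internal branch
#' length of the restricted triplet.
#'
#' @param trees list of rooted `gene_tree` objects.
#' @param species_triplets list/matrix of species triplets (character(3)).
#' @return data frame with columns `tree`, `sp1`, `sp2`, `sp3`, `odd`, `t`;
#'   attribute `n_skipped` counts tree-triplet pairs lacking a species or
#'   unresolved.
#' @export
extract_triplets <- function(trees, species_triplets) {
  if (is.matrix(species_triplets))
    species_triplets <- asplit(species_triplets, 1)
  if (!is.list(species_triplets)) species_triplets <- list(species_triplets)
  rows <- vector("list", length(trees) * length(species_triplets))
  ri <- 0L; skipped <- 0L
  for (ti in seq_along(trees)) {
    tr <- trees[[ti]]
    sp <- tip_species(tr)
    idx <- .tree_index(tr)
    for (qi in seq_along(species_triplets)) {
      trip <- species_triplets[[qi]]
      cand <- lapply(trip, function(s) which(sp == s))
      if (any(lengths(cand) == 0)) { skipped <- skipped + 1L; next }
      if (all(lengths(cand) == 1)) {
        tips <- c(cand[[1]], cand[[2]], cand[[3]])
      } else {
        combos <- expand.grid(cand, KEEP.OUT.ATTRS = FALSE)
        best <- NULL; bestd <- Inf
        for (r in seq_len(nrow(combos))) {
          tt <- as.integer(combos[r, ])
          d <- 0
          for (u in 1:2) for (v in (u + 1):3) {
            m <- .mrca2(idx, tt[u], tt[v])
            d <- d + idx$depth[tt[u]] + idx$depth[tt[v]] - 2 * idx$depth[m]
          }
          if (d < bestd) { bestd <- d; best <- tt }
        }
        tips <- best
      }
      obs <- .triplet_from_index(idx, tips)
      if (is.na(obs$odd)) { skipped <- skipped + 1L; next }
      ri <- ri + 1L
      rows[[ri]] <- data.frame(tree = ti, sp1 = trip[1], sp2 = trip[2],
                               sp3 = trip[3], odd = sp[obs$odd], t = obs$t,
                               stringsAsFactors = FALSE)
    }
  }
  out <- if (ri == 0) {
    data.frame(tree = integer(), sp1 = character(), sp2 = character(),
               sp3 = character(), odd = character(), t = numeric())
  } else do.call(rbind, rows[seq_len(ri)])
  attr(out, "n_skipped") <- skipped
  out
}

#' Fit the exponential / shifted-exponential mixture to triplet branch lengths
#'
#' One-component model: `t ~ Exp(lambda)` (pure ILS; the MLE is the sample
#' mean).  Two-component model: with weight `pi` a shifted exponential
#' `K + Exp(lambda)` (the non-ILS cohort) and with weight `1 - pi` the
#' unshifted exponential, sharing `lambda`.  The shift `K` is profiled on a
#' grid from 0 to the 99th percentile of `t` (`k_steps` points); at each `K`
#' an EM with closed-form M-steps runs to relative log-likelihood tolerance
#' `tol`, best of `n_restarts` starting weights.  Models are compared by BIC
#' (1 vs 3 free parameters); `Delta BIC = BIC1 - BIC2 > delta_bic` calls the
#' mixture.
#'
#' @param t non-negative internal branch lengths (N >= 20).
#' @param k_steps grid size for the shift parameter.
#' @param n_restarts number of EM starting values for `pi`.
#' @param tol EM relative log-likelihood convergence tolerance.
#' @param max_iter EM iteration cap per grid point.
#' @param delta_bic decision threshold (default 10).
#' @return object of class `triplet_fit`: `n`, `lambda1`, `logL1`, `pi`,
#'   `lambda2`, `shift`, `logL2`, `bic1`, `bic2`, `delta_bic`, `decision`
#'   (`"ILS-only"` or `"mixture"`), `ratio` = (1-pi)/pi.
#' @export
fit_branch_mixture <- function(t, k_steps = 200, n_restarts = 5,
                               tol = 1e-8, max_iter = 500, delta_bic = 10) {
  t <- as.numeric(t)
  if (anyNA(t) || any(t < 0)) stop("branch lengths must be non-negative")
  N <- length(t)
  if (N < 20) stop("insufficient observations (N = ", N, " < 20)")
  if (all(t == 0)) stop("degenerate fit: all branch lengths are zero")
  lam1 <- mean(t)
  logL1 <- sum(stats::dexp(t, rate = 1 / lam1, log = TRUE))
  kmax <- stats::quantile(t, 0.99, names = FALSE)
  grid <- seq(0, kmax, length.out = k_steps)
  starts <- seq(0.1, 0.9, length.out = n_restarts)
  best <- c(logL = -Inf, pi = 0, lam = lam1, K = 0)
  for (p0 in starts) {
    fit <- .em_profile_cpp(t, grid, p0, lam1, tol, max_iter)
    g <- which.max(fit[, 1])
    if (fit[g, 1] > best["logL"])
      best <- c(logL = fit[g, 1], pi = fit[g, 2], lam = fit[g, 3],
                K = grid[g])
  }
  logL2 <- max(best[["logL"]], logL1)   # grid includes K = 0: nested
  if (best[["logL"]] < logL1) best <- c(logL = logL1, pi = 0, lam = lam1, K = 0)
  bic1 <- -2 * logL1 + 1 * log(N)
  bic2 <- -2 * logL2 + 3 * log(N)
  dbic <- bic1 - bic2
  pi_hat <- best[["pi"]]
  structure(list(n = N, lambda1 = lam1, logL1 = logL1,
                 pi = pi_hat, lambda2 = best[["lam"]], shift = best[["K"]],
                 logL2 = logL2, bic1 = bic1, bic2 = bic2, delta_bic = dbic,
                 decision = if (dbic > delta_bic) "mixture" else "ILS-only",
                 ratio = if (pi_hat > 0) (1 - pi_hat) / pi_hat else Inf),
            class = "triplet_fit")
}

#' @export
print.triplet_fit <- function(x, ...) {
  cat(sprintf("triplet mixture fit (N = %d): %s\n", x$n, x$decision))
  cat(sprintf("  lambda1 = %.4g (logL %.2f);  pi = %.3f, lambda = %.4g, K = %.3f (logL %.2f)\n",
              x$lambda1, x$logL1, x$pi, x$lambda2, x$shift, x$logL2))
  cat(sprintf("  Delta BIC = %.2f\n", x$delta_bic))
  invisible(x)
}

## species-tree topology for each triplet: which species is the true outgroup
.true_outgroups <- function(species_tree, triplets) {
  if (inherits(species_tree, "species_network"))
    species_tree <- network_major_tree(species_tree)
  idx <- .tree_index(species_tree)
  vapply(triplets, function(trip) {
    tips <- match(trip, species_tree$tip.label)
    if (anyNA(tips))
      stop("triplet species absent from species tree: ",
           paste(trip[is.na(tips)], collapse = ", "))
    obs <- .triplet_from_index(idx, tips)
    if (is.na(obs$odd)) NA_character_ else species_tree$tip.label[obs$odd]
  }, character(1))
}

#' Resampled triplet-mixture protocol with species-pair aggregation
#'
#' Runs the mixture test over `n_runs` subsamples of `trees_per_run` gene
#' trees (sampled without replacement within a run).  Within a run every
#' requested triplet is split by observed topology and fit when it has at
#' least `min_obs` observations.  Fits for discordant topologies -- those
#' whose odd species differs from the species-tree outgroup of the triplet --
#' are attributed to the species pair united by the topology, and per-pair
#' averages are taken across triplets and runs.  A pair is flagged as a
#' hybridization signal when its average non-ILS rate (the fitted mixture
#' weight, counted as 0 for ILS-only decisions) exceeds `rate_threshold`.
#'
#' @param trees list of rooted `gene_tree` objects.
#' @param species_tree rooted species tree (`phylo` or `species_network`).
#' @param triplets list of species triplets; default all triplets of the
#'   species-tree taxa.
#' @param n_runs,trees_per_run resampling design (defaults 100 x 500).
#' @param seed integer seed for the run subsamples.
#' @param min_obs minimum observations per triplet-topology fit.
#' @param delta_bic,rate_threshold decision thresholds (defaults 10, 0.1).
#' @param ... further arguments to [fit_branch_mixture()].
#' @return object of class `triplet_protocol`: `fits` (per run/triplet/
#'   topology data frame) and `pairs` (per species pair: `avg_nonils_rate`,
#'   `mixture_call_frac`, `avg_ratio`, `n_fits`, `flagged`).
#' @export
run_triplet_protocol <- function(trees, species_tree, triplets = NULL,
                                 n_runs = 100, trees_per_run = 500,
                                 seed = 1L, min_obs = 20, delta_bic = 10,
                                 rate_threshold = 0.1, ...) {
  if (trees_per_run > length(trees))
    stop("trees_per_run exceeds the number of available trees")
  if (is.null(triplets)) {
    taxa <- if (inherits(species_tree, "species_network"))
      network_species(species_tree) else species_tree$tip.label
    triplets <- utils::combn(taxa, 3, simplify = FALSE)
  }
  if (is.matrix(triplets)) triplets <- asplit(triplets, 1)
  true_out <- .true_outgroups(species_tree, triplets)
  trip_key <- vapply(triplets, paste, character(1), collapse = "|")
  set.seed(seed)
  run_rows <- list()
  for (run in seq_len(n_runs)) {
    idx <- sample.int(length(trees), trees_per_run)
    obs <- extract_triplets(trees[idx], triplets)
    if (nrow(obs) == 0) next
    obs$key <- paste(obs$sp1, obs$sp2, obs$sp3, sep = "|")
    for (grp in split(obs, list(obs$key, obs$odd), drop = TRUE)) {
      if (nrow(grp) < min_obs) next
      fit <- tryCatch(fit_branch_mixture(grp$t, delta_bic = delta_bic, ...),
                      error = function(e) NULL)
      if (is.null(fit)) next
      tout <- true_out[match(grp$key[1], trip_key)]
      run_rows[[length(run_rows) + 1L]] <- data.frame(
        run = run, triplet = grp$key[1], odd = grp$odd[1],
        discordant = !is.na(tout) && grp$odd[1] != tout,
        n = fit$n, pi = fit$pi, lambda = fit$lambda2, shift = fit$shift,
        delta_bic = fit$delta_bic, decision = fit$decision,
        ratio = fit$ratio, stringsAsFactors = FALSE)
    }
  }
  fits <- if (length(run_rows) == 0) {
    data.frame(run = integer(), triplet = character(), odd = character(),
               discordant = logical(), n = integer(), pi = numeric(),
               lambda = numeric(), shift = numeric(), delta_bic = numeric(),
               decision = character(), ratio = numeric())
  } else do.call(rbind, run_rows)
  ## pair attribution: discordant topology (Others,(A,C)) unites the pair
  ## {odd-under-species-tree, C}: the two species grouped against the truth
  disc <- fits[fits$discordant, , drop = FALSE]
  pairs <- NULL
  if (nrow(disc) > 0) {
    sp_mat <- do.call(rbind, strsplit(disc$triplet, "|", fixed = TRUE))
    tout <- true_out[match(disc$triplet, trip_key)]
    pair <- character(nrow(disc))
    for (i in seq_len(nrow(disc))) {
      united <- setdiff(sp_mat[i, ], disc$odd[i])  # the two grouped species
      ## of those, the signal pair is (true outgroup, its new partner)
      pair[i] <- paste(sort(united), collapse = "~")
    }
    disc$pair <- pair
    nonils <- ifelse(disc$decision == "mixture", disc$pi, 0)
    agg <- split(seq_len(nrow(disc)), disc$pair)
    pairs <- do.call(rbind, lapply(names(agg), function(p) {
      i <- agg[[p]]
      ratios <- disc$ratio[i][disc$decision[i] == "mixture" &
                                is.finite(disc$ratio[i])]
      data.frame(pair = p,
                 n_fits = length(i),
                 avg_nonils_rate = mean(nonils[i]),
                 mixture_call_frac = mean(disc$decision[i] == "mixture"),
                 avg_ratio = if (length(ratios)) mean(ratios) else NA_real_,
                 stringsAsFactors = FALSE)
    }))
    pairs$flagged <- pairs$avg_nonils_rate > rate_threshold
  } else {
    pairs <- data.frame(pair = character(), n_fits = integer(),
                        avg_nonils_rate = numeric(),
                        mixture_call_frac = numeric(),
                        avg_ratio = numeric(), flagged = logical())
  }
  structure(list(fits = fits, pairs = pairs,
                 params = list(n_runs = n_runs, trees_per_run = trees_per_run,
                               seed = seed, min_obs = min_obs,
                               delta_bic = delta_bic,
                               rate_threshold = rate_threshold)),
            class = "triplet_protocol")
}

#' @export
print.triplet_protocol <- function(x, ...) {
  cat(sprintf("triplet protocol: %d fits over %d run(s)\n",
              nrow(x$fits), x$params$n_runs))
  if (nrow(x$pairs) > 0) {
    cat("species-pair aggregation (discordant topologies):\n")
    print(x$pairs, row.names = FALSE)
  } else cat("no discordant triplet-topology fits\n")
  invisible(x)
}
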