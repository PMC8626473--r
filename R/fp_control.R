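## Simulation-based false-positive control: gene trees are simulated under
## the species tree with ILS as the only source of conflict, the discordance
## analyses are re-run, and hybridization flags among focal pairs are counted
## across replicates.

#' Run the coalescent false-positive control
#'
#' Per replicate, simulates `n_trees` gene trees under the (reticulation-
#' free) species tree, runs the topology census and the triplet-mixture
#' protocol, and records any species pairs flagged as hybridization.  The
#' control passes when at least `pass_fraction` of replicates are flag-free.
#'
#' @param species_tree `species_network` (or `phylo`) without reticulations.
#' @param scheme optional [group_scheme()]; when supplied the census is run
#'   per replicate.
#' @param defs [type_definition()] for the census.
#' @param n_trees gene trees per replicate (default 2329).
#' @param n_replicates number of replicates (default 10).
#' @param seed master seed; per-replicate sub-seeds are derived from it.
#' @param triplets focal species triplets for the protocol.
#' @param n_runs,trees_per_run triplet-protocol resampling design per
#'   replicate.
#' @param rate_threshold hybridization flag threshold (default 0.1).
#' @param pass_fraction fraction of flag-free replicates required (default
#'   0.9).
#' @param ... further arguments to [run_triplet_protocol()].
#' @return object of class `fp_report`: per-replicate census tables, pair
#'   tables and flags, plus `frac_flag_free` and `pass`.
#' @export
run_fp_control <- function(species_tree, scheme = NULL,
                           defs = type_definition(),
                           n_trees = 2329, n_replicates = 10, seed = 1L,
                           triplets = NULL, n_runs = 10,
                           trees_per_run = min(500, n_trees),
                           rate_threshold = 0.1, pass_fraction = 0.9, ...) {
  if (inherits(species_tree, "phylo"))
    species_tree <- as_species_network(species_tree)
  if (any(species_tree$reticulate))
    stop("the false-positive control requires a species tree without ",
         "reticulations")
  if (n_replicates < 1) stop("n_replicates must be >= 1")
  set.seed(seed)
  sub_seeds <- sample.int(.Machine$integer.max - 1L, 2L * n_replicates)
  reps <- vector("list", n_replicates)
  for (r in seq_len(n_replicates)) {
    cfg <- sim_config(seed = sub_seeds[2L * r - 1L], n_trees = n_trees)
    trees <- simulate_msc_gene_trees(species_tree, cfg)
    cens <- NULL
    if (!is.null(scheme))
      cens <- suppressWarnings(census(trees, scheme, defs))
    prot <- run_triplet_protocol(trees, species_tree, triplets = triplets,
                                 n_runs = n_runs,
                                 trees_per_run = trees_per_run,
                                 seed = sub_seeds[2L * r],
                                 rate_threshold = rate_threshold, ...)
    flagged <- prot$pairs$pair[prot$pairs$flagged]
    reps[[r]] <- list(census = cens, pairs = prot$pairs, flagged = flagged)
  }
  flag_free <- vapply(reps, function(x) length(x$flagged) == 0, logical(1))
  structure(list(replicates = reps,
                 n_trees = n_trees, n_replicates = n_replicates,
                 frac_flag_free = mean(flag_free),
                 pass = mean(flag_free) >= pass_fraction),
            class = "fp_report")
}

#' @export
print.fp_report <- function(x, ...) {
  cat(sprintf("false-positive control: %d replicate(s) x %d trees\n",
              x$n_replicates, x$n_trees))
  cat(sprintf("flag-free replicates: %.0f%%  ->  %s\n",
              100 * x$frac_flag_free, if (x$pass) "PASS" else "FAIL"))
  for (r in seq_along(x$replicates)) {
    fl <- x$replicates[[r]]$flagged
    if (length(fl) > 0)
      cat(sprintf("  replicate %d flagged: %s\n", r,
                  paste(fl, collapse = ", ")))
  }
  invisible(x)
}
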