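## Rooted gene trees: an ape "phylo" plus a tip -> species map, an identifier,
## and optional genomic location used by the chromosome homogeneity test.

#' Construct a gene tree
#'
#' A `gene_tree` is an ape `phylo` carrying a tip-to-species assignment,
#' per-internal-edge supports on the 0-100 scale (stored as node labels), an
#' identifier, and optionally the chromosome/position of the gene.
#'
#' @param phy rooted `phylo` object.
#' @param species named character vector mapping every tip label to a species
#'   name. Defaults to the tip labels themselves.
#' @param tree_id opaque identifier.
#' @param gene_location optional list/vector with elements `chromosome` and
#'   `position`.
#' @return an object of class `gene_tree` (also `phylo`).
#' @export
gene_tree <- function(phy, species = NULL, tree_id = NULL,
                      gene_location = NULL) {
  if (!inherits(phy, "phylo")) stop("phy must be a 'phylo' object")
  if (!ape::is.rooted(phy)) stop("gene trees must be rooted")
  if (is.null(phy$edge.length)) {
    warning("tree has no branch lengths; treating all as 0")
    phy$edge.length <- rep(0, nrow(phy$edge))
  }
  if (anyNA(phy$edge.length)) {
    warning("missing branch lengths treated as 0")
    phy$edge.length[is.na(phy$edge.length)] <- 0
  }
  if (any(phy$edge.length < 0)) stop("branch lengths must be >= 0")
  if (is.null(species)) species <- stats::setNames(phy$tip.label, phy$tip.label)
  missing <- setdiff(phy$tip.label, names(species))
  if (length(missing) > 0)
    stop("no species assignment for tip(s): ", paste(missing, collapse = ", "))
  sup <- tree_support(phy)
  if (any(!is.na(sup) & (sup < 0 | sup > 100)))
    stop("support values must lie in [0, 100]")
  phy$species <- unname(species[phy$tip.label])
  names(phy$species) <- phy$tip.label
  phy$tree_id <- tree_id
  phy$gene_location <- gene_location
  class(phy) <- unique(c("gene_tree", class(phy)))
  phy
}

#' Per-internal-node support values
#'
#' Parses numeric node labels into supports; non-numeric or absent labels give
#' `NA`. Index `i` corresponds to internal node `ntip + i`.
#'
#' @param tree a `phylo` or `gene_tree`.
#' @return numeric vector of length `tree$Nnode`.
#' @export
tree_support <- function(tree) {
  if (is.null(tree$node.label)) return(rep(NA_real_, tree$Nnode))
  suppressWarnings(as.numeric(tree$node.label))
}

#' Species of each tip
#' @param tree a `gene_tree`.
#' @return named character vector, tip label -> species.
#' @export
tip_species <- function(tree) {
  if (!is.null(tree$species)) return(tree$species)
  stats::setNames(tree$tip.label, tree$tip.label)
}

#' Read a single newick string into a gene tree
#'
#' Internal node labels that parse as numbers are interpreted as bootstrap
#' supports (the IQ-TREE dialect); `dialect = "branch_comment"` instead reads
#' supports from `[..]` comments following the label.
#'
#' @param text newick string.
#' @param species_map optional named vector (tip label -> species) or a
#'   data frame as returned by [read_species_map()].
#' @param dialect where supports live: `"node_label"` (default) or
#'   `"branch_comment"`.
#' @param tree_id optional identifier.
#' @param require_species error when a tip is missing from `species_map`
#'   (default when a map is supplied).
#' @return a [gene_tree()].
#' @export
read_newick <- function(text, species_map = NULL,
                        dialect = c("node_label", "branch_comment"),
                        tree_id = NULL, require_species = !is.null(species_map)) {
  dialect <- match.arg(dialect)
  p <- .nwk_parse(text, labels_as_support = dialect == "node_label")
  phy <- .parse_to_phylo(p)
  if (is.null(phy$edge.length) || all(is.na(phy$edge.length))) {
    phy$edge.length <- NULL
  }
  species <- NULL
  gene_location <- NULL
  if (!is.null(species_map)) {
    if (is.data.frame(species_map)) {
      species <- stats::setNames(species_map$species, species_map$gene_id)
      if (all(c("chromosome", "position") %in% names(species_map))) {
        i <- match(phy$tip.label, species_map$gene_id)
        gene_location <- list(chromosome = species_map$chromosome[i],
                              position = species_map$position[i])
      }
    } else species <- species_map
    if (require_species) {
      missing <- setdiff(phy$tip.label, names(species))
      if (length(missing) > 0)
        stop("species mapping missing for tip(s): ",
             paste(missing, collapse = ", "))
    }
    species <- species[intersect(phy$tip.label, names(species))]
    absent <- setdiff(phy$tip.label, names(species))
    species <- c(species, stats::setNames(absent, absent))
  }
  suppressWarnings(gene_tree(phy, species = species, tree_id = tree_id,
                             gene_location = gene_location))
}

#' Read a file of newick trees (one per line)
#'
#' @param file path to a newick file, one tree per line.
#' @param species_map optional map passed to [read_newick()].
#' @param ... further arguments to [read_newick()].
#' @return list of `gene_tree` objects.
#' @export
read_gene_trees <- function(file, species_map = NULL, ...) {
  lines <- readLines(file)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  lapply(seq_along(lines), function(i)
    read_newick(lines[i], species_map = species_map, tree_id = i, ...))
}

#' Write a list of trees to a newick file, one per line
#' @param trees list of `phylo`/`gene_tree` objects.
#' @param file output path.
#' @export
write_gene_trees <- function(trees, file) {
  writeLines(vapply(trees, write_newick, character(1)), file)
  invisible(file)
}

#' Read a species map TSV
#'
#' Expected columns: `gene_id`, `species`, and optionally `chromosome`,
#' `position`.
#'
#' @param file path to a tab-separated file with a header line.
#' @return data frame.
#' @export
read_species_map <- function(file) {
  df <- utils::read.delim(file, stringsAsFactors = FALSE)
  need <- c("gene_id", "species")
  if (!all(need %in% names(df)))
    stop("species map must have columns: ", paste(need, collapse = ", "))
  df
}

## tip-index sets below every node (tips: singleton; internals accumulated
## in postorder); used by monophyly queries and the topology census.
.clade_tip_sets <- function(phy) {
  ntip <- length(phy$tip.label)
  nn <- ntip + phy$Nnode
  sets <- vector("list", nn)
  for (i in seq_len(ntip)) sets[[i]] <- i
  eo <- ape::reorder.phylo(phy, "postorder")$edge
  for (k in seq_len(nrow(eo))) {
    p <- eo[k, 1]; ch <- eo[k, 2]
    sets[[p]] <- c(sets[[p]], sets[[ch]])
  }
  sets
}

#' Species-level monophyly query
#'
#' TRUE iff some clade of the rooted tree contains exactly the tips belonging
#' to `species_set` (all copies of those species, and nothing else).
#'
#' @param tree a `gene_tree` (or `phylo`; tip labels then double as species).
#' @param species_set character vector of species names.
#' @return logical.
#' @export
is_monophyletic <- function(tree, species_set) {
  if (length(species_set) == 0) stop("species_set must be non-empty")
  sp <- tip_species(tree)
  missing <- setdiff(species_set, sp)
  if (length(missing) > 0)
    stop("species absent from tree: ", paste(missing, collapse = ", "))
  target <- sort(which(sp %in% species_set))
  ntip <- length(tree$tip.label)
  sets <- .clade_tip_sets(tree)
  for (i in (ntip + 1):(ntip + tree$Nnode)) {
    if (length(sets[[i]]) == length(target) &&
        all(sort(sets[[i]]) == target)) return(TRUE)
  }
  length(target) == 1L  # single tip is trivially a clade
}

#' Root a gene tree on its outgroup
#'
#' Roots on the edge separating all outgroup tips from the ingroup when the
#' outgroup is a split of the unrooted tree; otherwise roots on the edge with
#' the best outgroup/ingroup separation and flags the result with attribute
#' `outgroup_non_monophyletic = TRUE`.
#'
#' @param tree a `gene_tree`.
#' @param scheme a [group_scheme()] designating the outgroup.
#' @return rooted `gene_tree`; idempotent on correctly rooted input.
#' @export
root_by_outgroup <- function(tree, scheme) {
  sp <- tip_species(tree)
  out_tips <- which(scheme$groups[sp] %in% scheme$outgroup)
  if (length(out_tips) == 0) stop("tree has no outgroup tips")
  if (length(out_tips) == length(tree$tip.label))
    stop("all tips belong to the outgroup")
  ntip <- length(tree$tip.label)
  ## already rooted with the outgroup as one child of the root: return as-is
  if (ape::is.rooted(tree)) {
    root_children <- tree$edge[tree$edge[, 1] == ntip + 1L, 2]
    sets <- .clade_tip_sets(tree)
    for (ch in root_children) {
      below <- if (ch <= ntip) ch else sets[[ch]]
      if (setequal(below, out_tips)) return(tree)
    }
  }
  meta <- list(species = tree$species, tree_id = tree$tree_id,
               gene_location = tree$gene_location)
  phy <- ape::unroot(ape::as.phylo(tree))
  labels <- phy$tip.label
  out_lab <- labels[out_tips]
  mono <- ape::is.monophyletic(phy, out_lab)
  if (mono) {
    rooted <- ape::root(phy, outgroup = out_lab, resolve.root = TRUE)
  } else {
    ## pick the split with fewest misplaced tips
    sets <- .clade_tip_sets(phy)
    ntu <- length(phy$tip.label)
    best <- NULL; best_miss <- Inf
    n_out <- length(out_tips)
    for (i in (ntu + 2):(ntu + phy$Nnode)) {   # skip the (unrooted) root
      side <- sets[[i]]
      o_in <- length(intersect(out_tips, side))
      m1 <- (n_out - o_in) + (length(side) - o_in)        # side = outgroup
      m2 <- o_in + (ntu - length(side)) - (n_out - o_in)  # complement = outgroup
      if (m1 < best_miss) { best_miss <- m1; best <- labels[side] }
      if (m2 < best_miss) { best_miss <- m2; best <- labels[setdiff(seq_len(ntu), side)] }
    }
    rooted <- ape::root(phy, outgroup = best, resolve.root = TRUE)
  }
  res <- gene_tree(rooted,
                   species = meta$species[rooted$tip.label],
                   tree_id = meta$tree_id,
                   gene_location = meta$gene_location)
  if (!mono) attr(res, "outgroup_non_monophyletic") <- TRUE
  res
}

#' Species grouping scheme
#'
#' Maps species to clade labels (e.g. monocots, eudicots, a combined
#' Chloranthales+magnoliids group) and designates the outgroup label.
#'
#' @param groups named character vector, species -> group label.
#' @param outgroup group label(s) acting as outgroup.
#' @return object of class `group_scheme`.
#' @export
group_scheme <- function(groups, outgroup) {
  if (is.null(names(groups))) stop("groups must be a named vector")
  if (length(outgroup) == 0 || !any(groups %in% outgroup))
    stop("outgroup must be a non-empty group present in the scheme")
  structure(list(groups = groups, outgroup = outgroup),
            class = "group_scheme")
}
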