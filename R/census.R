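## Topology-type census: classify each rooted gene tree by the arrangement of
## three focal clades, apply the bootstrap filter, and summarize proportions,
## per-type monophyly fractions, and the chromosome homogeneity test.

#' Topology type definitions for a three-way conflict
#'
#' Type I: group 1 is sister to groups 2+3 (diagnostic clade = all focal tips
#' of groups 2 and 3, none of group 1).  Type II: groups 1+3 against group 2.
#' Type III: groups 1+2 against group 3.  Matching ignores species outside
#' the three focal groups (pruned view).
#'
#' @param group1,group2,group3 group labels as used in the [group_scheme()];
#'   by default the combined Chloranthales+magnoliids clade, monocots and
#'   eudicots.
#' @return object of class `type_definition`.
#' @export
type_definition <- function(group1 = "chloranthales_magnoliids",
                            group2 = "monocots", group3 = "eudicots") {
  structure(list(group1 = group1, group2 = group2, group3 = group3),
            class = "type_definition")
}

#' Classify one gene tree into a topology type
#'
#' Returns `"I"`, `"II"`, `"III"` when the corresponding diagnostic clade is
#' present with subtending-branch support at least `support_threshold`
#' (computed on focal tips only), otherwise `"other"`.  On a binary tree the
#' three diagnostic clades are mutually exclusive.
#'
#' @param tree rooted `gene_tree`.
#' @param scheme a [group_scheme()].
#' @param defs a [type_definition()].
#' @param support_threshold bootstrap filter on the diagnostic clade's
#'   subtending branch (default 70); missing supports pass.
#' @return character label.
#' @export
classify_tree <- function(tree, scheme, defs, support_threshold = 70) {
  sp <- tip_species(tree)
  grp <- unname(scheme$groups[sp])
  focal <- list(defs$group1, defs$group2, defs$group3)
  for (g in focal) {
    if (!any(grp %in% g))
      stop("focal group absent from tree: ", g)
  }
  ntip <- length(tree$tip.label)
  focal_tips <- which(grp %in% unlist(focal))
  g1 <- which(grp %in% defs$group1)
  g2 <- which(grp %in% defs$group2)
  g3 <- which(grp %in% defs$group3)
  targets <- list(I = sort(c(g2, g3)), II = sort(c(g1, g3)),
                  III = sort(c(g1, g2)))
  sets <- .clade_tip_sets(tree)
  sup <- tree_support(tree)
  best <- "other"
  for (v in (ntip + 1):(ntip + tree$Nnode)) {
    below <- intersect(sets[[v]], focal_tips)
    for (ty in names(targets)) {
      if (length(below) == length(targets[[ty]]) &&
          all(sort(below) == targets[[ty]])) {
        s <- sup[v - ntip]
        if (is.na(s) || s >= support_threshold) return(ty)
        best <- "other"
      }
    }
  }
  best
}

#' Census of topology types over a set of gene trees
#'
#' Aggregates [classify_tree()] over trees: per type the raw count (no
#' support filter), the count passing the filter, the proportion among
#' filtered typed trees, and the fraction of filtered trees of that type in
#' which `monophyly_set` is monophyletic.  Trees missing a focal group are
#' skipped with a warning.
#'
#' @param trees list of rooted `gene_tree` objects.
#' @param scheme a [group_scheme()].
#' @param defs a [type_definition()].
#' @param support_threshold bootstrap filter (default 70).
#' @param monophyly_set species set for the per-type monophyly fraction;
#'   default all species of `defs$group1`.
#' @return object of class `census_result`: data frame `type`, `count_raw`,
#'   `count_bs_pass`, `proportion`, `monophyly_fraction`, plus totals.
#' @export
census <- function(trees, scheme, defs = type_definition(),
                   support_threshold = 70, monophyly_set = NULL) {
  if (length(trees) == 0) stop("no trees supplied")
  if (is.null(monophyly_set))
    monophyly_set <- names(scheme$groups)[scheme$groups %in% defs$group1]
  types <- c("I", "II", "III")
  raw <- pass <- mono_n <- mono_k <- stats::setNames(integer(3), types)
  skipped <- 0L
  for (tr in trees) {
    lab_raw <- tryCatch(classify_tree(tr, scheme, defs, 0),
                        error = function(e) NA_character_)
    if (is.na(lab_raw)) { skipped <- skipped + 1L; next }
    if (lab_raw %in% types) raw[lab_raw] <- raw[lab_raw] + 1L
    lab <- classify_tree(tr, scheme, defs, support_threshold)
    if (lab %in% types) {
      pass[lab] <- pass[lab] + 1L
      present <- intersect(monophyly_set, tip_species(tr))
      if (length(present) > 1) {
        mono_n[lab] <- mono_n[lab] + 1L
        if (is_monophyletic(tr, present)) mono_k[lab] <- mono_k[lab] + 1L
      }
    }
  }
  if (skipped > 0)
    warning(skipped, " tree(s) skipped (missing focal group)")
  total_typed <- sum(pass)
  out <- data.frame(
    type = types, count_raw = as.integer(raw),
    count_bs_pass = as.integer(pass),
    proportion = if (total_typed > 0) as.numeric(pass / total_typed)
    else rep(NA_real_, 3),
    monophyly_fraction = ifelse(mono_n > 0, mono_k / mono_n, NA_real_))
  structure(list(table = out, n_trees = length(trees),
                 n_typed = total_typed, n_skipped = skipped,
                 support_threshold = support_threshold),
            class = "census_result")
}

#' @export
print.census_result <- function(x, ...) {
  cat(sprintf("topology census: %d trees, %d typed (BS >= %g), %d skipped\n",
              x$n_trees, x$n_typed, x$support_threshold, x$n_skipped))
  print(x$table, row.names = FALSE)
  invisible(x)
}

#' Census arithmetic from printed counts
#'
#' Computes type proportions (and optionally monophyly fractions) from count
#' tables, for working with published summaries rather than raw trees.
#'
#' @param counts named integer vector of per-type tree counts.
#' @param monophyly_counts optional named integer vector (same names) of
#'   trees in which the focal set was monophyletic.
#' @return data frame `type`, `count`, `proportion`, `percent` (rounded to
#'   the nearest integer), and when supplied `monophyly_fraction` /
#'   `monophyly_percent` (one decimal).
#' @export
census_summary <- function(counts, monophyly_counts = NULL) {
  out <- data.frame(type = names(counts), count = as.integer(counts),
                    proportion = as.numeric(counts) / sum(counts))
  out$percent <- round(100 * out$proportion)
  if (!is.null(monophyly_counts)) {
    out$monophyly_fraction <- as.numeric(monophyly_counts[out$type]) /
      out$count
    out$monophyly_percent <- round(100 * out$monophyly_fraction, 1)
  }
  out
}

#' Chi-square homogeneity test of chromosome distributions across types
#'
#' Pearson test of homogeneity on the type x chromosome contingency table;
#' chromosomes unobserved in every type are dropped with a warning.
#'
#' @param genes_by_type named list: type label -> vector of chromosome
#'   labels (one per gene).
#' @return list `statistic`, `df`, `p.value`, `table`.
#' @export
chromosome_homogeneity_test <- function(genes_by_type) {
  if (length(genes_by_type) < 2)
    stop("need at least two types")
  chrs <- sort(unique(unlist(lapply(genes_by_type, function(v)
    if (is.factor(v)) levels(v) else unique(as.character(v))))))
  tab <- t(vapply(genes_by_type, function(v)
    table(factor(as.character(v), levels = chrs)), numeric(length(chrs))))
  zero <- colSums(tab) == 0
  if (any(zero)) {
    warning("dropping chromosome categories with zero total count: ",
            paste(chrs[zero], collapse = ", "))
    tab <- tab[, !zero, drop = FALSE]
  }
  if (ncol(tab) < 2)
    stop("need at least two chromosome categories with observations")
  ht <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  list(statistic = unname(ht$statistic), df = unname(ht$parameter),
       p.value = ht$p.value, table = tab)
}
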