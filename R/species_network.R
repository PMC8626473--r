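## Rooted species trees / networks with branch lengths in coalescent units
## (time / 2N generations).  Reticulate nodes have two parent edges whose
## inheritance probabilities sum to one.

#' Read an extended-newick species network
#'
#' Understands plain newick (giving a network with no reticulations) and the
#' "rich" dialect where a reticulate node appears twice under a shared `#H`
#' tag and each occurrence carries `:length:support:gamma` (support may be
#' omitted: `:length::gamma`).
#'
#' @param text extended-newick string.
#' @return an object of class `species_network` with elements `label`
#'   (node labels, species names at leaves), `edges` (data frame with
#'   `child`, `parent`, `length`, `gamma`), and `root` (node id).
#' @export
read_enewick <- function(text) {
  p <- .nwk_parse(text, labels_as_support = TRUE)
  nn <- length(p$label)
  keep <- rep(TRUE, nn)
  canonical <- seq_len(nn)
  tags <- unique(stats::na.omit(p$hybrid))
  for (tg in tags) {
    occ <- which(p$hybrid == tg)
    if (length(occ) != 2)
      stop("reticulation tag #", tg, " must occur exactly twice", call. = FALSE)
    main <- occ[which.max(lengths(p$children)[occ])]
    other <- setdiff(occ, main)
    canonical[other] <- main
    keep[other] <- FALSE
    if (length(p$children[[other]]) > 0 && length(p$children[[main]]) > 0)
      stop("reticulation tag #", tg, " has children at both occurrences",
           call. = FALSE)
  }
  edges <- do.call(rbind, lapply(which(p$is_internal), function(i) {
    data.frame(parent = i, child = p$children[[i]],
               stringsAsFactors = FALSE)
  }))
  edges$length <- p$length[edges$child]
  edges$gamma <- p$gamma[edges$child]
  edges$child <- canonical[edges$child]
  edges$parent <- canonical[edges$parent]
  ## renumber to the kept nodes
  newid <- cumsum(keep)
  edges$child <- newid[edges$child]
  edges$parent <- newid[edges$parent]
  net <- structure(list(
    label = p$label[keep],
    is_leaf = !p$is_internal[keep] & !(seq_len(nn)[keep] %in%
                                         which(!keep)),
    edges = edges,
    root = newid[p$root]
  ), class = "species_network")
  nnode <- sum(keep)
  indeg <- tabulate(net$edges$child, nnode)
  outdeg <- tabulate(net$edges$parent, nnode)
  net$is_leaf <- outdeg == 0
  net$reticulate <- indeg == 2L
  if (any(indeg > 2)) stop("node with more than two parents", call. = FALSE)
  validate_species_network(net)
  net
}

#' Validate a species network
#'
#' Checks leaf-label uniqueness, non-negative branch lengths, gamma in (0,1)
#' with the two parent-edge gammas at each reticulate node summing to one,
#' and that dropping every minor reticulation edge leaves a tree.
#'
#' @param net a `species_network`.
#' @return `net`, invisibly; errors on violation.
#' @export
validate_species_network <- function(net) {
  leaves <- net$label[net$is_leaf]
  if (anyNA(leaves) || any(!nzchar(leaves)))
    stop("every leaf must be labelled", call. = FALSE)
  if (anyDuplicated(leaves)) stop("leaf labels must be unique", call. = FALSE)
  len <- net$edges$length
  if (any(!is.na(len) & len < 0))
    stop("branch lengths must be >= 0", call. = FALSE)
  for (v in which(net$reticulate)) {
    g <- net$edges$gamma[net$edges$child == v]
    if (anyNA(g))
      stop("reticulate node lacks an inheritance probability", call. = FALSE)
    if (any(g < 0 | g > 1))
      stop("inheritance probabilities must lie in (0,1)", call. = FALSE)
    if (any(g == 0 | g == 1))
      warning("degenerate inheritance probability (0 or 1); ",
              "the reticulation is effectively a tree edge")
    if (abs(sum(g) - 1) > 1e-8)
      stop("inheritance probabilities at a reticulate node must sum to 1",
           call. = FALSE)
  }
  ## major-tree check
  tr <- prune_reticulations(net, validate = FALSE)
  nnode <- length(tr$label)
  indeg <- tabulate(tr$edges$child, nnode)
  if (any(indeg[-tr$root] != 1L) || indeg[tr$root] != 0L)
    stop("removing minor reticulation edges does not yield a tree",
         call. = FALSE)
  invisible(net)
}

#' Drop minor reticulation edges
#'
#' Removes, at every reticulate node, the parent edge with the smaller
#' inheritance probability (ties broken toward the first edge), yielding the
#' "major tree" of the network. Node ids are preserved.
#'
#' @param net a `species_network`.
#' @param validate re-validate the result.
#' @return a `species_network` without reticulations.
#' @export
prune_reticulations <- function(net, validate = TRUE) {
  drop <- integer()
  for (v in which(net$reticulate)) {
    idx <- which(net$edges$child == v)
    g <- net$edges$gamma[idx]
    drop <- c(drop, idx[-which.max(g)])
  }
  if (length(drop) > 0) net$edges <- net$edges[-drop, , drop = FALSE]
  nnode <- length(net$label)
  net$reticulate <- tabulate(net$edges$child, nnode) == 2L
  net$edges$gamma <- NA_real_
  if (validate) validate_species_network(net)
  net
}

#' Convert a rooted phylo to a species network
#' @param phy rooted `phylo` with branch lengths in coalescent units.
#' @return `species_network`.
#' @export
as_species_network <- function(phy) {
  if (!inherits(phy, "phylo")) stop("expected a 'phylo' object")
  if (!ape::is.rooted(phy)) stop("species tree must be rooted")
  ntip <- length(phy$tip.label)
  nnode <- ntip + phy$Nnode
  lab <- c(phy$tip.label, rep(NA_character_, phy$Nnode))
  edges <- data.frame(parent = phy$edge[, 1], child = phy$edge[, 2],
                      length = if (is.null(phy$edge.length))
                        NA_real_ else phy$edge.length,
                      gamma = NA_real_)
  net <- structure(list(label = lab,
                        is_leaf = seq_len(nnode) <= ntip,
                        edges = edges,
                        root = ntip + 1L,
                        reticulate = rep(FALSE, nnode)),
                   class = "species_network")
  validate_species_network(net)
  net
}

#' Major tree of a network as phylo
#' @param net a `species_network`.
#' @return rooted `phylo` over the leaf labels.
#' @export
network_major_tree <- function(net) {
  tr <- prune_reticulations(net, validate = FALSE)
  leaves <- which(tr$is_leaf)
  ints <- which(!tr$is_leaf)
  ntip <- length(leaves)
  map <- integer(length(tr$label))
  map[leaves] <- seq_len(ntip)
  map[c(tr$root, setdiff(ints, tr$root))] <- ntip + seq_len(length(ints))
  edge <- cbind(map[tr$edges$parent], map[tr$edges$child])
  phy <- list(edge = edge, tip.label = tr$label[leaves],
              edge.length = tr$edges$length, Nnode = length(ints))
  class(phy) <- "phylo"
  ## suppress singleton nodes left by pruning (reticulate pass-throughs)
  ape::collapse.singles(phy)
}

## node ages (leaves at 0) via longest-path relaxation in topological order
.network_ages <- function(net) {
  nnode <- length(net$label)
  kids <- split(seq_len(nrow(net$edges)), net$edges$parent)
  age <- rep(0, nnode)
  remaining <- vapply(seq_len(nnode), function(v) {
    ks <- kids[[as.character(v)]]
    if (is.null(ks)) 0L else length(ks)
  }, integer(1))
  done_children <- integer(nnode)
  queue <- which(net$is_leaf)
  parents_of <- split(seq_len(nrow(net$edges)), net$edges$child)
  processed <- rep(FALSE, nnode)
  while (length(queue) > 0) {
    v <- queue[1]; queue <- queue[-1]
    if (processed[v]) next
    processed[v] <- TRUE
    for (e in parents_of[[as.character(v)]]) {
      p <- net$edges$parent[e]
      len <- net$edges$length[e]
      if (is.na(len)) len <- 0
      age[p] <- max(age[p], age[v] + len)
      done_children[p] <- done_children[p] + 1L
      if (done_children[p] >= remaining[p]) queue <- c(queue, p)
    }
  }
  age
}

#' Leaf labels of a species network
#' @param net a `species_network`.
#' @return character vector of species names.
#' @export
network_species <- function(net) net$label[net$is_leaf]

#' @export
print.species_network <- function(x, ...) {
  cat("species_network:", sum(x$is_leaf), "species,",
      sum(x$reticulate), "reticulation(s)\n")
  cat("  species:", paste(network_species(x), collapse = ", "), "\n")
  invisible(x)
}

#' Write a species network in extended newick
#' @param net a `species_network`.
#' @param file optional output path.
#' @param digits significant digits for lengths.
#' @return the string, invisibly when written to file.
#' @export
write_enewick <- function(net, file = NULL, digits = 10) {
  fmt <- function(x) sprintf("%.*g", digits, x)
  kids <- split(seq_len(nrow(net$edges)), net$edges$parent)
  htag <- integer(length(net$label))
  htag[which(net$reticulate)] <- seq_len(sum(net$reticulate))
  seen <- rep(FALSE, length(net$label))
  rec <- function(v, elen, egam) {
    lab <- if (net$is_leaf[v]) net$label[v] else ""
    if (net$reticulate[v]) {
      if (seen[v]) {
        body <- paste0(lab, "#H", htag[v])
      } else {
        seen[v] <<- TRUE
        ks <- kids[[as.character(v)]]
        inner <- paste(vapply(ks, function(e)
          rec(net$edges$child[e], net$edges$length[e], net$edges$gamma[e]),
          character(1)), collapse = ",")
        body <- paste0("(", inner, ")", lab, "#H", htag[v])
      }
    } else if (net$is_leaf[v]) {
      body <- lab
    } else {
      ks <- kids[[as.character(v)]]
      inner <- paste(vapply(ks, function(e)
        rec(net$edges$child[e], net$edges$length[e], net$edges$gamma[e]),
        character(1)), collapse = ",")
      body <- paste0("(", inner, ")")
    }
    if (!is.na(elen)) {
      body <- paste0(body, ":", fmt(elen))
      if (!is.na(egam)) body <- paste0(body, "::", fmt(egam))
    } else if (!is.na(egam)) {
      body <- paste0(body, ":0::", fmt(egam))
    }
    body
  }
  s <- paste0(rec(net$root, NA_real_, NA_real_), ";")
  if (is.null(file)) return(s)
  writeLines(s, file)
  invisible(s)
}
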