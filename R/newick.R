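## Recursive-descent newick / extended-newick ("rich" newick) parser.
##
## ape's reader neither reports character offsets on failure nor understands
## the ":len:support:gamma" inheritance-probability annotation used for
## reticulation edges, so parsing is done here; everything downstream is an
## ordinary ape "phylo" (trees) or a "species_network" (networks).

.nwk_state <- function(text) {
  chars <- strsplit(text, "", fixed = TRUE)[[1]]
  env <- new.env(parent = emptyenv())
  env$chars <- chars
  env$n <- length(chars)
  env$pos <- 1L
  ## flat node store
  env$label <- character()
  env$hybrid <- character()    # "#H1" tag sans '#', NA when not reticulate
  env$length <- numeric()
  env$support <- numeric()
  env$gamma <- numeric()
  env$children <- list()
  env
}

.nwk_error <- function(st, msg) {
  stop(sprintf("newick parse error at character %d: %s", st$pos, msg),
       call. = FALSE)
}

.nwk_peek <- function(st) {
  if (st$pos > st$n) return(NA_character_)
  st$chars[st$pos]
}

.nwk_skip_ws <- function(st) {
  while (st$pos <= st$n && st$chars[st$pos] %in% c(" ", "\t", "\n", "\r"))
    st$pos <- st$pos + 1L
}

.nwk_new_node <- function(st) {
  i <- length(st$label) + 1L
  st$label[i] <- NA_character_
  st$hybrid[i] <- NA_character_
  st$length[i] <- NA_real_
  st$support[i] <- NA_real_
  st$gamma[i] <- NA_real_
  st$children[[i]] <- integer()
  i
}

.nwk_read_name <- function(st) {
  stopchars <- c("(", ")", ",", ":", ";", "[")
  out <- character()
  if (identical(.nwk_peek(st), "'")) {        # quoted label
    st$pos <- st$pos + 1L
    while (TRUE) {
      ch <- .nwk_peek(st)
      if (is.na(ch)) .nwk_error(st, "unterminated quoted label")
      st$pos <- st$pos + 1L
      if (ch == "'") break
      out <- c(out, ch)
    }
  } else {
    while (TRUE) {
      ch <- .nwk_peek(st)
      if (is.na(ch) || ch %in% stopchars) break
      out <- c(out, ch)
      st$pos <- st$pos + 1L
    }
  }
  paste(out, collapse = "")
}

.nwk_read_number <- function(st, what) {
  start <- st$pos
  while (TRUE) {
    ch <- .nwk_peek(st)
    if (is.na(ch) || !grepl("[0-9eE\\.\\+\\-]", ch)) break
    st$pos <- st$pos + 1L
  }
  if (st$pos == start) .nwk_error(st, paste("expected numeric", what))
  val <- suppressWarnings(
    as.numeric(paste(st$chars[start:(st$pos - 1L)], collapse = "")))
  if (is.na(val)) .nwk_error(st, paste("malformed numeric", what))
  val
}

## label [#Htag] [:length[:support[:gamma]]]
.nwk_read_annotation <- function(st, node) {
  .nwk_skip_ws(st)
  name <- .nwk_read_name(st)
  if (nzchar(name)) {
    if (grepl("#", name, fixed = TRUE)) {
      parts <- strsplit(name, "#", fixed = TRUE)[[1]]
      if (nzchar(parts[1])) st$label[node] <- parts[1]
      st$hybrid[node] <- parts[2]
    } else {
      st$label[node] <- name
    }
  }
  ## bracket comment directly after the label: "[95]" branch-comment dialect
  if (identical(.nwk_peek(st), "[")) {
    st$pos <- st$pos + 1L
    com <- character()
    while (!identical(.nwk_peek(st), "]")) {
      if (is.na(.nwk_peek(st))) .nwk_error(st, "unterminated comment")
      com <- c(com, st$chars[st$pos])
      st$pos <- st$pos + 1L
    }
    st$pos <- st$pos + 1L
    comv <- suppressWarnings(as.numeric(gsub("[^0-9eE\\.\\+\\-]", "",
                                             paste(com, collapse = ""))))
    if (!is.na(comv)) st$support[node] <- comv
  }
  if (identical(.nwk_peek(st), ":")) {
    st$pos <- st$pos + 1L
    st$length[node] <- .nwk_read_number(st, "branch length")
    if (identical(.nwk_peek(st), ":")) {     # :len:support
      st$pos <- st$pos + 1L
      if (identical(.nwk_peek(st), ":")) {   # :len::gamma (support omitted)
        st$pos <- st$pos + 1L
        st$gamma[node] <- .nwk_read_number(st, "inheritance probability")
      } else {
        st$support[node] <- .nwk_read_number(st, "support")
        if (identical(.nwk_peek(st), ":")) { # :len:support:gamma
          st$pos <- st$pos + 1L
          st$gamma[node] <- .nwk_read_number(st, "inheritance probability")
        }
      }
    }
  }
  node
}

.nwk_read_subtree <- function(st) {
  .nwk_skip_ws(st)
  node <- .nwk_new_node(st)
  if (identical(.nwk_peek(st), "(")) {
    st$pos <- st$pos + 1L
    repeat {
      child <- .nwk_read_subtree(st)
      st$children[[node]] <- c(st$children[[node]], child)
      .nwk_skip_ws(st)
      ch <- .nwk_peek(st)
      if (identical(ch, ",")) {
        st$pos <- st$pos + 1L
      } else if (identical(ch, ")")) {
        st$pos <- st$pos + 1L
        break
      } else {
        .nwk_error(st, "expected ',' or ')'")
      }
    }
  }
  .nwk_read_annotation(st, node)
}

## Parse one newick string into a flat node table.  Internal-node labels that
## look numeric are interpreted as supports when `labels_as_support` is TRUE.
.nwk_parse <- function(text, labels_as_support = TRUE) {
  st <- .nwk_state(text)
  root <- .nwk_read_subtree(st)
  .nwk_skip_ws(st)
  if (!identical(.nwk_peek(st), ";"))
    .nwk_error(st, "expected ';'")
  st$pos <- st$pos + 1L
  .nwk_skip_ws(st)
  if (st$pos <= st$n) .nwk_error(st, "trailing characters after ';'")
  is_internal <- lengths(st$children) > 0L
  if (labels_as_support) {
    for (i in which(is_internal & !is.na(st$label))) {
      v <- suppressWarnings(as.numeric(st$label[i]))
      if (!is.na(v) && is.na(st$support[i])) {
        st$support[i] <- v
        st$label[i] <- NA_character_
      }
    }
  }
  list(root = root, label = st$label, hybrid = st$hybrid,
       length = st$length, support = st$support, gamma = st$gamma,
       children = st$children, is_internal = is_internal)
}

## Flat parse -> ape "phylo".  Fails if reticulations are present.
.parse_to_phylo <- function(p) {
  if (any(!is.na(p$hybrid)))
    stop("tree contains reticulation ('#H') labels; use read_enewick()",
         call. = FALSE)
  tips <- which(!p$is_internal)
  ints <- which(p$is_internal)
  ntip <- length(tips)
  if (ntip < 2L) stop("newick parse error: fewer than 2 tips", call. = FALSE)
  ## phylo numbering: tips 1..ntip in parse order, root = ntip+1, then the
  ## remaining internals in parse (preorder) order
  map <- integer(length(p$label))
  map[tips] <- seq_len(ntip)
  ord <- c(p$root, setdiff(ints, p$root))
  map[ord] <- ntip + seq_along(ord)
  nedge <- length(p$label) - 1L
  edge <- matrix(0L, nedge, 2L)
  elen <- numeric(nedge)
  k <- 0L
  for (i in ints) {
    for (ch in p$children[[i]]) {
      k <- k + 1L
      edge[k, ] <- c(map[i], map[ch])
      elen[k] <- p$length[ch]
    }
  }
  nlab <- character(length(ints))
  nlab[map[ints] - ntip] <- ifelse(is.na(p$support[ints]),
                                   ifelse(is.na(p$label[ints]), "",
                                          p$label[ints]),
                                   as.character(p$support[ints]))
  phy <- list(edge = edge, tip.label = p$label[tips],
              edge.length = elen, Nnode = length(ints),
              node.label = nlab)
  class(phy) <- "phylo"
  attr(phy, "order") <- NULL
  phy
}

#' Write a tree as a newick string
#'
#' Internal-edge supports (stored as node labels) are written as internal node
#' labels, the dialect produced by common maximum-likelihood tree software.
#'
#' @param tree a `phylo` or `gene_tree` object.
#' @param file optional path; when `NULL` the string is returned.
#' @param digits significant digits for branch lengths.
#' @return the newick string, invisibly when written to a file.
#' @export
write_newick <- function(tree, file = NULL, digits = 10) {
  phy <- tree
  ntip <- length(phy$tip.label)
  has_len <- !is.null(phy$edge.length)
  kids <- split(seq_len(nrow(phy$edge)), phy$edge[, 1])
  fmt <- function(x) sprintf("%.*g", digits, x)
  lab <- function(node) {
    if (node <= ntip) return(phy$tip.label[node])
    if (!is.null(phy$node.label)) {
      l <- phy$node.label[node - ntip]
      if (!is.na(l) && nzchar(l)) return(l)
    }
    ""
  }
  rec <- function(node, elen) {
    inner <- ""
    ks <- kids[[as.character(node)]]
    if (!is.null(ks)) {
      parts <- vapply(ks, function(e)
        rec(phy$edge[e, 2], if (has_len) phy$edge.length[e] else NA_real_),
        character(1))
      inner <- paste0("(", paste(parts, collapse = ","), ")")
    }
    out <- paste0(inner, lab(node))
    if (!is.na(elen)) out <- paste0(out, ":", fmt(elen))
    out
  }
  s <- paste0(rec(ntip + 1L, NA_real_), ";")
  if (is.null(file)) return(s)
  writeLines(s, file)
  invisible(s)
}
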