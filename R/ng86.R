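## Nei-Gojobori (1986) counting estimator of synonymous divergence, used to
## obtain pairwise Ks values from codon alignments.  Synonymous site counts
## are averaged over both sequences; synonymous differences average equally
## over the substitution pathways of multi-difference codons (pathways
## passing through stop codons are excluded).

.ng_bases <- c("T", "C", "A", "G")

.ng_codon_table <- local({
  aas <- strsplit(paste0(
    "FFLLSSSSYY**CC*W",   # TTT..TGG
    "LLLLPPPPHHQQRRRR",
    "IIIMTTTTNNKKSSRR",
    "VVVVAAAADDEEGGGG"), "")[[1]]
  codons <- character(64)
  k <- 0
  for (b1 in .ng_bases) for (b2 in .ng_bases) for (b3 in .ng_bases) {
    k <- k + 1
    codons[k] <- paste0(b1, b2, b3)
  }
  stats::setNames(aas, codons)
})

.ng_is_stop <- function(codon) .ng_codon_table[codon] == "*"

## synonymous site count of one codon: per position, the fraction of the 3
## alternative bases that are synonymous (changes to stops count as
## nonsynonymous)
.ng_syn_sites <- function(codon) {
  aa <- .ng_codon_table[codon]
  s <- 0
  cc <- strsplit(codon, "")[[1]]
  for (pos in 1:3) for (b in setdiff(.ng_bases, cc[pos])) {
    alt <- cc
    alt[pos] <- b
    altc <- paste(alt, collapse = "")
    if (!.ng_is_stop(altc) && .ng_codon_table[altc] == aa) s <- s + 1 / 3
  }
  s
}

.ng_site_cache <- local({
  codons <- names(.ng_codon_table)
  sense <- codons[.ng_codon_table != "*"]
  stats::setNames(vapply(sense, .ng_syn_sites, numeric(1)), sense)
})

## average (syn, nonsyn) difference counts over all substitution pathways
## between two codons; pathways through stop codons are dropped (all-blocked
## pairs fall back to counting stop steps as nonsynonymous)
.ng_pair_diffs <- function(c1, c2, allow_stops = FALSE) {
  pos <- which(strsplit(c1, "")[[1]] != strsplit(c2, "")[[1]])
  d <- length(pos)
  if (d == 0) return(c(sd = 0, nd = 0))
  perms <- .ng_perms(pos)
  tot_s <- 0; tot_n <- 0; npaths <- 0
  for (r in seq_len(nrow(perms))) {
    cur <- strsplit(c1, "")[[1]]
    tgt <- strsplit(c2, "")[[1]]
    s <- 0; n <- 0; ok <- TRUE
    for (p in perms[r, ]) {
      prev <- paste(cur, collapse = "")
      cur[p] <- tgt[p]
      nxt <- paste(cur, collapse = "")
      if (!allow_stops && .ng_is_stop(nxt) && nxt != c2) { ok <- FALSE; break }
      if (.ng_is_stop(prev) || .ng_is_stop(nxt)) { n <- n + 1 }
      else if (.ng_codon_table[prev] == .ng_codon_table[nxt]) s <- s + 1
      else n <- n + 1
    }
    if (ok) { tot_s <- tot_s + s; tot_n <- tot_n + n; npaths <- npaths + 1 }
  }
  if (npaths == 0) return(.ng_pair_diffs(c1, c2, allow_stops = TRUE))
  c(sd = tot_s / npaths, nd = tot_n / npaths)
}

.ng_perms <- function(x) {
  if (length(x) == 1) return(matrix(x, 1))
  out <- NULL
  for (i in seq_along(x))
    out <- rbind(out, cbind(x[i], .ng_perms(x[-i])))
  out
}

#' Pairwise Ks by Nei-Gojobori counting
#'
#' Counts synonymous sites per codon (averaged over both sequences) and
#' synonymous differences with equal-weight pathway averaging, then applies
#' the Jukes-Cantor correction `Ks = -3/4 log(1 - 4/3 pS)`.
#'
#' @param seq1,seq2 equal-length gapless coding sequences (characters),
#'   length divisible by 3, no internal stop codons.
#' @return list with `S`, `N`, `Sd`, `Nd`, `pS`, `pN`, `Ks`, `Ka`.
#' @export
ng86_ks <- function(seq1, seq2) {
  s1 <- toupper(gsub("U", "T", seq1))
  s2 <- toupper(gsub("U", "T", seq2))
  if (nchar(s1) != nchar(s2)) stop("sequences must have equal length")
  if (nchar(s1) %% 3 != 0) stop("sequence length must be divisible by 3")
  n_cod <- nchar(s1) / 3
  c1 <- substring(s1, 3 * seq_len(n_cod) - 2, 3 * seq_len(n_cod))
  c2 <- substring(s2, 3 * seq_len(n_cod) - 2, 3 * seq_len(n_cod))
  if (any(.ng_is_stop(c1)) || any(.ng_is_stop(c2)))
    stop("internal stop codon in input")
  S <- (sum(.ng_site_cache[c1]) + sum(.ng_site_cache[c2])) / 2
  N <- 3 * n_cod - S
  diffs <- vapply(seq_len(n_cod), function(i)
    .ng_pair_diffs(c1[i], c2[i]), numeric(2))
  Sd <- sum(diffs["sd", ])
  Nd <- sum(diffs["nd", ])
  pS <- if (S > 0) Sd / S else 0
  pN <- if (N > 0) Nd / N else 0
  if (pS >= 0.75)
    stop("synonymous sites saturated (pS = ", signif(pS, 4),
         " >= 0.75); Ks undefined")
  Ks <- -3 / 4 * log(1 - 4 / 3 * pS)
  Ka <- if (pN < 0.75) -3 / 4 * log(1 - 4 / 3 * pN) else NA_real_
  list(S = S, N = N, Sd = Sd, Nd = Nd, pS = pS, pN = pN, Ks = Ks, Ka = Ka)
}
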