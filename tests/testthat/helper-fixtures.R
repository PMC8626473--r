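# shared fixtures and independent oracles

# caterpillar tree (((...(t1,t2),t3)...,tn) with unit branch lengths
make_caterpillar <- function(n) {
  s <- "(t1:1,t2:1)"
  for (i in 3:n) s <- sprintf("(%s:1,t%d:%d)", s, i, i - 1)
  read_newick(paste0(s, ";"))
}

# independent clade enumeration via phangorn; returns list of tip-label sets
oracle_clades <- function(phy) {
  ntip <- length(phy$tip.label)
  desc <- phangorn::Descendants(phy, (ntip + 1):(ntip + phy$Nnode), "tips")
  lapply(desc, function(i) sort(phy$tip.label[i]))
}

# brute-force species-level monophyly: some clade's tips == all tips of the set
oracle_monophyletic <- function(tree, species_set) {
  sp <- tip_species(tree)
  target <- sort(names(sp)[sp %in% species_set])
  if (length(target) == 1) return(TRUE)
  any(vapply(oracle_clades(tree), identical, logical(1), y = target))
}

# a 4-group scheme over generic species names
toy_scheme <- function() {
  groups <- c(cm1 = "CM", cm2 = "CM", mo1 = "MO", mo2 = "MO",
              eu1 = "EU", eu2 = "EU", out = "OUT")
  group_scheme(groups, outgroup = "OUT")
}

toy_defs <- function() type_definition("CM", "MO", "EU")

# independent NG86 oracle built on Biostrings' genetic code and a recursive
# pathway enumerator (distinct from the package implementation)
oracle_ng86 <- local({
  gc <- Biostrings::GENETIC_CODE
  bases <- c("T", "C", "A", "G")
  aa <- function(codon) unname(gc[codon])
  syn_sites <- function(codon) {
    cc <- strsplit(codon, "")[[1]]
    tot <- 0
    for (p in 1:3) {
      for (b in bases[bases != cc[p]]) {
        alt <- cc; alt[p] <- b
        altc <- paste(alt, collapse = "")
        if (aa(altc) != "*" && aa(altc) == aa(codon)) tot <- tot + 1 / 3
      }
    }
    tot
  }
  # recursive pathway enumeration; skip stop intermediates
  paths <- function(c1, c2) {
    pos <- which(strsplit(c1, "")[[1]] != strsplit(c2, "")[[1]])
    if (length(pos) == 0) return(list(c(s = 0, n = 0)))
    out <- list()
    for (p in pos) {
      cc <- strsplit(c1, "")[[1]]
      cc[p] <- strsplit(c2, "")[[1]][p]
      mid <- paste(cc, collapse = "")
      if (aa(mid) == "*" && mid != c2) next
      step <- if (aa(c1) == aa(mid)) c(s = 1, n = 0) else c(s = 0, n = 1)
      for (rest in paths(mid, c2)) out[[length(out) + 1]] <- step + rest
    }
    out
  }
  function(c1, c2) {
    pw <- paths(c1, c2)
    if (length(pw) == 0) {
      # all pathways blocked by stops: count stop steps as nonsynonymous
      d <- sum(strsplit(c1, "")[[1]] != strsplit(c2, "")[[1]])
      return(list(S = (syn_sites(c1) + syn_sites(c2)) / 2,
                  Sd = NA_real_, Nd = NA_real_, d = d))
    }
    m <- colMeans(do.call(rbind, pw))
    list(S = (syn_sites(c1) + syn_sites(c2)) / 2,
         Sd = unname(m["s"]), Nd = unname(m["n"]))
  }
})
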