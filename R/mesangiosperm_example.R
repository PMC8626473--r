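## A synthetic 18-taxon mesangiosperm species tree and grouping scheme used
## as the default study system: three monocots, four eudicots, seven
## magnoliids, one Chloranthales, one Ceratophyllales and a two-species
## outgroup.  Branch lengths are in coalescent units, ultrametric, with a
## deliberately short internal branch (0.5) around the placement of the
## Chloranthales+magnoliids clade so that ILS discordance is present.

#' Synthetic mesangiosperm species tree (18 taxa)
#'
#' Rooted ultrametric species tree, branch lengths in coalescent units,
#' whose backbone places monocots, then Chloranthales+magnoliids, as
#' successive sisters to Ceratophyllales+eudicots.  The two internal
#' branches ordering the three focal clades have length
#' `conflict_branch` each, controlling the amount of ILS discordance.
#'
#' @param conflict_branch length (coalescent units) of the two backbone
#'   branches around the conflict (default 0.5).
#' @return a `species_network` with no reticulations.
#' @export
example_species_tree <- function(conflict_branch = 0.5) {
  cb <- conflict_branch
  ## node ages: groups coalesce by age 4; eudicots+Ceratophyllales at 5;
  ## + CM clade at 5 + cb; + monocots at 5 + 2 cb; root at 12
  mono <- sprintf("((Oryza_sativa:2,Musa_acuminata:2):1,Phalaenopsis_equestris:3):%g",
                  5 + 2 * cb - 3)
  eud <- paste0("((Arabidopsis_thaliana:2.5,Erythranthe_guttata:2.5):1,",
                "(Vitis_vinifera:3,Aquilegia_coerulea:3):0.5):1.5")  # crown 3.5, stem to 5
  cer <- "Ceratophyllum_demersum:5"
  mag <- paste0("(((Liriodendron_chinense:1.5,Magnolia_biondii:1.5):1.5,",
                "((Cinnamomum_kanehirae:1,Phoebe_bournei:1):1,Litsea_cubeba:2):1):0.5,",
                "(Piper_nigrum:3,Chimonanthus_salicifolius:3):0.5):0.5")  # crown 3.5, to 4
  cm <- sprintf("(%s,Chloranthus_spicatus:4):%g", mag, 1 + cb)  # crown 4, stem to 5+cb
  core <- sprintf("((%s,%s):%g,%s):%g", eud, cer, cb, cm, cb)   # 5 -> 5+cb -> 5+2cb
  root_age <- max(12, 5 + 2 * cb + 2)
  ingroup <- sprintf("(%s,%s):%g", core, mono, root_age - 5 - 2 * cb)
  outg <- sprintf("(Amborella_trichopoda:8,Nymphaea_colorata:8):%g",
                  root_age - 8)
  read_enewick(sprintf("(%s,%s);", ingroup, outg))
}

#' Grouping scheme for the example species tree
#'
#' Maps the 18 example species to the five mesangiosperm clades (with
#' Chloranthales and magnoliids combined into one focal group) plus the
#' outgroup.
#'
#' @return a [group_scheme()].
#' @export
example_group_scheme <- function() {
  groups <- c(
    Oryza_sativa = "monocots", Musa_acuminata = "monocots",
    Phalaenopsis_equestris = "monocots",
    Arabidopsis_thaliana = "eudicots", Erythranthe_guttata = "eudicots",
    Vitis_vinifera = "eudicots", Aquilegia_coerulea = "eudicots",
    Liriodendron_chinense = "chloranthales_magnoliids",
    Magnolia_biondii = "chloranthales_magnoliids",
    Cinnamomum_kanehirae = "chloranthales_magnoliids",
    Phoebe_bournei = "chloranthales_magnoliids",
    Litsea_cubeba = "chloranthales_magnoliids",
    Piper_nigrum = "chloranthales_magnoliids",
    Chimonanthus_salicifolius = "chloranthales_magnoliids",
    Chloranthus_spicatus = "chloranthales_magnoliids",
    Ceratophyllum_demersum = "ceratophyllales",
    Amborella_trichopoda = "outgroup", Nymphaea_colorata = "outgroup")
  group_scheme(groups, outgroup = "outgroup")
}

#' Default focal triplets for the example system
#'
#' One representative per focal clade, crossed: triplets spanning the
#' Chloranthales+magnoliids clade, monocots and eudicots, used by the
#' false-positive control.
#'
#' @param n_per_group representatives per clade (default 2).
#' @return list of species triplets.
#' @export
example_focal_triplets <- function(n_per_group = 2) {
  cm <- c("Chloranthus_spicatus", "Liriodendron_chinense",
          "Cinnamomum_kanehirae")[seq_len(n_per_group)]
  mo <- c("Oryza_sativa", "Musa_acuminata")[seq_len(min(n_per_group, 2))]
  eu <- c("Arabidopsis_thaliana", "Vitis_vinifera")[seq_len(min(n_per_group, 2))]
  out <- list()
  for (a in cm) for (b in mo) for (c_ in eu)
    out[[length(out) + 1L]] <- c(a, b, c_)
  out
}
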