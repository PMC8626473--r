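## Plain-text artifact I/O and run manifests.

#' Write a data frame as TSV
#' @param df data frame.
#' @param file output path.
#' @export
write_tsv <- function(df, file) {
  utils::write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' Read a TSV with a header
#' @param file input path.
#' @return data frame.
#' @export
read_tsv <- function(file) utils::read.delim(file, stringsAsFactors = FALSE)

#' Read a pairwise Ks table into gene families
#'
#' Expected columns: `family_id`, `gene_i`, `gene_j`, `ks`.
#'
#' @param file TSV path or data frame.
#' @return list of [gene_family()] objects.
#' @export
read_ks_table <- function(file) {
  df <- if (is.data.frame(file)) file else read_tsv(file)
  need <- c("family_id", "gene_i", "gene_j", "ks")
  if (!all(need %in% names(df)))
    stop("Ks table must have columns: ", paste(need, collapse = ", "))
  lapply(split(df, df$family_id), function(d) {
    genes <- sort(unique(c(d$gene_i, d$gene_j)))
    ks <- matrix(NA_real_, length(genes), length(genes),
                 dimnames = list(genes, genes))
    diag(ks) <- 0
    for (i in seq_len(nrow(d)))
      ks[d$gene_i[i], d$gene_j[i]] <- ks[d$gene_j[i], d$gene_i[i]] <- d$ks[i]
    if (anyNA(ks))
      stop("incomplete pairwise Ks table for family ", d$family_id[1])
    gene_family(d$family_id[1], ks)
  })
}

#' Write a reproducible run manifest
#'
#' Records the seed, parameters and md5 checksums of the listed artifact
#' files as JSON next to the outputs.
#'
#' @param dir output directory.
#' @param command subcommand or function name.
#' @param params named list of parameters.
#' @param files character vector of artifact paths.
#' @return path of the manifest, invisibly.
#' @export
write_manifest <- function(dir, command, params, files = character()) {
  manifest <- list(
    command = command,
    package = "phylodisc",
    version = as.character(utils::packageVersion("phylodisc")),
    params = params,
    artifacts = lapply(files, function(f)
      list(file = basename(f), md5 = unname(tools::md5sum(f))))
  )
  path <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}
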