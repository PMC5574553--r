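#' One-to-one ortholog tables
#'
#' An ortholog table holds 1-to-1(-to-1-to-1) quartets (or pairs) with one
#' column per species. Within the table each identifier appears in exactly
#' one row of its species column, so projection between any two species is a
#' bijection on the mapped genes. Identifiers are treated as opaque strings:
#' no version-suffix normalisation is attempted. Pairwise (two-species)
#' tables are supported as degenerate quartets; `NA` marks an absent member.
#'
#' @param quartets Data frame with one identifier column per species.
#' @param species Ordered species names (defaults to the column names).
#' @return An object of class `iec_orthologs`.
#' @export
ortholog_table <- function(quartets, species = colnames(quartets)) {
  if (!all(species %in% colnames(quartets)))
    stop2("missing species column(s): ",
          paste(setdiff(species, colnames(quartets)), collapse = ", "))
  quartets <- quartets[, species, drop = FALSE]
  for (sp in species) {
    v <- quartets[[sp]]
    v <- v[!is.na(v)]
    dup <- unique(v[duplicated(v)])
    if (length(dup))
      stop2("duplicate ", sp, " identifier(s) violate 1-to-1 orthology: ",
            paste(utils::head(dup, 10), collapse = ", "))
  }
  structure(list(quartets = quartets, species_order = species),
            class = "iec_orthologs")
}

#' @export
print.iec_orthologs <- function(x, ...) {
  cat(sprintf("Ortholog table: %d quartets across %s\n", nrow(x$quartets),
              paste(x$species_order, collapse = ", ")))
  invisible(x)
}

#' Load an ortholog table from TSV
#'
#' @param path TSV file with a header naming one column per species.
#' @param species Species columns to keep (default: all columns).
#' @return An [ortholog_table()] object. Duplicate identifiers within a
#'   species column are a validation error naming the offenders.
#' @export
load_ortholog_table <- function(path, species = NULL) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           na.strings = c("NA", ""))
  species <- species %||% colnames(tab)
  ortholog_table(tab, species)
}

#' Write an ortholog table as TSV
#' @param table An [ortholog_table()] object.
#' @param path Output path.
#' @export
write_ortholog_table <- function(table, path) {
  stopifnot(inherits(table, "iec_orthologs"))
  utils::write.table(table$quartets, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Project a gene set between species
#'
#' Maps identifiers through the 1-to-1 table. Inputs without an entry in the
#' `from` column (or whose quartet lacks the `to` member) are reported in
#' `unmapped`, never silently dropped.
#'
#' @param table An [ortholog_table()] object.
#' @param genes Character vector of `from`-species identifiers.
#' @param from,to Species names present in the table.
#' @return List with `genes` (named character vector: images keyed by input
#'   identifier) and `unmapped` (inputs with no image).
#' @export
project_genes <- function(table, genes, from, to) {
  stopifnot(inherits(table, "iec_orthologs"))
  for (sp in c(from, to))
    if (!sp %in% table$species_order)
      stop2("unknown species '", sp, "'")
  q <- table$quartets
  idx <- match(genes, q[[from]])
  img <- q[[to]][idx]
  ok <- !is.na(idx) & !is.na(img)
  out <- img[ok]
  names(out) <- genes[ok]
  list(genes = out, unmapped = genes[!ok])
}
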