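# Taxonomic lineage table and the genus-call rule.
#
# The classifier (PathSeq dialect) reports, per read, the set of
# best-scoring taxon ids; the scores CSV carries each taxon's lineage as a
# pipe-separated, rank-prefixed string. All quantification happens at
# genus rank: species/strain hits collapse upward, and a read whose hits
# span more than one genus is "unassigned" and contributes to no genus.

RANK_PREFIXES <- c(k = "kingdom", p = "phylum", c = "class", o = "order",
                   f = "family", g = "genus", s = "species", t = "strain")

#' Build a taxonomy table from parsed entries
#'
#' @param ids Integer taxon ids.
#' @param names Character taxon names.
#' @param ranks Character ranks (e.g. `"genus"`, `"species"`).
#' @param lineages List of `data.frame(rank, name)`, ordered root to leaf,
#'   ending at the entry's own rank.
#' @return Object of class `taxonomy_table`.
#' @export
taxonomy_table <- function(ids, names, ranks, lineages) {
  ids <- as.integer(ids)
  stopifnot(length(ids) == length(names), length(ids) == length(ranks),
            length(ids) == length(lineages))
  if (anyDuplicated(ids)) stop("duplicate taxon ids in taxonomy table")
  for (ln in lineages) {
    if (anyDuplicated(ln$rank)) stop("repeated rank within a lineage")
  }
  structure(list(ids = ids,
                 name = stats::setNames(as.character(names), ids),
                 rank = stats::setNames(as.character(ranks), ids),
                 lineage = stats::setNames(lineages, ids)),
            class = "taxonomy_table")
}

#' @export
print.taxonomy_table <- function(x, ...) {
  cat(sprintf("taxonomy_table: %d taxa (%s)\n", length(x$ids),
              paste(utils::head(sort(unique(unname(x$rank)))), collapse = ", ")))
  invisible(x)
}

#' Read a taxonomy table from a classifier scores CSV
#'
#' PathSeq-dialect scores CSV: one row per taxon with columns including
#' `tax_id`, `taxonomy` (pipe-separated rank-prefixed lineage such as
#' `k__Bacteria|p__Fusobacteriota|...|g__Fusobacterium`), `type` (the
#' entry's own rank) and `name`. Extra columns (scores, read counts) are
#' ignored.
#'
#' @param path Scores CSV path.
#' @return A `taxonomy_table`.
#' @export
read_taxonomy_table <- function(path) {
  if (!file.exists(path)) stop("taxonomy scores CSV not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("tax_id", "taxonomy", "type", "name")
  if (!all(need %in% names(df))) {
    stop("scores CSV must contain columns: ", paste(need, collapse = ", "))
  }
  lineages <- lapply(df$taxonomy, parse_lineage_string)
  taxonomy_table(df$tax_id, df$name, df$type, lineages)
}

#' Parse one pipe-separated rank-prefixed lineage string
#' @keywords internal
parse_lineage_string <- function(s) {
  parts <- strsplit(s, "|", fixed = TRUE)[[1]]
  parts <- parts[nzchar(parts)]
  pre <- sub("__.*$", "", parts)
  nm <- sub("^[a-z]__", "", parts)
  bad <- !(pre %in% names(RANK_PREFIXES)) | pre == parts
  if (any(bad)) {
    stop("unparseable lineage element(s): ", paste(parts[bad], collapse = "|"))
  }
  data.frame(rank = unname(RANK_PREFIXES[pre]), name = nm,
             stringsAsFactors = FALSE)
}

#' Serialise a lineage data.frame back to the scores-CSV string form
#' @keywords internal
format_lineage_string <- function(lineage) {
  pre <- names(RANK_PREFIXES)[match(lineage$rank, RANK_PREFIXES)]
  paste(paste0(pre, "__", lineage$name), collapse = "|")
}

#' Genus-rank name in a taxon's lineage
#'
#' Walks the lineage of `taxon_id` and returns the name at genus rank;
#' `NA` when the lineage carries no genus element (e.g. a family-level
#' id). Species- and strain-level ids therefore collapse upward to their
#' genus.
#'
#' @param taxon_id Integer taxon id (scalar).
#' @param table A `taxonomy_table`.
#' @return Genus name, or `NA_character_` if the lineage has no genus rank.
#' @export
genus_of <- function(taxon_id, table) {
  stopifnot(inherits(table, "taxonomy_table"))
  key <- as.character(as.integer(taxon_id))
  ln <- table$lineage[[key]]
  if (is.null(ln)) stop("unknown taxon id: ", taxon_id)
  hit <- ln$name[ln$rank == "genus"]
  if (length(hit) == 0L) NA_character_ else hit[1]
}

#' Collapse one read's taxonomic hits to a single genus call
#'
#' A read is assigned a genus only when every best-scoring taxon in its hit
#' maps to the same single genus; any disagreement at genus rank, or a hit
#' consisting solely of above-genus taxa, yields `"unassigned"`. The call
#' is invariant to the order of `taxon_ids`.
#'
#' @param taxon_ids Integer vector of best-scoring taxon ids for one read.
#' @param table A `taxonomy_table`.
#' @return Genus name or `"unassigned"`.
#' @export
assign_read_genus <- function(taxon_ids, table) {
  if (length(taxon_ids) == 0L) stop("empty hit: taxon_ids must be non-empty")
  genera <- vapply(taxon_ids, genus_of, character(1), table = table)
  genera <- unique(genera[!is.na(genera)])
  if (length(genera) == 1L) genera else "unassigned"
}

#' Read per-read classifier hits from a taxonomy-annotated alignment file
#'
#' The classifier writes its per-read taxon ids into an optional tag
#' (default `YP`) as a comma-separated list. Records without the tag are
#' unclassified and omitted.
#'
#' @param path Taxonomy-annotated SAM/BAM path.
#' @param taxon_tag Tag key holding the comma-separated taxon ids.
#' @return `data.frame` with `read_name` and list-column `taxon_ids`.
#' @export
read_taxonomic_hits <- function(path, taxon_tag = "YP") {
  aln <- read_tagged_alignments(path, extra_tags = taxon_tag,
                                keep_sequence = FALSE)
  aln <- aln[!is.na(aln[[taxon_tag]]) & !aln$is_secondary_or_supplementary, ,
             drop = FALSE]
  ids <- lapply(strsplit(aln[[taxon_tag]], ",", fixed = TRUE), as.integer)
  out <- data.frame(read_name = aln$read_name, stringsAsFactors = FALSE)
  out$taxon_ids <- ids
  out[!duplicated(out$read_name), , drop = FALSE]
}

#' Genus calls for a table of hits
#'
#' @param hits `data.frame` from [read_taxonomic_hits()].
#' @param table A `taxonomy_table`.
#' @return Named character vector: read name to genus or `"unassigned"`.
#' @export
genus_calls <- function(hits, table) {
  stats::setNames(
    vapply(hits$taxon_ids, assign_read_genus, character(1), table = table),
    hits$read_name)
}

#' Remove denylisted genera from a matrix
#'
#' Drops the named genus columns (and their UMI sets) wholesale. Cells are
#' retained even if all their counts were in denylisted genera; their
#' totals simply become zero. Denylisting a genus absent from the matrix is
#' a no-op, and the operation is idempotent.
#'
#' @param m A `genus_cell_matrix`.
#' @param denylist Character vector of genus names to exclude.
#' @return A `genus_cell_matrix` without the denylisted genera.
#' @export
apply_denylist <- function(m, denylist) {
  stopifnot(inherits(m, "genus_cell_matrix"))
  if (length(denylist) == 0L) return(m)
  keep <- !(m$umis$genus %in% denylist)
  out <- genus_cell_matrix(m$umis[keep, , drop = FALSE])
  # cells with all counts denylisted stay in the universe at total 0
  out$cell_ids <- m$cell_ids
  out
}

#' Contaminant genus preset
#'
#' The genera flagged as probable reagent/environmental contaminants in
#' low-biomass tumour cohorts. Shipped as a documented optional preset;
#' the default denylist everywhere in the package is empty.
#'
#' @return Character vector of genus names.
#' @export
contaminant_denylist <- function() {
  c("Patulibacter", "Pseudomonas", "Sphingomonas")
}
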