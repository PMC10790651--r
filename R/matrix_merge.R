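# Merge the GEX-library and 16S-enrichment-library matrices (and any
# number of samples) into one deduplicated bacteria UMI matrix.
#
# Both libraries derive from the same emulsion, so an identical
# (cell_id, genus, umi) observation in two libraries is one molecule: the
# deduplication key is the triplet, the merged UMI sets are unions, and
# counts are re-derived distinct-UMI cardinalities. Provenance records
# which source libraries observed each triplet.

#' Merge genus x cell UMI matrices with UMI deduplication
#'
#' Unions the per-(cell, genus) UMI sets of the inputs; each
#' `(cell_id, genus, umi)` triplet is counted exactly once regardless of
#' how many libraries or samples observed it. Cross-sample deduplication
#' never occurs in practice because cell ids carry sample prefixes. The
#' operation is commutative, associative and idempotent, and the merged
#' count never exceeds the sum of the input counts.
#'
#' Inputs must carry their UMI-set sidecars (a `genus_cell_matrix` always
#' does); bare count tables cannot be deduplicated and are refused by the
#' readers upstream.
#'
#' @param matrices List of `genus_cell_matrix` objects.
#' @param sources Optional character vector naming each input's source
#'   library (recycled into provenance); defaults to names of `matrices`
#'   or the input index.
#' @param whitelist_cells Optional character vector restricting the merged
#'   matrix to these cell ids (the GEX-derived whitelist after sample
#'   prefixing).
#' @return A `genus_cell_matrix` whose triplet table carries a `source`
#'   provenance column.
#' @export
merge_matrices <- function(matrices, sources = NULL, whitelist_cells = NULL) {
  if (length(matrices) == 0L) stop("no matrices to merge")
  lapply(matrices, function(m) {
    if (!inherits(m, "genus_cell_matrix")) {
      stop("merge requires genus_cell_matrix inputs (with UMI sets); ",
           "bare count tables cannot be deduplicated")
    }
  })
  if (is.null(sources)) {
    sources <- names(matrices)
    if (is.null(sources)) sources <- as.character(seq_along(matrices))
    sources[!nzchar(sources)] <- as.character(which(!nzchar(sources)))
  }
  parts <- lapply(seq_along(matrices), function(i) {
    tr <- matrices[[i]]$umis
    if (!"source" %in% names(tr)) {
      tr$source <- rep(sources[i], nrow(tr))
    }
    tr
  })
  all_tr <- do.call(rbind, parts)
  all_cells <- sort(unique(unlist(lapply(matrices, function(m) m$cell_ids))))
  if (!is.null(whitelist_cells)) {
    all_tr <- all_tr[all_tr$cell_id %in% whitelist_cells, , drop = FALSE]
    all_cells <- intersect(all_cells, whitelist_cells)
  }
  out <- genus_cell_matrix(all_tr)
  out$cell_ids <- all_cells
  out
}

#' Write the merged bacteria UMI matrix
#'
#' Writes the merged genus x cell CSV (default file name
#' `csv_novami.csv`, the name downstream single-cell analysis loads), the
#' merged UMI-set sidecar, and a provenance TSV of
#' `(cell_id, genus, umi, source)` rows.
#'
#' @param merged A merged `genus_cell_matrix`.
#' @param dir Output directory.
#' @param name CSV file name.
#' @return Path of the CSV, invisibly.
#' @export
write_merged_matrix <- function(merged, dir, name = "csv_novami.csv") {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  path <- file.path(dir, name)
  write_genus_matrix(merged, path)
  prov <- merged$umis
  if (!"source" %in% names(prov)) prov$source <- NA_character_
  utils::write.table(prov, file.path(dir, paste0(name, ".provenance.tsv")),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
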