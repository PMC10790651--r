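# Readers and writers for the external formats the pipeline touches:
# barcode whitelists (CellRanger barcodes.tsv[.gz] dialect), tagged SAM/BAM
# alignments, genus x cell count CSVs with a UMI-set sidecar, GMT gene sets,
# sample manifests and MTX expression matrices.

#' Detect gzip compression by magic bytes
#'
#' Looks at the first two bytes of a file rather than trusting the extension.
#'
#' @param path Path to a file.
#' @return `TRUE` if the file starts with the gzip magic bytes.
#' @keywords internal
is_gzipped <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readBin(con, "raw", n = 2L)
  length(magic) == 2L && magic[1] == as.raw(0x1f) && magic[2] == as.raw(0x8b)
}

#' Open a text connection, transparently decompressing gzip
#' @keywords internal
open_text <- function(path) {
  if (is_gzipped(path)) gzfile(path, "rt") else file(path, "rt")
}

#' Read a cell-barcode whitelist
#'
#' Reads the filtered cell-barcode list produced by the droplet caller
#' (`barcodes.tsv.gz` dialect: one barcode per line, gzipped or plain).
#' Barcodes are kept verbatim, including any trailing suffix such as
#' `"-1"`; membership tests downstream are exact string equality.
#'
#' @param path Path to a gzipped or plain one-column TSV.
#' @return Character vector of unique barcodes (class `barcode_whitelist`).
#' @examples
#' tf <- tempfile(fileext = ".tsv")
#' writeLines(c("AAAC-1", "CCGT-1"), tf)
#' wl <- read_barcode_whitelist(tf)
#' length(wl)
#' @export
read_barcode_whitelist <- function(path) {
  if (!file.exists(path)) stop("whitelist file not found: ", path)
  con <- open_text(path)
  on.exit(close(con))
  lines <- readLines(con)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) stop("empty whitelist: ", path)
  dup <- unique(lines[duplicated(lines)])
  if (length(dup) > 0L) {
    stop("duplicate barcode(s) in whitelist: ", paste(dup, collapse = ", "))
  }
  structure(lines, class = c("barcode_whitelist", "character"))
}

#' Write a cell-barcode whitelist
#'
#' @param barcodes Character vector of barcodes.
#' @param path Output path; written gzipped when it ends in `.gz`.
#' @return `path`, invisibly.
#' @export
write_barcode_whitelist <- function(barcodes, path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wt") else file(path, "wt")
  on.exit(close(con))
  writeLines(as.character(barcodes), con)
  invisible(path)
}

#' Read barcode/UMI-tagged alignments
#'
#' Parses a SAM or BAM file into one record per alignment line, surfacing
#' the fields the quantifier needs: host-mapped status (from the unmapped
#' flag), secondary/supplementary status, the cell-barcode and UMI tags,
#' and optionally further tags (e.g. the per-read taxon-id tag written by
#' the classifier). Text SAM input is converted to BAM on the fly via
#' `Rsamtools::asBam`; parsing itself is delegated to `Rsamtools::scanBam`
#' and is single-pass and order-preserving.
#'
#' Missing tags yield `NA` fields, never an error; only corrected tags
#' (defaults `CB`/`UB`) should be used, never the raw uncorrected ones.
#'
#' @param path Path to a SAM or BAM file.
#' @param cb_tag,umi_tag Tag keys for the cell barcode and UMI
#'   (CellRanger dialect defaults `CB` and `UB`).
#' @param extra_tags Character vector of further tag keys to extract,
#'   returned as additional character columns.
#' @param keep_sequence If `TRUE` (default) include the read sequence and
#'   the Phred+33 quality string.
#' @return A `data.frame` with columns `read_name`, `is_host_mapped`,
#'   `is_secondary_or_supplementary`, `cell_barcode`, `umi` and, when
#'   requested, `sequence`, `qualities` plus one column per extra tag.
#' @export
read_tagged_alignments <- function(path, cb_tag = "CB", umi_tag = "UB",
                                   extra_tags = character(),
                                   keep_sequence = TRUE) {
  if (!file.exists(path)) stop("alignment file not found: ", path)
  bam <- path
  if (!is_gzipped(path)) {
    # plain-text SAM: convert to a temporary BAM first
    dest <- tempfile(fileext = "")
    bam <- Rsamtools::asBam(path, destination = dest, overwrite = TRUE,
                            indexDestination = FALSE)
  }
  what <- c("qname", "flag")
  if (keep_sequence) what <- c(what, "seq", "qual")
  tags <- unique(c(cb_tag, umi_tag, extra_tags))
  param <- Rsamtools::ScanBamParam(what = what, tag = tags)
  res <- Rsamtools::scanBam(bam, param = param)[[1]]
  n <- length(res$qname)
  if (n == 0L) {
    out <- data.frame(read_name = character(), is_host_mapped = logical(),
                      is_secondary_or_supplementary = logical(),
                      cell_barcode = character(), umi = character(),
                      stringsAsFactors = FALSE)
    if (keep_sequence) {
      out$sequence <- character()
      out$qualities <- character()
    }
    for (t in extra_tags) out[[t]] <- character()
    return(out)
  }
  tag_col <- function(key) {
    v <- res$tag[[key]]
    if (is.null(v)) rep(NA_character_, n) else as.character(v)
  }
  flag <- res$flag
  out <- data.frame(
    read_name = res$qname,
    is_host_mapped = bitwAnd(flag, 4L) == 0L,
    is_secondary_or_supplementary =
      bitwAnd(flag, 256L) != 0L | bitwAnd(flag, 2048L) != 0L,
    cell_barcode = tag_col(cb_tag),
    umi = tag_col(umi_tag),
    stringsAsFactors = FALSE
  )
  if (keep_sequence) {
    out$sequence <- as.character(res$seq)
    out$qualities <- as.character(res$qual)
  }
  for (t in setdiff(extra_tags, c(cb_tag, umi_tag))) out[[t]] <- tag_col(t)
  out
}

#' Convert a Phred+33 quality string to integer scores
#'
#' @param qual Character vector of Phred+33 quality strings.
#' @return List of integer vectors (one per input string).
#' @export
phred_scores <- function(qual) {
  lapply(qual, function(q) {
    if (is.na(q) || !nzchar(q)) return(integer())
    as.integer(charToRaw(q)) - 33L
  })
}

#' Encode integer Phred scores as a Phred+33 string
#' @param scores Integer vector of Phred scores.
#' @return Single quality string.
#' @export
phred_string <- function(scores) {
  if (length(scores) == 0L) return("")
  rawToChar(as.raw(as.integer(scores) + 33L))
}

# ---- genus x cell matrix -------------------------------------------------

#' Construct a genus x cell UMI matrix
#'
#' The pipeline's central object: per-(cell, genus) sets of distinct UMI
#' sequences, from which integer counts are derived. Stored as a unique
#' triplet table `(cell_id, genus, umi)`, optionally with a `source`
#' column recording which libraries observed each triplet.
#'
#' @param triplets A `data.frame` with columns `cell_id`, `genus`, `umi`
#'   and optionally `source`. Duplicate `(cell_id, genus, umi)` rows are
#'   collapsed (set semantics); sources of collapsed rows are unioned.
#' @return An object of class `genus_cell_matrix`.
#' @export
genus_cell_matrix <- function(triplets = data.frame(cell_id = character(),
                                                    genus = character(),
                                                    umi = character())) {
  stopifnot(all(c("cell_id", "genus", "umi") %in% names(triplets)))
  tr <- data.frame(cell_id = as.character(triplets$cell_id),
                   genus = as.character(triplets$genus),
                   umi = as.character(triplets$umi),
                   stringsAsFactors = FALSE)
  has_src <- "source" %in% names(triplets)
  if (has_src) tr$source <- as.character(triplets$source)
  key <- paste(tr$cell_id, tr$genus, tr$umi, sep = "\r")
  if (anyDuplicated(key)) {
    if (has_src) {
      src <- vapply(split(tr$source, key), function(s) {
        paste(sort(unique(unlist(strsplit(s, ",", fixed = TRUE)))),
              collapse = ",")
      }, character(1))
      tr <- tr[!duplicated(key), , drop = FALSE]
      tr$source <- src[paste(tr$cell_id, tr$genus, tr$umi, sep = "\r")]
    } else {
      tr <- tr[!duplicated(key), , drop = FALSE]
    }
  }
  o <- order(tr$cell_id, tr$genus, tr$umi, method = "radix")
  tr <- tr[o, , drop = FALSE]
  rownames(tr) <- NULL
  structure(list(umis = tr,
                 cell_ids = sort(unique(tr$cell_id)),
                 genera = sort(unique(tr$genus))),
            class = "genus_cell_matrix")
}

#' @export
print.genus_cell_matrix <- function(x, ...) {
  cat(sprintf("genus_cell_matrix: %d cells x %d genera, %d distinct UMIs\n",
              length(x$cell_ids), length(x$genera), nrow(x$umis)))
  invisible(x)
}

#' Integer UMI counts of a genus x cell matrix
#'
#' @param m A `genus_cell_matrix`.
#' @param cell_ids,genera Optional row/column universes; defaults to the
#'   cells and genera present. Absent combinations count 0.
#' @return Integer matrix, cells as rows, genera as columns
#'   (lexicographically ordered).
#' @export
umi_counts <- function(m, cell_ids = NULL, genera = NULL) {
  stopifnot(inherits(m, "genus_cell_matrix"))
  cells <- if (is.null(cell_ids)) m$cell_ids else as.character(cell_ids)
  gens <- sort(if (is.null(genera)) m$genera else as.character(genera))
  out <- matrix(0L, nrow = length(cells), ncol = length(gens),
                dimnames = list(cells, gens))
  if (nrow(m$umis) > 0L && length(cells) > 0L && length(gens) > 0L) {
    keep <- m$umis$cell_id %in% cells & m$umis$genus %in% gens
    if (any(keep)) {
      tab <- table(factor(m$umis$cell_id[keep], levels = cells),
                   factor(m$umis$genus[keep], levels = gens))
      out[] <- as.integer(tab)
    }
  }
  out
}

#' Write a genus x cell matrix as CSV plus UMI-set sidecar
#'
#' The CSV holds integer distinct-UMI counts: one row per cell id, one
#' column per genus, genus columns in lexicographic order, UTF-8, numerics
#' unquoted. Counts alone cannot be deduplicated across libraries, so the
#' UMI sequences themselves are serialised to a TSV sidecar of
#' `(cell_id, genus, umi)` rows (plus `source` when present), which is what
#' makes later merging possible.
#'
#' @param m A `genus_cell_matrix`.
#' @param path Output CSV path.
#' @param sidecar_path Output sidecar TSV path; defaults to
#'   `paste0(path, ".umis.tsv")`.
#' @return `path`, invisibly.
#' @export
write_genus_matrix <- function(m, path,
                               sidecar_path = paste0(path, ".umis.tsv")) {
  stopifnot(inherits(m, "genus_cell_matrix"))
  cnt <- umi_counts(m)
  df <- data.frame(cell_id = as.character(rownames(cnt)),
                   stringsAsFactors = FALSE)
  for (g in colnames(cnt)) df[[g]] <- cnt[, g]
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  utils::write.table(m$umis, sidecar_path, sep = "\t", row.names = FALSE,
                     quote = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a genus x cell matrix written by [write_genus_matrix()]
#'
#' Counts in the CSV are cross-checked against the cardinalities of the
#' sidecar UMI sets; a mismatch, a malformed header, or a negative or
#' non-integer count is an error.
#'
#' @param path CSV path.
#' @param sidecar_path Sidecar TSV path; defaults to
#'   `paste0(path, ".umis.tsv")`.
#' @return A `genus_cell_matrix`.
#' @export
read_genus_matrix <- function(path,
                              sidecar_path = paste0(path, ".umis.tsv")) {
  if (!file.exists(path)) stop("matrix CSV not found: ", path)
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 1L || names(df)[1] != "cell_id") {
    stop("malformed matrix CSV header (expected first column 'cell_id'): ",
         path)
  }
  if (ncol(df) > 1L) {
    vals <- as.matrix(df[, -1, drop = FALSE])
    if (!is.numeric(vals) || any(vals < 0) || any(vals != round(vals))) {
      stop("matrix CSV contains negative or non-integer counts: ", path)
    }
  }
  if (!file.exists(sidecar_path)) {
    stop("UMI-set sidecar required for a mergeable matrix, not found: ",
         sidecar_path)
  }
  sc <- utils::read.table(sidecar_path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE,
                          colClasses = "character")
  m <- genus_cell_matrix(sc)
  cnt <- umi_counts(m, cell_ids = df$cell_id,
                    genera = if (ncol(df) > 1L) names(df)[-1] else character())
  if (ncol(df) > 1L) {
    stored <- as.matrix(df[, colnames(cnt), drop = FALSE])
    rownames(stored) <- df$cell_id
    if (!isTRUE(all.equal(unname(stored + 0L), unname(cnt + 0L)))) {
      stop("CSV counts disagree with sidecar UMI-set cardinalities: ", path)
    }
  }
  m
}

# ---- GMT gene sets -------------------------------------------------------

#' Read gene sets from a GMT file
#'
#' Standard tab-separated GMT: set name, description, then one gene symbol
#' per field. Per-set gene order is preserved.
#'
#' @param path GMT path.
#' @return Named list of character vectors (class `gene_set_collection`).
#' @export
read_gene_sets <- function(path) {
  if (!file.exists(path)) stop("GMT file not found: ", path)
  con <- open_text(path)
  on.exit(close(con))
  lines <- readLines(con)
  lines <- lines[nzchar(lines)]
  sets <- list()
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(fields) < 3L) {
      stop("GMT line ", i, " has fewer than 3 fields")
    }
    nm <- fields[1]
    if (nm %in% names(sets)) stop("duplicate gene-set name: ", nm)
    genes <- fields[-(1:2)]
    genes <- genes[nzchar(genes)]
    if (length(genes) == 0L) stop("gene set '", nm, "' is empty (line ", i, ")")
    sets[[nm]] <- genes
  }
  structure(sets, class = c("gene_set_collection", "list"))
}

#' Write gene sets to a GMT file
#'
#' @param sets Named list of character vectors.
#' @param path Output path.
#' @param descriptions Optional character vector of per-set descriptions.
#' @return `path`, invisibly.
#' @export
write_gene_sets <- function(sets, path, descriptions = NULL) {
  if (is.null(descriptions)) descriptions <- rep("na", length(sets))
  lines <- vapply(seq_along(sets), function(i) {
    paste(c(names(sets)[i], descriptions[i], sets[[i]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

# ---- sample manifest -----------------------------------------------------

#' Read a multi-sample run manifest
#'
#' CSV with columns `sample`, `gex`, `microbial`: one row per sample, the
#' two path columns pointing at that sample's gene-expression and
#' 16S-enrichment inputs.
#'
#' @param path Manifest CSV path.
#' @param check_paths If `TRUE`, require both path prefixes to exist.
#' @return `data.frame` with the three columns.
#' @export
read_sample_manifest <- function(path, check_paths = FALSE) {
  if (!file.exists(path)) stop("manifest not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("sample", "gex", "microbial")
  if (!all(need %in% names(df))) {
    stop("manifest must have columns 'sample', 'gex' and 'microbial'")
  }
  if (anyDuplicated(df$sample)) stop("duplicate sample names in manifest")
  if (check_paths) {
    missing <- c(df$gex, df$microbial)
    missing <- missing[!file.exists(missing) & !dir.exists(missing)]
    if (length(missing)) {
      stop("manifest paths do not resolve: ", paste(missing, collapse = ", "))
    }
  }
  df[, need]
}

# ---- expression matrix (MTX triplet + sidecars) --------------------------

#' Read a filtered gene-expression matrix (MTX layout)
#'
#' Reads the CellRanger-style triplet layout: `matrix.mtx`, `features.tsv`
#' (gene id, gene symbol[, type]) and `barcodes.tsv`, each optionally
#' gzipped.
#'
#' @param dir Directory containing the three files.
#' @return List with `counts` (sparse gene x cell `dgCMatrix`, rownames =
#'   gene symbols, colnames = barcodes) and `features` (`data.frame`).
#' @export
read_expression_matrix <- function(dir) {
  find1 <- function(base) {
    for (p in file.path(dir, c(base, paste0(base, ".gz")))) {
      if (file.exists(p)) return(p)
    }
    stop("expression input missing: ", file.path(dir, base), "[.gz]")
  }
  mtx <- find1("matrix.mtx")
  counts <- methods::as(Matrix::readMM(if (is_gzipped(mtx)) gzfile(mtx) else mtx),
                        "CsparseMatrix")
  fcon <- open_text(find1("features.tsv"))
  features <- utils::read.table(fcon, sep = "\t", header = FALSE,
                                stringsAsFactors = FALSE)
  close(fcon)
  names(features)[1:min(3, ncol(features))] <-
    c("gene_id", "gene_symbol", "type")[1:min(3, ncol(features))]
  bcon <- open_text(find1("barcodes.tsv"))
  barcodes <- readLines(bcon)
  close(bcon)
  if (nrow(features) != nrow(counts) || length(barcodes) != ncol(counts)) {
    stop("features/barcodes sidecars do not match matrix dimensions")
  }
  sym <- if ("gene_symbol" %in% names(features)) features$gene_symbol
         else features$gene_id
  dimnames(counts) <- list(make.unique(sym), barcodes)
  list(counts = counts, features = features)
}

#' Write a gene-expression matrix in MTX triplet layout
#'
#' @param counts Gene x cell matrix (dense or sparse); dimnames required.
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_expression_matrix <- function(counts, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  m <- methods::as(methods::as(Matrix::Matrix(counts, sparse = TRUE),
                               "generalMatrix"), "CsparseMatrix")
  Matrix::writeMM(m, file.path(dir, "matrix.mtx"))
  features <- data.frame(gene_id = rownames(counts),
                         gene_symbol = rownames(counts),
                         type = "Gene Expression")
  utils::write.table(features, file.path(dir, "features.tsv"), sep = "\t",
                     row.names = FALSE, col.names = FALSE, quote = FALSE)
  writeLines(colnames(counts), file.path(dir, "barcodes.tsv"))
  invisible(dir)
}

# ---- SAM writing (synthetic fixtures) ------------------------------------

#' Write tagged alignment records as plain-text SAM
#'
#' Emits a minimal valid SAM file for synthetic data: unmapped records use
#' flag 4 with `*` reference, host-mapped records are placed on a dummy
#' reference sequence. Cell-barcode, UMI and taxon-id tags are written as
#' `Z`-type optional fields when present.
#'
#' @param records `data.frame` with columns `read_name`, `is_host_mapped`,
#'   `is_secondary_or_supplementary`, `sequence`, `qualities` and
#'   optionally `cell_barcode`, `umi`, `taxon_ids` (comma-joined string).
#' @param path Output `.sam` path.
#' @param cb_tag,umi_tag,taxon_tag Tag keys to write.
#' @param ref_name,ref_len Dummy host reference for mapped records.
#' @return `path`, invisibly.
#' @export
write_tagged_sam <- function(records, path, cb_tag = "CB", umi_tag = "UB",
                             taxon_tag = "YP", ref_name = "host1",
                             ref_len = 100000L) {
  header <- c("@HD\tVN:1.6\tSO:unsorted",
              sprintf("@SQ\tSN:%s\tLN:%d", ref_name, ref_len))
  n <- nrow(records)
  tag_field <- function(col, key) {
    if (!col %in% names(records)) return(rep("", n))
    v <- records[[col]]
    ifelse(is.na(v) | !nzchar(v), "", paste0("\t", key, ":Z:", v))
  }
  sec <- if ("is_secondary_or_supplementary" %in% names(records)) {
    records$is_secondary_or_supplementary
  } else rep(FALSE, n)
  flag <- ifelse(records$is_host_mapped, 0L, 4L) + ifelse(sec, 256L, 0L)
  pos <- ifelse(records$is_host_mapped,
                1L + (seq_len(n) %% (ref_len - 200L)), 0L)
  body <- if (n == 0L) character() else paste0(
    records$read_name, "\t", flag, "\t",
    ifelse(records$is_host_mapped, ref_name, "*"), "\t", pos, "\t",
    ifelse(records$is_host_mapped, 60L, 0L), "\t",
    ifelse(records$is_host_mapped,
           paste0(nchar(records$sequence), "M"), "*"),
    "\t*\t0\t0\t", records$sequence, "\t", records$qualities,
    tag_field("cell_barcode", cb_tag),
    tag_field("umi", umi_tag),
    tag_field("taxon_ids", taxon_tag)
  )
  writeLines(c(header, body), path)
  invisible(path)
}
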