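# Pipeline core: candidate-read selection, Read-1 quality trimming for the
# amplicon path, the join with per-read genus calls, and accumulation of
# genus x cell distinct-UMI sets.

#' Trimming parameters for the amplicon Read-1 path
#'
#' Defaults mirror the protocol's single-end trimming command:
#' leading/trailing quality 3, sliding window 4 bases at mean quality 15,
#' minimum length 36, headcrop 15 (the 5' bases holding cell barcode and
#' UMI, already captured in the alignment tags).
#'
#' @param adapter_sequences Character vector of adapter sequences for the
#'   simplified clip step (default: the TruSeq read-1 adapter).
#' @param leading_q,trailing_q Phred thresholds for 5'/3' stripping.
#' @param window_len,window_q Sliding-window length (bases) and mean-Phred
#'   threshold.
#' @param min_len Minimum surviving read length; shorter reads discarded.
#' @param headcrop Number of leading bases removed before the quality steps.
#' @return Object of class `trim_params`.
#' @export
trim_params <- function(adapter_sequences = "AGATCGGAAGAGCACACGTCTGAACTCCAGTCA",
                        leading_q = 3, trailing_q = 3,
                        window_len = 4, window_q = 15,
                        min_len = 36, headcrop = 15) {
  stopifnot(leading_q >= 0, trailing_q >= 0, window_q >= 0,
            window_len >= 1, min_len >= 0, headcrop >= 0)
  structure(list(adapter_sequences = as.character(adapter_sequences),
                 leading_q = leading_q, trailing_q = trailing_q,
                 window_len = as.integer(window_len), window_q = window_q,
                 min_len = as.integer(min_len),
                 headcrop = as.integer(headcrop)),
            class = "trim_params")
}

#' Quality-trim one read
#'
#' Applies, in order: a simplified adapter clip (truncate at the leftmost
#' exact occurrence of any adapter anywhere in the read, or of an adapter
#' prefix of at least 10 bases sitting at the read's 3' end), HEADCROP,
#' LEADING (strip 5' bases with quality below `leading_q`), TRAILING
#' (strip 3' bases below `trailing_q`), SLIDINGWINDOW (scan 5' to 3'; at
#' the first window of `window_len` bases whose mean quality falls below
#' `window_q`, cut the read at the window start, then trim trailing bases
#' below `window_q`), and finally MINLEN (discard the read if shorter).
#' Headcrop precedes the quality steps so that MINLEN is the last gate, as
#' in a single trimming command where every operator applies to one read.
#'
#' The adapter clip deliberately replaces seed-and-extend/palindrome
#' matching with exact substring semantics; see the package vignette.
#'
#' @param sequence Nucleotide string.
#' @param qualities Integer vector of Phred scores, or a Phred+33 string.
#' @param params A [trim_params()] object.
#' @return List with `sequence` and `qualities` (integer vector) of the
#'   surviving read, or `NULL` if the read is discarded.
#' @export
quality_trim <- function(sequence, qualities, params = trim_params()) {
  stopifnot(inherits(params, "trim_params"))
  if (is.character(qualities) && length(qualities) == 1L) {
    qualities <- phred_scores(qualities)[[1]]
  }
  qualities <- as.integer(qualities)
  n <- nchar(sequence)
  if (length(qualities) != n) {
    stop("sequence and qualities lengths differ (", n, " vs ",
         length(qualities), ")")
  }
  # adapter clip: keep bases strictly before the adapter start
  cut <- n + 1L
  for (ad in params$adapter_sequences) {
    hit <- regexpr(ad, sequence, fixed = TRUE)
    if (hit > 0L && hit < cut) cut <- as.integer(hit)
    # 3'-terminal partial adapter: read suffix equals an adapter prefix >=10
    max_ov <- min(nchar(ad), n)
    if (max_ov >= 10L) {
      for (ov in max_ov:10L) {
        if (substring(sequence, n - ov + 1L, n) == substring(ad, 1L, ov)) {
          if (n - ov + 1L < cut) cut <- n - ov + 1L
          break
        }
      }
    }
  }
  if (cut <= n) {
    sequence <- substring(sequence, 1L, cut - 1L)
    qualities <- qualities[seq_len(cut - 1L)]
    n <- cut - 1L
  }
  # headcrop
  if (params$headcrop > 0L) {
    if (params$headcrop >= n) return(trim_check(NULL, params))
    sequence <- substring(sequence, params$headcrop + 1L, n)
    qualities <- qualities[(params$headcrop + 1L):n]
    n <- n - params$headcrop
  }
  # leading
  keep_from <- 1L
  while (keep_from <= n && qualities[keep_from] < params$leading_q) {
    keep_from <- keep_from + 1L
  }
  # trailing
  keep_to <- n
  while (keep_to >= keep_from && qualities[keep_to] < params$trailing_q) {
    keep_to <- keep_to - 1L
  }
  if (keep_from > keep_to) return(trim_check(NULL, params))
  sequence <- substring(sequence, keep_from, keep_to)
  qualities <- qualities[keep_from:keep_to]
  n <- keep_to - keep_from + 1L
  # sliding window
  if (n >= params$window_len) {
    for (start in seq_len(n - params$window_len + 1L)) {
      win <- qualities[start:(start + params$window_len - 1L)]
      if (mean(win) < params$window_q) {
        n <- start - 1L
        if (n == 0L) return(trim_check(NULL, params))
        sequence <- substring(sequence, 1L, n)
        qualities <- qualities[seq_len(n)]
        # trim trailing bases below the window threshold
        while (n >= 1L && qualities[n] < params$window_q) n <- n - 1L
        if (n == 0L) return(trim_check(NULL, params))
        sequence <- substring(sequence, 1L, n)
        qualities <- qualities[seq_len(n)]
        break
      }
    }
  }
  trim_check(list(sequence = sequence, qualities = qualities), params)
}

#' @keywords internal
trim_check <- function(res, params) {
  if (is.null(res) || nchar(res$sequence) < params$min_len) NULL else res
}

#' Select candidate reads for bacterial quantification
#'
#' For the gene-expression (`"gex"`) library, a candidate read is
#' host-unmapped, carries a whitelisted cell barcode and a UMI, and is a
#' primary alignment. For the 16S-enrichment (`"amplicon"`) library the
#' host-mapping status is ignored (the library is 16S-targeted, so host
#' mapping there is incidental); the barcode/UMI/primary requirements are
#' the same. Filtered reads are tallied per drop reason.
#'
#' @param alignments `data.frame` from [read_tagged_alignments()].
#' @param whitelist Barcode whitelist (character vector); matched verbatim.
#' @param library `"gex"` or `"amplicon"`.
#' @return List with `candidates` (`data.frame`: `read_name`,
#'   `cell_barcode`, `umi`, `library`, plus `sequence`/`qualities` when
#'   present in the input) and `drop_summary` (named integer vector over
#'   reasons `secondary`, `host_mapped`, `barcode`, `umi`, `kept`).
#' @export
extract_candidates <- function(alignments, whitelist,
                               library = c("gex", "amplicon")) {
  library <- match.arg(library)
  aln <- alignments
  n <- nrow(aln)
  reason <- rep("kept", n)
  sec <- aln$is_secondary_or_supplementary
  reason[sec] <- "secondary"
  if (library == "gex") {
    host <- reason == "kept" & aln$is_host_mapped
    reason[host] <- "host_mapped"
  }
  bad_cb <- reason == "kept" &
    (is.na(aln$cell_barcode) | !(aln$cell_barcode %in% whitelist))
  reason[bad_cb] <- "barcode"
  bad_umi <- reason == "kept" & (is.na(aln$umi) | !nzchar(aln$umi))
  reason[bad_umi] <- "umi"
  keep <- reason == "kept"
  cols <- intersect(c("read_name", "cell_barcode", "umi",
                      "sequence", "qualities"), names(aln))
  cand <- aln[keep, cols, drop = FALSE]
  cand$library <- rep(library, nrow(cand))
  rownames(cand) <- NULL
  summary <- vapply(c("secondary", "host_mapped", "barcode", "umi", "kept"),
                    function(r) sum(reason == r), integer(1))
  list(candidates = cand, drop_summary = summary)
}

#' Accumulate the genus x cell UMI matrix from classified candidates
#'
#' Every candidate read with a genus call other than `"unassigned"`
#' contributes its UMI to the set for `(sample_barcode, genus)`; counts are
#' the distinct-UMI cardinalities, so read duplicates of one molecule are
#' counted once. Cell ids are `sample` and barcode joined by an
#' underscore, matching the naming used when samples are merged into one
#' expression object. Candidates without any classification are ignored;
#' candidates classified `"unassigned"` appear in the read-level
#' annotation (for auditing) but never in the matrix.
#'
#' @param candidates `data.frame` from [extract_candidates()].
#' @param genus_calls Named character vector, read name to genus or
#'   `"unassigned"` (a subset of candidate read names).
#' @param sample Sample name used to prefix cell ids.
#' @return List with `matrix` (a `genus_cell_matrix`), `validation`
#'   (`data.frame`: `cell_id`, `genus`, `umi_count`,
#'   `is_bacteria_associated`, one row per nonzero cell/genus) and
#'   `annotation` (`data.frame`: one row per classified candidate with
#'   `read_name`, `cell_barcode`, `umi`, `genus`, `library`).
#' @export
build_umi_matrix <- function(candidates, genus_calls, sample) {
  cand <- candidates[candidates$read_name %in% names(genus_calls), ,
                     drop = FALSE]
  genus <- unname(genus_calls[cand$read_name])
  annotation <- data.frame(
    read_name = cand$read_name,
    cell_barcode = cand$cell_barcode,
    umi = cand$umi,
    genus = genus,
    library = if (nrow(cand)) cand$library else character(),
    stringsAsFactors = FALSE)
  assigned <- annotation[annotation$genus != "unassigned", , drop = FALSE]
  m <- genus_cell_matrix(data.frame(
    cell_id = if (nrow(assigned)) paste0(sample, "_", assigned$cell_barcode)
              else character(),
    genus = assigned$genus,
    umi = assigned$umi,
    source = if (nrow(assigned)) assigned$library else character(),
    stringsAsFactors = FALSE))
  validation <- validation_records(m)
  list(matrix = m, validation = validation, annotation = annotation)
}

#' Per-cell per-genus validation records of a matrix
#'
#' One row per nonzero (cell, genus) with its distinct-UMI count and the
#' bacteria-associated flag (count >= 1).
#'
#' @param m A `genus_cell_matrix`.
#' @return `data.frame` with `cell_id`, `genus`, `umi_count`,
#'   `is_bacteria_associated`.
#' @export
validation_records <- function(m) {
  stopifnot(inherits(m, "genus_cell_matrix"))
  if (nrow(m$umis) == 0L) {
    return(data.frame(cell_id = character(), genus = character(),
                      umi_count = integer(),
                      is_bacteria_associated = logical()))
  }
  agg <- stats::aggregate(list(umi_count = m$umis$umi),
                          by = list(cell_id = m$umis$cell_id,
                                    genus = m$umis$genus),
                          FUN = function(u) length(unique(u)))
  agg <- agg[order(agg$cell_id, agg$genus), , drop = FALSE]
  rownames(agg) <- NULL
  agg$umi_count <- as.integer(agg$umi_count)
  agg$is_bacteria_associated <- agg$umi_count >= 1L
  agg
}

#' Sequencing read budget
#'
#' Total reads required for an experiment: number of cells times target
#' reads per cell (e.g. 4,000 cells at 20,000 reads per cell require 80
#' million reads).
#'
#' @param n_cells Number of cells captured.
#' @param reads_per_cell Target reads per cell.
#' @return Total read count (numeric, exact for integer inputs).
#' @export
read_budget <- function(n_cells, reads_per_cell) {
  if (n_cells < 0 || reads_per_cell < 0) {
    stop("read budget inputs must be non-negative")
  }
  as.numeric(n_cells) * as.numeric(reads_per_cell)
}

#' Quantify one library end to end
#'
#' Convenience wrapper joining the pieces for a single sample/library:
#' read the tagged alignments, select candidates, (for the amplicon
#' library) quality-trim the candidate sequences and drop reads whose
#' trimmed Read 1 would not have reached the classifier, join with the
#' genus calls derived from the classifier hits, and build the matrix.
#'
#' @param alignment_path Barcode/UMI-tagged SAM/BAM.
#' @param whitelist Barcode whitelist (from the GEX library's filtered
#'   barcodes, for both libraries).
#' @param hits `data.frame` of per-read classifier hits
#'   (from [read_taxonomic_hits()]).
#' @param taxonomy A `taxonomy_table`.
#' @param sample Sample name.
#' @param library `"gex"` or `"amplicon"`.
#' @param trim `trim_params` for the amplicon path, or `NULL` to skip
#'   trimming.
#' @param cb_tag,umi_tag Alignment tag keys.
#' @return As [build_umi_matrix()], plus `drop_summary` and `n_trimmed_out`
#'   (number of candidates whose read failed trimming).
#' @export
quantify_library <- function(alignment_path, whitelist, hits, taxonomy,
                             sample, library = c("gex", "amplicon"),
                             trim = if (library[1] == "amplicon") trim_params() else NULL,
                             cb_tag = "CB", umi_tag = "UB") {
  library <- match.arg(library)
  aln <- read_tagged_alignments(alignment_path, cb_tag = cb_tag,
                                umi_tag = umi_tag)
  ext <- extract_candidates(aln, whitelist, library)
  cand <- ext$candidates
  n_trimmed_out <- 0L
  if (!is.null(trim) && nrow(cand) > 0L && "sequence" %in% names(cand)) {
    ok <- vapply(seq_len(nrow(cand)), function(i) {
      !is.null(quality_trim(cand$sequence[i], cand$qualities[i], trim))
    }, logical(1))
    n_trimmed_out <- sum(!ok)
    cand <- cand[ok, , drop = FALSE]
  }
  calls <- genus_calls(hits, taxonomy)
  res <- build_umi_matrix(cand, calls, sample)
  res$drop_summary <- ext$drop_summary
  res$n_trimmed_out <- n_trimmed_out
  res
}
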