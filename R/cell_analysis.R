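# Bacteria-status-conditioned host transcriptome analysis: attach per-cell
# bacterial metadata to the expression cells, classify cells by a UMI
# threshold, Wilcoxon differential expression with BH correction, and
# preranked gene-set enrichment.

#' Attach bacterial metadata to expression-matrix cells
#'
#' Joins the merged bacteria UMI matrix onto the cells of the host
#' expression object. Every expression cell receives an annotation;
#' cells absent from the merged matrix get all-zero counts (missing
#' becomes zero, never `NA`). Matrix cells absent from the expression
#' data are dropped, with the dropped count reported.
#'
#' @param cell_ids Character vector of expression-matrix cell ids
#'   (`sample_barcode` convention).
#' @param merged A `genus_cell_matrix` (typically from [merge_matrices()]).
#' @return `data.frame` with `cell_id`, one integer column per genus, and
#'   `Total` (the row sum). Attribute `n_dropped` carries the number of
#'   matrix cells not present in the expression data.
#' @export
attach_bacteria_metadata <- function(cell_ids, merged) {
  stopifnot(inherits(merged, "genus_cell_matrix"))
  cell_ids <- as.character(cell_ids)
  if (length(cell_ids) == 0L) stop("no expression cells to annotate")
  overlap <- intersect(cell_ids, merged$cell_ids)
  if (length(merged$cell_ids) > 0L && length(overlap) == 0L) {
    stop("no overlap between expression cells and bacteria matrix cells; ",
         "check the sample_barcode naming convention")
  }
  cnt <- umi_counts(merged, cell_ids = cell_ids)
  out <- data.frame(cell_id = cell_ids, cnt, check.names = FALSE,
                    stringsAsFactors = FALSE, row.names = NULL)
  out$Total <- as.integer(rowSums(cnt))
  attr(out, "n_dropped") <- length(setdiff(merged$cell_ids, cell_ids))
  out
}

#' Classify cells by bacterial UMI load
#'
#' Three-way grouping per cell: `"Positive"` when the chosen taxon's UMI
#' count is at least `pos_threshold`; `"Negative"` when the cell carries
#' no bacterial UMIs at all (`Total == 0`); otherwise `NA` (cells with
#' low, sub-threshold loads are excluded from comparisons). The protocol's
#' executable predicate is `>= threshold` with an example threshold of 4,
#' so the boundary count itself is Positive.
#'
#' @param annotations `data.frame` from [attach_bacteria_metadata()].
#' @param taxon Genus name, or `"Total"` for kingdom-level (any-bacteria)
#'   grouping.
#' @param pos_threshold Integer >= 1.
#' @return Character vector of labels (`"Positive"`, `"Negative"`, `NA`),
#'   named by cell id.
#' @export
classify_cells <- function(annotations, taxon = "Total", pos_threshold = 4L) {
  if (pos_threshold < 1L) stop("pos_threshold must be >= 1")
  if (!taxon %in% names(annotations)) {
    stop("taxon '", taxon, "' not present in annotations")
  }
  cnt <- annotations[[taxon]]
  lab <- ifelse(annotations$Total == 0L, "Negative",
                ifelse(cnt >= pos_threshold, "Positive", NA_character_))
  stats::setNames(lab, annotations$cell_id)
}

#' Library-size normalisation of expression counts
#'
#' `log1p` of counts scaled to a fixed total per cell (default scale
#' factor 10,000), the standard log-normalisation the protocol applies
#' before differential expression.
#'
#' @param counts Gene x cell count matrix (dense or sparse).
#' @param scale_factor Per-cell total after scaling.
#' @return Matrix of normalised expression, same dimensions.
#' @export
normalize_expression <- function(counts, scale_factor = 1e4) {
  lib <- Matrix::colSums(counts)
  lib[lib == 0] <- 1
  log1p(Matrix::t(Matrix::t(counts) / lib) * scale_factor)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Standard step-up false-discovery-rate control; the mapping back to
#' input positions is order-preserving.
#'
#' @param p_values Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted p-values, same order as the input.
#' @export
bh_adjust <- function(p_values) {
  if (any(is.na(p_values)) || any(p_values < 0 | p_values > 1)) {
    stop("p-values must lie in [0, 1]")
  }
  stats::p.adjust(p_values, method = "BH")
}

#' Differential expression between bacteria-positive and -negative cells
#'
#' Two-sided Wilcoxon rank-sum test per gene on normalised expression
#' between the `"Positive"` and `"Negative"` groups; `NA`-labelled cells
#' are excluded. A gene is tested when it is detected (expression > 0) in
#' at least `min_pct` of the cells of at least one group. The log2 fold
#' change is `log2((mean(expm1(x_pos)) + 1) / (mean(expm1(x_neg)) + 1))`,
#' i.e. the back-transformed normalised means with pseudocount 1. BH
#' adjustment is applied over the tested genes.
#'
#' @param expression Normalised gene x cell matrix
#'   (from [normalize_expression()]).
#' @param labels Character vector of group labels per cell
#'   (`"Positive"`/`"Negative"`/`NA`), aligned with `colnames(expression)`
#'   or in column order.
#' @param min_pct Minimum detection fraction (default 0.1).
#' @return `data.frame` with `gene`, `log2_fold_change`, `p_value`,
#'   `p_adjusted`, `pct_pos`, `pct_neg`, ordered by decreasing
#'   `log2_fold_change`.
#' @export
differential_expression <- function(expression, labels, min_pct = 0.1) {
  if (!is.null(names(labels)) && !is.null(colnames(expression))) {
    labels <- labels[colnames(expression)]
  }
  if (length(labels) != ncol(expression)) {
    stop("labels length must match the number of cells")
  }
  pos <- which(!is.na(labels) & labels == "Positive")
  neg <- which(!is.na(labels) & labels == "Negative")
  if (length(pos) < 2L || length(neg) < 2L) {
    stop("need at least 2 cells in each of Positive (", length(pos),
         ") and Negative (", length(neg), ")")
  }
  X <- as.matrix(expression)
  xp <- X[, pos, drop = FALSE]
  xn <- X[, neg, drop = FALSE]
  pct_pos <- rowMeans(xp > 0)
  pct_neg <- rowMeans(xn > 0)
  test <- pct_pos >= min_pct | pct_neg >= min_pct
  genes <- rownames(X)
  if (is.null(genes)) genes <- as.character(seq_len(nrow(X)))
  idx <- which(test)
  pv <- vapply(idx, function(i) {
    a <- xp[i, ]
    b <- xn[i, ]
    if (all(a == a[1]) && all(b == b[1]) && a[1] == b[1]) return(1)
    # ties force the normal approximation; that is expected with counts
    withCallingHandlers(
      stats::wilcox.test(a, b, alternative = "two.sided")$p.value,
      warning = function(w) {
        if (grepl("exact p-value", conditionMessage(w))) {
          invokeRestart("muffleWarning")
        }
      })
  }, numeric(1))
  lfc <- log2((rowMeans(expm1(xp[idx, , drop = FALSE])) + 1) /
                (rowMeans(expm1(xn[idx, , drop = FALSE])) + 1))
  out <- data.frame(gene = genes[idx],
                    log2_fold_change = unname(lfc),
                    p_value = unname(pv),
                    p_adjusted = bh_adjust(unname(pv)),
                    pct_pos = unname(pct_pos[idx]),
                    pct_neg = unname(pct_neg[idx]),
                    stringsAsFactors = FALSE)
  out[order(-out$log2_fold_change), , drop = FALSE]
}

#' Volcano-plot reporting table
#'
#' Flags differential-expression results at the conventional volcano
#' cutoffs: absolute log2 fold change at least `lfc_cut` (default 0.58,
#' i.e. 1.5-fold) and `-log10(p)` at least `neglog10p_cut` (default
#' 1.301, i.e. p <= 0.05). These are reporting thresholds only; they do
#' not affect testing.
#'
#' @param de `data.frame` from [differential_expression()].
#' @param lfc_cut,neglog10p_cut Significance cutoffs.
#' @param use_adjusted Flag on adjusted (default) or raw p-values.
#' @return `de` with added `neg_log10_p` and logical `significant`.
#' @export
volcano_table <- function(de, lfc_cut = 0.58, neglog10p_cut = 1.301,
                          use_adjusted = TRUE) {
  p <- if (use_adjusted) de$p_adjusted else de$p_value
  de$neg_log10_p <- -log10(p)
  de$significant <- abs(de$log2_fold_change) >= lfc_cut &
    de$neg_log10_p >= neglog10p_cut
  de
}

#' Preranked gene-set enrichment analysis
#'
#' Weighted Kolmogorov-Smirnov running-sum statistic on a gene ranking
#' (typically genes ordered by decreasing average log2 fold change).
#' Hits advance the running sum proportionally to `|ranking value|`
#' (weight exponent 1), misses retreat it by `1 / (n - n_hits)`; the
#' enrichment score (ES) is the signed maximum deviation from zero (a
#' magnitude tie between the extremes takes its sign from the net
#' running-sum area, keeping ES antisymmetric under ranking reversal). The
#' null is built by shuffling the gene labels `n_perm` times; the
#' normalised enrichment score (NES) divides ES by the mean `|null ES|`
#' of matching sign, and the permutation p-value is computed within the
#' matching-sign null with a +1 continuity correction.
#'
#' @param ranking Named numeric vector: values (e.g. log2 fold changes)
#'   named by gene, sorted in decreasing order (re-sorted if not).
#' @param sets Named list of gene vectors (a `gene_set_collection`).
#' @param n_perm Number of label permutations (default 1000).
#' @param seed Random seed for the permutation null (required).
#' @return `data.frame` with `set_name`, `size` (genes in the ranking),
#'   `enrichment_score`, `normalized_enrichment_score`, `p_value` and
#'   `leading_edge` (slash-joined genes). Sets disjoint from the ranking
#'   are reported with `NA` statistics rather than raising an error.
#' @export
preranked_gsea <- function(ranking, sets, n_perm = 1000L, seed) {
  if (missing(seed)) stop("a seed is required for the permutation null")
  if (is.null(names(ranking)) || !all(nzchar(names(ranking)))) {
    stop("ranking must be named by gene")
  }
  if (!all(is.finite(ranking))) stop("ranking values must be finite")
  ranking <- sort(ranking, decreasing = TRUE)
  genes <- names(ranking)
  rows <- lapply(names(sets), function(nm) {
    hit <- genes %in% sets[[nm]]
    size <- sum(hit)
    if (size == 0L) {
      return(data.frame(set_name = nm, size = 0L,
                        enrichment_score = NA_real_,
                        normalized_enrichment_score = NA_real_,
                        p_value = NA_real_, leading_edge = NA_character_,
                        stringsAsFactors = FALSE))
    }
    obs <- gsea_running_sum(ranking, hit)
    null_es <- gsea_null(ranking, size, n_perm,
                         seed = seed + match(nm, names(sets)) - 1L)
    matching <- null_es[sign(null_es) == sign(obs$es) | obs$es == 0]
    if (length(matching) == 0L) matching <- abs(null_es)
    nes <- obs$es / mean(abs(matching))
    p <- (1 + sum(abs(matching) >= abs(obs$es))) / (1 + length(matching))
    le <- gsea_leading_edge(ranking, hit, obs)
    data.frame(set_name = nm, size = size, enrichment_score = obs$es,
               normalized_enrichment_score = nes, p_value = p,
               leading_edge = paste(le, collapse = "/"),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Weighted KS running sum and its extremum
#' @keywords internal
gsea_running_sum <- function(ranking, hit) {
  n <- length(ranking)
  w <- abs(ranking)
  denom_hit <- sum(w[hit])
  if (denom_hit == 0) denom_hit <- 1  # all-zero weights: degenerate, flat hits
  n_miss <- n - sum(hit)
  step <- ifelse(hit, w / denom_hit,
                 if (n_miss > 0) -1 / n_miss else 0)
  rs <- cumsum(step)
  i_max <- which.max(rs)
  i_min <- which.min(rs)
  # signed maximum deviation; a magnitude tie (to numerical tolerance)
  # takes its sign from the net running-sum area, which keeps ES
  # antisymmetric under ranking reversal
  hi <- rs[i_max]
  lo <- rs[i_min]
  tol <- 1e-9 * max(1, abs(hi), abs(lo))
  es <- if (abs(hi) - abs(lo) > tol) hi
        else if (abs(lo) - abs(hi) > tol) lo
        else if (sum(rs) >= 0) hi else lo
  list(es = es, running = rs, i_max = i_max, i_min = i_min)
}

#' Permutation null ES by shuffling gene labels
#' @keywords internal
gsea_null <- function(ranking, size, n_perm, seed) {
  n <- length(ranking)
  set.seed(seed)
  vapply(seq_len(n_perm), function(b) {
    hit <- logical(n)
    hit[sample.int(n, size)] <- TRUE
    gsea_running_sum(ranking, hit)$es
  }, numeric(1))
}

#' Leading-edge genes of one set
#' @keywords internal
gsea_leading_edge <- function(ranking, hit, obs) {
  genes <- names(ranking)
  if (obs$es >= 0) {
    genes[hit & seq_along(genes) <= obs$i_max]
  } else {
    genes[hit & seq_along(genes) >= obs$i_min]
  }
}
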