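# Synthetic end-to-end fixtures with known ground truth, emulating the
# designs used to validate per-cell bacterial detection: dose-dependent
# infection (varying infected fraction as a proxy for MOI), nonadherent
# negative-control taxa that shed only ambient reads, and contaminant
# genera. The classifier is emulated by writing per-read hits directly;
# no sequence-based classification takes place.

#' Per-taxon simulation parameters
#'
#' @param genus Genus name.
#' @param infected_fraction Fraction of cells truly carrying this taxon.
#' @param mu,size Negative-binomial mean and dispersion (size) of the
#'   per-infected-cell distinct-UMI load. The negative binomial reflects
#'   the heavy-tailed loads seen in practice: a few cells with very many
#'   bacterial transcripts, most with one or none.
#' @param ambient_rate Expected number of ambient reads (reads carrying no
#'   valid cell barcode) for this taxon per dataset; a nonadherent
#'   negative-control taxon has `infected_fraction = 0` and a positive
#'   ambient rate.
#' @param contaminant Logical; marks the taxon as a simulated contaminant
#'   (recorded in truth tables so denylisting can be evaluated).
#' @return One-row `data.frame`.
#' @export
taxon_params <- function(genus, infected_fraction = 0.2, mu = 5, size = 0.3,
                         ambient_rate = 0, contaminant = FALSE) {
  stopifnot(infected_fraction >= 0, infected_fraction <= 1,
            mu >= 0, size > 0, ambient_rate >= 0)
  data.frame(genus = genus, infected_fraction = infected_fraction,
             mu = mu, size = size, ambient_rate = ambient_rate,
             contaminant = contaminant, stringsAsFactors = FALSE)
}

#' Simulation configuration
#'
#' The stated world of the generator. Defaults describe a desk-scale
#' droplet experiment: 200 cells, 16-base cell barcodes with the usual
#' `-1` suffix, 12-base UMIs, one adherent genus infecting 20% of cells
#' with a heavy-tailed negative-binomial UMI load, 50% read duplication,
#' and a 100-gene host expression matrix with 10 two-fold induced genes in
#' truly bacteria-positive cells.
#'
#' @param n_cells Number of whitelisted cells.
#' @param barcode_length,umi_length Barcode and UMI lengths in bases.
#' @param taxa `data.frame` of per-taxon parameters, one row per genus
#'   (see [taxon_params()]).
#' @param duplication_rate Probability parameter of the geometric number
#'   of extra reads per UMI (0 = every molecule sequenced once).
#' @param misassignment_prob Probability that a read's classifier hit also
#'   contains a species from a different genus, making the read
#'   genus-discordant (hence "unassigned").
#' @param n_genes,n_signal_genes Host genes simulated, and how many of
#'   them respond to bacterial presence.
#' @param signal_log2fc Configured log2 fold change of the signal genes in
#'   truly infected cells.
#' @param n_host_reads Host-mapped GEX reads (exercise the host filter).
#' @param seed Random seed (mandatory; same seed, same bytes).
#' @return Object of class `simulation_config`.
#' @export
simulation_config <- function(n_cells = 200L, barcode_length = 16L,
                              umi_length = 12L,
                              taxa = taxon_params("Fusobacterium"),
                              duplication_rate = 0.5,
                              misassignment_prob = 0,
                              n_genes = 100L, n_signal_genes = 10L,
                              signal_log2fc = 1.0,
                              n_host_reads = 500L, seed) {
  if (missing(seed)) stop("seed is mandatory")
  if (n_cells <= 0L) stop("degenerate config: n_cells must be positive")
  stopifnot(duplication_rate >= 0, duplication_rate < 1,
            misassignment_prob >= 0, misassignment_prob <= 1,
            all(taxa$infected_fraction >= 0 & taxa$infected_fraction <= 1))
  structure(list(n_cells = as.integer(n_cells),
                 barcode_length = as.integer(barcode_length),
                 umi_length = as.integer(umi_length),
                 taxa = taxa, duplication_rate = duplication_rate,
                 misassignment_prob = misassignment_prob,
                 n_genes = as.integer(n_genes),
                 n_signal_genes = as.integer(n_signal_genes),
                 signal_log2fc = signal_log2fc,
                 n_host_reads = as.integer(n_host_reads),
                 seed = as.integer(seed)),
            class = "simulation_config")
}

random_seqs <- function(n, len) {
  if (n == 0L) return(character())
  vapply(seq_len(n), function(i) {
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
  }, character(1))
}

#' Build the synthetic taxonomy table for a set of genera
#'
#' Each genus gets a genus-level entry and two species; one extra
#' family-level entry with no genus rank exercises the unassignable path.
#'
#' @param genera Character vector of genus names.
#' @return List with `table` (a `taxonomy_table`), `species_ids` (named
#'   list of the two species ids per genus) and `csv` rows ready to write.
#' @keywords internal
synthetic_taxonomy <- function(genera) {
  base <- data.frame(rank = c("kingdom", "phylum", "class", "order", "family"),
                     name = c("Bacteria", "SimPhylum", "SimClass",
                              "SimOrder", "SimFamily"),
                     stringsAsFactors = FALSE)
  ids <- integer(); nms <- character(); rks <- character(); lins <- list()
  species_ids <- list()
  next_id <- 100L
  for (g in genera) {
    glin <- rbind(base, data.frame(rank = "genus", name = g))
    ids <- c(ids, next_id); nms <- c(nms, g); rks <- c(rks, "genus")
    lins <- c(lins, list(glin))
    sp <- integer()
    for (k in 1:2) {
      next_id <- next_id + 1L
      snm <- paste0(g, "_sp", k)
      ids <- c(ids, next_id); nms <- c(nms, snm); rks <- c(rks, "species")
      lins <- c(lins, list(rbind(glin, data.frame(rank = "species",
                                                  name = snm))))
      sp <- c(sp, next_id)
    }
    species_ids[[g]] <- sp
    next_id <- next_id + 98L  # space ids out per genus
  }
  # family-level entry without a genus rank
  ids <- c(ids, 99L); nms <- c(nms, "SimFamily"); rks <- c(rks, "family")
  lins <- c(lins, list(base))
  tab <- taxonomy_table(ids, nms, rks, lins)
  csv <- data.frame(tax_id = ids, name = nms, type = rks,
                    taxonomy = vapply(lins, format_lineage_string,
                                      character(1)),
                    stringsAsFactors = FALSE)
  list(table = tab, species_ids = species_ids, csv = csv)
}

#' Simulate a complete dataset with known ground truth
#'
#' Generates, under one seed: a cell-barcode whitelist; barcode/UMI-tagged
#' GEX and 16S-amplicon alignment files (each bacterial molecule's reads
#' split between the two libraries, so the merge step has real overlap to
#' deduplicate); taxonomy-annotated classifier hits and the scores-CSV
#' taxonomy table; a host expression matrix with configured fold changes
#' between truly infected and uninfected cells; and truth tables with the
#' per-cell per-genus distinct-UMI counts and group memberships.
#'
#' Ambient reads (nonadherent taxa, or shedding) carry either no cell
#' barcode or a random barcode outside the whitelist, so they reach the
#' classifier but can never contribute cell-associated UMIs.
#'
#' @param config A [simulation_config()].
#' @param dir Output directory (created); all files are written here.
#' @return List of paths (`whitelist`, `gex_alignments`,
#'   `amplicon_alignments`, `gex_hits`, `amplicon_hits`, `taxonomy_csv`,
#'   `expression_dir`, `truth_counts`, `truth_cells`) plus in-memory
#'   `truth` (list with `counts`, `cells`, `signal_genes`), the taxonomy
#'   table, and `config`.
#' @export
simulate_dataset <- function(config, dir = tempfile("simdata")) {
  stopifnot(inherits(config, "simulation_config"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  set.seed(config$seed)
  n <- config$n_cells
  barcodes <- unique(random_seqs(2L * n, config$barcode_length))[seq_len(n)]
  barcodes <- paste0(barcodes, "-1")
  whitelist_path <- file.path(dir, "barcodes.tsv.gz")
  write_barcode_whitelist(barcodes, whitelist_path)

  tax <- synthetic_taxonomy(config$taxa$genus)
  taxonomy_csv <- file.path(dir, "taxonomy_scores.csv")
  utils::write.csv(tax$csv, taxonomy_csv, row.names = FALSE, quote = FALSE)
  other_species <- function(g) {
    pool <- unlist(tax$species_ids[setdiff(names(tax$species_ids), g)])
    if (length(pool) == 0L) tax$species_ids[[g]][1] else pool
  }

  # --- bacterial molecules ------------------------------------------------
  reads <- list()   # rows destined for the alignment files
  read_i <- 0L
  truth_counts <- list()
  infected <- matrix(FALSE, nrow = n, ncol = nrow(config$taxa),
                     dimnames = list(barcodes, config$taxa$genus))
  for (t in seq_len(nrow(config$taxa))) {
    tp <- config$taxa[t, ]
    inf <- stats::runif(n) < tp$infected_fraction
    loads <- integer(n)
    loads[inf] <- stats::rnbinom(sum(inf), mu = tp$mu, size = tp$size)
    infected[, t] <- inf & loads > 0L
    for (ci in which(loads > 0L)) {
      umis <- unique(random_seqs(loads[ci], config$umi_length))
      truth_counts[[length(truth_counts) + 1L]] <-
        data.frame(barcode = barcodes[ci], genus = tp$genus,
                   true_umi_count = length(umis), stringsAsFactors = FALSE)
      for (u in umis) {
        n_reads <- 1L + stats::rgeom(1L, prob = 1 - config$duplication_rate)
        for (r in seq_len(n_reads)) {
          read_i <- read_i + 1L
          hit <- sample(tax$species_ids[[tp$genus]],
                        size = sample(1:2, 1L))
          if (stats::runif(1) < config$misassignment_prob) {
            hit <- c(hit, sample(other_species(tp$genus), 1L))
          }
          reads[[read_i]] <- data.frame(
            read_name = sprintf("bac%07d", read_i),
            cell_barcode = barcodes[ci], umi = u,
            taxon_ids = paste(sort(hit), collapse = ","),
            library = sample(c("gex", "amplicon"), 1L),
            ambient = FALSE, stringsAsFactors = FALSE)
        }
      }
    }
  }
  # --- ambient reads: no valid barcode, classifier still sees them --------
  for (t in seq_len(nrow(config$taxa))) {
    tp <- config$taxa[t, ]
    n_amb <- stats::rpois(1L, tp$ambient_rate)
    for (a in seq_len(n_amb)) {
      read_i <- read_i + 1L
      no_cb <- stats::runif(1) < 0.5
      cb <- if (no_cb) NA_character_ else
        paste0(random_seqs(1L, config$barcode_length), "-0")
      reads[[read_i]] <- data.frame(
        read_name = sprintf("amb%07d", read_i),
        cell_barcode = cb,
        umi = random_seqs(1L, config$umi_length),
        taxon_ids = as.character(tax$species_ids[[tp$genus]][1]),
        library = sample(c("gex", "amplicon"), 1L),
        ambient = TRUE, stringsAsFactors = FALSE)
    }
  }
  reads <- if (read_i > 0L) do.call(rbind, reads) else
    data.frame(read_name = character(), cell_barcode = character(),
               umi = character(), taxon_ids = character(),
               library = character(), ambient = logical())

  # --- alignment records --------------------------------------------------
  mk_seq <- function(k, len) random_seqs(k, len)
  write_lib <- function(lib) {
    sel <- reads[reads$library == lib, , drop = FALSE]
    # amplicon reads are long enough to survive headcrop 15 + minlen 36
    len <- if (lib == "amplicon") 90L else 60L
    nrec <- nrow(sel)
    rec <- data.frame(
      read_name = sel$read_name,
      is_host_mapped = rep(FALSE, nrec),
      is_secondary_or_supplementary = rep(FALSE, nrec),
      sequence = mk_seq(nrec, len),
      qualities = rep(phred_string(rep(37L, len)), nrec),
      cell_barcode = sel$cell_barcode,
      umi = sel$umi, stringsAsFactors = FALSE)
    if (lib == "gex" && config$n_host_reads > 0L) {
      nh <- config$n_host_reads
      host <- data.frame(
        read_name = sprintf("host%06d", seq_len(nh)),
        is_host_mapped = TRUE, is_secondary_or_supplementary = FALSE,
        sequence = mk_seq(nh, 60L),
        qualities = rep(phred_string(rep(37L, 60L)), nh),
        cell_barcode = sample(barcodes, nh, replace = TRUE),
        umi = random_seqs(nh, config$umi_length),
        stringsAsFactors = FALSE)
      rec <- rbind(rec, host)
    }
    aln_path <- file.path(dir, paste0(lib, ".sam"))
    write_tagged_sam(rec, aln_path)
    # classifier hits for the same library's classified (bacterial) reads
    hits <- data.frame(
      read_name = sel$read_name,
      is_host_mapped = rep(FALSE, nrow(sel)),
      is_secondary_or_supplementary = rep(FALSE, nrow(sel)),
      sequence = mk_seq(nrow(sel), 40L),
      qualities = rep(phred_string(rep(37L, 40L)), nrow(sel)),
      taxon_ids = sel$taxon_ids, stringsAsFactors = FALSE)
    hit_path <- file.path(dir, paste0(lib, ".pathseq.sam"))
    write_tagged_sam(hits, hit_path)
    c(aln = aln_path, hits = hit_path)
  }
  gex_paths <- write_lib("gex")
  amp_paths <- write_lib("amplicon")

  # --- host expression ----------------------------------------------------
  any_infected <- rowSums(infected) > 0L
  expr <- simulate_expression_for_cells(
    cell_labels = ifelse(any_infected, "Positive", "Negative"),
    n_genes = config$n_genes, n_signal_genes = config$n_signal_genes,
    log2fc = config$signal_log2fc)
  colnames(expr$counts) <- barcodes
  expression_dir <- file.path(dir, "filtered_feature_bc_matrix")
  write_expression_matrix(expr$counts, expression_dir)

  truth_counts <- if (length(truth_counts)) do.call(rbind, truth_counts) else
    data.frame(barcode = character(), genus = character(),
               true_umi_count = integer())
  truth_cells <- data.frame(barcode = barcodes,
                            infected = any_infected,
                            stringsAsFactors = FALSE)
  for (g in config$taxa$genus) truth_cells[[g]] <- infected[, g]
  tc_path <- file.path(dir, "truth_counts.tsv")
  utils::write.table(truth_counts, tc_path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  cl_path <- file.path(dir, "truth_cells.tsv")
  utils::write.table(truth_cells, cl_path, sep = "\t", row.names = FALSE,
                     quote = FALSE)

  list(dir = dir, whitelist = whitelist_path,
       gex_alignments = unname(gex_paths["aln"]),
       amplicon_alignments = unname(amp_paths["aln"]),
       gex_hits = unname(gex_paths["hits"]),
       amplicon_hits = unname(amp_paths["hits"]),
       taxonomy_csv = taxonomy_csv, expression_dir = expression_dir,
       truth_counts = tc_path, truth_cells = cl_path,
       truth = list(counts = truth_counts, cells = truth_cells,
                    signal_genes = expr$signal_genes),
       taxonomy = tax$table, config = config)
}

#' Simulate host expression counts for labelled cells
#'
#' Poisson counts with lognormal gene base means; the first
#' `n_signal_genes` genes have their mean multiplied by `2^log2fc` in
#' cells labelled `"Positive"`.
#'
#' @param cell_labels Character vector (`"Positive"`/`"Negative"`) per cell.
#' @param n_genes,n_signal_genes Total and signal gene numbers.
#' @param log2fc Configured log2 fold change of signal genes.
#' @param base_meanlog,base_sdlog Lognormal parameters of gene base means.
#' @param signal_base_mean Fixed base mean of the signal genes (moderate
#'   expression so fold changes are estimable).
#' @return List with `counts` (gene x cell integer matrix) and
#'   `signal_genes` (character vector).
#' @export
simulate_expression_for_cells <- function(cell_labels, n_genes = 100L,
                                          n_signal_genes = 10L, log2fc = 1.0,
                                          base_meanlog = log(5),
                                          base_sdlog = 0.8,
                                          signal_base_mean = 5) {
  n_cells <- length(cell_labels)
  stopifnot(n_signal_genes <= n_genes)
  means <- stats::rlnorm(n_genes, base_meanlog, base_sdlog)
  genes <- sprintf("GENE%04d", seq_len(n_genes))
  signal <- character()
  if (n_signal_genes > 0L) {
    signal <- sprintf("SIG%03d", seq_len(n_signal_genes))
    genes[seq_len(n_signal_genes)] <- signal
    means[seq_len(n_signal_genes)] <- signal_base_mean
  }
  pos <- cell_labels == "Positive"
  mu <- matrix(means, nrow = n_genes, ncol = n_cells)
  if (n_signal_genes > 0L && any(pos)) {
    mu[seq_len(n_signal_genes), pos] <-
      mu[seq_len(n_signal_genes), pos] * 2^log2fc
  }
  counts <- matrix(stats::rpois(n_genes * n_cells, mu), nrow = n_genes,
                   dimnames = list(genes, NULL))
  list(counts = counts, signal_genes = signal)
}

#' Compare pipeline output with generator ground truth
#'
#' Reports: the exact-match fraction of per-(cell, genus) distinct-UMI
#' counts over the full cell x genus grid (1.0 whenever read duplication
#' is the only noise, since deduplication removes duplicates exactly);
#' sensitivity and specificity of bacteria-positive cell detection at a
#' UMI threshold; and, when a differential-expression table is supplied,
#' the mean estimated log2 fold change over the true signal genes and its
#' correlation with the configured effect.
#'
#' @param truth The `truth` element returned by [simulate_dataset()].
#' @param merged `genus_cell_matrix` produced by the pipeline. Cell ids
#'   may carry a `sample_` prefix, which is stripped for the comparison.
#' @param sample Sample prefix used in the pipeline cell ids.
#' @param threshold UMI threshold for positive-cell detection.
#' @param de Optional `data.frame` from [differential_expression()].
#' @param configured_log2fc Configured signal effect (for the DE block).
#' @return List with `exact_match_fraction`, `sensitivity`, `specificity`
#'   and optionally `mean_signal_log2fc`, `signal_recovery_error`.
#' @export
evaluate_recovery <- function(truth, merged, sample = "sample",
                              threshold = 1L, de = NULL,
                              configured_log2fc = NULL) {
  stopifnot(inherits(merged, "genus_cell_matrix"))
  cells <- truth$cells$barcode
  prefix <- paste0(sample, "_")
  obs_cells <- sub(paste0("^", prefix), "", merged$cell_ids)
  if (length(obs_cells) > 0L && length(setdiff(obs_cells, cells)) > 0L) {
    stop("pipeline matrix contains cells outside the truth universe")
  }
  genera <- sort(unique(c(truth$counts$genus, merged$genera)))
  true_cnt <- matrix(0L, length(cells), length(genera),
                     dimnames = list(cells, genera))
  if (nrow(truth$counts) > 0L) {
    true_cnt[cbind(truth$counts$barcode, truth$counts$genus)] <-
      truth$counts$true_umi_count
  }
  obs <- umi_counts(merged, cell_ids = paste0(prefix, cells),
                    genera = genera)
  rownames(obs) <- cells
  out <- list(
    exact_match_fraction = mean(true_cnt == obs),
    sensitivity = {
      tp <- rowSums(true_cnt) >= threshold
      if (any(tp)) mean(rowSums(obs)[tp] >= threshold) else NA_real_
    },
    specificity = {
      tn <- rowSums(true_cnt) < threshold
      if (any(tn)) mean(rowSums(obs)[tn] < threshold) else NA_real_
    })
  if (!is.null(de) && length(truth$signal_genes) > 0L) {
    sig <- de[de$gene %in% truth$signal_genes, , drop = FALSE]
    out$mean_signal_log2fc <- mean(sig$log2_fold_change)
    if (!is.null(configured_log2fc)) {
      out$signal_recovery_error <- out$mean_signal_log2fc - configured_log2fc
    }
  }
  out
}
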