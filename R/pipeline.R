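# File-driven stage runner. Stages communicate only via files, so any
# simulated input can be replaced by real upstream outputs (droplet
# aligner BAMs, classifier BAM + scores CSV) without code changes. A
# JSON-lines run log records parameters, seeds and per-stage record
# counts, because troubleshooting hinges on where reads are lost.

#' Build a run configuration
#'
#' @param sample Sample name (prefixes cell ids).
#' @param outdir Output directory.
#' @param gex_alignments,amplicon_alignments Tagged SAM/BAM paths.
#' @param gex_hits,amplicon_hits Taxonomy-annotated SAM/BAM paths.
#' @param taxonomy_csv Classifier scores CSV (lineage dialect).
#' @param whitelist Filtered barcode list from the GEX library.
#' @param expression_dir MTX triplet directory of the host matrix.
#' @param gene_sets Optional GMT path for the enrichment stage.
#' @param cb_tag,umi_tag,taxon_tag Alignment tag keys.
#' @param pos_threshold Positive-cell UMI threshold (default 4).
#' @param taxon Taxon used for cell classification (genus name or
#'   `"Total"`).
#' @param min_pct Minimum detection fraction for DE (default 0.1).
#' @param denylist Genus denylist (default empty; see
#'   [contaminant_denylist()] for the documented preset).
#' @param n_perm GSEA permutations.
#' @param seed Seed for all randomised steps.
#' @param trim `trim_params` for the amplicon path.
#' @return Object of class `run_config`.
#' @export
run_config <- function(sample, outdir,
                       gex_alignments = NULL, amplicon_alignments = NULL,
                       gex_hits = NULL, amplicon_hits = NULL,
                       taxonomy_csv = NULL, whitelist = NULL,
                       expression_dir = NULL, gene_sets = NULL,
                       cb_tag = "CB", umi_tag = "UB", taxon_tag = "YP",
                       pos_threshold = 4L, taxon = "Total", min_pct = 0.1,
                       denylist = character(), n_perm = 1000L, seed = 1L,
                       trim = trim_params()) {
  structure(list(sample = sample, outdir = outdir,
                 gex_alignments = gex_alignments,
                 amplicon_alignments = amplicon_alignments,
                 gex_hits = gex_hits, amplicon_hits = amplicon_hits,
                 taxonomy_csv = taxonomy_csv, whitelist = whitelist,
                 expression_dir = expression_dir, gene_sets = gene_sets,
                 cb_tag = cb_tag, umi_tag = umi_tag, taxon_tag = taxon_tag,
                 pos_threshold = as.integer(pos_threshold), taxon = taxon,
                 min_pct = min_pct, denylist = denylist,
                 n_perm = as.integer(n_perm), seed = as.integer(seed),
                 trim = trim),
            class = "run_config")
}

log_stage <- function(config, stage, ...) {
  entry <- c(list(time = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
                  stage = stage, sample = config$sample,
                  seed = config$seed), list(...))
  line <- jsonlite::toJSON(entry, auto_unbox = TRUE)
  cat(line, "\n", sep = "",
      file = file.path(config$outdir, "run_log.jsonl"), append = TRUE)
}

stage_outputs <- function(config, stage) {
  s <- config$sample
  o <- config$outdir
  switch(stage,
    "gex-quant" = file.path(o, paste0(s, c(".gex.genus.csv",
                                           ".gex.validate.csv"))),
    "amplicon-quant" = file.path(o, paste0(s, c(".16s.genus.csv",
                                                ".16s.validate.csv"))),
    "merge" = file.path(o, "csv_novami.csv"),
    "annotate" = file.path(o, paste0(s, ".cell_annotations.csv")),
    "analyze" = file.path(o, paste0(s, ".de_table.csv")),
    stop("unknown stage: ", stage))
}

require_inputs <- function(paths, stage, needed_stage) {
  missing <- paths[!vapply(paths, function(p)
    !is.null(p) && (file.exists(p) || dir.exists(p)), logical(1))]
  if (length(missing)) {
    stop("stage '", stage, "' is missing inputs (",
         paste(unlist(missing), collapse = ", "),
         "); run stage '", needed_stage, "' first or point the config ",
         "at existing files")
  }
}

quant_stage <- function(config, library) {
  lib_key <- if (library == "gex") "gex" else "16s"
  aln <- if (library == "gex") config$gex_alignments else
    config$amplicon_alignments
  hits_path <- if (library == "gex") config$gex_hits else config$amplicon_hits
  require_inputs(list(aln, hits_path, config$taxonomy_csv, config$whitelist),
                 paste0(library, "-quant"), "simulate")
  whitelist <- read_barcode_whitelist(config$whitelist)
  taxonomy <- read_taxonomy_table(config$taxonomy_csv)
  hits <- read_taxonomic_hits(hits_path, taxon_tag = config$taxon_tag)
  res <- quantify_library(aln, whitelist, hits, taxonomy,
                          sample = config$sample, library = library,
                          trim = if (library == "amplicon") config$trim else NULL,
                          cb_tag = config$cb_tag, umi_tag = config$umi_tag)
  s <- config$sample
  write_genus_matrix(res$matrix,
                     file.path(config$outdir,
                               paste0(s, ".", lib_key, ".genus.csv")))
  utils::write.csv(res$validation,
                   file.path(config$outdir,
                             paste0(s, ".", lib_key, ".validate.csv")),
                   row.names = FALSE, quote = FALSE)
  utils::write.table(res$annotation,
                     file.path(config$outdir,
                               paste0(s, ".", lib_key, ".read_annotation.tsv")),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  jsonlite::write_json(as.list(res$drop_summary),
                       file.path(config$outdir,
                                 paste0(s, ".", lib_key,
                                        ".drop_summary.json")),
                       auto_unbox = TRUE)
  log_stage(config, paste0(library, "-quant"),
            reads_kept = unname(res$drop_summary["kept"]),
            reads_dropped = sum(res$drop_summary) -
              unname(res$drop_summary["kept"]),
            trimmed_out = res$n_trimmed_out,
            cells = length(res$matrix$cell_ids),
            genera = length(res$matrix$genera))
  invisible(res)
}

merge_stage <- function(config) {
  s <- config$sample
  gex_csv <- file.path(config$outdir, paste0(s, ".gex.genus.csv"))
  amp_csv <- file.path(config$outdir, paste0(s, ".16s.genus.csv"))
  require_inputs(list(gex_csv), "merge", "gex-quant")
  require_inputs(list(amp_csv), "merge", "amplicon-quant")
  m_gex <- read_genus_matrix(gex_csv)
  m_amp <- read_genus_matrix(amp_csv)
  merged <- merge_matrices(list(gex = m_gex, `16s` = m_amp))
  if (length(config$denylist)) {
    merged <- apply_denylist(merged, config$denylist)
  }
  write_merged_matrix(merged, config$outdir)
  log_stage(config, "merge", cells = length(merged$cell_ids),
            genera = length(merged$genera),
            distinct_umis = nrow(merged$umis))
  invisible(merged)
}

annotate_stage <- function(config) {
  merged_csv <- file.path(config$outdir, "csv_novami.csv")
  require_inputs(list(merged_csv), "annotate", "merge")
  require_inputs(list(config$expression_dir), "annotate", "simulate")
  merged <- read_genus_matrix(merged_csv)
  expr <- read_expression_matrix(config$expression_dir)
  cell_ids <- paste0(config$sample, "_", colnames(expr$counts))
  ann <- attach_bacteria_metadata(cell_ids, merged)
  ann$group_label <- unname(classify_cells(ann, taxon = config$taxon,
                                           pos_threshold = config$pos_threshold))
  out <- file.path(config$outdir,
                   paste0(config$sample, ".cell_annotations.csv"))
  utils::write.csv(ann, out, row.names = FALSE, quote = FALSE, na = "NA")
  log_stage(config, "annotate", cells = nrow(ann),
            dropped_matrix_cells = attr(ann, "n_dropped"),
            positive = sum(ann$group_label == "Positive", na.rm = TRUE),
            negative = sum(ann$group_label == "Negative", na.rm = TRUE))
  invisible(ann)
}

analyze_stage <- function(config) {
  s <- config$sample
  ann_csv <- file.path(config$outdir, paste0(s, ".cell_annotations.csv"))
  require_inputs(list(ann_csv), "analyze", "annotate")
  require_inputs(list(config$expression_dir), "analyze", "simulate")
  ann <- utils::read.csv(ann_csv, stringsAsFactors = FALSE,
                         check.names = FALSE)
  expr <- read_expression_matrix(config$expression_dir)
  norm <- normalize_expression(expr$counts)
  colnames(norm) <- paste0(s, "_", colnames(expr$counts))
  labels <- stats::setNames(ann$group_label, ann$cell_id)
  de <- differential_expression(norm, labels, min_pct = config$min_pct)
  utils::write.csv(de, file.path(config$outdir, paste0(s, ".de_table.csv")),
                   row.names = FALSE, quote = FALSE)
  volc <- volcano_table(de)
  utils::write.table(volc, file.path(config$outdir,
                                     paste0(s, ".volcano.tsv")),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  gsea <- NULL
  if (!is.null(config$gene_sets) && file.exists(config$gene_sets)) {
    sets <- read_gene_sets(config$gene_sets)
    ranking <- stats::setNames(de$log2_fold_change, de$gene)
    gsea <- preranked_gsea(ranking, sets, n_perm = config$n_perm,
                           seed = config$seed)
    utils::write.csv(gsea, file.path(config$outdir,
                                     paste0(s, ".gsea_table.csv")),
                     row.names = FALSE, quote = FALSE)
  }
  log_stage(config, "analyze", genes_tested = nrow(de),
            gene_sets = if (is.null(gsea)) 0L else nrow(gsea))
  invisible(list(de = de, volcano = volc, gsea = gsea))
}

#' Run one pipeline stage (or all of them)
#'
#' Stages: `gex-quant` and `amplicon-quant` build the per-library genus x
#' cell UMI matrices; `merge` unions them with UMI deduplication into
#' `csv_novami.csv`; `annotate` joins the merged matrix onto the host
#' expression cells and classifies them; `analyze` runs differential
#' expression (and gene-set enrichment when a GMT is configured);
#' `simulate` generates a synthetic dataset into the output directory and
#' rewrites the config paths to point at it; `all` chains everything.
#' A completed stage whose outputs already exist is skipped unless
#' `force = TRUE`; a stage whose upstream artifacts are missing fails
#' with the name of the stage to run first.
#'
#' @param stage One of `"gex-quant"`, `"amplicon-quant"`, `"merge"`,
#'   `"annotate"`, `"analyze"`, `"simulate"`, `"all"`.
#' @param config A [run_config()].
#' @param force Re-run even when outputs exist.
#' @param sim_config Optional [simulation_config()] for the simulate
#'   stage (default: `simulation_config(seed = config$seed)`).
#' @return The (possibly updated) `run_config`, invisibly; stage artifacts
#'   are written under `config$outdir`.
#' @export
run_stage <- function(stage = c("all", "gex-quant", "amplicon-quant",
                                "merge", "annotate", "analyze", "simulate"),
                      config, force = FALSE, sim_config = NULL) {
  stage <- match.arg(stage)
  stopifnot(inherits(config, "run_config"))
  if (!dir.exists(config$outdir)) dir.create(config$outdir, recursive = TRUE)
  if (stage == "all") {
    # simulate only when no real inputs are configured
    if (is.null(config$gex_alignments) || !is.null(sim_config)) {
      config <- run_stage("simulate", config, force = force,
                          sim_config = sim_config)
    }
    for (st in c("gex-quant", "amplicon-quant", "merge", "annotate",
                 "analyze")) {
      config <- run_stage(st, config, force = force)
    }
    return(invisible(config))
  }
  if (stage == "simulate") {
    sim_dir <- file.path(config$outdir, "sim")
    if (dir.exists(sim_dir) && !force &&
        file.exists(file.path(sim_dir, "barcodes.tsv.gz"))) {
      log_stage(config, "simulate", skipped = TRUE)
    } else {
      if (is.null(sim_config)) {
        sim_config <- simulation_config(seed = config$seed)
      }
      simulate_dataset(sim_config, dir = sim_dir)
      log_stage(config, "simulate", skipped = FALSE,
                n_cells = sim_config$n_cells)
    }
    config$whitelist <- file.path(sim_dir, "barcodes.tsv.gz")
    config$gex_alignments <- file.path(sim_dir, "gex.sam")
    config$amplicon_alignments <- file.path(sim_dir, "amplicon.sam")
    config$gex_hits <- file.path(sim_dir, "gex.pathseq.sam")
    config$amplicon_hits <- file.path(sim_dir, "amplicon.pathseq.sam")
    config$taxonomy_csv <- file.path(sim_dir, "taxonomy_scores.csv")
    config$expression_dir <- file.path(sim_dir, "filtered_feature_bc_matrix")
    return(invisible(config))
  }
  outs <- stage_outputs(config, stage)
  if (!force && all(file.exists(outs))) {
    log_stage(config, stage, skipped = TRUE)
    return(invisible(config))
  }
  switch(stage,
    "gex-quant" = quant_stage(config, "gex"),
    "amplicon-quant" = quant_stage(config, "amplicon"),
    "merge" = merge_stage(config),
    "annotate" = annotate_stage(config),
    "analyze" = analyze_stage(config))
  invisible(config)
}
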