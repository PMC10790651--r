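test_that("candidate extraction applies the per-library filters", {
  wl <- c("AAAC-1", "CCGT-1")
  aln <- data.frame(
    read_name = c("host_cb", "unmapped_badcb", "ok", "sec", "no_umi",
                  "amp_host"),
    is_host_mapped = c(TRUE, FALSE, FALSE, FALSE, FALSE, TRUE),
    is_secondary_or_supplementary = c(FALSE, FALSE, FALSE, TRUE, FALSE,
                                      FALSE),
    cell_barcode = c("AAAC-1", "TTTT-1", "AAAC-1", "AAAC-1", "CCGT-1",
                     "CCGT-1"),
    umi = c("AC", "AC", "AC", "AC", NA, "GG"),
    stringsAsFactors = FALSE)
  gex <- extract_candidates(aln, wl, "gex")
  expect_identical(gex$candidates$read_name, "ok")
  expect_identical(unname(gex$drop_summary),
                   c(1L, 2L, 1L, 1L, 1L))  # sec, host x2, barcode, umi, kept
  expect_identical(names(gex$drop_summary),
                   c("secondary", "host_mapped", "barcode", "umi", "kept"))
  # amplicon path keeps host-mapped reads with valid CB+UMI
  amp <- extract_candidates(aln, wl, "amplicon")
  expect_setequal(amp$candidates$read_name, c("host_cb", "ok", "amp_host"))
})

test_that("candidate extraction equals a brute-force filter on 2,000 reads and tallies sum", {
  set.seed(17)
  n <- 2000L
  wl <- sprintf("BC%03d-1", 1:40)
  aln <- data.frame(
    read_name = sprintf("r%04d", 1:n),
    is_host_mapped = runif(n) < 0.4,
    is_secondary_or_supplementary = runif(n) < 0.1,
    cell_barcode = ifelse(runif(n) < 0.1, NA_character_,
                          sprintf("BC%03d-1", sample(60, n, replace = TRUE))),
    umi = ifelse(runif(n) < 0.1, NA_character_,
                 replicate(n, paste(sample(c("A", "C", "G", "T"), 8,
                                           replace = TRUE), collapse = ""))),
    stringsAsFactors = FALSE)
  for (lib in c("gex", "amplicon")) {
    res <- extract_candidates(aln, wl, lib)
    brute <- character()
    for (i in seq_len(n)) {
      if (aln$is_secondary_or_supplementary[i]) next
      if (lib == "gex" && aln$is_host_mapped[i]) next
      if (is.na(aln$cell_barcode[i]) || !(aln$cell_barcode[i] %in% wl)) next
      if (is.na(aln$umi[i])) next
      brute <- c(brute, aln$read_name[i])
    }
    expect_identical(res$candidates$read_name, brute)
    expect_identical(sum(res$drop_summary), n)
  }
  # order independence: shuffled input keeps the same candidate set
  perm <- sample(n)
  shuffled <- extract_candidates(aln[perm, ], wl, "gex")
  straight <- extract_candidates(aln, wl, "gex")
  expect_setequal(shuffled$candidates$read_name,
                  straight$candidates$read_name)
  expect_identical(shuffled$drop_summary, straight$drop_summary)
})

test_that("quality_trim worked examples behave as forced by the operator arithmetic", {
  p36 <- trim_params(adapter_sequences = character(), min_len = 36)
  p30 <- trim_params(adapter_sequences = character(), min_len = 30)
  q40_50 <- rep(40L, 50L)
  seq50 <- strrep("ACGTA", 10)
  # headcrop 15 leaves 35 bases: discarded at MINLEN 36, kept at MINLEN 30
  expect_null(quality_trim(seq50, q40_50, p36))
  kept <- quality_trim(seq50, q40_50, p30)
  expect_identical(nchar(kept$sequence), 35L)
  expect_identical(length(kept$qualities), 35L)
  # read of 36 Q2 bases: LEADING removes everything
  expect_null(quality_trim(strrep("A", 36), rep(2L, 36),
                           trim_params(adapter_sequences = character(),
                                       headcrop = 0)))
  # qualities may be supplied as a Phred+33 string
  expect_identical(quality_trim(seq50, phred_string(q40_50), p30)$sequence,
                   kept$sequence)
  expect_error(quality_trim("ACGT", c(30L, 30L), p36), "lengths differ")
  # adapter clip truncates at the leftmost exact adapter occurrence
  pa <- trim_params(adapter_sequences = "ACGTACGTACGTAC", headcrop = 0,
                    min_len = 5)
  sq <- paste0(strrep("G", 20), "ACGTACGTACGTAC", strrep("G", 6))
  out <- quality_trim(sq, rep(40L, nchar(sq)), pa)
  expect_identical(out$sequence, strrep("G", 20))
  # 3' partial adapter (>=10-base prefix at the read end) also clips
  sq2 <- paste0(strrep("G", 20), substr("ACGTACGTACGTAC", 1, 11))
  out2 <- quality_trim(sq2, rep(40L, nchar(sq2)), pa)
  expect_identical(out2$sequence, strrep("G", 20))
})

test_that("trimming never lengthens a read and keeps qualities aligned", {
  set.seed(31)
  params <- trim_params()
  for (i in 1:200) {
    r <- random_read()
    out <- quality_trim(r$sequence, r$qualities, params)
    if (!is.null(out)) {
      expect_lte(nchar(out$sequence), nchar(r$sequence))
      expect_identical(nchar(out$sequence), length(out$qualities))
      expect_gte(nchar(out$sequence), params$min_len)
    }
  }
})

test_that("build_umi_matrix counts distinct UMIs and audits unassigned reads", {
  cand <- data.frame(read_name = c("r1", "r2", "r3", "r4"),
                     cell_barcode = "AAAC-1",
                     umi = c("X", "X", "Y", "Z"),
                     library = "gex", stringsAsFactors = FALSE)
  calls <- c(r1 = "Fusobacterium", r2 = "Fusobacterium",
             r3 = "Fusobacterium", r4 = "unassigned")
  res <- build_umi_matrix(cand, calls, sample = "S1")
  expect_identical(unname(umi_counts(res$matrix)[, "Fusobacterium"]), 2L)
  expect_identical(res$matrix$cell_ids, "S1_AAAC-1")
  # unassigned read audited in annotations, absent from the matrix
  expect_identical(nrow(res$annotation), 4L)
  expect_identical(res$annotation$genus[res$annotation$read_name == "r4"],
                   "unassigned")
  expect_identical(res$validation$umi_count, 2L)
  expect_true(all(res$validation$is_bacteria_associated))
  # no candidates -> empty matrix
  empty <- build_umi_matrix(cand[0, ], calls, "S1")
  expect_identical(nrow(empty$matrix$umis), 0L)
  # uncovered reads (no classification) are ignored
  res2 <- build_umi_matrix(cand, calls[c("r1", "r4")], "S1")
  expect_identical(unname(umi_counts(res2$matrix)[, "Fusobacterium"]), 1L)
})

test_that("duplicating candidates leaves the matrix unchanged; adding never decreases counts", {
  set.seed(23)
  n <- 300L
  cand <- data.frame(
    read_name = sprintf("r%03d", 1:n),
    cell_barcode = sprintf("BC%02d-1", sample(10, n, replace = TRUE)),
    umi = replicate(n, paste(sample(c("A", "C", "G", "T"), 5,
                                    replace = TRUE), collapse = "")),
    library = "gex", stringsAsFactors = FALSE)
  calls <- setNames(sample(c("Fusobacterium", "Treponema", "unassigned"),
                           n, replace = TRUE), cand$read_name)
  base <- build_umi_matrix(cand, calls, "S")
  dup_cand <- rbind(cand, transform(cand, read_name = paste0(read_name, "d")))
  dup_calls <- c(calls, setNames(calls, paste0(names(calls), "d")))
  doubled <- build_umi_matrix(dup_cand, dup_calls, "S")
  expect_identical(gcm_triplets(doubled$matrix), gcm_triplets(base$matrix))
  # monotonicity under added candidates
  sub <- build_umi_matrix(cand[1:150, ], calls, "S")
  cells <- base$matrix$cell_ids
  gens <- base$matrix$genera
  expect_true(all(umi_counts(base$matrix, cells, gens) >=
                    umi_counts(sub$matrix, cells, gens)))
  # candidate order does not matter
  perm <- build_umi_matrix(cand[sample(n), ], calls, "S")
  expect_identical(gcm_triplets(perm$matrix), gcm_triplets(base$matrix))
})

test_that("read budget is the product of cells and per-cell depth", {
  expect_identical(read_budget(4000, 20000), 8e7)
  expect_identical(read_budget(0, 20000), 0)
  expect_identical(read_budget(1, 1), 1)
  expect_error(read_budget(-1, 10), "non-negative")
})
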