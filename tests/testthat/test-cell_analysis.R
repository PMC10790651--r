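test_that("bacterial metadata attaches with missing-to-zero and row-sum totals", {
  merged <- genus_cell_matrix(data.frame(
    cell_id = c(rep("S_c1", 5), rep("S_c1", 2), "S_gone"),
    genus = c(rep("Fusobacterium", 5), rep("Treponema", 2), "Fusobacterium"),
    umi = c(paste0("F", 1:5), paste0("T", 1:2), "Z1")))
  ann <- attach_bacteria_metadata(c("S_c1", "S_c2"), merged)
  expect_identical(ann$cell_id, c("S_c1", "S_c2"))
  expect_identical(ann$Fusobacterium, c(5L, 0L))
  expect_identical(ann$Total, c(7L, 0L))          # 5 + 2
  expect_identical(attr(ann, "n_dropped"), 1L)    # S_gone not in expression
  expect_error(attach_bacteria_metadata(c("X_c1", "X_c2"), merged),
               "naming convention")
})

test_that("a synthetic 1,000-cell join equals a brute-force dictionary join", {
  set.seed(71)
  cells <- sprintf("S_BC%04d-1", 1:1000)
  n <- 1500L
  tr <- data.frame(
    cell_id = sample(cells[1:800], n, replace = TRUE),
    genus = sample(c("Fusobacterium", "Treponema", "Prevotella"), n,
                   replace = TRUE),
    umi = replicate(n, paste(sample(c("A", "C", "G", "T"), 8,
                                    replace = TRUE), collapse = "")),
    stringsAsFactors = FALSE)
  merged <- genus_cell_matrix(tr)
  ann <- attach_bacteria_metadata(cells, merged)
  dict <- new.env()
  u <- unique(tr)
  for (i in seq_len(nrow(u))) {
    k <- paste(u$cell_id[i], u$genus[i])
    assign(k, get0(k, dict, ifnotfound = 0L) + 1L, dict)
  }
  for (g in merged$genera) {
    brute <- vapply(cells, function(cl)
      get0(paste(cl, g), dict, ifnotfound = 0L), integer(1))
    expect_identical(ann[[g]], unname(brute))
  }
  expect_identical(ann$Total,
                   as.integer(rowSums(as.matrix(ann[merged$genera]))))
})

test_that("cell classification follows the >= threshold / zero-total / NA rule", {
  ann <- data.frame(cell_id = c("c1", "c2", "c3"),
                    Fusobacterium = c(5L, 0L, 2L),
                    Total = c(5L, 0L, 2L))
  lab <- classify_cells(ann, taxon = "Fusobacterium", pos_threshold = 4L)
  expect_identical(unname(lab), c("Positive", "Negative", NA))
  # threshold 1 on Total: no NA possible
  lab1 <- classify_cells(ann, taxon = "Total", pos_threshold = 1L)
  expect_false(anyNA(lab1))
  expect_error(classify_cells(ann, pos_threshold = 0L), ">= 1")
  expect_error(classify_cells(ann, taxon = "Nope"), "Nope")

  # random tables match the brute-force three-way predicate,
  # and the Positive set shrinks monotonically with the threshold
  set.seed(13)
  for (rep in 1:5) {
    r <- data.frame(cell_id = sprintf("c%03d", 1:60),
                    Fusobacterium = rpois(60, 2))
    r$Treponema <- rpois(60, 1)
    r$Total <- r$Fusobacterium + r$Treponema
    lab <- classify_cells(r, "Fusobacterium", 3L)
    brute <- sapply(seq_len(60), function(i) {
      if (r$Total[i] == 0) "Negative"
      else if (r$Fusobacterium[i] >= 3) "Positive"
      else NA_character_
    })
    expect_identical(unname(lab), brute)
    prev <- NULL
    for (t in 1:6) {
      pos <- names(which(classify_cells(r, "Fusobacterium", t) == "Positive"))
      if (!is.null(prev)) expect_true(all(pos %in% prev))
      prev <- pos
    }
  }
})

test_that("BH adjustment equals brute-force step-up and satisfies its bounds", {
  expect_identical(bh_adjust(0.03), 0.03)
  expect_identical(bh_adjust(rep(0.2, 5)), rep(0.2, 5))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
  set.seed(19)
  for (rep in 1:10) {
    p <- runif(20)
    adj <- bh_adjust(p)
    expect_equal(adj, oracle_bh(p))
    expect_true(all(adj >= p & adj <= 1))
  }
})

test_that("Wilcoxon DE matches exact enumeration on a 3v3 toy and handles flat genes", {
  pos_vals <- c(1.2, 3.4, 2.2)
  neg_vals <- c(0.1, 0.5, 0.3)
  expr <- rbind(GENEA = c(pos_vals, neg_vals),
                FLAT = rep(2, 6))
  colnames(expr) <- sprintf("c%d", 1:6)
  labels <- setNames(rep(c("Positive", "Negative"), each = 3),
                     colnames(expr))
  de <- differential_expression(expr, labels, min_pct = 0.1)
  # exact enumeration of the rank-sum null over all C(6,3) labelings
  vals <- c(pos_vals, neg_vals)
  ranks <- rank(vals)
  combos <- combn(6, 3)
  null_w <- apply(combos, 2, function(ix) sum(ranks[ix])) - 6  # Mann-Whitney U
  obs_w <- sum(ranks[1:3]) - 6
  p_exact <- min(1, 2 * min(mean(null_w <= obs_w), mean(null_w >= obs_w)))
  expect_equal(de$p_value[de$gene == "GENEA"], p_exact)
  expect_identical(de$p_value[de$gene == "FLAT"], 1)
  expect_identical(de$log2_fold_change[de$gene == "FLAT"], 0)
  # declared fold-change definition
  lfc <- log2((mean(expm1(pos_vals)) + 1) / (mean(expm1(neg_vals)) + 1))
  expect_equal(de$log2_fold_change[de$gene == "GENEA"], lfc)
  expect_error(differential_expression(expr, c(labels[1:4], NA, NA)),
               "at least 2 cells")
})

test_that("DE is invariant to cell order and to NA cells' expression", {
  set.seed(47)
  n_genes <- 40L
  expr <- matrix(rpois(n_genes * 30, 5), nrow = n_genes,
                 dimnames = list(sprintf("G%02d", 1:n_genes),
                                 sprintf("c%02d", 1:30)))
  norm <- as.matrix(normalize_expression(expr))
  labels <- setNames(c(rep("Positive", 10), rep("Negative", 10),
                       rep(NA, 10)), colnames(norm))
  base <- differential_expression(norm, labels)
  perm <- sample(30)
  shuffled <- differential_expression(norm[, perm], labels[perm])
  expect_equal(shuffled, base)
  # NA-labelled cells' values are irrelevant
  norm2 <- norm
  norm2[, is.na(labels)] <- 999
  expect_equal(differential_expression(norm2, labels)[
    c("gene", "p_value", "log2_fold_change")],
    base[c("gene", "p_value", "log2_fold_change")])
  # min_pct filters genes undetected in both groups
  norm3 <- norm
  norm3["G01", !is.na(labels)] <- 0
  de3 <- differential_expression(norm3, labels, min_pct = 0.1)
  expect_false("G01" %in% de3$gene)
})

test_that("volcano table flags the conventional significance thresholds", {
  de <- data.frame(gene = c("A", "B", "C"),
                   log2_fold_change = c(1.0, 0.3, -0.8),
                   p_value = c(1e-4, 1e-4, 0.2),
                   p_adjusted = c(1e-3, 1e-3, 0.4))
  v <- volcano_table(de)
  expect_identical(v$significant, c(TRUE, FALSE, FALSE))
  expect_equal(v$neg_log10_p, -log10(de$p_adjusted))
})

test_that("GSEA ES equals hand/brute-force running sums and reversal negates it", {
  # 5-gene ranking, 2-gene set: hand-enumerated running-sum maximum
  vals <- c(g1 = 2.0, g2 = 1.0, g3 = 0.5, g4 = -0.5, g5 = -2.0)
  set2 <- c("g1", "g2")
  # hits at positions 1,2 with weights 2,1 (sum 3); misses step -1/3
  hand <- cumsum(c(2 / 3, 1 / 3, -1 / 3, -1 / 3, -1 / 3))
  hand_es <- hand[which.max(abs(hand))]
  res <- preranked_gsea(vals, list(S = set2), n_perm = 50, seed = 1)
  expect_equal(res$enrichment_score, hand_es)
  expect_equal(res$enrichment_score,
               oracle_gsea_es(vals, names(vals), set2))
  expect_identical(res$leading_edge, "g1/g2")
  # set == all ranked genes: brute-force running sum (monotone to 1)
  all_res <- preranked_gsea(vals, list(ALL = names(vals)), n_perm = 50,
                            seed = 1)
  expect_equal(all_res$enrichment_score,
               oracle_gsea_es(vals, names(vals), names(vals)))
  # reversing the ranking negates ES for every set
  set.seed(83)
  for (rep in 1:5) {
    v <- setNames(round(sort(rnorm(9), decreasing = TRUE), 3),
                  paste0("x", 1:9))
    sets <- list(A = paste0("x", c(1, 3, 8)), B = paste0("x", c(2, 9)))
    fwd <- preranked_gsea(v, sets, n_perm = 20, seed = 2)
    rev <- preranked_gsea(-v, sets, n_perm = 20, seed = 2)
    expect_equal(rev$enrichment_score, -fwd$enrichment_score)
    for (nm in names(sets)) {
      expect_equal(fwd$enrichment_score[fwd$set_name == nm],
                   oracle_gsea_es(v, names(sort(v, decreasing = TRUE)),
                                  sets[[nm]]))
    }
  }
})

test_that("GSEA reports untestable sets as NA, bounds ES, and ignores outside genes", {
  vals <- setNames(seq(2, -2, length.out = 8), paste0("g", 1:8))
  res <- preranked_gsea(vals, list(IN = c("g2", "g5"),
                                   OUT = c("zz1", "zz2")),
                        n_perm = 100, seed = 4)
  expect_true(is.na(res$enrichment_score[res$set_name == "OUT"]))
  es <- res$enrichment_score[res$set_name == "IN"]
  expect_lte(abs(es), 1)
  p <- res$p_value[res$set_name == "IN"]
  expect_gt(p, 0)
  expect_lte(p, 1)
  # genes outside both ranking and set do not change ES
  res2 <- preranked_gsea(vals, list(IN = c("g2", "g5", "absent_gene")),
                         n_perm = 100, seed = 4)
  expect_equal(res2$enrichment_score, es)
  expect_error(preranked_gsea(vals, list(S = "g1"), n_perm = 10),
               "seed")
  expect_error(preranked_gsea(c(vals, gz = Inf), list(S = "g1"),
                              n_perm = 10, seed = 1), "finite")
})
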