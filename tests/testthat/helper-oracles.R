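# Independent oracles and fixture builders. Everything here is written
# straight-line, separately from the package implementations it checks.

# -- independent text-mode SAM parser --------------------------------------
oracle_parse_sam <- function(path, cb_tag = "CB", umi_tag = "UB") {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "@")]
  rows <- lapply(lines, function(l) {
    f <- strsplit(l, "\t", fixed = TRUE)[[1]]
    flag <- as.integer(f[2])
    tags <- f[-(1:11)]
    grab <- function(key) {
      hit <- tags[startsWith(tags, paste0(key, ":Z:"))]
      if (length(hit) == 0L) NA_character_ else sub("^..:Z:", "", hit[1])
    }
    data.frame(read_name = f[1],
               is_host_mapped = (flag %% 8L) %/% 4L == 0L,
               is_secondary_or_supplementary =
                 (flag %% 512L) %/% 256L == 1L || (flag %% 4096L) %/% 2048L == 1L,
               cell_barcode = grab(cb_tag), umi = grab(umi_tag),
               sequence = f[10], qualities = f[11],
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

# -- straight-line reference trimmer ---------------------------------------
# Same operator definitions as the package: adapter clip (leftmost full
# occurrence, or >=10-base adapter prefix at the read 3' end), headcrop,
# leading, trailing, sliding window with trailing sweep, minlen.
oracle_trim <- function(seq, quals, adapters, leading_q, trailing_q,
                        window_len, window_q, min_len, headcrop) {
  n <- nchar(seq)
  cutpos <- NA_integer_
  for (start in seq_len(n)) {
    for (a in adapters) {
      alen <- nchar(a)
      if (start + alen - 1L <= n) {
        if (substr(seq, start, start + alen - 1L) == a) cutpos <- start
      } else {
        ov <- n - start + 1L
        if (ov >= 10L && substr(seq, start, n) == substr(a, 1L, ov)) {
          cutpos <- start
        }
      }
      if (!is.na(cutpos)) break
    }
    if (!is.na(cutpos)) break
  }
  if (!is.na(cutpos)) {
    seq <- substr(seq, 1L, cutpos - 1L)
    quals <- quals[seq_len(cutpos - 1L)]
    n <- cutpos - 1L
  }
  if (headcrop >= n) return(NULL)
  if (headcrop > 0L) {
    seq <- substr(seq, headcrop + 1L, n)
    quals <- quals[(headcrop + 1L):n]
    n <- n - headcrop
  }
  a <- 1L
  while (a <= n && quals[a] < leading_q) a <- a + 1L
  b <- n
  while (b >= a && quals[b] < trailing_q) b <- b - 1L
  if (a > b) return(NULL)
  seq <- substr(seq, a, b)
  quals <- quals[a:b]
  n <- b - a + 1L
  if (n >= window_len) {
    for (s in 1:(n - window_len + 1L)) {
      if (mean(quals[s:(s + window_len - 1L)]) < window_q) {
        n <- s - 1L
        while (n >= 1L && quals[n] < window_q) n <- n - 1L
        if (n == 0L) return(NULL)
        seq <- substr(seq, 1L, n)
        quals <- quals[1:n]
        break
      }
    }
  }
  if (nchar(seq) < min_len) return(NULL)
  list(sequence = seq, qualities = quals)
}

# -- brute-force BH step-up -------------------------------------------------
oracle_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  scaled <- p[o] * n / seq_len(n)
  adj <- rev(cummin(rev(scaled)))
  adj <- pmin(adj, 1)
  out <- numeric(n)
  out[o] <- adj
  out
}

# -- brute-force GSEA running sum -------------------------------------------
oracle_gsea_es <- function(values, genes, set_genes) {
  n <- length(values)
  hit <- genes %in% set_genes
  nh <- sum(abs(values[hit]))
  nm <- n - sum(hit)
  rs <- numeric(n)
  cur <- 0
  for (i in seq_len(n)) {
    cur <- cur + if (hit[i]) abs(values[i]) / nh else
      if (nm > 0) -1 / nm else 0
    rs[i] <- cur
  }
  hi <- max(rs)
  lo <- min(rs)
  tol <- 1e-9 * max(1, abs(hi), abs(lo))
  if (abs(hi) - abs(lo) > tol) hi
  else if (abs(lo) - abs(hi) > tol) lo
  else if (sum(rs) >= 0) hi else lo
}

# -- toy taxonomy -----------------------------------------------------------
# Lineages built by hand; a brute-force genus scan walks rank/name pairs.
toy_taxonomy <- function(genera = c("Fusobacterium", "Treponema",
                                    "Prevotella")) {
  base <- data.frame(rank = c("kingdom", "phylum", "family"),
                     name = c("Bacteria", "P1", "F1"),
                     stringsAsFactors = FALSE)
  ids <- integer(); nms <- character(); rks <- character(); lins <- list()
  id <- 10L
  for (g in genera) {
    glin <- rbind(base, data.frame(rank = "genus", name = g))
    ids <- c(ids, id); nms <- c(nms, g); rks <- c(rks, "genus")
    lins <- c(lins, list(glin))
    for (k in 1:2) {
      id <- id + 1L
      sn <- paste0(g, "_s", k)
      ids <- c(ids, id); nms <- c(nms, sn); rks <- c(rks, "species")
      lins <- c(lins, list(rbind(glin, data.frame(rank = "species",
                                                  name = sn))))
    }
    id <- id + 8L
  }
  ids <- c(ids, 9L); nms <- c(nms, "F1"); rks <- c(rks, "family")
  lins <- c(lins, list(base))
  taxonomy_table(ids, nms, rks, lins)
}

oracle_genus_scan <- function(id, table) {
  ln <- table$lineage[[as.character(id)]]
  res <- NA_character_
  for (i in seq_len(nrow(ln))) {
    if (ln$rank[i] == "genus") res <- ln$name[i]
  }
  res
}

# -- random genus x cell matrices -------------------------------------------
random_gcm <- function(seed, n_cells = 6, n_genera = 3, n_triplets = 40,
                       sample = "S") {
  set.seed(seed)
  cells <- paste0(sample, "_BC", sprintf("%02d-1", seq_len(n_cells)))
  genera <- sort(sample(c("Fusobacterium", "Treponema", "Prevotella",
                          "Pseudomonas", "Sphingomonas"), n_genera))
  umis <- apply(matrix(sample(c("A", "C", "G", "T"), n_triplets * 6,
                              replace = TRUE), ncol = 6), 1, paste,
                collapse = "")
  genus_cell_matrix(data.frame(
    cell_id = sample(cells, n_triplets, replace = TRUE),
    genus = sample(genera, n_triplets, replace = TRUE),
    umi = umis, stringsAsFactors = FALSE))
}

gcm_triplets <- function(m) m$umis[, c("cell_id", "genus", "umi")]

# -- random reads for the trimming oracle -----------------------------------
random_read <- function(len_range = c(20L, 150L)) {
  n <- sample(len_range[1]:len_range[2], 1L)
  list(sequence = paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                        collapse = ""),
       qualities = sample(2:40, n, replace = TRUE))
}

run_full_pipeline <- function(sim, sample = "S") {
  wl <- read_barcode_whitelist(sim$whitelist)
  tax <- read_taxonomy_table(sim$taxonomy_csv)
  gex <- quantify_library(sim$gex_alignments, wl,
                          read_taxonomic_hits(sim$gex_hits), tax,
                          sample = sample, library = "gex")
  amp <- quantify_library(sim$amplicon_alignments, wl,
                          read_taxonomic_hits(sim$amplicon_hits), tax,
                          sample = sample, library = "amplicon")
  merge_matrices(list(gex = gex$matrix, `16s` = amp$matrix))
}
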