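# The core detector: maximal exact inverted matches, the brute-force
# oracle, and redundancy filtering.

test_that("tile_fragments enumerates staggered k-mers with the right count", {
  expect_identical(tile_fragments(strrep("A", 22), 20, 1)$offset, 1:3)
  expect_identical(nrow(tile_fragments(strrep("A", 20), 20, 1)), 1L)
  expect_identical(nrow(tile_fragments(strrep("A", 19), 20, 1)), 0L)
  set.seed(3)
  for (i in 1:20) {
    len <- sample(5:200, 1); k <- sample(2:30, 1); st <- sample(1:5, 1)
    tf <- tile_fragments(random_dna(len), k, st)
    want <- if (len >= k) (len - k) %/% st + 1L else 0L
    expect_identical(nrow(tf), want)
    if (nrow(tf)) expect_true(all(nchar(tf$fragment) == k))
  }
})

test_that("a poly-A gene against a poly-T window yields the single full-length repeat after filtering", {
  h <- filter_redundant(
    find_inverted_repeats(strrep("A", 30), strrep("T", 30), search_config()))
  expect_identical(nrow(h), 1L)
  expect_identical(h$gene_start, 1L)
  expect_identical(h$gene_end, 30L)
  expect_identical(h$window_start, 1L)
  expect_identical(h$window_end, 30L)
  expect_identical(h$length, 30L)
})

test_that("a planted 60-bp segment is found exactly once at its planted coordinates", {
  set.seed(17)
  for (i in 1:20) {
    gene <- random_dna(300)
    window <- random_dna(800)
    window <- plant_inverted_copy(gene, window, g_at = 11, len = 60,
                                  w_at = 101)
    h <- find_inverted_repeats(gene, window, search_config())
    b <- brute_force_inverted_repeats(gene, window, 20)
    expect_identical(h, b)
    h60 <- h[h$length >= 60, ]
    expect_identical(nrow(h60), 1L)
    # extension into random context can lengthen the hit by a base or two,
    # but it must cover the planted intervals: gene 11..70, window 101..160
    expect_lte(h60$gene_start[1], 11L)
    expect_gte(h60$gene_end[1], 70L)
    expect_lte(h60$window_start[1], 101L)
    expect_gte(h60$window_end[1], 160L)
  }
})

test_that("a repeat one base below the threshold is never reported", {
  set.seed(19)
  for (i in 1:20) {
    gene <- random_dna(200)
    window <- random_dna(400)
    window <- plant_inverted_copy(gene, window, g_at = 21, len = 19,
                                  w_at = 201)
    # guard flanks so the planted copy cannot extend
    cfg <- search_config()
    h <- find_inverted_repeats(gene, window, cfg)
    covers <- h$gene_start <= 21 & h$gene_end >= 39
    if (any(covers)) {
      # only possible by chance extension; verify against the oracle
      expect_identical(h, brute_force_inverted_repeats(gene, window, 20))
    } else {
      expect_true(all(h$length >= 20))
    }
    # at min_ir_len 19 the planted repeat must appear
    h19 <- find_inverted_repeats(gene, window, search_config(min_ir_len = 19))
    expect_true(any(h19$gene_start <= 21 & h19$gene_end >= 39))
  }
})

test_that("every reported hit passes a character-by-character identity re-check", {
  set.seed(29)
  for (i in 1:30) {
    gene <- random_dna(sample(50:400, 1))
    window <- random_dna(sample(100:900, 1))
    if (i %% 2 == 0)
      window <- plant_inverted_copy(gene, window, 5, 25, 31)
    h <- find_inverted_repeats(gene, window,
                               search_config(min_ir_len = 12))
    expect_true(all(verify_hits(h, gene, window)))
  }
})

test_that("hits are maximal: one-base extensions break the identity", {
  set.seed(31)
  checked <- 0L
  for (i in 1:60) {
    gene <- random_dna(250)
    window <- plant_inverted_copy(gene, random_dna(600), 41, 35, 101)
    h <- find_inverted_repeats(gene, window, search_config(min_ir_len = 10))
    for (r in seq_len(nrow(h))) {
      gs <- h$gene_start[r]; ge <- h$gene_end[r]
      ws <- h$window_start[r]; we <- h$window_end[r]
      # left extension of gene pairs with right extension of window
      if (gs > 1L && we < nchar(window)) {
        ext <- data.frame(gene_start = gs - 1L, gene_end = ge,
                          window_start = ws, window_end = we + 1L)
        expect_false(verify_hits(ext, gene, window))
        checked <- checked + 1L
      }
      if (ge < nchar(gene) && ws > 1L) {
        ext <- data.frame(gene_start = gs, gene_end = ge + 1L,
                          window_start = ws - 1L, window_end = we)
        expect_false(verify_hits(ext, gene, window))
        checked <- checked + 1L
      }
    }
  }
  expect_gt(checked, 50L)
})

test_that("search is symmetric in the roles of gene and window", {
  set.seed(37)
  for (i in 1:25) {
    a <- random_dna(sample(40:300, 1))
    b <- random_dna(sample(40:300, 1))
    if (i %% 2 == 0) b <- plant_inverted_copy(a, b, 11, 22, 7)
    cfg <- search_config(min_ir_len = 10)
    h1 <- find_inverted_repeats(a, b, cfg)
    h2 <- find_inverted_repeats(b, a, cfg)
    t1 <- h1[order(h1$window_start, h1$gene_start),
             c("window_start", "window_end", "gene_start", "gene_end",
               "length")]
    names(t1) <- c("gene_start", "gene_end", "window_start", "window_end",
                   "length")
    t2 <- h2[order(h2$gene_start, h2$window_start), names(t1)]
    rownames(t1) <- rownames(t2) <- NULL
    expect_identical(t1, t2)
  }
})

test_that("lowering min_ir_len never removes a hit", {
  set.seed(41)
  for (i in 1:15) {
    gene <- random_dna(200)
    window <- plant_inverted_copy(gene, random_dna(500), 31, 40, 61)
    h_hi <- find_inverted_repeats(gene, window, search_config(min_ir_len = 25))
    h_lo <- find_inverted_repeats(gene, window, search_config(min_ir_len = 15))
    key <- function(h) paste(h$gene_start, h$gene_end, h$window_start,
                             h$window_end)
    expect_true(all(key(h_hi) %in% key(h_lo)))
  }
})

test_that("ambiguity codes never participate in a match", {
  gene <- paste0(strrep("A", 15), "N", strrep("A", 15))
  window <- strrep("T", 31)
  # N splits the poly-A run into two 15-mers, both below 20
  expect_identical(nrow(find_inverted_repeats(gene, window, search_config())),
                   0L)
  h <- find_inverted_repeats(gene, window, search_config(min_ir_len = 10))
  expect_true(all(h$length <= 15))
  # N in the window fails too, even against N in the gene
  expect_identical(
    nrow(find_inverted_repeats(strrep("N", 30), strrep("N", 30),
                               search_config())), 0L)
})

test_that("reverse (non-complement) repeat sense matches plain reversals", {
  set.seed(43)
  gene <- random_dna(100)
  frag <- substr(gene, 11, 40)
  window <- paste0(random_dna(60),
                   paste(rev(strsplit(frag, "")[[1]]), collapse = ""),
                   random_dna(60))
  cfg <- search_config(repeat_sense = "reverse")
  h <- find_inverted_repeats(gene, window, cfg)
  expect_true(any(h$gene_start <= 11 & h$gene_end >= 40))
  expect_true(all(verify_hits(h, gene, window, "reverse")))
  # the same window has no reverse-complement repeat of that length
  h_rc <- find_inverted_repeats(gene, window, search_config())
  expect_false(any(h_rc$length >= 30))
})

test_that("max_report_len truncates reported hits like a bounded fragment scan", {
  gene <- strrep("ACGGT", 200)  # 1000 bp
  window <- reverse_complement(gene)
  cfg <- search_config(max_report_len = 150)
  h <- filter_redundant(find_inverted_repeats(gene, window, cfg))
  expect_true(all(h$length <= 150))
  expect_true(all(verify_hits(h, gene, window)))
})

test_that("find_inverted_repeats equals the brute-force oracle on seeded instances", {
  set.seed(47)
  for (i in 1:150) {
    gc <- runif(1, 0.25, 0.75)
    gene <- random_dna(sample(20:600, 1), gc)
    window <- random_dna(sample(20:1200, 1), gc)
    if (i %% 3 == 0 && nchar(gene) >= 100 && nchar(window) >= 200) {
      L <- sample(20:70, 1)
      window <- plant_inverted_copy(gene, window, 15, L, 101)
    }
    k <- sample(c(8L, 12L, 20L), 1)
    h <- find_inverted_repeats(gene, window, search_config(min_ir_len = k))
    b <- brute_force_inverted_repeats(gene, window, k)
    expect_identical(h, b)
  }
})

test_that("the oracle refuses oversized inputs and handles trivial ones", {
  expect_error(brute_force_inverted_repeats(strrep("A", 6000),
                                            strrep("T", 6000), 20),
               "too large")
  expect_identical(nrow(brute_force_inverted_repeats("ACGTACGT", "", 2)), 0L)
  h <- brute_force_inverted_repeats("ACGT", "ACGT", 2)
  expect_true(any(h$length == 4L & h$gene_start == 1L))
})

test_that("filter_redundant removes nested hits and equals the quadratic oracle", {
  hits <- data.frame(gene_start = c(1L, 10L), gene_end = c(100L, 50L),
                     window_start = c(201L, 251L), window_end = c(300L, 291L),
                     length = c(100L, 41L))
  expect_identical(filter_redundant(hits)$gene_start, 1L)

  partial <- data.frame(gene_start = c(1L, 50L), gene_end = c(100L, 150L),
                        window_start = c(201L, 250L),
                        window_end = c(300L, 349L), length = c(100L, 101L))
  expect_identical(nrow(filter_redundant(partial)), 2L)

  dup <- rbind(hits[1, ], hits[1, ])
  expect_identical(nrow(filter_redundant(dup)), 1L)

  set.seed(53)
  for (i in 1:50) {
    n <- sample(1:12, 1)
    gs <- sample(1:50, n, TRUE); ge <- gs + sample(5:60, n, TRUE)
    ws <- sample(1:50, n, TRUE); we <- ws + sample(5:60, n, TRUE)
    hits <- data.frame(gene_start = gs, gene_end = ge, window_start = ws,
                       window_end = we, length = ge - gs + 1L)
    got <- filter_redundant(hits)
    want <- containment_filter_oracle(hits)
    key <- function(h) sort(paste(h$gene_start, h$gene_end, h$window_start,
                                  h$window_end))
    expect_identical(key(got), key(want))
  }
})
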