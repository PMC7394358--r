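# Shared helpers: seeded random DNA and planted-repeat construction.

random_dna <- function(n, gc = 0.5) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

# Plant revcomp(substr(gene, g_at, g_at+len-1)) into window at w_at,
# returning the modified window.
plant_inverted_copy <- function(gene, window, g_at, len, w_at) {
  frag <- substr(gene, g_at, g_at + len - 1L)
  stopifnot(nchar(frag) == len,
            w_at + len - 1L <= nchar(window))
  paste0(substr(window, 1L, w_at - 1L), reverse_complement(frag),
         substr(window, w_at + len, nchar(window)))
}

# Independent full-text scan of both strands for all occurrences of a
# pattern (oracle for locate_gene).
scan_both_strands <- function(pattern, genome_seq) {
  fwd <- gregexpr(pattern, genome_seq, fixed = TRUE)[[1]]
  rev <- gregexpr(reverse_complement(pattern), genome_seq, fixed = TRUE)[[1]]
  list(fwd = if (fwd[1] == -1L) integer(0) else as.integer(fwd),
       rev = if (rev[1] == -1L) integer(0) else as.integer(rev))
}

# Quadratic containment filter (oracle for filter_redundant).
containment_filter_oracle <- function(hits) {
  n <- nrow(hits)
  if (n <= 1L) return(hits)
  hits <- unique(hits)
  n <- nrow(hits)
  keep <- rep(TRUE, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j || !keep[i]) next
    if (hits$gene_start[i] >= hits$gene_start[j] &&
        hits$gene_end[i] <= hits$gene_end[j] &&
        hits$window_start[i] >= hits$window_start[j] &&
        hits$window_end[i] <= hits$window_end[j] &&
        !(hits$gene_start[i] == hits$gene_start[j] &&
          hits$gene_end[i] == hits$gene_end[j] &&
          hits$window_start[i] == hits$window_start[j] &&
          hits$window_end[i] == hits$window_end[j]))
      keep[i] <- FALSE
  }
  out <- hits[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

hit_key_cols <- c("gene_start", "gene_end", "window_start", "window_end",
                  "length")

sim_with_all_decoys <- function(seed, gene_strand = "+") {
  simulate_genome(simulation_params(
    seed = seed, gene_strand = gene_strand,
    decoys = c("below_min_len", "mismatched", "beyond_window",
               "direct_repeat")))
}

expressed_gene <- function(sim) {
  sim$annotations[sim$annotations$gene_id == "hsdS_1", , drop = FALSE]
}

scan_gene_of <- function(sim, config = search_config()) {
  scan_gene(sim$genome, expressed_gene(sim), config)
}

# Compare a scan result to the simulator truth table: exact coordinate
# set equality against the expected_detected rows.
expect_matches_truth <- function(hits, sim) {
  tr <- sim$truth[sim$truth$expected_detected, , drop = FALSE]
  got <- hits[order(hits$gene_start),
              c("gene_start", "gene_end", "partner_start", "partner_end",
                "length")]
  want <- tr[order(tr$gene_start),
             c("gene_start", "gene_end", "partner_start", "partner_end",
               "length")]
  rownames(got) <- rownames(want) <- NULL
  expect_identical(as.data.frame(got), as.data.frame(want))
}
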