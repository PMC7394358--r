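# Deterministic generator of test genomes carrying a planted inverting
# Type I restriction-modification locus (hsdR-hsdM-hsdS-hsdS'-recombinase)
# plus decoy repeats, with a ground-truth table.

#' Simulation parameters
#'
#' Configures [simulate_genome()]. Defaults emulate the architecture of a
#' two-repeat inverting Type I locus: an expressed hsdS whose leader repeat
#' (85 bp) precedes the 5'-TRD and whose mid repeat (33 bp) separates the
#' TRDs, and a silent, inverted hsdS' copy downstream carrying alternative
#' TRD variants between reverse-complemented copies of the same repeats.
#' The repeat lengths follow the SpnD39III shufflon (whose repeats are 15,
#' 85 and 33 bp; the two >= 20 bp lengths are planted so a default-threshold
#' scan detects both).
#'
#' @param seed Integer seed; identical seeds give byte-identical output.
#' @param genome_len Contig length in bases.
#' @param gc GC fraction of the i.i.d. background, 0-1.
#' @param ir_lengths Length-2 integer vector `c(leader, mid)` in bases.
#' @param trd5_len,trd3_len TRD lengths in bases.
#' @param n_trd5_variants,n_trd3_variants Variant counts, each >= 2
#'   (variant 1 sits in the expressed gene, variant 2 in the silent copy;
#'   further variants only enter the allele-space bookkeeping).
#' @param gene_strand Strand of the expressed hsdS on the contig.
#' @param decoys Character vector from `"below_min_len"`, `"mismatched"`,
#'   `"beyond_window"`, `"direct_repeat"`.
#' @param intergene_gap Gap in bases between consecutive locus genes.
#' @param locus_start Genome coordinate where the locus begins.
#' @param contig_id Contig name.
#' @return An object of class `sim_params`.
#' @export
simulation_params <- function(seed = 1L, genome_len = 45000L, gc = 0.5,
                              ir_lengths = c(85L, 33L),
                              trd5_len = 450L, trd3_len = 420L,
                              n_trd5_variants = 2L, n_trd3_variants = 2L,
                              gene_strand = c("+", "-"),
                              decoys = character(0),
                              intergene_gap = 150L,
                              locus_start = 2001L,
                              contig_id = "sim_contig_1") {
  gene_strand <- match.arg(gene_strand)
  if (length(decoys))
    decoys <- match.arg(decoys, c("below_min_len", "mismatched",
                                  "beyond_window", "direct_repeat"),
                        several.ok = TRUE)
  p <- list(seed = as.integer(seed), genome_len = as.integer(genome_len),
            gc = gc, ir_lengths = as.integer(ir_lengths),
            trd5_len = as.integer(trd5_len), trd3_len = as.integer(trd3_len),
            n_trd5_variants = as.integer(n_trd5_variants),
            n_trd3_variants = as.integer(n_trd3_variants),
            gene_strand = gene_strand, decoys = decoys,
            intergene_gap = as.integer(intergene_gap),
            locus_start = as.integer(locus_start),
            contig_id = contig_id)
  stopifnot(length(p$ir_lengths) == 2L, all(p$ir_lengths >= 1L),
            p$trd5_len >= 2L, p$trd3_len >= 2L,
            p$n_trd5_variants >= 2L, p$n_trd3_variants >= 2L,
            p$gc >= 0, p$gc <= 1, p$genome_len >= 1L,
            p$intergene_gap >= 0L, p$locus_start >= 1L)
  class(p) <- "sim_params"
  p
}

rand_dna <- function(n, gc) {
  if (n == 0L) return("")
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

# An ORF-like filler gene: ATG + random body + TAA, length n.
rand_orf <- function(n, gc) {
  stopifnot(n >= 6L)
  paste0("ATG", rand_dna(n - 6L, gc), "TAA")
}

splice_in <- function(genome_seq, at, fragment) {
  stopifnot(at >= 1L, at + nchar(fragment) - 1L <= nchar(genome_seq))
  paste0(substr(genome_seq, 1L, at - 1L), fragment,
         substr(genome_seq, at + nchar(fragment), nchar(genome_seq)))
}

# Force the character of s at pos to differ from `avoid` (cycle ACGT).
force_char_diff <- function(s, pos, avoid) {
  if (substr(s, pos, pos) == avoid) {
    repl <- setdiff(c("A", "C", "G", "T"), avoid)[1]
    substr(s, pos, pos) <- repl
  }
  s
}

#' Simulate a genome with a planted inverting Type I locus
#'
#' Draws an i.i.d. background at the requested GC content, splices in a
#' Type I locus (hsdR, hsdM, expressed hsdS, silent inverted hsdS',
#' recombinase), and optionally plants decoy repeats. The expressed hsdS is
#' `ATG + pad + leaderIR + TRD5(v1) + midIR + TRD3(v1) + TAA`; the silent
#' hsdS' sits on the opposite strand with a GTG start codon, its own pad,
#' and alternative TRD variants (v2) between identical copies of the two
#' repeats, so on the genome the repeats appear reverse-complemented and a
#' scan of the expressed gene's flanks finds exactly the two planted
#' inverted-repeat pairs.
#'
#' The single base on each side of every planted repeat copy is forced to
#' break the identity (pads end on different bases; TRD variant 2 starts
#' and ends on different bases than variant 1), so each planted pair is
#' maximal at exactly the recorded coordinates. Decoy copies get the same
#' guard on their flanking background bases.
#'
#' Decoys: `below_min_len` plants a 19-bp inverted copy of a gene segment
#' in the downstream flank; `mismatched` a 30-bp inverted copy with one
#' substitution at its centre; `beyond_window` a 60-bp inverted copy 1 kb
#' past the 30-kb downstream window edge; `direct_repeat` a 60-bp
#' non-inverted copy in the downstream flank.
#'
#' @param params A `sim_params` object.
#' @return A list of class `sim_genome`: `genome` (a `genome_set`),
#'   `annotations` (gene table with product labels), `truth` (`data.frame`
#'   of every planted repeat pair and decoy: `kind`, `side`, `gene_start`,
#'   `gene_end` (gene-local, coding orientation), `partner_start`,
#'   `partner_end` (genome), `length`, `mismatches`, `distance`,
#'   `expected_detected` under the default 20-bp/30-kb scan), `trd_truth`
#'   (planted repeat and TRD intervals within the expressed gene),
#'   `variants` (the planted sequences), and `params`.
#' @export
simulate_genome <- function(params = simulation_params()) {
  stopifnot(inherits(params, "sim_params"))
  old <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(params$seed)

  gc <- params$gc
  leader_len <- params$ir_lengths[1]; mid_len <- params$ir_lengths[2]
  pad_len <- 9L
  leader <- rand_dna(leader_len, gc)
  mid <- rand_dna(mid_len, gc)
  pad_e <- rand_dna(pad_len, gc)
  pad_s <- force_char_diff(rand_dna(pad_len, gc), pad_len,
                           substr(pad_e, pad_len, pad_len))
  trd5 <- vapply(seq_len(params$n_trd5_variants),
                 function(i) rand_dna(params$trd5_len, gc), "")
  trd3 <- vapply(seq_len(params$n_trd3_variants),
                 function(i) rand_dna(params$trd3_len, gc), "")
  # guard the repeat boundaries: the silent copy's TRD variants must differ
  # from the expressed ones at the bases abutting each repeat
  trd5[2] <- force_char_diff(trd5[2], 1L, substr(trd5[1], 1L, 1L))
  trd5[2] <- force_char_diff(trd5[2], params$trd5_len,
                             substr(trd5[1], params$trd5_len, params$trd5_len))
  trd3[2] <- force_char_diff(trd3[2], 1L, substr(trd3[1], 1L, 1L))

  hsds_expr <- paste0("ATG", pad_e, leader, trd5[1], mid, trd3[1], "TAA")
  hsds_silent_coding <- paste0("GTG", pad_s, leader, trd5[2], mid, trd3[2],
                               "TAA")

  hsdr <- rand_orf(900L, gc)
  hsdm <- rand_orf(1500L, gc)
  recomb <- rand_orf(600L, gc)
  gap <- params$intergene_gap

  # locus laid out in coding order; gene_strand "-" flips the cassette
  genes <- list(
    list(id = "hsdR_1", label = "hsdR", seq = hsdr, strand = "+"),
    list(id = "hsdM_1", label = "hsdM", seq = hsdm, strand = "+"),
    list(id = "hsdS_1", label = "hsdS", seq = hsds_expr, strand = "+"),
    list(id = "hsdS_2", label = "hsdS",
         seq = reverse_complement(hsds_silent_coding), strand = "-"),
    list(id = "int_1", label = "recombinase/integrase", seq = recomb,
         strand = "+"))
  cassette <- character(0)
  rel <- NULL
  pos <- 1L
  for (g in genes) {
    rel <- rbind(rel, data.frame(gene_id = g$id, start = pos,
                                 end = pos + nchar(g$seq) - 1L,
                                 strand = g$strand, product_label = g$label,
                                 stringsAsFactors = FALSE))
    cassette <- c(cassette, g$seq, rand_dna(gap, gc))
    pos <- pos + nchar(g$seq) + gap
  }
  cassette <- paste(cassette, collapse = "")
  cassette_len <- nchar(cassette)

  if (params$gene_strand == "-") {
    cassette <- reverse_complement(cassette)
    rel <- transform(rel,
                     start = cassette_len - end + 1L,
                     end = cassette_len - start + 1L,
                     strand = ifelse(strand == "+", "-", "+"))
  }

  locus_end <- params$locus_start + cassette_len - 1L
  if (locus_end > params$genome_len)
    stop(sprintf("locus (%d bp at %d) does not fit in a %d-bp genome",
                 cassette_len, params$locus_start, params$genome_len))

  genome_seq <- rand_dna(params$genome_len, gc)
  genome_seq <- splice_in(genome_seq, params$locus_start, cassette)

  ann <- data.frame(gene_id = rel$gene_id, contig_id = params$contig_id,
                    start = params$locus_start + rel$start - 1L,
                    end = params$locus_start + rel$end - 1L,
                    strand = rel$strand, product_label = rel$product_label,
                    stringsAsFactors = FALSE)
  ann <- ann[order(ann$start), ]
  rownames(ann) <- NULL

  expr <- ann[ann$gene_id == "hsdS_1", ]
  sil <- ann[ann$gene_id == "hsdS_2", ]

  # gene-local repeat coordinates in the expressed hsdS (coding
  # orientation): ATG | pad | leader | TRD5 | mid | TRD3 | TAA
  leader_g <- c(3L + pad_len + 1L, 3L + pad_len + leader_len)
  mid_g <- leader_g[2] + params$trd5_len + c(1L, mid_len)
  trd_truth <- list(leader_ir = leader_g,
                    trd5 = c(leader_g[2] + 1L, mid_g[1] - 1L),
                    mid_ir = mid_g,
                    trd3 = c(mid_g[2] + 1L, nchar(hsds_expr)))

  # genome coordinates of the repeat copies inside the silent gene (same
  # coding-local offsets; mapped through the silent gene's annotation)
  sil_genome <- function(iv) {
    if (sil$strand == "-") c(sil$end - iv[2] + 1L, sil$end - iv[1] + 1L)
    else c(sil$start + iv[1] - 1L, sil$start + iv[2] - 1L)
  }
  lead_part <- sil_genome(leader_g)
  mid_part <- sil_genome(mid_g)
  partner_side <- if (lead_part[1] > expr$end) "downstream" else "upstream"

  truth <- data.frame(
    kind = c("leader_ir", "mid_ir"),
    side = partner_side,
    gene_start = c(leader_g[1], mid_g[1]),
    gene_end = c(leader_g[2], mid_g[2]),
    partner_start = c(lead_part[1], mid_part[1]),
    partner_end = c(lead_part[2], mid_part[2]),
    length = c(leader_len, mid_len),
    mismatches = 0L,
    stringsAsFactors = FALSE)

  # --- decoys ------------------------------------------------------------
  window_default <- 30000L
  decoy_at <- locus_end + 2000L
  plant_decoy <- function(kind) {
    src <- switch(kind,
      below_min_len = list(g = c(10L, 28L), mm = 0L, invert = TRUE),
      mismatched = list(g = c(40L, 69L), mm = 1L, invert = TRUE),
      beyond_window = list(g = c(80L, 139L), mm = 0L, invert = TRUE),
      direct_repeat = list(g = c(150L, 209L), mm = 0L, invert = FALSE))
    len <- src$g[2] - src$g[1] + 1L
    # work in genome frame: "inverted" means the planted copy is the
    # reverse complement of the gene-region segment as it lies on the
    # genome, whatever strand the gene is annotated on
    glen <- nchar(hsds_expr)
    raw_gene <- if (params$gene_strand == "-") reverse_complement(hsds_expr)
                else hsds_expr
    riv <- if (params$gene_strand == "-")
      c(glen - src$g[2] + 1L, glen - src$g[1] + 1L) else src$g
    frag <- substr(raw_gene, riv[1], riv[2])
    if (src$mm > 0L) {
      midpos <- (len + 1L) %/% 2L
      orig <- substr(frag, midpos, midpos)
      substr(frag, midpos, midpos) <- setdiff(c("A", "C", "G", "T"), orig)[1]
    }
    planted <- if (src$invert) reverse_complement(frag) else frag
    at <- if (kind == "beyond_window") expr$end + window_default + 1000L
          else decoy_at
    if (at < 2L || at + len > params$genome_len)
      stop(sprintf("decoy '%s' does not fit in a %d-bp genome", kind,
                   params$genome_len))
    genome_seq <<- splice_in(genome_seq, at, planted)
    if (src$invert) {
      # guard bases so the planted copy cannot extend past its ends
      comp1 <- function(x) chartr("ACGT", "TGCA", x)
      left_avoid <- comp1(substr(raw_gene, riv[2] + 1L, riv[2] + 1L))
      right_avoid <- comp1(substr(raw_gene, riv[1] - 1L, riv[1] - 1L))
      genome_seq <<- force_char_diff(genome_seq, at - 1L, left_avoid)
      genome_seq <<- force_char_diff(genome_seq, at + len, right_avoid)
    }
    decoy_at <<- decoy_at + len + 200L
    data.frame(kind = paste0("decoy_", kind),
               side = if (at > expr$end) "downstream" else "upstream",
               gene_start = src$g[1], gene_end = src$g[2],
               partner_start = at, partner_end = at + len - 1L,
               length = len, mismatches = src$mm,
               stringsAsFactors = FALSE)
  }
  for (kind in params$decoys) truth <- rbind(truth, plant_decoy(kind))

  min_len_default <- 20L
  truth$distance <- as.integer(ifelse(
    truth$side == "upstream", expr$start - truth$partner_end - 1L,
    truth$partner_start - expr$end - 1L))
  truth$expected_detected <- truth$length >= min_len_default &
    truth$distance <= window_default & truth$mismatches == 0L &
    !grepl("direct_repeat", truth$kind)

  genome <- structure(stats::setNames(genome_seq, params$contig_id),
                      class = "genome_set")
  structure(list(genome = genome, annotations = ann, truth = truth,
                 trd_truth = trd_truth,
                 variants = list(trd5 = trd5, trd3 = trd3,
                                 leader = leader, mid = mid,
                                 hsds_expr = hsds_expr,
                                 hsds_silent = hsds_silent_coding),
                 params = params),
            class = "sim_genome")
}

#' @export
print.sim_genome <- function(x, ...) {
  cat(sprintf("sim_genome (seed %d): %d bp, %d annotations, %d truth rows\n",
              x$params$seed, nchar(x$genome[[1]]), nrow(x$annotations),
              nrow(x$truth)))
  invisible(x)
}

#' Write a simulated fixture to disk
#'
#' Writes `genome.fasta`, `annotations.gff3` and `truth.tsv` into a
#' directory; the files round-trip losslessly through [read_genome()] and
#' [read_annotations()].
#'
#' @param sim A `sim_genome` object.
#' @param out_dir Output directory (created if needed).
#' @return Named character vector of the three paths, invisibly.
#' @export
write_fixture <- function(sim, out_dir) {
  stopifnot(inherits(sim, "sim_genome"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) stop("cannot create output directory ", out_dir)
  paths <- c(genome = file.path(out_dir, "genome.fasta"),
             annotations = file.path(out_dir, "annotations.gff3"),
             truth = file.path(out_dir, "truth.tsv"))
  write_genome(sim$genome, paths[["genome"]])
  write_annotations_gff3(sim$annotations, paths[["annotations"]])
  utils::write.table(sim$truth, paths[["truth"]], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(paths)
}
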