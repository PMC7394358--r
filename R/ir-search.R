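# Maximal 100%-identity inverted-repeat detection between a gene and its
# flanking windows: k-mer seed-and-extend, a dynamic-programming brute-force
# oracle, and redundancy filtering.

# Replace every character outside ACGT with a sentinel so that ambiguity
# codes (including N) can never satisfy the 100%-identity criterion. The two
# sides get different sentinels so N never matches N.
mask_ambiguous <- function(seq, sentinel) {
  gsub("[^ACGT]", sentinel, seq)
}

# Oriented transform of the window for matching: under the default
# reverse-complement sense a gene/window inverted repeat is an exact forward
# match between the gene and revcomp(window); under the plain reverse sense,
# between the gene and reverse(window).
window_transform <- function(window_seq, repeat_sense) {
  if (repeat_sense == "reverse-complement") reverse_complement(window_seq)
  else reverse_seq(window_seq)
}

# Map an interval on the transformed (reversed) window back to window
# coordinates. The transform is a reversal either way, so position b in the
# transformed string is position W - b + 1 in the window.
map_transformed_interval <- function(b_start, b_end, window_len) {
  list(start = window_len - b_end + 1L, end = window_len - b_start + 1L)
}

#' Tile a gene into staggered fragments
#'
#' Decomposes a sequence into k-bp fragments staggered by a fixed number of
#' bases (fragment 1 = bp 1..k, fragment 2 = bp 1+stagger..k+stagger, ...).
#' These tiles are the seeds of the inverted-repeat search.
#'
#' @param gene_seq DNA string.
#' @param k Fragment length in bases (>= 1).
#' @param stagger Offset between successive fragments in bases (>= 1).
#' @return A `data.frame` with columns `offset` (1-based start within the
#'   gene) and `fragment`; zero rows when the gene is shorter than `k`.
#' @export
tile_fragments <- function(gene_seq, k = 20L, stagger = 1L) {
  k <- as.integer(k); stagger <- as.integer(stagger)
  stopifnot(k >= 1L, stagger >= 1L)
  n <- nchar(gene_seq)
  if (n < k)
    return(data.frame(offset = integer(0), fragment = character(0)))
  offsets <- seq.int(1L, n - k + 1L, by = stagger)
  data.frame(offset = offsets,
             fragment = substring(gene_seq, offsets, offsets + k - 1L),
             stringsAsFactors = FALSE)
}

# Internal engine: all maximal exact matches of length >= k between two
# plain strings a (gene) and b (already-transformed window), ambiguity
# characters pre-masked. Returns a data.frame with 1-based coordinates
# a_start, b_start, length. gene tiles are taken every `stagger` bases;
# b is k-merized at every position.
maximal_exact_matches <- function(a, b, k, stagger = 1L) {
  empty <- data.frame(a_start = integer(0), b_start = integer(0),
                      length = integer(0))
  n <- nchar(a); m <- nchar(b)
  if (n < k || m < k) return(empty)

  a_off <- seq.int(1L, n - k + 1L, by = stagger)
  a_kmers <- substring(a, a_off, a_off + k - 1L)
  b_off <- seq.int(1L, m - k + 1L)
  b_kmers <- substring(b, b_off, b_off + k - 1L)

  common <- intersect(unique(a_kmers), unique(b_kmers))
  common <- common[!grepl("[^ACGT]", common)]
  if (length(common) == 0L) return(empty)

  a_keep <- a_off[a_kmers %in% common]
  bpos_by_kmer <- split(b_off[b_kmers %in% common],
                        b_kmers[b_kmers %in% common])
  hits_b <- bpos_by_kmer[substring(a, a_keep, a_keep + k - 1L)]
  seed_a <- rep(a_keep, lengths(hits_b))
  seed_b <- unlist(hits_b, use.names = FALSE)
  if (length(seed_a) == 0L) return(empty)

  if (stagger == 1L) {
    # A seed whose predecessor (a-1, b-1) is also a seed lies inside the
    # same diagonal run; keeping only run-start seeds makes every kept seed
    # left-maximal already.
    keys <- paste(seed_a, seed_b)
    keep <- !(paste(seed_a - 1L, seed_b - 1L) %in% keys)
    seed_a <- seed_a[keep]; seed_b <- seed_b[keep]
  }

  av <- strsplit(a, "", fixed = TRUE)[[1]]
  bv <- strsplit(b, "", fixed = TRUE)[[1]]
  out_a <- integer(0); out_b <- integer(0); out_len <- integer(0)
  for (i in seq_along(seed_a)) {
    sa <- seed_a[i]; sb <- seed_b[i]
    # extend left (no-op when stagger == 1, see above)
    while (sa > 1L && sb > 1L && av[sa - 1L] == bv[sb - 1L]) {
      sa <- sa - 1L; sb <- sb - 1L
    }
    ea <- seed_a[i] + k - 1L; eb <- seed_b[i] + k - 1L
    while (ea < n && eb < m && av[ea + 1L] == bv[eb + 1L]) {
      ea <- ea + 1L; eb <- eb + 1L
    }
    out_a <- c(out_a, sa); out_b <- c(out_b, sb)
    out_len <- c(out_len, ea - sa + 1L)
  }
  res <- data.frame(a_start = out_a, b_start = out_b, length = out_len)
  res <- unique(res)
  res[order(res$a_start, res$b_start), , drop = FALSE]
}

# Shared wrap-up: transformed-frame matches -> gene/window-frame hit table.
matches_to_hits <- function(mm, window_len, config) {
  if (nrow(mm) > 0L && !is.null(config$max_report_len)) {
    mm$length <- pmin(mm$length, config$max_report_len)
  }
  win <- map_transformed_interval(mm$b_start, mm$b_start + mm$length - 1L,
                                  window_len)
  hits <- data.frame(gene_start = mm$a_start,
                     gene_end = mm$a_start + mm$length - 1L,
                     window_start = win$start, window_end = win$end,
                     length = mm$length)
  hits <- hits[order(hits$gene_start, hits$window_start), , drop = FALSE]
  rownames(hits) <- NULL
  hits
}

#' Find all maximal inverted repeats between a gene and a window
#'
#' Reports every maximal exact match of length >= `config$min_ir_len`
#' between `gene_seq` and the reverse complement of `window_seq` (or the
#' plain reversal under `repeat_sense = "reverse"`). Seeds are
#' `min_ir_len`-bp gene tiles located in the transformed window by exact
#' hashing, then extended to maximality in both directions; one hit is
#' reported per maximal diagonal run. Ambiguity characters (including N)
#' never match. There is no upper length cap unless `max_report_len` is set.
#'
#' @param gene_seq,window_seq DNA strings (normalized; see
#'   [normalize_seq()]).
#' @param config An `ir_config`.
#' @return A `data.frame` with columns `gene_start`, `gene_end`,
#'   `window_start`, `window_end`, `length`; all coordinates 1-based
#'   inclusive and local to each input string. Rows are sorted by
#'   `(gene_start, window_start)`.
#' @seealso [brute_force_inverted_repeats()] for the quadratic oracle,
#'   [filter_redundant()] to drop nested hits, [scan_gene()] for the
#'   genome-anchored driver.
#' @export
find_inverted_repeats <- function(gene_seq, window_seq,
                                  config = search_config()) {
  a <- mask_ambiguous(gene_seq, "!")
  b <- mask_ambiguous(window_transform(window_seq, config$repeat_sense), "?")
  mm <- maximal_exact_matches(a, b, config$min_ir_len, config$tile_stagger)
  matches_to_hits(mm, nchar(window_seq), config)
}

#' Brute-force inverted-repeat oracle
#'
#' Independent quadratic reference for [find_inverted_repeats()]: builds the
#' full match matrix between the gene and the transformed window and reads
#' maximal runs off its diagonals by dynamic programming. Intended for
#' tests; refuses inputs whose product exceeds `max_cells`.
#'
#' @param gene_seq,window_seq DNA strings.
#' @param min_len Minimum repeat length in bases.
#' @param repeat_sense As in [search_config()].
#' @param max_cells Size guard on `nchar(gene) * nchar(window)`.
#' @return Hit `data.frame` in the same shape and order as
#'   [find_inverted_repeats()].
#' @export
brute_force_inverted_repeats <- function(gene_seq, window_seq, min_len = 20L,
                                         repeat_sense = "reverse-complement",
                                         max_cells = 2.2e7) {
  min_len <- as.integer(min_len)
  n <- nchar(gene_seq); m <- nchar(window_seq)
  if (as.double(n) * m > max_cells)
    stop("input too large for the brute-force oracle (",
         format(as.double(n) * m, big.mark = ","), " cells)")
  a <- mask_ambiguous(gene_seq, "!")
  b <- mask_ambiguous(window_transform(window_seq, repeat_sense), "?")
  empty <- data.frame(a_start = integer(0), b_start = integer(0),
                      length = integer(0))
  if (n < min_len || m < min_len)
    return(matches_to_hits(empty, m, search_config(min_ir_len = max(1L, min_len))))
  av <- strsplit(a, "", fixed = TRUE)[[1]]
  bv <- strsplit(b, "", fixed = TRUE)[[1]]
  prev <- integer(m)
  ends_i <- integer(0); ends_j <- integer(0); ends_len <- integer(0)
  for (i in seq_len(n)) {
    eq <- bv == av[i]
    cur <- (c(0L, prev[-m]) + 1L) * eq
    # runs from row i-1 are maximal where the next diagonal cell is 0
    if (i > 1L) {
      done <- which(prev >= min_len & c(cur[-1L], 0L) == 0L)
      if (length(done)) {
        ends_i <- c(ends_i, rep.int(i - 1L, length(done)))
        ends_j <- c(ends_j, done)
        ends_len <- c(ends_len, prev[done])
      }
    }
    prev <- cur
  }
  done <- which(prev >= min_len)
  if (length(done)) {
    ends_i <- c(ends_i, rep.int(n, length(done)))
    ends_j <- c(ends_j, done)
    ends_len <- c(ends_len, prev[done])
  }
  mm <- data.frame(a_start = ends_i - ends_len + 1L,
                   b_start = ends_j - ends_len + 1L,
                   length = ends_len)
  cfg <- search_config(min_ir_len = min_len, repeat_sense = repeat_sense)
  matches_to_hits(mm, m, cfg)
}

#' Remove redundant (nested) repeat hits
#'
#' Drops every hit whose gene interval and partner interval are both
#' contained within those of another hit; exact duplicates collapse to one.
#' The result is an antichain under simultaneous containment.
#'
#' @param hits Hit `data.frame` from one gene/window pair, with columns
#'   `gene_start`, `gene_end` and either `window_start`/`window_end` or
#'   `partner_start`/`partner_end`.
#' @return The filtered `data.frame`, original column set preserved.
#' @export
filter_redundant <- function(hits) {
  if (nrow(hits) <= 1L) return(hits)
  ps <- if ("window_start" %in% names(hits)) hits$window_start else hits$partner_start
  pe <- if ("window_end" %in% names(hits)) hits$window_end else hits$partner_end
  gs <- hits$gene_start; ge <- hits$gene_end
  hits <- hits[!duplicated(data.frame(gs, ge, ps, pe)), , drop = FALSE]
  ps <- if ("window_start" %in% names(hits)) hits$window_start else hits$partner_start
  pe <- if ("window_end" %in% names(hits)) hits$window_end else hits$partner_end
  gs <- hits$gene_start; ge <- hits$gene_end
  n <- nrow(hits)
  keep <- rep(TRUE, n)
  for (i in seq_len(n)) {
    contained <- gs >= gs[i] & ge <= ge[i] & ps >= ps[i] & pe <= pe[i]
    contained[i] <- FALSE
    keep[contained] <- FALSE
  }
  out <- hits[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Scan one gene's flanks for inverted repeats
#'
#' The per-gene driver of the survey: normalizes the gene to coding
#' orientation (unless `legacy_strand`), extracts both flank windows,
#' searches each for maximal inverted repeats, filters nested hits, and maps
#' partner coordinates back to the genome.
#'
#' @param genome A `genome_set`.
#' @param gene One-row annotation `data.frame` with resolved strand (`+` or
#'   `-`); use [locate_gene()] when only the gene sequence is known.
#' @param config An `ir_config`.
#' @return A `data.frame` of class `ir_hits` with columns `gene_id`, `side`
#'   (`upstream`/`downstream`), `gene_start`, `gene_end` (1-based within the
#'   gene, coding orientation), `partner_contig`, `partner_start`,
#'   `partner_end` (genome coordinates), `length`, and `distance` (bases
#'   between the nearest gene and partner boundaries).
#' @export
scan_gene <- function(genome, gene, config = search_config()) {
  if (gene$strand[1] == "*")
    stop("gene strand unresolved; run locate_gene() first")
  raw <- substr(get_contig(genome, gene$contig_id[1]),
                gene$start[1], gene$end[1])
  glen <- nchar(raw)
  # An inverted repeat is defined in genome frame: a gene-region segment
  # whose reverse complement occurs in the flank. The search therefore runs
  # on the plus-strand gene sequence; for minus-strand genes the gene-side
  # coordinates are afterwards reflected into coding orientation (unless
  # legacy_strand, which keeps plus-strand gene coordinates).
  flip_gene_coords <- gene$strand[1] == "-" && !config$legacy_strand
  win <- suppressMessages(extract_window(genome, gene, config))

  one_side <- function(side, wseq, offset) {
    if (nchar(wseq) < config$min_ir_len) return(NULL)
    h <- find_inverted_repeats(raw, wseq, config)
    if (nrow(h) == 0L) return(NULL)
    h <- filter_redundant(h)
    if (flip_gene_coords) {
      gs <- glen - h$gene_end + 1L
      h$gene_end <- glen - h$gene_start + 1L
      h$gene_start <- gs
    }
    partner_start <- offset + h$window_start - 1L
    partner_end <- offset + h$window_end - 1L
    dist <- if (side == "upstream") gene$start[1] - partner_end - 1L
            else partner_start - gene$end[1] - 1L
    data.frame(gene_id = gene$gene_id[1], side = side,
               gene_start = h$gene_start, gene_end = h$gene_end,
               partner_contig = gene$contig_id[1],
               partner_start = partner_start, partner_end = partner_end,
               length = h$length, distance = as.integer(dist),
               stringsAsFactors = FALSE)
  }
  out <- rbind(one_side("upstream", win$upstream, win$upstream_offset),
               one_side("downstream", win$downstream, win$downstream_offset))
  if (is.null(out))
    out <- data.frame(gene_id = character(0), side = character(0),
                      gene_start = integer(0), gene_end = integer(0),
                      partner_contig = character(0),
                      partner_start = integer(0), partner_end = integer(0),
                      length = integer(0), distance = integer(0),
                      stringsAsFactors = FALSE)
  out <- out[order(out$side, out$gene_start, out$partner_start), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("ir_hits", "data.frame")
  out
}

#' @export
print.ir_hits <- function(x, ...) {
  cat(sprintf("ir_hits: %d maximal inverted repeat(s)", nrow(x)))
  if (nrow(x)) cat(sprintf(", lengths %d-%d bp", min(x$length), max(x$length)))
  cat("\n")
  print.data.frame(x, ...)
  invisible(x)
}

#' Export hits as TSV
#'
#' @param hits An `ir_hits` table (from [scan_gene()] or row-bound across
#'   genes).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_hits_tsv <- function(hits, path) {
  cols <- c("gene_id", "side", "gene_start", "gene_end", "partner_contig",
            "partner_start", "partner_end", "length", "distance")
  utils::write.table(as.data.frame(hits)[, cols], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a hits TSV written by [write_hits_tsv()]
#' @param path Input path.
#' @return An `ir_hits` table.
#' @export
read_hits_tsv <- function(path) {
  h <- utils::read.table(path, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE)
  for (cl in c("gene_start", "gene_end", "partner_start", "partner_end",
               "length", "distance"))
    h[[cl]] <- as.integer(h[[cl]])
  class(h) <- c("ir_hits", "data.frame")
  h
}

#' Export hit pairs as BED6
#'
#' Writes two BED records per hit (the gene-side interval and the partner
#' interval, both in genome coordinates, 0-based half-open), named
#' `gene_id:index`; the strand column encodes relative orientation (`+` for
#' the gene side, `-` for the inverted partner).
#'
#' @param hits An `ir_hits` table.
#' @param genes Annotation `data.frame` covering every `gene_id` in `hits`
#'   (needed to place gene-local coordinates on the genome).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_hits_bed <- function(hits, genes, path) {
  if (nrow(hits) == 0L) {
    writeLines(character(0), path)
    return(invisible(path))
  }
  idx <- match(hits$gene_id, genes$gene_id)
  if (anyNA(idx)) stop("hits reference gene_ids absent from annotations")
  gs <- genes$start[idx]; ge <- genes$end[idx]; gstrand <- genes$strand[idx]
  # gene-local coding coordinates -> genome coordinates
  g_start <- ifelse(gstrand == "-", ge - hits$gene_end + 1L,
                    gs + hits$gene_start - 1L)
  g_end <- ifelse(gstrand == "-", ge - hits$gene_start + 1L,
                  gs + hits$gene_end - 1L)
  nm <- paste0(hits$gene_id, ":", seq_len(nrow(hits)))
  bed <- rbind(
    data.frame(chrom = genes$contig_id[idx], start = g_start - 1L,
               end = g_end, name = nm, score = hits$length, strand = "+"),
    data.frame(chrom = hits$partner_contig, start = hits$partner_start - 1L,
               end = hits$partner_end, name = nm, score = hits$length,
               strand = "-"))
  bed <- bed[order(bed$name, bed$start), ]
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

# Re-verify a hit table character by character (soundness helper, exported
# for use in validation workflows).

#' Verify reported hits against the sequences
#'
#' Re-checks, character by character, that every hit satisfies the identity
#' `gene[gene_start..gene_end] == revcomp(window[window_start..window_end])`
#' (or plain reversal under `repeat_sense = "reverse"`).
#'
#' @param hits Hit `data.frame` with window-local coordinates.
#' @param gene_seq,window_seq The scanned strings.
#' @param repeat_sense As in [search_config()].
#' @return Logical vector, one element per hit.
#' @export
verify_hits <- function(hits, gene_seq, window_seq,
                        repeat_sense = "reverse-complement") {
  if (nrow(hits) == 0L) return(logical(0))
  vapply(seq_len(nrow(hits)), function(i) {
    g <- substr(gene_seq, hits$gene_start[i], hits$gene_end[i])
    w <- substr(window_seq, hits$window_start[i], hits$window_end[i])
    wt <- if (repeat_sense == "reverse-complement") reverse_complement(w)
          else reverse_seq(w)
    nchar(g) > 0L && g == wt && !grepl("[^ACGT]", g)
  }, logical(1))
}
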