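# DNA sequence primitives, gene location and flank-window extraction.

IUPAC_CHARS <- c("A", "C", "G", "T", "N", "R", "Y", "S", "W", "K", "M",
                 "B", "D", "H", "V", "U")
IUPAC_FROM <- "ACGTUNRYSWKMBDHV"
IUPAC_TO   <- "TGCAANYRSWMKVHDB"

#' Normalize a DNA sequence string
#'
#' Uppercases the input and validates it against the IUPAC nucleotide
#' alphabet. Ambiguity codes are preserved; they are simply never allowed to
#' participate in a 100%-identity match downstream.
#'
#' @param seq A single character string of nucleotides.
#' @param what Label used in error messages.
#' @return The uppercased sequence.
#' @export
normalize_seq <- function(seq, what = "sequence") {
  stopifnot(is.character(seq), length(seq) == 1L, !is.na(seq))
  seq <- toupper(seq)
  bad <- gregexpr(sprintf("[^%s]", paste(IUPAC_CHARS, collapse = "")), seq)[[1]]
  if (bad[1] != -1L) {
    stop(sprintf("invalid character '%s' in %s at position %d",
                 substr(seq, bad[1], bad[1]), what, bad[1]), call. = FALSE)
  }
  seq
}

#' Reverse complement of a DNA string
#'
#' Base-pairs and reverses the input. Ambiguity codes map to their IUPAC
#' complements (N to N, R to Y, ...). Applying the function twice returns the
#' input.
#'
#' @param seq A single DNA string over the IUPAC alphabet.
#' @return The reverse-complemented string.
#' @examples
#' reverse_complement("AAACCC")  # "GGGTTT"
#' @export
reverse_complement <- function(seq) {
  seq <- normalize_seq(seq)
  if (nchar(seq) == 0L) return(seq)
  comp <- chartr(IUPAC_FROM, IUPAC_TO, seq)
  paste(rev(strsplit(comp, "", fixed = TRUE)[[1]]), collapse = "")
}

# Plain reversal without complementation (repeat_sense = "reverse").
reverse_seq <- function(seq) {
  if (nchar(seq) == 0L) return(seq)
  paste(rev(strsplit(seq, "", fixed = TRUE)[[1]]), collapse = "")
}

#' Search configuration
#'
#' Holds the tunable parameters of the inverted-repeat search. Defaults are
#' the survey settings: 20-bp minimum repeat length, 30-kb flanks on each
#' side of the anchor gene, tiles staggered by 1 bp, and reverse-complement
#' ("inverted") matching.
#'
#' @param min_ir_len Minimum reported repeat length in bases (>= 1).
#' @param window Flank width in bases on each side of the gene (>= 0).
#' @param tile_stagger Stagger between successive gene tiles in bases (>= 1).
#'   Values above 1 trade sensitivity for speed and are not used by the
#'   default workflow.
#' @param repeat_sense `"reverse-complement"` matches the gene against the
#'   reverse complement of the flank (biological inversion); `"reverse"`
#'   matches against the plain reversal, provided for fidelity testing.
#' @param include_gene_body If `TRUE`, flank windows extend over the gene
#'   body as well (upstream window runs to the gene end, downstream window
#'   starts at the gene start). Default `FALSE`: flanks abut but never
#'   overlap the gene.
#' @param max_report_len Optional cap on reported repeat length; a maximal
#'   hit longer than the cap is truncated to its first `max_report_len`
#'   gene-side bases. `NULL` (default) reports true maximal lengths.
#' @param legacy_strand If `TRUE`, genes annotated on the minus strand are
#'   tiled as they appear on the plus strand instead of being normalized to
#'   coding orientation (an asymmetric historical mode). Default `FALSE`.
#' @return An object of class `ir_config`.
#' @export
search_config <- function(min_ir_len = 20L, window = 30000L, tile_stagger = 1L,
                          repeat_sense = c("reverse-complement", "reverse"),
                          include_gene_body = FALSE, max_report_len = NULL,
                          legacy_strand = FALSE) {
  repeat_sense <- match.arg(repeat_sense)
  min_ir_len <- as.integer(min_ir_len)
  window <- as.integer(window)
  tile_stagger <- as.integer(tile_stagger)
  if (is.na(min_ir_len) || min_ir_len < 1L) stop("min_ir_len must be >= 1")
  if (is.na(window) || window < 0L) stop("window must be >= 0")
  if (is.na(tile_stagger) || tile_stagger < 1L) stop("tile_stagger must be >= 1")
  if (!is.null(max_report_len)) {
    max_report_len <- as.integer(max_report_len)
    if (is.na(max_report_len) || max_report_len < min_ir_len)
      stop("max_report_len must be >= min_ir_len")
  }
  structure(list(min_ir_len = min_ir_len, window = window,
                 tile_stagger = tile_stagger, repeat_sense = repeat_sense,
                 include_gene_body = isTRUE(include_gene_body),
                 max_report_len = max_report_len,
                 legacy_strand = isTRUE(legacy_strand)),
            class = "ir_config")
}

#' @export
print.ir_config <- function(x, ...) {
  cat("Inverted-repeat search configuration\n")
  cat(sprintf("  min_ir_len:    %d bp\n", x$min_ir_len))
  cat(sprintf("  window:        %d bp each side\n", x$window))
  cat(sprintf("  tile_stagger:  %d bp\n", x$tile_stagger))
  cat(sprintf("  repeat_sense:  %s\n", x$repeat_sense))
  cat(sprintf("  include_gene_body: %s\n", x$include_gene_body))
  cat(sprintf("  max_report_len: %s\n",
              if (is.null(x$max_report_len)) "none" else x$max_report_len))
  cat(sprintf("  legacy_strand: %s\n", x$legacy_strand))
  invisible(x)
}

#' Read a (multi-)FASTA genome
#'
#' @param path Path to a FASTA file, wrapped or unwrapped, one record per
#'   contig.
#' @return A named character vector of uppercased contig sequences, class
#'   `genome_set`; names are the first whitespace-delimited token of each
#'   header.
#' @export
read_genome <- function(path) {
  set <- Biostrings::readDNAStringSet(path)
  seqs <- toupper(as.character(set))
  names(seqs) <- sub("\\s.*$", "", names(set))
  if (anyDuplicated(names(seqs)))
    stop("duplicate contig ids in ", path)
  class(seqs) <- "genome_set"
  seqs
}

#' Write a genome to FASTA
#'
#' @param genome Named character vector of contig sequences.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_genome <- function(genome, path) {
  set <- Biostrings::DNAStringSet(unclass(genome))
  Biostrings::writeXStringSet(set, path, width = 70L)
  invisible(path)
}

#' @export
print.genome_set <- function(x, ...) {
  cat(sprintf("genome_set: %d contig(s), %s bp total\n",
              length(x), format(sum(nchar(x)), big.mark = ",")))
  for (nm in names(x))
    cat(sprintf("  %s  %s bp\n", nm, format(nchar(x[[nm]]), big.mark = ",")))
  invisible(x)
}

get_contig <- function(genome, contig_id) {
  seq <- unclass(genome)[[contig_id]]
  if (is.null(seq))
    stop(sprintf("contig '%s' not present in genome", contig_id), call. = FALSE)
  seq
}

#' Construct a gene annotation table
#'
#' @param gene_id,contig_id Character vectors.
#' @param start,end 1-based inclusive genomic coordinates.
#' @param strand `"+"`, `"-"`, or `"*"` (unknown).
#' @param product_label Optional product text, e.g. `"hsdS"`.
#' @return A `data.frame` with one row per gene.
#' @export
gene_annotation <- function(gene_id, contig_id, start, end,
                            strand = "*", product_label = NA_character_) {
  ann <- data.frame(gene_id = as.character(gene_id),
                    contig_id = as.character(contig_id),
                    start = as.integer(start), end = as.integer(end),
                    strand = as.character(strand),
                    product_label = as.character(product_label),
                    stringsAsFactors = FALSE)
  validate_annotations(ann)
}

validate_annotations <- function(ann, genome = NULL) {
  stopifnot(is.data.frame(ann))
  need <- c("gene_id", "contig_id", "start", "end", "strand")
  miss <- setdiff(need, names(ann))
  if (length(miss)) stop("annotation table lacks columns: ",
                         paste(miss, collapse = ", "))
  if (!"product_label" %in% names(ann)) ann$product_label <- NA_character_
  ann$strand[is.na(ann$strand) | ann$strand == "" | ann$strand == "."] <- "*"
  if (!all(ann$strand %in% c("+", "-", "*")))
    stop("strand must be one of '+', '-', '*'")
  if (any(ann$start < 1L) || any(ann$end < ann$start))
    stop("annotations must satisfy 1 <= start <= end")
  if (!is.null(genome)) {
    lens <- nchar(unclass(genome))[ann$contig_id]
    if (anyNA(lens)) stop("annotation contig absent from genome")
    if (any(ann$end > lens)) stop("annotation end exceeds contig length")
  }
  ann
}

#' Read gene annotations from GFF3 or TSV
#'
#' Accepts GFF3 (gene id taken from the `ID`, `locus_tag` or `Name`
#' attribute; product label from `product` or `gene`) or a flat TSV with
#' header `gene_id contig_id start end strand` (strand blank or `.` means
#' unknown, as in REBASE-style dumps) and an optional `product_label`
#' column.
#'
#' @param path Input file.
#' @param format `"auto"` (by extension), `"gff3"` or `"tsv"`.
#' @return Annotation `data.frame` (see [gene_annotation()]).
#' @export
read_annotations <- function(path, format = c("auto", "gff3", "tsv")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.gff3?$", path, ignore.case = TRUE)) "gff3" else "tsv"
  }
  if (format == "gff3") {
    gr <- tryCatch(rtracklayer::import(path, format = "gff3"),
                   error = function(e) stop("malformed GFF3 '", path, "': ",
                                            conditionMessage(e), call. = FALSE))
    md <- as.data.frame(S4Vectors::mcols(gr))
    pick <- function(cols) {
      for (cl in cols) if (cl %in% names(md)) {
        v <- as.character(md[[cl]])
        if (any(!is.na(v))) return(v)
      }
      rep(NA_character_, length(gr))
    }
    ids <- pick(c("ID", "locus_tag", "Name"))
    ids[is.na(ids)] <- paste0("feature_", which(is.na(ids)))
    ann <- data.frame(
      gene_id = ids,
      contig_id = as.character(GenomicRanges::seqnames(gr)),
      start = GenomicRanges::start(gr), end = GenomicRanges::end(gr),
      strand = as.character(GenomicRanges::strand(gr)),
      product_label = pick(c("product", "gene")),
      stringsAsFactors = FALSE)
  } else {
    ann <- utils::read.table(path, header = TRUE, sep = "\t",
                             colClasses = "character", quote = "",
                             comment.char = "", na.strings = c("NA", ""))
    ann$start <- as.integer(ann$start)
    ann$end <- as.integer(ann$end)
    if (!"strand" %in% names(ann)) ann$strand <- "*"
  }
  validate_annotations(ann)
}

#' Write annotations to GFF3
#'
#' @param ann Annotation `data.frame`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_annotations_gff3 <- function(ann, path) {
  ann <- validate_annotations(ann)
  gr <- GenomicRanges::GRanges(
    seqnames = ann$contig_id,
    ranges = IRanges::IRanges(ann$start, ann$end),
    strand = ann$strand)
  S4Vectors::mcols(gr)$type <- "gene"
  S4Vectors::mcols(gr)$ID <- ann$gene_id
  S4Vectors::mcols(gr)$product <- ann$product_label
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Locate a gene sequence in a genome
#'
#' Finds the unique exact occurrence of `gene_seq` on either strand of any
#' contig and returns its coordinates and strand. REBASE-style annotations
#' lack strand information; this resolves it by alignment, as the survey
#' workflow requires.
#'
#' @param gene_seq The gene's nucleotide sequence in coding orientation.
#' @param genome A `genome_set` (see [read_genome()]).
#' @param gene_id Identifier for the returned annotation row.
#' @param product_label Optional product label to attach.
#' @return One-row annotation `data.frame` with resolved strand.
#' @export
locate_gene <- function(gene_seq, genome, gene_id = "gene",
                        product_label = NA_character_) {
  gene_seq <- normalize_seq(gene_seq, "gene sequence")
  if (nchar(gene_seq) == 0L) stop("gene sequence is empty")
  rc <- reverse_complement(gene_seq)
  occ <- list()
  for (contig in names(genome)) {
    seq <- get_contig(genome, contig)
    for (hit in find_all_fixed(seq, gene_seq))
      occ[[length(occ) + 1L]] <- list(contig, hit, "+")
    for (hit in find_all_fixed(seq, rc))
      if (rc != gene_seq)  # palindromic genes occur once per site
        occ[[length(occ) + 1L]] <- list(contig, hit, "-")
  }
  if (length(occ) == 0L)
    stop(sprintf("gene not found: '%s' has no exact occurrence on either strand",
                 gene_id), call. = FALSE)
  if (length(occ) > 1L) {
    desc <- vapply(occ, function(o)
      sprintf("%s:%d-%d(%s)", o[[1]], o[[2]], o[[2]] + nchar(gene_seq) - 1L,
              o[[3]]), "")
    stop(sprintf("ambiguous location for '%s': %d occurrences (%s)",
                 gene_id, length(occ), paste(desc, collapse = ", ")),
         call. = FALSE)
  }
  o <- occ[[1]]
  gene_annotation(gene_id, o[[1]], o[[2]], o[[2]] + nchar(gene_seq) - 1L,
                  o[[3]], product_label)
}

# All start positions of exact fixed-string occurrences (may overlap).
find_all_fixed <- function(text, pattern) {
  hits <- integer(0)
  from <- 1L
  n <- nchar(pattern)
  repeat {
    at <- regexpr(pattern, substr(text, from, nchar(text)), fixed = TRUE)
    if (at == -1L) break
    pos <- from + as.integer(at) - 1L
    hits <- c(hits, pos)
    from <- pos + 1L
  }
  hits
}

#' Extract the gene sequence for an annotation, in coding orientation
#'
#' @param genome A `genome_set`.
#' @param gene One-row annotation `data.frame`.
#' @return The gene's sequence; reverse-complemented when the gene is on the
#'   minus strand.
#' @export
gene_sequence <- function(genome, gene) {
  seq <- get_contig(genome, gene$contig_id[1])
  s <- substr(seq, gene$start[1], gene$end[1])
  if (identical(gene$strand[1], "-")) reverse_complement(s) else s
}

#' Extract the flank windows around a gene
#'
#' Returns the window upstream of the gene start and downstream of the gene
#' end (genome plus-strand coordinates), clamped at contig boundaries, with
#' the genome coordinate of each window's first base so hits map back.
#'
#' @param genome A `genome_set`.
#' @param gene One-row annotation `data.frame`.
#' @param config An `ir_config` (see [search_config()]).
#' @return A list with elements `upstream`, `downstream` (strings, possibly
#'   empty), `upstream_offset`, `downstream_offset` (genome coordinate of
#'   each window's first base; `NA` for an empty window), and logical
#'   `clamped`.
#' @export
extract_window <- function(genome, gene, config = search_config()) {
  seq <- get_contig(genome, gene$contig_id[1])
  L <- nchar(seq)
  if (gene$end[1] > L) stop("gene interval exceeds contig length")
  w <- config$window
  if (config$include_gene_body) {
    up_from <- max(1L, gene$start[1] - w); up_to <- gene$end[1]
    dn_from <- gene$start[1]; dn_to <- min(L, gene$end[1] + w)
  } else {
    up_from <- max(1L, gene$start[1] - w); up_to <- gene$start[1] - 1L
    dn_from <- gene$end[1] + 1L; dn_to <- min(L, gene$end[1] + w)
  }
  up <- if (up_to >= up_from) substr(seq, up_from, up_to) else ""
  dn <- if (dn_to >= dn_from) substr(seq, dn_from, dn_to) else ""
  clamped <- (gene$start[1] - w < 1L) || (gene$end[1] + w > L)
  if (clamped && w > 0L)
    message(sprintf("window for %s clamped at contig boundary", gene$gene_id[1]))
  list(upstream = up, downstream = dn,
       upstream_offset = if (nchar(up)) up_from else NA_integer_,
       downstream_offset = if (nchar(dn)) dn_from else NA_integer_,
       clamped = clamped)
}
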