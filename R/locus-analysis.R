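# From raw repeat hits to biology: collation of identical genes, inverting
# vs incidental locus calls, TRD segmentation, allele and population state
# enumeration, and survey summaries.

is_hsds_label <- function(label) {
  !is.na(label) & grepl("hsds", label, ignore.case = TRUE)
}

#' Collate identical gene sequences
#'
#' Groups gene ids by exact sequence identity, so that a locus represented
#' by many identical annotated copies is counted once. The representative of
#' each group is its lexicographically smallest gene id.
#'
#' @param gene_ids Character vector.
#' @param sequences Character vector of the same length, normalized, coding
#'   orientation.
#' @return A `data.frame` with columns `representative`, `n_members`,
#'   `members` (comma-joined ids), one row per distinct sequence, ordered by
#'   representative.
#' @export
collate_identical_genes <- function(gene_ids, sequences) {
  stopifnot(length(gene_ids) == length(sequences))
  if (length(gene_ids) == 0L)
    return(data.frame(representative = character(0), n_members = integer(0),
                      members = character(0), stringsAsFactors = FALSE))
  groups <- split(as.character(gene_ids), sequences)
  reps <- vapply(groups, function(ids) sort(ids)[1], "")
  out <- data.frame(representative = reps,
                    n_members = lengths(groups),
                    members = vapply(groups, function(ids)
                      paste(sort(ids), collapse = ","), ""),
                    stringsAsFactors = FALSE)
  out <- out[order(out$representative), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Does a gene lack an ATG start codon?
#'
#' Reads the first codon of an annotated gene in its annotated orientation.
#' A silent hsdS' copy has no ATG at its annotated start (promoter
#' prediction is not assessed).
#'
#' @param genome A `genome_set`.
#' @param gene One-row annotation `data.frame`.
#' @return `TRUE` when the first codon is not ATG.
#' @export
is_silent_gene <- function(genome, gene) {
  s <- gene_sequence(genome, gene)
  substr(s, 1L, 3L) != "ATG"
}

#' Classify a gene's locus from its inverted-repeat hits
#'
#' A locus is `inverting` when at least one hit's partner interval overlaps
#' (>= 1 bp) a second annotation labelled hsdS; `incidental_ir` when hits
#' exist but none do; `no_ir` when there are no hits. When a partner hsdS is
#' found and a genome is supplied, the partner's start codon is inspected to
#' flag a silent copy.
#'
#' @param gene One-row annotation `data.frame` (the scanned gene).
#' @param hits `ir_hits` for that gene (already redundancy-filtered).
#' @param annotations Annotation `data.frame` of features near the gene
#'   (may include the gene itself, which is ignored as a partner).
#' @param genome Optional `genome_set` for the silent-partner check.
#' @return An object of class `locus_call`: list with `gene_id`, `category`,
#'   `hits`, `partner_gene_id`, `partner_is_silent`.
#' @export
classify_locus <- function(gene, hits, annotations, genome = NULL) {
  annotations <- validate_annotations(annotations)
  partner_gene_id <- NA_character_
  partner_is_silent <- NA
  if (nrow(hits) == 0L) {
    category <- "no_ir"
  } else {
    others <- annotations[annotations$gene_id != gene$gene_id[1], , drop = FALSE]
    if (nrow(others) > 0L && all(is.na(others$product_label)))
      warning("no product labels on neighbouring annotations; ",
              "cannot recognise a partner hsdS", call. = FALSE)
    cand <- others[is_hsds_label(others$product_label), , drop = FALSE]
    best_overlap <- 0L
    if (nrow(cand) > 0L) {
      for (j in seq_len(nrow(cand))) {
        same <- hits$partner_contig == cand$contig_id[j]
        ov <- pmin(hits$partner_end, cand$end[j]) -
              pmax(hits$partner_start, cand$start[j]) + 1L
        ov[!same] <- 0L
        tot <- sum(pmax(ov, 0L))
        if (tot > best_overlap) {
          best_overlap <- tot
          partner_gene_id <- cand$gene_id[j]
        }
      }
    }
    category <- if (!is.na(partner_gene_id)) "inverting" else "incidental_ir"
    if (!is.na(partner_gene_id) && !is.null(genome)) {
      partner <- annotations[annotations$gene_id == partner_gene_id, ,
                             drop = FALSE][1, , drop = FALSE]
      partner_is_silent <- is_silent_gene(genome, partner)
    }
  }
  structure(list(gene_id = gene$gene_id[1], category = category,
                 hits = hits, partner_gene_id = partner_gene_id,
                 partner_is_silent = partner_is_silent),
            class = "locus_call")
}

#' @export
print.locus_call <- function(x, ...) {
  cat(sprintf("locus_call: %s -> %s (%d hit(s))", x$gene_id, x$category,
              nrow(x$hits)))
  if (!is.na(x$partner_gene_id))
    cat(sprintf("; partner %s%s", x$partner_gene_id,
                if (isTRUE(x$partner_is_silent)) " (silent)" else ""))
  cat("\n")
  invisible(x)
}

#' Segment an hsdS gene into target recognition domains
#'
#' Given the two inverted-repeat intervals inside the gene (the leader
#' repeat ahead of the 5'-TRD and the mid repeat between the TRDs), returns
#' the 5'-TRD (between the repeats) and the 3'-TRD (after the mid repeat to
#' the gene end).
#'
#' @param gene_len Gene length in bases (or a gene sequence string).
#' @param leader_ir,mid_ir Length-2 integer vectors `c(start, end)`, 1-based
#'   inclusive within the gene, ordered and non-overlapping.
#' @return An object of class `trd_segmentation`: list of intervals
#'   `leader_ir`, `trd5`, `mid_ir`, `trd3`.
#' @export
segment_trds <- function(gene_len, leader_ir, mid_ir) {
  if (is.character(gene_len)) gene_len <- nchar(gene_len)
  gene_len <- as.integer(gene_len)
  leader_ir <- as.integer(leader_ir); mid_ir <- as.integer(mid_ir)
  stopifnot(length(leader_ir) == 2L, length(mid_ir) == 2L)
  if (leader_ir[1] > leader_ir[2] || mid_ir[1] > mid_ir[2] ||
      leader_ir[1] < 1L || mid_ir[2] > gene_len)
    stop("unsegmentable locus: repeat intervals out of range")
  if (leader_ir[2] >= mid_ir[1])
    stop("unsegmentable locus: repeat intervals overlap or are out of order")
  trd5 <- c(leader_ir[2] + 1L, mid_ir[1] - 1L)
  trd3 <- c(mid_ir[2] + 1L, gene_len)
  if (trd5[1] > trd5[2])
    stop("unsegmentable locus: empty 5'-TRD between the repeats")
  if (trd3[1] > trd3[2])
    stop("unsegmentable locus: empty 3'-TRD after the mid repeat")
  structure(list(leader_ir = leader_ir, trd5 = trd5, mid_ir = mid_ir,
                 trd3 = trd3, gene_len = gene_len),
            class = "trd_segmentation")
}

#' @export
print.trd_segmentation <- function(x, ...) {
  fmt <- function(iv) sprintf("%d-%d (%d bp)", iv[1], iv[2], iv[2] - iv[1] + 1L)
  cat("TRD segmentation of a", x$gene_len, "bp gene\n")
  cat("  leader IR:", fmt(x$leader_ir), "\n")
  cat("  5'-TRD:   ", fmt(x$trd5), "\n")
  cat("  mid IR:   ", fmt(x$mid_ir), "\n")
  cat("  3'-TRD:   ", fmt(x$trd3), "\n")
  invisible(x)
}

allele_labels <- function(n) {
  if (n <= 26L) return(LETTERS[seq_len(n)])
  # beyond Z: AA, AB, ...
  extra <- n - 26L
  c(LETTERS,
    paste0(LETTERS[((seq_len(extra) - 1L) %/% 26L) + 1L],
           LETTERS[((seq_len(extra) - 1L) %% 26L) + 1L]))
}

#' Enumerate the hsdS allele space of a shufflon locus
#'
#' TRD shuffling by inversion lets any 5'-TRD variant combine with any
#' 3'-TRD variant, so a locus with `n5` distinct 5'-TRDs and `n3` distinct
#' 3'-TRDs can express `n5 * n3` hsdS alleles. Alleles are labelled A, B,
#' C, ... in row-major order over (5'-TRD variant, 3'-TRD variant).
#'
#' @param trd5_variants,trd3_variants Character vectors of variant
#'   sequences (distinctness is exact identity), or single counts.
#' @return An object of class `allele_space`: list with `n5`, `n3`,
#'   `n_alleles` and `alleles` (a `data.frame` of label and variant
#'   indices).
#' @export
enumerate_alleles <- function(trd5_variants, trd3_variants) {
  as_count <- function(x, what) {
    if (is.numeric(x) && length(x) == 1L) {
      n <- as.integer(x)
    } else {
      if (length(x) == 0L) stop("empty ", what, " variant set")
      n <- length(unique(as.character(x)))
    }
    if (is.na(n) || n < 1L) stop("empty ", what, " variant set")
    n
  }
  n5 <- as_count(trd5_variants, "5'-TRD")
  n3 <- as_count(trd3_variants, "3'-TRD")
  n_alleles <- n5 * n3
  alleles <- data.frame(
    label = allele_labels(n_alleles),
    trd5 = rep(seq_len(n5), each = n3),
    trd3 = rep(seq_len(n3), times = n5),
    stringsAsFactors = FALSE)
  structure(list(n5 = n5, n3 = n3, n_alleles = n_alleles, alleles = alleles),
            class = "allele_space")
}

#' @export
print.allele_space <- function(x, ...) {
  cat(sprintf("allele_space: %d x %d TRD variants -> %d hsdS allele(s)\n",
              x$n5, x$n3, x$n_alleles))
  print.data.frame(utils::head(x$alleles, 26L), row.names = FALSE)
  if (x$n_alleles > 26L) cat("  ...\n")
  invisible(x)
}

#' Population-level methyltransferase state count
#'
#' Each biphasic (ON/OFF) mod gene doubles the number of methylation states
#' a cell can be in, and each cell expresses exactly one hsdS allele of the
#' inverting Type I locus, so a population can hold
#' `2^num_biphasic_mod * num_hsds_alleles` distinct methyltransferase
#' activity combinations.
#'
#' @param num_biphasic_mod Count of independently switching ON/OFF mod
#'   genes (>= 0).
#' @param num_hsds_alleles Count of hsdS alleles (>= 1).
#' @return The combination count (numeric).
#' @examples
#' combinatorial_states(2, 4)  # 16
#' @export
combinatorial_states <- function(num_biphasic_mod, num_hsds_alleles) {
  num_biphasic_mod <- as.integer(num_biphasic_mod)
  num_hsds_alleles <- as.integer(num_hsds_alleles)
  if (is.na(num_biphasic_mod) || num_biphasic_mod < 0L)
    stop("num_biphasic_mod must be >= 0")
  if (is.na(num_hsds_alleles) || num_hsds_alleles < 1L)
    stop("num_hsds_alleles must be >= 1")
  2^num_biphasic_mod * num_hsds_alleles
}

#' Truncate a percentage to one decimal
#'
#' Survey percentages are floored (truncated), not rounded, to one decimal:
#' 875/22107 prints as 3.9%, although rounding would give 4.0%.
#'
#' @param x Numeric percentage(s).
#' @return Character vector formatted with one decimal.
#' @export
format_percent_truncated <- function(x) {
  sprintf("%.1f", trunc(x * 10 + 1e-9) / 10)
}

#' Summarize a survey of locus calls
#'
#' @param calls List of `locus_call` objects, one per scanned gene.
#' @param collation Optional output of [collate_identical_genes()]; when
#'   given, the number of distinct-sequence loci with at least one hit is
#'   reported via group representatives.
#' @param species Optional character vector parallel to `calls` (species of
#'   each gene's genome) for a per-species rollup.
#' @return An object of class `survey_summary`: list with `total_genes`,
#'   `genes_with_ir`, `collated_with_ir` (NA without `collation`),
#'   `inverting`, `incidental`, `percent_inverting` (raw float),
#'   `percent_inverting_formatted` (truncated to one decimal), and
#'   `per_species` (`data.frame` or NULL).
#' @export
summarize_survey <- function(calls, collation = NULL, species = NULL) {
  total <- length(calls)
  cats <- vapply(calls, function(x) x$category, "")
  has_ir <- vapply(calls, function(x) nrow(x$hits) > 0L, logical(1))
  inverting <- sum(cats == "inverting")
  pct <- if (total > 0L) 100 * inverting / total else 0
  collated_with_ir <- NA_integer_
  if (!is.null(collation)) {
    ids_with_ir <- vapply(calls, function(x) x$gene_id, "")[has_ir]
    member_lists <- strsplit(collation$members, ",", fixed = TRUE)
    collated_with_ir <- sum(vapply(member_lists, function(ms)
      any(ms %in% ids_with_ir), logical(1)))
  }
  per_species <- NULL
  if (!is.null(species)) {
    stopifnot(length(species) == total)
    per_species <- do.call(rbind, lapply(split(has_ir, species), function(v)
      data.frame(n_with_ir = sum(v), n_strains = length(v))))
    per_species <- data.frame(species = rownames(per_species), per_species,
                              row.names = NULL, stringsAsFactors = FALSE)
    per_species$note <- sprintf("%d of %d strains", per_species$n_with_ir,
                                per_species$n_strains)
  }
  structure(list(total_genes = total, genes_with_ir = sum(has_ir),
                 collated_with_ir = collated_with_ir,
                 inverting = inverting,
                 incidental = sum(cats == "incidental_ir"),
                 percent_inverting = pct,
                 percent_inverting_formatted = format_percent_truncated(pct),
                 per_species = per_species),
            class = "survey_summary")
}

#' @export
print.survey_summary <- function(x, ...) {
  cat("Survey summary\n")
  cat(sprintf("  genes scanned:            %d\n", x$total_genes))
  cat(sprintf("  genes with >=1 IR:        %d\n", x$genes_with_ir))
  if (!is.na(x$collated_with_ir))
    cat(sprintf("  collated loci with >=1 IR: %d\n", x$collated_with_ir))
  cat(sprintf("  inverting loci:           %d\n", x$inverting))
  cat(sprintf("  incidental-IR loci:       %d\n", x$incidental))
  cat(sprintf("  percent inverting:        %s%% (raw %.4f)\n",
              x$percent_inverting_formatted, x$percent_inverting))
  if (!is.null(x$per_species)) {
    cat("  per species:\n")
    for (i in seq_len(nrow(x$per_species)))
      cat(sprintf("    %s: %s\n", x$per_species$species[i],
                  x$per_species$note[i]))
  }
  invisible(x)
}

#' Combine disjoint phase-variation mechanism percentages
#'
#' Arithmetic sum of percentages of Type I systems that are phase-variable
#' by different, non-overlapping mechanisms (e.g. hsdM SSR tracts, hsdS SSR
#' tracts, and hsdS inversion).
#'
#' @param percents Numeric vector of percentages, each in 0-100.
#' @return The summed percentage (numeric); warns when the sum exceeds 100,
#'   which indicates overlapping categories.
#' @examples
#' combined_phase_variable_percentage(c(2.0, 7.9, 3.9))  # 13.8
#' @export
combined_phase_variable_percentage <- function(percents) {
  stopifnot(is.numeric(percents), all(percents >= 0), all(percents <= 100))
  s <- sum(percents)
  if (s > 100)
    warning("combined percentage exceeds 100%; categories overlap",
            call. = FALSE)
  as.numeric(format_percent_truncated(s))
}

#' Write locus calls as TSV
#'
#' One row per call with the summary fields of each locus.
#'
#' @param calls List of `locus_call` objects.
#' @param path Output path.
#' @param organism,strain Optional vectors parallel to `calls`.
#' @return `path`, invisibly.
#' @export
write_calls_tsv <- function(calls, path, organism = NA, strain = NA) {
  df <- data.frame(
    organism = organism, strain = strain,
    gene_id = vapply(calls, function(x) x$gene_id, ""),
    category = vapply(calls, function(x) x$category, ""),
    n_hits = vapply(calls, function(x) nrow(x$hits), integer(1)),
    max_ir_len = vapply(calls, function(x)
      if (nrow(x$hits)) max(x$hits$length) else 0L, integer(1)),
    partner_gene_id = vapply(calls, function(x) x$partner_gene_id, ""),
    partner_is_silent = vapply(calls, function(x)
      as.character(x$partner_is_silent), ""),
    stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
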