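#' Categorize new-annotation genes against the old annotation
#'
#' Produces the gene-level annotation diff: each gene (locus) of the new
#' annotation receives exactly one category from the per-transcript class
#' codes and junction evidence of its transcripts, by the first matching
#' rule:
#'
#' 1. `flipped` — at least one transcript overlaps an old gene on the
#'    opposite strand *and* at least one of its junction coordinate pairs
#'    coincides (ignoring strand, within `junction_tolerance` nt per
#'    boundary) with an old junction;
#' 2. `novel` — every transcript has a novel class code (`u`, `x`, `i`,
#'    `y`);
#' 3. `unchanged` — every transcript is `=`;
#' 4. `novel_splice_variant` — at least one transcript is `=` and at least
#'    one is `j`;
#' 5. `all_junctions_differ` — no transcript is `=` and none shares any
#'    junction with the old annotation;
#' 6. `all_transcripts_differ` — no transcript is `=` but at least one
#'    junction is shared;
#' 7. `uncategorized` — anything else (mixtures involving mono-exon, `o`
#'    or `c` edge cases).
#'
#' Flipped is tested before novel: a gene whose transcripts reuse an old
#' gene's junction coordinates from the opposite strand would otherwise be
#' swallowed by the novel rule, and the two categories are meant to be
#' disjoint alternatives.
#'
#' Categories depend only on junctions and strand, never on UTR ends, so
#' extending a transcript's UTRs cannot change its gene's category.
#'
#' @param tx_codes A transcript table of the new annotation joined with its
#'   class codes: must carry columns `transcript_id`, `gene_id` (the
#'   locus), `chrom`, `strand`, `start`, `end` plus per-transcript
#'   `class_code`.
#' @param old_index A `reference_index` over the old annotation.
#' @param junction_tolerance Maximum per-boundary coordinate difference (nt)
#'   for the flipped rule's junction coincidence. Default 0 (exact).
#' @return A tibble `gene_id`, `category`, with evidence columns
#'   `n_transcripts`, `n_eq`, `n_j`, `n_novel`, `n_shared_junctions`.
#' @export
categorize_genes <- function(tx_codes, old_index, junction_tolerance = 0L) {
  stopifnot(inherits(old_index, "reference_index"))
  tx <- as_transcripts(tx_codes[, c(
    "transcript_id", "gene_id", "chrom", "strand", "start", "end"
  )])
  codes <- dplyr::distinct(
    tibble::as_tibble(tx_codes)[, c("transcript_id", "class_code")]
  )
  if (nrow(tx) == 0) {
    rlang::abort("categorize_genes() needs at least one transcript")
  }
  s <- tx_summary(tx)
  s <- dplyr::left_join(s, codes, by = "transcript_id")
  if (anyNA(s$class_code)) {
    rlang::abort("every transcript needs a class_code")
  }
  qi <- tx_introns(tx)

  # same-strand junction sharing with the old annotation
  shares_junction <- rep(FALSE, nrow(s))
  if (nrow(qi) > 0 && length(old_index$junction_keys) > 0) {
    hit <- paste(qi$chrom, qi$strand, qi$start, qi$end) %in%
      old_index$junction_keys
    shares_junction[match(
      unique(qi$transcript_id[hit]), s$transcript_id
    )] <- TRUE
  }

  # flipped evidence: opposite-strand gene-span overlap plus strand-blind
  # junction coincidence
  flipped_tx <- rep(FALSE, nrow(s))
  if (nrow(qi) > 0 && nrow(old_index$genes) > 0) {
    span_gr <- GenomicRanges::GRanges(
      s$chrom, IRanges::IRanges(s$start, s$end)
    )
    h <- suppressWarnings(GenomicRanges::findOverlaps(
      span_gr, old_index$gene_gr,
      ignore.strand = TRUE
    ))
    opp <- s$strand[S4Vectors::queryHits(h)] !=
      as.character(BiocGenerics::strand(old_index$gene_gr))[S4Vectors::subjectHits(h)]
    opp_overlap <- rep(FALSE, nrow(s))
    opp_overlap[unique(S4Vectors::queryHits(h)[opp])] <- TRUE

    junction_flip <- rep(FALSE, nrow(s))
    old_introns <- old_index$introns
    if (nrow(old_introns) > 0) {
      if (junction_tolerance == 0) {
        hit <- paste(qi$chrom, qi$start, qi$end) %in%
          unique(paste(old_introns$chrom, old_introns$start, old_introns$end))
      } else {
        cand <- dplyr::inner_join(
          tibble::tibble(
            chrom = qi$chrom, qs = qi$start, qe = qi$end,
            i = seq_len(nrow(qi))
          ),
          tibble::tibble(
            chrom = old_introns$chrom,
            rs = old_introns$start, re = old_introns$end
          ),
          by = "chrom", relationship = "many-to-many"
        )
        cand <- cand[
          abs(cand$qs - cand$rs) <= junction_tolerance &
            abs(cand$qe - cand$re) <= junction_tolerance,
        ]
        hit <- seq_len(nrow(qi)) %in% cand$i
      }
      junction_flip[match(
        unique(qi$transcript_id[hit]), s$transcript_id
      )] <- TRUE
    }
    flipped_tx <- opp_overlap & junction_flip
  }

  per_gene <- dplyr::summarise(
    dplyr::group_by(s, .data$gene_id),
    n_transcripts = dplyr::n(),
    n_eq = sum(.data$class_code == "="),
    n_j = sum(.data$class_code == "j"),
    n_novel = sum(.data$class_code %in% c("u", "x", "i", "y")),
    n_shared_junctions = sum(shares_junction[match(
      .data$transcript_id, s$transcript_id
    )]),
    any_flipped = any(flipped_tx[match(.data$transcript_id, s$transcript_id)]),
    .groups = "drop"
  )
  per_gene$category <- dplyr::case_when(
    per_gene$any_flipped ~ "flipped",
    per_gene$n_novel == per_gene$n_transcripts ~ "novel",
    per_gene$n_eq == per_gene$n_transcripts ~ "unchanged",
    per_gene$n_eq > 0 & per_gene$n_j > 0 ~ "novel_splice_variant",
    per_gene$n_eq == 0 & per_gene$n_shared_junctions == 0 ~ "all_junctions_differ",
    per_gene$n_eq == 0 & per_gene$n_shared_junctions > 0 ~ "all_transcripts_differ",
    TRUE ~ "uncategorized"
  )
  per_gene[, c(
    "gene_id", "category", "n_transcripts", "n_eq", "n_j",
    "n_novel", "n_shared_junctions"
  )]
}

#' Old-annotation genes with no expression evidence
#'
#' Lists the genes of the old annotation none of whose exons overlap, on
#' either strand, any merged transcript's genomic span — i.e. reference
#' genes for which the assembled transcriptome contains no transcript at
#' all. An old gene touched only by an antisense transcript counts as
#' detected.
#'
#' @param old_tx A transcript table of the old annotation. An optional
#'   `biotype` column (for example `"coding"`/`"noncoding"`) is carried
#'   through.
#' @param merged A `merged_tx` object or a transcript table of the merged
#'   assembly.
#' @return A tibble `gene_id` (old gene), `biotype` (`NA` if `old_tx` has
#'   no biotype column).
#' @export
detect_unexpressed <- function(old_tx, merged) {
  old_tx <- tibble::as_tibble(old_tx)
  biotype <- if ("biotype" %in% names(old_tx)) {
    dplyr::distinct(old_tx[, c("gene_id", "biotype")])
  } else {
    NULL
  }
  old <- as_transcripts(old_tx[, c(
    "transcript_id", "gene_id", "chrom", "strand", "start", "end"
  )])
  mtx <- if (inherits(merged, "merged_tx")) merged$transcripts else as_transcripts(merged)
  all_genes <- unique(old$gene_id)
  detected <- character(0)
  if (nrow(mtx) > 0 && nrow(old) > 0) {
    ms <- tx_summary(mtx)
    h <- suppressWarnings(GenomicRanges::findOverlaps(
      GenomicRanges::GRanges(old$chrom, IRanges::IRanges(old$start, old$end)),
      GenomicRanges::GRanges(ms$chrom, IRanges::IRanges(ms$start, ms$end)),
      ignore.strand = TRUE
    ))
    detected <- unique(old$gene_id[S4Vectors::queryHits(h)])
  }
  out <- tibble::tibble(gene_id = sort(setdiff(all_genes, detected)))
  if (!is.null(biotype)) {
    out <- dplyr::left_join(out, biotype, by = "gene_id")
  } else {
    out$biotype <- NA_character_
  }
  out
}
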