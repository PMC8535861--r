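#' Positionally classify noncoding transcripts relative to coding genes
#'
#' Assigns each noncoding transcript one positional category with respect
#' to the coding genes of the *new* annotation, by the first matching rule:
#'
#' 1. `intronic` — fully contained in a single intron of a coding
#'    transcript, on either strand (position, not orientation, defines this
#'    category);
#' 2. `sense_overlap` — at least 1 bp of exonic overlap with a same-strand
#'    coding exon;
#' 3. `antisense` — at least 1 bp of exonic overlap with an
#'    opposite-strand coding exon;
#' 4. `intergenic` — none of the above (a lincRNA).
#'
#' Overlap is exon-level, never gene-span-level: a transcript sitting in an
#' intron does not "overlap" the gene's exons.
#'
#' @param nc_tx A transcript table of noncoding transcripts.
#' @param coding_tx A transcript table of coding transcripts.
#' @return A tibble with one row per noncoding transcript:
#'   `transcript_id`, `nc_category`, plus the orientation evidence flags
#'   `sense_exon_overlap` and `antisense_exon_overlap` used for gene-level
#'   calls.
#' @export
classify_nc_transcripts <- function(nc_tx, coding_tx) {
  nc_tx <- as_transcripts(nc_tx)
  coding_tx <- as_transcripts(coding_tx)
  s <- tx_summary(nc_tx)
  if (nrow(s) == 0) {
    return(tibble::tibble(
      transcript_id = character(), nc_category = character(),
      sense_exon_overlap = logical(), antisense_exon_overlap = logical()
    ))
  }
  sense <- rep(FALSE, nrow(s))
  anti <- rep(FALSE, nrow(s))
  intronic <- rep(FALSE, nrow(s))
  if (nrow(coding_tx) > 0) {
    gr <- function(df) {
      GenomicRanges::GRanges(
        df$chrom, IRanges::IRanges(df$start, df$end),
        strand = df$strand
      )
    }
    span_gr <- gr(s)
    exon_gr <- gr(nc_tx)
    cod_exon_gr <- gr(coding_tx)
    cod_introns <- tx_introns(coding_tx)

    if (nrow(cod_introns) > 0) {
      h <- suppressWarnings(GenomicRanges::findOverlaps(
        span_gr, gr(cod_introns),
        type = "within", ignore.strand = TRUE
      ))
      intronic[unique(S4Vectors::queryHits(h))] <- TRUE
    }
    h <- suppressWarnings(GenomicRanges::findOverlaps(exon_gr, cod_exon_gr, ignore.strand = TRUE))
    if (length(h) > 0) {
      a <- match(
        nc_tx$transcript_id[S4Vectors::queryHits(h)],
        s$transcript_id
      )
      same <- nc_tx$strand[S4Vectors::queryHits(h)] ==
        coding_tx$strand[S4Vectors::subjectHits(h)]
      sense[unique(a[same])] <- TRUE
      anti[unique(a[!same])] <- TRUE
    }
  }
  tibble::tibble(
    transcript_id = s$transcript_id,
    nc_category = dplyr::case_when(
      intronic ~ "intronic",
      sense ~ "sense_overlap",
      anti ~ "antisense",
      TRUE ~ "intergenic"
    ),
    sense_exon_overlap = sense,
    antisense_exon_overlap = anti
  )
}

#' Gene-level positional category of noncoding genes
#'
#' Rolls transcript-level positional categories up to the noncoding gene: a
#' gene whose transcripts overlap coding exons on both strands (some sense
#' and some antisense, or one transcript overlapping on both) is
#' `sense_and_antisense`; otherwise the majority transcript label wins,
#' with ties broken by the precedence intronic > sense_overlap > antisense
#' > intergenic.
#'
#' @param nc_classified The output of [classify_nc_transcripts()] with an
#'   added `gene_id` column assigning each transcript to its noncoding
#'   gene.
#' @return A tibble `gene_id`, `nc_category`.
#' @export
classify_nc_genes <- function(nc_classified) {
  nc_classified <- tibble::as_tibble(nc_classified)
  stopifnot(all(c(
    "gene_id", "transcript_id", "nc_category",
    "sense_exon_overlap", "antisense_exon_overlap"
  ) %in% names(nc_classified)))
  if (nrow(nc_classified) == 0) {
    rlang::abort("classify_nc_genes() needs at least one classified transcript")
  }
  precedence <- c("intronic", "sense_overlap", "antisense", "intergenic")
  dplyr::summarise(
    dplyr::group_by(nc_classified, .data$gene_id),
    nc_category = {
      if (any(.data$sense_exon_overlap) && any(.data$antisense_exon_overlap)) {
        "sense_and_antisense"
      } else {
        n <- table(factor(.data$nc_category, levels = precedence))
        precedence[which.max(n)] # which.max: ties go to higher precedence
      }
    },
    .groups = "drop"
  )
}
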