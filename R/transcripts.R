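#' Transcript tables
#'
#' The whole package works on one tabular currency: a *transcript table*, a
#' tibble with one row per exon and columns `transcript_id`, `gene_id`,
#' `chrom`, `strand` (`"+"` or `"-"`), `start`, `end`. Coordinates are
#' 1-based and inclusive on both ends, the convention GTF itself and the
#' Bioconductor ranges stack use, so a single-exon row `start = 101,
#' end = 200` is a 100 nt exon. Exons of one transcript must lie on one
#' chromosome and strand, be non-overlapping and separated by gaps of at
#' least 1 nt (the introns).
#'
#' `as_transcripts()` validates a data frame and returns it normalised: rows
#' sorted by chromosome, transcript and genomic position, columns in
#' canonical order.
#'
#' @param x A data frame with columns `transcript_id`, `gene_id`, `chrom`,
#'   `strand`, `start`, `end`.
#' @return A tibble with the same columns, validated and sorted.
#' @examples
#' tx <- tibble::tibble(
#'   transcript_id = "t1", gene_id = "g1", chrom = "chr1", strand = "+",
#'   start = c(101, 301), end = c(200, 400)
#' )
#' as_transcripts(tx)
#' @export
as_transcripts <- function(x) {
  required <- c("transcript_id", "gene_id", "chrom", "strand", "start", "end")
  missing_cols <- setdiff(required, names(x))
  if (length(missing_cols) > 0) {
    rlang::abort(paste0(
      "transcript table is missing column(s): ",
      paste(missing_cols, collapse = ", ")
    ))
  }
  tx <- tibble::as_tibble(x)[required]
  tx$start <- as.integer(tx$start)
  tx$end <- as.integer(tx$end)
  if (nrow(tx) == 0) {
    return(tx)
  }
  if (anyNA(tx)) {
    rlang::abort("transcript table contains missing values")
  }
  if (!all(tx$strand %in% c("+", "-"))) {
    bad <- unique(tx$strand[!tx$strand %in% c("+", "-")])
    rlang::abort(paste0(
      "strand must be '+' or '-'; found: ",
      paste(bad, collapse = ", "),
      " (unstranded records are rejected, not guessed)"
    ))
  }
  if (any(tx$start < 1L) || any(tx$end < tx$start)) {
    rlang::abort("exons must satisfy 1 <= start <= end")
  }
  tx <- dplyr::arrange(tx, .data$chrom, .data$transcript_id, .data$start)

  # one chromosome and strand per transcript; exon gaps >= 1 nt
  per_tx <- dplyr::summarise(
    dplyr::group_by(tx, .data$transcript_id),
    n_chrom = dplyr::n_distinct(.data$chrom),
    n_strand = dplyr::n_distinct(.data$strand),
    n_gene = dplyr::n_distinct(.data$gene_id),
    overlap = any(.data$start[-1] <= .data$end[-dplyr::n()] + 1L),
    .groups = "drop"
  )
  bad <- per_tx$transcript_id[per_tx$n_chrom > 1 | per_tx$n_strand > 1]
  if (length(bad) > 0) {
    rlang::abort(paste0(
      "transcript(s) mix chromosomes or strands: ",
      paste(utils::head(bad, 5), collapse = ", ")
    ))
  }
  bad <- per_tx$transcript_id[per_tx$n_gene > 1]
  if (length(bad) > 0) {
    rlang::abort(paste0(
      "transcript(s) carry more than one gene_id: ",
      paste(utils::head(bad, 5), collapse = ", ")
    ))
  }
  bad <- per_tx$transcript_id[per_tx$overlap]
  if (length(bad) > 0) {
    rlang::abort(paste0(
      "transcript(s) have overlapping or adjacent exons: ",
      paste(utils::head(bad, 5), collapse = ", ")
    ))
  }
  tx
}

#' Per-transcript summary of a transcript table
#'
#' Collapses an exon-level transcript table to one row per transcript with
#' its genomic span, exon count, spliced length and intron-chain key. The
#' intron-chain key is the ordered list of intron coordinates rendered as a
#' string; two multi-exon transcripts on the same chromosome and strand are
#' structurally identical exactly when their keys agree.
#'
#' @param tx A transcript table (see [as_transcripts()]).
#' @return A tibble with columns `transcript_id`, `gene_id`, `chrom`,
#'   `strand`, `start`, `end`, `n_exons`, `spliced_length`, `chain`
#'   (the intron-chain key; `""` for mono-exon transcripts).
#' @export
tx_summary <- function(tx) {
  tx <- as_transcripts(tx)
  if (nrow(tx) == 0) {
    return(tibble::tibble(
      transcript_id = character(), gene_id = character(),
      chrom = character(), strand = character(),
      start = integer(), end = integer(),
      n_exons = integer(), spliced_length = integer(), chain = character()
    ))
  }
  out <- dplyr::summarise(
    dplyr::group_by(tx, .data$transcript_id),
    gene_id = .data$gene_id[1],
    chrom = .data$chrom[1],
    strand = .data$strand[1],
    n_exons = dplyr::n(),
    spliced_length = sum(.data$end - .data$start + 1L),
    chain = chain_key(.data$start, .data$end),
    # start/end last: assigning them would shadow the exon columns above
    start = min(.data$start),
    end = max(.data$end),
    .groups = "drop"
  )
  out[, c(
    "transcript_id", "gene_id", "chrom", "strand", "start", "end",
    "n_exons", "spliced_length", "chain"
  )]
}

# intron-chain key from sorted exon starts/ends of one transcript
chain_key <- function(starts, ends) {
  n <- length(starts)
  if (n < 2) {
    return("")
  }
  paste(ends[-n] + 1L, starts[-1] - 1L, sep = "-", collapse = ";")
}

#' Intron table of a transcript table
#'
#' @param tx A transcript table.
#' @return A tibble with one row per intron: `transcript_id`, `gene_id`,
#'   `chrom`, `strand`, `start`, `end` (1-based inclusive intron
#'   coordinates), `intron_index`.
#' @export
tx_introns <- function(tx) {
  tx <- as_transcripts(tx)
  n <- nrow(tx)
  if (n < 2) {
    return(tibble::tibble(
      transcript_id = character(), gene_id = character(),
      chrom = character(), strand = character(),
      start = integer(), end = integer(), intron_index = integer()
    ))
  }
  # rows are sorted by (chrom, transcript, start), so a transcript's exons
  # are contiguous; an intron sits between consecutive rows of one transcript
  same <- tx$transcript_id[-1] == tx$transcript_id[-n]
  out <- tibble::tibble(
    transcript_id = tx$transcript_id[-1][same],
    gene_id = tx$gene_id[-1][same],
    chrom = tx$chrom[-1][same],
    strand = tx$strand[-1][same],
    start = tx$end[-n][same] + 1L,
    end = tx$start[-1][same] - 1L
  )
  out$intron_index <- stats::ave(
    seq_len(nrow(out)), out$transcript_id, FUN = seq_along
  )
  out
}
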