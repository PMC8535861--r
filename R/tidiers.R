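#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a refined annotation
#'
#' Returns the per-transcript table of a [run_pipeline()] result: one row
#' per reliable transcript with its structure, class code, coding features,
#' positional category and isoform group.
#'
#' @param x A `tx_annotation` object.
#' @param ... Unused.
#' @return A tibble.
#' @exportS3Method generics::tidy
tidy.tx_annotation <- function(x, ...) {
  x$transcripts
}

#' One-row summary of a refined annotation
#'
#' The headline counts of a [run_pipeline()] result: reliable transcripts,
#' coding/noncoding splits, novel genes, multi-isoform genes and the
#' alternative-splicing percentage.
#'
#' @param x A `tx_annotation` object.
#' @param ... Unused.
#' @return A one-row tibble.
#' @exportS3Method generics::glance
glance.tx_annotation <- function(x, ...) {
  r <- x$report
  tibble::tibble(
    n_transcripts = r$n_transcripts,
    n_coding_transcripts = r$n_coding_transcripts,
    n_noncoding_transcripts = r$n_noncoding_transcripts,
    n_coding_genes = r$n_coding_genes,
    n_noncoding_genes = r$n_noncoding_genes,
    n_novel_transcripts = r$n_novel_transcripts,
    n_novel_genes = r$n_novel_genes,
    n_unexpressed = r$n_unexpressed,
    n_multi_isoform_genes = r$n_multi_isoform_genes,
    n_multi_isoform_transcripts = r$n_multi_isoform_transcripts,
    alt_splicing_percent = r$alt_splicing_percent,
    multi_isoform_transcript_percent = r$multi_isoform_transcript_percent
  )
}
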