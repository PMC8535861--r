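#' Plot class-code composition of the refined annotation
#'
#' Bar chart of transcript counts per structural class code, the analogue
#' of a merged-assembly comparison summary.
#'
#' @param annotation A `tx_annotation` from [run_pipeline()].
#' @return A ggplot object.
#' @export
plot_class_codes <- function(annotation) {
  stopifnot(inherits(annotation, "tx_annotation"))
  counts <- annotation$report$class_code_counts
  df <- tibble::tibble(
    class_code = factor(names(counts), levels = names(counts)),
    count = as.integer(counts)
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$class_code, y = .data$count)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(
      x = "class code", y = "transcripts",
      title = "Structural relation of merged transcripts to the old annotation"
    ) +
    ggplot2::theme_minimal()
}

#' Plot transcript length distributions, new annotation vs old
#'
#' Overlaid histograms of spliced transcript lengths of the refined
#' annotation and the old annotation's models. Because the refinement adds
#' UTRs to ORF-only gene models, the new distribution is shifted to longer
#' transcripts.
#'
#' @param annotation A `tx_annotation` from [run_pipeline()].
#' @param reference A transcript table of the old annotation.
#' @param binwidth Histogram bin width in nt. Default 100.
#' @return A ggplot object.
#' @export
plot_transcript_lengths <- function(annotation, reference, binwidth = 100) {
  stopifnot(inherits(annotation, "tx_annotation"))
  df <- dplyr::bind_rows(
    tibble::tibble(
      length = annotation$transcripts$spliced_length,
      set = "new annotation"
    ),
    tibble::tibble(
      length = tx_summary(reference)$spliced_length,
      set = "old annotation"
    )
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$length, fill = .data$set)) +
    ggplot2::geom_histogram(
      binwidth = binwidth, position = "identity", alpha = 0.6
    ) +
    ggplot2::labs(
      x = "spliced transcript length (nt)", y = "transcripts",
      title = "Transcript lengths: refined vs old annotation"
    ) +
    ggplot2::theme_minimal()
}

#' Plot the within-locus protein similarity distribution
#'
#' Histogram of all pairwise within-locus protein similarity scores. On
#' data with real isoforms plus unrelated locus neighbours this is bimodal;
#' the isoform cutoff (vertical line) sits in the valley.
#'
#' @param scores Output of [isoform_pair_scores()] (or a
#'   `tx_annotation`, whose scores are used).
#' @param cutoff Similarity cutoff to mark. Default 49.
#' @param bin_width Histogram bin width in percent. Default 10.
#' @return A ggplot object.
#' @export
plot_similarity_scores <- function(scores, cutoff = 49, bin_width = 10) {
  if (inherits(scores, "tx_annotation")) {
    scores <- scores$isoform_scores
  }
  h <- similarity_score_histogram(scores, bin_width = bin_width)
  ggplot2::ggplot(h, ggplot2::aes(
    x = (.data$bin_start + .data$bin_end) / 2, y = .data$count
  )) +
    ggplot2::geom_col(width = bin_width * 0.9, fill = "grey40") +
    ggplot2::geom_vline(xintercept = cutoff, linetype = "dashed", colour = "red") +
    ggplot2::labs(
      x = "pairwise protein similarity (%)", y = "pairs",
      title = "Within-locus protein similarity"
    ) +
    ggplot2::theme_minimal()
}

#' Plot gene-level annotation-diff categories
#'
#' Bar chart of new-annotation gene counts per diff category (unchanged,
#' novel splice variant, all transcripts differ, all junctions differ,
#' flipped, novel, uncategorized).
#'
#' @param annotation A `tx_annotation` from [run_pipeline()].
#' @return A ggplot object.
#' @export
plot_gene_categories <- function(annotation) {
  stopifnot(inherits(annotation, "tx_annotation"))
  counts <- annotation$report$gene_category_counts
  df <- tibble::tibble(
    category = factor(names(counts), levels = rev(names(counts))),
    count = as.integer(counts)
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$count, y = .data$category)) +
    ggplot2::geom_col(fill = "darkorange") +
    ggplot2::labs(
      x = "genes", y = NULL,
      title = "New-annotation genes vs the old annotation"
    ) +
    ggplot2::theme_minimal()
}

#' Autoplot method for refined annotations
#'
#' @param object A `tx_annotation` object.
#' @param type One of `"class_codes"`, `"categories"`, `"similarity"`.
#' @param ... Passed to the underlying plot function.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.tx_annotation <- function(object, type = c("class_codes", "categories", "similarity"), ...) {
  type <- match.arg(type)
  switch(type,
    class_codes = plot_class_codes(object),
    categories = plot_gene_categories(object),
    similarity = plot_similarity_scores(object, ...)
  )
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
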