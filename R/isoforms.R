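#' Percent similarity of two proteins under global alignment
#'
#' Aligns two protein sequences globally (Needleman-Wunsch with BLOSUM62
#' substitution scores, gap opening penalty 11, gap extension penalty 1 per
#' gap position) and returns 100 x identical aligned positions / alignment
#' length (gap columns included). Symmetric in its arguments.
#'
#' @param p1,p2 Non-empty amino-acid strings.
#' @return A percent similarity in \[0, 100\].
#' @examples
#' pairwise_similarity("MKVLA", "MKVLA") # 100
#' @export
pairwise_similarity <- function(p1, p2) {
  stopifnot(is.character(p1), is.character(p2), length(p1) == 1, length(p2) == 1)
  if (!nzchar(p1) || !nzchar(p2)) {
    rlang::abort("pairwise_similarity() needs non-empty proteins")
  }
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(p1), Biostrings::AAString(p2),
    type = "global",
    substitutionMatrix = blosum62_matrix(),
    gapOpening = 11, gapExtension = 1
  )
  aligned <- as.character(Biostrings::pattern(aln))
  100 * Biostrings::nmatch(aln) / nchar(aligned)
}

# BLOSUM62, fetched once per session from Biostrings' shipped copy
blosum62_matrix <- local({
  m <- NULL
  function() {
    if (is.null(m)) {
      e <- new.env()
      utils::data("BLOSUM62", package = "Biostrings", envir = e)
      m <<- e$BLOSUM62
    }
    m
  }
})

#' All-pairs protein similarity scores within loci
#'
#' Computes [pairwise_similarity()] for every unordered pair of proteins at
#' each locus. Loci are never compared with each other.
#'
#' @param proteins A data frame with columns `locus`, `transcript_id`,
#'   `protein`.
#' @return A tibble `locus`, `id1`, `id2`, `similarity` (with `id1 < id2`
#'   lexicographically).
#' @export
isoform_pair_scores <- function(proteins) {
  proteins <- tibble::as_tibble(proteins)
  stopifnot(all(c("locus", "transcript_id", "protein") %in% names(proteins)))
  by_locus <- split(proteins, proteins$locus)
  rows <- purrr::map(by_locus, function(p) {
    n <- nrow(p)
    if (n < 2) {
      return(NULL)
    }
    idx <- utils::combn(n, 2)
    tibble::tibble(
      locus = p$locus[1],
      id1 = pmin(p$transcript_id[idx[1, ]], p$transcript_id[idx[2, ]]),
      id2 = pmax(p$transcript_id[idx[1, ]], p$transcript_id[idx[2, ]]),
      similarity = purrr::map2_dbl(
        p$protein[idx[1, ]], p$protein[idx[2, ]], pairwise_similarity
      )
    )
  })
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0) {
    return(tibble::tibble(
      locus = character(), id1 = character(), id2 = character(),
      similarity = numeric()
    ))
  }
  dplyr::arrange(out, .data$locus, .data$id1, .data$id2)
}

#' Group coding transcripts into isoform groups by connectivity
#'
#' Within each locus, connects every pair of transcripts whose protein
#' similarity reaches the cutoff (default 49 percent, accepted at exactly
#' 49) and takes connected components as isoform groups: if A is similar to
#' B and B to C, all three are one group even when A and C score below the
#' cutoff. Singleton groups are allowed; loci are never merged. Each
#' group's representative is its longest-protein member (ties broken by
#' transcript identifier).
#'
#' @param proteins A data frame with columns `locus`, `transcript_id`,
#'   `protein`.
#' @param cutoff Similarity cutoff in percent; pairs scoring `>= cutoff`
#'   are connected. Default 49.
#' @param scores Optionally, precomputed [isoform_pair_scores()] output (to
#'   avoid aligning twice).
#' @return A tibble `locus`, `transcript_id`, `group_id`, `representative`
#'   (logical). Group ids are `<locus>.g<k>`, numbered within each locus by
#'   first member.
#' @export
group_isoforms <- function(proteins, cutoff = 49, scores = NULL) {
  proteins <- tibble::as_tibble(proteins)
  stopifnot(all(c("locus", "transcript_id", "protein") %in% names(proteins)))
  if (nrow(proteins) == 0) {
    return(tibble::tibble(
      locus = character(), transcript_id = character(),
      group_id = character(), representative = logical()
    ))
  }
  if (is.null(scores)) {
    scores <- isoform_pair_scores(proteins)
  }
  proteins <- dplyr::arrange(proteins, .data$locus, .data$transcript_id)
  edges <- scores[scores$similarity >= cutoff, ]
  g <- igraph::make_empty_graph(n = nrow(proteins), directed = FALSE)
  if (nrow(edges) > 0) {
    a <- match(edges$id1, proteins$transcript_id)
    b <- match(edges$id2, proteins$transcript_id)
    g <- igraph::add_edges(g, rbind(a, b))
  }
  member <- igraph::components(g)$membership
  out <- proteins
  out$.member <- member
  out <- dplyr::group_by(out, .data$locus)
  out <- dplyr::mutate(
    out,
    group_id = paste0(
      .data$locus[1], ".g",
      match(.data$.member, unique(.data$.member))
    )
  )
  out <- dplyr::ungroup(out)
  out <- dplyr::group_by(out, .data$group_id)
  out <- dplyr::mutate(
    out,
    representative = seq_along(.data$transcript_id) ==
      order(-nchar(.data$protein), .data$transcript_id)[1]
  )
  dplyr::ungroup(out)[, c("locus", "transcript_id", "group_id", "representative")]
}

#' Histogram of pairwise similarity scores
#'
#' Bins similarity percentages into fixed-width bins over \[0, 100\] (the
#' last bin is closed at 100). On data with genuine isoform pairs and
#' unrelated within-locus neighbours the distribution is bimodal — high
#' scores for true isoforms, low for unrelated proteins — which is what
#' motivates a cutoff between the modes.
#'
#' @param scores A numeric vector of percentages, or the output of
#'   [isoform_pair_scores()].
#' @param bin_width Bin width in percent (must divide 100). Default 10.
#' @return A tibble `bin_start`, `bin_end`, `count`.
#' @export
similarity_score_histogram <- function(scores, bin_width = 10) {
  if (is.data.frame(scores)) {
    scores <- scores$similarity
  }
  if (length(scores) == 0) {
    rlang::abort("similarity_score_histogram() needs at least one score")
  }
  if (100 %% bin_width != 0) {
    rlang::abort("bin_width must divide 100")
  }
  breaks <- seq(0, 100, by = bin_width)
  bin <- findInterval(scores, breaks, rightmost.closed = TRUE)
  tibble::tibble(
    bin_start = breaks[-length(breaks)],
    bin_end = breaks[-1],
    count = as.integer(table(factor(bin, levels = seq_len(length(breaks) - 1))))
  )
}

#' Report isoform pairs in the borderline similarity band
#'
#' Pairs scoring in the band just above the cutoff (49-60 by default) are
#' the ones most at risk of being spurious connections; this lists them for
#' review rather than leaving the check to manual inspection.
#'
#' @param scores Output of [isoform_pair_scores()].
#' @param lower,upper Inclusive band bounds in percent. Defaults 49 and 60.
#' @return The rows of `scores` whose similarity lies in the band.
#' @export
borderline_pairs <- function(scores, lower = 49, upper = 60) {
  scores <- tibble::as_tibble(scores)
  scores[scores$similarity >= lower & scores$similarity <= upper, ]
}

#' Group noncoding transcripts into genes by overlap
#'
#' Connects noncoding transcripts on the same chromosome and strand that
#' overlap by at least 1 bp of genomic span; connected components form the
#' noncoding genes. Opposite-strand overlap never joins transcripts.
#'
#' @param nc_tx A transcript table of noncoding transcripts.
#' @return A tibble `transcript_id`, `nc_gene_id` (ids `NCG_00001`, ...,
#'   numbered by chromosome and leftmost start).
#' @export
group_noncoding_by_overlap <- function(nc_tx) {
  nc_tx <- as_transcripts(nc_tx)
  s <- tx_summary(nc_tx)
  if (nrow(s) == 0) {
    return(tibble::tibble(transcript_id = character(), nc_gene_id = character()))
  }
  span_gr <- GenomicRanges::GRanges(
    s$chrom, IRanges::IRanges(s$start, s$end),
    strand = s$strand
  )
  h <- GenomicRanges::findOverlaps(span_gr, span_gr, ignore.strand = FALSE)
  g <- igraph::make_empty_graph(n = nrow(s), directed = FALSE)
  g <- igraph::add_edges(g, rbind(S4Vectors::queryHits(h), S4Vectors::subjectHits(h)))
  member <- igraph::components(g)$membership
  ord <- order(s$chrom, s$start, s$end, s$transcript_id)
  first_seen <- !duplicated(member[ord])
  ranks <- stats::setNames(seq_len(sum(first_seen)), member[ord][first_seen])
  tibble::tibble(
    transcript_id = s$transcript_id,
    nc_gene_id = sprintf("NCG_%05d", as.integer(ranks[as.character(member)]))
  )
}
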