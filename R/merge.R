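#' Merge per-sample transcript assemblies into a non-redundant transcriptome
#'
#' Collapses structurally identical transcripts across samples: multi-exon
#' transcripts with the same chromosome, strand and intron chain become one
#' transcript whose first-exon start is the minimum and last-exon end the
#' maximum over the contributors (so per-sample UTR-end variation widens the
#' model but never duplicates it); mono-exon transcripts collapse with other
#' mono-exon transcripts they overlap on the same strand, taking the union
#' interval. Distinct intron chains are never collapsed. Merged transcripts
#' receive locus-scoped serial identifiers (`XLOC_000001.1`, ...); the
#' original (sample, transcript) pairs are preserved as provenance.
#'
#' @param samples A list of transcript tables, one per sample. Names are
#'   used as sample identifiers (defaults to `sample_1`, `sample_2`, ...).
#' @return An object of class `merged_tx`: a list with elements
#'   `transcripts` (an exon-level transcript table whose `gene_id` is the
#'   locus tag) and `provenance` (a tibble `transcript_id`, `sample`,
#'   `source_id`).
#' @export
merge_samples <- function(samples) {
  if (!is.list(samples) || length(samples) == 0 || is.data.frame(samples)) {
    rlang::abort("merge_samples() needs a non-empty list of transcript tables")
  }
  if (is.null(names(samples)) || any(!nzchar(names(samples)))) {
    names(samples) <- paste0("sample_", seq_along(samples))
  }
  combined <- dplyr::bind_rows(
    purrr::imap(samples, function(tx, nm) {
      tx <- as_transcripts(tx)
      tx$sample <- nm
      tx
    })
  )
  if (nrow(combined) == 0) {
    empty <- as_transcripts(tibble::tibble(
      transcript_id = character(), gene_id = character(),
      chrom = character(), strand = character(),
      start = integer(), end = integer()
    ))
    return(structure(
      list(
        transcripts = empty,
        provenance = tibble::tibble(
          transcript_id = character(), sample = character(),
          source_id = character()
        )
      ),
      class = "merged_tx"
    ))
  }
  # summarise each (sample, transcript)
  info <- dplyr::summarise(
    dplyr::group_by(combined, .data$sample, .data$transcript_id),
    chrom = .data$chrom[1], strand = .data$strand[1],
    n_exons = dplyr::n(),
    chain = chain_key(.data$start, .data$end),
    # start/end last: assigning them would shadow the exon columns above
    start = min(.data$start), end = max(.data$end),
    .groups = "drop"
  )

  multi <- info[info$n_exons > 1, ]
  mono <- info[info$n_exons == 1, ]

  groups <- list()
  if (nrow(multi) > 0) {
    multi_grp <- dplyr::summarise(
      dplyr::group_by(multi, .data$chrom, .data$strand, .data$chain),
      start = min(.data$start), end = max(.data$end),
      members = list(tibble::tibble(sample = sample, source_id = transcript_id)),
      .groups = "drop"
    )
    groups <- c(groups, list(multi_grp))
  }
  if (nrow(mono) > 0) {
    mono <- dplyr::arrange(mono, .data$chrom, .data$strand, .data$start, .data$end)
    grp <- dplyr::group_by(mono, .data$chrom, .data$strand)
    mono <- dplyr::mutate(
      grp,
      comp = cumsum(.data$start > dplyr::lag(cummax(.data$end), default = -1L))
    )
    mono_grp <- dplyr::summarise(
      dplyr::ungroup(mono) |>
        dplyr::group_by(.data$chrom, .data$strand, .data$comp),
      start = min(.data$start), end = max(.data$end),
      members = list(tibble::tibble(sample = sample, source_id = transcript_id)),
      .groups = "drop"
    )
    mono_grp$chain <- ""
    groups <- c(groups, list(mono_grp[, c("chrom", "strand", "chain", "start", "end", "members")]))
  }
  merged <- dplyr::bind_rows(groups)
  merged <- dplyr::arrange(merged, .data$chrom, .data$start, .data$end, .data$chain)

  # rebuild exon structures from chain + outer ends
  merged$.row <- seq_len(nrow(merged))
  exons <- purrr::pmap(
    merged[, c("chain", "start", "end", ".row")],
    function(chain, start, end, .row) {
      b <- chain_bounds(chain, start, end)
      tibble::tibble(.row = .row, start = b$start, end = b$end)
    }
  )
  exons <- dplyr::bind_rows(exons)
  exons <- dplyr::left_join(
    exons, merged[, c(".row", "chrom", "strand")],
    by = ".row"
  )

  # locus-scoped serial ids: loci = same-strand exon-overlap or shared-junction
  # components of the merged set
  tmp_tx <- tibble::tibble(
    transcript_id = paste0("tmp", exons$.row),
    gene_id = "tmp",
    chrom = exons$chrom, strand = exons$strand,
    start = exons$start, end = exons$end
  )
  locus <- assign_loci(tmp_tx)
  merged$locus <- locus$locus[match(paste0("tmp", merged$.row), locus$transcript_id)]
  merged <- dplyr::group_by(merged, .data$locus)
  merged <- dplyr::mutate(merged, serial = dplyr::row_number())
  merged <- dplyr::ungroup(merged)
  merged$gene_id <- sprintf("XLOC_%06d", merged$locus)
  merged$transcript_id <- sprintf("%s.%d", merged$gene_id, merged$serial)

  out_exons <- dplyr::left_join(
    exons,
    merged[, c(".row", "transcript_id", "gene_id")],
    by = ".row"
  )
  transcripts <- as_transcripts(out_exons[, c(
    "transcript_id", "gene_id", "chrom", "strand", "start", "end"
  )])
  provenance <- tidyr::unnest(
    merged[, c("transcript_id", "members")],
    cols = "members"
  )
  structure(
    list(transcripts = transcripts, provenance = provenance),
    class = "merged_tx"
  )
}

# exon boundaries implied by an intron-chain key and outer span ends
chain_bounds <- function(chain, start, end) {
  if (!nzchar(chain)) {
    return(list(start = start, end = end))
  }
  introns <- do.call(rbind, strsplit(strsplit(chain, ";", fixed = TRUE)[[1]], "-", fixed = TRUE))
  is_ <- as.integer(introns[, 1])
  ie_ <- as.integer(introns[, 2])
  list(start = c(start, ie_ + 1L), end = c(is_ - 1L, end))
}

#' @export
print.merged_tx <- function(x, ...) {
  n_tx <- dplyr::n_distinct(x$transcripts$transcript_id)
  cat(
    "Merged transcriptome:", n_tx, "transcripts from",
    dplyr::n_distinct(x$provenance$sample), "sample(s)\n"
  )
  invisible(x)
}

#' Drop transcripts shorter than a minimum spliced length
#'
#' Applies the minimum-length filter of the merge stage: transcripts whose
#' spliced length (sum of exon lengths) is *shorter than* `min_length` are
#' excluded; a transcript of exactly `min_length` nt is retained. Order is
#' preserved.
#'
#' @param x A `merged_tx` object from [merge_samples()] or a plain
#'   transcript table.
#' @param min_length Minimum spliced length in nt to keep. Default 200.
#' @return The same type as `x`, with short transcripts (and their
#'   provenance) removed.
#' @export
filter_by_length <- function(x, min_length = 200L) {
  if (!is.numeric(min_length) || length(min_length) != 1 || min_length < 1) {
    rlang::abort("min_length must be a single number >= 1")
  }
  tx <- if (inherits(x, "merged_tx")) x$transcripts else as_transcripts(x)
  keep <- tx_summary(tx)
  keep_ids <- keep$transcript_id[keep$spliced_length >= min_length]
  tx <- tx[tx$transcript_id %in% keep_ids, ]
  if (inherits(x, "merged_tx")) {
    x$transcripts <- tx
    x$provenance <- x$provenance[x$provenance$transcript_id %in% keep_ids, ]
    return(x)
  }
  tx
}

#' Assign transcripts to loci by same-strand structural linkage
#'
#' Two transcripts belong to the same locus when they share a splice
#' junction or overlap exonically on the same strand; loci are the
#' connected components of that relation. Locus numbering is deterministic:
#' ordered by chromosome, then leftmost transcript start.
#'
#' @param tx A transcript table.
#' @return A tibble `transcript_id`, `locus` (integer).
#' @export
assign_loci <- function(tx) {
  tx <- as_transcripts(tx)
  s <- tx_summary(tx)
  if (nrow(s) == 0) {
    return(tibble::tibble(transcript_id = character(), locus = integer()))
  }
  exon_gr <- GenomicRanges::GRanges(
    tx$chrom, IRanges::IRanges(tx$start, tx$end),
    strand = tx$strand
  )
  hits <- GenomicRanges::findOverlaps(exon_gr, exon_gr, ignore.strand = FALSE)
  qi <- match(tx$transcript_id[S4Vectors::queryHits(hits)], s$transcript_id)
  si <- match(tx$transcript_id[S4Vectors::subjectHits(hits)], s$transcript_id)
  edges <- unique(cbind(qi, si))
  # shared junctions (already implied by exon overlap in most cases, but two
  # transcripts can share a junction while their exons only touch the
  # junction from opposite sides)
  introns <- tx_introns(tx)
  if (nrow(introns) > 0) {
    key <- paste(introns$chrom, introns$strand, introns$start, introns$end)
    jpairs <- dplyr::inner_join(
      tibble::tibble(key = key, a = match(introns$transcript_id, s$transcript_id)),
      tibble::tibble(key = key, b = match(introns$transcript_id, s$transcript_id)),
      by = "key", relationship = "many-to-many"
    )
    edges <- rbind(edges, unique(cbind(jpairs$a, jpairs$b)))
  }
  g <- igraph::make_empty_graph(n = nrow(s), directed = FALSE)
  if (nrow(edges) > 0) {
    g <- igraph::add_edges(g, t(edges))
  }
  member <- igraph::components(g)$membership
  # renumber components deterministically by (chrom, leftmost start)
  ord <- order(s$chrom, s$start, s$end, s$transcript_id)
  first_seen <- !duplicated(member[ord])
  ranks <- stats::setNames(seq_len(sum(first_seen)), member[ord][first_seen])
  tibble::tibble(
    transcript_id = s$transcript_id,
    locus = as.integer(ranks[as.character(member)])
  )
}
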